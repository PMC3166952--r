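#' @importFrom stats pnorm qnorm ks.test residuals
NULL

#' Per-class precision statistics
#'
#' For every integer copy-number class, the sample mean and SD (n-1
#' denominator) of the combined unrounded values of the samples assigned to
#' that class, the normalised SD (SD divided by the integer, which makes
#' precision comparable across classes), and the predicted probability of
#' integer misassignment under the Gaussian error model
#' (\code{\link{misclassProbability}}).
#'
#' Sparse classes are reported conservatively: with fewer than 2 samples
#' the SD is NA; with fewer than \code{minForProbability} samples the error
#' probability is NA (too little data to trust the fitted normal). For
#' class 0 only the upper misassignment boundary exists (negative values
#' clamp to 0), so its probability is one-sided and flagged
#' \code{one_sided}, not comparable with the other classes.
#'
#' @param calls a \linkS4class{PRTCallSet}, or a data.frame with columns
#'   \code{combined_value} and \code{integer_call}.
#' @param minForProbability minimum class size for reporting an error
#'   probability (default 5).
#' @return data.frame with columns \code{integer_cn, n_samples, mean, sd,
#'   normalised_sd, probability_of_error, one_sided}.
#' @examples
#' cfg <- PRTSimConfig(c("1" = 0.3, "2" = 0.5, "3" = 0.2),
#'                     nControls = 300, seed = 5)
#' calls <- callCopyNumbers(generatePeakTable(sampleGenotypes(cfg), cfg))
#' classStatistics(calls)
#' @export
classStatistics <- function(calls, minForProbability = 5L) {
  df <- .valuesAndCalls(calls)
  df <- df[!is.na(df$integer_call), , drop = FALSE]
  if (nrow(df) == 0L) stop("no resolved calls")
  out <- do.call(rbind, lapply(sort(unique(df$integer_call)), function(k) {
    v <- df$combined_value[df$integer_call == k]
    n <- length(v)
    s <- if (n >= 2L) sd(v) else NA_real_
    p <- if (n >= minForProbability && !is.na(s) && s > 0)
      misclassProbability(mean(v), s, k) else NA_real_
    data.frame(
      integer_cn = k, n_samples = n, mean = mean(v), sd = s,
      normalised_sd = if (k >= 1L && !is.na(s)) s / k else NA_real_,
      probability_of_error = p, one_sided = k == 0L
    )
  }))
  rownames(out) <- NULL
  out
}

.valuesAndCalls <- function(calls) {
  if (is(calls, "PRTCallSet")) {
    data.frame(combined_value = combinedValue(calls),
               integer_call = integerCall(calls),
               status = sampleStatus(calls),
               stringsAsFactors = FALSE)
  } else {
    stopifnot(all(c("combined_value", "integer_call") %in% names(calls)))
    calls
  }
}

#' Overall normalised precision of a dataset
#'
#' Each combined unrounded value is divided by its integer call
#' (classes >= 1 only; class 0 cannot be normalised) and the SD of these
#' normalised values is taken over the whole dataset, and per cohort.
#' A well-behaved PRT dataset sits below about 0.1 on this scale.
#'
#' @param calls a \linkS4class{PRTCallSet} or a data.frame as in
#'   \code{\link{classStatistics}}.
#' @return list with elements \code{overall} (scalar SD) and
#'   \code{per_cohort} (named vector, split by status label).
#' @export
datasetPrecision <- function(calls) {
  df <- .valuesAndCalls(calls)
  df <- df[!is.na(df$integer_call) & df$integer_call >= 1L, , drop = FALSE]
  if (nrow(df) < 2L) stop("need at least 2 eligible samples (CN >= 1)")
  z <- df$combined_value / df$integer_call
  per <- tapply(z, df$status, function(v) {
    if (length(v) >= 2L) sd(v) else NA_real_
  })
  list(overall = sd(z), per_cohort = c(per))
}

#' Gaussian probability of integer misassignment
#'
#' Under the model that unrounded measurements of true copy number \eqn{n}
#' are normal with the class mean \eqn{\mu} and SD \eqn{\sigma}, the
#' probability that a measurement falls outside the rounding window
#' \eqn{(n - 0.5,\; n + 0.5)} and is therefore assigned a wrong integer:
#' \deqn{P = \Phi\!\left(\frac{n-0.5-\mu}{\sigma}\right) + 1 -
#'   \Phi\!\left(\frac{n+0.5-\mu}{\sigma}\right).}
#' For \eqn{n = 0} only the upper boundary exists (negative values clamp
#' to 0), so \eqn{P = 1 - \Phi((0.5-\mu)/\sigma)}.
#'
#' @param mean class mean \eqn{\mu}.
#' @param sd class SD \eqn{\sigma} (> 0; a degenerate \code{sd = 0}
#'   distribution returns 0 with a warning).
#' @param integer_cn the integer class \eqn{n}.
#' @return misassignment probability in [0, 1]; vectorised over arguments.
#' @examples
#' misclassProbability(2.021, 0.142, 2)   # ~4.9e-4
#' misclassProbability(4.977, 0.346, 5)   # ~0.149
#' @export
misclassProbability <- function(mean, sd, integer_cn) {
  if (any(sd < 0)) stop("sd must be non-negative")
  if (any(sd == 0)) warning("degenerate distribution (sd = 0): probability 0")
  n <- integer_cn
  lower <- ifelse(n >= 1, pnorm((n - 0.5 - mean) / sd), 0)
  ## upper tail computed directly to keep precision for tiny probabilities
  upper <- pnorm((n + 0.5 - mean) / sd, lower.tail = FALSE)
  p <- ifelse(sd == 0, 0, lower + upper)
  pmin(pmax(p, 0), 1)
}

#' Kolmogorov-Smirnov normality check for one copy-number class
#'
#' Supports the Gaussian misclassification model: the combined unrounded
#' values of one integer class are tested against a normal distribution
#' with the class's estimated mean and SD (one-sample KS test; note the
#' parameters are estimated from the same data, as in the standard
#' practice this mirrors, so the p-value is approximate and mildly
#' conservative toward normality). Q-Q coordinates are returned for
#' plotting.
#'
#' @param calls a \linkS4class{PRTCallSet} or data.frame (see
#'   \code{\link{classStatistics}}).
#' @param integer_cn which class to test.
#' @param min_n minimum class size (default 10); smaller or degenerate
#'   classes return a skipped report.
#' @return list with \code{integer_cn, n, statistic, p_value, skipped,
#'   qq} (data.frame of theoretical vs sample quantiles).
#' @export
normalityCheck <- function(calls, integer_cn, min_n = 10L) {
  df <- .valuesAndCalls(calls)
  v <- df$combined_value[!is.na(df$integer_call) &
                           df$integer_call == integer_cn]
  skipped <- function(reason) {
    list(integer_cn = integer_cn, n = length(v), statistic = NA_real_,
         p_value = NA_real_, skipped = reason, qq = NULL)
  }
  if (length(v) < min_n) return(skipped("too few samples"))
  if (sd(v) == 0) return(skipped("degenerate (constant) values"))
  kt <- suppressWarnings(ks.test(v, "pnorm", mean(v), sd(v)))
  vs <- sort(v)
  pp <- (seq_along(vs) - 0.5) / length(vs)
  list(integer_cn = integer_cn, n = length(v),
       statistic = unname(kt$statistic), p_value = kt$p.value,
       skipped = NA_character_,
       qq = data.frame(theoretical = qnorm(pp, mean(v), sd(v)),
                       sample = vs))
}
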