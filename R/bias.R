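#' @importFrom stats t.test ecdf
NULL

.empiricalCDF <- function(v) {
  vs <- sort(v)
  data.frame(value = vs, cumulative = seq_along(vs) / length(vs))
}

#' Differential-bias test for one integer class
#'
#' Small systematic shifts of the raw (unrounded) measurements between
#' sample batches — e.g. case vs control DNA prepared by different
#' extraction methods — show up as shifted distributions around the same
#' integer. This compares case and control unrounded values within one
#' integer class by a two-tailed Welch t-test and returns empirical
#' cumulative-frequency curves for plotting. A shift of order 0.1 copies is
#' detectable well before it perturbs integer calling, which is exactly why
#' raw values, not integer calls, are compared.
#'
#' @param case_values,control_values unrounded values of the samples of one
#'   integer class, split by status (each of length >= 2).
#' @param integer_cn optional class label carried into the report.
#' @return object of class \code{prtBiasReport}: list with
#'   \code{integer_cn, case_n, control_n, case_mean, control_mean,
#'   t_statistic, df, p_value, curves} (list of two CDF data.frames).
#' @examples
#' set.seed(1)
#' biasTest(rnorm(100, 1.91, 0.16), rnorm(120, 2.03, 0.16), 2L)
#' @export
biasTest <- function(case_values, control_values, integer_cn = NA_integer_) {
  if (length(case_values) < 2L || length(control_values) < 2L)
    stop("each group needs at least 2 values")
  if (isTRUE(all.equal(sd(c(case_values, control_values)), 0))) {
    tt <- list(statistic = c(t = 0), parameter = c(df = NA_real_),
               p.value = 1)
  } else {
    tt <- t.test(case_values, control_values)
  }
  structure(list(
    integer_cn = integer_cn,
    case_n = length(case_values), control_n = length(control_values),
    case_mean = mean(case_values), control_mean = mean(control_values),
    t_statistic = unname(tt$statistic), df = unname(tt$parameter),
    p_value = tt$p.value,
    curves = list(case = .empiricalCDF(case_values),
                  control = .empiricalCDF(control_values))
  ), class = "prtBiasReport")
}

#' @export
print.prtBiasReport <- function(x, ...) {
  cat(sprintf(
    "Differential bias, class %s: cases mean %.3f (n=%d) vs controls %.3f (n=%d), t = %.2f, p = %.3g\n",
    ifelse(is.na(x$integer_cn), "?", x$integer_cn),
    x$case_mean, x$case_n, x$control_mean, x$control_n,
    x$t_statistic, x$p_value))
  invisible(x)
}

#' Homogeneity of the PRT systems within one class
#'
#' Before pooling systems into one combined value it must be checked that
#' the systems measure equivalently: within one integer class, the
#' per-system unrounded values are compared pairwise by two-tailed Welch
#' t-tests, and per-system CDF curves are returned. Heterogeneity here
#' would mean one system is differentially sensitive to DNA quality or PCR
#' efficiency and would bias the combined value.
#'
#' @param calls a \linkS4class{PRTCallSet}.
#' @param integer_cn the class to examine (typically the modal class).
#' @param min_n minimum per-system sample count (default 2).
#' @return list with \code{integer_cn}, \code{applicable} (FALSE when
#'   fewer than 2 systems have data), \code{pairwise} (data.frame
#'   system_a, system_b, t_statistic, p_value) and \code{curves} (named
#'   list of CDF data.frames).
#' @export
systemHomogeneity <- function(calls, integer_cn, min_n = 2L) {
  stopifnot(is(calls, "PRTCallSet"))
  sel <- !is.na(integerCall(calls)) & integerCall(calls) == integer_cn
  mat <- unroundedValues(calls)[, sel, drop = FALSE]
  perSys <- lapply(rownames(mat), function(s) {
    v <- mat[s, ]
    v[!is.na(v)]
  })
  names(perSys) <- rownames(mat)
  perSys <- perSys[vapply(perSys, length, integer(1)) >= min_n]
  if (length(perSys) < 2L) {
    return(list(integer_cn = integer_cn, applicable = FALSE,
                pairwise = NULL, curves = NULL))
  }
  pairs <- utils::combn(names(perSys), 2L)
  pw <- do.call(rbind, lapply(seq_len(ncol(pairs)), function(j) {
    a <- pairs[1L, j]; b <- pairs[2L, j]
    tt <- t.test(perSys[[a]], perSys[[b]])
    data.frame(system_a = a, system_b = b,
               t_statistic = unname(tt$statistic),
               p_value = tt$p.value, stringsAsFactors = FALSE)
  }))
  list(integer_cn = integer_cn, applicable = TRUE, pairwise = pw,
       curves = lapply(perSys, .empiricalCDF))
}

#' Scan every copy-number class for differential bias
#'
#' Runs \code{\link{biasTest}} on each integer class with at least
#' \code{min_n} cases and \code{min_n} controls. The most populated class
#' is flagged primary — it has the greatest power to expose a shift; the
#' other classes are secondary corroboration and their p-values are
#' reported unadjusted.
#'
#' @param calls a \linkS4class{PRTCallSet} with case and control samples.
#' @param min_n minimum per-group class size (default 5).
#' @return list with \code{table} (one row per tested class: integer_cn,
#'   case_n, control_n, case_mean, control_mean, t_statistic, p_value,
#'   primary) and \code{reports} (named list of \code{prtBiasReport}).
#' @examples
#' cfg <- PRTSimConfig(c("1" = 0.2, "2" = 0.6, "3" = 0.2),
#'                     nCases = 150, nControls = 150,
#'                     biasShift = -0.12, seed = 9)
#' calls <- callCopyNumbers(generatePeakTable(sampleGenotypes(cfg), cfg))
#' biasScan(calls)$table
#' @export
biasScan <- function(calls, min_n = 5L) {
  df <- .valuesAndCalls(calls)
  df <- df[!is.na(df$integer_call), , drop = FALSE]
  classes <- sort(unique(df$integer_call))
  reports <- list()
  for (k in classes) {
    cs <- df$combined_value[df$integer_call == k & df$status == "case"]
    ct <- df$combined_value[df$integer_call == k & df$status == "control"]
    if (length(cs) >= min_n && length(ct) >= min_n) {
      reports[[as.character(k)]] <- biasTest(cs, ct, as.integer(k))
    }
  }
  if (!length(reports)) {
    return(list(table = NULL, reports = reports))
  }
  tab <- do.call(rbind, lapply(reports, function(r) {
    data.frame(integer_cn = r$integer_cn, case_n = r$case_n,
               control_n = r$control_n, case_mean = r$case_mean,
               control_mean = r$control_mean,
               t_statistic = r$t_statistic, p_value = r$p_value)
  }))
  tab$primary <- with(tab, case_n + control_n == max(case_n + control_n))
  rownames(tab) <- NULL
  list(table = tab, reports = reports)
}
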