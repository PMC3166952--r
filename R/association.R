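#' @importFrom stats rmultinom pt qt
NULL

#' Bundled case-control copy-number count tables
#'
#' Published integer copy-number distributions for the CCL3L1/CCL4L1
#' copy-variable region in three European case-control cohorts: Crohn's
#' disease (616 cases vs 252 UK/CEPH controls), rheumatoid arthritis
#' (252 cases vs the same 252 controls) and psoriasis (195 Dutch cases vs
#' 265 Dutch controls). Shipped as plain TSV under \code{inst/extdata}.
#'
#' @param cohort one of \code{"crohn"}, \code{"rheumatoid"},
#'   \code{"psoriasis"}.
#' @return data.frame with columns \code{cn, case_count, control_count}.
#' @examples
#' cohortCounts("crohn")
#' @export
cohortCounts <- function(cohort = c("crohn", "rheumatoid", "psoriasis")) {
  cohort <- match.arg(cohort)
  f <- system.file("extdata", paste0(cohort, "_cohort_counts.tsv"),
                   package = "prtcnv", mustWork = TRUE)
  utils::read.delim(f)
}

#' Bundled per-class precision reference
#'
#' The published per-class summary (class size, mean, SD and predicted
#' probability of integer error) for 1581 European samples genotyped by
#' three-system PRT; used as a reference point for the Gaussian error
#' model. Classes with fewer than 5 samples have no SD/probability.
#'
#' @return data.frame with columns \code{integer_cn, n_samples, mean, sd,
#'   normalised_sd, probability_of_error}.
#' @export
referenceClassStats <- function() {
  f <- system.file("extdata", "ccl3l1_reference_class_stats.tsv",
                   package = "prtcnv", mustWork = TRUE)
  utils::read.delim(f)
}

## Welch t-test from per-class counts, vectorised over replicate columns.
## caseK, ctrlK: (classes x replicates) count matrices; cn: class values.
.welchFromCounts <- function(cn, caseK, ctrlK) {
  stat <- function(K) {
    n <- colSums(K)
    m <- colSums(K * cn) / n
    ss <- colSums(K * cn^2) - n * m^2
    list(n = n, mean = m, var = ss / (n - 1))
  }
  a <- stat(caseK); b <- stat(ctrlK)
  se2 <- a$var / a$n + b$var / b$n
  t <- (a$mean - b$mean) / sqrt(se2)
  df <- se2^2 / ((a$var / a$n)^2 / (a$n - 1) + (b$var / b$n)^2 / (b$n - 1))
  p <- 2 * pt(-abs(t), df)
  ## both groups constant and equal: define t = 0, p = 1
  degen <- se2 == 0
  t[degen] <- 0; p[degen] <- 1
  list(t = t, df = df, p = p,
       case_mean = a$mean, control_mean = b$mean)
}

#' Case-control association test on copy-number distributions
#'
#' Tests for a difference in mean integer copy number between cases and
#' controls with a two-tailed Welch t-test. The count table is expanded to
#' one integer value per individual and passed to \code{stats::t.test};
#' a \linkS4class{PRTCallSet} is first summarised into a count table from
#' its resolved integer calls.
#'
#' @param x a count data.frame (\code{cn, case_count, control_count}, as
#'   from \code{\link{cohortCounts}}) or a \linkS4class{PRTCallSet} whose
#'   status column distinguishes "case"/"control".
#' @return list with \code{t_statistic, df, p_value, case_mean,
#'   control_mean, case_n, control_n}.
#' @examples
#' associationTest(cohortCounts("crohn"))$p_value   # > 0.05
#' @export
associationTest <- function(x) {
  counts <- if (is(x, "PRTCallSet")) .countsFromCalls(x) else x
  stopifnot(all(c("cn", "case_count", "control_count") %in% names(counts)))
  caseV <- rep(counts$cn, counts$case_count)
  ctrlV <- rep(counts$cn, counts$control_count)
  if (length(caseV) < 2L || length(ctrlV) < 2L)
    stop("each group needs at least 2 individuals")
  if (sd(caseV) == 0 && sd(ctrlV) == 0) {
    ## both groups constant: Welch SE is 0, so the test degenerates to an
    ## exact comparison of the two constants
    same <- mean(caseV) == mean(ctrlV)
    return(list(t_statistic = if (same) 0 else
                  sign(mean(caseV) - mean(ctrlV)) * Inf,
                df = NA_real_, p_value = if (same) 1 else 0,
                case_mean = mean(caseV), control_mean = mean(ctrlV),
                case_n = length(caseV), control_n = length(ctrlV)))
  }
  tt <- t.test(caseV, ctrlV)
  list(t_statistic = unname(tt$statistic), df = unname(tt$parameter),
       p_value = tt$p.value,
       case_mean = mean(caseV), control_mean = mean(ctrlV),
       case_n = length(caseV), control_n = length(ctrlV))
}

.countsFromCalls <- function(calls) {
  ic <- integerCall(calls)
  st <- sampleStatus(calls)
  keep <- !is.na(ic) & st %in% c("case", "control")
  ic <- ic[keep]; st <- st[keep]
  cn <- sort(unique(ic))
  data.frame(
    cn = cn,
    case_count = as.integer(table(factor(ic[st == "case"], levels = cn))),
    control_count = as.integer(table(factor(ic[st == "control"],
                                            levels = cn)))
  )
}

#' Case copy-number distribution under a per-copy odds ratio
#'
#' The trend-effect model used for power analysis: each additional copy of
#' the variable gene multiplies the disease odds by \code{odds_ratio}, so
#' the case probability of carrying \eqn{c} copies is proportional to the
#' control probability times \eqn{\mathrm{OR}^c}, renormalised.
#'
#' @param control_distribution named numeric vector of control class
#'   probabilities (names = integer copy numbers; sums to 1).
#' @param odds_ratio positive per-copy odds multiplier.
#' @return named numeric vector: the implied case class distribution.
#' @examples
#' ctrl <- c("0" = 4, "1" = 49, "2" = 149, "3" = 45, "4" = 5) / 252
#' sum(as.numeric(names(ctrl)) * caseDistributionUnderOR(ctrl, 1.5))
#' @export
caseDistributionUnderOR <- function(control_distribution, odds_ratio) {
  stopifnot(odds_ratio > 0, all(control_distribution >= 0),
            abs(sum(control_distribution) - 1) < 1e-9)
  cn <- as.numeric(names(control_distribution))
  w <- control_distribution * odds_ratio^cn
  w / sum(w)
}

#' Simulation-based power of a case-control CNV association design
#'
#' For each replicate, case genotype counts are drawn multinomially from
#' the odds-ratio-tilted distribution
#' (\code{\link{caseDistributionUnderOR}}) and control counts from the
#' control distribution; a two-tailed Welch t-test compares mean copy
#' number, and power is the fraction of replicates rejecting at
#' \code{alpha}. The per-replicate test is algebraically identical to
#' \code{\link{associationTest}} on the expanded individuals, computed
#' from counts for speed.
#'
#' @param control_distribution named numeric vector of control class
#'   probabilities.
#' @param n_cases,n_controls cohort sizes.
#' @param odds_ratio per-copy odds ratio (1 = null).
#' @param alpha two-tailed significance level (default 0.05).
#' @param n_replicates Monte-Carlo replicates (default 10000).
#' @param seed integer seed; the result is deterministic given it.
#' @return list with \code{power}, \code{se} (binomial Monte-Carlo SE),
#'   \code{n_replicates}, \code{odds_ratio}, \code{alpha}.
#' @examples
#' ctrl <- c("0" = 4, "1" = 49, "2" = 149, "3" = 45, "4" = 5) / 252
#' powerSimulation(ctrl, 616, 252, odds_ratio = 1.5,
#'                 n_replicates = 2000, seed = 1)
#' @export
powerSimulation <- function(control_distribution, n_cases, n_controls,
                            odds_ratio, alpha = 0.05,
                            n_replicates = 10000L, seed = 1L) {
  stopifnot(n_cases >= 2L, n_controls >= 2L, alpha > 0, alpha < 1,
            n_replicates >= 1L)
  caseP <- caseDistributionUnderOR(control_distribution, odds_ratio)
  cn <- as.numeric(names(control_distribution))
  set.seed(as.integer(seed))
  caseK <- rmultinom(n_replicates, n_cases, caseP)
  ctrlK <- rmultinom(n_replicates, n_controls, control_distribution)
  w <- .welchFromCounts(cn, caseK, ctrlK)
  rej <- w$p < alpha
  power <- mean(rej)
  list(power = power,
       se = sqrt(power * (1 - power) / n_replicates),
       n_replicates = n_replicates, odds_ratio = odds_ratio,
       alpha = alpha)
}
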