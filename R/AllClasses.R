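#' @import methods
#' @importFrom S4Vectors DataFrame metadata metadata<-
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' Simulation configuration for synthetic PRT peak-area data
#'
#' Holds every parameter of the synthetic-data generator: the copy-number
#' class frequencies of the two cohorts, cohort sizes, the per-system noise
#' model on the unrounded copy-number axis, an optional systematic
#' case-vs-control shift (differential bias), and the layout of plates and
#' calibration standards.
#'
#' The noise model places error on the copy-number axis, not the
#' fluorescence axis: a measurement of a sample with true copy number
#' \eqn{c} has standard deviation \eqn{s(c) = \sqrt{\sigma_f^2 +
#' \sigma_0^2 c}}, so precision degrades with copy number roughly as
#' \eqn{\sigma_0\sqrt{c}} with an additive floor \eqn{\sigma_f} that keeps
#' zero-copy samples noisy. The error is split into a sample-level (DNA)
#' component shared by all PRT systems and repeat runs of the same sample,
#' and a smaller per-system component controlled by
#' \code{sigmaSystemFrac}.
#'
#' @slot controlFrequencies named numeric, copy-number class probabilities
#'   for controls (names are non-negative integers; must sum to 1).
#' @slot caseFrequencies named numeric, class probabilities for cases.
#' @slot nCases,nControls integer cohort sizes.
#' @slot systems character, PRT system labels (one multiplexed PCR measures
#'   all of them per sample).
#' @slot sigma0 numeric, per-copy noise scale on the copy-number axis.
#' @slot sigmaFloor numeric, additive noise floor (dominates at CN 0).
#' @slot sigmaSystemFrac numeric in [0, 1), fraction of the total
#'   measurement SD attributed to the per-system component.
#' @slot biasShift numeric, additive shift applied to the unrounded values
#'   of every case sample (copy-number units; e.g. -0.12).
#' @slot referenceBaseArea numeric, expected reference-locus peak area
#'   (arbitrary fluorescence units).
#' @slot refAreaCV numeric, log-normal sigma of the reference-area jitter.
#' @slot plateSize integer, unknown samples per 96-well plate (the
#'   remaining wells hold the 4 x 3 calibration standards).
#' @slot nDuplicates integer, number of samples re-run on a second plate.
#' @slot seed integer RNG seed.
#' @aliases PRTSimConfig-class
#' @exportClass PRTSimConfig
setClass("PRTSimConfig",
  representation(
    controlFrequencies = "numeric",
    caseFrequencies = "numeric",
    nCases = "integer",
    nControls = "integer",
    systems = "character",
    sigma0 = "numeric",
    sigmaFloor = "numeric",
    sigmaSystemFrac = "numeric",
    biasShift = "numeric",
    referenceBaseArea = "numeric",
    refAreaCV = "numeric",
    plateSize = "integer",
    nDuplicates = "integer",
    seed = "integer"
  )
)

.checkFrequencies <- function(f, what) {
  if (length(f) == 0L) return(sprintf("%s is empty", what))
  if (is.null(names(f))) return(sprintf("%s must be named by integer copy number", what))
  cn <- suppressWarnings(as.numeric(names(f)))
  if (anyNA(cn) || any(cn < 0) || any(cn != round(cn)))
    return(sprintf("%s names must be non-negative integers", what))
  if (any(f < 0)) return(sprintf("%s has negative probabilities", what))
  if (abs(sum(f) - 1) > 1e-9)
    return(sprintf("%s must sum to 1 (got %.12f)", what, sum(f)))
  NULL
}

setValidity("PRTSimConfig", function(object) {
  msgs <- c(
    .checkFrequencies(object@controlFrequencies, "controlFrequencies"),
    .checkFrequencies(object@caseFrequencies, "caseFrequencies")
  )
  if (object@nCases < 0L || object@nControls < 0L)
    msgs <- c(msgs, "cohort sizes must be non-negative")
  if (length(object@systems) < 1L || anyDuplicated(object@systems))
    msgs <- c(msgs, "need at least one uniquely named PRT system")
  if (object@sigma0 < 0 || object@sigmaFloor < 0)
    msgs <- c(msgs, "sigma0 and sigmaFloor must be >= 0")
  if (object@sigmaSystemFrac < 0 || object@sigmaSystemFrac >= 1)
    msgs <- c(msgs, "sigmaSystemFrac must lie in [0, 1)")
  if (object@referenceBaseArea <= 0)
    msgs <- c(msgs, "referenceBaseArea must be positive")
  if (object@refAreaCV < 0) msgs <- c(msgs, "refAreaCV must be >= 0")
  if (object@plateSize < 1L) msgs <- c(msgs, "plateSize must be >= 1")
  if (object@nDuplicates < 0L ||
      object@nDuplicates > object@nCases + object@nControls)
    msgs <- c(msgs, "nDuplicates must be between 0 and the number of samples")
  if (length(msgs)) msgs else TRUE
})

#' Construct a simulation configuration
#'
#' @param controlFrequencies named numeric vector of copy-number class
#'   probabilities for the control cohort, e.g.
#'   \code{c("0" = 4, "1" = 49, "2" = 149, "3" = 45, "4" = 5) / 252}.
#' @param caseFrequencies class probabilities for the case cohort; defaults
#'   to the control distribution (no association).
#' @param nCases,nControls cohort sizes.
#' @param systems PRT system labels; the default is the three-system
#'   CCL3L1/CCL4L1 multiplex (CCL3C, CCL4A, LTR61A).
#' @param sigma0 per-copy noise scale; the default 0.10 reproduces observed
#'   per-class SDs of roughly \eqn{0.10\sqrt{c}} (0.097, 0.142, 0.178,
#'   0.203 for classes 1-4).
#' @param sigmaFloor additive noise floor; the default 0.068 matches the
#'   SD observed for zero-copy samples.
#' @param sigmaSystemFrac fraction of the measurement SD that is
#'   system-specific rather than sample-specific (default 0.2).
#' @param biasShift additive shift of case unrounded values (default 0).
#' @param referenceBaseArea expected reference peak area (default 5000).
#' @param refAreaCV log-normal jitter of reference areas (default 0.15).
#' @param plateSize unknown samples per plate (default 84 = 96 wells minus
#'   the 12 standard wells).
#' @param nDuplicates samples measured again on a different plate.
#' @param seed integer RNG seed.
#' @return A validated \linkS4class{PRTSimConfig} object.
#' @examples
#' cfg <- PRTSimConfig(
#'   controlFrequencies = c("1" = 0.2, "2" = 0.6, "3" = 0.2),
#'   nCases = 50, nControls = 50, seed = 1
#' )
#' cfg
#' @export
PRTSimConfig <- function(controlFrequencies,
                         caseFrequencies = controlFrequencies,
                         nCases = 0L, nControls = 0L,
                         systems = c("CCL3C", "CCL4A", "LTR61A"),
                         sigma0 = 0.10, sigmaFloor = 0.068,
                         sigmaSystemFrac = 0.2, biasShift = 0,
                         referenceBaseArea = 5000, refAreaCV = 0.15,
                         plateSize = 84L, nDuplicates = 0L, seed = 1L) {
  new("PRTSimConfig",
    controlFrequencies = controlFrequencies,
    caseFrequencies = caseFrequencies,
    nCases = as.integer(nCases), nControls = as.integer(nControls),
    systems = systems,
    sigma0 = sigma0, sigmaFloor = sigmaFloor,
    sigmaSystemFrac = sigmaSystemFrac, biasShift = biasShift,
    referenceBaseArea = referenceBaseArea, refAreaCV = refAreaCV,
    plateSize = as.integer(plateSize),
    nDuplicates = as.integer(nDuplicates), seed = as.integer(seed)
  )
}

setMethod("show", "PRTSimConfig", function(object) {
  cat("PRTSimConfig\n")
  cat("  cohorts: ", object@nCases, " cases / ", object@nControls,
      " controls\n", sep = "")
  cat("  systems: ", paste(object@systems, collapse = ", "), "\n", sep = "")
  cat("  noise:   sigma0 =", object@sigma0, ", floor =", object@sigmaFloor,
      ", system frac =", object@sigmaSystemFrac, "\n")
  cat("  bias shift (cases):", object@biasShift, "\n")
  cat("  seed:", object@seed, "\n")
  invisible(NULL)
})

#' Container for PRT copy-number calls
#'
#' A \linkS4class{SummarizedExperiment} whose single assay,
#' \code{"unrounded"}, is a systems-by-samples matrix of calibrated
#' unrounded copy-number values (NA where a system failed for a sample).
#' Per-sample results live in \code{colData}: cohort/status labels, plate,
#' the combined (arithmetic-mean) unrounded value, the integer call,
#' the concordance class and the number of systems used.
#'
#' Use the accessors \code{\link{combinedValue}}, \code{\link{integerCall}},
#' \code{\link{concordance}}, \code{\link{nSystemsUsed}},
#' \code{\link{unroundedValues}} and \code{\link{sampleStatus}} rather than
#' touching slots directly.
#'
#' @aliases PRTCallSet-class
#' @exportClass PRTCallSet
setClass("PRTCallSet", contains = "SummarizedExperiment")

setValidity("PRTCallSet", function(object) {
  msgs <- character()
  if (!"unrounded" %in% SummarizedExperiment::assayNames(object))
    msgs <- c(msgs, "assay 'unrounded' is required")
  need <- c("cohort", "status", "combined_value", "integer_call",
            "concordance", "n_systems_used")
  miss <- setdiff(need, colnames(SummarizedExperiment::colData(object)))
  if (length(miss))
    msgs <- c(msgs, paste("missing colData columns:",
                          paste(miss, collapse = ", ")))
  if (!length(msgs)) {
    ic <- object$integer_call
    if (any(!is.na(ic) & ic < 0))
      msgs <- c(msgs, "resolved integer calls must be non-negative")
    cc <- object$concordance
    bad <- setdiff(unique(as.character(cc)), .concordanceLevels)
    if (length(bad))
      msgs <- c(msgs, paste("unknown concordance labels:",
                            paste(bad, collapse = ", ")))
  }
  if (length(msgs)) msgs else TRUE
})

.concordanceLevels <- c("concordant_05", "concordant_075", "discordant",
                        "missing")

setMethod("show", "PRTCallSet", function(object) {
  cc <- table(factor(object$concordance, levels = .concordanceLevels))
  cat("PRTCallSet with", ncol(object), "samples,", nrow(object),
      "PRT systems\n")
  cat("  systems:", paste(rownames(object), collapse = ", "), "\n")
  cat("  concordance: ", paste(sprintf("%s=%d", names(cc), cc),
                               collapse = ", "), "\n", sep = "")
  res <- !is.na(object$integer_call)
  cat("  resolved integer calls:", sum(res), "of", ncol(object), "\n")
  if (any(res)) {
    tab <- table(object$integer_call[res])
    cat("  integer classes: ", paste(sprintf("%s:%d", names(tab), tab),
                                     collapse = " "), "\n", sep = "")
  }
  invisible(NULL)
})
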