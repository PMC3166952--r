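#' @importFrom stats lm coef
NULL

#' Test/reference peak-area ratio
#'
#' The raw PRT signal: area of the copy-variable test-locus peak divided by
#' the area of the copy-constant reference-locus peak. Invalid records
#' (missing areas, non-positive reference area, negative test area) give NA
#' and are counted in the \code{"n_invalid"} attribute; downstream calling
#' drops them while still using the sample's remaining systems.
#'
#' @param test_area numeric vector of test-locus peak areas (>= 0).
#' @param ref_area numeric vector of reference-locus peak areas (> 0).
#' @return numeric vector of ratios with attribute \code{n_invalid}.
#' @examples
#' computeRatio(c(5000, 0, 7500), c(5000, 5000, 5000))
#' @export
computeRatio <- function(test_area, ref_area) {
  bad <- is.na(test_area) | is.na(ref_area) | ref_area <= 0 | test_area < 0
  r <- ifelse(bad, NA_real_, test_area / ref_area)
  attr(r, "n_invalid") <- sum(bad)
  r
}

## closed-form pieces shared by fit + diagnostics are delegated to lm();
## this wrapper enforces the PRT-specific contract (>= 2 CN levels,
## positive slope).
.fitLine <- function(cn, ratio) {
  fit <- lm(ratio ~ cn)
  ss_tot <- sum((ratio - mean(ratio))^2)
  r2 <- if (ss_tot > 0) 1 - sum(residuals(fit)^2) / ss_tot else 1
  c(slope = unname(coef(fit)[2L]), intercept = unname(coef(fit)[1L]),
    r_squared = r2)
}

#' Fit per-plate, per-system calibration lines from reference standards
#'
#' For every plate/system combination, the ratios of the calibration
#' standards (DNA samples of established copy number, CN 1-4 in triplicate
#' per plate) are regressed on their known copy numbers by ordinary least
#' squares, \eqn{\mathrm{ratio} = a\,\mathrm{CN} + b}. The fitted line is
#' later inverted to map unknown samples' ratios onto the copy-number
#' scale. Calibration is per plate so that batch effects in PCR efficiency
#' cannot leak across plates.
#'
#' Plate/system combinations with fewer than two distinct standard levels,
#' or a non-positive fitted slope, are rejected (their unknowns cannot be
#' calibrated) and reported via warning and the \code{"failed"} attribute.
#'
#' @param peaks a peak-area data.frame (see \code{\link{generatePeakTable}}
#'   for the layout); only rows with \code{is_standard == TRUE} are used.
#' @return data.frame with one row per calibrated plate/system:
#'   \code{plate, system, slope, intercept, n_points, n_levels, r_squared},
#'   plus attribute \code{failed} (data.frame of rejected combinations).
#' @examples
#' cfg <- PRTSimConfig(c("2" = 1), nControls = 4, seed = 3)
#' pk <- generatePeakTable(sampleGenotypes(cfg), cfg)
#' fitCalibration(pk)
#' @export
fitCalibration <- function(peaks) {
  std <- peaks[peaks$is_standard & !is.na(peaks$standard_cn), , drop = FALSE]
  if (nrow(std) == 0L) stop("no calibration standards in peak table")
  std$ratio <- computeRatio(std$test_area, std$ref_area)
  std <- std[!is.na(std$ratio), , drop = FALSE]
  keys <- unique(std[c("plate", "system")])
  rows <- vector("list", nrow(keys))
  failed <- list()
  for (i in seq_len(nrow(keys))) {
    sel <- std$plate == keys$plate[i] & std$system == keys$system[i]
    cn <- std$standard_cn[sel]
    ratio <- std$ratio[sel]
    if (length(unique(cn)) < 2L) {
      failed[[length(failed) + 1L]] <-
        data.frame(keys[i, ], reason = "fewer than 2 distinct CN levels")
      next
    }
    est <- .fitLine(cn, ratio)
    if (est[["slope"]] <= 0) {
      failed[[length(failed) + 1L]] <-
        data.frame(keys[i, ], reason = "non-positive slope")
      next
    }
    rows[[i]] <- data.frame(
      plate = keys$plate[i], system = keys$system[i],
      slope = est[["slope"]], intercept = est[["intercept"]],
      n_points = length(ratio), n_levels = length(unique(cn)),
      r_squared = est[["r_squared"]], stringsAsFactors = FALSE
    )
  }
  out <- do.call(rbind, rows[!vapply(rows, is.null, logical(1))])
  if (is.null(out)) stop("no plate/system could be calibrated")
  rownames(out) <- NULL
  failedDF <- if (length(failed)) do.call(rbind, failed) else NULL
  if (!is.null(failedDF)) {
    warning(sprintf("calibration failed for %d plate/system combination(s)",
                    nrow(failedDF)))
  }
  attr(out, "failed") <- failedDF
  out
}

#' Map a peak-area ratio onto the copy-number scale
#'
#' Inverts a fitted calibration line: \eqn{(\mathrm{ratio} - b) / a}.
#' The result may be slightly negative for zero-copy samples (real data
#' show a zero-class mean just below 0); negatives are kept for precision
#' statistics and only clamped at integer assignment.
#'
#' @param ratio numeric vector of test/reference ratios.
#' @param slope,intercept calibration coefficients (one row of
#'   \code{\link{fitCalibration}} output).
#' @return numeric vector of unrounded copy-number values.
#' @examples
#' calibrateValue(c(1, 0), slope = 0.5, intercept = 0.02)
#' @export
calibrateValue <- function(ratio, slope, intercept) {
  if (any(slope <= 0)) stop("calibration slope must be positive")
  (ratio - intercept) / slope
}

#' Combine per-system unrounded values into one estimate
#'
#' Arithmetic mean over the systems with a usable measurement; systems that
#' failed (NA) are omitted. A sample with no usable system is missing.
#'
#' @param values numeric vector of per-system unrounded values (may
#'   contain NA).
#' @return scalar mean, or NA if no value is present.
#' @examples
#' combineSystems(c(1.9, 2.1, 2.0))
#' @export
combineSystems <- function(values) {
  v <- values[!is.na(values)]
  if (!length(v)) return(NA_real_)
  mean(v)
}

#' Assign the integer copy number
#'
#' Nearest non-negative integer to the combined unrounded value. Germline
#' copy numbers are integers, so this is the genotype call. Exact half-way
#' values round away from zero; negative values (possible for zero-copy
#' samples via the calibration intercept) clamp to 0.
#'
#' @param x numeric vector of combined unrounded values.
#' @return integer vector (NA propagates) with attribute \code{boundary}, a
#'   logical vector flagging calls that sat within \code{1e-9} of a
#'   rounding boundary.
#' @examples
#' assignInteger(c(2.021, -0.033, 2.5))
#' @export
assignInteger <- function(x) {
  n <- ifelse(is.na(x), NA_integer_, as.integer(pmax(0, floor(x + 0.5))))
  frac <- abs(x - floor(x) - 0.5)
  attr(n, "boundary") <- !is.na(x) & frac < 1e-9 & x >= 0.5 - 1e-9
  n
}

#' Classify agreement of the PRT systems for one sample
#'
#' All systems' unrounded values are compared against the consensus integer
#' (the call derived from the combined mean). If every deviation is within
#' 0.5 the call is \code{concordant_05}; within 0.75, \code{concordant_075};
#' otherwise \code{discordant}, in which case the integer call is not
#' trusted (unresolved) unless an external resolution is supplied.
#' Categories are nested: every concordant_05 sample is also within 0.75.
#' Single-system calls cannot be cross-checked and are labelled
#' concordant_05 by convention (they are identifiable via
#' \code{n_systems_used == 1}).
#'
#' @param values per-system unrounded values for one sample (NA = failed).
#' @param integer_call the consensus integer for the sample.
#' @param thresholds the two nested agreement windows (default 0.5, 0.75).
#' @return one of \code{"concordant_05"}, \code{"concordant_075"},
#'   \code{"discordant"}, \code{"missing"}.
#' @examples
#' classifyConcordance(c(2.2, 1.8, 2.4), 2L)
#' classifyConcordance(c(2.6, 1.9, 2.0), 2L)
#' classifyConcordance(c(3.0, 1.9, 2.0), 2L)
#' @export
classifyConcordance <- function(values, integer_call,
                                thresholds = c(0.5, 0.75)) {
  stopifnot(length(thresholds) == 2L, thresholds[1] > 0,
            thresholds[1] < thresholds[2])
  v <- values[!is.na(values)]
  if (!length(v) || is.na(integer_call)) return("missing")
  if (length(v) == 1L) return("concordant_05")
  dev <- max(abs(v - integer_call))
  if (dev <= thresholds[1]) "concordant_05"
  else if (dev <= thresholds[2]) "concordant_075"
  else "discordant"
}

#' Call integer copy numbers from a peak-area table
#'
#' The full calling pipeline: per-record test/reference ratios, per-plate
#' per-system calibration against the CN 1-4 standards, inversion of the
#' calibration line to unrounded copy-number values, averaging of repeat
#' runs within a system, arithmetic-mean combination across systems,
#' integer assignment and concordance classification. Samples whose systems
#' disagree by more than the outer threshold are left unresolved (integer
#' call NA) unless \code{resolution} supplies an externally determined
#' integer (e.g. from microsatellite genotyping); samples with no usable
#' measurement are reported as missing, not dropped.
#'
#' Calling never looks at case/control status: cohort labels are carried
#' through untouched and only consulted by the association stage.
#'
#' @param peaks peak-area data.frame (native layout of
#'   \code{\link{generatePeakTable}} / \code{\link{readPeakTable}}).
#' @param calibration optional precomputed \code{\link{fitCalibration}}
#'   table; fitted from \code{peaks} when absent.
#' @param resolution optional data.frame \code{(sample_id, integer_call)}
#'   resolving discordant samples.
#' @param thresholds nested concordance windows, default \code{c(0.5, 0.75)}.
#' @return a \linkS4class{PRTCallSet}.
#' @examples
#' cfg <- PRTSimConfig(c("1" = 0.25, "2" = 0.5, "3" = 0.25),
#'                     nCases = 20, nControls = 20, seed = 11)
#' calls <- callCopyNumbers(generatePeakTable(sampleGenotypes(cfg), cfg))
#' calls
#' table(integerCall(calls))
#' @export
callCopyNumbers <- function(peaks, calibration = NULL, resolution = NULL,
                            thresholds = c(0.5, 0.75)) {
  if (is.null(calibration)) calibration <- fitCalibration(peaks)
  unk <- peaks[!peaks$is_standard, , drop = FALSE]
  if (nrow(unk) == 0L) stop("no unknown samples in peak table")
  unk$ratio <- computeRatio(unk$test_area, unk$ref_area)
  m <- match(paste(unk$plate, unk$system),
             paste(calibration$plate, calibration$system))
  slope <- calibration$slope[m]
  intercept <- calibration$intercept[m]
  unk$value <- ifelse(is.na(unk$ratio) | is.na(m), NA_real_,
                      (unk$ratio - intercept) / slope)

  samples <- unique(unk$sample_id)
  systems <- unique(peaks$system)
  ## mean over repeat runs within sample x system
  agg <- tapply(unk$value,
                list(factor(unk$system, levels = systems),
                     factor(unk$sample_id, levels = samples)),
                function(v) combineSystems(v))
  mat <- matrix(unlist(agg), nrow = length(systems),
                dimnames = list(systems, samples))

  meta <- unk[!duplicated(unk$sample_id),
              c("sample_id", "cohort", "status", "plate"), drop = FALSE]
  meta <- meta[match(samples, meta$sample_id), , drop = FALSE]

  obj <- PRTCallSet(mat, status = meta$status, cohort = meta$cohort,
                    plate = meta$plate, thresholds = thresholds,
                    resolution = resolution)
  metadata(obj)$calibration <- calibration
  obj
}

#' Build a PRTCallSet from calibrated per-system values
#'
#' Constructor for users who already have calibrated unrounded values (one
#' row per PRT system, one column per sample): combines systems, assigns
#' integers and classifies concordance exactly as
#' \code{\link{callCopyNumbers}} does after calibration.
#'
#' @param values numeric matrix, systems x samples (dimnames required;
#'   NA marks a failed measurement).
#' @param status character vector of sample status labels
#'   ("case"/"control"/other), recycled if scalar.
#' @param cohort cohort labels, default equal to \code{status}.
#' @param plate plate labels, default "P01".
#' @param thresholds nested concordance windows.
#' @param resolution optional data.frame \code{(sample_id, integer_call)}
#'   for discordant samples.
#' @return a \linkS4class{PRTCallSet}.
#' @examples
#' m <- rbind(CCL3C = c(2.2, 1.1), CCL4A = c(1.8, 0.9),
#'            LTR61A = c(2.4, 1.0))
#' colnames(m) <- c("A", "B")
#' PRTCallSet(m, status = "control")
#' @export
PRTCallSet <- function(values, status, cohort = status, plate = "P01",
                       thresholds = c(0.5, 0.75), resolution = NULL) {
  stopifnot(is.matrix(values), !is.null(colnames(values)),
            !is.null(rownames(values)))
  samples <- colnames(values)
  n <- length(samples)
  status <- rep_len(status, n)
  cohort <- rep_len(cohort, n)
  plate <- rep_len(plate, n)

  combined <- apply(values, 2L, combineSystems)
  nUsed <- colSums(!is.na(values))
  intcall <- assignInteger(combined)
  boundary <- attr(intcall, "boundary")
  conc <- vapply(seq_len(n), function(j) {
    classifyConcordance(values[, j], intcall[j], thresholds)
  }, character(1))

  ## discordant samples are unresolved unless externally resolved
  intcall[conc == "discordant"] <- NA_integer_
  if (!is.null(resolution)) {
    r <- match(samples, resolution$sample_id)
    ext <- !is.na(r) & conc == "discordant"
    intcall[ext] <- as.integer(resolution$integer_call[r[ext]])
  }

  cd <- S4Vectors::DataFrame(
    cohort = cohort, status = status, plate = plate,
    combined_value = unname(combined),
    integer_call = as.integer(intcall),
    concordance = unname(conc),
    n_systems_used = unname(as.integer(nUsed)),
    boundary_call = unname(boundary),
    row.names = samples
  )
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(unrounded = values), colData = cd
  )
  obj <- new("PRTCallSet", se)
  metadata(obj)$thresholds <- thresholds
  obj
}

#' Read and write call tables
#'
#' Flat TSV rendering of a \linkS4class{PRTCallSet}: one row per sample
#' with per-system unrounded values (\code{value_<system>} columns), the
#' combined value, integer call ("unresolved"/"missing" where NA),
#' concordance and number of systems used. Numeric columns are serialised
#' at full precision so that identical analyses give byte-identical files.
#'
#' @param calls a \linkS4class{PRTCallSet}.
#' @param file output path.
#' @return \code{writeCallTable}: the path, invisibly.
#'   \code{callTable}: the data.frame rendering itself.
#' @export
callTable <- function(calls) {
  mat <- unroundedValues(calls)
  df <- data.frame(sample_id = colnames(calls),
                   cohort = calls$cohort, status = calls$status,
                   stringsAsFactors = FALSE)
  for (s in rownames(mat)) df[[paste0("value_", s)]] <- mat[s, ]
  ic <- integerCall(calls)
  df$combined_value <- combinedValue(calls)
  df$integer_call <- ifelse(is.na(ic),
                            ifelse(concordance(calls) == "missing",
                                   "missing", "unresolved"),
                            as.character(ic))
  df$concordance <- as.character(concordance(calls))
  df$n_systems_used <- nSystemsUsed(calls)
  rownames(df) <- NULL
  df
}

#' @rdname callTable
#' @export
writeCallTable <- function(calls, file) {
  df <- callTable(calls)
  num <- vapply(df, is.numeric, logical(1))
  df[num] <- lapply(df[num], function(x) sprintf("%.10g", x))
  utils::write.table(df, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}
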