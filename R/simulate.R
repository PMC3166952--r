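#' @importFrom stats rnorm rbinom setNames sd
NULL

## total measurement SD on the copy-number axis for true copy number cn
.noiseSD <- function(cn, sigma0, sigmaFloor) {
  sqrt(sigmaFloor^2 + sigma0^2 * cn)
}

#' Draw true genotypes for a simulated case-control cohort
#'
#' Each individual's diploid copy number is drawn independently from the
#' cohort's class-frequency table (a multinomial model on diploid totals;
#' no haplotype structure is imposed). Case and control samples are
#' randomly interleaved in the output order, which is the plating order
#' used by \code{\link{generatePeakTable}} — mirroring the lab practice of
#' interspersing cases and controls within plates and genotyping blind to
#' status.
#'
#' @param config a \linkS4class{PRTSimConfig}.
#' @return data.frame with columns \code{sample_id}, \code{status}
#'   ("case"/"control") and \code{true_cn}; one row per individual,
#'   deterministic given \code{config@seed}.
#' @examples
#' cfg <- PRTSimConfig(c("2" = 1), nCases = 3, nControls = 2, seed = 7)
#' sampleGenotypes(cfg)
#' @export
sampleGenotypes <- function(config) {
  stopifnot(is(config, "PRTSimConfig"))
  validObject(config)
  set.seed(config@seed)
  drawCohort <- function(freq, n) {
    cn <- as.integer(names(freq))
    if (n == 0L) return(integer(0))
    cn[sample.int(length(cn), n, replace = TRUE, prob = freq)]
  }
  caseCN <- drawCohort(config@caseFrequencies, config@nCases)
  ctrlCN <- drawCohort(config@controlFrequencies, config@nControls)
  n <- length(caseCN) + length(ctrlCN)
  if (n == 0L) {
    return(data.frame(sample_id = character(0), status = character(0),
                      true_cn = integer(0), stringsAsFactors = FALSE))
  }
  status <- c(rep("case", length(caseCN)), rep("control", length(ctrlCN)))
  cn <- c(caseCN, ctrlCN)
  ord <- sample.int(n)  # blind interleaving of cases and controls
  data.frame(
    sample_id = sprintf("S%05d", seq_len(n)),
    status = status[ord],
    true_cn = cn[ord],
    stringsAsFactors = FALSE
  )
}

## per-plate instrument response: ratio = slope * value + intercept
.plateResponse <- function(nPlates, systems) {
  resp <- expand.grid(plate = sprintf("P%02d", seq_len(nPlates)),
                      system = systems, stringsAsFactors = FALSE)
  resp$slope <- 0.5 * exp(rnorm(nrow(resp), 0, 0.05))
  ## non-negative intercept keeps the implied test peak physical (>= 0)
  ## for every non-negative copy-number value
  resp$intercept <- abs(rnorm(nrow(resp), 0, 0.02))
  resp
}

#' Generate a synthetic peak-area table from true genotypes
#'
#' Inverts the measurement model: for every sample and PRT system a noisy
#' unrounded copy-number value is drawn, mapped through a per-plate,
#' per-system linear response to a test/reference peak-area ratio, and
#' rendered as a pair of fluorescence peak areas. Calibration standards of
#' known copy number (CN 1-4, in triplicate) are added to every plate, so
#' the full calling pipeline — per-plate regression, calibration,
#' combination, integer assignment — can run on the output.
#'
#' The unrounded value for a measurement of a sample with true copy number
#' \eqn{c} is \eqn{c + b\,[\mathrm{case}] + \epsilon_{\mathrm{sample}} +
#' \epsilon_{\mathrm{system}}}, where \eqn{b} is \code{biasShift},
#' \eqn{\epsilon_{\mathrm{sample}}} (drawn once per sample, shared by all
#' systems and repeat runs — measurement error tied to the DNA preparation)
#' has SD \eqn{s(c)\sqrt{1-\rho^2}} and \eqn{\epsilon_{\mathrm{system}}}
#' (independent per measurement) has SD \eqn{s(c)\rho}, with
#' \eqn{s(c) = \sqrt{\sigma_f^2 + \sigma_0^2 c}} and
#' \eqn{\rho =} \code{sigmaSystemFrac}. Each single-system measurement
#' therefore has SD exactly \eqn{s(c)}.
#'
#' Negative implied ratios (possible for zero-copy samples) are clamped at
#' a zero test peak; slightly negative calibrated values can still arise
#' downstream through the calibration intercept, as observed for real
#' zero-copy samples.
#'
#' @param genotypes data.frame from \code{\link{sampleGenotypes}} (columns
#'   sample_id, status, true_cn).
#' @param config the same \linkS4class{PRTSimConfig}.
#' @return data.frame with columns \code{sample_id}, \code{cohort},
#'   \code{status}, \code{system}, \code{plate}, \code{test_area},
#'   \code{ref_area}, \code{is_standard}, \code{standard_cn}. Unknown
#'   samples carry status "case"/"control"; standards carry status
#'   "reference" and their known \code{standard_cn}. Deterministic given
#'   \code{config@seed}.
#' @examples
#' cfg <- PRTSimConfig(c("2" = 1), nCases = 0, nControls = 4, seed = 2)
#' pk <- generatePeakTable(sampleGenotypes(cfg), cfg)
#' head(pk)
#' @export
generatePeakTable <- function(genotypes, config) {
  stopifnot(is(config, "PRTSimConfig"))
  validObject(config)
  if (nrow(genotypes) == 0L) stop("genotypes is empty")
  set.seed((config@seed + 1L) %% .Machine$integer.max)

  systems <- config@systems
  nSys <- length(systems)
  n <- nrow(genotypes)
  plateIdx <- ceiling(seq_len(n) / config@plateSize)
  nPlates <- max(plateIdx)

  ## duplicate runs: first nDuplicates samples get a second run on the
  ## following plate (wrapping), or on an extra plate if only one exists
  dupIdx <- seq_len(min(config@nDuplicates, n))
  dupPlate <- integer(0)
  if (length(dupIdx)) {
    if (nPlates == 1L) {
      dupPlate <- rep(2L, length(dupIdx))
      nPlates <- 2L
    } else {
      dupPlate <- plateIdx[dupIdx] %% nPlates + 1L
    }
  }

  resp <- .plateResponse(nPlates, systems)

  s <- .noiseSD(genotypes$true_cn, config@sigma0, config@sigmaFloor)
  rho <- config@sigmaSystemFrac
  epsSample <- rnorm(n, 0, s * sqrt(1 - rho^2))
  shift <- ifelse(genotypes$status == "case", config@biasShift, 0)
  base <- genotypes$true_cn + shift + epsSample

  measureRun <- function(idx, plates) {
    ## one run = nSys measurements per sample in idx, on given plates
    k <- length(idx)
    df <- data.frame(
      sample_id = rep(genotypes$sample_id[idx], each = nSys),
      cohort = rep(ifelse(genotypes$status[idx] == "case",
                          "case_cohort", "control_cohort"), each = nSys),
      status = rep(genotypes$status[idx], each = nSys),
      system = rep(systems, times = k),
      plate = rep(sprintf("P%02d", plates), each = nSys),
      stringsAsFactors = FALSE
    )
    value <- rep(base[idx], each = nSys) +
      rnorm(k * nSys, 0, rep(s[idx], each = nSys) * rho)
    m <- match(paste(df$plate, df$system),
               paste(resp$plate, resp$system))
    ratio <- pmax(0, resp$slope[m] * value + resp$intercept[m])
    df$ref_area <- config@referenceBaseArea *
      exp(rnorm(k * nSys, 0, config@refAreaCV))
    df$test_area <- df$ref_area * ratio
    df$is_standard <- FALSE
    df$standard_cn <- NA_integer_
    df
  }

  standardsRun <- function(plate) {
    cn <- rep(1:4, each = 3L)
    rep_no <- rep(1:3, times = 4L)
    df <- data.frame(
      sample_id = sprintf("STD%d_R%d", cn, rep_no),
      cohort = "standard", status = "reference",
      system = rep(systems, each = 12L),
      plate = sprintf("P%02d", plate),
      stringsAsFactors = FALSE
    )
    cnAll <- rep(cn, times = nSys)
    value <- cnAll + rnorm(12L * nSys, 0,
                           .noiseSD(cnAll, config@sigma0, config@sigmaFloor))
    m <- match(paste(df$plate, df$system),
               paste(resp$plate, resp$system))
    ratio <- pmax(0, resp$slope[m] * value + resp$intercept[m])
    df$ref_area <- config@referenceBaseArea *
      exp(rnorm(12L * nSys, 0, config@refAreaCV))
    df$test_area <- df$ref_area * ratio
    df$is_standard <- TRUE
    df$standard_cn <- cnAll
    df
  }

  parts <- list(measureRun(seq_len(n), plateIdx))
  if (length(dupIdx)) parts <- c(parts, list(measureRun(dupIdx, dupPlate)))
  parts <- c(parts, lapply(seq_len(nPlates), standardsRun))
  out <- do.call(rbind, parts)
  rownames(out) <- NULL
  out[order(out$plate, out$is_standard, out$sample_id, out$system), ,
      drop = FALSE]
}

#' Read and write peak-area tables
#'
#' The native format is tab-separated text with header columns
#' \code{sample_id, cohort, status, system, plate, test_area, ref_area,
#' is_standard, standard_cn}. \code{readPeakTable} also accepts a minimal
#' fragment-analysis export dialect with columns \code{sample_name,
#' test_area, ref_area}, where \code{sample_name} is
#' \code{<sample>_<system>} and standards are named
#' \code{STD<cn>...}; such records are assigned to a single plate.
#'
#' @param peaks data.frame as produced by \code{\link{generatePeakTable}}.
#' @param file path to a TSV file.
#' @return \code{readPeakTable}: a peak-area data.frame in the native
#'   layout. \code{writePeakTable}: the file path, invisibly.
#' @export
writePeakTable <- function(peaks, file) {
  utils::write.table(peaks, file, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(file)
}

#' @rdname writePeakTable
#' @export
readPeakTable <- function(file) {
  df <- utils::read.delim(file, stringsAsFactors = FALSE)
  native <- c("sample_id", "cohort", "status", "system", "plate",
              "test_area", "ref_area", "is_standard", "standard_cn")
  if (all(native %in% names(df))) {
    df$is_standard <- as.logical(df$is_standard)
    return(df[native])
  }
  if (all(c("sample_name", "test_area", "ref_area") %in% names(df))) {
    key <- df$sample_name
    pos <- regexpr("_[^_]+$", key)
    if (any(pos < 0))
      stop("sample_name must be of the form <sample>_<system>")
    sample_id <- substr(key, 1L, pos - 1L)
    system <- substring(key, pos + 1L)
    isStd <- grepl("^STD[0-9]", sample_id)
    stdCN <- rep(NA_integer_, length(sample_id))
    stdCN[isStd] <- as.integer(sub("^STD([0-9]+).*$", "\\1",
                                   sample_id[isStd]))
    return(data.frame(
      sample_id = sample_id,
      cohort = ifelse(isStd, "standard", "unknown"),
      status = ifelse(isStd, "reference", "unknown"),
      system = system, plate = "P01",
      test_area = df$test_area, ref_area = df$ref_area,
      is_standard = isStd, standard_cn = stdCN,
      stringsAsFactors = FALSE
    ))
  }
  stop("unrecognised peak-table format: ", file)
}
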