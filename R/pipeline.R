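#' @importFrom jsonlite write_json
#' @importFrom yaml read_yaml
#' @importFrom tools md5sum
NULL

#' Run the full PRT analysis pipeline
#'
#' Executes simulate (optional) -> call -> qc -> bias -> assoc as one
#' reproducible run, writing every stage's table plus a JSON manifest to
#' \code{out_dir}. All randomness flows from the single seed recorded in
#' the manifest, so repeating a run with the same configuration gives
#' byte-identical call tables. Stage code before the association stage
#' never branches on case/control status; samples are processed
#' interleaved and blind.
#'
#' @param config a named list, or the path of a YAML file holding one.
#'   Recognised entries:
#'   \describe{
#'     \item{simulate}{list of \code{\link{PRTSimConfig}} arguments
#'       (with \code{controlFrequencies}/\code{caseFrequencies} as named
#'       maps); omit to analyse an existing peak table.}
#'     \item{peaks}{path of a peak-area TSV (required when
#'       \code{simulate} is absent).}
#'     \item{resolution}{optional path of a TSV with columns
#'       \code{sample_id, integer_call} resolving discordant samples.}
#'     \item{thresholds}{concordance windows, default \code{c(0.5, 0.75)}.}
#'     \item{alpha}{association significance level, default 0.05.}
#'     \item{seed}{integer seed, default 1.}
#'   }
#' @param out_dir output directory (created if absent).
#' @return the manifest, invisibly: a list recording package version,
#'   seed, per-stage output files and input digests.
#' @examples
#' cfg <- list(
#'   simulate = list(
#'     controlFrequencies = c("1" = 0.2, "2" = 0.6, "3" = 0.2),
#'     nCases = 40, nControls = 40
#'   ),
#'   seed = 4
#' )
#' man <- runPrtPipeline(cfg, tempfile("run"))
#' names(man$outputs)
#' @export
runPrtPipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1L) {
    if (!file.exists(config)) stop("[config] file not found: ", config)
    config <- read_yaml(config)
  }
  stopifnot(is.list(config))
  seed <- as.integer(config$seed %||% 1L)
  alpha <- config$alpha %||% 0.05
  thresholds <- as.numeric(config$thresholds %||% c(0.5, 0.75))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  outputs <- list()
  inputs <- list()
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      stop(sprintf("[%s] %s", name, conditionMessage(e)), call. = FALSE)
    })
  }

  ## -- simulate (optional) --------------------------------------------
  if (!is.null(config$simulate)) {
    peaks <- stage("simulate", {
      args <- config$simulate
      args$controlFrequencies <- unlist(args$controlFrequencies)
      if (!is.null(args$caseFrequencies))
        args$caseFrequencies <- unlist(args$caseFrequencies)
      if (is.null(args$seed)) args$seed <- seed
      simCfg <- do.call(PRTSimConfig, args)
      geno <- sampleGenotypes(simCfg)
      truthFile <- file.path(out_dir, "truth.tsv")
      utils::write.table(geno, truthFile, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      outputs$truth <- truthFile
      pk <- generatePeakTable(geno, simCfg)
      peaksFile <- file.path(out_dir, "peaks.tsv")
      writePeakTable(pk, peaksFile)
      outputs$peaks <- peaksFile
      pk
    })
  } else {
    peaks <- stage("input", {
      if (is.null(config$peaks)) stop("neither 'simulate' nor 'peaks' given")
      if (!file.exists(config$peaks))
        stop("peaks file not found: ", config$peaks)
      inputs$peaks <- config$peaks
      readPeakTable(config$peaks)
    })
  }

  ## -- call ------------------------------------------------------------
  calls <- stage("call", {
    resolution <- NULL
    if (!is.null(config$resolution)) {
      if (!file.exists(config$resolution))
        stop("resolution file not found: ", config$resolution)
      inputs$resolution <- config$resolution
      resolution <- utils::read.delim(config$resolution)
    }
    cl <- callCopyNumbers(peaks, resolution = resolution,
                          thresholds = thresholds)
    f <- file.path(out_dir, "calls.tsv")
    writeCallTable(cl, f)
    outputs$calls <- f
    cl
  })

  ## -- qc --------------------------------------------------------------
  stage("qc", {
    cs <- classStatistics(calls)
    f <- file.path(out_dir, "class_stats.tsv")
    utils::write.table(cs, f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$class_stats <- f
    prec <- datasetPrecision(calls)
    f2 <- file.path(out_dir, "precision.tsv")
    utils::write.table(
      data.frame(scope = c("overall", names(prec$per_cohort)),
                 normalised_sd = c(prec$overall, prec$per_cohort)),
      f2, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$precision <- f2
  })

  ## -- bias -------------------------------------------------------------
  stage("bias", {
    bs <- biasScan(calls)
    f <- file.path(out_dir, "bias_scan.tsv")
    if (is.null(bs$table)) {
      writeLines("integer_cn\tcase_n\tcontrol_n\tcase_mean\tcontrol_mean\tt_statistic\tp_value\tprimary", f)
    } else {
      utils::write.table(bs$table, f, sep = "\t", quote = FALSE,
                         row.names = FALSE)
      for (k in names(bs$reports)) {
        r <- bs$reports[[k]]
        cdf <- rbind(cbind(group = "case", r$curves$case),
                     cbind(group = "control", r$curves$control))
        fk <- file.path(out_dir, sprintf("cdf_class%s.tsv", k))
        utils::write.table(cdf, fk, sep = "\t", quote = FALSE,
                           row.names = FALSE)
        outputs[[sprintf("cdf_class%s", k)]] <- fk
      }
    }
    outputs$bias_scan <- f
  })

  ## -- assoc ------------------------------------------------------------
  stage("assoc", {
    at <- associationTest(calls)
    f <- file.path(out_dir, "association.tsv")
    utils::write.table(
      data.frame(case_n = at$case_n, control_n = at$control_n,
                 case_mean = at$case_mean, control_mean = at$control_mean,
                 t_statistic = at$t_statistic, df = at$df,
                 p_value = at$p_value, alpha = alpha,
                 significant = at$p_value < alpha),
      f, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs$association <- f
  })

  manifest <- list(
    package = "prtcnv",
    version = as.character(utils::packageVersion("prtcnv")),
    seed = seed, alpha = alpha, thresholds = thresholds,
    input_digests = if (length(inputs))
      as.list(md5sum(unlist(inputs))) else list(),
    outputs = outputs
  )
  write_json(manifest, file.path(out_dir, "manifest.json"),
             auto_unbox = TRUE, pretty = TRUE)
  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
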