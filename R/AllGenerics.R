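#' Accessors for PRTCallSet objects
#'
#' @param x a \linkS4class{PRTCallSet}.
#' @return \code{combinedValue}: numeric vector of arithmetic-mean unrounded
#'   copy numbers (NA for samples with no usable system).
#'   \code{integerCall}: integer vector of calls (NA = unresolved/missing).
#'   \code{concordance}: factor with levels concordant_05, concordant_075,
#'   discordant, missing. \code{nSystemsUsed}: integer vector.
#'   \code{unroundedValues}: the systems-by-samples matrix.
#'   \code{sampleStatus}: character vector of case/control labels.
#' @name PRTCallSet-accessors
#' @aliases combinedValue integerCall concordance nSystemsUsed
#'   unroundedValues sampleStatus
NULL

#' @rdname PRTCallSet-accessors
#' @export
setGeneric("combinedValue", function(x) standardGeneric("combinedValue"))

#' @rdname PRTCallSet-accessors
#' @export
setGeneric("integerCall", function(x) standardGeneric("integerCall"))

#' @rdname PRTCallSet-accessors
#' @export
setGeneric("concordance", function(x) standardGeneric("concordance"))

#' @rdname PRTCallSet-accessors
#' @export
setGeneric("nSystemsUsed", function(x) standardGeneric("nSystemsUsed"))

#' @rdname PRTCallSet-accessors
#' @export
setGeneric("unroundedValues", function(x) standardGeneric("unroundedValues"))

#' @rdname PRTCallSet-accessors
#' @export
setGeneric("sampleStatus", function(x) standardGeneric("sampleStatus"))

#' @rdname PRTCallSet-accessors
setMethod("combinedValue", "PRTCallSet", function(x) {
  stats::setNames(x$combined_value, colnames(x))
})

#' @rdname PRTCallSet-accessors
setMethod("integerCall", "PRTCallSet", function(x) {
  stats::setNames(x$integer_call, colnames(x))
})

#' @rdname PRTCallSet-accessors
setMethod("concordance", "PRTCallSet", function(x) {
  stats::setNames(factor(x$concordance, levels = .concordanceLevels),
                  colnames(x))
})

#' @rdname PRTCallSet-accessors
setMethod("nSystemsUsed", "PRTCallSet", function(x) {
  stats::setNames(x$n_systems_used, colnames(x))
})

#' @rdname PRTCallSet-accessors
setMethod("unroundedValues", "PRTCallSet", function(x) {
  SummarizedExperiment::assay(x, "unrounded")
})

#' @rdname PRTCallSet-accessors
setMethod("sampleStatus", "PRTCallSet", function(x) {
  stats::setNames(as.character(x$status), colnames(x))
})
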