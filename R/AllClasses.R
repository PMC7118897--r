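#' @import methods
#' @importClassesFrom SummarizedExperiment SummarizedExperiment
NULL

#' FeatureProfile: per-sample mutation counts for one mutation group
#'
#' Holds the raw per-feature event counts of one sample for one mutation
#' group (SNV, SV or MSI), keyed by the group's fixed feature catalog, plus a
#' tally of input records that were skipped during profiling, by reason.
#' Counts stay raw here; conversion to fractions happens only when profiles
#' are merged, so burden metrics ([tmb()], [svb()]) remain computable.
#'
#' @slot sampleID single sample identifier.
#' @slot group one of \code{"SNV"}, \code{"SV"}, \code{"MSI"}.
#' @slot counts named non-negative numeric vector over the group catalog.
#' @slot skipped named numeric tally of skipped input records by reason.
#' @export
setClass("FeatureProfile",
         representation(sampleID = "character",
                        group = "character",
                        counts = "numeric",
                        skipped = "numeric"))

setValidity("FeatureProfile", function(object) {
  msg <- character(0)
  if (length(object@sampleID) != 1L || is.na(object@sampleID) ||
      !nzchar(object@sampleID))
    msg <- c(msg, "sampleID must be a single non-empty string")
  if (!(length(object@group) == 1L && object@group %in% c("SNV", "SV", "MSI")))
    return("group must be one of SNV, SV, MSI")
  cat <- groupCatalog(object@group)
  if (!identical(names(object@counts), cat$featureID))
    msg <- c(msg, sprintf("counts must be keyed by the %d-feature %s catalog",
                          nrow(cat), object@group))
  if (any(!is.finite(object@counts)) || any(object@counts < 0))
    msg <- c(msg, "counts must be finite and non-negative")
  if (length(object@skipped) && any(object@skipped < 0))
    msg <- c(msg, "skipped tallies must be non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureProfile
#'
#' @param sampleID sample identifier.
#' @param group mutation group, \code{"SNV"}, \code{"SV"} or \code{"MSI"}.
#' @param counts named numeric vector; missing catalog features are
#'   zero-filled, unknown names are an error.
#' @param skipped optional named tally of skipped records by reason.
#' @return A [FeatureProfile-class] object.
#' @examples
#' p <- FeatureProfile("S1", "SNV", c(`G[T>C]G` = 1))
#' totalCount(p)
#' @export
FeatureProfile <- function(sampleID, group, counts = numeric(0),
                           skipped = numeric(0)) {
  cat <- groupCatalog(group)
  full <- setNames(numeric(nrow(cat)), cat$featureID)
  if (length(counts)) {
    bad <- setdiff(names(counts), cat$featureID)
    if (length(bad))
      stopf("unknown %s feature id(s): %s", group,
            paste(bad, collapse = ", "))
    full[names(counts)] <- as.numeric(counts)
  }
  new("FeatureProfile", sampleID = as.character(sampleID), group = group,
      counts = full, skipped = skipped)
}

#' FeatureMatrix: features x samples matrix on the fixed catalogs
#'
#' A thin extension of \linkS4class{SummarizedExperiment} whose rows are
#' mutation feature classes (rowData columns \code{group},
#' \code{variantType}, \code{subgroup}, \code{featureID}) and whose columns
#' are samples (or signatures, for a signature-probability matrix read from a
#' COSMIC/WTSI-layout file).  The single assay \code{"values"} holds raw
#' counts or fractions; \code{metadata(x)$valueType} records which.  Merged
#' matrices additionally carry the group weights and per-sample per-group
#' event totals used downstream by the bootstrap in [decipherSignatures()].
#'
#' @export
setClass("FeatureMatrix", contains = "SummarizedExperiment")

setValidity("FeatureMatrix", function(object) {
  msg <- character(0)
  rd <- SummarizedExperiment::rowData(object)
  need <- c("group", "variantType", "subgroup", "featureID")
  if (!all(need %in% colnames(rd)))
    return(paste("rowData must contain", paste(need, collapse = ", ")))
  if (anyDuplicated(rd$featureID))
    msg <- c(msg, "featureID values must be unique")
  v <- SummarizedExperiment::assay(object, "values")
  if (any(!is.finite(v)) || any(v < 0))
    msg <- c(msg, "values must be finite and non-negative")
  if (length(msg)) msg else TRUE
})

#' Construct a FeatureMatrix
#'
#' @param values numeric matrix, features in rows, samples in columns.
#' @param catalog catalog \code{data.frame} as returned by [fullCatalog()]
#'   (or a group catalog); row order must match \code{values}.
#' @param valueType \code{"counts"} or \code{"fractions"}.
#' @param weights optional named group-weight vector (merged matrices).
#' @param groupTotals optional groups x samples matrix of raw per-group event
#'   totals (merged matrices; consumed by the decipher bootstrap).
#' @return A [FeatureMatrix-class].
#' @export
FeatureMatrix <- function(values, catalog, valueType = c("counts", "fractions"),
                          weights = NULL, groupTotals = NULL) {
  valueType <- match.arg(valueType)
  values <- as.matrix(values)
  if (nrow(values) != nrow(catalog))
    stopf("values has %d rows but catalog has %d features",
          nrow(values), nrow(catalog))
  rownames(values) <- catalog$featureID
  se <- SummarizedExperiment::SummarizedExperiment(
    assays = list(values = values),
    rowData = S4Vectors::DataFrame(catalog))
  md <- list(valueType = valueType)
  if (!is.null(weights)) md$weights <- weights
  if (!is.null(groupTotals)) md$groupTotals <- groupTotals
  S4Vectors::metadata(se) <- md
  new("FeatureMatrix", se)
}

#' DecipherResult: NMF signatures, exposures and model-selection diagnostics
#'
#' Result container for [decipherSignatures()]: the signature probability
#' matrix P (features x k, columns sum to 1), the exposure matrix E
#' (k x samples), the selected number of signatures (NA when no k passed the
#' stability floor) and per-k diagnostics (mean bootstrap signature stability
#' as a cosine silhouette, and mean relative Frobenius reconstruction error).
#'
#' @slot signatures features x k probability matrix (P).
#' @slot exposures k x samples non-negative exposure matrix (E).
#' @slot kSelected integer, suggested number of signatures (may be NA).
#' @slot diagnostics data.frame with columns k, stability, reconError.
#' @slot config list of the configuration used.
#' @export
setClass("DecipherResult",
         representation(signatures = "matrix",
                        exposures = "matrix",
                        kSelected = "integer",
                        diagnostics = "data.frame",
                        config = "list"))

setValidity("DecipherResult", function(object) {
  P <- object@signatures; E <- object@exposures
  msg <- character(0)
  if (any(P < 0) || any(E < 0))
    msg <- c(msg, "signatures and exposures must be non-negative")
  if (ncol(P) != nrow(E))
    msg <- c(msg, "ncol(signatures) must equal nrow(exposures)")
  cs <- colSums(P)
  if (any(abs(cs - 1) > 1e-9 & cs > 0))
    msg <- c(msg, "signature columns must sum to 1")
  if (length(msg)) msg else TRUE
})
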