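#' @name cancerSig-accessors
#' @title Accessors for cancerSig objects
#' @description Accessor generics for [FeatureProfile-class],
#'   [FeatureMatrix-class] and [DecipherResult-class] objects.
#' @param x a cancerSig object.
#' @return The corresponding slot content (see individual methods).
NULL

#' @rdname cancerSig-accessors
#' @export
setGeneric("sampleID", function(x) standardGeneric("sampleID"))

#' @rdname cancerSig-accessors
#' @export
setGeneric("mutationGroup", function(x) standardGeneric("mutationGroup"))

#' @rdname cancerSig-accessors
#' @export
setGeneric("profileCounts", function(x) standardGeneric("profileCounts"))

#' @rdname cancerSig-accessors
#' @export
setGeneric("skippedRecords", function(x) standardGeneric("skippedRecords"))

#' @rdname cancerSig-accessors
#' @export
setGeneric("totalCount", function(x) standardGeneric("totalCount"))

#' @rdname cancerSig-accessors
#' @export
setGeneric("featureIDs", function(x) standardGeneric("featureIDs"))

#' @rdname cancerSig-accessors
#' @export
setGeneric("featureValues", function(x) standardGeneric("featureValues"))

#' @rdname cancerSig-accessors
#' @export
setGeneric("signatures", function(x) standardGeneric("signatures"))

#' @rdname cancerSig-accessors
#' @export
setGeneric("exposures", function(x) standardGeneric("exposures"))

#' @rdname cancerSig-accessors
#' @export
setGeneric("selectedK", function(x) standardGeneric("selectedK"))

#' @rdname cancerSig-accessors
#' @export
setGeneric("diagnostics", function(x) standardGeneric("diagnostics"))

## ---- FeatureProfile methods ----

#' @rdname cancerSig-accessors
#' @export
setMethod("sampleID", "FeatureProfile", function(x) x@sampleID)

#' @rdname cancerSig-accessors
#' @export
setMethod("mutationGroup", "FeatureProfile", function(x) x@group)

#' @rdname cancerSig-accessors
#' @export
setMethod("profileCounts", "FeatureProfile", function(x) x@counts)

#' @rdname cancerSig-accessors
#' @export
setMethod("skippedRecords", "FeatureProfile", function(x) x@skipped)

#' @rdname cancerSig-accessors
#' @export
setMethod("totalCount", "FeatureProfile", function(x) sum(x@counts))

#' @rdname cancerSig-accessors
#' @export
setMethod("featureIDs", "FeatureProfile", function(x) names(x@counts))

setMethod("show", "FeatureProfile", function(object) {
  cat(sprintf("FeatureProfile: sample '%s', group %s\n",
              object@sampleID, object@group))
  cat(sprintf("  %d features, %g events counted, %g records skipped\n",
              length(object@counts), sum(object@counts),
              sum(object@skipped)))
  nz <- object@counts[object@counts > 0]
  if (length(nz)) {
    top <- sort(nz, decreasing = TRUE)
    top <- head(top, 5)
    cat("  top classes:",
        paste(sprintf("%s=%g", names(top), top), collapse = ", "), "\n")
  }
})

## ---- FeatureMatrix methods ----

#' @rdname cancerSig-accessors
#' @export
setMethod("featureIDs", "FeatureMatrix",
          function(x) SummarizedExperiment::rowData(x)$featureID)

#' @rdname cancerSig-accessors
#' @export
setMethod("featureValues", "FeatureMatrix",
          function(x) SummarizedExperiment::assay(x, "values"))

#' @rdname cancerSig-accessors
#' @export
setMethod("sampleID", "FeatureMatrix", function(x) colnames(x))

setMethod("show", "FeatureMatrix", function(object) {
  md <- S4Vectors::metadata(object)
  cat(sprintf("FeatureMatrix: %d features x %d columns (%s)\n",
              nrow(object), ncol(object),
              if (is.null(md$valueType)) "values" else md$valueType))
  grp <- table(SummarizedExperiment::rowData(object)$group)
  cat("  groups:", paste(sprintf("%s=%d", names(grp), grp), collapse = ", "),
      "\n")
  if (!is.null(md$weights))
    cat("  group weights:",
        paste(sprintf("%s=%g", names(md$weights), md$weights),
              collapse = ", "), "\n")
})

## ---- DecipherResult methods ----

#' @rdname cancerSig-accessors
#' @export
setMethod("signatures", "DecipherResult", function(x) x@signatures)

#' @rdname cancerSig-accessors
#' @export
setMethod("exposures", "DecipherResult", function(x) x@exposures)

#' @rdname cancerSig-accessors
#' @export
setMethod("selectedK", "DecipherResult", function(x) x@kSelected)

#' @rdname cancerSig-accessors
#' @export
setMethod("diagnostics", "DecipherResult", function(x) x@diagnostics)

setMethod("show", "DecipherResult", function(object) {
  cat(sprintf("DecipherResult: %d features, %d samples\n",
              nrow(object@signatures), ncol(object@exposures)))
  if (is.na(object@kSelected)) {
    cat("  no k passed the stability floor; inspect diagnostics()\n")
  } else {
    cat(sprintf("  selected k = %d\n", object@kSelected))
  }
  print(object@diagnostics, row.names = FALSE)
})
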