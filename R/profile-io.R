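## COSMIC/WTSI-style tab-delimited profile tables.  Layout: three leading
## columns "Variant type", "Variant subgroup", "Feature ID", then one column
## per sample (or per signature, for a signature-probability table).

PROFILE_HEADER <- c("Variant type", "Variant subgroup", "Feature ID")

#' Write a profile table in COSMIC-style layout
#'
#' Writes a [FeatureMatrix-class] (or a list of [FeatureProfile-class]
#' objects of one group, one per sample) to a tab-delimited table whose
#' first three columns are the variant type, the variant subgroup and the
#' feature id, followed by one numeric column per sample.  Values are
#' written at full precision so that [readProfileTable()] round-trips
#' within 1e-12.
#'
#' @param x a \code{FeatureMatrix}, a single \code{FeatureProfile} or a list
#'   of \code{FeatureProfile}s of the same group with distinct samples.
#' @param path output file path.
#' @return \code{path}, invisibly.
#' @export
writeProfileTable <- function(x, path) {
  x <- asFeatureMatrix(x)
  vals <- featureValues(x)
  rd <- as.data.frame(SummarizedExperiment::rowData(x))
  df <- data.frame(rd$variantType, rd$subgroup, rd$featureID,
                   stringsAsFactors = FALSE, check.names = FALSE)
  colnames(df) <- PROFILE_HEADER
  for (j in seq_len(ncol(vals)))
    df[[colnames(vals)[j]]] <- sprintf("%.15g", vals[, j])
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

## accept FeatureMatrix | FeatureProfile | list of FeatureProfile
asFeatureMatrix <- function(x) {
  if (is(x, "FeatureMatrix")) return(x)
  if (is(x, "FeatureProfile")) x <- list(x)
  if (is.list(x) && length(x) && all(vapply(x, is, logical(1), "FeatureProfile"))) {
    grp <- unique(vapply(x, mutationGroup, character(1)))
    if (length(grp) != 1L)
      stopf("profiles span multiple groups (%s); merge them with mergeProfiles()",
            paste(grp, collapse = ", "))
    ids <- vapply(x, sampleID, character(1))
    if (anyDuplicated(ids))
      stopf("duplicate sample id(s): %s",
            paste(unique(ids[duplicated(ids)]), collapse = ", "))
    vals <- vapply(x, profileCounts, numeric(nrow(groupCatalog(grp))))
    colnames(vals) <- ids
    return(FeatureMatrix(vals, groupCatalog(grp), valueType = "counts"))
  }
  stopf("cannot write object of class '%s' as a profile table", class(x)[1])
}

#' Read a COSMIC-style profile or signature table
#'
#' Parses a tab-delimited table in the layout written by
#' [writeProfileTable()]: three leading feature-description columns followed
#' by one numeric column per sample (or per signature, when reading a
#' COSMIC/WTSI signature-probability file).  Feature ids must belong to the
#' package catalogs (any subset, e.g. a 96-row SNV-only table); unknown ids,
#' duplicated ids and negative values are rejected with the offending
#' row/column named.
#'
#' @param path input file path.
#' @return A [FeatureMatrix-class]; \code{metadata(x)$valueType} is
#'   \code{"counts"} when every value is integral, otherwise
#'   \code{"fractions"}.
#' @export
readProfileTable <- function(path) {
  if (!file.exists(path)) stopf("profile table '%s' does not exist", path)
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  if (ncol(df) < 4L)
    stopf("malformed profile table '%s': expected >= 4 columns, found %d",
          path, ncol(df))
  if (!identical(colnames(df)[1:3], PROFILE_HEADER))
    stopf(paste0("malformed header in '%s': expected columns '%s', found '%s'"),
          path, paste(PROFILE_HEADER, collapse = "', '"),
          paste(colnames(df)[1:3], collapse = "', '"))
  known <- fullCatalog()
  ids <- as.character(df[["Feature ID"]])
  bad <- setdiff(ids, known$featureID)
  if (length(bad))
    stopf("unknown feature id(s) in '%s': %s (first at row %d)",
          path, paste(head(bad, 5), collapse = ", "),
          which(ids == bad[1])[1])
  if (anyDuplicated(ids))
    stopf("duplicated feature id(s) in '%s': %s", path,
          paste(unique(ids[duplicated(ids)]), collapse = ", "))
  vals <- as.matrix(df[, -(1:3), drop = FALSE])
  if (!is.numeric(vals))
    stopf("non-numeric sample values in '%s'", path)
  neg <- which(vals < 0, arr.ind = TRUE)
  if (nrow(neg))
    stopf("negative value in '%s' at feature '%s', sample '%s'",
          path, ids[neg[1, 1]], colnames(vals)[neg[1, 2]])
  catalog <- known[match(ids, known$featureID), ]
  valueType <- if (isCountVector(as.numeric(vals))) "counts" else "fractions"
  FeatureMatrix(vals, catalog, valueType = valueType)
}
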