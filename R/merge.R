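## Merge per-sample SNV/SV/MSI profiles into one weighted feature matrix.
## Within each group the counts are normalized to fractions and scaled by
## the group weight, so every merged column sums to 1 and every group block
## sums to its weight -- the guard that stops a hypermutated group from
## overpowering the others.

DEFAULT_WEIGHTS <- c(SNV = 0.7, SV = 0.2, MSI = 0.1)

#' Group feature weights
#'
#' Validated named weight vector for the three mutation groups.  The default
#' 7:2:1 (SNV:SV:MSI) caps the fraction of the merged profile each group can
#' contribute.  Degenerate weights (e.g. \code{SNV = 1}) express single-group
#' profile modes.
#'
#' @param SNV,SV,MSI non-negative fractions summing to 1.
#' @return Named numeric vector of length 3.
#' @export
featureWeights <- function(SNV = 0.7, SV = 0.2, MSI = 0.1) {
  w <- c(SNV = SNV, SV = SV, MSI = MSI)
  if (any(!is.finite(w)) || any(w < 0) || any(w > 1))
    stopf("group weights must be fractions in [0, 1]")
  if (abs(sum(w) - 1) > 1e-9)
    stopf("group weights must sum to 1 (got %g)", sum(w))
  w
}

#' Read a feature-selection (weights) config file
#'
#' Parses a small key-value file mapping group names to weights, one
#' \code{group<TAB-or-=>weight} pair per line; \code{#} comments allowed.
#' Missing groups default to weight 0; the weights must sum to 1.
#'
#' @param path config file path.
#' @return Named weight vector as from [featureWeights()].
#' @export
readWeightsConfig <- function(path) {
  if (!file.exists(path)) stopf("weights config '%s' does not exist", path)
  lines <- readLines(path)
  lines <- trimws(sub("#.*$", "", lines))
  lines <- lines[nzchar(lines)]
  w <- c(SNV = 0, SV = 0, MSI = 0)
  for (ln in lines) {
    kv <- strsplit(ln, "[=\t ]+")[[1]]
    if (length(kv) != 2L || !(kv[1] %in% names(w)))
      stopf("malformed weights line '%s' (expect 'SNV 0.7' style)", ln)
    w[kv[1]] <- as.numeric(kv[2])
  }
  featureWeights(SNV = w["SNV"], SV = w["SV"], MSI = w["MSI"])
}

#' Merge per-sample group profiles into one weighted feature matrix
#'
#' For every sample, the counts of each mutation group are normalized to
#' within-group fractions and scaled by the group weight, then stacked over
#' the full 146-feature catalog.  Each merged column sums to 1 and each
#' group block sums to its weight, regardless of how imbalanced the raw
#' event counts are between groups.
#'
#' Samples whose profile for some group has zero total count are handled per
#' \code{missingGroupPolicy}: \code{"error"} aborts; \code{"zero-fill"}
#' leaves that block at zero and re-normalizes the remaining groups so the
#' column still sums to 1.  A missing (not supplied) group profile is
#' treated the same way.
#'
#' @param profiles list of [FeatureProfile-class] objects (any order; at
#'   most one profile per sample/group pair).
#' @param weights group weights from [featureWeights()].
#' @param missingGroupPolicy \code{"error"} (default) or \code{"zero-fill"}.
#' @return A [FeatureMatrix-class] of fractions with
#'   \code{metadata(x)$weights} and \code{metadata(x)$groupTotals} (raw
#'   per-group event totals, used by the decipher bootstrap).
#' @examples
#' p1 <- FeatureProfile("S1", "SNV", c(`A[C>A]A` = 3, `A[C>A]C` = 1))
#' p2 <- FeatureProfile("S1", "SV", c(`deletion_100-1K` = 2))
#' p3 <- FeatureProfile("S1", "MSI", c(A = 5))
#' M <- mergeProfiles(list(p1, p2, p3))
#' colSums(featureValues(M))  # 1
#' @export
mergeProfiles <- function(profiles, weights = featureWeights(),
                          missingGroupPolicy = c("error", "zero-fill")) {
  missingGroupPolicy <- match.arg(missingGroupPolicy)
  if (!length(profiles)) stopf("no profiles supplied")
  if (!all(vapply(profiles, is, logical(1), "FeatureProfile")))
    stopf("profiles must be a list of FeatureProfile objects")
  weights <- featureWeights(SNV = unname(weights["SNV"]),
                            SV = unname(weights["SV"]),
                            MSI = unname(weights["MSI"]))
  sampleIDs <- unique(vapply(profiles, sampleID, character(1)))
  groups <- names(DEFAULT_WEIGHTS)
  key <- paste(vapply(profiles, sampleID, character(1)),
               vapply(profiles, mutationGroup, character(1)))
  if (anyDuplicated(key))
    stopf("duplicate profile for %s", key[duplicated(key)][1])
  catalog <- fullCatalog()
  groupIdx <- split(seq_len(nrow(catalog)), catalog$group)[groups]
  vals <- matrix(0, nrow(catalog), length(sampleIDs),
                 dimnames = list(catalog$featureID, sampleIDs))
  totals <- matrix(0, length(groups), length(sampleIDs),
                   dimnames = list(groups, sampleIDs))
  byKey <- setNames(profiles, key)
  for (s in sampleIDs) {
    colW <- weights
    fracs <- setNames(vector("list", length(groups)), groups)
    for (g in groups) {
      p <- byKey[[paste(s, g)]]
      tot <- if (is.null(p)) 0 else totalCount(p)
      totals[g, s] <- tot
      if (is.null(p) || tot == 0) {
        if (colW[g] > 0 && missingGroupPolicy == "error")
          stopf("sample '%s' has %s profile for group %s (policy 'error')",
                s, if (is.null(p)) "no" else "an all-zero", g)
        colW[g] <- 0
        fracs[[g]] <- numeric(length(groupIdx[[g]]))
      } else {
        fracs[[g]] <- profileCounts(p) / tot
      }
    }
    if (sum(colW) == 0)
      stopf("sample '%s' has no usable mutation group", s)
    colW <- colW / sum(colW)  # re-normalize after zero-filled groups
    for (g in groups)
      vals[groupIdx[[g]], s] <- fracs[[g]] * colW[g]
  }
  FeatureMatrix(vals, catalog, valueType = "fractions",
                weights = weights, groupTotals = totals)
}
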