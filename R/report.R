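## Reporting: per-sample 4-page decomposition documents, the cohort
## normalized-weights table, signature-association calls and burden metrics.

#' Signatures associated with a sample
#'
#' A sample is associated with a signature when its decomposed exposure
#' fraction for that signature is strictly greater than the threshold
#' (default 30%): a fraction of exactly 0.30, or 0.26, is not an
#' association.
#'
#' @param exposureFractions named numeric vector of exposure fractions in
#'   [0, 1].
#' @param threshold association threshold (default 0.30).
#' @return Character vector of associated signature ids (possibly empty).
#' @examples
#' associatedSignatures(c(A = 0.5, B = 0.4, C = 0.1))  # "A" "B"
#' associatedSignatures(c(A = 0.30, B = 0.70))         # "B"
#' @export
associatedSignatures <- function(exposureFractions, threshold = 0.30) {
  if (any(exposureFractions < 0) || any(exposureFractions > 1 + 1e-9))
    stopf("exposure fractions must lie in [0, 1]")
  names(exposureFractions)[exposureFractions > threshold]
}

#' Tumor mutation burden (substitutions per Mbp)
#'
#' Total number of base substitutions in a raw-count SNV profile divided by
#' \code{exomeMb} (default 30, the exome-scale heuristic; whole-genome users
#' can override the denominator).
#'
#' @param snvProfile a [FeatureProfile-class] of group SNV holding raw
#'   counts (a fraction-normalized profile is rejected).
#' @param exomeMb denominator in megabases.
#' @return Substitutions per Mbp.
#' @examples
#' p <- FeatureProfile("S1", "SNV", c(`A[C>A]A` = 2040))
#' tmb(p)  # 68
#' @export
tmb <- function(snvProfile, exomeMb = 30) {
  stopifnot(is(snvProfile, "FeatureProfile"))
  if (mutationGroup(snvProfile) != "SNV")
    stopf("tmb() needs an SNV profile, got group %s",
          mutationGroup(snvProfile))
  cnt <- profileCounts(snvProfile)
  if (!isCountVector(cnt))
    stopf("tmb() needs raw counts; this profile appears fraction-normalized")
  sum(cnt) / exomeMb
}

#' Structural variation burden (event count)
#'
#' Total number of somatic structural events in a raw-count SV profile.
#'
#' @param svProfile a [FeatureProfile-class] of group SV with raw counts.
#' @return Total event count.
#' @export
svb <- function(svProfile) {
  stopifnot(is(svProfile, "FeatureProfile"))
  if (mutationGroup(svProfile) != "SV")
    stopf("svb() needs an SV profile, got group %s",
          mutationGroup(svProfile))
  sum(profileCounts(svProfile))
}

#' Per-sample decomposition summary
#'
#' Refits the sample's observed profile against the signature matrix and
#' assembles the quantities shown in the rendered report: exposure
#' fractions, reconstruction, residual (observed - reconstructed,
#' elementwise exact) and total reconstruction error.
#'
#' @param sample sample id.
#' @param P signature matrix (features x k, columns summing to 1).
#' @param observed observed profile vector for the sample.
#' @return List with \code{sampleID}, \code{fractions}, \code{observed},
#'   \code{reconstructed}, \code{residual}, \code{errorNorm} and
#'   \code{associated}.
#' @export
sampleReport <- function(sample, P, observed) {
  fit <- refitExposures(P, observed)
  list(sampleID = sample,
       fractions = fit$fractions,
       observed = as.numeric(observed),
       reconstructed = fit$reconstruction,
       residual = fit$residual,
       errorNorm = fit$residualNorm,
       associated = associatedSignatures(fit$fractions))
}

groupColors <- function(featureGroups) {
  c(SNV = "#3b7dd8", SV = "#d8663b", MSI = "#3bb273")[featureGroups]
}

#' Render a 4-page per-sample decomposition report
#'
#' Writes a PDF with one page each for (1) the pie chart of signature
#' exposure fractions, (2) the observed profile, (3) the profile
#' reconstructed from the fitted signatures, and (4) the prediction error
#' (observed - reconstructed).  A machine-readable numeric annex holding the
#' same values is written next to the PDF
#' (\code{<out>.report.tsv}).
#'
#' @param sample sample id.
#' @param P signature matrix.
#' @param observed observed profile vector (length \code{nrow(P)}).
#' @param outPath output PDF path.
#' @param featureGroups optional per-feature group labels used for bar
#'   colors; defaults to the full-catalog groups when lengths match.
#' @return Invisible list: the [sampleReport()] plus \code{pdf} and
#'   \code{annex} paths.
#' @export
renderReport <- function(sample, P, observed, outPath,
                         featureGroups = NULL) {
  P <- as.matrix(P)
  if (length(observed) != nrow(P))
    stopf("observed profile length %d does not match %d signature features",
          length(observed), nrow(P))
  rpt <- sampleReport(sample, P, observed)
  feats <- rownames(P)
  if (is.null(feats)) feats <- paste0("f", seq_len(nrow(P)))
  if (is.null(featureGroups)) {
    fc <- fullCatalog()
    featureGroups <- if (nrow(fc) == nrow(P) &&
                         all(feats == fc$featureID)) fc$group
                     else rep("SNV", nrow(P))
  }
  cols <- groupColors(featureGroups)
  grDevices::pdf(outPath, width = 11, height = 6, onefile = TRUE)
  on.exit(grDevices::dev.off(), add = TRUE)
  ## page 1: exposure pie
  fr <- rpt$fractions
  lab <- sprintf("%s (%.1f%%)", names(fr), 100 * fr)
  graphics::pie(pmax(fr, 1e-12), labels = ifelse(fr > 0.005, lab, NA),
                main = sprintf("%s: mutational signature components", sample),
                col = grDevices::hcl.colors(length(fr), "Set 2"))
  barPage <- function(v, title) {
    graphics::barplot(v, names.arg = NA, border = NA, col = cols,
                      main = sprintf("%s: %s", sample, title),
                      xlab = "mutation feature class", ylab = "fraction")
    graphics::legend("topright", legend = unique(featureGroups),
                     fill = groupColors(unique(featureGroups)), bty = "n")
  }
  ## page 2: observed; page 3: reconstructed; page 4: error
  barPage(rpt$observed, "observed profile")
  barPage(rpt$reconstructed, "reconstructed profile")
  barPage(rpt$residual,
          sprintf("prediction error (norm %.4g)", rpt$errorNorm))
  annex <- paste0(tools::file_path_sans_ext(outPath), ".report.tsv")
  annexDf <- data.frame(featureID = feats,
                        observed = rpt$observed,
                        reconstructed = rpt$reconstructed,
                        residual = rpt$residual,
                        stringsAsFactors = FALSE)
  write.table(annexDf, annex, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(c(rpt, list(pdf = outPath, annex = annex)))
}

#' Write the cohort normalized-weights table
#'
#' Writes \code{normalized_weights.txt}: one row per sample, one column per
#' signature, each cell the percentage of that signature in the sample's
#' decomposition (the same numbers as the report pie charts).  Every row
#' sums to 100.
#'
#' @param E exposure matrix, signatures x samples; columns are normalized
#'   to fractions before writing.
#' @param outPath output path.
#' @return \code{outPath}, invisibly.
#' @export
writeNormalizedWeights <- function(E, outPath) {
  E <- as.matrix(E)
  cs <- colSums(E)
  if (any(cs <= 0)) stopf("every sample must have positive total exposure")
  En <- sweep(E, 2L, cs, "/") * 100
  df <- data.frame(sample = colnames(En), stringsAsFactors = FALSE)
  for (i in seq_len(nrow(En)))
    df[[rownames(En)[i]]] <- sprintf("%.10g", En[i, ])
  write.table(df, outPath, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(outPath)
}

#' Read a normalized-weights table back as fractions
#'
#' Companion reader for [writeNormalizedWeights()], mainly for checking the
#' file against the exposure matrix it came from.
#'
#' @param path path to a normalized_weights.txt file.
#' @return Matrix of fractions, signatures x samples.
#' @export
readNormalizedWeights <- function(path) {
  df <- read.delim(path, check.names = FALSE, stringsAsFactors = FALSE)
  m <- t(as.matrix(df[, -1, drop = FALSE])) / 100
  colnames(m) <- df$sample
  m
}
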