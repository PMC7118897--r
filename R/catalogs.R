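## Fixed feature catalogs: 96 SNV trinucleotide classes, 32 SV class/size-bin
## combinations and 18 microsatellite repeat-unit classes.  Catalog order is
## deterministic so that profile tables are byte-identical across runs.

SUBSTITUTION_CLASSES <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")

SV_CLASSES <- c("deletion", "duplication", "inversion", "translocation")

SV_BIN_LABELS <- c("100-1K", "1K-10K", "10K-100K", "100K-1M",
                   "1M-10M", "10M-100M", "100M-1000M", "whole-chrom")

MSI_UNIT_CLASSES <- c("A", "C", "AC", "AG", "AT", "CG",
                      "AAC", "AAG", "AAT", "ACC", "ACG", "ACT",
                      "AGC", "AGG", "ATC", "CCG")

#' SNV feature catalog (96 trinucleotide-context classes)
#'
#' Builds the ordered catalog of the 96 single-base-substitution classes:
#' 6 pyrimidine-reference substitution types (C>A, C>G, C>T, T>A, T>C, T>G)
#' crossed with 4 possible 5' and 4 possible 3' flanking bases.  Feature ids
#' follow the COSMIC convention \code{"X[R>A]Y"}, e.g. \code{"G[T>C]G"}.
#' Order is substitution class major, then 5' base, then 3' base, both
#' alphabetical.
#'
#' @return A \code{data.frame} with columns \code{group}, \code{variantType}
#'   (substitution class), \code{subgroup} (trinucleotide context) and
#'   \code{featureID}, one row per class, 96 rows.
#' @examples
#' cat96 <- snvCatalog()
#' nrow(cat96)            # 96
#' "G[T>C]G" %in% cat96$featureID
#' @export
snvCatalog <- function() {
  rows <- lapply(SUBSTITUTION_CLASSES, function(sub) {
    ref <- substr(sub, 1L, 1L)
    grid <- expand.grid(three = DNA_BASES, five = DNA_BASES,
                        stringsAsFactors = FALSE)[, c("five", "three")]
    grid <- grid[order(grid$five, grid$three), ]
    data.frame(group = "SNV",
               variantType = sub,
               subgroup = paste0(grid$five, ref, grid$three),
               featureID = paste0(grid$five, "[", sub, "]", grid$three),
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' SV feature catalog (4 event classes x 8 size bins)
#'
#' Builds the ordered catalog of structural-variant classes: deletion,
#' duplication, inversion and translocation, each subclassified into 8
#' log10-scale size bins (100-1K, 1K-10K, ..., 100M-1000M, whole-chrom).
#'
#' @return A \code{data.frame} as in [snvCatalog()], 32 rows.
#' @examples
#' nrow(svCatalog())   # 32
#' @export
svCatalog <- function() {
  grid <- expand.grid(bin = SV_BIN_LABELS, cls = SV_CLASSES,
                      stringsAsFactors = FALSE)
  out <- data.frame(group = "SV",
                    variantType = grid$cls,
                    subgroup = grid$bin,
                    featureID = paste0(grid$cls, "_", grid$bin),
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' MSI feature catalog (18 repeat-unit classes)
#'
#' Builds the catalog of microsatellite repeat-unit classes: the 16 canonical
#' repeat-unit patterns of length 1-3 (equivalence classes under cyclic
#' rotation and reverse complementation) plus two pattern-free classes for
#' repeat units of 4 and 5 base pairs.
#'
#' @return A \code{data.frame} as in [snvCatalog()], 18 rows.
#' @examples
#' msiCatalog()$featureID
#' @export
msiCatalog <- function() {
  units <- c(MSI_UNIT_CLASSES, "unit4", "unit5")
  len <- c(nchar(MSI_UNIT_CLASSES), 4L, 5L)
  out <- data.frame(group = "MSI",
                    variantType = "repeat_unit",
                    subgroup = paste0("unit_len_", len),
                    featureID = units,
                    stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

#' Full merged catalog (146 features)
#'
#' Concatenates the SNV, SV and MSI catalogs in that fixed group order.
#'
#' @return A \code{data.frame} with 96 + 32 + 18 = 146 rows.
#' @export
fullCatalog <- function() {
  out <- rbind(snvCatalog(), svCatalog(), msiCatalog())
  rownames(out) <- NULL
  out
}

groupCatalog <- function(group) {
  switch(group,
         SNV = snvCatalog(),
         SV  = svCatalog(),
         MSI = msiCatalog(),
         stopf("unknown mutation group '%s'", group))
}
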