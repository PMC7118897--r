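## SNV profiling: classify somatic single-base substitutions into the 96
## trinucleotide-context classes, with flanking bases taken from the
## reference genome (never from the VCF).

#' Canonical pyrimidine-reference substitution class
#'
#' Maps an ordered (REF, ALT) single-base pair onto one of the six
#' substitution classes C>A, C>G, C>T, T>A, T>C, T>G.  Purine-reference
#' pairs are folded onto the pyrimidine strand by complementation, so each
#' class collects exactly two of the twelve ordered base pairs (e.g. both
#' G>T and C>A map to C>A).
#'
#' @param refBase,altBase single bases in \code{A,C,G,T}; must differ.
#' @return The class label, e.g. \code{"T>C"}.
#' @examples
#' canonicalSubstitution("T", "C")  # "T>C"
#' canonicalSubstitution("G", "T")  # "C>A"
#' @export
canonicalSubstitution <- function(refBase, altBase) {
  if (!(refBase %in% DNA_BASES) || !(altBase %in% DNA_BASES))
    stopf("bases must be one of A, C, G, T (got '%s'>'%s')", refBase, altBase)
  if (refBase == altBase)
    stopf("REF and ALT must differ (both '%s')", refBase)
  if (refBase %in% c("A", "G")) {
    refBase <- revcompBase(refBase)
    altBase <- revcompBase(altBase)
  }
  paste0(refBase, ">", altBase)
}

#' Trinucleotide-context feature class of a substitution
#'
#' Returns the feature id (one of the 96 catalog classes, format
#' \code{"X[R>A]Y"}) for a single-base substitution with the given 5' and 3'
#' reference flanks.  When REF is a purine the substitution and the context
#' are jointly reverse-complemented: the 5' and 3' flanks swap and are
#' complemented, so that a variant and its reverse-complement representation
#' always yield the same class.
#'
#' @param refBase,altBase the substitution, single bases.
#' @param fivePrime,threePrime reference bases immediately 5' and 3' of the
#'   variant position.
#' @return A feature id such as \code{"G[T>C]G"}.
#' @examples
#' trinucleotideClass("T", "C", "G", "G")  # "G[T>C]G"
#' trinucleotideClass("A", "G", "C", "T")  # "A[T>C]G"
#' @export
trinucleotideClass <- function(refBase, altBase, fivePrime, threePrime) {
  for (b in c(fivePrime, threePrime))
    if (!(b %in% DNA_BASES))
      stopf("flanking bases must be one of A, C, G, T (got '%s')", b)
  sub <- canonicalSubstitution(refBase, altBase)
  if (refBase %in% c("A", "G")) {
    tmp <- revcompBase(threePrime)
    threePrime <- revcompBase(fivePrime)
    fivePrime <- tmp
  }
  paste0(fivePrime, "[", sub, "]", threePrime)
}

## Reference accessor over a Biostrings::DNAStringSet; returns uppercase
## A/C/G/T/N, or NA outside the contig.  A per-contig character cache keeps
## random access O(1) when scanning many records.
referenceAccessor <- function(refSeqs) {
  cache <- new.env(parent = emptyenv())
  function(chrom, pos) {
    if (!(chrom %in% names(refSeqs))) return(NA_character_)
    chars <- cache[[chrom]]
    if (is.null(chars)) {
      chars <- strsplit(toupper(as.character(refSeqs[[chrom]])), "")[[1]]
      assign(chrom, chars, envir = cache)
    }
    if (pos < 1L || pos > length(chars)) return(NA_character_)
    chars[pos]
  }
}

#' Profile single-nucleotide variants from a VCF
#'
#' Scans a somatic VCF, classifies every accepted single-base substitution
#' into its trinucleotide-context class using the flanking bases of the
#' supplied reference genome, and returns the per-class counts as a
#' [FeatureProfile-class].  Acceptance rules: REF and ALT both single bases
#' (multi-allelic records are decomposed and each single-base ALT counted
#' independently); FILTER must be PASS or missing unless
#' \code{passOnly = FALSE}; the reference base at the position must match
#' the VCF REF; flanking bases must not be N and the position must not sit
#' at a contig edge.  Every rejected record is tallied by reason in
#' \code{skippedRecords()} -- accepted + skipped always reconciles with the
#' number of input (decomposed) records.
#'
#' @param vcfPath path to the VCF (plain or gzipped).
#' @param reference path to the reference FASTA, or a
#'   \code{Biostrings::DNAStringSet}.
#' @param sample sample identifier used to label the profile.
#' @param passOnly if \code{TRUE} (default) only records whose FILTER is
#'   \code{PASS} or \code{.} are counted.
#' @param verbose emit a one-line summary log.
#' @return A \code{FeatureProfile} of group \code{"SNV"}.
#' @export
profileSNV <- function(vcfPath, reference, sample, passOnly = TRUE,
                       verbose = FALSE) {
  if (!file.exists(vcfPath)) stopf("cannot read VCF '%s'", vcfPath)
  refSeqs <- if (is(reference, "DNAStringSet")) reference
             else Biostrings::readDNAStringSet(reference)
  ## index FASTA by first word of the header line
  names(refSeqs) <- sub("\\s.*$", "", names(refSeqs))

  refBase <- referenceAccessor(refSeqs)
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  fix <- vcfR::getFIX(vcf)
  cat96 <- snvCatalog()
  counts <- setNames(numeric(96L), cat96$featureID)
  skipped <- c(non_snv = 0, filter_fail = 0, ref_mismatch = 0, n_or_edge = 0)
  nrec <- 0L
  if (!is.null(fix) && nrow(rbind(fix)) > 0) {
    fix <- rbind(fix)  # single-record VCFs come back as a bare vector
    for (i in seq_len(nrow(fix))) {
      alts <- strsplit(fix[i, "ALT"], ",", fixed = TRUE)[[1]]
      for (alt in alts) {
        nrec <- nrec + 1L
        ref <- toupper(fix[i, "REF"]); alt <- toupper(alt)
        if (nchar(ref) != 1L || nchar(alt) != 1L ||
            !(ref %in% DNA_BASES) || !(alt %in% DNA_BASES) || ref == alt) {
          skipped["non_snv"] <- skipped["non_snv"] + 1
          next
        }
        filt <- fix[i, "FILTER"]
        if (passOnly && !is.na(filt) && !(filt %in% c("PASS", "."))) {
          skipped["filter_fail"] <- skipped["filter_fail"] + 1
          next
        }
        chrom <- fix[i, "CHROM"]
        pos <- as.integer(fix[i, "POS"])
        if (!(chrom %in% names(refSeqs)))
          stopf("contig '%s' (VCF record at %s:%d) absent from the reference",
                chrom, chrom, pos)
        atPos <- refBase(chrom, pos)
        if (is.na(atPos) || atPos != ref) {
          skipped["ref_mismatch"] <- skipped["ref_mismatch"] + 1
          next
        }
        five <- refBase(chrom, pos - 1L)
        three <- refBase(chrom, pos + 1L)
        if (is.na(five) || is.na(three) ||
            !(five %in% DNA_BASES) || !(three %in% DNA_BASES)) {
          skipped["n_or_edge"] <- skipped["n_or_edge"] + 1
          next
        }
        cls <- trinucleotideClass(ref, alt, five, three)
        counts[cls] <- counts[cls] + 1
      }
    }
  }
  sigLog("profileSNV", sample = sample, records = nrec,
         accepted = sum(counts), skipped = sum(skipped), verbose = verbose)
  new("FeatureProfile", sampleID = as.character(sample), group = "SNV",
      counts = counts, skipped = skipped)
}
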