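## SV profiling: 4 event classes (deletion, duplication, inversion,
## translocation) x 8 log10 size bins.  Event sizes follow the breakpoint
## convention: deletions/duplications/inversions measure nucleotides lost or
## gained (END - POS); a translocation measures the distance between the
## original and the new position, and an inter-chromosomal translocation has
## infinite size and falls in the whole-chromosome bin.

#' Map a VCF SVTYPE tag onto an event class
#'
#' \code{DEL} maps to deletion, \code{DUP} (including \code{DUP:TANDEM} and
#' other colon-qualified duplication subtypes) to duplication, \code{INV} to
#' inversion, and \code{TRA} or \code{BND} to translocation.  Unknown tags
#' return \code{NA} so the caller can tally the skip.
#'
#' @param svtype SVTYPE INFO tag value (character).
#' @return One of \code{"deletion"}, \code{"duplication"},
#'   \code{"inversion"}, \code{"translocation"}, or \code{NA}.
#' @examples
#' classifySvType("DUP")  # duplication
#' @export
classifySvType <- function(svtype) {
  if (is.na(svtype)) return(NA_character_)
  if (svtype == "DEL") return("deletion")
  if (svtype == "DUP" || startsWith(svtype, "DUP:")) return("duplication")
  if (svtype == "INV") return("inversion")
  if (svtype %in% c("TRA", "BND")) return("translocation")
  NA_character_
}

#' Size of a structural event in base pairs
#'
#' Deletions, duplications and inversions: \code{end - pos}.  Translocations:
#' the absolute distance between the two breakpoints when both are on the
#' same chromosome, \code{Inf} when the partner breakpoint is on a different
#' chromosome.  Returns \code{NA} when the size cannot be computed (missing
#' or inverted END).
#'
#' @param svClass event class as returned by [classifySvType()].
#' @param chrom,pos chromosome and 1-based position of the record.
#' @param end END INFO tag (or mate position for breakends); may be NA.
#' @param chr2 partner chromosome (CHR2 INFO tag or breakend mate contig);
#'   NA or equal to \code{chrom} for intra-chromosomal events.
#' @return Positive number of base pairs, \code{Inf}, or \code{NA}.
#' @examples
#' svEventSize("translocation", "chr1", 2e7, 2.5e7)       # 5e6
#' svEventSize("translocation", "chr1", 2e7, 123, "chr5") # Inf
#' @export
svEventSize <- function(svClass, chrom, pos, end, chr2 = NA) {
  if (svClass == "translocation") {
    if (!is.na(chr2) && chr2 != chrom) return(Inf)
    if (is.na(end)) return(NA_real_)
    return(abs(as.numeric(end) - as.numeric(pos)))
  }
  if (is.na(end)) return(NA_real_)
  size <- as.numeric(end) - as.numeric(pos)
  if (size < 0) return(NA_real_)
  size
}

#' Log10 size bin of a structural event
#'
#' Bins are half-open and lower-inclusive: [100, 1K), [1K, 10K), ...,
#' [100M, 1000M).  Infinite sizes -- and intra-chromosomal events at least as
#' long as their contig, when the contig length is known -- land in the
#' whole-chromosome bin.  Sizes below 100 bp are below the catalog and
#' return \code{NA}.
#'
#' @param size event size in base pairs (may be \code{Inf}).
#' @param contigLength optional length of the event's contig.
#' @return A bin label from the SV catalog, or \code{NA}.
#' @examples
#' svSizeBin(15000)  # "10K-100K"
#' svSizeBin(Inf)    # "whole-chrom"
#' @export
svSizeBin <- function(size, contigLength = NA) {
  if (is.na(size)) return(NA_character_)
  if (is.infinite(size)) return("whole-chrom")
  if (size < 100) return(NA_character_)
  if (!is.na(contigLength) && size >= contigLength) return("whole-chrom")
  k <- floor(log10(size))
  if (k > 8) return("whole-chrom")
  SV_BIN_LABELS[k - 1L]
}

## breakend ALT notation: t[chr:pos[ , t]chr:pos] , [chr:pos[t , ]chr:pos]t
parseBreakendAlt <- function(alt) {
  m <- regmatches(alt, regexec("[\\[\\]]([^\\[\\]:]+):([0-9]+)[\\[\\]]",
                               alt, perl = TRUE))[[1]]
  if (length(m) != 3L) return(NULL)
  list(chr2 = m[2], pos2 = as.numeric(m[3]))
}

infoTag <- function(info, tag) {
  m <- regmatches(info, regexec(paste0("(?:^|;)", tag, "=([^;]+)"), info))[[1]]
  if (length(m) != 2L) NA_character_ else m[2]
}

## default record parser (FindSV/TIDDIT/CNVnator/Manta dialects); returns a
## list(svClass, chrom, pos, end, chr2, pos2) or NULL when SVTYPE is absent
## or unknown.  Users with other caller dialects can pass their own.
parseSvRecord <- function(chrom, pos, alt, info) {
  svtype <- infoTag(info, "SVTYPE")
  svClass <- classifySvType(svtype)
  if (is.na(svClass)) return(NULL)
  end <- suppressWarnings(as.numeric(infoTag(info, "END")))
  chr2 <- infoTag(info, "CHR2")
  pos2 <- NA_real_
  if (!is.na(svtype) && svtype == "BND") {
    mate <- parseBreakendAlt(alt)
    if (!is.null(mate)) {
      if (is.na(chr2)) chr2 <- mate$chr2
      pos2 <- mate$pos2
      if (is.na(end)) end <- mate$pos2
    }
  }
  list(svClass = svClass, chrom = chrom, pos = as.numeric(pos),
       end = end, chr2 = chr2, pos2 = pos2, svtype = svtype)
}

## contig lengths from ##contig=<ID=...,length=...> header lines
vcfContigLengths <- function(meta) {
  hits <- grep("^##contig=", meta, value = TRUE)
  ids <- sub(".*[<,]ID=([^,>]+).*", "\\1", hits)
  lens <- suppressWarnings(as.numeric(
    ifelse(grepl("length=", hits), sub(".*length=([0-9]+).*", "\\1", hits), NA)))
  setNames(lens, ids)
}

#' Profile structural variants from a VCF
#'
#' Scans an SV VCF (SVTYPE/END/CHR2 INFO tags, breakend mates supported) and
#' counts accepted events over the 32-class catalog.  Paired breakend
#' records are counted once: only the mate whose (chromosome, position) sorts
#' first contributes.  Events smaller than 100 bp are below the catalog and
#' are skipped with a tally, as are records with unknown SVTYPE or
#' uncomputable size.  accepted + skipped always equals the number of input
#' records.
#'
#' @param vcfPath path to the SV VCF.
#' @param sample sample identifier used to label the profile.
#' @param parser record-parser hook: a function
#'   \code{(chrom, pos, alt, info) -> list(svClass, chrom, pos, end, chr2,
#'   pos2, svtype)} or NULL, substituting the built-in parser for other
#'   caller dialects.
#' @param verbose emit a one-line summary log.
#' @return A \code{FeatureProfile} of group \code{"SV"}.
#' @export
profileSV <- function(vcfPath, sample, parser = parseSvRecord,
                      verbose = FALSE) {
  if (!file.exists(vcfPath)) stopf("cannot read VCF '%s'", vcfPath)
  vcf <- vcfR::read.vcfR(vcfPath, verbose = FALSE)
  contigLens <- vcfContigLengths(vcf@meta)
  fix <- vcfR::getFIX(vcf)
  cat32 <- svCatalog()
  counts <- setNames(numeric(32L), cat32$featureID)
  skipped <- c(unknown_svtype = 0, bad_size = 0, below_catalog = 0,
               bnd_mate = 0)
  nrec <- 0L
  if (!is.null(fix) && nrow(rbind(fix)) > 0) {
    fix <- rbind(fix)
    info <- vcfR::getINFO(vcf)
    for (i in seq_len(nrow(fix))) {
      nrec <- nrec + 1L
      ev <- parser(fix[i, "CHROM"], as.numeric(fix[i, "POS"]),
                   fix[i, "ALT"], info[i])
      if (is.null(ev)) {
        skipped["unknown_svtype"] <- skipped["unknown_svtype"] + 1
        next
      }
      ## count each breakend pair once: keep the first-sorting mate
      if (!is.null(ev$svtype) && !is.na(ev$svtype) && ev$svtype == "BND" &&
          !is.na(ev$chr2) && !is.na(ev$pos2)) {
        mateFirst <- (ev$chr2 < ev$chrom) ||
          (ev$chr2 == ev$chrom && ev$pos2 < ev$pos)
        if (mateFirst) {
          skipped["bnd_mate"] <- skipped["bnd_mate"] + 1
          next
        }
      }
      size <- svEventSize(ev$svClass, ev$chrom, ev$pos, ev$end, ev$chr2)
      if (is.na(size)) {
        skipped["bad_size"] <- skipped["bad_size"] + 1
        next
      }
      cl <- contigLens[ev$chrom]
      bin <- svSizeBin(size, if (length(cl) && !is.na(cl)) cl else NA)
      if (is.na(bin)) {
        skipped["below_catalog"] <- skipped["below_catalog"] + 1
        next
      }
      fid <- paste0(ev$svClass, "_", bin)
      counts[fid] <- counts[fid] + 1
    }
  }
  sigLog("profileSV", sample = sample, records = nrec,
         accepted = sum(counts), skipped = sum(skipped), verbose = verbose)
  new("FeatureProfile", sampleID = as.character(sample), group = "SV",
      counts = counts, skipped = skipped)
}
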