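## MSI profiling: canonicalize microsatellite repeat units and count
## unstable loci per repeat-unit class from an MSIsensor-style somatic-site
## table.

cyclicRotations <- function(u) {
  n <- nchar(u)
  vapply(seq_len(n) - 1L, function(s)
    paste0(substr(u, s + 1L, n), substr(u, 1L, s)), character(1))
}

## is u a repetition of a strictly shorter unit? if so return the primitive
primitiveUnit <- function(u) {
  n <- nchar(u)
  for (d in seq_len(n - 1L)) {
    if (n %% d == 0L &&
        paste(rep(substr(u, 1L, d), n / d), collapse = "") == u)
      return(substr(u, 1L, d))
  }
  u
}

#' Canonical class of a microsatellite repeat unit
#'
#' For units of 1-3 bp the canonical class is the lexicographically smallest
#' string among all cyclic rotations of the unit and all cyclic rotations of
#' its reverse complement; units that are repetitions of a shorter unit
#' (e.g. \code{"CC"}) reduce to the shorter unit's class.  This convention
#' collapses the 84 possible 1-3 bp units onto exactly 16 classes
#' (A, C, AC, AG, AT, CG, AAC, AAG, AAT, ACC, ACG, ACT, AGC, AGG, ATC, CCG).
#' Units of declared length 4 or 5 are quantified pattern-free as
#' \code{"unit4"} / \code{"unit5"}; their internal repeat structure is never
#' inspected, so the declared length wins even for reducible motifs such as
#' \code{"ACAC"}.
#'
#' @param unit repeat-unit string, length 1-5, over A/C/G/T.
#' @return The class label (a catalog feature id).
#' @examples
#' canonicalRepeatUnit("GT")    # "AC"
#' canonicalRepeatUnit("ACGT")  # "unit4"
#' @export
canonicalRepeatUnit <- function(unit) {
  unit <- toupper(unit)
  n <- nchar(unit)
  if (n < 1L || n > 5L)
    stopf("repeat unit must be 1-5 bases long (got '%s')", unit)
  if (!grepl("^[ACGT]+$", unit))
    stopf("repeat unit must contain only A, C, G, T (got '%s')", unit)
  if (n == 4L) return("unit4")
  if (n == 5L) return("unit5")
  u <- primitiveUnit(unit)
  cands <- c(cyclicRotations(u), cyclicRotations(revcompUnit(u)))
  sort(cands)[1]
}

## default MSIsensor-style somatic-site parser: whitespace/tab-delimited
## columns (chromosome, location, left flank, repeat unit, repeat times,
## right flank); a header whose second field is non-numeric is skipped.
parseMsiLine <- function(fields) {
  if (length(fields) < 5L) return(NULL)
  unit <- toupper(fields[4])
  times <- suppressWarnings(as.integer(fields[5]))
  if (!grepl("^[ACGT]{1,5}$", unit) || is.na(times) || times < 1L)
    return(NULL)
  list(chrom = fields[1], pos = suppressWarnings(as.integer(fields[2])),
       repeatUnit = unit, repeatTimes = times)
}

#' Profile microsatellite-instability loci
#'
#' Reads an MSIsensor-style somatic-site table and counts the unstable loci
#' over the 18-class repeat-unit catalog ([msiCatalog()]).  Malformed rows
#' are skipped with a tally; accepted + skipped equals the number of data
#' rows.
#'
#' @param msiPath path to the locus table (whitespace/tab-delimited columns:
#'   chromosome, location, left flank, repeat unit, repeat times, right
#'   flank; an optional header line is detected and ignored).
#' @param sample sample identifier used to label the profile.
#' @param parser row-parser hook: a function taking the split fields of one
#'   line and returning \code{list(chrom, pos, repeatUnit, repeatTimes)} or
#'   \code{NULL}, substituting the built-in MSIsensor dialect.
#' @param verbose emit a one-line summary log.
#' @return A \code{FeatureProfile} of group \code{"MSI"}.
#' @export
profileMSI <- function(msiPath, sample, parser = parseMsiLine,
                       verbose = FALSE) {
  if (!file.exists(msiPath)) stopf("cannot read MSI table '%s'", msiPath)
  lines <- readLines(msiPath)
  lines <- lines[nzchar(trimws(lines))]
  cat18 <- msiCatalog()
  counts <- setNames(numeric(18L), cat18$featureID)
  skipped <- c(malformed = 0)
  nrow_ <- 0L
  for (i in seq_along(lines)) {
    fields <- strsplit(trimws(lines[i]), "[ \t]+")[[1]]
    ## header: second field non-numeric
    if (i == 1L && length(fields) >= 2L &&
        is.na(suppressWarnings(as.numeric(fields[2]))))
      next
    nrow_ <- nrow_ + 1L
    rec <- parser(fields)
    if (is.null(rec)) {
      skipped["malformed"] <- skipped["malformed"] + 1
      next
    }
    cls <- canonicalRepeatUnit(rec$repeatUnit)
    counts[cls] <- counts[cls] + 1
  }
  sigLog("profileMSI", sample = sample, rows = nrow_,
         accepted = sum(counts), skipped = sum(skipped), verbose = verbose)
  new("FeatureProfile", sampleID = as.character(sample), group = "MSI",
      counts = counts, skipped = skipped)
}
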