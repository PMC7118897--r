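## Deterministic synthetic data: a miniature reference genome, SNV/SV VCFs,
## MSIsensor-style locus tables and planted-signature cohorts.  All fixtures
## are written through the public file formats and re-read by the real
## parsers, and ground truth is recorded at generation time, so every
## profiler is exercised end to end with known expected counts.

#' Generate a deterministic miniature reference genome
#'
#' Random A/C/G/T sequence per contig (no N by default); optionally injects
#' N bases at recorded positions for context-skip tests.  Regenerating with
#' the same seed is byte-identical.
#'
#' @param seed integer seed.
#' @param contigs contig names.
#' @param length bases per contig (>= 3).
#' @param nInject number of N bases to inject per contig (never within the
#'   first/last 2 bp).
#' @param fastaPath optional path; when given, the FASTA is written there.
#' @return List with \code{sequences} (a \code{DNAStringSet}),
#'   \code{nPositions} (list of injected-N positions per contig) and
#'   \code{fasta} (the path or NULL).
#' @export
makeReference <- function(seed = 1L, contigs = "chr1", length = 1000L,
                          nInject = 0L, fastaPath = NULL) {
  stopifnot(length >= 3L)
  set.seed(deriveSeed(seed, "reference"))
  seqs <- character(0)
  nPos <- list()
  for (ctg in contigs) {
    bases <- sample(DNA_BASES, length, replace = TRUE)
    pos <- integer(0)
    if (nInject > 0L) {
      pos <- sort(sample(3:(length - 2L), nInject))
      bases[pos] <- "N"
    }
    seqs[ctg] <- paste(bases, collapse = "")
    nPos[[ctg]] <- pos
  }
  dss <- Biostrings::DNAStringSet(seqs)
  if (!is.null(fastaPath)) Biostrings::writeXStringSet(dss, fastaPath)
  list(sequences = dss, nPositions = nPos, fasta = fastaPath)
}

vcfHeaderLines <- function(contigs, contigLengths, extraInfo = character(0),
                           sample = NULL) {
  c("##fileformat=VCFv4.2",
    sprintf("##contig=<ID=%s,length=%d>", contigs, contigLengths),
    extraInfo,
    paste(c("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
            if (!is.null(sample)) c("FORMAT", sample)), collapse = "\t"))
}

## per-contig index of positions realizing each trinucleotide context,
## consumed front to back as variants are planted
contextSiteIndex <- function(seqs) {
  idx <- new.env(parent = emptyenv())
  for (ctg in names(seqs)) {
    chars <- strsplit(as.character(seqs[[ctg]]), "")[[1]]
    n <- length(chars)
    if (n < 3L) next
    tri <- paste0(chars[1:(n - 2L)], chars[2:(n - 1L)], chars[3:n])
    sites <- split(seq_len(n - 2L) + 1L, tri)
    for (t in names(sites))
      assign(paste0(ctg, ":", t), sites[[t]], envir = idx)
  }
  idx
}

takeContextSite <- function(idx, contigs, trinuc) {
  for (ctg in contigs) {
    key <- paste0(ctg, ":", trinuc)
    sites <- idx[[key]]
    if (!is.null(sites) && length(sites)) {
      assign(key, sites[-1L], envir = idx)
      return(list(contig = ctg, pos = sites[1L]))
    }
  }
  NULL
}

#' Generate an SNV VCF with planted trinucleotide classes
#'
#' For each requested feature class (e.g. \code{"G[T>C]G"}, repeated for
#' multiplicity) a locus realizing that trinucleotide context is located on
#' the reference and a corresponding substitution record is written.  The
#' planted class multiset is returned as ground truth; by construction it
#' equals what [profileSNV()] counts.  Classes are planted in their
#' pyrimidine-reference representation.
#'
#' @param reference result of [makeReference()] (or a \code{DNAStringSet}).
#' @param plantedClasses character vector of catalog feature ids (with
#'   repeats for multiplicity); may be empty.
#' @param vcfPath output VCF path.
#' @param seed integer seed (record shuffling).
#' @return List with \code{vcf} (path) and \code{truth} (named count vector
#'   over the planted classes).
#' @export
makeSnvVcf <- function(reference, plantedClasses, vcfPath, seed = 1L) {
  seqs <- if (is(reference, "DNAStringSet")) reference else reference$sequences
  recs <- character(length(plantedClasses))
  idx <- contextSiteIndex(seqs)
  for (j in seq_along(plantedClasses)) {
    cls <- plantedClasses[j]
    m <- regmatches(cls, regexec(
      "^([ACGT])\\[([ACGT])>([ACGT])\\]([ACGT])$", cls))[[1]]
    if (length(m) != 5L) stopf("'%s' is not a valid SNV feature id", cls)
    five <- m[2]; ref <- m[3]; alt <- m[4]; three <- m[5]
    site <- takeContextSite(idx, names(seqs), paste0(five, ref, three))
    if (is.null(site))
      stopf("context for class '%s' not realizable on this reference; use a longer reference",
            cls)
    recs[j] <- paste(site$contig, site$pos, ".", ref, alt, ".", "PASS",
                     ".", sep = "\t")
  }
  set.seed(deriveSeed(seed, "snv-vcf"))
  if (length(recs) > 1L) recs <- sample(recs)
  writeLines(c(vcfHeaderLines(names(seqs), Biostrings::width(seqs)), recs),
             vcfPath)
  truth <- if (length(plantedClasses)) table(plantedClasses) else table(character(0))
  list(vcf = vcfPath, truth = setNames(as.numeric(truth), names(truth)))
}

#' Generate an SV VCF with planted events
#'
#' Events are given as a data.frame with columns \code{svClass}
#' (deletion/duplication/inversion/translocation), \code{chrom}, \code{pos}
#' and either \code{size} (intra-chromosomal; \code{Inf} for
#' inter-chromosomal translocations, which are emitted as breakend mate
#' pairs on different contigs) or explicit \code{end}/\code{chr2}.  Ground
#' truth (the expected 32-class counts from [profileSV()]) is recorded at
#' generation time.
#'
#' @param events data.frame as described above.
#' @param vcfPath output VCF path.
#' @param contigs,contigLengths VCF header contigs (defaults cover chr1/chr2
#'   at 250 Mb).
#' @param seed integer seed (record shuffling).
#' @return List with \code{vcf} (path) and \code{truth} (named count vector
#'   over SV catalog feature ids).
#' @export
makeSvVcf <- function(events, vcfPath, contigs = c("chr1", "chr2"),
                      contigLengths = c(250000000L, 240000000L), seed = 1L) {
  hdr <- vcfHeaderLines(contigs, contigLengths, extraInfo = c(
    '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="SV type">',
    '##INFO=<ID=END,Number=1,Type=Integer,Description="End position">',
    '##INFO=<ID=CHR2,Number=1,Type=String,Description="Partner chromosome">'))
  recs <- character(0)
  truth <- setNames(numeric(32L), svCatalog()$featureID)
  idn <- 0L
  for (i in seq_len(nrow(events))) {
    ev <- events[i, ]
    idn <- idn + 1L
    if (ev$svClass == "translocation") {
      if (is.infinite(ev$size)) {
        chr2 <- setdiff(contigs, ev$chrom)[1]
        pos2 <- 1000L + idn
        recs <- c(recs,
          paste(ev$chrom, ev$pos, sprintf("bnd_%d_1", idn), "N",
                sprintf("N[%s:%d[", chr2, pos2), ".", "PASS",
                "SVTYPE=BND", sep = "\t"),
          paste(chr2, pos2, sprintf("bnd_%d_2", idn), "N",
                sprintf("]%s:%d]N", ev$chrom, ev$pos), ".", "PASS",
                "SVTYPE=BND", sep = "\t"))
        truth["translocation_whole-chrom"] <-
          truth["translocation_whole-chrom"] + 1
      } else {
        end <- ev$pos + ev$size
        recs <- c(recs, paste(ev$chrom, ev$pos, sprintf("tra_%d", idn), "N",
                              "<TRA>", ".", "PASS",
                              sprintf("SVTYPE=TRA;END=%d;CHR2=%s",
                                      as.integer(end), ev$chrom), sep = "\t"))
        bin <- svSizeBin(ev$size,
                         contigLengths[match(ev$chrom, contigs)])
        truth[paste0("translocation_", bin)] <-
          truth[paste0("translocation_", bin)] + 1
      }
    } else {
      tag <- c(deletion = "DEL", duplication = "DUP",
               inversion = "INV")[ev$svClass]
      end <- ev$pos + ev$size
      recs <- c(recs, paste(ev$chrom, ev$pos,
                            sprintf("%s_%d", tolower(tag), idn), "N",
                            sprintf("<%s>", tag), ".", "PASS",
                            sprintf("SVTYPE=%s;END=%d", tag, as.integer(end)),
                            sep = "\t"))
      bin <- svSizeBin(ev$size, contigLengths[match(ev$chrom, contigs)])
      if (is.na(bin)) next  # deliberately below-catalog event
      truth[paste0(ev$svClass, "_", bin)] <-
        truth[paste0(ev$svClass, "_", bin)] + 1
    }
  }
  set.seed(deriveSeed(seed, "sv-vcf"))
  if (length(recs) > 1L) recs <- sample(recs)
  writeLines(c(hdr, recs), vcfPath)
  list(vcf = vcfPath, truth = truth)
}

#' Generate an MSIsensor-style somatic locus table
#'
#' One row per planted locus; repeat units are written as given (possibly
#' non-canonical, e.g. \code{"GT"}), and the ground truth records the
#' canonical class counts expected from [profileMSI()].
#'
#' @param units character vector of repeat units (1-5 bp), one per locus.
#' @param tablePath output path.
#' @param seed integer seed (locus coordinates).
#' @param header write the MSIsensor header line.
#' @return List with \code{table} (path) and \code{truth} (named count
#'   vector over MSI catalog feature ids).
#' @export
makeMsiTable <- function(units, tablePath, seed = 1L, header = TRUE) {
  set.seed(deriveSeed(seed, "msi-table"))
  truth <- setNames(numeric(18L), msiCatalog()$featureID)
  rows <- character(0)
  for (u in units) {
    cls <- canonicalRepeatUnit(u)
    truth[cls] <- truth[cls] + 1
    rows <- c(rows, paste("chr1", sample.int(1e6, 1), "CATG", u,
                          sample(5:20, 1), "TTAG", sep = "\t"))
  }
  hdr <- paste("chromosome", "location", "left_flank", "repeat_unit",
               "repeat_times", "right_flank", sep = "\t")
  writeLines(c(if (header) hdr, rows), tablePath)
  list(table = tablePath, truth = truth)
}

## random column-stochastic signature respecting group-block weights
randomSignature <- function(catalog, weights, concentration = 0.3) {
  v <- numeric(nrow(catalog))
  for (g in names(weights)) {
    idx <- which(catalog$group == g)
    x <- stats::rgamma(length(idx), shape = concentration)
    if (sum(x) == 0) x[sample.int(length(x), 1)] <- 1
    v[idx] <- x / sum(x) * weights[g]
  }
  v
}

#' Generate a planted-signature cohort
#'
#' Draws k ground-truth signatures P0 (group blocks respecting the default
#' 7:2:1 weights, pairwise cosine similarity below \code{separation}),
#' per-sample exposures E0 from a flat Dirichlet, and per-sample per-group
#' event counts as multinomial draws from the group block of the expected
#' profile P0 E0.  The counts become [FeatureProfile-class] objects, so
#' [mergeProfiles()] on them reproduces the study's merged-matrix pipeline.
#' Everything is derived from the master seed; the same seed regenerates
#' the identical cohort.
#'
#' @param k number of planted signatures (>= 1).
#' @param nSamples cohort size (> k).
#' @param separation upper bound on pairwise cosine similarity of the
#'   planted signatures (default 0.3).
#' @param totals named per-group per-sample event totals (default SNV 5000,
#'   SV 200, MSI 100, echoing a tumor-cohort scale).
#' @param weights group weights (default 7:2:1).
#' @param seed master seed.
#' @param maxTries attempts at drawing a signature set meeting the
#'   separation bound before erroring.
#' @return List with \code{P0} (features x k), \code{E0} (k x samples),
#'   \code{profiles} (list of FeatureProfiles), \code{merged} (the merged
#'   [FeatureMatrix-class]) and \code{seed}.
#' @export
makePlantedCohort <- function(k = 3L, nSamples = 60L, separation = 0.3,
                              totals = c(SNV = 5000, SV = 200, MSI = 100),
                              weights = featureWeights(), seed = 1L,
                              maxTries = 500L) {
  stopifnot(k >= 1L, nSamples > k)
  catalog <- fullCatalog()
  set.seed(deriveSeed(seed, "cohort-signatures"))
  P0 <- NULL
  for (try in seq_len(maxTries)) {
    cand <- vapply(seq_len(k), function(i)
      randomSignature(catalog, weights), numeric(nrow(catalog)))
    cn <- sweep(cand, 2L, sqrt(colSums(cand^2)), "/")
    cos <- crossprod(cn)
    if (k == 1L || max(cos[upper.tri(cos)]) < separation) {
      P0 <- cand
      break
    }
  }
  if (is.null(P0))
    stopf("could not draw %d signatures with pairwise cosine < %g",
          k, separation)
  dimnames(P0) <- list(catalog$featureID, paste0("true", seq_len(k)))
  set.seed(deriveSeed(seed, "cohort-exposures"))
  E0 <- matrix(stats::rgamma(k * nSamples, shape = 1), k, nSamples)
  E0 <- sweep(E0, 2L, colSums(E0), "/")
  sampleIDs <- sprintf("S%03d", seq_len(nSamples))
  dimnames(E0) <- list(colnames(P0), sampleIDs)
  expected <- P0 %*% E0
  profiles <- list()
  groups <- names(totals)
  for (s in seq_len(nSamples)) {
    set.seed(deriveSeed(seed, paste0("cohort-counts-", s)))
    for (g in groups) {
      idx <- which(catalog$group == g)
      pr <- expected[idx, s]
      pr <- pr / sum(pr)
      cnt <- as.numeric(rmultinom(1L, size = totals[g], prob = pr))
      profiles[[length(profiles) + 1L]] <-
        FeatureProfile(sampleIDs[s], g,
                       setNames(cnt, catalog$featureID[idx]))
    }
  }
  merged <- mergeProfiles(profiles, weights = weights)
  list(P0 = P0, E0 = E0, profiles = profiles, merged = merged, seed = seed)
}

#' Match estimated signatures to ground truth by cosine similarity
#'
#' Greedy one-to-one assignment on the cosine-similarity matrix between
#' estimated and true signature columns (highest similarity first).  Used
#' to evaluate planted-signature recovery.
#'
#' @param P estimated signature matrix (features x k).
#' @param P0 true signature matrix (features x k).
#' @return data.frame with columns \code{estimated}, \code{truth},
#'   \code{cosine}.
#' @export
matchSignatures <- function(P, P0) {
  stopifnot(ncol(P) == ncol(P0))
  Pn <- sweep(P, 2L, pmax(sqrt(colSums(P^2)), 1e-12), "/")
  P0n <- sweep(P0, 2L, pmax(sqrt(colSums(P0^2)), 1e-12), "/")
  sim <- crossprod(Pn, P0n)  # est x true
  k <- ncol(P)
  out <- data.frame(estimated = character(k), truth = character(k),
                    cosine = numeric(k), stringsAsFactors = FALSE)
  simW <- sim
  for (r in seq_len(k)) {
    ij <- which(simW == max(simW), arr.ind = TRUE)[1, ]
    out$estimated[r] <- colnames(sim)[ij[1]]
    out$truth[r] <- colnames(P0)[ij[2]]
    out$cosine[r] <- sim[ij[1], ij[2]]
    simW[ij[1], ] <- -Inf
    simW[, ij[2]] <- -Inf
  }
  out
}
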