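test_that("substitutions fold onto the six pyrimidine-reference classes", {
  expect_equal(canonicalSubstitution("T", "C"), "T>C")
  expect_equal(canonicalSubstitution("C", "A"), "C>A")
  expect_equal(canonicalSubstitution("G", "T"), "C>A")
  ## exhaustive: the 12 ordered pairs are a 2-to-1 surjection onto 6 classes
  pairs <- expand.grid(ref = c("A", "C", "G", "T"),
                       alt = c("A", "C", "G", "T"),
                       stringsAsFactors = FALSE)
  pairs <- pairs[pairs$ref != pairs$alt, ]
  got <- mapply(canonicalSubstitution, pairs$ref, pairs$alt)
  expect_equal(sort(unique(got)),
               c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G"))
  expect_true(all(table(got) == 2L))
  ## each purine pair agrees with its complement-oracle image
  for (i in seq_len(nrow(pairs))) {
    if (pairs$ref[i] %in% c("A", "G")) {
      expect_equal(unname(got[i]),
                   canonicalSubstitution(oracleComplement(pairs$ref[i]),
                                         oracleComplement(pairs$alt[i])))
    }
  }
  expect_error(canonicalSubstitution("C", "C"), "must differ")
  expect_error(canonicalSubstitution("N", "A"), "A, C, G, T")
})

test_that("trinucleotide classes fold context together with the substitution", {
  expect_equal(trinucleotideClass("T", "C", "G", "G"), "G[T>C]G")
  expect_equal(trinucleotideClass("C", "T", "A", "A"), "A[C>T]A")
  expect_equal(trinucleotideClass("A", "G", "C", "T"), "A[T>C]G")

  ## exhaustive: 192 (substitution, context) combos, 2 per each of the 96
  ## classes, all agreeing with the reverse-complement oracle
  bases <- c("A", "C", "G", "T")
  combos <- expand.grid(ref = bases, alt = bases, five = bases,
                        three = bases, stringsAsFactors = FALSE)
  combos <- combos[combos$ref != combos$alt, ]
  expect_equal(nrow(combos), 192L)
  got <- mapply(trinucleotideClass, combos$ref, combos$alt, combos$five,
                combos$three)
  want <- mapply(oracleTrinucClass, combos$ref, combos$alt, combos$five,
                 combos$three)
  expect_equal(unname(got), unname(want))
  expect_equal(sort(unique(got)), sort(snvCatalog()$featureID))
  expect_true(all(table(got) == 2L))
})

test_that("strand symmetry: a variant and its reverse complement agree", {
  set.seed(5)
  bases <- c("A", "C", "G", "T")
  for (i in 1:50) {
    ref <- sample(bases, 1)
    alt <- sample(setdiff(bases, ref), 1)
    five <- sample(bases, 1); three <- sample(bases, 1)
    expect_equal(
      trinucleotideClass(ref, alt, five, three),
      trinucleotideClass(oracleComplement(ref), oracleComplement(alt),
                         oracleComplement(three), oracleComplement(five)))
  }
})

test_that("profileSNV reproduces the worked single-record example", {
  ref <- testReference()
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  fx <- makeSnvVcf(ref, "G[T>C]G", vcfPath)
  prof <- profileSNV(vcfPath, ref$sequences, "TUMOR1")
  expect_s4_class(prof, "FeatureProfile")
  expect_equal(unname(profileCounts(prof)["G[T>C]G"]), 1)
  expect_equal(totalCount(prof), 1)
  expect_equal(sum(profileCounts(prof) > 0), 1L)
})

test_that("profileSNV on an empty VCF yields an all-zero profile", {
  ref <- testReference()
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  suppressWarnings(makeSnvVcf(ref, character(0), vcfPath))
  prof <- suppressWarnings(profileSNV(vcfPath, ref$sequences, "S"))
  expect_equal(totalCount(prof), 0)
  expect_equal(length(profileCounts(prof)), 96L)
})

test_that("profileSNV recovers a planted 50-variant multiset exactly", {
  ref <- testReference()
  set.seed(7)
  planted <- sample(snvCatalog()$featureID, 50, replace = TRUE)
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  fx <- makeSnvVcf(ref, planted, vcfPath, seed = 3L)
  prof <- profileSNV(vcfPath, ref$sequences, "S")
  expect_equal(totalCount(prof), 50)
  got <- profileCounts(prof)
  expect_equal(got[names(fx$truth)], fx$truth, ignore_attr = FALSE)
  expect_equal(sum(got[setdiff(names(got), names(fx$truth))]), 0)
})

test_that("profileSNV tallies every rejected record by reason", {
  ref <- testReference()
  seqs <- ref$sequences
  ## craft records exercising each skip reason around one valid record
  chars <- strsplit(as.character(seqs[["chrA"]]), "")[[1]]
  pos <- which(chars[1:19998] == "A" & chars[2:19999] == "C" &
               chars[3:20000] == "G")[1] + 1L
  lines <- c(
    "##fileformat=VCFv4.2",
    "##contig=<ID=chrA,length=20000>",
    paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER", "INFO",
          sep = "\t"),
    sprintf("chrA\t%d\tok\tC\tT\t.\tPASS\t.", pos),
    sprintf("chrA\t%d\tindel\tC\tTA\t.\tPASS\t.", pos),          # non-SNV
    sprintf("chrA\t%d\tfiltered\tC\tT\t.\tq10\t.", pos),         # FILTER
    sprintf("chrA\t%d\tmismatch\t%s\tT\t.\tPASS\t.", pos,
            if (chars[pos] == "G") "C" else "G"),                # REF wrong
    "chrA\t1\tedge\tC\tG\t.\tPASS\t.",                            # contig edge
    sprintf("chrA\t%d\tmulti\tC\tT,G\t.\tPASS\t.", pos))         # decomposed
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, vcfPath)
  prof <- profileSNV(vcfPath, seqs, "S")
  ## multi-allelic record decomposes into 2; total input records = 7
  expect_equal(totalCount(prof) + sum(skippedRecords(prof)), 7)
  expect_equal(totalCount(prof), 3)  # ok + both decomposed alts
  sk <- skippedRecords(prof)
  expect_equal(unname(sk["non_snv"]), 1)
  expect_equal(unname(sk["filter_fail"]), 1)
  expect_gte(sk[["ref_mismatch"]] + sk[["n_or_edge"]], 2)
  ## filtered records are admitted when passOnly is off
  prof2 <- profileSNV(vcfPath, seqs, "S", passOnly = FALSE)
  expect_equal(totalCount(prof2), 4)
})

test_that("profileSNV fails hard on a contig missing from the reference", {
  ref <- testReference()
  lines <- c("##fileformat=VCFv4.2",
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"),
             "chrZ\t100\t.\tA\tG\t.\tPASS\t.")
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, vcfPath)
  expect_error(profileSNV(vcfPath, ref$sequences, "S"), "chrZ")
})
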