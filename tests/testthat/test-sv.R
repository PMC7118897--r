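test_that("SVTYPE tags map onto the four event classes", {
  expect_equal(classifySvType("DUP"), "duplication")
  expect_equal(classifySvType("DUP:TANDEM"), "duplication")
  expect_equal(classifySvType("DEL"), "deletion")
  expect_equal(classifySvType("INV"), "inversion")
  expect_equal(classifySvType("TRA"), "translocation")
  expect_equal(classifySvType("BND"), "translocation")
  expect_true(is.na(classifySvType("CNV")))
  expect_true(is.na(classifySvType(NA)))
})

test_that("event sizes follow the breakpoint-distance convention", {
  ## a 100 bp segment moved from 20 Mb to 25 Mb within one chromosome:
  ## the event size is the 5 Mb breakpoint distance, not the segment length
  expect_equal(svEventSize("translocation", "chr1", 20000000, 25000000),
               5e6)
  expect_equal(svEventSize("translocation", "chr1", 20000000, 123, "chr5"),
               Inf)
  expect_equal(svEventSize("duplication", "chr1", 10001, 25001), 15000)
  expect_equal(svEventSize("deletion", "chr1", 500, 1500), 1000)
  ## inverted END is uncomputable
  expect_true(is.na(svEventSize("deletion", "chr1", 1500, 500)))
  expect_true(is.na(svEventSize("inversion", "chr1", 1500, NA)))
})

test_that("size bins partition [100, Inf] on the log10 scale", {
  expect_equal(svSizeBin(15000), "10K-100K")
  expect_equal(svSizeBin(100), "100-1K")
  expect_equal(svSizeBin(5e6), "1M-10M")
  expect_equal(svSizeBin(Inf), "whole-chrom")
  expect_true(is.na(svSizeBin(99)))
  ## sweep: bin matches the floor(log10) oracle and is monotone in size
  sizes <- sort(c(10^(2:9), 10^(2:9) - 1, 10^(2:9) + 1,
                  round(10^runif(200, 2, 9))))
  sizes <- sizes[sizes >= 100]
  bins <- vapply(sizes, svSizeBin, character(1))
  labels <- c("100-1K", "1K-10K", "10K-100K", "100K-1M", "1M-10M",
              "10M-100M", "100M-1000M", "whole-chrom")
  oracleIdx <- pmin(floor(log10(sizes)) - 1, 8)
  expect_equal(bins, labels[oracleIdx])
  expect_true(all(diff(match(bins, labels)) >= 0))
  ## contig-length rule: an event spanning its whole contig escalates
  expect_equal(svSizeBin(5e6, contigLength = 5e6), "whole-chrom")
  expect_equal(svSizeBin(5e6, contigLength = 2e8), "1M-10M")
})

test_that("profileSV reproduces the worked 15 kb duplication example", {
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  fx <- makeSvVcf(data.frame(svClass = "duplication", chrom = "chr1",
                             pos = 10001, size = 15000), vcfPath)
  prof <- profileSV(vcfPath, "S")
  expect_equal(unname(profileCounts(prof)["duplication_10K-100K"]), 1)
  expect_equal(totalCount(prof), 1)
})

test_that("profileSV recovers planted events across all 32 classes", {
  cat32 <- svCatalog()
  set.seed(13)
  events <- list()
  ## at least one event per class: finite bins get a mid-bin size,
  ## whole-chrom classes get an oversized or inter-chromosomal event
  for (i in seq_len(nrow(cat32))) {
    cls <- cat32$variantType[i]; bin <- cat32$subgroup[i]
    if (bin == "whole-chrom") {
      if (cls == "translocation") {
        events[[i]] <- data.frame(svClass = cls, chrom = "chr1",
                                  pos = 5e6 + i, size = Inf)
      } else {
        ## intra-chromosomal event >= contig length
        events[[i]] <- data.frame(svClass = cls, chrom = "chr1",
                                  pos = 1, size = 2e9)
      }
    } else {
      lo <- c(`100-1K` = 100, `1K-10K` = 1e3, `10K-100K` = 1e4,
              `100K-1M` = 1e5, `1M-10M` = 1e6, `10M-100M` = 1e7,
              `100M-1000M` = 1e8)[bin]
      events[[i]] <- data.frame(svClass = cls, chrom = "chr1",
                                pos = 1000 + i * 7, size = 3 * lo)
    }
  }
  ## extra copies of a few classes to get multiplicities
  events <- c(events, events[c(1, 1, 10, 20)])
  events <- do.call(rbind, events)
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  ## an oversized fixture contig so the 100M-1000M bin stays below the
  ## whole-chromosome escalation rule
  fx <- makeSvVcf(events, vcfPath,
                  contigLengths = c(2000000000L, 240000000L), seed = 3L)
  prof <- profileSV(vcfPath, "S")
  expect_equal(profileCounts(prof), fx$truth)
  expect_equal(totalCount(prof), nrow(events))
  expect_true(all(profileCounts(prof) >= 1))
})

test_that("breakend mate pairs are counted once and reconcile", {
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  fx <- makeSvVcf(data.frame(svClass = "translocation", chrom = "chr1",
                             pos = 7e6, size = Inf), vcfPath)
  prof <- profileSV(vcfPath, "S")
  expect_equal(unname(profileCounts(prof)["translocation_whole-chrom"]), 1)
  expect_equal(totalCount(prof), 1)
  expect_equal(unname(skippedRecords(prof)["bnd_mate"]), 1)
  ## 2 VCF records, 1 accepted + 1 mate-skip
  expect_equal(totalCount(prof) + sum(skippedRecords(prof)), 2)
})

test_that("unknown SVTYPE and sub-catalog events are skipped with a tally", {
  lines <- c("##fileformat=VCFv4.2",
             "##contig=<ID=chr1,length=250000000>",
             '##INFO=<ID=SVTYPE,Number=1,Type=String,Description="t">',
             '##INFO=<ID=END,Number=1,Type=Integer,Description="e">',
             paste("#CHROM", "POS", "ID", "REF", "ALT", "QUAL", "FILTER",
                   "INFO", sep = "\t"),
             "chr1\t1000\ta\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=1500",
             "chr1\t1000\tb\tN\t<CNV>\t.\tPASS\tSVTYPE=CNV;END=9000",
             "chr1\t1000\tc\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL;END=1050",
             "chr1\t1000\td\tN\t<DEL>\t.\tPASS\tSVTYPE=DEL")
  vcfPath <- withr::local_tempfile(fileext = ".vcf")
  writeLines(lines, vcfPath)
  prof <- profileSV(vcfPath, "S")
  expect_equal(totalCount(prof), 1)
  sk <- skippedRecords(prof)
  expect_equal(unname(sk["unknown_svtype"]), 1)
  expect_equal(unname(sk["below_catalog"]), 1)
  expect_equal(unname(sk["bad_size"]), 1)
  expect_equal(totalCount(prof) + sum(sk), 4)
})
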