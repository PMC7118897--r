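countPdfPages <- function(path) {
  ## the pdf() device writes one "/Type /Page /Parent" object per page
  ## (the "/Pages" tree node does not match)
  raw <- readBin(path, "raw", file.info(path)$size)
  length(grepRaw("/Type /Page /Parent", raw, fixed = TRUE, all = TRUE))
}

test_that("signature association uses a strict 30% threshold", {
  fr <- c(S1 = 0.26, S2 = 0.30, S3 = 0.30 + 1e-9, S4 = 0.139999999)
  expect_equal(associatedSignatures(fr), "S3")
  expect_equal(associatedSignatures(c(A = 0.5, B = 0.4, C = 0.1)),
               c("A", "B"))
  expect_equal(associatedSignatures(c(A = 0.2, B = 0.3, C = 0.5),
                                    threshold = 0.5), character(0))
  expect_error(associatedSignatures(c(A = -0.1)), "\\[0, 1\\]")
})

test_that("tumor mutation burden divides substitution totals by 30", {
  expect_equal(tmb(FeatureProfile("S", "SNV")), 0)
  expect_equal(tmb(FeatureProfile("S", "SNV", c(`A[C>A]A` = 2040))), 68)
  expect_equal(tmb(FeatureProfile("S", "SNV", c(`A[C>A]A` = 26000,
                                                `T[T>G]T` = 430))), 881)
  ## linear in counts
  p1 <- FeatureProfile("S", "SNV", c(`A[C>A]A` = 30, `C[C>G]C` = 60))
  p2 <- FeatureProfile("S", "SNV", c(`A[C>A]A` = 90, `C[C>G]C` = 180))
  expect_equal(3 * tmb(p1), tmb(p2))
  ## fraction-normalized profiles are rejected
  frac <- FeatureProfile("S", "SNV", c(`A[C>A]A` = 0.7, `C[C>G]C` = 0.3))
  expect_error(tmb(frac), "raw counts")
  expect_error(tmb(FeatureProfile("S", "SV")), "SNV profile")
})

test_that("structural variation burden totals the SV profile", {
  expect_equal(svb(FeatureProfile("S", "SV")), 0)
  one <- setNames(rep(1, 32), svCatalog()$featureID)
  expect_equal(svb(FeatureProfile("S", "SV", one)), 32)
  expect_equal(svb(FeatureProfile("S", "SV", c(`deletion_1K-10K` = 40))), 40)
  expect_error(svb(FeatureProfile("S", "MSI")), "SV profile")
})

test_that("sample reports conserve observed = reconstructed + residual", {
  set.seed(8)
  P <- matrix(rgamma(146 * 3, 0.4), 146, 3,
              dimnames = list(fullCatalog()$featureID, c("A", "B", "C")))
  P <- sweep(P, 2, colSums(P), "/")
  m <- runif(146); m <- m / sum(m)
  rpt <- sampleReport("S1", P, m)
  expect_identical(rpt$observed - rpt$reconstructed, rpt$residual)
  expect_equal(sum(rpt$fractions), 1, tolerance = 1e-9)
  expect_equal(rpt$errorNorm, sqrt(sum(rpt$residual^2)))
})

test_that("rendered reports have 4 pages and a consistent numeric annex", {
  set.seed(9)
  P <- matrix(rgamma(146 * 3, 0.4), 146, 3,
              dimnames = list(fullCatalog()$featureID,
                              c("Signature.A", "Signature.B", "Signature.C")))
  P <- sweep(P, 2, colSums(P), "/")
  dir <- withr::local_tempdir()
  pdfPath <- file.path(dir, "S1.pdf")
  m <- 0.6 * P[, 1] + 0.4 * P[, 3]
  rpt <- renderReport("S1", P, m, pdfPath)
  expect_true(file.exists(pdfPath))
  expect_equal(countPdfPages(pdfPath), 4L)
  annex <- read.delim(rpt$annex)
  expect_equal(annex$observed, unname(m), tolerance = 1e-12)
  expect_equal(annex$observed - annex$reconstructed, annex$residual,
               tolerance = 1e-12)
  ## the pie fractions equal the normalized-weights row for the sample
  E <- matrix(rpt$fractions, ncol = 1,
              dimnames = list(names(rpt$fractions), "S1"))
  wPath <- file.path(dir, "normalized_weights.txt")
  writeNormalizedWeights(E, wPath)
  back <- readNormalizedWeights(wPath)
  expect_equal(back[, "S1"], rpt$fractions, tolerance = 1e-9)
  expect_equal(unname(rpt$fractions), c(0.6, 0, 0.4), tolerance = 1e-6)
  ## an observed profile equal to a signature column leaves zero residual
  rpt0 <- renderReport("S2", P, P[, 2], file.path(dir, "S2.pdf"))
  expect_lt(max(abs(rpt0$residual)), 1e-10)
  expect_error(renderReport("S3", P, m[-1], file.path(dir, "S3.pdf")),
               "does not match")
})

test_that("normalized weights rows sum to 100 and round-trip to E", {
  set.seed(10)
  E <- matrix(rgamma(4 * 7, 1), 4, 7,
              dimnames = list(paste0("Sig", 1:4), paste0("s", 1:7)))
  path <- withr::local_tempfile(fileext = ".txt")
  writeNormalizedWeights(E, path)
  tab <- read.delim(path, check.names = FALSE)
  expect_equal(colnames(tab), c("sample", paste0("Sig", 1:4)))
  sums <- rowSums(as.matrix(tab[, -1]))
  expect_true(all(abs(sums - 100) < 1e-6))
  back <- readNormalizedWeights(path)
  En <- sweep(E, 2, colSums(E), "/")
  expect_equal(back, En, tolerance = 1e-6)
  Ebad <- E; Ebad[, 2] <- 0
  expect_error(writeNormalizedWeights(Ebad, path), "positive total")
})
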