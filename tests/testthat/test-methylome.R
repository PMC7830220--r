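writeCalls <- function(rows) {
  f <- tempfile(fileext = ".tsv")
  writeLines(vapply(rows, paste, "", collapse = "\t"), f)
  f
}

test_that("call reading enforces the coverage floor and input sanity", {
  f <- writeCalls(list(c("chr1", 10, "+", "CG", 1, 3),
                       c("chr1", 20, "+", "CG", 2, 4),
                       c("chr1", 30, "-", "CHH", 0, 10)))
  tr <- readMethylationCalls(f, minCoverage = 4)
  expect_equal(length(tr), 2L)           # coverage 3 dropped, 4 kept
  expect_equal(start(trackSites(tr)), c(20L, 30L))

  dup <- writeCalls(list(c("chr1", 10, "+", "CG", 1, 5),
                         c("chr1", 10, "+", "CG", 2, 6)))
  expect_error(readMethylationCalls(dup), "duplicate")

  bad <- writeCalls(list(c("chr1", 10, "+", "CG", 7, 5)))
  expect_error(readMethylationCalls(bad), "exceeds total")
})

test_that("coverage filtering is an idempotent monotone filter", {
  set.seed(9)
  rows <- lapply(1:50, function(i)
    c("chr1", i * 10, "+", "CG", 0, sample(0:12, 1)))
  f <- writeCalls(rows)
  t4 <- readMethylationCalls(f, minCoverage = 4)
  t8direct <- readMethylationCalls(f, minCoverage = 8)
  gr <- trackSites(t4)
  keep <- mcols(gr)$tCount >= 8
  expect_equal(start(trackSites(t8direct)), start(gr)[keep])
})

test_that("site and region levels follow sum(m)/sum(t)", {
  expect_equal(siteLevel(2, 4), 0.5)
  expect_equal(siteLevel(0, 4), 0.0)
  expect_equal(siteLevel(4, 4), 1.0)
  expect_error(siteLevel(0, 0), "zero coverage")

  tr <- makeTrack(data.frame(chrom = "chr1", pos = c(10, 20, 100),
                             strand = "+", context = c("CG", "CG", "CHH"),
                             m = c(2, 0, 3), t = c(4, 4, 4)))
  reg <- GRanges("chr1", IRanges(1, 50))
  expect_equal(regionLevel(tr, reg, "CG"), 0.25)
  expect_equal(regionLevel(tr, GRanges("chr1", IRanges(90, 110)), "CHH"),
               0.75)
  expect_error(regionLevel(tr, GRanges("chr1", IRanges(200, 300)), "CG"),
               "no covered")
  # additivity: level of a union equals pooled counts of the parts
  both <- regionLevel(tr, GRanges("chr1", IRanges(1, 110)), "all")
  expect_equal(both, (2 + 0 + 3) / 12)
  # site weighting switch
  expect_equal(regionLevel(tr, reg, "CG", weighting = "site"), 0.25)
})

test_that("methylated-site calling uses the binomial tail against non-conversion", {
  # single (4/4) site at nc = 0.01: p = 0.01^4 = 1e-8
  one <- makeTrack(data.frame(chrom = "c", pos = 1, strand = "+",
                              context = "CG", m = 4, t = 4))
  expect_true(callMethylatedSites(one, 0.01, 0.05))
  # (0/10): p = 1
  zero <- makeTrack(data.frame(chrom = "c", pos = 1, strand = "+",
                               context = "CG", m = 0, t = 10))
  expect_false(callMethylatedSites(zero, 0.01, 0.05))
  # (1/30) at nc = 0.01: p = 1 - 0.99^30 ~= 0.26, not called
  weak <- makeTrack(data.frame(chrom = "c", pos = 1, strand = "+",
                               context = "CG", m = 1, t = 30))
  expect_false(callMethylatedSites(weak, 0.01, 0.05))
  p <- stats::pbinom(0, 30, 0.01, lower.tail = FALSE)
  expect_equal(p, 1 - 0.99^30)
})

test_that("genome summary composition sums to one and handles all-zero tracks", {
  tr <- makeTrack(data.frame(chrom = "c", pos = (1:10) * 10, strand = "+",
                             context = rep(c("CG", "CHG", "CHH"),
                                           c(3, 2, 5)),
                             m = c(rep(10, 5), rep(10, 5)), t = 10))
  gs <- genomeSummary(tr, nonConversion = 0.01)
  expect_equal(sum(gs$composition), 1, tolerance = 1e-12)
  expect_equal(as.numeric(gs$composition), c(0.3, 0.2, 0.5))
  expect_equal(unname(gs$levels), rep(1, 3))

  flat <- makeTrack(data.frame(chrom = "c", pos = (1:4) * 10, strand = "+",
                               context = "CG", m = 0, t = 8))
  gs0 <- genomeSummary(flat, nonConversion = 0.01)
  expect_false(gs0$anyMethylated)
  expect_equal(unname(gs0$composition), rep(0, 3))
  expect_equal(unname(gs0$levels[1]), 0)
})

test_that("chromosome windows tile each chromosome, short tail included", {
  tr <- makeTrack(data.frame(chrom = "chr1", pos = c(100, 6e6), strand = "+",
                             context = "CG", m = c(1, 3), t = c(4, 4)),
                  seqlengths = c(chr1 = 12e6))
  cw <- chromosomeWindows(tr, c(chr1 = 12e6), window = 5e6)
  expect_equal(nrow(cw), 3L)
  expect_equal(cw$end - cw$start + 1, c(5e6, 5e6, 2e6))
  expect_equal(cw$level_CG, c(0.25, 0.75, NA))
  expect_true(all(is.na(cw$level_CHH)))
})

test_that("conversion-rate estimation is pooled-count arithmetic", {
  tr <- makeTrack(data.frame(chrom = "ctl", pos = (1:100) * 3, strand = "+",
                             context = "CHH", m = c(rep(1, 8), rep(0, 92)),
                             t = 10))
  expect_equal(estimateConversionRate(tr), 1 - 8 / 1000)
  empty <- makeTrack(data.frame(chrom = character(), pos = integer(),
                                strand = character(), context = character(),
                                m = integer(), t = integer()))
  expect_error(estimateConversionRate(empty), "no covered")
})

test_that("tracks round-trip through the call TSV writer", {
  cfg <- simConfig(seed = 2, nChrom = 1L, chromLen = 20000L)
  w <- simulateGenome(cfg)
  pair <- simulateMethylomePair(w$genome, w$genes, w$tes, cfg)
  f <- tempfile(fileext = ".tsv")
  writeMethylationCalls(pair$trackA, f)
  back <- readMethylationCalls(f, minCoverage = 1)
  expect_equal(start(trackSites(back)), start(trackSites(pair$trackA)))
  expect_equal(mcols(trackSites(back))$mCount,
               mcols(trackSites(pair$trackA))$mCount)
})
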