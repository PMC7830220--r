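test_that("window generation matches the sliding-window arithmetic", {
  expect_equal(length(generateWindows(1000, 200, 50)), 17L)
  w1 <- generateWindows(200, 200, 50)
  expect_equal(length(w1), 1L)
  expect_equal(c(start(w1) - 1L, end(w1)), c(0L, 200L))
  expect_equal(length(generateWindows(199, 200, 50)), 0L)
  # multi-chromosome
  wm <- generateWindows(c(a = 1000, b = 200), 200, 50)
  expect_equal(sum(seqnames(wm) == "a"), 17L)
  expect_equal(sum(seqnames(wm) == "b"), 1L)
  expect_true(all(width(wm) == 200L))
})

test_that("two-sided Fisher p-values match enumeration and fisher.test", {
  expect_equal(fisherExact2x2(1, 1, 1, 1), 1.0)
  expect_equal(fisherExact2x2(3, 0, 0, 3), 0.1, tolerance = 1e-12)
  expect_equal(fisherExact2x2(10, 0, 0, 10), 2 / 184756, tolerance = 1e-12)
  expect_error(fisherExact2x2(-1, 1, 1, 1), "negative")

  set.seed(3)
  for (i in 1:50) {
    tab <- matrix(rpois(4, 8), 2)
    mine <- fisherExact2x2(tab[1, 1], tab[1, 2], tab[2, 1], tab[2, 2])
    ref <- stats::fisher.test(tab)$p.value
    expect_equal(mine, ref, tolerance = 1e-7)
    expect_equal(mine, fisherOracle(tab[1, 1], tab[1, 2], tab[2, 1],
                                    tab[2, 2]), tolerance = 1e-7)
  }
})

test_that("BH adjustment is step-up, order-preserving and clipped", {
  expect_equal(bhAdjust(c(0.01, 0.02, 0.03)), rep(0.03, 3))
  expect_equal(bhAdjust(0.05), 0.05)
  expect_equal(bhAdjust(c(0.04, 0.01)), c(0.04, 0.02))
  expect_error(bhAdjust(c(0.5, 1.2)), "\\[0, 1\\]")
})

test_that("window tests pool read counts over commonly covered sites", {
  a <- makeTrack(data.frame(chrom = "c", pos = c(10, 20, 500), strand = "+",
                            context = "CG", m = c(8, 2, 1),
                            t = c(10, 10, 10)))
  b <- makeTrack(data.frame(chrom = "c", pos = c(10, 20, 800), strand = "+",
                            context = "CG", m = c(1, 0, 5),
                            t = c(10, 10, 10)))
  win <- GRanges("c", IRanges(1, 200))
  tst <- testWindows(a, b, "CG", win)
  expect_equal(nrow(tst), 1L)
  expect_equal(tst$nSites, 2L)
  expect_equal(c(tst$mA, tst$tA - tst$mA, tst$mB, tst$tB - tst$mB),
               c(10L, 10L, 1L, 19L))
  expect_equal(tst$levelA, 0.5)
  expect_equal(tst$levelB, 0.05)
  # windows without common covered sites are absent
  tst2 <- testWindows(a, b, "CG", GRanges("c", IRanges(401, 900)))
  expect_equal(nrow(tst2), 0L)
  # identical tracks: all p = 1
  tst3 <- testWindows(a, a, "CG", win)
  expect_equal(tst3$p, 1)
  # a site covered 4x in one sample but 3x in the other is excluded
  a2 <- makeTrack(data.frame(chrom = "c", pos = 10, strand = "+",
                             context = "CG", m = 4, t = 4))
  b2 <- makeTrack(data.frame(chrom = "c", pos = 10, strand = "+",
                             context = "CG", m = 0, t = 3))
  expect_equal(nrow(testWindows(a2, b2, "CG", win)), 0L)
})

test_that("candidate selection applies q, strict fold and the zero-level rule", {
  tests <- data.frame(chrom = "c", start = c(1, 101, 201), end = c(200, 300, 400),
                      nSites = 5, mA = 0L, tA = 0L, mB = 0L, tB = 0L,
                      levelA = c(0.5, 0.5, 0.2), levelB = c(0.1, 0.25, 0.0),
                      p = 0.001, q = 0.001)
  sel <- selectCandidateWindows(tests, qMax = 0.01, minFold = 2.5)
  expect_equal(sel$start, c(1, 201))       # fold 5 kept, fold 2 dropped
  expect_equal(sel$direction, c("hypo", "hypo"))
  expect_equal(sel$fold, c(5, Inf))        # zero denominator passes
  # fold exactly 2.5 is excluded (strict inequality)
  tests$levelB <- c(0.2, 0.25, 0.0)
  sel2 <- selectCandidateWindows(tests, qMax = 0.01, minFold = 2.5)
  expect_equal(sel2$start, c(201))
  # q at threshold excluded
  tests$q <- 0.01
  expect_equal(nrow(selectCandidateWindows(tests)), 0L)
})

test_that("candidate unioning merges overlaps only within a direction", {
  cand <- data.frame(chrom = "c", start = c(1, 51, 151), end = c(200, 250, 350),
                     direction = c("hyper", "hyper", "hypo"))
  u <- unionCandidates(cand)
  expect_equal(length(u), 2L)
  hyper <- u[mcols(u)$direction == "hyper"]
  expect_equal(c(start(hyper), end(hyper)), c(1L, 250L))
  # bookended same-direction windows merge
  book <- data.frame(chrom = "c", start = c(1, 201), end = c(200, 400),
                     direction = "hyper")
  expect_equal(length(unionCandidates(book)), 1L)
  expect_equal(length(unionCandidates(cand[2, ])), 1L)
})

test_that("DMC calling applies the per-site exact test with dual coverage", {
  a <- makeTrack(data.frame(chrom = "c", pos = c(10, 20, 30), strand = "+",
                            context = "CG", m = c(10, 2, 9),
                            t = c(10, 4, 10)))
  b <- makeTrack(data.frame(chrom = "c", pos = c(10, 20, 30), strand = "+",
                            context = "CG", m = c(0, 2, 0),
                            t = c(10, 4, 3)))
  reg <- GRanges("c", IRanges(1, 100), direction = "hypo")
  dmcs <- callDmcs(a, b, reg, "CG", pMax = 0.01)
  # site 10: p = 2/184756 -> DMC; site 20: p = 1; site 30: B covered 3x only
  expect_equal(start(dmcs), 10L)
  expect_equal(mcols(dmcs)$p, 2 / 184756, tolerance = 1e-9)
})

makeExtremeSite <- function(pos, hypo = TRUE) {
  data.frame(chrom = "c", pos = pos, strand = "+", context = "CG",
             mA = if (hypo) 20L else 0L, mB = if (hypo) 0L else 20L)
}

# tracks with nSites extreme sites in each of the given candidate regions
extremePair <- function(regionStarts, regionEnds, nSites = 8) {
  pos <- unlist(lapply(seq_along(regionStarts), function(i)
    round(seq(regionStarts[i], regionEnds[i], length.out = nSites))))
  a <- makeTrack(data.frame(chrom = "c", pos = pos, strand = "+",
                            context = "CG", m = 20, t = 20))
  b <- makeTrack(data.frame(chrom = "c", pos = pos, strand = "+",
                            context = "CG", m = 0, t = 20))
  list(a = a, b = b)
}

test_that("DMR assembly enforces the minimum DMC count", {
  tr <- extremePair(101, 300, nSites = 7)
  reg <- GRanges("c", IRanges(101, 300), direction = "hypo")
  dmcs <- callDmcs(tr$a, tr$b, reg, "CG")
  expect_equal(length(dmcs), 7L)
  dmrs <- assembleDmrs(reg, dmcs, tr$a, tr$b, "CG", dmcMin = 7)
  expect_equal(length(dmrs), 1L)
  expect_equal(mcols(dmrs)$nDmc, 7L)
  expect_equal(mcols(dmrs)$direction, "hypo")
  # with only 6 DMCs no DMR is called
  tr6 <- extremePair(101, 300, nSites = 6)
  dmcs6 <- callDmcs(tr6$a, tr6$b, reg, "CG")
  expect_equal(length(assembleDmrs(reg, dmcs6, tr6$a, tr6$b, "CG")), 0L)
})

test_that("adjacent DMRs merge across gaps of at most 100 bp", {
  # 0-based [100,300) and [350,500): gap 50 -> merged
  tr <- extremePair(c(101, 351), c(300, 500))
  regs <- GRanges("c", IRanges(c(101, 351), c(300, 500)),
                  direction = "hypo")
  dmcs <- callDmcs(tr$a, tr$b, regs, "CG")
  dmrs <- assembleDmrs(regs, dmcs, tr$a, tr$b, "CG", mergeGap = 100)
  expect_equal(length(dmrs), 1L)
  expect_equal(c(start(dmrs) - 1L, end(dmrs)), c(100L, 500L))
  expect_equal(mcols(dmrs)$nDmc, 16L)  # recomputed on the merged span

  # 0-based [100,300) and [401,600): gap 101 -> kept separate
  tr2 <- extremePair(c(101, 402), c(300, 600))
  regs2 <- GRanges("c", IRanges(c(101, 402), c(300, 600)),
                   direction = "hypo")
  dmcs2 <- callDmcs(tr2$a, tr2$b, regs2, "CG")
  dmrs2 <- assembleDmrs(regs2, dmcs2, tr2$a, tr2$b, "CG", mergeGap = 100)
  expect_equal(length(dmrs2), 2L)

  # opposite directions never merge even when adjacent
  regs3 <- GRanges("c", IRanges(c(101, 351), c(300, 500)),
                   direction = c("hypo", "hyper"))
  m3 <- mergeDmrIntervals(regs3, 100)
  expect_equal(length(m3), 2L)
})

test_that("interval merging is idempotent and order-invariant", {
  set.seed(23)
  for (rep in 1:100) {
    n <- sample(2:12, 1)
    gr <- GRanges("c", IRanges(sample(1:5000, n), width = sample(50:300, n,
                                                                 TRUE)),
                  direction = sample(c("hyper", "hypo"), n, TRUE))
    m1 <- mergeDmrIntervals(gr, 100)
    m2 <- mergeDmrIntervals(m1, 100)
    expect_identical(granges(m1), granges(m2))
    sh <- gr[sample(length(gr))]
    m3 <- mergeDmrIntervals(sh, 100)
    expect_identical(granges(m1), granges(m3))
    # all surviving same-direction gaps exceed the merge gap
    for (d in c("hyper", "hypo")) {
      sub <- m1[mcols(m1)$direction == d]
      if (length(sub) > 1) {
        gaps <- start(sub)[-1] - end(sub)[-length(sub)] - 1L
        expect_true(all(gaps > 100))
      }
    }
  }
})

test_that("direction classification is antisymmetric under sample swap", {
  expect_equal(classifyDirection(0.1, 0.5), "hyper")
  expect_equal(classifyDirection(0.5, 0.1), "hypo")
  expect_error(classifyDirection(0.3, 0.3), "no direction")

  tr <- extremePair(c(101, 1001), c(400, 1300))
  sl <- c(c = 2000L)
  d1 <- callDmrs(tr$a, tr$b, sl, contexts = "CG")
  d2 <- callDmrs(tr$b, tr$a, sl, contexts = "CG")
  expect_equal(length(d1), length(d2))
  expect_equal(start(d1), start(d2))
  expect_true(all(mcols(d1)$direction == "hypo"))
  expect_true(all(mcols(d2)$direction == "hyper"))
})

test_that("DMR summary conserves counts and classifies level differences", {
  dmrs <- GRanges("c", IRanges(c(1, 300, 700), width = c(200, 250, 100)),
                  context = c("CG", "CG", "CHH"),
                  direction = c("hyper", "hypo", "hyper"),
                  levelA = c(0.1, 0.9, 0.2), levelB = c(0.7, 0.6, 0.5),
                  nDmc = 8L, fold = 3, qMin = 1e-4)
  s <- dmrSummary(dmrs)
  cg <- s[s$context == "CG", ]
  expect_equal(cg$total, cg$hyper + cg$hypo)
  expect_equal(cg$total, 2L)
  expect_equal(cg$lengthBp, 450L)
  expect_equal(cg$deltaGt50, 1L)
  expect_equal(cg$deltaLe50, 1L)
})
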