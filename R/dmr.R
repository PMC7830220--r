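#' Sliding windows over chromosomes
#'
#' Windows of `size` bp every `step` bp, starting at the chromosome start;
#' only full-size windows are emitted (no partial trailing window), so a
#' chromosome of length `L` yields `floor((L - size)/step) + 1` windows
#' (none when `L < size`).
#'
#' @param seqlengths Named integer vector of chromosome lengths; a single
#'   unnamed length is placed on a chromosome called `"seq1"`.
#' @param size Window size in bp (default 200).
#' @param step Step size in bp (default 50).
#' @return A `GRanges` of windows.
#' @examples
#' length(generateWindows(1000))  # 17
#' @export
generateWindows <- function(seqlengths, size = 200, step = 50) {
  stopifnot(step > 0, size >= step)
  if (is.null(names(seqlengths)))
    names(seqlengths) <- paste0("seq", seq_along(seqlengths))
  out <- lapply(names(seqlengths), function(ch) {
    L <- as.integer(seqlengths[[ch]])
    if (L < size) return(NULL)
    starts <- seq(1L, L - as.integer(size) + 1L, by = as.integer(step))
    data.frame(chrom = ch, start = starts)
  })
  tab <- do.call(rbind, Filter(Negate(is.null), out))
  if (is.null(tab)) return(GRanges())
  sl <- stats::setNames(as.integer(seqlengths), names(seqlengths))
  GRanges(tab$chrom, IRanges(tab$start, width = as.integer(size)),
          seqlengths = sl[unique(tab$chrom)])
}

#' Two-sided Fisher's exact test for 2x2 read-count tables
#'
#' Vectorised over tables `((m1, u1), (m2, u2))` of methylated and
#' unmethylated read counts in two samples.  The two-sided p-value sums all
#' hypergeometric outcomes no more probable than the observed table (with
#' the customary `1 + 1e-7` relative tie tolerance).  Implemented in
#' compiled code because a genome-wide window scan evaluates tens of
#' thousands of tables.
#'
#' @param m1,u1,m2,u2 Nonnegative integer vectors of equal length.
#' @return Numeric vector of p-values in (0, 1].
#' @export
fisherExact2x2 <- function(m1, u1, m2, u2) {
  if (any(c(m1, u1, m2, u2) < 0)) stop("negative cell count")
  .fisher2x2_cpp(as.integer(m1), as.integer(u1),
                 as.integer(m2), as.integer(u2))
}

#' Benjamini-Hochberg adjustment
#'
#' Step-up false-discovery-rate adjustment (via [stats::p.adjust()]),
#' returned in the input order and clipped at 1.
#'
#' @param p Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order.
#' @export
bhAdjust <- function(p) {
  if (any(is.na(p)) || any(p < 0 | p > 1)) stop("p-values must be in [0, 1]")
  stats::p.adjust(p, method = "BH")
}

# sites of one context covered >= minCoverage in BOTH tracks, with the two
# samples' counts side by side
.commonSites <- function(trackA, trackB, context, minCoverage = 4) {
  a <- trackSites(trackA)
  b <- trackSites(trackB)
  a <- a[mcols(a)$context == context & mcols(a)$tCount >= minCoverage]
  b <- b[mcols(b)$context == context & mcols(b)$tCount >= minCoverage]
  keyA <- paste(seqnames(a), start(a), strand(a))
  keyB <- paste(seqnames(b), start(b), strand(b))
  hit <- match(keyA, keyB)
  keep <- !is.na(hit)
  gr <- granges(a[keep])
  mcols(gr)$mA <- mcols(a)$mCount[keep]
  mcols(gr)$tA <- mcols(a)$tCount[keep]
  mcols(gr)$mB <- mcols(b)$mCount[hit[keep]]
  mcols(gr)$tB <- mcols(b)$tCount[hit[keep]]
  gr
}

.fold <- function(lA, lB) {
  hi <- pmax(lA, lB); lo <- pmin(lA, lB)
  ifelse(hi == 0, 1, ifelse(lo == 0, Inf, hi / lo))
}

#' Test sliding windows for differential methylation
#'
#' For each window, read counts of all context-matching sites covered at
#' least `minCoverage` in *both* samples are pooled into a 2x2 table
#' (methylated/unmethylated x sample) and tested with the two-sided Fisher
#' exact test; p-values are Benjamini-Hochberg adjusted across all tested
#' windows of the call (run one call per context genome-wide so the
#' adjustment spans the whole context).  Windows without common covered
#' sites are omitted.
#'
#' @param trackA,trackB Control and case [MethylomeTrack-class] objects.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param windows `GRanges` of windows, e.g. from [generateWindows()].
#' @param minCoverage Per-sample minimum coverage (default 4).
#' @return A `data.frame`: chrom, start, end, nSites, mA, tA, mB, tB,
#'   levelA, levelB, p, q.
#' @export
testWindows <- function(trackA, trackB, context, windows, minCoverage = 4) {
  cs <- .commonSites(trackA, trackB, context, minCoverage)
  hits <- GenomicRanges::findOverlaps(cs, windows, ignore.strand = TRUE)
  if (!length(hits)) {
    return(data.frame(chrom = character(), start = integer(),
                      end = integer(), nSites = integer(), mA = integer(),
                      tA = integer(), mB = integer(), tB = integer(),
                      levelA = numeric(), levelB = numeric(),
                      p = numeric(), q = numeric()))
  }
  q <- S4Vectors::queryHits(hits); w <- S4Vectors::subjectHits(hits)
  agg <- function(v) rowsum(as.numeric(v[q]), w)
  mA <- agg(mcols(cs)$mA); tA <- agg(mcols(cs)$tA)
  mB <- agg(mcols(cs)$mB); tB <- agg(mcols(cs)$tB)
  wi <- as.integer(rownames(mA))
  nSites <- as.integer(table(w))
  res <- data.frame(chrom = as.character(seqnames(windows))[wi],
                    start = start(windows)[wi], end = end(windows)[wi],
                    nSites = nSites,
                    mA = as.integer(mA), tA = as.integer(tA),
                    mB = as.integer(mB), tB = as.integer(tB))
  res$levelA <- res$mA / res$tA
  res$levelB <- res$mB / res$tB
  res$p <- fisherExact2x2(res$mA, res$tA - res$mA, res$mB, res$tB - res$mB)
  res$q <- bhAdjust(res$p)
  res
}

#' Select significant candidate windows
#'
#' Keeps windows with adjusted p-value below `qMax` and a methylation-level
#' fold change strictly greater than `minFold`, where fold is the ratio of
#' the larger to the smaller read-weighted level; a zero level with a
#' positive opposite level counts as an infinite fold and passes.
#'
#' @param tests Output of [testWindows()].
#' @param qMax Adjusted-p threshold (default 0.01).
#' @param minFold Fold-change threshold (default 2.5, strict).
#' @return The qualifying rows, with a `direction` column (`hyper`/`hypo`,
#'   sample B relative to A).
#' @export
selectCandidateWindows <- function(tests, qMax = 0.01, minFold = 2.5) {
  fold <- .fold(tests$levelA, tests$levelB)
  keep <- tests$q < qMax & fold > minFold
  out <- tests[keep, , drop = FALSE]
  out$fold <- fold[keep]
  out$direction <- ifelse(out$levelB > out$levelA, "hyper", "hypo")
  rownames(out) <- NULL
  out
}

#' Union overlapping candidate windows into candidate regions
#'
#' Overlapping or bookended significant windows of the same direction are
#' merged into maximal regions; windows of opposite direction never merge.
#' This keeps one locus from being counted once per overlapping window.
#'
#' @param candidates Output of [selectCandidateWindows()].
#' @return A `GRanges` with a `direction` metadata column, sorted.
#' @export
unionCandidates <- function(candidates) {
  if (!nrow(candidates)) return(GRanges(direction = character()))
  out <- lapply(c("hyper", "hypo"), function(d) {
    sub <- candidates[candidates$direction == d, , drop = FALSE]
    if (!nrow(sub)) return(NULL)
    gr <- reduce(GRanges(sub$chrom, IRanges(sub$start, sub$end)),
                 min.gapwidth = 1L)
    mcols(gr)$direction <- d
    gr
  })
  sort(do.call(c, Filter(Negate(is.null), out)), ignore.strand = TRUE)
}

#' Call differentially methylated cytosines within candidate regions
#'
#' Each context-matching site covered at least `minCoverage` in both
#' samples and lying in a candidate region is tested with the two-sided
#' Fisher exact test on its `((mA, uA), (mB, uB))` counts; sites with
#' p-value below `pMax` are differentially methylated cytosines (DMCs).
#'
#' @inheritParams testWindows
#' @param regions Candidate `GRanges`, e.g. from [unionCandidates()].
#' @param pMax Per-site p-value threshold (default 0.01, unadjusted).
#' @return A width-1 `GRanges` of DMCs with `mA`, `tA`, `mB`, `tB`, `p`.
#' @export
callDmcs <- function(trackA, trackB, regions, context, pMax = 0.01,
                     minCoverage = 4) {
  cs <- .commonSites(trackA, trackB, context, minCoverage)
  cs <- cs[overlapsAny(cs, regions, ignore.strand = TRUE)]
  if (!length(cs)) {
    mcols(cs)$p <- numeric()
    return(cs)
  }
  p <- fisherExact2x2(mcols(cs)$mA, mcols(cs)$tA - mcols(cs)$mA,
                      mcols(cs)$mB, mcols(cs)$tB - mcols(cs)$mB)
  mcols(cs)$p <- p
  cs[p < pMax]
}

#' Assemble DMRs from candidate regions and their DMCs
#'
#' Candidate regions containing at least `dmcMin` DMCs become DMRs,
#' keeping the candidate-region extent as the reported interval.
#' Same-direction DMRs separated by at most `mergeGap` bp are then merged,
#' and levels, DMC count and fold change are recomputed on the merged span
#' (re-testing every common site within it).  Output is coordinate-sorted.
#'
#' @inheritParams callDmcs
#' @param dmcs DMC `GRanges` from [callDmcs()] for the same regions.
#' @param dmcMin Minimum DMC count (default 7).
#' @param mergeGap Maximum gap in bp for merging (default 100).
#' @param windowTests Optional [testWindows()] output used to annotate each
#'   DMR with the minimum adjusted p of its source windows.
#' @return A `GRanges` of DMRs with metadata columns `context`,
#'   `direction`, `nDmc`, `levelA`, `levelB`, `fold`, `qMin`.
#' @export
assembleDmrs <- function(regions, dmcs, trackA, trackB, context,
                         dmcMin = 7, mergeGap = 100, pMax = 0.01,
                         minCoverage = 4, windowTests = NULL) {
  empty <- GRanges(context = character(), direction = character(),
                   nDmc = integer(), levelA = numeric(), levelB = numeric(),
                   fold = numeric(), qMin = numeric())
  if (!length(regions)) return(empty)
  nd <- GenomicRanges::countOverlaps(regions, dmcs, ignore.strand = TRUE)
  keep <- which(nd >= dmcMin)
  if (!length(keep)) return(empty)
  spans <- granges(regions[keep])
  mcols(spans)$direction <- mcols(regions)$direction[keep]

  merged <- mergeDmrIntervals(spans, mergeGap)

  cs <- .commonSites(trackA, trackB, context, minCoverage)
  out <- merged
  nDmc <- integer(length(merged))
  lA <- lB <- numeric(length(merged))
  for (i in seq_along(merged)) {
    s <- subsetByOverlaps(cs, merged[i], ignore.strand = TRUE)
    p <- fisherExact2x2(mcols(s)$mA, mcols(s)$tA - mcols(s)$mA,
                        mcols(s)$mB, mcols(s)$tB - mcols(s)$mB)
    nDmc[i] <- sum(p < pMax)
    lA[i] <- sum(mcols(s)$mA) / sum(mcols(s)$tA)
    lB[i] <- sum(mcols(s)$mB) / sum(mcols(s)$tB)
  }
  mcols(out)$context <- context
  mcols(out)$nDmc <- nDmc
  mcols(out)$levelA <- lA
  mcols(out)$levelB <- lB
  mcols(out)$fold <- .fold(lA, lB)
  qMin <- rep(NA_real_, length(out))
  if (!is.null(windowTests) && nrow(windowTests)) {
    wgr <- GRanges(windowTests$chrom,
                   IRanges(windowTests$start, windowTests$end))
    hv <- GenomicRanges::findOverlaps(out, wgr, ignore.strand = TRUE)
    if (length(hv))
      qMin <- as.numeric(tapply(windowTests$q[S4Vectors::subjectHits(hv)],
                                factor(S4Vectors::queryHits(hv),
                                       levels = seq_along(out)),
                                min))
  }
  mcols(out)$qMin <- qMin
  sort(out, ignore.strand = TRUE)
}

#' Merge same-direction DMR intervals across small gaps
#'
#' Intervals sharing a direction and separated by at most `mergeGap` bp
#' (overlapping included) are combined; opposite-direction intervals never
#' merge.  Idempotent and invariant to input order; all same-direction gaps
#' in the output exceed `mergeGap`.
#'
#' @param gr A `GRanges` with a `direction` metadata column.
#' @param mergeGap Maximum gap in bp (default 100).
#' @return A sorted merged `GRanges` with `direction`.
#' @export
mergeDmrIntervals <- function(gr, mergeGap = 100) {
  out <- lapply(c("hyper", "hypo"), function(d) {
    sub <- gr[mcols(gr)$direction == d]
    if (!length(sub)) return(NULL)
    m <- reduce(granges(sub), min.gapwidth = as.integer(mergeGap) + 1L)
    mcols(m)$direction <- d
    m
  })
  out <- Filter(Negate(is.null), out)
  if (!length(out)) return(GRanges(direction = character()))
  suppressWarnings(sort(do.call(c, out), ignore.strand = TRUE))
}

#' Direction of a DMR
#'
#' `hyper` when the case (B) level exceeds the control (A) level, `hypo`
#' when it is lower; equal levels cannot occur for a DMR (the fold filter
#' excludes them) and raise an error.
#'
#' @param levelA,levelB Region levels in control and case.
#' @return Character vector over `"hyper"`/`"hypo"`.
#' @export
classifyDirection <- function(levelA, levelB) {
  if (any(levelA == levelB))
    stop("equal levels have no direction (cannot occur for a DMR)")
  ifelse(levelB > levelA, "hyper", "hypo")
}

#' End-to-end DMR calling
#'
#' Runs the whole differential-methylation procedure per context: sliding
#' windows ([generateWindows()]), pooled Fisher window tests with
#' genome-wide BH adjustment per context ([testWindows()]), significance
#' and fold-change filtering ([selectCandidateWindows()]), same-direction
#' unioning ([unionCandidates()]), per-cytosine refinement ([callDmcs()])
#' and assembly with gap merging ([assembleDmrs()]).  Defaults are the
#' standard sliding-window parameters: 200-bp windows every 50 bp, coverage
#' >= 4 in both samples, adjusted p < 0.01 with fold change > 2.5, DMC
#' p < 0.01, at least 7 DMCs, and merging across gaps of at most 100 bp.
#'
#' @param trackA,trackB Control and case [MethylomeTrack-class] objects.
#' @param seqlengths Named chromosome lengths.
#' @param contexts Contexts to call (default all three).
#' @param windowSize,stepSize Sliding-window geometry (default 200/50).
#' @param minCoverage Per-sample site coverage floor (default 4).
#' @param qMax Window adjusted-p threshold (default 0.01).
#' @param minFold Window fold-change threshold (default 2.5).
#' @param dmcP DMC p-value threshold (default 0.01).
#' @param dmcMin Minimum DMCs per DMR (default 7).
#' @param mergeGap Merge gap in bp (default 100).
#' @return A `GRanges` of DMRs (as [assembleDmrs()]); `metadata()` carries
#'   `dmcs` (per-context DMC `GRanges`) and `params`.
#' @export
callDmrs <- function(trackA, trackB, seqlengths,
                     contexts = .CONTEXTS, windowSize = 200, stepSize = 50,
                     minCoverage = 4, qMax = 0.01, minFold = 2.5,
                     dmcP = 0.01, dmcMin = 7, mergeGap = 100) {
  windows <- generateWindows(seqlengths, windowSize, stepSize)
  allDmrs <- list(); allDmcs <- list()
  for (ctx in contexts) {
    tests <- testWindows(trackA, trackB, ctx, windows, minCoverage)
    cand <- selectCandidateWindows(tests, qMax, minFold)
    regions <- unionCandidates(cand)
    dmcs <- callDmcs(trackA, trackB, regions, ctx, dmcP, minCoverage)
    dmrs <- assembleDmrs(regions, dmcs, trackA, trackB, ctx,
                         dmcMin, mergeGap, dmcP, minCoverage,
                         windowTests = tests)
    allDmrs[[ctx]] <- dmrs
    mcols(dmcs)$context <- if (length(dmcs)) ctx else character()
    allDmcs[[ctx]] <- dmcs
  }
  out <- do.call(c, unname(allDmrs))
  out <- sort(out, ignore.strand = TRUE)
  metadata(out)$dmcs <- allDmcs
  metadata(out)$params <- list(windowSize = windowSize, stepSize = stepSize,
                               minCoverage = minCoverage, qMax = qMax,
                               minFold = minFold, dmcP = dmcP,
                               dmcMin = dmcMin, mergeGap = mergeGap)
  out
}

#' Summarise called DMRs
#'
#' Per context: total, hyper and hypo counts (hyper + hypo = total by
#' construction), total length in bp, and counts of DMRs whose level
#' difference `|levelB - levelA|` exceeds 0.5 versus at most 0.5.
#'
#' @param dmrs DMR `GRanges` from [callDmrs()]/[assembleDmrs()].
#' @return A `data.frame`, one row per context present.
#' @export
dmrSummary <- function(dmrs) {
  if (!length(dmrs))
    return(data.frame(context = character(), total = integer(),
                      hyper = integer(), hypo = integer(),
                      lengthBp = integer(), deltaGt50 = integer(),
                      deltaLe50 = integer()))
  ctx <- factor(mcols(dmrs)$context,
                levels = intersect(.CONTEXTS, mcols(dmrs)$context))
  delta <- abs(mcols(dmrs)$levelB - mcols(dmrs)$levelA)
  out <- data.frame(
    context = levels(ctx),
    total = as.integer(table(ctx)),
    hyper = as.integer(tapply(mcols(dmrs)$direction == "hyper", ctx, sum)),
    hypo = as.integer(tapply(mcols(dmrs)$direction == "hypo", ctx, sum)),
    lengthBp = as.integer(tapply(width(dmrs), ctx, sum)),
    deltaGt50 = as.integer(tapply(delta > 0.5, ctx, sum)),
    deltaLe50 = as.integer(tapply(delta <= 0.5, ctx, sum)))
  rownames(out) <- NULL
  out
}
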