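#' Read a per-cytosine methylation call table
#'
#' The call table dialect is a 6-column tab-separated file (gzip
#' transparent, no header): chromosome, 1-based position, strand (+/-),
#' context (CG/CHG/CHH), methylated read count, total read count.  Rows
#' whose total count falls below `minCoverage` are dropped -- only cytosines
#' with adequate sequencing depth enter any analysis (default 4).
#'
#' @param path Path to the call TSV.
#' @param minCoverage Minimum total read count for a site to be kept.
#' @param sampleId Library name stored on the track.
#' @param seqlengths Optional named chromosome lengths.
#' @return A [MethylomeTrack-class].
#' @export
readMethylationCalls <- function(path, minCoverage = 4, sampleId = NULL,
                                 seqlengths = NULL) {
  if (!file.exists(path)) stop("no such file: ", path)
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "pos", "strand", "context",
                                         "mCount", "tCount"),
                           colClasses = c("character", "integer", "character",
                                          "character", "integer", "integer"))
  bad <- which(tab$mCount > tab$tCount | tab$mCount < 0L)
  if (length(bad))
    stop("line ", bad[1], " of '", path, "': methylated count ",
         tab$mCount[bad[1]], " exceeds total ", tab$tCount[bad[1]])
  if (!all(tab$context %in% .CONTEXTS))
    stop("line ", which(!tab$context %in% .CONTEXTS)[1], " of '", path,
         "': unknown context")
  key <- paste(tab$chrom, tab$pos, tab$strand)
  if (anyDuplicated(key))
    stop("line ", which(duplicated(key))[1], " of '", path,
         "': duplicate (chrom, pos, strand)")
  keep <- tab$tCount >= minCoverage
  tab <- tab[keep, , drop = FALSE]
  if (is.null(sampleId))
    sampleId <- sub("\\.(tsv|txt)(\\.gz)?$", "", basename(path))
  MethylomeTrack(tab$chrom, tab$pos, tab$strand, tab$context,
                 tab$mCount, tab$tCount, sampleId = sampleId,
                 seqlengths = seqlengths,
                 provenance = list(path = path, minCoverage = minCoverage))
}

#' Write a MethylomeTrack as a call TSV
#'
#' Inverse of [readMethylationCalls()]; positions are written 1-based.
#'
#' @param track A [MethylomeTrack-class].
#' @param path Output path (`.gz` suffix writes gzip).
#' @return `path`, invisibly.
#' @export
writeMethylationCalls <- function(track, path) {
  gr <- trackSites(track)
  tab <- data.frame(chrom = as.character(seqnames(gr)), pos = start(gr),
                    strand = as.character(strand(gr)),
                    context = mcols(gr)$context,
                    mCount = mcols(gr)$mCount, tCount = mcols(gr)$tCount)
  con <- if (grepl("\\.gz$", path)) gzfile(path, "w") else file(path, "w")
  on.exit(close(con))
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Methylation level of a single site
#'
#' The fraction of methylated read observations, `mCount / tCount`.
#'
#' @param mCount,tCount Methylated and total read counts (vectorised).
#' @return Numeric vector of levels in \[0, 1\].
#' @export
siteLevel <- function(mCount, tCount) {
  if (any(tCount <= 0)) stop("site level undefined at zero coverage")
  if (any(mCount < 0 | mCount > tCount)) stop("need 0 <= mCount <= tCount")
  mCount / tCount
}

#' Read-weighted methylation level of a region
#'
#' The regional level is the proportion of methylated cytosine observations
#' among all cytosine observations, i.e. sum(m) / sum(t) over the covered,
#' context-matching sites in the region (read-weighted, the standard WGBS
#' convention).  `weighting = "site"` instead averages per-site levels.
#'
#' @param track A [MethylomeTrack-class].
#' @param region A `GRanges` (one or more ranges; their union is used).
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"all"`.
#' @param weighting `"read"` (default) or `"site"`.
#' @return A single level in \[0, 1\].
#' @export
regionLevel <- function(track, region, context = "all",
                        weighting = c("read", "site")) {
  weighting <- match.arg(weighting)
  gr <- trackSites(track)
  hit <- overlapsAny(gr, region, ignore.strand = TRUE)
  if (context != "all") hit <- hit & mcols(gr)$context == context
  if (!any(hit)) stop("no covered ", context, " sites in region")
  m <- mcols(gr)$mCount[hit]
  t <- mcols(gr)$tCount[hit]
  if (weighting == "read") sum(m) / sum(t) else mean(m / t)
}

#' Call methylated cytosine sites against the non-conversion rate
#'
#' A covered cytosine is called methylated when a one-sided binomial test of
#' its methylated count against the bisulfite non-conversion rate (the
#' probability that an unmethylated cytosine falsely reads as methylated)
#' is significant after Benjamini-Hochberg adjustment across all tested
#' sites.
#'
#' @param track A [MethylomeTrack-class].
#' @param nonConversion Non-conversion probability in \[0, 1).
#' @param qThreshold BH-adjusted significance threshold (default 0.05).
#' @return Logical vector, one element per site of the track.
#' @export
callMethylatedSites <- function(track, nonConversion, qThreshold = 0.05) {
  stopifnot(nonConversion >= 0, nonConversion < 1)
  gr <- trackSites(track)
  if (!length(gr)) return(logical())
  m <- mcols(gr)$mCount
  t <- mcols(gr)$tCount
  # one-sided binomial upper tail P(X >= m | t, nonConversion)
  p <- stats::pbinom(m - 1L, t, nonConversion, lower.tail = FALSE)
  q <- stats::p.adjust(p, method = "BH")
  q < qThreshold
}

#' Genome-wide methylation summary
#'
#' Counts methylated sites per context (via [callMethylatedSites()]),
#' their composition (fractions of all methylated cytosines that are CG,
#' CHG, CHH -- summing to 1), the fraction of all covered cytosines called
#' methylated, and the read-weighted methylation level per context over all
#' covered sites (mCG/CG etc.).
#'
#' @inheritParams callMethylatedSites
#' @return A list with elements `nSites`, `mCounts`, `composition`,
#'   `fracMethylated`, `levels`, `anyMethylated`.
#' @export
genomeSummary <- function(track, nonConversion = 0, qThreshold = 0.05) {
  gr <- trackSites(track)
  if (!length(gr)) stop("empty track")
  ctx <- factor(mcols(gr)$context, levels = .CONTEXTS)
  called <- callMethylatedSites(track, nonConversion, qThreshold)
  mCounts <- tapply(called, ctx, sum, default = 0L)
  total <- sum(mCounts)
  composition <- if (total > 0) mCounts / total else
    stats::setNames(rep(0, 3), .CONTEXTS)
  m <- tapply(mcols(gr)$mCount, ctx, sum, default = 0)
  t <- tapply(mcols(gr)$tCount, ctx, sum, default = 0)
  levels <- ifelse(t > 0, m / t, NA_real_)
  list(nSites = as.vector(table(ctx)) |> stats::setNames(.CONTEXTS),
       mCounts = mCounts, composition = composition,
       fracMethylated = mean(called),
       levels = stats::setNames(as.numeric(levels), .CONTEXTS),
       anyMethylated = total > 0)
}

#' Chromosome-scale methylation level track
#'
#' Tiles each chromosome with consecutive fixed-size windows (the last may
#' be short) and reports the read-weighted level per context per window --
#' the 5-Mb default matches the usual whole-chromosome methylation plots.
#' Windows with no covered sites for a context carry `NA`.
#'
#' @param track A [MethylomeTrack-class].
#' @param seqlengths Named integer vector of chromosome lengths.
#' @param window Window size in bp (default 5e6).
#' @return A `data.frame` with chrom, start (1-based), end, and one level
#'   column per context plus the per-context site counts.
#' @export
chromosomeWindows <- function(track, seqlengths, window = 5e6) {
  stopifnot(window > 0, length(seqlengths) > 0, !is.null(names(seqlengths)))
  gr <- trackSites(track)
  rows <- list()
  for (ch in names(seqlengths)) {
    L <- as.integer(seqlengths[[ch]])
    starts <- seq(1L, L, by = as.integer(window))
    ends <- pmin(starts + as.integer(window) - 1L, L)
    win <- GRanges(ch, IRanges(starts, ends))
    sub <- gr[as.character(seqnames(gr)) == ch]
    idx <- GenomicRanges::findOverlaps(sub, win, ignore.strand = TRUE)
    df <- data.frame(chrom = ch, start = starts, end = ends)
    for (ctx in .CONTEXTS) {
      inctx <- mcols(sub)$context[S4Vectors::queryHits(idx)] == ctx
      wi <- S4Vectors::subjectHits(idx)[inctx]
      m <- rowsum(mcols(sub)$mCount[S4Vectors::queryHits(idx)][inctx], wi)
      t <- rowsum(mcols(sub)$tCount[S4Vectors::queryHits(idx)][inctx], wi)
      lev <- rep(NA_real_, length(win))
      n <- rep(0L, length(win))
      at <- as.integer(rownames(m))
      lev[at] <- m[, 1] / t[, 1]
      n[at] <- as.integer(table(factor(wi, levels = seq_along(win))))[at]
      df[[paste0("level_", ctx)]] <- lev
      df[[paste0("n_", ctx)]] <- n
    }
    rows[[ch]] <- df
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Estimate the bisulfite conversion rate from an unmethylated control
#'
#' Given calls over a biologically unmethylated control sequence (for plant
#' studies, typically the chloroplast genome), the conversion rate is
#' 1 - sum(m)/sum(t): every methylated observation there is a conversion
#' failure.
#'
#' @param controlTrack A [MethylomeTrack-class] over the control sequence.
#' @return Estimated conversion rate in \[0, 1\].
#' @export
estimateConversionRate <- function(controlTrack) {
  gr <- trackSites(controlTrack)
  t <- sum(as.numeric(mcols(gr)$tCount))
  if (!length(gr) || t == 0) stop("no covered sites in control track")
  1 - sum(as.numeric(mcols(gr)$mCount)) / t
}
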