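# split [st, en] into n intervals whose lengths differ by at most 1,
# remainder spread over the leading intervals in 5'->3' orientation.
# Returns a matrix of starts/ends in genomic coordinates.
.splitEven <- function(st, en, n, fivePrimeLeft) {
  W <- en - st + 1L
  base <- W %/% n
  extra <- W %% n
  lens <- rep(base, n) + as.integer(seq_len(n) <= extra)
  if (!fivePrimeLeft) lens <- rev(lens)  # leading (5') bins sit at the right
  ends <- st - 1L + cumsum(lens)
  starts <- c(st, utils::head(ends, -1L) + 1L)
  cbind(start = starts, end = ends)
}

#' Bin a stranded feature and its flanks
#'
#' Divides a feature body into `nBins` near-equal intervals (any remainder
#' widens the leading, 5'-most bins) and each flank of `flankLen` bp into
#' `nBins` equal intervals, giving `3 * nBins` intervals ordered 5' to 3'
#' along the feature's strand: bins `1..nBins` are the upstream flank
#' (distal first), then the body, then the downstream flank.  For minus
#' strand features the genomic order is therefore reversed.  Flank bins are
#' clipped at chromosome edges (and dropped when fully outside).
#'
#' @param feature A length-1 stranded `GRanges`.
#' @param flankLen Flank width in bp (default 2000).
#' @param nBins Bins per zone (default 20).
#' @return A `GRanges` with metadata columns `bin` (1..3*nBins) and `zone`
#'   (`up`, `body`, `down`), or `NULL` with a warning when the body is
#'   shorter than `nBins`.
#' @export
binFeature <- function(feature, flankLen = 2000, nBins = 20) {
  stopifnot(length(feature) == 1L, flankLen > 0, nBins >= 1)
  std <- as.character(strand(feature))
  if (!std %in% c("+", "-")) stop("feature must be stranded")
  if (width(feature) < nBins) {
    warning("feature shorter than ", nBins, " bp skipped")
    return(NULL)
  }
  ch <- as.character(seqnames(feature))
  st <- start(feature); en <- end(feature)
  plus <- std == "+"
  body <- .splitEven(st, en, nBins, fivePrimeLeft = plus)
  left <- .splitEven(st - as.integer(flankLen), st - 1L, nBins,
                     fivePrimeLeft = plus)
  right <- .splitEven(en + 1L, en + as.integer(flankLen), nBins,
                      fivePrimeLeft = plus)
  if (plus) {
    coords <- rbind(left, body, right)
  } else {
    # 5' flank of a minus-strand feature is genomically right of the body;
    # bins are ordered distal-upstream -> body -> distal-downstream
    coords <- rbind(right[rev(seq_len(nBins)), , drop = FALSE],
                    body[rev(seq_len(nBins)), , drop = FALSE],
                    left[rev(seq_len(nBins)), , drop = FALSE])
  }
  zone <- rep(c("up", "body", "down"), each = nBins)
  bin <- seq_len(3L * nBins)
  sl <- seqlengths(feature)
  maxEnd <- if (!is.na(sl[ch])) sl[ch] else Inf
  keep <- coords[, "end"] >= 1L & coords[, "start"] <= maxEnd
  coords[, "start"] <- pmax(coords[, "start"], 1L)
  coords[, "end"] <- pmin(coords[, "end"], maxEnd)
  GRanges(ch, IRanges(coords[keep, "start"], coords[keep, "end"]),
          strand = std, bin = bin[keep], zone = zone[keep])
}

#' Metaprofile of methylation over a feature class
#'
#' Computes the average methylation profile over a set of features (gene
#' bodies or transposable elements): each feature body is divided into
#' `nBins` bins and its `flankLen` flanks into `nBins` bins each, and the
#' level of bin *i* is pooled over all features as sum(m)/sum(t) of every
#' context-matching site falling into bin *i* of any feature
#' (count-weighted pooling; `pooling = "feature"` averages per-feature bin
#' levels instead).  Bins with no data are `NA`.
#'
#' @param track A [MethylomeTrack-class].
#' @param features A stranded `GRanges` of feature bodies.
#' @param context `"CG"`, `"CHG"` or `"CHH"`.
#' @param flankLen Flank width in bp (default 2000).
#' @param nBins Bins per zone (default 20).
#' @param pooling `"count"` (default) or `"feature"`.
#' @return A `data.frame` with `bin`, `zone`, `level`, `nSites`, `nReads`
#'   (total read observations pooled into the bin); the number of usable
#'   features is in `attr(, "nFeatures")`.
#' @export
metaProfile <- function(track, features, context, flankLen = 2000,
                        nBins = 20, pooling = c("count", "feature")) {
  pooling <- match.arg(pooling)
  stopifnot(context %in% .CONTEXTS)
  gr <- trackSites(track)
  gr <- gr[mcols(gr)$context == context]
  nB <- 3L * nBins
  sumM <- numeric(nB); sumT <- numeric(nB); nSites <- integer(nB)
  featLevels <- matrix(NA_real_, nrow = 0, ncol = nB)
  used <- 0L
  for (i in seq_along(features)) {
    bins <- suppressWarnings(binFeature(features[i], flankLen, nBins))
    if (is.null(bins)) next
    used <- used + 1L
    hits <- GenomicRanges::findOverlaps(gr, bins, ignore.strand = TRUE)
    if (length(hits)) {
      q <- S4Vectors::queryHits(hits)
      b <- mcols(bins)$bin[S4Vectors::subjectHits(hits)]
      m <- rowsum(as.numeric(mcols(gr)$mCount[q]), b)
      t <- rowsum(as.numeric(mcols(gr)$tCount[q]), b)
      at <- as.integer(rownames(m))
      sumM[at] <- sumM[at] + m[, 1]
      sumT[at] <- sumT[at] + t[, 1]
      nSites[at] <- nSites[at] + as.integer(table(factor(b, levels = seq_len(nB))))[at]
      if (pooling == "feature") {
        lv <- rep(NA_real_, nB); lv[at] <- m[, 1] / t[, 1]
        featLevels <- rbind(featLevels, lv)
      }
    } else if (pooling == "feature") {
      featLevels <- rbind(featLevels, rep(NA_real_, nB))
    }
  }
  if (used == 0L) stop("no usable features (all shorter than nBins?)")
  level <- if (pooling == "count") ifelse(sumT > 0, sumM / sumT, NA_real_)
           else colMeans(featLevels, na.rm = TRUE)
  level[is.nan(level)] <- NA_real_
  out <- data.frame(bin = seq_len(nB),
                    zone = rep(c("up", "body", "down"), each = nBins),
                    context = context, level = level, nSites = nSites,
                    nReads = sumT)
  attr(out, "nFeatures") <- used
  out
}
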