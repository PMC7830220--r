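#' Write DMRs as BED6+4
#'
#' Columns: chrom, start (0-based), end, name (`context|direction`), score
#' (`-log10` of the minimum source-window adjusted p, capped at 1000),
#' strand (`.`), then levelA, levelB, nDmc, fold.
#'
#' @param dmrs DMR `GRanges` from [callDmrs()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDmrBed <- function(dmrs, path) {
  q <- mcols(dmrs)$qMin
  score <- ifelse(is.na(q), 0, pmin(1000, round(-log10(pmax(q, 1e-300)), 3)))
  tab <- data.frame(chrom = as.character(seqnames(dmrs)),
                    start = start(dmrs) - 1L, end = end(dmrs),
                    name = paste(mcols(dmrs)$context, mcols(dmrs)$direction,
                                 sep = "|"),
                    score = score, strand = ".",
                    levelA = signif(mcols(dmrs)$levelA, 6),
                    levelB = signif(mcols(dmrs)$levelB, 6),
                    nDmc = mcols(dmrs)$nDmc,
                    fold = signif(mcols(dmrs)$fold, 6))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeDmrBed
#' @export
readDmrBed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name",
                                         "score", "strand", "levelA",
                                         "levelB", "nDmc", "fold"))
  parts <- strsplit(tab$name, "|", fixed = TRUE)
  GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end),
          context = vapply(parts, `[`, "", 1L),
          direction = vapply(parts, `[`, "", 2L),
          nDmc = tab$nDmc, levelA = tab$levelA, levelB = tab$levelB,
          fold = tab$fold, qMin = 10^(-tab$score))
}

#' Write DMCs as BED4
#'
#' Columns: chrom, start (0-based), end, name (`context|p`).
#'
#' @param dmcs Either the per-context DMC list from
#'   `metadata(callDmrs(...))$dmcs` or a single DMC `GRanges` with a
#'   `context` column.
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
writeDmcBed <- function(dmcs, path) {
  if (is.list(dmcs)) {
    dmcs <- lapply(names(dmcs), function(ctx) {
      g <- dmcs[[ctx]]
      if (length(g)) mcols(g)$context <- ctx
      g
    })
    dmcs <- do.call(c, dmcs)
  }
  tab <- data.frame(chrom = as.character(seqnames(dmcs)),
                    start = start(dmcs) - 1L, end = start(dmcs),
                    name = paste(mcols(dmcs)$context,
                                 signif(mcols(dmcs)$p, 4), sep = "|"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
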