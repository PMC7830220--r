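#' Assign DMRs to gene functional regions
#'
#' A gene becomes a differentially methylated gene (DMG) when a DMR
#' overlaps any of its functional regions -- promoter, UTR, exon or intron
#' (positions in both UTR and exon count as UTR).  Every overlapping gene
#' is recorded, every overlapped region label per gene is kept, and genes
#' are deduplicated per (context, direction), the "non-repeat" counting
#' used for tabulating DMGs.
#'
#' @param dmrs DMR `GRanges` (metadata `context`, `direction`).
#' @param annotation A [GeneAnnotation-class].
#' @param promoterLen Promoter length in bp (default 2000).
#' @param minOverlap Minimum overlap in bp for a hit (default 1).
#' @return A `data.frame` with one row per (gene, context, direction):
#'   `gene_id`, `context`, `direction`, `regions` (comma-joined labels) and
#'   `dmrIds` (comma-joined `chrom:start-end` identifiers).
#' @export
assignDmrsToGenes <- function(dmrs, annotation, promoterLen = 2000,
                              minOverlap = 1) {
  fr <- functionalRegions(annotation, promoterLen)
  empty <- data.frame(gene_id = character(), context = character(),
                      direction = character(), regions = character(),
                      dmrIds = character())
  if (!length(dmrs) || !length(fr)) return(empty)
  hits <- GenomicRanges::findOverlaps(dmrs, fr, ignore.strand = TRUE,
                                      minoverlap = as.integer(minOverlap))
  if (!length(hits)) return(empty)
  di <- S4Vectors::queryHits(hits); fi <- S4Vectors::subjectHits(hits)
  dmrId <- paste0(seqnames(dmrs), ":", start(dmrs), "-", end(dmrs))
  tab <- data.frame(gene_id = mcols(fr)$gene_id[fi],
                    context = mcols(dmrs)$context[di],
                    direction = mcols(dmrs)$direction[di],
                    label = mcols(fr)$label[fi],
                    dmr = dmrId[di])
  key <- interaction(tab$gene_id, tab$context, tab$direction, drop = TRUE)
  rows <- lapply(split(tab, key), function(g) {
    data.frame(gene_id = g$gene_id[1], context = g$context[1],
               direction = g$direction[1],
               regions = paste(sort(unique(g$label)), collapse = ","),
               dmrIds = paste(sort(unique(g$dmr)), collapse = ","))
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$context, out$direction, out$gene_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Genomic composition of DMRs
#'
#' Assigns each DMR to exactly one compartment with precedence gene region
#' (exons, introns and UTRs, i.e. the gene body) > promoter > intergenic,
#' and reports per-context fractions (summing to 1).
#'
#' @inheritParams assignDmrsToGenes
#' @return A `data.frame` with `context`, `genic`, `promoter`,
#'   `intergenic` fraction columns and DMR counts.
#' @export
genomicComposition <- function(dmrs, annotation, promoterLen = 2000) {
  if (!length(dmrs))
    return(data.frame(context = character(), n = integer(),
                      genic = numeric(), promoter = numeric(),
                      intergenic = numeric()))
  bodies <- annotation@genes
  proms <- .promoterOf(bodies, promoterLen)
  comp <- rep("intergenic", length(dmrs))
  comp[overlapsAny(dmrs, proms, ignore.strand = TRUE)] <- "promoter"
  comp[overlapsAny(dmrs, bodies, ignore.strand = TRUE)] <- "genic"
  ctx <- mcols(dmrs)$context
  rows <- lapply(unique(ctx), function(cc) {
    sub <- comp[ctx == cc]
    data.frame(context = cc, n = length(sub),
               genic = mean(sub == "genic"),
               promoter = mean(sub == "promoter"),
               intergenic = mean(sub == "intergenic"))
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Functional-region distribution of DMGs
#'
#' Counts genes per context x direction x functional region.  A gene is
#' counted once per region label it hits, so region columns can sum to
#' more than the total; `total` is the non-repeat gene count.
#'
#' @param records Output of [assignDmrsToGenes()].
#' @return A `data.frame` with columns `context`, `direction`, `total`,
#'   `promoter`, `UTR`, `exon`, `intron`.
#' @export
regionDistribution <- function(records) {
  labels <- c("promoter", "UTR", "exon", "intron")
  if (!nrow(records)) {
    out <- data.frame(context = character(), direction = character(),
                      total = integer())
    for (l in labels) out[[l]] <- integer()
    return(out)
  }
  key <- interaction(records$context, records$direction, drop = TRUE)
  rows <- lapply(split(records, key), function(g) {
    hit <- strsplit(g$regions, ",", fixed = TRUE)
    d <- data.frame(context = g$context[1], direction = g$direction[1],
                    total = length(unique(g$gene_id)))
    for (l in labels)
      d[[l]] <- sum(vapply(hit, function(h) l %in% h, logical(1)))
    d
  })
  out <- do.call(rbind, rows)
  out <- out[order(out$context, out$direction), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Filter DMGs by expression level
#'
#' Keeps DMG records whose gene reaches `minTpm` transcripts per million;
#' genes absent from the expression table are dropped with a warning.
#'
#' @param records Output of [assignDmrsToGenes()].
#' @param tpm Named numeric vector of TPM values, or a `data.frame` with
#'   columns `gene_id` and `tpm`.
#' @param minTpm Minimum TPM (default 10; genes with TPM < 10 are removed).
#' @return Filtered records with a `tpm` column appended.
#' @export
expressionFilter <- function(records, tpm, minTpm = 10) {
  if (is.data.frame(tpm)) tpm <- stats::setNames(tpm$tpm, tpm$gene_id)
  v <- tpm[records$gene_id]
  missing <- is.na(v) & !(records$gene_id %in% names(tpm))
  if (any(missing))
    warning(sum(missing), " DMG record(s) without expression data dropped")
  keep <- !missing & !is.na(v) & v >= minTpm
  out <- records[keep, , drop = FALSE]
  out$tpm <- unname(v[keep])
  rownames(out) <- NULL
  out
}

#' Read a TPM expression table
#'
#' Two-column tab-separated file: gene id, TPM.  A header line is detected
#' and skipped when the second field is non-numeric.
#'
#' @param path TSV path.
#' @return Named numeric vector of TPM values.
#' @export
readTpmTable <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character")
  if (is.na(suppressWarnings(as.numeric(tab[1, 2]))))
    tab <- tab[-1, , drop = FALSE]
  stats::setNames(as.numeric(tab[[2]]), tab[[1]])
}
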