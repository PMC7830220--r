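#' Configuration for an end-to-end pipeline run
#'
#' Collects every analysis threshold with its standard default: 200-bp
#' windows stepped by 50 bp, coverage >= 4 in both libraries, window
#' adjusted p < 0.01 with fold change > 2.5, DMC p < 0.01, >= 7 DMCs per
#' DMR, 100-bp merge gap, 2-kb promoters, TPM >= 10 expression filter,
#' enrichment FDR < 0.01, 20-bin metaprofiles with 2-kb flanks and 5-Mb
#' chromosome windows.
#'
#' @param simulate Simulate inputs (`TRUE`) or read them from `paths`.
#' @param sim A [SimConfig-class] used when `simulate = TRUE`.
#' @param paths Named list of input paths when `simulate = FALSE`:
#'   `genome`, `annotation`, `callsA`, `callsB`, and optionally `tpm`,
#'   `terms`.
#' @param windowSize,stepSize,minCoverage,qMax,minFold,dmcP,dmcMin,mergeGap
#'   DMR-caller thresholds (see [callDmrs()]).
#' @param promoterLen,minTpm,fdrMax,nBins,flankLen,chromWindow Downstream
#'   thresholds.
#' @param contexts Contexts to analyse.
#' @return A named list of class `"methylwinConfig"`.
#' @export
pipelineConfig <- function(simulate = TRUE, sim = simConfig(),
                           paths = list(),
                           windowSize = 200, stepSize = 50, minCoverage = 4,
                           qMax = 0.01, minFold = 2.5, dmcP = 0.01,
                           dmcMin = 7, mergeGap = 100, promoterLen = 2000,
                           minTpm = 10, fdrMax = 0.01, nBins = 20,
                           flankLen = 2000, chromWindow = 5e6,
                           contexts = c("CG", "CHG", "CHH")) {
  cfg <- list(simulate = simulate, sim = sim, paths = paths,
              windowSize = windowSize, stepSize = stepSize,
              minCoverage = minCoverage, qMax = qMax, minFold = minFold,
              dmcP = dmcP, dmcMin = dmcMin, mergeGap = mergeGap,
              promoterLen = promoterLen, minTpm = minTpm, fdrMax = fdrMax,
              nBins = nBins, flankLen = flankLen, chromWindow = chromWindow,
              contexts = contexts)
  class(cfg) <- "methylwinConfig"
  cfg
}

.writeTsv <- function(x, path, col.names = TRUE) {
  utils::write.table(x, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = col.names)
}

#' Run the whole methylation analysis pipeline
#'
#' Orchestrates simulate (or load) -> genome summaries -> chromosome-window
#' tracks -> gene/TE metaprofiles -> DMR calling -> DMG assignment ->
#' optional expression filter and term enrichment, writing every product to
#' `outDir` as plain text: `genome.fa`, `annotation.gff3`,
#' `calls_A.tsv`/`calls_B.tsv`, `truth.bed` (simulation only),
#' `summary_*.tsv`, `chrom_windows_*.tsv`, `metaprofile_*.tsv`, `dmr.bed`,
#' `dmc.bed`, `dmr_summary.tsv`, `composition.tsv`, `dmg.tsv`,
#' `region_distribution.tsv`, `enrichment.tsv` and `run_config.txt`.
#' Deterministic given the configuration.
#'
#' @param config A [pipelineConfig()] list.
#' @param outDir Output directory (created if needed).
#' @return Invisibly, a list with the in-memory results (`tracks`, `dmrs`,
#'   `dmgs`, `summaries`, `metaprofiles`, `enrichment`, `truth`).
#' @export
runPipeline <- function(config = pipelineConfig(), outDir) {
  stopifnot(inherits(config, "methylwinConfig"))
  dir.create(outDir, showWarnings = FALSE, recursive = TRUE)

  truth <- NULL
  if (isTRUE(config$simulate)) {
    world <- simulateGenome(config$sim)
    genome <- world$genome; annotation <- world$genes; tes <- world$tes
    pair <- simulateMethylomePair(genome, annotation, tes, config$sim)
    trackA <- pair$trackA; trackB <- pair$trackB; truth <- pair$truth
    writeXStringSet(genome, file.path(outDir, "genome.fa"))
    writeGeneAnnotation(annotation, file.path(outDir, "annotation.gff3"),
                        tes = tes)
    writeMethylationCalls(trackA, file.path(outDir, "calls_A.tsv"))
    writeMethylationCalls(trackB, file.path(outDir, "calls_B.tsv"))
    writeTruthBed(truth, file.path(outDir, "truth.bed"))
    nonConversion <- config$sim@nonConversion
  } else {
    p <- config$paths
    for (need in c("genome", "annotation", "callsA", "callsB"))
      if (is.null(p[[need]]) || !file.exists(p[[need]]))
        stop("missing input: ", need)
    genome <- readGenomeFasta(p$genome)
    annotation <- readGeneAnnotation(p$annotation)
    tes <- tryCatch(readTeAnnotation(p$annotation), error = function(e) GRanges())
    sl <- stats::setNames(width(genome), names(genome))
    trackA <- readMethylationCalls(p$callsA, config$minCoverage,
                                   seqlengths = sl)
    trackB <- readMethylationCalls(p$callsB, config$minCoverage,
                                   seqlengths = sl)
    nonConversion <- if (!is.null(p$nonConversion)) p$nonConversion else 0
  }
  sl <- stats::setNames(width(genome), names(genome))

  log <- c(sprintf("methylwin %s", as.character(utils::packageVersion("methylwin"))),
           sprintf("sites A: %d  sites B: %d", length(trackA), length(trackB)))

  for (nm in c("A", "B")) {
    tr <- if (nm == "A") trackA else trackB
    gs <- genomeSummary(tr, nonConversion = nonConversion)
    .writeTsv(data.frame(context = names(gs$mCounts),
                         nSites = as.integer(gs$nSites),
                         mSites = as.integer(gs$mCounts),
                         composition = as.numeric(gs$composition),
                         level = gs$levels),
              file.path(outDir, paste0("summary_", nm, ".tsv")))
    .writeTsv(chromosomeWindows(tr, sl, config$chromWindow),
              file.path(outDir, paste0("chrom_windows_", nm, ".tsv")))
    for (feat in c("gene", "te")) {
      feats <- if (feat == "gene") geneBodies(annotation) else tes
      if (!length(feats)) next
      if (feat == "te" && all(as.character(strand(feats)) == "*"))
        strand(feats) <- "+"
      prof <- do.call(rbind, lapply(config$contexts, function(ctx)
        metaProfile(tr, feats, ctx, config$flankLen, config$nBins)))
      .writeTsv(prof, file.path(outDir, sprintf("metaprofile_%s_%s.tsv",
                                                feat, nm)))
    }
  }

  dmrs <- callDmrs(trackA, trackB, sl, contexts = config$contexts,
                   windowSize = config$windowSize, stepSize = config$stepSize,
                   minCoverage = config$minCoverage, qMax = config$qMax,
                   minFold = config$minFold, dmcP = config$dmcP,
                   dmcMin = config$dmcMin, mergeGap = config$mergeGap)
  writeDmrBed(dmrs, file.path(outDir, "dmr.bed"))
  writeDmcBed(metadata(dmrs)$dmcs, file.path(outDir, "dmc.bed"))
  dsum <- dmrSummary(dmrs)
  .writeTsv(dsum, file.path(outDir, "dmr_summary.tsv"))
  .writeTsv(genomicComposition(dmrs, annotation, config$promoterLen),
            file.path(outDir, "composition.tsv"))
  log <- c(log, sprintf("DMRs: %d (%s)", length(dmrs),
                        paste(dsum$context, dsum$total, sep = "=",
                              collapse = " ")))

  dmgs <- assignDmrsToGenes(dmrs, annotation, config$promoterLen)
  .writeTsv(regionDistribution(dmgs),
            file.path(outDir, "region_distribution.tsv"))
  log <- c(log, sprintf("DMG records: %d", nrow(dmgs)))

  enr <- NULL
  if (!is.null(config$paths$tpm) && nrow(dmgs)) {
    tpm <- readTpmTable(config$paths$tpm)
    dmgs <- expressionFilter(dmgs, tpm, config$minTpm)
  }
  .writeTsv(dmgs, file.path(outDir, "dmg.tsv"))
  if (!is.null(config$paths$terms) && nrow(dmgs)) {
    ann <- readTermAnnotations(config$paths$terms)
    universe <- unique(c(ann$gene_id,
                         mcols(geneBodies(annotation))$gene_id))
    enr <- enrichTerms(unique(dmgs$gene_id), ann, universe, config$fdrMax)
    .writeTsv(enr, file.path(outDir, "enrichment.tsv"))
    log <- c(log, sprintf("enriched terms at FDR<%g: %d", config$fdrMax,
                          sum(enr$significant)))
  }

  cfgTxt <- vapply(names(config), function(k) {
    v <- config[[k]]
    if (is(v, "SimConfig"))
      v <- paste(unlist(.configRecord(v)), collapse = ",")
    paste0(k, "=", paste(unlist(v), collapse = ","))
  }, character(1))
  writeLines(cfgTxt, file.path(outDir, "run_config.txt"))
  writeLines(log, file.path(outDir, "run_log.txt"))

  invisible(list(tracks = list(A = trackA, B = trackB), dmrs = dmrs,
                 dmgs = dmgs, truth = truth, summary = dsum,
                 enrichment = enr, outDir = outDir))
}

#' Nucleotide-level precision and recall of called DMRs against truth
#'
#' Compares called DMR intervals with ground-truth regions base by base:
#' precision is the fraction of called bases lying inside truth regions of
#' the same context, recall the fraction of truth bases covered by calls.
#'
#' @param dmrs Called DMR `GRanges` (with `context`).
#' @param truth Truth `GRanges` (with `context`), e.g. [truthRegions()].
#' @param context Optional single context to restrict to.
#' @return Named numeric vector `c(precision, recall)`; `NaN` when there is
#'   nothing called/true.
#' @export
dmrRecovery <- function(dmrs, truth, context = NULL) {
  if (!is.null(context)) {
    dmrs <- dmrs[mcols(dmrs)$context == context]
    truth <- truth[mcols(truth)$context == context]
  }
  called <- reduce(granges(dmrs), ignore.strand = TRUE)
  true <- reduce(granges(truth), ignore.strand = TRUE)
  inter <- GenomicRanges::intersect(called, true, ignore.strand = TRUE)
  c(precision = sum(width(inter)) / sum(width(called)),
    recall = sum(width(inter)) / sum(width(true)))
}
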