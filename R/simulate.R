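# run code under a fixed seed without disturbing the caller's RNG stream
.withSeed <- function(seed, code) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

.defaultBaseLevels <- function() {
  matrix(c(0.35, 0.08, 0.03,   # gene body: CG-dominated body methylation
           0.90, 0.70, 0.15,   # TEs: hypermethylated in all contexts
           0.60, 0.40, 0.08),  # intergenic background
         nrow = 3, byrow = TRUE,
         dimnames = list(c("gene", "te", "intergenic"), .CONTEXTS))
}

#' Configure the synthetic methylome generator
#'
#' Returns a validated [SimConfig-class].  The defaults emulate a
#' two-sample plant WGBS study: ~13x mean coverage, 0.8% bisulfite
#' non-conversion (conversion rate 99.2%), CG > CHG > CHH baseline levels
#' within each feature class, hypermethylated transposable elements and
#' CG-dominated gene-body methylation.
#'
#' @param seed Integer seed (the simulation is fully deterministic given it).
#' @param nChrom,chromLen Number and length (bp) of chromosomes.
#' @param geneDensity,teDensity Features per Mb.
#' @param baseLevels 3x3 matrix of true levels (see [SimConfig-class]).
#' @param meanDepth Mean Poisson coverage per site.
#' @param nonConversion,overConversion Bisulfite error probabilities.
#' @param dmrSpec `data.frame(context, delta, length, count)` of spiked
#'   differential regions; empty by default (null simulation).
#' @return A [SimConfig-class].
#' @export
simConfig <- function(seed = 1L, nChrom = 2L, chromLen = 500000L,
                      geneDensity = 80, teDensity = 40,
                      baseLevels = .defaultBaseLevels(),
                      meanDepth = 13, nonConversion = 0.008,
                      overConversion = 0,
                      dmrSpec = data.frame(context = character(),
                                           delta = numeric(),
                                           length = integer(),
                                           count = integer())) {
  new("SimConfig", seed = as.integer(seed), nChrom = as.integer(nChrom),
      chromLen = as.integer(chromLen), geneDensity = geneDensity,
      teDensity = teDensity, baseLevels = baseLevels, meanDepth = meanDepth,
      nonConversion = nonConversion, overConversion = overConversion,
      dmrSpec = dmrSpec)
}

# serialisable record of a config, stored in track provenance
.configRecord <- function(config) {
  list(seed = config@seed, nChrom = config@nChrom,
       chromLen = config@chromLen, geneDensity = config@geneDensity,
       teDensity = config@teDensity,
       baseLevels = as.vector(config@baseLevels),
       meanDepth = config@meanDepth, nonConversion = config@nonConversion,
       overConversion = config@overConversion,
       dmrSpec = config@dmrSpec)
}

# place n non-overlapping intervals of the given lengths on [1, L];
# `avoid` is an IRanges of forbidden space
.placeIntervals <- function(n, lens, L, avoid = IRanges()) {
  placed <- IRanges()
  tries <- 0L
  while (length(placed) < n) {
    if (tries > 200L * max(n, 1L))
      stop("cannot place ", n, " features of mean length ",
           round(mean(lens)), " on ", L, " bp")
    tries <- tries + 1L
    len <- lens[length(placed) + 1L]
    if (len >= L) stop("feature length ", len, " exceeds chromosome")
    st <- sample.int(L - len, 1L)
    cand <- IRanges(st, width = len)
    if (!any(IRanges::overlapsAny(cand, placed)) &&
        !any(IRanges::overlapsAny(cand, avoid)))
      placed <- c(placed, cand)
  }
  placed[order(IRanges::start(placed))]
}

# split a gene body into alternating exon/intron pieces and carve UTRs
.geneStructure <- function(chrom, st, en, strand, id) {
  len <- en - st + 1L
  nEx <- sample(1:5, 1L)
  minPiece <- 60L
  while (nEx > 1L && len < minPiece * (2L * nEx - 1L)) nEx <- nEx - 1L
  nPiece <- 2L * nEx - 1L
  w <- stats::runif(nPiece) + 0.25
  lens <- pmax(minPiece, floor(len * w / sum(w)))
  lens[1] <- lens[1] + (len - sum(lens))  # absorb remainder
  if (lens[1] < minPiece) { lens[1] <- minPiece; lens[nPiece] <- len - sum(lens[-nPiece]) }
  if (any(lens <= 0L) || sum(lens) != len) {  # degenerate cut: one exon
    nEx <- 1L; nPiece <- 1L; lens <- len
  }
  ends <- st - 1L + cumsum(lens)
  starts <- c(st, utils::head(ends, -1L) + 1L)
  exonIdx <- seq(1L, nPiece, by = 2L)
  exons <- GRanges(chrom, IRanges(starts[exonIdx], ends[exonIdx]),
                   strand = strand)
  # UTRs sit at the transcript ends, inside the terminal exons
  firstEx <- exons[1]; lastEx <- exons[length(exons)]
  if (strand == "-") { tmp <- firstEx; firstEx <- lastEx; lastEx <- tmp }
  u5len <- min(150L, width(firstEx) - 10L)
  u3len <- min(120L, width(lastEx) - 10L)
  if (length(exons) == 1L) {  # both UTRs share the exon
    room <- width(firstEx) - 20L
    if (u5len + u3len > room) { u5len <- room %/% 2L; u3len <- room - u5len }
  }
  utr5 <- if (u5len > 0L) {
    if (strand == "+") GRanges(chrom, IRanges(start(firstEx),
                                              start(firstEx) + u5len - 1L),
                               strand = strand)
    else GRanges(chrom, IRanges(end(firstEx) - u5len + 1L, end(firstEx)),
                 strand = strand)
  } else GRanges()
  utr3 <- if (u3len > 0L) {
    if (strand == "+") GRanges(chrom, IRanges(end(lastEx) - u3len + 1L,
                                              end(lastEx)), strand = strand)
    else GRanges(chrom, IRanges(start(lastEx), start(lastEx) + u3len - 1L),
                 strand = strand)
  } else GRanges()
  list(exons = exons, utr5 = utr5, utr3 = utr3)
}

#' Simulate a genome with gene and transposable-element annotation
#'
#' Draws uniform-composition chromosome sequences, places non-overlapping
#' gene models (1-5 exons with intervening introns and terminal UTRs) and
#' transposable elements in the remaining space, at the densities given in
#' the configuration.  Deterministic given `config@seed`.
#'
#' @param config A [SimConfig-class].
#' @return A list with elements `genome` (`DNAStringSet`), `genes`
#'   ([GeneAnnotation-class]) and `tes` (`GRanges` with `te_id`, `family`).
#' @export
simulateGenome <- function(config) {
  validObject(config)
  .withSeed(config@seed, {
    chromNames <- paste0("chr", seq_len(config@nChrom))
    L <- config@chromLen
    seqs <- vapply(chromNames, function(ch)
      paste(sample(c("A", "C", "G", "T"), L, replace = TRUE), collapse = ""),
      character(1))
    genome <- DNAStringSet(seqs)
    names(genome) <- chromNames
    sl <- stats::setNames(rep(L, length(chromNames)), chromNames)

    geneRows <- list(); exonL <- list(); u5L <- list(); u3L <- list()
    teRows <- list()
    gid <- 0L; tid <- 0L
    for (ch in chromNames) {
      nGene <- round(config@geneDensity * L / 1e6)
      nTe <- round(config@teDensity * L / 1e6)
      gLens <- sample(1000:4000, max(nGene, 1L), replace = TRUE)
      gPlaced <- if (nGene > 0) .placeIntervals(nGene, gLens, L) else IRanges()
      for (i in seq_along(gPlaced)) {
        gid <- gid + 1L
        id <- sprintf("gene%04d", gid)
        std <- sample(c("+", "-"), 1L)
        body <- GRanges(ch, gPlaced[i], strand = std, seqlengths = sl)
        mcols(body)$gene_id <- id
        parts <- .geneStructure(ch, start(gPlaced[i]), end(gPlaced[i]), std, id)
        geneRows[[id]] <- body
        exonL[[id]] <- parts$exons
        u5L[[id]] <- parts$utr5
        u3L[[id]] <- parts$utr3
      }
      tLens <- sample(500:3000, max(nTe, 1L), replace = TRUE)
      tPlaced <- if (nTe > 0) .placeIntervals(nTe, tLens, L, avoid = gPlaced)
                 else IRanges()
      for (i in seq_along(tPlaced)) {
        tid <- tid + 1L
        te <- GRanges(ch, tPlaced[i], seqlengths = sl)
        mcols(te)$te_id <- sprintf("te%04d", tid)
        mcols(te)$family <- sample(c("Gypsy", "Copia", "hAT", "MULE",
                                     "CACTA"), 1L)
        teRows[[mcols(te)$te_id]] <- te
      }
    }
    genes <- if (length(geneRows)) do.call(c, unname(geneRows))
             else GRanges(gene_id = character(), seqlengths = sl)
    tes <- if (length(teRows)) do.call(c, unname(teRows))
           else GRanges(te_id = character(), family = character(),
                        seqlengths = sl)
    ann <- new("GeneAnnotation", genes = genes,
               exons = GRangesList(exonL), utr5 = GRangesList(u5L),
               utr3 = GRangesList(u3L))
    list(genome = genome, genes = ann, tes = tes)
  })
}

# pick a direction for a truth region: every site's level must stay in
# [0, 1] and the implied level ratio must exceed the 2.5-fold threshold,
# so that a spiked region is a differential region by the study's own
# definition (otherwise the location is rejected and resampled).
.chooseDirection <- function(pA, delta, minFold = 2.5) {
  meanA <- mean(pA)
  feas <- c(hyper = max(pA) + delta <= 1, hypo = min(pA) - delta >= 0)
  ratio <- c(hyper = (meanA + delta) / meanA,
             hypo = if (meanA - delta <= 0) Inf else meanA / (meanA - delta))
  cand <- names(feas)[feas & ratio > minFold]
  if (!length(cand)) return(NA_character_)
  if (length(cand) == 1L) cand else sample(cand, 1L)
}

#' Simulate a pair of methylomes with ground-truth differential regions
#'
#' Every context-defined cytosine of the genome receives a true methylation
#' probability from its feature class (TE > gene body > intergenic
#' precedence) and context.  Spiked truth regions shift sample B's
#' probability by exactly `delta` at every context-matching site; outside
#' them the two samples are exchangeable.  Per site and sample, coverage is
#' Poisson(`meanDepth`) and the methylated count is binomial with observed
#' probability `p(1 - overConversion) + (1 - p) nonConversion`.  Sites with
#' zero coverage are absent from the emitted track, as in real call tables.
#' Truth regions are only placed where at least 10 context-matching
#' cytosines exist, so downstream minimum-site rules are attainable.
#'
#' @param genome,annotation,tes Output of [simulateGenome()].
#' @param config The same [SimConfig-class] used for the genome.
#' @param cytosines Optional precomputed [enumerateCytosines()] result for
#'   `genome`, to avoid re-enumeration across replicate simulations.
#' @return A list with `trackA`, `trackB` ([MethylomeTrack-class]) and
#'   `truth` ([SimTruth-class]).
#' @export
simulateMethylomePair <- function(genome, annotation, tes, config,
                                  cytosines = NULL) {
  validObject(config)
  .withSeed(config@seed + 1L, {
    cyt <- if (is.null(cytosines)) enumerateCytosines(genome) else cytosines
    n <- length(cyt)
    ctx <- mcols(cyt)$context
    cls <- rep("intergenic", n)
    cls[overlapsAny(cyt, annotation@genes, ignore.strand = TRUE)] <- "gene"
    cls[overlapsAny(cyt, tes, ignore.strand = TRUE)] <- "te"
    pA <- config@baseLevels[cbind(cls, ctx)]
    pB <- pA

    truth <- GRanges(seqlengths = seqlengths(cyt))
    spec <- config@dmrSpec
    if (nrow(spec)) {
      placedAll <- GRanges(seqlengths = seqlengths(cyt))
      regs <- list()
      for (r in seq_len(nrow(spec))) {
        rc <- spec$context[r]; delta <- spec$delta[r]
        rlen <- as.integer(spec$length[r]); cnt <- as.integer(spec$count[r])
        got <- 0L; tries <- 0L
        while (got < cnt) {
          if (tries > 500L * cnt)
            stop("cannot place ", cnt, " truth regions (", rc,
                 ", delta ", delta, ")")
          tries <- tries + 1L
          ch <- sample(names(genome), 1L)
          st <- sample.int(config@chromLen - rlen, 1L)
          cand <- GRanges(ch, IRanges(st, width = rlen),
                          seqlengths = seqlengths(cyt))
          if (any(overlapsAny(cand, placedAll, ignore.strand = TRUE))) next
          inReg <- overlapsAny(cyt, cand, ignore.strand = TRUE) & ctx == rc
          if (sum(inReg) < 10L) next
          dir <- .chooseDirection(pA[inReg], delta)
          if (is.na(dir)) next
          sgn <- if (dir == "hyper") 1 else -1
          pB[inReg] <- pA[inReg] + sgn * delta
          lvlA <- mean(pA[inReg])
          mcols(cand)$context <- rc
          mcols(cand)$direction <- dir
          mcols(cand)$levelA <- lvlA
          mcols(cand)$levelB <- lvlA + sgn * delta
          mcols(cand)$delta <- delta
          regs[[length(regs) + 1L]] <- cand
          placedAll <- c(placedAll, granges(cand))
          got <- got + 1L
        }
      }
      truth <- sort(do.call(c, regs), ignore.strand = TRUE)
    }

    nc <- config@nonConversion; oc <- config@overConversion
    obs <- function(p) p * (1 - oc) + (1 - p) * nc
    tA <- stats::rpois(n, config@meanDepth)
    tB <- stats::rpois(n, config@meanDepth)
    mA <- stats::rbinom(n, tA, obs(pA))
    mB <- stats::rbinom(n, tB, obs(pB))

    prov <- list(config = .configRecord(config))
    mk <- function(t, m, id) {
      keep <- t > 0L
      sub <- cyt[keep]
      MethylomeTrack(as.character(seqnames(sub)), start(sub),
                     as.character(strand(sub)), mcols(sub)$context,
                     m[keep], t[keep], sampleId = id,
                     seqlengths = seqlengths(cyt), provenance = prov)
    }
    sp <- DataFrame(chrom = as.character(seqnames(cyt)), pos = start(cyt),
                    strand = as.character(strand(cyt)), context = ctx,
                    class = cls, pA = pA, pB = pB)
    list(trackA = mk(tA, mA, "sampleA"),
         trackB = mk(tB, mB, "sampleB"),
         truth = new("SimTruth", regions = truth, siteParams = sp,
                     config = config))
  })
}

#' Simulate an unmethylated control track
#'
#' Generates calls over a biologically unmethylated sequence (the role the
#' chloroplast genome plays in plant WGBS studies): every methylated read
#' observation is a bisulfite conversion failure, so
#' [estimateConversionRate()] applied to the result recovers
#' `1 - nonConversion`.
#'
#' @param length Control sequence length in bp.
#' @param config A [SimConfig-class] (depth, non-conversion and seed are
#'   used).
#' @return A [MethylomeTrack-class] on a sequence named `"control"`.
#' @export
simulateControlTrack <- function(length, config) {
  stopifnot(length > 0)
  validObject(config)
  .withSeed(config@seed + 2L, {
    seq <- paste(sample(c("A", "C", "G", "T"), length, replace = TRUE),
                 collapse = "")
    genome <- DNAStringSet(c(control = seq))
    cyt <- enumerateCytosines(genome)
    n <- base::length(cyt)
    t <- stats::rpois(n, config@meanDepth)
    m <- stats::rbinom(n, t, config@nonConversion)
    keep <- t > 0L
    if (!any(keep)) {
      return(new("MethylomeTrack",
                 sites = GRanges(context = character(), mCount = integer(),
                                 tCount = integer()),
                 sampleId = "control",
                 provenance = list(config = .configRecord(config))))
    }
    sub <- cyt[keep]
    MethylomeTrack(as.character(seqnames(sub)), start(sub),
                   as.character(strand(sub)), mcols(sub)$context,
                   m[keep], t[keep], sampleId = "control",
                   seqlengths = seqlengths(cyt),
                   provenance = list(config = .configRecord(config)))
  })
}

#' Write / read ground-truth regions as BED
#'
#' BED conventions: 0-based half-open coordinates, name field
#' `context|direction|delta`.
#'
#' @param truth A [SimTruth-class].
#' @param path Output BED path.
#' @return `path` invisibly (writer); a `GRanges` (reader).
#' @export
writeTruthBed <- function(truth, path) {
  gr <- truthRegions(truth)
  tab <- data.frame(chrom = as.character(seqnames(gr)),
                    start = start(gr) - 1L, end = end(gr),
                    name = paste(mcols(gr)$context, mcols(gr)$direction,
                                 mcols(gr)$delta, sep = "|"))
  utils::write.table(tab, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' @rdname writeTruthBed
#' @export
readTruthBed <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           col.names = c("chrom", "start", "end", "name"))
  parts <- strsplit(tab$name, "|", fixed = TRUE)
  GRanges(tab$chrom, IRanges(tab$start + 1L, tab$end),
          context = vapply(parts, `[`, "", 1L),
          direction = vapply(parts, `[`, "", 2L),
          delta = as.numeric(vapply(parts, `[`, "", 3L)))
}
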