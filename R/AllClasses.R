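#' @import methods
#' @importFrom S4Vectors mcols mcols<- metadata metadata<- DataFrame
#' @importFrom GenomicRanges GRanges GRangesList seqnames start end width
#'   strand findOverlaps reduce
#' @importFrom IRanges IRanges subsetByOverlaps overlapsAny
#' @importFrom GenomeInfoDb seqlengths seqlevels
#' @importFrom Biostrings DNAStringSet readDNAStringSet writeXStringSet
#' @useDynLib methylwin, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

.CONTEXTS <- c("CG", "CHG", "CHH")

#' MethylomeTrack: per-cytosine methylation calls for one sample
#'
#' A `MethylomeTrack` holds the bisulfite evidence for one library: one
#' record per cytosine site giving its strand, sequence context (CG, CHG or
#' CHH), methylated read count and total read count.  Sites live in a
#' [GenomicRanges::GRanges] of width-1 ranges with metadata columns
#' `context`, `mCount` and `tCount`, kept sorted with at most one record per
#' (chromosome, position, strand).
#'
#' @slot sites A `GRanges` of width-1 ranges with `context`, `mCount`,
#'   `tCount` metadata columns.
#' @slot sampleId Single string naming the library.
#' @slot provenance List recording how the track was produced (input file or
#'   simulation configuration).
#'
#' @seealso [readMethylationCalls()], [simulateMethylomePair()],
#'   [regionLevel()], [genomeSummary()]
#' @export
setClass("MethylomeTrack",
  slots = c(sites = "GRanges", sampleId = "character", provenance = "list"),
  prototype = prototype(sampleId = NA_character_, provenance = list())
)

setValidity("MethylomeTrack", function(object) {
  gr <- object@sites
  msg <- character()
  need <- c("context", "mCount", "tCount")
  if (!all(need %in% colnames(mcols(gr))))
    return(paste("sites must carry metadata columns:",
                 paste(need, collapse = ", ")))
  if (length(gr)) {
    if (any(width(gr) != 1L))
      msg <- c(msg, "all sites must have width 1")
    if (!all(as.character(strand(gr)) %in% c("+", "-")))
      msg <- c(msg, "site strand must be '+' or '-'")
    if (!all(mcols(gr)$context %in% .CONTEXTS))
      msg <- c(msg, "context must be one of CG, CHG, CHH")
    m <- mcols(gr)$mCount; t <- mcols(gr)$tCount
    if (any(m < 0L) || any(m > t))
      msg <- c(msg, "counts must satisfy 0 <= mCount <= tCount")
    key <- paste(seqnames(gr), start(gr), strand(gr))
    if (anyDuplicated(key))
      msg <- c(msg, "duplicate (chrom, position, strand) site")
    if (is.unsorted(order(as.integer(seqnames(gr)), start(gr))))
      msg <- c(msg, "sites must be coordinate-sorted")
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

#' @describeIn MethylomeTrack-class Number of sites in the track.
#' @param x,object A `MethylomeTrack`.
#' @export
setMethod("length", "MethylomeTrack", function(x) length(x@sites))

setMethod("show", "MethylomeTrack", function(object) {
  gr <- object@sites
  cat("MethylomeTrack '", object@sampleId, "': ",
      length(gr), " sites on ",
      length(unique(as.character(seqnames(gr)))), " sequence(s)\n", sep = "")
  if (length(gr)) {
    tab <- table(factor(mcols(gr)$context, levels = .CONTEXTS))
    cat("  context counts:",
        paste(names(tab), tab, sep = "=", collapse = " "), "\n")
    cat("  mean coverage:", round(mean(mcols(gr)$tCount), 2), "\n")
  }
  invisible(object)
})

#' Accessors for MethylomeTrack
#'
#' `trackSites()` returns the underlying site `GRanges`; `sampleId()` the
#' library name; `trackProvenance()` the provenance record.
#'
#' @param x A [MethylomeTrack-class] object.
#' @return `trackSites()`: a `GRanges`; `sampleId()`: a string;
#'   `trackProvenance()`: a list.
#' @export
trackSites <- function(x) {
  stopifnot(is(x, "MethylomeTrack"))
  x@sites
}

#' @rdname trackSites
#' @export
sampleId <- function(x) {
  stopifnot(is(x, "MethylomeTrack"))
  x@sampleId
}

#' @rdname trackSites
#' @export
trackProvenance <- function(x) {
  stopifnot(is(x, "MethylomeTrack"))
  x@provenance
}

#' Construct a MethylomeTrack from per-site vectors
#'
#' Low-level constructor used by the reader and the simulator.  Sites are
#' sorted; duplicates are an error.
#'
#' @param chrom Character vector of chromosome names.
#' @param pos Integer vector of 1-based positions.
#' @param strand Character vector, "+" or "-".
#' @param context Character vector over CG/CHG/CHH.
#' @param mCount,tCount Integer vectors of methylated and total read counts.
#' @param sampleId Library name.
#' @param seqlengths Optional named integer vector of chromosome lengths.
#' @param provenance Optional list describing the origin of the calls.
#' @return A [MethylomeTrack-class].
#' @export
MethylomeTrack <- function(chrom, pos, strand, context, mCount, tCount,
                           sampleId = "sample", seqlengths = NULL,
                           provenance = list()) {
  gr <- GRanges(chrom, IRanges(as.integer(pos), width = 1L), strand = strand,
                seqlengths = seqlengths)
  mcols(gr)$context <- as.character(context)
  mcols(gr)$mCount <- as.integer(mCount)
  mcols(gr)$tCount <- as.integer(tCount)
  gr <- gr[order(as.integer(seqnames(gr)), start(gr), as.character(strand(gr)))]
  new("MethylomeTrack", sites = gr, sampleId = sampleId,
      provenance = provenance)
}

#' GeneAnnotation: gene models with exon/intron/UTR structure
#'
#' Container for gene models used for functional-region assignment and
#' metaprofiles.  Gene bodies are a `GRanges` (metadata column `gene_id`,
#' stranded); exons and UTRs are `GRangesList`s named by gene id.  Introns
#' are derived as the within-body complement of the exons.
#'
#' @slot genes `GRanges` of gene bodies with `gene_id` metadata column.
#' @slot exons,utr5,utr3 `GRangesList` keyed by gene id.
#' @export
setClass("GeneAnnotation",
  slots = c(genes = "GRanges", exons = "GRangesList",
            utr5 = "GRangesList", utr3 = "GRangesList")
)

setValidity("GeneAnnotation", function(object) {
  g <- object@genes
  msg <- character()
  if (length(g)) {
    if (is.null(mcols(g)$gene_id))
      return("genes must carry a gene_id metadata column")
    if (anyDuplicated(mcols(g)$gene_id))
      msg <- c(msg, "gene ids must be unique")
    if (!all(as.character(strand(g)) %in% c("+", "-")))
      msg <- c(msg, "gene strand must be '+' or '-'")
    ids <- mcols(g)$gene_id
    if (!all(names(object@exons) %in% ids))
      msg <- c(msg, "exon list names must be gene ids")
    # exons within body, non-overlapping within a gene
    for (id in names(object@exons)) {
      ex <- object@exons[[id]]
      body <- g[mcols(g)$gene_id == id]
      if (length(ex)) {
        if (any(start(ex) < start(body)) || any(end(ex) > end(body))) {
          msg <- c(msg, paste0("exons of ", id, " exceed gene body"))
          break
        }
        if (length(reduce(ex)) != length(ex)) {
          msg <- c(msg, paste0("exons of ", id, " overlap"))
          break
        }
      }
    }
  }
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "GeneAnnotation", function(object) {
  cat("GeneAnnotation:", length(object@genes), "genes,",
      sum(lengths(object@exons)), "exons\n")
  invisible(object)
})

#' @describeIn GeneAnnotation-class Gene-body `GRanges`.
#' @param x A `GeneAnnotation`.
#' @export
geneBodies <- function(x) {
  stopifnot(is(x, "GeneAnnotation"))
  x@genes
}

#' @describeIn GeneAnnotation-class Exon `GRangesList` keyed by gene id.
#' @export
geneExons <- function(x) {
  stopifnot(is(x, "GeneAnnotation"))
  x@exons
}

#' @describeIn GeneAnnotation-class 5' and 3' UTR `GRangesList`s.
#' @export
geneUtr5 <- function(x) {
  stopifnot(is(x, "GeneAnnotation"))
  x@utr5
}

#' @rdname geneUtr5
#' @export
geneUtr3 <- function(x) {
  stopifnot(is(x, "GeneAnnotation"))
  x@utr3
}

#' SimConfig: parameters of the synthetic methylome generator
#'
#' Bundles every knob of the two-sample methylome simulation.  Defaults
#' reflect a typical plant WGBS study: ~13x mean depth, 0.8% bisulfite
#' non-conversion, and context-dependent baseline levels ordered
#' CG > CHG > CHH within each feature class, with transposable elements
#' hypermethylated relative to intergenic space and gene bodies carrying
#' CG-dominated methylation.
#'
#' @slot seed Integer seed; the whole simulation is deterministic given it.
#' @slot nChrom,chromLen Number and length (bp) of simulated chromosomes.
#' @slot geneDensity,teDensity Features per Mb.
#' @slot baseLevels Numeric matrix, rows `gene`, `te`, `intergenic`, columns
#'   `CG`, `CHG`, `CHH`: true methylation probability per class and context.
#' @slot meanDepth Mean sequencing coverage (Poisson).
#' @slot nonConversion Probability an unmethylated cytosine reads as
#'   methylated (bisulfite non-conversion failure).
#' @slot overConversion Probability a methylated cytosine reads as
#'   unmethylated; 0 by default.
#' @slot dmrSpec `data.frame` with columns `context`, `delta`, `length`,
#'   `count` describing spiked ground-truth differential regions.
#' @seealso [simConfig()], [simulateGenome()], [simulateMethylomePair()]
#' @export
setClass("SimConfig",
  slots = c(seed = "integer", nChrom = "integer", chromLen = "integer",
            geneDensity = "numeric", teDensity = "numeric",
            baseLevels = "matrix", meanDepth = "numeric",
            nonConversion = "numeric", overConversion = "numeric",
            dmrSpec = "data.frame")
)

setValidity("SimConfig", function(object) {
  msg <- character()
  if (object@meanDepth <= 0) msg <- c(msg, "meanDepth must be > 0")
  if (object@nonConversion < 0 || object@nonConversion >= 1)
    msg <- c(msg, "nonConversion must be in [0, 1)")
  if (object@overConversion < 0 || object@overConversion >= 1)
    msg <- c(msg, "overConversion must be in [0, 1)")
  bl <- object@baseLevels
  if (!identical(rownames(bl), c("gene", "te", "intergenic")) ||
      !identical(colnames(bl), .CONTEXTS))
    msg <- c(msg, "baseLevels must have rows gene/te/intergenic and columns CG/CHG/CHH")
  else if (any(bl < 0) || any(bl > 1))
    msg <- c(msg, "baseLevels must be probabilities in [0, 1]")
  ds <- object@dmrSpec
  if (nrow(ds)) {
    if (!all(c("context", "delta", "length", "count") %in% names(ds)))
      msg <- c(msg, "dmrSpec needs columns context, delta, length, count")
    else {
      if (!all(ds$context %in% .CONTEXTS))
        msg <- c(msg, "dmrSpec context must be CG/CHG/CHH")
      if (any(ds$delta <= 0 | ds$delta > 1))
        msg <- c(msg, "dmrSpec delta must be in (0, 1]")
    }
  }
  if (object@nChrom < 1L || object@chromLen < 1000L)
    msg <- c(msg, "need nChrom >= 1 and chromLen >= 1000")
  if (length(msg)) paste(msg, collapse = "; ") else TRUE
})

setMethod("show", "SimConfig", function(object) {
  cat("SimConfig: seed", object@seed, "|", object@nChrom, "chrom x",
      object@chromLen, "bp | depth", object@meanDepth,
      "| non-conversion", object@nonConversion, "\n")
  cat("  spiked differential regions:", sum(object@dmrSpec$count), "\n")
  invisible(object)
})

#' SimTruth: ground truth emitted by the methylome simulator
#'
#' @slot regions `GRanges` of spiked differential regions with metadata
#'   columns `context`, `direction` (of sample B relative to A), `levelA`,
#'   `levelB`, `delta`.
#' @slot siteParams `DataFrame` of per-site true methylation probabilities
#'   (`pA`, `pB`) with chromosome, position, strand, context and feature
#'   class.
#' @slot config The [SimConfig-class] that produced the simulation.
#' @export
setClass("SimTruth",
  slots = c(regions = "GRanges", siteParams = "DataFrame",
            config = "SimConfig")
)

setValidity("SimTruth", function(object) {
  gr <- object@regions
  if (!length(gr)) return(TRUE)
  need <- c("context", "direction", "levelA", "levelB", "delta")
  if (!all(need %in% colnames(mcols(gr))))
    return(paste("regions need metadata:", paste(need, collapse = ", ")))
  for (ctx in unique(mcols(gr)$context)) {
    sub <- gr[mcols(gr)$context == ctx]
    if (length(reduce(sub, min.gapwidth = 0L)) != length(sub))
      return(paste0("truth regions overlap within context ", ctx))
  }
  d <- abs(mcols(gr)$levelA - mcols(gr)$levelB)
  if (any(abs(d - mcols(gr)$delta) > 1e-9))
    return("levelA/levelB must differ by exactly delta")
  TRUE
})

setMethod("show", "SimTruth", function(object) {
  cat("SimTruth:", length(object@regions), "spiked regions,",
      nrow(object@siteParams), "sites with recorded parameters\n")
  invisible(object)
})

#' @describeIn SimTruth-class Ground-truth region `GRanges`.
#' @param x A `SimTruth`.
#' @export
truthRegions <- function(x) {
  stopifnot(is(x, "SimTruth"))
  x@regions
}

#' @describeIn SimTruth-class Per-site true methylation probabilities.
#' @export
truthSiteParams <- function(x) {
  stopifnot(is(x, "SimTruth"))
  x@siteParams
}
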