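#' Load a reference genome from FASTA
#'
#' Reads a (possibly gzipped, multi-line) FASTA file into a
#' [Biostrings::DNAStringSet], uppercases the sequences and validates them:
#' record names (first word of each header) must be unique and sequences may
#' contain only A, C, G, T or N.
#'
#' @param path Path to a FASTA file.
#' @return A `DNAStringSet` named by chromosome.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">chr1", "acgt"), fa)
#' genome <- readGenomeFasta(fa)
#' width(genome)
#' @export
readGenomeFasta <- function(path) {
  if (!file.exists(path)) stop("no such file: ", path)
  seqs <- tryCatch(
    withCallingHandlers(readDNAStringSet(path),
                        warning = function(w) stop(conditionMessage(w))),
    error = function(e) stop("malformed FASTA '", path, "': ",
                             conditionMessage(e), call. = FALSE))
  if (length(seqs) == 0L) stop("FASTA '", path, "' contains no records")
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  if (any(names(seqs) == ""))
    stop("FASTA '", path, "' has an empty record name")
  if (anyDuplicated(names(seqs)))
    stop("duplicate record name in '", path, "': ",
         names(seqs)[duplicated(names(seqs))][1])
  seqs <- Biostrings::DNAStringSet(toupper(seqs))
  bad <- Biostrings::letterFrequency(seqs, letters = "ACGTN")
  other <- width(seqs) - rowSums(bad)
  if (any(other > 0))
    stop("non-ACGTN characters in record '",
         names(seqs)[which(other > 0)[1]], "'")
  seqs
}

# chromosome sequence as a character vector, one element per base
.chromChars <- function(genome, chrom) {
  if (!chrom %in% names(genome)) stop("unknown chromosome: ", chrom)
  strsplit(as.character(genome[[chrom]]), "", fixed = TRUE)[[1]]
}

.H <- c("A", "C", "T")           # IUPAC H: not G
.H_COMP <- c("T", "G", "A")      # bases whose complement is in H

# context from the two bases downstream of a C, already strand-oriented:
# b1 and b2 are the next bases read 5'->3' on the strand of the cytosine
# (NA when off the end of the chromosome).  Returns CG/CHG/CHH or NA.
.contextFromDownstream <- function(b1, b2) {
  ctx <- rep(NA_character_, length(b1))
  ok1 <- !is.na(b1)
  ctx[ok1 & b1 == "G"] <- "CG"
  h1 <- ok1 & b1 %in% .H
  ok2 <- h1 & !is.na(b2)
  ctx[ok2 & b2 == "G"] <- "CHG"
  ctx[ok2 & b2 %in% .H] <- "CHH"
  ctx
}

#' Classify the sequence context of cytosines
#'
#' Plant cytosine methylation is described in three sequence contexts -- CG,
#' CHG and CHH, where H is A, C or T -- read 5' to 3' on the strand carrying
#' the cytosine.  For a minus-strand cytosine (a G in the reference) the two
#' upstream reference bases are reverse-complemented before classification.
#' Contexts that would run off the chromosome end or across an N are
#' undefined and returned as `NA`.
#'
#' @param genome A `DNAStringSet` as from [readGenomeFasta()].
#' @param chrom Chromosome name.
#' @param pos Integer vector of 1-based positions.
#' @param strand `"+"` or `"-"`, recycled to `length(pos)`.
#' @return Character vector over `"CG"`, `"CHG"`, `"CHH"` or `NA`.
#' @examples
#' fa <- tempfile(fileext = ".fa")
#' writeLines(c(">c", "ACGT"), fa)
#' classifyContext(readGenomeFasta(fa), "c", 2, "+")  # CG
#' @export
classifyContext <- function(genome, chrom, pos, strand) {
  s <- .chromChars(genome, chrom)
  len <- length(s)
  pos <- as.integer(pos)
  strand <- rep_len(as.character(strand), length(pos))
  if (any(pos < 1L | pos > len)) stop("position outside chromosome")
  ctx <- rep(NA_character_, length(pos))

  plus <- strand == "+"
  if (any(plus)) {
    p <- pos[plus]
    if (any(s[p] != "C"))
      stop("base at position ", p[which(s[p] != "C")[1]],
           " is not C on the + strand")
    b1 <- ifelse(p + 1L <= len, s[pmin(p + 1L, len)], NA_character_)
    b2 <- ifelse(p + 2L <= len, s[pmin(p + 2L, len)], NA_character_)
    ctx[plus] <- .contextFromDownstream(b1, b2)
  }
  minus <- strand == "-"
  if (any(minus)) {
    p <- pos[minus]
    if (any(s[p] != "G"))
      stop("base at position ", p[which(s[p] != "G")[1]],
           " is not C on the - strand (reference base must be G)")
    comp <- c(A = "T", C = "G", G = "C", T = "A")
    b1 <- ifelse(p - 1L >= 1L, unname(comp[s[pmax(p - 1L, 1L)]]), NA_character_)
    b2 <- ifelse(p - 2L >= 1L, unname(comp[s[pmax(p - 2L, 1L)]]), NA_character_)
    ctx[minus] <- .contextFromDownstream(b1, b2)
  }
  if (any(!plus & !minus)) stop("strand must be '+' or '-'")
  ctx
}

#' Enumerate all context-defined cytosines of a genome
#'
#' Emits every cytosine on the plus strand and every guanine position (a
#' minus-strand cytosine) whose context is defined, exactly once, in
#' coordinate order.  Sites whose context window spans an N or the
#' chromosome end are omitted.
#'
#' @param genome A `DNAStringSet`.
#' @param chroms Optional subset of chromosome names.
#' @return A width-1 `GRanges` with strand and a `context` metadata column.
#' @export
enumerateCytosines <- function(genome, chroms = names(genome)) {
  sl <- stats::setNames(width(genome), names(genome))
  out <- lapply(chroms, function(ch) {
    s <- .chromChars(genome, ch)
    pp <- which(s == "C")
    pm <- which(s == "G")
    cp <- if (length(pp)) classifyContext(genome, ch, pp, "+") else character()
    cm <- if (length(pm)) classifyContext(genome, ch, pm, "-") else character()
    pos <- c(pp[!is.na(cp)], pm[!is.na(cm)])
    std <- c(rep("+", sum(!is.na(cp))), rep("-", sum(!is.na(cm))))
    ctx <- c(cp[!is.na(cp)], cm[!is.na(cm)])
    o <- order(pos, std)
    GRanges(rep(ch, length(pos)), IRanges(pos[o], width = 1L),
            strand = std[o], context = ctx[o], seqlengths = sl)
  })
  ans <- do.call(c, out)
  ans
}

.promoterOf <- function(body, promoterLen, chromLen = NA_integer_) {
  plus <- as.character(strand(body)) == "+"
  st <- ifelse(plus, pmax(1L, start(body) - as.integer(promoterLen)),
               end(body) + 1L)
  en <- ifelse(plus, start(body) - 1L,
               end(body) + as.integer(promoterLen))
  if (!is.na(chromLen)) en <- pmin(en, chromLen)
  keep <- en >= st
  gr <- GRanges(seqnames(body), IRanges(st[keep], en[keep]),
                strand = strand(body)[keep])
  mcols(gr) <- mcols(body)[keep, , drop = FALSE]
  gr
}

#' Functional regions of annotated genes
#'
#' Decomposes each gene into labelled intervals: `promoter` (a fixed length
#' upstream of the transcription start site, strand-aware and clipped at the
#' chromosome edge), `UTR` (5' and 3' UTRs), `exon` (exonic sequence outside
#' the UTRs -- positions in both are labelled UTR) and `intron` (gene body
#' minus exons).  Within one gene the four labels are pairwise disjoint and
#' together cover promoter plus gene body.
#'
#' @param annotation A [GeneAnnotation-class].
#' @param promoterLen Promoter length in bp upstream of the TSS (default
#'   2000).
#' @param seqlengths Optional named chromosome lengths used to clip
#'   promoters; taken from the annotation's seqinfo when present.
#' @return A `GRanges` with metadata columns `gene_id` and `label`.
#' @export
functionalRegions <- function(annotation, promoterLen = 2000,
                              seqlengths = NULL) {
  stopifnot(is(annotation, "GeneAnnotation"), promoterLen > 0)
  genes <- annotation@genes
  if (is.null(seqlengths)) seqlengths <- seqlengths(genes)
  pieces <- list()
  for (i in seq_along(genes)) {
    body <- genes[i]
    id <- mcols(body)$gene_id
    ch <- as.character(seqnames(body))
    chromLen <- if (!is.null(seqlengths) && ch %in% names(seqlengths))
      as.integer(seqlengths[[ch]]) else NA_integer_
    prom <- .promoterOf(body, promoterLen, chromLen)
    ex <- if (id %in% names(annotation@exons)) annotation@exons[[id]]
          else GRanges()
    u5 <- if (id %in% names(annotation@utr5)) annotation@utr5[[id]]
          else GRanges()
    u3 <- if (id %in% names(annotation@utr3)) annotation@utr3[[id]]
          else GRanges()
    utr <- reduce(c(granges(u5), granges(u3)))
    exon <- GenomicRanges::setdiff(granges(ex), utr, ignore.strand = TRUE)
    intron <- GenomicRanges::setdiff(granges(body), granges(ex),
                                     ignore.strand = TRUE)
    lab <- function(gr, label) {
      if (!length(gr)) return(NULL)
      gr <- granges(gr)
      mcols(gr)$gene_id <- id
      mcols(gr)$label <- label
      gr
    }
    pieces[[length(pieces) + 1L]] <-
      do.call(c, Filter(Negate(is.null),
                        list(lab(prom, "promoter"), lab(utr, "UTR"),
                             lab(exon, "exon"), lab(intron, "intron"))))
  }
  if (!length(pieces)) return(GRanges(gene_id = character(), label = character()))
  ans <- do.call(c, pieces)
  sort(ans, ignore.strand = TRUE)
}

#' @importFrom GenomicRanges granges
NULL

#' Read gene models from GFF3
#'
#' Builds a [GeneAnnotation-class] from a GFF3 file using feature types
#' `gene`, `exon`, `five_prime_UTR` and `three_prime_UTR`.  Exons and UTRs
#' are attached to genes through their `Parent` attribute (one level of
#' mRNA indirection is resolved when present).
#'
#' @param path GFF3 file path.
#' @return A [GeneAnnotation-class].
#' @export
readGeneAnnotation <- function(path) {
  gff <- rtracklayer::import(path, format = "gff3")
  genes <- gff[gff$type == "gene"]
  mcols(genes) <- DataFrame(gene_id = as.character(genes$ID))
  id_of <- function(parent) {
    p <- as.character(unlist(parent))
    # resolve exon -> mRNA -> gene if mRNA records are present
    mrna <- gff[gff$type %in% c("mRNA", "transcript")]
    if (length(mrna)) {
      hit <- match(p, as.character(mrna$ID))
      p[!is.na(hit)] <- as.character(unlist(mrna$Parent))[hit[!is.na(hit)]]
    }
    p
  }
  pick <- function(type) {
    f <- gff[gff$type == type]
    if (!length(f)) return(GRangesList())
    parent <- id_of(f$Parent)
    mcols(f) <- NULL
    GenomicRanges::split(f, factor(parent, levels = unique(parent)))
  }
  new("GeneAnnotation", genes = genes, exons = pick("exon"),
      utr5 = pick("five_prime_UTR"), utr3 = pick("three_prime_UTR"))
}

#' Read transposable elements from GFF3
#'
#' @param path GFF3 file path.
#' @param featureType GFF3 `type` of TE records (default
#'   `"transposable_element"`).
#' @return A `GRanges` with metadata columns `te_id` and `family`.
#' @export
readTeAnnotation <- function(path, featureType = "transposable_element") {
  gff <- rtracklayer::import(path, format = "gff3")
  tes <- gff[gff$type == featureType]
  fam <- if (!is.null(tes$family)) as.character(tes$family)
         else rep(NA_character_, length(tes))
  mcols(tes) <- DataFrame(te_id = as.character(tes$ID), family = fam)
  tes
}

#' Write a GeneAnnotation (and optional TEs) to GFF3
#'
#' @param annotation A [GeneAnnotation-class].
#' @param path Output GFF3 path.
#' @param tes Optional TE `GRanges` (with `te_id`, `family`) appended as
#'   `transposable_element` records.
#' @return `path`, invisibly.
#' @export
writeGeneAnnotation <- function(annotation, path, tes = NULL) {
  rows <- list()
  genes <- annotation@genes
  for (i in seq_along(genes)) {
    g <- genes[i]
    id <- mcols(g)$gene_id
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = as.character(seqnames(g)), source = "methylwin", type = "gene",
      start = start(g), end = end(g), score = ".",
      strand = as.character(strand(g)), phase = ".",
      attributes = paste0("ID=", id))
    add <- function(gr, type) {
      if (is.null(gr) || !length(gr)) return(NULL)
      data.frame(seqid = as.character(seqnames(g)), source = "methylwin",
                 type = type, start = start(gr), end = end(gr), score = ".",
                 strand = as.character(strand(g)), phase = ".",
                 attributes = paste0("ID=", id, ":", type,
                                     seq_along(gr), ";Parent=", id))
    }
    rows[[length(rows) + 1L]] <- add(annotation@exons[[id]], "exon")
    if (id %in% names(annotation@utr5))
      rows[[length(rows) + 1L]] <- add(annotation@utr5[[id]], "five_prime_UTR")
    if (id %in% names(annotation@utr3))
      rows[[length(rows) + 1L]] <- add(annotation@utr3[[id]], "three_prime_UTR")
  }
  if (!is.null(tes) && length(tes)) {
    rows[[length(rows) + 1L]] <- data.frame(
      seqid = as.character(seqnames(tes)), source = "methylwin",
      type = "transposable_element", start = start(tes), end = end(tes),
      score = ".", strand = ".", phase = ".",
      attributes = paste0("ID=", mcols(tes)$te_id,
                          ";family=", mcols(tes)$family))
  }
  tab <- do.call(rbind, Filter(Negate(is.null), rows))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines("##gff-version 3", con)
  utils::write.table(tab, con, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  invisible(path)
}
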