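test_that("FASTA loading normalises case and rejects malformed input", {
  g <- fastaGenome(chr1 = "acgt")
  expect_equal(as.character(g[["chr1"]]), "ACGT")
  expect_equal(unname(width(g)), 4L)

  empty <- tempfile(fileext = ".fa")
  file.create(empty)
  expect_error(readGenomeFasta(empty))

  dup <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACGT", ">a", "GGCC"), dup)
  expect_error(readGenomeFasta(dup), "duplicate")

  badchar <- tempfile(fileext = ".fa")
  writeLines(c(">a", "ACXT"), badchar)
  expect_error(readGenomeFasta(badchar), "non-ACGTN|malformed")
})

test_that("context classification matches spec examples on both strands", {
  expect_equal(classifyContext(fastaGenome(c = "ACGT"), "c", 2, "+"), "CG")
  expect_equal(classifyContext(fastaGenome(c = "CAG"), "c", 1, "+"), "CHG")
  # minus-strand read of CCGG at its last base is C,C,G -> CHG
  expect_equal(classifyContext(fastaGenome(c = "CCGG"), "c", 4, "-"), "CHG")
  expect_equal(classifyContext(fastaGenome(c = "CCTA"), "c", 2, "+"), "CHH")
  # not a cytosine on the requested strand
  expect_error(classifyContext(fastaGenome(c = "ACGT"), "c", 1, "+"),
               "not C")
  # context undefined over N or chromosome edge
  expect_true(is.na(classifyContext(fastaGenome(c = "CN"), "c", 1, "+")))
  expect_true(is.na(classifyContext(fastaGenome(c = "AC"), "c", 2, "+")))
})

test_that("cytosine enumeration is complete, ordered and palindromic for CG", {
  g <- fastaGenome(c = "CG")
  cyt <- enumerateCytosines(g)
  expect_equal(length(cyt), 2L)
  expect_equal(start(cyt), c(1L, 2L))
  expect_equal(as.character(strand(cyt)), c("+", "-"))
  expect_equal(mcols(cyt)$context, c("CG", "CG"))

  expect_equal(length(enumerateCytosines(fastaGenome(c = "AAAA"))), 0L)
  expect_equal(length(enumerateCytosines(fastaGenome(c = "CN"))), 0L)

  # CG palindromy on a random N-free genome
  set.seed(7)
  seq <- paste(sample(c("A", "C", "G", "T"), 4000, TRUE), collapse = "")
  cyt <- enumerateCytosines(fastaGenome(chrX = seq))
  cg <- cyt[mcols(cyt)$context == "CG"]
  expect_equal(sum(strand(cg) == "+"), sum(strand(cg) == "-"))
  # each site emitted once
  expect_false(anyDuplicated(paste(start(cyt), strand(cyt))) > 0)
})

test_that("functional regions honour strand, clipping and UTR precedence", {
  # + strand gene body at 0-based [5000, 8000), 2 kb promoter -> [3000, 5000)
  sl <- c(chr1 = 20000L)
  mkAnn <- function(start, end, strand, u5 = GRanges(), u3 = GRanges()) {
    body <- GRanges("chr1", IRanges(start, end), strand = strand,
                    seqlengths = sl)
    mcols(body)$gene_id <- "g1"
    ex <- GRangesList(g1 = GRanges("chr1", IRanges(start, end),
                                   strand = strand))
    u5l <- if (length(u5)) GRangesList(g1 = u5) else GRangesList()
    u3l <- if (length(u3)) GRangesList(g1 = u3) else GRangesList()
    new("GeneAnnotation", genes = body, exons = ex, utr5 = u5l, utr3 = u3l)
  }
  fr <- functionalRegions(mkAnn(5001, 8000, "+"), promoterLen = 2000)
  prom <- fr[mcols(fr)$label == "promoter"]
  expect_equal(c(start(prom) - 1L, end(prom)), c(3000L, 5000L))

  fr <- functionalRegions(mkAnn(5001, 8000, "-"), promoterLen = 2000)
  prom <- fr[mcols(fr)$label == "promoter"]
  expect_equal(c(start(prom) - 1L, end(prom)), c(8000L, 10000L))

  # promoter clipped at the chromosome start (TSS at 0-based 500)
  fr <- functionalRegions(mkAnn(501, 2000, "+"), promoterLen = 2000)
  prom <- fr[mcols(fr)$label == "promoter"]
  expect_equal(c(start(prom) - 1L, end(prom)), c(0L, 500L))

  # a position in both UTR and exon is labelled UTR only
  ann <- mkAnn(1001, 2000, "+",
               u5 = GRanges("chr1", IRanges(1001, 1100), strand = "+"))
  fr <- functionalRegions(ann, promoterLen = 500)
  utr <- fr[mcols(fr)$label == "UTR"]
  exon <- fr[mcols(fr)$label == "exon"]
  expect_equal(start(utr), 1001L)
  expect_equal(end(utr), 1100L)
  expect_equal(start(exon), 1101L)  # exon excludes the UTR bases
  # labels tile promoter + body without overlap
  expect_equal(sum(width(fr)), 500L + 1000L)
  expect_equal(length(reduce(fr, ignore.strand = TRUE)),
               length(reduce(c(granges(fr[1]), granges(fr)),
                             ignore.strand = TRUE)))
  ov <- findOverlaps(fr, fr, ignore.strand = TRUE)
  expect_equal(length(ov), length(fr))  # only self-overlaps
})

test_that("gene annotation round-trips through GFF3", {
  cfg <- simConfig(seed = 3, nChrom = 1L, chromLen = 60000L,
                   geneDensity = 100, teDensity = 60)
  w <- simulateGenome(cfg)
  gff <- tempfile(fileext = ".gff3")
  writeGeneAnnotation(w$genes, gff, tes = w$tes)
  back <- readGeneAnnotation(gff)
  expect_equal(mcols(back@genes)$gene_id, mcols(w$genes@genes)$gene_id)
  expect_equal(start(back@genes), start(w$genes@genes))
  expect_equal(as.character(strand(back@genes)),
               as.character(strand(w$genes@genes)))
  id <- mcols(w$genes@genes)$gene_id[1]
  expect_equal(start(back@exons[[id]]), start(w$genes@exons[[id]]))
  tes <- readTeAnnotation(gff)
  expect_equal(length(tes), length(w$tes))
  expect_equal(mcols(tes)$family, mcols(w$tes)$family)
})
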