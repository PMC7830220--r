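suppressPackageStartupMessages({
  library(GenomicRanges)
  library(IRanges)
  library(S4Vectors)
  library(Biostrings)
})

# write a one-record FASTA and load it
fastaGenome <- function(...) {
  seqs <- c(...)
  fa <- tempfile(fileext = ".fa")
  writeLines(unlist(lapply(seq_along(seqs), function(i)
    c(paste0(">", names(seqs)[i]), seqs[i]))), fa)
  readGenomeFasta(fa)
}

# MethylomeTrack from a compact data.frame(chrom, pos, strand, context, m, t)
makeTrack <- function(df, sampleId = "s", seqlengths = NULL) {
  MethylomeTrack(df$chrom, df$pos, df$strand, df$context, df$m, df$t,
                 sampleId = sampleId, seqlengths = seqlengths)
}

# independent two-sided Fisher oracle: explicit hypergeometric enumeration
# with choose(); sums outcomes no more probable than the observed table
fisherOracle <- function(a, b, c, d) {
  n1 <- a + b; n2 <- c + d; K <- a + c; N <- n1 + n2
  if (N == 0) return(1)
  xs <- max(0, K - n2):min(K, n1)
  pm <- choose(n1, xs) * choose(n2, K - xs) / choose(N, K)
  obs <- pm[xs == a]
  min(1, sum(pm[pm <= obs * (1 + 1e-7)]))
}

# definitional BH step-up oracle
bhOracle <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  pmin(1, adj)[order(o)]
}

# brute-force trinucleotide context table, plus strand orientation
contextOracle <- function(tri) {
  b <- strsplit(tri, "")[[1]]
  if (b[1] != "C") return(NA_character_)
  if (b[2] == "G") return("CG")
  if (!b[2] %in% c("A", "C", "T")) return(NA_character_)
  if (b[3] == "G") return("CHG")
  if (b[3] %in% c("A", "C", "T")) return("CHH")
  NA_character_
}

revcomp <- function(s) {
  as.character(Biostrings::reverseComplement(Biostrings::DNAString(s)))
}
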