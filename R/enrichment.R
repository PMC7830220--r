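#' Hypergeometric upper tail
#'
#' Over-representation probability `P(X >= k)` for drawing `k` annotated
#' genes in a list of `n` from a universe of `N` genes of which `K` carry
#' the annotation (via [stats::phyper()]).
#'
#' @param N Universe size.
#' @param K Annotated genes in the universe.
#' @param n List size.
#' @param k Annotated genes in the list.
#' @return p-value in (0, 1].
#' @export
hypergeomUpperTail <- function(N, K, n, k) {
  if (any(K < 0 | K > N) || any(n < 0 | n > N) ||
      any(k < 0 | k > pmin(K, n)))
    stop("need 0 <= K <= N, 0 <= n <= N, 0 <= k <= min(K, n)")
  stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
}

#' Term over-representation test for a gene list
#'
#' One hypergeometric test per term having at least one annotated gene in
#' the universe and at least one in the list, Benjamini-Hochberg adjusted
#' across all tested terms; terms with FDR below `fdrMax` are flagged
#' significant.  Results are sorted by FDR and invariant to gene-list
#' ordering.
#'
#' @param geneList Character vector of gene ids (must lie in `universe`).
#' @param annotations `data.frame` with columns `gene_id`, `term_id` and
#'   optionally `term_name`.
#' @param universe Character vector: the background gene universe.
#' @param fdrMax Significance threshold on the FDR (default 0.01).
#' @return A `data.frame`: `term_id`, `term_name`, `bgCount` (K),
#'   `listCount` (k), `universeSize` (N), `listSize` (n), `p`, `fdr`,
#'   `significant`.
#' @export
enrichTerms <- function(geneList, annotations, universe, fdrMax = 0.01) {
  universe <- unique(universe)
  if (!length(universe)) stop("empty background universe")
  geneList <- unique(geneList)
  if (!all(geneList %in% universe))
    stop("gene list contains ids outside the universe")
  ann <- annotations[annotations$gene_id %in% universe, , drop = FALSE]
  ann <- unique(ann[, intersect(c("gene_id", "term_id"), names(ann))])
  nameMap <- NULL
  if ("term_name" %in% names(annotations))
    nameMap <- unique(annotations[, c("term_id", "term_name")])
  N <- length(universe); n <- length(geneList)
  terms <- split(ann$gene_id, ann$term_id)
  rows <- lapply(names(terms), function(tid) {
    genes <- unique(terms[[tid]])
    K <- length(genes)
    k <- sum(geneList %in% genes)
    if (K < 1L || k < 1L) return(NULL)
    data.frame(term_id = tid, bgCount = K, listCount = k,
               universeSize = N, listSize = n,
               p = hypergeomUpperTail(N, K, n, k))
  })
  rows <- Filter(Negate(is.null), rows)
  if (!length(rows)) {
    return(data.frame(term_id = character(), term_name = character(),
                      bgCount = integer(), listCount = integer(),
                      universeSize = integer(), listSize = integer(),
                      p = numeric(), fdr = numeric(),
                      significant = logical()))
  }
  out <- do.call(rbind, rows)
  out$fdr <- bhAdjust(out$p)
  out$significant <- out$fdr < fdrMax
  out$term_name <- if (!is.null(nameMap))
    nameMap$term_name[match(out$term_id, nameMap$term_id)]
  else NA_character_
  out <- out[order(out$fdr, out$p, out$term_id),
             c("term_id", "term_name", "bgCount", "listCount",
               "universeSize", "listSize", "p", "fdr", "significant")]
  rownames(out) <- NULL
  out
}

#' Read gene-to-term annotations
#'
#' Tab-separated file with columns gene id, term id and optionally a term
#' name.
#'
#' @param path TSV path.
#' @return `data.frame` with `gene_id`, `term_id` (and `term_name`).
#' @export
readTermAnnotations <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = FALSE,
                           colClasses = "character", quote = "",
                           comment.char = "#")
  names(tab) <- c("gene_id", "term_id", "term_name")[seq_len(ncol(tab))]
  tab
}
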