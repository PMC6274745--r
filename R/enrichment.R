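#' Hypergeometric over-representation test of a gene list
#'
#' For each term, the upper-tail hypergeometric probability of drawing at
#' least k annotated genes in a sample of n from a universe of N
#' containing K annotated genes: p = P(X >= k). P-values are BH-adjusted
#' within each ontology source; significance follows the dual regime of
#' the study design: GO sources at adjusted p <= `go_fdr`, pathway source
#' at raw p < `pathway_p`.
#'
#' @param input Character vector of genes of interest (must be a subset
#'   of `universe`).
#' @param universe Character vector of all eligible genes (e.g. every
#'   gene retained by the expression filter).
#' @param terms A data.frame with columns `term_id`, `term_name`,
#'   `source` (one of `GO_BP`, `GO_CC`, `GO_MF`, `PATHWAY`) and `gene_id`
#'   (one row per term-gene link).
#' @param go_fdr Adjusted-p threshold for GO sources (default 0.05,
#'   inclusive).
#' @param pathway_p Raw-p threshold for the pathway source (default 0.05,
#'   strict).
#' @return A data.frame `term_id`, `term_name`, `source`, `k`, `K`, `n`,
#'   `N`, `p`, `p_fdr`, `significant`, sorted by source then p. Terms
#'   with `k = 0` or `K = 0` carry `p = 1` and are never significant.
#' @examples
#' terms <- data.frame(term_id = "T1", term_name = "toy", source = "GO_BP",
#'                     gene_id = c("g1", "g2", "g3"))
#' hypergeom_enrich(c("g1", "g2", "g4", "g5"), paste0("g", 1:10), terms)
#' @export
hypergeom_enrich <- function(input, universe, terms, go_fdr = 0.05,
                             pathway_p = 0.05) {
  input <- unique(input); universe <- unique(universe)
  offenders <- setdiff(input, universe)
  if (length(offenders))
    stop("input genes absent from the universe: ",
         paste(offenders, collapse = ", "))
  if (!nrow(terms)) stop("no terms supplied")
  terms <- terms[terms$gene_id %in% universe, , drop = FALSE]
  N <- length(universe); n <- length(input)
  by_term <- split(terms$gene_id, terms$term_id)
  meta <- terms[!duplicated(terms$term_id),
                c("term_id", "term_name", "source")]
  rownames(meta) <- meta$term_id
  rows <- lapply(names(by_term), function(tid) {
    genes <- unique(by_term[[tid]])
    K <- length(genes)
    k <- length(intersect(genes, input))
    p <- if (k == 0L || K == 0L) 1
         else stats::phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.frame(term_id = tid, term_name = meta[tid, "term_name"],
               source = meta[tid, "source"], k = k, K = K, n = n, N = N,
               p = p, stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  res$p_fdr <- NA_real_
  for (src in unique(res$source)) {
    i <- res$source == src
    res$p_fdr[i] <- bh_adjust(res$p[i])
  }
  is_go <- res$source %in% c("GO_BP", "GO_CC", "GO_MF")
  res$significant <- res$k > 0 &
    ((is_go & res$p_fdr <= go_fdr) |
       (res$source == "PATHWAY" & res$p < pathway_p))
  res <- res[order(res$source, res$p, res$term_id), ]
  rownames(res) <- NULL
  res
}
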