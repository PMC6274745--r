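#' Protein-coding genes within a window of a lncRNA locus
#'
#' Returns every coding gene whose span lies within or overlaps the
#' interval \[lncRNA start - window, lncRNA end + window\] on the same
#' chromosome; the boundary is inclusive at exactly `window` bp.
#'
#' @param lncrna A [transcript_model()].
#' @param coding An [annotation_set()] of protein-coding genes.
#' @param window Window size in bp on each side (default 50000).
#' @return A data.frame `gene_id`, `chrom`, `gene_start`, `gene_end`,
#'   `distance` (minimal span gap, 0 when overlapping).
#' @export
window_candidates <- function(lncrna, coding, window = 50000) {
  gs <- gene_spans(coding)
  gs <- gs[gs$chrom == lncrna$chrom, , drop = FALSE]
  if (!nrow(gs))
    return(data.frame(gene_id = character(0), chrom = character(0),
                      gene_start = numeric(0), gene_end = numeric(0),
                      distance = numeric(0)))
  d <- vapply(seq_len(nrow(gs)), function(i)
    span_gap(tx_start(lncrna), tx_end(lncrna), gs$start[i], gs$end[i]),
    numeric(1))
  keep <- d <= window
  data.frame(gene_id = gs$gene[keep], chrom = gs$chrom[keep],
             gene_start = gs$start[keep], gene_end = gs$end[keep],
             distance = d[keep], stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Pearson correlation with a t-based p-value
#'
#' Sample Pearson r plus the two-sided p-value from
#' t = r sqrt(n-2) / sqrt(1 - r^2) against Student's t with n - 2 degrees
#' of freedom. With the study design of 18 libraries per treatment, the
#' printed correlations of the cis-target tables reproduce their printed
#' p-values through exactly this transform.
#'
#' @param x,y Numeric vectors of equal length n >= 3.
#' @return A list `(r, p, n)`. Constant input yields `r = NA`, `p = NA`
#'   with a warning (such pairs are excluded from cis calling).
#' @examples
#' # r = 0.821379 at n = 18 gives p = 2.93e-5
#' @export
pearson_with_p <- function(x, y) {
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3L) stop("need n >= 3")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant vector: correlation undefined")
    return(list(r = NA_real_, p = NA_real_, n = n))
  }
  r <- stats::cor(x, y)
  r2 <- min(r^2, 1)
  if (r2 >= 1) return(list(r = r, p = 0, n = n))
  t <- r * sqrt(n - 2) / sqrt(1 - r2)
  list(r = r, p = 2 * stats::pt(-abs(t), df = n - 2), n = n)
}

## p-value from a known r and n (used when only r is available)
pearson_p_from_r <- function(r, n) {
  t <- r * sqrt(n - 2) / sqrt(1 - r^2)
  2 * stats::pt(-abs(t), df = n - 2)
}

#' Call cis target genes of lncRNAs
#'
#' A coding gene is called a potential cis target of a lncRNA when its
#' span lies within `window` bp of the lncRNA locus and the Pearson
#' correlation of their expression across the treatment's libraries
#' strictly exceeds `r_cutoff`. Expression is log2(normalized count + 1)
#' by default (`scale = "log2norm"`); `scale = "norm"` correlates
#' normalized counts directly. Correlations are computed separately per
#' treatment.
#'
#' @param lncrnas [annotation_set()] of lncRNAs (or a subset of ids via
#'   `lncrna_ids`).
#' @param coding [annotation_set()] of protein-coding genes.
#' @param counts `count_matrix` or matrix holding both lncRNA and gene
#'   features.
#' @param design Library design data.frame (`library_id`, `treatment`).
#' @param lncrna_ids Optional subset of lncRNA transcript ids (e.g. the
#'   DE set for the DE-restricted report).
#' @param window Window in bp (default 50000, inclusive boundary).
#' @param r_cutoff Correlation threshold (default 0.7, strict).
#' @param scale `"log2norm"` (default) or `"norm"`.
#' @param factors Optional precomputed size factors.
#' @return A data.frame `treatment`, `lncrna_id`, `gene_id`, `r`, `p`,
#'   `distance`, `chrom`, `gene_start`, `gene_end` of called pairs.
#' @export
call_cis_pairs <- function(lncrnas, coding, counts, design,
                           lncrna_ids = NULL, window = 50000,
                           r_cutoff = 0.7, scale = c("log2norm", "norm"),
                           factors = NULL) {
  scale <- match.arg(scale)
  m <- as_counts(counts)
  if (is.null(factors)) factors <- size_factors(m)
  norm <- normalized_counts(m, factors)
  expr <- if (scale == "log2norm") log2(norm + 1) else norm
  if (is.null(lncrna_ids)) lncrna_ids <- names(lncrnas$transcripts)
  lncrna_ids <- intersect(lncrna_ids, rownames(expr))
  ## gene expression: sum transcript counts per gene before normalization
  ## is upstream's concern; here rows are assumed to be one per feature id
  out <- list()
  for (tr in unique(design$treatment)) {
    libs <- design$library_id[design$treatment == tr]
    for (lid in lncrna_ids) {
      cand <- window_candidates(lncrnas$transcripts[[lid]], coding, window)
      for (i in seq_len(nrow(cand))) {
        gid <- cand$gene_id[i]
        if (!gid %in% rownames(expr)) next
        x <- expr[lid, libs]; y <- expr[gid, libs]
        if (stats::sd(x) == 0 || stats::sd(y) == 0) next
        cp <- pearson_with_p(x, y)
        if (!is.na(cp$r) && cp$r > r_cutoff) {
          out[[length(out) + 1L]] <- data.frame(
            treatment = tr, lncrna_id = lid, gene_id = gid,
            r = cp$r, p = cp$p, distance = cand$distance[i],
            chrom = cand$chrom[i], gene_start = cand$gene_start[i],
            gene_end = cand$gene_end[i], stringsAsFactors = FALSE
          )
        }
      }
    }
  }
  if (!length(out))
    return(data.frame(treatment = character(0), lncrna_id = character(0),
                      gene_id = character(0), r = numeric(0),
                      p = numeric(0), distance = numeric(0),
                      chrom = character(0), gene_start = numeric(0),
                      gene_end = numeric(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
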