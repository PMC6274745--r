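#' Construct a count matrix container
#'
#' @param counts Integer matrix, features x libraries, with dimnames.
#' @param lengths Named numeric vector of feature lengths (nt).
#' @return An object of class `count_matrix` (list with `counts`,
#'   `lengths`).
#' @export
count_matrix <- function(counts, lengths) {
  counts <- as.matrix(counts)
  if (is.null(rownames(counts)) || is.null(colnames(counts)))
    stop("counts must carry feature and library names")
  if (any(counts < 0)) stop("negative counts")
  lengths <- lengths[rownames(counts)]
  if (anyNA(lengths) || any(lengths <= 0))
    stop("every feature needs a positive length")
  structure(list(counts = counts, lengths = lengths),
            class = "count_matrix")
}

as_counts <- function(x) if (inherits(x, "count_matrix")) x$counts else as.matrix(x)

#' Median-of-ratios size factors
#'
#' The DESeq-style normalization constant per library: each feature's
#' geometric mean across libraries forms a pseudo-reference (features with
#' any zero count are excluded), and a library's factor is the median of
#' its count-to-reference ratios.
#'
#' @param counts A `count_matrix` or plain matrix (features x libraries).
#' @return Named numeric vector of positive size factors.
#' @examples
#' m <- matrix(c(10, 20, 40, 20, 40, 80), ncol = 2,
#'             dimnames = list(paste0("f", 1:3), c("A", "B")))
#' size_factors(m)  # (1/sqrt(2), sqrt(2))
#' @export
size_factors <- function(counts) {
  m <- as_counts(counts)
  nonzero <- rowSums(m == 0) == 0L
  if (!any(nonzero))
    stop("no feature has nonzero counts in every library; ",
         "filter low-count features before normalization")
  mm <- m[nonzero, , drop = FALSE]
  geo <- exp(rowMeans(log(mm)))
  apply(mm, 2L, function(col) stats::median(col / geo))
}

#' Normalized counts
#'
#' @param counts A `count_matrix` or matrix.
#' @param factors Size factors from [size_factors()].
#' @return Matrix of counts divided by their library's factor.
#' @export
normalized_counts <- function(counts, factors) {
  m <- as_counts(counts)
  sweep(m, 2L, unname(factors[colnames(m)]), "/")
}

#' Truly-expressed feature filter
#'
#' A feature is retained when its normalized count reaches `min_count` in
#' at least `ceiling(min_frac * n_libraries)` libraries (with 36 libraries
#' and the default 10%, that is 4 libraries).
#'
#' @param counts A `count_matrix` or matrix.
#' @param factors Size factors.
#' @param min_count Normalized-count threshold (default 5).
#' @param min_frac Minimum fraction of libraries (default 0.10).
#' @return Character vector of retained feature ids.
#' @export
expressed_filter <- function(counts, factors, min_count = 5,
                             min_frac = 0.10) {
  norm <- normalized_counts(counts, factors)
  need <- ceiling(min_frac * ncol(norm))
  keep <- rowSums(norm >= min_count) >= need
  rownames(norm)[keep]
}

#' FPKM expression values
#'
#' FPKM_ij = count_ij * 1e9 / (N_j * L_i), with N_j the total counted
#' fragments of library j (the column sum) and L_i the feature length in
#' nt.
#'
#' @param counts A `count_matrix` (lengths required) or matrix plus
#'   `lengths`.
#' @param lengths Named feature lengths, when `counts` is a plain matrix.
#' @return A list: `fpkm` (matrix) and `mean_fpkm` (per-feature mean over
#'   libraries).
#' @export
fpkm <- function(counts, lengths = NULL) {
  m <- as_counts(counts)
  if (is.null(lengths)) {
    if (!inherits(counts, "count_matrix"))
      stop("feature lengths required")
    lengths <- counts$lengths
  }
  lengths <- lengths[rownames(m)]
  N <- colSums(m)
  if (any(N == 0)) stop("library with zero total count")
  f <- sweep(sweep(m, 2L, N, "/"), 1L, lengths, "/") * 1e9
  list(fpkm = f, mean_fpkm = rowMeans(f))
}

#' Descriptive expression summaries
#'
#' Reproduces the descriptive reporting of the discovery stage: the top-k
#' most expressed lncRNAs per known/novel status (mean FPKM, ties broken
#' by id, lexicographically), the transcript-length histogram in the bins
#' 200--999, 1000--2499 and >= 2500 nt, the transcripts-per-gene
#' distribution and per-chromosome counts.
#'
#' @param mean_fpkm Named per-feature mean FPKM.
#' @param status Named character vector (`"known"`/`"novel"`).
#' @param lengths Named feature lengths (nt).
#' @param gene_of Named transcript-to-gene map.
#' @param chrom Named transcript-to-chromosome map.
#' @param top_k How many top features per status (default 15).
#' @return A list of data.frames: `top_expressed`, `length_hist`,
#'   `transcripts_per_gene`, `per_chromosome`.
#' @export
summarize_expression <- function(mean_fpkm, status, lengths, gene_of,
                                 chrom, top_k = 15L) {
  ids <- names(mean_fpkm)
  top <- do.call(rbind, lapply(c("known", "novel"), function(st) {
    sub <- ids[status[ids] == st]
    sub <- sub[order(-mean_fpkm[sub], sub)]
    head_ids <- utils::head(sub, top_k)
    if (!length(head_ids)) return(NULL)
    data.frame(status = st, transcript_id = head_ids,
               mean_fpkm = unname(mean_fpkm[head_ids]),
               stringsAsFactors = FALSE)
  }))
  len <- lengths[ids]
  bin <- cut(len, breaks = c(200, 1000, 2500, Inf), right = FALSE,
             labels = c("200-999", "1000-2499", ">=2500"))
  hist <- as.data.frame(table(bin), stringsAsFactors = FALSE)
  names(hist) <- c("bin", "n")
  hist$pct <- round(100 * hist$n / max(1L, length(ids)), 2)
  tpg <- table(table(gene_of[ids]))
  tpg <- data.frame(n_transcripts = as.integer(names(tpg)),
                    n_genes = as.integer(tpg))
  tpg$pct <- round(100 * tpg$n_genes / max(1L, sum(tpg$n_genes)), 2)
  pc <- as.data.frame(table(chrom[ids]), stringsAsFactors = FALSE)
  names(pc) <- c("chrom", "n")
  list(top_expressed = top, length_hist = hist,
       transcripts_per_gene = tpg, per_chromosome = pc)
}
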