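## Fickett TESTCODE lookup tables (classic 1982 parameterization): for each
## base, a position-asymmetry parameter and a composition parameter are
## mapped through interval lookup tables to probabilities, combined with
## per-base weights. Interval vectors give lower bounds, most stringent
## first; a parameter falls in the first interval whose bound it meets.
FICKETT_POSITION_PARA <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
FICKETT_POSITION_PROB <- list(
  A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
  C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
  G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
  T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09)
)
FICKETT_POSITION_WEIGHT <- c(A = 0.26, C = 0.18, G = 0.31, T = 0.33)
FICKETT_CONTENT_PARA <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19,
                          0.17, 0.0)
FICKETT_CONTENT_PROB <- list(
  A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
  C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
  G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
  T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58)
)
FICKETT_CONTENT_WEIGHT <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)

check_nucleotides <- function(seq) {
  if (!is.character(seq) || length(seq) != 1L)
    stop("sequence must be a single character string")
  if (grepl("[^ACGT]", seq))
    stop("sequence contains characters outside A/C/G/T")
  invisible(seq)
}

#' Find the longest open reading frame
#'
#' Scans the sense strand in all three frames for the longest ATG-to-stop
#' (TAA/TAG/TGA) open reading frame; the stop codon counts toward the
#' length. With `both_strands = TRUE` the reverse complement is scanned as
#' well and the longer ORF wins (coordinates then refer to the strand on
#' which it was found).
#'
#' @param seq Nucleotide string over A/C/G/T.
#' @param both_strands Also scan the reverse complement (default `FALSE`;
#'   assemblies are stranded).
#' @return A list `(start, end, length)` in 1-based inclusive coordinates,
#'   or `(0, 0, 0)` when no complete ORF exists.
#' @examples
#' find_longest_orf("ATGAAATAA")$length  # 9
#' @export
find_longest_orf <- function(seq, both_strands = FALSE) {
  check_nucleotides(seq)
  scan1 <- function(s) {
    n <- nchar(s)
    codons_at <- function(from) {
      if (n - from + 1L < 3L) return(character(0))
      starts <- seq(from, n - 2L, by = 3L)
      substring(s, starts, starts + 2L)
    }
    best <- list(start = 0, end = 0, length = 0)
    for (frame in 1:3) {
      cds <- codons_at(frame)
      if (!length(cds)) next
      open_at <- NA_integer_
      for (i in seq_along(cds)) {
        if (is.na(open_at) && cds[i] == "ATG") open_at <- i
        if (!is.na(open_at) && cds[i] %in% c("TAA", "TAG", "TGA")) {
          len <- (i - open_at + 1L) * 3L
          if (len > best$length)
            best <- list(start = frame + (open_at - 1L) * 3L,
                         end = frame + i * 3L - 1L, length = len)
          open_at <- NA_integer_
        }
      }
    }
    best
  }
  best <- scan1(seq)
  if (both_strands) {
    rc <- chartr("ACGT", "TGCA", paste(rev(strsplit(seq, "")[[1]]),
                                       collapse = ""))
    alt <- scan1(rc)
    if (alt$length > best$length) best <- alt
  }
  best
}

fickett_lookup <- function(value, para, prob) {
  prob[which(value >= para)[1L]]
}

#' Fickett TESTCODE statistic
#'
#' The classic TESTCODE measure of coding character: for each base the
#' position parameter max(frame counts)/(min(frame counts)+1) and the
#' composition parameter (base fraction) are mapped through the published
#' lookup tables to probabilities and combined with the published weights.
#' Scores around 0.95 and above indicate coding character in the original
#' formulation; here the raw statistic is used as one feature of the
#' logistic coding-potential model.
#'
#' @param seq Nucleotide string over A/C/G/T; sequences shorter than 200 nt
#'   are scored with a warning (the statistic was designed for >= 200 nt).
#' @return The TESTCODE score (real, roughly 0.2--1.7).
#' @export
fickett_score <- function(seq) {
  check_nucleotides(seq)
  n <- nchar(seq)
  if (n == 0L) stop("empty sequence")
  if (n < 200L) warning("fickett_score on a sequence shorter than 200 nt")
  bases <- strsplit(seq, "")[[1]]
  frame <- rep_len(1:3, n)
  score <- 0
  for (b in c("A", "C", "G", "T")) {
    counts <- vapply(1:3, function(f) sum(bases == b & frame == f),
                     numeric(1))
    pos_par <- max(counts) / (min(counts) + 1)
    comp_par <- sum(counts) / n
    score <- score +
      fickett_lookup(pos_par, FICKETT_POSITION_PARA,
                     FICKETT_POSITION_PROB[[b]]) *
        FICKETT_POSITION_WEIGHT[[b]] +
      fickett_lookup(comp_par, FICKETT_CONTENT_PARA,
                     FICKETT_CONTENT_PROB[[b]]) *
        FICKETT_CONTENT_WEIGHT[[b]]
  }
  score
}

all_hexamers <- function() {
  b <- c("A", "C", "G", "T")
  g <- expand.grid(b, b, b, b, b, b, stringsAsFactors = FALSE)
  ## first factor varies slowest so that names sort lexicographically
  apply(g[, 6:1], 1L, paste, collapse = "")
}

#' Build smoothed hexamer frequency tables from training sequences
#'
#' Counts in-frame hexamers (step 3 from position 1) over each training
#' set, adds a pseudocount of 1 to every one of the 4096 hexamers, and
#' normalizes to frequencies.
#'
#' @param coding_seqs,noncoding_seqs Character vectors of A/C/G/T
#'   sequences.
#' @return A list with named numeric vectors `coding` and `noncoding`
#'   (each of length 4096, summing to 1).
#' @export
build_hexamer_tables <- function(coding_seqs, noncoding_seqs) {
  hx <- sort(all_hexamers())
  count_set <- function(seqs) {
    counts <- stats::setNames(rep(1, length(hx)), hx)  # pseudocount 1
    for (s in seqs) {
      n <- nchar(s)
      if (n < 6L) next
      starts <- seq(1L, n - 5L, by = 3L)
      tab <- table(substring(s, starts, starts + 5L))
      counts[names(tab)] <- counts[names(tab)] + as.numeric(tab)
    }
    counts / sum(counts)
  }
  list(coding = count_set(coding_seqs),
       noncoding = count_set(noncoding_seqs))
}

#' Hexamer usage bias score
#'
#' Mean log-likelihood ratio, over in-frame sliding hexamers (step 3,
#' starting at position 1), of coding versus non-coding hexamer
#' frequencies. Natural log; positive values favour the coding model.
#'
#' @param seq Nucleotide string over A/C/G/T, length >= 6.
#' @param coding_table,noncoding_table Named frequency vectors covering all
#'   4096 hexamers (see [build_hexamer_tables()]).
#' @return Mean per-hexamer log ratio (real).
#' @export
hexamer_score <- function(seq, coding_table, noncoding_table) {
  check_nucleotides(seq)
  n <- nchar(seq)
  if (n < 6L) stop("sequence shorter than 6 nt")
  starts <- seq(1L, n - 5L, by = 3L)
  hx <- substring(seq, starts, starts + 5L)
  mean(log(coding_table[hx] / noncoding_table[hx]))
}

#' Extract the coding-feature vector of a sequence
#'
#' @param seq Nucleotide string.
#' @param hex_tables Output of [build_hexamer_tables()].
#' @param both_strands Passed to [find_longest_orf()].
#' @return A one-row data.frame: `orf_length`, `orf_coverage`, `fickett`,
#'   `hexamer`.
#' @export
coding_features <- function(seq, hex_tables, both_strands = FALSE) {
  orf <- find_longest_orf(seq, both_strands = both_strands)
  data.frame(
    orf_length = orf$length,
    orf_coverage = orf$length / nchar(seq),
    fickett = suppressWarnings(fickett_score(seq)),
    hexamer = hexamer_score(seq, hex_tables$coding, hex_tables$noncoding)
  )
}

#' Train the logistic coding-potential model and classify candidates
#'
#' Fits a logistic regression of coding status on the four standardized
#' features (ORF length, ORF coverage, TESTCODE score, hexamer bias) of the
#' labelled training sequences, then scores each candidate sequence. A
#' candidate with coding probability at or above `cutoff` is labelled
#' `coding` (and is removed from the lncRNA pipeline); probabilities below
#' the cutoff are `noncoding`.
#'
#' Externally computed probabilities can be substituted for the internal
#' model via `external_prob`, keeping the classifier stage pluggable.
#'
#' @param train_seqs Named character vector of training sequences.
#' @param train_labels Character vector (`"coding"`/`"noncoding"`) aligned
#'   with `train_seqs`; at least 50 of each class.
#' @param candidate_seqs Named character vector of sequences to classify.
#' @param cutoff Coding-probability cutoff (default 0.4); the boundary
#'   value itself counts as coding.
#' @param hex_tables Optional pre-built hexamer tables; by default they are
#'   built from the training sequences themselves.
#' @param both_strands Passed to [find_longest_orf()].
#' @param external_prob Optional named numeric vector of probabilities for
#'   the candidates, bypassing feature extraction and the internal model.
#' @return A data.frame with `transcript_id`, the four features (NA when
#'   `external_prob` is used), `probability` and `label`; the fitted model
#'   and feature scaling are attached as attributes `model` and `scaling`.
#' @export
train_and_classify <- function(train_seqs, train_labels, candidate_seqs,
                               cutoff = 0.4, hex_tables = NULL,
                               both_strands = FALSE,
                               external_prob = NULL) {
  if (!is.null(external_prob)) {
    ids <- names(candidate_seqs)
    prob <- unname(external_prob[ids])
    if (anyNA(prob)) stop("external_prob missing for some candidates")
    return(data.frame(
      transcript_id = ids, orf_length = NA_real_, orf_coverage = NA_real_,
      fickett = NA_real_, hexamer = NA_real_, probability = prob,
      label = ifelse(prob >= cutoff, "coding", "noncoding"),
      stringsAsFactors = FALSE, row.names = NULL
    ))
  }
  tab <- table(factor(train_labels, levels = c("coding", "noncoding")))
  if (any(tab < 50))
    stop("need >= 50 training sequences of each class (got ",
         paste(tab, collapse = "/"), ")")
  if (is.null(hex_tables))
    hex_tables <- build_hexamer_tables(train_seqs[train_labels == "coding"],
                                       train_seqs[train_labels == "noncoding"])
  feat <- function(seqs)
    do.call(rbind, lapply(seqs, coding_features, hex_tables = hex_tables,
                          both_strands = both_strands))
  tr <- feat(train_seqs)
  mu <- colMeans(tr); sd <- apply(tr, 2L, stats::sd)
  sd[sd == 0] <- 1
  std <- function(x) sweep(sweep(as.matrix(x), 2L, mu), 2L, sd, "/")
  dtr <- as.data.frame(std(tr))
  dtr$y <- as.integer(train_labels == "coding")
  ## well-separated training sets can separate perfectly; the fitted
  ## probabilities are still valid for thresholding, so silence glm's
  ## separation warnings
  fit <- suppressWarnings(
    stats::glm(y ~ orf_length + orf_coverage + fickett + hexamer,
               family = stats::binomial(), data = dtr))
  ca <- feat(candidate_seqs)
  prob <- as.numeric(stats::predict(fit, newdata = as.data.frame(std(ca)),
                                    type = "response"))
  out <- data.frame(
    transcript_id = names(candidate_seqs), ca,
    probability = prob,
    label = ifelse(prob >= cutoff, "coding", "noncoding"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  attr(out, "model") <- fit
  attr(out, "scaling") <- list(center = mu, scale = sd)
  out
}

#' Drop candidates present in an exclusion list
#'
#' Consumes the output of an external protein-similarity search (e.g. a
#' Swiss-prot hit list at e-value < 1e-5): candidates on the list are
#' removed by set difference.
#'
#' @param candidates Character vector of candidate ids.
#' @param exclusions Character vector of ids to drop.
#' @return Retained ids, in input order.
#' @export
apply_exclusion_list <- function(candidates, exclusions) {
  retained <- setdiff(candidates, exclusions)
  if (!length(retained) && length(candidates))
    warning("every candidate was excluded")
  retained
}
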