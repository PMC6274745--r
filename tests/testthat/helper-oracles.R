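# Independent reference implementations used as oracles. Each is written
# straight from the definitions, favouring clarity over speed, and is
# deliberately separate from the package's code paths.

# --- random transcript models for fuzzing -------------------------------
random_tx <- function(id, chrom = sample(c("chr1", "chr2"), 1),
                      strand = sample(c("+", "-"), 1),
                      max_pos = 6000) {
  n_ex <- sample(1:4, 1)
  start <- sample(0:max_pos, 1)
  exons <- matrix(NA_real_, n_ex, 2)
  pos <- start
  for (i in seq_len(n_ex)) {
    w <- sample(50:300, 1)
    exons[i, ] <- c(pos, pos + w)
    pos <- pos + w + sample(50:500, 1)
  }
  transcript_model(id, chrom, strand, exons)
}

# --- class-code oracle: test every predicate explicitly, then apply the
# precedence = > c > j > o > x > i > u over all reference transcripts ----
oracle_pair_codes <- function(q, r) {
  if (q$chrom != r$chrom) return(character(0))
  same <- q$strand == r$strand
  qex <- q$exons; rex <- r$exons
  qn <- nrow(qex); rn <- nrow(rex)
  intr <- function(ex) if (nrow(ex) < 2) matrix(numeric(0), ncol = 2)
    else cbind(ex[-nrow(ex), 2], ex[-1, 1])
  qi <- intr(qex); ri <- intr(rex)
  chain_str <- function(ii) paste(t(ii), collapse = ",")
  ov <- FALSE
  for (a in seq_len(qn)) for (b in seq_len(rn))
    if (qex[a, 1] < rex[b, 2] && rex[b, 1] < qex[a, 2]) ov <- TRUE
  qs <- qex[1, 1]; qe <- qex[qn, 2]
  rs <- rex[1, 1]; re <- rex[rn, 2]

  codes <- character(0)
  if (same && qn > 1 && rn > 1 && identical(chain_str(qi), chain_str(ri)))
    codes <- c(codes, "=")
  if (same && qn == 1 && rn == 1 && ov) codes <- c(codes, "=")
  if (same && qn == 1 && rn > 1 &&
      any(rex[, 1] <= qs & qe <= rex[, 2])) codes <- c(codes, "c")
  if (same && qn > 1 && rn > qn && qs >= rs && qe <= re) {
    # q's intron chain as a consecutive run of r's
    qstr <- chain_str(qi)
    for (off in seq_len(nrow(ri) - nrow(qi) + 1))
      if (identical(chain_str(ri[off:(off + nrow(qi) - 1), , drop = FALSE]),
                    qstr)) codes <- c(codes, "c")
  }
  if (same && qn > 1 && rn > 1) {
    shared <- FALSE
    for (a in seq_len(nrow(qi))) for (b in seq_len(nrow(ri)))
      if (qi[a, 1] == ri[b, 1] && qi[a, 2] == ri[b, 2]) shared <- TRUE
    if (shared) codes <- c(codes, "j")
  }
  if (ov) codes <- c(codes, if (same) "o" else "x")
  if (nrow(ri) > 0 && any(ri[, 1] <= qs & qe <= ri[, 2]))
    codes <- c(codes, "i")
  codes
}

oracle_class_code <- function(q, reference) {
  prec <- c("=", "c", "j", "o", "x", "i", "u")
  all_codes <- unlist(lapply(reference$transcripts, oracle_pair_codes, q = q))
  # within a pair the most specific code wins, and across pairs too, so
  # the overall code is simply the highest-precedence code seen anywhere
  if (!length(all_codes)) return("u")
  prec[min(match(all_codes, prec))]
}

# --- longest-ORF oracle: enumerate every ATG, scan to first in-frame stop
oracle_orf <- function(seq) {
  n <- nchar(seq)
  best <- 0
  if (n >= 6) {
    for (i in seq_len(n - 2)) {
      if (substr(seq, i, i + 2) != "ATG") next
      j <- i + 3
      while (j + 2 <= n) {
        cod <- substr(seq, j, j + 2)
        if (cod %in% c("TAA", "TAG", "TGA")) {
          best <- max(best, j + 2 - i + 1)
          break
        }
        j <- j + 3
      }
    }
  }
  best
}

# --- BH step-up oracle --------------------------------------------------
oracle_bh <- function(p) {
  m <- length(p)
  o <- order(p)
  adj <- p[o] * m / seq_len(m)
  adj <- rev(cummin(rev(adj)))
  adj <- pmin(adj, 1)
  out <- numeric(m)
  out[o] <- adj
  out
}

# --- hypergeometric upper tail by exhaustive enumeration ---------------
oracle_hyper_tail <- function(k, K, n, N) {
  kk <- k:min(K, n)
  sum(choose(K, kk) * choose(N - K, n - kk)) / choose(N, n)
}

# --- median-of-ratios oracle -------------------------------------------
oracle_size_factors <- function(m) {
  keep <- apply(m, 1, function(x) all(x > 0))
  mm <- m[keep, , drop = FALSE]
  geo <- apply(mm, 1, function(x) prod(x)^(1 / length(x)))
  apply(mm, 2, function(col) median(col / geo))
}

# --- Fickett TESTCODE oracle with its own copies of the lookup tables --
oracle_fickett <- function(seq, pos_weight = c(A = 0.26, C = 0.18,
                                               G = 0.31, T = 0.33)) {
  pos_para <- c(1.9, 1.8, 1.7, 1.6, 1.5, 1.4, 1.3, 1.2, 1.1, 0.0)
  pos_prob <- list(
    A = c(0.94, 0.68, 0.84, 0.93, 0.58, 0.68, 0.45, 0.34, 0.20, 0.22),
    C = c(0.80, 0.70, 0.70, 0.81, 0.66, 0.48, 0.51, 0.33, 0.30, 0.23),
    G = c(0.90, 0.88, 0.74, 0.64, 0.53, 0.48, 0.27, 0.16, 0.08, 0.08),
    T = c(0.97, 0.97, 0.91, 0.68, 0.69, 0.44, 0.54, 0.20, 0.09, 0.09))
  con_para <- c(0.33, 0.31, 0.29, 0.27, 0.25, 0.23, 0.21, 0.19, 0.17, 0.0)
  con_prob <- list(
    A = c(0.28, 0.49, 0.44, 0.55, 0.62, 0.49, 0.67, 0.65, 0.81, 0.21),
    C = c(0.82, 0.64, 0.51, 0.64, 0.59, 0.59, 0.43, 0.44, 0.39, 0.31),
    G = c(0.40, 0.54, 0.47, 0.64, 0.64, 0.73, 0.41, 0.41, 0.33, 0.29),
    T = c(0.28, 0.24, 0.39, 0.40, 0.55, 0.75, 0.56, 0.69, 0.51, 0.58))
  con_weight <- c(A = 0.11, C = 0.12, G = 0.15, T = 0.14)
  ch <- strsplit(seq, "")[[1]]
  total <- 0
  for (b in c("A", "C", "G", "T")) {
    in_frame <- vapply(1:3, function(f)
      sum(ch[seq(f, length(ch), by = 3)] == b), numeric(1))
    pp <- max(in_frame) / (min(in_frame) + 1)
    cp <- sum(in_frame) / length(ch)
    total <- total +
      pos_prob[[b]][which(pp >= pos_para)[1]] * pos_weight[[b]] +
      con_prob[[b]][which(cp >= con_para)[1]] * con_weight[[b]]
  }
  total
}

random_seq <- function(n, prob = c(0.25, 0.25, 0.25, 0.25)) {
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE, prob = prob),
        collapse = "")
}
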