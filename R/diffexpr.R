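## Negative-binomial log-likelihood for one group of counts with known
## per-library size factors: mu_j = s_j * q, dispersion alpha (var =
## mu + alpha * mu^2), parameterized as theta = (log q).
nb_group_loglik <- function(k, s, log_q, alpha) {
  mu <- s * exp(log_q)
  sum(stats::dnbinom(k, mu = mu, size = 1 / alpha, log = TRUE))
}

## expected information of one group's log-mean at dispersion alpha
nb_group_info <- function(k, s, log_q, alpha) {
  mu <- s * exp(log_q)
  sum(mu / (1 + alpha * mu))
}

## ML fit of a two-group NB model for one feature. The dispersion is
## estimated by Cox-Reid adjusted maximum likelihood (the adjustment
## -0.5 log det I(beta) corrects the downward bias of plain ML at small
## group sizes, as in the gene-wise fits of the established NB DE tools).
## Returns log_qA, log_qB, alpha-hat, and the Wald SE of
## beta = log_qB - log_qA from the expected information at the fit.
nb_fit_feature <- function(kA, sA, kB, sB, alpha_floor = 1e-8,
                           prior = NULL) {
  ## moment starting values on the normalized scale
  qA0 <- max(mean(kA / sA), 1e-8); qB0 <- max(mean(kB / sB), 1e-8)
  nll <- function(par) {
    a <- exp(par[3L])
    cr <- 0.5 * (log(nb_group_info(kA, sA, par[1L], a)) +
                   log(nb_group_info(kB, sB, par[2L], a)))
    pen <- if (is.null(prior)) 0
           else (par[3L] - prior$log_alpha)^2 / (2 * prior$var)
    -(nb_group_loglik(kA, sA, par[1L], a) +
        nb_group_loglik(kB, sB, par[2L], a)) + cr + pen
  }
  fit <- try(stats::optim(c(log(qA0), log(qB0), log(0.1)), nll,
                          method = "L-BFGS-B",
                          lower = c(-30, -30, log(alpha_floor)),
                          upper = c(30, 30, log(100)),
                          hessian = FALSE),
             silent = TRUE)
  if (inherits(fit, "try-error"))
    fit <- stats::optim(c(log(qA0), log(qB0), log(0.1)), nll,
                        method = "Nelder-Mead")
  par <- fit$par
  alpha <- max(exp(par[3L]), alpha_floor)
  ## the two groups are independent, so the 2x2 information in
  ## (log_qA, log_qB) is diagonal and var(beta) = var(log_qA) + var(log_qB)
  iA <- nb_group_info(kA, sA, par[1L], alpha)
  iB <- nb_group_info(kB, sB, par[2L], alpha)
  se <- sqrt(1 / max(iA, 1e-12) + 1 / max(iB, 1e-12))
  list(log_qA = par[1L], log_qB = par[2L], alpha = alpha, se = se)
}

#' Two-group negative-binomial Wald test
#'
#' A simplified DESeq2-style test: for each feature a negative-binomial
#' model with log link and library size-factor offsets is fitted by
#' maximum likelihood per group, with a gene-wise ML dispersion (floored
#' at `alpha_floor`, no shrinkage). The Wald statistic on the group
#' log-ratio coefficient is referred to the standard normal, two-sided.
#' The reported `log2FC` is log2((meanB + prior)/(meanA + prior)) on
#' size-factor-normalized counts with a prior count of 0.5, in the
#' direction B over A.
#'
#' @param counts A `count_matrix` or matrix (features x libraries).
#' @param design A data.frame with columns `library_id`, `treatment`,
#'   `day` (see [simulate_counts()]).
#' @param contrast A list or character vector
#'   `(treatment, dayA, dayB)`; libraries of that treatment at `dayA` form
#'   group A, at `dayB` group B.
#' @param factors Optional precomputed size factors (computed from the
#'   full matrix otherwise).
#' @param prior_count Prior added to normalized group means for the
#'   reported fold change (default 0.5).
#' @param alpha_floor Dispersion floor (default 1e-8).
#' @param trend_shrink Moderate gene-wise dispersions toward a parametric
#'   mean-dispersion trend alpha(mu) = a0 + a1/mu via a log-normal prior
#'   whose width follows the spread of the gene-wise estimates around the
#'   trend (sampling variance approximated by trigamma((m - p)/2)), as in
#'   the established NB DE tools. Default `FALSE` (plain gene-wise ML).
#' @return A data.frame `feature_id`, `baseMeanA`, `baseMeanB`, `log2FC`,
#'   `dispersion`, `stat`, `p` (unadjusted), `flagged` (all-zero
#'   features, reported with `p = 1`, `log2FC = 0`).
#' @export
nb_wald_test <- function(counts, design, contrast, factors = NULL,
                         prior_count = 0.5, alpha_floor = 1e-8,
                         trend_shrink = FALSE) {
  m <- as_counts(counts)
  contrast <- as.list(contrast)
  names(contrast)[1:3] <- c("treatment", "dayA", "dayB")
  libA <- design$library_id[design$treatment == contrast$treatment &
                              design$day == contrast$dayA]
  libB <- design$library_id[design$treatment == contrast$treatment &
                              design$day == contrast$dayB]
  if (length(libA) < 2L || length(libB) < 2L)
    stop("each contrast group needs >= 2 libraries")
  if (is.null(factors)) factors <- size_factors(m)
  sA <- unname(factors[libA]); sB <- unname(factors[libB])
  one_pass <- function(f, prior = NULL) {
    kA <- m[f, libA]; kB <- m[f, libB]
    mA <- mean(kA / sA); mB <- mean(kB / sB)
    lfc <- log2((mB + prior_count) / (mA + prior_count))
    if (all(kA == 0) && all(kB == 0))
      return(data.frame(feature_id = f, baseMeanA = 0, baseMeanB = 0,
                        log2FC = 0, dispersion = NA_real_, stat = 0,
                        p = 1, flagged = TRUE, stringsAsFactors = FALSE))
    fit <- nb_fit_feature(kA, sA, kB, sB, alpha_floor, prior = prior)
    stat <- (fit$log_qB - fit$log_qA) / fit$se
    data.frame(feature_id = f, baseMeanA = mA, baseMeanB = mB,
               log2FC = lfc, dispersion = fit$alpha, stat = stat,
               p = 2 * stats::pnorm(-abs(stat)), flagged = FALSE,
               stringsAsFactors = FALSE)
  }
  res <- do.call(rbind, lapply(rownames(m), one_pass))
  if (trend_shrink && sum(!res$flagged) >= 20L) {
    ok <- !res$flagged & res$dispersion > 1e-6
    base_mean <- (res$baseMeanA + res$baseMeanB) / 2
    trend <- fit_dispersion_trend(res$dispersion[ok], base_mean[ok])
    a_tr <- pmax(trend$a0 + trend$a1 / base_mean, 1e-8)
    ## prior width: spread of log gene-wise estimates around the trend
    ## in excess of the estimator's own sampling variance
    m_df <- length(libA) + length(libB) - 2L
    svar <- trigamma(m_df / 2)
    lr <- log(res$dispersion[ok]) - log(a_tr[ok])
    pvar <- max(stats::var(lr) - svar, 0.0625)
    res <- do.call(rbind, lapply(seq_len(nrow(res)), function(i)
      one_pass(res$feature_id[i],
               prior = list(log_alpha = log(a_tr[i]), var = pvar))))
  }
  rownames(res) <- NULL
  res
}

## parametric mean-dispersion trend alpha(mu) = a0 + a1/mu, fitted by
## gamma GLM with two trimming passes against outliers
fit_dispersion_trend <- function(alpha_hat, base_mean) {
  keep <- rep(TRUE, length(alpha_hat))
  a0 <- stats::median(alpha_hat); a1 <- 0
  for (it in 1:3) {
    fit <- try(suppressWarnings(
      stats::glm(alpha_hat[keep] ~ I(1 / base_mean[keep]),
                 family = stats::Gamma(link = "identity"),
                 start = c(max(a0, 1e-4), max(a1, 1e-4)))),
      silent = TRUE)
    if (inherits(fit, "try-error")) break
    co <- stats::coef(fit)
    a0 <- max(co[1L], 1e-8); a1 <- max(co[2L], 0)
    pred <- a0 + a1 / base_mean
    ratio <- alpha_hat / pred
    keep <- ratio < 10 & ratio > 1e-4
  }
  list(a0 = a0, a1 = a1)
}

#' Benjamini-Hochberg adjusted p-values
#'
#' Step-up FDR adjustment: padj_(i) = min_{j >= i} (m/j) p_(j), capped at
#' 1 and mapped back to input order.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted p-values, same order as the input.
#' @export
bh_adjust <- function(pvalues) {
  if (anyNA(pvalues) || any(pvalues < 0 | pvalues > 1))
    stop("p-values must lie in [0, 1]")
  stats::p.adjust(pvalues, method = "BH")
}

#' Fold-change magnitude and direction from log2 fold change
#'
#' The reporting convention of the differential-expression tables:
#' down-regulated features carry a negative log2FC but a positive linear
#' fold-change magnitude, FC = 2^|log2FC| rounded to 3 decimals.
#'
#' @param log2fc Numeric vector of log2 fold changes.
#' @return A data.frame with `FC` (magnitude, 3 decimals) and `direction`
#'   (`"up"`, `"down"`, `"flat"`).
#' @examples
#' fc_from_log2fc(c(1.208, -1.459, 0))
#' @export
fc_from_log2fc <- function(log2fc) {
  if (any(!is.finite(log2fc))) stop("log2FC must be finite")
  data.frame(
    FC = round(2^abs(log2fc), 3),
    direction = ifelse(log2fc > 0, "up", ifelse(log2fc < 0, "down", "flat")),
    stringsAsFactors = FALSE
  )
}

#' Differential expression over all diet/timepoint contrasts
#'
#' Runs the NB Wald test for the three day contrasts (D-14 vs D+7, D+7 vs
#' D+28, D-14 vs D+28) within each treatment, BH-adjusts p-values within
#' each contrast, and flags significance at `padj < padj_cutoff`.
#'
#' @param counts A `count_matrix` or matrix.
#' @param design Library design data.frame.
#' @param padj_cutoff Significance threshold on adjusted p (default 0.1,
#'   strict inequality).
#' @param treatments,days Levels defining the contrasts; defaults taken
#'   from `design`.
#' @param ... Passed to [nb_wald_test()].
#' @return A data.frame of per-feature results with `treatment`, `dayA`,
#'   `dayB`, `FC`, `direction`, `padj`, `significant` columns appended.
#' @export
de_all_contrasts <- function(counts, design, padj_cutoff = 0.1,
                             treatments = unique(design$treatment),
                             days = unique(design$day), ...) {
  pairs <- utils::combn(days, 2L, simplify = FALSE)
  res <- list()
  for (tr in treatments) {
    for (dp in pairs) {
      de <- nb_wald_test(counts, design,
                         list(treatment = tr, dayA = dp[1L], dayB = dp[2L]),
                         ...)
      de$treatment <- tr; de$dayA <- dp[1L]; de$dayB <- dp[2L]
      de$padj <- bh_adjust(de$p)
      fc <- fc_from_log2fc(de$log2FC)
      de$FC <- fc$FC; de$direction <- fc$direction
      de$significant <- de$padj < padj_cutoff
      res[[paste(tr, dp[1L], dp[2L], sep = "|")]] <- de
    }
  }
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Overlap table of significant features across contrasts
#'
#' Venn-style summary: for every combination of contrasts within a
#' treatment, the number (and ids) of features significant in exactly that
#' combination.
#'
#' @param de Output of [de_all_contrasts()].
#' @return A data.frame `treatment`, `contrasts` (comma-joined), `n`,
#'   `feature_ids` (comma-joined).
#' @export
de_overlap_table <- function(de) {
  de$contrast <- paste(de$dayA, "vs", de$dayB)
  sig <- de[de$significant, c("treatment", "contrast", "feature_id")]
  out <- list()
  for (tr in unique(de$treatment)) {
    s <- sig[sig$treatment == tr, ]
    if (!nrow(s)) next
    membership <- tapply(s$contrast, s$feature_id, function(x)
      paste(sort(unique(x)), collapse = ","))
    tab <- table(membership)
    out[[tr]] <- data.frame(
      treatment = tr, contrasts = names(tab), n = as.integer(tab),
      feature_ids = vapply(names(tab), function(ct)
        paste(sort(names(membership)[membership == ct]), collapse = ","),
        character(1)),
      stringsAsFactors = FALSE
    )
  }
  if (!length(out))
    return(data.frame(treatment = character(0), contrasts = character(0),
                      n = integer(0), feature_ids = character(0)))
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
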