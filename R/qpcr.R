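#' Relative expression by the 2^-ddCt method
#'
#' Classic relative qPCR quantification with reference-gene normalization:
#' per reaction, dCt = target Ct minus the arithmetic mean of the
#' reference-gene Cts of the same sample and replicate (equivalent to
#' geometric-mean normalization on the linear scale); dCt is averaged
#' within each group; ddCt = mean dCt(case) - mean dCt(control); fold
#' change = 2^-ddCt.
#'
#' @param assays Long-format data.frame with columns `sample_id`, `group`,
#'   `replicate`, `gene`, `ct`. Reference genes (e.g. RPS15/GAPDH
#'   analogues) are identified by `reference`.
#' @param case,control Group labels; `control` is the calibrator.
#' @param reference Character vector naming the reference gene(s); at
#'   least one required in every sample/replicate.
#' @return A data.frame `gene`, `mean_dct_case`, `mean_dct_control`,
#'   `ddct`, `fold_change`, one row per non-reference gene.
#' @examples
#' a <- expand.grid(sample_id = c("s1", "s2"), replicate = 1,
#'                  gene = c("tgt", "ref"), stringsAsFactors = FALSE)
#' a$group <- ifelse(a$sample_id == "s1", "case", "control")
#' a$ct <- ifelse(a$gene == "ref", 20, ifelse(a$group == "case", 18, 20))
#' ddct_fold_change(a, "case", "control", reference = "ref")  # fold 4
#' @export
ddct_fold_change <- function(assays, case, control, reference) {
  need <- c("sample_id", "group", "replicate", "gene", "ct")
  if (!all(need %in% names(assays)))
    stop("assays must have columns: ", paste(need, collapse = ", "))
  if (any(assays$ct <= 0 | assays$ct >= 45))
    stop("Ct values must lie in (0, 45)")
  for (g in c(case, control))
    if (!any(assays$group == g)) stop("group not present: ", g)
  targets <- setdiff(unique(assays$gene), reference)
  if (!length(targets)) stop("no target genes")
  key <- interaction(assays$sample_id, assays$replicate, drop = TRUE)
  ref_rows <- assays$gene %in% reference
  ref_mean <- tapply(assays$ct[ref_rows], key[ref_rows], mean)
  rows <- lapply(targets, function(tg) {
    sel <- assays$gene == tg
    rm_ <- ref_mean[as.character(key[sel])]
    if (anyNA(rm_))
      stop("missing reference Ct for some reactions of ", tg)
    dct <- assays$ct[sel] - as.numeric(rm_)
    grp <- assays$group[sel]
    if (!any(grp == case) || !any(grp == control))
      stop("target ", tg, " lacks case or control reactions")
    dcase <- mean(dct[grp == case]); dctrl <- mean(dct[grp == control])
    ddct <- dcase - dctrl
    data.frame(gene = tg, mean_dct_case = dcase,
               mean_dct_control = dctrl, ddct = ddct,
               fold_change = 2^(-ddct), stringsAsFactors = FALSE)
  })
  res <- do.call(rbind, rows)
  rownames(res) <- NULL
  res
}
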