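#' Pipeline configuration
#'
#' All thresholds of the identification and interpretation cascade, with
#' the study defaults: minimum transcript length 200 nt, coding
#' probability cutoff 0.4 (at-or-above is coding), normalized-count
#' expression filter of 5 in at least 10% of libraries, DE significance
#' at adjusted p < 0.1, cis window 50 kb with correlation > 0.7, GO
#' enrichment at adjusted p <= 0.05 and pathway enrichment at raw
#' p < 0.05.
#'
#' @param min_length,coding_cutoff,expr_min_norm_count,expr_min_lib_frac,de_padj,cis_window,cis_r,go_fdr,kegg_p
#'   Thresholds; see above for defaults and semantics.
#' @param seed Seed recorded for provenance.
#' @param correlation_scale `"log2norm"` or `"norm"` (see
#'   [call_cis_pairs()]).
#' @param orf_both_strands Scan both strands for ORFs (default `FALSE`).
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(min_length = 200, coding_cutoff = 0.4,
                            expr_min_norm_count = 5,
                            expr_min_lib_frac = 0.10, de_padj = 0.1,
                            cis_window = 50000, cis_r = 0.7,
                            go_fdr = 0.05, kegg_p = 0.05, seed = 1L,
                            correlation_scale = "log2norm",
                            orf_both_strands = FALSE) {
  stopifnot(min_length > 0, coding_cutoff >= 0, coding_cutoff <= 1,
            expr_min_norm_count > 0, expr_min_lib_frac > 0,
            expr_min_lib_frac <= 1, de_padj > 0, de_padj <= 1,
            cis_window > 0, cis_r >= -1, cis_r <= 1,
            go_fdr > 0, go_fdr <= 1, kegg_p > 0, kegg_p <= 1)
  structure(list(
    min_length = min_length, coding_cutoff = coding_cutoff,
    expr_min_norm_count = expr_min_norm_count,
    expr_min_lib_frac = expr_min_lib_frac, de_padj = de_padj,
    cis_window = cis_window, cis_r = cis_r, go_fdr = go_fdr,
    kegg_p = kegg_p, seed = as.integer(seed),
    correlation_scale = correlation_scale,
    orf_both_strands = orf_both_strands
  ), class = "pipeline_config")
}

stage_count <- function(stage, n_in, n_removed)
  data.frame(stage = stage, n_in = n_in, n_removed = n_removed,
             n_retained = n_in - n_removed, stringsAsFactors = FALSE)

#' Run the lncRNA identification cascade
#'
#' Executes the discovery stages in order: length filter, class-code
#' filter against the known (protein-coding and other non-coding)
#' annotation, coding-potential classification, exclusion-list removal,
#' known/novel labelling against the lncRNA catalogue, and positional
#' classification against protein-coding genes. Per-stage candidate
#' counts are logged.
#'
#' @param assembled Candidate [annotation_set()].
#' @param reference Reference [annotation_set()] carrying biotypes
#'   (`protein_coding` / `other_ncRNA` for the filter stage, `lncRNA`
#'   for the labelling stage).
#' @param cand_seqs Named character vector of candidate sequences.
#' @param train_seqs,train_labels Labelled training sequences for the
#'   coding-potential model.
#' @param exclusions Character vector of ids with external protein hits
#'   (default none).
#' @param config A [pipeline_config()].
#' @return A list: `lncrnas` (annotation_set of identified lncRNAs),
#'   `status` (known/novel vector), `position` (positional report),
#'   `coding_calls`, `classcode_log`, `stage_log`.
#' @export
run_identify <- function(assembled, reference, cand_seqs, train_seqs,
                         train_labels, exclusions = character(0),
                         config = pipeline_config()) {
  log <- list()
  ids0 <- names(assembled$transcripts)

  ## stage 1+2: length then class code, against the non-lncRNA reference
  known_ref <- annotation_subset(reference,
                                 c("protein_coding", "other_ncRNA"))
  filt <- filter_lncrna_candidates(assembled, known_ref,
                                   min_length = config$min_length)
  n_len <- sum(filt$log$reason == "length", na.rm = TRUE)
  n_code <- sum(filt$log$reason == "code", na.rm = TRUE)
  log[["length"]] <- stage_count("length_filter", length(ids0), n_len)
  log[["code"]] <- stage_count("classcode_filter", length(ids0) - n_len,
                               n_code)
  ids <- names(filt$retained$transcripts)

  ## stage 3: coding potential
  calls <- train_and_classify(train_seqs, train_labels, cand_seqs[ids],
                              cutoff = config$coding_cutoff,
                              both_strands = config$orf_both_strands)
  noncoding <- calls$transcript_id[calls$label == "noncoding"]
  log[["coding"]] <- stage_count("coding_filter", length(ids),
                                 length(ids) - length(noncoding))

  ## stage 4: exclusion list (external protein hits)
  kept <- apply_exclusion_list(noncoding, exclusions)
  log[["exclusion"]] <- stage_count("exclusion_list", length(noncoding),
                                    length(noncoding) - length(kept))

  lncrnas <- annotation_set(assembled$transcripts[kept],
                            assembled$gene_of[kept], assembled$biotype)

  ## stage 5: known/novel labelling against the lncRNA catalogue
  lnc_ref <- annotation_subset(reference, "lncRNA")
  status <- label_known_novel(lncrnas, lnc_ref)

  ## stage 6: positional classification against protein-coding genes
  coding_ref <- annotation_subset(reference, "protein_coding")
  position <- classify_positions(lncrnas, coding_ref)

  stage_log <- do.call(rbind, log)
  rownames(stage_log) <- NULL
  list(lncrnas = lncrnas, status = status, position = position,
       coding_calls = calls, classcode_log = filt$log,
       stage_log = stage_log)
}

#' Run quantification, differential expression, cis calling and enrichment
#'
#' Applies the expression filter, computes FPKM and the descriptive
#' summaries, tests all treatment x day-pair contrasts, calls cis target
#' genes per treatment (for all identified lncRNAs and for the DE
#' subset), and — when a gene-term annotation is supplied — runs the
#' hypergeometric enrichment of the cis target lists.
#'
#' @param identify Output of [run_identify()].
#' @param counts A [count_matrix()] holding lncRNA transcripts and coding
#'   genes.
#' @param design Library design data.frame.
#' @param coding [annotation_set()] of protein-coding genes.
#' @param terms Optional gene-term table for [hypergeom_enrich()].
#' @param config A [pipeline_config()].
#' @return A list: `expressed_ids`, `size_factors`, `fpkm_mean`,
#'   `summaries`, `de`, `de_overlap`, `cis_all`, `cis_de`, `enrichment`
#'   (possibly `NULL`), `stage_log`.
#' @export
run_quantify <- function(identify, counts, design, coding, terms = NULL,
                         config = pipeline_config()) {
  m <- counts$counts
  factors <- size_factors(m)
  expressed <- expressed_filter(m, factors,
                                min_count = config$expr_min_norm_count,
                                min_frac = config$expr_min_lib_frac)
  lnc_ids <- intersect(names(identify$lncrnas$transcripts), expressed)
  stage_log <- stage_count("expression_filter",
                           length(names(identify$lncrnas$transcripts)),
                           length(names(identify$lncrnas$transcripts)) -
                             length(lnc_ids))

  fp <- fpkm(counts)
  summaries <- summarize_expression(
    fp$mean_fpkm[lnc_ids], identify$status,
    stats::setNames(vapply(identify$lncrnas$transcripts, `[[`,
                           numeric(1), "length"),
                    names(identify$lncrnas$transcripts)),
    identify$lncrnas$gene_of,
    stats::setNames(vapply(identify$lncrnas$transcripts, `[[`,
                           character(1), "chrom"),
                    names(identify$lncrnas$transcripts))
  )

  keep <- rownames(m) %in% expressed
  mf <- m[keep, , drop = FALSE]
  de <- de_all_contrasts(mf[rownames(mf) %in% lnc_ids, , drop = FALSE],
                         design, padj_cutoff = config$de_padj,
                         factors = factors, trend_shrink = TRUE)
  overlap <- de_overlap_table(de)

  lnc_set <- annotation_set(identify$lncrnas$transcripts[lnc_ids],
                            identify$lncrnas$gene_of[lnc_ids],
                            identify$lncrnas$biotype)
  cis_all <- call_cis_pairs(lnc_set, coding, mf, design,
                            window = config$cis_window,
                            r_cutoff = config$cis_r,
                            scale = config$correlation_scale,
                            factors = factors)
  de_ids <- unique(de$feature_id[de$significant])
  cis_de <- call_cis_pairs(lnc_set, coding, mf, design,
                           lncrna_ids = de_ids,
                           window = config$cis_window,
                           r_cutoff = config$cis_r,
                           scale = config$correlation_scale,
                           factors = factors)

  enr <- NULL
  if (!is.null(terms) && nrow(cis_all)) {
    universe <- intersect(rownames(mf), unique(coding$gene_of))
    input <- intersect(unique(cis_all$gene_id), universe)
    if (length(input))
      enr <- hypergeom_enrich(input, universe, terms,
                              go_fdr = config$go_fdr,
                              pathway_p = config$kegg_p)
  }

  list(expressed_ids = expressed, size_factors = factors,
       fpkm_mean = fp$mean_fpkm, summaries = summaries, de = de,
       de_overlap = overlap, cis_all = cis_all, cis_de = cis_de,
       enrichment = enr, stage_log = stage_log)
}

#' End-to-end synthetic run with reports written to disk
#'
#' Simulates every input under `cfg`, runs identification and
#' quantification, and writes all reports as TSV files. Re-running with
#' the same configuration reproduces every output byte-identically.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory.
#' @param config A [pipeline_config()].
#' @return Invisibly, a list `identify`, `quantify`, `sim`.
#' @export
run_all_synthetic <- function(cfg, dir, config = pipeline_config(seed = cfg$seed)) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(cfg)
  seqs <- simulate_sequences(cfg, ann$truth)
  cm <- simulate_counts(cfg, ann$truth)
  train <- simulate_labeled_sequences(60, 60, seed = cfg$seed)
  idf <- run_identify(ann$assembled, ann$reference, seqs, train$seqs,
                      train$labels, config = config)
  coding_ref <- annotation_subset(ann$reference, "protein_coding")
  qt <- run_quantify(idf, cm$counts, cm$design, coding_ref,
                     config = config)
  wr <- function(df, name)
    utils::write.table(df, file.path(dir, name), sep = "\t",
                       quote = FALSE, row.names = FALSE)
  wr(idf$stage_log, "stage_log.tsv")
  wr(idf$classcode_log, "classcode_log.tsv")
  wr(idf$coding_calls, "coding_calls.tsv")
  wr(idf$position, "position.tsv")
  wr(data.frame(transcript_id = names(idf$status),
                status = unname(idf$status)), "known_novel.tsv")
  wr(data.frame(library_id = names(qt$size_factors),
                size_factor = unname(qt$size_factors)), "size_factors.tsv")
  wr(qt$de, "de.tsv")
  wr(qt$de_overlap, "de_overlap.tsv")
  wr(qt$cis_all, "cis_all.tsv")
  wr(qt$cis_de, "cis_de.tsv")
  wr(qt$summaries$length_hist, "length_hist.tsv")
  invisible(list(identify = idf, quantify = qt, sim = cm))
}
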