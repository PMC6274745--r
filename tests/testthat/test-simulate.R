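small_cfg <- function(seed = 1, ...) {
  ## 75 genes leave enough hosts for the ten gene-anchored classes at
  ## their 5-instance floors
  sim_config(seed = seed, n_coding_genes = 75, n_ref_lncrna = 15,
             n_lncrna = 40, n_coding_match = 4, ...)
}

test_that("configurations are validated up front", {
  expect_error(sim_config(class_mix = c(intergenic_gt1kb = 0.9)), "sum to 1")
  expect_error(sim_config(class_mix = c(somewhere_else = 1)), "unknown")
  expect_error(sim_config(nb_dispersion = 0), "positive")
  expect_error(sim_config(n_short = 2), "n_short")
  # chromosomes too small for the requested genes: sizing error
  expect_error(simulate_annotation(sim_config(chrom_length = 4e5,
                                              n_coding_genes = 200)),
               "sizing error.*CG")
})

test_that("identical configurations give byte-identical files", {
  cfg <- small_cfg(seed = 3)
  d1 <- file.path(tempdir(), "simA"); d2 <- file.path(tempdir(), "simB")
  simulate_to_dir(cfg, d1)
  simulate_to_dir(cfg, d2)
  for (f in list.files(d1)) {
    expect_identical(readBin(file.path(d1, f), "raw", n = 2e7),
                     readBin(file.path(d2, f), "raw", n = 2e7),
                     info = f)
  }
  # a different seed changes the data
  simulate_to_dir(small_cfg(seed = 4), d2)
  expect_false(identical(readBin(file.path(d1, "counts.tsv"), "raw", 2e7),
                         readBin(file.path(d2, "counts.tsv"), "raw", 2e7)))
})

test_that("truth, annotation, sequences and counts agree on feature ids", {
  cfg <- small_cfg(seed = 5)
  ann <- simulate_annotation(cfg)
  expect_equal(anyDuplicated(ann$truth$feature_id), 0)
  expect_setequal(
    ann$truth$feature_id[ann$truth$feature_type %in%
                           c("candidate", "coding_match", "short")],
    names(ann$assembled$transcripts))
  seqs <- simulate_sequences(cfg, ann$truth)
  expect_setequal(names(seqs), ann$truth$feature_id)
  expect_equal(unname(nchar(seqs[ann$truth$feature_id])),
               ann$truth$length)
  cm <- simulate_counts(cfg, ann$truth)
  expect_true(all(names(ann$assembled$transcripts) %in%
                    rownames(cm$counts$counts)))
  expect_equal(ncol(cm$counts$counts), 36)
  expect_equal(nrow(cm$design), 36)
  expect_equal(unname(table(cm$design$treatment)), c(18L, 18L),
               ignore_attr = TRUE)
  # full 2 x 3 x 6 design
  expect_equal(unname(table(cm$design$treatment, cm$design$day)),
               matrix(6L, 2, 3), ignore_attr = TRUE)
})

test_that("planted classes, matches and shorts occur as contracted", {
  cfg <- small_cfg(seed = 6)
  ann <- simulate_annotation(cfg)
  truth <- ann$truth
  planted <- table(truth$positional_class)
  expect_true(all(planted[names(cfg$class_mix)[cfg$class_mix > 0]] >= 5))
  expect_equal(sum(truth$feature_type == "short"), 3)
  lens <- vapply(ann$assembled$transcripts, `[[`, numeric(1), "length")
  expect_equal(sum(lens < 200), 3)
  # intergenic-only mix puts every candidate > 1 kb from any gene
  cfg1 <- small_cfg(seed = 7, known_frac = 0,
                    class_mix = c(intergenic_gt1kb = 1))
  ann1 <- simulate_annotation(cfg1)
  pos <- classify_positions(ann1$assembled,
                            annotation_subset(ann1$reference,
                                              "protein_coding"))
  planted1 <- !is.na(ann1$truth$positional_class[
    match(pos$lncrna_id, ann1$truth$feature_id)])
  expect_true(all(pos$distance[planted1] > 1000))
})

test_that("sequences respect the coding and length contracts", {
  cfg <- small_cfg(seed = 8)
  ann <- simulate_annotation(cfg)
  seqs <- simulate_sequences(cfg, ann$truth)
  coding_ids <- ann$truth$feature_id[ann$truth$coding_label == "coding"]
  for (id in sample(coding_ids, 20)) {
    orf <- find_longest_orf(seqs[[id]])
    expect_gte(orf$length / nchar(seqs[[id]]), 0.5)
  }
  expect_false(any(grepl("[^ACGT]", seqs)))
  # hexamer separation between the two generative models
  tr <- simulate_labeled_sequences(40, 40, seed = 9)
  tabs <- build_hexamer_tables(tr$seqs[tr$labels == "coding"],
                               tr$seqs[tr$labels == "noncoding"])
  sc <- vapply(seqs[coding_ids[1:25]], hexamer_score, numeric(1),
               tabs$coding, tabs$noncoding)
  nc_ids <- ann$truth$feature_id[ann$truth$coding_label == "noncoding"]
  sn <- vapply(seqs[nc_ids[1:25]], hexamer_score, numeric(1),
               tabs$coding, tabs$noncoding)
  expect_gt(mean(sc), mean(sn))
})

test_that("NB draws match their stated mean-variance relationship", {
  set.seed(131)
  mu <- 150; disp <- 0.08
  x <- rnbinom(4000, mu = mu, size = 1 / disp)
  expect_lt(abs(mean(x) / mu - 1), 0.05)
  expect_lt(abs(var(x) / (mu + disp * mu^2) - 1), 0.05)
  cfg_bad <- small_cfg(seed = 2)
  cfg_bad$nb_dispersion <- -0.1
  ann <- simulate_annotation(cfg_bad)
  expect_error(simulate_counts(cfg_bad, ann$truth), "positive")
})

test_that("planted correlations and fold changes shape the counts", {
  cfg <- small_cfg(seed = 10)
  ann <- simulate_annotation(cfg)
  cm <- simulate_counts(cfg, ann$truth)
  sf <- size_factors(cm$counts)
  expr <- log2(normalized_counts(cm$counts, sf) + 1)
  for (tr in c("LSO", "SFO")) {
    libs <- cm$design$library_id[cm$design$treatment == tr]
    rs <- vapply(seq_len(nrow(cm$planted_cis)), function(i) {
      p <- cm$planted_cis[i, ]
      cor(expr[p$lncrna_id, libs], expr[p$gene_id, libs])
    }, numeric(1))
    expect_true(all(abs(rs - cm$planted_cis$r) <= 0.05))
  }
  # a far-apart user-specified pair is rejected
  cfg_bad <- small_cfg(seed = 10)
  cfg_bad$planted_cis <- data.frame(
    lncrna_id = cm$planted_cis$lncrna_id[1], gene_id = "CG0039",
    r = 0.9, stringsAsFactors = FALSE)
  expect_error(simulate_counts(cfg_bad, ann$truth), "50 kb")
})
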