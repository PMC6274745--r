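test_that("the 50 kb window is inclusive at the boundary", {
  mk_gene <- function(id, start, end) transcript_model(
    paste0(id, ".t"), "chr1", "+", cbind(start, end))
  coding <- annotation_set(
    list(mk_gene("near", 151000, 152000),   # gap 49,999
         mk_gene("edge", 151001, 152000),   # gap 50,000
         mk_gene("far", 151002, 152000),    # gap 50,001
         mk_gene("inside", 100500, 100800)),
    setNames(c("near", "edge", "far", "inside"),
             c("near.t", "edge.t", "far.t", "inside.t")),
    setNames(rep("protein_coding", 4), c("near", "edge", "far", "inside")))
  lnc <- transcript_model("l", "chr1", "+", cbind(100000, 101001))
  cand <- window_candidates(lnc, coding)
  expect_setequal(cand$gene_id, c("near", "edge", "inside"))
  expect_equal(cand$distance[cand$gene_id == "edge"], 50000)
  expect_equal(cand$distance[cand$gene_id == "inside"], 0)
})

test_that("window queries equal a brute-force all-pairs distance scan", {
  set.seed(91)
  coding <- annotation_set(
    lapply(1:25, function(i) random_tx(paste0("g", i, ".t"),
                                       chrom = "chr1", max_pos = 200000)),
    setNames(paste0("g", 1:25), paste0("g", 1:25, ".t")),
    setNames(rep("protein_coding", 25), paste0("g", 1:25)))
  spans <- t(vapply(coding$transcripts, function(tx)
    c(tx$exons[1, 1], tx$exons[nrow(tx$exons), 2]), numeric(2)))
  for (k in 1:40) {
    lnc <- random_tx("l", chrom = "chr1", max_pos = 200000)
    w <- sample(c(500, 5000, 50000), 1)
    got <- window_candidates(lnc, coding, window = w)
    ls <- lnc$exons[1, 1]; le <- lnc$exons[nrow(lnc$exons), 2]
    d_all <- pmax(spans[, 1] - le, ls - spans[, 2], 0)
    ov <- spans[, 1] < le & ls < spans[, 2]
    d_all[ov] <- 0
    want <- sub("\\.t$", "", rownames(spans)[d_all <= w])
    expect_setequal(got$gene_id, want)
    expect_equal(got$distance,
                 unname(d_all[paste0(got$gene_id, ".t",
                                     recycle0 = TRUE)]))
  }
})

test_that("correlation p-values reproduce the t-transform closed form", {
  # printed correlation/p pairs of the cis-target table, n = 18
  expect_equal(signif(bovlnc:::pearson_p_from_r(0.821379, 18), 3), 2.93e-5)
  expect_equal(signif(bovlnc:::pearson_p_from_r(0.940505, 18), 3), 6.54e-9)
  expect_equal(signif(bovlnc:::pearson_p_from_r(0.739728, 18), 2), 4.5e-4)
  set.seed(92)
  for (k in 1:50) {
    n <- sample(5:40, 1)
    x <- rnorm(n); y <- rnorm(n) + 0.5 * x
    res <- pearson_with_p(x, y)
    r <- sum((x - mean(x)) * (y - mean(y))) /
      sqrt(sum((x - mean(x))^2) * sum((y - mean(y))^2))
    expect_equal(res$r, r, tolerance = 1e-10)
    tt <- r * sqrt(n - 2) / sqrt(1 - r^2)
    expect_equal(res$p, 2 * pt(-abs(tt), n - 2), tolerance = 1e-12)
    expect_equal(cor.test(x, y)$p.value, res$p, tolerance = 1e-9)
    swapped <- pearson_with_p(y, x)
    expect_equal(swapped$r, res$r)
    expect_equal(swapped$p, res$p)
  }
  xx <- rnorm(10)
  self <- pearson_with_p(xx, xx)
  expect_equal(self$r, 1)
  expect_lt(self$p, 1e-12)
  expect_warning(res <- pearson_with_p(rep(1, 10), rnorm(10)), "constant")
  expect_true(is.na(res$r))
  expect_error(pearson_with_p(1:4, 1:3), "equal length")
})

test_that("cis calling requires strictly more than the correlation cutoff", {
  cfg <- sim_config(seed = 14, n_coding_genes = 40, n_ref_lncrna = 0,
                    known_frac = 0, n_lncrna = 12,
                    class_mix = c(intergenic_gt1kb = 1),
                    n_cis = 4, cis_r = 0.9, n_de = 0)
  ann <- simulate_annotation(cfg)
  cm <- simulate_counts(cfg, ann$truth)
  lnc <- annotation_set(ann$assembled$transcripts[cm$planted_cis$lncrna_id],
                        ann$assembled$gene_of[cm$planted_cis$lncrna_id])
  coding <- annotation_subset(ann$reference, "protein_coding")
  cis <- call_cis_pairs(lnc, coding, cm$counts, cm$design)
  p1 <- cis[1, ]
  # raising the cutoff to the pair's own r drops it: > is strict
  at_r <- call_cis_pairs(lnc, coding, cm$counts, cm$design,
                         r_cutoff = p1$r)
  expect_false(any(at_r$lncrna_id == p1$lncrna_id &
                     at_r$gene_id == p1$gene_id &
                     at_r$treatment == p1$treatment))
  just_below <- call_cis_pairs(lnc, coding, cm$counts, cm$design,
                               r_cutoff = p1$r - 1e-9)
  expect_true(any(just_below$lncrna_id == p1$lncrna_id &
                    just_below$gene_id == p1$gene_id &
                    just_below$treatment == p1$treatment))
  # every called pair satisfies both the window and the correlation rule
  expect_true(all(cis$r > 0.7))
  expect_true(all(cis$distance <= 50000))
})

test_that("planted pairs are recovered and weak decoys stay uncalled", {
  cfg <- sim_config(seed = 15, n_coding_genes = 40, n_ref_lncrna = 0,
                    known_frac = 0, n_lncrna = 15,
                    class_mix = c(intergenic_gt1kb = 1),
                    n_cis = 12, cis_r = c(rep(0.9, 6), rep(0.3, 6)),
                    n_de = 0)
  ann <- simulate_annotation(cfg)
  cm <- simulate_counts(cfg, ann$truth)
  lnc <- annotation_set(ann$assembled$transcripts[cm$planted_cis$lncrna_id],
                        ann$assembled$gene_of[cm$planted_cis$lncrna_id])
  cis <- call_cis_pairs(lnc, annotation_subset(ann$reference,
                                               "protein_coding"),
                        cm$counts, cm$design)
  key <- unique(paste(cis$lncrna_id, cis$gene_id))
  planted <- paste(cm$planted_cis$lncrna_id, cm$planted_cis$gene_id)
  expect_setequal(intersect(planted, key),
                  planted[cm$planted_cis$r == 0.9])
})
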