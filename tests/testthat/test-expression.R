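test_that("median-of-ratios size factors behave on forced cases", {
  m <- matrix(c(10, 20, 40, 10, 20, 40), ncol = 2,
              dimnames = list(paste0("f", 1:3), c("A", "B")))
  expect_equal(unname(size_factors(m)), c(1, 1))
  # library B exactly twice library A: geometric means sqrt(2) * A,
  # forcing the symmetric pair (1/sqrt(2), sqrt(2))
  m2 <- cbind(A = c(10, 20, 40), B = c(20, 40, 80))
  rownames(m2) <- paste0("f", 1:3)
  expect_equal(unname(size_factors(m2)), c(1 / sqrt(2), sqrt(2)))
  expect_error(size_factors(cbind(A = c(0, 5), B = c(3, 0))), "filter")
})

test_that("size factors match the straight-line oracle and DESeq2", {
  set.seed(71)
  m <- matrix(rnbinom(200 * 8, mu = 80, size = 5), nrow = 200,
              dimnames = list(paste0("f", 1:200), paste0("L", 1:8)))
  sf <- size_factors(m)
  expect_equal(unname(sf), unname(oracle_size_factors(m)),
               tolerance = 1e-12)
  ## DESeq2 takes the median on the log-ratio scale; with an even number
  ## of usable features the two medians differ in the interpolated case,
  ## hence the loose tolerance
  expect_equal(unname(sf),
               unname(DESeq2::estimateSizeFactorsForMatrix(m)),
               tolerance = 1e-3)
})

test_that("scaling one library rescales only its factor", {
  set.seed(72)
  m <- matrix(rnbinom(150 * 6, mu = 100, size = 10) + 1, nrow = 150,
              dimnames = list(paste0("f", 1:150), paste0("L", 1:6)))
  sf <- size_factors(m)
  m2 <- m; m2[, 3] <- m2[, 3] * 4
  sf2 <- size_factors(m2)
  # all-positive matrix: no zero-exclusion changes; the scaled library's
  # factor grows by c^(1 - 1/n) and the others shrink by c^(-1/n)
  # through the geometric-mean reference
  expect_equal(unname(sf2[3] / sf[3]), 4 * 4^(-1 / 6), tolerance = 1e-9)
  expect_equal(unname(sf2[-3] / sf[-3]), rep(4^(-1 / 6), 5),
               tolerance = 1e-9)
  # normalized counts of the scaled library are invariant up to that
  # global reference shift
  norm1 <- normalized_counts(m, sf)
  norm2 <- normalized_counts(m2, sf2)
  expect_equal(norm2[, 3] / norm1[, 3], rep(4^(1 / 6), 150),
               ignore_attr = TRUE, tolerance = 1e-9)
  # doubling every library leaves the factors unchanged (composition,
  # not depth, is what median-of-ratios measures relative to the
  # in-matrix reference)
  expect_equal(size_factors(m * 2), sf, tolerance = 1e-12)
})

test_that("the truly-expressed filter applies >=5 in >=10% with a ceiling", {
  libs <- paste0("L", 1:36)
  sf <- setNames(rep(1, 36), libs)
  m <- rbind(
    just_in = c(rep(5, 4), rep(0, 32)),     # exactly 4 libraries at 5.0
    three_libs = c(rep(50, 3), rep(0, 33)), # one library short
    below = rep(4.99, 36)                   # everywhere, but under 5
  )
  colnames(m) <- libs
  kept <- expressed_filter(m, sf)
  expect_equal(kept, "just_in")
  # monotonicity: raising any count never removes a retained feature
  m2 <- m; m2["three_libs", 4] <- 50
  expect_true(all(kept %in% expressed_filter(m2, sf)))
  expect_true("three_libs" %in% expressed_filter(m2, sf))
})

test_that("a planted below-threshold fraction is filtered exactly", {
  libs <- paste0("L", 1:36)
  sf <- setNames(rep(1, 36), libs)
  n <- 100
  m <- matrix(0, n, 36, dimnames = list(paste0("f", 1:n), libs))
  m[1:40, 1:10] <- 100  # 40% clearly expressed
  m[41:100, 1:36] <- 2  # 60% planted below the normalized threshold
  expect_equal(length(expressed_filter(m, sf)) / n, 0.4)
})

test_that("FPKM follows count * 1e9 / (N * L) exactly", {
  m <- matrix(c(10, 999990, 0, 1e6), ncol = 2,
              dimnames = list(c("a", "b"), c("L1", "L2")))
  lens <- c(a = 1000, b = 2000)
  f <- fpkm(m, lens)
  expect_equal(f$fpkm["a", "L1"], 10)   # 10 reads, 1 kb, 1e6 total
  expect_equal(f$fpkm["a", "L2"], 0)    # zero count
  set.seed(73)
  mm <- matrix(rpois(50 * 4, 60), nrow = 50,
               dimnames = list(paste0("f", 1:50), paste0("L", 1:4)))
  ll <- setNames(sample(200:3000, 50), rownames(mm))
  f2 <- fpkm(mm, ll)
  oracle <- mm * 1e9 / outer(ll, colSums(mm))
  expect_equal(f2$fpkm, oracle, tolerance = 1e-12)
  expect_equal(f2$mean_fpkm, rowMeans(oracle), tolerance = 1e-12)
  # FPKM scales as 1/L at fixed counts and 1/N at fixed counts and length
  expect_equal(unname(fpkm(mm, ll * 2)$fpkm), unname(f2$fpkm / 2))
  expect_error(fpkm(cbind(L1 = c(a = 0, b = 0)), c(a = 10, b = 10)),
               "zero")
})

test_that("summaries bin lengths and break FPKM ties lexicographically", {
  ids <- c("t_b", "t_a", "t_c", "t_d")
  mean_fpkm <- setNames(c(5, 5, 5, 1), ids)
  status <- setNames(c("novel", "novel", "novel", "known"), ids)
  lengths <- setNames(c(250, 1000, 2499, 2500), ids)
  s <- summarize_expression(mean_fpkm, status, lengths,
                            gene_of = setNames(c("g1", "g1", "g2", "g3"),
                                               ids),
                            chrom = setNames(rep("chr1", 4), ids),
                            top_k = 2)
  top_novel <- s$top_expressed[s$top_expressed$status == "novel", ]
  expect_equal(top_novel$transcript_id, c("t_a", "t_b"))
  expect_equal(s$length_hist$n, c(1, 2, 1))  # 250 sits in [200, 999]
  expect_equal(s$length_hist$bin, c("200-999", "1000-2499", ">=2500"))
  expect_equal(sum(s$transcripts_per_gene$n_genes), 3)
})
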