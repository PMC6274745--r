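one_gene <- function(strand = "+", exons = cbind(c(10000, 12000),
                                                 c(11000, 13000))) {
  annotation_set(list(transcript_model("g1.t1", "chr1", strand, exons)),
                 c(g1.t1 = "g1"), c(g1 = "protein_coding"))
}

test_that("canonical geometries land in their positional classes", {
  coding <- one_gene()
  # 5 kb away from the only gene: intergenic, distance > 1 kb
  res <- classify_position(transcript_model("l", "chr1", "+",
                                            cbind(4000, 5000)), coding)
  expect_equal(res$class, "intergenic_gt1kb")
  expect_equal(res$distance, 5000)
  expect_equal(res$nearest_gene_id, "g1")
  # exon overlapping a coding exon, same strand
  res <- classify_position(transcript_model("l", "chr1", "+",
                                            cbind(10500, 11500)), coding)
  expect_equal(res$class, "exonic_overlap_sense")
  expect_equal(res$distance, 0)
  # ... and opposite strand
  res <- classify_position(transcript_model("l", "chr1", "-",
                                            cbind(10500, 11500)), coding)
  expect_equal(res$class, "exonic_overlap_antisense")
  # ending 500 bp before the TSS, same strand
  res <- classify_position(transcript_model("l", "chr1", "+",
                                            cbind(9000, 9500)), coding)
  expect_equal(res$class, "upstream_1kb_sense")
  expect_equal(res$distance, 500)
  # inside the intron, both orientations
  res <- classify_position(transcript_model("l", "chr1", "+",
                                            cbind(11200, 11700)), coding)
  expect_equal(res$class, "intronic_sense")
  res <- classify_position(transcript_model("l", "chr1", "-",
                                            cbind(11200, 11700)), coding)
  expect_equal(res$class, "intronic_antisense")
  # gene fully inside the lncRNA's intron
  res <- classify_position(
    transcript_model("l", "chr1", "+",
                     cbind(c(9000, 14000), c(9500, 14500))), coding)
  expect_equal(res$class, "gene_in_lncrna_intron")
  # divergent within 250 bp: shared bidirectional promoter
  res <- classify_position(transcript_model("l", "chr1", "-",
                                            cbind(9300, 9900)), coding)
  expect_equal(res$class, "bidirectional_promoter_shared")
  # divergent at 600 bp: upstream antisense
  res <- classify_position(transcript_model("l", "chr1", "-",
                                            cbind(9000, 9400)), coding)
  expect_equal(res$class, "upstream_1kb_antisense")
  # past the TES, both orientations
  res <- classify_position(transcript_model("l", "chr1", "+",
                                            cbind(13400, 13900)), coding)
  expect_equal(res$class, "downstream_1kb_sense")
  res <- classify_position(transcript_model("l", "chr1", "-",
                                            cbind(13400, 13900)), coding)
  expect_equal(res$class, "downstream_1kb_antisense")
})

test_that("the 1 kb flank boundary is inclusive at exactly 1000 bp", {
  coding <- one_gene()
  at_1000 <- classify_position(transcript_model("l", "chr1", "+",
                                                cbind(8500, 9000)), coding)
  expect_equal(at_1000$class, "upstream_1kb_sense")
  expect_equal(at_1000$distance, 1000)
  at_1001 <- classify_position(transcript_model("l", "chr1", "+",
                                                cbind(8499, 8999)), coding)
  expect_equal(at_1001$class, "intergenic_gt1kb")
  expect_equal(at_1001$distance, 1001)
})

test_that("planted synthetic classes are recovered perfectly", {
  cfg <- sim_config(seed = 5)
  ann <- simulate_annotation(cfg)
  pos <- classify_positions(ann$assembled,
                            annotation_subset(ann$reference,
                                              "protein_coding"))
  truth <- ann$truth[match(pos$lncrna_id, ann$truth$feature_id), ]
  planted <- !is.na(truth$positional_class)
  # every class with positive mix weight occurs at least 5 times
  expect_true(all(table(truth$positional_class[planted]) >= 5))
  expect_equal(pos$class[planted], truth$positional_class[planted])
  # distances agree where the generator recorded the flank gap
  flank <- planted & grepl("upstream|downstream|bidirectional",
                           truth$positional_class)
  expect_equal(pos$distance[flank], truth$nearest_gene_distance[flank])
  ## the classified gene is the planted host wherever the class ties the
  ## lncRNA to a specific gene (intergenic loci may sit closer to the
  ## preceding gene than to the host used for placement)
  anchored <- planted & truth$positional_class != "intergenic_gt1kb"
  expect_equal(pos$nearest_gene_id[anchored], truth$nearest_gene_id[anchored])
})

test_that("every random locus is classified, with a sane distance", {
  set.seed(61)
  coding <- annotation_set(
    lapply(1:15, function(i) random_tx(paste0("g", i, ".t"), chrom = "chr1",
                                       max_pos = 30000)),
    setNames(paste0("g", 1:15),
             paste0("g", 1:15, ".t")),
    setNames(rep("protein_coding", 15), paste0("g", 1:15)))
  for (k in 1:150) {
    lnc <- random_tx("l", chrom = "chr1", max_pos = 35000)
    res <- classify_position(lnc, coding)
    expect_true(res$class %in% POSITIONAL_CLASSES)
    expect_gte(res$distance, 0)
    if (res$class == "intergenic_gt1kb") expect_gt(res$distance, 1000)
  }
})

test_that("a lncRNA on an unannotated chromosome degrades gracefully", {
  expect_warning(
    res <- classify_position(transcript_model("l", "chrZ", "+",
                                              cbind(0, 500)), one_gene()),
    "absent")
  expect_equal(res$class, "intergenic_gt1kb")
  expect_equal(res$distance, Inf)
})
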