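## Seeded generators for every input the pipeline consumes, with planted
## ground truth. One root seed; each sub-generator re-seeds from a fixed
## hash of (seed, stage) so that adding features to one stage never
## perturbs another stage's stream.
stage_seed <- function(seed, stage) {
  idx <- match(stage, c("annotation", "sequences", "counts", "training"))
  as.integer((as.numeric(seed) * 7919 + idx * 104729) %% 2147483629)
}

DEFAULT_CLASS_MIX <- c(
  intergenic_gt1kb = 0.6237,
  exonic_overlap_sense = 0.1200,
  exonic_overlap_antisense = 0.1186,
  upstream_1kb_sense = 0.0300,
  upstream_1kb_antisense = 0.0300,
  bidirectional_promoter_shared = 0.0274,
  downstream_1kb_sense = 0.0080,
  downstream_1kb_antisense = 0.0074,
  intronic_sense = 0.0110,
  intronic_antisense = 0.0107,
  gene_in_lncrna_intron = 0.0132
)

#' Simulation configuration
#'
#' Defines the study conditions for the synthetic dataset: a
#' multi-chromosome toy genome with protein-coding genes and lncRNAs
#' planted in known positional classes, and a 2-treatment x 3-timepoint x
#' 6-cow fragment-count design (36 libraries, 18 per treatment) with
#' planted log2 fold changes and planted lncRNA-mRNA correlation within
#' 50 kb.
#'
#' @param seed Root integer seed; drives every stream.
#' @param n_chromosomes,chrom_length Genome shape (default 3 x 3 Mb).
#' @param n_coding_genes Protein-coding genes in the reference (1-10
#'   exons each; default 90).
#' @param n_ref_lncrna Known lncRNAs in the reference catalogue (3 exons;
#'   default 60).
#' @param n_lncrna Planted candidate lncRNAs, apportioned over
#'   `class_mix`; every class with positive weight is planted at least 5
#'   times (default 110).
#' @param known_frac Fraction of candidates planted as matches (codes
#'   `=`/`c`/`j`) of reference lncRNAs, hence labelled "known" (default
#'   0.066, the known share of the discovery setting this emulates).
#' @param n_coding_match Assembled transcripts identical to reference
#'   coding transcripts, removed at the class-code stage (default 8).
#' @param n_short Planted transcripts under 200 nt exercising the length
#'   filter (default 3; minimum 3).
#' @param class_mix Named proportions over [POSITIONAL_CLASSES]; must sum
#'   to 1.
#' @param design List: `treatments` (default LSO/SFO), `days` (default
#'   D-14/D+7/D+28), `cows_per_treatment` (default 6).
#' @param planted_lfc `NULL` for the default plan (`n_de` candidates at
#'   +/- `de_lfc` spread over all treatment x day-pair contrasts) or a
#'   data.frame `feature_id`, `treatment`, `dayA`, `dayB`, `log2fc`.
#' @param n_de,de_lfc Default differential-expression plan (12 features
#'   at |log2FC| = 1.2).
#' @param planted_cis `NULL` for the default plan (`n_cis` lncRNA-gene
#'   pairs at target `cis_r`) or a data.frame `lncrna_id`, `gene_id`,
#'   `r`. Each pair must couple a candidate with its nearest coding gene
#'   at a distance of at most 50 kb (validated at generation time).
#' @param n_cis,cis_r Default cis plan (8 pairs at r = 0.9); `cis_r` may
#'   be a vector, recycled over the pairs.
#' @param nb_dispersion NB dispersion alpha (var = mu + alpha mu^2;
#'   default 0.05).
#' @param mean_depth Mean fragments per library (default 1e5).
#' @return A validated list of class `sim_config`.
#' @export
sim_config <- function(seed = 1L, n_chromosomes = 3L, chrom_length = 3e6,
                       n_coding_genes = 90L, n_ref_lncrna = 60L,
                       n_lncrna = 110L, known_frac = 0.066,
                       n_coding_match = 8L, n_short = 3L,
                       class_mix = DEFAULT_CLASS_MIX,
                       design = list(treatments = c("LSO", "SFO"),
                                     days = c("D-14", "D+7", "D+28"),
                                     cows_per_treatment = 6L),
                       planted_lfc = NULL, n_de = 12L, de_lfc = 1.2,
                       planted_cis = NULL, n_cis = 8L, cis_r = 0.9,
                       nb_dispersion = 0.05, mean_depth = 1e5) {
  stopifnot(n_chromosomes >= 1, chrom_length > 0, n_coding_genes >= 1,
            n_ref_lncrna >= 0, n_lncrna >= 0, n_short >= 3)
  if (abs(sum(class_mix) - 1) > 1e-9)
    stop("class_mix proportions must sum to 1")
  if (any(class_mix < 0)) stop("class_mix proportions must be >= 0")
  bad <- setdiff(names(class_mix), POSITIONAL_CLASSES)
  if (length(bad)) stop("unknown positional class(es): ",
                        paste(bad, collapse = ", "))
  if (nb_dispersion <= 0) stop("nb_dispersion must be positive")
  structure(list(
    seed = as.integer(seed), n_chromosomes = as.integer(n_chromosomes),
    chrom_length = chrom_length, n_coding_genes = as.integer(n_coding_genes),
    n_ref_lncrna = as.integer(n_ref_lncrna), n_lncrna = as.integer(n_lncrna),
    known_frac = known_frac, n_coding_match = as.integer(n_coding_match),
    n_short = as.integer(n_short), class_mix = class_mix, design = design,
    planted_lfc = planted_lfc, n_de = as.integer(n_de), de_lfc = de_lfc,
    planted_cis = planted_cis, n_cis = as.integer(n_cis), cis_r = cis_r,
    nb_dispersion = nb_dispersion, mean_depth = mean_depth
  ), class = "sim_config")
}

## planted candidate count per class: every class with positive weight
## appears at least 5 times
class_counts <- function(cfg) {
  mix <- cfg$class_mix
  n <- ifelse(mix > 0, pmax(5L, round(mix * cfg$n_lncrna)), 0L)
  stats::setNames(as.integer(n), names(mix))
}

runi <- function(n, lo, hi) floor(stats::runif(n, lo, hi + 1))

#' Generate the reference and assembled annotations with planted truth
#'
#' Builds (i) a reference annotation of protein-coding genes (1-10
#' exons) plus a known-lncRNA catalogue, and (ii) an assembled candidate
#' annotation with lncRNAs planted in known positional classes, matches
#' of reference lncRNAs (known), matches of coding transcripts (to be
#' removed at the class-code stage) and sub-200-nt transcripts (to be
#' removed at the length stage). Identical configuration gives
#' byte-identical GTF output.
#'
#' @param cfg A [sim_config()].
#' @return A list `reference` (annotation_set), `assembled`
#'   (annotation_set), `truth` (data.frame: `feature_id`, `gene_id`,
#'   `feature_type`, `chrom`, `strand`, `length`, `positional_class`,
#'   `known_novel`, `coding_label`, `nearest_gene_id`,
#'   `nearest_gene_distance`).
#' @export
simulate_annotation <- function(cfg) {
  set.seed(stage_seed(cfg$seed, "annotation"))
  chroms <- paste0("chr", seq_len(cfg$n_chromosomes))

  ## --- reference coding genes, cursor placement per chromosome ---
  genes <- list(); gene_tx <- list()
  cursors <- stats::setNames(rep(50000, cfg$n_chromosomes), chroms)
  for (i in seq_len(cfg$n_coding_genes)) {
    chrom <- chroms[((i - 1L) %% cfg$n_chromosomes) + 1L]
    n_ex <- runi(1, 1, 10)
    ## exons >= 200 nt so every coding transcript clears the length
    ## filter and only the deliberately planted short features fail it
    ex_len <- runi(n_ex, 200, 400)
    in_len <- if (n_ex > 1L) runi(n_ex - 1L, 500, 3000) else numeric(0)
    pre_gap <- runi(1, 20000, 40000)
    g_start <- cursors[[chrom]] + pre_gap
    starts <- g_start + c(0, cumsum(ex_len[-n_ex] + in_len))
    exons <- cbind(starts, starts + ex_len)
    g_end <- max(exons[, 2L])
    if (g_end > cfg$chrom_length - 350000)
      stop("sizing error: cannot place coding gene CG",
           sprintf("%04d", i), " on ", chrom,
           " (chromosome too short)")
    gid <- sprintf("CG%04d", i)
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    genes[[gid]] <- list(gene = gid, chrom = chrom, start = g_start,
                         end = g_end, strand = strand, n_ex = n_ex,
                         pre_gap = pre_gap, exons = exons)
    gene_tx[[gid]] <- transcript_model(paste0(gid, ".t1"), chrom, strand,
                                       exons)
    cursors[[chrom]] <- g_end
  }

  ## --- reference lncRNA catalogue in the chromosome tails (3 exons,
  ## first exon >= 250 nt so contained matches stay >= 200 nt) ---
  tail_cursor <- cursors + 20000
  ref_lnc <- list()
  for (i in seq_len(cfg$n_ref_lncrna)) {
    chrom <- chroms[((i - 1L) %% cfg$n_chromosomes) + 1L]
    ex_len <- c(runi(1, 250, 450), runi(2, 150, 400))
    in_len <- runi(2, 300, 1500)
    start <- tail_cursor[[chrom]]
    starts <- start + c(0, cumsum(ex_len[-3L] + in_len))
    exons <- cbind(starts, starts + ex_len)
    if (max(exons[, 2L]) > cfg$chrom_length - 5000)
      stop("sizing error: cannot place reference lncRNA LREF",
           sprintf("%04d", i), " on ", chrom)
    strand <- if (stats::runif(1) < 0.5) "+" else "-"
    tid <- sprintf("LREF%04d.t1", i)
    ref_lnc[[tid]] <- transcript_model(tid, chrom, strand, exons)
    tail_cursor[[chrom]] <- max(exons[, 2L]) + runi(1, 6000, 10000)
  }

  ## reference annotation set
  ref_txs <- c(gene_tx, ref_lnc)
  ref_gene_of <- c(
    stats::setNames(names(gene_tx), vapply(gene_tx, `[[`, character(1), "id")),
    stats::setNames(sub("\\.t1$", "", names(ref_lnc)), names(ref_lnc))
  )
  ref_biotype <- c(
    stats::setNames(rep("protein_coding", length(gene_tx)), names(gene_tx)),
    stats::setNames(rep("lncRNA", length(ref_lnc)),
                    sub("\\.t1$", "", names(ref_lnc)))
  )
  reference <- annotation_set(unname(ref_txs), ref_gene_of, ref_biotype)

  ## --- planted candidates ---
  cand <- list(); truth_rows <- list()
  cand_i <- 0L
  add_candidate <- function(chrom, strand, exons, type, pclass, kn,
                            coding_label, ngene, ndist) {
    cand_i <<- cand_i + 1L
    tid <- sprintf("TCONS_%05d", cand_i)
    tx <- transcript_model(tid, chrom, strand, exons)
    cand[[tid]] <<- tx
    truth_rows[[tid]] <<- data.frame(
      feature_id = tid, gene_id = sprintf("XLOC_%05d", cand_i),
      feature_type = type, chrom = chrom, strand = strand,
      length = tx$length, positional_class = pclass, known_novel = kn,
      coding_label = coding_label, nearest_gene_id = ngene,
      nearest_gene_distance = ndist, stringsAsFactors = FALSE
    )
    tid
  }

  counts_per_class <- class_counts(cfg)
  gene_list <- genes[order(names(genes))]
  multi <- names(gene_list)[vapply(gene_list, `[[`, numeric(1), "n_ex") > 1]
  used_host <- character(0)
  next_host <- function(need_multi = FALSE) {
    pool <- setdiff(if (need_multi) multi else names(gene_list), used_host)
    if (!length(pool))
      stop("sizing error: not enough host genes for the requested class mix")
    h <- pool[1L]
    used_host <<- c(used_host, h)
    gene_list[[h]]
  }
  flank_slots <- stats::setNames(rep(0L, length(gene_list)), names(gene_list))

  plant_one <- function(class) {
    switch(class,
      intergenic_gt1kb = {
        ## pre-gap of a cycled gene, 2-12 kb upstream of its span;
        ## rotate over genes (least-used first) so consecutive intergenic
        ## candidates sit next to distinct genes
        avail <- names(flank_slots)[flank_slots < 3L]
        if (!length(avail))
          stop("sizing error: no intergenic slot left for a candidate")
        avail <- avail[order(flank_slots[avail], avail)]
        g <- gene_list[[avail[1L]]]
        slot <- flank_slots[[g$gene]]
        flank_slots[[g$gene]] <<- slot + 1L
        offset <- 2000 + slot * 4500
        n_ex <- runi(1, 1, 3)
        ex_len <- runi(n_ex, 200, 500)
        in_len <- if (n_ex > 1L) runi(n_ex - 1L, 200, 600) else numeric(0)
        span <- sum(ex_len) + sum(in_len)
        end <- g$start - offset
        starts <- (end - span) + c(0, cumsum(ex_len[-n_ex] + in_len))
        strand <- if (stats::runif(1) < 0.5) "+" else "-"
        add_candidate(g$chrom, strand, cbind(starts, starts + ex_len),
                      "candidate", class, "novel", "noncoding",
                      g$gene, offset)
      },
      exonic_overlap_sense = ,
      exonic_overlap_antisense = {
        ## multi-exon host so the same-strand overlap codes "o", not "="
        g <- next_host(need_multi = TRUE)
        ex <- g$exons[nrow(g$exons), , drop = FALSE]  # last exon
        start <- ex[1L] + 20
        end <- ex[2L] + runi(1, 150, 400)
        strand <- if (class == "exonic_overlap_sense") g$strand
                  else setdiff(c("+", "-"), g$strand)
        add_candidate(g$chrom, strand, cbind(start, end), "candidate",
                      class, "novel", "noncoding", g$gene, 0)
      },
      intronic_sense = ,
      intronic_antisense = {
        g <- next_host(need_multi = TRUE)
        i_s <- g$exons[1L, 2L]; i_e <- g$exons[2L, 1L]  # first intron
        len <- min(400, i_e - i_s - 100)
        start <- i_s + 50
        strand <- if (class == "intronic_sense") g$strand
                  else setdiff(c("+", "-"), g$strand)
        add_candidate(g$chrom, strand, cbind(start, start + len),
                      "candidate", class, "novel", "noncoding", g$gene, 0)
      },
      gene_in_lncrna_intron = {
        g <- next_host()
        exons <- rbind(c(g$start - 800, g$start - 500),
                       c(g$end + 500, g$end + 800))
        add_candidate(g$chrom, g$strand, exons, "candidate", class,
                      "novel", "noncoding", g$gene, 0)
      },
      upstream_1kb_sense = ,
      upstream_1kb_antisense = ,
      bidirectional_promoter_shared = ,
      downstream_1kb_sense = ,
      downstream_1kb_antisense = {
        g <- next_host()
        gap <- switch(class,
          upstream_1kb_sense = runi(1, 300, 1000),
          upstream_1kb_antisense = runi(1, 251, 1000),
          bidirectional_promoter_shared = runi(1, 10, 250),
          runi(1, 50, 1000))
        len <- runi(1, 250, 600)
        upstream <- grepl("upstream|bidirectional", class)
        ## upstream lies on the TSS side, downstream on the TES side
        left_side <- (g$strand == "+") == upstream
        exon <- if (left_side) {
          e <- (if (g$strand == "+") g$start else g$start) - gap
          c(e - len, e)
        } else {
          s <- g$end + gap
          c(s, s + len)
        }
        same <- class %in% c("upstream_1kb_sense", "downstream_1kb_sense")
        strand <- if (same) g$strand else setdiff(c("+", "-"), g$strand)
        add_candidate(g$chrom, strand, rbind(exon), "candidate", class,
                      "novel", "noncoding", g$gene, gap)
      },
      stop("unknown positional class: ", class))
  }
  for (cl in names(counts_per_class))
    for (k in seq_len(counts_per_class[[cl]])) plant_one(cl)

  ## --- known-lncRNA candidates: =, c, j matches of the catalogue ---
  k_known <- if (cfg$n_ref_lncrna > 0 && cfg$known_frac > 0)
    max(5L, round(cfg$known_frac * cfg$n_lncrna)) else 0L
  k_known <- min(k_known, cfg$n_ref_lncrna)
  variants <- c("=", "c", "j")
  for (i in seq_len(k_known)) {
    ref <- ref_lnc[[i]]
    v <- variants[((i - 1L) %% 3L) + 1L]
    exons <- switch(v,
      "=" = ref$exons,
      "c" = cbind(ref$exons[1L, 1L] + 10,
                  ref$exons[1L, 1L] + 10 + 220),
      "j" = rbind(ref$exons[1L, ],
                  c(ref$exons[2L, 1L], tx_end(ref) + 200)))
    ## nearest coding gene: the last gene on this chromosome (tail
    ## placement); distance recomputed downstream, > 1 kb by design
    gs_chr <- Filter(function(g) g$chrom == ref$chrom, gene_list)
    last_g <- gs_chr[[which.max(vapply(gs_chr, `[[`, numeric(1), "end"))]]
    add_candidate(ref$chrom, ref$strand, exons, "candidate",
                  "intergenic_gt1kb", "known", "noncoding",
                  last_g$gene, tx_start(ref) - last_g$end)
  }

  ## --- assembled matches of coding transcripts (removed by class code) ---
  for (i in seq_len(cfg$n_coding_match)) {
    g <- gene_list[[((i - 1L) %% length(gene_list)) + 1L]]
    add_candidate(g$chrom, g$strand, g$exons, "coding_match",
                  NA_character_, NA_character_, "coding", g$gene, 0)
  }

  ## --- sub-200-nt transcripts (removed by the length filter) ---
  for (i in seq_len(cfg$n_short)) {
    chrom <- chroms[((i - 1L) %% cfg$n_chromosomes) + 1L]
    start <- tail_cursor[[chrom]]
    len <- runi(1, 120, 180)
    if (start + len > cfg$chrom_length)
      stop("sizing error: cannot place short transcript on ", chrom)
    tail_cursor[[chrom]] <- start + len + 3000
    add_candidate(chrom, "+", cbind(start, start + len), "short",
                  NA_character_, NA_character_, "noncoding",
                  NA_character_, NA_real_)
  }

  truth <- do.call(rbind, truth_rows)
  rownames(truth) <- NULL
  assembled <- annotation_set(
    unname(cand),
    stats::setNames(truth$gene_id, truth$feature_id),
    stats::setNames(rep("other_ncRNA", nrow(truth)), truth$gene_id)
  )
  ## reference truth rows (sequences are generated for these too)
  ref_ids <- vapply(ref_txs, `[[`, character(1), "id")
  names(ref_txs) <- ref_ids
  ref_truth <- data.frame(
    feature_id = ref_ids,
    gene_id = unname(ref_gene_of[ref_ids]),
    feature_type = ifelse(grepl("^CG", ref_ids),
                          "reference_coding", "reference_lncrna"),
    chrom = vapply(ref_txs, `[[`, character(1), "chrom"),
    strand = vapply(ref_txs, `[[`, character(1), "strand"),
    length = vapply(ref_txs, `[[`, numeric(1), "length"),
    positional_class = NA_character_, known_novel = NA_character_,
    coding_label = ifelse(grepl("^CG", names(ref_txs)),
                          "coding", "noncoding"),
    nearest_gene_id = NA_character_, nearest_gene_distance = NA_real_,
    stringsAsFactors = FALSE, row.names = NULL
  )
  truth <- rbind(truth, ref_truth)
  list(reference = reference, assembled = assembled, truth = truth)
}

## fixed codon-usage weights for the coding sequence model: GC-rich third
## positions and purine-leaning first positions, stops excluded
codon_weights <- function() {
  b <- c("A", "C", "G", "T")
  codons <- as.vector(outer(as.vector(outer(b, b, paste0)), b, paste0))
  codons <- setdiff(codons, c("TAA", "TAG", "TGA"))
  w <- 0.3 + 2.0 * (substr(codons, 3L, 3L) %in% c("G", "C")) +
    0.7 * (substr(codons, 1L, 1L) %in% c("A", "G"))
  stats::setNames(w / sum(w), codons)
}

NONCODING_BASE_PROB <- c(A = 0.30, C = 0.20, G = 0.20, T = 0.30)

random_noncoding <- function(n) {
  if (n <= 0L) return("")
  paste(sample(names(NONCODING_BASE_PROB), n, replace = TRUE,
               prob = NONCODING_BASE_PROB), collapse = "")
}

## one coding sequence of total length n: ORF covers >= orf_frac of it
random_coding <- function(n, orf_frac = stats::runif(1, 0.6, 0.9)) {
  cw <- codon_weights()
  orf_nt <- max(3L * floor(orf_frac * n / 3), 3L * ceiling(0.5 * n / 3))
  n_codons <- orf_nt %/% 3L - 2L  # minus ATG and stop
  orf <- paste0("ATG",
                paste(sample(names(cw), max(n_codons, 1L), replace = TRUE,
                             prob = cw), collapse = ""),
                "TAA")
  rest <- n - nchar(orf)
  utr5 <- max(0L, rest %/% 2L); utr3 <- max(0L, rest - utr5)
  ## UTRs must not harbour an upstream ATG creating a longer frame; a
  ## plain noncoding fill is fine (the planted ORF dominates by length)
  paste0(random_noncoding(utr5), orf, random_noncoding(utr3))
}

#' Generate transcript sequences for every feature in the truth table
#'
#' Coding-labelled features receive a sequence with a long in-frame ORF
#' (>= 50% of the transcript) sampled from a codon-biased model;
#' noncoding features are sampled from a near-uniform base model. Lengths
#' follow the annotated transcript lengths (the planted sub-200-nt
#' features keep their short lengths).
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [simulate_annotation()].
#' @return A named character vector of A/C/G/T sequences (one per
#'   feature id).
#' @export
simulate_sequences <- function(cfg, truth) {
  set.seed(stage_seed(cfg$seed, "sequences"))
  seqs <- character(nrow(truth))
  for (i in seq_len(nrow(truth))) {
    n <- truth$length[i]
    seqs[i] <- if (truth$coding_label[i] == "coding")
      random_coding(n) else random_noncoding(n)
  }
  stats::setNames(seqs, truth$feature_id)
}

#' Generate labelled training sequences for the coding-potential model
#'
#' Standalone draw from the same coding/noncoding sequence models,
#' suitable for training and held-out evaluation of the classifier.
#'
#' @param n_coding,n_noncoding Number of sequences per class.
#' @param length_range Length range in nt (default 200-3000).
#' @param seed Integer seed.
#' @return A list `seqs` (named character vector) and `labels`
#'   (`"coding"`/`"noncoding"`).
#' @export
simulate_labeled_sequences <- function(n_coding, n_noncoding,
                                       length_range = c(200, 3000),
                                       seed = 1L) {
  set.seed(stage_seed(seed, "training"))
  lens_c <- runi(n_coding, length_range[1L], length_range[2L])
  lens_n <- runi(n_noncoding, length_range[1L], length_range[2L])
  seqs <- c(vapply(lens_c, function(n) random_coding(n), character(1)),
            vapply(lens_n, random_noncoding, character(1)))
  labels <- c(rep("coding", n_coding), rep("noncoding", n_noncoding))
  names(seqs) <- sprintf("TRAIN_%s_%04d", ifelse(labels == "coding", "C", "N"),
                         seq_along(seqs))
  list(seqs = seqs, labels = labels)
}

## resolve the default planted-effect plans against a generated truth
resolve_plants <- function(cfg, truth) {
  cand <- truth[truth$feature_type == "candidate" &
                  !is.na(truth$positional_class), ]
  eligible <- cand[cand$positional_class == "intergenic_gt1kb" &
                     cand$known_novel == "novel" &
                     !is.na(cand$nearest_gene_distance) &
                     cand$nearest_gene_distance <= 50000, ]
  cis <- cfg$planted_cis
  if (is.null(cis)) {
    ## one pair per partner gene so latent factors never stack
    pool <- eligible[!duplicated(eligible$nearest_gene_id), ]
    n <- min(cfg$n_cis, nrow(pool))
    take <- pool[seq_len(n), ]
    cis <- data.frame(lncrna_id = take$feature_id,
                      gene_id = take$nearest_gene_id,
                      r = rep_len(cfg$cis_r, n), stringsAsFactors = FALSE)
  }
  if (nrow(cis)) {
    d <- truth$nearest_gene_distance[match(cis$lncrna_id, truth$feature_id)]
    own <- truth$nearest_gene_id[match(cis$lncrna_id, truth$feature_id)]
    bad <- which(own != cis$gene_id | is.na(d) | d > 50000)
    if (length(bad))
      stop("planted cis pair outside the 50 kb window: ",
           cis$lncrna_id[bad[1L]], " / ", cis$gene_id[bad[1L]])
  }
  lfc <- cfg$planted_lfc
  if (is.null(lfc)) {
    pool <- setdiff(eligible$feature_id, cis$lncrna_id)
    n <- min(cfg$n_de, length(pool))
    days <- cfg$design$days
    pairs <- utils::combn(days, 2L, simplify = FALSE)
    combos <- expand.grid(tr = cfg$design$treatments,
                          pair = seq_along(pairs),
                          stringsAsFactors = FALSE)
    idx <- ((seq_len(n) - 1L) %% nrow(combos)) + 1L
    lfc <- data.frame(
      feature_id = pool[seq_len(n)],
      treatment = combos$tr[idx],
      dayA = vapply(combos$pair[idx], function(k) pairs[[k]][1L], character(1)),
      dayB = vapply(combos$pair[idx], function(k) pairs[[k]][2L], character(1)),
      log2fc = cfg$de_lfc * (-1)^(seq_len(n) - 1L),
      stringsAsFactors = FALSE
    )
  }
  list(cis = cis, lfc = lfc)
}

## Counts for one cis pair at latent scale sigma: the pair shares a
## per-library factor exp(sigma z - sigma^2/2); the NB draws reuse fixed
## uniform quantiles so the whole map sigma -> counts is deterministic
## and (nearly) monotone, which makes the realized correlation a
## searchable function of sigma.
cis_pair_counts <- function(sigma, muL, muG, z, uL, uG, alpha) {
  fac <- exp(sigma * z - sigma^2 / 2)
  list(kL = stats::qnbinom(uL, mu = muL * fac, size = 1 / alpha),
       kG = stats::qnbinom(uG, mu = muG * fac, size = 1 / alpha))
}

## 1-D search for the latent scale sigma that makes the realized
## log-scale Pearson correlation of THIS draw (over one treatment's
## library block, n = 18 in the default design) match the target r
calibrate_cis_sigma <- function(target, muL, muG, z, uL, uG, alpha, s) {
  realized <- function(sigma) {
    k <- cis_pair_counts(sigma, muL, muG, z, uL, uG, alpha)
    eL <- log2(k$kL / s + 1); eG <- log2(k$kG / s + 1)
    if (stats::sd(eL) == 0 || stats::sd(eG) == 0) return(0)
    stats::cor(eL, eG)
  }
  f <- function(sigma) realized(sigma) - target
  lo <- 1e-3; hi <- 3
  if (f(lo) >= 0) return(lo)
  if (f(hi) <= 0) return(hi)
  stats::uniroot(f, lower = lo, upper = hi, tol = 1e-4)$root
}

#' Generate the fragment count matrix and library design
#'
#' Draws negative-binomial counts for every candidate transcript and
#' every coding gene over the full 2-treatment x 3-day x
#' `cows_per_treatment` design. Planted log2 fold changes scale the mean
#' of the affected treatment/day libraries; planted cis pairs share a
#' lognormal latent factor whose variance is calibrated by a
#' one-dimensional search so the realized log-scale Pearson correlation
#' approximates the target at the per-treatment sample size.
#'
#' @param cfg A [sim_config()].
#' @param truth Truth table from [simulate_annotation()].
#' @return A list: `counts` (a [count_matrix()]), `design` (data.frame
#'   `library_id`, `cow`, `treatment`, `day`), `planted_lfc`,
#'   `planted_cis` (resolved plans), `true_size_factors`.
#' @export
simulate_counts <- function(cfg, truth) {
  if (cfg$nb_dispersion <= 0) stop("nb_dispersion must be positive")
  set.seed(stage_seed(cfg$seed, "counts"))
  plants <- resolve_plants(cfg, truth)

  ## features: candidate transcripts + coding genes (gene-level mRNA rows)
  cand <- truth[truth$feature_type %in% c("candidate", "coding_match",
                                          "short"), ]
  genes <- truth[truth$feature_type == "reference_coding", ]
  feat_ids <- c(cand$feature_id, genes$gene_id)
  feat_len <- c(stats::setNames(cand$length, cand$feature_id),
                stats::setNames(genes$length, genes$gene_id))

  des <- expand.grid(cow = seq_len(cfg$design$cows_per_treatment),
                     day = cfg$design$days,
                     treatment = cfg$design$treatments,
                     stringsAsFactors = FALSE)
  design <- data.frame(
    library_id = sprintf("%s_%s_c%d", des$treatment, des$day, des$cow),
    cow = sprintf("%s_cow%d", des$treatment, des$cow),
    treatment = des$treatment, day = des$day, stringsAsFactors = FALSE
  )
  n_lib <- nrow(design); n_feat <- length(feat_ids)

  ## relative abundances; planted features are lifted to the upper range
  ## so they survive the expression filter
  w <- stats::rlnorm(n_feat, 0, 1.3)
  names(w) <- feat_ids
  planted_ids <- unique(c(plants$lfc$feature_id, plants$cis$lncrna_id,
                          plants$cis$gene_id))
  w[planted_ids] <- pmax(w[planted_ids], stats::quantile(w, 0.6))
  w <- w / sum(w)
  mu0 <- cfg$mean_depth * w

  ## library depth factors, centred on geometric mean 1
  s <- exp(stats::rnorm(n_lib, 0, 0.15))
  s <- s / exp(mean(log(s)))
  names(s) <- design$library_id

  ## mean matrix with planted effects
  M <- matrix(rep(mu0, n_lib), nrow = n_feat,
              dimnames = list(feat_ids, design$library_id))
  M <- sweep(M, 2L, s, "*")
  for (k in seq_len(nrow(plants$lfc))) {
    p <- plants$lfc[k, ]
    libs <- design$library_id[design$treatment == p$treatment &
                                design$day == p$dayB]
    M[p$feature_id, libs] <- M[p$feature_id, libs] * 2^p$log2fc
  }
  counts <- matrix(stats::rnbinom(n_feat * n_lib, mu = M,
                                  size = 1 / cfg$nb_dispersion),
                   nrow = n_feat,
                   dimnames = list(feat_ids, design$library_id))

  ## cis pairs: replace both members' rows with draws sharing a latent
  ## factor; each treatment block gets its own calibrated scale so the
  ## realized within-treatment correlation of the log-normalized values
  ## matches the target
  treat_blocks <- lapply(cfg$design$treatments, function(tr)
    which(design$treatment == tr))
  for (k in seq_len(nrow(plants$cis))) {
    p <- plants$cis[k, ]
    z <- stats::rnorm(n_lib)
    uL <- stats::runif(n_lib); uG <- stats::runif(n_lib)
    muL <- M[p$lncrna_id, ]; muG <- M[p$gene_id, ]
    for (b in treat_blocks) {
      sig <- calibrate_cis_sigma(p$r, muL[b], muG[b], z[b], uL[b], uG[b],
                                 cfg$nb_dispersion, s[b])
      kk <- cis_pair_counts(sig, muL[b], muG[b], z[b], uL[b], uG[b],
                            cfg$nb_dispersion)
      counts[p$lncrna_id, b] <- kk$kL
      counts[p$gene_id, b] <- kk$kG
    }
  }
  list(counts = count_matrix(counts, feat_len), design = design,
       planted_lfc = plants$lfc, planted_cis = plants$cis,
       true_size_factors = s)
}

#' Write every synthetic input to disk
#'
#' Emits the reference GTF, assembled GTF, transcript FASTA, count TSV,
#' library-design TSV and truth-table TSV, all byte-deterministic for a
#' fixed configuration.
#'
#' @param cfg A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
simulate_to_dir <- function(cfg, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  ann <- simulate_annotation(cfg)
  seqs <- simulate_sequences(cfg, ann$truth)
  cm <- simulate_counts(cfg, ann$truth)
  write_gtf(ann$reference, file.path(dir, "reference.gtf"))
  write_gtf(ann$assembled, file.path(dir, "assembled.gtf"))
  Biostrings::writeXStringSet(Biostrings::DNAStringSet(seqs),
                              file.path(dir, "transcripts.fa"))
  utils::write.table(data.frame(feature_id = rownames(cm$counts$counts),
                                cm$counts$counts, check.names = FALSE),
                     file.path(dir, "counts.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cm$design, file.path(dir, "design.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(ann$truth, file.path(dir, "truth.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(list(annotation = ann, sequences = seqs, counts = cm))
}
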