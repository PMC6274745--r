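#' The 11-class positional taxonomy
#'
#' Genomic-location/orientation classes of a lncRNA relative to
#' protein-coding annotation, in precedence order (highest first):
#' exonic overlap (sense/antisense), intronic (sense/antisense), a coding
#' gene inside a lncRNA intron, upstream within 1 kb (sense/antisense),
#' downstream within 1 kb (sense/antisense), shared bidirectional
#' promoter, and intergenic at more than 1 kb. Sense/antisense is strand
#' equality with the classified gene.
#'
#' `upstream_1kb_antisense` covers divergent lncRNAs whose gap to the gene
#' TSS is in (250, 1000] bp; `bidirectional_promoter_shared` covers the
#' tight head-to-head arrangement with a gap of at most 250 bp, the scale
#' at which two transcripts plausibly share one promoter. The two are
#' disjoint by construction.
#'
#' @format Character vector of the 11 class names.
#' @export
POSITIONAL_CLASSES <- c(
  "exonic_overlap_sense", "exonic_overlap_antisense",
  "intronic_sense", "intronic_antisense",
  "gene_in_lncrna_intron",
  "upstream_1kb_sense", "upstream_1kb_antisense",
  "downstream_1kb_sense", "downstream_1kb_antisense",
  "bidirectional_promoter_shared",
  "intergenic_gt1kb"
)

## minimal gap between two spans (0 if they overlap), 0-based half-open
span_gap <- function(s1, e1, s2, e2) {
  if (s1 < e2 && s2 < e1) return(0)
  max(s2 - e1, s1 - e2, 0)
}

## classify lncRNA against ONE gene (its transcripts), returning the class
## this gene supports (or NA) plus the span distance
classify_vs_gene <- function(lnc, gtxs, gspan) {
  same <- lnc$strand == gspan$strand
  dist <- span_gap(tx_start(lnc), tx_end(lnc), gspan$start, gspan$end)
  ori <- if (same) "sense" else "antisense"

  ## exonic overlap with any transcript of the gene
  if (any(vapply(gtxs, exonic_overlap, logical(1), a = lnc)))
    return(list(class = paste0("exonic_overlap_", ori), distance = dist))

  ## lncRNA entirely inside one intron of a gene transcript
  for (g in gtxs) {
    gi <- tx_introns(g)
    if (nrow(gi) &&
        any(gi[, 1L] <= tx_start(lnc) & tx_end(lnc) <= gi[, 2L]))
      return(list(class = paste0("intronic_", ori), distance = dist))
  }
  ## looser intronic: contained in the gene span with no exon overlap
  if (gspan$start <= tx_start(lnc) && tx_end(lnc) <= gspan$end)
    return(list(class = paste0("intronic_", ori), distance = dist))

  ## whole gene inside one intron of the lncRNA
  li <- tx_introns(lnc)
  if (nrow(li) &&
      any(li[, 1L] <= gspan$start & gspan$end <= li[, 2L]))
    return(list(class = "gene_in_lncrna_intron", distance = dist))

  ## non-overlapping (or boundary-straddling) flank geometry, measured
  ## from the lncRNA's nearest boundary to the gene's TSS/TES on the
  ## gene's strand
  tss <- if (gspan$strand == "+") gspan$start else gspan$end
  tes <- if (gspan$strand == "+") gspan$end else gspan$start
  lnc_upstream <- if (gspan$strand == "+") tx_end(lnc) <= gspan$start
                  else tx_start(lnc) >= gspan$end
  lnc_downstream <- if (gspan$strand == "+") tx_start(lnc) >= gspan$end
                    else tx_end(lnc) <= gspan$start
  if (lnc_upstream) {
    gap <- if (gspan$strand == "+") tss - tx_end(lnc) else tx_start(lnc) - tss
    if (gap <= 250 && !same)
      return(list(class = "bidirectional_promoter_shared", distance = dist))
    if (gap <= 1000)
      return(list(class = paste0("upstream_1kb_", ori), distance = dist))
  } else if (lnc_downstream) {
    gap <- if (gspan$strand == "+") tx_start(lnc) - tes else tes - tx_end(lnc)
    if (gap <= 1000)
      return(list(class = paste0("downstream_1kb_", ori), distance = dist))
  } else {
    ## straddles a gene boundary without exon overlap or containment:
    ## treat as the flank whose boundary it straddles, distance 0
    str_tss <- tx_start(lnc) <= tss && tss <= tx_end(lnc)
    return(list(class = paste0(if (str_tss) "upstream_1kb_"
                               else "downstream_1kb_", ori),
                distance = dist))
  }
  list(class = NA_character_, distance = dist)
}

#' Positionally classify a lncRNA against protein-coding annotation
#'
#' Assigns one of the 11 positional classes (see [POSITIONAL_CLASSES]),
#' resolving multi-gene eligibility by class precedence and, within a
#' class, by smaller distance. The reported distance is the minimal gap
#' between the lncRNA span and the nearest gene span (0 when they
#' overlap); `intergenic_gt1kb` implies distance > 1000 bp.
#'
#' @param lncrna A [transcript_model()].
#' @param coding An [annotation_set()] of protein-coding genes.
#' @param window_kb Flank window in kb for the upstream/downstream classes
#'   (default 1; currently informational, the taxonomy is defined at 1 kb).
#' @return A list `lncrna_id`, `class`, `nearest_gene_id`, `distance`.
#' @export
classify_position <- function(lncrna, coding, window_kb = 1) {
  gs <- gene_spans(coding)
  gs <- gs[gs$chrom == lncrna$chrom, , drop = FALSE]
  if (!nrow(gs)) {
    warning("lncRNA ", lncrna$id,
            " lies on a chromosome absent from the coding annotation")
    return(list(lncrna_id = lncrna$id, class = "intergenic_gt1kb",
                nearest_gene_id = NA_character_, distance = Inf))
  }
  tx_by_gene <- split(coding$transcripts, unname(coding$gene_of))
  best <- NULL; best_rank <- length(POSITIONAL_CLASSES) + 1L
  nearest_gene <- NA_character_; nearest_dist <- Inf
  for (i in seq_len(nrow(gs))) {
    res <- classify_vs_gene(lncrna, tx_by_gene[[gs$gene[i]]], gs[i, ])
    if (res$distance < nearest_dist) {
      nearest_dist <- res$distance; nearest_gene <- gs$gene[i]
    }
    if (!is.na(res$class)) {
      rank <- match(res$class, POSITIONAL_CLASSES)
      if (rank < best_rank ||
          (rank == best_rank && res$distance < best$distance)) {
        best_rank <- rank
        best <- list(gene = gs$gene[i], class = res$class,
                     distance = res$distance)
      }
    }
  }
  if (is.null(best))
    return(list(lncrna_id = lncrna$id, class = "intergenic_gt1kb",
                nearest_gene_id = nearest_gene, distance = nearest_dist))
  list(lncrna_id = lncrna$id, class = best$class,
       nearest_gene_id = best$gene, distance = best$distance)
}

#' Positional classification report for a set of lncRNAs
#'
#' @param lncrnas An [annotation_set()] of lncRNA transcripts.
#' @param coding An [annotation_set()] of protein-coding genes.
#' @return A data.frame with `lncrna_id`, `class`, `nearest_gene_id`,
#'   `distance`, plus an attribute `class_freq` — the class-frequency
#'   summary (count and percentage per class).
#' @export
classify_positions <- function(lncrnas, coding) {
  res <- lapply(lncrnas$transcripts, classify_position, coding = coding)
  out <- data.frame(
    lncrna_id = vapply(res, `[[`, character(1), "lncrna_id"),
    class = vapply(res, `[[`, character(1), "class"),
    nearest_gene_id = vapply(res, `[[`, character(1), "nearest_gene_id"),
    distance = vapply(res, `[[`, numeric(1), "distance"),
    stringsAsFactors = FALSE, row.names = NULL
  )
  counts <- table(factor(out$class, levels = POSITIONAL_CLASSES))
  attr(out, "class_freq") <- data.frame(
    class = names(counts), n = as.integer(counts),
    pct = round(100 * as.integer(counts) / max(1L, nrow(out)), 2),
    stringsAsFactors = FALSE
  )
  out
}
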