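#' Construct a transcript model
#'
#' A transcript model is the unit of all exon-chain comparisons: an ordered
#' set of exons on one strand of one chromosome. Coordinates are 0-based
#' half-open internally; GTF input/output converts to and from the 1-based
#' inclusive convention.
#'
#' @param id Transcript identifier (unique within an annotation set).
#' @param chrom Chromosome name.
#' @param strand `"+"` or `"-"`.
#' @param exons Two-column matrix (start, end) of 0-based half-open exon
#'   coordinates. Rows need not be pre-sorted; they are sorted on
#'   construction. Exons must not overlap or abut (introns are >= 1 bp).
#' @return An object of class `transcript_model` with fields `id`, `chrom`,
#'   `strand`, `exons` (sorted matrix) and `length` (sum of exon widths, nt).
#' @examples
#' tx <- transcript_model("t1", "chr1", "+", cbind(c(0, 300), c(100, 500)))
#' tx$length  # 300
#' @export
transcript_model <- function(id, chrom, strand, exons) {
  if (!is.character(id) || length(id) != 1L || !nzchar(id))
    stop("transcript id must be a non-empty string")
  if (!strand %in% c("+", "-"))
    stop("strand must be '+' or '-' for transcript ", id)
  exons <- matrix(as.numeric(exons), ncol = 2L,
                  dimnames = list(NULL, c("start", "end")))
  if (nrow(exons) < 1L) stop("transcript ", id, " has no exons")
  exons <- exons[order(exons[, 1L]), , drop = FALSE]
  if (any(exons[, 2L] <= exons[, 1L]))
    stop("transcript ", id, " has an empty or inverted exon")
  if (nrow(exons) > 1L) {
    gaps <- exons[-1L, 1L] - exons[-nrow(exons), 2L]
    if (any(gaps < 1))
      stop("transcript ", id, " has overlapping or abutting exons")
  }
  structure(
    list(id = id, chrom = chrom, strand = strand, exons = exons,
         length = sum(exons[, 2L] - exons[, 1L])),
    class = "transcript_model"
  )
}

#' @export
print.transcript_model <- function(x, ...) {
  cat(sprintf("<transcript_model> %s %s:%d-%d(%s) %d exon(s), %d nt\n",
              x$id, x$chrom, tx_start(x), tx_end(x), x$strand,
              nrow(x$exons), x$length))
  invisible(x)
}

## span accessors (0-based half-open)
tx_start <- function(tx) tx$exons[1L, 1L]
tx_end <- function(tx) tx$exons[nrow(tx$exons), 2L]

## introns as a (possibly empty) 2-column matrix
tx_introns <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(matrix(numeric(0), ncol = 2L))
  cbind(tx$exons[-n, 2L], tx$exons[-1L, 1L])
}

## splice sites in chain order: c(end1, start2, end2, start3, ...)
tx_splice_chain <- function(tx) {
  n <- nrow(tx$exons)
  if (n < 2L) return(numeric(0))
  as.vector(t(tx_introns(tx)))
}

#' Construct an annotation set
#'
#' Bundles transcript models with their gene assignment and gene biotype,
#' the substrate for class-code assignment, positional classification and
#' window queries.
#'
#' @param transcripts List of [transcript_model()] objects.
#' @param gene_of Named character vector mapping transcript id to gene id.
#'   Defaults to one gene per transcript (gene id = transcript id).
#' @param biotype Named character vector mapping gene id to one of
#'   `"protein_coding"`, `"lncRNA"`, `"other_ncRNA"`. Defaults to
#'   `"protein_coding"` for every gene.
#' @return An object of class `annotation_set` with fields `transcripts`
#'   (named list), `gene_of`, `biotype`.
#' @export
annotation_set <- function(transcripts, gene_of = NULL, biotype = NULL) {
  ids <- vapply(transcripts, `[[`, character(1), "id")
  if (anyDuplicated(ids))
    stop("duplicate transcript ids: ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  names(transcripts) <- ids
  if (is.null(gene_of)) gene_of <- stats::setNames(ids, ids)
  missing_map <- setdiff(ids, names(gene_of))
  if (length(missing_map))
    stop("transcripts without a gene mapping: ",
         paste(missing_map, collapse = ", "))
  gene_of <- gene_of[ids]
  genes <- unique(unname(gene_of))
  if (is.null(biotype))
    biotype <- stats::setNames(rep("protein_coding", length(genes)), genes)
  bad <- setdiff(unique(unname(biotype)),
                 c("protein_coding", "lncRNA", "other_ncRNA"))
  if (length(bad)) stop("unknown biotype(s): ", paste(bad, collapse = ", "))
  structure(list(transcripts = transcripts, gene_of = gene_of,
                 biotype = biotype),
            class = "annotation_set")
}

#' @export
print.annotation_set <- function(x, ...) {
  cat(sprintf("<annotation_set> %d transcript(s), %d gene(s)\n",
              length(x$transcripts), length(unique(x$gene_of))))
  invisible(x)
}

#' Subset an annotation set by gene biotype
#'
#' @param ann An [annotation_set()].
#' @param biotypes Character vector of biotypes to keep.
#' @return An `annotation_set` restricted to transcripts of genes with the
#'   requested biotypes.
#' @export
annotation_subset <- function(ann, biotypes) {
  keep_genes <- names(ann$biotype)[ann$biotype %in% biotypes]
  keep_tx <- names(ann$gene_of)[ann$gene_of %in% keep_genes]
  annotation_set(ann$transcripts[keep_tx],
                 ann$gene_of[keep_tx],
                 ann$biotype[keep_genes])
}

## gene spans (union of transcript spans), as a data.frame
gene_spans <- function(ann) {
  tx <- ann$transcripts
  df <- data.frame(
    gene = unname(ann$gene_of),
    chrom = vapply(tx, `[[`, character(1), "chrom"),
    start = vapply(tx, tx_start, numeric(1)),
    end = vapply(tx, tx_end, numeric(1)),
    strand = vapply(tx, `[[`, character(1), "strand"),
    stringsAsFactors = FALSE
  )
  out <- do.call(rbind, lapply(split(df, df$gene), function(g) {
    data.frame(gene = g$gene[1L], chrom = g$chrom[1L],
               start = min(g$start), end = max(g$end),
               strand = g$strand[1L], stringsAsFactors = FALSE)
  }))
  rownames(out) <- out$gene
  out
}

#' Write an annotation set as GTF
#'
#' Emits one `exon` feature line per exon with `gene_id`, `transcript_id`
#' and `gene_biotype` attributes, converting internal 0-based half-open
#' coordinates to the 1-based inclusive GTF convention. Output is fully
#' deterministic (transcripts in list order, exons left to right), so a
#' generator run under a fixed seed reproduces the file byte for byte.
#'
#' @param ann An [annotation_set()].
#' @param path Output file path.
#' @return `path`, invisibly.
#' @export
write_gtf <- function(ann, path) {
  lines <- unlist(lapply(ann$transcripts, function(tx) {
    gene <- unname(ann$gene_of[[tx$id]])
    bt <- unname(ann$biotype[[gene]])
    sprintf(
      '%s\tbovlnc\texon\t%d\t%d\t.\t%s\t.\tgene_id "%s"; transcript_id "%s"; gene_biotype "%s";',
      tx$chrom, as.integer(tx$exons[, 1L]) + 1L, as.integer(tx$exons[, 2L]),
      tx$strand, gene, tx$id, bt
    )
  }), use.names = FALSE)
  writeLines(lines, path)
  invisible(path)
}

#' Read a GTF file into an annotation set
#'
#' Exon features are grouped by `transcript_id`; 1-based inclusive GTF
#' coordinates are converted to the internal 0-based half-open convention.
#' A `gene_biotype` attribute is honoured when present, otherwise every
#' gene defaults to `protein_coding`.
#'
#' @param path GTF file path.
#' @return An [annotation_set()].
#' @export
read_gtf <- function(path) {
  gr <- rtracklayer::import(path, format = "gtf")
  gr <- gr[gr$type == "exon"]
  if (!length(gr)) stop("no exon features in ", path)
  tid <- as.character(gr$transcript_id)
  gid <- as.character(gr$gene_id)
  bt <- if (!is.null(gr$gene_biotype)) as.character(gr$gene_biotype)
        else rep("protein_coding", length(gr))
  starts <- BiocGenerics::start(gr) - 1L  # to 0-based half-open
  ends <- BiocGenerics::end(gr)
  chrom <- as.character(GenomicRanges::seqnames(gr))
  strand <- as.character(BiocGenerics::strand(gr))
  idx <- split(seq_along(gr), tid)
  txs <- lapply(names(idx), function(id) {
    i <- idx[[id]]
    transcript_model(id, chrom[i[1L]], strand[i[1L]],
                     cbind(starts[i], ends[i]))
  })
  first <- vapply(idx, `[`, integer(1), 1L)
  gene_of <- stats::setNames(gid[first], names(idx))
  gene_first <- tapply(seq_along(gr), gid, `[`, 1L)
  biotype <- stats::setNames(bt[gene_first], names(gene_first))
  annotation_set(txs, gene_of, biotype)
}
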