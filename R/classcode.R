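## Exon-chain class codes in the cuffcompare tradition, restricted to the
## seven codes the identification cascade consumes. Precedence, most
## specific first:
CLASS_CODE_PRECEDENCE <- c("=", "c", "j", "o", "x", "i", "u")

## does any exon of a overlap any exon of b (>= 1 shared base)?
exonic_overlap <- function(a, b) {
  for (i in seq_len(nrow(a$exons))) {
    if (any(a$exons[i, 1L] < b$exons[, 2L] & b$exons[, 1L] < a$exons[i, 2L]))
      return(TRUE)
  }
  FALSE
}

## class code for one (query, reference transcript) pair, or NA if unrelated
pair_class_code <- function(q, r) {
  if (q$chrom != r$chrom) return(NA_character_)
  same_strand <- q$strand == r$strand
  qn <- nrow(q$exons); rn <- nrow(r$exons)
  q_chain <- tx_splice_chain(q); r_chain <- tx_splice_chain(r)
  ex_ov <- exonic_overlap(q, r)

  ## "=": identical intron chain; single-exon queries match single-exon
  ## references by exonic overlap on the same strand
  if (same_strand) {
    if (qn > 1L && rn > 1L &&
        length(q_chain) == length(r_chain) && all(q_chain == r_chain))
      return("=")
    if (qn == 1L && rn == 1L && ex_ov)
      return("=")
  }

  ## "c": contained, internal splice sites matching. Single-exon query:
  ## inside one reference exon. Multi-exon query: intron chain is a
  ## consecutive sub-chain of the reference's and the query span is
  ## contained in the reference span.
  if (same_strand) {
    if (qn == 1L && rn > 1L &&
        any(r$exons[, 1L] <= tx_start(q) & tx_end(q) <= r$exons[, 2L]))
      return("c")
    if (qn > 1L && rn > qn &&
        tx_start(q) >= tx_start(r) && tx_end(q) <= tx_end(r)) {
      nq <- length(q_chain); nr <- length(r_chain)
      for (off in seq(1L, nr - nq + 1L, by = 2L)) {
        if (all(r_chain[off:(off + nq - 1L)] == q_chain)) return("c")
      }
    }
  }

  ## "j": at least one shared splice junction (identical intron), chains
  ## not matching (the cases above)
  if (same_strand && qn > 1L && rn > 1L) {
    qi <- tx_introns(q); ri <- tx_introns(r)
    shared <- outer(qi[, 1L], ri[, 1L], "==") & outer(qi[, 2L], ri[, 2L], "==")
    if (any(shared)) return("j")
  }

  if (ex_ov) return(if (same_strand) "o" else "x")

  ## "i": query entirely inside one intron of the reference, either strand
  ri <- tx_introns(r)
  if (nrow(ri) &&
      any(ri[, 1L] <= tx_start(q) & tx_end(q) <= ri[, 2L]))
    return("i")

  NA_character_
}

#' Assign a class code to an assembled transcript
#'
#' Compares one query transcript against every transcript of a reference
#' annotation and returns the single highest-precedence class code, with
#' precedence `=` > `c` > `j` > `o` > `x` > `i` > `u`:
#'
#' * `=` complete match of the intron chain (single-exon queries: exonic
#'   overlap with a single-exon reference on the same strand),
#' * `c` contained in a reference transcript with matching internal splice
#'   sites,
#' * `j` shares at least one splice junction (a novel isoform),
#' * `o` generic same-strand exonic overlap,
#' * `x` exonic overlap on the opposite strand,
#' * `i` lies entirely within a reference intron (either strand),
#' * `u` intergenic: none of the above.
#'
#' @param query A [transcript_model()].
#' @param reference An [annotation_set()].
#' @return A list with `query_id`, `code` and `ref_id` (the reference
#'   transcript yielding the code; `NA` when the code is `u`).
#' @examples
#' ref <- annotation_set(list(
#'   transcript_model("r1", "chr1", "+", cbind(c(0, 500), c(200, 800)))))
#' q <- transcript_model("q1", "chr1", "+", cbind(c(10, 500), c(200, 700)))
#' assign_class_code(q, ref)$code  # "=" (same intron chain)
#' @export
assign_class_code <- function(query, reference) {
  if (!inherits(query, "transcript_model"))
    stop("query must be a transcript_model")
  best_code <- "u"; best_ref <- NA_character_
  best_rank <- match("u", CLASS_CODE_PRECEDENCE)
  for (r in reference$transcripts) {
    code <- pair_class_code(query, r)
    if (is.na(code)) next
    rank <- match(code, CLASS_CODE_PRECEDENCE)
    if (rank < best_rank) {
      best_rank <- rank; best_code <- code; best_ref <- r$id
      if (rank == 1L) break
    }
  }
  list(query_id = query$id, code = best_code, ref_id = best_ref)
}

#' Class codes for every transcript of an assembled set
#'
#' @param assembled,reference [annotation_set()] objects.
#' @return A data.frame with columns `query_id`, `code`, `ref_id`.
#' @export
classify_against <- function(assembled, reference) {
  res <- lapply(assembled$transcripts, assign_class_code,
                reference = reference)
  data.frame(
    query_id = vapply(res, `[[`, character(1), "query_id"),
    code = vapply(res, `[[`, character(1), "code"),
    ref_id = vapply(res, `[[`, character(1), "ref_id"),
    stringsAsFactors = FALSE, row.names = NULL
  )
}

#' Filter assembled transcripts down to lncRNA candidates
#'
#' Applies the two structural screens of the identification cascade:
#' transcripts shorter than `min_length` are removed, and the remainder are
#' compared against the full reference annotation, keeping only class codes
#' `i`, `o`, `u` and `x` (transcripts matching known genes via `=`, `c` or
#' `j` are discarded).
#'
#' @param assembled Candidate [annotation_set()].
#' @param reference Reference [annotation_set()] (all known biotypes).
#' @param min_length Minimum transcript length in nt (default 200).
#' @param keep_codes Retained class codes (default `c("i","o","u","x")`).
#' @return A list: `retained` (annotation_set), `log` (data.frame with
#'   `query_id`, `length`, `code`, `retained`, `reason` — `"length"` or
#'   `"code"` for removals, `NA` otherwise).
#' @export
filter_lncrna_candidates <- function(assembled, reference,
                                     min_length = 200,
                                     keep_codes = c("i", "o", "u", "x")) {
  if (!length(assembled$transcripts)) {
    warning("empty assembled set: no candidates to filter")
    return(list(retained = assembled,
                log = data.frame(query_id = character(0),
                                 length = numeric(0), code = character(0),
                                 retained = logical(0), reason = character(0))))
  }
  lens <- vapply(assembled$transcripts, `[[`, numeric(1), "length")
  codes <- classify_against(assembled, reference)
  too_short <- lens < min_length
  bad_code <- !(codes$code %in% keep_codes)
  retained <- !too_short & !bad_code
  reason <- ifelse(too_short, "length", ifelse(bad_code, "code", NA))
  keep_ids <- codes$query_id[retained]
  list(
    retained = annotation_set(assembled$transcripts[keep_ids],
                              assembled$gene_of[keep_ids],
                              assembled$biotype),
    log = data.frame(query_id = codes$query_id, length = unname(lens),
                     code = codes$code, retained = retained,
                     reason = reason, stringsAsFactors = FALSE,
                     row.names = NULL)
  )
}

#' Label candidate lncRNAs as known or novel
#'
#' A candidate matching a reference lncRNA with class code `=`, `c` or `j`
#' is a known lncRNA; everything else is novel.
#'
#' @param candidates [annotation_set()] of retained candidates.
#' @param lncrna_reference [annotation_set()] of known lncRNA transcripts.
#' @return Named character vector (`"known"`/`"novel"`) over candidate ids.
#' @export
label_known_novel <- function(candidates, lncrna_reference) {
  codes <- classify_against(candidates, lncrna_reference)
  stats::setNames(
    ifelse(codes$code %in% c("=", "c", "j"), "known", "novel"),
    codes$query_id
  )
}
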