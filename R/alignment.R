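# Alignment ingestion and filtering: a built-in exhaustive test aligner for
# desk-scale panels, the edit-distance fraction filter, and best-hit tie-set
# selection.

#' Exhaustively align reads against a reference panel
#'
#' Semi-global alignment (read consumed end-to-end, free reference ends) of
#' every read against every reference on both strands, by dynamic programming.
#' Every (reference, strand, end position) whose minimal edit distance is at
#' most the read's edit budget is emitted, with a traceback CIGAR. This is a
#' transparent stand-in for a production short-read mapper, exact by
#' construction and intended for at most thousands of reads against dozens of
#' references.
#'
#' @param reads Tibble with `read_id` and `sequence`.
#' @param panel A `ref_panel` (see [make_reference_panel()]) or a named
#'   character vector of reference sequences.
#' @param max_edit Integer edit budget, recycled per read; if `NULL`, computed
#'   as `floor(edit_frac * read_len)` so hits the 5% rule would discard are
#'   never generated.
#' @param edit_frac Edit-distance fraction used when `max_edit` is `NULL`
#'   (default 0.05).
#' @return Tibble of hits: `read_id`, `ref_accession`, `strand` (`+`/`-`;
#'   minus means the reverse complement of the read matches the reference as
#'   written), `ref_start`, `ref_end` (1-based, inclusive), `edit_distance`,
#'   `cigar` (for the aligned strand), `read_len`.
#' @export
exhaustive_align <- function(reads, panel, max_edit = NULL, edit_frac = 0.05) {
  seqs <- if (inherits(panel, "ref_panel")) panel$sequences else panel
  stopifnot(length(seqs) > 0, !is.null(names(seqs)))
  if (is.null(max_edit)) {
    max_edit <- as.integer(floor(edit_frac * nchar(reads$sequence)))
  } else {
    max_edit <- as.integer(max_edit)
  }
  hits <- semiglobal_align_cpp(
    as.character(reads$read_id), toupper(as.character(reads$sequence)),
    names(seqs), unname(unlist(seqs)), max_edit
  )
  as_tibble(hits)
}

#' Edit-distance fraction filter
#'
#' Discards alignments whose edit distance exceeds `frac` of the read length;
#' equality is kept (a 100 nt read with edit distance 5 passes at the default
#' 5%, edit distance 6 does not). Soft-clipped bases count toward read length.
#'
#' @param hits Hit tibble (see [exhaustive_align()] / [read_sam()]).
#' @param frac Maximum edit distance as a fraction of read length.
#' @return Filtered hit tibble.
#' @export
edit_distance_filter <- function(hits, frac = 0.05) {
  stopifnot(frac >= 0)
  hits[hits$edit_distance <= frac * hits$read_len, , drop = FALSE]
}

#' Best-hit tie sets
#'
#' For each read, keeps the hits achieving that read's minimal edit distance,
#' collapsed to one row per reference (multiple placements on the same
#' reference count once, so long references cannot dominate the downstream
#' LCA vote). Within a reference the retained row is deterministic: the
#' placement with the fewest indel bases in its CIGAR (a substitution-only
#' alignment is kept in preference to tied variants that trade a terminal
#' mismatch for an indel), then smallest start, then `+` before `-`.
#'
#' @param hits Hit tibble, typically already passed through
#'   [edit_distance_filter()].
#' @return Tibble of tied best hits, one row per (read, reference).
#' @export
best_hits <- function(hits) {
  if (nrow(hits) == 0) return(hits)
  hits$n_indel <- cigar_indel_len(hits$cigar)
  hits |>
    dplyr::group_by(.data$read_id) |>
    dplyr::filter(.data$edit_distance == min(.data$edit_distance)) |>
    dplyr::group_by(.data$read_id, .data$ref_accession) |>
    dplyr::arrange(.data$n_indel, .data$ref_start, .data$strand,
                   .by_group = TRUE) |>
    dplyr::slice(1) |>
    dplyr::ungroup()
}
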