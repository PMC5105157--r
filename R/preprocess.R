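# Read-level filters for degraded shotgun libraries: exact-duplicate
# removal, minimum length, and a DUST-style low-complexity score.

#' Remove exact duplicate reads
#'
#' Drops a read when its sequence is an exact copy (same sequence, hence same
#' length) of a read seen earlier in the stream; the first occurrence is kept
#' and input order is preserved. The comparison is strand-naive and
#' quality-blind: a reverse complement is *not* a duplicate.
#'
#' @param reads Tibble with at least a `sequence` column.
#' @return The deduplicated tibble.
#' @export
remove_exact_duplicates <- function(reads) {
  reads[!duplicated(reads$sequence), , drop = FALSE]
}

#' Minimum-length filter
#'
#' Keeps reads of `min_len` or more nucleotides; reads shorter than `min_len`
#' are discarded (a 25-mer passes the default).
#'
#' @param reads Tibble with a `sequence` column.
#' @param min_len Minimum retained length (default 25 nt).
#' @return Filtered tibble.
#' @export
length_filter <- function(reads, min_len = 25) {
  stopifnot(min_len >= 1)
  reads[nchar(reads$sequence) >= min_len, , drop = FALSE]
}

#' DUST low-complexity score
#'
#' For each sliding window of length `w = min(64, len)`, with counts `c_t` of
#' the overlapping trinucleotides in the window (triplets containing a non-
#' ACGT base are not counted), the window score is
#' `sum_t c_t (c_t - 1) / 2 / (w - 3)`; the sequence score is the maximum over
#' windows. A homopolymer of length 64 scores 31.0; random sequence scores
#' well below 1. Sequences shorter than 3 nt score 0 by convention.
#'
#' @param sequences Character vector of DNA sequences.
#' @return Numeric vector of scores.
#' @export
#' @examples
#' dust_score(c(strrep("A", 64), "ACGTGGTCAATGCA"))
dust_score <- function(sequences) {
  dust_score_cpp(toupper(as.character(sequences)))
}

#' Low-complexity filter
#'
#' Drops reads whose [dust_score()] exceeds `max_score`; a score exactly equal
#' to the threshold is kept.
#'
#' @param reads Tibble with a `sequence` column.
#' @param max_score Highest retained score (default 1).
#' @return Filtered tibble.
#' @export
dust_filter <- function(reads, max_score = 1) {
  reads[dust_score(reads$sequence) <= max_score, , drop = FALSE]
}

#' Run the full pre-processing chain
#'
#' Exact-duplicate removal, then the minimum-length filter, then the DUST
#' filter, with per-stage survivor counts. (The stage order does not affect
#' the surviving set — each filter is a pointwise predicate except
#' deduplication, which acts on full sequences — but the per-stage counts
#' refer to this order.)
#'
#' @param reads Tibble with `sequence` (and usually `read_id`, `quality`).
#' @param min_len Minimum read length (default 25).
#' @param dust_max Maximum DUST score (default 1).
#' @return List with `reads` (survivors) and `report` (tibble: stage, n_in,
#'   n_out).
#' @export
preprocess_reads <- function(reads, min_len = 25, dust_max = 1) {
  n0 <- nrow(reads)
  r1 <- remove_exact_duplicates(reads)
  r2 <- length_filter(r1, min_len)
  r3 <- dust_filter(r2, dust_max)
  report <- tibble(
    stage = c("deduplicate", "length_filter", "dust_filter"),
    n_in = c(n0, nrow(r1), nrow(r2)),
    n_out = c(nrow(r1), nrow(r2), nrow(r3))
  )
  list(reads = r3, report = report)
}
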