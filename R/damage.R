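# Ancient-DNA damage authentication: frequency of C->T misincorporations at
# the 5' terminus of reads assigned to a taxon, plus an optional positional
# profile along the first 25 nt.

# choose one alignment per read for damage geometry, deterministically:
# lexicographically smallest accession, then smallest start, then '+' strand
.damage_geometry_hits <- function(hits, read_ids) {
  hits[hits$read_id %in% read_ids, , drop = FALSE] |>
    dplyr::arrange(.data$read_id, .data$ref_accession, .data$ref_start,
                   .data$strand) |>
    dplyr::distinct(.data$read_id, .keep_all = TRUE)
}

# For each hit, the reference base paired with read position p (1-based from
# the read's sequenced 5' end) and the read base there. Minus-strand hits use
# the reverse complement of the reference window, so position 1 pairs with
# the *end* of the window on the reference as written. Only alignments whose
# relevant terminal CIGAR operation is M are usable (an indel or clip leaves
# no paired reference base); `all_m_only` further restricts to gapless
# alignments, which makes interior positions exact.
.pair_bases <- function(hits, reads, seqs, p = 1, all_m_only = FALSE) {
  first_op <- stringr::str_match(hits$cigar, "^\\d+([A-Z])")[, 2]
  last_op <- stringr::str_match(hits$cigar, "([A-Z])$")[, 2]
  gapless <- !grepl("[ID]", hits$cigar)
  usable <- if (all_m_only) {
    gapless
  } else {
    ifelse(hits$strand == "+", first_op == "M", last_op == "M")
  }
  usable <- usable & (hits$ref_end - hits$ref_start + 1 >= p) & (hits$read_len >= p)
  h <- hits[usable, , drop = FALSE]
  if (nrow(h) == 0) {
    return(tibble(read_id = character(), ref_base = character(),
                  read_base = character()))
  }
  refs <- unname(unlist(seqs)[match(h$ref_accession, names(seqs))])
  if (anyNA(refs)) {
    stop("reference sequence(s) missing for: ",
         paste(unique(h$ref_accession[is.na(refs)]), collapse = ", "))
  }
  pos <- ifelse(h$strand == "+", h$ref_start + p - 1L, h$ref_end - p + 1L)
  rb <- substr(refs, pos, pos)
  rb <- ifelse(h$strand == "-", chartr("ACGT", "TGCA", rb), rb)
  seq <- reads$sequence[match(h$read_id, reads$read_id)]
  tibble(read_id = h$read_id, ref_base = rb, read_base = substr(seq, p, p))
}

#' 5' C->T misincorporation frequency for one taxon
#'
#' Among reads assigned to `taxon` whose chosen best alignment pairs the
#' read's 5'-terminal base with a reference base, the estimate is the
#' fraction of reads carrying T where the reference carries C at position 1.
#' Post-mortem cytosine deamination concentrates at fragment termini, so an
#' elevated frequency authenticates the taxon's reads as ancient. Estimates
#' are suppressed (zero-row result) when fewer than `min_reads` reads
#' qualify, since small read sets give unstable frequencies.
#'
#' @param assignments Assignment tibble ([assign_reads()]).
#' @param hits Best-hit tibble ([best_hits()]) carrying alignment geometry.
#' @param reads Read tibble with `read_id`, `sequence` (as sequenced).
#' @param panel `ref_panel` or named character vector of reference sequences.
#' @param tree A [taxonomy_tree()].
#' @param taxon Taxid or scientific name; reads assigned to the node or any
#'   descendant are used.
#' @param min_reads Minimum qualifying reads to report (default 500).
#' @return Tibble with one row — `taxon`, `taxid`, `n_reads_used`, `n_ref_c`,
#'   `freq_ct_pos1` — or zero rows when the gate suppresses the estimate.
#' @export
ct_frequency <- function(assignments, hits, reads, panel, tree, taxon,
                         min_reads = 500) {
  seqs <- if (inherits(panel, "ref_panel")) panel$sequences else panel
  taxid <- if (is.character(taxon)) {
    hit <- tree$nodes$taxid[tree$nodes$name == taxon]
    if (length(hit) != 1) stop("taxon '", taxon, "' does not resolve to one node")
    hit
  } else as.integer(taxon)
  sel <- assignments$read_id[is_within(tree, assignments$taxid, taxon_name(tree, taxid))]
  geom <- .damage_geometry_hits(hits, sel)
  pb <- .pair_bases(geom, reads, seqs, p = 1)
  empty <- tibble(taxon = character(), taxid = integer(), n_reads_used = integer(),
                  n_ref_c = integer(), freq_ct_pos1 = double())
  if (nrow(pb) < min_reads) return(empty)
  ref_c <- pb$ref_base == "C"
  tibble(
    taxon = taxon_name(tree, taxid), taxid = taxid,
    n_reads_used = nrow(pb), n_ref_c = sum(ref_c),
    freq_ct_pos1 = if (sum(ref_c) > 0) mean(pb$read_base[ref_c] == "T") else NA_real_
  )
}

#' Positional 5' C->T profile
#'
#' The C->T frequency at each of the first `positions` read positions,
#' computed over gapless alignments of the reads assigned to `taxon`. With
#' terminal deamination the curve decays geometrically into the read.
#'
#' @inheritParams ct_frequency
#' @param positions How many 5' positions to profile (default 25).
#' @return Tibble: `position`, `n_ref_c`, `freq_ct`.
#' @export
ct_profile <- function(assignments, hits, reads, panel, tree, taxon,
                       positions = 25) {
  seqs <- if (inherits(panel, "ref_panel")) panel$sequences else panel
  taxid <- if (is.character(taxon)) {
    hit <- tree$nodes$taxid[tree$nodes$name == taxon]
    if (length(hit) != 1) stop("taxon '", taxon, "' does not resolve to one node")
    hit
  } else as.integer(taxon)
  sel <- assignments$read_id[is_within(tree, assignments$taxid, taxon_name(tree, taxid))]
  geom <- .damage_geometry_hits(hits, sel)
  purrr::map_dfr(seq_len(positions), function(p) {
    pb <- .pair_bases(geom, reads, seqs, p = p, all_m_only = TRUE)
    ref_c <- pb$ref_base == "C"
    tibble(
      position = p, n_ref_c = sum(ref_c),
      freq_ct = if (sum(ref_c) > 0) mean(pb$read_base[ref_c] == "T") else NA_real_
    )
  })
}
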