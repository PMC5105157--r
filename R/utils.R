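# Small shared helpers.

#' Reverse complement of DNA strings
#'
#' Vectorised reverse complement over the alphabet A, C, G, T, N.
#'
#' @param x Character vector of DNA sequences.
#' @return Character vector of the same length.
#' @export
#' @examples
#' revcomp("ACGTT")
revcomp <- function(x) {
  out <- as.character(Biostrings::reverseComplement(Biostrings::DNAStringSet(x)))
  names(out) <- names(x)
  out
}

# Run `code` with the RNG seeded at `seed`, restoring the caller's RNG state.
with_seed <- function(seed, code) {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    old <- get(".Random.seed", envir = globalenv())
    on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  } else {
    on.exit(suppressWarnings(rm(".Random.seed", envir = globalenv())), add = TRUE)
  }
  set.seed(seed)
  force(code)
}

# CIGAR helpers: ops consuming read bases (M, I, S) and reference bases (M, D, N)
cigar_ops <- function(cigar) {
  lens <- lapply(stringr::str_extract_all(cigar, "\\d+"), as.integer)
  ops <- stringr::str_extract_all(cigar, "[A-Z=]")
  list(lengths = lens, ops = ops)
}

cigar_read_len <- function(cigar) {
  co <- cigar_ops(cigar)
  mapply(function(l, o) sum(l[o %in% c("M", "I", "S", "=", "X")]), co$lengths, co$ops)
}

cigar_indel_len <- function(cigar) {
  co <- cigar_ops(cigar)
  mapply(function(l, o) sum(l[o %in% c("I", "D")]), co$lengths, co$ops)
}

cigar_ref_len <- function(cigar) {
  co <- cigar_ops(cigar)
  mapply(function(l, o) sum(l[o %in% c("M", "D", "N", "=", "X")]), co$lengths, co$ops)
}
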