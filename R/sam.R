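# Minimal SAM text reader/writer for the hit records this package consumes:
# coordinates stay 1-based as in SAM; the in-memory tibble carries the same
# columns the built-in aligner emits.

#' Read alignments from a SAM file
#'
#' Parses mapped records into the package's hit tibble. Unmapped records
#' (FLAG bit 0x4) are skipped; secondary alignments are kept. Each mapped
#' record must carry an `NM:i` edit-distance tag. Read length is taken from
#' the CIGAR (M/I/S/=/X operations), so soft-clipped bases count.
#'
#' @param path Path to a SAM text file.
#' @return Hit tibble: `read_id`, `ref_accession`, `strand`, `ref_start`,
#'   `ref_end`, `edit_distance`, `cigar`, `read_len`.
#' @export
read_sam <- function(path) {
  lines <- readr::read_lines(path)
  lines <- lines[!startsWith(lines, "@")]
  empty <- tibble(read_id = character(), ref_accession = character(),
                  strand = character(), ref_start = integer(),
                  ref_end = integer(), edit_distance = integer(),
                  cigar = character(), read_len = integer())
  if (length(lines) == 0) return(empty)
  fields <- stringr::str_split(lines, "\t")
  flag <- vapply(fields, function(f) as.integer(f[2]), integer(1))
  mapped <- bitwAnd(flag, 4L) == 0L
  fields <- fields[mapped]
  flag <- flag[mapped]
  if (length(fields) == 0) return(empty)
  nm <- vapply(seq_along(fields), function(i) {
    f <- fields[[i]]
    tag <- grep("^NM:i:", f[-(1:11)], value = TRUE)
    if (length(tag) == 0) {
      stop("mapped SAM record without NM tag: read '", f[1], "' at line ", i)
    }
    as.integer(sub("^NM:i:", "", tag[1]))
  }, integer(1))
  cigar <- vapply(fields, `[`, "", 6)
  ref_start <- vapply(fields, function(f) as.integer(f[4]), integer(1))
  tibble(
    read_id = vapply(fields, `[`, "", 1),
    ref_accession = vapply(fields, `[`, "", 3),
    strand = ifelse(bitwAnd(flag, 16L) > 0L, "-", "+"),
    ref_start = ref_start,
    ref_end = ref_start + as.integer(cigar_ref_len(cigar)) - 1L,
    edit_distance = nm,
    cigar = cigar,
    read_len = as.integer(cigar_read_len(cigar))
  )
}

#' Write alignments to a SAM file
#'
#' Emits one mapped record per hit with `@HD`/`@SQ` headers and an `NM:i`
#' tag. When `reads` is given, SEQ holds the read on the aligned strand
#' (reverse-complemented for `-` hits, as SAM requires); otherwise SEQ is
#' `*`.
#'
#' @param hits Hit tibble (see [exhaustive_align()]).
#' @param panel `ref_panel` or named character vector of references (for
#'   `@SQ` lines).
#' @param path Output path.
#' @param reads Optional tibble with `read_id`, `sequence`.
#' @return `path`, invisibly.
#' @export
write_sam <- function(hits, panel, path, reads = NULL) {
  seqs <- if (inherits(panel, "ref_panel")) panel$sequences else panel
  header <- c(
    "@HD\tVN:1.6\tSO:unknown",
    paste0("@SQ\tSN:", names(seqs), "\tLN:", nchar(seqs))
  )
  seq_field <- rep("*", nrow(hits))
  qual_field <- rep("*", nrow(hits))
  if (!is.null(reads) && nrow(hits) > 0) {
    s <- reads$sequence[match(hits$read_id, reads$read_id)]
    seq_field <- ifelse(hits$strand == "-", revcomp(s), s)
  }
  body <- if (nrow(hits) == 0) character(0) else paste(
    hits$read_id,
    ifelse(hits$strand == "-", 16L, 0L),
    hits$ref_accession,
    hits$ref_start,
    255L,
    hits$cigar,
    "*", 0L, 0L,
    seq_field, qual_field,
    paste0("NM:i:", hits$edit_distance),
    sep = "\t"
  )
  readr::write_lines(c(header, body), path)
  invisible(path)
}
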