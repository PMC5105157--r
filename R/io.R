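# Sequence-format I/O, thin wrappers over Biostrings plus tidy tables.

#' Read and write FASTQ
#'
#' Four-line FASTQ with Phred+33 qualities, as a tidy tibble of reads.
#'
#' @param path File path.
#' @return `read_fastq()`: tibble with `read_id`, `sequence`, `quality`.
#' @export
read_fastq <- function(path) {
  lines <- readr::read_lines(path)
  while (length(lines) > 0 && lines[length(lines)] == "") {
    lines <- lines[-length(lines)]
  }
  if (length(lines) == 0) {
    return(tibble(read_id = character(), sequence = character(), quality = character()))
  }
  if (length(lines) %% 4 != 0) stop("truncated FASTQ: ", path)
  i <- seq(1, length(lines), by = 4)
  tibble(
    read_id = sub("^@", "", sub("\\s.*$", "", lines[i])),
    sequence = toupper(lines[i + 1]),
    quality = lines[i + 3]
  )
}

#' @rdname read_fastq
#' @param reads Tibble with `read_id`, `sequence` and (optionally) `quality`.
#' @return `write_fastq()`: `path`, invisibly.
#' @export
write_fastq <- function(reads, path) {
  if (nrow(reads) == 0) {
    readr::write_lines(character(0), path)
    return(invisible(path))
  }
  qual <- if ("quality" %in% names(reads)) reads$quality else strrep("F", nchar(reads$sequence))
  readr::write_lines(
    as.vector(rbind(paste0("@", reads$read_id), reads$sequence,
                    rep("+", nrow(reads)), qual)),
    path
  )
  invisible(path)
}

#' Read and write FASTA
#'
#' @param path File path.
#' @return `read_fasta()`: named character vector of sequences.
#' @export
read_fasta <- function(path) {
  x <- Biostrings::readDNAStringSet(path)
  out <- as.character(x)
  names(out) <- sub("\\s.*$", "", names(x))
  out
}

#' @rdname read_fasta
#' @param sequences Named character vector (names become headers).
#' @return `write_fasta()`: `path`, invisibly.
#' @export
write_fasta <- function(sequences, path) {
  Biostrings::writeXStringSet(
    Biostrings::DNAStringSet(unlist(sequences)), path
  )
  invisible(path)
}

#' Write a reference panel as FASTA plus accession map
#'
#' @param panel A [make_reference_panel()] result.
#' @param fasta_file,map_file Output paths; the map is a 2-column TSV
#'   `accession`, `taxid`.
#' @return `panel`, invisibly.
#' @export
write_ref_panel <- function(panel, fasta_file, map_file) {
  write_fasta(panel$sequences, fasta_file)
  readr::write_tsv(panel$accessions[, c("accession", "taxid")], map_file)
  invisible(panel)
}

#' Read a reference panel from FASTA plus accession map
#'
#' @param fasta_file,map_file Paths written by [write_ref_panel()] (or any
#'   FASTA whose records are listed in the accession map).
#' @param tree Optional [taxonomy_tree()] passed to [read_accession_map()].
#' @return A `ref_panel` object.
#' @export
read_ref_panel <- function(fasta_file, map_file, tree = NULL) {
  seqs <- read_fasta(fasta_file)
  map <- read_accession_map(map_file, tree)
  map <- map[map$accession %in% names(seqs), ]
  if (!is.null(tree)) map$name <- taxon_name(tree, map$taxid)
  structure(list(sequences = seqs[map$accession], accessions = map),
            class = "ref_panel")
}
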