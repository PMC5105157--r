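# Majority-rule consensus from reads realigned against a single reference,
# with per-position coverage depth.

#' Majority-rule pileup consensus
#'
#' Tallies the observed base at every reference position across all aligned
#' reads (match/mismatch CIGAR operations only: deletions leave a position
#' unobserved, insertions have no reference coordinate) and calls the most
#' frequent base. Ties are called `N` rather than falling back on the
#' reference, to avoid reference bias; positions with depth below `min_depth`
#' (default 1, i.e. only uncovered positions) are also `N`. Mean depth is
#' total aligned read bases divided by reference length.
#'
#' @param hits Hit tibble; every row must target `ref_name`.
#' @param reads Tibble with `read_id`, `sequence` (as sequenced).
#' @param reference Reference sequence (single string) or a `ref_panel`
#'   containing it.
#' @param ref_name Accession of the reference the hits target; defaults to
#'   the single accession present in `hits`.
#' @param min_depth Minimum depth to call a base (default 1).
#' @return A `consensus_result`: list with `consensus` (string), `depth`
#'   (integer vector), `mean_depth`, `n_reads`, `ref_name`.
#' @export
pileup_consensus <- function(hits, reads, reference, ref_name = NULL,
                             min_depth = 1) {
  if (is.null(ref_name)) {
    ref_name <- unique(hits$ref_accession)
    if (length(ref_name) > 1) {
      stop("hits target multiple references: ", paste(ref_name, collapse = ", "))
    }
  }
  if (nrow(hits) > 0 && any(hits$ref_accession != ref_name)) {
    stop("hit(s) to foreign reference: ",
         paste(setdiff(hits$ref_accession, ref_name), collapse = ", "))
  }
  ref <- if (inherits(reference, "ref_panel")) {
    reference$sequences[[ref_name]]
  } else if (length(reference) > 1 || !is.null(names(reference))) {
    reference[[ref_name]]
  } else {
    reference
  }
  if (is.null(ref)) stop("reference sequence '", ref_name, "' not found")
  n <- nchar(ref)
  counts <- matrix(0L, nrow = 4, ncol = n, dimnames = list(c("A", "C", "G", "T")))

  if (nrow(hits) > 0) {
    seqs <- reads$sequence[match(hits$read_id, reads$read_id)]
    if (anyNA(seqs)) stop("read sequence(s) missing for some hits")
    aligned <- ifelse(hits$strand == "-", revcomp(seqs), seqs)
    co <- cigar_ops(hits$cigar)
    for (k in seq_len(nrow(hits))) {
      rpos <- hits$ref_start[k]  # next reference position (1-based)
      qpos <- 1L                 # next read position on aligned strand
      lens <- co$lengths[[k]]; ops <- co$ops[[k]]
      s <- aligned[k]
      for (j in seq_along(ops)) {
        L <- lens[j]
        if (ops[j] %in% c("M", "=", "X")) {
          b <- strsplit(substr(s, qpos, qpos + L - 1L), "")[[1]]
          idx <- match(b, c("A", "C", "G", "T"))
          keep <- !is.na(idx)
          pos <- rpos:(rpos + L - 1L)
          for (i in which(keep)) counts[idx[i], pos[i]] <- counts[idx[i], pos[i]] + 1L
          rpos <- rpos + L; qpos <- qpos + L
        } else if (ops[j] %in% c("D", "N")) {
          rpos <- rpos + L
        } else if (ops[j] %in% c("I", "S")) {
          qpos <- qpos + L
        }
      }
    }
  }

  depth <- colSums(counts)
  best <- apply(counts, 2, max)
  n_best <- colSums(counts == rep(best, each = 4))
  call <- rownames(counts)[apply(counts, 2, which.max)]
  call[n_best > 1 | depth < min_depth | depth == 0] <- "N"
  structure(
    list(consensus = paste(call, collapse = ""),
         depth = as.integer(depth),
         mean_depth = sum(depth) / n,
         n_reads = nrow(hits),
         ref_name = ref_name),
    class = "consensus_result"
  )
}

#' @export
print.consensus_result <- function(x, ...) {
  cat("<consensus_result> ", nchar(x$consensus), " nt vs ", x$ref_name,
      ": mean depth ", round(x$mean_depth, 2), " from ", x$n_reads, " reads; ",
      sum(strsplit(x$consensus, "")[[1]] == "N"), " N position(s)\n", sep = "")
  invisible(x)
}

#' @rdname pileup_consensus
#' @param x A `consensus_result`.
#' @param ... Unused.
#' @return `glance()`: one-row tibble with `ref_name`, `n_reads`,
#'   `mean_depth`, `n_called`, `n_uncalled`.
#' @export
glance.consensus_result <- function(x, ...) {
  nn <- sum(strsplit(x$consensus, "")[[1]] == "N")
  tibble(ref_name = x$ref_name, n_reads = x$n_reads, mean_depth = x$mean_depth,
         n_called = nchar(x$consensus) - nn, n_uncalled = nn)
}
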