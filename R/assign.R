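# Turning best-hit tie sets into taxonomic assignments: direct assignment
# for unique best hits, lowest common ancestor for ties; vertebrate rank
# restriction; helminth unique-assignment counting.

#' Assign reads to taxonomy nodes by lowest common ancestor
#'
#' Maps each tied reference to its taxid; a read whose tie set maps to a
#' single taxid is assigned directly to that node (`unique = TRUE`), a read
#' with several distinct taxids is assigned to their lowest common ancestor
#' (`unique = FALSE`). Hits to accessions missing from the map are dropped
#' with a message reporting the count; a read left with no mapped hit yields
#' no assignment.
#'
#' @param tie_hits Best-hit tibble from [best_hits()] (one row per read and
#'   reference).
#' @param acc_map Tibble `accession` -> `taxid` (see [read_accession_map()]);
#'   a `ref_panel`'s `accessions` table also works.
#' @param tree A [taxonomy_tree()].
#' @return Assignment tibble: `read_id`, `taxid`, `rank`, `name`,
#'   `n_tied_refs`, `unique`.
#' @export
assign_reads <- function(tie_hits, acc_map, tree) {
  if (inherits(acc_map, "ref_panel")) acc_map <- acc_map$accessions
  empty <- tibble(read_id = character(), taxid = integer(), rank = character(),
                  name = character(), n_tied_refs = integer(), unique = logical())
  if (nrow(tie_hits) == 0) return(empty)
  mapped <- dplyr::left_join(
    tie_hits[, c("read_id", "ref_accession")],
    acc_map[, c("accession", "taxid")],
    by = c(ref_accession = "accession")
  )
  n_unmapped <- sum(is.na(mapped$taxid))
  if (n_unmapped > 0) {
    message(n_unmapped, " hit(s) to accessions without a taxid mapping; dropped")
    mapped <- mapped[!is.na(mapped$taxid), ]
  }
  if (nrow(mapped) == 0) return(empty)

  per_read <- mapped |>
    dplyr::group_by(.data$read_id) |>
    dplyr::summarise(
      n_tied_refs = dplyr::n(),
      taxids = list(unique(.data$taxid)),
      .groups = "drop"
    )
  multi <- lengths(per_read$taxids) > 1
  assigned <- integer(nrow(per_read))
  assigned[!multi] <- vapply(per_read$taxids[!multi], `[`, integer(1), 1)
  if (any(multi)) {
    # memoise LCA on the distinct tie sets; ambiguous reads repeat few patterns
    keys <- vapply(per_read$taxids[multi],
                   function(x) paste(sort(x), collapse = ","), "")
    uk <- !duplicated(keys)
    lcas <- vapply(per_read$taxids[multi][uk], function(x) lca(tree, x), integer(1))
    assigned[multi] <- lcas[match(keys, keys[uk])]
  }
  tibble(
    read_id = per_read$read_id,
    taxid = assigned,
    rank = taxon_rank(tree, assigned),
    name = taxon_name(tree, assigned),
    n_tied_refs = per_read$n_tied_refs,
    unique = !multi
  )
}

#' Restrict assignments to vertebrates at family level or lower
#'
#' Keeps assignments whose node lies within Vertebrata *and* sits at or below
#' family rank (family, subfamily, genus, species, subspecies; `"no rank"`
#' nodes resolve through their nearest ranked ancestor). Assignments landing
#' above family remain in the unrestricted table for audit but are excluded
#' from profiles.
#'
#' @param assignments Assignment tibble from [assign_reads()].
#' @param tree A [taxonomy_tree()].
#' @param clade Name of the enclosing clade (default `"Vertebrata"`).
#' @param rank Rank threshold (default `"family"`).
#' @return Filtered assignment tibble.
#' @export
restrict_vertebrate <- function(assignments, tree, clade = "Vertebrata",
                                rank = "family") {
  if (nrow(assignments) == 0) return(assignments)
  tax <- unique(assignments$taxid)
  ok <- is_within(tree, tax, clade) & is_at_or_below_rank(tree, tax, rank)
  assignments[assignments$taxid %in% tax[ok], , drop = FALSE]
}

#' Count reads uniquely assigned to helminth species
#'
#' Counts reads whose assignment node *is* the target species itself — reads
#' resolved only to a genus or family (e.g. an LCA across congeneric
#' tapeworms) contribute to no species count. Targets must be species inside
#' the tapeworm (Taeniidae) or roundworm (Toxocaridae) families.
#'
#' @param assignments Assignment tibble from [assign_reads()].
#' @param tree A [taxonomy_tree()].
#' @param targets Character vector of species names, or integer taxids.
#' @return Tibble: `name`, `taxid`, `n_reads` (zero rows included).
#' @export
helminth_unique_counts <- function(assignments, tree, targets) {
  if (is.character(targets)) {
    taxids <- vapply(targets, function(nm) {
      hit <- tree$nodes$taxid[tree$nodes$name == nm]
      if (length(hit) != 1) stop("target '", nm, "' does not resolve to one node")
      hit
    }, integer(1))
  } else {
    taxids <- as.integer(targets)
  }
  in_fam <- is_within(tree, taxids, "Taeniidae") | is_within(tree, taxids, "Toxocaridae")
  if (any(!in_fam)) {
    stop("target(s) outside Taeniidae/Toxocaridae: ",
         paste(taxon_name(tree, taxids[!in_fam]), collapse = ", "))
  }
  taxids <- unname(taxids)
  tibble(
    name = taxon_name(tree, taxids),
    taxid = taxids,
    n_reads = vapply(taxids, function(t) sum(assignments$taxid == t), integer(1))
  )
}
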