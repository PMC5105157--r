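# Per-layer faunal profiles: merging libraries from the same stratigraphic
# layer, collapsing redundant higher-order taxa, relative abundances,
# vertebrate DNA concentration, and rank tallies.

#' Merge per-library assignments into per-layer profiles
#'
#' Sediment and helminth shotgun libraries from the same (site, layer) are
#' merged wholesale to increase sample size: assigned read counts are summed
#' per taxon and the totals of reads analysed are summed. The result is a
#' tidy profile table, one row per (site, layer, taxon).
#'
#' @param assignments Assignment tibble carrying a `library_id` column
#'   (e.g. [assign_reads()] output bound across libraries).
#' @param metas Library metadata tibble: `library_id`, `site`, `layer`,
#'   optionally `culture` and `library_type` (`"sediment"`/`"helminth"`), and
#'   `n_reads_analysed` (reads that went into the assignment run).
#' @return Profile tibble: `site`, `layer`, `taxid`, `name`, `rank`, `count`,
#'   `total_reads_analysed` (the layer total, repeated within a layer).
#' @export
merge_layers <- function(assignments, metas) {
  stopifnot("library_id" %in% names(assignments))
  unknown <- setdiff(unique(assignments$library_id), metas$library_id)
  if (length(unknown)) {
    stop("assignments reference unknown library/libraries: ",
         paste(unknown, collapse = ", "))
  }
  totals <- metas |>
    dplyr::group_by(.data$site, .data$layer) |>
    dplyr::summarise(total_reads_analysed = sum(.data$n_reads_analysed),
                     .groups = "drop")
  assignments |>
    dplyr::left_join(metas[, c("library_id", "site", "layer")], by = "library_id") |>
    dplyr::count(.data$site, .data$layer, .data$taxid, .data$name, .data$rank,
                 name = "count") |>
    dplyr::left_join(totals, by = c("site", "layer")) |>
    dplyr::arrange(.data$site, .data$layer, dplyr::desc(.data$count))
}

#' Default taxon-collapsing rules
#'
#' Higher-order taxa represented in practice by a single species are folded
#' into that species for display and comparison: Bos/Bovinae to *Bos*;
#' Canis, *C. lupus* and *C. lupus familiaris* to *C. lupus*; Pusa and
#' *P. hispida* to *P. hispida*; Balaenidae and *B. mysticetus* to
#' *B. mysticetus*; Cervidae, Odocoilinae and *R. tarandus* to *R. tarandus*.
#'
#' @return List of rules, each `list(sources = <names>, target = <name>)`.
#' @export
collapse_rules_default <- function() {
  list(
    list(sources = c("Bos", "Bovinae"), target = "Bos"),
    list(sources = c("Canis", "Canis lupus", "Canis lupus familiaris"),
         target = "Canis lupus"),
    list(sources = c("Pusa", "Pusa hispida"), target = "Pusa hispida"),
    list(sources = c("Balaenidae", "Balaena mysticetus"),
         target = "Balaena mysticetus"),
    list(sources = c("Cervidae", "Odocoilinae", "Rangifer tarandus"),
         target = "Rangifer tarandus")
  )
}

#' Collapse redundant higher-order taxa in a profile
#'
#' Applies name-based collapsing rules (counts of each rule's source nodes
#' are added to its target node), then optionally an automatic pass that
#' folds any ancestor node carrying counts into its unique species-or-below
#' descendant with nonzero counts — the generalisation of the named rules to
#' arbitrary profiles. Rules whose target is not a descendant-or-equal of a
#' source trigger a warning but are still applied. Total counts are
#' conserved.
#'
#' @param profile Profile tibble from [merge_layers()] (or any tibble with
#'   `taxid`, `name`, `rank`, `count`, optionally grouped by `site`/`layer`).
#' @param tree A [taxonomy_tree()].
#' @param rules Rule list as in [collapse_rules_default()]; rules naming taxa
#'   absent from the tree are skipped.
#' @param auto If `TRUE`, also collapse automatically as described above;
#'   uniqueness of the nonzero descendant is judged across the whole profile
#'   (all sites and layers), matching "represented by a single species in the
#'   data set".
#' @return Profile tibble with collapsed counts.
#' @export
collapse_taxa <- function(profile, tree, rules = collapse_rules_default(),
                          auto = FALSE) {
  if (nrow(profile) == 0) return(profile)
  remap <- setNames(tree$nodes$taxid, tree$nodes$taxid)  # taxid -> taxid

  resolve <- function(nm) {
    hit <- tree$nodes$taxid[tree$nodes$name == nm]
    if (length(hit) == 1) hit else NA_integer_
  }
  for (r in rules) {
    tgt <- resolve(r$target)
    src <- vapply(r$sources, resolve, integer(1))
    src <- src[!is.na(src)]
    if (is.na(tgt) || length(src) == 0) next
    bad <- setdiff(src[!vapply(src, function(s) {
      s %in% root_path(tree, tgt) || tgt %in% root_path(tree, s)
    }, logical(1))], tgt)
    if (length(bad)) {
      warning("collapse target '", r$target,
              "' is not a descendant of source(s): ",
              paste(taxon_name(tree, bad), collapse = ", "),
              "; rule applied anyway")
    }
    remap[as.character(src)] <- tgt
  }

  if (auto) {
    species_lvl <- .rank_level("species")
    nonzero <- profile |>
      dplyr::group_by(.data$taxid) |>
      dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
      dplyr::filter(.data$count > 0)
    sp_nodes <- nonzero$taxid[
      !is.na(.effective_rank(tree, .tree_pos(tree, nonzero$taxid))) &
        .rank_level(.effective_rank(tree, .tree_pos(tree, nonzero$taxid))) >= species_lvl
    ]
    # ancestors (above species) present in the profile with counts
    anc_nodes <- setdiff(nonzero$taxid, sp_nodes)
    for (a in anc_nodes) {
      under <- sp_nodes[vapply(sp_nodes, function(s) a %in% root_path(tree, s),
                               logical(1))]
      if (length(under) == 1 && remap[[as.character(a)]] == a) {
        remap[[as.character(a)]] <- under
      }
    }
  }

  profile$taxid <- unname(remap[as.character(profile$taxid)])
  profile$name <- taxon_name(tree, profile$taxid)
  profile$rank <- taxon_rank(tree, profile$taxid)
  group_cols <- intersect(c("site", "layer"), names(profile))
  extra <- intersect("total_reads_analysed", names(profile))
  profile |>
    dplyr::group_by(dplyr::across(dplyr::all_of(
      c(group_cols, "taxid", "name", "rank", extra)))) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::relocate(dplyr::all_of(c(group_cols, "taxid", "name", "rank", "count")))
}

#' Relative abundances over a taxon subset
#'
#' Adds a `fraction` column: each taxon's share of the layer total over the
#' chosen subset (fractions sum to 1 within a layer whenever the subset total
#' is positive; an all-zero subset yields zero fractions and a warning).
#'
#' @param profile Profile tibble ([merge_layers()] output).
#' @param taxa Optional subset, as taxids (integer) or names (character);
#'   default: all taxa in the profile.
#' @return The subset profile with a `fraction` column.
#' @export
relative_abundance <- function(profile, taxa = NULL) {
  sub <- profile
  if (!is.null(taxa)) {
    sub <- if (is.character(taxa)) {
      profile[profile$name %in% taxa, , drop = FALSE]
    } else {
      profile[profile$taxid %in% as.integer(taxa), , drop = FALSE]
    }
  }
  group_cols <- intersect(c("site", "layer"), names(sub))
  out <- sub |>
    dplyr::group_by(dplyr::across(dplyr::all_of(group_cols))) |>
    dplyr::mutate(fraction = if (sum(.data$count) > 0) {
      .data$count / sum(.data$count)
    } else 0) |>
    dplyr::ungroup()
  if (nrow(out) > 0) {
    key <- if (length(group_cols)) do.call(paste, out[group_cols]) else rep("all", nrow(out))
    if (any(tapply(out$count, key, sum) == 0)) {
      warning("subset total is zero in at least one layer; fractions set to 0")
    }
  }
  out
}

#' The n globally most abundant species
#'
#' Selects the most common species-or-below taxa by total count across all
#' sites and layers (the "10 most common species across all sites" display
#' convention).
#'
#' @param profile Profile tibble.
#' @param tree A [taxonomy_tree()].
#' @param n How many species (default 10).
#' @param within Optional clade name to restrict to (e.g. `"Mammalia"`).
#' @return Integer vector of taxids, most abundant first.
#' @export
top_species <- function(profile, tree, n = 10, within = NULL) {
  tax <- unique(profile$taxid)
  eff <- .effective_rank(tree, .tree_pos(tree, tax))
  keep <- !is.na(eff) & .rank_level(eff) >= .rank_level("species")
  if (!is.null(within)) keep <- keep & is_within(tree, tax, within)
  tot <- profile |>
    dplyr::filter(.data$taxid %in% tax[keep]) |>
    dplyr::group_by(.data$taxid) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop") |>
    dplyr::arrange(dplyr::desc(.data$count))
  utils::head(tot$taxid, n)
}

#' Vertebrate DNA concentration per layer
#'
#' Defined as vertebrate-assigned DNA reads per million reads analysed:
#' `1e6 * sum(vertebrate counts) / total_reads_analysed`.
#'
#' @param profile Profile tibble with `total_reads_analysed`.
#' @param tree A [taxonomy_tree()].
#' @param clade Clade whose reads are counted (default `"Vertebrata"`).
#' @return Tibble: `site`, `layer`, `vertebrate_reads`,
#'   `total_reads_analysed`, `reads_per_million`.
#' @export
vertebrate_concentration <- function(profile, tree, clade = "Vertebrata") {
  tax <- unique(profile$taxid)
  vert <- tax[is_within(tree, tax, clade)]
  profile |>
    dplyr::group_by(.data$site, .data$layer, .data$total_reads_analysed) |>
    dplyr::summarise(
      vertebrate_reads = sum(.data$count[.data$taxid %in% vert]),
      .groups = "drop"
    ) |>
    dplyr::mutate(
      reads_per_million = ifelse(
        .data$total_reads_analysed > 0,
        1e6 * .data$vertebrate_reads / .data$total_reads_analysed, 0
      )
    ) |>
    dplyr::relocate("site", "layer", "vertebrate_reads", "total_reads_analysed")
}

#' Tally distinct taxa per rank
#'
#' Counts the distinct assigned nodes at each rank (e.g. "1 subspecies, 23
#' species, 9 genera, ..." style summaries).
#'
#' @param assignments Assignment tibble (post-restriction).
#' @return Tibble `rank`, `n_taxa`, ordered root-most first.
#' @export
rank_tally <- function(assignments) {
  if (nrow(assignments) == 0) return(tibble(rank = character(), n_taxa = integer()))
  assignments |>
    dplyr::distinct(.data$taxid, .data$rank) |>
    dplyr::count(.data$rank, name = "n_taxa") |>
    dplyr::arrange(match(.data$rank, taxonomy_ranks))
}
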