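# Taxonomy trees in the NCBI dump dialect: node table with taxid, parent,
# rank and scientific name; ancestor-path, rank and LCA queries.

#' Controlled rank vocabulary
#'
#' The ranks recognised by the package, ordered from root-most to leaf-most.
#' `"no rank"` sorts outside the ladder; rank-threshold queries resolve such
#' nodes through their nearest ranked ancestor.
#'
#' @export
taxonomy_ranks <- c(
  "no rank", "superkingdom", "kingdom", "phylum", "class", "order",
  "family", "subfamily", "genus", "species", "subspecies"
)

# ranked ladder (excludes "no rank"); larger index = lower (more specific)
.rank_level <- function(rank) match(rank, taxonomy_ranks[-1])

#' Construct a taxonomy tree from a node table
#'
#' @param nodes Data frame with columns `taxid` (positive integer), `parent`
#'   (taxid; the root points at itself), `rank` (one of [taxonomy_ranks]) and
#'   `name` (scientific name).
#' @return A `taxonomy_tree` object.
#' @details Validates that exactly one root exists, every parent is present,
#'   ranks are in the controlled vocabulary, and the parent relation is
#'   acyclic. Node depths are precomputed for LCA queries.
#' @export
taxonomy_tree <- function(nodes) {
  nodes <- as_tibble(nodes)
  stopifnot(all(c("taxid", "parent", "rank", "name") %in% names(nodes)))
  nodes <- dplyr::mutate(nodes,
    taxid = as.integer(.data$taxid), parent = as.integer(.data$parent)
  )
  if (anyDuplicated(nodes$taxid)) {
    stop("duplicated taxid(s): ",
         paste(unique(nodes$taxid[duplicated(nodes$taxid)]), collapse = ", "))
  }
  bad_rank <- setdiff(unique(nodes$rank), taxonomy_ranks)
  if (length(bad_rank)) stop("unknown rank(s): ", paste(bad_rank, collapse = ", "))
  root <- nodes$taxid[nodes$taxid == nodes$parent]
  if (length(root) != 1) stop("tree must have exactly one root (parent == taxid)")
  dangling <- setdiff(nodes$parent, nodes$taxid)
  if (length(dangling)) {
    off <- nodes$taxid[nodes$parent %in% dangling]
    stop("parent taxid(s) absent from tree: ", paste(dangling, collapse = ", "),
         " (referenced by taxid ", paste(off, collapse = ", "), ")")
  }

  idx <- setNames(seq_len(nrow(nodes)), nodes$taxid)
  parent_idx <- unname(idx[as.character(nodes$parent)])

  # depth with cycle detection: 0 = unvisited, 1 = in progress, 2 = done
  n <- nrow(nodes)
  depth <- integer(n)
  state <- integer(n)
  root_i <- unname(idx[as.character(root)])
  depth[root_i] <- 0L
  state[root_i] <- 2L
  for (i in seq_len(n)) {
    if (state[i] == 2L) next
    path <- integer(0)
    j <- i
    while (state[j] == 0L) {
      state[j] <- 1L
      path <- c(path, j)
      j <- parent_idx[j]
      if (state[j] == 1L) {
        stop("cycle detected in taxonomy involving taxid ", nodes$taxid[j])
      }
    }
    for (p in rev(path)) {
      depth[p] <- depth[parent_idx[p]] + 1L
      state[p] <- 2L
    }
  }

  structure(
    list(nodes = nodes, root = root,
         .idx = idx, .parent_idx = parent_idx, .depth = depth),
    class = "taxonomy_tree"
  )
}

#' @export
print.taxonomy_tree <- function(x, ...) {
  cat("<taxonomy_tree> ", nrow(x$nodes), " nodes, root taxid ", x$root,
      ", max depth ", max(x$.depth), "\n", sep = "")
  invisible(x)
}

.tree_pos <- function(tree, taxids) {
  pos <- unname(tree$.idx[as.character(taxids)])
  if (anyNA(pos)) {
    stop("taxid(s) not in tree: ", paste(taxids[is.na(pos)], collapse = ", "))
  }
  pos
}

#' Look up node attributes
#'
#' @param tree A [taxonomy_tree()].
#' @param taxids Integer vector of taxids (must exist in the tree).
#' @return Character/integer vector aligned with `taxids`.
#' @export
taxon_name <- function(tree, taxids) tree$nodes$name[.tree_pos(tree, taxids)]

#' @rdname taxon_name
#' @export
taxon_rank <- function(tree, taxids) tree$nodes$rank[.tree_pos(tree, taxids)]

#' Path from a node to the root
#'
#' @inheritParams taxon_name
#' @param taxid A single taxid.
#' @return Integer vector of taxids from `taxid` (inclusive) up to the root.
#' @export
root_path <- function(tree, taxid) {
  i <- .tree_pos(tree, taxid)
  path <- integer(0)
  repeat {
    path <- c(path, tree$nodes$taxid[i])
    p <- tree$.parent_idx[i]
    if (p == i) break
    i <- p
  }
  path
}

#' Lowest common ancestor of a set of taxa
#'
#' The deepest node that lies on the root path of every member of `taxids`.
#' Used to assign reads with several equally good reference hits to the most
#' specific taxon consistent with all of them.
#'
#' @inheritParams taxon_name
#' @param taxids Nonempty vector of taxids, all present in the tree.
#' @return A single taxid.
#' @export
#' @examples
#' tr <- make_toy_taxonomy()
#' lca(tr, c(50, 51))  # two congeneric tapeworms -> their genus
lca <- function(tree, taxids) {
  taxids <- unique(as.integer(taxids))
  if (length(taxids) == 0) stop("lca() needs at least one taxid")
  pos <- .tree_pos(tree, taxids)
  a <- pos[1]
  for (b in pos[-1]) {
    da <- tree$.depth[a]; db <- tree$.depth[b]
    while (da > db) { a <- tree$.parent_idx[a]; da <- da - 1L }
    while (db > da) { b <- tree$.parent_idx[b]; db <- db - 1L }
    while (a != b) { a <- tree$.parent_idx[a]; b <- tree$.parent_idx[b] }
  }
  tree$nodes$taxid[a]
}

# nearest ranked ancestor-or-self; NA_character_ if none (root unranked)
.effective_rank <- function(tree, pos) {
  rk <- tree$nodes$rank
  out <- character(length(pos))
  for (k in seq_along(pos)) {
    i <- pos[k]
    while (rk[i] == "no rank" && tree$.parent_idx[i] != i) i <- tree$.parent_idx[i]
    out[k] <- if (rk[i] == "no rank") NA_character_ else rk[i]
  }
  out
}

#' Test whether taxa sit at or below a rank threshold
#'
#' A node passes when its own rank — or, for `"no rank"` nodes, the rank of
#' its nearest ranked ancestor — is at least as specific as `rank`
#' (e.g. family, subfamily, genus, species or subspecies for
#' `rank = "family"`).
#'
#' @inheritParams taxon_name
#' @param rank A ranked level from [taxonomy_ranks] (not `"no rank"`).
#' @return Logical vector aligned with `taxids`.
#' @export
is_at_or_below_rank <- function(tree, taxids, rank = "family") {
  lvl <- .rank_level(rank)
  if (length(rank) != 1 || is.na(lvl)) {
    stop("rank must be one ranked level of taxonomy_ranks, got: ", rank)
  }
  eff <- .effective_rank(tree, .tree_pos(tree, taxids))
  !is.na(eff) & .rank_level(eff) >= lvl
}

#' Test descent from a named ancestor
#'
#' @inheritParams taxon_name
#' @param ancestor_name Scientific name resolving to exactly one node.
#' @return Logical vector: `TRUE` where `ancestor_name` lies on the node's
#'   root path (a node is within itself).
#' @export
is_within <- function(tree, taxids, ancestor_name) {
  hit <- which(tree$nodes$name == ancestor_name)
  if (length(hit) == 0) stop("no node named '", ancestor_name, "'")
  if (length(hit) > 1) stop("ambiguous name '", ancestor_name, "'")
  anc <- hit
  pos <- .tree_pos(tree, taxids)
  vapply(pos, function(i) {
    repeat {
      if (i == anc) return(TRUE)
      p <- tree$.parent_idx[i]
      if (p == i) return(FALSE)
      i <- p
    }
  }, logical(1))
}

# ---- dump-dialect I/O -------------------------------------------------------

.split_dmp <- function(lines) {
  lines <- sub("\t\\|$", "", lines)
  stringr::str_split(lines, stringr::fixed("\t|\t"))
}

#' Parse taxonomy dump files
#'
#' Reads node and name tables in the NCBI taxonomy dump dialect (fields
#' separated by `"\t|\t"`, records terminated by `"\t|"`). Only rows of name
#' class `"scientific name"` bind names; other name classes are ignored.
#'
#' @param nodes_file,names_file Paths to `nodes.dmp` / `names.dmp`-style files.
#' @return A [taxonomy_tree()].
#' @export
parse_taxonomy <- function(nodes_file, names_file) {
  nd <- .split_dmp(readr::read_lines(nodes_file))
  nd <- nd[lengths(nd) >= 3]
  nodes <- tibble(
    taxid = as.integer(vapply(nd, `[`, "", 1)),
    parent = as.integer(vapply(nd, `[`, "", 2)),
    rank = vapply(nd, `[`, "", 3)
  )
  nm <- .split_dmp(readr::read_lines(names_file))
  nm <- nm[lengths(nm) >= 4]
  names_tbl <- tibble(
    taxid = as.integer(vapply(nm, `[`, "", 1)),
    name = vapply(nm, `[`, "", 2),
    class = vapply(nm, `[`, "", 4)
  )
  sci <- dplyr::filter(names_tbl, .data$class == "scientific name")
  nodes <- dplyr::left_join(nodes, dplyr::select(sci, "taxid", "name"), by = "taxid")
  nodes$name[is.na(nodes$name)] <- paste0("taxid:", nodes$taxid[is.na(nodes$name)])
  taxonomy_tree(nodes)
}

#' Write a taxonomy tree in the dump dialect
#'
#' @param tree A [taxonomy_tree()].
#' @param nodes_file,names_file Output paths.
#' @return `tree`, invisibly.
#' @export
write_taxonomy <- function(tree, nodes_file, names_file) {
  n <- tree$nodes
  readr::write_lines(
    paste(n$taxid, n$parent, n$rank, sep = "\t|\t") |> paste0("\t|"),
    nodes_file
  )
  readr::write_lines(
    paste(n$taxid, n$name, "", "scientific name", sep = "\t|\t") |> paste0("\t|"),
    names_file
  )
  invisible(tree)
}

#' Read an accession-to-taxid table
#'
#' Two-column TSV mapping reference identifiers (accessions, or legacy gi
#' numbers treated as strings) to taxids. When `tree` is supplied, rows whose
#' taxid is absent from the tree are dropped with a message reporting the
#' count, mirroring how reads mapped to obsolete identifiers are handled.
#'
#' @param file Path to a TSV with columns `accession` and `taxid` (header
#'   optional; detected).
#' @param tree Optional [taxonomy_tree()] to validate taxids against.
#' @return Tibble with columns `accession` (character), `taxid` (integer).
#' @export
read_accession_map <- function(file, tree = NULL) {
  first <- readr::read_lines(file, n_max = 1)
  has_header <- grepl("accession", first, ignore.case = TRUE)
  map <- readr::read_tsv(
    file,
    col_names = if (has_header) TRUE else c("accession", "taxid"),
    skip = 0, show_col_types = FALSE
  )
  map <- tibble(accession = as.character(map[[1]]), taxid = as.integer(map[[2]]))
  if (!is.null(tree)) {
    known <- map$taxid %in% tree$nodes$taxid
    if (any(!known)) {
      message(sum(!known), " accession(s) mapped to taxids absent from the tree; dropped")
      map <- map[known, ]
    }
  }
  map
}
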