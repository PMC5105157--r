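# Ordination of layer profiles: Bray-Curtis dissimilarity and non-metric
# multidimensional scaling (NMDS, Kruskal stress-1) via vegan.

#' Bray-Curtis dissimilarity
#'
#' `1 - 2 * sum(min(u_i, v_i)) / (sum(u) + sum(v))`: 0 for identical
#' abundance vectors, 1 for disjoint supports. Scale-sensitive by
#' construction (doubling one vector changes it), so compare like with like
#' (all counts, or all fractions).
#'
#' @param u,v Nonnegative numeric vectors of equal length, in the same taxon
#'   order, not both all-zero.
#' @return Dissimilarity in `[0, 1]`.
#' @export
#' @examples
#' bray_curtis(c(6, 2, 0), c(2, 2, 4))  # 0.5
bray_curtis <- function(u, v) {
  stopifnot(length(u) == length(v), all(u >= 0), all(v >= 0))
  tot <- sum(u) + sum(v)
  if (tot == 0) stop("both vectors are all-zero")
  1 - 2 * sum(pmin(u, v)) / tot
}

#' Layer-by-layer Bray-Curtis distance matrix
#'
#' Spreads a profile into a layers-by-taxa abundance matrix (absent taxa
#' count 0) and computes all pairwise Bray-Curtis dissimilarities.
#'
#' @param profile Profile tibble ([merge_layers()] output).
#' @param value Column to use as abundance (`"count"` or `"fraction"`).
#' @return A `dist` object labelled `site:layer`.
#' @export
profile_dist <- function(profile, value = "count") {
  wide <- profile |>
    dplyr::mutate(label = paste(.data$site, .data$layer, sep = ":")) |>
    dplyr::select("label", "taxid", dplyr::all_of(value)) |>
    tidyr::pivot_wider(names_from = "taxid", values_from = dplyr::all_of(value),
                       values_fill = 0, values_fn = sum)
  m <- as.matrix(wide[, -1, drop = FALSE])
  rownames(m) <- wide$label
  n <- nrow(m)
  d <- matrix(0, n, n, dimnames = list(rownames(m), rownames(m)))
  for (i in seq_len(n)) {
    for (j in seq_len(i - 1)) {
      d[i, j] <- d[j, i] <- bray_curtis(m[i, ], m[j, ])
    }
  }
  stats::as.dist(d)
}

#' Non-metric multidimensional scaling of layer profiles
#'
#' Embeds a dissimilarity matrix in `k` dimensions minimising Kruskal
#' stress-1 (monotone regression of embedded distances on input
#' dissimilarities), taking the best of `restarts` random starts. Backed by
#' `vegan::metaMDS`/`monoMDS`, the standard implementation in community
#' ecology.
#'
#' @param d A `dist` object (symmetric, zero diagonal), e.g. from
#'   [profile_dist()].
#' @param k Embedding dimension (default 2).
#' @param seed RNG seed; results are reproducible given the seed.
#' @param restarts Number of random starts (default 20).
#' @return A `sedaprof_nmds` object: `points` tibble (`label`, `NMDS1`,
#'   `NMDS2`, ...), `stress`, `k`, `seed`, `restarts`.
#' @export
nmds <- function(d, k = 2, seed = 42, restarts = 20) {
  n <- attr(d, "Size")
  if (is.null(n) || n < 3) stop("NMDS needs at least 3 layers")
  ord <- with_seed(seed, vegan::metaMDS(d, k = k, try = restarts,
                                        trymax = restarts, trace = 0))
  pts <- as_tibble(as.data.frame(ord$points), rownames = "label")
  names(pts)[-1] <- paste0("NMDS", seq_len(k))
  structure(
    list(points = pts, stress = ord$stress, k = k, seed = seed,
         restarts = restarts),
    class = "sedaprof_nmds"
  )
}

#' Kruskal stress-1 of a fixed layout
#'
#' Evaluates the same stress function NMDS minimises for an arbitrary
#' configuration (no iterations are run), e.g. to compare a fitted ordination
#' against random layouts.
#'
#' @param d A `dist` object.
#' @param coords Numeric matrix (layers x dimensions) or the `points` of a
#'   [nmds()] result.
#' @return Stress-1 value.
#' @export
layout_stress <- function(d, coords) {
  if (is.data.frame(coords)) {
    coords <- as.matrix(coords[, grep("^NMDS", names(coords)), drop = FALSE])
  }
  vegan::monoMDS(d, y = coords, maxit = 0)$stress
}

#' @export
print.sedaprof_nmds <- function(x, ...) {
  cat("<sedaprof_nmds> ", nrow(x$points), " layers in ", x$k,
      " dimensions; stress-1 = ", signif(x$stress, 4),
      " (best of ", x$restarts, " starts, seed ", x$seed, ")\n", sep = "")
  invisible(x)
}

#' Tidy an NMDS ordination
#'
#' @param x A `sedaprof_nmds` object.
#' @param ... Unused.
#' @return `tidy()`: the coordinates tibble; `glance()`: one-row tibble with
#'   `stress`, `n_layers`, `k`, `restarts`, `seed`.
#' @export
tidy.sedaprof_nmds <- function(x, ...) x$points

#' @rdname tidy.sedaprof_nmds
#' @export
glance.sedaprof_nmds <- function(x, ...) {
  tibble(stress = x$stress, n_layers = nrow(x$points), k = x$k,
         restarts = x$restarts, seed = x$seed)
}
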