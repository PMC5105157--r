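# Correlating DNA read counts with the zooarchaeological record: Pearson
# correlation, MNI scaling to the full (unexcavated) deposit, and bone-count
# shares.

#' Pearson correlation with a two-sided t-test
#'
#' Sample correlation with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on `n - 2` degrees of freedom
#' (perfect correlation gives p = 0).
#'
#' @param x,y Numeric vectors, `n >= 3`, finite, each with nonzero variance.
#' @return One-row tibble: `rho`, `p_value`, `n`.
#' @export
pearson_cor <- function(x, y) {
  stopifnot(length(x) == length(y))
  if (length(x) < 3) stop("need at least 3 paired observations")
  if (!all(is.finite(x)) || !all(is.finite(y))) stop("values must be finite")
  if (stats::sd(x) == 0 || stats::sd(y) == 0) stop("zero variance input")
  ct <- cor.test(x, y, method = "pearson", alternative = "two.sided")
  rho <- unname(ct$estimate)
  p <- if (abs(rho) >= 1) 0 else unname(ct$p.value)
  tibble(rho = rho, p_value = p, n = length(x))
}

#' Scale MNI counts to the whole deposit
#'
#' Minimum-number-of-individuals counts from a partially excavated midden are
#' extrapolated by the reciprocal of the excavated fraction, rounded to one
#' decimal (an excavated fraction of ~8.7% gives the factor 11.5).
#'
#' @param mni Numeric vector of MNI counts.
#' @param excavated_fraction Fraction of the deposit the counts represent,
#'   in `(0, 1]`.
#' @return Tibble: `mni`, `factor`, `mni_scaled`.
#' @export
#' @examples
#' scale_mni(c(4, 40), 0.087)
scale_mni <- function(mni, excavated_fraction) {
  stopifnot(length(excavated_fraction) == 1,
            excavated_fraction > 0, excavated_fraction <= 1)
  fac <- round(1 / excavated_fraction, 1)
  tibble(mni = mni, factor = fac, mni_scaled = mni * fac)
}

#' Correlate profile read counts with a zooarchaeological column
#'
#' Aligns species between a DNA profile and a bone table by scientific name
#' and computes the Pearson correlation between read counts and the chosen
#' quantity (expected biomass, NISP, scaled MNI, ...). Species present on
#' only one side are excluded and reported. Raw counts are used by default;
#' set `log = TRUE` for log10(x + 1) on both sides.
#'
#' @param counts Tibble with `name` and `count` (e.g. a [merge_layers()]
#'   profile filtered to one layer, or any species-count table).
#' @param reference Tibble with a `name` column and the column `column`.
#' @param column Which reference column to correlate against.
#' @param log Correlate on log10(x + 1) scale (default `FALSE`).
#' @return One-row tibble: `rho`, `p_value`, `n`, `n_excluded`; the excluded
#'   species names are attached as attribute `"excluded"`.
#' @export
correlate_profiles <- function(counts, reference, column, log = FALSE) {
  stopifnot(column %in% names(reference))
  counts <- counts |>
    dplyr::group_by(.data$name) |>
    dplyr::summarise(count = sum(.data$count), .groups = "drop")
  shared <- dplyr::inner_join(counts, reference, by = "name")
  excluded <- c(setdiff(counts$name, reference$name),
                setdiff(reference$name, counts$name))
  if (nrow(shared) < 3) {
    stop("need at least 3 shared species, got ", nrow(shared))
  }
  if (length(excluded)) {
    message(length(excluded), " species present on one side only; excluded: ",
            paste(excluded, collapse = ", "))
  }
  x <- shared$count
  y <- shared[[column]]
  if (log) { x <- log10(x + 1); y <- log10(y + 1) }
  out <- pearson_cor(x, y)
  out$n_excluded <- length(excluded)
  attr(out, "excluded") <- excluded
  out
}

#' Share of bones attributed to a group
#'
#' Percentage of identified bone specimens belonging to a group of taxa (for
#' example, cetacean finds among all excavated bones at a site).
#'
#' @param bones Tibble with columns `site`, `taxon`, `group`, `count`, where
#'   rows with `group == total_group` carry the site's total excavated bone
#'   count. The package ships such a table for the printed cetacean finds:
#'   `system.file("extdata", "site_bone_counts.tsv", package = "sedaprof")`.
#' @param site Site to evaluate.
#' @param group Group whose share is computed (default `"cetacean"`).
#' @param total_group Group label of the total row (default `"total"`).
#' @return Percentage (0-100).
#' @export
bone_group_share <- function(bones, site, group = "cetacean",
                             total_group = "total") {
  b <- bones[bones$site == site, , drop = FALSE]
  tot <- sum(b$count[b$group == total_group])
  if (tot == 0) stop("no total bone count for site '", site, "'")
  100 * sum(b$count[b$group == group]) / tot
}
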