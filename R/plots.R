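# ggplot2 displays for the main result types.

#' Plot an NMDS ordination
#'
#' Layers as labelled points in the first two ordination dimensions, with the
#' stress in the subtitle.
#'
#' @param object A `sedaprof_nmds` object.
#' @param colour_by Optional vector (length = layers, in `points` order) used
#'   to colour points, e.g. culture labels.
#' @param ... Unused.
#' @return A ggplot.
#' @export
autoplot.sedaprof_nmds <- function(object, colour_by = NULL, ...) {
  pts <- object$points
  if (!is.null(colour_by)) pts$colour_by <- colour_by
  p <- ggplot2::ggplot(pts, ggplot2::aes(x = .data$NMDS1, y = .data$NMDS2)) +
    ggplot2::geom_point(
      if (is.null(colour_by)) NULL else ggplot2::aes(colour = .data$colour_by),
      size = 3
    ) +
    ggplot2::geom_text(ggplot2::aes(label = .data$label),
                       vjust = -0.8, size = 3) +
    ggplot2::labs(
      title = "NMDS of layer faunal profiles (Bray-Curtis)",
      subtitle = paste0("stress-1 = ", signif(object$stress, 3)),
      colour = NULL
    ) +
    ggplot2::theme_minimal()
  p
}

#' Stacked relative-abundance barplot of layer profiles
#'
#' One bar per (site, layer), filled by taxon fraction — the standard midden
#' faunal-profile display.
#'
#' @param profile Profile tibble with a `fraction` column (see
#'   [relative_abundance()]).
#' @return A ggplot.
#' @export
plot_layer_profiles <- function(profile) {
  stopifnot("fraction" %in% names(profile))
  ggplot2::ggplot(
    profile,
    ggplot2::aes(x = paste(.data$site, .data$layer, sep = ":"),
                 y = .data$fraction, fill = .data$name)
  ) +
    ggplot2::geom_col() +
    ggplot2::labs(x = NULL, y = "relative abundance", fill = NULL) +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45, hjust = 1))
}

#' Plot a positional C->T damage profile
#'
#' C->T misincorporation frequency along the first 5' positions; authentic
#' ancient DNA shows an elevated terminal frequency decaying into the read.
#'
#' @param profile Tibble from [ct_profile()].
#' @param taxon Optional label for the title.
#' @return A ggplot.
#' @export
plot_damage_profile <- function(profile, taxon = NULL) {
  ggplot2::ggplot(profile, ggplot2::aes(x = .data$position, y = .data$freq_ct)) +
    ggplot2::geom_line(colour = "firebrick") +
    ggplot2::geom_point(colour = "firebrick") +
    ggplot2::labs(
      x = "read position (5' -> 3')", y = "C->T frequency",
      title = paste(c("5' C->T misincorporation profile", taxon), collapse = " - ")
    ) +
    ggplot2::theme_minimal()
}
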