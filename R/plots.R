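ellipse_path <- function(ellipse, n = 200) {
  th <- ellipse$angle_deg * pi / 180
  t <- seq(0, 2 * pi, length.out = n)
  u <- (ellipse$width / 2) * cos(t)
  v <- (ellipse$height / 2) * sin(t)
  tibble(region = ellipse$region,
         x = ellipse$center_x + u * cos(th) - v * sin(th),
         y = ellipse$center_y + u * sin(th) + v * cos(th))
}

#' BOILED-Egg plot of classified compounds
#'
#' Draws the absorption (white) and blood-brain-barrier (yolk) ellipses in
#' the (TPSA, WLOGP) plane with one labelled point per compound.
#'
#' @param x A `plif_bbb` tibble from [boiled_egg()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
plot_boiled_egg <- function(x, ...) {
  ells <- boiled_egg_ellipses()
  paths <- bind_rows(ellipse_path(ells[1, ]), ellipse_path(ells[2, ]))
  ggplot2::ggplot() +
    ggplot2::geom_polygon(
      data = filter(paths, .data$region == "white"),
      ggplot2::aes(.data$x, .data$y), fill = "grey92", colour = "grey60") +
    ggplot2::geom_polygon(
      data = filter(paths, .data$region == "yolk"),
      ggplot2::aes(.data$x, .data$y), fill = "lightgoldenrod1",
      colour = "goldenrod") +
    ggplot2::geom_point(
      data = x, ggplot2::aes(.data$tpsa, .data$wlogp,
                             colour = .data$bbb_permeant)) +
    ggplot2::geom_text(
      data = x, ggplot2::aes(.data$tpsa, .data$wlogp,
                             label = .data$compound),
      vjust = -0.8, size = 3) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey30"),
      name = "BBB permeant") +
    ggplot2::labs(x = "TPSA (Å²)", y = "WLOGP") +
    ggplot2::theme_minimal()
}

#' @rdname plot_boiled_egg
#' @export
autoplot.plif_bbb <- function(x, ...) plot_boiled_egg(x, ...)

#' Heatmap of pairwise chemical similarity
#'
#' @param x A `plif_chemsim` from [chem_similarity_matrix()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plif_chemsim <- function(x, ...) {
  ggplot2::ggplot(x$long,
                  ggplot2::aes(.data$compound_a, .data$compound_b,
                               fill = .data$similarity)) +
    ggplot2::geom_tile() +
    ggplot2::scale_fill_gradient(low = "white", high = "steelblue4",
                                 limits = c(0, 1)) +
    ggplot2::labs(x = NULL, y = NULL, fill = "Tanimoto") +
    ggplot2::theme_minimal() +
    ggplot2::theme(axis.text.x = ggplot2::element_text(angle = 45,
                                                       hjust = 1))
}

#' Rank-similarity plot of a screening run
#'
#' Shows every ranked library entry by similarity, highlighting the
#' entries that pass the empirical p-value threshold and are approved
#' drugs.
#'
#' @param x A `plif_screen` from [screen()].
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.plif_screen <- function(x, ...) {
  ranked <- as_tibble(x$ranking) |>
    mutate(hit = .data$complex_id %in% x$hits$complex_id)
  ggplot2::ggplot(ranked, ggplot2::aes(.data$rank, .data$similarity)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$hit), size = 1) +
    ggplot2::scale_colour_manual(
      values = c(`TRUE` = "firebrick", `FALSE` = "grey60"),
      name = sprintf("hit (p ≤ %g)", x$params$p_max)) +
    ggplot2::labs(x = "rank", y = "Tanimoto similarity to query") +
    ggplot2::theme_minimal()
}
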