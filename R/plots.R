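# ggplot2 views of the result objects: reconstructed landscapes, averaged
# reaction profiles with SD/SE bands, hemisphere discs and binned
# reaction-coordinate observables.

#' @exportS3Method ggplot2::autoplot
autoplot.glycofel_fel <- function(object, ...) {
  cv <- attr(object, "cv_names")
  if (length(cv) == 1) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[cv[1]]], y = .data$fel)) +
      ggplot2::geom_line(linewidth = 0.8) +
      ggplot2::labs(x = cv[1], y = "free energy (kcal/mol)") +
      ggplot2::theme_minimal()
  } else if (length(cv) == 2) {
    ggplot2::ggplot(object, ggplot2::aes(x = .data[[cv[1]]], y = .data[[cv[2]]])) +
      ggplot2::geom_raster(ggplot2::aes(fill = .data$fel)) +
      ggplot2::geom_contour(ggplot2::aes(z = .data$fel), binwidth = 1,
                            colour = "grey30", linewidth = 0.2) +
      ggplot2::scale_fill_viridis_c(name = "F (kcal/mol)") +
      ggplot2::coord_equal() +
      ggplot2::theme_minimal()
  } else {
    abort("autoplot supports 1D and 2D landscapes; project higher-dimensional grids first")
  }
}

#' @exportS3Method ggplot2::autoplot
autoplot.glycofel_avg_profile <- function(object, ...) {
  ggplot2::ggplot(object, ggplot2::aes(x = .data$s)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$f_avg - .data$sd,
                                      ymax = .data$f_avg + .data$sd),
                         fill = "darkgreen", alpha = 0.25) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$f_avg - .data$se,
                                      ymax = .data$f_avg + .data$se),
                         fill = "steelblue", alpha = 0.35) +
    ggplot2::geom_line(ggplot2::aes(y = .data$f_avg), colour = "red",
                       linewidth = 0.9) +
    ggplot2::labs(x = "reaction coordinate (Å)",
                  y = "free energy (kcal/mol)",
                  caption = "red: exponential average; green band: SD; blue band: SE") +
    ggplot2::theme_minimal()
}

#' Disc plot of puckering states on one hemisphere
#'
#' Scatter of [hemisphere_projection()] output on the projected disc, with
#' the equator rim and the canonical conformers of that hemisphere marked.
#'
#' @param projected Output of [hemisphere_projection()].
#' @return A ggplot object.
#' @export
plot_pucker_disc <- function(projected) {
  hemi <- attr(projected, "hemisphere") %||% "north"
  lat <- conformer_table()
  lat <- lat[if (hemi == "north") lat$canonical_theta <= 90 else
    lat$canonical_theta >= 90, ]
  lp <- hemisphere_projection(lat[, c("canonical_theta", "canonical_phi")] |>
                                rlang::set_names(c("theta", "phi")), hemi)
  lp$name <- lat$name
  rim <- tibble(
    x = cos(seq(0, 2 * pi, length.out = 181)),
    y = sin(seq(0, 2 * pi, length.out = 181))
  )
  ggplot2::ggplot(projected, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_path(data = rim, colour = "grey60") +
    ggplot2::geom_point(alpha = 0.4, size = 0.8) +
    ggplot2::geom_point(data = lp, colour = "red3", shape = 3) +
    ggplot2::geom_text(data = lp, ggplot2::aes(label = .data$name),
                       colour = "red3", vjust = -0.8, size = 3) +
    ggplot2::coord_equal() +
    ggplot2::labs(title = paste0(hemi, "ern hemisphere"), x = NULL, y = NULL) +
    ggplot2::theme_void()
}

#' Plot binned observables along the normalized reaction coordinate
#'
#' Mean +/- SD per bin of each observable from
#' [normalized_reaction_coordinate()] against xi.
#'
#' @param binned Output of [normalized_reaction_coordinate()].
#' @return A ggplot object.
#' @export
plot_reaction_coordinate <- function(binned) {
  means <- names(binned)[endsWith(names(binned), "_mean")]
  long <- purrr::map_dfr(means, function(m) {
    ob <- sub("_mean$", "", m)
    tibble(xi = binned$xi, observable = ob,
           mean = binned[[m]], sd = binned[[paste0(ob, "_sd")]])
  })
  ggplot2::ggplot(long, ggplot2::aes(x = .data$xi, y = .data$mean,
                                     colour = .data$observable,
                                     fill = .data$observable)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$mean - .data$sd,
                                      ymax = .data$mean + .data$sd),
                         alpha = 0.2, colour = NA) +
    ggplot2::geom_line() +
    ggplot2::labs(x = expression(xi), y = "distance (Å)") +
    ggplot2::theme_minimal()
}
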