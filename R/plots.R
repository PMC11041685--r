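# ggplot2 visualisations for the main result types.

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

#' Plot an assembly
#'
#' Monomer beads as points (participating interface beads highlighted),
#' fractal bonds as segments between the bonded dimers' corner midpoints.
#'
#' @param object An `assembly`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.assembly <- function(object, ...) {
  a <- object
  m <- a$monomers
  p <- ggplot2::ggplot(m, ggplot2::aes(x = .data$x, y = .data$y)) +
    ggplot2::geom_point(ggplot2::aes(colour = .data$participates),
                        size = 2, show.legend = FALSE) +
    ggplot2::scale_colour_manual(values = c("FALSE" = "grey40",
                                            "TRUE" = "firebrick")) +
    ggplot2::coord_equal() +
    ggplot2::labs(x = "x (nm)", y = "y (nm)") +
    ggplot2::theme_minimal()
  if (nrow(a$fractal_bonds) > 0) {
    site <- function(d) {
      r <- a$dimers[match(d, a$dimers$id), ]
      h <- a$hexamers[match(r$hexamer_id, a$hexamers$id), ]
      w <- a$params$hexamer_width / 2
      tibble::tibble(x = h$x + r$corner_dx * w, y = h$y + r$corner_dy * w)
    }
    s1 <- site(a$fractal_bonds$dimer1)
    s2 <- site(a$fractal_bonds$dimer2)
    seg <- tibble::tibble(x = s1$x, y = s1$y, xend = s2$x, yend = s2$y)
    p <- p + ggplot2::geom_segment(
      data = seg,
      ggplot2::aes(x = .data$x, y = .data$y,
                   xend = .data$xend, yend = .data$yend),
      colour = "steelblue", linewidth = 0.6)
  }
  p
}

#' Plot a box-count scaling fit
#'
#' Log-log box counts per offset with the fitted dimension in the title.
#'
#' @param object A `dimension_fit`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.dimension_fit <- function(object, ...) {
  ct <- object$counts
  ggplot2::ggplot(ct, ggplot2::aes(x = log(1 / .data$box_size),
                                   y = log(.data$count),
                                   colour = factor(.data$offset))) +
    ggplot2::geom_point() +
    ggplot2::geom_smooth(method = "lm", se = FALSE, formula = y ~ x,
                         linewidth = 0.5) +
    ggplot2::labs(x = "log(1 / box size)", y = "log(count)",
                  colour = "grid offset",
                  title = sprintf("D = %.3f +/- %.3f, R2 = %.4f",
                                  object$D, object$D_sd, object$R2)) +
    ggplot2::theme_minimal()
}

#' Plot a species distribution
#'
#' Subunit fractions across the oligomer ladder.
#'
#' @param object A `species_distribution`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.species_distribution <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d$species <- factor(d$species, levels = d$species)
  ggplot2::ggplot(d, ggplot2::aes(x = .data$species,
                                  y = .data$subunit_fraction)) +
    ggplot2::geom_col(fill = "steelblue") +
    ggplot2::labs(x = NULL, y = "subunit fraction") +
    ggplot2::theme_minimal()
}

#' Plot a scattering profile
#'
#' Intensity versus q on a log-log scale.
#'
#' @param object A `scattering_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.scattering_profile <- function(object, ...) {
  d <- tibble::as_tibble(object)
  d <- d[d$q > 0, ]
  ggplot2::ggplot(d, ggplot2::aes(x = .data$q, y = .data$intensity)) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::scale_x_log10() + ggplot2::scale_y_log10() +
    ggplot2::labs(x = "q (1/nm)", y = "I(q)") +
    ggplot2::theme_minimal()
}

#' Plot a titration curve
#'
#' Subunit fraction of each species along the scanned variable.
#'
#' @param curve Output of [titration_curve()].
#' @param variable Axis label for the scanned variable.
#' @return A ggplot object.
#' @export
plot_titration <- function(curve, variable = "value") {
  ggplot2::ggplot(curve, ggplot2::aes(x = .data$value,
                                      y = .data$subunit_fraction,
                                      colour = .data$species)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = variable, y = "subunit fraction", colour = NULL) +
    ggplot2::theme_minimal()
}
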