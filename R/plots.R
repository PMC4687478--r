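#' Plot a potential curve
#'
#' @param object A `vibhb_curve`.
#' @param ... Unused.
#' @importFrom ggplot2 autoplot
#' @method autoplot vibhb_curve
#' @export
autoplot.vibhb_curve <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$q, y = .data$energy)) +
    ggplot2::geom_line() +
    ggplot2::geom_point(size = 0.6) +
    ggplot2::labs(
      x = "q (Å)", y = "E (kcal/mol)",
      title = curve_label(object),
      subtitle = sprintf("R = %.2f Å + q", curve_r0(object))
    )
}

#' Plot a spectrum over its potential curve
#'
#' Draws the curve, horizontal level lines, and the probability
#' densities |psi|^2 offset to their level energies (the conventional
#' way vibrational states on a proton-transfer curve are displayed).
#'
#' @param object A `vibhb_spectrum`.
#' @param curve The `vibhb_curve` it was solved on.
#' @param scale Vertical scaling of the densities, kcal/mol per
#'   probability-density unit.
#' @param ... Unused.
#' @method autoplot vibhb_spectrum
#' @export
autoplot.vibhb_spectrum <- function(object, curve, scale = 0.5, ...) {
  q <- grid_points(object$grid)
  dens <- purrr::imap(
    rlang::set_names(seq_along(object$energies),
                     seq_along(object$energies) - 1L),
    function(j, nm) tibble::tibble(
      state = as.integer(nm), q = q,
      y = object$energies[[j]] + scale * object$wavefunctions[, j]^2
    )
  ) |> purrr::list_rbind()
  ggplot2::ggplot() +
    ggplot2::geom_line(
      data = tibble::as_tibble(curve),
      ggplot2::aes(x = .data$q, y = .data$energy)
    ) +
    ggplot2::geom_hline(yintercept = object$energies,
                        linetype = "dashed", linewidth = 0.3) +
    ggplot2::geom_line(
      data = dens,
      ggplot2::aes(x = .data$q, y = .data$y,
                   colour = factor(.data$state))
    ) +
    ggplot2::labs(x = "q (Å)", y = "E (kcal/mol)",
                  colour = "state",
                  title = sprintf("%s on %s",
                                  object$mass$isotope_label,
                                  object$curve_label))
}

#' @method autoplot vibhb_report
#' @export
autoplot.vibhb_report <- function(object, ...) {
  plots <- purrr::imap(object$spectra,
                       ~ autoplot.vibhb_spectrum(.x, object$curve))
  if (length(plots) == 1L) plots[[1]] else plots
}
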