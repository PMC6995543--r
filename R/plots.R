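# ggplot2 visualisations for the main result types.

#' @export
autoplot.t_histogram <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object), ggplot2::aes(.data$bin, .data$count)) +
    ggplot2::geom_col(width = 1, fill = "steelblue") +
    ggplot2::labs(
      x = "t angle (degrees)", y = "count",
      title = "Distribution of the parametric t angle (1-degree bins)"
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.fod_profile <- function(object, ...) {
  df <- object$residues |>
    tidyr::pivot_longer(
      c("t_dens", "o_dens", "r_u"),
      names_to = "distribution", values_to = "density"
    ) |>
    dplyr::mutate(distribution = dplyr::recode(.data$distribution,
      t_dens = "T (theoretical)", o_dens = "O (observed)", r_u = "R (uniform)"
    ))
  ggplot2::ggplot(df, ggplot2::aes(.data$index, .data$density, colour = .data$distribution)) +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "residue", y = "hydrophobicity density",
      title = sprintf("FOD profile of %s (RD = %.3f)", object$id, object$rd)
    ) +
    ggplot2::theme_minimal()
}

#' @export
autoplot.code_screen <- function(object, ...) {
  df <- tibble::as_tibble(object) |> dplyr::filter(!is.na(.data$r))
  ggplot2::ggplot(df, ggplot2::aes(
    x = rank(.data$r), y = .data$r, colour = .data$sign
  )) +
    ggplot2::geom_point(size = 0.8) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2) +
    ggplot2::scale_colour_manual(
      values = c(negative = "firebrick", positive = "steelblue", none = "grey60")
    ) +
    ggplot2::labs(
      x = "key (ordered by r)", y = "Pearson r",
      title = sprintf("Correlation screen (%s mode)", attr(object, "mode"))
    ) +
    ggplot2::theme_minimal()
}

#' Ramachandran plot of an encoded domain
#'
#' Shows the observed (phi, psi) points coloured by structural code, with
#' the elliptical early-stage path overlaid.
#'
#' @param encoding result of [encode_domain()].
#' @param e the [ellipse_spec()] used to encode (for the path overlay).
#' @return a ggplot object.
#' @export
plot_ramachandran <- function(encoding, e = default_ellipse()) {
  path <- purrr::map(seq(0, 359.5, by = 0.5), function(t) {
    p <- ellipse_point_at_t(e, t)
    tibble::tibble(phi = p[1], psi = p[2])
  }) |> dplyr::bind_rows()
  df <- dplyr::filter(tibble::as_tibble(encoding), !is.na(.data$code))
  ggplot2::ggplot(df, ggplot2::aes(.data$phi, .data$psi)) +
    ggplot2::geom_path(data = path, colour = "grey50") +
    ggplot2::geom_point(ggplot2::aes(colour = .data$code)) +
    ggplot2::coord_fixed(xlim = c(-180, 180), ylim = c(-180, 180)) +
    ggplot2::labs(x = expression(phi), y = expression(psi)) +
    ggplot2::theme_minimal()
}

#' Plot the intrinsic hydrophobicity profile of a short sequence
#'
#' @param sequence string over the 20-letter alphabet (e.g. a tetrapeptide).
#' @param scale named hydrophobicity vector.
#' @return a ggplot object.
#' @export
plot_hydrophobicity_profile <- function(sequence, scale = hydrophobicity_scale()) {
  df <- hydrophobicity_profile(sequence, scale)
  ggplot2::ggplot(df, ggplot2::aes(.data$position, .data$hr)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_text(ggplot2::aes(label = .data$aa), vjust = -0.8) +
    ggplot2::labs(x = "position", y = "intrinsic hydrophobicity") +
    ggplot2::theme_minimal()
}
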