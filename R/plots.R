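heat_panel <- function(df, value, title, diverging = FALSE) {
  p <- ggplot2::ggplot(df, ggplot2::aes(.data$dose1, .data$dose2,
                                        fill = .data[[value]])) +
    ggplot2::geom_raster() +
    ggplot2::labs(title = title, x = "dose 1", y = "dose 2", fill = NULL) +
    ggplot2::theme_minimal(base_size = 10)
  if (diverging) {
    p + ggplot2::scale_fill_gradient2(low = "firebrick", mid = "grey95",
                                      high = "forestgreen", midpoint = 0)
  } else {
    p + ggplot2::scale_fill_viridis_c()
  }
}

#' Plot a Hand-GP analysis
#'
#' Heatmap panels in the standard four-row layout: fitted surface, Hand null
#' reference, effect surface (green = synergy, red = antagonism) and
#' residuals at the design doses.
#'
#' @param object A `hand_gp` fit.
#' @param which Panels to draw (subset of `"fitted"`, `"null"`, `"effect"`,
#'   `"residuals"`).
#' @param ... Unused.
#' @return A patchwork object if the patchwork package is installed and more
#'   than one panel is requested; otherwise a (list of) ggplot object(s).
#' @export
autoplot.hand_gp <- function(object,
                             which = c("fitted", "null", "effect", "residuals"),
                             ...) {
  which <- match.arg(which, several.ok = TRUE)
  panels <- list()
  if ("fitted" %in% which) {
    panels$fitted <- heat_panel(as_tibble(object$fitted), "mean", "GP fit")
  }
  if ("null" %in% which) {
    panels$null <- heat_panel(as_tibble(object$null), "null", "Hand null reference")
  }
  if ("effect" %in% which) {
    panels$effect <- heat_panel(as_tibble(object$effect), "effect",
                                "Effect (null - fit)", diverging = TRUE)
  }
  if ("residuals" %in% which) {
    panels$residuals <- ggplot2::ggplot(
      object$residuals,
      ggplot2::aes(.data$dose1, .data$dose2, fill = .data$residual)
    ) +
      ggplot2::geom_tile() +
      ggplot2::scale_fill_gradient2(low = "navy", mid = "grey95", high = "darkred") +
      ggplot2::labs(title = "Residuals", x = "dose 1", y = "dose 2", fill = NULL) +
      ggplot2::theme_minimal(base_size = 10)
  }
  if (length(panels) == 1) return(panels[[1]])
  if (requireNamespace("patchwork", quietly = TRUE)) {
    return(patchwork::wrap_plots(panels, ncol = 2))
  }
  panels
}

#' Monotherapy slice plot with credible bands
#'
#' @param fit A `hand_gp` object.
#' @return A ggplot object: fitted monotherapy slices (ribbon = 95% band)
#'   with the observed monotherapy points.
#' @export
plot_monotherapy <- function(fit) {
  at <- dr_attrs(fit$data)
  s1 <- dplyr::mutate(surface_slice(fit$fitted, "drug1"), drug = at$drug1)
  s2 <- dplyr::mutate(surface_slice(fit$fitted, "drug2"), drug = at$drug2)
  obs <- dplyr::bind_rows(
    dplyr::mutate(monotherapy(fit$data, "drug1"), drug = at$drug1),
    dplyr::mutate(monotherapy(fit$data, "drug2"), drug = at$drug2)
  )
  ggplot2::ggplot(dplyr::bind_rows(s1, s2),
                  ggplot2::aes(.data$position, .data$mean)) +
    ggplot2::geom_ribbon(ggplot2::aes(ymin = .data$lower, ymax = .data$upper),
                         fill = "steelblue", alpha = 0.25) +
    ggplot2::geom_line(colour = "steelblue") +
    ggplot2::geom_point(data = obs,
                        ggplot2::aes(.data$dose, .data$response), size = 1) +
    ggplot2::scale_x_continuous(trans = "log1p") +
    ggplot2::facet_wrap(~drug, scales = "free_x") +
    ggplot2::labs(x = sprintf("dose (%s, log1p scale)", at$dose_unit),
                  y = "response") +
    ggplot2::theme_minimal(base_size = 10)
}

#' Screen-level volume-difference scatter
#'
#' @param screen A tibble from [run_screen] (columns `vd_handgp`,
#'   `vd_musyc`).
#' @return A ggplot object comparing the Hand-GP and MuSyC volume scores.
#' @export
plot_screen <- function(screen) {
  ggplot2::ggplot(screen, ggplot2::aes(.data$vd_handgp, .data$vd_musyc)) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_vline(xintercept = 0, colour = "grey70") +
    ggplot2::geom_point() +
    ggplot2::geom_abline(slope = 1, intercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::labs(x = "volume difference (Hand-GP)",
                  y = "volume difference (MuSyC)") +
    ggplot2::theme_minimal(base_size = 10)
}
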