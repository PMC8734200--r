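#' Hand-GP synergy analysis of a two-drug checkerboard
#'
#' The full analysis in one call:
#' \enumerate{
#'   \item build data-driven Gamma priors ([gp_priors]) and estimate the GP
#'     hyperparameters, either by HMC ([fit_gp_hmc], posterior-mean plug-in)
#'     or by deterministic MAP optimisation ([fit_gp_map]);
#'   \item fit the GP posterior surface on a dense log1p-spaced grid
#'     ([gp_posterior]);
#'   \item extract the fitted monotherapy curves (extended beyond the design
#'     span so the construction can follow equivalent doses past the maximal
#'     design dose) and build the Hand null reference ([hand_null_surface]);
#'   \item form the effect surface `null - fitted` ([effect_surface]), the
#'     volume-difference score ([volume_difference]) with its correlated-
#'     error 95% band, per-design-dose synergy calls, and residuals.
#' }
#'
#' @param data A [dose_response] data set (or plain tibble with
#'   `dose1,dose2,response`, interpreted with default metadata).
#' @param mode `"map"` (fast, deterministic; default) or `"hmc"`.
#' @param n_per_axis Prediction grid size per axis.
#' @param priors A [gp_priors]; default built from the data.
#' @param settings An [hmc_settings] for `mode = "hmc"`.
#' @param theta Optional fixed [gp_hyperparameters]; skips estimation.
#' @return A `hand_gp` object: list with `fitted` (`gp_surface`), `null`
#'   (`hand_null`), `effect` (`effect_surface`), `volumes` (with
#'   `vd_lower`/`vd_upper`), `calls` (per design dose pair), `residuals`,
#'   `mse`, `theta`, `inference`, `priors`, `data`, `grid`.
#' @examples
#' d <- simulate_combination(alpha = 0.5, seed = 1)
#' fit <- hand_gp(d, n_per_axis = 41)
#' glance(fit)
#' @export
hand_gp <- function(data, mode = c("map", "hmc"), n_per_axis = 101,
                    priors = NULL, settings = hmc_settings(), theta = NULL) {
  mode <- match.arg(mode)
  if (!inherits(data, "dose_response")) data <- dose_response(data)
  at <- dr_attrs(data)
  priors <- priors %||% gp_priors(data)
  inference <- NULL
  if (is.null(theta)) {
    if (mode == "hmc") {
      inference <- fit_gp_hmc(data, priors = priors, settings = settings)
      theta <- inference$posterior_mean
    } else {
      inference <- fit_gp_map(data, priors = priors)
      theta <- inference$theta
    }
  }
  grid <- dose_grid(data, n_per_axis = n_per_axis,
                    lengthscales = c(theta$l1, theta$l2))
  fitted <- gp_posterior(data, theta, grid)
  f1 <- gp_mono_curve(data, theta, grid, which = "drug1")
  f2 <- gp_mono_curve(data, theta, grid, which = "drug2")
  null <- hand_null_surface(f1, f2, grid)
  eff <- effect_surface(fitted, null, direction = at$direction)
  vols <- volume_difference(fitted, null, direction = at$direction)
  # correlated-error band: the fitted surface's pointwise 1.96 sd integrated
  # over the dose plane (errors treated as fully correlated -- conservative)
  v_sd <- volume_under_surface(grid, sqrt(fitted$var))
  vols$vd_lower <- vols$volume_difference - 1.96 * v_sd
  vols$vd_upper <- vols$volume_difference + 1.96 * v_sd
  vols$call <- dplyr::case_when(
    vols$vd_lower > 0 ~ "synergy",
    vols$vd_upper < 0 ~ "antagonism",
    TRUE ~ "additive"
  )
  design <- dplyr::distinct(as_tibble(data)[c("dose1", "dose2")])
  calls <- dplyr::inner_join(design, as_tibble(eff), by = c("dose1", "dose2"))
  obs <- dplyr::left_join(as_tibble(data), as_tibble(fitted)[c("dose1", "dose2", "mean")],
                          by = c("dose1", "dose2"))
  residuals <- dplyr::mutate(obs, residual = .data$response - .data$mean)
  structure(
    list(
      fitted = fitted, null = null, effect = eff, volumes = vols,
      calls = calls,
      residuals = residuals[c("dose1", "dose2", "response", "residual")],
      mse = mean(residuals$residual^2),
      mse_mono = c(drug1 = surface_mse(data, fitted, "drug1"),
                   drug2 = surface_mse(data, fitted, "drug2")),
      theta = theta, inference = inference, priors = priors,
      data = data, grid = grid, mono_curves = list(drug1 = f1, drug2 = f2)
    ),
    class = "hand_gp"
  )
}

# fitted monotherapy curve on the grid axis, extended beyond the design span
# (log1p spacing continued out to `extend` times the maximal design dose) so
# that Hand inversion has headroom for equivalent doses past the design
gp_mono_curve <- function(data, theta, grid, which = c("drug1", "drug2"),
                          extend = 4) {
  which <- match.arg(which)
  axis <- if (which == "drug1") grid$axis1 else grid$axis2
  l <- if (which == "drug1") theta$l1 else theta$l2
  dmax <- max(axis)
  u_max <- log1p(dmax / l)
  u_ext <- log1p(extend * dmax / l)
  n_ext <- max(8L, ceiling(length(axis) / 2))
  ext <- l * expm1(seq(u_max, u_ext, length.out = n_ext + 1L)[-1])
  doses <- c(axis, ext)
  pts <- if (which == "drug1") {
    tibble(dose1 = doses, dose2 = 0)
  } else {
    tibble(dose1 = 0, dose2 = doses)
  }
  y <- data$response
  A <- gram_matrix(data, theta) + diag(theta$sigma2, length(y))
  ch <- chol(A)
  Ks <- cross_matrix(data, pts, theta)
  mu <- drop(crossprod(Ks, backsolve(ch, forwardsolve(t(ch), y))))
  monotherapy_curve(doses, mu)
}

#' @export
print.hand_gp <- function(x, ...) {
  at <- dr_attrs(x$data)
  cat(sprintf("<hand_gp> %s x %s (%d points)\n", at$drug1, at$drug2, nrow(x$data)))
  print(x$theta)
  cat(sprintf("  volume difference %.4g [%.4g, %.4g] -> %s\n",
              x$volumes$volume_difference, x$volumes$vd_lower,
              x$volumes$vd_upper, x$volumes$call))
  cat(sprintf("  surface MSE %.4g; calls at design doses: %s\n", x$mse,
              paste(names(table(x$calls$call)), table(x$calls$call),
                    sep = "=", collapse = ", ")))
  invisible(x)
}

#' @describeIn hand_gp per-design-dose effect table: `dose1`, `dose2`,
#'   `effect`, `lower`, `upper`, `call`.
#' @param x,object A `hand_gp` object.
#' @param ... Unused.
#' @export
tidy.hand_gp <- function(x, ...) {
  as_tibble(x$calls)
}

#' @describeIn hand_gp one-row summary: volumes, volume difference with its
#'   95% band and call, surface and monotherapy MSEs, hyperparameters.
#' @export
glance.hand_gp <- function(x, ...) {
  tibble(
    volume_fitted = x$volumes$volume_fitted,
    volume_null = x$volumes$volume_null,
    volume_difference = x$volumes$volume_difference,
    vd_lower = x$volumes$vd_lower,
    vd_upper = x$volumes$vd_upper,
    call = x$volumes$call,
    mse = x$mse,
    mse_mono1 = unname(x$mse_mono["drug1"]),
    mse_mono2 = unname(x$mse_mono["drug2"]),
    sigma_f2 = x$theta$sigma_f2, l1 = x$theta$l1, l2 = x$theta$l2,
    sigma2 = x$theta$sigma2
  )
}

#' Diagonal fractional-effect profile of a Hand-GP fit
#'
#' @param fit A `hand_gp` object.
#' @param from Fractional-effect axis from the fitted or the null diagonal.
#' @return See [fractional_effect_curve].
#' @export
hand_gp_fractional_effect <- function(fit, from = c("fitted", "null")) {
  nd_tbl <- as_tibble(fit$null)
  nd_tbl$mean <- nd_tbl$null
  nd <- surface_slice(structure(nd_tbl, grid = attr(fit$null, "grid")), "diagonal")
  fd <- surface_slice(fit$fitted, "diagonal")
  fractional_effect_curve(nd, fd, from = from)
}
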