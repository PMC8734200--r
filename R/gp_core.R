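#' Log marginal likelihood of the GP dose-response model
#'
#' Under the zero-mean GP with the 2-D logarithmic kernel and i.i.d. Gaussian
#' noise, the observations are jointly Gaussian:
#' `y ~ N(0, K + sigma2 * I)`. This returns `log p(y | X, theta)` evaluated
#' via a Cholesky factorisation.
#'
#' @param data A [dose_response] data set.
#' @param theta A [gp_hyperparameters] object.
#' @param jitter Relative diagonal jitter (see [gram_matrix]).
#' @return The log marginal likelihood (scalar).
#' @export
gp_log_marginal <- function(data, theta, jitter = 1e-8) {
  y <- data$response
  n <- length(y)
  A <- gram_matrix(data, theta, jitter = jitter) + diag(theta$sigma2, n)
  ch <- tryCatch(chol(A), error = function(e) {
    abort("covariance matrix not positive definite after jitter")
  })
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  -0.5 * sum(y * alpha) - sum(log(diag(ch))) - n / 2 * log(2 * pi)
}

# gradient of gp_log_marginal w.r.t. (l1, l2, sigma_f2, sigma2), natural scale
gp_log_marginal_grad <- function(data, theta, jitter = 1e-8) {
  y <- data$response
  n <- length(y)
  u1 <- log1p(data$dose1 / theta$l1)
  u2 <- log1p(data$dose2 / theta$l2)
  D <- outer(u1, u1, "-")^2 + outer(u2, u2, "-")^2
  K <- theta$sigma_f2 * exp(-D / 2)
  A <- K + diag(jitter * theta$sigma_f2 + theta$sigma2, n)
  ch <- chol(A)
  Ainv <- chol2inv(ch)
  alpha <- Ainv %*% y
  W <- tcrossprod(alpha) - Ainv # dL/dA = W/2
  # du/dl = -x / (l (l + x))
  g1 <- -data$dose1 / (theta$l1 * (theta$l1 + data$dose1))
  g2 <- -data$dose2 / (theta$l2 * (theta$l2 + data$dose2))
  dK_l1 <- -K * outer(u1, u1, "-") * outer(g1, g1, "-")
  dK_l2 <- -K * outer(u2, u2, "-") * outer(g2, g2, "-")
  dK_sf <- K / theta$sigma_f2 + diag(jitter, n)
  c(
    l1 = 0.5 * sum(W * dK_l1),
    l2 = 0.5 * sum(W * dK_l2),
    sigma_f2 = 0.5 * sum(W * dK_sf),
    sigma2 = 0.5 * sum(diag(W))
  )
}

#' GP posterior predictive surface on a dose grid
#'
#' Exact GP regression: for each grid node x*,
#' `mu = k' (K + sigma2 I)^-1 y` and
#' `v = k(x*,x*) - k' (K + sigma2 I)^-1 k`, with 95% intervals
#' `mu +/- 1.96 sqrt(v)`. By default the predictive is for the latent,
#' noise-free surface f*; set `include_noise = TRUE` to predict new
#' observations y* (adds `sigma2` to the variance).
#'
#' @inheritParams gp_log_marginal
#' @param grid A [dose_grid]; defaults to a 101-point-per-axis log1p grid
#'   warped by the length scales in `theta`.
#' @param include_noise Predict y* instead of f*.
#' @return A `gp_surface`: tibble with `dose1`, `dose2`, `mean`, `var`,
#'   `lower`, `upper`, carrying the grid, `theta` and training data as
#'   attributes.
#' @export
gp_posterior <- function(data, theta, grid = NULL, include_noise = FALSE,
                         jitter = 1e-8) {
  if (is.null(grid)) {
    grid <- dose_grid(data, lengthscales = c(theta$l1, theta$l2))
  }
  y <- data$response
  n <- length(y)
  A <- gram_matrix(data, theta, jitter = jitter) + diag(theta$sigma2, n)
  ch <- tryCatch(chol(A), error = function(e) {
    abort("covariance matrix not positive definite after jitter")
  })
  nodes <- grid_points(grid)
  Ks <- cross_matrix(data, nodes, theta) # n x m
  alpha <- backsolve(ch, forwardsolve(t(ch), y))
  mu <- drop(crossprod(Ks, alpha))
  V <- forwardsolve(t(ch), Ks) # n x m
  v <- pmax(theta$sigma_f2 - colSums(V^2), 0)
  if (include_noise) v <- v + theta$sigma2
  s <- sqrt(v)
  out <- tibble(
    dose1 = nodes$dose1, dose2 = nodes$dose2,
    mean = mu, var = v, lower = mu - 1.96 * s, upper = mu + 1.96 * s
  )
  structure(out, class = c("gp_surface", class(out)),
            grid = grid, theta = theta, data = data)
}

#' @export
print.gp_surface <- function(x, ...) {
  g <- attr(x, "grid")
  cat(sprintf("<gp_surface> %d x %d grid (%s spacing)\n",
              length(g$axis1), length(g$axis2), g$spacing))
  NextMethod()
}

surface_matrix <- function(surface, value = "mean") {
  g <- attr(surface, "grid")
  matrix(surface[[value]], nrow = length(g$axis1), ncol = length(g$axis2))
}

#' Extract a 1-D slice from a fitted surface
#'
#' @param surface A `gp_surface` (from [gp_posterior]) or any grid tibble
#'   with `mean`/`lower`/`upper` columns and a `grid` attribute.
#' @param which `"drug1"` / `"drug2"`: monotherapy slices (other dose fixed
#'   at 0); `"diagonal"`: pairs the i-th grid dose of each axis (the equal
#'   design-ratio diagonal of the checkerboard); `"ray"`: the line
#'   dose2 = `ratio` * dose1, bilinearly interpolated on the grid.
#' @param ratio Dose ratio for `which = "ray"`.
#' @return Tibble with `dose1`, `dose2`, `position` (dose along the slice's
#'   own axis), `mean`, `lower`, `upper`.
#' @export
surface_slice <- function(surface, which = c("drug1", "drug2", "diagonal", "ray"),
                          ratio = 1) {
  which <- match.arg(which)
  g <- attr(surface, "grid")
  if (is.null(g)) abort("surface has no grid attribute")
  cols <- intersect(c("mean", "var", "lower", "upper"), names(surface))
  if (which == "drug1") {
    out <- surface[surface$dose2 == 0, c("dose1", "dose2", cols)]
    out$position <- out$dose1
  } else if (which == "drug2") {
    out <- surface[surface$dose1 == 0, c("dose1", "dose2", cols)]
    out$position <- out$dose2
  } else if (which == "diagonal") {
    i <- seq_along(g$axis1)
    idx <- (i - 1) * length(g$axis1) + i # node (axis1[i], axis2[i])
    out <- surface[idx, c("dose1", "dose2", cols)]
    out$position <- sqrt(out$dose1^2 + out$dose2^2)
  } else {
    d1 <- g$axis1
    d2 <- pmin(ratio * d1, max(g$axis2))
    out <- tibble(dose1 = d1, dose2 = d2)
    for (col in cols) {
      out[[col]] <- bilinear(g, surface_matrix(surface, col), d1, d2)
    }
    out$position <- sqrt(d1^2 + d2^2)
  }
  as_tibble(out)
}

# bilinear interpolation of a grid-valued matrix at arbitrary points
bilinear <- function(grid, M, x1, x2) {
  i <- findInterval(x1, grid$axis1, all.inside = TRUE)
  j <- findInterval(x2, grid$axis2, all.inside = TRUE)
  x1a <- grid$axis1[i]; x1b <- grid$axis1[i + 1]
  x2a <- grid$axis2[j]; x2b <- grid$axis2[j + 1]
  tx <- ifelse(x1b > x1a, (x1 - x1a) / (x1b - x1a), 0)
  ty <- ifelse(x2b > x2a, (x2 - x2a) / (x2b - x2a), 0)
  f11 <- M[cbind(i, j)]; f21 <- M[cbind(i + 1, j)]
  f12 <- M[cbind(i, j + 1)]; f22 <- M[cbind(i + 1, j + 1)]
  (1 - tx) * (1 - ty) * f11 + tx * (1 - ty) * f21 +
    (1 - tx) * ty * f12 + tx * ty * f22
}

#' Mean squared error between observations and a fitted surface
#'
#' Design doses are always grid nodes (see [dose_grid] snapping), so every
#' observation has an exact prediction.
#'
#' @param data A [dose_response] data set.
#' @param surface A `gp_surface` or any tibble with `dose1`, `dose2`, `mean`.
#' @param which `"all"` for the whole surface; `"drug1"` / `"drug2"` restrict
#'   to that drug's monotherapy points (other dose 0, dose 0 included).
#' @return Mean of squared residuals over the selected points.
#' @export
surface_mse <- function(data, surface, which = c("all", "drug1", "drug2")) {
  which <- match.arg(which)
  obs <- as_tibble(data)[c("dose1", "dose2", "response")]
  if (which == "drug1") obs <- obs[obs$dose2 == 0, ]
  if (which == "drug2") obs <- obs[obs$dose1 == 0, ]
  if (nrow(obs) == 0) abort("no observations selected")
  pred <- dplyr::left_join(obs, as_tibble(surface)[c("dose1", "dose2", "mean")],
                           by = c("dose1", "dose2"))
  if (anyNA(pred$mean)) abort("some observations have no matching grid node")
  mean((pred$response - pred$mean)^2)
}
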