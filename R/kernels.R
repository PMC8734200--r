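#' GP hyperparameters for the two-drug surface model
#'
#' The bivariate GP has four hyperparameters: the signal variance
#' `sigma_f2`, one length scale per dose axis (`l1`, `l2`, in dose units;
#' their ratio l1/l2 is the potency ratio of the two drugs) and the
#' observation-noise variance `sigma2`.
#'
#' @param sigma_f2 Signal variance, > 0.
#' @param l1,l2 Length scales, > 0.
#' @param sigma2 Noise variance, >= 0.
#' @return A named list of class `gp_hyperparameters`.
#' @export
gp_hyperparameters <- function(sigma_f2, l1, l2, sigma2 = 0) {
  if (!is.finite(sigma_f2) || sigma_f2 <= 0) abort("sigma_f2 must be > 0")
  if (!is.finite(l1) || l1 <= 0 || !is.finite(l2) || l2 <= 0) {
    abort("length scales must be > 0")
  }
  if (!is.finite(sigma2) || sigma2 < 0) abort("sigma2 must be >= 0")
  structure(list(sigma_f2 = sigma_f2, l1 = l1, l2 = l2, sigma2 = sigma2),
            class = "gp_hyperparameters")
}

#' @export
print.gp_hyperparameters <- function(x, ...) {
  cat(sprintf("<gp_hyperparameters> sigma_f2 = %.4g, l1 = %.4g, l2 = %.4g, sigma2 = %.4g\n",
              x$sigma_f2, x$l1, x$l2, x$sigma2))
  invisible(x)
}

#' Squared-exponential kernel
#'
#' `k(x, x') = sigma_f2 * exp(-(x - x')^2 / (2 l^2))`. Vectorised over
#' `x`/`x2`.
#'
#' @param x,x2 Numeric inputs.
#' @param sigma_f2 Signal variance.
#' @param l Length scale, > 0.
#' @return Covariance values.
#' @export
k_se <- function(x, x2, sigma_f2 = 1, l) {
  if (any(l <= 0)) abort("length scale must be > 0")
  sigma_f2 * exp(-(x - x2)^2 / (2 * l^2))
}

#' Logarithmic squared-exponential kernel
#'
#' The squared-exponential kernel composed with the warp
#' u = log(1 + x / l): `k(x, x') = sigma_f2 * exp(-(u - u')^2 / 2)`.
#' It captures the log-dose dependence of cellular responses while remaining
#' defined at dose 0 (where a plain log transform fails). For doses much
#' smaller than `l` it coincides with [k_se] since log(1 + x/l) ~ x/l.
#'
#' @param x,x2 Non-negative doses.
#' @inheritParams k_se
#' @return Covariance values.
#' @export
k_log <- function(x, x2, sigma_f2 = 1, l) {
  if (any(l <= 0)) abort("length scale must be > 0")
  if (any(x < 0) || any(x2 < 0)) abort("doses must be non-negative")
  du <- log1p(x / l) - log1p(x2 / l)
  sigma_f2 * exp(-du^2 / 2)
}

#' Two-dimensional logarithmic kernel
#'
#' Product of one logarithmic kernel per dose axis with a single shared
#' amplitude:
#' `k(p, q) = sigma_f2 * exp(-1/2 * sum_i (log(1 + x_i/l_i) - log(1 + x_i'/l_i))^2)`.
#'
#' @param x1,x2 Dose coordinates of the first point (vectorised).
#' @param y1,y2 Dose coordinates of the second point.
#' @param theta A [gp_hyperparameters] object.
#' @return Covariance values.
#' @export
k_log2d <- function(x1, x2, y1, y2, theta) {
  if (any(c(x1, x2, y1, y2) < 0)) abort("doses must be non-negative")
  du1 <- log1p(x1 / theta$l1) - log1p(y1 / theta$l1)
  du2 <- log1p(x2 / theta$l2) - log1p(y2 / theta$l2)
  theta$sigma_f2 * exp(-(du1^2 + du2^2) / 2)
}

#' Gram matrix of the 2-D logarithmic kernel
#'
#' @param points Data frame or matrix with dose columns (first two columns
#'   are used: dose1, dose2).
#' @param theta A [gp_hyperparameters] object.
#' @param jitter Relative diagonal jitter; `jitter * sigma_f2` is added to the
#'   diagonal so that duplicated dose pairs (replicates) keep the matrix
#'   factorisable.
#' @return An n x n symmetric positive semi-definite matrix.
#' @export
gram_matrix <- function(points, theta, jitter = 1e-8) {
  pts <- as.matrix(as.data.frame(points)[, 1:2])
  if (any(!is.finite(pts))) abort("non-finite dose coordinates")
  u1 <- log1p(pts[, 1] / theta$l1)
  u2 <- log1p(pts[, 2] / theta$l2)
  d2 <- outer(u1, u1, "-")^2 + outer(u2, u2, "-")^2
  K <- theta$sigma_f2 * exp(-d2 / 2)
  if (any(!is.finite(K))) abort("non-finite kernel entries")
  dimnames(K) <- NULL
  K + diag(jitter * theta$sigma_f2, nrow(K))
}

# cross-covariance between two point sets (no jitter)
cross_matrix <- function(points, points2, theta) {
  a <- as.matrix(as.data.frame(points)[, 1:2])
  b <- as.matrix(as.data.frame(points2)[, 1:2])
  du1 <- outer(log1p(a[, 1] / theta$l1), log1p(b[, 1] / theta$l1), "-")
  du2 <- outer(log1p(a[, 2] / theta$l2), log1p(b[, 2] / theta$l2), "-")
  K <- theta$sigma_f2 * exp(-(du1^2 + du2^2) / 2)
  dimnames(K) <- NULL
  K
}
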