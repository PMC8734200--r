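#' Synergy effect surface: null reference minus fitted response
#'
#' For inhibitory data the effect is `null - fitted`: a positive value means
#' the observed (fitted) response is lower than the non-interactive
#' prediction, i.e. more inhibition than expected -- synergy. For stimulatory
#' data the sign is flipped. The 95% band uses the fitted surface's
#' predictive variance, treating the null (built from the same posterior's
#' monotherapy slices) as fixed.
#'
#' @param fitted A `gp_surface` from [gp_posterior].
#' @param null A `hand_null` from [hand_null_surface] on the same grid.
#' @param direction `"inhibitory"` or `"stimulatory"`.
#' @return An `effect_surface` tibble: `dose1`, `dose2`, `effect`, `lower`,
#'   `upper`, `call` (`"synergy"` / `"antagonism"` / `"additive"`; additive
#'   iff 0 is inside the 95% band).
#' @export
effect_surface <- function(fitted, null,
                           direction = c("inhibitory", "stimulatory")) {
  direction <- match.arg(direction)
  if (nrow(fitted) != nrow(null) ||
      !isTRUE(all.equal(fitted$dose1, null$dose1)) ||
      !isTRUE(all.equal(fitted$dose2, null$dose2))) {
    abort("fitted and null surfaces are on different grids")
  }
  eff <- if (direction == "inhibitory") null$null - fitted$mean else fitted$mean - null$null
  half <- 1.96 * sqrt(fitted$var)
  out <- tibble(
    dose1 = fitted$dose1, dose2 = fitted$dose2,
    effect = eff, lower = eff - half, upper = eff + half,
    call = dplyr::case_when(
      eff - half > 0 ~ "synergy",
      eff + half < 0 ~ "antagonism",
      TRUE ~ "additive"
    )
  )
  structure(out, class = c("effect_surface", class(out)),
            grid = attr(fitted, "grid"), direction = direction)
}

#' Volume under a gridded surface by Delaunay triangulation
#'
#' Triangulates the rectangular grid (each cell split along a diagonal -- a
#' Delaunay triangulation of the node set) and sums, over triangles, the
#' triangle area times the mean of its three vertex values; exact for
#' piecewise-planar surfaces.
#'
#' Integration coordinates follow the grid's spacing. Linear grids integrate
#' in linear dose units. log1p grids integrate over their warped dose
#' coordinates u = log(1 + x / l), rescaled to \[0, 100\] per axis: the
#' measure is then dimensionless and independent of dose units, comparable
#' across drug pairs (a volume of V corresponds to a mean effect of
#' V / 10^4 response units), and it weights the pharmacologically active
#' log-dose range evenly instead of letting the highest decade of doses
#' dominate the integral.
#'
#' @param grid A [dose_grid], or a list with numeric `axis1`, `axis2`.
#' @param values Surface values, ordered as [grid_points] (dose1 fastest), or
#'   a matrix `length(axis1) x length(axis2)`.
#' @param diagonal Which cell diagonal to use; the two choices agree exactly
#'   for planar surfaces and to discretisation error for smooth ones.
#' @return The volume (scalar).
#' @export
volume_under_surface <- function(grid, values, diagonal = c("sw-ne", "nw-se")) {
  diagonal <- match.arg(diagonal)
  ax <- volume_axes(grid)
  a1 <- ax$axis1
  a2 <- ax$axis2
  if (length(a1) < 2 || length(a2) < 2) abort("degenerate grid: need at least 2 x 2 nodes")
  M <- if (is.matrix(values)) values else matrix(values, length(a1), length(a2))
  if (any(!is.finite(M))) abort("non-finite surface values")
  w <- diff(a1) # cell widths
  h <- diff(a2) # cell heights
  area2 <- outer(w, h) / 2 # each cell splits into two triangles of equal area
  f11 <- M[-nrow(M), -ncol(M)]
  f21 <- M[-1, -ncol(M)]
  f12 <- M[-nrow(M), -1]
  f22 <- M[-1, -1]
  if (diagonal == "sw-ne") {
    # triangles (11,21,22) and (11,12,22)
    s <- (f11 + f21 + f22) / 3 + (f11 + f12 + f22) / 3
  } else {
    # triangles (11,21,12) and (21,12,22)
    s <- (f11 + f21 + f12) / 3 + (f21 + f12 + f22) / 3
  }
  sum(area2 * s)
}

# integration axes for a grid: warped coordinates scaled to [0, 100] for
# log1p grids, raw dose axes otherwise
volume_axes <- function(grid) {
  spacing <- grid$spacing %||% "linear"
  if (spacing == "log1p" && !is.null(grid$lengthscales)) {
    u1 <- log1p(grid$axis1 / grid$lengthscales[1])
    u2 <- log1p(grid$axis2 / grid$lengthscales[2])
    list(axis1 = 100 * u1 / max(u1), axis2 = 100 * u2 / max(u2))
  } else {
    list(axis1 = grid$axis1, axis2 = grid$axis2)
  }
}

#' Volume-difference synergy score
#'
#' Signed difference of the volumes under the null reference and the fitted
#' surface, oriented so that positive means synergy: for inhibitory data
#' `V(null) - V(fitted)` (a fitted surface lying below the null means more
#' inhibition than expected), for stimulatory data the opposite sign.
#'
#' @inheritParams effect_surface
#' @return A one-row tibble: `volume_fitted`, `volume_null`,
#'   `volume_difference`.
#' @export
volume_difference <- function(fitted, null,
                              direction = c("inhibitory", "stimulatory")) {
  direction <- match.arg(direction)
  g <- attr(fitted, "grid") %||% attr(null, "grid")
  vf <- volume_under_surface(g, fitted$mean)
  vn <- volume_under_surface(g, null$null)
  vd <- if (direction == "inhibitory") vn - vf else vf - vn
  tibble(volume_fitted = vf, volume_null = vn, volume_difference = vd)
}

#' Fractional-effect view of the diagonal synergy profile
#'
#' Re-expresses the effect difference along the equal-dose diagonal as a
#' function of fractional effect (0 = no effect, 1 = maximal effect), the
#' x-axis used in classical combination-index plots. Percent-scale responses
#' are converted to fractions of the starting (zero-dose) response.
#'
#' @param null_diag,fitted_diag Diagonal slices (tibbles with `position` and
#'   `mean` or `null` columns), e.g. from [surface_slice].
#' @param from Take the fractional-effect axis from the fitted curve
#'   (default, as in combination-index plots) or from the null curve.
#' @param e0 Zero-dose response level; defaults to the first value of the
#'   null diagonal.
#' @return Tibble with `fractional_effect`, `difference` (null - fitted) and
#'   `position`, restricted to the monotone part of the chosen curve.
#' @export
fractional_effect_curve <- function(null_diag, fitted_diag,
                                    from = c("fitted", "null"), e0 = NULL) {
  from <- match.arg(from)
  nv <- null_diag[[if ("null" %in% names(null_diag)) "null" else "mean"]]
  fv <- fitted_diag$mean
  if (length(nv) != length(fv)) abort("diagonal slices have different lengths")
  if (is.null(e0)) e0 <- nv[1]
  if (e0 == 0) abort("zero starting response; cannot form fractional effects")
  fe_src <- if (from == "fitted") fv else nv
  fe <- 1 - fe_src / e0 # fraction of the achievable inhibition
  keep <- seq_len(longest_monotone(fe))
  if (length(keep) < length(fe)) {
    warn("non-monotone fractional-effect axis; restricted to its monotone start")
  }
  tibble(
    fractional_effect = pmin(pmax(fe[keep], 0), 1),
    difference = (nv - fv)[keep],
    position = null_diag$position[keep]
  )
}

longest_monotone <- function(x) {
  d <- diff(x)
  if (length(d) == 0 || d[1] == 0) return(1L)
  dir <- sign(d[1])
  k <- 1L
  while (k <= length(d) && sign(d[k]) == dir) k <- k + 1L
  k
}
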