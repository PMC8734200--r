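#' Monotherapy curve for Hand inversion
#'
#' Wraps a densely evaluated single-drug dose-effect curve (typically a GP
#' posterior-mean slice) and locates the longest strictly monotone segment
#' starting at dose 0, which is the part the Hand construction can invert.
#' Effects requested outside the segment's range are clamped (and flagged)
#' rather than failing the whole surface.
#'
#' @param dose Increasing non-negative doses (dense grid).
#' @param effect Effect values at `dose`.
#' @return A `mono_curve` tibble with columns `dose`, `effect` and attributes
#'   `seg_end` (last index of the monotone segment) and `decreasing`.
#' @export
monotherapy_curve <- function(dose, effect) {
  if (is.unsorted(dose, strictly = TRUE)) abort("doses must be strictly increasing")
  if (any(dose < 0) || any(!is.finite(effect))) abort("invalid curve values")
  n <- length(dose)
  if (n < 2) abort("non-invertible monotherapy: need at least 2 points")
  d <- diff(effect)
  dir <- sign(d[match(TRUE, d != 0)])
  if (is.na(dir) || d[1] == 0) {
    abort("non-invertible monotherapy: no strictly monotone segment from dose 0")
  }
  seg_end <- 1L
  while (seg_end < n && sign(d[seg_end]) == dir) seg_end <- seg_end + 1L
  structure(
    tibble(dose = dose, effect = effect),
    class = c("mono_curve", class(tibble())),
    seg_end = seg_end, decreasing = dir < 0
  )
}

#' @export
print.mono_curve <- function(x, ...) {
  cat(sprintf("<mono_curve> %d points, %s, monotone segment 1..%d (dose <= %g)\n",
              nrow(x), if (attr(x, "decreasing")) "decreasing" else "increasing",
              attr(x, "seg_end"), x$dose[attr(x, "seg_end")]))
  NextMethod()
}

curve_segment <- function(curve) {
  k <- attr(curve, "seg_end")
  list(dose = curve$dose[seq_len(k)], effect = curve$effect[seq_len(k)],
       decreasing = attr(curve, "decreasing"))
}

# dose producing effect E on the segment (E assumed already clamped);
# approx needs ascending x, so decreasing curves are reversed
inv_interp <- function(seg, E) {
  if (seg$decreasing) {
    approx(rev(seg$effect), rev(seg$dose), xout = E, rule = 2,
           ties = "ordered")$y
  } else {
    approx(seg$effect, seg$dose, xout = E, rule = 2, ties = "ordered")$y
  }
}

#' Numerically invert a monotherapy curve
#'
#' Finds the dose producing a given effect by monotone linear interpolation
#' on the curve's invertible segment. Effects outside the segment's range are
#' clamped to the nearest endpoint dose.
#'
#' @param curve A [monotherapy_curve].
#' @param effect Effect value(s) to invert.
#' @param warn_clamp Emit a warning when clamping occurs.
#' @return Dose(s), with a logical attribute `clamped`.
#' @export
invert_curve <- function(curve, effect, warn_clamp = TRUE) {
  seg <- curve_segment(curve)
  lo <- min(seg$effect); hi <- max(seg$effect)
  clamped <- effect < lo | effect > hi
  dose <- inv_interp(seg, pmin(pmax(effect, lo), hi))
  if (warn_clamp && any(clamped)) {
    warn(sprintf("%d effect value(s) outside the invertible range were clamped",
                 sum(clamped)))
  }
  structure(dose, clamped = clamped)
}

#' Partition counts for the Hand construction
#'
#' The number of partitions for a dose `x` is the number of grid points
#' strictly between dose 0 and the grid point nearest to `x`, inclusive of
#' that point (i.e. the index of the nearest grid point minus one). Ties
#' between two equally near grid points break toward the lower index;
#' `x = 0` gives 0 partitions.
#'
#' @param grid A [dose_grid], or a numeric grid axis.
#' @param x1,x2 Doses on axis 1 and 2 (vectorised).
#' @return A list with integer vectors `N1`, `N2`.
#' @export
choose_partitions <- function(grid, x1, x2) {
  ax1 <- if (inherits(grid, "dose_grid")) grid$axis1 else grid
  ax2 <- if (inherits(grid, "dose_grid")) grid$axis2 else grid
  list(N1 = partitions_axis(ax1, x1), N2 = partitions_axis(ax2, x2))
}

partitions_axis <- function(axis, x) {
  vapply(x, function(xi) {
    if (xi == 0) return(0L)
    max(1L, which.min(abs(axis - xi)) - 1L) # which.min ties -> lower index
  }, integer(1))
}

# Vectorised alternating-step Hand engine. One step maps the running effect
# E to f_i(f_i^{-1}(E) + delta_i); each of the N = max(N1, N2) rounds
# averages the two application orders (drug1-then-drug2 and
# drug2-then-drug1), which makes the round map symmetric in the two drugs --
# drug-swap commutativity then holds to machine precision and the splitting
# error drops to second order in 1/N. Effects deeper than a curve's
# invertible range leave E unchanged (the drug cannot be "un-applied");
# equivalent doses past the curve's segment end are clamped to it. Both
# cases set the clamp flag.
hand_engine <- function(f1, f2, x1, x2, N1, N2, shared_tol = 0.01) {
  seg1 <- curve_segment(f1)
  seg2 <- curve_segment(f2)
  e1_0 <- seg1$effect[1]
  e2_0 <- seg2$effect[1]
  rng <- diff(range(c(seg1$effect, seg2$effect)))
  if (rng <= 0) abort("degenerate curves: zero effect range")
  start <- e1_0
  if (abs(e1_0 - e2_0) > shared_tol * rng) {
    warn(sprintf("monotherapy curves disagree at dose 0 (%.4g vs %.4g); using their average",
                 e1_0, e2_0))
    start <- (e1_0 + e2_0) / 2
  }
  m <- length(x1)
  N <- pmax(N1, N2)
  N[x1 == 0 & x2 == 0] <- 0L
  d1 <- ifelse(x1 > 0 & N > 0, x1 / N, 0)
  d2 <- ifelse(x2 > 0 & N > 0, x2 / N, 0)
  E <- rep(start, m)
  clamped <- rep(FALSE, m)

  # monotherapy shortcut: with one zero dose the construction reduces to the
  # other drug's curve evaluated at its full dose
  only1 <- x2 == 0 & x1 > 0
  only2 <- x1 == 0 & x2 > 0
  if (any(only1)) {
    E[only1] <- approx(f1$dose, f1$effect, xout = pmin(x1[only1], max(f1$dose)),
                       rule = 2, ties = "ordered")$y
  }
  if (any(only2)) {
    E[only2] <- approx(f2$dose, f2$effect, xout = pmin(x2[only2], max(f2$dose)),
                       rule = 2, ties = "ordered")$y
  }
  todo <- which(!only1 & !only2 & N > 0)
  if (length(todo) > 0) {
    for (r in seq_len(max(N[todo]))) {
      act <- todo[N[todo] >= r]
      if (length(act) == 0) break
      a1 <- hand_step(E[act], seg1, d1[act])
      a2 <- hand_step(a1$E, seg2, d2[act])
      b2 <- hand_step(E[act], seg2, d2[act])
      b1 <- hand_step(b2$E, seg1, d1[act])
      E[act] <- (a2$E + b1$E) / 2
      clamped[act] <- clamped[act] | a1$clamped | a2$clamped |
        b1$clamped | b2$clamped
    }
  }
  list(effect = E, clamped = clamped, start = start)
}

hand_step <- function(E, seg, delta) {
  if (all(delta == 0)) return(list(E = E, clamped = rep(FALSE, length(E))))
  e_end <- seg$effect[length(seg$effect)]
  d_max <- seg$dose[length(seg$dose)]
  deeper <- if (seg$decreasing) E < e_end else E > e_end
  lo <- min(seg$effect); hi <- max(seg$effect)
  d_eq <- inv_interp(seg, pmin(pmax(E, lo), hi))
  d_new <- pmin(d_eq + delta, d_max)
  over <- (d_eq + delta) > d_max
  E_new <- approx(seg$dose, seg$effect, xout = d_new, rule = 2, ties = "ordered")$y
  E_new[deeper] <- E[deeper] # already past this curve's reachable range
  E_new[delta == 0] <- E[delta == 0]
  list(E = E_new, clamped = (deeper | over) & delta > 0)
}

#' Hand-model combination effect for one dose pair
#'
#' Splits the doses `x1`, `x2` into small partitions and applies them
#' alternately along the two monotherapy curves: each step converts the
#' running effect to an equivalent dose of the acting drug, advances that
#' dose by the partition size, and reads the new effect off the curve. With
#' `N = max(N1, N2)` alternating rounds of per-drug step sizes `x_i / N`,
#' the construction converges (as N grows) to the Hand null model, the
#' infinitesimal form of Loewe additivity. Each round averages the two
#' application orders, so the result is invariant under swapping the drugs
#' (a defining property of the Hand model) up to machine precision.
#'
#' @param f1,f2 [monotherapy_curve] objects sharing the starting effect at
#'   dose 0 (within 1% of the effect range; otherwise the average is used,
#'   with a warning).
#' @param x1,x2 Doses to combine (scalars).
#' @param N1,N2 Partition counts (see [choose_partitions]).
#' @return The null-model effect at `(x1, x2)` (scalar, with attribute
#'   `clamped`).
#' @export
hand_construct <- function(f1, f2, x1, x2, N1, N2) {
  res <- hand_engine(f1, f2, x1, x2, as.integer(N1), as.integer(N2))
  structure(res$effect, clamped = res$clamped)
}

#' Hand null reference surface on a prediction grid
#'
#' Evaluates [hand_construct] at every grid node, with per-node partition
#' counts from [choose_partitions]. The monotherapy edges of the result equal
#' the input curves, and the construction is commutative in the two drugs up
#' to discretisation error.
#'
#' The curves should extend somewhat beyond the grid span when possible
#' (e.g. GP slices predicted out to the combined dose range): during the
#' construction the equivalent single-drug dose at high combination doses
#' exceeds the design's maximal dose, and curves that stop there are clamped
#' (flagged per node in `clamped`).
#'
#' @inheritParams hand_construct
#' @param grid A [dose_grid].
#' @return A `hand_null` tibble: `dose1`, `dose2`, `null`, `N1`, `N2`,
#'   `clamped`, with the grid as attribute.
#' @export
hand_null_surface <- function(f1, f2, grid) {
  nodes <- grid_points(grid)
  parts <- choose_partitions(grid, nodes$dose1, nodes$dose2)
  res <- hand_engine(f1, f2, nodes$dose1, nodes$dose2, parts$N1, parts$N2)
  out <- tibble(
    dose1 = nodes$dose1, dose2 = nodes$dose2, null = res$effect,
    N1 = parts$N1, N2 = parts$N2, clamped = res$clamped
  )
  structure(out, class = c("hand_null", class(out)), grid = grid,
            start_effect = res$start)
}

#' @export
print.hand_null <- function(x, ...) {
  cat(sprintf("<hand_null> %d nodes, start effect %.4g, %d clamped\n",
              nrow(x), attr(x, "start_effect"), sum(x$clamped)))
  NextMethod()
}
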