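#' MuSyC parameter set
#'
#' The MuSyC response surface is the steady state of a four-state
#' mass-action system (drug-free, drug-1 bound, drug-2 bound, both bound)
#' whose occupancies weight the state effects `E0`, `E1`, `E2`, `E3`. The
#' monotherapy edges are Hill curves `(E0, E1, h1, C1)` and
#' `(E0, E2, h2, C2)`. Synergy is carried by five parameters: `alpha12`,
#' `alpha21` (potency: drug i multiplies the other drug's effective dose),
#' `gamma12`, `gamma21` (cooperativity: change of the other drug's Hill
#' slope) and the derived efficacy gain
#' `beta = (min(E1, E2) - E3) / (E0 - min(E1, E2))`. The additive
#' (non-interactive) reference has `alpha12 = alpha21 = gamma12 =
#' gamma21 = 1` and `beta = 0`.
#'
#' @param E0,E1,E2,E3 State effects.
#' @param h1,h2 Hill slopes (> 0).
#' @param C1,C2 Half-maximal doses (> 0).
#' @param alpha12,alpha21 Potency synergy factors (>= 0).
#' @param gamma12,gamma21 Cooperativity synergy factors (> 0).
#' @return A `musyc_params` named list (with derived `beta`).
#' @export
musyc_params <- function(E0, E1, E2, E3, h1, h2, C1, C2,
                         alpha12 = 1, alpha21 = 1, gamma12 = 1, gamma21 = 1) {
  if (h1 <= 0 || h2 <= 0 || C1 <= 0 || C2 <= 0) abort("h and C must be > 0")
  if (alpha12 < 0 || alpha21 < 0) abort("alpha must be >= 0")
  if (gamma12 <= 0 || gamma21 <= 0) abort("gamma must be > 0")
  p <- list(E0 = E0, E1 = E1, E2 = E2, E3 = E3, h1 = h1, h2 = h2,
            C1 = C1, C2 = C2, alpha12 = alpha12, alpha21 = alpha21,
            gamma12 = gamma12, gamma21 = gamma21)
  p$beta <- (min(E1, E2) - E3) / (E0 - min(E1, E2))
  structure(p, class = "musyc_params")
}

#' @export
print.musyc_params <- function(x, ...) {
  cat(sprintf(
    "<musyc_params> E0..E3 = %.4g/%.4g/%.4g/%.4g, h = %.3g/%.3g, C = %.4g/%.4g\n  alpha = %.3g/%.3g, gamma = %.3g/%.3g, beta = %.3g\n",
    x$E0, x$E1, x$E2, x$E3, x$h1, x$h2, x$C1, x$C2,
    x$alpha12, x$alpha21, x$gamma12, x$gamma21, x$beta
  ))
  invisible(x)
}

musyc_par_vec <- function(p) {
  c(p$E0, p$E1, p$E2, p$E3, p$h1, p$h2, p$C1, p$C2,
    p$alpha12, p$alpha21, p$gamma12, p$gamma21)
}

#' MuSyC response surface
#'
#' @param params A [musyc_params] object.
#' @param d1,d2 Doses (vectorised, recycled to a common length).
#' @return Response value(s).
#' @export
musyc_response <- function(params, d1, d2) {
  if (!inherits(params, "musyc_params")) abort("params must be musyc_params")
  if (any(d1 < 0) || any(d2 < 0)) abort("doses must be non-negative")
  n <- max(length(d1), length(d2))
  out <- drop(musyc_response_cpp(rep_len(as.numeric(d1), n),
                                 rep_len(as.numeric(d2), n),
                                 musyc_par_vec(params)))
  if (any(!is.finite(out))) abort("MuSyC steady state failed for some doses")
  out
}

default_musyc_bounds <- function(data) {
  at <- dr_attrs(data)
  scale_max <- if (at$response_scale == "percent") 100 else 1
  rmax <- max(data$response)
  dpos1 <- data$dose1[data$dose1 > 0]
  dpos2 <- data$dose2[data$dose2 > 0]
  list(
    E0 = c(0, 1.1 * rmax), E = c(0, scale_max),
    h = c(0.1, 10),
    C1 = c(min(dpos1) / 10, 10 * max(data$dose1)),
    C2 = c(min(dpos2) / 10, 10 * max(data$dose2)),
    alpha = c(1e-6, 100), gamma = c(0.1, 10)
  )
}

#' Fit the MuSyC surface to a checkerboard data set
#'
#' Bounded least squares over the 12 MuSyC parameters (or 7 when
#' `constrained = TRUE`: the additive null with
#' `alpha12 = alpha21 = gamma12 = gamma21 = 1`, `beta = 0`, i.e.
#' `E3 = min(E1, E2)`). Multi-starts are derived from Hill fits of the two
#' monotherapy edges; the fit is deterministic.
#'
#' @param data A [dose_response] data set covering a full dose matrix.
#' @param constrained Fit the additive null instead of the full model.
#' @param bounds Optional bounds list (see `default_musyc_bounds`); `E1`,
#'   `E2`, `E3` are bounded by the response scale (\[0, 100\] or \[0, 1\]).
#' @return A `musyc_fit`: list with `params` ([musyc_params]),
#'   `residual_sd`, `sse`, `constrained`, and the data.
#' @export
fit_musyc <- function(data, constrained = FALSE, bounds = NULL) {
  bounds <- bounds %||% default_musyc_bounds(data)
  y <- data$response
  h1f <- fit_hill(monotherapy(data, "drug1"))
  h2f <- fit_hill(monotherapy(data, "drug2"))

  # free-parameter layout: E0, E1, E2 [, E3], log h1, log h2, log C1, log C2
  # [, log alpha12, log alpha21, log gamma12, log gamma21]
  build <- function(q) {
    if (constrained) {
      musyc_params(E0 = q[1], E1 = q[2], E2 = q[3], E3 = min(q[2], q[3]),
                   h1 = exp(q[4]), h2 = exp(q[5]), C1 = exp(q[6]), C2 = exp(q[7]))
    } else {
      musyc_params(E0 = q[1], E1 = q[2], E2 = q[3], E3 = q[4],
                   h1 = exp(q[5]), h2 = exp(q[6]), C1 = exp(q[7]), C2 = exp(q[8]),
                   alpha12 = exp(q[9]), alpha21 = exp(q[10]),
                   gamma12 = exp(q[11]), gamma21 = exp(q[12]))
    }
  }
  obj <- function(q) {
    r <- y - drop(musyc_response_cpp(data$dose1, data$dose2,
                                     musyc_par_vec(build(q))))
    if (any(!is.finite(r))) return(1e12)
    sum(r^2)
  }
  lower <- c(bounds$E0[1], bounds$E[1], bounds$E[1],
             if (!constrained) bounds$E[1],
             log(bounds$h[1]), log(bounds$h[1]), log(bounds$C1[1]), log(bounds$C2[1]),
             if (!constrained) rep(c(log(bounds$alpha[1]), log(bounds$gamma[1])), each = 2))
  upper <- c(bounds$E0[2], bounds$E[2], bounds$E[2],
             if (!constrained) bounds$E[2],
             log(bounds$h[2]), log(bounds$h[2]), log(bounds$C1[2]), log(bounds$C2[2]),
             if (!constrained) rep(c(log(bounds$alpha[2]), log(bounds$gamma[2])), each = 2))
  e0 <- unname((h1f$params["E0"] + h2f$params["E0"]) / 2)
  e1 <- unname(h1f$params["Emax"]); e2 <- unname(h2f$params["Emax"])
  base <- c(e0, e1, e2, if (!constrained) min(e1, e2),
            log(unname(h1f$params["h"])), log(unname(h2f$params["h"])),
            log(unname(h1f$params["C"])), log(unname(h2f$params["C"])),
            if (!constrained) rep(0, 4))
  starts <- list(base)
  if (!constrained) {
    for (a in c(log(0.2), log(5))) {
      s <- base; s[9:10] <- a; starts <- c(starts, list(s))
    }
  } else {
    starts <- c(starts, list(base * 0 + (lower + upper) / 2))
  }
  clamp <- function(q) pmin(pmax(q, lower), upper)
  runs <- purrr::map(starts, function(s) {
    tryCatch(
      optim(clamp(s), obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 1000)),
      error = function(e) NULL
    )
  })
  runs <- purrr::compact(runs)
  if (length(runs) == 0) abort("all MuSyC fit starts failed")
  best <- runs[[which.min(purrr::map_dbl(runs, "value"))]]
  params <- build(best$par)
  res <- y - musyc_response(params, data$dose1, data$dose2)
  n_par <- if (constrained) 7 else 12
  structure(
    list(params = params, sse = best$value,
         residual_sd = sqrt(sum(res^2) / max(1, length(res) - n_par)),
         df = max(1L, length(res) - n_par),
         constrained = constrained, data = data, bounds = bounds,
         par_free = best$par, lower = lower, upper = upper),
    class = "musyc_fit"
  )
}

#' @export
print.musyc_fit <- function(x, ...) {
  cat(sprintf("<musyc_fit>%s residual sd %.3g\n",
              if (x$constrained) " (constrained null)" else "", x$residual_sd))
  print(x$params)
  invisible(x)
}

#' @export
predict.musyc_fit <- function(object, d1, d2, ...) {
  musyc_response(object$params, d1, d2)
}

#' @describeIn fit_musyc parameter table (with bootstrap intervals when
#'   passed via `ci`).
#' @param x A `musyc_fit`.
#' @param ci Optional interval tibble from [bootstrap_ci].
#' @param ... Unused.
#' @export
tidy.musyc_fit <- function(x, ci = NULL, ...) {
  p <- x$params
  terms <- c("E0", "E1", "E2", "E3", "h1", "h2", "C1", "C2",
             "alpha12", "alpha21", "gamma12", "gamma21", "beta")
  out <- tibble(term = terms,
                estimate = purrr::map_dbl(terms, ~ p[[.x]]))
  if (!is.null(ci)) out <- dplyr::left_join(out, ci, by = "term")
  out
}

#' @describeIn fit_musyc one-row fit summary.
#' @param object A `musyc_fit`.
#' @export
glance.musyc_fit <- function(object, ...) {
  tibble(
    sse = object$sse, residual_sd = object$residual_sd,
    mse = object$sse / nrow(object$data),
    n = nrow(object$data), constrained = object$constrained
  )
}

#' @export
bootstrap_ci.musyc_fit <- function(fit, B = 1000, seed = 0, level = 0.95) {
  mu <- predict(fit, fit$data$dose1, fit$data$dose2)
  terms <- c("E0", "E1", "E2", "E3", "h1", "h2", "C1", "C2",
             "alpha12", "alpha21", "gamma12", "gamma21", "beta")
  build <- function(q) {
    if (fit$constrained) {
      musyc_params(E0 = q[1], E1 = q[2], E2 = q[3], E3 = min(q[2], q[3]),
                   h1 = exp(q[4]), h2 = exp(q[5]), C1 = exp(q[6]), C2 = exp(q[7]))
    } else {
      musyc_params(E0 = q[1], E1 = q[2], E2 = q[3], E3 = q[4],
                   h1 = exp(q[5]), h2 = exp(q[6]), C1 = exp(q[7]), C2 = exp(q[8]),
                   alpha12 = exp(q[9]), alpha21 = exp(q[10]),
                   gamma12 = exp(q[11]), gamma21 = exp(q[12]))
    }
  }
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(B), function(b) {
      sb <- fit$residual_sd * sqrt(fit$df / stats::rchisq(1, fit$df))
      yb <- mu + rnorm(length(mu), sd = sb)
      obj <- function(q) {
        r <- yb - drop(musyc_response_cpp(fit$data$dose1, fit$data$dose2,
                                          musyc_par_vec(build(q))))
        if (any(!is.finite(r))) return(1e12)
        sum(r^2)
      }
      r <- tryCatch(
        optim(fit$par_free, obj, method = "L-BFGS-B",
              lower = fit$lower, upper = fit$upper,
              control = list(maxit = 400)),
        error = function(e) NULL
      )
      if (is.null(r)) return(NULL)
      p <- build(r$par)
      purrr::map_dbl(terms, ~ p[[.x]])
    })
  })
  draws <- do.call(rbind, purrr::compact(draws))
  boot_percentiles(draws, terms, B, level)
}

#' MuSyC effect surface and volume difference
#'
#' Mirrors the Hand-GP effect construction for the MuSyC baseline: the
#' constrained (additive-null) surface minus the full 12-parameter surface
#' for inhibitory data, with the volume difference computed on the same
#' grid. No confidence band is attached to the null-derived summaries.
#'
#' @param full,null `musyc_fit` objects (full and constrained) on the same
#'   data.
#' @param grid A [dose_grid].
#' @param direction `"inhibitory"` or `"stimulatory"`.
#' @return List with `effect` (tibble `dose1`, `dose2`, `effect`) and
#'   `volumes` (one-row tibble as in [volume_difference]).
#' @export
musyc_effect <- function(full, null, grid,
                         direction = c("inhibitory", "stimulatory")) {
  direction <- match.arg(direction)
  if (!null$constrained || full$constrained) {
    abort("expected `full` unconstrained and `null` constrained")
  }
  nodes <- grid_points(grid)
  pf <- musyc_response(full$params, nodes$dose1, nodes$dose2)
  pn <- musyc_response(null$params, nodes$dose1, nodes$dose2)
  eff <- if (direction == "inhibitory") pn - pf else pf - pn
  vf <- volume_under_surface(grid, pf)
  vn <- volume_under_surface(grid, pn)
  vd <- if (direction == "inhibitory") vn - vf else vf - vn
  list(
    effect = tibble(dose1 = nodes$dose1, dose2 = nodes$dose2, effect = eff),
    volumes = tibble(volume_fitted = vf, volume_null = vn, volume_difference = vd)
  )
}

#' Full MuSyC synergy analysis of one data set
#'
#' Convenience wrapper: fits the full and constrained MuSyC models and
#' returns both fits plus the effect surface and volume difference.
#'
#' @inheritParams fit_musyc
#' @param grid A [dose_grid]; defaults to a 101-point log1p grid so that the
#'   volume score is computed in the same warped coordinates as the Hand-GP
#'   score (pass the Hand-GP fit's grid for an exact like-for-like
#'   comparison).
#' @return A `musyc_synergy` list: `full`, `null`, `effect`, `volumes`,
#'   `mse`.
#' @export
musyc_synergy <- function(data, grid = NULL, bounds = NULL) {
  at <- dr_attrs(data)
  if (is.null(grid)) grid <- dose_grid(data, n_per_axis = 101)
  full <- fit_musyc(data, constrained = FALSE, bounds = bounds)
  null <- fit_musyc(data, constrained = TRUE, bounds = bounds)
  me <- musyc_effect(full, null, grid, direction = at$direction)
  structure(
    list(full = full, null = null, effect = me$effect, volumes = me$volumes,
         mse = full$sse / nrow(data), grid = grid),
    class = "musyc_synergy"
  )
}

#' @export
print.musyc_synergy <- function(x, ...) {
  cat(sprintf("<musyc_synergy> volume difference %.4g (surface MSE %.4g)\n",
              x$volumes$volume_difference, x$mse))
  invisible(x)
}
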