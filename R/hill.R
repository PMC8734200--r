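#' Four-parameter Hill dose-response curve
#'
#' `E(d) = Emax + (E0 - Emax) / (1 + (d / C)^h)`: `E0` is the zero-dose
#' response, `Emax` the asymptotic response at infinite dose, `C` the
#' half-maximal dose (EC50) and `h` the Hill slope. For inhibitory data
#' `E0 >= Emax`.
#'
#' @param dose Non-negative dose(s).
#' @param E0,Emax,h,C Hill parameters (`h > 0`, `C > 0`).
#' @return Response value(s).
#' @export
hill_response <- function(dose, E0, Emax, h, C) {
  if (any(dose < 0)) abort("doses must be non-negative")
  if (h <= 0 || C <= 0) abort("h and C must be > 0")
  Emax + (E0 - Emax) / (1 + (dose / C)^h)
}

# inverse Hill: dose producing effect E (inhibitory orientation handled by
# the formula itself); E strictly between Emax and E0
hill_inverse <- function(E, E0, Emax, h, C) {
  C * ((E0 - Emax) / (E - Emax) - 1)^(1 / h)
}

#' Extract one drug's monotherapy points
#'
#' @param data A [dose_response] data set.
#' @param which `"drug1"` or `"drug2"`.
#' @return Tibble with `dose`, `response` (the zero-dose rows included).
#' @export
monotherapy <- function(data, which = c("drug1", "drug2")) {
  which <- match.arg(which)
  if (which == "drug1") {
    rows <- data$dose2 == 0
    tibble(dose = data$dose1[rows], response = data$response[rows])
  } else {
    rows <- data$dose1 == 0
    tibble(dose = data$dose2[rows], response = data$response[rows])
  }
}

default_hill_bounds <- function(mono) {
  rmax <- max(mono$response)
  dpos <- mono$dose[mono$dose > 0]
  list(
    E0 = c(0, 1.1 * rmax), Emax = c(0, 1.1 * rmax),
    h = c(0.1, 10), C = c(min(dpos) / 10, 10 * max(mono$dose))
  )
}

#' Fit a Hill curve to monotherapy data
#'
#' Bounded least squares with a deterministic multi-start grid (EC50 starts
#' at the dose quartiles, slope starts at 0.5 / 1 / 2). Default bounds keep
#' `E0` and `Emax` within \[0, 1.1 x max response\], `h` in \[0.1, 10\] and
#' `C` within a decade of the design's dose range.
#'
#' @param mono Tibble with `dose`, `response` columns (see [monotherapy]),
#'   containing dose 0 and at least 4 distinct doses.
#' @param bounds Optional list with elements `E0`, `Emax`, `h`, `C`, each
#'   `c(lower, upper)`.
#' @return A `hill_fit`: list with `params` (named vector), `residual_sd`,
#'   `sse`, plus the data and bounds.
#' @export
fit_hill <- function(mono, bounds = NULL) {
  mono <- as_tibble(mono)[c("dose", "response")]
  if (length(unique(mono$dose)) < 4 || !any(mono$dose == 0)) {
    abort("need monotherapy data at >= 4 distinct doses including 0")
  }
  bounds <- bounds %||% default_hill_bounds(mono)
  lower <- c(bounds$E0[1], bounds$Emax[1], log(bounds$h[1]), log(bounds$C[1]))
  upper <- c(bounds$E0[2], bounds$Emax[2], log(bounds$h[2]), log(bounds$C[2]))
  clamp <- function(p) pmin(pmax(p, lower), upper)
  obj <- function(p) {
    r <- mono$response - hill_response(mono$dose, p[1], p[2], exp(p[3]), exp(p[4]))
    sum(r^2)
  }
  e0_start <- mean(mono$response[mono$dose == 0])
  emax_start <- min(mono$response)
  dpos <- sort(unique(mono$dose[mono$dose > 0]))
  c_starts <- unique(quantile(dpos, c(0.25, 0.5, 0.75), names = FALSE))
  starts <- expand.grid(C = c_starts, h = c(0.5, 1, 2))
  runs <- purrr::map(seq_len(nrow(starts)), function(i) {
    p0 <- clamp(c(e0_start, emax_start, log(starts$h[i]), log(starts$C[i])))
    tryCatch(
      optim(p0, obj, method = "L-BFGS-B", lower = lower, upper = upper,
            control = list(maxit = 500)),
      error = function(e) NULL
    )
  })
  runs <- purrr::compact(runs)
  if (length(runs) == 0) abort("all Hill fit starts failed")
  best <- runs[[which.min(purrr::map_dbl(runs, "value"))]]
  p <- best$par
  params <- c(E0 = p[1], Emax = p[2], h = exp(p[3]), C = exp(p[4]))
  res <- mono$response - hill_response(mono$dose, p[1], p[2], exp(p[3]), exp(p[4]))
  # df-corrected residual sd: the parametric bootstrap resamples with this
  # noise level, and n is small relative to the 4 parameters
  structure(
    list(params = params, sse = best$value,
         residual_sd = sqrt(sum(res^2) / max(1, length(res) - 4)),
         df = max(1L, length(res) - 4L),
         data = mono, bounds = bounds),
    class = "hill_fit"
  )
}

#' @export
print.hill_fit <- function(x, ...) {
  cat(sprintf("<hill_fit> E0 = %.4g, Emax = %.4g, h = %.4g, C = %.4g (residual sd %.3g)\n",
              x$params["E0"], x$params["Emax"], x$params["h"], x$params["C"],
              x$residual_sd))
  invisible(x)
}

#' @export
predict.hill_fit <- function(object, dose, ...) {
  p <- object$params
  hill_response(dose, p["E0"], p["Emax"], p["h"], p["C"])
}

#' @describeIn fit_hill parameter table (with bootstrap intervals when
#'   [bootstrap_ci] results are passed via `ci`).
#' @param x A `hill_fit`.
#' @param ci Optional interval tibble from [bootstrap_ci].
#' @param ... Unused.
#' @export
tidy.hill_fit <- function(x, ci = NULL, ...) {
  out <- tibble(term = names(x$params), estimate = unname(x$params))
  if (!is.null(ci)) out <- dplyr::left_join(out, ci, by = "term")
  out
}

#' @describeIn fit_hill one-row fit summary.
#' @param object A `hill_fit`.
#' @export
glance.hill_fit <- function(object, ...) {
  tibble(
    sse = object$sse, residual_sd = object$residual_sd,
    mse = object$sse / nrow(object$data), n = nrow(object$data)
  )
}

#' Parametric-bootstrap confidence intervals
#'
#' Resamples responses as `fitted + N(0, s_b^2)`, refits `B` times (starting
#' each refit from the original estimate) and returns percentile 95%
#' intervals per parameter. Each replicate's noise level `s_b` is drawn from
#' the scaled inverse-chi-square distribution of the residual variance
#' (`s_b = residual_sd * sqrt(df / rchisq(1, df))`): with few residual
#' degrees of freedom the variance estimate itself is uncertain, and
#' ignoring that collapses the intervals whenever the fit happens to be
#' tight -- the bootstrap analogue of a t rather than a normal interval.
#' Seeded and bit-reproducible.
#'
#' @param fit A `hill_fit` or `musyc_fit`.
#' @param B Number of bootstrap replicates.
#' @param seed Integer seed.
#' @param level Interval level (default 0.95).
#' @return Tibble with `term`, `conf.low`, `conf.high` (and attribute
#'   `failures`, the number of failed refits).
#' @export
bootstrap_ci <- function(fit, B = 1000, seed = 0, level = 0.95) {
  UseMethod("bootstrap_ci")
}

boot_percentiles <- function(draws, terms, B, level) {
  failures <- B - nrow(draws)
  if (failures > 0.2 * B) {
    warn(sprintf("%d of %d bootstrap refits failed; intervals use the successes",
                 failures, B))
  }
  probs <- c((1 - level) / 2, 1 - (1 - level) / 2)
  structure(
    tibble(
      term = terms,
      conf.low = apply(draws, 2, quantile, probs[1], names = FALSE),
      conf.high = apply(draws, 2, quantile, probs[2], names = FALSE)
    ),
    failures = failures
  )
}

#' @export
bootstrap_ci.hill_fit <- function(fit, B = 1000, seed = 0, level = 0.95) {
  mu <- predict(fit, fit$data$dose)
  p <- fit$params
  start <- c(p["E0"], p["Emax"], log(p["h"]), log(p["C"]))
  lower <- c(fit$bounds$E0[1], fit$bounds$Emax[1], log(fit$bounds$h[1]), log(fit$bounds$C[1]))
  upper <- c(fit$bounds$E0[2], fit$bounds$Emax[2], log(fit$bounds$h[2]), log(fit$bounds$C[2]))
  draws <- withr::with_seed(seed, {
    purrr::map(seq_len(B), function(b) {
      sb <- fit$residual_sd * sqrt(fit$df / stats::rchisq(1, fit$df))
      yb <- mu + rnorm(length(mu), sd = sb)
      obj <- function(q) sum((yb - hill_response(fit$data$dose, q[1], q[2],
                                                 exp(q[3]), exp(q[4])))^2)
      r <- tryCatch(
        optim(pmin(pmax(start, lower), upper), obj, method = "L-BFGS-B",
              lower = lower, upper = upper, control = list(maxit = 300)),
        error = function(e) NULL
      )
      if (is.null(r)) NULL else c(r$par[1], r$par[2], exp(r$par[3]), exp(r$par[4]))
    })
  })
  draws <- do.call(rbind, purrr::compact(draws))
  boot_percentiles(draws, names(p), B, level)
}
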