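#' Data-driven Gamma priors for the GP hyperparameters
#'
#' Weakly informative Gamma(shape `alpha`, rate `beta`) priors built from the
#' design, by moment matching:
#' \itemize{
#'   \item each length scale `l_i`: prior mean `m = c * Dmax_i` (the maximal
#'     dose of that drug scaled by the constant `c`) and prior variance
#'     `v = 0.1 * (c * Dmax_i / 2)`, giving `beta = m / v`, `alpha = m * beta`;
#'   \item signal amplitude `sigma_f` (the GP standard deviation; its square
#'     is the kernel variance): mean `m = Emax_obs / 2` and variance
#'     `v = 0.1 * (Emax_obs / 2)` where `Emax_obs` is the maximum response
#'     level reached, giving `beta = 10`, `alpha = 5 * Emax_obs`;
#'   \item noise standard deviation `sigma`: Gamma(2, 1) for percent-scale
#'     data, Gamma(0.14, 1.14) for fraction-scale data (the scale difference
#'     is the only reason for the two defaults).
#' }
#' The constant `c` reflects how much the effect changes over the observed
#' doses; `c = NULL` (auto) sets it to the ratio of the minimal to the
#' maximal response reached on the monotherapy data (<= 1: strongly changing
#' effects shorten the length scales into the log-dose regime, flat curves
#' keep them near the dose span).
#'
#' @param data A [dose_response] data set.
#' @param c Positive scaling constant for the length-scale prior means, or
#'   `NULL` for the automatic rule.
#' @return A `gp_priors` object: list with `(alpha, beta)` per hyperparameter
#'   and the constant `c` used.
#' @export
gp_priors <- function(data, c = NULL) {
  at <- dr_attrs(data)
  dmax1 <- max(data$dose1)
  dmax2 <- max(data$dose2)
  if (dmax1 <= 0 || dmax2 <= 0) abort("zero dose range")
  if (is.null(c)) {
    mono <- data$response[data$dose1 == 0 | data$dose2 == 0]
    pos <- mono[mono > 0]
    if (length(pos) == 0) abort("cannot auto-scale c: no positive monotherapy responses")
    c <- min(pos) / max(pos)
  }
  if (!is.finite(c) || c <= 0) abort("c must be a positive number")
  ls_prior <- function(dmax) {
    m <- c * dmax
    v <- 0.1 * (c * dmax / 2)
    beta <- m / v
    list(alpha = m * beta, beta = beta)
  }
  emax_obs <- max(abs(data$response)) # maximum response level reached
  m_sf <- emax_obs / 2
  v_sf <- 0.1 * (emax_obs / 2)
  noise <- if (at$response_scale == "percent") {
    list(alpha = 2, beta = 1)
  } else {
    list(alpha = 0.14, beta = 1.14)
  }
  structure(
    list(
      l1 = ls_prior(dmax1),
      l2 = ls_prior(dmax2),
      sigma_f = list(alpha = m_sf * (m_sf / v_sf), beta = m_sf / v_sf),
      sigma = noise,
      c = c
    ),
    class = "gp_priors"
  )
}

#' @export
print.gp_priors <- function(x, ...) {
  for (p in c("l1", "l2", "sigma_f", "sigma")) {
    cat(sprintf("  %-9s ~ Gamma(%.4g, %.4g)  mean %.4g\n",
                p, x[[p]]$alpha, x[[p]]$beta, x[[p]]$alpha / x[[p]]$beta))
  }
  cat(sprintf("  c = %.4g\n", x$c))
  invisible(x)
}

prior_matrix <- function(priors) {
  rbind(
    alpha = c(priors$l1$alpha, priors$l2$alpha, priors$sigma_f$alpha, priors$sigma$alpha),
    beta = c(priors$l1$beta, priors$l2$beta, priors$sigma_f$beta, priors$sigma$beta)
  )
}

#' Settings for Hamiltonian Monte Carlo hyperparameter sampling
#'
#' Defaults follow the reference analysis settings: 1000 burn-in steps,
#' 100,000 samples, 75% target acceptance, 5 leapfrog steps, and a step-size
#' candidate grid equally spaced on the log scale; the largest candidate
#' whose pilot run reaches the target acceptance is used.
#'
#' @param burn_in,n_samples Chain lengths.
#' @param target_accept Target acceptance rate in (0, 1).
#' @param leapfrog_steps Leapfrog steps per proposal.
#' @param step_size_grid Increasing candidate step sizes.
#' @param step_size Fixed step size; skips the pilot search when given.
#' @param pilot_iters Iterations per pilot run during step-size selection.
#' @param seed Integer seed for the sampler.
#' @return An `hmc_settings` list.
#' @export
hmc_settings <- function(burn_in = 1000, n_samples = 100000,
                         target_accept = 0.75, leapfrog_steps = 5,
                         step_size_grid = c(0.01, 0.02, 0.03, 0.05, 0.08,
                                            0.1, 0.2, 0.3, 0.6, 1.00),
                         step_size = NULL, pilot_iters = 100, seed = 0) {
  if (target_accept <= 0 || target_accept >= 1) abort("target_accept must be in (0, 1)")
  if (is.unsorted(step_size_grid, strictly = TRUE)) {
    abort("step_size_grid must be strictly increasing")
  }
  structure(
    list(burn_in = as.integer(burn_in), n_samples = as.integer(n_samples),
         target_accept = target_accept, leapfrog_steps = as.integer(leapfrog_steps),
         step_size_grid = step_size_grid, step_size = step_size,
         pilot_iters = as.integer(pilot_iters), seed = as.integer(seed)),
    class = "hmc_settings"
  )
}

# log posterior (and gradient) in the unconstrained space
# phi = log(l1, l2, sigma_f, sigma) -- note: log *standard deviations* for
# the amplitude and noise -- including the log-Jacobian sum(phi). R
# reference implementation; the C++ sampler reimplements this and the two
# are cross-checked in the tests.
phi_to_theta <- function(phi) {
  gp_hyperparameters(sigma_f2 = exp(2 * phi[3]), l1 = exp(phi[1]),
                     l2 = exp(phi[2]), sigma2 = exp(2 * phi[4]))
}

log_posterior_phi <- function(phi, data, priors, jitter = 1e-8) {
  theta <- phi_to_theta(phi)
  pm <- prior_matrix(priors)
  th <- exp(phi)
  lp <- sum(dgamma(th, shape = pm["alpha", ], rate = pm["beta", ], log = TRUE)) +
    sum(phi)
  gp_log_marginal(data, theta, jitter = jitter) + lp
}

log_posterior_phi_grad <- function(phi, data, priors, jitter = 1e-8) {
  theta <- phi_to_theta(phi)
  th <- exp(phi)
  pm <- prior_matrix(priors)
  g_nat <- gp_log_marginal_grad(data, theta, jitter = jitter)
  # d(theta_kernel)/d(phi): l on the log scale, variances = exp(2 phi)
  g_phi <- c(th[1] * g_nat[["l1"]], th[2] * g_nat[["l2"]],
             2 * theta$sigma_f2 * g_nat[["sigma_f2"]],
             2 * theta$sigma2 * g_nat[["sigma2"]])
  g_phi + (pm["alpha", ] - 1) - pm["beta", ] * th + 1
}

#' Sample GP hyperparameters with Hamiltonian Monte Carlo
#'
#' Samples `(l1, l2, sigma_f, sigma)` from the posterior proportional to
#' the GP marginal likelihood times the Gamma priors. Sampling runs in the
#' unconstrained space `log(theta)` with the Jacobian correction; proposals
#' use leapfrog integration of Hamiltonian dynamics. Unless a fixed
#' `step_size` is supplied, candidates from `step_size_grid` are piloted
#' largest-first and the largest one whose acceptance rate reaches
#' `target_accept` is used (falling back to the smallest candidate, with a
#' warning, if none does).
#'
#' @inheritParams gp_log_marginal
#' @param priors A [gp_priors] object (default: built from `data`).
#' @param settings An [hmc_settings] object.
#' @return A `gp_posterior_samples` object: list with `samples` (tibble of
#'   draws of `l1`, `l2`, `sigma_f`, `sigma` in natural space),
#'   `posterior_mean` ([gp_hyperparameters]),
#'   `hpd95` (per-parameter intervals), `acceptance_rate`, `step_size_used`,
#'   `rhat` (split-Rhat per parameter), and the inputs.
#' @export
fit_gp_hmc <- function(data, priors = gp_priors(data), settings = hmc_settings(),
                       jitter = 1e-8) {
  X <- as.matrix(as_tibble(data)[, c("dose1", "dose2")])
  y <- data$response
  pm <- prior_matrix(priors)
  phi0 <- log(pmax(pm["alpha", ] / pm["beta", ], 1e-6)) # start at prior means
  eps <- settings$step_size
  if (is.null(eps)) {
    eps <- min(settings$step_size_grid)
    found <- FALSE
    for (cand in rev(settings$step_size_grid)) {
      pilot <- hmc_chain_cpp(X, y, pm["alpha", ], pm["beta", ], phi0,
                             settings$pilot_iters, 0L, settings$leapfrog_steps,
                             cand, settings$seed + 101L, jitter)
      if (pilot$acceptance_rate >= settings$target_accept) {
        eps <- cand
        found <- TRUE
        break
      }
    }
    if (!found) {
      warn(sprintf("no step size reached target acceptance %.2f; using smallest (%.3g)",
                   settings$target_accept, eps))
    }
  }
  run <- hmc_chain_cpp(X, y, pm["alpha", ], pm["beta", ], phi0,
                       settings$n_samples, settings$burn_in,
                       settings$leapfrog_steps, eps, settings$seed, jitter)
  draws <- exp(run$samples) # n_samples x 4, columns l1, l2, sigma_f, sigma
  colnames(draws) <- c("l1", "l2", "sigma_f", "sigma")
  samples <- as_tibble(draws)
  if (run$divergence_rate > 0.05) {
    warn(sprintf("%.1f%% divergent trajectories", 100 * run$divergence_rate))
  }
  structure(
    list(
      samples = samples,
      # plug-in hyperparameters: posterior means, variances averaged on the
      # variance scale
      posterior_mean = gp_hyperparameters(sigma_f2 = mean(draws[, "sigma_f"]^2),
                                          l1 = mean(draws[, "l1"]),
                                          l2 = mean(draws[, "l2"]),
                                          sigma2 = mean(draws[, "sigma"]^2)),
      hpd95 = purrr::map(samples, hpd_interval),
      acceptance_rate = run$acceptance_rate,
      step_size_used = eps,
      rhat = purrr::map_dbl(samples, split_rhat),
      settings = settings, priors = priors, data = data
    ),
    class = "gp_posterior_samples"
  )
}

#' @export
print.gp_posterior_samples <- function(x, ...) {
  cat(sprintf("<gp_posterior_samples> %d draws, acceptance %.2f, step size %.3g\n",
              nrow(x$samples), x$acceptance_rate, x$step_size_used))
  for (p in names(x$hpd95)) {
    cat(sprintf("  %-9s %.4g  [%.4g, %.4g]  Rhat %.3f\n",
                p, mean(x$samples[[p]]), x$hpd95[[p]][1], x$hpd95[[p]][2],
                x$rhat[[p]]))
  }
  invisible(x)
}

#' @describeIn fit_gp_hmc posterior draws as a tibble.
#' @param x,object A `gp_posterior_samples` object.
#' @param ... Unused.
#' @export
tidy.gp_posterior_samples <- function(x, ...) {
  tibble(
    term = names(x$hpd95),
    estimate = purrr::map_dbl(names(x$hpd95), ~ mean(x$samples[[.x]])),
    hpd_low = purrr::map_dbl(x$hpd95, 1),
    hpd_high = purrr::map_dbl(x$hpd95, 2),
    rhat = unname(x$rhat)
  )
}

#' @describeIn fit_gp_hmc one-row chain summary.
#' @export
glance.gp_posterior_samples <- function(x, ...) {
  tibble(
    n_samples = nrow(x$samples),
    acceptance_rate = x$acceptance_rate,
    step_size = x$step_size_used,
    max_rhat = max(x$rhat)
  )
}

# split-Rhat (two halves of one chain), rank-free classic form
split_rhat <- function(x) {
  n <- length(x)
  if (n < 4) return(NA_real_)
  half <- floor(n / 2)
  chains <- cbind(x[seq_len(half)], x[(n - half + 1):n])
  m <- ncol(chains)
  means <- colMeans(chains)
  vars <- apply(chains, 2, var)
  B <- half * var(means)
  W <- mean(vars)
  if (W == 0) return(1)
  sqrt(((half - 1) / half * W + B / half) / W)
}

#' Highest posterior density interval
#'
#' Shortest interval containing `level` posterior mass, by the sorted-window
#' method: among all windows of `ceiling(level * n)` consecutive order
#' statistics, the narrowest one.
#'
#' @param samples Numeric vector of draws.
#' @param level Interval mass (default 0.95).
#' @return Numeric `c(low, high)`.
#' @export
hpd_interval <- function(samples, level = 0.95) {
  if (length(samples) == 0) abort("empty samples")
  x <- sort(samples)
  n <- length(x)
  k <- min(n, ceiling(level * n))
  if (k == n) return(c(x[1], x[n]))
  widths <- x[(k + 1):n] - x[1:(n - k)]
  i <- which.min(widths)
  c(x[i], x[i + k])
}

#' MAP estimate of the GP hyperparameters
#'
#' Deterministic alternative to [fit_gp_hmc]: maximises the log marginal
#' likelihood plus log Gamma priors over `log(theta)` with L-BFGS-B from a
#' fixed list of multi-starts (prior mean, and scaled versions of it).
#'
#' @inheritParams fit_gp_hmc
#' @param start_factors Multiplicative offsets applied to the prior-mean
#'   start, one optimisation run each.
#' @return A `gp_map_fit`: list with `theta` ([gp_hyperparameters]),
#'   `log_posterior`, and the per-start objective values.
#' @export
fit_gp_map <- function(data, priors = gp_priors(data),
                       start_factors = c(1, 0.3, 3, 0.1), jitter = 1e-8) {
  pm <- prior_matrix(priors)
  phi_mean <- log(pmax(pm["alpha", ] / pm["beta", ], 1e-6))
  fn <- function(phi) -log_posterior_phi(phi, data, priors, jitter)
  gr <- function(phi) -log_posterior_phi_grad(phi, data, priors, jitter)
  runs <- purrr::map(start_factors, function(f) {
    tryCatch(
      optim(phi_mean + log(f), fn, gr, method = "L-BFGS-B",
            lower = phi_mean - 12, upper = phi_mean + 12,
            control = list(maxit = 300)),
      error = function(e) NULL
    )
  })
  runs <- purrr::compact(runs)
  if (length(runs) == 0) abort("all optimisation starts failed")
  best <- runs[[which.min(purrr::map_dbl(runs, "value"))]]
  phi <- best$par
  structure(
    list(
      theta = phi_to_theta(phi),
      log_posterior = -best$value,
      start_values = -purrr::map_dbl(runs, "value"),
      priors = priors
    ),
    class = "gp_map_fit"
  )
}

#' @export
print.gp_map_fit <- function(x, ...) {
  cat(sprintf("<gp_map_fit> log posterior %.3f\n", x$log_posterior))
  print(x$theta)
  invisible(x)
}
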