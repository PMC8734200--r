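# shared fixtures: built in code, deterministic

greco_design1 <- c(0, 2, 5, 10, 20, 50)
greco_design2 <- c(0, 0.2, 0.5, 1, 2, 5)

hill_a <- list(E0 = 100, Emax = 0, h = 0.87, C = 8.16)
hill_b <- list(E0 = 100, Emax = 0, h = 1.27, C = 0.79)

# dense monotherapy curve from a Hill parameter set (log1p-style spacing)
hill_curve_fixture <- function(hill, dmax, n = 201, l = dmax / 10) {
  doses <- l * expm1(seq(0, log1p(dmax / l), length.out = n))
  doses[1] <- 0
  monotherapy_curve(doses, hill_response(doses, hill$E0, hill$Emax, hill$h, hill$C))
}

# small deterministic dose-response tibble (4 x 4, additive, no noise)
tiny_data <- function() {
  simulate_combination(design1 = c(0, 2, 10, 50), design2 = c(0, 0.5, 2, 5),
                       alpha = 0, noise_sd = 0, seed = 1)
}

reduced_hmc <- function(seed = 0, burn_in = 500, n_samples = 5000, ...) {
  hmc_settings(burn_in = burn_in, n_samples = n_samples, pilot_iters = 100,
               seed = seed, ...)
}

# random dose pairs on the Greco-like ranges
random_dose_set <- function(n, seed) {
  withr::with_seed(seed, {
    tibble::tibble(dose1 = runif(n, 0, 50), dose2 = runif(n, 0, 5))
  })
}

# brute-force multivariate normal log density (independent of the GP code
# path: determinant + explicit inverse instead of Cholesky solves)
dmvnorm_log <- function(y, S) {
  n <- length(y)
  -0.5 * drop(t(y) %*% solve(S, y)) -
    0.5 * as.numeric(determinant(S)$modulus) - n / 2 * log(2 * pi)
}
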