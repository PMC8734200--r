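test_that("the Hill curve evaluates its closed form", {
  expect_equal(hill_response(0, 100, 0, 1, 10), 100)
  expect_equal(hill_response(10, 100, 20, 2, 10), 60) # E(C) = (E0 + Emax)/2
  expect_equal(hill_response(30, 100, 0, 1, 10), 25)  # 100 / (1 + 3)
  expect_error(hill_response(-1, 100, 0, 1, 10), "non-negative")
  expect_error(hill_response(1, 100, 0, -1, 10), "must be > 0")
})

test_that("Hill fits recover noiseless parameters and are deterministic", {
  truth <- c(E0 = 90, Emax = 5, h = 1.6, C = 12)
  mono <- tibble::tibble(
    dose = c(0, 2, 5, 12, 30, 80),
    response = hill_response(c(0, 2, 5, 12, 30, 80), 90, 5, 1.6, 12)
  )
  fit <- fit_hill(mono)
  expect_equal(unname(fit$params / truth), rep(1, 4), tolerance = 1e-4)
  expect_identical(fit_hill(mono)$params, fit$params)
  expect_error(fit_hill(mono[1:3, ]), "4 distinct")
  expect_equal(predict(fit, 12), hill_response(12, fit$params["E0"],
                                               fit$params["Emax"],
                                               fit$params["h"],
                                               fit$params["C"]),
               ignore_attr = TRUE)
})

test_that("constant monotherapy data fit without error (slope unidentifiable)", {
  mono <- tibble::tibble(dose = c(0, 1, 5, 20), response = rep(80, 4))
  fit <- fit_hill(mono)
  expect_true(all(is.finite(fit$params)))
  expect_lt(glance(fit)$mse, 1e-6)
})

test_that("parametric bootstrap intervals are seeded, degenerate at zero noise, and widen with it", {
  doses <- c(0, 1, 3, 8, 20, 50)
  make_mono <- function(sd, seed) {
    tibble::tibble(
      dose = doses,
      response = hill_response(doses, 100, 0, 1.3, 8) +
        withr::with_seed(seed, rnorm(6, sd = sd))
    )
  }
  clean <- fit_hill(make_mono(0, 1))
  ci0 <- bootstrap_ci(clean, B = 50, seed = 2)
  expect_equal(ci0$conf.low, ci0$conf.high, tolerance = 1e-6)

  noisy <- fit_hill(make_mono(2, 3))
  ci_a <- bootstrap_ci(noisy, B = 100, seed = 4)
  ci_b <- bootstrap_ci(noisy, B = 100, seed = 4)
  expect_identical(ci_a, ci_b) # bit-reproducible
  noisier <- fit_hill(make_mono(6, 5))
  ci_c <- bootstrap_ci(noisier, B = 100, seed = 4)
  width <- function(ci) mean(ci$conf.high - ci$conf.low)
  expect_gt(width(ci_c), width(ci_a))
  td <- tidy(noisy, ci = ci_a)
  expect_true(all(c("conf.low", "conf.high") %in% names(td)))
})

test_that("MuSyC boundary behaviour: corners and Hill edges", {
  p <- musyc_params(E0 = 100, E1 = 10, E2 = 30, E3 = 5,
                    h1 = 1.2, h2 = 0.9, C1 = 8, C2 = 0.8,
                    alpha12 = 2, alpha21 = 0.5, gamma12 = 1.5, gamma21 = 0.7)
  expect_equal(musyc_response(p, 0, 0), 100)
  expect_equal(musyc_response(p, 1e9, 0), 10, tolerance = 1e-4)
  expect_equal(musyc_response(p, 0, 1e9), 30, tolerance = 1e-4)
  expect_equal(musyc_response(p, 1e9, 1e9), 5, tolerance = 1e-3)
  d1 <- c(0, 0.5, 2, 8, 30, 100)
  expect_equal(musyc_response(p, d1, 0),
               hill_response(d1, 100, 10, 1.2, 8), tolerance = 1e-10)
  d2 <- c(0, 0.1, 0.8, 3, 10)
  expect_equal(musyc_response(p, 0, d2),
               hill_response(d2, 100, 30, 0.9, 0.8), tolerance = 1e-10)
  # beta derives from the state effects
  expect_equal(p$beta, (min(10, 30) - 5) / (100 - min(10, 30)))
  expect_error(musyc_params(100, 10, 30, 5, h1 = -1, h2 = 1, C1 = 1, C2 = 1))
})

test_that("the additive MuSyC surface reduces to products of Hill occupancies", {
  # alpha = gamma = 1: closed-form two-dimensional Hill surface
  p <- musyc_params(E0 = 100, E1 = 0, E2 = 20, E3 = 0,
                    h1 = 1, h2 = 1.5, C1 = 10, C2 = 1)
  d1 <- c(0, 2, 7, 30)
  d2 <- c(0, 0.4, 1.2, 5)
  grid <- expand.grid(d1 = d1, d2 = d2)
  occ1 <- grid$d1 / (grid$d1 + 10) # h1 = 1
  u1 <- 10 / (grid$d1 + 10)
  occ2 <- grid$d2^1.5 / (grid$d2^1.5 + 1)
  u2 <- 1 / (grid$d2^1.5 + 1)
  closed <- 100 * u1 * u2 + 0 * occ1 * u2 + 20 * u1 * occ2 + 0 * occ1 * occ2
  expect_equal(musyc_response(p, grid$d1, grid$d2), closed, tolerance = 1e-10)
  # identical Hill edges and shared floor: the null diagonal is
  # E3 + (E0 - E3) u^2 with u the single-drug unaffected fraction, so it
  # lies between the shared monotherapy curve and the floor E3
  pid <- musyc_params(E0 = 100, E1 = 5, E2 = 5, E3 = 5,
                      h1 = 1.3, h2 = 1.3, C1 = 4, C2 = 4)
  pd <- seq(0, 30, length.out = 13)
  diag_resp <- musyc_response(pid, pd, pd)
  mono <- musyc_response(pid, pd, 0)
  u <- 4^1.3 / (pd^1.3 + 4^1.3)
  expect_equal(diag_resp, 5 + 95 * u^2, tolerance = 1e-10)
  expect_true(all(diag_resp <= mono + 1e-8 & diag_resp >= 5 - 1e-8))
})

test_that("MuSyC fits recover simulated parameters within 10%", {
  truth <- musyc_params(E0 = 100, E1 = 5, E2 = 15, E3 = 2,
                        h1 = 1.1, h2 = 1.4, C1 = 10, C2 = 1,
                        alpha12 = 1.8, alpha21 = 0.8,
                        gamma12 = 1, gamma21 = 1)
  des1 <- c(0, 1.5, 3, 6, 12, 25, 50, 100)
  des2 <- c(0, 0.15, 0.3, 0.6, 1.2, 2.5, 5, 10)
  grid <- expand.grid(dose1 = des1, dose2 = des2)
  resp <- musyc_response(truth, grid$dose1, grid$dose2) +
    withr::with_seed(31, rnorm(64, sd = 0.5))
  d <- dose_response(tibble::tibble(grid, response = resp))
  fit <- fit_musyc(d)
  for (nm in c("E0", "C1", "C2")) {
    expect_lt(abs(fit$params[[nm]] - truth[[nm]]) / truth[[nm]], 0.1)
  }
  for (nm in c("E1", "E2", "E3")) { # scale-relative for near-zero effects
    expect_lt(abs(fit$params[[nm]] - truth[[nm]]) / 100, 0.1)
  }
})

test_that("constrained MuSyC fits additive data at the noise level", {
  d <- simulate_combination(alpha = 0, noise_sd = 2, seed = 12)
  nullfit <- fit_musyc(d, constrained = TRUE)
  expect_equal(nullfit$params$alpha12, 1)
  expect_equal(nullfit$params$beta, 0)
  expect_lt(nullfit$residual_sd, 2 * 2)
})

test_that("MuSyC effect surfaces share the Hand-GP sign convention", {
  # data generated from a MuSyC surface with potency synergy: the full fit
  # must beat its constrained null in the interior, with positive volume
  # difference (positive = synergy, as for Hand-GP)
  truth <- musyc_params(E0 = 100, E1 = 5, E2 = 10, E3 = 0, h1 = 1.2,
                        h2 = 1.3, C1 = 8, C2 = 0.8,
                        alpha12 = 4, alpha21 = 4)
  grid <- expand.grid(dose1 = c(0, 2, 5, 10, 20, 50),
                      dose2 = c(0, 0.2, 0.5, 1, 2, 5))
  resp <- musyc_response(truth, grid$dose1, grid$dose2) +
    withr::with_seed(40, rnorm(36, sd = 1))
  d <- dose_response(tibble::tibble(grid, response = resp))
  ms <- musyc_synergy(d)
  expect_false(ms$full$constrained)
  expect_true(ms$null$constrained)
  interior <- ms$effect$dose1 >= 10 & ms$effect$dose2 >= 1
  expect_gt(mean(ms$effect$effect[interior] > 0), 0.8)
  expect_gt(ms$volumes$volume_difference, 0)
  expect_equal(ms$volumes$volume_difference,
               ms$volumes$volume_null - ms$volumes$volume_fitted)
  # full == null parameters -> identically zero effect
  same <- musyc_effect(
    structure(list(params = ms$null$params, constrained = FALSE), class = "musyc_fit"),
    ms$null, ms$grid
  )
  expect_true(all(same$effect$effect == 0))
  expect_equal(same$volumes$volume_difference, 0)
})

test_that("blocked-drug regimes leave cooperativity parameters unidentified", {
  # alpha ~ 0: drug 1 bound blocks drug 2, so gamma12 cannot matter and its
  # bootstrap interval must be wide
  truth <- musyc_params(E0 = 100, E1 = 10, E2 = 20, E3 = 15,
                        h1 = 1.2, h2 = 1.1, C1 = 8, C2 = 0.8,
                        alpha12 = 1e-4, alpha21 = 1e-4,
                        gamma12 = 1, gamma21 = 1)
  grid <- expand.grid(dose1 = c(0, 2, 5, 10, 20, 50),
                      dose2 = c(0, 0.2, 0.5, 1, 2, 5))
  resp <- musyc_response(truth, grid$dose1, grid$dose2) +
    withr::with_seed(17, rnorm(36, sd = 1))
  d <- dose_response(tibble::tibble(grid, response = resp))
  fit <- fit_musyc(d)
  ci <- bootstrap_ci(fit, B = 60, seed = 18)
  logw <- function(term) {
    row <- ci[ci$term == term, ]
    log(row$conf.high / max(row$conf.low, 1e-6))
  }
  expect_gt(logw("gamma12"), 5 * logw("h1"))
  expect_gt(logw("gamma21"), 5 * logw("h2"))
})
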