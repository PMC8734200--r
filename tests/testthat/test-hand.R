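linear_curve <- function(E0 = 100, slope = 2, dmax = 50, n = 51) {
  doses <- seq(0, dmax, length.out = n)
  monotherapy_curve(doses, E0 - slope * doses)
}

test_that("curve inversion: linear curves exact, Hill curves to grid resolution", {
  lc <- linear_curve()
  expect_equal(as.numeric(invert_curve(lc, 100)), 0)
  expect_equal(as.numeric(invert_curve(lc, 60)), 20) # E = 100 - 2d
  expect_warning(invert_curve(lc, 150), "clamped")

  f <- hill_curve_fixture(hill_a, dmax = 50, n = 101)
  d_in <- f$dose[seq(2, 100, by = 7)]
  back <- as.numeric(invert_curve(f, approx(f$dose, f$effect, d_in)$y,
                                  warn_clamp = FALSE))
  expect_lt(max(abs(back - d_in)), max(diff(f$dose)))

  expect_error(monotherapy_curve(c(0, 1, 2), c(5, 5, 5)), "non-invertible")
  expect_error(monotherapy_curve(c(0, 1, 0.5), c(3, 2, 1)), "increasing")
})

test_that("partition counts follow the nearest-grid-point rule", {
  d <- tiny_data()
  g <- dose_grid(d, n_per_axis = 101, lengthscales = c(10, 1))
  x40 <- g$axis1[41] # the 40th positive grid point
  parts <- choose_partitions(g, x40, 0)
  expect_equal(parts$N1, 40L)
  expect_equal(parts$N2, 0L)
  # midway between grid points: nearest wins; exact ties break lower
  ax <- c(0, 1, 2, 3)
  expect_equal(handgp:::partitions_axis(ax, 1.4), 1L)
  expect_equal(handgp:::partitions_axis(ax, 1.6), 2L)
  expect_equal(handgp:::partitions_axis(ax, 1.5), 1L) # tie -> lower index
})

test_that("sham combination converges to f(x1 + x2)", {
  f <- hill_curve_fixture(hill_a, dmax = 100, n = 401)
  rng <- diff(range(f$effect))
  for (pair in list(c(10, 20), c(5, 5), c(30, 40))) {
    got <- hand_construct(f, f, pair[1], pair[2], 100, 100)
    expect_lt(abs(as.numeric(got) -
                    hill_response(sum(pair), hill_a$E0, hill_a$Emax,
                                  hill_a$h, hill_a$C)),
              0.005 * rng)
  }
})

test_that("linear monotherapies combine additively for any partition count", {
  f1 <- linear_curve(E0 = 100, slope = 2, dmax = 100, n = 41)
  f2 <- linear_curve(E0 = 100, slope = 5, dmax = 40, n = 41)
  for (N in c(1L, 3L, 7L)) {
    got <- as.numeric(hand_construct(f1, f2, 10, 4, N, N))
    expect_equal(got, 100 - 2 * 10 - 5 * 4, tolerance = 1e-10)
  }
})

test_that("the construction commutes under drug swap", {
  f1 <- hill_curve_fixture(hill_a, dmax = 150, n = 501)
  f2 <- hill_curve_fixture(hill_b, dmax = 15, n = 501)
  rng <- diff(range(c(f1$effect, f2$effect)))
  for (pair in list(c(10, 1), c(40, 4), c(5, 0.3))) {
    a <- as.numeric(hand_construct(f1, f2, pair[1], pair[2], 200, 200))
    b <- as.numeric(hand_construct(f2, f1, pair[2], pair[1], 200, 200))
    expect_lt(abs(a - b), 1e-6 * rng)
  }
})

test_that("curves with different starting effects average with a warning", {
  f1 <- linear_curve(E0 = 100, slope = 2)
  f2 <- linear_curve(E0 = 90, slope = 2)
  expect_warning(res <- hand_construct(f1, f2, 5, 5, 10, 10), "average")
  # beyond the shared-start tolerance the construction starts at the average
  # and is only required to stay within the bracketing single-curve results
  expect_gte(as.numeric(res), 90 - 2 * 10)
  expect_lte(as.numeric(res), 100 - 2 * 10)
})

test_that("null surface edges equal the monotherapy curves exactly", {
  d <- tiny_data()
  g <- dose_grid(d, n_per_axis = 41, lengthscales = c(10, 1))
  f1 <- hill_curve_fixture(hill_a, dmax = 100, n = 301)
  f2 <- hill_curve_fixture(hill_b, dmax = 10, n = 301)
  null <- hand_null_surface(f1, f2, g)
  edge1 <- null[null$dose2 == 0, ]
  expect_equal(edge1$null,
               approx(f1$dose, f1$effect, xout = edge1$dose1)$y,
               tolerance = 1e-12)
  expect_equal(edge1$N2, rep(0L, nrow(edge1)))
  edge2 <- null[null$dose1 == 0, ]
  expect_equal(edge2$null, approx(f2$dose, f2$effect, xout = edge2$dose2)$y,
               tolerance = 1e-12)
  expect_equal(null$null[null$dose1 == 0 & null$dose2 == 0],
               attr(null, "start_effect"))
})

test_that("sham null surfaces match f(x1 + x2) node-wise within 0.5%", {
  d <- dose_response(tibble::tibble(
    dose1 = c(greco_design1, rep(0, 5)), dose2 = c(rep(0, 6), greco_design1[-1]),
    response = hill_response(c(greco_design1, greco_design1[-1]),
                             hill_a$E0, hill_a$Emax, hill_a$h, hill_a$C)
  ))
  g <- dose_grid(d, n_per_axis = 101, lengthscales = c(10, 10))
  f <- hill_curve_fixture(hill_a, dmax = 120, n = 601)
  null <- hand_null_surface(f, f, g)
  truth <- hill_response(null$dose1 + null$dose2, hill_a$E0, hill_a$Emax,
                         hill_a$h, hill_a$C)
  rng <- diff(range(f$effect))
  expect_lt(max(abs(null$null - truth)), 0.005 * rng)
})

test_that("refinement: doubling the partitions converges (Cauchy)", {
  f1 <- hill_curve_fixture(hill_a, dmax = 150, n = 801)
  f2 <- hill_curve_fixture(hill_b, dmax = 15, n = 801)
  at <- function(N) as.numeric(hand_construct(f1, f2, 30, 3, N, N))
  d1 <- abs(at(50) - at(25))
  d2 <- abs(at(100) - at(50))
  d3 <- abs(at(200) - at(100))
  expect_lt(d2, d1)
  expect_lt(d3, d2)
})

test_that("clamping flags fire when curves run out of invertible range", {
  # curves stop at the design span: corner nodes need equivalent doses past
  # the end and must be flagged, not fail
  f1 <- hill_curve_fixture(hill_a, dmax = 50, n = 201)
  f2 <- hill_curve_fixture(hill_b, dmax = 5, n = 201)
  d <- tiny_data()
  g <- dose_grid(d, n_per_axis = 21, lengthscales = c(10, 1))
  null <- hand_null_surface(f1, f2, g)
  corner <- null[null$dose1 == 50 & null$dose2 == 5, ]
  expect_true(corner$clamped)
  expect_true(all(is.finite(null$null)))
})
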