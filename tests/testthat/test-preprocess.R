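mk_series <- function(red, nir, s6, s7, valid = TRUE) {
  n <- max(length(red), length(nir), length(s6), length(s7))
  list(dates = seq_len(n), rho_red = rep_len(red, n),
       rho_nir = rep_len(nir, n), rho_swir6 = rep_len(s6, n),
       rho_swir7 = rep_len(s7, n), valid = rep_len(valid, n))
}

test_that("index formulas match hand-computed values", {
  ind <- compute_indices(mk_series(0.05, 0.3, 0.2, 0.1))
  expect_equal(ind$evi2[1], 2.5 * 0.25 / 1.42, tolerance = 1e-12)  # 0.4401
  # NIR == SWIR6 makes LSWI zero
  expect_equal(compute_indices(mk_series(0.05, 0.2, 0.2, 0.1))$lswi[1], 0)
  # equal SWIR bands make NMDI one
  expect_equal(compute_indices(mk_series(0.05, 0.3, 0.2, 0.2))$nmdi[1], 1)
})

test_that("zero denominators flag the date invalid instead of erroring", {
  s <- mk_series(0.05, 0, 0, 0.1)  # LSWI denominator 0, NMDI denom -0.1
  ind <- compute_indices(s)
  expect_false(any(ind$valid))
  expect_true(all(is.na(ind$lswi)))
})

test_that("Whittaker smoother satisfies its algebraic identities", {
  days <- composite_days(); grid <- daily_grid()
  n <- length(days)
  # constant input -> constant output at any lambda
  z <- whittaker_smooth(rep(0.5, n), rep(TRUE, n), days, lambda = 1234, grid)
  expect_equal(z, rep(0.5, length(grid)), tolerance = 1e-8)
  # all days observed, lambda -> 0: output reproduces input
  y <- sin(seq(0, 3 * pi, length.out = 200)) * 0.3 + 0.5
  g <- seq_len(200)
  z <- whittaker_smooth(y, rep(TRUE, 200), g, lambda = 1e-8, grid = g)
  expect_equal(z, y, tolerance = 1e-8)
  # linearity in the input for a fixed gap pattern
  set.seed(1)
  y1 <- runif(n); keep <- runif(n) > 0.2
  a <- whittaker_smooth(3 * y1, keep, days, 500, grid)
  b <- whittaker_smooth(y1, keep, days, 500, grid)
  expect_equal(a, 3 * b, tolerance = 1e-10)
})

test_that("smoothing a noisy sinusoid beats the raw observations", {
  days <- seq(1, 361, by = 8)
  truth <- 0.5 + 0.3 * sin(2 * pi * days / 365)
  wins <- 0
  for (k in 1:100) {
    set.seed(k)
    obs <- truth + rnorm(length(days), 0, 0.05)
    z <- whittaker_smooth(obs, rep(TRUE, length(days)), days, lambda = 100,
                          grid = seq(1, 368))
    sm <- z[match(days, seq(1, 368))]
    if (sqrt(mean((sm - truth)^2)) < sqrt(mean((obs - truth)^2)))
      wins <- wins + 1
  }
  expect_gte(wins, 95)
})

test_that("smoother output stays near the observed range", {
  days <- composite_days(); grid <- daily_grid()
  px <- simulate_pixel(246, noise_sd = 0.02, seed = 8)
  ind <- compute_indices(px)
  for (lam in c(100, 500, 5000)) {
    z <- whittaker_smooth(ind$evi2, ind$valid, days, lam, grid)
    at_obs <- z[match(days, grid)]
    rng <- range(ind$evi2); slack <- 0.05 * diff(rng)
    expect_true(all(at_obs >= rng[1] - slack & at_obs <= rng[2] + slack))
  }
})

test_that("too few valid observations marks the pixel unprocessable", {
  days <- composite_days(); n <- length(days)
  expect_error(whittaker_smooth(runif(n), c(rep(TRUE, 7), rep(FALSE, n - 7)),
                                days, 500), "fewer than 8")
  px <- simulate_pixel(15, gap_rate = 0.95, seed = 4)
  idx <- preprocess_series(px)
  expect_true(idx$unprocessable)
  expect_equal(idx$availability$class, "low")
})

test_that("availability classes split at 70% and 50%, inclusive boundaries", {
  days <- seq(1, 361, by = 8)
  in_season <- days >= 60 & days <= 304
  n <- sum(in_season)
  mk_valid <- function(f) {
    v <- rep(FALSE, length(days))
    v[which(in_season)[seq_len(round(f * n))]] <- TRUE
    v
  }
  frac <- function(f) data_availability(mk_valid(f), days)
  expect_equal(frac(0.90)$class, "good")
  expect_equal(frac(0.60)$class, "medium")
  expect_equal(frac(0.40)$class, "low")
  # exact boundaries land in the medium class
  n_at <- function(k) { v <- rep(FALSE, length(days)); v[which(in_season)[seq_len(k)]] <- TRUE; v }
  f70 <- data_availability(n_at(round(0.7 * n)), days)
  expect_equal(f70$fraction, 0.7, tolerance = 1e-9)
  expect_equal(f70$class, "medium")
  f50 <- data_availability(n_at(round(0.5 * n)), days)
  expect_equal(f50$class, "medium")
  expect_error(data_availability(rep(TRUE, 3), c(1, 9, 17),
                                 season = c(60, 59)), "empty season")
})
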