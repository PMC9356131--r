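test_that("rice metrics follow the RCLE definition", {
  g <- 1:100
  w <- data.frame(start = 5, tillering = 20, heading = 80, harvest = 95)
  # constant LSWI, rising EVI2: rcle 0
  evi2 <- seq(0.2, 0.6, length.out = 100)
  m <- rice_metrics(rep(0.25, 100), evi2, w, g)
  expect_equal(m$rcle, 0)
  expect_equal(m$lswi_min, 0.25)
  # LSWI range 0.2 over an EVI2 rise of 0.4 -> rcle 0.5
  lswi <- 0.2 + 0.2 * (g - 1) / 99
  evi2b <- 0.2 + 0.4 * (g - 20) / 60          # 0.2 at tillering, 0.6 at heading
  m2 <- rice_metrics(lswi, evi2b, w, g)
  expect_equal(m2$rcle, (max(lswi[20:80]) - min(lswi[20:80])) / 0.4,
               tolerance = 1e-9)
  expect_equal(m2$rcle, 0.2 * (60 / 99) / 0.4, tolerance = 1e-9)
  # non-positive EVI2 rise -> undefined metric
  m3 <- rice_metrics(lswi, rev(evi2b), w, g)
  expect_true(is.na(m3$rcle))
})

test_that("a simulated rice pixel satisfies the pure-pixel rice rule", {
  cyc <- list(crop_cycle("rice", 130, 195, 130, flood_lswi_level = 0.25))
  idx <- preprocess_series(simulate_pixel(15, cycles = cyc, seed = 1))
  seas <- segment_seasons(idx$evi2, 1, idx$grid)
  m <- rice_metrics(idx$lswi, idx$evi2, seas[1, ], idx$grid)
  expect_gt(m$lswi_min, 0.1)
  expect_lt(m$rcle, 0.42)
})

test_that("wheat metrics follow the EVE/EVL definitions", {
  g <- -100:300
  cal <- wheat_calendar(115, 160)
  # constant EVI2 -> both variations zero
  m0 <- wheat_metrics(rep(0.4, length(g)), cal, 170, g)
  expect_equal(m0$eve, 0); expect_equal(m0$evl, 0)
  # piecewise linear: seedling 0.2 rising to 0.6 at heading, down to 0.25
  evi2 <- approx(x = c(-100, -45, 115, 170, 300),
                 y = c(0.2, 0.2, 0.6, 0.25, 0.25), xout = g)$y
  m <- wheat_metrics(evi2, cal, 170, g)
  expect_equal(m$eve, (0.6 - 0.2) + (0.6 - 0.2), tolerance = 1e-9)  # 0.8
  expect_equal(m$evl, (0.6 - 0.25) + (0.6 - 0.25), tolerance = 1e-9)  # 0.7
  # windows outside the series span -> not classifiable
  m2 <- wheat_metrics(evi2[g >= 0], wheat_calendar(115, 160), 170, g[g >= 0])
  expect_true(is.na(m2$eve))
})

test_that("a simulated winter wheat pixel satisfies the pure-pixel rule", {
  idx <- preprocess_series(simulate_pixel(16, seed = 1))
  seas <- segment_seasons(idx$evi2, 1, idx$grid)
  m <- wheat_metrics(idx$evi2, wheat_calendar(115, 160), seas$harvest[1],
                     idx$grid)
  expect_gt(m$eve, 0.32)
  expect_gt(m$evl, 0.12)
})

test_that("RCPN follows the slope-ratio definition", {
  g <- 0:40
  expect_equal(maize_metrics(rep(0.5, 41), c(0, 40), grid = g), 0)
  # monotone rising NMDI: N_late = 0 -> rcpn 0
  expect_equal(maize_metrics(0.4 + 0.005 * g, c(0, 40), grid = g), 0)
  # +0.005/day for 20 d then -0.005/day for 20 d, sigma 0.01 -> ~9.09
  nmdi <- c(0.4 + 0.005 * (0:20), 0.5 - 0.005 * (1:20))
  expect_equal(maize_metrics(nmdi, c(0, 40), sigma = 0.01, grid = g),
               0.1 * (0.1 / 0.11) * 100, tolerance = 1e-9)
})

test_that("wheat calendar trend surfaces evaluate and dispatch correctly", {
  # intercept-only surface returns the intercepts everywhere
  cal <- estimate_wheat_calendar(35, altitude = 500, wheat_type = "winter",
                                 coef = list(heading = c(120, 0, 0),
                                             egl = c(150, 0, 0)))
  expect_equal(cal$heading_doy, 120)
  expect_equal(cal$early_growing_length, 150)
  # planar surface matches the hand-computed plane
  cal2 <- estimate_wheat_calendar(40, altitude = 1000, wheat_type = "winter",
                                  coef = list(heading = c(60, 1.5, 0.01),
                                              egl = c(100, 1, 0.002)))
  expect_equal(cal2$heading_doy, 60 + 1.5 * 40 + 0.01 * 1000)
  expect_equal(cal2$early_growing_length, 100 + 40 + 2)
  # wheat_type dispatches to its own default surface
  w <- estimate_wheat_calendar(40, wheat_type = "winter")
  s <- estimate_wheat_calendar(40, accum_temp = 2000, wheat_type = "spring")
  expect_equal(w$heading_doy, 115); expect_equal(s$heading_doy, 170)
  expect_warning(estimate_wheat_calendar(80, wheat_type = "winter"),
                 "clamped")
})

test_that("decision rules reproduce the stratified threshold behaviour", {
  # pure-pixel rice: lswi_min 0.25 > 0.1 and rcle 0.3 < 0.42
  r <- classify_season(list(lswi_min = 0.25, rcle = 0.3, eve = NA, evl = NA,
                            rcpn = 0), "pure")
  expect_equal(r$label, "rice")
  # rcle 0.5: not rice under pure (0.42) but rice under serious (0.62)
  m <- list(lswi_min = 0.25, rcle = 0.5, eve = NA, evl = NA, rcpn = 0)
  expect_equal(classify_season(m, "pure")$label, "other")
  expect_equal(classify_season(m, "serious")$label, "rice")
  # eve 0.20: below the pure floor 0.32, above the serious floor 0.16
  mw <- list(lswi_min = 0, rcle = 1, eve = 0.20, evl = 0.20, rcpn = 0)
  expect_equal(classify_season(mw, "pure")$label, "other")
  expect_equal(classify_season(mw, "serious")$label, "wheat")
})

test_that("conflicts resolve by largest relative margin, rice first on ties", {
  # both rice and maize fire; maize margin much larger
  m <- list(lswi_min = 0.12, rcle = 0.41, eve = NA, evl = NA, rcpn = 5)
  expect_equal(classify_season(m, "pure")$label, "maize")
  # exact tie engineered: rice margin == maize margin == 1 -> rice wins
  m2 <- list(lswi_min = 0.2, rcle = 0, eve = NA, evl = NA, rcpn = 0.9)
  cl <- classify_season(m2, "pure")
  expect_identical(unname(cl$margins["rice"]), unname(cl$margins["maize"]))
  expect_equal(cl$label, "rice")
})

test_that("rules are monotone in their thresholds and nested across strata", {
  set.seed(33)
  n <- 2000
  grid <- data.frame(lswi_min = runif(n, -0.2, 0.5),
                     rcle = runif(n, 0, 1.2),
                     eve = runif(n, 0, 1.2), evl = runif(n, 0, 0.6),
                     rcpn = runif(n, 0, 1))
  lab <- function(th, stratum) vapply(seq_len(n), function(i)
    classify_season(as.list(grid[i, ]), stratum, th)$label, character(1))
  th0 <- threshold_config()
  # raising theta5 never adds maize; lowering theta2 never adds rice
  th_hi5 <- threshold_config(theta5 = c(pure = 0.6, moderate = 0.5,
                                        serious = 0.4))
  th_lo2 <- threshold_config(theta2 = c(pure = 0.3, moderate = 0.4,
                                        serious = 0.5))
  l0 <- lab(th0, "pure")
  expect_true(all(lab(th_hi5, "pure") != "maize" | l0 == "maize"))
  expect_true(all(lab(th_lo2, "pure") != "rice" | l0 == "rice"))
  # stratum nesting: each crop's rule-fire set grows pure -> moderate -> serious
  fires <- function(stratum, crop) vapply(seq_len(n), function(i)
    classify_season(as.list(grid[i, ]), stratum, th0)$margins[crop] > 0,
    logical(1))
  for (crop in c("rice", "wheat", "maize")) {
    expect_true(all(!fires("pure", crop) | fires("moderate", crop)))
    expect_true(all(!fires("moderate", crop) | fires("serious", crop)))
  }
})
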