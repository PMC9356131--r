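test_that("flat series yields zero centres and zero intensity", {
  g <- daily_grid()
  wf <- wavelet_spectrum(rep(0.3, length(g)), g)
  expect_equal(nrow(wf$centers), 0)
  expect_equal(cropping_index(wf), 0L)
})

test_that("a single cycle gives one centre near its peak", {
  g <- daily_grid()
  cyc <- crop_cycle("other", 140, 200, 120, evi2_amplitude = 0.5)
  evi2 <- endmember_indices(list(cyc), g)$evi2
  wf <- wavelet_spectrum(evi2, g)
  in_year <- wf$centers[wf$centers$day >= 1 & wf$centers$day <= 365, ]
  expect_equal(nrow(in_year), 1)
  expect_lte(abs(in_year$day - 200), 16)
  expect_equal(cropping_index(wf), 1L)
})

test_that("two well-separated cycles give two centres with disjoint skeletons", {
  g <- daily_grid()
  evi2 <- endmember_indices(default_pattern_cycles(255), g)$evi2
  wf <- wavelet_spectrum(evi2, g)
  ce <- wf$centers[wf$centers$scale <= 170, ]
  expect_equal(nrow(ce), 2)
  expect_lt(ce$day[1] + ce$skeleton_width[1] / 2,
            ce$day[2] - ce$skeleton_width[2] / 2)
  expect_equal(cropping_index(wf), 2L)
})

test_that("intensity matches truth on noise-free patterns, capped at 3", {
  truth_int <- c("0" = 0, "14" = 1, "15" = 1, "16" = 1, "17" = 1,
                 "245" = 2, "246" = 2, "255" = 2, "256" = 2, "277" = 2,
                 "3" = 3)
  for (code in names(truth_int)) {
    idx <- preprocess_series(simulate_pixel(as.integer(code), seed = 1))
    it <- cropping_index(wavelet_spectrum(idx$evi2, idx$grid))
    expect_equal(it, unname(truth_int[code]), label = paste("code", code))
    expect_lte(it, 3L)
  }
})

test_that("intensity is invariant to EVI2 offset and positive scaling", {
  idx <- preprocess_series(simulate_pixel(246, seed = 6))
  base <- cropping_index(wavelet_spectrum(idx$evi2, idx$grid))
  shifted <- cropping_index(wavelet_spectrum(idx$evi2 + 0.2, idx$grid))
  scaled <- cropping_index(wavelet_spectrum(idx$evi2 * 1.4, idx$grid))
  expect_equal(shifted, base)
  expect_equal(scaled, base)
})

test_that("wavelet count equals brute-force prominent-peak count, noise-free", {
  codes <- pattern_code_table()$code
  for (k in seq_len(22)) {
    code <- codes[(k - 1) %% length(codes) + 1]
    idx <- preprocess_series(simulate_pixel(code, seed = 100 + k))
    wl <- cropping_index(wavelet_spectrum(idx$evi2, idx$grid))
    bf <- oracle_intensity(idx$evi2, idx$grid)
    expect_equal(wl, bf, label = paste("code", code, "seed", 100 + k))
  }
})

test_that("intensity stays accurate under noise and gaps", {
  codes <- pattern_code_table()$code
  truth_int <- c(0, 1, 1, 1, 1, 2, 2, 2, 2, 2, 3)
  hits <- 0; n <- 0
  set.seed(20)
  for (k in seq_len(44)) {
    j <- (k - 1) %% length(codes) + 1
    px <- simulate_pixel(codes[j], purity = runif(1, 0.5, 1),
                         noise_sd = 0.02, gap_rate = 0.2, seed = 300 + k)
    idx <- preprocess_series(px)
    if (idx$unprocessable) next
    it <- cropping_index(wavelet_spectrum(idx$evi2, idx$grid))
    n <- n + 1
    if (it == truth_int[j]) hits <- hits + 1
  }
  expect_gte(hits / n, 0.95)
})

test_that("season windows are ordered, disjoint, and anchored on peaks", {
  idx <- preprocess_series(simulate_pixel(246, seed = 2))
  seas <- segment_seasons(idx$evi2, 2, idx$grid)
  expect_equal(nrow(seas), 2)
  expect_true(all(seas$start < seas$tillering &
                    seas$tillering < seas$heading &
                    seas$heading < seas$harvest))
  expect_lt(seas$harvest[1], seas$start[2] + 1)
  # single symmetric cycle peaking day 200
  g <- daily_grid()
  evi2 <- endmember_indices(list(crop_cycle("other", 140, 200, 120)), g)$evi2
  s1 <- segment_seasons(evi2, 1, g)
  expect_lte(abs(s1$heading - 200), 1)
  expect_equal(nrow(segment_seasons(evi2, 0, g)), 0)
})

test_that("plateau maxima break ties to the earliest day", {
  g <- 1:200
  x <- c(seq(0, 0.6, length.out = 90), rep(0.6, 20),
         seq(0.6, 0, length.out = 90))
  s <- segment_seasons(x, 1, g, min_amplitude = 0.1)
  expect_equal(s$heading, 90)  # plateau spans days 90..111; earliest wins
})
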