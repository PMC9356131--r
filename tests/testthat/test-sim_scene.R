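test_that("simulate_pixel is deterministic and leaves the RNG untouched", {
  set.seed(123); before <- runif(1)
  set.seed(123)
  a <- simulate_pixel(246, purity = 0.7, noise_sd = 0.02, gap_rate = 0.3,
                      seed = 11)
  mid <- runif(1)
  b <- simulate_pixel(246, purity = 0.7, noise_sd = 0.02, gap_rate = 0.3,
                      seed = 11)
  expect_identical(a[], b[])
  expect_equal(before, mid)  # global RNG stream restored
})

test_that("linear mixing: purity interpolates exactly between endmembers", {
  p1 <- simulate_pixel(15, purity = 1, seed = 3)
  p0 <- simulate_pixel(15, purity = 0, seed = 3)
  pm <- simulate_pixel(15, purity = 0.37, seed = 3)
  for (b in c("rho_red", "rho_nir", "rho_swir6", "rho_swir7")) {
    expect_equal(pm[[b]], 0.37 * p1[[b]] + 0.63 * p0[[b]], tolerance = 1e-12)
    # purity 0 equals the constant background endmember
    expect_equal(diff(range(p0[[b]])), 0, tolerance = 1e-12)
  }
})

test_that("rice flood signature survives the index round trip", {
  cyc <- list(crop_cycle("rice", 130, 195, 130, flood_lswi_level = 0.25))
  px <- simulate_pixel(15, cycles = cyc, seed = 5)
  ind <- compute_indices(px)
  seas <- segment_seasons(preprocess_series(px)$evi2, 1)
  sel <- px$dates >= seas$tillering[1] & px$dates <= seas$heading[1]
  expect_gte(min(ind$lswi[sel]), 0.25 - 0.01)
})

test_that("indices derived from simulated bands equal the generator targets", {
  for (code in c(15, 16, 14, 246)) {
    px <- simulate_pixel(code, seed = 2)
    tgt <- endmember_indices(default_pattern_cycles(code), px$dates)
    ind <- compute_indices(px)
    expect_equal(ind$evi2, tgt$evi2, tolerance = 1e-6)
    expect_equal(ind$lswi, tgt$lswi, tolerance = 1e-6)
    expect_equal(ind$nmdi, tgt$nmdi, tolerance = 1e-6)
  }
})

test_that("reflectance stays within [0,1] across the documented ranges", {
  for (code in pattern_code_table()$code) {
    for (p in c(0, 0.4, 1)) {
      px <- simulate_pixel(code, purity = p, noise_sd = 0.05, seed = 7)
      for (b in c("rho_red", "rho_nir", "rho_swir6", "rho_swir7")) {
        v <- px[[b]][px$valid]
        expect_true(all(v >= 0 & v <= 1))
      }
    }
  }
})

test_that("cycle/pattern mismatches are rejected with explicit messages", {
  expect_error(simulate_pixel(255, cycles = default_pattern_cycles(15)),
               "2 growing cycle")
  expect_error(simulate_pixel(246, cycles = default_pattern_cycles(255)),
               "do not match pattern code")
  expect_error(simulate_pixel(99), "unknown pattern code")
  expect_error(crop_cycle("rice", 200, 150, 100), "sowing_doy")
})

test_that("simulate_scene reproduces truth, honours gap_rate, is deterministic", {
  pm <- matrix(15L, 2, 2)
  sc <- simulate_scene(scene_config(pm, seed = 1))
  expect_identical(sc$truth, pm)

  cfg <- scene_config(all_codes_map(10), noise_sd = 0, gap_rate = 0.3,
                      seed = 42)
  s1 <- simulate_scene(cfg)
  s2 <- simulate_scene(cfg)
  expect_identical(s1$refl, s2$refl)
  expect_identical(s1$valid, s2$valid)
  # mean masked fraction ~ Binomial(n composites, 0.3)
  expect_equal(mean(!s1$valid), 0.3, tolerance = 0.05)

  expect_error(scene_config(matrix(c(15, 999), 1, 2)), "invalid pattern code")
})

test_that("per-pixel sub-seeds are position-stable", {
  sc <- simulate_scene(scene_config(matrix(15L, 2, 3),
                                    noise_sd = 0.02, seed = 9))
  px <- simulate_pixel(15, noise_sd = 0.02,
                       seed = phenocrop:::sub_seed(9, 2, 3))
  expect_equal(sc$refl[2, 3, , 2], px$rho_nir)
})
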