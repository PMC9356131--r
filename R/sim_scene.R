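#' 8-day composite calendar in the mapping-year coordinate
#'
#' Composite start days for the mapping year plus roughly 90 days of padding
#' on either side (the padding carries winter-wheat autumn growth and keeps
#' the smoother well-conditioned at the year edges). Composites follow the
#' MODIS 8-day convention: within each calendar year they start at day 1, 9,
#' ..., 361, and each composite is timestamped at its first day.
#'
#' @return Integer vector of composite start days (length 70): days in the
#'   previous year are negative, days in the following year exceed 365.
#' @export
composite_days <- function() {
  c(seq(273L, 361L, by = 8L) - 365L,  # previous-year padding
    seq(1L, 361L, by = 8L),           # mapping year (46 composites)
    seq(1L, 89L, by = 8L) + 365L)     # following-year padding
}

#' Daily grid spanned by the simulated composites
#' @return Integer vector of consecutive days covering the padded year.
#' @export
daily_grid <- function() {
  d <- composite_days()
  seq(min(d), max(d) + 7L)
}

#' Back-solve band reflectances from index trajectories
#'
#' Given EVI2/LSWI/NMDI target values, constructs red, NIR, SWIR(1640 nm)
#' and SWIR(2130 nm) reflectances that reproduce those indices exactly under
#' the standard index formulas. Red reflectance follows a canopy-coupled
#' profile (bright bare soil ~0.15 declining to ~0.04 under full canopy,
#' linear in EVI2) unless a fixed value is supplied; the remaining three
#' bands are then solved in sequence: NIR from EVI2, SWIR6 from LSWI,
#' SWIR7 from NMDI. One consistent solution of an under-determined system
#' (4 bands, 3 indices); it requires NMDI >= LSWI, which the index model
#' guarantees.
#'
#' @param evi2,lswi,nmdi numeric vectors of equal length.
#' @param rho_red optional fixed red reflectance; default NULL uses the
#'   canopy-coupled profile.
#' @return A list with numeric vectors `rho_red`, `rho_nir`, `rho_swir6`,
#'   `rho_swir7`, all within \[0, 1\].
#' @export
bands_from_indices <- function(evi2, lswi, nmdi, rho_red = NULL) {
  if (any(evi2 >= 2.5)) stop2("bands_from_indices: EVI2 must be < 2.5")
  r <- if (is.null(rho_red)) {
    pmin(pmax(0.15 - 0.11 * (evi2 - 0.10) / 0.85, 0.04), 0.15)
  } else rep(rho_red, length.out = length(evi2))
  n <- (2.5 * r + evi2 * (2.4 * r + 1)) / (2.5 - evi2)
  s6 <- n * (1 - lswi) / (1 + lswi)
  d <- n * (1 - nmdi) / (1 + nmdi)
  s7 <- s6 - d
  list(rho_red = unname(clamp01(r)), rho_nir = unname(clamp01(n)),
       rho_swir6 = unname(clamp01(s6)), rho_swir7 = unname(clamp01(s7)))
}

.band_names <- c("rho_red", "rho_nir", "rho_swir6", "rho_swir7")

.pattern_intensity <- function(code) {
  if (code == 0) 0L else if (code == 3) 3L else if (code < 100) 1L else 2L
}

# crop digit -> simulator crop class (wheat types share digit 6)
.digit_crop <- c("4" = "maize", "5" = "rice", "6" = "wheat", "7" = "other")

.cycle_crop_digit <- function(crop) {
  switch(crop, maize = 4L, rice = 5L, wheat_winter = 6L, wheat_spring = 6L,
         other = 7L)
}

# Check that the supplied cycles are compatible with the pattern code:
# matching cycle count, and for single/double codes matching crop digits.
.check_cycles_pattern <- function(code, cycles) {
  intensity <- .pattern_intensity(code)
  if (length(cycles) != intensity)
    stop2("simulate_pixel: pattern code ", code, " implies ", intensity,
          " growing cycle(s) but ", length(cycles), " were supplied")
  if (code %in% c(0L, 3L)) return(invisible(TRUE))
  digits <- sort(vapply(cycles, function(cy) .cycle_crop_digit(cy$crop),
                        integer(1)))
  want <- if (code < 100) code %% 10L else c((code %/% 10L) %% 10L,
                                             code %% 10L)
  want <- sort(want)
  # staple + other doubles are coded 277 with the staple in a sidecar
  if (code == 277L) want <- digits
  if (!identical(digits, as.integer(want)))
    stop2("simulate_pixel: cycle crops (digits ",
          paste(digits, collapse = ","), ") do not match pattern code ", code)
  invisible(TRUE)
}

#' Simulate one pixel's 8-day reflectance time series
#'
#' Generates a MODIS-like 4-band surface-reflectance series for one pixel of
#' known cropping pattern. The pure-crop endmember is built in index space
#' from double-logistic canopy cycles ([endmember_indices()]), back-solved
#' to band reflectances, linearly mixed with a constant non-crop background
#' endmember according to the pixel's cropland fraction, and degraded with
#' Gaussian band noise and randomly masked (cloudy) composites.
#'
#' @param pattern cropping-pattern code giving the pixel's ground truth.
#' @param cycles list of [crop_cycle()]; defaults to the standard calendar
#'   for `pattern` ([default_pattern_cycles()]).
#' @param purity cropland fraction in \[0, 1\] (linear mixing weight of the
#'   crop endmember).
#' @param noise_sd standard deviation of additive Gaussian reflectance
#'   noise, per band and composite.
#' @param gap_rate probability that a composite is masked invalid (cloud).
#' @param seed integer; identical inputs and seed give identical output.
#' @return An object of class `reflectance_series`: a list with `dates`
#'   (composite start days), the four band vectors, `valid`, and a `truth`
#'   attribute recording pattern, cycles and purity.
#' @export
#' @examples
#' px <- simulate_pixel(15, seed = 1)
#' head(as.data.frame(px))
simulate_pixel <- function(pattern, cycles = default_pattern_cycles(pattern),
                           purity = 1, noise_sd = 0, gap_rate = 0, seed = 1L) {
  pattern <- as.integer(pattern)
  if (is.na(match(pattern, pattern_code_table()$code)))
    stop2("simulate_pixel: unknown pattern code ", pattern)
  if (purity < 0 || purity > 1) stop2("simulate_pixel: purity must be in [0,1]")
  if (gap_rate < 0 || gap_rate >= 1)
    stop2("simulate_pixel: gap_rate must be in [0,1)")
  .check_cycles_pattern(pattern, cycles)

  days <- composite_days()
  idx <- endmember_indices(cycles, days)
  crop <- bands_from_indices(idx$evi2, idx$lswi, idx$nmdi)
  bgi <- .background_indices
  bg <- bands_from_indices(rep(bgi[["evi2"]], length(days)),
                           rep(bgi[["lswi"]], length(days)),
                           rep(bgi[["nmdi"]], length(days)))

  old <- if (exists(".Random.seed", globalenv())) get(".Random.seed", globalenv())
  on.exit(if (!is.null(old)) assign(".Random.seed", old, globalenv()))
  set.seed(as.integer(seed))

  # observation noise: the dominant error in composited surface reflectance
  # is the atmospheric-correction residual, which is strongly correlated
  # across bands of the same composite; a smaller independent sensor/BRDF
  # component completes the per-band standard deviation noise_sd
  rho_spec <- 0.8
  common <- if (noise_sd > 0)
    stats::rnorm(length(days), 0, noise_sd * sqrt(rho_spec)) else 0
  bands <- lapply(.band_names, function(b) {
    x <- purity * crop[[b]] + (1 - purity) * bg[[b]]
    if (noise_sd > 0)
      x <- clamp01(x + common +
                     stats::rnorm(length(x), 0, noise_sd * sqrt(1 - rho_spec)))
    x
  })
  names(bands) <- .band_names
  valid <- if (gap_rate > 0) stats::runif(length(days)) >= gap_rate
           else rep(TRUE, length(days))
  for (b in .band_names) bands[[b]][!valid] <- NA_real_

  structure(
    c(list(dates = days), bands, list(valid = valid)),
    truth = list(pattern = pattern, cycles = cycles, purity = purity),
    class = "reflectance_series")
}

#' @export
as.data.frame.reflectance_series <- function(x, ...) {
  data.frame(date = x$dates, rho_red = x$rho_red, rho_nir = x$rho_nir,
             rho_swir6 = x$rho_swir6, rho_swir7 = x$rho_swir7,
             valid = x$valid)
}

#' @export
print.reflectance_series <- function(x, ...) {
  tr <- attr(x, "truth")
  cat("<reflectance_series> ", length(x$dates), " composites, ",
      sum(x$valid), " valid; pattern ", tr$pattern,
      ", purity ", tr$purity, "\n", sep = "")
  invisible(x)
}

#' Scene configuration for the simulator
#'
#' @param pattern_map integer matrix of ground-truth pattern codes.
#' @param purity_map numeric matrix of cropland fractions in \[0, 1\]
#'   (defaults to all 1).
#' @param noise_sd,gap_rate,seed as in [simulate_pixel()].
#' @return An object of class `scene_config`.
#' @export
scene_config <- function(pattern_map, purity_map = NULL, noise_sd = 0,
                         gap_rate = 0, seed = 1L) {
  pattern_map <- as.matrix(pattern_map)
  bad <- which(!(pattern_map %in% pattern_code_table()$code))
  if (length(bad)) {
    cells <- arrayInd(bad, dim(pattern_map))
    stop2("scene_config: invalid pattern code(s) at cell(s) ",
          paste(utils::head(paste(cells[, 1], cells[, 2], sep = ","), 10),
                collapse = "; "))
  }
  if (is.null(purity_map))
    purity_map <- matrix(1, nrow(pattern_map), ncol(pattern_map))
  purity_map <- as.matrix(purity_map)
  if (!all(dim(purity_map) == dim(pattern_map)))
    stop2("scene_config: purity_map and pattern_map dimensions differ")
  if (any(purity_map < 0 | purity_map > 1))
    stop2("scene_config: purity_map values must lie in [0, 1]")
  if (gap_rate < 0 || gap_rate >= 1)
    stop2("scene_config: gap_rate must be in [0, 1)")
  structure(list(pattern_map = pattern_map, purity_map = purity_map,
                 noise_sd = noise_sd, gap_rate = gap_rate,
                 seed = as.integer(seed)),
            class = "scene_config")
}

#' Simulate a whole scene
#'
#' Runs [simulate_pixel()] for every cell of the configured pattern map,
#' with per-pixel sub-seeds derived deterministically from the scene seed
#' and the pixel position (so results do not depend on traversal order).
#'
#' @param config a [scene_config()].
#' @return An object of class `pheno_scene`: a list with `refl` (4-d array
#'   rows x cols x composites x bands), `valid` (3-d logical array), `dates`,
#'   `truth` (the pattern map), `purity` (the fraction map) and `config`.
#' @export
simulate_scene <- function(config) {
  stopifnot(inherits(config, "scene_config"))
  pm <- config$pattern_map
  nr <- nrow(pm); nc <- ncol(pm)
  days <- composite_days()
  nt <- length(days)
  refl <- array(NA_real_, c(nr, nc, nt, 4),
                dimnames = list(NULL, NULL, NULL, .band_names))
  valid <- array(NA, c(nr, nc, nt))
  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      px <- simulate_pixel(pm[i, j], purity = config$purity_map[i, j],
                           noise_sd = config$noise_sd,
                           gap_rate = config$gap_rate,
                           seed = sub_seed(config$seed, i, j))
      for (b in seq_along(.band_names))
        refl[i, j, , b] <- px[[.band_names[b]]]
      valid[i, j, ] <- px$valid
    }
  }
  structure(list(refl = refl, valid = valid, dates = days, truth = pm,
                 purity = config$purity_map, config = config),
            class = "pheno_scene")
}

#' Extract one pixel's series from a simulated scene
#' @param scene a `pheno_scene`.
#' @param row,col pixel position.
#' @return A `reflectance_series`.
#' @export
scene_pixel <- function(scene, row, col) {
  stopifnot(inherits(scene, "pheno_scene"))
  bands <- lapply(seq_along(.band_names),
                  function(b) scene$refl[row, col, , b])
  names(bands) <- .band_names
  structure(
    c(list(dates = scene$dates), bands,
      list(valid = as.logical(scene$valid[row, col, ]))),
    truth = list(pattern = scene$truth[row, col],
                 purity = scene$purity[row, col]),
    class = "reflectance_series")
}

#' @export
print.pheno_scene <- function(x, ...) {
  cat("<pheno_scene> ", nrow(x$truth), "x", ncol(x$truth), " pixels, ",
      dim(x$refl)[3], " composites, noise_sd=", x$config$noise_sd,
      ", gap_rate=", x$config$gap_rate, ", seed=", x$config$seed, "\n",
      sep = "")
  cat("pattern codes:",
      paste(names(table(x$truth)), "(", as.vector(table(x$truth)), ")",
            sep = "", collapse = " "), "\n")
  invisible(x)
}
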