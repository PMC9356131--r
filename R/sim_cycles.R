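#' Growing-cycle parameters for the scene simulator
#'
#' Describes one crop growing cycle of a simulated pixel: when it is sown,
#' when its canopy peaks, how long it lasts, and the index-space signatures
#' that the phenological classifiers key on (flood-period LSWI for paddy
#' rice, the flowering NMDI excursion for maize).
#'
#' Day-of-year values use the mapping-year coordinate: day 1 is 1 January of
#' the mapping year, negative days fall in the preceding year (winter wheat
#' is sown there), days above 365 in the following year. Leap days are
#' ignored throughout.
#'
#' @param crop one of `"rice"`, `"wheat_winter"`, `"wheat_spring"`,
#'   `"maize"`, `"other"`.
#' @param sowing_doy day the cycle starts (field preparation / sowing).
#' @param peak_doy day of maximum canopy (taken as the heading date).
#' @param season_length days from sowing to harvest.
#' @param evi2_amplitude peak EVI2 of the cycle above the bare-soil
#'   baseline, in (0, 1).
#' @param flood_lswi_level rice only: LSWI plateau maintained from
#'   transplanting until heading while the paddy is flooded.
#' @param nmdi_flowering_rise maize only: size of the NMDI rise (and
#'   symmetric fall) across the flowering window centred on `peak_doy`.
#' @return An object of class `crop_cycle`.
#' @export
#' @examples
#' crop_cycle("rice", sowing_doy = 130, peak_doy = 195, season_length = 130)
crop_cycle <- function(crop, sowing_doy, peak_doy, season_length,
                       evi2_amplitude = 0.65,
                       flood_lswi_level = 0.32,
                       nmdi_flowering_rise = 0.18) {
  crop <- match.arg(crop,
                    c("rice", "wheat_winter", "wheat_spring", "maize", "other"))
  if (!(sowing_doy < peak_doy))
    stop2("crop_cycle: sowing_doy must precede peak_doy")
  if (!(season_length > 0))
    stop2("crop_cycle: season_length must be positive")
  if (!(evi2_amplitude > 0 && evi2_amplitude < 1))
    stop2("crop_cycle: evi2_amplitude must lie in (0, 1)")
  structure(
    list(crop = crop, sowing_doy = sowing_doy, peak_doy = peak_doy,
         season_length = season_length, evi2_amplitude = evi2_amplitude,
         flood_lswi_level = flood_lswi_level,
         nmdi_flowering_rise = nmdi_flowering_rise),
    class = "crop_cycle")
}

# Baseline (non-crop / bare-stubble) index levels of the crop endmember and
# the constant non-crop background endmember. The background is chosen so
# that no crop decision rule can fire on it: modest greenness, zero LSWI,
# high (dry-soil) NMDI with no flowering dynamics.
.index_baseline <- list(evi2 = 0.10, lswi = -0.05, nmdi = 0.60)
.background_indices <- c(evi2 = 0.15, lswi = 0.00, nmdi = 0.60)

# Normalized double-logistic canopy development curve on `days`, rising from
# 0 to 1 at the peak and back; inflection points at the midpoints between
# sowing/peak and peak/harvest.
.double_logistic <- function(days, sowing, peak, harvest) {
  t1 <- (sowing + peak) / 2
  t2 <- (peak + harvest) / 2
  r1 <- max((peak - sowing) / 8, 2)
  r2 <- max((harvest - peak) / 8, 2)
  g <- 1 / (1 + exp(-(days - t1) / r1)) - 1 / (1 + exp(-(days - t2) / r2))
  gmax <- max(g)
  if (gmax > 0) g / gmax else g
}

# Canopy curve for one cycle. Winter wheat is the one asymmetric case: an
# autumn establishment bump after sowing, a dormancy trough over winter, and
# the main spring green-up peaking at heading.
.cycle_canopy <- function(cycle, days) {
  harvest <- cycle$sowing_doy + cycle$season_length
  if (cycle$crop == "wheat_winter") {
    autumn_peak <- cycle$sowing_doy + 45
    autumn_end <- autumn_peak + 55
    spring_start <- cycle$peak_doy - 80
    g_aut <- .double_logistic(days, cycle$sowing_doy, autumn_peak, autumn_end)
    g_spr <- .double_logistic(days, spring_start, cycle$peak_doy, harvest)
    g <- g_spr + 0.35 * g_aut
    pmin(g, 1)
  } else {
    .double_logistic(days, cycle$sowing_doy, cycle$peak_doy, harvest)
  }
}

#' Daily endmember index trajectories for a set of growing cycles
#'
#' Builds the noise-free EVI2 / LSWI / NMDI trajectories of the pure-crop
#' endmember on an arbitrary day grid. This is the simulator's ground truth
#' in index space; band reflectances are back-solved from it so that the
#' index formulas recover these curves exactly.
#'
#' Signatures realized per crop: paddy rice holds LSWI at or above its
#' flood level from transplanting to heading while EVI2 rises (small
#' LSWI-to-EVI2 change ratio); maize superimposes a rise-then-fall NMDI
#' excursion across the flowering window (peak +/- 24 days); winter wheat
#' spans the year boundary with a dormancy trough between autumn
#' establishment and spring green-up. Vegetation lowers NMDI and raises
#' LSWI in proportion to canopy cover for every crop.
#'
#' @param cycles list of [crop_cycle()] objects (possibly empty = fallow).
#' @param days integer vector of days (mapping-year coordinate).
#' @return A list with numeric vectors `evi2`, `lswi`, `nmdi` on `days`.
#' @export
endmember_indices <- function(cycles, days) {
  base <- .index_baseline
  evi2 <- rep(base$evi2, length(days))
  lswi <- rep(base$lswi, length(days))
  nmdi <- rep(base$nmdi, length(days))
  for (cy in cycles) {
    g <- .cycle_canopy(cy, days)
    evi2 <- evi2 + cy$evi2_amplitude * g
    if (cy$crop == "rice") {
      # flooded paddy: LSWI plateau from transplanting through heading,
      # with only a shallow canopy-driven rise (small RCLE), draining
      # gradually after heading
      ramp <- sstep((days - (cy$sowing_doy - 5)) / 12) *
        (1 - sstep((days - (cy$peak_doy + 15)) / 30))
      lswi <- lswi + (cy$flood_lswi_level - base$lswi + 0.08 * g) * ramp
    } else {
      lswi <- lswi + 0.45 * g
    }
    nmdi <- nmdi - 0.06 * g
    if (cy$crop == "maize") {
      u <- (days - cy$peak_doy) / 40
      nmdi <- nmdi + cy$nmdi_flowering_rise * pmax(1 - abs(u), 0)
    }
  }
  evi2 <- pmin(evi2, 0.95)
  # keep NMDI >= LSWI so that SWIR2130 reflectance stays non-negative in
  # the band back-solve (see bands_from_indices)
  nmdi <- pmax(nmdi, lswi + 0.02)
  list(evi2 = evi2, lswi = lswi, nmdi = nmdi)
}

#' Default growing-cycle calendars for each cropping-pattern code
#'
#' Returns the simulator's standard cycle parameters for a pattern code:
#' the crop sequence matching the code's digits, with sowing/peak/harvest
#' dates laid out as in the corresponding real cropping systems (winter
#' wheat sown the previous autumn and heading in mid-April; early/late
#' double rice; summer maize after a winter or early-season crop; a spring
#' cycle plus an autumn cycle for generic double cropping). Triple cropping
#' carries no crop composition in the code and is simulated as three
#' generic cycles.
#'
#' @param code a cropping-pattern code (see [decode_pattern()]).
#' @return A list of [crop_cycle()] objects (empty for fallow).
#' @export
default_pattern_cycles <- function(code) {
  code <- as.integer(code)
  switch(as.character(code),
    "0" = list(),
    "14" = list(crop_cycle("maize", 120, 210, 140)),
    "15" = list(crop_cycle("rice", 130, 195, 130)),
    "16" = list(crop_cycle("wheat_winter", -80, 115, 240)),
    "17" = list(crop_cycle("other", 120, 190, 130, evi2_amplitude = 0.6)),
    "245" = list(crop_cycle("rice", 90, 150, 110, evi2_amplitude = 0.6),
                 crop_cycle("maize", 205, 265, 110, evi2_amplitude = 0.6)),
    "246" = list(crop_cycle("wheat_winter", -80, 115, 240),
                 crop_cycle("maize", 165, 225, 115, evi2_amplitude = 0.6)),
    "255" = list(crop_cycle("rice", 90, 150, 110, evi2_amplitude = 0.6),
                 crop_cycle("rice", 205, 260, 105, evi2_amplitude = 0.6)),
    "256" = list(crop_cycle("wheat_winter", -80, 115, 240),
                 crop_cycle("rice", 170, 230, 110, evi2_amplitude = 0.6)),
    "277" = list(crop_cycle("other", 115, 170, 100, evi2_amplitude = 0.55),
                 crop_cycle("other", 220, 275, 100, evi2_amplitude = 0.55)),
    "3" = list(crop_cycle("other", 30, 80, 95, evi2_amplitude = 0.55),
               crop_cycle("other", 140, 190, 95, evi2_amplitude = 0.55),
               crop_cycle("other", 250, 300, 95, evi2_amplitude = 0.55)),
    stop2("default_pattern_cycles: unknown pattern code ", code)
  )
}
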