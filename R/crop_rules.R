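# Phenological metrics per growing season and the purity-stratified
# decision rules labeling each season rice, wheat, maize or other.

#' Decision-rule thresholds
#'
#' The stratified thresholds of the crop decision rules. `theta2` (rice
#' RCLE ceiling), `theta3` (wheat EVE floor) and `theta5` (maize RCPN
#' floor) vary by pixel-purity stratum -- rice's ceiling loosens and the
#' wheat/maize floors drop as mixing dilutes the crop signal -- while
#' `theta1` (flood LSWI floor) and `theta4` (wheat EVL floor) are common
#' to all strata. `sigma` stabilizes the RCPN denominator.
#'
#' @param theta1 LSWI minimum for the rice flood signal.
#' @param theta2 named triple (pure, moderate, serious): RCLE must stay
#'   below this for rice.
#' @param theta3 named triple: EVE must exceed this for wheat.
#' @param theta4 EVL floor for wheat.
#' @param theta5 named triple: RCPN must exceed this for maize.
#' @param sigma small positive stabilizer in the RCPN denominator.
#' @return A list of class `threshold_config`.
#' @export
#' @examples
#' threshold_config()
threshold_config <- function(theta1 = 0.1,
                             theta2 = c(pure = 0.42, moderate = 0.52,
                                        serious = 0.62),
                             theta3 = c(pure = 0.32, moderate = 0.24,
                                        serious = 0.16),
                             theta4 = 0.12,
                             theta5 = c(pure = 0.45, moderate = 0.35,
                                        serious = 0.25),
                             sigma = 0.01) {
  strata <- c("pure", "moderate", "serious")
  for (nm in c("theta2", "theta3", "theta5")) {
    v <- get(nm)
    if (length(v) != 3) stop2("threshold_config: ", nm, " needs 3 values")
    if (is.null(names(v)) || !all(strata %in% names(v)))
      names(v) <- strata
    assign(nm, v[strata])
  }
  if (sigma <= 0) stop2("threshold_config: sigma must be positive")
  structure(list(theta1 = theta1, theta2 = theta2, theta3 = theta3,
                 theta4 = theta4, theta5 = theta5, sigma = sigma),
            class = "threshold_config")
}

.day_at <- function(values, grid, day) values[match(round(day), grid)]

#' Rice metrics: flood-period LSWI and the RCLE ratio
#'
#' Over the tillering-to-heading window, flooded paddy keeps LSWI high
#' (above the flood floor) and nearly flat while EVI2 rises steeply, so
#' the Ratio of Change amplitude of LSWI to EVI2,
#' `RCLE = (LSWI_max - LSWI_min) / (EVI2_heading - EVI2_tillering)`,
#' is small for rice and large for other crops.
#'
#' @param lswi_daily,evi2_daily daily index trajectories on `grid`.
#' @param window one row of [segment_seasons()] output.
#' @param grid daily grid.
#' @return A list with `lswi_min`, `lswi_max`, `rcle` (NA when the EVI2
#'   rise is non-positive, in which case the season cannot be rice).
#' @export
rice_metrics <- function(lswi_daily, evi2_daily, window, grid = daily_grid()) {
  if (!(window$tillering < window$heading))
    stop2("rice_metrics: tillering must precede heading")
  sel <- grid >= window$tillering & grid <= window$heading
  lmin <- min(lswi_daily[sel]); lmax <- max(lswi_daily[sel])
  rise <- .day_at(evi2_daily, grid, window$heading) -
    .day_at(evi2_daily, grid, window$tillering)
  rcle <- if (is.na(rise) || rise <= 0) NA_real_ else (lmax - lmin) / rise
  list(lswi_min = lmin, lswi_max = lmax, rcle = rcle)
}

#' Wheat metrics: EVI2 variation before and after heading
#'
#' `EVE = (EVI2_heading - EVI2_seedling) + (EVI2_max1 - EVI2_min1)` over
#' the early growth stage (seedling to heading) and
#' `EVL = (EVI2_heading - EVI2_harvesting) + (EVI2_max2 - EVI2_min2)` over
#' the late stage (heading to harvest). Winter wheat scores high on both:
#' the dormancy trough makes the early-stage range large, and the sharp
#' post-heading senescence makes the late-stage drop large. The seedling
#' date is `heading - early_growing_length` from the phenology calendar.
#'
#' @param evi2_daily daily EVI2 on `grid`.
#' @param calendar a [wheat_calendar()] giving heading date and early
#'   growing length.
#' @param harvest_doy harvest date (from season segmentation).
#' @param grid daily grid.
#' @return A list with `eve`, `evl` (both NA, season not classifiable as
#'   wheat, when the windows fall outside the series span).
#' @export
wheat_metrics <- function(evi2_daily, calendar, harvest_doy,
                          grid = daily_grid()) {
  heading <- calendar$heading_doy
  seedling <- heading - calendar$early_growing_length
  if (seedling < min(grid) || harvest_doy > max(grid) ||
      !(seedling < heading) || !(heading < harvest_doy))
    return(list(eve = NA_real_, evl = NA_real_,
                reason = "wheat windows outside series span"))
  early <- grid >= seedling & grid <= heading
  late <- grid >= heading & grid <= harvest_doy
  e_head <- .day_at(evi2_daily, grid, heading)
  eve <- (e_head - .day_at(evi2_daily, grid, seedling)) +
    (max(evi2_daily[early]) - min(evi2_daily[early]))
  evl <- (e_head - .day_at(evi2_daily, grid, harvest_doy)) +
    (max(evi2_daily[late]) - min(evi2_daily[late]))
  list(eve = eve, evl = evl, reason = NULL)
}

#' Maize metric: cumulative NMDI slope ratio over flowering
#'
#' Maize leaf moisture rises then falls across the flowering stage, so its
#' NMDI shows a rise-then-fall excursion that other crops lack. With the
#' flowering window split at its midpoint into early and late halves,
#' `P_x` the sum of positive day-to-day NMDI differences and `N_x` the sum
#' of absolute negative differences in half `x`,
#' `RCPN = (P_early + P_late) * N_late / (N_early + N_late + sigma) * 100`.
#' A flat or monotone NMDI yields 0.
#'
#' @param nmdi_daily daily NMDI on `grid`.
#' @param flowering_window two days (start, end); the pipeline builds it
#'   as heading +/- 36 days by default.
#' @param sigma denominator stabilizer.
#' @param grid daily grid.
#' @return The RCPN value (scalar).
#' @export
maize_metrics <- function(nmdi_daily, flowering_window, sigma = 0.01,
                          grid = daily_grid()) {
  lo <- max(flowering_window[1], min(grid))
  hi <- min(flowering_window[2], max(grid))
  if (hi <= lo) stop2("maize_metrics: empty flowering window")
  mid <- (lo + hi) / 2
  sel_e <- grid >= lo & grid <= mid
  sel_l <- grid >= mid & grid <= hi
  slopes <- function(sel) {
    d <- diff(nmdi_daily[sel])
    c(P = sum(pmax(d, 0)), N = sum(pmax(-d, 0)))
  }
  e <- slopes(sel_e); l <- slopes(sel_l)
  unname((e["P"] + l["P"]) * l["N"] / (e["N"] + l["N"] + sigma) * 100)
}

#' Wheat phenology calendar
#'
#' @param heading_doy wheat heading date (day of mapping year).
#' @param early_growing_length days from seedling establishment to heading.
#' @param wheat_type `"winter"` or `"spring"`.
#' @return A list of class `wheat_calendar`.
#' @export
wheat_calendar <- function(heading_doy, early_growing_length,
                           wheat_type = c("winter", "spring")) {
  wheat_type <- match.arg(wheat_type)
  if (early_growing_length <= 0)
    stop2("wheat_calendar: early_growing_length must be positive")
  structure(list(heading_doy = heading_doy,
                 early_growing_length = early_growing_length,
                 wheat_type = wheat_type),
            class = "wheat_calendar")
}

#' Estimate the wheat calendar from a trend surface
#'
#' Planar (linear two-predictor) trend surfaces give the expected heading
#' date and early growing length at a site: latitude and altitude for
#' winter wheat, latitude and accumulated temperature above 5 degrees C
#' for spring wheat. Coefficients come from configuration; the defaults
#' are intercept-only surfaces matching the simulator's declared calendar
#' (heading day 115, early growing length 160 for winter wheat; day 170
#' and 80 for spring wheat). Out-of-domain predictors are clamped with a
#' warning.
#'
#' @param latitude degrees north.
#' @param altitude metres (winter wheat predictor).
#' @param accum_temp accumulated temperature above 5 C (spring wheat
#'   predictor).
#' @param wheat_type `"winter"` or `"spring"`.
#' @param coef named list of two coefficient triples
#'   `heading = c(intercept, b_lat, b_second)` and `egl = c(...)`, where
#'   the second predictor is altitude (winter) or accumulated temperature
#'   (spring).
#' @param domain list of predictor ranges used for clamping.
#' @return A [wheat_calendar()].
#' @export
estimate_wheat_calendar <- function(latitude, altitude = 0, accum_temp = 0,
                                    wheat_type = c("winter", "spring"),
                                    coef = NULL,
                                    domain = list(latitude = c(18, 54),
                                                  altitude = c(0, 5000),
                                                  accum_temp = c(0, 6000))) {
  wheat_type <- match.arg(wheat_type)
  if (is.null(coef)) {
    coef <- if (wheat_type == "winter")
      list(heading = c(115, 0, 0), egl = c(160, 0, 0))
    else list(heading = c(170, 0, 0), egl = c(80, 0, 0))
  }
  clamp_warn <- function(x, rng, nm) {
    if (x < rng[1] || x > rng[2]) {
      warning("estimate_wheat_calendar: ", nm, " ", x,
              " outside domain [", rng[1], ", ", rng[2], "], clamped",
              call. = FALSE)
      min(max(x, rng[1]), rng[2])
    } else x
  }
  lat <- clamp_warn(latitude, domain$latitude, "latitude")
  second <- if (wheat_type == "winter")
    clamp_warn(altitude, domain$altitude, "altitude")
  else clamp_warn(accum_temp, domain$accum_temp, "accum_temp")
  plane <- function(b) b[1] + b[2] * lat + b[3] * second
  wheat_calendar(plane(coef$heading), plane(coef$egl), wheat_type)
}

#' Classify one growing season
#'
#' Applies the three crop decision rules with the purity stratum's
#' threshold column:
#' rice if `LSWI_min > theta1` and `RCLE < theta2`;
#' wheat if `EVE > theta3` and `EVL > theta4`;
#' maize if `RCPN > theta5`.
#' When several rules fire, the label with the largest relative margin
#' (metric minus threshold, scaled by the threshold; the minimum margin
#' over a rule's two conditions) wins, with the deterministic ordering
#' rice, wheat, maize on exact ties. No rule fired gives `"other"`.
#'
#' @param metrics list with `lswi_min`, `rcle`, `eve`, `evl`, `rcpn`
#'   (NA allowed; an NA metric simply cannot fire its rule).
#' @param stratum `"pure"`, `"moderate"` or `"serious"`.
#' @param thresholds a [threshold_config()].
#' @return A list with `label` and the per-crop relative `margins`.
#' @export
#' @examples
#' classify_season(list(lswi_min = 0.25, rcle = 0.3, eve = NA, evl = NA,
#'                      rcpn = 0), "pure")
classify_season <- function(metrics, stratum,
                            thresholds = threshold_config()) {
  stratum <- match.arg(stratum, c("pure", "moderate", "serious"))
  th <- thresholds
  m <- metrics
  rice_m <- if (is.na(m$rcle %||% NA) || is.na(m$lswi_min %||% NA)) -Inf else
    min((m$lswi_min - th$theta1) / th$theta1,
        (th$theta2[[stratum]] - m$rcle) / th$theta2[[stratum]])
  wheat_m <- if (is.na(m$eve %||% NA) || is.na(m$evl %||% NA)) -Inf else
    min((m$eve - th$theta3[[stratum]]) / th$theta3[[stratum]],
        (m$evl - th$theta4) / th$theta4)
  maize_m <- if (is.na(m$rcpn %||% NA)) -Inf else
    (m$rcpn - th$theta5[[stratum]]) / th$theta5[[stratum]]
  margins <- c(rice = rice_m, wheat = wheat_m, maize = maize_m)
  fired <- margins > 0
  label <- if (!any(fired)) "other"
           else names(margins)[fired][which.max(margins[fired])]
  list(label = label, margins = margins)
}

#' Per-season metrics and labels for one pixel
#'
#' Computes the full metric set for each season window of a preprocessed
#' pixel and classifies it. The wheat rule is only evaluated for seasons
#' whose detected heading date falls within `wheat_gate_days` of the
#' calendar-predicted wheat heading date (the potential wheat window);
#' rice tillering/heading dates come from the season segmentation.
#'
#' @param idx an [preprocess_series()] result.
#' @param seasons a [segment_seasons()] data.frame.
#' @param stratum purity stratum.
#' @param thresholds a [threshold_config()].
#' @param calendar a [wheat_calendar()] for the scene.
#' @param flowering_half_width half-width (days) of the maize flowering
#'   window around heading.
#' @param wheat_gate_days tolerance around the calendar heading date.
#' @return A data.frame with one row per season: the metrics and `label`.
#' @export
classify_pixel_seasons <- function(idx, seasons, stratum,
                                   thresholds = threshold_config(),
                                   calendar = wheat_calendar(115, 160),
                                   flowering_half_width = 36,
                                   wheat_gate_days = 30) {
  if (!nrow(seasons))
    return(data.frame(lswi_min = numeric(0), rcle = numeric(0),
                      eve = numeric(0), evl = numeric(0), rcpn = numeric(0),
                      label = character(0), stringsAsFactors = FALSE))
  rows <- lapply(seq_len(nrow(seasons)), function(k) {
    w <- seasons[k, ]
    rm <- rice_metrics(idx$lswi, idx$evi2, w, idx$grid)
    rcpn <- maize_metrics(idx$nmdi,
                          c(w$heading - flowering_half_width,
                            w$heading + flowering_half_width),
                          sigma = thresholds$sigma, grid = idx$grid)
    if (abs(w$heading - calendar$heading_doy) <= wheat_gate_days) {
      wm <- wheat_metrics(idx$evi2, calendar, w$harvest, idx$grid)
    } else {
      wm <- list(eve = NA_real_, evl = NA_real_)
    }
    met <- list(lswi_min = rm$lswi_min, rcle = rm$rcle,
                eve = wm$eve, evl = wm$evl, rcpn = rcpn)
    cl <- classify_season(met, stratum, thresholds)
    data.frame(lswi_min = rm$lswi_min,
               rcle = rm$rcle %||% NA_real_,
               eve = wm$eve, evl = wm$evl, rcpn = rcpn,
               label = cl$label, stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
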