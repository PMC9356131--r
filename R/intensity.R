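# Cropping-intensity detection from wavelet spectra of the daily EVI2
# trajectory, plus growing-season segmentation for the crop classifiers.

# Local maxima of a numeric vector, earliest day on plateaus.
.local_maxima <- function(x) {
  n <- length(x)
  if (n < 3) return(integer(0))
  r <- rle(x)
  ends <- cumsum(r$lengths)
  starts <- ends - r$lengths + 1
  k <- length(r$values)
  out <- integer(0)
  for (i in seq_len(k)) {
    left_ok <- i > 1 && r$values[i - 1] < r$values[i]
    right_ok <- i < k && r$values[i + 1] < r$values[i]
    if (left_ok && right_ok) out <- c(out, starts[i])
  }
  out
}

# Topographic prominence of peak at index p: height above the higher of the
# two key saddles (minimum until the next strictly higher ground on each
# side; series edge counts as ground level of the minimum reached).
.prominence <- function(x, p) {
  left <- x[seq_len(p - 1)]
  right <- x[seq(p + 1, length(x))]
  lm <- if (any(left > x[p])) {
    j <- max(which(left > x[p])); min(x[j:p])
  } else min(c(left, x[p]))
  rm <- if (any(right > x[p])) {
    j <- p + min(which(right > x[p])); min(x[p:j])
  } else min(c(x[p], right))
  x[p] - max(lm, rm)
}

# Prominent, mutually separated peaks of a daily series. Peaks closer than
# merge_days keep only the more prominent one (a stressed crop's double
# peak counts once).
.prominent_peaks <- function(x, min_prominence, merge_days) {
  idx <- .local_maxima(x)
  if (!length(idx)) return(integer(0))
  prom <- vapply(idx, function(p) .prominence(x, p), numeric(1))
  keep <- prom >= min_prominence
  idx <- idx[keep]; prom <- prom[keep]
  if (!length(idx)) return(integer(0))
  ord <- order(prom, decreasing = TRUE)
  chosen <- integer(0)
  for (p in idx[ord]) {
    if (!length(chosen) || all(abs(chosen - p) >= merge_days))
      chosen <- c(chosen, p)
  }
  sort(chosen)
}

#' Continuous wavelet spectrum of a daily EVI2 series
#'
#' Mexican-hat continuous wavelet transform of the mean-centred daily EVI2
#' trajectory over a band of season-length scales, with detection of
#' "strong brightness centres" (local maxima of the positive spectrum
#' exceeding a relative power threshold), their skeleton widths (contiguous
#' above-threshold ridge extent in time at the centre's scale) and scale
#' intervals (contiguous above-threshold extent across scales at the
#' centre's day). The scale axis is expressed as the width of the wavelet's
#' positive lobe in days, which matches the duration of the canopy bump the
#' wavelet responds to most strongly.
#'
#' @param evi2_daily numeric daily EVI2 values on `grid`.
#' @param grid integer daily grid.
#' @param scales scale band in days (defaults to 30--240, step 10).
#' @param rel_power_threshold centres must exceed this fraction of the
#'   global spectrum maximum.
#' @param merge_days centres closer in time than this merge into one.
#' @return An object of class `wavelet_features`: the `power` matrix
#'   (time x scale), a `centers` data.frame (`day`, `scale`, `power`,
#'   `skeleton_width`, `scale_min`, `scale_max`), the `scales`, `grid`
#'   and the overall EVI2 `amplitude`.
#' @export
wavelet_spectrum <- function(evi2_daily, grid = daily_grid(),
                             scales = seq(30, 240, by = 10),
                             rel_power_threshold = 0.2, merge_days = 45) {
  stopifnot(length(evi2_daily) == length(grid), all(is.finite(evi2_daily)))
  x <- evi2_daily - mean(evi2_daily)
  n <- length(x)
  power <- matrix(0, n, length(scales))
  for (j in seq_along(scales)) {
    s <- scales[j] / 2           # positive lobe of the Mexican hat is 2s wide
    h <- ceiling(4 * s)
    u <- seq(-h, h) / s
    psi <- (1 - u^2) * exp(-u^2 / 2) / s  # L1-type scaling
    w <- stats::convolve(x, rev(psi), type = "open")[(h + 1):(h + n)]
    power[, j] <- pmax(w, 0)
  }
  pmax_all <- max(power)
  centers <- data.frame(day = integer(0), scale = numeric(0),
                        power = numeric(0), skeleton_width = numeric(0),
                        scale_min = numeric(0), scale_max = numeric(0))
  if (pmax_all > 0) {
    thr <- rel_power_threshold * pmax_all
    cand <- list()
    nj <- length(scales)
    for (j in seq_len(nj)) {
      ti <- .local_maxima(power[, j])
      for (i in ti) {
        if (power[i, j] <= thr) next
        lo <- if (j > 1) power[i, j - 1] else -Inf
        hi <- if (j < nj) power[i, j + 1] else -Inf
        if (power[i, j] >= lo && power[i, j] >= hi)
          cand[[length(cand) + 1]] <- c(i, j, power[i, j])
      }
    }
    if (length(cand)) {
      cand <- do.call(rbind, cand)
      # merge centres within merge_days, keeping the strongest
      ord <- order(cand[, 3], decreasing = TRUE)
      keep <- integer(0)
      for (k in ord) {
        if (!length(keep) ||
            all(abs(grid[cand[keep, 1]] - grid[cand[k, 1]]) >= merge_days))
          keep <- c(keep, k)
      }
      cand <- cand[keep, , drop = FALSE]
      cand <- cand[order(cand[, 1]), , drop = FALSE]
      centers <- do.call(rbind, lapply(seq_len(nrow(cand)), function(k) {
        i <- cand[k, 1]; j <- cand[k, 2]
        above_t <- power[, j] > thr
        run <- .run_containing(above_t, i)
        above_s <- power[i, ] > thr
        srun <- .run_containing(above_s, j)
        data.frame(day = grid[i], scale = scales[j], power = cand[k, 3],
                   skeleton_width = diff(range(grid[run])) + 1,
                   scale_min = scales[min(srun)], scale_max = scales[max(srun)])
      }))
    }
  }
  structure(list(power = power, centers = centers, scales = scales,
                 grid = grid,
                 amplitude = max(evi2_daily) - min(evi2_daily)),
            class = "wavelet_features")
}

# indices of the contiguous TRUE run in `flag` containing position i
.run_containing <- function(flag, i) {
  lo <- i
  while (lo > 1 && flag[lo - 1]) lo <- lo - 1
  hi <- i
  while (hi < length(flag) && flag[hi + 1]) hi <- hi + 1
  lo:hi
}

#' @export
print.wavelet_features <- function(x, ...) {
  cat("<wavelet_features> ", nrow(x$centers), " centre(s), EVI2 amplitude ",
      round(x$amplitude, 3), "\n", sep = "")
  if (nrow(x$centers)) print(x$centers)
  invisible(x)
}

#' Cropping intensity from wavelet features
#'
#' Counts the strong brightness centres that look like crop seasons: centre
#' day within the mapping year, skeleton width of at least
#' `min_skeleton_days`, and scale interval intersecting the crop-season
#' scale band. Pixels whose overall EVI2 amplitude is below `min_amplitude`
#' are fallow (intensity 0); the count is capped at 3 (triple cropping).
#'
#' @param features a [wavelet_spectrum()] result.
#' @param min_amplitude fallow floor on the overall EVI2 amplitude.
#' @param min_skeleton_days minimum ridge extent in time.
#' @param season_band crop-season scale band in days.
#' @param max_season_scale cap on a centre's own (best-response) scale. A
#'   single growing season concentrates its spectral energy below this
#'   scale; local maxima at larger scales are multi-season envelopes (the
#'   interference response midway between two seasons peaks near twice
#'   their separation) and must not be counted as seasons.
#' @param year_span days counted as the mapping year.
#' @return Integer intensity in 0..3.
#' @export
cropping_index <- function(features, min_amplitude = 0.15,
                           min_skeleton_days = 30, season_band = c(60, 200),
                           max_season_scale = 170, year_span = c(1, 365)) {
  stopifnot(inherits(features, "wavelet_features"))
  if (features$amplitude < min_amplitude) return(0L)
  ce <- features$centers
  if (!nrow(ce)) return(0L)
  ok <- ce$day >= year_span[1] & ce$day <= year_span[2] &
    ce$skeleton_width >= min_skeleton_days &
    ce$scale <= max_season_scale &
    ce$scale_min <= season_band[2] & ce$scale_max >= season_band[1]
  min(sum(ok), 3L)
}

#' Segment the mapping year into growing-season windows
#'
#' Splits the daily EVI2 trajectory into one window per detected cycle.
#' The heading date is the day of the cycle's EVI2 maximum (earliest day on
#' a plateau); season start and harvest are where EVI2 crosses 10 percent
#' of the cycle amplitude on the rising and falling flanks; the tillering
#' date is the 30 percent crossing on the rising flank. Windows are
#' disjoint and ordered in time. Winter-wheat-like cycles may start before
#' day 1 (in the previous year's padding).
#'
#' @param evi2_daily daily EVI2 on `grid`.
#' @param intensity number of cycles to segment (from [cropping_index()]).
#' @param grid daily grid.
#' @param min_amplitude prominence floor for candidate peaks.
#' @param merge_days peak merge distance in days.
#' @param year_span days counted as the mapping year.
#' @return A data.frame of class `season_windows` with one row per season:
#'   `start`, `tillering`, `heading`, `harvest`, `amplitude`.
#' @export
segment_seasons <- function(evi2_daily, intensity, grid = daily_grid(),
                            min_amplitude = 0.15, merge_days = 45,
                            year_span = c(1, 365)) {
  empty <- structure(
    data.frame(start = numeric(0), tillering = numeric(0),
               heading = numeric(0), harvest = numeric(0),
               amplitude = numeric(0)),
    class = c("season_windows", "data.frame"))
  if (intensity < 1) return(empty)
  peaks <- .prominent_peaks(evi2_daily, min_amplitude, merge_days)
  peaks <- peaks[grid[peaks] >= year_span[1] & grid[peaks] <= year_span[2]]
  if (!length(peaks)) return(empty)
  if (length(peaks) > intensity) {
    prom <- vapply(peaks, function(p) .prominence(evi2_daily, p), numeric(1))
    peaks <- sort(peaks[order(prom, decreasing = TRUE)][seq_len(intensity)])
  }
  n <- length(evi2_daily)
  bounds <- c(1, vapply(seq_len(length(peaks) - 1), function(k) {
    seg <- peaks[k]:peaks[k + 1]
    seg[which.min(evi2_daily[seg])]
  }, numeric(1)), n)
  rows <- lapply(seq_along(peaks), function(k) {
    p <- peaks[k]
    lo <- bounds[k]; hi <- bounds[k + 1]
    vl <- (lo:p)[which.min(evi2_daily[lo:p])]
    vr <- (p:hi)[which.min(evi2_daily[p:hi])]
    base <- min(evi2_daily[vl], evi2_daily[vr])
    amp <- evi2_daily[p] - base
    lvl10_l <- evi2_daily[vl] + 0.1 * (evi2_daily[p] - evi2_daily[vl])
    lvl30_l <- evi2_daily[vl] + 0.3 * (evi2_daily[p] - evi2_daily[vl])
    lvl10_r <- evi2_daily[vr] + 0.1 * (evi2_daily[p] - evi2_daily[vr])
    below <- function(rng, lvl) {
      b <- rng[evi2_daily[rng] <= lvl]
      if (length(b)) max(b) else rng[1]
    }
    start <- below(vl:p, lvl10_l)
    tillering <- below(vl:p, lvl30_l)
    hb <- (p:vr)[evi2_daily[p:vr] <= lvl10_r]
    harvest <- if (length(hb)) min(hb) else vr
    data.frame(start = grid[start], tillering = grid[tillering],
               heading = grid[p], harvest = grid[harvest], amplitude = amp)
  })
  out <- do.call(rbind, rows)
  class(out) <- c("season_windows", "data.frame")
  out
}
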