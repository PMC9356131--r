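#' Spectral indices from band reflectances
#'
#' Computes the three indices the crop classifiers use, at each valid
#' observation date:
#' \deqn{EVI2 = 2.5 (\rho_{NIR} - \rho_{Red}) / (\rho_{NIR} + 2.4 \rho_{Red} + 1)}
#' \deqn{LSWI = (\rho_{NIR} - \rho_{SWIR6}) / (\rho_{NIR} + \rho_{SWIR6})}
#' \deqn{NMDI = (\rho_{NIR} - (\rho_{SWIR6} - \rho_{SWIR7})) /
#'              (\rho_{NIR} + (\rho_{SWIR6} - \rho_{SWIR7}))}
#' where SWIR6 and SWIR7 are the shortwave-infrared bands centred near
#' 1640 nm and 2130 nm. A zero denominator yields an invalid value at that
#' date (flagged in `valid`), never an error.
#'
#' @param series a `reflectance_series` (see [simulate_pixel()]), or any
#'   list with the four band vectors and a `valid` flag.
#' @return A list with `dates`, numeric vectors `evi2`, `lswi`, `nmdi`
#'   (NA where not computable) and the updated `valid` flag.
#' @export
#' @examples
#' compute_indices(simulate_pixel(15, seed = 1))$evi2[20:24]
compute_indices <- function(series) {
  nir <- series$rho_nir; red <- series$rho_red
  s6 <- series$rho_swir6; s7 <- series$rho_swir7
  valid <- series$valid & !is.na(nir) & !is.na(red) & !is.na(s6) & !is.na(s7)

  den1 <- nir + 2.4 * red + 1
  den2 <- nir + s6
  d <- s6 - s7
  den3 <- nir + d

  evi2 <- ifelse(valid & den1 != 0, 2.5 * (nir - red) / den1, NA_real_)
  lswi <- ifelse(valid & den2 != 0, (nir - s6) / den2, NA_real_)
  nmdi <- ifelse(valid & den3 != 0, (nir - d) / den3, NA_real_)
  valid <- valid & !is.na(evi2) & !is.na(lswi) & !is.na(nmdi)

  list(dates = series$dates, evi2 = evi2, lswi = lswi, nmdi = nmdi,
       valid = valid)
}

#' Whittaker smoother on a daily grid
#'
#' Reconstructs a continuous daily trajectory from sparse, possibly gappy
#' observations by solving the penalized least-squares system
#' \deqn{(W + \lambda D'D) z = W y}
#' on the daily grid, where `W` is diagonal with weight 1 at valid
#' observation days and 0 everywhere else (invalid observations keep their
#' grid position with zero weight, so the second-difference matrix `D` is
#' constant), and `D` takes second-order differences. Large `lambda` gives
#' smoother output; as `lambda` approaches 0 with all days observed, the
#' output reproduces the input.
#'
#' @param values observed values at `dates`.
#' @param valid logical; which observations carry weight.
#' @param dates integer observation days (must be a subset of `grid`).
#' @param lambda positive smoothness penalty.
#' @param grid integer daily grid (consecutive days).
#' @return Numeric vector of smoothed values on `grid`.
#' @export
whittaker_smooth <- function(values, valid, dates, lambda = 500,
                             grid = daily_grid()) {
  if (lambda <= 0) stop2("whittaker_smooth: lambda must be positive")
  valid <- valid & !is.na(values)
  if (sum(valid) < 8)
    stop2("whittaker_smooth: fewer than 8 valid observations")
  n <- length(grid)
  pos <- match(dates, grid)
  if (anyNA(pos)) stop2("whittaker_smooth: observation dates outside grid")
  w <- numeric(n); y <- numeric(n)
  w[pos[valid]] <- 1
  y[pos[valid]] <- values[valid]
  D <- Matrix::bandSparse(n - 2, n, k = 0:2,
                          diagonals = list(rep(1, n - 2), rep(-2, n - 2),
                                           rep(1, n - 2)))
  A <- Matrix::Diagonal(n, w) + lambda * Matrix::crossprod(D)
  as.numeric(Matrix::solve(A, w * y))
}

#' Growing-season data-availability class
#'
#' Fraction of in-season composites (March--October by default) that are
#' valid, grouped into the three availability classes used for map
#' reliability flags: greater than 70 percent valid is good (1),
#' 50--70 percent (inclusive at both ends) is medium (2), below 50 percent
#' is low (3).
#'
#' @param valid logical vector per composite.
#' @param dates composite start days.
#' @param season two-element numeric, first and last day of the growing
#'   season (defaults to 1 March -- 31 October, days 60 and 304).
#' @return A list with `fraction` and `class` (`"good"`, `"medium"` or
#'   `"low"`) and the numeric `group` code 1/2/3.
#' @export
data_availability <- function(valid, dates, season = c(60, 304)) {
  in_season <- dates >= season[1] & dates <= season[2]
  if (!any(in_season)) stop2("data_availability: empty season window")
  f <- mean(valid[in_season])
  cls <- if (f > 0.70) "good" else if (f >= 0.50) "medium" else "low"
  list(fraction = f, class = cls,
       group = c(good = 1L, medium = 2L, low = 3L)[[cls]])
}

#' Preprocess one pixel: indices plus daily smoothing
#'
#' Convenience wrapper chaining [compute_indices()], [whittaker_smooth()]
#' per index and [data_availability()]. Pixels with fewer than 8 valid
#' observations are returned as unprocessable (no daily trajectories), which
#' downstream stages propagate as an explicit no-classification code.
#'
#' @param series a `reflectance_series`.
#' @param lambda smoothness penalty for EVI2 and LSWI.
#' @param lambda_nmdi smoothness penalty for NMDI. NMDI is much noisier
#'   than the other indices (its denominator nearly cancels), and its
#'   classifier integrates day-to-day slopes, so it is smoothed harder.
#' @param grid daily grid.
#' @return An object of class `index_series`: `grid`, daily `evi2`, `lswi`,
#'   `nmdi`, `availability` (see [data_availability()]), `n_valid` and
#'   `unprocessable`.
#' @export
preprocess_series <- function(series, lambda = 500, lambda_nmdi = 10000,
                              grid = daily_grid()) {
  ind <- compute_indices(series)
  avail <- data_availability(ind$valid, ind$dates)
  if (sum(ind$valid) < 8) {
    return(structure(list(grid = grid, evi2 = NULL, lswi = NULL, nmdi = NULL,
                          availability = avail, n_valid = sum(ind$valid),
                          unprocessable = TRUE),
                     truth = attr(series, "truth"), class = "index_series"))
  }
  sm <- function(v, lam) whittaker_smooth(v, ind$valid, ind$dates, lam, grid)
  structure(list(grid = grid,
                 evi2 = sm(ind$evi2, lambda),
                 lswi = sm(ind$lswi, lambda),
                 nmdi = sm(ind$nmdi, lambda_nmdi),
                 availability = avail, n_valid = sum(ind$valid),
                 unprocessable = FALSE),
            truth = attr(series, "truth"), class = "index_series")
}

#' @export
print.index_series <- function(x, ...) {
  cat("<index_series> ", length(x$grid), " days, availability ",
      x$availability$class, " (", round(100 * x$availability$fraction), "%), ",
      x$n_valid, " valid obs",
      if (x$unprocessable) " [unprocessable]", "\n", sep = "")
  invisible(x)
}

#' @export
plot.index_series <- function(x, ...) {
  if (x$unprocessable) stop2("pixel is unprocessable (too few observations)")
  graphics::plot(x$grid, x$evi2, type = "l", xlab = "day of mapping year",
                 ylab = "index value", ylim = range(x$evi2, x$lswi, x$nmdi),
                 ...)
  graphics::lines(x$grid, x$lswi, lty = 2)
  graphics::lines(x$grid, x$nmdi, lty = 3)
  graphics::legend("topleft", c("EVI2", "LSWI", "NMDI"), lty = 1:3, bty = "n")
  invisible(x)
}
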