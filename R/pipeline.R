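# End-to-end pipeline: preprocess -> purity -> intensity -> crop rules ->
# pattern codes -> (optional) validation.

#' Pipeline configuration
#'
#' All tunable constants of the mapping pipeline in one validated object.
#' Unknown arguments are rejected.
#'
#' @param lambda Whittaker penalty for EVI2/LSWI daily reconstruction.
#' @param lambda_nmdi Whittaker penalty for NMDI (smoothed harder; see
#'   [preprocess_series()]).
#' @param thresholds a [threshold_config()].
#' @param calendar a [wheat_calendar()] for the scene.
#' @param min_amplitude fallow floor on EVI2 amplitude.
#' @param min_skeleton_days,season_band,scales,rel_power_threshold,merge_days
#'   wavelet intensity constants (see [wavelet_spectrum()] and
#'   [cropping_index()]).
#' @param flowering_half_width maize flowering half-window, days.
#' @param wheat_gate_days tolerance around the calendar heading date for
#'   applying the wheat rule.
#' @param suitability optional named list of binary matrices (`rice`,
#'   `maize`, `wheat`) applied as suitability masks.
#' @param nodata integer written for unclassifiable pixels.
#' @return A list of class `pipeline_config`.
#' @export
pipeline_config <- function(lambda = 500, lambda_nmdi = 10000,
                            thresholds = threshold_config(),
                            calendar = wheat_calendar(115, 160),
                            min_amplitude = 0.15, min_skeleton_days = 30,
                            season_band = c(60, 200),
                            max_season_scale = 170,
                            scales = seq(30, 240, by = 10),
                            rel_power_threshold = 0.2, merge_days = 45,
                            flowering_half_width = 36, wheat_gate_days = 30,
                            suitability = NULL, nodata = 65535L) {
  stopifnot(lambda > 0, lambda_nmdi > 0,
            inherits(thresholds, "threshold_config"),
            inherits(calendar, "wheat_calendar"))
  structure(as.list(environment()), class = "pipeline_config")
}

# classify one preprocessed pixel; returns list(code, intensity, labels,
# seasons, reason)
.classify_pixel <- function(idx, stratum, cfg) {
  if (idx$unprocessable)
    return(list(code = NA_integer_, intensity = NA_integer_,
                labels = character(0), seasons = NULL,
                reason = "too few valid observations"))
  if (stratum == "excluded")
    return(list(code = NA_integer_, intensity = NA_integer_,
                labels = character(0), seasons = NULL,
                reason = "cropland fraction below 0.30"))
  wf <- wavelet_spectrum(idx$evi2, idx$grid, scales = cfg$scales,
                         rel_power_threshold = cfg$rel_power_threshold,
                         merge_days = cfg$merge_days)
  intensity <- cropping_index(wf, min_amplitude = cfg$min_amplitude,
                              min_skeleton_days = cfg$min_skeleton_days,
                              season_band = cfg$season_band,
                              max_season_scale = cfg$max_season_scale)
  seasons <- segment_seasons(idx$evi2, intensity, idx$grid,
                             min_amplitude = cfg$min_amplitude,
                             merge_days = cfg$merge_days)
  intensity <- nrow(seasons)  # windows actually recovered
  if (intensity == 0)
    return(list(code = 0L, intensity = 0L, labels = character(0),
                seasons = seasons, reason = NA_character_))
  met <- classify_pixel_seasons(idx, seasons, stratum, cfg$thresholds,
                                cfg$calendar, cfg$flowering_half_width,
                                cfg$wheat_gate_days)
  code <- as.integer(encode_pattern(intensity, met$label))
  list(code = code, intensity = intensity, labels = met$label,
       seasons = cbind(seasons, met), reason = NA_character_)
}

#' Run the full cropping-pattern mapping pipeline on a scene
#'
#' Executes preprocessing (indices + daily Whittaker reconstruction),
#' purity stratification, wavelet cropping-intensity detection, season
#' segmentation, the purity-stratified crop decision rules, pattern
#' encoding and, when the scene carries ground truth, accuracy assessment.
#' Every input pixel appears in the output either as a pattern code or as
#' an explicit no-data reason (excluded purity or too few observations).
#'
#' @param scene a `pheno_scene` from [simulate_scene()], or a list of
#'   `reflectance_series` (as from [read_scene_csv()]) with attributes
#'   `nrow`/`ncol`.
#' @param config a [pipeline_config()].
#' @param fraction optional cropland-fraction matrix; defaults to the
#'   scene's purity map (or 1 everywhere).
#' @return An object of class `pheno_map`: `pattern` (integer matrix, NA =
#'   no-data), `intensity`, `availability` (1/2/3), `stratum`, `reasons`,
#'   `seasons` (per-pixel season table), `area` (sown areas at a nominal
#'   25 ha per pixel), and `report` (an `accuracy_report`, when truth is
#'   available).
#' @export
#' @examples
#' sc <- simulate_scene(scene_config(matrix(c(15, 16, 14, 0), 2, 2)))
#' run_pipeline(sc)
run_pipeline <- function(scene, config = pipeline_config(),
                         fraction = NULL) {
  stopifnot(inherits(config, "pipeline_config"))
  if (inherits(scene, "pheno_scene")) {
    nr <- nrow(scene$truth); nc <- ncol(scene$truth)
    get_px <- function(i, j) scene_pixel(scene, i, j)
    truth <- scene$truth
    if (is.null(fraction)) fraction <- scene$purity
  } else if (is.list(scene) && !is.null(attr(scene, "nrow"))) {
    nr <- attr(scene, "nrow"); nc <- attr(scene, "ncol")
    get_px <- function(i, j) scene[[sprintf("%d_%d", i, j)]]
    truth <- NULL
  } else stop2("run_pipeline: unsupported scene object")
  if (is.null(fraction)) fraction <- matrix(1, nr, nc)
  if (!all(dim(as.matrix(fraction)) == c(nr, nc)))
    stop2("run_pipeline: fraction raster does not match the scene grid")

  stratum <- classify_purity(as.matrix(fraction))
  pattern <- matrix(NA_integer_, nr, nc)
  intensity <- matrix(NA_integer_, nr, nc)
  availability <- matrix(NA_integer_, nr, nc)
  reasons <- matrix(NA_character_, nr, nc)
  season_rows <- list()

  for (i in seq_len(nr)) {
    for (j in seq_len(nc)) {
      px <- get_px(i, j)
      idx <- preprocess_series(px, lambda = config$lambda,
                               lambda_nmdi = config$lambda_nmdi)
      availability[i, j] <- idx$availability$group
      res <- .classify_pixel(idx, stratum[i, j], config)
      pattern[i, j] <- res$code
      intensity[i, j] <- res$intensity
      reasons[i, j] <- res$reason
      if (!is.null(res$seasons) && nrow(res$seasons))
        season_rows[[length(season_rows) + 1]] <-
          cbind(data.frame(pixel_id = sprintf("%d_%d", i, j),
                           season_rank = seq_len(nrow(res$seasons))),
                res$seasons)
    }
  }

  if (!is.null(config$suitability)) {
    for (crop in names(config$suitability))
      pattern <- apply_suitability_mask(pattern, config$suitability[[crop]],
                                        crop)
  }

  seasons <- if (length(season_rows)) do.call(rbind, season_rows)
             else NULL
  area <- crop_area(pattern, as.matrix(fraction), pixel_area_ha = 25)

  report <- NULL
  if (!is.null(truth)) {
    ok <- !is.na(pattern)
    if (any(ok)) {
      codes <- pattern_code_table()$code
      report <- accuracy_metrics(
        confusion_matrix(as.character(pattern[ok]),
                         as.character(truth[ok]),
                         classes = as.character(codes)))
    }
  }

  structure(list(pattern = pattern, intensity = intensity,
                 availability = availability, stratum = stratum,
                 reasons = reasons, seasons = seasons, area = area,
                 report = report, config = config, truth = truth),
            class = "pheno_map")
}

#' @export
print.pheno_map <- function(x, ...) {
  cat("<pheno_map> ", nrow(x$pattern), "x", ncol(x$pattern), " pixels\n",
      sep = "")
  tab <- table(x$pattern, useNA = "ifany")
  cat("pattern codes:",
      paste(names(tab), "(", as.vector(tab), ")", sep = "", collapse = " "),
      "\n")
  if (!is.null(x$report))
    cat("overall pattern accuracy vs truth: ",
        round(100 * x$report$oa, 2), "%\n", sep = "")
  invisible(x)
}

#' @export
summary.pheno_map <- function(object, ...) {
  list(patterns = table(object$pattern, useNA = "ifany"),
       availability = table(object$availability),
       area = object$area,
       oa = if (!is.null(object$report)) object$report$oa else NA_real_)
}

#' Write the pipeline's rasters and tables to a directory
#'
#' @param map a `pheno_map`.
#' @param dir output directory (created if missing).
#' @param nodata no-data value for the pattern raster.
#' @return `dir`, invisibly.
#' @export
write_map <- function(map, dir, nodata = 65535) {
  stopifnot(inherits(map, "pheno_map"))
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  write_asc(map$pattern, file.path(dir, "pattern.asc"), nodata = nodata)
  write_asc(map$availability, file.path(dir, "availability.asc"))
  write_asc(map$intensity, file.path(dir, "intensity.asc"), nodata = nodata)
  if (!is.null(map$seasons))
    utils::write.csv(map$seasons, file.path(dir, "seasons.csv"),
                     row.names = FALSE)
  utils::write.csv(map$area, file.path(dir, "area.csv"), row.names = FALSE)
  invisible(dir)
}
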