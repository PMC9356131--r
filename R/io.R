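# Raster and table I/O. Rasters travel as Esri ASCII grids (plain text,
# widely readable); per-pixel series and ground truth as long-format CSV.

#' Write a matrix as an Esri ASCII grid
#'
#' @param x numeric or integer matrix (row 1 = northernmost row).
#' @param path output file.
#' @param xll,yll lower-left corner coordinates (default WGS-84 degrees).
#' @param cellsize cell size in the same units.
#' @param nodata value written for NA cells.
#' @return `path`, invisibly.
#' @export
write_asc <- function(x, path, xll = 0, yll = 0, cellsize = 1/240,
                      nodata = -9999) {
  x <- as.matrix(x)
  con <- file(path, "w")
  on.exit(close(con))
  num <- function(v) formatC(v, format = "g", digits = 17)
  writeLines(c(paste("ncols", ncol(x)),
               paste("nrows", nrow(x)),
               paste("xllcorner", num(xll)),
               paste("yllcorner", num(yll)),
               paste("cellsize", num(cellsize)),
               paste("NODATA_value", num(nodata))), con)
  vals <- x
  vals[is.na(vals)] <- nodata
  utils::write.table(vals, con, row.names = FALSE, col.names = FALSE)
  invisible(path)
}

#' Read an Esri ASCII grid
#'
#' @param path input file.
#' @return A numeric matrix with NA at no-data cells; grid metadata
#'   (`xll`, `yll`, `cellsize`, `nodata`) in attributes.
#' @export
read_asc <- function(path) {
  if (!file.exists(path)) stop2("read_asc: no such file: ", path)
  hdr_lines <- readLines(path, n = 6)
  hdr <- strsplit(trimws(hdr_lines), "\\s+")
  keys <- tolower(vapply(hdr, `[`, "", 1))
  vals <- as.numeric(vapply(hdr, `[`, "", 2))
  names(vals) <- keys
  need <- c("ncols", "nrows", "nodata_value")
  if (!all(need %in% keys)) stop2("read_asc: malformed header in ", path)
  m <- as.matrix(utils::read.table(path, skip = 6))
  dimnames(m) <- NULL
  if (nrow(m) != vals["nrows"] || ncol(m) != vals["ncols"])
    stop2("read_asc: data block does not match header dimensions")
  m[m == vals["nodata_value"]] <- NA
  attr(m, "xll") <- unname(vals["xllcorner"])
  attr(m, "yll") <- unname(vals["yllcorner"])
  attr(m, "cellsize") <- unname(vals["cellsize"])
  attr(m, "nodata") <- unname(vals["nodata_value"])
  m
}

#' Write a scene's reflectance stack as long-format CSV
#'
#' Columns: `pixel_id` (row_col), `date` (day of mapping year), one column
#' per band, and `valid`. Lossless for round-tripping simulated scenes.
#'
#' @param scene a `pheno_scene`.
#' @param path output CSV.
#' @return `path`, invisibly.
#' @export
write_scene_csv <- function(scene, path) {
  stopifnot(inherits(scene, "pheno_scene"))
  nr <- nrow(scene$truth); nc <- ncol(scene$truth)
  rows <- vector("list", nr * nc)
  k <- 0
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    k <- k + 1
    rows[[k]] <- data.frame(
      pixel_id = sprintf("%d_%d", i, j),
      date = scene$dates,
      rho_red = scene$refl[i, j, , 1], rho_nir = scene$refl[i, j, , 2],
      rho_swir6 = scene$refl[i, j, , 3], rho_swir7 = scene$refl[i, j, , 4],
      valid = as.logical(scene$valid[i, j, ]))
  }
  utils::write.csv(do.call(rbind, rows), path, row.names = FALSE)
  invisible(path)
}

#' Read a long-format scene CSV
#'
#' @param path CSV written by [write_scene_csv()].
#' @return A list of `reflectance_series`, named by `pixel_id`, plus
#'   attributes `nrow`/`ncol` recovered from the ids.
#' @export
read_scene_csv <- function(path) {
  if (!file.exists(path)) stop2("read_scene_csv: no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("pixel_id", "date", "rho_red", "rho_nir", "rho_swir6",
            "rho_swir7", "valid")
  if (!all(need %in% names(df)))
    stop2("read_scene_csv: missing column(s): ",
          paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(is.na(df$date))
  if (length(bad))
    stop2("read_scene_csv: malformed row(s): ",
          paste(utils::head(bad, 5), collapse = ", "))
  split_px <- split(df, df$pixel_id)
  out <- lapply(split_px, function(d) {
    d <- d[order(d$date), ]
    structure(list(dates = d$date, rho_red = d$rho_red, rho_nir = d$rho_nir,
                   rho_swir6 = d$rho_swir6, rho_swir7 = d$rho_swir7,
                   valid = as.logical(d$valid)),
              class = "reflectance_series")
  })
  ij <- do.call(rbind, strsplit(names(out), "_"))
  attr(out, "nrow") <- max(as.integer(ij[, 1]))
  attr(out, "ncol") <- max(as.integer(ij[, 2]))
  out
}

#' Read a ground-truth label table
#'
#' @param path CSV with columns `site_id`, `lon`, `lat`, `year`, `class`
#'   (extra columns are kept).
#' @return A data.frame.
#' @export
read_ground_truth <- function(path) {
  if (!file.exists(path)) stop2("read_ground_truth: no such file: ", path)
  df <- utils::read.csv(path)
  need <- c("site_id", "lon", "lat", "year", "class")
  if (!all(need %in% names(df)))
    stop2("read_ground_truth: missing column(s): ",
          paste(setdiff(need, names(df)), collapse = ", "))
  bad <- which(is.na(df$year) | !nzchar(as.character(df$class)))
  if (length(bad))
    stop2("read_ground_truth: malformed row(s): ",
          paste(utils::head(bad, 5), collapse = ", "))
  df
}
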