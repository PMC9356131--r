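#' Aggregate a fine binary cropland mask to a coarse fraction map
#'
#' Each coarse cell is the mean of its `factor` x `factor` block of fine
#' binary cells (e.g. 30 m cropland pixels aggregated to a ~500 m fraction
#' map). Edge blocks, when the fine grid is not divisible by `factor`, use
#' the mean of the partial block.
#'
#' @param fine_mask binary matrix (0/1).
#' @param factor integer block size.
#' @return Numeric matrix of cropland fractions in \[0, 1\].
#' @export
#' @examples
#' aggregate_fraction(matrix(c(1, 1, 1, 0), 2, 2), factor = 2)
aggregate_fraction <- function(fine_mask, factor) {
  fine_mask <- as.matrix(fine_mask)
  if (!all(fine_mask %in% c(0, 1)))
    stop2("aggregate_fraction: fine mask must be binary (0/1)")
  factor <- as.integer(factor)
  if (factor < 1) stop2("aggregate_fraction: factor must be >= 1")
  nr <- ceiling(nrow(fine_mask) / factor)
  nc <- ceiling(ncol(fine_mask) / factor)
  out <- matrix(NA_real_, nr, nc)
  for (i in seq_len(nr)) {
    rows <- ((i - 1) * factor + 1):min(i * factor, nrow(fine_mask))
    for (j in seq_len(nc)) {
      cols <- ((j - 1) * factor + 1):min(j * factor, ncol(fine_mask))
      out[i, j] <- mean(fine_mask[rows, cols])
    }
  }
  out
}

#' Pixel-purity stratum from cropland fraction
#'
#' Strata select the threshold column of the crop decision rules: fractions
#' above 0.90 are pure cropland pixels, 0.50--0.90 moderately mixed,
#' 0.30--0.50 (exclusive above) seriously mixed; pixels with less than 30
#' percent cropland are excluded from classification (emitted as an
#' explicit no-data stratum, never dropped). Boundary values 0.90 and 0.50
#' fall in the moderate stratum, 0.30 in the serious stratum.
#'
#' @param fraction numeric vector or matrix of cropland fractions in
#'   \[0, 1\].
#' @return Character vector/matrix with values `"pure"`, `"moderate"`,
#'   `"serious"`, `"excluded"`.
#' @export
#' @examples
#' classify_purity(c(0.95, 0.70, 0.40, 0.20))
classify_purity <- function(fraction) {
  if (any(fraction < 0 | fraction > 1, na.rm = TRUE))
    stop2("classify_purity: fraction must lie in [0, 1]")
  out <- ifelse(fraction > 0.90, "pure",
         ifelse(fraction >= 0.50, "moderate",
         ifelse(fraction >= 0.30, "serious", "excluded")))
  if (is.matrix(fraction)) matrix(out, nrow(fraction), ncol(fraction)) else out
}

# numeric stratum codes used in rasters: 1 pure, 2 moderate, 3 serious,
# 0 excluded
.stratum_code <- c(excluded = 0L, pure = 1L, moderate = 2L, serious = 3L)
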