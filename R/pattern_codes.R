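#' Cropping-pattern code vocabulary
#'
#' The integer coding scheme for annual cropping patterns. The first digit
#' is the cropping intensity (0 fallow, 1 single, 2 double, 3 triple); the
#' crop digits are 4 maize, 5 paddy rice, 6 wheat, 7 other crops. Single
#' cropping carries one crop digit; double cropping carries both crop
#' digits in ascending numeric order (the temporal sequence is not stored
#' in the code); triple cropping carries no crop composition.
#'
#' @return A data.frame with columns `code`, `abbrev` and `name`.
#' @export
#' @examples
#' pattern_code_table()
pattern_code_table <- function() {
  data.frame(
    code = c(0L, 14L, 15L, 16L, 17L, 245L, 246L, 255L, 256L, 277L, 3L),
    abbrev = c("F", "SM", "SR", "SW", "SO", "R-M", "W-M", "R-R", "W-R",
               "OD", "T"),
    name = c("fallow", "single maize", "single rice", "single wheat",
             "single others", "rice-maize", "wheat-maize", "double rice",
             "wheat-rice", "double others", "triple cropping"),
    stringsAsFactors = FALSE)
}

.crop_digits <- c(maize = 4L, rice = 5L, wheat = 6L, other = 7L)

#' Encode intensity and season labels as a pattern code
#'
#' @param intensity cropping intensity in 0..3.
#' @param season_labels character vector of per-season crop labels in
#'   temporal order, each of `"rice"`, `"wheat"`, `"maize"`, `"other"`;
#'   length must equal `intensity`.
#' @return Integer pattern code. Double patterns pairing one staple with an
#'   "other" season (or two distinct staples outside the standard
#'   rotations) are not part of the code vocabulary and are mapped to 277
#'   (other double cropping), with the original labels kept in the
#'   `"seasons"` attribute. Triple cropping encodes as 3 regardless of
#'   composition.
#' @export
#' @examples
#' encode_pattern(2, c("wheat", "maize"))  # 246
#' encode_pattern(2, c("rice", "rice"))    # 255
encode_pattern <- function(intensity, season_labels = character(0)) {
  intensity <- as.integer(intensity)
  if (intensity < 0 || intensity > 3)
    stop2("encode_pattern: intensity must be in 0..3")
  if (length(season_labels) != intensity)
    stop2("encode_pattern: ", length(season_labels),
          " season label(s) supplied for intensity ", intensity)
  if (intensity > 0 && !all(season_labels %in% names(.crop_digits)))
    stop2("encode_pattern: labels must be among ",
          paste(names(.crop_digits), collapse = ", "))
  code <- if (intensity == 0L) {
    0L
  } else if (intensity == 1L) {
    10L + .crop_digits[[season_labels]]
  } else if (intensity == 3L) {
    3L
  } else {
    d <- sort(.crop_digits[season_labels])
    cand <- 200L + 10L * d[1] + d[2]
    if (cand %in% c(245L, 246L, 255L, 256L, 277L)) cand else 277L
  }
  structure(code, seasons = season_labels)
}

#' Decode a pattern code
#'
#' Inverse of [encode_pattern()] up to temporal order (not stored in the
#' code) and up to the collapsing of non-standard doubles into 277 and of
#' any triple composition into 3.
#'
#' @param code an integer code from [pattern_code_table()].
#' @return A list with `intensity`, `crops` (character multiset; empty for
#'   fallow, other-other for 277, none recorded for triple) and `name`.
#' @export
#' @examples
#' decode_pattern(256)
decode_pattern <- function(code) {
  tab <- pattern_code_table()
  code <- as.integer(code)
  k <- match(code, tab$code)
  if (is.na(k))
    stop2("decode_pattern: unknown code ", code, "; valid codes are ",
          paste(tab$code, collapse = ", "))
  digit_crop <- stats::setNames(names(.crop_digits), .crop_digits)
  crops <- if (code == 0L || code == 3L) character(0)
           else if (code < 100L) digit_crop[[as.character(code %% 10L)]]
           else c(digit_crop[[as.character((code %/% 10L) %% 10L)]],
                  digit_crop[[as.character(code %% 10L)]])
  intensity <- if (code == 0L) 0L else if (code == 3L) 3L
               else if (code < 100L) 1L else 2L
  list(intensity = intensity, crops = unname(crops), name = tab$name[k])
}

#' Demote a crop outside its suitability mask
#'
#' Pixels labeled with the target crop but lying outside its suitable area
#' (a binary mask derived from topographic/climatic constraints, supplied
#' as input) are re-labeled: the target crop's seasons become "other" and
#' the pattern code is re-encoded. All other pixels are unchanged.
#'
#' @param pattern integer matrix of pattern codes (NA allowed for no-data).
#' @param mask binary matrix, 1 = suitable; must match `pattern` in shape.
#' @param target crop to demote: `"rice"`, `"wheat"` or `"maize"`.
#' @return The updated pattern matrix.
#' @export
apply_suitability_mask <- function(pattern, mask, target) {
  target <- match.arg(target, c("rice", "wheat", "maize"))
  pattern <- as.matrix(pattern); mask <- as.matrix(mask)
  if (!all(dim(pattern) == dim(mask)))
    stop2("apply_suitability_mask: pattern and mask grids are misaligned")
  if (!all(mask %in% c(0, 1)))
    stop2("apply_suitability_mask: mask must be binary")
  out <- pattern
  for (k in which(mask == 0 & !is.na(pattern))) {
    dec <- decode_pattern(pattern[k])
    if (target %in% dec$crops) {
      labs <- replace(dec$crops, dec$crops == target, "other")
      out[k] <- as.integer(encode_pattern(dec$intensity, labs))
    }
  }
  out
}

#' Fraction-weighted sown areas per crop
#'
#' Sown-area convention: every cropping season counts, so a wheat-maize
#' pixel contributes its cropland area to both wheat and maize, and a
#' double-rice pixel contributes twice to rice. Triple-cropping and
#' other-crop seasons carry no staple-crop area.
#'
#' @param pattern integer matrix of pattern codes (NA = no-data, skipped).
#' @param fraction cropland-fraction matrix aligned with `pattern`.
#' @param pixel_area_ha area of one pixel in hectares.
#' @return A data.frame with columns `crop` and `area_ha` for rice, wheat,
#'   maize and other.
#' @export
#' @examples
#' crop_area(matrix(246), matrix(0.5), pixel_area_ha = 25)
crop_area <- function(pattern, fraction, pixel_area_ha) {
  pattern <- as.matrix(pattern); fraction <- as.matrix(fraction)
  if (!all(dim(pattern) == dim(fraction)))
    stop2("crop_area: pattern and fraction grids are misaligned")
  if (pixel_area_ha <= 0) stop2("crop_area: pixel_area_ha must be positive")
  crops <- c("rice", "wheat", "maize", "other")
  area <- stats::setNames(numeric(4), crops)
  for (k in seq_along(pattern)) {
    if (is.na(pattern[k])) next
    for (cr in decode_pattern(pattern[k])$crops)
      area[cr] <- area[cr] + fraction[k] * pixel_area_ha
  }
  data.frame(crop = crops, area_ha = unname(area), stringsAsFactors = FALSE)
}
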