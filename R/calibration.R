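#' Two-point qBEI material calibration
#'
#' In quantitative backscattered electron imaging the detector signal grows
#' monotonically with the mean atomic number of the target, hence with the
#' local mineral (calcium) content of bone.  Gray levels are put on an
#' absolute calcium weight-percent scale with two reference materials
#' imaged in the same frame: pure carbon (Z = 6, defines 0 wt% Ca) and pure
#' aluminum (Z = 13, defines [ca_equiv_aluminum()] wt% Ca under the linear
#' atomic-number model).
#'
#' @param gl_carbon mean gray level measured on the carbon standard.
#' @param gl_aluminum mean gray level measured on the aluminum standard;
#'   must exceed `gl_carbon`.
#' @param ca_equiv_aluminum_wtpct calcium-equivalent of aluminum, wt% Ca.
#' @return An object of class `calibration_standards`.
#' @seealso [fit_calibration()], [measure_standard_gray()]
#' @export
calibration_standards <- function(gl_carbon, gl_aluminum,
                                  ca_equiv_aluminum_wtpct = ca_equiv_aluminum()) {
  stop_if_not_scalar_num(gl_carbon, "gl_carbon", lower = 0)
  stop_if_not_scalar_num(gl_aluminum, "gl_aluminum", lower = 0)
  stop_if_not_scalar_num(ca_equiv_aluminum_wtpct, "ca_equiv_aluminum_wtpct",
                         lower = 1e-9)
  if (gl_aluminum <= gl_carbon)
    stop("calibration error: gl_aluminum must exceed gl_carbon", call. = FALSE)
  structure(list(gl_carbon = gl_carbon, gl_aluminum = gl_aluminum,
                 ca_equiv_aluminum_wtpct = ca_equiv_aluminum_wtpct),
            class = "calibration_standards")
}

#' Mean gray level over a standard's region of interest
#'
#' @param image a [qbei_image()].
#' @param roi logical mask of the image, or a two-column matrix of 0-based
#'   (row, col) pixel coordinates.
#' @return Arithmetic mean gray level (a single number).
#' @export
measure_standard_gray <- function(image, roi) {
  stopifnot(inherits(image, "qbei_image"))
  if (is.matrix(roi) && !is.logical(roi) && ncol(roi) == 2L) {
    i <- roi[, 1] + 1L; j <- roi[, 2] + 1L
    if (any(i < 1L | i > nrow(image$gray) | j < 1L | j > ncol(image$gray)))
      stop("roi coordinates outside image bounds", call. = FALSE)
    v <- image$gray[cbind(i, j)]
  } else {
    v <- image$gray[as_mask(roi, dim(image$gray))]
  }
  if (length(v) == 0L) stop("empty standard roi", call. = FALSE)
  mean(v)
}

#' Fit the linear gray-to-calcium calibration curve
#'
#' The curve is anchored exactly at both standards: carbon maps to 0 wt% Ca
#' and aluminum to the calcium-equivalent value in `standards`.
#'
#' @param standards a [calibration_standards()] object.
#' @param saturation_wtpct physical upper bound of the scale; defaults to
#'   39.86 wt% Ca, pure hydroxyapatite.
#' @return An object of class `calibration_curve` with fields `slope`
#'   (wt% Ca per gray unit), `intercept` (wt% Ca at gray 0), `valid_range`
#'   (gray levels mapping into `[0, saturation]`) and `saturation_wtpct`.
#' @export
#' @examples
#' cur <- fit_calibration(calibration_standards(25, 225))
#' predict(cur, c(25, 125, 225))
fit_calibration <- function(standards, saturation_wtpct = CA_SATURATION_WTPCT) {
  stopifnot(inherits(standards, "calibration_standards"))
  slope <- standards$ca_equiv_aluminum_wtpct /
    (standards$gl_aluminum - standards$gl_carbon)
  intercept <- -slope * standards$gl_carbon
  structure(list(slope = slope, intercept = intercept,
                 valid_range = c(min_gl = 0,
                                 max_gl = (saturation_wtpct - intercept) / slope),
                 saturation_wtpct = saturation_wtpct,
                 standards = standards),
            class = "calibration_curve")
}

#' @export
predict.calibration_curve <- function(object, newdata, ...) {
  object$intercept + object$slope * newdata
}

#' @export
print.calibration_curve <- function(x, ...) {
  cat(sprintf(paste0("qBEI calibration: wt%% Ca = %.6g + %.6g * GL ",
                     "(carbon GL %.6g, aluminum GL %.6g)\n"),
              x$intercept, x$slope, x$standards$gl_carbon,
              x$standards$gl_aluminum))
  invisible(x)
}

#' Convert a qBEI image to a calcium map
#'
#' Applies the calibration per pixel.  Gray levels below the carbon anchor
#' (detector noise) are clamped to 0 wt% Ca and remain valid; pixels that
#' would exceed the hydroxyapatite saturation are flagged invalid in
#' `valid_mask` because bone cannot exceed hydroxyapatite stoichiometry.
#'
#' @param image a [qbei_image()].
#' @param curve a [calibration_curve] from [fit_calibration()].
#' @return An object of class `calcium_map` with fields `wtpct_ca`
#'   (numeric matrix), `valid_mask` (logical matrix) and `pixel_size_um`.
#' @export
apply_calibration <- function(image, curve) {
  stopifnot(inherits(image, "qbei_image"), inherits(curve, "calibration_curve"))
  wt <- curve$intercept + curve$slope * image$gray
  valid <- wt <= curve$saturation_wtpct
  wt[wt < 0] <- 0
  calcium_map(wt, valid, image$pixel_size_um,
              saturation_wtpct = curve$saturation_wtpct)
}

#' Construct a calcium map object
#'
#' @param wtpct_ca numeric matrix of calcium concentrations, wt% Ca.
#' @param valid_mask logical matrix marking pixels inside the calibrated
#'   range; defaults to all valid.
#' @param pixel_size_um pixel edge length, micrometers.
#' @param saturation_wtpct scale upper bound, wt% Ca.
#' @return An object of class `calcium_map`.
#' @export
calcium_map <- function(wtpct_ca, valid_mask = NULL, pixel_size_um = 1.8,
                        saturation_wtpct = CA_SATURATION_WTPCT) {
  stopifnot(is.matrix(wtpct_ca))
  if (is.null(valid_mask)) valid_mask <- matrix(TRUE, nrow(wtpct_ca), ncol(wtpct_ca))
  valid_mask <- as_mask(valid_mask, dim(wtpct_ca))
  if (any(wtpct_ca[valid_mask] < 0) ||
      any(wtpct_ca[valid_mask] > saturation_wtpct + 1e-9))
    stop("valid calcium values must lie in [0, saturation]", call. = FALSE)
  structure(list(wtpct_ca = wtpct_ca, valid_mask = valid_mask,
                 pixel_size_um = pixel_size_um,
                 saturation_wtpct = saturation_wtpct),
            class = "calcium_map")
}

#' @export
print.calcium_map <- function(x, ...) {
  v <- x$wtpct_ca[x$valid_mask]
  cat(sprintf("calcium map: %d x %d px, %.3g um/px, %.1f%% valid, range [%.2f, %.2f] wt%% Ca\n",
              nrow(x$wtpct_ca), ncol(x$wtpct_ca), x$pixel_size_um,
              100 * mean(x$valid_mask), min(v), max(v)))
  invisible(x)
}

# Serialise / restore a calibration curve (JSON round trip for the CLI).
write_calibration <- function(curve, path) {
  jsonlite::write_json(
    list(slope = curve$slope, intercept = curve$intercept,
         valid_range = as.list(curve$valid_range),
         saturation_wtpct = curve$saturation_wtpct,
         gl_carbon = curve$standards$gl_carbon,
         gl_aluminum = curve$standards$gl_aluminum,
         ca_equiv_aluminum_wtpct = curve$standards$ca_equiv_aluminum_wtpct),
    path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

read_calibration <- function(path) {
  x <- jsonlite::read_json(path, simplifyVector = TRUE)
  fit_calibration(
    calibration_standards(x$gl_carbon, x$gl_aluminum, x$ca_equiv_aluminum_wtpct),
    saturation_wtpct = x$saturation_wtpct)
}
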