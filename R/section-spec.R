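#' Specification of a synthetic transiliac section
#'
#' Describes the stated world a synthetic cross-section is drawn from: two
#' cortical plates flanking a trabecular compartment, marrow with roundish
#' adipocytes, osteoid seams, a mineralized matrix whose calcium values
#' follow a Gaussian mixture, embedded carbon/aluminum calibration patches
#' and additive detector noise.  Defaults emulate an infant transiliac
#' biopsy at the published pediatric reference values: BV/TV 17.7%, Tb.Th
#' 101 um, cortical width 300 um per plate (infant scale), O.Th 5.8 um,
#' OS/BS 34%, and a mineralization mixture whose dominant (lamellar) mode
#' sits at the reference CaPeak 23.4 wt% Ca with sigma = CaWidth/2.355.
#'
#' @param image_height_px,image_width_px image size in pixels.
#' @param pixel_size_um pixel edge length; 1.8 um is the conventional qBEI
#'   overview resolution.
#' @param cortical_width_um widths of the two cortical plates, micrometers.
#' @param trabecular_target_bvtv_pct target trabecular bone area fraction,
#'   percent of the trabecular compartment.
#' @param trabecular_thickness_um nominal thickness of generated trabeculae.
#' @param osteoid_seam_thickness_um thickness of osteoid seams (0 disables).
#' @param osteoid_surface_fraction fraction of the bone surface covered by
#'   osteoid seams, in `[0, 1]`.
#' @param mineralization_mixture list of `c(mean, sd, weight)` triples
#'   (wt% Ca); weights must sum to 1.
#' @param cartilage_peak optional `c(mean, sd, weight)` triple describing a
#'   highly mineralized residual-cartilage mode; its weight is the fraction
#'   of mineralized pixels relabelled as cartilage.
#' @param adipocyte_count number of marrow adipocytes to place.
#' @param adipocyte_area_um2_range `c(min, max)` area range, square um.
#' @param gray_noise_sd standard deviation of the additive Gaussian detector
#'   noise, in gray levels.
#' @param standards_patch_gray `c(gl_carbon, gl_aluminum)` mean gray levels
#'   at which the two calibration patches are stamped.
#' @param surface_fractions named vector with elements `osteoblast`,
#'   `osteoclast`, `eroded`: fractions of the bone surface stamped with each
#'   annotation (defaults follow the pediatric reference means 8.5%, 1.1%,
#'   14.8%).
#' @param bit_depth gray bit depth of the synthesized image (8 or 16).
#' @param seed default RNG seed used by [simulate_section()].
#' @return An object of class `section_spec`.
#' @export
#' @examples
#' spec <- section_spec(image_height_px = 400, image_width_px = 300,
#'                      adipocyte_count = 10)
#' sim <- simulate_section(spec, seed = 1)
#' sim$image
section_spec <- function(image_height_px = 1100L,
                         image_width_px = 900L,
                         pixel_size_um = 1.8,
                         cortical_width_um = c(300, 300),
                         trabecular_target_bvtv_pct = 17.7,
                         trabecular_thickness_um = 101,
                         osteoid_seam_thickness_um = 5.8,
                         osteoid_surface_fraction = 0.34,
                         mineralization_mixture = list(
                           lamellar = c(mean = 23.4, sd = 1.55, weight = 0.85),
                           woven    = c(mean = 20.3, sd = 2.00, weight = 0.15)),
                         cartilage_peak = NULL,
                         adipocyte_count = 50L,
                         adipocyte_area_um2_range = c(600, 1800),
                         gray_noise_sd = 350,
                         standards_patch_gray = c(gl_carbon = 5000,
                                                  gl_aluminum = 45000),
                         surface_fractions = c(osteoblast = 0.085,
                                               osteoclast = 0.011,
                                               eroded = 0.148),
                         bit_depth = 16L,
                         seed = 1L) {
  spec <- structure(
    list(image_height_px = as.integer(image_height_px),
         image_width_px = as.integer(image_width_px),
         pixel_size_um = pixel_size_um,
         cortical_width_um = cortical_width_um,
         trabecular_target_bvtv_pct = trabecular_target_bvtv_pct,
         trabecular_thickness_um = trabecular_thickness_um,
         osteoid_seam_thickness_um = osteoid_seam_thickness_um,
         osteoid_surface_fraction = osteoid_surface_fraction,
         mineralization_mixture = mineralization_mixture,
         cartilage_peak = cartilage_peak,
         adipocyte_count = as.integer(adipocyte_count),
         adipocyte_area_um2_range = adipocyte_area_um2_range,
         gray_noise_sd = gray_noise_sd,
         standards_patch_gray = standards_patch_gray,
         surface_fractions = surface_fractions,
         bit_depth = as.integer(bit_depth),
         seed = as.integer(seed)),
    class = "section_spec")
  validate_section_spec(spec)
  spec
}

#' Validate a section specification
#'
#' Checks the structural invariants: positive geometry, mixture weights
#' summing to 1 within 1e-9, all component means inside `[0, 39.86]` wt% Ca,
#' and cortical plates that fit inside the image with room for a trabecular
#' compartment.  Errors are signalled with condition class
#' `osteosect_invalid_spec`.
#'
#' @param spec a [section_spec()] object (or a bare list with its fields).
#' @return `spec`, invisibly, if valid.
#' @export
validate_section_spec <- function(spec) {
  bad <- function(msg) stop(structure(
    class = c("osteosect_invalid_spec", "error", "condition"),
    list(message = paste0("invalid section spec: ", msg), call = NULL)))
  if (spec$image_height_px < 1L || spec$image_width_px < 1L)
    bad("image dimensions must be positive")
  if (!is.numeric(spec$pixel_size_um) || spec$pixel_size_um <= 0)
    bad("pixel_size_um must be positive")
  cw <- spec$cortical_width_um
  if (length(cw) != 2L || any(cw <= 0)) bad("cortical_width_um must be two positive widths")
  if (sum(cw / spec$pixel_size_um) > spec$image_height_px - 16L)
    bad("cortices wider than image: no room for a trabecular compartment")
  b <- spec$trabecular_target_bvtv_pct
  if (!is.numeric(b) || b <= 0 || b >= 100) bad("trabecular_target_bvtv_pct must be in (0, 100)")
  if (spec$trabecular_thickness_um <= 0) bad("trabecular_thickness_um must be positive")
  if (spec$osteoid_seam_thickness_um < 0) bad("osteoid_seam_thickness_um must be nonnegative")
  f <- spec$osteoid_surface_fraction
  if (f < 0 || f > 1) bad("osteoid_surface_fraction must be in [0, 1]")
  mix <- spec$mineralization_mixture
  if (length(mix) < 1L) bad("mineralization_mixture needs at least one component")
  comp <- vapply(mix, function(x) x[c("mean", "sd", "weight")], numeric(3))
  if (anyNA(comp)) bad("mixture components need named mean, sd, weight")
  if (abs(sum(comp["weight", ]) - 1) > 1e-9) bad("mixture weights must sum to 1")
  if (any(comp["mean", ] < 0 | comp["mean", ] > CA_SATURATION_WTPCT))
    bad("mixture means must lie in [0, 39.86] wt% Ca")
  if (any(comp["sd", ] < 0)) bad("mixture sds must be nonnegative")
  cp <- spec$cartilage_peak
  if (!is.null(cp)) {
    cp <- cp[c("mean", "sd", "weight")]
    if (anyNA(cp)) bad("cartilage_peak needs named mean, sd, weight")
    if (cp["mean"] < 0 || cp["mean"] > CA_SATURATION_WTPCT)
      bad("cartilage_peak mean must lie in [0, 39.86] wt% Ca")
    if (cp["weight"] < 0 || cp["weight"] >= 1)
      bad("cartilage_peak weight must lie in [0, 1)")
  }
  if (spec$adipocyte_count < 0L) bad("adipocyte_count must be nonnegative")
  ar <- spec$adipocyte_area_um2_range
  if (length(ar) != 2L || any(ar <= 0) || ar[1] > ar[2])
    bad("adipocyte_area_um2_range must be (min, max) positive")
  if (spec$gray_noise_sd < 0) bad("gray_noise_sd must be nonnegative")
  g <- spec$standards_patch_gray
  if (length(g) != 2L || g[2] <= g[1]) bad("standards_patch_gray must be (gl_carbon, gl_aluminum) with gl_aluminum > gl_carbon")
  if (g[2] > 2^spec$bit_depth - 1) bad("standards_patch_gray exceeds the image bit range")
  sf <- spec$surface_fractions
  if (anyNA(sf[c("osteoblast", "osteoclast", "eroded")]) ||
      any(sf < 0) || sum(sf) > 1)
    bad("surface_fractions must be nonnegative and sum to at most 1")
  invisible(spec)
}

#' @export
print.section_spec <- function(x, ...) {
  cat(sprintf(paste0("section spec: %d x %d px @ %.3g um/px, cortices %g/%g um,\n",
                     "  target BV/TV %.1f%%, Tb thickness %g um, %d adipocytes, ",
                     "noise sd %g GL, seed %d\n"),
              x$image_height_px, x$image_width_px, x$pixel_size_um,
              x$cortical_width_um[1], x$cortical_width_um[2],
              x$trabecular_target_bvtv_pct, x$trabecular_thickness_um,
              x$adipocyte_count, x$gray_noise_sd, x$seed))
  invisible(x)
}

# YAML round trip for specs (CLI and pipeline config).
write_section_spec <- function(spec, path) {
  x <- unclass(spec)
  x$mineralization_mixture <- lapply(x$mineralization_mixture, as.list)
  if (!is.null(x$cartilage_peak)) x$cartilage_peak <- as.list(x$cartilage_peak)
  x$standards_patch_gray <- as.list(x$standards_patch_gray)
  x$surface_fractions <- as.list(x$surface_fractions)
  yaml::write_yaml(x, path)
  invisible(path)
}

read_section_spec <- function(path) {
  section_spec_from_list(yaml::read_yaml(path))
}

# Build a section_spec from a plain list (YAML config block), applying
# defaults for absent fields.
section_spec_from_list <- function(x) {
  stopifnot(is.list(x))
  num_triple <- function(v) {
    if (is.null(v)) return(NULL)
    out <- unlist(v)
    if (is.null(names(out)) || !all(c("mean", "sd", "weight") %in% names(out)))
      names(out) <- c("mean", "sd", "weight")[seq_along(out)]
    out
  }
  args <- x
  if (!is.null(args$mineralization_mixture))
    args$mineralization_mixture <- lapply(args$mineralization_mixture, num_triple)
  args$cartilage_peak <- num_triple(args$cartilage_peak)
  for (fld in c("standards_patch_gray", "surface_fractions",
                "cortical_width_um", "adipocyte_area_um2_range"))
    if (!is.null(args[[fld]])) args[[fld]] <- unlist(args[[fld]])
  known <- names(formals(section_spec))
  do.call(section_spec, args[intersect(names(args), known)])
}
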