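# Synthetic transiliac section generator.  The geometry model is
# deliberately simple (this is test scaffolding, not electron-matter
# physics): two wavy cortical plates, randomly oriented trabecular strips
# trimmed to a target BV/TV by iterative erosion/dilation, osteoid seams
# and surface annotations stamped on randomly chosen boundary arcs, and
# elliptical adipocytes rejection-sampled into the marrow.  The gray image
# is synthesized by inverting the same two-anchor linear calibration that
# the analysis side fits, which makes the calibration round trip testable
# to machine precision on noiseless images.

PHASE_CODES <- c(marrow = 0L, mineralized_bone = 1L, osteoid = 2L,
                 adipocyte = 3L, mineralized_cartilage = 4L,
                 calibration_standard = 5L)

# width (px) of the marrow margin strip holding the calibration patches
MARGIN_PX <- 36L
PATCH_PX <- 22L

#' Construct a phase label map
#'
#' @param labels integer matrix with codes 0 marrow, 1 mineralized bone,
#'   2 osteoid, 3 adipocyte, 4 mineralized cartilage, 5 calibration patch.
#' @param surface_annotations list with integer vectors `osteoblast_covered`,
#'   `osteoclast_covered`, `eroded` of linear pixel indices into `labels`;
#'   every annotated pixel must be 8-adjacent to a mineralized-bone pixel.
#' @param pixel_size_um pixel edge length, micrometers.
#' @return An object of class `phase_label_map`.
#' @export
phase_label_map <- function(labels,
                            surface_annotations = list(
                              osteoblast_covered = integer(0),
                              osteoclast_covered = integer(0),
                              eroded = integer(0)),
                            pixel_size_um = 1.8) {
  stopifnot(is.matrix(labels))
  storage.mode(labels) <- "integer"
  if (!all(labels %in% PHASE_CODES))
    stop("label codes restricted to {0,1,2,3,4,5}", call. = FALSE)
  need <- c("osteoblast_covered", "osteoclast_covered", "eroded")
  if (!all(need %in% names(surface_annotations)))
    stop("surface_annotations needs osteoblast_covered, osteoclast_covered, eroded",
         call. = FALSE)
  near_bone <- dilate_mask(matrix(labels %in% c(1L, 4L), nrow(labels)), 8L)
  for (nm in need) {
    idx <- surface_annotations[[nm]]
    if (length(idx) && !all(near_bone[idx]))
      stop("annotation pixels must be 8-adjacent to mineralized bone", call. = FALSE)
  }
  structure(list(labels = labels,
                 surface_annotations = surface_annotations[need],
                 pixel_size_um = pixel_size_um),
            class = "phase_label_map")
}

#' @export
print.phase_label_map <- function(x, ...) {
  tab <- table(factor(x$labels, levels = PHASE_CODES, labels = names(PHASE_CODES)))
  cat(sprintf("phase label map: %d x %d px, %.3g um/px\n",
              nrow(x$labels), ncol(x$labels), x$pixel_size_um))
  print(tab)
  invisible(x)
}

# rasterize an ellipse; returns linear indices (column-major)
ellipse_indices <- function(nr, nc, ci, cj, a, b, theta) {
  r <- ceiling(max(a, b)) + 1L
  ii <- max(1L, floor(ci - r)):min(nr, ceiling(ci + r))
  jj <- max(1L, floor(cj - r)):min(nc, ceiling(cj + r))
  di <- outer(ii - ci, rep(1, length(jj)))
  dj <- outer(rep(1, length(ii)), jj - cj)
  u <- (di * cos(theta) + dj * sin(theta)) / a
  v <- (-di * sin(theta) + dj * cos(theta)) / b
  inside <- u * u + v * v <= 1
  cbind(rep(ii, length(jj)), rep(jj, each = length(ii)))[as.vector(inside), , drop = FALSE]
}

# rasterize a thick segment (stadium shape): pixels within t/2 of the segment
strip_mask_add <- function(mask, ci, cj, theta, len, thick) {
  nr <- nrow(mask); nc <- ncol(mask)
  h <- len / 2; r <- thick / 2
  ex <- cos(theta); ey <- sin(theta)
  pad <- ceiling(h + r)
  ii <- max(1L, floor(ci - pad)):min(nr, ceiling(ci + pad))
  jj <- max(1L, floor(cj - pad)):min(nc, ceiling(cj + pad))
  di <- outer(ii - ci, rep(1, length(jj)))
  dj <- outer(rep(1, length(ii)), jj - cj)
  tpar <- pmin(pmax(di * ex + dj * ey, -h), h)
  d2 <- (di - tpar * ex)^2 + (dj - tpar * ey)^2
  sub <- mask[ii, jj, drop = FALSE]
  sub[d2 <= r * r] <- TRUE
  mask[ii, jj] <- sub
  mask
}

# sample from a Gaussian mixture given a 3 x k matrix (mean, sd, weight)
sample_mixture <- function(n, comp) {
  if (n == 0L) return(numeric(0))
  k <- sample.int(ncol(comp), n, replace = TRUE, prob = comp["weight", ])
  pmin(pmax(rnorm(n, comp["mean", k], comp["sd", k]), 0), CA_SATURATION_WTPCT)
}

# pick m pixels from idx clustered around n_anchors random anchors
select_near_anchors <- function(idx, dims, m, n_anchors = 12L) {
  n <- length(idx)
  if (m <= 0L || n == 0L) return(integer(0))
  if (m >= n) return(idx)
  anchors <- idx[sample.int(n, min(n_anchors, n))]
  ai <- (anchors - 1L) %% dims[1] + 1L; aj <- (anchors - 1L) %/% dims[1] + 1L
  bi <- (idx - 1L) %% dims[1] + 1L;     bj <- (idx - 1L) %/% dims[1] + 1L
  d2 <- outer(bi, ai, "-")^2 + outer(bj, aj, "-")^2
  dmin <- do.call(pmin, as.data.frame(d2))
  idx[order(dmin, idx)[seq_len(m)]]
}

#' Simulate a transiliac bone cross-section
#'
#' Generates a qBEI-style gray-level image, a Goldner-style phase label map
#' and the noiseless ground truth for the section described by `spec`.
#' Identical `(spec, seed)` pairs give bit-identical output.
#'
#' The noiseless ground-truth calcium map is defined on the quantized gray
#' grid: sampled calcium values are mapped to gray levels through the
#' inverse calibration, rounded to integers, and mapped back.  The
#' quantization step is tiny relative to any biological scale (about
#' 0.0009 wt% Ca with the default 16-bit anchors) and makes the
#' fit/apply calibration round trip exact on noiseless images.
#'
#' @param spec a [section_spec()].
#' @param seed RNG seed; defaults to `spec$seed`.
#' @return A list of class `section_simulation` with elements `image`
#'   (a [qbei_image()]), `phases` (a [phase_label_map()]) and `truth`
#'   (class `section_ground_truth`: `true_calcium_map`,
#'   `true_phase_area_um2`, `true_bmdd_params`, `true_adipocyte_areas_um2`,
#'   `mineralized`, `compartments`, `spec_echo`).
#' @export
simulate_section <- function(spec, seed = spec$seed) {
  validate_section_spec(spec)
  with_seed(seed, simulate_section_impl(spec))
}

simulate_section_impl <- function(spec) {
  H <- spec$image_height_px; W <- spec$image_width_px
  px <- spec$pixel_size_um
  labels <- matrix(PHASE_CODES[["marrow"]], H, W)
  maxval <- 2^spec$bit_depth - 1

  tissue_cols <- if (W > MARGIN_PX + 8L) (MARGIN_PX + 1L):W else 1:W
  margin_cols <- setdiff(1:W, tissue_cols)

  ## cortical plates with wavy endosteal boundaries
  w1 <- spec$cortical_width_um[1] / px
  w2 <- spec$cortical_width_um[2] / px
  wave <- function(w) {
    amp <- 0.08 * w
    ph <- runif(2, 0, 2 * pi)
    x <- seq_len(W) / W
    pmax(4, round(w + amp * sin(2 * pi * 2 * x + ph[1]) +
                    0.5 * amp * sin(2 * pi * 5 * x + ph[2])))
  }
  d1 <- wave(w1); d2 <- wave(w2)
  bone <- matrix(FALSE, H, W)
  cortex1 <- matrix(FALSE, H, W)
  cortex2 <- matrix(FALSE, H, W)
  for (j in tissue_cols) {
    cortex1[seq_len(min(d1[j], H)), j] <- TRUE
    cortex2[max(1L, H - d2[j] + 1L):H, j] <- TRUE
  }
  cortex2 <- cortex2 & !cortex1
  bone <- cortex1 | cortex2

  ## trabecular compartment between the plates
  trab <- matrix(FALSE, H, W)
  trab[, tissue_cols] <- TRUE
  trab <- trab & !cortex1 & !cortex2
  n_trab <- sum(trab)

  ## trabecular strips, then erosion/dilation toward the target BV/TV
  target <- spec$trabecular_target_bvtv_pct / 100
  t_px <- spec$trabecular_thickness_um / px
  tbone <- matrix(FALSE, H, W)
  frac <- 0
  guard <- 0L
  while (frac < target && guard < 5000L) {
    guard <- guard + 1L
    ci <- runif(1, 1, H); cj <- runif(1, min(tissue_cols), W)
    theta <- runif(1, 0, pi)
    len <- runif(1, 250, 600) / px
    tbone <- strip_mask_add(tbone, ci, cj, theta, len, t_px)
    tbone <- tbone & trab
    frac <- sum(tbone) / n_trab
  }
  repeat {
    if (frac > target) cand <- erode_mask(tbone, 8L) & trab
    else cand <- dilate_mask(tbone, 8L) & trab
    cfrac <- sum(cand) / n_trab
    if (abs(cfrac - target) < abs(frac - target)) {
      tbone <- cand; frac <- cfrac
    } else break
  }
  bone <- bone | tbone
  labels[bone] <- PHASE_CODES[["mineralized_bone"]]

  ## residual mineralized cartilage: contiguous patches inside the bone
  cart_idx <- integer(0)
  cp <- spec$cartilage_peak
  if (!is.null(cp) && cp[["weight"]] > 0) {
    bone_idx <- which(bone)
    cart_idx <- select_near_anchors(bone_idx, c(H, W),
                                    round(cp[["weight"]] * length(bone_idx)),
                                    n_anchors = 6L)
    labels[cart_idx] <- PHASE_CODES[["mineralized_cartilage"]]
  }

  ## osteoid seams on randomly chosen arcs of the bone surface
  roi_tissue <- matrix(FALSE, H, W); roi_tissue[, tissue_cols] <- TRUE
  bnd <- boundary_mask(bone, roi_tissue)
  os_idx <- integer(0)
  k_os <- spec$osteoid_seam_thickness_um / px
  if (spec$osteoid_surface_fraction > 0 && k_os > 0 && any(bnd)) {
    arc <- select_near_anchors(which(bnd), c(H, W),
                               round(spec$osteoid_surface_fraction * sum(bnd)))
    arc_mask <- matrix(FALSE, H, W); arc_mask[arc] <- TRUE
    near <- distance_transform(!arc_mask) <= k_os + 0.5
    os_idx <- which(near & !bone & roi_tissue & labels == 0L)
    labels[os_idx] <- PHASE_CODES[["osteoid"]]
  }

  ## adipocytes: non-overlapping ellipses in trabecular marrow
  adip_areas <- numeric(0)
  if (spec$adipocyte_count > 0L) {
    marrow_open <- trab & labels == 0L
    open_idx <- which(marrow_open)
    tries <- 0L; placed <- 0L
    while (placed < spec$adipocyte_count && tries < 400L * spec$adipocyte_count &&
           length(open_idx) > 0L) {
      tries <- tries + 1L
      area_px <- runif(1, spec$adipocyte_area_um2_range[1],
                       spec$adipocyte_area_um2_range[2]) / px^2
      q <- runif(1, 0.6, 1.0)
      a <- sqrt(area_px / (pi * q)); b <- q * a
      ctr <- open_idx[sample.int(length(open_idx), 1L)]
      ci <- (ctr - 1L) %% H + 1L; cj <- (ctr - 1L) %/% H + 1L
      epix <- ellipse_indices(H, W, ci, cj, a, b, runif(1, 0, pi))
      if (nrow(epix) == 0L) next
      lin <- (epix[, 2] - 1L) * H + epix[, 1]
      if (all(labels[lin] == 0L & trab[lin])) {
        labels[lin] <- PHASE_CODES[["adipocyte"]]
        adip_areas <- c(adip_areas, length(lin) * px^2)
        placed <- placed + 1L
        open_idx <- setdiff(open_idx, lin)
      }
    }
  }

  ## calibration standard patches in the marrow margin strip
  patch_c <- patch_al <- matrix(FALSE, H, W)
  if (length(margin_cols) >= PATCH_PX + 8L || length(margin_cols) > 0L) {
    pc <- margin_cols[seq_len(min(PATCH_PX, length(margin_cols))) + 4L]
    pc <- pc[!is.na(pc) & pc <= W]
    r1 <- 8L:min(8L + PATCH_PX - 1L, H)
    r2 <- max(1L, H - 8L - PATCH_PX + 1L):max(1L, H - 8L)
    patch_c[r1, pc] <- TRUE
    patch_al[r2, pc] <- TRUE
    patch_al <- patch_al & !patch_c
    labels[patch_c | patch_al] <- PHASE_CODES[["calibration_standard"]]
  }

  ## calcium assignment
  comp <- vapply(spec$mineralization_mixture,
                 function(x) x[c("mean", "sd", "weight")], numeric(3))
  ca <- matrix(0, H, W)
  bone_now <- labels == PHASE_CODES[["mineralized_bone"]]
  ca[bone_now] <- sample_mixture(sum(bone_now), comp)
  if (length(cart_idx))
    ca[cart_idx] <- pmin(pmax(rnorm(length(cart_idx), cp[["mean"]], cp[["sd"]]),
                              0), CA_SATURATION_WTPCT)
  if (length(os_idx))
    ca[os_idx] <- pmax(rnorm(length(os_idx), 1.2, 0.4), 0)  # unmineralized seam

  ## gray synthesis through the inverse calibration, quantized
  stdg <- spec$standards_patch_gray
  curve <- fit_calibration(calibration_standards(stdg[[1]], stdg[[2]]))
  g0 <- round((ca - curve$intercept) / curve$slope)
  g0 <- pmin(pmax(g0, 0), maxval)
  g0[patch_c] <- round(stdg[[1]])
  g0[patch_al] <- round(stdg[[2]])
  true_ca <- curve$intercept + curve$slope * g0
  true_ca[true_ca < 0] <- 0

  gray <- g0
  if (spec$gray_noise_sd > 0)
    gray <- pmin(pmax(round(g0 + rnorm(length(g0), 0, spec$gray_noise_sd)), 0),
                 maxval)
  dim(gray) <- c(H, W)
  storage.mode(gray) <- "integer"

  ## surface annotations on the final mineralized surface
  mineralized <- labels %in% c(1L, 4L); dim(mineralized) <- c(H, W)
  bnd_all <- which(boundary_mask(mineralized, labels != 5L))
  n_bnd <- length(bnd_all)
  remaining <- bnd_all
  take <- function(frac) {
    sel <- select_near_anchors(remaining, c(H, W), round(frac * n_bnd))
    remaining <<- setdiff(remaining, sel)
    sel
  }
  sf <- spec$surface_fractions
  ann <- list(osteoblast_covered = take(sf[["osteoblast"]]),
              osteoclast_covered = take(sf[["osteoclast"]]),
              eroded = take(sf[["eroded"]]))

  phases <- phase_label_map(labels, ann, px)
  image <- qbei_image(gray, px)

  ## ground truth
  areas <- vapply(PHASE_CODES, function(code) sum(labels == code) * px^2,
                  numeric(1))
  marrow_mask <- (labels == 0L | labels == 3L) & roi_tissue
  compartments <- list(trabecular = trab, cortex1 = cortex1, cortex2 = cortex2,
                       marrow = marrow_mask)
  truth <- structure(
    list(true_calcium_map = true_ca,
         true_phase_area_um2 = areas,
         true_adipocyte_areas_um2 = adip_areas,
         mineralized = mineralized,
         compartments = compartments,
         true_bmdd_params = NULL,
         spec_echo = spec),
    class = "section_ground_truth")
  truth$true_bmdd_params <- true_parameters(truth, compartments)

  structure(list(image = image, phases = phases, truth = truth),
            class = "section_simulation")
}

#' @export
print.section_simulation <- function(x, ...) {
  cat("synthetic transiliac section\n")
  print(x$image)
  a <- x$truth$true_phase_area_um2
  cat(sprintf("  true BV/TV (trabecular): %.2f%%; %d adipocytes; phases [um^2]:\n",
              100 * sum(x$truth$mineralized & x$truth$compartments$trabecular) /
                max(1, sum(x$truth$compartments$trabecular)),
              length(x$truth$true_adipocyte_areas_um2)))
  print(round(a))
  invisible(x)
}

#' Exhaustive (histogram-free) BMDD parameters from ground truth
#'
#' The simulator-side oracle: statistics are computed directly from the
#' noiseless calcium values of every mineralized pixel, with no binning.
#' CaMean, CaLow and CaHigh are exact sample statistics; CaPeak and CaWidth
#' are taken from a Gaussian kernel density estimate (the mode and its full
#' width at half maximum), or are the common value and 0 for a degenerate
#' (constant) compartment.
#'
#' @param truth a `section_ground_truth` (or any list with elements
#'   `true_calcium_map` and `mineralized`).
#' @param compartments named list of logical compartment masks; defaults to
#'   the masks stored in `truth`.
#' @param t_low,t_high CaLow/CaHigh thresholds, wt% Ca (17.68 and 25.30, the
#'   5th/95th percentiles of the adult trabecular reference BMDD).
#' @return Named list of [bmdd_parameters] objects, one per nonempty
#'   compartment (empty compartments are dropped).  Errors if every
#'   compartment is empty.
#' @export
true_parameters <- function(truth, compartments = truth$compartments,
                            t_low = 17.68, t_high = 25.30) {
  stopifnot(!is.null(truth$true_calcium_map), !is.null(truth$mineralized))
  dims <- dim(truth$true_calcium_map)
  out <- list()
  for (nm in names(compartments)) {
    m <- compartments[[nm]]
    if (is.null(m)) next
    if (!identical(dim(m), dims))
      stop("compartment mask outside image bounds", call. = FALSE)
    v <- truth$true_calcium_map[m & truth$mineralized]
    if (length(v) == 0L) next
    out[[nm]] <- exhaustive_bmdd_params(v, t_low, t_high)
  }
  if (length(out) == 0L)
    stop("undefined statistics: all compartment masks are empty", call. = FALSE)
  out
}

exhaustive_bmdd_params <- function(v, t_low = 17.68, t_high = 25.30) {
  if (length(v) == 0L) stop("undefined statistics: empty compartment", call. = FALSE)
  if (diff(range(v)) < 1e-12) {
    peak <- v[1]; width <- 0
  } else {
    d <- density(v, n = 2048)
    peak <- d$x[which.max(d$y)]
    width <- fwhm_linear(d$x, d$y)
  }
  new_bmdd_parameters(ca_mean_wtpct = mean(v),
                      ca_peak_wtpct = peak,
                      ca_width_wtpct = width,
                      ca_low_pct_area = 100 * mean(v < t_low),
                      ca_high_pct_area = 100 * mean(v > t_high),
                      t_low = t_low, t_high = t_high,
                      n_pixels = length(v))
}

#' Compartment masks of a simulated section
#'
#' @param truth a `section_ground_truth`.
#' @return Named list of logical masks: `trabecular`, `cortex1`, `cortex2`,
#'   `marrow`.
#' @export
compartment_masks <- function(truth) {
  stopifnot(inherits(truth, "section_ground_truth"))
  truth$compartments
}

#' Write a simulated section to disk
#'
#' The image is written as 16-bit (or 8-bit) grayscale PGM, the label map
#' as 8-bit PGM, compartment masks as 8-bit PGMs, the ground truth as JSON
#' and the generating spec as YAML.
#'
#' @param sim a `section_simulation` from [simulate_section()].
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_section <- function(sim, dir) {
  stopifnot(inherits(sim, "section_simulation"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  spec <- sim$truth$spec_echo
  write_pgm(sim$image$gray, file.path(dir, "qbei.pgm"),
            maxval = 2^spec$bit_depth - 1)
  write_pgm(sim$phases$labels, file.path(dir, "phases.pgm"), maxval = 255L)
  for (nm in names(sim$truth$compartments))
    write_mask_pgm(sim$truth$compartments[[nm]],
                   file.path(dir, paste0("mask_", nm, ".pgm")))
  ann <- lapply(sim$phases$surface_annotations, as.integer)
  truth <- sim$truth
  jsonlite::write_json(
    list(true_phase_area_um2 = as.list(truth$true_phase_area_um2),
         true_adipocyte_areas_um2 = truth$true_adipocyte_areas_um2,
         true_bmdd_params = lapply(truth$true_bmdd_params, unclass),
         surface_annotations = ann),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  write_section_spec(spec, file.path(dir, "spec.yaml"))
  invisible(dir)
}
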