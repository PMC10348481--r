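# Two-dimensional bone histomorphometry in Parfitt nomenclature.
# Structural indices come from the mineralized mask of the qBEI image;
# osteoid and cell-surface indices come from the Goldner-style phase label
# map.  Surfaces are one-pixel-wide boundary sets; ROI cut edges are open
# (a trabecula truncated by the field edge has no surface there).

#' Structural histomorphometric indices
#'
#' * `bv_tv_pct`: mineralized area / trabecular compartment area, percent.
#' * `tb_th_um`: trabecular thickness under the 2D plate model,
#'   `2 * area / perimeter`.
#' * `tb_n_per_mm`: trabecular number, `(BV/TV fraction) / Tb.Th`, per mm;
#'   the plate-model identity `Tb.N * Tb.Th = BV/TV` holds by construction.
#' * `ct_wd_mm`: cortical width, twice the mean distance-transform ridge
#'   value along the cortical medial axis, averaged over available
#'   cortices, reported in millimeters.
#'
#' With `tb_th_method = "dt"` trabecular thickness is instead estimated as
#' twice the mean distance-transform ridge value of the trabecular mask (a
#' cross-check; the plate identity then no longer holds exactly).
#'
#' @param mineralized logical mask of mineralized pixels.
#' @param masks a [compartment_masks_set()] (or named list with at least
#'   `trabecular`; `cortex1`/`cortex2` enable `ct_wd_mm`).
#' @param pixel_size_um pixel edge length, micrometers.
#' @param tb_th_method `"plate"` (default, 2A/P) or `"dt"`.
#' @return An object of class `structural_indices`.
#' @export
structural_indices <- function(mineralized, masks, pixel_size_um,
                               tb_th_method = c("plate", "dt")) {
  tb_th_method <- match.arg(tb_th_method)
  stop_if_not_scalar_num(pixel_size_um, "pixel_size_um", lower = 1e-9)
  mineralized <- as_mask(mineralized)
  trab <- as_mask(masks$trabecular, dim(mineralized))
  if (!any(trab)) stop("empty trabecular mask", call. = FALSE)
  tb_bone <- mineralized & trab
  bv_tv <- 100 * sum(tb_bone) / sum(trab)

  if (!any(tb_bone)) {
    tb_th <- NA_real_; tb_n <- NA_real_
  } else if (all(tb_bone == trab)) {
    # fully mineralized compartment: BV/TV 100%, no surface, thickness
    # undefined under the plate model
    tb_th <- NA_real_; tb_n <- NA_real_
  } else {
    area_um2 <- sum(tb_bone) * pixel_size_um^2
    per_um <- perimeter_length(tb_bone, trab) * pixel_size_um
    if (per_um <= 0)
      stop("degenerate geometry: nonzero bone area with zero perimeter",
           call. = FALSE)
    tb_th <- if (tb_th_method == "plate") 2 * area_um2 / per_um
    else ridge_thickness(tb_bone) * pixel_size_um
    tb_n <- (bv_tv / 100) / tb_th * 1000  # per mm
  }

  ct <- c(cortex1 = NA_real_, cortex2 = NA_real_)
  for (nm in c("cortex1", "cortex2")) {
    cm <- masks[[nm]]
    if (is.null(cm)) next
    cb <- mineralized & as_mask(cm, dim(mineralized))
    if (any(cb)) ct[nm] <- ridge_thickness(cb) * pixel_size_um
  }
  ct_wd_mm <- if (all(is.na(ct))) NA_real_ else mean(ct, na.rm = TRUE) / 1000

  structure(list(bv_tv_pct = bv_tv, tb_th_um = tb_th, tb_n_per_mm = tb_n,
                 ct_wd_mm = ct_wd_mm, ct_wd_per_cortex_um = ct,
                 tb_th_method = tb_th_method),
            class = "structural_indices")
}

# twice the mean Euclidean distance-transform value over the ridge (local
# maxima of the distance map): a medial-axis thickness estimator
ridge_thickness <- function(mask) {
  # pad with background so a plate cut by the image edge (e.g. the
  # periosteal side of a cortex) is measured two-sided, not doubled
  nr <- nrow(mask); nc <- ncol(mask)
  padded <- matrix(FALSE, nr + 2L, nc + 2L)
  padded[2:(nr + 1L), 2:(nc + 1L)] <- mask
  d <- distance_transform(padded)[2:(nr + 1L), 2:(nc + 1L)]
  ridge <- mask
  for (k in seq_len(nrow(NEIGH8)))
    ridge <- ridge & d >= shift_mat(d, NEIGH8[k, 1], NEIGH8[k, 2], 0)
  ridge <- ridge & d > 0
  if (!any(ridge)) return(2 * max(d))
  2 * mean(d[ridge])
}

#' @export
print.structural_indices <- function(x, ...) {
  cat(sprintf("BV/TV %.2f%%, Tb.Th %.1f um, Tb.N %.2f /mm, Ct.Wd %s mm\n",
              x$bv_tv_pct, x$tb_th_um, x$tb_n_per_mm,
              ifelse(is.na(x$ct_wd_mm), "NA", sprintf("%.2f", x$ct_wd_mm))))
  invisible(x)
}

# bone surface helpers over a phase label map ---------------------------

bone_mask_of <- function(phases) {
  m <- phases$labels %in% c(1L, 4L)
  dim(m) <- dim(phases$labels)
  m
}

tissue_roi_of <- function(phases) {
  m <- phases$labels != 5L
  dim(m) <- dim(phases$labels)
  m
}

#' Osteoid indices from a phase label map
#'
#' `OV/BV` is the osteoid share of total bone area, `OS/BS` the share of
#' the bone surface in contact with osteoid (boundary pixels 8-adjacent to
#' an osteoid pixel), and `O.Th` the mean seam thickness, osteoid area per
#' unit contact length.  With no osteoid all three are 0.
#'
#' @param phases a [phase_label_map()].
#' @return An object of class `osteoid_indices` with fields `o_th_um`,
#'   `os_bs_pct`, `ov_bv_pct`.
#' @export
osteoid_indices <- function(phases) {
  stopifnot(inherits(phases, "phase_label_map"))
  px <- phases$pixel_size_um
  bone <- bone_mask_of(phases)
  if (!any(bone)) stop("no bone in the section", call. = FALSE)
  ost <- phases$labels == 2L; dim(ost) <- dim(phases$labels)
  a_ost <- sum(ost) * px^2
  a_bone <- sum(bone) * px^2
  ov_bv <- 100 * a_ost / (a_ost + a_bone)
  bnd <- boundary_mask(bone, tissue_roi_of(phases))
  touching <- bnd & dilate_mask(ost, 8L)
  n_bnd <- sum(bnd)
  os_bs <- if (n_bnd == 0L) 0 else 100 * sum(touching) / n_bnd
  o_th <- if (sum(touching) == 0L) 0 else a_ost / (sum(touching) * px)
  structure(list(o_th_um = o_th, os_bs_pct = os_bs, ov_bv_pct = ov_bv),
            class = "osteoid_indices")
}

#' @export
print.osteoid_indices <- function(x, ...) {
  cat(sprintf("O.Th %.2f um, OS/BS %.2f%%, OV/BV %.2f%%\n",
              x$o_th_um, x$os_bs_pct, x$ov_bv_pct))
  invisible(x)
}

#' Cell-surface indices from annotated surfaces
#'
#' Each index is the annotated share of the total bone surface, in percent
#' of boundary pixels: osteoblast-covered (Ob.S/BS), osteoclast-covered
#' (Oc.S/BS) and eroded (ES/BS) surface.  If an annotation layer is `NULL`
#' (missing, as opposed to empty) the index is reported `"not evaluable"`.
#'
#' @param phases a [phase_label_map()].
#' @return An object of class `surface_indices` with fields `ob_s_bs_pct`,
#'   `oc_s_bs_pct`, `es_bs_pct`; each a percentage or `"not evaluable"`.
#' @export
surface_indices <- function(phases) {
  stopifnot(inherits(phases, "phase_label_map"))
  bone <- bone_mask_of(phases)
  bnd <- boundary_mask(bone, tissue_roi_of(phases))
  n_bnd <- sum(bnd)
  one <- function(idx) {
    if (is.null(idx)) return("not evaluable")
    if (n_bnd == 0L) return(0)
    100 * sum(bnd[idx]) / n_bnd
  }
  ann <- phases$surface_annotations
  structure(list(ob_s_bs_pct = one(ann$osteoblast_covered),
                 oc_s_bs_pct = one(ann$osteoclast_covered),
                 es_bs_pct = one(ann$eroded)),
            class = "surface_indices")
}

#' @export
print.surface_indices <- function(x, ...) {
  f <- function(v) if (is.character(v)) v else sprintf("%.2f%%", v)
  cat(sprintf("Ob.S/BS %s, Oc.S/BS %s, ES/BS %s\n",
              f(x$ob_s_bs_pct), f(x$oc_s_bs_pct), f(x$es_bs_pct)))
  invisible(x)
}
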