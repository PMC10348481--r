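# Shared fixtures, all generated in code.

# small, fast default-world section (noisy)
small_spec <- function(adipocyte_count = 25L, ...) {
  section_spec(image_height_px = 500L, image_width_px = 420L,
               adipocyte_count = adipocyte_count, ...)
}

# same geometry without detector noise
small_spec0 <- function(...) small_spec(gray_noise_sd = 0, ...)

# a calcium map with given values everywhere (uniform or supplied matrix)
uniform_map <- function(value, nr = 20, nc = 20, pixel_size_um = 1.8) {
  calcium_map(matrix(value, nr, nc), pixel_size_um = pixel_size_um)
}

# phase label map of a full-width horizontal bone strip with an osteoid
# seam of `seam_px` rows on its top face; pixel size in um
strip_phases <- function(nr, nc, bone_rows, seam_px = 0, pixel_size_um = 2) {
  labels <- matrix(0L, nr, nc)
  labels[bone_rows, ] <- 1L
  if (seam_px > 0)
    labels[(min(bone_rows) - seam_px):(min(bone_rows) - 1L), ] <- 2L
  phase_label_map(labels, pixel_size_um = pixel_size_um)
}

ctr_of <- function(h) (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2

# rectangular "adipocyte" region helper: stamps a wpx x hpx rectangle of
# label 3 with its top-left corner at (r0, c0)
stamp_rect <- function(labels, r0, c0, hpx, wpx, code = 3L) {
  labels[r0:(r0 + hpx - 1L), c0:(c0 + wpx - 1L)] <- code
  labels
}
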