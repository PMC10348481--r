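# geometry oracles: axis-aligned strips of known width in a known ROI,
# where BV/TV, Tb.Th and Tb.N have closed forms

test_that("full-width strips recover BV/TV exactly and Tb.Th within 5%", {
  px <- 2  # um; 1 x 1 mm ROI = 500 x 500 px
  for (w_um in c(50, 100, 200)) {
    wpx <- w_um / px
    mineralized <- matrix(FALSE, 500, 500)
    mineralized[101:(100 + wpx), ] <- TRUE
    masks <- list(trabecular = matrix(TRUE, 500, 500))
    st <- structural_indices(mineralized, masks, px)
    expect_equal(st$bv_tv_pct, 100 * wpx / 500)        # exact pixel counting
    expect_lt(abs(st$tb_th_um - w_um) / w_um, 0.05)
    # plate-model identity to machine precision
    expect_equal(st$tb_n_per_mm * st$tb_th_um / 1000, st$bv_tv_pct / 100,
                 tolerance = 1e-12)
    expect_lt(abs(st$tb_n_per_mm - 1000 * (wpx / 500) / w_um) /
                (1000 * (wpx / 500) / w_um), 0.05)
  }
})

test_that("degenerate structural inputs error or saturate as declared", {
  masks <- list(trabecular = matrix(TRUE, 50, 50))
  st <- structural_indices(matrix(TRUE, 50, 50), masks, 2)
  expect_equal(st$bv_tv_pct, 100)
  empty <- structural_indices(matrix(FALSE, 50, 50), masks, 2)
  expect_equal(empty$bv_tv_pct, 0)
  expect_true(is.na(empty$tb_th_um))
  expect_error(structural_indices(matrix(TRUE, 50, 50),
                                  list(trabecular = matrix(FALSE, 50, 50)), 2),
               "empty trabecular")
})

test_that("cortical width is recovered from band geometry", {
  mineralized <- matrix(FALSE, 300, 400)
  mineralized[1:60, ] <- TRUE          # 60 px band
  mineralized[261:300, ] <- TRUE       # 40 px band
  masks <- list(trabecular = {
    m <- matrix(FALSE, 300, 400); m[61:260, ] <- TRUE; m
  },
  cortex1 = { m <- matrix(FALSE, 300, 400); m[1:60, ] <- TRUE; m },
  cortex2 = { m <- matrix(FALSE, 300, 400); m[261:300, ] <- TRUE; m })
  st <- structural_indices(mineralized, masks, 2)
  # ridge estimator: band of W px gives ~W (+1 px half-open bias)
  expect_lt(abs(st$ct_wd_per_cortex_um[["cortex1"]] - 120) / 120, 0.05)
  expect_lt(abs(st$ct_wd_per_cortex_um[["cortex2"]] - 80) / 80, 0.05)
  expect_equal(st$ct_wd_mm,
               mean(st$ct_wd_per_cortex_um) / 1000)
})

test_that("osteoid indices match the seam geometry oracle", {
  # bone strip rows 81:120 (40 px), seam 10 px on the top face, px = 2 um
  ph <- strip_phases(200, 300, 81:120, seam_px = 10, pixel_size_um = 2)
  oi <- osteoid_indices(ph)
  expect_equal(oi$os_bs_pct, 50)                 # one of two long faces
  expect_equal(oi$o_th_um, 20)                   # 10 px * 2 um
  a_ost <- 10 * 300; a_bone <- 40 * 300
  expect_equal(oi$ov_bv_pct, 100 * a_ost / (a_ost + a_bone))
})

test_that("osteoid indices degenerate cases", {
  ph <- strip_phases(100, 200, 41:60, seam_px = 0)
  oi <- osteoid_indices(ph)
  expect_equal(oi$o_th_um, 0)
  expect_equal(oi$os_bs_pct, 0)
  expect_equal(oi$ov_bv_pct, 0)

  # osteoid area equal to bone area -> OV/BV = 50%
  labels <- matrix(0L, 100, 200)
  labels[41:60, ] <- 1L
  labels[21:40, ] <- 2L
  oi2 <- osteoid_indices(phase_label_map(labels, pixel_size_um = 2))
  expect_equal(oi2$ov_bv_pct, 50)
  expect_error(osteoid_indices(phase_label_map(matrix(0L, 10, 10))), "no bone")
})

test_that("surface indices are boundary-share percentages", {
  labels <- matrix(0L, 120, 150)
  labels[41:80, ] <- 1L
  bone <- labels == 1L; dim(bone) <- dim(labels)
  bnd <- which(osteosect:::boundary_mask(bone))
  # full coverage and empty coverage
  ph_full <- phase_label_map(labels, list(osteoblast_covered = bnd,
                                          osteoclast_covered = integer(0),
                                          eroded = integer(0)))
  si <- surface_indices(ph_full)
  expect_equal(si$ob_s_bs_pct, 100)
  expect_equal(si$oc_s_bs_pct, 0)
  expect_equal(si$es_bs_pct, 0)
  # missing layer -> not evaluable
  ph_na <- phase_label_map(labels, list(osteoblast_covered = NULL,
                                        osteoclast_covered = integer(0),
                                        eroded = integer(0)))
  expect_identical(surface_indices(ph_na)$ob_s_bs_pct, "not evaluable")
})

test_that("simulator-stamped osteoblast coverage of 25% is recovered", {
  spec <- small_spec(surface_fractions = c(osteoblast = 0.25,
                                           osteoclast = 0.011, eroded = 0.148))
  sim <- simulate_section(spec, seed = 19)
  si <- surface_indices(sim$phases)
  expect_lt(abs(si$ob_s_bs_pct - 25), 2)
})

test_that("ratio indices are invariant to pixel-size rescaling", {
  ph1 <- strip_phases(120, 160, 51:80, seam_px = 6, pixel_size_um = 1.8)
  # same geometry, each pixel split 2x2, half the pixel size
  up <- function(m) m[rep(seq_len(nrow(m)), each = 2),
                      rep(seq_len(ncol(m)), each = 2)]
  ph2 <- phase_label_map(up(ph1$labels), pixel_size_um = 0.9)
  o1 <- osteoid_indices(ph1); o2 <- osteoid_indices(ph2)
  expect_lt(abs(o1$ov_bv_pct - o2$ov_bv_pct), 1e-9)
  expect_lt(abs(o1$os_bs_pct - o2$os_bs_pct), 1)
  expect_lt(abs(o1$o_th_um - o2$o_th_um), 1)
  m1 <- ph1$labels == 1L; dim(m1) <- dim(ph1$labels)
  m2 <- ph2$labels == 1L; dim(m2) <- dim(ph2$labels)
  s1 <- structural_indices(m1, list(trabecular = matrix(TRUE, 120, 160)), 1.8)
  s2 <- structural_indices(m2, list(trabecular = matrix(TRUE, 240, 320)), 0.9)
  expect_equal(s1$bv_tv_pct, s2$bv_tv_pct)
  expect_lt(abs(s1$tb_th_um - s2$tb_th_um) / s1$tb_th_um, 0.02)
})

test_that("BV/TV on simulated labels equals the simulator's mineralized fraction", {
  sim <- simulate_section(small_spec0(), seed = 29)
  masks <- sim$truth$compartments
  st <- structural_indices(sim$truth$mineralized, masks,
                           sim$image$pixel_size_um)
  expect_equal(st$bv_tv_pct,
               100 * sum(sim$truth$mineralized & masks$trabecular) /
                 sum(masks$trabecular))
})
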