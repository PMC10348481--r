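test_that("identical (spec, seed) gives bit-identical output", {
  spec <- small_spec()
  a <- simulate_section(spec, seed = 11)
  b <- simulate_section(spec, seed = 11)
  expect_identical(a$image$gray, b$image$gray)
  expect_identical(a$phases$labels, b$phases$labels)
  expect_identical(a$phases$surface_annotations, b$phases$surface_annotations)
  expect_identical(a$truth$true_calcium_map, b$truth$true_calcium_map)
  c <- simulate_section(spec, seed = 12)
  expect_false(identical(a$image$gray, c$image$gray))
})

test_that("per-phase areas are consistent and sum to the image area", {
  sim <- simulate_section(small_spec(), seed = 2)
  spec <- sim$truth$spec_echo
  areas <- sim$truth$true_phase_area_um2
  expect_true(all(areas >= 0))
  expect_equal(sum(areas),
               spec$image_height_px * spec$image_width_px * spec$pixel_size_um^2)
  # label map and truth agree pixel by pixel
  expect_equal(unname(areas[["adipocyte"]]),
               sum(sim$phases$labels == 3L) * spec$pixel_size_um^2)
  expect_equal(sum(sim$truth$true_adipocyte_areas_um2),
               unname(areas[["adipocyte"]]))
})

test_that("adipocyte_count = 0 yields no label-3 pixels and zero area", {
  sim <- simulate_section(small_spec(adipocyte_count = 0L), seed = 5)
  expect_equal(unname(sim$truth$true_phase_area_um2[["adipocyte"]]), 0)
  expect_false(any(sim$phases$labels == 3L))
})

test_that("impossible geometry is rejected as an invalid spec", {
  expect_error(section_spec(image_height_px = 200, cortical_width_um = c(300, 300)),
               class = "osteosect_invalid_spec")
  expect_error(section_spec(mineralization_mixture = list(
    a = c(mean = 22, sd = 1, weight = 0.7), b = c(mean = 20, sd = 1, weight = 0.4))),
    class = "osteosect_invalid_spec")
  expect_error(section_spec(mineralization_mixture = list(
    a = c(mean = 45, sd = 1, weight = 1))), class = "osteosect_invalid_spec")
  expect_error(section_spec(trabecular_target_bvtv_pct = 0),
               class = "osteosect_invalid_spec")
  expect_error(section_spec(standards_patch_gray = c(200, 100)),
               class = "osteosect_invalid_spec")
})

test_that("realized trabecular BV/TV is within 3 points of the target", {
  for (target in c(9.6, 17.7, 22.3)) {
    sim <- simulate_section(small_spec0(trabecular_target_bvtv_pct = target),
                            seed = 31)
    got <- 100 * sum(sim$truth$mineralized & sim$truth$compartments$trabecular) /
      sum(sim$truth$compartments$trabecular)
    expect_lt(abs(got - target), 3)
  }
})

test_that("noiseless mineralized calcium matches the mixture mean (>= 1e5 px)", {
  mix <- list(lamellar = c(mean = 23.4, sd = 1.55, weight = 0.85),
              woven = c(mean = 20.3, sd = 2.0, weight = 0.15))
  sim <- simulate_section(small_spec0(mineralization_mixture = mix), seed = 8)
  v <- sim$truth$true_calcium_map[sim$truth$mineralized &
                                    sim$phases$labels == 1L]
  expect_gte(length(v), 1e5)
  mix_mean <- sum(vapply(mix, function(x) x[["mean"]] * x[["weight"]], 0))
  expect_lt(abs(mean(v) - mix_mean) / mix_mean, 0.005)
})

test_that("label codes, annotations and cartilage behave as declared", {
  spec <- small_spec(cartilage_peak = c(mean = 27.5, sd = 0.8, weight = 0.05))
  sim <- simulate_section(spec, seed = 21)
  expect_true(all(sim$phases$labels %in% 0:5))
  expect_gt(sum(sim$phases$labels == 4L), 0)
  # every annotation pixel 8-adjacent to mineralized bone (constructor
  # enforces it; re-check directly)
  bone <- sim$phases$labels %in% c(1L, 4L)
  dim(bone) <- dim(sim$phases$labels)
  near <- osteosect:::dilate_mask(bone, 8L)
  for (idx in sim$phases$surface_annotations)
    expect_true(all(near[idx]))
  # annotation sets are pairwise disjoint
  ann <- sim$phases$surface_annotations
  expect_length(intersect(ann$osteoblast_covered, ann$osteoclast_covered), 0)
  expect_length(intersect(ann$osteoblast_covered, ann$eroded), 0)
})

test_that("true_parameters is exact on constructed degenerate maps", {
  mk_truth <- function(vals, mineralized = NULL) {
    m <- if (is.null(mineralized)) matrix(TRUE, nrow(vals), ncol(vals))
    else mineralized
    list(true_calcium_map = vals, mineralized = m,
         compartments = list(all = matrix(TRUE, nrow(vals), ncol(vals))))
  }
  u <- matrix(22, 30, 30)
  p <- true_parameters(mk_truth(u))$all
  expect_equal(p$ca_mean_wtpct, 22)
  expect_equal(p$ca_peak_wtpct, 22)
  expect_equal(p$ca_width_wtpct, 0)

  lo <- matrix(15, 30, 30)  # all below 17.68
  p <- true_parameters(mk_truth(lo))$all
  expect_equal(p$ca_low_pct_area, 100)
  expect_equal(p$ca_high_pct_area, 0)

  two <- matrix(c(20, 24), 30, 30)  # 50/50 two-valued
  p <- true_parameters(mk_truth(two))$all
  expect_equal(p$ca_mean_wtpct, 22)

  empty <- matrix(FALSE, 30, 30)
  expect_error(true_parameters(mk_truth(u, empty)), "undefined statistics")
})

test_that("write_section round-trips image, labels and masks on disk", {
  dir <- withr::local_tempdir()
  sim <- simulate_section(small_spec(adipocyte_count = 5L), seed = 4)
  write_section(sim, dir)
  img <- read_pgm(file.path(dir, "qbei.pgm"))
  expect_identical(img, matrix(as.integer(sim$image$gray),
                               nrow(sim$image$gray)))
  lab <- read_pgm(file.path(dir, "phases.pgm"))
  expect_identical(lab, sim$phases$labels)
  trab <- osteosect:::read_mask_pgm(file.path(dir, "mask_trabecular.pgm"))
  expect_identical(trab, sim$truth$compartments$trabecular)
  spec2 <- osteosect:::read_section_spec(file.path(dir, "spec.yaml"))
  expect_equal(spec2$trabecular_target_bvtv_pct,
               sim$truth$spec_echo$trabecular_target_bvtv_pct)
})
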