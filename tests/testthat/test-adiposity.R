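test_that("the 525 um^2 minimum-size filter is exact", {
  # three rectangular regions of exactly 600, 550 and 300 um^2 (px = 1 um)
  labels <- matrix(0L, 200, 200)
  labels <- stamp_rect(labels, 20, 20, 24, 25)    # 600 um^2
  labels <- stamp_rect(labels, 80, 80, 22, 25)    # 550 um^2
  labels <- stamp_rect(labels, 150, 150, 15, 20)  # 300 um^2
  ph <- phase_label_map(labels, pixel_size_um = 1)
  res <- detect_adipocytes(ph, params = adipocyte_params())
  expect_equal(res$count, 2L)
  expect_equal(res$adipocyte_area_um2, 1150)
  expect_equal(sort(res$areas_um2), c(550, 600))
  expect_equal(nrow(res$regions), 3L)
  expect_equal(sum(res$regions$kept), 2L)
  expect_equal(res$fraction_pct, 100 * 1150 / res$marrow_area_um2)
})

test_that("degenerate inputs behave as declared", {
  labels <- matrix(0L, 50, 50)
  res <- detect_adipocytes(phase_label_map(labels))
  expect_equal(res$count, 0L)
  expect_equal(res$fraction_pct, 0)

  all_adip <- matrix(3L, 50, 50)
  res2 <- detect_adipocytes(phase_label_map(all_adip), pixel_size_um = 1.8)
  expect_equal(res2$fraction_pct, 100)

  expect_error(detect_adipocytes(phase_label_map(matrix(1L, 20, 20))),
               "empty marrow")
})

test_that("lowering the minimum area never decreases the count", {
  sim <- simulate_section(small_spec(adipocyte_count = 30L), seed = 41)
  cuts <- c(2000, 1200, 525, 100, 10)
  counts <- vapply(cuts, function(a)
    detect_adipocytes(sim$phases,
                      params = adipocyte_params(min_area_um2 = a))$count,
    integer(1))
  expect_true(all(diff(counts) >= 0))
  # conservation: fraction in [0, 100], adipocyte area <= marrow area
  res <- detect_adipocytes(sim$phases)
  expect_lte(res$adipocyte_area_um2, res$marrow_area_um2)
  expect_gte(res$fraction_pct, 0); expect_lte(res$fraction_pct, 100)
})

test_that("circularity rejects slivers but keeps roundish cells", {
  labels <- matrix(0L, 120, 400)
  labels <- stamp_rect(labels, 10, 10, 2, 350)    # 700 um^2 sliver (2 x 350)
  labels <- stamp_rect(labels, 60, 60, 26, 26)    # 676 um^2 square
  ph <- phase_label_map(labels, pixel_size_um = 1)
  res <- detect_adipocytes(ph, params = adipocyte_params(min_circularity = 0.4))
  expect_equal(res$count, 1L)
  expect_equal(res$areas_um2, 676)
  # with the circularity gate off both pass the area filter
  res2 <- detect_adipocytes(ph, params = adipocyte_params(min_circularity = 0))
  expect_equal(res2$count, 2L)
})

test_that("grayscale input thresholds bright regions inside the marrow", {
  gray <- matrix(50, 100, 100)
  gray[30:55, 30:55] <- 220   # bright 26 x 26 void
  marrow <- matrix(TRUE, 100, 100)
  res <- detect_adipocytes(gray, marrow_mask = marrow,
                           params = adipocyte_params(gray_threshold = 128),
                           pixel_size_um = 1)
  expect_equal(res$count, 1L)
  expect_equal(res$areas_um2, 676)
  expect_error(detect_adipocytes(gray, marrow_mask = marrow,
                                 params = adipocyte_params(),
                                 pixel_size_um = 1),
               "gray_threshold")
})

test_that("pixel-size halving moves the fraction by under 1 point", {
  labels <- matrix(0L, 150, 150)
  labels <- stamp_rect(labels, 30, 30, 30, 30)
  labels <- stamp_rect(labels, 90, 90, 28, 24)
  up <- labels[rep(seq_len(150), each = 2), rep(seq_len(150), each = 2)]
  f1 <- detect_adipocytes(phase_label_map(labels, pixel_size_um = 1.8))$fraction_pct
  f2 <- detect_adipocytes(phase_label_map(up, pixel_size_um = 0.9))$fraction_pct
  expect_lt(abs(f1 - f2), 1)
})

test_that("field aggregation pools areas and reports per-field fractions", {
  mk <- function(adip, marrow) structure(
    list(adipocyte_area_um2 = adip, marrow_area_um2 = marrow),
    class = "adipocyte_result")
  expect_equal(as.numeric(aggregate_fields(list(mk(20, 100), mk(20, 100),
                                                mk(20, 100)))), 20)
  pooled <- aggregate_fields(list(mk(10, 100), mk(30, 100)))
  expect_equal(as.numeric(pooled), 20)
  expect_equal(unname(attr(pooled, "per_field_pct")), c(10, 30))
  expect_equal(attr(pooled, "mean_of_fractions_pct"), 20)
  # unequal marrow areas: pooled-areas is the headline, mean differs
  pooled2 <- aggregate_fields(list(mk(10, 50), mk(10, 150)))
  expect_equal(as.numeric(pooled2), 10)
  expect_equal(attr(pooled2, "mean_of_fractions_pct"), mean(c(20, 10 / 1.5)))
  expect_error(aggregate_fields(list()), "empty")
})

test_that("detection recovers the simulator's drawn adipocyte fraction", {
  sim <- simulate_section(small_spec(adipocyte_count = 40L), seed = 43)
  marrow <- sim$truth$compartments$marrow
  res <- detect_adipocytes(sim$phases, marrow_mask = marrow)
  truth_frac <- 100 * sum(sim$truth$true_adipocyte_areas_um2) /
    (sum(marrow) * sim$phases$pixel_size_um^2)
  expect_lt(abs(res$fraction_pct - truth_frac) / truth_frac, 0.02)
})
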