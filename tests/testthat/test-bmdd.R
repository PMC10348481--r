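test_that("mineralized_mask thresholds valid pixels only", {
  expect_true(all(mineralized_mask(uniform_map(22), 5.2)))
  expect_false(any(mineralized_mask(uniform_map(2), 5.2)))
  half <- calcium_map(matrix(rep(c(2, 22), each = 10), 20, 20))
  mm <- mineralized_mask(half, 5.2)
  expect_equal(mm, half$wtpct_ca == 22)
  expect_error(mineralized_mask(uniform_map(22), 0), "t0")
})

test_that("compute_bmdd normalizes to 100 and bins on the wt% scale", {
  h <- compute_bmdd(uniform_map(22), matrix(TRUE, 20, 20))
  expect_equal(sum(h$area_pct), 100)
  expect_equal(sum(h$area_pct > 0), 1L)       # one occupied bin
  ctr <- (h$bin_edges[-1] + h$bin_edges[-length(h$bin_edges)]) / 2
  expect_lt(abs(ctr[which.max(h$area_pct)] - 22), h$bin_width / 2 + 1e-12)

  set.seed(42)
  vals <- matrix(pmax(rnorm(600 * 600, 21, 1.5), 0), 600, 600)
  h2 <- compute_bmdd(calcium_map(vals), matrix(TRUE, 600, 600))
  expect_equal(sum(h2$area_pct), 100)
  expect_lt(abs(sum(h2$area_pct * ctr_of(h2)) / 100 - mean(vals)), 0.01)

  expect_error(compute_bmdd(uniform_map(22), matrix(FALSE, 20, 20)), "empty")
})

test_that("bmdd_parameters handles degenerate and two-bin histograms", {
  # single occupied bin centered at 22.0 (bin width 0.5, grid offset 0.25)
  edges <- seq(0.25, 40.25, by = 0.5)
  p <- numeric(length(edges) - 1L); p[44] <- 100
  h <- bmdd_histogram(edges, p)
  expect_equal(ctr_of(h)[44], 22)
  par <- bmdd_parameters(h)
  expect_equal(par$ca_mean_wtpct, 22)
  expect_equal(par$ca_peak_wtpct, 22)
  expect_equal(par$ca_width_wtpct, 0.5)
  expect_equal(par$ca_high_pct_area, 0)

  # equal mass at bin centers 20.0 and 24.0 only: CaMean 22 by symmetry,
  # CaPeak 20 under the lowest-bin tie-break
  p2 <- numeric(length(edges) - 1L)
  p2[40] <- 50; p2[48] <- 50
  h2 <- bmdd_histogram(edges, p2)
  expect_equal(ctr_of(h2)[c(40, 48)], c(20, 24))
  par2 <- bmdd_parameters(h2)
  expect_equal(par2$ca_mean_wtpct, 22)
  expect_equal(par2$ca_peak_wtpct, 20)
  expect_lte(par2$ca_low_pct_area + par2$ca_high_pct_area, 100)
})

test_that("all-zero histograms and bad bins are rejected", {
  edges <- seq(0, 40, by = 0.5)
  expect_error(bmdd_histogram(edges, numeric(length(edges) - 1L)), "sum to 100")
  expect_error(bmdd_histogram(c(0, 1, 3), c(50, 50)), "constant width")
})

test_that("Gaussian sections recover closed-form FWHM and tail areas", {
  set.seed(7)
  n <- 1000 * 1000
  sigma <- 1.5
  vals <- matrix(rnorm(n, 21, sigma), 1000, 1000)
  h <- compute_bmdd(calcium_map(vals), matrix(TRUE, 1000, 1000))
  par <- bmdd_parameters(h)
  expect_lt(abs(par$ca_mean_wtpct - 21), 0.01)
  fwhm <- 2 * sqrt(2 * log(2)) * sigma
  expect_lt(abs(par$ca_width_wtpct - fwhm) / fwhm, 0.02)
  expect_lt(abs(par$ca_low_pct_area - 100 * pnorm((17.68 - 21) / sigma)), 0.3)
  expect_lt(abs(par$ca_high_pct_area - 100 * pnorm((21 - 25.30) / sigma)), 0.3)
})

test_that("CaWidth tracks 2.3548 sigma for sigma >= 3 bin widths", {
  set.seed(15)
  for (sigma in c(0.51, 1.0, 2.0)) {  # >= 3 x 0.17
    vals <- matrix(rnorm(4e5, 22, sigma), 500, 800)
    par <- bmdd_parameters(compute_bmdd(calcium_map(vals), matrix(TRUE, 500, 800)))
    expect_lt(abs(par$ca_width_wtpct - 2.3548 * sigma) / (2.3548 * sigma), 0.02)
  }
})

test_that("shifting all pixels by a bin-commensurate delta shifts CaMean/CaPeak exactly", {
  sim <- simulate_section(small_spec0(), seed = 17)
  cur <- osteosect:::fit_from_patches(sim$image, sim$phases)
  cm <- apply_calibration(sim$image, cur)
  mm <- mineralized_mask(cm) & sim$truth$compartments$trabecular
  delta <- 2 * 0.17
  shifted <- calcium_map(cm$wtpct_ca + delta, cm$valid_mask, cm$pixel_size_um)
  p0 <- bmdd_parameters(compute_bmdd(cm, mm))
  p1 <- bmdd_parameters(compute_bmdd(shifted, mm))
  expect_equal(p1$ca_mean_wtpct, p0$ca_mean_wtpct + delta, tolerance = 1e-9)
  expect_equal(p1$ca_peak_wtpct, p0$ca_peak_wtpct + delta, tolerance = 1e-9)
})

test_that("histogram pipeline agrees with the exhaustive ground-truth oracle", {
  # sharp mixture: isolates discretization error from mode-estimator noise
  mix <- list(a = c(mean = 21.0, sd = 0, weight = 0.6),
              b = c(mean = 24.5, sd = 0, weight = 0.4))
  sim <- simulate_section(small_spec0(mineralization_mixture = mix), seed = 23)
  cur <- osteosect:::fit_from_patches(sim$image, sim$phases)
  cm <- apply_calibration(sim$image, cur)
  masks <- sim$truth$compartments
  res <- compartment_bmdd(cm, masks)
  truth <- sim$truth$true_bmdd_params
  for (nm in c("trabecular", "cortex1", "cortex2")) {
    expect_lt(abs(res[[nm]]$ca_mean_wtpct - truth[[nm]]$ca_mean_wtpct), 0.17 / 2)
    expect_lt(abs(res[[nm]]$ca_peak_wtpct - truth[[nm]]$ca_peak_wtpct), 0.17 / 2)
    expect_lt(abs(res[[nm]]$ca_low_pct_area - truth[[nm]]$ca_low_pct_area), 0.2)
    expect_lt(abs(res[[nm]]$ca_high_pct_area - truth[[nm]]$ca_high_pct_area), 0.2)
  }
  # smooth mixture: CaMean and the thresholded tails still agree
  sim2 <- simulate_section(small_spec0(), seed = 24)
  cur2 <- osteosect:::fit_from_patches(sim2$image, sim2$phases)
  res2 <- compartment_bmdd(apply_calibration(sim2$image, cur2),
                           sim2$truth$compartments)
  truth2 <- sim2$truth$true_bmdd_params
  expect_lt(abs(res2$trabecular$ca_mean_wtpct - truth2$trabecular$ca_mean_wtpct),
            0.17 / 2)
  expect_lt(abs(res2$trabecular$ca_low_pct_area -
                  truth2$trabecular$ca_low_pct_area), 0.2)
})

test_that("cortical averaging follows the arithmetic-mean rule", {
  mk <- function(...) osteosect:::new_bmdd_parameters(...)
  p <- mk(20, 21, 4, 10, 1)
  same <- cortical_mean(p, p)
  for (f in c("ca_mean_wtpct", "ca_peak_wtpct", "ca_width_wtpct",
              "ca_low_pct_area", "ca_high_pct_area"))
    expect_identical(same[[f]], p[[f]])
  # patient per-cortex CaMean values from the clinical workup: 20.31, 19.09
  p1 <- mk(20.31, 21.83, 4.68, 15.24, 0.37)
  p2 <- mk(19.09, 20.45, 4.51, 24.90, 0.02)
  avg <- cortical_mean(p1, p2)
  expect_equal(avg$ca_mean_wtpct, 19.70)
  expect_equal(avg$ca_width_wtpct, (4.68 + 4.51) / 2)
  # single cortex: summary equals it
  expect_equal(cortical_mean(p1)$ca_mean_wtpct, 20.31)
})

test_that("empty compartments are flagged not evaluable, not fatal", {
  cm <- uniform_map(22, 40, 40)
  masks <- list(trabecular = rbind(matrix(TRUE, 20, 40), matrix(FALSE, 20, 40)),
                cortex1 = rbind(matrix(FALSE, 20, 40), matrix(TRUE, 20, 40)),
                cortex2 = matrix(FALSE, 40, 40))
  res <- compartment_bmdd(cm, masks)
  expect_s3_class(res$trabecular, "bmdd_parameters")
  expect_identical(res$cortex2, "not evaluable")
  expect_equal(res$cortical$ca_mean_wtpct, res$cortex1$ca_mean_wtpct)
})
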