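# Bone mineralization density distribution (BMDD): the area-fraction
# histogram of calcium weight percent over mineralized bone, and its five
# canonical parameters.  CaLow/CaHigh thresholds 17.68 and 25.30 wt% Ca are
# the 5th and 95th percentiles of the adult trabecular reference BMDD.

T_LOW_WTPCT <- 17.68
T_HIGH_WTPCT <- 25.30
DEFAULT_BIN_WIDTH <- 0.17  # conventional qBEI binning granularity
DEFAULT_T0 <- 5.2          # mineralized-vs-soft-tissue cut, wt% Ca

#' Mineralized-pixel mask of a calcium map
#'
#' Valid pixels whose calcium concentration exceeds `t0`.  The cut
#' separates mineralized matrix from osteoid, marrow and embedding; 5.2
#' wt% Ca is well below any mineralized bone value and well above soft
#' tissue.
#'
#' @param map a [calcium_map()].
#' @param t0 threshold in wt% Ca, inside `(0, saturation)`.
#' @return Logical matrix.
#' @export
mineralized_mask <- function(map, t0 = DEFAULT_T0) {
  stopifnot(inherits(map, "calcium_map"))
  stop_if_not_scalar_num(t0, "t0", lower = 1e-12, upper = map$saturation_wtpct)
  map$valid_mask & map$wtpct_ca > t0
}

#' Construct a BMDD histogram object
#'
#' @param bin_edges ascending, uniformly spaced bin edges, wt% Ca.
#' @param area_pct per-bin percentage of mineralized bone area; must sum to
#'   100 within 1e-6.
#' @param n_pixels number of pixels the histogram was built from.
#' @return An object of class `bmdd_histogram`.
#' @export
bmdd_histogram <- function(bin_edges, area_pct, n_pixels = NA_integer_) {
  stopifnot(length(bin_edges) == length(area_pct) + 1L)
  w <- diff(bin_edges)
  if (any(w <= 0) || diff(range(w)) > 1e-9 * mean(w))
    stop("bin edges must be ascending with constant width", call. = FALSE)
  if (abs(sum(area_pct) - 100) > 1e-6)
    stop("area percentages must sum to 100", call. = FALSE)
  structure(list(bin_edges = bin_edges, area_pct = area_pct,
                 n_pixels = n_pixels, bin_width = mean(w)),
            class = "bmdd_histogram")
}

#' Compute the BMDD histogram of a calcium map
#'
#' Bins the calcium values of the masked (mineralized) pixels on a fixed
#' grid anchored at 0 wt% Ca and normalizes to area percent.  Binning is
#' done on the calibrated wt% scale, never on raw gray levels, so gray and
#' calcium bins cannot alias.
#'
#' @param map a [calcium_map()].
#' @param mask logical pixel mask (typically from [mineralized_mask()]).
#' @param bin_width histogram bin width, wt% Ca.
#' @return A [bmdd_histogram()].
#' @export
compute_bmdd <- function(map, mask, bin_width = DEFAULT_BIN_WIDTH) {
  stopifnot(inherits(map, "calcium_map"))
  mask <- as_mask(mask, dim(map$wtpct_ca)) & map$valid_mask
  v <- map$wtpct_ca[mask]
  if (length(v) == 0L) stop("empty mask: no pixels to bin", call. = FALSE)
  stop_if_not_scalar_num(bin_width, "bin_width", lower = 1e-9)
  nbin <- ceiling((map$saturation_wtpct + 1e-9) / bin_width)
  edges <- seq(0, by = bin_width, length.out = nbin + 1L)
  idx <- pmin(pmax(floor(v / bin_width), 0), nbin - 1L) + 1L
  counts <- tabulate(idx, nbins = nbin)
  bmdd_histogram(edges, 100 * counts / sum(counts), n_pixels = length(v))
}

bin_centers <- function(hist) {
  (hist$bin_edges[-1] + hist$bin_edges[-length(hist$bin_edges)]) / 2
}

# full width at half maximum of a sampled curve by linear interpolation,
# measured at the half-maximum crossings nearest the global peak (the
# dominant mode of a multimodal curve)
fwhm_linear <- function(x, y) {
  m <- which.max(y)
  half <- y[m] / 2
  step <- x[2] - x[1]
  left <- x[1] - step / 2
  if (m > 1L) for (i in (m - 1L):1L) {
    if (y[i] < half) {
      left <- x[i] + (half - y[i]) / (y[i + 1L] - y[i]) * step
      break
    }
  }
  n <- length(y)
  right <- x[n] + step / 2
  if (m < n) for (i in (m + 1L):n) {
    if (y[i] < half) {
      right <- x[i - 1L] + (y[i - 1L] - half) / (y[i - 1L] - y[i]) * step
      break
    }
  }
  right - left
}

new_bmdd_parameters <- function(ca_mean_wtpct, ca_peak_wtpct, ca_width_wtpct,
                                ca_low_pct_area, ca_high_pct_area,
                                t_low = T_LOW_WTPCT, t_high = T_HIGH_WTPCT,
                                n_pixels = NA_integer_) {
  structure(list(ca_mean_wtpct = ca_mean_wtpct,
                 ca_peak_wtpct = ca_peak_wtpct,
                 ca_width_wtpct = ca_width_wtpct,
                 ca_low_pct_area = ca_low_pct_area,
                 ca_high_pct_area = ca_high_pct_area,
                 thresholds = c(t_low = t_low, t_high = t_high),
                 n_pixels = n_pixels),
            class = "bmdd_parameters")
}

#' @export
print.bmdd_parameters <- function(x, ...) {
  cat(sprintf(paste0("BMDD parameters: CaMean %.2f, CaPeak %.2f, CaWidth %.2f ",
                     "wt%% Ca; CaLow %.2f%%, CaHigh %.2f%% (thresholds %.2f/%.2f)\n"),
              x$ca_mean_wtpct, x$ca_peak_wtpct, x$ca_width_wtpct,
              x$ca_low_pct_area, x$ca_high_pct_area,
              x$thresholds[["t_low"]], x$thresholds[["t_high"]]))
  invisible(x)
}

# share of area_pct below / above a threshold, apportioning the straddling
# bin by linear sub-bin interpolation (removes bin-width sensitivity)
tail_area_pct <- function(hist, threshold, upper = FALSE) {
  e <- hist$bin_edges; p <- hist$area_pct
  lowfrac <- pmin(pmax((threshold - e[-length(e)]) / hist$bin_width, 0), 1)
  below <- sum(p * lowfrac)
  if (upper) sum(p) - below else below
}

#' The five canonical BMDD parameters of a histogram
#'
#' * `CaMean`: area-weighted mean calcium concentration (bin centers
#'   weighted by area percent).
#' * `CaPeak`: position of the most frequent calcium concentration.  With
#'   `peak_smooth = TRUE` a 3-bin moving average is applied before the
#'   argmax (a deterministic guard against single-bin noise); ties are
#'   broken toward the lowest bin center.
#' * `CaWidth`: full width at half maximum of the raw histogram, by linear
#'   interpolation between bin centers, measured at the crossings nearest
#'   the global peak.
#' * `CaLow` / `CaHigh`: percent of bone area below 17.68 / above 25.30
#'   wt% Ca, with the straddling bin apportioned linearly.
#'
#' @param hist a [bmdd_histogram()].
#' @param peak_smooth smooth the histogram over 3 bins before locating the
#'   peak.
#' @param t_low,t_high CaLow/CaHigh thresholds, wt% Ca.
#' @return A `bmdd_parameters` object.
#' @export
#' @examples
#' h <- bmdd_histogram(seq(0, 40, by = 0.5), {
#'   p <- numeric(80); p[45] <- 100; p  # all mass at 22.25 wt% Ca
#' })
#' bmdd_parameters(h)
bmdd_parameters <- function(hist, peak_smooth = TRUE,
                            t_low = T_LOW_WTPCT, t_high = T_HIGH_WTPCT) {
  stopifnot(inherits(hist, "bmdd_histogram"))
  p <- hist$area_pct
  if (all(p == 0)) stop("all-zero histogram", call. = FALSE)
  ctr <- bin_centers(hist)
  ca_mean <- sum(p * ctr) / sum(p)
  pk <- p
  if (peak_smooth) {
    n <- length(p)
    pk <- (c(0, p[-n]) + p + c(p[-1], 0)) / 3  # 3-bin moving average
  }
  # ties on the (smoothed) maximum: prefer the highest raw bin (so an
  # isolated spike keeps its own bin), then the lowest bin center
  mx <- which(pk == max(pk))
  if (length(mx) > 1L) mx <- mx[order(-p[mx], mx)]
  ca_peak <- ctr[mx[1L]]
  ca_width <- fwhm_linear(ctr, p)
  new_bmdd_parameters(ca_mean, ca_peak, ca_width,
                      tail_area_pct(hist, t_low, upper = FALSE),
                      tail_area_pct(hist, t_high, upper = TRUE),
                      t_low, t_high, hist$n_pixels)
}

#' Compartment masks container
#'
#' @param trabecular,cortex1,cortex2,marrow logical pixel masks; `cortex2`
#'   may be `NULL` when only one cortex is available.
#' @return A named list of class `compartment_masks_set`.
#' @export
compartment_masks_set <- function(trabecular, cortex1, cortex2 = NULL,
                                  marrow = NULL) {
  ms <- Filter(Negate(is.null),
               list(trabecular = trabecular, cortex1 = cortex1,
                    cortex2 = cortex2, marrow = marrow))
  dims <- dim(ms[[1]])
  ms <- lapply(ms, as_mask, dims = dims)
  pair_overlap <- 0L
  nm <- setdiff(names(ms), "marrow")
  for (i in seq_along(nm)) for (j in seq_along(nm)) if (i < j)
    pair_overlap <- pair_overlap + sum(ms[[nm[i]]] & ms[[nm[j]]])
  if (pair_overlap > 0L)
    stop("compartment masks must be pairwise disjoint", call. = FALSE)
  structure(ms, class = "compartment_masks_set")
}

#' Per-compartment BMDD with cortical averaging
#'
#' Evaluates the BMDD separately in the trabecular compartment and in each
#' cortical plate, then summarizes cortical bone as the arithmetic mean of
#' the two cortices' parameters (or the single cortex when only one is
#' available).  A compartment that is empty after mineralized masking is
#' reported as "not evaluable" (`NA` parameters) rather than failing.
#'
#' @param map a [calcium_map()].
#' @param masks a [compartment_masks_set()] (or plain named list of masks).
#' @param t0 mineralized threshold, wt% Ca.
#' @param bin_width histogram bin width, wt% Ca.
#' @param peak_smooth passed to [bmdd_parameters()].
#' @return List of class `compartment_bmdd` with elements `trabecular`,
#'   `cortex1`, `cortex2` (if provided), `cortical` (the summary) -- each a
#'   `bmdd_parameters` object or the string `"not evaluable"` -- plus
#'   `histograms`, the per-compartment [bmdd_histogram()]s.
#' @export
compartment_bmdd <- function(map, masks, t0 = DEFAULT_T0,
                             bin_width = DEFAULT_BIN_WIDTH,
                             peak_smooth = TRUE) {
  stopifnot(inherits(map, "calcium_map"))
  mm <- mineralized_mask(map, t0)
  comps <- intersect(c("trabecular", "cortex1", "cortex2"), names(masks))
  out <- list(); hists <- list()
  for (nm in comps) {
    cm <- as_mask(masks[[nm]], dim(map$wtpct_ca)) & mm
    if (!any(cm)) { out[[nm]] <- "not evaluable"; next }
    h <- compute_bmdd(map, cm, bin_width)
    hists[[nm]] <- h
    out[[nm]] <- bmdd_parameters(h, peak_smooth = peak_smooth)
  }
  cort <- Filter(function(x) inherits(x, "bmdd_parameters"),
                 out[intersect(c("cortex1", "cortex2"), names(out))])
  out$cortical <- if (length(cort) == 0L) "not evaluable"
  else cortical_mean(cort[[1]], if (length(cort) > 1L) cort[[2]])
  out$histograms <- hists
  structure(out, class = "compartment_bmdd")
}

#' Arithmetic mean of two cortices' BMDD parameters
#'
#' The cortical summary convention: each of the five parameters is averaged
#' arithmetically over the available cortices; with a single cortex the
#' summary equals its values.
#'
#' @param p1 `bmdd_parameters` of the first cortex.
#' @param p2 `bmdd_parameters` of the second cortex, or `NULL`.
#' @return A `bmdd_parameters` object.
#' @export
#' @examples
#' p1 <- osteosect:::new_bmdd_parameters(20.31, 21.83, 4.68, 15.24, 0.37)
#' p2 <- osteosect:::new_bmdd_parameters(19.09, 20.45, 4.51, 24.90, 0.02)
#' cortical_mean(p1, p2)$ca_mean_wtpct  # 19.70
cortical_mean <- function(p1, p2 = NULL) {
  stopifnot(inherits(p1, "bmdd_parameters"))
  if (is.null(p2)) return(p1)
  stopifnot(inherits(p2, "bmdd_parameters"))
  flds <- c("ca_mean_wtpct", "ca_peak_wtpct", "ca_width_wtpct",
            "ca_low_pct_area", "ca_high_pct_area")
  avg <- lapply(flds, function(f) (p1[[f]] + p2[[f]]) / 2)
  names(avg) <- flds
  do.call(new_bmdd_parameters, c(avg, list(
    t_low = p1$thresholds[["t_low"]], t_high = p1$thresholds[["t_high"]],
    n_pixels = sum(c(p1$n_pixels, p2$n_pixels), na.rm = TRUE))))
}

#' Write a BMDD histogram as CSV
#'
#' @param hist a [bmdd_histogram()].
#' @param path output CSV path (columns `bin_center`, `area_pct`).
#' @return `path`, invisibly.
#' @export
write_bmdd_csv <- function(hist, path) {
  write.csv(data.frame(bin_center = bin_centers(hist),
                       area_pct = hist$area_pct),
            path, row.names = FALSE)
  invisible(path)
}
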