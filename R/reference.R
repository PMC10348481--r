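# Pediatric reference ranges and comparison arithmetic.  Reference values
# are bundled verbatim as a versioned CSV; note they come from older
# children (structural/osteoid/surface indices: ages 1.5-6.9 years; BMDD:
# healthy children, n = 50), so for an infant sample the comparison flags
# the age mismatch rather than adjusting for it.

#' Bundled pediatric reference ranges
#'
#' @param path optional CSV path; defaults to the table shipped with the
#'   package.
#' @return Data frame with columns `parameter`, `compartment`, `group`,
#'   `kind` (`mean_sd`, `median_iqr` or `undefined`), `center`, `sd`,
#'   `q25`, `q75`, `unit`, `source_label`.
#' @export
reference_ranges <- function(path = NULL) {
  if (is.null(path))
    path <- system.file("extdata", "reference_ranges.csv",
                        package = "osteosect", mustWork = TRUE)
  read.csv(path, stringsAsFactors = FALSE)
}

#' Look up a single reference range
#'
#' @param parameter_name row name as printed in the clinical tables (e.g.
#'   `"Bone volume/tissue volume"`, `"CaMean"`).
#' @param compartment disambiguates BMDD rows (`"cancellous"` or
#'   `"cortical"`); ignored when unique.
#' @param references a data frame from [reference_ranges()].
#' @return A list of class `reference_range`.
#' @export
reference_range <- function(parameter_name, compartment = NULL,
                            references = reference_ranges()) {
  hit <- references[references$parameter == parameter_name, , drop = FALSE]
  if (!is.null(compartment))
    hit <- hit[hit$compartment == compartment, , drop = FALSE]
  if (nrow(hit) == 0L)
    stop("unknown parameter: ", parameter_name,
         if (!is.null(compartment)) paste0(" (", compartment, ")"),
         call. = FALSE)
  r <- as.list(hit[1L, ])
  if (r$kind == "mean_sd" && (is.na(r$sd) || r$sd <= 0))
    stop("invalid reference: mean_sd needs sd > 0", call. = FALSE)
  if (r$kind == "median_iqr" &&
      (is.na(r$q25) || is.na(r$q75) || r$q25 > r$center || r$center > r$q75))
    stop("invalid reference: need q25 <= median <= q75", call. = FALSE)
  class(r) <- "reference_range"
  r
}

#' Compare a measured value against a reference range
#'
#' For `mean_sd` references the z-score `(measured - center) / sd` is
#' computed and the value is classified against the interval center +/- 2
#' SD; for `median_iqr` references only the position relative to
#' `[q25, q75]` is reported.  The relative difference from the reference
#' center, `100 * (measured / center - 1)`, is always attached (reported,
#' never asserted).
#'
#' @param measured measured value, in the reference's unit.
#' @param range a [reference_range()] (or a row passed through it).
#' @return List of class `comparison_result`: `parameter_name`, `measured`,
#'   `z_score` (`NA` unless `mean_sd`), `position` (`"below"`, `"within"`,
#'   `"above"` or `"not defined"`), `percent_change_pct`,
#'   `interval_definition`.
#' @export
#' @examples
#' r <- reference_range("Bone volume/tissue volume")
#' compare_to_reference(9.6, r)  # z = -3.115, below
compare_to_reference <- function(measured, range) {
  stopifnot(inherits(range, "reference_range"))
  z <- NA_real_; pos <- "not defined"; defn <- "not defined"
  if (range$kind == "mean_sd") {
    z <- (measured - range$center) / range$sd
    lo <- range$center - 2 * range$sd; hi <- range$center + 2 * range$sd
    pos <- if (measured < lo) "below" else if (measured > hi) "above" else "within"
    defn <- "center +/- 2 SD"
  } else if (range$kind == "median_iqr") {
    pos <- if (measured < range$q25) "below"
    else if (measured > range$q75) "above" else "within"
    defn <- "interquartile range [q25, q75]"
  }
  structure(list(parameter_name = range$parameter,
                 measured = measured,
                 z_score = z,
                 position = pos,
                 percent_change_pct =
                   if (!is.na(range$center) && range$center != 0)
                     100 * (measured / range$center - 1) else NA_real_,
                 interval_definition = defn,
                 source_label = range$source_label),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat(sprintf("%s: measured %.3g -> %s (%s)%s\n", x$parameter_name,
              x$measured, x$position, x$interval_definition,
              if (!is.na(x$z_score)) sprintf(", z = %.3f", x$z_score) else ""))
  invisible(x)
}
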