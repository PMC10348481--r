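# Report assembly: one row per clinical-table parameter, grouped the way
# the standard transiliac workup tables are laid out (structural indices,
# static formation/resorption indices, marrow adiposity, BMDD per
# compartment), with reference comparison where a reference exists.
# Values are rounded to 2 decimals, the precision of the clinical tables;
# a JSON report therefore parses back to exactly the values it shows.

report_value <- function(x) if (is.null(x) || is.character(x) || is.na(x))
  NA_real_ else round(x, 2)

#' Assemble a section report
#'
#' Builds the full tabular report from whatever result blocks are
#' available; blocks that are `NULL` (not measured) or individual values
#' flagged `"not evaluable"` appear as such in the output rather than
#' failing.
#'
#' @param bmdd a [compartment_bmdd()] result (cancellous + cortical rows).
#' @param structural a [structural_indices()] result.
#' @param osteoid an [osteoid_indices()] result.
#' @param surface a [surface_indices()] result.
#' @param adiposity an [detect_adipocytes()] result, or the pooled
#'   percentage from [aggregate_fields()].
#' @param references data frame from [reference_ranges()].
#' @return Object of class `section_report`: a list with `rows` (data
#'   frame: `group`, `parameter`, `compartment`, `unit`, `value`,
#'   `z_score`, `position`, `reference`) and `meta`.
#' @export
build_report <- function(bmdd = NULL, structural = NULL, osteoid = NULL,
                         surface = NULL, adiposity = NULL,
                         references = reference_ranges()) {
  if (is.null(bmdd) && is.null(structural) && is.null(osteoid) &&
      is.null(surface) && is.null(adiposity))
    stop("empty input: no result block to report", call. = FALSE)

  rows <- list()
  add <- function(group, parameter, compartment, value) {
    ref <- references[references$parameter == parameter &
                        references$compartment == compartment, , drop = FALSE]
    z <- NA_real_; pos <- NA_character_; lab <- NA_character_
    v <- report_value(value)
    if (nrow(ref) == 1L && ref$kind != "undefined" && !is.na(v)) {
      cmp <- compare_to_reference(v, reference_range(parameter, compartment,
                                                     references))
      z <- round(cmp$z_score, 3); pos <- cmp$position; lab <- cmp$source_label
    }
    unit <- if (nrow(ref) == 1L) ref$unit else ""
    rows[[length(rows) + 1L]] <<- data.frame(
      group = group, parameter = parameter, compartment = compartment,
      unit = unit, value = v, z_score = z, position = pos, reference = lab,
      stringsAsFactors = FALSE)
  }

  add("structural", "Bone volume/tissue volume", "trabecular",
      structural$bv_tv_pct)
  add("structural", "Trabecular thickness", "trabecular", structural$tb_th_um)
  add("structural", "Trabecular number", "trabecular", structural$tb_n_per_mm)
  add("structural", "Cortical width", "cortical", structural$ct_wd_mm)
  add("osteoid", "Osteoid thickness", "trabecular", osteoid$o_th_um)
  add("osteoid", "Osteoid surface/bone surface", "trabecular",
      osteoid$os_bs_pct)
  add("osteoid", "Osteoid volume/bone volume", "trabecular", osteoid$ov_bv_pct)
  add("surface", "Osteoblast surface/bone surface", "trabecular",
      surface$ob_s_bs_pct)
  add("surface", "Osteoclast surface/bone surface", "trabecular",
      surface$oc_s_bs_pct)
  add("surface", "Eroded surface/bone surface", "trabecular", surface$es_bs_pct)
  adip_pct <- if (inherits(adiposity, "adipocyte_result"))
    adiposity$fraction_pct else if (is.numeric(adiposity)) as.numeric(adiposity)
  add("adiposity", "Adipocyte area/marrow area", "marrow", adip_pct)

  bmdd_fields <- c(CaMean = "ca_mean_wtpct", CaPeak = "ca_peak_wtpct",
                   CaWidth = "ca_width_wtpct", CaLow = "ca_low_pct_area",
                   CaHigh = "ca_high_pct_area")
  for (which_comp in c("cancellous", "cortical")) {
    p <- switch(which_comp, cancellous = bmdd$trabecular,
                cortical = bmdd$cortical)
    for (nm in names(bmdd_fields))
      add("bmdd", nm, which_comp,
          if (inherits(p, "bmdd_parameters")) p[[bmdd_fields[[nm]]]])
  }

  rows <- do.call(rbind, rows)
  structure(list(rows = rows,
                 meta = list(package = "osteosect",
                             version = as.character(utils::packageVersion("osteosect")),
                             note = paste("reference ranges are from older",
                                          "children; age mismatch is flagged,",
                                          "not adjusted for"))),
            class = "section_report")
}

#' @export
print.section_report <- function(x, ...) {
  df <- x$rows
  df$value <- ifelse(is.na(df$value), "Not evaluable", sprintf("%.2f", df$value))
  print(df[, c("group", "parameter", "compartment", "unit", "value",
               "z_score", "position")], row.names = FALSE)
  invisible(x)
}

#' Write a report as JSON and/or CSV
#'
#' Unmeasured values are rendered as `"Not evaluable"` in the CSV and as
#' `null` in the JSON.
#'
#' @param report a [build_report()] result.
#' @param json_path,csv_path output paths (`NULL` skips that format).
#' @return `report`, invisibly.
#' @export
write_report <- function(report, json_path = NULL, csv_path = NULL) {
  stopifnot(inherits(report, "section_report"))
  if (!is.null(json_path))
    jsonlite::write_json(list(rows = report$rows, meta = report$meta),
                         json_path, auto_unbox = TRUE, digits = NA,
                         na = "null", pretty = TRUE)
  if (!is.null(csv_path)) {
    df <- report$rows
    df$value <- ifelse(is.na(df$value), "Not evaluable",
                       sprintf("%.2f", df$value))
    write.csv(df, csv_path, row.names = FALSE)
  }
  invisible(report)
}

#' Read back a JSON report
#'
#' @param json_path path written by [write_report()].
#' @return A `section_report`.
#' @export
read_report <- function(json_path) {
  x <- jsonlite::read_json(json_path, simplifyVector = TRUE)
  structure(list(rows = x$rows, meta = x$meta), class = "section_report")
}
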