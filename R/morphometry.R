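# Comparative head/optic-nerve morphometry arithmetic and summaries.

# unit factors relative to mm
.length_units <- c(um = 1e-3, mm = 1, cm = 10, m = 1e3)

#' Head diameter from head width and height
#'
#' Defined as the arithmetic mean of head width and head height.
#'
#' @param width,height Head width and height in mm, > 0.
#' @return Head diameter in mm.
#' @export
head_diameter <- function(width, height) {
  if (any(!is.finite(c(width, height))) || any(c(width, height) <= 0)) {
    stop("head width and height must be positive")
  }
  (width + height) / 2
}

#' Head cross-sectional area from head diameter
#'
#' CSA = pi/4 * HD^2, treating the head cross-section as a circle of
#' diameter HD.
#'
#' @param hd Head diameter in mm, > 0.
#' @return Cross-sectional area in mm^2.
#' @export
head_csa <- function(hd) {
  if (any(!is.finite(hd)) || any(hd <= 0)) stop("head diameter must be positive")
  pi / 4 * hd^2
}

#' A measurement as a percentage of a reference dimension
#'
#' Computes 100 * value / reference after reconciling units. Units must be
#' stated explicitly when they differ (e.g. a skull thickness in um against
#' a head diameter in mm); silent unit mixing is the classic morphometry
#' table error.
#'
#' @param value Numeric measurement.
#' @param reference Reference measurement, > 0.
#' @param value_unit,reference_unit Length units, one of
#'   `"um"`, `"mm"`, `"cm"`, `"m"`. For already-commensurate quantities
#'   (e.g. mm^2 over mm^2) leave both at the default.
#' @return Percentage.
#' @export
relative_percent <- function(value, reference,
                             value_unit = "mm", reference_unit = "mm") {
  if (!value_unit %in% names(.length_units) ||
      !reference_unit %in% names(.length_units)) {
    stop("unknown unit; supported: ", paste(names(.length_units), collapse = ", "))
  }
  if (any(!is.finite(reference)) || any(reference <= 0)) {
    stop("reference must be positive")
  }
  factor <- .length_units[[value_unit]] / .length_units[[reference_unit]]
  100 * value * factor / reference
}

#' Estimate absolute optic-nerve depth from its relative depth
#'
#' Applies a relative nerve depth (percent of head diameter, from one data
#' set) to the head diameter of another specimen to estimate its absolute
#' nerve depth.
#'
#' @param relative_depth Nerve depth as percent of head diameter, > 0.
#' @param hd Head diameter in mm, > 0.
#' @return Estimated depth in mm (full precision; round at output time).
#' @export
estimate_on_depth <- function(relative_depth, hd) {
  if (any(!is.finite(c(relative_depth, hd))) || any(c(relative_depth, hd) <= 0)) {
    stop("relative depth and head diameter must be positive")
  }
  relative_depth / 100 * hd
}

#' Specimen morphometry fields recognised by [summarize_records()]
#' @export
specimen_fields <- c(
  "total_length_mm", "head_width_mm", "head_height_mm", "head_diameter_mm",
  "body_volume_mm3", "skull_thickness_um", "dermis_thickness_um",
  "on_depth_mm", "on_layers", "on_layer_thickness_um", "on_csa_mm2"
)

#' Mean and SD summaries of specimen records
#'
#' Per-field arithmetic mean and sample SD (n - 1 denominator), skipping
#' missing values and reporting the per-field n. Fields that are entirely
#' missing are dropped with a warning.
#'
#' @param records A data.frame of specimen records, one row per individual,
#'   numeric columns named as in [specimen_fields] (extra columns such as
#'   `species` are ignored unless requested).
#' @param fields Character vector of columns to summarise; defaults to all
#'   recognised fields present.
#' @return A data.frame with columns `field`, `mean`, `sd`, `n`. A field
#'   with a single present value gets `sd = NA`.
#' @export
summarize_records <- function(records, fields = NULL) {
  if (!nrow(records)) stop("records must be nonempty")
  if (is.null(fields)) fields <- intersect(specimen_fields, names(records))
  missing_cols <- setdiff(fields, names(records))
  if (length(missing_cols)) {
    stop("records lack columns: ", paste(missing_cols, collapse = ", "))
  }
  rows <- lapply(fields, function(f) {
    v <- records[[f]]
    v <- v[!is.na(v)]
    if (!length(v)) {
      warning("field '", f, "' is entirely missing; omitted")
      return(NULL)
    }
    data.frame(field = f, mean = mean(v),
               sd = if (length(v) > 1L) stats::sd(v) else NA_real_,
               n = length(v))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) stop("no field had any data")
  out
}
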