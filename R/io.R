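# CSV readers/writers for the package's tabular formats.
#
# One dialect throughout: comma-separated, UTF-8, "." decimal mark. Spectral
# curves carry their quantity in a key-value sidecar (`<file>.meta`) so a
# bare two-column CSV stays instrument-friendly.

read_numeric_csv <- function(path, expected_header) {
  if (!file.exists(path)) stop("input file not found: ", path)
  raw <- utils::read.csv(path, colClasses = "character", check.names = FALSE)
  if (!identical(names(raw), expected_header)) {
    stop(path, ": header must be '", paste(expected_header, collapse = ","),
         "', got '", paste(names(raw), collapse = ","), "'")
  }
  out <- lapply(names(raw), function(col) {
    v <- suppressWarnings(as.numeric(raw[[col]]))
    bad <- which(is.na(v) & !(raw[[col]] %in% c("NA", "")))
    if (length(bad)) {
      stop(path, ": non-numeric value '", raw[[col]][bad[1]],
           "' in column '", col, "' at data line ", bad[1] + 1L)
    }
    v
  })
  names(out) <- names(raw)
  as.data.frame(out, check.names = FALSE)
}

#' Read a spectral curve from CSV
#'
#' Expects the exact header `wavelength_nm,value`. The quantity is taken
#' from `quantity`, or else from a sidecar file `<path>.meta` containing
#' `key=value` lines (keys `quantity`, optionally `label`).
#'
#' @param path CSV file path.
#' @param quantity Optional quantity tag overriding the sidecar.
#' @return A [spectral_curve()].
#' @export
read_spectral_csv <- function(path, quantity = NULL) {
  df <- read_numeric_csv(path, c("wavelength_nm", "value"))
  w <- df$wavelength_nm
  if (anyNA(w)) stop(path, ": missing wavelengths")
  dup <- which(duplicated(w))
  if (length(dup)) {
    stop(path, ": duplicated wavelength ", w[dup[1]],
         " at data line ", dup[1] + 1L)
  }
  uns <- which(diff(w) < 0)
  if (length(uns)) {
    stop(path, ": wavelengths not sorted at data line ", uns[1] + 2L)
  }
  label <- NULL
  if (is.null(quantity)) {
    meta_path <- paste0(path, ".meta")
    if (file.exists(meta_path)) {
      meta <- read_keyvalue(meta_path)
      quantity <- meta[["quantity"]]
      label <- meta[["label"]]
    }
    if (is.null(quantity)) {
      stop(path, ": no quantity given and no sidecar '", meta_path, "'")
    }
  }
  spectral_curve(w, df$value, quantity, label = label)
}

#' Write a spectral curve to CSV (plus metadata sidecar)
#'
#' @param curve A [spectral_curve()].
#' @param path Output CSV path; a `<path>.meta` sidecar records quantity and
#'   label.
#' @return `path`, invisibly.
#' @export
write_spectral_csv <- function(curve, path) {
  assert_curve(curve)
  df <- data.frame(wavelength_nm = curve$wavelength, value = curve$value)
  utils::write.csv(format(df, digits = 17, scientific = NA, trim = TRUE),
                   path, row.names = FALSE, quote = FALSE)
  meta <- c(paste0("quantity=", curve$quantity),
            if (!is.null(curve$label)) paste0("label=", curve$label))
  writeLines(meta, paste0(path, ".meta"))
  invisible(path)
}

read_keyvalue <- function(path) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  kv <- strsplit(lines, "=", fixed = TRUE)
  bad <- lengths(kv) < 2L
  if (any(bad)) stop(path, ": malformed key=value line: ", lines[bad][1])
  stats::setNames(
    as.list(vapply(kv, function(x) paste(x[-1L], collapse = "="), "")),
    vapply(kv, `[[`, "", 1L)
  )
}

#' Read a depth series from a manifest
#'
#' The manifest CSV has header `depth_m,file`; files are resolved relative
#' to the manifest's directory and must all be photon-irradiance spectral
#' CSVs on one grid.
#'
#' @param path Manifest CSV path.
#' @return A [depth_series()].
#' @export
read_depth_series <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  man <- utils::read.csv(path, colClasses = c("numeric", "character"))
  if (!identical(names(man), c("depth_m", "file"))) {
    stop(path, ": manifest header must be 'depth_m,file'")
  }
  dir <- dirname(path)
  curves <- lapply(man$file, function(f) {
    read_spectral_csv(file.path(dir, f), quantity = "photon_irradiance")
  })
  depth_series(man$depth_m, curves)
}

#' Write a depth series as per-depth CSVs plus a manifest
#'
#' @param series A [depth_series()].
#' @param dir Output directory (created if needed).
#' @param prefix File-name prefix for the per-depth CSVs.
#' @return Manifest path, invisibly.
#' @export
write_depth_series <- function(series, dir, prefix = "irradiance") {
  if (!inherits(series, "depth_series")) stop("series must be a depth_series")
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  files <- sprintf("%s_%04.1fm.csv", prefix, series$depths)
  for (i in seq_along(files)) {
    write_spectral_csv(series$curves[[i]], file.path(dir, files[i]))
  }
  man <- data.frame(depth_m = series$depths, file = files)
  man_path <- file.path(dir, paste0(prefix, "_manifest.csv"))
  utils::write.csv(man, man_path, row.names = FALSE, quote = FALSE)
  invisible(man_path)
}

#' Read nerve-section layer measurements
#'
#' Header: `individual,side,distance_mm,layer_index,angle_deg,length_um`.
#'
#' @param path CSV path.
#' @return A data.frame with those columns.
#' @export
read_sections_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  need <- c("individual", "side", "distance_mm", "layer_index",
            "angle_deg", "length_um")
  if (!identical(names(df), need)) {
    stop(path, ": header must be '", paste(need, collapse = ","), "'")
  }
  num <- c("distance_mm", "layer_index", "angle_deg", "length_um")
  for (col in num) {
    if (!is.numeric(df[[col]])) {
      stop(path, ": column '", col, "' contains non-numeric values")
    }
  }
  if (any(df$length_um <= 0)) stop(path, ": layer lengths must be > 0")
  df
}

#' Write nerve-section layer measurements
#'
#' @param sections Data.frame with columns `distance_mm`, `layer_index`,
#'   `angle_deg`, `length_um` and optionally `individual`, `side` (filled
#'   with defaults when absent).
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_sections_csv <- function(sections, path) {
  if (is.null(sections$individual)) sections$individual <- "ind1"
  if (is.null(sections$side)) sections$side <- "L"
  cols <- c("individual", "side", "distance_mm", "layer_index",
            "angle_deg", "length_um")
  utils::write.csv(sections[, cols], path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

#' Read specimen morphometry records
#'
#' @param path CSV path with a `species` column plus numeric columns from
#'   [specimen_fields] (any subset).
#' @return A data.frame.
#' @export
read_morphometry_csv <- function(path) {
  if (!file.exists(path)) stop("input file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE)
  known <- intersect(specimen_fields, names(df))
  if (!length(known)) {
    stop(path, ": no recognised morphometry columns found")
  }
  for (col in known) {
    if (!is.numeric(df[[col]])) {
      stop(path, ": column '", col, "' contains non-numeric values")
    }
    if (any(df[[col]] <= 0, na.rm = TRUE)) {
      stop(path, ": column '", col, "' has non-positive values")
    }
  }
  df
}

#' Write specimen morphometry records
#'
#' @param records Data.frame of specimen records.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_morphometry_csv <- function(records, path) {
  utils::write.csv(records, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}
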