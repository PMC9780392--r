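#' Spectral collections as wide tibbles
#'
#' A spectral dataset is a tibble with one row per measured spectrum:
#' metadata columns first (typically `condition`, `day`, `fruit_id`,
#' `position`, `replicate`), then one numeric column per wavelength channel,
#' named by its centre in nanometres (e.g. `"1404.1"`). Every function in the
#' package takes and returns this shape, so calls chain with the pipe.
#'
#' @param meta Data frame of per-spectrum metadata (may have zero columns).
#' @param wavelengths Numeric vector of channel centres in nm, strictly
#'   increasing after sorting; rounded to 4 decimals for stable column names.
#' @param absorbance Numeric matrix, `nrow(meta)` rows by
#'   `length(wavelengths)` columns, unitless absorbance.
#' @return A tibble of class `spectra_tbl`.
#' @export
#' @examples
#' spectra_tbl(
#'   meta = data.frame(condition = "CF", day = 0),
#'   wavelengths = c(1400, 1410, 1420),
#'   absorbance = matrix(c(0.5, 0.6, 0.55), nrow = 1)
#' )
spectra_tbl <- function(meta, wavelengths, absorbance) {
  absorbance <- as.matrix(absorbance)
  meta <- tibble::as_tibble(meta)
  wavelengths <- round(as.numeric(wavelengths), 4)
  if (length(wavelengths) != ncol(absorbance)) {
    abort_aqua("`wavelengths` length must equal the absorbance column count.", "schema")
  }
  if (nrow(meta) != nrow(absorbance)) {
    abort_aqua("metadata row count must equal the absorbance row count.", "schema")
  }
  if (anyDuplicated(wavelengths)) {
    abort_aqua("wavelengths must be strictly increasing.", "schema")
  }
  ord <- order(wavelengths)
  wavelengths <- wavelengths[ord]
  absorbance <- absorbance[, ord, drop = FALSE]
  colnames(absorbance) <- wl_to_name(wavelengths)
  out <- dplyr::bind_cols(meta, tibble::as_tibble(absorbance))
  out <- new_spectra_tbl(out)
  validate_spectra(out)
  out
}

new_spectra_tbl <- function(x) {
  class(x) <- unique(c("spectra_tbl", class(tibble::as_tibble(x))))
  x
}

#' Coerce a data frame to a spectra tibble
#'
#' Columns whose names parse as numbers are taken to be wavelength channels;
#' all other columns are metadata.
#'
#' @param x A data frame.
#' @return A validated `spectra_tbl`.
#' @export
as_spectra_tbl <- function(x) {
  x <- tibble::as_tibble(x)
  wl_cols <- spc_wl_cols(x)
  if (length(wl_cols) == 0L) {
    abort_aqua("no wavelength columns found (numeric column names).", "schema")
  }
  spectra_tbl(
    meta = x[setdiff(names(x), wl_cols)],
    wavelengths = as.numeric(wl_cols),
    absorbance = as.matrix(x[wl_cols])
  )
}

# values are pre-rounded to 4 decimals, so default double formatting is exact
wl_to_name <- function(wl) as.character(wl)

is_wl_name <- function(x) grepl("^[0-9]+(\\.[0-9]+)?$", x)

spc_wl_cols <- function(ds) names(ds)[is_wl_name(names(ds))]

#' @rdname spectra_accessors
#' @export
spc_wavelengths <- function(ds) as.numeric(spc_wl_cols(ds))

#' Accessors for spectra tibbles
#'
#' `spc_wavelengths()` returns the channel centres in nm, `spc_matrix()` the
#' absorbance matrix (spectra by channels), and `spc_meta()` the metadata
#' columns.
#'
#' @param ds A `spectra_tbl` (or any data frame in the wide dialect).
#' @return A numeric vector, numeric matrix, or tibble respectively.
#' @name spectra_accessors
#' @export
spc_matrix <- function(ds) {
  cols <- spc_wl_cols(ds)
  m <- as.matrix(ds[cols])
  storage.mode(m) <- "double"
  m
}

#' @rdname spectra_accessors
#' @export
spc_meta <- function(ds) tibble::as_tibble(ds)[setdiff(names(ds), spc_wl_cols(ds))]

#' @rdname spectra_accessors
#' @param m Replacement absorbance matrix with matching dimensions.
#' @export
spc_set_matrix <- function(ds, m) {
  cols <- spc_wl_cols(ds)
  m <- as.matrix(m)
  colnames(m) <- cols
  ds[cols] <- tibble::as_tibble(m)
  new_spectra_tbl(ds)
}

validate_spectra <- function(ds) {
  wl <- spc_wavelengths(ds)
  if (length(wl) == 0L) abort_aqua("dataset has no wavelength columns.", "schema")
  if (anyDuplicated(wl) || is.unsorted(wl, strictly = TRUE)) {
    abort_aqua("wavelengths must be strictly increasing.", "schema")
  }
  m <- spc_matrix(ds)
  if (anyNA(m) || any(!is.finite(m))) {
    bad <- which(!is.finite(m), arr.ind = TRUE)[1, ]
    abort_aqua(
      sprintf("non-finite absorbance value at row %d, channel %s nm.", bad[1], wl[bad[2]]),
      "parse"
    )
  }
  meta <- spc_meta(ds)
  if ("day" %in% names(meta)) {
    d <- meta$day
    if (anyNA(d) || any(d < 0) || any(d != round(d))) {
      abort_aqua("`day` must be a non-negative integer storage-day label.", "schema")
    }
  }
  if ("replicate" %in% names(meta)) {
    r <- meta$replicate
    if (anyNA(r) || any(r < 1) || any(r != round(r))) {
      abort_aqua("`replicate` must be a positive integer.", "schema")
    }
  }
  invisible(ds)
}

design_key_cols <- c("condition", "day", "fruit_id", "position", "replicate")

#' Read a wide spectral table
#'
#' Reads a CSV in the wide dialect: metadata columns plus one column per
#' wavelength named by its nm value. An optional JSON sidecar (or named list)
#' maps file column names onto the canonical metadata names.
#'
#' @param path Path to a CSV file.
#' @param meta Character vector of metadata column names expected in the file
#'   (after applying `schema`). Default: every column whose name does not
#'   parse as a number.
#' @param schema Optional named character vector/list mapping canonical
#'   metadata names to file column names, or the path to a JSON file holding
#'   such a mapping.
#' @return A validated [spectra_tbl].
#' @export
read_spectra <- function(path, meta = NULL, schema = NULL) {
  if (!file.exists(path)) abort_aqua(sprintf("file not found: %s", path), "io")
  df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE,
                        name_repair = "minimal")
  if (!is.null(schema)) {
    if (is.character(schema) && length(schema) == 1L && file.exists(schema)) {
      schema <- jsonlite::read_json(schema, simplifyVector = TRUE)
    }
    schema <- unlist(schema)
    missing_src <- setdiff(unname(schema), names(df))
    if (length(missing_src) > 0L) {
      abort_aqua(sprintf("schema refers to absent column(s): %s",
                         paste(missing_src, collapse = ", ")), "schema")
    }
    names(df)[match(unname(schema), names(df))] <- names(schema)
  }
  if (is.null(meta)) {
    meta <- names(df)[!is_wl_name(names(df))]
  } else {
    absent <- setdiff(meta, names(df))
    if (length(absent) > 0L) {
      abort_aqua(sprintf("missing metadata column(s): %s",
                         paste(absent, collapse = ", ")), "schema")
    }
  }
  wl_cols <- setdiff(names(df), meta)
  bad_names <- wl_cols[!is_wl_name(wl_cols)]
  if (length(bad_names) > 0L) {
    abort_aqua(sprintf(
      "column(s) neither declared metadata nor numeric wavelengths: %s",
      paste(bad_names, collapse = ", ")), "schema")
  }
  if (length(wl_cols) == 0L) abort_aqua("no wavelength columns in file.", "schema")
  abs_df <- df[wl_cols]
  for (cn in wl_cols) {
    v <- abs_df[[cn]]
    if (!is.numeric(v)) {
      parsed <- suppressWarnings(as.numeric(as.character(v)))
      bad <- which(is.na(parsed) & !is.na(v))
      if (length(bad) > 0L) {
        abort_aqua(sprintf("non-numeric absorbance in column %s nm, row %d.",
                           cn, bad[1]), "parse")
      }
      abs_df[[cn]] <- parsed
    }
  }
  ds <- spectra_tbl(df[meta], as.numeric(wl_cols), as.matrix(abs_df))
  key <- intersect(design_key_cols, names(spc_meta(ds)))
  if (setequal(key, design_key_cols)) {
    dup <- duplicated(spc_meta(ds)[key])
    if (any(dup)) {
      abort_aqua(sprintf("duplicate (condition, day, fruit_id, position, replicate) record at row %d.",
                         which(dup)[1]), "duplicate_record")
    }
  }
  ds
}

#' Write a spectra tibble to the wide CSV dialect
#'
#' @param ds A [spectra_tbl].
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_spectra <- function(ds, path) {
  validate_spectra(ds)
  readr::write_csv(tibble::as_tibble(ds), path, progress = FALSE)
  invisible(path)
}

#' Restrict a dataset to a wavelength region
#'
#' The analyses work in the first overtone of water, 1300--1600 nm; this
#' keeps the channels whose centres fall inside `[lo, hi]`.
#'
#' @param ds A [spectra_tbl].
#' @param lo,hi Region bounds in nm, `lo < hi`.
#' @return A [spectra_tbl] with the retained channels; metadata unchanged.
#' @export
crop_region <- function(ds, lo, hi) {
  if (!(lo < hi)) abort_aqua("`lo` must be smaller than `hi`.", "parameter")
  wl <- spc_wavelengths(ds)
  keep <- wl >= lo & wl <= hi
  if (!any(keep)) {
    abort_aqua(sprintf("no channels in [%s, %s] nm.", lo, hi), "empty_region")
  }
  drop_cols <- spc_wl_cols(ds)[!keep]
  out <- ds[setdiff(names(ds), drop_cols)]
  new_spectra_tbl(out)
}

#' Index of the channel nearest a nominal band
#'
#' Nominal water-band positions rarely coincide exactly with instrument
#' channels; this snaps a band to the closest channel, breaking exact ties
#' toward the lower wavelength.
#'
#' @param ds A [spectra_tbl].
#' @param band Band position in nm; must lie within one grid step of the
#'   measured range.
#' @return Integer channel index (vectorised over `band`).
#' @export
nearest_channel <- function(ds, band) {
  wl <- spc_wavelengths(ds)
  step <- if (length(wl) > 1L) stats::median(diff(wl)) else 0
  vapply(band, function(b) {
    if (b < wl[1] - step || b > wl[length(wl)] + step) {
      abort_aqua(sprintf("band %s nm outside the padded grid range [%s, %s].",
                         b, wl[1] - step, wl[length(wl)] + step), "out_of_range")
    }
    d <- abs(wl - b)
    which(d == min(d))[1]
  }, integer(1))
}

#' Average consecutive replicate measurements
#'
#' Collapses the three consecutive measurements per fruit/position to their
#' mean. The default analysis mode keeps raw replicates; this enables the
#' replicate-averaged mode.
#'
#' @param ds A [spectra_tbl] with a `replicate` metadata column.
#' @return A [spectra_tbl] with one row per remaining metadata combination.
#' @export
average_replicates <- function(ds) {
  meta <- names(spc_meta(ds))
  if (!"replicate" %in% meta) abort_aqua("no `replicate` column to average over.", "schema")
  average_by(ds, setdiff(meta, "replicate"))
}

#' @export
print.spectra_tbl <- function(x, ...) {
  wl <- spc_wavelengths(x)
  cat(sprintf("# spectra_tbl: %d spectra x %d channels (%.1f-%.1f nm)\n",
              nrow(x), length(wl), min(wl), max(wl)))
  NextMethod()
}
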