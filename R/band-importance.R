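#' Locate peaks in a per-channel statistic
#'
#' Finds local extrema of `|v|` (difference spectra, discriminating power,
#' regression vectors) whose magnitude reaches at least
#' `prominence_frac * max(|v|)`. Interior extrema only: a monotone ramp has
#' no peaks. Signs are preserved so negative difference-spectrum minima are
#' reported as such.
#'
#' @param v Numeric per-channel vector, length at least 3.
#' @param prominence_frac Magnitude threshold as a fraction of the largest
#'   magnitude (default 0.05).
#' @return Tibble `channel`, `sign`, `magnitude`, ordered by channel; empty
#'   for an all-zero vector.
#' @export
find_peaks <- function(v, prominence_frac = 0.05) {
  n <- length(v)
  if (n < 3L) abort_aqua("peak picking needs at least three channels.", "insufficient_data")
  m <- abs(v)
  empty <- tibble::tibble(channel = integer(), sign = numeric(), magnitude = numeric())
  if (max(m) == 0) return(empty)
  thr <- prominence_frac * max(m)
  i <- 2:(n - 1)
  is_peak <- m[i] >= m[i - 1] & m[i] >= m[i + 1] &
    (m[i] > m[i - 1] | m[i] > m[i + 1]) & m[i] >= thr
  idx <- i[is_peak]
  tibble::tibble(channel = idx, sign = sign(v[idx]), magnitude = m[idx])
}

#' The packaged WAMACS catalogue
#'
#' Water matrix coordinates: narrow wavelength regions (6--20 nm) in the
#' first overtone of water, each attributed to a specific water molecular
#' conformation, plus four tentative single-wavelength coordinates (Ci--Cl
#' at 1503, 1528, 1534 and 1559 nm) in the strongly hydrogen-bonded region.
#' Each row is one influential band with its region, an importance count
#' (number of appearances as an influential variable across the analyses)
#' and a conformational assignment.
#'
#' @param path Optional path to an alternative catalogue CSV with the same
#'   columns (`band_nm`, `label`, `lo_nm`, `hi_nm`, `importance`,
#'   `assignment`).
#' @return A validated tibble.
#' @export
wamacs_catalog <- function(path = NULL) {
  if (is.null(path)) {
    path <- system.file("extdata", "wamacs_catalog.csv", package = "aquastore",
                        mustWork = TRUE)
  }
  cat_df <- readr::read_csv(path, show_col_types = FALSE, progress = FALSE)
  need <- c("band_nm", "label", "lo_nm", "hi_nm", "importance")
  absent <- setdiff(need, names(cat_df))
  if (length(absent) > 0L) {
    abort_aqua(sprintf("catalogue missing column(s): %s", paste(absent, collapse = ", ")),
               "catalog_integrity")
  }
  if (any(cat_df$lo_nm > cat_df$hi_nm)) {
    abort_aqua("catalogue has a region with lo > hi.", "catalog_integrity")
  }
  regions <- dplyr::distinct(cat_df[cat_df$lo_nm < cat_df$hi_nm, ],
                             .data$label, .data$lo_nm, .data$hi_nm) |>
    dplyr::arrange(.data$lo_nm)
  if (nrow(regions) > 1L) {
    overlap <- regions$lo_nm[-1] < regions$hi_nm[-nrow(regions)]
    if (any(overlap)) {
      i <- which(overlap)[1]
      abort_aqua(sprintf("catalogue regions %s and %s overlap.",
                         regions$label[i], regions$label[i + 1]), "catalog_integrity")
    }
  }
  cat_df
}

#' Static functional-role annotations for the axis bands
#'
#' A lookup of reported roles of each water absorbance band in biological
#' processes; shipped as a static annotation table only.
#'
#' @return Tibble `band_nm`, `roles`.
#' @export
wamacs_roles <- function() {
  readr::read_csv(system.file("extdata", "wamacs_roles.csv", package = "aquastore",
                              mustWork = TRUE),
                  show_col_types = FALSE, progress = FALSE)
}

#' Assign a wavelength to a WAMACS label
#'
#' A band falling inside a catalogued region gets that region's label; a
#' band within `tol` nm of a tentative single-wavelength coordinate gets the
#' tentative label; anything else gets `NA`.
#'
#' @param band Numeric wavelength(s) in nm.
#' @param catalog A catalogue tibble from [wamacs_catalog()].
#' @param tol Snap tolerance for tentative coordinates (default 3 nm).
#' @return Character vector of labels (`NA` where unassigned).
#' @export
#' @examples
#' assign_wamacs(c(1385, 1503, 1300))
assign_wamacs <- function(band, catalog = wamacs_catalog(), tol = 3) {
  ranged <- dplyr::distinct(catalog[catalog$lo_nm < catalog$hi_nm, ],
                            .data$label, .data$lo_nm, .data$hi_nm) |>
    dplyr::arrange(.data$lo_nm)
  tentative <- dplyr::distinct(catalog[catalog$lo_nm == catalog$hi_nm, ],
                               .data$label, .data$lo_nm)
  vapply(band, function(b) {
    hit <- which(ranged$lo_nm <= b & b <= ranged$hi_nm)
    if (length(hit) > 0L) return(ranged$label[hit[1]])
    if (nrow(tentative) > 0L) {
      d <- abs(tentative$lo_nm - b)
      if (min(d) <= tol) return(tentative$label[which.min(d)])
    }
    NA_character_
  }, character(1))
}

#' Tally how often bands surface as influential variables
#'
#' Aggregates the influential wavelengths reported by the individual
#' analyses (difference-spectrum extrema, SIMCA discriminating power peaks,
#' PLSR regression-vector peaks) into one importance table: per band, the
#' number of distinct analyses citing it, the citing analyses, and the
#' WAMACS label if any.
#'
#' @param peak_sets Either a tibble with columns `analysis_id` and
#'   `band_nm`, or a named list of wavelength vectors (names are the
#'   analysis identifiers). Bands should already be snapped to a common
#'   grid.
#' @param catalog A catalogue tibble from [wamacs_catalog()].
#' @param tol Tolerance passed to [assign_wamacs()].
#' @return A tibble of class `band_importance`, sorted by wavelength:
#'   `band_nm`, `importance`, `sources` (list column), `wamacs`.
#' @export
tally_importance <- function(peak_sets, catalog = wamacs_catalog(), tol = 3) {
  if (is.list(peak_sets) && !is.data.frame(peak_sets)) {
    if (length(peak_sets) > 0L &&
        (is.null(names(peak_sets)) || any(names(peak_sets) == ""))) {
      abort_aqua("list-form `peak_sets` must be fully named by analysis id.", "parameter")
    }
    converted <- purrr::imap_dfr(peak_sets, function(bands, id) {
      tibble::tibble(analysis_id = id, band_nm = as.numeric(bands))
    })
    peak_sets <- if (nrow(converted) == 0L) {
      tibble::tibble(analysis_id = character(), band_nm = numeric())
    } else {
      converted
    }
  }
  peak_sets <- tibble::as_tibble(peak_sets)
  if (nrow(peak_sets) == 0L) {
    out <- tibble::tibble(band_nm = numeric(), importance = integer(),
                          sources = list(), wamacs = character())
    class(out) <- c("band_importance", class(out))
    return(out)
  }
  out <- peak_sets |>
    dplyr::group_by(.data$band_nm) |>
    dplyr::summarise(
      importance = dplyr::n_distinct(.data$analysis_id),
      sources = list(sort(unique(.data$analysis_id))),
      .groups = "drop"
    ) |>
    dplyr::arrange(.data$band_nm) |>
    dplyr::mutate(wamacs = assign_wamacs(.data$band_nm, catalog, tol))
  class(out) <- c("band_importance", class(out))
  out
}

#' Select aquagram axis bands from an importance tally
#'
#' Keeps every band cited by at least `min_importance` analyses, plus any
#' band assigned to a tentative coordinate, then deduplicates to one
#' representative per WAMACS region: highest importance wins, the lower
#' wavelength breaks ties. Bands with no label are kept as-is. This
#' selection rule is a package design choice.
#'
#' @param tally A `band_importance` table from [tally_importance()].
#' @param min_importance Minimum citation count (default 2).
#' @param catalog A catalogue tibble, used to recognise tentative labels.
#' @return Sorted numeric vector of axis wavelengths in nm.
#' @export
select_axes <- function(tally, min_importance = 2, catalog = wamacs_catalog()) {
  tentative_labels <- unique(catalog$label[catalog$lo_nm == catalog$hi_nm])
  keep <- tally$importance >= min_importance |
    (!is.na(tally$wamacs) & tally$wamacs %in% tentative_labels)
  kept <- tally[keep, , drop = FALSE]
  if (nrow(kept) == 0L) return(numeric())
  labelled <- kept[!is.na(kept$wamacs), , drop = FALSE]
  unlabelled <- kept[is.na(kept$wamacs), , drop = FALSE]
  dedup <- labelled |>
    dplyr::group_by(.data$wamacs) |>
    dplyr::arrange(dplyr::desc(.data$importance), .data$band_nm, .by_group = TRUE) |>
    dplyr::slice(1L) |>
    dplyr::ungroup()
  sort(c(dedup$band_nm, unlabelled$band_nm))
}

#' Preset aquagram axis bands
#'
#' The representative water absorbance bands used as aquagram radial axes.
#' The 20-band preset is the full annotated set; the 19-band preset merges
#' the two structural-water bands with identical functional annotations
#' (1521 and 1528 nm) into 1528 nm.
#'
#' @param n Either 20 (default) or 19.
#' @return Sorted numeric vector of band positions in nm.
#' @export
wamacs_axes <- function(n = 20) {
  bands <- wamacs_roles()$band_nm
  if (n == 20) return(sort(bands))
  if (n == 19) return(sort(setdiff(bands, 1521)))
  abort_aqua("`n` must be 19 or 20.", "parameter")
}
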