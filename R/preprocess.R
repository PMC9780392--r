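#' Standard normal variate transformation
#'
#' Standardises every spectrum to zero mean and unit sample standard
#' deviation across its channels, removing additive baseline offsets and
#' multiplicative scatter differences between spectra. Applied before
#' difference spectra and before aquagram computation; SIMCA and PLSR consume
#' raw spectra.
#'
#' @param ds A [spectra_tbl] with at least two channels.
#' @return A [spectra_tbl]; every row has mean 0 and sample sd 1.
#' @export
#' @examples
#' ds <- spectra_tbl(data.frame(id = 1), c(1400, 1410, 1420),
#'                   matrix(c(1, 2, 3), nrow = 1))
#' spc_matrix(snv(ds))
snv <- function(ds) {
  x <- spc_matrix(ds)
  if (ncol(x) < 2L) abort_aqua("SNV needs at least two channels per spectrum.", "parameter")
  s <- row_sds(x)
  if (any(s == 0)) {
    abort_aqua(sprintf("zero-spread spectrum at row %d; SNV undefined.", which(s == 0)[1]),
               "degenerate_spectrum")
  }
  spc_set_matrix(ds, (x - rowMeans(x)) / s)
}

#' Column mean-centering
#'
#' Subtracts the per-channel mean. SIMCA and PLSR operate on mean-centred
#' raw spectra.
#'
#' @param x A numeric matrix, or a [spectra_tbl] whose wavelength columns are
#'   centred.
#' @return Same type as `x`, with zero column means.
#' @export
mean_center <- function(x) {
  if (inherits(x, "spectra_tbl") || (is.data.frame(x) && length(spc_wl_cols(x)) > 0)) {
    m <- spc_matrix(x)
    if (nrow(m) < 2L) abort_aqua("mean-centering needs at least two spectra.", "insufficient_data")
    return(spc_set_matrix(x, sweep(m, 2L, colMeans(m))))
  }
  x <- as.matrix(x)
  if (nrow(x) < 2L) abort_aqua("mean-centering needs at least two rows.", "insufficient_data")
  sweep(x, 2L, colMeans(x))
}

#' Group-average spectra
#'
#' Averages absorbance channel-wise within every distinct combination of the
#' given metadata keys (e.g. per condition and storage day before computing
#' difference spectra or aquagrams).
#'
#' @param ds A [spectra_tbl].
#' @param keys Character vector of metadata column names to group by.
#' @return A [spectra_tbl] with one row per key combination.
#' @export
average_by <- function(ds, keys) {
  if (length(keys) == 0L) abort_aqua("`keys` must name at least one metadata field.", "parameter")
  meta_names <- names(spc_meta(ds))
  unknown <- setdiff(keys, meta_names)
  if (length(unknown) > 0L) {
    abort_aqua(sprintf("unknown metadata key(s): %s", paste(unknown, collapse = ", ")), "schema")
  }
  wl_cols <- spc_wl_cols(ds)
  out <- tibble::as_tibble(ds) |>
    dplyr::group_by(dplyr::across(dplyr::all_of(keys))) |>
    dplyr::summarise(dplyr::across(dplyr::all_of(wl_cols), mean), .groups = "drop") |>
    dplyr::arrange(dplyr::across(dplyr::all_of(keys)))
  new_spectra_tbl(out)
}

#' Day-to-day difference spectrum
#'
#' Difference between the day-averaged SNV-transformed spectra of a target
#' and a reference storage day within one condition:
#' `delta = avg(S_target) - avg(S_reference)`. The reference defaults to
#' day 1 (the first day *in* storage); day 0 (pre-storage) may be requested
#' instead.
#'
#' @param ds A [spectra_tbl] with `condition` and `day` metadata.
#' @param condition Condition label to subset (e.g. `"CF"`).
#' @param target_day,reference_day Integer day labels; both must be present
#'   for the condition.
#' @param apply_snv Apply [snv()] first (default `TRUE`, the documented
#'   pipeline); set `FALSE` if `ds` is already SNV-transformed.
#' @return A tibble of class `difference_spectrum` with columns `wavelength`
#'   and `delta`, and attributes `condition`, `target_day`, `reference_day`.
#' @export
difference_spectrum <- function(ds, condition, target_day, reference_day = 1,
                                apply_snv = TRUE) {
  sub <- dplyr::filter(tibble::as_tibble(ds), .data$condition == .env$condition)
  if (nrow(sub) == 0L) {
    abort_aqua(sprintf("no spectra for condition %s.", condition), "missing_group")
  }
  sub <- new_spectra_tbl(sub)
  if (apply_snv) sub <- snv(sub)
  avg <- average_by(sub, "day")
  for (d in c(target_day, reference_day)) {
    if (!d %in% avg$day) {
      abort_aqua(sprintf("day %s absent for condition %s.", d, condition), "missing_group")
    }
  }
  m <- spc_matrix(avg)
  delta <- m[match(target_day, avg$day), ] - m[match(reference_day, avg$day), ]
  out <- tibble::tibble(wavelength = spc_wavelengths(avg), delta = unname(delta))
  structure(out,
            condition = condition, target_day = target_day,
            reference_day = reference_day,
            class = c("difference_spectrum", class(out)))
}

#' All difference spectra of a condition against one reference day
#'
#' @inheritParams difference_spectrum
#' @param days Target days; default every day present except the reference.
#' @return A long tibble with columns `condition`, `target_day`,
#'   `reference_day`, `wavelength`, `delta`.
#' @export
difference_spectra <- function(ds, condition, days = NULL, reference_day = 1,
                               apply_snv = TRUE) {
  sub <- dplyr::filter(tibble::as_tibble(ds), .data$condition == .env$condition)
  if (nrow(sub) == 0L) {
    abort_aqua(sprintf("no spectra for condition %s.", condition), "missing_group")
  }
  if (is.null(days)) days <- setdiff(sort(unique(sub$day)), reference_day)
  purrr::map_dfr(days, function(d) {
    ds1 <- difference_spectrum(ds, condition, d, reference_day, apply_snv)
    tibble::tibble(condition = condition, target_day = d,
                   reference_day = reference_day,
                   wavelength = ds1$wavelength, delta = ds1$delta)
  })
}

#' Per-wavelength standardisation
#'
#' Z-scores every channel across all spectra in the dataset (both conditions
#' and all days pooled, so profiles share one scale), using sample standard
#' deviations. This is the "normalisation" step of the classical aquagram.
#'
#' @param ds A [spectra_tbl] with at least two spectra.
#' @return A [spectra_tbl]; every channel has mean 0 and sample sd 1.
#' @export
standardize_per_wavelength <- function(ds) {
  x <- spc_matrix(ds)
  if (nrow(x) < 2L) {
    abort_aqua("per-wavelength standardisation needs at least two spectra.",
               "insufficient_data")
  }
  s <- col_sds(x)
  if (any(s == 0)) {
    wl <- spc_wavelengths(ds)
    abort_aqua(sprintf("zero-variance channel at %s nm.", wl[which(s == 0)[1]]),
               "degenerate_channel")
  }
  spc_set_matrix(ds, sweep(sweep(x, 2L, colMeans(x)), 2L, s, "/"))
}

#' @export
autoplot.difference_spectrum <- function(object, ...) {
  ggplot2::ggplot(tibble::as_tibble(object),
                  ggplot2::aes(x = .data$wavelength, y = .data$delta)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(
      x = "wavelength (nm)", y = "absorbance difference",
      title = sprintf("%s: day %s - day %s", attr(object, "condition"),
                      attr(object, "target_day"), attr(object, "reference_day"))
    )
}
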