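#' Classical aquagram / water spectral pattern
#'
#' Computes the water spectral pattern (WASP) of every (condition, day)
#' group on the chosen axis bands: spectra are SNV-transformed, every
#' channel is z-scored across the pooled dataset (both conditions, all
#' days, so the two fridges share one scale), the values are averaged per
#' condition and day, the reference-day average of the same condition is
#' subtracted, and the result is read off at the channels nearest the axis
#' bands. The reference defaults to day 1 (the first day in storage).
#'
#' @param ds A [spectra_tbl] with `condition` and `day` metadata.
#' @param axes Nominal axis bands in nm (default [wamacs_axes()]); each must
#'   snap to a distinct channel.
#' @param reference_day Day whose profile is subtracted per condition
#'   (default 1; day 0 selects the pre-storage spectra instead).
#' @return A tibble of class `aquagram_profile`: `condition`, `day`,
#'   `band_nm`, `wavelength_nm` (snapped channel), `value`; attribute
#'   `reference_day`.
#' @export
compute_aquagram <- function(ds, axes = wamacs_axes(), reference_day = 1) {
  if (length(axes) == 0L) abort_aqua("`axes` must name at least one band.", "parameter")
  idx <- nearest_channel(ds, axes)
  if (anyDuplicated(idx)) {
    dup <- axes[duplicated(idx) | duplicated(idx, fromLast = TRUE)]
    abort_aqua(sprintf("axes snap to a shared channel: %s nm.",
                       paste(dup, collapse = ", ")), "axis_collision")
  }
  wl <- spc_wavelengths(ds)
  avg <- ds |> snv() |> standardize_per_wavelength() |> average_by(c("condition", "day"))
  for (cond in unique(avg$condition)) {
    if (!reference_day %in% avg$day[avg$condition == cond]) {
      abort_aqua(sprintf("reference day %s absent for condition %s.",
                         reference_day, cond), "missing_group")
    }
  }
  m <- spc_matrix(avg)
  meta <- spc_meta(avg)
  # subtract each condition's reference-day average row-wise
  ref_idx <- vapply(meta$condition, function(cond) {
    which(meta$condition == cond & meta$day == reference_day)[1]
  }, integer(1))
  centred <- m - m[ref_idx, , drop = FALSE]
  out <- tidyr::expand_grid(row = seq_len(nrow(meta)), ax = seq_along(axes))
  out <- tibble::tibble(
    condition = meta$condition[out$row],
    day = meta$day[out$row],
    band_nm = axes[out$ax],
    wavelength_nm = wl[idx[out$ax]],
    value = centred[cbind(out$row, idx[out$ax])]
  )
  structure(dplyr::arrange(out, .data$condition, .data$day, .data$band_nm),
            reference_day = reference_day,
            class = c("aquagram_profile", class(out)))
}

#' Extract one (condition, day) pattern as a named vector
#'
#' @param p An `aquagram_profile`.
#' @param condition,day Group selector.
#' @return Named numeric vector (names are the axis bands in nm).
#' @export
profile_vector <- function(p, condition, day) {
  sub <- p[p$condition == condition & p$day == day, , drop = FALSE]
  if (nrow(sub) == 0L) {
    abort_aqua(sprintf("no profile for condition %s, day %s.", condition, day),
               "missing_group")
  }
  sub <- sub[order(sub$band_nm), , drop = FALSE]
  stats::setNames(sub$value, sub$band_nm)
}

cosine_sim <- function(u, v) {
  nu <- sqrt(sum(u^2))
  nv <- sqrt(sum(v^2))
  if (nu == 0 && nv == 0) return(1)
  if (nu == 0 || nv == 0) return(NA_real_)
  sum(u * v) / (nu * nv)
}

#' Compare water spectral patterns between groups
#'
#' Cosine similarity and root-mean-square difference across the axis bands
#' for every requested pair of (condition, day) profiles — e.g. to ask which
#' control-fridge day the supercooling-fridge day-7 pattern most resembles.
#'
#' @param p An `aquagram_profile`.
#' @param pairs Tibble with columns `condition_a`, `day_a`, `condition_b`,
#'   `day_b`.
#' @return `pairs` with `cosine` and `rms` columns appended.
#' @export
compare_profiles <- function(p, pairs) {
  pairs <- tibble::as_tibble(pairs)
  need <- c("condition_a", "day_a", "condition_b", "day_b")
  absent <- setdiff(need, names(pairs))
  if (length(absent) > 0L) {
    abort_aqua(sprintf("`pairs` missing column(s): %s", paste(absent, collapse = ", ")),
               "schema")
  }
  res <- purrr::pmap_dfr(pairs, function(condition_a, day_a, condition_b, day_b, ...) {
    u <- profile_vector(p, condition_a, day_a)
    v <- profile_vector(p, condition_b, day_b)
    tibble::tibble(cosine = cosine_sim(u, v), rms = sqrt(mean((u - v)^2)))
  })
  dplyr::bind_cols(pairs, res)
}

#' Find the reference-condition day most similar to a target pattern
#'
#' Scans the days of a reference condition and ranks their similarity to a
#' single target profile; used to quantify the storage-delay effect (the
#' supercooling-fridge day-7 pattern matching the control-fridge day-4
#' pattern implies a roughly 3-day lag).
#'
#' @param p An `aquagram_profile`.
#' @param condition,day The target profile.
#' @param reference_condition Condition scanned (default `"CF"`).
#' @param days Candidate days (default: all days of the reference condition
#'   except the aquagram reference day).
#' @return Tibble `day`, `cosine`, `rms` sorted by day, with attribute
#'   `best_day`, the day of maximal similarity (minimal RMS difference).
#'   RMS is used for the arg-max because day profiles within a linear
#'   stretch of the storage dynamics are nearly collinear — cosine cannot
#'   separate them, while the pattern magnitude can.
#' @export
profile_lag_match <- function(p, condition, day, reference_condition = "CF",
                              days = NULL) {
  ref_day <- attr(p, "reference_day")
  if (is.null(days)) {
    days <- sort(setdiff(unique(p$day[p$condition == reference_condition]), ref_day))
  }
  res <- compare_profiles(p, tibble::tibble(
    condition_a = condition, day_a = day,
    condition_b = reference_condition, day_b = days
  ))
  out <- tibble::tibble(day = days, cosine = res$cosine, rms = res$rms)
  attr(out, "best_day") <- days[which.min(out$rms)]
  out
}

#' Export an aquagram profile
#'
#' @param p An `aquagram_profile`.
#' @param path Output path.
#' @param format `"csv"` (default) or `"json"`.
#' @return `path`, invisibly.
#' @export
write_aquagram <- function(p, path, format = c("csv", "json")) {
  format <- match.arg(format)
  df <- tibble::as_tibble(p)
  if (format == "csv") {
    readr::write_csv(df, path, progress = FALSE)
  } else {
    jsonlite::write_json(
      list(reference_day = attr(p, "reference_day"), profile = df),
      path, digits = NA, auto_unbox = TRUE
    )
  }
  invisible(path)
}

#' Radar-style display of water spectral patterns
#'
#' One polar trace per storage day, faceted by condition. The tested
#' artifact is the value table; this is a convenience rendering.
#'
#' @param object An `aquagram_profile`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.aquagram_profile <- function(object, ...) {
  df <- tibble::as_tibble(object)
  df$band <- factor(df$band_nm, levels = sort(unique(df$band_nm)))
  ggplot2::ggplot(df, ggplot2::aes(x = .data$band, y = .data$value,
                                   group = .data$day,
                                   colour = factor(.data$day))) +
    ggplot2::geom_hline(yintercept = 0, colour = "grey70") +
    ggplot2::geom_line() +
    ggplot2::coord_polar() +
    ggplot2::facet_wrap(ggplot2::vars(.data$condition)) +
    ggplot2::labs(x = NULL, y = "reference-subtracted standardised absorbance",
                  colour = "day", title = "Water spectral patterns")
}
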