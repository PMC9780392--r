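run_stage <- function(name, expr) {
  tryCatch(
    c(list(status = "ok"), expr),
    aquastore_error = function(e) list(status = "failed", error = conditionMessage(e)),
    error = function(e) list(status = "failed", error = conditionMessage(e))
  )
}

#' Run the full storage-monitoring analysis
#'
#' Orchestrates every stage on one dataset: weight statistics, SNV
#' difference spectra against a configurable reference day, SIMCA
#' storage-day classification (4-, 8- and 14-day windows) with
#' discriminating power, PLS1 time regression (4-day and 14-day windows)
#' with segment-exclusion cross-validation, the band-importance tally on
#' the WAMACS catalogue, and aquagram water spectral patterns with the
#' CF-vs-SCF day-by-day comparison. Inputs are either file paths or the
#' synthetic design; a failed stage is recorded with its cause and later
#' independent stages still run. Deterministic for a given seed.
#'
#' @param config A [synthetic_config()], or a list with elements
#'   `spectra_path` (and optionally `weights_path`, `schema`) naming input
#'   files in the package CSV dialects.
#' @param seed Integer master seed (used for data generation when
#'   synthesising).
#' @param out_dir Optional directory for CSV/JSON artifacts; created if
#'   needed.
#' @param reference_day Reference day of difference spectra and aquagrams
#'   (0 or 1; default 1).
#' @param windows List of `c(first_day, last_day)` SIMCA windows. The PLSR
#'   stage uses the first and last windows.
#' @param axes Aquagram axis bands (default the 20-band preset).
#' @param segment Cross-validation exclusion block size (default 6).
#' @param region Wavelength analysis window in nm; all spectral stages work
#'   in the first overtone of water, 1300--1600 nm, by default. `NULL`
#'   keeps the full measured grid.
#' @return A list of class `pipeline_report` with one block per stage.
#' @export
run_pipeline <- function(config = synthetic_config(), seed = 1,
                         out_dir = NULL, reference_day = 1,
                         windows = list(c(1, 4), c(1, 8), c(0, 14)),
                         axes = wamacs_axes(20), segment = 6,
                         region = c(1300, 1600)) {
  seeds <- split_seed(seed, 2)
  have_weights <- TRUE
  if (inherits(config, "synthetic_config")) {
    ds <- generate_spectra(config, seed = seeds[1])
    weights <- generate_weights(config, seed = seeds[2])
  } else {
    ds <- read_spectra(config$spectra_path, schema = config$schema)
    weights <- NULL
    if (!is.null(config$weights_path)) {
      weights <- read_weights(config$weights_path)
    } else {
      have_weights <- FALSE
    }
  }
  if (!is.null(region)) ds <- crop_region(ds, region[1], region[2])
  conditions <- sort(unique(spc_meta(ds)$condition))
  days_present <- sort(unique(spc_meta(ds)$day))
  report <- list(
    seed = seed, reference_day = reference_day,
    region = region, conditions = conditions,
    n_spectra = nrow(ds), n_channels = length(spc_wavelengths(ds))
  )

  report$weights <- if (!have_weights) {
    list(status = "skipped", reason = "no weight table supplied")
  } else {
    run_stage("weights", {
      target_day <- min(7, max(weights$day))
      rates <- weight_loss_rates(weights, target_day)
      by_cond <- rates |>
        dplyr::group_by(.data$condition) |>
        dplyr::summarise(mean_loss_pct = mean(.data$loss_pct),
                         sd_loss_pct = stats::sd(.data$loss_pct), .groups = "drop")
      tt <- if (length(conditions) == 2L) {
        equal_variance_ttest(rates$loss_pct[rates$condition == conditions[1]],
                             rates$loss_pct[rates$condition == conditions[2]])
      } else NULL
      daily <- daily_weight_changes(weights) |>
        dplyr::group_by(.data$condition, .data$day) |>
        dplyr::summarise(mean_change_g = mean(.data$change_g), .groups = "drop")
      list(loss_day = target_day, loss_by_condition = by_cond,
           t_test = tt, daily_change = daily)
    })
  }

  report$difference_spectra <- run_stage("difference_spectra", {
    tabs <- purrr::map(conditions, function(cond) {
      difference_spectra(ds, cond, reference_day = reference_day)
    })
    list(reference_day = reference_day, tables = stats::setNames(tabs, conditions))
  })

  report$simca <- run_stage("simca", {
    res <- purrr::map(conditions, function(cond) {
      sub <- new_spectra_tbl(dplyr::filter(tibble::as_tibble(ds),
                                           .data$condition == cond))
      purrr::map(windows, function(w) {
        wd <- new_spectra_tbl(dplyr::filter(tibble::as_tibble(sub),
                                            .data$day >= w[1], .data$day <= w[2]))
        model <- fit_simca(wd)
        d <- model$distance[upper.tri(model$distance)]
        list(window = w, accuracy_pct = simca_accuracy(model, wd),
             min_interclass_distance = min(d),
             median_interclass_distance = stats::median(d),
             discriminating_power = tidy(model))
      })
    })
    list(windows = windows, by_condition = stats::setNames(res, conditions))
  })

  plsr_windows <- windows[c(1, length(windows))]
  report$plsr <- run_stage("plsr", {
    res <- purrr::map(conditions, function(cond) {
      sub <- new_spectra_tbl(dplyr::filter(tibble::as_tibble(ds),
                                           .data$condition == cond))
      purrr::map(plsr_windows, function(w) {
        wd <- new_spectra_tbl(dplyr::filter(tibble::as_tibble(sub),
                                            .data$day >= w[1], .data$day <= w[2]))
        cv <- plsr_cv(wd, n_lv_max = 15, segment = segment)
        list(window = w, n_lv = cv$n_lv, SECV = cv$SECV, R2cv = cv$R2cv,
             SEC = cv$metrics$SEC[cv$n_lv], R2c = cv$metrics$R2c[cv$n_lv],
             regression_vector = tidy(cv$model))
      })
    })
    list(windows = plsr_windows, by_condition = stats::setNames(res, conditions))
  })

  report$band_importance <- run_stage("band_importance", {
    wl <- spc_wavelengths(ds)
    peak_sets <- list()
    if (identical(report$difference_spectra$status, "ok")) {
      for (cond in conditions) {
        tab <- report$difference_spectra$tables[[cond]]
        for (d in intersect(c(4, max(days_present)), unique(tab$target_day))) {
          v <- tab$delta[tab$target_day == d]
          pk <- find_peaks(v)
          peak_sets[[sprintf("%s_diff_day%d", cond, d)]] <- wl[pk$channel]
        }
      }
    }
    if (identical(report$simca$status, "ok")) {
      for (cond in conditions) {
        for (i in seq_along(windows)) {
          dp <- report$simca$by_condition[[cond]][[i]]$discriminating_power
          pk <- find_peaks(dp$discriminating_power)
          peak_sets[[sprintf("%s_simca_w%d", cond, i)]] <- wl[pk$channel]
        }
      }
    }
    if (identical(report$plsr$status, "ok")) {
      for (cond in conditions) {
        for (i in seq_along(plsr_windows)) {
          rv <- report$plsr$by_condition[[cond]][[i]]$regression_vector
          pk <- find_peaks(rv$coefficient)
          peak_sets[[sprintf("%s_plsr_w%d", cond, i)]] <- wl[pk$channel]
        }
      }
    }
    tally <- tally_importance(peak_sets)
    list(tally = tally, selected_axes = select_axes(tally))
  })

  report$aquagram <- run_stage("aquagram", {
    prof <- compute_aquagram(ds, axes = axes, reference_day = reference_day)
    cmp_days <- intersect(1:7, days_present)
    day_by_day <- if (length(conditions) == 2L && length(cmp_days) > 0L) {
      compare_profiles(prof, tibble::tibble(
        condition_a = conditions[1], day_a = cmp_days,
        condition_b = conditions[2], day_b = cmp_days
      ))
    } else NULL
    lag <- if (all(c("CF", "SCF") %in% conditions) && 7 %in% days_present) {
      lm <- profile_lag_match(prof, "SCF", 7, "CF")
      list(target = "SCF day 7", best_cf_day = attr(lm, "best_day"), table = lm)
    } else NULL
    list(profile = tibble::as_tibble(prof), day_by_day = day_by_day, lag_match = lag)
  })

  report <- structure(report, class = "pipeline_report")
  if (!is.null(out_dir)) write_report(report, out_dir)
  report
}

#' Write pipeline artifacts
#'
#' Emits `report.json` plus CSV tables for the main stage outputs.
#'
#' @param report A `pipeline_report`.
#' @param out_dir Output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
write_report <- function(report, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       digits = 10, auto_unbox = TRUE, pretty = TRUE,
                       dataframe = "columns")
  if (identical(report$difference_spectra$status, "ok")) {
    readr::write_csv(dplyr::bind_rows(report$difference_spectra$tables),
                     file.path(out_dir, "difference_spectra.csv"), progress = FALSE)
  }
  if (identical(report$band_importance$status, "ok")) {
    tab <- report$band_importance$tally
    tab$sources <- vapply(tab$sources, paste, character(1), collapse = ";")
    readr::write_csv(tab, file.path(out_dir, "band_importance.csv"), progress = FALSE)
  }
  if (identical(report$aquagram$status, "ok")) {
    readr::write_csv(report$aquagram$profile,
                     file.path(out_dir, "aquagram_profile.csv"), progress = FALSE)
  }
  invisible(out_dir)
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat("Storage-monitoring pipeline report\n")
  cat(sprintf("  %d spectra, %d channels, conditions: %s\n",
              x$n_spectra, x$n_channels, paste(x$conditions, collapse = ", ")))
  for (stage in c("weights", "difference_spectra", "simca", "plsr",
                  "band_importance", "aquagram")) {
    cat(sprintf("  %-20s %s\n", stage, x[[stage]]$status))
  }
  invisible(x)
}
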