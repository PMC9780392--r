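#' Default synthetic water-band set
#'
#' Gaussian absorbance components used by the spectral generator: the 28
#' influential first-overtone bands of the WAMACS catalogue with widths of
#' 8--15 nm (overlapping on the ~6.1 nm default grid, so peak picking is
#' non-trivially exercised), plus two broad background components shaping
#' the overall water overtone hump.
#'
#' @return Tibble `centre`, `width`, `base_amp` (absorbance units).
#' @export
default_bands <- function() {
  centres <- wamacs_catalog()$band_nm
  widths <- rep_len(c(10, 12, 8, 14, 11, 9, 13, 15), length(centres))
  base <- 0.25 + 0.35 * exp(-0.5 * ((centres - 1450) / 90)^2)
  dplyr::bind_rows(
    tibble::tibble(centre = centres, width = widths, base_amp = base),
    tibble::tibble(centre = c(1190, 1450), width = c(120, 80),
                   base_amp = c(0.25, 0.9))
  )
}

# piecewise-linear per-band amplitude offsets (absorbance units) as a
# function of storage day, one block per condition; knots encode the
# observed storage dynamics: vapor-like bands rising to day 4 then falling,
# free-water bands declining monotonically (steeper in the control fridge),
# bulk-water bands rising after day 4 in the control fridge only, a step
# increase of the 1503 nm strongly-bound band in both fridges, and decline
# (CF) versus retention (SCF) of the structural-water bands.
traj_knots <- function(condition, centre, days, offsets) {
  tibble::tibble(condition = condition, centre = centre, day = days, offset = offsets)
}

#' Default per-band storage trajectories
#'
#' @return Tibble `condition`, `centre`, `day`, `offset` of piecewise-linear
#'   knots; days without a knot are linearly interpolated, and bands without
#'   a trajectory stay at their base amplitude.
#' @export
default_trajectories <- function() {
  dplyr::bind_rows(
    # vapor-like / proton-hydrate region: rise to day 4, then decline
    traj_knots("CF", 1360, c(0, 4, 14), c(0, 0.020, -0.025)),
    traj_knots("SCF", 1360, c(0, 4, 14), c(0, 0.026, -0.005)),
    traj_knots("CF", 1373, c(0, 1, 4, 9, 14), c(0, 0.005, 0.035, -0.020, -0.035)),
    traj_knots("SCF", 1373, c(0, 1, 4, 9, 14), c(0, 0.006, 0.045, -0.005, -0.015)),
    # hydration shell: modest rise then sharp drop after day 5 in CF
    traj_knots("CF", 1385, c(0, 4, 5, 14), c(0, 0.010, 0.000, -0.045)),
    traj_knots("SCF", 1385, c(0, 4, 5, 14), c(0, 0.012, 0.008, -0.015)),
    # trapped water
    traj_knots("CF", 1391, c(0, 5, 14), c(0, 0.005, -0.030)),
    traj_knots("SCF", 1391, c(0, 5, 14), c(0, 0.020, -0.005)),
    # free water: monotone decline, steeper in CF
    traj_knots("CF", 1404, c(0, 14), c(0, -0.050)),
    traj_knots("SCF", 1404, c(0, 14), c(0, -0.035)),
    traj_knots("CF", 1410, c(0, 14), c(0, -0.040)),
    traj_knots("SCF", 1410, c(0, 14), c(0, -0.055)),
    # hydration band 1428: drying rise in CF, early slight decline in SCF
    traj_knots("CF", 1428, c(0, 4, 14), c(0, 0.000, 0.040)),
    traj_knots("SCF", 1428, c(0, 1, 14), c(0, -0.010, -0.015)),
    # solvation shell 1447: negative trend
    traj_knots("CF", 1447, c(0, 4, 14), c(0, 0.000, -0.030)),
    traj_knots("SCF", 1447, c(0, 4, 14), c(0, -0.005, -0.020)),
    # bulk water 1459-1484: post-day-4 rise in CF only
    traj_knots("CF", 1459, c(0, 4, 14), c(0, 0.000, 0.050)),
    traj_knots("SCF", 1459, c(0, 6, 14), c(0, 0.000, 0.020)),
    traj_knots("CF", 1478, c(0, 4, 14), c(0, 0.000, 0.045)),
    traj_knots("SCF", 1478, c(0, 6, 14), c(0, 0.000, 0.015)),
    traj_knots("CF", 1484, c(0, 4, 14), c(0, 0.000, 0.030)),
    traj_knots("SCF", 1484, c(0, 6, 14), c(0, 0.000, 0.010)),
    # four-hydrogen-bond water 1490: sharp early decrease, CF recovers late
    traj_knots("CF", 1490, c(0, 1, 4, 14), c(0, -0.020, -0.020, 0.010)),
    traj_knots("SCF", 1490, c(0, 1, 14), c(0, -0.020, -0.030)),
    # strongly bound 1503: step increase upon storage in both fridges
    traj_knots("CF", 1503, c(0, 1, 14), c(0, 0.030, 0.035)),
    traj_knots("SCF", 1503, c(0, 1, 14), c(0, 0.030, 0.035)),
    # structural water: decline in CF, retention / slight gain in SCF
    traj_knots("CF", 1521, c(0, 4, 14), c(0, -0.005, -0.035)),
    traj_knots("SCF", 1521, c(0, 4, 14), c(0, 0.005, 0.000)),
    traj_knots("CF", 1528, c(0, 4, 14), c(0, 0.010, -0.040)),
    traj_knots("SCF", 1528, c(0, 4, 14), c(0, 0.012, 0.010)),
    traj_knots("CF", 1534, c(0, 4, 14), c(0, 0.012, -0.045)),
    traj_knots("SCF", 1534, c(0, 4, 14), c(0, 0.014, 0.012)),
    traj_knots("CF", 1559, c(0, 4, 14), c(0, -0.010, -0.040)),
    traj_knots("SCF", 1559, c(0, 4, 14), c(0, 0.008, 0.012))
  )
}

#' Configuration of the synthetic storage experiment
#'
#' Describes the two-fridge strawberry design the generator emulates: 2
#' conditions x 15 day labels (0--14) x 24 fruits x 2 positions x 3
#' consecutive replicates = 2,160 spectra per condition, on 125 channels
#' spanning 908--1,670 nm (~6.1 nm step). Spectra are sums of Gaussian water
#' bands whose amplitudes follow per-condition piecewise-linear day
#' trajectories, wrapped in per-spectrum multiplicative gain, additive
#' offset, and a mild wavelength slope (all removable or attenuated by SNV),
#' plus white noise. Biological individuality enters as a per-fruit
#' "effective age" shift and a per-(fruit, day) age jitter shared by the
#' replicates of that fruit and day; these bound how precisely storage time
#' can be predicted from spectra, emulating the roughly 2-day
#' cross-validated error of the real experiment.
#'
#' Weights decline linearly with day; default per-day loss rates are
#' calibrated so that mean day-7 loss is about 7.3% (CF) and 5.9% (SCF),
#' with per-fruit variation of both initial weight and loss rate.
#'
#' @param n_days Number of day labels (default 15: days 0--14).
#' @param n_fruits,n_positions,n_replicates Design counts per condition.
#' @param wl_lo,wl_hi,n_channels Wavelength grid specification (nm).
#' @param bands Tibble `centre`, `width`, `base_amp` (default
#'   [default_bands()]).
#' @param trajectories Tibble `condition`, `centre`, `day`, `offset`
#'   (default [default_trajectories()]).
#' @param baseline_offset_sd,baseline_slope_sd,gain_sd Per-spectrum scatter
#'   model: additive offset sd (absorbance), slope sd (absorbance per nm),
#'   and sd of the multiplicative gain around 1.
#' @param noise_sd White noise sd in absorbance units.
#' @param fruit_age_sd Per-fruit effective-age shift sd (days).
#' @param age_jitter_sd Per-(fruit, day) effective-age jitter sd (days).
#' @param weight_initial Mean fresh weight (g).
#' @param weight_initial_cv Coefficient of variation of fresh weight.
#' @param loss_rate Named per-day fractional loss rates per condition.
#' @param loss_rate_cv Per-fruit coefficient of variation of the loss rate.
#' @param scf_delay If non-`NULL`, SCF spectral trajectories are the CF
#'   trajectories delayed by this many days (clamped at day 0) — the
#'   constructed scenario behind the storage-delay analysis.
#' @param conditions Condition labels (default `c("CF", "SCF")`).
#' @param seed Default seed used by the generators.
#' @return A list of class `synthetic_config`.
#' @export
synthetic_config <- function(n_days = 15, n_fruits = 24, n_positions = 2,
                             n_replicates = 3,
                             wl_lo = 908, wl_hi = 1670, n_channels = 125,
                             bands = default_bands(),
                             trajectories = default_trajectories(),
                             baseline_offset_sd = 0.05,
                             baseline_slope_sd = 5e-5,
                             gain_sd = 0.05,
                             noise_sd = 0.005,
                             fruit_age_sd = 1.0,
                             age_jitter_sd = 1.5,
                             weight_initial = 20,
                             weight_initial_cv = 0.10,
                             loss_rate = c(CF = 0.073 / 7, SCF = 0.059 / 7),
                             loss_rate_cv = 0.13,
                             scf_delay = NULL,
                             conditions = c("CF", "SCF"),
                             seed = 1L) {
  cfg <- list(
    n_days = n_days, n_fruits = n_fruits, n_positions = n_positions,
    n_replicates = n_replicates,
    wl_lo = wl_lo, wl_hi = wl_hi, n_channels = n_channels,
    bands = tibble::as_tibble(bands),
    trajectories = tibble::as_tibble(trajectories),
    baseline_offset_sd = baseline_offset_sd,
    baseline_slope_sd = baseline_slope_sd,
    gain_sd = gain_sd, noise_sd = noise_sd,
    fruit_age_sd = fruit_age_sd, age_jitter_sd = age_jitter_sd,
    weight_initial = weight_initial, weight_initial_cv = weight_initial_cv,
    loss_rate = loss_rate, loss_rate_cv = loss_rate_cv,
    scf_delay = scf_delay, conditions = conditions, seed = seed
  )
  validate_config(cfg)
  structure(cfg, class = "synthetic_config")
}

validate_config <- function(cfg) {
  counts <- c(cfg$n_days, cfg$n_fruits, cfg$n_positions, cfg$n_replicates)
  if (any(counts < 1) || any(counts != round(counts))) {
    abort_aqua("design counts must be positive integers.", "config")
  }
  if (cfg$n_channels < 2) abort_aqua("need at least two channels.", "config")
  if (any(cfg$bands$width <= 0)) abort_aqua("band widths must be positive.", "config")
  if (cfg$noise_sd < 0) abort_aqua("noise_sd must be non-negative.", "config")
  missing_rates <- setdiff(cfg$conditions, names(cfg$loss_rate))
  if (length(missing_rates) > 0L) {
    abort_aqua(sprintf("no loss rate for condition(s): %s",
                       paste(missing_rates, collapse = ", ")), "config")
  }
  # worst plausible fruit must keep a positive weight over the horizon
  worst <- max(cfg$loss_rate[cfg$conditions]) * (1 + 5 * cfg$loss_rate_cv) *
    (cfg$n_days - 1)
  if (worst >= 1) {
    abort_aqua("loss rates produce non-positive weights within the design horizon.",
               "config")
  }
  invisible(cfg)
}

config_grid <- function(cfg) {
  seq(cfg$wl_lo, cfg$wl_hi, length.out = cfg$n_channels)
}

# per-(condition, centre) interpolators; returns function(cond, centre, day)
trajectory_fun <- function(cfg) {
  tr <- cfg$trajectories
  keys <- unique(tr[c("condition", "centre")])
  funs <- new.env(parent = emptyenv())
  for (i in seq_len(nrow(keys))) {
    sub <- tr[tr$condition == keys$condition[i] & tr$centre == keys$centre[i], ]
    sub <- sub[order(sub$day), ]
    f <- if (nrow(sub) == 1L) {
      local({ v <- sub$offset; function(d) rep(v, length(d)) })
    } else {
      stats::approxfun(sub$day, sub$offset, rule = 2)
    }
    assign(paste(keys$condition[i], keys$centre[i]), f, envir = funs)
  }
  delay <- cfg$scf_delay
  function(cond, centre, day) {
    if (!is.null(delay) && cond == "SCF") {
      cond <- "CF"
      day <- pmax(day - delay, 0)
    }
    f <- get0(paste(cond, centre), envir = funs)
    if (is.null(f)) return(rep(0, length(day))) else f(day)
  }
}

#' Generate a synthetic spectral dataset
#'
#' Draws the full design of the configuration. Deterministic for a given
#' seed; the draw order is documented (per condition: fruit age shifts, then
#' per-fruit-day age jitter, then per-spectrum offset/slope/gain, then the
#' noise matrix), so a dataset is reproducible in isolation.
#'
#' @param config A [synthetic_config()].
#' @param seed Integer seed (default `config$seed`).
#' @return A [spectra_tbl] with `2 * n_days * n_fruits * n_positions *
#'   n_replicates` rows under the default two-condition design.
#' @export
generate_spectra <- function(config = synthetic_config(), seed = config$seed) {
  cfg <- validate_config(config)
  wl <- config_grid(cfg)
  tf <- trajectory_fun(cfg)
  G <- exp(-0.5 * sweep(outer(cfg$bands$centre, wl, "-")^2, 1L,
                        cfg$bands$width^2, "/"))
  with_seed(seed, {
    parts <- lapply(cfg$conditions, function(cond) {
      meta <- tidyr::expand_grid(
        condition = cond,
        day = seq_len(cfg$n_days) - 1L,
        fruit_id = seq_len(cfg$n_fruits),
        position = c("front", "back")[seq_len(cfg$n_positions)],
        replicate = seq_len(cfg$n_replicates)
      )
      n_sp <- nrow(meta)
      age_shift <- stats::rnorm(cfg$n_fruits, 0, cfg$fruit_age_sd)
      jitter <- matrix(stats::rnorm(cfg$n_fruits * cfg$n_days, 0, cfg$age_jitter_sd),
                       cfg$n_fruits, cfg$n_days)
      eff_day <- pmin(pmax(meta$day + age_shift[meta$fruit_id] +
                             jitter[cbind(meta$fruit_id, meta$day + 1L)], 0),
                      cfg$n_days - 1)
      offset <- stats::rnorm(n_sp, 0, cfg$baseline_offset_sd)
      slope <- stats::rnorm(n_sp, 0, cfg$baseline_slope_sd)
      gain <- pmax(1 + stats::rnorm(n_sp, 0, cfg$gain_sd), 0.1)
      amp <- matrix(rep(cfg$bands$base_amp, each = n_sp), n_sp, nrow(cfg$bands))
      for (b in seq_len(nrow(cfg$bands))) {
        amp[, b] <- amp[, b] + tf(cond, cfg$bands$centre[b], eff_day)
      }
      s <- amp %*% G
      s <- s * gain + offset + outer(slope, wl - cfg$wl_lo)
      if (cfg$noise_sd > 0) {
        s <- s + matrix(stats::rnorm(n_sp * length(wl), 0, cfg$noise_sd),
                        n_sp, length(wl))
      }
      spectra_tbl(meta, wl, s)
    })
    new_spectra_tbl(dplyr::bind_rows(parts))
  })
}

#' Generate a synthetic weight table
#'
#' Linearly declining weights with per-fruit variation of both fresh weight
#' and loss rate: `weight = initial * (1 + eps_f) * (1 - rate_c * (1 +
#' eta_f) * day)`. The control-fridge default rate exceeds the
#' supercooling-fridge rate.
#'
#' @inheritParams generate_spectra
#' @return A validated weight table (`fruit_id`, `condition`, `day`,
#'   `weight_g`).
#' @export
generate_weights <- function(config = synthetic_config(), seed = config$seed) {
  cfg <- validate_config(config)
  with_seed(seed, {
    parts <- lapply(cfg$conditions, function(cond) {
      eps <- stats::rnorm(cfg$n_fruits, 0, cfg$weight_initial_cv)
      eta <- stats::rnorm(cfg$n_fruits, 0, cfg$loss_rate_cv)
      grid <- tidyr::expand_grid(fruit_id = seq_len(cfg$n_fruits),
                                 day = seq_len(cfg$n_days) - 1L)
      rate <- cfg$loss_rate[[cond]]
      w <- cfg$weight_initial * (1 + eps[grid$fruit_id]) *
        (1 - rate * (1 + eta[grid$fruit_id]) * grid$day)
      tibble::tibble(fruit_id = grid$fruit_id, condition = cond,
                     day = grid$day, weight_g = pmax(w, 1e-6))
    })
    validate_weights(dplyr::bind_rows(parts))
  })
}
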