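test_that("the generator honours the declared design counts", {
  cfg <- tiny_config(n_days = 3)
  ds <- generate_spectra(cfg, seed = 1)
  expect_equal(nrow(ds), 2 * 3 * 4)
  expect_setequal(unique(spc_meta(ds)$condition), c("CF", "SCF"))
  expect_equal(sort(unique(spc_meta(ds)$day)), 0:2)
  expect_equal(length(spc_wavelengths(ds)), 125L)
  wt <- generate_weights(cfg, seed = 1)
  counts <- dplyr::count(wt, condition, fruit_id)
  expect_true(all(counts$n == 3))
})

test_that("the same seed reproduces bit-identical data", {
  cfg <- tiny_config()
  expect_identical(generate_spectra(cfg, seed = 5), generate_spectra(cfg, seed = 5))
  expect_identical(generate_weights(cfg, seed = 5), generate_weights(cfg, seed = 5))
  expect_false(identical(spc_matrix(generate_spectra(cfg, seed = 5)),
                         spc_matrix(generate_spectra(cfg, seed = 6))))
})

test_that("with all randomness off, spectra equal the deterministic band curves", {
  bands <- tibble::tibble(centre = c(1400, 1500), width = c(10, 20),
                          base_amp = c(0.5, 0.2))
  traj <- tibble::tibble(condition = "CF", centre = 1400,
                         day = c(0, 4), offset = c(0, 0.1))
  cfg <- synthetic_config(n_days = 5, n_fruits = 1, n_positions = 1,
                          n_replicates = 1, bands = bands, trajectories = traj,
                          noise_sd = 0, gain_sd = 0, baseline_offset_sd = 0,
                          baseline_slope_sd = 0, fruit_age_sd = 0,
                          age_jitter_sd = 0, conditions = "CF",
                          loss_rate = c(CF = 0.005))
  ds <- generate_spectra(cfg, seed = 1)
  wl <- seq(908, 1670, length.out = 125)  # the generator's exact grid
  day <- spc_meta(ds)$day
  expected <- sapply(seq_along(day), function(i) {
    amp1400 <- 0.5 + 0.1 * day[i] / 4
    amp1400 * exp(-0.5 * ((wl - 1400) / 10)^2) +
      0.2 * exp(-0.5 * ((wl - 1500) / 20)^2)
  })
  expect_equal(unname(spc_matrix(ds)), t(expected), tolerance = 1e-12)
})

test_that("SNV wipes out the baseline parameters of the generator", {
  # two worlds differing only in scatter/baseline magnitude give the same
  # post-SNV day means up to Monte-Carlo error
  mean_after_snv <- function(offset_sd, gain_sd, seed) {
    cfg <- synthetic_config(n_fruits = 12, n_positions = 1, n_replicates = 1,
                            baseline_offset_sd = offset_sd,
                            gain_sd = gain_sd, baseline_slope_sd = 0,
                            fruit_age_sd = 0, age_jitter_sd = 0)
    ds <- snv(generate_spectra(cfg, seed = seed))
    meta <- spc_meta(ds)
    colMeans(spc_matrix(ds)[meta$condition == "CF" & meta$day == 7, ])
  }
  set.seed(55)
  d_baseline <- replicate(10, {
    s <- sample.int(1e8, 1)
    max(abs(mean_after_snv(0.05, 0.05, s) - mean_after_snv(0.5, 0.2, s)))
  })
  # scale yardstick: pure Monte-Carlo variation between independent draws
  d_seed <- replicate(10, {
    s <- sample.int(1e8, 2)
    max(abs(mean_after_snv(0.05, 0.05, s[1]) - mean_after_snv(0.05, 0.05, s[2])))
  })
  expect_lt(median(d_baseline), median(d_seed))
})

test_that("weights decline linearly and respect their invariants", {
  cfg <- tiny_config(weight_initial_cv = 0, loss_rate_cv = 0)
  wt <- generate_weights(cfg, seed = 2)
  # exact linear decline at zero fruit-level variation
  cf <- dplyr::filter(wt, condition == "CF", fruit_id == 1)
  expect_equal(cf$weight_g, 20 * (1 - (0.073 / 7) * cf$day), tolerance = 1e-12)
  # zero rates, zero noise: constant weights and zero loss rate
  flat <- generate_weights(tiny_config(loss_rate = c(CF = 0, SCF = 0),
                                       weight_initial_cv = 0, loss_rate_cv = 0),
                           seed = 3)
  expect_true(all(flat$weight_g == 20))
  expect_equal(weight_loss_rate(flat, 1, "CF", 7), 0)
})

test_that("default rates are calibrated to the reported day-7 loss means", {
  set.seed(77)
  means <- replicate(100, {
    wt <- generate_weights(synthetic_config(), seed = sample.int(1e8, 1))
    r <- weight_loss_rates(wt, 7)
    c(mean(r$loss_pct[r$condition == "CF"]), mean(r$loss_pct[r$condition == "SCF"]))
  })
  expect_lt(abs(median(means[1, ]) - 7.3), 0.5)
  expect_lt(abs(median(means[2, ]) - 5.9), 0.5)
})

test_that("invalid configurations are rejected", {
  expect_error(synthetic_config(n_fruits = 0), class = "aquastore_error_config")
  expect_error(synthetic_config(n_channels = 1), class = "aquastore_error_config")
  expect_error(synthetic_config(noise_sd = -1), class = "aquastore_error_config")
  expect_error(synthetic_config(loss_rate = c(CF = 0.2, SCF = 0.2)),
               class = "aquastore_error_config")
  expect_error(synthetic_config(conditions = c("CF", "SCF", "XX")),
               class = "aquastore_error_config")
})
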