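test_that("find_peaks locates interior extrema of |v| with the magnitude threshold", {
  x <- seq_len(81)
  bump <- exp(-0.5 * ((x - 40) / 4)^2)
  pk <- find_peaks(bump)
  expect_equal(pk$channel, 40L)
  expect_equal(pk$sign, 1)
  # a monotone ramp has no interior extremum
  expect_equal(nrow(find_peaks(x / 81)), 0L)
  # negative extrema keep their sign
  pk_neg <- find_peaks(-bump)
  expect_equal(pk_neg$sign, -1)
  # two bumps with 10:1 magnitude: both at 5%, only the larger at 20%
  v <- exp(-0.5 * ((x - 20) / 3)^2) + 0.1 * exp(-0.5 * ((x - 60) / 3)^2)
  expect_equal(find_peaks(v, 0.05)$channel, c(20L, 60L))
  expect_equal(find_peaks(v, 0.2)$channel, 20L)
  expect_equal(nrow(find_peaks(rep(0, 10))), 0L)
  expect_error(find_peaks(c(1, 2)), class = "aquastore_error_insufficient_data")
})

test_that("find_peaks agrees with a brute-force scan on random vectors", {
  for (seed in 1:10) {
    set.seed(seed)
    v <- rnorm(60)
    pk <- find_peaks(v, prominence_frac = 0.3)
    m <- abs(v)
    brute <- which(vapply(2:59, function(i) {
      m[i] >= m[i - 1] && m[i] >= m[i + 1] && (m[i] > m[i - 1] || m[i] > m[i + 1]) &&
        m[i] >= 0.3 * max(m)
    }, logical(1))) + 1L
    expect_equal(pk$channel, brute)
  }
})

test_that("the packaged catalogue holds 28 bands: 24 named WAMACS plus 4 tentative", {
  cat_df <- wamacs_catalog()
  expect_equal(nrow(cat_df), 28L)
  expect_equal(length(unique(cat_df$band_nm)), 28L)
  named <- grepl("^C[0-9]+$", cat_df$label)
  expect_equal(sum(named), 24L)
  expect_setequal(cat_df$label[!named], c("Ci", "Cj", "Ck", "Cl"))
  expect_equal(cat_df$band_nm[!named], c(1503, 1528, 1534, 1559))
  # the 1534 nm band is the most frequently recurring influential variable
  expect_equal(cat_df$importance[cat_df$band_nm == 1534], 5L)
})

test_that("assign_wamacs resolves ranges, tentative bands and misses", {
  expect_equal(assign_wamacs(1385), "C4")
  expect_equal(assign_wamacs(1503), "Ci")
  expect_equal(assign_wamacs(1300), NA_character_)
  expect_equal(assign_wamacs(c(1410, 1428, 1450)), c("C5", "C6", "C8"))
  # tentative snap tolerance
  expect_equal(assign_wamacs(1530, tol = 3), "Cj")
  expect_equal(assign_wamacs(1550, tol = 3), NA_character_)
})

test_that("every catalogued band carries exactly one well-formed label", {
  cat_df <- wamacs_catalog()
  expect_true(all(grepl("^C([0-9]+|[i-l])$", cat_df$label)))
  expect_true(all(table(cat_df$band_nm) == 1))
  # bands printed a few nm outside their assigned region: range-based
  # assignment returns NA for them, the catalogue label stands
  off_range <- cat_df$band_nm[cat_df$lo_nm < cat_df$hi_nm &
                                (cat_df$band_nm < cat_df$lo_nm |
                                   cat_df$band_nm > cat_df$hi_nm)]
  expect_setequal(off_range, c(1379, 1391, 1416, 1447, 1497, 1521))
  in_range <- setdiff(cat_df$band_nm, off_range)
  for (b in in_range) {
    expect_equal(assign_wamacs(b, cat_df),
                 cat_df$label[cat_df$band_nm == b][1])
  }
})

test_that("a catalogue with interior-overlapping regions is rejected at load", {
  bad <- withr::local_tempfile(fileext = ".csv")
  readr::write_csv(tibble::tibble(
    band_nm = c(1350, 1360), label = c("A", "B"),
    lo_nm = c(1340, 1355), hi_nm = c(1358, 1370),
    importance = c(1, 1), assignment = ""
  ), bad)
  expect_error(wamacs_catalog(bad), class = "aquastore_error_catalog_integrity")
})

test_that("tally_importance counts distinct citing analyses per band", {
  sets <- list(diff_cf = c(1373, 1404), simca_cf = c(1373, 1534), plsr_cf = c(1373))
  tab <- tally_importance(sets)
  expect_equal(tab$importance[tab$band_nm == 1373], 3L)
  expect_equal(tab$importance[tab$band_nm == 1404], 1L)
  expect_equal(tab$wamacs[tab$band_nm == 1534], "Ck")
  expect_equal(tab$sources[tab$band_nm == 1373][[1]],
               c("diff_cf", "plsr_cf", "simca_cf"))
  # permutation invariance
  tab2 <- tally_importance(rev(sets))
  expect_equal(tab2, tab)
  # duplicate citations within one analysis count once
  tab3 <- tally_importance(list(a = c(1373, 1373)))
  expect_equal(tab3$importance, 1L)
  empty <- tally_importance(list())
  expect_equal(nrow(empty), 0L)
})

test_that("axis selection keeps importance >= 2 plus tentative bands, one per region", {
  tab <- tally_importance(list(
    a = c(1379, 1385, 1404, 1503), b = c(1385, 1404), c = c(1385)
  ))
  axes <- select_axes(tab, min_importance = 2)
  # 1385 (importance 3) beats 1379 within C4; 1404 kept; 1503 tentative kept
  expect_setequal(axes, c(1385, 1404, 1503))
  # tie on importance resolves to the lower wavelength within a region
  tie <- tally_importance(list(a = c(1382, 1385), b = c(1382, 1385)))
  expect_equal(select_axes(tie), 1382)
})

test_that("axis presets expose the 20- and 19-band sets", {
  expect_length(wamacs_axes(20), 20L)
  expect_length(wamacs_axes(19), 19L)
  expect_setequal(setdiff(wamacs_axes(20), wamacs_axes(19)), 1521)
  expect_error(wamacs_axes(7), class = "aquastore_error_parameter")
})

test_that("an injected storage trend surfaces in all three analyses of the tally", {
  # one band with a strong day trend must be cited by difference spectra,
  # discriminating power and the regression vector
  wl0 <- seq(1300, 1600, length.out = 50)
  target <- wl0[25]
  bands <- tibble::tibble(centre = c(wl0[10], target, wl0[40]),
                          width = 8, base_amp = 0.4)
  traj <- tibble::tibble(condition = "CF", centre = target,
                         day = c(0, 14), offset = c(0, 0.3))
  cfg <- synthetic_config(n_days = 15, n_fruits = 5, n_positions = 1,
                          n_replicates = 1, wl_lo = 1300, wl_hi = 1600,
                          n_channels = 50, bands = bands, trajectories = traj,
                          fruit_age_sd = 0, age_jitter_sd = 0, gain_sd = 0,
                          baseline_offset_sd = 0, baseline_slope_sd = 0,
                          conditions = "CF", loss_rate = c(CF = 0.005),
                          noise_sd = 0.01)
  ds <- generate_spectra(cfg, seed = 42)
  wl <- spc_wavelengths(ds)
  step <- wl[2] - wl[1]
  snap <- function(channels) wl[channels]
  d <- difference_spectrum(ds, "CF", 14, 1)
  peaks_diff <- snap(find_peaks(d$delta, 0.5)$channel)
  m <- fit_simca(ds)
  peaks_dp <- snap(find_peaks(m$discriminating_power, 0.5)$channel)
  cv <- plsr_cv(ds, n_lv_max = 5, segment = 5)
  peaks_rv <- snap(find_peaks(cv$model$regression_vector, 0.5)$channel)
  hit <- function(p) p[which.min(abs(p - target))]
  tab <- tally_importance(list(diff = hit(peaks_diff), dp = hit(peaks_dp),
                               rv = hit(peaks_rv)))
  near <- tab[abs(tab$band_nm - target) <= step, ]
  expect_equal(sum(near$importance), 3L)
})
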