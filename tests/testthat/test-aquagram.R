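test_that("the reference-day profile is identically zero", {
  ds <- generate_spectra(tiny_config(), seed = 1)
  p <- compute_aquagram(ds, reference_day = 1)
  ref <- p$value[p$day == 1]
  expect_equal(ref, rep(0, length(ref)))
  expect_equal(attr(p, "reference_day"), 1)
  # day 0 reference also supported
  p0 <- compute_aquagram(ds, reference_day = 0)
  expect_equal(p0$value[p0$day == 0], rep(0, sum(p0$day == 0)))
})

test_that("profiles are invariant to constant offset and positive gain on raw spectra", {
  ds <- generate_spectra(tiny_config(n_days = 6), seed = 2)
  p1 <- compute_aquagram(ds)
  shifted <- spc_set_matrix(ds, 2.5 * spc_matrix(ds) + 7)
  p2 <- compute_aquagram(shifted)
  expect_equal(p2$value, p1$value, tolerance = 1e-10)
})

test_that("profiles are antisymmetric under swapping reference and target day", {
  ds <- generate_spectra(tiny_config(n_days = 6), seed = 3)
  p_ref1 <- compute_aquagram(ds, reference_day = 1)
  p_ref4 <- compute_aquagram(ds, reference_day = 4)
  v14 <- p_ref1$value[p_ref1$condition == "CF" & p_ref1$day == 4]
  v41 <- p_ref4$value[p_ref4$condition == "CF" & p_ref4$day == 1]
  expect_equal(v41, -v14, tolerance = 1e-10)
})

test_that("axis order does not affect the values", {
  ds <- generate_spectra(tiny_config(n_days = 4), seed = 4)
  axes <- c(1360, 1410, 1459, 1534)
  p1 <- compute_aquagram(ds, axes = axes)
  p2 <- compute_aquagram(ds, axes = rev(axes))
  expect_equal(tibble::as_tibble(p1), tibble::as_tibble(p2))
})

test_that("axis snapping errors are raised", {
  ds <- generate_spectra(tiny_config(n_days = 4), seed = 5)
  expect_error(compute_aquagram(ds, axes = c(1400, 1401)),
               class = "aquastore_error_axis_collision")
  expect_error(compute_aquagram(ds, axes = 2100),
               class = "aquastore_error_out_of_range")
  expect_error(compute_aquagram(dplyr::filter(tibble::as_tibble(ds), day > 2)),
               class = "aquastore_error_missing_group")
})

test_that("profile comparison has the expected identities", {
  ds <- generate_spectra(tiny_config(n_days = 6), seed = 6)
  p <- compute_aquagram(ds)
  self <- compare_profiles(p, tibble::tibble(
    condition_a = "CF", day_a = 4, condition_b = "CF", day_b = 4))
  expect_equal(self$cosine, 1)
  expect_equal(self$rms, 0)
  expect_error(
    compare_profiles(p, tibble::tibble(condition_a = "CF", day_a = 99,
                                       condition_b = "CF", day_b = 4)),
    class = "aquastore_error_missing_group")
  # a profile against its negation
  u <- profile_vector(p, "CF", 4)
  expect_equal(aquastore:::cosine_sim(u, -u), -1)
})

test_that("identically parameterised conditions give matching day-1 patterns", {
  # CF and SCF share every trajectory: day-1 profile differences stay inside
  # the per-axis standard-error envelope of the group means
  traj <- default_trajectories()
  cf <- traj[traj$condition == "CF", ]
  scf <- dplyr::mutate(cf, condition = "SCF")
  cfg <- synthetic_config(n_fruits = 12, n_positions = 1, n_replicates = 1,
                          trajectories = dplyr::bind_rows(cf, scf),
                          fruit_age_sd = 0.3, age_jitter_sd = 0.3)
  axes <- wamacs_axes(20)
  set.seed(70)
  inside <- unlist(lapply(1:20, function(i) {
    ds <- generate_spectra(cfg, seed = sample.int(1e8, 1))
    p <- compute_aquagram(ds, reference_day = 0)
    d <- profile_vector(p, "CF", 1) - profile_vector(p, "SCF", 1)
    # per-axis SE of the difference of reference-subtracted group means
    z <- standardize_per_wavelength(snv(ds))
    idx <- nearest_channel(ds, axes)
    meta <- spc_meta(z)
    zm <- spc_matrix(z)[, idx, drop = FALSE]
    grp_var <- function(cond, day) {
      apply(zm[meta$condition == cond & meta$day == day, , drop = FALSE], 2, var)
    }
    n <- cfg$n_fruits
    se <- sqrt((grp_var("CF", 1) + grp_var("CF", 0) +
                  grp_var("SCF", 1) + grp_var("SCF", 0)) / n)
    abs(d[order(as.numeric(names(d)))]) <= 3 * se[order(axes)]
  }))
  expect_gt(mean(inside), 0.95)
})

test_that("exports write the profile tables", {
  ds <- generate_spectra(tiny_config(n_days = 4), seed = 8)
  p <- compute_aquagram(ds)
  csv <- withr::local_tempfile(fileext = ".csv")
  js <- withr::local_tempfile(fileext = ".json")
  write_aquagram(p, csv)
  write_aquagram(p, js, format = "json")
  back <- readr::read_csv(csv, show_col_types = FALSE)
  expect_equal(nrow(back), nrow(p))
  parsed <- jsonlite::read_json(js, simplifyVector = TRUE)
  expect_equal(parsed$reference_day, 1)
  expect_s3_class(autoplot(p), "ggplot")
})
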