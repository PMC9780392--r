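test_that("exactly rank-k class data is captured with near-zero residuals", {
  set.seed(1)
  p <- 30
  scores <- matrix(rnorm(10 * 2), 10, 2)
  basis <- qr.Q(qr(matrix(rnorm(p * 2), p, 2)))
  x1 <- scores %*% t(basis)                      # rank-2 around zero mean
  x2 <- matrix(rnorm(10 * p, 5, 1), 10, p)       # a second, separated class
  ds <- spectra_tbl(data.frame(day = rep(0:1, each = 10)),
                    seq(1300, 1600, length.out = p), rbind(x1, x2))
  m <- fit_simca(ds)
  expect_equal(unname(m$k["0"]), 2L)
  expect_lt(m$s2_pooled["0", "0"], 1e-20)
})

test_that("interclass distance separates distinct classes and not identical ones", {
  # distinct means, tiny isotropic noise
  sep <- two_class_spectra(15, 40, shift = rnorm(40, 0, 1), noise_sd = 0.05, seed = 2)
  m <- fit_simca(sep)
  expect_gt(interclass_distance(m, "0", "1"), 3)
  expect_equal(interclass_distance(m, "0", "0"), 0)
  expect_equal(m$distance["0", "1"], m$distance["1", "0"])
  # same distribution: small distance on one draw
  same <- two_class_spectra(40, 40, shift = rep(0, 40), seed = 3)
  expect_lt(interclass_distance(fit_simca(same), "0", "1"), 0.5)
})

test_that("interclass distance grows with injected mean separation", {
  d_at <- vapply(c(0.5, 2, 8), function(s) {
    ds <- two_class_spectra(15, 30, shift = rep(s, 30), noise_sd = 1, seed = 4)
    interclass_distance(fit_simca(ds), "0", "1")
  }, numeric(1))
  expect_true(all(diff(d_at) > 0))
})

test_that("classification assigns class means to their class and recovers held-out labels", {
  set.seed(6)
  p <- 40
  centers <- matrix(rnorm(5 * p, 0, 4), 5, p)
  x <- do.call(rbind, lapply(1:5, function(c0) {
    matrix(rnorm(12 * p, 0, 0.2), 12, p) + matrix(centers[c0, ], 12, p, byrow = TRUE)
  }))
  days <- rep(0:4, each = 12)
  train <- c(outer(1:9, (0:4) * 12, `+`))
  test <- setdiff(seq_len(60), train)
  wl <- seq(1300, 1600, length.out = p)
  ds_train <- spectra_tbl(data.frame(day = days[train]), wl, x[train, ])
  ds_test <- spectra_tbl(data.frame(day = days[test]), wl, x[test, ])
  m <- fit_simca(ds_train)
  # a class mean classifies to its class with near-zero distance
  res_mu <- classify(m, m$mu["2", ])
  expect_equal(res_mu$pred, "2")
  expect_lt(res_mu$.dist_2, 0.5)
  # well-separated held-out spectra: 100% accuracy
  expect_equal(simca_accuracy(m, ds_test), 100)
  expect_error(classify(m, x[1, 1:10]), class = "aquastore_error_incompatible_grid")
})

test_that("permuted labels drop held-out accuracy to chance", {
  set.seed(8)
  accs <- replicate(50, {
    p <- 20
    centers <- matrix(rnorm(5 * p, 0, 4), 5, p)
    x <- do.call(rbind, lapply(1:5, function(c0) {
      matrix(rnorm(8 * p, 0, 0.2), 8, p) + matrix(centers[c0, ], 8, p, byrow = TRUE)
    }))
    train <- c(outer(1:6, (0:4) * 8, `+`))
    # labels shuffled but balanced, so classes are unrelated to the clusters
    lab_train <- sample(rep(0:4, each = 6))
    lab_test <- sample(rep(0:4, each = 2))
    wl <- seq(1300, 1600, length.out = p)
    m <- fit_simca(spectra_tbl(data.frame(day = lab_train), wl, x[train, ]))
    simca_accuracy(m, spectra_tbl(data.frame(day = lab_test), wl, x[-train, ]))
  })
  # binomial CI around the 20% chance level
  expect_gt(mean(accs), 10)
  expect_lt(mean(accs), 30)
})

test_that("discriminating power is flat near 1 for identical classes and localises differences", {
  same <- two_class_spectra(40, 30, shift = rep(0, 30), seed = 10)
  dp <- discriminating_power(fit_simca(same))
  expect_true(all(dp > 0.5 & dp < 2))
  # classes differing only at channel 17
  shift <- rep(0, 30); shift[17] <- 3
  diffd <- two_class_spectra(25, 30, shift = shift, seed = 11)
  m <- fit_simca(diffd)
  expect_equal(which.max(m$discriminating_power), 17L)
  # scale invariance: doubling the absorbance units leaves the profile unchanged
  doubled <- spc_set_matrix(diffd, 2 * spc_matrix(diffd))
  expect_equal(discriminating_power(fit_simca(doubled)),
               m$discriminating_power, tolerance = 1e-10)
})

test_that("training accuracy is at least held-out accuracy on average", {
  set.seed(12)
  gap <- replicate(30, {
    p <- 15
    centers <- matrix(rnorm(3 * p, 0, 1), 3, p)
    x <- do.call(rbind, lapply(1:3, function(c0) {
      matrix(rnorm(10 * p, 0, 1), 10, p) + matrix(centers[c0, ], 10, p, byrow = TRUE)
    }))
    days <- rep(0:2, each = 10)
    train <- c(outer(1:7, (0:2) * 10, `+`))
    wl <- seq(1300, 1600, length.out = p)
    m <- fit_simca(spectra_tbl(data.frame(day = days[train]), wl, x[train, ]))
    simca_accuracy(m, spectra_tbl(data.frame(day = days[train]), wl, x[train, ])) -
      simca_accuracy(m, spectra_tbl(data.frame(day = days[-train]), wl, x[-train, ]))
  })
  expect_gte(mean(gap), 0)
})

test_that("degenerate inputs raise the documented errors", {
  ds <- rand_spectra(6, 10, seed = 13, days = rep(0, 6))
  expect_error(fit_simca(ds), class = "aquastore_error_need_two_classes")
  small <- rand_spectra(4, 10, seed = 14, days = c(0, 0, 0, 1))
  expect_error(fit_simca(small), class = "aquastore_error_undersized_class")
  expect_error(fit_simca(ds, class_key = "nope"), class = "aquastore_error_schema")
})

test_that("JSON serialisation round-trips classification behaviour", {
  ds <- two_class_spectra(10, 15, shift = rep(1, 15), seed = 15)
  m <- fit_simca(ds)
  path <- withr::local_tempfile(fileext = ".json")
  write_simca(m, path)
  back <- read_simca(path)
  expect_equal(back$distance, m$distance, tolerance = 1e-8)
  expect_equal(back$discriminating_power, m$discriminating_power, tolerance = 1e-8)
  expect_equal(classify(back, ds)$pred, classify(m, ds)$pred)
})

test_that("tidy and glance expose the model summaries", {
  ds <- two_class_spectra(10, 15, shift = rep(1, 15), seed = 16)
  m <- fit_simca(ds)
  td <- tidy(m)
  expect_named(td, c("wavelength", "discriminating_power"))
  expect_equal(nrow(td), 15L)
  gl <- glance(m)
  expect_equal(gl$n_classes, 2L)
  expect_s3_class(autoplot(m), "ggplot")
})
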