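# shared fixtures: all data are generated in code at test time

grid125 <- seq(908, 1670, length.out = 125)

# scaled-down storage design: 4 fruits, one position, single replicates
tiny_config <- function(...) {
  args <- utils::modifyList(
    list(n_fruits = 4, n_positions = 1, n_replicates = 1), list(...))
  do.call(synthetic_config, args)
}

# random labelled dataset on an arbitrary grid
rand_spectra <- function(n, p, seed = 1, days = NULL) {
  set.seed(seed)
  if (is.null(days)) days <- rep(0L, n)
  spectra_tbl(
    meta = data.frame(condition = "CF", day = days),
    wavelengths = seq(1300, 1600, length.out = p),
    absorbance = matrix(stats::rnorm(n * p), n, p)
  )
}

# two-class dataset with a given per-channel mean shift applied to class 1
two_class_spectra <- function(n_per, p, shift, noise_sd = 1, seed = 1) {
  set.seed(seed)
  base <- stats::rnorm(p)
  x <- rbind(
    matrix(stats::rnorm(n_per * p, 0, noise_sd), n_per, p),
    matrix(stats::rnorm(n_per * p, 0, noise_sd), n_per, p) +
      matrix(shift, n_per, p, byrow = TRUE)
  )
  x <- sweep(x, 2L, -base)
  spectra_tbl(
    meta = data.frame(condition = "CF", day = rep(0:1, each = n_per)),
    wavelengths = seq(1300, 1600, length.out = p),
    absorbance = x
  )
}
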