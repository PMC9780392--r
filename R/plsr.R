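# NIPALS PLS1 core. For a univariate response the weight update is
# non-iterative: w = X'y / ||X'y|| per component, followed by deflation.
# Returns the decomposition plus per-component regression vectors.
nipals_pls1 <- function(X, y, n_lv, tol = 1e-12) {
  n <- nrow(X)
  p <- ncol(X)
  xm <- colMeans(X)
  ym <- mean(y)
  Xd <- sweep(X, 2L, xm)
  yd <- y - ym
  W <- matrix(0, p, n_lv)
  P <- matrix(0, p, n_lv)
  Tt <- matrix(0, n, n_lv)
  q <- numeric(n_lv)
  a_used <- 0L
  for (a in seq_len(n_lv)) {
    w <- crossprod(Xd, yd)
    nw <- sqrt(sum(w^2))
    if (nw < tol) break
    w <- w / nw
    t_a <- Xd %*% w
    tt <- sum(t_a^2)
    if (tt < tol) break
    p_a <- crossprod(Xd, t_a) / tt
    q_a <- sum(yd * t_a) / tt
    Xd <- Xd - tcrossprod(t_a, p_a)
    yd <- yd - q_a * t_a
    W[, a] <- w
    P[, a] <- p_a
    Tt[, a] <- t_a
    q[a] <- q_a
    a_used <- a
  }
  if (a_used == 0L) abort_aqua("X carries no covariance with the response.", "degenerate_response")
  list(W = W[, seq_len(a_used), drop = FALSE],
       P = P[, seq_len(a_used), drop = FALSE],
       scores = Tt[, seq_len(a_used), drop = FALSE],
       q = q[seq_len(a_used)], x_mean = xm, y_mean = ym, n_lv = a_used)
}

# regression vector using the first k components
pls1_coef <- function(fit, k = fit$n_lv) {
  Wk <- fit$W[, seq_len(k), drop = FALSE]
  Pk <- fit$P[, seq_len(k), drop = FALSE]
  drop(Wk %*% solve(crossprod(Pk, Wk), fit$q[seq_len(k)]))
}

resolve_xy <- function(x, y) {
  if (inherits(x, "spectra_tbl") || (is.data.frame(x) && length(spc_wl_cols(x)) > 0)) {
    X <- spc_matrix(x)
    wl <- spc_wavelengths(x)
    if (is.null(y)) y <- "day"
    if (is.character(y) && length(y) == 1L) {
      meta <- spc_meta(x)
      if (!y %in% names(meta)) abort_aqua(sprintf("unknown response column: %s", y), "schema")
      y <- as.numeric(meta[[y]])
    }
  } else {
    X <- as.matrix(x)
    wl <- seq_len(ncol(X))
    if (is.null(y)) abort_aqua("`y` is required when `x` is a matrix.", "parameter")
  }
  if (length(y) != nrow(X)) abort_aqua("response length must match the spectrum count.", "schema")
  list(X = X, y = as.numeric(y), wl = wl)
}

#' PLS1 regression of spectra on storage time
#'
#' NIPALS partial least squares with a single response (days of storage),
#' fitted on mean-centred raw spectra and a centred response. Calibration
#' metrics follow the chemometric convention: `SEC = sqrt(RSS / n)` and
#' `R2c = 1 - RSS / TSS`. The number of latent variables is capped at 15.
#'
#' A roughness statistic (sum of squared second differences of the
#' regression vector, normalised by its squared norm) automates the visual
#' "jaggedness" overfitting check: models whose roughness exceeds 10 times
#' the 2-component baseline are flagged, not rejected.
#'
#' @param x A [spectra_tbl] or numeric matrix of predictors.
#' @param y Response: numeric vector, or the name of a metadata column when
#'   `x` is a spectra tibble (default `"day"`).
#' @param n_lv Number of latent variables, `1 <= n_lv <= 15`.
#' @return An object of class `plsr_model`: decomposition, per-channel
#'   regression vector, intercept, fitted values, `SEC`, `R2c`, roughness.
#' @export
fit_plsr <- function(x, y = NULL, n_lv = 10) {
  dat <- resolve_xy(x, y)
  if (n_lv < 1) abort_aqua("`n_lv` must be at least 1.", "parameter")
  if (n_lv > 15) abort_aqua("number of latent variables limited to 15.", "limit_exceeded")
  if (nrow(dat$X) <= n_lv) {
    abort_aqua("need more spectra than latent variables.", "insufficient_data")
  }
  if (stats::sd(dat$y) == 0) abort_aqua("response is constant.", "degenerate_response")
  fit <- nipals_pls1(dat$X, dat$y, n_lv)
  coef <- pls1_coef(fit)
  intercept <- fit$y_mean - sum(fit$x_mean * coef)
  fitted <- drop(intercept + dat$X %*% coef)
  rss <- sum((dat$y - fitted)^2)
  tss <- sum((dat$y - mean(dat$y))^2)
  coef2 <- pls1_coef(fit, min(2L, fit$n_lv))
  structure(
    list(
      wavelengths = dat$wl, n_lv = fit$n_lv,
      weights = fit$W, loadings = fit$P, scores = fit$scores, q = fit$q,
      x_mean = fit$x_mean, y_mean = fit$y_mean,
      regression_vector = coef, intercept = intercept,
      fitted = fitted, y = dat$y,
      SEC = sqrt(rss / length(dat$y)), R2c = 1 - rss / tss,
      roughness = roughness(coef), roughness_baseline = roughness(coef2)
    ),
    class = "plsr_model"
  )
}

#' Roughness of a regression vector
#'
#' Sum of squared second differences normalised by the squared norm; the
#' automated stand-in for visual inspection of regression vectors for
#' jaggedness.
#'
#' @param b Numeric coefficient vector.
#' @return Non-negative roughness statistic.
#' @export
roughness <- function(b) {
  if (length(b) < 3L || sum(b^2) == 0) return(0)
  sum(diff(b, differences = 2)^2) / sum(b^2)
}

#' Predict storage days from spectra
#'
#' @param object A `plsr_model`.
#' @param newdata A [spectra_tbl] or matrix on the training grid.
#' @param ... Unused.
#' @return Numeric vector of predicted days.
#' @export
predict.plsr_model <- function(object, newdata, ...) {
  if (inherits(newdata, "spectra_tbl") ||
      (is.data.frame(newdata) && length(spc_wl_cols(newdata)) > 0)) {
    wl <- spc_wavelengths(newdata)
    if (length(wl) != length(object$wavelengths) ||
        max(abs(wl - object$wavelengths)) > 1e-6) {
      abort_aqua("wavelength grid does not match the training grid.", "incompatible_grid")
    }
    X <- spc_matrix(newdata)
  } else {
    X <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
    if (ncol(X) != length(object$wavelengths)) {
      abort_aqua("spectrum length does not match the training grid.", "incompatible_grid")
    }
  }
  drop(object$intercept + X %*% object$regression_vector)
}

#' Segment-exclusion cross-validation of the PLS1 time regression
#'
#' Leaves out `segment` spectra at a time — by default contiguous blocks in
#' dataset (acquisition) order, matching a stepwise exclusion of six spectra
#' per iteration; a venetian-blind alternative interleaves the folds. For
#' every candidate number of latent variables it accumulates PRESS over the
#' held-out predictions: `SECV = sqrt(PRESS / n)`, `R2cv = 1 - PRESS / TSS`.
#' The returned model is refitted on all data with the SECV-minimising
#' number of components.
#'
#' @inheritParams fit_plsr
#' @param n_lv_max Largest number of latent variables scanned (<= 15).
#' @param segment Spectra excluded per iteration (default 6).
#' @param scheme `"block"` (contiguous, default) or `"venetian"`.
#' @return An object of class `plsr_cv`: `metrics` (one row per n_lv with
#'   `SEC`, `R2c`, `SECV`, `R2cv`, roughness and jaggedness flag), the
#'   chosen `n_lv`, held-out predictions at the chosen rank, and the
#'   refitted `model`.
#' @export
plsr_cv <- function(x, y = NULL, n_lv_max = 15, segment = 6,
                    scheme = c("block", "venetian")) {
  scheme <- match.arg(scheme)
  dat <- resolve_xy(x, y)
  if (segment <= 0) abort_aqua("`segment` must be positive.", "parameter")
  if (n_lv_max > 15) abort_aqua("number of latent variables limited to 15.", "limit_exceeded")
  n <- nrow(dat$X)
  if (n < 2 * segment) {
    abort_aqua("need at least two segments' worth of spectra.", "insufficient_data")
  }
  if (stats::sd(dat$y) == 0) abort_aqua("response is constant.", "degenerate_response")
  n_fold <- ceiling(n / segment)
  fold_id <- switch(scheme,
    block = rep(seq_len(n_fold), each = segment, length.out = n),
    venetian = rep_len(seq_len(n_fold), n)
  )
  a_max <- min(n_lv_max, ncol(dat$X))
  press <- numeric(a_max)
  cv_pred <- matrix(NA_real_, n, a_max)
  for (f in seq_len(n_fold)) {
    test <- fold_id == f
    Xtr <- dat$X[!test, , drop = FALSE]
    ytr <- dat$y[!test]
    a_f <- min(a_max, nrow(Xtr) - 1L)
    fit <- nipals_pls1(Xtr, ytr, a_f)
    for (k in seq_len(a_max)) {
      kk <- min(k, fit$n_lv)
      bk <- pls1_coef(fit, kk)
      icept <- fit$y_mean - sum(fit$x_mean * bk)
      cv_pred[test, k] <- drop(icept + dat$X[test, , drop = FALSE] %*% bk)
    }
  }
  tss <- sum((dat$y - mean(dat$y))^2)
  press <- colSums((cv_pred - dat$y)^2)
  secv <- sqrt(press / n)
  r2cv <- 1 - press / tss

  # full-data fit once at the largest rank; per-rank calibration metrics
  full <- nipals_pls1(dat$X, dat$y, a_max)
  sec <- numeric(a_max)
  r2c <- numeric(a_max)
  rough <- numeric(a_max)
  for (k in seq_len(a_max)) {
    kk <- min(k, full$n_lv)
    bk <- pls1_coef(full, kk)
    icept <- full$y_mean - sum(full$x_mean * bk)
    res <- dat$y - drop(icept + dat$X %*% bk)
    sec[k] <- sqrt(sum(res^2) / n)
    r2c[k] <- 1 - sum(res^2) / tss
    rough[k] <- roughness(bk)
  }
  base <- rough[min(2L, a_max)]
  metrics <- tibble::tibble(
    n_lv = seq_len(a_max), SEC = sec, R2c = r2c, SECV = secv, R2cv = r2cv,
    roughness = rough,
    jagged = base > 0 & rough > 10 * base
  )
  chosen <- which.min(secv)
  model <- fit_plsr(dat$X, dat$y, n_lv = chosen)
  model$wavelengths <- dat$wl
  structure(
    list(metrics = metrics, n_lv = chosen, model = model,
         cv_predictions = cv_pred[, chosen], y = dat$y,
         SECV = secv[chosen], R2cv = r2cv[chosen],
         segment = segment, scheme = scheme, n_folds = n_fold),
    class = "plsr_cv"
  )
}

#' @export
print.plsr_model <- function(x, ...) {
  cat(sprintf("PLS1 model: %d latent variables, %d channels\n", x$n_lv,
              length(x$wavelengths)))
  cat(sprintf("R2c = %.4f, SEC = %.4f\n", x$R2c, x$SEC))
  invisible(x)
}

#' @export
print.plsr_cv <- function(x, ...) {
  cat(sprintf("PLS1 cross-validation (%s segments of %d, %d folds)\n",
              x$scheme, x$segment, x$n_folds))
  cat(sprintf("chosen n_lv = %d: R2cv = %.4f, SECV = %.4f\n",
              x$n_lv, x$R2cv, x$SECV))
  invisible(x)
}

#' @export
tidy.plsr_model <- function(x, ...) {
  tibble::tibble(wavelength = x$wavelengths, coefficient = x$regression_vector)
}

#' @export
glance.plsr_model <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, SEC = x$SEC, R2c = x$R2c,
                 roughness = x$roughness)
}

#' @export
tidy.plsr_cv <- function(x, ...) x$metrics

#' @export
glance.plsr_cv <- function(x, ...) {
  tibble::tibble(n_lv = x$n_lv, SEC = x$metrics$SEC[x$n_lv],
                 R2c = x$metrics$R2c[x$n_lv], SECV = x$SECV, R2cv = x$R2cv)
}

#' @export
predict.plsr_cv <- function(object, newdata, ...) predict(object$model, newdata, ...)

#' @export
autoplot.plsr_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$wavelength, y = .data$coefficient)) +
    ggplot2::geom_hline(yintercept = 0, linetype = 2, colour = "grey60") +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "regression coefficient",
                  title = sprintf("PLS1 regression vector (%d LV)", object$n_lv))
}

#' @export
autoplot.plsr_cv <- function(object, ...) {
  long <- tidyr::pivot_longer(object$metrics, c("SEC", "SECV"),
                              names_to = "metric", values_to = "error")
  ggplot2::ggplot(long, ggplot2::aes(x = .data$n_lv, y = .data$error,
                                     colour = .data$metric)) +
    ggplot2::geom_line() +
    ggplot2::geom_point() +
    ggplot2::geom_vline(xintercept = object$n_lv, linetype = 3) +
    ggplot2::labs(x = "latent variables", y = "error (days)",
                  title = "Calibration and cross-validation error")
}

#' Export the cross-validation metrics table
#'
#' @param cv A `plsr_cv` object.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_plsr_metrics <- function(cv, path) {
  readr::write_csv(cv$metrics, path, progress = FALSE)
  invisible(path)
}
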