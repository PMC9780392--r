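#' Fit a SIMCA model (one PCA per class)
#'
#' Soft independent modelling of class analogies: a separate principal
#' component model is fitted to the mean-centred spectra of every class
#' (here, storage day). Cross-fitted residual variances — class-i samples
#' reconstructed under the class-j model — drive classification, the
#' interclass distance matrix and the per-wavelength discriminating power.
#' SIMCA consumes raw (not SNV-transformed) spectra.
#'
#' The number of retained components per class is the smallest number
#' explaining at least `var_explained` of the class variance, capped at
#' `min(k_max, n_c - 2)`.
#'
#' @param ds A [spectra_tbl] (raw spectra).
#' @param class_key Metadata column defining classes (default `"day"`).
#' @param var_explained Variance fraction a class model must explain
#'   (default 0.95).
#' @param k_max Hard cap on components per class (default 5).
#' @return An object of class `simca_model` with per-class means, loadings,
#'   retained ranks, the cross-residual variance tables (pooled and
#'   per-channel), the interclass distance matrix and the discriminating
#'   power vector.
#' @export
fit_simca <- function(ds, class_key = "day", var_explained = 0.95, k_max = 5) {
  meta <- spc_meta(ds)
  if (!class_key %in% names(meta)) {
    abort_aqua(sprintf("unknown class key: %s", class_key), "schema")
  }
  x <- spc_matrix(ds)
  wl <- spc_wavelengths(ds)
  cls <- as.character(meta[[class_key]])
  classes <- as.character(sort(unique(meta[[class_key]])))
  g <- length(classes)
  if (g < 2L) abort_aqua("SIMCA needs at least two classes.", "need_two_classes")
  p <- ncol(x)

  mu <- matrix(NA_real_, g, p, dimnames = list(classes, NULL))
  loadings <- vector("list", g)
  names(loadings) <- classes
  k <- integer(g)
  n_per <- integer(g)
  for (ci in seq_len(g)) {
    xc <- x[cls == classes[ci], , drop = FALSE]
    n_c <- nrow(xc)
    if (n_c < 3L) {
      abort_aqua(sprintf("class %s has %d spectra; at least 3 required.",
                         classes[ci], n_c), "undersized_class")
    }
    n_per[ci] <- n_c
    mu[ci, ] <- colMeans(xc)
    z <- sweep(xc, 2L, mu[ci, ])
    sv <- svd(z)
    tot <- sum(sv$d^2)
    cap <- max(1L, min(k_max, n_c - 2L))
    if (tot <= .Machine$double.eps) {
      k_c <- 1L
    } else {
      frac <- cumsum(sv$d^2) / tot
      k_c <- min(which(frac >= var_explained - 1e-12)[1], cap)
    }
    k[ci] <- k_c
    loadings[[ci]] <- sv$v[, seq_len(k_c), drop = FALSE]
  }

  # cross residual variances: class-a rows under class-b model
  s2_pooled <- matrix(NA_real_, g, g, dimnames = list(classes, classes))
  s2_channel <- array(NA_real_, dim = c(g, g, p),
                      dimnames = list(classes, classes, NULL))
  for (a in seq_len(g)) {
    xa <- x[cls == classes[a], , drop = FALSE]
    for (b in seq_len(g)) {
      z <- sweep(xa, 2L, mu[b, ])
      e <- z - (z %*% loadings[[b]]) %*% t(loadings[[b]])
      s2_channel[a, b, ] <- colMeans(e^2)
      s2_pooled[a, b] <- mean(e^2)
    }
  }

  model <- structure(
    list(
      classes = classes, class_key = class_key, wavelengths = wl,
      mu = mu, loadings = loadings, k = stats::setNames(k, classes),
      n_per_class = stats::setNames(n_per, classes),
      s2_pooled = s2_pooled, s2_channel = s2_channel,
      settings = list(var_explained = var_explained, k_max = k_max)
    ),
    class = "simca_model"
  )
  model$distance <- interclass_distances(model)
  model$discriminating_power <- discriminating_power(model)
  model
}

#' Interclass distance between two SIMCA class models
#'
#' `sqrt((s_ij^2 + s_ji^2) / (s_ii^2 + s_jj^2)) - 1` with `s_ab^2` the pooled
#' mean squared residual of class-a samples under the class-b model. The
#' offset makes identically distributed classes score approximately zero;
#' well separated storage days score well above 1.
#'
#' @param model A `simca_model`.
#' @param i,j Class labels (or indices).
#' @return Non-negative distance (0 when `i == j`).
#' @export
interclass_distance <- function(model, i, j) {
  i <- resolve_class(model, i)
  j <- resolve_class(model, j)
  if (i == j) return(0)
  s2 <- model$s2_pooled
  denom <- s2[i, i] + s2[j, j]
  if (denom <= 0) {
    abort_aqua("both classes have zero self-residual variance.", "degenerate_model")
  }
  sqrt((s2[i, j] + s2[j, i]) / denom) - 1
}

resolve_class <- function(model, i) {
  if (is.numeric(i)) {
    if (i < 1 || i > length(model$classes)) abort_aqua("class index out of range.", "parameter")
    return(as.integer(i))
  }
  pos <- match(as.character(i), model$classes)
  if (is.na(pos)) abort_aqua(sprintf("unknown class: %s", i), "parameter")
  pos
}

interclass_distances <- function(model) {
  g <- length(model$classes)
  d <- matrix(0, g, g, dimnames = list(model$classes, model$classes))
  for (a in seq_len(g)) for (b in seq_len(g)) {
    if (a < b) {
      d[a, b] <- d[b, a] <- interclass_distance(model, a, b)
    }
  }
  d
}

#' Per-wavelength discriminating power
#'
#' Ratio of between-class to within-class residual variance at every
#' channel: `sqrt(sum_{i<j}(s_ij^2(l) + s_ji^2(l)) / sum_i s_ii^2(l))`.
#' Channels where classes differ only in directions outside their own class
#' models light up; for two identically distributed classes the profile is
#' flat at about 1. The statistic is invariant to rescaling the absorbance
#' units.
#'
#' @param model A `simca_model`.
#' @return Numeric vector, one non-negative value per channel.
#' @export
discriminating_power <- function(model) {
  g <- length(model$classes)
  p <- length(model$wavelengths)
  num <- rep(0, p)
  den <- rep(0, p)
  for (a in seq_len(g)) {
    den <- den + model$s2_channel[a, a, ]
    for (b in seq_len(g)) {
      if (a != b) num <- num + model$s2_channel[a, b, ]
    }
  }
  if (any(den == 0)) {
    rlang::warn("zero within-class residual variance at some channel(s); floored at machine epsilon.")
    den[den == 0] <- .Machine$double.eps
  }
  sqrt(num / den)
}

#' Classify spectra against a SIMCA model
#'
#' Every spectrum is assigned to the class with the smallest standardised
#' residual distance (RMS reconstruction residual under the class model,
#' divided by the class pooled residual sd). A spectrum whose best residual
#' variance exceeds the class critical limit (F test at `alpha`) is flagged
#' `no_match`, but still carries the arg-min label — accuracy reporting has
#' no reject class.
#'
#' @param model A `simca_model`.
#' @param newdata A [spectra_tbl], numeric matrix on the training grid, or a
#'   single spectrum vector.
#' @param alpha Significance level of the no-match limit (default 0.05).
#' @return Tibble: one row per spectrum with `pred`, `no_match`, and one
#'   `.dist_<class>` column per class.
#' @export
classify <- function(model, newdata, alpha = 0.05) {
  x <- resolve_grid(model, newdata)
  g <- length(model$classes)
  p <- ncol(x)
  vmat <- matrix(NA_real_, nrow(x), g)  # mean squared residual per class
  for (b in seq_len(g)) {
    z <- sweep(x, 2L, model$mu[b, ])
    e <- z - (z %*% model$loadings[[b]]) %*% t(model$loadings[[b]])
    vmat[, b] <- rowMeans(e^2)
  }
  s0 <- diag(model$s2_pooled)
  if (any(s0 <= 0)) {
    abort_aqua("a class has zero self-residual variance; distances undefined.",
               "degenerate_model")
  }
  dist <- sweep(vmat, 2L, s0, "/")
  dist <- sqrt(dist)
  best <- max.col(-dist, ties.method = "first")
  crit <- vapply(seq_len(g), function(b) {
    df1 <- max(1L, p - model$k[b])
    df2 <- max(1L, (model$n_per_class[b] - model$k[b] - 1L) * (p - model$k[b]))
    stats::qf(1 - alpha, df1, df2)
  }, numeric(1))
  no_match <- vmat[cbind(seq_len(nrow(x)), best)] / s0[best] > crit[best]
  out <- tibble::tibble(pred = model$classes[best], no_match = no_match)
  dist_df <- tibble::as_tibble(as.data.frame(dist))
  names(dist_df) <- paste0(".dist_", model$classes)
  dplyr::bind_cols(out, dist_df)
}

resolve_grid <- function(model, newdata) {
  if (inherits(newdata, "spectra_tbl") ||
      (is.data.frame(newdata) && length(spc_wl_cols(newdata)) > 0)) {
    wl <- spc_wavelengths(newdata)
    if (length(wl) != length(model$wavelengths) ||
        max(abs(wl - model$wavelengths)) > 1e-6) {
      abort_aqua("wavelength grid does not match the training grid.", "incompatible_grid")
    }
    return(spc_matrix(newdata))
  }
  x <- if (is.null(dim(newdata))) matrix(newdata, nrow = 1) else as.matrix(newdata)
  if (ncol(x) != length(model$wavelengths)) {
    abort_aqua("spectrum length does not match the training grid.", "incompatible_grid")
  }
  x
}

#' Classification accuracy of a SIMCA model on labelled spectra
#'
#' @param model A `simca_model`.
#' @param ds A labelled [spectra_tbl] (must carry the model's class key).
#' @return Percent of spectra whose arg-min class equals the label.
#' @export
simca_accuracy <- function(model, ds) {
  truth <- as.character(spc_meta(ds)[[model$class_key]])
  pred <- classify(model, ds)$pred
  mean(pred == truth) * 100
}

#' @export
print.simca_model <- function(x, ...) {
  cat(sprintf("SIMCA model: %d classes by `%s`, %d channels\n",
              length(x$classes), x$class_key, length(x$wavelengths)))
  cat(sprintf("components per class: %s\n", paste(x$k, collapse = ", ")))
  d <- x$distance[upper.tri(x$distance)]
  cat(sprintf("interclass distance: min %.2f, median %.2f, max %.2f\n",
              min(d), stats::median(d), max(d)))
  invisible(x)
}

#' @export
tidy.simca_model <- function(x, ...) {
  tibble::tibble(wavelength = x$wavelengths,
                 discriminating_power = x$discriminating_power)
}

#' @export
glance.simca_model <- function(x, ...) {
  d <- x$distance[upper.tri(x$distance)]
  tibble::tibble(
    n_classes = length(x$classes),
    n_spectra = sum(x$n_per_class),
    mean_components = mean(x$k),
    min_interclass_distance = min(d),
    median_interclass_distance = stats::median(d)
  )
}

#' @export
autoplot.simca_model <- function(object, ...) {
  ggplot2::ggplot(tidy(object),
                  ggplot2::aes(x = .data$wavelength, y = .data$discriminating_power)) +
    ggplot2::geom_line() +
    ggplot2::labs(x = "wavelength (nm)", y = "discriminating power",
                  title = sprintf("SIMCA discriminating power (%d classes)",
                                  length(object$classes)))
}

#' Serialise a SIMCA model to JSON
#'
#' Stores means, loadings, residual variances and settings so classification
#' is reproducible without the training data.
#'
#' @param model A `simca_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_simca <- function(model, path) {
  payload <- list(
    classes = model$classes, class_key = model$class_key,
    wavelengths = model$wavelengths,
    mu = model$mu, k = unname(model$k),
    n_per_class = unname(model$n_per_class),
    loadings = lapply(model$loadings, unclass),
    s2_pooled = model$s2_pooled,
    s2_channel = list(dim = dim(model$s2_channel),
                      values = as.vector(model$s2_channel)),
    settings = model$settings
  )
  jsonlite::write_json(payload, path, digits = NA, auto_unbox = TRUE)
  invisible(path)
}

#' @rdname write_simca
#' @export
read_simca <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  classes <- as.character(p$classes)
  g <- length(classes)
  model <- structure(
    list(
      classes = classes, class_key = p$class_key,
      wavelengths = as.numeric(p$wavelengths),
      mu = structure(as.matrix(p$mu), dimnames = list(classes, NULL)),
      loadings = stats::setNames(lapply(p$loadings, function(l) as.matrix(l)), classes),
      k = stats::setNames(as.integer(p$k), classes),
      n_per_class = stats::setNames(as.integer(p$n_per_class), classes),
      s2_pooled = structure(as.matrix(p$s2_pooled),
                            dimnames = list(classes, classes)),
      s2_channel = array(p$s2_channel$values, dim = p$s2_channel$dim,
                         dimnames = list(classes, classes, NULL)),
      settings = p$settings
    ),
    class = "simca_model"
  )
  model$distance <- interclass_distances(model)
  model$discriminating_power <- discriminating_power(model)
  model
}
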