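#' Weight tables
#'
#' Daily fruit weights are kept in a plain tibble with columns `fruit_id`,
#' `condition`, `day` and `weight_g` — one record per (fruit, condition, day),
#' strictly positive weights. `read_weights()` loads and validates the CSV
#' dialect; `validate_weights()` checks an in-memory table.
#'
#' @param path CSV path with columns `fruit_id`, `condition`, `day`,
#'   `weight_g`.
#' @return A validated tibble.
#' @export
read_weights <- function(path) {
  if (!file.exists(path)) abort_aqua(sprintf("file not found: %s", path), "io")
  validate_weights(readr::read_csv(path, show_col_types = FALSE, progress = FALSE))
}

#' @rdname read_weights
#' @param weights Data frame of weight records.
#' @export
validate_weights <- function(weights) {
  weights <- tibble::as_tibble(weights)
  need <- c("fruit_id", "condition", "day", "weight_g")
  absent <- setdiff(need, names(weights))
  if (length(absent) > 0L) {
    abort_aqua(sprintf("missing weight column(s): %s", paste(absent, collapse = ", ")),
               "schema")
  }
  if (anyNA(weights[need])) abort_aqua("weight table contains missing values.", "parse")
  if (any(weights$weight_g <= 0)) abort_aqua("weights must be strictly positive.", "schema")
  if (any(weights$day < 0 | weights$day != round(weights$day))) {
    abort_aqua("`day` must be a non-negative integer.", "schema")
  }
  if (anyDuplicated(weights[c("fruit_id", "condition", "day")])) {
    abort_aqua("duplicate (fruit_id, condition, day) weight record.", "duplicate_record")
  }
  weights
}

weight_at <- function(weights, fruit_id, condition, day) {
  hit <- weights$fruit_id == fruit_id & weights$condition == condition &
    weights$day == day
  if (!any(hit)) return(NA_real_)
  weights$weight_g[which(hit)[1]]
}

#' Weight loss rate relative to the fresh weight
#'
#' Percent weight lost since the pre-storage measurement:
#' `(W_f - W_s) / W_f * 100`, where `W_f` is the day-0 (fresh) weight and
#' `W_s` the weight on the requested day. A negative value (weight gain) is
#' returned with a warning.
#'
#' @param weights A validated weight table (see [read_weights()]).
#' @param fruit_id,condition,day Identify the record; a day-0 baseline must
#'   exist for the fruit.
#' @return Percent weight loss (scalar).
#' @export
#' @examples
#' wt <- tibble::tibble(fruit_id = 1, condition = "CF", day = c(0, 7),
#'                      weight_g = c(20, 18.54))
#' weight_loss_rate(wt, 1, "CF", 7) # 7.3
weight_loss_rate <- function(weights, fruit_id, condition, day) {
  w_f <- weight_at(weights, fruit_id, condition, 0)
  if (is.na(w_f)) {
    abort_aqua(sprintf("no day-0 baseline weight for fruit %s (%s).", fruit_id, condition),
               "missing_baseline")
  }
  w_s <- weight_at(weights, fruit_id, condition, day)
  if (is.na(w_s)) {
    abort_aqua(sprintf("no weight record for fruit %s (%s) on day %s.",
                       fruit_id, condition, day), "missing_group")
  }
  rate <- (w_f - w_s) / w_f * 100
  if (rate < 0) {
    rlang::warn(sprintf("fruit %s (%s) gained weight by day %s.", fruit_id, condition, day),
                class = "aquastore_warning_weight_gain")
  }
  rate
}

#' Per-fruit weight loss rates on one day
#'
#' Vectorised companion to [weight_loss_rate()]: one row per fruit that has
#' both a day-0 and a target-day record.
#'
#' @inheritParams weight_loss_rate
#' @return Tibble with columns `condition`, `fruit_id`, `loss_pct`.
#' @export
weight_loss_rates <- function(weights, day) {
  base <- dplyr::filter(weights, .data$day == 0) |>
    dplyr::select("fruit_id", "condition", w_f = "weight_g")
  cur <- dplyr::filter(weights, .data$day == .env$day) |>
    dplyr::select("fruit_id", "condition", w_s = "weight_g")
  dplyr::inner_join(base, cur, by = c("fruit_id", "condition")) |>
    dplyr::mutate(loss_pct = (.data$w_f - .data$w_s) / .data$w_f * 100) |>
    dplyr::select("condition", "fruit_id", "loss_pct") |>
    dplyr::arrange(.data$condition, .data$fruit_id)
}

#' Daily weight change
#'
#' Weight on a storage day minus the weight on the previous day, in grams
#' (negative while the fruit loses weight). Undefined for day 0.
#'
#' @inheritParams weight_loss_rate
#' @return Grams changed since the previous day (scalar).
#' @export
daily_weight_change <- function(weights, fruit_id, condition, day) {
  if (day == 0) {
    abort_aqua("daily change undefined for the pre-storage baseline (day 0).", "baseline")
  }
  w_prev <- weight_at(weights, fruit_id, condition, day - 1)
  if (is.na(w_prev)) {
    abort_aqua(sprintf("no record for fruit %s (%s) on day %s (gap).",
                       fruit_id, condition, day - 1), "gap")
  }
  w <- weight_at(weights, fruit_id, condition, day)
  if (is.na(w)) {
    abort_aqua(sprintf("no record for fruit %s (%s) on day %s.", fruit_id, condition, day),
               "missing_group")
  }
  w - w_prev
}

#' All daily weight changes of a table
#'
#' @param weights A validated weight table.
#' @return Tibble `condition`, `fruit_id`, `day`, `change_g` for every day
#'   with a preceding record.
#' @export
daily_weight_changes <- function(weights) {
  tibble::as_tibble(weights) |>
    dplyr::arrange(.data$condition, .data$fruit_id, .data$day) |>
    dplyr::group_by(.data$condition, .data$fruit_id) |>
    dplyr::mutate(change_g = .data$weight_g - dplyr::lag(.data$weight_g),
                  gap = .data$day - dplyr::lag(.data$day)) |>
    dplyr::ungroup() |>
    dplyr::filter(!is.na(.data$change_g), .data$gap == 1) |>
    dplyr::select("condition", "fruit_id", "day", "change_g")
}

#' Two-group t test assuming equal variances
#'
#' Pooled-variance two-sample t statistic
#' `t = (mean_a - mean_b) / sqrt(s_p^2 (1/n_a + 1/n_b))` with
#' `df = n_a + n_b - 2` and a two-sided p-value, used to compare day-7 weight
#' loss between the two cooling conditions. A paired variant is available for
#' day-wise pairing.
#'
#' @param a,b Numeric sample vectors, each of length at least 2 (equal
#'   lengths when `paired = TRUE`).
#' @param paired Use the paired one-sample-on-differences form.
#' @return A one-row tibble: `statistic`, `df`, `p_value`, `mean_a`, `mean_b`.
#' @export
equal_variance_ttest <- function(a, b, paired = FALSE) {
  if (length(a) < 2L || length(b) < 2L) {
    abort_aqua("both samples need at least two observations.", "insufficient_data")
  }
  if (paired && length(a) != length(b)) {
    abort_aqua("paired samples must have equal length.", "parameter")
  }
  ht <- stats::t.test(a, b, var.equal = TRUE, paired = paired)
  tibble::tibble(
    statistic = unname(ht$statistic),
    df = unname(ht$parameter),
    p_value = ht$p.value,
    mean_a = mean(a),
    mean_b = mean(b)
  )
}
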