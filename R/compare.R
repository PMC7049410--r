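#' Decolorization percentage from absorbance readings
#'
#' `100 * (Ab_initial - Ab_final) / Ab_initial`, the fractional loss of
#' absorbance at the dye's absorption maximum (587 nm for Direct Blue 71).
#'
#' @param ab_initial Initial absorbance (> 0).
#' @param ab_final Final absorbance (>= 0).
#' @return Decolorization in percent; vectorized.
#' @examples
#' decolorization_percent(0.5, 0.1)   # 80
#' @export
decolorization_percent <- function(ab_initial, ab_final) {
  stopifnot(is.numeric(ab_initial), is.numeric(ab_final))
  if (any(ab_initial <= 0))
    stop("'ab_initial' must be positive", call. = FALSE)
  if (any(ab_final < 0))
    stop("'ab_final' must be nonnegative", call. = FALSE)
  100 * (ab_initial - ab_final) / ab_initial
}

#' Absolute average deviation of predictions
#'
#' `AAD = (1/p) * sum_i |observed_i - predicted_i| / |observed_i|`,
#' reported both as a fraction and multiplied by 100 as a percent, since
#' published tables use either convention.
#'
#' @param observed,predicted Aligned numeric vectors; observed entries must
#'   be nonzero.
#' @return A list with `fraction` and `percent`.
#' @examples
#' aad(c(100, 50), c(90, 50))   # fraction 0.05
#' @export
aad <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 1L)
  zero <- which(observed == 0)
  if (length(zero))
    stop("AAD undefined: observed value is zero in run(s) ",
         paste(zero, collapse = ", "), call. = FALSE)
  fraction <- mean(abs(observed - predicted) / abs(observed))
  list(fraction = fraction, percent = 100 * fraction)
}

#' Coefficient of determination of predictions
#'
#' `R^2 = 1 - SSE / centered SS of observed`, with the adjusted version
#' `1 - (1 - R^2)(n - 1)/(n - k - 1)` for `k` predictors. Negative values
#' (predictions worse than the mean) are reported as computed, with a
#' warning.
#'
#' @param observed,predicted Aligned numeric vectors of length >= 3.
#' @param k Number of model predictors for the adjustment (default 9, the
#'   non-intercept terms of the full quadratic).
#' @return A list with `r_squared` and `adj_r_squared`.
#' @export
goodness_r2 <- function(observed, predicted, k = 9L) {
  n <- length(observed)
  stopifnot(n == length(predicted), n >= 3L)
  sst <- sum((observed - mean(observed))^2)
  if (sst == 0)
    stop("observed values have zero variance; R^2 undefined", call. = FALSE)
  r2 <- 1 - sum((observed - predicted)^2) / sst
  if (r2 < 0)
    warning("negative R^2: predictions are worse than the observed mean",
            call. = FALSE)
  list(r_squared = r2,
       adj_r_squared = 1 - (1 - r2) * (n - 1) / (n - k - 1))
}

#' Compare two predictors on the same runs
#'
#' Assembles the residual-analysis statistics used to arbitrate between a
#' response-surface model and a neural network: R-squared, adjusted
#' R-squared and absolute average deviation per model, a per-run deviation
#' table, and a per-metric winner (higher R-squared, lower AAD).
#'
#' @param observed Observed responses.
#' @param rsm_predicted,ann_predicted Aligned prediction vectors.
#' @param k Predictor count for the R-squared adjustment.
#' @return A `comparison_report` list: `metrics` (one row per model),
#'   `per_run`, `winner` (named character vector by metric, `"tie"` when
#'   equal), `n`.
#' @export
compare_models <- function(observed, rsm_predicted, ann_predicted, k = 9L) {
  stopifnot(length(observed) == length(rsm_predicted),
            length(observed) == length(ann_predicted))
  one <- function(pred) {
    g <- goodness_r2(observed, pred, k = k)
    a <- aad(observed, pred)
    c(r_squared = g$r_squared, adj_r_squared = g$adj_r_squared,
      aad_fraction = a$fraction, aad_percent = a$percent)
  }
  m <- rbind(RSM = one(rsm_predicted), ANN = one(ann_predicted))
  metrics <- data.frame(model = rownames(m), m, row.names = NULL)
  pick <- function(vals, larger) {
    if (isTRUE(all.equal(vals[1], vals[2]))) "tie"
    else metrics$model[if (larger) which.max(vals) else which.min(vals)]
  }
  winner <- c(r_squared = pick(metrics$r_squared, TRUE),
              aad = pick(metrics$aad_fraction, FALSE))
  per_run <- data.frame(
    run = seq_along(observed), observed = observed,
    rsm_predicted = rsm_predicted, ann_predicted = ann_predicted,
    rsm_abs_rel_dev = abs(observed - rsm_predicted) / abs(observed),
    ann_abs_rel_dev = abs(observed - ann_predicted) / abs(observed))
  structure(list(metrics = metrics, per_run = per_run, winner = winner,
                 n = length(observed)),
            class = "comparison_report")
}

#' @export
print.comparison_report <- function(x, ...) {
  cat("Model comparison over", x$n, "runs\n")
  m <- x$metrics
  m[, -1] <- round(m[, -1], 4)
  print(m, row.names = FALSE)
  cat("winner by R2:", x$winner["r_squared"],
      "; by AAD:", x$winner["aad"], "\n")
  invisible(x)
}
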