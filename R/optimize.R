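#' Per-factor goal policy for desirability optimization
#'
#' Each factor gets a goal: `"maximize"` (pin at its upper limit),
#' `"minimize"` (pin at the lower limit), `"in_range"` (free to move within
#' limits), or a number (fixed at that natural-unit value). The response
#' goal is always maximize. The default policy is the dye study's: dye
#' concentration and yeast extract at their trial maxima, pH free.
#'
#' @param ... One goal per factor, in factor order.
#' @return A list of class `factor_goals`.
#' @examples
#' factor_goals("maximize", "maximize", "in_range")
#' @export
factor_goals <- function(...) {
  goals <- list(...)
  if (length(goals) == 1L && is.list(goals[[1]]) &&
      !inherits(goals[[1]], "factor_goals")) goals <- goals[[1]]
  ok <- vapply(goals, function(g)
    (is.character(g) && g %in% c("maximize", "minimize", "in_range")) ||
    (is.numeric(g) && length(g) == 1L && is.finite(g)), logical(1))
  if (!all(ok))
    stop("each goal must be 'maximize', 'minimize', 'in_range' or a number",
         call. = FALSE)
  structure(goals, class = "factor_goals")
}

# quadratic y = b0 + b'x + x'Qx in coded units, from the 10 coefficients
quad_matrices <- function(coefficients) {
  b0 <- coefficients[1L]
  b <- coefficients[2:4]
  Q <- diag(coefficients[8:10])
  Q[1, 2] <- Q[2, 1] <- coefficients[5L] / 2
  Q[1, 3] <- Q[3, 1] <- coefficients[6L] / 2
  Q[2, 3] <- Q[3, 2] <- coefficients[7L] / 2
  list(b0 = b0, b = b, Q = Q)
}

predict_any <- function(predictor, coded) {
  if (inherits(predictor, "quadratic_model"))
    predict(predictor, coded, units = "coded")
  else if (inherits(predictor, "mlp_model"))
    predict(predictor, coded, units = "coded")
  else stop("predictor must be a quadratic_model or mlp_model",
            call. = FALSE)
}

#' Locate the desirability optimum of a fitted response surface
#'
#' Applies a per-factor goal policy: goal-maximized/minimized factors are
#' pinned at their limits, fixed factors at the given value, and the
#' remaining free factors are chosen to maximize the predicted response
#' within the design box. For a quadratic model the restricted optimum is
#' found in closed form (stationary point of the restricted quadratic,
#' clipped to the box, compared against a dense grid / multi-start polish
#' as a safeguard); for a network predictor a seeded dense grid
#' (coded step 0.001 in one free dimension) with multi-start polish is
#' used. The single-response desirability is
#' `d = (y_hat - L) / (T - L)` clipped to `[0, 1]`, anchored at the
#' observed response range `L`..`T` of the input data; being a monotone
#' transform it does not move the argmax.
#'
#' @param predictor A `quadratic_model` or `mlp_model`.
#' @param goals A [factor_goals()]; default pins the first two factors at
#'   their maxima and frees the third.
#' @param observed Observed responses anchoring the desirability scale;
#'   defaults to the responses stored in a quadratic model.
#' @param n_starts Multi-start count for free dimensions >= 2 (seeded).
#' @param grid_step Coded-unit grid resolution for one free dimension.
#' @param seed Seed for the multi-start draw.
#' @return An `optimum_result`: `natural` and `coded` settings,
#'   `predicted` response (%), `desirability` in `[0, 1]` and a `method`
#'   note.
#' @examples
#' fit <- fit_quadratic(db71_runs())
#' optimize_surface(fit)   # 150 ppm, 3 g/L, pH ~6.645, ~92.2 %
#' @export
optimize_surface <- function(predictor,
                             goals = factor_goals("maximize", "maximize",
                                                  "in_range"),
                             observed = NULL, n_starts = 25L,
                             grid_step = 0.001, seed = 1L) {
  stopifnot(inherits(goals, "factor_goals"))
  factors <- predictor$factors
  k <- length(factors)
  if (length(goals) != k)
    stop("got ", length(goals), " goals for ", k, " factors", call. = FALSE)
  pinned <- rep(NA_real_, k)
  for (i in seq_len(k)) {
    g <- goals[[i]]
    if (identical(g, "maximize")) pinned[i] <- 1
    else if (identical(g, "minimize")) pinned[i] <- -1
    else if (is.numeric(g)) {
      ci <- (g - factor_mid(factors)[i]) / factor_half(factors)[i]
      if (abs(ci) > 1 + 1e-9)
        stop("fixed value ", g, " outside limits of factor '",
             factors[[i]]$name, "'", call. = FALSE)
      pinned[i] <- ci
    }
  }
  free <- which(is.na(pinned))
  objective <- function(cfree) {
    x <- pinned; x[free] <- cfree
    predict_any(predictor, matrix(x, nrow = 1L))
  }
  method <- "pinned point"
  if (length(free) == 0L) {
    best_free <- numeric(0)
  } else {
    cand <- list()
    if (inherits(predictor, "quadratic_model")) {
      qm <- quad_matrices(predictor$coefficients)
      gfree <- qm$b[free] + 2 * qm$Q[free, -free, drop = FALSE] %*%
        (if (length(free) < k) pinned[-free] else numeric(0))
      Hff <- 2 * qm$Q[free, free, drop = FALSE]
      if (abs(det(Hff)) > 1e-12) {
        stat <- drop(solve(Hff, -gfree))
        cand <- c(cand, list(pmin(1, pmax(-1, stat))))
      }
      method <- "closed-form stationary point + grid check"
    } else {
      method <- "seeded grid + multi-start polish"
    }
    if (length(free) == 1L) {
      grid <- seq(-1, 1, by = grid_step)
      vals <- vapply(grid, objective, numeric(1))
      cand <- c(cand, list(grid[which.max(vals)]))
    } else {
      set.seed(seed)
      starts <- matrix(stats::runif(n_starts * length(free), -1, 1),
                       n_starts, length(free))
      starts <- rbind(starts, rep(0, length(free)))
      for (s in seq_len(nrow(starts))) {
        op <- stats::optim(starts[s, ], function(z) -objective(z),
                           method = "L-BFGS-B", lower = -1, upper = 1)
        cand <- c(cand, list(op$par))
      }
    }
    vals <- vapply(cand, objective, numeric(1))
    best_free <- cand[[which.max(vals)]]
  }
  coded <- pinned; coded[free] <- best_free
  predicted <- objective(best_free)
  if (!is.finite(predicted))
    stop("predictor undefined at the candidate optimum", call. = FALSE)
  if (is.null(observed) && !is.null(predictor$y)) observed <- predictor$y
  desirability <- if (is.null(observed)) NA_real_ else {
    lo <- min(observed); hi <- max(observed)
    min(1, max(0, (predicted - lo) / (hi - lo)))
  }
  natural <- decode_factors(factors, coded)
  structure(list(natural = stats::setNames(natural, factor_names(factors)),
                 coded = coded, predicted = predicted,
                 desirability = desirability, method = method),
            class = "optimum_result")
}

#' @export
print.optimum_result <- function(x, ...) {
  cat("Optimum (", x$method, ")\n", sep = "")
  for (i in seq_along(x$natural))
    cat(sprintf("  %s = %.4g (coded %+.4f)\n", names(x$natural)[i],
                x$natural[i], x$coded[i]))
  cat(sprintf("  predicted response %.2f %%  desirability %.3f\n",
              x$predicted, x$desirability))
  invisible(x)
}

#' Relative deviation of a validated optimum
#'
#' `100 * (predicted - experimental) / predicted`, the signed percent
#' deviation between a model's predicted optimum response and the
#' experimentally validated mean.
#'
#' @param predicted Predicted response (%); must be positive.
#' @param experimental Experimentally measured mean response (%).
#' @return Deviation in percent.
#' @examples
#' validation_deviation(92.2, 86.13)   # 6.58
#' @export
validation_deviation <- function(predicted, experimental) {
  stopifnot(is.numeric(predicted), is.numeric(experimental))
  if (any(predicted <= 0))
    stop("'predicted' must be positive", call. = FALSE)
  100 * (predicted - experimental) / predicted
}

#' Export a response-surface grid over two factors
#'
#' Evaluates a predictor on a rectangular grid spanning two factors'
#' limits while holding the remaining factor fixed -- the data behind a
#' 3-D surface or contour plot, in long format for external plotting.
#'
#' @param predictor A `quadratic_model` or `mlp_model`.
#' @param vary Indices (or names) of the two varying factors.
#' @param fixed Natural-unit value(s) of the remaining factor(s).
#' @param resolution Grid points per axis (>= 2).
#' @return A long data frame: one natural-unit column per factor plus
#'   `predicted`.
#' @export
surface_grid <- function(predictor, vary, fixed, resolution = 25L) {
  factors <- predictor$factors
  k <- length(factors)
  if (is.character(vary)) vary <- match(vary, factor_names(factors))
  vary <- as.integer(vary)
  stopifnot(length(vary) == 2L, !anyNA(vary), resolution >= 2L)
  rest <- setdiff(seq_len(k), vary)
  stopifnot(length(fixed) == length(rest))
  ax <- lapply(vary, function(i)
    seq(factors[[i]]$low, factors[[i]]$high, length.out = resolution))
  grid <- expand.grid(ax[[1]], ax[[2]])
  natural <- matrix(NA_real_, nrow(grid), k)
  natural[, vary[1L]] <- grid[, 1L]
  natural[, vary[2L]] <- grid[, 2L]
  natural[, rest] <- matrix(rep(as.numeric(fixed), each = nrow(grid)),
                            nrow(grid))
  colnames(natural) <- factor_names(factors)
  out <- as.data.frame(natural)
  out$predicted <- if (inherits(predictor, "quadratic_model"))
    predict(predictor, natural, units = "natural")
  else predict(predictor, natural, units = "natural")
  out
}
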