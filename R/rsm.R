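quad_terms <- function() c("intercept", "A", "B", "C", "AB", "AC", "BC",
                           "A2", "B2", "C2")

# 10-column model matrix of the full second-order expansion in coded units
quad_expand <- function(coded) {
  if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1L)
  stopifnot(ncol(coded) == 3L)
  A <- coded[, 1L]; B <- coded[, 2L]; C <- coded[, 3L]
  X <- cbind(1, A, B, C, A * B, A * C, B * C, A^2, B^2, C^2)
  colnames(X) <- quad_terms()
  X
}

#' Fit the ten-term coded quadratic response surface
#'
#' Ordinary least-squares fit of the full second-order model
#' `y = b0 + b1 A + b2 B + b3 C + b12 AB + b13 AC + b23 BC +
#' b11 A^2 + b22 B^2 + b33 C^2` in coded factor units (design limits at
#' -1/+1). The intercept is then the predicted response at the design
#' center. The fit is delegated to [stats::lm()]; the returned object keeps
#' the coefficient covariance, residuals, leverages and the design needed
#' for the downstream ANOVA, PRESS and diagnostic computations.
#'
#' @param design A `design_table` with responses on at least 10 runs.
#' @return An object of class `quadratic_model` with elements
#'   `coefficients` (named by term: intercept, A, B, C, AB, AC, BC, A2, B2,
#'   C2), `sigma2` (residual mean square), `vcov`, `leverages`, `fitted`,
#'   `residuals`, `df_residual`, plus the design data for refits.
#' @examples
#' fit <- fit_quadratic(db71_runs())
#' coef(fit)["B"]      # yeast-extract linear effect, % per coded unit
#' @export
fit_quadratic <- function(design) {
  stopifnot(inherits(design, "design_table"))
  y <- design$response
  if (anyNA(y)) stop("design has missing responses; attach_response() first",
                     call. = FALSE)
  n <- length(y)
  if (n < 10L) stop("need >= 10 runs to fit the 10-term quadratic; got ", n,
                    call. = FALSE)
  X <- quad_expand(design$coded)
  qrX <- qr(X)
  if (qrX$rank < 10L) {
    bad <- setdiff(colnames(X), colnames(X)[qrX$pivot[seq_len(qrX$rank)]])
    stop("singular design: term(s) ", paste(bad, collapse = ", "),
         " are collinear with the others", call. = FALSE)
  }
  dat <- as.data.frame(X[, -1L, drop = FALSE])
  dat$..y <- y
  lmfit <- stats::lm(..y ~ ., data = dat)
  co <- stats::setNames(unname(stats::coef(lmfit)), quad_terms())
  h <- stats::hatvalues(lmfit)
  sigma2 <- sum(stats::resid(lmfit)^2) / (n - 10L)
  xtx_inv <- solve(crossprod(X))
  dimnames(xtx_inv) <- list(quad_terms(), quad_terms())
  structure(list(coefficients = co,
                 sigma2 = sigma2,
                 vcov = sigma2 * xtx_inv,
                 leverages = unname(h),
                 fitted = unname(stats::fitted(lmfit)),
                 residuals = unname(stats::resid(lmfit)),
                 df_residual = n - 10L,
                 X = X, y = y,
                 coded = design$coded,
                 center = design$center,
                 factors = design$factors),
            class = "quadratic_model")
}

#' @export
coef.quadratic_model <- function(object, ...) object$coefficients

#' @export
print.quadratic_model <- function(x, ...) {
  cat("Coded quadratic response-surface model (10 terms)\n")
  print(round(x$coefficients, 4))
  cat(sprintf("Residual MS %.4f on %d df\n", x$sigma2, x$df_residual))
  invisible(x)
}

#' Predict from a quadratic response-surface model
#'
#' @param object A `quadratic_model`.
#' @param settings A length-3 vector or 3-column matrix of factor settings.
#' @param units `"coded"` or `"natural"`; natural inputs are coded through
#'   the model's factor limits first.
#' @param ... Unused.
#' @return Predicted response (% decolorization), one value per row.
#'   Extrapolation beyond the coded cube is permitted but reported via a
#'   message.
#' @export
predict.quadratic_model <- function(object, settings,
                                    units = c("coded", "natural"), ...) {
  units <- match.arg(units)
  coded <- if (units == "natural") code_factors(object$factors, settings)
           else settings
  if (is.null(dim(coded))) coded <- matrix(coded, ncol = 3L)
  if (any(abs(coded) > 1 + 1e-9))
    message("predicting outside the coded design cube (|coded| > 1)")
  drop(quad_expand(coded) %*% object$coefficients)
}

# pure-error / lack-of-fit split: group runs with identical coded settings
pure_error_split <- function(model) {
  key <- apply(round(model$coded, 10L), 1L, paste, collapse = "|")
  groups <- split(model$y, key)
  ss_pe <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1)))
  df_pe <- length(model$y) - length(groups)
  list(ss = ss_pe, df = df_pe)
}

#' ANOVA for a fitted quadratic response surface
#'
#' Produces the Design-Expert style analysis-of-variance table for the
#' ten-term coded quadratic: overall model test, one row per model term
#' with its partial (type-III) sum of squares -- the increase in residual
#' SS when that single term is deleted from the full model -- the
#' residual, its lack-of-fit / pure-error decomposition over replicated
#' settings, and the corrected total. The summary statistics R-squared,
#' adjusted and predicted R-squared, PRESS and adequate precision are
#' attached. For a three-factor Box-Behnken design the linear and
#' interaction columns are mutually orthogonal, so their partial SS equal
#' the sequential ones.
#'
#' @param model A `quadratic_model` from [fit_quadratic()].
#' @return An `anova_report`: a list with a `table` data frame (`source`,
#'   `ss`, `df`, `ms`, `f`, `p`) and scalar fields `r_squared`,
#'   `adj_r_squared`, `pred_r_squared`, `press`, `adequate_precision`.
#' @examples
#' rsm_anova(fit_quadratic(db71_runs()))
#' @export
rsm_anova <- function(model) {
  stopifnot(inherits(model, "quadratic_model"))
  y <- model$y; n <- length(y)
  ss_res <- sum(model$residuals^2)
  ss_tot <- sum((y - mean(y))^2)
  ss_mod <- ss_tot - ss_res
  df_mod <- 9L; df_res <- model$df_residual
  ms_res <- model$sigma2
  # partial SS: deletion refits of the full model matrix
  ss_term <- vapply(2:10, function(j) {
    fitj <- stats::lm.fit(model$X[, -j, drop = FALSE], y)
    sum(fitj$residuals^2) - ss_res
  }, numeric(1))
  rows <- data.frame(
    source = c("Model", quad_terms()[-1L]),
    ss = c(ss_mod, ss_term),
    df = c(df_mod, rep(1L, 9L)),
    stringsAsFactors = FALSE)
  rows$ms <- rows$ss / rows$df
  rows$f <- rows$ms / ms_res
  rows$p <- stats::pf(rows$f, rows$df, df_res, lower.tail = FALSE)
  resid_row <- data.frame(source = "Residual", ss = ss_res, df = df_res,
                          ms = ms_res, f = NA_real_, p = NA_real_)
  pe <- pure_error_split(model)
  if (pe$df > 0L) {
    ss_lof <- ss_res - pe$ss
    df_lof <- df_res - pe$df
    f_lof <- if (df_lof > 0L) (ss_lof / df_lof) / (pe$ss / pe$df) else NA_real_
    lof_rows <- data.frame(
      source = c("Lack of fit", "Pure error"),
      ss = c(ss_lof, pe$ss), df = c(df_lof, pe$df),
      ms = c(if (df_lof > 0L) ss_lof / df_lof else NA_real_, pe$ss / pe$df),
      f = c(f_lof, NA_real_),
      p = c(if (is.na(f_lof)) NA_real_
            else stats::pf(f_lof, df_lof, pe$df, lower.tail = FALSE),
            NA_real_))
  } else lof_rows <- NULL  # no replicated settings: split not fabricated
  tot_row <- data.frame(source = "Cor total", ss = ss_tot, df = n - 1L,
                        ms = NA_real_, f = NA_real_, p = NA_real_)
  tab <- rbind(rows, resid_row, lof_rows, tot_row)
  rownames(tab) <- NULL
  press <- tryCatch(press_stat(model), error = function(e) {
    warning(conditionMessage(e), call. = FALSE)
    NA_real_
  })
  structure(list(table = tab,
                 r_squared = 1 - ss_res / ss_tot,
                 adj_r_squared = 1 - (ss_res / df_res) / (ss_tot / (n - 1L)),
                 press = press,
                 pred_r_squared = 1 - press / ss_tot,
                 adequate_precision = adequate_precision(model)),
            class = "anova_report")
}

#' @export
print.anova_report <- function(x, ...) {
  tab <- x$table
  tab$ss <- round(tab$ss, 2); tab$ms <- round(tab$ms, 2)
  tab$f <- round(tab$f, 2)
  tab$p <- ifelse(is.na(tab$p), NA,
                  ifelse(tab$p < 1e-4, "<0.0001", sprintf("%.4f", tab$p)))
  print(tab, row.names = FALSE)
  cat(sprintf("R2 %.4f  adj R2 %.4f  pred R2 %.4f  PRESS %.2f  adeq. precision %.3f\n",
              x$r_squared, x$adj_r_squared, x$pred_r_squared, x$press,
              x$adequate_precision))
  invisible(x)
}

#' Prediction error sum of squares (PRESS)
#'
#' Sum over runs of the squared leave-one-out deletion residual,
#' `(e_i / (1 - h_ii))^2`, computed from the ordinary residuals and the
#' hat-matrix diagonal; equal to the brute-force leave-one-out refit
#' statistic for any least-squares fit.
#'
#' @param model A `quadratic_model`.
#' @return PRESS, in squared % decolorization.
#' @export
press_stat <- function(model) {
  stopifnot(inherits(model, "quadratic_model"))
  h <- model$leverages
  if (any(h >= 1 - 1e-10))
    stop("PRESS undefined: run(s) ", paste(which(h >= 1 - 1e-10),
         collapse = ", "), " have leverage 1 (exact interpolation)",
         call. = FALSE)
  sum((model$residuals / (1 - h))^2)
}

#' Adequate precision (signal-to-noise) of a fitted surface
#'
#' The range of fitted values across the design runs divided by the average
#' prediction standard deviation, `sqrt(p * sigma2 / n)` with `p = 10`
#' model terms; values above 4 conventionally indicate an adequate signal.
#'
#' @param model A `quadratic_model`.
#' @return The adequate-precision ratio; `Inf` with a warning when the
#'   residual variance is zero.
#' @export
adequate_precision <- function(model) {
  stopifnot(inherits(model, "quadratic_model"))
  signal <- max(model$fitted) - min(model$fitted)
  if (model$sigma2 <= 0) {
    warning("zero residual variance: adequate precision is infinite",
            call. = FALSE)
    return(Inf)
  }
  signal / sqrt(10 * model$sigma2 / length(model$y))
}

#' Studentized residual diagnostics
#'
#' Internally studentized residuals `e_i / (sigma_hat * sqrt(1 - h_ii))`
#' with normal-probability plotting positions (expected normal order
#' statistics from the `(i - 0.375) / (n + 0.25)` quantile rule), the raw
#' material of the usual residual diagnostic panels.
#'
#' @param model A `quadratic_model`.
#' @return A data frame with columns `run`, `fitted`, `residual`,
#'   `leverage`, `studentized`, `normal_quantile`.
#' @export
studentized_residuals <- function(model) {
  stopifnot(inherits(model, "quadratic_model"))
  n <- length(model$y)
  h <- model$leverages
  s <- sqrt(model$sigma2)
  # guard against an exact (noise-free) fit, where residuals and sigma are
  # both numerical zero and the ratio is meaningless
  exact <- model$sigma2 <= 1e-14 * stats::var(model$y)
  stud <- if (exact) rep(0, n) else model$residuals / (s * sqrt(1 - h))
  pos <- stats::qnorm((rank(stud, ties.method = "first") - 0.375) /
                      (n + 0.25))
  data.frame(run = seq_len(n), fitted = model$fitted,
             residual = model$residuals, leverage = h,
             studentized = stud, normal_quantile = pos)
}
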