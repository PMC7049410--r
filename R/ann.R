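transfer_fun <- function(name) {
  switch(name,
    tanh = list(f = function(z) tanh(z), df = function(z, a) 1 - a^2),
    sigmoid = list(f = function(z) 1 / (1 + exp(-z)),
                   df = function(z, a) a * (1 - a)),
    linear = list(f = function(z) z, df = function(z, a) rep(1, length(a))),
    stop("unknown transfer function '", name, "'", call. = FALSE))
}

# output-scaling anchors keeping targets inside each transfer's range
output_anchor <- function(transfer) {
  switch(transfer, sigmoid = c(0.05, 0.95), tanh = c(-0.9, 0.9),
         linear = c(0, 1),
         stop("unknown transfer function '", transfer, "'", call. = FALSE))
}

scale_response <- function(y, anchor)
  anchor[1L] + (anchor[2L] - anchor[1L]) * y / 100
unscale_response <- function(s, anchor)
  100 * (s - anchor[1L]) / (anchor[2L] - anchor[1L])

#' Training configuration for batch backpropagation
#'
#' Defaults are conventional full-batch backpropagation settings: learning
#' rate 0.1, momentum 0.9, weights initialized uniformly in +/-0.3, up to
#' 100,000 epochs, stopping when the scaled-output training RMSE falls to
#' 1e-3, best of 10 seeded restarts.
#'
#' @param learning_rate Gradient-descent step size (> 0).
#' @param momentum Momentum coefficient in `[0, 1)`.
#' @param max_epochs Epoch budget per restart.
#' @param rmse_tol Early-stopping threshold on training RMSE in scaled
#'   output units (>= 0).
#' @param restarts Number of random restarts (>= 1); the restart with the
#'   lowest final training RMSE wins.
#' @param init_range Half-width of the uniform weight initialization.
#' @param seed Integer; restart `r` draws its weights from seed `seed + r - 1`,
#'   so a fixed config is bit-reproducible.
#' @return A list of class `mlp_control`.
#' @export
mlp_control <- function(learning_rate = 0.1, momentum = 0.9,
                        max_epochs = 100000L, rmse_tol = 1e-3,
                        restarts = 10L, init_range = 0.3,
                        seed = 20200218L) {
  stopifnot(learning_rate > 0, momentum >= 0, momentum < 1,
            max_epochs >= 0, rmse_tol >= 0, restarts >= 1, init_range >= 0)
  structure(list(learning_rate = learning_rate, momentum = momentum,
                 max_epochs = as.integer(max_epochs), rmse_tol = rmse_tol,
                 restarts = as.integer(restarts), init_range = init_range,
                 seed = as.integer(seed)),
            class = "mlp_control")
}

mlp_forward <- function(net, X, hf, of) {
  Z1 <- sweep(X %*% t(net$W1), 2L, net$b1, "+")
  A1 <- hf$f(Z1)
  z2 <- drop(A1 %*% t(net$W2)) + net$b2
  list(Z1 = Z1, A1 = A1, z2 = z2, out = of$f(z2))
}

# mean-squared-error loss and analytic gradients for one 3-H-1 net
mlp_loss_grad <- function(net, X, target, hf, of) {
  n <- nrow(X)
  fw <- mlp_forward(net, X, hf, of)
  err <- fw$out - target
  d2 <- (2 / n) * err * of$df(fw$z2, fw$out)          # n
  gW2 <- matrix(colSums(d2 * fw$A1), nrow = 1L)        # 1 x H
  gb2 <- sum(d2)
  D1 <- (d2 %o% drop(net$W2)) * hf$df(fw$Z1, fw$A1)    # n x H
  list(loss = mean(err^2),
       rmse = sqrt(mean(err^2)),
       grad = list(W1 = t(D1) %*% X, b1 = colSums(D1), W2 = gW2, b2 = gb2))
}

mlp_init <- function(hidden, n_in, range) {
  list(W1 = matrix(stats::runif(hidden * n_in, -range, range), hidden, n_in),
       b1 = stats::runif(hidden, -range, range),
       W2 = matrix(stats::runif(hidden, -range, range), 1L, hidden),
       b2 = stats::runif(1L, -range, range))
}

mlp_train_core <- function(X, target, hidden, hf, of, control) {
  best <- NULL
  for (r in seq_len(control$restarts)) {
    set.seed(control$seed + r - 1L)
    net <- mlp_init(hidden, ncol(X), control$init_range)
    vel <- lapply(net, function(w) w * 0)
    rmse <- Inf; epoch <- 0L
    while (epoch < control$max_epochs) {
      lg <- mlp_loss_grad(net, X, target, hf, of)
      if (!is.finite(lg$loss))
        stop("training diverged (non-finite loss); reduce learning_rate",
             call. = FALSE)
      rmse <- lg$rmse
      if (rmse <= control$rmse_tol) break
      for (w in names(net)) {
        vel[[w]] <- control$momentum * vel[[w]] -
                    control$learning_rate * lg$grad[[w]]
        net[[w]] <- net[[w]] + vel[[w]]
      }
      epoch <- epoch + 1L
    }
    rmse <- sqrt(mean((mlp_forward(net, X, hf, of)$out - target)^2))
    if (is.null(best) || rmse < best$rmse)
      best <- list(net = net, rmse = rmse, epochs = epoch, restart = r)
    if (best$rmse <= control$rmse_tol) break
  }
  best
}

#' Train a 3-H-1 feedforward network by batch backpropagation
#'
#' Full-batch gradient descent with momentum on the mean squared error of
#' scaled outputs, the classical batch-backpropagation trainer. Inputs are
#' coded to `[-1, 1]` from the factor limits; the response is mapped
#' affinely from `[0, 100]` % into the output transfer's working range
#' (e.g. `[0.05, 0.95]` for a sigmoid output). Training restarts from
#' several seeded initializations and keeps the best fit.
#'
#' @param design A `design_table` with responses (typically the training
#'   subset from [split_runs()]).
#' @param hidden Number of hidden neurons (>= 1); 26 is the topology used
#'   for the dye study.
#' @param hidden_transfer,output_transfer One of `"tanh"`, `"sigmoid"`,
#'   `"linear"`.
#' @param control An [mlp_control()].
#' @return An `mlp_model`: weights (`W1`, `b1`, `W2`, `b2`), transfer
#'   names, factor-based input scaling, output-scaling anchors, the
#'   control used, training metrics ([fit_metrics()]) and provenance
#'   (`epochs`, `restart`).
#' @examples
#' \donttest{
#' d <- split_runs(db71_runs())
#' m <- train_mlp(d$train, hidden = 8,
#'                control = mlp_control(max_epochs = 2000, restarts = 2))
#' }
#' @export
train_mlp <- function(design, hidden = 26L, hidden_transfer = "tanh",
                      output_transfer = "sigmoid",
                      control = mlp_control()) {
  stopifnot(inherits(design, "design_table"), hidden >= 1L)
  y <- design$response
  if (length(y) == 0L || anyNA(y))
    stop("training design must have complete responses", call. = FALSE)
  hf <- transfer_fun(hidden_transfer)
  of <- transfer_fun(output_transfer)
  anchor <- output_anchor(output_transfer)
  X <- design$coded
  target <- scale_response(y, anchor)
  best <- mlp_train_core(X, target, as.integer(hidden), hf, of, control)
  model <- structure(list(hidden = as.integer(hidden),
                          hidden_transfer = hidden_transfer,
                          output_transfer = output_transfer,
                          W1 = best$net$W1, b1 = best$net$b1,
                          W2 = best$net$W2, b2 = best$net$b2,
                          factors = design$factors,
                          output_anchor = anchor,
                          control = control,
                          epochs = best$epochs, restart = best$restart),
                     class = "mlp_model")
  model$train_metrics <- fit_metrics(y, predict(model, design$natural))
  model
}

#' @export
print.mlp_model <- function(x, ...) {
  cat(sprintf("Feedforward network 3-%d-1 (%s hidden, %s output)\n",
              x$hidden, x$hidden_transfer, x$output_transfer))
  if (!is.null(x$train_metrics))
    cat(sprintf("training RMSE %.4f %%, R2 %.4f, DC %.4f (restart %d, %d epochs)\n",
                x$train_metrics$rmse, x$train_metrics$r_squared,
                x$train_metrics$dc, x$restart, x$epochs))
  invisible(x)
}

#' Predict decolorization from a trained network
#'
#' @param object An `mlp_model`.
#' @param settings A length-3 vector or 3-column matrix of factor settings.
#' @param units `"natural"` (default) or `"coded"`.
#' @param ... Unused.
#' @return Predicted response in % decolorization.
#' @export
predict.mlp_model <- function(object, settings,
                              units = c("natural", "coded"), ...) {
  units <- match.arg(units)
  coded <- if (units == "natural") code_factors(object$factors, settings)
           else settings
  if (is.null(dim(coded))) coded <- matrix(coded, ncol = 3L)
  fw <- mlp_forward(object, coded, transfer_fun(object$hidden_transfer),
                    transfer_fun(object$output_transfer))
  unscale_response(fw$out, object$output_anchor)
}

#' Goodness-of-fit metrics for predictions
#'
#' Root mean squared error, Pearson correlation `r` of predicted versus
#' observed, its square, and the determination coefficient
#' `DC = 1 - SSE / centered SS of observed`. DC and `r^2` differ when
#' predictions are biased, which is why both are reported.
#'
#' @param observed,predicted Aligned numeric vectors.
#' @return A list with `rmse`, `r`, `r_squared`, `dc`, `n`.
#' @export
fit_metrics <- function(observed, predicted) {
  stopifnot(length(observed) == length(predicted), length(observed) >= 2L)
  sse <- sum((observed - predicted)^2)
  sst <- sum((observed - mean(observed))^2)
  r <- suppressWarnings(stats::cor(observed, predicted))
  list(rmse = sqrt(mean((observed - predicted)^2)), r = r,
       r_squared = r^2, dc = 1 - sse / sst, n = length(observed))
}

#' Split a run table into training and testing subsets
#'
#' The canonical 17-run dye dataset carries its published split (test runs
#' 3, 6, 9, 13 and 16 -- run 16 being a center replicate); any other table
#' requires an explicit `test_runs` argument.
#'
#' @param design A `design_table`.
#' @param test_runs Optional integer vector of run ids to hold out.
#' @return A list with `design_table` elements `train` and `test`.
#' @examples
#' sp <- split_runs(db71_runs())
#' length(sp$train$run)   # 12
#' @export
split_runs <- function(design, test_runs = NULL) {
  stopifnot(inherits(design, "design_table"))
  if (is.null(test_runs)) {
    if (is.null(design$split))
      stop("design carries no split labels; supply 'test_runs' explicitly",
           call. = FALSE)
    test_idx <- which(design$split == "test")
  } else {
    test_idx <- match(test_runs, design$run)
    if (anyNA(test_idx))
      stop("unknown run id(s) in 'test_runs'", call. = FALSE)
  }
  list(train = design_subset(design, setdiff(seq_along(design$run), test_idx)),
       test = design_subset(design, test_idx))
}

#' Compare candidate network topologies
#'
#' Trains one network per (hidden size, transfer pair) candidate on the
#' training subset and ranks them by held-out determination coefficient,
#' then held-out squared correlation -- the usual topology-selection table.
#'
#' @param train,test `design_table` subsets from [split_runs()].
#' @param hidden Integer vector of candidate hidden-layer sizes.
#' @param transfers Data frame with columns `hidden_transfer` and
#'   `output_transfer`; defaults to the four classical combinations.
#' @param control An [mlp_control()] shared by every candidate.
#' @return A `topology_search` list: `report` (one ranked row per
#'   candidate, with training/testing RMSE, R2 and DC) and `models` (in
#'   report order).
#' @export
topology_search <- function(train, test, hidden = 26L,
                            transfers = data.frame(
                              hidden_transfer = c("tanh", "tanh", "sigmoid",
                                                  "linear"),
                              output_transfer = c("sigmoid", "tanh", "tanh",
                                                  "sigmoid")),
                            control = mlp_control()) {
  stopifnot(length(hidden) >= 1L, nrow(transfers) >= 1L)
  grid <- merge(data.frame(hidden = as.integer(hidden)), transfers)
  fits <- lapply(seq_len(nrow(grid)), function(i) {
    m <- train_mlp(train, hidden = grid$hidden[i],
                   hidden_transfer = grid$hidden_transfer[i],
                   output_transfer = grid$output_transfer[i],
                   control = control)
    tr <- fit_metrics(train$response, predict(m, train$natural))
    te <- fit_metrics(test$response, predict(m, test$natural))
    list(model = m, train = tr, test = te)
  })
  report <- data.frame(
    hidden = grid$hidden,
    hidden_transfer = grid$hidden_transfer,
    output_transfer = grid$output_transfer,
    train_rmse = vapply(fits, function(f) f$train$rmse, numeric(1)),
    train_r2 = vapply(fits, function(f) f$train$r_squared, numeric(1)),
    train_dc = vapply(fits, function(f) f$train$dc, numeric(1)),
    test_rmse = vapply(fits, function(f) f$test$rmse, numeric(1)),
    test_r2 = vapply(fits, function(f) f$test$r_squared, numeric(1)),
    test_dc = vapply(fits, function(f) f$test$dc, numeric(1)))
  ord <- order(-report$test_dc, -report$test_r2)
  structure(list(report = report[ord, , drop = FALSE],
                 models = fits[ord]),
            class = "topology_search")
}

#' @export
print.topology_search <- function(x, ...) {
  cat("Topology search (ranked by testing DC):\n")
  print(cbind(x$report[, 1:3],
              round(x$report[, -(1:3)], 4)), row.names = FALSE)
  invisible(x)
}
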