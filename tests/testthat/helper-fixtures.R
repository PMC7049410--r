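# shared helpers: small training budgets and deterministic mini-fixtures

`%||%` <- function(a, b) if (is.null(a)) b else a

quick_ctl <- function(...) {
  mlp_control(max_epochs = 3000L, restarts = 2L, seed = 7L, ...)
}

# 13-run noise-free design from known coefficients, for oracle refits
noiseless_design <- function(coefficients = c(80, -5, 12, 2, 4, -1.5, -2,
                                              -2, -8, -6),
                             n_center = 1L) {
  truth <- surface_truth(coefficients, noise_sd = 0)
  simulate_bbd_responses(truth, n_center = n_center, seed = 1L)
}

# brute-force leave-one-out PRESS: refit without each run in turn
loo_press_oracle <- function(design) {
  n <- length(design$run)
  sum(vapply(seq_len(n), function(i) {
    X <- decolopt:::quad_expand(design$coded)
    fit <- stats::lm.fit(X[-i, , drop = FALSE], design$response[-i])
    pred <- drop(X[i, ] %*% fit$coefficients)
    (design$response[i] - pred)^2
  }, numeric(1)))
}
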