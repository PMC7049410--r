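test_that("restricted 1-D quadratic optimum matches the closed form", {
  # truth with interior maximum in C once A and B are pinned at +1:
  # dy/dC = b_C + b_AC + b_BC + 2 b_CC C = 0
  truth <- c(80, -5, 12, 2, 4, -1.5, -2, -2, -8, -6)
  fit <- fit_quadratic(noiseless_design(truth, n_center = 5))
  opt <- optimize_surface(fit)
  c_star <- -(truth[4] + truth[6] + truth[7]) / (2 * truth[10])
  expect_equal(opt$coded[3], c_star, tolerance = 1e-6)
  expect_equal(unname(opt$coded[1:2]), c(1, 1))
  # grid scan agrees within one grid step
  grid <- seq(-1, 1, 0.001)
  vals <- predict(fit, cbind(1, 1, grid))
  expect_lt(abs(grid[which.max(vals)] - opt$coded[3]), 0.0011)
})

test_that("stationary points outside the box are clipped to the boundary", {
  # large positive linear C effect, weak curvature: argmax beyond +1
  truth <- c(80, -5, 12, 20, 4, 0, 0, -2, -8, -1)
  fit <- fit_quadratic(noiseless_design(truth, n_center = 5))
  opt <- optimize_surface(fit)
  expect_equal(opt$coded[3], 1, tolerance = 1e-9)
  expect_equal(unname(opt$natural["pH"]), 7.5)
})

test_that("goal policies pin, fix and free factors as requested", {
  fit <- fit_quadratic(db71_runs())
  opt <- optimize_surface(fit, factor_goals("minimize", 1.75, "in_range"))
  expect_equal(unname(opt$natural["dye_conc"]), 50)
  expect_equal(unname(opt$natural["yeast_extract"]), 1.75)
  expect_error(optimize_surface(fit, factor_goals("maximize", 10, "in_range")),
               "outside limits")
  expect_error(optimize_surface(fit, factor_goals("maximize", "in_range")),
               "2 goals")
  # fully free optimization explores the interior
  opt3 <- optimize_surface(fit, factor_goals("in_range", "in_range",
                                             "in_range"))
  expect_true(all(abs(opt3$coded) <= 1 + 1e-9))
  expect_gte(opt3$predicted, opt$predicted - 1e-9)
})

test_that("optimum respects limits and desirability is a clipped rescale", {
  fit <- fit_quadratic(db71_runs())
  opt <- optimize_surface(fit)
  nat <- opt$natural
  for (i in 1:3) {
    expect_gte(nat[i], fit$factors[[i]]$low - 1e-9)
    expect_lte(nat[i], fit$factors[[i]]$high + 1e-9)
  }
  expect_gte(opt$desirability, 0)
  expect_lte(opt$desirability, 1)
  y <- db71_runs()$response
  expect_equal(opt$desirability,
               (opt$predicted - min(y)) / (max(y) - min(y)))
})

test_that("network optima come from the seeded grid search", {
  sp <- split_runs(db71_runs())
  m <- train_mlp(sp$train, hidden = 6, control = quick_ctl())
  opt <- optimize_surface(m, observed = sp$train$response)
  expect_equal(unname(opt$coded[1:2]), c(1, 1))
  grid <- seq(-1, 1, 0.001)
  vals <- predict(m, cbind(1, 1, grid), units = "coded")
  expect_equal(opt$predicted, max(vals), tolerance = 1e-9)
  # multi-start polish for two free dimensions stays inside the box
  opt2 <- optimize_surface(m, factor_goals("maximize", "in_range",
                                           "in_range"),
                           observed = sp$train$response)
  expect_true(all(abs(opt2$coded) <= 1 + 1e-6))
  expect_gte(opt2$predicted, opt$predicted - 1e-6)
})

test_that("validation deviation is the signed relative difference", {
  expect_equal(validation_deviation(92.2, 86.13), 6.58, tolerance = 0.005)
  expect_equal(validation_deviation(89.9, 86.5), 3.78, tolerance = 0.005)
  expect_equal(validation_deviation(55, 55), 0)
  expect_equal(validation_deviation(80, 90), -12.5)
  expect_error(validation_deviation(-1, 50), "positive")
})

test_that("surface grids span the limits and reflect the fitted geometry", {
  fit <- fit_quadratic(db71_runs())
  g <- surface_grid(fit, vary = c("yeast_extract", "pH"), fixed = 150,
                    resolution = 41)
  expect_equal(nrow(g), 41^2)
  expect_true(all(g$dye_conc == 150))
  top <- g[which.max(g$predicted), ]
  expect_lt(abs(top$yeast_extract - 3), (3 - 0.5) / 40 + 1e-9)
  expect_lt(abs(top$pH - 6.645), 1.5 / 40 + 1e-9)
  # every yeast-extract profile is concave (negative B^2 curvature), and
  # at the high-dye edge the response rises monotonically with yeast
  g2 <- surface_grid(fit, vary = c("dye_conc", "yeast_extract"),
                     fixed = 6.645, resolution = 21)
  for (a in unique(g2$dye_conc)) {
    col <- g2$predicted[g2$dye_conc == a][order(unique(g2$yeast_extract))]
    expect_true(all(diff(diff(col)) < 1e-9))
  }
  hi <- g2[g2$dye_conc == 150, ]
  expect_true(all(diff(hi$predicted[order(hi$yeast_extract)]) > 0))
  # constant predictor: flat grid
  d <- noiseless_design(n_center = 1)
  mconst <- train_mlp(d, hidden = 1, hidden_transfer = "linear",
                      output_transfer = "sigmoid",
                      control = mlp_control(max_epochs = 0, restarts = 1,
                                            init_range = 0))
  gc <- surface_grid(mconst, vary = c(1, 2), fixed = 6.75, resolution = 5)
  expect_equal(diff(range(gc$predicted)), 0)
})
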