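test_that("noise-free synthetic data is recovered exactly by the fit", {
  truth <- c(80, -5, 12, 2, 4, -1.5, -2, -2, -8, -6)
  d <- noiseless_design(truth, n_center = 5)
  fit <- fit_quadratic(d)
  expect_equal(unname(coef(fit)), truth, tolerance = 1e-8)
  expect_equal(sum(fit$residuals^2), 0, tolerance = 1e-12)
  an <- suppressWarnings(rsm_anova(fit))
  expect_equal(an$r_squared, 1, tolerance = 1e-10)
  expect_true(all(studentized_residuals(fit)$studentized == 0))
})

test_that("degenerate designs raise informative errors", {
  d <- bbd_design(db71_factors(), n_center = 1)
  expect_error(fit_quadratic(d), "missing responses")
  small <- decolopt:::design_subset(attach_response(d, seq_len(13)), 1:9)
  expect_error(fit_quadratic(small), ">= 10 runs")
  # all-center design: every non-intercept column is zero -> singular
  ctr <- decolopt:::design_subset(
    attach_response(bbd_design(db71_factors(), n_center = 10),
                    rep(50, 22)), 13:22)
  expect_error(fit_quadratic(ctr), "singular design")
})

test_that("predictions evaluate the quadratic in both unit systems", {
  fit <- fit_quadratic(db71_runs())
  expect_equal(predict(fit, c(0, 0, 0)), unname(coef(fit)[1]))
  expect_equal(predict(fit, c(-1, 1, 0)), 94.1, tolerance = 0.05)
  expect_equal(predict(fit, c(50, 3, 6.75), units = "natural"),
               predict(fit, c(-1, 1, 0)))
  expect_message(predict(fit, c(2, 0, 0)), "outside")
  expect_equal(predict(fit, db71_runs()$coded), fit$fitted)
})

test_that("the ANOVA decomposition is additive with correct bookkeeping", {
  datasets <- c(list(db71_runs()),
                lapply(1:5, function(s)
                  simulate_bbd_responses(surface_truth(noise_sd = 2),
                                         seed = s)))
  for (d in datasets) {
    fit <- fit_quadratic(d)
    an <- rsm_anova(fit)
    tab <- an$table
    g <- function(src, col) tab[tab$source == src, col]
    n <- length(d$run)
    expect_equal(g("Model", "ss") + g("Residual", "ss"),
                 g("Cor total", "ss"), tolerance = 1e-6)
    expect_equal(g("Lack of fit", "ss") + g("Pure error", "ss"),
                 g("Residual", "ss"), tolerance = 1e-8)
    expect_equal(g("Model", "df"), 9L)
    expect_equal(g("Residual", "df"), n - 10L)
    expect_equal(g("Pure error", "df"), sum(d$center) - 1L)
    expect_equal(g("Lack of fit", "df"),
                 g("Residual", "df") - g("Pure error", "df"))
    expect_equal(g("Cor total", "df"), n - 1L)
    expect_gte(an$press, g("Residual", "ss"))
    expect_lte(an$pred_r_squared, an$r_squared)
    expect_lte(an$adj_r_squared, an$r_squared)
    # leverages: in (0, 1], sum to the parameter count
    expect_true(all(fit$leverages > 0 & fit$leverages <= 1))
    expect_equal(sum(fit$leverages), 10, tolerance = 1e-8)
    # intercept model: residuals sum to zero
    expect_equal(sum(fit$residuals), 0, tolerance = 1e-8)
  }
})

test_that("partial SS of orthogonal terms match the closed form", {
  # on a 3-factor BBD the linear/interaction columns are orthogonal, so the
  # partial SS is b^2 * sum(x^2): 8 for linear terms, 4 for interactions
  d <- simulate_bbd_responses(surface_truth(noise_sd = 2), seed = 42)
  fit <- fit_quadratic(d)
  an <- rsm_anova(fit)
  b <- coef(fit)
  for (term in c("A", "B", "C"))
    expect_equal(an$table$ss[an$table$source == term],
                 8 * b[[term]]^2, tolerance = 1e-8)
  for (term in c("AB", "AC", "BC"))
    expect_equal(an$table$ss[an$table$source == term],
                 4 * b[[term]]^2, tolerance = 1e-8)
})

test_that("lack-of-fit split is omitted when no setting is replicated", {
  d <- noiseless_design(n_center = 1)
  set.seed(3)
  d$response <- d$response + rnorm(13, sd = 0.5)
  # the single center run of a 13-run BBD is fitted exactly (leverage 1),
  # so PRESS is undefined here and reported as NA with a warning
  expect_warning(an <- rsm_anova(fit_quadratic(d)), "leverage 1")
  expect_false(any(c("Lack of fit", "Pure error") %in% an$table$source))
  expect_true(is.na(an$press))
})

test_that("PRESS matches the brute-force leave-one-out refit oracle", {
  d <- noiseless_design(n_center = 3)
  set.seed(5)
  d$response <- d$response + rnorm(15, sd = 2)
  fit <- fit_quadratic(d)
  expect_equal(press_stat(fit), loo_press_oracle(d), tolerance = 1e-8)
})

test_that("adequate precision is the fitted range over average prediction sd", {
  fit <- fit_quadratic(db71_runs())
  num <- max(fit$fitted) - min(fit$fitted)
  expect_equal(num, 94.1 - 55.23, tolerance = 0.05)
  expect_equal(adequate_precision(fit),
               num / sqrt(10 * fit$sigma2 / 17), tolerance = 1e-12)
  # flat surface carries no signal
  flat <- fit
  flat$coefficients[2:10] <- 0
  flat$fitted <- rep(flat$coefficients[1], 17)
  expect_equal(adequate_precision(flat), 0)
})

test_that("studentized residuals are standardized and carry plot positions", {
  fit <- fit_quadratic(db71_runs())
  sr <- studentized_residuals(fit)
  expect_true(all(abs(sr$studentized) <= 3))
  expect_equal(sr$studentized,
               fit$residuals / (sqrt(fit$sigma2) * sqrt(1 - sr$leverage)))
  expect_equal(sort(sr$normal_quantile),
               qnorm(((1:17) - 0.375) / 17.25))
})
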