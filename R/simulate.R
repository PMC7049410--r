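#' Ground-truth quadratic surface for simulation
#'
#' Bundles the ten coded-term coefficients of a quadratic response surface
#' (ordering: intercept, A, B, C, AB, AC, BC, A^2, B^2, C^2), a replicate
#' noise standard deviation and the factor specifications, for use with
#' [simulate_bbd_responses()]. The defaults reproduce the statistical
#' structure of the dye-decolorization study: its fitted surface and a
#' noise level matching the observed center-replicate scatter
#' (pure-error mean square 3.66, i.e. sd ~1.91 % decolorization).
#'
#' @param coefficients Numeric vector of 10 coded-term coefficients.
#' @param noise_sd Replicate standard deviation in % decolorization
#'   (>= 0).
#' @param factors List of [factor_spec()] (default [db71_factors()]).
#' @return An object of class `surface_truth`.
#' @export
surface_truth <- function(coefficients = c(89.84, -5.90, 13.53, 2.35, 4.89,
                                           -1.72, -2.44, -1.93, -8.34, -6.49),
                          noise_sd = sqrt(3.66),
                          factors = db71_factors()) {
  check_factors(factors)
  coefficients <- as.numeric(coefficients)
  stopifnot(length(coefficients) == 10L, all(is.finite(coefficients)),
            is.numeric(noise_sd), length(noise_sd) == 1L, noise_sd >= 0)
  structure(list(coefficients = stats::setNames(coefficients, quad_terms()),
                 noise_sd = noise_sd, factors = factors),
            class = "surface_truth")
}

# evaluate the 10-term coded quadratic at a coded settings matrix
eval_quadratic <- function(coefficients, coded) {
  X <- quad_expand(coded)
  drop(X %*% coefficients)
}

#' Simulate a Box-Behnken dataset from a known quadratic surface
#'
#' Builds the three-factor Box-Behnken design, evaluates the true quadratic
#' at every coded run and adds independent Gaussian noise. Center replicates
#' share a setting but receive independent noise, so the simulated
#' pure-error sum of squares has expectation `(n_center - 1) * noise_sd^2`.
#' Responses are not clipped to `[0, 100]` unless requested, keeping
#' estimator checks unbiased.
#'
#' @param truth A [surface_truth()].
#' @param n_center Number of center replicates (default 5).
#' @param seed Integer seed; fixed seed gives a bit-identical table.
#' @param clip If `TRUE`, clamp responses into `[0, 100]`.
#' @return A `design_table` with simulated responses.
#' @examples
#' d <- simulate_bbd_responses(surface_truth(noise_sd = 0), seed = 1)
#' fit_quadratic(d)   # recovers the generating coefficients
#' @export
simulate_bbd_responses <- function(truth, n_center = 5L, seed = NULL,
                                   clip = FALSE) {
  stopifnot(inherits(truth, "surface_truth"))
  design <- bbd_design(truth$factors, n_center = n_center)
  mu <- eval_quadratic(truth$coefficients, design$coded)
  if (!is.null(seed)) set.seed(seed)
  y <- mu + stats::rnorm(length(mu), 0, truth$noise_sd)
  if (clip) y <- pmin(100, pmax(0, y))
  suppressWarnings(attach_response(design, y))
}
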