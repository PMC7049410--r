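#' The canonical 17-run dye decolorization dataset
#'
#' The Box-Behnken run table of the Direct Blue 71 decolorization study:
#' 17 runs over dye concentration (50-150 ppm), yeast extract (0.5-3 g/L)
#' and pH (6-7.5), with the measured decolorization percentage and the
#' train/test split labels used for neural-network modelling (runs 3, 6, 9,
#' 13 and 16 are the held-out test set; run 16 is a center replicate).
#'
#' @return A `design_table` with responses and a `split` factor
#'   (`"train"`/`"test"`).
#' @examples
#' d <- db71_runs()
#' range(d$response)   # 54.43 to 94.9 % decolorization
#' @export
db71_runs <- function() {
  natural <- matrix(c(
    100, 1.75, 6.75,
    100, 1.75, 6.75,
     50, 3.00, 6.75,
    150, 3.00, 6.75,
    150, 1.75, 6.00,
    150, 0.50, 6.75,
    100, 3.00, 6.00,
    100, 0.50, 7.50,
    150, 1.75, 7.50,
    100, 1.75, 6.75,
    100, 3.00, 7.50,
     50, 0.50, 6.75,
    100, 0.50, 6.00,
     50, 1.75, 6.00,
    100, 1.75, 6.75,
    100, 1.75, 6.75,
     50, 1.75, 7.50), ncol = 3L, byrow = TRUE)
  response <- c(90.97, 87.15, 94.90, 89.86, 77.03, 54.43, 88.69, 66.18,
                77.01, 88.57, 89.80, 79.06, 55.31, 82.38, 90.72, 91.77,
                89.22)
  factors <- db71_factors()
  coded <- code_factors(factors, natural)
  split <- rep("train", 17L)
  split[c(3L, 6L, 9L, 13L, 16L)] <- "test"
  d <- new_design_table(coded, factors, center = rowSums(abs(coded)) == 0,
                        response = response, split = split)
  d$natural <- natural  # printed values are exact; avoid round-trip noise
  colnames(d$natural) <- factor_names(factors)
  d
}

#' Reference predictions for the canonical dataset
#'
#' The per-run predicted decolorization values reported alongside the
#' canonical 17-run dataset for the quadratic response-surface model and
#' the published 3-26-1 neural network. The RSM column is reproducible from
#' [fit_quadratic()]; the ANN column depends on an external trainer's
#' undisclosed internals and is reproducible only approximately.
#'
#' @return A data frame with columns `run`, `predicted_rsm`, `predicted_ann`.
#' @export
db71_reference_predictions <- function() {
  data.frame(
    run = 1:17,
    predicted_rsm = c(89.84, 89.84, 94.10, 92.09, 74.87, 55.23, 88.62,
                      66.25, 76.14, 89.84, 88.44, 76.83, 56.67, 83.25,
                      89.84, 89.84, 91.38),
    predicted_ann = c(89.356, 89.382, 92.076, 89.862, 77.030, 58.118,
                      88.689, 66.180, 78.499, 89.347, 89.799, 79.060,
                      61.547, 82.381, 89.328, 90.356, 89.222))
}
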