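#' Define an experimental factor with natural-unit limits
#'
#' A factor specification names one controllable process variable and the
#' lower/upper limits between which it is varied in the design. The limits
#' define the coding transform: `low` maps to coded -1, `high` to +1 and the
#' midpoint to 0.
#'
#' @param name Factor label, e.g. `"dye_conc"`.
#' @param unit Unit string, e.g. `"ppm"`; may be `""` for dimensionless
#'   factors such as pH.
#' @param low,high Natural-unit design limits; `high` must exceed `low`.
#' @return An object of class `factor_spec`.
#' @examples
#' factor_spec("yeast_extract", "g/L", 0.5, 3)
#' @export
factor_spec <- function(name, unit, low, high) {
  stopifnot(is.character(name), nzchar(name), length(name) == 1L)
  stopifnot(is.numeric(low), is.numeric(high), length(low) == 1L,
            length(high) == 1L, is.finite(low), is.finite(high))
  if (high <= low)
    stop("factor '", name, "': 'high' (", high, ") must exceed 'low' (",
         low, ")", call. = FALSE)
  structure(list(name = name, unit = as.character(unit),
                 low = as.numeric(low), high = as.numeric(high)),
            class = "factor_spec")
}

#' @export
print.factor_spec <- function(x, ...) {
  cat(sprintf("Factor %s [%s]: %g to %g\n", x$name,
              if (nzchar(x$unit)) x$unit else "-", x$low, x$high))
  invisible(x)
}

#' Factor limits for the Direct Blue 71 decolorization study
#'
#' The three factors of the canonical dye-decolorization Box-Behnken study:
#' dye concentration 50-150 ppm, yeast extract 0.5-3 g/L, pH 6-7.5.
#'
#' @return A list of three [factor_spec()] objects.
#' @examples
#' db71_factors()
#' @export
db71_factors <- function() {
  list(factor_spec("dye_conc", "ppm", 50, 150),
       factor_spec("yeast_extract", "g/L", 0.5, 3),
       factor_spec("pH", "", 6, 7.5))
}

check_factors <- function(factors) {
  if (!is.list(factors) || length(factors) == 0L)
    stop("'factors' must be a nonempty list of factor_spec objects",
         call. = FALSE)
  ok <- vapply(factors, inherits, logical(1), "factor_spec")
  if (!all(ok))
    stop("'factors' entries ", paste(which(!ok), collapse = ", "),
         " are not factor_spec objects", call. = FALSE)
  invisible(factors)
}

factor_names <- function(factors) vapply(factors, `[[`, character(1), "name")
factor_mid  <- function(factors)
  vapply(factors, function(f) (f$high + f$low) / 2, numeric(1))
factor_half <- function(factors)
  vapply(factors, function(f) (f$high - f$low) / 2, numeric(1))

as_settings_matrix <- function(x, k, what) {
  if (is.data.frame(x)) x <- as.matrix(x)
  if (is.null(dim(x))) {
    if (length(x) != k)
      stop(what, " has length ", length(x), "; expected ", k, call. = FALSE)
    x <- matrix(as.numeric(x), nrow = 1L)
  } else {
    if (ncol(x) != k)
      stop(what, " has ", ncol(x), " columns; expected ", k, call. = FALSE)
    x <- matrix(as.numeric(x), nrow = nrow(x))
  }
  if (any(!is.finite(x)))
    stop(what, " contains non-finite values", call. = FALSE)
  x
}

#' Convert between natural and coded factor units
#'
#' `code_factors()` maps natural settings to coded units via
#' `(x - midpoint) / half_range`, so the design limits land on -1/+1;
#' `decode_factors()` is the exact inverse.
#'
#' @param factors List of [factor_spec()].
#' @param natural,coded Settings: a vector (one run) or a matrix/data.frame
#'   with one column per factor.
#' @return A numeric vector or matrix of the same shape, in the other unit
#'   system.
#' @examples
#' code_factors(db71_factors(), c(100, 1.75, 6.75))  # center -> (0, 0, 0)
#' @export
code_factors <- function(factors, natural) {
  check_factors(factors)
  k <- length(factors)
  drop1d <- is.null(dim(natural)) && !is.data.frame(natural)
  x <- as_settings_matrix(natural, k, "'natural'")
  out <- sweep(sweep(x, 2L, factor_mid(factors)), 2L, factor_half(factors), "/")
  colnames(out) <- factor_names(factors)
  if (drop1d) drop(out) else out
}

#' @rdname code_factors
#' @export
decode_factors <- function(factors, coded) {
  check_factors(factors)
  k <- length(factors)
  drop1d <- is.null(dim(coded)) && !is.data.frame(coded)
  x <- as_settings_matrix(coded, k, "'coded'")
  out <- sweep(sweep(x, 2L, factor_half(factors), "*"), 2L,
               factor_mid(factors), "+")
  colnames(out) <- factor_names(factors)
  if (drop1d) drop(out) else out
}

new_design_table <- function(coded, factors, center, response = NULL,
                             split = NULL) {
  n <- nrow(coded)
  natural <- decode_factors(factors, coded)
  if (is.null(dim(natural))) natural <- matrix(natural, nrow = 1L)
  colnames(coded) <- c("A", "B", "C")[seq_along(factors)]
  structure(list(run = seq_len(n), coded = coded, natural = natural,
                 center = center,
                 response = if (is.null(response)) rep(NA_real_, n)
                            else as.numeric(response),
                 split = split, factors = factors),
            class = "design_table")
}

#' Build a three-factor Box-Behnken design
#'
#' Generates the 12 edge runs of a three-factor Box-Behnken design -- for
#' each of the three factor pairs, the four (-1,-1), (+1,-1), (-1,+1),
#' (+1,+1) combinations with the remaining factor at its midpoint -- plus
#' `n_center` all-midpoint replicate runs. Standard order is factor-pair
#' blocks (AB, AC, BC) followed by the center block; an optional seeded
#' shuffle emulates randomized run order.
#'
#' @param factors List of exactly three [factor_spec()] objects.
#' @param n_center Number of center replicates (default 5, giving the
#'   classical 17-run design).
#' @param randomize If `TRUE`, shuffle the run order (seeded).
#' @param seed Integer seed used only when `randomize = TRUE`.
#' @return A `design_table`: run ids, coded and natural setting matrices,
#'   center flags, an (initially missing) response vector and the factor
#'   list.
#' @examples
#' bbd_design(db71_factors())          # 17 runs, 5 at the center
#' @export
bbd_design <- function(factors, n_center = 5L, randomize = FALSE,
                       seed = NULL) {
  check_factors(factors)
  if (length(factors) != 3L)
    stop("Box-Behnken construction implemented for exactly 3 factors; got ",
         length(factors), call. = FALSE)
  n_center <- as.integer(n_center)
  stopifnot(n_center >= 1L)
  pm <- cbind(c(-1, 1, -1, 1), c(-1, -1, 1, 1))
  blocks <- lapply(list(c(1L, 2L), c(1L, 3L), c(2L, 3L)), function(pair) {
    m <- matrix(0, 4L, 3L)
    m[, pair] <- pm
    m
  })
  coded <- rbind(do.call(rbind, blocks), matrix(0, n_center, 3L))
  center <- c(rep(FALSE, 12L), rep(TRUE, n_center))
  if (randomize) {
    if (!is.null(seed)) set.seed(seed)
    ord <- sample.int(nrow(coded))
    coded <- coded[ord, , drop = FALSE]
    center <- center[ord]
  }
  new_design_table(coded, factors, center)
}

#' Attach measured responses to a design table
#'
#' @param design A `design_table`.
#' @param responses Numeric vector, one response (% decolorization) per run.
#'   Values outside `[0, 100]` are accepted with a warning.
#' @return The design with the response column filled.
#' @export
attach_response <- function(design, responses) {
  stopifnot(inherits(design, "design_table"))
  responses <- as.numeric(responses)
  n <- length(design$run)
  if (length(responses) != n)
    stop("got ", length(responses), " responses for ", n, " runs",
         call. = FALSE)
  out <- which(is.finite(responses) & (responses < 0 | responses > 100))
  if (length(out))
    warning("response outside [0, 100] % in run(s) ",
            paste(design$run[out], collapse = ", "), call. = FALSE)
  design$response <- responses
  design
}

#' @export
print.design_table <- function(x, ...) {
  cat(sprintf("Box-Behnken design table: %d runs (%d center replicates)\n",
              length(x$run), sum(x$center)))
  print(utils::head(as.data.frame(x), 10L))
  if (length(x$run) > 10L) cat("  ... ", length(x$run) - 10L,
                               " more runs\n", sep = "")
  invisible(x)
}

#' Flatten a design table to a data frame
#'
#' @param x A `design_table`.
#' @param row.names,optional Ignored; present for S3 compatibility.
#' @param coded If `TRUE`, append the coded settings as `coded_A` ... columns.
#' @param ... Unused.
#' @return A data frame with run id, natural settings, response and center
#'   flag (plus coded columns on request).
#' @export
as.data.frame.design_table <- function(x, row.names = NULL, optional = FALSE,
                                       coded = FALSE, ...) {
  df <- data.frame(run = x$run, x$natural, check.names = FALSE)
  df$decolorization_pct <- x$response
  df$center <- x$center
  if (!is.null(x$split)) df$split <- x$split
  if (coded) {
    cm <- x$coded
    colnames(cm) <- paste0("coded_", colnames(cm))
    df <- cbind(df, cm)
  }
  rownames(df) <- NULL
  df
}

# subset runs, keeping metadata consistent
design_subset <- function(design, idx) {
  stopifnot(inherits(design, "design_table"))
  structure(list(run = design$run[idx],
                 coded = design$coded[idx, , drop = FALSE],
                 natural = design$natural[idx, , drop = FALSE],
                 center = design$center[idx],
                 response = design$response[idx],
                 split = if (is.null(design$split)) NULL else design$split[idx],
                 factors = design$factors),
            class = "design_table")
}
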