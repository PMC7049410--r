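sanitize_unit <- function(unit) {
  u <- gsub("/", "_per_", unit, fixed = TRUE)
  gsub("[^A-Za-z0-9]+", "_", u)
}

run_table_columns <- function(factors) {
  cols <- vapply(factors, function(f) {
    if (nzchar(f$unit)) paste0(f$name, "_", sanitize_unit(f$unit))
    else f$name
  }, character(1))
  c("run", cols, "decolorization_pct")
}

#' Read a run table from CSV
#'
#' Expects a header row with columns `run`, one natural-unit column per
#' factor (factor name plus sanitized unit, e.g. `dye_conc_ppm`,
#' `yeast_extract_g_per_L`, `pH`) and `decolorization_pct`, decimal point
#' and comma separator. All schema violations are reported together;
#' decimal commas raise an explicit dialect error rather than a silent
#' misparse. An optional `split` column (`train`/`test`) is honored.
#'
#' @param path CSV file path.
#' @param factors List of [factor_spec()] defining the expected columns and
#'   the coding transform.
#' @return A `design_table`.
#' @export
read_run_table <- function(path, factors = db71_factors()) {
  if (!file.exists(path)) stop("file not found: ", path, call. = FALSE)
  raw <- utils::read.csv(path, stringsAsFactors = FALSE,
                         colClasses = "character", check.names = FALSE)
  wanted <- run_table_columns(factors)
  problems <- character(0)
  missing <- setdiff(wanted, names(raw))
  if (length(missing))
    problems <- c(problems, paste0("missing column(s): ",
                                   paste(missing, collapse = ", ")))
  num_cols <- intersect(wanted, names(raw))
  for (cn in num_cols) {
    v <- raw[[cn]]
    if (any(grepl(",", v, fixed = TRUE)))
      problems <- c(problems, paste0("column '", cn, "' contains decimal ",
        "commas; this reader requires decimal points (CSV dialect error)"))
    else if (any(is.na(suppressWarnings(as.numeric(v))) & nzchar(v)))
      problems <- c(problems, paste0("column '", cn,
                                     "' has non-numeric entries"))
  }
  if (length(problems))
    stop("run table schema violations in ", path, ":\n  - ",
         paste(problems, collapse = "\n  - "), call. = FALSE)
  natural <- as.matrix(sapply(wanted[2:(length(factors) + 1L)],
                              function(cn) as.numeric(raw[[cn]])))
  coded <- code_factors(factors, natural)
  if (is.null(dim(coded))) coded <- matrix(coded, nrow = 1L)
  split <- if ("split" %in% names(raw)) raw$split else NULL
  d <- new_design_table(coded, factors,
                        center = rowSums(abs(coded)) < 1e-9,
                        split = split)
  d$natural <- natural
  colnames(d$natural) <- factor_names(factors)
  d$run <- as.integer(as.numeric(raw$run))
  suppressWarnings(attach_response(d, as.numeric(raw$decolorization_pct)))
}

#' Write a run table to CSV
#'
#' @param design A `design_table`.
#' @param path Output CSV path.
#' @param coded Also emit the coded settings columns.
#' @return `path`, invisibly.
#' @export
write_run_table <- function(design, path, coded = FALSE) {
  stopifnot(inherits(design, "design_table"))
  df <- as.data.frame(design, coded = coded)
  names(df)[2:(length(design$factors) + 1L)] <-
    run_table_columns(design$factors)[2:(length(design$factors) + 1L)]
  df$center <- NULL
  utils::write.csv(df, path, row.names = FALSE, quote = FALSE)
  invisible(path)
}

factors_to_list <- function(factors)
  lapply(factors, function(f) f[c("name", "unit", "low", "high")])

factors_from_list <- function(x) {
  if (is.data.frame(x))
    x <- lapply(seq_len(nrow(x)), function(i) as.list(x[i, ]))
  lapply(x, function(f)
    factor_spec(f$name, f$unit, as.numeric(f$low), as.numeric(f$high)))
}

#' Serialize a fitted model to JSON
#'
#' Both model classes round-trip exactly: predictions from a reloaded
#' model are bit-identical. Files carry a schema version and provenance
#' (package version, write time).
#'
#' @param model A `quadratic_model` or `mlp_model`.
#' @param path Output JSON path.
#' @return `path`, invisibly.
#' @export
write_model <- function(model, path) {
  prov <- list(package = "decolopt",
               version = as.character(utils::packageVersion("decolopt")),
               written = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"))
  if (inherits(model, "quadratic_model")) {
    obj <- list(schema = "decolopt/quadratic_model/1",
                coefficients = as.list(model$coefficients),
                sigma2 = model$sigma2,
                df_residual = model$df_residual,
                vcov = model$vcov,
                leverages = model$leverages,
                coded = model$coded, y = model$y, center = model$center,
                factors = factors_to_list(model$factors),
                provenance = prov)
  } else if (inherits(model, "mlp_model")) {
    obj <- list(schema = "decolopt/mlp_model/1",
                hidden = model$hidden,
                hidden_transfer = model$hidden_transfer,
                output_transfer = model$output_transfer,
                W1 = model$W1, b1 = model$b1, W2 = model$W2, b2 = model$b2,
                output_anchor = model$output_anchor,
                factors = factors_to_list(model$factors),
                control = unclass(model$control),
                epochs = model$epochs, restart = model$restart,
                provenance = prov)
  } else stop("cannot serialize objects of class ",
              paste(class(model), collapse = "/"), call. = FALSE)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}

#' Read a serialized model
#'
#' @param path JSON path written by [write_model()].
#' @return A `quadratic_model` or `mlp_model`.
#' @export
read_model <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  if (identical(obj$schema, "decolopt/quadratic_model/1")) {
    coded <- matrix(obj$coded, ncol = 3L)
    co <- stats::setNames(unlist(obj$coefficients), quad_terms())
    X <- quad_expand(coded)
    fitted <- drop(X %*% co)
    structure(list(coefficients = co, sigma2 = obj$sigma2,
                   vcov = matrix(obj$vcov, 10L, 10L),
                   leverages = obj$leverages,
                   fitted = fitted, residuals = obj$y - fitted,
                   df_residual = obj$df_residual,
                   X = X, y = obj$y, coded = coded, center = obj$center,
                   factors = factors_from_list(obj$factors)),
              class = "quadratic_model")
  } else if (identical(obj$schema, "decolopt/mlp_model/1")) {
    structure(list(hidden = obj$hidden,
                   hidden_transfer = obj$hidden_transfer,
                   output_transfer = obj$output_transfer,
                   W1 = matrix(obj$W1, nrow = obj$hidden),
                   b1 = obj$b1,
                   W2 = matrix(obj$W2, nrow = 1L),
                   b2 = obj$b2,
                   output_anchor = obj$output_anchor,
                   factors = factors_from_list(obj$factors),
                   control = do.call(mlp_control, as.list(obj$control)),
                   epochs = obj$epochs, restart = obj$restart),
              class = "mlp_model")
  } else stop("unrecognized model schema in ", path, call. = FALSE)
}

pipeline_stage <- function(stage, expr) {
  tryCatch(expr, error = function(e)
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE))
}

#' Run the full optimization pipeline
#'
#' Fit the quadratic surface, compute its ANOVA and residual diagnostics,
#' train the neural network on the training split, locate both models'
#' desirability optima under the goal policy, and compare the two
#' predictors over all runs. All artifacts (CSV/JSON plus a human-readable
#' summary) are written under `out_dir`; a stage failure aborts with the
#' stage name, preserving artifacts already written.
#'
#' @param design A `design_table` with responses, or a run-table CSV path.
#' @param out_dir Output directory (created if needed).
#' @param factors Factor specs used when `design` is a path.
#' @param goals Goal policy for [optimize_surface()].
#' @param hidden Hidden-layer size for the network.
#' @param control [mlp_control()] for network training.
#' @param test_runs Optional explicit held-out run ids (defaults to the
#'   design's stored split).
#' @return Invisibly, a list with the fitted objects and reports.
#' @export
run_full_pipeline <- function(design, out_dir = "decolopt-out",
                              factors = db71_factors(),
                              goals = factor_goals("maximize", "maximize",
                                                   "in_range"),
                              hidden = 26L, control = mlp_control(),
                              test_runs = NULL) {
  if (is.character(design))
    design <- pipeline_stage("read", read_run_table(design, factors))
  stopifnot(inherits(design, "design_table"))
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  fit <- pipeline_stage("fit", fit_quadratic(design))
  write_model(fit, file.path(out_dir, "rsm_model.json"))
  an <- pipeline_stage("anova", rsm_anova(fit))
  utils::write.csv(an$table, file.path(out_dir, "anova.csv"),
                   row.names = FALSE)
  diag <- pipeline_stage("diagnostics", studentized_residuals(fit))
  utils::write.csv(diag, file.path(out_dir, "diagnostics.csv"),
                   row.names = FALSE)
  sp <- pipeline_stage("split", split_runs(design, test_runs))
  ann <- pipeline_stage("ann-train",
                        train_mlp(sp$train, hidden = hidden,
                                  control = control))
  write_model(ann, file.path(out_dir, "ann_model.json"))
  opt_rsm <- pipeline_stage("optimize",
                            optimize_surface(fit, goals,
                                             observed = design$response))
  opt_ann <- pipeline_stage("optimize",
                            optimize_surface(ann, goals,
                                             observed = design$response))
  jsonlite::write_json(lapply(unclass(opt_rsm), unname),
                       file.path(out_dir, "optimum_rsm.json"),
                       auto_unbox = TRUE, digits = NA)
  jsonlite::write_json(lapply(unclass(opt_ann), unname),
                       file.path(out_dir, "optimum_ann.json"),
                       auto_unbox = TRUE, digits = NA)
  cmp <- pipeline_stage("compare",
                        compare_models(design$response,
                                       predict(fit, design$coded),
                                       predict(ann, design$natural)))
  utils::write.csv(cmp$metrics, file.path(out_dir, "comparison.csv"),
                   row.names = FALSE)
  summary_path <- file.path(out_dir, "summary.txt")
  withr_local <- file(summary_path, "w"); on.exit(close(withr_local))
  sink(withr_local); on.exit(sink(), add = TRUE, after = FALSE)
  cat("decolopt pipeline summary\n=========================\n\n")
  print(an); cat("\n")
  cat("RSM optimum:\n"); print(opt_rsm)
  cat("\nANN optimum:\n"); print(opt_ann)
  cat("\n"); print(cmp)
  invisible(list(design = design, fit = fit, anova = an,
                 diagnostics = diag, ann = ann, optimum_rsm = opt_rsm,
                 optimum_ann = opt_ann, comparison = cmp,
                 out_dir = out_dir))
}
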