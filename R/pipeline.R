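# End-to-end workflows tying the stages together: fit a surrogate on a
# design table, maximize it with the GA, and assemble a report bundle.
# A single top-level seed fans out to per-stage seeds by fixed offsets
# (GA: seed, ANN restarts: seed, seed+1, ...), so each stage is
# independently reproducible.

#' Response-surface workflow: quadratic fit, ANOVA, GA maximization
#'
#' @param design A `ccd_design` with observed responses.
#' @param bounds Box bounds for the GA (default: the design box). The
#'   optimum of a quadratic over a box often sits on its boundary, so the
#'   choice of box is part of the scientific question, not a nuisance
#'   setting.
#' @param basis Fit basis, see [fit_quadratic()].
#' @param ga A [ga_config()].
#' @param baseline Optional unoptimized activity (U/mL) for a fold-change
#'   entry in the summary.
#' @param out_dir Optional directory; when given, writes `rsm_model.json`,
#'   `rsm_anova.csv`, `ga_trace.csv` and `summary.json` there.
#' @param seed Top-level seed (overrides `ga$seed`).
#' @return List of class `rsm_ga_report`: `model`, `anova`, `metrics`
#'   (in-sample), `ga`, `summary`.
#' @export
run_rsm_ga <- function(design, bounds = NULL, basis = "uncoded",
                       ga = ga_config(), baseline = NULL, out_dir = NULL,
                       seed = 1L) {
  factors <- attr(design, "factors")
  if (is.null(bounds)) bounds <- design_bounds(factors)
  model <- fit_quadratic(design, basis = basis)
  anova <- anova_table(model)
  keep <- is.finite(design$observed)
  metrics <- model_metrics(design$observed[keep],
                           predict(model, design_matrix(design)[keep, , drop = FALSE]))
  ga$seed <- as.integer(seed)
  eval_model <- if (identical(basis, "coded")) convert_basis(model, "uncoded") else model
  run <- ga_optimize(function(p) predict(eval_model, p), bounds, ga)
  summary <- list(
    r_squared = model$diagnostics$r_squared,
    r = model$diagnostics$r,
    best_composition = as.list(run$best_point),
    predicted_activity = run$best_fitness,
    generations_used = run$generations_used,
    stop_reason = run$stop_reason,
    seed = as.integer(seed)
  )
  if (!is.null(baseline)) {
    summary$baseline <- baseline
    summary$fold_change <- fold_change(run$best_fitness, baseline)
  }
  out <- structure(list(model = model, anova = anova, metrics = metrics,
                        ga = run, summary = summary),
                   class = "rsm_ga_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    rsm_to_json(model, file.path(out_dir, "rsm_model.json"))
    utils::write.csv(anova, file.path(out_dir, "rsm_anova.csv"),
                     row.names = FALSE)
    utils::write.csv(run$trace, file.path(out_dir, "ga_trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}

#' Neural-network workflow: restart training, GA maximization
#'
#' Trains `length(seeds)` networks, keeps the restart with the best
#' validation correlation (see [nn_restarts()]), and maximizes the selected
#' network over the bounds with the GA.
#'
#' @inheritParams run_rsm_ga
#' @param n_hidden Hidden-layer width (default 15).
#' @param seeds Restart seeds; defaults to `seed + 0:9`.
#' @param config An [nn_config()].
#' @param init_scale Passed to [nn_init()].
#' @return List of class `ann_ga_report`: `model`, `report`, `restarts`,
#'   `ga`, `summary`.
#' @export
run_ann_ga <- function(design, bounds = NULL, n_hidden = 15L, seeds = NULL,
                       config = nn_config(), ga = ga_config(),
                       init_scale = 0.5, baseline = NULL, out_dir = NULL,
                       seed = 1L) {
  factors <- attr(design, "factors")
  if (is.null(bounds)) bounds <- design_bounds(factors)
  if (is.null(seeds)) seeds <- as.integer(seed) + 0:9
  fit <- nn_restarts(design, n_hidden = n_hidden, seeds = seeds,
                     config = config, init_scale = init_scale)
  ga$seed <- as.integer(seed)
  run <- ga_optimize(function(p) nn_forward(fit$model, p), bounds, ga)
  summary <- list(
    best_seed = fit$best_seed,
    r_train = fit$report$r_train,
    r_test = fit$report$r_test,
    r_validation = fit$report$r_validation,
    best_composition = as.list(run$best_point),
    predicted_activity = run$best_fitness,
    generations_used = run$generations_used,
    stop_reason = run$stop_reason,
    seed = as.integer(seed)
  )
  if (!is.null(baseline)) {
    summary$baseline <- baseline
    summary$fold_change <- fold_change(run$best_fitness, baseline)
  }
  out <- structure(list(model = fit$model, report = fit$report,
                        restarts = fit$summary, ga = run, summary = summary),
                   class = "ann_ga_report")
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    nn_to_json(fit$model, file.path(out_dir, "ann_model.json"))
    utils::write.csv(fit$summary, file.path(out_dir, "ann_restarts.csv"),
                     row.names = FALSE)
    utils::write.csv(run$trace, file.path(out_dir, "ga_trace.csv"),
                     row.names = FALSE)
    jsonlite::write_json(summary, file.path(out_dir, "summary.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  out
}
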