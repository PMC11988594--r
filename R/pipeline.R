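#' Configuration of a full traceability run
#'
#' Bundles the per-stage settings of the generate -> screen -> split/scale ->
#' train -> evaluate -> explain pipeline. One global seed deterministically
#' derives the stage seeds (cohort: seed, split: seed + 1, training:
#' seed + 2, explanation: seed + 3), so a single integer reproduces the
#' whole experiment bit-for-bit; each stage seed can be overridden.
#'
#' @param seed Global seed.
#' @param out_dir Output directory for run artifacts (`NULL` for in-memory
#'   runs only).
#' @param n_per_origin,clip_at_zero,sd_scale Cohort generator settings, see
#'   [generate_cohort()].
#' @param alpha ANOVA screening level.
#' @param train_fraction,stratified Split settings, see [stratified_split()].
#' @param cnn Named list of [cnn_config()] overrides (e.g. `epochs`).
#' @param shap Named list: `method` ("permutation" or "exact"), `n_perm`,
#'   `mode`, `max_samples` (cap on explained test samples).
#' @param explain Run the Shapley stage (default `TRUE`).
#' @param stage_seeds Optional named list overriding the derived seeds
#'   (`cohort`, `split`, `train`, `shap`).
#' @return A list of class `kelp_run_config`.
#' @export
run_config <- function(seed = 1L, out_dir = NULL, n_per_origin = 30L,
                       clip_at_zero = FALSE, sd_scale = 1, alpha = 0.05,
                       train_fraction = 0.7, stratified = TRUE,
                       cnn = list(), shap = list(), explain = TRUE,
                       stage_seeds = list()) {
  check_number(seed, "seed")
  check_number(alpha, "alpha", lower = 0, upper = 1)
  shap_defaults <- list(method = "permutation", n_perm = 10L,
                        mode = "sample-average", max_samples = Inf)
  derived <- list(
    cohort = derive_seed(seed, 0L), split = derive_seed(seed, 1L),
    train = derive_seed(seed, 2L), shap = derive_seed(seed, 3L)
  )
  cfg <- list(
    seed = as.integer(seed), out_dir = out_dir,
    n_per_origin = as.integer(n_per_origin),
    clip_at_zero = isTRUE(clip_at_zero), sd_scale = sd_scale,
    alpha = alpha, train_fraction = train_fraction,
    stratified = isTRUE(stratified),
    cnn = cnn,
    shap = modifyList(shap_defaults, shap),
    explain = isTRUE(explain),
    stage_seeds = modifyList(derived, stage_seeds)
  )
  class(cfg) <- "kelp_run_config"
  cfg
}

log_stage <- function(fmt, ...) {
  message(sprintf("[%s] %s", format(Sys.time(), "%H:%M:%S"), sprintf(fmt, ...)))
}

#' Run the full origin-traceability pipeline
#'
#' Executes, in order: synthetic cohort generation from the packaged
#' reference table, per-feature ANOVA screening with Duncan letters,
#' stratified 7:3 splitting, train-only z-score standardization, 1D-CNN
#' training, test-set evaluation (confusion matrix, per-class metrics,
#' one-vs-rest ROC/AUC), and — unless disabled — Shapley explanation of the
#' test predictions against the standardized training background. When
#' `config$out_dir` is set, eight artifacts are written (cohort, screening
#' table, split indices, scaler, model, training history, evaluation
#' report, explanation table) plus sidecar summaries and a manifest that
#' suffices to reproduce the run.
#'
#' @param config A [run_config()].
#' @param ref A `voc_reference` (defaults to the packaged table).
#' @return An object of class `kelp_run`: all in-memory stage results plus
#'   the manifest.
#' @export
#' @examples
#' \donttest{
#' run <- run_pipeline(run_config(seed = 1, explain = FALSE,
#'                                cnn = list(epochs = 30)))
#' glance(run$evaluation)
#' }
run_pipeline <- function(config = run_config(), ref = voc_reference()) {
  stopifnot(inherits(config, "kelp_run_config"))
  out_dir <- config$out_dir
  write_out <- !is.null(out_dir)
  if (write_out && !dir.exists(out_dir)) {
    dir.create(out_dir, recursive = TRUE)
  }
  artifacts <- list()
  sidecars <- list()
  timings <- list()
  tick <- function(stage, expr) {
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(expr, error = function(e) {
      stop_kelp(sprintf("stage '%s' failed: %s", stage, conditionMessage(e)),
                class = "kelptrace_stage_error")
    })
    timings[[stage]] <<- round(proc.time()[["elapsed"]] - t0, 3)
    res
  }
  seeds <- config$stage_seeds

  log_stage("generate: cohort of %d x 3 samples (seed %d)",
            config$n_per_origin, seeds$cohort)
  cohort <- tick("generate", generate_cohort(
    ref, n_per_origin = config$n_per_origin, seed = seeds$cohort,
    clip_at_zero = config$clip_at_zero, sd_scale = config$sd_scale
  ))
  if (write_out) {
    artifacts$cohort <- file.path(out_dir, "cohort.tsv")
    write_cohort(cohort, artifacts$cohort)
  }

  log_stage("screen: one-way ANOVA at alpha = %g", config$alpha)
  screen <- tick("screen", screen_features(cohort, alpha = config$alpha))
  if (length(screen$selected_ids) == 0L) {
    stop_kelp("stage 'screen' failed: 0 features selected",
              class = "kelptrace_stage_error")
  }
  if (write_out) {
    artifacts$screen <- file.path(out_dir, "screen.tsv")
    sidecars$screen_summary <- file.path(out_dir, "screen_summary.json")
    write_screen_report(screen, artifacts$screen, sidecars$screen_summary)
  }

  log_stage("split: stratified %g:%g (seed %d)", config$train_fraction,
            1 - config$train_fraction, seeds$split)
  split <- tick("split", stratified_split(
    screen$cohort, train_fraction = config$train_fraction,
    seed = seeds$split, stratified = config$stratified
  ))
  if (write_out) {
    artifacts$split <- file.path(out_dir, "split.json")
    jsonlite::write_json(
      list(train_idx = split$train_idx, test_idx = split$test_idx,
           train_ids = split$train$sample_id, test_ids = split$test$sample_id),
      artifacts$split, auto_unbox = FALSE, digits = NA
    )
  }

  scaler <- tick("scale", fit_scaler(split$train))
  train_scaled <- apply_scaler(scaler, split$train)
  test_scaled <- apply_scaler(scaler, split$test)
  if (write_out) {
    artifacts$scaler <- file.path(out_dir, "scaler.json")
    jsonlite::write_json(
      list(mu = as.list(scaler$mu), sigma = as.list(scaler$sigma),
           sd_convention = scaler$sd_convention),
      artifacts$scaler, auto_unbox = TRUE, digits = NA
    )
  }

  cnn_args <- modifyList(
    list(input_len = length(screen$selected_ids), seed = seeds$train),
    config$cnn
  )
  cnn_cfg <- do.call(cnn_config, cnn_args)
  log_stage("train: %d epochs, batch %d (seed %d)", cnn_cfg$epochs,
            cnn_cfg$batch_size, seeds$train)
  model <- tick("train", fit_origin_cnn(train_scaled, config = cnn_cfg))
  if (write_out) {
    artifacts$model <- file.path(out_dir, "model.json")
    write_cnn(model, artifacts$model)
    artifacts$history <- file.path(out_dir, "history.csv")
    readr::write_csv(model$history, artifacts$history, progress = FALSE)
  }

  log_stage("evaluate: %d held-out samples", nrow(split$test))
  test_probs <- predict(model, test_scaled, type = "matrix")
  evaluation <- tick("evaluate",
                     evaluate_predictions(split$test$origin, test_probs,
                                          n_classes = cnn_cfg$n_classes))
  # per-class mean training-set output: the explanation base values
  train_base <- colMeans(predict(model, train_scaled, type = "matrix"))
  names(train_base) <- names(.kelp_origins)[seq_along(train_base)]
  if (write_out) {
    artifacts$evaluation <- file.path(out_dir, "evaluation.json")
    jsonlite::write_json(
      list(confusion = unclass(evaluation$confusion),
           accuracy = evaluation$accuracy,
           macro = as.list(evaluation$macro),
           per_class = evaluation$metrics,
           auc = as.list(evaluation$auc),
           train_base_values = as.list(train_base),
           n_test = evaluation$n_test),
      artifacts$evaluation, auto_unbox = TRUE, digits = NA
    )
  }

  explanation <- NULL
  if (config$explain) {
    shap_cfg <- config$shap
    x_test <- cohort_matrix(test_scaled)
    keep <- seq_len(min(nrow(x_test), shap_cfg$max_samples))
    x_test <- x_test[keep, , drop = FALSE]
    bg <- cohort_matrix(train_scaled)
    log_stage("explain: %s Shapley over %d test samples (seed %d)",
              shap_cfg$method, nrow(x_test), seeds$shap)
    explanation <- tick("explain", {
      if (shap_cfg$method == "exact") {
        shap_exact(model, x_test, bg, mode = shap_cfg$mode)
      } else {
        shap_permutation(model, x_test, bg, n_perm = shap_cfg$n_perm,
                         seed = seeds$shap, mode = shap_cfg$mode)
      }
    })
    if (write_out) {
      artifacts$explanation <- file.path(out_dir, "explanation.tsv")
      sidecars$explanation_meta <- file.path(out_dir, "explanation_meta.json")
      write_explanation(explanation, artifacts$explanation,
                        sidecars$explanation_meta)
    }
  }

  manifest <- list(
    package_version = as.character(utils::packageVersion("kelptrace")),
    created = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    config = config[setdiff(names(config), "out_dir")],
    stage_seeds = seeds,
    artifacts = artifacts,
    sidecars = sidecars,
    wall_clock_sec = timings,
    n_train = nrow(split$train), n_test = nrow(split$test),
    n_selected_features = length(screen$selected_ids),
    generator_note = paste(
      "per-feature independent Normal(mean, sd) draws per origin;",
      "negative draws clipped to 0"
    )
  )
  if (!is.finite(manifest$config$shap$max_samples)) {
    manifest$config$shap$max_samples <- "all"
  }
  if (write_out) {
    jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, null = "null",
                         force = TRUE)
  }

  structure(
    list(config = config, cohort = cohort, screen = screen, split = split,
         scaler = scaler, model = model, evaluation = evaluation,
         train_base_values = train_base, explanation = explanation,
         manifest = manifest),
    class = "kelp_run"
  )
}

#' @export
print.kelp_run <- function(x, ...) {
  cat(sprintf("kelptrace run (seed %d): %d features selected, test accuracy %.1f%%, mean AUC %.3f\n",
              x$config$seed, length(x$screen$selected_ids),
              100 * x$evaluation$accuracy, mean(x$evaluation$auc)))
  invisible(x)
}
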