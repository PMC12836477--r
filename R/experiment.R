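#' Configuration of the nested cross-validation experiment
#'
#' @param feature_sets subset of `"demographics"`,
#'   `"digital_phenotyping"`, `"combined"`.
#' @param families subset of `"dummy"`, `"elasticnet_logreg"`,
#'   `"random_forest"`.
#' @param digital_mode `"boruta"` (all-relevant selection of the digital
#'   features per outer split) or `"fixed"` (a single pre-chosen digital
#'   feature, mirroring a post-hoc simplification to the most stable
#'   feature; note that choosing that feature from full-data stability is
#'   itself a source of leakage, which is why this is an explicit mode
#'   rather than a default).
#' @param fixed_feature digital feature used in fixed mode.
#' @param k_outer outer folds (default 5).
#' @param tuning_folds inner stratified CV folds (default 10).
#' @param boruta_max_iter,boruta_num_trees,boruta_alpha Boruta settings.
#' @param grids optional named list of per-family hyperparameter grids.
#' @param seed master seed; every stochastic component derives its own
#'   seed from it.
#' @return list of class `experiment_config`.
#' @export
experiment_config <- function(feature_sets = c("demographics",
                                               "digital_phenotyping",
                                               "combined"),
                              families = c("dummy", "elasticnet_logreg",
                                           "random_forest"),
                              digital_mode = c("boruta", "fixed"),
                              fixed_feature = "n_trajectories_total",
                              k_outer = 5, tuning_folds = 10,
                              boruta_max_iter = 100, boruta_num_trees = 100,
                              boruta_alpha = 0.05, grids = list(),
                              seed = 1) {
  feature_sets <- match.arg(feature_sets, several.ok = TRUE)
  families <- match.arg(families, several.ok = TRUE)
  digital_mode <- match.arg(digital_mode)
  structure(list(feature_sets = feature_sets, families = families,
                 digital_mode = digital_mode, fixed_feature = fixed_feature,
                 k_outer = k_outer, tuning_folds = tuning_folds,
                 boruta_max_iter = boruta_max_iter,
                 boruta_num_trees = boruta_num_trees,
                 boruta_alpha = boruta_alpha, grids = grids,
                 seed = as.integer(seed)),
            class = "experiment_config")
}

DEMOGRAPHIC_FEATURES <- c("age", "sex", "years_education")

# Everything on the training side of one outer split: preprocessing,
# digital-feature selection and model fitting. Never sees test labels.
train_fold <- function(X_df, y, train_idx, config, fold_seed) {
  pp <- fit_preprocessor(X_df[train_idx, , drop = FALSE])
  X_tr <- apply_preprocessor(pp, X_df[train_idx, , drop = FALSE])
  y_tr <- y[train_idx]
  digital_cols <- setdiff(colnames(X_tr), DEMOGRAPHIC_FEATURES)

  boruta <- NULL
  if (config$digital_mode == "fixed") {
    if (!config$fixed_feature %in% digital_cols)
      stop("fixed_feature not found among digital features: ",
           config$fixed_feature, call. = FALSE)
    selected <- config$fixed_feature
  } else {
    boruta <- boruta_select(X_tr[, digital_cols, drop = FALSE], y_tr,
                            max_iter = config$boruta_max_iter,
                            alpha = config$boruta_alpha,
                            num_trees = config$boruta_num_trees,
                            seed = fold_seed)
    selected <- boruta$confirmed
    # a split may confirm nothing; fall back to the single most-hit
    # feature so every cell still has a model to evaluate
    if (!length(selected))
      selected <- names(which.max(boruta$hits))
  }

  cols_for <- function(fs) switch(fs,
    demographics = intersect(DEMOGRAPHIC_FEATURES, colnames(X_tr)),
    digital_phenotyping = selected,
    combined = c(intersect(DEMOGRAPHIC_FEATURES, colnames(X_tr)), selected))

  fits <- list()
  for (fs in config$feature_sets) {
    fits[[fs]] <- list()
    cols <- cols_for(fs)
    for (fam in config$families) {
      spec <- model_spec(fam, config$grids[[fam]],
                         tuning_folds = config$tuning_folds)
      fits[[fs]][[fam]] <- tune_and_train(spec,
                                          X_tr[, cols, drop = FALSE],
                                          y_tr, seed = fold_seed)
    }
  }
  list(preprocessor = pp, selected = selected, boruta = boruta, fits = fits)
}

#' Run the full nested cross-validation experiment
#'
#' Stratified k-fold outer split; per split, train-only min-max scaling
#' and mean imputation, digital-feature selection (Boruta or a fixed
#' single feature), grid-search tuning of every requested model family by
#' stratified inner cross-validation maximizing AUROC, and evaluation on
#' the held-out partition. Metrics are aggregated across folds by median
#' and range. Deterministic given `config$seed`.
#'
#' @param analysis an `analysis_dataset` from [apply_inclusion()] (or any
#'   list with `features` and `labels` of the same shape).
#' @param config an [experiment_config()].
#' @param plan optional precomputed [make_outer_folds()] plan (defaults
#'   to a fresh stratified split from `config$seed`).
#' @return object of class `experiment_report`: `metrics` (one row per
#'   feature set x family x fold), `aggregates` (median/min/max over
#'   folds), `selected_features` (per fold), `stability` (selection
#'   counts across folds), `plan`, `fold_models`, `fold_data`, `config`.
#' @export
run_experiment <- function(analysis, config = experiment_config(),
                           plan = NULL) {
  y <- as.integer(analysis$labels)
  if (length(unique(y)) < 2)
    stop("both outcome classes must be present", call. = FALSE)
  X_df <- analysis$features
  X_df <- X_df[, setdiff(names(X_df), "participant_id"), drop = FALSE]
  if (is.null(plan)) plan <- make_outer_folds(y, config$k_outer, config$seed)
  fold_seeds <- withr::with_seed(config$seed,
                                 sample.int(2^30, length(plan$folds)))

  metrics <- list(); fold_models <- list(); fold_data <- list()
  selected_features <- list()
  for (f in seq_along(plan$folds)) {
    test_idx <- plan$folds[[f]]
    train_idx <- setdiff(seq_along(y), test_idx)
    tr <- train_fold(X_df, y, train_idx, config, fold_seeds[f])
    X_te <- apply_preprocessor(tr$preprocessor, X_df[test_idx, , drop = FALSE])
    X_tr <- apply_preprocessor(tr$preprocessor, X_df[train_idx, , drop = FALSE])
    selected_features[[f]] <- tr$selected
    fold_models[[f]] <- tr$fits
    fold_data[[f]] <- list(train_idx = train_idx, test_idx = test_idx,
                           X_train = X_tr, X_test = X_te,
                           y_train = y[train_idx], y_test = y[test_idx])
    for (fs in config$feature_sets) {
      for (fam in config$families) {
        model <- tr$fits[[fs]][[fam]]
        m <- evaluate_model(model, X_te[, model$features, drop = FALSE],
                            y[test_idx])
        metrics[[length(metrics) + 1]] <-
          data.frame(feature_set = fs, family = fam, fold = f, t(m),
                     stringsAsFactors = FALSE)
      }
    }
  }
  metrics <- do.call(rbind, metrics)
  rownames(metrics) <- NULL

  metric_cols <- setdiff(names(metrics), c("feature_set", "family", "fold"))
  agg <- list()
  for (fs in config$feature_sets) for (fam in config$families) {
    sub <- metrics[metrics$feature_set == fs & metrics$family == fam,
                   metric_cols, drop = FALSE]
    agg[[length(agg) + 1]] <- data.frame(
      feature_set = fs, family = fam, metric = metric_cols,
      median = vapply(sub, median, numeric(1)),
      min = vapply(sub, min, numeric(1)),
      max = vapply(sub, max, numeric(1)), stringsAsFactors = FALSE)
  }
  aggregates <- do.call(rbind, agg)
  rownames(aggregates) <- NULL

  sel_tab <- table(unlist(selected_features))
  stability <- data.frame(feature = names(sel_tab),
                          n_folds_selected = as.integer(sel_tab),
                          stringsAsFactors = FALSE)
  stability <- stability[order(-stability$n_folds_selected,
                               stability$feature), , drop = FALSE]
  rownames(stability) <- NULL

  structure(list(metrics = metrics, aggregates = aggregates,
                 selected_features = selected_features,
                 stability = stability, plan = plan,
                 fold_models = fold_models, fold_data = fold_data,
                 config = config),
            class = "experiment_report")
}

#' @export
print.experiment_report <- function(x, ...) {
  cat("<experiment_report>\n")
  au <- x$aggregates[x$aggregates$metric == "auroc", , drop = FALSE]
  for (r in seq_len(nrow(au)))
    cat(sprintf("  %-20s %-18s median AUROC %.3f (range %.3f-%.3f)\n",
                au$feature_set[r], au$family[r], au$median[r], au$min[r],
                au$max[r]))
  if (nrow(x$stability)) {
    cat("  most stable digital features:\n")
    top <- head(x$stability, 3)
    for (r in seq_len(nrow(top)))
      cat(sprintf("    %s (%d/%d folds)\n", top$feature[r],
                  top$n_folds_selected[r], length(x$plan$folds)))
  }
  invisible(x)
}
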