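#' Model specification for the tuning loop
#'
#' @param family one of `"dummy"`, `"elasticnet_logreg"`, `"random_forest"`.
#' @param grid data frame of hyperparameter candidates, one row per grid
#'   point, evaluated in row order (ties in tuning score go to the first
#'   row). Ignored by the dummy family. `NULL` selects the default grid:
#'   elastic net - regularization strength lambda in {0.01, 0.1, 1, 10}
#'   crossed with mixing alpha in {0.1, 0.5, 0.9}; random forest - trees
#'   in {100, 500}, max depth in {unbounded, 3, 5}, min node size in
#'   {1, 5}.
#' @param tuning_folds inner stratified CV folds (default 10).
#' @return object of class `model_spec`.
#' @export
model_spec <- function(family = c("dummy", "elasticnet_logreg", "random_forest"),
                       grid = NULL, tuning_folds = 10) {
  family <- match.arg(family)
  if (is.null(grid)) grid <- default_grid(family)
  if (family != "dummy" && (!is.data.frame(grid) || nrow(grid) == 0))
    stop("hyperparameter grid must be a non-empty data frame", call. = FALSE)
  structure(list(family = family, grid = grid, tuning_folds = tuning_folds),
            class = "model_spec")
}

default_grid <- function(family) {
  switch(family,
         dummy = NULL,
         elasticnet_logreg = expand.grid(lambda = c(0.01, 0.1, 1, 10),
                                         alpha = c(0.1, 0.5, 0.9),
                                         KEEP.OUT.ATTRS = FALSE),
         random_forest = expand.grid(num_trees = c(100, 500),
                                     max_depth = c(0, 3, 5),  # 0 = unbounded
                                     min_node_size = c(1, 5),
                                     KEEP.OUT.ATTRS = FALSE))
}

# glmnet needs >= 2 columns; a zero column is penalty-neutral padding
pad_single_col <- function(X) {
  if (ncol(X) == 1) cbind(X, .pad0 = 0) else X
}

fit_family <- function(family, X, y, params, seed) {
  if (family == "elasticnet_logreg") {
    X <- pad_single_col(X)
    # fit along a short descending path ending at the requested lambda
    # (glmnet's recommended usage); predictions are taken at that lambda
    path <- sort(unique(params$lambda * c(100, 10, 1)), decreasing = TRUE)
    fit <- glmnet::glmnet(X, factor(y, levels = c(0, 1)), family = "binomial",
                          alpha = params$alpha, lambda = path,
                          standardize = FALSE)
    fit$.dp_lambda <- params$lambda
    fit
  } else {
    ranger::ranger(x = X, y = factor(y, levels = c(0, 1)),
                   num.trees = params$num_trees,
                   max.depth = params$max_depth,
                   min.node.size = params$min_node_size,
                   probability = TRUE, seed = seed, num.threads = 1)
  }
}

score_family <- function(family, fit, X) {
  if (family == "elasticnet_logreg") {
    as.numeric(predict(fit, newx = pad_single_col(X), type = "response",
                       s = fit$.dp_lambda))
  } else {
    predict(fit, data = X, num.threads = 1)$predictions[, "1"]
  }
}

#' Grid-search tune and train a model
#'
#' Evaluates every grid point by stratified inner cross-validation on the
#' training data, selects the one with the highest mean validation AUROC
#' (ties go to the first grid row), and refits it on all of the training
#' data. The dummy family ignores the features and emits a constant score
#' of 0.5, with seeded uniform label outputs for class metrics.
#'
#' @param spec a [model_spec()].
#' @param X_train numeric matrix of preprocessed, selected features.
#' @param y_train 0/1 labels.
#' @param seed integer seed for inner folds, model fitting and the dummy
#'   label stream.
#' @return object of class `dp_model` with elements `family`, `fit`,
#'   `chosen` (selected grid row), `cv_auroc`, `features`, `seed`.
#' @export
tune_and_train <- function(spec, X_train, y_train, seed = 1) {
  stopifnot(inherits(spec, "model_spec"))
  y_train <- as.integer(y_train)
  if (spec$family == "dummy") {
    return(structure(list(family = "dummy", fit = NULL, chosen = NULL,
                          cv_auroc = NA_real_, features = colnames(X_train),
                          seed = seed), class = "dp_model"))
  }
  X_train <- as.matrix(X_train)
  grid <- spec$grid
  cv_score <- rep(NA_real_, nrow(grid))
  if (nrow(grid) > 1) {
    plan <- make_outer_folds(y_train, k = spec$tuning_folds, seed = seed)
    for (g in seq_len(nrow(grid))) {
      aucs <- vapply(plan$folds, function(val_idx) {
        tr <- setdiff(seq_along(y_train), val_idx)
        fit <- fit_family(spec$family, X_train[tr, , drop = FALSE],
                          y_train[tr], grid[g, ], seed)
        s <- score_family(spec$family, fit, X_train[val_idx, , drop = FALSE])
        if (length(unique(y_train[val_idx])) < 2) NA_real_
        else auroc(s, y_train[val_idx])
      }, numeric(1))
      cv_score[g] <- mean(aucs, na.rm = TRUE)
    }
    best <- which(cv_score == max(cv_score))[1]
  } else best <- 1L
  fit <- fit_family(spec$family, X_train, y_train, grid[best, ], seed)
  structure(list(family = spec$family, fit = fit, chosen = grid[best, ],
                 cv_auroc = cv_score[best], features = colnames(X_train),
                 seed = seed), class = "dp_model")
}

#' Predicted probability of the symptomatic class
#'
#' @param model a `dp_model`.
#' @param X feature matrix in training column order.
#' @return numeric vector of scores in `[0, 1]`; the dummy family returns
#'   a constant 0.5.
#' @export
predict_scores <- function(model, X) {
  stopifnot(inherits(model, "dp_model"))
  if (model$family == "dummy") return(rep(0.5, nrow(as.matrix(X))))
  score_family(model$family, model$fit,
               as.matrix(X)[, model$features, drop = FALSE])
}

predict_labels <- function(model, X, threshold = 0.5) {
  n <- nrow(as.matrix(X))
  if (model$family == "dummy")
    return(withr::with_seed(model$seed, sample(c(0L, 1L), n, replace = TRUE)))
  as.integer(predict_scores(model, X) >= threshold)
}

#' @export
print.dp_model <- function(x, ...) {
  cat("<dp_model>", x$family)
  if (!is.null(x$chosen))
    cat(" (", paste(names(x$chosen), unlist(x$chosen), sep = "=",
                    collapse = ", "), ")", sep = "")
  cat("\n  features:", paste(x$features, collapse = ", "), "\n")
  invisible(x)
}

#' Area under the ROC curve via the rank statistic
#'
#' Equals the probability that a random positive is scored above a random
#' negative, with half credit for ties (average ranks). A constant score
#' yields exactly 0.5.
#'
#' @param scores numeric scores, higher = more positive.
#' @param y 0/1 labels, both classes present.
#' @return AUROC in `[0, 1]`.
#' @export
auroc <- function(scores, y) {
  y <- as.integer(y)
  n1 <- sum(y == 1); n0 <- sum(y == 0)
  if (n1 == 0 || n0 == 0)
    stop("AUROC requires both classes in y", call. = FALSE)
  r <- rank(scores, ties.method = "average")
  (sum(r[y == 1]) - n1 * (n1 + 1) / 2) / (n0 * n1)
}

prf <- function(pred, truth, positive) {
  tp <- sum(pred == positive & truth == positive)
  fp <- sum(pred == positive & truth != positive)
  fn <- sum(pred != positive & truth == positive)
  precision <- if (tp + fp == 0) 0 else tp / (tp + fp)
  recall <- if (tp + fn == 0) 0 else tp / (tp + fn)
  f1 <- if (precision + recall == 0) 0 else
    2 * precision * recall / (precision + recall)
  c(precision = precision, recall = recall, f1 = f1)
}

#' Evaluate a trained model on a held-out test set
#'
#' Computes AUROC (rank-based, average-rank ties), accuracy, balanced
#' accuracy, and per-class precision/recall/F1 at a 0.5 decision
#' threshold, with the 0-on-zero-division convention. The dummy family
#' scores a constant 0.5 (AUROC exactly 0.5) and draws its class labels
#' from a seeded uniform stream.
#'
#' @param model a `dp_model`.
#' @param X_test feature matrix.
#' @param y_test 0/1 labels; both classes must be present.
#' @param threshold decision threshold for class metrics.
#' @return named numeric vector: `auroc`, `accuracy`,
#'   `balanced_accuracy`, `precision_0`, `precision_1`, `recall_0`,
#'   `recall_1`, `f1_0`, `f1_1`.
#' @export
evaluate_model <- function(model, X_test, y_test, threshold = 0.5) {
  y_test <- as.integer(y_test)
  if (length(unique(y_test)) < 2)
    stop("test labels must contain both classes", call. = FALSE)
  scores <- predict_scores(model, X_test)
  pred <- predict_labels(model, X_test, threshold)
  m0 <- prf(pred, y_test, 0L)
  m1 <- prf(pred, y_test, 1L)
  c(auroc = auroc(scores, y_test),
    accuracy = mean(pred == y_test),
    balanced_accuracy = (m0[["recall"]] + m1[["recall"]]) / 2,
    precision_0 = m0[["precision"]], precision_1 = m1[["precision"]],
    recall_0 = m0[["recall"]], recall_1 = m1[["recall"]],
    f1_0 = m0[["f1"]], f1_1 = m1[["f1"]])
}
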