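test_that("stratified folds balance classes and reproduce with the seed", {
  y <- rep(c(0, 1), each = 10)
  plan <- make_outer_folds(y, k = 5, seed = 4)
  expect_identical(sort(unlist(plan$folds)), 1:20)
  for (f in plan$folds) {
    expect_identical(length(f), 4L)
    expect_identical(sum(y[f] == 1), 2L)
  }
  expect_identical(make_outer_folds(y, 5, 4)$folds, plan$folds)
  expect_false(identical(make_outer_folds(y, 5, 5)$folds, plan$folds))
  expect_error(make_outer_folds(c(0, 0, 1, 1), k = 5), "at least k")

  # 217 participants, 109/108: fold sizes 43-44, class balance within 1
  y217 <- c(rep(1, 109), rep(0, 108))
  p <- make_outer_folds(y217, 5, seed = 1)
  sizes <- sort(vapply(p$folds, length, integer(1)))
  expect_identical(sizes, c(43L, 43L, 43L, 44L, 44L))
  for (f in p$folds) {
    expect_true(sum(y217[f] == 1) %in% 21:22)
    expect_true(sum(y217[f] == 0) %in% 21:22)
  }
})

test_that("preprocessor scales by train range, imputes train means, never clips", {
  train <- data.frame(a = c(0, 10, 5, NA), b = c(2, 2, 2, 2), c = 1:4)
  pp <- fit_preprocessor(train)
  tr <- apply_preprocessor(pp, train)
  expect_equal(range(tr[, "a"]), c(0, 1))
  expect_equal(unname(tr[, "b"]), rep(0, 4))            # constant -> 0
  expect_equal(unname(tr[4, "a"]), 0.5)                 # imputed at train mean
  test <- data.frame(a = c(15, NA), b = c(7, 2), c = c(0, 5))
  te <- apply_preprocessor(pp, test)
  expect_equal(unname(te[1, "a"]), 1.5)                 # outside [0,1], no clip
  expect_equal(unname(te[2, "a"]), 0.5)
  expect_error(fit_preprocessor(data.frame(a = c(NA_real_, NA_real_), b = 1:2)),
               "no non-missing.*a")
})

test_that("AUROC equals the concordant-pair oracle on fuzzed scores", {
  set.seed(12)
  for (r in 1:200) {
    n <- sample(4:100, 1)
    y <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # many ties
    expect_equal(auroc(scores, y), oracle_auroc(scores, y),
                 info = paste("rep", r))
  }
  expect_equal(auroc(rep(0.5, 10), rep(c(0, 1), 5)), 0.5)
  expect_error(auroc(1:4, c(1, 1, 1, 1)), "both classes")
})

test_that("Boruta confirms a planted signal and rejects noise", {
  set.seed(5)
  n <- 150
  y <- rep(0:1, each = n / 2)
  X <- cbind(signal = y + rnorm(n, 0, 0.4),
             matrix(rnorm(n * 5), n, 5,
                    dimnames = list(NULL, paste0("noise", 1:5))))
  res <- boruta_select(X, y, max_iter = 40, num_trees = 60, seed = 2)
  expect_true("signal" %in% res$confirmed)
  expect_false("signal" %in% res$rejected)
  expect_gte(length(res$rejected), 3)
  expect_identical(sort(c(res$confirmed, res$tentative, res$rejected)),
                   sort(colnames(X)))
  # deterministic given the seed
  res2 <- boruta_select(X, y, max_iter = 40, num_trees = 60, seed = 2)
  expect_identical(res$hits, res2$hits)
  expect_error(boruta_select(X, rep(1, n)), "both classes")
  expect_error(boruta_select(X[, 1, drop = FALSE], y), "at least 2")
})

test_that("a permuted shadow column keeps its marginal distribution", {
  x <- rnorm(50)
  shadow <- withr::with_seed(1, sample(x))
  expect_identical(sort(shadow), sort(x))
  expect_false(identical(shadow, x))
})

test_that("grid tuning picks by inner AUROC and a 1-point grid is a direct fit", {
  set.seed(3)
  n <- 80
  y <- rep(0:1, each = n / 2)
  X <- cbind(f1 = y + rnorm(n, 0, 0.3), f2 = rnorm(n))
  one <- model_spec("elasticnet_logreg",
                    grid = data.frame(lambda = 0.01, alpha = 0.5))
  m1 <- tune_and_train(one, X, y, seed = 1)
  direct <- glmnet::glmnet(digiphen:::pad_single_col(X),
                           factor(y, levels = c(0, 1)), family = "binomial",
                           alpha = 0.5,
                           lambda = sort(unique(0.01 * c(100, 10, 1)),
                                         decreasing = TRUE),
                           standardize = FALSE)
  expect_equal(predict_scores(m1, X),
               as.numeric(predict(direct, newx = X, type = "response",
                                  s = 0.01)))

  # linearly separable data: training AUROC 1 for the logistic model
  Xs <- cbind(f1 = c(rep(0, 20), rep(1, 20)), f2 = rnorm(40))
  ys <- rep(0:1, each = 20)
  ms <- tune_and_train(model_spec("elasticnet_logreg", tuning_folds = 4),
                       Xs, ys, seed = 2)
  expect_equal(auroc(predict_scores(ms, Xs), ys), 1)

  rf <- tune_and_train(model_spec("random_forest",
                                  grid = data.frame(num_trees = 50,
                                                    max_depth = 3,
                                                    min_node_size = 1)),
                       X, y, seed = 3)
  expect_gt(auroc(predict_scores(rf, X), y), 0.9)
  expect_error(model_spec("random_forest", grid = data.frame()), "non-empty")
})

test_that("evaluation metrics: perfect scores, dummy AUROC, zero-division", {
  X <- matrix(rnorm(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  y <- rep(0:1, each = 10)
  dm <- tune_and_train(model_spec("dummy"), X, y, seed = 9)
  met <- evaluate_model(dm, X, y)
  expect_equal(unname(met["auroc"]), 0.5)
  expect_true(all(met >= 0 & met <= 1))

  # perfect separation -> all metrics 1
  Xs <- cbind(a = c(rep(0, 10), rep(10, 10)), b = 0)
  ms <- tune_and_train(model_spec("elasticnet_logreg",
                                  grid = data.frame(lambda = 0.001, alpha = 0.5)),
                       Xs, y, seed = 1)
  mp <- evaluate_model(ms, Xs, y)
  expect_equal(unname(mp[c("auroc", "accuracy", "f1_0", "f1_1", "precision_0",
                           "precision_1", "recall_0", "recall_1")]),
               rep(1, 8))

  # degenerate predictions: all class 0 -> precision_1 = recall_1 = f1_1 = 0
  met0 <- digiphen:::prf(rep(0L, 20), y, 1L)
  expect_equal(unname(met0), c(0, 0, 0))
  expect_error(evaluate_model(dm, X, rep(1, 20)), "both classes")
})

test_that("the experiment produces 45 rows, exact medians, and is reproducible", {
  an <- fake_analysis(n = 60, effect = 20, seed = 1)
  cfg <- experiment_config(tuning_folds = 4, boruta_max_iter = 20,
                           boruta_num_trees = 40,
                           grids = list(random_forest =
                                          data.frame(num_trees = 60,
                                                     max_depth = 3,
                                                     min_node_size = 1)),
                           seed = 11)
  rep1 <- run_experiment(an, cfg)
  expect_identical(nrow(rep1$metrics), 45L)
  expect_identical(length(rep1$fold_models), 5L)

  # median aggregation is the middle order statistic of the 5 fold values
  sub <- rep1$metrics[rep1$metrics$feature_set == "digital_phenotyping" &
                        rep1$metrics$family == "elasticnet_logreg", ]
  agg <- rep1$aggregates[rep1$aggregates$feature_set == "digital_phenotyping" &
                           rep1$aggregates$family == "elasticnet_logreg" &
                           rep1$aggregates$metric == "auroc", ]
  expect_equal(agg$median, sort(sub$auroc)[3])
  expect_equal(agg$min, min(sub$auroc))
  expect_equal(agg$max, max(sub$auroc))

  # dummy rows are 0.5 in every fold and feature set
  expect_true(all(rep1$metrics$auroc[rep1$metrics$family == "dummy"] == 0.5))

  rep2 <- run_experiment(an, cfg)
  expect_equal(rep1$metrics, rep2$metrics)
  expect_identical(rep1$selected_features, rep2$selected_features)
})

test_that("fixed digital mode uses exactly the named feature", {
  an <- fake_analysis(n = 50, effect = 15, seed = 2)
  cfg <- experiment_config(feature_sets = c("digital_phenotyping", "combined"),
                           families = "elasticnet_logreg",
                           digital_mode = "fixed", tuning_folds = 4, seed = 3)
  rep <- run_experiment(an, cfg)
  expect_true(all(vapply(rep$selected_features, identical,
                         logical(1), "n_trajectories_total")))
  dig <- rep$fold_models[[1]]$digital_phenotyping$elasticnet_logreg
  expect_identical(dig$features, "n_trajectories_total")
  comb <- rep$fold_models[[1]]$combined$elasticnet_logreg
  expect_identical(comb$features, c("age", "sex", "years_education",
                                    "n_trajectories_total"))
})

test_that("no training artifact depends on held-out test labels (leakage canary)", {
  an <- fake_analysis(n = 50, effect = 15, seed = 4)
  y <- an$labels
  plan <- make_outer_folds(y, 5, seed = 6)
  cfg <- experiment_config(families = "elasticnet_logreg",
                           feature_sets = "digital_phenotyping",
                           tuning_folds = 4, boruta_max_iter = 15,
                           boruta_num_trees = 30, seed = 6)
  r1 <- run_experiment(an, cfg, plan = plan)

  an2 <- an
  an2$labels[plan$folds[[1]]] <- 1L - an2$labels[plan$folds[[1]]]
  r2 <- run_experiment(an2, cfg, plan = plan)

  expect_identical(r1$selected_features[[1]], r2$selected_features[[1]])
  m1 <- r1$fold_models[[1]]$digital_phenotyping$elasticnet_logreg
  m2 <- r2$fold_models[[1]]$digital_phenotyping$elasticnet_logreg
  expect_equal(as.matrix(coef(m1$fit, s = m1$fit$.dp_lambda)),
               as.matrix(coef(m2$fit, s = m2$fit$.dp_lambda)))
  # while test-side metrics do change
  expect_false(isTRUE(all.equal(r1$metrics$auroc, r2$metrics$auroc)))
})
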