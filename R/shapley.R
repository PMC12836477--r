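shapley_weights <- function(p) {
  # weight of a coalition of size s (excluding the player): s!(p-s-1)!/p!
  s <- 0:(p - 1)
  exp(lgamma(s + 1) + lgamma(p - s) - lgamma(p + 1))
}

#' Exact Shapley values by coalition enumeration
#'
#' Attributes a model prediction for one instance to its features. The
#' value of a coalition S is the marginal (interventional) expectation:
#' the mean prediction over the background set with the features in S
#' fixed to the instance's values. All 2^p coalitions are enumerated, so
#' the efficiency, symmetry and null-feature axioms hold to numerical
#' precision; the base value is the mean prediction over the background
#' set.
#'
#' @param predict_fun function taking a numeric matrix (rows = instances,
#'   columns = the features of `instance`) and returning numeric scores.
#' @param background matrix/data frame of background instances (typically
#'   the training fold of the explained model).
#' @param instance numeric vector (one instance, in background column
#'   order).
#' @return list with `values` (named attribution vector) and
#'   `base_value`.
#' @export
exact_shapley <- function(predict_fun, background, instance) {
  background <- as.matrix(background)
  p <- length(instance)
  stopifnot(p == ncol(background))
  if (p > 15)
    stop("exact enumeration is limited to 15 features; use sampling_shapley()",
         call. = FALSE)
  nb <- nrow(background)
  n_sets <- bitwShiftL(1L, p)

  # v(S): mean prediction with S-features taken from the instance. Masks
  # are stacked into large blocks so predict_fun is called a handful of
  # times instead of once per coalition.
  v <- numeric(n_sets)
  masks_per_chunk <- max(1L, min(n_sets, as.integer(2e6 / nb)))
  mask0 <- 0L
  while (mask0 < n_sets) {
    masks <- mask0:min(n_sets - 1L, mask0 + masks_per_chunk - 1L)
    M <- background[rep(seq_len(nb), times = length(masks)), , drop = FALSE]
    for (mi in seq_along(masks)) {
      rows <- (mi - 1L) * nb + seq_len(nb)
      for (i in seq_len(p))
        if (bitwAnd(masks[mi], bitwShiftL(1L, i - 1L)) != 0L)
          M[rows, i] <- instance[i]
    }
    preds <- predict_fun(M)
    v[masks + 1L] <- colMeans(matrix(preds, nrow = nb))
    mask0 <- mask0 + masks_per_chunk
  }

  w <- shapley_weights(p)
  sizes <- vapply(0:(n_sets - 1), function(m) sum(bitwAnd(m, bitwShiftL(1L, 0:(p - 1))) != 0L),
                  numeric(1))
  phi <- numeric(p)
  for (i in seq_len(p)) {
    bit <- bitwShiftL(1L, i - 1L)
    without <- which(bitwAnd(0:(n_sets - 1), bit) == 0L) - 1L
    phi[i] <- sum(w[sizes[without + 1] + 1] *
                    (v[without + bit + 1] - v[without + 1]))
  }
  names(phi) <- colnames(background)
  list(values = phi, base_value = v[1])
}

#' Monte-Carlo Shapley values by permutation sampling
#'
#' Seeded permutation-sampling estimator for models with more features
#' than exact enumeration can handle. Unbiased; the efficiency axiom
#' holds in expectation only.
#'
#' @inheritParams exact_shapley
#' @param n_perm number of sampled feature permutations.
#' @param seed integer seed.
#' @return list with `values` and `base_value`.
#' @export
sampling_shapley <- function(predict_fun, background, instance,
                             n_perm = 200, seed = 1) {
  background <- as.matrix(background)
  p <- length(instance)
  phi <- numeric(p)
  withr::with_seed(seed, {
    for (r in seq_len(n_perm)) {
      perm <- sample.int(p)
      M <- background
      prev <- mean(predict_fun(M))
      for (i in perm) {
        M[, i] <- instance[i]
        cur <- mean(predict_fun(M))
        phi[i] <- phi[i] + (cur - prev)
        prev <- cur
      }
    }
  })
  phi <- phi / n_perm
  names(phi) <- colnames(background)
  list(values = phi, base_value = mean(predict_fun(background)))
}

#' Shapley attribution matrix for a set of instances
#'
#' Explains the predicted probability of the symptomatic class for each
#' instance, using a background set (typically the training fold of the
#' model). Exact enumeration is used up to 15 features, permutation
#' sampling beyond.
#'
#' @param model a `dp_model`, or a prediction function over feature
#'   matrices.
#' @param background scaled feature matrix used as the background set.
#' @param instances scaled feature matrix of the instances to explain.
#' @param ... passed to [sampling_shapley()] when sampling is needed.
#' @return object of class `attribution_matrix`: list with `values`
#'   (instances x features), `base_value`, `feature_order` (features by
#'   descending mean absolute attribution), and `instances` (the feature
#'   values explained).
#' @export
explain_model <- function(model, background, instances, ...) {
  predict_fun <- if (inherits(model, "dp_model"))
    function(M) predict_scores(model, M) else model
  background <- as.matrix(background)
  instances <- as.matrix(instances)
  p <- ncol(background)
  one <- function(x) {
    if (p <= 15) exact_shapley(predict_fun, background, x)
    else sampling_shapley(predict_fun, background, x, ...)
  }
  res <- lapply(seq_len(nrow(instances)), function(r) one(instances[r, ]))
  values <- do.call(rbind, lapply(res, function(z) z$values))
  colnames(values) <- colnames(background)
  mean_abs <- colMeans(abs(values))
  ord <- order(-mean_abs, colnames(values))
  structure(list(values = values, base_value = res[[1]]$base_value,
                 feature_order = colnames(values)[ord],
                 instances = instances),
            class = "attribution_matrix")
}

#' Beeswarm-ready attribution export and importance ranking
#'
#' Produces the long-format records a beeswarm plot is drawn from, an
#' importance ranking by mean absolute attribution (ties broken by
#' feature name), and for each feature the sign of the Spearman rank
#' correlation between its values and its attributions - the "direction"
#' a beeswarm plot is read for.
#'
#' @param matrix an `attribution_matrix` from [explain_model()].
#' @param feature_values optional matrix of (scaled) feature values to
#'   export alongside the attributions; defaults to the instances stored
#'   in the matrix.
#' @return list with `beeswarm` (instance, feature, feature_value,
#'   shap_value), `importance` (feature, mean_abs_shap, rank) and
#'   `direction` (feature, rank_correlation, sign).
#' @export
attribution_summary <- function(matrix, feature_values = NULL) {
  stopifnot(inherits(matrix, "attribution_matrix"))
  V <- matrix$values
  if (is.null(feature_values)) feature_values <- matrix$instances
  feats <- colnames(V)
  n <- nrow(V)
  beeswarm <- data.frame(
    instance = rep(seq_len(n), times = length(feats)),
    feature = rep(feats, each = n),
    feature_value = as.vector(feature_values[, feats, drop = FALSE]),
    shap_value = as.vector(V), stringsAsFactors = FALSE)
  mean_abs <- colMeans(abs(V))
  ord <- order(-mean_abs, feats)
  importance <- data.frame(feature = feats[ord],
                           mean_abs_shap = unname(mean_abs[ord]),
                           rank = seq_along(feats), stringsAsFactors = FALSE)
  direction <- data.frame(feature = feats, rank_correlation = vapply(feats,
    function(f) {
      x <- feature_values[, f]; s <- V[, f]
      if (sd(x) == 0 || sd(s) == 0) return(NA_real_)
      suppressWarnings(cor(x, s, method = "spearman"))
    }, numeric(1)), stringsAsFactors = FALSE)
  direction$sign <- sign(direction$rank_correlation)
  rownames(direction) <- NULL
  list(beeswarm = beeswarm, importance = importance, direction = direction)
}
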