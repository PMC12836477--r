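#' Stratified k-fold split plan
#'
#' Partitions indices into k folds, stratified by the binary label:
#' within each class, indices are randomly permuted and fold sizes differ
#' by at most one, so per-fold class proportions stay within one
#' participant of the global proportions. Deterministic given the seed.
#'
#' @param labels 0/1 integer vector.
#' @param k number of folds (default 5).
#' @param seed integer seed.
#' @return object of class `split_plan`: list with `folds` (list of k
#'   disjoint index vectors), `k`, `seed`.
#' @export
make_outer_folds <- function(labels, k = 5, seed = 1) {
  labels <- as.integer(labels)
  for (cls in c(0L, 1L)) {
    if (sum(labels == cls) < k)
      stop(sprintf("class %d has %d members; need at least k = %d", cls,
                   sum(labels == cls), k), call. = FALSE)
  }
  folds <- withr::with_seed(seed, {
    assignment <- integer(length(labels))
    fold_tot <- integer(k)
    for (cls in c(0L, 1L)) {
      idx <- sample(which(labels == cls))
      n_c <- length(idx)
      counts <- rep(n_c %/% k, k)
      extra <- n_c %% k
      if (extra > 0) {
        # spill the remainder into the currently smallest folds so overall
        # fold sizes also stay within one of each other
        ord <- sample(seq_len(k))
        ord <- ord[order(fold_tot[ord])]
        counts[ord[seq_len(extra)]] <- counts[ord[seq_len(extra)]] + 1L
      }
      assignment[idx] <- rep(seq_len(k), counts)
      fold_tot <- fold_tot + counts
    }
    lapply(seq_len(k), function(f) which(assignment == f))
  })
  structure(list(folds = folds, k = k, seed = seed), class = "split_plan")
}

#' Fit a train-only preprocessor (mean imputation + min-max scaling)
#'
#' Computes per-feature training means (for imputing missing values in
#' both the training and the associated test set) and training min/max
#' (mapping the training range to `[0, 1]`). Test values outside the
#' training range are not clipped, so they may fall outside `[0, 1]`.
#' Constant features map to 0.
#'
#' @param train_features numeric data frame (participants x features).
#' @return object of class `preprocessor`.
#' @export
fit_preprocessor <- function(train_features) {
  stopifnot(is.data.frame(train_features) || is.matrix(train_features))
  X <- as.data.frame(train_features)
  all_missing <- vapply(X, function(v) all(is.na(v)), logical(1))
  if (any(all_missing))
    stop("feature(s) with no non-missing training value: ",
         paste(names(X)[all_missing], collapse = ", "), call. = FALSE)
  structure(list(
    mean = vapply(X, function(v) mean(v, na.rm = TRUE), numeric(1)),
    min = vapply(X, function(v) min(v, na.rm = TRUE), numeric(1)),
    max = vapply(X, function(v) max(v, na.rm = TRUE), numeric(1)),
    features = names(X)), class = "preprocessor")
}

#' Apply a fitted preprocessor
#'
#' @param pp a `preprocessor` from [fit_preprocessor()].
#' @param features data frame with (at least) the training features.
#' @return numeric matrix of imputed, min-max scaled features in training
#'   column order.
#' @export
apply_preprocessor <- function(pp, features) {
  stopifnot(inherits(pp, "preprocessor"))
  X <- as.data.frame(features)[, pp$features, drop = FALSE]
  out <- vapply(pp$features, function(f) {
    v <- X[[f]]
    v[is.na(v)] <- pp$mean[[f]]
    rng <- pp$max[[f]] - pp$min[[f]]
    if (rng == 0) rep(0, length(v)) else (v - pp$min[[f]]) / rng
  }, numeric(nrow(X)))
  if (nrow(X) == 1) out <- matrix(out, nrow = 1, dimnames = list(NULL, pp$features))
  colnames(out) <- pp$features
  out
}
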