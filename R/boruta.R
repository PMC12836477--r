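#' Boruta all-relevant feature selection
#'
#' Each iteration appends an independently permuted "shadow" copy of every
#' feature, fits a random forest on the augmented matrix, and records a
#' hit for every real feature whose importance exceeds the maximum shadow
#' importance. After `max_iter` iterations, features are confirmed or
#' rejected by two-sided binomial tests of their hit counts against
#' p = 0.5 with Bonferroni correction over features; everything else is
#' tentative (and treated as not selected downstream). Deterministic
#' given the seed.
#'
#' @param X numeric matrix or data frame (observations x features, >= 2
#'   features, no missing values).
#' @param y 0/1 labels; both classes must be present.
#' @param max_iter number of shadow iterations (default 100).
#' @param alpha familywise significance level (default 0.05).
#' @param num_trees trees per internal random forest (default 100).
#' @param importance ranger importance measure; the default "permutation"
#'   is the out-of-bag permutation importance the original algorithm is
#'   built on ("impurity" is faster and usually agrees).
#' @param seed integer seed.
#' @return object of class `boruta_result`: list with character vectors
#'   `confirmed`, `tentative`, `rejected`, the per-feature `hits`,
#'   `n_iter`, and adjusted p-values `p_adj`.
#' @export
boruta_select <- function(X, y, max_iter = 100, alpha = 0.05,
                          num_trees = 100, importance = "permutation",
                          seed = 1) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("Boruta needs at least 2 features", call. = FALSE)
  y <- as.integer(y)
  if (length(unique(y)) < 2)
    stop("y must contain both classes", call. = FALSE)
  p <- ncol(X)
  feat <- colnames(X)
  if (is.null(feat)) feat <- colnames(X) <- paste0("x", seq_len(p))

  hits <- setNames(integer(p), feat)
  withr::with_seed(seed, {
    rf_seeds <- sample.int(.Machine$integer.max, max_iter)
    for (it in seq_len(max_iter)) {
      shadow <- apply(X, 2, sample)
      colnames(shadow) <- paste0(".shadow_", feat)
      aug <- cbind(X, shadow)
      fit <- ranger::ranger(
        x = aug, y = factor(y, levels = c(0, 1)),
        num.trees = num_trees, importance = importance,
        seed = rf_seeds[it], num.threads = 1)
      imp <- fit$variable.importance
      thr <- max(imp[colnames(shadow)])
      hits <- hits + as.integer(imp[feat] > thr)
    }
  })

  # two-sided exact binomial test of hits against chance (p = 0.5)
  pval <- vapply(hits, function(h) {
    min(1, 2 * min(pbinom(h, max_iter, 0.5),
                   1 - pbinom(h - 1, max_iter, 0.5)))
  }, numeric(1))
  p_adj <- pmin(1, pval * p)
  confirmed <- feat[p_adj < alpha & hits > max_iter / 2]
  rejected <- feat[p_adj < alpha & hits < max_iter / 2]
  tentative <- setdiff(feat, c(confirmed, rejected))
  structure(list(confirmed = confirmed, tentative = tentative,
                 rejected = rejected, hits = hits, n_iter = max_iter,
                 p_adj = p_adj),
            class = "boruta_result")
}

#' @export
print.boruta_result <- function(x, ...) {
  cat("<boruta_result>", x$n_iter, "iterations\n")
  cat("  confirmed:", if (length(x$confirmed)) paste(x$confirmed, collapse = ", ") else "(none)", "\n")
  cat("  tentative:", length(x$tentative), " rejected:", length(x$rejected), "\n")
  invisible(x)
}
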