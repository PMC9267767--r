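#' Error-pattern feature matrix for variant classification
#'
#' Selects the three error-type percentages (not-a-verb, unrelated verb,
#' missing) as features and the diagnostic group as the label, dropping HC
#' rows. Accuracy is the linear complement of the three and is deliberately
#' excluded as redundant.
#'
#' @param profiles Subject profile tibble (see [subject_profiles()]).
#' @return List with `x` (tibble of features) and `y` (character labels).
#' @export
error_feature_matrix <- function(profiles) {
  pats <- filter(profiles, .data$group != "HC")
  list(
    x = select(pats, "pct_not_verb", "pct_unrelated_verb", "pct_missing"),
    y = pats$group
  )
}

vg_stratified_folds <- function(y, k) {
  folds <- integer(length(y))
  for (cl in unique(y)) {
    idx <- which(y == cl)
    idx <- idx[sample.int(length(idx))]
    folds[idx] <- rep_len(seq_len(k), length(idx))
  }
  folds
}

vg_cv_accuracy <- function(xmat, y, k) {
  folds <- vg_stratified_folds(y, k)
  vapply(seq_len(k), function(f) {
    test <- folds == f
    tree <- fit_tree(xmat[!test, , drop = FALSE], y[!test])
    mean(predict(tree, xmat[test, , drop = FALSE]) == y[test])
  }, numeric(1))
}

#' Stratified cross-validated classification accuracy
#'
#' Stratified k-fold cross-validation of the depth-2 decision tree: folds
#' preserve class proportions, the tree is refit on each training split, and
#' accuracy is averaged over held-out folds. When the smallest class has fewer
#' members than `k_folds`, k is reduced to that size with a warning.
#'
#' @param x Feature data frame/matrix.
#' @param y Class labels.
#' @param k_folds Number of folds (default 5).
#' @param seed Integer seed controlling the fold assignment; identical seeds
#'   give identical folds and scores.
#' @return List with `mean`, `sd`, `fold_scores`, `k_folds`.
#' @export
cross_validated_score <- function(x, y, k_folds = 5, seed) {
  y <- as.character(y)
  min_class <- min(table(y))
  if (min_class < k_folds) {
    warn(sprintf("smallest class has %d members; reducing k_folds to %d",
                 min_class, min_class))
    k_folds <- min_class
  }
  xmat <- as.matrix(x)
  scores <- withr::with_seed(seed, vg_cv_accuracy(xmat, y, k_folds))
  list(mean = mean(scores), sd = sd(scores), fold_scores = scores,
       k_folds = k_folds)
}

#' Permutation test of classification performance
#'
#' Estimates the chance level empirically: the cross-validated score is
#' recomputed for `n_perm` random relabelings of the subjects (the full CV
#' loop rerun each time, with freshly stratified folds), and the observed
#' score is referred to that null sample. The empirical p-value is
#' `(1 + #(null >= observed)) / (1 + n_perm)`, never exactly zero. The
#' theoretical chance level `1 / #classes` is reported alongside.
#'
#' @inheritParams cross_validated_score
#' @param n_perm Number of label permutations (default 1000; fewer than 100
#'   triggers an unstable-p warning).
#' @return A `vg_classification` object with `cv_mean`, `cv_sd`,
#'   `null_scores`, `p_empirical`, `chance_theoretical`, and the tree fitted
#'   on all data; has [tidy()], [glance()] and [autoplot()] methods.
#' @export
permutation_test <- function(x, y, n_perm = 1000, k_folds = 5, seed) {
  y <- as.character(y)
  if (n_perm < 100) {
    warn("n_perm < 100 gives an unstable empirical p-value")
  }
  min_class <- min(table(y))
  if (min_class < k_folds) {
    warn(sprintf("smallest class has %d members; reducing k_folds to %d",
                 min_class, min_class))
    k_folds <- min_class
  }
  xmat <- as.matrix(x)
  res <- withr::with_seed(seed, {
    obs <- vg_cv_accuracy(xmat, y, k_folds)
    null_scores <- vapply(seq_len(n_perm), function(b) {
      mean(vg_cv_accuracy(xmat, sample(y), k_folds))
    }, numeric(1))
    list(obs = obs, null = null_scores)
  })
  structure(
    list(
      cv_mean = mean(res$obs), cv_sd = sd(res$obs),
      fold_scores = res$obs, null_scores = res$null,
      p_empirical = (1 + sum(res$null >= mean(res$obs))) / (1 + n_perm),
      chance_theoretical = 1 / length(unique(y)),
      n_perm = n_perm, k_folds = k_folds, seed = seed,
      tree = fit_tree(xmat, y)
    ),
    class = "vg_classification"
  )
}

#' Classify patients into variants from their error patterns
#'
#' End-to-end wrapper: builds the error-pattern feature matrix from subject
#' profiles and runs [permutation_test()].
#'
#' @inheritParams permutation_test
#' @param profiles Subject profile tibble.
#' @return A `vg_classification` object.
#' @export
classify_variants <- function(profiles, n_perm = 1000, k_folds = 5, seed) {
  fm <- error_feature_matrix(profiles)
  permutation_test(fm$x, fm$y, n_perm = n_perm, k_folds = k_folds,
                   seed = seed)
}

#' @export
print.vg_classification <- function(x, ...) {
  cat(sprintf(
    paste0("Cross-validated score = %.2f +/- %.2f ",
           "(theoretical chance %.2f%%)\n"),
    x$cv_mean, x$cv_sd, 100 * x$chance_theoretical
  ))
  cat(sprintf("Permutation p = %.4g (%d permutations, %d-fold CV)\n",
              x$p_empirical, x$n_perm, x$k_folds))
  invisible(x)
}

#' @export
tidy.vg_classification <- function(x, ...) {
  tibble(fold = seq_along(x$fold_scores), accuracy = x$fold_scores)
}

#' @export
glance.vg_classification <- function(x, ...) {
  tibble(
    cv_mean = x$cv_mean, cv_sd = x$cv_sd,
    p_empirical = x$p_empirical,
    chance_theoretical = x$chance_theoretical,
    null_mean = mean(x$null_scores),
    null_q95 = unname(stats::quantile(x$null_scores, 0.95)),
    n_perm = x$n_perm, k_folds = x$k_folds
  )
}

#' Plot the permutation null against the observed score
#'
#' Density of the permutation score distribution with the observed
#' cross-validated score and the theoretical chance level marked.
#'
#' @param object A `vg_classification`.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.vg_classification <- function(object, ...) {
  df <- tibble(score = object$null_scores)
  ggplot2::ggplot(df, ggplot2::aes(x = .data$score)) +
    ggplot2::geom_density(fill = "tan", alpha = 0.6) +
    ggplot2::geom_vline(xintercept = object$cv_mean, colour = "darkorange",
                        linewidth = 1) +
    ggplot2::geom_vline(xintercept = object$chance_theoretical,
                        linetype = "dashed") +
    ggplot2::labs(
      x = "cross-validated accuracy",
      y = "density",
      title = sprintf("Observed %.2f vs permutation null (p = %.3g)",
                      object$cv_mean, object$p_empirical)
    ) +
    ggplot2::theme_minimal()
}
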