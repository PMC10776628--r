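# Subject-level probabilistic discrimination: min-max normalization fitted on
# training folds, inner-loop hyperparameter tuning, gradient-boosted trees,
# repeated stratified cross-validation.

#' Min-max normalization with training-set extrema
#'
#' `(x - min_train) / (max_train - min_train)`; a constant training feature
#' maps everything to 0; values outside the training range are not clipped.
#'
#' @param train Numeric training values (>= 2, may contain NA).
#' @param apply_to Values to rescale (defaults to `train`).
#' @return Normalized numeric vector.
#' @export
minmax_normalize <- function(train, apply_to = train) {
  train <- train[!is.na(train)]
  if (length(train) == 0L) abort_validation("minmax_normalize: empty training vector")
  rng <- range(train)
  if (rng[1] == rng[2]) return(rep(0, length(apply_to)))
  (apply_to - rng[1]) / (rng[2] - rng[1])
}

#' Stratified fold assignment
#'
#' Random partition into `k` folds preserving the proportion of labels per
#' fold (each class is shuffled and dealt round-robin), so fold class
#' proportions match the full sample within one subject.
#'
#' @param labels Binary labels (factor/character/logical).
#' @param k Number of folds.
#' @return Integer vector of fold ids in `1:k`.
#' @export
stratified_folds <- function(labels, k = 5) {
  fold <- integer(length(labels))
  for (cl in unique(labels)) {
    idx <- which(labels == cl)
    if (length(idx) < k) abort_validation("a class has fewer members than folds")
    fold[sample(idx)] <- rep_len(seq_len(k), length(idx))
  }
  fold
}

#' Area under the ROC curve from decision scores
#'
#' Rank-based (Mann-Whitney) AUC with average ranks for ties.
#'
#' @param scores Numeric decision scores.
#' @param labels Binary labels; `positive` marks the positive class.
#' @param positive Positive class label (default: the larger level).
#' @return AUC in `[0, 1]`.
#' @export
auc_score <- function(scores, labels, positive = NULL) {
  positive <- positive %||% sort(unique(labels))[length(unique(labels))]
  pos <- labels == positive
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0L || n0 == 0L) abort_validation("auc_score needs both classes present")
  r <- rank(scores)
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

# Columns other than nrounds are passed straight to xgboost, so the grid can
# tune any booster parameter. The default favors shallow, feature-subsampled
# trees: with a few dozen subjects and mostly-uninformative features, heavier
# trees latch onto noise columns.
default_tuning_grid <- function() {
  expand.grid(max_depth = c(1L, 2L), eta = 0.1, nrounds = 60L,
              colsample_bytree = c(0.5, 1), subsample = 0.8,
              KEEP.OUT.ATTRS = FALSE)
}

grid_params <- function(cfg) {
  as.list(cfg[setdiff(names(cfg), c("nrounds", "fold", "iteration"))])
}

# Fit one gradient-boosted tree model; single-threaded for reproducibility.
fit_gbm <- function(X, y, params, nrounds) {
  dtrain <- xgboost::xgb.DMatrix(X, label = y)
  xgboost::xgb.train(
    params = c(params, list(objective = "binary:logistic", nthread = 1, seed = 0)),
    data = dtrain, nrounds = nrounds, verbose = 0
  )
}

predict_gbm <- function(model, X) {
  as.numeric(stats::predict(model, xgboost::xgb.DMatrix(X)))
}

# Median-impute and min-max-normalize columns using training-fold statistics
# only (no leakage from the test fold).
fit_preprocessor <- function(X_train) {
  med <- apply(X_train, 2, median, na.rm = TRUE)
  med[is.na(med)] <- 0
  Xi <- X_train
  for (j in seq_len(ncol(Xi))) Xi[is.na(Xi[, j]), j] <- med[j]
  rng <- apply(Xi, 2, range)
  list(median = med, range = rng)
}

apply_preprocessor <- function(prep, X) {
  for (j in seq_len(ncol(X))) {
    X[is.na(X[, j]), j] <- prep$median[j]
    lo <- prep$range[1, j]; hi <- prep$range[2, j]
    X[, j] <- if (hi == lo) 0 else (X[, j] - lo) / (hi - lo)
  }
  X
}

# Inner-loop grid search: 3-fold stratified CV on the training rows,
# selecting the configuration with the best pooled inner AUC.
tune_gbm <- function(X, y, grid, inner_folds = 3L) {
  fold <- stratified_folds(y, inner_folds)
  scores <- vapply(seq_len(nrow(grid)), function(i) {
    cfg <- grid[i, ]
    preds <- numeric(length(y))
    for (f in seq_len(inner_folds)) {
      tr <- fold != f
      prep <- fit_preprocessor(X[tr, , drop = FALSE])
      m <- fit_gbm(apply_preprocessor(prep, X[tr, , drop = FALSE]), y[tr],
                   grid_params(cfg), cfg$nrounds)
      preds[!tr] <- predict_gbm(m, apply_preprocessor(prep, X[!tr, , drop = FALSE]))
    }
    auc_score(preds, y)
  }, numeric(1))
  grid[which.max(scores), ]
}

#' Repeated stratified cross-validated gradient-boosted classification
#'
#' Restricts the feature matrix to two groups and, for each of
#' `n_iterations` random stratified `n_folds` partitions: fits the missing
#' -value imputer and min-max normalizer on the training folds only, tunes
#' the boosting hyperparameters by an inner stratified 3-fold grid search on
#' the training folds, fits the model, and collects test-fold decision
#' scores. Each iteration's AUC is computed from the pooled out-of-fold
#' scores; the report aggregates the mean and SD over iterations.
#'
#' @param fm A `plt_feature_matrix` tibble.
#' @param pair Character vector of two group labels, e.g. `c("PD", "HC")`;
#'   the first is the positive class.
#' @param n_folds Number of outer folds (default 5).
#' @param n_iterations Number of random repartitions.
#' @param grid Hyperparameter grid (`max_depth`, `eta`, `nrounds` columns);
#'   default [default_tuning_grid()].
#' @param seed Integer seed fixing all randomness.
#' @param paper_mode If `TRUE`, the min-max normalizer is fitted once on the
#'   full sample before partitioning (for faithfulness comparisons; the
#'   default fits within training folds to avoid leakage).
#' @param tune If `FALSE`, skip the inner search and use the first grid row.
#' @return A `plt_classifier_report`: list with `pair`, `auc` (per-iteration
#'   vector), `auc_mean`, `auc_sd`, `scores` (per-subject mean decision
#'   score tibble), `chosen` (per iteration x fold hyperparameters), `seed`.
#' @export
crossval_classify <- function(fm, pair, n_folds = 5, n_iterations = 1000,
                              grid = default_tuning_grid(), seed = 1,
                              paper_mode = FALSE, tune = TRUE) {
  stopifnot(length(pair) == 2L)
  sub <- fm[fm$group %in% pair, , drop = FALSE]
  y <- as.integer(sub$group == pair[1])
  if (min(table(y)) < n_folds) abort_validation("both classes need >= n_folds members")
  X0 <- as.matrix(sub[, feature_names()])

  if (paper_mode) {
    prep_full <- fit_preprocessor(X0)
    X0 <- apply_preprocessor(prep_full, X0)
  }

  score_sum <- numeric(length(y))
  aucs <- numeric(n_iterations)
  chosen <- vector("list", n_iterations)
  for (it in seq_len(n_iterations)) {
    set.seed(derive_seed(seed, paste0("cv-iteration-", it)))
    fold <- stratified_folds(y, n_folds)
    preds <- numeric(length(y))
    cfgs <- vector("list", n_folds)
    for (f in seq_len(n_folds)) {
      tr <- fold != f
      Xtr <- X0[tr, , drop = FALSE]; Xte <- X0[!tr, , drop = FALSE]
      if (!paper_mode) {
        prep <- fit_preprocessor(Xtr)
        Xtr <- apply_preprocessor(prep, Xtr)
        Xte <- apply_preprocessor(prep, Xte)
      }
      cfg <- if (tune && nrow(grid) > 1L) tune_gbm(Xtr, y[tr], grid) else grid[1, ]
      m <- fit_gbm(Xtr, y[tr], grid_params(cfg), cfg$nrounds)
      preds[!tr] <- predict_gbm(m, Xte)
      cfgs[[f]] <- cfg
    }
    aucs[it] <- auc_score(preds, y, positive = 1L)
    score_sum <- score_sum + preds
    chosen[[it]] <- dplyr::bind_rows(cfgs, .id = "fold")
  }
  structure(list(
    pair = paste(pair, collapse = "-vs-"),
    auc = aucs, auc_mean = mean(aucs), auc_sd = sd(aucs),
    scores = tibble::tibble(participant_id = sub$participant_id,
                            group = sub$group, label = y,
                            mean_score = score_sum / n_iterations),
    chosen = dplyr::bind_rows(chosen, .id = "iteration"),
    seed = seed, n_folds = n_folds, n_iterations = n_iterations,
    paper_mode = paper_mode
  ), class = "plt_classifier_report")
}

#' @export
print.plt_classifier_report <- function(x, ...) {
  cat(sprintf("<plt_classifier_report> %s: AUC %.3f +/- %.3f over %d iterations\n",
              x$pair, x$auc_mean, x$auc_sd, x$n_iterations))
  invisible(x)
}
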