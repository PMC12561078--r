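# Ensemble-rank majority-voting feature selection.
#
# Five importance-producing models are fit on the standardized per-subject
# metadata matrix; per model, importances are converted to ranks (1 = most
# important), each feature's vote is the weighted harmonic-rank sum
# v_f = sum_m w_m / r_{m,f}, votes are normalized to confidence scores
# s_f = v_f / sum v, and the top-k features by score are selected.

FS_DEFAULT_MODELS <- c("random_forest", "extra_trees", "gradient_boosting",
                       "adaboost", "ridge_logistic")

#' Fit the importance-model ensemble
#'
#' Fits each configured model on subject-level metadata (one row per subject,
#' never per slice) and extracts a non-negative importance per feature.
#' Models: `random_forest` (randomForest, mean Gini decrease), `extra_trees`
#' (ranger with the extratrees split rule, impurity importance),
#' `gradient_boosting` (xgboost gain), `adaboost` (SAMME over depth-1 rpart
#' stumps, implemented in-package, alpha-weighted split improvements), and
#' `ridge_logistic` (glmnet multinomial ridge, mean |coefficient| across
#' classes). Hyperparameters are fixed defaults recorded in the result.
#'
#' @param X standardized numeric matrix, rows = subjects, named columns.
#' @param y class labels (factor or character), >= 2 classes present.
#' @param seed integer seed; the fit is deterministic given it.
#' @param models character vector of model names (default all five).
#' @return `importance_matrix`: list with `importances`
#'   (`n_models x n_features` matrix), `models`, `feature_names`, `settings`.
#' @export
fit_importances <- function(X, y, seed = 1, models = FS_DEFAULT_MODELS) {
  X <- as.matrix(X)
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2)
    nn_stop("selection_error", "need >= 2 classes to fit importance models")
  y <- droplevels(y)
  if (is.null(colnames(X)))
    colnames(X) <- paste0("f", seq_len(ncol(X)))
  feats <- colnames(X)
  # model formulas need syntactic names; keep a lookup to the clinical names
  Xs <- X
  colnames(Xs) <- sprintf("V%d", seq_len(ncol(X)))
  imp <- matrix(0, nrow = length(models), ncol = length(feats),
                dimnames = list(models, feats))
  set.seed(seed)
  for (m in models) {
    v <- switch(m,
      random_forest = imp_random_forest(Xs, y),
      extra_trees = imp_extra_trees(Xs, y, seed),
      gradient_boosting = imp_xgboost(Xs, y),
      adaboost = imp_adaboost(Xs, y),
      ridge_logistic = imp_ridge(Xs, y),
      nn_stop("selection_error", "unknown importance model '%s'", m))
    vv <- setNames(numeric(ncol(Xs)), colnames(Xs))
    vv[names(v)] <- v
    imp[m, ] <- pmax(vv, 0)
  }
  structure(list(importances = imp, models = models, feature_names = feats,
                 settings = fs_default_settings()),
            class = "importance_matrix")
}

fs_default_settings <- function() {
  list(random_forest = list(ntree = 300),
       extra_trees = list(num.trees = 300, num.random.splits = 1),
       gradient_boosting = list(nrounds = 50, max_depth = 3, eta = 0.3),
       adaboost = list(n_rounds = 50, stump_depth = 1),
       ridge_logistic = list(alpha = 0, lambda = 0.05))
}

imp_random_forest <- function(X, y) {
  fit <- randomForest::randomForest(X, y, ntree = 300, importance = FALSE)
  v <- fit$importance[, "MeanDecreaseGini"]
  setNames(as.numeric(v), rownames(fit$importance))
}

imp_extra_trees <- function(X, y, seed) {
  df <- data.frame(X, .y = y)
  fit <- ranger::ranger(dependent.variable.name = ".y", data = df,
                        num.trees = 300, splitrule = "extratrees",
                        num.random.splits = 1, importance = "impurity",
                        num.threads = 1, seed = seed)
  fit$variable.importance
}

imp_xgboost <- function(X, y) {
  dm <- xgboost::xgb.DMatrix(X, label = as.integer(y) - 1L, nthread = 1)
  fit <- xgboost::xgb.train(params = list(objective = "multi:softprob",
                                          num_class = nlevels(y),
                                          max_depth = 3, eta = 0.3,
                                          nthread = 1),
                            data = dm, nrounds = 50, verbose = 0)
  it <- xgboost::xgb.importance(model = fit)
  setNames(it$Gain, it$Feature)
}

imp_ridge <- function(X, y) {
  fit <- glmnet::glmnet(X, y, family = "multinomial", alpha = 0,
                        lambda = 0.05, standardize = FALSE)
  co <- glmnet::coef.glmnet(fit)
  mats <- lapply(co, function(m) abs(as.numeric(m)[-1]))  # drop intercept
  setNames(Reduce(`+`, mats) / length(mats), colnames(X))
}

# SAMME AdaBoost over depth-1 rpart stumps. Importance of a feature is the
# sum over boosting rounds of alpha_m times the stump's split improvement
# when the stump splits on that feature.
imp_adaboost <- function(X, y, n_rounds = 50) {
  n <- nrow(X)
  K <- nlevels(y)
  w <- rep(1 / n, n)
  imp <- setNames(numeric(ncol(X)), colnames(X))
  df <- data.frame(X, .y = y)
  for (m in seq_len(n_rounds)) {
    fit <- rpart::rpart(.y ~ ., data = df, weights = w,
                        method = "class",
                        control = rpart::rpart.control(maxdepth = 1, cp = 0,
                                                       minsplit = 2,
                                                       minbucket = 1,
                                                       xval = 0))
    pred <- predict(fit, df, type = "class")
    err <- sum(w * (pred != y)) / sum(w)
    if (err >= 1 - 1 / K || is.na(err)) break
    err <- max(err, 1e-10)
    alpha <- log((1 - err) / err) + log(K - 1)
    vi <- fit$variable.importance
    if (!is.null(vi)) {
      vi <- vi[names(vi) %in% names(imp)]
      if (length(vi)) imp[names(vi)] <- imp[names(vi)] + alpha * vi
    }
    w <- w * exp(alpha * (pred != y))
    w <- w / sum(w)
    if (err <= 1e-10) break
  }
  imp
}

#' Convert importances to per-model ranks
#'
#' Per model row, descending importance maps to ascending rank starting at 1.
#' Ties keep the stable input order of the feature list (documented tie
#' rule), so every row is a permutation of `1..n_features`.
#'
#' @param importances an `importance_matrix` or a plain numeric matrix
#'   (models x features).
#' @return integer rank matrix of the same shape.
#' @export
rank_features <- function(importances) {
  m <- if (inherits(importances, "importance_matrix"))
    importances$importances else as.matrix(importances)
  if (anyNA(m))
    nn_stop("selection_error", "importances contain NA")
  ranks <- t(apply(m, 1, function(row) {
    ord <- order(-row)           # stable: ties keep input order
    r <- integer(length(row))
    r[ord] <- seq_along(row)
    r
  }))
  dimnames(ranks) <- dimnames(m)
  storage.mode(ranks) <- "integer"
  ranks
}

#' Harmonic-rank voting and top-k selection
#'
#' Computes `v_f = sum_m w_m / r_{m,f}`, normalizes to confidence scores
#' `s_f = v_f / sum(v)` (which always sum to 1), and selects the `k` features
#' with the largest scores. Score ties break by larger vote, then input
#' order.
#'
#' @param ranks rank matrix from [rank_features()].
#' @param model_weights per-model non-negative weights (default all 1);
#'   rescaling all weights by a positive constant leaves scores unchanged.
#' @param k number of features to keep (default 5).
#' @return `feature_ranking`: list with `ranks`, `model_weights`, `votes`,
#'   `scores`, `selected` (ordered top-k feature names), `k`.
#' @export
vote_and_score <- function(ranks, model_weights = NULL, k = 5) {
  ranks <- as.matrix(ranks)
  nf <- ncol(ranks)
  w <- model_weights %||% rep(1, nrow(ranks))
  if (length(w) != nrow(ranks) || any(w < 0) || sum(w) == 0)
    nn_stop("selection_error",
            "model_weights must be non-negative, not all zero, one per model")
  if (k < 1 || k > nf)
    nn_stop("selection_error", "k must lie in 1..%d", nf)
  votes <- as.numeric(w %*% (1 / ranks))
  names(votes) <- colnames(ranks)
  scores <- votes / sum(votes)
  ord <- order(-scores, -votes, seq_len(nf))
  sel <- colnames(ranks)[ord[seq_len(k)]]
  structure(list(ranks = ranks, model_weights = w, votes = votes,
                 scores = scores, selected = sel, k = as.integer(k)),
            class = "feature_ranking")
}

#' End-to-end feature selection on a cohort
#'
#' Standardizes the per-subject metadata (population sd), fits the model
#' ensemble, ranks, votes and selects the top-k features.
#'
#' @param cohort list of subject records.
#' @param k number of features to keep.
#' @param seed integer seed.
#' @param models importance models to use.
#' @return a `feature_ranking` with the fitted `importance_matrix` attached
#'   as `$importances`.
#' @export
select_features <- function(cohort, k = 5, seed = 1,
                            models = FS_DEFAULT_MODELS) {
  md <- cohort_metadata(cohort)
  X <- as.matrix(md[, METADATA_FIELDS])
  y <- md$label
  Xs <- apply_standardizer(X, fit_standardizer(X))
  im <- fit_importances(Xs, y, seed = seed, models = models)
  fr <- vote_and_score(rank_features(im), k = k)
  fr$importances <- im
  fr
}

#' Write a feature ranking to JSON
#'
#' @param ranking a `feature_ranking`.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_feature_ranking <- function(ranking, path) {
  out <- list(feature_names = colnames(ranking$ranks),
              ranks = ranking$ranks,
              model_weights = ranking$model_weights,
              votes = ranking$votes,
              scores = ranking$scores,
              selected = ranking$selected,
              k = ranking$k)
  if (!is.null(ranking$importances)) {
    out$importances <- ranking$importances$importances
    out$model_settings <- ranking$importances$settings
  }
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       matrix = "rowmajor")
  invisible(path)
}
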