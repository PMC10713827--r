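#' Binary treated/control labels for wells
#'
#' Vehicle wells are `control`; any compound at any tested dose (0.01-2 uM)
#' is `treated`.
#'
#' @param table well feature table with `compound` and `dose_uM`.
#' @return factor with levels `control`, `treated`.
#' @export
label_wells <- function(table) {
  if (any(is.na(table$compound))) stop("unknown condition: NA compound")
  y <- ifelse(table$compound == "vehicle" | table$dose_uM == 0, "control", "treated")
  factor(y, levels = c("control", "treated"))
}

#' Stratified train/test split of well rows
#'
#' Draws `test_fraction` of each class (rounded, at least 1 well) into the
#' test set; the split is over well rows and deterministic under the seed.
#'
#' @param table well feature table.
#' @param test_fraction fraction held out (default 0.10).
#' @param seed integer seed.
#' @return list with `train` and `test` data.frames (disjoint, union = all).
#' @export
split_train_test <- function(table, test_fraction = 0.10, seed = 1L) {
  y <- label_wells(table)
  if (any(table(y) < 2)) stop("both classes need at least 2 wells")
  set.seed(seed)
  test_idx <- integer(0)
  for (cl in levels(y)) {
    idx <- which(y == cl)
    n_test <- max(1L, round(length(idx) * test_fraction))
    test_idx <- c(test_idx, sample(idx, n_test))
  }
  list(train = table[-test_idx, , drop = FALSE],
       test = table[sort(test_idx), , drop = FALSE])
}

# stratified fold assignment, balancing overall fold sizes
stratified_folds <- function(y, k, seed) {
  set.seed(seed)
  fold <- integer(length(y))
  sizes <- integer(k)
  for (cl in levels(factor(y))) {
    idx <- sample(which(y == cl))
    for (i in seq_along(idx)) {
      f <- order(sizes)[1]          # fold with fewest members so far
      fold[idx[i]] <- f
      sizes[f] <- sizes[f] + 1L
    }
  }
  fold
}

# feature matrix with NA imputed by (train) column medians
feature_matrix <- function(table, impute_from = NULL) {
  X <- as.matrix(table[, feature_cols(table), drop = FALSE])
  src <- if (is.null(impute_from)) X else
    as.matrix(impute_from[, colnames(X), drop = FALSE])
  for (j in seq_len(ncol(X))) {
    if (anyNA(X[, j])) {
      med <- stats::median(src[, j], na.rm = TRUE)
      X[is.na(X[, j]), j] <- if (is.finite(med)) med else 0
    }
  }
  X
}

#' Default hyperparameter grids
#'
#' Linear discriminant: moment vs. maximum-likelihood covariance estimates.
#' Boosted trees: number of rounds, learning rate, and either tree depth
#' (level-wise growth) or leaf count (leaf-wise growth).
#'
#' @param kind `"lda"`, `"boost_depth"` (level-wise trees) or
#'   `"boost_leaf"` (leaf-wise trees).
#' @return data.frame, one row per grid point.
#' @export
default_grid <- function(kind) {
  switch(kind,
    lda = data.frame(method = c("moment", "mle"), stringsAsFactors = FALSE),
    boost_depth = expand.grid(nrounds = c(100, 300), eta = c(0.05, 0.1),
                              max_depth = c(3, 6)),
    boost_leaf = expand.grid(nrounds = c(100, 300), eta = c(0.05, 0.1),
                             max_leaves = c(15, 31)),
    stop("unknown classifier kind: ", kind))
}

# fit one classifier on a feature matrix; returns an edc_model
fit_one <- function(kind, X, y, params, seed = 1L) {
  keep <- which(apply(X, 2, stats::sd) > 1e-10)
  Xk <- X[, keep, drop = FALSE]
  model <- if (kind == "lda") {
    suppressWarnings(MASS::lda(Xk, grouping = y, method = params$method))
  } else {
    set.seed(seed)
    xp <- list(objective = "binary:logistic", nthread = 1,
               eta = params$eta, seed = seed)
    if (kind == "boost_depth") {
      xp$max_depth <- params$max_depth
    } else {
      xp$grow_policy <- "lossguide"
      xp$max_depth <- 0
      xp$max_leaves <- params$max_leaves
      xp$tree_method <- "hist"
    }
    dtr <- xgboost::xgb.DMatrix(Xk, label = as.numeric(y == "treated"))
    xgboost::xgb.train(params = xp, data = dtr, nrounds = params$nrounds,
                       verbose = 0)
  }
  structure(list(kind = kind, fit = model, params = params,
                 features = colnames(X), kept = keep,
                 feature_sd = apply(Xk, 2, stats::sd)),
            class = "edc_model")
}

# class predictions and control-class probabilities
predict_model <- function(model, X) {
  Xk <- X[, model$kept, drop = FALSE]
  if (model$kind == "lda") {
    pr <- stats::predict(model$fit, Xk)
    list(class = factor(as.character(pr$class), levels = c("control", "treated")),
         prob_control = pr$posterior[, "control"])
  } else {
    p_treated <- stats::predict(model$fit, xgboost::xgb.DMatrix(Xk))
    cls <- ifelse(p_treated > 0.5, "treated", "control")
    list(class = factor(cls, levels = c("control", "treated")),
         prob_control = 1 - p_treated)
  }
}

#' Grid-search hyperparameters and train the final model
#'
#' Exhaustive search over the grid, scored by stratified `cv_folds`-fold CV
#' accuracy on the training set; the best grid point (first maximum) is
#' refit on the full training set.
#'
#' @param kind classifier kind (see [default_grid()]).
#' @param X training feature matrix.
#' @param y training labels (factor control/treated).
#' @param grid hyperparameter grid (data.frame; default [default_grid()]).
#' @param cv_folds folds for the grid search (default 5).
#' @param seed integer seed.
#' @return list: `model` (fitted on full train), `best_params`,
#'   `grid_scores` (grid with a `cv_accuracy` column).
#' @export
tune_and_train <- function(kind, X, y, grid = default_grid(kind),
                           cv_folds = 5L, seed = 1L) {
  if (!nrow(grid)) stop("empty hyperparameter grid")
  if (nlevels(droplevels(y)) < 2) stop("training data must contain both classes")
  fold <- stratified_folds(y, cv_folds, seed)
  scores <- numeric(nrow(grid))
  for (g in seq_len(nrow(grid))) {
    acc <- numeric(cv_folds)
    for (f in seq_len(cv_folds)) {
      tr <- fold != f
      if (nlevels(droplevels(y[tr])) < 2 || !any(!tr)) { acc[f] <- NA; next }
      m <- fit_one(kind, X[tr, , drop = FALSE], y[tr], grid[g, , drop = FALSE], seed)
      pr <- predict_model(m, X[!tr, , drop = FALSE])
      acc[f] <- mean(pr$class == y[!tr])
    }
    scores[g] <- mean(acc, na.rm = TRUE)
  }
  best <- which.max(scores)
  model <- fit_one(kind, X, y, grid[best, , drop = FALSE], seed)
  grid$cv_accuracy <- scores
  list(model = model, best_params = grid[best, setdiff(names(grid), "cv_accuracy"),
                                         drop = FALSE],
       grid_scores = grid)
}

#' k-fold cross-validated accuracies
#'
#' Stratified k-fold CV of one classifier kind at fixed hyperparameters;
#' returns the per-fold accuracies with min/median/max.
#'
#' @param kind classifier kind.
#' @param X feature matrix.
#' @param y labels.
#' @param k folds (default 10).
#' @param params hyperparameters (default: first row of the default grid).
#' @param seed integer seed.
#' @return list: `accuracies` (length k), `min`, `median`, `max`.
#' @export
cross_validate <- function(kind, X, y, k = 10L,
                           params = default_grid(kind)[1, , drop = FALSE],
                           seed = 1L) {
  if (k > length(y)) stop("k exceeds the number of rows")
  fold <- stratified_folds(y, k, seed)
  acc <- numeric(k)
  for (f in seq_len(k)) {
    tr <- fold != f
    m <- fit_one(kind, X[tr, , drop = FALSE], y[tr], params, seed)
    pr <- predict_model(m, X[!tr, , drop = FALSE])
    acc[f] <- mean(pr$class == y[!tr])
  }
  list(accuracies = acc, min = min(acc), median = stats::median(acc), max = max(acc))
}

#' Evaluate a fitted model on a held-out test set
#'
#' @param model an `edc_model` from [tune_and_train()] / `fit_one`.
#' @param X test feature matrix.
#' @param y test labels.
#' @return list: `confusion` (named TN/FP/FN/TP with control = negative
#'   class), `accuracy`, `prob_control` per test row.
#' @export
evaluate_model <- function(model, X, y) {
  if (!nrow(X)) stop("empty test set")
  pr <- predict_model(model, X)
  cm <- confusion_counts(y, pr$class)
  list(confusion = cm, accuracy = confusion_accuracy(cm),
       prob_control = pr$prob_control, predicted = pr$class)
}

#' Confusion counts for binary treated/control predictions
#'
#' @param truth,pred factors with levels control/treated.
#' @return named vector TN, FP, FN, TP (control = negative class).
#' @export
confusion_counts <- function(truth, pred) {
  c(TN = sum(truth == "control" & pred == "control"),
    FP = sum(truth == "control" & pred == "treated"),
    FN = sum(truth == "treated" & pred == "control"),
    TP = sum(truth == "treated" & pred == "treated"))
}

#' Accuracy from confusion counts
#'
#' `(TN + TP) / (TN + FP + FN + TP)`.
#'
#' @param cm named vector from [confusion_counts()] (or the four counts).
#' @return accuracy in `[0, 1]`.
#' @export
confusion_accuracy <- function(cm) {
  unname((cm["TN"] + cm["TP"]) / sum(cm))
}

#' Ranked feature importances
#'
#' Linear discriminant: absolute standardized discriminant coefficients
#' (|coefficient| x feature SD). Boosted trees: gain-based importances.
#' Both are normalized to fractions summing to 1 over all features.
#'
#' @param model an `edc_model`.
#' @param top_n how many top features to return (default 10).
#' @return list: `all` (named, descending), `top` (first `top_n`).
#' @export
feature_importance <- function(model, top_n = 10L) {
  if (!inherits(model, "edc_model")) stop("not a fitted model")
  imp <- stats::setNames(rep(0, length(model$features)), model$features)
  if (model$kind == "lda") {
    w <- abs(model$fit$scaling[, 1]) * model$feature_sd[rownames(model$fit$scaling)]
    imp[names(w)] <- w
  } else {
    it <- xgboost::xgb.importance(model = model$fit)
    imp[it$Feature] <- it$Gain
  }
  if (sum(imp) > 0) imp <- imp / sum(imp)
  imp <- sort(imp, decreasing = TRUE)
  list(all = imp, top = imp[seq_len(min(top_n, length(imp)))])
}

#' Full classification study on a well feature table
#'
#' The complete treated-vs-control procedure for each classifier kind:
#' robust scaling (fit on the training split only, unless
#' `config$scale_before_split`), a stratified 90/10 split, 5-fold grid
#' search, refit, 10-fold CV on the training set, held-out evaluation and
#' feature importances.
#'
#' @param table unscaled well feature table.
#' @param kinds classifier kinds to run.
#' @param config pipeline config.
#' @param seed integer seed.
#' @return named list of reports; each has `kind`, `best_params`, `cv`
#'   (10-fold accuracies + summary), `confusion`, `accuracy`,
#'   `prob_control`, `importance` (top-10), `n_train`, `n_test`.
#' @export
classify_wells <- function(table, kinds = c("lda", "boost_depth", "boost_leaf"),
                           config = default_config(), seed = 1L) {
  table <- table[!is.na(table$n_living_cells) & table$n_living_cells > 0, ,
                 drop = FALSE]
  if (isTRUE(config$scale_before_split)) {
    table <- robust_scale(table)
    sp <- split_train_test(table, config$test_fraction, seed)
    train <- sp$train; test <- sp$test
  } else {
    sp <- split_train_test(table, config$test_fraction, seed)
    train <- robust_scale(sp$train)
    test <- apply_robust_scale(sp$test, attr(train, "scale_center"),
                               attr(train, "scale_iqr"))
  }
  ytr <- label_wells(train); yte <- label_wells(test)
  Xtr <- feature_matrix(train)
  Xte <- feature_matrix(test, impute_from = train)
  out <- list()
  for (kind in kinds) {
    tt <- tune_and_train(kind, Xtr, ytr, default_grid(kind),
                         config$grid_cv_folds, seed)
    cv <- cross_validate(kind, Xtr, ytr, config$cv_folds,
                         tt$best_params, seed)
    ev <- evaluate_model(tt$model, Xte, yte)
    imp <- feature_importance(tt$model)
    out[[kind]] <- list(kind = kind, best_params = tt$best_params,
                        grid_scores = tt$grid_scores, cv = cv,
                        confusion = ev$confusion, accuracy = ev$accuracy,
                        prob_control = ev$prob_control,
                        importance = imp$top, importance_all = imp$all,
                        n_train = nrow(train), n_test = nrow(test))
  }
  out
}
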