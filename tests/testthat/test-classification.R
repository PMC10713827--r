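# a synthetic, learnable well table: treated wells shift 5 features
toy_table <- function(n_control = 30, n_treated = 30, shift = 2, seed = 1) {
  set.seed(seed)
  cat126 <- feature_catalogue()
  n <- n_control + n_treated
  X <- as.data.frame(matrix(rnorm(n * 126), n, 126))
  names(X) <- cat126$name
  moved <- cat126$name[c(1, 20, 50, 80, 110)]
  for (nm in moved)
    X[[nm]][(n_control + 1):n] <- X[[nm]][(n_control + 1):n] + shift
  cbind(data.frame(plate = "p", well = sprintf("W%03d", seq_len(n)),
                   compound = rep(c("vehicle", "BPA"), c(n_control, n_treated)),
                   dose_uM = rep(c(0, 2), c(n_control, n_treated)),
                   replicate = 1L, n_fields = 4L, n_living_cells = 10L,
                   stringsAsFactors = FALSE), X)
}

test_that("labels are control for vehicle and treated otherwise", {
  tab <- toy_table(3, 4)
  y <- label_wells(tab)
  expect_equal(as.character(y), rep(c("control", "treated"), c(3, 4)))
  expect_equal(levels(y), c("control", "treated"))
})

test_that("the 90/10 split is stratified and reproduces the worked sizes", {
  # 150 control + 110 treated wells -> 15 + 11 test wells
  tab <- toy_table(150, 110)
  sp <- split_train_test(tab, 0.10, seed = 2L)
  yte <- label_wells(sp$test)
  expect_equal(sum(yte == "control"), 15)
  expect_equal(sum(yte == "treated"), 11)
  expect_equal(nrow(sp$train) + nrow(sp$test), 260)
  expect_equal(length(intersect(sp$train$well, sp$test$well)), 0)
})

test_that("stratified folds balance both class and total counts", {
  y <- factor(rep(c("control", "treated"), c(12, 48)))
  fold <- edcprofiler:::stratified_folds(y, 10, seed = 3L)
  expect_true(all(table(fold) %in% 6))
  expect_true(all(table(fold[y == "control"]) %in% 1:2))
})

test_that("confusion accuracy reproduces the printed worked examples", {
  # 15 control wells with 1 miss, 11 treated with 1 miss
  cm1 <- c(TN = 14, FP = 1, FN = 1, TP = 10)
  expect_equal(round(confusion_accuracy(cm1), 2), 0.92)
  # 1 control error, no treated errors
  cm2 <- c(TN = 14, FP = 1, FN = 0, TP = 11)
  expect_equal(round(confusion_accuracy(cm2), 2), 0.96)
  # and the counts route matches the prediction route
  truth <- factor(rep(c("control", "treated"), c(15, 11)),
                  levels = c("control", "treated"))
  pred <- truth; pred[15] <- "treated"; pred[16] <- "control"
  expect_equal(confusion_counts(truth, pred), cm1)
})

test_that("all three kinds learn a separable toy problem", {
  tab <- toy_table(30, 30, shift = 3)
  sc <- robust_scale(tab)
  X <- edcprofiler:::feature_matrix(sc)
  y <- label_wells(sc)
  for (kind in c("lda", "boost_depth", "boost_leaf")) {
    tt <- tune_and_train(kind, X, y, cv_folds = 3L, seed = 5L)
    ev <- evaluate_model(tt$model, X, y)
    expect_gt(ev$accuracy, 0.9)
    expect_equal(sum(ev$confusion), 60)
    expect_true(all(ev$prob_control >= 0 & ev$prob_control <= 1))
    expect_true(all(c("cv_accuracy") %in% names(tt$grid_scores)))
  }
})

test_that("cross-validation reports k accuracies with summary stats", {
  tab <- toy_table(20, 20, shift = 3)
  X <- edcprofiler:::feature_matrix(robust_scale(tab))
  y <- label_wells(tab)
  cv <- cross_validate("boost_depth", X, y, k = 10L,
                       params = data.frame(nrounds = 50, eta = 0.1, max_depth = 3),
                       seed = 6L)
  expect_length(cv$accuracies, 10)
  expect_equal(cv$min, min(cv$accuracies))
  expect_equal(cv$median, stats::median(cv$accuracies))
  expect_equal(cv$max, max(cv$accuracies))
  expect_error(cross_validate("boost_depth", X, y, k = 50L), "exceeds")
})

test_that("importances are non-negative fractions summing to at most 1", {
  tab <- toy_table(30, 30, shift = 3)
  X <- edcprofiler:::feature_matrix(robust_scale(tab))
  y <- label_wells(tab)
  for (kind in c("lda", "boost_leaf")) {
    m <- edcprofiler:::fit_one(kind, X, y, default_grid(kind)[1, , drop = FALSE])
    imp <- feature_importance(m, top_n = 10)
    expect_length(imp$top, 10)
    expect_true(all(imp$all >= 0 & imp$all <= 1))
    expect_lte(sum(imp$all), 1 + 1e-9)
    expect_true(!is.unsorted(rev(imp$all)))
    expect_true(all(names(imp$all) %in% feature_catalogue()$name))
  }
})

test_that("tree models find the truly shifted features", {
  tab <- toy_table(40, 40, shift = 3, seed = 8)
  X <- edcprofiler:::feature_matrix(robust_scale(tab))
  y <- label_wells(tab)
  moved <- feature_catalogue()$name[c(1, 20, 50, 80, 110)]
  m <- edcprofiler:::fit_one("boost_depth", X, y,
                             data.frame(nrounds = 100, eta = 0.1, max_depth = 3))
  top <- names(feature_importance(m, top_n = 10)$top)
  expect_gte(length(intersect(top, moved)), 3)
})

test_that("duplicated feature columns share importance (sum preserved)", {
  tab <- toy_table(40, 40, shift = 3, seed = 9)
  sc <- robust_scale(tab)
  X <- edcprofiler:::feature_matrix(sc)
  moved <- feature_catalogue()$name[1]
  y <- label_wells(sc)
  p <- data.frame(nrounds = 100, eta = 0.1, max_depth = 3)
  imp_single <- feature_importance(
    edcprofiler:::fit_one("boost_depth", X, y, p))$all
  Xdup <- cbind(X, dup_col = X[, moved])
  imp_dup <- feature_importance(
    edcprofiler:::fit_one("boost_depth", Xdup, y, p))$all
  combined <- imp_dup[moved] + imp_dup["dup_col"]
  expect_equal(unname(combined), unname(imp_single[moved]), tolerance = 0.15)
})

test_that("classify_wells produces full reports on a learnable table", {
  tab <- toy_table(25, 25, shift = 3, seed = 10)
  rep <- classify_wells(tab, kinds = "boost_depth",
                        config = default_config(cv_folds = 5L), seed = 10L)
  r <- rep$boost_depth
  expect_named(r$confusion, c("TN", "FP", "FN", "TP"))
  expect_equal(r$accuracy,
               unname((r$confusion["TN"] + r$confusion["TP"]) / sum(r$confusion)))
  expect_equal(r$n_train + r$n_test, 50)
  expect_length(r$cv$accuracies, 5)
  expect_length(r$importance, 10)
})

test_that("degenerate inputs raise errors", {
  tab <- toy_table(3, 3)
  expect_error(tune_and_train("nonsense", matrix(0, 2, 2),
                              factor(c("a", "b"))), "unknown classifier")
  y1 <- factor(rep("control", 6), levels = c("control", "treated"))
  X <- edcprofiler:::feature_matrix(tab)
  expect_error(tune_and_train("lda", X, y1), "both classes")
})
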