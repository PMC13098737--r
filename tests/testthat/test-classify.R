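test_that("train/test split is stratified, exhaustive and reproducible", {
  fm <- random_feature_matrix(10, 3, seed = 1)
  y <- rep(c("A", "B"), each = 5)
  sp1 <- split_train_test(fm, y, 0.2, seed = 4)
  sp2 <- split_train_test(fm, y, 0.2, seed = 4)
  expect_identical(sp1, sp2)
  expect_setequal(c(sp1$train, sp1$test), 1:10)
  expect_length(intersect(sp1$train, sp1$test), 0L)

  # patient-grouped mode keeps whole patients on one side
  fmp <- random_feature_matrix(40, 3, seed = 2)
  yp <- rep(c("A", "B"), 20)
  spp <- split_train_test(fmp, yp, 0.25, seed = 9,
                          stratify_by = "patient")
  expect_length(intersect(fmp$patient_id[spp$train],
                          fmp$patient_id[spp$test]), 0L)
  expect_error(split_train_test(fm, rep("A", 10), 0.2, 1), "both classes")
})

test_that("L1 selection recovers a planted support (median over 20 seeds)", {
  hits <- vapply(1:20, function(sd) {
    fm <- random_feature_matrix(600, 72, seed = 1000 + sd, shift = 3,
                                shifted_cols = 13)
    X <- as.matrix(fm[, -(1:2)])
    y <- rep(c("A", "B"), length.out = 600)
    sel <- select_features_l1(X, y, 13)
    sum(sel %in% sprintf("f%02d", 1:13))
  }, numeric(1))
  expect_gte(median(hits), 11)
})

test_that("L1 selection handles edge cases deterministically", {
  fm <- random_feature_matrix(80, 6, seed = 3, shift = 2, shifted_cols = 2)
  X <- as.matrix(fm[, -(1:2)])
  y <- rep(c("A", "B"), length.out = 80)
  expect_identical(select_features_l1(X, y, 6), colnames(X))
  # a duplicated (perfectly collinear) column still yields the exact count
  X2 <- cbind(X, f_dup = X[, 1])
  sel <- select_features_l1(X2, y, 4)
  expect_length(sel, 4L)
  expect_length(unique(sel), 4L)
  expect_error(select_features_l1(X, y, 10), "exceeds")
})

test_that("grid search finds separable data and honours a single grid point", {
  fm <- random_feature_matrix(100, 6, seed = 5, shift = 8, shifted_cols = 3)
  X <- as.matrix(fm[, -(1:2)])
  y <- rep(c("A", "B"), length.out = 100)
  cfg <- model_config(C_grid = c(0.1, 1), feature_count_grid = c(2, 4),
                      seed = 7)
  gs <- grid_search_cv(X, y, positive = "B", cfg)
  expect_equal(max(gs$cv_table$mean_auc), 1.0, tolerance = 1e-9)

  cfg1 <- model_config(C_grid = 1, feature_count_grid = 3, seed = 7)
  gs1 <- grid_search_cv(X, y, positive = "B", cfg1)
  expect_identical(gs1$best$C, 1)
  expect_identical(gs1$best$n_features, 3L)
  expect_identical(nrow(gs1$cv_table), 1L)
})

test_that("permuted labels give chance-level cross-validated AUC", {
  cfg <- model_config(C_grid = c(0.1, 1, 10),
                      feature_count_grid = c(2, 4, 8), seed = 1)
  best <- vapply(1:20, function(sd) {
    fm <- random_feature_matrix(300, 10, seed = 400 + sd)
    X <- as.matrix(fm[, -(1:2)])
    set.seed(sd)
    y <- sample(rep(c("A", "B"), length.out = 300))
    cfg$seed <- sd
    grid_search_cv(X, y, positive = "B", cfg)$cv_table$mean_auc |> max()
  }, numeric(1))
  expect_gt(mean(best), 0.43)
  expect_lt(mean(best), 0.57)
})

test_that("ROC, AUC and the operating point follow their definitions", {
  # perfectly ordered scores
  y <- rep(c("neg", "pos"), each = 10)
  sc <- c(rnorm(10, -3, 0.1), rnorm(10, 3, 0.1))
  roc <- roc_curve(sc, y, "pos")
  expect_equal(roc_auc(roc), 1.0)
  op <- ramanfcd:::operating_point(roc)
  cm <- ramanfcd:::confusion_at(sc, y, "pos", roc$threshold[op])
  expect_equal(unname(cm["TP"] / (cm["TP"] + cm["FN"])), 1)
  expect_equal(unname(cm["TN"] / (cm["TN"] + cm["FP"])), 1)

  # closed-form contingency: TP 10, FN 0, FP 1, TN 9
  scores <- c(rep(1, 10), 1, rep(-1, 9))
  labels <- c(rep("pos", 10), rep("neg", 10))
  roc2 <- roc_curve(scores, labels, "pos")
  op2 <- ramanfcd:::operating_point(roc2)
  cm2 <- ramanfcd:::confusion_at(scores, labels, "pos", roc2$threshold[op2])
  expect_identical(unname(cm2), c(10L, 0L, 1L, 9L))
  sens <- cm2["TP"] / (cm2["TP"] + cm2["FN"])
  spec <- cm2["TN"] / (cm2["TN"] + cm2["FP"])
  acc <- (cm2["TP"] + cm2["TN"]) / sum(cm2)
  expect_equal(unname(c(sens, spec, acc)), c(1.00, 0.90, 0.95))
})

test_that("AUC equals the Mann-Whitney rank statistic on random scores", {
  set.seed(11)
  for (r in 1:200) {
    n1 <- sample(3:15, 1); n0 <- sample(3:15, 1)
    sc <- c(rnorm(n1, 0.5), rnorm(n0))
    y <- c(rep("pos", n1), rep("neg", n0))
    a <- roc_auc(scores = sc, labels = y, positive = "pos")
    rk <- rank(sc)
    u <- sum(rk[y == "pos"]) - n1 * (n1 + 1) / 2
    expect_equal(a, u / (n1 * n0), tolerance = 1e-12)
  }
})

test_that("AUC is invariant under strictly monotone score transforms", {
  set.seed(12)
  sc <- rnorm(40)
  y <- sample(rep(c("pos", "neg"), 20))
  a1 <- roc_auc(scores = sc, labels = y, positive = "pos")
  a2 <- roc_auc(scores = exp(2 * sc) + 5, labels = y, positive = "pos")
  expect_equal(a1, a2, tolerance = 1e-12)
})

test_that("AUC agrees with pROC on a random score set", {
  skip_if_not_installed("pROC")
  set.seed(13)
  sc <- rnorm(60)
  y <- sample(rep(c("pos", "neg"), 30))
  ours <- roc_auc(scores = sc, labels = y, positive = "pos")
  theirs <- as.numeric(pROC::auc(pROC::roc(
    response = y, predictor = sc, levels = c("neg", "pos"),
    direction = "<", quiet = TRUE)))
  expect_equal(ours, theirs, tolerance = 1e-9)
})

test_that("run_model is deterministic and internally consistent", {
  fm <- random_feature_matrix(120, 8, seed = 6, shift = 2.5,
                              shifted_cols = 3)
  y <- rep(c("A", "B"), length.out = 120)
  cfg <- model_config(C_grid = c(0.1, 1), feature_count_grid = c(2, 4),
                      seed = 21)
  r1 <- run_model(fm, y, positive = "B", config = cfg)
  r2 <- run_model(fm, y, positive = "B", config = cfg)
  expect_equal(r1$auc, r2$auc)
  expect_identical(r1$confusion, r2$confusion)
  expect_identical(r1$selected_features, r2$selected_features)
  # metrics recomputed from the confusion matrix match the report
  cm <- r1$confusion
  expect_equal(unname(r1$sensitivity), unname(cm["TP"] / (cm["TP"] + cm["FN"])))
  expect_equal(unname(r1$specificity), unname(cm["TN"] / (cm["TN"] + cm["FP"])))
  expect_equal(unname(r1$accuracy), unname((cm["TP"] + cm["TN"]) / sum(cm)))
  expect_identical(sum(cm), length(r1$split$test))
  expect_error(run_model(fm, y, positive = "C", config = cfg), "unknown")
})

test_that("null-effect feature matrices give chance-level test accuracy", {
  # n large enough that picking the operating threshold on the test ROC
  # cannot inflate null accuracy beyond the calibration band
  cfg <- model_config(C_grid = c(0.1, 1), feature_count_grid = c(2, 4))
  accs <- vapply(1:20, function(sd) {
    fm <- random_feature_matrix(500, 8, seed = 600 + sd)
    set.seed(sd)
    y <- sample(rep(c("A", "B"), length.out = 500))
    cfg$seed <- sd
    as.numeric(run_model(fm, y, positive = "B", config = cfg)$accuracy)
  }, numeric(1))
  expect_gt(mean(accs), 0.4)
  expect_lt(mean(accs), 0.6)
})

test_that("nothing fitted on training data depends on test labels", {
  fm <- random_feature_matrix(100, 6, seed = 8, shift = 2, shifted_cols = 2)
  y <- rep(c("A", "B"), length.out = 100)
  # patient-grouped split: the partition is independent of the labels, so
  # permuting test labels must leave the fitted model untouched
  cfg <- model_config(C_grid = 1, feature_count_grid = 3, seed = 5,
                      stratify_by = "patient")
  r1 <- run_model(fm, y, positive = "B", config = cfg)
  # permute the labels of the test rows only and rerun
  y2 <- y
  set.seed(99)
  y2[r1$split$test] <- sample(y[r1$split$test])
  r2 <- run_model(fm, y2, positive = "B", config = cfg)
  expect_identical(r1$selected_features, r2$selected_features)
  expect_equal(r1$scores, r2$scores, tolerance = 1e-12)
})
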