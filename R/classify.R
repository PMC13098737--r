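#' Model-building configuration
#'
#' Hyperparameter grids and resampling settings of the two-stage classifier:
#' an L1-penalized linear selector ranks features, and an L2 linear SVM is
#' trained on the retained ones; both the SVM cost C and the number of
#' retained features are tuned by stratified five-fold cross-validation on
#' ROC AUC, with a 20% class-stratified test set held out beforehand.
#'
#' @param C_grid SVM cost grid (default `c(0.01, 0.1, 1, 10, 100)`).
#' @param feature_count_grid Retained-feature-count grid (default
#'   `c(4, 8, 13, 24, 48, 72)`, capped at the matrix width at run time).
#' @param folds Cross-validation folds (default 5).
#' @param test_fraction Held-out test fraction (default 0.2).
#' @param seed Integer seed controlling the split and fold assignment.
#' @param stratify_by `"class"` (default) or `"patient"` (all spectra of a
#'   patient on one side of the split).
#' @return An object of class `model_config`.
#' @export
model_config <- function(C_grid = c(0.01, 0.1, 1, 10, 100),
                         feature_count_grid = c(4, 8, 13, 24, 48, 72),
                         folds = 5L, test_fraction = 0.2, seed = 1L,
                         stratify_by = c("class", "patient")) {
  if (folds < 2L) stop("folds must be >= 2")
  if (test_fraction <= 0 || test_fraction >= 1) {
    stop("test_fraction must be in (0, 1)")
  }
  structure(list(C_grid = C_grid,
                 feature_count_grid = as.integer(feature_count_grid),
                 folds = as.integer(folds), test_fraction = test_fraction,
                 seed = as.integer(seed),
                 stratify_by = match.arg(stratify_by)),
            class = "model_config")
}

#' Split a feature matrix into train and test sets
#'
#' Disjoint, exhaustive split. In class-stratified mode the test set takes
#' `round(test_fraction * n_c)` spectra of each class; in patient-grouped
#' mode whole patients are moved to the test side until its size is as close
#' as possible to `round(test_fraction * n)`.
#'
#' @param fm Feature matrix (rows keyed by `spectrum_id`).
#' @param labels Factor/character vector of class labels, one per row.
#' @param test_fraction Test fraction (default 0.2).
#' @param seed Integer seed.
#' @param stratify_by `"class"` or `"patient"`.
#' @return List with integer row indices `train` and `test`.
#' @export
split_train_test <- function(fm, labels, test_fraction = 0.2, seed = 1L,
                             stratify_by = c("class", "patient")) {
  stratify_by <- match.arg(stratify_by)
  labels <- as.character(labels)
  if (length(unique(labels)) < 2L) stop("both classes must be present")
  n <- nrow(fm)
  set.seed(as.integer(seed))
  if (stratify_by == "class") {
    test <- integer(0)
    for (cls in sort(unique(labels))) {
      ix <- which(labels == cls)
      k <- round(test_fraction * length(ix))
      test <- c(test, sort(sample(ix, k)))
    }
    test <- sort(test)
  } else {
    pid <- fm$patient_id
    if (is.null(pid)) stop("patient-grouped split needs a patient_id column")
    target <- round(test_fraction * n)
    pats <- sample(unique(pid))
    sizes <- cumsum(vapply(pats, function(p) sum(pid == p), numeric(1)))
    k <- which.min(abs(sizes - target))
    if (sizes[k] == 0) k <- 1L
    test <- sort(which(pid %in% pats[seq_len(k)]))
  }
  train <- setdiff(seq_len(n), test)
  if (stratify_by == "class" &&
      (length(unique(labels[train])) < 2L ||
       length(unique(labels[test])) < 2L)) {
    stop("a class is absent from one side of the split")
  }
  list(train = train, test = test)
}

# feature standardization fitted on training data only
fit_scaler <- function(X) {
  mu <- colMeans(X)
  sdv <- apply(X, 2L, stats::sd)
  sdv[!is.finite(sdv) | sdv == 0] <- 1
  list(mean = mu, sd = sdv)
}

apply_scaler <- function(X, scaler) {
  sweep(sweep(as.matrix(X), 2L, scaler$mean), 2L, scaler$sd, `/`)
}

#' Rank and select features with an L1-penalized linear model
#'
#' Fits an L1-regularized linear classifier (sparse logistic regression,
#' glmnet lasso path) on the standardized training features and retains the
#' `target_count` features with the largest absolute coefficients at the
#' strongest penalty whose support reaches `target_count`. Walking the
#' penalty path plays the role of tuning the selector strength until enough
#' coefficients are nonzero. Ties and rank gaps (e.g. perfectly collinear
#' columns) are broken by column order, so exactly `target_count` names are
#' always returned.
#'
#' @param X Numeric training matrix (rows = spectra).
#' @param y Binary labels (factor or character).
#' @param target_count Number of features to retain.
#' @param standardize Standardize internally before fitting (default TRUE).
#' @return Character vector of `target_count` selected feature names, ranked
#'   by decreasing |coefficient|.
#' @export
select_features_l1 <- function(X, y, target_count, standardize = TRUE) {
  X <- as.matrix(X)
  if (target_count > ncol(X)) {
    stop("target_count exceeds the number of features")
  }
  if (target_count == ncol(X)) return(colnames(X))
  y <- factor(y)
  if (nlevels(y) != 2L) stop("need exactly two classes")
  if (standardize) X <- apply_scaler(X, fit_scaler(X))
  fit <- glmnet::glmnet(X, y, family = "binomial", alpha = 1,
                        standardize = FALSE, nlambda = 200,
                        lambda.min.ratio = 1e-4)
  df <- fit$df
  idx <- which(df >= target_count)
  lam_idx <- if (length(idx)) idx[1L] else length(fit$lambda)
  co <- abs(as.numeric(fit$beta[, lam_idx]))
  ranked <- order(co, decreasing = TRUE)  # order() breaks ties by position
  colnames(X)[ranked[seq_len(target_count)]]
}

# linear SVM wrapped with a deterministic score orientation: positive
# decision scores point toward the positive class
fit_linear_svm <- function(X, y, C, positive) {
  y <- factor(y)
  svm <- e1071::svm(X, y, kernel = "linear", cost = C, scale = FALSE)
  sc <- as.numeric(attr(stats::predict(svm, X, decision.values = TRUE),
                        "decision.values"))
  flip <- if (mean(sc[y == positive]) < mean(sc[y != positive])) -1 else 1
  list(svm = svm, flip = flip, positive = positive)
}

svm_scores <- function(model, X) {
  model$flip * as.numeric(attr(
    stats::predict(model$svm, X, decision.values = TRUE),
    "decision.values"))
}

# stratified fold assignment
make_folds <- function(y, k) {
  fold <- integer(length(y))
  for (cls in unique(y)) {
    ix <- sample(which(y == cls))
    fold[ix] <- rep_len(seq_len(k), length(ix))
  }
  fold
}

#' Empirical ROC curve
#'
#' Thresholds are the sorted unique decision scores plus infinite endpoints;
#' a case is called positive when its score is >= the threshold.
#'
#' @param scores Numeric decision scores.
#' @param labels Class labels.
#' @param positive Positive-class label.
#' @return data.frame with `threshold`, `fpr`, `tpr`, ordered by increasing
#'   FPR.
#' @export
roc_curve <- function(scores, labels, positive) {
  is_pos <- labels == positive
  n_pos <- sum(is_pos)
  n_neg <- sum(!is_pos)
  if (n_pos == 0L || n_neg == 0L) stop("single-class label set")
  thr <- c(Inf, sort(unique(scores), decreasing = TRUE), -Inf)
  tpr <- vapply(thr, function(t) sum(scores[is_pos] >= t) / n_pos, numeric(1))
  fpr <- vapply(thr, function(t) sum(scores[!is_pos] >= t) / n_neg, numeric(1))
  data.frame(threshold = thr, fpr = fpr, tpr = tpr)
}

#' Area under the ROC curve (trapezoidal rule)
#'
#' @param roc data.frame from [roc_curve()], or `NULL` to compute from
#'   `scores`/`labels`/`positive`.
#' @param scores,labels,positive Used when `roc` is `NULL`.
#' @return AUC in \[0, 1\].
#' @export
roc_auc <- function(roc = NULL, scores = NULL, labels = NULL,
                    positive = NULL) {
  if (is.null(roc)) roc <- roc_curve(scores, labels, positive)
  o <- order(roc$fpr, roc$tpr)
  f <- roc$fpr[o]; t <- roc$tpr[o]
  sum(diff(f) * (utils::head(t, -1) + utils::tail(t, -1)) / 2)
}

# upper-left operating point: minimize distance to (FPR 0, TPR 1),
# ties broken toward the higher TPR
operating_point <- function(roc) {
  d <- sqrt(roc$fpr^2 + (1 - roc$tpr)^2)
  best <- which(d == min(d))
  best[which.max(roc$tpr[best])]
}

confusion_at <- function(scores, labels, positive, threshold) {
  pred_pos <- scores >= threshold
  is_pos <- labels == positive
  c(TP = sum(pred_pos & is_pos), FN = sum(!pred_pos & is_pos),
    FP = sum(pred_pos & !is_pos), TN = sum(!pred_pos & !is_pos))
}

#' Evaluate a fitted classifier on a held-out test set
#'
#' Computes the test ROC from decision scores, the trapezoidal AUC, and the
#' confusion matrix with sensitivity, specificity and accuracy at the
#' upper-left operating point (the ROC point closest to FPR 0 / TPR 1; ties
#' resolved toward higher TPR).
#'
#' @param fit A fitted pipeline from [run_model()]'s internals: list with
#'   `scaler`, `features`, `model` (linear SVM wrapper).
#' @param X_test Numeric test feature matrix (unstandardized, full width).
#' @param y_test Test labels.
#' @return An `eval_report` object.
#' @export
evaluate_on_test <- function(fit, X_test, y_test) {
  y_test <- as.character(y_test)
  if (length(unique(y_test)) < 2L) stop("single-class test set")
  Xs <- apply_scaler(as.matrix(X_test)[, names(fit$scaler$mean),
                                       drop = FALSE], fit$scaler)
  scores <- svm_scores(fit$model, Xs[, fit$features, drop = FALSE])
  positive <- fit$model$positive
  roc <- roc_curve(scores, y_test, positive)
  auc <- roc_auc(roc)
  op <- operating_point(roc)
  cm <- confusion_at(scores, y_test, positive, roc$threshold[op])
  report <- structure(
    list(roc = roc, auc = auc,
         operating_threshold = roc$threshold[op],
         confusion = cm,
         sensitivity = cm["TP"] / (cm["TP"] + cm["FN"]),
         specificity = cm["TN"] / (cm["TN"] + cm["FP"]),
         accuracy = (cm["TP"] + cm["TN"]) / sum(cm),
         positive = positive,
         scores = scores, labels = y_test,
         n_test = length(y_test)),
    class = "eval_report")
  report
}

#' @export
print.eval_report <- function(x, ...) {
  cat(sprintf("<eval_report> positive class: %s\n", x$positive))
  cat(sprintf("  AUC %.3f | accuracy %.1f%% | sensitivity %.1f%% | specificity %.1f%%\n",
              x$auc, 100 * x$accuracy, 100 * x$sensitivity,
              100 * x$specificity))
  cat(sprintf("  confusion (test n=%d): TP %d  FN %d  FP %d  TN %d\n",
              x$n_test, x$confusion["TP"], x$confusion["FN"],
              x$confusion["FP"], x$confusion["TN"]))
  if (!is.null(x$chosen)) {
    cat(sprintf("  chosen C = %g, retained features = %d\n",
                x$chosen$C, x$chosen$n_features))
  }
  invisible(x)
}

#' Cross-validated grid search over C and the retained-feature count
#'
#' For every grid point, feature standardization and L1 selection are fitted
#' inside each training fold (no leakage into validation folds); the fold
#' score is the validation ROC AUC of the linear SVM. The best grid point
#' has the highest mean AUC; ties are broken toward fewer features, then
#' smaller C.
#'
#' @param X Training feature matrix.
#' @param y Training labels.
#' @param positive Positive-class label.
#' @param config A [model_config()]; fold assignment uses `config$seed`.
#' @return List with `best` (C, n_features), and `cv_table` (one row per
#'   grid point with mean/sd of fold AUCs).
#' @export
grid_search_cv <- function(X, y, positive, config = model_config()) {
  X <- as.matrix(X)
  y <- as.character(y)
  k_grid <- sort(unique(pmin(config$feature_count_grid, ncol(X))))
  counts <- table(y)
  if (any(counts < config$folds)) {
    stop("need at least `folds` samples per class for stratified CV")
  }
  set.seed(config$seed)
  fold <- make_folds(y, config$folds)
  # selection depends only on the fold and k, not on C: precompute
  sel <- vector("list", config$folds)
  for (f in seq_len(config$folds)) {
    tr <- fold != f
    sel[[f]] <- lapply(k_grid, function(k) {
      select_features_l1(X[tr, , drop = FALSE], y[tr], k)
    })
    names(sel[[f]]) <- as.character(k_grid)
  }
  grid <- expand.grid(C = config$C_grid, n_features = k_grid)
  aucs <- matrix(NA_real_, nrow(grid), config$folds)
  for (f in seq_len(config$folds)) {
    tr <- fold != f
    scaler <- fit_scaler(X[tr, , drop = FALSE])
    Xtr <- apply_scaler(X[tr, , drop = FALSE], scaler)
    Xva <- apply_scaler(X[!tr, , drop = FALSE], scaler)
    yva <- y[!tr]
    for (g in seq_len(nrow(grid))) {
      feats <- sel[[f]][[as.character(grid$n_features[g])]]
      m <- fit_linear_svm(Xtr[, feats, drop = FALSE], y[tr], grid$C[g],
                          positive)
      sc <- svm_scores(m, Xva[, feats, drop = FALSE])
      aucs[g, f] <- roc_auc(scores = sc, labels = yva, positive = positive)
    }
  }
  cv_table <- cbind(grid,
                    mean_auc = rowMeans(aucs),
                    sd_auc = apply(aucs, 1L, stats::sd))
  o <- order(-cv_table$mean_auc, cv_table$n_features, cv_table$C)
  best <- cv_table[o[1L], ]
  list(best = list(C = best$C, n_features = best$n_features),
       cv_table = cv_table)
}

#' Run one complete classification model
#'
#' Full procedure: class-stratified (or patient-grouped) 20% test split,
#' cross-validated grid search on the training set, final standardization /
#' L1 selection / linear SVM fit on all training data, evaluation on the
#' held-out test set at the upper-left ROC operating point.
#'
#' @param fm Feature matrix from [extract_features()] (or any data.frame
#'   with feature columns, `spectrum_id`, optional `patient_id`).
#' @param labels Binary labels, one per row (after any class grouping).
#' @param positive Positive-class label.
#' @param config A [model_config()].
#' @return An `eval_report` additionally carrying `chosen` hyperparameters,
#'   `selected_features`, `cv_table`, and train/test class counts.
#' @export
run_model <- function(fm, labels, positive, config = model_config()) {
  labels <- as.character(labels)
  if (!positive %in% labels) stop("unknown positive_class: ", positive)
  if (length(unique(labels)) != 2L) {
    stop("labels must contain exactly two classes")
  }
  feats <- feature_columns(fm)
  if (!length(feats)) {
    feats <- names(fm)[vapply(fm, is.numeric, logical(1))]
    feats <- setdiff(feats, c("spectrum_id", "patient_id"))
  }
  X <- as.matrix(fm[, feats, drop = FALSE])
  sp <- split_train_test(fm, labels, config$test_fraction, config$seed,
                         config$stratify_by)
  Xtr <- X[sp$train, , drop = FALSE]
  ytr <- labels[sp$train]
  gs <- grid_search_cv(Xtr, ytr, positive, config)
  scaler <- fit_scaler(Xtr)
  Xtr_s <- apply_scaler(Xtr, scaler)
  selected <- select_features_l1(Xtr_s, ytr, gs$best$n_features,
                                 standardize = FALSE)
  model <- fit_linear_svm(Xtr_s[, selected, drop = FALSE], ytr,
                          gs$best$C, positive)
  fit <- list(scaler = scaler, features = selected, model = model)
  report <- evaluate_on_test(fit, X[sp$test, , drop = FALSE],
                             labels[sp$test])
  report$chosen <- gs$best
  report$selected_features <- selected
  report$cv_table <- gs$cv_table
  report$counts <- list(
    train = as.list(table(ytr)),
    test = as.list(table(labels[sp$test])))
  report$split <- sp
  report$fit <- fit
  report
}

#' Serialize an evaluation report to JSON
#'
#' @param report An `eval_report`.
#' @param path Output path.
#' @return Invisibly, `path`.
#' @export
write_eval_report <- function(report, path) {
  out <- list(
    positive = report$positive,
    auc = report$auc,
    accuracy = as.numeric(report$accuracy),
    sensitivity = as.numeric(report$sensitivity),
    specificity = as.numeric(report$specificity),
    operating_threshold = report$operating_threshold,
    confusion = as.list(report$confusion),
    chosen = report$chosen,
    selected_features = report$selected_features,
    counts = report$counts,
    n_test = report$n_test,
    roc = report$roc)
  jsonlite::write_json(out, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}
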