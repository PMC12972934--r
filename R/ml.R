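#' @title Machine-learning target prioritization
#' @description The prioritization stage turns each target's PPI topology
#'   profile into a 0-15 priority score: features are min-max scaled, binary
#'   labels are derived from the 70th percentile of a composite centrality
#'   score, a bagged-tree (random forest) and a gradient-boosted-tree
#'   (XGBoost) classifier are tuned by grid search with 5-fold
#'   cross-validation and audited for overfitting, and two regressors on the
#'   composite score are averaged and linearly mapped to [0, 15].
#' @name ml_prioritizer
NULL

#' Fixed feature column order used by the prioritizer
#' @export
feature_columns <- function() .topology_feature_cols

#' Assemble the feature matrix from a topology table
#'
#' Takes the table from [compute_topology()] and returns the eight feature
#' columns in fixed order as a numeric matrix with target symbols as row
#' names. MCC is deliberately excluded: it defines the PPI-hub evidence
#' channel and must stay independent of the machine-learning channel.
#'
#' @param topology Data frame with a `node` column and the eight feature
#'   columns.
#' @return Numeric matrix, one row per target, 8 columns.
#' @export
build_features <- function(topology) {
  cols <- .topology_feature_cols
  missing_cols <- setdiff(c("node", cols), names(topology))
  if (length(missing_cols)) {
    stop("topology table lacks column(s): ",
         paste(missing_cols, collapse = ", "), call. = FALSE)
  }
  m <- as.matrix(topology[, cols])
  rownames(m) <- topology$node
  if (anyNA(m)) stop("missing feature values in topology table", call. = FALSE)
  if (anyDuplicated(rownames(m))) stop("duplicate target ids", call. = FALSE)
  m
}

#' Column-wise min-max scaling to [0, 1]
#'
#' Each column is mapped by (x - min) / (max - min); a constant column is
#' mapped to all zeros (with a message).
#'
#' @param m Numeric matrix with >= 2 rows.
#' @return Matrix of the same shape, every column in [0, 1].
#' @export
minmax_scale <- function(m) {
  stopifnot(is.matrix(m), nrow(m) >= 2)
  out <- apply(m, 2, function(x) {
    r <- max(x) - min(x)
    if (r == 0) rep(0, length(x)) else (x - min(x)) / r
  })
  const <- apply(m, 2, function(x) max(x) == min(x))
  if (any(const)) {
    message("constant column(s) mapped to 0: ",
            paste(colnames(m)[const], collapse = ", "))
  }
  rownames(out) <- rownames(m)
  out
}

#' Percentile-threshold binary labels from a composite centrality score
#'
#' The composite score of a target is the mean of its scaled
#' degree-centrality, betweenness and closeness (configurable via `basis`).
#' The label is 1 when the composite strictly exceeds the given percentile
#' of the composite distribution (linear-interpolation percentile between
#' order statistics).
#'
#' @param scaled Min-max scaled feature matrix.
#' @param percentile Percentile in (0, 100) defining the threshold
#'   (default 70).
#' @param basis Feature columns averaged into the composite score.
#' @return List with `labels` (named integer 0/1), `threshold`, `composite`
#'   (named numeric), `percentile`, `basis`.
#' @export
make_labels <- function(scaled, percentile = 70,
                        basis = c("degree_centrality", "betweenness",
                                  "closeness")) {
  if (percentile <= 0 || percentile >= 100) {
    stop("percentile must be in (0, 100)", call. = FALSE)
  }
  stopifnot(all(basis %in% colnames(scaled)))
  composite <- rowMeans(scaled[, basis, drop = FALSE])
  threshold <- unname(stats::quantile(composite, percentile / 100, type = 7))
  labels <- as.integer(composite > threshold)
  names(labels) <- rownames(scaled)
  list(labels = labels, threshold = threshold, composite = composite,
       percentile = percentile, basis = basis)
}

#' Stratified train/test split
#'
#' Splits targets 7:3 (by default) with stratification on the label. The
#' test set holds `ceiling((1 - ratio) * n)` targets, allocated to classes
#' proportionally (largest-remainder rounding); the split is deterministic
#' for a fixed seed.
#'
#' @param features Feature matrix (rows = targets).
#' @param labels Integer 0/1 vector aligned with the rows.
#' @param ratio Training fraction (default 0.7).
#' @param seed Integer seed.
#' @return List with `train` and `test`, each a list `x` (matrix), `y`
#'   (integer), `idx` (row indices into `features`).
#' @export
split_data <- function(features, labels, ratio = 0.7, seed = 1) {
  n <- nrow(features)
  stopifnot(length(labels) == n, n >= 10)
  test_n <- as.integer(ceiling((1 - ratio) * n))
  classes <- sort(unique(labels))
  n_c <- vapply(classes, function(cl) sum(labels == cl), integer(1))
  base_alloc <- floor(test_n * n_c / n)
  frac <- test_n * n_c / n - base_alloc
  rem <- test_n - sum(base_alloc)
  if (rem > 0) {
    bump <- order(-frac, classes)[seq_len(rem)]
    base_alloc[bump] <- base_alloc[bump] + 1L
  }
  test_idx <- integer(0)
  withr::with_seed(seed, {
    for (i in seq_along(classes)) {
      members <- which(labels == classes[i])
      test_idx <- c(test_idx, sample(members, base_alloc[i]))
    }
  })
  test_idx <- sort(test_idx)
  train_idx <- setdiff(seq_len(n), test_idx)
  for (cl in classes) {
    if (!any(labels[train_idx] == cl) || !any(labels[test_idx] == cl)) {
      stop("class ", cl, " absent from one side of the split; ",
           "input too small or too imbalanced", call. = FALSE)
    }
  }
  list(
    train = list(x = features[train_idx, , drop = FALSE],
                 y = labels[train_idx], idx = train_idx),
    test = list(x = features[test_idx, , drop = FALSE],
                y = labels[test_idx], idx = test_idx)
  )
}

#' Default hyperparameter grids for the two tree ensembles
#'
#' Small grids (at most 3 values per knob) so the 5-fold grid search runs
#' in seconds; a full configuration can be supplied in the same shape.
#'
#' @return List with `rf` and `xgb` grids (lists of vectors).
#' @export
default_grids <- function() {
  list(
    rf = list(ntree = c(500), mtry = c(3, 8), nodesize = c(1, 5)),
    xgb = list(nrounds = c(100, 300), max_depth = c(3, 4), eta = c(0.05, 0.3))
  )
}

f1_score <- function(truth, pred) {
  tp <- sum(truth == 1 & pred == 1)
  fp <- sum(truth == 0 & pred == 1)
  fn <- sum(truth == 1 & pred == 0)
  if (2 * tp + fp + fn == 0) return(0)
  2 * tp / (2 * tp + fp + fn)
}

accuracy_score <- function(truth, pred) mean(truth == pred)

fit_rf_classifier <- function(x, y, params) {
  randomForest::randomForest(
    x = x, y = factor(y, levels = c(0, 1)),
    ntree = params$ntree,
    mtry = min(params$mtry, ncol(x)),
    nodesize = params$nodesize
  )
}

fit_xgb_classifier <- function(x, y, params) {
  xgboost::xgb.train(
    params = list(objective = "binary:logistic",
                  max_depth = params$max_depth, eta = params$eta,
                  nthread = 1),
    data = xgboost::xgb.DMatrix(x, label = y),
    nrounds = params$nrounds, verbose = 0
  )
}

predict_class <- function(model, x) {
  if (inherits(model, "randomForest")) {
    as.integer(as.character(predict(model, x)))
  } else {
    as.integer(predict(model, xgboost::xgb.DMatrix(x)) > 0.5)
  }
}

make_folds <- function(n, k) {
  # assumes the RNG state is already seeded by the caller
  split(sample(seq_len(n)), rep_len(seq_len(k), n))
}

cv_f1 <- function(x, y, k, fitter, params) {
  folds <- make_folds(length(y), k)
  f1s <- vapply(folds, function(test) {
    train <- setdiff(seq_along(y), test)
    if (length(unique(y[train])) < 2) return(NA_real_)
    model <- fitter(x[train, , drop = FALSE], y[train], params)
    f1_score(y[test], predict_class(model, x[test, , drop = FALSE]))
  }, numeric(1))
  f1s[!is.na(f1s)]
}

grid_search <- function(x, y, grid, fitter, k = 5) {
  configs <- expand.grid(grid, KEEP.OUT.ATTRS = FALSE)
  means <- vapply(seq_len(nrow(configs)), function(i) {
    mean(cv_f1(x, y, k, fitter, as.list(configs[i, , drop = FALSE])))
  }, numeric(1))
  best <- which.max(means)  # ties: first (lowest-complexity-first ordering)
  list(best = as.list(configs[best, , drop = FALSE]),
       cv_f1 = means[best], all = cbind(configs, cv_f1 = means))
}

#' Tune and fit the two tree-ensemble classifiers
#'
#' Grid search with 5-fold cross-validation on the training partition,
#' selecting each model's configuration by mean fold F1, then refitting on
#' the full training set. Seeded and deterministic.
#'
#' @param train Training partition (`$x`, `$y`) from [split_data()].
#' @param grids Hyperparameter grids as from [default_grids()].
#' @param seed Integer seed.
#' @return List with `rf`, `xgb` (fitted models), `best` (chosen
#'   hyperparameters per model) and `search` (full grid results).
#' @export
train_models <- function(train, grids = default_grids(), seed = 1) {
  stopifnot(length(unique(train$y)) == 2)
  withr::with_seed(seed, {
    rf_sel <- grid_search(train$x, train$y, grids$rf, fit_rf_classifier)
    xgb_sel <- grid_search(train$x, train$y, grids$xgb, fit_xgb_classifier)
    rf <- fit_rf_classifier(train$x, train$y, rf_sel$best)
    xgb <- fit_xgb_classifier(train$x, train$y, xgb_sel$best)
  })
  list(rf = rf, xgb = xgb,
       best = list(rf = rf_sel$best, xgb = xgb_sel$best),
       search = list(rf = rf_sel$all, xgb = xgb_sel$all))
}

model_importances <- function(model, feature_names) {
  imp <- stats::setNames(numeric(length(feature_names)), feature_names)
  if (inherits(model, "randomForest")) {
    gi <- randomForest::importance(model)[, "MeanDecreaseGini"]
    imp[names(gi)] <- gi
  } else {
    tab <- xgboost::xgb.importance(model = model)
    imp[tab$Feature] <- tab$Gain
  }
  s <- sum(imp)
  if (s > 0) imp <- imp / s
  imp
}

#' Evaluate fitted classifiers: test metrics, stability, overfitting
#'
#' Reports per model the train and test accuracy and F1, a 10-fold
#' cross-validation F1 mean and standard deviation on the full labeled set
#' (refitting with the chosen hyperparameters), the train-minus-test
#' overfit gaps, and normalized feature importances.
#'
#' @param models Output of [train_models()].
#' @param split Output of [split_data()].
#' @param features Full feature matrix (train and test rows).
#' @param labels Full label vector.
#' @param seed Integer seed for the 10-fold partition.
#' @return A `model_report`: nested list, one entry per model, plus the
#'   split sizes and seed.
#' @export
evaluate_models <- function(models, split, features, labels, seed = 1) {
  feature_names <- colnames(features)
  per_model <- lapply(c(rf = "rf", xgb = "xgb"), function(key) {
    model <- models[[key]]
    fitter <- if (key == "rf") fit_rf_classifier else fit_xgb_classifier
    pred_tr <- predict_class(model, split$train$x)
    pred_te <- predict_class(model, split$test$x)
    cv <- withr::with_seed(seed,
      cv_f1(features, labels, 10, fitter, models$best[[key]]))
    list(
      accuracy_train = accuracy_score(split$train$y, pred_tr),
      f1_train = f1_score(split$train$y, pred_tr),
      accuracy_test = accuracy_score(split$test$y, pred_te),
      f1_test = f1_score(split$test$y, pred_te),
      cv10_f1_mean = mean(cv),
      cv10_f1_sd = stats::sd(cv),
      overfit_gap_accuracy = accuracy_score(split$train$y, pred_tr) -
        accuracy_score(split$test$y, pred_te),
      overfit_gap_f1 = f1_score(split$train$y, pred_tr) -
        f1_score(split$test$y, pred_te),
      best_hyperparameters = models$best[[key]],
      feature_importances = model_importances(model, feature_names)
    )
  })
  structure(list(models = per_model,
                 n_train = length(split$train$y),
                 n_test = length(split$test$y),
                 seed = seed),
            class = "model_report")
}

#' @export
print.model_report <- function(x, ...) {
  cat("<model_report> train n =", x$n_train, ", test n =", x$n_test, "\n")
  for (key in names(x$models)) {
    m <- x$models[[key]]
    cat(sprintf("  %-4s acc %.3f / F1 %.3f (test); CV10 F1 %.3f +/- %.3f; gaps %.3f/%.3f\n",
                key, m$accuracy_test, m$f1_test, m$cv10_f1_mean,
                m$cv10_f1_sd, m$overfit_gap_accuracy, m$overfit_gap_f1))
  }
  invisible(x)
}

#' Ensemble priority scores on a 0-15 scale
#'
#' Fits a random-forest regressor and a gradient-boosted-tree regressor to
#' the composite centrality score, averages their predictions
#' arithmetically, and maps the averaged prediction linearly to [0, 15].
#' If the raw predictions are all equal the scores degenerate to 0 and the
#' result is flagged.
#'
#' @param features Scaled feature matrix.
#' @param composite Named numeric regression target (the composite score
#'   whose percentile defined the labels).
#' @param seed Integer seed.
#' @param rf_ntree,xgb_nrounds,xgb_max_depth,xgb_eta Regressor settings.
#' @return Data frame `target`, `raw_ensemble`, `scaled_score`, `rank`
#'   (descending score, competition ranking), with attributes `r2` (each
#'   regressor's coefficient of determination on the fit data) and
#'   `degenerate`.
#' @export
ensemble_score <- function(features, composite, seed = 1,
                           rf_ntree = 500, xgb_nrounds = 200,
                           xgb_max_depth = 3, xgb_eta = 0.1) {
  stopifnot(nrow(features) == length(composite))
  withr::with_seed(seed, {
    rf <- randomForest::randomForest(x = features, y = composite,
                                     ntree = rf_ntree)
    xgb <- xgboost::xgb.train(
      params = list(objective = "reg:squarederror",
                    max_depth = xgb_max_depth, eta = xgb_eta, nthread = 1),
      data = xgboost::xgb.DMatrix(features, label = composite),
      nrounds = xgb_nrounds, verbose = 0
    )
  })
  pred_rf <- predict(rf, features)
  pred_xgb <- predict(xgb, xgboost::xgb.DMatrix(features))
  raw <- (pred_rf + pred_xgb) / 2
  rng <- max(raw) - min(raw)
  degenerate <- rng == 0
  scaled <- if (degenerate) rep(0, length(raw)) else
    15 * (raw - min(raw)) / rng
  if (degenerate) warning("degenerate raw predictions; all scores set to 0")
  r2 <- function(pred) 1 - sum((composite - pred)^2) /
    sum((composite - mean(composite))^2)
  targets <- rownames(features)
  if (is.null(targets)) targets <- sprintf("row%03d", seq_len(nrow(features)))
  ord <- order(-scaled, targets)
  out <- data.frame(target = targets[ord],
                    raw_ensemble = raw[ord],
                    scaled_score = scaled[ord],
                    rank = rank(-scaled, ties.method = "min")[ord],
                    row.names = NULL, stringsAsFactors = FALSE)
  attr(out, "r2") <- c(rf = r2(pred_rf), xgb = r2(pred_xgb))
  attr(out, "degenerate") <- degenerate
  out
}

#' Run the full machine-learning prioritization stage
#'
#' Convenience wrapper chaining [build_features()], [minmax_scale()],
#' [make_labels()], [split_data()], [train_models()], [evaluate_models()]
#' and [ensemble_score()].
#'
#' @param topology Topology table from [compute_topology()].
#' @param seed Integer seed driving every random step.
#' @param ratio Training fraction (default 0.7).
#' @param percentile Label percentile (default 70).
#' @param grids Hyperparameter grids.
#' @param label_basis Columns averaged into the composite label score.
#' @param holdout_label_features If TRUE, the label-defining columns are
#'   excluded from the classifier features (non-circular mode).
#' @return List with `scaled`, `labels`, `split`, `models`, `report`,
#'   `scores`.
#' @export
ml_prioritize <- function(topology, seed = 1, ratio = 0.7, percentile = 70,
                          grids = default_grids(),
                          label_basis = c("degree_centrality", "betweenness",
                                          "closeness"),
                          holdout_label_features = FALSE) {
  features <- minmax_scale(build_features(topology))
  lab <- make_labels(features, percentile = percentile, basis = label_basis)
  clf_features <- features
  if (holdout_label_features) {
    clf_features <- features[, setdiff(colnames(features), label_basis),
                             drop = FALSE]
  }
  split <- split_data(clf_features, lab$labels, ratio = ratio, seed = seed)
  models <- train_models(split$train, grids = grids, seed = seed)
  report <- evaluate_models(models, split, clf_features, lab$labels,
                            seed = seed)
  scores <- ensemble_score(features, lab$composite, seed = seed)
  list(scaled = features, labels = lab, split = split, models = models,
       report = report, scores = scores)
}
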