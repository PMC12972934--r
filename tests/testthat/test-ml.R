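# shared fixture: topology of one synthetic 60-node network
local_topology <- local({
  topo <- NULL
  function() {
    if (is.null(topo)) {
      d <- tempfile()
      man <- gen_ppi_network(seed = 400, dir = d, n_nodes = 60)
      topo <<- compute_topology(read_edge_list(man$files$edges))
      unlink(d, recursive = TRUE)
    }
    topo
  }
})

test_that("feature matrix has the fixed 8-column layout without MCC", {
  topo <- local_topology()
  m <- build_features(topo)
  expect_equal(colnames(m), feature_columns())
  expect_equal(nrow(m), nrow(topo))
  expect_false("mcc" %in% colnames(m))
  expect_false(anyNA(m))
  expect_error(build_features(topo[, -2]), "lacks column")
})

test_that("min-max scaling maps each column to [0,1], constants to zero", {
  m <- cbind(a = c(0, 5, 10), b = c(3, 3, 3), c = c(-1, 0, 3))
  expect_message(s <- minmax_scale(m), "constant column")
  expect_equal(s[, "a"], c(0, 0.5, 1), ignore_attr = TRUE)
  expect_equal(s[, "b"], c(0, 0, 0), ignore_attr = TRUE)
  withr::local_seed(5)
  r <- minmax_scale(matrix(stats::rnorm(60), 10, 6,
                           dimnames = list(NULL, letters[1:6])))
  expect_equal(unname(apply(r, 2, min)), rep(0, 6))
  expect_equal(unname(apply(r, 2, max)), rep(1, 6))
})

test_that("percentile labels use linear interpolation and strict exceedance", {
  m <- matrix(rep((1:10) / 10, 3), ncol = 3,
              dimnames = list(letters[1:10],
                              c("degree_centrality", "betweenness",
                                "closeness")))
  lab <- make_labels(m, percentile = 70)
  expect_equal(lab$threshold, 0.73)
  expect_equal(sum(lab$labels), 3)  # 0.8, 0.9, 1.0 exceed
  expect_equal(names(lab$labels)[lab$labels == 1], c("h", "i", "j"))
  # all-equal composites: nothing strictly exceeds the threshold
  m2 <- m; m2[] <- 0.5
  expect_equal(sum(make_labels(m2)$labels), 0)
  expect_error(make_labels(m, percentile = 100), "percentile")
})

test_that("about 30 percent of targets are labeled positive", {
  topo <- local_topology()
  scaled <- minmax_scale(build_features(topo))
  lab <- make_labels(scaled)
  frac <- mean(lab$labels)
  expect_gt(frac, 0.15)
  expect_lte(frac, 0.5)
})

test_that("stratified split has 7:3 sizes, both classes, and is seeded", {
  n <- 126
  x <- matrix(stats::rnorm(n * 3), n, 3,
              dimnames = list(sprintf("T%03d", 1:n), letters[1:3]))
  y <- rep(c(0L, 1L), c(88, 38))
  sp <- split_data(x, y, ratio = 0.7, seed = 9)
  expect_equal(length(sp$train$y), 88)
  expect_equal(length(sp$test$y), 38)
  expect_setequal(unique(sp$train$y), c(0, 1))
  expect_setequal(unique(sp$test$y), c(0, 1))
  # proportional allocation: test positives ~ 38 * 38/126
  expect_equal(sum(sp$test$y), round(38 * 38 / 126))
  sp2 <- split_data(x, y, ratio = 0.7, seed = 9)
  expect_identical(sp$test$idx, sp2$test$idx)
  sp3 <- split_data(x, y, ratio = 0.7, seed = 10)
  expect_false(identical(sp$test$idx, sp3$test$idx))
  expect_error(split_data(x[1:12, ], rep(c(0L, 1L), c(11, 1)), seed = 1),
               "absent")
})

test_that("grid search returns the sole configuration of a singleton grid", {
  withr::local_seed(21)
  x <- matrix(stats::rnorm(200), 50, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(x[, 1] > 0)
  grids <- list(rf = list(ntree = 100, mtry = 2, nodesize = 1),
                xgb = list(nrounds = 30, max_depth = 2, eta = 0.3))
  models <- train_models(list(x = x, y = y), grids = grids, seed = 3)
  expect_equal(models$best$rf, list(ntree = 100, mtry = 2, nodesize = 1))
  expect_equal(models$best$xgb, list(nrounds = 30, max_depth = 2, eta = 0.3))
})

test_that("linearly separable labels are fit exactly on the training set", {
  withr::local_seed(22)
  x <- matrix(stats::runif(300), 75, 4,
              dimnames = list(NULL, paste0("f", 1:4)))
  y <- as.integer(x[, 1] > 0.5)
  models <- train_models(list(x = x, y = y), seed = 4)
  expect_equal(accuracy_score <- mean(
    as.integer(as.character(predict(models$rf, x))) == y), 1.0)
})

test_that("model report carries metrics in [0,1], gaps and importances", {
  withr::local_seed(23)
  n <- 80
  x <- matrix(stats::runif(n * 4), n, 4,
              dimnames = list(sprintf("T%02d", 1:n), paste0("f", 1:4)))
  y <- as.integer(x[, 1] > 0.6)
  sp <- split_data(x, y, seed = 5)
  models <- train_models(sp$train, seed = 5)
  rep <- evaluate_models(models, sp, x, y, seed = 5)
  for (m in rep$models) {
    metrics <- unlist(m[c("accuracy_train", "f1_train", "accuracy_test",
                          "f1_test", "cv10_f1_mean")])
    expect_true(all(metrics >= 0 & metrics <= 1))
    expect_equal(m$overfit_gap_accuracy, m$accuracy_train - m$accuracy_test)
    expect_equal(m$overfit_gap_f1, m$f1_train - m$f1_test)
    expect_equal(sum(m$feature_importances), 1, tolerance = 1e-6)
  }
})

test_that("F1 of a constant predictor on a mixed set is zero", {
  expect_equal(f1_score(c(0, 1, 1, 0), c(0, 0, 0, 0)), 0)
  expect_equal(f1_score(c(1, 1), c(1, 1)), 1)
})

test_that("ensemble scores span [0,15], rank by score, and are reproducible", {
  topo <- local_topology()
  scaled <- minmax_scale(build_features(topo))
  composite <- make_labels(scaled)$composite
  sc <- ensemble_score(scaled, composite, seed = 7)
  expect_true(all(sc$scaled_score >= 0 & sc$scaled_score <= 15))
  expect_equal(max(sc$scaled_score), 15)
  expect_equal(min(sc$scaled_score), 0)
  expect_equal(sc$rank[1], 1)
  expect_true(all(diff(sc$scaled_score) <= 0))
  # ranking by scaled equals ranking by raw
  expect_equal(order(-sc$raw_ensemble), order(-sc$scaled_score))
  sc2 <- ensemble_score(scaled, composite, seed = 7)
  expect_identical(sc$scaled_score, sc2$scaled_score)
})

test_that("a degenerate constant prediction target is flagged", {
  x <- matrix(stats::runif(40), 20, 2, dimnames = list(NULL, c("a", "b")))
  expect_warning(
    expect_warning(sc <- ensemble_score(x, rep(1, 20), seed = 1),
                   "degenerate"),
    "five or fewer")  # randomForest also notes the constant response
  expect_equal(sc$scaled_score, rep(0, 20))
})

test_that("the full prioritization stage runs end to end and is seeded", {
  topo <- local_topology()
  fit <- ml_prioritize(topo, seed = 31)
  expect_equal(nrow(fit$scores), nrow(topo))
  expect_equal(colnames(fit$split$train$x), feature_columns())
  fit_h <- ml_prioritize(topo, seed = 31, holdout_label_features = TRUE)
  expect_equal(ncol(fit_h$split$train$x), 5)  # label basis excluded
  fit2 <- ml_prioritize(topo, seed = 31)
  expect_identical(fit$scores, fit2$scores)
  expect_identical(fit$report$models$rf$accuracy_test,
                   fit2$report$models$rf$accuracy_test)
})
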