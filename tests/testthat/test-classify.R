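test_that("the train/test split is reproducible and class-complete", {
  tab <- gen_lesion_metrics(3264, seed = 71)
  sp <- split_data(tab, n_train = 3000, seed = 1)
  expect_equal(nrow(sp$train), 3000)
  expect_equal(nrow(sp$test), 264)
  expect_setequal(unique(sp$train$rimla_label), unique(tab$rimla_label))
  expect_setequal(unique(sp$test$rimla_label), unique(tab$rimla_label))
  sp2 <- split_data(tab, n_train = 3000, seed = 1)
  expect_identical(sp$train$lesion_id, sp2$train$lesion_id)
  expect_error(split_data(tab, n_train = 4000), "smaller")
})

test_that("balanced trees train even when a class is rarer than the per-class draw", {
  tab <- gen_lesion_metrics(600, seed = 72,
                            prevalence = c(stable = 0.85, shrinking = 0.05,
                                           enlarging = 0.05, new = 0.05))
  # rarest class ~30 lesions, far below the 250-per-class draw
  fit <- train_balanced_forest(tab, n_trees = 30, per_tree = 1000, seed = 1)
  expect_equal(fit$per_tree, 1000)
  expect_equal(fit$per_class, 250)
  probs <- predict(fit, tab[1:5, ], type = "prob")
  expect_identical(colnames(probs), c("enlarging", "shrinking", "stable", "new"))
  expect_equal(unname(rowSums(probs)), rep(1, 5), tolerance = 1e-9)
  miss <- tab[tab$rimla_label != "new", ]
  expect_error(train_balanced_forest(miss), "missing")
})

test_that("a separable synthetic design is classified perfectly", {
  tab <- gen_lesion_metrics(400, seed = 73)
  # make one feature perfectly separating
  sep <- c(stable = 0, shrinking = 10, enlarging = 20, new = 30)
  tab$T1z_lesion_mean <- sep[tab$rimla_label] + runif(nrow(tab))
  sp <- split_data(tab, n_train = 300, seed = 2)
  fit <- train_balanced_forest(sp$train, n_trees = 100, per_tree = 200, seed = 2)
  yhat <- predict(fit, sp$test, type = "class")
  expect_equal(mean(yhat == sp$test$rimla_label), 1.0)
  rep <- evaluate_classifier(fit, sp$test, n_perm = 200, seed = 2)
  expect_equal(unname(rep$balanced_accuracy), rep(1, 4))
  expect_equal(rep$multiclass_auc, 1.0)
  expect_equal(rep$krippendorff$alpha, 1.0)
  expect_lt(rep$krippendorff$p, 0.05)
})

test_that("label-permuted training yields chance-level agreement", {
  tab <- gen_lesion_metrics(800, seed = 74)
  sp <- split_data(tab, n_train = 600, seed = 3)
  shuffled <- sp$train
  set.seed(99)
  shuffled$rimla_label <- sample(shuffled$rimla_label)
  fit <- train_balanced_forest(shuffled, n_trees = 60, per_tree = 400, seed = 3)
  yhat <- predict(fit, sp$test, type = "class")
  a <- krippendorff_alpha(sp$test$rimla_label, yhat, n_perm = 0)
  expect_lt(abs(a$alpha), 0.1)
})

test_that("permutation importance flags signal and nulls correctly", {
  set.seed(75)
  n <- 500
  tab <- data.frame(
    rimla_label = sample(c("enlarging", "shrinking", "stable", "new"), n, TRUE),
    noise1 = rnorm(n), noise2 = rnorm(n), stringsAsFactors = FALSE)
  shift <- c(enlarging = 0, shrinking = 2, stable = 4, new = 6)
  tab$signal <- shift[tab$rimla_label] + rnorm(n, 0, 0.5)
  sp <- split_data(tab, n_train = 350, seed = 4)
  fit <- train_balanced_forest(sp$train,
                               feature_cols = c("noise1", "noise2", "signal"),
                               n_trees = 80, per_tree = 200, seed = 4)
  imp <- permutation_importance(fit, sp$test, n_perm = 10, seed = 4)
  expect_identical(imp$feature[which.max(imp$importance_mean)], "signal")
  for (f in c("noise1", "noise2")) {
    row <- imp[imp$feature == f, ]
    expect_lt(abs(row$importance_mean), 2 * row$importance_sd + 0.02)
  }
  imp1 <- permutation_importance(fit, sp$test, n_perm = 1, seed = 4)
  expect_true(all(imp1$importance_sd == 0))
})

test_that("per-class balanced accuracy follows its closed forms", {
  y <- rep(c("enlarging", "shrinking"), each = 10)
  expect_equal(unname(balanced_accuracy_per_class(y, y,
                                                  c("enlarging", "shrinking"))),
               c(1, 1))
  const <- rep("enlarging", 20)
  expect_equal(unname(balanced_accuracy_per_class(y, const,
                                                  c("enlarging", "shrinking"))),
               c(0.5, 0.5))
  flip <- rep(c("shrinking", "enlarging"), each = 10)
  expect_equal(unname(balanced_accuracy_per_class(y, flip,
                                                  c("enlarging", "shrinking"))),
               c(0, 0))
})

test_that("multiclass AUC reduces to the binary AUC and has correct limits", {
  set.seed(76)
  y <- sample(c("a", "b"), 200, replace = TRUE)
  score <- rnorm(200) + (y == "a") * 1.2
  probs <- cbind(a = score, b = -score)
  got <- multiclass_auc(probs, y)
  oracle <- as.numeric(pROC::auc(pROC::roc(response = y, predictor = score,
                                           levels = c("b", "a"), direction = "<",
                                           quiet = TRUE)))
  expect_equal(got, oracle, tolerance = 1e-10)
  # perfectly ordered probabilities
  y4 <- rep(c("a", "b", "c", "d"), each = 25)
  p4 <- t(vapply(y4, function(cl)
    setNames(as.numeric(c("a", "b", "c", "d") == cl), c("a", "b", "c", "d")),
    numeric(4)))
  expect_equal(multiclass_auc(p4, y4), 1.0)
  # probabilities independent of the labels
  pr <- matrix(runif(400 * 4), ncol = 4, dimnames = list(NULL, c("a", "b", "c", "d")))
  yr <- sample(c("a", "b", "c", "d"), 400, replace = TRUE)
  expect_lt(abs(multiclass_auc(pr, yr) - 0.5), 0.05)
})

test_that("Krippendorff alpha matches the hand-built coincidence oracle", {
  expect_equal(krippendorff_alpha(c("A", "A", "B", "B"),
                                  c("A", "A", "B", "B"), n_perm = 0)$alpha, 1)
  # hand computation: o_AA=2, o_AB=o_BA=1, o_BB=4; D_o=0.25, D_e=30/56
  a <- krippendorff_alpha(c("A", "A", "B", "B"), c("A", "B", "B", "B"),
                          n_perm = 0)
  expect_equal(a$alpha, 1 - 0.25 / (30 / 56), tolerance = 1e-12)
  # random relabelling: alpha centred on zero
  set.seed(77)
  y <- sample(c("a", "b", "c", "d"), 200, replace = TRUE)
  null <- vapply(1:200, function(i)
    krippendorff_alpha(y, sample(y), n_perm = 0)$alpha, numeric(1))
  expect_lt(abs(mean(null)), 0.03)
})

test_that("variance inflation factors match their closed forms", {
  set.seed(78)
  # columns exactly orthogonal to each other and to the intercept
  Q <- qr.Q(qr(cbind(1, matrix(rnorm(100 * 3), 100, 3))))[, 2:4]
  colnames(Q) <- c("x1", "x2", "x3")
  expect_equal(unname(vif(Q)), rep(1, 3), tolerance = 1e-10)
  # a pair with exact empirical correlation 0.9
  x1 <- Q[, 1]
  x2 <- 0.9 * x1 + sqrt(1 - 0.81) * Q[, 2]
  X <- cbind(a = x1, b = x2, c = Q[, 3])
  v <- vif(X)
  expect_equal(unname(v["a"]), 1 / (1 - 0.81), tolerance = 1e-9)
  expect_equal(unname(v["b"]), 1 / (1 - 0.81), tolerance = 1e-9)
  # perfect collinearity flagged, not fatal
  X2 <- cbind(a = x1, b = 2 * x1, c = Q[, 3])
  expect_true(is.infinite(vif(X2)["a"]))
  # cross-check against the reference implementation on generic data
  Z <- as.data.frame(matrix(rnorm(200 * 4), 200, 4))
  names(Z) <- paste0("v", 1:4)
  Z$y <- rnorm(200)
  ref <- car::vif(lm(y ~ v1 + v2 + v3 + v4, data = Z))
  expect_equal(unname(vif(Z[, 1:4])), unname(ref), tolerance = 1e-8)
})

test_that("duplicating a feature splits its importance across the copies", {
  set.seed(79)
  n <- 600
  tab <- data.frame(
    rimla_label = sample(c("enlarging", "shrinking", "stable", "new"), n, TRUE),
    stringsAsFactors = FALSE)
  shift <- c(enlarging = 0, shrinking = 1.5, stable = 3, new = 4.5)
  tab$signal <- shift[tab$rimla_label] + rnorm(n, 0, 0.4)
  tab$noise <- rnorm(n)
  sp <- split_data(tab, n_train = 450, seed = 5)
  fit1 <- train_balanced_forest(sp$train, feature_cols = c("signal", "noise"),
                                n_trees = 100, per_tree = 200, seed = 5)
  imp1 <- permutation_importance(fit1, sp$test, n_perm = 15, seed = 5)
  dup <- sp$train; dup$signal2 <- dup$signal
  test_dup <- sp$test; test_dup$signal2 <- test_dup$signal
  fit2 <- train_balanced_forest(dup, feature_cols = c("signal", "signal2", "noise"),
                                n_trees = 100, per_tree = 200, seed = 5)
  imp2 <- permutation_importance(fit2, test_dup, n_perm = 15, seed = 5)
  single <- imp1$importance_mean[imp1$feature == "signal"]
  copies <- imp2$importance_mean[imp2$feature %in% c("signal", "signal2")]
  expect_true(all(copies < single))
  expect_gt(min(copies), 0)
})
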