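.class_order <- c("enlarging", "shrinking", "stable", "new")

#' Train/test split with all classes represented
#'
#' Uniform random split without replacement; the split is redrawn (up to
#' 1000 attempts) until both partitions contain at least one lesion of each
#' class present in the data.
#'
#' @param table feature table with a `rimla_label` column.
#' @param n_train number of training rows.
#' @param seed integer seed.
#' @return List with data frames `train` and `test`.
#' @export
split_data <- function(table, n_train = 3000, seed = 1L) {
  n <- nrow(table)
  if (n_train >= n) stop("n_train must be smaller than the number of lesions")
  cls <- unique(table$rimla_label)
  set.seed(seed)
  for (i in seq_len(1000)) {
    idx <- sample.int(n, n_train)
    tr <- table[idx, , drop = FALSE]
    te <- table[-idx, , drop = FALSE]
    if (all(cls %in% tr$rimla_label) && all(cls %in% te$rimla_label))
      return(list(train = tr, test = te))
  }
  stop("could not draw a split with every class in both partitions")
}

#' Balanced random forest for lesion-class prediction
#'
#' Random forest in which every tree is grown on a balanced bootstrap draw:
#' `per_tree` lesions per tree, `per_tree / 4` drawn with replacement from
#' each of the four classes regardless of the training prevalences. Class
#' probabilities are exposed for downstream ROC analysis.
#'
#' @param train training feature table (`rimla_label` + feature columns).
#' @param feature_cols predictor column names (default: the 18 z metrics,
#'   volume, and a binary phenotype indicator if present).
#' @param n_trees number of trees.
#' @param per_tree lesions drawn per tree (split equally over classes).
#' @param seed integer seed.
#' @return Object of class `lesion_forest` wrapping the fitted forest, the
#'   class order and the feature columns.
#' @export
train_balanced_forest <- function(train, feature_cols = NULL, n_trees = 500,
                                  per_tree = 1000, seed = 1L) {
  cls <- intersect(.class_order, unique(train$rimla_label))
  if (length(setdiff(unique(train$rimla_label), .class_order)) > 0)
    stop("unknown class labels in training data")
  if (!all(.class_order %in% train$rimla_label))
    stop("every class must be present in the training set; missing: ",
         paste(setdiff(.class_order, train$rimla_label), collapse = ", "))
  if (is.null(feature_cols)) feature_cols <- .default_feature_cols(train)
  y <- factor(train$rimla_label, levels = .class_order)
  x <- .predictor_matrix(train, feature_cols)
  per_class <- floor(per_tree / length(.class_order))
  pools <- lapply(.class_order, function(cl) which(y == cl))
  set.seed(seed)
  # each tree is grown on its own balanced bootstrap draw (with replacement)
  # so the per-tree class composition is 25% each whatever the training
  # prevalences; the tree itself then uses the draw verbatim
  trees <- lapply(seq_len(n_trees), function(t) {
    idx <- unlist(lapply(pools, function(p) sample(p, per_class, replace = TRUE)))
    randomForest::randomForest(x = x[idx, , drop = FALSE], y = y[idx],
                               ntree = 1, replace = FALSE,
                               sampsize = length(idx))
  })
  rf <- do.call(randomForest::combine, trees)
  structure(list(model = rf, classes = .class_order,
                 feature_cols = feature_cols,
                 per_tree = per_class * length(.class_order),
                 per_class = per_class),
            class = "lesion_forest")
}

.default_feature_cols <- function(tab) {
  cols <- intersect(c(feature_columns(), "volume_uL"), names(tab))
  if ("phenotype" %in% names(tab)) cols <- c(cols, "phenotype")
  cols
}

.predictor_matrix <- function(tab, feature_cols) {
  x <- tab[, feature_cols, drop = FALSE]
  if ("phenotype" %in% feature_cols)
    x$phenotype <- as.numeric(factor(x$phenotype)) - 1
  as.matrix(x)
}

#' @export
print.lesion_forest <- function(x, ...) {
  cat(sprintf("Balanced random forest: %d trees, %d lesions/tree (balanced), %d features\n",
              x$model$ntree, x$per_tree, length(x$feature_cols)))
  invisible(x)
}

#' @export
predict.lesion_forest <- function(object, newdata,
                                  type = c("prob", "class"), ...) {
  type <- match.arg(type)
  x <- .predictor_matrix(newdata, object$feature_cols)
  if (type == "prob") predict(object$model, x, type = "prob")
  else as.character(predict(object$model, x, type = "response"))
}

#' Permutation variable importance on held-out data
#'
#' Importance of a feature is the drop in overall held-out classification
#' accuracy when that feature's column is randomly permuted; the mean and
#' standard deviation over `n_perm` permutations are reported.
#'
#' @param model a [train_balanced_forest()] fit.
#' @param data evaluation table (typically the test set).
#' @param n_perm number of permutations.
#' @param seed integer seed.
#' @return Data frame with `feature`, `importance_mean`, `importance_sd`,
#'   ordered as the model's feature columns.
#' @export
permutation_importance <- function(model, data, n_perm = 50, seed = 1L) {
  y <- data$rimla_label
  base_acc <- mean(predict(model, data, type = "class") == y)
  set.seed(seed)
  drops <- matrix(NA_real_, n_perm, length(model$feature_cols),
                  dimnames = list(NULL, model$feature_cols))
  for (p in seq_len(n_perm)) {
    for (f in model$feature_cols) {
      perm <- data
      perm[[f]] <- perm[[f]][sample.int(nrow(perm))]
      drops[p, f] <- base_acc - mean(predict(model, perm, type = "class") == y)
    }
  }
  data.frame(feature = model$feature_cols,
             importance_mean = colMeans(drops),
             importance_sd = if (n_perm > 1) apply(drops, 2, sd) else
               rep(0, ncol(drops)),
             row.names = NULL, stringsAsFactors = FALSE)
}

#' One-vs-rest balanced accuracy per class
#'
#' For each class, the mean of recall (sensitivity) and specificity in the
#' one-vs-rest dichotomy.
#'
#' @param y true labels.
#' @param yhat predicted labels.
#' @param classes class order of the output.
#' @return Named numeric vector of balanced accuracies.
#' @export
balanced_accuracy_per_class <- function(y, yhat, classes = .class_order) {
  classes <- intersect(classes, unique(c(y, yhat)))
  vapply(setNames(classes, classes), function(cl) {
    pos <- y == cl
    recall <- if (any(pos)) mean(yhat[pos] == cl) else NA_real_
    spec <- if (any(!pos)) mean(yhat[!pos] != cl) else NA_real_
    (recall + spec) / 2
  }, numeric(1))
}

# rank-based two-class AUC of scores for the positive class
.binary_auc <- function(scores_pos, scores_neg) {
  r <- rank(c(scores_pos, scores_neg), ties.method = "average")
  n1 <- length(scores_pos); n2 <- length(scores_neg)
  (sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2) / (n1 * n2)
}

#' Multiclass area under the ROC curve (pairwise average)
#'
#' The multiclass AUC is the average over all unordered class pairs (i, j)
#' of `(A(i|j) + A(j|i)) / 2`, where `A(i|j)` is the rank-based AUC of the
#' class-i probability column restricted to observations of classes i and
#' j; ties receive half credit. For two classes this reduces to the
#' standard binary AUC.
#'
#' @param probs numeric matrix of class probabilities, columns named by
#'   class.
#' @param y true labels.
#' @return A single fraction in \[0, 1\].
#' @export
multiclass_auc <- function(probs, y) {
  classes <- intersect(colnames(probs), unique(y))
  if (length(classes) < 2) stop("need at least 2 classes present")
  pairs <- combn(classes, 2)
  mean(apply(pairs, 2, function(pr) {
    i <- pr[1]; j <- pr[2]
    a_ij <- .binary_auc(probs[y == i, i], probs[y == j, i])
    a_ji <- .binary_auc(probs[y == j, j], probs[y == i, j])
    (a_ij + a_ji) / 2
  }))
}

#' Krippendorff's alpha for nominal agreement between two label vectors
#'
#' Chance-corrected agreement `alpha = 1 - D_o / D_e` computed from the
#' coincidence matrix of the two codings (nominal difference function),
#' with a one-sided permutation p value for alpha > 0 obtained by permuting
#' the second coding.
#'
#' @param y,yhat label vectors of equal length.
#' @param n_perm number of permutations for the p value (0 skips it).
#' @param seed integer seed for the permutation test.
#' @return List with `alpha` and `p` (`NA` if `n_perm == 0`).
#' @export
krippendorff_alpha <- function(y, yhat, n_perm = 10000, seed = 1L) {
  stopifnot(length(y) == length(yhat))
  alpha_of <- function(a, b) {
    lev <- sort(unique(c(a, b)))
    af <- factor(a, lev); bf <- factor(b, lev)
    # coincidence matrix: each unit contributes both ordered pairs
    o <- table(af, bf) + t(table(af, bf))
    n_c <- rowSums(o)
    n <- sum(o)
    d_o <- (n - sum(diag(o))) / n
    d_e <- (sum(outer(n_c, n_c)) - sum(n_c^2)) / (n * (n - 1))
    if (d_e == 0) return(1)
    1 - d_o / d_e
  }
  a <- alpha_of(y, yhat)
  p <- NA_real_
  if (n_perm > 0) {
    set.seed(seed)
    null <- vapply(seq_len(n_perm), function(i)
      alpha_of(y, sample(yhat)), numeric(1))
    p <- (1 + sum(null >= a)) / (n_perm + 1)
  }
  list(alpha = a, p = p)
}

#' Variance inflation factors
#'
#' `VIF_j = 1 / (1 - R^2_j)` where `R^2_j` is from the ordinary regression
#' of predictor j on all remaining predictors. Perfectly collinear
#' predictors are reported as `Inf` rather than raising an error.
#'
#' @param X numeric matrix or data frame of predictors (columns named).
#' @return Named numeric vector of VIFs (all >= 1).
#' @export
vif <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2) stop("need at least 2 predictors")
  vapply(setNames(seq_len(ncol(X)), colnames(X)), function(j) {
    yj <- X[, j]
    Z <- cbind(1, X[, -j, drop = FALSE])
    res <- qr.resid(qr(Z), yj)
    tss <- sum((yj - mean(yj))^2)
    if (tss == 0) return(1)
    r2 <- 1 - sum(res^2) / tss
    if (r2 >= 1 - 1e-12) Inf else max(1, 1 / (1 - r2))
  }, numeric(1))
}

#' Evaluate a lesion classifier on held-out data
#'
#' Computes the confusion matrix, overall accuracy, per-class balanced
#' accuracy, pairwise-average multiclass AUC and Krippendorff's alpha with
#' its permutation p value.
#'
#' @param model a [train_balanced_forest()] fit.
#' @param test held-out feature table.
#' @param n_perm permutations for the alpha p value.
#' @param seed integer seed.
#' @return Object of class `classifier_report`.
#' @export
evaluate_classifier <- function(model, test, n_perm = 10000, seed = 1L) {
  y <- test$rimla_label
  probs <- predict(model, test, type = "prob")
  yhat <- predict(model, test, type = "class")
  ka <- krippendorff_alpha(y, yhat, n_perm = n_perm, seed = seed)
  cm <- table(truth = factor(y, model$classes),
              predicted = factor(yhat, model$classes))
  structure(list(
    accuracy = mean(yhat == y),
    balanced_accuracy = balanced_accuracy_per_class(y, yhat, model$classes),
    multiclass_auc = multiclass_auc(probs, y),
    krippendorff = ka,
    confusion = cm,
    auc_method = "pairwise-average (Hand-Till) multiclass AUC",
    n_test = length(y)), class = "classifier_report")
}

#' @export
print.classifier_report <- function(x, ...) {
  cat(sprintf("Classifier report (n = %d test lesions)\n", x$n_test))
  cat(sprintf("  overall accuracy: %.3f;  multiclass AUC: %.3f\n",
              x$accuracy, x$multiclass_auc))
  ba <- sprintf("%s %.0f%%", names(x$balanced_accuracy),
                100 * x$balanced_accuracy)
  cat("  balanced accuracy:", paste(ba, collapse = ", "), "\n")
  cat(sprintf("  Krippendorff alpha: %.3f (permutation p = %.2g)\n",
              x$krippendorff$alpha, x$krippendorff$p))
  invisible(x)
}
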