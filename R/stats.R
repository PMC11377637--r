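#' Holm step-down adjustment
#'
#' Orders p values ascending, multiplies the i-th by `m - i + 1`, enforces
#' monotonicity with a running maximum, caps at 1 and returns the values in
#' the original order (delegates to [stats::p.adjust()]).
#'
#' @param pvals numeric vector of raw p values.
#' @return Adjusted p values, same order as the input.
#' @export
holm_adjust <- function(pvals) p.adjust(pvals, method = "holm")

# build the design for class + nuisance factors, dropping single-level terms
.art_design <- function(classes, patients, phenotypes) {
  df <- data.frame(.class = factor(classes))
  terms <- ".class"
  if (!is.null(phenotypes) && length(unique(phenotypes)) > 1) {
    df$.phen <- factor(phenotypes)
    terms <- c(terms, ".phen")
  }
  if (!is.null(patients) && length(unique(patients)) > 1) {
    df$.pat <- factor(patients)
    terms <- c(terms, ".pat")
  }
  X <- model.matrix(stats::reformulate(terms), df)
  list(X = X, nuisance = grepl("^\\.phen|^\\.pat", colnames(X)),
       class_cols = grepl("^\\.class", colnames(X)), df = df, terms = terms)
}

#' Aligned-rank-transform ANOVA for the lesion-class effect
#'
#' Nonparametric factorial ANOVA in the classical aligned-rank construction:
#' the response is aligned for the class effect by subtracting the additive
#' least-squares estimates of the patient and disease-course (phenotype)
#' effects, the aligned values are ranked (mid-ranks for ties), and a
#' fixed-effects ANOVA with the same factors is run on the ranks. The F
#' ratio and p value refer to the class effect, adjusted for the nuisance
#' factors; the effect size is the partial eta squared
#' `SS_class / (SS_class + SS_resid)` on the ranked aligned response.
#' With a single patient and a single phenotype the procedure reduces to a
#' one-way ANOVA on plain ranks.
#'
#' @param values numeric response (one z-score metric per lesion).
#' @param classes lesion class per observation (factor or character).
#' @param patients,phenotypes optional nuisance factors (patient id,
#'   RR/SP disease course).
#' @param posthoc if `TRUE`, Holm-adjusted pairwise rank-sum comparisons
#'   between all class pairs are included.
#' @return An object of class `art_anova`: list with `F`, `df`, `p`,
#'   `eta_sq`, `group_medians`, `group_iqr`, `n`, and optionally `posthoc`.
#' @export
art_anova <- function(values, classes, patients = NULL, phenotypes = NULL,
                      posthoc = TRUE) {
  ok <- is.finite(values)
  values <- values[ok]
  classes <- as.character(classes)[ok]
  if (!is.null(patients)) patients <- as.character(patients)[ok]
  if (!is.null(phenotypes)) phenotypes <- as.character(phenotypes)[ok]

  tab <- table(classes)
  small <- names(tab)[tab < 2]
  if (length(small) > 0) {
    warning("dropping class(es) with < 2 observations: ",
            paste(small, collapse = ", "))
    keep <- !(classes %in% small)
    values <- values[keep]; classes <- classes[keep]
    if (!is.null(patients)) patients <- patients[keep]
    if (!is.null(phenotypes)) phenotypes <- phenotypes[keep]
  }
  if (length(unique(classes)) < 2)
    stop("need at least 2 classes with at least 2 observations each")

  des <- .art_design(classes, patients, phenotypes)
  qrX <- qr(des$X)
  beta <- qr.coef(qrX, values)
  beta[is.na(beta)] <- 0
  nuis <- des$X[, des$nuisance, drop = FALSE] %*% beta[des$nuisance]
  aligned <- values - as.vector(nuis)
  r <- rank(aligned, ties.method = "average")

  # rank-stage fixed-effects ANOVA: class F adjusted for nuisance factors
  fit_full <- lm.fit(des$X, r)
  rss_full <- sum(fit_full$residuals^2)
  X_red <- des$X[, !des$class_cols, drop = FALSE]
  fit_red <- lm.fit(X_red, r)
  rss_red <- sum(fit_red$residuals^2)
  df_class <- qrX$rank - qr(X_red)$rank
  df_resid <- length(r) - qrX$rank
  ss_class <- rss_red - rss_full
  Fstat <- (ss_class / df_class) / (rss_full / df_resid)
  p <- pf(Fstat, df_class, df_resid, lower.tail = FALSE)
  eta <- ss_class / (ss_class + rss_full)

  med <- tapply(values, classes, median)
  iqr <- tapply(values, classes, IQR)
  out <- list(F = Fstat, df = c(df_class, df_resid), p = p, eta_sq = eta,
              group_medians = med, group_iqr = iqr, n = length(values))
  if (posthoc) out$posthoc <- posthoc_pairwise(r, classes)
  class(out) <- "art_anova"
  out
}

#' @export
print.art_anova <- function(x, ...) {
  cat(sprintf("Aligned-rank ANOVA: F(%d, %d) = %.2f, p = %.3g, partial eta^2 = %.3f\n",
              x$df[1], x$df[2], x$F, x$p, x$eta_sq))
  med <- sprintf("%s %.2f [%.2f]", names(x$group_medians),
                 x$group_medians, x$group_iqr)
  cat("  medians [IQR]:", paste(med, collapse = ", "), "\n")
  if (!is.null(x$posthoc)) {
    sig <- x$posthoc$p_adj < 0.05
    cat(sprintf("  post-hoc: %d/%d pairs significant at p_adj < 0.05\n",
                sum(sig), length(sig)))
  }
  invisible(x)
}

#' Holm-adjusted pairwise class comparisons
#'
#' Two-sided rank-sum tests between all pairs of classes on the supplied
#' (typically aligned-and-ranked) values, Holm-corrected over the pairs.
#'
#' @param values numeric response.
#' @param classes class label per observation.
#' @param adjust correction method (Holm).
#' @return Data frame with `class1`, `class2`, `p` and `p_adj`.
#' @export
posthoc_pairwise <- function(values, classes, adjust = "holm") {
  cls <- sort(unique(as.character(classes)))
  pairs <- combn(cls, 2)
  p <- apply(pairs, 2, function(pr) {
    wilcox.test(values[classes == pr[1]], values[classes == pr[2]],
                exact = FALSE, correct = TRUE)$p.value
  })
  data.frame(class1 = pairs[1, ], class2 = pairs[2, ], p = p,
             p_adj = p.adjust(p, method = adjust),
             stringsAsFactors = FALSE)
}

#' Aligned-rank ANOVA over a family of metrics
#'
#' Runs [art_anova()] for each metric column of a feature table and Holm
#' adjusts the class-effect p values across the metric family, mirroring
#' the layout of a per-metric results table.
#'
#' @param features feature table from [build_feature_table()] or
#'   [gen_lesion_metrics()].
#' @param metrics metric column names (default: the 18 z metrics + volume).
#' @param class_col,patient_col,phenotype_col column names.
#' @return Data frame with one row per metric: `F`, `p`, `p_adj`, `eta_sq`
#'   and per-class medians.
#' @export
art_anova_table <- function(features,
                            metrics = intersect(c(feature_columns(), "volume_uL"),
                                                names(features)),
                            class_col = "rimla_label",
                            patient_col = "patient_id",
                            phenotype_col = "phenotype") {
  res <- lapply(metrics, function(m) {
    a <- art_anova(features[[m]], features[[class_col]],
                   features[[patient_col]], features[[phenotype_col]],
                   posthoc = FALSE)
    data.frame(metric = m, F = a$F, p = a$p, eta_sq = a$eta_sq,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  out$p_adj <- holm_adjust(out$p)
  out[, c("metric", "F", "p", "p_adj", "eta_sq")]
}

#' Wilcoxon comparison of metric distributions between disease courses
#'
#' Within each lesion class, compares the metric between the
#' relapsing-remitting and secondary-progressive subgroups with a two-sided
#' rank-sum test (normal approximation with tie correction) and Holm
#' adjusts over the family of tests performed.
#'
#' @param values numeric metric values.
#' @param phenotype RR/SP (or any two-level) subgroup label per observation.
#' @param classes lesion class per observation.
#' @return Data frame with `class`, `n_RR` and `n_SP` style counts, `W`,
#'   `p` and Holm-adjusted `p_adj`.
#' @export
subgroup_wilcoxon <- function(values, phenotype, classes) {
  phenotype <- as.character(phenotype)
  lv <- sort(unique(phenotype))
  if (length(lv) != 2) stop("phenotype must have exactly 2 levels, got ",
                            length(lv))
  cls <- sort(unique(as.character(classes)))
  rows <- lapply(cls, function(cl) {
    x <- values[classes == cl & phenotype == lv[1]]
    y <- values[classes == cl & phenotype == lv[2]]
    x <- x[is.finite(x)]; y <- y[is.finite(y)]
    if (length(x) == 0 || length(y) == 0)
      stop("empty subgroup for class ", cl)
    wt <- wilcox.test(x, y, exact = FALSE, correct = FALSE)
    data.frame(class = cl, n1 = length(x), n2 = length(y),
               W = unname(wt$statistic), p = wt$p.value,
               stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  out$p_adj <- holm_adjust(out$p)
  out
}
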