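#' Fit a voxelwise normative atlas
#'
#' Fits, independently at every voxel and for every modality, the ordinary
#' least-squares regression
#' `E(X) = beta0 + beta_sex * sex + beta_age * age_c + beta_age2 * age_c^2`
#' with sex binary (1 = male) and age centred at `age_center` (the cohort
#' mean age by default). The per-voxel residual standard deviation (denominator
#' `n - 4`) is retained as the normative spread used for z-scoring. Voxels
#' where the spread is below `sigma_eps` (e.g. a noise-free fit) or where the
#' design is rank deficient are flagged invalid.
#'
#' @param cohort list of subjects, each `list(maps, age, sex)` with `maps` a
#'   named list of 3-D arrays on one common grid (see [gen_healthy_cohort()]).
#' @param age_center centring constant in years; cohort mean age if `NULL`.
#' @param sigma_eps validity threshold on the residual SD, native units.
#' @return An object of class `normative_atlas` with, per modality, the four
#'   coefficient volumes, the residual-spread volume and a validity mask,
#'   plus `age_center` and `n_subjects`.
#' @export
fit_atlas <- function(cohort, age_center = NULL, sigma_eps = 1e-6) {
  n <- length(cohort)
  if (n < 5) stop("at least 5 subjects are required (4 coefficients + spread)")
  ages <- vapply(cohort, `[[`, numeric(1), "age")
  sexes <- vapply(cohort, `[[`, numeric(1), "sex")
  if (is.null(age_center)) age_center <- mean(ages)
  age_c <- ages - age_center
  X <- cbind(1, sexes, age_c, age_c^2)
  colnames(X) <- c("beta0", "beta_sex", "beta_age", "beta_age2")
  qrX <- qr(X)
  rank_ok <- qrX$rank == 4L
  if (!rank_ok)
    warning("rank-deficient design (e.g. single sex or single age); ",
            "all voxels flagged invalid")

  modalities <- names(cohort[[1]]$maps)
  dims <- dim(cohort[[1]]$maps[[1]])
  per_mod <- lapply(modalities, function(mod) {
    Y <- vapply(cohort, function(s) as.vector(s$maps[[mod]]),
                numeric(prod(dims)))        # V x n
    Y <- t(Y)                               # n x V
    beta <- qr.coef(qrX, Y)
    beta[is.na(beta)] <- 0
    res <- Y - X %*% beta
    sigma <- sqrt(colSums(res^2) / (n - 4))
    valid <- rank_ok & (sigma >= sigma_eps)
    list(beta = lapply(setNames(seq_len(4), colnames(X)),
                       function(k) array(beta[k, ], dims)),
         sigma = array(sigma, dims),
         valid = array(valid, dims))
  })
  names(per_mod) <- modalities
  structure(list(modalities = per_mod, age_center = age_center,
                 n_subjects = n, dim = dims),
            class = "normative_atlas")
}

#' @export
print.normative_atlas <- function(x, ...) {
  cat(sprintf("Normative atlas: %s grid, %d subjects, age centred at %.1f y\n",
              paste(x$dim, collapse = "x"), x$n_subjects, x$age_center))
  for (mod in names(x$modalities)) {
    v <- x$modalities[[mod]]$valid
    cat(sprintf("  %-5s valid voxels: %d/%d\n", mod, sum(v), length(v)))
  }
  invisible(x)
}

#' Expected normative map for a subject
#'
#' Evaluates the fitted voxelwise regression at the given age and sex.
#'
#' @param object a [fit_atlas()] result.
#' @param modality modality name present in the atlas.
#' @param age,sex subject covariates (sex binary, 1 = male).
#' @param ... unused.
#' @return 3-D array of expected values in native units.
#' @export
predict.normative_atlas <- function(object, modality, age, sex, ...) {
  m <- object$modalities[[modality]]
  if (is.null(m)) stop("unknown modality: ", modality)
  age_c <- age - object$age_center
  m$beta$beta0 + m$beta$beta_sex * sex + m$beta$beta_age * age_c +
    m$beta$beta_age2 * age_c^2
}

#' Voxelwise z-score deviation map
#'
#' Converts a patient quantitative map into deviations from the normative
#' model, `z = (x - E(X | age, sex)) / sigma`, with invalid atlas voxels set
#' to `NA`.
#'
#' @param map 3-D array on the atlas grid.
#' @param atlas a [fit_atlas()] result.
#' @param modality modality of `map`.
#' @param age,sex patient covariates.
#' @return A list of class `zscore_map` with elements `z` (array), `modality`,
#'   `age`, `sex`.
#' @export
zscore <- function(map, atlas, modality, age, sex) {
  stopifnot(inherits(atlas, "normative_atlas"), all(dim(map) == atlas$dim))
  m <- atlas$modalities[[modality]]
  if (is.null(m)) stop("unknown modality: ", modality)
  expected <- predict(atlas, modality, age, sex)
  z <- (map - expected) / m$sigma
  z[!m$valid] <- NA_real_
  structure(list(z = z, modality = modality, age = age, sex = sex),
            class = "zscore_map")
}

#' @export
print.zscore_map <- function(x, ...) {
  v <- x$z[is.finite(x$z)]
  cat(sprintf("z-score map (%s), %s grid; %d finite voxels, mean %.3f, sd %.3f\n",
              x$modality, paste(dim(x$z), collapse = "x"),
              length(v), mean(v), sd(v)))
  invisible(x)
}

#' Voxelwise T2-over-T1 ratio map
#'
#' @param t2,t1 co-registered 3-D arrays on the same grid (ms).
#' @return 3-D array of T2/T1; voxels with non-positive or non-finite T1
#'   are `NA`.
#' @export
t2t1_ratio <- function(t2, t1) {
  stopifnot(all(dim(t2) == dim(t1)))
  out <- t2 / t1
  out[!is.finite(t1) | t1 <= 0] <- NA_real_
  out
}

#' Mutual information of two maps from their joint histogram
#'
#' Estimates the mutual information (in nats) over jointly finite voxels.
#' Binning is equal-width over each map's finite range by default;
#' `binning = "quantile"` uses equal-count bins, which makes the estimate
#' invariant to monotone intensity rescaling. Empty bins contribute zero.
#'
#' @param a,b arrays of identical dimension.
#' @param bins number of histogram bins per axis.
#' @param binning `"width"` or `"quantile"`.
#' @return Non-negative mutual information in nats.
#' @export
mutual_information <- function(a, b, bins = 64, binning = c("width", "quantile")) {
  stopifnot(all(dim(a) == dim(b)))
  binning <- match.arg(binning)
  ok <- is.finite(a) & is.finite(b)
  av <- as.vector(a[ok]); bv <- as.vector(b[ok])
  if (length(av) == 0) stop("no jointly finite voxels")
  cut1 <- function(x) {
    if (binning == "width") {
      br <- seq(min(x), max(x), length.out = bins + 1)
    } else {
      br <- unique(quantile(x, probs = seq(0, 1, length.out = bins + 1),
                            names = FALSE, type = 7))
    }
    if (length(br) < 2) return(rep(1L, length(x)))
    findInterval(x, br, rightmost.closed = TRUE, all.inside = TRUE)
  }
  joint <- table(cut1(av), cut1(bv))
  pxy <- joint / sum(joint)
  px <- rowSums(pxy); py <- colSums(pxy)
  nz <- pxy > 0
  mi <- sum(pxy[nz] * log(pxy[nz] / outer(px, py)[nz]))
  max(0, mi)
}

#' Registration quality control by mutual-information thresholding
#'
#' Flags subjects whose mutual information falls below the cohort's
#' `percentile`-th percentile (linear interpolation).
#'
#' @param mi_values numeric vector of per-subject mutual information.
#' @param percentile percentile defining the threshold (default 5).
#' @return A list with `threshold` and logical `pass` (fail iff
#'   `mi < threshold`).
#' @export
qc_pass <- function(mi_values, percentile = 5) {
  stopifnot(length(mi_values) >= 1, all(is.finite(mi_values)))
  thr <- unname(quantile(mi_values, percentile / 100, type = 7))
  list(threshold = thr, pass = mi_values >= thr)
}
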