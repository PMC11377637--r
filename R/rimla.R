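#' Match lesions across repeated scans and collect volume tuples
#'
#' Matches individual lesions across co-registered label maps by maximal
#' spatial overlap (at least one shared voxel; ties broken towards the lower
#' label id) against the first scan, then retains only lesions present in
#' every scan with all volumes inside `volume_bounds`.
#'
#' @param label_maps list (length >= 2) of [new_lesion_label_map()] objects
#'   in a common space.
#' @param volume_bounds inclusive volume window in uL.
#' @return Numeric matrix (matched lesion x scan) of volumes in uL; row
#'   names are the reference-scan label ids.
#' @export
match_scan_rescan <- function(label_maps, volume_bounds = c(3, 150)) {
  if (length(label_maps) < 2) stop("at least 2 scans are required")
  ref <- label_maps[[1]]
  ref_ids <- sort(unique(ref$labels[ref$labels > 0]))
  vols <- matrix(NA_real_, length(ref_ids), length(label_maps),
                 dimnames = list(as.character(ref_ids), NULL))
  vols[, 1] <- lesion_volumes(ref)[as.character(ref_ids)]
  for (s in seq_along(label_maps)[-1]) {
    lm_s <- label_maps[[s]]
    vol_s <- lesion_volumes(lm_s)
    for (i in seq_along(ref_ids)) {
      sel <- lm_s$labels[ref$labels == ref_ids[i]]
      sel <- sel[sel > 0]
      if (length(sel) == 0) next
      ov <- table(sel)
      best <- names(ov)[ov == max(ov)]
      best <- min(as.integer(best))        # tie -> lower label id
      vols[i, s] <- vol_s[as.character(best)]
    }
  }
  keep <- apply(vols, 1, function(v) all(is.finite(v)) &&
                  all(v >= volume_bounds[1] & v <= volume_bounds[2]))
  vols[keep, , drop = FALSE]
}

#' Scan-rescan coefficient of variation
#'
#' Per-lesion COV (sample SD over mean of the repeated volume measurements)
#' and the unweighted average COV across lesions, the repeatability proxy
#' propagated into the bootstrap slope analysis.
#'
#' @param quadruplets numeric matrix, lesions in rows and repeated scans in
#'   columns (any number of scans >= 2).
#' @return List with `cov` (per lesion) and `mean_cov`.
#' @export
compute_cov <- function(quadruplets) {
  stopifnot(is.matrix(quadruplets), ncol(quadruplets) >= 2)
  covs <- apply(quadruplets, 1, function(v) sd(v) / mean(v))
  list(cov = covs, mean_cov = mean(covs))
}

#' Synthetic volume draws around observed measurements
#'
#' For each detected timepoint draws `n_synth` values from
#' `N(v(t), cov * v(t))`, resampling non-positive draws so volumes remain
#' physical without biasing the mean near zero.
#'
#' @param volumes observed volumes (uL), `NA` where undetected.
#' @param cov repeatability coefficient of variation.
#' @param n_synth draws per timepoint.
#' @param seed integer seed.
#' @return Matrix `n_synth` x n_detected of draws; the detected timepoint
#'   indices are attached as attribute `timepoints`.
#' @export
simulate_volumes <- function(volumes, cov, n_synth = 100, seed = 1L) {
  stopifnot(cov >= 0)
  det <- which(is.finite(volumes))
  set.seed(seed)
  draws <- vapply(det, function(j) {
    if (cov == 0) rep(volumes[j], n_synth)
    else .rnorm_pos(n_synth, volumes[j], cov * volumes[j])
  }, numeric(n_synth))
  draws <- matrix(draws, nrow = n_synth)
  attr(draws, "timepoints") <- det
  draws
}

#' Bootstrap distribution of the lesion volume slope
#'
#' Repeats `n_boot` times: sample (with replacement) one synthetic
#' observation per timepoint and fit the least-squares line of volume on
#' time. Returns the slope of each fit; the associated intercepts are
#' attached as an attribute.
#'
#' @param draws matrix of synthetic draws (rows = draws, columns =
#'   timepoints), as from [simulate_volumes()].
#' @param times observation times in days (one per column of `draws`).
#' @param n_boot number of bootstrap fits.
#' @param seed integer seed.
#' @return Numeric vector of `n_boot` slopes (uL/day), with attribute
#'   `intercepts`.
#' @export
bootstrap_slopes <- function(draws, times, n_boot = 100, seed = 1L) {
  nt <- ncol(draws)
  stopifnot(length(times) == nt)
  if (nt < 2) stop("slope undefined: fewer than 2 detected timepoints")
  set.seed(seed)
  pick <- matrix(sample.int(nrow(draws), n_boot * nt, replace = TRUE), n_boot, nt)
  V <- matrix(draws[cbind(as.vector(pick), rep(seq_len(nt), each = n_boot))],
              n_boot, nt)
  tc <- times - mean(times)
  slopes <- as.vector(V %*% tc) / sum(tc^2)
  intercepts <- rowMeans(V) - slopes * mean(times)
  attr(slopes, "intercepts") <- intercepts
  slopes
}

#' Classify one lesion from its bootstrap slope distribution
#'
#' Applies the phenotype rules: `new` if detected only at the last
#' timepoint; `discarded` if any other timepoint is missing; otherwise
#' `enlarging` (`shrinking`) when at least `sig_fraction` of bootstrap
#' slopes are positive (negative), else `stable`. The bootstrap p value is
#' the one-sided sign fraction against the null slope,
#' `1 - max(frac > 0, frac < 0)`.
#'
#' @param slopes bootstrap slopes from [bootstrap_slopes()] (may be `NULL`
#'   for new/discarded lesions).
#' @param detected logical detection flag per timepoint.
#' @param sig_fraction inclusive significance threshold (default 0.95).
#' @return An object of class `rimla_fit`: list with `label`,
#'   `median_slope`, `intercept`, `bootstrap_p`, `slope_samples`.
#' @export
classify_lesion <- function(slopes, detected, sig_fraction = 0.95) {
  nt <- length(detected)
  if (!(all(detected) && nt >= 2)) {
    label <- if (detected[nt] && !any(detected[-nt])) "new" else "discarded"
    return(structure(list(label = label, median_slope = NA_real_,
                          intercept = NA_real_, bootstrap_p = NA_real_,
                          slope_samples = NULL),
                     class = "rimla_fit"))
  }
  stopifnot(!is.null(slopes))
  fpos <- mean(slopes > 0)
  fneg <- mean(slopes < 0)
  label <- if (fpos >= sig_fraction) "enlarging"
           else if (fneg >= sig_fraction) "shrinking"
           else "stable"
  structure(list(label = label,
                 median_slope = median(slopes),
                 intercept = median(attr(slopes, "intercepts") %||% NA_real_),
                 bootstrap_p = 1 - max(fpos, fneg),
                 slope_samples = as.vector(slopes)),
            class = "rimla_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' @export
print.rimla_fit <- function(x, ...) {
  if (is.na(x$median_slope)) {
    cat(sprintf("RIMLA fit: %s\n", x$label))
  } else {
    cat(sprintf("RIMLA fit: %s (median slope %.4g uL/day, bootstrap p %.3f)\n",
                x$label, x$median_slope, x$bootstrap_p))
  }
  invisible(x)
}

#' Repeatability-informed longitudinal assessment of lesion volumes
#'
#' The central fitting function. For every lesion series it propagates the
#' scan-rescan repeatability (COV) through the measured volumes by drawing
#' `n_synth` synthetic values per timepoint from
#' `N(v(t), cov * v(t))`, refits the line `v(t) = b0 + b1 t` on `n_boot`
#' bootstrap samples (one synthetic observation per timepoint), and labels
#' the lesion `enlarging` or `shrinking` when at least `sig_fraction` of
#' bootstrap slopes share a sign, `stable` otherwise. Lesions detected only
#' at the last timepoint are `new`; lesions with other missing timepoints
#' are `discarded`. Each lesion uses a random stream derived from
#' `(seed, lesion rank)`, so results do not depend on row order.
#'
#' @param series data frame with columns `lesion_id`, `time_days`,
#'   `volume_uL`, `detected` (see [gen_lesion_series()]).
#' @param cov repeatability coefficient of variation (e.g. from
#'   [compute_cov()]).
#' @param n_synth synthetic draws per timepoint.
#' @param n_boot bootstrap refits per lesion.
#' @param sig_fraction inclusive sign-fraction threshold.
#' @param seed integer master seed.
#' @return An object of class `rimla`: list with `fits` (data frame of
#'   per-lesion label, median slope, intercept and bootstrap p), `counts`
#'   (table of labels), `slope_samples` (matrix lesion x `n_boot`),
#'   and the call parameters.
#' @export
rimla <- function(series, cov, n_synth = 100, n_boot = 100,
                  sig_fraction = 0.95, seed = 1L) {
  stopifnot(all(c("lesion_id", "time_days", "volume_uL", "detected") %in%
                  names(series)), cov >= 0)
  ids <- sort(unique(series$lesion_id))
  fits <- vector("list", length(ids))
  slope_mat <- matrix(NA_real_, length(ids), n_boot,
                      dimnames = list(as.character(ids), NULL))
  for (i in seq_along(ids)) {
    s <- series[series$lesion_id == ids[i], , drop = FALSE]
    s <- s[order(s$time_days), , drop = FALSE]
    if (any(diff(s$time_days) <= 0)) stop("times must be strictly increasing")
    detected <- s$detected & is.finite(s$volume_uL)
    sub_seed <- .substream_seed(seed, i)
    if (all(detected) && length(detected) >= 2) {
      draws <- simulate_volumes(ifelse(detected, s$volume_uL, NA_real_),
                                cov, n_synth, seed = sub_seed)
      slopes <- bootstrap_slopes(draws, s$time_days[detected], n_boot,
                                 seed = sub_seed + 1L)
      fit <- classify_lesion(slopes, detected, sig_fraction)
      slope_mat[i, ] <- fit$slope_samples
    } else {
      fit <- classify_lesion(NULL, detected, sig_fraction)
    }
    fits[[i]] <- data.frame(lesion_id = ids[i], label = fit$label,
                            median_slope = fit$median_slope,
                            intercept = fit$intercept,
                            bootstrap_p = fit$bootstrap_p,
                            stringsAsFactors = FALSE)
  }
  fits <- if (length(fits)) do.call(rbind, fits) else
    data.frame(lesion_id = character(), label = character(),
               median_slope = numeric(), intercept = numeric(),
               bootstrap_p = numeric(), stringsAsFactors = FALSE)
  counts <- table(factor(fits$label,
                         levels = c("enlarging", "shrinking", "stable",
                                    "new", "discarded")))
  structure(list(fits = fits, counts = counts, slope_samples = slope_mat,
                 cov = cov, n_synth = n_synth, n_boot = n_boot,
                 sig_fraction = sig_fraction, seed = seed),
            class = "rimla")
}

#' @export
print.rimla <- function(x, ...) {
  cat(sprintf("RIMLA: %d lesion series, COV %.3f, %d synthetic draws x %d bootstraps\n",
              nrow(x$fits), x$cov, x$n_synth, x$n_boot))
  print(x$counts)
  invisible(x)
}

#' @export
summary.rimla <- function(object, ...) {
  f <- object$fits
  sl <- f$median_slope[is.finite(f$median_slope)]
  out <- list(counts = object$counts,
              slope_quartiles = if (length(sl)) quantile(sl) else NULL,
              cov = object$cov, sig_fraction = object$sig_fraction)
  class(out) <- "summary.rimla"
  out
}

#' @export
print.summary.rimla <- function(x, ...) {
  cat("RIMLA summary\n  label counts:\n")
  print(x$counts)
  if (!is.null(x$slope_quartiles)) {
    cat("  median-slope quartiles (uL/day):\n")
    print(signif(x$slope_quartiles, 4))
  }
  cat(sprintf("  COV %.3f, sign-fraction threshold %.2f\n", x$cov, x$sig_fraction))
  invisible(x)
}

#' @export
coef.rimla <- function(object, ...) {
  setNames(object$fits$median_slope, object$fits$lesion_id)
}

#' Plot bootstrap slope distributions
#'
#' Histogram of the bootstrap slope samples of one lesion (mirroring the
#' slope-distribution panel of the method), or a strip of median slopes by
#' label when `lesion_id` is `NULL`.
#'
#' @param x a [rimla()] fit.
#' @param lesion_id optional lesion to plot.
#' @param ... passed to [graphics::hist()].
#' @export
plot.rimla <- function(x, lesion_id = NULL, ...) {
  if (!is.null(lesion_id)) {
    sl <- x$slope_samples[as.character(lesion_id), ]
    if (all(is.na(sl))) stop("no slope samples for lesion ", lesion_id)
    graphics::hist(sl, main = paste("Bootstrap slopes, lesion", lesion_id),
                   xlab = "slope (uL/day)", ...)
    graphics::abline(v = 0, lty = 2)
  } else {
    f <- x$fits[is.finite(x$fits$median_slope), ]
    graphics::stripchart(median_slope ~ factor(label), data = f,
                         vertical = TRUE, method = "jitter", pch = 16,
                         ylab = "median slope (uL/day)")
    graphics::abline(h = 0, lty = 2)
  }
  invisible(x)
}
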