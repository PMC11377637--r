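#' Configuration for the synthetic-data generators
#'
#' Bundles every parameter the generators need: the voxel grid, the healthy
#' cohort composition, the per-modality normative forward model, the
#' per-phenotype lesion contrasts, the longitudinal series model and the
#' scan-rescan repeatability. Defaults reflect the study conditions the
#' analysis is designed for: a healthy cohort centred at 37.3 years, lesion
#' phenotype prevalences of 62.4/14.6/12.1/10.9 % (stable / shrinking /
#' enlarging / new), lesion-core z-score contrasts taken from the published
#' per-class medians, and a scan-rescan volumetric coefficient of variation
#' of 0.17.
#'
#' @param grid_shape integer(3), voxel grid dimensions.
#' @param voxel_dims numeric(3), voxel size in mm.
#' @param n_healthy number of healthy subjects to simulate.
#' @param age_range numeric(2), uniform age range in years.
#' @param age_center centring constant (years) used by the forward model.
#' @param sex_ratio fraction of female subjects (sex is coded 1 = male).
#' @param modality_models named list (`T1`, `T2`, `T2T1`), each with entries
#'   `beta0`, `beta_sex`, `beta_age`, `beta_age2`, `noise_sd` in native units
#'   (ms for T1/T2, unitless for the ratio).
#' @param lesion_spec named list per phenotype with entries `prevalence`,
#'   `mean_z` (lesion-core z target), `ring1_z` (first-ring z target) and
#'   `sd_z` (voxelwise z spread inside the planted regions).
#' @param series_spec named list per phenotype with entries `slope`
#'   (true volumetric change, uL/day), `n_timepoints` and `interval` (days).
#' @param cov_true true scan-rescan coefficient of variation of volume
#'   measurements.
#' @param seed integer master seed; every generator derives its random
#'   stream from it.
#'
#' @return An object of class `synth_config` (a validated list).
#' @export
synth_config <- function(grid_shape = c(40L, 40L, 40L),
                         voxel_dims = c(1, 1, 1),
                         n_healthy = 50L,
                         age_range = c(20, 60),
                         age_center = 37.3,
                         sex_ratio = 0.6,
                         modality_models = NULL,
                         lesion_spec = NULL,
                         series_spec = NULL,
                         cov_true = 0.17,
                         seed = 1L) {
  if (is.null(modality_models)) {
    modality_models <- list(
      T1   = list(beta0 = 850,   beta_sex = 20,    beta_age = 1.5,
                  beta_age2 = 0.02,   noise_sd = 40),
      T2   = list(beta0 = 80,    beta_sex = 1.5,   beta_age = 0.15,
                  beta_age2 = 0.002,  noise_sd = 5),
      T2T1 = list(beta0 = 0.094, beta_sex = -5e-4, beta_age = -1e-4,
                  beta_age2 = 1e-6,   noise_sd = 0.006)
    )
  }
  if (is.null(lesion_spec)) {
    lesion_spec <- list(
      stable    = list(prevalence = 0.624, mean_z = 4.33, ring1_z = 1.14, sd_z = 1.92),
      shrinking = list(prevalence = 0.146, mean_z = 3.97, ring1_z = 1.41, sd_z = 1.33),
      enlarging = list(prevalence = 0.121, mean_z = 3.84, ring1_z = 1.30, sd_z = 1.51),
      new       = list(prevalence = 0.109, mean_z = 2.77, ring1_z = 0.97, sd_z = 0.98)
    )
  }
  if (is.null(series_spec)) {
    series_spec <- list(
      stable    = list(slope = 0,    n_timepoints = 4L, interval = 182.5),
      shrinking = list(slope = -0.5, n_timepoints = 4L, interval = 182.5),
      enlarging = list(slope = 0.5,  n_timepoints = 4L, interval = 182.5),
      new       = list(slope = 0,    n_timepoints = 4L, interval = 182.5)
    )
  }
  cfg <- list(grid_shape = as.integer(grid_shape), voxel_dims = as.numeric(voxel_dims),
              n_healthy = as.integer(n_healthy), age_range = age_range,
              age_center = age_center, sex_ratio = sex_ratio,
              modality_models = modality_models, lesion_spec = lesion_spec,
              series_spec = series_spec, cov_true = cov_true, seed = as.integer(seed))
  validate_synth_config(cfg)
  class(cfg) <- "synth_config"
  cfg
}

validate_synth_config <- function(cfg) {
  stopifnot(length(cfg$grid_shape) == 3, all(cfg$grid_shape > 0),
            length(cfg$voxel_dims) == 3, all(cfg$voxel_dims > 0))
  prev <- vapply(cfg$lesion_spec, `[[`, numeric(1), "prevalence")
  if (abs(sum(prev) - 1) > 1e-9)
    stop("lesion phenotype prevalences must sum to 1 (got ", sum(prev), ")")
  noise <- vapply(cfg$modality_models, `[[`, numeric(1), "noise_sd")
  spread <- vapply(cfg$lesion_spec, `[[`, numeric(1), "sd_z")
  if (any(noise < 0) || any(spread < 0)) stop("noise and spread parameters must be >= 0")
  if (cfg$cov_true < 0) stop("cov_true must be >= 0")
  invisible(cfg)
}

#' @export
print.synth_config <- function(x, ...) {
  cat("Synthetic-data configuration\n")
  cat(sprintf("  grid %s at %s mm, %d healthy subjects (ages %g-%g, centred %g y)\n",
              paste(x$grid_shape, collapse = "x"),
              paste(x$voxel_dims, collapse = "x"),
              x$n_healthy, x$age_range[1], x$age_range[2], x$age_center))
  prev <- vapply(x$lesion_spec, `[[`, numeric(1), "prevalence")
  cat("  phenotype prevalences:",
      paste(sprintf("%s %.1f%%", names(prev), 100 * prev), collapse = ", "), "\n")
  cat(sprintf("  scan-rescan COV %.3f, seed %d\n", x$cov_true, x$seed))
  invisible(x)
}

.modality_expectation <- function(model, age_c, sex) {
  model$beta0 + model$beta_sex * sex + model$beta_age * age_c +
    model$beta_age2 * age_c^2
}

#' Simulate a healthy reference cohort of quantitative maps
#'
#' Draws ages and sexes, then fills each subject's T1, T2 and T2/T1 maps from
#' the additive forward model `beta0 + beta_sex*sex + beta_age*age_c +
#' beta_age2*age_c^2 + N(0, noise_sd)` with age centred at
#' `cfg$age_center`. This is exactly the generative model the voxelwise
#' normative regression assumes, so [fit_atlas()] applied to the output is a
#' correctly specified fit.
#'
#' @param cfg a [synth_config()].
#' @param seed optional seed overriding `cfg$seed`.
#' @return A list of subjects, each a list with elements `maps` (named list
#'   of 3-D arrays), `age` (years) and `sex` (1 = male, 0 = female).
#' @export
gen_healthy_cohort <- function(cfg, seed = cfg$seed) {
  validate_synth_config(cfg)
  if (cfg$n_healthy < 5)
    stop("at least 5 subjects are required to fit 4 regression coefficients")
  set.seed(seed)
  nvox <- prod(cfg$grid_shape)
  lapply(seq_len(cfg$n_healthy), function(i) {
    age <- runif(1, cfg$age_range[1], cfg$age_range[2])
    sex <- rbinom(1, 1, 1 - cfg$sex_ratio)
    age_c <- age - cfg$age_center
    maps <- lapply(cfg$modality_models, function(m) {
      mu <- .modality_expectation(m, age_c, sex)
      array(mu + rnorm(nvox, 0, m$noise_sd), dim = cfg$grid_shape)
    })
    list(maps = maps, age = age, sex = sex)
  })
}

# three-label head model: 0 background, 1 cortical band, 2 WM + subcortical
.synth_tissue <- function(grid_shape, voxel_dims, band = 2L) {
  cx <- (grid_shape + 1) / 2
  ax <- pmax(grid_shape * voxel_dims * 0.45, 3 * voxel_dims)
  idx <- arrayInd(seq_len(prod(grid_shape)), grid_shape)
  r2 <- ((idx[, 1] - cx[1]) * voxel_dims[1] / ax[1])^2 +
        ((idx[, 2] - cx[2]) * voxel_dims[2] / ax[2])^2 +
        ((idx[, 3] - cx[3]) * voxel_dims[3] / ax[3])^2
  brain <- array(r2 <= 1, dim = grid_shape)
  interior <- brain
  for (i in seq_len(band)) interior <- .erode26(interior)
  tissue <- array(0L, dim = grid_shape)
  tissue[brain] <- 1L
  tissue[interior] <- 2L
  tissue
}

#' Simulate a patient case with planted lesions
#'
#' Generates background maps from the healthy forward model for the patient's
#' age and sex, then plants approximately spherical lesions inside the white
#' matter whose voxelwise z-scores (with respect to the true generating
#' atlas) follow `N(mean_z, sd_z)` for the assigned phenotype, and whose
#' first perilesional ring follows `N(ring1_z, sd_z)`. Lesion centres are
#' kept at pairwise distance of at least `2 * (3.5 + max radius)` mm so rings
#' do not interact, unless `allow_overlap = TRUE`.
#'
#' @param cfg a [synth_config()].
#' @param n_lesions number of lesions to plant.
#' @param age,sex patient covariates; drawn from the config ranges if `NULL`.
#' @param phenotypes optional character vector of phenotypes (one per
#'   lesion); sampled from the configured prevalences when `NULL`.
#' @param volume_range target lesion volumes, uL (uniform draw).
#' @param allow_overlap if `TRUE`, the minimum-separation constraint is
#'   dropped (used to exercise the multi-lesion exclusion rule).
#' @param seed optional seed overriding `cfg$seed`.
#' @return A list with `maps` (named list of arrays), `labels` (a
#'   [lesion_label_map]), `tissue` (integer array: 0 background, 1 cortical
#'   band, 2 white matter/subcortical), `phenotype` (character per lesion),
#'   `age`, `sex`.
#' @export
gen_patient_case <- function(cfg, n_lesions, age = NULL, sex = NULL,
                             phenotypes = NULL, volume_range = c(8, 40),
                             allow_overlap = FALSE, seed = cfg$seed) {
  validate_synth_config(cfg)
  set.seed(seed)
  if (is.null(age)) age <- runif(1, cfg$age_range[1], cfg$age_range[2])
  if (is.null(sex)) sex <- rbinom(1, 1, 1 - cfg$sex_ratio)
  if (is.null(phenotypes)) {
    prev <- vapply(cfg$lesion_spec, `[[`, numeric(1), "prevalence")
    phenotypes <- sample(names(prev), n_lesions, replace = TRUE, prob = prev)
  }
  stopifnot(length(phenotypes) == n_lesions,
            all(phenotypes %in% names(cfg$lesion_spec)))

  tissue <- .synth_tissue(cfg$grid_shape, cfg$voxel_dims)
  # distance of every voxel to the nearest non-WM voxel: a sphere of radius r
  # centred where this exceeds r + 1 voxel is fully inside the eroded WM
  d_inside <- array(
    .edt3d_cpp(as.vector(tissue != 2L), cfg$grid_shape, cfg$voxel_dims),
    dim = cfg$grid_shape)

  radii <- (3 * runif(n_lesions, volume_range[1], volume_range[2]) / (4 * pi))^(1 / 3)
  margin <- max(cfg$voxel_dims)
  min_sep <- 2 * (3.5 + max(radii))
  idx <- arrayInd(seq_len(prod(cfg$grid_shape)), cfg$grid_shape)
  coords <- sweep(idx, 2, cfg$voxel_dims, `*`)

  centres <- matrix(NA_real_, n_lesions, 3)
  placed <- 0L
  for (i in seq_len(n_lesions)) {
    ok <- which(d_inside > radii[i] + margin)
    if (placed > 0 && !allow_overlap) {
      for (k in seq_len(placed)) {
        dd <- sqrt((coords[ok, 1] - centres[k, 1])^2 +
                   (coords[ok, 2] - centres[k, 2])^2 +
                   (coords[ok, 3] - centres[k, 3])^2)
        ok <- ok[dd >= min_sep]
      }
    }
    if (length(ok) == 0)
      stop(sprintf("could not place lesion %d of %d; at most %d lesions fit this grid",
                   i, n_lesions, placed))
    centres[i, ] <- coords[sample(ok, 1), ]
    placed <- i
  }

  labels <- array(0L, dim = cfg$grid_shape)
  for (i in seq_len(n_lesions)) {
    d2 <- sqrt((coords[, 1] - centres[i, 1])^2 + (coords[, 2] - centres[i, 2])^2 +
               (coords[, 3] - centres[i, 3])^2)
    labels[d2 <= radii[i]] <- i
  }

  age_c <- age - cfg$age_center
  maps <- lapply(cfg$modality_models, function(m) {
    mu <- .modality_expectation(m, age_c, sex)
    array(mu + rnorm(prod(cfg$grid_shape), 0, m$noise_sd), dim = cfg$grid_shape)
  })

  # plant lesion-core and first-ring z profiles: value = E + z * sigma_true
  for (i in seq_len(n_lesions)) {
    spec_i <- cfg$lesion_spec[[phenotypes[i]]]
    d2 <- sqrt((coords[, 1] - centres[i, 1])^2 + (coords[, 2] - centres[i, 2])^2 +
               (coords[, 3] - centres[i, 3])^2)
    core <- which(as.vector(labels) == i)
    ring1 <- which(d2 > radii[i] & d2 < radii[i] + 2 & as.vector(labels) == 0L)
    for (mod in names(maps)) {
      m <- cfg$modality_models[[mod]]
      mu <- .modality_expectation(m, age_c, sex)
      z_core <- spec_i$mean_z + rnorm(length(core), 0, spec_i$sd_z)
      maps[[mod]][core] <- mu + z_core * m$noise_sd
      z_ring <- spec_i$ring1_z + rnorm(length(ring1), 0, spec_i$sd_z)
      maps[[mod]][ring1] <- mu + z_ring * m$noise_sd
    }
  }

  list(maps = maps,
       labels = new_lesion_label_map(labels, cfg$voxel_dims),
       tissue = tissue, phenotype = phenotypes, age = age, sex = sex)
}

#' Simulate longitudinal lesion-volume series
#'
#' For each lesion a phenotype is drawn (or given), a true linear volume
#' trajectory `v(t) = v0 + slope * t` (truncated below at 0.5 uL) is built on
#' the configured visit schedule, and observed volumes are drawn from
#' `N(v(t), cov_true * v(t))` with non-positive draws resampled. Lesions of
#' the "new" phenotype are flagged undetected at every timepoint except the
#' last, where a small volume is observed.
#'
#' @param cfg a [synth_config()].
#' @param n_lesions number of series to generate.
#' @param classes optional character vector of true phenotypes.
#' @param baseline_range uniform range of baseline volumes, uL.
#' @param seed optional seed overriding `cfg$seed`.
#' @return A data frame with columns `lesion_id`, `time_days`, `volume_uL`,
#'   `detected`; the true class and slope per lesion are attached as the
#'   `truth` attribute (a data frame).
#' @export
gen_lesion_series <- function(cfg, n_lesions, classes = NULL,
                              baseline_range = c(50, 150), seed = cfg$seed) {
  validate_synth_config(cfg)
  if (cfg$cov_true < 0) stop("cov_true must be >= 0")
  set.seed(seed)
  if (is.null(classes)) {
    prev <- vapply(cfg$lesion_spec, `[[`, numeric(1), "prevalence")
    classes <- sample(names(prev), n_lesions, replace = TRUE, prob = prev)
  }
  stopifnot(length(classes) == n_lesions)
  for (cl in unique(classes)) {
    if (cl != "new" && cfg$series_spec[[cl]]$n_timepoints < 3)
      stop("non-new series need at least 3 timepoints")
  }
  rows <- vector("list", n_lesions)
  truth <- data.frame(lesion_id = sprintf("L%04d", seq_len(n_lesions)),
                      class = classes,
                      slope = vapply(classes, function(cl) cfg$series_spec[[cl]]$slope,
                                     numeric(1)),
                      stringsAsFactors = FALSE)
  for (i in seq_len(n_lesions)) {
    sp <- cfg$series_spec[[classes[i]]]
    times <- (seq_len(sp$n_timepoints) - 1) * sp$interval
    if (classes[i] == "new") {
      v_last <- runif(1, 3, 15)
      v_obs <- rep(NA_real_, length(times))
      v_obs[length(times)] <- if (cfg$cov_true > 0)
        .rnorm_pos(1, v_last, cfg$cov_true * v_last) else v_last
      detected <- c(rep(FALSE, length(times) - 1), TRUE)
    } else {
      v0 <- runif(1, baseline_range[1], baseline_range[2])
      v_true <- pmax(0.5, v0 + sp$slope * times)
      v_obs <- if (cfg$cov_true > 0)
        .rnorm_pos(length(times), v_true, cfg$cov_true * v_true) else v_true
      detected <- rep(TRUE, length(times))
    }
    rows[[i]] <- data.frame(lesion_id = truth$lesion_id[i], time_days = times,
                            volume_uL = v_obs, detected = detected,
                            stringsAsFactors = FALSE)
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "truth") <- truth
  out
}

#' Simulate scan-rescan volume measurements
#'
#' Each lesion gets a true volume (uniform in 3-150 uL) and `n_scans`
#' repeated measurements drawn from `N(v_true, cov_true * v_true)`.
#'
#' @param cfg a [synth_config()].
#' @param n_lesions number of lesions.
#' @param n_scans number of repeated scans (at least 2; the coefficient of
#'   variation is undefined for a single measurement).
#' @param seed optional seed overriding `cfg$seed`.
#' @return A numeric matrix (lesion x scan) with the true volumes attached
#'   as attribute `v_true`.
#' @export
gen_scan_rescan <- function(cfg, n_lesions, n_scans = 4L, seed = cfg$seed) {
  validate_synth_config(cfg)
  if (n_scans < 2) stop("n_scans must be >= 2: COV is undefined for a single scan")
  set.seed(seed)
  v_true <- runif(n_lesions, 3, 150)
  vols <- matrix(NA_real_, n_lesions, n_scans,
                 dimnames = list(sprintf("L%04d", seq_len(n_lesions)),
                                 sprintf("scan%d", seq_len(n_scans))))
  for (i in seq_len(n_lesions)) {
    vols[i, ] <- if (cfg$cov_true > 0)
      .rnorm_pos(n_scans, v_true[i], cfg$cov_true * v_true[i]) else v_true[i]
  }
  attr(vols, "v_true") <- v_true
  vols
}

#' Per-phenotype reference profiles of the microstructural metrics
#'
#' Published per-class medians and interquartile ranges of the 18 z-score
#' metrics (3 modalities x 3 regions x mean/SD) and lesion volume, used as
#' the default targets of [gen_lesion_metrics()].
#'
#' @return A data frame with one row per metric and, per phenotype, columns
#'   `<class>_median` and `<class>_iqr`.
#' @export
class_profiles <- function() {
  m <- c("T1z_lesion_mean", "T1z_lesion_sd", "T1z_ring1_mean", "T1z_ring1_sd",
         "T1z_ring2_mean", "T1z_ring2_sd",
         "T2z_lesion_mean", "T2z_lesion_sd", "T2z_ring1_mean", "T2z_ring1_sd",
         "T2z_ring2_mean", "T2z_ring2_sd",
         "T2T1z_lesion_mean", "T2T1z_lesion_sd", "T2T1z_ring1_mean",
         "T2T1z_ring1_sd", "T2T1z_ring2_mean", "T2T1z_ring2_sd",
         "volume_uL")
  data.frame(
    metric = m,
    stable_median    = c(4.33, 1.92, 1.14, 1.24, 0.39, 0.82,
                         3.10, 1.10, 1.61, 1.13, 0.90, 0.95,
                         -0.41, 0.91, 0.45, 0.95, 0.40, 0.88, 27),
    stable_iqr       = c(2.31, 1.42, 1.02, 0.43, 0.78, 0.28,
                         2.03, 0.89, 1.12, 0.52, 0.94, 0.33,
                         1.21, 0.47, 0.83, 0.31, 0.72, 0.26, 10),
    enlarging_median = c(3.84, 1.51, 1.30, 1.16, 0.56, 0.84,
                         3.01, 0.93, 1.67, 1.13, 0.94, 1.01,
                         -0.27, 0.82, 0.43, 0.91, 0.35, 0.87, 16),
    enlarging_iqr    = c(1.98, 0.93, 1.03, 0.39, 0.82, 0.29,
                         1.74, 0.70, 1.03, 0.52, 0.92, 0.39,
                         1.20, 0.44, 0.85, 0.30, 0.75, 0.27, 21.75),
    shrinking_median = c(3.97, 1.33, 1.41, 1.28, 0.56, 0.86,
                         2.48, 0.72, 1.59, 0.97, 1.00, 0.95,
                         -0.62, 0.72, 0.21, 0.92, 0.31, 0.86, 11),
    shrinking_iqr    = c(2.23, 1.04, 1.12, 0.47, 0.80, 0.28,
                         1.72, 0.55, 1.25, 0.43, 0.98, 0.33,
                         1.23, 0.42, 0.79, 0.29, 0.75, 0.28, 17),
    new_median       = c(2.77, 0.98, 0.97, 1.07, 0.37, 0.81,
                         2.12, 0.60, 1.32, 0.92, 0.76, 0.91,
                         -0.30, 0.62, 0.35, 0.83, 0.35, 0.84, 9),
    new_iqr          = c(2.53, 0.92, 1.13, 0.47, 0.78, 0.30,
                         1.85, 0.54, 1.42, 0.44, 1.08, 0.38,
                         1.27, 0.50, 0.92, 0.29, 0.72, 0.28, 12),
    stringsAsFactors = FALSE
  )
}

#' Simulate a lesion feature table with class-dependent metric distributions
#'
#' Draws per-lesion metric values from normal distributions whose median and
#' IQR match the per-phenotype reference profiles (`sd = IQR / 1.349`), with
#' standard-deviation metrics resampled to stay positive and volumes kept in
#' the 3-150 uL analysis window. Lesions are distributed over patients, and
#' patients over the relapsing-remitting / secondary-progressive disease
#' courses.
#'
#' @param n_lesions number of lesion rows.
#' @param n_patients number of patients lesions are nested in.
#' @param prevalence named phenotype probabilities (defaults to the
#'   configured prevalences of [synth_config()]).
#' @param sp_fraction fraction of patients with secondary-progressive course.
#' @param profiles per-class metric profiles, see [class_profiles()].
#' @param seed integer seed.
#' @return A data frame with `lesion_id`, `patient_id`, `phenotype`
#'   (RR or SP), `rimla_label` (the true class) and the 19 metric columns.
#' @export
gen_lesion_metrics <- function(n_lesions, n_patients = 50,
                               prevalence = NULL, sp_fraction = 32 / 283,
                               profiles = class_profiles(), seed = 1L) {
  set.seed(seed)
  if (is.null(prevalence))
    prevalence <- c(stable = 0.624, shrinking = 0.146, enlarging = 0.121, new = 0.109)
  cls <- sample(names(prevalence), n_lesions, replace = TRUE, prob = prevalence)
  pat <- sample(sprintf("P%03d", seq_len(n_patients)), n_lesions, replace = TRUE)
  course <- setNames(ifelse(runif(n_patients) < sp_fraction, "SP", "RR"),
                     sprintf("P%03d", seq_len(n_patients)))
  out <- data.frame(lesion_id = sprintf("L%05d", seq_len(n_lesions)),
                    patient_id = pat, phenotype = unname(course[pat]),
                    rimla_label = cls, stringsAsFactors = FALSE)
  for (k in seq_len(nrow(profiles))) {
    metric <- profiles$metric[k]
    vals <- numeric(n_lesions)
    for (cl in unique(cls)) {
      sel <- which(cls == cl)
      mu <- profiles[[paste0(cl, "_median")]][k]
      sdv <- profiles[[paste0(cl, "_iqr")]][k] / 1.349
      if (metric == "volume_uL") {
        vals[sel] <- .rnorm_pos(length(sel), mu, sdv, lower = 3)
      } else if (grepl("_sd$", metric)) {
        vals[sel] <- .rnorm_pos(length(sel), mu, sdv, lower = 0)
      } else {
        vals[sel] <- rnorm(length(sel), mu, sdv)
      }
    }
    out[[metric]] <- vals
  }
  out
}
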