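#' Pipeline configuration
#'
#' Single source of all pipeline constants: the analysis thresholds (ring
#' cutoffs, volume window, bootstrap sizes, sign-fraction rule, QC
#' percentile, classifier settings) and the synthetic-scene parameters. The
#' configuration round-trips losslessly through JSON via
#' [write_pipeline_config()] / [read_pipeline_config()].
#'
#' @param ring_cutoffs mm, perilesional ring cutoffs.
#' @param volume_bounds uL, inclusive lesion-volume window.
#' @param n_synth,n_boot synthetic draws and bootstrap refits per lesion.
#' @param sig_fraction inclusive bootstrap sign-fraction threshold.
#' @param mi_percentile registration-QC percentile.
#' @param n_train,per_tree,n_perm,n_trees classifier settings; when
#'   `n_train` is at least the number of available lesions, an 80/20 split
#'   is used instead so small scenes remain runnable.
#' @param grid_shape,voxel_dims,n_healthy,n_patients,lesions_per_patient,
#'   n_scan_rescan synthetic scene size.
#' @param seed master seed; all stage seeds derive from it.
#' @return Object of class `pipeline_config`.
#' @export
pipeline_config <- function(ring_cutoffs = c(2, 3.5),
                            volume_bounds = c(3, 150),
                            n_synth = 100, n_boot = 100,
                            sig_fraction = 0.95, mi_percentile = 5,
                            n_train = 3000, per_tree = 1000,
                            n_perm = 50, n_trees = 500,
                            grid_shape = c(48L, 48L, 48L),
                            voxel_dims = c(1, 1, 1),
                            n_healthy = 30L, n_patients = 12L,
                            lesions_per_patient = 4L,
                            n_scan_rescan = 200L,
                            seed = 1L) {
  cfg <- list(ring_cutoffs = as.numeric(ring_cutoffs),
              volume_bounds = as.numeric(volume_bounds),
              n_synth = as.integer(n_synth), n_boot = as.integer(n_boot),
              sig_fraction = sig_fraction, mi_percentile = mi_percentile,
              n_train = as.integer(n_train), per_tree = as.integer(per_tree),
              n_perm = as.integer(n_perm), n_trees = as.integer(n_trees),
              grid_shape = as.integer(grid_shape),
              voxel_dims = as.numeric(voxel_dims),
              n_healthy = as.integer(n_healthy),
              n_patients = as.integer(n_patients),
              lesions_per_patient = as.integer(lesions_per_patient),
              n_scan_rescan = as.integer(n_scan_rescan),
              seed = as.integer(seed))
  validate_pipeline_config(cfg)
  class(cfg) <- "pipeline_config"
  cfg
}

validate_pipeline_config <- function(cfg) {
  stopifnot(length(cfg$ring_cutoffs) == 2, cfg$ring_cutoffs[1] <= cfg$ring_cutoffs[2],
            all(cfg$ring_cutoffs >= 0),
            length(cfg$volume_bounds) == 2, cfg$volume_bounds[1] <= cfg$volume_bounds[2])
  if (cfg$n_boot < 1) stop("n_boot must be >= 1")
  if (cfg$n_synth < 1) stop("n_synth must be >= 1")
  if (cfg$sig_fraction <= 0.5 || cfg$sig_fraction > 1)
    stop("sig_fraction must be in (0.5, 1]")
  if (cfg$mi_percentile < 0 || cfg$mi_percentile > 100)
    stop("mi_percentile must be in [0, 100]")
  invisible(cfg)
}

#' @export
print.pipeline_config <- function(x, ...) {
  cat("Pipeline configuration\n")
  cat(sprintf("  rings %g/%g mm, volumes [%g, %g] uL, %d x %d bootstrap, >= %.0f%% sign rule\n",
              x$ring_cutoffs[1], x$ring_cutoffs[2], x$volume_bounds[1],
              x$volume_bounds[2], x$n_synth, x$n_boot, 100 * x$sig_fraction))
  cat(sprintf("  scene: %s grid, %d healthy, %d patients x %d lesions, seed %d\n",
              paste(x$grid_shape, collapse = "x"), x$n_healthy,
              x$n_patients, x$lesions_per_patient, x$seed))
  invisible(x)
}

#' Write / read a pipeline configuration as JSON
#'
#' @param cfg a [pipeline_config()].
#' @param path JSON file path.
#' @return `read_pipeline_config()` returns the restored
#'   `pipeline_config`; `write_pipeline_config()` returns `path`
#'   invisibly.
#' @export
write_pipeline_config <- function(cfg, path) {
  jsonlite::write_json(unclass(cfg), path, auto_unbox = FALSE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

#' @rdname write_pipeline_config
#' @export
read_pipeline_config <- function(path) {
  raw <- jsonlite::read_json(path, simplifyVector = TRUE)
  do.call(pipeline_config, raw)
}

#' Write / read quantitative volumes as NIfTI
#'
#' Voxel dimensions are stored in the NIfTI pixdim and restored on read;
#' missing values round-trip as NaN.
#'
#' @param x 3-D array.
#' @param voxel_dims numeric(3), mm.
#' @param path `.nii` or `.nii.gz` file path.
#' @return `read_quantmap()` returns a list with `data` (array, `NaN`
#'   mapped back to `NA`) and `voxel_dims`.
#' @export
write_quantmap <- function(x, voxel_dims, path) {
  img <- RNifti::asNifti(array(as.numeric(x), dim = dim(x)))
  RNifti::pixdim(img) <- voxel_dims
  RNifti::writeNifti(img, path)
  invisible(path)
}

#' @rdname write_quantmap
#' @export
read_quantmap <- function(path) {
  img <- RNifti::readNifti(path)
  arr <- array(as.numeric(img), dim = dim(img))
  arr[is.nan(arr)] <- NA_real_
  list(data = arr, voxel_dims = RNifti::pixdim(img)[seq_len(3)])
}

#' Write / read a lesion label map as NIfTI
#'
#' @param lm a [new_lesion_label_map()].
#' @param path file path.
#' @return `read_label_map()` returns a `lesion_label_map`.
#' @export
write_label_map <- function(lm, path) {
  img <- RNifti::asNifti(array(as.integer(lm$labels), dim = dim(lm$labels)))
  RNifti::pixdim(img) <- lm$voxel_dims
  RNifti::writeNifti(img, path, datatype = "int32")
  invisible(path)
}

#' @rdname write_label_map
#' @export
read_label_map <- function(path) {
  img <- RNifti::readNifti(path)
  new_lesion_label_map(array(as.integer(img), dim = dim(img)),
                       RNifti::pixdim(img)[seq_len(3)])
}

# CSV writer: numeric columns rounded to 9 significant digits
.write_csv9 <- function(df, path) {
  for (j in seq_along(df))
    if (is.numeric(df[[j]])) df[[j]] <- signif(df[[j]], 9)
  write.csv(df, path, row.names = FALSE)
  invisible(path)
}

#' Read a lesion series table from CSV
#'
#' Expects columns `lesion_id`, `time_days`, `volume_uL`, `detected`;
#' parse problems name the offending column.
#'
#' @param path CSV path.
#' @return Data frame suitable for [rimla()].
#' @export
read_series_csv <- function(path) {
  df <- read.csv(path, stringsAsFactors = FALSE)
  need <- c("lesion_id", "time_days", "volume_uL", "detected")
  miss <- setdiff(need, names(df))
  if (length(miss) > 0)
    stop("malformed series CSV ", path, ": missing column(s) ",
         paste(miss, collapse = ", "))
  df$detected <- as.logical(df$detected)
  if (any(is.na(df$detected)))
    stop("malformed series CSV ", path, ": column 'detected' row(s) ",
         paste(head(which(is.na(df$detected))), collapse = ", "),
         " are not logical")
  df
}

#' Run the full synthetic analysis pipeline
#'
#' Executes the stages in dependency order -- simulate, geometry (label,
#' volume filter, rings, white-matter restriction), normative atlas fit,
#' registration QC, z-scoring, repeatability-informed longitudinal
#' classification, feature extraction, aligned-rank ANOVA, and balanced
#' random-forest classification -- writing every stage output plus a
#' manifest (config, seeds, per-stage counts, file checksums) to
#' `out_dir`. Reruns with the same configuration are bit-identical.
#'
#' @param cfg a [pipeline_config()].
#' @param out_dir output directory (created if needed).
#' @return The manifest, invisibly.
#' @export
run_pipeline <- function(cfg, out_dir) {
  validate_pipeline_config(cfg)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  counts <- list()

  scfg <- synth_config(grid_shape = cfg$grid_shape, voxel_dims = cfg$voxel_dims,
                       n_healthy = cfg$n_healthy, cov_true = 0.17,
                       seed = cfg$seed)

  ## stage 1: simulate
  cohort <- gen_healthy_cohort(scfg, seed = .substream_seed(cfg$seed, 1))
  cases <- lapply(seq_len(cfg$n_patients), function(i)
    gen_patient_case(scfg, cfg$lesions_per_patient,
                     seed = .substream_seed(cfg$seed, 100 + i)))
  rescan <- gen_scan_rescan(scfg, cfg$n_scan_rescan,
                            seed = .substream_seed(cfg$seed, 2))
  counts$healthy_subjects <- length(cohort)
  counts$patients <- length(cases)
  counts$lesions_simulated <- sum(vapply(cases, function(cs)
    length(cs$phenotype), integer(1)))

  ## stage 2: repeatability
  cov_hat <- compute_cov(rescan)$mean_cov
  counts$scan_rescan_lesions <- nrow(rescan)
  .write_csv9(data.frame(lesion_id = rownames(rescan), rescan,
                         row.names = NULL), file.path(out_dir, "scan_rescan.csv"))

  ## stage 3: atlas + QC
  atlas <- fit_atlas(cohort, age_center = scfg$age_center)
  template <- Reduce(`+`, lapply(cohort, function(s) s$maps$T1)) / length(cohort)
  mi <- vapply(cases, function(cs) mutual_information(cs$maps$T1, template),
               numeric(1))
  qc <- qc_pass(mi, cfg$mi_percentile)
  counts$qc_failed <- sum(!qc$pass)
  .write_csv9(data.frame(patient = seq_along(mi), mi = mi, pass = qc$pass),
              file.path(out_dir, "qc.csv"))

  ## stages 4-7 per patient: series + RIMLA, geometry, z-scores, features
  all_series <- list(); feature_cases <- list(); rimla_fits <- list()
  excl <- c(volume = 0L, wm = 0L, not_all_timepoints = 0L)
  for (i in seq_along(cases)) {
    if (!qc$pass[i]) next
    cs <- cases[[i]]
    pid <- sprintf("P%03d", i)
    n_les <- length(cs$phenotype)
    series <- gen_lesion_series(scfg, n_les, classes = cs$phenotype,
                                seed = .substream_seed(cfg$seed, 200 + i))
    series$lesion_id <- paste0(pid, "_", series$lesion_id)
    all_series[[i]] <- series
    fit <- rimla(series, cov_hat, n_synth = cfg$n_synth, n_boot = cfg$n_boot,
                 sig_fraction = cfg$sig_fraction,
                 seed = .substream_seed(cfg$seed, 300 + i))
    rimla_fits[[i]] <- fit$fits
    labels_by_lesion <- setNames(fit$fits$label, as.character(seq_len(n_les)))
    excl["not_all_timepoints"] <- excl["not_all_timepoints"] +
      sum(fit$fits$label == "discarded")
    labels_by_lesion[labels_by_lesion == "discarded"] <- NA_character_

    vols <- lesion_volumes(cs$labels)
    kept_vol <- filter_by_volume(vols, cfg$volume_bounds[1], cfg$volume_bounds[2])
    excl["volume"] <- excl["volume"] + (length(vols) - length(kept_vol))
    kept_wm <- restrict_to_wm(cs$labels, cs$tissue)
    excl["wm"] <- excl["wm"] + length(setdiff(kept_vol, kept_wm))

    zmaps <- lapply(setNames(names(cs$maps), names(cs$maps)), function(mod)
      zscore(cs$maps[[mod]], atlas, mod, cs$age, cs$sex))
    feature_cases[[i]] <- list(zmaps = zmaps, labels = cs$labels,
                               tissue = cs$tissue,
                               rimla_labels = labels_by_lesion,
                               patient_id = pid,
                               phenotype = if (i %% 8 == 0) "SP" else "RR")
  }
  feature_cases <- Filter(Negate(is.null), feature_cases)
  series_all <- do.call(rbind, all_series)
  .write_csv9(series_all, file.path(out_dir, "lesion_series.csv"))
  fits_all <- do.call(rbind, rimla_fits)
  .write_csv9(fits_all, file.path(out_dir, "rimla_fits.csv"))
  counts$excluded <- as.list(excl)
  counts$rimla_labels <- as.list(table(fits_all$label))

  suppressMessages(
    features <- build_feature_table(feature_cases,
                                    volume_bounds = cfg$volume_bounds,
                                    cutoffs = cfg$ring_cutoffs))
  counts$feature_rows <- nrow(features)
  .write_csv9(features, file.path(out_dir, "features.csv"))

  ## stage 8: univariate statistics
  stats_tab <- tryCatch(
    suppressWarnings(art_anova_table(features)),
    error = function(e) data.frame(metric = character(), F = numeric(),
                                   p = numeric(), p_adj = numeric(),
                                   eta_sq = numeric()))
  .write_csv9(stats_tab, file.path(out_dir, "art_anova.csv"))
  counts$metrics_tested <- nrow(stats_tab)

  ## stage 9: classification (skipped when a class is absent)
  features <- features[complete.cases(features), , drop = FALSE]
  classify_ok <- all(.class_order %in% features$rimla_label) &&
    nrow(features) >= 20
  if (classify_ok) {
    n_train <- if (cfg$n_train < nrow(features)) cfg$n_train else
      floor(0.8 * nrow(features))
    split <- split_data(features, n_train,
                        seed = .substream_seed(cfg$seed, 400))
    forest <- train_balanced_forest(split$train, n_trees = cfg$n_trees,
                                    per_tree = cfg$per_tree,
                                    seed = .substream_seed(cfg$seed, 401))
    report <- evaluate_classifier(forest, split$test, n_perm = 1000,
                                  seed = .substream_seed(cfg$seed, 402))
    imp <- permutation_importance(forest, split$test, n_perm = cfg$n_perm,
                                  seed = .substream_seed(cfg$seed, 403))
    .write_csv9(imp, file.path(out_dir, "importance.csv"))
    .write_csv9(as.data.frame(report$confusion),
                file.path(out_dir, "confusion.csv"))
    vifs <- vif(.predictor_matrix(features, .default_feature_cols(features)))
    .write_csv9(data.frame(predictor = names(vifs), vif = vifs),
                file.path(out_dir, "vif.csv"))
    counts$classifier <- list(accuracy = report$accuracy,
                              multiclass_auc = report$multiclass_auc,
                              krippendorff_alpha = report$krippendorff$alpha)
  } else {
    counts$classifier <- "skipped: not every class present"
  }

  write_pipeline_config(cfg, file.path(out_dir, "config.json"))

  files <- sort(setdiff(list.files(out_dir), "manifest.json"))
  manifest <- list(
    config = unclass(cfg),
    config_hash = unname(tools::md5sum(file.path(out_dir, "config.json"))),
    seed = cfg$seed,
    counts = counts,
    files = lapply(setNames(files, files), function(f)
      unname(tools::md5sum(file.path(out_dir, f)))))
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(manifest)
}
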