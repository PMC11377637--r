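.feature_regions <- c("lesion", "ring1", "ring2")

#' Canonical feature-column order
#'
#' The 18 z-score metric names in the stable, documented order:
#' modality (T1z, T2z, T2T1z) x region (lesion, ring1, ring2) x statistic
#' (mean, sd).
#'
#' @param modalities modality names as used in the z-score maps.
#' @return Character vector of 18 column names.
#' @export
feature_columns <- function(modalities = c("T1", "T2", "T2T1")) {
  as.vector(vapply(modalities, function(mod)
    as.vector(vapply(.feature_regions, function(rg)
      paste0(mod, "z_", rg, c("_mean", "_sd")), character(2))),
    character(6)))
}

#' Extract the per-lesion microstructural feature vector
#'
#' Computes the mean and sample standard deviation of z-scores inside the
#' lesion and in each perilesional ring, for every modality: 18 metrics per
#' lesion. Invalid (non-finite) z voxels are excluded; a region with fewer
#' than 2 valid voxels yields missing metrics but the row is retained.
#'
#' @param zmaps named list of [zscore()] maps (or plain arrays), one per
#'   modality.
#' @param lesion_voxels integer voxel indices of the lesion (column-major).
#' @param rings list with elements `ring1` and `ring2` of voxel indices, as
#'   stored per lesion in [make_rings()] output.
#' @param meta named list merged into the row (e.g. `lesion_id`,
#'   `patient_id`, `phenotype`, `rimla_label`, `volume_uL`).
#' @return One-row data frame: metadata columns then the 18 metrics in
#'   [feature_columns()] order.
#' @export
extract_features <- function(zmaps, lesion_voxels, rings, meta = list()) {
  regions <- list(lesion = lesion_voxels, ring1 = rings$ring1, ring2 = rings$ring2)
  row <- as.data.frame(meta, stringsAsFactors = FALSE)
  if (nrow(row) == 0) row <- data.frame(row.names = 1)
  for (mod in names(zmaps)) {
    zm <- zmaps[[mod]]
    z <- if (inherits(zm, "zscore_map")) zm$z else zm
    for (rg in .feature_regions) {
      v <- z[regions[[rg]]]
      v <- v[is.finite(v)]
      row[[paste0(mod, "z_", rg, "_mean")]] <-
        if (length(v) >= 2) mean(v) else NA_real_
      row[[paste0(mod, "z_", rg, "_sd")]] <-
        if (length(v) >= 2) sd(v) else NA_real_
    }
  }
  row
}

#' Build the lesion feature table for one or more patient cases
#'
#' Applies the full exclusion cascade per case -- volume window, deep
#' white-matter restriction, and availability of a longitudinal label --
#' then extracts the 18 z-score metrics per surviving lesion and joins the
#' metadata. Lesions without a longitudinal label are excluded with a
#' message.
#'
#' @param cases list of cases; each case is a list with elements `zmaps`
#'   (named list of z-score maps), `labels` (a [new_lesion_label_map()]),
#'   `tissue` (tissue mask array), `rimla_labels` (named character vector,
#'   names = lesion ids), `patient_id`, `phenotype` (RR/SP), and optionally
#'   precomputed `rings`.
#' @param volume_bounds inclusive volume window in uL.
#' @param cutoffs ring cutoffs in mm.
#' @return Data frame, one row per retained lesion, with metadata and the
#'   18 metrics plus `volume_uL`.
#' @export
build_feature_table <- function(cases, volume_bounds = c(3, 150),
                                cutoffs = c(2, 3.5)) {
  rows <- list()
  for (case in cases) {
    lm <- case$labels
    vols <- lesion_volumes(lm)
    keep <- filter_by_volume(vols, volume_bounds[1], volume_bounds[2])
    keep <- intersect(keep, restrict_to_wm(lm, case$tissue))
    if (length(keep) == 0) next
    rings <- case$rings %||% make_rings(lm, cutoffs = cutoffs)
    for (id in keep) {
      lab <- case$rimla_labels[[id]]
      if (is.null(lab) || is.na(lab)) {
        message("lesion ", id, " of patient ", case$patient_id,
                " excluded: no longitudinal label")
        next
      }
      meta <- list(lesion_id = paste0(case$patient_id, "_", id),
                   patient_id = case$patient_id,
                   phenotype = case$phenotype %||% NA_character_,
                   rimla_label = lab,
                   volume_uL = unname(vols[id]))
      rows[[length(rows) + 1L]] <-
        extract_features(case$zmaps,
                         which(lm$labels == as.integer(id)),
                         rings$rings[[id]], meta)
    }
  }
  if (length(rows) == 0) return(data.frame())
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}
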