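#' Lesion label maps
#'
#' A `lesion_label_map` holds an integer 3-D volume (0 = background, lesions
#' numbered 1..n) together with the voxel dimensions in mm. Labels are
#' consecutive and each label is one connected component.
#'
#' @param labels integer 3-D array.
#' @param voxel_dims numeric(3), voxel size in mm.
#' @return An object of class `lesion_label_map`.
#' @export
new_lesion_label_map <- function(labels, voxel_dims) {
  stopifnot(length(dim(labels)) == 3, length(voxel_dims) == 3, all(voxel_dims > 0))
  structure(list(labels = labels, voxel_dims = as.numeric(voxel_dims)),
            class = "lesion_label_map")
}

#' @export
print.lesion_label_map <- function(x, ...) {
  n <- max(0L, max(x$labels))
  cat(sprintf("Lesion label map: %s grid at %s mm, %d lesion(s)\n",
              paste(dim(x$labels), collapse = "x"),
              paste(x$voxel_dims, collapse = "x"), n))
  invisible(x)
}

#' Label connected lesion components
#'
#' Labels connected components of a binary lesion mask. Labelling is
#' deterministic: components are numbered by the position (column-major scan
#' order) of their first voxel.
#'
#' @param mask binary 3-D array (logical, or numeric in \{0, 1\}).
#' @param voxel_dims numeric(3), voxel size in mm.
#' @param connectivity one of 6, 18, 26 (voxel neighbourhoods sharing a
#'   face, an edge, or a corner).
#' @return A [new_lesion_label_map()].
#' @export
label_lesions <- function(mask, voxel_dims = c(1, 1, 1), connectivity = 26) {
  if (!.is_binary(mask)) stop("lesion mask must be binary")
  connectivity <- match.arg(as.character(connectivity), c("26", "18", "6"))
  dims <- dim(mask)
  lab <- .label_cc_cpp(as.logical(as.vector(mask)), as.integer(dims),
                       as.integer(connectivity))
  new_lesion_label_map(array(lab, dim = dims), voxel_dims)
}

#' Lesion volumes in microlitres
#'
#' Volume is voxel count times voxel volume; 1 uL = 1 mm^3.
#'
#' @param lm a [new_lesion_label_map()].
#' @return Named numeric vector of volumes (uL), one entry per present label.
#' @export
lesion_volumes <- function(lm) {
  stopifnot(inherits(lm, "lesion_label_map"))
  counts <- table(lm$labels[lm$labels > 0])
  vv <- prod(lm$voxel_dims)
  setNames(as.numeric(counts) * vv, names(counts))
}

#' Filter lesions by volume
#'
#' Keeps lesions whose volume lies in the closed interval `[vmin, vmax]`;
#' only strict violations ("smaller than 3 uL or larger than 150 uL") are
#' discarded.
#'
#' @param volumes named vector from [lesion_volumes()].
#' @param vmin,vmax inclusive bounds in uL.
#' @return Character vector of kept lesion ids.
#' @export
filter_by_volume <- function(volumes, vmin = 3, vmax = 150) {
  names(volumes)[volumes >= vmin & volumes <= vmax]
}

#' Euclidean distance to the nearest lesion
#'
#' Computes, for every voxel, the exact Euclidean distance (mm, honouring
#' anisotropic voxel dimensions) to the nearest lesion voxel, the label of
#' the nearest lesion, and the number of distinct lesions within
#' `outer_cutoff` mm. Distance is 0 inside lesions. The per-label transform
#' uses an exact separable lower-envelope algorithm.
#'
#' @param lm a [new_lesion_label_map()] with at least one lesion.
#' @param outer_cutoff radius (mm) used for the multi-lesion count.
#' @return A list with arrays `distance` (mm), `nearest` (label id, 0 where
#'   no lesion exists) and `n_within` (lesions within `outer_cutoff`).
#' @export
distance_to_lesions <- function(lm, outer_cutoff = 3.5) {
  stopifnot(inherits(lm, "lesion_label_map"))
  ids <- sort(unique(lm$labels[lm$labels > 0]))
  if (length(ids) == 0) stop("label map contains no lesions")
  dims <- dim(lm$labels)
  dmin <- rep(Inf, prod(dims))
  nearest <- integer(prod(dims))
  n_within <- integer(prod(dims))
  for (id in ids) {
    d <- .edt3d_cpp(as.vector(lm$labels == id), as.integer(dims), lm$voxel_dims)
    upd <- d < dmin
    dmin[upd] <- d[upd]
    nearest[upd] <- id
    n_within <- n_within + (d < outer_cutoff)
  }
  list(distance = array(dmin, dims), nearest = array(nearest, dims),
       n_within = array(n_within, dims))
}

#' Delineate perilesional rings
#'
#' Discretizes the distance map into two exclusive perilesional rings per
#' lesion: ring 1 holds voxels at distance in (0, `cutoffs[1]`) mm from the
#' lesion border and ring 2 voxels in `[cutoffs[1], cutoffs[2])` mm. Voxels
#' inside any lesion never belong to a ring, and voxels simultaneously in
#' the neighbourhood (within `cutoffs[2]` mm) of two or more distinct
#' lesions are discarded from all rings so perilesional signal stays
#' specific to one lesion.
#'
#' @param lm a [new_lesion_label_map()].
#' @param dist optional precomputed result of [distance_to_lesions()]
#'   (must have been computed with `outer_cutoff = cutoffs[2]`).
#' @param cutoffs numeric(2), ring cutoffs in mm (default 2 and 3.5).
#' @return An object of class `ring_masks`: per lesion id, integer vectors
#'   `ring1` and `ring2` of voxel indices (column-major), plus the cutoffs
#'   and grid dimensions.
#' @export
make_rings <- function(lm, dist = NULL, cutoffs = c(2, 3.5)) {
  stopifnot(inherits(lm, "lesion_label_map"), length(cutoffs) == 2,
            cutoffs[1] <= cutoffs[2])
  if (is.null(dist)) dist <- distance_to_lesions(lm, outer_cutoff = cutoffs[2])
  d <- as.vector(dist$distance)
  nearest <- as.vector(dist$nearest)
  shared <- as.vector(dist$n_within) >= 2L
  ids <- sort(unique(lm$labels[lm$labels > 0]))
  rings <- lapply(ids, function(id) {
    mine <- nearest == id & !shared & d > 0
    list(ring1 = which(mine & d < cutoffs[1]),
         ring2 = which(mine & d >= cutoffs[1] & d < cutoffs[2]))
  })
  names(rings) <- as.character(ids)
  structure(list(rings = rings, cutoffs = cutoffs, dim = dim(lm$labels)),
            class = "ring_masks")
}

#' @export
print.ring_masks <- function(x, ...) {
  n1 <- sum(vapply(x$rings, function(r) length(r$ring1), integer(1)))
  n2 <- sum(vapply(x$rings, function(r) length(r$ring2), integer(1)))
  cat(sprintf("Perilesional rings for %d lesion(s), cutoffs %g/%g mm: %d + %d voxels\n",
              length(x$rings), x$cutoffs[1], x$cutoffs[2], n1, n2))
  invisible(x)
}

# binary erosion by one voxel with the full 26-neighbourhood; voxels on the
# array boundary are eroded (treated as adjacent to background)
.erode26 <- function(mask) {
  dims <- dim(mask)
  m <- array(FALSE, dims + 2L)
  m[2:(dims[1] + 1), 2:(dims[2] + 1), 2:(dims[3] + 1)] <- mask
  out <- mask
  for (dx in -1:1) for (dy in -1:1) for (dz in -1:1) {
    if (dx == 0 && dy == 0 && dz == 0) next
    out <- out & m[(2 + dx):(dims[1] + 1 + dx),
                   (2 + dy):(dims[2] + 1 + dy),
                   (2 + dz):(dims[3] + 1 + dz)]
  }
  out
}

#' Restrict lesions to deep white matter
#'
#' Erodes the white-matter/subcortical region by one voxel (26-connectivity)
#' and keeps only lesions entirely contained in the eroded region, i.e.
#' lesions further than one voxel from the tissue boundary.
#'
#' @param lm a [new_lesion_label_map()].
#' @param tissue_mask integer array on the same grid; voxels equal to
#'   `wm_label` form the white-matter/subcortical region.
#' @param wm_label label of the white-matter region in `tissue_mask`.
#' @return Character vector of kept lesion ids.
#' @export
restrict_to_wm <- function(lm, tissue_mask, wm_label = 2L) {
  stopifnot(inherits(lm, "lesion_label_map"),
            all(dim(tissue_mask) == dim(lm$labels)))
  eroded <- .erode26(tissue_mask == wm_label)
  ids <- sort(unique(lm$labels[lm$labels > 0]))
  keep <- vapply(ids, function(id) all(eroded[lm$labels == id]), logical(1))
  as.character(ids[keep])
}
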