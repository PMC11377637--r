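# Brute-force oracle for lesion distance maps: pairwise physical distances
# between every voxel and every lesion voxel, per label. Independent of the
# separable transform used by the package.
brute_distance <- function(lm, outer_cutoff = 3.5) {
  labels <- lm$labels
  dims <- dim(labels)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  coords <- sweep(idx, 2, lm$voxel_dims, `*`)
  ids <- sort(unique(labels[labels > 0]))
  per_label <- sapply(ids, function(id) {
    les <- coords[labels == id, , drop = FALSE]
    apply(coords, 1, function(v)
      sqrt(min((les[, 1] - v[1])^2 + (les[, 2] - v[2])^2 + (les[, 3] - v[3])^2)))
  })
  per_label <- matrix(per_label, ncol = length(ids))
  dmin <- apply(per_label, 1, min)
  nearest <- ids[apply(per_label, 1, which.min)]
  n_within <- rowSums(per_label < outer_cutoff)
  # voxels whose per-label distance sits on a cutoff boundary are sensitive
  # to floating-point tie-breaking; flag them so comparisons can skip them
  boundary <- apply(per_label, 1, function(v)
    any(abs(v - outer_cutoff) < 1e-9 | abs(v - 2) < 1e-9))
  # voxels equidistant from two lesions: the nearest id is tie-broken by
  # floating-point noise, so comparisons should skip them
  tie <- if (ncol(per_label) > 1) {
    apply(per_label, 1, function(v) diff(sort(v))[1] < 1e-9)
  } else rep(FALSE, nrow(per_label))
  list(distance = array(dmin, dims),
       nearest = array(as.integer(nearest), dims),
       n_within = array(as.integer(n_within), dims),
       boundary = array(boundary, dims),
       tie = array(tie, dims))
}

# random multi-lesion scene on a small grid; returns a labelled map
random_scene <- function(dims = c(20, 20, 20), voxel_dims = c(1, 1, 1),
                         n_seeds = 3, blob_radius = 1.6) {
  mask <- array(FALSE, dims)
  idx <- arrayInd(seq_len(prod(dims)), dims)
  coords <- sweep(idx, 2, voxel_dims, `*`)
  for (k in seq_len(n_seeds)) {
    centre <- runif(3, 0.2, 0.8) * dims * voxel_dims
    d <- sqrt((coords[, 1] - centre[1])^2 + (coords[, 2] - centre[2])^2 +
                (coords[, 3] - centre[3])^2)
    mask[d <= blob_radius] <- TRUE
  }
  if (!any(mask)) mask[ceiling(dims[1] / 2), ceiling(dims[2] / 2),
                       ceiling(dims[3] / 2)] <- TRUE
  label_lesions(mask, voxel_dims)
}

# exact two-sided rank-sum p value by enumeration of all group assignments
exact_ranksum_p <- function(x, y) {
  n1 <- length(x); n <- n1 + length(y)
  r <- rank(c(x, y))
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- combn(n, n1)
  w_all <- apply(combs, 2, function(ix) sum(r[ix]) - n1 * (n1 + 1) / 2)
  mu <- mean(w_all)
  mean(abs(w_all - mu) >= abs(w_obs - mu))
}

# tiny default config for image-based tests
small_cfg <- function(...) {
  synth_config(grid_shape = c(16, 16, 16), n_healthy = 20, seed = 42, ...)
}
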