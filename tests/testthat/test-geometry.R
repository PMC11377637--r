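test_that("connected-component labelling follows the connectivity contract", {
  empty <- array(FALSE, c(5, 5, 5))
  expect_equal(max(label_lesions(empty)$labels), 0)

  m <- array(FALSE, c(5, 5, 5))
  m[2, 2, 2] <- TRUE; m[3, 2, 2] <- TRUE            # face neighbours
  expect_equal(max(label_lesions(m, connectivity = 26)$labels), 1)
  expect_equal(max(label_lesions(m, connectivity = 6)$labels), 1)

  m2 <- array(FALSE, c(9, 5, 5))
  m2[2, 2, 2] <- TRUE; m2[7, 2, 2] <- TRUE          # 5 mm apart at 1 mm
  expect_equal(max(label_lesions(m2)$labels), 2)

  m3 <- array(0, c(3, 3, 3)); m3[1, 1, 1] <- 2
  expect_error(label_lesions(m3), "binary")
})

test_that("corner-touching voxels merge only under 26-connectivity", {
  m <- array(FALSE, c(4, 4, 4))
  m[2, 2, 2] <- TRUE; m[3, 3, 3] <- TRUE
  expect_equal(max(label_lesions(m, connectivity = 26)$labels), 1)
  expect_equal(max(label_lesions(m, connectivity = 18)$labels), 2)
  expect_equal(max(label_lesions(m, connectivity = 6)$labels), 2)
})

test_that("lesion volumes use physical voxel dimensions (1 uL = 1 mm^3)", {
  m <- array(FALSE, c(10, 4, 4)); m[1:10, 1, 1] <- TRUE
  expect_equal(unname(lesion_volumes(label_lesions(m, c(1, 1, 1)))), 10)
  expect_equal(unname(lesion_volumes(label_lesions(m, c(0.7, 0.7, 3.0)))),
               14.7, tolerance = 1e-12)
})

test_that("volume filter keeps the closed interval [3, 150]", {
  v <- c(a = 2.9, b = 3.0, c = 150.0, d = 150.1)
  expect_setequal(filter_by_volume(v), c("b", "c"))
  expect_length(filter_by_volume(numeric(0)), 0)
  expect_setequal(filter_by_volume(c(x = 10, y = 80)), c("x", "y"))
})

test_that("distances honour anisotropic voxels and basic adjacency", {
  m <- array(FALSE, c(5, 5, 5)); m[3, 3, 3] <- TRUE
  lm1 <- label_lesions(m, c(1, 1, 1))
  d <- distance_to_lesions(lm1)
  expect_equal(d$distance[4, 3, 3], 1.0)
  expect_equal(d$distance[3, 3, 3], 0)
  lm2 <- label_lesions(m, c(0.7, 0.7, 3.0))
  d2 <- distance_to_lesions(lm2)
  expect_equal(d2$distance[3, 3, 4], 3.0)
  expect_equal(d2$distance[4, 3, 3], 0.7)
  expect_error(distance_to_lesions(label_lesions(array(FALSE, c(3, 3, 3)))),
               "no lesions")
})

test_that("distance maps equal the brute-force pairwise oracle", {
  set.seed(101)
  for (rep in 1:6) {
    vd <- if (rep %% 2 == 0) c(0.7, 0.7, 3.0) else c(1, 1, 1)
    lm <- random_scene(dims = c(14, 12, 10), voxel_dims = vd,
                       n_seeds = sample(1:4, 1))
    got <- distance_to_lesions(lm, outer_cutoff = 3.5)
    want <- brute_distance(lm, outer_cutoff = 3.5)
    expect_equal(got$distance, want$distance, tolerance = 1e-9)
    ok <- !as.vector(want$boundary)
    expect_equal(as.vector(got$n_within)[ok], as.vector(want$n_within)[ok])
    # nearest ids must agree wherever the nearest lesion is unique
    amb <- want$tie | abs(got$distance - want$distance) > 1e-9
    expect_equal(got$nearest[!amb], want$nearest[!amb])
  }
})

test_that("a single voxel lesion on a 1 mm grid has a 26-voxel first ring", {
  m <- array(FALSE, c(11, 11, 11)); m[6, 6, 6] <- TRUE
  lm <- label_lesions(m, c(1, 1, 1))
  r <- make_rings(lm)
  # neighbours at distance 1, sqrt2, sqrt3 are all < 2; distance 2 excluded
  expect_length(r$rings[["1"]]$ring1, 26)
  expect_false(any(r$rings[["1"]]$ring1 %in% which(m)))
})

test_that("rings are exclusive between nearby lesions and empty at zero cutoffs", {
  m <- array(FALSE, c(13, 7, 7))
  m[5, 4, 4] <- TRUE; m[9, 4, 4] <- TRUE            # 4 mm apart
  lm <- label_lesions(m, c(1, 1, 1))
  r <- make_rings(lm)
  # midline voxels within 3.5 mm of both lesions belong to neither ring
  d <- distance_to_lesions(lm, outer_cutoff = 3.5)
  shared <- which(d$n_within >= 2)
  expect_gt(length(shared), 0)
  all_ring <- unlist(lapply(r$rings, function(x) c(x$ring1, x$ring2)))
  expect_length(intersect(shared, all_ring), 0)

  r0 <- make_rings(lm, cutoffs = c(0, 0))
  expect_true(all(vapply(r0$rings, function(x)
    length(x$ring1) + length(x$ring2), integer(1)) == 0))
})

test_that("ring properties hold on randomized scenes", {
  set.seed(77)
  for (rep in 1:5) {
    lm <- random_scene(dims = c(16, 16, 12), n_seeds = sample(2:4, 1))
    r <- make_rings(lm)
    lesion_vox <- which(lm$labels > 0)
    for (id in names(r$rings)) {
      ring1 <- r$rings[[id]]$ring1; ring2 <- r$rings[[id]]$ring2
      expect_length(intersect(ring1, ring2), 0)
      expect_length(intersect(c(ring1, ring2), lesion_vox), 0)
    }
    # no voxel sits in rings of two different lesions
    all_vox <- unlist(lapply(r$rings, function(x) c(x$ring1, x$ring2)))
    expect_equal(anyDuplicated(all_vox), 0)
  }
})

test_that("rings are invariant to lesion label permutation", {
  set.seed(13)
  lm <- random_scene(dims = c(15, 15, 15), n_seeds = 3)
  ids <- sort(unique(lm$labels[lm$labels > 0]))
  perm <- rev(ids)
  relab <- lm$labels
  for (k in seq_along(ids)) relab[lm$labels == ids[k]] <- perm[k]
  lm2 <- new_lesion_label_map(relab, lm$voxel_dims)
  r1 <- make_rings(lm)
  r2 <- make_rings(lm2)
  for (k in seq_along(ids)) {
    expect_identical(sort(r1$rings[[as.character(ids[k])]]$ring1),
                     sort(r2$rings[[as.character(perm[k])]]$ring1))
    expect_identical(sort(r1$rings[[as.character(ids[k])]]$ring2),
                     sort(r2$rings[[as.character(perm[k])]]$ring2))
  }
})

test_that("white-matter restriction keeps only fully interior lesions", {
  tissue <- array(0L, c(12, 12, 12))
  tissue[3:10, 3:10, 3:10] <- 2L
  m <- array(FALSE, c(12, 12, 12))
  m[6:7, 6:7, 6:7] <- TRUE                 # deep interior
  m[3, 6, 6] <- TRUE                       # on the WM boundary layer
  lm <- label_lesions(m, c(1, 1, 1))
  kept <- restrict_to_wm(lm, tissue)
  vols <- lesion_volumes(lm)
  interior_id <- names(vols)[vols == max(vols)]
  expect_identical(kept, interior_id)
  expect_length(restrict_to_wm(lm, array(0L, c(12, 12, 12))), 0)
})
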