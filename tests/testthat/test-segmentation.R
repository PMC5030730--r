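test_that("normalization inverts and is an involution on the rescaled image", {
  m8 <- matrix(c(0, 255, 128, 64), 2, 2)
  inv <- normalize_and_invert(m8)
  expect_equal(inv[1, 1], 1)
  expect_equal(inv[2, 1], 0)
  expect_equal(1 - inv, m8 / 255)
  expect_equal(normalize_and_invert(matrix(0, 3, 3)), matrix(1, 3, 3))
  expect_error(normalize_and_invert(array(0, c(2, 2, 2))), "2-D")
  expect_error(normalize_and_invert(matrix(c(1, NA), 1, 2)), "finite")
})

test_that("foreground mask thresholds at the configured values", {
  inv <- matrix(c(0.8, 0.5), 1, 2)
  expect_equal(foreground_mask(inv, 0.78), matrix(c(TRUE, FALSE), 1, 2))
  expect_equal(foreground_mask(inv, 0.75), matrix(c(TRUE, FALSE), 1, 2))
  expect_false(any(foreground_mask(matrix(0.1, 5, 5), 0.74)))
  expect_error(foreground_mask(inv, 1.2), "theta")
  # monotonicity: lowering theta never shrinks the mask
  set.seed(5)
  inv2 <- matrix(runif(400), 20, 20)
  thetas <- sort(runif(5, 0.1, 0.9), decreasing = TRUE)
  prev <- foreground_mask(inv2, thetas[1])
  for (th in thetas[-1]) {
    cur <- foreground_mask(inv2, th)
    expect_true(all(cur[prev]))  # superset
    prev <- cur
  }
})

test_that("connected-component labeling honours connectivity and raster order", {
  m <- matrix(0L, 7, 7)
  m[2, 2] <- 1L; m[3, 3] <- 1L  # diagonal pair
  m[6, 6] <- 1L
  l8 <- label_components(m, 8L)
  expect_equal(max(l8), 2L)
  expect_equal(l8[2, 2], 1L)  # raster-first pixel gets label 1
  expect_equal(l8[6, 6], 2L)
  l4 <- label_components(m, 4L)
  expect_equal(max(l4), 3L)
  expect_equal(max(label_components(matrix(0L, 4, 4))), 0L)
})

test_that("per-scale identification filters by equivalent diameter and border", {
  cfg <- segmentation_config()
  shape <- c(80L, 80L)
  d12 <- disk_mask(shape, 40, 40, 6)  # equivalent diameter ~12
  area <- sum(d12)
  eqd <- 2 * sqrt(area / pi)  # oracle: brute-force pixel count
  expect_true(eqd >= 5 && eqd <= 20)
  expect_equal(max(identify_scale_objects(d12, cfg$scales[[1]], cfg)), 1L)
  expect_equal(max(identify_scale_objects(d12, cfg$scales[[3]], cfg)), 0L)
  # border-clipped disk discarded
  clipped <- disk_mask(shape, 2, 40, 6)
  expect_equal(max(identify_scale_objects(clipped, cfg$scales[[1]], cfg)), 0L)
  cfg2 <- segmentation_config(discard_border = FALSE)
  expect_equal(max(identify_scale_objects(clipped, cfg2$scales[[1]], cfg2)), 1L)
})

test_that("distance unification merges at the documented pixel distance", {
  lab <- matrix(0L, 20, 30)
  lab[5:9, 5:9] <- 1L
  lab[5:9, 11:15] <- 2L   # one empty column: min centre distance 2
  u <- unify_by_distance(lab, 2)
  expect_equal(max(u), 1L)
  expect_equal(oracle_min_distance(lab, 1L, 2L), 2)

  lab2 <- matrix(0L, 20, 30)
  lab2[5:9, 5:9] <- 1L
  lab2[5:9, 13:17] <- 2L  # three empty columns: min distance 4
  expect_equal(oracle_min_distance(lab2, 1L, 2L), 4)
  expect_equal(max(unify_by_distance(lab2, 2)), 2L)
  expect_identical(unify_by_distance(lab2, 2), lab2)

  single <- matrix(0L, 10, 10); single[3:5, 3:5] <- 1L
  expect_identical(unify_by_distance(single, 2), single)
  expect_error(unify_by_distance(lab, -1), "max_dist")
})

test_that("scale priority removes sub-objects of larger scales", {
  shape <- c(60L, 60L)
  small <- matrix(0L, shape[1], shape[2])
  small[disk_mask(shape, 30, 30, 4)] <- 1L          # inside the big object
  big <- matrix(0L, shape[1], shape[2])
  big[disk_mask(shape, 30, 30, 20)] <- 1L
  out <- apply_scale_priority(list(small, big), segmentation_config())
  expect_equal(max(out[[1]]), 0L)
  expect_equal(max(out[[2]]), 1L)
  # disjoint objects both retained
  small2 <- matrix(0L, shape[1], shape[2])
  small2[disk_mask(shape, 10, 10, 3)] <- 1L
  out2 <- apply_scale_priority(list(small2, big), segmentation_config())
  expect_equal(max(out2[[1]]), 1L)
  # empty small-scale map leaves the stack unchanged
  out3 <- apply_scale_priority(list(matrix(0L, shape[1], shape[2]), big),
                               segmentation_config())
  expect_equal(max(out3[[1]]), 0L)
  expect_identical(out3[[2]], relabel_raster(big))
  expect_error(apply_scale_priority(list(small, matrix(0L, 5, 5))), "shape")
})

test_that("contract/merge/relabel/expand conserves well-separated objects", {
  shape <- c(80L, 80L)
  lab <- matrix(0L, shape[1], shape[2])
  lab[disk_mask(shape, 20, 20, 8)] <- 1L
  lab[disk_mask(shape, 55, 55, 10)] <- 2L
  out <- contract_merge_relabel_expand(list(lab), segmentation_config())
  expect_true(same_partition(out, lab))
  # thin object survives via ultimate erosion
  thin <- matrix(0L, 20, 20)
  thin[8:9, 4:15] <- 1L  # 2 pixels wide: plain erosion would erase it
  out2 <- contract_merge_relabel_expand(list(thin), segmentation_config())
  expect_equal(max(out2), 1L)
  expect_true(same_partition(out2, thin))
})

test_that("touching objects from different scales stay separate; overlapping merge", {
  shape <- c(40L, 60L)
  a <- matrix(0L, shape[1], shape[2]); a[10:20, 10:20] <- 1L
  b <- matrix(0L, shape[1], shape[2]); b[10:20, 21:31] <- 1L  # touching, no overlap
  out <- contract_merge_relabel_expand(list(a, b), segmentation_config())
  expect_equal(max(out), 2L)
  expect_equal(sum(out > 0), sum(a > 0) + sum(b > 0))
  # overlapping segmentations of the same region fuse into one
  b2 <- matrix(0L, shape[1], shape[2]); b2[10:20, 15:25] <- 1L
  out2 <- contract_merge_relabel_expand(list(a, b2), segmentation_config())
  expect_equal(max(out2), 1L)
})

test_that("frame segmentation is deterministic and finds the three scales", {
  f <- disk_frame(c(200L, 200L), list(c(40, 40), c(60, 140), c(140, 80)),
                  c(10, 30, 55))
  lab1 <- segment_frame(f$image)
  lab2 <- segment_frame(f$image)
  expect_identical(lab1, lab2)
  expect_equal(max(lab1), 3L)
  m <- segmentation_metrics(lab1, f$truth)
  expect_equal(m$precision, 1)
  expect_equal(m$recall, 1)
  expect_equal(max(segment_frame(matrix(0.85, 64, 64))), 0L)
})

test_that("a clump passing only the large scale segments as one object", {
  # two touching disks: the union's equivalent diameter exceeds scale 1
  f <- disk_frame(c(120L, 120L), list(c(60, 50), c(60, 66)), c(16, 16))
  lab <- segment_frame(f$image)
  expect_equal(max(lab), 1L)
  # oracle: the union is one 8-connected component of the thresholded mask
  inv <- 1 - f$image
  expect_equal(max(label_components(inv >= 0.74, 8L)), 1L)
})

test_that("configuration validation catches inconsistent scale setups", {
  expect_error(scale_config(1.2, 5, 20), "theta")
  expect_error(scale_config(0.5, 20, 5), "d_min")
  expect_error(segmentation_config(scales = list(scale_config(0.7, 21, 40),
                                                 scale_config(0.8, 5, 20))),
               "increasing")
  expect_error(segmentation_config(scales = list(scale_config(0.7, 5, 20),
                                                 scale_config(0.8, 21, 40))),
               "non-increasing")
})
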