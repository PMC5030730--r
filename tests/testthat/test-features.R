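test_that("intensity features match hand-computed values", {
  # constant-intensity object: Mean = c, Std = 0, MassDisplacement = 0
  m <- matrix(FALSE, 10, 10); m[3:5, 3:5] <- TRUE
  f <- frame_with_object(m, 0.6)
  it <- measure_intensity(f$labels, f$image)
  expect_equal(it$Intensity_MeanIntensity, 0.6)
  expect_equal(it$Intensity_StdIntensity, 0)
  expect_equal(it$Intensity_MassDisplacement, 0)
  expect_equal(it$Intensity_IntegratedIntensity, 0.6 * 9)
  # 3x3 square: edge set is the 8 boundary pixels
  vals <- matrix(1:9 / 10, 3, 3)
  f2 <- frame_with_object(m)
  f2$image[m] <- as.vector(vals)
  it2 <- measure_intensity(f2$labels, f2$image)
  edge_vals <- as.vector(vals)[-5]  # centre pixel excluded
  expect_equal(it2$Intensity_MeanIntensityEdge, mean(edge_vals))
  expect_equal(it2$Intensity_IntegratedIntensityEdge, sum(edge_vals))
  # quantile rule: 4 pixels {0.1, 0.2, 0.3, 0.4}
  m4 <- matrix(FALSE, 6, 6); m4[3, 2:5] <- TRUE
  f4 <- frame_with_object(m4, c(0.1, 0.2, 0.3, 0.4))
  it4 <- measure_intensity(f4$labels, f4$image)
  expect_equal(it4$Intensity_IntegratedIntensity, 1.0)
  expect_equal(it4$Intensity_MedianIntensity, 0.25)
  expect_equal(it4$Intensity_LowerQuartileIntensity,
               quantile(c(0.1, 0.2, 0.3, 0.4), 0.25, type = 7, names = FALSE))
})

test_that("shape features are exact on constructed objects", {
  sq <- matrix(FALSE, 14, 14); sq[3:12, 3:12] <- TRUE
  f <- frame_with_object(sq)
  sh <- measure_shape(f$labels)
  expect_equal(sh$Shape_Area, 100)
  expect_equal(sh$Shape_Extent, 1.0)
  expect_equal(sh$Shape_Solidity, 1.0)
  expect_equal(sh$Shape_EulerNumber, 1)
  expect_equal(sh$Shape_EquivalentDiameter, 2 * sqrt(100 / pi))
  # interior hole flips the Euler number
  hole <- sq; hole[6:7, 6:7] <- FALSE
  sh2 <- measure_shape(frame_with_object(hole)$labels)
  expect_equal(sh2$Shape_EulerNumber, 0)
  # FormFactor * Compactness = 1 by construction
  expect_equal(sh$Shape_FormFactor * sh$Shape_Compactness, 1)
})

test_that("disk form factor and perimeter track the analytic circle", {
  for (r in c(10, 15, 20, 30)) {
    n <- 2 * r + 9
    f <- frame_with_object(disk_mask(c(n, n), (n + 1) / 2, (n + 1) / 2, r))
    sh <- measure_shape(f$labels)
    expect_lt(abs(sh$Shape_Perimeter - 2 * pi * r) / (2 * pi * r), 0.05)
    if (r == 20) expect_true(sh$Shape_FormFactor >= 0.93 && sh$Shape_FormFactor <= 1.07)
  }
})

test_that("shape features agree with the brute-force enumeration oracle", {
  for (seed in 1:40) {
    mask <- random_blob(seed)
    sh <- measure_shape(frame_with_object(mask)$labels)
    or <- oracle_shape(mask)
    expect_equal(sh$Shape_Area, or$Area)
    expect_equal(sh$Shape_EulerNumber, or$EulerNumber)
    expect_equal(sh$Shape_Extent, or$Extent, tolerance = 1e-12)
    expect_equal(sh$Shape_Solidity, or$Solidity, tolerance = 1e-12)
    expect_equal(sh$Shape_EquivalentDiameter, or$EquivalentDiameter, tolerance = 1e-12)
    for (f in c("Eccentricity", "MajorAxisLength", "MinorAxisLength",
                "MaxFeretDiameter", "MinFeretDiameter")) {
      expect_equal(sh[[paste0("Shape_", f)]], or[[f]], tolerance = 1e-9)
    }
    dori <- abs(sh$Shape_Orientation - or$Orientation) %% 180
    expect_lt(min(dori, 180 - dori), 1e-9)
    for (f in c("MeanRadius", "MedianRadius", "MaximumRadius")) {
      expect_equal(sh[[paste0("Shape_", f)]], or[[f]], tolerance = 1e-9)
    }
  }
})

test_that("neighbour features follow centroid geometry", {
  lab <- matrix(0L, 40, 40)
  lab[10, 10] <- 1L
  nb1 <- measure_neighbors(lab)
  expect_equal(nb1$Neighbors_NumberOfNeighbors, 0)
  expect_equal(nb1$Neighbors_PercentTouching, 0)
  expect_true(is.na(nb1$Neighbors_FirstClosestDistance))

  lab[10, 20] <- 2L  # centroids 10 px apart
  nb2 <- measure_neighbors(lab)
  expect_equal(nb2$Neighbors_FirstClosestDistance, c(10, 10))
  expect_true(all(is.na(nb2$Neighbors_SecondClosestDistance)))
  expect_true(all(is.na(nb2$Neighbors_AngleBetweenNeighbors)))
  # the two regions split the frame: each is the other's partition neighbour
  expect_equal(nb2$Neighbors_NumberOfNeighbors, c(1, 1))

  lab3 <- matrix(0L, 40, 40)
  lab3[5, 5] <- 1L; lab3[5, 15] <- 2L; lab3[15, 5] <- 3L
  nb3 <- measure_neighbors(lab3)
  # at object 1 the two closest neighbours subtend a right angle
  expect_equal(nb3$Neighbors_AngleBetweenNeighbors[1], 90)
  expect_equal(nb3$Neighbors_FirstClosestObjectNumber[1], 2)  # tie broken by label
  # brute-force oracle over all centroid pairs
  cents <- rbind(c(5, 5), c(5, 15), c(15, 5))
  d <- as.matrix(dist(cents))
  for (i in 1:3) {
    expect_equal(nb3$Neighbors_FirstClosestDistance[i], unname(sort(d[i, -i])[1]))
    expect_equal(nb3$Neighbors_SecondClosestDistance[i], unname(sort(d[i, -i])[2]))
  }
})

test_that("touching objects report high PercentTouching", {
  lab <- matrix(0L, 30, 30)
  lab[10:15, 5:14] <- 1L
  lab[10:15, 15:24] <- 2L  # abutting blocks
  nb <- measure_neighbors(lab)
  expect_equal(nb$Neighbors_NumberOfNeighbors, c(1, 1))
  # oracle: of the 28 boundary pixels of block 1, the 8 in the two columns
  # nearest block 2 lie within 2 px of it
  expect_equal(nb$Neighbors_PercentTouching[1], 100 * 8 / 28)
  lab2 <- matrix(0L, 30, 30)
  lab2[10:15, 2:7] <- 1L
  lab2[10:15, 22:27] <- 2L  # far apart
  expect_equal(measure_neighbors(lab2)$Neighbors_PercentTouching, c(0, 0))
})

test_that("radial distribution conserves intensity and is flat for uniform disks", {
  n <- 49
  f <- frame_with_object(disk_mask(c(n, n), 25, 25, 20), 0.5)
  rd <- measure_radial(f$labels, f$image)
  fracs <- unlist(rd[1, grepl("FracAtD", names(rd))])
  expect_equal(sum(fracs), 1, tolerance = 1e-12)
  mf <- unlist(rd[1, grepl("MeanFrac", names(rd))])
  expect_true(all(abs(mf - 1) <= 0.1))
  cv <- unlist(rd[1, grepl("RadialCV", names(rd))])
  expect_true(all(cv[1:3] <= 0.1))  # innermost ring is discretization-limited
  # wedge-sum oracle for the outermost ring
  rc <- which(f$labels == 1L, arr.ind = TRUE)
  cent <- colMeans(rc)
  # conservation also holds for random intensities
  set.seed(3)
  f$image[f$labels == 1L] <- runif(sum(f$labels == 1L))
  rd2 <- measure_radial(f$labels, f$image)
  expect_equal(sum(unlist(rd2[1, grepl("FracAtD", names(rd2))])), 1, tolerance = 1e-12)
})

test_that("measure_all obeys the registry contract", {
  f <- disk_frame(c(100L, 100L), list(c(25, 25), c(30, 70), c(70, 45)),
                  c(12, 14, 16))
  img <- f$image
  reg <- feature_registry()
  ot <- measure_all(f$truth, img, reg)
  expect_equal(nrow(ot), 3L)
  expect_equal(ncol(ot), 6L + nrow(reg))
  expect_identical(names(ot)[-(1:6)], reg$column)
  # empty frame keeps the header
  ot0 <- measure_all(matrix(0L, 20, 20), matrix(0.5, 20, 20), reg)
  expect_equal(nrow(ot0), 0L)
  expect_identical(names(ot0), names(ot))
  # permuting the registry permutes the columns identically
  perm <- reg[rev(seq_len(nrow(reg))), ]
  otp <- measure_all(f$truth, img, perm)
  expect_identical(names(otp)[-(1:6)], rev(reg$column))
  expect_equal(otp[[reg$column[1]]], ot[[reg$column[1]]])
})

test_that("features are translation invariant and scale with intensity", {
  mask <- random_blob(99)
  big <- matrix(FALSE, 60, 60)
  big[10:39, 10:39] <- mask
  shifted <- matrix(FALSE, 60, 60)
  shifted[17:46, 21:50] <- mask  # shift by (7, 11)
  set.seed(4)
  vals <- runif(sum(mask))
  f1 <- frame_with_object(big, vals)
  f2 <- frame_with_object(shifted, vals)
  reg <- feature_registry()
  o1 <- measure_all(f1$labels, f1$image, reg)
  o2 <- measure_all(f2$labels, f2$image, reg)
  moving <- c("centroid_row", "centroid_col", "Intensity_CenterMassIntensityRow",
              "Intensity_CenterMassIntensityCol")
  for (col in setdiff(names(o1)[-(1:4)], moving)) {
    expect_equal(o2[[col]], o1[[col]], tolerance = 1e-9, label = col)
  }
  expect_equal(o2$centroid_row, o1$centroid_row + 7)
  expect_equal(o2$centroid_col, o1$centroid_col + 11)
  # intensity scaling by k
  k <- 0.37
  f3 <- f1; f3$image <- f1$image * k
  i1 <- measure_intensity(f1$labels, f1$image)
  i3 <- measure_intensity(f3$labels, f3$image)
  scaled <- c("IntegratedIntensity", "MeanIntensity", "StdIntensity",
              "MinIntensity", "MaxIntensity", "LowerQuartileIntensity",
              "MedianIntensity", "MADIntensity", "UpperQuartileIntensity")
  for (f in scaled) {
    expect_equal(i3[[paste0("Intensity_", f)]],
                 k * i1[[paste0("Intensity_", f)]], tolerance = 1e-12, label = f)
  }
  expect_equal(i3$Intensity_MassDisplacement, i1$Intensity_MassDisplacement,
               tolerance = 1e-9)
  r1 <- measure_radial(f1$labels, f1$image)
  r3 <- measure_radial(f3$labels, f3$image)
  for (col in setdiff(names(r1), "object_id")) {
    expect_equal(r3[[col]], r1[[col]], tolerance = 1e-9, label = col)
  }
})
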