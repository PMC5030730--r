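# Per-object morphometry: intensity, area/shape, neighbour and radial
# distribution feature families. Conventions, stated once and used
# everywhere: quantiles use linear interpolation between order statistics
# (type 7); standard deviations are population SDs (divide by n); angles are
# degrees in [0, 180]; coordinates are 1-based (row, col) pixel centres.

quart <- function(x, p) as.numeric(quantile(x, p, type = 7, names = FALSE))

#' Measure per-object intensity features
#'
#' For each object: integrated/mean/population-SD/min/max intensity over all
#' pixels and over the 8-connected boundary pixels; mass displacement (the
#' Euclidean distance in pixels between the binary centroid and the
#' intensity-weighted centroid); lower quartile, median, median absolute
#' deviation and upper quartile of intensities; and the intensity-weighted
#' centre of mass (row, col) — 17 features.
#'
#' @param labels LabelMap.
#' @param image GrayImage of the same shape (normalized intensities).
#' @return data.frame: `object_id` plus `Intensity_*` columns.
#' @export
measure_intensity <- function(labels, image) {
  if (!identical(dim(labels), dim(image))) stopf("labels/image shape mismatch")
  sets <- label_pixel_sets(labels)
  bnds <- object_boundaries(labels)
  out <- lapply(names(sets), function(id) {
    px <- sets[[id]]
    v <- image[px]
    rc <- idx_to_rc(px, nrow(labels))
    epx <- bnds[[id]]
    ev <- image[epx]
    tot <- sum(v)
    bc <- c(mean(rc[, 1L]), mean(rc[, 2L]))
    if (tot > 0) {
      wc <- c(sum(rc[, 1L] * v), sum(rc[, 2L] * v)) / tot
      md <- sqrt(sum((bc - wc)^2))
    } else {
      wc <- c(NA_real_, NA_real_); md <- NA_real_
    }
    c(IntegratedIntensity = tot, MeanIntensity = mean(v), StdIntensity = pop_sd(v),
      MinIntensity = min(v), MaxIntensity = max(v),
      IntegratedIntensityEdge = sum(ev), MeanIntensityEdge = mean(ev),
      StdIntensityEdge = pop_sd(ev), MinIntensityEdge = min(ev),
      MaxIntensityEdge = max(ev), MassDisplacement = md,
      LowerQuartileIntensity = quart(v, 0.25), MedianIntensity = quart(v, 0.5),
      MADIntensity = median(abs(v - median(v))),
      UpperQuartileIntensity = quart(v, 0.75),
      CenterMassIntensityRow = wc[1L], CenterMassIntensityCol = wc[2L])
  })
  names(out) <- names(sets)
  as_feature_frame(out, "Intensity")
}

# Second central moments of a pixel set under the unit-square pixel model
# (each pixel contributes variance 1/12 about its centre); x = col,
# y = -row so that orientation is counterclockwise in display coordinates.
pixel_moments <- function(rc) {
  x <- rc[, 2L]; y <- -rc[, 1L]
  mxx <- mean((x - mean(x))^2) + 1 / 12
  myy <- mean((y - mean(y))^2) + 1 / 12
  mxy <- mean((x - mean(x)) * (y - mean(y)))
  common <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (mxx + myy + common) / 2
  l2 <- (mxx + myy - common) / 2
  theta <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  if (theta < 0) theta <- theta + 180
  list(l1 = l1, l2 = l2, orientation = theta)
}

# Unit-square corner points of a pixel set (for convex hull / calipers).
pixel_corners <- function(rc) {
  r <- rc[, 1L]; cc <- rc[, 2L]
  cbind(row = c(r - 0.5, r - 0.5, r + 0.5, r + 0.5),
        col = c(cc - 0.5, cc + 0.5, cc - 0.5, cc + 0.5))
}

# Shoelace polygon area for hull vertex indices in order.
polygon_area <- function(pts) {
  x <- pts[, 2L]; y <- pts[, 1L]
  abs(sum(x * c(y[-1L], y[1L]) - c(x[-1L], x[1L]) * y)) / 2
}

# Corner-corrected chain-code perimeter (Vossepoel-Smeulders weights):
# 0.980 per orthogonal step, 1.406 per diagonal step, -0.091 per direction
# change — calibrated so digital-disk circumference matches 2*pi*r closely
# (plain 1/sqrt(2) path length overestimates disks by a constant ~4.9%).
chain_perimeter <- function(contour) {
  n <- nrow(contour)
  if (n < 2L) return(1)
  p <- rbind(contour, contour[1L, ])
  st <- diff(p)
  diagonal <- st[, 1L] != 0 & st[, 2L] != 0
  dirs <- atan2(st[, 2L], st[, 1L])
  corners <- sum(dirs != c(dirs[-1L], dirs[1L]))
  0.980 * sum(!diagonal) + 1.406 * sum(diagonal) - 0.091 * corners
}

# Feret diameters by rotating calipers over the corner hull, 1-degree sweep.
feret_diameters <- function(hull_pts) {
  ang <- seq(0, 179) * pi / 180
  x <- hull_pts[, 2L]; y <- hull_pts[, 1L]
  widths <- vapply(ang, function(a) {
    pr <- x * cos(a) + y * sin(a)
    max(pr) - min(pr)
  }, 0)
  c(max_feret = max(widths), min_feret = min(widths))
}

#' Measure per-object area and shape features
#'
#' For each object: area (pixel count); perimeter (corner-corrected
#' chain-code length of the outer 8-connected boundary path); form factor
#' `4*pi*Area/Perimeter^2` and its reciprocal compactness; eccentricity,
#' major/minor axis length and orientation of the ellipse with matching
#' second central moments (unit-square pixel model); solidity (area over
#' convex-hull area of pixel corners); extent (area over bounding-box area);
#' Euler number (components minus holes); equivalent diameter; max/min Feret
#' diameter (1-degree caliper sweep over the convex hull); and mean, median
#' and maximum interior distance-transform radius — 17 features.
#'
#' @param labels LabelMap.
#' @return data.frame: `object_id` plus `Shape_*` columns.
#' @export
measure_shape <- function(labels) {
  sets <- label_pixel_sets(labels)
  if (length(sets) == 0L) return(as_feature_frame(list(), "Shape"))
  contours <- EBImage::ocontour(EBImage::Image(t(labels)))
  dm <- label_distance_radii(labels)
  out <- lapply(names(sets), function(id) {
    px <- sets[[id]]
    rc <- idx_to_rc(px, nrow(labels))
    area <- length(px)
    # ocontour works on the transposed (x, y) image, 0-based
    ct <- contours[[id]]
    per <- if (is.null(ct) || nrow(ct) < 2L) 1 else chain_perimeter(ct)
    ff <- 4 * pi * area / per^2
    mom <- pixel_moments(rc)
    corners <- pixel_corners(rc)
    h <- chull(corners[, 2L], corners[, 1L])
    hull <- corners[h, , drop = FALSE]
    sol <- area / polygon_area(hull)
    bbox <- (diff(range(rc[, 1L])) + 1) * (diff(range(rc[, 2L])) + 1)
    fer <- feret_diameters(hull)
    radii <- dm[px]
    c(Area = area, Perimeter = per, FormFactor = ff, Compactness = 1 / ff,
      Eccentricity = sqrt(max(0, 1 - mom$l2 / mom$l1)),
      MajorAxisLength = 4 * sqrt(mom$l1), MinorAxisLength = 4 * sqrt(mom$l2),
      Orientation = mom$orientation, Solidity = sol, Extent = area / bbox,
      EulerNumber = euler_number(rc), EquivalentDiameter = equivalent_diameter(area),
      MaxFeretDiameter = fer[["max_feret"]], MinFeretDiameter = fer[["min_feret"]],
      MeanRadius = mean(radii), MedianRadius = median(radii),
      MaximumRadius = max(radii))
  })
  names(out) <- names(sets)
  as_feature_frame(out, "Shape")
}

# Interior Euclidean distance to background for all objects at once.
label_distance_radii <- function(labels) {
  interior_distance(labels > 0L)
}

# Euler number of one object's pixel set: 1 - number of holes, where holes
# are 4-connected background components in the padded bounding box that do
# not touch the pad border (foreground 8-connected implies background holes
# 4-connected).
euler_number <- function(rc) {
  rr <- rc[, 1L] - min(rc[, 1L]) + 2L
  cc <- rc[, 2L] - min(rc[, 2L]) + 2L
  nr <- max(rr) + 1L; nc <- max(cc) + 1L
  m <- matrix(0L, nr, nc)
  m[cbind(rr, cc)] <- 1L
  bg <- matrix(as.integer(EBImage::bwlabel(1L - m)), nr, nc)  # 4-connected
  border <- unique(c(bg[1L, ], bg[nr, ], bg[, 1L], bg[, nc]))
  holes <- setdiff(unique(bg[bg > 0L]), border)
  1L - length(holes)
}

#' Measure per-object neighbour features
#'
#' Objects are expanded into the nearest-object partition of the frame (each
#' pixel assigned to the object at minimum Euclidean distance, ties to the
#' smaller label); neighbours are objects whose partition regions are
#' 8-adjacent. PercentTouching is the percentage of an object's boundary
#' pixels lying within `touch_dist` pixels of another object. Closest-object
#' features use centroid-to-centroid distances; the angle between the two
#' closest neighbours is measured at the object's centroid, in degrees
#' within [0, 180]. With fewer than 2 (or 3) objects in the frame the
#' closest (second-closest/angle) features are `NA` — 7 features.
#'
#' @param labels LabelMap.
#' @param touch_dist touching threshold in pixels (default 2).
#' @return data.frame: `object_id` plus `Neighbors_*` columns.
#' @export
measure_neighbors <- function(labels, touch_dist = 2) {
  sets <- label_pixel_sets(labels)
  n <- length(sets)
  if (n == 0L) return(as_feature_frame(list(), "Neighbors"))
  nr <- nrow(labels)
  ids <- as.integer(names(sets))
  cent <- t(vapply(sets, function(px) colMeans(idx_to_rc(px, nr)), numeric(2)))
  # distance of every pixel to each object (0 on the object)
  dmaps <- lapply(ids, function(k) {
    m <- matrix(as.numeric(labels != k), nrow(labels), ncol(labels))
    matrix(as.numeric(EBImage::distmap(m, metric = "euclidean")),
           nrow(labels), ncol(labels))
  })
  # nearest-object partition, ties to smaller label
  part <- matrix(ids[1L], nrow(labels), ncol(labels))
  best <- dmaps[[1L]]
  if (n > 1L) for (k in 2L:n) {
    better <- dmaps[[k]] < best
    part[better] <- ids[k]
    best[better] <- dmaps[[k]][better]
  }
  adj <- partition_adjacency(part)
  bnds <- object_boundaries(labels)
  out <- lapply(seq_len(n), function(i) {
    k <- ids[i]
    nn <- sum(adj[i, ])
    bpx <- bnds[[i]]
    if (n > 1L) {
      other_min <- Reduce(pmin, lapply(setdiff(seq_len(n), i),
                                       function(j) dmaps[[j]][bpx]))
      pct <- 100 * mean(other_min <= touch_dist)
      d <- sqrt(rowSums((cent[-i, , drop = FALSE] -
                         matrix(cent[i, ], n - 1L, 2L, byrow = TRUE))^2))
      ord <- order(d, ids[-i])
      nb_ids <- unname(ids[-i][ord]); nb_d <- unname(d[ord])
      first_id <- nb_ids[1L]; first_d <- nb_d[1L]
      if (n > 2L) {
        second_id <- nb_ids[2L]; second_d <- nb_d[2L]
        v1 <- cent[match(first_id, ids), ] - cent[i, ]
        v2 <- cent[match(second_id, ids), ] - cent[i, ]
        cosang <- sum(v1 * v2) / (sqrt(sum(v1^2)) * sqrt(sum(v2^2)))
        ang <- acos(min(1, max(-1, cosang))) * 180 / pi
      } else {
        second_id <- NA_real_; second_d <- NA_real_; ang <- NA_real_
      }
    } else {
      pct <- 0; first_id <- NA_real_; first_d <- NA_real_
      second_id <- NA_real_; second_d <- NA_real_; ang <- NA_real_
    }
    c(NumberOfNeighbors = nn, PercentTouching = pct,
      FirstClosestObjectNumber = as.numeric(first_id),
      FirstClosestDistance = first_d,
      SecondClosestObjectNumber = as.numeric(second_id),
      SecondClosestDistance = second_d, AngleBetweenNeighbors = ang)
  })
  names(out) <- names(sets)
  as_feature_frame(out, "Neighbors")
}

# 8-adjacency between regions of a full-frame partition.
partition_adjacency <- function(part) {
  ids <- sort(unique(as.vector(part)))
  n <- length(ids)
  adj <- matrix(FALSE, n, n, dimnames = list(ids, ids))
  nr <- nrow(part); nc <- ncol(part)
  pairs <- rbind(
    cbind(as.vector(part[-nr, ]), as.vector(part[-1L, ])),
    cbind(as.vector(part[, -nc]), as.vector(part[, -1L])),
    cbind(as.vector(part[-nr, -nc]), as.vector(part[-1L, -1L])),
    cbind(as.vector(part[-nr, -1L]), as.vector(part[-1L, -nc])))
  pairs <- pairs[pairs[, 1L] != pairs[, 2L], , drop = FALSE]
  if (nrow(pairs)) {
    i <- match(pairs[, 1L], ids); j <- match(pairs[, 2L], ids)
    adj[cbind(i, j)] <- TRUE
    adj[cbind(j, i)] <- TRUE
  }
  adj
}

#' Measure per-object radial intensity distribution features
#'
#' Each object pixel gets a normalized radial coordinate
#' `r = d_edge / (d_edge + d_centre)` (0 towards the edge, 1 at the centre),
#' where `d_edge` is the interior Euclidean distance to background and
#' `d_centre` the distance to the object's innermost pixels (the maxima of
#' the distance transform). The coordinate is split into `n_rings` equal
#' bins, ring 1 outermost. Per ring: `FracAtD` (fraction of total object
#' intensity), `MeanFrac` (`FracAtD` over the fraction of pixels in the
#' ring; 1 everywhere for uniform objects), and `RadialCV` (population
#' coefficient of variation of per-wedge intensity sums across `n_wedges`
#' angular sectors about the centroid) — `3 * n_rings` features (12 at
#' defaults).
#'
#' @param labels LabelMap.
#' @param image GrayImage of the same shape.
#' @param n_rings number of radial bins (default 4).
#' @param n_wedges number of angular wedges (default 8).
#' @return data.frame: `object_id` plus `Radial_*` columns.
#' @export
measure_radial <- function(labels, image, n_rings = 4L, n_wedges = 8L) {
  if (!identical(dim(labels), dim(image))) stopf("labels/image shape mismatch")
  sets <- label_pixel_sets(labels)
  d_edge_all <- interior_distance(labels > 0L)
  nr <- nrow(labels)
  out <- lapply(sets, function(px) {
    rc <- idx_to_rc(px, nr)
    d_edge <- d_edge_all[px]
    centers <- rc[abs(d_edge - max(d_edge)) < 1e-9, , drop = FALSE]
    d_cen <- apply(rc, 1L, function(p) {
      sqrt(min((centers[, 1L] - p[1L])^2 + (centers[, 2L] - p[2L])^2))
    })
    rhat <- d_edge / (d_edge + d_cen)
    rhat[d_edge + d_cen == 0] <- 1
    ring <- pmin(floor(rhat * n_rings) + 1L, n_rings)
    v <- image[px]
    tot <- sum(v)
    cent <- colMeans(rc)
    ang <- atan2(rc[, 1L] - cent[1L], rc[, 2L] - cent[2L])
    ang[ang < 0] <- ang[ang < 0] + 2 * pi
    wedge <- pmin(floor(ang / (2 * pi / n_wedges)) + 1L, n_wedges)
    frac <- mfrac <- rcv <- rep(NA_real_, n_rings)
    for (b in seq_len(n_rings)) {
      in_ring <- ring == b
      if (!any(in_ring)) { frac[b] <- 0; next }
      frac[b] <- if (tot > 0) sum(v[in_ring]) / tot else NA_real_
      mfrac[b] <- frac[b] / (sum(in_ring) / length(px))
      wsum <- vapply(seq_len(n_wedges),
                     function(w) sum(v[in_ring & wedge == w]), 0)
      rcv[b] <- if (mean(wsum) > 0) pop_sd(wsum) / mean(wsum) else NA_real_
    }
    setNames(c(frac, mfrac, rcv), radial_feature_names(n_rings))
  })
  as_feature_frame(out, "Radial", radial_feature_names(n_rings))
}

as_feature_frame <- function(out, family, feature_names = NULL) {
  if (length(out) == 0L) {
    nm <- switch(family,
                 Intensity = intensity_feature_names,
                 Shape = shape_feature_names,
                 Neighbors = neighbor_feature_names,
                 feature_names %||% character(0))
    df <- as.data.frame(matrix(numeric(0), 0L, length(nm) + 1L))
    names(df) <- c("object_id", paste(family, nm, sep = "_"))
    return(df)
  }
  m <- do.call(rbind, out)
  df <- data.frame(object_id = as.integer(names(out)), m, check.names = FALSE)
  names(df) <- c("object_id", paste(family, colnames(m), sep = "_"))
  rownames(df) <- NULL
  df
}

#' Measure all registry features for one frame
#'
#' Runs the four measurement families and assembles one row per object with
#' frame metadata, centroid coordinates, and the registry's features in
#' registry order.
#'
#' @param labels LabelMap.
#' @param image GrayImage of the same shape.
#' @param registry feature registry (default [feature_registry()]); only
#'   registered columns are kept, in registry order.
#' @param meta frame metadata as from [parse_frame_metadata()] (or a list
#'   with `plate_id`, `well_id`, `hour`).
#' @return ObjectTable data.frame (0 rows for an empty frame, header kept).
#' @export
measure_all <- function(labels, image, registry = feature_registry(),
                        meta = list(plate_id = "P1", well_id = "A1", hour = 0L)) {
  n_rings <- sum(grepl("^FracAtD_", registry$name[registry$family == "Radial"]))
  if (n_rings == 0L) n_rings <- 4L
  parts <- list(measure_intensity(labels, image), measure_shape(labels),
                measure_neighbors(labels), measure_radial(labels, image, n_rings))
  sets <- label_pixel_sets(labels)
  cent <- if (length(sets)) {
    t(vapply(sets, function(px) colMeans(idx_to_rc(px, nrow(labels))), numeric(2)))
  } else matrix(numeric(0), 0L, 2L)
  df <- data.frame(plate_id = rep(meta$plate_id, length(sets)),
                   well_id = rep(meta$well_id, length(sets)),
                   hour = rep(as.integer(meta$hour), length(sets)),
                   object_id = as.integer(names(sets)),
                   centroid_row = cent[, 1L], centroid_col = cent[, 2L],
                   stringsAsFactors = FALSE)
  for (p in parts) {
    stopifnot(nrow(p) == nrow(df))
    for (col in setdiff(names(p), "object_id")) df[[col]] <- p[[col]]
  }
  missing_cols <- setdiff(registry$column, names(df))
  if (length(missing_cols)) {
    stopf("registry features not produced by measurement: %s",
          paste(missing_cols, collapse = ", "))
  }
  df[, c("plate_id", "well_id", "hour", "object_id", "centroid_row",
         "centroid_col", registry$column), drop = FALSE]
}
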