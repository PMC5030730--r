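# Fixture builders and independent brute-force oracles. Oracles are written
# as plain enumerations, independent of the package's implementation paths.

# ---- fixture builders -------------------------------------------------------

# Render a digital disk mask: pixel centres within radius r of (cr, cc).
disk_mask <- function(shape, cr, cc, r) {
  rows <- matrix(rep(seq_len(shape[1]), shape[2]), shape[1], shape[2])
  cols <- matrix(rep(seq_len(shape[2]), each = shape[1]), shape[1], shape[2])
  sqrt((rows - cr)^2 + (cols - cc)^2) <= r
}

# Frame with dark disks on a bright background (full contrast for the
# default segmentation thresholds); returns image + truth label map.
disk_frame <- function(shape, centers, diameters, bg = 0.85, fg = 0.10) {
  img <- matrix(bg, shape[1], shape[2])
  truth <- matrix(0L, shape[1], shape[2])
  for (k in seq_along(diameters)) {
    m <- disk_mask(shape, centers[[k]][1], centers[[k]][2], diameters[k] / 2)
    img[m] <- fg
    truth[m] <- k
  }
  list(image = img, truth = truth)
}

# Random frame of well-separated disks, one diameter drawn per disk from the
# three scale bands; rejection placement with edge-to-edge gap >= gap px and
# a clear border margin.
random_multiscale_frame <- function(seed, shape = c(220L, 220L),
                                    bands = list(c(6, 18), c(24, 38), c(44, 60)),
                                    n_range = 2:4, gap = 5) {
  set.seed(seed)
  n <- sample(n_range, 1)
  ds <- vapply(seq_len(n), function(i) {
    b <- bands[[sample(length(bands), 1)]]
    runif(1, b[1], b[2])
  }, 0)
  ds <- sort(ds, decreasing = TRUE)  # place big ones first
  centers <- list()
  for (k in seq_len(n)) {
    r <- ds[k] / 2
    for (try in 1:500) {
      p <- c(runif(1, r + 3, shape[1] - r - 3), runif(1, r + 3, shape[2] - r - 3))
      ok <- TRUE
      for (j in seq_len(k - 1)) {
        if (sqrt(sum((p - centers[[j]])^2)) < r + ds[j] / 2 + gap) { ok <- FALSE; break }
      }
      if (ok) { centers[[k]] <- p; break }
    }
    if (length(centers) < k) stop("placement failed")
  }
  c(disk_frame(shape, centers, ds), list(diameters = ds, centers = centers))
}

# Random connected blob within a box: union of a few small disks, kept to
# its largest 8-connected component.
random_blob <- function(seed, box = 30L) {
  set.seed(seed)
  m <- matrix(FALSE, box, box)
  n <- sample(2:4, 1)
  for (i in seq_len(n)) {
    m <- m | disk_mask(c(box, box), runif(1, 8, box - 8), runif(1, 8, box - 8),
                       runif(1, 2.5, 6))
  }
  lab <- label_components(m, 8L)
  areas <- tabulate(lab[lab > 0], nbins = max(lab))
  (lab == which.max(areas))
}

# Single-object frame: label map + intensity image from a mask.
frame_with_object <- function(mask, values = NULL) {
  lab <- matrix(0L, nrow(mask), ncol(mask))
  lab[mask] <- 1L
  img <- matrix(0, nrow(mask), ncol(mask))
  if (!is.null(values)) img[mask] <- values
  list(labels = lab, image = img)
}

# ---- brute-force oracles ----------------------------------------------------

# (row, col) coordinates of a mask's pixels.
mask_rc <- function(mask) which(mask, arr.ind = TRUE)

shoelace <- function(x, y) {
  abs(sum(x * c(y[-1], y[1]) - c(x[-1], x[1]) * y)) / 2
}

# Shape oracle: direct pixel enumeration, same definitions as documented
# (unit-square pixel model, +1/12 moments, 1-degree caliper sweep,
# brute-force interior radii), coded without package internals.
oracle_shape <- function(mask) {
  rc <- mask_rc(mask)
  area <- nrow(rc)
  # moments (x = col, y = -row)
  x <- rc[, 2]; y <- -rc[, 1]
  mxx <- sum((x - mean(x))^2) / area + 1 / 12
  myy <- sum((y - mean(y))^2) / area + 1 / 12
  mxy <- sum((x - mean(x)) * (y - mean(y))) / area
  tr <- mxx + myy; dt <- sqrt((mxx - myy)^2 + 4 * mxy^2)
  l1 <- (tr + dt) / 2; l2 <- (tr - dt) / 2
  ori <- 0.5 * atan2(2 * mxy, mxx - myy) * 180 / pi
  if (ori < 0) ori <- ori + 180
  # hull of pixel corners
  cx <- c(rc[, 2] - 0.5, rc[, 2] + 0.5, rc[, 2] - 0.5, rc[, 2] + 0.5)
  cy <- c(rc[, 1] - 0.5, rc[, 1] - 0.5, rc[, 1] + 0.5, rc[, 1] + 0.5)
  h <- chull(cx, cy)
  hull_area <- shoelace(cx[h], cy[h])
  # Feret by explicit sweep
  widths <- vapply(seq(0, 179) * pi / 180, function(a) {
    pr <- cx[h] * cos(a) + cy[h] * sin(a)
    max(pr) - min(pr)
  }, 0)
  # Euler: flood-fill background 4-connected in padded bbox (1-px pad on
  # every side so the outer background is a single component)
  rr <- rc[, 1] - min(rc[, 1]) + 2L
  cc2 <- rc[, 2] - min(rc[, 2]) + 2L
  nr <- max(rr) + 1L; nc <- max(cc2) + 1L
  g <- matrix(FALSE, nr, nc)
  g[cbind(rr, cc2)] <- TRUE
  seen <- g
  flood <- function(sr, sc) {
    stack <- list(c(sr, sc)); px <- 0L
    while (length(stack)) {
      p <- stack[[length(stack)]]; stack[[length(stack)]] <- NULL
      if (p[1] < 1 || p[1] > nr || p[2] < 1 || p[2] > nc) next
      if (seen[p[1], p[2]]) next
      seen[p[1], p[2]] <<- TRUE; px <- px + 1L
      stack <- c(stack, list(c(p[1] - 1, p[2]), c(p[1] + 1, p[2]),
                             c(p[1], p[2] - 1), c(p[1], p[2] + 1)))
    }
    px
  }
  flood(1L, 1L)  # outer background (box border is background by construction)
  holes <- 0L
  for (i in seq_len(nr)) for (j in seq_len(nc)) {
    if (!seen[i, j]) { holes <- holes + 1L; flood(i, j) }
  }
  # interior radii: min distance to any background pixel (including border
  # beyond the image, handled by the pad used in the implementation; here
  # the blob never touches the frame border so in-frame background suffices)
  bg <- which(!mask, arr.ind = TRUE)
  radii <- apply(rc, 1, function(p) {
    sqrt(min((bg[, 1] - p[1])^2 + (bg[, 2] - p[2])^2))
  })
  list(Area = area,
       Extent = area / ((diff(range(rc[, 1])) + 1) * (diff(range(rc[, 2])) + 1)),
       Solidity = area / hull_area,
       EulerNumber = 1L - holes,
       EquivalentDiameter = 2 * sqrt(area / pi),
       Eccentricity = sqrt(max(0, 1 - l2 / l1)),
       MajorAxisLength = 4 * sqrt(l1), MinorAxisLength = 4 * sqrt(l2),
       Orientation = ori,
       MaxFeretDiameter = max(widths), MinFeretDiameter = min(widths),
       MeanRadius = mean(radii), MedianRadius = median(radii),
       MaximumRadius = max(radii))
}

# Literal implementation of the outlier-excluded interquartile mean:
# (1) drop values beyond sd_k population SDs from the mean, one pass;
# (2) Q1/Q3 by linear interpolation; (3) mean of survivors within [Q1, Q3].
oracle_hourly_stat <- function(x, sd_k = 3) {
  x <- x[is.finite(x)]
  mu <- sum(x) / length(x)
  s <- sqrt(sum((x - mu)^2) / length(x))
  kept <- x[abs(x - mu) <= sd_k * s]
  q <- quantile(kept, c(0.25, 0.75), type = 7, names = FALSE)
  mean(kept[kept >= q[1] & kept <= q[2]])
}

# Brute-force IoU matrix between two label maps.
oracle_iou <- function(pred, truth) {
  np <- max(pred); nt <- max(truth)
  m <- matrix(0, np, nt)
  for (i in seq_len(np)) {
    pi_ <- which(pred == i)
    for (j in seq_len(nt)) {
      tj <- which(truth == j)
      inter <- length(intersect(pi_, tj))
      m[i, j] <- inter / (length(pi_) + length(tj) - inter)
    }
  }
  m
}

# Minimum pixel-centre distance between two pixel index sets of a matrix.
oracle_min_distance <- function(lab, a, b) {
  ra <- which(lab == a, arr.ind = TRUE)
  rb <- which(lab == b, arr.ind = TRUE)
  sqrt(min(outer(ra[, 1], rb[, 1], "-")^2 + outer(ra[, 2], rb[, 2], "-")^2))
}

# Pixel sets of a label map as a canonical (sorted) list for set comparison.
pixel_set_list <- function(lab) {
  ids <- setdiff(sort(unique(as.vector(lab))), 0L)
  lapply(ids, function(k) sort(which(lab == k)))
}

# Do two label maps induce the same partition of foreground pixels?
same_partition <- function(a, b) {
  sa <- pixel_set_list(a); sb <- pixel_set_list(b)
  if (length(sa) != length(sb)) return(FALSE)
  key <- function(s) paste(vapply(s, function(p) paste(p, collapse = ","), ""), collapse = ";")
  setequal(vapply(sa, function(p) paste(p, collapse = ","), ""),
           vapply(sb, function(p) paste(p, collapse = ","), ""))
}
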