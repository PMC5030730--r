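# Synthetic phase-contrast-like time-lapse plates with ground truth, and
# synthetic feature tables with known linear trends. The generator emulates
# hourly imaging of adherent cells: dark, roughly circular cells on a bright
# background with a thin bright halo, spreading (area growing linearly at a
# condition-dependent rate) and optionally clumping over time. It does not
# model phase-contrast optics, cell division or death.

#' Specification for a synthetic plate
#'
#' Defaults emulate the study conditions of the motivating assay: hourly
#' frames over 24 h, two cell lines plated on three fibronectin
#' concentrations (1, 5, 25 ug/mL), with the area growth rate increasing
#' with concentration (higher FN, faster spreading). Cell intensity defaults
#' put inverted cell pixels (1 - (background - contrast) = 0.90) above the
#' strictest segmentation threshold (0.78), and the halo above background so
#' thresholding excludes it.
#'
#' @param wells data.frame with columns `well`, `cell_line`, `condition`
#'   (and optionally `condition_value`); default 2 lines x 3 conditions.
#' @param plate_id plate identifier (default `"P1"`).
#' @param n_hours hourly frames per well (default 24; hours 0..23).
#' @param cells_per_well initial cells per well (default 8).
#' @param radius_mean,radius_sd initial cell radius distribution, px.
#' @param growth_rates named numeric: area growth rate (px^2 per hour) per
#'   condition label.
#' @param clump_prob probability per hour that a pair of cells is moved into
#'   contact and merges into one clump object (default 0).
#' @param background,contrast,halo background intensity, cell contrast and
#'   halo amplitude on the normalized [0, 1] scale.
#' @param noise_sd additive Gaussian noise SD (default 0.01).
#' @param shape frame shape `c(rows, cols)` (default 192 x 192).
#' @param min_gap minimum edge-to-edge gap enforced at placement, accounting
#'   for final radii (default 6 px).
#' @param seed base seed; every stream (placement, clumping, noise) derives
#'   from it, so plates are fully reproducible.
#' @return a `synthetic_plate_spec` list.
#' @export
synthetic_plate_spec <- function(wells = default_plate_wells(),
                                 plate_id = "P1", n_hours = 24L,
                                 cells_per_well = 8L, radius_mean = 5,
                                 radius_sd = 0.8,
                                 growth_rates = c("1" = 2, "5" = 4, "25" = 8),
                                 clump_prob = 0, background = 0.85,
                                 contrast = 0.75, halo = 0.08,
                                 noise_sd = 0.01, shape = c(192L, 192L),
                                 min_gap = 6, seed = 1L) {
  stopifnot(is.data.frame(wells), all(c("well", "cell_line", "condition") %in% names(wells)))
  if (clump_prob < 0 || clump_prob > 1) stopf("clump_prob must lie in [0, 1]")
  if (radius_mean <= 0) stopf("radius_mean must be positive")
  miss <- setdiff(unique(as.character(wells$condition)), names(growth_rates))
  if (length(miss)) stopf("no growth rate for condition(s): %s",
                          paste(miss, collapse = ", "))
  if (is.null(wells$condition_value)) {
    wells$condition_value <- suppressWarnings(as.numeric(wells$condition))
  }
  structure(list(wells = wells, plate_id = plate_id,
                 n_hours = as.integer(n_hours),
                 cells_per_well = as.integer(cells_per_well),
                 radius_mean = radius_mean, radius_sd = radius_sd,
                 growth_rates = growth_rates, clump_prob = clump_prob,
                 background = background, contrast = contrast, halo = halo,
                 noise_sd = noise_sd, shape = as.integer(shape),
                 min_gap = min_gap, seed = as.integer(seed)),
            class = "synthetic_plate_spec")
}

default_plate_wells <- function() {
  data.frame(well = c("B2", "B3", "B4", "C2", "C3", "C4"),
             cell_line = rep(c("L1", "L2"), each = 3L),
             condition = rep(c("1", "5", "25"), 2L),
             stringsAsFactors = FALSE)
}

well_index <- function(spec, well) {
  i <- match(well, spec$wells$well)
  if (is.na(i)) stopf("well '%s' is not in the plate spec", well)
  i
}

# Deterministic per-well cell trajectory: positions, per-hour radii, clump
# membership per hour. Growth is linear in area at the condition's rate.
well_trajectory <- function(spec, well) {
  i <- well_index(spec, well)
  cond <- as.character(spec$wells$condition[i])
  g <- spec$growth_rates[[cond]]
  n <- spec$cells_per_well
  nh <- spec$n_hours
  with_seed(derive_seed(spec$seed, i), {
    r0 <- pmax(2, rnorm(n, spec$radius_mean, spec$radius_sd))
    area <- outer(r0^2 * pi, g * (0:(nh - 1L)), "+")   # n x nh
    radius <- sqrt(area / pi)
    r_final <- radius[, nh]
    margin <- max(r_final) + 3
    nr <- spec$shape[1L]; nc <- spec$shape[2L]
    if (2 * margin >= min(nr, nc)) {
      stopf("frame %dx%d too small for cells of final radius %.1f",
            nr, nc, max(r_final))
    }
    pos <- matrix(NA_real_, n, 2L)
    for (k in seq_len(n)) {
      placed <- FALSE
      for (try in seq_len(1000L)) {
        p <- c(runif(1, margin, nr - margin), runif(1, margin, nc - margin))
        if (k == 1L) { ok <- TRUE } else {
          d <- sqrt(rowSums((pos[seq_len(k - 1L), , drop = FALSE] -
                             matrix(p, k - 1L, 2L, byrow = TRUE))^2))
          ok <- all(d >= r_final[k] + r_final[seq_len(k - 1L)] + spec$min_gap)
        }
        if (ok) { pos[k, ] <- p; placed <- TRUE; break }
      }
      if (!placed) stopf("could not place cell %d in well %s after 1000 tries", k, well)
    }
    # clump events: at each hour, with clump_prob, move the closest pair of
    # cells from different clumps into contact; membership persists
    clump <- matrix(rep(seq_len(n), nh), n, nh)
    member <- seq_len(n)
    for (h in seq_len(nh - 1L)) {  # events at hours 1..nh-1
      if (n >= 2L && runif(1) < spec$clump_prob && length(unique(member)) > 1L) {
        d <- as.matrix(dist(pos))
        d[outer(member, member, "==")] <- Inf
        pick <- arrayInd(which.min(d), dim(d))
        a <- pick[1L]; b <- pick[2L]
        dir <- pos[a, ] - pos[b, ]
        dir <- dir / sqrt(sum(dir^2))
        pos[b, ] <- pos[a, ] - dir * (radius[a, h + 1L] + radius[b, h + 1L] - 1)
        member[member == member[b]] <- member[a]
      }
      clump[, h + 1L] <- member
    }
    list(pos = pos, radius = radius, clump = clump, condition = cond,
         cell_line = spec$wells$cell_line[i])
  })
}

#' Render one synthetic frame with its ground-truth label map
#'
#' Cells are dark disks (`background - contrast`) with a bright 1.5-px halo
#' ring (`background + halo`); Gaussian noise is added and the image clipped
#' to `[0, 1]`. The truth LabelMap is rendered before noise; cells that have
#' clumped share one truth label from the first contact hour onward. Fully
#' deterministic given `(spec, well, hour)`.
#'
#' @param spec [synthetic_plate_spec()].
#' @param well well id present in `spec$wells`.
#' @param hour hour in `0..n_hours-1`.
#' @return list with `image` (GrayImage), `labels` (truth LabelMap), and
#'   `truth` (data.frame: `object_id`, `centroid_row`, `centroid_col`,
#'   `area`, `n_cells`).
#' @export
generate_frame <- function(spec, well, hour) {
  if (hour < 0L || hour >= spec$n_hours) {
    stopf("hour %d outside 0..%d", hour, spec$n_hours - 1L)
  }
  traj <- well_trajectory(spec, well)
  nr <- spec$shape[1L]; nc <- spec$shape[2L]
  h <- hour + 1L
  img <- matrix(spec$background, nr, nc)
  disk <- matrix(FALSE, nr, nc)
  halo <- matrix(FALSE, nr, nc)
  cell_mask <- vector("list", nrow(traj$pos))
  rows <- matrix(rep(seq_len(nr), nc), nr, nc)
  cols <- matrix(rep(seq_len(nc), each = nr), nr, nc)
  for (k in seq_len(nrow(traj$pos))) {
    d <- sqrt((rows - traj$pos[k, 1L])^2 + (cols - traj$pos[k, 2L])^2)
    m <- d <= traj$radius[k, h]
    cell_mask[[k]] <- m
    disk <- disk | m
    halo <- halo | (d > traj$radius[k, h] & d <= traj$radius[k, h] + 1.5)
  }
  halo <- halo & !disk
  img[halo] <- spec$background + spec$halo
  img[disk] <- spec$background - spec$contrast
  if (spec$noise_sd > 0) {
    i <- well_index(spec, well)
    with_seed(derive_seed(spec$seed, i, hour + 1L), {
      img <- img + matrix(rnorm(nr * nc, 0, spec$noise_sd), nr, nc)
    })
  }
  img <- pmin(pmax(img, 0), 1)
  # truth labels: one label per clump group, relabeled in raster order
  groups <- traj$clump[, h]
  lab <- matrix(0L, nr, nc)
  for (g in unique(groups)) {
    m <- Reduce(`|`, cell_mask[groups == g])
    lab[m] <- as.integer(g)
  }
  lab <- relabel_raster(lab)
  sets <- label_pixel_sets(lab)
  truth <- data.frame(
    object_id = as.integer(names(sets)),
    centroid_row = vapply(sets, function(px) mean(idx_to_rc(px, nr)[, 1L]), 0),
    centroid_col = vapply(sets, function(px) mean(idx_to_rc(px, nr)[, 2L]), 0),
    area = vapply(sets, length, 0L),
    n_cells = vapply(as.integer(names(sets)), function(l) {
      sum(vapply(seq_along(cell_mask), function(k) {
        any(lab[cell_mask[[k]]] == l)
      }, logical(1)))
    }, 0L),
    stringsAsFactors = FALSE)
  rownames(truth) <- NULL
  list(image = img, labels = lab, truth = truth)
}

#' Generate a full synthetic time-lapse plate on disk
#'
#' Writes one frame per (well, hour) using the plate filename template, the
#' matching truth label maps, a per-object truth table (CSV) and a plate-map
#' CSV, ready for [cmd_segment()].
#'
#' @param spec [synthetic_plate_spec()].
#' @param dir output directory (created if absent).
#' @param format `"tiff"` (16-bit, default) or `"png"` (8-bit).
#' @param template filename template with `{plate}`, `{well}`, `{hour}`.
#' @return manifest list: `frame_dir`, `truth_dir`, `plate_map` (path),
#'   `truth_table` (path), `frames` (data.frame of paths + metadata).
#' @export
generate_timelapse <- function(spec, dir, format = c("tiff", "png"),
                               template = "{plate}_{well}_{hour}h.tif") {
  format <- match.arg(format)
  ext <- if (format == "tiff") "tif" else "png"
  template <- sub("\\.[A-Za-z]+$", paste0(".", ext), template)
  frame_dir <- file.path(dir, "frames")
  truth_dir <- file.path(dir, "truth")
  dir.create(frame_dir, recursive = TRUE, showWarnings = FALSE)
  dir.create(truth_dir, recursive = TRUE, showWarnings = FALSE)
  rows <- list(); truths <- list()
  for (w in spec$wells$well) {
    for (hour in 0:(spec$n_hours - 1L)) {
      fr <- generate_frame(spec, w, hour)
      base <- template
      base <- sub("{plate}", spec$plate_id, base, fixed = TRUE)
      base <- sub("{well}", w, base, fixed = TRUE)
      base <- sub("{hour}", sprintf("%02d", hour), base, fixed = TRUE)
      fpath <- file.path(frame_dir, base)
      write_frame(fr$image, fpath, bits = if (format == "tiff") 16L else 8L)
      lpath <- file.path(truth_dir, paste0(tools::file_path_sans_ext(base),
                                           "_labels.tif"))
      write_label_map(fr$labels, lpath)
      rows[[length(rows) + 1L]] <- data.frame(
        plate_id = spec$plate_id, well_id = w, hour = hour, path = fpath,
        truth_path = lpath, stringsAsFactors = FALSE)
      tr <- fr$truth
      if (nrow(tr)) {
        tr$plate_id <- spec$plate_id; tr$well_id <- w; tr$hour <- hour
        truths[[length(truths) + 1L]] <- tr
      }
    }
  }
  pm_path <- file.path(dir, "plate_map.csv")
  pm <- data.frame(plate = spec$plate_id, well = spec$wells$well,
                   cell_line = spec$wells$cell_line,
                   condition = spec$wells$condition,
                   condition_value = spec$wells$condition_value,
                   replicate_group = spec$wells$cell_line,
                   stringsAsFactors = FALSE)
  write.table(pm, pm_path, sep = ",", row.names = FALSE, qmethod = "double")
  tt_path <- file.path(dir, "truth_objects.csv")
  tt <- do.call(rbind, truths)
  write.table(tt, tt_path, sep = ",", row.names = FALSE, qmethod = "double")
  list(frame_dir = frame_dir, truth_dir = truth_dir, plate_map = pm_path,
       truth_table = tt_path, frames = do.call(rbind, rows),
       template = template)
}

#' Synthetic object table with known linear feature trends
#'
#' Object values of feature `f` at hour `h` are drawn as
#' `intercept_f + slope_f * h + N(0, noise_sd)` — a direct test harness for
#' the trend-reduction step with exactly known ground truth.
#'
#' @param registry feature registry whose columns are generated.
#' @param slopes,intercepts numeric, length 1 or `nrow(registry)` (named by
#'   registry column or positional).
#' @param noise_sd Gaussian noise SD (0 gives exactly linear data).
#' @param objects_per_hour scalar or per-hour vector; hours with 0 objects
#'   are absent from the table.
#' @param n_hours number of hours (0-indexed).
#' @param seed RNG seed.
#' @param plate,well,cell_line,condition metadata stamped on all rows.
#' @return annotated ObjectTable data.frame.
#' @export
generate_feature_table <- function(registry = feature_registry(), slopes = 1,
                                   intercepts = 0, noise_sd = 0,
                                   objects_per_hour = 50L, n_hours = 24L,
                                   seed = 1L, plate = "P1", well = "B2",
                                   cell_line = "L1", condition = "1") {
  nf <- nrow(registry)
  expand <- function(x) {
    if (length(x) == 1L) return(rep(as.numeric(x), nf))
    if (!is.null(names(x))) {
      out <- x[registry$column]
      if (anyNA(out)) stopf("slopes/intercepts do not cover the registry")
      return(as.numeric(out))
    }
    if (length(x) != nf) stopf("slopes/intercepts length must be 1 or %d", nf)
    as.numeric(x)
  }
  sl <- expand(slopes); ic <- expand(intercepts)
  oph <- if (length(objects_per_hour) == 1L) rep(objects_per_hour, n_hours) else objects_per_hour
  if (length(oph) != n_hours) stopf("objects_per_hour must have length 1 or n_hours")
  with_seed(derive_seed(seed, 1L), {
    rows <- list()
    for (h in 0:(n_hours - 1L)) {
      m <- oph[h + 1L]
      if (m == 0L) next
      vals <- matrix(rep(ic + sl * h, each = m), m, nf)
      if (noise_sd > 0) vals <- vals + matrix(rnorm(m * nf, 0, noise_sd), m, nf)
      df <- data.frame(plate_id = plate, well_id = well, hour = h,
                       object_id = seq_len(m),
                       centroid_row = runif(m, 1, 100),
                       centroid_col = runif(m, 1, 100),
                       stringsAsFactors = FALSE)
      colnames(vals) <- registry$column
      rows[[length(rows) + 1L]] <- cbind(df, as.data.frame(vals))
    }
    out <- do.call(rbind, rows)
    out$cell_line <- cell_line
    out$condition <- condition
    rownames(out) <- NULL
    out
  })
}
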