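# Multi-scale segmentation of single-channel phase-contrast frames.
#
# The frame is inverted (cells darker than background become bright), then
# thresholded and labeled independently at several length scales, each with
# its own manual threshold and equivalent-diameter band. The per-scale maps
# are integrated by largest-object priority (a smaller-scale object
# overlapping a larger-scale object is discarded as a sub-object) and fused
# through a contract/merge/relabel/expand round trip, which deliberately
# leaves touching cells in a clump as one object while keeping distinct
# neighbouring objects separate.

#' Per-scale segmentation parameters
#'
#' @param theta manual threshold in (0, 1) applied to the inverted,
#'   normalized frame: pixels with intensity >= `theta` are foreground.
#' @param d_min,d_max equivalent-diameter bounds in pixels for objects kept
#'   at this scale.
#' @param scale_index 1-based position of the scale (small to large).
#' @return a `scale_config` list.
#' @export
scale_config <- function(theta, d_min, d_max, scale_index = NA_integer_) {
  if (!is.numeric(theta) || theta <= 0 || theta >= 1) {
    stopf("theta must lie strictly inside (0, 1), got %s", format(theta))
  }
  if (!(d_min > 0 && d_max > d_min)) stopf("need 0 < d_min < d_max")
  structure(list(theta = theta, d_min = d_min, d_max = d_max,
                 scale_index = as.integer(scale_index)),
            class = "scale_config")
}

#' Segmentation configuration
#'
#' Defaults follow the three-scale setup used for iPSC phase-contrast frames:
#' thresholds 0.78 / 0.75 / 0.74 with diameter bands 5-20, 21-40, 41-65
#' pixels, within-scale unification distance 2 px, and a 1-px
#' contract/expand radius for the integration round trip.
#'
#' @param scales ordered list of [scale_config()] objects, small to large.
#' @param unify_distance objects at one scale closer than this (minimum
#'   pixel-centre Euclidean distance, px) are merged before integration.
#' @param contraction_radius erosion/expansion radius (px, Chebyshev) in the
#'   contract/merge/relabel/expand step.
#' @param final_d_range advisory equivalent-diameter bounds for final
#'   objects; only enforced when `enforce_final_d_range = TRUE`, because
#'   discarding large merged objects would delete clumps.
#' @param connectivity 4 or 8 (default 8) for components and boundaries.
#' @param discard_border drop objects touching the frame border at each
#'   scale (default `TRUE`).
#' @param overlap_policy fraction of a smaller-scale object's pixels that may
#'   overlap larger-scale objects before it is discarded as a sub-object;
#'   the default 0 discards on any shared pixel.
#' @param enforce_final_d_range apply `final_d_range` strictly (default
#'   `FALSE`).
#' @return a `segmentation_config` list.
#' @export
segmentation_config <- function(scales = list(scale_config(0.78, 5, 20, 1L),
                                              scale_config(0.75, 21, 40, 2L),
                                              scale_config(0.74, 41, 65, 3L)),
                                unify_distance = 2,
                                contraction_radius = 1L,
                                final_d_range = c(1, 40),
                                connectivity = 8L,
                                discard_border = TRUE,
                                overlap_policy = 0,
                                enforce_final_d_range = FALSE) {
  if (length(scales) < 1L) stopf("need at least one scale")
  d_max <- vapply(scales, function(s) s$d_max, 0)
  theta <- vapply(scales, function(s) s$theta, 0)
  if (is.unsorted(d_max, strictly = TRUE)) {
    stopf("scales must be ordered by strictly increasing d_max")
  }
  if (any(diff(theta) > 0)) {
    stopf("thresholds must be non-increasing from small to large scales")
  }
  if (unify_distance < 0) stopf("unify_distance must be >= 0")
  if (overlap_policy < 0 || overlap_policy >= 1) {
    stopf("overlap_policy must lie in [0, 1)")
  }
  structure(list(scales = scales, unify_distance = unify_distance,
                 contraction_radius = as.integer(contraction_radius),
                 final_d_range = final_d_range,
                 connectivity = as.integer(connectivity),
                 discard_border = isTRUE(discard_border),
                 overlap_policy = overlap_policy,
                 enforce_final_d_range = isTRUE(enforce_final_d_range)),
            class = "segmentation_config")
}

#' Normalize a raw frame to [0, 1] and invert it
#'
#' Cells in phase-contrast frames are darker than the background; inversion
#' makes them bright so that a single lower threshold isolates them. Integer
#' input is rescaled by its nominal bit-depth range (255 for 8-bit, 65535 for
#' 16-bit); floating-point input already in `[0, 1]` is used as is.
#'
#' @param image 2-D numeric matrix, any supported bit depth.
#' @param bit_depth override the inferred bit depth (8 or 16).
#' @return GrayImage: numeric matrix in `[0, 1]`, `1 - normalized(image)`.
#' @export
normalize_and_invert <- function(image, bit_depth = NULL) {
  if (!is.matrix(image) || !is.numeric(image)) {
    stopf("image must be a 2-D numeric matrix")
  }
  if (any(!is.finite(image))) stopf("image contains non-finite values")
  if (!is.null(bit_depth)) {
    rng <- switch(as.character(bit_depth), "8" = 255, "16" = 65535,
                  stopf("bit_depth must be 8 or 16"))
    img <- image / rng
  } else if (max(image) <= 1 && min(image) >= 0) {
    img <- image
  } else if (max(image) <= 255) {
    img <- image / 255
  } else if (max(image) <= 65535) {
    img <- image / 65535
  } else {
    stopf("cannot infer bit depth: image maximum %s", format(max(image)))
  }
  if (max(img) > 1 || min(img) < 0) stopf("normalized image escapes [0, 1]")
  1 - img
}

#' Threshold an inverted frame into a foreground mask
#'
#' @param inv GrayImage (inverted, normalized frame).
#' @param theta threshold in (0, 1); foreground is `inv >= theta`.
#' @return logical mask of the same shape.
#' @export
foreground_mask <- function(inv, theta) {
  if (!is.numeric(theta) || length(theta) != 1L || theta <= 0 || theta >= 1) {
    stopf("theta must be a single value strictly inside (0, 1)")
  }
  inv >= theta
}

#' Identify objects at one scale
#'
#' Connected components of the mask are filtered to the scale's
#' equivalent-diameter band (`2*sqrt(area/pi)` within `[d_min, d_max]`);
#' objects touching the frame border are discarded when configured. Labels
#' are renumbered in raster-scan order.
#'
#' @param mask logical foreground mask.
#' @param scale [scale_config()] for this scale.
#' @param config [segmentation_config()] (connectivity, border rule).
#' @return LabelMap.
#' @export
identify_scale_objects <- function(mask, scale, config = segmentation_config()) {
  lab <- label_components(mask, config$connectivity)
  if (max(lab) == 0L) return(lab)
  keep <- seq_len(max(lab))
  areas <- tabulate(lab[lab > 0L], nbins = max(lab))
  eqd <- equivalent_diameter(areas)
  keep <- keep[eqd >= scale$d_min & eqd <= scale$d_max]
  if (config$discard_border) keep <- setdiff(keep, border_labels(lab))
  lab[!(lab %in% keep)] <- 0L
  relabel_raster(lab)
}

#' Merge nearby objects within one scale
#'
#' Objects whose minimum pixel-centre Euclidean distance is `<= max_dist`
#' are merged (transitively); a merged object keeps the smaller label before
#' the map is renumbered contiguously in raster order.
#'
#' @param labels LabelMap.
#' @param max_dist maximum merge distance in pixels (default 2).
#' @return LabelMap.
#' @export
unify_by_distance <- function(labels, max_dist = 2) {
  if (max_dist < 0) stopf("max_dist must be >= 0")
  n <- max(labels)
  if (n <= 1L) return(labels)
  bnd <- mask_boundary(labels > 0L)
  sets <- label_pixel_sets(labels * bnd)
  # objects entirely boundary-less cannot occur (every object has a boundary)
  rc <- lapply(sets, idx_to_rc, nr = nrow(labels))
  bb <- t(vapply(rc, function(p) c(min(p[, 1L]), max(p[, 1L]),
                                   min(p[, 2L]), max(p[, 2L])), numeric(4)))
  ids <- as.integer(names(sets))
  edges <- NULL
  for (i in seq_along(ids)) {
    for (j in seq_len(i - 1L)) {
      # bounding-box prefilter
      if (bb[i, 1L] > bb[j, 2L] + max_dist || bb[j, 1L] > bb[i, 2L] + max_dist ||
          bb[i, 3L] > bb[j, 4L] + max_dist || bb[j, 3L] > bb[i, 4L] + max_dist) next
      a <- rc[[i]]; b <- rc[[j]]
      d2 <- outer(a[, 1L], b[, 1L], "-")^2 + outer(a[, 2L], b[, 2L], "-")^2
      if (min(d2) <= max_dist^2) edges <- rbind(edges, c(ids[i], ids[j]))
    }
  }
  if (is.null(edges)) return(labels)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, n - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  # each merged group keeps its smallest member label
  grp_min <- tapply(seq_len(n), memb, min)
  out <- labels
  out[labels > 0L] <- as.integer(grp_min[memb[labels[labels > 0L]]])
  relabel_raster(out)
}

#' Apply largest-object priority across scales
#'
#' For each scale, any object whose pixel-overlap fraction with the union of
#' all larger-scale objects exceeds `config$overlap_policy` is removed
#' entirely (discarded as a sub-object). The largest scale is never changed.
#'
#' @param stack list of LabelMaps ordered small to large scale.
#' @param config [segmentation_config()].
#' @return list of filtered LabelMaps (same order).
#' @export
apply_scale_priority <- function(stack, config = segmentation_config()) {
  S <- length(stack)
  if (S == 0L) return(stack)
  shp <- dim(stack[[1L]])
  for (s in seq_len(S)) {
    if (!identical(dim(stack[[s]]), shp)) stopf("stack maps differ in shape")
  }
  if (S == 1L) return(stack)
  out <- stack
  larger_union <- matrix(FALSE, shp[1L], shp[2L])
  for (s in rev(seq_len(S))) {
    if (s < S) {
      lab <- out[[s]]
      if (max(lab) > 0L) {
        areas <- tabulate(lab[lab > 0L], nbins = max(lab))
        ov <- tabulate(lab[lab > 0L & larger_union], nbins = max(lab))
        drop <- which(ov / areas > config$overlap_policy)
        lab[lab %in% drop] <- 0L
        out[[s]] <- relabel_raster(lab)
      }
    }
    larger_union <- larger_union | (out[[s]] > 0L)
  }
  out
}

# Erode a binary mask r times with the 3x3 box (Chebyshev radius r), treating
# off-image pixels as background.
erode_box <- function(mask, r) {
  if (r <= 0L) return(mask != 0)
  m <- pad_matrix(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), r)
  e <- EBImage::erode(m, EBImage::makeBrush(2L * r + 1L, "box"))
  unpad_matrix(matrix(as.logical(e > 0.5), nrow(m), ncol(m)), r,
               nrow(mask), ncol(mask))
}

dilate_box <- function(mask, r) {
  if (r <= 0L) return(mask != 0)
  m <- pad_matrix(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), r)
  d <- EBImage::dilate(m, EBImage::makeBrush(2L * r + 1L, "box"))
  unpad_matrix(matrix(as.logical(d > 0.5), nrow(m), ncol(m)), r,
               nrow(mask), ncol(mask))
}

# Euclidean distance of each foreground pixel to the nearest background
# pixel (EBImage exact distance map), padded so the image border does not
# count as background.
interior_distance <- function(mask) {
  m <- pad_matrix(matrix(as.numeric(mask != 0), nrow(mask), ncol(mask)), 1L)
  d <- EBImage::distmap(m, metric = "euclidean")
  unpad_matrix(matrix(as.numeric(d), nrow(m), ncol(m)), 1L, nrow(mask), ncol(mask))
}

#' Fuse a scale-priority-filtered stack into one label map
#'
#' Each object is eroded by `contraction_radius` (3x3 structuring element,
#' independently per object; an object that would vanish is replaced by its
#' ultimate-eroded pixel set, the maxima of its distance transform). The
#' eroded binaries are unioned, connected components of the union are
#' relabeled, and each label is expanded back into pixels of the pre-erosion
#' union only, by successive one-pixel dilations until the union is fully
#' reassigned (nominally `contraction_radius` steps; narrow protrusions such
#' as digital-disk tips, which erosion removes to a depth greater than the
#' radius, are recovered by the extra steps so that the round trip is
#' conservative). Contested pixels go to the nearest label in dilation steps,
#' ties to the smaller label. For well-separated objects the round trip
#' reproduces the input pixel sets exactly; overlapping per-scale
#' segmentations of the same cell merge, while distinct objects touching
#' along a boundary stay separate because their eroded cores stay apart.
#'
#' @param stack list of LabelMaps (small to large), already priority-filtered.
#' @param config [segmentation_config()].
#' @return final LabelMap with contiguous labels.
#' @export
contract_merge_relabel_expand <- function(stack, config = segmentation_config()) {
  if (length(stack) == 0L) stopf("empty stack")
  nr <- nrow(stack[[1L]]); nc <- ncol(stack[[1L]])
  r <- config$contraction_radius
  pre_union <- matrix(FALSE, nr, nc)
  eroded_union <- matrix(FALSE, nr, nc)
  eroded_sets <- list()  # eroded pixel indices per input object
  for (lab in stack) {
    for (px in label_pixel_sets(lab)) {
      mask <- matrix(FALSE, nr, nc)
      mask[px] <- TRUE
      pre_union <- pre_union | mask
      er <- erode_box(mask, r)
      if (!any(er)) {
        # ultimate erosion: pixels at the maximal interior distance
        dm <- interior_distance(mask)
        er <- mask & (abs(dm - max(dm[mask])) < 1e-9)
      }
      eroded_union <- eroded_union | er
      eroded_sets[[length(eroded_sets) + 1L]] <- which(er)
    }
  }
  merged <- label_components(eroded_union, config$connectivity)
  if (max(merged) == 0L) return(merged)
  # resegmentation must not split a single input object whose erosion
  # disconnected (e.g. the thin neck of a touching-cell clump): merged
  # components sharing an input object are reunified, while components
  # that also share pixels with another scale's object fuse with it.
  g <- igraph::make_empty_graph(n = max(merged), directed = FALSE)
  for (px in eroded_sets) {
    labs <- unique(merged[px])
    labs <- labs[labs > 0L]
    if (length(labs) > 1L) {
      g <- igraph::add_edges(g, as.vector(rbind(labs[-length(labs)], labs[-1L])))
    }
  }
  grp <- igraph::components(g)$membership
  grp_min <- tapply(seq_len(max(merged)), grp, min)
  merged[merged > 0L] <- as.integer(grp_min[grp[merged[merged > 0L]]])
  merged <- relabel_raster(merged)
  n <- max(merged)
  # expand each label back into the pre-erosion union; geodesic growth,
  # nearest core (in dilation steps) wins, ties to the smaller label
  assigned <- merged
  todo <- pre_union & assigned == 0L
  if (any(todo)) {
    reach <- lapply(seq_len(n), function(k) merged == k)
    max_steps <- nr + nc
    for (step in seq_len(max_steps)) {
      claims <- matrix(0L, nr, nc)
      for (k in seq_len(n)) {
        reach[[k]] <- dilate_box(reach[[k]], 1L) & (pre_union | merged == k)
        new_px <- reach[[k]] & assigned == 0L & claims == 0L
        claims[new_px] <- k
      }
      grew <- claims > 0L
      if (!any(grew)) break
      assigned[grew] <- claims[grew]
      if (!any(pre_union & assigned == 0L)) break
    }
  }
  out <- relabel_raster(assigned)
  if (config$enforce_final_d_range) {
    areas <- tabulate(out[out > 0L], nbins = max(out))
    eqd <- equivalent_diameter(areas)
    drop <- which(eqd < config$final_d_range[1L] | eqd > config$final_d_range[2L])
    out[out %in% drop] <- 0L
    out <- relabel_raster(out)
  }
  out
}

#' Segment one frame
#'
#' Full pipeline: normalize and invert, then per scale threshold, identify
#' and unify objects; apply largest-object priority across scales; fuse with
#' [contract_merge_relabel_expand()]. Deterministic for fixed input and
#' configuration (no randomness anywhere in segmentation).
#'
#' @param image raw gray frame (matrix, any supported bit depth).
#' @param config [segmentation_config()].
#' @param bit_depth optional bit-depth override for normalization.
#' @return final LabelMap.
#' @export
segment_frame <- function(image, config = segmentation_config(), bit_depth = NULL) {
  inv <- normalize_and_invert(image, bit_depth = bit_depth)
  stack <- lapply(config$scales, function(sc) {
    mask <- foreground_mask(inv, sc$theta)
    lab <- identify_scale_objects(mask, sc, config)
    unify_by_distance(lab, config$unify_distance)
  })
  stack <- apply_scale_priority(stack, config)
  contract_merge_relabel_expand(stack, config)
}
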