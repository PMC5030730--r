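# Label-map primitives: connected-component labeling, relabeling conventions,
# boundary extraction. A LabelMap is an integer matrix, 0 = background,
# object labels contiguous 1..N; each label's pixel set is connected under the
# configured connectivity.

#' Label connected components of a binary mask
#'
#' Labels foreground components of a logical/0-1 matrix under 4- or
#' 8-connectivity. Labels are renumbered `1..N` in raster-scan (row-major)
#' order of each component's first pixel, so the result is a pure function of
#' the mask.
#'
#' @param mask logical or 0/1 matrix.
#' @param connectivity 4 or 8 (default 8): whether diagonally adjacent
#'   foreground pixels belong to the same object.
#' @return integer LabelMap matrix of the same shape.
#' @export
label_components <- function(mask, connectivity = 8L) {
  if (!is.matrix(mask)) stopf("mask must be a matrix")
  if (!connectivity %in% c(4L, 8L)) stopf("connectivity must be 4 or 8")
  m <- matrix(as.integer(mask != 0), nrow(mask), ncol(mask))
  if (!any(m > 0L)) return(matrix(0L, nrow(m), ncol(m)))
  lab4 <- matrix(as.integer(EBImage::bwlabel(m)), nrow(m), ncol(m))
  if (connectivity == 8L) {
    lab4 <- merge_diagonal_labels(lab4)
  }
  relabel_raster(lab4)
}

# Merge 4-connected components that touch diagonally (yielding 8-connectivity)
# by building the (small) graph of diagonally adjacent label pairs.
merge_diagonal_labels <- function(lab) {
  nr <- nrow(lab); nc <- ncol(lab)
  if (nr < 2L || nc < 2L) return(lab)
  a1 <- lab[-nr, -nc]; b1 <- lab[-1L, -1L]   # down-right
  a2 <- lab[-nr, -1L]; b2 <- lab[-1L, -nc]   # down-left
  keep1 <- a1 > 0L & b1 > 0L & a1 != b1
  keep2 <- a2 > 0L & b2 > 0L & a2 != b2
  edges <- rbind(cbind(a1[keep1], b1[keep1]), cbind(a2[keep2], b2[keep2]))
  if (nrow(edges) == 0L) return(lab)
  nlab <- max(lab)
  g <- igraph::graph_from_edgelist(edges, directed = FALSE)
  g <- igraph::add_vertices(g, max(0L, nlab - igraph::vcount(g)))
  memb <- igraph::components(g)$membership
  out <- lab
  out[lab > 0L] <- as.integer(memb[lab[lab > 0L]])
  out
}

# Renumber labels 1..N in raster-scan (row-major) order of first pixel.
relabel_raster <- function(lab) {
  labs <- lab[lab > 0L]
  if (length(labs) == 0L) return(matrix(0L, nrow(lab), ncol(lab)))
  idx <- which(lab > 0L)
  nr <- nrow(lab)
  r <- (idx - 1L) %% nr + 1L
  cc <- (idx - 1L) %/% nr + 1L
  key <- (r - 1) * ncol(lab) + cc  # row-major scan position
  first <- tapply(key, labs, min)
  ord <- order(first)
  remap <- integer(max(lab))
  remap[as.integer(names(first))[ord]] <- seq_along(ord)
  out <- lab
  out[idx] <- remap[labs]
  out
}

# List of pixel index vectors per label (names = label).
label_pixel_sets <- function(lab) {
  idx <- which(lab > 0L)
  if (length(idx) == 0L) return(list())
  split(idx, lab[idx])
}

# (row, col) coordinates for matrix indices.
idx_to_rc <- function(idx, nr) {
  cbind(row = (idx - 1L) %% nr + 1L, col = (idx - 1L) %/% nr + 1L)
}

# Boundary pixels of a binary mask: foreground pixels with at least one
# 8-neighbour (or off-image neighbour) that is background.
mask_boundary <- function(mask) {
  m <- pad_matrix(matrix(as.integer(mask != 0), nrow(mask), ncol(mask)), 1L)
  nr <- nrow(m); nc <- ncol(m)
  nb <- matrix(0L, nr, nc)
  for (dr in -1:1) for (dc in -1:1) {
    if (dr == 0L && dc == 0L) next
    sh <- matrix(0L, nr, nc)
    rs <- (1L + max(0L, dr)):(nr + min(0L, dr))
    cs <- (1L + max(0L, dc)):(nc + min(0L, dc))
    sh[rs - dr, cs - dc] <- m[rs, cs]
    nb <- nb + sh
  }
  core <- unpad_matrix(m == 1L & nb == 8L, 1L, nrow(mask), ncol(mask))
  (mask != 0) & !core
}

# Per-object boundary pixels: pixels of label k with at least one
# 8-neighbour (or off-image neighbour) outside k — other objects count as
# outside, unlike the union boundary of mask_boundary().
object_boundaries <- function(labels) {
  sets <- label_pixel_sets(labels)
  nr <- nrow(labels)
  lapply(sets, function(px) {
    rc <- idx_to_rc(px, nr)
    r1 <- min(rc[, 1L]); c1 <- min(rc[, 2L])
    crop <- matrix(FALSE, max(rc[, 1L]) - r1 + 1L, max(rc[, 2L]) - c1 + 1L)
    crop[cbind(rc[, 1L] - r1 + 1L, rc[, 2L] - c1 + 1L)] <- TRUE
    b <- mask_boundary(crop)
    keep <- b[cbind(rc[, 1L] - r1 + 1L, rc[, 2L] - c1 + 1L)]
    px[keep]
  })
}

# Labels touching the image border.
border_labels <- function(lab) {
  unique(c(lab[1L, ], lab[nrow(lab), ], lab[, 1L], lab[, ncol(lab)])) |>
    setdiff(0L)
}

# Equivalent diameter of a pixel count: diameter of the circle with the same
# area, 2*sqrt(area/pi).
equivalent_diameter <- function(area) 2 * sqrt(area / pi)
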