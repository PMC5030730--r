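# Time-dimensionality reduction of per-object features: per-group population
# heatmaps over time, per-hour central statistics with outlier exclusion,
# linear-regression trend reduction, gradient signature vectors and
# correlation matrices between them.

#' Dynamic histogram bin specification for one feature in one group
#'
#' Bin edges are equally spaced over the global `[min, max]` of the feature
#' within the aggregation group (all hours pooled), so every value of the
#' group falls inside the edges. The last bin is right-closed. When
#' `min == max` the spec degenerates to a single bin containing that value.
#'
#' @param values all finite feature values of the group across hours.
#' @param n_bins number of bins (default 50).
#' @return list with `edges`, `n_bins`, `bin_size`, `degenerate`.
#' @export
compute_bin_spec <- function(values, n_bins = 50L) {
  v <- values[is.finite(values)]
  if (length(v) == 0L) stopf("no finite values to bin")
  lo <- min(v); hi <- max(v)
  if (lo == hi) {
    return(list(edges = c(lo, hi), n_bins = 1L, bin_size = 0,
                degenerate = TRUE))
  }
  edges <- seq(lo, hi, length.out = n_bins + 1L)
  list(edges = edges, n_bins = as.integer(n_bins),
       bin_size = (hi - lo) / n_bins, degenerate = FALSE)
}

bin_index <- function(x, spec) {
  if (spec$degenerate) return(rep(1L, length(x)))
  findInterval(x, spec$edges, rightmost.closed = TRUE, all.inside = TRUE)
}

#' Population heatmap of one feature over time
#'
#' Row `h` is the histogram of the feature over all objects of the group at
#' hour `h`, normalized to unit sum, so hours with different cell counts are
#' comparable (each row a probability distribution). Rows for hours without
#' objects are all zero and flagged in `populated`. A `max` normalization
#' (divide each row by its maximum) is available as an alternative.
#'
#' @param objects ObjectTable rows of one group (already filtered/annotated).
#' @param feature feature column name (e.g. `"Shape_Area"`).
#' @param spec bin spec from [compute_bin_spec()]; default computed from the
#'   given rows.
#' @param hours hours forming the rows (default the full integer range
#'   present in `objects`).
#' @param normalize `"row"` (unit sum, default) or `"max"`.
#' @param group_id label stored with the heatmap.
#' @return object of class `population_heatmap`: list with `matrix`
#'   (`n_hours x n_bins`), `hours`, `populated`, `spec`, `feature`,
#'   `group_id`.
#' @export
population_heatmap <- function(objects, feature, spec = NULL, hours = NULL,
                               normalize = c("row", "max"), group_id = NA_character_) {
  normalize <- match.arg(normalize)
  if (!feature %in% names(objects)) stopf("unknown feature column: %s", feature)
  vals <- objects[[feature]]
  keep <- is.finite(vals)
  vals <- vals[keep]
  hrs <- objects$hour[keep]
  if (is.null(spec)) spec <- compute_bin_spec(vals)
  if (is.null(hours)) {
    if (length(hrs) == 0L) stopf("no finite values for feature %s", feature)
    hours <- seq(min(hrs), max(hrs))
  }
  m <- matrix(0, length(hours), spec$n_bins,
              dimnames = list(hour = hours, bin = seq_len(spec$n_bins)))
  populated <- logical(length(hours))
  for (i in seq_along(hours)) {
    x <- vals[hrs == hours[i]]
    if (length(x) == 0L) next
    populated[i] <- TRUE
    counts <- tabulate(bin_index(x, spec), nbins = spec$n_bins)
    m[i, ] <- if (normalize == "row") counts / length(x)
              else counts / max(counts)
  }
  structure(list(matrix = m, hours = hours, populated = populated, spec = spec,
                 feature = feature, group_id = group_id),
            class = "population_heatmap")
}

#' @export
print.population_heatmap <- function(x, ...) {
  cat(sprintf("population_heatmap: %s [%s], %d hours x %d bins (%d populated)\n",
              x$feature, x$group_id, nrow(x$matrix), ncol(x$matrix),
              sum(x$populated)))
  invisible(x)
}

#' Per-hour central statistic with outlier exclusion
#'
#' In a single non-iterative pass, values farther than `sd_k` population
#' standard deviations from the hour's mean are excluded; quartiles Q1 and Q3
#' (linear interpolation) of the remainder are computed; the default
#' statistic is the interquartile mean — the mean of remaining values lying
#' within `[Q1, Q3]`. `"iqr_width"` (Q3 - Q1) and `"midhinge"`
#' (`(Q1 + Q3) / 2`) are available as alternatives.
#'
#' @param values feature values at one hour (`NA`s dropped).
#' @param sd_k outlier exclusion threshold in population SDs (default 3).
#' @param mode `"iq_mean"` (default), `"iqr_width"`, or `"midhinge"`.
#' @return the statistic (scalar), `NA` if no finite values.
#' @export
hourly_statistic <- function(values, sd_k = 3,
                             mode = c("iq_mean", "iqr_width", "midhinge")) {
  mode <- match.arg(mode)
  x <- values[is.finite(values)]
  if (length(x) == 0L) return(NA_real_)
  mu <- mean(x); s <- pop_sd(x)
  kept <- x[abs(x - mu) <= sd_k * s]
  if (length(kept) == 0L) stopf("outlier exclusion removed all values")  # unreachable for sd_k > 0
  q1 <- quart(kept, 0.25); q3 <- quart(kept, 0.75)
  switch(mode,
         iq_mean = mean(kept[kept >= q1 & kept <= q3]),
         iqr_width = q3 - q1,
         midhinge = (q1 + q3) / 2)
}

#' Ordinary-least-squares linear trend over hours
#'
#' Closed-form OLS of the per-hour statistic on the integer hour index.
#' Missing hours are simply absent from the fit.
#'
#' @param hours integer hours (strictly increasing).
#' @param values per-hour statistics, same length.
#' @param min_fit_points minimum points required (default 3).
#' @return object of class `trend_fit`: list with `gradient` (feature units
#'   per hour), `intercept`, `n_hours_used`, `residual_se`.
#' @export
fit_trend <- function(hours, values, min_fit_points = 3L) {
  ok <- is.finite(hours) & is.finite(values)
  h <- as.numeric(hours[ok]); y <- values[ok]
  if (is.unsorted(h, strictly = TRUE)) stopf("hours must be strictly increasing")
  n <- length(h)
  if (n < min_fit_points) {
    stopf("insufficient data for trend fit: %d points (need %d)", n, min_fit_points)
  }
  sxx <- sum((h - mean(h))^2)
  if (sxx == 0) stopf("degenerate trend fit: all hours identical")
  slope <- sum((h - mean(h)) * (y - mean(y))) / sxx
  intercept <- mean(y) - slope * mean(h)
  res <- y - intercept - slope * h
  rse <- if (n > 2L) sqrt(sum(res^2) / (n - 2L)) else NA_real_
  structure(list(gradient = slope, intercept = intercept, n_hours_used = n,
                 residual_se = rse,
                 gradient_se = if (is.na(rse)) NA_real_ else rse / sqrt(sxx)),
            class = "trend_fit")
}

#' @export
print.trend_fit <- function(x, ...) {
  cat(sprintf("trend_fit: gradient %.6g / h, intercept %.6g (n = %d)\n",
              x$gradient, x$intercept, x$n_hours_used))
  invisible(x)
}

group_columns <- function(group_level) {
  switch(group_level,
         well = c("plate_id", "well_id"),
         condition = c("cell_line", "condition"),
         stopf("group_level must be 'well' or 'condition'"))
}

#' Reduce an object table to per-group per-feature linear trends
#'
#' For every group (well, or `(cell_line, condition)` pooling replicate
#' wells) and every registry feature, the per-hour statistic
#' ([hourly_statistic()]) is regressed on the hour index
#' ([fit_trend()]); the gradient and intercept are emitted to the summary
#' table. Groups with fewer usable hours than `min_fit_points` keep their
#' row with missing gradient/intercept.
#'
#' @param objects annotated ObjectTable.
#' @param registry feature registry (default [feature_registry()]).
#' @param group_level `"well"` or `"condition"`.
#' @param sd_k,mode passed to [hourly_statistic()].
#' @param min_fit_points minimum hours for a fit (default 3).
#' @return SummaryTable data.frame: `group_id`, `cell_line`, `condition`,
#'   `feature_name`, `gradient`, `intercept`, `n_hours_used`, `residual_se`.
#' @export
build_summary <- function(objects, registry = feature_registry(),
                          group_level = c("well", "condition"), sd_k = 3,
                          mode = "iq_mean", min_fit_points = 3L) {
  group_level <- match.arg(group_level)
  gcols <- group_columns(group_level)
  empty <- data.frame(group_id = character(0), cell_line = character(0),
                      condition = character(0), feature_name = character(0),
                      gradient = numeric(0), intercept = numeric(0),
                      n_hours_used = integer(0), residual_se = numeric(0),
                      stringsAsFactors = FALSE)
  if (nrow(objects) == 0L) return(empty)
  miss <- setdiff(gcols, names(objects))
  if (length(miss)) stopf("objects lack grouping column(s): %s",
                          paste(miss, collapse = ", "))
  key <- do.call(paste, c(objects[gcols], sep = "|"))
  rows <- list()
  for (g in sort(unique(key))) {
    sub <- objects[key == g, , drop = FALSE]
    cl <- if ("cell_line" %in% names(sub)) sub$cell_line[1L] else NA_character_
    cond <- if ("condition" %in% names(sub)) sub$condition[1L] else NA_character_
    for (f in registry$column) {
      if (!f %in% names(sub)) stopf("feature column missing from objects: %s", f)
      hrs <- sort(unique(sub$hour))
      stat <- vapply(hrs, function(h) {
        hourly_statistic(sub[[f]][sub$hour == h], sd_k = sd_k, mode = mode)
      }, 0)
      ok <- is.finite(stat)
      fit <- tryCatch(fit_trend(hrs[ok], stat[ok], min_fit_points),
                      error = function(e) NULL)
      rows[[length(rows) + 1L]] <- data.frame(
        group_id = g, cell_line = cl, condition = cond, feature_name = f,
        gradient = if (is.null(fit)) NA_real_ else fit$gradient,
        intercept = if (is.null(fit)) NA_real_ else fit$intercept,
        n_hours_used = if (is.null(fit)) sum(ok) else fit$n_hours_used,
        residual_se = if (is.null(fit)) NA_real_ else fit$residual_se,
        stringsAsFactors = FALSE)
    }
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Assemble gradient signature vectors from a condition-level summary
#'
#' One vector of per-feature gradients per `(cell_line, condition)`, ordered
#' by the feature registry. Missing gradients stay `NA` (never zero-filled).
#'
#' @param summary SummaryTable from [build_summary()] at condition level.
#' @param registry feature registry fixing the order.
#' @return object of class `signature_set`: list with `matrix` (features x
#'   vectors, rownames = feature columns) and `meta` (data.frame with
#'   `vector_id`, `cell_line`, `condition`).
#' @export
signature_vectors <- function(summary, registry = feature_registry()) {
  ids <- sort(unique(summary$group_id))
  m <- matrix(NA_real_, nrow(registry), length(ids),
              dimnames = list(registry$column, ids))
  meta <- data.frame(vector_id = ids, cell_line = NA_character_,
                     condition = NA_character_, stringsAsFactors = FALSE)
  for (j in seq_along(ids)) {
    sub <- summary[summary$group_id == ids[j], , drop = FALSE]
    hit <- match(registry$column, sub$feature_name)
    m[, j] <- sub$gradient[hit]
    meta$cell_line[j] <- sub$cell_line[1L]
    meta$condition[j] <- sub$condition[1L]
  }
  structure(list(matrix = m, meta = meta), class = "signature_set")
}

#' @export
print.signature_set <- function(x, ...) {
  cat(sprintf("signature_set: %d features x %d vectors\n",
              nrow(x$matrix), ncol(x$matrix)))
  invisible(x)
}

#' Correlation matrix between signature vectors
#'
#' Pearson correlation between gradient signature vectors, on
#' pairwise-complete features. Because gradients carry heterogeneous units,
#' a per-feature z-scored variant (standardize across vectors before
#' correlating) is offered.
#'
#' @param signatures `signature_set` from [signature_vectors()], or a
#'   numeric matrix (features x vectors).
#' @param condition optional condition label to subset vectors at one
#'   condition level.
#' @param standardize z-score each feature across vectors first (default
#'   `FALSE`).
#' @return symmetric correlation matrix with unit diagonal.
#' @export
correlation_matrix <- function(signatures, condition = NULL, standardize = FALSE) {
  if (inherits(signatures, "signature_set")) {
    m <- signatures$matrix
    if (!is.null(condition)) {
      keep <- signatures$meta$condition == condition
      if (sum(keep) < 2L) stopf("need at least 2 vectors at condition '%s'", condition)
      m <- m[, keep, drop = FALSE]
    }
  } else {
    m <- as.matrix(signatures)
  }
  if (ncol(m) < 2L) stopf("need at least 2 signature vectors")
  if (standardize) {
    mu <- rowMeans(m, na.rm = TRUE)
    s <- apply(m, 1L, sd, na.rm = TRUE)
    s[s == 0 | !is.finite(s)] <- NA_real_
    m <- (m - mu) / s
  }
  cm <- suppressWarnings(cor(m, use = "pairwise.complete.obs", method = "pearson"))
  diag(cm) <- 1
  cm
}
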