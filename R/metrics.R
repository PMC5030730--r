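# Segmentation evaluation against ground truth: greedy one-to-one IoU
# matching, the synthetic analogue of comparing object counts to a manual
# gold standard.

#' Segmentation metrics against a ground-truth label map
#'
#' Predicted and true objects are matched one-to-one greedily by descending
#' pairwise intersection-over-union (ties broken by smaller predicted, then
#' smaller true label, so the matching is deterministic); matches with
#' IoU >= `iou_threshold` are true positives.
#'
#' @param pred predicted LabelMap.
#' @param truth ground-truth LabelMap, same shape.
#' @param iou_threshold IoU required for a true positive (default 0.5).
#' @return list: `precision` (1 when there are no predictions), `recall`
#'   (1 when there are no truth objects), `count_error` (predicted minus
#'   true object count), `n_pred`, `n_truth`, `n_matched`.
#' @export
segmentation_metrics <- function(pred, truth, iou_threshold = 0.5) {
  if (!identical(dim(pred), dim(truth))) stopf("pred/truth shape mismatch")
  n_pred <- max(pred); n_truth <- max(truth)
  if (n_pred == 0L || n_truth == 0L) {
    return(list(precision = if (n_pred == 0L) 1 else 0,
                recall = if (n_truth == 0L) 1 else 0,
                count_error = n_pred - n_truth,
                n_pred = n_pred, n_truth = n_truth, n_matched = 0L))
  }
  both <- pred > 0L & truth > 0L
  inter <- table(factor(pred[both], levels = seq_len(n_pred)),
                 factor(truth[both], levels = seq_len(n_truth)))
  area_p <- tabulate(pred[pred > 0L], nbins = n_pred)
  area_t <- tabulate(truth[truth > 0L], nbins = n_truth)
  pairs <- which(inter > 0, arr.ind = TRUE)
  if (nrow(pairs) == 0L) {
    return(list(precision = 0, recall = 0, count_error = n_pred - n_truth,
                n_pred = n_pred, n_truth = n_truth, n_matched = 0L))
  }
  ious <- vapply(seq_len(nrow(pairs)), function(r) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    inter[i, j] / (area_p[i] + area_t[j] - inter[i, j])
  }, 0)
  ord <- order(-ious, pairs[, 1L], pairs[, 2L])
  used_p <- logical(n_pred); used_t <- logical(n_truth)
  matched <- 0L
  for (r in ord) {
    i <- pairs[r, 1L]; j <- pairs[r, 2L]
    if (used_p[i] || used_t[j]) next
    if (ious[r] < iou_threshold) break
    used_p[i] <- TRUE; used_t[j] <- TRUE
    matched <- matched + 1L
  }
  list(precision = matched / n_pred, recall = matched / n_truth,
       count_error = n_pred - n_truth, n_pred = n_pred, n_truth = n_truth,
       n_matched = matched)
}
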