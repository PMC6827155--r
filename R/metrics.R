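# VOC2007-style detection evaluation: IoU, greedy score-descending
# one-to-one matching, pooled precision/recall/F1, and 11-point
# interpolated average precision.

#' Intersection over union of two boxes
#'
#' Areas under the 0-based half-open convention. Degenerate (zero-area)
#' boxes yield 0 with a warning.
#'
#' @param a,b boxes `c(x0, y0, x1, y1)`.
#' @return IoU in `[0, 1]`.
#' @export
iou <- function(a, b) {
  if (box_area(a) <= 0 || box_area(b) <= 0) {
    warning("zero-area box in IoU; returning 0")
    return(0)
  }
  iw <- min(a[3], b[3]) - max(a[1], b[1])
  ih <- min(a[4], b[4]) - max(a[2], b[2])
  if (iw <= 0 || ih <= 0) return(0)
  inter <- iw * ih
  inter / (box_area(a) + box_area(b) - inter)
}

#' Greedy matching of detections to ground truths
#'
#' Detections are visited in descending score (ties by input order); each
#' claims its best-IoU unmatched ground truth (IoU ties by lowest ground
#' truth index) and is a true positive iff that IoU reaches the threshold.
#' Each ground truth is matched at most once; leftover ground truths are
#' false negatives.
#'
#' @param dets data.frame/matrix with columns `x0, y0, x1, y1, score`.
#' @param gts matrix of ground-truth boxes.
#' @param iou_threshold matching threshold (default 0.5).
#' @return list with `tp`, `fp`, `fn`, `matched_pairs` (data.frame det, gt,
#'   iou), and `det_is_tp` (logical per detection, input order).
#' @export
match_detections <- function(dets, gts, iou_threshold = 0.5) {
  gts <- boxes_as_matrix(gts)
  dets <- as.data.frame(dets)
  n_det <- nrow(dets); n_gt <- nrow(gts)
  det_is_tp <- logical(n_det)
  pairs <- NULL
  if (n_det > 0) {
    names(dets)[1:5] <- c("x0", "y0", "x1", "y1", "score")
    ord <- order(-dets$score)          # stable: ties keep input order
    gt_used <- logical(n_gt)
    for (i in ord) {
      if (n_gt == 0) break
      ious <- vapply(seq_len(n_gt), function(j)
        iou(as.numeric(dets[i, 1:4]), gts[j, ]), numeric(1))
      ious[gt_used] <- -1
      j <- which.max(ious)             # first index wins IoU ties
      if (ious[j] >= iou_threshold) {
        det_is_tp[i] <- TRUE
        gt_used[j] <- TRUE
        pairs <- rbind(pairs, data.frame(det = i, gt = j, iou = ious[j]))
      }
    }
  }
  tp <- sum(det_is_tp)
  list(tp = tp, fp = n_det - tp, fn = n_gt - tp,
       matched_pairs = if (is.null(pairs))
         data.frame(det = integer(0), gt = integer(0), iou = numeric(0))
       else pairs,
       det_is_tp = det_is_tp)
}

#' Precision
#' @param tp,fp counts.
#' @return `tp / (tp + fp)`, 0 when the denominator is 0.
#' @export
precision <- function(tp, fp) if (tp + fp == 0) 0 else tp / (tp + fp)

#' Recall (sensitivity)
#' @param tp,fn counts.
#' @return `tp / (tp + fn)`, 0 when the denominator is 0.
#' @export
recall <- function(tp, fn) if (tp + fn == 0) 0 else tp / (tp + fn)

#' F1 score
#'
#' Harmonic mean of precision and recall: `2 / (1/p + 1/r)`.
#'
#' @param p,r precision and recall in `[0, 1]`.
#' @return F1 in `[0, 1]`; 0 when both are 0.
#' @export
f1 <- function(p, r) if (p + r == 0) 0 else 2 * p * r / (p + r)

#' Precision-recall curve from a ranked detection list
#'
#' @param scores detection scores.
#' @param is_tp logical per detection.
#' @param n_gt total number of ground truths.
#' @return data.frame `(recall, precision)` ordered by descending score;
#'   recall is nondecreasing along the sweep.
#' @export
pr_curve <- function(scores, is_tp, n_gt) {
  if (length(scores) == 0)
    return(data.frame(recall = numeric(0), precision = numeric(0)))
  ord <- order(-scores)
  tp_cum <- cumsum(is_tp[ord])
  fp_cum <- cumsum(!is_tp[ord])
  data.frame(recall = if (n_gt > 0) tp_cum / n_gt else rep(0, length(scores)),
             precision = tp_cum / (tp_cum + fp_cum))
}

#' 11-point interpolated average precision
#'
#' Mean over recall levels 0.0, 0.1, ..., 1.0 of the maximum precision at
#' recall >= that level (0 when no point reaches it) — the VOC2007 rule.
#'
#' @param curve data.frame `(recall, precision)` from [pr_curve()].
#' @return AP in `[0, 1]`.
#' @export
ap_11point <- function(curve) {
  if (nrow(curve) == 0) return(0)
  mean(vapply(seq(0, 1, by = 0.1), function(r) {
    p <- curve$precision[curve$recall >= r - 1e-12]
    if (length(p) == 0) 0 else max(p)
  }, numeric(1)))
}

#' Evaluate detections against ground truth over an image set
#'
#' Matches per image (greedy, score-descending), then pools counts and
#' ranks all detections globally by score for the PR curve and AP —
#' the VOC convention (pooled, not per-image averaged).
#'
#' @param dets_by_image named list; per image a data.frame with columns
#'   `x0, y0, x1, y1, score`.
#' @param gts_by_image named list of ground-truth box matrices; names must
#'   cover every detection image id.
#' @param iou_threshold matching threshold.
#' @return list with `precision`, `recall`, `f1`, `ap`, `tp`, `fp`, `fn`,
#'   and the pooled `curve`.
#' @export
evaluate <- function(dets_by_image, gts_by_image, iou_threshold = 0.5) {
  stray <- setdiff(names(dets_by_image), names(gts_by_image))
  if (length(stray) > 0)
    stop_input("detections reference unknown image id(s): ",
               paste(stray, collapse = ", "))
  all_scores <- numeric(0); all_tp <- logical(0)
  tp <- fp <- fn <- 0L
  for (id in names(gts_by_image)) {
    gts <- boxes_as_matrix(gts_by_image[[id]])
    dets <- dets_by_image[[id]]
    if (is.null(dets)) dets <- data.frame(x0 = numeric(0), y0 = numeric(0),
                                          x1 = numeric(0), y1 = numeric(0),
                                          score = numeric(0))
    m <- match_detections(dets, gts, iou_threshold)
    tp <- tp + m$tp; fp <- fp + m$fp; fn <- fn + m$fn
    if (nrow(as.data.frame(dets)) > 0) {
      all_scores <- c(all_scores, as.data.frame(dets)[[5]])
      all_tp <- c(all_tp, m$det_is_tp)
    }
  }
  n_gt <- tp + fn
  curve <- pr_curve(all_scores, all_tp, n_gt)
  p <- precision(tp, fp); r <- recall(tp, fn)
  list(precision = p, recall = r, f1 = f1(p, r), ap = ap_11point(curve),
       tp = tp, fp = fp, fn = fn, curve = curve)
}
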