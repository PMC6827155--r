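# Composite training objective for the detector + attention neck.
#
#   Loss = L_detection + lambda * L_attention
#
# L_detection is the usual two-term proposal loss over training triples
# (B = anchor box, T = target box, R = target objectness): smooth-L1 on the
# (dx, dy, dw, dh) box offsets normalized by N_L, plus binary cross-entropy
# on objectness normalized by N_O. L_attention compares the predicted score
# map against a ground-truth map in which annotated boxes carry their
# confidence scores and all remaining cells a fixed background fill of
# 0.05; the comparison is the squared Frobenius norm (switchable to mean).

#' Loss configuration
#'
#' @param lambda weight of the attention term (>= 0).
#' @param attention_reduction `"sum"` (squared Frobenius norm) or `"mean"`.
#' @param score_map_stride stride at which score maps are built relative to
#'   the image grid (the neck output stride).
#' @param fill background fill value of the ground-truth score map.
#' @return a `loss_config` list.
#' @export
loss_config <- function(lambda = 1, attention_reduction = c("sum", "mean"),
                        score_map_stride = 4L, fill = 0.05) {
  if (lambda < 0) stop_input("lambda must be >= 0")
  structure(list(lambda = lambda,
                 attention_reduction = match.arg(attention_reduction),
                 score_map_stride = as.integer(score_map_stride),
                 fill = fill),
            class = "loss_config")
}

#' Build a ground-truth score map
#'
#' Cells inside each box are set to that box's confidence score; where
#' boxes overlap the maximum score wins; every remaining cell gets the
#' background `fill` (default 0.05).
#'
#' @param boxes 0-based half-open boxes on the map grid.
#' @param scores per-box confidence scores in `[0, 1]`.
#' @param shape `c(h, w)` of the map.
#' @param fill background value.
#' @return `h x w` numeric matrix.
#' @export
build_gt_score_map <- function(boxes, scores, shape, fill = 0.05) {
  boxes <- boxes_as_matrix(boxes)
  if (nrow(boxes) != length(scores))
    stop_input("need one score per box")
  if (length(scores) && (any(scores < 0) || any(scores > 1)))
    stop_input("scores must lie in [0, 1]")
  m <- matrix(fill, shape[1], shape[2])
  if (nrow(boxes) == 0) return(m)
  if (any(boxes[, 1] < 0 | boxes[, 2] < 0 |
          boxes[, 3] > shape[2] | boxes[, 4] > shape[1]))
    stop_input("box outside the score-map raster")
  for (i in order(scores)) {           # ascending: later (higher) wins = max
    rows <- (boxes[i, 2] + 1):boxes[i, 4]
    cols <- (boxes[i, 1] + 1):boxes[i, 3]
    m[rows, cols] <- pmax(m[rows, cols], scores[i])
  }
  m
}

#' Attention loss between predicted and ground-truth score maps
#'
#' @param X predicted score map (matrix).
#' @param D ground-truth score map of the same shape.
#' @param reduction `"sum"` or `"mean"` of squared differences.
#' @return nonnegative scalar; 0 iff `X == D`.
#' @export
attention_loss <- function(X, D, reduction = c("sum", "mean")) {
  if (!identical(dim(X), dim(D))) stop_input("score map shapes differ")
  reduction <- match.arg(reduction)
  sq <- (X - D)^2
  if (reduction == "sum") sum(sq) else mean(sq)
}

#' Smooth-L1 (Huber, delta = 1)
#'
#' @param x numeric vector of residuals.
#' @return elementwise `0.5 x^2` for `|x| < 1`, else `|x| - 0.5`.
#' @export
smooth_l1 <- function(x) ifelse(abs(x) < 1, 0.5 * x^2, abs(x) - 0.5)

# Faster-R-CNN-style box offsets of `box` relative to anchor `anchor`,
# both 0-based half-open.
encode_box <- function(box, anchor) {
  bw <- box[3] - box[1]; bh <- box[4] - box[2]
  aw <- anchor[3] - anchor[1]; ah <- anchor[4] - anchor[2]
  c((box[1] + bw / 2 - (anchor[1] + aw / 2)) / aw,
    (box[2] + bh / 2 - (anchor[2] + ah / 2)) / ah,
    log(bw / aw), log(bh / ah))
}

binary_cross_entropy <- function(p, r, eps = 1e-12) {
  p <- clamp(p, eps, 1 - eps)
  -(r * log(p) + (1 - r) * log(1 - p))
}

#' Detection loss over training triples
#'
#' `(1/N_L) sum smooth_l1(t_pred - t_target) + (1/N_O) sum BCE(p, R)` where
#' `t_pred`, `t_target` are the offset encodings of the predicted and
#' target boxes against each triple's anchor. Zero iff every predicted box
#' and score matches its target exactly (with R in {0, 1}).
#'
#' @param pred_boxes matrix of predicted boxes, one row per triple.
#' @param pred_scores predicted objectness probabilities in `[0, 1]`.
#' @param triples list of `list(B = anchor, T = target_box, R = target)`.
#' @param n_loc,n_obj normalizers; default the triple count.
#' @return nonnegative scalar.
#' @export
detection_loss <- function(pred_boxes, pred_scores, triples,
                           n_loc = length(triples),
                           n_obj = length(triples)) {
  if (length(triples) == 0)
    stop_input("no training triples: both loss terms undefined")
  pred_boxes <- boxes_as_matrix(pred_boxes)
  stopifnot(nrow(pred_boxes) == length(triples),
            length(pred_scores) == length(triples))
  loc <- obj <- 0
  for (k in seq_along(triples)) {
    tr <- triples[[k]]
    resid <- encode_box(pred_boxes[k, ], tr$B) - encode_box(tr$T, tr$B)
    loc <- loc + sum(smooth_l1(resid))
    obj <- obj + binary_cross_entropy(pred_scores[k], tr$R)
  }
  loc / n_loc + obj / n_obj
}

#' Combine detection and attention losses
#'
#' @param det detection loss.
#' @param attn attention loss.
#' @param lambda attention weight.
#' @return `det + lambda * attn`.
#' @export
total_loss <- function(det, attn, lambda = 1) {
  if (!is.finite(det) || !is.finite(attn)) stop_input("losses must be finite")
  det + lambda * attn
}
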