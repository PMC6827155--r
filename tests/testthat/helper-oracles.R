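# Independent brute-force oracles used across the suite. These deliberately
# re-derive quantities from first principles (loops, exhaustive search)
# rather than calling the package's vectorized implementations.

# Otsu: exhaustive scan of all 255 candidate thresholds, maximizing
# between-class variance of the {<= t} / {> t} split.
oracle_otsu <- function(gray) {
  v <- as.integer(round(gray))
  best_t <- -1L; best_var <- -Inf
  for (t in 0:254) {
    lo <- v[v <= t]; hi <- v[v > t]
    if (length(lo) == 0 || length(hi) == 0) next
    w0 <- length(lo) / length(v); w1 <- 1 - w0
    bv <- w0 * w1 * (mean(hi) - mean(lo))^2
    if (bv > best_var + 1e-12) { best_var <- bv; best_t <- t }
  }
  best_t
}

# Minimal L-infinity gap from a half-open box to any set pixel of mask,
# by direct scan (0 when a vessel pixel lies inside the box).
oracle_box_gap <- function(box, mask) {
  idx <- which(mask != 0)
  if (length(idx) == 0) return(Inf)
  h <- nrow(mask)
  best <- Inf
  for (ii in idx) {
    py <- (ii - 1) %% h
    px <- (ii - 1) %/% h
    gx <- max(box[1] - px, px - (box[3] - 1), 0)
    gy <- max(box[2] - py, py - (box[4] - 1), 0)
    best <- min(best, max(gx, gy))
  }
  best
}

# 11-point AP directly from scored detections + TP flags: for each recall
# level, scan every prefix of the ranking for the max precision achieving
# at least that recall.
oracle_ap11 <- function(scores, is_tp, n_gt) {
  ord <- order(-scores)
  tp <- cumsum(is_tp[ord]); fp <- cumsum(!is_tp[ord])
  rec <- if (n_gt > 0) tp / n_gt else rep(0, length(tp))
  prec <- tp / (tp + fp)
  total <- 0
  for (r in seq(0, 1, by = 0.1)) {
    best <- 0
    for (k in seq_along(rec))
      if (rec[k] >= r - 1e-12 && prec[k] > best) best <- prec[k]
    total <- total + best
  }
  total / 11
}

# Exhaustive optimal one-to-one assignment maximizing the TP count at a
# given IoU threshold (instances small enough to enumerate permutations).
oracle_optimal_tp <- function(dets, gts, thr) {
  nd <- nrow(dets); ng <- nrow(gts)
  if (nd == 0 || ng == 0) return(0L)
  iou_mat <- matrix(0, nd, ng)
  for (i in seq_len(nd)) for (j in seq_len(ng))
    iou_mat[i, j] <- maScreen::iou(as.numeric(dets[i, 1:4]), gts[j, ])
  feasible <- iou_mat >= thr
  best <- 0L
  assign_rec <- function(i, used, count) {
    if (count + (nd - i + 1) <= best) return()
    if (i > nd) { best <<- max(best, count); return() }
    assign_rec(i + 1, used, count)
    for (j in seq_len(ng)) if (!used[j] && feasible[i, j]) {
      used[j] <- TRUE
      assign_rec(i + 1, used, count + 1L)
      used[j] <- FALSE
    }
  }
  assign_rec(1L, logical(ng), 0L)
  best
}

# Straight-line scalar reference of the fusion neck: projection by explicit
# per-cell matrix multiply, nearest math for bilinear resize with half-pixel
# centres, fusion and channel attention written as loops.
oracle_fused_map <- function(pyramid, params) {
  proj <- function(map, W) {
    d <- dim(map$data)
    out <- array(0, c(d[1], d[2], nrow(W)))
    for (y in seq_len(d[1])) for (x in seq_len(d[2]))
      out[y, x, ] <- as.numeric(W %*% map$data[y, x, ])
    out
  }
  resize <- function(arr, th, tw) {
    d <- dim(arr)
    out <- array(0, c(th, tw, d[3]))
    for (y in seq_len(th)) for (x in seq_len(tw)) {
      sy <- min(max((y - 0.5) * d[1] / th - 0.5, 0), d[1] - 1)
      sx <- min(max((x - 0.5) * d[2] / tw - 0.5, 0), d[2] - 1)
      y0 <- floor(sy); x0 <- floor(sx)
      y1 <- min(y0 + 1, d[1] - 1); x1 <- min(x0 + 1, d[2] - 1)
      wy <- sy - y0; wx <- sx - x0
      out[y, x, ] <- (1 - wy) * (1 - wx) * arr[y0 + 1, x0 + 1, ] +
                     (1 - wy) * wx       * arr[y0 + 1, x1 + 1, ] +
                     wy       * (1 - wx) * arr[y1 + 1, x0 + 1, ] +
                     wy       * wx       * arr[y1 + 1, x1 + 1, ]
    }
    out
  }
  attn <- function(arr, ap) {
    d <- dim(arr)
    z <- numeric(d[3])
    for (k in seq_len(d[3])) z[k] <- mean(arr[, , k])
    u <- as.numeric(ap$W1 %*% z); u[u < 0] <- 0
    v <- as.numeric(ap$W2 %*% u)
    e <- exp(v - max(v)); s <- e / sum(e)
    for (k in seq_len(d[3])) arr[, , k] <- arr[, , k] * s[k]
    arr
  }
  run <- proj(pyramid$C5, params$projections$C5)
  for (l in 4:2) {
    key <- paste0("C", l)
    p <- proj(pyramid[[key]], params$projections[[key]])
    d <- dim(p)
    up <- resize(run, d[1], d[2])
    fp <- params$fusion[[key]]
    fused <- fp$alpha1 * p + fp$alpha2 * up
    run <- if (is.null(params$attention[[key]])) fused
           else attn(fused, params$attention[[key]])
  }
  run
}

# Small random pyramid with halving spatial dims, suitable for the neck.
random_pyramid <- function(h2 = 8, w2 = 8, channels = c(8, 8, 16, 16),
                           seed = 1) {
  set.seed(seed)
  out <- list()
  for (l in 2:5) {
    h <- max(1, h2 %/% 2^(l - 2)); w <- max(1, w2 %/% 2^(l - 2))
    out[[paste0("C", l)]] <-
      feature_map(array(rnorm(h * w * channels[l - 1]),
                        c(h, w, channels[l - 1])), l)
  }
  out
}

small_scene <- function(seed, ...) {
  render_scene(scene_spec(width = 128, height = 128, n_mas = 5,
                          vessel_density = 4, seed = seed, ...))
}
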