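# Attention-based multilayer feature fusion neck.
#
# Small lesions live in the shallow, high-resolution feature levels of a
# backbone, so the neck consumes levels C2..C5 (strides 4/8/16/32), projects
# each to a common channel width with a 1x1 linear map, and fuses top-down:
# the coarser map is upsampled bilinearly and combined with the current
# level by a learnable weighted sum
#
#     F_i = alpha1 * f_i + alpha2 * up(f_{i+1}),   alpha init 1,
#
# followed by channel-wise attention: global average pooling gives a
# channel statistic z, a two-layer bottleneck (c -> c/8 -> c, ReLU between)
# produces logits, softmax over channels gives weights s (sum 1), and each
# channel of F_i is scaled by its weight. The finest fused map (level 2,
# stride 4) is the neck output handed to a detector backend.
#
# Feature maps are plain arrays dim c(h, w, c); everything is deterministic
# given parameters, and analytic gradients are provided for the learnable
# scalars and bottleneck matrices.

#' Construct a feature map
#'
#' @param data numeric array dim `c(h, w, c)`.
#' @param level pyramid level in 2..5; the map's stride is `2^level`.
#' @return a `feature_map` list with `data`, `level`, `stride`.
#' @export
feature_map <- function(data, level) {
  if (length(dim(data)) != 3L) stop_input("feature map data must be h x w x c")
  level <- as.integer(level)
  if (level < 2L || level > 5L) stop_input("level must be in 2..5")
  structure(list(data = data, level = level, stride = as.integer(2^level)),
            class = "feature_map")
}

#' Select pyramid levels C2..C5 from backbone outputs
#'
#' @param backbone_outputs named list with elements `"C2"`..`"C5"` (extra
#'   levels are ignored), each a `feature_map` or raw array.
#' @return list of `feature_map`s named C2..C5.
#' @export
select_layers <- function(backbone_outputs) {
  need <- paste0("C", 2:5)
  miss <- setdiff(need, names(backbone_outputs))
  if (length(miss) > 0)
    stop_input("backbone is missing pyramid level(s): ",
               paste(miss, collapse = ", "))
  out <- lapply(2:5, function(l) {
    m <- backbone_outputs[[paste0("C", l)]]
    if (inherits(m, "feature_map")) m else feature_map(m, l)
  })
  names(out) <- need
  out
}

#' Tiny deterministic demo backbone
#'
#' Stands in for a convolutional backbone in tests and demos: each level is
#' the input image average-pooled to stride `2^level`, expanded to
#' `channels[level-1]` channels through a seeded random affine map with a
#' tanh nonlinearity. Not a trained network; it only supplies shaped,
#' input-dependent pyramids.
#'
#' @param image grayscale matrix, 0-255.
#' @param channels channel counts for C2..C5 (each divisible by 8).
#' @param seed integer seed for the channel maps.
#' @return named list C2..C5 of `feature_map`s.
#' @export
demo_backbone <- function(image, channels = c(16, 32, 64, 128), seed = 1L) {
  pool2 <- function(m) {
    h <- 2L * (nrow(m) %/% 2L); w <- 2L * (ncol(m) %/% 2L)
    m <- m[seq_len(h), seq_len(w), drop = FALSE]
    0.25 * (m[seq(1, h, 2), seq(1, w, 2), drop = FALSE] +
            m[seq(2, h, 2), seq(1, w, 2), drop = FALSE] +
            m[seq(1, h, 2), seq(2, w, 2), drop = FALSE] +
            m[seq(2, h, 2), seq(2, w, 2), drop = FALSE])
  }
  x <- image / 255
  with_seed(seed, {
    out <- list()
    for (l in 2:5) {
      for (k in seq_len(if (l == 2) 2 else 1)) x <- pool2(x)
      c_l <- channels[l - 1]
      wts <- stats::rnorm(c_l, 0, 1); bias <- stats::rnorm(c_l, 0, 0.1)
      arr <- array(0, c(nrow(x), ncol(x), c_l))
      for (k in seq_len(c_l)) arr[, , k] <- tanh(wts[k] * x + bias[k])
      out[[paste0("C", l)]] <- feature_map(arr, l)
    }
    out
  })
}

#' 1x1 channel projection
#'
#' Linear map applied independently at every spatial cell, taking the map
#' to `out_c` channels (the common fusion width).
#'
#' @param map a `feature_map`.
#' @param out_c output channel count.
#' @param weights `out_c x c` matrix; identity-like default (`NULL`) draws a
#'   seeded Xavier-scaled random matrix.
#' @param seed seed used when `weights` is `NULL`.
#' @return projected `feature_map` with the same spatial size and level.
#' @export
project_channels <- function(map, out_c = 256, weights = NULL, seed = 1L) {
  d <- dim(map$data)
  if (is.null(weights))
    weights <- with_seed(seed,
      matrix(stats::rnorm(out_c * d[3], 0, 1 / sqrt(d[3])), out_c, d[3]))
  if (!all(dim(weights) == c(out_c, d[3])))
    stop_input("projection weights must be out_c x c")
  flat <- matrix(map$data, d[1] * d[2], d[3])
  feature_map(array(flat %*% t(weights), c(d[1], d[2], out_c)), map$level)
}

# Per-axis bilinear sampling indices/weights, half-pixel-centre convention
# (align_corners = FALSE): source coordinate of target cell t is
# (t + 0.5) * src/dst - 0.5, clamped to the valid range.
bilinear_axis <- function(src_n, dst_n) {
  pos <- clamp(((seq_len(dst_n) - 0.5) * src_n / dst_n) - 0.5, 0, src_n - 1)
  lo <- pmin(floor(pos), src_n - 1)
  hi <- pmin(lo + 1, src_n - 1)
  list(lo = lo + 1, hi = hi + 1, w = pos - lo)
}

#' Bilinear upsampling of a feature map
#'
#' Deterministic bilinear interpolation (half-pixel centres) to an exact
#' target spatial shape; channel count unchanged.
#'
#' @param map a `feature_map`.
#' @param target_hw `c(h, w)` target spatial size (>= source).
#' @param level level to assign to the result (defaults to `map$level - 1`).
#' @return upsampled `feature_map`.
#' @export
upsample_to <- function(map, target_hw, level = max(2L, map$level - 1L)) {
  d <- dim(map$data)
  if (target_hw[1] < d[1] || target_hw[2] < d[2])
    stop_input("target smaller than source; this is an upsampler")
  ay <- bilinear_axis(d[1], target_hw[1])
  ax <- bilinear_axis(d[2], target_hw[2])
  out <- array(0, c(target_hw[1], target_hw[2], d[3]))
  for (k in seq_len(d[3])) {
    ch <- matrix(map$data[, , k], d[1], d[2])
    rows <- ch[ay$lo, , drop = FALSE] * (1 - ay$w) +
            ch[ay$hi, , drop = FALSE] * ay$w
    out[, , k] <- rows[, ax$lo, drop = FALSE] * rep(1 - ax$w, each = target_hw[1]) +
                  rows[, ax$hi, drop = FALSE] * rep(ax$w, each = target_hw[1])
  }
  feature_map(out, level)
}

#' Learnable layer-fusion weights
#'
#' @param alpha1,alpha2 scalar weights for the current level and the
#'   upsampled coarser level; initialized to 1.
#' @return a `layer_fusion_params` list.
#' @export
layer_fusion_params <- function(alpha1 = 1, alpha2 = 1) {
  if (!is.finite(alpha1) || !is.finite(alpha2))
    stop_input("fusion weights must be finite")
  structure(list(alpha1 = alpha1, alpha2 = alpha2),
            class = "layer_fusion_params")
}

#' Weighted layer fusion
#'
#' `F_i = alpha1 * f_i + alpha2 * up(f_{i+1})`, elementwise on maps of
#' identical shape.
#'
#' @param f_i current-level `feature_map`.
#' @param f_up upsampled next-level `feature_map` of the same shape.
#' @param params a [layer_fusion_params()].
#' @return fused `feature_map` at `f_i`'s level.
#' @export
layer_fuse <- function(f_i, f_up, params = layer_fusion_params()) {
  if (!identical(dim(f_i$data), dim(f_up$data)))
    stop_input("layer_fuse requires identical shapes")
  feature_map(params$alpha1 * f_i$data + params$alpha2 * f_up$data, f_i$level)
}

#' Global average pooling
#'
#' @param map a `feature_map` or h x w x c array.
#' @return numeric vector of per-channel spatial means (length c).
#' @export
global_avg_pool <- function(map) {
  data <- if (inherits(map, "feature_map")) map$data else map
  apply(data, 3, mean)
}

#' Channel-attention bottleneck parameters
#'
#' @param c channel count (must be divisible by 8).
#' @param seed seed for the small random init; `zero = TRUE` gives all-zero
#'   matrices (uniform attention, useful as a neutral start).
#' @param zero logical; see above.
#' @return a `channel_attn_params` list with `W1` (c/8 x c), `W2` (c x c/8).
#' @export
channel_attn_params <- function(c, seed = 1L, zero = FALSE) {
  if (c %% 8L != 0L) stop_input("channel count must be divisible by 8")
  r <- c %/% 8L
  if (zero) {
    W1 <- matrix(0, r, c); W2 <- matrix(0, c, r)
  } else {
    with_seed(seed, {
      W1 <- matrix(stats::rnorm(r * c, 0, 1 / sqrt(c)), r, c)
      W2 <- matrix(stats::rnorm(c * r, 0, 1 / sqrt(r)), c, r)
    })
  }
  structure(list(W1 = W1, W2 = W2), class = "channel_attn_params")
}

softmax <- function(x) {
  e <- exp(x - max(x))
  e / sum(e)
}

#' Channel attention weights for a fused map
#'
#' `s = softmax(W2 %*% relu(W1 %*% z))` with `z` the global average pooled
#' channel statistic; entries are nonnegative and sum to 1.
#'
#' @param map a `feature_map`.
#' @param params a [channel_attn_params()].
#' @return numeric weight vector of length c.
#' @export
channel_attention_weights <- function(map, params) {
  z <- global_avg_pool(map)
  c <- length(z)
  if (!all(dim(params$W1) == c(c %/% 8L, c)) ||
      !all(dim(params$W2) == c(c, c %/% 8L)))
    stop_input("attention bottleneck shapes inconsistent with channel count")
  softmax(as.numeric(params$W2 %*% pmax(params$W1 %*% z, 0)))
}

#' Channel-wise attention fusion
#'
#' Scales every channel of the map by its softmax attention weight.
#'
#' @inheritParams channel_attention_weights
#' @return reweighted `feature_map` of identical shape.
#' @export
channel_fuse <- function(map, params) {
  s <- channel_attention_weights(map, params)
  d <- dim(map$data)
  feature_map(map$data * rep(s, each = d[1] * d[2]), map$level)
}

#' Initialize all neck parameters for a pyramid
#'
#' One projection per level and one (layer-fusion, channel-attention) pair
#' per top-down junction (i = 4, 3, 2); alphas start at 1.
#'
#' @param pyramid list C2..C5 of `feature_map`s (see [select_layers()]).
#' @param out_c common fused channel width (divisible by 8).
#' @param seed integer seed.
#' @param with_attention if `FALSE`, channel attention is disabled
#'   (junctions fuse layers only).
#' @return a `fusion_params` list.
#' @export
init_fusion_params <- function(pyramid, out_c = 256, seed = 1L,
                               with_attention = TRUE) {
  proj <- list()
  for (l in 2:5) {
    c_in <- dim(pyramid[[paste0("C", l)]]$data)[3]
    proj[[paste0("C", l)]] <- with_seed(seed + l,
      matrix(stats::rnorm(out_c * c_in, 0, 1 / sqrt(c_in)), out_c, c_in))
  }
  fuse <- attn <- list()
  for (l in 4:2) {
    fuse[[paste0("C", l)]] <- layer_fusion_params()
    attn[[paste0("C", l)]] <-
      if (with_attention) channel_attn_params(out_c, seed = seed + 10L + l)
      else NULL
  }
  structure(list(out_c = out_c, projections = proj, fusion = fuse,
                 attention = attn),
            class = "fusion_params")
}

#' Build the fused feature map
#'
#' Top-down pass C5 -> C2: project each level to the common width, upsample
#' the running coarse map to the current level, fuse with the learnable
#' weighted sum, then apply channel attention (when enabled). The output is
#' the fused level-2 map (stride 4).
#'
#' @param pyramid list C2..C5 of `feature_map`s.
#' @param params a [init_fusion_params()] result.
#' @return `feature_map` at level 2 with `params$out_c` channels.
#' @export
build_fused_map <- function(pyramid, params) {
  pyramid <- select_layers(pyramid)
  proj <- function(l) project_channels(pyramid[[paste0("C", l)]],
                                       params$out_c,
                                       params$projections[[paste0("C", l)]])
  run <- proj(5)
  for (l in 4:2) {
    key <- paste0("C", l)
    p_l <- proj(l)
    up <- upsample_to(run, dim(p_l$data)[1:2], level = l)
    fused <- layer_fuse(p_l, up, params$fusion[[key]])
    run <- if (is.null(params$attention[[key]])) fused
           else channel_fuse(fused, params$attention[[key]])
  }
  run
}

#' Analytic gradients of a sum readout through one fusion junction
#'
#' For `L = sum(channel_fuse(layer_fuse(f, g, alpha), attn))`, returns
#' `dL/dalpha1`, `dL/dalpha2`, `dL/dW1`, `dL/dW2` in closed form (softmax
#' Jacobian, ReLU gate, pooling averaging). Used to verify, against central
#' finite differences, that the junction is differentiable in all learnable
#' parameters.
#'
#' @param f,g same-shape `feature_map`s (current level, upsampled coarser).
#' @param fuse_params a [layer_fusion_params()].
#' @param attn_params a [channel_attn_params()].
#' @return list with `loss`, `alpha1`, `alpha2`, `W1`, `W2`.
#' @export
junction_gradients <- function(f, g, fuse_params, attn_params) {
  d <- dim(f$data)
  hw <- d[1] * d[2]
  Fm <- fuse_params$alpha1 * f$data + fuse_params$alpha2 * g$data
  z <- apply(Fm, 3, mean)
  u <- as.numeric(attn_params$W1 %*% z)
  a <- pmax(u, 0)
  v <- as.numeric(attn_params$W2 %*% a)
  s <- softmax(v)
  A <- apply(Fm, 3, sum)                 # dL/ds
  loss <- sum(s * A)
  # softmax Jacobian applied to A
  dv <- s * (A - sum(s * A))
  dW2 <- outer(dv, a)
  da <- as.numeric(t(attn_params$W2) %*% dv)
  du <- da * (u > 0)
  dW1 <- outer(du, z)
  dz <- as.numeric(t(attn_params$W1) %*% du)
  # dL/dF has a direct path (through A, weight s per channel) and a pooled
  # path (through z); both are constant within a channel here
  dF_chan <- s + dz / hw                 # per-channel scalar
  dalpha1 <- sum(vapply(seq_len(d[3]), function(k)
    dF_chan[k] * sum(f$data[, , k]), numeric(1)))
  dalpha2 <- sum(vapply(seq_len(d[3]), function(k)
    dF_chan[k] * sum(g$data[, , k]), numeric(1)))
  list(loss = loss, alpha1 = dalpha1, alpha2 = dalpha2, W1 = dW1, W2 = dW2)
}
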