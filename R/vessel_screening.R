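# Secondary screening of candidate detections by spatial confidence.
#
# MAs form by capillary dilation and sit close to vessels, so a candidate's
# distance to the nearest vessel carries evidence. The distance is computed
# by iterative box dilation: grow the candidate box by `step` px per round
# (clamped to the image) until it contains a vessel pixel; the distance is
# step * rounds. Spatial confidence is C_i = (C_p - d) / C_p (clamped to
# [0, 1]; optionally forced to 0 at d = 0, since detections sitting exactly
# on a vessel are typically dark vessel pixels, not lesions). The final
# vote S = alpha * P_class + beta * C_i keeps a candidate iff it reaches
# the vote threshold.

#' Screening configuration
#'
#' @param c_p critical distance in pixels: confidence hits 0 at this
#'   distance. Default 100 px, inside which ~98% of true MAs lie.
#' @param alpha,beta vote weights for the detector's class probability and
#'   the spatial confidence (defaults 0.9 / 0.1).
#' @param step box dilation increment in pixels per round.
#' @param vote_threshold candidates with vote >= threshold are kept.
#' @param on_vessel_zero if `TRUE` (default), distance 0 maps to confidence
#'   0 rather than 1: on-vessel hits are treated as suspect.
#' @param max_distance distance reported when no vessel is found anywhere
#'   (`NULL`: `max(image width, height)` at call time).
#' @return a `screening_config` list.
#' @export
screening_config <- function(c_p = 100, alpha = 0.9, beta = 0.1, step = 5L,
                             vote_threshold = 0.8, on_vessel_zero = TRUE,
                             max_distance = NULL) {
  if (c_p <= 0) stop_input("critical distance c_p must be > 0")
  if (alpha + beta <= 0) stop_input("alpha + beta must be > 0")
  if (step < 1) stop_input("step must be >= 1")
  structure(list(c_p = c_p, alpha = alpha, beta = beta,
                 step = as.integer(step), vote_threshold = vote_threshold,
                 on_vessel_zero = isTRUE(on_vessel_zero),
                 max_distance = max_distance),
            class = "screening_config")
}

#' Distance from a candidate box to the nearest vessel
#'
#' Implements the iterative dilation scan: if the (clamped) box already
#' contains a vessel pixel the distance is 0; otherwise the box is grown by
#' `step` px on every side (clamped to the raster) and the distance
#' accumulates by `step` per round. Returns `max_distance` (with attribute
#' `saturated = TRUE`) when the full raster holds no vessel pixel.
#'
#' @param box 0-based half-open box `c(x0, y0, x1, y1)`.
#' @param vessel_mask 0/1 matrix.
#' @param step dilation increment (pixels).
#' @param max_distance value reported on an empty mask.
#' @return distance in pixels, a multiple of `step`.
#' @export
box_vessel_distance <- function(box, vessel_mask, step = 5L,
                                max_distance = max(dim(vessel_mask))) {
  H <- nrow(vessel_mask); W <- ncol(vessel_mask)
  x0 <- clamp(floor(box[1]), 0, W - 1); y0 <- clamp(floor(box[2]), 0, H - 1)
  x1 <- clamp(ceiling(box[3]), x0 + 1, W); y1 <- clamp(ceiling(box[4]), y0 + 1, H)
  d <- 0
  repeat {
    if (any(vessel_mask[(y0 + 1):y1, (x0 + 1):x1] != 0)) return(d)
    if (x0 == 0 && y0 == 0 && x1 == W && y1 == H)
      return(structure(max_distance, saturated = TRUE))
    x0 <- max(x0 - step, 0); y0 <- max(y0 - step, 0)
    x1 <- min(x1 + step, W); y1 <- min(y1 + step, H)
    d <- d + step
  }
}

#' Spatial confidence of a candidate
#'
#' `C_i = (C_p - d) / C_p`, clamped to `[0, 1]`; when `on_vessel_zero` is
#' set, `d = 0` yields 0.
#'
#' @param d distance in pixels (>= 0).
#' @param config a [screening_config()].
#' @return confidence in `[0, 1]`.
#' @export
spatial_confidence <- function(d, config = screening_config()) {
  if (any(d < 0)) stop_input("distance must be >= 0")
  ci <- clamp((config$c_p - d) / config$c_p, 0, 1)
  if (config$on_vessel_zero) ci[d == 0] <- 0
  ci
}

#' Weighted vote score
#'
#' `S = alpha * P_class + beta * C_i`.
#'
#' @param p_class detector class probability in `[0, 1]`.
#' @param c_i spatial confidence in `[0, 1]`.
#' @param config a [screening_config()].
#' @return vote score.
#' @export
vote_score <- function(p_class, c_i, config = screening_config()) {
  config$alpha * p_class + config$beta * c_i
}

#' Screen candidates against a vessel mask
#'
#' Computes distance, spatial confidence and vote score for every
#' candidate (order preserved) and keeps those with vote >= threshold
#' (inclusive).
#'
#' @param candidates data.frame or matrix with columns `x0, y0, x1, y1,
#'   p_class` (0-based half-open boxes).
#' @param vessel_mask 0/1 matrix.
#' @param config a [screening_config()].
#' @return data.frame with the candidate columns plus `distance`, `c_i`,
#'   `s_t`, `kept`.
#' @export
screen <- function(candidates, vessel_mask, config = screening_config()) {
  candidates <- as.data.frame(candidates)
  if (nrow(candidates) == 0) {
    return(cbind(candidates,
                 data.frame(distance = numeric(0), c_i = numeric(0),
                            s_t = numeric(0), kept = logical(0))))
  }
  names(candidates)[1:5] <- c("x0", "y0", "x1", "y1", "p_class")
  maxd <- if (is.null(config$max_distance)) max(dim(vessel_mask))
          else config$max_distance
  d <- vapply(seq_len(nrow(candidates)), function(i)
    as.numeric(box_vessel_distance(as.numeric(candidates[i, 1:4]),
                                   vessel_mask, config$step, maxd)),
    numeric(1))
  ci <- spatial_confidence(d, config)
  st <- vote_score(candidates$p_class, ci, config)
  cbind(candidates,
        data.frame(distance = d, c_i = ci, s_t = st,
                   kept = st >= config$vote_threshold))
}
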