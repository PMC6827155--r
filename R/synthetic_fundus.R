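# Seeded synthetic fundus scene generator.
#
# Emulates the aspects of a macula-centred colour fundus photograph that the
# downstream stages actually consume: a circular field of view (FOV) on a
# dark background, a connected curvilinear vessel tree, and microaneurysms
# (MAs) rendered as small dark disks whose diameters and vessel distances
# follow configurable bin distributions, with exact ground truth (vessel
# mask, lesion mask, boxes, sampled distances) returned alongside the image.

#' Default microaneurysm diameter distribution (pixels)
#'
#' Bin probabilities follow the observed size distribution of MAs on
#' full-resolution fundus photographs: diameters concentrate between 10 and
#' 40 px, with 10-20 px alone accounting for ~47% of lesions.
#'
#' @return data.frame with columns `lo`, `hi` (pixels, bin is `[lo, hi)`)
#'   and `p` (probability).
#' @export
default_size_bins <- function() {
  data.frame(
    lo = c(2, 5, 10, 20, 30, 40, 50),
    hi = c(5, 10, 20, 30, 40, 50, 60),
    p  = c(0.0002, 0.0158, 0.4740, 0.3970, 0.0980, 0.0120, 0.0030)
  )
}

#' Default microaneurysm-to-vessel distance distribution (pixels)
#'
#' MAs form by capillary dilation and so sit close to vessels: ~81% lie
#' within 10 px of the nearest vessel and ~98% within 100 px.
#'
#' @return data.frame with columns `lo`, `hi`, `p` as in
#'   [default_size_bins()].
#' @export
default_distance_bins <- function() {
  data.frame(
    lo = c(0, 10, 20, 30, 40, 50, 100),
    hi = c(10, 20, 30, 40, 50, 100, 200),
    p  = c(0.8070, 0.0760, 0.0420, 0.0130, 0.0220, 0.0220, 0.0180)
  )
}

check_bins <- function(bins, what = "bins") {
  if (is.null(bins) || nrow(as.data.frame(bins)) == 0L)
    stop_input(what, " must contain at least one bin")
  bins <- as.data.frame(bins)
  if (!all(c("lo", "hi", "p") %in% names(bins)))
    stop_input(what, " needs columns lo, hi, p")
  if (any(bins$lo >= bins$hi)) stop_input(what, ": require lo < hi")
  if (any(bins$p < 0)) stop_input(what, ": negative probability")
  if (abs(sum(bins$p) - 1) > 1e-9)
    stop_input(what, ": probabilities must sum to 1 (got ", sum(bins$p), ")")
  bins
}

#' Specify a synthetic fundus scene
#'
#' @param width,height image size in pixels (>= 64).
#' @param fov_radius_frac FOV disc radius as a fraction of `min(width, height)`.
#' @param n_mas number of microaneurysms to place.
#' @param size_bins MA diameter distribution; see [default_size_bins()].
#' @param distance_bins MA-to-vessel L-infinity distance distribution; see
#'   [default_distance_bins()].
#' @param illumination one of `"normal"`, `"bright"`, `"dark"`; bright/dark
#'   emulate over/under-exposed acquisitions that quality screening should
#'   reject.
#' @param vessel_density number of vessel branches grown per scene.
#' @param min_distance smallest admissible MA-to-vessel gap in pixels;
#'   sampled distances below it are clamped up (default 1: lesions sit next
#'   to, but distinct from, vessels).
#' @param seed integer seed; the full scene is a pure function of the spec.
#' @return object of class `scene_spec`.
#' @export
scene_spec <- function(width = 256, height = 256, fov_radius_frac = 0.47,
                       n_mas = 8,
                       size_bins = default_size_bins(),
                       distance_bins = default_distance_bins(),
                       illumination = c("normal", "bright", "dark"),
                       vessel_density = 6, min_distance = 1, seed = 1L) {
  if (width < 64 || height < 64) stop_input("width and height must be >= 64")
  if (n_mas < 0) stop_input("n_mas must be >= 0")
  if (fov_radius_frac <= 0 || fov_radius_frac > 0.5)
    stop_input("fov_radius_frac must lie in (0, 0.5]")
  spec <- list(
    width = as.integer(width), height = as.integer(height),
    fov_radius_frac = fov_radius_frac, n_mas = as.integer(n_mas),
    size_bins = check_bins(size_bins, "size_bins"),
    distance_bins = check_bins(distance_bins, "distance_bins"),
    illumination = match.arg(illumination),
    vessel_density = as.integer(vessel_density),
    min_distance = min_distance, seed = as.integer(seed)
  )
  class(spec) <- "scene_spec"
  spec
}

fov_geometry <- function(spec) {
  list(cx = (spec$width - 1) / 2, cy = (spec$height - 1) / 2,
       r = spec$fov_radius_frac * min(spec$width, spec$height))
}

# Draw from a binned distribution: pick a bin with its probability, then
# uniform within [lo, hi). Uses the caller's RNG stream.
sample_binned <- function(n, bins) {
  bins <- check_bins(bins)
  k <- sample.int(nrow(bins), n, replace = TRUE, prob = bins$p)
  stats::runif(n, bins$lo[k], bins$hi[k])
}

#' Sample microaneurysm diameters
#'
#' @param n number of draws.
#' @param bins diameter bins (see [default_size_bins()]).
#' @return numeric vector of diameters in pixels; uses the current RNG
#'   stream, so seed with `set.seed()` (or rely on [render_scene()], which
#'   seeds from its spec).
#' @export
sample_ma_diameter <- function(n, bins = default_size_bins()) {
  sample_binned(n, bins)
}

#' Sample microaneurysm-to-vessel distances
#'
#' @inheritParams sample_ma_diameter
#' @param bins distance bins (see [default_distance_bins()]).
#' @export
sample_ma_vessel_distance <- function(n, bins = default_distance_bins()) {
  sample_binned(n, bins)
}

# Stamp a disc of radius `rad` (pixels, L2) centred at 0-based (x, y) onto
# mask, restricted to the FOV disc.
stamp_disc <- function(mask, x, y, rad, geo) {
  h <- nrow(mask); w <- ncol(mask)
  x0 <- max(0L, floor(x - rad)); x1 <- min(w - 1L, ceiling(x + rad))
  y0 <- max(0L, floor(y - rad)); y1 <- min(h - 1L, ceiling(y + rad))
  if (x0 > x1 || y0 > y1) return(mask)
  xs <- x0:x1; ys <- y0:y1
  dx <- outer(rep(1, length(ys)), xs - x)
  dy <- outer(ys - y, rep(1, length(xs)))
  inside <- (dx^2 + dy^2 <= rad^2) &
    ((outer(rep(1, length(ys)), xs) - geo$cx)^2 +
       (outer(ys, rep(1, length(xs))) - geo$cy)^2 <= geo$r^2)
  sub <- mask[ys + 1L, xs + 1L, drop = FALSE]
  sub[inside] <- 1L
  mask[ys + 1L, xs + 1L] <- sub
  mask
}

#' Generate a connected synthetic vessel tree
#'
#' Grows `vessel_density` curvilinear branches by a seeded random walk with
#' angle jitter; every branch after the first starts on an existing branch,
#' so the stroke set is 8-connected. Strokes are 3-10 px wide, confined to
#' the FOV disc, and cover between 1% and 15% of it.
#'
#' @param spec a [scene_spec()].
#' @return 0/1 integer matrix (`height` x `width`).
#' @export
generate_vessel_tree <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  mask <- matrix(0L, spec$height, spec$width)
  if (spec$vessel_density <= 0) return(mask)
  geo <- fov_geometry(spec)
  fov_px <- sum((outer(seq_len(spec$height) - 1 - geo$cy, rep(1, spec$width))^2 +
                 outer(rep(1, spec$height), seq_len(spec$width) - 1 - geo$cx)^2) <= geo$r^2)
  with_seed(spec$seed, {
    pts <- NULL  # matrix of visited (x, y) walk points, branch anchors
    n_branches <- 0L
    while (n_branches < spec$vessel_density && sum(mask) / fov_px < 0.12) {
      if (is.null(pts)) {
        ang0 <- stats::runif(1, 0, 2 * pi)
        x <- geo$cx + 0.92 * geo$r * cos(ang0)
        y <- geo$cy + 0.92 * geo$r * sin(ang0)
        ang <- ang0 + pi + stats::runif(1, -0.3, 0.3)  # point inward
      } else {
        k <- sample.int(nrow(pts), 1)
        x <- pts[k, 1]; y <- pts[k, 2]
        ang <- stats::runif(1, 0, 2 * pi)
      }
      wdt <- stats::runif(1, 3, 10)
      len <- stats::runif(1, 0.6, 1.6) * geo$r
      step <- 2
      path <- matrix(NA_real_, ceiling(len / step), 2)
      for (i in seq_len(nrow(path))) {
        x <- x + step * cos(ang); y <- y + step * sin(ang)
        ang <- ang + stats::rnorm(1, 0, 0.18)
        if ((x - geo$cx)^2 + (y - geo$cy)^2 > (0.98 * geo$r)^2) break
        path[i, ] <- c(x, y)
        mask <- stamp_disc(mask, x, y, wdt / 2, geo)
      }
      path <- path[!is.na(path[, 1]), , drop = FALSE]
      if (nrow(path) > 2) {
        pts <- rbind(pts, path)
        n_branches <- n_branches + 1L
      }
    }
    # density floor: keep growing from the existing tree if too sparse
    guard <- 0L
    while (sum(mask) / fov_px < 0.01 && guard < 50L && !is.null(pts)) {
      k <- sample.int(nrow(pts), 1)
      x <- pts[k, 1]; y <- pts[k, 2]
      ang <- stats::runif(1, 0, 2 * pi)
      wdt <- stats::runif(1, 4, 10)
      for (i in seq_len(80)) {
        x <- x + 2 * cos(ang); y <- y + 2 * sin(ang)
        ang <- ang + stats::rnorm(1, 0, 0.18)
        if ((x - geo$cx)^2 + (y - geo$cy)^2 > (0.98 * geo$r)^2) break
        mask <- stamp_disc(mask, x, y, wdt / 2, geo)
      }
      guard <- guard + 1L
    }
  })
  mask
}

# Place MA centres by rejection sampling against the Chebyshev distance
# transform of the vessel mask, so that each lesion box sits at its sampled
# L-infinity gap from the tree (within rasterization slack).
place_mas <- function(spec, vessel_mask, geo) {
  empty <- list(centers = matrix(numeric(0), 0, 2), diam = numeric(0),
                dist = numeric(0),
                boxes = boxes_as_matrix(NULL))
  if (spec$n_mas == 0L) return(empty)
  if (sum(vessel_mask) == 0L) {
    warning("no vessel pixels: cannot honour distance bins; placing 0 MAs")
    return(empty)
  }
  max_need <- ceiling(max(spec$distance_bins$hi) + max(spec$size_bins$hi)) + 2L
  dt <- chebyshev_dt(vessel_mask, max_need)
  h <- spec$height; w <- spec$width
  ys0 <- matrix(seq_len(h) - 1, h, w)
  xs0 <- matrix(rep(seq_len(w) - 1, each = h), h, w)
  in_fov <- ((xs0 - geo$cx)^2 + (ys0 - geo$cy)^2) <= (0.95 * geo$r)^2

  centers <- matrix(numeric(0), 0, 2)
  diams <- dists <- numeric(0)
  boxes <- NULL
  kept <- 0L
  for (m in seq_len(spec$n_mas)) {
    placed <- FALSE
    for (try in seq_len(100L)) {
      d <- max(2L, as.integer(round(sample_ma_diameter(1, spec$size_bins))))
      g <- as.integer(round(max(spec$min_distance,
                                sample_ma_vessel_distance(1, spec$distance_bins))))
      half <- d %/% 2L
      target <- g + half
      cand <- which(abs(dt - target) <= 0L & in_fov)
      if (length(cand) == 0L)
        cand <- which(abs(dt - target) <= 1L & in_fov)
      if (length(cand) == 0L) next
      pick <- cand[sample.int(length(cand), 1L)]
      cy <- (pick - 1L) %% h          # 0-based row
      cx <- (pick - 1L) %/% h         # 0-based col
      box <- c(cx - half, cy - half, cx - half + d, cy - half + d)
      if (box[1] < 0 || box[2] < 0 || box[3] > w || box[4] > h) next
      # >= 3 px separation so anti-aliased disks never merge under
      # 8-connectivity
      if (!is.null(boxes) && nrow(boxes) > 0) {
        sep <- boxes[, 1] >= box[3] + 3 | boxes[, 3] <= box[1] - 3 |
               boxes[, 2] >= box[4] + 3 | boxes[, 4] <= box[2] - 3
        if (!all(sep)) next
      }
      centers <- rbind(centers, c(cx, cy))
      diams <- c(diams, d); dists <- c(dists, g)
      boxes <- rbind(boxes, box)
      placed <- TRUE
      break
    }
    if (placed) kept <- kept + 1L
  }
  if (kept < spec$n_mas)
    warning(sprintf("placed only %d of %d MAs after bounded retries", kept,
                    spec$n_mas))
  rownames(boxes) <- NULL
  list(centers = centers, diam = diams, dist = dists,
       boxes = boxes_as_matrix(boxes))
}

#' Render a synthetic fundus scene with ground truth
#'
#' Deterministically renders the scene described by `spec`: a smoothly
#' shaded reddish fundus disc, a connected vessel tree drawn dark, and MAs
#' as anti-aliased dark disks at 0.4-0.7 x the local background intensity.
#' Bright/dark illumination variants shift the whole disc out of the
#' acceptable exposure band used by quality screening.
#'
#' @param spec a [scene_spec()].
#' @return a `scene_truth` list: `image` (h x w x 3, 0-255), `vessel_mask`
#'   and `ma_mask` (0/1 matrices), `ma_boxes` (matrix of 0-based half-open
#'   boxes), `sampled_distances` (pixels), `ma_diameters`, and `spec`.
#' @export
render_scene <- function(spec) {
  stopifnot(inherits(spec, "scene_spec"))
  geo <- fov_geometry(spec)
  vessel <- generate_vessel_tree(spec)
  with_seed(spec$seed + 7L, {
    h <- spec$height; w <- spec$width
    ys <- matrix(seq_len(h) - 1, h, w)
    xs <- matrix(rep(seq_len(w) - 1, each = h), h, w)
    r2 <- (xs - geo$cx)^2 + (ys - geo$cy)^2
    fov <- r2 <= geo$r^2
    fall <- 1 - 0.18 * r2 / geo$r^2

    g <- 115 * fall + matrix(stats::rnorm(h * w, 0, 2.5), h, w)
    r <- 170 * fall + matrix(stats::rnorm(h * w, 0, 2.5), h, w)
    b <- 45 * fall + matrix(stats::rnorm(h * w, 0, 2), h, w)

    vz <- vessel == 1L
    g[vz] <- g[vz] * 0.60
    r[vz] <- r[vz] * 0.62
    b[vz] <- b[vz] * 0.85

    pl <- place_mas(spec, vessel, geo)
    ma_mask <- matrix(0L, h, w)
    truth_boxes <- NULL
    if (nrow(pl$centers) > 0) {
      for (m in seq_len(nrow(pl$centers))) {
        cx <- pl$centers[m, 1]; cy <- pl$centers[m, 2]
        rad <- pl$diam[m] / 2
        f <- stats::runif(1, 0.4, 0.7)  # lesion-to-background intensity
        x0 <- max(0, floor(cx - rad - 1)); x1 <- min(w - 1, ceiling(cx + rad + 1))
        y0 <- max(0, floor(cy - rad - 1)); y1 <- min(h - 1, ceiling(cy + rad + 1))
        xs_ <- x0:x1; ys_ <- y0:y1
        dd <- sqrt(outer((ys_ - cy)^2, rep(1, length(xs_))) +
                   outer(rep(1, length(ys_)), (xs_ - cx)^2))
        cov <- clamp(rad + 0.5 - dd, 0, 1)  # anti-aliased edge coverage
        ii <- ys_ + 1; jj <- xs_ + 1
        g[ii, jj] <- g[ii, jj] * (1 - cov * (1 - f))
        r[ii, jj] <- r[ii, jj] * (1 - cov * (1 - f * 1.1))
        core <- cov >= 0.5
        sub <- ma_mask[ii, jj]; sub[core] <- 1L
        ma_mask[ii, jj] <- sub
        # truth box = tight box of the rendered lesion pixels (0-based,
        # half-open), so it always encloses its mask component exactly
        rr <- range(ys_[row(core)[core]]); cc <- range(xs_[col(core)[core]])
        truth_boxes <- rbind(truth_boxes, c(cc[1], rr[1], cc[2] + 1, rr[2] + 1))
      }
    }
    pl$boxes <- boxes_as_matrix(truth_boxes)

    shift <- switch(spec$illumination, normal = 0, bright = 95, dark = 0)
    scale <- switch(spec$illumination, normal = 1, bright = 1, dark = 0.22)
    img <- array(0, dim = c(h, w, 3))
    img[, , 1] <- (r * scale + shift) * fov
    img[, , 2] <- (g * scale + shift) * fov
    img[, , 3] <- (b * scale + shift) * fov
    img <- round(clamp(img, 0, 255))

    structure(list(image = img, vessel_mask = vessel, ma_mask = ma_mask,
                   ma_boxes = pl$boxes, sampled_distances = pl$dist,
                   ma_diameters = pl$diam, spec = spec),
              class = "scene_truth")
  })
}
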