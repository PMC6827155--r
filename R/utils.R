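# Internal helpers shared across modules.
#
# Raster conventions used throughout the package:
#  * grayscale rasters are numeric matrices indexed [row = y, col = x],
#    values in 0..255;
#  * binary masks are 0/1 integer matrices of the same orientation;
#  * RGB rasters are arrays dim c(h, w, 3), values 0..255;
#  * bounding boxes are 0-based, half-open: c(x0, y0, x1, y1) covers pixel
#    columns x0..x1-1 and rows y0..y1-1. Conversion to the 1-based inclusive
#    Pascal VOC convention happens only at the VOC XML boundary.

clamp <- function(x, lo, hi) pmin(pmax(x, lo), hi)

#' Evaluate an expression under a temporary RNG seed
#'
#' Saves and restores `.Random.seed` so that seeded package internals never
#' disturb the caller's random number stream.
#'
#' @param seed integer seed.
#' @param expr expression to evaluate.
#' @return the value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  had <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (had) get(".Random.seed", envir = globalenv()) else NULL
  on.exit({
    if (had) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  }, add = TRUE)
  set.seed(as.integer(seed))
  expr
}

stop_input <- function(...) stop(..., call. = FALSE)

# Validate a c(x0, y0, x1, y1) half-open box.
check_box <- function(box) {
  if (length(box) != 4L || anyNA(box))
    stop_input("box must be c(x0, y0, x1, y1) without NAs")
  if (box[1] >= box[3] || box[2] >= box[4])
    stop_input("degenerate box: require x0 < x1 and y0 < y1")
  invisible(box)
}

box_area <- function(box) (box[3] - box[1]) * (box[4] - box[2])

boxes_as_matrix <- function(boxes) {
  if (is.null(boxes) || length(boxes) == 0L)
    return(matrix(numeric(0), ncol = 4,
                  dimnames = list(NULL, c("x0", "y0", "x1", "y1"))))
  if (is.data.frame(boxes)) boxes <- as.matrix(boxes[, 1:4])
  if (is.vector(boxes)) boxes <- matrix(boxes, ncol = 4, byrow = TRUE)
  colnames(boxes) <- c("x0", "y0", "x1", "y1")
  boxes
}

#' Label 8-connected components of a binary mask
#'
#' EBImage's labeller is 4-connected; lesions and vessel strokes here are
#' defined with diagonal adjacency, so this builds the 8-neighbour pixel
#' graph and labels its connected components.
#'
#' @param mask 0/1 matrix.
#' @return integer matrix of the same shape; 0 = background, components
#'   numbered from 1 in first-pixel order.
#' @export
label_components8 <- function(mask) {
  m <- mask != 0
  h <- nrow(m); w <- ncol(m)
  idx <- which(m)
  lab <- matrix(0L, h, w)
  if (length(idx) == 0L) return(lab)
  r <- ((idx - 1L) %% h) + 1L
  cc <- ((idx - 1L) %/% h) + 1L
  # map pixel linear index -> vertex id
  vid <- integer(h * w); vid[idx] <- seq_along(idx)
  edges <- integer(0)
  for (off in list(c(1L, 0L), c(0L, 1L), c(1L, 1L), c(-1L, 1L))) {
    r2 <- r + off[1]; c2 <- cc + off[2]
    ok <- r2 >= 1L & r2 <= h & c2 >= 1L & c2 <= w
    if (!any(ok)) next
    j <- (c2[ok] - 1L) * h + r2[ok]
    hit <- m[j]
    if (!any(hit)) next
    edges <- c(edges, rbind(vid[idx[ok][hit]], vid[j[hit]]))
  }
  g <- igraph::make_graph(edges = edges, n = length(idx), directed = FALSE)
  comp <- igraph::components(g)$membership
  # renumber in order of first appearance (column-major scan order)
  first <- match(unique(comp), comp)
  relab <- integer(max(comp)); relab[comp[sort(first)]] <- seq_along(first)
  lab[idx] <- relab[comp]
  lab
}

# Chebyshev (L-infinity) distance transform to the nearest set pixel of
# `mask`, computed by iterated 3x3 dilation. Cells further than `max_d`
# get max_d + 1. Vectorized: each round is 8 shifted pmax's.
chebyshev_dt <- function(mask, max_d) {
  m <- mask != 0
  h <- nrow(m); w <- ncol(m)
  dt <- matrix(max_d + 1, h, w)
  dt[m] <- 0
  cur <- m
  for (d in seq_len(max_d)) {
    if (all(cur)) break
    # separable 3x3 square dilation: rows, then columns
    nxt <- cur
    nxt[-1, ] <- nxt[-1, ] | cur[-h, ]
    nxt[-h, ] <- nxt[-h, ] | cur[-1, ]
    tmp <- nxt
    nxt[, -1] <- nxt[, -1] | tmp[, -w]
    nxt[, -w] <- nxt[, -w] | tmp[, -1]
    newly <- nxt & !cur
    if (!any(newly)) break
    dt[newly] <- d
    cur <- nxt
  }
  dt
}

# Minimal L-infinity gap from a half-open box to the nearest set pixel of
# `mask`, by direct scan over all set pixels. Used as the ground-truth
# distance when building scenes; intentionally simple.
box_mask_linf_gap <- function(box, mask) {
  idx <- which(mask != 0)
  if (length(idx) == 0L) return(Inf)
  h <- nrow(mask)
  py <- ((idx - 1L) %% h)          # 0-based pixel rows
  px <- ((idx - 1L) %/% h)         # 0-based pixel cols
  gx <- pmax(box[1] - px, px - (box[3] - 1), 0)
  gy <- pmax(box[2] - py, py - (box[4] - 1), 0)
  min(pmax(gx, gy))
}
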