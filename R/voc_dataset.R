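# Pascal VOC patch dataset construction.
#
# Full-resolution fundus images are far larger than a detector's input, and
# MAs occupy a few dozen pixels, so images are sliced into overlapping-free
# window patches; boxes are derived from the binary lesion map, patches
# without a usable lesion or consisting mostly of background are discarded,
# and the survivors are written out in Pascal VOC layout (PNG patches, one
# XML annotation each, plain-text train/test manifests).
#
# Internally boxes are 0-based half-open; VOC XML uses 1-based inclusive
# coordinates and the conversion happens exactly once, at read/write time.

#' Sliding-window patch origins and patches
#'
#' Origins form the regular grid 0, s, 2s, ...; when the grid does not reach
#' the image edge a final right/bottom-aligned window is added so that every
#' pixel is covered by at least one window.
#'
#' @param image matrix (grayscale raster).
#' @param window `c(w, h)` window size in pixels.
#' @param stride `c(sx, sy)` strides (>= 1).
#' @return list of records `list(origin = c(x, y), patch = matrix)`, origins
#'   0-based.
#' @export
slide_windows <- function(image, window, stride = window) {
  W <- ncol(image); H <- nrow(image)
  w <- window[1]; h <- window[2]
  sx <- stride[1]; sy <- stride[2]
  if (w > W || h > H) stop_input("window larger than image")
  if (sx < 1 || sy < 1) stop_input("strides must be >= 1")
  grid_1d <- function(size, win, s) {
    o <- seq(0L, size - win, by = s)
    if (max(o) + win < size) o <- c(o, size - win)
    as.integer(o)
  }
  xs <- grid_1d(W, w, sx); ys <- grid_1d(H, h, sy)
  out <- vector("list", length(xs) * length(ys))
  k <- 1L
  for (y in ys) for (x in xs) {
    out[[k]] <- list(origin = c(x, y),
                     patch = image[(y + 1):(y + h), (x + 1):(x + w),
                                   drop = FALSE])
    k <- k + 1L
  }
  out
}

#' Tight bounding boxes of lesion mask components
#'
#' One box per 8-connected component of the mask; components smaller than
#' `min_diameter` in both extents are dropped (the far tail of the MA size
#' distribution, indistinguishable from noise).
#'
#' @param ma_mask 0/1 matrix.
#' @param min_diameter smallest kept `max(width, height)` in pixels.
#' @return matrix of 0-based half-open boxes (possibly 0 rows).
#' @export
boxes_from_mask <- function(ma_mask, min_diameter = 5) {
  lab <- label_components8(ma_mask)
  n <- max(lab)
  if (n == 0L) return(boxes_as_matrix(NULL))
  boxes <- NULL
  for (k in seq_len(n)) {
    idx <- which(lab == k)
    rr <- range(((idx - 1L) %% nrow(lab)))       # 0-based rows
    cc <- range(((idx - 1L) %/% nrow(lab)))      # 0-based cols
    b <- c(cc[1], rr[1], cc[2] + 1L, rr[2] + 1L)
    if (max(b[3] - b[1], b[4] - b[2]) >= min_diameter)
      boxes <- rbind(boxes, b)
  }
  boxes_as_matrix(boxes)
}

#' Decide whether a patch enters the dataset
#'
#' A patch is kept iff it contains at least one box lying fully inside it
#' and its nonzero-pixel fraction reaches `roi_fraction_min` (discarding
#' mostly-black background blocks from outside the fundus disc).
#'
#' @param patch matrix.
#' @param boxes boxes already expressed in patch coordinates and clipped to
#'   the patch.
#' @param roi_fraction_min minimum fraction of nonzero pixels.
#' @return logical.
#' @export
keep_patch <- function(patch, boxes, roi_fraction_min = 0.1) {
  boxes <- boxes_as_matrix(boxes)
  w <- ncol(patch); h <- nrow(patch)
  inside <- nrow(boxes) > 0 &&
    any(boxes[, 1] >= 0 & boxes[, 2] >= 0 & boxes[, 3] <= w & boxes[, 4] <= h)
  inside && mean(patch != 0) >= roi_fraction_min
}

#' Build patch records from an image and its lesion mask
#'
#' Slides windows, derives boxes from the mask, assigns each box to the
#' patches that fully contain it (boxes straddling a patch edge are dropped
#' from that patch, not clipped: a truncated lesion is corrupt truth), and
#' applies [keep_patch()].
#'
#' @param image grayscale matrix (typically `equalize()$pixels`).
#' @param ma_mask 0/1 lesion mask of the same shape.
#' @param window,stride see [slide_windows()].
#' @param min_diameter see [boxes_from_mask()].
#' @param roi_fraction_min see [keep_patch()].
#' @param clip_boxes if `TRUE`, straddling boxes are clipped to the patch
#'   instead of dropped.
#' @param source_id identifier recorded on every patch.
#' @return list of `patch_record` lists: `id`, `patch`, `origin`, `boxes`
#'   (patch coordinates), `source_id`.
#' @export
build_patches <- function(image, ma_mask, window = c(128, 128),
                          stride = window, min_diameter = 5,
                          roi_fraction_min = 0.1, clip_boxes = FALSE,
                          source_id = "scene") {
  stopifnot(identical(dim(image), dim(ma_mask)))
  boxes <- boxes_from_mask(ma_mask, min_diameter)
  wins <- slide_windows(image, window, stride)
  out <- list()
  for (wrec in wins) {
    ox <- wrec$origin[1]; oy <- wrec$origin[2]
    w <- ncol(wrec$patch); h <- nrow(wrec$patch)
    local <- NULL
    if (nrow(boxes) > 0) {
      for (i in seq_len(nrow(boxes))) {
        b <- boxes[i, ] - c(ox, oy, ox, oy)
        if (b[1] >= 0 && b[2] >= 0 && b[3] <= w && b[4] <= h) {
          local <- rbind(local, b)
        } else if (clip_boxes) {
          cb <- c(max(b[1], 0), max(b[2], 0), min(b[3], w), min(b[4], h))
          if (cb[1] < cb[3] && cb[2] < cb[4]) local <- rbind(local, cb)
        }
      }
    }
    local <- boxes_as_matrix(local)
    if (keep_patch(wrec$patch, local, roi_fraction_min)) {
      id <- sprintf("%s_x%04d_y%04d", source_id, ox, oy)
      out[[length(out) + 1L]] <- structure(
        list(id = id, patch = wrec$patch, origin = c(ox, oy), boxes = local,
             source_id = source_id),
        class = "patch_record")
    }
  }
  out
}

voc_paths <- function(dir, id) {
  list(xml = file.path(dir, "Annotations", paste0(id, ".xml")),
       png = file.path(dir, "JPEGImages", paste0(id, ".png")))
}

#' Write a patch record in Pascal VOC layout
#'
#' Writes `JPEGImages/<id>.png` and `Annotations/<id>.xml`. Boxes are
#' converted from the internal 0-based half-open convention to VOC's
#' 1-based inclusive one: `xmin = x0 + 1`, `xmax = x1`.
#'
#' @param record a `patch_record` from [build_patches()].
#' @param dir dataset root directory (created if missing).
#' @return the record's id, invisibly.
#' @export
write_voc <- function(record, dir) {
  p <- voc_paths(dir, record$id)
  dir.create(dirname(p$xml), recursive = TRUE, showWarnings = FALSE)
  dir.create(dirname(p$png), recursive = TRUE, showWarnings = FALSE)
  png::writePNG(clamp(record$patch, 0, 255) / 255, p$png)

  doc <- xml2::xml_new_root("annotation")
  xml2::xml_add_child(doc, "folder", basename(dir))
  xml2::xml_add_child(doc, "filename", paste0(record$id, ".png"))
  xml2::xml_add_child(doc, "source_id", record$source_id)
  sz <- xml2::xml_add_child(doc, "size")
  xml2::xml_add_child(sz, "width", as.character(ncol(record$patch)))
  xml2::xml_add_child(sz, "height", as.character(nrow(record$patch)))
  xml2::xml_add_child(sz, "depth", "1")
  boxes <- boxes_as_matrix(record$boxes)
  if (nrow(boxes) > 0) {
    for (i in seq_len(nrow(boxes))) {
      ob <- xml2::xml_add_child(doc, "object")
      xml2::xml_add_child(ob, "name", "MA")
      xml2::xml_add_child(ob, "difficult", "0")
      bb <- xml2::xml_add_child(ob, "bndbox")
      xml2::xml_add_child(bb, "xmin", as.character(boxes[i, 1] + 1L))
      xml2::xml_add_child(bb, "ymin", as.character(boxes[i, 2] + 1L))
      xml2::xml_add_child(bb, "xmax", as.character(boxes[i, 3]))
      xml2::xml_add_child(bb, "ymax", as.character(boxes[i, 4]))
    }
  }
  xml2::write_xml(doc, p$xml)
  invisible(record$id)
}

#' Read a patch record back from a VOC directory
#'
#' Inverse of [write_voc()]; box coordinates are converted back to the
#' internal 0-based half-open convention.
#'
#' @param dir dataset root.
#' @param id patch identifier.
#' @return a `patch_record`.
#' @export
read_voc <- function(dir, id) {
  p <- voc_paths(dir, id)
  doc <- tryCatch(xml2::read_xml(p$xml),
                  error = function(e)
                    stop_input("malformed VOC XML in ", p$xml, ": ",
                               conditionMessage(e)))
  patch <- round(png::readPNG(p$png) * 255)
  if (length(dim(patch)) == 3L) patch <- patch[, , 1]
  num <- function(node, tag)
    as.numeric(xml2::xml_text(xml2::xml_find_first(node, tag)))
  boxes <- NULL
  for (ob in xml2::xml_find_all(doc, "object")) {
    bb <- xml2::xml_find_first(ob, "bndbox")
    boxes <- rbind(boxes, c(num(bb, "xmin") - 1, num(bb, "ymin") - 1,
                            num(bb, "xmax"), num(bb, "ymax")))
  }
  # origin is encoded in the id by build_patches; recover when it matches
  m <- regmatches(id, regexec("_x([0-9]+)_y([0-9]+)$", id))[[1]]
  origin <- if (length(m) == 3) as.integer(m[2:3]) else c(NA_integer_, NA_integer_)
  structure(list(id = id, patch = patch, origin = origin,
                 boxes = boxes_as_matrix(boxes),
                 source_id = xml2::xml_text(
                   xml2::xml_find_first(doc, "source_id"))),
            class = "patch_record")
}

#' Split patch ids into train and test sets
#'
#' Seeded shuffle; the test set gets `round(test_fraction * N)` ids, the
#' rest train. Disjoint and exhaustive by construction.
#'
#' @param ids character vector of patch ids.
#' @param test_fraction in (0, 1).
#' @param seed integer seed.
#' @return list with `train_ids`, `test_ids`, `seed`.
#' @export
make_split <- function(ids, test_fraction, seed = 1L) {
  n <- length(ids)
  if (n < 2) stop_input("need at least 2 ids to split")
  if (test_fraction <= 0 || test_fraction >= 1)
    stop_input("test_fraction must lie in (0, 1)")
  perm <- with_seed(seed, sample.int(n))
  n_test <- round(test_fraction * n)
  list(train_ids = ids[perm[seq_len(n - n_test)]],
       test_ids = ids[perm[seq(n - n_test + 1, length.out = n_test)]],
       seed = as.integer(seed))
}

#' Write train/test manifests
#'
#' @param split a list from [make_split()].
#' @param dir dataset root; writes `ImageSets/Main/train.txt` and `test.txt`.
#' @return invisibly, the directory.
#' @export
write_split <- function(split, dir) {
  d <- file.path(dir, "ImageSets", "Main")
  dir.create(d, recursive = TRUE, showWarnings = FALSE)
  writeLines(split$train_ids, file.path(d, "train.txt"))
  writeLines(split$test_ids, file.path(d, "test.txt"))
  invisible(dir)
}
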