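# Fundus image quality equalization.
#
# Pipeline: extract the green channel (the plane with the best
# lesion/background contrast on fundus photographs), enhance it with CLAHE,
# in parallel threshold the raw green channel with Otsu to recover the
# circular field-of-view foreground, and combine the two into a
# contrast-enhanced, ROI-masked image. A quality screen rejects over/under
# exposed images and images whose ROI is dominated by extreme-intensity
# regions before any of this is attempted.

#' Equalization configuration
#'
#' @param clahe_clip_limit CLAHE contrast clip factor (> 0).
#' @param clahe_tiles CLAHE tile grid as `c(rows, cols)`.
#' @param brightness_low,brightness_high acceptable mean green intensity
#'   inside the Otsu foreground, on the 0-255 scale.
#' @param reject_on_quality if `TRUE`, [equalize()] refuses images the
#'   quality screen rejects.
#' @param lesion_area_frac reject when extreme-intensity connected
#'   components cover more than this fraction of the ROI.
#' @param extreme_low,extreme_high intensities below/above which a pixel
#'   counts as extreme for the lesion-coverage screen.
#' @param lesion_min_area smallest extreme component (pixels) that counts.
#' @return an `equalization_config` list.
#' @export
equalization_config <- function(clahe_clip_limit = 2, clahe_tiles = c(8, 8),
                                brightness_low = 40, brightness_high = 180,
                                reject_on_quality = TRUE,
                                lesion_area_frac = 0.20,
                                extreme_low = 25, extreme_high = 230,
                                lesion_min_area = 64) {
  if (clahe_clip_limit <= 0) stop_input("clahe_clip_limit must be > 0")
  if (!(brightness_low >= 0 && brightness_low < brightness_high &&
        brightness_high <= 255))
    stop_input("require 0 <= brightness_low < brightness_high <= 255")
  structure(list(clahe_clip_limit = clahe_clip_limit,
                 clahe_tiles = as.integer(clahe_tiles),
                 brightness_low = brightness_low,
                 brightness_high = brightness_high,
                 reject_on_quality = isTRUE(reject_on_quality),
                 lesion_area_frac = lesion_area_frac,
                 extreme_low = extreme_low, extreme_high = extreme_high,
                 lesion_min_area = lesion_min_area),
            class = "equalization_config")
}

#' Extract the green channel of an RGB raster
#'
#' @param rgb array of dim `c(h, w, 3)`, values 0-255.
#' @return `h x w` matrix equal to the green plane, unmodified.
#' @export
extract_green <- function(rgb) {
  if (length(dim(rgb)) != 3L || dim(rgb)[3] != 3L)
    stop_input("expected a 3-channel RGB array")
  rgb[, , 2]
}

#' Contrast-limited adaptive histogram equalization
#'
#' Tile-wise histogram equalization with a clip limit and bilinear
#' interpolation between tile mappings (delegated to EBImage's CLAHE).
#'
#' @param gray matrix, values 0-255.
#' @param config an [equalization_config()].
#' @return matrix of the same shape, values in 0-255.
#' @export
clahe_enhance <- function(gray, config = equalization_config()) {
  tiles <- config$clahe_tiles
  if (nrow(gray) < tiles[1] || ncol(gray) < tiles[2])
    stop_input("CLAHE tile grid larger than image")
  if (diff(range(gray)) == 0) return(gray)  # single level: nothing to map
  if (prod(tiles) < 4)  # single tile: global clipped equalization
    return(global_equalize(gray, config$clahe_clip_limit))
  # EBImage images are [x, y]; transpose in and out
  img <- EBImage::Image(t(gray) / 255)
  out <- EBImage::clahe(img, nx = tiles[2], ny = tiles[1], bins = 256,
                        limit = config$clahe_clip_limit)
  t(clamp(EBImage::imageData(out), 0, 1)) * 255
}

# One-tile limiting case of CLAHE: the histogram is clipped at
# clip * (mean bin count), the excess is redistributed uniformly, and the
# CDF maps levels onto 0..255.
global_equalize <- function(gray, clip) {
  v <- as.integer(round(clamp(gray, 0, 255)))
  counts <- tabulate(v + 1L, nbins = 256L)
  if (is.finite(clip)) {
    cl <- clip * length(v) / 256
    excess <- sum(pmax(counts - cl, 0))
    counts <- pmin(counts, cl) + excess / 256
  }
  lut <- cumsum(counts) / sum(counts) * 255
  matrix(lut[v + 1L], nrow(gray), ncol(gray))
}

#' Otsu threshold of an 8-bit image
#'
#' Maximizes between-class variance over the 256-bin histogram; ties are
#' broken toward the lowest threshold. The foreground is `pixel > t`.
#'
#' @param gray matrix, values 0-255.
#' @return integer threshold t in 0..254.
#' @export
otsu_threshold <- function(gray) {
  v <- as.integer(round(clamp(as.numeric(gray), 0, 255)))
  if (length(unique(v)) < 2L)
    stop_input("degenerate histogram: image has a single intensity level")
  counts <- tabulate(v + 1L, nbins = 256L)
  p <- counts / sum(counts)
  levs <- 0:255
  w0 <- cumsum(p)[1:255]            # class {0..t}, t = 0..254
  mu_c <- cumsum(p * levs)[1:255]
  mu_t <- sum(p * levs)
  w1 <- 1 - w0
  valid <- w0 > 0 & w1 > 0
  sb <- rep(-Inf, 255)
  sb[valid] <- (mu_t * w0[valid] - mu_c[valid])^2 / (w0[valid] * w1[valid])
  which.max(sb) - 1L               # which.max takes the first (lowest) tie
}

#' Otsu foreground mask
#'
#' @inheritParams otsu_threshold
#' @return 0/1 integer matrix: 1 where `gray > t`.
#' @export
otsu_mask <- function(gray) {
  t <- otsu_threshold(gray)
  m <- matrix(0L, nrow(gray), ncol(gray))
  m[gray > t] <- 1L
  m
}

#' Combine an enhanced image with an ROI mask
#'
#' @param enhanced matrix, values 0-255.
#' @param mask 0/1 matrix of the same shape.
#' @param provenance optional string recorded with the result.
#' @return an `equalized_image` list: `pixels` (0 outside the ROI),
#'   `roi_mask`, `provenance`.
#' @export
combine_roi <- function(enhanced, mask, provenance = NA_character_) {
  if (!identical(dim(enhanced), dim(mask)))
    stop_input("enhanced image and mask shapes differ")
  structure(list(pixels = enhanced * (mask != 0), roi_mask = (mask != 0) * 1L,
                 provenance = provenance),
            class = "equalized_image")
}

#' Screen an image for acquisition quality
#'
#' Decides from the raw green channel whether the image is usable:
#' over/under exposure is judged from the mean intensity inside the Otsu
#' foreground; images whose ROI is dominated by large extreme-intensity
#' connected components (severe obscuring lesions, flash artefacts) are
#' rejected too.
#'
#' @param rgb RGB array, 0-255.
#' @param config an [equalization_config()].
#' @return one of `"accept"`, `"reject_bright"`, `"reject_dark"`,
#'   `"reject_lesion"`.
#' @export
screen_quality <- function(rgb, config = equalization_config()) {
  g <- extract_green(rgb)
  if (diff(range(g)) == 0) {
    # flat image: classify on its single level
    if (g[1] <= config$brightness_low) return("reject_dark")
    if (g[1] >= config$brightness_high) return("reject_bright")
    return("accept")
  }
  roi <- otsu_mask(g)
  mu <- mean(g[roi == 1L])
  if (mu < config$brightness_low) return("reject_dark")
  if (mu > config$brightness_high) return("reject_bright")
  extreme <- roi == 1L & (g < config$extreme_low | g > config$extreme_high)
  if (any(extreme)) {
    lab <- label_components8(extreme * 1L)
    sizes <- tabulate(lab[lab > 0])
    area <- sum(sizes[sizes >= config$lesion_min_area])
    if (area / sum(roi) > config$lesion_area_frac) return("reject_lesion")
  }
  "accept"
}

#' Equalize a fundus image
#'
#' Full quality-equalization pass: green channel -> CLAHE, in parallel
#' green channel -> Otsu foreground, then the enhanced plane is masked to
#' the ROI. Deterministic for a fixed input and configuration.
#'
#' @inheritParams screen_quality
#' @param provenance optional source label stored on the result.
#' @return an `equalized_image` (see [combine_roi()]).
#' @export
equalize <- function(rgb, config = equalization_config(),
                     provenance = NA_character_) {
  if (config$reject_on_quality) {
    dec <- screen_quality(rgb, config)
    if (dec != "accept")
      stop_input("image rejected by quality screen: ", dec)
  }
  g <- extract_green(rgb)
  enhanced <- clahe_enhance(g, config)
  roi <- otsu_mask(g)   # on the raw green channel, not the CLAHE output
  combine_roi(enhanced, roi, provenance)
}
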