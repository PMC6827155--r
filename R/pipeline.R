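# Orchestration: configuration, detector backends, and the end-to-end
# pipeline (synthesize/load -> equalize -> patch dataset -> detect ->
# vessel screening -> evaluation). Each stage writes files that the next
# stage (or a user) can consume independently; a thin command-line wrapper
# in inst/cli exposes the same steps as subcommands.

#' Read a PNG file as a 0-255 raster
#'
#' @param path PNG file.
#' @return matrix (grayscale) or h x w x 3 array (colour), values 0-255.
#' @export
read_raster <- function(path) {
  x <- png::readPNG(path)
  if (length(dim(x)) == 3L && dim(x)[3] > 3L) x <- x[, , 1:3]  # drop alpha
  round(x * 255)
}

#' Write a 0-255 raster to PNG
#'
#' @param raster matrix or h x w x 3 array, values 0-255.
#' @param path output file.
#' @return `path`, invisibly.
#' @export
write_raster <- function(raster, path) {
  png::writePNG(clamp(raster, 0, 255) / 255, path)
  invisible(path)
}

#' Default run configuration
#'
#' Per-module blocks plus the detector-training hyperparameters shipped as
#' defaults (learning rate 0.001, momentum 0.9, gamma 0.1, weight decay
#' 0.0001, batch size 64; the seed/output proposal-box counts belong to the
#' proposal stage of a full-scale detector and are carried for
#' completeness).
#'
#' @return nested list mirroring `inst/extdata/config/default.yaml`.
#' @export
default_config <- function() {
  yaml::read_yaml(system.file("extdata", "config", "default.yaml",
                              package = "maScreen", mustWork = TRUE))
}

merge_config <- function(base, override, path = "") {
  for (key in names(override)) {
    here <- if (nzchar(path)) paste0(path, ".", key) else key
    if (!key %in% names(base))
      stop_input("unknown configuration key: ", here)
    if (is.list(base[[key]]) && is.list(override[[key]]))
      base[[key]] <- merge_config(base[[key]], override[[key]], here)
    else base[[key]] <- override[[key]]
  }
  base
}

#' Load and validate a run configuration
#'
#' Starts from [default_config()] and overlays the given YAML file or list;
#' unknown keys are rejected by name.
#'
#' @param config `NULL` (defaults), a YAML file path, or a nested list of
#'   overrides.
#' @return validated nested configuration list.
#' @export
run_config <- function(config = NULL) {
  base <- default_config()
  if (is.null(config)) return(base)
  if (is.character(config)) config <- yaml::read_yaml(config)
  merge_config(base, config)
}

#' Oracle detector backend built from scene ground truth
#'
#' Emits the scene's true boxes with high class probability (optionally
#' jittered), plus planted false positives: low-probability boxes centred
#' on vessel pixels (the dark-vessel-pixel failure mode that spatial
#' screening exists to remove) and, optionally, boxes far from any vessel.
#' Used to exercise the screening and evaluation stages without a trained
#' network.
#'
#' @param truth a `scene_truth` from [render_scene()].
#' @param p_class_tp class probability assigned to true boxes.
#' @param n_fp_on_vessel number of planted on-vessel false positives.
#' @param p_class_fp class probability of planted false positives.
#' @param fp_size side length of planted false-positive boxes (pixels).
#' @param jitter max uniform perturbation (pixels) of true box corners.
#' @param seed integer seed.
#' @return data.frame with columns `x0, y0, x1, y1, p_class, is_truth`.
#' @export
detector_oracle <- function(truth, p_class_tp = 0.9, n_fp_on_vessel = 5,
                            p_class_fp = 0.4, fp_size = 12, jitter = 0,
                            seed = 1L) {
  with_seed(seed, {
    out <- NULL
    boxes <- boxes_as_matrix(truth$ma_boxes)
    if (nrow(boxes) > 0) {
      jit <- matrix(stats::runif(4 * nrow(boxes), -jitter, jitter),
                    nrow(boxes), 4)
      out <- data.frame(x0 = boxes[, 1] + jit[, 1], y0 = boxes[, 2] + jit[, 2],
                        x1 = boxes[, 3] + jit[, 3], y1 = boxes[, 4] + jit[, 4],
                        p_class = p_class_tp, is_truth = TRUE)
    }
    vpix <- which(truth$vessel_mask != 0)
    if (n_fp_on_vessel > 0 && length(vpix) > 0) {
      h <- nrow(truth$vessel_mask); w <- ncol(truth$vessel_mask)
      pick <- sample(vpix, min(n_fp_on_vessel, length(vpix)))
      cy <- (pick - 1L) %% h; cx <- (pick - 1L) %/% h
      half <- fp_size / 2
      fp <- data.frame(x0 = clamp(cx - half, 0, w - fp_size),
                       y0 = clamp(cy - half, 0, h - fp_size),
                       p_class = p_class_fp, is_truth = FALSE)
      fp$x1 <- fp$x0 + fp_size; fp$y1 <- fp$y0 + fp_size
      out <- rbind(out, fp[, c("x0", "y0", "x1", "y1", "p_class", "is_truth")])
    }
    if (is.null(out))
      out <- data.frame(x0 = numeric(0), y0 = numeric(0), x1 = numeric(0),
                        y1 = numeric(0), p_class = numeric(0),
                        is_truth = logical(0))
    rownames(out) <- NULL
    out
  })
}

scene_spec_from_config <- function(cfg, seed) {
  s <- cfg$synth
  scene_spec(width = s$width, height = s$height,
             fov_radius_frac = s$fov_radius_frac, n_mas = s$n_mas,
             illumination = s$illumination,
             vessel_density = s$vessel_density,
             min_distance = s$min_distance, seed = seed)
}

#' Write a scene and its ground truth to a directory
#'
#' Writes `image.png`, `vessels.png`, `ma_mask.png` and `truth.json`
#' (boxes, sampled distances, diameters, seed).
#'
#' @param truth a `scene_truth`.
#' @param dir output directory (created if missing).
#' @return `dir`, invisibly.
#' @export
write_scene <- function(truth, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  write_raster(truth$image, file.path(dir, "image.png"))
  write_raster(truth$vessel_mask * 255, file.path(dir, "vessels.png"))
  write_raster(truth$ma_mask * 255, file.path(dir, "ma_mask.png"))
  jsonlite::write_json(
    list(ma_boxes = truth$ma_boxes,
         sampled_distances = truth$sampled_distances,
         ma_diameters = truth$ma_diameters,
         seed = truth$spec$seed, illumination = truth$spec$illumination),
    file.path(dir, "truth.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Run the full pipeline on a synthetic scene
#'
#' Renders a scene, screens/equalizes it, builds the VOC patch dataset,
#' runs a detector backend (default: the ground-truth oracle with planted
#' on-vessel false positives), screens candidates against the vessel mask,
#' and evaluates kept detections against ground truth. All intermediate
#' artifacts are written under `out_dir`.
#'
#' @param config see [run_config()].
#' @param out_dir output directory.
#' @param seed global seed (overrides the config's).
#' @param detector detector backend: `function(truth, seed)` returning a
#'   candidate data.frame (see [detector_oracle()]); `NULL` uses the oracle
#'   with the config's planted-false-positive settings.
#' @return invisibly, a list with the evaluation `report`, the screening
#'   table, and artifact paths.
#' @export
run_pipeline <- function(config = NULL, out_dir = tempfile("ma_run_"),
                         seed = NULL, detector = NULL) {
  cfg <- run_config(config)
  if (!is.null(seed)) cfg$seed <- as.integer(seed)
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  spec <- scene_spec_from_config(cfg, cfg$seed)
  truth <- render_scene(spec)
  write_scene(truth, file.path(out_dir, "scene"))

  eq_cfg <- equalization_config(
    clahe_clip_limit = cfg$equalization$clahe_clip_limit,
    clahe_tiles = unlist(cfg$equalization$clahe_tiles),
    brightness_low = cfg$equalization$brightness_low,
    brightness_high = cfg$equalization$brightness_high,
    reject_on_quality = cfg$equalization$reject_on_quality)
  eq <- equalize(truth$image, eq_cfg, provenance = "synthetic")
  write_raster(eq$pixels, file.path(out_dir, "equalized.png"))

  voc_dir <- file.path(out_dir, "voc")
  recs <- build_patches(eq$pixels, truth$ma_mask,
                        window = rep(cfg$voc$window, 2),
                        stride = rep(cfg$voc$stride, 2),
                        min_diameter = cfg$voc$min_diameter,
                        roi_fraction_min = cfg$voc$roi_fraction_min)
  ids <- vapply(recs, function(r) write_voc(r, voc_dir), character(1))
  if (length(ids) >= 2)
    write_split(make_split(ids, cfg$voc$test_fraction, cfg$seed), voc_dir)

  if (is.null(detector))
    detector <- function(truth, seed)
      detector_oracle(truth,
                      p_class_tp = cfg$detector$p_class_tp,
                      n_fp_on_vessel = cfg$detector$n_fp_on_vessel,
                      p_class_fp = cfg$detector$p_class_fp,
                      fp_size = cfg$detector$fp_size, seed = seed)
  cands <- detector(truth, cfg$seed)
  jsonlite::write_json(cands, file.path(out_dir, "detections.json"),
                       auto_unbox = TRUE, digits = NA)

  scr_cfg <- screening_config(c_p = cfg$screening$c_p,
                              alpha = cfg$screening$alpha,
                              beta = cfg$screening$beta,
                              step = cfg$screening$step,
                              vote_threshold = cfg$screening$vote_threshold,
                              on_vessel_zero = cfg$screening$on_vessel_zero)
  screened <- screen(cands[, 1:5], truth$vessel_mask, scr_cfg)
  screened$is_truth <- cands$is_truth
  jsonlite::write_json(screened, file.path(out_dir, "screened.json"),
                       auto_unbox = TRUE, digits = NA)

  kept <- screened[screened$kept, c("x0", "y0", "x1", "y1", "s_t")]
  names(kept)[5] <- "score"
  report <- evaluate(list(scene = kept),
                     list(scene = truth$ma_boxes),
                     iou_threshold = cfg$eval$iou_threshold)
  jsonlite::write_json(report[c("precision", "recall", "f1", "ap",
                                "tp", "fp", "fn")],
                       file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(report = report, screened = screened, truth = truth,
                 out_dir = out_dir, n_patches = length(ids)))
}
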