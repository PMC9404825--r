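#' Pipeline configuration
#'
#' One declarative object holding every stage's settings. The defaults are
#' calibrated for trichrome-stained renal fields in the package's working
#' conditions; as with any staining-based morphometry, the threshold
#' correction factors and bounds are the settings to adapt per image lot.
#'
#' @param unmix_tubules Length-2 character vector `(primary, secondary)` of
#'   stain names for the tubule-detection unmixing stage.
#' @param smooth_sigma Gaussian sigma (pixels) for the tubule stage.
#' @param tubule_filter,interstitium_filter [object_filter()]s for the two
#'   structure-detection stages.
#' @param tubule_threshold,interstitium_threshold,fibrosis_threshold
#'   [threshold_spec()]s for the three thresholding stages.
#' @param unmix_fibrosis Length-2 character vector `(primary, secondary)` for
#'   the collagen unmixing stage.
#' @param gray_weights RGB-to-gray weights (must sum to 1).
#' @param roi_dir Optional directory of per-image ROI YAML files (matched to
#'   images by stem name) listing regions to exclude.
#' @param save_intermediates Write stage images (PNG) next to the results?
#' @param output_dir Output directory for [run_batch()].
#' @param stain_overrides Optional named list of absorbance 3-vectors
#'   overriding the built-in [stain_library()].
#' @return An object of class `pipeline_config`.
#' @export
pipeline_config <- function(unmix_tubules = c("hematoxylin_pas", "pas"),
                            smooth_sigma = 0.5,
                            tubule_filter = object_filter(10, 120, 8, TRUE),
                            tubule_threshold = threshold_spec("otsu", 1, 0.85, 0.97),
                            interstitium_filter = object_filter(2, 30, 8, TRUE),
                            interstitium_threshold = threshold_spec("otsu", 1, 0.60, 0.95),
                            unmix_fibrosis = c("methyl_blue", "ponceau_fuchsin"),
                            fibrosis_threshold = threshold_spec("otsu", 1, 0.20, 0.90),
                            gray_weights = c(0.299, 0.587, 0.114),
                            roi_dir = NULL,
                            save_intermediates = FALSE,
                            output_dir = ".",
                            stain_overrides = NULL) {
  fq_assert(length(unmix_tubules) == 2L && length(unmix_fibrosis) == 2L,
            "fq_parameter_error", "unmix stages need a primary and a secondary stain name")
  fq_assert(inherits(tubule_filter, "object_filter") &&
              inherits(interstitium_filter, "object_filter"),
            "fq_type_error", "filters must be object_filter objects")
  fq_assert(inherits(tubule_threshold, "threshold_spec") &&
              inherits(interstitium_threshold, "threshold_spec") &&
              inherits(fibrosis_threshold, "threshold_spec"),
            "fq_type_error", "thresholds must be threshold_spec objects")
  lib <- stain_library(stain_overrides)
  for (nm in c(unmix_tubules, unmix_fibrosis)) get_stain(nm, lib)  # names must resolve
  structure(list(unmix_tubules = unmix_tubules, smooth_sigma = smooth_sigma,
                 tubule_filter = tubule_filter, tubule_threshold = tubule_threshold,
                 interstitium_filter = interstitium_filter,
                 interstitium_threshold = interstitium_threshold,
                 unmix_fibrosis = unmix_fibrosis,
                 fibrosis_threshold = fibrosis_threshold,
                 gray_weights = gray_weights, roi_dir = roi_dir,
                 save_intermediates = isTRUE(save_intermediates),
                 output_dir = output_dir, stain_library = lib),
            class = "pipeline_config")
}

ts_from_list <- function(x, default) {
  if (is.null(x)) return(default)
  threshold_spec(method = x$method %||% default$method,
                 correction_factor = x$correction_factor %||% default$correction_factor,
                 lower_bound = x$lower_bound %||% default$lower_bound,
                 upper_bound = x$upper_bound %||% default$upper_bound,
                 fixed_value = x$fixed_value %||% default$fixed_value)
}

of_from_list <- function(x, default) {
  if (is.null(x)) return(default)
  object_filter(min_diameter = x$min_diameter %||% default$min_diameter,
                max_diameter = x$max_diameter %||% default$max_diameter,
                connectivity = x$connectivity %||% default$connectivity,
                keep_border = x$keep_border %||% default$keep_border)
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Read a pipeline configuration file
#'
#' YAML with one key per [pipeline_config()] field; nested specs use their
#' own field names, e.g.
#' ```yaml
#' fibrosis_threshold: {method: otsu, correction_factor: 1.2, lower_bound: 0.2}
#' tubule_filter: {min_diameter: 15, max_diameter: 120}
#' ```
#' Missing keys keep their defaults.
#'
#' @param path Path to a YAML config file.
#' @return A `pipeline_config`.
#' @export
read_pipeline_config <- function(path) {
  fq_assert(file.exists(path), "fq_io_error", "cannot read config: no such file '%s'", path)
  x <- yaml::read_yaml(path)
  d <- pipeline_config()
  pipeline_config(
    unmix_tubules = unlist(x$unmix_tubules) %||% d$unmix_tubules,
    smooth_sigma = x$smooth_sigma %||% d$smooth_sigma,
    tubule_filter = of_from_list(x$tubule_filter, d$tubule_filter),
    tubule_threshold = ts_from_list(x$tubule_threshold, d$tubule_threshold),
    interstitium_filter = of_from_list(x$interstitium_filter, d$interstitium_filter),
    interstitium_threshold = ts_from_list(x$interstitium_threshold, d$interstitium_threshold),
    unmix_fibrosis = unlist(x$unmix_fibrosis) %||% d$unmix_fibrosis,
    fibrosis_threshold = ts_from_list(x$fibrosis_threshold, d$fibrosis_threshold),
    gray_weights = unlist(x$gray_weights) %||% d$gray_weights,
    roi_dir = x$roi_dir,
    save_intermediates = x$save_intermediates %||% FALSE,
    output_dir = x$output_dir %||% ".",
    stain_overrides = x$stain_overrides)
}

#' Blend object foreground over an image for visual comparison
#'
#' @param img RGB array.
#' @param mask Logical foreground mask.
#' @param color RGB triple of the overlay colour.
#' @param alpha Blend weight in `[0, 1]`: foreground pixels become
#'   `alpha * color + (1 - alpha) * original`.
#' @return RGB array.
#' @export
overlay_objects <- function(img, mask, color = c(1, 0.1, 0.1), alpha = 0.5) {
  validate_rgb(img)
  validate_mask(mask, image_dims(img), "mask")
  fq_assert(length(color) == 3L && all(color >= 0) && all(color <= 1),
            "fq_parameter_error", "color must be an RGB triple in [0, 1]")
  fq_assert(alpha >= 0 && alpha <= 1, "fq_parameter_error", "alpha must lie in [0, 1]")
  out <- img
  for (k in 1:3) {
    ch <- out[, , k]
    ch[mask] <- alpha * color[k] + (1 - alpha) * ch[mask]
    out[, , k] <- ch
  }
  out
}

#' Run the full fibrosis-quantification pipeline on one image
#'
#' Stage order: (1) unmix the nuclear stain (tubule signal); (2) Gaussian
#' smoothing; (3) identify tubules; (4) invert the smoothed tubule image
#' (kept as an intermediate); (5) mask tubules out of the original;
#' (6) convert to grayscale; (7) mask out any manual ROIs; (8) identify and
#' mask out small normal-interstitium/intratubular bright areas; (9) unmix
#' Methyl Blue against Ponceau-fuchsin on the remaining image; (10) invert
#' the collagen transmission image; (11) threshold and measure the fibrotic
#' area over the full frame.
#'
#' @param img RGB array.
#' @param cfg A [pipeline_config()].
#' @param rois Optional [roi_set()] of regions to exclude.
#' @param image_id Identifier recorded in the result.
#' @param keep_intermediates Keep stage images in the result?
#' @return An object of class `fibrosis_result`: `image_id`, `measurement`
#'   (an `area_measurement`), `fibrosis_threshold_used`, `n_tubules`,
#'   `n_interstitium_objects`, `n_fibrosis_objects`, `fibrosis_mask`, and
#'   optionally `intermediates`.
#' @export
run_pipeline <- function(img, cfg = pipeline_config(), rois = NULL,
                         image_id = "image", keep_intermediates = FALSE) {
  validate_rgb(img)
  fq_assert(inherits(cfg, "pipeline_config"), "fq_type_error", "cfg must be a pipeline_config")
  lib <- cfg$stain_library
  dims <- image_dims(img)
  keep <- if (keep_intermediates || cfg$save_intermediates) list() else NULL

  conc_tub <- unmix_colors(img, cfg$unmix_tubules[1], cfg$unmix_tubules[2], library = lib)
  gray_tub <- concentration_to_gray(conc_tub, "stain")
  smoothed <- smooth_gaussian(gray_tub, cfg$smooth_sigma)
  tubules <- identify_primary_objects(smoothed, cfg$tubule_filter, cfg$tubule_threshold)
  if (!is.null(keep)) {
    keep$unmix_tubules <- gray_tub
    keep$smoothed <- smoothed
    keep$tubules_inverted <- image_math("invert", smoothed)
  } else {
    invisible(image_math("invert", smoothed))   # stage 4 intermediate
  }

  m <- mask_image(img, objects_to_mask(tubules), invert_mask = TRUE)
  rgb_cur <- m$image; validity <- m$validity
  gray_cur <- color_to_gray(rgb_cur, cfg$gray_weights)
  if (!is.null(keep)) keep$tubule_less_gray <- gray_cur

  if (!is.null(rois) && length(rois$polygons)) {
    roi_mask <- rasterize_rois(rois, dims[1], dims[2])
    m <- mask_image(rgb_cur, roi_mask, invert_mask = TRUE, validity = validity)
    rgb_cur <- m$image; validity <- m$validity
    gray_cur <- color_to_gray(rgb_cur, cfg$gray_weights)
  }

  interstitium <- identify_primary_objects(gray_cur, cfg$interstitium_filter,
                                           cfg$interstitium_threshold, validity)
  m <- mask_image(rgb_cur, objects_to_mask(interstitium), invert_mask = TRUE,
                  validity = validity)
  rgb_cur <- m$image; validity <- m$validity

  conc_fib <- unmix_colors(rgb_cur, cfg$unmix_fibrosis[1], cfg$unmix_fibrosis[2],
                           library = lib)
  trans_fib <- concentration_to_gray(conc_fib, "transmission")
  gray_fib <- image_math("invert", trans_fib)
  if (!is.null(keep)) keep$collagen_signal <- gray_fib

  fib <- measure_fibrosis(gray_fib, cfg$fibrosis_threshold, validity)
  fib_objects <- label_components(fib$mask, cfg$tubule_filter$connectivity)
  if (!is.null(keep)) {
    keep$fibrosis_mask <- fib$mask
    keep$overlay <- overlay_objects(img, fib$mask)
  }

  structure(list(image_id = image_id,
                 measurement = fib$measurement,
                 fibrosis_threshold_used = fib$threshold,
                 n_tubules = n_objects(tubules),
                 n_interstitium_objects = n_objects(interstitium),
                 n_fibrosis_objects = n_objects(fib_objects),
                 fibrosis_mask = fib$mask,
                 intermediates = keep),
            class = "fibrosis_result")
}

#' @export
print.fibrosis_result <- function(x, ...) {
  cat(sprintf("<fibrosis result '%s': %.2f%% (threshold %.3f, %d tubule(s) excluded)>\n",
              x$image_id, x$measurement$percent, x$fibrosis_threshold_used, x$n_tubules))
  invisible(x)
}

#' Batch-process images and export a results spreadsheet
#'
#' Processes every image independently and writes `fibrosis_results.csv` to
#' the configured output directory with one row per image. The exported area
#' columns carry the spreadsheet names downstream tooling expects:
#' `AreaOccupied_AreaOccupied_ThresholdFibrosis` (fibrotic pixel count) and
#' `AreaOccupied_TotalArea_ThresholdFibrosis` (frame pixel count); the
#' derived `percent_fibrosis` column is `100 *` their ratio. Failed images
#' are flagged in the `status` column, never dropped.
#'
#' If a ROI directory is configured, an image `stem.ext` is paired with
#' `stem.yaml` (or `stem.yml`) when present.
#'
#' @param input_paths Character vector of image files (at least one).
#' @param cfg A [pipeline_config()].
#' @param verbose Emit a per-image progress message?
#' @return The results data frame, invisibly; also written as CSV.
#' @export
run_batch <- function(input_paths, cfg = pipeline_config(), verbose = FALSE) {
  fq_assert(is.character(input_paths) && length(input_paths) >= 1L,
            "fq_usage_error", "at least one input image path is required")
  fq_assert(inherits(cfg, "pipeline_config"), "fq_type_error", "cfg must be a pipeline_config")
  if (!dir.exists(cfg$output_dir)) {
    ok <- dir.create(cfg$output_dir, recursive = TRUE, showWarnings = FALSE)
    fq_assert(ok, "fq_io_error", "cannot create output directory '%s'", cfg$output_dir)
  }
  rows <- lapply(sort(input_paths), function(path) {
    id <- tools::file_path_sans_ext(basename(path))
    res <- tryCatch({
      img <- read_image(path)
      rois <- NULL
      if (!is.null(cfg$roi_dir)) {
        for (ext in c("yaml", "yml")) {
          rp <- file.path(cfg$roi_dir, paste0(id, ".", ext))
          if (file.exists(rp)) { rois <- read_roi_file(rp); break }
        }
      }
      r <- run_pipeline(img, cfg, rois = rois, image_id = id,
                        keep_intermediates = cfg$save_intermediates)
      if (cfg$save_intermediates) {
        for (nm in names(r$intermediates)) {
          im <- r$intermediates[[nm]]
          if (is.logical(im)) im <- im * 1
          write_image(im, file.path(cfg$output_dir, sprintf("%s_%s.png", id, nm)))
        }
      }
      if (verbose) message(sprintf("%s: %.2f%% fibrosis (threshold %.3f)",
                                   id, r$measurement$percent, r$fibrosis_threshold_used))
      data.frame(image_id = id,
                 AreaOccupied_AreaOccupied_ThresholdFibrosis = r$measurement$area_occupied,
                 AreaOccupied_TotalArea_ThresholdFibrosis = r$measurement$total_area,
                 percent_fibrosis = r$measurement$percent,
                 fibrosis_threshold_used = r$fibrosis_threshold_used,
                 n_tubules = r$n_tubules,
                 status = "ok")
    }, error = function(e) {
      if (verbose) message(sprintf("%s: FAILED (%s)", id, conditionMessage(e)))
      data.frame(image_id = id,
                 AreaOccupied_AreaOccupied_ThresholdFibrosis = NA_real_,
                 AreaOccupied_TotalArea_ThresholdFibrosis = NA_real_,
                 percent_fibrosis = NA_real_, fibrosis_threshold_used = NA_real_,
                 n_tubules = NA_integer_, status = "failed")
    })
    res
  })
  out <- do.call(rbind, rows)
  utils::write.csv(out, file.path(cfg$output_dir, "fibrosis_results.csv"),
                   row.names = FALSE)
  invisible(out)
}
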