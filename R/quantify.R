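#' Percent fibrosis formula
#'
#' `%fibrosis = (area occupied by fibrosis / total area) * 100`.
#'
#' @param area_occupied Foreground (fibrotic) pixel count.
#' @param total_area Total frame pixel count, `> 0`.
#' @return Percent in `[0, 100]`.
#' @export
percent_fibrosis <- function(area_occupied, total_area) {
  fq_assert(is.numeric(total_area) && length(total_area) == 1L && total_area > 0,
            "fq_division_error", "total_area must be positive")
  fq_assert(is.numeric(area_occupied) && length(area_occupied) == 1L &&
              area_occupied >= 0 && area_occupied <= total_area,
            "fq_consistency_error",
            "area_occupied must lie in [0, total_area] (got %s of %s)",
            format(area_occupied), format(total_area))
  100 * area_occupied / total_area
}

new_area_measurement <- function(area_occupied, total_area) {
  structure(list(area_occupied = as.numeric(area_occupied),
                 total_area = as.numeric(total_area),
                 percent = percent_fibrosis(area_occupied, total_area)),
            class = "area_measurement")
}

#' @export
print.area_measurement <- function(x, ...) {
  cat(sprintf("<area measurement: %g / %g pixels = %.2f%%>\n",
              x$area_occupied, x$total_area, x$percent))
  invisible(x)
}

#' Measure the area occupied by a binary mask
#'
#' The area accounting of the pipeline's final stage: `area_occupied` is the
#' foreground pixel count and `total_area` is the full frame `H * W` — not
#' the valid-pixel count, so that excluded structures (tubules, manual ROIs)
#' still dilute the percentage.
#'
#' @param mask Logical foreground mask.
#' @return An `area_measurement`: `area_occupied`, `total_area`, `percent`.
#' @export
measure_area_occupied <- function(mask) {
  validate_mask(mask, what = "mask")
  new_area_measurement(sum(mask), length(mask))
}

#' Threshold the collagen signal and measure the fibrotic area
#'
#' Computes a threshold from the valid pixels, binarizes, and reports the
#' area occupied over the full frame together with the threshold used and
#' the binary fibrosis mask.
#'
#' @param img Grayscale matrix (collagen signal bright).
#' @param spec A [threshold_spec()].
#' @param validity Validity mask (`NULL` = all valid).
#' @return A list: `measurement` (an `area_measurement`), `threshold` and
#'   `mask`.
#' @export
measure_fibrosis <- function(img, spec, validity = NULL) {
  t <- compute_threshold(img, spec, validity)
  mask <- apply_threshold(img, t, validity)
  list(measurement = measure_area_occupied(mask), threshold = t, mask = mask)
}

#' Reference (single-channel interval threshold) measurement
#'
#' Specification of the simple cross-check measurement: extract one RGB
#' channel and count the pixels whose value lies within a closed
#' `[min_threshold, max_threshold]` interval, as done interactively in
#' general-purpose image software. On trichrome images the green channel
#' separates blue collagen (low green transmission) from the red
#' counterstain.
#'
#' @param channel `"red"`, `"green"` or `"blue"`.
#' @param min_threshold,max_threshold Interval bounds in `[0, 1]`, ordered;
#'   both ends inclusive.
#' @return An object of class `reference_spec`.
#' @export
reference_spec <- function(channel = c("green", "red", "blue"),
                           min_threshold = 0, max_threshold = 0.58) {
  channel <- match.arg(channel)
  fq_assert(min_threshold >= 0 && max_threshold <= 1 && min_threshold <= max_threshold,
            "fq_parameter_error", "need 0 <= min_threshold <= max_threshold <= 1")
  structure(list(channel = channel, min_threshold = min_threshold,
                 max_threshold = max_threshold),
            class = "reference_spec")
}

#' Measure fibrotic area with the reference channel-threshold procedure
#'
#' @param img RGB array.
#' @param spec A [reference_spec()].
#' @return An `area_measurement` over the full frame.
#' @export
reference_measure <- function(img, spec = reference_spec()) {
  validate_rgb(img)
  fq_assert(inherits(spec, "reference_spec"), "fq_type_error", "spec must be a reference_spec")
  k <- match(spec$channel, c("red", "green", "blue"))
  ch <- img[, , k]
  sel <- ch >= spec$min_threshold & ch <= spec$max_threshold
  new_area_measurement(sum(sel), length(ch))
}
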