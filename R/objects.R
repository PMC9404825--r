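#' Threshold specification
#'
#' Governs foreground/background separation. With `method = "otsu"` the
#' threshold is computed from a 256-bin histogram of the valid (unmasked)
#' pixels by minimizing the weighted intra-class variance; with
#' `method = "fixed"` the given value is used. In both cases the value is
#' multiplied by `correction_factor` and then clamped to
#' `[lower_bound, upper_bound]` — the correction factor is the main knob for
#' adapting the pipeline to a new staining lot.
#'
#' @param method `"otsu"` or `"fixed"`.
#' @param correction_factor Positive multiplier applied to the computed
#'   threshold before clamping.
#' @param lower_bound,upper_bound Clamp bounds in `[0, 1]`, ordered.
#' @param fixed_value Threshold used when `method = "fixed"`.
#' @return An object of class `threshold_spec`.
#' @export
threshold_spec <- function(method = c("otsu", "fixed"), correction_factor = 1,
                           lower_bound = 0, upper_bound = 1, fixed_value = 0.5) {
  method <- match.arg(method)
  fq_assert(is.numeric(correction_factor) && correction_factor > 0,
            "fq_parameter_error", "correction_factor must be positive")
  fq_assert(lower_bound >= 0 && upper_bound <= 1 && lower_bound <= upper_bound,
            "fq_parameter_error", "bounds must satisfy 0 <= lower <= upper <= 1")
  fq_assert(fixed_value >= 0 && fixed_value <= 1, "fq_parameter_error",
            "fixed_value must lie in [0, 1]")
  structure(list(method = method, correction_factor = correction_factor,
                 lower_bound = lower_bound, upper_bound = upper_bound,
                 fixed_value = fixed_value),
            class = "threshold_spec")
}

#' Object size/connectivity filter
#'
#' Objects are retained iff their equivalent-circle diameter
#' `d = 2 * sqrt(area / pi)` lies within `[min_diameter, max_diameter]`.
#' Border-touching objects are kept by default: a tubule partially in frame
#' must still be excluded from the fibrosis area.
#'
#' @param min_diameter,max_diameter Diameter bounds in pixels, `0 < min <= max`.
#' @param connectivity Pixel connectivity for object formation, 4 or 8.
#' @param keep_border Keep objects touching the frame border?
#' @return An object of class `object_filter`.
#' @export
object_filter <- function(min_diameter = 1, max_diameter = Inf,
                          connectivity = 8, keep_border = TRUE) {
  fq_assert(is.numeric(min_diameter) && is.numeric(max_diameter) &&
              min_diameter > 0 && min_diameter <= max_diameter,
            "fq_parameter_error", "need 0 < min_diameter <= max_diameter")
  fq_assert(connectivity %in% c(4, 8), "fq_parameter_error",
            "connectivity must be 4 or 8")
  structure(list(min_diameter = min_diameter, max_diameter = max_diameter,
                 connectivity = as.integer(connectivity),
                 keep_border = isTRUE(keep_border)),
            class = "object_filter")
}

#' Mask-aware Gaussian smoothing
#'
#' Smooths a grayscale image with a Gaussian kernel using normalized
#' (mask-aware) convolution: the image is convolved weighted by the validity
#' mask and renormalized by the convolved mask, so invalid pixels contribute
#' nothing and constants are preserved up to the frame border. Output pixels
#' with no valid support are 0.
#'
#' @param img Grayscale matrix.
#' @param sigma Gaussian standard deviation in pixels, `> 0`. The kernel is
#'   truncated at 4 sigma.
#' @param validity Validity mask (`NULL` = all valid).
#' @return Smoothed grayscale matrix, clipped to `[0, 1]`.
#' @export
smooth_gaussian <- function(img, sigma, validity = NULL) {
  validate_gray(img)
  fq_assert(is.numeric(sigma) && length(sigma) == 1L && sigma > 0,
            "fq_parameter_error", "sigma must be positive")
  v <- resolve_validity(validity, img)
  r <- max(1L, ceiling(4 * sigma))
  g <- exp(-(seq(-r, r))^2 / (2 * sigma^2))
  band <- function(n) {
    B <- matrix(0, n, n)
    for (k in seq(-r, r)) {
      idx <- which(seq_len(n) + k >= 1 & seq_len(n) + k <= n)
      B[cbind(idx, idx + k)] <- g[k + r + 1]
    }
    B
  }
  Bh <- band(nrow(img)); Bw <- band(ncol(img))
  vm <- v * 1
  num <- Bh %*% (img * vm) %*% Bw   # Bw symmetric
  den <- Bh %*% vm %*% Bw
  out <- ifelse(den > 0, num / den, 0)
  out[!v] <- 0
  clamp01(out)
}

# bin index in 0..255 for intensities in [0,1]
.hist_bin <- function(x) pmin(floor(x * 256), 255)

#' Compute a threshold from the valid pixels of an image
#'
#' Otsu's method on a fixed 256-bin histogram of the valid pixels: the bin
#' edge minimizing the weighted intra-class variance is selected (ties break
#' toward the lowest threshold). The result is multiplied by the spec's
#' correction factor and clamped to its bounds. A constant valid region is a
#' degenerate case and yields the constant itself (then corrected/clamped),
#' so a featureless field thresholds to empty foreground under the strict
#' inequality of [apply_threshold()].
#'
#' @param img Grayscale matrix.
#' @param spec A [threshold_spec()].
#' @param validity Validity mask (`NULL` = all valid).
#' @return Threshold value in `[0, 1]`.
#' @export
compute_threshold <- function(img, spec, validity = NULL) {
  validate_gray(img)
  fq_assert(inherits(spec, "threshold_spec"), "fq_type_error", "spec must be a threshold_spec")
  v <- resolve_validity(validity, img)
  finish <- function(t0) {
    min(max(t0 * spec$correction_factor, spec$lower_bound), spec$upper_bound)
  }
  if (spec$method == "fixed") return(finish(spec$fixed_value))
  vals <- img[v]
  fq_assert(length(vals) > 0L, "fq_empty_input_error",
            "no valid pixels to compute a threshold from")
  if (max(vals) == min(vals)) return(finish(vals[1]))
  counts <- tabulate(.hist_bin(vals) + 1L, nbins = 256L)
  centers <- (seq_len(256L) - 0.5) / 256
  w <- counts / sum(counts)
  # cumulative moments over splits after bin k (k = 1..255)
  cw1 <- cumsum(w)[1:255]
  cm1 <- cumsum(w * centers)[1:255]
  cq1 <- cumsum(w * centers^2)[1:255]
  w2 <- 1 - cw1
  m1 <- ifelse(cw1 > 0, cm1 / cw1, 0)
  tot_m <- sum(w * centers); tot_q <- sum(w * centers^2)
  m2 <- ifelse(w2 > 0, (tot_m - cm1) / w2, 0)
  var1 <- ifelse(cw1 > 0, cq1 / cw1 - m1^2, 0)
  var2 <- ifelse(w2 > 0, (tot_q - cq1) / w2 - m2^2, 0)
  objective <- cw1 * var1 + w2 * var2
  k <- which.min(objective)          # lowest split on ties
  finish(k / 256)
}

#' Apply a threshold to the valid pixels of an image
#'
#' Foreground = valid pixels strictly greater than `t`; invalid pixels are
#' always background. The result is the binary image with foreground white
#' (1) and background black (0).
#'
#' @param img Grayscale matrix.
#' @param t Threshold in `[0, 1]`.
#' @param validity Validity mask (`NULL` = all valid).
#' @return Logical foreground mask.
#' @export
apply_threshold <- function(img, t, validity = NULL) {
  validate_gray(img)
  fq_assert(is.numeric(t) && length(t) == 1L && t >= 0 && t <= 1,
            "fq_parameter_error", "threshold must lie in [0, 1]")
  v <- resolve_validity(validity, img)
  (img > t) & v
}

#' Label connected foreground components
#'
#' Maximal connected foreground regions under 4- or 8-connectivity receive
#' distinct integer labels `1..N`, numbered in raster-scan (row-major) order
#' of each region's first pixel. Label 0 is background.
#'
#' @param mask Logical foreground mask.
#' @param connectivity 4 or 8.
#' @return Integer `H x W` label matrix with attribute `n_objects`.
#' @export
label_components <- function(mask, connectivity = 8) {
  validate_mask(mask, what = "mask")
  fq_assert(connectivity %in% c(4, 8), "fq_parameter_error", "connectivity must be 4 or 8")
  H <- nrow(mask); W <- ncol(mask)
  lab <- matrix(0L, H, W)
  fg <- which(mask)                           # column-major linear indices
  if (length(fg)) {
    rows <- ((fg - 1L) %% H) + 1L
    cols <- ((fg - 1L) %/% H) + 1L
    edge_to <- function(dr, dc) {
      ok <- rows + dr >= 1L & rows + dr <= H & cols + dc >= 1L & cols + dc <= W
      to <- fg[ok] + dr + dc * H
      keep <- mask[to]
      cbind(fg[ok][keep], to[keep])
    }
    shifts <- list(c(1L, 0L), c(0L, 1L))
    if (connectivity == 8) shifts <- c(shifts, list(c(1L, 1L), c(-1L, 1L)))
    edges <- do.call(rbind, lapply(shifts, function(s) edge_to(s[1], s[2])))
    gr <- igraph::graph_from_data_frame(
      data.frame(from = as.character(edges[, 1]), to = as.character(edges[, 2])),
      directed = FALSE,
      vertices = data.frame(name = as.character(fg)))
    comp <- igraph::components(gr)$membership
    pix <- as.integer(names(comp))
    # renumber components in raster-scan order of their first pixel
    rscan <- order(((pix - 1L) %% H), ((pix - 1L) %/% H))   # row-major order
    first_seen <- comp[rscan][!duplicated(comp[rscan])]
    relabel <- integer(max(comp)); relabel[first_seen] <- seq_along(first_seen)
    lab[pix] <- relabel[comp]
  }
  attr(lab, "n_objects") <- length(unique(lab[lab > 0L]))
  lab
}

#' Number of objects in a label map
#' @param labels Integer label matrix from [label_components()].
#' @return Object count.
#' @export
n_objects <- function(labels) {
  n <- attr(labels, "n_objects")
  if (is.null(n)) n <- length(setdiff(unique(as.integer(labels)), 0L))
  n
}

#' Convert a label map to a foreground mask
#' @param labels Integer label matrix.
#' @return Logical mask, `TRUE` wherever the label is positive.
#' @export
objects_to_mask <- function(labels) {
  fq_assert(is.matrix(labels) && is.numeric(labels), "fq_type_error",
            "labels must be an integer matrix")
  labels > 0L
}

#' Measure labeled objects
#'
#' @param labels Integer label matrix.
#' @return A data frame with one row per object: `label`, `area` (pixels),
#'   `centroid_x`, `centroid_y` (0-based pixel-center coordinates) and
#'   `equiv_diameter` (`2 * sqrt(area / pi)`).
#' @export
measure_objects <- function(labels) {
  fq_assert(is.matrix(labels) && is.numeric(labels), "fq_type_error",
            "labels must be an integer matrix")
  idx <- which(labels > 0L)
  if (!length(idx)) {
    return(data.frame(label = integer(), area = integer(),
                      centroid_x = numeric(), centroid_y = numeric(),
                      equiv_diameter = numeric()))
  }
  H <- nrow(labels)
  lb <- as.integer(labels[idx])
  rows0 <- ((idx - 1L) %% H)        # 0-based row
  cols0 <- ((idx - 1L) %/% H)       # 0-based col
  area <- tabulate(lb)
  labs <- which(area > 0L)
  cx <- vapply(split(cols0 + 0.5, lb), mean, 0)
  cy <- vapply(split(rows0 + 0.5, lb), mean, 0)
  data.frame(label = labs, area = area[labs],
             centroid_x = as.numeric(cx), centroid_y = as.numeric(cy),
             equiv_diameter = 2 * sqrt(area[labs] / pi), row.names = NULL)
}

#' Identify primary objects by thresholding and size filtering
#'
#' The automatic structure-detection stage: compute a threshold on the valid
#' pixels, binarize, label connected components, discard objects whose
#' equivalent-circle diameter falls outside the filter's range (and
#' border-touching objects if `keep_border` is `FALSE`), and relabel the
#' survivors contiguously from 1 in raster-scan order.
#'
#' @param img Grayscale matrix (objects bright).
#' @param filter An [object_filter()].
#' @param spec A [threshold_spec()].
#' @param validity Validity mask (`NULL` = all valid).
#' @return Integer label matrix with attributes `n_objects` and
#'   `threshold_used`.
#' @export
identify_primary_objects <- function(img, filter, spec, validity = NULL) {
  fq_assert(inherits(filter, "object_filter"), "fq_type_error", "filter must be an object_filter")
  t <- compute_threshold(img, spec, validity)
  mask <- apply_threshold(img, t, validity)
  lab <- label_components(mask, filter$connectivity)
  meas <- measure_objects(lab)
  keep <- meas$label[meas$equiv_diameter >= filter$min_diameter &
                       meas$equiv_diameter <= filter$max_diameter]
  if (!filter$keep_border && length(keep)) {
    border <- unique(c(lab[1, ], lab[nrow(lab), ], lab[, 1], lab[, ncol(lab)]))
    keep <- setdiff(keep, border)
  }
  out <- matrix(0L, nrow(lab), ncol(lab))
  if (length(keep)) {
    relabel <- integer(max(lab)); relabel[sort(keep)] <- seq_along(keep)
    pos <- lab > 0L & lab %in% keep
    out[pos] <- relabel[lab[pos]]
  }
  attr(out, "n_objects") <- length(keep)
  attr(out, "threshold_used") <- t
  out
}
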