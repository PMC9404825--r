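#' @title Raster conventions
#' @description
#' Images are plain base-R arrays in a fixed convention used throughout the
#' package:
#'
#' * an RGB image is an `H x W x 3` numeric array with values in `[0, 1]`;
#' * a grayscale image is an `H x W` numeric matrix in `[0, 1]`;
#' * a binary mask is an `H x W` logical matrix (`TRUE` = selected);
#' * a validity mask is an `H x W` logical matrix (`TRUE` = the pixel
#'   participates in statistics); it defaults to all-`TRUE` and is intersected
#'   (logical AND) at every masking stage.
#'
#' Pixel coordinates are 0-based with the origin at the top-left corner,
#' `x` = column and `y` = row; the center of pixel `(row r, col c)` is at
#' `(x = c + 0.5, y = r + 0.5)`.
#'
#' @name raster-conventions
NULL

is_rgb_image <- function(x) {
  is.array(x) && length(dim(x)) == 3L && dim(x)[3] == 3L && is.numeric(x)
}

is_gray_image <- function(x) is.matrix(x) && is.numeric(x)

validate_rgb <- function(img, what = "image") {
  fq_assert(is_rgb_image(img), "fq_type_error", "%s must be an H x W x 3 numeric array", what)
  fq_assert(all(is.finite(img)) && min(img) >= 0 && max(img) <= 1,
            "fq_range_error", "%s must be finite and within [0, 1]", what)
  invisible(img)
}

validate_gray <- function(img, what = "image") {
  fq_assert(is_gray_image(img), "fq_type_error", "%s must be an H x W numeric matrix", what)
  fq_assert(all(is.finite(img)) && min(img) >= 0 && max(img) <= 1,
            "fq_range_error", "%s must be finite and within [0, 1]", what)
  invisible(img)
}

validate_mask <- function(mask, dims = NULL, what = "mask") {
  fq_assert(is.matrix(mask) && is.logical(mask), "fq_type_error",
            "%s must be an H x W logical matrix", what)
  fq_assert(!anyNA(mask), "fq_type_error", "%s must not contain NA", what)
  if (!is.null(dims)) {
    fq_assert(identical(dim(mask), as.integer(dims)), "fq_shape_error",
              "%s has shape %d x %d, expected %d x %d",
              what, nrow(mask), ncol(mask), dims[1], dims[2])
  }
  invisible(mask)
}

image_dims <- function(img) {
  d <- dim(img)
  c(d[1], d[2])
}

full_validity <- function(img) {
  d <- image_dims(img)
  matrix(TRUE, d[1], d[2])
}

resolve_validity <- function(validity, img) {
  if (is.null(validity)) return(full_validity(img))
  validate_mask(validity, image_dims(img), "validity")
}

clamp01 <- function(x) pmin(pmax(x, 0), 1)

#' Read an image file as an RGB array
#'
#' Decodes a PNG, JPEG or TIFF raster and normalizes it to the package's
#' `H x W x 3` convention with intensities in `[0, 1]`. Integer samples are
#' divided by the maximum representable value for their bit depth (255 for
#' 8-bit, 65535 for 16-bit). Grayscale inputs are replicated to three
#' channels; an alpha channel is dropped.
#'
#' @param path Path to an image file (`.png`, `.jpg`/`.jpeg`, `.tif`/`.tiff`).
#' @return An `H x W x 3` numeric array in `[0, 1]`.
#' @export
read_image <- function(path) {
  fq_assert(file.exists(path), "fq_io_error", "cannot read image: no such file '%s'", path)
  img <- tryCatch(EBImage::readImage(path),
                  error = function(e) fq_stop("fq_io_error", "failed to decode '%s': %s",
                                              path, conditionMessage(e)))
  a <- EBImage::imageData(img)   # EBImage stores width x height [x channels]
  if (length(dim(a)) == 2L) {
    a <- array(rep(t(a), 3L), dim = c(ncol(a), nrow(a), 3L))  # already transposed
    return(validate_rgb(clamp01(a), path))
  }
  nc <- dim(a)[3]
  fq_assert(nc %in% c(3L, 4L), "fq_format_error",
            "'%s' has %d channels; expected 1, 3 or 4", path, nc)
  out <- array(0, dim = c(dim(a)[2], dim(a)[1], 3L))
  for (k in 1:3) out[, , k] <- t(a[, , k])
  validate_rgb(clamp01(out), path)
}

#' Write an image to a lossless PNG file
#'
#' Accepts either an RGB array or a grayscale matrix in the package
#' convention. All intermediate and overlay output in the pipeline is PNG.
#'
#' @param img RGB array or grayscale matrix, values in `[0, 1]`.
#' @param path Output path; the `.png` format is implied by the extension.
#' @return `path`, invisibly.
#' @export
write_image <- function(img, path) {
  if (is_rgb_image(img)) {
    validate_rgb(img)
    a <- array(0, dim = c(dim(img)[2], dim(img)[1], 3L))
    for (k in 1:3) a[, , k] <- t(img[, , k])
    e <- EBImage::Image(a, colormode = "Color")
  } else {
    validate_gray(img)
    e <- EBImage::Image(t(img), colormode = "Grayscale")
  }
  EBImage::writeImage(e, path)
  invisible(path)
}

#' Convert an RGB image to grayscale by channel weights
#'
#' @param img RGB array.
#' @param weights Three non-negative channel weights summing to 1. The default
#'   is the Rec. 601 luminance triple.
#' @return Grayscale matrix.
#' @export
color_to_gray <- function(img, weights = c(0.299, 0.587, 0.114)) {
  validate_rgb(img)
  fq_assert(length(weights) == 3L && all(is.finite(weights)) && all(weights >= 0),
            "fq_parameter_error", "weights must be 3 non-negative numbers")
  fq_assert(abs(sum(weights) - 1) < 1e-8, "fq_parameter_error",
            "weights must sum to 1 (got %g)", sum(weights))
  g <- img[, , 1] * weights[1] + img[, , 2] * weights[2] + img[, , 3] * weights[3]
  clamp01(g)
}

#' Pixelwise arithmetic on grayscale images
#'
#' Mirrors the elementary image-math stage of the pipeline: `invert` computes
#' `1 - a`; the binary operations combine `a` with a second image or a scalar
#' pixel by pixel. Division by zero maps to 0.
#'
#' @param op One of `"invert"`, `"add"`, `"subtract"`, `"multiply"`, `"divide"`.
#' @param a Grayscale matrix.
#' @param b Second operand for binary ops: grayscale matrix of the same shape,
#'   or a single number. Ignored for `invert`.
#' @param clamp If `TRUE` (default) the result is clipped to `[0, 1]`.
#' @return Numeric matrix (clipped to `[0, 1]` when `clamp` is `TRUE`).
#' @export
image_math <- function(op = c("invert", "add", "subtract", "multiply", "divide"),
                       a, b = NULL, clamp = TRUE) {
  op <- match.arg(op)
  validate_gray(a, "a")
  if (op == "invert") {
    out <- 1 - a
  } else {
    if (is.matrix(b)) {
      fq_assert(identical(dim(a), dim(b)), "fq_shape_error",
                "operand shapes differ: %d x %d vs %d x %d",
                nrow(a), ncol(a), nrow(b), ncol(b))
    } else {
      fq_assert(is.numeric(b) && length(b) == 1L && is.finite(b),
                "fq_parameter_error", "b must be a matrix or a finite scalar")
    }
    out <- switch(op,
      add      = a + b,
      subtract = a - b,
      multiply = a * b,
      divide   = {
        r <- a / b
        r[!is.finite(r)] <- 0
        r
      })
  }
  if (clamp) out <- clamp01(out)
  out
}

#' Mask an image and track pixel validity
#'
#' Pixels where `mask` (xor `invert_mask`) is `FALSE` are set to zero and
#' marked invalid; retained pixels are unchanged. Validity is intersected with
#' the incoming validity mask so that successive maskings compose, and
#' downstream threshold statistics are computed on unmasked pixels only.
#'
#' @param img RGB array or grayscale matrix.
#' @param mask Logical selection mask of the image's shape.
#' @param invert_mask If `TRUE`, keep pixels where `mask` is `FALSE`.
#' @param validity Incoming validity mask (`NULL` = all valid).
#' @return A list with elements `image` (same kind as `img`) and `validity`.
#' @export
mask_image <- function(img, mask, invert_mask = FALSE, validity = NULL) {
  dims <- image_dims(img)
  validate_mask(mask, dims, "mask")
  validity <- if (is.null(validity)) matrix(TRUE, dims[1], dims[2])
              else validate_mask(validity, dims, "validity")
  keep <- if (invert_mask) !mask else mask
  out <- img
  if (is_rgb_image(img)) {
    for (k in 1:3) {
      ch <- out[, , k]
      ch[!keep] <- 0
      out[, , k] <- ch
    }
  } else {
    validate_gray(img)
    out[!keep] <- 0
  }
  list(image = out, validity = validity & keep)
}

#' Construct a region-of-interest set
#'
#' A declarative replacement for interactive freehand selection: a list of
#' polygons (each an `n x 2` matrix of `(x, y)` pixel coordinates) naming
#' areas to exclude from analysis, e.g. glomeruli or over-stained regions.
#'
#' @param polygons List of `n x 2` numeric matrices (columns `x`, `y`),
#'   each with at least 3 vertices. Vertices may lie outside the frame; they
#'   are clipped at rasterization.
#' @param names Optional character vector of polygon names.
#' @return An object of class `roi_set`.
#' @export
roi_set <- function(polygons = list(), names = NULL) {
  polygons <- lapply(seq_along(polygons), function(i) {
    p <- polygons[[i]]
    p <- as.matrix(p)
    fq_assert(is.numeric(p) && ncol(p) == 2L, "fq_format_error",
              "polygon %d must be an n x 2 numeric matrix", i)
    fq_assert(nrow(p) >= 3L, "fq_format_error",
              "polygon %d has %d vertices; at least 3 required", i, nrow(p))
    fq_assert(all(is.finite(p)), "fq_format_error", "polygon %d has non-finite vertices", i)
    dimnames(p) <- list(NULL, c("x", "y"))
    p
  })
  if (!is.null(names)) names(polygons) <- names
  structure(list(polygons = polygons), class = "roi_set")
}

#' @export
print.roi_set <- function(x, ...) {
  cat(sprintf("<roi_set: %d polygon(s)>\n", length(x$polygons)))
  invisible(x)
}

#' Read a region-of-interest file
#'
#' ROI files are plain YAML listing named polygons as vertex coordinate
#' pairs, one file per image, matched to the image by stem name:
#' ```yaml
#' rois:
#'   - name: glomerulus_1
#'     vertices: [[10.5, 20.0], [40.0, 22.5], [25.0, 60.0]]
#' ```
#'
#' @param path Path to a ROI YAML file.
#' @return An object of class [roi_set()].
#' @export
read_roi_file <- function(path) {
  fq_assert(file.exists(path), "fq_io_error", "cannot read ROI file: no such file '%s'", path)
  doc <- yaml::read_yaml(path)
  entries <- doc$rois
  fq_assert(is.list(entries) || is.null(entries), "fq_format_error",
            "'%s': top-level key 'rois' must be a sequence", path)
  polys <- lapply(entries, function(e) {
    v <- e$vertices
    fq_assert(!is.null(v), "fq_format_error", "'%s': ROI entry lacks 'vertices'", path)
    do.call(rbind, lapply(v, function(xy) as.numeric(xy)))
  })
  nms <- vapply(entries, function(e) if (is.null(e$name)) "" else as.character(e$name), "")
  roi_set(polys, names = nms)
}

#' Rasterize ROI polygons to a binary mask
#'
#' A pixel is selected iff its center (`col + 0.5`, `row + 0.5` in 0-based
#' coordinates) lies inside any polygon under the even-odd rule. Polygons
#' extending beyond the frame are effectively clipped.
#'
#' @param rois A [roi_set()].
#' @param H,W Frame height and width in pixels.
#' @return `H x W` logical mask.
#' @export
rasterize_rois <- function(rois, H, W) {
  fq_assert(inherits(rois, "roi_set"), "fq_type_error", "rois must be a roi_set")
  fq_assert(H >= 1 && W >= 1, "fq_parameter_error", "frame must be at least 1 x 1")
  mask <- matrix(FALSE, H, W)
  if (length(rois$polygons) == 0L) return(mask)
  xc <- rep(seq_len(W) - 0.5, each = H)   # column-major: matches matrix layout
  yc <- rep(seq_len(H) - 0.5, times = W)
  for (p in rois$polygons) {
    inside <- rep(FALSE, H * W)
    n <- nrow(p)
    j <- n
    for (i in seq_len(n)) {
      x1 <- p[j, 1]; y1 <- p[j, 2]; x2 <- p[i, 1]; y2 <- p[i, 2]
      crosses <- which((y1 > yc) != (y2 > yc))
      if (length(crosses)) {
        xint <- x1 + (yc[crosses] - y1) * (x2 - x1) / (y2 - y1)
        flip <- crosses[xc[crosses] < xint]
        inside[flip] <- !inside[flip]
      }
      j <- i
    }
    mask <- mask | matrix(inside, H, W)
  }
  mask
}
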