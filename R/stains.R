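#' Construct a stain absorbance vector
#'
#' A stain is characterized by its per-channel optical densities (R, G, B)
#' per unit concentration under the Beer-Lambert model. Vectors are
#' normalized to unit Euclidean length, the convention of the colour
#' deconvolution literature, so that a concentration of `c` means an optical
#' density of `c` along the stain's direction.
#'
#' @param name Stain name.
#' @param absorbance Three non-negative absorbances (R, G, B); any positive
#'   scale is accepted and normalized away.
#' @return An object of class `stain_vector` with fields `name` and
#'   `absorbance` (unit norm).
#' @export
stain_vector <- function(name, absorbance) {
  fq_assert(is.character(name) && length(name) == 1L && nzchar(name),
            "fq_parameter_error", "stain name must be a non-empty string")
  a <- as.numeric(absorbance)
  fq_assert(length(a) == 3L && all(is.finite(a)) && all(a >= 0),
            "fq_parameter_error", "absorbance must be 3 finite non-negative numbers")
  nrm <- sqrt(sum(a^2))
  fq_assert(nrm > 0, "fq_parameter_error", "absorbance must have at least one positive component")
  structure(list(name = name, absorbance = a / nrm), class = "stain_vector")
}

#' @export
print.stain_vector <- function(x, ...) {
  cat(sprintf("<stain '%s': OD (R, G, B) = %.3f, %.3f, %.3f>\n",
              x$name, x$absorbance[1], x$absorbance[2], x$absorbance[3]))
  invisible(x)
}

# Default absorbance triples. Hematoxylin and the hematoxylin+PAS combination
# follow the standard published colour-deconvolution values; Methyl Blue is a
# blue-transmitting anionic dye (smallest absorbance in the blue channel) and
# Ponceau-fuchsin a red-transmitting counterstain (smallest in red). All are
# overridable: pass custom entries to the functions that take stains.
.default_stains <- list(
  hematoxylin      = c(0.644, 0.717, 0.267),
  pas              = c(0.175, 0.972, 0.155),
  hematoxylin_pas  = c(0.553, 0.754, 0.354),
  methyl_blue      = c(0.799, 0.591, 0.105),
  ponceau_fuchsin  = c(0.100, 0.737, 0.666)
)

#' Built-in stain library
#'
#' Named absorbance vectors for the dyes involved in Masson's-trichrome renal
#' morphometry: `hematoxylin` (nuclei), `pas`, `hematoxylin_pas` (the
#' combined primary used for tubule detection), `methyl_blue` (collagen) and
#' `ponceau_fuchsin` (red cytoplasm counterstain). Each entry is unit-norm.
#'
#' @param overrides Optional named list of 3-vectors replacing or extending
#'   the defaults.
#' @return Named list of [stain_vector()] objects.
#' @export
stain_library <- function(overrides = NULL) {
  vals <- .default_stains
  if (!is.null(overrides)) {
    fq_assert(is.list(overrides) && !is.null(names(overrides)),
              "fq_parameter_error", "overrides must be a named list")
    for (nm in names(overrides)) vals[[nm]] <- overrides[[nm]]
  }
  out <- lapply(names(vals), function(nm) stain_vector(nm, vals[[nm]]))
  names(out) <- names(vals)
  out
}

#' Look up a stain by name
#'
#' @param name Stain name present in the library.
#' @param library A stain library as returned by [stain_library()].
#' @return A [stain_vector()].
#' @export
get_stain <- function(name, library = stain_library()) {
  if (inherits(name, "stain_vector")) return(name)
  fq_assert(is.character(name) && length(name) == 1L, "fq_parameter_error",
            "stain name must be a string")
  v <- library[[name]]
  fq_assert(!is.null(v), "fq_unknown_stain_error",
            "unknown stain '%s'; available: %s", name,
            paste(names(library), collapse = ", "))
  v
}

#' Optical-density (absorbance) transform
#'
#' Converts transmitted intensities to per-channel optical density,
#' `OD = -log10(max(I, eps))`, so that white maps to zero and stains add
#' linearly under the Beer-Lambert model. Values are capped at `-log10(eps)`.
#'
#' @param img RGB array in `[0, 1]`.
#' @param eps Positive floor on intensity before the logarithm. The default
#'   `1/256` sits one quantization step below the darkest 8-bit level, giving
#'   an OD cap of about 2.41.
#' @return `H x W x 3` array of non-negative optical densities.
#' @export
od_transform <- function(img, eps = 1/256) {
  validate_rgb(img)
  fq_assert(is.numeric(eps) && length(eps) == 1L && eps > 0 && eps < 1,
            "fq_parameter_error", "eps must be in (0, 1)")
  -log10(pmax(img, eps))
}

#' Unmix a stain from an RGB image by optical-density decomposition
#'
#' Each pixel's OD vector is decomposed by ordinary least squares onto the
#' absorbance direction(s) of the given stain(s); the coefficient of the
#' primary stain, floored at zero, is returned as a concentration map in OD
#' units. With a secondary stain the decomposition is onto the span of both
#' (any residual is orthogonal to both and does not affect the coefficients);
#' with `secondary = NULL` it is the projection onto the primary alone.
#'
#' @param img RGB array.
#' @param primary Primary stain: a [stain_vector()] or a library name.
#' @param secondary Optional secondary stain unmixed jointly with the primary.
#' @param eps Intensity floor for [od_transform()].
#' @param library Stain library used to resolve names.
#' @return `H x W` numeric matrix of non-negative primary-stain
#'   concentrations (OD units).
#' @export
unmix_colors <- function(img, primary, secondary = NULL, eps = 1/256,
                         library = stain_library()) {
  od <- od_transform(img, eps)
  v1 <- get_stain(primary, library)$absorbance
  d <- dim(od)
  odm <- matrix(od, d[1] * d[2], 3L)
  if (is.null(secondary)) {
    conc <- as.vector(odm %*% v1)
  } else {
    v2 <- get_stain(secondary, library)$absorbance
    cosang <- sum(v1 * v2)                # both unit norm
    fq_assert(1 - cosang^2 > 1e-12, "fq_degenerate_basis_error",
              "primary and secondary stain vectors are collinear")
    A <- cbind(v1, v2)
    coefs <- odm %*% A %*% solve(crossprod(A))
    conc <- coefs[, 1]
  }
  matrix(pmax(conc, 0), d[1], d[2])
}

#' Forward Beer-Lambert compositing of stain concentration fields
#'
#' The inverse of unmixing: given per-stain concentration maps, computes the
#' transmitted RGB image `I_c = background_c * 10^(-sum_s map_s * A_{s,c})`,
#' clipped to `[0, 1]`. Used by the synthetic generator and by round-trip
#' tests of the unmixing stage.
#'
#' @param maps List of `list(map = H x W matrix, stain = stain_vector)`
#'   entries; all maps must share one shape.
#' @param background RGB triple of the unstained background, channels in
#'   `(0, 1]` (default white).
#' @return RGB array.
#' @export
composite_stains <- function(maps, background = c(1, 1, 1)) {
  fq_assert(is.list(maps), "fq_parameter_error", "maps must be a list")
  fq_assert(length(background) == 3L && all(background > 0) && all(background <= 1),
            "fq_parameter_error", "background channels must lie in (0, 1]")
  fq_assert(length(maps) >= 1L, "fq_parameter_error", "at least one stain map required")
  d <- dim(maps[[1]]$map)
  od <- array(0, dim = c(d[1], d[2], 3L))
  for (entry in maps) {
    m <- entry$map
    fq_assert(is.matrix(m) && identical(dim(m), d), "fq_shape_error",
              "all concentration maps must share one shape")
    fq_assert(all(is.finite(m)) && min(m) >= 0, "fq_range_error",
              "concentrations must be finite and non-negative")
    v <- get_stain(entry$stain)$absorbance
    for (k in 1:3) od[, , k] <- od[, , k] + m * v[k]
  }
  out <- array(0, dim = c(d[1], d[2], 3L))
  for (k in 1:3) out[, , k] <- clamp01(background[k] * 10^(-od[, , k]))
  out
}

#' Render a concentration map as a display grayscale image
#'
#' Internal pipeline math stays in OD units; for thresholding and export the
#' map is rendered either as the transmission image of the lone stain
#' (`mode = "transmission"`, stain dark on a bright field, `10^-c`) or as its
#' complement (`mode = "stain"`, stain bright, `1 - 10^-c`).
#'
#' @param map Concentration matrix (OD units, non-negative).
#' @param mode `"transmission"` or `"stain"`.
#' @return Grayscale matrix in `[0, 1]`.
#' @export
concentration_to_gray <- function(map, mode = c("transmission", "stain")) {
  mode <- match.arg(mode)
  fq_assert(is.matrix(map) && all(is.finite(map)) && min(map) >= 0,
            "fq_range_error", "concentration map must be finite and non-negative")
  tr <- 10^(-map)
  if (mode == "transmission") tr else 1 - tr
}
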