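#' Construct a slide image
#'
#' Wraps an 8-bit RGB pixel array together with its physical scale
#' (microns per pixel). This is the raw substrate for all downstream
#' analysis; pixel coordinates throughout the package are 0-based with
#' the origin at the top-left corner and y increasing downwards.
#'
#' @param pixels Numeric array `height x width x 3` with values in
#'   `[0, 255]` (8-bit per channel, R/G/B in that order).
#' @param mpp Microns per pixel, a single positive number. Pixels are
#'   assumed isotropic (same scale in x and y); anisotropic inputs must
#'   be resampled before use and are rejected here.
#' @return An object of class `slide_image`.
#' @export
slide_image <- function(pixels, mpp) {
  if (!is.array(pixels) || length(dim(pixels)) != 3L || dim(pixels)[3] != 3L) {
    stop("`pixels` must be a height x width x 3 RGB array", call. = FALSE)
  }
  if (dim(pixels)[1] < 1L || dim(pixels)[2] < 1L) {
    stop("image must be at least 1 x 1 pixel", call. = FALSE)
  }
  if (anyNA(pixels) || min(pixels) < 0 || max(pixels) > 255) {
    stop("channel values must lie in [0, 255]", call. = FALSE)
  }
  if (length(mpp) != 1L || !is.finite(mpp) || mpp <= 0) {
    stop("`mpp` must be a single positive number (microns per pixel)",
         call. = FALSE)
  }
  structure(list(pixels = pixels, mpp = as.numeric(mpp)),
            class = "slide_image")
}

#' @export
print.slide_image <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("<slide_image> %d x %d px, %.4g microns/px (%.2f x %.2f mm)\n",
              d[2], d[1], x$mpp,
              d[2] * x$mpp / 1000, d[1] * x$mpp / 1000))
  invisible(x)
}

#' Hematoxylin--DAB stain basis
#'
#' Unit optical-density direction vectors for hematoxylin, DAB and a
#' residual channel, as columns of a 3x3 matrix in RGB-OD space. The
#' defaults are the published Ruifrok--Johnston H-DAB vectors,
#' normalized to unit length; the residual is the normalized cross
#' product of the two, so the basis is always invertible.
#'
#' @param hema,dab Length-3 numeric vectors giving the optical-density
#'   direction of each stain in (R, G, B); need not be pre-normalized.
#' @return A 3x3 numeric matrix with columns `hema`, `dab`, `residual`,
#'   each of unit Euclidean norm.
#' @export
stain_basis <- function(hema = c(0.650, 0.704, 0.286),
                        dab  = c(0.269, 0.568, 0.776)) {
  stopifnot(length(hema) == 3L, length(dab) == 3L)
  unit <- function(v) v / sqrt(sum(v^2))
  h <- unit(hema)
  d <- unit(dab)
  res <- c(h[2] * d[3] - h[3] * d[2],
           h[3] * d[1] - h[1] * d[3],
           h[1] * d[2] - h[2] * d[1])
  if (sqrt(sum(res^2)) < 1e-8) {
    stop("hematoxylin and DAB vectors are collinear; basis is singular",
         call. = FALSE)
  }
  m <- cbind(hema = h, dab = d, residual = unit(res))
  rownames(m) <- c("R", "G", "B")
  m
}

#' RGB image to optical density
#'
#' Beer--Lambert transform of an 8-bit RGB image: per channel,
#' `OD = -log10(max(I, 1) / 255)`. The one-intensity-unit guard keeps
#' the transform finite at `I = 0` (capping OD at about 2.407) and a
#' pure white pixel (255) maps exactly to zero absorbance. Intensities
#' are rounded to the nearest integer before the transform, matching
#' 8-bit storage.
#'
#' @param image A [slide_image()].
#' @return Numeric array of the same shape, all values `>= 0`, with
#'   class `od_image` and the source `mpp` attached as an attribute.
#' @export
rgb_to_od <- function(image) {
  if (!inherits(image, "slide_image")) {
    stop("`image` must be a slide_image", call. = FALSE)
  }
  i <- round(image$pixels)
  od <- -log10(pmax(i, 1) / 255)
  attr(od, "mpp") <- image$mpp
  class(od) <- c("od_image", class(od))
  od
}

#' Unmix optical densities into per-stain concentrations
#'
#' Solves the 3x3 linear system `od = basis %*% concentration` at every
#' pixel. Optical density is additive across chromogens, so unmixing is
#' a single matrix solve. Physically impossible negative concentrations
#' are clamped to zero when `clamp = TRUE` (the default); the unclamped
#' solution satisfies the reconstruction identity exactly.
#'
#' @param od An `od_image` from [rgb_to_od()], or any `h x w x 3` array
#'   of optical densities.
#' @param basis A 3x3 stain matrix from [stain_basis()].
#' @param clamp Clamp negative concentrations to 0?
#' @return List of three `h x w` matrices, `hema`, `dab`, `residual`,
#'   with `mpp` attached when present on `od`.
#' @export
deconvolve_stains <- function(od, basis = stain_basis(), clamp = TRUE) {
  stopifnot(is.array(od), length(dim(od)) == 3L, dim(od)[3] == 3L)
  if (!is.matrix(basis) || any(dim(basis) != 3L)) {
    stop("`basis` must be a 3x3 matrix", call. = FALSE)
  }
  if (abs(det(basis)) < 1e-10) {
    stop("stain basis is singular and cannot be inverted", call. = FALSE)
  }
  d <- dim(od)
  flat <- matrix(od, nrow = d[1] * d[2], ncol = 3L)   # pixels x channels
  conc <- flat %*% t(solve(basis))                    # pixels x stains
  if (clamp) conc[conc < 0] <- 0
  out <- list(
    hema     = matrix(conc[, 1], d[1], d[2]),
    dab      = matrix(conc[, 2], d[1], d[2]),
    residual = matrix(conc[, 3], d[1], d[2])
  )
  attr(out, "mpp") <- attr(od, "mpp")
  out
}

#' Forward-synthesize optical densities from stain concentrations
#'
#' Inverse companion of [deconvolve_stains()]: given per-pixel
#' hematoxylin and DAB concentrations, produces the `h x w x 3` RGB
#' optical-density array `basis %*% c(hema, dab, 0)`. Used by the slide
#' simulator and by round-trip consistency checks.
#'
#' @param hema,dab Equal-shaped numeric matrices of concentrations.
#' @param basis A 3x3 stain matrix from [stain_basis()].
#' @return Numeric `h x w x 3` optical-density array.
#' @export
synthesize_od <- function(hema, dab, basis = stain_basis()) {
  stopifnot(is.matrix(hema), is.matrix(dab), all(dim(hema) == dim(dab)))
  conc <- cbind(as.vector(hema), as.vector(dab), 0)
  flat <- conc %*% t(basis)
  array(flat, dim = c(dim(hema), 3L))
}

#' Optical density to 8-bit RGB intensities
#'
#' `I = round(255 * 10^-OD)`, clamped to `[0, 255]`.
#'
#' @param od Numeric `h x w x 3` optical-density array.
#' @param mpp Microns per pixel for the resulting image.
#' @return A [slide_image()].
#' @export
od_to_rgb <- function(od, mpp) {
  i <- round(255 * 10^(-od))
  i[i < 0] <- 0
  i[i > 255] <- 255
  slide_image(i, mpp)
}
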