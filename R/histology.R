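# Immunostain quantification: GFAP pixel coverage relative to soma intensity
# and the ezrin territorial-domain-to-soma intensity ratio. Brightfield DAB
# images must be inverted before analysis so signal increases with stain.

#' Construct a stain image
#'
#' @param pixels 2D numeric intensity matrix, finite and >= 0; for DAB
#'   brightfield input set `invert_8bit = TRUE` so that signal increases with
#'   stain (signal = 255 - value).
#' @param px_size Pixel size in micrometers (default 1).
#' @param invert_8bit Invert an 8-bit brightfield image (default FALSE).
#' @return An object of class `stain_image`.
#' @export
stain_image <- function(pixels, px_size = 1, invert_8bit = FALSE) {
  pixels <- as.matrix(pixels)
  if (any(!is.finite(pixels)) || any(pixels < 0))
    stop("pixel intensities must be finite and >= 0")
  if (px_size <= 0) stop("px_size must be > 0")
  if (invert_8bit) pixels <- 255 - pixels
  structure(list(pixels = pixels, px_size = px_size,
                 inverted = invert_8bit),
            class = "stain_image")
}

# Validate a region mask against an image.
.check_mask <- function(image, mask, what) {
  if (is.list(mask) && !is.null(mask$mask)) mask <- mask$mask
  mask <- as.matrix(mask)
  if (!all(dim(mask) == dim(image$pixels)))
    stop(sprintf("%s mask shape does not match the image", what))
  mask <- mask != 0
  if (!any(mask)) stop(sprintf("%s mask is empty", what))
  mask
}

#' GFAP pixel coverage of a frame
#'
#' Percentage of all pixels in the frame whose intensity strictly exceeds 10
#' percent of the mean soma intensity.
#'
#' @param image A [stain_image()].
#' @param soma Logical soma mask (same shape) or a list with a `mask` field.
#' @param threshold_frac Fraction of the mean soma intensity used as
#'   threshold (default 0.10).
#' @return Coverage percentage (0-100).
#' @export
gfap_coverage <- function(image, soma, threshold_frac = 0.10) {
  stopifnot(inherits(image, "stain_image"))
  soma <- .check_mask(image, soma, "soma")
  soma_mean <- mean(image$pixels[soma])
  if (!is.finite(soma_mean) || soma_mean <= 0)
    stop("zero soma mean intensity: coverage threshold undefined")
  thr <- threshold_frac * soma_mean
  100 * sum(image$pixels > thr) / length(image$pixels)
}

#' Ezrin domain-to-soma intensity ratio
#'
#' Mean stain intensity over the astrocyte territorial domain normalized to
#' the mean intensity over the soma.
#'
#' @param image A [stain_image()].
#' @param domain,soma Logical region masks (same shape as the image).
#' @return Dimensionless ratio.
#' @export
ezrin_domain_ratio <- function(image, domain, soma) {
  stopifnot(inherits(image, "stain_image"))
  domain <- .check_mask(image, domain, "domain")
  soma <- .check_mask(image, soma, "soma")
  soma_mean <- mean(image$pixels[soma])
  if (!is.finite(soma_mean) || soma_mean <= 0)
    stop("zero soma mean intensity: normalization undefined")
  mean(image$pixels[domain]) / soma_mean
}

#' Rasterize a polygon into a region mask
#'
#' Vertex coordinates are pixel positions (x = column, y = row); a pixel is
#' inside when its center is inside the polygon (even-odd rule).
#'
#' @param vertices Two-column matrix or data frame of (x, y) vertices.
#' @param dim Mask dimensions `(nrow, ncol)`.
#' @return Logical matrix.
#' @export
polygon_mask <- function(vertices, dim) {
  vx <- vertices[[1]]; vy <- vertices[[2]]
  n <- length(vx)
  xs <- matrix(rep(seq_len(dim[2]), each = dim[1]), dim[1], dim[2])
  ys <- matrix(rep(seq_len(dim[1]), dim[2]), dim[1], dim[2])
  inside <- matrix(FALSE, dim[1], dim[2])
  j <- n
  for (i in seq_len(n)) {
    crosses <- ((vy[i] > ys) != (vy[j] > ys)) &
      (xs < (vx[j] - vx[i]) * (ys - vy[i]) / (vy[j] - vy[i]) + vx[i])
    inside <- xor(inside, crosses)
    j <- i
  }
  inside
}
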