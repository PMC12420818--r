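#' @name morphology
#' @title Flat grayscale morphology with a disc structuring element
#' @description
#' Erosion, dilation, opening and the white top-hat with a flat disc
#' structuring element. At image borders the min/max is taken over the
#' in-image part of the structuring element only, so the operators are
#' well defined without any padding convention; with this choice the opening
#' never exceeds the input and the top-hat is non-negative everywhere.
NULL

#' Disc structuring-element offsets
#'
#' All integer offsets `(dy, dx)` with `dy^2 + dx^2 <= radius^2`.
#'
#' @param radius_px disc radius in pixels (>= 1).
#' @return two-column integer matrix of offsets.
#' @export
disc_offsets <- function(radius_px) {
  radius_px <- as.integer(radius_px)
  if (radius_px < 1L) stop("radius_px must be >= 1")
  g <- expand.grid(dy = -radius_px:radius_px, dx = -radius_px:radius_px)
  g <- g[g$dy^2 + g$dx^2 <= radius_px^2, , drop = FALSE]
  as.matrix(g)
}

# min/max over the disc neighbourhood of every pixel; `fill` is the identity
# element so out-of-image neighbours never win.
.morph_extreme <- function(img, offsets, fun, fill) {
  ny <- nrow(img); nx <- ncol(img)
  out <- matrix(fill, ny, nx)
  for (k in seq_len(nrow(offsets))) {
    dy <- offsets[k, 1L]; dx <- offsets[k, 2L]
    ys <- max(1L, 1L + dy):min(ny, ny + dy)
    xs <- max(1L, 1L + dx):min(nx, nx + dx)
    out[ys - dy, xs - dx] <- fun(out[ys - dy, xs - dx], img[ys, xs])
  }
  out
}

#' Grayscale erosion by a disc
#' @param img numeric matrix.
#' @param radius_px disc radius in pixels.
#' @return matrix of the same shape.
#' @export
erode_disc <- function(img, radius_px) {
  .morph_extreme(img, disc_offsets(radius_px), pmin, Inf)
}

#' Grayscale dilation by a disc
#' @inheritParams erode_disc
#' @return matrix of the same shape.
#' @export
dilate_disc <- function(img, radius_px) {
  .morph_extreme(img, disc_offsets(radius_px), pmax, -Inf)
}

#' Grayscale opening by a disc
#'
#' Erosion followed by dilation. Removes bright structures smaller than the
#' disc while leaving larger structures (and slowly varying background)
#' intact; always pointwise `<=` the input.
#'
#' @inheritParams erode_disc
#' @return matrix of the same shape.
#' @export
opening_disc <- function(img, radius_px) {
  dilate_disc(erode_disc(img, radius_px), radius_px)
}

#' White top-hat transform
#'
#' Input minus its grayscale opening by a disc. Isolates bright features
#' smaller than the structuring element (diffraction-limited kinetochore
#' spots) on a flat zero background, suppressing slowly varying chromatin and
#' cytoplasm signal. The output is non-negative everywhere.
#'
#' @param image numeric matrix (a single projected channel).
#' @param radius_px disc radius in pixels; should exceed the spot radius so
#'   spots pass and extended background is removed.
#' @return matrix of the same shape, `>= 0`.
#' @export
tophat_transform <- function(image, radius_px) {
  if (!is.matrix(image)) stop("image must be a 2-d matrix")
  image - opening_disc(image, radius_px)
}
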