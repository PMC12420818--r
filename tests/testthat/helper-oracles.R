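# Independent brute-force oracles and tiny image builders used across tests.

# grayscale opening by per-pixel loops: erosion then dilation over the disc
# neighbourhood, min/max over in-image neighbours only
brute_opening <- function(img, radius) {
  offs <- expand.grid(dy = -radius:radius, dx = -radius:radius)
  offs <- offs[offs$dy^2 + offs$dx^2 <= radius^2, ]
  ny <- nrow(img); nx <- ncol(img)
  pass <- function(m, fun) {
    out <- matrix(NA_real_, ny, nx)
    for (y in seq_len(ny)) for (x in seq_len(nx)) {
      ys <- y + offs$dy; xs <- x + offs$dx
      ok <- ys >= 1 & ys <= ny & xs >= 1 & xs <= nx
      out[y, x] <- fun(m[cbind(ys[ok], xs[ok])])
    }
    out
  }
  pass(pass(img, min), max)
}

brute_tophat <- function(img, radius) img - brute_opening(img, radius)

# background accrual oracle: global sort of every pixel by distance from the
# ROI centre (ties row-major), dropping ROI and mask pixels
brute_accrue <- function(roi, mask, target) {
  ny <- nrow(mask); nx <- ncol(mask)
  g <- expand.grid(y = seq_len(ny), x = seq_len(nx))
  d2 <- (g$y - roi$center[1])^2 + (g$x - roi$center[2])^2
  in_roi <- paste(g$y, g$x) %in% paste(roi$pixels[, 1], roi$pixels[, 2])
  elig <- !in_roi & !mask[cbind(g$y, g$x)]
  g <- g[elig, ]; d2 <- d2[elig]
  ord <- order(d2, g$y, g$x)[seq_len(target)]
  cbind(y = g$y[ord], x = g$x[ord])
}

# add a 2D Gaussian of peak `amp` and width `sigma` at a (subpixel) centre
add_gauss <- function(img, cy, cx, amp, sigma) {
  ny <- nrow(img); nx <- ncol(img)
  yy <- matrix(seq_len(ny), ny, nx); xx <- t(matrix(seq_len(nx), nx, ny))
  img + amp * exp(-((yy - cy)^2 + (xx - cx)^2) / (2 * sigma^2))
}

# single-channel noiseless stack from a matrix
mat_stack <- function(m, pixel_size_um = 0.1, role = "outer_kt") {
  image_stack(m, pixel_size_um,
              channel_roles = stats::setNames(1L, role))
}
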