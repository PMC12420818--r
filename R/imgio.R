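#' Multi-channel image stack container
#'
#' An `ImageStack` holds a multi-channel, optionally z-resolved pixel array
#' together with the acquisition metadata the quantification needs: the
#' lateral pixel size in micrometres, the z-step, and a map from channel index
#' to biological role (`dna`, `reference_kt`, `outer_kt`, `measure_1`, ...).
#'
#' Pixels are stored as a 4-dimensional array indexed
#' `(channel, z, y, x)`; a plain matrix is promoted to a single-channel,
#' single-slice stack. Intensities are raw detector units and may include a
#' camera offset; no non-negativity is assumed.
#'
#' Coordinates throughout the package are `(y, x)` with 1-based pixel centres
#' at integer positions; all distances are centre-to-centre.
#'
#' @param pixels 4-d array `(channel, z, y, x)` or a 2-d matrix `(y, x)`.
#' @param pixel_size_um lateral pixel size, micrometres per pixel (> 0).
#' @param channel_roles named integer vector mapping role name to channel
#'   index, e.g. `c(dna = 1, reference_kt = 2, measure_1 = 3)`. At most one
#'   channel per role; every index must exist in `pixels`.
#' @param z_step_um z spacing in micrometres, or `NA` for 2D data.
#' @param condition_label free-text experimental condition.
#' @return An object of class `ImageStack`.
#' @export
image_stack <- function(pixels, pixel_size_um, channel_roles = NULL,
                        z_step_um = NA_real_, condition_label = "") {
  if (is.matrix(pixels)) {
    dim(pixels) <- c(1L, 1L, nrow(pixels), ncol(pixels))
  }
  if (length(dim(pixels)) != 4L)
    stop("pixels must be a (channel, z, y, x) array or a 2-d matrix")
  if (!is.numeric(pixel_size_um) || length(pixel_size_um) != 1L ||
      pixel_size_um <= 0)
    stop("pixel_size_um must be a single positive number")
  nc <- dim(pixels)[1L]
  if (!is.null(channel_roles)) {
    channel_roles <- .check_roles(channel_roles, nc)
  }
  structure(list(pixels = pixels,
                 pixel_size_um = pixel_size_um,
                 z_step_um = z_step_um,
                 channel_roles = channel_roles,
                 condition_label = condition_label),
            class = "ImageStack")
}

.check_roles <- function(channel_roles, n_channels) {
  channel_roles <- vapply(channel_roles, as.integer, integer(1))
  if (is.null(names(channel_roles)) || any(!nzchar(names(channel_roles))))
    stop("channel_roles must be a named vector (role -> channel index)")
  if (anyDuplicated(names(channel_roles)))
    stop("at most one channel per role")
  bad <- channel_roles < 1L | channel_roles > n_channels
  if (any(bad))
    stop(sprintf("role '%s' refers to channel %d but the image has %d channel(s)",
                 names(channel_roles)[bad][1L], channel_roles[bad][1L],
                 n_channels))
  channel_roles
}

#' @export
print.ImageStack <- function(x, ...) {
  d <- dim(x$pixels)
  cat(sprintf("ImageStack: %d channel(s), %d z-slice(s), %d x %d px, %.4g um/px\n",
              d[1L], d[2L], d[3L], d[4L], x$pixel_size_um))
  if (!is.null(x$channel_roles))
    cat("  roles:", paste(sprintf("%s=%d", names(x$channel_roles),
                                  x$channel_roles), collapse = ", "), "\n")
  invisible(x)
}

#' Extract one channel of an ImageStack by role
#'
#' @param stack an `ImageStack`.
#' @param role a role name present in `stack$channel_roles`.
#' @param drop_z collapse a singleton z axis and return a matrix.
#' @return numeric array `(z, y, x)`, or a `(y, x)` matrix when `drop_z` and
#'   the stack has one slice.
#' @export
get_channel <- function(stack, role, drop_z = TRUE) {
  stopifnot(inherits(stack, "ImageStack"))
  if (is.null(stack$channel_roles) || !(role %in% names(stack$channel_roles)))
    stop(sprintf("no channel with role '%s'", role))
  ch <- stack$channel_roles[[role]]
  a <- stack$pixels[ch, , , , drop = FALSE]
  dim(a) <- dim(stack$pixels)[2:4]
  if (drop_z && dim(a)[1L] == 1L) {
    m <- a[1L, , ]
    dim(m) <- dim(a)[2:3]
    return(m)
  }
  a
}

#' Read a TIFF file into an ImageStack
#'
#' Reads single- or multi-page TIFF files (8/16-bit integer or 32-bit float).
#' Multi-page files may store channels either interleaved per z-slice
#' (page order z1c1, z1c2, ..., z2c1, ...) or as separate channel blocks
#' (c1z1, c1z2, ..., c2z1, ...); the layout is declared, not guessed.
#'
#' @param path TIFF file path.
#' @param channel_roles named integer vector, role -> channel index.
#' @param pixel_size_um lateral pixel size in micrometres.
#' @param n_channels number of channels in the file; default
#'   `max(channel_roles)`.
#' @param layout `"interleaved"` (channel fastest) or `"planar"`
#'   (channel-major blocks).
#' @param z_step_um z spacing in micrometres (optional).
#' @param condition_label free-text condition.
#' @return An `ImageStack`. Integer data round-trips bit-exactly through
#'   [write_stack()].
#' @export
read_stack <- function(path, channel_roles, pixel_size_um,
                       n_channels = max(channel_roles),
                       layout = c("interleaved", "planar"),
                       z_step_um = NA_real_, condition_label = "") {
  layout <- match.arg(layout)
  if (!file.exists(path)) stop(sprintf("cannot read '%s'", path))
  pages <- tiff::readTIFF(path, all = TRUE, as.is = TRUE)
  if (!is.list(pages)) pages <- list(pages)
  pages <- lapply(pages, function(p) {
    if (length(dim(p)) == 3L) p[, , 1L] else p
  })
  np <- length(pages)
  n_channels <- as.integer(n_channels)
  if (np %% n_channels != 0L)
    stop(sprintf("%d page(s) not divisible by %d channel(s)", np, n_channels))
  nz <- np %/% n_channels
  ny <- nrow(pages[[1L]]); nx <- ncol(pages[[1L]])
  px <- array(0, dim = c(n_channels, nz, ny, nx))
  for (i in seq_len(np)) {
    if (layout == "interleaved") {
      z <- (i - 1L) %/% n_channels + 1L
      ch <- (i - 1L) %% n_channels + 1L
    } else {
      ch <- (i - 1L) %/% nz + 1L
      z <- (i - 1L) %% nz + 1L
    }
    px[ch, z, , ] <- pages[[i]]
  }
  image_stack(px, pixel_size_um, channel_roles = channel_roles,
              z_step_um = z_step_um, condition_label = condition_label)
}

#' Write an ImageStack to a multi-page TIFF
#'
#' Pages are written as 16-bit integers. Integer-valued stacks round-trip
#' bit-exactly through [read_stack()]; fractional intensities (e.g.
#' synthetic images with read noise) are rounded to the nearest detector
#' unit and clamped at zero, the quantisation a real camera applies.
#'
#' @param stack an `ImageStack`.
#' @param path output file path.
#' @param layout page layout, as in [read_stack()].
#' @return `path`, invisibly.
#' @export
write_stack <- function(stack, path, layout = c("interleaved", "planar")) {
  layout <- match.arg(layout)
  stopifnot(inherits(stack, "ImageStack"))
  px <- stack$pixels
  d <- dim(px)
  if (max(px) > 65535)
    stop("intensities exceed the 16-bit range")
  px <- pmax(round(px), 0)
  pages <- vector("list", d[1L] * d[2L])
  i <- 1L
  if (layout == "interleaved") {
    for (z in seq_len(d[2L])) for (ch in seq_len(d[1L])) {
      pages[[i]] <- px[ch, z, , ]; dim(pages[[i]]) <- d[3:4]; i <- i + 1L
    }
  } else {
    for (ch in seq_len(d[1L])) for (z in seq_len(d[2L])) {
      pages[[i]] <- px[ch, z, , ]; dim(pages[[i]]) <- d[3:4]; i <- i + 1L
    }
  }
  pages <- lapply(pages, function(p) p / 65535)
  tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  invisible(path)
}

.project <- function(stack, fun) {
  d <- dim(stack$pixels)
  out <- array(0, dim = c(d[1L], 1L, d[3L], d[4L]))
  for (ch in seq_len(d[1L])) {
    sl <- stack$pixels[ch, , , , drop = FALSE]
    dim(sl) <- d[2:4]
    out[ch, 1L, , ] <- apply(sl, c(2L, 3L), fun)
  }
  res <- stack
  res$pixels <- out
  res
}

#' Sum-project a z-stack
#'
#' Collapses the z axis by per-pixel summation over all slices, per channel.
#' Quantification operates on sum projections so that the full axial extent
#' of each kinetochore contributes to its measured intensity.
#'
#' @param stack an `ImageStack` with >= 1 z-slice.
#' @return An `ImageStack` with a singleton z axis; metadata preserved.
#' @export
sum_project <- function(stack) {
  stopifnot(inherits(stack, "ImageStack"))
  if (dim(stack$pixels)[2L] == 1L) return(stack)
  .project(stack, sum)
}

#' Max-project a z-stack
#'
#' Per-pixel maximum over z, per channel. Used for display; quantification
#' uses [sum_project()].
#'
#' @inheritParams sum_project
#' @return An `ImageStack` with a singleton z axis.
#' @export
max_project <- function(stack) {
  stopifnot(inherits(stack, "ImageStack"))
  if (dim(stack$pixels)[2L] == 1L) return(stack)
  .project(stack, max)
}

#' Crop a square cell window from an image
#'
#' Cuts a `side_px` x `side_px` window around a centre pixel. Windows that
#' extend beyond the parent image are zero-padded and flagged rather than
#' rejected, with the padding amounts recorded.
#'
#' @param stack an `ImageStack`.
#' @param center `(y, x)` centre pixel, inside the image.
#' @param side_px window side length in pixels (default 250).
#' @return A `CellCrop`: an `ImageStack` with extra fields `origin` (the
#'   `(y, x)` position in the parent image that maps to crop pixel `(1, 1)`),
#'   `side_px`, `padded`, and `pad` (pixels of padding on each edge).
#' @export
crop_cell <- function(stack, center, side_px = 250L) {
  stopifnot(inherits(stack, "ImageStack"))
  d <- dim(stack$pixels)
  cy <- as.integer(round(center[1L])); cx <- as.integer(round(center[2L]))
  if (cy < 1L || cy > d[3L] || cx < 1L || cx > d[4L])
    stop("crop center outside image")
  side_px <- as.integer(side_px)
  y0 <- cy - (side_px - 1L) %/% 2L
  x0 <- cx - (side_px - 1L) %/% 2L
  ys <- y0:(y0 + side_px - 1L)
  xs <- x0:(x0 + side_px - 1L)
  out <- array(0, dim = c(d[1L], d[2L], side_px, side_px))
  yin <- ys >= 1L & ys <= d[3L]
  xin <- xs >= 1L & xs <= d[4L]
  out[, , yin, xin] <- stack$pixels[, , ys[yin], xs[xin], drop = FALSE]
  pad <- c(top = sum(ys < 1L), bottom = sum(ys > d[3L]),
           left = sum(xs < 1L), right = sum(xs > d[4L]))
  res <- stack
  res$pixels <- out
  res$origin <- c(y = y0, x = x0)
  res$side_px <- side_px
  res$padded <- any(pad > 0L)
  res$pad <- pad
  class(res) <- c("CellCrop", "ImageStack")
  res
}

#' Convert a pixel distance to micrometres
#'
#' @param d_px distance in pixels.
#' @param pixel_size_um micrometres per pixel (> 0).
#' @return distance in micrometres.
#' @export
px_to_um <- function(d_px, pixel_size_um) {
  if (any(pixel_size_um <= 0)) stop("pixel_size_um must be positive")
  d_px * pixel_size_um
}
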