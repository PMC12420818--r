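#' Build a binary kinetochore mask from the reference channel
#'
#' The reference kinetochore channel (e.g. CENP-C) is white top-hat filtered
#' to isolate spot-scale structure, then thresholded with the
#' iterative-intermeans method. The mask marks pixels carrying kinetochore
#' signal and is used to keep background ROIs off neighbouring kinetochores.
#' Because the top-hat removes any constant offset, the mask is invariant to
#' adding a constant to the channel.
#'
#' @param reference_channel numeric matrix, the projected reference channel.
#' @param tophat_radius disc radius for the top-hat, pixels (default 5).
#' @return A `KinetochoreMask`: list with `mask` (logical matrix),
#'   `threshold_value`, `tophat` (the filtered image) and `tophat_radius`.
#' @export
build_kinetochore_mask <- function(reference_channel, tophat_radius = 5L) {
  th <- tophat_transform(reference_channel, tophat_radius)
  thr <- isodata_threshold(th)
  structure(list(mask = th > thr,
                 threshold_value = thr,
                 tophat = th,
                 tophat_radius = as.integer(tophat_radius)),
            class = "KinetochoreMask")
}

#' Detect non-overlapping kinetochore maxima
#'
#' Finds local maxima of the top-hat-filtered reference channel and greedily
#' keeps the `n_spots` brightest subject to a pairwise minimum separation, so
#' each retained maximum corresponds to an individual, non-overlapping
#' kinetochore. Working on the top-hat image (not the raw channel) prevents
#' tilted background from creating false maxima. Intensity ties are broken in
#' row-major order so the selection is deterministic.
#'
#' @param reference_channel numeric matrix.
#' @param n_spots number of maxima requested (default 20).
#' @param min_sep_px minimum centre-to-centre separation in pixels
#'   (default 8, the ROI diameter).
#' @param tophat_radius disc radius for the top-hat (default 5).
#' @param tophat optional precomputed top-hat image (skips the filter).
#' @return integer matrix with columns `y`, `x`, one row per retained
#'   maximum, in descending top-hat intensity. If fewer than `n_spots`
#'   qualify, the shorter list is returned with a warning.
#' @export
detect_maxima <- function(reference_channel, n_spots = 20L, min_sep_px = 8,
                          tophat_radius = 5L, tophat = NULL) {
  th <- if (is.null(tophat)) tophat_transform(reference_channel, tophat_radius)
        else tophat
  ny <- nrow(th); nx <- ncol(th)
  # local maxima: >= all 8 neighbours (in-image neighbours only), > 0
  is_max <- matrix(TRUE, ny, nx)
  for (dy in -1:1) for (dx in -1:1) {
    if (dy == 0L && dx == 0L) next
    ys <- max(1L, 1L + dy):min(ny, ny + dy)
    xs <- max(1L, 1L + dx):min(nx, nx + dx)
    is_max[ys - dy, xs - dx] <- is_max[ys - dy, xs - dx] &
      (th[ys - dy, xs - dx] >= th[ys, xs])
  }
  is_max <- is_max & th > 0
  idx <- which(is_max)
  if (length(idx) == 0L) {
    warning("no candidate maxima found")
    return(matrix(integer(0), ncol = 2L, dimnames = list(NULL, c("y", "x"))))
  }
  cy <- (idx - 1L) %% ny + 1L
  cx <- (idx - 1L) %/% ny + 1L
  # descending intensity, ties row-major (y then x)
  ord <- order(-th[idx], cy, cx)
  cy <- cy[ord]; cx <- cx[ord]
  keep_y <- integer(0); keep_x <- integer(0)
  for (i in seq_along(cy)) {
    if (length(keep_y) == 0L ||
        all((keep_y - cy[i])^2 + (keep_x - cx[i])^2 >= min_sep_px^2)) {
      keep_y <- c(keep_y, cy[i]); keep_x <- c(keep_x, cx[i])
      if (length(keep_y) == n_spots) break
    }
  }
  if (length(keep_y) < n_spots)
    warning(sprintf("only %d of %d requested maxima found",
                    length(keep_y), n_spots))
  cbind(y = keep_y, x = keep_x)
}

#' Circular spot region of interest
#'
#' Rasterises a circular ROI of the given diameter at a detected maximum.
#' Even diameters are centred on the pixel corner nearest the given centre
#' and take the lattice pixels whose centres lie strictly inside the disc;
#' with diameter 8 this yields exactly 52 pixels, matching the 52-pixel
#' background ROI so that spot and background means are computed over an
#' equivalent number of pixels. Odd diameters are centred on the nearest
#' pixel centre.
#'
#' @param center `(y, x)` position (need not be integer).
#' @param diameter_px ROI diameter in pixels (default 8).
#' @param image_dim optional `(ny, nx)`; when given, an ROI extending beyond
#'   the image is an error.
#' @return A `SpotROI`: list with `center` (the rasterisation centre),
#'   `diameter_px` and `pixels` (two-column matrix of `(y, x)` lattice
#'   pixels).
#' @export
build_spot_roi <- function(center, diameter_px = 8L, image_dim = NULL) {
  diameter_px <- as.integer(diameter_px)
  if (diameter_px < 1L) stop("diameter_px must be >= 1")
  r <- diameter_px / 2
  if (diameter_px %% 2L == 0L) {
    # nearest pixel corner: corners live at half-integers
    c0 <- floor(center) + 0.5
  } else {
    c0 <- round(center)
  }
  span <- ceiling(r)
  ys <- (floor(c0[1L]) - span):(ceiling(c0[1L]) + span)
  xs <- (floor(c0[2L]) - span):(ceiling(c0[2L]) + span)
  g <- expand.grid(y = ys, x = xs)
  inside <- (g$y - c0[1L])^2 + (g$x - c0[2L])^2 < r^2
  pix <- as.matrix(g[inside, , drop = FALSE])
  if (!is.null(image_dim)) {
    if (any(pix[, 1L] < 1L | pix[, 1L] > image_dim[1L] |
            pix[, 2L] < 1L | pix[, 2L] > image_dim[2L]))
      stop("spot ROI extends beyond image")
  }
  structure(list(center = c0, diameter_px = diameter_px, pixels = pix),
            class = "SpotROI")
}

#' Accrue a mask-aware local background ROI
#'
#' Collects background pixels for one spot by visiting candidate pixels in
#' order of increasing Euclidean distance from the spot-ROI centre, skipping
#' pixels inside the spot ROI and pixels marked as kinetochore signal in the
#' binary mask, until `target_size` pixels have been accrued. Ties in
#' distance are broken in row-major order so the result is deterministic.
#' The default target of 52 pixels equals the default spot-ROI size, so spot
#' and background means are taken over the same number of pixels.
#'
#' @param roi a `SpotROI`.
#' @param kt_mask a `KinetochoreMask`, or a logical matrix (`TRUE` =
#'   kinetochore signal to avoid).
#' @param target_size number of background pixels to accrue (default 52).
#' @return A `BackgroundROI`: list with `pixels` (two-column `(y, x)`
#'   matrix of exactly `target_size` rows) and `spot_center`.
#' @export
accrue_background <- function(roi, kt_mask, target_size = 52L) {
  mask <- if (inherits(kt_mask, "KinetochoreMask")) kt_mask$mask else kt_mask
  ny <- nrow(mask); nx <- ncol(mask)
  c0 <- roi$center
  roi_key <- roi$pixels[, 1L] + ny * roi$pixels[, 2L]
  # grow a square window until enough eligible candidates are inside the
  # inscribed disc, then order by exact distance
  r_try <- ceiling(roi$diameter_px / 2) + ceiling(sqrt(target_size))
  repeat {
    ys <- max(1L, floor(c0[1L] - r_try)):min(ny, ceiling(c0[1L] + r_try))
    xs <- max(1L, floor(c0[2L] - r_try)):min(nx, ceiling(c0[2L] + r_try))
    g <- expand.grid(y = ys, x = xs)
    d2 <- (g$y - c0[1L])^2 + (g$x - c0[2L])^2
    elig <- d2 <= r_try^2 &
      !(g$y + ny * g$x) %in% roi_key &
      !mask[cbind(g$y, g$x)]
    full_window <- length(ys) == ny && length(xs) == nx
    if (sum(elig) >= target_size || full_window) {
      if (sum(elig) < target_size)
        stop(sprintf("insufficient background: %d eligible pixel(s), %d needed",
                     sum(elig), target_size))
      g <- g[elig, , drop = FALSE]
      d2 <- d2[elig]
      ord <- order(d2, g$y, g$x)[seq_len(target_size)]
      return(structure(list(pixels = cbind(y = g$y[ord], x = g$x[ord]),
                            spot_center = c0,
                            target_size = as.integer(target_size)),
                       class = "BackgroundROI"))
    }
    r_try <- r_try * 2
  }
}

#' Measure one kinetochore spot across channels
#'
#' For each channel of a sum-projected image, computes the mean intensity
#' over the spot ROI and over its background ROI, the background-corrected
#' value `max(roi_mean - bg_mean, 0)` (negative values are set to zero), and
#' the ratio of the corrected value to the corrected reference-kinetochore
#' channel. The ratio is only defined when the corrected reference signal is
#' positive; otherwise the measurement is flagged invalid rather than
#' raising.
#'
#' @param projection an `ImageStack` with a singleton z axis and a
#'   `reference_kt` role.
#' @param roi a `SpotROI`.
#' @param bg a `BackgroundROI`.
#' @return A `SpotMeasurement`: data frame with one row per mapped channel
#'   (`role`, `channel`, `roi_mean`, `bg_mean`, `corrected`, `ratio`) plus a
#'   `valid` attribute.
#' @export
measure_spot <- function(projection, roi, bg) {
  stopifnot(inherits(projection, "ImageStack"))
  if (dim(projection$pixels)[2L] != 1L)
    stop("measure_spot expects a projected (single z) stack")
  roles <- projection$channel_roles
  if (is.null(roles) || !("reference_kt" %in% names(roles)))
    stop("projection must map a reference_kt channel")
  rows <- lapply(names(roles), function(role) {
    m <- get_channel(projection, role)
    data.frame(role = role, channel = roles[[role]],
               roi_mean = mean(m[roi$pixels]),
               bg_mean = mean(m[bg$pixels]))
  })
  df <- do.call(rbind, rows)
  df$corrected <- pmax(df$roi_mean - df$bg_mean, 0)
  ref_corr <- df$corrected[df$role == "reference_kt"]
  valid <- ref_corr > 0
  df$ratio <- if (valid) df$corrected / ref_corr else NA_real_
  attr(df, "valid") <- valid
  class(df) <- c("SpotMeasurement", "data.frame")
  df
}

#' Quantify kinetochore recruitment in one cell
#'
#' Runs the full per-cell spot pipeline on a (cropped, projected) cell image:
#' builds the kinetochore mask from the reference channel, detects the
#' `n_spots` brightest non-overlapping maxima, and for each places a circular
#' spot ROI, accrues a mask-aware local background ROI, and measures every
#' channel. Per-channel ratios to the reference channel are averaged over the
#' valid kinetochores of the cell; invalid measurements (zero corrected
#' reference signal) and maxima whose ROI would leave the image are counted
#' as exclusions.
#'
#' @param crop an `ImageStack` or `CellCrop`; z-stacks are sum-projected.
#' @param n_spots kinetochores to measure per cell (default 20).
#' @param roi_diameter spot ROI diameter, px (default 8).
#' @param bg_size background ROI size, px (default 52).
#' @param tophat_radius top-hat disc radius, px (default 5).
#' @param cell_id identifier copied into the summary.
#' @return A `CellSummary`: list with `cell_id`, `condition_label`,
#'   `mean_ratio` (named per-role vector over valid kinetochores),
#'   `n_kinetochores`, `n_excluded` and `spots` (long per-kinetochore
#'   data frame).
#' @export
quantify_cell <- function(crop, n_spots = 20L, roi_diameter = 8L,
                          bg_size = 52L, tophat_radius = 5L, cell_id = "") {
  stopifnot(inherits(crop, "ImageStack"))
  proj <- sum_project(crop)
  ref <- get_channel(proj, "reference_kt")
  km <- build_kinetochore_mask(ref, tophat_radius = tophat_radius)
  centers <- detect_maxima(ref, n_spots = n_spots, min_sep_px = roi_diameter,
                           tophat = km$tophat)
  dims <- dim(ref)
  spots <- list()
  n_excluded <- 0L
  for (i in seq_len(nrow(centers))) {
    roi <- tryCatch(build_spot_roi(centers[i, ], diameter_px = roi_diameter,
                                   image_dim = dims),
                    error = function(e) NULL)
    if (is.null(roi)) { n_excluded <- n_excluded + 1L; next }
    bg <- accrue_background(roi, km, target_size = bg_size)
    sm <- measure_spot(proj, roi, bg)
    if (!attr(sm, "valid")) { n_excluded <- n_excluded + 1L; next }
    sm$kinetochore <- length(spots) + 1L
    sm$y <- centers[i, 1L]; sm$x <- centers[i, 2L]
    spots[[length(spots) + 1L]] <- sm
  }
  spot_df <- if (length(spots)) do.call(rbind, lapply(spots, as.data.frame))
             else NULL
  mean_ratio <- if (!is.null(spot_df))
    tapply(spot_df$ratio, spot_df$role, mean) else NULL
  structure(list(cell_id = cell_id,
                 condition_label = crop$condition_label,
                 mean_ratio = mean_ratio,
                 n_kinetochores = length(spots),
                 n_excluded = n_excluded,
                 mask = km,
                 spots = spot_df),
            class = "CellSummary")
}
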