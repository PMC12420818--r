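#' Bilinear interpolation of a matrix at arbitrary points
#' @param img numeric matrix with 1-based pixel centres at integer `(y, x)`.
#' @param y,x coordinates of the sample points (inside the image).
#' @return numeric vector of interpolated values.
#' @keywords internal
bilinear_sample <- function(img, y, x) {
  ny <- nrow(img); nx <- ncol(img)
  if (any(y < 1 | y > ny | x < 1 | x > nx))
    stop("sample point outside image")
  y0 <- pmin(floor(y), ny - 1L); x0 <- pmin(floor(x), nx - 1L)
  fy <- y - y0; fx <- x - x0
  v00 <- img[cbind(y0, x0)];     v01 <- img[cbind(y0, x0 + 1L)]
  v10 <- img[cbind(y0 + 1L, x0)]; v11 <- img[cbind(y0 + 1L, x0 + 1L)]
  (1 - fy) * ((1 - fx) * v00 + fx * v01) + fy * ((1 - fx) * v10 + fx * v11)
}

#' Sample a multi-channel line profile
#'
#' Samples the intensity along the segment from `p0` to `p1` at (near) unit
#' pixel spacing using bilinear interpolation, across every channel at
#' identical coordinates — so per-channel peak positions along the profile
#' are directly comparable. A width greater than 1 averages samples at
#' perpendicular offsets placed symmetrically about the line.
#'
#' @param projection an `ImageStack` with a singleton z axis.
#' @param p0,p1 `(y, x)` endpoints, inside the image.
#' @param width_px integer profile width (default 1).
#' @return A `LineProfile`: list with `p0`, `p1`, `width_px`,
#'   `positions_px` (distance along the segment, starting at 0, of the
#'   `ceil(|p1 - p0|) + 1` sample points, endpoints included), `samples`
#'   (channels x positions matrix, rownames = roles or channel indices) and
#'   `pixel_size_um`.
#' @export
sample_line_profile <- function(projection, p0, p1, width_px = 1L) {
  stopifnot(inherits(projection, "ImageStack"))
  if (dim(projection$pixels)[2L] != 1L)
    stop("sample_line_profile expects a projected (single z) stack")
  p0 <- as.numeric(p0); p1 <- as.numeric(p1)
  L <- sqrt(sum((p1 - p0)^2))
  n <- ceiling(L) + 1L
  tt <- if (L > 0) seq(0, 1, length.out = n) else 0
  py <- p0[1L] + tt * (p1[1L] - p0[1L])
  px <- p0[2L] + tt * (p1[2L] - p0[2L])
  # unit perpendicular for width averaging
  u <- if (L > 0) (p1 - p0) / L else c(0, 1)
  perp <- c(-u[2L], u[1L])
  offs <- seq(-(width_px - 1) / 2, (width_px - 1) / 2, length.out = width_px)
  d <- dim(projection$pixels)
  roles <- projection$channel_roles
  ch_names <- as.character(seq_len(d[1L]))
  if (!is.null(roles)) ch_names[roles] <- names(roles)
  samples <- matrix(0, nrow = d[1L], ncol = length(tt),
                    dimnames = list(ch_names, NULL))
  for (ch in seq_len(d[1L])) {
    img <- projection$pixels[ch, 1L, , ]
    dim(img) <- d[3:4]
    acc <- 0
    for (o in offs)
      acc <- acc + bilinear_sample(img, py + o * perp[1L], px + o * perp[2L])
    samples[ch, ] <- acc / length(offs)
  }
  structure(list(p0 = p0, p1 = p1, width_px = as.integer(width_px),
                 positions_px = tt * L, samples = samples,
                 pixel_size_um = projection$pixel_size_um),
            class = "LineProfile")
}

#' Normalise a group of line profiles to a 0-100 scale
#'
#' Applies the display normalisation used for grouped line scans: per
#' channel, 0 is the smallest sample value across the whole group and 100 is
#' the largest value of the group mean curve. After normalisation the group
#' minimum is exactly 0 and the mean curve peaks at exactly 100, so curves
#' from different channels and experiments are directly comparable.
#'
#' @param profiles list of `LineProfile`s of identical length (see
#'   [align_profiles()]).
#' @return the list with each profile's `samples` replaced by its normalised
#'   values (percent).
#' @export
normalize_profile_group <- function(profiles) {
  stopifnot(length(profiles) >= 1L)
  ns <- vapply(profiles, function(p) ncol(p$samples), integer(1))
  if (length(unique(ns)) != 1L)
    stop("profiles must have identical length; use align_profiles() first")
  nch <- nrow(profiles[[1L]]$samples)
  for (ch in seq_len(nch)) {
    vals <- vapply(profiles, function(p) p$samples[ch, ],
                   numeric(ns[1L]))           # positions x profiles
    lo <- min(vals)
    mean_curve <- rowMeans(vals)
    denom <- max(mean_curve) - lo
    if (denom <= 0) stop("constant profile group cannot be normalised")
    for (i in seq_along(profiles))
      profiles[[i]]$samples[ch, ] <-
        (profiles[[i]]$samples[ch, ] - lo) / denom * 100
  }
  profiles
}

#' Align profiles to a common length and average them
#'
#' Linearly resamples each profile to the median profile length (endpoints
#' preserved, midpoints registered — the profiles are assumed to be drawn
#' between the same pair of landmarks) and returns the per-position mean and
#' standard error of the mean.
#'
#' @param profiles list of >= 2 `LineProfile`s.
#' @return list with `profiles` (the resampled list), `mean` and `sem`
#'   (channels x positions matrices), and `n`.
#' @export
align_profiles <- function(profiles) {
  if (length(profiles) < 2L) stop("need at least 2 profiles to average")
  ns <- vapply(profiles, function(p) ncol(p$samples), integer(1))
  m <- as.integer(round(stats::median(ns)))
  target <- seq(0, 1, length.out = m)
  res <- lapply(profiles, function(p) {
    n <- ncol(p$samples)
    xin <- seq(0, 1, length.out = n)
    out <- t(apply(p$samples, 1L, function(v)
      stats::approx(xin, v, xout = target)$y))
    dimnames(out) <- list(rownames(p$samples), NULL)
    p$samples <- out
    p$positions_px <- target * max(p$positions_px)
    p
  })
  nch <- nrow(res[[1L]]$samples)
  mu <- matrix(0, nch, m, dimnames = dimnames(res[[1L]]$samples))
  se <- mu
  for (ch in seq_len(nch)) {
    vals <- vapply(res, function(p) p$samples[ch, ], numeric(m))
    mu[ch, ] <- rowMeans(vals)
    se[ch, ] <- apply(vals, 1L, stats::sd) / sqrt(length(res))
  }
  list(profiles = res, mean = mu, sem = se, n = length(res))
}

#' Fit a single Gaussian peak to a profile
#'
#' Least-squares fit of `offset + A * exp(-(x - mu)^2 / (2 * sigma^2))` to a
#' single-channel sample sequence, via Levenberg-Marquardt. Initialised from
#' the sample maximum (amplitude and position), minimum (offset), and the
#' second moment of the baseline-subtracted samples (sigma). Iterations are
#' bounded; non-convergence is reported on the result rather than silently
#' ignored.
#'
#' @param y numeric vector of >= 5 samples, not constant.
#' @param x positions of the samples (default `0:(n-1)`, pixels).
#' @return A `GaussianFit`: list with `amplitude`, `mean`, `sigma`, `offset`,
#'   `rmse`, `converged` and `n`.
#' @export
fit_gaussian <- function(y, x = seq_along(y) - 1) {
  y <- as.numeric(y); x <- as.numeric(x)
  if (length(y) < 5L) stop("need at least 5 samples")
  if (diff(range(y)) == 0) stop("constant input cannot be fitted")
  off0 <- min(y)
  a0 <- max(y) - off0
  mu0 <- x[which.max(y)]
  w <- pmax(y - off0, 0)
  s0 <- sqrt(sum(w * (x - mu0)^2) / sum(w))
  rng <- diff(range(x))
  if (!is.finite(s0) || s0 <= 0) s0 <- rng / 6
  s0 <- min(max(s0, 0.5), rng / 2)
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ off + A * exp(-(x - mu)^2 / (2 * s^2)),
                      start = list(off = off0, A = a0, mu = mu0, s = s0),
                      lower = c(-Inf, 0, min(x), 1e-6),
                      upper = c(Inf, Inf, max(x), rng),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (!is.null(fit)) {
    cf <- stats::coef(fit)
    rmse <- sqrt(mean(stats::residuals(fit)^2))
    conv <- fit$convInfo$isConv %||% TRUE
  } else {
    # Nelder-Mead fallback on the same least-squares objective
    obj <- function(p) {
      if (p[4L] <= 0) return(Inf)
      sum((y - (p[1L] + p[2L] * exp(-(x - p[3L])^2 / (2 * p[4L]^2))))^2)
    }
    op <- stats::optim(c(off0, a0, mu0, s0), obj,
                       control = list(maxit = 2000))
    cf <- c(off = op$par[1L], A = op$par[2L], mu = op$par[3L],
            s = abs(op$par[4L]))
    rmse <- sqrt(op$value / length(y))
    conv <- op$convergence == 0L
  }
  structure(list(amplitude = unname(cf["A"]), mean = unname(cf["mu"]),
                 sigma = unname(cf["s"]), offset = unname(cf["off"]),
                 rmse = rmse, converged = conv,
                 n = length(y)),
            class = "GaussianFit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Inter-kinetochore (KT-KT) distance
#'
#' Euclidean centre-to-centre distance between two (sub-pixel) kinetochore
#' centres, converted to micrometres. Symmetric in its arguments and
#' invariant to image translation.
#'
#' @param centerA,centerB `(y, x)` positions in pixels.
#' @param pixel_size_um micrometres per pixel.
#' @param cell_id identifier carried on the result.
#' @return A `DistanceMeasurement`: list with `kind = "kt_kt"`, `value_um`
#'   and `cell_id`. One kinetochore pair is one replicate.
#' @export
kt_kt_distance <- function(centerA, centerB, pixel_size_um, cell_id = "") {
  d <- sqrt(sum((as.numeric(centerA) - as.numeric(centerB))^2))
  structure(list(kind = "kt_kt",
                 value_um = px_to_um(d, pixel_size_um),
                 cell_id = cell_id),
            class = "DistanceMeasurement")
}

#' Intra-kinetochore distance from two Gaussian fits
#'
#' Distance between two markers within one kinetochore (e.g. CENP-A vs
#' NDC80), estimated as the absolute difference between the Gaussian-fit peak
#' positions of the two channels along the same line profile. Both fits must
#' come from profiles sampled at identical coordinates.
#'
#' @param fitA,fitB `GaussianFit`s from the same profile.
#' @param pixel_size_um micrometres per pixel.
#' @param cell_id identifier carried on the result.
#' @return A `DistanceMeasurement` with `kind = "intra_kt"`. One kinetochore
#'   is one replicate.
#' @export
intra_kt_distance <- function(fitA, fitB, pixel_size_um, cell_id = "") {
  stopifnot(inherits(fitA, "GaussianFit"), inherits(fitB, "GaussianFit"))
  if (fitA$n != fitB$n)
    stop("fits come from profiles of different lengths; same-line fits required")
  structure(list(kind = "intra_kt",
                 value_um = px_to_um(abs(fitA$mean - fitB$mean),
                                     pixel_size_um),
                 cell_id = cell_id),
            class = "DistanceMeasurement")
}

#' Automated KT-KT distance for one spot pair
#'
#' Measures the centre-to-centre distance of a kinetochore pair in a single
#' channel: the two brightest non-overlapping maxima are detected on the
#' top-hat image, a 1-px line profile is sampled along the axis through them
#' (extended beyond both spots), the profile is split at its midpoint and a
#' Gaussian is fitted to each half, and the distance is the difference of the
#' two fitted peak positions along the line, converted to micrometres. The
#' Gaussian-mean estimator localises each peak to sub-pixel precision.
#'
#' @param stack an `ImageStack` containing the pair; z-stacks are
#'   sum-projected.
#' @param role channel role carrying the spot pair (default `"outer_kt"`).
#' @param extend_px how far the profile extends beyond each detected maximum
#'   (default 6 px, clipped to the image).
#' @param tophat_radius top-hat disc radius for maxima detection (default 5).
#' @param min_sep_px minimum separation between the two maxima (default 4).
#' @param step_px sampling step of the internal fitting profiles (default
#'   0.25 px; the fine step averages out the phase-dependent part of the
#'   bilinear interpolation error).
#' @param cell_id identifier carried on the result.
#' @return A `DistanceMeasurement` with `kind = "kt_kt"`, the two
#'   `GaussianFit`s attached as `fits` and the refined sub-pixel `centers`.
#' @export
measure_pair_distance <- function(stack, role = "outer_kt", extend_px = 6,
                                  tophat_radius = 5L, min_sep_px = 4,
                                  step_px = 0.25, cell_id = "") {
  proj <- sum_project(stack)
  img <- get_channel(proj, role)
  centers <- detect_maxima(img, n_spots = 2L, min_sep_px = min_sep_px,
                           tophat_radius = tophat_radius)
  if (nrow(centers) < 2L) stop("could not detect two spot maxima")
  A <- as.numeric(centers[1L, ]); B <- as.numeric(centers[2L, ])
  L <- sqrt(sum((B - A)^2))
  u <- (B - A) / L
  clip <- function(p) pmin(pmax(p, 1), dim(img))
  p0 <- clip(A - extend_px * u)
  p1 <- clip(B + extend_px * u)
  sample_seg <- function(q0, q1) {
    len <- sqrt(sum((q1 - q0)^2))
    tt <- seq(0, len, by = step_px)
    d <- (q1 - q0) / len
    list(pos = tt,
         v = bilinear_sample(img, q0[1L] + tt * d[1L], q0[2L] + tt * d[2L]))
  }
  prof <- sample_seg(p0, p1)
  v <- prof$v
  pos <- prof$pos
  # position of each detected maximum along the profile
  sA <- sum((A - p0) * u); sB <- sum((B - p0) * u)
  mid <- (sA + sB) / 2
  half1 <- pos <= mid
  f1 <- fit_gaussian(v[half1], pos[half1])
  f2 <- fit_gaussian(v[!half1], pos[!half1])
  # 2D sub-pixel centres: refine the perpendicular coordinate of each peak
  # with a second 1D fit across the line
  perp <- c(-u[2L], u[1L])
  refine <- function(f) {
    ci <- p0 + f$mean * u
    q0 <- clip(ci - extend_px * perp)
    q1 <- clip(ci + extend_px * perp)
    pp <- sample_seg(q0, q1)
    vv <- (q1 - q0) / max(pp$pos)
    fp <- fit_gaussian(pp$v, pp$pos)
    ci + (fp$mean - sum((ci - q0) * vv)) * vv
  }
  cA <- refine(f1); cB <- refine(f2)
  res <- structure(list(kind = "kt_kt",
                        value_um = px_to_um(sqrt(sum((cB - cA)^2)),
                                            stack$pixel_size_um),
                        cell_id = cell_id),
                   class = "DistanceMeasurement")
  res$fits <- list(f1, f2)
  res$centers <- rbind(cA, cB)
  res
}
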