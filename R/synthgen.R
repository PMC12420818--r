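#' Spot amplitude that achieves a target peak signal-to-noise ratio
#'
#' SNR is defined as peak amplitude over the noise standard deviation at the
#' peak; with Poisson shot noise on `A + background` photons plus additive
#' read noise this gives `A / sqrt(A + background + read_sd^2) = snr`, solved
#' in closed form.
#'
#' @param snr target peak SNR.
#' @param background expected background photons under the peak.
#' @param read_sd read-noise standard deviation (detector units at gain 1).
#' @return peak amplitude in expected photons.
#' @export
amplitude_for_snr <- function(snr, background, read_sd = 0) {
  b <- background + read_sd^2
  (snr^2 + snr * sqrt(snr^2 + 4 * b)) / 2
}

#' Synthetic mitotic-scene specification
#'
#' Describes one synthetic cell: an elliptical chromatin region over a
#' uniform cytoplasm, kinetochore spot pairs (diffraction-limited Gaussian
#' spots at controlled separations), optional inner-marker spots offset
#' inward along each pair axis, a pericentric band centred between the pair
#' members, per-channel condition factors, the PSF width, and the noise
#' model (Poisson shot noise on expected photons, additive zero-mean read
#' noise, constant camera offset).
#'
#' Per-channel composition is given as photon amplitudes for four
#' components: `chromatin` (inside the ellipse), `cytoplasm` (everywhere),
#' `spot` (outer-kinetochore Gaussian peaks), `inner_spot` (inner-marker
#' peaks) and `band` (pericentric ridge). Condition factors multiply the
#' spot, inner-spot and band amplitudes of their channel only, emulating
#' depletion of the measured protein without touching DNA or background.
#'
#' Defaults emulate the widefield acquisition geometry the quantification
#' assumes: 250 px cells, a 2 um stack at 0.2 um intervals (11 slices),
#' 0.1075 um pixels, a 0.1 um PSF sigma, and spot amplitudes set for a peak
#' SNR of 10 over the local background.
#'
#' @param size_px image side, pixels.
#' @param nz number of z slices.
#' @param z_step_um z spacing, micrometres.
#' @param pixel_size_um lateral pixel size, micrometres.
#' @param psf_sigma_um in-focus PSF sigma, micrometres.
#' @param z_r_um defocus range: per-slice sigma is
#'   `psf_sigma_um * sqrt(1 + (z/z_r_um)^2)` with the 2D integral conserved.
#' @param channels named list (role -> named numeric vector with entries
#'   `chromatin`, `cytoplasm`, `spot`, `inner_spot`, `band`).
#' @param n_pairs number of kinetochore pairs placed when `pairs` is `NULL`.
#' @param separation_um true pair separation, micrometres.
#' @param inner_offset_um inner-marker offset inward of each outer spot.
#' @param band_width_um pericentric band cross-axis sigma, micrometres.
#' @param chromatin_axes_px ellipse semi-axes `(y, x)`, pixels.
#' @param pairs optional data frame `mid_y, mid_x, angle` fixing the pair
#'   geometry; otherwise it is drawn at render time.
#' @param noise list with `poisson`, `read_sd`, `offset`, `gain`.
#' @param condition_factors named per-role multiplicative factors.
#' @param condition_label free-text label copied onto rendered stacks.
#' @return A `SceneSpec` list.
#' @export
scene_spec <- function(size_px = 250L, nz = 11L, z_step_um = 0.2,
                       pixel_size_um = 0.1075, psf_sigma_um = 0.1,
                       z_r_um = 0.4, channels = NULL, n_pairs = 13L,
                       separation_um = 1.0, inner_offset_um = 0.1,
                       band_width_um = 0.25,
                       chromatin_axes_px = c(55, 80),
                       pairs = NULL,
                       noise = list(poisson = TRUE, read_sd = 2,
                                    offset = 100, gain = 1),
                       condition_factors = NULL,
                       condition_label = "") {
  if (is.null(channels)) {
    A <- amplitude_for_snr(10, background = 8, read_sd = noise$read_sd %||% 2)
    ch <- c(chromatin = 0, cytoplasm = 8, spot = 0, inner_spot = 0, band = 0)
    channels <- list(
      dna          = replace(ch, "chromatin", 150),
      reference_kt = replace(ch, "spot", A),
      measure_1    = replace(ch, "spot", A),
      measure_2    = replace(ch, "band", A))
  }
  channels <- lapply(channels, function(v) {
    full <- c(chromatin = 0, cytoplasm = 0, spot = 0, inner_spot = 0, band = 0)
    full[names(v)] <- v
    if (any(full < 0)) stop("channel amplitudes must be >= 0")
    full
  })
  if (is.null(condition_factors)) {
    condition_factors <- stats::setNames(rep(1, length(channels)),
                                         names(channels))
  }
  stopifnot(pixel_size_um > 0, psf_sigma_um > 0, band_width_um > 0,
            inner_offset_um >= 0, separation_um >= 0)
  structure(list(size_px = as.integer(size_px), nz = as.integer(nz),
                 z_step_um = z_step_um, pixel_size_um = pixel_size_um,
                 psf_sigma_um = psf_sigma_um, z_r_um = z_r_um,
                 channels = channels, n_pairs = as.integer(n_pairs),
                 separation_um = separation_um,
                 inner_offset_um = inner_offset_um,
                 band_width_um = band_width_um,
                 chromatin_axes_px = chromatin_axes_px,
                 pairs = pairs, noise = noise,
                 condition_factors = condition_factors,
                 condition_label = condition_label),
            class = "SceneSpec")
}

# draw pair midpoints/orientations inside the chromatin ellipse such that all
# outer spot centres are pairwise separated by >= min_sep px
.draw_pairs <- function(spec, min_sep = 9, margin = 15, max_tries = 5000L) {
  n <- spec$size_px
  c0 <- (n + 1) / 2
  ax <- spec$chromatin_axes_px * 0.8
  sep_px <- spec$separation_um / spec$pixel_size_um
  ys <- numeric(0); xs <- numeric(0)
  pairs <- data.frame(mid_y = numeric(0), mid_x = numeric(0),
                      angle = numeric(0))
  tries <- 0L
  while (nrow(pairs) < spec$n_pairs && tries < max_tries) {
    tries <- tries + 1L
    my <- c0 + stats::runif(1, -1, 1) * ax[1L]
    mx <- c0 + stats::runif(1, -1, 1) * ax[2L]
    if (((my - c0) / ax[1L])^2 + ((mx - c0) / ax[2L])^2 > 1) next
    ang <- stats::runif(1, 0, pi)
    u <- c(sin(ang), cos(ang))
    py <- my + c(-1, 1) * u[1L] * sep_px / 2
    px <- mx + c(-1, 1) * u[2L] * sep_px / 2
    if (any(py < margin | py > n - margin | px < margin | px > n - margin))
      next
    if (length(ys) &&
        any(outer(py, ys, `-`)^2 + outer(px, xs, `-`)^2 < min_sep^2)) next
    ys <- c(ys, py); xs <- c(xs, px)
    pairs <- rbind(pairs, data.frame(mid_y = my, mid_x = mx, angle = ang))
  }
  if (nrow(pairs) < spec$n_pairs)
    warning(sprintf("placed %d of %d pairs", nrow(pairs), spec$n_pairs))
  pairs
}

# add an elliptical-Gaussian bump evaluated on a local window
.add_bump <- function(img, cy, cx, amp, sy, sx, u = NULL) {
  if (amp == 0) return(img)
  ny <- nrow(img); nx <- ncol(img)
  w <- ceiling(5 * max(sy, sx))
  ys <- max(1L, floor(cy - w)):min(ny, ceiling(cy + w))
  xs <- max(1L, floor(cx - w)):min(nx, ceiling(cx + w))
  dy <- ys - cy; dx <- xs - cx
  if (is.null(u)) {
    g <- exp(-outer(dy^2 / (2 * sy^2), dx^2 / (2 * sx^2), `+`))
  } else {
    # axes along u (sy) and perpendicular (sx)
    DY <- matrix(dy, length(dy), length(dx))
    DX <- matrix(dx, length(dy), length(dx), byrow = TRUE)
    a <- DY * u[1L] + DX * u[2L]
    b <- -DY * u[2L] + DX * u[1L]
    g <- exp(-(a^2 / (2 * sy^2) + b^2 / (2 * sx^2)))
  }
  img[ys, xs] <- img[ys, xs] + amp * g
  img
}

#' Render a synthetic mitotic scene
#'
#' Composes the expected-photon field for every channel and z-slice
#' (chromatin ellipse + uniform cytoplasm + PSF-blurred spots + pericentric
#' bands, with per-slice defocus broadening), then applies Poisson shot
#' noise, additive read noise and the camera offset. With a fixed seed the
#' output is byte-identical between runs.
#'
#' @param spec a `SceneSpec`.
#' @param seed integer seed, or `NULL` to draw from the current RNG stream.
#' @return list with `stack` (an `ImageStack` whose channel roles follow the
#'   spec's channel names) and `truth` (a `GroundTruth` list: per-spot
#'   subpixel centres and amplitudes, per-pair separations, condition
#'   factors, and the true chromatin/cytoplasm masks).
#' @export
render_scene <- function(spec, seed = NULL) {
  stopifnot(inherits(spec, "SceneSpec"))
  if (!is.null(seed)) set.seed(seed)
  n <- spec$size_px
  nz <- spec$nz
  roles <- names(spec$channels)
  nc <- length(roles)
  c0 <- (n + 1) / 2
  ax <- spec$chromatin_axes_px
  yy <- matrix(seq_len(n), n, n)
  xx <- t(yy)
  ellipse <- ((yy - c0) / ax[1L])^2 + ((xx - c0) / ax[2L])^2 <= 1
  pairs <- if (!is.null(spec$pairs)) spec$pairs else .draw_pairs(spec)
  sep_px <- spec$separation_um / spec$pixel_size_um
  inner_px <- spec$inner_offset_um / spec$pixel_size_um
  band_px <- spec$band_width_um / spec$pixel_size_um
  s0 <- spec$psf_sigma_um / spec$pixel_size_um

  # ground-truth spot table
  spots <- NULL
  if (nrow(pairs) > 0) {
    spots <- do.call(rbind, lapply(seq_len(nrow(pairs)), function(i) {
      u <- c(sin(pairs$angle[i]), cos(pairs$angle[i]))
      outer_y <- pairs$mid_y[i] + c(-1, 1) * u[1L] * sep_px / 2
      outer_x <- pairs$mid_x[i] + c(-1, 1) * u[2L] * sep_px / 2
      inner_y <- outer_y - c(-1, 1) * u[1L] * inner_px
      inner_x <- outer_x - c(-1, 1) * u[2L] * inner_px
      data.frame(pair_id = i, member = c(1L, 2L, 1L, 2L),
                 kind = rep(c("outer", "inner"), each = 2L),
                 y = c(outer_y, inner_y), x = c(outer_x, inner_x))
    }))
  }

  zrel <- if (nz == 1L || !is.finite(spec$z_step_um)) numeric(nz)
          else (seq_len(nz) - (nz + 1) / 2) * spec$z_step_um
  sz <- s0 * sqrt(1 + (zrel / spec$z_r_um)^2)
  focus <- (s0 / sz)^2                      # peak scaling, integral conserved

  px <- array(0, dim = c(nc, nz, n, n))
  for (ci in seq_len(nc)) {
    amp <- spec$channels[[ci]]
    f <- spec$condition_factors[[roles[ci]]]
    base <- amp[["cytoplasm"]] + amp[["chromatin"]] * ellipse
    for (z in seq_len(nz)) {
      img <- matrix(base / 1, n, n)         # per-slice expected photons
      if (!is.null(spots) && (amp[["spot"]] > 0 || amp[["inner_spot"]] > 0)) {
        for (si in seq_len(nrow(spots))) {
          a <- if (spots$kind[si] == "outer") amp[["spot"]]
               else amp[["inner_spot"]]
          if (a == 0) next
          img <- .add_bump(img, spots$y[si], spots$x[si],
                           f * a * focus[z], sz[z], sz[z])
        }
      }
      if (nrow(pairs) > 0 && amp[["band"]] > 0) {
        for (i in seq_len(nrow(pairs))) {
          u <- c(sin(pairs$angle[i]), cos(pairs$angle[i]))
          s_along <- max(sep_px / 4, band_px)
          img <- .add_bump(img, pairs$mid_y[i], pairs$mid_x[i],
                           f * amp[["band"]] * focus[z],
                           sqrt(s_along^2 + (sz[z]^2 - s0^2)),
                           sqrt(band_px^2 + (sz[z]^2 - s0^2)), u = u)
        }
      }
      px[ci, z, , ] <- img
    }
  }
  nz_noise <- spec$noise
  if (isTRUE(nz_noise$poisson)) {
    px[] <- stats::rpois(length(px), px)
  }
  gain <- nz_noise$gain %||% 1
  px <- px * gain
  if ((nz_noise$read_sd %||% 0) > 0) {
    px <- px + stats::rnorm(length(px), sd = nz_noise$read_sd)
  }
  px <- px + (nz_noise$offset %||% 0)

  margin <- 10L
  extent <- matrix(FALSE, n, n)
  extent[(margin + 1L):(n - margin), (margin + 1L):(n - margin)] <- TRUE
  grown <- dilate_disc(ellipse * 1, 2L) > 0.5
  truth <- structure(list(
    spots = spots,
    pairs = if (nrow(pairs) > 0)
      cbind(pairs, separation_um = spec$separation_um) else pairs,
    condition_factors = spec$condition_factors,
    chromatin_mask = ellipse,
    cytoplasm_mask = extent & !grown,
    psf_sigma_px = s0), class = "GroundTruth")
  stack <- image_stack(px, spec$pixel_size_um,
                       channel_roles = stats::setNames(seq_len(nc), roles),
                       z_step_um = spec$z_step_um,
                       condition_label = spec$condition_label)
  list(stack = stack, truth = truth)
}

#' Generate a multi-condition synthetic dataset
#'
#' Renders `n_cells` independent scenes per condition, each with freshly
#' drawn pair geometry, applying the condition's multiplicative factor to
#' the spot/band amplitudes of the measured channels. This emulates a
#' control-versus-depletion experiment in which the measured protein's
#' recruitment is reduced by a known factor while the reference marker and
#' DNA stain are untouched, providing crisp ground truth for end-to-end
#' parameter-recovery tests.
#'
#' @param base_spec a `SceneSpec`; its `condition_factors` are overridden
#'   per condition for `measure_roles`.
#' @param conditions named numeric vector, label -> amplitude factor
#'   (default `c(ctrl = 1, dep = 0.2)`).
#' @param n_cells cells per condition (default 20).
#' @param seed integer seed for the whole dataset.
#' @param measure_roles roles the factor applies to; default every role
#'   starting with `"measure"`.
#' @param out_dir optional directory: images are written as multi-page TIFF
#'   plus a `ground_truth.csv`.
#' @return list with `images` (list of `ImageStack`s), `truth` (data frame:
#'   `cell_id`, `condition`, `factor`) and `scene_truth` (per-cell
#'   `GroundTruth`s).
#' @export
make_condition_dataset <- function(base_spec = scene_spec(),
                                   conditions = c(ctrl = 1, dep = 0.2),
                                   n_cells = 20L, seed = NULL,
                                   measure_roles = NULL, out_dir = NULL) {
  stopifnot(all(conditions >= 0))
  if (!is.null(seed)) set.seed(seed)
  if (is.null(measure_roles))
    measure_roles <- grep("^measure", names(base_spec$channels), value = TRUE)
  images <- list(); scene_truth <- list()
  rows <- list()
  for (lab in names(conditions)) {
    for (i in seq_len(n_cells)) {
      sp <- base_spec
      sp$condition_factors[measure_roles] <- conditions[[lab]]
      sp$condition_label <- lab
      sc <- render_scene(sp, seed = NULL)
      id <- sprintf("%s_%03d", lab, i)
      images[[id]] <- sc$stack
      scene_truth[[id]] <- sc$truth
      rows[[id]] <- data.frame(cell_id = id, condition = lab,
                               factor = conditions[[lab]])
    }
  }
  truth <- do.call(rbind, rows)
  rownames(truth) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (id in names(images))
      write_stack(images[[id]], file.path(out_dir, paste0(id, ".tif")))
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(images = images, truth = truth, scene_truth = scene_truth)
}

#' Generate a synthetic kinetochore-pair distance dataset
#'
#' Renders `n_pairs` single-pair scenes at one true centre separation with
#' random orientation and sub-pixel midpoint jitter, for validating the
#' line-profile distance estimators. STED-like mode uses fine pixels (30 nm)
#' and a narrow PSF (sigma 60 nm); widefield-like mode uses the default
#' camera geometry. The separation is fixed (not jittered) so the recovery
#' target is crisp.
#'
#' @param separation_um true pair separation, micrometres.
#' @param n_pairs number of pairs (default 50).
#' @param sted_like use STED-like sampling (default `TRUE`).
#' @param seed integer seed.
#' @param snr peak signal-to-noise ratio of each spot (default 10).
#' @param out_dir optional directory for TIFFs plus `ground_truth.csv`.
#' @return list with `stacks` (list of single-channel `ImageStack`s, role
#'   `outer_kt`), `truth` (data frame: `pair_id`, `separation_um`, `angle`,
#'   `mid_y`, `mid_x`) and the generation parameters.
#' @export
make_distance_dataset <- function(separation_um, n_pairs = 50L,
                                  sted_like = TRUE, seed = NULL, snr = 10,
                                  out_dir = NULL) {
  stopifnot(separation_um >= 0)
  if (!is.null(seed)) set.seed(seed)
  pixel_size_um <- if (sted_like) 0.03 else 0.1075
  psf_sigma_um <- if (sted_like) 0.06 else 0.1
  sep_px <- separation_um / pixel_size_um
  size <- as.integer(ceiling(sep_px) + 40L)
  cyt <- 8; read_sd <- 2
  A <- amplitude_for_snr(snr, background = cyt, read_sd = read_sd)
  stacks <- list(); rows <- list()
  for (i in seq_len(n_pairs)) {
    mid <- (size + 1) / 2 + stats::rnorm(2, sd = 1)
    ang <- stats::runif(1, 0, pi)
    sp <- scene_spec(size_px = size, nz = 1L, z_step_um = NA_real_,
                     pixel_size_um = pixel_size_um,
                     psf_sigma_um = psf_sigma_um,
                     channels = list(outer_kt = c(cytoplasm = cyt, spot = A)),
                     n_pairs = 1L, separation_um = separation_um,
                     pairs = data.frame(mid_y = mid[1L], mid_x = mid[2L],
                                        angle = ang),
                     noise = list(poisson = TRUE, read_sd = read_sd,
                                  offset = 100, gain = 1))
    stacks[[i]] <- render_scene(sp, seed = NULL)$stack
    rows[[i]] <- data.frame(pair_id = i, separation_um = separation_um,
                            angle = ang, mid_y = mid[1L], mid_x = mid[2L])
  }
  truth <- do.call(rbind, rows)
  if (!is.null(out_dir)) {
    dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    for (i in seq_along(stacks))
      write_stack(stacks[[i]],
                  file.path(out_dir, sprintf("pair_%03d.tif", i)))
    utils::write.csv(truth, file.path(out_dir, "ground_truth.csv"),
                     row.names = FALSE)
  }
  list(stacks = stacks, truth = truth, pixel_size_um = pixel_size_um,
       psf_sigma_um = psf_sigma_um, snr = snr)
}
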