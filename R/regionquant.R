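#' Chromatin and cytoplasm masks from the DNA channel
#'
#' Segments the mitotic chromatin of one cell from its DNA (Hoechst) channel:
#' the channel is Gaussian-smoothed, thresholded with the iterative-intermeans
#' method, and the largest connected component is kept as the chromatin mask.
#' The cytoplasm mask is the cell extent minus a small dilation of the
#' chromatin, so the two masks are disjoint by construction and the cytoplasm
#' mean is not contaminated by out-of-focus chromatin edge signal.
#'
#' @param dna_channel numeric matrix, the projected DNA channel.
#' @param cell_extent optional logical matrix marking the whole cell (from a
#'   whole-cell channel threshold); by default the crop bounds minus a border
#'   margin.
#' @param smooth_sigma Gaussian pre-smoothing sigma, px (default 1).
#' @param dilate_px chromatin dilation radius before subtraction (default 2).
#' @param border_margin_px margin excluded from the default cell extent
#'   (default 10).
#' @param cell_id identifier carried on the result.
#' @return A `RegionMasks`: list with logical `chromatin` and `cytoplasm`
#'   masks (disjoint, both non-empty) and `threshold_value`.
#' @export
make_region_masks <- function(dna_channel, cell_extent = NULL,
                              smooth_sigma = 1, dilate_px = 2L,
                              border_margin_px = 10L, cell_id = "") {
  if (!is.matrix(dna_channel)) stop("dna_channel must be a 2-d matrix")
  ny <- nrow(dna_channel); nx <- ncol(dna_channel)
  sm <- if (smooth_sigma > 0)
    as.matrix(EBImage::gblur(dna_channel, sigma = smooth_sigma))
  else dna_channel
  thr <- isodata_threshold(sm)
  fg <- sm > thr
  if (!any(fg)) stop("empty chromatin mask")
  lab <- EBImage::bwlabel(fg)
  tab <- tabulate(as.integer(lab))
  chromatin <- matrix(as.integer(lab) == which.max(tab), ny, nx)
  if (is.null(cell_extent)) {
    cell_extent <- matrix(FALSE, ny, nx)
    m <- border_margin_px
    cell_extent[(m + 1L):(ny - m), (m + 1L):(nx - m)] <- TRUE
  }
  grown <- if (dilate_px >= 1L)
    dilate_disc(chromatin * 1, dilate_px) > 0.5
  else chromatin
  cytoplasm <- cell_extent & !grown
  if (!any(cytoplasm)) stop("empty cytoplasm mask")
  structure(list(chromatin = chromatin, cytoplasm = cytoplasm,
                 threshold_value = thr, cell_id = cell_id),
            class = "RegionMasks")
}

#' Region-level signal measurement with cytoplasmic correction
#'
#' Measures chromatin-associated signal per channel for one cell. Channels of
#' class `"corrected"` (CPC subunits, Aurora B) are background-corrected by
#' subtracting the mean cytoplasmic signal, with negative values set to zero;
#' channels of class `"uncorrected"` (H3pS10, which is chromatin-intrinsic)
#' use the raw chromatin mean. All values are then normalised by the mean DNA
#' signal over the chromatin mask, which compensates for differences in
#' chromatin content and staining between cells.
#'
#' @param projection an `ImageStack` with a singleton z axis and a `dna`
#'   role.
#' @param masks a `RegionMasks`.
#' @param channel_class_map named character vector mapping measured roles to
#'   `"corrected"` or `"uncorrected"`.
#' @return A `RegionMeasurement`: data frame with one row per measured
#'   channel (`role`, `class`, `chromatin_mean`, `cytoplasm_mean`,
#'   `corrected`, `dna_mean`, `normalized`) and a `valid` attribute
#'   (`FALSE` when the DNA mean is not positive).
#' @export
measure_region <- function(projection, masks, channel_class_map) {
  stopifnot(inherits(projection, "ImageStack"), inherits(masks, "RegionMasks"))
  if (dim(projection$pixels)[2L] != 1L)
    stop("measure_region expects a projected (single z) stack")
  roles <- projection$channel_roles
  if (is.null(roles) || !("dna" %in% names(roles)))
    stop("projection must map a dna channel")
  if (any(!names(channel_class_map) %in% names(roles)))
    stop("channel_class_map names a role absent from the stack")
  if (any(!channel_class_map %in% c("corrected", "uncorrected")))
    stop("channel classes must be 'corrected' or 'uncorrected'")
  dna <- get_channel(projection, "dna")
  dna_mean <- mean(dna[masks$chromatin])
  rows <- lapply(names(channel_class_map), function(role) {
    m <- get_channel(projection, role)
    cm <- mean(m[masks$chromatin])
    cy <- mean(m[masks$cytoplasm])
    corr <- if (channel_class_map[[role]] == "corrected")
      max(cm - cy, 0) else cm
    data.frame(role = role, class = channel_class_map[[role]],
               chromatin_mean = cm, cytoplasm_mean = cy,
               corrected = corr, dna_mean = dna_mean,
               normalized = if (dna_mean > 0) corr / dna_mean else NA_real_)
  })
  df <- do.call(rbind, rows)
  attr(df, "valid") <- dna_mean > 0
  class(df) <- c("RegionMeasurement", "data.frame")
  df
}

#' Scale per-cell measurements to the control-condition mean
#'
#' Divides every value by the mean of the control group, so the control mean
#' maps to exactly 1 and other conditions read as fold changes relative to
#' control.
#'
#' @param values numeric vector of per-cell normalized values.
#' @param condition character/factor vector of condition labels, same length.
#' @param control_label the label of the control condition.
#' @return numeric vector of scaled values.
#' @export
scale_to_control <- function(values, condition, control_label) {
  stopifnot(length(values) == length(condition))
  ctrl <- values[condition == control_label]
  if (length(ctrl) == 0L) stop("control group is empty")
  m <- mean(ctrl)
  if (!is.finite(m) || m <= 0) stop("control-group mean must be positive")
  values / m
}
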