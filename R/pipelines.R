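#' Run the region pipeline over a set of cell images
#'
#' For each image: sum-project, build chromatin/cytoplasm masks from the DNA
#' channel, measure the mapped channels, and collect the DNA-normalised
#' values into one long table ready for [scale_to_control()] and
#' [kruskal_dunn()].
#'
#' @param images named list of `ImageStack`s (names become `cell_id`).
#' @param channel_class_map named character vector, role ->
#'   `"corrected"`/`"uncorrected"` (see [measure_region()]).
#' @param ... passed to [make_region_masks()].
#' @return data frame: `cell_id`, `condition`, `role`, `normalized`.
#' @export
quantify_regions <- function(images, channel_class_map, ...) {
  rows <- lapply(names(images), function(id) {
    proj <- sum_project(images[[id]])
    masks <- make_region_masks(get_channel(proj, "dna"), cell_id = id, ...)
    rm <- measure_region(proj, masks, channel_class_map)
    data.frame(cell_id = id, condition = images[[id]]$condition_label,
               role = rm$role, normalized = rm$normalized)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Run the kinetochore-spot pipeline over a set of cell images
#'
#' Applies [quantify_cell()] to each image and collects the per-cell mean
#' ratios (measured channel over reference) into one long table, one row per
#' cell and channel role.
#'
#' @param images named list of `ImageStack`s (names become `cell_id`).
#' @param ... passed to [quantify_cell()].
#' @return data frame: `cell_id`, `condition`, `role`, `mean_ratio`,
#'   `n_kinetochores`, `n_excluded`.
#' @export
quantify_spot_dataset <- function(images, ...) {
  rows <- lapply(names(images), function(id) {
    cs <- quantify_cell(images[[id]], cell_id = id, ...)
    if (is.null(cs$mean_ratio)) return(NULL)
    data.frame(cell_id = id, condition = images[[id]]$condition_label,
               role = names(cs$mean_ratio),
               mean_ratio = as.numeric(cs$mean_ratio),
               n_kinetochores = cs$n_kinetochores,
               n_excluded = cs$n_excluded)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

#' Measure all pairs of a distance dataset
#'
#' Applies [measure_pair_distance()] to each stack of a
#' [make_distance_dataset()] result and returns the recovered distances.
#'
#' @param dataset result of [make_distance_dataset()].
#' @param ... passed to [measure_pair_distance()].
#' @return data frame: `pair_id`, `true_um`, `measured_um`.
#' @export
measure_distance_dataset <- function(dataset, ...) {
  rows <- lapply(seq_along(dataset$stacks), function(i) {
    dm <- measure_pair_distance(dataset$stacks[[i]], role = "outer_kt", ...)
    data.frame(pair_id = i, true_um = dataset$truth$separation_um[i],
               measured_um = dm$value_um)
  })
  do.call(rbind, rows)
}
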