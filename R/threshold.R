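#' Iterative-intermeans (isodata) threshold
#'
#' Computes the classical fixed-point intensity threshold: starting from the
#' global mean, the threshold is repeatedly replaced by the average of the
#' mean of the pixels at or below it and the mean of the pixels above it,
#' until it moves by less than `eps`. At the fixed point the threshold lies
#' halfway between the two class means, which is the usual criterion for
#' separating bright foreground (kinetochore or chromatin signal) from
#' background.
#'
#' @param values numeric vector, matrix or array of intensities with at least
#'   two distinct values.
#' @param eps convergence tolerance. Default: 0.5 intensity units for
#'   integer-valued input, `1e-6 * diff(range(values))` otherwise.
#' @param max_iter iteration cap (the iteration normally converges in a
#'   handful of steps).
#' @return the converged threshold (a single number). Pixels strictly above
#'   it are foreground under the conventions used elsewhere in the package.
#' @export
isodata_threshold <- function(values, eps = NULL, max_iter = 1000L) {
  v <- as.numeric(values)
  v <- v[is.finite(v)]
  if (length(v) < 2L || diff(range(v)) == 0)
    stop("degenerate input: need at least two distinct intensity values")
  if (is.null(eps)) {
    eps <- if (all(v == round(v))) 0.5 else 1e-6 * diff(range(v))
  }
  t_cur <- mean(v)
  for (i in seq_len(max_iter)) {
    lo <- v[v <= t_cur]
    hi <- v[v > t_cur]
    if (length(hi) == 0L || length(lo) == 0L) break
    t_new <- (mean(lo) + mean(hi)) / 2
    if (abs(t_new - t_cur) < eps) return(t_new)
    t_cur <- t_new
  }
  t_cur
}
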