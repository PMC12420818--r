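#' Significance stars for a p-value
#'
#' Maps a p-value to the conventional star labels: `ns` for p > 0.05, `*`
#' for p < 0.05, `**` for p < 0.01, `***` for p < 0.001 and `****` for
#' p < 0.0001. A p-value exactly equal to a threshold is assigned the weaker
#' category (p = 0.05 is `ns`).
#'
#' @param p p-value(s) in `[0, 1]`.
#' @return character vector of labels.
#' @export
stars <- function(p) {
  if (any(!is.finite(p) | p < 0 | p > 1)) stop("p must lie in [0, 1]")
  out <- rep("ns", length(p))
  out[p < 0.05]   <- "*"
  out[p < 0.01]   <- "**"
  out[p < 0.001]  <- "***"
  out[p < 0.0001] <- "****"
  out
}

#' Two-tailed unpaired Student's t-test
#'
#' Classical pooled-variance two-sample t-test, two-tailed, used for
#' comparing distance measurements between mitotic stages. Degenerate inputs
#' are handled by convention: zero pooled variance with equal means gives
#' p = 1; zero pooled variance with unequal means gives p = 0 and is flagged
#' degenerate.
#'
#' @param groupA,groupB numeric samples with >= 2 values each.
#' @param labels length-2 character vector of group names.
#' @return A `StatResult`: list with `test_name`, `groups`, `statistic` (t),
#'   `p_value`, `stars`, `n`, `mean`, `sd` and `degenerate`.
#' @export
unpaired_ttest <- function(groupA, groupB, labels = c("A", "B")) {
  a <- as.numeric(groupA); b <- as.numeric(groupB)
  if (length(a) < 2L || length(b) < 2L) stop("each group needs n >= 2")
  degenerate <- FALSE
  if (stats::var(a) == 0 && stats::var(b) == 0) {
    if (mean(a) == mean(b)) {
      tt <- 0; p <- 1
    } else {
      tt <- sign(mean(a) - mean(b)) * Inf; p <- 0; degenerate <- TRUE
    }
  } else {
    ht <- stats::t.test(a, b, var.equal = TRUE)
    tt <- unname(ht$statistic); p <- ht$p.value
  }
  structure(list(test_name = "two-tailed unpaired t-test (pooled variance)",
                 groups = labels, statistic = tt, p_value = p,
                 stars = stars(p), n = c(length(a), length(b)),
                 mean = c(mean(a), mean(b)),
                 sd = c(stats::sd(a), stats::sd(b)),
                 degenerate = degenerate),
            class = "StatResult")
}

#' Kruskal-Wallis test with Dunn's post hoc comparisons
#'
#' Nonparametric multi-group analysis for per-cell recruitment measurements:
#' an omnibus Kruskal-Wallis test (with tie correction on mid-ranks) followed
#' by Dunn's z-tests on the rank means for the requested group pairs, with
#' Bonferroni adjustment over the requested (planned) comparisons only.
#' Adjusted p-values are capped at 1.
#'
#' @param groups named list of numeric samples (>= 2 groups, every group
#'   non-empty, total n >= 3).
#' @param comparisons list of length-2 character vectors of group names, or
#'   strings `"a:b"`. Default: every group vs the first (control-style
#'   comparisons).
#' @return list with `kruskal` (a `StatResult` holding H and its p-value) and
#'   `dunn` (data frame: `group1`, `group2`, `z`, `p_value`, `adjusted_p`,
#'   `stars`, `n1`, `n2`).
#' @export
kruskal_dunn <- function(groups, comparisons = NULL) {
  if (is.null(names(groups)) || any(!nzchar(names(groups))))
    stop("groups must be a named list")
  if (length(groups) < 2L) stop("need >= 2 groups")
  n_i <- lengths(groups)
  if (any(n_i == 0L)) stop("empty group")
  N <- sum(n_i)
  if (N < 3L) stop("total n must be >= 3")
  values <- unlist(groups, use.names = FALSE)
  labels <- factor(rep(names(groups), n_i), levels = names(groups))
  kw <- stats::kruskal.test(values, labels)
  kres <- structure(list(test_name = "Kruskal-Wallis rank sum test",
                         groups = names(groups),
                         statistic = unname(kw$statistic),
                         p_value = kw$p.value,
                         stars = stars(kw$p.value),
                         n = as.integer(n_i)),
                    class = "StatResult")
  if (is.null(comparisons))
    comparisons <- lapply(names(groups)[-1L],
                          function(g) c(names(groups)[1L], g))
  comparisons <- lapply(comparisons, function(cmp) {
    if (is.character(cmp) && length(cmp) == 1L)
      cmp <- strsplit(cmp, ":", fixed = TRUE)[[1L]]
    if (length(cmp) != 2L || any(!cmp %in% names(groups)))
      stop("each comparison must name two existing groups")
    cmp
  })
  r <- rank(values)                      # mid-ranks
  rbar <- tapply(r, labels, mean)
  ties <- table(values)
  tie_term <- sum(ties^3 - ties) / (12 * (N - 1))
  s2 <- N * (N + 1) / 12 - tie_term      # variance factor with tie correction
  m <- length(comparisons)
  dunn <- do.call(rbind, lapply(comparisons, function(cmp) {
    se <- sqrt(s2 * (1 / n_i[[cmp[1L]]] + 1 / n_i[[cmp[2L]]]))
    z <- (rbar[[cmp[1L]]] - rbar[[cmp[2L]]]) / se
    p <- 2 * stats::pnorm(-abs(z))
    data.frame(group1 = cmp[1L], group2 = cmp[2L], z = z, p_value = p,
               adjusted_p = min(p * m, 1),
               n1 = n_i[[cmp[1L]]], n2 = n_i[[cmp[2L]]])
  }))
  dunn$stars <- stars(dunn$adjusted_p)
  list(kruskal = kres, dunn = dunn)
}

#' Aggregate measurements to the declared replicate level
#'
#' Recruitment analyses treat each cell as one biological replicate, so
#' kinetochore-level values are averaged per cell before testing; distance
#' analyses treat each kinetochore pair as a replicate, so pair-level values
#' pass through unchanged.
#'
#' @param measurements data frame with columns `condition`, `value`, and
#'   `cell_id` (plus `pair_id` for pair-level data).
#' @param level `"cell"` or `"kinetochore_pair"`.
#' @return data frame with one row per replicate: `condition`, replicate id,
#'   `value`, and (for cell level) `n_obs` averaged per replicate.
#' @export
replicate_table <- function(measurements, level = c("cell", "kinetochore_pair")) {
  level <- match.arg(level)
  req <- c("condition", "value",
           if (level == "cell") "cell_id" else c("cell_id", "pair_id"))
  if (any(!req %in% names(measurements)))
    stop(sprintf("measurements must have columns: %s",
                 paste(req, collapse = ", ")))
  if (level == "cell") {
    ag <- stats::aggregate(value ~ condition + cell_id, data = measurements,
                           FUN = mean)
    cnt <- stats::aggregate(value ~ condition + cell_id, data = measurements,
                            FUN = length)
    ag$n_obs <- cnt$value
    ag[order(ag$condition, ag$cell_id), , drop = FALSE]
  } else {
    out <- measurements[, c("condition", "cell_id", "pair_id", "value")]
    out[order(out$condition, out$cell_id, out$pair_id), , drop = FALSE]
  }
}

#' @export
print.StatResult <- function(x, ...) {
  cat(x$test_name, "\n")
  cat("  groups:", paste(x$groups, collapse = ", "),
      " n =", paste(x$n, collapse = ", "), "\n")
  cat(sprintf("  statistic = %.4g, p = %.4g (%s)\n",
              x$statistic, x$p_value, x$stars))
  invisible(x)
}
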