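#' Random-model accuracy as a function of panel size
#'
#' For each candidate size, draws `n_models` random gene panels from the
#' shared pool, trains a forest on each, and records the mean pooled
#' concordance with the reference labels. The resulting curve rises steeply
#' for small panels and flattens once additional genes stop adding
#' information; its smoothed form (see [smooth_curve()]) drives the
#' marginal-gain choice of the panel size.
#'
#' Scoring uses the evaluation cohorts by default; `include_holdout = TRUE`
#' additionally pools the holdout samples for strict replication of designs
#' that sized the panel on every available sample.
#'
#' @param cohorts a preprocessed `cohort_collection`.
#' @param sizes increasing integer grid of candidate panel sizes
#'   (production setting: `2:60`).
#' @param n_models random panels per size (production setting: 1000).
#' @param trees trees per forest.
#' @param mtry variables per split (`NULL` = sqrt rule).
#' @param seed integer seed.
#' @param include_holdout also score the holdout cohort's samples.
#' @return An object of class `panel_size_curve`: `sizes`, `mean_accuracy`
#'   (fractions in \[0,1\]), `n_models`, `smoothed` (NULL until smoothed),
#'   `selected_k` (NA until selected).
#' @export
random_model_curve <- function(cohorts, sizes = 2:60, n_models = 1000L,
                               trees = 5000L, mtry = NULL, seed = 1L,
                               include_holdout = FALSE) {
  sizes <- as.integer(sizes)
  if (is.unsorted(sizes, strictly = TRUE))
    stop("`sizes` must be strictly increasing")
  pool <- genes(cohorts$training$expr)
  if (max(sizes) > length(pool))
    stop("largest size (", max(sizes), ") exceeds the pool (", length(pool), ")")
  score_cohorts <- cohorts
  if (include_holdout && !is.null(cohorts$holdout)) {
    score_cohorts$evaluation <- c(cohorts$evaluation, list(cohorts$holdout))
    score_cohorts$holdout <- NULL
  }
  set.seed(as.integer(seed))
  mean_acc <- vapply(sizes, function(s) {
    # draw all seeds and panels for this size up front, so the sampling
    # stream is independent of forest internals
    panel_seeds <- sample.int(.Machine$integer.max - 1L, n_models)
    panels <- lapply(seq_len(n_models), function(i) sample(pool, s))
    mean(vapply(seq_len(n_models), function(i)
      evaluate_subset(panels[[i]], score_cohorts,
                      forest_config(trees = trees, mtry = mtry,
                                    seed = panel_seeds[i]))$pooled,
      numeric(1)))
  }, numeric(1))
  structure(list(sizes = sizes, mean_accuracy = mean_acc,
                 n_models = as.integer(n_models), smoothed = NULL,
                 selected_k = NA_integer_),
            class = "panel_size_curve")
}

#' Smooth a panel-size curve by local polynomial regression
#'
#' Fits a degree-2 loess of mean accuracy against size and stores the
#' fitted values at the grid sizes. Smoothing suppresses the sampling noise
#' of the random panels so the marginal gain per added gene can be read off
#' the fitted curve.
#'
#' @param curve a `panel_size_curve` with at least 5 sizes.
#' @param span loess span (default 0.75).
#' @param degree local polynomial degree (default 2).
#' @return The curve with `smoothed` filled in.
#' @export
smooth_curve <- function(curve, span = 0.75, degree = 2L) {
  if (length(curve$sizes) < 5L)
    stop("need at least 5 sizes to smooth the curve")
  fit <- stats::loess(acc ~ size,
                      data = data.frame(size = curve$sizes,
                                        acc = curve$mean_accuracy),
                      span = span, degree = degree,
                      control = stats::loess.control(surface = "direct"))
  curve$smoothed <- as.numeric(stats::predict(fit, curve$sizes))
  curve
}

#' Choose the panel size by the marginal-gain rule
#'
#' Walks the smoothed curve's forward differences and selects the largest
#' grid size reached before the first gain below `gain_threshold` percentage
#' points of accuracy per additional step -- i.e. genes keep being added
#' only while each step still improves the smoothed mean model accuracy by
#' at least the threshold. If every gain is sub-threshold the smallest grid
#' size is returned with a warning.
#'
#' @param curve a smoothed `panel_size_curve`.
#' @param gain_threshold minimum gain per step, in percentage points
#'   (default 0.001).
#' @return The selected size (integer); also stored in `curve$selected_k`
#'   when you keep the returned attribute `"curve"`.
#' @export
select_panel_size <- function(curve, gain_threshold = 0.001) {
  if (is.null(curve$smoothed))
    stop("curve has no smoothed values; call smooth_curve() first")
  gains_pp <- diff(curve$smoothed) * 100
  below <- which(gains_pp < gain_threshold)
  if (length(below) == 0L) {
    k <- curve$sizes[length(curve$sizes)]
  } else {
    if (length(below) == length(gains_pp))
      warning("all marginal gains are below the threshold; ",
              "selecting the smallest grid size")
    k <- curve$sizes[min(below)]
  }
  as.integer(k)
}

#' Full panel-size selection pipeline
#'
#' Convenience wrapper: [random_model_curve()] then [smooth_curve()] then
#' [select_panel_size()], returning the curve with `smoothed` and
#' `selected_k` populated.
#'
#' @inheritParams random_model_curve
#' @inheritParams smooth_curve
#' @inheritParams select_panel_size
#' @return A `panel_size_curve` with `selected_k` set.
#' @export
panel_size_curve <- function(cohorts, sizes = 2:60, n_models = 1000L,
                             trees = 5000L, mtry = NULL, seed = 1L,
                             include_holdout = FALSE, span = 0.75,
                             gain_threshold = 0.001) {
  curve <- random_model_curve(cohorts, sizes = sizes, n_models = n_models,
                              trees = trees, mtry = mtry, seed = seed,
                              include_holdout = include_holdout)
  curve <- smooth_curve(curve, span = span)
  curve$selected_k <- select_panel_size(curve, gain_threshold)
  curve
}

#' @export
print.panel_size_curve <- function(x, ...) {
  cat(sprintf("panel-size curve: sizes %d..%d, %d random models/size\n",
              min(x$sizes), max(x$sizes), x$n_models))
  cat(sprintf("mean accuracy range: %.4f .. %.4f%s\n",
              min(x$mean_accuracy), max(x$mean_accuracy),
              if (is.null(x$smoothed)) " (unsmoothed)" else ""))
  if (!is.na(x$selected_k))
    cat(sprintf("selected panel size: %d\n", x$selected_k))
  invisible(x)
}

#' Plot a panel-size curve
#'
#' Raw per-size mean accuracies as points, the loess fit as a line, and the
#' selected size (when set) as a dotted drop line.
#'
#' @param x a `panel_size_curve`.
#' @param ... passed to [graphics::plot()].
#' @export
plot.panel_size_curve <- function(x, ...) {
  graphics::plot(x$sizes, x$mean_accuracy, pch = 16, cex = 0.7,
                 xlab = "panel size (genes)",
                 ylab = "mean random-model concordance", ...)
  if (!is.null(x$smoothed))
    graphics::lines(x$sizes, x$smoothed, lwd = 2)
  if (!is.na(x$selected_k)) {
    graphics::abline(v = x$selected_k, lty = 3)
    graphics::mtext(sprintf("k = %d", x$selected_k), side = 3, at = x$selected_k,
                    cex = 0.8)
  }
  invisible(x)
}
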