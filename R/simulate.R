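#' Simulate multi-cohort labelled expression data with planted markers
#'
#' Generates the statistical structure the panel search is designed for:
#' several cohorts of log-intensity expression over a shared gene universe,
#' a handful of class-informative genes among many noise genes, per-sample
#' class labels, and cohort-aligned batch effects (one batch per cohort, as
#' when each cohort comes from a different platform).
#'
#' Each gene gets a baseline level drawn from Normal(7, 1) (a typical
#' log2-intensity scale). An informative gene is a subtype-marker: one
#' "up" class, drawn at random, is shifted by `delta * noise_sd` above
#' baseline; all samples then receive Normal noise with sd `noise_sd`.
#' Noise genes ignore class entirely. Cohort `i` is distorted by
#' `values * batch_scale[i] + batch_offset[i]` before being returned, so
#' batch adjustment has real structure to remove.
#'
#' Cohort 1 is the training cohort, the last cohort is the holdout (when
#' `n_cohorts >= 3`), and the rest are evaluation cohorts.
#'
#' @param n_cohorts number of cohorts (>= 2).
#' @param n_classes number of classes (default 4, as in four-subtype tumor
#'   classification).
#' @param n_informative,n_noise informative / noise gene counts
#'   (defaults 40 / 160).
#' @param samples_per_class samples per class in every cohort (default 15).
#' @param delta class-mean shift in units of `noise_sd` (default 2).
#' @param noise_sd within-class standard deviation (default 1).
#' @param batch_offsets additive per-cohort shifts; default `0.5 * (i - 1)`.
#' @param batch_scales multiplicative per-cohort factors; default all 1.
#' @param seed integer seed; identical seeds give identical data.
#' @return A list with `cohorts` (a `cohort_collection`) and `truth`
#'   (list: `informative`, `up_class` per informative gene, `class_means`
#'   gene-by-class matrix before batch distortion, `labels` per cohort,
#'   `informative_fraction`).
#' @export
simulate_cohorts <- function(n_cohorts = 3L, n_classes = 4L,
                             n_informative = 40L, n_noise = 160L,
                             samples_per_class = 15L, delta = 2,
                             noise_sd = 1, batch_offsets = NULL,
                             batch_scales = NULL, seed = 1L) {
  if (n_cohorts < 2L) stop("need >= 2 cohorts (one training, >= 1 evaluation)")
  if (n_classes < 2L) stop("need >= 2 classes")
  if (n_informative < 1L || n_noise < 0L || samples_per_class < 1L)
    stop("counts must be positive")
  if (delta < 0 || noise_sd <= 0) stop("need delta >= 0 and noise_sd > 0")
  batch_offsets <- batch_offsets %||% (0.5 * (seq_len(n_cohorts) - 1))
  batch_scales <- batch_scales %||% rep(1, n_cohorts)
  if (length(batch_offsets) != n_cohorts || length(batch_scales) != n_cohorts)
    stop("batch_offsets/batch_scales must have one entry per cohort")
  set.seed(as.integer(seed))
  n_genes <- n_informative + n_noise
  gene_ids <- sprintf("g%04d", seq_len(n_genes))
  classes <- paste0("class", seq_len(n_classes))
  informative <- sort(sample(gene_ids, n_informative))
  up_class <- stats::setNames(sample(classes, n_informative, replace = TRUE),
                              informative)
  baseline <- stats::setNames(stats::rnorm(n_genes, mean = 7, sd = 1), gene_ids)
  class_means <- matrix(baseline, nrow = n_genes, ncol = n_classes,
                        dimnames = list(gene_ids, classes))
  class_means[cbind(informative, up_class)] <-
    class_means[cbind(informative, up_class)] + delta * noise_sd
  n_per <- samples_per_class * n_classes
  make_cohort <- function(i) {
    labels <- stats::setNames(rep(classes, each = samples_per_class),
                              sprintf("c%d_s%03d", i, seq_len(n_per)))
    mu <- class_means[, labels, drop = FALSE]
    vals <- mu + matrix(stats::rnorm(n_genes * n_per, sd = noise_sd),
                        nrow = n_genes)
    vals <- vals * batch_scales[i] + batch_offsets[i]
    dimnames(vals) <- list(gene_ids, names(labels))
    list(expr = expression_matrix(vals, batch_id = sprintf("cohort%d", i)),
         labels = labels)
  }
  cos <- lapply(seq_len(n_cohorts), make_cohort)
  holdout <- if (n_cohorts >= 3L) cos[[n_cohorts]] else NULL
  n_eval <- if (n_cohorts >= 3L) n_cohorts - 1L else n_cohorts
  cohorts <- cohort_collection(training = cos[[1L]],
                               evaluation = cos[2:n_eval],
                               holdout = holdout)
  truth <- list(informative = informative, up_class = up_class,
                class_means = class_means,
                labels = lapply(cos, `[[`, "labels"),
                informative_fraction = n_informative / n_genes)
  list(cohorts = cohorts, truth = truth)
}

#' How well a selected panel recovers the planted informative genes
#'
#' Precision is the fraction of panel genes that are truly informative;
#' enrichment is that precision divided by the informative fraction of the
#' whole gene universe, so enrichment > 1 means the search concentrated
#' signal genes beyond what random sampling of the pool would give.
#'
#' @param panel character vector of selected gene symbols.
#' @param truth the `truth` component of [simulate_cohorts()].
#' @return List with `precision` and `enrichment`.
#' @export
planted_recovery_score <- function(panel, truth) {
  precision <- mean(panel %in% truth$informative)
  list(precision = precision,
       enrichment = precision / truth$informative_fraction)
}
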