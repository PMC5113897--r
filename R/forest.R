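#' Forest configuration for panel fitness models
#'
#' All forests in a run are built identically: `trees` trees (default 5000,
#' the production setting; tests and quick exploration typically use far
#' fewer) and `mtry` variables tried at each split, defaulting to
#' `floor(sqrt(panel size))` -- the standard classification default of the
#' randomForest implementation.
#'
#' @param trees number of trees per forest (>= 1).
#' @param mtry variables sampled at each node, or `NULL` for the sqrt rule.
#' @param seed integer seed for forest construction.
#' @return A list of class `forest_config`.
#' @importFrom randomForest randomForest
#' @importFrom limma normalizeQuantiles
#' @export
forest_config <- function(trees = 5000L, mtry = NULL, seed = 1L) {
  trees <- as.integer(trees)
  if (is.na(trees) || trees < 1L) stop("`trees` must be >= 1")
  if (!is.null(mtry)) {
    mtry <- as.integer(mtry)
    if (is.na(mtry) || mtry < 1L) stop("`mtry` must be >= 1 or NULL")
  }
  structure(list(trees = trees, mtry = mtry, seed = as.integer(seed)),
            class = "forest_config")
}

resolve_mtry <- function(config, panel_size) {
  m <- config$mtry %||% floor(sqrt(panel_size))
  if (m > panel_size)
    stop("mtry (", m, ") exceeds panel size (", panel_size, ")")
  as.integer(max(1L, m))
}

#' Train a random forest restricted to a gene panel
#'
#' Builds the per-panel classifier scored by the genetic algorithm: a
#' random forest on the training cohort using only the panel's rows. Panel
#' genes are sorted internally so the fit does not depend on the order the
#' genes are listed. Deterministic given `config$seed`.
#'
#' @param train cohort list with `expr` (`expr_matrix`) and `labels`
#'   (named character, sample id -> class); at least 2 classes.
#' @param panel character vector of gene symbols, all present in `train`.
#' @param config a [forest_config()].
#' @return A list of class `subset_model` with the fitted forest, the
#'   (sorted) panel, and the class levels.
#' @export
train_subset_model <- function(train, panel, config = forest_config()) {
  panel <- sort(unique(as.character(panel)))
  missing <- setdiff(panel, genes(train$expr))
  if (length(missing) > 0L)
    stop("panel gene(s) absent from training matrix: ",
         paste(missing, collapse = ", "))
  ids <- names(train$labels)
  y <- factor(train$labels[ids])
  if (nlevels(y) < 2L) stop("training labels must contain >= 2 classes")
  if (any(table(y) == 0L))
    stop("class with 0 training samples: ",
         paste(levels(y)[table(y) == 0L], collapse = ", "))
  x <- t(train$expr$values[panel, ids, drop = FALSE])
  set.seed(config$seed)
  fit <- randomForest::randomForest(x = x, y = y, ntree = config$trees,
                                    mtry = resolve_mtry(config, length(panel)))
  structure(list(forest = fit, panel = panel, classes = levels(y),
                 config = config), class = "subset_model")
}

#' Predict class labels for a query matrix with a subset model
#'
#' @param object a `subset_model`.
#' @param query an `expr_matrix` containing every panel gene (extra genes
#'   are ignored).
#' @param type `"class"` for labels, `"votes"` for the per-class tree vote
#'   fractions (rows sum to 1).
#' @param ... unused.
#' @return Named character vector of labels, or a vote-fraction matrix.
#' @export
predict.subset_model <- function(object, query, type = c("class", "votes"), ...) {
  type <- match.arg(type)
  missing <- setdiff(object$panel, genes(query))
  if (length(missing) > 0L)
    stop("panel gene(s) absent from query matrix: ",
         paste(missing, collapse = ", "))
  newx <- t(query$values[object$panel, , drop = FALSE])
  if (type == "class") {
    p <- stats::predict(object$forest, newdata = newx, type = "response")
    stats::setNames(as.character(p), rownames(newx))
  } else {
    v <- stats::predict(object$forest, newdata = newx, type = "vote",
                        norm.votes = TRUE)
    v[rownames(newx), , drop = FALSE]
  }
}

#' Classification concordance between two label vectors
#'
#' The fitness currency of the whole framework: the fraction of samples for
#' which the reduced-panel prediction is identical to the reference
#' (full-signature) classification.
#'
#' @param predicted,reference named character vectors over the same sample
#'   id set.
#' @return Fraction in \[0, 1\].
#' @export
concordance <- function(predicted, reference) {
  if (!setequal(names(predicted), names(reference)))
    stop("predicted and reference cover different sample sets")
  ids <- names(reference)
  mean(predicted[ids] == reference[ids])
}

#' Score a gene panel's fitness over the evaluation cohorts
#'
#' Trains a forest on the training cohort, predicts every evaluation cohort,
#' and returns per-cohort concordances plus the pooled concordance over all
#' evaluation samples (total correct / total samples) -- the scalar the
#' genetic algorithm ranks panels by. The holdout cohort is never touched.
#'
#' @param panel character vector of gene symbols.
#' @param cohorts a `cohort_collection` (gene-intersected and normalized).
#' @param config a [forest_config()].
#' @return A list of class `fitness_record`: `panel`, `per_cohort`
#'   (named numeric), `pooled`, `n_samples`.
#' @export
evaluate_subset <- function(panel, cohorts, config = forest_config()) {
  if (length(cohorts$evaluation) == 0L)
    stop("no evaluation cohorts to score fitness on")
  model <- train_subset_model(cohorts$training, panel, config)
  correct <- 0; total <- 0
  per <- numeric(length(cohorts$evaluation))
  names(per) <- vapply(cohorts$evaluation, function(co) co$expr$batch_id, "")
  for (i in seq_along(cohorts$evaluation)) {
    co <- cohorts$evaluation[[i]]
    ids <- names(co$labels)
    pred <- predict(model, co$expr)[ids]
    per[i] <- mean(pred == co$labels[ids])
    correct <- correct + sum(pred == co$labels[ids])
    total <- total + length(ids)
  }
  structure(list(panel = model$panel, per_cohort = per,
                 pooled = correct / total, n_samples = total),
            class = "fitness_record")
}
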