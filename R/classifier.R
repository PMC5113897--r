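#' Fit the final reduced-panel classifier
#'
#' Once a panel has been selected, this fits the persistable production
#' classifier: a random forest on the training cohort restricted to the
#' panel, carrying metadata (training cohort id, forest settings,
#' normalization mode) so queries can be checked for compatibility. Query
#' matrices must be normalized the same way as the training data; RNA-seq
#' queries against microarray-trained panels should use rank scores
#' (`normalization = "rank"`).
#'
#' @param train cohort list (`expr`, `labels`).
#' @param panel character vector of gene symbols.
#' @param config a [forest_config()].
#' @param normalization string recorded in the metadata:
#'   `"quantile"`, `"rank"`, or `"none"`.
#' @return An object of class `panel_rf`.
#' @export
fit_panel_classifier <- function(train, panel, config = forest_config(),
                                 normalization = c("quantile", "rank", "none")) {
  normalization <- match.arg(normalization)
  model <- train_subset_model(train, panel, config)
  structure(list(model = model, panel = model$panel,
                 classes = model$classes,
                 meta = list(training_cohort = train$expr$batch_id,
                             trees = config$trees, mtry = config$mtry,
                             seed = config$seed,
                             normalization = normalization)),
            class = "panel_rf")
}

#' @export
print.panel_rf <- function(x, ...) {
  cat(sprintf("reduced-panel classifier: %d genes, classes {%s}\n",
              length(x$panel), paste(x$classes, collapse = ", ")))
  cat(sprintf("trained on '%s' (%d trees, %s normalization)\n",
              x$meta$training_cohort, x$meta$trees, x$meta$normalization))
  invisible(x)
}

#' Classify query samples with a reduced-panel classifier
#'
#' Each query sample receives the majority tree vote; `type = "votes"`
#' returns the per-class vote fractions (each row sums to 1). Every panel
#' gene must be present in the query (extra genes are ignored); missing
#' genes are a hard error rather than being imputed.
#'
#' @param object a `panel_rf`.
#' @param newdata an `expr_matrix`.
#' @param type `"class"`, `"votes"`, or `"table"` (data.frame with labels
#'   and vote fractions, the export format of the `classify` CLI).
#' @param ... unused.
#' @export
predict.panel_rf <- function(object, newdata,
                             type = c("class", "votes", "table"), ...) {
  type <- match.arg(type)
  if (type != "table") return(predict(object$model, newdata, type = type))
  labels <- predict(object$model, newdata, type = "class")
  votes <- predict(object$model, newdata, type = "votes")
  data.frame(sample_id = names(labels), predicted_class = unname(labels),
             votes, check.names = FALSE, row.names = NULL)
}

#' Persist / restore a reduced-panel classifier
#'
#' The model directory holds the gene list as plain text (the compatibility
#' contract), the configuration as JSON, and the serialized forest (an RDS
#' blob, versioned with the package).
#'
#' @param object a `panel_rf`.
#' @param dir directory to create/populate.
#' @return `save_panel_classifier` returns `dir` invisibly;
#'   `load_panel_classifier` returns the restored `panel_rf`.
#' @export
save_panel_classifier <- function(object, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  writeLines(object$panel, file.path(dir, "panel.txt"))
  jsonlite::write_json(c(object$meta, list(classes = object$classes)),
                       file.path(dir, "config.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  saveRDS(object, file.path(dir, "model.rds"))
  invisible(dir)
}

#' @rdname save_panel_classifier
#' @export
load_panel_classifier <- function(dir) {
  path <- file.path(dir, "model.rds")
  if (!file.exists(path)) stop("no model.rds under ", dir)
  obj <- readRDS(path)
  if (!inherits(obj, "panel_rf")) stop("model.rds is not a panel_rf object")
  obj
}

#' Nearest-centroid reference labeler
#'
#' A simple centroid classifier used as plumbing to produce reference
#' labels when an external full-signature classification is not available:
#' each query sample is assigned the class of the nearest per-class mean
#' expression profile, under euclidean or Pearson-correlation distance.
#' Ties go to the first class in label-set order.
#'
#' @param train cohort list (`expr`, `labels`); every class needs at least
#'   one training sample.
#' @param query an `expr_matrix` sharing the training gene set.
#' @param metric `"euclidean"` or `"pearson"` (distance = 1 - correlation).
#' @return Named character vector, sample id -> class.
#' @export
nearest_centroid_labels <- function(train, query,
                                    metric = c("euclidean", "pearson")) {
  metric <- match.arg(metric)
  shared <- intersect(genes(train$expr), genes(query))
  if (length(shared) == 0L) stop("train and query share no genes")
  y <- if (is.factor(train$labels)) train$labels else factor(train$labels)
  if (any(table(y) == 0L))
    stop("class with 0 training samples: ",
         paste(levels(y)[table(y) == 0L], collapse = ", "))
  tv <- train$expr$values[shared, names(train$labels), drop = FALSE]
  centroids <- matrix(
    vapply(levels(y), function(cl)
      rowMeans(tv[, y == cl, drop = FALSE]), numeric(length(shared))),
    nrow = length(shared), dimnames = list(shared, levels(y)))
  qv <- query$values[shared, , drop = FALSE]
  d <- if (metric == "euclidean") {
    vapply(seq_len(nlevels(y)), function(j)
      colSums((qv - centroids[, j])^2), numeric(ncol(qv)))
  } else {
    1 - stats::cor(qv, centroids)
  }
  d <- matrix(d, nrow = ncol(qv))
  picks <- apply(d, 1L, which.min)  # which.min: first class on ties
  stats::setNames(levels(y)[picks], colnames(qv))
}
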