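#' Quantile-normalize cohorts over their combined samples
#'
#' Columns of the column-bound combined matrix are forced onto a common
#' distribution (the per-rank mean across samples, with ties within a column
#' receiving the mean of the tied ranks' reference values), then split back
#' into the original cohorts. All matrices must share an identical gene set
#' and ordering (run [intersect_genes()] first).
#'
#' @param matrices list of `expr_matrix` objects with identical row order.
#' @return List of `expr_matrix` objects, same shapes and batch ids.
#' @export
quantile_normalize <- function(matrices) {
  if (inherits(matrices, "expr_matrix")) matrices <- list(matrices)
  gsets <- lapply(matrices, genes)
  if (!all(vapply(gsets, identical, TRUE, y = gsets[[1L]])))
    stop("matrices do not share an identical gene set and ordering")
  combined <- do.call(cbind, lapply(matrices, function(m) m$values))
  normed <- limma::normalizeQuantiles(combined, ties = TRUE)
  dimnames(normed) <- dimnames(combined)
  offsets <- cumsum(c(0L, vapply(matrices, function(m) ncol(m$values), 1L)))
  lapply(seq_along(matrices), function(i) {
    cols <- (offsets[i] + 1L):offsets[i + 1L]
    expression_matrix(normed[, cols, drop = FALSE],
                      batch_id = matrices[[i]]$batch_id)
  })
}

#' Adjust batch effects on a combined expression matrix
#'
#' The built-in `center_scale` mode is a location--scale standardization:
#' within each batch every gene is centred and scaled, then mapped back to
#' the gene's global mean and pooled within-batch standard deviation. This
#' removes additive and multiplicative batch shifts; it does not perform the
#' empirical-Bayes shrinkage of full ComBat, which can be substituted by
#' `mode = "combat"` (requires the `sva` package). A gene with zero variance
#' inside some batch has its scale step skipped there (location-only), with
#' a message.
#'
#' @param x combined `expr_matrix` (all batches column-bound).
#' @param batches named character vector, sample id -> batch; every sample
#'   of `x` must be present and every batch must hold at least 2 samples.
#' @param mode `"center_scale"` (default), `"combat"`, or `"none"`.
#' @return An `expr_matrix` of the same shape.
#' @export
batch_adjust <- function(x, batches, mode = c("center_scale", "combat", "none")) {
  mode <- match.arg(mode)
  if (mode == "none") return(x)
  sid <- samples(x)
  if (!all(sid %in% names(batches)))
    stop("every sample needs a batch label; missing: ",
         paste(setdiff(sid, names(batches)), collapse = ", "))
  b <- factor(batches[sid])
  sizes <- table(b)
  if (any(sizes < 2L))
    stop("each batch needs >= 2 samples; too small: ",
         paste(names(sizes)[sizes < 2L], collapse = ", "))
  if (mode == "combat") {
    if (!requireNamespace("sva", quietly = TRUE))
      stop("mode 'combat' requires the sva package")
    out <- sva::ComBat(dat = x$values, batch = b)
    return(expression_matrix(out, batch_id = x$batch_id))
  }
  v <- x$values
  out <- v
  gmean <- rowMeans(v)
  lev <- levels(b)
  bmean <- vapply(lev, function(l) rowMeans(v[, b == l, drop = FALSE]),
                  numeric(nrow(v)))
  bvar <- vapply(lev, function(l) apply(v[, b == l, drop = FALSE], 1L, stats::var),
                 numeric(nrow(v)))
  df <- as.numeric(sizes[lev]) - 1
  pooled_sd <- sqrt(as.vector(bvar %*% df) / sum(df))
  degenerate <- bvar == 0
  if (any(degenerate))
    message(sum(rowSums(degenerate) > 0),
            " gene(s) with zero within-batch variance: scale step skipped there")
  for (j in seq_along(lev)) {
    cols <- b == lev[j]
    centred <- v[, cols, drop = FALSE] - bmean[, j]
    scale_fac <- ifelse(degenerate[, j] | pooled_sd == 0, 1,
                        pooled_sd / sqrt(bvar[, j]))
    out[, cols] <- centred * scale_fac + gmean
  }
  expression_matrix(out, batch_id = x$batch_id)
}

#' Rank-normalize each sample column
#'
#' Replaces every column by fractional ranks scaled to (0, 1] (ties receive
#' the mean tied rank). Rank scores depend only on within-sample ordering,
#' which makes them suitable for comparing RNA-seq queries against
#' microarray-trained classifiers.
#'
#' @param x an `expr_matrix`.
#' @return An `expr_matrix` of rank scores.
#' @export
rank_normalize <- function(x) {
  n <- nrow(x$values)
  out <- apply(x$values, 2L, function(col) rank(col, ties.method = "average") / n)
  dimnames(out) <- dimnames(x$values)
  expression_matrix(out, batch_id = x$batch_id)
}

#' Preprocess a cohort collection for panel evolution
#'
#' The standard cross-cohort harmonization stack: restrict to shared genes,
#' quantile-normalize over the combined samples, then adjust batch effects
#' (one batch per cohort, taken from each matrix's `batch_id`) on the
#' combined matrix before splitting back into cohorts. `normalize = "rank"`
#' replaces quantile normalization by per-sample rank scores for
#' cross-platform inputs.
#'
#' @param cohorts a `cohort_collection`.
#' @param normalize `"quantile"` (default), `"rank"`, or `"none"`.
#' @param batch_mode passed to [batch_adjust()].
#' @return The preprocessed `cohort_collection`.
#' @export
preprocess_cohorts <- function(cohorts,
                               normalize = c("quantile", "rank", "none"),
                               batch_mode = c("center_scale", "combat", "none")) {
  normalize <- match.arg(normalize)
  batch_mode <- match.arg(batch_mode)
  cohorts <- intersect_genes(cohorts)
  cos <- all_cohorts(cohorts)
  mats <- lapply(cos, function(co) co$expr)
  mats <- switch(normalize,
    quantile = quantile_normalize(mats),
    rank     = lapply(mats, rank_normalize),
    none     = mats)
  if (batch_mode != "none") {
    combined <- do.call(cbind, lapply(mats, function(m) m$values))
    batches <- stats::setNames(
      unlist(lapply(mats, function(m) rep(m$batch_id, ncol(m$values))),
             use.names = FALSE),
      unlist(lapply(mats, function(m) colnames(m$values)), use.names = FALSE))
    adj <- batch_adjust(expression_matrix(combined, batch_id = "combined"),
                        batches, mode = batch_mode)
    offsets <- cumsum(c(0L, vapply(mats, function(m) ncol(m$values), 1L)))
    mats <- lapply(seq_along(mats), function(i) {
      cols <- (offsets[i] + 1L):offsets[i + 1L]
      expression_matrix(adj$values[, cols, drop = FALSE],
                        batch_id = mats[[i]]$batch_id)
    })
  }
  put_back <- function(co, m) { co$expr <- m; co }
  k <- 1L
  cohorts$training <- put_back(cohorts$training, mats[[k]])
  for (i in seq_along(cohorts$evaluation)) {
    k <- k + 1L
    cohorts$evaluation[[i]] <- put_back(cohorts$evaluation[[i]], mats[[k]])
  }
  if (!is.null(cohorts$holdout))
    cohorts$holdout <- put_back(cohorts$holdout, mats[[k + 1L]])
  cohorts
}
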