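#' Construct a gene-by-sample expression matrix
#'
#' The basic container used throughout the package: a numeric matrix of
#' log-scale intensities (or rank scores) with gene symbols as row names and
#' sample ids as column names, plus a batch label used during batch
#' adjustment. Duplicate gene rows are permitted before probe collapse
#' (see [collapse_probes()]); afterwards rows must be unique.
#'
#' @param values numeric matrix, genes in rows, samples in columns. Row and
#'   column names are required and become the gene symbols and sample ids.
#' @param batch_id single string labelling the batch (typically the cohort
#'   or platform) the samples came from.
#' @param allow_duplicate_genes logical; permit duplicate row identifiers
#'   (pre-collapse probe-level data).
#' @return An object of class `expr_matrix`: a list with elements `values`,
#'   `batch_id`.
#' @export
expression_matrix <- function(values, batch_id = "batch1",
                              allow_duplicate_genes = FALSE) {
  if (!is.matrix(values) || !is.numeric(values))
    stop("`values` must be a numeric matrix")
  if (is.null(rownames(values)) || is.null(colnames(values)))
    stop("`values` must have gene symbols as rownames and sample ids as colnames")
  if (anyDuplicated(colnames(values)))
    stop("duplicate sample ids: ",
         paste(unique(colnames(values)[duplicated(colnames(values))]), collapse = ", "))
  if (!allow_duplicate_genes && anyDuplicated(rownames(values)))
    stop("duplicate gene symbols: ",
         paste(unique(rownames(values)[duplicated(rownames(values))]), collapse = ", "))
  if (!all(is.finite(values)))
    stop("all expression values must be finite")
  if (!is.character(batch_id) || length(batch_id) != 1L)
    stop("`batch_id` must be a single string")
  structure(list(values = values, batch_id = batch_id), class = "expr_matrix")
}

#' @export
print.expr_matrix <- function(x, ...) {
  cat(sprintf("expression matrix: %d genes x %d samples (batch '%s')\n",
              nrow(x$values), ncol(x$values), x$batch_id))
  invisible(x)
}

#' @rdname expression_matrix
#' @param x an `expr_matrix`.
#' @export
genes <- function(x) rownames(x$values)

#' @rdname expression_matrix
#' @export
samples <- function(x) colnames(x$values)

#' Read an expression table from TSV/CSV
#'
#' Expects genes in rows and samples in columns: a header row of sample ids
#' and a first column of gene (or probe) identifiers. Duplicate gene rows are
#' allowed at this stage, since probe-level tables carry several rows per
#' gene until [collapse_probes()] is applied. Any non-numeric cell (including
#' literal `NA`) is a hard parse error naming the offending gene and sample.
#'
#' @param path path to the table.
#' @param dialect `"tsv"` or `"csv"`.
#' @param batch_id batch label to attach (defaults to the file name).
#' @return An `expr_matrix` (possibly with duplicate gene rows).
#' @export
read_expression_table <- function(path, dialect = c("tsv", "csv"),
                                  batch_id = NULL) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file not found: ", path)
  sep <- if (dialect == "tsv") "\t" else ","
  raw <- utils::read.table(path, sep = sep, header = TRUE, check.names = FALSE,
                           colClasses = "character", quote = "\"",
                           comment.char = "", stringsAsFactors = FALSE)
  if (nrow(raw) == 0L) stop("no data rows in ", path)
  if (ncol(raw) < 2L) stop("expected a gene column plus at least one sample column")
  gene_ids <- raw[[1L]]
  sample_ids <- colnames(raw)[-1L]
  if (anyDuplicated(sample_ids))
    stop("duplicate sample ids in header: ",
         paste(unique(sample_ids[duplicated(sample_ids)]), collapse = ", "))
  vals <- as.matrix(raw[, -1L, drop = FALSE])
  suppressWarnings(num <- matrix(as.numeric(vals), nrow = nrow(vals)))
  bad <- which(is.na(num), arr.ind = TRUE)
  if (nrow(bad) > 0L) {
    stop(sprintf("non-numeric value '%s' for gene '%s', sample '%s'",
                 vals[bad[1L, 1L], bad[1L, 2L]],
                 gene_ids[bad[1L, 1L]], sample_ids[bad[1L, 2L]]))
  }
  dimnames(num) <- list(gene_ids, sample_ids)
  expression_matrix(num, batch_id = batch_id %||% basename(path),
                    allow_duplicate_genes = TRUE)
}

#' Write an expression table to TSV/CSV
#'
#' Inverse of [read_expression_table()]; the first column is named `gene`.
#'
#' @param x an `expr_matrix`.
#' @param path output path.
#' @param dialect `"tsv"` or `"csv"`.
#' @export
write_expression_table <- function(x, path, dialect = c("tsv", "csv")) {
  dialect <- match.arg(dialect)
  sep <- if (dialect == "tsv") "\t" else ","
  df <- data.frame(gene = rownames(x$values), x$values,
                   check.names = FALSE, stringsAsFactors = FALSE)
  utils::write.table(df, path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Collapse probe-level rows to one row per gene
#'
#' Microarray tables often carry several probes per gene; the retained row
#' for each gene is its "brightest" probe -- the probe whose summary
#' intensity across this dataset's samples is highest. Ties are broken by
#' the first probe in input order.
#'
#' @param x an `expr_matrix` whose rows are probe identifiers.
#' @param probe_map named character vector mapping probe id -> gene symbol;
#'   must cover every row of `x`.
#' @param summary `"mean"` (default) or `"median"` brightness summary.
#' @return An `expr_matrix` with one row per gene symbol.
#' @export
collapse_probes <- function(x, probe_map, summary = c("mean", "median")) {
  summary <- match.arg(summary)
  if (length(probe_map) == 0L) stop("`probe_map` is empty")
  probes <- rownames(x$values)
  missing <- setdiff(probes, names(probe_map))
  if (length(missing) > 0L)
    stop("probe_map does not cover probes: ", paste(missing, collapse = ", "))
  gene_of <- probe_map[probes]
  bright <- if (summary == "mean") rowMeans(x$values)
            else apply(x$values, 1L, stats::median)
  keep <- integer(0)
  for (g in unique(gene_of)) {
    idx <- which(gene_of == g)
    keep <- c(keep, idx[which.max(bright[idx])])  # which.max: first on ties
  }
  out <- x$values[keep, , drop = FALSE]
  rownames(out) <- unname(gene_of[keep])
  expression_matrix(out, batch_id = x$batch_id)
}

#' Bundle cohorts into a training / evaluation / holdout collection
#'
#' A cohort is a list with elements `expr` (an `expr_matrix`) and `labels`
#' (a named character vector, sample id -> class). Fitness evaluation during
#' panel evolution uses the training and evaluation cohorts only; the
#' holdout cohort is scored exactly once, after the best panel has been
#' selected, to detect overtraining.
#'
#' @param training cohort used to train every forest.
#' @param evaluation list of cohorts scored for fitness.
#' @param holdout optional cohort reserved for final validation.
#' @return An object of class `cohort_collection`.
#' @export
cohort_collection <- function(training, evaluation, holdout = NULL) {
  if (!is.null(evaluation) && !is.null(evaluation$expr))
    evaluation <- list(evaluation)  # single cohort passed bare
  check_cohort <- function(co, name, min_classes = 1L) {
    if (!inherits(co$expr, "expr_matrix"))
      stop(name, ": `expr` must be an expr_matrix")
    if (is.null(co$labels) || is.null(names(co$labels)))
      stop(name, ": `labels` must be a named character vector")
    unknown <- setdiff(names(co$labels), samples(co$expr))
    if (length(unknown) > 0L)
      stop(name, ": labelled samples absent from matrix: ",
           paste(unknown, collapse = ", "))
    if (length(unique(co$labels)) < min_classes)
      stop(name, ": needs at least ", min_classes, " classes")
    co$labels <- as.character(co$labels) |> stats::setNames(names(co$labels))
    co
  }
  training <- check_cohort(training, "training", min_classes = 2L)
  if (length(evaluation) < 1L) stop("at least one evaluation cohort is required")
  evaluation <- lapply(seq_along(evaluation), function(i)
    check_cohort(evaluation[[i]], paste0("evaluation[", i, "]")))
  if (!is.null(holdout)) holdout <- check_cohort(holdout, "holdout")
  structure(list(training = training, evaluation = evaluation,
                 holdout = holdout),
            class = "cohort_collection")
}

#' @export
print.cohort_collection <- function(x, ...) {
  n_eval <- length(x$evaluation)
  cat(sprintf(
    "cohort collection: training (%d samples), %d evaluation cohort%s (%d samples)%s\n",
    ncol(x$training$expr$values), n_eval, if (n_eval == 1L) "" else "s",
    sum(vapply(x$evaluation, function(co) ncol(co$expr$values), 1L)),
    if (is.null(x$holdout)) ""
    else sprintf(", holdout (%d samples)", ncol(x$holdout$expr$values))))
  cat(sprintf("  shared genes: %d\n", length(genes(x$training$expr))))
  invisible(x)
}

all_cohorts <- function(cohorts) {
  c(list(training = cohorts$training),
    stats::setNames(cohorts$evaluation,
                    paste0("evaluation", seq_along(cohorts$evaluation))),
    if (!is.null(cohorts$holdout)) list(holdout = cohorts$holdout))
}

#' Restrict all cohorts to their shared gene set
#'
#' Only genes present under the same symbol in every cohort are usable for a
#' cross-cohort panel; all matrices are restricted to the lexicographically
#' sorted intersection so that downstream matrices align deterministically.
#'
#' @param cohorts a `cohort_collection` of probe-collapsed matrices.
#' @return The `cohort_collection` with every matrix restricted and
#'   reordered to the shared genes (attribute `"shared_genes"` reports them).
#' @export
intersect_genes <- function(cohorts) {
  cos <- all_cohorts(cohorts)
  sets <- lapply(cos, function(co) genes(co$expr))
  shared <- Reduce(intersect, sets)
  if (length(shared) == 0L)
    stop("empty gene intersection; per-cohort gene counts: ",
         paste(sprintf("%s=%d", names(sets), lengths(sets)), collapse = ", "))
  shared <- sort(shared)
  restrict <- function(co) {
    co$expr <- expression_matrix(co$expr$values[shared, , drop = FALSE],
                                 batch_id = co$expr$batch_id)
    co
  }
  cohorts$training <- restrict(cohorts$training)
  cohorts$evaluation <- lapply(cohorts$evaluation, restrict)
  if (!is.null(cohorts$holdout)) cohorts$holdout <- restrict(cohorts$holdout)
  attr(cohorts, "shared_genes") <- shared
  cohorts
}

`%||%` <- function(a, b) if (is.null(a)) b else a
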