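#' Parse a cohort manifest
#'
#' The manifest is a YAML file describing a run's inputs: a `cohorts` list
#' whose entries carry `path` (expression table), `role` (one of
#' `training`, `evaluation`, `holdout`), `batch` (batch label), and
#' `labels` (two-column sample_id/class file); plus optional top-level
#' `normalization`, `panel_size`, `runs`, `trees`, `seed`. Exactly one
#' training cohort, at least one evaluation cohort, and at most one holdout
#' cohort are required; roles are never inferred from file names.
#'
#' @param path YAML manifest path.
#' @return A validated list of class `garf_manifest`.
#' @export
parse_manifest <- function(path) {
  if (!file.exists(path)) stop("manifest not found: ", path)
  m <- yaml::read_yaml(path)
  if (is.null(m$cohorts) || length(m$cohorts) == 0L)
    stop("manifest has no `cohorts` entries")
  roles <- vapply(m$cohorts, function(co) co$role %||% "", "")
  bad <- setdiff(roles, c("training", "evaluation", "holdout"))
  if (length(bad) > 0L)
    stop("unknown cohort role(s): ", paste(unique(bad), collapse = ", "))
  if (sum(roles == "training") != 1L)
    stop("manifest must declare exactly one training cohort (found ",
         sum(roles == "training"), ")")
  if (sum(roles == "evaluation") < 1L)
    stop("manifest must declare at least one evaluation cohort")
  if (sum(roles == "holdout") > 1L)
    stop("manifest must declare at most one holdout cohort")
  for (i in seq_along(m$cohorts)) {
    co <- m$cohorts[[i]]
    if (is.null(co$path)) stop("cohort ", i, " has no `path`")
    if (is.null(co$labels)) stop("cohort ", i, " has no `labels` path")
    if (is.null(co$batch)) m$cohorts[[i]]$batch <- paste0("batch", i)
  }
  m$normalization <- m$normalization %||% "quantile"
  structure(m, class = "garf_manifest")
}

read_labels_file <- function(path) {
  df <- utils::read.table(path, sep = "\t", header = TRUE,
                          stringsAsFactors = FALSE, check.names = FALSE)
  if (ncol(df) < 2L) stop("labels file needs two columns (sample_id, class): ", path)
  stats::setNames(as.character(df[[2L]]), as.character(df[[1L]]))
}

#' Load the cohorts a manifest describes
#'
#' Reads every expression table and labels file (paths resolved relative to
#' the manifest's directory), attaches batch labels, and assembles a
#' `cohort_collection`. Tables are expected probe-collapsed; apply
#' [preprocess_cohorts()] afterwards.
#'
#' @param manifest a `garf_manifest` (or path to one).
#' @param base_dir directory paths are resolved against; defaults to the
#'   manifest's own directory when `manifest` is a path, else the working
#'   directory.
#' @return A `cohort_collection`.
#' @export
load_cohorts <- function(manifest, base_dir = NULL) {
  if (is.character(manifest)) {
    base_dir <- base_dir %||% dirname(manifest)
    manifest <- parse_manifest(manifest)
  }
  base_dir <- base_dir %||% "."
  resolve <- function(p) if (file.exists(p)) p else file.path(base_dir, p)
  dialect_of <- function(p) if (grepl("\\.csv$", p)) "csv" else "tsv"
  load_one <- function(co) {
    p <- resolve(co$path)
    expr <- read_expression_table(p, dialect = dialect_of(p),
                                  batch_id = co$batch)
    list(expr = expr, labels = read_labels_file(resolve(co$labels)))
  }
  roles <- vapply(manifest$cohorts, `[[`, "", "role")
  training <- load_one(manifest$cohorts[[which(roles == "training")]])
  evaluation <- lapply(manifest$cohorts[roles == "evaluation"], load_one)
  holdout <- if (any(roles == "holdout"))
    load_one(manifest$cohorts[[which(roles == "holdout")]]) else NULL
  cohort_collection(training, evaluation, holdout)
}

#' Write run artifacts for a fitted GARF search
#'
#' Writes, under `out_dir`: `best_panel.txt` (one gene symbol per line),
#' `run_summary.json` (seeds, settings, per-run best fitness, holdout
#' concordance), and one `run_XX_generations.tsv` per run (generation,
#' pool size, mean and best fitness, accepted flag). Together with the
#' master seed these make the search replayable.
#'
#' @param result a `garf` object.
#' @param out_dir output directory (created if needed).
#' @return `out_dir`, invisibly.
#' @export
log_run <- function(result, out_dir) {
  if (!dir.exists(out_dir)) {
    ok <- dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
    if (!ok) stop("cannot create output directory: ", out_dir)
  }
  writeLines(result$best_panel, file.path(out_dir, "best_panel.txt"))
  for (r in seq_along(result$runs)) {
    run <- result$runs[[r]]
    tab <- data.frame(
      generation = vapply(run$history, `[[`, 1L, "generation"),
      pool_size = vapply(run$history, function(g) length(g$pool), 1L),
      mean_fitness = vapply(run$history, `[[`, 1, "mean_fitness"),
      best_fitness = vapply(run$history, `[[`, 1, "best_fitness"),
      accepted = run$accepted)
    utils::write.table(tab,
                       file.path(out_dir, sprintf("run_%02d_generations.tsv", r)),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  summary <- list(
    panel_size = result$panel_size, n_runs = result$n_runs,
    trees = result$trees, master_seed = result$seed,
    run_seeds = vapply(result$runs, `[[`, 1L, "seed"),
    best_run = result$best_run, best_fitness = result$best_fitness,
    best_panel = result$best_panel,
    stop_reasons = vapply(result$runs, `[[`, "", "stop_reason"),
    holdout_concordance = if (is.na(result$holdout_concordance)) NULL
                          else result$holdout_concordance)
  jsonlite::write_json(summary, file.path(out_dir, "run_summary.json"),
                       auto_unbox = TRUE, pretty = TRUE, digits = NA)
  invisible(out_dir)
}
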