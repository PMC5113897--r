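# Shared fixture builders. Everything is generated in code at test time.

# A tiny expr_matrix from a plain numeric matrix.
em <- function(values, genes = NULL, samples = NULL, batch = "b1") {
  if (!is.null(genes)) rownames(values) <- genes
  if (!is.null(samples)) colnames(values) <- samples
  expression_matrix(values, batch_id = batch)
}

# Perfectly separable two-class data: class means +/- delta/2 on every gene,
# tiny noise, so any sensible classifier is exact.
separable_cohort <- function(n_genes = 4L, n_per_class = 20L, delta = 6,
                             sd = 0.1, batch = "b1", seed = 1L,
                             classes = c("A", "B")) {
  set.seed(seed)
  n <- n_per_class * length(classes)
  labels <- stats::setNames(rep(classes, each = n_per_class),
                            sprintf("%s_s%02d", batch, seq_len(n)))
  shift <- ifelse(labels == classes[1L], -delta / 2, delta / 2)
  vals <- matrix(stats::rnorm(n_genes * n, sd = sd), nrow = n_genes) +
    matrix(shift, nrow = n_genes, ncol = n, byrow = TRUE)
  dimnames(vals) <- list(sprintf("gene%02d", seq_len(n_genes)), names(labels))
  list(expr = expression_matrix(vals, batch_id = batch), labels = labels)
}

separable_cohorts <- function(n_genes = 4L, n_per_class = 20L, holdout = TRUE,
                              seed = 1L) {
  cohort_collection(
    training = separable_cohort(n_genes, n_per_class, batch = "train",
                                seed = seed),
    evaluation = list(separable_cohort(n_genes, n_per_class, batch = "eval1",
                                       seed = seed + 1L)),
    holdout = if (holdout)
      separable_cohort(n_genes, n_per_class, batch = "hold", seed = seed + 2L))
}

# Small planted-signal simulation used by several engine tests.
small_sim <- function(seed = 1L) {
  simulate_cohorts(n_cohorts = 3L, n_classes = 3L, n_informative = 10L,
                   n_noise = 30L, samples_per_class = 10L, delta = 3,
                   seed = seed)
}

# Write a cohort to disk as the TSV pair (expression + labels) the manifest
# format expects; returns the two paths.
write_cohort_files <- function(cohort, dir, stem) {
  expr_path <- file.path(dir, paste0(stem, ".tsv"))
  labels_path <- file.path(dir, paste0(stem, "_labels.tsv"))
  write_expression_table(cohort$expr, expr_path)
  utils::write.table(
    data.frame(sample_id = names(cohort$labels), class = cohort$labels),
    labels_path, sep = "\t", quote = FALSE, row.names = FALSE)
  c(expr = expr_path, labels = labels_path)
}
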