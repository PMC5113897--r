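#' Number of survivor models kept per generation
#'
#' The dynamic survivor rule: a generation built from a pool of `pool_size`
#' genes keeps its top `ceiling(pool_size / k)` models, the minimum number
#' whose panels could in principle carry every pool gene into the next
#' generation (since `ceiling(p/k) * k >= p`). With a 400-gene pool and
#' 48-gene panels this keeps 9 models (400/48 = 8.32), i.e. up to 432 genes
#' if the panels were disjoint.
#'
#' @param pool_size genes currently in the pool (>= `k`).
#' @param k panel size.
#' @return Positive integer count of survivor models.
#' @export
survivor_count <- function(pool_size, k) {
  if (pool_size < k)
    stop("pool (", pool_size, ") is smaller than the panel size (", k,
         "); it can no longer seed a panel")
  as.integer(ceiling(pool_size / k))
}

#' Survivor percentage implied by the panel size
#'
#' The share of a generation's models that survives, `100 / k` percent
#' (rounded to 2 decimals): 2.08% for 48-gene panels, 3.13% for 32.
#'
#' @param k panel size (>= 1).
#' @return Percentage, rounded to 2 decimals.
#' @export
survivor_percentage <- function(k) {
  if (k < 1L) stop("`k` must be >= 1")
  floor(100 / k * 100 + 0.5) / 100  # half-up, so 100/32 = 3.125 -> 3.13
}

#' Sample one generation of candidate panels from the pool
#'
#' Every generation holds as many panels as the pool holds genes; each panel
#' is `k` distinct genes drawn uniformly without replacement from the pool
#' (panels may coincide by chance). Genes within a panel are stored sorted.
#'
#' @param pool character vector of gene symbols.
#' @param k panel size (`|pool| >= k`).
#' @param n_panels number of panels; defaults to `length(pool)`.
#' @return List of `n_panels` character vectors of length `k`.
#' @export
sample_generation <- function(pool, k, n_panels = length(pool)) {
  if (length(pool) < k)
    stop("pool (", length(pool), ") is smaller than the panel size (", k, ")")
  lapply(seq_len(n_panels), function(i) sort(sample(pool, k)))
}

default_evaluator <- function(cohorts, trees, mtry) {
  force(cohorts); force(trees); force(mtry)
  function(panels, panel_seeds) {
    vapply(seq_along(panels), function(i)
      evaluate_subset(panels[[i]], cohorts,
                      forest_config(trees = trees, mtry = mtry,
                                    seed = panel_seeds[i]))$pooled,
      numeric(1))
  }
}

#' Advance the genetic algorithm by one generation
#'
#' Samples `|pool|` panels, scores each by pooled evaluation-cohort
#' concordance, ranks them (ties broken by lower panel index), keeps the top
#' [survivor_count()] models, and forms the next pool as the union of the
#' survivors' genes. Mean fitness is averaged over *all* panels in the
#' generation, not just the survivors.
#'
#' @param pool character vector of gene symbols.
#' @param k panel size.
#' @param evaluator function `(panels, panel_seeds) -> numeric` of pooled
#'   fitness values, one per panel (see [garf()] for the default).
#' @param generation generation index recorded in the result.
#' @param panels optional pre-built list of panels (one per pool gene),
#'   replacing the random sampling -- useful for controlled studies.
#' @return A list of class `generation_record` with `generation`, `pool`,
#'   `panels`, `fitness`, `survivors` (panel indices), `next_pool`,
#'   `mean_fitness`, `best_fitness`, `best_panel`.
#' @export
garf_step <- function(pool, k, evaluator, generation = 1L, panels = NULL) {
  panels <- panels %||% sample_generation(pool, k)
  panel_seeds <- sample.int(.Machine$integer.max - 1L, length(panels))
  fitness <- evaluator(panels, panel_seeds)
  stopifnot(length(fitness) == length(panels))
  ord <- order(-fitness, seq_along(fitness))
  keep <- ord[seq_len(survivor_count(length(pool), k))]
  next_pool <- sort(unique(unlist(panels[keep])))
  structure(list(generation = as.integer(generation), pool = pool,
                 panels = panels, fitness = fitness, survivors = keep,
                 next_pool = next_pool, mean_fitness = mean(fitness),
                 best_fitness = fitness[ord[1L]],
                 best_panel = panels[[ord[1L]]]),
            class = "generation_record")
}

#' One run of the genetic algorithm
#'
#' Iterates [garf_step()] from the starting pool. A generation is accepted
#' only if its mean fitness strictly exceeds the previous accepted
#' generation's; the run stops when a generation fails to improve, when the
#' pool reaches the target size, when no gene is eliminated (the pool would
#' loop), or at the `max_generations` safeguard. The best panel is the
#' top-fitness panel of the best-performing (last accepted) generation.
#'
#' @param cohorts a preprocessed `cohort_collection` (ignored when a custom
#'   `evaluator` is supplied).
#' @param k panel size.
#' @param trees,mtry forest settings for the default evaluator.
#' @param seed integer seed governing panel sampling and forest seeds.
#' @param target_pool_size stop once the next pool is this small
#'   (default `k`).
#' @param max_generations hard iteration cap.
#' @param start_pool starting gene pool; defaults to all training genes.
#' @param evaluator optional replacement fitness function, as in
#'   [garf_step()] -- used for simulation studies and stubbed fitness.
#' @param log_file optional path; one TSV row is appended (and flushed) per
#'   generation so partial runs remain inspectable.
#' @return A list of class `garf_run`: `history` (generation records),
#'   `accepted` (logical per generation), `best_panel`, `best_fitness`,
#'   `best_generation`, `stop_reason`, `seed`.
#' @export
run_garf <- function(cohorts = NULL, k, trees = 150L, mtry = NULL, seed = 1L,
                     target_pool_size = k, max_generations = 40L,
                     start_pool = NULL, evaluator = NULL, log_file = NULL) {
  if (target_pool_size < k) stop("`target_pool_size` must be >= k")
  if (is.null(evaluator)) {
    if (is.null(cohorts)) stop("either `cohorts` or `evaluator` is required")
    evaluator <- default_evaluator(cohorts, trees, mtry)
    pool <- start_pool %||% genes(cohorts$training$expr)
  } else {
    pool <- start_pool
    if (is.null(pool)) {
      if (is.null(cohorts)) stop("`start_pool` is required with a custom evaluator")
      pool <- genes(cohorts$training$expr)
    }
  }
  if (length(pool) < k)
    stop("starting pool (", length(pool), ") is smaller than k (", k, ")")
  if (!is.null(log_file))
    cat("generation\tpool_size\tmean_fitness\tbest_fitness\taccepted\n",
        file = log_file)
  set.seed(as.integer(seed))
  history <- list()
  accepted <- logical(0)
  last_mean <- -Inf
  stop_reason <- "max_generations"
  for (g in seq_len(max_generations)) {
    rec <- garf_step(pool, k, evaluator, generation = g)
    ok <- rec$mean_fitness > last_mean
    history[[g]] <- rec
    accepted[g] <- ok
    if (!is.null(log_file))
      cat(sprintf("%d\t%d\t%.6f\t%.6f\t%s\n", g, length(rec$pool),
                  rec$mean_fitness, rec$best_fitness, ok),
          file = log_file, append = TRUE)
    if (!ok) { stop_reason <- "no_improvement"; break }
    last_mean <- rec$mean_fitness
    if (length(rec$next_pool) <= target_pool_size) {
      stop_reason <- "target_reached"; break
    }
    if (length(rec$next_pool) == length(rec$pool)) {
      stop_reason <- "no_elimination"; break
    }
    pool <- rec$next_pool
  }
  acc_idx <- which(accepted)
  best_gen <- acc_idx[which.max(vapply(history[acc_idx],
                                       function(r) r$mean_fitness, 1))]
  best <- history[[best_gen]]
  structure(list(history = history, accepted = accepted,
                 best_panel = best$best_panel,
                 best_fitness = best$best_fitness,
                 best_generation = best_gen,
                 stop_reason = stop_reason, seed = as.integer(seed)),
            class = "garf_run")
}

#' Evolve a reduced gene panel with the genetic-algorithm/random-forest search
#'
#' The main fitting function. Starting from the pool of genes shared by all
#' cohorts, each generation samples as many fixed-size panels as the pool
#' holds genes, scores every panel by the classification concordance of a
#' random forest (trained on the training cohort, scored on the pooled
#' evaluation cohorts against the reference labels), and carries the unique
#' genes of the top `ceiling(pool/k)` models into the next pool. The search
#' is repeated `n_runs` times from independent seeds and the best panel
#' across runs (by pooled evaluation concordance) is selected; only then is
#' the holdout cohort scored, once, to detect overtraining.
#'
#' @param cohorts a `cohort_collection`, already preprocessed (see
#'   [preprocess_cohorts()]).
#' @param panel_size number of genes per panel (k).
#' @param n_runs independent restarts (production setting: 10).
#' @param trees trees per forest (production setting: 5000; small studies
#'   and tests use fewer).
#' @param mtry variables per split (`NULL` = `floor(sqrt(panel_size))`).
#' @param seed master seed; run seeds are derived from it.
#' @param target_pool_size,max_generations,start_pool,evaluator passed to
#'   [run_garf()].
#' @param log_dir optional directory for per-generation TSV logs and run
#'   summaries (see [log_run()]).
#' @return An object of class `garf` with components `runs` (list of
#'   `garf_run`), `best_run`, `best_panel`, `best_fitness`,
#'   `holdout_concordance` (NA when no holdout cohort), `final_model`
#'   (a `subset_model` refit on the best panel), and `call` metadata.
#' @seealso [panel_size_curve()] to choose `panel_size`,
#'   [fit_panel_classifier()] for a persistable classifier on the result.
#' @export
garf <- function(cohorts, panel_size, n_runs = 10L, trees = 5000L,
                 mtry = NULL, seed = 1L, target_pool_size = panel_size,
                 max_generations = 40L, start_pool = NULL, evaluator = NULL,
                 log_dir = NULL) {
  seeds <- derive_seeds(seed, n_runs + 1L)
  if (!is.null(log_dir) && !dir.exists(log_dir))
    dir.create(log_dir, recursive = TRUE)
  runs <- lapply(seq_len(n_runs), function(r)
    run_garf(cohorts, k = panel_size, trees = trees, mtry = mtry,
             seed = seeds[r], target_pool_size = target_pool_size,
             max_generations = max_generations, start_pool = start_pool,
             evaluator = evaluator,
             log_file = if (is.null(log_dir)) NULL
                        else file.path(log_dir, sprintf("run_%02d_generations.tsv", r))))
  best_fit <- vapply(runs, function(r) r$best_fitness, 1)
  best_run <- which.max(best_fit)  # ties: lower run index
  best_panel <- runs[[best_run]]$best_panel
  final_model <- NULL
  holdout <- NA_real_
  if (!is.null(cohorts) && is.null(evaluator)) {
    final_model <- train_subset_model(cohorts$training, best_panel,
                                      forest_config(trees = trees, mtry = mtry,
                                                    seed = seeds[n_runs + 1L]))
    if (!is.null(cohorts$holdout)) {
      ids <- names(cohorts$holdout$labels)
      pred <- predict(final_model, cohorts$holdout$expr)[ids]
      holdout <- mean(pred == cohorts$holdout$labels[ids])
    }
  }
  res <- structure(list(runs = runs, best_run = best_run,
                        best_panel = best_panel,
                        best_fitness = best_fit[best_run],
                        holdout_concordance = holdout,
                        final_model = final_model,
                        panel_size = as.integer(panel_size),
                        n_runs = as.integer(n_runs),
                        trees = as.integer(trees), seed = as.integer(seed)),
                   class = "garf")
  if (!is.null(log_dir)) log_run(res, log_dir)
  res
}

#' @export
print.garf <- function(x, ...) {
  cat(sprintf("GARF panel search: k = %d, %d run%s, %d trees/forest\n",
              x$panel_size, x$n_runs, if (x$n_runs == 1L) "" else "s", x$trees))
  cat(sprintf("best panel (run %d): pooled evaluation concordance %.4f\n",
              x$best_run, x$best_fitness))
  if (!is.na(x$holdout_concordance))
    cat(sprintf("holdout concordance (scored once, post-selection): %.4f\n",
                x$holdout_concordance))
  cat("genes:", paste(x$best_panel, collapse = " "), "\n")
  invisible(x)
}

#' @export
summary.garf <- function(object, ...) {
  runs <- object$runs
  tab <- data.frame(
    run = seq_along(runs),
    generations = vapply(runs, function(r) length(r$history), 1L),
    best_generation = vapply(runs, function(r) r$best_generation, 1L),
    final_pool = vapply(runs, function(r)
      length(r$history[[r$best_generation]]$next_pool), 1L),
    best_fitness = vapply(runs, function(r) r$best_fitness, 1),
    stop_reason = vapply(runs, function(r) r$stop_reason, ""))
  structure(list(table = tab, best_run = object$best_run,
                 holdout = object$holdout_concordance), class = "summary.garf")
}

#' @export
print.summary.garf <- function(x, ...) {
  print(x$table, row.names = FALSE)
  cat(sprintf("overall best: run %d", x$best_run))
  if (!is.na(x$holdout)) cat(sprintf("; holdout concordance %.4f", x$holdout))
  cat("\n")
  invisible(x)
}

#' Plot mean-fitness trajectories of a GARF search
#'
#' One line per run: mean pooled concordance of all panels in each
#' generation. Accepted generations rise by construction; the terminal dip,
#' when present, is the non-improving generation that stopped the run.
#'
#' @param x a `garf` object.
#' @param ... passed to [graphics::matplot()].
#' @export
plot.garf <- function(x, ...) {
  traj <- lapply(x$runs, function(r)
    vapply(r$history, function(g) g$mean_fitness, 1))
  gmax <- max(lengths(traj))
  m <- vapply(traj, function(v) c(v, rep(NA_real_, gmax - length(v))),
              numeric(gmax))
  graphics::matplot(seq_len(gmax), m, type = "b", pch = 1, lty = 1,
                    xlab = "generation", ylab = "mean pooled concordance",
                    main = sprintf("GARF fitness trajectories (k = %d)",
                                   x$panel_size), ...)
  invisible(x)
}

#' Predict classes for new samples with the selected panel
#'
#' Applies the forest refit on the overall best panel to a query matrix.
#' The query must be normalized the same way as the training data.
#'
#' @param object a fitted `garf` object.
#' @param newdata an `expr_matrix` containing every panel gene.
#' @param type `"class"` or `"votes"`.
#' @param ... unused.
#' @export
predict.garf <- function(object, newdata, type = c("class", "votes"), ...) {
  if (is.null(object$final_model))
    stop("this garf object was fitted with a custom evaluator; no forest available")
  predict(object$final_model, newdata, type = match.arg(type))
}

#' Derive independent sub-seeds from a master seed
#'
#' @param master integer master seed.
#' @param n number of seeds.
#' @return Integer vector of `n` seeds in `[1, 2^31 - 2]`.
#' @export
derive_seeds <- function(master, n) {
  set.seed(as.integer(master))
  sample.int(.Machine$integer.max - 1L, n)
}

#' Exact binomial coefficient as a big integer
#'
#' The size of the panel search space, e.g. `choose(753, 48)`, overflows
#' double precision well before the pool sizes this package works with, so
#' the count is computed exactly with schoolbook big-integer arithmetic
#' (multiply then exact divide, chunked base 1e9) and returned as a decimal
#' string.
#'
#' @param n,k nonnegative integers, `k <= n`.
#' @return Decimal string of `choose(n, k)`.
#' @export
big_choose <- function(n, k) {
  if (k < 0 || n < 0 || k > n) stop("need 0 <= k <= n")
  k <- min(k, n - k)
  base <- 1e9
  acc <- 1  # little-endian chunks
  mul_small <- function(x, m) {
    carry <- 0
    for (i in seq_along(x)) {
      v <- x[i] * m + carry
      x[i] <- v %% base
      carry <- v %/% base
    }
    while (carry > 0) { x <- c(x, carry %% base); carry <- carry %/% base }
    x
  }
  div_small <- function(x, d) {  # exact division
    carry <- 0
    for (i in rev(seq_along(x))) {
      v <- carry * base + x[i]
      x[i] <- v %/% d
      carry <- v %% d
    }
    stopifnot(carry == 0)
    while (length(x) > 1L && x[length(x)] == 0) x <- x[-length(x)]
    x
  }
  for (i in seq_len(k)) {
    acc <- mul_small(acc, n - k + i)
    acc <- div_small(acc, i)
  }
  paste0(c(format(acc[length(acc)], scientific = FALSE),
           sprintf("%09d", rev(acc[-length(acc)]))), collapse = "")
}
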