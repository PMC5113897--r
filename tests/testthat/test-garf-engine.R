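test_that("the survivor rule keeps ceiling(pool / k) models", {
  expect_identical(survivor_count(400, 48), 9L)
  expect_identical(survivor_count(48, 48), 1L)
  expect_identical(survivor_count(753, 48), 16L)
  expect_error(survivor_count(40, 48), "smaller than the panel size")

  # enough models always survive for every pool gene to remain reachable
  set.seed(14)
  for (i in 1:50) {
    k <- sample(2:60, 1)
    p <- k + sample(0:1000, 1)
    expect_gte(survivor_count(p, k) * k, p)
  }

  expect_equal(survivor_percentage(48), 2.08)
  expect_equal(survivor_percentage(100), 1.00)
  expect_equal(survivor_percentage(32), 3.13)
})

test_that("each generation holds one panel per pool gene, sampled uniformly", {
  pool <- sprintf("g%03d", 1:753)
  set.seed(1)
  panels <- sample_generation(pool, 48)
  expect_length(panels, 753)
  expect_true(all(lengths(panels) == 48))
  expect_true(all(vapply(panels, function(p) !anyDuplicated(p), TRUE)))

  # pool of exactly k genes: every panel is forced to be the whole pool
  forced <- sample_generation(letters[1:5], 5)
  expect_true(all(vapply(forced, setequal, TRUE, y = letters[1:5])))

  expect_error(sample_generation(letters[1:4], 5), "smaller than the panel")

  # uniform inclusion: 10,000 panels of 12 from 200 genes
  pool <- sprintf("g%03d", 1:200)
  set.seed(2)
  draws <- unlist(replicate(50, sample_generation(pool, 12), simplify = FALSE))
  freq <- table(factor(unlist(draws), levels = pool)) / 10000
  p <- 12 / 200
  se <- sqrt(p * (1 - p) / 10000)
  expect_true(all(abs(freq - p) < 4 * se))
  expect_lt(mean(abs(freq - p) > 3 * se), 0.02)  # rare 3-SE excursions only
})

test_that("a step ranks panels, applies the tie-break, and unions survivors", {
  pool <- sprintf("g%02d", 1:30)
  scripted <- NULL
  evaluator <- function(panels, seeds) scripted
  set.seed(4)
  scripted <- round(runif(30), 2)  # duplicates force tie-breaks
  rec <- garf_step(pool, k = 5, evaluator)
  m <- survivor_count(30, 5)
  # brute-force top-m with ties broken by lower panel index
  oracle <- order(-scripted, seq_along(scripted))[1:m]
  expect_identical(rec$survivors, oracle)
  expect_setequal(rec$next_pool, unique(unlist(rec$panels[oracle])))
  expect_equal(rec$mean_fitness, mean(scripted))
  expect_true(all(rec$next_pool %in% pool))

  # disjoint survivor panels: next pool is exactly their union
  pool432 <- sprintf("g%03d", 1:432)
  disjoint <- split(pool432, rep(1:9, each = 48))
  filler <- sample_generation(pool432, 48, n_panels = 432 - 9)
  fixed_panels <- c(unname(disjoint), filler)
  evaluator2 <- function(panels, seeds) c(rep(1, 9), rep(0, 432 - 9))
  rec2 <- garf_step(pool432, k = 48, evaluator2, panels = fixed_panels)
  expect_identical(rec2$survivors, 1:9)
  expect_length(rec2$next_pool, 432)

  # identical survivor panels: union degenerates to k genes
  same <- replicate(30, sort(sample(pool, 5)), simplify = FALSE)
  same[1:m] <- replicate(m, same[[1]], simplify = FALSE)
  rec3 <- garf_step(pool, 5, function(p, s) c(rep(1, m), rep(0, 30 - m)),
                    panels = same)
  expect_length(rec3$next_pool, 5)
})

test_that("a run stops on failure to improve and reports the best generation", {
  means <- c(0.80, 0.85, 0.84)
  gen <- 0
  evaluator <- function(panels, seeds) {
    gen <<- gen + 1
    rep(means[gen], length(panels))
  }
  r <- run_garf(k = 5, seed = 6, start_pool = sprintf("g%02d", 1:60),
                evaluator = evaluator, max_generations = 10)
  expect_length(r$history, 3)
  expect_identical(r$stop_reason, "no_improvement")
  expect_identical(r$best_generation, 2L)
  expect_true(all(r$best_panel %in% r$history[[2]]$pool))
  expect_equal(r$accepted, c(TRUE, TRUE, FALSE))
})

test_that("a pool already at the target stops after a single generation", {
  co <- separable_cohorts()
  r <- run_garf(co, k = 4, trees = 50, seed = 8)  # pool == k == 4
  expect_length(r$history, 1)
  expect_identical(r$stop_reason, "target_reached")
  expect_setequal(r$best_panel, genes(co$training$expr))
})

test_that("pool shrinks monotonically and accepted fitness rises strictly", {
  sim <- small_sim(seed = 2)
  co <- preprocess_cohorts(sim$cohorts)
  r <- run_garf(co, k = 6, trees = 80, seed = 10)
  sizes <- vapply(r$history, function(g) length(g$pool), 1L)
  expect_true(all(diff(sizes) <= 0))
  for (g in r$history) {
    expect_true(all(g$next_pool %in% g$pool))
    expect_lte(length(g$survivors), length(g$panels))
  }
  acc_means <- vapply(r$history[r$accepted], `[[`, 1, "mean_fitness")
  if (length(acc_means) > 1) expect_true(all(diff(acc_means) > 0))

  # bit-reproducible under the same seed
  r2 <- run_garf(co, k = 6, trees = 80, seed = 10)
  expect_identical(r$best_panel, r2$best_panel)
  expect_identical(vapply(r$history, `[[`, 1, "mean_fitness"),
                   vapply(r2$history, `[[`, 1, "mean_fitness"))
})

test_that("multi-run selection picks the best run's panel", {
  run_scores <- c(0.86, 0.91, 0.88)
  call_n <- 0
  evaluator <- function(panels, seeds) {
    call_n <<- call_n + 1
    rep(run_scores[call_n], length(panels))
  }
  res <- garf(cohorts = NULL, panel_size = 5, n_runs = 3, seed = 3,
              start_pool = sprintf("g%02d", 1:40), evaluator = evaluator,
              max_generations = 1)
  expect_identical(res$best_run, 2L)
  expect_equal(res$best_fitness, 0.91)
  expect_identical(res$best_panel, res$runs[[2]]$best_panel)

  # n_runs = 1 degenerates to that run's best
  call_n <- 0
  res1 <- garf(cohorts = NULL, panel_size = 5, n_runs = 1, seed = 3,
               start_pool = sprintf("g%02d", 1:40), evaluator = evaluator,
               max_generations = 1)
  expect_identical(res1$best_panel, res1$runs[[1]]$best_panel)
})

test_that("the holdout cohort never influences panel selection", {
  sim <- small_sim(seed = 5)
  co <- preprocess_cohorts(sim$cohorts)
  with_hold <- garf(co, panel_size = 5, n_runs = 2, trees = 60, seed = 13,
                    max_generations = 4)
  no_hold <- co
  no_hold$holdout <- NULL
  without <- garf(no_hold, panel_size = 5, n_runs = 2, trees = 60, seed = 13,
                  max_generations = 4)
  expect_identical(with_hold$best_panel, without$best_panel)
  expect_identical(with_hold$best_fitness, without$best_fitness)
  expect_false(is.na(with_hold$holdout_concordance))
  expect_true(is.na(without$holdout_concordance))

  # determinism of the full multi-run object
  again <- garf(co, panel_size = 5, n_runs = 2, trees = 60, seed = 13,
                max_generations = 4)
  expect_identical(with_hold$best_panel, again$best_panel)
  expect_identical(with_hold$holdout_concordance, again$holdout_concordance)
})

test_that("exact binomial counts match small closed forms and scale up", {
  expect_identical(big_choose(5, 2), "10")
  expect_identical(big_choose(10, 0), "1")
  expect_identical(big_choose(60, 30), "118264581564861424")
  # cross-check against log-scale arithmetic for a huge count
  s <- big_choose(200, 12)
  expect_identical(s, "6107693672247476400")
  expect_equal(nchar(big_choose(753, 48)) - 1, floor(lchoose(753, 48) / log(10)))
})
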