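test_that("expression tables parse, validate, and round-trip", {
  path <- withr::local_tempfile(fileext = ".tsv")
  writeLines(c("gene\ts1\ts2", "g1\t1.5\t2", "g2\t3\t4.25", "g3\t5\t6"), path)
  x <- read_expression_table(path)
  expect_equal(dim(x$values), c(3L, 2L))
  expect_equal(genes(x), c("g1", "g2", "g3"))
  expect_equal(x$values["g2", "s2"], 4.25)

  # round trip preserves representable decimals exactly
  out <- withr::local_tempfile(fileext = ".csv")
  write_expression_table(x, out, dialect = "csv")
  expect_equal(read_expression_table(out, dialect = "csv")$values, x$values)

  writeLines("gene\ts1\ts2", path)
  expect_error(read_expression_table(path), "no data rows")

  writeLines(c("gene\ts1\ts2", "g1\t1\t2", "g2\tNA\t4"), path)
  expect_error(read_expression_table(path), "gene 'g2'.*sample 's1'")

  writeLines(c("gene\ts1\ts1", "g1\t1\t2"), path)
  expect_error(read_expression_table(path), "duplicate sample ids")
})

test_that("constructor rejects malformed matrices", {
  m <- matrix(1:4, 2, dimnames = list(c("g1", "g2"), c("s1", "s2")))
  expect_s3_class(expression_matrix(m * 1.0), "expr_matrix")
  expect_error(expression_matrix(matrix(1:4, 2)), "rownames")
  bad <- m; bad[1, 1] <- NA
  expect_error(expression_matrix(bad * 1.0), "finite")
  dup <- m; rownames(dup) <- c("g1", "g1")
  expect_error(expression_matrix(dup * 1.0), "duplicate gene")
  expect_s3_class(expression_matrix(dup * 1.0, allow_duplicate_genes = TRUE),
                  "expr_matrix")
})

test_that("probe collapse keeps the brightest probe per gene", {
  vals <- rbind(p1 = c(4, 6), p2 = c(6, 8), p3 = c(1, 1))
  colnames(vals) <- c("s1", "s2")
  x <- expression_matrix(vals, allow_duplicate_genes = TRUE)
  pm <- c(p1 = "G", p2 = "G", p3 = "H")
  col <- collapse_probes(x, pm)
  expect_equal(genes(col), c("G", "H"))
  expect_equal(unname(col$values["G", ]), c(6, 8))  # p2, mean 7 > 5

  # one probe per gene: identity up to renaming
  one <- collapse_probes(x, c(p1 = "A", p2 = "B", p3 = "C"))
  expect_equal(unname(one$values), unname(vals))

  # ties broken by first probe in input order
  tie_vals <- matrix(c(2, 2, 3, 1), 2, byrow = TRUE,
                     dimnames = list(c("q1", "q2"), c("s1", "s2")))
  tie <- expression_matrix(tie_vals, allow_duplicate_genes = TRUE)
  keep <- collapse_probes(tie, c(q1 = "G", q2 = "G"))
  expect_equal(unname(keep$values["G", ]), c(2, 2))

  expect_error(collapse_probes(x, character(0)), "empty")
  expect_error(collapse_probes(x, c(p1 = "G")), "does not cover")
})

test_that("probe collapse matches a brute-force per-gene argmax oracle", {
  set.seed(42)
  vals <- matrix(rnorm(5 * 6), 5, 6,
                 dimnames = list(paste0("p", 1:5), paste0("s", 1:6)))
  x <- expression_matrix(vals, allow_duplicate_genes = TRUE)
  pm <- c(p1 = "G1", p2 = "G1", p3 = "G2", p4 = "G2", p5 = "G2")
  got <- collapse_probes(x, pm)
  # oracle: exhaustive argmax over each gene's probes
  for (g in c("G1", "G2")) {
    probes <- names(pm)[pm == g]
    best <- probes[which.max(sapply(probes, function(p) mean(vals[p, ])))]
    expect_equal(got$values[g, ], vals[best, ])
  }
  expect_equal(nrow(got$values), length(unique(pm)))
})

test_that("gene intersection restricts all cohorts to the shared sorted set", {
  mk <- function(gs, batch) {
    v <- matrix(seq_along(gs), ncol = 1,
                dimnames = list(gs, paste0(batch, "_s1")))
    v <- cbind(v, v + 1); colnames(v) <- paste0(batch, c("_s1", "_s2"))
    list(expr = expression_matrix(v, batch_id = batch),
         labels = stats::setNames(c("A", "B"), colnames(v)))
  }
  co <- cohort_collection(mk(c("A", "B", "C"), "t"),
                          list(mk(c("B", "C", "D"), "e")))
  out <- intersect_genes(co)
  expect_equal(attr(out, "shared_genes"), c("B", "C"))
  expect_equal(genes(out$training$expr), c("B", "C"))
  expect_equal(genes(out$evaluation[[1]]$expr), c("B", "C"))

  # identical sets: values unchanged up to ordering
  co2 <- cohort_collection(mk(c("C", "A", "B"), "t"),
                           list(mk(c("A", "B", "C"), "e")))
  out2 <- intersect_genes(co2)
  expect_equal(genes(out2$training$expr), c("A", "B", "C"))
  expect_equal(out2$training$expr$values["C", ],
               co2$training$expr$values["C", ])

  expect_error(intersect_genes(
    cohort_collection(mk(c("A", "B"), "t"), list(mk(c("C", "D"), "e")))),
    "empty gene intersection.*training=2.*evaluation1=2")
})

test_that("random gene sets intersect to the set-operation oracle", {
  set.seed(7)
  universe <- sprintf("g%03d", 1:100)
  sets <- lapply(c(50, 60, 70), function(n) sample(universe, n))
  mk <- function(gs, batch) {
    v <- matrix(rnorm(length(gs) * 2), ncol = 2,
                dimnames = list(gs, paste0(batch, c("_1", "_2"))))
    list(expr = expression_matrix(v, batch_id = batch),
         labels = stats::setNames(c("A", "B"), colnames(v)))
  }
  co <- cohort_collection(mk(sets[[1]], "t"),
                          list(mk(sets[[2]], "e1"), mk(sets[[3]], "e2")))
  out <- intersect_genes(co)
  oracle <- sort(intersect(intersect(sets[[1]], sets[[2]]), sets[[3]]))
  expect_equal(attr(out, "shared_genes"), oracle)
  gsets <- lapply(all_cohorts <- c(list(out$training), out$evaluation),
                  function(c) genes(c$expr))
  for (g in gsets) expect_equal(g, oracle)
})
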