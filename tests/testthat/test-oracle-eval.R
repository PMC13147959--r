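test_that("AUC matches brute-force pair counting and handles orientation", {
  expect_equal(roc_auc(c(0.9, 0.8, 0.7, 0.6), c(1, 0, 1, 0)), 0.75)
  # perfect separation
  expect_equal(roc_auc(c(5, 6, 7, 1, 2), c(1, 1, 1, 0, 0)), 1.0)
  # lower-is-better metric flips orientation
  expect_equal(roc_auc(c(0.5, 1.5, 2.5, 3.5), c(1, 1, 0, 0),
                       higher_is_better = FALSE), 1.0)

  set.seed(1)
  for (k in 1:100) {
    n <- sample(4:30, 1)
    scores <- sample(seq(0, 1, by = 0.1), n, replace = TRUE)  # force ties
    labels <- c(0, 1, sample(0:1, n - 2, replace = TRUE))
    expect_equal(roc_auc(scores, labels), pair_counting_auc(scores, labels),
                 tolerance = 1e-12)
  }
  expect_error(roc_auc(1:3, c(1, 1, 1)), "classes")
  expect_error(roc_auc(1:3, c(1, 0)), "mismatch")
})

test_that("AUC complement symmetry is exact and monotone-invariant", {
  set.seed(2)
  scores <- rnorm(500)
  labels <- rbinom(500, 1, 0.4)
  a <- roc_auc(scores, labels)
  expect_equal(a + roc_auc(scores, 1 - labels), 1, tolerance = 1e-15)
  expect_equal(roc_auc(exp(scores), labels), a, tolerance = 1e-12)
  expect_equal(roc_auc(rank(scores), labels), a, tolerance = 1e-12)
})

test_that("labels unrelated to scores give chance-level AUC", {
  set.seed(3)
  scores <- runif(2000)
  labels <- rbinom(2000, 1, 0.5)
  a <- roc_auc(scores, labels)
  expect_gt(a, 0.45)
  expect_lt(a, 0.55)
})

make_outcomes <- function(n, seed = 1) {
  set.seed(seed)
  data.frame(design_id = sprintf("d%04d", 1:n),
             plddt_mean = runif(n, 40, 100),
             scrmsd = runif(n, 0, 6),
             outcome = rbinom(n, 1, 0.4))
}

test_that("the default grid has 121 cells whose counts recount exactly", {
  tab <- make_outcomes(300, seed = 4)
  grid <- threshold_grid_sweep(tab)
  expect_equal(nrow(grid), 121L)
  expect_true(all(grid$tp + grid$fp + grid$fn + grid$tn == nrow(tab)))
  for (i in sample(nrow(grid), 25)) {
    pred <- tab$plddt_mean >= grid$plddt_min[i] &
      tab$scrmsd <= grid$scrmsd_max[i]
    expect_equal(grid$tp[i], sum(pred & tab$outcome == 1))
    expect_equal(grid$fp[i], sum(pred & tab$outcome == 0))
    expect_equal(grid$fn[i], sum(!pred & tab$outcome == 1))
    expect_equal(grid$tn[i], sum(!pred & tab$outcome == 0))
  }
  expect_true(all(grid$precision >= 0 & grid$precision <= 1))
  expect_true(all(grid$f1 >= 0 & grid$f1 <= 1))
})

test_that("the (70, 2.0) grid cell reproduces the designability pass set", {
  tab <- make_outcomes(200, seed = 5)
  grid <- threshold_grid_sweep(tab)
  cell <- grid[grid$plddt_min == 70 & grid$scrmsd_max == 2.0, ]
  records <- design_records(tab$design_id, "t", tab$plddt_mean, tab$scrmsd,
                            length = rep(100, nrow(tab)))
  expect_equal(cell$tp + cell$fp,
               round(designability_fraction(records, 70, 2.0) * nrow(tab)))
  expect_equal((cell$tp + cell$fp) / nrow(tab),
               designability_fraction(records, 70, 2.0))
})

test_that("a separable table reaches F1 = 1 somewhere", {
  tab <- data.frame(design_id = sprintf("d%d", 1:40),
                    plddt_mean = c(runif(20, 80, 100), runif(20, 40, 60)),
                    scrmsd = c(runif(20, 0, 1.5), runif(20, 3, 6)),
                    outcome = rep(c(1L, 0L), each = 20))
  grid <- threshold_grid_sweep(tab)
  expect_equal(max(grid$f1), 1.0)
})

test_that("optimum selection is stringent under ties", {
  tab <- make_outcomes(100, seed = 6)
  grid <- threshold_grid_sweep(tab)
  opt <- select_optimum(grid, "f1")
  expect_equal(opt$f1, max(grid$f1))
  ties <- grid[grid$f1 == max(grid$f1), ]
  expect_equal(opt$plddt_min, max(ties$plddt_min))
  best_p <- ties[ties$plddt_min == max(ties$plddt_min), ]
  expect_equal(opt$scrmsd_max, min(best_p$scrmsd_max))

  # degenerate: no predicted positive anywhere
  tab0 <- data.frame(design_id = "d", plddt_mean = 10, scrmsd = 10,
                     outcome = 1L)
  g0 <- threshold_grid_sweep(tab0)
  o0 <- select_optimum(g0, "precision")
  expect_true(attr(o0, "flagged"))
})

test_that("Fisher's exact test matches enumeration and base R", {
  expect_equal(fisher_exact_2x2(matrix(c(1, 1, 1, 1), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(5, 0, 0, 5), 2)), 2 / 252,
               tolerance = 1e-12)
  expect_equal(fisher_exact_2x2(matrix(c(0, 0, 3, 4), 2)), 1.0)
  expect_equal(fisher_exact_2x2(matrix(c(2, 0, 5, 0), 2)), 1.0)
  expect_error(fisher_exact_2x2(matrix(c(-1, 1, 1, 1), 2)), "negative")

  set.seed(7)
  for (k in 1:50) {
    tab <- matrix(rpois(4, 4), 2)
    if (sum(tab) == 0) tab[1, 1] <- 1
    expect_equal(fisher_exact_2x2(tab), fisher_enumeration_oracle(tab),
                 tolerance = 1e-9)
    expect_equal(fisher_exact_2x2(tab), fisher.test(tab)$p.value,
                 tolerance = 1e-7)
  }
})

test_that("length matching reproduces the case histogram proportionally", {
  set.seed(8)
  cases <- data.frame(length = sample(60:160, 40, replace = TRUE))
  # pool with at least 3x the cases everywhere
  pool <- data.frame(length = rep(cases$length, 5) +
                       sample(-2:2, 200, replace = TRUE))
  pool$length <- pmin(pmax(pool$length, 60), 160)
  sub <- matched_subset_by_length(cases, pool, n_bins = 10, rng_seed = 1)
  width <- (max(cases$length) - min(cases$length)) / 10
  bin_of <- function(x) pmin(floor((x - min(cases$length)) / width), 9)
  ch <- table(factor(bin_of(cases$length), levels = 0:9))
  sh <- table(factor(bin_of(sub$length), levels = 0:9))
  ratio <- as.numeric(sh[ch > 0]) / as.numeric(ch[ch > 0])
  expect_true(all(ratio == ratio[1]))
  expect_gte(ratio[1], 3)

  # self-matching returns the entire pool
  self <- matched_subset_by_length(cases, cases, n_bins = 10, rng_seed = 2)
  expect_equal(nrow(self), nrow(cases))

  empty_pool <- data.frame(length = rep(60, 5))
  expect_error(matched_subset_by_length(cases, empty_pool, 10, 1), "bin")
})

test_that("outcome tables round-trip through CSV", {
  tab <- make_outcomes(15, seed = 9)
  tab$dataset <- "setA"
  f <- withr::local_tempfile(fileext = ".csv")
  write_outcome_table(tab, f)
  tab2 <- read_outcome_table(f)
  expect_equal(tab2$outcome, tab$outcome)
  expect_equal(tab2$scrmsd, tab$scrmsd)
})
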