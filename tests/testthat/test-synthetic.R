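test_that("ideal backbones have trans-peptide CA spacing and reproduce", {
  for (lay in list(data.frame(state = "H", length = 15),
                   data.frame(state = c("H", "C", "E"), length = c(10, 6, 5)),
                   data.frame(state = "C", length = 12))) {
    s <- make_ideal_backbone(lay, seed = 5)
    d <- sqrt(rowSums(diff(s$ca_coords)^2))
    expect_true(all(d > 3.7 & d < 3.9))
  }
  a <- make_ideal_backbone(data.frame(state = "H", length = 10), seed = 9)
  b <- make_ideal_backbone(data.frame(state = "H", length = 10), seed = 9)
  expect_identical(a$ca_coords, b$ca_coords)
  expect_error(make_ideal_backbone(data.frame(state = "H", length = 0)[0, ]),
               "empty")
})

test_that("built helices close the loop with the secondary-structure module", {
  h <- make_ideal_backbone(data.frame(state = "H", length = 20), seed = 1)
  expect_gte(ss_composition(assign_secondary_structure(h))[["helix"]], 90)
})

test_that("compact steering yields domain-like extent", {
  # an 80-residue steered coil should be far more compact than the stiff
  # unsteered chain
  rg <- function(ca) sqrt(mean(rowSums(sweep(ca, 2, colMeans(ca))^2)))
  lay <- data.frame(state = "C", length = 80)
  expect_lt(rg(make_ideal_backbone(lay, seed = 2, compact = TRUE)$ca_coords),
            0.6 * rg(make_ideal_backbone(lay, seed = 2)$ca_coords))
})

test_that("a noise-free, tail-free prediction is the target itself", {
  sp <- synthetic_spec(core_length = 40, tail_c = 0, core_noise_sigma = 0,
                      tail_mode = "none", seed = 3)
  pair <- synthetic_pair(sp)
  expect_equal(scrmsd(pair$prediction, pair$target, "mean"), 0,
               tolerance = 1e-9)
  expect_equal(chain_length(pair$prediction), 40L)
})

test_that("core noise produces the expected scRMSD scale", {
  sp <- synthetic_spec(core_length = 80, tail_c = 0, core_noise_sigma = 0.5,
                      tail_mode = "none", seed = 4)
  target <- make_target(sp)
  vals <- sapply(1:300, function(k)
    scrmsd(simulate_prediction(target, sp, seed = 1000L + k), target, "mean"))
  expected <- sqrt(3) * 0.5
  expect_gt(mean(vals), 0.8 * expected)
  expect_lt(mean(vals), 1.2 * expected)
})

test_that("predictions are deterministic given the seed", {
  sp <- synthetic_spec(seed = 6)
  p1 <- synthetic_pair(sp)
  p2 <- synthetic_pair(sp)
  expect_identical(p1$prediction$ca_coords, p2$prediction$ca_coords)
  expect_identical(p1$prediction$plddt, p2$prediction$plddt)
  p3 <- simulate_prediction(p1$target, sp, seed = 999L)
  expect_false(identical(p1$prediction$ca_coords, p3$ca_coords))
})

test_that("hinged tails inflate the naive scRMSD but not the corrected one", {
  n_ok_naive <- 0; n_ok_corr <- 0; n_seeds <- 40
  for (s in seq_len(n_seeds)) {
    pair <- synthetic_pair(synthetic_spec(seed = s))
    if (scrmsd(pair$prediction, pair$target, "mean") > 2.0)
      n_ok_naive <- n_ok_naive + 1
    if (corrected_scrmsd(pair$prediction, pair$target)$scrmsd <= 2.0)
      n_ok_corr <- n_ok_corr + 1
  }
  expect_gte(n_ok_naive / n_seeds, 0.95)
  expect_gte(n_ok_corr / n_seeds, 0.9)

  # noise-free construction: the corrected median collapses to ~0
  sp0 <- synthetic_spec(core_noise_sigma = 0, seed = 77)
  pr0 <- synthetic_pair(sp0)
  expect_gt(scrmsd(pr0$prediction, pr0$target, "mean"), 2.0)
  expect_lt(corrected_scrmsd(pr0$prediction, pr0$target)$scrmsd, 0.5)
})

test_that("random-walk tails behave like divergent termini too", {
  sp <- synthetic_spec(tail_mode = "walk", seed = 12)
  pair <- synthetic_pair(sp)
  d <- sqrt(rowSums(diff(pair$prediction$ca_coords[81:100, ])^2))
  expect_true(all(abs(d - 3.8) < 1e-6))
  expect_gt(scrmsd(pair$prediction, pair$target, "mean"),
            corrected_scrmsd(pair$prediction, pair$target)$scrmsd)
})

test_that("tail confidence is low and core confidence high", {
  pair <- synthetic_pair(synthetic_spec(seed = 13))
  expect_gt(mean(pair$prediction$plddt[1:80]), 80)
  expect_lt(mean(pair$prediction$plddt[81:100]), 60)
  expect_true(all(pair$prediction$plddt >= 0 & pair$prediction$plddt <= 100))
})

test_that("simulated MSAs have controlled depth and diversity", {
  q <- random_aa_seq(50)
  m0 <- simulate_msa(q, depth = 0, seed = 1)
  expect_equal(median_neff(m0), 1.0)

  m_same <- simulate_msa(q, depth = 100, divergence = 0, gap_rate = 0,
                         seed = 2)
  expect_equal(median_neff(m_same), 1.0)

  # Neff grows with divergence at fixed depth
  for (s in 1:3) {
    lo <- median_neff(simulate_msa(q, 20, divergence = 0.05, seed = s))
    hi <- median_neff(simulate_msa(q, 20, divergence = 0.5, seed = s))
    expect_gt(hi, lo)
  }
  expect_identical(simulate_msa(q, 10, seed = 5)$rows,
                   simulate_msa(q, 10, seed = 5)$rows)
})

test_that("logistic outcomes recover the planted metric effects", {
  set.seed(20)
  records <- design_records(sprintf("d%d", 1:2000), "t",
                            plddt_mean = runif(2000, 65, 95),
                            scrmsd_naive = runif(2000, 0, 6),
                            length = rep(100, 2000))
  null_tab <- simulate_outcomes(records, outcome_model(0, 0, 0, seed = 1))
  a0 <- roc_auc(null_tab$plddt_mean, null_tab$outcome)
  expect_gt(a0, 0.45); expect_lt(a0, 0.55)

  eff <- simulate_outcomes(records,
                           outcome_model(-13, 0.2, -1.0, seed = 2))
  expect_gt(roc_auc(eff$plddt_mean, eff$outcome), 0.75)
  expect_gt(roc_auc(eff$scrmsd, eff$outcome, higher_is_better = FALSE), 0.75)
  expect_true(all(eff$outcome %in% 0:1))
})
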