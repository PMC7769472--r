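test_that("MCOA pairwise kappa matches frozen hand-computed values", {
  expect_equal(as.numeric(mcoa_pair_kappa(0.3, 0.3)), 1)
  # margins (2,8) vs (4,6) on 10 cases: max diagonal 8, p_e 0.56
  expect_equal(as.numeric(mcoa_pair_kappa(0.2, 0.4)), 0.24 / 0.44)
  # disjoint margins: zero possible agreement, but chance agreement is also
  # zero, so the kappa-maximum floors at exactly 0 -- it is never negative,
  # since p_o_max - p_e = 2 min(p_a, p_b) min(1-p_a, 1-p_b) >= 0
  expect_equal(as.numeric(mcoa_pair_kappa(0, 1)), 0)
  withr::with_seed(3, {
    expect_true(all(mcoa_pair_kappa(runif(200), runif(200)) >= 0))
  })
  expect_error(mcoa_pair_kappa(-0.1, 0.5), "\\[0, 1\\]")
})

test_that("MCOA kappa is symmetric and flags forced agreement", {
  withr::with_seed(1, {
    pa <- runif(50); pb <- runif(50)
    expect_equal(as.numeric(mcoa_pair_kappa(pa, pb)),
                 as.numeric(mcoa_pair_kappa(pb, pa)))
  })
  k <- mcoa_pair_kappa(0, 0)
  expect_equal(as.numeric(k), 1)
  expect_true(attr(k, "degenerate"))
})

test_that("OMECA pairwise kappa matches frozen cumulative-overlap values", {
  expect_equal(as.numeric(omeca_pair_kappa(c(0.2, 0.5, 0.3), c(0.2, 0.5, 0.3))), 1)
  # overlaps 0.2 + 0.4 + 0.3 = 0.9; p_e = 0.35
  expect_equal(as.numeric(omeca_pair_kappa(c(0.2, 0.5, 0.3), c(0.3, 0.4, 0.3))),
               (0.9 - 0.35) / 0.65)
  # fully polarized raters: no overlap, but also no chance agreement
  expect_equal(as.numeric(omeca_pair_kappa(c(1, 0, 0), c(0, 0, 1))), 0)
  # disjoint intervals with shared middle mass: genuinely negative
  expect_equal(as.numeric(omeca_pair_kappa(c(0.6, 0.4, 0), c(0, 0.4, 0.6))),
               -0.16 / 0.84)
  expect_error(omeca_pair_kappa(c(0.5, 0.4, 0.2), c(0.3, 0.3, 0.4)), "sum to 1")
  degen <- omeca_pair_kappa(c(0, 1, 0), c(0, 1, 0))
  expect_true(attr(degen, "degenerate"))
  expect_equal(as.numeric(degen), 1)
})

test_that("OMECA kappa is symmetric and bounded by the multi-category kappa-maximum", {
  withr::with_seed(2, {
    for (rep in 1:100) {
      a <- random_pir(); b <- random_pir()
      k_ab <- as.numeric(omeca_pair_kappa(a, b))
      expect_equal(k_ab, as.numeric(omeca_pair_kappa(b, a)), tolerance = 1e-12)
      # overlap numerator is at most sum_k min(a_k, b_k) (Sim-Wright numerator)
      p_e <- sum(a * b)
      k_max <- (sum(pmin(a, b)) - p_e) / (1 - p_e)
      expect_lte(k_ab, k_max + 1e-12)
      expect_gte(k_ab, -1); expect_lte(k_ab, 1)
    }
  })
})

test_that("group ISK is the unweighted mean over unordered pairs", {
  # binary rates 0.2, 0.2, 0.4 at one level
  pir <- rbind(c(0.2, 0.5, 0.3), c(0.2, 0.4, 0.4), c(0.4, 0.3, 0.3))
  prof <- profile_from_pir(pir, 100)
  k <- group_isk(prof, "MCOA", score_level = 1)
  expect_equal(k, (1 + 2 * 0.24 / 0.44) / 3, tolerance = 1e-12)

  # identical raters agree perfectly under both assumptions
  same <- profile_from_pir(matrix(rep(c(0.2, 0.5, 0.3), 10), 10, byrow = TRUE), 100)
  expect_equal(group_isk(same, "MCOA", score_level = 2), 1)
  expect_equal(group_isk(same, "OMECA"), 1)
})

test_that("group ISK input contracts are enforced", {
  prof <- profile_from_pir(rbind(c(0.2, 0.5, 0.3), c(0.3, 0.4, 0.3)), 50)
  expect_error(group_isk(prof, "OMECA", score_level = 1), "whole axis")
  expect_error(group_isk(prof, "MCOA"), "score_level")
  prof$flagged[2] <- TRUE
  expect_warning(expect_error(group_isk(prof, "OMECA"), "at least 2"),
                 "excluded")
})

test_that("volume weighting changes the pairwise mean as expected", {
  pir <- rbind(c(0.2, 0.5, 0.3), c(0.2, 0.5, 0.3), c(0.45, 0.3, 0.25))
  prof <- profile_from_pir(pir, c(400, 400, 40))
  unw <- group_isk(prof, "OMECA")
  wt <- group_isk(prof, "OMECA", weighting = "volume")
  # the identical high-volume pair dominates the weighted mean
  expect_gt(wt, unw)
})

test_that("bootstrap CI is deterministic under its seed and brackets the point", {
  cases <- simulate_cohort(paper_like_preset(seed = 6))
  prof <- profile_raters(cases, "NS", summarize_cohort(cases)$eligible_rater_ids)
  e1 <- bootstrap_ci(prof, "MCOA", 1, n_boot = 300, seed = 99)
  e2 <- bootstrap_ci(prof, "MCOA", 1, n_boot = 300, seed = 99)
  expect_identical(e1$ci_low, e2$ci_low)
  expect_identical(e1$replicates, e2$replicates)
  e3 <- bootstrap_ci(prof, "MCOA", 1, n_boot = 300, seed = 100)
  expect_false(identical(e1$ci_low, e3$ci_low))

  expect_lte(e1$ci_low, e1$statistic)
  expect_gte(e1$ci_high, e1$statistic)
  expect_equal(e1$target, "NS1")
})

test_that("bootstrap of identical high-volume raters concentrates near 1", {
  prof <- profile_from_pir(matrix(rep(c(0.25, 0.5, 0.25), 6), 6, byrow = TRUE),
                           2000)
  e <- bootstrap_ci(prof, "OMECA", NULL, n_boot = 300, seed = 5)
  expect_equal(e$statistic, 1)
  expect_gt(e$ci_low, 0.9)
  expect_lte(e$ci_high, 1)
  expect_error(bootstrap_ci(prof, "OMECA", NULL, n_boot = 100), "at least 200")
})

test_that("ISK recovers perfect agreement and separates distinct raters", {
  group <- list(TS = c(9, 23, 66) / 98, NS = c(5, 57, 37) / 99,
                MS = c(57, 21, 20) / 98)
  shared <- synthetic_config(6, volumes = rep(5000, 6), true_pir = group,
                             seed = 21)
  cases <- simulate_cohort(shared)
  k_same <- group_isk(profile_raters(cases, "NS"), "OMECA")
  expect_gt(k_same, 0.95)

  far <- group
  far$NS <- rbind(matrix(rep(c(0.7, 0.2, 0.1), 3), 3, byrow = TRUE),
                  matrix(rep(c(0.1, 0.2, 0.7), 3), 3, byrow = TRUE))
  cases2 <- simulate_cohort(synthetic_config(6, volumes = rep(5000, 6),
                                             true_pir = far, seed = 21))
  k_far <- group_isk(profile_raters(cases2, "NS"), "OMECA")
  expect_lt(k_far, k_same - 0.2)
})
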