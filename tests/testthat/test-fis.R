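test_that("subset sampling is uniform, reproducible and validated", {
  expect_error(sample_subsets(5, 6, 10), "cannot exceed")
  # K = m: every draw is the full panel
  s <- sample_subsets(3, 3, 25, seed = 4)
  expect_true(all(apply(s, 1, function(r) setequal(r, 1:3))))
  # determinism
  expect_identical(sample_subsets(18, 7, 500, seed = 11),
                   sample_subsets(18, 7, 500, seed = 11))
  # within-draw distinctness and uniform inclusion (binomial 3 SE band)
  s <- sample_subsets(18, 7, 5000, seed = 2)
  expect_true(all(apply(s, 1, anyDuplicated) == 0))
  freq <- tabulate(s, 18) / nrow(s)
  p <- 7 / 18
  se <- sqrt(p * (1 - p) / nrow(s))
  expect_true(all(abs(freq - p) < 3.5 * se))
})

test_that("single-subset FIS matches direct distance arithmetic", {
  cfg0 <- overlap_config(0)
  ctrl <- random_profiles(3, 4, seed = 1)
  case <- random_profiles(1, 4, seed = 2)
  J <- c(1, 2, 4)
  for (j in J) {
    expect_equal(fis_one(case, ctrl, J, j, cfg = cfg0),
                 oracle_fis(case, ctrl, J, j), tolerance = 1e-12)
  }
  expect_error(fis_one(case, ctrl, J, 3, cfg = cfg0), "member")
  expect_error(fis_one(case, ctrl, 2, 2, cfg = cfg0), "at least 2")
})

test_that("a feature carrying the only case-control difference scores positive", {
  base <- c(10, 10, 10, 10)
  ctrl <- rbind(base, base, base)
  case <- c(40, 10, 10, 10)  # differs only in feature 1
  cfg <- overlap_config(0.5)
  subsets <- enumerate_subsets(4, 3)
  with1 <- subsets[apply(subsets, 1, function(r) 1 %in% r), , drop = FALSE]
  for (s in seq_len(nrow(with1))) {
    J <- with1[s, ]
    f1 <- fis_one(case, ctrl, J, 1, cfg = cfg)
    expect_gt(f1, 0)
    # the perturbed feature always dominates the unaffected ones that share
    # its subset (an unaffected feature's own FIS can take either sign: it
    # also measures how much it dilutes the divergence carried by feature 1)
    for (j in setdiff(J, 1)) {
      expect_gt(f1, fis_one(case, ctrl, J, j, cfg = cfg))
    }
  }
  # identical case: FIS is exactly zero everywhere
  for (s in seq_len(nrow(subsets))) {
    J <- subsets[s, ]
    for (j in J) expect_equal(fis_one(base, ctrl, J, j, cfg = cfg), 0)
  }
})

test_that("the batch engine reproduces exhaustive R-level medians exactly", {
  ctrl <- random_profiles(4, 4, seed = 31)
  cases <- random_profiles(2, 4, seed = 32)
  subsets <- enumerate_subsets(4, 2)
  res <- median_fis(cases, ctrl, subsets, cfg = overlap_config(0.5))
  for (c_i in 1:2) {
    expect_equal(unname(res$medians[c_i, ]),
                 oracle_median_fis(cases[c_i, , drop = FALSE], ctrl,
                                   subsets, pc = 0.5),
                 tolerance = 1e-12)
  }
  expect_equal(unname(res$n_evals), rep(3L, 4))
})

test_that("null cases yield zero medians; unsampled features warn", {
  base <- c(5, 6, 7, 8)
  ctrl <- rbind(base, base, base)
  res <- median_fis(rbind(base), ctrl, enumerate_subsets(4, 2),
                    cfg = overlap_config(0.5))
  expect_true(all(abs(res$medians) < 1e-12))
  expect_warning(
    res2 <- median_fis(rbind(base), ctrl, rbind(c(1L, 2L)),
                       cfg = overlap_config(0.5)),
    "never sampled")
  expect_true(all(is.na(res2$medians[, 3:4])))
})

test_that("median FIS grows with the injected effect size", {
  base <- c(10, 10, 10, 10, 10, 10)
  ctrl <- rbind(base, base, base, base)
  subsets <- enumerate_subsets(6, 3)
  meds <- sapply(c(0.5, 1, 2, 4), function(f) {
    case <- base; case[2] <- base[2] * 2^f
    median_fis(rbind(case), ctrl, subsets,
               cfg = overlap_config(0.5))$medians[1, 2]
  })
  expect_true(all(diff(meds) > 0))
})

test_that("significance calling flags consistently positive features only", {
  set.seed(8)
  n <- 20
  medians <- cbind(
    pos = abs(rnorm(n, 0.05, 0.01)),        # positive in every case
    sym = rnorm(n, 0, 0.05),                # symmetric about zero
    zero = rep(0, n)                        # degenerate
  )
  tab <- fis_significance(medians, fdr_alpha = 0.05)
  expect_true(tab$significant[tab$feature == "pos"])
  expect_false(tab$significant[tab$feature == "sym"])
  expect_equal(tab$p[tab$feature == "zero"], 1)
  expect_error(fis_significance(medians[1:3, ]), "at least 5")
})

test_that("run_fis is seed-deterministic end to end", {
  cs <- toy_cohort(K = 6, n_case = 5, n_ctrl = 6, seed = 12)
  cfg <- fis_config(subset_size = 3, n_subsets = 300, seed = 21)
  r1 <- run_fis(cs, "hiv_pos", cfg = cfg)
  r2 <- run_fis(cs, "hiv_pos", cfg = cfg)
  expect_identical(r1$table, r2$table)
  expect_identical(r1$medians, r2$medians)
  # per-visit mode restricts the cases
  r56 <- run_fis(cs, "hiv_pos", timepoint = 56, cfg = cfg)
  expect_equal(nrow(r56$medians), 5)
  expect_equal(nrow(r1$medians), 15)
})
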