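test_that("I-index hits its analytic anchors", {
  cfg0 <- overlap_config(pseudocount = 0)
  # identical profiles: zero divergence
  x <- rbind(c(3, 2, 1), c(3, 2, 1))
  expect_equal(i_index(x, cfg = cfg0), 1)
  # disjoint supports: maximal divergence
  y <- rbind(c(1, 0, 0, 0), c(0, 0, 2, 3))
  expect_equal(i_index(y, cfg = cfg0), 0)
  # hand-computed half-overlap pair: H(P)=H(Q)=log 2, M=(1/4,1/2,1/4)
  p <- rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5))
  expected <- 1 - (h2(c(0.25, 0.5, 0.25)) - 1) / 1  # log2 oracle
  expect_equal(i_index(p, cfg = cfg0), expected, tolerance = 1e-12)
})

test_that("I-index is symmetric, bounded and matches the entropy oracle", {
  for (seed in 1:25) {
    n <- sample(2:5, 1)
    K <- sample(3:8, 1)
    x <- random_profiles(n, K, seed)
    v <- i_index(x, cfg = overlap_config(0))
    expect_gte(v, 0)
    expect_lte(v, 1)
    # profile-order and population-order invariance
    expect_equal(i_index(x[rev(seq_len(n)), ], cfg = overlap_config(0)), v)
    expect_equal(i_index(x[, rev(seq_len(K))], cfg = overlap_config(0)), v)
    # base invariance: the oracle works in log2, the package in nats
    expect_equal(v, oracle_i_index(x), tolerance = 1e-12)
    # pseudocount path agrees too
    expect_equal(i_index(x, cfg = overlap_config(0.5)),
                 oracle_i_index(x, pc = 0.5), tolerance = 1e-12)
  }
})

test_that("restriction to a feature subset equals explicit renormalization", {
  x <- random_profiles(4, 6, seed = 42)
  S <- c(2, 3, 5)
  direct <- i_index(x, subset = S, cfg = overlap_config(0))
  renorm <- x[, S] / rowSums(x[, S])
  expect_equal(direct, i_index(renorm, cfg = overlap_config(0)),
               tolerance = 1e-12)
})

test_that("set_distance measures the overlap lost by adding the case", {
  cfg0 <- overlap_config(0)
  ctrl <- rbind(c(5, 5, 5, 5), c(5, 5, 5, 5), c(5, 5, 5, 5))
  # duplicate case adds nothing
  expect_equal(set_distance(c(5, 5, 5, 5), ctrl, cfg = cfg0), 0)
  # disjoint-support case strictly reduces overlap
  ctrl2 <- rbind(c(1, 1, 0, 0), c(1, 1, 0, 0))
  expect_gt(set_distance(c(0, 0, 1, 1), ctrl2, cfg = cfg0), 0)
  # fixed instance equals two direct generalized-JSD oracle evaluations
  ctrl3 <- random_profiles(3, 4, seed = 9)
  case <- random_profiles(1, 4, seed = 10)
  expect_equal(set_distance(case, ctrl3, cfg = cfg0),
               oracle_set_distance(case, ctrl3, 1:4), tolerance = 1e-12)
  # restriction precedes entropy computation
  expect_equal(set_distance(case, ctrl3, subset = c(1, 3), cfg = cfg0),
               oracle_set_distance(case, ctrl3, c(1, 3)), tolerance = 1e-12)
  expect_error(set_distance(case, ctrl3, subset = integer(0)), "non-empty")
  expect_error(set_distance(case, ctrl3[1, , drop = FALSE]), "2 controls")
})

test_that("trajectory distance is 1 - I of the pooled set and tracks effect size", {
  cfg0 <- overlap_config(0)
  ctrl <- rbind(c(4, 3, 2, 1), c(4, 3, 2, 1), c(4, 3, 2, 1))
  # case identical to homogeneous controls: duplicate changes nothing
  expect_equal(trajectory_distance(c(4, 3, 2, 1), ctrl, cfg = cfg0),
               1 - i_index(ctrl, cfg = cfg0), tolerance = 1e-12)
  # disjoint case value from the oracle
  case <- c(0, 0, 0, 9)
  ctrl2 <- rbind(c(1, 1, 1, 0), c(1, 1, 1, 0))
  expect_equal(trajectory_distance(case, ctrl2, cfg = cfg0),
               1 - oracle_i_index(rbind(ctrl2, case)), tolerance = 1e-12)
  # shrinking the case toward the control mean never increases the distance
  base <- c(10, 10, 10, 10)
  shift <- c(30, -5, -5, -5)
  ctrlh <- rbind(base, base, base, base)
  d <- sapply(c(1, 0.6, 0.3, 0), function(a)
    trajectory_distance(base + a * shift, ctrlh, cfg = overlap_config(0.5)))
  expect_true(all(diff(d) <= 1e-12))
})

test_that("similarity matrices are symmetric, unit-diagonal pairwise I-indexes", {
  x <- random_profiles(4, 5, seed = 5)
  cs_like <- x
  sm <- similarity_matrix(cs_like, cfg = overlap_config(0))
  expect_equal(diag(sm$values), setNames(rep(1, 4), rownames(x)))
  expect_true(isSymmetric(unname(sm$values)))
  for (i in 1:3) for (j in (i + 1):4) {
    expect_equal(sm$values[i, j],
                 i_index(x[c(i, j), ], cfg = overlap_config(0)),
                 tolerance = 1e-12)
  }
  # permutation equivariance
  perm <- c(3, 1, 4, 2)
  sm2 <- similarity_matrix(x[perm, ], cfg = overlap_config(0))
  expect_equal(sm2$values, sm$values[perm, perm])
  # identical pair
  z <- rbind(a = c(1, 2), b = c(1, 2))
  expect_equal(unname(similarity_matrix(z, cfg = overlap_config(0))$values),
               matrix(1, 2, 2))
})

test_that("overlap usage errors are caught", {
  expect_error(i_index(rbind(c(1, 2, 3))), "at least 2")
  expect_error(overlap_config(-1), "non-negative")
})
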