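# Independent direct-entropy oracles, deliberately written in log base 2 with
# explicit loops so they share no code path (and no log base) with the package.

h2 <- function(p) {
  s <- 0
  for (v in p) if (v > 0) s <- s - v * log2(v)
  s
}

oracle_i_index <- function(x, pc = 0) {
  x <- rbind(x) + pc
  n <- nrow(x)
  p <- x
  for (i in seq_len(n)) p[i, ] <- x[i, ] / sum(x[i, ])
  mix <- colSums(p) / n
  jsd <- h2(mix) - sum(apply(p, 1, h2)) / n
  1 - jsd / log2(n)
}

oracle_set_distance <- function(case, ctrl, S, pc = 0) {
  oracle_i_index(ctrl[, S, drop = FALSE], pc) -
    oracle_i_index(rbind(ctrl, case)[, S, drop = FALSE], pc)
}

oracle_fis <- function(case, ctrl, J, j, pc = 0) {
  oracle_set_distance(case, ctrl, J, pc) -
    oracle_set_distance(case, ctrl, setdiff(J, j), pc)
}

# Exhaustive per-feature median FIS for one case over a subset matrix.
oracle_median_fis <- function(case, ctrl, subsets, pc = 0) {
  K <- ncol(ctrl)
  vals <- vector("list", K)
  for (s in seq_len(nrow(subsets))) {
    J <- subsets[s, ]
    for (j in J) {
      vals[[j]] <- c(vals[[j]], oracle_fis(case, ctrl, J, j, pc))
    }
  }
  vapply(vals, function(v) if (is.null(v)) NA_real_ else median(v), numeric(1))
}

# Plain single-pass average-linkage agglomeration over a distance matrix,
# returning the sequence of merge heights.
oracle_average_linkage_heights <- function(d) {
  groups <- as.list(seq_len(nrow(d)))
  heights <- numeric(0)
  while (length(groups) > 1) {
    best <- c(NA, NA)
    best_d <- Inf
    for (a in seq_len(length(groups) - 1)) {
      for (b in seq(a + 1, length(groups))) {
        dd <- mean(d[groups[[a]], groups[[b]]])
        if (dd < best_d) {
          best_d <- dd
          best <- c(a, b)
        }
      }
    }
    heights <- c(heights, best_d)
    groups[[best[1]]] <- c(groups[[best[1]]], groups[[best[2]]])
    groups[[best[2]]] <- NULL
  }
  heights
}

# Small random counts-profile matrix (strictly positive so pseudocount-0
# entropies are finite).
random_profiles <- function(n, K, seed) {
  set.seed(seed)
  matrix(rgamma(n * K, shape = 2, rate = 1) + 0.05, nrow = n,
         dimnames = list(paste0("p", seq_len(n)), paste0("f", seq_len(K))))
}

# Tiny valid cohort_set built in code: nc cases x 3 visits plus controls.
toy_cohort <- function(K = 4, n_case = 3, n_ctrl = 4, seed = 1) {
  set.seed(seed)
  panel <- population_panel(paste0("pop", seq_len(K)))
  meta <- rbind(
    expand.grid(subject_id = sprintf("S%02d", seq_len(n_case)),
                timepoint_days = c(56L, 180L, 365L),
                stringsAsFactors = FALSE),
    data.frame(subject_id = sprintf("C%02d", seq_len(n_ctrl)),
               timepoint_days = NA_integer_)
  )
  meta$cohort <- c(rep("hiv_pos", n_case * 3), rep("control", n_ctrl))
  counts <- matrix(rpois(nrow(meta) * K, lambda = 50) + 1, nrow = nrow(meta))
  colnames(counts) <- panel$ids
  cohort_set(panel, meta, counts)
}
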