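#' Cohort effect templates
#'
#' An effect template perturbs one population's mean proportion in a case
#' cohort relative to the control baseline, on the log2 scale, with a
#' per-visit decay multiplier encoding convergence toward controls over the
#' post-transplant year. The effective log2 fold change at visit v is
#' `log2fc * decay[v]`.
#'
#' @param feature population id the effect acts on.
#' @param log2fc log2 fold effect versus the control mean (positive or
#'   negative).
#' @param decay per-visit multipliers over the case visits, values in
#'   \[0, 1\], non-increasing.
#' @return An object of class `effect_template`.
#' @export
effect_template <- function(feature, log2fc, decay = c(1, 0.6, 0.35)) {
  if (any(decay < 0) || any(decay > 1)) {
    stop("decay values must lie in [0, 1]", call. = FALSE)
  }
  if (is.unsorted(rev(decay))) {
    stop("decay must be non-increasing across visits", call. = FALSE)
  }
  structure(list(feature = feature, log2fc = log2fc, decay = decay),
            class = "effect_template")
}

#' Default cohort effect templates
#'
#' Encodes the qualitative direction catalog of the study cohorts. The
#' HIV-positive template elevates activated T cells and memory/effector
#' cytotoxic T cells and depresses naive/memory T helper cells, activated B
#' cells and NK subsets, with effects decaying toward controls across the
#' three visits. The HIV-negative template carries transient early effects —
#' elevated late-activated T cells (CD134+ without CD69) and activated /
#' degranulating NK subsets at day 56 — that resolve fully by day 365.
#'
#' @param panel a [population_panel()] (the preset 18- or 100-population
#'   panel, or any panel containing the affected ids).
#' @return Named list with `hiv_pos` and `hiv_neg` elements, each a list of
#'   [effect_template()]s restricted to populations present in the panel.
#' @export
default_templates <- function(panel) {
  stopifnot(inherits(panel, "population_panel"))
  hp <- list(
    effect_template("CD3+/HLA-DR+",                1.5),
    effect_template("CD3+/HLA-DR+/CD69+/CD134-",   1.5),
    effect_template("CD8+/CD45RA-",                1.2),
    effect_template("CD8+/CD45RO+",                1.2),
    effect_template("CD8+/CD27-",                  1.0),
    effect_template("Total CD8+",                  1.0),
    effect_template("CD3+/CD86+",                  0.8),
    effect_template("CD4+/CD45RA+",               -1.5),
    effect_template("CD4+/CD45RO+",               -1.0),
    effect_template("CD4+/CD27+",                 -0.8),
    effect_template("CD3+/CD134+",                -0.8),
    effect_template("CD19+/CD80+",                -1.5),
    effect_template("CD19+/CD86+",                -1.0),
    effect_template("CD3-/CD56+/CD16+/CD134+",    -1.2),
    effect_template("CD3-/CD56+/CD16+/CD159a+",   -1.0)
  )
  hn <- list(
    effect_template("CD3+/HLA-DR+/CD134+/CD69-",   1.5, decay = c(1, 0.5, 0)),
    effect_template("CD3-/CD56+/CD16+/CD107a/b+",  1.5, decay = c(1, 0.5, 0)),
    effect_template("CD3-/CD56+/CD16+/CD134+",     1.0, decay = c(1, 0.5, 0)),
    effect_template("CD3+/HLA-DR+",                0.8, decay = c(1, 0.5, 0))
  )
  keep <- function(tpl) Filter(function(t) t$feature %in% panel$ids, tpl)
  list(hiv_pos = keep(hp), hiv_neg = keep(hn))
}

# Plausible mean control proportions for the 18-subset panel (relative
# abundances over the panel; renormalized on use). Order follows the preset.
.baseline18 <- c(
  0.080, 0.020, 0.010, 0.020, 0.030,
  0.120, 0.100, 0.110,
  0.180, 0.060, 0.050, 0.030,
  0.015, 0.015,
  0.070, 0.020, 0.005, 0.015
)

# Baseline for an arbitrary panel: curated values where known, a smooth
# geometric abundance decay elsewhere.
default_baseline <- function(panel) {
  stopifnot(inherits(panel, "population_panel"))
  p18 <- panel_preset(18)$ids
  base <- exp(seq(log(0.05), log(5e-4), length.out = panel$K))
  names(base) <- panel$ids
  known <- intersect(panel$ids, p18)
  base[known] <- .baseline18[match(known, p18)]
  base / sum(base)
}

#' Simulation configuration
#'
#' Defines the three-cohort longitudinal study the generator emulates: an
#' HIV-positive transplant cohort (default n = 37) and an HIV-negative
#' transplant cohort (n = 30) sampled at days 56, 180 and 365, and a healthy
#' control cohort (n = 71) sampled once. Compositions are drawn
#' Dirichlet-multinomially around cohort-by-visit mean proportions (so
#' populations compete compositionally, matching percent-of-lymphocytes
#' measurement), with total lymphocyte counts drawn log-normally (cells/uL).
#'
#' @param panel a [population_panel()] (default: the 18-subset preset).
#' @param n_hiv_pos,n_hiv_neg,n_control cohort sizes (>= 3).
#' @param timepoints case visit days.
#' @param baseline mean control proportion vector over the panel (default
#'   [default_baseline()]); normalized to sum to 1.
#' @param concentration Dirichlet concentration (larger = less compositional
#'   overdispersion).
#' @param total_meanlog,total_sdlog log-normal parameters of the absolute
#'   lymphocyte count (cells/uL).
#' @param templates named list of cohort effect-template lists (default
#'   [default_templates()]); `NULL` or empty lists give a null (no-effect)
#'   simulation.
#' @param seed RNG seed; the generator is fully seed-deterministic.
#' @return An object of class `sim_config`.
#' @export
sim_config <- function(panel = panel_preset(18),
                       n_hiv_pos = 37, n_hiv_neg = 30, n_control = 71,
                       timepoints = c(56, 180, 365),
                       baseline = NULL, concentration = 150,
                       total_meanlog = log(1800), total_sdlog = 0.35,
                       templates = default_templates(panel), seed = 1) {
  stopifnot(inherits(panel, "population_panel"))
  if (min(n_hiv_pos, n_hiv_neg, n_control) < 3) {
    stop("cohort sizes must be >= 3", call. = FALSE)
  }
  if (is.null(baseline)) baseline <- default_baseline(panel)
  if (length(baseline) != panel$K) {
    stop("baseline must have one value per panel population", call. = FALSE)
  }
  if (any(baseline <= 0)) stop("baseline proportions must be positive",
                               call. = FALSE)
  baseline <- baseline / sum(baseline)
  if (is.null(templates)) templates <- list(hiv_pos = list(), hiv_neg = list())
  for (cohort in names(templates)) {
    for (t in templates[[cohort]]) {
      if (!t$feature %in% panel$ids) {
        stop("effect on unknown feature: ", t$feature, call. = FALSE)
      }
      if (length(t$decay) != length(timepoints)) {
        stop("decay length must match the number of visits", call. = FALSE)
      }
    }
  }
  structure(list(panel = panel, n_hiv_pos = n_hiv_pos, n_hiv_neg = n_hiv_neg,
                 n_control = n_control, timepoints = timepoints,
                 baseline = baseline, concentration = concentration,
                 total_meanlog = total_meanlog, total_sdlog = total_sdlog,
                 templates = templates, seed = as.integer(seed)),
            class = "sim_config")
}

# Cohort-by-visit mean proportions: decayed multiplicative effects applied to
# the baseline on the proportion scale, then renormalized (large effects
# therefore slightly perturb unaffected populations, as real compositional
# measurement does).
visit_means <- function(cfg, cohort, visit_index) {
  mu <- cfg$baseline
  tpl <- cfg$templates[[cohort]]
  if (!is.null(tpl)) {
    for (t in tpl) {
      mu[t$feature] <- mu[t$feature] * 2^(t$log2fc * t$decay[visit_index])
    }
  }
  mu / sum(mu)
}

rdirichlet1 <- function(alpha) {
  g <- rgamma(length(alpha), shape = alpha, rate = 1)
  s <- sum(g)
  if (s <= 0) { # numerically degenerate draw; fall back to the mean
    return(alpha / sum(alpha))
  }
  g / s
}

#' Generate a synthetic three-cohort longitudinal dataset
#'
#' For every subject-visit the generator draws an absolute lymphocyte count
#' log-normally, computes cohort-by-visit mean proportions by applying the
#' decayed effect templates to the control baseline, draws the composition
#' Dirichlet-multinomially, and emits absolute counts. Controls receive one
#' visit-less profile. Identical seeds give identical output.
#'
#' @param cfg a [sim_config()].
#' @return A [cohort_set()].
#' @export
simulate_cohorts <- function(cfg) {
  stopifnot(inherits(cfg, "sim_config"))
  K <- cfg$panel$K
  with_seed(cfg$seed, {
    meta <- list()
    counts <- list()
    draw_profile <- function(mu) {
      total <- round(rlnorm(1, cfg$total_meanlog, cfg$total_sdlog))
      total <- max(total, K)  # degenerate tiny draws still yield a profile
      p <- rdirichlet1(cfg$concentration * mu)
      as.numeric(rmultinom(1, size = total, prob = p))
    }
    add_cases <- function(cohort, n, prefix) {
      for (i in seq_len(n)) {
        sid <- sprintf("%s%03d", prefix, i)
        for (v in seq_along(cfg$timepoints)) {
          mu <- visit_means(cfg, cohort, v)
          meta[[length(meta) + 1L]] <<- data.frame(
            subject_id = sid, cohort = cohort,
            timepoint_days = cfg$timepoints[v], stringsAsFactors = FALSE)
          counts[[length(counts) + 1L]] <<- draw_profile(mu)
        }
      }
    }
    add_cases("hiv_pos", cfg$n_hiv_pos, "HP")
    add_cases("hiv_neg", cfg$n_hiv_neg, "HN")
    for (i in seq_len(cfg$n_control)) {
      meta[[length(meta) + 1L]] <- data.frame(
        subject_id = sprintf("HC%03d", i), cohort = "control",
        timepoint_days = NA_integer_, stringsAsFactors = FALSE)
      counts[[length(counts) + 1L]] <- draw_profile(cfg$baseline)
    }
    cm <- do.call(rbind, counts)
    colnames(cm) <- cfg$panel$ids
    cohort_set(cfg$panel, do.call(rbind, meta), cm)
  })
}
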