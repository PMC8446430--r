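#' FIS analysis configuration
#'
#' Settings for the random feature-subset Feature Importance Score analysis.
#' The study design draws 500,000 subsets of 10 populations from the
#' 100-population panel and of 7 populations from the 18-population panel; the
#' package default of 20,000 subsets gives medians within Monte Carlo noise of
#' the full design at a fraction of the cost and is switchable back to the
#' full 500,000.
#'
#' @param subset_size m, number of populations per random subset (>= 2).
#' @param n_subsets M, number of independently drawn subsets (>= 1).
#' @param seed RNG seed controlling subset sampling.
#' @param measure `"counts"` or `"proportions"`, the profile measure the
#'   distances are computed on.
#' @param fdr_alpha significance level applied to FDR-adjusted q-values.
#' @param alternative `"greater"` (one-sided signed-rank against 0, the
#'   default reading of "positive FIS in almost all recipients") or
#'   `"two.sided"`.
#' @param pseudocount passed to [overlap_config()].
#' @return An object of class `fis_config`.
#' @export
fis_config <- function(subset_size = 7, n_subsets = 20000, seed = 1,
                       measure = c("counts", "proportions"),
                       fdr_alpha = 0.05,
                       alternative = c("greater", "two.sided"),
                       pseudocount = 0.5) {
  measure <- match.arg(measure)
  alternative <- match.arg(alternative)
  if (subset_size < 2) stop("subset_size must be >= 2", call. = FALSE)
  if (n_subsets < 1) stop("n_subsets must be >= 1", call. = FALSE)
  structure(list(subset_size = as.integer(subset_size),
                 n_subsets = as.integer(n_subsets),
                 seed = as.integer(seed), measure = measure,
                 fdr_alpha = fdr_alpha, alternative = alternative,
                 pseudocount = pseudocount),
            class = "fis_config")
}

#' Draw random feature subsets
#'
#' Each subset is an independent uniform draw of `m` distinct features from
#' the `K`-population panel; repetition across draws is allowed (an i.i.d.
#' subset design, under which collisions are negligible for the study panels).
#' Fully reproducible given `seed`.
#'
#' @param K panel size.
#' @param m subset size (2 <= m <= K).
#' @param M number of subsets.
#' @param seed RNG seed.
#' @return Integer matrix of dimension M x m with 1-based feature indices.
#' @export
sample_subsets <- function(K, m, M, seed = 1) {
  if (m > K) stop("subset size m cannot exceed panel size K", call. = FALSE)
  if (m < 2) stop("subset size m must be >= 2", call. = FALSE)
  with_seed(seed, {
    t(vapply(seq_len(M), function(i) sample.int(K, m), integer(m)))
  })
}

#' Enumerate all feature subsets of a given size
#'
#' Exhaustive counterpart of [sample_subsets()] for small panels, used as the
#' enumeration oracle that the sampled analysis is checked against.
#'
#' @inheritParams sample_subsets
#' @return Integer matrix, one row per subset (choose(K, m) rows).
#' @export
enumerate_subsets <- function(K, m) {
  t(utils::combn(K, m))
}

#' Feature importance score of one feature within one subset
#'
#' The contribution of population `feature` to the case-versus-control-set
#' distance in the context of feature subset `subset`:
#' `set_distance(case, controls, subset) - set_distance(case, controls,
#' subset minus feature)`. Positive values mean the feature contributes to the
#' divergence of the case from the controls.
#'
#' @param case single case profile (vector or 1-row matrix of panel counts).
#' @param controls control profile matrix (>= 2 rows) or [cohort_set()].
#' @param subset feature subset J: population ids or indices, length >= 2.
#' @param feature the feature j, which must be a member of `subset`.
#' @inheritParams set_distance
#' @return A single number.
#' @export
fis_one <- function(case, controls, subset, feature,
                    measure = c("counts", "proportions"),
                    cfg = overlap_config()) {
  measure <- match.arg(measure)
  if (length(subset) < 2) {
    stop("subset must have at least 2 features", call. = FALSE)
  }
  if (!feature %in% subset) {
    stop("feature must be a member of the subset", call. = FALSE)
  }
  set_distance(case, controls, measure, subset = subset, cfg = cfg) -
    set_distance(case, controls, measure,
                 subset = setdiff(subset, feature), cfg = cfg)
}

#' Median FIS per feature and case over sampled subsets
#'
#' For every case and every feature, computes the median of [fis_one()] over
#' all supplied subsets containing that feature, using a compiled batch
#' engine. Features never sampled are reported as `NA` with a warning
#' (possible at very small subset counts).
#'
#' @param cases case profile matrix (one or more rows) or [cohort_set()].
#' @param controls control profile matrix (>= 2 rows) or [cohort_set()].
#' @param subsets integer subset matrix from [sample_subsets()] or
#'   [enumerate_subsets()] (1-based feature indices, one subset per row).
#' @param measure `"counts"` or `"proportions"`.
#' @param cfg an [overlap_config()].
#' @return List with `medians` (cases x K matrix) and `n_evals` (per-feature
#'   number of subsets containing the feature).
#' @export
median_fis <- function(cases, controls, subsets,
                       measure = c("counts", "proportions"),
                       cfg = overlap_config()) {
  measure <- match.arg(measure)
  ctrl <- as_profile_matrix(controls, measure)
  cas <- as_profile_matrix(cases, measure)
  if (nrow(ctrl) < 2) stop("need at least 2 controls", call. = FALSE)
  subsets <- as.matrix(subsets)
  storage.mode(subsets) <- "integer"
  res <- .fis_engine_medians(ctrl, cas, subsets - 1L, cfg$pseudocount)
  colnames(res$medians) <- colnames(ctrl)
  rownames(res$medians) <- rownames(cas)
  names(res$n_evals) <- colnames(ctrl)
  if (any(res$n_evals == 0)) {
    warning("feature(s) never sampled, reported as NA: ",
            paste(names(res$n_evals)[res$n_evals == 0], collapse = ", "),
            call. = FALSE)
  }
  res
}

#' Significance calling on per-case median FIS values
#'
#' For each feature, the per-case medians are tested against zero with a
#' one-sample Wilcoxon signed-rank test (one-sided "greater" by default, the
#' reading under which a significant feature has positive FIS in almost all
#' recipients), followed by Benjamini-Hochberg adjustment across features.
#' A feature whose medians are all exactly zero is assigned p = 1 by
#' convention (degenerate signed-rank).
#'
#' @param medians cases x features matrix of per-case median FIS values
#'   (from [median_fis()]).
#' @param fdr_alpha FDR level for the significance flag.
#' @param alternative `"greater"` or `"two.sided"`.
#' @return data.frame with one row per feature: `feature`, `n_cases`,
#'   `median_of_medians`, `n_evals` left to the caller, `p`, `q`,
#'   `significant`.
#' @export
fis_significance <- function(medians, fdr_alpha = 0.05,
                             alternative = c("greater", "two.sided")) {
  alternative <- match.arg(alternative)
  medians <- rbind(medians)
  if (nrow(medians) < 5) {
    stop("significance calling needs at least 5 cases", call. = FALSE)
  }
  features <- colnames(medians)
  if (is.null(features)) features <- paste0("feature", seq_len(ncol(medians)))
  p <- vapply(seq_len(ncol(medians)), function(j) {
    x <- medians[, j]
    x <- x[!is.na(x)]
    if (length(x) == 0 || all(x == 0)) return(1)
    suppressWarnings(
      wilcox.test(x, mu = 0, alternative = alternative, exact = FALSE,
                  correct = TRUE)$p.value
    )
  }, numeric(1))
  q <- p.adjust(p, method = "BH")
  data.frame(
    feature = features,
    n_cases = colSums(!is.na(medians)),
    median_of_medians = apply(medians, 2, median, na.rm = TRUE),
    p = p, q = q,
    significant = q < fdr_alpha,
    row.names = NULL, stringsAsFactors = FALSE
  )
}

#' Run the full FIS analysis on a cohort set
#'
#' Orchestrates subset sampling, batch median-FIS evaluation and significance
#' calling for one case cohort against the compound control set. In per-visit
#' mode (`timepoint` given) cases are restricted to one visit; in pooled mode
#' (`timepoint = NULL`) every case-visit profile is treated as an observation.
#'
#' @param cs a [cohort_set()] containing cases and controls.
#' @param case_cohort cohort label of the cases (`"hiv_pos"` or `"hiv_neg"`).
#' @param timepoint optional single visit day; `NULL` pools all visits.
#' @param cfg a [fis_config()].
#' @return List of class `fis_result`: `table` (per-feature significance
#'   table), `medians` (cases x features), `violin` (long-format per-case
#'   medians for violin plots), `subsets`, `config`.
#' @export
run_fis <- function(cs, case_cohort = "hiv_pos", timepoint = NULL,
                    cfg = fis_config()) {
  stopifnot(inherits(cs, "cohort_set"))
  controls <- subset_cohort(cs, cohort = "control")
  if (n_profiles(controls) < 2) {
    stop("FIS needs at least 2 control profiles", call. = FALSE)
  }
  cases <- subset_cohort(cs, cohort = case_cohort, timepoint = timepoint)
  if (n_profiles(cases) < 5) {
    stop("FIS significance calling needs at least 5 case profiles",
         call. = FALSE)
  }
  K <- cs$panel$K
  subsets <- sample_subsets(K, cfg$subset_size, cfg$n_subsets, cfg$seed)
  ocfg <- overlap_config(cfg$pseudocount)
  mf <- median_fis(cases, controls, subsets, measure = cfg$measure, cfg = ocfg)
  tab <- fis_significance(mf$medians, fdr_alpha = cfg$fdr_alpha,
                          alternative = cfg$alternative)
  tab$n_evals <- mf$n_evals[tab$feature]
  tab$timepoint <- if (is.null(timepoint)) NA_integer_ else timepoint
  violin <- data.frame(
    feature = rep(colnames(mf$medians), each = nrow(mf$medians)),
    case = rep(rownames(mf$medians), times = ncol(mf$medians)),
    timepoint = tab$timepoint[1],
    median_fis = as.vector(mf$medians),
    stringsAsFactors = FALSE
  )
  structure(list(table = tab, medians = mf$medians, violin = violin,
                 subsets = subsets, config = cfg),
            class = "fis_result")
}

#' @export
print.fis_result <- function(x, ...) {
  sig <- x$table$feature[x$table$significant]
  cat("<fis_result>", nrow(x$medians), "cases,", ncol(x$medians),
      "features,", nrow(x$subsets), "subsets\n")
  cat(" significant features (q <", x$config$fdr_alpha, "):",
      if (length(sig)) paste(sig, collapse = ", ") else "none", "\n")
  invisible(x)
}

#' Significant feature set of a FIS result
#' @param x a `fis_result` from [run_fis()].
#' @return Character vector of significant feature ids.
#' @export
significant_features <- function(x) {
  stopifnot(inherits(x, "fis_result"))
  x$table$feature[x$table$significant]
}
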