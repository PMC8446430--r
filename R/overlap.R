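#' Overlap configuration
#'
#' The overlap index is computed on distributions obtained by adding a small
#' pseudocount to every category and renormalizing. The default of 0.5 is on
#' the counts scale (half a cell per uL) and keeps profiles with disjoint
#' support at finite divergence; a pseudocount of 0 gives the analytic
#' definition used in closed-form checks. Entropies use the natural logarithm
#' internally; the normalization by `log(n)` makes the index base-invariant.
#'
#' @param pseudocount non-negative real added to every category before
#'   normalization.
#' @return An object of class `overlap_config`.
#' @export
overlap_config <- function(pseudocount = 0.5) {
  if (length(pseudocount) != 1 || is.na(pseudocount) || pseudocount < 0) {
    stop("pseudocount must be a single non-negative number", call. = FALSE)
  }
  structure(list(pseudocount = pseudocount), class = "overlap_config")
}

# Shannon entropy (nats) of a probability vector; 0 log 0 = 0.
shannon_entropy <- function(p) {
  p <- p[p > 0]
  -sum(p * log(p))
}

# Rows of `x` (non-negative) + pseudocount, renormalized to distributions.
normalize_rows <- function(x, pseudocount) {
  x <- x + pseudocount
  rs <- rowSums(x)
  if (any(rs <= 0)) {
    stop("profile with zero total after restriction; use a positive pseudocount",
         call. = FALSE)
  }
  x / rs
}

# Coerce a cohort_set / matrix / vector stack into a profile value matrix.
as_profile_matrix <- function(x, measure, subset = NULL) {
  if (inherits(x, "cohort_set")) {
    return(profile_matrix(x, measure, subset))
  }
  x <- rbind(x)  # promotes a vector to a 1-row matrix
  if (!is.null(subset)) x <- x[, subset, drop = FALSE]
  x
}

#' I-index overlap of a set of composition profiles
#'
#' The I-index of n profiles is defined as `1 - JSD / log(n)`, where JSD is
#' the generalized Jensen-Shannon divergence of the n profile distributions
#' with uniform mixture weights: the entropy of their mean distribution minus
#' the mean of their entropies. It equals 1 for identical distributions and 0
#' for pairwise-disjoint supports (at pseudocount 0), and is invariant to the
#' order of profiles, the order of populations, and the logarithm base.
#'
#' @param x a [cohort_set()] or a numeric matrix with one profile per row.
#' @param measure `"counts"` or `"proportions"` (profiles are renormalized to
#'   distributions either way; the measure selects the values the pseudocount
#'   is added to).
#' @param subset optional population ids restricting the panel; restriction
#'   precedes all entropy computation.
#' @param cfg an [overlap_config()].
#' @return A single number in \[0, 1\].
#' @examples
#' p <- rbind(c(0.5, 0.5, 0), c(0, 0.5, 0.5))
#' i_index(p, cfg = overlap_config(pseudocount = 0))
#' @export
i_index <- function(x, measure = c("counts", "proportions"), subset = NULL,
                    cfg = overlap_config()) {
  measure <- match.arg(measure)
  p <- as_profile_matrix(x, measure, subset)
  n <- nrow(p)
  if (n < 2) stop("i_index needs at least 2 profiles", call. = FALSE)
  p <- normalize_rows(p, cfg$pseudocount)
  jsd <- shannon_entropy(colMeans(p)) -
    mean(apply(p, 1, shannon_entropy))
  val <- 1 - jsd / log(n)
  min(max(val, 0), 1)
}

#' Distance of one case profile from a control set
#'
#' The divergence that a single case adds to a homogeneous control set,
#' reported as the overlap lost: `I(controls) - I(controls + case)`, both
#' restricted to `subset` before any entropy computation. A case identical to
#' duplicate controls contributes 0; a case with disjoint support contributes
#' a strictly positive distance. Larger values mean a more divergent case.
#'
#' @param case a single profile: numeric vector of length K (or a 1-row
#'   matrix) on the same panel as `controls`.
#' @param controls numeric matrix (>= 2 rows) or [cohort_set()] of control
#'   profiles.
#' @param subset optional population ids; restriction precedes renormalization.
#' @inheritParams i_index
#' @return A single number (positive when the case reduces overlap).
#' @export
set_distance <- function(case, controls,
                         measure = c("counts", "proportions"),
                         subset = NULL, cfg = overlap_config()) {
  measure <- match.arg(measure)
  if (!is.null(subset) && length(subset) == 0) {
    stop("feature subset must be non-empty", call. = FALSE)
  }
  ctrl <- as_profile_matrix(controls, measure, subset)
  if (nrow(ctrl) < 2) stop("need at least 2 controls", call. = FALSE)
  cas <- as_profile_matrix(case, measure, subset)
  if (nrow(cas) != 1) stop("case must be a single profile", call. = FALSE)
  if (ncol(cas) != ncol(ctrl)) {
    stop("case and controls must share the panel", call. = FALSE)
  }
  i_index(ctrl, measure, cfg = cfg) -
    i_index(rbind(ctrl, cas), measure, cfg = cfg)
}

#' Per-subject distance-from-control trajectory value
#'
#' The distance of one case from the compound control set at one visit,
#' defined as `1 - I-index` of the pooled set (case plus all controls) over
#' the full panel. Tracking this value across visits gives a per-subject
#' reconstitution trajectory; values shrink as the case approaches the
#' controls.
#'
#' @inheritParams set_distance
#' @return A single number in \[0, 1\].
#' @export
trajectory_distance <- function(case, controls,
                                measure = c("counts", "proportions"),
                                cfg = overlap_config()) {
  measure <- match.arg(measure)
  ctrl <- as_profile_matrix(controls, measure)
  if (nrow(ctrl) < 2) stop("need at least 2 controls", call. = FALSE)
  cas <- as_profile_matrix(case, measure)
  1 - i_index(rbind(ctrl, cas), measure, cfg = cfg)
}

#' Pairwise I-index similarity matrix
#'
#' Computes the I-index for every pair of profiles in a cohort set. The
#' result is symmetric with unit diagonal and entries in \[0, 1\], and is the
#' input to similarity-based hierarchical clustering.
#'
#' @param cs a [cohort_set()] (or numeric profile matrix with row names).
#' @inheritParams i_index
#' @return An object of class `similarity_matrix`: list with `labels` and the
#'   square numeric matrix `values`.
#' @export
similarity_matrix <- function(cs, measure = c("counts", "proportions"),
                              cfg = overlap_config()) {
  measure <- match.arg(measure)
  x <- as_profile_matrix(cs, measure)
  n <- nrow(x)
  if (n < 2) stop("need at least 2 profiles", call. = FALSE)
  labels <- rownames(x)
  if (is.null(labels)) labels <- paste0("profile", seq_len(n))
  p <- normalize_rows(x, cfg$pseudocount)
  h <- apply(p, 1, shannon_entropy)
  v <- diag(1, n)
  log2n <- log(2)
  for (i in seq_len(n - 1)) {
    for (j in seq(i + 1, n)) {
      jsd <- shannon_entropy((p[i, ] + p[j, ]) / 2) - (h[i] + h[j]) / 2
      val <- min(max(1 - jsd / log2n, 0), 1)
      v[i, j] <- val
      v[j, i] <- val
    }
  }
  dimnames(v) <- list(labels, labels)
  structure(list(labels = labels, values = v), class = "similarity_matrix")
}

#' @export
print.similarity_matrix <- function(x, ...) {
  cat("<similarity_matrix>", length(x$labels), "profiles\n")
  invisible(x)
}

#' Write a similarity matrix as labeled TSV
#' @param sm a [similarity_matrix()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_similarity <- function(sm, path) {
  df <- data.frame(label = sm$labels, sm$values, check.names = FALSE)
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
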