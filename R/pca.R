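#' Per-visit principal component analysis with cohort convergence summaries
#'
#' For each visit, PCA is fitted on the pooled matrix of that visit's case
#' profiles and the full (once-sampled) control set. Columns are centered and,
#' by default, standardized, since absolute counts span orders of magnitude;
#' constant columns are dropped with a warning when scaling. Cohort centroids
#' in PC space and their pairwise Euclidean distances quantify how cohorts
#' approach each other across visits.
#'
#' @param cs a [cohort_set()].
#' @param measure `"counts"` or `"proportions"`.
#' @param n_components number of principal components retained (>= 1).
#' @param scale standardize columns before PCA (default `TRUE`).
#' @param timepoints visit days to fit (default `c(56, 180, 365)`).
#' @return Object of class `pca_result`: per-visit list (`scores`,
#'   `loadings`, `explained_variance`, `centroids`) and a
#'   `centroid_distances` data.frame (`pair`, `timepoint`, `distance`).
#' @export
pca_by_visit <- function(cs, measure = c("counts", "proportions"),
                         n_components = 2, scale = TRUE,
                         timepoints = c(56, 180, 365)) {
  measure <- match.arg(measure)
  stopifnot(inherits(cs, "cohort_set"))
  if (n_components > cs$panel$K) {
    stop("n_components cannot exceed the panel size", call. = FALSE)
  }
  visits <- list()
  dists <- list()
  for (tp in timepoints) {
    sub <- subset_cohort(cs, timepoint = tp, keep_controls = TRUE)
    cohorts <- sub$meta$cohort
    if (length(unique(cohorts)) < 2) {
      warning("skipping day ", tp, ": fewer than 2 cohorts present",
              call. = FALSE)
      next
    }
    if (any(table(cohorts) < 3)) {
      warning("day ", tp, ": a cohort has fewer than 3 subjects",
              call. = FALSE)
    }
    x <- profile_matrix(sub, measure)
    if (scale) {
      const <- apply(x, 2, sd) == 0
      if (any(const)) {
        warning("day ", tp, ": dropping constant column(s): ",
                paste(colnames(x)[const], collapse = ", "), call. = FALSE)
        x <- x[, !const, drop = FALSE]
      }
    }
    fit <- prcomp(x, center = TRUE, scale. = scale)
    nc <- min(n_components, ncol(fit$x))
    scores <- fit$x[, seq_len(nc), drop = FALSE]
    ev <- fit$sdev^2 / sum(fit$sdev^2)
    cents <- do.call(rbind, lapply(split(seq_len(nrow(scores)), cohorts),
                                   function(i) colMeans(scores[i, , drop = FALSE])))
    labs <- rownames(cents)
    for (i in seq_len(nrow(cents) - 1)) {
      for (j in seq(i + 1, nrow(cents))) {
        dists[[length(dists) + 1L]] <- data.frame(
          pair = paste(labs[i], labs[j], sep = " vs "),
          timepoint = tp,
          distance = sqrt(sum((cents[i, ] - cents[j, ])^2)),
          stringsAsFactors = FALSE
        )
      }
    }
    visits[[as.character(tp)]] <- list(
      scores = scores, loadings = fit$rotation[, seq_len(nc), drop = FALSE],
      explained_variance = ev, centroids = cents,
      cohorts = cohorts
    )
  }
  structure(list(visits = visits,
                 centroid_distances = do.call(rbind, dists),
                 measure = measure),
            class = "pca_result")
}

#' @export
print.pca_result <- function(x, ...) {
  cat("<pca_result>", length(x$visits), "visit fits\n")
  print(x$centroid_distances, row.names = FALSE)
  invisible(x)
}

#' Centroid distance trajectory for one cohort pair
#' @param x a [pca_by_visit()] result.
#' @param pair pair label, e.g. `"control vs hiv_pos"` (order as reported in
#'   `x$centroid_distances`).
#' @return Numeric vector of distances ordered by timepoint.
#' @export
centroid_trajectory <- function(x, pair) {
  stopifnot(inherits(x, "pca_result"))
  d <- x$centroid_distances
  d <- d[d$pair == pair, , drop = FALSE]
  if (!nrow(d)) {
    stop("pair not found; available: ",
         paste(unique(x$centroid_distances$pair), collapse = ", "),
         call. = FALSE)
  }
  d <- d[order(d$timepoint), ]
  setNames(d$distance, d$timepoint)
}
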