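#' Reciprocal-of-comparisons significance cutoff
#'
#' The comparison battery flags a test as significant when its p-value falls
#' below one over the total number of comparisons in the design, rounded to
#' the printed precision. The three study designs give 1/162 = 0.006 (3
#' decimals), 1/300 = 0.0033 (4 decimals) and 1/54 = 0.0185 (4 decimals).
#'
#' @param n_comparisons total number of comparisons in the design (>= 1).
#' @param decimals rounding precision of the cutoff.
#' @return A single numeric cutoff.
#' @examples
#' significance_threshold(162, 3)
#' significance_threshold(300, 4)
#' significance_threshold(54, 4)
#' @export
significance_threshold <- function(n_comparisons, decimals = 3) {
  if (length(n_comparisons) != 1 || is.na(n_comparisons) ||
      n_comparisons < 1) {
    stop("n_comparisons must be a positive integer", call. = FALSE)
  }
  round(1 / n_comparisons, decimals)
}

#' Wilcoxon rank-sum comparison battery
#'
#' Runs a two-sided Wilcoxon rank-sum test for every (population, timepoint,
#' cohort pair) cell of the design and applies the reciprocal-of-comparisons
#' cutoff computed from the total design size. Controls are sampled once, so
#' a pair side labelled `"control"` uses the full control set at every
#' timepoint. Exact p-values are used when both sides have at most 25
#' subjects and no ties; otherwise the normal approximation with continuity
#' correction. Fold ratios are medians of the first cohort over medians of
#' the second; a zero denominator median is flagged (`fold_defined = FALSE`).
#'
#' @param cs a [cohort_set()].
#' @param cohort_pairs list of length-2 character vectors, e.g.
#'   `list(c("hiv_pos", "control"))`; the first element is the numerator of
#'   the fold ratio.
#' @param timepoints visit days to test (default `c(56, 180, 365)`).
#' @param measure `"counts"` or `"proportions"`.
#' @param populations optional subset of panel ids (default: full panel).
#' @param threshold_decimals rounding precision for the cutoff (3 reproduces
#'   the 162-comparison design's printed 0.006; use 4 for the 300- and
#'   54-comparison designs).
#' @return data.frame of class `battery_result`, one row per design cell:
#'   `population`, `timepoint`, `pair`, `statistic`, `p_value`, `threshold`,
#'   `significant`, `median_a`, `median_b`, `fold_ratio`, `fold_defined`.
#' @export
rank_sum_battery <- function(cs, cohort_pairs,
                             timepoints = c(56, 180, 365),
                             measure = c("counts", "proportions"),
                             populations = NULL, threshold_decimals = 3) {
  measure <- match.arg(measure)
  stopifnot(inherits(cs, "cohort_set"))
  if (!is.list(cohort_pairs)) cohort_pairs <- list(cohort_pairs)
  if (is.null(populations)) populations <- cs$panel$ids
  x <- profile_matrix(cs, measure)
  n_comparisons <- length(populations) * length(timepoints) *
    length(cohort_pairs)
  threshold <- significance_threshold(n_comparisons, threshold_decimals)

  side_rows <- function(cohort, tp) {
    if (cohort == "control") {
      which(cs$meta$cohort == "control")
    } else {
      which(cs$meta$cohort == cohort & cs$meta$timepoint_days %in% tp)
    }
  }

  out <- list()
  for (pair in cohort_pairs) {
    pair_lab <- paste(pair, collapse = " vs ")
    for (tp in timepoints) {
      ia <- side_rows(pair[1], tp)
      ib <- side_rows(pair[2], tp)
      if (length(ia) < 3 || length(ib) < 3) {
        warning(sprintf("skipping %s at day %s: fewer than 3 subjects per side",
                        pair_lab, tp), call. = FALSE)
        next
      }
      for (pop in populations) {
        a <- x[ia, pop]
        b <- x[ib, pop]
        exact <- length(a) <= 25 && length(b) <= 25 &&
          !anyDuplicated(c(a, b))
        wt <- suppressWarnings(
          wilcox.test(a, b, alternative = "two.sided", exact = exact,
                      correct = TRUE)
        )
        med_a <- median(a)
        med_b <- median(b)
        out[[length(out) + 1L]] <- data.frame(
          population = pop, timepoint = tp, pair = pair_lab,
          statistic = unname(wt$statistic), p_value = wt$p.value,
          threshold = threshold, significant = wt$p.value < threshold,
          median_a = med_a, median_b = med_b,
          fold_ratio = if (med_b > 0) med_a / med_b else NA_real_,
          fold_defined = med_b > 0,
          stringsAsFactors = FALSE
        )
      }
    }
  }
  if (!length(out)) {
    stop("no testable design cell had >= 3 subjects per side", call. = FALSE)
  }
  res <- do.call(rbind, out)
  class(res) <- c("battery_result", class(res))
  res
}

#' Significance-masked fold-change heatmap data
#'
#' Assembles the battery records of one run into a population x
#' (pair, timepoint) matrix of fold ratios in which non-significant cells are
#' masked (`NA`) — blank cells represent a lack of significant difference.
#'
#' @param records a [rank_sum_battery()] result.
#' @param populations optional row order / restriction (default: populations
#'   present in the records).
#' @return List of class `fold_heatmap`: `matrix` (masked fold ratios),
#'   `tidy` (long-format records with a `masked` flag).
#' @export
fold_heatmap <- function(records, populations = NULL) {
  stopifnot(is.data.frame(records))
  if (is.null(populations)) populations <- unique(records$population)
  records <- records[records$population %in% populations, , drop = FALSE]
  col_key <- paste(records$pair, paste0("d", records$timepoint), sep = " | ")
  cols <- unique(col_key)
  m <- matrix(NA_real_, nrow = length(populations), ncol = length(cols),
              dimnames = list(populations, cols))
  keep <- records$significant & records$fold_defined
  if (any(keep)) {
    m[cbind(match(records$population[keep], populations),
            match(col_key[keep], cols))] <- records$fold_ratio[keep]
  }
  tidy <- data.frame(
    population = records$population, timepoint = records$timepoint,
    pair = records$pair, fold_ratio = records$fold_ratio,
    masked = !keep, stringsAsFactors = FALSE
  )
  structure(list(matrix = m, tidy = tidy), class = "fold_heatmap")
}

#' @export
print.fold_heatmap <- function(x, ...) {
  cat("<fold_heatmap>", nrow(x$matrix), "populations x", ncol(x$matrix),
      "cells;", sum(!is.na(x$matrix)), "unmasked\n")
  invisible(x)
}
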