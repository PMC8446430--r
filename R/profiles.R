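#' Cohort sets of immune composition profiles
#'
#' A `cohort_set` holds one composition profile per (subject, visit): absolute
#' subset counts (cells/uL) for every population of a shared panel, together
#' with the subject's cohort label and post-transplant visit day. Healthy
#' controls are sampled once and carry no visit day (`NA`). Proportions are
#' always defined over the panel under analysis (each row renormalized to sum
#' to one across the K selected populations), because the overlap index
#' requires distributions on a common support; the study panels are not
#' exhaustive partitions of all gated lymphocytes.
#'
#' @param panel a [population_panel()].
#' @param meta data.frame with columns `subject_id` (character), `cohort`
#'   (one of `"hiv_pos"`, `"hiv_neg"`, `"control"`) and `timepoint_days`
#'   (integer day post-transplant, `NA` for controls).
#' @param counts numeric matrix, one row per profile and one column per panel
#'   population (cells/uL, non-negative; no all-zero rows).
#' @return An object of class `cohort_set` with elements `panel`, `meta` and
#'   `counts`.
#' @seealso [read_cohort()], [write_cohort()], [profile_matrix()]
#' @export
cohort_set <- function(panel, meta, counts) {
  stopifnot(inherits(panel, "population_panel"))
  counts <- as.matrix(counts)
  meta <- as.data.frame(meta)
  if (!all(c("subject_id", "cohort", "timepoint_days") %in% names(meta))) {
    stop("meta must have subject_id, cohort and timepoint_days columns",
         call. = FALSE)
  }
  meta$subject_id <- as.character(meta$subject_id)
  meta$cohort <- as.character(meta$cohort)
  bad_cohort <- setdiff(unique(meta$cohort), c("hiv_pos", "hiv_neg", "control"))
  if (length(bad_cohort)) {
    stop("unknown cohort label(s): ", paste(bad_cohort, collapse = ", "),
         call. = FALSE)
  }
  meta$timepoint_days <- as.integer(meta$timepoint_days)
  if (nrow(counts) != nrow(meta)) {
    stop("counts and meta must have the same number of rows", call. = FALSE)
  }
  if (ncol(counts) != panel$K) {
    stop("counts must have one column per panel population (K = ", panel$K,
         ")", call. = FALSE)
  }
  if (is.null(colnames(counts))) {
    colnames(counts) <- panel$ids
  } else if (!identical(colnames(counts), panel$ids)) {
    if (!setequal(colnames(counts), panel$ids)) {
      stop("count columns do not match the panel ids", call. = FALSE)
    }
    counts <- counts[, panel$ids, drop = FALSE]
  }
  if (nrow(counts)) {
    neg <- which(counts < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      stop(sprintf("negative count in row %d, population '%s'",
                   neg[1, 1], colnames(counts)[neg[1, 2]]), call. = FALSE)
    }
    zero_rows <- which(rowSums(counts) == 0)
    if (length(zero_rows)) {
      stop("all-zero profile(s) in row(s): ",
           paste(zero_rows, collapse = ", "), call. = FALSE)
    }
    key <- paste(meta$subject_id, meta$timepoint_days, sep = "@")
    if (anyDuplicated(key)) {
      stop("duplicate subject_id x timepoint pairs: ",
           paste(unique(key[duplicated(key)]), collapse = ", "), call. = FALSE)
    }
  }
  rownames(counts) <- profile_labels(meta)
  structure(list(panel = panel, meta = meta, counts = counts),
            class = "cohort_set")
}

profile_labels <- function(meta) {
  ifelse(is.na(meta$timepoint_days), meta$subject_id,
         paste0(meta$subject_id, "@d", meta$timepoint_days))
}

#' @export
print.cohort_set <- function(x, ...) {
  cat("<cohort_set>", nrow(x$counts), "profiles over", x$panel$K,
      "populations\n")
  print(table(cohort = x$meta$cohort))
  invisible(x)
}

#' Number of profiles in a cohort set
#' @param cs a [cohort_set()].
#' @return Integer number of (subject, visit) profiles.
#' @export
n_profiles <- function(cs) nrow(cs$counts)

#' Extract the profile measurement matrix
#'
#' Every downstream analysis takes an explicit measure selector: `"counts"`
#' returns absolute cells/uL, `"proportions"` returns each profile renormalized
#' to sum to one over the panel (or over a restricted population subset).
#'
#' @param cs a [cohort_set()].
#' @param measure `"counts"` or `"proportions"`.
#' @param subset optional character vector of population ids (or integer
#'   indices) restricting the panel; restriction precedes renormalization.
#' @return Numeric matrix, one row per profile.
#' @export
profile_matrix <- function(cs, measure = c("counts", "proportions"),
                           subset = NULL) {
  measure <- match.arg(measure)
  x <- cs$counts
  if (!is.null(subset)) {
    if (is.character(subset)) {
      missing <- setdiff(subset, cs$panel$ids)
      if (length(missing)) {
        stop("unknown population(s): ", paste(missing, collapse = ", "),
             call. = FALSE)
      }
    }
    x <- x[, subset, drop = FALSE]
  }
  if (measure == "proportions") x <- x / rowSums(x)
  x
}

#' Subset a cohort set by cohort and/or visit
#'
#' Controls carry no visit day, so `timepoint` never filters them out when
#' `keep_controls = TRUE`: every per-visit analysis compares that visit's cases
#' against the full once-sampled control set.
#'
#' @param cs a [cohort_set()].
#' @param cohort optional cohort label(s) to keep.
#' @param timepoint optional visit day(s) to keep (applied to cases only).
#' @param keep_controls keep visit-less control profiles when filtering by
#'   timepoint (default `FALSE`; set `TRUE` to retain them alongside cases).
#' @return A filtered [cohort_set()].
#' @export
subset_cohort <- function(cs, cohort = NULL, timepoint = NULL,
                          keep_controls = FALSE) {
  keep <- rep(TRUE, nrow(cs$meta))
  if (!is.null(cohort)) keep <- keep & cs$meta$cohort %in% cohort
  if (!is.null(timepoint)) {
    tp_ok <- cs$meta$timepoint_days %in% timepoint
    if (keep_controls) tp_ok <- tp_ok | is.na(cs$meta$timepoint_days)
    keep <- keep & tp_ok
  }
  cohort_set(cs$panel, cs$meta[keep, , drop = FALSE],
             cs$counts[keep, , drop = FALSE])
}

#' Convert percent-of-lymphocytes to absolute counts
#'
#' Absolute subset counts are derived from the percentage of total gated
#' lymphocytes and the absolute lymphocyte count from a hematology analyzer:
#' `counts = percentages / 100 * total_lymphocytes`, linear in the total.
#'
#' @param percentages numeric vector of percentages in \[0, 100\].
#' @param total_lymphocytes absolute lymphocyte count (cells/uL, >= 0).
#' @return Numeric vector of absolute counts (cells/uL).
#' @examples
#' to_absolute(c(50, 12.5), total_lymphocytes = 1600)
#' @export
to_absolute <- function(percentages, total_lymphocytes) {
  if (any(percentages < 0) || any(percentages > 100)) {
    stop("percentages must lie in [0, 100]", call. = FALSE)
  }
  if (any(total_lymphocytes < 0)) {
    stop("total_lymphocytes must be non-negative", call. = FALSE)
  }
  percentages / 100 * total_lymphocytes
}

#' Read a cohort table from delimited text
#'
#' Expects a header row with `subject_id`, `cohort`, `timepoint_days` and one
#' column per population. Separator is inferred from the extension (`.csv`
#' comma, otherwise tab). When `values = "proportions"`, each row is
#' renormalized to sum to one over the panel; rows whose stored sum deviates
#' from 1 by more than `1e-6` trigger a warning naming the rows.
#'
#' @param path file path.
#' @param panel optional [population_panel()]; when `NULL` the panel is taken
#'   from the non-metadata columns of the header.
#' @param values whether stored per-population values are `"counts"` or
#'   `"proportions"`.
#' @return A validated [cohort_set()].
#' @export
read_cohort <- function(path, panel = NULL,
                        values = c("counts", "proportions")) {
  values <- match.arg(values)
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- read.delim(path, sep = sep, check.names = FALSE,
                   stringsAsFactors = FALSE)
  required <- c("subject_id", "cohort", "timepoint_days")
  missing <- setdiff(required, names(df))
  if (length(missing)) {
    stop("missing required column(s): ", paste(missing, collapse = ", "),
         call. = FALSE)
  }
  pop_cols <- setdiff(names(df), required)
  if (is.null(panel)) {
    panel <- population_panel(pop_cols)
  } else {
    missing_pops <- setdiff(panel$ids, pop_cols)
    if (length(missing_pops)) {
      stop("file lacks panel population column(s): ",
           paste(missing_pops, collapse = ", "), call. = FALSE)
    }
  }
  x <- as.matrix(df[, panel$ids, drop = FALSE])
  storage.mode(x) <- "double"
  if (nrow(x)) {
    neg <- which(x < 0, arr.ind = TRUE)
    if (nrow(neg)) {
      stop(sprintf("negative value in data row %d, population '%s'",
                   neg[1, 1], panel$ids[neg[1, 2]]), call. = FALSE)
    }
    if (values == "proportions") {
      rs <- rowSums(x)
      off <- which(abs(rs - 1) > 1e-6)
      if (length(off)) {
        warning("renormalizing proportion rows not summing to 1: rows ",
                paste(off, collapse = ", "), call. = FALSE)
      }
      x <- x / rs
    }
  }
  cohort_set(panel, df[, required, drop = FALSE], x)
}

#' Write a cohort table to delimited text
#'
#' Inverse of [read_cohort()]: `read_cohort(write_cohort(cs))` reproduces the
#' counts exactly (values are written at full precision).
#'
#' @param cs a [cohort_set()].
#' @param path output path (`.csv` comma-separated, otherwise tab).
#' @return `path`, invisibly.
#' @export
write_cohort <- function(cs, path) {
  sep <- if (grepl("\\.csv$", path, ignore.case = TRUE)) "," else "\t"
  df <- cbind(cs$meta[, c("subject_id", "cohort", "timepoint_days")],
              as.data.frame(cs$counts, check.names = FALSE))
  write.table(format(df, digits = 17, trim = TRUE, scientific = FALSE),
              path, sep = sep, quote = FALSE, row.names = FALSE)
  invisible(path)
}
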