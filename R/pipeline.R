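#' Run the end-to-end analysis pipeline
#'
#' Orchestrates the package stages in dependency order from a single
#' configuration: obtain a cohort (simulate, or read a TSV/CSV), then any of
#' the `iindex` (similarity matrix), `cluster` (dendrogram + Newick), `fis`,
#' `battery` and `pca` analyses. All outputs are plain text (TSV, JSON,
#' Newick) written under `out_dir`, together with a run manifest recording
#' the configuration hash, seed and output files. Given the same
#' configuration and seed, reruns are byte-identical. Per-stage RNG
#' substreams are derived deterministically from the global seed (simulation
#' uses `seed`, FIS subset sampling `seed + 1`).
#'
#' @param config path to a YAML configuration file, or an equivalent named
#'   list. Recognized top-level keys: `seed`; `simulate` (a list of
#'   [sim_config()] arguments, with `panel` given as 18 or 100) or `input`
#'   (list with `path` and optional `values`); `analyses` (character vector
#'   among `"iindex"`, `"cluster"`, `"fis"`, `"battery"`, `"pca"`); `measure`;
#'   and optional per-stage lists `fis`, `battery`, `pca`.
#' @param out_dir output directory (created if missing).
#' @param seed optional seed overriding the configuration's.
#' @return Invisibly, a list with the cohort, stage results, and the manifest.
#' @export
run_pipeline <- function(config, out_dir, seed = NULL) {
  cfg <- if (is.character(config)) yaml::read_yaml(config) else config
  if (!is.list(cfg)) stop("config must be a YAML file path or a list",
                          call. = FALSE)
  if (!is.null(seed)) cfg$seed <- seed
  if (is.null(cfg$seed)) cfg$seed <- 1L
  cfg$seed <- as.integer(cfg$seed)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  measure <- cfg$measure %||% "counts"
  analyses <- cfg$analyses %||% c("iindex", "cluster", "fis", "battery", "pca")
  unknown <- setdiff(analyses, c("iindex", "cluster", "fis", "battery", "pca"))
  if (length(unknown)) {
    stop("unknown analysis stage(s): ", paste(unknown, collapse = ", "),
         call. = FALSE)
  }
  outputs <- character()
  emit <- function(df, name) {
    path <- file.path(out_dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    outputs[[length(outputs) + 1L]] <<- name
    path
  }

  # --- cohort ---------------------------------------------------------------
  if (!is.null(cfg$simulate)) {
    sim_args <- cfg$simulate
    if (!is.null(sim_args$panel)) sim_args$panel <- panel_preset(sim_args$panel)
    sim_args$seed <- cfg$seed
    scfg <- do.call(sim_config, sim_args)
    cs <- simulate_cohorts(scfg)
  } else if (!is.null(cfg$input)) {
    cs <- read_cohort(cfg$input$path, values = cfg$input$values %||% "counts")
  } else {
    stop("config needs either a 'simulate' block or an 'input' block",
         call. = FALSE)
  }
  write_cohort(cs, file.path(out_dir, "cohort.tsv"))
  outputs <- c(outputs, "cohort.tsv")
  panel_json <- list(ids = cs$panel$ids,
                     annotations = as.list(cs$panel$annotations))
  jsonlite::write_json(panel_json, file.path(out_dir, "panel.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  outputs <- c(outputs, "panel.json")

  results <- list(cohort = cs)

  # --- similarity / clustering ---------------------------------------------
  if (any(c("iindex", "cluster") %in% analyses)) {
    sm <- similarity_matrix(cs, measure = measure)
    results$similarity <- sm
    if ("iindex" %in% analyses) {
      write_similarity(sm, file.path(out_dir, "similarity.tsv"))
      outputs <- c(outputs, "similarity.tsv")
    }
    if ("cluster" %in% analyses) {
      tree <- cluster_profiles(sm)
      export_newick(tree, file.path(out_dir, "tree.newick"))
      outputs <- c(outputs, "tree.newick")
      results$tree <- tree
    }
  }

  # --- FIS ------------------------------------------------------------------
  if ("fis" %in% analyses) {
    fa <- cfg$fis %||% list()
    fcfg <- fis_config(
      subset_size = fa$subset_size %||% 7,
      n_subsets = fa$n_subsets %||% 20000,
      seed = cfg$seed + 1L,
      measure = fa$measure %||% measure,
      fdr_alpha = fa$fdr_alpha %||% 0.05
    )
    fr <- run_fis(cs, case_cohort = fa$case_cohort %||% "hiv_pos",
                  timepoint = fa$timepoint, cfg = fcfg)
    emit(fr$table, "fis_table.tsv")
    emit(fr$violin, "fis_violin.tsv")
    results$fis <- fr
  }

  # --- battery --------------------------------------------------------------
  if ("battery" %in% analyses) {
    ba <- cfg$battery %||% list()
    pairs <- ba$pairs %||% list(c("hiv_pos", "control"),
                                c("hiv_neg", "control"),
                                c("hiv_pos", "hiv_neg"))
    br <- rank_sum_battery(
      cs, cohort_pairs = pairs,
      timepoints = unlist(ba$timepoints %||% c(56, 180, 365)),
      measure = ba$measure %||% measure,
      threshold_decimals = ba$decimals %||% 3
    )
    emit(br, "battery.tsv")
    hm <- fold_heatmap(br)
    emit(hm$tidy, "heatmap.tsv")
    results$battery <- br
    results$heatmap <- hm
  }

  # --- PCA ------------------------------------------------------------------
  if ("pca" %in% analyses) {
    pa <- cfg$pca %||% list()
    pr <- pca_by_visit(cs, measure = pa$measure %||% "proportions",
                       n_components = pa$n_components %||% 2)
    emit(pr$centroid_distances, "pca_centroid_distances.tsv")
    for (tp in names(pr$visits)) {
      sc <- pr$visits[[tp]]$scores
      emit(data.frame(label = rownames(sc), cohort = pr$visits[[tp]]$cohorts,
                      sc, check.names = FALSE),
           sprintf("pca_scores_d%s.tsv", tp))
    }
    results$pca <- pr
  }

  # --- manifest -------------------------------------------------------------
  manifest <- list(
    package = "immunofis",
    version = as.character(utils::packageVersion("immunofis")),
    config_hash = rlang::hash(cfg),
    seed = cfg$seed,
    analyses = analyses,
    measure = measure,
    outputs = as.character(outputs)
  )
  jsonlite::write_json(manifest, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, pretty = TRUE)
  results$manifest <- manifest
  invisible(results)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
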