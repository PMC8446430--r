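#' Population panels
#'
#' A `population_panel` is the ordered set of immune-marker-combination
#' identifiers (lymphocyte subsets defined by surface-marker positivity or
#' negativity, e.g. `"CD3+/HLA-DR+"`) over which composition profiles are
#' expressed. Overlapping gate definitions are deliberately kept as separate
#' features: the analysis treats populations as unordered categories and does
#' not deduplicate nested gates.
#'
#' @param ids character vector of unique, non-empty population identifiers
#'   (at least two).
#' @param annotations optional named character vector mapping ids to a
#'   functional description of the subset.
#' @return An object of class `population_panel` with elements `ids`,
#'   `annotations` and `K` (panel size).
#' @examples
#' p <- population_panel(c("CD3+/HLA-DR+", "CD4+/CD45RA+", "CD8+/CD45RA-"))
#' p$K
#' @export
population_panel <- function(ids, annotations = NULL) {
  ids <- as.character(ids)
  if (length(ids) < 2) stop("a panel needs at least 2 populations", call. = FALSE)
  if (anyDuplicated(ids)) stop("panel ids must be unique", call. = FALSE)
  if (any(!nzchar(ids))) stop("panel ids must be non-empty", call. = FALSE)
  if (!is.null(annotations)) {
    annotations <- annotations[intersect(names(annotations), ids)]
  }
  structure(list(ids = ids, annotations = annotations, K = length(ids)),
            class = "population_panel")
}

#' @export
print.population_panel <- function(x, ...) {
  cat("<population_panel> K =", x$K, "populations\n")
  cat(" ", paste(head(x$ids, 6), collapse = ", "),
      if (x$K > 6) "..." else "", "\n")
  invisible(x)
}

# Curated 18-subset panel: activated / naive / memory / effector T cells,
# activated B cells, and cytotoxic NK subsets bearing activation, degranulation
# and inhibition markers.
.panel18_annotations <- c(
  "CD3+/HLA-DR+"               = "Activated T cells expressing the late activation marker HLA-DR",
  "CD3+/HLA-DR+/CD69+/CD134-"  = "Activated T cells with early (CD69) and late (HLA-DR) activation markers, lacking CD134",
  "CD3+/HLA-DR+/CD134+/CD69-"  = "Late-activated T cells expressing CD134 without CD69",
  "CD3+/CD134+"                = "T cells expressing the late activation marker CD134 (OX40)",
  "CD3+/CD86+"                 = "Activated / effector-memory T cells expressing CD86",
  "CD4+/CD45RA+"               = "Naive T helper cells",
  "CD4+/CD45RO+"               = "Memory T helper cells",
  "CD4+/CD27+"                 = "Naive and memory T helper cells",
  "Total CD8+"                 = "Total cytotoxic T cells",
  "CD8+/CD45RA-"               = "Memory cytotoxic T cells",
  "CD8+/CD45RO+"               = "Memory cytotoxic T cells",
  "CD8+/CD27-"                 = "Effector cytotoxic T cells",
  "CD19+/CD80+"                = "Activated B cells",
  "CD19+/CD86+"                = "Activated B cells expressing CD86",
  "CD3-/CD56+/CD16+"           = "Cytotoxic NK cells",
  "CD3-/CD56+/CD16+/CD134+"    = "Cytotoxic NK cells expressing a marker of stimulation",
  "CD3-/CD56+/CD16+/CD107a/b+" = "Cytotoxic NK cells expressing a marker of degranulation",
  "CD3-/CD56+/CD16+/CD159a+"   = "Cytotoxic NK cells expressing the inhibitory receptor NKG2A"
)

# Additional curated subsets used to seed the 100-population panel.
.panel100_extra <- c(
  "CD4+/CD45RO-", "CD4+/CD29-", "CD4+/CD27-", "CD4+/CD127+", "CD4+/CD25+",
  "CD8+/CD25-", "CD8+/CD25+", "CD8+/CD127-", "CD8+/CD29+",
  "CD8+/CD45RA-/CD29+", "CD8+/CD45RO+/CD29+",
  "CD27-/CD45RO+", "CD29-/CD45RO+", "CD45RA+/CD45RO+",
  "CD3+/CD314+",
  "CD3-/CD56+/CD16-/CD63+", "CD3-/CD56+/CD16-/CD314+",
  "CD3-/CD56+/CD16+/CD314+", "CD3-/CD56+/CD16+/CD63+/CD314+",
  "CD3-/CD56+/CD16+/CD117-", "CD3-/CD56+/CD16+/CD159a+/CD314+"
)

#' Preset population panels
#'
#' Two study panels are supported: an 18-subset panel mixing activated, naive,
#' memory and effector T-cell subsets with activated B cells and functional NK
#' subsets, and a 100-subset panel extending it with additional
#' marker-combination gates across the T, B and NK compartments.
#'
#' @param size `"18"` or `"100"` (numbers accepted).
#' @return A [population_panel()].
#' @examples
#' panel_preset(18)$K
#' panel_preset(100)$K
#' @export
panel_preset <- function(size = c("18", "100")) {
  size <- match.arg(as.character(size), c("18", "100"))
  base18 <- names(.panel18_annotations)
  if (size == "18") {
    return(population_panel(base18, .panel18_annotations))
  }
  ids <- unique(c(base18, .panel100_extra))
  # fill to 100 with systematic lineage x marker combination gates
  lineages <- c("CD3+", "CD4+", "CD8+", "CD19+", "CD3-/CD56+")
  markers <- c("CD25", "CD27", "CD28", "CD38", "CD57", "CD62L", "CD69",
               "CD95", "CD127", "HLA-DR")
  for (lin in lineages) {
    for (mk in markers) {
      for (sign in c("+", "-")) {
        if (length(ids) >= 100) break
        cand <- paste0(lin, "/", mk, sign)
        if (!cand %in% ids) ids <- c(ids, cand)
      }
    }
  }
  ann <- .panel18_annotations
  population_panel(ids[seq_len(100)], ann)
}
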