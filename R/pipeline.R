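#' Run the MTDG stage for every eligible tissue
#'
#' For each tissue having tumor, cell-line and normal samples, runs the
#' permutation differential-expression analysis over the analyzed gene
#' universe for the tumor-vs-normal and cell-line-vs-normal comparisons,
#' selects genes at the FDR target, and assembles the per-tissue MTDG
#' table.
#'
#' @param ds log2-scale `expression_dataset`.
#' @param universe gene IDs analyzed (e.g. on-array membranome members).
#' @param fdr_target FDR threshold for both comparisons (default 0.01).
#' @param B maximum permutations per comparison.
#' @param seed integer seed.
#' @param tissues optional subset of tissues; default all eligible.
#' @return named list of `mtdg_table`, one per tissue.
#' @export
run_mtdg_analysis <- function(ds, universe, fdr_target = 0.01, B = 100L,
                              seed = 1L, tissues = NULL) {
  stopifnot(inherits(ds, "expression_dataset"))
  man <- ds$manifest
  universe <- intersect(unique(as.character(universe)), rownames(ds$matrix))
  eligible <- Filter(function(t) {
    cls <- man$sample_class[man$tissue == t]
    all(c("tumor", "cell_line", "normal") %in% cls) &&
      min(table(cls)) >= 2L
  }, sort(unique(man$tissue)))
  if (!is.null(tissues)) eligible <- intersect(eligible, tissues)
  if (length(eligible) == 0L) stop("no tissue has all three sample classes")
  xs <- ds$matrix[universe, , drop = FALSE]
  out <- list()
  for (i in seq_along(eligible)) {
    t <- eligible[i]
    run_one <- function(cls, offset) {
      keep <- man$tissue == t & man$sample_class %in% c("normal", cls)
      lab <- factor(man$sample_class[keep], levels = c("normal", cls))
      res <- sam(xs[, keep, drop = FALSE], lab, B = B,
                 seed = seed + 7L * i + offset)
      select_significant(res, fdr_target = fdr_target,
                         label = paste0(cls, "_vs_normal/", t))
    }
    out[[t]] <- identify_mtdg(run_one("tumor", 0L), run_one("cell_line", 1L),
                              universe = universe, tissue = t)
  }
  out
}

#' Compare pipeline outputs with the planted truth
#'
#' Scores any of the supplied pipeline outputs against the generative
#' truth of a synthetic compendium:
#' \itemize{
#' \item `mtdg_tables`: estimated directional consistency percentages
#'   (pooled across tissues) versus the planted retention probabilities,
#'   plus sensitivity and realized false-discovery proportion of the
#'   tumor-vs-normal stage against the planted deregulation;
#' \item `curves` (a `power_curves`): whether the membranome curve's mean
#'   misclassification is below the non-membranome curve's at every size,
#'   with the paired one-sided p-values;
#' \item `correlation_summaries`: for how many tumor tissues the cognate
#'   cell-line distribution has the maximal mean;
#' \item `overlap`: for how many tissues the overlap-matrix diagonal is
#'   the column maximum.
#' }
#'
#' @param truth long truth data.frame from [generate_dataset()].
#' @param mtdg_tables,curves,correlation_summaries,overlap optional
#'   pipeline outputs.
#' @return list of report components for the outputs provided.
#' @export
evaluate_recovery <- function(truth, mtdg_tables = NULL, curves = NULL,
                              correlation_summaries = NULL, overlap = NULL) {
  report <- list()
  if (!is.null(mtdg_tables)) {
    genes_known <- unique(truth$gene_id)
    for (tb in mtdg_tables)
      if (length(setdiff(tb$universe, genes_known)) > 0L)
        stop("MTDG universe contains genes unknown to the truth table")
    per <- lapply(mtdg_tables, consistency_percentages)
    cnt <- Reduce(`+`, lapply(per, `[[`, "counts"))
    tp <- fp <- pos <- 0L
    for (tb in mtdg_tables) {
      tr <- truth[truth$tissue == tb$tissue, ]
      true_up <- tr$gene_id[tr$planted_up]
      true_down <- tr$gene_id[tr$planted_down]
      calls <- c(tb$t_up, tb$t_down)
      hits <- length(intersect(tb$t_up, true_up)) +
              length(intersect(tb$t_down, true_down))
      tp <- tp + hits
      fp <- fp + length(calls) - hits
      pos <- pos + length(intersect(true_up, tb$universe)) +
                   length(intersect(true_down, tb$universe))
    }
    report$consistency <- list(
      per_tissue = per,
      pct_up = if (cnt["t_up"] > 0) 100 * cnt["common_up"] / cnt["t_up"] else NA_real_,
      pct_down = if (cnt["t_down"] > 0) 100 * cnt["common_down"] / cnt["t_down"] else NA_real_,
      counts = cnt)
    report$dge <- list(
      sensitivity = if (pos > 0) tp / pos else NA_real_,
      realized_fdp = if (tp + fp > 0) fp / (tp + fp) else NA_real_,
      n_called = tp + fp, n_planted = pos)
  }
  if (!is.null(curves)) {
    cmp <- compare_curves(curves)
    report$classification <- list(
      comparison = cmp,
      membranome_always_lower = all(cmp$mean_a < cmp$mean_b),
      max_p = max(cmp$p_less))
  }
  if (!is.null(correlation_summaries)) {
    sm <- correlation_summaries$summaries
    tts <- intersect(unique(sm$tumor_tissue), unique(sm$cellline_tissue))
    is_max <- vapply(tts, function(tt) {
      rows <- sm[sm$tumor_tissue == tt, ]
      rows$cellline_tissue[which.max(rows$mean)] == tt
    }, logical(1L))
    report$cognate <- list(per_tissue = stats::setNames(is_max, tts),
                           n_max = sum(is_max), n_tissues = length(tts))
  }
  if (!is.null(overlap)) {
    dm <- overlap$diagonal_is_column_max
    report$overlap <- list(per_tissue = dm, n_max = sum(dm),
                           n_tissues = length(dm))
  }
  report
}
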