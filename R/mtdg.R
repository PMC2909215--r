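#' Assemble the membranome tumor-deregulated gene table for one tissue
#'
#' Combines the up/down gene lists of the tumor-vs-normal and
#' cell-line-vs-normal comparisons (run at the same FDR target over the
#' same analyzed gene universe) into a single per-tissue table.
#'
#' @param tumor_lists,cl_lists `deregulated_gene_lists` from the two
#'   comparisons (see [select_significant()]); plain lists with `up` and
#'   `down` character vectors are also accepted.
#' @param universe character vector of all analyzed genes.
#' @param tissue tissue label.
#' @return object of class `mtdg_table` with sets `t_up`, `t_down`,
#'   `cl_up`, `cl_down` and the `universe`.
#' @export
identify_mtdg <- function(tumor_lists, cl_lists, universe, tissue = NA_character_) {
  universe <- unique(as.character(universe))
  check <- function(v, what) {
    v <- unique(as.character(v))
    out <- setdiff(v, universe)
    if (length(out) > 0L)
      stop("gene(s) in ", what, " outside the universe: ",
           paste(out, collapse = ", "))
    v
  }
  t_up <- check(tumor_lists$up, "tumor up"); t_down <- check(tumor_lists$down, "tumor down")
  cl_up <- check(cl_lists$up, "cell-line up"); cl_down <- check(cl_lists$down, "cell-line down")
  if (length(intersect(t_up, t_down)) > 0L || length(intersect(cl_up, cl_down)) > 0L)
    stop("up and down lists overlap")
  structure(list(tissue = tissue, t_up = t_up, t_down = t_down,
                 cl_up = cl_up, cl_down = cl_down, universe = universe),
            class = "mtdg_table")
}

#' @export
print.mtdg_table <- function(x, ...) {
  cat(sprintf("MTDG table (%s): tumor %d up / %d down; cell line %d up / %d down; universe %d\n",
              x$tissue, length(x$t_up), length(x$t_down),
              length(x$cl_up), length(x$cl_down), length(x$universe)))
  invisible(x)
}

#' Directional consistency of tumor deregulation in cell lines
#'
#' Percentages of tumor-deregulated membranome genes whose deregulation is
#' retained, with the same direction, in the cognate cell lines:
#' `pct_up = 100 |t_up & cl_up| / |t_up|`, analogously for down, and the
#' combined percentage over both directions (denominators are the
#' tumor-side counts). Reported both exact and rounded to the nearest
#' integer (ties away from zero).
#'
#' @param table an `mtdg_table`.
#' @return object of class `consistency_report` with the seven counts and
#'   the three percentages.
#' @export
consistency_percentages <- function(table) {
  stopifnot(inherits(table, "mtdg_table"))
  n_up_common <- length(intersect(table$t_up, table$cl_up))
  n_down_common <- length(intersect(table$t_down, table$cl_down))
  n_t_up <- length(table$t_up); n_t_down <- length(table$t_down)
  pct <- function(num, den) if (den == 0L) NA_real_ else 100 * num / den
  pct_up <- pct(n_up_common, n_t_up)
  pct_down <- pct(n_down_common, n_t_down)
  pct_combined <- pct(n_up_common + n_down_common, n_t_up + n_t_down)
  structure(list(
    tissue = table$tissue,
    counts = c(cl_up = length(table$cl_up), cl_down = length(table$cl_down),
               t_up = n_t_up, t_down = n_t_down,
               common_up = n_up_common, common_down = n_down_common,
               common_total = n_up_common + n_down_common),
    pct_up = pct_up, pct_down = pct_down, pct_combined = pct_combined,
    pct_up_rounded = round_half_away(pct_up),
    pct_down_rounded = round_half_away(pct_down),
    pct_combined_rounded = round_half_away(pct_combined)
  ), class = "consistency_report")
}

#' @export
print.consistency_report <- function(x, ...) {
  cat(sprintf("Consistency (%s): up %d/%d (%d%%), down %d/%d (%d%%), combined %d/%d (%d%%)\n",
              x$tissue, x$counts["common_up"], x$counts["t_up"], x$pct_up_rounded,
              x$counts["common_down"], x$counts["t_down"], x$pct_down_rounded,
              x$counts["common_total"], x$counts["t_up"] + x$counts["t_down"],
              x$pct_combined_rounded))
  invisible(x)
}

#' One-sided overlap significance of two gene sets
#'
#' Hypergeometric enrichment tail P(X >= overlap) for the intersection of
#' two gene sets drawn from a common universe, computed in log space so
#' that `-log10(p)` survives p below 1e-300.
#'
#' @param set_a,set_b character vectors, subsets of `universe`.
#' @param universe character vector of all eligible genes.
#' @param overlap optionally override the observed overlap count (used by
#'   direction-aware callers); default `|set_a & set_b|`.
#' @return list with `p_value`, `minus_log10_p`, `n_overlap`, and the 2x2
#'   margins.
#' @export
overlap_significance <- function(set_a, set_b, universe, overlap = NULL) {
  universe <- unique(as.character(universe))
  if (length(universe) == 0L) stop("empty universe")
  a <- unique(as.character(set_a)); b <- unique(as.character(set_b))
  if (length(setdiff(a, universe)) > 0L || length(setdiff(b, universe)) > 0L)
    stop("sets must be subsets of the universe")
  k <- if (is.null(overlap)) length(intersect(a, b)) else as.integer(overlap)
  N <- length(universe); K <- length(a); n <- length(b)
  log_p <- stats::phyper(k - 1L, K, N - K, n, lower.tail = FALSE, log.p = TRUE)
  list(p_value = exp(log_p), minus_log10_p = -log_p / log(10),
       n_overlap = k, n_universe = N, n_set_a = K, n_set_b = n)
}

#' Cross-tissue MTDG overlap matrix
#'
#' Entry (cell-line tissue, tumor tissue) is `-log10` of the one-sided
#' Fisher/hypergeometric p-value for the overlap between the cell line's
#' and the tumor's deregulated membranome genes. By default the overlap is
#' direction-aware: set A is the cell line's up-or-down genes, set B the
#' tumor's, and the intersection counts only genes deregulated in the same
#' direction in both; `direction_aware = FALSE` counts any shared
#' deregulated gene. A maximality check reports whether each diagonal
#' entry is its column maximum.
#'
#' @param tables list of `mtdg_table`, one per tissue, sharing a universe.
#' @param direction_aware logical.
#' @return object of class `overlap_matrix`: the `-log10 p` matrix
#'   (rounded to one decimal in printing), the raw matrix, and the
#'   diagonal-maximality table.
#' @export
overlap_matrix <- function(tables, direction_aware = TRUE) {
  stopifnot(length(tables) >= 1L)
  tissues <- vapply(tables, `[[`, character(1L), "tissue")
  names(tables) <- tissues
  uni <- tables[[1L]]$universe
  for (tb in tables) if (!setequal(tb$universe, uni))
    stop("tables do not share a universe")
  m <- matrix(NA_real_, length(tissues), length(tissues),
              dimnames = list(cellline = tissues, tumor = tissues))
  for (ct in tissues) for (tt in tissues) {
    a <- union(tables[[ct]]$cl_up, tables[[ct]]$cl_down)
    b <- union(tables[[tt]]$t_up, tables[[tt]]$t_down)
    k <- if (direction_aware)
      length(intersect(tables[[ct]]$cl_up, tables[[tt]]$t_up)) +
      length(intersect(tables[[ct]]$cl_down, tables[[tt]]$t_down))
    else length(intersect(a, b))
    m[ct, tt] <- overlap_significance(a, b, uni, overlap = k)$minus_log10_p
  }
  diag_max <- vapply(tissues, function(tt)
    m[tt, tt] >= max(m[, tt]), logical(1L))
  structure(list(minus_log10_p = m,
                 diagonal_is_column_max = diag_max,
                 direction_aware = direction_aware),
            class = "overlap_matrix")
}

#' @export
print.overlap_matrix <- function(x, ...) {
  cat("-log10 overlap p-values (rows: cell lines, columns: tumors)\n")
  print(round(x$minus_log10_p, 1))
  cat("diagonal is column max:",
      paste(names(x$diagonal_is_column_max)[x$diagonal_is_column_max],
            collapse = ", "), "\n")
  invisible(x)
}
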