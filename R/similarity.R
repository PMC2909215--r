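#' All-pairs Pearson correlations between two sample groups
#'
#' Entry (i, j) is the Pearson correlation over `gene_subset` between
#' sample i of group A and sample j of group B. Zero-variance profiles
#' produce undefined correlations, recorded as NA with a warning.
#'
#' @param ds log2-scale `expression_dataset` (or matrix).
#' @param gene_subset gene IDs over which to correlate (>= 3 must be
#'   present in the dataset), e.g. the on-array membranome.
#' @param group_a,group_b disjoint character vectors of sample IDs, or
#'   logical selectors over manifest rows.
#' @return matrix of correlations, rows = group A samples, columns =
#'   group B samples.
#' @export
pairwise_correlations <- function(ds, gene_subset, group_a, group_b) {
  x <- if (inherits(ds, "expression_dataset")) ds$matrix else ds
  ids <- colnames(x)
  sel <- function(g) if (is.character(g)) intersect(g, ids) else ids[g]
  a <- sel(group_a); b <- sel(group_b)
  if (length(intersect(a, b)) > 0L) stop("groups must be disjoint")
  genes <- intersect(as.character(gene_subset), rownames(x))
  if (length(genes) < 3L) stop("need >= 3 genes present in the dataset")
  xa <- x[genes, a, drop = FALSE]; xb <- x[genes, b, drop = FALSE]
  zero_a <- apply(xa, 2L, stats::sd) == 0
  zero_b <- apply(xb, 2L, stats::sd) == 0
  if (any(zero_a) || any(zero_b))
    warning("zero-variance profile(s): ",
            paste(c(a[zero_a], b[zero_b]), collapse = ", "),
            "; their correlations are undefined (NA)")
  r <- suppressWarnings(stats::cor(xa, xb, method = "pearson"))
  r[zero_a, ] <- NA_real_
  r[, zero_b] <- NA_real_
  r
}

#' Grouped tumor vs cell-line correlation distributions
#'
#' Computes the all-pairs correlation between every tumor tissue group and
#' every cell-line tissue group over a gene subset and summarizes each
#' distribution (five-number summary with type-7 quartiles, mean, cognate
#' flag). Undefined pairs are excluded from summaries but counted.
#'
#' @param ds log2-scale `expression_dataset`.
#' @param gene_subset gene IDs used for the correlations.
#' @param tumor_class,cellline_class manifest `sample_class` values
#'   defining the two groups.
#' @return object of class `correlation_summaries`: data.frame with one
#'   row per (tumor_tissue, cellline_tissue) pair, plus the raw
#'   correlation lists.
#' @export
group_distributions <- function(ds, gene_subset, tumor_class = "tumor",
                                cellline_class = "cell_line") {
  stopifnot(inherits(ds, "expression_dataset"))
  man <- ds$manifest
  t_tissues <- sort(unique(man$tissue[man$sample_class == tumor_class]))
  c_tissues <- sort(unique(man$tissue[man$sample_class == cellline_class]))
  if (length(t_tissues) == 0L || length(c_tissues) == 0L)
    stop("no samples in one of the classes")
  rows <- list(); raw <- list()
  for (tt in t_tissues) for (ct in c_tissues) {
    a <- man$sample_id[man$tissue == tt & man$sample_class == tumor_class]
    b <- man$sample_id[man$tissue == ct & man$sample_class == cellline_class]
    r <- pairwise_correlations(ds, gene_subset, a, b)
    v <- as.numeric(r); n_undef <- sum(is.na(v)); v <- v[!is.na(v)]
    q <- stats::quantile(v, c(0, 0.25, 0.5, 0.75, 1), type = 7, names = FALSE)
    key <- paste(tt, ct, sep = "|")
    raw[[key]] <- v
    rows[[key]] <- data.frame(
      tumor_tissue = tt, cellline_tissue = ct, is_cognate = tt == ct,
      n_pairs = length(a) * length(b), n_undefined = n_undef,
      mean = mean(v), min = q[1L], q1 = q[2L], median = q[3L],
      q3 = q[4L], max = q[5L], stringsAsFactors = FALSE)
  }
  structure(list(summaries = do.call(rbind, c(rows, make.row.names = FALSE)),
                 correlations = raw),
            class = "correlation_summaries")
}

#' @export
print.correlation_summaries <- function(x, ...) {
  cat("Tumor vs cell-line correlation distributions\n")
  print(x$summaries, row.names = FALSE, digits = 3)
  invisible(x)
}

#' Cognate vs non-cognate correlation tests
#'
#' For each tumor tissue, compares the cognate cell-line correlation
#' distribution against each non-cognate distribution by a two-sample
#' Student's t-test (equal variances; Welch only as a flagged fallback
#' when a distribution is degenerate), Bonferroni-corrected over the full
#' family of tests. The per-tissue verdict `cognate_max` is TRUE when the
#' cognate mean is the largest and every adjusted p-value is below
#' `alpha`.
#'
#' @param summaries a `correlation_summaries` object.
#' @param alpha significance level for the verdict (default 0.01).
#' @return list with `tests` (data.frame of all pairwise tests) and
#'   `verdicts` (per tumor tissue).
#' @export
cognate_tests <- function(summaries, alpha = 0.01) {
  stopifnot(inherits(summaries, "correlation_summaries"))
  sm <- summaries$summaries
  t_tissues <- unique(sm$tumor_tissue)
  c_tissues <- unique(sm$cellline_tissue)
  tests <- list()
  for (tt in intersect(t_tissues, c_tissues)) {
    cog <- summaries$correlations[[paste(tt, tt, sep = "|")]]
    for (ct in setdiff(c_tissues, tt)) {
      oth <- summaries$correlations[[paste(tt, ct, sep = "|")]]
      if (length(cog) < 2L || length(oth) < 2L) next
      welch <- stats::sd(cog) == 0 || stats::sd(oth) == 0
      ht <- tryCatch(
        stats::t.test(cog, oth, var.equal = !welch),
        error = function(e) NULL)
      tests[[paste(tt, ct, sep = "|")]] <- data.frame(
        tumor_tissue = tt, other_tissue = ct,
        mean_cognate = mean(cog), mean_other = mean(oth),
        t = if (is.null(ht)) NA_real_ else unname(ht$statistic),
        p = if (is.null(ht)) 1 else ht$p.value,
        welch_fallback = welch, stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, c(tests, make.row.names = FALSE))
  n_tests <- nrow(tab)
  tab$p_adjusted <- pmin(1, tab$p * n_tests)
  verdicts <- do.call(rbind, lapply(unique(tab$tumor_tissue), function(tt) {
    rows <- tab[tab$tumor_tissue == tt, ]
    data.frame(tumor_tissue = tt,
               cognate_max = all(rows$mean_cognate > rows$mean_other) &&
                 all(rows$p_adjusted < alpha),
               stringsAsFactors = FALSE)
  }))
  list(tests = tab, verdicts = verdicts, n_tests = n_tests, alpha = alpha)
}
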