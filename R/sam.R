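#' Two-class moderated difference statistic
#'
#' Per-gene statistic
#' \deqn{d(i) = (\bar x_2(i) - \bar x_1(i)) / (s(i) + s_0)}
#' with the pooled standard error
#' \deqn{s(i) = \sqrt{(1/n_1 + 1/n_2)/(n_1+n_2-2) \,
#'   [\sum_1 (x-\bar x_1)^2 + \sum_2 (x-\bar x_2)^2]}.}
#' The fudge factor `s0` keeps `d` finite and damps genes whose variance
#' estimate is near zero.
#'
#' @param ds log2-scale `expression_dataset` or genes x samples matrix.
#' @param labels two-level class label per sample; the statistic is
#'   class2 minus class1 with levels in sorted order (or factor-level
#'   order if `labels` is a factor).
#' @param s0 fudge factor, >= 0.
#' @return list with `d`, `s`, `mean_diff` per gene and the class levels.
#' @export
d_statistic <- function(ds, labels, s0 = 0) {
  x <- if (inherits(ds, "expression_dataset")) ds$matrix else ds
  stopifnot(is.matrix(x), ncol(x) == length(labels))
  if (s0 < 0) stop("s0 must be non-negative")
  lv <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  labels <- as.character(labels)
  if (length(lv) != 2L) stop("exactly two classes required")
  i1 <- labels == lv[1L]; i2 <- labels == lv[2L]
  n1 <- sum(i1); n2 <- sum(i2)
  if (n1 < 2L || n2 < 2L) stop("both classes need >= 2 samples")
  m1 <- rowMeans(x[, i1, drop = FALSE]); m2 <- rowMeans(x[, i2, drop = FALSE])
  ss1 <- rowSums((x[, i1, drop = FALSE] - m1)^2)
  ss2 <- rowSums((x[, i2, drop = FALSE] - m2)^2)
  s <- sqrt((1 / n1 + 1 / n2) / (n1 + n2 - 2) * (ss1 + ss2))
  list(d = (m2 - m1) / (s + s0), s = s, mean_diff = m2 - m1, levels = lv)
}

#' Choose the fudge factor s0
#'
#' Picks the percentile of the gene-wise scales `s` that minimizes the
#' coefficient of variation of the `d` statistic across windows of genes
#' grouped by quantiles of `s` (variation measured by the median absolute
#' deviation within each window). Deterministic.
#'
#' @param ds dataset or matrix (passed to [d_statistic()]).
#' @param labels two-level class labels.
#' @param percentiles candidate percentiles of `s` (in \[0, 1\]).
#' @param n_windows number of s-quantile windows.
#' @return list with `s0`, the chosen `percentile` and the CV per candidate.
#' @export
estimate_s0 <- function(ds, labels, percentiles = seq(0, 1, by = 0.05),
                        n_windows = 10L) {
  base <- d_statistic(ds, labels, s0 = 0)
  s <- base$s
  r <- base$mean_diff
  if (length(s) < 10L) stop("need >= 10 genes to tune s0")
  if (max(s) - min(s) < 1e-12) {
    warning("all gene scales equal; s0 degenerate")
    return(list(s0 = s[1L], percentile = percentiles[1L],
                cv = stats::setNames(rep(0, length(percentiles)), percentiles),
                degenerate = TRUE))
  }
  br <- unique(stats::quantile(s, probs = seq(0, 1, length.out = n_windows + 1L),
                               type = 7))
  win <- cut(s, breaks = br, include.lowest = TRUE)
  cvs <- vapply(percentiles, function(p) {
    s0 <- stats::quantile(s, probs = p, type = 7)
    dd <- r / (s + s0)
    mads <- tapply(dd, win, stats::mad)
    mads <- mads[!is.na(mads)]
    stats::sd(mads) / mean(mads)
  }, numeric(1L))
  best <- which.min(cvs)
  list(s0 = unname(stats::quantile(s, probs = percentiles[best], type = 7)),
       percentile = percentiles[best],
       cv = stats::setNames(cvs, percentiles), degenerate = FALSE)
}

#' Permutation differential expression analysis
#'
#' Fits the moderated difference statistic, estimates its null
#' distribution by permuting class labels (all distinct label assignments
#' when their number does not exceed `B`, otherwise `B` random
#' permutations), and tabulates, for a grid of thresholds `delta` on the
#' deviation between observed and expected order statistics, the number of
#' genes called and the estimated false discovery rate
#' \deqn{\widehat{FDR}(\Delta) = \hat\pi_0 \cdot
#'   \mathrm{median}_b \#\{d_b \;\mathrm{beyond\;cuts}\} / n_{called},}
#' the conservative median-based estimate. The null proportion
#' \eqn{\hat\pi_0} is the count of observed `d` inside the interquartile
#' range of the permuted `d` values divided by half the gene count, capped
#' at 1.
#'
#' @inheritParams d_statistic
#' @param B maximum number of permutations (>= 50 unless exhaustive).
#' @param seed integer seed for sampled permutations.
#' @param s0 fudge factor; `NULL` tunes it with [estimate_s0()].
#' @param n_delta size of the threshold grid.
#' @param fdr_center how the permutation exceedance counts are summarized:
#'   `"mean"` (default; conservative, since the count distribution is
#'   right-skewed and the mean avoids the median's collapse to zero at
#'   small call counts) or `"median"`.
#' @return object of class `sam`: observed statistics, expected order
#'   statistics, permutation matrix summary, `delta_table`, `pi0`.
#' @export
sam <- function(ds, labels, B = 300L, seed = 1L, s0 = NULL, n_delta = 60L,
                fdr_center = c("mean", "median")) {
  fdr_center <- match.arg(fdr_center)
  x <- if (inherits(ds, "expression_dataset")) ds$matrix else ds
  stopifnot(is.matrix(x))
  lv <- if (is.factor(labels)) levels(labels) else sort(unique(as.character(labels)))
  labels <- as.character(labels)
  if (length(lv) != 2L) stop("exactly two classes required")
  if (is.null(s0)) s0 <- estimate_s0(x, factor(labels, levels = lv))$s0
  obs <- d_statistic(x, factor(labels, levels = lv), s0 = s0)
  n <- ncol(x); n1 <- sum(labels == lv[1L])
  perms <- .label_permutations(labels, lv, B, seed)
  exhaustive <- attr(perms, "exhaustive")
  d_perm <- matrix(NA_real_, nrow(x), ncol(perms))
  for (b in seq_len(ncol(perms))) {
    d_perm[, b] <- d_statistic(x, factor(perms[, b], levels = lv), s0 = s0)$d
  }
  d_sorted <- sort(obs$d)
  d_expected <- rowMeans(apply(d_perm, 2L, sort))
  pi0 <- {
    q <- stats::quantile(as.numeric(d_perm), c(0.25, 0.75), type = 7)
    min(1, sum(obs$d > q[1L] & obs$d < q[2L]) / (0.5 * length(obs$d)))
  }
  dev <- abs(d_sorted - d_expected)
  # quantile grid resolves the dense (null) deviation range, the uniform
  # grid the sparse upper range where true effects live
  half <- ceiling(n_delta / 2)
  deltas <- sort(unique(c(
    0, stats::quantile(dev, probs = seq(0, 1, length.out = half), type = 7),
    seq(0, max(dev), length.out = half), max(dev) + 1e-9)))
  delta_table <- do.call(rbind, lapply(deltas, function(dl) {
    cuts <- .sam_cuts(d_sorted, d_expected, dl)
    called_up <- obs$d >= cuts$up
    called_down <- obs$d <= cuts$low
    n_called <- sum(called_up) + sum(called_down)
    if (n_called == 0L)
      return(data.frame(delta = dl, cut_low = cuts$low, cut_up = cuts$up,
                        n_called = 0L, n_false = NA_real_, fdr = NA_real_))
    false_b <- apply(d_perm, 2L, function(db) sum(db >= cuts$up) + sum(db <= cuts$low))
    n_false <- if (fdr_center == "median") stats::median(false_b) else mean(false_b)
    data.frame(delta = dl, cut_low = cuts$low, cut_up = cuts$up,
               n_called = n_called, n_false = n_false,
               fdr = pi0 * n_false / n_called)
  }))
  structure(list(gene_ids = rownames(x), d = obs$d, s = obs$s, s0 = s0,
                 d_expected = d_expected, n_permutations = ncol(perms),
                 exhaustive = exhaustive, pi0 = pi0, fdr_center = fdr_center,
                 delta_table = delta_table, levels = lv,
                 comparison = paste(lv[2L], "vs", lv[1L])),
            class = "sam")
}

# All distinct assignments of samples to the two classes (preserving class
# sizes) when choose(n, n1) <= B, else B seeded random label shuffles.
.label_permutations <- function(labels, lv, B, seed) {
  n <- length(labels); n1 <- sum(labels == lv[1L])
  n_all <- choose(n, n1)
  if (n_all <= B) {
    combos <- utils::combn(n, n1)
    out <- matrix(lv[2L], n, ncol(combos))
    for (j in seq_len(ncol(combos))) out[combos[, j], j] <- lv[1L]
    attr(out, "exhaustive") <- TRUE
    return(out)
  }
  if (B < 50L) stop("B must be >= 50 (or exhaustive)")
  restore <- local_rng(seed)
  out <- replicate(B, sample(labels))
  restore()
  attr(out, "exhaustive") <- FALSE
  out
}

# Threshold crossing on the quantile-quantile display: walking up from the
# middle, the upper cut is the smallest observed d whose deviation above the
# expected order statistic exceeds delta (and symmetrically below).
.sam_cuts <- function(d_sorted, d_expected, delta) {
  n <- length(d_sorted)
  mid <- which.min(abs(d_expected))
  up <- Inf
  for (i in seq(mid, n)) {
    if (d_sorted[i] - d_expected[i] >= delta) { up <- d_sorted[i]; break }
  }
  low <- -Inf
  for (i in seq(mid, 1L)) {
    if (d_expected[i] - d_sorted[i] >= delta) { low <- d_sorted[i]; break }
  }
  list(low = low, up = up)
}

#' @export
print.sam <- function(x, ...) {
  cat(sprintf("Permutation DGE (%s): %d genes, %d permutations%s, s0 = %.4g, pi0 = %.3f\n",
              x$comparison, length(x$d), x$n_permutations,
              if (x$exhaustive) " (exhaustive)" else "", x$s0, x$pi0))
  tb <- x$delta_table
  show <- tb[!is.na(tb$fdr) & tb$fdr <= 1, ]
  if (nrow(show) > 0L) print(utils::head(show, 10L), row.names = FALSE)
  invisible(x)
}

#' @export
summary.sam <- function(object, fdr_target = 0.01, ...) {
  lists <- select_significant(object, fdr_target = fdr_target)
  cat(sprintf("%s at FDR < %g: %d up, %d down\n", object$comparison,
              fdr_target, length(lists$up), length(lists$down)))
  invisible(lists)
}

#' Select significant genes at a target FDR
#'
#' Chooses the smallest threshold `delta` whose estimated FDR is below
#' `fdr_target`; genes at or above the upper cut are called up, at or
#' below the lower cut down. If no threshold achieves the target the
#' result is empty and flagged.
#'
#' @param res a fitted `sam` object.
#' @param fdr_target target false discovery rate (default 0.01).
#' @param label comparison label carried into the result.
#' @return object of class `deregulated_gene_lists`: `up`, `down`
#'   (character vectors), `comparison`, `fdr_target`, `delta`,
#'   `achieved_fdr`, `empty_flag`.
#' @export
select_significant <- function(res, fdr_target = 0.01, label = res$comparison) {
  stopifnot(inherits(res, "sam"))
  tb <- res$delta_table
  ok <- !is.na(tb$fdr) & tb$fdr < fdr_target
  if (!any(ok)) {
    return(structure(list(up = character(), down = character(),
                          comparison = label, fdr_target = fdr_target,
                          delta = NA_real_, achieved_fdr = NA_real_,
                          empty_flag = TRUE),
                     class = "deregulated_gene_lists"))
  }
  row <- tb[which(ok)[1L], ]
  up <- res$gene_ids[res$d >= row$cut_up]
  down <- res$gene_ids[res$d <= row$cut_low]
  structure(list(up = up, down = down, comparison = label,
                 fdr_target = fdr_target, delta = row$delta,
                 achieved_fdr = row$fdr, empty_flag = FALSE),
            class = "deregulated_gene_lists")
}

#' @export
print.deregulated_gene_lists <- function(x, ...) {
  cat(sprintf("%s (FDR < %g): %d up, %d down%s\n", x$comparison,
              x$fdr_target, length(x$up), length(x$down),
              if (isTRUE(x$empty_flag)) " [no threshold met the target]" else ""))
  invisible(x)
}

#' Collapse probe-level calls to gene level
#'
#' A gene is called if any of its probes is called; its direction is the
#' majority probe direction, with exact ties excluded.
#'
#' @param lists a `deregulated_gene_lists` of probe IDs.
#' @param probe_map data.frame with columns `probe_id`, `gene_id`.
#' @return a `deregulated_gene_lists` of gene IDs.
#' @export
collapse_probes <- function(lists, probe_map) {
  stopifnot(inherits(lists, "deregulated_gene_lists"),
            all(c("probe_id", "gene_id") %in% names(probe_map)))
  gene_of <- stats::setNames(as.character(probe_map$gene_id),
                             as.character(probe_map$probe_id))
  up_g <- table(gene_of[intersect(lists$up, names(gene_of))])
  down_g <- table(gene_of[intersect(lists$down, names(gene_of))])
  genes <- union(names(up_g), names(down_g))
  nu <- as.numeric(up_g[genes]); nu[is.na(nu)] <- 0
  nd <- as.numeric(down_g[genes]); nd[is.na(nd)] <- 0
  structure(list(up = genes[nu > nd], down = genes[nd > nu],
                 comparison = lists$comparison, fdr_target = lists$fdr_target,
                 delta = lists$delta, achieved_fdr = lists$achieved_fdr,
                 empty_flag = length(genes) == 0L),
            class = "deregulated_gene_lists")
}
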