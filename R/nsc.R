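#' Fit a nearest shrunken centroid classifier
#'
#' Standardized class-centroid offsets
#' \deqn{d_{ik} = (\bar x_{ik} - \bar x_i) / (m_k (s_i + s_0))}
#' with \eqn{m_k = \sqrt{1/n_k - 1/n}}, pooled within-class standard
#' deviations \eqn{s_i}, and fudge factor \eqn{s_0} (median of the
#' \eqn{s_i} by default) are soft-thresholded by the shrinkage parameter
#' \eqn{\Delta}: \eqn{d'_{ik} = \mathrm{sign}(d_{ik}) (|d_{ik}| -
#' \Delta)_+}. Genes with a nonzero shrunken offset in any class are the
#' active genes; shrinkage implicitly selects genes.
#'
#' @param ds an `expression_dataset` on the log2 scale, or a plain numeric
#'   genes x samples matrix.
#' @param labels class label (e.g. tissue of origin) per sample.
#' @param delta shrinkage threshold, >= 0.
#' @param priors per-class prior probabilities; default class-proportional.
#' @param s0 fudge factor; default `median(s_i)`.
#' @return an object of class `nsc`: centroids, scales, offsets, shrunken
#'   offsets, active gene set.
#' @export
nsc <- function(ds, labels, delta = 0, priors = NULL, s0 = NULL) {
  x <- if (inherits(ds, "expression_dataset")) {
    if (ds$scale_state != "log2")
      stop("classifier expects log2-scale data; run the preprocessing chain first")
    ds$matrix
  } else ds
  stopifnot(is.matrix(x), ncol(x) == length(labels), delta >= 0)
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes")
  n <- ncol(x)
  nk <- table(factor(labels, levels = classes))
  if (any(nk < 2L))
    stop("class(es) with fewer than 2 samples (pooled variance undefined): ",
         paste(classes[nk < 2L], collapse = ", "))
  overall <- rowMeans(x)
  cent <- vapply(classes, function(k) rowMeans(x[, labels == k, drop = FALSE]),
                 numeric(nrow(x)))
  # pooled within-class variance: sum_k sum_{j in k} (x - xbar_k)^2 / (n - K)
  ss <- matrix(0, nrow(x), length(classes))
  for (j in seq_along(classes)) {
    xi <- x[, labels == classes[j], drop = FALSE]
    ss[, j] <- rowSums((xi - cent[, j])^2)
  }
  s <- stats::setNames(sqrt(rowSums(ss) / (n - length(classes))), rownames(x))
  if (is.null(s0)) s0 <- stats::median(s)
  if (s0 < 0) stop("s0 must be non-negative")
  mk <- sqrt(1 / as.numeric(nk) - 1 / n)
  d <- sweep(cent - overall, 1L, s + s0, `/`)
  d <- sweep(d, 2L, mk, `/`)
  dprime <- sign(d) * pmax(abs(d) - delta, 0)
  if (is.null(priors)) priors <- as.numeric(nk) / n
  stopifnot(length(priors) == length(classes), all(priors > 0))
  priors <- priors / sum(priors)
  names(priors) <- classes
  active <- rownames(x)[rowSums(dprime != 0) > 0L]
  shrunk_cent <- overall + sweep(sweep(dprime, 1L, s + s0, `*`), 2L, mk, `*`)
  dimnames(shrunk_cent) <- dimnames(cent) <- dimnames(d) <-
    dimnames(dprime) <- list(rownames(x), classes)
  structure(list(class_labels = classes, overall_centroid = overall,
                 class_centroids = cent, shrunken_centroids = shrunk_cent,
                 pooled_scales = s, s0 = s0, delta = delta,
                 class_factors = stats::setNames(mk, classes),
                 priors = priors, offsets = d, shrunken_offsets = dprime,
                 active_genes = active, n_per_class = as.numeric(nk)),
            class = "nsc")
}

#' @export
print.nsc <- function(x, ...) {
  cat(sprintf("Nearest shrunken centroid classifier: %d classes, delta = %g\n",
              length(x$class_labels), x$delta))
  cat(sprintf("  active genes: %d of %d\n", length(x$active_genes),
              length(x$overall_centroid)))
  invisible(x)
}

#' Predict class labels from a fitted nearest shrunken centroid model
#'
#' Discriminant score for class k:
#' \deqn{\delta_k(x^*) = \sum_{i \in \mathrm{active}} (x^*_i - \bar
#' x'_{ik})^2 / (s_i + s_0)^2 - 2 \log \pi_k}
#' The predicted label minimizes the score; with no active genes the score
#' reduces to the prior term and prediction falls back to the prior argmax.
#' Ties break to the lexicographically smallest class label.
#'
#' @param object a fitted `nsc` model.
#' @param newdata genes x samples matrix (or `expression_dataset`) whose
#'   gene set covers the model's active genes.
#' @param ... unused.
#' @return list with `labels` (predicted class per sample) and `scores`
#'   (samples x classes discriminant matrix).
#' @export
predict.nsc <- function(object, newdata, ...) {
  x <- if (inherits(newdata, "expression_dataset")) newdata$matrix else newdata
  if (is.null(dim(x))) x <- matrix(x, ncol = 1L,
                                   dimnames = list(names(x), "sample1"))
  act <- object$active_genes
  if (length(act) > 0L) {
    missing <- setdiff(act, rownames(x))
    if (length(missing) > 0L)
      stop("profile lacks active gene(s): ", paste(missing, collapse = ", "))
  }
  scores <- matrix(rep(-2 * log(object$priors), each = ncol(x)),
                   ncol(x), length(object$class_labels),
                   dimnames = list(colnames(x), object$class_labels))
  if (length(act) > 0L) {
    xs <- x[act, , drop = FALSE]
    denom <- (object$pooled_scales[act] + object$s0)^2
    for (k in object$class_labels) {
      dev <- (xs - object$shrunken_centroids[act, k])^2 / denom
      scores[, k] <- scores[, k] + colSums(dev)
    }
  }
  # argmin with lexicographic tie-break (columns already sorted by label)
  labels <- object$class_labels[apply(scores, 1L, which.min)]
  list(labels = stats::setNames(labels, colnames(x)), scores = scores)
}

#' Cross-validated misclassification rate
#'
#' Stratified k-fold cross-validation of the nearest shrunken centroid
#' classifier. Folds are drawn per class from the supplied seed; if some
#' class has fewer samples than `n_folds` the fold count is reduced with a
#' warning (every training split must keep >= 2 samples per class).
#'
#' @inheritParams nsc
#' @param n_folds number of folds (>= 2).
#' @param seed integer seed controlling fold assignment.
#' @return misclassification rate in `[0, 1]`.
#' @export
cv_misclassification <- function(ds, labels, delta = 0, n_folds = 5L,
                                 seed = 1L) {
  x <- if (inherits(ds, "expression_dataset")) ds$matrix else ds
  labels <- as.character(labels)
  classes <- sort(unique(labels))
  if (length(classes) < 2L) stop("need at least two classes")
  stopifnot(n_folds >= 2L)
  min_class <- min(table(labels))
  if (min_class < 3L)
    stop("smallest class has ", min_class,
         " samples; cross-validation needs >= 3 per class")
  eff_folds <- min(n_folds, min_class)
  # every training split must keep >= 2 samples per class; for very small
  # classes that forces leave-one-out within the class
  if (ceiling(min_class / eff_folds) > min_class - 2L) eff_folds <- min_class
  if (eff_folds != n_folds) {
    warning("adjusting folds from ", n_folds, " to ", eff_folds,
            " (smallest class has ", min_class, " samples)")
    n_folds <- eff_folds
  }
  fold <- integer(ncol(x))
  rng <- local_rng(seed)
  for (k in classes) {
    idx <- which(labels == k)
    fold[idx] <- (sample(length(idx)) %% n_folds) + 1L
  }
  rng()
  wrong <- 0L
  for (f in seq_len(n_folds)) {
    test <- fold == f
    fit <- nsc(x[, !test, drop = FALSE], labels[!test], delta = delta)
    pred <- predict(fit, x[, test, drop = FALSE])$labels
    wrong <- wrong + sum(pred != labels[test])
  }
  wrong / ncol(x)
}

# evaluate a block with a private RNG state seeded from `seed`;
# returns a restore function.
local_rng <- function(seed) {
  has_old <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  old <- if (has_old) get(".Random.seed", envir = globalenv())
  set.seed(seed)
  function() {
    if (has_old) assign(".Random.seed", old, envir = globalenv())
    invisible(NULL)
  }
}

#' Resampled misclassification curves for two gene pools
#'
#' For each classifier size N and each gene pool, draws N genes uniformly
#' without replacement, estimates the cross-validated misclassification
#' rate, repeats `n_replicates` times and averages. The same per-replicate
#' fold seed is used for both pools so replicate rates pair naturally for
#' one-sided comparison. Pools are sorted internally, making the result
#' invariant to gene and sample order.
#'
#' @param ds log2-scale `expression_dataset` (or matrix).
#' @param labels class label per sample.
#' @param pool_a,pool_b gene ID vectors, e.g. membranome members and a
#'   non-membranome pool; both must contain at least `max(sizes)` genes
#'   present in the dataset.
#' @param sizes classifier sizes (numbers of genes) to test.
#' @param n_replicates random gene draws per size.
#' @param seed integer seed.
#' @param delta shrinkage used in each fit (protocol default 0: the drawn
#'   list is the classifier).
#' @param n_folds folds for [cv_misclassification()].
#' @param labels_a,labels_b names used for the two curves.
#' @return object of class `power_curves`: per-pool data.frames of mean
#'   rates by size and the per-replicate rate matrices.
#' @export
power_curve <- function(ds, labels, pool_a, pool_b, sizes,
                        n_replicates = 1000L, seed = 1L, delta = 0,
                        n_folds = 5L,
                        labels_a = "membranome", labels_b = "not_membranome") {
  x <- if (inherits(ds, "expression_dataset")) ds$matrix else ds
  labels <- as.character(labels)
  ord <- order(colnames(x))
  x <- x[, ord, drop = FALSE]
  labels <- labels[ord]
  pool_a <- sort(intersect(as.character(pool_a), rownames(x)))
  pool_b <- sort(intersect(as.character(pool_b), rownames(x)))
  sizes <- sort(unique(as.integer(sizes)))
  if (max(sizes) > min(length(pool_a), length(pool_b)))
    stop("requested size ", max(sizes), " exceeds a gene pool (",
         length(pool_a), ", ", length(pool_b), ")")
  restore <- local_rng(seed)
  rep_seeds <- sample.int(.Machine$integer.max, n_replicates)
  draw_seeds <- matrix(sample.int(.Machine$integer.max,
                                  2L * n_replicates * length(sizes)),
                       ncol = 2L)
  restore()
  rates <- array(NA_real_, dim = c(n_replicates, length(sizes), 2L),
                 dimnames = list(NULL, as.character(sizes),
                                 c(labels_a, labels_b)))
  row_i <- 0L
  for (si in seq_along(sizes)) {
    for (r in seq_len(n_replicates)) {
      row_i <- row_i + 1L
      for (p in 1:2) {
        pool <- if (p == 1L) pool_a else pool_b
        restore2 <- local_rng(draw_seeds[row_i, p])
        genes <- sample(pool, sizes[si])
        restore2()
        rates[r, si, p] <- cv_misclassification(
          x[genes, , drop = FALSE], labels, delta = delta,
          n_folds = n_folds, seed = rep_seeds[r])
      }
    }
  }
  curve_of <- function(p, lab) {
    rr <- matrix(rates[, , p], nrow = n_replicates,
                 dimnames = list(NULL, as.character(sizes)))
    structure(list(gene_pool_label = lab, sizes = sizes,
                   mean_rates = stats::setNames(colMeans(rr), as.character(sizes)),
                   n_replicates = n_replicates,
                   per_replicate_rates = rr),
              class = "misclassification_curve")
  }
  structure(list(curve_a = curve_of(1L, labels_a), curve_b = curve_of(2L, labels_b),
                 sizes = sizes, n_replicates = n_replicates, seed = seed),
            class = "power_curves")
}

#' @export
print.power_curves <- function(x, ...) {
  cat("Resampled misclassification curves\n")
  tab <- data.frame(size = x$sizes,
                    a = x$curve_a$mean_rates, b = x$curve_b$mean_rates)
  names(tab)[2:3] <- c(x$curve_a$gene_pool_label, x$curve_b$gene_pool_label)
  print(tab, row.names = FALSE)
  invisible(x)
}

#' Exponential decay fit to a misclassification curve
#'
#' Least-squares fit of `rate = a * exp(-b * size) + c` with constraints
#' `b >= 0` and `c` in `[0, 1]` (Levenberg-Marquardt). Initialization:
#' `a = max - min` rate, `c = min` rate, `b` from a log-linear regression
#' on `rate - c`. Non-convergence is flagged and the best iterate returned.
#'
#' @param curve a `misclassification_curve`, or a list/data.frame with
#'   `sizes` and `mean_rates`.
#' @return list with `params` (a, b, c), `fitted`, `residuals`,
#'   `converged`.
#' @export
fit_exponential <- function(curve) {
  sizes <- as.numeric(curve$sizes)
  rates <- as.numeric(curve$mean_rates)
  if (length(sizes) < 4L) stop("need at least 4 points")
  c0 <- min(rates)
  a0 <- max(rates) - c0
  pos <- rates - c0 + 1e-8
  b0 <- tryCatch({
    sl <- stats::coef(stats::lm(log(pos) ~ sizes))[2L]
    max(1e-6, -as.numeric(sl))
  }, error = function(e) 0.05)
  if (a0 <= 0) a0 <- 1e-6
  dat <- data.frame(size = sizes, rate = rates)
  fit <- tryCatch(
    minpack.lm::nlsLM(rate ~ a * exp(-b * size) + c, data = dat,
                      start = list(a = a0, b = b0, c = max(0, min(1, c0))),
                      lower = c(a = -Inf, b = 0, c = 0),
                      upper = c(a = Inf, b = Inf, c = 1),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    fitted <- rep(mean(rates), length(sizes))
    return(list(params = c(a = 0, b = 0, c = mean(rates)), fitted = fitted,
                residuals = rates - fitted, converged = FALSE))
  }
  converged <- fit$convInfo$isConv
  p <- stats::coef(fit)
  list(params = c(a = unname(p["a"]), b = unname(p["b"]), c = unname(p["c"])),
       fitted = as.numeric(stats::fitted(fit)),
       residuals = as.numeric(stats::residuals(fit)),
       converged = isTRUE(converged))
}

#' Paired comparison of two misclassification curves
#'
#' One-sided paired t-test per size that curve A's replicate rates are
#' lower than curve B's, plus the overall mean difference.
#'
#' @param curves a `power_curves` object.
#' @return data.frame with per-size mean rates, mean paired difference and
#'   one-sided p-value (A < B).
#' @export
compare_curves <- function(curves) {
  stopifnot(inherits(curves, "power_curves"))
  ra <- curves$curve_a$per_replicate_rates
  rb <- curves$curve_b$per_replicate_rates
  if (is.null(dim(ra))) { ra <- matrix(ra, ncol = 1L); rb <- matrix(rb, ncol = 1L) }
  rows <- lapply(seq_along(curves$sizes), function(i) {
    d <- ra[, i] - rb[, i]
    p <- if (stats::sd(d) == 0) ifelse(mean(d) < 0, 0, 1)
         else stats::t.test(d, alternative = "less")$p.value
    data.frame(size = curves$sizes[i],
               mean_a = mean(ra[, i]), mean_b = mean(rb[, i]),
               mean_diff = mean(d), p_less = p)
  })
  do.call(rbind, rows)
}
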