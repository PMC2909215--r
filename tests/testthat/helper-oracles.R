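# Independent oracle implementations used to validate the package's
# statistics. These deliberately use plain loops and definitional formulas,
# not the package's code paths.

# Brute-force nearest-shrunken-centroid statistics from the definitional
# formulas: d_ik = (xbar_ik - xbar_i) / (m_k (s_i + s0)),
# d'_ik = sign(d_ik) (|d_ik| - delta)+, m_k = sqrt(1/n_k - 1/n).
oracle_nsc <- function(x, labels, delta = 0, s0 = NULL) {
  classes <- sort(unique(labels))
  n <- ncol(x); G <- nrow(x); K <- length(classes)
  xbar <- numeric(G); s2 <- numeric(G)
  cent <- matrix(0, G, K, dimnames = list(rownames(x), classes))
  for (i in seq_len(G)) xbar[i] <- sum(x[i, ]) / n
  for (k in seq_len(K)) {
    idx <- which(labels == classes[k])
    for (i in seq_len(G)) cent[i, k] <- sum(x[i, idx]) / length(idx)
  }
  for (i in seq_len(G)) {
    acc <- 0
    for (k in seq_len(K)) {
      idx <- which(labels == classes[k])
      for (j in idx) acc <- acc + (x[i, j] - cent[i, k])^2
    }
    s2[i] <- acc / (n - K)
  }
  s <- sqrt(s2)
  if (is.null(s0)) s0 <- median(s)
  d <- dp <- matrix(0, G, K, dimnames = list(rownames(x), classes))
  for (k in seq_len(K)) {
    nk <- sum(labels == classes[k])
    mk <- sqrt(1 / nk - 1 / n)
    for (i in seq_len(G)) {
      d[i, k] <- (cent[i, k] - xbar[i]) / (mk * (s[i] + s0))
      dp[i, k] <- sign(d[i, k]) * max(abs(d[i, k]) - delta, 0)
    }
  }
  shrunk <- matrix(0, G, K, dimnames = list(rownames(x), classes))
  for (k in seq_len(K)) {
    nk <- sum(labels == classes[k])
    mk <- sqrt(1 / nk - 1 / n)
    for (i in seq_len(G))
      shrunk[i, k] <- xbar[i] + mk * (s[i] + s0) * dp[i, k]
  }
  list(d = d, dprime = dp, s = s, s0 = s0, shrunken_centroids = shrunk,
       overall = xbar, classes = classes)
}

# Exhaustive evaluation of the discriminant over active genes.
oracle_nsc_predict <- function(orc, priors, profile) {
  active <- which(rowSums(orc$dprime != 0) > 0)
  scores <- numeric(length(orc$classes))
  names(scores) <- orc$classes
  for (k in seq_along(orc$classes)) {
    acc <- -2 * log(priors[k])
    for (i in active)
      acc <- acc + (profile[i] - orc$shrunken_centroids[i, k])^2 /
        (orc$s[i] + orc$s0)^2
    scores[k] <- acc
  }
  names(scores)[which.min(scores)]
}

# One-sided hypergeometric tail P(X >= k) by exhaustive enumeration of
# overlap counts (feasible for small N).
oracle_hyper_tail <- function(k, N, K, n) {
  total <- choose(N, n)
  p <- 0
  for (j in seq(k, min(K, n))) p <- p + choose(K, j) * choose(N - K, n - j)
  p / total
}

# Two-sided Fisher exact p for a 2x2 table by enumerating all tables with
# the observed margins; two-sided p sums probabilities <= that of the
# observed table (with a tiny tolerance, as fisher.test does).
oracle_fisher_two_sided <- function(tab) {
  r1 <- sum(tab[1, ]); r2 <- sum(tab[2, ]); c1 <- sum(tab[, 1])
  N <- r1 + r2
  probs <- vapply(max(0, c1 - r2):min(r1, c1), function(a)
    choose(r1, a) * choose(r2, c1 - a) / choose(N, c1), numeric(1))
  p_obs <- choose(r1, tab[1, 1]) * choose(r2, tab[2, 1]) / choose(N, c1)
  sum(probs[probs <= p_obs * (1 + 1e-7)])
}

# Small labelled matrix fixture with distinct per-class means.
make_fixture <- function(n_genes, per_class, n_classes = 2L, effect = 1,
                         seed = 1L) {
  set.seed(seed)
  classes <- LETTERS[seq_len(n_classes)]
  labels <- rep(classes, each = per_class)
  x <- matrix(rnorm(n_genes * length(labels)), n_genes, length(labels),
              dimnames = list(sprintf("g%02d", seq_len(n_genes)),
                              sprintf("s%02d", seq_along(labels))))
  for (k in seq_len(n_classes))
    x[k, labels == classes[k]] <- x[k, labels == classes[k]] + effect
  list(x = x, labels = labels)
}

# Minimal valid manifest for matrix columns.
make_manifest <- function(ids, tissue = "brain", cls = "tumor",
                          study = "s1", repgrp = NA_character_) {
  data.frame(sample_id = ids,
             tissue = rep_len(tissue, length(ids)),
             sample_class = rep_len(cls, length(ids)),
             study_id = rep_len(study, length(ids)),
             replicate_group = rep_len(repgrp, length(ids)),
             stringsAsFactors = FALSE)
}

make_dataset <- function(x, ..., scale_state = "linear") {
  expression_dataset(x, make_manifest(colnames(x), ...), scale_state)
}
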