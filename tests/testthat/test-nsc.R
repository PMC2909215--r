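test_that("centroid shrinkage matches the definitional brute-force oracle", {
  for (seed in 1:4) {
    fx <- make_fixture(n_genes = 6, per_class = 4, n_classes = 2, seed = seed)
    for (delta in c(0, 0.3, 1)) {
      fit <- nsc(fx$x, fx$labels, delta = delta)
      orc <- oracle_nsc(fx$x, fx$labels, delta = delta)
      expect_equal(fit$offsets, orc$d, tolerance = 1e-12)
      expect_equal(fit$shrunken_offsets, orc$dprime, tolerance = 1e-12)
      expect_equal(unname(fit$pooled_scales), unname(orc$s), tolerance = 1e-12)
      expect_equal(fit$shrunken_centroids, orc$shrunken_centroids,
                   tolerance = 1e-12)
    }
  }
})

test_that("prediction agrees with exhaustive discriminant evaluation", {
  for (seed in 5:8) {
    fx <- make_fixture(n_genes = 10, per_class = 4, n_classes = 3,
                       effect = 1.5, seed = seed)
    fit <- nsc(fx$x, fx$labels, delta = 0.2)
    orc <- oracle_nsc(fx$x, fx$labels, delta = 0.2)
    pred <- predict(fit, fx$x)$labels
    for (j in seq_len(ncol(fx$x))) {
      expect_equal(unname(pred[j]),
                   oracle_nsc_predict(orc, fit$priors, fx$x[, j]))
    }
  }
})

test_that("shrinkage delta spans all genes down to the prior fallback", {
  fx <- make_fixture(n_genes = 8, per_class = 5, seed = 3)
  fit0 <- nsc(fx$x, fx$labels, delta = 0)
  # at delta 0 every gene with a nonzero offset is active (all, generically)
  expect_setequal(fit0$active_genes, rownames(fx$x))
  expect_equal(fit0$shrunken_offsets, fit0$offsets)
  big <- max(abs(fit0$offsets)) + 1
  fitmax <- nsc(fx$x, fx$labels, delta = big, priors = c(0.75, 0.25))
  expect_length(fitmax$active_genes, 0L)
  # with no genes, prediction is the prior argmax for every profile
  pred <- predict(fitmax, fx$x)$labels
  expect_true(all(pred == "A"))
})

test_that("the active set shrinks monotonically in delta", {
  for (seed in 1:5) {
    fx <- make_fixture(n_genes = 12, per_class = 4, n_classes = 3, seed = seed)
    sizes <- vapply(seq(0, 2, by = 0.25), function(d)
      length(nsc(fx$x, fx$labels, delta = d)$active_genes), integer(1))
    expect_true(all(diff(sizes) <= 0))
  }
})

test_that("degenerate class sizes are rejected", {
  fx <- make_fixture(n_genes = 4, per_class = 3, seed = 1)
  expect_error(nsc(fx$x[, 1:4], c("A", "A", "A", "B")), "fewer than 2")
  expect_error(nsc(fx$x, rep("A", ncol(fx$x))), "two classes")
})

test_that("prediction refuses profiles lacking active genes", {
  fx <- make_fixture(n_genes = 6, per_class = 4, seed = 2)
  fit <- nsc(fx$x, fx$labels, delta = 0)
  expect_error(predict(fit, fx$x[1:3, ]), "lacks active gene")
})

test_that("a profile equal to a shrunken centroid classifies to its class", {
  fx <- make_fixture(n_genes = 6, per_class = 6, effect = 2, seed = 9)
  fit <- nsc(fx$x, fx$labels, delta = 0.1, priors = c(0.5, 0.5))
  for (k in fit$class_labels) {
    prof <- fit$shrunken_centroids[, k]
    expect_equal(unname(predict(fit, cbind(p = prof))$labels), k)
  }
})

test_that("cross-validated error is zero for separated classes and ~0.5 under label noise", {
  # disjoint value ranges, large effect
  x <- cbind(matrix(rnorm(60, 0, 0.1), 5), matrix(rnorm(60, 5, 0.1), 5))
  dimnames(x) <- list(sprintf("g%d", 1:5), sprintf("s%02d", 1:24))
  labels <- rep(c("A", "B"), each = 12)
  expect_equal(cv_misclassification(x, labels, seed = 1), 0)
  # permuted labels on structureless data: rate near one half
  set.seed(20)
  rates <- replicate(60, {
    y <- matrix(rnorm(10 * 16), 10, 16,
                dimnames = list(sprintf("g%d", 1:10), sprintf("s%02d", 1:16)))
    cv_misclassification(y, sample(rep(c("A", "B"), each = 8)),
                         seed = sample.int(1e6, 1))
  })
  expect_gt(mean(rates), 0.35)
  expect_lt(mean(rates), 0.65)
})

test_that("cross-validation is deterministic given the seed", {
  fx <- make_fixture(n_genes = 8, per_class = 8, effect = 0.6, seed = 13)
  r1 <- cv_misclassification(fx$x, fx$labels, seed = 7)
  r2 <- cv_misclassification(fx$x, fx$labels, seed = 7)
  expect_identical(r1, r2)
})

test_that("power curves pair replicates and collapse variance at full pool size", {
  fx <- make_fixture(n_genes = 30, per_class = 10, effect = 1, seed = 21)
  pool_a <- rownames(fx$x)[1:12]
  pool_b <- rownames(fx$x)[13:24]
  pc <- power_curve(fx$x, fx$labels, pool_a, pool_b, sizes = c(5, 12),
                    n_replicates = 8, seed = 3)
  # size == |pool|: the drawn list is always the whole pool, so identical
  # pools give bitwise-identical replicate rates (folds are shared); the
  # only replicate-to-replicate variation left is the fold redraw
  pc_same <- power_curve(fx$x, fx$labels, pool_a, pool_a, sizes = 12,
                         n_replicates = 8, seed = 3)
  expect_identical(pc_same$curve_a$per_replicate_rates,
                   pc_same$curve_b$per_replicate_rates)
  cmp <- compare_curves(pc)
  expect_equal(nrow(cmp), 2L)
  expect_true(all(cmp$p_less >= 0 & cmp$p_less <= 1))
  expect_error(power_curve(fx$x, fx$labels, pool_a, pool_b, sizes = 20,
                           n_replicates = 2, seed = 1), "exceeds")
})

test_that("identical pools give curves with paired differences centered at zero", {
  fx <- make_fixture(n_genes = 20, per_class = 8, effect = 0.5, seed = 30)
  pool <- rownames(fx$x)
  pc <- power_curve(fx$x, fx$labels, pool, pool, sizes = 8,
                    n_replicates = 40, seed = 9)
  d <- pc$curve_a$per_replicate_rates[, 1] - pc$curve_b$per_replicate_rates[, 1]
  if (stats::sd(d) > 0)
    expect_gt(stats::t.test(d)$p.value, 0.01)
  else expect_equal(mean(d), 0)
})

test_that("power curve means are invariant to gene and sample order", {
  fx <- make_fixture(n_genes = 16, per_class = 6, effect = 1, seed = 31)
  pool_a <- rownames(fx$x)[1:8]; pool_b <- rownames(fx$x)[9:16]
  pc1 <- power_curve(fx$x, fx$labels, pool_a, pool_b, sizes = 4,
                     n_replicates = 5, seed = 2)
  perm_g <- sample(nrow(fx$x)); perm_s <- sample(ncol(fx$x))
  pc2 <- power_curve(fx$x[perm_g, perm_s], fx$labels[perm_s],
                     sample(pool_a), sample(pool_b), sizes = 4,
                     n_replicates = 5, seed = 2)
  expect_equal(pc1$curve_a$mean_rates, pc2$curve_a$mean_rates)
  expect_equal(pc1$curve_b$mean_rates, pc2$curve_b$mean_rates)
})

test_that("exponential fits recover known decay parameters", {
  sizes <- c(5, 10, 25, 50, 100, 250)
  exact <- 0.5 * exp(-0.1 * sizes) + 0.05
  fit <- fit_exponential(list(sizes = sizes, mean_rates = exact))
  expect_equal(unname(fit$params), c(0.5, 0.1, 0.05), tolerance = 1e-6)
  expect_true(fit$converged)
  # constant curve degenerates to a ~ 0, c ~ the constant
  flat <- fit_exponential(list(sizes = sizes, mean_rates = rep(0.2, 6)))
  expect_equal(unname(flat$params["c"] + flat$params["a"] *
                        mean(exp(-flat$params["b"] * sizes))), 0.2,
               tolerance = 1e-6)
  expect_error(fit_exponential(list(sizes = 1:3, mean_rates = c(1, 2, 3))),
               "4 points")
})

test_that("noisy exponential curves are recovered within sampling error", {
  set.seed(77)
  sizes <- c(5, 10, 25, 50, 100, 250)
  truth <- c(a = 0.4, b = 0.05, c = 0.1)
  reps <- replicate(20, {
    noisy <- truth["a"] * exp(-truth["b"] * sizes) + truth["c"] +
      rnorm(length(sizes), 0, 0.01)
    fit_exponential(list(sizes = sizes, mean_rates = noisy))$params
  })
  se <- apply(reps, 1, sd)
  expect_true(all(abs(rowMeans(reps) - truth) < 3 * se / sqrt(20) + 1e-3))
})
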