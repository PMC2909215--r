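test_that("the moderated difference statistic follows its definition", {
  x <- rbind(g1 = c(1, 1, 3, 3), g2 = c(2, 3, 2, 3))
  colnames(x) <- sprintf("s%d", 1:4)
  lab <- c("a", "a", "b", "b")
  res <- d_statistic(x, lab, s0 = 0.5)
  # equal class means -> d = 0
  expect_equal(unname(res$d["g2"]), 0)
  # zero pooled scatter: d = 2 / s0 = 4
  expect_equal(unname(res$s["g1"]), 0)
  expect_equal(unname(res$d["g1"]), 4)
  # pooled standard error matches the explicit formula on random data
  set.seed(8)
  y <- matrix(rnorm(5 * 9), 5, 9,
              dimnames = list(sprintf("g%d", 1:5), sprintf("s%d", 1:9)))
  laby <- c(rep("a", 4), rep("b", 5))
  ry <- d_statistic(y, laby, s0 = 0.1)
  for (i in 1:5) {
    v1 <- y[i, laby == "a"]; v2 <- y[i, laby == "b"]
    s_hand <- sqrt((1 / 4 + 1 / 5) / 7 *
                     (sum((v1 - mean(v1))^2) + sum((v2 - mean(v2))^2)))
    expect_equal(unname(ry$s[i]), s_hand, tolerance = 1e-12)
    expect_equal(unname(ry$d[i]), (mean(v2) - mean(v1)) / (s_hand + 0.1),
                 tolerance = 1e-12)
  }
  # swapping class labels flips every sign
  swapped <- d_statistic(y, factor(laby, levels = c("b", "a")), s0 = 0.1)
  expect_equal(swapped$d, -ry$d)
  expect_error(d_statistic(y, laby, s0 = -1), "non-negative")
})

test_that("fudge-factor tuning is deterministic and handles degenerate scales", {
  set.seed(15)
  x <- matrix(rnorm(100 * 12), 100, 12,
              dimnames = list(sprintf("g%03d", 1:100), sprintf("s%02d", 1:12)))
  lab <- rep(c("a", "b"), each = 6)
  e1 <- estimate_s0(x, lab)
  e2 <- estimate_s0(x, lab)
  expect_identical(e1$s0, e2$s0)
  # a single candidate percentile is returned as-is
  e3 <- estimate_s0(x, lab, percentiles = 0.5)
  expect_equal(e3$percentile, 0.5)
  expect_equal(e3$s0, unname(quantile(d_statistic(x, lab)$s, 0.5, type = 7)))
  # all scales equal: degenerate, flagged, s0 equals that value
  xeq <- matrix(rep(c(0, 1, 0, 1), 12), 12, 4, byrow = TRUE,
                dimnames = list(sprintf("g%d", 1:12), sprintf("s%d", 1:4)))
  expect_warning(eq <- estimate_s0(xeq, c("a", "b", "a", "b")), "degenerate")
  expect_equal(unname(eq$s0), unname(d_statistic(xeq, c("a", "b", "a", "b"))$s[1]))
})

test_that("s0 selection is stable across homoscedastic replications", {
  set.seed(123)
  pcts <- replicate(30, {
    x <- matrix(rnorm(200 * 10), 200, 10,
                dimnames = list(sprintf("g%03d", 1:200), sprintf("s%02d", 1:10)))
    estimate_s0(x, rep(c("a", "b"), each = 5))$percentile
  })
  # homoscedastic data pushes the choice to the top of the scale
  # distribution in the large majority of replications
  expect_gte(max(table(pcts)) / 30, 0.8)
  expect_gte(stats::median(pcts), 0.9)
})

sam_noise_fixture <- function(seed, n_genes = 20, per_class = 4) {
  set.seed(seed)
  x <- matrix(rnorm(n_genes * 2 * per_class), n_genes, 2 * per_class,
              dimnames = list(sprintf("g%03d", seq_len(n_genes)),
                              sprintf("s%02d", seq_len(2 * per_class))))
  list(x = x, lab = rep(c("a", "b"), each = per_class))
}

test_that("exhaustive permutation analysis is seed-independent", {
  fx <- sam_noise_fixture(1)  # choose(8,4) = 70 permutations, exhaustive
  r1 <- sam(fx$x, fx$lab, B = 100, seed = 1)
  r2 <- sam(fx$x, fx$lab, B = 100, seed = 999)
  expect_true(r1$exhaustive)
  expect_equal(r1$d_expected, r2$d_expected)
  expect_equal(r1$delta_table, r2$delta_table)
})

test_that("under pure noise the first called threshold carries a high estimated FDR", {
  first <- vapply(1:6, function(seed) {
    fx <- sam_noise_fixture(seed)
    res <- sam(fx$x, fx$lab, B = 100, seed = seed)
    tb <- res$delta_table[res$delta_table$n_called > 0, ]
    tb$fdr[1]  # smallest threshold that calls anything
  }, numeric(1))
  expect_true(all(first > 0.5))
})

test_that("duplicating every gene duplicates statistics and calls exactly", {
  fx <- sam_noise_fixture(4)
  x2 <- rbind(fx$x, fx$x)
  rownames(x2) <- c(rownames(fx$x), paste0(rownames(fx$x), "_dup"))
  r1 <- sam(fx$x, fx$lab, B = 100, seed = 2, s0 = 0.2)
  r2 <- sam(x2, fx$lab, B = 100, seed = 2, s0 = 0.2)
  expect_equal(unname(r2$d[seq_len(20)]), unname(r2$d[21:40]))
  expect_equal(unname(r1$d), unname(r2$d[seq_len(20)]))
})

test_that("swapping class labels exchanges up and down calls", {
  set.seed(33)
  fx <- sam_noise_fixture(33, n_genes = 60)
  fx$x[1:6, fx$lab == "b"] <- fx$x[1:6, fx$lab == "b"] + 3
  fx$x[7:12, fx$lab == "b"] <- fx$x[7:12, fx$lab == "b"] - 3
  r_ab <- sam(fx$x, factor(fx$lab, levels = c("a", "b")), B = 100, seed = 3)
  r_ba <- sam(fx$x, factor(fx$lab, levels = c("b", "a")), B = 100, seed = 3)
  s_ab <- select_significant(r_ab, 0.05)
  s_ba <- select_significant(r_ba, 0.05)
  expect_setequal(s_ab$up, s_ba$down)
  expect_setequal(s_ab$down, s_ba$up)
})

test_that("call sets shrink as the FDR target tightens", {
  set.seed(44)
  fx <- sam_noise_fixture(44, n_genes = 100)
  fx$x[1:10, fx$lab == "b"] <- fx$x[1:10, fx$lab == "b"] + 2.5
  res <- sam(fx$x, fx$lab, B = 100, seed = 4)
  targets <- c(Inf, 0.5, 0.1, 0.01, 0.001)
  calls <- lapply(targets, function(tg) {
    s <- select_significant(res, tg); c(s$up, s$down)
  })
  for (i in seq_len(length(calls) - 1))
    expect_true(all(calls[[i + 1]] %in% calls[[i]]))
  # an infinite target admits every gene beyond the minimal threshold
  expect_equal(length(calls[[1]]), res$delta_table$n_called[1])
})

test_that("planted effects are recovered with controlled false discoveries", {
  n_rep <- 25
  fdp <- sens <- numeric(n_rep)
  for (i in seq_len(n_rep)) {
    set.seed(500 + i)
    x <- matrix(rnorm(500 * 16), 500, 16,
                dimnames = list(sprintf("g%03d", 1:500), sprintf("s%02d", 1:16)))
    lab <- rep(c("a", "b"), each = 8)
    planted <- sample(rownames(x), 50)
    x[planted, lab == "b"] <- x[planted, lab == "b"] + 2
    sel <- select_significant(sam(x, lab, B = 100, seed = i), 0.01)
    called <- c(sel$up, sel$down)
    fdp[i] <- length(setdiff(called, planted)) / max(1, length(called))
    sens[i] <- length(intersect(called, planted)) / 50
  }
  # realized false-discovery proportion controlled in nearly all repeats
  expect_gte(mean(fdp <= 0.05), 0.95)
  # power: the attainable envelope at this effect size and n (an oracle
  # thresholding at true FDP 0.01 reaches ~0.76 here)
  expect_gte(mean(sens), 0.55)
})

test_that("probe-level calls collapse to genes by any-called with majority direction", {
  lists <- structure(list(up = c("p1", "p2", "p5"), down = c("p3", "p4"),
                          comparison = "x", fdr_target = 0.01, delta = 1,
                          achieved_fdr = 0, empty_flag = FALSE),
                     class = "deregulated_gene_lists")
  pm <- data.frame(probe_id = sprintf("p%d", 1:6),
                   gene_id = c("gA", "gA", "gB", "gB", "gC", "gD"))
  out <- collapse_probes(lists, pm)
  expect_setequal(out$up, c("gA", "gC"))  # gA: 2 up probes; gC: 1 up
  expect_setequal(out$down, "gB")         # gB: 2 down probes
  expect_false("gD" %in% c(out$up, out$down))  # no called probes
})
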