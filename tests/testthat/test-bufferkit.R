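rate_tbl <- function(gene_id, alpha, synthesis) {
  tibble::tibble(gene_id = gene_id, alpha = alpha, synthesis = synthesis,
                 half_life_min = log(2) / alpha)
}

test_that("rate_fold_changes joins on shared genes with log2 ratios", {
  wt <- rate_tbl(c("a", "b", "c"), c(0.2, 0.4, 0.8), c(2, 4, 8))
  # identical tables: all fold changes zero
  same <- rate_fold_changes(wt, wt)
  expect_equal(same$log2fc_synthesis, rep(0, 3))
  expect_equal(same$log2fc_decay, rep(0, 3))
  # uniform 3.2-fold decay reduction
  mut <- rate_tbl(c("b", "c", "d"), c(0.4, 0.8, 1) / 3.2, c(4, 8, 1))
  cmp <- rate_fold_changes(wt, mut)
  expect_identical(cmp$gene_id, c("b", "c"))
  expect_equal(cmp$log2fc_decay, rep(-log2(3.2), 2), tolerance = 1e-12)
  expect_equal(round(log2(3.2), 3), 1.678)
  expect_error(rate_fold_changes(wt, rate_tbl("z", 1, 1)), "shared")
})

test_that("buffering correlation is Spearman with mid-ranked ties", {
  mono <- tibble::tibble(gene_id = letters[1:5],
                         log2fc_synthesis = 1:5, log2fc_decay = (1:5)^3)
  expect_equal(buffering_correlation(mono)$rho, 1)
  anti <- tibble::tibble(gene_id = letters[1:5],
                         log2fc_synthesis = 1:5, log2fc_decay = 5:1)
  expect_equal(buffering_correlation(anti)$rho, -1)
  # hand-rankable 5-point case: d^2 = (1,1,1,1,0), rho = 1 - 24/120 = 0.8
  five <- tibble::tibble(gene_id = letters[1:5],
                         log2fc_synthesis = c(1, 2, 3, 4, 5),
                         log2fc_decay = c(2, 1, 4, 3, 5))
  expect_equal(buffering_correlation(five)$rho, 0.8, tolerance = 1e-12)
  # invariant to monotone transforms of either axis
  five2 <- five
  five2$log2fc_decay <- exp(five2$log2fc_decay)
  expect_equal(buffering_correlation(five2)$rho, 0.8, tolerance = 1e-12)
  expect_error(buffering_correlation(five[1:2, ]), "3 genes")
})

test_that("rank-sum comparison: exact enumeration and medians", {
  # most extreme arrangement of 3 vs 3: two of C(6,3)=20 orderings
  res <- compare_rate_distributions(c(1, 2, 3), c(4, 5, 6))
  expect_equal(res$p_value, 0.1, tolerance = 1e-12)
  # identical samples
  same <- compare_rate_distributions(c(2, 2, 3), c(2, 2, 3))
  expect_equal(same$median_ratio, 1)
  expect_equal(same$p_value, 1)
  # elementwise 3.2-fold reduction shows up as the WT/mutant median ratio
  wt <- c(0.1, 0.2, 0.3, 0.5, 1.1)
  shift <- compare_rate_distributions(wt, wt / 3.2)
  expect_equal(shift$median_ratio, 3.2, tolerance = 1e-12)
})

test_that("exact rank-sum p agrees with the reference implementation", {
  # the no-ties exact p of wilcox.test is an independent oracle
  cases <- list(list(x = c(1.2, 3.1, 4.7), y = c(2.2, 5.5, 6.1, 0.4)),
                list(x = c(10, 12, 14, 16, 18), y = c(11, 13, 15)),
                list(x = c(0.5, 9.9), y = c(1, 2, 3, 4, 5, 6)))
  for (cs in cases) {
    ours <- compare_rate_distributions(cs$x, cs$y)$p_value
    ref <- wilcox.test(cs$x, cs$y, exact = TRUE)$p.value
    expect_equal(ours, ref, tolerance = 1e-12)
  }
  # large samples fall back to the tie-corrected normal approximation
  big <- compare_rate_distributions(1:50, (1:50) + 15)
  expect_equal(big$method, "normal approximation (tie-corrected)")
  expect_lt(big$p_value, 0.05)
})

test_that("top_percentile sizes, determinism and tie-breaks", {
  cmp <- tibble::tibble(gene_id = sprintf("g%03d", 1:100),
                        log2fc_synthesis = seq(-3, 3, length.out = 100),
                        log2fc_decay = 0)
  expect_length(top_percentile(cmp, "synthesis", 20)$members, 20)
  expect_length(top_percentile(cmp, "synthesis", 100)$members, 100)
  expect_length(top_percentile(cmp[1:7, ], "synthesis", 20)$members, 2)
  # magnitude, not sign: extremes from both ends selected
  top4 <- top_percentile(cmp, "synthesis", 4)$members
  expect_setequal(top4, c("g001", "g002", "g099", "g100"))
  # deterministic lexicographic tie-break
  tied <- tibble::tibble(gene_id = c("z", "a", "m"),
                         log2fc_decay = c(1, 1, 1), log2fc_synthesis = 0)
  expect_identical(top_percentile(tied, "decay", 33)$members, "a")
  expect_error(top_percentile(cmp, "synthesis", 0), "pct")
})

test_that("BH adjustment matches the step-up procedure by hand", {
  expect_equal(bh_adjust(c(0.01, 0.02, 0.03, 0.04)), rep(0.04, 4))
  expect_equal(bh_adjust(0.42), 0.42)
  expect_equal(bh_adjust(c(0.001, 1)), c(0.002, 1))
  p <- c(0.003, 0.04, 0.7, 0.012, 1, 0.2)
  adj <- bh_adjust(p)
  expect_true(all(adj >= p))          # adjustment never decreases p
  expect_true(all(adj <= 1))
  expect_equal(order(adj), order(p))  # order-restoring
  expect_error(bh_adjust(c(0.5, 1.2)), "0, 1")
})

test_that("threshold selection uses strict inequalities", {
  rule <- threshold_rule(2, 0.01)
  fc <- c(4, 2.5, 2.0, 0.3, 1.0, 3.0)
  padj <- c(0.001, 0.5, 0.001, 0.001, 0.001, 0.009)
  ids <- paste0("g", 1:6)
  sel <- threshold_select(ids, fc, padj, rule)
  expect_setequal(sel$up$members, c("g1", "g6"))  # g3 at exactly 2 excluded
  expect_setequal(sel$down$members, "g4")
  one <- threshold_select("x", 4, 0.005, rule)
  expect_identical(one$up$members, "x")
  expect_error(threshold_select(ids, fc, padj[1:3], rule), "aligned")
})

test_that("set overlap and hypergeometric tail", {
  u <- gene_set("universe", paste0("g", 1:10))
  a <- gene_set("a", paste0("g", 1:5))
  b <- gene_set("b", paste0("g", c(1:3, 5)))
  res <- set_overlap(a, b, u)
  expect_equal(res$overlap, 4)
  expect_equal(res$p_value, 5 / 210, tolerance = 1e-12)
  # disjoint sets
  d <- set_overlap(gene_set("x", "g1"), gene_set("y", "g2"), u)
  expect_equal(d$overlap, 0)
  expect_equal(d$p_value, 1)
  expect_equal(set_overlap(a, a, u)$overlap, 5)
  expect_error(set_overlap(gene_set("w", "nope"), b, u), "universe")
})

test_that("hypergeometric p matches brute-force enumeration on small universes", {
  withr::with_seed(3, {
    for (rep in 1:20) {
      nu <- sample(5:12, 1)
      universe <- paste0("g", seq_len(nu))
      a <- sample(universe, sample(1:nu, 1))
      nb <- sample(1:nu, 1)
      b_obs <- sample(universe, nb)
      k_obs <- length(intersect(a, b_obs))
      # enumerate every possible draw of |b| genes from the universe
      draws <- combn(universe, nb)
      ks <- apply(draws, 2, function(s) length(intersect(a, s)))
      brute <- mean(ks >= k_obs)
      res <- set_overlap(gene_set("a", a), gene_set("b", b_obs),
                         gene_set("u", universe))
      expect_equal(res$p_value, brute, tolerance = 1e-12)
    }
  })
})

test_that("surrogate DE test flags shifts and is calibrated under the null", {
  a <- matrix(2^c(5, 5, 5, 7, 7, 7), nrow = 2, byrow = TRUE,
              dimnames = list(c("g1", "g2"), NULL))
  # identical matrices: zero fold changes, p = 1
  same <- surrogate_de_test(a, a)
  expect_equal(same$log2fc, c(0, 0))
  expect_equal(same$p_value, c(1, 1))
  expect_identical(attr(same, "method"), "surrogate_t")
  # one gene shifted 8-fold with tiny variance dominates
  withr::with_seed(11, {
    base <- matrix(2^rnorm(300 * 3, 8, 0.2), nrow = 300)
    shifted <- base
    shifted[7, ] <- base[7, ] * 8
    res <- surrogate_de_test(base, shifted)
    expect_equal(which.min(res$p_value), 7)
    expect_gt(res$log2fc[7], 2.5)
  })
  # type-I error calibration on a null simulation
  withr::with_seed(12, {
    x <- matrix(2^rnorm(1000 * 4, 8, 0.3), nrow = 1000)
    y <- matrix(2^rnorm(1000 * 4, 8, 0.3), nrow = 1000)
    frac <- mean(surrogate_de_test(x, y)$p_value < 0.05)
    expect_gt(frac, 0.03)
    expect_lt(frac, 0.07)
  })
  expect_error(surrogate_de_test(a[, 1, drop = FALSE], a[, 1, drop = FALSE]),
               "replicates")
})
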