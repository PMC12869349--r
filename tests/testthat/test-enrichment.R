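test_that("pearson residuals match hand-derived examples", {
  even <- pearson_residuals(matrix(10, 2, 2))
  expect_true(all(even$residuals == 0))
  diag2 <- pearson_residuals(matrix(c(20, 0, 0, 20), 2, 2))
  expect_equal(diag2$expected, matrix(10, 2, 2))
  expect_equal(round(diag2$residuals, 4),
               matrix(c(3.1623, -3.1623, -3.1623, 3.1623), 2, 2))
  r <- pearson_residuals(matrix(c(30, 10, 10, 10), 2, 2, byrow = TRUE))
  expect_equal(round(r$residuals, 4),
               matrix(c(0.6455, -0.9129, -0.9129, 1.2910), 2, 2,
                      byrow = TRUE))
})

test_that("residuals agree with chisq.test and sum-of-squares identity", {
  set.seed(19)
  for (i in 1:50) {
    tab <- matrix(rpois(6, 20) + 1, 2, 3)
    r <- pearson_residuals(tab)
    ct <- suppressWarnings(chisq.test(tab, correct = FALSE))
    expect_lt(max(abs(r$residuals - ct$residuals)), 1e-12)
    expect_equal(r$chisq, unname(ct$statistic), tolerance = 1e-9)
    # transpose symmetry
    expect_equal(pearson_residuals(t(tab))$residuals, t(r$residuals),
                 tolerance = 1e-12)
  }
  expect_error(pearson_residuals(matrix(c(0, 0, 1, 2), 2, 2)), "marginal")
})

test_that("two-group rank test: exact p by enumeration, symmetry, ties", {
  p <- proportion_group_test(list(a = c(0.1, 0.2, 0.3),
                                  b = c(0.7, 0.8, 0.9)))
  expect_equal(p$p_value, 0.1)
  expect_identical(p$method, "wilcoxon_exact")
  expect_identical(p$direction, -1)
  expect_equal(p$p_value,
               enumerate_ranksum_p(c(0.1, 0.2, 0.3), c(0.7, 0.8, 0.9)))
  # symmetry under group swap
  q <- proportion_group_test(list(b = c(0.7, 0.8, 0.9),
                                  a = c(0.1, 0.2, 0.3)))
  expect_equal(q$p_value, p$p_value)
  expect_identical(q$direction, 1)
  # identical groups: exact p = 1
  s <- proportion_group_test(list(a = c(1, 3, 5), b = c(2, 4, 6)))
  expect_equal(s$p_value,
               enumerate_ranksum_p(c(1, 3, 5), c(2, 4, 6)))
  # ties force the normal approximation
  t2 <- proportion_group_test(list(a = c(1, 1, 2), b = c(1, 2, 3)))
  expect_identical(t2$method, "wilcoxon_normal_approx")
  expect_error(proportion_group_test(list(a = numeric(0), b = 1)), "empty")
})

test_that("exact p matches enumeration on random small instances", {
  set.seed(23)
  for (i in 1:10) {
    x <- runif(sample(3:6, 1))
    y <- runif(sample(3:6, 1))
    got <- proportion_group_test(list(x = x, y = y))$p_value
    expect_equal(got, enumerate_ranksum_p(x, y), tolerance = 1e-12)
  }
})

test_that("three groups fall back to Kruskal-Wallis", {
  set.seed(4)
  g <- list(a = runif(8), b = runif(8), c = runif(8) + 2)
  res <- proportion_group_test(g)
  expect_identical(res$method, "kruskal_wallis")
  ref <- kruskal.test(list(g$a, g$b, g$c))
  expect_equal(res$p_value, ref$p.value)
})

test_that("de_markers applies the keep rule exactly", {
  set.seed(8)
  n <- 60
  labels <- rep(c("A", "B"), each = n)
  expr <- matrix(rnorm(20 * 2 * n, 1, 0.3), 20)
  rownames(expr) <- sprintf("g%02d", 1:20)
  expr[1, labels == "A"] <- expr[1, labels == "A"] + 2  # strong A marker
  expr[expr < 0] <- 0
  mk <- de_markers(expr, labels)
  expect_s3_class(mk, "marker_table")
  expect_true(mk$kept[mk$gene == "g01" & mk$cluster == "A"])
  # keep flag is exactly the conjunction of the two thresholds
  expect_identical(mk$kept, mk$log2fc > 0.4 & mk$p_adj < 0.05)
  # BH is monotone in raw-p rank order within each cluster
  for (cl in unique(mk$cluster)) {
    sub <- mk[mk$cluster == cl, ]
    ord <- order(sub$p)
    expect_true(all(diff(sub$p_adj[ord]) >= -1e-12))
    expect_equal(sub$p_adj, p.adjust(sub$p, "BH"))
  }
})

test_that("de_markers vectorised p matches wilcox.test per gene", {
  set.seed(15)
  labels <- rep(c("A", "B"), c(20, 25))
  expr <- matrix(rnorm(10 * 45), 10)
  expr[3, ] <- round(expr[3, ], 1)  # introduce ties
  rownames(expr) <- sprintf("g%d", 1:10)
  mk <- de_markers(expr, labels, lfc_min = 0, alpha = 1)
  a_rows <- mk[mk$cluster == "A", ]
  for (g in rownames(expr)) {
    ref <- suppressWarnings(
      wilcox.test(expr[g, labels == "A"], expr[g, labels == "B"],
                  exact = FALSE, correct = TRUE))$p.value
    expect_equal(a_rows$p[a_rows$gene == g], ref, tolerance = 1e-9)
  }
  # a tiny cluster is skipped with a warning
  expect_warning(de_markers(expr, rep(c("A", "B", "C"), c(2, 21, 22))),
                 "skipped")
})

test_that("refine_signature drops lineage-promiscuous genes", {
  lm <- rbind(g1 = c(T = 10, Fib = 0.5, Mye = 1),
              g2 = c(T = 4, Fib = 4, Mye = 0.1),
              g3 = c(T = 6, Fib = 1, Mye = 3.5))
  sig <- refine_signature(c("g1", "g2", "g3"), lm, target = "T",
                          max_other_ratio = 0.5)
  expect_identical(sig$genes, "g1")  # g2 equal in Fib, g3 > 0.5x in Mye
  expect_identical(sig$source, "marker_derived")
  expect_warning(
    empty <- refine_signature("g2", lm, target = "T", max_other_ratio = 0.5),
    "no gene")
  expect_length(empty$genes, 0)
  expect_error(refine_signature("gX", lm, target = "T"), "gX")
})
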