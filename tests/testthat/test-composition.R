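make_cells <- function(sample_id, subtype, lineage = subtype) {
  data.frame(cell_id = sprintf("c%d", seq_along(sample_id)),
             sample_id = sample_id, subtype = subtype, lineage = lineage,
             stringsAsFactors = FALSE)
}

test_that("build_composition tallies fractions correctly", {
  cells <- make_cells(rep("S1", 4), c("A", "A", "B", "B"))
  comp <- build_composition(cells)
  expect_equal(unname(comp["S1", ]), c(0.5, 0.5))
  # absent subtype keeps a zero column when the universe is fixed
  comp2 <- build_composition(cells, subtypes = c("A", "B", "C"))
  expect_equal(unname(comp2["S1", "C"]), 0)
  expect_identical(colnames(comp2), c("A", "B", "C"))
})

test_that("fractions equal a brute-force tally on random tables", {
  set.seed(7)
  for (rep in 1:5) {
    n <- 300
    cells <- make_cells(sample(sprintf("S%d", 1:6), n, TRUE),
                        sample(LETTERS[1:8], n, TRUE))
    comp <- build_composition(cells)
    for (s in rownames(comp)) for (t in colnames(comp))
      expect_equal(comp[s, t], tally_fraction(cells, s, t))
    expect_true(all(abs(rowSums(comp) - 1) < 1e-12))
  }
})

test_that("parent-lineage denominator normalises within lineage blocks", {
  cells <- make_cells(rep("S1", 6), c("a1", "a2", "a2", "b1", "b1", "b1"),
                      c("A", "A", "A", "B", "B", "B"))
  comp <- build_composition(cells, denominator = "parent_lineage")
  expect_equal(unname(comp["S1", c("a1", "a2")]), c(1 / 3, 2 / 3))
  expect_equal(unname(comp["S1", "b1"]), 1)
  # within-lineage fractions sum to 1 per block
  lin <- attr(comp, "lineage_of")
  for (l in unique(lin))
    expect_equal(sum(comp["S1", lin == l]), 1)
})

test_that("scale_composition standardises columns (n-1 sd)", {
  comp <- matrix(c(0.1, 0.3, 0.9, 0.7), 2, 2,
                 dimnames = list(c("S1", "S2"), c("A", "B")))
  sc <- scale_composition(comp)
  expect_equal(unname(sc[, "A"]), c(-1, 1) / sqrt(2), tolerance = 1e-12)
  expect_equal(round(unname(sc[, "A"]), 4), c(-0.7071, 0.7071))
  # constant column maps to zeros
  const <- cbind(comp, C = c(0.4, 0.4))
  sc2 <- scale_composition(const)
  expect_true(all(sc2[, "C"] == 0))
  # column means 0 and sds 1 on a random matrix
  set.seed(1)
  m <- matrix(runif(60), 10)
  z <- scale_composition(m)
  expect_true(all(abs(colMeans(z)) < 1e-9))
  expect_true(all(abs(apply(z, 2, sd) - 1) < 1e-9))
  expect_error(scale_composition(m[1, , drop = FALSE]), "2 samples")
})

test_that("infer_ecotypes separates two obvious blobs and handles k bounds", {
  m <- matrix(c(0, 0.1, 10, 10.1), 4, 1,
              dimnames = list(sprintf("S%d", 1:4), "x"))
  mod <- infer_ecotypes(m, k = 2)
  a <- mod$assignments
  expect_identical(a[["S1"]], a[["S2"]])
  expect_identical(a[["S3"]], a[["S4"]])
  expect_false(a[["S1"]] == a[["S3"]])
  # k = n: singletons
  mod_n <- infer_ecotypes(m, k = 4)
  expect_identical(length(unique(mod_n$assignments)), 4L)
  expect_error(infer_ecotypes(m, k = 5), "k")
  expect_error(infer_ecotypes(m, k = 0), "k")
})

test_that("Ward merge heights are monotone and labels ordered by size", {
  set.seed(3)
  m <- matrix(rnorm(40 * 5), 40)
  mod <- infer_ecotypes(m, k = 4)
  expect_true(all(diff(mod$hclust$height) >= -1e-12))
  sizes <- as.integer(table(mod$assignments))
  expect_true(all(diff(sizes) <= 0))  # E1 is the largest ecotype
})

test_that("assignments are invariant to sample order (up to labels)", {
  set.seed(11)
  m <- matrix(rnorm(25 * 6), 25, dimnames = list(sprintf("S%02d", 1:25), NULL))
  mod1 <- infer_ecotypes(m, k = 3)
  perm <- sample(25)
  mod2 <- infer_ecotypes(m[perm, ], k = 3)
  expect_true(same_partition(
    as.character(mod1$assignments[rownames(m)]),
    as.character(mod2$assignments[rownames(m)])))
})

test_that("ecotype_group_distribution computes counts and percentages", {
  m <- matrix(c(0, 0.1, 0.2, 0.3, 10, 10.1), 6, 1,
              dimnames = list(sprintf("S%d", 1:6), "x"))
  mod <- infer_ecotypes(m, k = 2)
  samples <- data.frame(sample_id = sprintf("S%d", 1:6),
                        cancer_type = "BCC",
                        stage = c("early", "early", "early", "advanced",
                                  "advanced", "advanced"))
  dist <- ecotype_group_distribution(mod, samples, by = "stage")
  # E1 = the 4-sample cluster: 3 early + 1 advanced -> 75/25
  expect_equal(unname(dist$ecotype_pct["E1", c("advanced", "early")]),
               c(25, 75))
  expect_true(all(abs(rowSums(dist$ecotype_pct) - 100) < 1e-6))
  # single-group cohort: 100 everywhere
  one <- ecotype_group_distribution(mod, transform(samples, stage = "early"),
                                    by = "stage")
  expect_true(all(one$ecotype_pct == 100))
  expect_error(ecotype_group_distribution(mod, samples[-1, ], by = "stage"),
               "S1")
})

test_that("dendrogram export round-trips through Newick", {
  set.seed(5)
  m <- matrix(rnorm(12 * 3), 12, dimnames = list(sprintf("S%02d", 1:12), NULL))
  mod <- infer_ecotypes(m, k = 3)
  nwk <- export_dendrogram(mod)
  phy <- ape::read.tree(text = nwk)
  expect_identical(ape::Ntip(phy), 12L)
  expect_setequal(phy$tip.label, rownames(m))
  # two-leaf tree: "(A:h/2,B:h/2);" shape
  m2 <- matrix(c(0, 3), 2, 1, dimnames = list(c("A", "B"), NULL))
  mod2 <- infer_ecotypes(m2, k = 1)
  phy2 <- ape::read.tree(text = export_dendrogram(mod2))
  expect_equal(sort(phy2$edge.length), rep(mod2$hclust$height / 2, 2))
})

test_that("annotate_ecotypes names ecotypes by dominant lineage", {
  cells <- make_cells(rep(c("S1", "S2", "S3", "S4"), each = 10),
                      rep(c("t1", "f1"), c(20, 20)),
                      rep(c("TNK", "Fibroblast"), c(20, 20)))
  comp <- build_composition(cells)
  mod <- infer_ecotypes(scale_composition(comp), k = 2)
  lin <- build_composition(cells, level = "lineage")
  ann <- annotate_ecotypes(mod, lin)
  expect_setequal(unname(ann), c("TNK", "Fibroblast"))
})
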