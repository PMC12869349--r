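test_that("simulation is byte-identical under a fixed seed", {
  cfg <- simulation_config(n_samples = 8, n_cells_range = c(100, 200),
                           seed = 11)
  a <- simulate_cohort(cfg)
  b <- simulate_cohort(cfg)
  expect_identical(a, b)
  ea <- simulate_expression(a, cfg)
  eb <- simulate_expression(b, cfg)
  expect_identical(ea, eb)
  sc <- runif(20)
  sa <- simulate_survival(sc, seed = 3)
  set.seed(99)  # ambient RNG state must not leak in
  sb <- simulate_survival(sc, seed = 3)
  expect_identical(sa, sb)
})

test_that("flat-profile subtype fractions match the Dirichlet mean", {
  n_sub <- 10
  sub <- data.frame(subtype = sprintf("s%02d", 1:n_sub),
                    lineage = "L", stringsAsFactors = FALSE)
  flat <- list(flat = ecotype_profile("flat", rep(5, n_sub)))
  cfg <- simulation_config(n_samples = 60, subtypes = sub,
                           n_cells_range = c(1000, 1000), profiles = flat,
                           qc_violation_rate = 0, seed = 21)
  co <- simulate_cohort(cfg)
  comp <- build_composition(co$cells)
  means <- colMeans(comp)
  # Dirichlet mean alpha_k / sum(alpha) = 1/n_sub; MC sd of the mean of 60
  # Dirichlet draws with alpha0 = 50: sqrt(p(1-p)/(alpha0+1)/60)
  mc_se <- sqrt((1 / n_sub) * (1 - 1 / n_sub) / (5 * n_sub + 1) / 60)
  expect_true(all(abs(means - 1 / n_sub) < 3 * mc_se + 3e-3))
  # composition rows sum to one
  expect_true(all(abs(rowSums(comp) - 1) < 1e-12))
})

test_that("invalid configurations are rejected", {
  expect_error(ecotype_profile("bad", c(1, -1, 2)), "strictly positive")
  expect_error(ecotype_profile("bad", c(1, 2), c(early = 0, advanced = 0)),
               "stage_bias")
  expect_error(simulation_config(n_samples = 0), "n_samples")
  expect_error(simulate_survival(runif(5), censor_rate = 1), "censor_rate")
  expect_error(simulate_survival(runif(5), hazard_ratio = 0), "hazard_ratio")
})

test_that("planted QC violations are detected by apply_qc", {
  cfg <- simulation_config(n_samples = 6, n_cells_range = c(400, 600),
                           qc_violation_rate = 0.05, seed = 5)
  co <- simulate_cohort(cfg)
  rep <- apply_qc(co$cells)
  planted <- co$cells$planted_violation != ""
  # every planted low-gene / high-mito cell must fail
  expect_true(all(!rep$cells$pass[co$cells$planted_violation %in%
                                    c("low_genes", "high_mito")]))
  # large majority of MAD outliers are caught (they sit far below the band)
  mad_out <- co$cells$planted_violation == "mad_outlier"
  expect_gt(mean(!rep$cells$pass[mad_out]), 0.9)
  # false-positive rate on clean cells stays small
  expect_lt(mean(!rep$cells$pass[!planted]), 0.05)
})

test_that("expression simulation plants recoverable markers", {
  sub <- data.frame(subtype = c("A", "B", "C"), lineage = c("A", "B", "C"),
                    stringsAsFactors = FALSE)
  prof <- list(flat = ecotype_profile("flat", rep(3, 3)))
  cfg <- simulation_config(n_samples = 4, subtypes = sub,
                           n_cells_range = c(150, 150), profiles = prof,
                           n_genes = 60, n_markers_per_subtype = 4,
                           marker_effect = 2, seed = 31)
  co <- simulate_cohort(cfg)
  expr <- simulate_expression(co, cfg)
  mm <- attr(expr, "marker_map")
  expect_named(mm, c("A", "B", "C"))
  norm <- log_normalize(expr + 0L)
  mk <- de_markers(norm, co$cells$subtype)
  kept_a <- mk$gene[mk$cluster == "A" & mk$kept]
  expect_gte(mean(mm$A %in% kept_a), 0.9)  # planted-marker recall
})

test_that("null expression shows no subtype shift beyond chance", {
  sub <- data.frame(subtype = c("A", "B"), lineage = c("A", "B"),
                    stringsAsFactors = FALSE)
  prof <- list(flat = ecotype_profile("flat", rep(3, 2)))
  cfg <- simulation_config(n_samples = 3, subtypes = sub,
                           n_cells_range = c(200, 200), profiles = prof,
                           n_genes = 100, n_markers_per_subtype = 2,
                           marker_effect = 0, seed = 41)
  co <- simulate_cohort(cfg)
  expr <- simulate_expression(co, cfg)
  norm <- log_normalize(expr + 0L)
  mk <- de_markers(norm, co$cells$subtype, lfc_min = 0, alpha = 1)
  # raw p-values roughly uniform: rejection at .05 within binomial noise
  rej <- mean(mk$p < 0.05)
  expect_lt(rej, 0.05 + 3 * sqrt(0.05 * 0.95 / nrow(mk)) + 0.02)
})

test_that("censor_rate = 0 observes every event", {
  sv <- simulate_survival(runif(50), censor_rate = 0, seed = 9)
  expect_true(all(sv$event == 1))
  expect_true(all(sv$time > 0))
})

test_that("cohort invariants hold and files round-trip", {
  cfg <- simulation_config(n_samples = 10, n_cells_range = c(100, 150),
                           normal_fraction = 0.2, seed = 13)
  co <- simulate_cohort(cfg)
  expect_true(all(co$cells$sample_id %in% co$samples$sample_id))
  tumour <- co$samples$sample_id[co$samples$stage != "normal"]
  expect_setequal(names(co$true_ecotype), tumour)
  expect_true(all(co$cells$housekeeping_count <= co$cells$gene_count))
  expect_true(all(co$cells$mito_fraction >= 0 & co$cells$mito_fraction <= 1))
  dir <- withr::local_tempdir()
  expr <- simulate_expression(co, cfg, max_cells = 200)
  sv <- simulate_survival(stats::setNames(runif(10), co$samples$sample_id))
  write_cohort(co, dir, expression = expr, survival = sv)
  expect_true(all(file.exists(file.path(dir,
    c("cells.tsv", "samples.tsv", "truth.json", "counts.mtx",
      "features.tsv", "barcodes.tsv", "survival.csv")))))
  cells2 <- read.delim(file.path(dir, "cells.tsv"))
  expect_identical(nrow(cells2), nrow(co$cells))
  # MTX header is valid coordinate format
  hdr <- readLines(file.path(dir, "counts.mtx"), n = 2)
  expect_match(hdr[1], "MatrixMarket matrix coordinate integer general")
})
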