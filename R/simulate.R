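# Seeded synthetic cohorts with the statistical structure the analysis
# assumes: latent ecotype profiles -> Dirichlet subtype proportions ->
# multinomial cell counts, per-cell QC metrics with planted violations,
# log-normal-Poisson expression with planted subtype markers, and
# proportional-hazards survival driven by a score threshold.

#' Latent ecotype profile
#'
#' @param name profile label.
#' @param concentration strictly positive Dirichlet concentration vector over
#'   subtypes.
#' @param stage_bias named nonnegative sampling weights per stage (not all
#'   zero), e.g. `c(early = 0.8, advanced = 0.2)`.
#' @return An `ecotype_profile` object.
#' @export
ecotype_profile <- function(name, concentration,
                            stage_bias = c(early = 1, advanced = 1)) {
  if (!is.numeric(concentration) || any(concentration <= 0) ||
      any(!is.finite(concentration)))
    stopf("profile `%s`: concentration must be strictly positive", name)
  if (any(stage_bias < 0) || all(stage_bias == 0) || is.null(names(stage_bias)))
    stopf("profile `%s`: stage_bias must be named, nonnegative, not all zero",
          name)
  structure(list(name = as.character(name), concentration = concentration,
                 stage_bias = stage_bias),
            class = "ecotype_profile")
}

#' Default subtype universe: 44 subtypes across 7 lineages
#'
#' @return data.frame with `subtype` and `lineage` columns (T/NK 10, myeloid
#'   8, fibroblast 6, endothelial 4, B/plasma 4, DC 2, tumour 10).
#' @export
default_subtypes <- function() {
  blocks <- c(TNK = 10L, Myeloid = 8L, Fibroblast = 6L, Endothelial = 4L,
              Bcell = 4L, DC = 2L, Tumour = 10L)
  data.frame(
    subtype = unlist(lapply(names(blocks), function(b)
      sprintf("%s_c%02d", b, seq_len(blocks[[b]])))),
    lineage = rep(names(blocks), blocks),
    stringsAsFactors = FALSE)
}

#' Default ecotype archetypes
#'
#' Five profiles mirroring the archetypes recovered from skin-tumour
#' microenvironments: T-cell-dominant (early-stage-biased), stromal-enriched,
#' balanced, immune-desert (tumour-cell-dominated, advanced-stage-biased) and
#' myeloid-enriched. Block profiles put concentration `conc_block` on their
#' own lineage block and `conc_bg` elsewhere; the balanced profile is uniform.
#'
#' @param subtypes subtype/lineage table as from [default_subtypes()].
#' @param conc_block own-block concentration (default 50).
#' @param conc_bg background concentration (default 0.5).
#' @return Named list of [ecotype_profile()] objects.
#' @export
default_profiles <- function(subtypes = default_subtypes(),
                             conc_block = 50, conc_bg = 0.5) {
  block <- function(lineages) {
    conc <- ifelse(subtypes$lineage %in% lineages, conc_block, conc_bg)
    names(conc) <- subtypes$subtype
    conc
  }
  uniform <- stats::setNames(rep(2, nrow(subtypes)), subtypes$subtype)
  list(
    T_dominant = ecotype_profile("T_dominant", block("TNK"),
                                 c(early = 0.8, advanced = 0.2)),
    stromal = ecotype_profile("stromal", block(c("Fibroblast", "Endothelial")),
                              c(early = 0.5, advanced = 0.5)),
    balanced = ecotype_profile("balanced", uniform,
                               c(early = 0.5, advanced = 0.5)),
    desert = ecotype_profile("desert", block("Tumour"),
                             c(early = 0.2, advanced = 0.8)),
    myeloid = ecotype_profile("myeloid", block("Myeloid"),
                              c(early = 0.5, advanced = 0.5))
  )
}

#' Disjoint-block profiles for recovery experiments
#'
#' `k` profiles over `n_subtypes` subtypes, each putting concentration
#' `conc_block` on its own contiguous block (blocks partition the subtypes)
#' and `conc_bg` everywhere else. The well-separated stated world for
#' clustering-recovery checks.
#'
#' @param k number of profiles.
#' @param n_subtypes number of subtypes (default 44).
#' @param conc_block,conc_bg block / background concentrations (50 / 0.5).
#' @return Named list of [ecotype_profile()] objects.
#' @export
block_profiles <- function(k, n_subtypes = 44, conc_block = 50,
                           conc_bg = 0.5) {
  stopifnot(k >= 1, n_subtypes >= k)
  bounds <- floor(seq(0, n_subtypes, length.out = k + 1))
  out <- lapply(seq_len(k), function(i) {
    conc <- rep(conc_bg, n_subtypes)
    conc[(bounds[i] + 1):bounds[i + 1]] <- conc_block
    ecotype_profile(sprintf("P%d", i), conc)
  })
  names(out) <- vapply(out, `[[`, character(1), "name")
  out
}

#' Simulation configuration
#'
#' @param n_samples number of samples (default 120).
#' @param subtypes subtype/lineage table; its row count is the number of
#'   subtypes (default 44 via [default_subtypes()]).
#' @param n_cells_range per-sample cell count drawn uniformly from this range
#'   (default 500-3000, emulating heterogeneous sample sizes).
#' @param profiles named list of [ecotype_profile()]s (default
#'   [default_profiles()]).
#' @param normal_fraction fraction of samples that are adjacent-normal skin
#'   (stage `normal`, no ecotype truth; default 0).
#' @param qc_violation_rate fraction of cells with a planted QC violation
#'   (default 0.02).
#' @param n_genes,n_markers_per_subtype expression-simulation dimensions
#'   (defaults 300 and 3).
#' @param marker_effect natural-log-fold elevation of planted subtype markers
#'   (default 2).
#' @param hazard_ratio hazard multiplier above the survival score cutoff
#'   (default 3).
#' @param seed integer master seed.
#' @return A `simulation_config` object.
#' @export
simulation_config <- function(n_samples = 120, subtypes = default_subtypes(),
                              n_cells_range = c(500, 3000),
                              profiles = default_profiles(subtypes),
                              normal_fraction = 0,
                              qc_violation_rate = 0.02,
                              n_genes = 300, n_markers_per_subtype = 3,
                              marker_effect = 2, hazard_ratio = 3,
                              seed = 1L) {
  if (nrow(subtypes) < 2L) stopf("need at least 2 subtypes")
  if (!length(profiles)) stopf("need at least one profile")
  for (p in profiles) {
    if (!inherits(p, "ecotype_profile")) stopf("profiles must be ecotype_profile")
    if (length(p$concentration) != nrow(subtypes))
      stopf("profile `%s`: concentration length %d != %d subtypes",
            p$name, length(p$concentration), nrow(subtypes))
  }
  assert_scalar_number(n_samples, "n_samples", lower = 1)
  assert_scalar_number(qc_violation_rate, "qc_violation_rate", lower = 0,
                       upper = 1)
  assert_scalar_number(normal_fraction, "normal_fraction", lower = 0,
                       upper = 0.9)
  assert_scalar_number(marker_effect, "marker_effect", lower = 0)
  assert_scalar_number(hazard_ratio, "hazard_ratio", lower = 0,
                       strict_lower = TRUE)
  stopifnot(length(n_cells_range) == 2L, n_cells_range[1] >= 1,
            n_cells_range[2] >= n_cells_range[1])
  structure(list(n_samples = as.integer(n_samples), subtypes = subtypes,
                 n_cells_range = as.integer(round(n_cells_range)),
                 profiles = profiles, normal_fraction = normal_fraction,
                 qc_violation_rate = qc_violation_rate,
                 n_genes = as.integer(n_genes),
                 n_markers_per_subtype = as.integer(n_markers_per_subtype),
                 marker_effect = marker_effect, hazard_ratio = hazard_ratio,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

rdirichlet1 <- function(alpha) {
  g <- stats::rgamma(length(alpha), shape = alpha, rate = 1)
  if (sum(g) == 0) g[which.max(alpha)] <- 1   # numerically degenerate alphas
  g / sum(g)
}

#' Simulate a synthetic cohort
#'
#' Per sample: a cancer type (uniform over BCC/SCC/CM/AM) and stage (early or
#' advanced, equiprobable) are drawn; an ecotype profile is drawn with
#' probability proportional to its `stage_bias` weight for that stage;
#' subtype proportions follow `Dirichlet(concentration)` and cell counts a
#' multinomial over them. Per-cell QC metrics: UMIs and genes detected
#' jointly log-normal (correlation 0.9), housekeeping genes a binomial
#' thinning of genes detected, mitochondrial fraction Beta(2, 20); a
#' `qc_violation_rate` fraction of cells gets one planted violation (low
#' genes < 200, mitochondrial fraction > 0.2, or a low-count outlier below
#' the per-sample median-minus-3-MAD band), recorded in
#' `cells$planted_violation`.
#'
#' @param config a [simulation_config()].
#' @return A `simulated_cohort`: list with `cells` (per-cell table),
#'   `samples` (metadata), `true_ecotype` (named vector over tumour samples),
#'   `proportions` (true samples x subtypes Dirichlet draws), `config`.
#' @export
simulate_cohort <- function(config = simulation_config()) {
  stopifnot(inherits(config, "simulation_config"))
  with_seed(config$seed, {
    ns <- config$n_samples
    subtypes <- config$subtypes
    sample_id <- sprintf("S%03d", seq_len(ns))
    n_normal <- round(config$normal_fraction * ns)
    is_normal <- seq_len(ns) <= n_normal
    cancer_type <- ifelse(is_normal, "AdjNormal",
                          sample(c("BCC", "SCC", "CM", "AM"), ns, TRUE))
    stage <- ifelse(is_normal, "normal",
                    sample(c("early", "advanced"), ns, TRUE))

    prof_names <- names(config$profiles)
    true_eco <- rep(NA_character_, ns)
    prop <- matrix(0, ns, nrow(subtypes),
                   dimnames = list(sample_id, subtypes$subtype))
    n_cells <- sample(config$n_cells_range[1]:config$n_cells_range[2], ns,
                      replace = TRUE)

    cells_list <- vector("list", ns)
    for (i in seq_len(ns)) {
      if (is_normal[i]) {
        # adjacent normal: mildly T/fibroblast-rich uniform-ish tissue
        alpha <- stats::setNames(rep(2, nrow(subtypes)), subtypes$subtype)
        alpha[subtypes$lineage == "Tumour"] <- 0.2
      } else {
        w <- vapply(config$profiles, function(p) {
          b <- p$stage_bias[stage[i]]
          if (is.na(b)) 0 else unname(b)
        }, numeric(1))
        if (all(w == 0)) w <- rep(1, length(w))
        pick <- sample(prof_names, 1L, prob = w)
        true_eco[i] <- pick
        alpha <- config$profiles[[pick]]$concentration
      }
      pr <- rdirichlet1(alpha)
      prop[i, ] <- pr
      counts <- as.integer(stats::rmultinom(1L, n_cells[i], pr))
      subtype_vec <- rep(subtypes$subtype, counts)
      lineage_vec <- rep(subtypes$lineage, counts)
      nc <- length(subtype_vec)

      # correlated log-normal UMIs / genes; housekeeping by thinning. Spreads
      # kept tight enough that median - 3 MAD stays a meaningful lower bound
      z1 <- stats::rnorm(nc)
      z2 <- 0.9 * z1 + sqrt(1 - 0.9^2) * stats::rnorm(nc)
      gene_count <- pmax(50L, as.integer(round(exp(log(1500) + 0.15 * z1))))
      umi_count <- pmax(100L, as.integer(round(exp(log(5000) + 0.18 * z2))))
      housekeeping_count <- stats::rbinom(nc, gene_count, 0.04)
      mito_fraction <- stats::rbeta(nc, 2, 20)
      mito_fraction <- pmin(mito_fraction, 0.19)  # keep baseline below gate

      planted <- rep("", nc)
      n_bad <- stats::rbinom(1L, nc, config$qc_violation_rate)
      if (n_bad > 0) {
        bad <- sample.int(nc, n_bad)
        kind <- sample(c("low_genes", "high_mito", "mad_outlier"), n_bad,
                       replace = TRUE)
        low <- bad[kind == "low_genes"]
        gene_count[low] <- sample(20:199, length(low), replace = TRUE)
        umi_count[low] <- pmax(100L, as.integer(gene_count[low] * 2.5))
        housekeeping_count[low] <- stats::rbinom(length(low), gene_count[low],
                                                 0.04)
        hi <- bad[kind == "high_mito"]
        mito_fraction[hi] <- stats::runif(length(hi), 0.25, 0.6)
        out <- bad[kind == "mad_outlier"]
        gene_count[out] <- as.integer(round(gene_count[out] * 0.15))
        umi_count[out] <- as.integer(round(umi_count[out] * 0.15))
        housekeeping_count[out] <- pmin(housekeeping_count[out],
                                        as.integer(gene_count[out] * 0.02))
        planted[bad] <- kind
      }
      housekeeping_count <- pmin(housekeeping_count, gene_count)

      cells_list[[i]] <- data.frame(
        cell_id = sprintf("%s_C%05d", sample_id[i], seq_len(nc)),
        sample_id = sample_id[i], lineage = lineage_vec,
        subtype = subtype_vec, umi_count = umi_count,
        gene_count = gene_count, housekeeping_count = housekeeping_count,
        mito_fraction = mito_fraction, planted_violation = planted,
        stringsAsFactors = FALSE)
    }

    cells <- do.call(rbind, cells_list)
    rownames(cells) <- NULL
    samples <- data.frame(sample_id = sample_id,
                          patient_id = sprintf("P%03d", seq_len(ns)),
                          cancer_type = cancer_type, stage = stage,
                          n_cells = n_cells, stringsAsFactors = FALSE)
    true_ecotype <- stats::setNames(true_eco[!is_normal],
                                    sample_id[!is_normal])
    structure(list(cells = cells, samples = samples,
                   true_ecotype = true_ecotype, proportions = prop,
                   config = config),
              class = "simulated_cohort")
  })
}

#' @export
print.simulated_cohort <- function(x, ...) {
  cat(sprintf("simulated cohort: %d samples, %d cells, %d subtypes, seed %d\n",
              nrow(x$samples), nrow(x$cells), nrow(x$config$subtypes),
              x$config$seed))
  invisible(x)
}

#' Simulate single-cell expression counts with planted markers
#'
#' Gene counts per cell follow a log-normal-Poisson model: the Poisson rate
#' is `exp(baseline_g + depth_c + noise)`, with each subtype's marker genes
#' elevated by `marker_effect` (natural-log fold) in cells of that subtype.
#' Marker genes are disjoint across subtypes.
#'
#' @param cohort a `simulated_cohort` (or any data.frame of cells with
#'   `cell_id` and `subtype`).
#' @param config a [simulation_config()]; `n_genes`,
#'   `n_markers_per_subtype`, `marker_effect` and `seed` are used.
#' @param max_cells optional cap: a deterministic subsample of cells to keep
#'   matrices tractable (default `Inf`).
#' @return genes x cells integer matrix with attribute `marker_map` (named
#'   list subtype -> marker gene ids).
#' @export
simulate_expression <- function(cohort, config = cohort$config,
                                max_cells = Inf) {
  cells <- if (inherits(cohort, "simulated_cohort")) cohort$cells else cohort
  if (!nrow(cells)) stopf("cohort has no cells")
  with_seed(derive_seed(config$seed, "expression"), {
    if (nrow(cells) > max_cells)
      cells <- cells[sort(sample.int(nrow(cells), max_cells)), , drop = FALSE]
    subtypes <- sort(unique(cells$subtype))
    ng <- config$n_genes
    nm <- config$n_markers_per_subtype
    if (ng < length(subtypes) * nm)
      stopf("n_genes too small for %d markers per %d subtypes",
            nm, length(subtypes))
    genes <- sprintf("G%04d", seq_len(ng))
    marker_map <- stats::setNames(
      lapply(seq_along(subtypes), function(i)
        genes[((i - 1) * nm + 1):(i * nm)]),
      subtypes)

    baseline <- stats::rnorm(ng, mean = 0, sd = 0.5)
    depth <- stats::rnorm(nrow(cells), mean = 0, sd = 0.3)
    logmu <- outer(baseline, depth, "+")
    for (s in subtypes) {
      gi <- match(marker_map[[s]], genes)
      ci <- which(cells$subtype == s)
      logmu[gi, ci] <- logmu[gi, ci] + config$marker_effect
    }
    noise <- matrix(stats::rnorm(ng * nrow(cells), sd = 0.2), ng)
    counts <- matrix(stats::rpois(ng * nrow(cells), exp(logmu + noise)), ng,
                     dimnames = list(genes, cells$cell_id))
    attr(counts, "marker_map") <- marker_map
    counts
  })
}

#' Simulate survival driven by a score threshold
#'
#' Event times are exponential with baseline rate `base_rate`, multiplied by
#' `hazard_ratio` when `score > cutoff`. Censoring is independent
#' exponential, with rate `base_rate * censor_rate / (1 - censor_rate)` so
#' the marginal censoring fraction is about `censor_rate` when
#' `hazard_ratio = 1`; `censor_rate = 0` means no censoring.
#'
#' @param score numeric per-sample scores.
#' @param cutoff threshold splitting low/high hazard.
#' @param hazard_ratio hazard multiplier above the cutoff (> 0).
#' @param censor_rate target censoring fraction in `[0, 1)`.
#' @param base_rate baseline exponential rate (default 1).
#' @param seed integer seed.
#' @return data.frame `sample_id`, `time`, `event`, `score`.
#' @export
simulate_survival <- function(score, cutoff = 0.5, hazard_ratio = 3,
                              censor_rate = 0.3, base_rate = 1, seed = 1L) {
  assert_scalar_number(hazard_ratio, "hazard_ratio", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(base_rate, "base_rate", lower = 0, strict_lower = TRUE)
  if (!is.numeric(censor_rate) || length(censor_rate) != 1L ||
      censor_rate < 0 || censor_rate >= 1)
    stopf("`censor_rate` must lie in [0, 1)")
  n <- length(score)
  if (n < 1L) stopf("`score` must be nonempty")
  with_seed(seed, {
    rate <- base_rate * ifelse(score > cutoff, hazard_ratio, 1)
    t_event <- stats::rexp(n, rate)
    if (censor_rate > 0) {
      t_cens <- stats::rexp(n, base_rate * censor_rate / (1 - censor_rate))
      time <- pmin(t_event, t_cens)
      event <- as.integer(t_event <= t_cens)
    } else {
      time <- t_event
      event <- rep(1L, n)
    }
    data.frame(sample_id = names(score) %||% sprintf("S%03d", seq_len(n)),
               time = time, event = event, score = as.numeric(score),
               stringsAsFactors = FALSE)
  })
}

#' Write a simulated cohort to disk
#'
#' Writes `cells.tsv`, `samples.tsv`, `truth.json`, and (when supplied)
#' expression as MatrixMarket `counts.mtx` + `features.tsv` + `barcodes.tsv`
#' and `survival.csv`.
#'
#' @param cohort a `simulated_cohort`.
#' @param dir output directory (created).
#' @param expression optional genes x cells counts matrix.
#' @param survival optional survival data.frame.
#' @return Invisibly, the directory.
#' @export
write_cohort <- function(cohort, dir, expression = NULL, survival = NULL) {
  stopifnot(inherits(cohort, "simulated_cohort"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  utils::write.table(cohort$cells, file.path(dir, "cells.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(cohort$samples, file.path(dir, "samples.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  jsonlite::write_json(as.list(cohort$true_ecotype),
                       file.path(dir, "truth.json"), auto_unbox = TRUE,
                       digits = NA, pretty = TRUE)
  if (!is.null(expression)) {
    write_mtx(expression, file.path(dir, "counts.mtx"))
    writeLines(rownames(expression), file.path(dir, "features.tsv"))
    writeLines(colnames(expression), file.path(dir, "barcodes.tsv"))
  }
  if (!is.null(survival))
    utils::write.csv(survival, file.path(dir, "survival.csv"),
                     row.names = FALSE, quote = FALSE)
  invisible(dir)
}

# minimal MatrixMarket coordinate writer for a dense integer matrix
write_mtx <- function(m, path) {
  nz <- which(m != 0, arr.ind = TRUE)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(c("%%MatrixMarket matrix coordinate integer general",
               sprintf("%d %d %d", nrow(m), ncol(m), nrow(nz))), con)
  if (nrow(nz))
    writeLines(sprintf("%d %d %d", nz[, 1], nz[, 2], m[nz]), con)
  invisible(path)
}
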