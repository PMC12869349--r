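# End-to-end orchestration: simulate/ingest -> QC -> composition -> ecotypes
# -> enrichment -> scoring -> survival, from a single JSON-serialisable
# config, with a machine-readable run report (parameter echo + file digests).

#' Default pipeline configuration
#'
#' A complete, modest-sized configuration running every stage on a simulated
#' cohort. Any entry may be overridden before [run_pipeline()].
#'
#' @param out_dir output directory.
#' @param seed master seed; each stage derives its own sub-seed from it.
#' @return Nested list understood by [run_pipeline()].
#' @export
default_pipeline_config <- function(out_dir = "tmeco_run", seed = 1L) {
  list(
    seed = as.integer(seed),
    out_dir = out_dir,
    stages = list(simulate = TRUE, qc = TRUE, composition = TRUE,
                  ecotype = TRUE, enrichment = TRUE, scoring = TRUE,
                  survival = TRUE),
    inputs = list(cells = NULL, samples = NULL),
    simulate = list(n_samples = 24, n_cells_range = c(150, 400),
                    normal_fraction = 0, qc_violation_rate = 0.02,
                    n_genes = 200, n_markers_per_subtype = 3,
                    marker_effect = 2),
    qc = list(min_genes = 200, mad_multiplier = 3, max_mito = 0.2,
              mad_scale = 1.4826),
    ecotype = list(k = 5, denominator = "all_cells"),
    enrichment = list(by = "stage"),
    scoring = list(method = "ssgsea", alpha = 0.25, normalize = TRUE,
                   max_cells = 4000, signature_subtype = NULL),
    survival = list(minprop = 0.1, cutoff = 0.5, hazard_ratio = 3,
                    censor_rate = 0.3)
  )
}

#' Read / write a pipeline config
#'
#' @param path JSON file.
#' @return The config list ([read_pipeline_config()]) or `path`, invisibly.
#' @export
read_pipeline_config <- function(path) {
  cfg <- jsonlite::read_json(path, simplifyVector = TRUE)
  base <- default_pipeline_config()
  utils::modifyList(base, cfg)
}

#' @rdname read_pipeline_config
#' @param config config list.
#' @export
write_pipeline_config <- function(config, path) {
  jsonlite::write_json(config, path, auto_unbox = TRUE, digits = NA,
                       pretty = TRUE)
  invisible(path)
}

pipeline_log <- function(quiet, stage, fmt, ...) {
  if (!quiet) message(sprintf("[%s] %s", stage, sprintf(fmt, ...)))
}

#' Run the full analysis pipeline
#'
#' Executes the enabled stages in dependency order, writing each stage's
#' outputs under `config$out_dir` and a `MANIFEST` of completed stages. On a
#' stage failure the error is re-raised prefixed with the stage name; partial
#' outputs and the MANIFEST are retained. The run report (`run_report.json`)
#' echoes the config, records counts and warnings, and digests (MD5) every
#' file written, so identical config + inputs reproduce identical digests.
#'
#' @param config list as produced by [default_pipeline_config()] (or read
#'   from JSON); unknown entries are ignored.
#' @param quiet suppress progress messages.
#' @return The run report, invisibly (also written as JSON).
#' @export
run_pipeline <- function(config = default_pipeline_config(), quiet = FALSE) {
  cfg <- utils::modifyList(default_pipeline_config(), config)
  dir.create(cfg$out_dir, recursive = TRUE, showWarnings = FALSE)
  done <- character(0)
  warnings_log <- character(0)
  counts <- list()
  manifest_path <- file.path(cfg$out_dir, "MANIFEST")
  note_warning <- function(stage, msg) {
    warnings_log <<- c(warnings_log, sprintf("[%s] %s", stage, msg))
  }
  run_stage <- function(name, body) {
    pipeline_log(quiet, name, "start")
    withCallingHandlers(
      tryCatch(body(), error = function(e) {
        writeLines(done, manifest_path)
        stopf("stage `%s` failed: %s", name, conditionMessage(e))
      }),
      warning = function(w) {
        note_warning(name, conditionMessage(w))
        invokeRestart("muffleWarning")
      })
    done <<- c(done, name)
    writeLines(done, manifest_path)
    pipeline_log(quiet, name, "done")
  }
  on <- function(stage) isTRUE(cfg$stages[[stage]])

  cells <- samples <- cohort <- NULL

  if (on("simulate")) {
    run_stage("simulate", function() {
      sim <- cfg$simulate
      sc <- simulation_config(
        n_samples = sim$n_samples, n_cells_range = unlist(sim$n_cells_range),
        normal_fraction = sim$normal_fraction %||% 0,
        qc_violation_rate = sim$qc_violation_rate %||% 0.02,
        n_genes = sim$n_genes %||% 200,
        n_markers_per_subtype = sim$n_markers_per_subtype %||% 3,
        marker_effect = sim$marker_effect %||% 2,
        hazard_ratio = cfg$survival$hazard_ratio %||% 3,
        seed = derive_seed(cfg$seed, "simulate"))
      cohort <<- simulate_cohort(sc)
      cells <<- cohort$cells
      samples <<- cohort$samples
      write_cohort(cohort, cfg$out_dir)
      counts$samples <<- nrow(samples)
      counts$cells_in <<- nrow(cells)
    })
  } else {
    run_stage("ingest", function() {
      if (is.null(cfg$inputs$cells) || is.null(cfg$inputs$samples))
        stopf("stages$simulate is off and inputs$cells/samples are not set")
      for (p in c(cfg$inputs$cells, cfg$inputs$samples))
        if (!file.exists(p)) stopf("input path does not exist: %s", p)
      cells <<- utils::read.delim(cfg$inputs$cells, stringsAsFactors = FALSE)
      samples <<- utils::read.delim(cfg$inputs$samples,
                                    stringsAsFactors = FALSE)
      counts$samples <<- nrow(samples)
      counts$cells_in <<- nrow(cells)
    })
  }

  if (on("qc")) {
    run_stage("qc", function() {
      thr <- qc_thresholds(cfg$qc$min_genes, cfg$qc$mad_multiplier,
                           cfg$qc$max_mito, cfg$qc$mad_scale)
      qcr <- apply_qc(cells, thr)
      write_qc_report(qcr, cfg$out_dir)
      cells <<- qc_pass_cells(qcr)
      counts$cells_removed <<- qcr$n_removed
      counts$cells_kept <<- qcr$n_kept
    })
  } else {
    note_warning("qc", "stage disabled; downstream consumes raw cells")
  }

  comp <- scaled <- model <- NULL
  if (on("composition")) {
    run_stage("composition", function() {
      comp <<- build_composition(cells, level = "subtype",
                                 denominator = cfg$ecotype$denominator)
      utils::write.table(
        data.frame(sample_id = rownames(comp), unclass(comp),
                   check.names = FALSE),
        file.path(cfg$out_dir, "composition.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      scaled <<- scale_composition(comp)
      utils::write.table(
        data.frame(sample_id = rownames(scaled), unclass(scaled),
                   check.names = FALSE),
        file.path(cfg$out_dir, "composition_scaled.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
    })
  }

  if (on("ecotype")) {
    run_stage("ecotype", function() {
      if (is.null(scaled)) stopf("composition stage must run before ecotype")
      model <<- infer_ecotypes(scaled, k = cfg$ecotype$k)
      assign_df <- data.frame(sample_id = names(model$assignments),
                              ecotype = as.character(model$assignments))
      if ("lineage" %in% names(cells)) {
        lin_comp <- build_composition(cells, level = "lineage")
        ann <- annotate_ecotypes(model, lin_comp)
        assign_df$dominant_lineage <- unname(ann[assign_df$ecotype])
      }
      utils::write.table(assign_df,
                         file.path(cfg$out_dir, "ecotype_assignments.tsv"),
                         sep = "\t", quote = FALSE, row.names = FALSE)
      export_dendrogram(model, file.path(cfg$out_dir, "dendrogram.nwk"))
      counts$ecotypes <<- model$k
    })
  }

  if (on("enrichment")) {
    run_stage("enrichment", function() {
      if (is.null(model)) stopf("ecotype stage must run before enrichment")
      dist <- ecotype_group_distribution(model, samples,
                                         by = cfg$enrichment$by)
      res <- pearson_residuals(dist$counts)
      write_tab <- function(m, name) utils::write.table(
        data.frame(ecotype = rownames(m), m, check.names = FALSE),
        file.path(cfg$out_dir, name), sep = "\t", quote = FALSE,
        row.names = FALSE)
      write_tab(dist$counts, "ecotype_group_counts.tsv")
      write_tab(dist$ecotype_pct, "ecotype_group_pct.tsv")
      write_tab(res$residuals, "ecotype_group_residuals.tsv")
    })
  }

  scores <- NULL
  if (on("scoring")) {
    run_stage("scoring", function() {
      if (is.null(cohort))
        stopf("scoring stage requires the simulate stage (expression model)")
      expr <- simulate_expression(cohort, cohort$config,
                                  max_cells = cfg$scoring$max_cells %||% 4000)
      marker_map <- attr(expr, "marker_map")
      # pseudobulk per sample, then library-size log-normalisation
      sid <- cells$sample_id[match(colnames(expr), cells$cell_id)]
      keep <- !is.na(sid)
      bulk <- t(rowsum(t(expr[, keep, drop = FALSE]), sid[keep]))
      bulk_norm <- log_normalize(bulk, 1e4)
      target <- cfg$scoring$signature_subtype %||% names(marker_map)[1L]
      sig <- gene_signature(paste0(target, "_markers"), marker_map[[target]],
                            source = "marker_derived")
      scores <<- if (identical(cfg$scoring$method, "module")) {
        s <- module_score(bulk_norm, sig,
                          seed = derive_seed(cfg$seed, "module"))
        matrix(s, ncol = 1, dimnames = list(names(s), sig$name))
      } else {
        ssgsea_score(bulk_norm, sig, alpha = cfg$scoring$alpha %||% 0.25,
                     normalize = cfg$scoring$normalize %||% TRUE)
      }
      utils::write.table(
        data.frame(sample_id = rownames(scores), scores, check.names = FALSE),
        file.path(cfg$out_dir, "signature_scores.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      counts$scored_samples <<- nrow(scores)
    })
  }

  if (on("survival")) {
    run_stage("survival", function() {
      if (is.null(scores)) stopf("survival stage requires scoring")
      sv <- cfg$survival
      score <- stats::setNames(scores[, 1L], rownames(scores))
      cut_true <- sv$cutoff %||% stats::median(score)
      surv <- simulate_survival(score, cutoff = cut_true,
                                hazard_ratio = sv$hazard_ratio,
                                censor_rate = sv$censor_rate,
                                seed = derive_seed(cfg$seed, "survival"))
      utils::write.csv(surv, file.path(cfg$out_dir, "survival.csv"),
                       row.names = FALSE, quote = FALSE)
      cp <- optimal_cutpoint(surv$time, surv$event, surv$score,
                             minprop = sv$minprop)
      grp <- surv$score > cp$cutpoint
      lr <- logrank_test(surv$time, surv$event, grp)
      km_high <- km_estimate(surv$time[grp], surv$event[grp])
      km_low <- km_estimate(surv$time[!grp], surv$event[!grp])
      utils::write.table(
        rbind(cbind(group = "high", km_high), cbind(group = "low", km_low)),
        file.path(cfg$out_dir, "km_curves.tsv"),
        sep = "\t", quote = FALSE, row.names = FALSE)
      jsonlite::write_json(list(
        cutpoint = cp$cutpoint, statistic = cp$statistic,
        cutpoint_p = cp$p_value, logrank_chisq = lr$statistic,
        logrank_p = lr$p_value, n_high = cp$n_high, n_low = cp$n_low
      ), file.path(cfg$out_dir, "survival_summary.json"),
      auto_unbox = TRUE, digits = NA, pretty = TRUE)
    })
  }

  files <- setdiff(list.files(cfg$out_dir, recursive = TRUE),
                   c("run_report.json"))
  digests <- as.list(tools::md5sum(file.path(cfg$out_dir, files)))
  names(digests) <- files
  report <- list(config = cfg, completed_stages = done, counts = counts,
                 warnings = warnings_log, digests = digests)
  jsonlite::write_json(report, file.path(cfg$out_dir, "run_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE,
                       null = "null")
  invisible(report)
}
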