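# Cell-level quality control: fixed minimum gene count, per-sample robust
# lower thresholds (median - k * MAD) on UMIs / genes / housekeeping genes,
# and a mitochondrial-fraction ceiling.

#' Robust lower threshold: median minus a multiple of the MAD
#'
#' Computes `median(x) - multiplier * mad_scale * median(|x - median(x)|)`,
#' the per-sample lower bound used for QC metrics. `mad_scale` is the MAD
#' consistency constant; the default 1.4826 makes the MAD a consistent
#' estimator of the standard deviation under normality (the R `mad()`
#' convention), and can be set to 1 for the raw MAD.
#'
#' @param values numeric vector (at least one value).
#' @param multiplier nonnegative multiplier for the MAD (default 3).
#' @param mad_scale MAD consistency constant (default 1.4826).
#' @return The threshold, a single number.
#' @export
#' @examples
#' robust_lower_threshold(c(500, 510, 520, 530, 540, 100))  # 448.28
robust_lower_threshold <- function(values, multiplier = 3, mad_scale = 1.4826) {
  if (length(values) < 1L || !is.numeric(values))
    stopf("`values` must be a nonempty numeric vector")
  if (anyNA(values)) stopf("`values` must not contain NA")
  assert_scalar_number(multiplier, "multiplier", lower = 0)
  assert_scalar_number(mad_scale, "mad_scale", lower = 0, strict_lower = TRUE)
  med <- stats::median(values)
  raw_mad <- stats::median(abs(values - med))
  med - multiplier * mad_scale * raw_mad
}

#' QC thresholds container
#'
#' @param min_genes minimum genes detected per cell (cells strictly below are
#'   removed); default 200.
#' @param mad_multiplier MAD multiplier for the per-sample lower thresholds;
#'   default 3.
#' @param max_mito maximum mitochondrial transcript fraction (cells strictly
#'   above are removed); default 0.20.
#' @param mad_scale MAD consistency constant; default 1.4826.
#' @return An object of class `qc_thresholds`.
#' @export
qc_thresholds <- function(min_genes = 200, mad_multiplier = 3,
                          max_mito = 0.20, mad_scale = 1.4826) {
  assert_scalar_number(min_genes, "min_genes", lower = 0, strict_lower = TRUE)
  assert_scalar_number(mad_multiplier, "mad_multiplier", lower = 0,
                       strict_lower = TRUE)
  assert_scalar_number(max_mito, "max_mito", lower = 0, upper = 1,
                       strict_lower = TRUE)
  assert_scalar_number(mad_scale, "mad_scale", lower = 0, strict_lower = TRUE)
  structure(list(min_genes = min_genes, mad_multiplier = mad_multiplier,
                 max_mito = max_mito, mad_scale = mad_scale),
            class = "qc_thresholds")
}

qc_metric_cols <- c("umi_count", "gene_count", "housekeeping_count",
                    "mito_fraction")

#' Apply cell-level QC filters
#'
#' A cell is removed iff any rule triggers:
#' * `gene_count < min_genes`;
#' * `umi_count`, `gene_count` or `housekeeping_count` below its per-sample
#'   robust lower threshold (median minus `mad_multiplier` x MAD, computed on
#'   all cells of the sample *before* any removal);
#' * `mito_fraction > max_mito`;
#' * `is_doublet` is `TRUE`, when that column is present (doublet calls are
#'   honoured, never computed here).
#'
#' Because thresholds are computed once on the unfiltered table, QC is *not*
#' idempotent: re-applying it to an already filtered table recomputes
#' thresholds on the survivors and may remove further cells.
#'
#' @param cells data.frame with columns `cell_id`, `sample_id`, `umi_count`,
#'   `gene_count`, `housekeeping_count`, `mito_fraction` and optionally
#'   `is_doublet`.
#' @param thresholds a [qc_thresholds()] object.
#' @return A `qc_report`: list with `cells` (input plus `pass` flag and
#'   `fail_rules` string), `sample_thresholds` (per-sample lower bounds per
#'   metric), and `removed_per_rule` counts. A cell may fail several rules;
#'   `removed_per_rule` counts each triggered rule, `n_removed` counts cells.
#' @export
apply_qc <- function(cells, thresholds = qc_thresholds()) {
  stopifnot(inherits(thresholds, "qc_thresholds"))
  if (!is.data.frame(cells) || nrow(cells) == 0L)
    stopf("`cells` must be a nonempty data.frame")
  needed <- c("cell_id", "sample_id", qc_metric_cols)
  missing_cols <- setdiff(needed, names(cells))
  if (length(missing_cols))
    stopf("`cells` is missing column(s): %s", paste(missing_cols, collapse = ", "))
  for (m in qc_metric_cols) {
    bad <- which(!is.finite(cells[[m]]))
    if (length(bad))
      stopf("metric `%s` missing or non-finite for cell `%s`",
            m, cells$cell_id[bad[1L]])
  }
  if (any(cells$mito_fraction < 0 | cells$mito_fraction > 1))
    stopf("`mito_fraction` must lie in [0, 1]")

  samples <- unique(as.character(cells$sample_id))
  mad_metrics <- c("umi_count", "gene_count", "housekeeping_count")
  thr <- do.call(rbind, lapply(samples, function(s) {
    idx <- cells$sample_id == s
    vals <- vapply(mad_metrics, function(m)
      robust_lower_threshold(cells[[m]][idx], thresholds$mad_multiplier,
                             thresholds$mad_scale), numeric(1))
    data.frame(sample_id = s, metric = mad_metrics, threshold = unname(vals),
               stringsAsFactors = FALSE)
  }))

  thr_wide <- lapply(mad_metrics, function(m) {
    v <- thr$threshold[thr$metric == m]
    names(v) <- thr$sample_id[thr$metric == m]
    v
  })
  names(thr_wide) <- mad_metrics

  sid <- as.character(cells$sample_id)
  fails <- list(
    min_genes = cells$gene_count < thresholds$min_genes,
    low_umi = cells$umi_count < thr_wide$umi_count[sid],
    low_genes = cells$gene_count < thr_wide$gene_count[sid],
    low_housekeeping =
      cells$housekeeping_count < thr_wide$housekeeping_count[sid],
    max_mito = cells$mito_fraction > thresholds$max_mito
  )
  if ("is_doublet" %in% names(cells))
    fails$doublet <- cells$is_doublet %in% TRUE

  fail_mat <- do.call(cbind, fails)
  pass <- rowSums(fail_mat) == 0L
  fail_rules <- apply(fail_mat, 1L, function(r)
    paste(names(fails)[r], collapse = ";"))

  out <- cells
  out$pass <- pass
  out$fail_rules <- fail_rules
  structure(list(
    cells = out,
    sample_thresholds = thr,
    thresholds = thresholds,
    removed_per_rule = colSums(fail_mat),
    n_removed = sum(!pass),
    n_kept = sum(pass)
  ), class = "qc_report")
}

#' @export
print.qc_report <- function(x, ...) {
  cat(sprintf("QC report: %d cells in, %d removed, %d kept\n",
              nrow(x$cells), x$n_removed, x$n_kept))
  cat("removed per rule (a cell can trigger several):\n")
  print(x$removed_per_rule)
  invisible(x)
}

#' Keep only cells passing QC
#'
#' @param report a `qc_report` from [apply_qc()].
#' @return The input cell table restricted to passing cells, helper columns
#'   dropped.
#' @export
qc_pass_cells <- function(report) {
  stopifnot(inherits(report, "qc_report"))
  kept <- report$cells[report$cells$pass, , drop = FALSE]
  kept$pass <- NULL
  kept$fail_rules <- NULL
  rownames(kept) <- NULL
  kept
}

#' Write a QC report to disk
#'
#' Writes `qc_cells.tsv` (per-cell flags), `qc_thresholds.tsv` (per-sample
#' lower bounds) and `qc_summary.json`.
#'
#' @param report a `qc_report`.
#' @param dir output directory (created if needed).
#' @return Invisibly, the paths written.
#' @export
write_qc_report <- function(report, dir) {
  stopifnot(inherits(report, "qc_report"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  p1 <- file.path(dir, "qc_cells.tsv")
  p2 <- file.path(dir, "qc_thresholds.tsv")
  p3 <- file.path(dir, "qc_summary.json")
  utils::write.table(report$cells, p1, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  utils::write.table(report$sample_thresholds, p2, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  jsonlite::write_json(list(
    n_cells = nrow(report$cells), n_removed = report$n_removed,
    n_kept = report$n_kept,
    removed_per_rule = as.list(report$removed_per_rule),
    thresholds = unclass(report$thresholds)
  ), p3, auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(c(p1, p2, p3))
}
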