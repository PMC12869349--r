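# Enrichment / depletion statistics: Pearson residuals of contingency tables,
# rank-based group tests on per-sample fractions, one-vs-rest marker
# detection, and lineage-specificity refinement of marker signatures.

#' Pearson residuals of a contingency table
#'
#' For each cell of a group x cluster count table, computes
#' `R = (obs - exp) / sqrt(exp)` with `exp[i, j] = rowsum_i * colsum_j / N`.
#' Positive residuals indicate relative enrichment of a cluster in a group,
#' negative residuals depletion; the squared residuals sum to the Pearson
#' chi-square statistic of the table.
#'
#' @param counts nonnegative numeric matrix (at least 2 x 2 for a meaningful
#'   analysis), rows = groups, columns = cell clusters.
#' @return A `residual_matrix`: list with `residuals`, `expected`,
#'   `observed`, and `chisq` (sum of squared residuals).
#' @export
#' @examples
#' pearson_residuals(matrix(c(20, 0, 0, 20), 2, 2))$residuals
pearson_residuals <- function(counts) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("`counts` must be a numeric matrix")
  if (any(counts < 0)) stopf("`counts` must be nonnegative")
  total <- sum(counts)
  if (total <= 0) stopf("table total must be > 0")
  rs <- rowSums(counts)
  cs <- colSums(counts)
  if (any(rs == 0) || any(cs == 0))
    stopf("all-zero row or column marginal; drop empty groups/clusters first")
  expected <- outer(rs, cs) / total
  res <- (counts - expected) / sqrt(expected)
  structure(list(residuals = res, expected = expected, observed = counts,
                 chisq = sum(res^2)),
            class = "residual_matrix")
}

#' Rank-based test of per-sample fractions between groups
#'
#' Two groups: two-sided Wilcoxon rank-sum, exact when both groups have at
#' most 25 observations and there are no ties, normal approximation with tie
#' and continuity correction otherwise. Three or more groups: Kruskal-Wallis.
#'
#' @param fractions named list mapping group -> numeric vector of per-sample
#'   values (e.g. subset fractions).
#' @param exact_max largest per-group size for which the exact two-group
#'   distribution is used (default 25).
#' @return List with `p_value`, `method`, `direction` (two groups only: sign
#'   of `median(g1) - median(g2)`), and `statistic`.
#' @export
proportion_group_test <- function(fractions, exact_max = 25) {
  if (!is.list(fractions) || length(fractions) < 2L)
    stopf("`fractions` must be a list of >= 2 groups")
  sizes <- lengths(fractions)
  if (any(sizes == 0L))
    stopf("empty group: %s",
          paste(names(fractions)[sizes == 0L], collapse = ", "))
  if (length(fractions) == 2L) {
    x <- fractions[[1L]]; y <- fractions[[2L]]
    ties <- anyDuplicated(c(x, y)) > 0L
    use_exact <- !ties && length(x) <= exact_max && length(y) <= exact_max
    wt <- suppressWarnings(
      stats::wilcox.test(x, y, alternative = "two.sided", exact = use_exact,
                         correct = TRUE))
    list(p_value = wt$p.value,
         method = if (use_exact) "wilcoxon_exact" else "wilcoxon_normal_approx",
         direction = sign(stats::median(x) - stats::median(y)),
         statistic = unname(wt$statistic))
  } else {
    values <- unlist(fractions, use.names = FALSE)
    groups <- factor(rep(names(fractions) %||% seq_along(fractions), sizes))
    kt <- stats::kruskal.test(values, groups)
    list(p_value = kt$p.value, method = "kruskal_wallis",
         direction = NA_real_, statistic = unname(kt$statistic))
  }
}

#' One-vs-rest marker genes per cluster
#'
#' For each cluster, tests every gene against all remaining cells with a
#' two-sided rank-sum test (normal approximation with tie correction,
#' vectorised over genes), adjusts p-values by Benjamini-Hochberg within the
#' cluster, and computes the log2 fold change on de-logged means:
#' `log2((mean(expm1(in)) + 1) / (mean(expm1(out)) + 1))`. A gene is kept iff
#' `log2FC > lfc_min` and adjusted p `< alpha`.
#'
#' @param expr genes x cells matrix of log-normalised expression.
#' @param labels cluster label per cell (length = ncol(expr)).
#' @param lfc_min log2 fold-change threshold (default 0.4).
#' @param alpha adjusted-p threshold (default 0.05).
#' @param min_cells clusters with fewer cells are skipped with a warning
#'   (default 3).
#' @return A `marker_table` data.frame: `gene`, `cluster`, `log2fc`, `p`,
#'   `p_adj`, `kept`.
#' @export
de_markers <- function(expr, labels, lfc_min = 0.4, alpha = 0.05,
                       min_cells = 3L) {
  if (!is.matrix(expr) || !is.numeric(expr))
    stopf("`expr` must be a numeric genes x cells matrix")
  if (length(labels) != ncol(expr))
    stopf("`labels` must have one entry per cell")
  labels <- as.character(labels)
  clusters <- sort(unique(labels))
  if (length(clusters) < 2L) stopf("need >= 2 clusters")
  if (is.null(rownames(expr))) rownames(expr) <- paste0("g", seq_len(nrow(expr)))

  res <- lapply(clusters, function(cl) {
    inn <- labels == cl
    n1 <- sum(inn); n2 <- sum(!inn)
    if (n1 < min_cells) {
      warnf("cluster `%s` has %d < %d cells; skipped", cl, n1, min_cells)
      return(NULL)
    }
    p <- ranksum_p_rows(expr, inn)
    mean_in <- rowMeans(expm1(expr[, inn, drop = FALSE]))
    mean_out <- rowMeans(expm1(expr[, !inn, drop = FALSE]))
    lfc <- log2((mean_in + 1) / (mean_out + 1))
    p_adj <- stats::p.adjust(p, method = "BH")
    data.frame(gene = rownames(expr), cluster = cl, log2fc = lfc, p = p,
               p_adj = p_adj, kept = lfc > lfc_min & p_adj < alpha,
               row.names = NULL, stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, res)
  class(out) <- c("marker_table", class(out))
  out
}

# vectorised two-sided rank-sum p per gene row (normal approximation with tie
# and continuity correction, matching wilcox.test(correct = TRUE))
ranksum_p_rows <- function(expr, in_group) {
  n1 <- sum(in_group); n2 <- sum(!in_group); n <- n1 + n2
  rk <- t(apply(expr, 1L, rank))
  W <- rowSums(rk[, in_group, drop = FALSE]) - n1 * (n1 + 1) / 2
  mu <- n1 * n2 / 2
  # tie correction per gene
  tie_term <- apply(rk, 1L, function(r) {
    tt <- table(r)
    sum(tt^3 - tt)
  })
  sigma2 <- (n1 * n2 / 12) * ((n + 1) - tie_term / (n * (n - 1)))
  z <- W - mu
  z <- sign(z) * pmax(abs(z) - 0.5, 0) / sqrt(pmax(sigma2, .Machine$double.eps))
  p <- 2 * stats::pnorm(-abs(z))
  pmin(p, 1)
}

#' Refine a marker set by lineage specificity
#'
#' Drops marker genes that are also highly expressed in major cell lineages
#' other than the target: a gene is removed when its mean expression in any
#' non-target lineage exceeds `max_other_ratio` times its mean in the target
#' lineage.
#'
#' @param genes character vector of candidate marker genes (e.g. kept rows of
#'   a [de_markers()] table for one cluster).
#' @param lineage_means genes x lineages matrix of mean expression.
#' @param target name of the target lineage (column of `lineage_means`).
#' @param max_other_ratio specificity threshold (default 0.5).
#' @param name signature name for the returned object.
#' @return A [gene_signature()] (source `"marker_derived"`); empty with a
#'   warning if no gene survives.
#' @export
refine_signature <- function(genes, lineage_means, target,
                             max_other_ratio = 0.5, name = target) {
  if (!is.matrix(lineage_means)) stopf("`lineage_means` must be a matrix")
  if (!target %in% colnames(lineage_means))
    stopf("target lineage `%s` not a column of `lineage_means`", target)
  missing <- setdiff(genes, rownames(lineage_means))
  if (length(missing))
    stopf("marker gene(s) absent from `lineage_means`: %s",
          paste(missing, collapse = ", "))
  others <- setdiff(colnames(lineage_means), target)
  keep <- vapply(genes, function(g) {
    tgt <- lineage_means[g, target]
    if (tgt <= 0) return(FALSE)
    all(lineage_means[g, others] <= max_other_ratio * tgt)
  }, logical(1))
  kept <- genes[keep]
  if (!length(kept)) {
    warnf("no gene survived lineage-specificity refinement for `%s`", name)
    return(structure(list(name = name, genes = character(0),
                          source = "marker_derived"),
                     class = "gene_signature"))
  }
  gene_signature(name, kept, source = "marker_derived")
}
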