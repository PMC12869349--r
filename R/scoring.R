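# Normalisation and signature scoring: library-size log-normalisation,
# binned-control module scores per cell, and single-sample GSEA enrichment
# scores per bulk sample. GMT reader/writer for signature files.

#' Gene signature
#'
#' @param name signature label.
#' @param genes character vector of gene identifiers; duplicates removed,
#'   order preserved.
#' @param source `"curated"` or `"marker_derived"`.
#' @return A `gene_signature` object.
#' @export
gene_signature <- function(name, genes, source = c("curated", "marker_derived")) {
  source <- match.arg(source)
  genes <- unique(as.character(genes))
  if (!length(genes)) stopf("signature `%s` has no genes", name)
  structure(list(name = as.character(name), genes = genes, source = source),
            class = "gene_signature")
}

#' @export
print.gene_signature <- function(x, ...) {
  cat(sprintf("<gene_signature> %s (%s, %d genes): %s\n", x$name, x$source,
              length(x$genes), paste(utils::head(x$genes, 8), collapse = ", ")))
  invisible(x)
}

#' Read gene signatures from a GMT file
#'
#' Standard GMT: one set per line, tab-separated `name`, `description`,
#' genes. Empty lines and lines starting with `#` are skipped.
#'
#' @param path GMT file path.
#' @param source provenance tag applied to every signature read.
#' @return Named list of [gene_signature()] objects.
#' @export
read_gmt <- function(path, source = "curated") {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines)) & !startsWith(trimws(lines), "#")]
  sigs <- lapply(lines, function(ln) {
    parts <- strsplit(ln, "\t", fixed = TRUE)[[1L]]
    if (length(parts) < 3L)
      stopf("malformed GMT line (need name, description, >= 1 gene): %s",
            substr(ln, 1, 60))
    gene_signature(parts[1L], parts[-(1:2)], source = source)
  })
  names(sigs) <- vapply(sigs, `[[`, character(1), "name")
  sigs
}

#' Write gene signatures to a GMT file
#'
#' @param sigs list of [gene_signature()] objects.
#' @param path output path.
#' @return Invisibly, `path`.
#' @export
write_gmt <- function(sigs, path) {
  if (inherits(sigs, "gene_signature")) sigs <- list(sigs)
  lines <- vapply(sigs, function(s)
    paste(c(s$name, s$source, s$genes), collapse = "\t"), character(1))
  writeLines(lines, path)
  invisible(path)
}

#' Bundled signatures
#'
#' The signature sets shipped with the package: the 11-gene cytotoxicity and
#' 11-gene exhaustion/inhibitory T-cell programs, and the refined
#' monocyte/macrophage subpopulation sets (c2, c4, c5/c6, c8/c9) used for
#' bulk deconvolution.
#'
#' @return Named list of [gene_signature()] objects.
#' @export
bundled_signatures <- function() {
  read_gmt(system.file("extdata", "signatures.gmt", package = "tmeco"))
}

#' Library-size log-normalisation
#'
#' `value = ln(1 + count * scale_factor / unit_total)` per column (cell or
#' sample).
#'
#' @param counts genes x units matrix of nonnegative counts.
#' @param scale_factor library-size target (default 10000).
#' @return A matrix of the same shape, attribute `scale_factor` set.
#' @export
log_normalize <- function(counts, scale_factor = 1e4) {
  if (!is.matrix(counts) || !is.numeric(counts))
    stopf("`counts` must be a numeric genes x units matrix")
  if (any(counts < 0)) stopf("`counts` must be nonnegative")
  totals <- colSums(counts)
  zero <- which(totals == 0)
  if (length(zero)) {
    nm <- colnames(counts)[zero[1L]] %||% as.character(zero[1L])
    stopf("unit `%s` has all-zero counts", nm)
  }
  out <- log1p(sweep(counts, 2L, totals, "/") * scale_factor)
  attr(out, "scale_factor") <- scale_factor
  out
}

#' Binned-control module score per cell
#'
#' Genes are ranked by mean expression across units and split into `n_bins`
#' equal-frequency bins; for each signature gene, `n_ctrl` control genes are
#' drawn (without replacement) from its bin, and the per-unit score is the
#' mean expression of the signature genes minus the mean of the pooled
#' control genes. Gene matching is case-insensitive (identifiers are
#' uppercased on both sides).
#'
#' @param expr genes x units log-normalised expression matrix with row names.
#' @param sig a [gene_signature()] or character vector of genes.
#' @param n_bins number of expression bins (default 24).
#' @param n_ctrl controls drawn per signature gene (default 100, capped at
#'   bin size minus signature members).
#' @param seed integer seed for the control draw.
#' @return Numeric vector of scores, one per unit (named by column).
#' @export
module_score <- function(expr, sig, n_bins = 24, n_ctrl = 100, seed = 1L) {
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stopf("`expr` must be a matrix with gene row names")
  genes <- if (inherits(sig, "gene_signature")) sig$genes else as.character(sig)
  up <- toupper(rownames(expr))
  hit <- match(toupper(genes), up)
  if (all(is.na(hit)))
    stopf("no signature gene found in the expression matrix")
  if (anyNA(hit))
    warnf("dropping %d signature gene(s) absent from the matrix", sum(is.na(hit)))
  sig_idx <- hit[!is.na(hit)]

  avg <- rowMeans(expr)
  n_bins_eff <- max(1L, min(as.integer(n_bins), nrow(expr)))
  # equal-frequency bins on the rank of average expression; random jitter-free
  bin <- ceiling(rank(avg, ties.method = "first") / nrow(expr) * n_bins_eff)

  ctrl_idx <- with_seed(seed, {
    unique(unlist(lapply(sig_idx, function(i) {
      pool <- setdiff(which(bin == bin[i]), sig_idx)
      if (!length(pool)) return(integer(0))
      pool[sample.int(length(pool), min(n_ctrl, length(pool)))]
    })))
  })
  sig_mean <- colMeans(expr[sig_idx, , drop = FALSE])
  ctrl_mean <- if (length(ctrl_idx))
    colMeans(expr[ctrl_idx, , drop = FALSE]) else sig_mean
  sig_mean - ctrl_mean
}

#' Single-sample GSEA enrichment scores
#'
#' Per sample, genes are ranked by expression (ties by average rank); the
#' enrichment score of a set is the sum, over the ranked gene list, of the
#' difference between the weighted in-set empirical CDF (weights
#' `rank^alpha`) and the unweighted out-of-set empirical CDF. With
#' `normalize = TRUE` the whole score matrix is divided by its range
#' (max - min), the conventional single-sample GSEA normalisation. Scores
#' depend on ranks only, so they are invariant to strictly increasing
#' per-sample transforms of expression. Gene matching is case-insensitive.
#'
#' @param expr genes x samples numeric matrix with row names.
#' @param sigs a [gene_signature()], a character vector, or a (named) list of
#'   either.
#' @param alpha rank-weighting exponent (default 0.25).
#' @param normalize divide all scores by the overall score range (default
#'   `TRUE`).
#' @return samples x signatures numeric matrix of enrichment scores.
#' @export
ssgsea_score <- function(expr, sigs, alpha = 0.25, normalize = TRUE) {
  if (!is.matrix(expr) || is.null(rownames(expr)))
    stopf("`expr` must be a matrix with gene row names")
  if (nrow(expr) < 2L) stopf("need at least 2 genes")
  if (inherits(sigs, "gene_signature") || is.character(sigs)) sigs <- list(sigs)
  sig_genes <- lapply(sigs, function(s)
    if (inherits(s, "gene_signature")) s$genes else as.character(s))
  nm <- names(sigs)
  if (is.null(nm) || any(!nzchar(nm)))
    nm <- vapply(seq_along(sigs), function(i) {
      s <- sigs[[i]]
      if (inherits(s, "gene_signature")) s$name else paste0("set", i)
    }, character(1))

  up <- toupper(rownames(expr))
  n <- nrow(expr)
  idx_sets <- lapply(sig_genes, function(g) {
    i <- unique(match(toupper(g), up))
    i <- i[!is.na(i)]
    if (!length(i)) stopf("a signature shares no genes with the matrix")
    if (length(i) == n) stopf("signature covers every gene (empty complement)")
    i
  })

  scores <- matrix(0, ncol(expr), length(idx_sets),
                   dimnames = list(colnames(expr), nm))
  for (j in seq_len(ncol(expr))) {
    x <- expr[, j]
    r <- rank(x, ties.method = "average")
    ord <- order(r, decreasing = TRUE)       # walk from highest expression
    for (s in seq_along(idx_sets)) {
      inset <- logical(n)
      inset[idx_sets[[s]]] <- TRUE
      ins <- inset[ord]
      w <- abs(r[ord])^alpha
      w[!ins] <- 0
      cdf_in <- cumsum(w) / sum(w)
      cdf_out <- cumsum(!ins) / (n - sum(ins))
      scores[j, s] <- sum(cdf_in - cdf_out)
    }
  }
  if (normalize) {
    rng <- max(scores) - min(scores)
    if (rng > 0) scores <- scores / rng
  }
  scores
}
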