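# Sample-by-subtype composition matrices, per-subtype standardisation, and
# ecotype inference by Ward (ward.D2) hierarchical clustering of samples.

#' Build a sample-by-subtype composition matrix
#'
#' Tallies annotated cells into per-sample fractions. With
#' `denominator = "all_cells"` fractions are over every cell of the sample;
#' with `"parent_lineage"` each subtype's fraction is taken within its parent
#' lineage (the convention for subset-level dot plots), in which case `cells`
#' must carry a `lineage` column and rows sum to 1 *within each lineage
#' block*.
#'
#' @param cells data.frame with `sample_id` and a label column given by
#'   `level` (default `"subtype"`); `lineage` required for the
#'   `parent_lineage` denominator.
#' @param level name of the label column to tally (`"subtype"` or
#'   `"lineage"`).
#' @param denominator `"all_cells"` or `"parent_lineage"`.
#' @param subtypes optional character vector fixing the column set/order
#'   (labels absent from `cells` get zero columns).
#' @return A `composition_matrix`: numeric samples x subtypes matrix with
#'   attributes `denominator` and (if relevant) `lineage_of`.
#' @export
build_composition <- function(cells, level = "subtype",
                              denominator = c("all_cells", "parent_lineage"),
                              subtypes = NULL) {
  denominator <- match.arg(denominator)
  if (!is.data.frame(cells) || nrow(cells) == 0L)
    stopf("`cells` must be a nonempty data.frame")
  if (!level %in% names(cells))
    stopf("unknown level `%s`: no such column in `cells`", level)
  if (!"sample_id" %in% names(cells))
    stopf("`cells` must have a `sample_id` column")
  if (denominator == "parent_lineage" && !"lineage" %in% names(cells))
    stopf("denominator `parent_lineage` requires a `lineage` column")

  lab <- as.character(cells[[level]])
  sid <- as.character(cells$sample_id)
  all_labels <- subtypes %||% sort(unique(lab))
  unknown <- setdiff(lab, all_labels)
  if (length(unknown))
    stopf("labels not in `subtypes`: %s", paste(unknown, collapse = ", "))

  counts <- table(factor(sid, levels = sort(unique(sid))),
                  factor(lab, levels = all_labels))
  counts <- matrix(as.numeric(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))

  if (denominator == "all_cells") {
    denom <- rowSums(counts)
    keep <- denom > 0
    if (any(!keep)) {
      warnf("dropping %d sample(s) with zero cells", sum(!keep))
      counts <- counts[keep, , drop = FALSE]
      denom <- denom[keep]
    }
    frac <- counts / denom
    lineage_of <- NULL
  } else {
    # within-lineage fractions: denominator = cells of the subtype's parent
    # lineage in that sample
    lin_map <- tapply(as.character(cells$lineage), lab, function(v) {
      u <- unique(v)
      if (length(u) > 1L)
        stopf("label `%s` maps to several lineages: %s", v[1L],
              paste(u, collapse = ", "))
      u
    })
    lineage_of <- as.character(lin_map[all_labels])
    names(lineage_of) <- all_labels
    lin_counts <- table(factor(sid, levels = rownames(counts)),
                        factor(as.character(cells$lineage)))
    lin_counts <- matrix(as.numeric(lin_counts), nrow = nrow(lin_counts),
                         dimnames = dimnames(lin_counts))
    denom <- lin_counts[, lineage_of, drop = FALSE]
    frac <- counts
    frac[denom > 0] <- counts[denom > 0] / denom[denom > 0]
    frac[denom == 0] <- 0
  }

  structure(frac, class = c("composition_matrix", class(frac)),
            denominator = denominator, lineage_of = lineage_of)
}

#' Standardise a composition matrix across cell types
#'
#' Centers and scales each subtype column across samples (sample standard
#' deviation, n - 1 denominator), the relative-abundance transform applied
#' before ecotype clustering. Constant columns map to all zeros.
#'
#' @param comp a `composition_matrix` (or any samples x subtypes numeric
#'   matrix) with at least 2 samples.
#' @return A `scaled_composition` matrix with attributes `center` and
#'   `spread` holding the per-column statistics used.
#' @export
scale_composition <- function(comp) {
  m <- unclass(comp)
  attr(m, "denominator") <- NULL
  attr(m, "lineage_of") <- NULL
  if (!is.matrix(m) || !is.numeric(m)) stopf("`comp` must be a numeric matrix")
  if (nrow(m) < 2L) stopf("scaling needs at least 2 samples")
  ctr <- colMeans(m)
  spr <- apply(m, 2L, stats::sd)
  out <- sweep(m, 2L, ctr, "-")
  nz <- spr > 0
  out[, nz] <- sweep(out[, nz, drop = FALSE], 2L, spr[nz], "/")
  out[, !nz] <- 0
  structure(out, class = c("scaled_composition", "matrix", "array"),
            center = ctr, spread = spr)
}

#' Infer ecotypes by Ward hierarchical clustering
#'
#' Agglomerates samples on Euclidean distances between scaled composition
#' rows under Ward's minimum-variance criterion (the `ward.D2` convention:
#' each merge minimises the increase in total within-cluster sum of squares),
#' then cuts the tree into `k` groups. Ecotype labels `E1..Ek` are assigned
#' in decreasing order of group size (ties by first occurrence).
#'
#' @param scaled a `scaled_composition` (or numeric samples x features
#'   matrix) with row names.
#' @param k number of ecotypes, `1 <= k <=` number of samples; default 5.
#' @param silhouette_scan if `TRUE`, additionally report the mean silhouette
#'   width for each k in 2..10 (informational; never changes `k`).
#' @return An `ecotype_model`: list with `hclust` (the merge tree), `k`,
#'   `assignments` (named factor sample -> `E1..Ek`), `ordering` (dendrogram
#'   leaf order), `silhouette` (mean silhouette width per candidate k, if
#'   computed).
#' @export
infer_ecotypes <- function(scaled, k = 5, silhouette_scan = FALSE) {
  m <- unclass(scaled)
  if (!is.matrix(m) || !is.numeric(m)) stopf("`scaled` must be a numeric matrix")
  n <- nrow(m)
  if (is.null(rownames(m))) rownames(m) <- paste0("S", seq_len(n))
  if (k < 1 || k > n) stopf("`k` must be in [1, %d], got %g", n, k)
  d <- stats::dist(m)
  hc <- stats::hclust(d, method = "ward.D2")
  cut <- stats::cutree(hc, k = k)
  sizes <- table(cut)
  # relabel by size descending, stable on ties
  ord <- order(-as.numeric(sizes), as.integer(names(sizes)))
  relabel <- stats::setNames(paste0("E", seq_len(k)), names(sizes)[ord])
  assignments <- factor(relabel[as.character(cut)],
                        levels = paste0("E", seq_len(k)))
  names(assignments) <- rownames(m)
  sil <- NULL
  if (isTRUE(silhouette_scan) && n >= 4L) {
    ks <- 2:min(10L, n - 1L)
    dm <- as.matrix(d)
    sil <- vapply(ks, function(kk)
      mean_silhouette(dm, stats::cutree(hc, k = kk)), numeric(1))
    names(sil) <- ks
  }
  structure(list(hclust = hc, k = k, assignments = assignments,
                 ordering = hc$order, silhouette = sil),
            class = "ecotype_model")
}

# mean silhouette width for a labeling, from a distance matrix
mean_silhouette <- function(dm, labels) {
  n <- nrow(dm)
  labs <- unique(labels)
  if (length(labs) < 2L) return(NA_real_)
  s <- vapply(seq_len(n), function(i) {
    own <- labels == labels[i]
    own[i] <- FALSE
    a <- if (any(own)) mean(dm[i, own]) else 0
    b <- min(vapply(setdiff(labs, labels[i]), function(l)
      mean(dm[i, labels == l]), numeric(1)))
    if (max(a, b) == 0) 0 else (b - a) / max(a, b)
  }, numeric(1))
  mean(s)
}

#' @export
print.ecotype_model <- function(x, ...) {
  cat(sprintf("ecotype model: %d samples cut into k = %d ecotypes\n",
              length(x$assignments), x$k))
  print(table(x$assignments))
  invisible(x)
}

#' Cross-tabulate ecotypes against a clinical grouping
#'
#' Counts and row percentages of each group within each ecotype (and the
#' transposed view), mirroring ecotype-by-stage / ecotype-by-tumour-type
#' summaries.
#'
#' @param model an `ecotype_model`.
#' @param samples data.frame of sample metadata with `sample_id` and the
#'   grouping column(s).
#' @param by grouping: `"stage"`, `"cancer_type"` or `"cancer_type_stage"`
#'   (interaction).
#' @return An `ecotype_distribution`: list with `counts` (ecotype x group),
#'   `ecotype_pct` (rows sum to 100: composition of each ecotype), and
#'   `group_pct` (columns of `counts` as percentages: ecotype mix of each
#'   group).
#' @export
ecotype_group_distribution <- function(model, samples,
                                       by = c("stage", "cancer_type",
                                              "cancer_type_stage")) {
  by <- match.arg(by)
  stopifnot(inherits(model, "ecotype_model"))
  if (!"sample_id" %in% names(samples))
    stopf("`samples` must have a `sample_id` column")
  ids <- names(model$assignments)
  missing <- setdiff(ids, as.character(samples$sample_id))
  if (length(missing))
    stopf("metadata missing for sample(s): %s", paste(missing, collapse = ", "))
  meta <- samples[match(ids, as.character(samples$sample_id)), , drop = FALSE]
  grp <- switch(by,
    stage = as.character(meta$stage),
    cancer_type = as.character(meta$cancer_type),
    cancer_type_stage = paste(meta$cancer_type, meta$stage, sep = ":"))
  counts <- table(ecotype = model$assignments, group = grp)
  counts <- matrix(as.numeric(counts), nrow = nrow(counts),
                   dimnames = dimnames(counts))
  ecotype_pct <- 100 * counts / pmax(rowSums(counts), 1)
  ecotype_pct[rowSums(counts) == 0, ] <- 0
  group_pct <- t(100 * t(counts) / pmax(colSums(counts), 1))
  structure(list(counts = counts, ecotype_pct = ecotype_pct,
                 group_pct = group_pct, by = by),
            class = "ecotype_distribution")
}

#' Annotate ecotypes by dominant lineage
#'
#' Post-hoc naming rule: each ecotype is labelled by the lineage with the
#' highest mean composition among its samples (e.g. a T/NK-dominated group of
#' samples reads as the T-cell-dominant ecotype). Annotation only; the
#' clustering itself never sees lineage labels.
#'
#' @param model an `ecotype_model`.
#' @param lineage_comp samples x lineage `composition_matrix` (all-cells
#'   denominator, `level = "lineage"`).
#' @return Named character vector: ecotype -> dominant lineage.
#' @export
annotate_ecotypes <- function(model, lineage_comp) {
  stopifnot(inherits(model, "ecotype_model"))
  m <- unclass(lineage_comp)
  ids <- intersect(names(model$assignments), rownames(m))
  if (!length(ids)) stopf("no overlap between model samples and composition rows")
  vapply(levels(model$assignments), function(e) {
    rows <- ids[model$assignments[ids] == e]
    if (!length(rows)) return(NA_character_)
    colnames(m)[which.max(colMeans(m[rows, , drop = FALSE]))]
  }, character(1))
}

#' Export an ecotype dendrogram as Newick
#'
#' Merge heights become branch lengths (ultrametric tree, leaf depth =
#' height/2 on each side of a merge).
#'
#' @param model an `ecotype_model`.
#' @param file optional path; when given the tree is written there.
#' @return The Newick string, invisibly when `file` is given.
#' @export
export_dendrogram <- function(model, file = NULL) {
  stopifnot(inherits(model, "ecotype_model"))
  phy <- ape::as.phylo(model$hclust)
  txt <- ape::write.tree(phy)
  if (!is.null(file)) {
    writeLines(txt, file)
    return(invisible(txt))
  }
  txt
}
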