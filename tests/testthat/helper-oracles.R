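# Independent oracles used to cross-check the package implementations.
# Deliberately naive: each recomputes its quantity from first principles and
# shares no code with the functions it checks.

# total within-cluster sum of squares of a row set
.ess <- function(M) {
  ctr <- colMeans(M)
  sum(sweep(M, 2L, ctr)^2)
}

# Brute-force Ward agglomeration: at every step evaluate, for every cluster
# pair, the exact increase in total within-cluster SS of merging them, and
# merge the cheapest pair. Returns the partition (integer labels) for every
# k from n down to 1.
brute_ward_partitions <- function(X) {
  n <- nrow(X)
  clusters <- as.list(seq_len(n))
  ess_of <- rep(0, n)   # SS of each current cluster (recomputed on merge)
  out <- vector("list", n)
  lab <- seq_len(n)
  out[[n]] <- lab
  while (length(clusters) > 1L) {
    best_cost <- Inf
    best <- NULL
    for (i in seq_len(length(clusters) - 1L)) {
      for (j in (i + 1L):length(clusters)) {
        union_ss <- .ess(X[c(clusters[[i]], clusters[[j]]), , drop = FALSE])
        cost <- union_ss - ess_of[i] - ess_of[j]
        if (cost < best_cost) {
          best_cost <- cost
          best <- c(i, j)
        }
      }
    }
    merged <- c(clusters[[best[1L]]], clusters[[best[2L]]])
    clusters <- clusters[-best]
    ess_of <- ess_of[-best]
    clusters[[length(clusters) + 1L]] <- merged
    ess_of[length(clusters)] <- .ess(X[merged, , drop = FALSE])
    k <- length(clusters)
    lab <- integer(n)
    for (ci in seq_along(clusters)) lab[clusters[[ci]]] <- ci
    out[[k]] <- lab
  }
  out
}

same_partition <- function(a, b) {
  isTRUE(all.equal(adjusted_rand_index(a, b), 1))
}

# Brute-force single-sample GSEA running sum for one sample and one set:
# walk genes from highest to lowest expression, accumulating the weighted
# in-set CDF minus the out-set CDF.
brute_ssgsea_one <- function(x, in_set, alpha = 0.25) {
  n <- length(x)
  r <- rank(x, ties.method = "average")
  ord <- order(r, decreasing = TRUE)
  denom_in <- sum(r[in_set]^alpha)
  denom_out <- n - sum(in_set)
  p_in <- 0
  p_out <- 0
  es <- 0
  for (i in ord) {
    if (in_set[i]) p_in <- p_in + r[[i]]^alpha / denom_in
    else p_out <- p_out + 1 / denom_out
    es <- es + (p_in - p_out)
  }
  unname(es)
}

# Exact two-sided rank-sum p by enumeration of all group assignments.
enumerate_ranksum_p <- function(x, y) {
  n1 <- length(x)
  pooled <- c(x, y)
  r <- rank(pooled)
  w_obs <- sum(r[seq_len(n1)]) - n1 * (n1 + 1) / 2
  combs <- utils::combn(length(pooled), n1)
  w_all <- apply(combs, 2L, function(i) sum(r[i]) - n1 * (n1 + 1) / 2)
  min(1, 2 * min(mean(w_all <= w_obs), mean(w_all >= w_obs)))
}

# naive tally oracle for composition fractions
tally_fraction <- function(cells, sample, subtype) {
  inn <- cells$sample_id == sample
  sum(inn & cells$subtype == subtype) / sum(inn)
}

# small deterministic QC fixture with nominal metrics
nominal_cells <- function(n, sample = "S1", genes = 500, umi = 2000,
                          hk = 30, mito = 0.05) {
  data.frame(cell_id = sprintf("%s_c%d", sample, seq_len(n)),
             sample_id = sample,
             umi_count = rep_len(umi, n), gene_count = rep_len(genes, n),
             housekeeping_count = rep_len(hk, n),
             mito_fraction = rep_len(mito, n), stringsAsFactors = FALSE)
}
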