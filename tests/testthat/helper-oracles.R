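# Independent oracles used across the suite. These deliberately avoid the
# package's own code paths: order-statistic tails via summed binomial
# coefficients, hypergeometric tails via exhaustive subset enumeration,
# ssGSEA via a direct per-position double loop, pruning via an explicit
# pairwise overlap matrix, and interval overlap via an all-pairs scan.

# P(j-th order statistic of k uniforms <= r) as a summed binomial tail:
# at least j of the k ranks fall at or below r.
oracle_order_stat_tail <- function(r, j, k) {
  sum(choose(k, j:k) * r^(j:k) * (1 - r)^(k - (j:k)))
}

oracle_rho <- function(ranks, alpha) {
  r <- sort(ranks)
  k <- length(r)
  vals <- c()
  for (j in seq_len(k)) {
    if (r[j] <= alpha) vals <- c(vals, oracle_order_stat_tail(r[j], j, k))
  }
  if (length(vals) == 0) 1 else min(vals)
}

# Exact permutation tail P(null rho <= observed rho) by enumerating every
# size-k subset of the pooled rank list. The tie tolerance keeps exact ties
# (the observed subset is itself enumerated) from falling on the wrong side
# of <= through last-bit differences between the summed-binomial form and
# the regularized incomplete beta.
oracle_perm_tail <- function(pooled_ranks, k, rho_obs, alpha) {
  combos <- utils::combn(length(pooled_ranks), k)
  null_rho <- apply(combos, 2, function(i) oracle_rho(pooled_ranks[i], alpha))
  mean(null_rho <= rho_obs + 1e-9)
}

# Upper-tail hypergeometric p by enumerating all candidate draws of size n.
oracle_hypergeom <- function(N, K, n, k_obs) {
  draws <- utils::combn(N, n)
  hits <- apply(draws, 2, function(d) sum(d <= K))
  mean(hits >= k_obs)
}

# ssGSEA enrichment score by a direct double loop: at every rank position,
# recompute both ECDFs from scratch.
oracle_ssgsea_es <- function(x, in_set, weight) {
  n <- length(x)
  ord <- order(-x, names(x))
  rank_value <- n:1
  w <- rank_value^weight
  inset <- names(x)[ord] %in% in_set
  total_in <- sum(w[inset])
  n_out <- sum(!inset)
  es <- 0
  for (i in seq_len(n)) {
    cdf_in <- sum(w[seq_len(i)][inset[seq_len(i)]]) / total_in
    cdf_out <- sum(!inset[seq_len(i)]) / n_out
    es <- es + cdf_in - cdf_out
  }
  es
}

# Redundancy pruning by explicit pairwise overlap fractions.
oracle_prune <- function(rows, members, threshold, retained_only) {
  ord <- order(rows$fdr, rows$p, rows$set_id)
  rows <- rows[ord, , drop = FALSE]
  members <- members[rows$set_id]
  n <- nrow(rows)
  frac <- matrix(0, n, n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    a <- members[[i]]
    if (length(a) > 0)
      frac[i, j] <- length(intersect(a, members[[j]])) / length(a)
  }
  retained <- logical(n)
  for (i in seq_len(n)) {
    earlier <- seq_len(i - 1L)
    if (retained_only) earlier <- earlier[retained[earlier]]
    retained[i] <- !any(frac[i, earlier] > threshold)
  }
  data.frame(set_id = rows$set_id, retained = retained,
             stringsAsFactors = FALSE)
}

# All-pairs closed-interval overlap of peaks with strand-aware promoter
# windows.
oracle_promoter_calls <- function(peaks, tss, upstream, downstream) {
  called <- character(0)
  for (g in seq_len(nrow(tss))) {
    if (tss$strand[g] == "+") {
      s <- tss$pos[g] - upstream; e <- tss$pos[g] + downstream
    } else {
      s <- tss$pos[g] - downstream; e <- tss$pos[g] + upstream
    }
    for (p in seq_len(nrow(peaks))) {
      if (peaks$chrom[p] == tss$chrom[g] &&
          peaks$start[p] <= e && peaks$end[p] >= s) {
        called <- c(called, tss$gene_symbol[g])
        break
      }
    }
  }
  sort(unique(called))
}

# Small ranked score table built from an explicit gene order.
ranked_table <- function(genes, mean_lfc = NULL) {
  n <- length(genes)
  df <- data.frame(gene_symbol = genes,
                   target_id = genes,
                   n_guides = 3L,
                   mean_lfc = mean_lfc %||% rev(seq_len(n)) / n,
                   rho = seq_len(n) / (n + 1),
                   perm_p = seq_len(n) / (n + 1),
                   gene_rank = seq_len(n),
                   stringsAsFactors = FALSE)
  df
}

`%||%` <- function(a, b) if (is.null(a)) b else a
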