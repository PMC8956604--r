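# Guide-level enrichment and gene-level robust rank aggregation (RRA).
#
# The gene score follows the alpha-RRA idea used for pooled screens: each
# guide receives a normalized rank of its -log2 fold change; for a gene with
# sorted guide ranks r(1) <= ... <= r(k), guides beyond the aggregation
# percentile alpha are skipped and
#   rho = min over retained j of P(Beta(j, k - j + 1) <= r(j)),
# the tail probability that the j-th order statistic of k uniforms falls at
# or below r(j). Significance comes from a permutation null that redraws
# guide ranks from the pooled rank list per gene size class.

#' Normalize a guide count matrix
#'
#' `total_count` rescales each sample to the mean library size.
#' `median_ratio` uses median-of-ratios size factors (each sample divided by
#' the median of count / geometric row mean over guides with all-positive
#' rows), which is robust to the composition shifts a strong selection
#' induces. Either way the relative ordering of guides within a sample is
#' preserved.
#'
#' @param counts Count data.frame (`guide_id`, `target_id`, `gene_symbol`
#'   plus one numeric column per sample) or an `sgrna_screen`.
#' @param method `"median_ratio"` (default) or `"total_count"`.
#' @return The data.frame with sample columns replaced by normalized
#'   real-valued counts; multiplicative per-sample factors in attribute
#'   `norm_factors`.
#' @export
normalize_counts <- function(counts, method = c("median_ratio", "total_count")) {
  method <- match.arg(method)
  if (inherits(counts, "sgrna_screen")) counts <- counts$counts
  sc <- sample_columns(counts)
  abort_if(length(sc) == 0, "no sample columns found")
  m <- as.matrix(counts[, sc, drop = FALSE])
  abort_if(any(m < 0), "counts must be non-negative")
  if (method == "total_count") {
    libsize <- colSums(m)
    abort_if(any(libsize == 0), "a sample has zero total count")
    factors <- mean(libsize) / libsize
  } else {
    pos <- rowSums(m > 0) == ncol(m)
    if (!any(pos))
      stop("median_ratio normalization needs at least one guide with ",
           "positive counts in every sample; use method = \"total_count\"",
           call. = FALSE)
    geo <- exp(rowMeans(log(m[pos, , drop = FALSE])))
    size <- apply(m[pos, , drop = FALSE] / geo, 2, median)
    abort_if(any(size == 0), "degenerate size factor of zero")
    factors <- 1 / size
  }
  counts[, sc] <- sweep(m, 2, factors, `*`)
  attr(counts, "norm_factors") <- setNames(factors, sc)
  counts
}

#' Guide-level log2 fold change and normalized ranks
#'
#' Computes `lfc = log2((selected + pc) / (control + pc))` per guide and the
#' normalized rank of each guide by descending LFC (rank 1/N = most
#' enriched), with midranks for ties, so ranks lie in (0, 1].
#'
#' @param normalized Normalized count data.frame (see [normalize_counts()]).
#' @param selected_sample,control_sample Column names of the selected arm and
#'   its paired no-T-cell control.
#' @param pseudocount Positive stabilizer added to both arms (default 1).
#' @return data.frame with `guide_id`, `target_id`, `gene_symbol`,
#'   `control_norm`, `selected_norm`, `lfc`, `normalized_rank`.
#' @export
compute_sgrna_lfc <- function(normalized, selected_sample, control_sample,
                              pseudocount = 1) {
  abort_if(pseudocount <= 0, "pseudocount must be > 0")
  for (s in c(selected_sample, control_sample))
    abort_if(!s %in% names(normalized), "unknown sample id: ", s)
  sel <- normalized[[selected_sample]]
  ctl <- normalized[[control_sample]]
  lfc <- log2((sel + pseudocount) / (ctl + pseudocount))
  out <- normalized[, intersect(c("guide_id", "target_id", "gene_symbol"),
                                names(normalized)), drop = FALSE]
  out$control_norm <- ctl
  out$selected_norm <- sel
  out$lfc <- lfc
  out$normalized_rank <- rank(-lfc, ties.method = "average") / length(lfc)
  out
}

# rho for one gene: sorted normalized ranks r, aggregation percentile alpha.
rho_from_ranks <- function(r, alpha) {
  r <- sort(r)
  k <- length(r)
  j <- seq_len(k)
  keep <- r <= alpha
  if (!any(keep)) return(1)
  min(pbeta(r[keep], j[keep], k - j[keep] + 1))
}

# Vectorized rho for an m x k matrix of rank draws (rows = permutations).
rho_matrix <- function(R, alpha) {
  m <- nrow(R); k <- ncol(R)
  R <- matrix(R[order(row(R), R)], nrow = m, byrow = TRUE)  # row-wise sort
  best <- rep(Inf, m)
  for (j in seq_len(k)) {
    p <- pbeta(R[, j], j, k - j + 1)
    p[R[, j] > alpha] <- Inf
    best <- pmin(best, p)
  }
  best[!is.finite(best)] <- 1
  best
}

#' Gene-level robust rank aggregation score
#'
#' Aggregates guide normalized ranks per target with the alpha-RRA order
#' statistic, attaches a permutation p-value, and collapses targets to gene
#' symbols by their best-scoring target.
#'
#' The permutation null redraws, for every gene size class k, `n_permutations`
#' sets of k ranks (without replacement) from the pooled observed rank list;
#' `perm_p = (1 + #\{null rho <= observed rho\}) / (1 + n_permutations)`, so p
#' is never exactly 0. `n_permutations = 0` skips the permutation stage
#' (`perm_p = NA`), which is useful when only mean LFCs are needed.
#'
#' @param enrichment Guide table from [compute_sgrna_lfc()].
#' @param alpha Aggregation percentile in (0, 1]: guides with normalized rank
#'   above `alpha` are skipped (default 0.05).
#' @param n_permutations Permutations per gene size class (default 10000; a
#'   warning is logged below 100).
#' @param seed Integer seed for the permutation draws.
#' @param collapse Collapse targets to gene symbols by minimum
#'   (`perm_p`, `rho`) (default TRUE). With one target per gene this is the
#'   identity.
#' @return data.frame with `gene_symbol`, `target_id`, `n_guides`,
#'   `mean_lfc`, `rho`, `perm_p`.
#' @export
rra_gene_score <- function(enrichment, alpha = 0.05, n_permutations = 10000,
                           seed = 1L, collapse = TRUE) {
  abort_if(!is.numeric(alpha) || alpha <= 0 || alpha > 1,
           "alpha must lie in (0, 1]")
  abort_if(n_permutations < 0 || n_permutations != floor(n_permutations),
           "n_permutations must be a non-negative integer")
  if (n_permutations > 0 && n_permutations < 100)
    warning("n_permutations < 100 gives a coarse permutation p-value",
            call. = FALSE)
  by <- if ("target_id" %in% names(enrichment)) "target_id" else "gene_symbol"
  grp <- split(seq_len(nrow(enrichment)), enrichment[[by]])
  ranks <- enrichment$normalized_rank
  lfc <- enrichment$lfc
  k_vec <- lengths(grp)
  rho <- vapply(grp, function(i) rho_from_ranks(ranks[i], alpha), numeric(1))
  scores <- data.frame(
    target_id = names(grp),
    gene_symbol = enrichment$gene_symbol[vapply(grp, `[`, integer(1), 1L)],
    n_guides = as.integer(k_vec),
    mean_lfc = vapply(grp, function(i) mean(lfc[i]), numeric(1)),
    rho = rho,
    stringsAsFactors = FALSE
  )
  if (n_permutations > 0) {
    scores$perm_p <- NA_real_
    set.seed(derive_seed(seed, 0))
    for (k in sort(unique(k_vec))) {
      idx <- matrix(0L, nrow = n_permutations, ncol = k)
      for (p in seq_len(n_permutations))
        idx[p, ] <- sample.int(length(ranks), k)
      null_rho <- sort(rho_matrix(matrix(ranks[idx], ncol = k), alpha))
      sel <- k_vec == k
      scores$perm_p[sel] <-
        (1 + findInterval(scores$rho[sel], null_rho)) / (1 + n_permutations)
    }
  } else {
    scores$perm_p <- NA_real_
  }
  rownames(scores) <- NULL
  if (collapse && by == "target_id") {
    pp <- ifelse(is.na(scores$perm_p), 2, scores$perm_p)
    ord <- order(scores$gene_symbol, pp, scores$rho, -scores$mean_lfc,
                 scores$target_id)
    scores <- scores[ord, , drop = FALSE]
    scores <- scores[!duplicated(scores$gene_symbol), , drop = FALSE]
    rownames(scores) <- NULL
  }
  scores[, c("gene_symbol", "target_id", "n_guides", "mean_lfc", "rho",
             "perm_p")]
}

#' Rank a gene score table
#'
#' Deterministic total order by permutation p ascending, then rho ascending,
#' then mean LFC descending, then gene symbol; `gene_rank` is 1-based with no
#' gaps. Missing permutation p-values sort last.
#'
#' @param scores Output of [rra_gene_score()].
#' @return `scores` sorted with a `gene_rank` column.
#' @export
rank_genes <- function(scores) {
  abort_if(!all(c("gene_symbol", "rho", "mean_lfc") %in% names(scores)),
           "scores must be a gene score table")
  pp <- if ("perm_p" %in% names(scores))
    ifelse(is.na(scores$perm_p), 2, scores$perm_p) else rep(2, nrow(scores))
  ord <- order(pp, scores$rho, -scores$mean_lfc, scores$gene_symbol)
  scores <- scores[ord, , drop = FALSE]
  scores$gene_rank <- seq_len(nrow(scores))
  rownames(scores) <- NULL
  scores
}

#' Gini coefficient of a guide count distribution
#'
#' Measures the skew of a library distribution,
#' `G = sum_ij |x_i - x_j| / (2 n^2 mean(x))`; 0 for a perfectly uniform
#' library, approaching 1 as a few guides dominate. Used to track
#' round-over-round skew increase under selection.
#'
#' @param x Non-negative numeric vector of counts (>= 2 guides, not all 0).
#' @return Gini coefficient in \[0, 1).
#' @export
distribution_skew <- function(x) {
  abort_if(length(x) < 2, "need at least 2 guides")
  abort_if(any(x < 0), "counts must be non-negative")
  abort_if(all(x == 0), "all-zero sample has undefined skew")
  x <- sort(as.numeric(x))
  n <- length(x)
  sum((2 * seq_len(n) - n - 1) * x) / (n^2 * mean(x))
}

#' Score one screening replicate end to end
#'
#' Convenience wrapper: normalize, compute guide LFCs for the replicate's
#' final-round selected/control pair, aggregate with [rra_gene_score()], and
#' rank with [rank_genes()].
#'
#' @param screen An `sgrna_screen`, or a count data.frame (then
#'   `selected_sample`/`control_sample` are required).
#' @param replicate Replicate index (used when `screen` is an
#'   `sgrna_screen`).
#' @param selected_sample,control_sample Explicit sample columns.
#' @param normalization Passed to [normalize_counts()].
#' @param pseudocount,alpha,n_permutations,seed Passed through.
#' @return Ranked gene score table.
#' @export
score_screen <- function(screen, replicate = 1, selected_sample = NULL,
                         control_sample = NULL,
                         normalization = "median_ratio", pseudocount = 1,
                         alpha = 0.05, n_permutations = 10000, seed = 1L) {
  if (inherits(screen, "sgrna_screen") && is.null(selected_sample)) {
    pair <- final_round_samples(screen, replicate)
    selected_sample <- pair[["selected"]]
    control_sample <- pair[["control"]]
  }
  norm <- normalize_counts(screen, method = normalization)
  enr <- compute_sgrna_lfc(norm, selected_sample, control_sample, pseudocount)
  rank_genes(rra_gene_score(enr, alpha = alpha,
                            n_permutations = n_permutations, seed = seed))
}
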