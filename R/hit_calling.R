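# Candidate gene calling from per-replicate rankings.

#' Empirical FDR against negative-control genes
#'
#' For each gene, the fraction of designated housekeeping negative-control
#' genes whose average sgRNA enrichment (mean guide log2 fold change) is
#' strictly higher than the gene's. Controls absent from the score table are
#' dropped with a warning; ties with a control LFC do not inflate the FDR
#' (strict inequality) and are logged.
#'
#' @param scores Gene score table with `gene_symbol` and `mean_lfc`.
#' @param controls Character vector of negative-control gene symbols.
#' @return `scores` with an `empirical_fdr` column in \[0, 1\].
#' @export
empirical_fdr <- function(scores, controls) {
  abort_if(!all(c("gene_symbol", "mean_lfc") %in% names(scores)),
           "scores must carry gene_symbol and mean_lfc")
  present <- intersect(controls, scores$gene_symbol)
  dropped <- setdiff(controls, present)
  if (length(dropped) > 0)
    warning(length(dropped), " control gene(s) absent from the score table ",
            "were dropped", call. = FALSE)
  abort_if(length(present) == 0, "no negative-control gene present in scores")
  ctl_lfc <- sort(scores$mean_lfc[match(present, scores$gene_symbol)])
  m <- length(ctl_lfc)
  # strict inequality: #{controls > v} = m - #{controls <= v}
  n_le <- findInterval(scores$mean_lfc, ctl_lfc)
  noncontrol <- !scores$gene_symbol %in% present
  if (any(scores$mean_lfc[noncontrol] %in% ctl_lfc))
    message("ties between gene and control mean LFC resolved strictly")
  scores$empirical_fdr <- (m - n_le) / m
  scores
}

#' Select candidate genes by replicate overlap
#'
#' Per replicate, the top set is every gene with
#' `gene_rank <= ceiling(top_fraction * n_genes)` (inclusive reading of a
#' "top X%" rule); candidates are genes appearing in at least
#' `min_replicates` top sets. Acute and chronic screen replicates are pooled
#' into a single replicate list by the caller.
#'
#' @param rankings List of ranked gene score tables ([rank_genes()]), one per
#'   screening replicate.
#' @param top_fraction Fraction in (0, 1] (default 0.01, the top 1%).
#' @param min_replicates Minimum number of supporting replicates (default 2).
#' @return data.frame of class `candidate_set`: `gene_symbol`, `support`,
#'   one logical `in_top_rep<i>` column per replicate, and
#'   `min_empirical_fdr` when the rankings carry [empirical_fdr()] columns.
#' @export
select_candidates <- function(rankings, top_fraction = 0.01,
                              min_replicates = 2) {
  abort_if(!is.list(rankings) || length(rankings) == 0,
           "rankings must be a non-empty list of gene score tables")
  assert_fraction(top_fraction, "top_fraction")
  abort_if(!is_count(min_replicates), "min_replicates must be a positive integer")
  abort_if(min_replicates > length(rankings),
           "min_replicates exceeds the number of replicate rankings")
  top_sets <- lapply(rankings, function(rk) {
    abort_if(!"gene_rank" %in% names(rk),
             "each ranking needs a gene_rank column; run rank_genes() first")
    rk$gene_symbol[rk$gene_rank <= ceiling(top_fraction * nrow(rk))]
  })
  genes <- sort(unique(unlist(top_sets)))
  member <- vapply(top_sets, function(s) genes %in% s,
                   logical(length(genes)))
  member <- matrix(member, nrow = length(genes),
                   dimnames = list(NULL, sprintf("in_top_rep%d",
                                                 seq_along(rankings))))
  support <- rowSums(member)
  keep <- support >= min_replicates
  out <- data.frame(gene_symbol = genes[keep],
                    support = as.integer(support[keep]),
                    stringsAsFactors = FALSE)
  out <- cbind(out, as.data.frame(member[keep, , drop = FALSE]))
  if (all(vapply(rankings, function(rk) "empirical_fdr" %in% names(rk),
                 logical(1))) && nrow(out) > 0) {
    out$min_empirical_fdr <- vapply(out$gene_symbol, function(g) {
      min(vapply(rankings, function(rk) {
        i <- match(g, rk$gene_symbol)
        if (is.na(i)) Inf else rk$empirical_fdr[i]
      }, numeric(1)))
    }, numeric(1), USE.NAMES = FALSE)
  }
  out <- out[order(-out$support, out$gene_symbol), , drop = FALSE]
  rownames(out) <- NULL
  class(out) <- c("candidate_set", "data.frame")
  out
}

#' Overlap fraction between two top-N gene lists
#'
#' Reproduces the replicate-concordance diagnostic: the fraction of the top
#' `n` genes shared by two rankings. Two independent random rankings of `N`
#' genes give `n / N` in expectation.
#'
#' @param ranking_a,ranking_b Ranked gene score tables.
#' @param n Top-list size (must not exceed either ranking).
#' @return Overlap fraction in \[0, 1\].
#' @export
top_n_overlap <- function(ranking_a, ranking_b, n) {
  abort_if(!is_count(n), "n must be a positive integer")
  abort_if(n > nrow(ranking_a) || n > nrow(ranking_b),
           "n exceeds the size of a ranking")
  top <- function(rk) {
    abort_if(!"gene_rank" %in% names(rk), "rankings need gene_rank")
    rk$gene_symbol[rk$gene_rank <= n]
  }
  length(intersect(top(ranking_a), top(ranking_b))) / n
}
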