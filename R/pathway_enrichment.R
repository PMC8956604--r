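# Hypergeometric pathway enrichment with redundancy pruning.

#' Upper-tail hypergeometric enrichment test
#'
#' `P(X >= k)` where `X` counts candidate genes falling in the pathway when
#' `n = |candidates|` genes are drawn without replacement from a universe of
#' `N` genes containing `K = |pathway|` pathway members. Candidate and
#' pathway sets are intersected with the universe first.
#'
#' @param candidates,pathway,universe Character vectors of gene symbols.
#' @return p-value in (0, 1].
#' @export
hypergeometric_test <- function(candidates, pathway, universe) {
  abort_if(length(universe) == 0, "empty universe")
  universe <- unique(universe)
  candidates <- intersect(candidates, universe)
  pathway <- intersect(pathway, universe)
  k <- length(intersect(candidates, pathway))
  phyper(k - 1, length(pathway), length(universe) - length(pathway),
         length(candidates), lower.tail = FALSE)
}

#' Benjamini-Hochberg adjustment
#'
#' Standard step-up FDR adjustment with monotonicity enforcement; adjusted
#' values stay attached to their original positions, so the result is stable
#' under input permutation.
#'
#' @param pvalues Numeric vector of p-values in \[0, 1\].
#' @return Adjusted values, same order as the input.
#' @export
benjamini_hochberg <- function(pvalues) {
  abort_if(length(pvalues) == 0, "no p-values supplied")
  abort_if(any(is.na(pvalues)) || any(pvalues < 0) || any(pvalues > 1),
           "p-values must lie in [0, 1]")
  p.adjust(pvalues, method = "BH")
}

#' Pathway enrichment of a candidate gene set
#'
#' Restricts every gene set to the universe, keeps sets whose in-universe
#' size lies in `[min_size, max_size]` (the size band applied before
#' testing), tests each with [hypergeometric_test()], adjusts over the tested
#' family with [benjamini_hochberg()], and returns the sets passing
#' `fdr < fdr_threshold`, sorted by FDR (ties by raw p, then set id).
#'
#' @param candidates Character vector of candidate gene symbols.
#' @param collection Named list of gene sets (see [read_gmt()]).
#' @param universe Character vector of all genes that could have been
#'   candidates (typically every gene scored in the screen).
#' @param min_size,max_size In-universe size band (defaults 5 and 200).
#' @param fdr_threshold Significance cutoff on the adjusted value
#'   (default 0.05).
#' @return data.frame with `set_id`, `set_size`, `overlap`, `p`, `fdr`.
#' @export
enrich_pathways <- function(candidates, collection, universe,
                            min_size = 5, max_size = 200,
                            fdr_threshold = 0.05) {
  abort_if(min_size > max_size, "min_size must not exceed max_size")
  abort_if(is.null(names(collection)) || anyDuplicated(names(collection)) > 0,
           "collection must be a uniquely named list of gene sets")
  universe <- unique(universe)
  candidates <- intersect(candidates, universe)
  inuniv <- lapply(collection, intersect, universe)
  sizes <- lengths(inuniv)
  keep <- sizes >= min_size & sizes <= max_size
  empty <- data.frame(set_id = character(0), set_size = integer(0),
                      overlap = integer(0), p = numeric(0), fdr = numeric(0),
                      stringsAsFactors = FALSE)
  if (!any(keep)) {
    warning("no gene set within the size band after universe restriction",
            call. = FALSE)
    return(empty)
  }
  inuniv <- inuniv[keep]
  out <- data.frame(
    set_id = names(inuniv),
    set_size = as.integer(lengths(inuniv)),
    overlap = vapply(inuniv, function(s)
      length(intersect(s, candidates)), integer(1)),
    stringsAsFactors = FALSE
  )
  out$p <- vapply(inuniv, function(s)
    hypergeometric_test(candidates, s, universe), numeric(1))
  out$fdr <- benjamini_hochberg(out$p)
  out <- out[out$fdr < fdr_threshold, , drop = FALSE]
  out <- out[order(out$fdr, out$p, out$set_id), , drop = FALSE]
  rownames(out) <- NULL
  out
}

#' Prune redundant enriched pathways
#'
#' Sorts enrichment rows by FDR (ties by raw p, then set id) and excludes any
#' pathway whose member set overlaps a lower-FDR pathway by more than
#' `overlap_threshold` of its own (in-universe) size. The default, literal
#' rule compares against all lower-FDR pathways whether or not those were
#' themselves retained; `compare = "retained_only"` gives the greedy variant
#' that only compares against surviving pathways.
#'
#' @param rows Enrichment rows (from [enrich_pathways()]) carrying `set_id`,
#'   `p`, `fdr`.
#' @param collection Named list of gene sets covering every `set_id`.
#' @param overlap_threshold Fraction in (0, 1); default 0.30.
#' @param universe Optional universe to restrict member sets to (use the one
#'   given to [enrich_pathways()]).
#' @param compare `"all_lower"` (default) or `"retained_only"`.
#' @return `rows` sorted by FDR with a logical `retained` column.
#' @export
prune_redundant <- function(rows, collection, overlap_threshold = 0.30,
                            universe = NULL,
                            compare = c("all_lower", "retained_only")) {
  compare <- match.arg(compare)
  abort_if(overlap_threshold <= 0 || overlap_threshold >= 1,
           "overlap_threshold must lie in (0, 1)")
  missing <- setdiff(rows$set_id, names(collection))
  abort_if(length(missing) > 0, "set id(s) missing from collection: ",
           paste(missing, collapse = ", "))
  rows <- rows[order(rows$fdr, rows$p, rows$set_id), , drop = FALSE]
  rownames(rows) <- NULL
  members <- lapply(collection[rows$set_id], function(s)
    if (is.null(universe)) unique(s) else intersect(s, universe))
  n <- nrow(rows)
  retained <- logical(n)
  for (i in seq_len(n)) {
    a <- members[[i]]
    earlier <- seq_len(i - 1L)
    if (compare == "retained_only") earlier <- earlier[retained[earlier]]
    redundant <- FALSE
    for (j in earlier) {
      if (length(a) > 0 &&
          length(intersect(a, members[[j]])) / length(a) > overlap_threshold) {
        redundant <- TRUE
        break
      }
    }
    retained[i] <- !redundant
  }
  rows$retained <- retained
  rows
}
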