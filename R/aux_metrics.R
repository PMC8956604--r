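# Small closed-form study metrics and supporting rules: cytotoxicity
# percent survival, caliper tumor volume, the bulk RNA-seq differential
# expression rule, and the promoter-overlap regulator call.

#' Percent survival in a T cell cytotoxicity assay
#'
#' `100 * viability_with_t / viability_without_t`, where the denominator is
#' the paired control not incubated with T cells. Values above 100 (net
#' outgrowth under co-culture) are allowed.
#'
#' @param viability_with_t Luminescence of cells incubated with T cells.
#' @param viability_without_t Luminescence of the paired no-T-cell control
#'   (must be > 0).
#' @return Percent survival (vectorized).
#' @export
percent_survival <- function(viability_with_t, viability_without_t) {
  abort_if(any(viability_without_t <= 0),
           "control viability must be positive")
  100 * viability_with_t / viability_without_t
}

#' Caliper tumor volume
#'
#' `(L * W^2) / 2` in mm^3, with L the longest dimension and W the longest
#' perpendicular dimension.
#'
#' @param length_mm Tumor length in mm (>= width).
#' @param width_mm Tumor width in mm.
#' @return Volume in mm^3 (vectorized).
#' @export
tumor_volume <- function(length_mm, width_mm) {
  abort_if(any(width_mm < 0), "dimensions must be non-negative")
  abort_if(any(width_mm > length_mm),
           "width exceeds length; length must be the longest dimension")
  length_mm * width_mm^2 / 2
}

#' Differential expression between two replicate groups
#'
#' Reproduces the bulk RNA-seq rule: on log2(TPM + 1) matrices, keep genes
#' detected (TPM >= `detect_min`, or the log2 value when
#' `detect_on = "log2"`) in at least `detect_min_libraries` libraries across
#' both groups, run a per-gene two-sample t test (equal-variance Student by
#' default), adjust with Benjamini-Hochberg, and flag genes with
#' `fdr < fdr_level` whose absolute log2 fold change also exceeds
#' `lfc_cutoff` (the fold-change filter is skipped when `lfc_cutoff <= 0`).
#'
#' @param expr_a,expr_b Matrices of log2(TPM + 1), genes x replicates (>= 2
#'   replicates each), identical rownames. Fold change is `b` minus `a`.
#' @param detect_min Detection threshold (default 10).
#' @param detect_min_libraries Libraries required at or above the threshold
#'   (default 3).
#' @param fdr_level BH significance level (default 0.01).
#' @param lfc_cutoff Absolute log2 fold-change requirement (default 1).
#' @param detect_on Interpret `detect_min` on the `"tpm"` (default) or
#'   `"log2"` scale.
#' @param var_equal Pooled-variance t test (default TRUE; FALSE for Welch).
#' @return data.frame with `gene_symbol`, `mean_a`, `mean_b`, `lfc`, `t`,
#'   `p`, `fdr`, `significant`, one row per detected gene.
#' @export
differential_expression <- function(expr_a, expr_b, detect_min = 10,
                                    detect_min_libraries = 3,
                                    fdr_level = 0.01, lfc_cutoff = 1,
                                    detect_on = c("tpm", "log2"),
                                    var_equal = TRUE) {
  detect_on <- match.arg(detect_on)
  abort_if(ncol(expr_a) < 2 || ncol(expr_b) < 2,
           "each condition needs at least 2 replicates")
  abort_if(!identical(rownames(expr_a), rownames(expr_b)),
           "expression matrices must share rownames")
  both <- cbind(expr_a, expr_b)
  lev <- if (detect_on == "tpm") 2^both - 1 else both
  detected <- rowSums(lev >= detect_min) >= detect_min_libraries
  a <- expr_a[detected, , drop = FALSE]
  b <- expr_b[detected, , drop = FALSE]
  na <- ncol(a); nb <- ncol(b)
  ma <- rowMeans(a); mb <- rowMeans(b)
  va <- rowSums((a - ma)^2) / (na - 1)
  vb <- rowSums((b - mb)^2) / (nb - 1)
  if (var_equal) {
    sp2 <- ((na - 1) * va + (nb - 1) * vb) / (na + nb - 2)
    se <- sqrt(sp2 * (1 / na + 1 / nb))
    df <- rep(na + nb - 2, length(se))
  } else {
    se <- sqrt(va / na + vb / nb)
    df <- (va / na + vb / nb)^2 /
      ((va / na)^2 / (na - 1) + (vb / nb)^2 / (nb - 1))
  }
  delta <- mb - ma
  t_stat <- delta / se
  t_stat[se == 0 & delta == 0] <- 0
  p <- 2 * pt(-abs(t_stat), df)
  p[se == 0 & delta == 0] <- 1
  p <- pmax(p, .Machine$double.xmin)
  fdr <- if (length(p) > 0) benjamini_hochberg(p) else numeric(0)
  out <- data.frame(gene_symbol = rownames(a), mean_a = ma, mean_b = mb,
                    lfc = delta, t = t_stat, p = p, fdr = fdr,
                    stringsAsFactors = FALSE)
  out$significant <- out$fdr < fdr_level &
    (lfc_cutoff <= 0 | abs(out$lfc) > lfc_cutoff)
  rownames(out) <- NULL
  out
}

#' Strand-aware promoter windows around transcription start sites
#'
#' The promoter of a gene is the closed interval from `upstream` bp upstream
#' to `downstream` bp downstream of its TSS (defaults 2000 and 500);
#' "upstream" follows the strand, so on the minus strand the window extends
#' toward larger coordinates.
#'
#' @param tss_table data.frame with `gene_symbol`, `chrom`, `pos` (1-based
#'   TSS coordinate), `strand` (`"+"`/`"-"`).
#' @param upstream,downstream Window extents in bp.
#' @return `tss_table` with `start` and `end` columns (1-based, closed;
#'   width = upstream + downstream + 1).
#' @export
promoter_windows <- function(tss_table, upstream = 2000, downstream = 500) {
  abort_if(!all(c("gene_symbol", "chrom", "pos", "strand") %in%
                  names(tss_table)),
           "tss_table needs gene_symbol, chrom, pos, strand")
  abort_if(!all(tss_table$strand %in% c("+", "-")),
           "strand must be '+' or '-'")
  plus <- tss_table$strand == "+"
  tss_table$start <- ifelse(plus, tss_table$pos - upstream,
                            tss_table$pos - downstream)
  tss_table$end <- ifelse(plus, tss_table$pos + downstream,
                          tss_table$pos + upstream)
  tss_table
}

#' Call genes with a peak in their promoter
#'
#' A gene is called a potential regulatory target when any peak interval
#' intersects its promoter window by at least 1 bp (closed-interval
#' intersection). Peaks read from BED files ([read_peaks_bed()]) are already
#' converted from 0-based half-open to 1-based closed coordinates.
#'
#' @param peaks data.frame with `chrom`, `start`, `end` (1-based closed).
#' @param tss_table See [promoter_windows()].
#' @param upstream,downstream Promoter extents in bp.
#' @return Sorted character vector of called gene symbols.
#' @export
promoter_overlap_calls <- function(peaks, tss_table, upstream = 2000,
                                   downstream = 500) {
  abort_if(!all(c("chrom", "start", "end") %in% names(peaks)),
           "peaks need chrom, start, end")
  abort_if(any(peaks$end < peaks$start), "malformed peak interval (end < start)")
  win <- promoter_windows(tss_table, upstream, downstream)
  pk <- GenomicRanges::GRanges(peaks$chrom,
                               IRanges::IRanges(peaks$start, peaks$end))
  pr <- GenomicRanges::GRanges(win$chrom, IRanges::IRanges(win$start, win$end))
  hits <- GenomicRanges::findOverlaps(pr, pk)
  sort(unique(win$gene_symbol[unique(S4Vectors::queryHits(hits))]))
}
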