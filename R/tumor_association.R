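# Cytolytic-activity correlation and ssGSEA responder comparison.

#' Cytolytic activity (CYT) per sample
#'
#' The local immune cytolytic activity proxy: the geometric mean of GZMA
#' (granzyme A) and PRF1 (perforin 1) expression on the linear scale,
#' `sqrt((GZMA + offset) * (PRF1 + offset))`. Log2-scale cohorts are
#' back-transformed as `2^x - 1` first; the offset keeps the score positive
#' when a marker is unexpressed.
#'
#' @param cohort An [expression_cohort()] containing GZMA and PRF1.
#' @param offset Small positive offset (default 0.01).
#' @return Named numeric vector (one positive value per sample) of class
#'   `cytolytic_vector`.
#' @export
cytolytic_activity <- function(cohort, offset = 0.01) {
  lin <- linear_values(cohort)
  for (g in c("GZMA", "PRF1"))
    abort_if(!g %in% rownames(lin), "marker gene missing from cohort: ", g)
  cyt <- sqrt((lin["GZMA", ] + offset) * (lin["PRF1", ] + offset))
  structure(cyt, class = "cytolytic_vector")
}

#' Correlate gene expression with cytolytic activity
#'
#' Per tumor type (the cohort's `dataset_id` grouping) and per gene: Pearson
#' correlation between expression and the cytolytic score, significance from
#' the Fisher transformation (`z = atanh(r) * sqrt(n - 3)`, two-sided normal
#' p), and Benjamini-Hochberg adjustment within the tumor type. A gene is
#' flagged significantly positive when `r > 0` and `fdr < fdr_threshold`.
#'
#' Correlations are computed on the cohort's stored scale; the cytolytic
#' score is matched to it (`log2(CYT + 1)` for log2 cohorts) unless
#' `cyt_scale = "linear"`.
#'
#' @param cohort An [expression_cohort()]; every tumor type needs n >= 4.
#' @param cyt Output of [cytolytic_activity()] (recomputed when `NULL`).
#' @param fdr_threshold FDR cutoff for the positive flag (default 0.05).
#' @param genes Genes to test (default: all non-marker genes).
#' @param cyt_scale `"match"` (default) or `"linear"`.
#' @return data.frame with `gene_symbol`, `tumor_type`, `n`, `r`, `p`,
#'   `fdr`, `significant_positive`. Zero-variance genes get `r = NA`,
#'   `p = 1` and a logged note.
#' @export
correlate_gene_cytolytic <- function(cohort, cyt = NULL, fdr_threshold = 0.05,
                                     genes = NULL,
                                     cyt_scale = c("match", "linear")) {
  cyt_scale <- match.arg(cyt_scale)
  if (is.null(cyt)) cyt <- cytolytic_activity(cohort)
  abort_if(length(cyt) != ncol(cohort$values),
           "cytolytic vector length must equal the sample count")
  y_all <- if (cohort$scale == "log2" && cyt_scale == "match")
    log2(as.numeric(cyt) + 1) else as.numeric(cyt)
  if (is.null(genes))
    genes <- setdiff(rownames(cohort$values), c("GZMA", "PRF1"))
  types <- unique(cohort$metadata$dataset_id)
  res <- vector("list", length(types))
  n_flat <- 0L
  for (ti in seq_along(types)) {
    sel <- cohort$metadata$dataset_id == types[ti]
    n <- sum(sel)
    abort_if(n < 4, "tumor type ", types[ti], " has fewer than 4 samples")
    x <- cohort$values[genes, sel, drop = FALSE]
    y <- y_all[sel]
    r <- suppressWarnings(as.numeric(cor(t(x), y)))
    flat <- is.na(r)
    n_flat <- n_flat + sum(flat)
    z <- atanh(pmin(pmax(r, -1), 1)) * sqrt(n - 3)
    p <- 2 * pnorm(-abs(z))
    p[flat] <- 1
    r[flat] <- NA_real_
    p <- pmax(p, .Machine$double.xmin)  # underflow floor for |r| ~ 1
    fdr <- benjamini_hochberg(p)
    res[[ti]] <- data.frame(
      gene_symbol = genes, tumor_type = types[ti], n = n, r = r, p = p,
      fdr = fdr,
      significant_positive = !is.na(r) & r > 0 & fdr < fdr_threshold,
      stringsAsFactors = FALSE
    )
  }
  if (n_flat > 0)
    message(n_flat, " zero-variance gene/type pair(s): r undefined, p set to 1")
  out <- do.call(rbind, res)
  rownames(out) <- NULL
  out
}

#' Pan-cancer summary of cytolytic correlations
#'
#' Per gene: in how many tumor types its expression correlates significantly
#' and positively with cytolytic activity, with flags for "at least 1 tumor
#' type" and "more than 25% of tumor types".
#'
#' @param rows Output of [correlate_gene_cytolytic()].
#' @return data.frame with `gene_symbol`, `n_types_tested`,
#'   `n_types_significant`, `fraction`, `any_type`, `over_quarter`.
#' @export
summarize_pan_cancer <- function(rows) {
  abort_if(nrow(rows) == 0, "no correlation rows supplied")
  tested <- tapply(rows$tumor_type, rows$gene_symbol,
                   function(x) length(unique(x)))
  sig <- tapply(rows$significant_positive, rows$gene_symbol, sum)
  genes <- names(tested)
  out <- data.frame(
    gene_symbol = genes,
    n_types_tested = as.integer(tested),
    n_types_significant = as.integer(sig[genes]),
    stringsAsFactors = FALSE
  )
  out$fraction <- out$n_types_significant / out$n_types_tested
  out$any_type <- out$n_types_significant >= 1
  out$over_quarter <- out$fraction > 0.25
  rownames(out) <- NULL
  out[order(out$gene_symbol), , drop = FALSE]
}

#' Average replicate samples from the same patient
#'
#' Collapses sample columns to one column per patient by the arithmetic mean
#' on the cohort's stored scale. Metadata is collapsed alongside;
#' conflicting response labels (or dataset ids) within a patient raise an
#' error.
#'
#' @param cohort An [expression_cohort()].
#' @param patient_map Named character vector mapping every sample id to a
#'   patient id.
#' @return A collapsed [expression_cohort()] whose sample ids are patient
#'   ids.
#' @export
average_patient_replicates <- function(cohort, patient_map) {
  samples <- colnames(cohort$values)
  abort_if(!all(samples %in% names(patient_map)),
           "patient_map must cover every sample")
  patient <- patient_map[samples]
  patients <- unique(patient)
  vals <- vapply(patients, function(p)
    rowMeans(cohort$values[, patient == p, drop = FALSE]),
    numeric(nrow(cohort$values)))
  colnames(vals) <- patients
  md <- cohort$metadata
  collapse_field <- function(field) {
    vapply(patients, function(p) {
      v <- unique(md[[field]][patient == p])
      abort_if(length(v) > 1, "conflicting ", field, " within patient ", p)
      v
    }, character(1), USE.NAMES = FALSE)
  }
  meta <- data.frame(sample_id = patients,
                     dataset_id = collapse_field("dataset_id"),
                     stringsAsFactors = FALSE)
  if ("response" %in% names(md)) meta$response <- collapse_field("response")
  expression_cohort(vals, meta, scale = cohort$scale)
}

# ssGSEA running-sum for one sample. x: expression vector (named); inset:
# logical mask aligned with x.
ssgsea_es_sample <- function(x, inset, weight) {
  n <- length(x)
  # rank-normalized values: highest-expressed gene -> n, lowest -> 1; ties
  # broken by gene name for determinism
  ord <- order(-x, names(x))
  rv <- (n:1)^weight
  in_ord <- inset[ord]
  w_in <- ifelse(in_ord, rv, 0)
  cdf_in <- cumsum(w_in) / sum(w_in)
  cdf_out <- cumsum(!in_ord) / (n - sum(inset))
  sum(cdf_in - cdf_out)
}

#' Single-sample gene set enrichment (ssGSEA)
#'
#' Per sample, genes are ranked by expression (descending) and replaced by
#' their ranks (rank normalization: the top gene takes value N). The
#' enrichment score is the sum over all rank positions of the difference
#' between the weighted in-set ECDF (steps proportional to rank^weight,
#' normalized over set members) and the uniform out-of-set ECDF (steps
#' 1/(N - set size)). The normalized score NES divides ES by the range
#' (max - min) of ES across all samples of the run, so at least two samples
#' are required.
#'
#' @param cohort An [expression_cohort()].
#' @param signature Character vector of signature gene symbols; the
#'   intersection with the cohort's genes must be non-empty and must not
#'   cover every gene.
#' @param weight Rank-weighting exponent (default 0.25, the customary
#'   default of single-sample GSEA implementations).
#' @return data.frame with `sample_id`, `dataset_id`, `es`, `nes` (plus
#'   `response` when the cohort metadata carries it).
#' @export
ssgsea_score <- function(cohort, signature, weight = 0.25) {
  genes <- rownames(cohort$values)
  sig <- intersect(signature, genes)
  abort_if(length(sig) == 0, "signature does not intersect the cohort genes")
  abort_if(length(sig) == length(genes),
           "signature covers every cohort gene; out-of-set ECDF undefined")
  abort_if(ncol(cohort$values) < 2,
           "NES needs at least two samples (ES is normalized by the ",
           "across-sample range)")
  inset <- genes %in% sig
  es <- vapply(seq_len(ncol(cohort$values)), function(j) {
    x <- cohort$values[, j]
    names(x) <- genes
    ssgsea_es_sample(x, inset, weight)
  }, numeric(1))
  rng <- max(es) - min(es)
  abort_if(rng == 0, "degenerate run: identical ES across samples")
  out <- data.frame(sample_id = colnames(cohort$values),
                    dataset_id = cohort$metadata$dataset_id,
                    es = es, nes = es / rng, stringsAsFactors = FALSE)
  if ("response" %in% names(cohort$metadata))
    out$response <- cohort$metadata$response
  out
}

#' Z-score normalized enrichment scores within datasets
#'
#' `z = (NES - dataset mean) / dataset sample SD` (ddof = 1), computed per
#' dataset and concatenated, so scores from cohorts profiled on different
#' scales can be aggregated.
#'
#' @param scores Output of [ssgsea_score()]; every dataset needs >= 2
#'   samples and non-zero NES spread.
#' @return `scores` with a `z` column (dataset means 0, SDs 1).
#' @export
zscore_by_dataset <- function(scores) {
  abort_if(!all(c("dataset_id", "nes") %in% names(scores)),
           "scores must carry dataset_id and nes")
  scores$z <- NA_real_
  for (d in unique(scores$dataset_id)) {
    sel <- scores$dataset_id == d
    abort_if(sum(sel) < 2, "dataset ", d, " has fewer than 2 samples")
    s <- sd(scores$nes[sel])
    abort_if(s == 0, "dataset ", d, " has zero NES variance")
    scores$z[sel] <- (scores$nes[sel] - mean(scores$nes[sel])) / s
  }
  scores
}

#' Compare responders and nonresponders on z-scored NES
#'
#' Two-sample two-tailed t test (equal-variance by default, Welch optional)
#' of the per-dataset z-scored NES between immunotherapy responders and
#' nonresponders.
#'
#' @param scores Output of [zscore_by_dataset()] with a `response` column
#'   (`"responder"`/`"nonresponder"`), each group with >= 2 samples.
#' @param var_equal Use the pooled-variance t test (default TRUE).
#' @return List with `statistic` (t, nonresponder minus responder),
#'   `p_value`, `df`, `mean_responder`, `mean_nonresponder`,
#'   `higher_group`.
#' @export
compare_response_groups <- function(scores, var_equal = TRUE) {
  abort_if(!all(c("z", "response") %in% names(scores)),
           "scores must carry z and response columns")
  zr <- scores$z[scores$response == "responder"]
  zn <- scores$z[scores$response == "nonresponder"]
  abort_if(length(zr) < 2 || length(zn) < 2,
           "both response groups need at least 2 samples")
  tt <- t.test(zn, zr, var.equal = var_equal)
  list(statistic = unname(tt$statistic),
       p_value = tt$p.value,
       df = unname(tt$parameter),
       mean_responder = mean(zr),
       mean_nonresponder = mean(zn),
       higher_group = if (mean(zn) >= mean(zr)) "nonresponder" else "responder")
}
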