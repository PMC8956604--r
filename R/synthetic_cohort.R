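# Synthetic tumor expression cohorts with planted immune signal.

#' Expression cohort container
#'
#' A gene-by-sample expression matrix with per-sample metadata and an
#' explicit scale flag. `log2` means log2(TPM + 1)-like values; `linear`
#' means TPM-like values (non-negative).
#'
#' @param values Numeric matrix, genes in rows (rownames = symbols), samples
#'   in columns (colnames = sample ids).
#' @param metadata data.frame with columns `sample_id`, `dataset_id` and
#'   optionally `response` (`"responder"`/`"nonresponder"`), one row per
#'   sample.
#' @param scale `"log2"` or `"linear"`.
#' @return An `expression_cohort` object.
#' @export
expression_cohort <- function(values, metadata, scale = c("log2", "linear")) {
  scale <- match.arg(scale)
  abort_if(!is.matrix(values) || is.null(rownames(values)) ||
             is.null(colnames(values)),
           "values must be a matrix with gene rownames and sample colnames")
  abort_if(!all(c("sample_id", "dataset_id") %in% names(metadata)),
           "metadata needs sample_id and dataset_id columns")
  abort_if(!setequal(metadata$sample_id, colnames(values)) ||
             anyDuplicated(metadata$sample_id) > 0,
           "metadata must cover every sample exactly once")
  abort_if(scale == "linear" && any(values < 0),
           "negative values are not allowed on the linear scale")
  metadata <- metadata[match(colnames(values), metadata$sample_id), ,
                       drop = FALSE]
  rownames(metadata) <- NULL
  structure(list(values = values, metadata = metadata, scale = scale),
            class = "expression_cohort")
}

#' @export
print.expression_cohort <- function(x, ...) {
  cat("expression_cohort:", nrow(x$values), "genes x", ncol(x$values),
      "samples (", x$scale, "scale ),",
      length(unique(x$metadata$dataset_id)), "dataset(s)\n")
  invisible(x)
}

#' Linear-scale expression of a cohort
#'
#' Back-transforms log2(TPM + 1) values as `2^x - 1` when needed.
#' @param cohort An `expression_cohort`.
#' @return Numeric matrix on the linear (TPM-like) scale.
#' @export
linear_values <- function(cohort) {
  if (cohort$scale == "linear") cohort$values else 2^cohort$values - 1
}

#' Cohort simulation configuration
#'
#' Parameters for [simulate_expression_cohort()]. The generator emulates the
#' statistical structure of bulk tumor cohorts used for cytolytic-activity
#' correlation (per-"dataset" groups double as tumor types) and of pooled
#' checkpoint-blockade cohorts: a per-sample latent immune-activity factor
#' drives the cytolytic marker genes GZMA and PRF1, signature genes track the
#' factor with correlation `planted_correlation`, and nonresponders carry a
#' `signature_shift` standardized upward shift of signature-gene expression.
#'
#' @param n_genes Number of genes in the simulated universe (GZMA and PRF1
#'   are appended if absent).
#' @param n_samples_per_dataset Samples per dataset (recycled over datasets).
#' @param n_datasets Number of datasets / tumor types.
#' @param planted_correlation Target Pearson r between signature-gene
#'   expression and the log-scale cytolytic score, in \[-1, 1\].
#' @param responder_fraction Proportion of responders in (0, 1); the
#'   per-dataset responder count is fixed at `round(fraction * n)`.
#' @param signature_shift Standardized mean difference added to signature
#'   genes in nonresponders (log2 scale, units of `log_sd`).
#' @param log_mean,log_sd Log2-scale mean and SD of gene expression.
#' @param dataset_offsets Optional numeric vector of additive per-dataset
#'   scale offsets (log2 scale); default 0 for all.
#' @param seed Integer master seed.
#' @return A list of class `cohort_sim_config`.
#' @export
cohort_sim_config <- function(n_genes = 500, n_samples_per_dataset = 100,
                              n_datasets = 1, planted_correlation = 0,
                              responder_fraction = 0.3, signature_shift = 0,
                              log_mean = 3, log_sd = 1,
                              dataset_offsets = NULL, seed = 1L) {
  abort_if(!is_count(n_genes) || !is_count(n_datasets),
           "n_genes and n_datasets must be positive integers")
  abort_if(!all(vapply(n_samples_per_dataset, is_count, logical(1))),
           "n_samples_per_dataset must be positive integer(s)")
  abort_if(abs(planted_correlation) > 1,
           "planted_correlation must lie in [-1, 1]")
  abort_if(responder_fraction <= 0 || responder_fraction >= 1,
           "responder_fraction must lie in (0, 1)")
  abort_if(log_sd <= 0, "log_sd must be positive")
  if (!is.null(dataset_offsets))
    abort_if(length(dataset_offsets) != n_datasets,
             "dataset_offsets must have one entry per dataset")
  structure(list(
    n_genes = n_genes,
    n_samples_per_dataset = rep_len(n_samples_per_dataset, n_datasets),
    n_datasets = as.integer(n_datasets),
    planted_correlation = planted_correlation,
    responder_fraction = responder_fraction,
    signature_shift = signature_shift,
    log_mean = log_mean, log_sd = log_sd,
    dataset_offsets = dataset_offsets %||% rep(0, n_datasets),
    seed = as.integer(seed)
  ), class = "cohort_sim_config")
}

#' Simulate a tumor expression cohort
#'
#' Generates log2(TPM + 1)-like expression for `n_genes` genes (plus GZMA and
#' PRF1) across one or more datasets. Per sample, a latent immune-activity
#' factor a ~ N(0, 1) drives GZMA and PRF1 (so the log cytolytic score tracks
#' a almost deterministically); each signature gene is
#' `log_mean + log_sd * (r * a + sqrt(1 - r^2) * noise)` with
#' r = `planted_correlation`, plus `signature_shift * log_sd` in
#' nonresponders; all other genes are independent noise. Log values are
#' floored at 0 so the linear scale stays non-negative.
#'
#' Random stream order, per dataset `d` (sub-seed from `config$seed` and
#' `d`): latent factors, marker noise (GZMA then PRF1), signature-gene noise
#' (gene-major), background-gene noise, responder label shuffle.
#'
#' @param config A [cohort_sim_config()].
#' @param signature_genes Character vector of signature gene symbols; must be
#'   drawn from the simulated universe `GENE00001..` (GZMA/PRF1 excluded).
#' @return An [expression_cohort()] on the log2 scale, with `response`
#'   metadata and attribute `signature_genes`.
#' @export
simulate_expression_cohort <- function(config, signature_genes = character(0)) {
  abort_if(!inherits(config, "cohort_sim_config"),
           "config must be created with cohort_sim_config()")
  genes <- sprintf("GENE%05d", seq_len(config$n_genes))
  universe <- c(genes, "GZMA", "PRF1")
  missing <- setdiff(signature_genes, genes)
  abort_if(length(missing) > 0,
           "signature genes absent from the simulated universe: ",
           paste(missing, collapse = ", "))
  r <- config$planted_correlation
  vals <- list(); meta <- list()
  for (d in seq_len(config$n_datasets)) {
    n <- config$n_samples_per_dataset[d]
    off <- config$dataset_offsets[d]
    set.seed(derive_seed(config$seed, d))
    a <- rnorm(n)
    m <- matrix(0, nrow = length(universe), ncol = n,
                dimnames = list(universe, sprintf("DS%d_S%03d", d, seq_len(n))))
    m["GZMA", ] <- config$log_mean + a + 0.05 * rnorm(n)
    m["PRF1", ] <- config$log_mean + a + 0.05 * rnorm(n)
    n_resp <- round(config$responder_fraction * n)
    abort_if(n_resp < 1 || n_resp >= n,
             "responder_fraction yields an empty response group at n = ", n)
    sig <- intersect(genes, signature_genes)
    bg <- setdiff(genes, sig)
    if (length(sig) > 0) {
      noise <- matrix(rnorm(length(sig) * n), nrow = length(sig))
      m[sig, ] <- config$log_mean + config$log_sd *
        (r * matrix(a, nrow = length(sig), ncol = n, byrow = TRUE) +
           sqrt(1 - r^2) * noise)
    }
    if (length(bg) > 0)
      m[bg, ] <- config$log_mean +
        config$log_sd * matrix(rnorm(length(bg) * n), nrow = length(bg))
    response <- rep("nonresponder", n)
    response[sample.int(n, n_resp)] <- "responder"
    if (length(sig) > 0 && config$signature_shift != 0) {
      nr <- response == "nonresponder"
      m[sig, nr] <- m[sig, nr] + config$signature_shift * config$log_sd
    }
    m <- pmax(m + off, 0)
    vals[[d]] <- m
    meta[[d]] <- data.frame(sample_id = colnames(m),
                            dataset_id = sprintf("DS%d", d),
                            response = response, stringsAsFactors = FALSE)
  }
  cohort <- expression_cohort(do.call(cbind, vals),
                              do.call(rbind, meta), scale = "log2")
  attr(cohort, "signature_genes") <- intersect(genes, signature_genes)
  cohort
}
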