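# Synthetic guide libraries and selection-screen count matrices.
#
# The simulator emulates a pooled CRISPRa survival screen: a right-skewed
# baseline library (log-normal abundances), per-round multiplicative fitness
# advantages for planted resistance genes in the T cell-selected arm, and
# overdispersed negative-binomial sequencing counts. The acute arm is one
# round of selection, the chronic arm three.

#' Generate a synthetic CRISPRa guide library
#'
#' Builds a library manifest with a fixed number of guides per target
#' (isoform-level ids mapped to gene symbols) and flags a random subset of
#' gene symbols as housekeeping-style negative controls. The real library the
#' design emulates carries 3 guides per coding isoform and a panel of 311
#' housekeeping negative-control genes; both are free parameters here.
#'
#' @param n_targets Number of targets (isoforms). Each target gets exactly
#'   `guides_per_target` guides.
#' @param guides_per_target Guides designed per target (default 3).
#' @param n_negative_controls Number of gene symbols flagged as negative
#'   controls (housekeeping surrogates).
#' @param isoforms_per_gene Targets per gene symbol; with the default 1 the
#'   target and gene levels coincide.
#' @param seed Integer seed; the manifest is a pure function of the
#'   arguments.
#' @return A `data.frame` of class `sgrna_library` with columns `guide_id`,
#'   `target_id`, `gene_symbol`, `is_negative_control`.
#' @examples
#' lib <- generate_library(100, 3, n_negative_controls = 10, seed = 1)
#' nrow(lib) # 300 guides
#' @export
generate_library <- function(n_targets, guides_per_target = 3,
                             n_negative_controls, isoforms_per_gene = 1,
                             seed = 1L) {
  abort_if(!is_count(n_targets) || !is_count(guides_per_target) ||
             !is_count(n_negative_controls) || !is_count(isoforms_per_gene),
           "invalid library config: all counts must be positive integers")
  n_genes <- ceiling(n_targets / isoforms_per_gene)
  gene_symbols <- sprintf("GENE%05d", seq_len(n_genes))
  gene_of_target <- gene_symbols[ceiling(seq_len(n_targets) / isoforms_per_gene)]
  iso_index <- stats::ave(seq_len(n_targets), gene_of_target, FUN = seq_along)
  target_id <- paste0(gene_of_target, ".", iso_index)
  abort_if(n_negative_controls > n_genes,
           "n_negative_controls exceeds the number of distinct gene symbols (",
           n_genes, ")")
  set.seed(derive_seed(seed, 0))
  controls <- sort(sample(gene_symbols, n_negative_controls))
  lib <- data.frame(
    guide_id = paste0(rep(target_id, each = guides_per_target), "_sg",
                      seq_len(guides_per_target)),
    target_id = rep(target_id, each = guides_per_target),
    gene_symbol = rep(gene_of_target, each = guides_per_target),
    stringsAsFactors = FALSE
  )
  lib$is_negative_control <- lib$gene_symbol %in% controls
  class(lib) <- c("sgrna_library", "data.frame")
  attr(lib, "negative_control_genes") <- controls
  attr(lib, "guides_per_target") <- as.integer(guides_per_target)
  lib
}

#' Negative-control genes of a library
#' @param library An `sgrna_library`.
#' @return Character vector of control gene symbols.
#' @export
negative_control_genes <- function(library) {
  attr(library, "negative_control_genes") %||%
    sort(unique(library$gene_symbol[library$is_negative_control]))
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Screen simulation configuration
#'
#' Validated parameter set for [simulate_screen()]. Effects are
#' per-round multiplicative fitness advantages (dimensionless, >= 1; 1 for
#' every non-resistance gene). Counts follow a negative binomial with
#' variance mu + dispersion * mu^2.
#'
#' @param n_resistance_genes Number of genes given a planted effect when
#'   `effects` is not supplied.
#' @param effect_size Per-round multiplicative advantage for planted genes.
#' @param rounds Selection rounds: 1 = acute exposure, 3 = chronic.
#' @param sequencing_depth Mean reads per guide.
#' @param nb_dispersion Negative-binomial dispersion alpha (> 0).
#' @param n_replicates Screening replicates (each with its own baseline
#'   library draw and paired no-T-cell control arm).
#' @param seed Integer master seed.
#' @param effects Optional named numeric vector of per-round effects keyed by
#'   gene symbol; overrides `n_resistance_genes`/`effect_size`.
#' @return A list of class `screen_sim_config`.
#' @export
screen_sim_config <- function(n_resistance_genes = 50, effect_size = 2,
                              rounds = 3, sequencing_depth = 500,
                              nb_dispersion = 0.2, n_replicates = 2,
                              seed = 1L, effects = NULL) {
  abort_if(!is_count(rounds), "rounds must be a positive integer (>= 1)")
  abort_if(!is_count(n_replicates), "n_replicates must be a positive integer")
  abort_if(!is.numeric(sequencing_depth) || sequencing_depth <= 0,
           "sequencing_depth must be positive")
  abort_if(!is.numeric(nb_dispersion) || nb_dispersion <= 0,
           "nb_dispersion must be > 0")
  abort_if(!is.numeric(effect_size) || any(effect_size < 1),
           "effect_size must be >= 1")
  abort_if(!(is_count(n_resistance_genes) || n_resistance_genes == 0),
           "n_resistance_genes must be a non-negative integer")
  if (!is.null(effects)) {
    abort_if(is.null(names(effects)) || any(!nzchar(names(effects))),
             "effects must be a named numeric vector keyed by gene symbol")
    abort_if(any(effects < 1), "planted effects must be >= 1")
  }
  structure(list(
    n_resistance_genes = n_resistance_genes, effect_size = effect_size,
    rounds = as.integer(rounds), sequencing_depth = sequencing_depth,
    nb_dispersion = nb_dispersion, n_replicates = as.integer(n_replicates),
    seed = as.integer(seed), effects = effects
  ), class = "screen_sim_config")
}

# Abundance recursion: baseline vector `a` (summing to 1), per-guide
# multiplicative effect `e`; each round multiplies then renormalizes.
# Returns a (rounds + 1) x n matrix, row r+1 = abundance after r rounds.
evolve_abundance <- function(a, e, rounds) {
  out <- matrix(0, nrow = rounds + 1L, ncol = length(a))
  out[1L, ] <- a / sum(a)
  for (r in seq_len(rounds)) {
    nxt <- out[r, ] * e
    out[r + 1L, ] <- nxt / sum(nxt)
  }
  out
}

#' Simulate a selection screen
#'
#' Draws baseline guide abundances log-normally (sigma 0.5 on the natural-log
#' scale), multiplies the selected arm by each guide's per-round effect with
#' renormalization after every round, and samples negative-binomial counts at
#' the configured depth for every round (0 = pre-selection baseline) of both
#' arms of every replicate.
#'
#' Random stream order, per replicate `i` (sub-seed derived from
#' `config$seed` and `i`): baseline abundances, then counts for rounds
#' 0..rounds, control arm before selected arm within each round. Planted
#' resistance genes (when `config$effects` is `NULL`) are drawn once from the
#' non-control genes under sub-seed index 0.
#'
#' @param library An `sgrna_library` from [generate_library()].
#' @param config A [screen_sim_config()].
#' @return A list of class `sgrna_screen` with elements `counts` (data.frame:
#'   `guide_id`, `target_id`, `gene_symbol`, one integer column per sample
#'   named `arm_repR_roundK`), `samples` (metadata: `sample`, `arm`,
#'   `replicate`, `round`), `effects` (named per-gene effect vector) and
#'   `resistance_genes`.
#' @export
simulate_screen <- function(library, config) {
  abort_if(!inherits(config, "screen_sim_config"),
           "config must be created with screen_sim_config()")
  genes <- unique(library$gene_symbol)
  controls <- negative_control_genes(library)
  effects <- config$effects
  if (is.null(effects)) {
    pool <- setdiff(genes, controls)
    abort_if(config$n_resistance_genes > length(pool),
             "more resistance genes requested than non-control genes available")
    set.seed(derive_seed(config$seed, 0))
    planted <- if (config$n_resistance_genes > 0)
      sort(sample(pool, config$n_resistance_genes)) else character(0)
    effects <- setNames(rep(config$effect_size, length(planted)), planted)
  } else {
    missing <- setdiff(names(effects), genes)
    abort_if(length(missing) > 0, "effect map references genes absent from ",
             "the library: ", paste(missing, collapse = ", "))
    clash <- intersect(names(effects)[effects > 1], controls)
    abort_if(length(clash) > 0, "negative-control genes must keep effect 1: ",
             paste(clash, collapse = ", "))
  }
  e_guide <- rep(1, nrow(library))
  hit <- match(library$gene_symbol, names(effects))
  e_guide[!is.na(hit)] <- effects[hit[!is.na(hit)]]

  n_guides <- nrow(library)
  counts <- data.frame(guide_id = library$guide_id,
                       target_id = library$target_id,
                       gene_symbol = library$gene_symbol,
                       stringsAsFactors = FALSE)
  meta <- list()
  for (i in seq_len(config$n_replicates)) {
    set.seed(derive_seed(config$seed, i))
    base <- rlnorm(n_guides, meanlog = 0, sdlog = 0.5)
    ab <- evolve_abundance(base / sum(base), e_guide, config$rounds)
    for (r in 0:config$rounds) {
      for (arm in c("control", "selected")) {
        a <- if (arm == "control") ab[1L, ] else ab[r + 1L, ]
        mu <- a * config$sequencing_depth * n_guides
        nm <- sprintf("%s_rep%d_round%d", arm, i, r)
        counts[[nm]] <- rnbinom(n_guides, mu = mu, size = 1 / config$nb_dispersion)
        meta[[nm]] <- data.frame(sample = nm, arm = arm, replicate = i,
                                 round = r, stringsAsFactors = FALSE)
      }
    }
  }
  structure(list(
    counts = counts,
    samples = do.call(rbind, c(meta, list(make.row.names = FALSE))),
    effects = effects,
    resistance_genes = names(effects)[effects > 1],
    negative_control_genes = controls,
    config = config
  ), class = "sgrna_screen")
}

#' Names of the final-round selected/control sample pair of a replicate
#' @param screen An `sgrna_screen`.
#' @param replicate Replicate index.
#' @return Named character vector with elements `selected` and `control`.
#' @export
final_round_samples <- function(screen, replicate) {
  r <- screen$config$rounds
  c(selected = sprintf("selected_rep%d_round%d", replicate, r),
    control = sprintf("control_rep%d_round%d", replicate, r))
}
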