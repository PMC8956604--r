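---
title: "Methods: scoring CRISPRa resistance screens and tumor-immune association"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: scoring CRISPRa resistance screens and tumor-immune association}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(crisprhit)
```

# The problem

Pooled CRISPR activation (CRISPRa) screens upregulate one gene per cell
across a whole library of guide RNAs and then apply a selective pressure —
here, co-culture with cytotoxic T cells. Cells whose activated gene confers
resistance survive and their guides become over-represented in the
sequenced library. Calling genes from such screens is harder than in a
typical dropout screen: co-cultures with primary T cells from different
donors are noisy, replicates correlate modestly, and strong selection skews
the library so that naive per-guide statistics are dominated by a few
surviving clones. This package implements the full calling chain — guide
normalization, enrichment ranking, gene-level rank aggregation, empirical
FDR against housekeeping controls, replicate-overlap candidate selection —
and the downstream patient-cohort analyses used to ask whether candidate
resistance genes matter in tumors (cytolytic-activity correlation, ssGSEA
responder/nonresponder comparison), exercised end to end on synthetic data
with planted, recoverable signal.

# Screen scoring model

## Guide-level statistic

Counts are normalized either by total count (each sample rescaled to the
mean library size) or, by default, by median-of-ratios size factors, which
tolerate the composition shift a strong positive selection induces. The
guide statistic is a pseudocount-stabilized log fold change,

$$\mathrm{lfc}_g = \log_2 \frac{n^{\mathrm{sel}}_g + c}{n^{\mathrm{ctl}}_g + c},
\qquad c = 1,$$

against the replicate's paired no-T-cell control. Each guide then receives
a normalized rank $r_g \in (0, 1]$ of $-\mathrm{lfc}$ (rank $1/N$ = most
enriched), with midranks for ties so that ports of the pipeline agree
bit-for-bit on tied inputs.

## Gene-level robust rank aggregation

For a gene with sorted guide ranks $r_{(1)} \le \dots \le r_{(k)}$, guides
beyond the aggregation percentile $\alpha$ are ignored and

$$\rho = \min_{j : r_{(j)} \le \alpha}
  P\!\left(\mathrm{Beta}(j,\, k - j + 1) \le r_{(j)}\right),$$

the tail probability that the $j$-th order statistic of $k$ uniform ranks
falls at or below the observed one. This is the alpha-RRA statistic used by
MAGeCK-style screen analysis. A gene with no retained guide gets
$\rho = 1$. Significance comes from a permutation null: for every gene size
class $k$, `n_permutations` draws of $k$ ranks (without replacement) from
the pooled observed rank list, with

$$p_{\mathrm{perm}} = \frac{1 + \#\{\rho_{\mathrm{null}} \le
\rho_{\mathrm{obs}}\}}{1 + n_{\mathrm{perm}}},$$

so the p-value is never exactly zero. Genes are ranked by
$(p_{\mathrm{perm}}, \rho, -\overline{\mathrm{lfc}},\ \mathrm{symbol})$ — a
deterministic total order.

Parameter defaults and rationale:

* `alpha = 0.05`. With three guides per target, resistance calls should
  require consistent behavior of a gene's guides near the top of the
  ranking; a strict percentile focuses $\rho$ on exactly that. It is a
  free parameter.
* `pseudocount = 1` stabilizes LFC at low counts.
* `n_permutations = 10000` by default; the suite and the examples use
  1000–2000 where only rank order matters, since ties in $p_{\mathrm{perm}}$
  are broken by the continuous $\rho$.
* Scoring is one-sided (enrichment only): a survival screen reads out
  positive selection, and depletion is confounded with fitness.
* Targets are scored at the library's target (isoform) level and collapsed
  to gene symbols by the best-scoring target; with the default one isoform
  per simulated gene the two levels coincide. Scoring at target level
  first keeps the permutation size classes honest when isoform counts vary.

## Empirical FDR and candidate selection

The screen's false-discovery estimate is deliberately nonparametric: for
each gene, the fraction of designated housekeeping negative-control genes
whose mean guide LFC is *strictly* higher. Housekeeping genes (ribosomal
proteins, polymerases, translation factors) are assumed selection-neutral,
so they trace the null enrichment distribution under the actual noise of
the experiment. "Average sgRNA enrichment" is taken as the arithmetic mean
of guide log2 fold changes — the most direct reading — with a $\rho$-based
variant available by ranking on $\rho$ instead.

Candidates are genes ranked in the top fraction (`ceiling(f * n)` genes,
an inclusive reading of a "top f%" rule) of at least `min_replicates`
replicate rankings, with acute- and chronic-arm replicates pooled into one
list. Under two independent null replicates the expected candidate count is
$f^2 n$ — about one gene for $f = 0.01$, $n = 10{,}000$ — which the test
suite verifies on all-null simulations.

# The synthetic screen

The generator defines the conditions under which every downstream claim is
tested:

* **Baseline library**: per-guide abundances drawn log-normal with
  $\sigma = 0.5$ on the natural-log scale, reproducing the right-skewed
  distributions of pooled plasmid libraries.
* **Selection**: each round multiplies a guide's abundance by its gene's
  effect (a per-round fitness advantage, 1 for all but the planted
  resistance genes) and renormalizes; one round models acute exposure,
  three rounds chronic exposure. Effector-to-target ratios and exposure
  times are biological settings outside the count model.
* **Sequencing**: negative-binomial counts with mean
  $\mu_g = a_g \cdot \mathrm{depth} \cdot N$ and variance
  $\mu + \alpha\mu^2$, $\alpha = 0.2$ — standard overdispersion for screen
  sequencing — at a mean depth of 500 reads per guide.
* **Controls**: negative-control genes are guaranteed effect 1, since they
  serve as the empirical null downstream; planted genes are drawn from the
  non-control pool.
* **Determinism**: all randomness flows from one integer seed through a
  documented sub-seed derivation per replicate and stage, so outputs are
  reproducible piecewise.

The standard spike-in instance used throughout the tests is 1,000 genes
$\times$ 3 guides, 50 planted genes with per-round effect 2.0, chronic
(3-round) selection, 2 replicates. The magnitude of a true resistance
effect is unknowable from first principles; 2.0 per round was chosen once
as a moderate advantage — after three rounds an 8-fold abundance gain,
comparable to what strong survivors show in enrichment screens — and is a
config parameter, not a constant.

Two consequences of these conditions are worth stating explicitly. First,
with 50 of 1,000 genes planted (5%), a top-1% cut can contain at most 10
genes, so *recall* is assessed at the top 5% (where ≥80% of planted genes
land per replicate) while the stricter top-1%/≥2-replicate rule is
assessed as *precision*: essentially every gene it admits is planted.
Second, the selection recursion increases the Gini coefficient of the
selected arm's abundances strictly every round, but at depth 500 the
round-0 to round-1 increment (~0.012) is smaller than the sampling noise
of the count-level Gini estimate, so strict per-round monotonicity of
*counts* holds in most but not all screens; across rounds 0→3 together the
increase (~0.13) is unambiguous in every simulated screen.

# Pathway enrichment and redundancy pruning

Enrichment of the candidate set against a GMT collection is the upper-tail
hypergeometric test, conditioned on a universe that defaults to every gene
scored in the screen (enrichment should condition on what could have been
a candidate). Sets are restricted to the universe and filtered to an
in-universe size of 5–200 before testing; Benjamini–Hochberg is applied
over the tested family only; sets with FDR < 0.05 are reported.

Redundancy pruning sorts the surviving sets by FDR (ties by raw p, then
set id, for determinism) and excludes any set whose members overlap a
lower-FDR set by more than 30% *of its own size* — the set being examined
is the one whose redundancy is in question, so it supplies the
denominator. The default rule compares against **all** lower-FDR sets,
the literal reading of "overlapping a different pathway with lower FDR";
a greedy variant comparing only against already-retained sets is available
behind `compare = "retained_only"`, since both readings are defensible.
Both are tested against a brute-force all-pairs filter.

# Tumor-cohort association

## Cytolytic activity

Local immune cytolytic activity is the geometric mean of the effector
transcripts granzyme A and perforin 1 on the linear expression scale,
$\mathrm{CYT} = \sqrt{(\mathrm{GZMA} + \delta)(\mathrm{PRF1} + \delta)}$
with $\delta = 0.01$ tolerating unexpressed markers. Correlations between
gene expression and CYT are computed on the cohort's stored scale —
log2(TPM+1) cohorts correlate against $\log_2(\mathrm{CYT} + 1)$ — because
bulk cohorts are conventionally analyzed in log space; a linear-scale CYT
option is exposed. Significance uses the Fisher transformation,
$z = \operatorname{atanh}(r)\sqrt{n - 3}$, two-sided against the standard
normal (the transformation itself does not fix a side; "positively
correlated" is then the conjunction of $r > 0$ and FDR < 0.05). BH is
applied within tumor type, the family a per-type heatmap implies; a
pan-cancer family is a one-line change.

## ssGSEA and responder comparison

The per-sample signature score follows the rank-weighted ECDF form of
single-sample GSEA with its customary defaults: genes ranked by expression,
rank-normalized (top gene takes value $N$), in-set ECDF steps proportional
to $\mathrm{rank}^{0.25}$ normalized over set members, out-of-set steps
$1/(N - m)$, ES the sum of the ECDF differences over all positions, and
NES = ES divided by the ES range across the samples of the run (hence at
least two samples). Scores are z-scored within each dataset (ddof = 1) so
cohorts profiled on different platforms can be aggregated, and responders
and nonresponders are compared with a two-tailed two-sample t test
(pooled-variance by default, mirroring the generic test; Welch behind a
flag). Responder labels are fixed upstream by the cohort loader
(complete/partial response, clinical benefit, or no progression map to
"responder").

The cohort generator plants this structure directly: a latent per-sample
immune-activity factor drives the two marker genes almost
deterministically, signature genes track the factor with a configured
Pearson correlation, and nonresponders carry a configured standardized
upward shift of signature-gene expression. It emulates the statistical
skeleton of real cohorts — it does not model tumor purity, batch effects
within a dataset, compositional normalization artifacts, or correlated
co-expression modules, so passing tests demonstrate calibration and power
of the statistics under their own assumptions, not robustness to every
failure mode of real RNA-seq.

# Numerical choices and degenerate inputs

* Permutation p-values are floored by the +1 correction; Fisher-z and
  t-test p-values are floored at the smallest positive double on perfect
  correlation or zero variance of the difference.
* Zero-variance genes in the correlation stage yield `r = NA`, `p = 1`
  and a logged note rather than an error: flat genes are common in
  filtered cohorts.
* Ties: guide LFC ties take midranks; ranking ties fall through
  $p_{\mathrm{perm}} \to \rho \to \overline{\mathrm{lfc}} \to$ symbol;
  FDR ties in pruning fall through raw p to set id; ties between a gene
  and a control mean LFC are resolved strictly (they do not inflate the
  empirical FDR) and logged.
* Median-ratio normalization requires a guide with positive counts in
  every sample and otherwise fails with a pointer to total-count
  normalization.
* BED peak intervals are converted from 0-based half-open to the 1-based
  closed convention on import; promoter windows are closed intervals of
  width upstream + downstream + 1 and a 1-bp touch counts as overlap.
* Detection thresholds for differential expression are interpreted on the
  TPM scale (TPM ≥ 10); interpreting the same number on the log2 scale
  would demand TPM ≥ 1023, an implausibly stringent filter, but a flag
  supports it.

# Problem sizes

The shipped tests run the full chain at sizes chosen to make Monte-Carlo
bounds tight while keeping the suite quick: 10,000-gene null screens
(20 seeds) for FDR calibration, the 1,000-gene spike-in for recovery,
1,000 simulated cohorts for type-I rates, 200 for shift-detection power,
and exhaustive enumeration oracles at $N \le 25$ (hypergeometric),
9 guides (permutation null), and 50 genes (ssGSEA).

# Known limitations

* The screen model plants multiplicative, round-constant effects; it does
  not model guide-efficiency heterogeneity, off-target activation,
  multiple integration at high MOI, or clone-level drift, so it
  understates some real-world variance components.
* The empirical FDR inherits the quality of the housekeeping panel; genes
  whose controls are themselves under selection would bias it.
* ssGSEA NES normalization by the across-run ES range makes NES values
  run-relative; comparisons are only meaningful within a scored run,
  which is why z-scoring within dataset precedes any pooled test.
* No survival analysis, copy-number analysis, or external data download
  is included.

# A worked run

```{r, eval = FALSE}
lib <- generate_library(1000, 3, n_negative_controls = 100, seed = 1)
scr <- simulate_screen(lib, screen_sim_config(
  n_resistance_genes = 50, effect_size = 2, rounds = 3, n_replicates = 2,
  seed = 1))
rks <- lapply(1:2, function(i) {
  rk <- score_screen(scr, i, n_permutations = 2000, seed = i)
  empirical_fdr(rk, scr$negative_control_genes)
})
select_candidates(rks, top_fraction = 0.05, min_replicates = 2)
```
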