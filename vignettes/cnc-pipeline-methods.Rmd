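---
title: "Methods: from two-group lncRNA/mRNA arrays to co-expression networks and biomarker statistics"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: from two-group lncRNA/mRNA arrays to co-expression networks and biomarker statistics}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(cncnet)
```

# Scope and model

`cncnet` implements the computational chain used in cadmium-toxicology
transcriptomics studies that profile long non-coding RNAs (lncRNAs) and
mRNAs on a two-color style array in a two-group design (here: Cd-transformed
versus untreated bronchial epithelial cells), then interpret the results
through a coding--non-coding co-expression (CNC) network and downstream
biomarker statistics on exposed-worker cohorts and comet-assay DNA-damage
measurements. Every stage is a plain function over explicit containers, and
a synthetic-data generator plants ground truth for all of them, so the whole
chain is testable without any array data.

The stages, in order:

1. **Quantile normalization** of the probes-by-samples intensity matrix
   (via `limma::normalizeQuantiles`): afterwards every sample shares the
   across-sample mean order statistics.
2. **Transcript-to-gene collapse** for coding probes only: per-sample
   *median* across a gene's transcripts (even counts: mean of the central
   pair); lncRNA probes pass through untouched.
3. **Differential screening**: the linear fold change `FC` is the ratio of
   treated to control group means on the linear scale; the P value is a
   two-sample t-test on log2 intensities. A feature is *up* iff
   `FC >= 2` and `p <= 0.05`, *down* iff `FC <= 1/2` and `p <= 0.05`
   (both thresholds configurable, applied as closed inequalities).
   `log2fc` is the log2 of the absolute fold change signed by direction.
4. **Enrichment**: one-sided hypergeometric (Fisher) over-representation
   tests. GO terms are tested with *elim* pruning on the ontology DAG;
   pathway gene sets with Benjamini--Hochberg FDR control.
5. **CNC network**: Pearson correlation of every differentially expressed
   lncRNA against every differentially expressed mRNA; edges kept when
   `|r| >= 0.99` and the BH q over all candidate pairs is `<= 0.05`.
   Node degree and k-core index are computed, and single-lncRNA
   subnetworks can be extracted.
6. **Cohort statistics**: Pearson/Spearman correlation, first- and
   higher-order partial correlation, one-way ANOVA with Dunnett
   many-to-one comparisons, chi-square tests on damage rates, exposure
   stratification, and `2^-ddCt` qPCR relative quantification.
7. **Comet metrics**: head/tail segmentation of 1-D intensity profiles and
   the damage metrics tail length, tail-DNA fraction, tail moment
   (`TM = tail length x tail fraction`) and Olive tail moment
   (`OTM = |tail centroid - head centroid| x tail fraction`).

# Statistical choices and their rationale

**Two-sample test.** The screening test is Student's pooled-variance t on
log2 intensities by default, with Welch available by configuration. Array
screening pipelines of this vintage computed "the fold-change and P-value
from the normalized expression" without naming the variant; the pooled test
is the common default at n = 3 per group, and offering both makes the
choice explicit. No multiple-testing correction is applied at the DE stage
by default because the screening convention is a raw `P < 0.05` paired with
the fold-change cut; BH q-values can be switched on.

**Correlation threshold reads `|r|`, not signed r.** The network retains
edges by the magnitude of the Pearson coefficient with the sign kept as an
edge attribute. A signed `r >= 0.99` rule could never produce the negative
co-expression pairs that these networks are described as containing;
reading the threshold on `|r|` reconciles the cutoff with the existence of
anti-correlated pairs.

**Only lncRNA--mRNA pairs are tested.** Network construction is strictly
bipartite; mRNA--mRNA correlation is available through the same
`pairwise_correlation()` primitive but is not part of `build_network()`.

**Edge P values.** For each pair, `t = r sqrt((n-2)/(1-r^2))` on `n - 2`
df, two-sided, with BH adjustment across all candidate pairs. Zero-variance
features cannot yield a defined r; their pairs are dropped with a message
rather than carried as NaN (they could never satisfy the threshold).

**elim enrichment.** Terms are processed bottom-up by longest-path depth
(deepest first; ties broken by lexicographic term id, fixed purely for
determinism). When a term's P falls at or below the elimination threshold
`alpha`, its *currently annotated* genes are removed from all ancestors
before those are tested. The study size `n` and universe size `N` stay
global; elimination shrinks only the term's `K` and `k`. The gene universe
is a required explicit argument everywhere — defaulting it silently (all
array genes versus detectable genes) changes every P value. GO significance
is reported on raw `p_elim < 0.05`; pathway significance on `q < 0.05`.

**Dunnett comparisons.** The adjusted P of comparison *i* is
`1 - P(max_j |T_j| <= |t_i|)` under the multivariate t distribution of the
comparison statistics with correlation
`sqrt(n_i n_j / ((n_i + n_0)(n_j + n_0)))` and the residual df. This
rectangle probability is evaluated directly with `mvtnorm::pmvt`, whose
quasi-Monte-Carlo error is controlled and far below any decision
threshold; the test suite cross-checks the result against `multcomp` and
verifies family-wise error control by null simulation.

**Partial correlation.** The recursion
`r_xy.z = (r_xy - r_xz r_yz) / sqrt((1-r_xz^2)(1-r_yz^2))` is applied
control-by-control for any order; the residual-regression formulation is
algebraically identical and serves as the independent oracle in the tests
(agreement to 1e-10). P values use the t transform on `n - 2 - k` df,
two-sided everywhere: the underlying reports state signed correlations
with significance, never one-sided claims.

**Exposure strata.** Cut points follow the occupational convention for
urinary cadmium (2 and 5 ug/g creatinine). Intervals are lower-closed /
upper-open, so a value equal to a printed cut point enters the
higher-labelled stratum; the printed "0--2 / 2--5 / >5" labels are
ambiguous exactly at the boundary, and one rule is fixed and documented.

**Comet conventions.** Profiles are 1-D (already integrated perpendicular
to the electrophoresis axis), with migration toward increasing position.
The background is a scalar per profile, supplied or estimated as the
minimum over the leading 10% of positions. The head is the contiguous
above-background region around the global peak; the boundary is the first
position past it at or below background. The damage-classification rule
behind a "DNA damage rate" is rarely stated by image-analysis software; the
default here is `tail_dna_fraction > 0.05`, configurable, and explicitly a
stand-in rather than an inference of any vendor's rule.

# The synthetic-data generator

`synthetic_config()` fixes the study conditions once; every generator is
deterministic given `(seed, config)` and restores the caller's RNG state.

**Expression.** Per-feature baselines are uniform on log2 [6, 12];
planted up/down features receive `+/- log2(FC)` in the treated group
(default linear fold change 4, comfortably past the 2.0 screening cut);
noise is additive Gaussian on the log2 scale (log-normal on the linear
scale, the standard array noise model), default SD 0.25. Three arrays per
group mirror a typical minimal two-group array design; the deposited
series this emulates does not state its replicate count, so 3 is a free
default, not inferred intent.

**Co-expression modules.** Each module is one planted-up hub lncRNA plus
mRNA partners driven by a shared standard-normal latent factor per sample
with loadings +1/-1 and residual SD `module_noise_sd`. Positive-loading
partners are drawn from the planted-up mRNAs; the one negative-loading
partner per module comes from the planted-*down* mRNAs, because the
treated-group mean shift is common to hub and partner: an up-regulated
partner with a negative loading would have its anti-correlation swamped by
the shared shift, whereas a down-regulated one has shift and loading
aligned and correlates near -1 exactly. Module features carry only the
module residual noise (their sample-to-sample variation *is* the latent
factor), which also means "all noise parameters zero" is only meaningful
for a module-free configuration — the zero-noise exact-recovery check
therefore uses `n_coexpr_modules = 0`.

An important emergent property: after DE selection, *any* two
differentially expressed features correlate strongly across samples,
because the treated/control mean shift dominates the sample-to-sample
variance. The planted modules are recovered, but the |r| >= 0.99 network
is considerably denser than the planted structure — which is exactly the
regime reported for real two-group CNC networks, where a few hundred DE
genes yield tens of thousands of qualifying pairs. Passing the
planted-recovery tests therefore demonstrates correct computation, not
that thresholded co-expression on three replicates per group isolates
mechanistic pairs.

**GO universe.** A three-branch, two-level rooted DAG over the mRNA gene
universe; annotations are made at the leaves and closed under ancestor
propagation (true-path rule). Planted enriched leaves are annotated with
the planted up-regulated mRNA genes plus a thin background.

**Exposure cohort.** A Gaussian copula with lognormal margins (positive
skew, as observed for urinary Cd). The latent normal correlation is
calibrated in closed form,
`rho = log(1 + r sqrt((e^{s_i^2}-1)(e^{s_j^2}-1))) / (s_i s_j)`,
so that the *population Pearson correlations after the marginal transform*
equal the targets exactly; rank correlations keep their copula values
because the transform is monotone. Default targets carry the reported
worker-cohort values (expression vs urinary Cd 0.676, blood Cd 0.610,
beta2-microglobulin 0.719) plus moderate positive exposure-exposure
correlations chosen to keep the matrix positive semi-definite; shape
parameters (sigma 1.0 for UCd, B2MG and expression, 0.7 for BCd) reproduce
the reported skew of these biomarkers (for the expression variable,
a coefficient of variation near 1.4). Non-positive-semi-definite target
matrices — and calibrated latent matrices that fail PSD — are refused,
never silently repaired. Medians anchor the units: 1.61 ug/g Cr (UCd),
1.5 ug/L (BCd), 300 ug/g Cr (B2MG), 1.0 (relative expression). At
n = 10^4 the sampling SD of the empirical r is about 0.0125 for the
0.61 pair and up to ~0.02 for the heaviest-tailed pairs; test tolerances
(0.03 and 0.08) are multiples of these Monte-Carlo bounds, not round
guesses.

**Comet profiles.** Each cell is a truncated-Gaussian head (center 30 um,
SD 2, support +/-8) and, for damaged classes, a truncated-Gaussian tail
(SD 4, support +/-16) displaced by a per-cell uniform distance on
[26, 60] um, carrying exactly the class tail fraction of the total mass.
Supports never overlap and both shapes are symmetric on the 0.5 um grid,
so the true OTM is exactly `distance x tail_fraction` and segmentation
recovers the planted head edge exactly. Per-cell amplitude is lognormal
(SD 0.2 on the log scale) — immaterial to the metrics, which are scale
invariant. What this generator does *not* emulate: overlapping head/tail
mass, per-pixel noise, background gradients, or the 2-D image-analysis
step; recovery at machine precision shows the metric definitions are
implemented correctly, not that segmentation is robust to imaging noise.

# Numerical and degenerate-input conventions

* Quantile normalization requires >= 2 samples; a single column has no
  reference distribution.
* Fold change at a zero (or negative) linear control mean is an error,
  not infinity: callers must pre-filter unexpressed probes. The
  "detectable probe" criterion used by array vendors is never published,
  so detection filtering is deliberately upstream of this package.
* Identical groups give `t = 0, P = 1`; a nonzero mean difference with
  zero within-group variance gives `P = 0`.
* Correlations are clipped to [-1, 1] before the t transform; |r| = 1
  maps to P = 0.
* `bh_fdr` rejects P values outside [0, 1]; `go_elim` rejects annotations
  referencing unknown terms; DAG readers reject cycles on load; all IO
  readers reject rather than repair malformed records and name the
  offending record in the error.
* Empty networks, empty study sets and tail-free comet profiles are valid
  inputs with well-defined outputs (empty results, P = 1, OTM = 0); an
  all-background comet profile is an error.

# Problem sizes

The shipped test-and-verification workloads use 600-probe arrays with 3
samples per group, 12-term ontologies over a 300-gene universe, cohorts
of 10^4 subjects for correlation recovery, 100--400 comet cells, 1,000
null replicates for the enrichment type-I check and 1,200 for the Dunnett
family-wise error check — sizes at which the brute-force oracles
(exhaustive hypergeometric enumeration, exhaustive k-core subgraph search,
literal step-up and elim transcriptions) remain feasible while the
statistical bands (3 standard errors) stay tight enough to be meaningful.

# Known limitations

* The GEO series-matrix reader ingests the processed-matrix dialect only
  (no raw vendor feature-extraction files), and the deposited scale must
  be declared by the caller: submitters do not record it uniformly.
* k-core here is the standard graph-theoretic core index. Legacy
  descriptions of CNC networks sometimes gloss k-core in terms of
  "gene expression"; that reading is not well defined and is not
  implemented.
* Published node counts for CNC networks are sometimes internally
  inconsistent between probe-level and gene-level accounting; this
  package reports whatever level it was given, and both can be computed
  by collapsing (or not) before network construction.
* No batch correction, background correction, flag filtering, network
  visualization, or pathway-topology analysis; gene sets are plain sets.
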