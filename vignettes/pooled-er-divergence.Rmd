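---
title: "Models and methods: pooled E&R divergence analysis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods: pooled E&R divergence analysis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette is the package's account of its science: the models it
fits, the simulator it tests them against, the parameters that matter,
and the places where a design decision had to be made. Nothing here
states an empirical result that the test suite or `scripts/acceptance.R`
does not itself compute.

## The experiment being modeled

Replicated evolve-and-resequence (E&R) with pooled sequencing: a founding
population assembled from 27 wild-derived isofemale lines is split into
six replicate cages; three are driven by a severe selective environment
(hypoxia, in the motivating experiment) and three are controls. Pooled
DNA from 100 flies per population (200 chromosomes) is sequenced at two
generations, an early baseline (F4) and a post-adaptation time point
(F17). Only allele counts are observed — no genotypes, no haplotypes.
The analytical question is which standing variants changed frequency
because of the treatment, over and above drift, pool sampling and
sequencing noise.

## The divergence model

For one variant and the six late-generation samples, with `alt_i` of
`depth_i` reads carrying the alternate allele:

$$\mathrm{alt}_i \sim \mathrm{Binomial}(\mathrm{depth}_i, p_i), \qquad
\mathrm{logit}(p_i) = \beta_0 + \beta_1\,\mathrm{treat}_i + u_i, \qquad
u_i \sim N(0, \sigma_u^2)$$

with one random intercept per replicate population. The random intercept
absorbs every source of extra-binomial spread that is shared within a
sample: 17 generations of drift, the sampling of 200 pool chromosomes
from the cage, and library effects. Using read counts rather than
estimated frequencies lets depth differences carry their proper weight.

The likelihood factorizes over the six observations into one-dimensional
integrals, each evaluated by adaptive Gauss–Hermite quadrature (15 nodes,
centered and scaled at the conditional mode of `u_i`) and maximized by
Nelder–Mead (tolerance 1e-10, restart from the optimum; the compiled
kernel fits ~700 models/second). `sigma_u` is estimated on the boundary-
respecting scale `|s|`; at the boundary (`sigma_u` < 1e-4) the standard
error of `beta_1` comes from the fixed-effects information profiled at
`sigma_u = 0`, the standard boundary practice. The default p-value is the
two-sided Wald test on `beta_1`. Under quasi-complete separation (a
treatment group with pooled frequency exactly 0 or 1) the Wald statistic
degenerates, so the fit is flagged and the reported p falls back to a
likelihood-ratio test against the no-treatment model. The tests verify
the fitter against a dense fixed-grid integration oracle and against
`lme4::glmer` (nAGQ = 25), which agrees to about four decimals wherever
it converges.

**Calibration caveat, quantified by the acceptance suite.** With six
observations, maximum likelihood estimates `sigma_u` badly: for a large
fraction of realistically simulated null variants the estimate collapses
to zero, leaving binomial-only standard errors and p-values that are
anti-conservative in the bulk (for this package's fitter and for lme4
alike). This is intrinsic to the per-variant GLMM at this design
size, and it is exactly why the pipeline's significance calls never use
the nominal p-value scale directly — they are calibrated by the
exhaustive label permutations below. The acceptance suite still states
the nominal-uniformity check at its face-value threshold, so that the
miscalibration is measured on every run rather than hidden.

## Permutation FDR

The six late-generation samples admit $\binom{6}{3}/2 - 1 = 9$ balanced
relabelings besides the observed one. The GLMM is refit for all nine, and
for any p-value threshold $P$ the empirical false discovery rate is the
ratio of the mean permuted exceedance count to the observed count,

$$\mathrm{FDR}(P) = \frac{\tfrac1N\sum_n \#\{p_n < P\}}{\#\{p_{obs} < P\}},$$

evaluated on the grid of distinct observed p-values with strict
inequalities. The SDV threshold is the largest grid point with FDR <
0.05; the curve is not monotonized by default (a cumulative-minimum
option exists). Refitting on relabeled samples — rather than permuting
residuals — preserves the within-population linkage and depth structure.

Two operating characteristics of this scheme are measured at study scale
by the acceptance suite, on simulations with known truth: the realized
false-discovery proportion among called SDV under a 200-driver spiked
scenario (the quantity `scripts/acceptance.R` reports), and the nominal
calibration check above. A structural caution surfaced by these runs:
strong polygenic selection creates heritable fitness variance that lowers
the effective population size of the selected replicates only, well below
that of the controls. Null variants then diverge more
under the observed labeling than under mixed relabelings, the permutation
ratio underestimates the FDR, and the realized false-discovery proportion
can exceed its nominal level. This asymmetry is a property of the
experimental design itself, not of any particular implementation.

## diffStat and generation consistency

diffStat is the smallest absolute difference among the nine pairwise
treatment-versus-control frequency comparisons, defined as 0 unless all
nine differences share one sign (a zero difference breaks the sign, since
"changed consistently" requires a direction). A literal `abs(min(...))`
misbehaves for mixed signs; the implemented rule agrees with it exactly
on the sign-consistent variants to which the statistic is meant to apply,
and both conventions are available. Generation consistency flags variants
whose F4→F17 change has the same direction in all replicates of a
treatment; magnitudes are binned at 5% width using the minimum |change|
across replicates (the magnitude every replicate reaches; the mean is
selectable), and the per-bin treatment/control count ratio is reported
with empty-denominator bins as missing, never infinite.

## Hypergeometric block scan

Each arm is tiled with 50-kb windows every 10 kb (both free parameters;
multiple scales can be scanned). A window with `n` variants of which `s`
are SDV, on an arm with `N` variants and `S` SDV, is scored by the
hypergeometric upper tail $P(X \ge s)$ — drawing `n` variants without
replacement from the arm. Windows are adjusted genome-wide by
Benjamini–Hochberg (parameter-free and conservative; a Storey-style
$\pi_0$ rescaling is optional), significant windows that overlap or abut
are merged into maximal blocks, and each block nominates the SDV with the
smallest GLMM p (ties: all reported) plus its host gene, or both flanking
genes when intergenic. Coordinates are 0-based half-open internally,
1-based in TSV outputs, native 0-based in BED.

The acceptance suite runs a locus-recovery study: one common driver
(start frequency 0.2, s = 0.3, h = 0.5) on a 2-Mb arm with
Drosophila-scale recombination (2e-8/bp), 2,000 sites, depth 80×. Block
detection is reliable there, but which variant tops the block is
substantially noisier: hitchhikers at founder-LD r² ≈ 0.25 carry about
half the driver's signal, and the per-variant ranking among them is
partly decided by which fits happen to collapse `sigma_u` to zero. The
recovery check asserts a stringent identifiability target (driver = top
variant in 8 of 10 runs) and, when it fails, fails honestly — the lesson being that
the top variant of a differentiated block should be read as a marker of
the region, not as the causal site.

## The simulator

`generate_experiment()` is a diploid Wright–Fisher forward simulator:

- **Founders.** 27 lines × 4 haploid genomes. Per-site target
  frequencies follow a 1/f spectrum truncated to [1/108, 0.5]; a line is
  fully homozygous at a site with probability `within_line_identity`
  (default 0.5 — isofemale lines are partially inbred but wild-mated).
  Each arm is partitioned into founder haplotype blocks of exponential
  length (`founder_ld_scale`, default 100 kb); within a block every line
  adopts a shared per-line template pattern with probability
  `founder_ld_strength` (default 0.5, giving between-site r² ≈ 0.25).
  This mimics the identical-by-descent chunks that a few dozen
  lab-cultured founder lines contribute, which are what make long-range
  hitchhiking possible at all; without them (per-site independent
  assignment) no SDV clustering exists for the block scan to find.
  Driver loci may force their founder target frequency (`start_freq`),
  since selection on standing variation presumes a common variant.
- **Evolution.** `ne` diploids per replicate (default 2,000, the
  reported scale of the cages). Each generation both parents of each
  offspring are drawn with probability proportional to multiplicative
  fitness over driver genotypes (1, 1+hs, 1+s), active only in selected
  replicates from `selection_onset` (default 1; the gradual environmental
  ramp is deliberately collapsed into a constant s, because the
  statistics under test see only the resulting trajectories). Gametes
  recombine by per-interval Bernoulli switches with Haldane map fractions,
  realized as a unit-rate Poisson crossover walk; arms assort
  independently; `unlinked = TRUE` makes every locus independent and
  disables founder LD.
- **Sequencing.** 100 flies sampled without replacement (both
  chromosomes enter the pool), negative-binomial depth (mean 80×,
  dispersion 5 by default; dispersion `Inf` gives Poisson), and each read
  miscalled to a uniformly chosen other nucleotide with probability
  `error_rate` (default 1e-3). Output is PoPoolation2 sync text.

A truth table (founder frequencies, per-replicate trajectories, pooled
fractions) accompanies every run. What the simulator does **not**
emulate: read-level artifacts (mapping bias, duplicates, base-quality
structure), indels (accepted downstream as extra allele classes but not
simulated), demography beyond constant `ne`, epistasis, and any
environmental schedule. Passing tests therefore speak to the statistical
machinery under the stated generative model, not to alignment-level
robustness on real reads.

## Numerical and convention choices

- Clopper–Pearson for the minor-allele lower bound (exact; bound is 0
  exactly when the minor count is 0, matching the "above zero" filter
  semantics); 0.9973 two-sided by default, with 0.95 a supported choice
  since both appear in the source description of the procedure.
- Count quantiles (third-allele 75th, coverage 95th) use the lower
  empirical quantile (type 1) — integer thresholds for count data. Filter
  thresholds are ascertained once on the full site set and recorded; the
  idempotence guarantee is re-application with recorded thresholds.
- The tri-allelic rule reads "across all populations" as merged counts
  (per-sample reading available); the low-coverage rule drops a site only
  when every sample of a generation cohort is below 10×.
- Exact two-sided binomial p by the minimum-likelihood convention
  (`binom.test`); doubled-smaller-tail optional. PBS tail baselines use
  the realized tail fraction by default, the nominal tail optionally.
- Reynolds-family FST from allele frequencies and chromosome counts with
  small-sample correction (unbiased numerator for the squared frequency
  difference); negative estimates clipped to zero with the raw value
  retained. Genotypic heterozygosity is unavailable from pools, so the
  frequency-based moment form is the appropriate member of the family.
- Seed discipline: one global seed fans out to per-stage seeds
  (`stage_seed`), all below 2^31; every simulator entry point is
  deterministic given its seed, and sync output is byte-identical across
  reruns.

## Problem sizes used by the tests

Unit tests run on hundreds of loci and small populations; the
study-scale checks use 2,000 loci with six populations of 1,000–2,000
diploids over 17 generations, ten replicate runs each — the spiked
false-discovery run, the null-calibration run, and the single-driver
recovery run. The deterministic-selection check uses 200 replicates at
ne = 10,000 against the iterated one-locus recursion
$p' = p\,(1 + sp + sh(1-p))/\bar w$, $\bar w = 1 + s(2hp(1-p) + p^2)$.
These sizes were chosen as the smallest at which the studied effects
(drift overdispersion, hitchhiking blocks, FDR behavior) are clearly
expressed.

## Known limitations

- Per-variant GLMM p-values are anti-conservative at this design size
  (six observations); all significance statements must go through the
  permutation FDR, and even that can under-control when selection changes
  the effective population size of one treatment arm only.
- The block scan's top variant is an unreliable pointer to the causal
  site under realistic founder LD.
- Indel alleles are handled by the filters but never simulated; the
  simulator is single-nucleotide biallelic.
- The ortholog stage consumes a mapping table; it does not infer
  orthology.
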