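---
title: "Methods: faster-X analysis for X1X2/0 spiders"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: faster-X analysis for X1X2/0 spiders}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
```

spiderfx implements a complete analysis chain for detecting and
interpreting faster-X evolution in species with X1X2/0 sex determination
(males carry one copy of each of two X chromosomes and no Y, as in
*Stegodyphus* social spiders). This vignette explains the statistical
models behind each stage, the defaults and why they were chosen, what the
synthetic-data generators do and do not emulate, and the numerical
decisions a maintainer would want written down.

## 1. Scaffold assignment from flow-sorted sperm pools

Sperm nuclei either carry both X chromosomes or neither, so two
flow-sorted pools — an X-free pool ("pool 0") and an X-bearing pool
("pool X") — differ only in X content. After sequencing both pools and
mapping to the genome, the statistic

$$P_0 = \frac{\mathrm{reads}_{\mathrm{pool0}}}
            {\mathrm{reads}_{\mathrm{pool0}} + \mathrm{reads}_{\mathrm{poolX}}}$$

is near 0 for X-linked scaffolds (pool-0 reads arise only through sorting
impurity) and near 0.5 for autosomal scaffolds. The stages are:

* `normalize_pools()` equalizes library sizes by down-sampling the larger
  pool read-by-read without replacement (multivariate hypergeometric), so
  $P_0$ is not biased by sequencing depth.
* `compute_p0()` forms the statistic and flags *candidates*: scaffolds
  with at least `min_poolX = 100` pool-X reads. Below that depth an X
  origin cannot be assessed and the scaffold stays unassigned.
* `fit_p0_mixture()` separates the two modes with a two-component beta
  mixture fitted by EM from several random restarts. A beta family is the
  natural choice for a proportion with one component near the boundary.
  The M-step is weighted *maximum likelihood* (moment matching is used
  only to initialize the optimizer): moment estimates are quadratically
  sensitive to stray points far from a component's core, and with a
  near-point-mass X component they inflate its variance until the
  component swallows outliers from the other mode.
* `assign_scaffolds()` converts posteriors into two thresholds at a
  nominal FDR (default 2.5%): $t_x$ is the largest $P_0$ cutoff such that
  the expected autosomal fraction among calls below it stays at or below
  the FDR, and $t_a$ mirrors this on the autosomal side. The expectation
  is evaluated along the contiguous run of scaffolds whose posterior
  already favours the called component (posterior > 1/2). Without this
  restriction the "largest cutoff" would always pad the call set with
  roughly `fdr` × n scaffolds the model itself considers non-members, and
  a perfectly separated dataset would still make false calls; with it, a
  clean gap yields a threshold inside the gap and zero realized FDR.

Scaffolds enter the likelihood unweighted (one point each), not
read-weighted; a read-weighted density is a plausible alternative reading
of the source analysis and can be emulated upstream, but it is not the
default. Exact zeros are clamped to $10^{-6}$ for the beta likelihood.

## 2. Lineage-specific dN/dS from three-species codon alignments

`lineage_counts()` re-implements a counting estimator in the
Nei–Gojobori (1986) tradition rather than ML codon models: with
synonymous divergences below 1%, multiple hits are rare and counting and
ML agree closely, while the counting estimator is dependency-free and
fast enough to permute thousands of times. Choices that matter:

* *Site counts.* Synonymous site counts per codon are averaged over the
  three sequences. Mutational opportunities that create stop codons are
  excluded from both site classes (the substitution process never fixes
  them), so S + N sites can total slightly less than the codon count
  times three.
* *Polarization.* The ancestral base at each codon position is the
  outgroup base when it matches at least one ingroup; codons with a
  position where the outgroup matches neither ingroup are unassignable
  and are excluded from numerator *and* denominator, avoiding biased
  branch attribution.
* *Multiple hits.* Differences between an inferred ancestral codon and a
  tip codon are classified by averaging over minimal mutational pathways,
  discarding paths through stop codons (all paths are kept if every one
  is blocked). The 64 × 64 pathway tables are precomputed once.
* *Pooling.* Overall estimates pool counts before dividing
  (`pool_dnds()`): $d_N = \sum N_d / \sum N_{\mathrm{sites}}$, so
  $\omega$ equals the ratio of pooled rates by construction, and the
  estimate is invariant to gene order and to splitting genes.

Uncertainty comes from bootstrapping genes (`bootstrap_genes()`, default
1,000 replicates, percentile intervals). Hypotheses are tested by
`randomization_test()`: gene labels (chromosomal class, or species
origin) are permuted, the pooled contrast is recomputed, and the
two-tailed p-value uses the add-one form
$(1 + \#\{|T_{\mathrm{null}}| \ge |T_{\mathrm{obs}}|\})/(n+1)$, with
ratio statistics compared on the log scale. The add-one form keeps
p-values valid (never zero) and uniform under the null, which the test
suite checks by simulation.

## 3. Diversity from RAD loci

`nei_pi()` is the classic Nei–Li per-site pairwise diversity with
pairwise deletion, delegated to `ape`'s raw distance matrix; a
brute-force all-pairs oracle in the test suite pins the exact semantics
(each pair's denominator counts only sites where both members carry an
unambiguous base).

Because individual RAD loci are short, confidence intervals are built on
concatenated *subalignments* (`build_subalignments()`): per population
and chromosome class, loci are concatenated in a fixed order (scaffold,
then position — the order is a package choice; determinism is what
matters), missing individuals are written as gap rows, and the
concatenation is cut into equal blocks. The universal block length is
set from the population with the smallest X coverage (default: that
population gets 15 X blocks), identical across all sets, with floor
semantics and the remainder discarded so all blocks are exactly equal.

piX/piA replicates are built by `pair_pix_pia()`: autosomal blocks are
randomly grouped into as many groups as there are X blocks, each group is
summarized by its *median* (the autosomal pi distribution is strongly
right-skewed when many blocks have zero diversity), and groups are paired
randomly with X blocks. The species contrast is a likelihood-ratio test
of `ratio ~ species + (1 | population)` fitted by ML with `lme4`,
falling back to a t-test on population means when the population variance
is estimated at zero; ratios (not log-ratios) are the default response.
Within-species differences use a one-way F-test with Tukey HSD letters.
Scaffold-level dispersion uses the coefficient of variation (SD/mean)
over scaffolds with at least three RAD loci, bootstrapped over scaffolds;
the CV is undefined and flagged when mean diversity is zero.

## 4. RAD library construction rules

`radlib` encodes the consensus and reference-building rules used for RAD
data: consensus bases are called at depth ≥ 8; depths 1–7 are masked as
N; a two-base IUPAC ambiguity is called when the strongest minority base
has ≥ 3 reads **or** frequency > 10% (the inclusive-OR reading of an
"and/or" rule; `rule = "and"` gives the conjunctive variant); consensus
sequences with ≥ 2.5% IUPAC symbols are discarded (Ns do not count);
stacks need ≥ 3 identical reads; conspecific stacks are clustered
greedily at > 98% identity (centroids visited by descending count, ties
lexicographic); one reference survives per genomic position (highest
count, then lexicographically smallest); IUPAC consensus positions are
split into two phased alleles with arbitrary phase — per-site allele
frequencies, and hence pi, are phase-invariant. Read quality scores are
not modelled: the synthetic data carries none, and all thresholds here
are count-based. Coordinates are 0-based half-open throughout.

## 5. McDonald–Kreitman test

`classify_variant()` reclassifies coding variants against the reference
codon (stop gain/loss is "other" and excluded), `build_mk_tables()`
counts polymorphisms at ≥ 10× coverage and joins lineage divergence
counts, and `mk_alpha()` computes
$\alpha = 1 - (D_s P_n)/(D_n P_s)$ with the neutrality index
$(P_n/P_s)/(D_n/D_s)$. No Jukes–Cantor or low-frequency-polymorphism
corrections are applied. Sites both polymorphic and divergent count in
both categories. The divergence counts default to this package's own
lineage counts; any external source can be supplied as a table.

## 6. Closed-form theory

Wright's effective sizes give
$N_{eX}/N_{eA} = 9(N_m+N_f) / (8(2N_m+N_f))$ — 0.75 at an equal sex
ratio, bounded in (9/16, 9/8). The X1X2/0 karyotype needs no special
treatment: both X chromosomes are hemizygous in males, so each behaves as
a standard X. `expected_pix_pia()` multiplies this by a standardization
factor anchoring the curve to an observed ratio (a multiplicative anchor
is the default; the wording of the source analysis also permits an
additive one, and the factor is an explicit argument so either can be
supplied). `invert_sex_ratio()` inverts the curve by bisection to
$10^{-6}$.

Male mutation bias uses the Miyata relation
$k_X/k_A = \tfrac{2}{3}(2+\alpha)/(1+\alpha)$, inverted in closed form as
$\alpha = (4-3k)/(3k-2)$ on its valid domain $(2/3, 4/3]$. Because X
chromosomes coalesce faster in the ancestor, the raw divergence ratio is
first divided by the relative X/A divergence time
$(T + 2 f N_A)/(T + 2 N_A)$; with the stated ancestral size
$N_A = 300{,}000$, $f = 0.75$ and $T = 400{,}000$ generations this factor
is exactly 0.85. The generation count is the unique value consistent with
the published 85% under these inputs (the original conversion from a 1 My
split is not public); it is a default, not an assertion about the
original derivation. Note the inversion is extremely sensitive near
$k = 2/3$: two-decimal rounding of $k$ moves $\alpha$ by several tenths,
so adjusted ratios should be carried at full precision when possible.

## 7. Founder-event simulations

`run_scenario()` contrasts an X and an autosomal compartment under an
identical schedule of recurrent founder events, all sizes scaled by
`ne_x/ne_a`. The engine (`simulate_compartment()`, C++) is a backward
Kingman coalescent with piecewise-constant population size and
infinite-sites mutation; a coalescent formulation makes 20,000
independent 100-bp loci a sub-second task where a forward simulator would
need hours. Defaults follow the study conditions: $N_{eA} = 20{,}000$,
$N_{eX} = 15{,}000$, $\mu = 1.2\times10^{-8}$ per site per generation,
20,000 loci of 100 bp, crashes every 50 or 100 generations to 1% or 10%
of full size, 20 chromosomes sampled. Choices:

* Crashes last one generation with instantaneous recovery by default
  (`recovery = "exponential"` regrows over the full cycle); the original
  growth handling is unstated, so the simplest model is the default.
* Founder events can also be given as an absolute chromosome count
  (`founder_chroms`). The count is on the autosomal scale and the X
  compartment's founder size is scaled by `ne_x/ne_a` like every other
  size — a founding propagule carries about three X lineages for every
  four autosomal ones. Equal *proportional* crashes perturb the ratio
  only weakly (both compartments' harmonic-mean sizes shrink together);
  the strong depression of piX/piA comes from the X compartment losing
  diversity faster than it recovers, and is most visible with few
  founders.
* Sampling happens at the end of each cycle, one generation before the
  next crash, from cycle `burn_in + 1` (default 5 cycles of burn-in)
  onward; `summarize_pn()` averages the ratio over those time points and
  bootstraps a CI.

## 8. Synthetic data: what it does and does not emulate

Every input class the pipeline consumes has a seed-deterministic
generator with known truth: sorted-pool counts (`gen_sort_counts()`:
Poisson reads proportional to scaffold length × pool composition,
log-normal scaffold lengths with sdlog 0.7), three-species codon
alignments (`gen_codon_alignments()`: uniform-mutation codon-site model
with per-branch synonymous rate and dN/dS, stop codons forbidden — under
NG86-style site counting this makes E[dS] equal the branch parameter
exactly), RAD locus alignments (`gen_population_rad()`: independent
constant-size coalescents per locus, infinite sites, phased alleles), and
exact-count MK datasets (`gen_mk_dataset()`).

Defaults mirror the study system: sorting impurity near 12% (class-mean
$P_0$ near 0.12 and 0.5), dS below 1% with a lower X rate, diversity near
$\theta_A = 0.005$ with `x_factor = 0.75`. What the generators do *not*
emulate: read quality, mapping error, indels and frameshifts, linked
selection, shared coalescent history between populations, transition/
transversion bias, and codon usage bias. Passing recovery tests therefore
demonstrates estimator correctness under the stated models, not
robustness to alignment or mapping artefacts in real data.

## 9. Orchestration, reproducibility and problem sizes

`run_pipeline()` runs every stage in dependency order from one config
(`pipeline_config()`), validating settings before any stage runs. A
single master seed is fanned out into per-stage seeds by one
`sample.int()` draw under that seed; the manifest records stage seeds,
timings and a config hash, and identical configs give byte-identical
outputs. All generators take explicit seeds and restore the caller's RNG
state.

The test suite runs the full model-recovery checks at deliberately
moderate sizes chosen as the package's own desk-scale defaults — e.g.
3,000 scaffolds over 20 sorting replicates, 2,000 genes per class for
rate recovery, the study's 20,000 autosomal + 3,000 X loci for the
piX/piA recovery, 20,000 loci for the neutral coalescent check, and ten
seeds of 8,000-locus founder-event scenarios — so the whole suite
completes in a few minutes on one core while keeping Monte-Carlo error
well inside each test's tolerance.

## 10. Known limitations

* The counting dN/dS estimator slightly underestimates rates when
  divergence is large (pathway averaging saturates); it is tuned to the
  sub-1% divergences this system presents.
* The beta mixture assumes two unimodal components; heavy contamination
  of the sorted pools (impurity ≥ 25%) merges the modes and assignment
  accuracy degrades, which the property tests document.
* The mixed-model species test treats piX/piA replicates as exchangeable
  within populations; with very few blocks the fallback t-test on
  population means is conservative.
* Coalescence-time adjustment takes the ancestral size as an external
  input; it is not estimated here.
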