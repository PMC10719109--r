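---
title: "Methods: colony phylogenomics of gene-modified haematopoiesis"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Methods: colony phylogenomics of gene-modified haematopoiesis}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

This vignette documents the models, parameter choices and numerical
decisions behind `clonotrace`, and states what the synthetic-data tests do
and do not demonstrate about real sequencing data.

## 1. The measurement model

Each methylcellulose colony grows from a single HSPC, so colony whole-genome
sequencing reads out the founder cell's somatic genome. The package's
central object (`read_count_matrix()`) holds, for each candidate mutation
and colony, the variant read count `NV` and total depth `NR`. A heterozygous
somatic mutation present in a pure colony generates `NV ~ Binomial(NR, 0.5)`;
in a colony of purity `q` (fraction of cells from the founder clone) the
expected VAF drops to `q/2`; hemizygous male X/Y sites sit at `q`. Everything
downstream — filtering, genotyping, branch assignment, sensitivity
correction — is built on this binomial read-sampling model.

## 2. Somatic filtering (`run_filter_chain()`)

Calls made against an unmatched reference retain germline polymorphisms and
recurrent artifacts. Filters are applied in a fixed order; each sees only
the survivors of the previous one:

1. **Germline** — aggregate `NV`/`NR` over all colonies; one-sided exact
   binomial test against p = 0.5 (0.95 hemizygous), alternative "less";
   Benjamini–Hochberg; somatic iff q < 1e-5. The q-threshold and BH
   correction are this package's choice, set conservatively because
   >100,000 sites are tested at once.
2. **Beta-binomial overdispersion** — true somatic variants are bimodal
   across colonies (≈50% in carriers, ≈0 elsewhere), hence strongly
   overdispersed. Per mutation we grid-maximise the beta-binomial likelihood
   over ρ ∈ [1e-6, 0.9] (41 log-spaced points, mean fixed at the aggregate
   VAF) and drop mutations with ρ̂ < 0.1. The dense-grid oracle test pins
   ρ̂ to within one grid step.
3. **Depth** — mean `NR` outside [8, 40] indicates unmappable or
   copy-altered sites; bounds applied inclusively, ties as printed.
4. **Aggregate positive** — pooling colonies with NV ≥ 3, the aggregate VAF
   must not fall significantly (p < 0.001) below a contamination-tolerant
   heterozygous null of 0.425.
5. **VAF support** — at least one colony with NV ≥ 3, NR ≥ 6 and VAF > 0.2.
   The NV/NR minima are this package's instantiation of "minimum
   thresholds"; NV ≥ 3 mirrors the positivity definition used elsewhere in
   the chain.

The chain is idempotent and invariant to row/column order (tested).

## 3. Colony QC

* **Peak VAF** (`peak_vaf()`): mode of a Gaussian KDE over a colony's
  somatic VAFs, bandwidth 0.05 on a 512-point grid over [0, 1]. The
  bandwidth is a package choice: wide enough to smooth binomial noise at
  ~12×, narrow enough to resolve a 0.35 vs 0.5 peak. Colonies with < 30
  usable VAFs are indeterminate and excluded. Purity = 2 × peak VAF.
* **Screens**: coverage < 4× → `low_coverage`; peak VAF < 0.4 (purity
  < 80%) → `non_clonal`. After a first-pass tree, each colony is tested
  branch-by-branch (aggregated counts; one-sided exact binomial tests at
  p0 = 0.425 "less" and p0 = 0.05 "greater"); a branch failing both after
  per-colony Bonferroni correction is highly inconsistent, both raw p < 0.05
  is minor; ≥ 1 highly or ≥ 3 minor inconsistencies flag the colony. The
  Bonferroni denominator is per-colony (the count of testable branches in
  that colony) — the alternative, correcting across colonies, was rejected
  as it couples one colony's verdict to the cohort size.
* **Duplicates**: repeat picks of one physical colony are near-identical on
  the tree and their private mutations are culture-acquired, with a
  distinct (C>A-rich) spectrum. Candidate pairs are tip pairs below the 5th
  percentile of pairwise divergence plus well-adjacent pairs; each member's
  private spectrum is decomposed (NNLS) into in-vitro + BM profiles, and a
  pair is a duplicate if either member has < 15 BM-attributed mutations.
  One member per duplicate cluster is kept (lexicographically first — an
  arbitrary, documented policy).

## 4. Phylogeny

Genotypes are binarized (present: NV ≥ 2 and VAF ≥ 0.15; absent: NV = 0 and
NR ≥ 6; else uncertain) and grouped by colony-support pattern. Patterns are
accepted greedily in order of decreasing *mutation* support into a laminar
family (perfect phylogeny); conflicting patterns — overwhelmingly
dropout-induced and mutation-poor — are deferred. A conflict rate above 20%
aborts with a contamination diagnosis. Every mutation is then re-assigned to
the branch maximising the binomial read-count likelihood (expected VAF
purity/2 below the branch, 0.002 elsewhere), ties broken towards the root;
this likelihood step rescues mutations whose evidence in one colony is a
single variant read. This two-step scheme is a deliberate, simpler stand-in
for parsimony-search plus likelihood reassignment tooling; its adequacy is
demonstrated by simulation recovery (RF distance 0 on clean 50-tip cohorts,
≥ 99% of mutations on their true branch at 12×) rather than by citation.

Time calibration is a constant-rate linear map of sensitivity-corrected
molecular depth to age, averaged over descendant tips to force
ultrametricity. A full Bayesian time-tree was deliberately not implemented:
only relative within-branch timing enters the driver-age formula, for which
constant-rate scaling suffices. Post-GT coalescences are internal nodes
whose subtended tips are all post-therapy colonies and whose molecular depth
exceeds the developmental epoch (50 mutations — the same threshold used to
exclude embryonic branches from signature fitting).

## 5. Burden and branch-length correction

Germline-SNP call sensitivity is the workhorse: the fraction of a colony's
germline panel recovered under the same support rule the filter chain
applies. Private branches scale by `1/p_i`; shared branches by
`1/(1 − Π(1 − p_i))` (a clade member calling the mutation rescues placement
for the rest). Two stated imperfections of the shared-branch formula —
low-coverage regions are correlated between samples, and rescue is not
guaranteed — are accepted as-is; no covariance model is attempted. For
impure colonies (peak VAF < 0.48) a Monte-Carlo clonality correction draws
`n_v ~ Binomial(N, peak VAF)` over the germline depth distribution and
scores calls against a sensitivity matrix estimated from pooled germline
outcomes (isotonically smoothed in `n_v`, since calling probability cannot
decrease with more supporting reads). 100,000 draws with a fixed default
seed: reproducibility over the last decimal.

The orthogonal asymptotic-regression route fits
`y = Asym + (R0 − Asym)·exp(−exp(lrc)·x)` to burden-vs-coverage pairs and
shifts eligible colonies (peak VAF > 0.46, ≥ 10×) to the expected 30×
burden. When a cohort is already saturated the model is degenerate and the
fit falls back to a constant curve (zero corrections) rather than failing.
Age adjustment uses a reference ageing rate of 16.8 SNVs/yr — the midpoint
of the 14–18 range the mutation-rate literature reports — configurable.

## 6. Signatures

96-channel spectra use the standard pyrimidine-strand COSMIC channel order;
purine-strand records fold by reverse complement (an involution, tested).
Exposure fitting is non-negative least squares (Lawson–Hanson): the
refitting objective of the field's standard tool is the same least-squares
criterion, so NNLS was chosen over a multinomial MLE. Branches with < 50
mutations are excluded from per-branch fits (sampling noise dominates).
The "entire branch is < 50 mutations of molecular time" definition of
embryonic branches conflates length and depth; here a branch is embryonic if
its lower node sits at molecular depth < 50. De novo signature extraction is
out of scope: the package consumes a reference profile set, and
`synthetic_signature_set()` provides a deterministic, clearly synthetic
9-profile stand-in (5 in-vivo-like, 2 culture-artifact-like, an SBS1-like
embryonic profile and a C>A-rich duplicate-derived in-vitro profile).

## 7. Vector copy number and integration sites

VCN = vector coverage / (0.5 × autosomal coverage) − background, the
background (~0.3) being the mean un-subtracted value over pre-transduction
colonies (mismapping). Integration sites are clustered per chromosome by
exact 1-D k-medians dynamic programming (k ∈ 1..3) — oracle-tested against
brute-force partition enumeration — with k selected by BIC under a
per-cluster Laplace dispersion model (the scale floored at 0.5 bp to keep
the likelihood finite for zero-spread clusters). Clusters with centres
< 1 kb apart merge first; the ≥ 4-read support threshold applies after
merging (matching the order in which the rules are stated).

## 8. Engraftment ABC

`grow_clones()` implements the urn birth process two ways: the literal
compiled cell-by-cell urn, and the exact distributional shortcut
(clone fractions ~ flat Dirichlet; sizes = 1 + multinomial). Their
equivalence is asserted by a KS test on largest-clone fractions (5,000
replicates). The ABC grid is log2-spaced with step 0.1 over [2^10, 2^16.6]
— log spacing matches the power-of-two endpoints of the stated prior and
makes the uniform grid prior log-uniform. Colonies are drawn without
replacement (population ≫ sample, so the distinction is negligible). The
point estimate is the posterior **median**; the source analysis does not
name its summary statistic, so the median was adopted for its invariance
under the log grid, and the 95% prediction interval is reported alongside.
Candidate k above the current final population size saturates at one cell
per clone. `chao_richness()` (bias-corrected Chao1, cross-checked against
vegan) provides the orthogonal VIS-based clone-count estimate.

## 9. Driver tracking and timing

Driver flagging is mechanical (gene list × consequence class); curation is
an input, not a computation. Clone trajectories aggregate duplex counts
across clone mutations, doubling `NR` at hemizygous sites; expansion is a
two-sided Fisher test between the pre-therapy and final timepoints, with
the zero-pre-VAF guard reporting a *minimum* fold change against the
pre-therapy upper Clopper–Pearson bound. The Fisher two-sided convention is
R's minimum-likelihood convention; published two-sided conventions vary,
and one printed p-value (driver proportions, 1/1,161 vs 12/1,431) is not
reproduced exactly by this convention — the comparison's direction and
significance are, and that is what the tests assert.

Retrospective timing bootstraps the panel read counts parametrically
(`NV* ~ Binomial(NR, VAF-hat)`; the resampling scheme is unstated in the
source, and the parametric binomial matches the package's read model),
ranks the driver among the panel sites (descending, ties uniform at
random), converts the panel rank to a branch-wide rank by an
order-statistic draw, and applies
`A_DRIVER = A_P + (r_f/n_mut)(A_D − A_P)`. Rank 1 = highest VAF = earliest;
the `r_f = n_mut ⇒ A_DRIVER = A_D` endpoint identity fixes the rank
direction.

## 10. The synthetic-data generator: what it emulates, what it does not

The generator reproduces the statistical structure the analysis relies on:

* constant postnatal mutation accrual (16 SNVs + 0.7 indels per HSC-year by
  default; patient age 20 y);
* a developmental burst (default 30 mutations root-to-tip) on a random-join
  early topology, each division depositing `1 + Poisson` mutations — the
  guaranteed mutation per division keeps every true branch identifiable,
  which is the premise of a topology-recovery test; real embryonic branches
  can in principle carry zero detected mutations, and such branches would be
  unrecoverable by any method;
* binomial read sampling at 12× Poisson depth with 0.002/allele error;
* a transplant bottleneck (default 3,000 clones into 1e5 active cells,
  2 years before post-GT sampling) whose sampled clone collisions appear as
  postnatal clades;
* artifact colonies: 10% two-founder mixtures, 7% duplicates (each with
  ~Poisson(30) in vitro mutations at expected VAF 0.4, i.e. acquired at or
  near the first colony division), 0.5% low-coverage failures —
  proportions chosen from the exclusion tallies of a real 2,030-colony
  cohort (10 low-coverage, 291 non-clonal, 149 duplicates);
* a 100,000-site heterozygous germline panel; ~2% hemizygous X/Y sites in
  male cohorts;
* duplex panels at Poisson 12,000× per site;
* vector evidence: true VCN ∈ {0..3}, anchored reads scattered N(0, 150 bp)
  around each true integration, 0.3 background mismapping.

It does **not** emulate: alignment and library artifacts with locus
structure (mappability, cruciform-DNA errors), correlated coverage dropout
between samples, non-constant mutation rates (e.g. disease-driven
elevation), indel-realignment noise, real genome coordinates or sequence
context beyond sampled trinucleotides, or selection during engraftment.
Passing tests therefore demonstrate correctness of the statistics under the
stated model, not robustness to every failure mode of real WGS. Duplicate
pairs are placed in adjacent wells with buffer wells between pairs — real
plates can abut unrelated colonies, in which case a well-adjacent candidate
pair containing one true duplicate would be (correctly) rejected only by
its partner's BM-rich spectrum; the either-member rule is deliberately
aggressive, as in the source analysis.

## 11. Problem sizes and determinism

All randomness flows through explicit seeds (`with_seed` internally;
pipeline stages derive child seeds from one master seed), so identical
configurations are byte-identical. The test suite runs cohorts of 20–50
colonies with 1,000–100,000-site germline panels, ABC recovery at 34 grid
points × 200 draws over 48 seeded replicates, and 1,000–2,000-replicate
bootstrap/urn checks — sizes chosen so the full suite completes in a couple
of minutes while leaving every assertion statistically comfortable.
`scripts/acceptance.R` runs the full published ABC configuration
(67 grid points × 5 population sizes × 1,000 draws).

## 12. Known limitations

* The perfect-phylogeny builder drops conflicting patterns rather than
  soft-assigning them; with heavy contamination it aborts rather than
  guessing (by design).
* Tie-broken hard assignment of mutations to branches differs from soft
  (probability-weighted) assignment; deep-vs-shallow ties default to the
  root side and are not otherwise resolved.
* Shared-branch correction under-corrects when coverage gaps are correlated
  across clade members.
* The engraftment model ignores steady-state HSC turnover; all late
  coalescences are attributed to the transplant, which is reasonable only
  within a few years of engraftment in young, polyclonal patients.
* Timing intervals account for read-sampling and panel-subsampling
  uncertainty, not for rate variation along the branch or time-tree error.
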