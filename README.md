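# clonotrace

Phylogenomic clonal tracking of haematopoietic stem cells (HSCs) through
autologous gene therapy, from whole-genome sequencing of single-cell-derived
HSPC colonies.

## The problem

Gene therapy for sickle cell disease harvests a patient's CD34+ stem/progenitor
cells, transduces them with a lentiviral vector, and returns them after
myeloablation. Three questions matter for safety and efficacy:

1. **How many transplanted cells actually engraft and keep producing blood?**
2. **Does the procedure itself mutate the genome of engrafting HSCs?**
3. **Are clones carrying leukaemia-associated driver mutations selected for?**

Because every HSC accumulates somatic mutations at a near-constant rate
(~14–18 SNVs/year), the genome of each single-cell-derived colony is a
lineage barcode. A phylogeny built over colonies sampled before and after
therapy exposes the transplant bottleneck: the fewer the engrafting cells,
the more often two sampled colonies descend from the same engrafted clone,
producing late branch points ("coalescences") in the tree.

`clonotrace` implements that analysis end to end for per-colony read-count
matrices, plus a synthetic-data generator with the same statistical
structure, so the whole pipeline is testable without access-controlled
patient data.

## What is in the box

| Stage | Functions |
| --- | --- |
| Synthetic cohorts | `sim_config()`, `simulate_hsc_phylogeny()`, `simulate_reads()`, `inject_artifacts()`, `simulate_transplant()`, `simulate_duplex()`, `simulate_cohort()` |
| Somatic filtering | `germline_exact_binomial_filter()`, `beta_binomial_filter()`, `depth_filter()`, `aggregate_positive_binomial_filter()`, `vaf_support_filter()`, `run_filter_chain()` |
| Colony QC | `peak_vaf()`, `clonality_screen()`, `tree_consistency_screen()`, `detect_duplicates()`, `define_invitro_signature()` |
| Phylogeny | `binarize_genotypes()`, `build_tree()`, `assign_mutations_to_branches()`, `count_post_gt_coalescences()`, `time_calibrate()` |
| Burden correction | `germline_sensitivity()`, `sensitivity_matrix()`, `somatic_sensitivity()`, `correct_private_branch()`, `correct_shared_branch()`, `asymptotic_regression_correction()`, `subtract_invitro()`, `excess_gt_mutations()` |
| Signatures | `mutation_spectrum()`, `fit_exposures()`, `branch_level_exposures()`, `colony_signature_contributions()` |
| Vector analysis | `vcn()`, `estimate_background()`, `call_vis()`, `classify_modified()` |
| Engraftment ABC | `grow_clones()`, `sample_coalescences()`, `abc_engraftment()`, `chao_richness()` |
| Driver tracking | `driver_proportion_test()`, `clone_vaf_trajectory()`, `expansion_test()`, `gene_burden_trajectory()`, `detection_probability()`, `duplex_denovo_filter()`, `bootstrap_driver_timing()` |
| Orchestration | `pipeline_config()`, `run_pipeline()`, `make_report()` |

## The core model: engrafting-cell number by ABC

Repopulation after transplant is modelled as a birth process: `k` engrafting
clones start at size 1 and the population grows to `n_final` cells by
repeatedly incrementing a clone chosen with probability proportional to its
current size (a Pólya urn; the resulting clone fractions are jointly
flat-Dirichlet over the `k` clones). Sampling `n` colonies from the final
population yields `n − (number of distinct clones sampled)` post-therapy
coalescences. For each `k` on a log2 grid spanning 2^10 to 2^16.6, the
likelihood of `k` is the fraction of simulated colony samples (1,000 per
clone-size distribution, pooled over final population sizes 1e5–2e6) whose
coalescence count equals the observed one; with the uniform grid prior the
normalised likelihood is the posterior, summarised by its median and 95%
prediction interval.

Mutation burdens and branch lengths are corrected for sequencing depth and
colony purity via the germline-SNP call sensitivity `p_i` of each colony:
private branches scale as `n_cSNV = n_SNV / p_i`, shared branches as
`n_cSNV = n_SNV / (1 − Π_i (1 − p_i))`. Driver acquisition is timed
retrospectively from duplex VAF ranks:
`A_DRIVER = A_P + (r_f / n_mut) × (A_D − A_P)`.

## Worked example

The published coalescence counts are directly usable. Patient SCD2: 74
post-therapy colonies, 2 post-therapy coalescences:

```r
library(clonotrace)
post <- abc_engraftment(2, 74, draws_per_sim = 300, seed = 1)
post
#> Engrafting-cell number (ABC over urn clone-size model)
#>   observed: 2 coalescences among 74 post-GT colonies
#>   estimate: 3,104 cells (95% PI 1,176 - 18,820)
```

About 3,100 engrafting long-term repopulating cells, with a wide prediction
interval — two coalescences among 74 colonies is informative but not sharp.

A full synthetic round trip (simulate → filter → QC → tree → burden →
signatures → vector → ABC):

```r
cfg <- pipeline_config(
  seed = 1,
  sim = list(n_colonies_pre = 25, n_colonies_post = 15,
             germline_snp_count = 2000, n_engrafted_true = 50,
             n_final = 5000),
  abc = list(grid_step = 0.4, n_final = 1e5, draws_per_sim = 150))
man <- run_pipeline(cfg, out_dir = "demo")
make_report(man)
#>   patient colonies excluded_low_coverage excluded_non_clonal excluded_duplicate
#> 1     PT1       40                     0                   6                  2
#>   passing pct_gene_modified mean_burden_pre mean_burden_post
#> 1      32          73.33333        388.7594         400.5003
#>   post_gt_coalescences engrafting_cells engrafting_lower engrafting_upper
#> 1                    1             1783             1024            12417
```

The QC stage finds the injected mixed and duplicate colonies; corrected
burdens sit near the simulated truth (rate × age + developmental burst ≈
364 plus in-vitro/duplicate inflation); the post-GT coalescence count feeds
the engraftment posterior. Stage outputs land in `demo/` as TSV/newick.

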