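# Shared fixtures, built once per test run and cached.

.fixtures <- new.env(parent = emptyenv())

fixture <- function(name, build) {
  if (is.null(.fixtures[[name]])) .fixtures[[name]] <- build()
  .fixtures[[name]]
}

# A clean (artifact-free) 40-colony simulation at 12x with a reduced germline
# panel; used across filter, phylogeny and burden tests.
clean_sim <- function() {
  fixture("clean_sim", function() {
    cfg <- sim_config(seed = 3, n_colonies_pre = 40, n_colonies_post = 0,
                      germline_snp_count = 20000, contamination_fraction = 0,
                      duplicate_fraction = 0, lowcov_fraction = 0)
    truth <- simulate_hsc_phylogeny(cfg, n_tips = 40)
    sim <- simulate_reads(truth, cfg)
    fc <- run_filter_chain(sim$rcm)
    bt <- build_tree(binarize_genotypes(fc$rcm))
    ph <- assign_mutations_to_branches(bt$tree, fc$rcm)
    list(cfg = cfg, truth = truth, sim = sim, fc = fc, bt = bt, ph = ph)
  })
}

# A small artifact-bearing cohort for QC and pipeline tests.
artifact_cohort <- function() {
  fixture("artifact_cohort", function() {
    cfg <- sim_config(seed = 11, n_colonies_pre = 30, n_colonies_post = 20,
                      germline_snp_count = 3000, n_engrafted_true = 40,
                      n_final = 5000)
    simulate_cohort(cfg)
  })
}

# A tiny read-count matrix with known structure.
toy_rcm <- function(NV, NR, hemizygous = NULL) {
  n <- nrow(NV)
  mut <- data.frame(chrom = rep("1", n), pos = seq_len(n), ref = rep("C", n),
                    alt = rep("T", n), class = rep("SNV", n),
                    context = rep("ACA", n),
                    hemizygous = hemizygous %||% rep(FALSE, n))
  read_count_matrix(NV, NR, mut)
}

`%||%` <- function(x, y) if (is.null(x)) y else x

# evaluate expr under a fixed seed without disturbing the session RNG
with_seed_test <- function(seed, expr) withr::with_seed(seed, expr)
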