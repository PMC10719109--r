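test_that("config validation rejects impossible settings", {
  expect_error(sim_config(contamination_fraction = 0.7, duplicate_fraction = 0.5),
               "sum to at most 1")
  expect_error(sim_config(n_engrafted_true = 10, n_final = 5), "n_final")
  expect_error(sim_config(snv_rate = -1), "non-negative")
})

test_that("private branch lengths are Poisson(rate x age) and trees are seed-reproducible", {
  cfg <- sim_config(seed = 5, age_years = 20, snv_rate = 16, indel_rate = 0,
                    developmental_burst = 10)
  # two-tip trees: each private branch has mean rate x age = 320
  lens <- unlist(lapply(1:40, function(i) {
    tr <- simulate_hsc_phylogeny(cfg, n_tips = 2, seed = 1000 + i)
    tr$tree$edge.length[tr$tree$edge[, 2] <= 2]
  }))
  expect_equal(mean(lens), 320, tolerance = 3 * sqrt(320 / length(lens)) / 320 + 0.02)
  t1 <- simulate_hsc_phylogeny(cfg, n_tips = 12, seed = 42)
  t2 <- simulate_hsc_phylogeny(cfg, n_tips = 12, seed = 42)
  expect_identical(t1$newick, t2$newick)
  expect_identical(t1$mutations, t2$mutations)
  expect_error(simulate_hsc_phylogeny(sim_config(snv_rate = 0,
                                                 developmental_burst = 0)),
               "degenerate")
})

test_that("postnatal clades respect the clone cap", {
  cfg <- sim_config(seed = 2, clone_cap = 0.01,
                    driver_spec = list(list(size = 10, gene = "DNMT3A"),
                                       list(size = 5, gene = "TET2")))
  tr <- simulate_hsc_phylogeny(cfg, n_tips = 200)
  clades <- setdiff(tr$postnatal_nodes, tr$tree$tip.label)
  nl <- c(tr$tree$tip.label, tr$tree$node.label)
  # no postnatal internal node subtends more than 1% of 200 tips = 2
  for (b in clades) {
    node <- match(b, nl)
    ntips_below <- length(ape::extract.clade(tr$tree, node)$tip.label)
    expect_lte(ntips_below, 2)
  }
  # the driver label landed on a clade branch
  expect_true(any(tr$mutations$gene %in% "DNMT3A"))
})

test_that("every mutation sits on exactly one branch and burdens match rate x age + burst", {
  cs <- clean_sim()
  tr <- cs$truth
  ids <- unname(unlist(tr$branch_mutations))
  expect_identical(sort(ids), sort(tr$mutations$id))   # partition
  expect_false(any(duplicated(ids)))
  cfg <- cs$cfg
  expected <- (cfg$snv_rate + cfg$indel_rate) * cfg$age_years +
    cfg$developmental_burst
  se <- sd(tr$tip_burden) / sqrt(length(tr$tip_burden))
  expect_lt(abs(mean(tr$tip_burden) - expected), 2 * se + 0.02 * expected)
})

test_that("read simulation follows the binomial allele-sampling model", {
  cfg <- sim_config(seed = 8, n_colonies_pre = 6, snv_rate = 8, age_years = 10,
                    germline_snp_count = 500, mean_depth = 20, error_rate = 0)
  tr <- simulate_hsc_phylogeny(cfg, n_tips = 6)
  sim <- simulate_reads(tr, cfg, seed = 21)
  som <- rownames(sim$presence)
  nv <- sim$rcm$NV[som, ]; nr <- sim$rcm$NR[som, ]
  # absent mutations with zero error never show variant reads
  expect_true(all(nv[!sim$presence] == 0))
  # present mutations: VAF ~ 0.5 on average (hemizygous male sites higher)
  hemi <- sim$rcm$mutations[som, "hemizygous"]
  pres_auto <- sim$presence & !hemi & nr > 0
  expect_equal(sum(nv[pres_auto]) / sum(nr[pres_auto]), 0.5, tolerance = 0.02)
  # germline SNPs present everywhere at ~0.5
  gl <- sim$germline_ids
  g_auto <- !sim$rcm$mutations[gl, "hemizygous"]
  expect_equal(sum(sim$rcm$NV[gl[g_auto], ]) / sum(sim$rcm$NR[gl[g_auto], ]),
               0.5, tolerance = 0.02)
  # reduced purity halves towards purity/2
  sim2 <- simulate_reads(tr, cfg, seed = 22,
                         purity = setNames(rep(0.7, 6), tr$tree$tip.label))
  nv2 <- sim2$rcm$NV[som, ]; nr2 <- sim2$rcm$NR[som, ]
  pres2 <- sim2$presence & !hemi
  expect_equal(sum(nv2[pres2]) / sum(nr2[pres2]), 0.35, tolerance = 0.02)
})

test_that("artifact injection produces the intended colony classes", {
  co <- artifact_cohort()
  lab <- co$labels
  expect_setequal(unique(lab$artifact),
                  c("none", "non_clonal", "duplicate"))
  # duplicates share their partner's lineage mutations and add ~lambda private
  dup <- lab$colony[lab$artifact == "duplicate"][1]
  src <- lab$partner[lab$colony == dup]
  iv_dup <- grep(paste0("^V", dup), rownames(co$rcm$NV), value = TRUE)
  expect_gt(length(iv_dup), 10)   # Poisson(30) private in vitro mutations
  shared <- co$presence[, src]
  vaf_dup <- co$rcm$NV[names(shared)[shared], dup] /
    pmax(co$rcm$NR[names(shared)[shared], dup], 1)
  expect_gt(mean(vaf_dup), 0.4)   # carries the partner's true mutations
  # contaminated colonies sit at half VAF on lineage-specific mutations
  mix <- lab$colony[lab$artifact == "non_clonal"][1]
  own <- co$presence[, mix] & !co$presence[, lab$partner[lab$colony == mix]]
  vaf_mix <- sum(co$rcm$NV[names(own)[own], mix]) /
    sum(co$rcm$NR[names(own)[own], mix])
  expect_equal(vaf_mix, 0.25, tolerance = 0.05)
  expect_error(
    inject_artifacts(list(rcm = toy_rcm(matrix(0L, 1, 1), matrix(9L, 1, 1)),
                          presence = matrix(TRUE, 1, 1)),
                     NULL, sim_config(duplicate_fraction = 1,
                                      contamination_fraction = 0,
                                      lowcov_fraction = 0)),
    "at least 2")
})

test_that("transplant sampling matches the urn collision law", {
  t1 <- simulate_transplant(1, 1000, 10, seed = 1)
  expect_equal(t1$coalescences, 9L)
  t2 <- simulate_transplant(1000, 1000, 10, seed = 1)
  expect_equal(t2$coalescences, 0L)
  expect_error(simulate_transplant(10, 100, 200), "cannot sample")
  # E[coalescences] ~ C(74,2) * 2/(k+1) for k = 2700 under flat Dirichlet
  reps <- with_seed_test(99, vapply(1:3000, function(i)
    simulate_transplant(2700, 5e4, 74)$coalescences, numeric(1)))
  expect_equal(mean(reps), choose(74, 2) * 2 / 2701, tolerance = 0.08)
})

test_that("duplex panels reproduce closed-form detection arithmetic", {
  p0 <- simulate_duplex(c(t0 = 0), n_sites = 5, mean_site_depth = 1000, seed = 1)
  expect_true(all(p0$NV == 0))
  # 11 sites at 12,000x, clone at 1/11,000: P(any variant read) ~ 0.95
  hits <- with_seed_test(7, vapply(1:400, function(i) {
    p <- simulate_duplex(c(t1 = 1 / 11000), n_sites = 11,
                         mean_site_depth = 12000)
    sum(p$NV) >= 1
  }, logical(1)))
  expect_equal(mean(hits), 1 - exp(-3), tolerance = 0.045)
  a <- simulate_duplex(c(t0 = 0.01, t1 = 0.02), 10, 5000, seed = 33)
  b <- simulate_duplex(c(t0 = 0.01, t1 = 0.02), 10, 5000, seed = 33)
  expect_identical(a, b)
})

test_that("idealised caller recovers every simulated mutation at high depth", {
  cfg <- sim_config(seed = 14, n_colonies_pre = 8, germline_snp_count = 100,
                    mean_depth = 400, error_rate = 0,
                    contamination_fraction = 0, duplicate_fraction = 0,
                    lowcov_fraction = 0)
  tr <- simulate_hsc_phylogeny(cfg, n_tips = 8)
  sim <- simulate_reads(tr, cfg)
  som <- rownames(sim$presence)
  vaf <- sim$rcm$NV[som, ] / pmax(sim$rcm$NR[som, ], 1)
  called <- vaf > 0.2 & sim$rcm$NV[som, ] >= 3
  # self-consistency: every mutation is called in every carrier colony
  expect_true(all(called[sim$presence]))
  expect_false(any(called[!sim$presence]))
})
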