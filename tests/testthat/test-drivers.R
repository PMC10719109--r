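test_that("driver flagging is a mechanical gene/consequence screen", {
  mut <- data.frame(gene = c("DNMT3A", "DNMT3A", "ACTB", NA),
                    consequence = c("missense", "synonymous", "missense", NA))
  out <- flag_driver_candidates(mut, gene_list = c("DNMT3A", "TET2"))
  expect_identical(out$driver_candidate, c(TRUE, FALSE, FALSE, FALSE))
  expect_warning(flag_driver_candidates(
    data.frame(gene = "TET2", consequence = NA), "TET2"), "skipped")
})

test_that("driver-proportion comparison uses Fisher and Clopper-Pearson", {
  res <- driver_proportion_test(1, 1161, 12, 1431)
  expect_equal(res$proportion_pre, 1 / 1161)
  expect_equal(res$proportion_post, 12 / 1431)
  expect_lt(res$p_value, 0.05)
  expect_lt(unname(res$ci_pre["lower"]), 1e-4)  # near-zero lower bound at 1/1161
  # identical arms are null
  same <- driver_proportion_test(5, 100, 5, 100)
  expect_equal(same$p_value, 1)
  # extreme table against brute-force hypergeometric enumeration
  ext <- driver_proportion_test(0, 10, 10, 10)
  probs <- dhyper(0:10, 10, 10, 10)
  brute <- sum(probs[probs <= dhyper(0, 10, 10, 10) * (1 + 1e-7)])
  expect_equal(ext$p_value, brute)
  expect_equal(brute, 2 / choose(20, 10))
  expect_error(driver_proportion_test(1, 0, 1, 10), "positive")
})

test_that("clone VAF trajectories aggregate counts with the hemizygous rule", {
  panel <- data.frame(site = rep(1:3, 2), timepoint = rep(c("t0", "t1"), each = 3),
                      NV = c(5L, 5L, 5L, 10L, 10L, 10L),
                      NR = rep(10000L, 6), hemizygous = FALSE)
  tr <- clone_vaf_trajectory(panel)
  expect_equal(tr$vaf[tr$timepoint == "t0"], 15 / 30000)
  ci <- clonotrace:::clopper_pearson(15, 30000)
  expect_equal(tr$lower[1], unname(ci["lower"]))
  # hemizygous site contributes at doubled depth
  ph <- panel; ph$hemizygous <- c(TRUE, FALSE, FALSE, TRUE, FALSE, FALSE)
  trh <- clone_vaf_trajectory(ph)
  expect_equal(trh$nr[1], 40000)
  # Clopper-Pearson closed form for 0/30000
  ci0 <- clonotrace:::clopper_pearson(0, 30000)
  expect_equal(unname(ci0["upper"]), 1 - 0.025^(1 / 30000), tolerance = 1e-9)
})

test_that("expansion testing reports fold changes with the zero-VAF guard", {
  mk_panel <- function(nv0, nv1, nr = 100000L) {
    data.frame(site = c(1, 1), timepoint = c("pre", "post"),
               NV = c(nv0, nv1), NR = nr)
  }
  same <- expansion_test(mk_panel(10L, 10L), "pre", "post")
  expect_equal(same$fold_change, 1)
  expect_equal(same$p_value, 1)
  x4 <- expansion_test(mk_panel(10L, 40L), "pre", "post")
  expect_equal(x4$fold_change, 4)
  guard <- expansion_test(mk_panel(0L, 50L), "pre", "post")
  expect_true(guard$fold_is_minimum)
  expect_equal(guard$fold_change,
               (50 / 1e5) / unname(clonotrace:::clopper_pearson(0, 1e5)["upper"]))
  expect_error(expansion_test(mk_panel(1L, 2L), "pre", "absent"), "present")
})

test_that("gene burden posterior matches Beta means and a convolution oracle", {
  one <- gene_burden_trajectory(0L, 10000L, n_draws = 2e5, seed = 1)
  expect_equal(one$mean, 1 / 10002, tolerance = 0.02)
  two <- gene_burden_trajectory(c(10L, 10L), c(10000L, 10000L),
                                n_draws = 1e5, seed = 2)
  expect_equal(two$mean, 2 * 11 / 10002, tolerance = 0.02)
  # numeric convolution of the two Beta posteriors for the 97.5 percentile
  grid <- seq(0, 0.01, length.out = 20001)
  d1 <- dbeta(grid, 11, 9991)
  conv <- convolve(d1, rev(d1), type = "open")[seq_along(grid) * 2 - 1]
  conv_grid <- 2 * grid
  cdf <- cumsum(conv) / sum(conv)
  q975 <- conv_grid[which(cdf >= 0.975)[1]]
  expect_equal(two$upper, q975, tolerance = 0.03)
})

test_that("detection probability follows the closed form and is monotone", {
  p <- detection_probability(rep(12000, 11), 1 / 22000)
  expect_equal(p, 1 - (1 - 1 / 44000)^132000, tolerance = 1e-12)
  expect_equal(p, 1 - exp(-3), tolerance = 1e-3)
  expect_gt(p, 0.95)
  expect_equal(detection_probability(10, 1), 1 - 0.5^10)
  expect_equal(detection_probability(0, 0.5), 0)
  # hemizygous sites detect at the full clone frequency
  expect_gt(detection_probability(100, 0.01, hemizygous = TRUE),
            detection_probability(100, 0.01))
  # monotone in depth and frequency
  expect_gt(detection_probability(2000, 1e-4), detection_probability(1000, 1e-4))
  expect_gt(detection_probability(1000, 2e-4), detection_probability(1000, 1e-4))
})

test_that("passenger-count probability is the discrete uniform tail", {
  expect_equal(passenger_count_probability(40, 10), 31 / 41)
  expect_equal(passenger_count_probability(40, 0), 1)
  expect_equal(passenger_count_probability(40, 41), 0)
  # oracle: integrate Binomial(40, f) over f ~ U(0,1) by direct summation
  oracle <- mean(vapply(0:40, function(x)
    integrate(function(f) dbinom(x, 40, f), 0, 1)$value, numeric(1)) *
      (0:40 >= 10)) * 41
  expect_equal(passenger_count_probability(40, 10), oracle, tolerance = 1e-6)
})

test_that("duplex de novo filtering applies support, germline and contamination rules", {
  calls <- rbind(
    data.frame(variant = "v1", individual = "A", sample = "A1", NV = 2L,
               NR = 10000L, class = "SNV", annotation = "missense_variant",
               impact = "MODERATE"),
    data.frame(variant = "v2", individual = "A", sample = "A1", NV = 2L,
               NR = 10000L, class = "SNV", annotation = "missense_variant",
               impact = "MODERATE"),
    data.frame(variant = "v2", individual = "A", sample = "A2", NV = 1L,
               NR = 10000L, class = "SNV", annotation = "missense_variant",
               impact = "MODERATE"),
    data.frame(variant = "v3", individual = "A", sample = "A1", NV = 4500L,
               NR = 10000L, class = "SNV", annotation = "missense_variant",
               impact = "HIGH"),
    data.frame(variant = "v3", individual = "B", sample = "B1", NV = 10L,
               NR = 10000L, class = "SNV", annotation = "missense_variant",
               impact = "HIGH"),
    data.frame(variant = "v4", individual = "B", sample = "B1", NV = 8L,
               NR = 10000L, class = "SNV", annotation = "synonymous_variant",
               impact = "LOW"),
    data.frame(variant = "v5", individual = "B", sample = "B1", NV = 6L,
               NR = 10000L, class = "SNV", annotation = "missense_variant",
               impact = "LOW"),
    data.frame(variant = "v6", individual = "B", sample = "B1", NV = 9L,
               NR = 100L, class = "indel", annotation = "missense_variant",
               impact = "HIGH")
  )
  out <- duplex_denovo_filter(calls, wgs_sites = character(0))
  # v1: 2 reads, single sample -> dropped; v2: rescued by two samples
  expect_false("v1" %in% out$retained$variant)
  expect_true("v2" %in% out$retained$variant)
  # v3: germline VAF in A poisons B's low-VAF observation too
  expect_false("v3" %in% out$retained$variant)
  # v4 is a control; v5 fails the impact rule; v6 is an indel (excluded)
  expect_identical(out$controls$variant, "v4")
  expect_false("v5" %in% out$retained$variant)
  expect_false("v6" %in% out$retained$variant)
  # order invariance
  out2 <- duplex_denovo_filter(calls[rev(seq_len(nrow(calls))), ])
  expect_setequal(out2$retained$variant, out$retained$variant)
  # WGS-clone sites are excluded from controls
  out3 <- duplex_denovo_filter(calls, wgs_sites = "v4")
  expect_equal(nrow(out3$controls), 0)
})

test_that("driver timing bootstrap respects the branch endpoints", {
  # driver VAF far above the passengers: acquisition near the branch top
  with_seed_test(21, {
    panel <- data.frame(site = 1:41,
                        NV = c(600L, rbinom(40, 12000, 0.002)),
                        NR = 12000L)
    td <- bootstrap_driver_timing(panel, n_mut = 500, a_p = 2, a_d = 22,
                                  n_boot = 2000, seed = 7)
    expect_true(all(td$a_driver >= 2 & td$a_driver <= 22))
    expect_lt(td$median, 4)
    # driver far below all passengers: acquisition near the branch bottom
    panel2 <- data.frame(site = 1:41,
                         NV = c(5L, rbinom(40, 12000, 0.05)),
                         NR = 12000L)
    td2 <- bootstrap_driver_timing(panel2, n_mut = 500, a_p = 2, a_d = 22,
                                   n_boot = 2000, seed = 8)
    expect_gt(td2$median, 20)
    expect_true(all(td2$a_driver >= 2 & td2$a_driver <= 22))
  })
  expect_error(bootstrap_driver_timing(
    data.frame(site = 1:5, NV = 1L, NR = 100L), 500, 2, 22, n_boot = 10),
    "too few passenger")
  expect_error(bootstrap_driver_timing(
    data.frame(site = 1:41, NV = 1L, NR = 100L), 500, 22, 2, n_boot = 10),
    "A_P < A_D")
})
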