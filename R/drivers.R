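#' Flag candidate driver mutations
#'
#' Mechanical screen: mutations annotated to a gene on the supplied
#' haematological-malignancy / clonal-haematopoiesis gene list with a
#' missense, truncating or splice consequence are flagged. Manual curation
#' verdicts, where available, are an input column, not computed.
#'
#' @param mutations data frame with `gene` and `consequence` columns.
#' @param gene_list character vector of driver genes.
#' @param consequences consequence classes that qualify.
#' @return the input with a logical `driver_candidate` column; rows without
#'   annotation are skipped with a warning.
#' @export
flag_driver_candidates <- function(mutations, gene_list,
                                   consequences = c("missense", "truncating",
                                                    "splice")) {
  miss <- is.na(mutations$gene) & is.na(mutations$consequence)
  known <- !is.na(mutations$gene)
  if (any(is.na(mutations$consequence) & known)) {
    warning("mutations with a gene but no consequence annotation were skipped")
  }
  mutations$driver_candidate <- !is.na(mutations$gene) &
    mutations$gene %in% gene_list &
    !is.na(mutations$consequence) & mutations$consequence %in% consequences
  mutations
}

#' Compare pre- and post-GT driver-colony proportions
#'
#' Two-sided Fisher's exact test on the 2x2 table of driver-carrying vs other
#' colonies, with per-arm Clopper-Pearson 95% confidence intervals.
#'
#' @param k_pre,n_pre driver-carrying and total colonies pre-GT.
#' @param k_post,n_post same post-GT.
#' @return list with per-arm proportions and CIs, and the Fisher p-value.
#' @export
driver_proportion_test <- function(k_pre, n_pre, k_post, n_post) {
  assert_that(n_pre > 0 && n_post > 0, "arm sizes must be positive")
  assert_that(k_pre <= n_pre && k_post <= n_post, "k must not exceed n")
  tab <- matrix(c(k_pre, n_pre - k_pre, k_post, n_post - k_post), 2,
                dimnames = list(c("driver", "other"), c("pre", "post")))
  ft <- fisher.test(tab)
  list(
    proportion_pre = k_pre / n_pre, ci_pre = clopper_pearson(k_pre, n_pre),
    proportion_post = k_post / n_post, ci_post = clopper_pearson(k_post, n_post),
    p_value = ft$p.value, table = tab
  )
}

# adjusted depth: hemizygous sites count double (their VAF is twice the
# heterozygous expectation, so doubling NR puts them on the same scale)
adjust_depth <- function(nr, hemizygous) nr * ifelse(hemizygous, 2L, 1L)

#' Aggregate clone VAF trajectory from a duplex panel
#'
#' Per timepoint, variant and (hemizygosity-adjusted) total reads are summed
#' across all clone mutations; the aggregate VAF and its exact binomial 95%
#' CI track the clone's size over time.
#'
#' @param panel data frame with `site`, `timepoint`, `NV`, `NR` and optional
#'   `hemizygous`.
#' @return data frame per timepoint: `nv`, `nr`, `vaf`, `lower`, `upper`;
#'   zero-depth timepoints are omitted with a warning.
#' @export
clone_vaf_trajectory <- function(panel) {
  hemi <- panel$hemizygous %||% rep(FALSE, nrow(panel))
  nr_adj <- adjust_depth(panel$NR, hemi)
  tps <- unique(panel$timepoint)
  rows <- lapply(tps, function(tp) {
    sel <- panel$timepoint == tp
    nv <- sum(panel$NV[sel]); nr <- sum(nr_adj[sel])
    if (nr == 0) {
      warning("timepoint ", tp, " has zero aggregate depth; omitted")
      return(NULL)
    }
    ci <- clopper_pearson(nv, nr)
    data.frame(timepoint = tp, nv = nv, nr = nr, vaf = nv / nr,
               lower = ci[1], upper = ci[2], row.names = NULL)
  })
  do.call(rbind, rows)
}

#' Test clone expansion between two timepoints
#'
#' Two-sided Fisher's exact test on the aggregated (variant, reference) read
#' counts at the pre-therapy and final post-therapy timepoints. The fold
#' change is the VAF ratio; when the pre-GT VAF is zero, the minimum fold
#' change (post VAF over the pre-GT upper CI) is reported instead.
#'
#' @param panel as in [clone_vaf_trajectory()].
#' @param pre_timepoint,final_timepoint timepoint labels to compare.
#' @return list with `fold_change`, `fold_is_minimum`, `p_value` and the
#'   aggregate counts.
#' @export
expansion_test <- function(panel, pre_timepoint, final_timepoint) {
  traj <- clone_vaf_trajectory(panel)
  pre <- traj[traj$timepoint == pre_timepoint, ]
  fin <- traj[traj$timepoint == final_timepoint, ]
  assert_that(nrow(pre) == 1 && nrow(fin) == 1,
              "both timepoints must be present in the panel")
  tab <- matrix(c(pre$nv, pre$nr - pre$nv, fin$nv, fin$nr - fin$nv), 2)
  p <- fisher.test(tab)$p.value
  if (pre$vaf > 0) {
    list(fold_change = fin$vaf / pre$vaf, fold_is_minimum = FALSE,
         p_value = p, pre = pre, final = fin)
  } else {
    list(fold_change = fin$vaf / pre$upper, fold_is_minimum = TRUE,
         p_value = p, pre = pre, final = fin)
  }
}

#' Total gene mutation burden with Bayesian credible interval
#'
#' The burden of a gene at a timepoint is the sum of the VAFs of its
#' mutations. Each mutation's VAF gets an independent
#' `Beta(NV + 1, NR - NV + 1)` posterior; the summed-VAF posterior is formed
#' by Monte-Carlo over the per-mutation posteriors.
#'
#' @param nv,nr per-mutation variant and total read counts at one timepoint.
#' @param n_draws Monte-Carlo draws (default 100,000).
#' @param seed RNG seed.
#' @return list with `mean`, `lower`, `upper` (2.5/97.5 percentiles).
#' @export
gene_burden_trajectory <- function(nv, nr, n_draws = 1e5, seed = 1) {
  assert_that(length(nv) >= 1, "need at least one mutation")
  with_seed(seed, {
    draws <- matrix(rbeta(n_draws * length(nv), rep(nv + 1, each = n_draws),
                          rep(nr - nv + 1, each = n_draws)),
                    n_draws, length(nv))
    tot <- rowSums(draws)
    list(mean = mean(tot), lower = unname(quantile(tot, 0.025)),
         upper = unname(quantile(tot, 0.975)))
  })
}

#' Probability of detecting a clone across a site panel
#'
#' The chance that at least one variant read is seen across the panel for a
#' clone at cell frequency `f`: heterozygous sites carry the variant at VAF
#' `f/2` (hemizygous at `f`), so the detection probability is
#' `1 - prod((1 - f/2)^depth)`.
#'
#' @param depths per-site duplex depths.
#' @param f clone cell frequency in (0, 1].
#' @param hemizygous optional logical per site.
#' @return detection probability.
#' @export
detection_probability <- function(depths, f, hemizygous = NULL) {
  assert_that(f > 0 && f <= 1, "frequency must lie in (0, 1]")
  assert_that(all(depths >= 0), "depths must be non-negative")
  hemi <- hemizygous %||% rep(FALSE, length(depths))
  vaf <- ifelse(hemi, f, f / 2)
  1 - prod((1 - vaf)^depths)
}

#' Probability a driver clone has enough true passengers on the panel
#'
#' Clone mutations acquired before the driver are true passengers (VAF >= the
#' driver's); those acquired after are subclonal. If the driver arrives
#' uniformly at random over the clone's mutational lifespan, the number of
#' true passengers among `n_sequenced` sampled clone mutations is uniform on
#' `{0, ..., n_sequenced}` (a binomial mixed over a uniform fraction), so
#' `P(X >= threshold) = (n_sequenced - threshold + 1) / (n_sequenced + 1)` —
#' 31/41 (~3/4) for ten of forty.
#'
#' @param n_sequenced clone mutations on the panel (default 40).
#' @param threshold required true passengers (default 10).
#' @return the probability.
#' @export
passenger_count_probability <- function(n_sequenced = 40, threshold = 10) {
  assert_that(threshold <= n_sequenced + 1, "threshold exceeds panel size")
  if (threshold <= 0) return(1)
  (n_sequenced - threshold + 1) / (n_sequenced + 1)
}

#' Filter de novo duplex variant calls
#'
#' Applies the duplex calling rules: retain SNVs with at least 3 supporting
#' reads, or independently observed (NV >= 1) in two or more samples of the
#' same individual; drop variants reaching germline-like VAF (> 0.3) anywhere
#' — and the same variant at any VAF in other individuals, as potential cross
#' contamination; keep putatively functional classes at MODERATE/HIGH impact.
#' Control variants (synonymous/intron/upstream) are selected by class alone,
#' excluding sites already known from the WGS clones.
#'
#' @param calls data frame with columns `variant`, `individual`, `sample`,
#'   `NV`, `NR`, `class` (e.g. `"SNV"`), `annotation`, `impact`.
#' @param wgs_sites optional character vector of variant ids found in WGS
#'   clones (excluded from the control set).
#' @param functional_classes,control_classes annotation classes.
#' @param germline_vaf germline exclusion threshold (default 0.3).
#' @return list with `retained` (functional set) and `controls` data frames.
#' @export
duplex_denovo_filter <- function(calls, wgs_sites = character(0),
                                 functional_classes = c("missense_variant",
                                                        "stop_gained",
                                                        "splice_region_variant",
                                                        "splice_acceptor_variant"),
                                 control_classes = c("synonymous_variant",
                                                     "intron_variant",
                                                     "upstream_gene_variant"),
                                 germline_vaf = 0.3) {
  calls <- calls[calls$class == "SNV", , drop = FALSE]
  vaf <- calls$NV / pmax(calls$NR, 1)
  # germline / cross-contamination: variant exceeding the VAF bound in any
  # individual poisons that variant everywhere
  bad_variants <- unique(calls$variant[vaf > germline_vaf])
  calls <- calls[!(calls$variant %in% bad_variants), , drop = FALSE]
  # support: NV >= 3, or NV >= 1 in >= 2 samples of the same individual
  key <- paste(calls$variant, calls$individual)
  n_pos_samples <- ave(calls$NV >= 1, key, FUN = sum)
  supported <- calls$NV >= 3 | (calls$NV >= 1 & n_pos_samples >= 2)
  calls <- calls[supported, , drop = FALSE]
  functional <- calls$annotation %in% functional_classes &
    calls$impact %in% c("MODERATE", "HIGH")
  controls <- calls$annotation %in% control_classes &
    !(calls$variant %in% wgs_sites)
  list(retained = calls[functional, , drop = FALSE],
       controls = calls[controls, , drop = FALSE])
}

#' Retrospective driver-mutation timing by VAF-rank bootstrap
#'
#' Within a clone, earlier mutations have higher bulk VAFs. The driver's VAF
#' rank among the clone mutations on the duplex panel therefore estimates its
#' relative position along the branch. Per bootstrap, each site's variant
#' count is resampled as `Binomial(NR, VAF-hat)`; the driver's descending
#' rank `r_i` among the (up to 41) panel sites (ties broken at random) is
#' converted to a rank `r_f` among all `n_mut` branch mutations by an
#' order-statistic draw (sample 41 ranks from `1..n_mut`, sort, take position
#' `r_i`); the acquisition age is
#' `A_DRIVER = A_P + (r_f / n_mut) (A_D - A_P)` where `A_P` and `A_D` are the
#' time-tree ages of the branch's endpoints.
#'
#' @param panel one-timepoint data frame with `site`, `NV`, `NR`, optional
#'   `hemizygous`; site 1 (or `driver_site`) is the driver.
#' @param n_mut total mutations on the branch (>= panel size).
#' @param a_p,a_d ages (years) of the branch's upper and lower endpoints.
#' @param driver_site which site is the driver (default 1).
#' @param n_boot bootstrap replicates (default 10,000).
#' @param seed RNG seed.
#' @param min_passengers minimum usable passenger sites (default 10).
#' @return object of class `timing_distribution`: `a_driver` (bootstrap
#'   samples), `r_i`, `r_f`, endpoints and the median/90% interval.
#' @export
bootstrap_driver_timing <- function(panel, n_mut, a_p, a_d, driver_site = 1,
                                    n_boot = 10000, seed = NULL,
                                    min_passengers = 10) {
  assert_that(a_p < a_d, "branch endpoint ages must satisfy A_P < A_D")
  keep <- panel$NR > 0
  panel <- panel[keep, , drop = FALSE]
  assert_that(driver_site %in% panel$site, "driver site has zero depth")
  assert_that(sum(panel$site != driver_site) >= min_passengers,
              "too few passenger sites with coverage")
  n_sites <- nrow(panel)
  assert_that(n_mut >= n_sites, "n_mut must be at least the panel size")
  hemi <- panel$hemizygous %||% rep(FALSE, n_sites)
  nr_adj <- adjust_depth(panel$NR, hemi)
  vaf_hat <- panel$NV / nr_adj
  di <- which(panel$site == driver_site)
  with_seed(seed, {
    nv_star <- matrix(rbinom(n_sites * n_boot, rep(panel$NR, n_boot),
                             rep(vaf_hat, n_boot)), n_sites, n_boot)
    vaf_star <- nv_star / matrix(nr_adj, n_sites, n_boot)
    r_i <- vapply(seq_len(n_boot), function(b) {
      rank(-vaf_star[, b], ties.method = "random")[di]
    }, numeric(1))
    r_f <- vapply(r_i, function(ri) {
      sort(sample.int(n_mut, n_sites))[ri]
    }, numeric(1))
    a_driver <- a_p + (r_f / n_mut) * (a_d - a_p)
    structure(list(
      a_driver = a_driver, r_i = r_i, r_f = r_f, a_p = a_p, a_d = a_d,
      n_mut = n_mut, median = median(a_driver),
      interval90 = unname(quantile(a_driver, c(0.05, 0.95)))
    ), class = "timing_distribution")
  })
}

#' @export
print.timing_distribution <- function(x, ...) {
  cat(sprintf(
    "Driver acquisition timing: median %.1f y (90%% interval %.1f - %.1f) on branch [%.1f, %.1f] y\n",
    x$median, x$interval90[1], x$interval90[2], x$a_p, x$a_d))
  invisible(x)
}
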