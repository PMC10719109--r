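#' Post-hoc somatic mutation filters
#'
#' Candidate mutations called against an unmatched reference retain germline
#' polymorphisms and recurrent low-level artifacts. These filters operate
#' purely on the per-colony read-count matrices and are applied in a fixed
#' order by [run_filter_chain()]:
#' germline (exact binomial on aggregated counts), beta-binomial
#' overdispersion, site depth, aggregate positive-sample binomial, and
#' VAF support.
#'
#' @name somatic_filters
NULL

#' Exact binomial germline filter
#'
#' Aggregates variant and total reads across all colonies per mutation and
#' tests the aggregate against the germline expectation (heterozygous
#' autosomal p = 0.5; hemizygous male X/Y p = 0.95) with a one-sided exact
#' binomial test (alternative "less"): true somatic mutations are confined to
#' a lineage subset, so their aggregate VAF falls well below the germline
#' null. P-values are Benjamini-Hochberg adjusted; a mutation is classified
#' somatic when q < `q_max`.
#'
#' @param m a [read_count_matrix()].
#' @param q_max BH-adjusted significance threshold (default 1e-5, conservative
#'   for panels of >100,000 tested sites).
#' @param p_het,p_hemi null proportions for autosomal and hemizygous sites.
#' @return a `filter_report` data frame with per-mutation verdicts
#'   (`somatic`, `germline` or `indeterminate`) and the test q-values.
#' @export
germline_exact_binomial_filter <- function(m, q_max = 1e-5, p_het = 0.5,
                                           p_hemi = 0.95) {
  assert_that(ncol(m$NV) >= 2, "germline filter needs at least 2 colonies")
  nv <- rowSums(m$NV); nr <- rowSums(m$NR)
  p0 <- ifelse(m$mutations$hemizygous, p_hemi, p_het)
  p <- pbinom_less(nv, nr, p0)
  q <- p.adjust(p, method = "BH")
  verdict <- ifelse(nr == 0, "indeterminate", ifelse(q < q_max, "somatic", "germline"))
  data.frame(id = rownames(m$NV), filter = "germline_binomial",
             pass = verdict == "somatic", verdict = verdict,
             statistic = q, stringsAsFactors = FALSE)
}

# Beta-binomial log-likelihood of counts (nv, nr) across colonies at mean mu
# and overdispersion rho, vectorised over a grid of rho for a block of
# mutations. Returns an M x G matrix.
bb_loglik_grid <- function(NV, NR, mu, rho_grid) {
  M <- nrow(NV)
  out <- matrix(NA_real_, M, length(rho_grid))
  lc <- lchoose(NR, NV)
  for (g in seq_along(rho_grid)) {
    rho <- rho_grid[g]
    a <- mu * (1 - rho) / rho
    b <- (1 - mu) * (1 - rho) / rho
    ll <- lc + lbeta(NV + a, NR - NV + b) - lbeta(a, b)
    out[, g] <- rowSums(ll)
  }
  out
}

#' Beta-binomial overdispersion filter
#'
#' True somatic mutations are present at ~50% VAF in a subset of colonies and
#' absent elsewhere, so their read counts across colonies are strongly
#' overdispersed relative to a binomial; uniform low-level noise is not. Per
#' mutation, the overdispersion `rho` of a beta-binomial (mean fixed at the
#' aggregate VAF) is estimated by grid-search maximum likelihood over
#' `rho_grid`; mutations with `rho_hat < rho_min` are removed.
#'
#' @param m a [read_count_matrix()].
#' @param rho_min retention threshold on the estimated overdispersion
#'   (default 0.1).
#' @param rho_grid search grid, log-spaced over `[1e-6, 0.9]` by default.
#' @return a `filter_report` data frame with `rho_hat` as statistic.
#' @export
beta_binomial_filter <- function(m, rho_min = 0.1,
                                 rho_grid = exp(seq(log(1e-6), log(0.9),
                                                    length.out = 41))) {
  assert_that(ncol(m$NV) >= 5, "beta-binomial filter needs at least 5 colonies")
  nv <- rowSums(m$NV); nr <- rowSums(m$NR)
  mu <- pmin(pmax(nv / pmax(nr, 1), 1e-9), 1 - 1e-9)
  ll <- bb_loglik_grid(m$NV, m$NR, mu, rho_grid)
  rho_hat <- rho_grid[max.col(ll, ties.method = "first")]
  pass <- rho_hat >= rho_min & nv > 0
  data.frame(id = rownames(m$NV), filter = "beta_binomial", pass = pass,
             verdict = ifelse(nv == 0, "no_signal",
                              ifelse(pass, "retained", "underdispersed")),
             statistic = rho_hat, stringsAsFactors = FALSE)
}

#' Mean-depth filter
#'
#' Removes mutations whose mean depth across colonies is below 8x (poorly
#' mappable) or above 40x (collapsed repeats / CNV artifact territory).
#'
#' @param m a [read_count_matrix()].
#' @param min_mean,max_mean inclusive retention bounds on mean depth.
#' @return a `filter_report` data frame.
#' @export
depth_filter <- function(m, min_mean = 8, max_mean = 40) {
  md <- rowMeans(m$NR)
  pass <- md >= min_mean & md <= max_mean
  data.frame(id = rownames(m$NV), filter = "depth", pass = pass,
             verdict = ifelse(pass, "retained",
                              ifelse(md < min_mean, "low_depth", "high_depth")),
             statistic = md, stringsAsFactors = FALSE)
}

#' Aggregate positive-sample binomial filter
#'
#' Restricts each mutation to its positive colonies (NV >= `nv_positive`),
#' aggregates their counts, and applies a one-sided exact binomial test
#' (alternative "less") against a contamination-tolerant heterozygous null
#' (default p0 = 0.425). Mutations whose aggregate positive VAF is
#' significantly below the null (p < `p_max`) are not credible heterozygous
#' somatic mutations and are removed, as are mutations with no positive
#' colony.
#'
#' @param m a [read_count_matrix()].
#' @param nv_positive minimum variant reads defining a positive colony.
#' @param p0 null VAF (0.425 tolerates modest contamination).
#' @param p_max removal threshold on the one-sided p-value.
#' @return a `filter_report` data frame.
#' @export
aggregate_positive_binomial_filter <- function(m, nv_positive = 3, p0 = 0.425,
                                               p_max = 0.001) {
  pos <- m$NV >= nv_positive
  nv <- rowSums(m$NV * pos); nr <- rowSums(m$NR * pos)
  # hemizygous male X/Y: effective depth doubled would halve the VAF; instead
  # test against the hemizygous expectation directly
  p_null <- ifelse(m$mutations$hemizygous, min(1, 2 * p0), p0)
  p <- pbinom_less(nv, nr, p_null)
  pass <- nr > 0 & p >= p_max
  data.frame(id = rownames(m$NV), filter = "aggregate_positive", pass = pass,
             verdict = ifelse(nr == 0, "no_positive_colony",
                              ifelse(pass, "retained", "low_aggregate_vaf")),
             statistic = p, stringsAsFactors = FALSE)
}

#' VAF support filter
#'
#' Retains a mutation only if at least one colony shows convincing clonal
#' support: NV >= `nv_min`, NR >= `nr_min` and VAF > `vaf_min`.
#'
#' @param m a [read_count_matrix()].
#' @param nv_min,nr_min,vaf_min support thresholds (defaults 3 reads, 6x
#'   depth, VAF > 0.2; the VAF bound is strict as stated).
#' @return a `filter_report` data frame.
#' @export
vaf_support_filter <- function(m, nv_min = 3, nr_min = 6, vaf_min = 0.2) {
  vaf <- m$NV / pmax(m$NR, 1)
  ok <- m$NV >= nv_min & m$NR >= nr_min & vaf > vaf_min
  pass <- rowSums(ok) > 0
  data.frame(id = rownames(m$NV), filter = "vaf_support", pass = pass,
             verdict = ifelse(pass, "retained", "no_supported_colony"),
             statistic = apply(vaf, 1, max), stringsAsFactors = FALSE)
}

#' Run the full post-hoc filter chain
#'
#' Applies, in order: germline exact binomial, beta-binomial overdispersion,
#' mean depth, aggregate positive-sample binomial, and VAF support. Each
#' filter sees only the mutations surviving the previous ones; the report
#' records every verdict. The chain is idempotent on its own output.
#'
#' @param m a [read_count_matrix()].
#' @param config optional named list overriding filter parameters
#'   (`q_max`, `rho_min`, `min_mean`, `max_mean`, `nv_positive`, `p0`,
#'   `p_max`, `nv_min`, `nr_min`, `vaf_min`).
#' @return list with `rcm` (surviving mutations) and `report` (row-bound
#'   per-filter verdicts).
#' @export
run_filter_chain <- function(m, config = list()) {
  cfg <- utils::modifyList(list(
    q_max = 1e-5, rho_min = 0.1, min_mean = 8, max_mean = 40,
    nv_positive = 3, p0 = 0.425, p_max = 0.001,
    nv_min = 3, nr_min = 6, vaf_min = 0.2
  ), config)
  if (nrow(m$NV) == 0) {
    return(list(rcm = m, report = data.frame(
      id = character(0), filter = character(0), pass = logical(0),
      verdict = character(0), statistic = numeric(0))))
  }
  reports <- list()
  keep <- function(rep) rep$id[rep$pass]
  r1 <- germline_exact_binomial_filter(m, cfg$q_max)
  reports$germline <- r1
  m1 <- m[rownames(m$NV) %in% keep(r1), ]
  if (nrow(m1$NV) > 0) {
    r2 <- beta_binomial_filter(m1, cfg$rho_min)
    reports$beta_binomial <- r2
    m1 <- m1[rownames(m1$NV) %in% keep(r2), ]
  }
  if (nrow(m1$NV) > 0) {
    r3 <- depth_filter(m1, cfg$min_mean, cfg$max_mean)
    reports$depth <- r3
    m1 <- m1[rownames(m1$NV) %in% keep(r3), ]
  }
  if (nrow(m1$NV) > 0) {
    r4 <- aggregate_positive_binomial_filter(m1, cfg$nv_positive, cfg$p0, cfg$p_max)
    reports$aggregate_positive <- r4
    m1 <- m1[rownames(m1$NV) %in% keep(r4), ]
  }
  if (nrow(m1$NV) > 0) {
    r5 <- vaf_support_filter(m1, cfg$nv_min, cfg$nr_min, cfg$vaf_min)
    reports$vaf_support <- r5
    m1 <- m1[rownames(m1$NV) %in% keep(r5), ]
  }
  list(rcm = m1, report = do.call(rbind, c(reports, list(make.row.names = FALSE))))
}
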