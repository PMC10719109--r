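#' Germline-polymorphism call sensitivity of a colony
#'
#' The fraction of a reference panel of germline SNPs (or indels) that are
#' recovered in a colony's call set, used as a surrogate for the somatic
#' variant calling sensitivity at that colony's coverage.
#'
#' @param nv,nr variant and total read counts at the germline sites for this
#'   colony.
#' @param called optional logical vector saying which sites made the final
#'   call set; by default a site is called when `nv >= nv_min`.
#' @param nv_min minimum variant reads defining a call (default 3).
#' @return the sensitivity (proportion of sites called).
#' @export
germline_sensitivity <- function(nv, nr, called = NULL, nv_min = 3) {
  assert_that(length(nv) > 0, "empty germline site set")
  called <- called %||% (nv >= nv_min)
  mean(called)
}

#' Build a call-sensitivity matrix from pooled germline data
#'
#' Estimates the probability that a variant with `n_v` variant reads out of
#' `N` total is called, from germline polymorphism outcomes pooled over many
#' colonies. Sparse (n_v, N) cells inherit information through isotonic
#' smoothing in `n_v` at fixed `N` (calling probability cannot decrease with
#' more supporting reads).
#'
#' @param nv,nr integer vectors (pooled over colonies) of variant/total reads
#'   at germline sites.
#' @param called logical vector: was the site called in that colony's final
#'   set.
#' @param max_n largest total depth modelled (deeper cells use `max_n`).
#' @return a `sensitivity_matrix`: rows n_v = 0..max_n, columns N = 1..max_n.
#' @export
sensitivity_matrix <- function(nv, nr, called, max_n = 60) {
  assert_that(length(nv) == length(called), "nv and called lengths differ")
  S <- matrix(NA_real_, max_n + 1, max_n, dimnames = list(0:max_n, 1:max_n))
  nr_c <- pmin(nr, max_n); nv_c <- pmin(nv, nr_c)
  for (N in 1:max_n) {
    sel <- nr_c == N
    if (!any(sel)) next
    tab <- tapply(called[sel], factor(nv_c[sel], levels = 0:max_n), mean)
    S[, N] <- as.numeric(tab)
    known <- which(!is.na(S[, N]))
    if (length(known) >= 2) {
      iso <- isoreg(known - 1, S[known, N])
      S[known, N] <- iso$yf
    }
    # fill gaps: carry the isotonic fit outward
    if (length(known) > 0) {
      filled <- S[, N]
      for (i in seq_len(max_n + 1)) {
        if (is.na(filled[i])) {
          below <- known[known < i]
          filled[i] <- if (length(below)) S[max(below), N] else 0
        }
      }
      S[, N] <- pmin(pmax(filled, 0), 1)
    }
  }
  structure(S, class = c("sensitivity_matrix", "matrix"))
}

#' Somatic variant sensitivity with clonality correction
#'
#' For colonies of purity below ~96% (peak VAF < 0.48), germline sensitivity
#' overestimates somatic sensitivity because somatic mutations are absent
#' from the contaminating cells. This Monte-Carlo correction draws, for each
#' germline-site depth `N`, a variant read count
#' `n_v ~ Binomial(N, p_peak)` and scores a successful call with the
#' probability looked up in the sensitivity matrix; the mean success rate is
#' the somatic sensitivity. Colonies with peak VAF > 0.48 should use the
#' germline sensitivity directly.
#'
#' @param p_peak the colony's somatic peak VAF, in (0, 0.5].
#' @param depths depth distribution to sample from (the colony's germline
#'   site depths).
#' @param S a [sensitivity_matrix()].
#' @param n_draws Monte-Carlo draws (default 100,000).
#' @param seed RNG seed (default 1; reproducibility over exactness).
#' @return the estimated somatic variant sensitivity.
#' @export
somatic_sensitivity <- function(p_peak, depths, S, n_draws = 1e5, seed = 1) {
  assert_that(p_peak > 0 && p_peak <= 0.5,
              "p_peak must lie in (0, 0.5]; for higher purity use germline sensitivity")
  with_seed(seed, {
    max_n <- ncol(S)
    N <- sample(depths, n_draws, replace = TRUE)
    N <- pmin(pmax(N, 0), max_n)
    nv <- rbinom(n_draws, N, p_peak)
    ok <- N >= 1
    p_call <- numeric(n_draws)
    p_call[ok] <- S[cbind(nv[ok] + 1, N[ok])]
    p_call[is.na(p_call)] <- 0
    mean(runif(n_draws) < p_call)
  })
}

#' Correct a private branch length for call sensitivity
#'
#' `n_cSNV = n_SNV / p_i`: mutations private to colony i are missed with
#' probability `1 - p_i`, so the observed count under-estimates the branch by
#' that factor.
#'
#' @param n_snv observed SNV count on the branch.
#' @param p_i the colony's somatic variant sensitivity, in (0, 1].
#' @return corrected count.
#' @export
correct_private_branch <- function(n_snv, p_i) {
  assert_that(all(p_i > 0 & p_i <= 1), "sensitivity must lie in (0, 1]")
  n_snv / p_i
}

#' Correct a shared branch length for call sensitivity
#'
#' A mutation on a branch shared by a clade is recovered if at least one
#' clade member calls it (a single called sample rescues correct placement
#' for the rest), so the detection probability is
#' `1 - prod(1 - p_i)` and `n_cSNV = n_SNV / (1 - prod(1 - p_i))`.
#'
#' @param n_snv observed SNV count on the shared branch.
#' @param p clade members' somatic variant sensitivities.
#' @return corrected count.
#' @export
correct_shared_branch <- function(n_snv, p) {
  assert_that(length(p) >= 2, "a shared branch needs at least 2 clade members")
  assert_that(all(p >= 0 & p <= 1), "sensitivities must lie in [0, 1]")
  assert_that(any(p > 0), "all sensitivities are zero")
  n_snv / (1 - prod(1 - p))
}

#' Sensitivity-correct all branch lengths of a phylogeny
#'
#' Applies [correct_private_branch()] to terminal branches and
#' [correct_shared_branch()] to internal branches, using each colony's
#' somatic variant sensitivity. Only the SNV component of each branch is
#' scaled; indels ride along uncorrected.
#'
#' @param phylo a `colony_phylogeny`.
#' @param sensitivities named vector of per-colony somatic sensitivities.
#' @return the `colony_phylogeny` with `corrected_lengths` added and the
#'   tree's edge lengths replaced by corrected values.
#' @export
correct_branch_lengths <- function(phylo, sensitivities) {
  tree <- phylo$tree
  clades <- branch_clades(tree)
  corrected <- phylo$raw_lengths
  for (b in names(phylo$branch_mutations)) {
    ids <- phylo$branch_mutations[[b]]
    n_snv <- sum(phylo$mutations[ids, "class"] == "SNV")
    n_other <- length(ids) - n_snv
    members <- if (b == "root") tree$tip.label else clades[[b]]
    p <- sensitivities[members]
    corrected[b] <- n_other + if (length(members) == 1)
      correct_private_branch(n_snv, p) else correct_shared_branch(n_snv, p)
  }
  phylo$corrected_lengths <- corrected
  phylo$tree$edge.length <-
    as.numeric(corrected[names(branch_clades(tree))])
  phylo
}

#' Per-colony corrected burden from corrected branch lengths
#'
#' The corrected SNV burden of a colony is the sum of its corrected ancestral
#' branch lengths back to the root.
#'
#' @param phylo a `colony_phylogeny` after [correct_branch_lengths()].
#' @param corrected use corrected (default) or raw lengths.
#' @return named numeric vector of burdens per colony.
#' @export
colony_burdens <- function(phylo, corrected = TRUE) {
  lens <- if (corrected) phylo$corrected_lengths %||% phylo$raw_lengths
          else phylo$raw_lengths
  vapply(phylo$tree$tip.label, function(tip) {
    sum(lens[ancestral_branches(phylo, tip)], na.rm = TRUE)
  }, numeric(1))
}

#' Asymptotic-regression burden correction
#'
#' Called mutation counts rise with sequencing coverage and plateau near
#' ~30x. An asymptotic regression
#' `y = Asym + (R0 - Asym) exp(-exp(lrc) x)` is fitted to burden-vs-coverage
#' pairs (requires high-coverage anchor colonies); each eligible colony's
#' burden is then shifted by `yhat(30) - yhat(coverage)`. Only high-purity
#' (peak VAF > 0.46), adequately covered (>= 10x) colonies are corrected;
#' the rest are flagged.
#'
#' @param burden,coverage numeric vectors per colony.
#' @param peak_vaf per-colony peak VAF.
#' @param target reference coverage (default 30).
#' @param min_peak_vaf,min_coverage eligibility thresholds.
#' @return data frame with raw and corrected burdens, the eligibility flag,
#'   and the fitted curve as an attribute `fit`.
#' @export
asymptotic_regression_correction <- function(burden, coverage, peak_vaf,
                                             target = 30, min_peak_vaf = 0.46,
                                             min_coverage = 10) {
  assert_that(length(burden) >= 10, "need at least 10 colonies to fit")
  df <- data.frame(y = burden, x = coverage)
  fit <- tryCatch(
    # scaleOffset keeps the convergence test meaningful for near-exact fits
    nls(y ~ SSasymp(x, Asym, R0, lrc), data = df,
        control = stats::nls.control(maxiter = 200, scaleOffset = 1)),
    error = function(e) e
  )
  if (inherits(fit, "error")) {
    # a cohort already at the plateau (no burden-coverage trend) degenerates
    # the asymptotic model; treat the curve as constant (zero corrections)
    slope <- stats::lm(y ~ x, data = df)
    if (summary(slope)$coefficients["x", "Pr(>|t|)"] > 0.05) {
      fit <- stats::lm(y ~ 1, data = df)
    } else {
      stop("asymptotic regression failed to converge: ",
           conditionMessage(fit), call. = FALSE)
    }
  }
  yhat <- function(x) as.numeric(predict(fit, newdata = data.frame(x = x)))
  eligible <- peak_vaf > min_peak_vaf & coverage >= min_coverage
  corrected <- ifelse(eligible, burden + (yhat(target) - yhat(coverage)), NA)
  structure(
    data.frame(burden = burden, coverage = coverage, peak_vaf = peak_vaf,
               eligible = eligible, corrected = corrected),
    fit = fit
  )
}

#' Subtract in vitro signature exposures from a burden
#'
#' Removes the culture-acquired component of a colony's burden: the summed
#' exposures attributed to in vitro profiles are subtracted, floored at zero
#' (a warning is raised if the fit pathologically exceeds the burden).
#'
#' @param burden raw or corrected burden.
#' @param exposures named exposure vector from [fit_exposures()].
#' @param invitro_names names of the in vitro profiles (default: the
#'   `in_vitro`-flagged columns of [synthetic_signature_set()]).
#' @return adjusted burden.
#' @export
subtract_invitro <- function(burden, exposures,
                             invitro_names = c("InVitro1", "InVitro2",
                                               "InVitroDup")) {
  iv <- sum(exposures[intersect(names(exposures), invitro_names)])
  if (iv > burden) warning("in vitro exposures exceed the burden; flooring at 0")
  max(0, burden - iv)
}

#' Excess mutations attributable to gene therapy
#'
#' Subtracts the expected ageing contribution (`reference_rate x` elapsed
#' years) from each post-GT burden, then compares age-adjusted means between
#' arms with a Welch two-sided t-test.
#'
#' @param pre_burden,post_burden corrected burdens per colony in each arm.
#' @param elapsed_years years between the pre- and post-GT timepoints.
#' @param reference_rate SNVs acquired per year during normal ageing
#'   (default 16.8/yr).
#' @return list with `difference`, `conf_int`, `p_value` and the arm means.
#' @export
excess_gt_mutations <- function(pre_burden, post_burden, elapsed_years,
                                reference_rate = 16.8) {
  assert_that(length(pre_burden) >= 2 && length(post_burden) >= 2,
              "need at least 2 colonies per arm")
  adj_post <- post_burden - reference_rate * elapsed_years
  tt <- t.test(adj_post, pre_burden)
  list(difference = unname(diff(rev(tt$estimate))),
       conf_int = unname(tt$conf.int), p_value = tt$p.value,
       mean_pre = unname(tt$estimate[2]), mean_post_adjusted = unname(tt$estimate[1]))
}
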