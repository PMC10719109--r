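#' Peak VAF of a colony
#'
#' The mode of a Gaussian kernel density estimate (bandwidth 0.05, 512-point
#' grid on [0, 1]) over a colony's somatic variant allele fractions. A clonal
#' single-cell-derived colony peaks at 0.5; mixtures peak lower, and
#' purity = 2 x peak VAF (capped at 1).
#'
#' @param vafs numeric vector of somatic VAFs.
#' @param min_n minimum number of values for a stable estimate (default 30);
#'   fewer returns `NA` (indeterminate).
#' @param bw kernel bandwidth.
#' @return the peak VAF, or `NA_real_` when indeterminate.
#' @export
peak_vaf <- function(vafs, min_n = 30, bw = 0.05) {
  vafs <- vafs[!is.na(vafs)]
  if (length(vafs) < min_n) return(NA_real_)
  d <- density(vafs, bw = bw, from = 0, to = 1, n = 512)
  d$x[which.max(d$y)]
}

#' First-pass colony clonality and coverage screen
#'
#' Flags colonies with mean autosomal coverage below `min_coverage` (4x) as
#' `low_coverage` and colonies whose somatic peak VAF falls below
#' `min_peak_vaf` (0.4, i.e. purity < 80%) as `non_clonal`. Colonies with too
#' few somatic VAFs for a stable peak are `indeterminate` and excluded.
#'
#' @param m a filtered [read_count_matrix()] of somatic mutations.
#' @param coverage named mean autosomal coverage per colony (defaults to the
#'   column means of `NR`).
#' @param min_coverage,min_peak_vaf thresholds as above.
#' @param nv_positive minimum NV for a mutation to contribute a VAF.
#' @return data frame with one row per colony: `peak_vaf`, `purity`,
#'   `coverage` and a `flag` in
#'   `{pass, low_coverage, non_clonal, indeterminate}`.
#' @export
clonality_screen <- function(m, coverage = NULL, min_coverage = 4,
                             min_peak_vaf = 0.4, nv_positive = 3) {
  coverage <- coverage %||% colMeans(m$NR)
  pk <- vapply(seq_along(m$colonies), function(j) {
    sel <- m$NV[, j] >= nv_positive
    peak_vaf(m$NV[sel, j] / pmax(m$NR[sel, j], 1))
  }, numeric(1))
  flag <- ifelse(coverage[m$colonies] < min_coverage, "low_coverage",
          ifelse(is.na(pk), "indeterminate",
          ifelse(pk < min_peak_vaf, "non_clonal", "pass")))
  data.frame(colony = m$colonies, peak_vaf = pk,
             purity = pmin(1, 2 * pk), coverage = as.numeric(coverage[m$colonies]),
             flag = flag, stringsAsFactors = FALSE)
}

#' Phylogeny-consistency screen for residual non-clonal colonies
#'
#' A clonal colony should be cleanly positive (VAF ~ 0.5) or negative
#' (VAF ~ 0) on every branch of the phylogeny. Per branch, the colony's
#' variant and total reads are aggregated over the branch's mutations and
#' tested twice: (A) one-sided exact binomial, alternative "less", null
#' p0 = 0.425 (at least a contamination-tolerant heterozygous signal) and
#' (B) alternative "greater", null p0 = 0.05 (no more than background false
#' positives). A branch rejected by both tests after per-colony Bonferroni
#' correction (max q < 0.05) is highly inconsistent; both raw p < 0.05 is
#' minorly inconsistent. The colony is called non-clonal with >= 1 highly or
#' >= 3 minorly inconsistent branches.
#'
#' @param phylo a `colony_phylogeny` built from first-pass colonies.
#' @param m the [read_count_matrix()] (may include colonies not in the tree).
#' @param colony colony id to screen.
#' @param p0_present,p0_absent nulls for tests A and B.
#' @param alpha significance level.
#' @return list with `verdict` (`"pass"` or `"non_clonal"`) and the
#'   per-branch test table.
#' @export
tree_consistency_screen <- function(phylo, m, colony, p0_present = 0.425,
                                    p0_absent = 0.05, alpha = 0.05) {
  branches <- names(phylo$branch_mutations)
  rows <- lapply(branches, function(b) {
    ids <- intersect(phylo$branch_mutations[[b]], rownames(m$NV))
    if (length(ids) == 0) return(NULL)
    nv <- sum(m$NV[ids, colony]); nr <- sum(m$NR[ids, colony])
    if (nr == 0) return(NULL)
    data.frame(branch = b, nv = nv, nr = nr,
               p_less = pbinom_less(nv, nr, p0_present),
               p_greater = pbinom_greater(nv, nr, p0_absent),
               stringsAsFactors = FALSE)
  })
  tab <- do.call(rbind, rows)
  if (is.null(tab) || nrow(tab) == 0) {
    return(list(verdict = "pass", branches = tab))
  }
  B <- nrow(tab)
  tab$q_less <- pmin(1, tab$p_less * B)
  tab$q_greater <- pmin(1, tab$p_greater * B)
  tab$highly <- pmax(tab$q_less, tab$q_greater) < alpha
  tab$minorly <- pmax(tab$p_less, tab$p_greater) < alpha
  verdict <- if (any(tab$highly) || sum(tab$minorly) >= 3) "non_clonal" else "pass"
  list(verdict = verdict, branches = tab)
}

#' Define the in vitro mutational signature from confident duplicate pairs
#'
#' Pools the private mutations of well-adjacent (confident) duplicate pairs —
#' whose private branches consist almost entirely of culture-acquired
#' mutations — into a normalized 96-channel profile.
#'
#' @param mutations data frame of pooled private mutations (with `ref`,
#'   `alt`, `context`).
#' @param min_mutations minimum pooled mutations for a stable profile
#'   (default 200).
#' @return numeric vector of 96 channel probabilities summing to 1.
#' @export
define_invitro_signature <- function(mutations, min_mutations = 200) {
  assert_that(NROW(mutations) >= min_mutations,
              sprintf("need at least %d pooled mutations for a stable profile",
                      min_mutations))
  sp <- mutation_spectrum(mutations)
  assert_that(sum(sp) >= min_mutations,
              sprintf("need at least %d pooled mutations for a stable profile",
                      min_mutations))
  sp / sum(sp)
}

#' Detect colony duplicates from private-branch mutational signatures
#'
#' Colony duplicates are repeat picks of the same physical colony: their
#' private mutations are culture-acquired, not bone-marrow-acquired. For each
#' candidate pair, each member's private mutation spectrum is decomposed into
#' the in vitro and BM reference signatures by non-negative least squares;
#' the pair is called a duplicate when either member has fewer than
#' `bm_min` (15) mutations attributed to the BM signature. In each duplicate
#' cluster the lexicographically first colony is retained, the rest flagged.
#'
#' @param phylo a `colony_phylogeny` (for private branch mutation lists).
#' @param candidate_pairs two-column matrix/data frame of colony id pairs.
#' @param invitro 96-channel in vitro profile.
#' @param bm 96-channel BM (HSC-like) profile.
#' @param bm_min minimum BM-attributed mutations for a genuine in vivo
#'   relationship.
#' @return data frame, one row per candidate pair, with BM-attributed counts
#'   and the duplicate verdict, plus an attribute `flagged` listing colonies
#'   to drop.
#' @export
detect_duplicates <- function(phylo, candidate_pairs, invitro, bm, bm_min = 15) {
  profiles <- cbind(InVitro = invitro, BM = bm)
  bm_count <- function(colony) {
    ids <- phylo$branch_mutations[[colony]]
    mut <- phylo$mutations[intersect(ids, rownames(phylo$mutations)), , drop = FALSE]
    if (NROW(mut) == 0) return(c(private = 0, bm = 0))
    sp <- mutation_spectrum(mut)
    fit <- fit_exposures(sp, profiles)
    c(private = sum(sp), bm = unname(fit$exposures["BM"]))
  }
  pairs <- as.data.frame(candidate_pairs, stringsAsFactors = FALSE)
  names(pairs) <- c("colony1", "colony2")
  stats <- lapply(seq_len(nrow(pairs)), function(i) {
    a <- bm_count(pairs$colony1[i]); b <- bm_count(pairs$colony2[i])
    data.frame(pairs[i, ], private1 = a["private"], bm1 = a["bm"],
               private2 = b["private"], bm2 = b["bm"],
               duplicate = a["bm"] < bm_min || b["bm"] < bm_min,
               row.names = NULL)
  })
  out <- do.call(rbind, stats)
  # retention: build duplicate clusters, keep the first id of each
  flagged <- character(0)
  if (any(out$duplicate)) {
    g <- out[out$duplicate, c("colony1", "colony2")]
    clusters <- list()
    for (i in seq_len(nrow(g))) {
      hit <- which(vapply(clusters, function(cl)
        any(c(g$colony1[i], g$colony2[i]) %in% cl), logical(1)))
      if (length(hit) == 0) {
        clusters[[length(clusters) + 1]] <- c(g$colony1[i], g$colony2[i])
      } else {
        clusters[[hit[1]]] <- union(clusters[[hit[1]]],
                                    c(g$colony1[i], g$colony2[i]))
      }
    }
    flagged <- unlist(lapply(clusters, function(cl) sort(cl)[-1]))
  }
  structure(out, flagged = flagged)
}

#' Candidate duplicate pairs from tree divergence and well adjacency
#'
#' All tip pairs whose summed private branch lengths fall below the given
#' percentile of tip-pair divergences, plus any well-adjacent pairs.
#'
#' @param phylo a `colony_phylogeny`.
#' @param wells optional named well positions (e.g. `"A1"`); horizontally
#'   adjacent wells are candidate duplicate picks.
#' @param percentile divergence percentile below which pairs are candidates.
#' @return two-column data frame of colony pairs (may have zero rows).
#' @export
candidate_duplicate_pairs <- function(phylo, wells = NULL, percentile = 0.05) {
  tree <- phylo$tree
  tips <- tree$tip.label
  dm <- ape::cophenetic.phylo(tree)
  ut <- which(upper.tri(dm), arr.ind = TRUE)
  div <- dm[ut]
  thr <- quantile(div, percentile)
  sel <- which(div <= thr)
  out <- data.frame(colony1 = tips[ut[sel, 1]], colony2 = tips[ut[sel, 2]],
                    stringsAsFactors = FALSE)
  if (!is.null(wells)) {
    adj <- well_adjacent_pairs(wells[tips])
    out <- unique(rbind(out, adj))
  }
  out
}

# pairs of colonies in horizontally adjacent wells (same row, column +/- 1)
well_adjacent_pairs <- function(wells) {
  wells <- wells[!is.na(wells)]
  row <- substr(wells, 1, 1)
  col <- as.integer(substring(wells, 2))
  out <- list()
  nm <- names(wells)
  for (i in seq_along(wells)) for (j in seq_along(wells)) {
    if (i < j && row[i] == row[j] && abs(col[i] - col[j]) == 1) {
      out[[length(out) + 1]] <- data.frame(colony1 = min(nm[i], nm[j]),
                                           colony2 = max(nm[i], nm[j]),
                                           stringsAsFactors = FALSE)
    }
  }
  if (length(out)) unique(do.call(rbind, out)) else
    data.frame(colony1 = character(0), colony2 = character(0))
}
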