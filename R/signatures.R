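#' The 96 single-base-substitution channels
#'
#' Channel labels follow the standard pyrimidine-strand convention used by
#' COSMIC-style signature tables: six substitution types (C>A, C>G, C>T,
#' T>A, T>C, T>G), each in 16 trinucleotide contexts, ordered
#' lexicographically by 5' then 3' flanking base, e.g. `"A[C>A]A"`.
#'
#' @return character vector of length 96.
#' @export
sbs_channels <- function() {
  subs <- c("C>A", "C>G", "C>T", "T>A", "T>C", "T>G")
  flank <- c("A", "C", "G", "T")
  unlist(lapply(subs, function(s) {
    as.vector(t(outer(flank, flank, function(a, b) paste0(a, "[", s, "]", b))))
  }))
}

revcomp <- function(x) {
  vapply(x, function(s) {
    paste(rev(strsplit(chartr("ACGT", "TGCA", s), "")[[1]]), collapse = "")
  }, character(1), USE.NAMES = FALSE)
}

#' Build a 96-channel mutation spectrum
#'
#' Counts SNVs per substitution-in-trinucleotide-context channel. Purine-strand
#' calls (ref A or G) are folded onto the pyrimidine strand by
#' reverse-complementing ref, alt and context, so the spectrum is invariant to
#' the reported strand. Records with an invalid or missing context are counted
#' in a `rejected` attribute and raise a warning.
#'
#' @param mutations data frame with columns `ref`, `alt` and `context` (the
#'   reference-strand trinucleotide centred on the mutated base). Non-SNV rows
#'   (from a `class` column) are ignored.
#' @return integer vector of length 96 named by [sbs_channels()], with
#'   attribute `rejected` giving the number of unusable records.
#' @export
mutation_spectrum <- function(mutations) {
  chan <- sbs_channels()
  out <- setNames(integer(96), chan)
  if (NROW(mutations) == 0) return(structure(out, rejected = 0L))
  if (!is.null(mutations$class)) mutations <- mutations[mutations$class == "SNV", , drop = FALSE]
  ref <- as.character(mutations$ref); alt <- as.character(mutations$alt)
  ctx <- as.character(mutations$context %||% rep(NA_character_, length(ref)))
  ok <- !is.na(ctx) & nchar(ctx) == 3 & substr(ctx, 2, 2) == ref &
    ref %in% c("A", "C", "G", "T") & alt %in% c("A", "C", "G", "T") & ref != alt
  rejected <- sum(!ok)
  if (rejected > 0) warning(rejected, " mutation(s) with invalid context rejected")
  ref <- ref[ok]; alt <- alt[ok]; ctx <- ctx[ok]
  pur <- ref %in% c("A", "G")
  if (any(pur)) {
    ref[pur] <- chartr("AG", "TC", ref[pur])
    alt[pur] <- chartr("ACGT", "TGCA", alt[pur])
    ctx[pur] <- revcomp(ctx[pur])
  }
  lab <- paste0(substr(ctx, 1, 1), "[", ref, ">", alt, "]", substr(ctx, 3, 3))
  tab <- table(factor(lab, levels = chan))
  out[] <- as.integer(tab)
  structure(out, rejected = as.integer(rejected))
}

#' Synthetic reference mutational-signature set
#'
#' A deterministic, synthetic stand-in for the expanded reference set used to
#' refit colony spectra: five in-vivo-like profiles (a dominant bone-marrow
#' HSC-like profile plus four minor processes), two putative culture-artifact
#' profiles, an embryonic profile (CpG C>T dominated, SBS1-like) and an
#' "in vitro" profile of the kind derived from colony-duplicate private
#' mutations (C>A dominated, oxidative-damage-like). These are not estimates
#' from any cohort; they exist so that signature refitting, duplicate
#' detection and in-vitro burden subtraction can be exercised and tested.
#'
#' @return a 96 x 9 matrix of channel probabilities (columns sum to 1) with
#'   a logical attribute `in_vitro` marking the culture-artifact columns.
#' @export
synthetic_signature_set <- function() {
  chan <- sbs_channels()
  sub_of <- sub(".*\\[(.*)\\].*", "\\1", chan)
  ctx5 <- substr(chan, 1, 1)
  ctx3 <- substr(chan, nchar(chan), nchar(chan))
  boost <- function(w) w / sum(w)
  base <- rep(1, 96)
  profs <- list(
    # broad, gently C>T / T>C tilted clock-like profile (HSC bone marrow)
    BM = boost(base * ifelse(sub_of == "T>C", 2.0, 1) * ifelse(sub_of == "C>T", 1.6, 1)),
    SigB = boost(base * ifelse(sub_of == "T>A", 3.5, 1) * ifelse(ctx5 == "T", 1.8, 1)),
    SigC = boost(base * ifelse(sub_of == "C>G", 4.0, 1) * ifelse(ctx3 == "T", 1.7, 1)),
    SigD = boost(base * ifelse(sub_of == "T>G", 4.0, 1) * ifelse(ctx5 == "G", 1.6, 1)),
    SigE = boost(base * ifelse(sub_of == "C>T" & ctx5 == "T", 5.0, 1)),
    InVitro1 = boost(base * ifelse(sub_of == "C>A" & ctx3 == "T", 8.0, 1)),
    InVitro2 = boost(base * ifelse(sub_of == "T>C" & ctx5 == "A", 7.0, 1)),
    Embryonic = boost(base * ifelse(sub_of == "C>T" & ctx3 == "G", 30.0, 1)),
    InVitroDup = boost(base * ifelse(sub_of == "C>A", 6.0, 1) * ifelse(ctx5 == "C", 2.0, 1))
  )
  m <- do.call(cbind, profs)
  rownames(m) <- chan
  structure(m, in_vitro = colnames(m) %in% c("InVitro1", "InVitro2", "InVitroDup"))
}

#' Fit non-negative signature exposures to a spectrum
#'
#' Solves the non-negative least-squares problem `min || P e - s ||` over
#' exposures `e >= 0`, where `P` holds the reference profiles column-wise and
#' `s` is the observed 96-channel count spectrum. Exposures are reported in
#' mutation units (they need not sum exactly to the spectrum total; the
#' residual is reported, not redistributed).
#'
#' @param spectrum numeric vector of 96 channel counts.
#' @param profiles 96 x k matrix of reference profiles (columns sum to 1).
#' @param redistribute_residual if `TRUE`, rescale exposures proportionally so
#'   they sum to the spectrum total (used where downstream accounting must be
#'   exact).
#' @return list with `exposures` (named vector, mutation units), `residual`
#'   (Euclidean norm of the unexplained spectrum) and `fitted` (the
#'   reconstructed spectrum).
#' @export
fit_exposures <- function(spectrum, profiles, redistribute_residual = FALSE) {
  profiles <- as.matrix(profiles)
  assert_that(length(spectrum) == nrow(profiles), "spectrum/profile dimension mismatch")
  assert_that(ncol(profiles) >= 1, "at least one reference profile required")
  if (sum(spectrum) == 0) {
    e <- setNames(numeric(ncol(profiles)), colnames(profiles))
    return(list(exposures = e, residual = 0, fitted = numeric(length(spectrum))))
  }
  fit <- pracma::lsqnonneg(profiles, as.numeric(spectrum))
  e <- setNames(fit$x, colnames(profiles))
  if (redistribute_residual && sum(e) > 0) e <- e * sum(spectrum) / sum(e)
  list(exposures = e, residual = sqrt(max(fit$resid.norm, 0)),
       fitted = as.numeric(profiles %*% fit$x))
}

#' Per-branch signature exposures across a phylogeny
#'
#' Treats every branch of the phylogeny as an independent sample: the spectrum
#' of the mutations assigned to the branch is refitted to the reference
#' profiles. Branches with fewer than `min_branch` mutations are excluded,
#' because sampling noise in the channel proportions dominates below that
#' size.
#'
#' @param phylo a [colony_phylogeny()] with mutations assigned to branches.
#' @param profiles reference profile matrix as in [fit_exposures()].
#' @param min_branch minimum mutations per branch (default 50).
#' @return data frame with one row per branch: branch id, mutation count,
#'   `included` flag and one exposure column per reference profile.
#' @export
branch_level_exposures <- function(phylo, profiles, min_branch = 50) {
  branches <- names(phylo$branch_mutations)
  k <- ncol(profiles)
  res <- matrix(NA_real_, length(branches), k,
                dimnames = list(branches, colnames(profiles)))
  n_mut <- integer(length(branches))
  for (i in seq_along(branches)) {
    ids <- phylo$branch_mutations[[i]]
    mut <- phylo$mutations[ids, , drop = FALSE]
    mut <- mut[mut$class == "SNV", , drop = FALSE]
    n_mut[i] <- nrow(mut)
    if (n_mut[i] >= min_branch) {
      res[i, ] <- fit_exposures(mutation_spectrum(mut), profiles)$exposures
    }
  }
  out <- data.frame(branch = branches, n_mutations = n_mut,
                    included = n_mut >= min_branch, stringsAsFactors = FALSE)
  cbind(out, as.data.frame(res))
}

#' Per-colony absolute signature contributions
#'
#' For each colony, the exposure fractions of its ancestral branches (those on
#' the root-to-tip path that passed the branch-size threshold) are averaged
#' with weights equal to the branch lengths, then rescaled by the colony's
#' corrected mutation burden to give absolute attributed mutation counts.
#' Colonies with no included ancestral branch are flagged `NA`.
#'
#' @param phylo a [colony_phylogeny()].
#' @param branch_exposures output of [branch_level_exposures()].
#' @param burdens named numeric vector of corrected burdens per colony.
#' @return data frame, one row per colony, one column per signature, plus a
#'   `defined` flag.
#' @export
colony_signature_contributions <- function(phylo, branch_exposures, burdens) {
  sig_cols <- setdiff(colnames(branch_exposures), c("branch", "n_mutations", "included"))
  tips <- phylo$tree$tip.label
  out <- matrix(NA_real_, length(tips), length(sig_cols),
                dimnames = list(tips, sig_cols))
  defined <- logical(length(tips))
  for (i in seq_along(tips)) {
    anc <- ancestral_branches(phylo, tips[i])
    be <- branch_exposures[branch_exposures$branch %in% anc & branch_exposures$included, , drop = FALSE]
    if (nrow(be) == 0) next
    w <- be$n_mutations
    fr <- as.matrix(be[, sig_cols, drop = FALSE])
    fr <- fr / pmax(rowSums(fr), .Machine$double.eps)  # per-branch fractions
    mean_fr <- colSums(fr * w) / sum(w)
    out[i, ] <- mean_fr * (burdens[tips[i]] %||% NA_real_)
    defined[i] <- TRUE
  }
  data.frame(colony = tips, defined = defined, out,
             check.names = FALSE, stringsAsFactors = FALSE)
}
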