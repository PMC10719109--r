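test_that("peak VAF finds the density mode and respects the minimum count", {
  expect_equal(peak_vaf(rep(0.5, 40)), 0.5, tolerance = 0.003)
  expect_true(is.na(peak_vaf(rep(0.5, 10))))
  # 70:30 mixture: VAFs ~ Binomial(20, 0.35)/20 peak near 0.35
  v <- with_seed_test(4, rbinom(400, 20, 0.35) / 20)
  expect_lt(abs(peak_vaf(v) - 0.35), 0.03)
})

test_that("clonality screen applies coverage and purity cut-offs strictly", {
  NV <- matrix(rep(c(6L, 5L, 4L), each = 40), 40)
  NR <- matrix(rep(c(12L, 13L, 12L), each = 40), 40)
  m <- toy_rcm(NV, NR)
  sc <- clonality_screen(m, coverage = setNames(c(12, 3.9, 12), m$colonies))
  expect_identical(sc$flag[2], "low_coverage")
  # colony 3: VAFs ~0.17 -> peak far below 0.4 -> non-clonal
  expect_identical(sc$flag[3], "non_clonal")
  expect_identical(sc$flag[1], "pass")
  expect_equal(sc$purity[1], min(1, 2 * sc$peak_vaf[1]))
})

test_that("tree-consistency screen catches 50:50 mixtures but tolerates pure colonies", {
  cs <- clean_sim()
  ph <- cs$ph
  m <- cs$fc$rcm
  pure <- tree_consistency_screen(ph, m, ph$tree$tip.label[1])
  expect_identical(pure$verdict, "pass")
  # synthesise a 50:50 mixture of two unrelated colonies: halve the variant
  # reads on the first colony's lineage branches
  victim <- ph$tree$tip.label[1]
  mix <- m
  own <- unlist(ph$branch_mutations[ancestral_branches(ph, victim)])
  mix$NV[own, victim] <- with_seed_test(31,
    rbinom(length(own), mix$NR[own, victim], 0.25))
  scr <- tree_consistency_screen(ph, mix, victim)
  expect_identical(scr$verdict, "non_clonal")
  expect_true(any(scr$branches$highly))
  # direct check of the exact binomial tails the screen uses
  expect_equal(pbinom(50, 200, 0.425),
               binom.test(50, 200, 0.425, alternative = "less")$p.value)
  expect_equal(pbinom(49, 200, 0.05, lower.tail = FALSE),
               binom.test(50, 200, 0.05, alternative = "greater")$p.value)
})

test_that("two minorly inconsistent branches pass; three flag the colony", {
  # 10 branches, one mutation each; intermediate VAF 18/60 gives raw p < 0.05
  # on both tests but survives the per-colony Bonferroni correction
  mk <- function(n_minor) {
    NV <- matrix(c(rep(18L, n_minor), rep(30L, 10 - n_minor)), ncol = 1)
    NR <- matrix(60L, 10, 1)
    m <- toy_rcm(NV, NR)
    ph <- structure(list(
      branch_mutations = split(rownames(m$NV), seq_len(10)),
      mutations = m$mutations), class = "colony_phylogeny")
    tree_consistency_screen(ph, m, m$colonies[1])
  }
  expect_gt(pbinom(18, 60, 0.425), 0.005)  # not Bonferroni-significant at B=10
  expect_lt(pbinom(18, 60, 0.425), 0.05)   # but minorly inconsistent
  two <- mk(2); three <- mk(3)
  expect_identical(two$verdict, "pass")
  expect_equal(sum(two$branches$minorly), 2)
  expect_identical(three$verdict, "non_clonal")
})

test_that("in vitro signature definition needs enough pooled mutations", {
  profs <- synthetic_signature_set()
  mk <- function(n, prof, seed) with_seed_test(seed, {
    ch <- sample(sbs_channels(), n, replace = TRUE, prob = profs[, prof])
    data.frame(ref = sub(".*\\[(.)>.*", "\\1", ch),
               alt = sub(".*>(.)\\].*", "\\1", ch),
               context = paste0(substr(ch, 1, 1), sub(".*\\[(.)>.*", "\\1", ch),
                                substr(ch, nchar(ch), nchar(ch))),
               class = "SNV")
  })
  expect_error(define_invitro_signature(mk(100, "InVitroDup", 1)), "at least 200")
  expect_error(define_invitro_signature(data.frame()), "at least 200")
  s <- define_invitro_signature(mk(2000, "InVitroDup", 2))
  expect_equal(sum(s), 1)
  # two disjoint draws from the same generative profile agree closely
  s2 <- define_invitro_signature(mk(2000, "InVitroDup", 3))
  cosine <- sum(s * s2) / sqrt(sum(s^2) * sum(s2^2))
  expect_gt(cosine, 0.95)
})

test_that("duplicate detection keys on the BM-attributed private mutation count", {
  profs <- synthetic_signature_set()
  iv <- profs[, "InVitroDup"]; bm <- profs[, "BM"]
  mk_branch <- function(n, prof, seed) with_seed_test(seed, {
    ch <- sample(sbs_channels(), n, replace = TRUE, prob = profs[, prof])
    data.frame(id = sprintf("x%d_%d", seed, seq_len(n)),
               ref = sub(".*\\[(.)>.*", "\\1", ch),
               alt = sub(".*>(.)\\].*", "\\1", ch),
               context = paste0(substr(ch, 1, 1), sub(".*\\[(.)>.*", "\\1", ch),
                                substr(ch, nchar(ch), nchar(ch))),
               class = "SNV", row.names = sprintf("x%d_%d", seed, seq_len(n)))
  })
  fake_phylo <- function(spec) {
    muts <- do.call(rbind, lapply(names(spec), function(cl) spec[[cl]]))
    tree <- ape::read.tree(text = paste0("(", paste(names(spec), collapse = ","),
                                         ")r;"))
    structure(list(tree = tree,
                   branch_mutations = lapply(spec, function(s) s$id),
                   mutations = muts), class = "colony_phylogeny")
  }
  # all-in-vitro private branches of 30 mutations -> duplicate pair
  ph1 <- fake_phylo(list(A = mk_branch(30, "InVitroDup", 10),
                         B = mk_branch(30, "InVitroDup", 11)))
  d1 <- detect_duplicates(ph1, data.frame(colony1 = "A", colony2 = "B"), iv, bm)
  expect_true(d1$duplicate[1])
  expect_identical(attr(d1, "flagged"), "B")
  # 60 BM-drawn private mutations each -> genuinely related, not duplicates
  ph2 <- fake_phylo(list(A = mk_branch(60, "BM", 12),
                         B = mk_branch(60, "BM", 13)))
  d2 <- detect_duplicates(ph2, data.frame(colony1 = "A", colony2 = "B"), iv, bm)
  expect_false(d2$duplicate[1])
  expect_gt(min(d2$bm1, d2$bm2), 15 * 0.8)
  # tiny private branches are duplicates regardless of profile
  ph3 <- fake_phylo(list(A = mk_branch(10, "BM", 14),
                         B = mk_branch(10, "BM", 15)))
  d3 <- detect_duplicates(ph3, data.frame(colony1 = "A", colony2 = "B"), iv, bm)
  expect_true(d3$duplicate[1])
})

test_that("duplicate detection on the simulated cohort finds the injected pairs", {
  co <- artifact_cohort()
  fc <- run_filter_chain(co$rcm)
  cs <- clonality_screen(fc$rcm)
  pass1 <- cs$colony[cs$flag == "pass"]
  sub <- fc$rcm[, pass1]
  bt <- build_tree(binarize_genotypes(sub))
  ph <- assign_mutations_to_branches(bt$tree, sub)
  wells <- setNames(co$labels$well, co$labels$colony)
  pairs <- candidate_duplicate_pairs(ph, wells = wells[pass1])
  profs <- synthetic_signature_set()
  dup <- detect_duplicates(ph, pairs, profs[, "InVitroDup"], profs[, "BM"])
  called <- dup[dup$duplicate, c("colony1", "colony2")]
  called_pairs <- apply(called, 1, function(r) paste(sort(r), collapse = "+"))
  lab <- co$labels
  dup_lab <- lab[lab$artifact == "duplicate" & lab$colony %in% pass1 &
                   lab$partner %in% pass1, ]
  true_pairs <- apply(dup_lab[, c("colony", "partner")],
                      1, function(r) paste(sort(r), collapse = "+"))
  # perfect precision and recall at lambda >= 25 and private burdens >= 30
  expect_setequal(unique(called_pairs), unique(true_pairs))
  # exactly one member of each pair is flagged for removal
  expect_equal(length(attr(dup, "flagged")), length(true_pairs))
})

test_that("QC never removes mutations from other colonies' genotypes", {
  co <- artifact_cohort()
  fc <- run_filter_chain(co$rcm)
  drop <- co$labels$colony[co$labels$artifact != "none"]
  kept <- setdiff(fc$rcm$colonies, drop)
  sub <- fc$rcm[, kept]
  expect_identical(sub$NV[, kept], fc$rcm$NV[, kept])
})
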