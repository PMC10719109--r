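#' Binarize per-colony genotypes from read counts
#'
#' A mutation is called present in a colony when `NV >= 2` and `VAF >= 0.15`,
#' absent when `NV = 0` with depth `NR >= 6`, and uncertain otherwise.
#' Uncertain cells do not vote during tree building; branch assignment later
#' returns to the raw read counts.
#'
#' @param m a [read_count_matrix()].
#' @param nv_present,vaf_present,nr_absent thresholds as above.
#' @return integer matrix (mutation x colony) with 1 = present, 0 = absent,
#'   `NA` = uncertain.
#' @export
binarize_genotypes <- function(m, nv_present = 2, vaf_present = 0.15,
                               nr_absent = 6) {
  vaf <- m$NV / pmax(m$NR, 1)
  g <- matrix(NA_integer_, nrow(m$NV), ncol(m$NV), dimnames = dimnames(m$NV))
  g[m$NV >= nv_present & vaf >= vaf_present] <- 1L
  g[m$NV == 0 & m$NR >= nr_absent] <- 0L
  g
}

#' Build a colony phylogeny by perfect-phylogeny reconstruction
#'
#' Mutations are grouped by their colony-support pattern (the set of colonies
#' in which they are called present). Patterns are accepted greedily in order
#' of decreasing mutation support (spurious patterns caused by allele dropout
#' carry few mutations, true clade patterns carry many); a pattern is accepted
#' only if it nests with every previously accepted pattern (disjoint or
#' contained). The accepted laminar family defines a rooted tree whose branch
#' lengths are the pattern mutation counts. Mutations on rejected patterns
#' join the uncertain pool and are placed later by
#' [assign_mutations_to_branches()].
#'
#' @param genotypes output of [binarize_genotypes()].
#' @param max_conflict maximum tolerated fraction of mutations on rejected
#'   (conflicting) patterns before an error is raised (default 0.2; higher
#'   rates indicate upstream contamination).
#' @return list with `tree` (rooted [ape::phylo], internal nodes labelled),
#'   `pattern_of` (accepted branch per mutation, `NA` if unresolved),
#'   `conflict_rate` and `root_mutations` (ids present in every colony).
#' @export
build_tree <- function(genotypes, max_conflict = 0.2) {
  C <- ncol(genotypes)
  assert_that(C >= 2, "need at least 2 colonies to build a tree")
  colonies <- colnames(genotypes)
  pres <- genotypes == 1L & !is.na(genotypes)
  supp <- rowSums(pres)
  informative <- supp > 0 & supp < C
  root_ids <- rownames(genotypes)[supp == C]
  key <- apply(pres[informative, , drop = FALSE], 1, function(r)
    paste(which(r), collapse = ","))
  ids_by_pattern <- split(rownames(genotypes)[informative], key)
  pat_sets <- lapply(strsplit(names(ids_by_pattern), ","), as.integer)
  n_mut <- lengths(ids_by_pattern)
  ord <- order(-n_mut, -lengths(pat_sets))
  accepted <- list(); accepted_names <- character(0)
  rejected_mut <- 0L
  pattern_of <- setNames(rep(NA_character_, nrow(genotypes)), rownames(genotypes))
  for (i in ord) {
    s <- pat_sets[[i]]
    ok <- all(vapply(accepted, function(a) {
      common <- length(intersect(s, a))
      common == 0 || common == length(s) || common == length(a)
    }, logical(1)))
    if (ok) {
      accepted[[length(accepted) + 1]] <- s
      accepted_names <- c(accepted_names, names(ids_by_pattern)[i])
    } else {
      rejected_mut <- rejected_mut + n_mut[i]
    }
  }
  conflict_rate <- if (sum(n_mut) > 0) rejected_mut / sum(n_mut) else 0
  if (conflict_rate > max_conflict) {
    stop(sprintf(
      "irresolvable genotype conflicts affect %.1f%% of mutations (> %.0f%%); check for contamination",
      100 * conflict_rate, 100 * max_conflict), call. = FALSE)
  }
  names(accepted) <- accepted_names
  counts <- n_mut[accepted_names]
  # parent of each accepted set = its smallest accepted strict superset
  sizes <- lengths(accepted)
  parent <- integer(length(accepted))  # 0 = root
  for (i in seq_along(accepted)) {
    sup <- which(vapply(accepted, function(a)
      length(a) > sizes[i] && all(accepted[[i]] %in% a), logical(1)))
    parent[i] <- if (length(sup) == 0) 0L else sup[which.min(sizes[sup])]
  }
  env <- new.env(); env$n <- 0L
  build <- function(node_idx) {
    members <- if (node_idx == 0L) seq_len(C) else accepted[[node_idx]]
    len <- if (node_idx == 0L) 0L else as.integer(counts[[node_idx]])
    if (node_idx != 0L && length(members) == 1) {
      return(sprintf("%s:%d", colonies[members], len))   # private branch
    }
    kids <- which(parent == node_idx)
    if (node_idx != 0L) kids <- setdiff(kids, node_idx)
    parts <- vapply(kids, build, character(1))
    loose <- setdiff(members, unlist(accepted[kids]))
    parts <- c(parts, sprintf("%s:0", colonies[loose]))
    env$n <- env$n + 1L
    sprintf("(%s)pp%d:%d", paste(parts, collapse = ","), env$n, len)
  }
  nwk <- build(0L)
  tree <- ape::read.tree(text = paste0(nwk, ";"))
  # record the accepted pattern branch for each mutation
  nl <- c(tree$tip.label, tree$node.label)
  clades <- branch_clades(tree)
  clade_key <- vapply(clades, function(tp)
    paste(sort(match(tp, colonies)), collapse = ","), character(1))
  for (nm in accepted_names) {
    skey <- paste(sort(accepted[[nm]]), collapse = ",")
    br <- names(clade_key)[match(skey, clade_key)]
    if (!is.na(br)) pattern_of[ids_by_pattern[[nm]]] <- br
  }
  pattern_of[root_ids] <- "root"
  list(tree = tree, pattern_of = pattern_of, conflict_rate = conflict_rate,
       root_mutations = root_ids)
}

#' Assign every mutation to a branch by read-count likelihood
#'
#' With the topology fixed, each mutation is assigned to the branch that
#' maximises a binomial likelihood of its read counts: colonies below the
#' branch expect VAF `purity/2` (purity for hemizygous sites), all others
#' expect the background error rate. Ties are broken towards the root. A
#' pseudo-branch `"root"` (clade = all colonies) captures mutations present
#' everywhere; mutations with zero depth in every colony go to the unassigned
#' pool.
#'
#' @param tree a rooted [ape::phylo] with labelled internal nodes (from
#'   [build_tree()]).
#' @param m the [read_count_matrix()] of surviving mutations.
#' @param purity optional named colony purities (default 1).
#' @param eps background per-read error VAF (default 0.002).
#' @return an object of class `colony_phylogeny`: `tree` with raw
#'   mutation-count edge lengths, `branch_mutations` (ids per branch, keyed by
#'   child node label, plus `"root"`), `raw_lengths`, `mutations`,
#'   `unassigned`.
#' @export
assign_mutations_to_branches <- function(tree, m, purity = NULL, eps = 0.002) {
  colonies <- tree$tip.label
  m <- m[, colonies]
  C <- length(colonies)
  purity <- (purity %||% setNames(rep(1, C), colonies))[colonies]
  clades <- branch_clades(tree)
  branches <- c(names(clades), "root")
  ind <- matrix(0, C, length(branches), dimnames = list(colonies, branches))
  for (b in names(clades)) ind[clades[[b]], b] <- 1
  ind[, "root"] <- 1
  p1 <- matrix(rep(purity / 2, each = nrow(m$NV)), nrow(m$NV), C)
  hemi <- m$mutations$hemizygous
  if (any(hemi)) p1[hemi, ] <- matrix(rep(purity, each = sum(hemi)), sum(hemi), C)
  L1 <- dbinom(m$NV, m$NR, p1, log = TRUE)
  L0 <- dbinom(m$NV, m$NR, eps, log = TRUE)
  delta <- pmin(pmax(L1 - L0, -1e6), 1e6)  # keep -Inf out of the matrix product
  score <- delta %*% ind
  # depth of each branch's child node (edges from root); root pseudo-branch 0
  depth <- node_edge_depth(tree)
  branch_depth <- c(depth[names(clades)], root = 0)
  zero_depth <- rowSums(m$NR) == 0
  assign <- character(nrow(m$NV))
  for (i in seq_len(nrow(m$NV))) {
    if (zero_depth[i]) { assign[i] <- NA_character_; next }
    s <- score[i, ]
    best <- which(s >= max(s) - 1e-9)
    assign[i] <- branches[best[which.min(branch_depth[best])]]
  }
  ids <- rownames(m$NV)
  branch_mutations <- split(ids[!is.na(assign)],
                            factor(assign[!is.na(assign)], levels = branches))
  raw <- lengths(branch_mutations)
  tree$edge.length <- as.numeric(raw[names(clades)])
  structure(list(
    tree = tree, branch_mutations = branch_mutations,
    raw_lengths = raw, mutations = m$mutations,
    unassigned = ids[is.na(assign)], rcm = m
  ), class = "colony_phylogeny")
}

#' @export
print.colony_phylogeny <- function(x, ...) {
  cat(sprintf(
    "<colony_phylogeny> %d colonies, %d mutations on %d branches (%d unassigned)\n",
    length(x$tree$tip.label), sum(x$raw_lengths),
    sum(x$raw_lengths > 0), length(x$unassigned)))
  invisible(x)
}

# number of edges between the root and each node, named by node label
node_edge_depth <- function(tree) {
  nl <- c(tree$tip.label, tree$node.label)
  depth <- numeric(length(nl))
  for (e in seq_len(nrow(tree$edge))) {
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + 1
  }
  setNames(depth, nl)
}

# molecular depth (sum of branch lengths root -> node), named by node label
node_molecular_depth <- function(tree, lengths = NULL) {
  nl <- c(tree$tip.label, tree$node.label)
  el <- lengths %||% tree$edge.length
  depth <- numeric(length(nl))
  for (e in seq_len(nrow(tree$edge))) {
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + el[e]
  }
  setNames(depth, nl)
}

#' Branches ancestral to a colony
#'
#' @param phylo a `colony_phylogeny`.
#' @param tip a colony id.
#' @return character vector of branch ids (child-node labels) on the
#'   root-to-tip path, tip branch first, ending with `"root"`.
#' @export
ancestral_branches <- function(phylo, tip) {
  tree <- phylo$tree
  nl <- c(tree$tip.label, tree$node.label)
  node <- match(tip, nl)
  assert_that(!is.na(node), paste("unknown colony:", tip))
  path <- character(0)
  repeat {
    e <- which(tree$edge[, 2] == node)
    if (length(e) == 0) break
    path <- c(path, nl[node])
    node <- tree$edge[e, 1]
  }
  c(path, "root")
}

#' Count post-GT coalescences on a colony phylogeny
#'
#' Counts internal nodes whose subtended colonies are all post-GT and whose
#' molecular depth (mutations from the root) exceeds the developmental epoch,
#' so purely developmental branch points shared by chance are not mistaken
#' for transplant-driven expansions.
#'
#' @param phylo a `colony_phylogeny`.
#' @param post_colonies character vector of post-GT colony ids.
#' @param dev_threshold molecular-time depth separating development from
#'   postnatal life (default 50 mutations).
#' @param lengths optional alternative branch lengths (e.g. corrected).
#' @return integer number of post-GT coalescences.
#' @export
count_post_gt_coalescences <- function(phylo, post_colonies, dev_threshold = 50,
                                       lengths = NULL) {
  tree <- phylo$tree
  nl <- c(tree$tip.label, tree$node.label)
  depth <- node_molecular_depth(tree, lengths)
  clades <- branch_clades(tree)
  count <- 0L
  for (b in names(clades)) {
    node <- match(b, nl)
    if (node <= length(tree$tip.label)) next        # tips are not coalescences
    if (all(clades[[b]] %in% post_colonies) && depth[b] > dev_threshold) {
      count <- count + 1L
    }
  }
  count
}

#' Convert a mutation tree to a time tree by constant-rate scaling
#'
#' Assumes a constant postnatal mutation acquisition rate: each node's age is
#' `age_at_sampling x (molecular depth of the node / molecular depth of the
#' tip)`, averaged over its descendant tips to force ultrametricity, and every
#' tip is pinned at the sampling age.
#'
#' @param phylo a `colony_phylogeny`.
#' @param age_at_sampling years since conception at sampling.
#' @param lengths optional branch lengths to use (defaults to the tree's
#'   current, typically sensitivity-corrected, lengths).
#' @return list of class `timed_tree`: `tree` (ultrametric, edge lengths in
#'   years), `ages` (node ages named by node label).
#' @export
time_calibrate <- function(phylo, age_at_sampling, lengths = NULL) {
  tree <- phylo$tree
  nl <- c(tree$tip.label, tree$node.label)
  ntip <- length(tree$tip.label)
  depth <- node_molecular_depth(tree, lengths)
  assert_that(all(depth[seq_len(ntip)] > 0),
              "zero root-to-tip molecular depth; cannot calibrate")
  clades <- branch_clades(tree)
  ages <- setNames(numeric(length(nl)), nl)
  ages[seq_len(ntip)] <- age_at_sampling
  for (b in names(clades)) {
    node <- match(b, nl)
    if (node <= ntip) next
    tips <- clades[[b]]
    ages[b] <- age_at_sampling * mean(depth[b] / depth[tips])
  }
  root_lab <- nl[ntip + 1]
  ages[root_lab] <- 0
  # enforce parent <= child despite tip-averaging
  for (e in seq_len(nrow(tree$edge))) {
    p <- nl[tree$edge[e, 1]]; ch <- nl[tree$edge[e, 2]]
    if (ages[ch] < ages[p]) ages[ch] <- ages[p]
  }
  timed <- tree
  timed$edge.length <- ages[nl[tree$edge[, 2]]] - ages[nl[tree$edge[, 1]]]
  structure(list(tree = timed, ages = ages, age_at_sampling = age_at_sampling),
            class = "timed_tree")
}
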