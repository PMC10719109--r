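#' Simulation configuration for synthetic colony cohorts
#'
#' Bundles every parameter of the synthetic-data generator. Defaults emulate
#' the sampling conditions of colony-based gene-therapy phylogenomics:
#' HSCs acquire roughly 14-18 SNVs and ~0.7 indels per year (default rate 16
#' SNVs/yr), colonies are sequenced to ~12x mean depth, a transplant
#' bottleneck of a few thousand engrafting clones repopulates an active
#' progenitor pool of ~1e5 cells, and a germline SNP panel of 100,000
#' heterozygous autosomal sites rides along for sensitivity estimation.
#'
#' @param seed integer seed; identical seeds give byte-identical outputs.
#' @param n_patients number of simulated patients (cohort level).
#' @param age_years patient age at sampling.
#' @param snv_rate,indel_rate mutations acquired per HSC per year.
#' @param developmental_burst expected mutations acquired over the early
#'   developmental epoch (root-to-tip); each early cell division deposits at
#'   least one mutation so lineage branches are identifiable.
#' @param n_colonies_pre,n_colonies_post colonies sampled before/after GT.
#' @param mean_depth mean sequencing depth per site (reads).
#' @param n_engrafted_true true number of engrafting clones (ABC truth).
#' @param n_final final active HSPC population grown from the engrafted pool.
#' @param post_gt_years years between GT and post-GT sampling.
#' @param contamination_fraction,duplicate_fraction,lowcov_fraction
#'   proportions of colonies turned into two-founder mixtures, technical
#'   duplicates, or low-coverage failures.
#' @param invitro_lambda mean in vitro mutations per duplicate colony.
#' @param invitro_vaf expected VAF of in vitro mutations that pass filters
#'   (acquired at/near the first colony division, so slightly below 0.5).
#' @param germline_snp_count heterozygous autosomal germline sites simulated.
#' @param error_rate per-allele sequencing error rate.
#' @param clone_cap maximum fraction of colonies any postnatal clone may
#'   contribute (clades are truncated to this size).
#' @param sex `"male"` or `"female"`; male cohorts carry a small fraction of
#'   hemizygous X/Y sites.
#' @param hemizygous_fraction fraction of sites hemizygous in males.
#' @param driver_spec list of postnatal driver-clone expansions, each a list
#'   with `size` (tips in the clade) and `gene` (label attached to the clone's
#'   driver mutation).
#' @return an object of class `sim_config` (a validated list).
#' @export
sim_config <- function(seed = 1L,
                       n_patients = 1L,
                       age_years = 20,
                       snv_rate = 16,
                       indel_rate = 0.7,
                       developmental_burst = 30,
                       n_colonies_pre = 100L,
                       n_colonies_post = 74L,
                       mean_depth = 12,
                       n_engrafted_true = 3000L,
                       n_final = 1e5,
                       post_gt_years = 2,
                       contamination_fraction = 0.1,
                       duplicate_fraction = 0.07,
                       lowcov_fraction = 0.005,
                       invitro_lambda = 30,
                       invitro_vaf = 0.4,
                       germline_snp_count = 100000L,
                       error_rate = 0.002,
                       clone_cap = 0.01,
                       sex = c("male", "female"),
                       hemizygous_fraction = 0.02,
                       driver_spec = list()) {
  sex <- match.arg(sex)
  cfg <- list(
    seed = as.integer(seed), n_patients = as.integer(n_patients),
    age_years = age_years, snv_rate = snv_rate, indel_rate = indel_rate,
    developmental_burst = developmental_burst,
    n_colonies_pre = as.integer(n_colonies_pre),
    n_colonies_post = as.integer(n_colonies_post),
    mean_depth = mean_depth, n_engrafted_true = as.integer(n_engrafted_true),
    n_final = n_final, post_gt_years = post_gt_years,
    contamination_fraction = contamination_fraction,
    duplicate_fraction = duplicate_fraction, lowcov_fraction = lowcov_fraction,
    invitro_lambda = invitro_lambda, invitro_vaf = invitro_vaf,
    germline_snp_count = as.integer(germline_snp_count),
    error_rate = error_rate, clone_cap = clone_cap, sex = sex,
    hemizygous_fraction = hemizygous_fraction, driver_spec = driver_spec
  )
  rates <- c(cfg$snv_rate, cfg$indel_rate, cfg$developmental_burst,
             cfg$mean_depth, cfg$invitro_lambda)
  assert_that(all(rates >= 0), "all rates must be non-negative")
  fr <- c(cfg$contamination_fraction, cfg$duplicate_fraction, cfg$lowcov_fraction)
  assert_that(all(fr >= 0 & fr <= 1), "artifact fractions must lie in [0, 1]")
  assert_that(sum(fr) <= 1, "artifact fractions must sum to at most 1")
  assert_that(cfg$n_engrafted_true <= cfg$n_final,
              "n_engrafted_true must not exceed n_final")
  structure(cfg, class = "sim_config")
}

#' @export
print.sim_config <- function(x, ...) {
  cat("<sim_config>\n")
  cat(sprintf("  %d patient(s), age %.1f y; %.1f SNV/yr + %.2f indel/yr, burst ~%.0f\n",
              x$n_patients, x$age_years, x$snv_rate, x$indel_rate,
              x$developmental_burst))
  cat(sprintf("  colonies: %d pre-GT + %d post-GT at %.1fx depth; %d germline SNPs\n",
              x$n_colonies_pre, x$n_colonies_post, x$mean_depth,
              x$germline_snp_count))
  cat(sprintf("  transplant: %d engrafting clones -> %g final cells\n",
              x$n_engrafted_true, x$n_final))
  invisible(x)
}

# -- internal tree assembly ---------------------------------------------------

# Random sequential joins of `units` (each a list(newick, tips)) into one
# rooted binary tree; returns the merged unit. `node_env` supplies fresh
# internal node labels and records which labels are created by this call.
join_units <- function(units, node_env, record = NULL) {
  while (length(units) > 1) {
    pick <- sample.int(length(units), 2)
    node_env$counter <- node_env$counter + 1L
    lab <- paste0("n", node_env$counter)
    if (!is.null(record)) node_env[[record]] <- c(node_env[[record]], lab)
    merged <- list(
      newick = paste0("(", units[[pick[1]]]$newick, ",", units[[pick[2]]]$newick,
                      ")", lab),
      tips = c(units[[pick[1]]]$tips, units[[pick[2]]]$tips)
    )
    units <- c(units[-pick], list(merged))
  }
  units[[1]]
}

#' Simulate an HSC phylogeny with per-branch mutation counts
#'
#' Generates a rooted binary tree whose tips are colony founder cells. The
#' internal skeleton represents the developmental epoch: each early division
#' deposits `1 + Poisson` mutations, scaled so the expected root-to-tip
#' developmental burden matches `config$developmental_burst`. Each tip then
#' accrues an independent private branch of `Poisson(snv_rate x age)` SNVs
#' (plus indels), reflecting postnatal polyclonal haematopoiesis. Optional
#' postnatal clades (clonal expansions, or post-transplant clones sharing an
#' engrafted founder) coalesce after development; no clade may subtend more
#' than `clone_cap` of the tips (default 1%).
#'
#' @param config a [sim_config()].
#' @param n_tips number of founder tips (default `config$n_colonies_pre`).
#' @param tip_labels optional tip names.
#' @param clades optional list; each element is a list with `tips` (integer
#'   indices forming a postnatal clade), optional `split_years` (age at which
#'   the clade's founder lineage split into the sampled lineages) and
#'   optional `gene` (driver label).
#' @param seed RNG seed (default `config$seed`).
#' @return a list of class `hsc_truth`: `tree` (an [ape::phylo] with edge
#'   lengths equal to branch mutation counts), `mutations` (catalogue with
#'   true branch assignment), `branch_mutations` (mutation ids per branch,
#'   keyed by the branch's child node label), `tip_burden`, `postnatal_nodes`,
#'   and the generating config.
#' @export
simulate_hsc_phylogeny <- function(config, n_tips = NULL, tip_labels = NULL,
                                   clades = NULL, seed = config$seed) {
  n <- as.integer(n_tips %||% config$n_colonies_pre)
  assert_that(n >= 2, "at least 2 colonies required")
  assert_that(config$snv_rate > 0 || config$developmental_burst > 0,
              "zero mutation rate with zero developmental burst gives a degenerate tree")
  labels <- tip_labels %||% sprintf("C%03d", seq_len(n))
  if (is.null(clades) && length(config$driver_spec) > 0) {
    used <- integer(0)
    clades <- lapply(config$driver_spec, function(d) {
      sz <- as.integer(d$size %||% 2L)
      avail <- setdiff(seq_len(n), used)
      tips <- avail[seq_len(min(sz, length(avail)))]
      used <<- c(used, tips)
      list(tips = tips, gene = d$gene %||% NA_character_)
    })
  }
  with_seed(seed, {
    cap <- max(2L, floor(config$clone_cap * n))
    env <- new.env(); env$counter <- 0L; env$postnatal <- character(0)
    env$developmental <- character(0)
    clade_info <- list()
    units <- list()
    used <- integer(0)
    for (cl in clades %||% list()) {
      tips <- setdiff(cl$tips, used)
      # transplant clades reflect the sampled bottleneck, not a pre-GT
      # expansion, and are exempt from the clone cap
      cap_here <- if (isTRUE(cl$cap_exempt)) length(tips) else cap
      if (length(tips) > cap_here) tips <- tips[seq_len(cap_here)]
      if (length(tips) < 2) next
      used <- c(used, tips)
      sub <- join_units(lapply(tips, function(i) list(newick = labels[i], tips = i)),
                        env, record = "postnatal")
      clade_root <- sub("^.*\\)", "", sub$newick)
      clade_info[[length(clade_info) + 1]] <- list(
        root = clade_root, tips = tips, gene = cl$gene %||% NA_character_,
        split_years = cl$split_years %||% (config$age_years * runif(1, 0.3, 0.7))
      )
      units <- c(units, list(sub))
    }
    singles <- setdiff(seq_len(n), used)
    units <- c(units, lapply(singles, function(i) list(newick = labels[i], tips = i)))
    root_unit <- join_units(units, env, record = "developmental")
    tree <- ape::read.tree(text = paste0(root_unit$newick, ";"))

    node_labels <- c(tree$tip.label, tree$node.label)
    children_lab <- node_labels[tree$edge[, 2]]
    div_depth <- node_division_depth(tree, env$developmental)
    D <- max(1, mean(div_depth$tip_divisions))
    lambda_extra <- max(0, config$developmental_burst / D - 1)

    clade_of_tip <- rep(NA_integer_, n)
    for (i in seq_along(clade_info)) clade_of_tip[clade_info[[i]]$tips] <- i

    ne <- nrow(tree$edge)
    edge_class <- character(ne)   # developmental | clade_shared | clade_internal | private
    edge_years <- numeric(ne)
    for (e in seq_len(ne)) {
      ch <- children_lab[e]
      if (ch %in% env$developmental) {
        edge_class[e] <- "developmental"
      } else if (ch %in% env$postnatal) {
        edge_class[e] <- "clade_internal"
      } else {
        ti <- match(ch, labels)
        cl <- clade_of_tip[ti]
        edge_class[e] <- "private"
        edge_years[e] <- if (is.na(cl)) config$age_years
          else config$age_years - clade_info[[cl]]$split_years
      }
    }
    # the edge into a clade's root carries the founder's life up to the split
    for (ci in clade_info) {
      e <- which(children_lab == ci$root)
      edge_class[e] <- "clade_shared"
      edge_years[e] <- ci$split_years
    }

    n_snv <- integer(ne); n_indel <- integer(ne)
    for (e in seq_len(ne)) {
      switch(edge_class[e],
        developmental = { n_snv[e] <- 1L + rpois(1, lambda_extra) },
        clade_internal = { n_snv[e] <- rpois(1, 1) },
        clade_shared = {
          n_snv[e] <- rpois(1, config$snv_rate * edge_years[e])
          n_indel[e] <- rpois(1, config$indel_rate * edge_years[e])
        },
        private = {
          n_snv[e] <- rpois(1, config$snv_rate * edge_years[e])
          n_indel[e] <- rpois(1, config$indel_rate * edge_years[e])
        }
      )
    }
    tree$edge.length <- as.numeric(n_snv + n_indel)

    # mutation catalogue
    profs <- synthetic_signature_set()
    branch_ids <- children_lab
    total_snv <- sum(n_snv); total_indel <- sum(n_indel)
    profile_for_edge <- ifelse(edge_class == "developmental", "Embryonic", "BM")
    mut <- make_mutation_catalogue(
      n_snv, n_indel, branch_ids, profile_for_edge, profs,
      hemi_fraction = if (config$sex == "male") config$hemizygous_fraction else 0
    )
    # attach driver labels: one mutation on each clade's shared branch
    mut$gene <- NA_character_; mut$consequence <- NA_character_
    for (ci in clade_info) {
      if (is.na(ci$gene)) next
      idx <- which(mut$branch == ci$root & mut$class == "SNV")
      if (length(idx) > 0) {
        mut$gene[idx[1]] <- ci$gene
        mut$consequence[idx[1]] <- "missense"
      }
    }
    branch_mutations <- split(mut$id, factor(mut$branch, levels = branch_ids))
    tip_burden <- tip_burdens_from_tree(tree)
    postnatal_nodes <- c(env$postnatal, vapply(clade_info, `[[`, "", "root"))
    structure(list(
      tree = tree, mutations = mut, branch_mutations = branch_mutations,
      tip_burden = tip_burden, postnatal_nodes = unique(postnatal_nodes),
      clades = clade_info, config = config,
      newick = ape::write.tree(tree)
    ), class = "hsc_truth")
  })
}

# division depth (number of edges from root) per node/tip; edges from
# ape::read.tree are in cladewise (preorder) order so parents fill first
node_division_depth <- function(tree, dev_nodes) {
  ntip <- length(tree$tip.label)
  depth <- numeric(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + 1
  }
  list(tip_divisions = depth[seq_len(ntip)], all = depth)
}

# root-to-tip sum of edge lengths
tip_burdens_from_tree <- function(tree) {
  ntip <- length(tree$tip.label)
  depth <- numeric(ntip + tree$Nnode)
  for (e in seq_len(nrow(tree$edge))) {
    depth[tree$edge[e, 2]] <- depth[tree$edge[e, 1]] + tree$edge.length[e]
  }
  setNames(depth[seq_len(ntip)], tree$tip.label)
}

# Draw SNV/indel records per branch. Contexts are sampled from the given
# signature profile per edge; half the SNVs are emitted on the purine strand
# so spectrum folding is exercised downstream.
make_mutation_catalogue <- function(n_snv, n_indel, branch_ids, profile_for_edge,
                                    profiles, hemi_fraction = 0) {
  chan <- sbs_channels()
  rows <- list()
  counter <- 0L
  for (e in seq_along(branch_ids)) {
    ns <- n_snv[e]; ni <- n_indel[e]
    if (ns + ni == 0) next
    recs <- data.frame(
      branch = branch_ids[e],
      class = c(rep("SNV", ns), rep("indel", ni)),
      stringsAsFactors = FALSE
    )
    if (ns > 0) {
      ch <- sample(chan, ns, replace = TRUE, prob = profiles[, profile_for_edge[e]])
      ref <- sub(".*\\[(.)>.*", "\\1", ch)
      alt <- sub(".*>(.)\\].*", "\\1", ch)
      ctx <- paste0(substr(ch, 1, 1), ref, substr(ch, nchar(ch), nchar(ch)))
      flip <- runif(ns) < 0.5
      ref[flip] <- chartr("CT", "GA", ref[flip])
      alt[flip] <- chartr("ACGT", "TGCA", alt[flip])
      ctx[flip] <- revcomp(ctx[flip])
      recs$ref <- c(ref, rep(NA, ni)); recs$alt <- c(alt, rep(NA, ni))
      recs$context <- c(ctx, rep(NA, ni))
    } else {
      recs$ref <- NA_character_; recs$alt <- NA_character_
      recs$context <- NA_character_
    }
    if (ni > 0) {
      recs$ref[ns + seq_len(ni)] <- "A"
      recs$alt[ns + seq_len(ni)] <- "AT"
    }
    rows[[length(rows) + 1]] <- recs
  }
  mut <- if (length(rows)) do.call(rbind, rows) else
    data.frame(branch = character(0), class = character(0), ref = character(0),
               alt = character(0), context = character(0))
  m <- nrow(mut)
  if (m > 0) {
    mut$id <- sprintf("M%06d", seq_len(m))
    mut$hemizygous <- runif(m) < hemi_fraction
    mut$chrom <- ifelse(mut$hemizygous, "X", as.character(sample.int(22, m, replace = TRUE)))
    mut$pos <- sample.int(2.4e8, m)
    mut <- mut[, c("id", "chrom", "pos", "ref", "alt", "class", "context",
                   "hemizygous", "branch")]
    rownames(mut) <- mut$id
  }
  mut
}

#' Simulate per-colony read counts for a true phylogeny
#'
#' For every mutation x colony cell, total depth is `NR ~ Poisson(mean_depth)`
#' and variant reads are `NV ~ Binomial(NR, purity/2)` when the mutation is
#' ancestral to the colony (purity for hemizygous male X/Y sites) or
#' `Binomial(NR, error_rate)` otherwise. A panel of heterozygous germline SNPs
#' present in every colony at expected VAF 0.5 is appended; these are the
#' substrate of the germline filter and of sensitivity estimation.
#'
#' @param truth output of [simulate_hsc_phylogeny()].
#' @param config a [sim_config()].
#' @param purity optional named vector of colony purities (default 1).
#' @param seed RNG seed.
#' @return list with `rcm` (a [read_count_matrix()] holding somatic candidates
#'   and germline SNPs), `germline_ids`, and `presence` (the true mutation x
#'   colony presence matrix for the somatic rows).
#' @export
simulate_reads <- function(truth, config, purity = NULL, seed = config$seed + 1L) {
  tree <- truth$tree
  colonies <- tree$tip.label
  C <- length(colonies)
  purity <- purity %||% setNames(rep(1, C), colonies)
  mut <- truth$mutations
  M <- nrow(mut)
  with_seed(seed, {
    clades <- branch_clades(tree)         # tips below each branch (child label)
    presence <- matrix(FALSE, M, C, dimnames = list(mut$id, colonies))
    for (b in names(clades)) {
      rows <- truth$branch_mutations[[b]]
      if (length(rows)) presence[rows, clades[[b]]] <- TRUE
    }
    p_present <- matrix(rep(purity / 2, each = M), M, C)
    if (any(mut$hemizygous)) {
      p_present[mut$hemizygous, ] <- matrix(rep(purity, each = sum(mut$hemizygous)),
                                            sum(mut$hemizygous), C)
    }
    p <- ifelse(presence, p_present, config$error_rate)
    NR <- matrix(rpois(M * C, config$mean_depth), M, C)
    NV <- matrix(rbinom(M * C, NR, p), M, C)

    G <- config$germline_snp_count
    hemi_g <- runif(G) < (if (config$sex == "male") config$hemizygous_fraction else 0)
    gNR <- matrix(rpois(G * C, config$mean_depth), G, C)
    pg <- ifelse(rep(hemi_g, C), 1 - config$error_rate, 0.5)
    gNV <- matrix(rbinom(G * C, gNR, pg), G, C)
    gl_ids <- sprintf("G%06d", seq_len(G))
    gl_mut <- data.frame(
      id = gl_ids, chrom = ifelse(hemi_g, "X", "1"),
      pos = sample.int(2.4e8, G) + 2.4e8, ref = "C", alt = "T", class = "SNV",
      context = "ACA", hemizygous = hemi_g, branch = NA_character_,
      gene = NA_character_, consequence = NA_character_,
      stringsAsFactors = FALSE
    )
    all_mut <- rbind(mut, gl_mut)
    NV <- rbind(NV, gNV); NR <- rbind(NR, gNR)
    rownames(NV) <- rownames(NR) <- all_mut$id
    rcm <- read_count_matrix(NV, pmax(NR, NV), all_mut, colonies)
    list(rcm = rcm, germline_ids = gl_ids, presence = presence)
  })
}

# tips subtended by every branch, keyed by child-node label
branch_clades <- function(tree) {
  nl <- c(tree$tip.label, tree$node.label)
  ntip <- length(tree$tip.label)
  out <- vector("list", nrow(tree$edge))
  names(out) <- nl[tree$edge[, 2]]
  desc <- vector("list", ntip + tree$Nnode)
  for (i in seq_len(ntip)) desc[[i]] <- tree$tip.label[i]
  for (e in ape::postorder(tree)) {
    p <- tree$edge[e, 1]; ch <- tree$edge[e, 2]
    desc[[p]] <- c(desc[[p]], desc[[ch]])
  }
  for (e in seq_len(nrow(tree$edge))) out[[e]] <- desc[[tree$edge[e, 2]]]
  out
}

#' Inject sequencing artifacts into a simulated cohort
#'
#' Converts randomly chosen colonies into the three artifact classes the QC
#' module must catch: two-founder mixtures (read counts redrawn from the
#' average of two colonies' genotypes), low-coverage failures (reads thinned
#' to ~3x) and technical duplicates (a second sample of an existing colony's
#' founder, with an independent set of `Poisson(invitro_lambda)` in vitro
#' mutations drawn from the culture-artifact signature for each member of the
#' pair). Duplicate pairs are placed in adjacent wells, mirroring systematic
#' colony picking.
#'
#' @param sim output of [simulate_reads()].
#' @param truth output of [simulate_hsc_phylogeny()].
#' @param config a [sim_config()].
#' @param seed RNG seed.
#' @return list with the modified `rcm`, a `labels` data frame (colony,
#'   artifact class, partner, well), and `invitro_ids` (ids of injected in
#'   vitro mutations).
#' @export
inject_artifacts <- function(sim, truth, config, seed = config$seed + 2L) {
  rcm <- sim$rcm
  C <- length(rcm$colonies)
  fr <- c(config$contamination_fraction, config$duplicate_fraction,
          config$lowcov_fraction)
  assert_that(sum(fr) <= 1, "artifact fractions must sum to at most 1")
  n_dup <- floor(config$duplicate_fraction * C)
  assert_that(n_dup == 0 || C >= 2, "duplicates require at least 2 colonies")
  with_seed(seed, {
    n_cont <- floor(config$contamination_fraction * C)
    n_low <- floor(config$lowcov_fraction * C)
    picks <- sample(rcm$colonies, n_cont + n_dup + n_low)
    cont <- picks[seq_len(n_cont)]
    dups <- picks[n_cont + seq_len(n_dup)]
    lows <- picks[n_cont + n_dup + seq_len(n_low)]
    labels <- data.frame(
      colony = rcm$colonies, artifact = "none", partner = NA_character_,
      purity = 1, stringsAsFactors = FALSE
    )
    rownames(labels) <- rcm$colonies
    som <- rownames(sim$presence)

    for (cc in cont) {
      other <- sample(setdiff(rcm$colonies, cc), 1)
      mix <- 0.5
      pres_self <- sim$presence[, cc]; pres_oth <- sim$presence[, other]
      p <- 0.5 * (mix * pres_self + (1 - mix) * pres_oth)
      p[p == 0] <- config$error_rate
      rcm$NV[som, cc] <- rbinom(length(som), rcm$NR[som, cc], p)
      labels[cc, c("artifact", "partner")] <- c("non_clonal", other)
      labels[cc, "purity"] <- 2 * 0.5 * max(mix, 1 - mix)
    }

    invitro_rows <- list()
    profs <- synthetic_signature_set()
    src_pool <- setdiff(rcm$colonies, c(dups, cont, lows))
    assert_that(length(src_pool) >= n_dup,
                "not enough unaffected colonies to source duplicates")
    srcs <- sample(src_pool, n_dup)   # distinct partner per duplicate
    for (di in seq_along(dups)) {
      dd <- dups[di]
      src <- srcs[di]
      p <- ifelse(sim$presence[, src], 0.5, config$error_rate)
      p[rcm$mutations[som, "hemizygous"]] <- ifelse(
        sim$presence[rcm$mutations[som, "hemizygous"], src], 1 - config$error_rate,
        config$error_rate)
      rcm$NV[som, dd] <- rbinom(length(som), rcm$NR[som, dd], p)
      labels[dd, c("artifact", "partner")] <- c("duplicate", src)
      for (member in c(dd, src)) {
        k <- rpois(1, config$invitro_lambda)
        if (k == 0) next
        iv <- make_mutation_catalogue(k, 0L, NA_character_, "InVitroDup", profs)
        iv$id <- sprintf("V%s_%03d", member, seq_len(k))
        iv$gene <- NA_character_; iv$consequence <- NA_character_
        rownames(iv) <- iv$id
        nv <- matrix(0L, k, C, dimnames = list(iv$id, rcm$colonies))
        nr <- matrix(rpois(k * C, config$mean_depth), k, C,
                     dimnames = list(iv$id, rcm$colonies))
        nv[] <- rbinom(k * C, nr, config$error_rate)
        nv[, member] <- rbinom(k, nr[, member], config$invitro_vaf)
        invitro_rows[[length(invitro_rows) + 1]] <- list(mut = iv, NV = nv, NR = nr)
      }
    }

    for (lc in lows) {
      q <- min(1, 3 / config$mean_depth)
      keep_v <- rbinom(nrow(rcm$NV), rcm$NV[, lc], q)
      keep_r <- keep_v + rbinom(nrow(rcm$NV), rcm$NR[, lc] - rcm$NV[, lc], q)
      rcm$NV[, lc] <- keep_v; rcm$NR[, lc] <- keep_r
      labels[lc, "artifact"] <- "low_coverage"
    }

    if (length(invitro_rows)) {
      NV <- rbind(rcm$NV, do.call(rbind, lapply(invitro_rows, `[[`, "NV")))
      NR <- rbind(rcm$NR, do.call(rbind, lapply(invitro_rows, `[[`, "NR")))
      mut <- rbind(rcm$mutations,
                   do.call(rbind, lapply(invitro_rows, `[[`, "mut"))[, colnames(rcm$mutations)])
      rcm <- read_count_matrix(NV, pmax(NR, NV), mut, rcm$colonies)
    }
    # duplicate pairs sit in adjacent wells (systematic picking around the
    # well), separated by empty wells; remaining colonies fill later rows
    assign <- setNames(rep(NA_character_, C), rcm$colonies)
    for (di in seq_along(dups)) {
      row <- LETTERS[(di - 1) %/% 4 + 1]
      col <- 3 * ((di - 1) %% 4) + 1
      assign[dups[di]] <- paste0(row, col)
      assign[labels[dups[di], "partner"]] <- paste0(row, col + 1)
    }
    rest <- names(assign)[is.na(assign)]
    first_free_row <- length(dups) %/% 4 + 2
    rest_wells <- paste0(rep(LETTERS[first_free_row:26], each = 6),
                         rep(2 * (1:6) - 1, 26 - first_free_row + 1))
    assign[rest] <- rest_wells[seq_along(rest)]
    labels$well <- assign[labels$colony]
    list(rcm = rcm, labels = labels,
         invitro_ids = unlist(lapply(invitro_rows, function(r) r$mut$id)))
  })
}

#' Simulate a transplant bottleneck and post-GT colony sampling
#'
#' Clone sizes are grown from `n_engrafted` unit-size clones to a final
#' population `n_final` by the urn birth process (see [grow_clones()]);
#' `n_sampled` colonies are then drawn without replacement, weighted by clone
#' size. Sampled colonies sharing a clone coalesce after GT, so the true
#' number of post-therapy coalescences is `n_sampled` minus the number of
#' distinct clones sampled.
#'
#' @param n_engrafted true number of engrafting clones (k).
#' @param n_final final active HSPC population size.
#' @param n_sampled number of post-GT colonies drawn.
#' @param seed RNG seed.
#' @param method clone-growth method passed to [grow_clones()].
#' @return list with `clone_ids` (per sampled colony), `coalescences`,
#'   `n_distinct` and the engrafted clone `sizes`.
#' @export
simulate_transplant <- function(n_engrafted, n_final, n_sampled, seed = NULL,
                                method = c("dirichlet", "urn")) {
  assert_that(n_engrafted >= 1, "n_engrafted must be at least 1")
  assert_that(n_sampled >= 1, "n_sampled must be at least 1")
  assert_that(n_sampled <= n_final, "cannot sample more colonies than cells")
  method <- match.arg(method)
  with_seed(seed, {
    sizes <- grow_clones(n_engrafted, n_final, method = method)
    ids <- sample_clone_ids(sizes, n_sampled)
    list(clone_ids = ids, coalescences = n_sampled - length(unique(ids)),
         n_distinct = length(unique(ids)), sizes = sizes)
  })
}

#' Simulate a duplex-sequencing clone panel
#'
#' Per site and timepoint, duplex depth is `NR ~ Poisson(mean_site_depth)` and
#' variant reads are `NV ~ Binomial(NR, freq/2)` where `freq` is the clone's
#' cell frequency at that timepoint (VAF is half the clone frequency for
#' heterozygous sites). A fraction of passenger sites can be made subclonal
#' (reduced frequency), mimicking clone mutations acquired after the driver.
#'
#' @param clone_freq named numeric vector: clone cell frequency per timepoint
#'   (names are timepoints in years relative to GT).
#' @param n_sites number of panel sites (driver + passengers).
#' @param mean_site_depth mean duplex depth per site (default 12000).
#' @param seed RNG seed.
#' @param subclonal_fraction fraction of passenger sites at reduced frequency.
#' @param subclonal_factor frequency multiplier for subclonal sites.
#' @param error_rate per-read background error.
#' @return data frame with columns `site`, `timepoint`, `NV`, `NR`,
#'   `subclonal`.
#' @export
simulate_duplex <- function(clone_freq, n_sites, mean_site_depth = 12000,
                            seed = NULL, subclonal_fraction = 0,
                            subclonal_factor = 0.3, error_rate = 0) {
  assert_that(all(clone_freq >= 0 & clone_freq <= 1),
              "clone frequencies must lie in [0, 1]")
  tps <- names(clone_freq) %||% as.character(seq_along(clone_freq))
  with_seed(seed, {
    sub <- runif(n_sites) < subclonal_fraction
    sub[1] <- FALSE  # site 1 is the driver itself
    out <- expand.grid(site = seq_len(n_sites), timepoint = tps,
                       KEEP.OUT.ATTRS = FALSE, stringsAsFactors = FALSE)
    f <- clone_freq[out$timepoint] * ifelse(sub[out$site], subclonal_factor, 1)
    out$NR <- rpois(nrow(out), mean_site_depth)
    out$NV <- rbinom(nrow(out), out$NR, pmin(1, f / 2 + error_rate))
    out$subclonal <- sub[out$site]
    out
  })
}

#' Simulate a full pre/post-GT colony cohort
#'
#' Composes the generator: a transplant bottleneck decides which post-GT
#' colonies share engrafted clones; an HSC phylogeny is built over the pre-GT
#' founders plus the distinct sampled clones (post-GT colonies of one clone
#' form a postnatal clade); read counts, germline SNPs, vector evidence and
#' artifact colonies are then layered on top.
#'
#' @param config a [sim_config()].
#' @return a list of class `cohort_truth` with elements `truth` (the colony
#'   phylogeny ground truth), `rcm`, `germline_ids`, `colony_meta`,
#'   `transplant`, `vector_truth`, `labels` and `config`.
#' @export
simulate_cohort <- function(config) {
  with_seed(config$seed, {
    tr <- simulate_transplant(config$n_engrafted_true, config$n_final,
                              config$n_colonies_post,
                              seed = child_seed(config$seed, "transplant"))
    clone_map <- split(seq_len(config$n_colonies_post), tr$clone_ids)
    d <- length(clone_map)
    n_pre <- config$n_colonies_pre
    pre_ids <- sprintf("P%03d", seq_len(n_pre))
    post_ids <- sprintf("Q%03d", seq_len(config$n_colonies_post))
    # tips: pre colonies then one founder per distinct post clone; clones with
    # >1 colony become postnatal clades over their colony tips
    tip_labels <- c(pre_ids, rep(NA, config$n_colonies_post))
    clades <- list()
    k <- n_pre
    singles <- character(0)
    for (cl in clone_map) {
      tip_labels[n_pre + cl] <- post_ids[cl]
      if (length(cl) > 1) {
        clades[[length(clades) + 1]] <- list(
          tips = n_pre + cl, cap_exempt = TRUE,
          split_years = config$age_years - config$post_gt_years + 0.01
        )
      }
    }
    truth <- simulate_hsc_phylogeny(
      config, n_tips = n_pre + config$n_colonies_post,
      tip_labels = tip_labels, clades = clades,
      seed = child_seed(config$seed, "phylogeny")
    )
    sim <- simulate_reads(truth, config, seed = child_seed(config$seed, "reads"))
    art <- inject_artifacts(sim, truth, config,
                            seed = child_seed(config$seed, "artifacts"))
    vec <- simulate_vector_evidence(post_ids, config,
                                    seed = child_seed(config$seed, "vector"))
    meta <- data.frame(
      colony = c(pre_ids, post_ids),
      patient = "PT1",
      timepoint = c(rep(0, n_pre), rep(config$post_gt_years * 12, length(post_ids))),
      phase = c(rep("pre", n_pre), rep("post", length(post_ids))),
      stringsAsFactors = FALSE
    )
    meta$well <- art$labels[meta$colony, "well"]
    structure(list(
      truth = truth, rcm = art$rcm, germline_ids = sim$germline_ids,
      presence = sim$presence, colony_meta = meta, transplant = tr,
      vector_truth = vec, labels = art$labels, invitro_ids = art$invitro_ids,
      config = config
    ), class = "cohort_truth")
  })
}

# Ground-truth vector integrations for post-GT colonies: true VCN, true VIS
# positions and the anchored-read evidence downstream callers consume.
simulate_vector_evidence <- function(post_ids, config, seed = NULL,
                                     modified_fraction = 0.7,
                                     background_vcn = 0.3,
                                     reads_per_vis = 8) {
  with_seed(seed, {
    n <- length(post_ids)
    vcn_true <- ifelse(runif(n) < modified_fraction,
                       sample(1:3, n, replace = TRUE, prob = c(0.6, 0.3, 0.1)), 0L)
    evid <- list(); vis_truth <- list()
    for (i in seq_len(n)) {
      auto_cov <- rpois(1, config$mean_depth)
      vec_cov <- max(0, (vcn_true[i] + background_vcn) * 0.5 * auto_cov +
                       stats::rnorm(1, 0, 0.2))
      reads <- data.frame(colony = character(0), chrom = character(0),
                          pos = integer(0))
      if (vcn_true[i] > 0) {
        for (v in seq_len(vcn_true[i])) {
          center <- sample.int(2.4e8, 1)
          chrom <- as.character(sample.int(22, 1))
          k <- max(4, rpois(1, reads_per_vis))
          reads <- rbind(reads, data.frame(
            colony = post_ids[i], chrom = chrom,
            pos = pmax(1, center + as.integer(round(stats::rnorm(k, 0, 150))))
          ))
          vis_truth[[length(vis_truth) + 1]] <- data.frame(
            colony = post_ids[i], chrom = chrom, pos = center
          )
        }
      }
      evid[[i]] <- list(colony = post_ids[i], vector_cov = vec_cov,
                        autosomal_cov = auto_cov, reads = reads)
    }
    list(vcn_true = setNames(vcn_true, post_ids),
         vis_true = if (length(vis_truth)) do.call(rbind, vis_truth) else NULL,
         evidence = evid, background = background_vcn)
  })
}
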