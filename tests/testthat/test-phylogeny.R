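test_that("genotype binarization applies the presence/absence thresholds", {
  NV <- rbind(8L, 0L, 1L, 2L, 0L)
  NR <- rbind(16L, 12L, 3L, 20L, 4L)
  g <- binarize_genotypes(toy_rcm(NV, NR))
  expect_identical(as.vector(g), c(1L, 0L, NA, NA, NA))
  # 2/20 has NV >= 2 but VAF 0.1 < 0.15 -> uncertain; 0/4 lacks depth
})

test_that("perfect phylogeny reconstructs nested support patterns", {
  # tips A,B: patterns {AB} x5, {A} x3, {B} x2
  NV <- matrix(0L, 10, 2, dimnames = list(NULL, c("A", "B")))
  NR <- matrix(20L, 10, 2)
  NV[1:5, ] <- 10L
  NV[6:8, 1] <- 10L
  NV[9:10, 2] <- 10L
  bt <- build_tree(binarize_genotypes(toy_rcm(NV, NR)))
  expect_identical(sort(bt$tree$tip.label), c("A", "B"))
  lens <- setNames(bt$tree$edge.length,
                   c(bt$tree$tip.label, bt$tree$node.label)[bt$tree$edge[, 2]])
  expect_equal(unname(lens[c("A", "B")]), c(3, 2))
  expect_equal(bt$conflict_rate, 0)
  # identical tips (an unremoved duplicate pair) still give a valid tree
  NVd <- cbind(NV, B2 = NV[, 2])
  NRd <- cbind(NR, 20L)
  colnames(NVd) <- c("A", "B", "B2")
  btd <- build_tree(binarize_genotypes(toy_rcm(NVd, NRd)))
  expect_equal(length(btd$tree$tip.label), 3)
  expect_error(ape::write.tree(btd$tree), NA)
})

test_that("heavily conflicting genotypes raise a contamination error", {
  # two equally supported incompatible patterns: {A,B} vs {B,C}
  NV <- matrix(0L, 10, 3, dimnames = list(NULL, c("A", "B", "C")))
  NR <- matrix(20L, 10, 3)
  NV[1:5, c(1, 2)] <- 10L
  NV[6:10, c(2, 3)] <- 10L
  expect_error(build_tree(binarize_genotypes(toy_rcm(NV, NR))),
               "contamination")
})

test_that("branch assignment maximises the read-count likelihood", {
  # cherry (A,B) + outgroup C; shared branch mutation with a dropout in B
  tree <- ape::read.tree(text = "((A:1,B:1)n1:1,C:1)r;")
  # shared A+B mutation: B is down to a single variant read (too weak to
  # binarize as present) yet the likelihood still places it on the shared
  # branch; second mutation is private to A
  NV <- rbind(c(8L, 1L, 0L),
              c(7L, 0L, 0L))
  NR <- rbind(c(16L, 2L, 14L),
              c(15L, 12L, 13L))
  colnames(NV) <- colnames(NR) <- c("A", "B", "C")
  ph <- assign_mutations_to_branches(tree, toy_rcm(NV, NR))
  expect_identical(unname(ph$branch_mutations[["n1"]]), rownames(ph$rcm$NV)[1])
  expect_identical(unname(ph$branch_mutations[["A"]]), rownames(ph$rcm$NV)[2])
  # direct likelihood oracle for the dropout case
  ll <- function(clade) {
    p <- ifelse(c("A", "B", "C") %in% clade, 0.5, 0.002)
    sum(dbinom(NV[1, ], NR[1, ], p, log = TRUE))
  }
  expect_gt(ll(c("A", "B")), ll("A"))
  # zero-depth mutations fall into the unassigned pool
  NV0 <- rbind(NV, c(0L, 0L, 0L)); NR0 <- rbind(NR, c(0L, 0L, 0L))
  colnames(NV0) <- colnames(NR0) <- c("A", "B", "C")
  ph0 <- assign_mutations_to_branches(tree, toy_rcm(NV0, NR0))
  expect_equal(length(ph0$unassigned), 1)
  # partition invariant: branch lengths sum to assigned mutations
  expect_equal(sum(ph$raw_lengths), nrow(NV))
})

test_that("clean simulations recover the true topology and branch placement", {
  cs <- clean_sim()
  skip_if_not_installed("phangorn")
  rf <- phangorn::RF.dist(ape::unroot(cs$ph$tree), ape::unroot(cs$truth$tree))
  expect_equal(rf, 0)
  # >= 99% of surviving mutations assigned to their true branch: compare the
  # clades below the assigned vs true branch
  truth_clades <- lapply(clonotrace:::branch_clades(cs$truth$tree), sort)
  built_clades <- lapply(clonotrace:::branch_clades(cs$ph$tree), sort)
  amap <- rep(names(cs$ph$branch_mutations), lengths(cs$ph$branch_mutations))
  names(amap) <- unlist(cs$ph$branch_mutations)
  ids <- intersect(names(amap), cs$truth$mutations$id)
  tb <- cs$truth$mutations$branch[match(ids, cs$truth$mutations$id)]
  same <- mapply(function(a, t) {
    if (a == "root" || t == "root") return(a == t)
    identical(built_clades[[a]], truth_clades[[t]])
  }, amap[ids], tb)
  expect_gt(mean(same), 0.99)
})

test_that("tree building is invariant to tip input order", {
  cs <- clean_sim()
  m <- cs$fc$rcm
  perm <- with_seed_test(9, m[, sample(ncol(m$NV))])
  bt2 <- build_tree(binarize_genotypes(perm))
  skip_if_not_installed("phangorn")
  expect_equal(phangorn::RF.dist(ape::unroot(bt2$tree),
                                 ape::unroot(cs$bt$tree)), 0)
})

test_that("post-GT coalescence counting respects the developmental epoch", {
  # ((Q1,Q2)x:300,(P1,Q3)y:300) with developmental root edges of 10
  tree <- ape::read.tree(
    text = "((Q1:40,Q2:40)x:300,(P1:330,Q3:330)y:10)r;")
  ph <- structure(list(tree = tree), class = "colony_phylogeny")
  post <- c("Q1", "Q2", "Q3")
  # node x: all-post clade at depth 300 > 50 -> counted
  # node y: contains pre-GT colony P1 -> not counted
  expect_equal(count_post_gt_coalescences(ph, post), 1L)
  # unrelated post tips only -> 0
  expect_equal(count_post_gt_coalescences(ph, "Q1"), 0L)
  # a post-GT triplet clade counts its 2 internal nodes
  tree3 <- ape::read.tree(text = "(((Q1:10,Q2:10)a:100,Q3:110)b:200,P1:310)r;")
  ph3 <- structure(list(tree = tree3), class = "colony_phylogeny")
  expect_equal(count_post_gt_coalescences(ph3, c("Q1", "Q2", "Q3")), 2L)
  # a developmental cherry (depth below 50) is not a transplant signal
  treeD <- ape::read.tree(text = "((Q1:300,Q2:300)x:20,P1:320)r;")
  phD <- structure(list(tree = treeD), class = "colony_phylogeny")
  expect_equal(count_post_gt_coalescences(phD, c("Q1", "Q2")), 0L)
})

test_that("time calibration maps molecular depth linearly and stays ultrametric", {
  tree <- ape::read.tree(text = "((A:200,B:200)n1:200,C:400)r;")
  ph <- structure(list(tree = tree), class = "colony_phylogeny")
  tt <- time_calibrate(ph, age_at_sampling = 20)
  expect_equal(unname(tt$ages["n1"]), 10)   # 200/400 of 20 years
  expect_equal(unname(tt$ages[c("A", "B", "C")]), c(20, 20, 20))
  d <- ape::node.depth.edgelength(tt$tree)
  expect_true(all(abs(d[1:3] - 20) < 1e-9))  # ultrametric tips
  # parent < child ordering preserved
  nl <- c(tt$tree$tip.label, tt$tree$node.label)
  for (e in seq_len(nrow(tt$tree$edge))) {
    expect_gte(tt$ages[nl[tt$tree$edge[e, 2]]] + 1e-12,
               tt$ages[nl[tt$tree$edge[e, 1]]])
  }
  expect_error(time_calibrate(structure(list(
    tree = ape::read.tree(text = "(A:0,B:0)r;")), class = "colony_phylogeny"),
    20), "zero root-to-tip")
})

test_that("node ages on simulated constant-rate trees are close to truth", {
  cs <- clean_sim()
  ph <- cs$ph
  tt <- time_calibrate(ph, age_at_sampling = cs$cfg$age_years)
  # postnatal private branches span ~the full lifetime; their parents (the
  # developmental epoch) should be dated in the first years of life
  nl <- c(ph$tree$tip.label, ph$tree$node.label)
  internal <- setdiff(nl, ph$tree$tip.label)
  depths <- clonotrace:::node_molecular_depth(ph$tree)
  dev_nodes <- internal[depths[internal] < 50]
  expect_true(all(tt$ages[dev_nodes] < 0.2 * cs$cfg$age_years))
})
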