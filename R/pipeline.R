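#' Pipeline configuration
#'
#' Flat, schema-checked configuration for [run_pipeline()]: simulation
#' parameters (see [sim_config()]) plus per-stage analysis parameters with
#' defaults matching the published thresholds. Unknown keys are rejected.
#'
#' @param ... overrides of the default parameters.
#' @param file optional YAML file to read overrides from.
#' @return a named list of class `pipeline_config`.
#' @export
pipeline_config <- function(..., file = NULL) {
  defaults <- list(
    seed = 1L,
    sim = as.list(unclass(sim_config())),
    filters = list(q_max = 1e-5, rho_min = 0.1, min_mean = 8, max_mean = 40,
                   nv_positive = 3, p0 = 0.425, p_max = 0.001,
                   nv_min = 3, nr_min = 6, vaf_min = 0.2),
    qc = list(min_coverage = 4, min_peak_vaf = 0.4, bm_min = 15),
    tree = list(eps = 0.002, dev_threshold = 50),
    burden = list(reference_rate = 16.8, target_coverage = 30),
    signatures = list(min_branch = 50),
    vector = list(min_support = 4, merge_distance = 1000, background = 0.3),
    abc = list(grid_lo = 10, grid_hi = 16.6, grid_step = 0.1,
               n_final = c(1e5, 2e5, 5e5, 1e6, 2e6), draws_per_sim = 1000)
  )
  over <- list(...)
  if (!is.null(file)) over <- utils::modifyList(yaml::read_yaml(file), over)
  bad <- setdiff(names(over), names(defaults))
  assert_that(length(bad) == 0,
              paste("unknown configuration keys:", paste(bad, collapse = ", ")))
  cfg <- utils::modifyList(defaults, over)
  class(cfg) <- "pipeline_config"
  cfg
}

write_tsv <- function(df, path) {
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  path
}

#' Run the full synthetic-cohort analysis pipeline
#'
#' Executes, in dependency order: cohort simulation, somatic filtering,
#' colony QC (coverage/clonality, tree-consistency, duplicate detection),
#' phylogeny building and branch assignment, burden correction, signature
#' refitting, vector VCN/VIS calling, and engraftment ABC. Stage outputs are
#' written as TSV/newick/JSON-free text under `out_dir`; a manifest records
#' per-stage status, wall-clock time and output checksums. A failed stage
#' isolates its downstream dependents but leaves completed results in place.
#'
#' @param config a [pipeline_config()].
#' @param out_dir output directory (created if missing).
#' @return a `run_manifest` list with `stages`, `results` and `config`.
#' @export
run_pipeline <- function(config = pipeline_config(), out_dir = tempfile("run")) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  yaml::write_yaml(unclass(config)[setdiff(names(config), character(0))],
                   file.path(out_dir, "config.yaml"))
  manifest <- list(stages = list(), results = list(), config = config,
                   out_dir = out_dir)
  run_stage <- function(name, deps, fun) {
    for (d in deps) {
      if (is.null(manifest$stages[[d]]) ||
          manifest$stages[[d]]$status != "ok") {
        manifest$stages[[name]] <<- list(status = "skipped",
                                         reason = paste("dependency failed:", d))
        return(invisible(NULL))
      }
    }
    t0 <- proc.time()[["elapsed"]]
    res <- tryCatch(list(ok = TRUE, value = fun()),
                    error = function(e) list(ok = FALSE, err = conditionMessage(e)))
    el <- proc.time()[["elapsed"]] - t0
    if (res$ok) {
      manifest$results[[name]] <<- res$value
      files <- res$value$files %||% character(0)
      manifest$stages[[name]] <<- list(
        status = "ok", seconds = el,
        checksums = if (length(files)) tools::md5sum(files) else NULL)
    } else {
      manifest$stages[[name]] <<- list(status = "failed", seconds = el,
                                       reason = res$err)
    }
    invisible(NULL)
  }

  scfg <- do.call(sim_config, utils::modifyList(config$sim,
                                                list(seed = config$seed)))
  run_stage("simulate", character(0), function() {
    cohort <- simulate_cohort(scfg)
    f1 <- write_tsv(cohort$colony_meta, file.path(out_dir, "colonies.tsv"))
    f2 <- file.path(out_dir, "truth.nwk")
    writeLines(cohort$truth$newick, f2)
    list(cohort = cohort, files = c(f1, f2))
  })

  run_stage("filter", "simulate", function() {
    cohort <- manifest$results$simulate$cohort
    fc <- run_filter_chain(cohort$rcm, config$filters)
    f <- write_tsv(fc$report, file.path(out_dir, "filter_report.tsv"))
    list(fc = fc, files = f)
  })

  run_stage("qc", "filter", function() {
    cohort <- manifest$results$simulate$cohort
    fc <- manifest$results$filter$fc
    cs <- clonality_screen(fc$rcm, min_coverage = config$qc$min_coverage,
                           min_peak_vaf = config$qc$min_peak_vaf)
    pass1 <- cs$colony[cs$flag == "pass"]
    # first-pass tree for consistency screening and duplicate detection
    sub <- fc$rcm[, pass1]
    bt <- build_tree(binarize_genotypes(sub))
    ph <- assign_mutations_to_branches(bt$tree, sub, eps = config$tree$eps)
    verdicts <- vapply(pass1, function(cl)
      tree_consistency_screen(ph, sub, cl)$verdict, character(1))
    cs$flag[match(names(verdicts)[verdicts == "non_clonal"], cs$colony)] <- "non_clonal"
    pass2 <- cs$colony[cs$flag == "pass"]
    wells <- setNames(cohort$colony_meta$well, cohort$colony_meta$colony)
    pairs <- candidate_duplicate_pairs(ph, wells = wells)
    pairs <- pairs[pairs$colony1 %in% pass2 & pairs$colony2 %in% pass2, ]
    profs <- synthetic_signature_set()
    dup <- if (nrow(pairs) > 0)
      detect_duplicates(ph, pairs, profs[, "InVitroDup"], profs[, "BM"],
                        bm_min = config$qc$bm_min)
    else structure(data.frame(), flagged = character(0))
    flagged <- attr(dup, "flagged")
    cs$flag[cs$colony %in% flagged] <- "duplicate"
    f <- write_tsv(cs, file.path(out_dir, "qc_report.tsv"))
    list(qc = cs, duplicates = dup, passing = cs$colony[cs$flag == "pass"],
         files = f)
  })

  run_stage("tree", "qc", function() {
    fc <- manifest$results$filter$fc
    passing <- manifest$results$qc$passing
    sub <- fc$rcm[, passing]
    bt <- build_tree(binarize_genotypes(sub))
    ph <- assign_mutations_to_branches(bt$tree, sub, eps = config$tree$eps)
    f <- file.path(out_dir, "tree.nwk")
    writeLines(ape::write.tree(ph$tree), f)
    list(phylo = ph, files = f)
  })

  run_stage("burden", "tree", function() {
    cohort <- manifest$results$simulate$cohort
    ph <- manifest$results$tree$phylo
    gl <- intersect(cohort$germline_ids, rownames(cohort$rcm$NV))
    # sensitivity uses the same support rule the filter chain applies
    sens <- vapply(ph$tree$tip.label, function(cl) {
      nv <- cohort$rcm$NV[gl, cl]; nr <- cohort$rcm$NR[gl, cl]
      germline_sensitivity(nv, nr,
        called = nv >= config$filters$nv_min & nr >= config$filters$nr_min &
          nv / pmax(nr, 1) > config$filters$vaf_min)
    }, numeric(1))
    ph <- correct_branch_lengths(ph, sens)
    burdens <- colony_burdens(ph)
    meta <- cohort$colony_meta
    tab <- data.frame(colony = names(burdens),
                      raw = colony_burdens(ph, corrected = FALSE),
                      corrected = burdens,
                      sensitivity = sens[names(burdens)],
                      phase = meta$phase[match(names(burdens), meta$colony)])
    f <- write_tsv(tab, file.path(out_dir, "burden.tsv"))
    list(phylo = ph, burdens = tab, files = f)
  })

  run_stage("signatures", "burden", function() {
    ph <- manifest$results$burden$phylo
    burdens <- manifest$results$burden$burdens
    profs <- synthetic_signature_set()
    be <- branch_level_exposures(ph, profs,
                                 min_branch = config$signatures$min_branch)
    contrib <- colony_signature_contributions(
      ph, be, setNames(burdens$corrected, burdens$colony))
    f <- write_tsv(be, file.path(out_dir, "branch_exposures.tsv"))
    list(branch_exposures = be, contributions = contrib, files = f)
  })

  run_stage("vector", "simulate", function() {
    cohort <- manifest$results$simulate$cohort
    vt <- cohort$vector_truth
    rows <- lapply(vt$evidence, function(ev) {
      v <- vcn(ev$vector_cov, ev$autosomal_cov, config$vector$background)
      vis <- call_vis(ev$reads, min_support = config$vector$min_support,
                      merge_distance = config$vector$merge_distance)
      cm <- classify_modified(v$rounded, nrow(vis))
      data.frame(colony = ev$colony, vcn_raw = v$raw, vcn = v$rounded,
                 n_vis = nrow(vis), modified = cm$modified,
                 discordant = cm$discordant)
    })
    tab <- do.call(rbind, rows)
    f <- write_tsv(tab, file.path(out_dir, "vector.tsv"))
    list(vcn = tab, files = f)
  })

  run_stage("engraftment", "tree", function() {
    cohort <- manifest$results$simulate$cohort
    ph <- manifest$results$tree$phylo
    post <- cohort$colony_meta$colony[cohort$colony_meta$phase == "post"]
    coal <- count_post_gt_coalescences(ph, post,
                                       dev_threshold = config$tree$dev_threshold)
    abc <- abc_engraftment(
      coal, sum(ph$tree$tip.label %in% post),
      grid = 2^seq(config$abc$grid_lo, config$abc$grid_hi,
                   by = config$abc$grid_step),
      n_final = config$abc$n_final,
      draws_per_sim = config$abc$draws_per_sim,
      seed = child_seed(config$seed, "abc"))
    f <- write_tsv(data.frame(k = abc$grid, likelihood = abc$likelihood,
                              posterior = abc$posterior),
                   file.path(out_dir, "abc_posterior.tsv"))
    list(coalescences = coal, abc = abc, files = f)
  })

  class(manifest) <- "run_manifest"
  manifest
}

#' @export
print.run_manifest <- function(x, ...) {
  cat("<run_manifest>", x$out_dir, "\n")
  for (nm in names(x$stages)) {
    st <- x$stages[[nm]]
    cat(sprintf("  %-12s %s%s\n", nm, st$status,
                if (!is.null(st$seconds)) sprintf(" (%.1fs)", st$seconds) else ""))
  }
  invisible(x)
}

#' Summarise a pipeline run per patient
#'
#' Builds the reporting table: colonies sequenced and excluded per QC class,
#' percent gene-modified, mean corrected burden pre/post, post-GT coalescence
#' count and the engraftment posterior summary. Regeneration from the same
#' manifest is idempotent.
#'
#' @param manifest a `run_manifest` from [run_pipeline()].
#' @return a one-row-per-patient data frame.
#' @export
make_report <- function(manifest) {
  res <- manifest$results
  qc <- res$qc$qc
  burdens <- res$burden$burdens
  pre_b <- burdens$corrected[burdens$phase == "pre"]
  post_b <- burdens$corrected[burdens$phase == "post"]
  vcn_tab <- res$vector$vcn
  abc <- res$engraftment$abc
  data.frame(
    patient = "PT1",
    colonies = nrow(qc),
    excluded_low_coverage = sum(qc$flag == "low_coverage"),
    excluded_non_clonal = sum(qc$flag %in% c("non_clonal", "indeterminate")),
    excluded_duplicate = sum(qc$flag == "duplicate"),
    passing = sum(qc$flag == "pass"),
    pct_gene_modified = if (!is.null(vcn_tab)) 100 * mean(vcn_tab$modified) else NA,
    mean_burden_pre = if (length(pre_b)) mean(pre_b) else NA,
    mean_burden_post = if (length(post_b)) mean(post_b) else NA,
    post_gt_coalescences = res$engraftment$coalescences %||% NA,
    engrafting_cells = if (!is.null(abc)) abc$estimate else NA,
    engrafting_lower = if (!is.null(abc)) abc$interval[1] else NA,
    engrafting_upper = if (!is.null(abc)) abc$interval[2] else NA,
    row.names = NULL
  )
}
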