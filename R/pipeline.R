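# build one stage network (adjacency -> TOM -> modules -> merge) on a
# sample subset of the DE genes; returns NULL partition when too few genes
.build_network <- function(logcpm, gene_ids, sample_idx, config) {
  ids <- intersect(gene_ids, rownames(logcpm))
  empty <- list(partition = NULL, tom = NULL, beta = NA_real_,
                fit_table = NULL)
  if (length(ids) < max(3, config$min_module_size)) return(empty)
  x <- logcpm[ids, sample_idx, drop = FALSE]
  keep <- apply(x, 1, sd) > 0
  x <- x[keep, , drop = FALSE]
  if (nrow(x) < max(3, config$min_module_size)) return(empty)
  fit_table <- NULL
  beta <- config$beta
  if (identical(beta, "auto")) {
    pick <- tryCatch(
      pick_soft_threshold(x, config$beta_grid, config$scale_free_r2_target),
      error = function(e) NULL)
    if (is.null(pick)) {
      beta <- 6
    } else {
      beta <- pick$beta
      fit_table <- pick$fit_table
    }
  }
  adj <- soft_adjacency(x, beta)
  tom <- topological_overlap(adj)
  part <- suppressWarnings(
    cut_modules(tom, config$min_module_size, config$deep_split))
  if (part$module_count > 1)
    part <- merge_modules(x, part, config$merge_dissimilarity)
  list(partition = part, tom = tom, beta = beta, fit_table = fit_table)
}

# fixtures used when the run is simulation-backed and no external
# annotation / function-set tables were supplied
.resolve_fixtures <- function(config, cohort) {
  ann <- config$annotation
  fs <- config$function_sets
  has_markers <- !is.null(cohort$truth) &&
    (length(cohort$truth$common_markers) +
       length(unlist(cohort$truth$specific_markers))) > 0
  if (is.null(ann)) {
    if (is.null(cohort$truth))
      stop("no annotation table supplied and no planted truth to derive one")
    ann <- if (has_markers)
      generate_annotation_fixture(cohort$truth, n_decoys = 25L,
                                  dropout = 0, seed = config$seed + 101L)
    else
      data.frame(mirna_id = character(0), disease = character(0))
  }
  if (is.null(fs)) {
    if (is.null(cohort$truth))
      stop("no function sets supplied and no planted truth to derive them")
    fs <- if (has_markers)
      generate_function_sets(cohort$truth, n_sets = 8L, set_size = 20L,
                             enrichment_bias = 0.8,
                             seed = config$seed + 202L)
    else
      data.frame(set_id = character(0), mirna_id = character(0))
  }
  list(annotation = ann, function_sets = fs)
}

#' Run the full EV-miRNA biomarker screening pipeline
#'
#' Executes the end-to-end screen: (1) cohort acquisition (simulation with
#' planted truth, or counts/metadata files); (2) TMM/logCPM normalization;
#' (3) dual differential expression over all pairwise group contrasts with
#' the union-plus-prevalence call; (4) two network arms — the all-stage arm
#' builds one co-expression network per group on the pooled DE set, the
#' per-stage arm builds one network per disease stage on that stage's
#' control-vs-stage DE set over {stage, control} samples; (5) cross-stage
#' module linkage, with annotation filtering (all-stage arm) and
#' enrichment-then-annotation filtering (per-stage arm, order configurable);
#' (6) candidate extraction (common vs. stage-specific); (7) validation by
#' stagewise ROC contrasts and by qPCR 2^-ddCt fold changes with ANOVA +
#' Dunnett. The run is fully deterministic given the config seed.
#'
#' @param config a [run_config()].
#' @param outdir optional directory; when given, all result tables and a
#'   checksum manifest are written via [write_results_tables()].
#' @return a `run_summary` list with all intermediate objects and the
#'   headline counts.
#' @export
run_pipeline <- function(config = run_config(), outdir = NULL) {
  stopifnot(inherits(config, "run_config"))
  t_start <- Sys.time()
  stage_log <- character(0)
  tick <- function(stage) {
    stage_log <<- c(stage_log,
                    sprintf("%s\t%.2fs", stage,
                            as.numeric(Sys.time() - t_start, units = "secs")))
  }
  cohort <- if (!is.null(config$simulation)) {
    generate_cohort(config$simulation)
  } else if (!is.null(config$counts_path)) {
    load_cohort(config$counts_path, config$metadata_path)
  } else {
    stop("config must carry either a simulation or counts/metadata paths")
  }
  tick("cohort")
  groups <- cohort$samples$group
  present <- .GROUPS[.GROUPS %in% groups]
  pd_present <- intersect(.PD_STAGES, present)
  norm <- normalize_logcpm(cohort, config$prior_count)
  tick("normalize")

  # --- dual differential expression over all pairwise contrasts ----------
  contrasts <- combn(present, 2, simplify = FALSE)
  de_list <- lapply(contrasts, function(ct)
    de_test(cohort, ct, norm, config$p_cut, config$logfc_cut, config$t_cut))
  names(de_list) <- vapply(contrasts, paste, character(1), collapse = "_vs_")
  de_union <- call_de_union(de_list, cohort$counts, config$prevalence)
  de_table <- do.call(rbind, c(lapply(de_list, as.data.frame),
                               make.row.names = FALSE))
  tick("differential_expression")

  # per-stage DE sets: control-vs-stage union calls, prevalence-filtered
  stage_sets <- lapply(setNames(pd_present, pd_present), function(s) {
    d <- de_list[[paste("control", s, sep = "_vs_")]]
    intersect(d$mirna_id[d$in_union], de_union$union)
  })

  # --- network arms ------------------------------------------------------
  all_stage <- lapply(setNames(present, present), function(g)
    .build_network(norm$logcpm, de_union$union, which(groups == g), config))
  per_stage_samples <- if (config$stage_network_samples == "stage_only")
    lapply(pd_present, function(s) which(groups == s))
  else
    lapply(pd_present, function(s) which(groups %in% c("control", s)))
  names(per_stage_samples) <- pd_present
  per_stage <- lapply(setNames(pd_present, pd_present), function(s)
    .build_network(norm$logcpm, stage_sets[[s]], per_stage_samples[[s]],
                   config))

  tick("networks")
  parts <- function(nets) {
    p <- lapply(nets, `[[`, "partition")
    p[!vapply(p, is.null, logical(1))]
  }
  all_parts <- parts(all_stage[pd_present])    # control excluded from linkage
  per_parts <- parts(per_stage)

  fixtures <- .resolve_fixtures(config, cohort)

  build_graph <- function(plist) {
    if (length(plist) >= 2) build_linkage_graph(plist)
    else if (length(plist) == 1) build_linkage_graph(plist,
                                                     include_intra = TRUE)
    else NULL
  }
  empty_graph <- function() {
    g <- list(nodes = data.frame(stage = character(0),
                                 module = character(0), size = integer(0)),
              members = list(),
              edges = data.frame(stage_a = character(0),
                                 module_a = character(0),
                                 stage_b = character(0),
                                 module_b = character(0),
                                 weight = integer(0)))
    class(g) <- "linkage_graph"
    g
  }
  g_all <- build_graph(all_parts)
  if (is.null(g_all)) g_all <- empty_graph()
  g_per <- build_graph(per_parts)
  if (is.null(g_per)) g_per <- empty_graph()

  g_all_f <- suppressWarnings(
    filter_key_modules_by_annotation(g_all, fixtures$annotation))

  per_background <- sort(unique(unlist(lapply(g_per$members, identity))))
  enr <- NULL
  g_per_f <- g_per
  if (length(g_per$members) > 0) {
    fs <- fixtures$function_sets
    fs <- fs[fs$mirna_id %in% per_background, , drop = FALSE]
    if (config$filter_order == "enrichment_then_annotation") {
      e <- enrich_and_filter(g_per, fs, per_background,
                             config$enrichment_fdr)
      enr <- e$enrichment
      g_per_f <- suppressWarnings(
        filter_key_modules_by_annotation(e$graph, fixtures$annotation))
    } else {
      g1 <- suppressWarnings(
        filter_key_modules_by_annotation(g_per, fixtures$annotation))
      e <- enrich_and_filter(g1, fs, per_background, config$enrichment_fdr)
      enr <- e$enrichment
      g_per_f <- e$graph
    }
  }

  candidates <- suppressWarnings(
    extract_candidates(g_all_f, g_per_f, pd_present))
  tick("linkage_and_candidates")

  # --- validation --------------------------------------------------------
  roc <- stagewise_contrasts(candidates, norm, groups, pd_present)
  cand_ids <- unique(candidates$table$mirna_id)
  qpcr <- data.frame(mirna_id = character(0), group = character(0),
                     mean_fold = numeric(0), sd_fold = numeric(0),
                     dunnett_p = numeric(0))
  qpcr_valid <- character(0)
  if (length(cand_ids) > 0) {
    ct <- generate_ct_table(cohort, cand_ids, slope = 1, intercept = 30,
                            noise_sd = config$ct_noise_sd,
                            seed = config$seed + 303L)
    dd <- ddct_fold_change(ct)
    rows <- list()
    for (id in cand_ids) {
      resp <- if (config$qpcr_scale == "log2_fold") -dd$ddct[id, ]
      else dd$fold[id, ]
      ad <- anova_dunnett(resp, dd$groups)
      s <- dd$summary[dd$summary$mirna_id == id, ]
      s$dunnett_p <- ad$dunnett$p_adj[match(s$group, ad$dunnett$group)]
      rows[[id]] <- s
      cls <- candidates$table$class[match(id, candidates$table$mirna_id)]
      stg <- candidates$table$stage[match(id, candidates$table$mirna_id)]
      pd <- ad$dunnett[ad$dunnett$group %in% pd_present, ]
      ok <- if (cls == "common") {
        all(pd$p_adj < 0.05)
      } else {
        own <- pd$p_adj[pd$group == stg]
        length(own) == 1 && own < 0.05 &&
          all(pd$p_adj[pd$group != stg] >= 0.05)
      }
      if (isTRUE(ok)) qpcr_valid <- c(qpcr_valid, id)
    }
    qpcr <- do.call(rbind, c(rows, make.row.names = FALSE))
  }

  # ROC-validated: every required contrast's CI excludes 0.5
  roc_valid <- character(0)
  if (nrow(roc) > 0) {
    ok <- tapply(roc$ci_low > 0.5, roc$mirna_id, all)
    roc_valid <- names(ok)[ok]
  }
  both_valid <- sort(intersect(roc_valid, qpcr_valid))
  tick("validation")

  summary <- list(
    n_mirna = nrow(cohort$counts),
    n_samples = ncol(cohort$counts),
    de_union_size = length(de_union$union),
    de_by_nb = length(de_union$by_nb),
    de_by_t = length(de_union$by_t),
    de_both = length(de_union$both),
    de_removed_by_prevalence = length(de_union$removed_by_prevalence),
    modules_per_stage_all_arm = vapply(all_stage, function(n)
      if (is.null(n$partition)) 0L else n$partition$module_count,
      integer(1)),
    modules_per_stage_per_arm = vapply(per_stage, function(n)
      if (is.null(n$partition)) 0L else n$partition$module_count,
      integer(1)),
    key_modules_all_arm = nrow(g_all_f$nodes),
    key_modules_per_arm = nrow(g_per_f$nodes),
    n_common = length(candidates$common),
    n_specific = lengths(candidates$specific),
    roc_validated = sort(roc_valid),
    qpcr_validated = sort(qpcr_valid),
    both_validated = both_valid,
    seed = config$seed
  )

  result <- list(
    config = config, cohort = cohort, norm = norm,
    de = list(per_contrast = de_list, union = de_union, table = de_table,
              venn = de_union$venn),
    networks = list(
      all_stage = list(nets = all_stage,
                       partitions = lapply(all_stage, `[[`, "partition")),
      per_stage = list(nets = per_stage,
                       partitions = lapply(per_stage, `[[`, "partition"))),
    linkage = list(all_stage = g_all, per_stage = g_per,
                   all_stage_filtered = g_all_f,
                   per_stage_filtered = g_per_f,
                   enrichment = enr),
    candidates = candidates,
    validation = list(roc = roc, qpcr = qpcr,
                      roc_validated = sort(roc_valid),
                      qpcr_validated = sort(qpcr_valid),
                      both_validated = both_valid),
    summary = summary
  )
  # drop NULL partitions from the writable partition lists
  for (arm in c("all_stage", "per_stage")) {
    p <- result$networks[[arm]]$partitions
    result$networks[[arm]]$partitions <-
      p[!vapply(p, is.null, logical(1))]
  }
  result$stage_log <- stage_log
  class(result) <- "run_summary"
  if (!is.null(outdir)) {
    result$manifest <- write_results_tables(result, outdir)
    # timings are not deterministic, so the log stays out of the manifest
    writeLines(c(sprintf("seed\t%d", config$seed), stage_log),
               file.path(outdir, "run_log.txt"))
  }
  result
}

#' @export
print.run_summary <- function(x, ...) {
  s <- x$summary
  cat("EV-miRNA screening run (seed ", s$seed, ")\n", sep = "")
  cat("  cohort: ", s$n_mirna, " miRNAs x ", s$n_samples, " samples\n",
      sep = "")
  cat("  DE union: ", s$de_union_size, " (NB ", s$de_by_nb, ", t ",
      s$de_by_t, ", both ", s$de_both, "; prevalence removed ",
      s$de_removed_by_prevalence, ")\n", sep = "")
  cat("  modules (all-stage arm):",
      paste(sprintf("%s=%d", names(s$modules_per_stage_all_arm),
                    s$modules_per_stage_all_arm), collapse = " "), "\n")
  cat("  modules (per-stage arm):",
      paste(sprintf("%s=%d", names(s$modules_per_stage_per_arm),
                    s$modules_per_stage_per_arm), collapse = " "), "\n")
  cat("  key modules: all-stage arm ", s$key_modules_all_arm,
      ", per-stage arm ", s$key_modules_per_arm, "\n", sep = "")
  cat("  candidates: ", s$n_common, " common; specific ",
      paste(sprintf("%s=%d", names(s$n_specific), s$n_specific),
            collapse = " "), "\n", sep = "")
  cat("  validated: ROC ", length(s$roc_validated), ", qPCR ",
      length(s$qpcr_validated), ", both ", length(s$both_validated), "\n",
      sep = "")
  if (length(s$both_validated) > 0)
    cat("  both-methods set:", paste(s$both_validated, collapse = ", "),
        "\n")
  invisible(x)
}
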