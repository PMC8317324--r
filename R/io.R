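#' Write a cohort to TSV files
#'
#' Counts are written as a header-bearing TSV with miRNA rows and sample
#' columns; metadata as (`sample_id`, `group`); planted truth, when present,
#' as (`mirna_id`, `module`, `marker_class`, `stage`, `direction`).
#'
#' @param cohort a cohort.
#' @param counts_path,metadata_path,truth_path output paths; `truth_path`
#'   may be `NULL`.
#' @return invisibly, the paths written.
#' @export
write_cohort <- function(cohort, counts_path, metadata_path,
                         truth_path = NULL) {
  cts <- data.frame(mirna_id = rownames(cohort$counts), cohort$counts,
                    check.names = FALSE, stringsAsFactors = FALSE)
  write.table(cts, counts_path, sep = "\t", quote = FALSE, row.names = FALSE)
  write.table(cohort$samples, metadata_path, sep = "\t", quote = FALSE,
              row.names = FALSE)
  paths <- c(counts_path, metadata_path)
  if (!is.null(truth_path) && !is.null(cohort$truth)) {
    tr <- cohort$truth
    ids <- names(tr$module_of)
    marker_class <- rep("none", length(ids))
    stage <- rep(NA_character_, length(ids))
    marker_class[ids %in% tr$common_markers] <- "common"
    for (s in names(tr$specific_markers)) {
      hit <- ids %in% tr$specific_markers[[s]]
      marker_class[hit] <- "specific"
      stage[hit] <- s
    }
    df <- data.frame(mirna_id = ids, module = unname(tr$module_of),
                     marker_class = marker_class, stage = stage,
                     direction = unname(tr$direction),
                     stringsAsFactors = FALSE)
    write.table(df, truth_path, sep = "\t", quote = FALSE, row.names = FALSE)
    paths <- c(paths, truth_path)
  }
  invisible(paths)
}

#' Load a cohort from counts and metadata TSVs
#'
#' Validates that every metadata sample matches a counts column, that counts
#' are non-negative integers, that group labels are known, and that miRNA
#' ids are unique; errors carry the offending row/column.
#'
#' @param counts_path TSV with a `mirna_id` column then one column per
#'   sample.
#' @param metadata_path TSV with columns `sample_id`, `group`.
#' @return a `cohort` (without truth).
#' @export
load_cohort <- function(counts_path, metadata_path) {
  if (!file.exists(counts_path)) stop("counts file not found: ", counts_path)
  if (!file.exists(metadata_path))
    stop("metadata file not found: ", metadata_path)
  cts <- read.delim(counts_path, check.names = FALSE,
                    stringsAsFactors = FALSE)
  meta <- read.delim(metadata_path, stringsAsFactors = FALSE)
  if (!"mirna_id" %in% names(cts))
    stop("counts file lacks a 'mirna_id' column")
  if (!all(c("sample_id", "group") %in% names(meta)))
    stop("metadata must have columns sample_id and group")
  if (anyDuplicated(cts$mirna_id))
    stop("duplicate miRNA ids in counts: ",
         paste(unique(cts$mirna_id[duplicated(cts$mirna_id)]), collapse = ", "))
  missing <- setdiff(meta$sample_id, names(cts))
  if (length(missing) > 0)
    stop("metadata sample(s) absent from counts: ",
         paste(missing, collapse = ", "))
  bad_groups <- setdiff(unique(meta$group), .GROUPS)
  if (length(bad_groups) > 0)
    stop("unknown group label(s): ", paste(bad_groups, collapse = ", "))
  m <- as.matrix(cts[, meta$sample_id, drop = FALSE])
  if (!is.numeric(m) || any(!is.finite(m)) || any(m < 0) ||
      any(m != round(m))) {
    bad <- which(!is.finite(m) | m < 0 | m != round(m), arr.ind = TRUE)[1, ]
    stop("non-integer or negative count at miRNA '", cts$mirna_id[bad[1]],
         "', sample '", meta$sample_id[bad[2]], "'")
  }
  storage.mode(m) <- "integer"
  rownames(m) <- cts$mirna_id
  cohort <- list(counts = m,
                 samples = meta[, c("sample_id", "group")],
                 mirna_ids = cts$mirna_id,
                 truth = NULL)
  class(cohort) <- "cohort"
  cohort
}

#' Export a thresholded TOM as a Cytoscape-compatible edge list
#'
#' Writes one TSV row (`source`, `target`, `weight`) per unordered pair with
#' topological overlap at or above `threshold`, with `source` preceding
#' `target` in matrix order.
#'
#' @param tom symmetric TOM matrix with miRNA dimnames.
#' @param threshold export cut in `[0, 1]`.
#' @param path output TSV path.
#' @return the number of edges written.
#' @export
export_cytoscape_edges <- function(tom, threshold, path) {
  if (threshold < 0 || threshold > 1) stop("threshold must lie in [0, 1]")
  if (!isTRUE(all.equal(tom, t(tom), tolerance = 1e-8)))
    stop("TOM must be symmetric")
  n <- nrow(tom)
  ut <- which(upper.tri(tom) & tom >= threshold, arr.ind = TRUE)
  df <- data.frame(source = rownames(tom)[ut[, 1]],
                   target = colnames(tom)[ut[, 2]],
                   weight = tom[ut],
                   stringsAsFactors = FALSE)
  df <- df[order(match(df$source, rownames(tom)),
                 match(df$target, colnames(tom))), , drop = FALSE]
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  nrow(df)
}

#' Assemble the run configuration
#'
#' Collects every tunable of the screening pipeline: differential-expression
#' cuts, the prevalence fraction, co-expression network settings, per-stage
#' TOM export thresholds, the enrichment FDR cut, validation settings, and
#' the seed. Defaults follow the pipeline's reference settings (P < 0.05
#' with |logFC| > 1 for the NB test; P < 0.05 with |t| > 2 for the t-test;
#' prevalence one half; TOM export thresholds 0.05/0.43/0.05/0.05 for
#' control/II/III/IV; enrichment FDR < 0.05).
#'
#' @param p_cut,logfc_cut,t_cut differential-expression thresholds.
#' @param prevalence fraction in `(0, 1]` of samples in which a miRNA must
#'   have a nonzero count.
#' @param beta soft-threshold power; the default 6 is the canonical
#'   unsigned-network power. `"auto"` selects by scale-free fit via
#'   [pick_soft_threshold()], which is informative only for networks large
#'   enough to exhibit a degree distribution.
#' @param beta_grid candidate powers used when `beta = "auto"`.
#' @param scale_free_r2_target target fit index for automatic selection.
#' @param min_module_size,deep_split,merge_dissimilarity module-detection
#'   settings (see [cut_modules()] and [merge_modules()]).
#' @param tom_export_thresholds named per-stage TOM edge-export cuts.
#' @param enrichment_fdr BH FDR cut for function-set enrichment.
#' @param filter_order `"enrichment_then_annotation"` or the reverse, for the
#'   per-stage arm.
#' @param stage_network_samples samples entering each per-stage network:
#'   the stage's own samples (`"stage_only"`, default — module identity then
#'   reflects pure co-expression) or the stage plus the control group
#'   (`"stage_plus_control"`, which folds the case-control axis into the
#'   correlation structure).
#' @param qpcr_scale scale on which the qPCR group comparison is tested:
#'   `"log2_fold"` (default; the -ddCt scale, variance-stabilized) or
#'   `"fold"` (raw `2^-ddCt` ratios).
#' @param prior_count prior added when computing logCPM.
#' @param ct_noise_sd Ct noise used when simulating the qPCR validation
#'   table.
#' @param seed integer seed for the whole run.
#' @param simulation optional [simulation_config()]; when present the
#'   pipeline simulates its cohort.
#' @param counts_path,metadata_path input files used when no simulation is
#'   requested.
#' @param annotation,function_sets disease-annotation and function-set
#'   tables (data.frames) or `NULL` to derive fixtures from planted truth.
#' @return a `run_config` list.
#' @export
run_config <- function(p_cut = 0.05, logfc_cut = 1, t_cut = 2,
                       prevalence = 0.5,
                       beta = 6,
                       beta_grid = c(1:10, 12, 14, 16, 18, 20),
                       scale_free_r2_target = 0.8,
                       min_module_size = 5L,
                       deep_split = 2L,
                       merge_dissimilarity = 0.25,
                       tom_export_thresholds =
                         c(control = 0.05, II = 0.43, III = 0.05, IV = 0.05),
                       enrichment_fdr = 0.05,
                       filter_order = c("enrichment_then_annotation",
                                        "annotation_then_enrichment"),
                       stage_network_samples = c("stage_only",
                                                 "stage_plus_control"),
                       qpcr_scale = c("log2_fold", "fold"),
                       prior_count = 2,
                       ct_noise_sd = 0.25,
                       seed = 1L,
                       simulation = NULL,
                       counts_path = NULL, metadata_path = NULL,
                       annotation = NULL, function_sets = NULL) {
  filter_order <- match.arg(filter_order)
  stage_network_samples <- match.arg(stage_network_samples)
  qpcr_scale <- match.arg(qpcr_scale)
  if (prevalence <= 0 || prevalence > 1)
    stop("prevalence must lie in (0, 1]")
  if (!all(is.finite(c(p_cut, logfc_cut, t_cut, enrichment_fdr))))
    stop("all cuts must be finite")
  if (!setequal(names(tom_export_thresholds), .GROUPS))
    stop("tom_export_thresholds must cover control, II, III, IV")
  cfg <- list(p_cut = p_cut, logfc_cut = logfc_cut, t_cut = t_cut,
              prevalence = prevalence, beta = beta, beta_grid = beta_grid,
              scale_free_r2_target = scale_free_r2_target,
              min_module_size = as.integer(min_module_size),
              deep_split = as.integer(deep_split),
              merge_dissimilarity = merge_dissimilarity,
              tom_export_thresholds = tom_export_thresholds[.GROUPS],
              enrichment_fdr = enrichment_fdr,
              filter_order = filter_order,
              stage_network_samples = stage_network_samples,
              qpcr_scale = qpcr_scale,
              prior_count = prior_count,
              ct_noise_sd = ct_noise_sd,
              seed = as.integer(seed),
              simulation = simulation,
              counts_path = counts_path, metadata_path = metadata_path,
              annotation = annotation, function_sets = function_sets)
  class(cfg) <- "run_config"
  cfg
}

#' Write all pipeline result tables plus a checksum manifest
#'
#' Tables are written with a fixed column order so that re-running an
#' identical configuration reproduces identical files; the manifest lists
#' each file with its MD5 checksum. The fully resolved run configuration is
#' written alongside as JSON.
#'
#' @param result a [run_pipeline()] result.
#' @param dir output directory (created if needed).
#' @return the manifest data.frame (`file`, `md5`).
#' @export
write_results_tables <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  if (!dir.exists(dir)) stop("cannot create output directory: ", dir)
  files <- character(0)
  wr <- function(df, name) {
    path <- file.path(dir, name)
    write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
    files <<- c(files, path)
  }
  wr(result$de$table, "de_table.tsv")
  wr(result$de$venn, "venn_counts.tsv")
  for (arm in c("all_stage", "per_stage")) {
    parts <- result$networks[[arm]]$partitions
    for (st in names(parts)) {
      df <- data.frame(mirna_id = names(parts[[st]]$assignment),
                       module_label = unname(parts[[st]]$assignment),
                       stringsAsFactors = FALSE)
      wr(df, sprintf("modules_%s_%s.tsv", arm, st))
      dend <- parts[[st]]$dendrogram
      if (!is.null(dend))
        wr(data.frame(merge_height = dend$height),
           sprintf("dendro_heights_%s_%s.tsv", arm, st))
    }
    nets <- result$networks[[arm]]$nets
    for (st in names(nets)) {
      net <- nets[[st]]
      if (is.null(net$tom)) next
      thr <- result$config$tom_export_thresholds[[st]]
      path <- file.path(dir, sprintf("edges_%s_%s.tsv", arm, st))
      export_cytoscape_edges(net$tom, thr, path)
      files <- c(files, path)
      if (!is.null(net$fit_table))
        wr(net$fit_table, sprintf("scale_free_fit_%s_%s.tsv", arm, st))
    }
  }
  wr(result$linkage$all_stage$edges, "linkage_edges_all_stage.tsv")
  wr(result$linkage$per_stage$edges, "linkage_edges_per_stage.tsv")
  wr(result$candidates$table, "candidates.tsv")
  wr(result$validation$roc, "roc.tsv")
  wr(result$validation$qpcr, "qpcr.tsv")
  cfg_path <- file.path(dir, "resolved_config.json")
  cfg <- result$config
  cfg$simulation <- unclass(cfg$simulation)
  jsonlite::write_json(unclass(cfg), cfg_path, auto_unbox = TRUE,
                       digits = NA, null = "null", pretty = TRUE)
  files <- c(files, cfg_path)
  manifest <- data.frame(file = basename(files),
                         md5 = unname(tools::md5sum(files)),
                         stringsAsFactors = FALSE)
  write.table(manifest, file.path(dir, "manifest.tsv"), sep = "\t",
              quote = FALSE, row.names = FALSE)
  manifest
}
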