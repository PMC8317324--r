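#' Simulation configuration for a ground-truthed EV-miRNA cohort
#'
#' Builds the parameter set for [generate_cohort()]. The default ("desk")
#' profile is a 300 miRNA x 60 sample cohort (group sizes 15/10/20/15) with
#' four planted co-expression modules of 25 miRNAs; the "fullsize" profile
#' matches the scale of a 1486 miRNA x 103 sample study cohort with group
#' sizes 31/8/42/22.
#'
#' Planted modules carry the differential-expression effect for all of their
#' members: one module is shifted in every disease stage (the "common"
#' module) and one module per stage is shifted in that stage only. Named
#' markers are representative members of those modules and are the miRNAs a
#' disease-annotation table is expected to cover.
#'
#' @param n_mirna number of miRNAs (rows).
#' @param group_sizes named integer vector of samples per group; names must
#'   be `control`, `II`, `III`, `IV`.
#' @param n_modules number of planted co-expression modules.
#' @param module_sizes integer vector (length `n_modules`) of module sizes;
#'   their sum must not exceed `n_mirna`.
#' @param within_module_loading strength in `[0, 1]` of the per-module latent
#'   factor shared by module members (log2 scale).
#' @param n_common_markers number of named markers in the common module.
#' @param n_specific_markers_per_stage named integer vector (`II`, `III`,
#'   `IV`) of named markers in each stage-specific module.
#' @param common_effect_log2fc log2 fold change applied to common-module
#'   members in every disease stage.
#' @param specific_effect_log2fc log2 fold change applied to stage-module
#'   members in their own stage only.
#' @param nb_dispersion negative-binomial dispersion phi (> 0) with
#'   `Var = mu + phi * mu^2`.
#' @param libsize_log_sd sdlog of the lognormal library sizes (median 1e6).
#' @param baseline_log2cpm_range range of baseline log2CPM for background
#'   miRNAs.
#' @param signal_log2cpm_range range of baseline log2CPM for planted module
#'   members (kept in the well-expressed band so planted structure is
#'   observable).
#' @param seed integer seed; the same configuration and seed reproduce the
#'   count matrix bit for bit.
#' @param profile `"desk"` (default) or `"fullsize"`; presets for `n_mirna`
#'   and `group_sizes`, overridable by the explicit arguments.
#' @return a `simulation_config` list.
#' @export
simulation_config <- function(n_mirna = NULL,
                              group_sizes = NULL,
                              n_modules = 4L,
                              module_sizes = rep(25L, 4L),
                              within_module_loading = 0.9,
                              n_common_markers = 4L,
                              n_specific_markers_per_stage =
                                c(II = 3L, III = 1L, IV = 9L),
                              common_effect_log2fc = 2,
                              specific_effect_log2fc = 2,
                              nb_dispersion = 0.1,
                              libsize_log_sd = 0.3,
                              baseline_log2cpm_range = c(-5, 15),
                              signal_log2cpm_range = c(2, 12),
                              seed = 1L,
                              profile = c("desk", "fullsize")) {
  profile <- match.arg(profile)
  if (is.null(n_mirna))
    n_mirna <- if (profile == "fullsize") 1486L else 300L
  if (is.null(group_sizes))
    group_sizes <- if (profile == "fullsize")
      c(control = 31L, II = 8L, III = 42L, IV = 22L)
    else
      c(control = 15L, II = 10L, III = 20L, IV = 15L)

  if (!setequal(names(group_sizes), .GROUPS))
    stop("group_sizes must be named control, II, III, IV")
  group_sizes <- group_sizes[.GROUPS]
  if (all(group_sizes[.PD_STAGES] == 0L))
    stop("at least one disease stage must have samples")
  if (length(module_sizes) != n_modules)
    stop("module_sizes must have length n_modules")
  if (sum(module_sizes) > n_mirna)
    stop("sum(module_sizes) exceeds n_mirna")
  if (within_module_loading < 0 || within_module_loading > 1)
    stop("within_module_loading must lie in [0, 1]")
  if (nb_dispersion <= 0) stop("nb_dispersion must be > 0")
  if (libsize_log_sd < 0) stop("libsize_log_sd must be >= 0")
  if (!all(is.finite(c(common_effect_log2fc, specific_effect_log2fc))))
    stop("effect sizes must be finite")
  stages_with_markers <- names(n_specific_markers_per_stage)[
    n_specific_markers_per_stage > 0]
  needed <- (n_common_markers > 0) + length(stages_with_markers)
  if (needed > n_modules)
    stop("not enough modules to host the requested marker classes")

  cfg <- list(
    n_mirna = as.integer(n_mirna),
    group_sizes = group_sizes,
    n_modules = as.integer(n_modules),
    module_sizes = as.integer(module_sizes),
    within_module_loading = within_module_loading,
    n_common_markers = as.integer(n_common_markers),
    n_specific_markers_per_stage = n_specific_markers_per_stage,
    common_effect_log2fc = common_effect_log2fc,
    specific_effect_log2fc = specific_effect_log2fc,
    nb_dispersion = nb_dispersion,
    libsize_log_sd = libsize_log_sd,
    baseline_log2cpm_range = baseline_log2cpm_range,
    signal_log2cpm_range = signal_log2cpm_range,
    seed = as.integer(seed),
    profile = profile
  )
  class(cfg) <- "simulation_config"
  cfg
}

# module "roles": which planted module carries which effect class.
# module 1 -> common (if common markers requested), following modules -> one
# per stage that has specific markers; any remainder are background
# co-expression modules with no group effect.
.module_roles <- function(config) {
  roles <- rep("background", config$n_modules)
  i <- 1L
  if (config$n_common_markers > 0) {
    roles[i] <- "common"
    i <- i + 1L
  }
  for (s in .PD_STAGES) {
    ns <- config$n_specific_markers_per_stage[[s]]
    if (!is.null(ns) && ns > 0) {
      roles[i] <- s
      i <- i + 1L
    }
  }
  roles
}

#' Generate a synthetic cohort with planted truth
#'
#' Draws a miRNA-by-sample count matrix from a negative-binomial model
#' `log2 mu = baseline + group effect + loading * module factor +
#' log2(libsize / 1e6)`, with one latent Gaussian factor per module per
#' sample inducing within-module co-expression. The returned cohort carries
#' a `truth` record (module membership, marker sets, directions) used by the
#' test suites and the run summary.
#'
#' Marker directions alternate up/down within each planted module.
#'
#' @param config a [simulation_config()].
#' @return a `cohort`: list with integer `counts` (miRNA x sample),
#'   `samples` data.frame (`sample_id`, `group`), `mirna_ids`, and `truth`.
#' @export
generate_cohort <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  set.seed(config$seed)

  n <- config$n_mirna
  gs <- config$group_sizes
  n_s <- sum(gs)
  groups <- rep(names(gs), gs)
  sample_ids <- sprintf("S%03d", seq_len(n_s))
  mirna_ids <- sprintf("miR-%04d", seq_len(n))

  # module membership: contiguous blocks at the top of the matrix
  module_of <- rep(NA_integer_, n)
  idx <- 1L
  for (m in seq_len(config$n_modules)) {
    sz <- config$module_sizes[m]
    module_of[idx:(idx + sz - 1L)] <- m
    idx <- idx + sz
  }
  roles <- .module_roles(config)

  baseline <- runif(n, config$baseline_log2cpm_range[1],
                    config$baseline_log2cpm_range[2])
  in_module <- !is.na(module_of)
  baseline[in_module] <- runif(sum(in_module), config$signal_log2cpm_range[1],
                               config$signal_log2cpm_range[2])

  # direction alternates within each module; background genes have none
  direction <- rep(NA_character_, n)
  for (m in seq_len(config$n_modules)) {
    members <- which(module_of == m)
    direction[members] <- ifelse(seq_along(members) %% 2L == 1L, "up", "down")
  }

  # per-gene per-group log2 shifts
  delta <- matrix(0, n, length(.GROUPS), dimnames = list(NULL, .GROUPS))
  sgn <- ifelse(is.na(direction), 0, ifelse(direction == "up", 1, -1))
  for (m in seq_len(config$n_modules)) {
    members <- which(module_of == m)
    if (roles[m] == "common") {
      for (s in .PD_STAGES)
        delta[members, s] <- sgn[members] * config$common_effect_log2fc
    } else if (roles[m] %in% .PD_STAGES) {
      delta[members, roles[m]] <-
        sgn[members] * config$specific_effect_log2fc
    }
  }

  # one latent factor per module per sample; a stage-specific module's
  # co-expression program is active only in that stage's samples, while
  # common/background programs run in every sample
  factors <- matrix(rnorm(max(config$n_modules, 1) * n_s),
                    max(config$n_modules, 1), n_s)
  activity <- matrix(1, max(config$n_modules, 1), n_s)
  for (m in seq_len(config$n_modules))
    if (roles[m] %in% .PD_STAGES)
      activity[m, groups != roles[m]] <- 0
  libsize <- round(rlnorm(n_s, meanlog = log(1e6),
                          sdlog = config$libsize_log_sd))

  log2mu <- matrix(baseline, n, n_s) + delta[, groups, drop = FALSE]
  if (config$n_modules > 0) {
    load_mat <- matrix(0, n, n_s)
    load_mat[in_module, ] <- config$within_module_loading *
      (factors * activity)[module_of[in_module], , drop = FALSE]
    log2mu <- log2mu + load_mat
  }
  mu <- 2^log2mu * rep(libsize / 1e6, each = n)
  counts <- matrix(rnbinom(n * n_s, mu = mu, size = 1 / config$nb_dispersion),
                   n, n_s, dimnames = list(mirna_ids, sample_ids))
  storage.mode(counts) <- "integer"

  # named markers: alternating-direction representatives of their module
  common_markers <- character(0)
  specific_markers <- setNames(vector("list", length(.PD_STAGES)), .PD_STAGES)
  for (m in seq_len(config$n_modules)) {
    members <- mirna_ids[which(module_of == m)]
    if (roles[m] == "common") {
      common_markers <- head(members, config$n_common_markers)
    } else if (roles[m] %in% .PD_STAGES) {
      specific_markers[[roles[m]]] <-
        head(members, config$n_specific_markers_per_stage[[roles[m]]])
    }
  }
  specific_markers <- specific_markers[!vapply(specific_markers, is.null,
                                               logical(1))]

  truth <- list(
    module_of = setNames(
      ifelse(is.na(module_of), "none", .module_label(module_of)), mirna_ids),
    module_role = setNames(roles, .module_label(seq_len(config$n_modules))),
    common_markers = common_markers,
    specific_markers = specific_markers,
    direction = setNames(direction, mirna_ids)
  )

  cohort <- list(
    counts = counts,
    samples = data.frame(sample_id = sample_ids, group = groups,
                         stringsAsFactors = FALSE),
    mirna_ids = mirna_ids,
    truth = truth
  )
  class(cohort) <- "cohort"
  cohort
}

#' @export
print.cohort <- function(x, ...) {
  cat("cohort:", nrow(x$counts), "miRNAs x", ncol(x$counts), "samples\n")
  print(table(x$samples$group)[.GROUPS])
  if (!is.null(x$truth))
    cat("planted truth:", length(x$truth$common_markers), "common and",
        sum(lengths(x$truth$specific_markers)), "stage-specific markers\n")
  invisible(x)
}

#' Synthesize a disease-annotation table from planted truth
#'
#' Emulates an offline disease-miRNA annotation resource (HMDD-like): each
#' planted marker is included with probability `1 - dropout`, and `n_decoys`
#' non-marker miRNAs are added as annotation noise.
#'
#' @param truth the `truth` element of a simulated [generate_cohort()].
#' @param n_decoys number of annotated non-marker miRNAs.
#' @param dropout probability in `[0, 1]` that a planted marker is missing
#'   from the table (incomplete curation).
#' @param seed integer seed.
#' @return data.frame with columns `mirna_id`, `disease`.
#' @export
generate_annotation_fixture <- function(truth, n_decoys = 25L, dropout = 0,
                                        seed = 1L) {
  if (dropout < 0 || dropout > 1) stop("dropout must lie in [0, 1]")
  markers <- union(truth$common_markers, unlist(truth$specific_markers))
  if (length(markers) == 0) stop("truth contains no planted markers")
  set.seed(seed)
  keep <- markers[runif(length(markers)) >= dropout]
  universe <- names(truth$module_of)
  pool <- setdiff(universe, markers)
  decoys <- if (n_decoys > 0)
    sample(pool, min(n_decoys, length(pool))) else character(0)
  ids <- c(keep, decoys)
  data.frame(mirna_id = ids,
             disease = rep("target_disease", length(ids)),
             stringsAsFactors = FALSE)
}

#' Synthesize miRNA function sets from planted truth
#'
#' Emulates an offline miRNA function-set resource (TAM-like). The first
#' `min(n_sets, n planted modules)` sets are biased draws: a fraction
#' `enrichment_bias` of each is sampled from one planted module, the rest
#' uniformly; remaining sets are uniform draws and serve as enrichment
#' decoys.
#'
#' @param truth `truth` element of a simulated cohort.
#' @param n_sets number of function sets.
#' @param set_size miRNAs per set (>= 1).
#' @param enrichment_bias fraction in `[0, 1]` of a biased set drawn from its
#'   module.
#' @param seed integer seed.
#' @return data.frame with columns `set_id`, `mirna_id`.
#' @export
generate_function_sets <- function(truth, n_sets = 8L, set_size = 20L,
                                   enrichment_bias = 0.8, seed = 1L) {
  if (set_size < 1) stop("set_size must be >= 1")
  if (n_sets == 0)
    return(data.frame(set_id = character(0), mirna_id = character(0),
                      stringsAsFactors = FALSE))
  set.seed(seed)
  universe <- names(truth$module_of)
  modules <- setdiff(unique(truth$module_of), "none")
  rows <- list()
  for (i in seq_len(n_sets)) {
    if (i <= length(modules)) {
      members <- universe[truth$module_of == modules[i]]
      n_bias <- min(round(enrichment_bias * set_size), length(members))
      picked <- sample(members, n_bias)
      rest <- sample(setdiff(universe, picked), set_size - n_bias)
      ids <- c(picked, rest)
    } else {
      ids <- sample(universe, min(set_size, length(universe)))
    }
    rows[[i]] <- data.frame(set_id = sprintf("FS%02d", i), mirna_id = ids,
                            stringsAsFactors = FALSE)
  }
  do.call(rbind, rows)
}

#' Synthesize a qPCR Ct table from a cohort
#'
#' Ct values follow the standard amplification model
#' `Ct = intercept - slope * log2(1 + CPM) + N(0, noise_sd)`, where CPM is
#' the library-size-normalized expression of the miRNA in that sample, plus
#' a constant-mean reference row `U6` (mean Ct 15). With `noise_sd = 0` the
#' table is an exact closed form of the expression matrix, so downstream
#' [ddct_fold_change()] recovers planted fold changes exactly.
#'
#' @param cohort a [generate_cohort()] or loaded cohort.
#' @param mirnas character vector of target miRNAs (subset of the cohort).
#' @param slope,intercept amplification line parameters.
#' @param noise_sd Gaussian Ct noise (>= 0).
#' @param seed integer seed.
#' @return a `ct_table`: list with `ct` matrix ((targets + U6) x samples) and
#'   `groups` per sample.
#' @export
generate_ct_table <- function(cohort, mirnas, slope = 1, intercept = 30,
                              noise_sd = 0.25, seed = 1L) {
  if (noise_sd < 0) stop("noise_sd must be >= 0")
  if (!all(mirnas %in% rownames(cohort$counts)))
    stop("mirnas must all be present in the cohort")
  set.seed(seed)
  libsize <- colSums(cohort$counts)
  cpm <- t(t(cohort$counts[mirnas, , drop = FALSE]) / libsize) * 1e6
  ct <- intercept - slope * log2(1 + cpm)
  u6 <- rep(15, ncol(cpm))
  ct <- rbind(ct, U6 = u6)
  if (noise_sd > 0)
    ct <- ct + matrix(rnorm(length(ct), sd = noise_sd), nrow(ct), ncol(ct))
  out <- list(ct = ct,
              groups = setNames(cohort$samples$group,
                                cohort$samples$sample_id))
  class(out) <- "ct_table"
  out
}
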