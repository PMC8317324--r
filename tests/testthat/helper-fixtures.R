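# small configs shared across tests; all fixtures are generated in code

desk_config <- function(seed = 1L, ...) {
  simulation_config(seed = seed, ...)
}

# cohort with no planted signal at all (null calibration)
null_config <- function(seed = 1L, n_mirna = 300L,
                        group_sizes = c(control = 15L, II = 15L,
                                        III = 0L, IV = 0L)) {
  simulation_config(
    n_mirna = n_mirna, group_sizes = group_sizes,
    n_modules = 0L, module_sizes = integer(0),
    within_module_loading = 0,
    n_common_markers = 0L,
    n_specific_markers_per_stage = c(II = 0L, III = 0L, IV = 0L),
    common_effect_log2fc = 0, specific_effect_log2fc = 0,
    seed = seed)
}

# reduced cohort for pipeline-level plumbing tests (fast end-to-end runs)
small_config <- function(seed = 1L) {
  simulation_config(
    n_mirna = 150L,
    group_sizes = c(control = 10L, II = 8L, III = 12L, IV = 10L),
    n_modules = 4L, module_sizes = rep(18L, 4L),
    n_common_markers = 3L,
    n_specific_markers_per_stage = c(II = 2L, III = 1L, IV = 3L),
    seed = seed)
}

# default-scale cohort whose only structure is co-expression (no group
# shifts): the module-recovery setting
module_recovery_config <- function(seed = 1L) {
  simulation_config(
    n_mirna = 300L, n_modules = 4L, module_sizes = rep(25L, 4L),
    within_module_loading = 0.9, n_common_markers = 0L,
    n_specific_markers_per_stage = c(II = 0L, III = 0L, IV = 0L),
    common_effect_log2fc = 0, specific_effect_log2fc = 0, seed = seed)
}

# modules without any group effect (pure co-expression structure)
structure_config <- function(loading, seed = 1L) {
  simulation_config(
    n_mirna = 120L,
    group_sizes = c(control = 15L, II = 15L, III = 15L, IV = 15L),
    n_modules = 4L, module_sizes = rep(20L, 4L),
    within_module_loading = loading,
    n_common_markers = 0L,
    n_specific_markers_per_stage = c(II = 0L, III = 0L, IV = 0L),
    common_effect_log2fc = 0, specific_effect_log2fc = 0,
    seed = seed)
}

# deterministic toy cohort small enough to reason about by hand
toy_cohort <- function(counts, groups) {
  n <- nrow(counts)
  ids <- sprintf("miR-%04d", seq_len(n))
  rownames(counts) <- ids
  colnames(counts) <- sprintf("S%03d", seq_len(ncol(counts)))
  storage.mode(counts) <- "integer"
  co <- list(counts = counts,
             samples = data.frame(sample_id = colnames(counts),
                                  group = groups,
                                  stringsAsFactors = FALSE),
             mirna_ids = ids, truth = NULL)
  class(co) <- "cohort"
  co
}

# brute-force O(n^3) TOM used as the independent oracle
tom_bruteforce <- function(a) {
  diag(a) <- 0
  n <- nrow(a)
  k <- rowSums(a)
  tom <- diag(n)
  for (i in seq_len(n)) for (j in seq_len(n)) {
    if (i == j) next
    num <- sum(a[i, ] * a[, j]) + a[i, j]
    tom[i, j] <- num / (min(k[i], k[j]) + 1 - a[i, j])
  }
  dimnames(tom) <- dimnames(a)
  tom
}

# brute-force all-pairs AUC (ties count 1/2)
auc_bruteforce <- function(scores, labels, positive = TRUE) {
  p <- scores[labels == positive]
  n <- scores[labels != positive]
  s <- 0
  for (x in p) for (y in n) s <- s + (x > y) + 0.5 * (x == y)
  s / (length(p) * length(n))
}
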