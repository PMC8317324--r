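#' Soft-threshold adjacency
#'
#' Unsigned weighted adjacency `a_ij = |cor(x_i, x_j)|^beta` from Pearson
#' correlation of expression rows; the diagonal is set to 0 so that row sums
#' are network connectivities. Constant rows have undefined correlation and
#' contribute zero adjacency (with a warning).
#'
#' @param x expression matrix, miRNAs x samples (>= 3 samples).
#' @param beta soft-threshold power (> 0).
#' @return symmetric adjacency matrix with zero diagonal.
#' @export
soft_adjacency <- function(x, beta) {
  if (ncol(x) < 3) stop("need at least 3 samples")
  if (beta <= 0) stop("beta must be > 0")
  suppressWarnings(cc <- cor(t(x)))
  if (anyNA(cc)) {
    warning("constant rows produce undefined correlations; treated as 0")
    cc[is.na(cc)] <- 0
  }
  a <- abs(cc)^beta
  diag(a) <- 0
  a
}

#' Scale-free topology fit and automatic soft-threshold selection
#'
#' For each candidate power, fits the log-log regression of the binned
#' connectivity distribution, `log10 p(k)` on `log10 k`, and reports the fit
#' index r-squared together with the slope. The selected power is the
#' smallest usable candidate whose fit reaches `r2_target` with a negative
#' slope; if none qualifies, the usable candidate with the best fit. Ties
#' prefer the smaller power. A candidate is usable when its fitted slope is
#' negative and it is not below `min_beta`. On small screened gene sets the
#' fit index is often non-identifying (it can grow with the power as the
#' network disconnects), which is why the pipeline defaults to a fixed
#' canonical power instead of automatic selection; see [run_config()].
#'
#' @param x expression matrix, miRNAs x samples.
#' @param grid candidate powers.
#' @param r2_target target fit index in `(0, 1)`.
#' @param n_bins connectivity histogram bins.
#' @param min_beta minimum admissible power (0 disables the floor).
#' @return list with `beta` and a `fit_table` data.frame
#'   (`beta`, `r_squared`, `slope`, `mean_k`).
#' @export
pick_soft_threshold <- function(x, grid = c(1:10, 12, 14, 16, 18, 20),
                                r2_target = 0.8, n_bins = 10,
                                min_beta = 0) {
  if (length(grid) == 0) stop("candidate grid is empty")
  rows <- lapply(grid, function(b) {
    a <- soft_adjacency(x, b)
    k <- rowSums(a)
    if (max(k) - min(k) < 1e-12)
      return(data.frame(beta = b, r_squared = NA_real_, slope = NA_real_,
                        mean_k = mean(k)))
    brk <- seq(min(k), max(k), length.out = n_bins + 1)
    bin <- cut(k, brk, include.lowest = TRUE)
    pk <- tapply(k, bin, length) / length(k)
    mk <- tapply(k, bin, mean)
    ok <- !is.na(pk) & pk > 0 & mk > 0
    if (sum(ok) < 3)
      return(data.frame(beta = b, r_squared = NA_real_, slope = NA_real_,
                        mean_k = mean(k)))
    fit <- lm(log10(pk[ok]) ~ log10(mk[ok]))
    data.frame(beta = b, r_squared = summary(fit)$r.squared,
               slope = unname(coef(fit)[2]), mean_k = mean(k))
  })
  tab <- do.call(rbind, rows)
  usable <- !is.na(tab$r_squared) & tab$slope < 0 & tab$beta >= min_beta
  if (!any(usable))  # relax the power floor rather than fail outright
    usable <- !is.na(tab$r_squared) & tab$slope < 0
  hit <- usable & tab$r_squared >= r2_target
  beta <- if (any(hit)) {
    tab$beta[which(hit)[1]]
  } else if (any(usable)) {
    cand <- tab[usable, ]
    cand$beta[which.max(cand$r_squared)]
  } else {
    stop("no candidate power yields a usable scale-free fit")
  }
  list(beta = beta, fit_table = tab)
}

#' Topological overlap matrix
#'
#' Unsigned TOM,
#' `TOM_ij = (sum_u a_iu a_uj + a_ij) / (min(k_i, k_j) + 1 - a_ij)` with
#' `k_i = sum_u a_iu` and unit diagonal; shared-neighbour similarity on top
#' of direct adjacency. `1 - TOM` is the clustering dissimilarity.
#'
#' @param adjacency symmetric matrix with values in `[0, 1]` and zero
#'   diagonal.
#' @return symmetric TOM matrix with unit diagonal.
#' @export
topological_overlap <- function(adjacency) {
  a <- adjacency
  if (!isTRUE(all.equal(a, t(a), tolerance = 1e-8)))
    stop("adjacency must be symmetric")
  if (any(a < 0 | a > 1)) stop("adjacency values must lie in [0, 1]")
  diag(a) <- 0
  k <- rowSums(a)
  num <- a %*% a + a
  den <- outer(k, k, pmin) + 1 - a
  tom <- num / den
  diag(tom) <- 1
  dimnames(tom) <- dimnames(adjacency)
  tom
}

# medoid of a module: the member with the highest mean TOM to the others
.module_medoid <- function(tom, members) {
  if (length(members) == 1) return(members)
  sub <- tom[members, members, drop = FALSE]
  diag(sub) <- NA
  members[which.max(rowMeans(sub, na.rm = TRUE))]
}

#' Module detection by dendrogram cutting with medoid assignment
#'
#' Average-linkage hierarchical clustering on `1 - TOM`, a static cut whose
#' height adapts to the network density (dissimilarity
#' `1 - m * mean(off-diagonal TOM)`, with the multiplier `m` controlled by
#' `deep_split`: deeper splits cut lower and split more finely), retention
#' of clusters of at least `min_module_size` leaves as module cores, and a
#' PAM-like second pass that assigns each remaining leaf to the module whose
#' medoid it most resembles, provided that similarity reaches
#' `pam_strictness` times the module's own member-to-medoid similarity.
#' Leaves failing that remain `"grey"` (unassigned). Module labels are
#' color-like strings ordered by decreasing module size. An explicit
#' `cut_height` overrides the adaptive rule.
#'
#' @param tom TOM matrix with miRNA dimnames.
#' @param min_module_size smallest retained core size.
#' @param deep_split integer 0-4; larger values cut deeper and so split more
#'   finely.
#' @param cut_height optional explicit dendrogram cut height.
#' @param pam_stage run the medoid-assignment pass.
#' @param pam_strictness fraction of within-module medoid similarity a leaf
#'   must reach to be adopted.
#' @return a `module_partition`: list with `assignment` (named character,
#'   `"grey"` for unassigned), `dendrogram` (hclust), `module_count`,
#'   `sizes`.
#' @export
cut_modules <- function(tom, min_module_size = 5L, deep_split = 2L,
                        cut_height = NULL, pam_stage = TRUE,
                        pam_strictness = 0.1) {
  ids <- rownames(tom)
  n <- nrow(tom)
  empty <- function(dend) {
    p <- list(assignment = setNames(rep("grey", n), ids), dendrogram = dend,
              module_count = 0L, sizes = integer(0))
    class(p) <- "module_partition"
    p
  }
  if (n < 2 || n < min_module_size) {
    warning("fewer miRNAs than min_module_size; all unassigned")
    return(empty(NULL))
  }
  diss <- 1 - tom
  h <- hclust(as.dist(diss), method = "average")
  if (is.null(cut_height)) {
    mult <- c(1.5, 1.75, 2, 2.25, 2.5)[pmin(pmax(deep_split, 0L), 4L) + 1L]
    mean_tom <- mean(tom[upper.tri(tom)])
    cut_height <- 1 - mult * mean_tom
    cut_height <- min(cut_height, 0.99 * max(h$height))
    cut_height <- max(cut_height, min(h$height) + 1e-10)
  }
  cl <- cutree(h, h = cut_height)
  sizes <- table(cl)
  cores <- names(sizes)[sizes >= min_module_size]
  if (length(cores) == 0) {
    warning("no cluster reaches min_module_size; all unassigned")
    return(empty(h))
  }
  assignment <- setNames(rep("grey", n), ids)
  for (i in seq_along(cores))
    assignment[cl == as.integer(cores[i])] <- paste0("core", i)

  if (pam_stage) {
    mods <- unique(assignment[assignment != "grey"])
    medoids <- vapply(mods, function(m)
      .module_medoid(tom, ids[assignment == m]), character(1))
    med_sim <- vapply(mods, function(m) {
      members <- setdiff(ids[assignment == m], medoids[m])
      if (length(members) == 0) return(1)
      mean(tom[members, medoids[m]])
    }, numeric(1))
    for (leaf in ids[assignment == "grey"]) {
      sims <- tom[leaf, medoids]
      best <- which.max(sims)
      if (sims[best] >= pam_strictness * med_sim[best])
        assignment[leaf] <- mods[best]
    }
  }
  .relabel_partition(assignment, h)
}

# stable color-like labels ordered by decreasing module size; ties broken by
# first appearance in the input order
.relabel_partition <- function(assignment, dend) {
  mods <- unique(assignment[assignment != "grey"])
  if (length(mods) > 0) {
    sz <- vapply(mods, function(m) sum(assignment == m), integer(1))
    mods <- mods[order(-sz, match(mods, mods))]
    new <- setNames(.module_label(seq_along(mods)), mods)
    assignment[assignment != "grey"] <- new[assignment[assignment != "grey"]]
  }
  sizes <- table(assignment[assignment != "grey"])
  p <- list(assignment = assignment, dendrogram = dend,
            module_count = length(sizes),
            sizes = sizes[order(-as.integer(sizes))])
  class(p) <- "module_partition"
  p
}

#' @export
print.module_partition <- function(x, ...) {
  cat("module partition:", x$module_count, "modules,",
      sum(x$assignment == "grey"), "unassigned of", length(x$assignment),
      "\n")
  if (x$module_count > 0) print(x$sizes)
  invisible(x)
}

#' Module eigengenes
#'
#' First principal component of each module's standardized expression,
#' represented as unit-norm sample scores and sign-oriented to correlate
#' positively with the module's mean expression profile.
#'
#' @param x expression matrix, miRNAs x samples.
#' @param assignment named module assignment (`"grey"` ignored).
#' @return matrix samples x modules of eigengene scores.
#' @export
module_eigengenes <- function(x, assignment) {
  mods <- setdiff(unique(assignment), "grey")
  me <- sapply(mods, function(m) {
    sub <- x[names(assignment)[assignment == m], , drop = FALSE]
    scaled <- t(scale(t(sub)))
    scaled[!is.finite(scaled)] <- 0
    sv <- svd(scaled, nu = 0, nv = 1)
    e <- sv$v[, 1]
    mean_prof <- colMeans(sub)
    if (stats::sd(mean_prof) > 0 && cor(e, mean_prof) < 0) e <- -e
    e
  })
  me <- matrix(me, ncol = length(mods),
               dimnames = list(colnames(x), mods))
  me
}

#' Merge modules with similar eigengenes
#'
#' Iteratively merges the module pair whose eigengene dissimilarity
#' `1 - |cor|` is smallest, while it is below `merge_dissimilarity`,
#' recomputing eigengenes after every merge. The merged module keeps the
#' label of the larger member; labels are refreshed by size at the end.
#'
#' @param x expression matrix, miRNAs x samples.
#' @param partition a [cut_modules()] result.
#' @param merge_dissimilarity threshold in `[0, 1]`; 0 merges nothing, 1
#'   collapses all correlated modules.
#' @return a new `module_partition`.
#' @export
merge_modules <- function(x, partition, merge_dissimilarity = 0.25) {
  if (merge_dissimilarity < 0 || merge_dissimilarity > 1)
    stop("merge_dissimilarity must lie in [0, 1]")
  assignment <- partition$assignment
  if (partition$module_count < 2 || merge_dissimilarity == 0)
    return(partition)
  repeat {
    mods <- setdiff(unique(assignment), "grey")
    if (length(mods) < 2) break
    me <- module_eigengenes(x, assignment)
    d <- 1 - abs(suppressWarnings(cor(me)))
    d[!is.finite(d)] <- 1
    diag(d) <- Inf
    best <- which(d == min(d), arr.ind = TRUE)[1, ]
    if (d[best[1], best[2]] >= merge_dissimilarity) break
    a <- mods[best[1]]; b <- mods[best[2]]
    keep <- if (sum(assignment == a) >= sum(assignment == b)) a else b
    drop <- setdiff(c(a, b), keep)
    assignment[assignment == drop] <- keep
  }
  .relabel_partition(assignment, partition$dendrogram)
}
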