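#' Common negative-binomial dispersion by profile maximum likelihood
#'
#' Maximizes the NB log-likelihood over a single dispersion phi shared by
#' all miRNAs, with per-gene per-group means proportional to effective
#' library sizes (rate estimated as the library-weighted group mean).
#'
#' @param counts integer matrix, genes x samples.
#' @param groups group label per sample.
#' @param eff_libsize effective library sizes (library size x TMM factor).
#' @return the estimated dispersion phi (`Var = mu + phi mu^2`).
#' @export
estimate_common_dispersion <- function(counts, groups,
                                       eff_libsize = colSums(counts)) {
  keep <- rowSums(counts) > 0
  counts <- counts[keep, , drop = FALSE]
  groups <- as.character(groups)
  mu <- matrix(0, nrow(counts), ncol(counts))
  for (g in unique(groups)) {
    j <- groups == g
    rate <- rowSums(counts[, j, drop = FALSE]) / sum(eff_libsize[j])
    mu[, j] <- outer(rate, eff_libsize[j])
  }
  ok <- mu > 0
  negll <- function(log_phi) {
    -sum(dnbinom(counts[ok], size = 1 / exp(log_phi), mu = mu[ok],
                 log = TRUE))
  }
  opt <- optimize(negll, interval = log(c(1e-4, 4)))
  exp(opt$minimum)
}

# Conditional NB exact two-sided p-value for a split (s1, s2) of group sums
# over nA and nB samples at a common library size. Under H0 the group sums
# are NB(n*mu, size n/phi); p = sum of conditional probabilities not
# exceeding that of the observed split. Support is restricted to the region
# carrying all but ~1e-12 of the conditional mass (plus the observed point).
.nb_exact_pvalue <- function(s1, s2, nA, nB, phi) {
  t <- s1 + s2
  if (t == 0) return(1)
  mu <- t / (nA + nB)
  size_a <- nA / phi
  size_b <- nB / phi
  mu_a <- nA * mu
  mu_b <- nB * mu
  lo <- max(0, min(qnbinom(1e-12, size = size_a, mu = mu_a),
                   t - qnbinom(1e-12, size = size_b, mu = mu_b,
                               lower.tail = FALSE)))
  hi <- min(t, max(qnbinom(1e-12, size = size_a, mu = mu_a,
                           lower.tail = FALSE),
                   t - qnbinom(1e-12, size = size_b, mu = mu_b)))
  lo <- min(lo, s1); hi <- max(hi, s1)
  s <- lo:hi
  logp <- dnbinom(s, size = size_a, mu = mu_a, log = TRUE) +
    dnbinom(t - s, size = size_b, mu = mu_b, log = TRUE)
  obs <- logp[s == s1]
  tot <- sum(exp(logp - max(logp)))
  num <- sum(exp(logp[logp <= obs + 1e-10] - max(logp)))
  min(1, num / tot)
}

#' Negative-binomial conditional exact test for one contrast
#'
#' edgeR-style classic exact test with a common dispersion: counts are
#' scaled to the geometric-mean effective library size, and for each miRNA
#' the split of the group-sum given the total is tested against the
#' conditional distribution implied by equal-mean negative binomials.
#'
#' @param cohort a cohort.
#' @param contrast character vector `c(groupA, groupB)`; logFC is log2 of B
#'   over A.
#' @param norm optional [normalize_logcpm()] result (recomputed if absent).
#' @param dispersion optional common dispersion; estimated on the contrast's
#'   samples when `NULL`.
#' @return data.frame (`mirna_id`, `logFC`, `nb_p`) with the dispersion in
#'   attribute `"dispersion"`.
#' @export
nb_exact_test <- function(cohort, contrast, norm = NULL, dispersion = NULL) {
  groups <- cohort$samples$group
  jA <- which(groups == contrast[1])
  jB <- which(groups == contrast[2])
  if (length(jA) < 2 || length(jB) < 2)
    stop("contrast not testable: both groups need >= 2 samples")
  if (is.null(norm)) norm <- normalize_logcpm(cohort)
  eff <- norm$eff_libsize
  j <- c(jA, jB)
  if (is.null(dispersion))
    dispersion <- estimate_common_dispersion(
      cohort$counts[, j, drop = FALSE], groups[j], eff[j])

  lstar <- exp(mean(log(eff[j])))
  pseudo <- t(t(cohort$counts[, j, drop = FALSE]) * (lstar / eff[j]))
  nA <- length(jA); nB <- length(jB)
  sA <- round(rowSums(pseudo[, seq_len(nA), drop = FALSE]))
  sB <- round(rowSums(pseudo[, nA + seq_len(nB), drop = FALSE]))
  p <- vapply(seq_along(sA), function(i)
    .nb_exact_pvalue(sA[i], sB[i], nA, nB, dispersion), numeric(1))
  logfc <- log2((sB / nB + 0.5) / (sA / nA + 0.5))
  out <- data.frame(mirna_id = rownames(cohort$counts), logFC = logfc,
                    nb_p = p, stringsAsFactors = FALSE, row.names = NULL)
  attr(out, "dispersion") <- dispersion
  attr(out, "contrast") <- contrast
  out
}

#' Welch t-test on logCPM for one contrast
#'
#' Row-wise unequal-variance t statistics with Welch-Satterthwaite degrees
#' of freedom; rows with zero variance in both groups are reported as
#' `t = 0`, `p = 1` and flagged.
#'
#' @param norm a [normalize_logcpm()] result.
#' @param groups group label per sample (same order as columns).
#' @param contrast `c(groupA, groupB)`; positive t means higher in B.
#' @return data.frame (`mirna_id`, `t_stat`, `t_p`, `zero_variance`).
#' @export
welch_t_test <- function(norm, groups, contrast) {
  jA <- which(groups == contrast[1])
  jB <- which(groups == contrast[2])
  if (length(jA) < 2 || length(jB) < 2)
    stop("contrast not testable: both groups need >= 2 samples")
  xA <- norm$logcpm[, jA, drop = FALSE]
  xB <- norm$logcpm[, jB, drop = FALSE]
  nA <- length(jA); nB <- length(jB)
  mA <- rowMeans(xA); mB <- rowMeans(xB)
  vA <- apply(xA, 1, var); vB <- apply(xB, 1, var)
  se2 <- vA / nA + vB / nB
  zero <- se2 == 0
  t_stat <- ifelse(zero, 0, (mB - mA) / sqrt(se2))
  df <- ifelse(zero, NA,
               se2^2 / ((vA / nA)^2 / (nA - 1) + (vB / nB)^2 / (nB - 1)))
  p <- ifelse(zero, 1, 2 * pt(-abs(t_stat), df))
  data.frame(mirna_id = rownames(norm$logcpm), t_stat = t_stat, t_p = p,
             zero_variance = zero, stringsAsFactors = FALSE,
             row.names = NULL)
}

#' Full dual differential-expression table for one contrast
#'
#' Runs [nb_exact_test()] and [welch_t_test()] on one pairwise contrast and
#' applies the calling thresholds: the NB arm calls a miRNA when
#' `nb_p < p_cut` and `|logFC| > logfc_cut`; the t arm when `t_p < p_cut`
#' and `|t_stat| > t_cut`; `in_union` is their disjunction. No
#' multiple-testing correction is applied by default, matching the raw
#' P-threshold design; BH-adjusted calling is available via `adjust`.
#'
#' @param cohort a cohort.
#' @param contrast `c(groupA, groupB)`.
#' @param norm optional normalized matrix.
#' @param p_cut,logfc_cut,t_cut thresholds.
#' @param dispersion optional common dispersion passed to the NB test.
#' @param adjust apply BH within each method's p-values before thresholding.
#' @return a `de_result` data.frame with per-miRNA statistics and flags.
#' @export
de_test <- function(cohort, contrast, norm = NULL,
                    p_cut = 0.05, logfc_cut = 1, t_cut = 2,
                    dispersion = NULL, adjust = FALSE) {
  if (is.null(norm)) norm <- normalize_logcpm(cohort)
  nb <- nb_exact_test(cohort, contrast, norm, dispersion)
  tt <- welch_t_test(norm, cohort$samples$group, contrast)
  nb_p <- if (adjust) p.adjust(nb$nb_p, "BH") else nb$nb_p
  t_p <- if (adjust) p.adjust(tt$t_p, "BH") else tt$t_p
  out <- data.frame(
    mirna_id = nb$mirna_id,
    contrast = paste(contrast[1], "vs", contrast[2]),
    logFC = nb$logFC, nb_p = nb$nb_p,
    t_stat = tt$t_stat, t_p = tt$t_p,
    de_by_nb = nb_p < p_cut & abs(nb$logFC) > logfc_cut,
    de_by_t = t_p < p_cut & abs(tt$t_stat) > t_cut,
    stringsAsFactors = FALSE
  )
  out$in_union <- out$de_by_nb | out$de_by_t
  attr(out, "dispersion") <- attr(nb, "dispersion")
  class(out) <- c("de_result", class(out))
  out
}

#' Union DE call across contrasts with a prevalence filter
#'
#' Pools the per-contrast union calls, then removes miRNAs whose raw count
#' is nonzero in fewer than `ceiling(prevalence * n_samples)` samples.
#' Returns the union and the per-method sets (for Venn reporting).
#'
#' @param de_list list of [de_test()] results (one per contrast).
#' @param counts raw count matrix used for the prevalence filter.
#' @param prevalence required fraction of samples with a nonzero count.
#' @return list with `union`, `by_nb`, `by_t`, `both`,
#'   `removed_by_prevalence`, and a `venn` data.frame of counts.
#' @export
call_de_union <- function(de_list, counts, prevalence = 0.5) {
  if (length(de_list) == 0) stop("no contrasts supplied")
  by_nb <- sort(unique(unlist(lapply(de_list, function(d)
    d$mirna_id[d$de_by_nb]))))
  by_t <- sort(unique(unlist(lapply(de_list, function(d)
    d$mirna_id[d$de_by_t]))))
  pooled <- union(by_nb, by_t)
  n_expr <- rowSums(counts > 0)
  min_n <- ceiling(prevalence * ncol(counts))
  prevalent <- rownames(counts)[n_expr >= min_n]
  removed <- setdiff(pooled, prevalent)
  keep <- function(x) sort(intersect(x, prevalent))
  res <- list(union = keep(pooled),
              by_nb = keep(by_nb), by_t = keep(by_t),
              both = keep(intersect(by_nb, by_t)),
              removed_by_prevalence = sort(removed))
  res$venn <- data.frame(
    set = c("nb", "t", "both", "union", "removed_by_prevalence"),
    n = c(length(res$by_nb), length(res$by_t), length(res$both),
          length(res$union), length(removed)))
  res
}
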