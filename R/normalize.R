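#' TMM normalization factors
#'
#' Trimmed mean of M-values between each library and a reference library
#' (the one whose upper-quartile CPM is closest to the mean upper quartile).
#' Log-ratios are doubly trimmed (30 percent on M, 5 percent on A) and
#' inverse-variance weighted; factors are centred so their geometric mean
#' is 1.
#'
#' @param counts integer matrix, genes x samples.
#' @param libsize library sizes (defaults to column sums).
#' @param logratio_trim,sum_trim trim fractions for M and A values.
#' @param do_weighting use delta-method inverse-variance weights.
#' @return numeric vector of per-sample normalization factors.
#' @export
tmm_norm_factors <- function(counts, libsize = colSums(counts),
                             logratio_trim = 0.3, sum_trim = 0.05,
                             do_weighting = TRUE) {
  if (any(libsize <= 0)) {
    bad <- colnames(counts)[libsize <= 0]
    stop("all-zero library: ", paste(bad, collapse = ", "))
  }
  uq <- apply(counts, 2, function(x) quantile(x / sum(x), 0.75))
  ref <- which.min(abs(uq - mean(uq)))
  f <- vapply(seq_len(ncol(counts)), function(j) {
    .tmm_pair(counts[, j], counts[, ref], libsize[j], libsize[ref],
              logratio_trim, sum_trim, do_weighting)
  }, numeric(1))
  f <- 2^f
  f / exp(mean(log(f)))
}

.tmm_pair <- function(obs, ref, n_obs, n_ref, logratio_trim, sum_trim,
                      do_weighting) {
  keep <- obs > 0 & ref > 0
  obs <- obs[keep]; ref <- ref[keep]
  if (length(obs) == 0) return(0)
  m <- log2((obs / n_obs) / (ref / n_ref))
  a <- 0.5 * log2((obs / n_obs) * (ref / n_ref))
  v <- (n_obs - obs) / n_obs / obs + (n_ref - ref) / n_ref / ref
  fin <- is.finite(m) & is.finite(a)
  m <- m[fin]; a <- a[fin]; v <- v[fin]
  n <- length(m)
  if (n == 0) return(0)
  if (max(abs(m)) < 1e-6) return(0)
  lo_m <- floor(n * logratio_trim) + 1
  hi_m <- n + 1 - lo_m
  lo_a <- floor(n * sum_trim) + 1
  hi_a <- n + 1 - lo_a
  keep <- rank(m) >= lo_m & rank(m) <= hi_m &
    rank(a) >= lo_a & rank(a) <= hi_a
  if (!any(keep)) return(0)
  f <- if (do_weighting)
    sum(m[keep] / v[keep]) / sum(1 / v[keep])
  else
    mean(m[keep])
  if (!is.finite(f)) 0 else f
}

#' Library-size and TMM normalization to (log)CPM
#'
#' Computes CPM against effective library sizes (library size times TMM
#' factor) and logCPM as `log2(CPM + prior_count)`, the matrix underlying
#' the t-test arm and the co-expression networks.
#'
#' @param cohort a cohort.
#' @param prior_count prior added to CPM before taking logs.
#' @return a `normalized_matrix`: list with `logcpm`, `cpm`, `norm_factors`,
#'   `eff_libsize`, `prior_count`.
#' @export
normalize_logcpm <- function(cohort, prior_count = 2) {
  counts <- cohort$counts
  libsize <- colSums(counts)
  if (any(libsize == 0))
    stop("all-zero sample: ",
         paste(colnames(counts)[libsize == 0], collapse = ", "))
  nf <- tmm_norm_factors(counts, libsize)
  eff <- libsize * nf
  cpm <- t(t(counts) / eff) * 1e6
  out <- list(logcpm = log2(cpm + prior_count), cpm = cpm,
              norm_factors = nf, eff_libsize = eff,
              prior_count = prior_count)
  class(out) <- "normalized_matrix"
  out
}

#' Overlay of per-sample logCPM densities
#'
#' One kernel-density curve per sample, the standard global QC view of a
#' normalized miRNA count matrix.
#'
#' @param norm a [normalize_logcpm()] result.
#' @param ... passed to [plot()].
#' @return invisibly, `NULL`.
#' @export
plot_logcpm_density <- function(norm, ...) {
  dens <- apply(norm$logcpm, 2, stats::density)
  xr <- range(vapply(dens, function(d) range(d$x), numeric(2)))
  yr <- range(vapply(dens, function(d) range(d$y), numeric(2)))
  cols <- hcl.colors(length(dens), "Dynamic")
  plot(NA, xlim = xr, ylim = yr, xlab = "logCPM", ylab = "density", ...)
  for (j in seq_along(dens)) lines(dens[[j]], col = cols[j])
  invisible(NULL)
}
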