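#' ROC AUC with DeLong confidence interval and test against 0.5
#'
#' AUC is the Mann-Whitney concordance probability (ties count one half).
#' The DeLong placement-based variance gives a normal-approximation 95
#' percent CI (clipped to `[0, 1]`) and a two-sided p-value against
#' AUC = 0.5. Orientation is chosen so the reported AUC is at least 0.5 and
#' is recorded (`"up"` when higher scores mark the positive class).
#'
#' @param scores numeric scores per sample.
#' @param labels logical or two-level vector; `positive` marks the positive
#'   class.
#' @param positive value of `labels` identifying positives.
#' @param conf_level confidence level.
#' @return a `roc_result` list: `auc`, `ci95`, `p_vs_half`, `orientation`,
#'   `n_pos`, `n_neg`.
#' @export
roc_auc_ci <- function(scores, labels, positive = TRUE, conf_level = 0.95) {
  pos <- scores[labels == positive]
  neg <- scores[labels != positive]
  if (length(pos) == 0 || length(neg) == 0)
    stop("need at least one positive and one negative sample")
  placement <- function(p, n) {
    vapply(p, function(x) mean((x > n) + 0.5 * (x == n)), numeric(1))
  }
  v10 <- placement(pos, neg)
  auc <- mean(v10)
  orientation <- "up"
  if (auc < 0.5) {
    orientation <- "down"
    pos <- -pos; neg <- -neg
    v10 <- placement(pos, neg)
    auc <- mean(v10)
  }
  v01 <- 1 - placement(neg, pos)
  s2 <- var(v10) / length(pos) + var(v01) / length(neg)
  se <- sqrt(max(s2, 0))
  z <- stats::qnorm(1 - (1 - conf_level) / 2)
  ci <- c(max(0, auc - z * se), min(1, auc + z * se))
  p <- if (se > 0) 2 * pnorm(-abs(auc - 0.5) / se)
  else if (abs(auc - 0.5) < .Machine$double.eps) 1 else 0
  out <- list(auc = auc, ci95 = ci, p_vs_half = p,
              orientation = orientation,
              n_pos = length(pos), n_neg = length(neg))
  class(out) <- "roc_result"
  out
}

#' Stagewise ROC contrasts for candidate miRNAs
#'
#' Implements the one-vs-each validation design: each common candidate is
#' tested stage-vs-control for every disease stage; each stage-specific
#' candidate is tested own-stage vs control and own-stage vs each other
#' disease stage. Scores are the miRNA's logCPM values.
#'
#' @param candidates a [extract_candidates()] result.
#' @param norm a [normalize_logcpm()] result for the cohort.
#' @param groups group label per sample.
#' @param pd_stages disease stage labels.
#' @return data.frame (`mirna_id`, `class`, `contrast`, `auc`, `ci_low`,
#'   `ci_high`, `p`, `orientation`).
#' @export
stagewise_contrasts <- function(candidates, norm, groups,
                                pd_stages = c("II", "III", "IV")) {
  one <- function(id, cls, positive, negative) {
    j <- groups %in% c(positive, negative)
    if (!id %in% rownames(norm$logcpm)) return(NULL)
    r <- roc_auc_ci(norm$logcpm[id, j], groups[j], positive)
    data.frame(mirna_id = id, class = cls,
               contrast = paste(positive, "vs", negative),
               auc = r$auc, ci_low = r$ci95[1], ci_high = r$ci95[2],
               p = r$p_vs_half, orientation = r$orientation,
               stringsAsFactors = FALSE)
  }
  rows <- list()
  for (id in candidates$common)
    for (s in pd_stages)
      rows[[length(rows) + 1]] <- one(id, "common", s, "control")
  for (s in pd_stages)
    for (id in candidates$specific[[s]])
      for (other in c("control", setdiff(pd_stages, s)))
        rows[[length(rows) + 1]] <- one(id, "specific", s, other)
  rows <- rows[!vapply(rows, is.null, logical(1))]
  if (length(rows) == 0)
    return(data.frame(mirna_id = character(0), class = character(0),
                      contrast = character(0), auc = numeric(0),
                      ci_low = numeric(0), ci_high = numeric(0),
                      p = numeric(0), orientation = character(0)))
  do.call(rbind, c(rows, make.row.names = FALSE))
}

#' Relative quantification by the 2^-ddCt method
#'
#' Per sample, `dCt = Ct_target - Ct_reference`; `ddCt` subtracts the mean
#' dCt of the control group; the fold change is `2^-ddCt`, so the control
#' group mean ddCt is 0 by construction and adding a constant to every Ct of
#' a sample cancels through the reference.
#'
#' @param ct a `ct_table` (see [generate_ct_table()]) or list with `ct`
#'   matrix (targets + reference row) and `groups`.
#' @param control_group control group label.
#' @param reference reference row name (default `"U6"`).
#' @return a `ddct_result`: list with `fold` matrix (targets x samples),
#'   `ddct`, `groups`, and a per-group `summary` data.frame (`mirna_id`,
#'   `group`, `mean_fold`, `sd_fold`, `n`).
#' @export
ddct_fold_change <- function(ct, control_group = "control",
                             reference = "U6") {
  m <- ct$ct
  groups <- ct$groups
  if (!reference %in% rownames(m))
    stop("reference row '", reference, "' missing from the Ct table")
  if (any(!is.finite(m))) stop("Ct values must be finite")
  if (!control_group %in% groups)
    stop("control group '", control_group, "' absent")
  targets <- setdiff(rownames(m), reference)
  dct <- m[targets, , drop = FALSE] -
    matrix(m[reference, ], length(targets), ncol(m), byrow = TRUE)
  ctrl_mean <- rowMeans(dct[, groups == control_group, drop = FALSE])
  ddct <- dct - ctrl_mean
  fold <- 2^(-ddct)
  summ <- do.call(rbind, lapply(targets, function(id) {
    do.call(rbind, lapply(unique(groups), function(g) {
      f <- fold[id, groups == g]
      data.frame(mirna_id = id, group = g, mean_fold = mean(f),
                 sd_fold = sd(f), n = length(f), stringsAsFactors = FALSE)
    }))
  }))
  out <- list(fold = fold, ddct = ddct, groups = groups, summary = summ)
  class(out) <- "ddct_result"
  out
}

# P(max_i |T_i| <= q) for Dunnett statistics T_i with correlation
# lambda_i lambda_j (lambda_i = sqrt(n_i / (n_i + n0))) and df error
# degrees of freedom. Uses the one-factor representation
# T_i = (lambda_i Z0 + sqrt(1 - lambda_i^2) Z_i) / (chi_df / sqrt(df)) and
# integrates deterministically over the shared factor Z0 and the scale
# chi_df / sqrt(df).
.dunnett_box_prob <- function(q, lambda, df) {
  s <- sqrt(1 - lambda^2)
  inner <- function(u) {
    # for one scale value u, expectation over the shared factor
    f <- function(z) {
      acc <- rep(1, length(z))
      for (i in seq_along(lambda))
        acc <- acc * (pnorm((q * u - lambda[i] * z) / s[i]) -
                        pnorm((-q * u - lambda[i] * z) / s[i]))
      acc * stats::dnorm(z)
    }
    stats::integrate(f, -9, 9, rel.tol = 1e-9)$value
  }
  chi_dens <- function(u)
    exp(log(2) + (df / 2) * log(df / 2) - lgamma(df / 2) +
          (df - 1) * log(u) - df * u^2 / 2)
  g <- function(u) vapply(u, function(ui) chi_dens(ui) * inner(ui),
                          numeric(1))
  stats::integrate(g, 0, Inf, rel.tol = 1e-7)$value
}

#' One-way ANOVA with Dunnett many-to-one comparisons
#'
#' Classical one-way ANOVA F test plus Dunnett-adjusted two-sided p-values
#' for each group against the control, using the equicorrelated
#' multivariate-t box probability evaluated by deterministic two-level
#' quadrature over the shared-factor representation of the Dunnett
#' statistics. With a single comparison the adjusted p-value reduces to the
#' pooled two-sample t-test p-value.
#'
#' @param values numeric response (e.g. qPCR fold changes).
#' @param groups group label per value.
#' @param control_group the shared control.
#' @return list with `F`, `p_anova`, and `dunnett` data.frame (`group`,
#'   `estimate`, `t`, `p_adj`).
#' @export
anova_dunnett <- function(values, groups, control_group = "control") {
  groups <- as.character(groups)
  tab <- table(groups)
  if (length(tab) < 2 || any(tab < 2))
    stop("need >= 2 groups with >= 2 samples each")
  if (!control_group %in% groups) stop("control group absent")
  fit <- aov(values ~ factor(groups))
  an <- suppressWarnings(anova(fit))
  s2 <- an[["Mean Sq"]][2]
  df <- an[["Df"]][2]
  if (!is.finite(s2) || s2 <= 1e-20 * (1 + mean(values^2)))
    stop("zero within-group variance everywhere")
  others <- setdiff(names(tab), control_group)
  n0 <- tab[[control_group]]
  m0 <- mean(values[groups == control_group])
  est <- vapply(others, function(g)
    mean(values[groups == g]) - m0, numeric(1))
  ni <- vapply(others, function(g) tab[[g]], numeric(1))
  tstat <- est / sqrt(s2 * (1 / ni + 1 / n0))
  k <- length(others)
  lam <- sqrt(ni / (ni + n0))
  p_adj <- vapply(seq_len(k), function(i) {
    q <- abs(tstat[i])
    if (k == 1) return(2 * pt(-q, df))
    max(0, min(1, 1 - .dunnett_box_prob(q, lam, df)))
  }, numeric(1))
  list(F = an[["F value"]][1], p_anova = an[["Pr(>F)"]][1],
       dunnett = data.frame(group = others, estimate = est, t = tstat,
                            p_adj = p_adj, stringsAsFactors = FALSE,
                            row.names = NULL))
}
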