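test_that("AUC equals brute-force pair concordance, with ties and orientation", {
  set.seed(55)
  for (rep in 1:25) {
    n <- sample(10:30, 1)
    scores <- round(rnorm(n), 1)  # rounding forces ties
    labels <- sample(c(TRUE, FALSE), n, replace = TRUE)
    if (length(unique(labels)) < 2) next
    r <- roc_auc_ci(scores, labels, positive = TRUE)
    raw <- auc_bruteforce(scores, labels)
    expect_equal(r$auc, max(raw, 1 - raw), tolerance = 1e-12)
    expect_identical(r$orientation, if (raw >= 0.5) "up" else "down")
    expect_true(r$ci95[1] <= r$auc && r$auc <= r$ci95[2])
  }
  # perfect separation
  r1 <- roc_auc_ci(c(1, 2, 3, 10, 11, 12), rep(c(FALSE, TRUE), each = 3))
  expect_equal(r1$auc, 1)
  expect_error(roc_auc_ci(1:4, rep(TRUE, 4)), "positive and one negative")
})

test_that("DeLong confidence intervals match pROC", {
  skip_if_not_installed("pROC")
  set.seed(66)
  for (rep in 1:10) {
    scores <- rnorm(40)
    labels <- rep(c(0, 1), each = 20)
    scores[labels == 1] <- scores[labels == 1] + runif(1, 0, 2)
    r <- roc_auc_ci(scores, labels, positive = 1)
    pr <- pROC::roc(labels, scores, quiet = TRUE, direction = "<")
    ci <- suppressWarnings(pROC::ci.auc(pr, method = "delong"))
    expect_equal(r$auc, as.numeric(pROC::auc(pr)), tolerance = 1e-10)
    expect_equal(r$ci95[1], max(0, ci[1]), tolerance = 1e-6)
    expect_equal(r$ci95[2], min(1, ci[3]), tolerance = 1e-6)
  }
})

test_that("AUC is near one half with uniform p-values under the null", {
  set.seed(77)
  aucs <- numeric(200); ps <- numeric(200)
  for (i in 1:200) {
    scores <- rnorm(60)
    labels <- rep(c(0, 1), each = 30)
    r <- roc_auc_ci(scores, labels, positive = 1)
    aucs[i] <- if (r$orientation == "up") r$auc else 1 - r$auc
    ps[i] <- r$p_vs_half
  }
  expect_lt(abs(mean(aucs) - 0.5), 0.02)
  # two-sided p under the null is roughly uniform
  expect_gt(mean(ps < 0.5), 0.35)
  expect_lt(mean(ps < 0.05), 0.12)
})

test_that("stagewise contrasts follow the one-vs-each design", {
  co <- generate_cohort(small_config(seed = 3L))
  norm <- normalize_logcpm(co)
  cand <- list(common = co$truth$common_markers[1],
               specific = list(II = character(0), III = character(0),
                               IV = co$truth$specific_markers$IV[1]))
  class(cand) <- "candidate_sets"
  roc <- stagewise_contrasts(cand, norm, co$samples$group)
  common_rows <- roc[roc$class == "common", ]
  expect_identical(nrow(common_rows), 3L)
  expect_setequal(common_rows$contrast,
                  c("II vs control", "III vs control", "IV vs control"))
  spec_rows <- roc[roc$class == "specific", ]
  expect_identical(nrow(spec_rows), 3L)
  expect_setequal(spec_rows$contrast,
                  c("IV vs control", "IV vs II", "IV vs III"))
  # planted markers discriminate their stage from control
  expect_true(all(roc$auc[roc$contrast %in%
                            c("IV vs control", "II vs control",
                              "III vs control")] > 0.5))
})

test_that("ddCt recovers planted folds exactly on noise-free tables", {
  co <- generate_cohort(small_config(seed = 8L))
  ids <- co$truth$common_markers
  ct <- generate_ct_table(co, ids, slope = 1, intercept = 30, noise_sd = 0)
  dd <- ddct_fold_change(ct)
  libsize <- colSums(co$counts)
  cpm <- t(t(co$counts[ids, , drop = FALSE]) / libsize) * 1e6
  lg <- log2(1 + cpm)
  ctrl <- co$samples$group == "control"
  expected_fold <- 2^(lg - rowMeans(lg[, ctrl, drop = FALSE]))
  expect_equal(dd$fold, expected_fold, tolerance = 1e-12)
  # control-group mean ddCt is zero by construction
  expect_equal(unname(rowMeans(dd$ddct[, ctrl, drop = FALSE])),
               rep(0, length(ids)), tolerance = 1e-12)
})

test_that("ddCt closed forms and sample-shift invariance hold", {
  ctm <- rbind(target = c(24, 24, 25, 25), U6 = c(20, 20, 20, 20))
  colnames(ctm) <- sprintf("S%d", 1:4)
  ct <- list(ct = ctm, groups = setNames(c("control", "control", "II", "II"),
                                         colnames(ctm)))
  class(ct) <- "ct_table"
  dd <- ddct_fold_change(ct)
  # case dCt 5, control mean dCt 4: ddCt 1, fold 0.5
  expect_equal(unname(dd$ddct["target", 3]), 1)
  expect_equal(unname(dd$fold["target", 3]), 0.5)

  # adding a constant to all Cts of one sample cancels through U6
  ct2 <- ct
  ct2$ct[, 3] <- ct2$ct[, 3] + 3.7
  expect_equal(ddct_fold_change(ct2)$fold, dd$fold, tolerance = 1e-12)

  # all-equal Cts give fold 1 everywhere
  ct3 <- ct; ct3$ct["target", ] <- 22
  expect_true(all(ddct_fold_change(ct3)$fold == 1))
  ct4 <- ct; rownames(ct4$ct) <- c("target", "other")
  expect_error(ddct_fold_change(ct4), "U6")
})

test_that("Dunnett adjustment matches multcomp and its limit cases", {
  set.seed(91)
  v <- rnorm(48)
  g <- rep(c("control", "II", "III", "IV"), each = 12)
  v[g == "II"] <- v[g == "II"] + 0.8
  ours <- anova_dunnett(v, g)
  # ANOVA F/p against the base aov
  ref <- anova(aov(v ~ factor(g)))
  expect_equal(ours$F, ref[["F value"]][1])
  expect_equal(ours$p_anova, ref[["Pr(>F)"]][1])

  skip_if_not_installed("multcomp")
  fg <- factor(g, levels = c("control", "II", "III", "IV"))
  fit <- aov(v ~ fg)
  gl <- multcomp::glht(fit, linfct = multcomp::mcp(fg = "Dunnett"))
  theirs <- summary(gl, test = multcomp::adjusted("single-step"))
  expect_equal(unname(ours$dunnett$p_adj),
               unname(as.numeric(theirs$test$pvalues)), tolerance = 2e-3)

  # adjusted p dominates the per-contrast t-test p
  for (grp in ours$dunnett$group) {
    sub <- g %in% c("control", grp)
    t_p <- 2 * pt(-abs(ours$dunnett$t[ours$dunnett$group == grp]),
                  length(v) - 4)
    expect_gte(ours$dunnett$p_adj[ours$dunnett$group == grp], t_p - 1e-10)
  }

  # two groups only: Dunnett reduces to the pooled t-test
  v2 <- v[g %in% c("control", "II")]
  g2 <- g[g %in% c("control", "II")]
  two <- anova_dunnett(v2, g2)
  tt <- t.test(v2[g2 == "II"], v2[g2 == "control"], var.equal = TRUE)
  expect_equal(two$dunnett$p_adj, tt$p.value, tolerance = 1e-10)

  # identical groups: F near zero and adjusted p near one
  v3 <- rep(c(1, 2, 3, 4), times = 4)
  g3 <- rep(c("control", "II", "III", "IV"), each = 4)
  same <- anova_dunnett(v3, g3)
  expect_lt(same$F, 1e-20)
  expect_true(all(same$dunnett$p_adj > 0.999))
  expect_error(anova_dunnett(rep(1, 8), rep(c("control", "b"), 4)),
               "zero within-group variance")
})

test_that("Dunnett adjusted p grows with the number of comparisons", {
  # same statistic and error df; only the size of the comparison family
  # changes (balanced design, common correlation)
  q <- 2.1; df <- 40
  lam <- rep(sqrt(0.5), 6)
  p_by_k <- vapply(2:6, function(k)
    1 - evmirnet:::.dunnett_box_prob(q, lam[1:k], df), numeric(1))
  expect_true(all(diff(p_by_k) > 0))
  # and every family size dominates the unadjusted two-sided t p-value
  expect_true(all(p_by_k > 2 * pt(-q, df)))
})
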