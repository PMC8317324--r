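test_that("soft adjacency matches the elementwise closed form", {
  set.seed(10)
  x <- matrix(rnorm(10 * 20), 10, 20,
              dimnames = list(sprintf("g%d", 1:10), NULL))
  beta <- 3.5
  a <- soft_adjacency(x, beta)
  # brute-force elementwise oracle
  for (i in 1:10) for (j in 1:10) {
    expected <- if (i == j) 0 else abs(cor(x[i, ], x[j, ]))^beta
    expect_equal(a[i, j], expected, tolerance = 1e-12)
  }
  # perfectly correlated pair has adjacency 1 for any power
  y <- rbind(a = 1:10, b = 2 * (1:10) + 3, c = rnorm(10))
  expect_equal(soft_adjacency(y, 7)["a", "b"], 1, tolerance = 1e-12)
  # cor 0.8 at beta 2 gives 0.64 (constructed pair)
  expect_equal(abs(0.8)^2, 0.64)
  expect_error(soft_adjacency(x[, 1:2], 2), "samples")
  expect_error(soft_adjacency(x, 0), "beta")
  expect_warning(soft_adjacency(rbind(x, const = rep(1, 20)), 2),
                 "constant")
})

test_that("scale-free selection finds a good power on a heavy-tailed network", {
  # expression whose correlation network has hub structure: genes loaded on
  # a shared factor with power-law loadings
  set.seed(77)
  n <- 150; s <- 50
  loadings <- (1:n)^(-0.7)
  f <- rnorm(s)
  x <- loadings %o% f + matrix(rnorm(n * s, sd = 0.6), n, s)
  rownames(x) <- sprintf("g%d", 1:n)
  pick <- pick_soft_threshold(x, grid = 1:10, r2_target = 0.8)
  fit <- pick$fit_table
  expect_gte(fit$r_squared[fit$beta == pick$beta], 0.8)
  expect_lt(fit$slope[fit$beta == pick$beta], 0)
  # ties and thresholds prefer the smallest qualifying power
  first_hit <- min(fit$beta[!is.na(fit$r_squared) & fit$slope < 0 &
                              fit$r_squared >= 0.8])
  expect_identical(pick$beta, first_hit)
})

test_that("TOM equals the brute-force O(n^3) oracle on random adjacencies", {
  set.seed(123)
  for (rep in 1:20) {
    n <- 8
    a <- matrix(runif(n * n), n)
    a <- (a + t(a)) / 2
    diag(a) <- 0
    dimnames(a) <- list(sprintf("g%d", 1:n), sprintf("g%d", 1:n))
    tom <- topological_overlap(a)
    expect_equal(tom, tom_bruteforce(a), tolerance = 1e-12)
    expect_true(all(tom >= 0 & tom <= 1 + 1e-12))
    expect_equal(tom, t(tom), tolerance = 1e-12)
  }
  # hand computation: 3 nodes, all off-diagonal adjacency 0.5
  a3 <- matrix(0.5, 3, 3); diag(a3) <- 0
  t3 <- topological_overlap(a3)
  expect_equal(t3[1, 2], (0.25 + 0.5) / (1 + 1 - 0.5), tolerance = 1e-12)
  # zero adjacency gives zero overlap
  z <- matrix(0, 4, 4)
  expect_equal(topological_overlap(z)[upper.tri(z)], rep(0, 6))
})

test_that("TOM never decreases when adjacency is scaled toward one", {
  set.seed(9)
  for (rep in 1:10) {
    a <- matrix(runif(36), 6); a <- (a + t(a)) / 2; diag(a) <- 0
    t1 <- topological_overlap(a)
    t2 <- topological_overlap(a + (1 - a) * 0.3 * (1 - diag(6)))
    off <- upper.tri(a)
    expect_true(all(t2[off] >= t1[off] - 1e-12))
  }
})

test_that("module detection recovers planted blocks and degenerate cases", {
  # two perfectly coherent blocks with independent noise between them
  set.seed(21)
  f1 <- rnorm(30); f2 <- rnorm(30)
  x <- rbind(t(replicate(10, f1 + rnorm(30, sd = 0.05))),
             t(replicate(10, f2 + rnorm(30, sd = 0.05))))
  rownames(x) <- sprintf("g%d", 1:20)
  tom <- topological_overlap(soft_adjacency(x, 6))
  part <- cut_modules(tom, min_module_size = 5)
  expect_identical(part$module_count, 2L)
  expect_identical(length(unique(part$assignment[1:10])), 1L)
  expect_identical(length(unique(part$assignment[11:20])), 1L)
  expect_false(part$assignment[1] == part$assignment[11])

  # min_module_size larger than n: everything unassigned
  expect_warning(p0 <- cut_modules(tom, min_module_size = 50L), "unassigned")
  expect_true(all(p0$assignment == "grey"))

  # permutation invariance up to relabelling
  perm <- sample(20)
  part2 <- cut_modules(tom[perm, perm], min_module_size = 5)
  skip_if_not_installed("mclust")
  ari <- mclust::adjustedRandIndex(part$assignment[rownames(tom)],
                                   part2$assignment[rownames(tom)])
  expect_equal(ari, 1)
})

test_that("eigengene merging respects thresholds and planted shared factors", {
  set.seed(33)
  f <- rnorm(40)
  # two modules generated from the same latent factor, one from another
  x <- rbind(t(replicate(8, f + rnorm(40, sd = 0.3))),
             t(replicate(8, f + rnorm(40, sd = 0.3))),
             t(replicate(8, rnorm(40))))
  rownames(x) <- sprintf("g%d", 1:24)
  assignment <- setNames(rep(c("turquoise", "blue", "brown"), each = 8),
                         rownames(x))
  part <- list(assignment = assignment, dendrogram = NULL,
               module_count = 3L,
               sizes = table(assignment))
  class(part) <- "module_partition"

  # threshold 0: nothing merges
  expect_identical(merge_modules(x, part, 0)$module_count, 3L)
  # same-factor modules merge at 0.25; the independent one survives
  merged <- merge_modules(x, part, 0.25)
  expect_identical(merged$module_count, 2L)
  expect_identical(length(unique(merged$assignment[1:16])), 1L)
  # threshold 1 collapses everything correlated above zero
  expect_identical(merge_modules(x, part, 1)$module_count, 1L)
  expect_error(merge_modules(x, part, 1.2), "merge_dissimilarity")

  # eigengenes are unit-norm and oriented with module mean expression
  me <- module_eigengenes(x, assignment)
  expect_equal(unname(colSums(me^2)), rep(1, 3), tolerance = 1e-10)
  for (m in colnames(me))
    expect_gte(cor(me[, m], colMeans(x[assignment == m, ])), 0)
})

test_that("planted-module recovery reaches high adjusted Rand index", {
  skip_if_not_installed("mclust")
  co <- generate_cohort(module_recovery_config(seed = 2L))
  norm <- normalize_logcpm(co)
  planted <- co$truth$module_of
  in_mod <- names(planted)[planted != "none"]
  x <- norm$logcpm[in_mod, ]
  tom <- topological_overlap(soft_adjacency(x, 6))
  part <- merge_modules(x, cut_modules(tom, min_module_size = 5L), 0.25)
  ari <- mclust::adjustedRandIndex(planted[in_mod], part$assignment[in_mod])
  expect_gte(ari, 0.8)
})
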