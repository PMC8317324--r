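make_partition <- function(assignment) {
  p <- list(assignment = assignment, dendrogram = NULL,
            module_count = length(setdiff(unique(assignment), "grey")),
            sizes = table(assignment[assignment != "grey"]))
  class(p) <- "module_partition"
  p
}

test_that("linkage weights equal brute-force set intersections", {
  # deterministic toy: stage A module {a,b,c}, stage B module {b,c,d}
  pa <- make_partition(c(a = "turquoise", b = "turquoise", c = "turquoise",
                         d = "grey"))
  pb <- make_partition(c(a = "grey", b = "blue", c = "blue", d = "blue"))
  g <- build_linkage_graph(list(II = pa, III = pb))
  expect_identical(nrow(g$edges), 1L)
  expect_identical(g$edges$weight, 2L)

  # disjoint memberships give no edges
  pc <- make_partition(c(x = "turquoise", y = "turquoise",
                         z = "turquoise"))
  g0 <- build_linkage_graph(list(II = pa, III = pc))
  expect_identical(nrow(g0$edges), 0L)

  # random partitions against a brute-force intersection oracle
  set.seed(14)
  ids <- sprintf("m%02d", 1:50)
  stages <- lapply(c(II = 1, III = 2, IV = 3), function(i) {
    lab <- sample(c("turquoise", "blue", "brown", "grey"), 50,
                  replace = TRUE)
    make_partition(setNames(lab, ids))
  })
  g <- build_linkage_graph(stages)
  for (r in seq_len(nrow(g$edges))) {
    e <- g$edges[r, ]
    ma <- names(stages[[e$stage_a]]$assignment)[
      stages[[e$stage_a]]$assignment == e$module_a]
    mb <- names(stages[[e$stage_b]]$assignment)[
      stages[[e$stage_b]]$assignment == e$module_b]
    expect_identical(e$weight, length(intersect(ma, mb)))
    expect_lte(e$weight, min(length(ma), length(mb)))
  }
  # no intra-stage edges by default; all weights >= 1
  expect_true(all(g$edges$stage_a != g$edges$stage_b))
  expect_true(all(g$edges$weight >= 1))
})

test_that("annotation filter keeps exactly the modules with annotated members", {
  pa <- make_partition(c(a = "turquoise", b = "turquoise", c = "blue",
                         d = "blue", e = "brown", f = "brown"))
  pb <- make_partition(c(a = "turquoise", c = "turquoise", e = "blue",
                         f = "blue"))
  g <- build_linkage_graph(list(II = pa, III = pb))

  # annotation covering everything changes nothing
  all_ids <- letters[1:6]
  expect_identical(nrow(filter_key_modules_by_annotation(g, all_ids)$nodes),
                   nrow(g$nodes))
  # disjoint annotation empties the graph
  expect_warning(
    empty <- filter_key_modules_by_annotation(g, character(0)), "empty")
  expect_identical(nrow(empty$nodes), 0L)
  # hits in 2 of 3 stage-II modules keep exactly those, plus edge pruning
  f2 <- filter_key_modules_by_annotation(g, c("a", "c"))
  keys <- paste0(f2$nodes$stage, ":", f2$nodes$module)
  expect_setequal(keys, c("II:turquoise", "II:blue", "III:turquoise"))

  # monotone: enlarging the annotation never removes a retained module
  f3 <- filter_key_modules_by_annotation(g, c("a", "c", "e"))
  expect_true(all(keys %in% paste0(f3$nodes$stage, ":", f3$nodes$module)))
})

test_that("hypergeometric enrichment matches direct summation and BH", {
  pa <- make_partition(setNames(rep(c("turquoise", "blue", "grey"),
                                    each = 5), sprintf("m%02d", 1:15)))
  pb <- make_partition(setNames(rep(c("turquoise", "grey", "blue"),
                                    each = 5), sprintf("m%02d", 1:15)))
  g <- build_linkage_graph(list(II = pa, III = pb))
  background <- sprintf("m%02d", 1:15)

  # a set identical to one module: tail probability by direct summation
  fs <- data.frame(set_id = "FS01", mirna_id = sprintf("m%02d", 1:5))
  e <- enrich_and_filter(g, fs, background, fdr_cut = 0.05)
  row <- e$enrichment[e$enrichment$stage == "II" &
                        e$enrichment$module == "turquoise", ]
  direct <- sum(vapply(5:5, function(k)
    choose(5, k) * choose(10, 5 - k) / choose(15, 5), numeric(1)))
  expect_equal(row$p, direct, tolerance = 1e-12)
  expect_true("II:turquoise" %in% names(e$graph$members))

  # sets disjoint from all modules retain nothing
  fs2 <- data.frame(set_id = "FS01",
                    mirna_id = sprintf("m%02d", 11:15))
  g2 <- build_linkage_graph(list(II = make_partition(
    setNames(rep(c("turquoise", "grey"), c(5, 10)),
             sprintf("m%02d", 1:15))), III = pb))
  # q >= p always
  e2 <- enrich_and_filter(g2, fs2, background)
  expect_true(all(e2$enrichment$q >= e2$enrichment$p - 1e-12))

  # ids outside the background are an error
  fs3 <- data.frame(set_id = "FS01", mirna_id = "zzz")
  expect_error(enrich_and_filter(g, fs3, background), "background")

  # BH on a hand-checked p-vector
  expect_equal(p.adjust(c(0.01, 0.02, 0.04), "BH"),
               c(0.03, 0.03, 0.04))
})

test_that("candidate extraction separates common from stage-specific", {
  # all-stage arm: one module shared by all three stages
  mk <- function(ids, lab) make_partition(setNames(rep(lab, length(ids)),
                                                   ids))
  common_ids <- c("hsa-miR-19b-3p", "hsa-miR-374b-5p", "hsa-miR-9-5p",
                  "hsa-miR-374a-5p")
  all_arm <- build_linkage_graph(list(
    II = mk(common_ids, "turquoise"),
    III = mk(c(common_ids, "x1"), "blue"),
    IV = mk(common_ids, "brown")))
  per_arm <- build_linkage_graph(list(
    II = mk(c("hsa-miR-199a-3p", "s1", "s2"), "turquoise"),
    III = mk(c("hsa-miR-28-5p", "s3", "s4"), "blue"),
    IV = mk(c("s5", "s6", "s7"), "brown")))
  cand <- extract_candidates(all_arm, per_arm)
  expect_setequal(cand$common, common_ids)
  expect_true("hsa-miR-199a-3p" %in% cand$specific$II)
  expect_true("hsa-miR-28-5p" %in% cand$specific$III)
  # a miRNA in two stage networks is not specific
  per2 <- build_linkage_graph(list(
    II = mk(c("dup", "s1", "s2"), "turquoise"),
    III = mk(c("dup", "s3"), "blue"),
    IV = mk("s5", "brown")))
  cand2 <- extract_candidates(all_arm, per2)
  expect_false("dup" %in% unlist(cand2$specific))
  # classes are disjoint and the additive identity holds
  expect_length(intersect(cand$common, unlist(cand$specific)), 0L)
  expect_identical(nrow(cand$table),
                   length(cand$common) + sum(lengths(cand$specific)))

  # a stage with no retained module forces an empty common set
  all_empty <- build_linkage_graph(list(
    II = mk(common_ids, "turquoise"),
    III = mk(common_ids, "blue")))
  expect_warning(c3 <- extract_candidates(all_empty, per_arm,
                                          pd_stages = c("II", "III", "IV")),
                 "no retained modules")
  expect_length(c3$common, 0L)
})
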