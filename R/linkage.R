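#' Cross-stage module-linkage graph
#'
#' Connects co-expression modules of different stage networks that share
#' miRNAs: nodes are (stage, module) pairs with their member sets
#' (unassigned miRNAs excluded), and each edge weight counts the miRNAs
#' shared by the two modules. The more miRNAs two modules share, the
#' stronger their linkage. Zero-weight pairs are omitted; within-stage edges
#' only appear when `include_intra = TRUE`.
#'
#' @param partitions named list (stage -> [cut_modules()] result or named
#'   assignment vector).
#' @param include_intra also link modules within the same stage.
#' @return a `linkage_graph`: list with `nodes` data.frame (`stage`,
#'   `module`, `size`), `members` (named list keyed `"stage:module"`), and
#'   `edges` data.frame (`stage_a`, `module_a`, `stage_b`, `module_b`,
#'   `weight`).
#' @export
build_linkage_graph <- function(partitions, include_intra = FALSE) {
  if (length(partitions) < 2 && !include_intra)
    stop("need at least two stage partitions")
  members <- list()
  nodes <- list()
  for (stage in names(partitions)) {
    p <- partitions[[stage]]
    a <- if (inherits(p, "module_partition")) p$assignment else p
    mods <- setdiff(unique(a), "grey")
    if (anyDuplicated(mods)) stop("duplicate module labels in stage ", stage)
    for (m in mods) {
      key <- paste0(stage, ":", m)
      members[[key]] <- names(a)[a == m]
      nodes[[key]] <- data.frame(stage = stage, module = m,
                                 size = sum(a == m),
                                 stringsAsFactors = FALSE)
    }
  }
  nodes <- if (length(nodes) > 0) do.call(rbind, c(nodes, make.row.names = FALSE))
  else data.frame(stage = character(0), module = character(0),
                  size = integer(0))
  edges <- list()
  keys <- names(members)
  if (length(keys) >= 2) {
    for (i in seq_len(length(keys) - 1)) {
      for (j in (i + 1):length(keys)) {
        if (!include_intra && nodes$stage[i] == nodes$stage[j]) next
        w <- length(intersect(members[[keys[i]]], members[[keys[j]]]))
        if (w >= 1)
          edges[[length(edges) + 1]] <- data.frame(
            stage_a = nodes$stage[i], module_a = nodes$module[i],
            stage_b = nodes$stage[j], module_b = nodes$module[j],
            weight = w, stringsAsFactors = FALSE)
      }
    }
  }
  edges <- if (length(edges) > 0)
    do.call(rbind, c(edges, make.row.names = FALSE))
  else data.frame(stage_a = character(0), module_a = character(0),
                  stage_b = character(0), module_b = character(0),
                  weight = integer(0))
  g <- list(nodes = nodes, members = members, edges = edges)
  class(g) <- "linkage_graph"
  g
}

# drop nodes by key, along with their incident edges
.subset_graph <- function(graph, keep_keys) {
  nodes <- graph$nodes
  keys <- paste0(nodes$stage, ":", nodes$module)
  keep <- keys %in% keep_keys
  members <- graph$members[keys[keep]]
  nodes <- nodes[keep, , drop = FALSE]
  e <- graph$edges
  if (nrow(e) > 0) {
    ka <- paste0(e$stage_a, ":", e$module_a)
    kb <- paste0(e$stage_b, ":", e$module_b)
    e <- e[ka %in% keep_keys & kb %in% keep_keys, , drop = FALSE]
  }
  g <- list(nodes = nodes, members = members, edges = e)
  class(g) <- "linkage_graph"
  g
}

#' Retain key modules by disease annotation
#'
#' Keeps a module if and only if at least one of its members appears in the
#' disease-annotation table; incident edges of removed modules are dropped.
#' A stricter per-miRNA mode restricts retained modules to their annotated
#' members.
#'
#' @param graph a [build_linkage_graph()] result.
#' @param annotation data.frame with a `mirna_id` column, or a character
#'   vector of annotated miRNA ids.
#' @param per_mirna restrict retained modules to annotated members.
#' @return the filtered `linkage_graph`.
#' @export
filter_key_modules_by_annotation <- function(graph, annotation,
                                             per_mirna = FALSE) {
  ids <- if (is.data.frame(annotation)) unique(annotation$mirna_id)
  else unique(annotation)
  if (length(ids) == 0) {
    warning("empty annotation table: no key modules retained")
    return(.subset_graph(graph, character(0)))
  }
  keep <- names(graph$members)[vapply(graph$members, function(m)
    length(intersect(m, ids)) > 0, logical(1))]
  out <- .subset_graph(graph, keep)
  if (per_mirna)
    out$members <- lapply(out$members, intersect, y = ids)
  out
}

#' Function-set enrichment filtering of modules
#'
#' One-sided hypergeometric over-representation of each function set in
#' each module against a fixed background, BH-corrected across the whole
#' module-by-set family; a module is retained when at least one set reaches
#' `q < fdr_cut`.
#'
#' @param graph a `linkage_graph`.
#' @param function_sets data.frame (`set_id`, `mirna_id`); every id must be
#'   in `background`.
#' @param background character vector, the enrichment universe (all miRNAs
#'   entering the networks).
#' @param fdr_cut BH FDR threshold.
#' @return list with the filtered `graph` and the `enrichment` data.frame
#'   (`stage`, `module`, `set_id`, `overlap`, `p`, `q`).
#' @export
enrich_and_filter <- function(graph, function_sets, background,
                              fdr_cut = 0.05) {
  bad <- setdiff(unique(function_sets$mirna_id), background)
  if (length(bad) > 0)
    stop("function set ids outside the background: ",
         paste(head(bad, 5), collapse = ", "))
  mods_missing <- unlist(lapply(graph$members, setdiff, y = background))
  if (length(mods_missing) > 0)
    stop("module members outside the background: ",
         paste(head(mods_missing, 5), collapse = ", "))
  fs <- unique(function_sets[, c("set_id", "mirna_id")])
  sets <- split(fs$mirna_id, fs$set_id)
  n_bg <- length(background)
  rows <- list()
  for (key in names(graph$members)) {
    mem <- graph$members[[key]]
    st <- strsplit(key, ":", fixed = TRUE)[[1]]
    for (sid in names(sets)) {
      s <- sets[[sid]]
      ov <- length(intersect(mem, s))
      p <- phyper(ov - 1, length(s), n_bg - length(s), length(mem),
                  lower.tail = FALSE)
      rows[[length(rows) + 1]] <- data.frame(
        stage = st[1], module = st[2], set_id = sid, overlap = ov,
        p = p, stringsAsFactors = FALSE)
    }
  }
  enr <- if (length(rows) > 0) do.call(rbind, c(rows, make.row.names = FALSE))
  else data.frame(stage = character(0), module = character(0),
                  set_id = character(0), overlap = integer(0), p = numeric(0))
  enr$q <- p.adjust(enr$p, method = "BH")
  hit_keys <- unique(paste0(enr$stage, ":", enr$module)[enr$q < fdr_cut])
  list(graph = .subset_graph(graph, hit_keys), enrichment = enr)
}

#' Extract common and stage-specific candidate miRNAs
#'
#' From the filtered all-stage arm, the common set holds miRNAs present in a
#' retained module of every disease stage; from the filtered per-stage arm,
#' the specific sets hold miRNAs present in retained modules of exactly one
#' stage. Any overlap between the classes is resolved in favour of the
#' specific set: stage-specificity is the stronger claim, demonstrated in
#' the stage-resolved arm, whereas pan-stage module membership can arise
#' from weak chance assignments. The classes stay disjoint. Per-miRNA
#' provenance (the modules that carried it) is recorded.
#'
#' @param all_stage_graph filtered `linkage_graph` of the all-stage arm.
#' @param per_stage_graph filtered `linkage_graph` of the per-stage arm.
#' @param pd_stages disease stage labels.
#' @return a `candidate_sets`: list with `common`, `specific` (named list),
#'   `provenance` data.frame, and a flat `table`.
#' @export
extract_candidates <- function(all_stage_graph, per_stage_graph,
                               pd_stages = c("II", "III", "IV")) {
  stage_members <- function(graph, stage) {
    keys <- names(graph$members)[graph$nodes$stage == stage]
    unique(unlist(graph$members[keys]))
  }
  per_stage_sets <- lapply(setNames(pd_stages, pd_stages), stage_members,
                           graph = all_stage_graph)
  empty_stages <- pd_stages[lengths(per_stage_sets) == 0]
  if (length(empty_stages) > 0)
    warning("no retained modules for stage(s) ",
            paste(empty_stages, collapse = ", "),
            "; common set is necessarily empty")
  common <- if (length(empty_stages) > 0) character(0)
  else sort(Reduce(intersect, per_stage_sets))

  spec_members <- lapply(setNames(pd_stages, pd_stages), stage_members,
                         graph = per_stage_graph)
  all_spec <- unique(unlist(spec_members))
  n_stages <- vapply(all_spec, function(id)
    sum(vapply(spec_members, function(s) id %in% s, logical(1))),
    integer(1))
  specific <- lapply(setNames(pd_stages, pd_stages), function(s)
    sort(intersect(spec_members[[s]], all_spec[n_stages == 1])))
  common <- setdiff(common, unlist(specific))

  prov <- list()
  add_prov <- function(graph, arm) {
    for (key in names(graph$members)) {
      st <- strsplit(key, ":", fixed = TRUE)[[1]]
      for (id in graph$members[[key]])
        prov[[length(prov) + 1]] <<- data.frame(
          mirna_id = id, arm = arm, stage = st[1], module = st[2],
          stringsAsFactors = FALSE)
    }
  }
  add_prov(all_stage_graph, "all_stage")
  add_prov(per_stage_graph, "per_stage")
  prov <- if (length(prov) > 0) do.call(rbind, c(prov, make.row.names = FALSE))
  else data.frame(mirna_id = character(0), arm = character(0),
                  stage = character(0), module = character(0))

  tab <- rbind(
    if (length(common) > 0)
      data.frame(mirna_id = common, class = "common", stage = "all",
                 stringsAsFactors = FALSE),
    do.call(rbind, lapply(pd_stages, function(s)
      if (length(specific[[s]]) > 0)
        data.frame(mirna_id = specific[[s]], class = "specific", stage = s,
                   stringsAsFactors = FALSE)))
  )
  if (is.null(tab))
    tab <- data.frame(mirna_id = character(0), class = character(0),
                      stage = character(0))
  out <- list(common = common, specific = specific, provenance = prov,
              table = tab)
  class(out) <- "candidate_sets"
  out
}

#' @export
print.candidate_sets <- function(x, ...) {
  cat("candidates:", length(x$common), "common;",
      paste(sprintf("%s: %d", names(x$specific), lengths(x$specific)),
            collapse = ", "), "stage-specific\n")
  invisible(x)
}
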