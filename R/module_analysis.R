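#' Build the coherent association network
#'
#' Turns a coherent pair list into a simple undirected graph (no
#' self-loops, duplicate pairs collapsed). Nodes are exactly the
#' endpoints of the pairs.
#'
#' @param coherent_pairs data frame with columns `node_a`, `node_b`
#'   (e.g. from [select_coherent_pairs()]).
#' @return an [igraph::graph] object; empty (with a warning) when the
#'   pair list is empty.
#' @export
build_coherent_network <- function(coherent_pairs) {
  if (nrow(coherent_pairs) == 0) {
    warning("empty coherent pair list: returning an empty graph")
    return(igraph::make_empty_graph(0, directed = FALSE))
  }
  el <- as.matrix(coherent_pairs[, c("node_a", "node_b")])
  g <- igraph::graph_from_edgelist(el, directed = FALSE)
  igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
}

#' Detect network modules by modularity maximization
#'
#' Runs greedy modularity-maximizing community detection (with vertices
#' pre-sorted by node ID so results are reproducible), relabels the
#' communities by decreasing size — module 1 is the largest, ties broken
#' by smallest member ID — and marks members of communities smaller than
#' `min_size` as unassigned (module 0, the "gray" nodes).
#'
#' @param graph an undirected [igraph::graph] with named vertices.
#' @param min_size smallest community kept as a module (default 3).
#' @param seed RNG seed fixed for reproducibility of any stochastic
#'   detector plugged in via `method`.
#' @param method community detection function taking a graph and
#'   returning an `igraph` communities object; default
#'   [igraph::cluster_fast_greedy].
#' @return a `module_assignment`: data frame `node`, `module` (0 =
#'   unassigned) with a `sizes` attribute (named vector of module
#'   sizes).
#' @export
detect_modules <- function(graph, min_size = 3, seed = 1,
                           method = igraph::cluster_fast_greedy) {
  if (igraph::vcount(graph) == 0) stop("graph is empty")
  perm <- order(igraph::V(graph)$name)
  graph <- igraph::permute(graph, order(perm))
  comm <- withr::with_seed(seed, method(graph))
  memb <- igraph::membership(comm)
  nodes <- igraph::V(graph)$name
  # relabel by decreasing size; ties by smallest member node ID
  memb <- as.character(memb)
  sizes <- table(memb)
  first_node <- tapply(nodes, memb, min)
  ord_ids <- names(sizes)[order(-as.integer(sizes), first_node[names(sizes)])]
  rank_of <- stats::setNames(seq_along(ord_ids), ord_ids)
  module <- unname(rank_of[memb])
  keep_ids <- ord_ids[as.integer(sizes[ord_ids]) >= min_size]
  module[!(memb %in% keep_ids)] <- 0L
  kept <- sort(unique(module[module > 0]))
  module[module > 0] <- match(module[module > 0], kept)
  out <- data.frame(node = nodes, module = module, stringsAsFactors = FALSE)
  out <- out[order(out$node), , drop = FALSE]
  rownames(out) <- NULL
  attr(out, "sizes") <- table(out$module[out$module > 0])
  class(out) <- c("module_assignment", "data.frame")
  out
}

#' Cross-cohort membership table
#'
#' For node sets observed in two or more cohorts (e.g. the lncRNAs of
#' each subtype's coherent network), tabulates every non-empty cohort
#' combination with the nodes present in exactly that combination —
#' the numbers behind a Venn diagram. Counts over all combinations sum
#' to the union size.
#'
#' @param node_sets named list (length >= 2) of character vectors.
#' @return data frame `combination` (cohort names joined by `&`),
#'   `count`, `nodes` (comma-joined IDs); one row per non-empty subset
#'   of cohorts.
#' @export
intersect_across_cohorts <- function(node_sets) {
  if (length(node_sets) < 2) stop("need at least 2 cohorts")
  if (is.null(names(node_sets))) {
    names(node_sets) <- paste0("cohort", seq_along(node_sets))
  }
  all_nodes <- sort(unique(unlist(node_sets)))
  member <- vapply(node_sets, function(s) all_nodes %in% s,
                   logical(length(all_nodes)))
  member <- matrix(member, nrow = length(all_nodes),
                   dimnames = list(all_nodes, names(node_sets)))
  n <- length(node_sets)
  combos <- lapply(seq_len(2^n - 1), function(mask) {
    as.logical(bitwAnd(mask, 2^(seq_len(n) - 1)) > 0)
  })
  rows <- lapply(combos, function(inc) {
    hit <- apply(member, 1, function(r) all(r == inc))
    data.frame(
      combination = paste(names(node_sets)[inc], collapse = "&"),
      count = sum(hit),
      nodes = paste(all_nodes[hit], collapse = ","),
      stringsAsFactors = FALSE)
  })
  do.call(rbind, rows)
}
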