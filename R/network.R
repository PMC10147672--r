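#' Build the IBD-sharing graph
#'
#' Each individual is a node; each edge weight is the total length of IBD in
#' cM that one individual shares with another. Extreme edges with totals
#' strictly greater than `max_edge_cM` are excluded as more reflective of
#' close familial relationships than of population structure (the threshold
#' itself is kept: a 142 cM total survives the default filter).
#'
#' @param totals a pair-sharing table from [pair_totals()].
#' @param max_edge_cM edge exclusion threshold (default 142).
#' @param nodes optional character vector of node ids to force into the graph
#'   even when isolated (e.g. samples with no retained sharing).
#' @return An undirected weighted `igraph` object with `max_edge_cM` stored
#'   as a graph attribute.
#' @export
build_graph <- function(totals, max_edge_cM = 142, nodes = NULL) {
  totals <- as.data.table(totals)
  if (!nrow(totals)) {
    warning("empty sharing table: returning an empty graph")
    g <- igraph::make_empty_graph(0, directed = FALSE)
  } else {
    keep <- totals[total_cM > 0 & total_cM <= max_edge_cM]
    ids <- sort(unique(c(totals$sample1, totals$sample2, nodes)))
    g <- igraph::graph_from_data_frame(
      keep[, .(from = sample1, to = sample2, weight = total_cM)],
      directed = FALSE, vertices = data.frame(name = ids))
  }
  g <- igraph::set_graph_attr(g, "max_edge_cM", max_edge_cM)
  g
}

#' Louvain community detection with pinned node order
#'
#' Modularity-maximising Louvain partition. The algorithm is visitation-order
#' dependent, so nodes are first sorted by id and then shuffled under the
#' given seed: identical graph and seed give an identical partition.
#'
#' @param graph a weighted undirected `igraph`.
#' @param seed integer seed controlling the node order.
#' @param resolution modularity resolution (1 = classical modularity).
#' @return A named integer membership vector (names = sample ids).
#' @export
louvain_partition <- function(graph, seed = 1L, resolution = 1.0) {
  n <- igraph::vcount(graph)
  if (n == 0L) return(setNames(integer(0), character(0)))
  ids <- igraph::V(graph)$name
  if (igraph::ecount(graph) == 0L) {
    warning("graph has no edges: every node is its own community")
    return(setNames(seq_len(n), ids))
  }
  set.seed(derive_seed(seed, 31L))
  ord <- order(ids)[sample.int(n)]
  g2 <- igraph::permute(graph, order(ord))
  cl <- igraph::cluster_louvain(g2, resolution = resolution)
  mem <- igraph::membership(cl)
  out <- setNames(as.integer(mem[match(ids, igraph::V(g2)$name)]), ids)
  out
}

#' Three-level hierarchical Louvain clustering
#'
#' Level 1 is a Louvain partition of the full graph; each level-k community
#' with at least `min_subgraph` members is re-clustered on its induced
#' subgraph to produce level k+1, and smaller communities pass through
#' unchanged. Labels encode the hierarchy path with communities ranked by
#' size (e.g. `"1.2"` is the second-largest child of the largest level-1
#' community), so level-(k+1) clusters nest exactly inside level-k clusters.
#'
#' @param graph a weighted undirected `igraph` from [build_graph()].
#' @param levels number of rounds of clustering (default 3).
#' @param min_subgraph minimum community size eligible for re-clustering.
#' @param seed integer seed (passed to every Louvain round).
#' @param resolution modularity resolution.
#' @return An object of class `ibd_hierarchy`: a `data.frame` with columns
#'   `id`, `level1`, ..., `level<levels>`.
#' @export
hierarchical_cluster <- function(graph, levels = 3L, min_subgraph = 10L,
                                 seed = 1L, resolution = 1.0) {
  if (levels < 1L) stop("levels must be >= 1")
  ids <- igraph::V(graph)$name
  lab <- matrix(NA_character_, length(ids), levels,
                dimnames = list(ids, paste0("level", seq_len(levels))))
  recurse <- function(sub, prefix, level) {
    mem <- louvain_partition(sub, seed = seed, resolution = resolution)
    sizes <- sort(table(mem), decreasing = TRUE)
    rank_of <- setNames(seq_along(sizes), names(sizes))
    labels <- paste0(prefix, ifelse(prefix == "", "", "."),
                     rank_of[as.character(mem)])
    names(labels) <- names(mem)
    lab[names(labels), level] <<- labels
    if (level == levels) return(invisible(NULL))
    for (comm in unique(labels)) {
      members <- names(labels)[labels == comm]
      if (length(members) >= min_subgraph) {
        recurse(igraph::induced_subgraph(graph, members), comm, level + 1L)
      } else {
        ## pass through unchanged: a single child cluster
        lab[members, (level + 1L):levels] <<-
          matrix(rep(paste0(comm, strrep(".1", seq_len(levels - level))),
                     each = length(members)),
                 nrow = length(members))
      }
    }
    invisible(NULL)
  }
  suppressWarnings(recurse(graph, "", 1L))
  out <- data.frame(id = ids, lab, stringsAsFactors = FALSE,
                    row.names = NULL)
  class(out) <- c("ibd_hierarchy", "data.frame")
  out
}

#' @export
print.ibd_hierarchy <- function(x, ...) {
  lev <- grep("^level", names(x), value = TRUE)
  cat(sprintf("hierarchical IBD clustering: %d samples\n", nrow(x)))
  for (l in lev)
    cat(sprintf("  %s: %d clusters\n", l, length(unique(x[[l]]))))
  invisible(x)
}

#' Adjusted Rand index between two partitions
#'
#' @param labels_a,labels_b named label vectors over the same sample set
#'   (names are matched; unnamed vectors are compared positionally).
#' @return The adjusted Rand index.
#' @export
compare_partitions <- function(labels_a, labels_b) {
  if (!is.null(names(labels_a)) && !is.null(names(labels_b))) {
    if (!setequal(names(labels_a), names(labels_b)))
      stop("partitions cover different sample sets")
    labels_b <- labels_b[names(labels_a)]
  } else if (length(labels_a) != length(labels_b))
    stop("partitions cover different sample sets")
  mclust::adjustedRandIndex(as.character(labels_a), as.character(labels_b))
}
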