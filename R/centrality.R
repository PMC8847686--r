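# The five node-topology metrics the screening cascade uses. Conventions
# follow the CytoNCA plug-in's raw (unnormalized) output:
#   * degree        -- number of distinct neighbors
#   * betweenness   -- Brandes, unnormalized, each unordered pair counted once
#   * closeness     -- component-wise (c-1)/sum(d); values in (0,1], isolated 0
#   * neighborhood connectivity -- mean degree of the node's neighbors
#   * local average connectivity (LAC) -- mean, over the node's neighbors, of
#     their degree within the subgraph induced by those neighbors
# Degree-0 nodes score 0 on every metric so stage medians are well defined.

#' Node degree
#' @param net an undirected simple `igraph` graph.
#' @return named integer vector, one entry per node (lexicographic order).
#' @export
degree_centrality <- function(net) {
  net <- normalize_graph(net, provenance = provenance(net))
  igraph::degree(net, loops = FALSE)
}

#' Unnormalized shortest-path betweenness
#'
#' \eqn{B(v) = \sum_{\{s,t\}: s \ne v \ne t} \sigma_{st}(v)/\sigma_{st}},
#' each unordered pair counted once; pairs in different components
#' contribute 0. Computed with Brandes' accumulation algorithm.
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
betweenness_centrality <- function(net) {
  net <- normalize_graph(net, provenance = provenance(net))
  igraph::betweenness(net, directed = FALSE, normalized = FALSE)
}

#' Component-wise closeness centrality
#'
#' For a node in a connected component of size \eqn{c \ge 2},
#' \eqn{C(v) = (c-1)/\sum_u d(v,u)} with the sum over the component;
#' isolated nodes score 0. Values lie in (0, 1], with 1 for a node adjacent
#' to every other node of its component at distance 1.
#' @inheritParams degree_centrality
#' @return named numeric vector in [0, 1].
#' @export
closeness_centrality <- function(net) {
  net <- normalize_graph(net, provenance = provenance(net))
  cl <- suppressWarnings(igraph::closeness(net, normalized = TRUE))
  cl[!is.finite(cl)] <- 0
  cl
}

#' Neighborhood connectivity
#'
#' Mean degree (in the full graph) of a node's neighbors; 0 for isolated
#' nodes.
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
neighborhood_connectivity <- function(net) {
  net <- normalize_graph(net, provenance = provenance(net))
  deg <- igraph::degree(net)
  adj <- igraph::as_adj_list(net)
  out <- vapply(adj, function(nb) {
    if (length(nb) == 0) 0 else mean(deg[igraph::as_ids(nb)])
  }, numeric(1))
  names(out) <- igraph::V(net)$name
  out
}

#' Local average connectivity (LAC)
#'
#' For node \eqn{v} with neighbor set \eqn{N(v)}, the mean degree of the
#' neighbors within the subgraph induced by \eqn{N(v)} (the node itself is
#' excluded): \eqn{LAC(v) = 2 e(N(v)) / |N(v)|} where \eqn{e(N(v))} counts
#' edges among the neighbors. 0 for isolated nodes.
#' @inheritParams degree_centrality
#' @return named numeric vector.
#' @export
local_average_connectivity <- function(net) {
  net <- normalize_graph(net, provenance = provenance(net))
  adj <- igraph::as_adj_list(net)
  nbr_sets <- lapply(adj, igraph::as_ids)
  out <- vapply(seq_along(nbr_sets), function(i) {
    nb <- nbr_sets[[i]]
    if (length(nb) == 0) return(0)
    # edges among neighbors, each counted once
    e_nb <- sum(vapply(nb, function(w) sum(nbr_sets[[w]] %in% nb), numeric(1))) / 2
    2 * e_nb / length(nb)
  }, numeric(1))
  names(out) <- igraph::V(net)$name
  out
}

#' Compute all five screening metrics for every node
#'
#' @inheritParams degree_centrality
#' @return a tibble with one row per node (lexicographic node order) and
#'   columns `node`, `degree`, `betweenness`, `closeness`,
#'   `neighborhood_connectivity`, `lac`.
#' @export
compute_all <- function(net) {
  net <- normalize_graph(net, provenance = provenance(net))
  nodes <- igraph::V(net)$name
  tibble::tibble(
    node = nodes,
    degree = as.numeric(unname(degree_centrality(net)[nodes])),
    betweenness = unname(betweenness_centrality(net)[nodes]),
    closeness = unname(closeness_centrality(net)[nodes]),
    neighborhood_connectivity = unname(neighborhood_connectivity(net)[nodes]),
    lac = unname(local_average_connectivity(net)[nodes])
  )
}

#' Write a centrality table as TSV (10 significant digits for reals)
#' @param table a tibble from [compute_all()].
#' @param path output file.
#' @export
write_centrality_table <- function(table, path) {
  out <- table
  for (col in c("betweenness", "closeness", "neighborhood_connectivity", "lac")) {
    out[[col]] <- formatC(out[[col]], digits = 10, format = "g")
  }
  utils::write.table(out, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
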