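#' Expand a seed set into its one-hop seeded PPI subnetwork
#'
#' Mirrors the "seed + direct interactors" expansion that interactome tools
#' apply to a target list: the subnetwork contains every seed that maps into
#' the interactome, all of their direct neighbors, and every interactome
#' edge with both endpoints in that node set (the induced subgraph). Seeds
#' absent from the interactome are ignored with a warning; the expansion is
#' exactly one hop.
#'
#' @param interactome an undirected simple `igraph` graph.
#' @param seeds a [seed_set()].
#' @return an `igraph` subnetwork with graph attribute `provenance` set to
#'   the seed set's name.
#' @export
build_seed_network <- function(interactome, seeds) {
  stopifnot(igraph::is_igraph(interactome), inherits(seeds, "seed_set"))
  present <- intersect(seeds$members, igraph::V(interactome)$name)
  missing <- setdiff(seeds$members, present)
  if (length(present) == 0) {
    stop("no seeds mappable: none of the ", length(seeds$members),
         " '", seeds$name, "' seeds occur in the interactome")
  }
  if (length(missing) > 0) {
    warning(length(missing), " '", seeds$name,
            "' seed(s) absent from the interactome were ignored")
  }
  nbrs <- unique(unlist(lapply(
    igraph::adjacent_vertices(interactome, present),
    function(v) igraph::as_ids(v)
  )))
  keep <- union(present, nbrs)
  sub <- igraph::induced_subgraph(interactome, keep)
  normalize_graph(sub, provenance = seeds$name)
}

#' Intersect two subnetworks on both nodes and edges
#'
#' Cytoscape Merge-intersection semantics: the result keeps exactly the
#' nodes present in both networks and the edges present in both networks.
#' Nodes left isolated by the edge intersection are retained, so downstream
#' degree medians see them. Commutative and idempotent; an empty
#' intersection is a legal outcome reported via a message, not an error.
#'
#' @param a,b `igraph` subnetworks.
#' @return an `igraph` subnetwork with provenance `"intersection"`.
#' @export
intersect_networks <- function(a, b) {
  stopifnot(igraph::is_igraph(a), igraph::is_igraph(b))
  nodes <- sort(intersect(igraph::V(a)$name, igraph::V(b)$name))
  key <- function(m) paste(m[, 1], m[, 2], sep = "\r")
  ea <- edge_pairs(a); eb <- edge_pairs(b)
  common <- ea[key(ea) %in% key(eb), , drop = FALSE]
  # guard against edges whose endpoints are not shared nodes (cannot happen
  # for valid subnetworks, but keep the output self-consistent regardless)
  common <- common[common[, 1] %in% nodes & common[, 2] %in% nodes, , drop = FALSE]
  if (length(nodes) == 0) message("network intersection is empty")
  g <- igraph::graph_from_data_frame(
    as.data.frame(common, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  normalize_graph(g, provenance = "intersection")
}
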