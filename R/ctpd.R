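# The compound-target-pathway-disease (C-T-P-D) network: a tetrapartite
# graph linking one compound node to the screened core targets, each target
# to the significant terms that contain it, and each significant term to
# one disease node. Node size metadata is proportional to degree.

#' Assemble the compound-target-pathway-disease network
#'
#' Edges: compound-target for every target; target-pathway for every
#' (target, significant term) pair with the target among the term's
#' members; pathway-disease for every significant term. Node degrees are
#' computed on the assembled graph and `size_score = degree / max(degree)`
#' (strictly increasing in degree, as "node size proportional to degree"
#' requires).
#'
#' @param compound_id label for the single compound node.
#' @param targets character vector of target identifiers (non-empty).
#' @param enrichment tibble from [enrich()] computed on these targets.
#' @param disease_id label for the single disease node.
#' @param db the [annotation_db()] the enrichment was run against (supplies
#'   term membership).
#' @return an `igraph` graph with vertex attributes `layer`
#'   (`compound`/`target`/`pathway`/`disease`), `degree`, `size_score` and
#'   edge attribute `layer_pair`.
#' @export
build_ctpd <- function(compound_id, targets, enrichment, disease_id, db) {
  targets <- sort(unique(as.character(targets)))
  stopifnot(length(targets) > 0, inherits(db, "annotation_db"))
  sig_terms <- enrichment$term_id[enrichment$significant]
  if (length(sig_terms) == 0) {
    warning("no significant terms: C-T-P-D network has only compound-target edges")
  }
  reserved <- c(compound_id, disease_id)
  if (any(targets %in% reserved) || any(sig_terms %in% reserved)) {
    stop("compound/disease labels collide with target or term identifiers")
  }
  edges <- data.frame(from = compound_id, to = targets,
                      layer_pair = "compound-target",
                      stringsAsFactors = FALSE)
  for (tid in sort(sig_terms)) {
    hit <- intersect(db$terms[[tid]]$members, targets)
    if (length(hit) > 0) {
      edges <- rbind(edges, data.frame(from = hit, to = tid,
                                       layer_pair = "target-pathway",
                                       stringsAsFactors = FALSE))
    }
    edges <- rbind(edges, data.frame(from = tid, to = disease_id,
                                     layer_pair = "pathway-disease",
                                     stringsAsFactors = FALSE))
  }
  nodes <- data.frame(
    name = c(compound_id, targets, sort(sig_terms), disease_id),
    layer = c("compound", rep("target", length(targets)),
              rep("pathway", length(sig_terms)), "disease"),
    stringsAsFactors = FALSE
  )
  g <- igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
  deg <- igraph::degree(g)
  igraph::V(g)$degree <- as.numeric(deg)
  igraph::V(g)$size_score <- if (max(deg) > 0) as.numeric(deg) / max(deg) else 0
  g
}

#' Export a C-T-P-D network
#'
#' GraphML carries `layer`, `degree` and `size_score` as typed node
#' attributes. The TSV dialect writes two files, `<path>_nodes.tsv`
#' (columns `id`, `layer`, `degree`, `size_score`) and `<path>_edges.tsv`
#' (columns `from`, `to`, `layer_pair`). Both round-trip through
#' [read_ctpd()].
#'
#' @param net graph from [build_ctpd()].
#' @param path output file (graphml) or file prefix (tsv).
#' @param dialect `"graphml"` or `"tsv"`.
#' @return `path`, invisibly.
#' @export
export_ctpd <- function(net, path, dialect = c("graphml", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  nodes <- data.frame(
    id = igraph::V(net)$name, layer = igraph::V(net)$layer,
    degree = igraph::V(net)$degree, size_score = igraph::V(net)$size_score,
    stringsAsFactors = FALSE
  )
  nodes <- nodes[order(nodes$id), ]
  el <- igraph::as_edgelist(net, names = TRUE)
  edges <- data.frame(from = el[, 1], to = el[, 2],
                      layer_pair = igraph::E(net)$layer_pair,
                      stringsAsFactors = FALSE)
  edges <- edges[order(edges$from, edges$to), ]
  utils::write.table(nodes, paste0(path, "_nodes.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  utils::write.table(edges, paste0(path, "_edges.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read a C-T-P-D network back from an export
#' @param path as passed to [export_ctpd()].
#' @param dialect `"graphml"` or `"tsv"`.
#' @return an `igraph` graph with the C-T-P-D attributes.
#' @export
read_ctpd <- function(path, dialect = c("graphml", "tsv")) {
  dialect <- match.arg(dialect)
  if (dialect == "graphml") {
    return(igraph::read_graph(path, format = "graphml"))
  }
  nodes <- utils::read.delim(paste0(path, "_nodes.tsv"), stringsAsFactors = FALSE)
  edges <- utils::read.delim(paste0(path, "_edges.tsv"), stringsAsFactors = FALSE)
  names(nodes)[names(nodes) == "id"] <- "name"
  igraph::graph_from_data_frame(edges, directed = FALSE, vertices = nodes)
}

#' Check the tetrapartite layer structure of a C-T-P-D network
#'
#' Asserts that edges run only between adjacent layers (compound-target,
#' target-pathway, pathway-disease), that every target touches the compound
#' and every pathway touches the disease.
#'
#' @param net graph from [build_ctpd()].
#' @return `TRUE` invisibly; stops with a message otherwise.
#' @export
validate_ctpd <- function(net) {
  layer <- stats::setNames(igraph::V(net)$layer, igraph::V(net)$name)
  el <- igraph::as_edgelist(net, names = TRUE)
  pair <- apply(el, 1, function(e) paste(sort(layer[e]), collapse = "-"))
  allowed <- c("compound-target", "pathway-target", "disease-pathway")
  if (!all(pair %in% allowed)) {
    stop("non-adjacent-layer edge(s) present: ", paste(unique(setdiff(pair, allowed)), collapse = ", "))
  }
  compound <- names(layer)[layer == "compound"]
  for (v in names(layer)[layer == "target"]) {
    if (!igraph::are_adjacent(net, v, compound)) stop("target ", v, " not linked to compound")
  }
  disease <- names(layer)[layer == "disease"]
  for (v in names(layer)[layer == "pathway"]) {
    if (!igraph::are_adjacent(net, v, disease)) stop("pathway ", v, " not linked to disease")
  }
  invisible(TRUE)
}
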