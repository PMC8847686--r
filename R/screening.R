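# Two-stage median-threshold topological screening.
#
# Stage 1 ("hit hubs"): keep nodes whose degree strictly exceeds twice the
# median degree of the network under screening (isolates included in the
# median). Stage 2 ("core targets"): recompute all five metrics on the
# hit-hub network and keep nodes strictly exceeding the median of every
# metric simultaneously. Medians are computed on the stage-input network,
# so rerunning a stage on its own output is not idempotent in general.

#' Stage-1 degree filter: hit hubs
#'
#' Keeps nodes whose degree strictly exceeds twice the median degree of
#' `net` (all nodes, isolates included) and returns the induced subgraph.
#' An empty survivor set is a warning, not an error.
#'
#' @param net an `igraph` network (the intersection network, usually).
#' @return a list with elements `network` (induced subgraph, provenance
#'   `"hit_hubs"`) and `threshold` (the degree cut actually used).
#' @export
hit_hub_filter <- function(net) {
  net <- normalize_graph(net, provenance = provenance(net))
  if (igraph::vcount(net) < 1) stop("hit_hub_filter needs a non-empty network")
  deg <- igraph::degree(net)
  threshold <- 2 * stats::median(deg)
  keep <- names(deg)[deg > threshold]
  if (length(keep) == 0) {
    warning("hit-hub filter kept no nodes (threshold ", threshold, ")")
  }
  sub <- igraph::induced_subgraph(net, keep)
  list(network = normalize_graph(sub, provenance = "hit_hubs"),
       threshold = threshold)
}

#' Stage-2 five-metric filter: core targets
#'
#' Computes degree, betweenness, closeness, neighborhood connectivity and
#' LAC on `net` (normally the hit-hub network); each cut is the median of
#' that metric over `net`'s nodes (or over `median_table` when a different
#' median scope is requested); survivors strictly exceed all five cuts
#' simultaneously.
#'
#' @param net an `igraph` network.
#' @param median_table optional centrality table whose columns supply the
#'   medians instead of `net`'s own (the "intersection" median scope);
#'   node metric values are always computed on `net`.
#' @return a list with elements `network` (induced subgraph, provenance
#'   `"core"`), `thresholds` (named list `degree_cut`, `closeness_cut`,
#'   `betweenness_cut`, `nc_cut`, `lac_cut`, `rule`) and `table` (the
#'   centrality table of `net` the decision was made on).
#' @export
core_target_filter <- function(net, median_table = NULL) {
  net <- normalize_graph(net, provenance = provenance(net))
  if (igraph::vcount(net) < 1) stop("core_target_filter needs a non-empty network")
  tab <- compute_all(net)
  med_src <- if (is.null(median_table)) tab else median_table
  thresholds <- list(
    degree_cut = stats::median(med_src$degree),
    closeness_cut = stats::median(med_src$closeness),
    betweenness_cut = stats::median(med_src$betweenness),
    nc_cut = stats::median(med_src$neighborhood_connectivity),
    lac_cut = stats::median(med_src$lac),
    rule = if (is.null(median_table)) "median" else "median_of_parent"
  )
  keep <- tab$node[
    tab$degree > thresholds$degree_cut &
      tab$closeness > thresholds$closeness_cut &
      tab$betweenness > thresholds$betweenness_cut &
      tab$neighborhood_connectivity > thresholds$nc_cut &
      tab$lac > thresholds$lac_cut
  ]
  if (length(keep) == 0) {
    warning("core-target filter kept no nodes")
  }
  sub <- igraph::induced_subgraph(net, keep)
  list(network = normalize_graph(sub, provenance = "core"),
       thresholds = thresholds, table = tab)
}

#' Run the full screening cascade on a drug and a disease subnetwork
#'
#' Composes [intersect_networks()], [hit_hub_filter()] and
#' [core_target_filter()], recording every stage's network, centrality
#' table and thresholds, and reporting node/edge counts per stage.
#'
#' @param drug_net,disease_net seeded `igraph` subnetworks.
#' @param median_scope where stage-2 medians come from: `"stage"` (the
#'   hit-hub network itself, the default) or `"intersection"` (the
#'   intersection network's metric distribution).
#' @return an object of class `screening_result`: a list with components
#'   `intersection`, `intersection_table`, `hit_hubs`, `hit_hub_threshold`,
#'   `hit_hubs_table`, `core`, `core_thresholds`, `median_scope`.
#' @export
run_screening <- function(drug_net, disease_net,
                          median_scope = c("stage", "intersection")) {
  median_scope <- match.arg(median_scope)
  inter <- intersect_networks(drug_net, disease_net)
  message("screening: intersection has ", igraph::vcount(inter), " nodes and ",
          igraph::ecount(inter), " edges")
  inter_table <- if (igraph::vcount(inter) > 0) compute_all(inter) else NULL
  empty <- function() normalize_graph(
    igraph::make_empty_graph(0, directed = FALSE), provenance = "core")
  if (igraph::vcount(inter) == 0) {
    res <- list(
      intersection = inter, intersection_table = inter_table,
      hit_hubs = normalize_graph(igraph::make_empty_graph(0, directed = FALSE),
                                 provenance = "hit_hubs"),
      hit_hub_threshold = NA_real_, hit_hubs_table = NULL,
      core = empty(), core_thresholds = NULL, median_scope = median_scope
    )
    return(structure(res, class = "screening_result"))
  }
  hh <- hit_hub_filter(inter)
  message("screening: hit hubs (degree > ", hh$threshold, "): ",
          igraph::vcount(hh$network), " nodes and ",
          igraph::ecount(hh$network), " edges")
  if (igraph::vcount(hh$network) == 0) {
    res <- list(
      intersection = inter, intersection_table = inter_table,
      hit_hubs = hh$network, hit_hub_threshold = hh$threshold,
      hit_hubs_table = NULL, core = empty(), core_thresholds = NULL,
      median_scope = median_scope
    )
    return(structure(res, class = "screening_result"))
  }
  core <- core_target_filter(
    hh$network,
    median_table = if (median_scope == "intersection") inter_table else NULL
  )
  message("screening: core targets: ", igraph::vcount(core$network),
          " nodes and ", igraph::ecount(core$network), " edges")
  res <- list(
    intersection = inter, intersection_table = inter_table,
    hit_hubs = hh$network, hit_hub_threshold = hh$threshold,
    hit_hubs_table = core$table, core = core$network,
    core_thresholds = core$thresholds, median_scope = median_scope
  )
  structure(res, class = "screening_result")
}

#' @export
print.screening_result <- function(x, ...) {
  cat("<screening_result>\n")
  cat("  intersection:", igraph::vcount(x$intersection), "nodes,",
      igraph::ecount(x$intersection), "edges\n")
  cat("  hit hubs    :", igraph::vcount(x$hit_hubs), "nodes,",
      igraph::ecount(x$hit_hubs), "edges (degree >",
      format(x$hit_hub_threshold), ")\n")
  cat("  core targets:", igraph::vcount(x$core), "nodes,",
      igraph::ecount(x$core), "edges\n")
  invisible(x)
}

#' Rank nodes by degree
#'
#' Descending by degree, ties broken lexicographically by node id;
#' returns `min(k, n)` rows. Used for the "top targets" bar-chart table.
#'
#' @param table a centrality table from [compute_all()].
#' @param k number of rows wanted (k >= 1).
#' @return a tibble with columns `node`, `degree`.
#' @export
top_k_by_degree <- function(table, k) {
  stopifnot(k >= 1)
  ord <- order(-table$degree, table$node)
  out <- table[ord, c("node", "degree")]
  utils::head(out, k)
}

#' Serialize a screening result to a directory
#'
#' Writes each stage's network (TSV + GraphML), each stage's centrality
#' table (TSV), and a JSON report of counts and thresholds whose keys
#' mirror the stage-by-stage narrative of a screening run.
#'
#' @param res a `screening_result`.
#' @param dir output directory (created if needed).
#' @return the report list, invisibly.
#' @export
write_screening_result <- function(res, dir) {
  stopifnot(inherits(res, "screening_result"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  stages <- list(intersection = res$intersection, hit_hubs = res$hit_hubs,
                 core = res$core)
  for (nm in names(stages)) {
    write_network(stages[[nm]], file.path(dir, paste0(nm, ".tsv")), "tsv")
    write_network(stages[[nm]], file.path(dir, paste0(nm, ".graphml")), "graphml")
  }
  if (!is.null(res$intersection_table)) {
    write_centrality_table(res$intersection_table,
                           file.path(dir, "intersection_centrality.tsv"))
  }
  if (!is.null(res$hit_hubs_table)) {
    write_centrality_table(res$hit_hubs_table,
                           file.path(dir, "hit_hubs_centrality.tsv"))
  }
  report <- screening_report(res)
  jsonlite::write_json(report, file.path(dir, "screening_report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

# Internal: counts + thresholds of a screening result as a plain list.
screening_report <- function(res) {
  list(
    intersection_nodes = igraph::vcount(res$intersection),
    intersection_edges = igraph::ecount(res$intersection),
    hit_hub_nodes = igraph::vcount(res$hit_hubs),
    hit_hub_edges = igraph::ecount(res$hit_hubs),
    hit_hub_degree_threshold = res$hit_hub_threshold,
    core_nodes = igraph::vcount(res$core),
    core_edges = igraph::ecount(res$core),
    core_thresholds = res$core_thresholds,
    median_scope = res$median_scope,
    core_targets = igraph::V(res$core)$name
  )
}
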