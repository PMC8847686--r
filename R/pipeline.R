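# End-to-end orchestration: simulate (or load) -> build seed networks ->
# intersect -> screen -> enrich -> C-T-P-D network, with every intermediate
# artifact written to the output directory and a machine-readable run
# report written last.

#' Read a pipeline configuration file
#'
#' JSON always works; YAML works when the `yaml` package is installed.
#' The configuration mirrors the argument of [run_pipeline()].
#'
#' @param path a `.json`, `.yaml` or `.yml` file.
#' @return a configuration list.
#' @export
read_pipeline_config <- function(path) {
  if (!file.exists(path)) stop("config file does not exist: ", path)
  ext <- tolower(tools::file_ext(path))
  if (ext %in% c("yaml", "yml")) {
    if (!requireNamespace("yaml", quietly = TRUE)) {
      stop("reading YAML configs requires the 'yaml' package")
    }
    yaml::read_yaml(path)
  } else {
    jsonlite::read_json(path, simplifyVector = TRUE)
  }
}

#' Run the full screening pipeline from one configuration
#'
#' The configuration is a list with sections:
#' \describe{
#'   \item{simulate}{arguments for [sim_config()]; mutually exclusive with
#'     `inputs`.}
#'   \item{inputs}{paths `interactome` (TSV edge list), `drug_seeds`,
#'     `disease_seeds` (one id per line) and `gmt`.}
#'   \item{screening}{optional; `median_scope` = `"stage"` (default) or
#'     `"intersection"`.}
#'   \item{enrichment}{optional; `alpha` (default 0.05),
#'     `query` = `"core"` (default: enrich the screened core targets).}
#'   \item{ctpd}{optional; `compound` and `disease` node labels.}
#' }
#' Exactly one of `simulate`/`inputs` must be present. Every stage artifact
#' is written under `out_dir`; the JSON run report is written last.
#'
#' @param config a configuration list or a path to a config file.
#' @param out_dir output directory.
#' @return the run report (class `ppiscreen_report`), invisibly.
#' @export
run_pipeline <- function(config, out_dir) {
  if (is.character(config) && length(config) == 1) {
    config <- read_pipeline_config(config)
  }
  has_sim <- !is.null(config$simulate)
  has_inputs <- !is.null(config$inputs)
  if (has_sim == has_inputs) {
    stop("config must contain exactly one of the sections 'simulate' or 'inputs'")
  }
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)

  if (has_sim) {
    scfg <- do.call(sim_config, config$simulate)
    message("pipeline: simulating study (rng_seed ", scfg$rng_seed, ")")
    study <- simulate_study(scfg, dir = file.path(out_dir, "simulated_inputs"))
    interactome <- study$interactome
    drug_seeds <- study$seeds$drug
    disease_seeds <- study$seeds$disease
    db <- study$db
    truth <- study$truth
    rng_seed <- scfg$rng_seed
  } else {
    need <- c("interactome", "drug_seeds", "disease_seeds", "gmt")
    miss <- need[!need %in% names(config$inputs)]
    if (length(miss) > 0) {
      stop("config section 'inputs' is missing field(s): ",
           paste(miss, collapse = ", "))
    }
    interactome <- read_edge_list(config$inputs$interactome, "tsv")
    drug_seeds <- read_seed_list(config$inputs$drug_seeds, "drug")
    disease_seeds <- read_seed_list(config$inputs$disease_seeds, "disease")
    db <- read_gmt(config$inputs$gmt,
                   background = igraph::V(interactome)$name)
    truth <- NULL
    rng_seed <- NA_integer_
  }

  message("pipeline: interactome has ", igraph::vcount(interactome),
          " nodes and ", igraph::ecount(interactome), " edges")
  drug_net <- build_seed_network(interactome, drug_seeds)
  message("pipeline: drug seed network has ", igraph::vcount(drug_net),
          " nodes and ", igraph::ecount(drug_net), " edges")
  disease_net <- build_seed_network(interactome, disease_seeds)
  message("pipeline: disease seed network has ", igraph::vcount(disease_net),
          " nodes and ", igraph::ecount(disease_net), " edges")
  write_network(drug_net, file.path(out_dir, "drug_network.tsv"), "tsv")
  write_network(disease_net, file.path(out_dir, "disease_network.tsv"), "tsv")

  median_scope <- config$screening$median_scope %||% "stage"
  screening <- run_screening(drug_net, disease_net, median_scope = median_scope)
  write_screening_result(screening, file.path(out_dir, "screening"))
  core_targets <- igraph::V(screening$core)$name

  alpha <- config$enrichment$alpha %||% 0.05
  enrichment <- NULL
  sig_terms <- character(0)
  if (length(core_targets) > 0) {
    enrichment <- enrich(core_targets, db, alpha = alpha)
    write_enrichment(enrichment, file.path(out_dir, "enrichment.tsv"))
    sig_terms <- enrichment$term_id[enrichment$significant]
    message("pipeline: ", nrow(enrichment), " terms tested, ",
            length(sig_terms), " significant at FDR < ", alpha)
  } else {
    warning("empty core target set: enrichment and C-T-P-D stages skipped")
  }

  ctpd <- NULL
  if (length(core_targets) > 0) {
    compound <- config$ctpd$compound %||% "compound"
    disease <- config$ctpd$disease %||% "disease"
    ctpd <- build_ctpd(compound, core_targets, enrichment, disease, db)
    validate_ctpd(ctpd)
    export_ctpd(ctpd, file.path(out_dir, "ctpd.graphml"), "graphml")
    export_ctpd(ctpd, file.path(out_dir, "ctpd"), "tsv")
  }

  report <- structure(list(
    software = paste0("ppiscreen ",
                      as.character(utils::packageVersion("ppiscreen"))),
    rng_seed = rng_seed,
    config = config,
    interactome_nodes = igraph::vcount(interactome),
    interactome_edges = igraph::ecount(interactome),
    drug_network_nodes = igraph::vcount(drug_net),
    drug_network_edges = igraph::ecount(drug_net),
    disease_network_nodes = igraph::vcount(disease_net),
    disease_network_edges = igraph::ecount(disease_net),
    screening = screening_report(screening),
    n_terms_tested = if (is.null(enrichment)) 0L else nrow(enrichment),
    significant_terms = sig_terms,
    core_targets = core_targets
  ), class = "ppiscreen_report")
  jsonlite::write_json(unclass(report), file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, pretty = TRUE)
  invisible(report)
}

#' @export
print.ppiscreen_report <- function(x, ...) {
  cat("<ppiscreen_report>\n")
  cat("  interactome :", x$interactome_nodes, "nodes,",
      x$interactome_edges, "edges\n")
  cat("  drug net    :", x$drug_network_nodes, "nodes,",
      x$drug_network_edges, "edges\n")
  cat("  disease net :", x$disease_network_nodes, "nodes,",
      x$disease_network_edges, "edges\n")
  cat("  intersection:", x$screening$intersection_nodes, "nodes,",
      x$screening$intersection_edges, "edges\n")
  cat("  hit hubs    :", x$screening$hit_hub_nodes, "nodes (degree >",
      format(x$screening$hit_hub_degree_threshold), ")\n")
  cat("  core targets:", x$screening$core_nodes, "nodes,",
      x$screening$core_edges, "edges\n")
  cat("  enrichment  :", length(x$significant_terms), "significant term(s) of",
      x$n_terms_tested, "tested\n")
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
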