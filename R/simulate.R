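# Synthetic interactomes with planted structure. The generator emulates
# what the screening assumes about real PPI data: a scale-free (hub
# dominated) interactome, a dense "core" module that both seed neighborhoods
# reach, and annotation terms over-represented in that core. Everything is
# a pure function of the configuration, including its single integer seed.

#' Simulation configuration
#'
#' Defaults describe the standard benchmark world used throughout the
#' package's validation: a 500-protein interactome grown by preferential
#' attachment (3 edges per new node), a 30-node planted core densified to
#' edge density 0.8, two seed sets of 40 targets each with 80% drawn from
#' the core neighborhood, and 200 annotation terms of 10-40 members of
#' which 5 draw 90% of their members from the core.
#'
#' @param n_proteins number of interactome nodes.
#' @param attachment_edges edges added per new node in preferential
#'   attachment.
#' @param core_size number of planted-core nodes (0 disables the core).
#' @param core_density target edge density among core nodes in [0, 1].
#' @param n_drug_seeds,n_disease_seeds seed-set sizes.
#' @param seed_core_fraction fraction of each seed set drawn from core
#'   nodes or their direct neighbors, in [0, 1].
#' @param n_terms number of annotation terms.
#' @param term_size_range integer pair: min/max term size.
#' @param n_enriched_terms number of terms planted as core-enriched.
#' @param enrichment_strength fraction of an enriched term's members drawn
#'   from the core, in [0, 1].
#' @param rng_seed single integer; identical seeds give bit-identical output.
#' @return a validated list of class `sim_config`.
#' @export
sim_config <- function(n_proteins = 500, attachment_edges = 3,
                       core_size = 30, core_density = 0.8,
                       n_drug_seeds = 40, n_disease_seeds = 40,
                       seed_core_fraction = 0.8,
                       n_terms = 200, term_size_range = c(10, 40),
                       n_enriched_terms = 5, enrichment_strength = 0.9,
                       rng_seed = 1) {
  cfg <- list(n_proteins = as.integer(n_proteins),
              attachment_edges = as.integer(attachment_edges),
              core_size = as.integer(core_size),
              core_density = as.numeric(core_density),
              n_drug_seeds = as.integer(n_drug_seeds),
              n_disease_seeds = as.integer(n_disease_seeds),
              seed_core_fraction = as.numeric(seed_core_fraction),
              n_terms = as.integer(n_terms),
              term_size_range = as.integer(term_size_range),
              n_enriched_terms = as.integer(n_enriched_terms),
              enrichment_strength = as.numeric(enrichment_strength),
              rng_seed = as.integer(rng_seed))
  check <- function(ok, field, why) {
    if (!isTRUE(ok)) stop("invalid simulation config: field '", field, "' ", why)
  }
  check(cfg$n_proteins >= 2, "n_proteins", "must be >= 2")
  check(cfg$attachment_edges >= 1, "attachment_edges", "must be >= 1")
  check(cfg$core_size >= 0 && cfg$core_size < cfg$n_proteins, "core_size",
        "must satisfy 0 <= core_size < n_proteins")
  check(cfg$core_density >= 0 && cfg$core_density <= 1, "core_density",
        "must lie in [0, 1]")
  check(cfg$n_drug_seeds >= 1, "n_drug_seeds", "must be >= 1")
  check(cfg$n_disease_seeds >= 1, "n_disease_seeds", "must be >= 1")
  check(cfg$n_drug_seeds + cfg$n_disease_seeds <= cfg$n_proteins,
        "n_drug_seeds", "+ n_disease_seeds must be <= n_proteins")
  check(cfg$seed_core_fraction >= 0 && cfg$seed_core_fraction <= 1,
        "seed_core_fraction", "must lie in [0, 1]")
  check(cfg$n_terms >= 0, "n_terms", "must be >= 0")
  check(length(cfg$term_size_range) == 2 &&
          cfg$term_size_range[1] >= 2 &&
          cfg$term_size_range[1] <= cfg$term_size_range[2],
        "term_size_range", "must be an increasing pair with min >= 2")
  check(cfg$term_size_range[2] <= cfg$n_proteins, "term_size_range",
        "max must be <= n_proteins")
  check(cfg$n_enriched_terms >= 0 && cfg$n_enriched_terms <= cfg$n_terms,
        "n_enriched_terms", "must lie in [0, n_terms]")
  check(cfg$enrichment_strength >= 0 && cfg$enrichment_strength <= 1,
        "enrichment_strength", "must lie in [0, 1]")
  check(is.finite(cfg$rng_seed), "rng_seed", "must be a finite integer")
  structure(cfg, class = "sim_config")
}

# Internal: zero-padded protein/term identifiers, diff-stable.
pad_ids <- function(prefix, n) {
  sprintf(paste0(prefix, "%0", max(4L, nchar(as.character(n))), "d"), seq_len(n))
}

#' Simulate a scale-free interactome with a planted dense core
#'
#' Grows a Barabasi-Albert preferential-attachment graph (simple,
#' connected, hub-dominated), then designates `core_size` random nodes as
#' the planted core and adds random core-core edges until the induced core
#' subgraph reaches `core_density`. Node identifiers are `"P0001"...`.
#'
#' @param config a [sim_config()].
#' @return a list with `interactome` (an `igraph` graph) and `truth`
#'   (list with `core_nodes`; `enriched_term_ids` is filled by
#'   [simulate_annotation_db()]).
#' @export
simulate_interactome <- function(config) {
  stopifnot(inherits(config, "sim_config"))
  withr::with_seed(config$rng_seed, {
    g <- igraph::sample_pa(config$n_proteins, m = config$attachment_edges,
                           directed = FALSE)
    igraph::V(g)$name <- pad_ids("P", config$n_proteins)
    core <- sort(sample(igraph::V(g)$name, config$core_size))
    if (config$core_size >= 2) {
      n_pairs <- choose(config$core_size, 2)
      target_edges <- ceiling(config$core_density * n_pairs)
      all_pairs <- t(utils::combn(core, 2))
      have <- igraph::as_edgelist(igraph::induced_subgraph(g, core), names = TRUE)
      key <- function(m) paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]), sep = "\r")
      missing <- all_pairs[!(key(all_pairs) %in% key_or_empty(have)), , drop = FALSE]
      need <- target_edges - (n_pairs - nrow(missing))
      if (need > 0) {
        pick <- missing[sample(nrow(missing), min(need, nrow(missing))), , drop = FALSE]
        g <- igraph::add_edges(g, as.vector(t(pick)))
      }
    }
    g <- normalize_graph(g)
    list(interactome = g,
         truth = list(core_nodes = core, enriched_term_ids = character(0)))
  })
}

# Internal: edge key helper tolerant of zero-row edge lists.
key_or_empty <- function(m) {
  if (is.null(m) || nrow(m) == 0) return(character(0))
  paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]), sep = "\r")
}

#' Sample drug and disease seed sets around the planted core
#'
#' A fraction `seed_core_fraction` of each set (rounded up) is drawn from
#' the core-adjacent pool (core nodes plus their direct neighbors); the
#' remainder is drawn uniformly from nodes outside that pool. The two sets
#' are drawn independently and may overlap.
#'
#' @param interactome graph from [simulate_interactome()].
#' @param truth matching ground truth.
#' @param config the [sim_config()] used.
#' @return list with `drug` and `disease` [seed_set()]s.
#' @export
sample_seed_sets <- function(interactome, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  nodes <- igraph::V(interactome)$name
  core <- truth$core_nodes
  adjacent <- if (length(core) > 0) {
    union(core, unique(unlist(lapply(
      igraph::adjacent_vertices(interactome, core),
      function(v) igraph::as_ids(v)
    ))))
  } else character(0)
  outside <- setdiff(nodes, adjacent)
  draw <- function(size) {
    n_core <- min(ceiling(config$seed_core_fraction * size), length(adjacent))
    n_out <- size - n_core
    if (n_out > length(outside)) {
      stop("requested seed-set size exceeds available nodes outside the core pool")
    }
    sort(c(sample(adjacent, n_core), sample(outside, n_out)))
  }
  withr::with_seed(config$rng_seed + 1L, {
    drug <- draw(config$n_drug_seeds)
    disease <- draw(config$n_disease_seeds)
  })
  list(drug = seed_set("drug", drug), disease = seed_set("disease", disease))
}

#' Simulate an annotation term database with planted core enrichment
#'
#' Generates `n_terms` terms ("T0001"...) with sizes uniform in
#' `term_size_range`. The first `n_enriched_terms` terms draw
#' `ceiling(enrichment_strength * size)` members from the planted core
#' (capped at the core size) and the rest uniformly from non-core nodes;
#' all other terms draw uniformly from all nodes. The background is the
#' full interactome node set.
#'
#' @inheritParams sample_seed_sets
#' @return list with `db` (an [annotation_db()]) and `truth` (input truth
#'   with `enriched_term_ids` filled in).
#' @export
simulate_annotation_db <- function(interactome, truth, config) {
  stopifnot(inherits(config, "sim_config"))
  nodes <- igraph::V(interactome)$name
  core <- truth$core_nodes
  noncore <- setdiff(nodes, core)
  ids <- pad_ids("T", config$n_terms)
  withr::with_seed(config$rng_seed + 2L, {
    size_choices <- seq(config$term_size_range[1], config$term_size_range[2])
    sizes <- size_choices[sample.int(length(size_choices), config$n_terms,
                                     replace = TRUE)]
    terms <- lapply(seq_len(config$n_terms), function(i) {
      if (i <= config$n_enriched_terms) {
        n_core <- min(ceiling(config$enrichment_strength * sizes[i]), length(core))
        members <- c(sample(core, n_core),
                     sample(noncore, sizes[i] - n_core))
        list(description = "synthetic|planted core-enriched term",
             members = sort(members))
      } else {
        list(description = "synthetic|background term",
             members = sort(sample(nodes, sizes[i])))
      }
    })
  })
  names(terms) <- ids
  enriched <- ids[seq_len(config$n_enriched_terms)]
  truth$enriched_term_ids <- enriched
  list(db = annotation_db(terms, background = nodes), truth = truth)
}

#' Run the whole generator and write every artifact to a directory
#'
#' Writes the interactome (TSV and SIF), both seed lists, the annotation
#' database (GMT) and the ground truth (JSON).
#'
#' @param config a [sim_config()].
#' @param dir output directory (created if needed).
#' @return invisibly, a list with `interactome`, `seeds`, `db`, `truth`.
#' @export
simulate_study <- function(config, dir = NULL) {
  sim <- simulate_interactome(config)
  seeds <- sample_seed_sets(sim$interactome, sim$truth, config)
  ann <- simulate_annotation_db(sim$interactome, sim$truth, config)
  out <- list(interactome = sim$interactome, seeds = seeds,
              db = ann$db, truth = ann$truth)
  if (!is.null(dir)) {
    dir.create(dir, recursive = TRUE, showWarnings = FALSE)
    write_network(sim$interactome, file.path(dir, "interactome.tsv"), "tsv")
    write_network(sim$interactome, file.path(dir, "interactome.sif"), "sif")
    write_seed_list(seeds$drug, file.path(dir, "drug_seeds.txt"))
    write_seed_list(seeds$disease, file.path(dir, "disease_seeds.txt"))
    write_gmt(ann$db, file.path(dir, "annotation.gmt"))
    jsonlite::write_json(out$truth, file.path(dir, "ground_truth.json"),
                         auto_unbox = FALSE, pretty = TRUE)
  }
  invisible(out)
}
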