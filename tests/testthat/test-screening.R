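test_that("hit-hub filter keeps nodes strictly above twice the median degree", {
  star <- star_graph(8)  # degrees 8, 1x8 -> median 1, threshold 2
  out <- hit_hub_filter(star)
  expect_equal(out$threshold, 2)
  expect_equal(igraph::V(out$network)$name, "C")
  expect_equal(igraph::ecount(out$network), 0)

  ring <- cycle_graph(paste0("N", 1:6))  # regular: nobody beats 2x own degree
  expect_warning(out <- hit_hub_filter(ring), "no nodes")
  expect_equal(igraph::vcount(out$network), 0)

  single <- graph_from_pairs(list(), isolates = "A")
  expect_warning(out <- hit_hub_filter(single), "no nodes")
  expect_equal(out$threshold, 0)
  expect_equal(igraph::vcount(out$network), 0)
})

test_that("core filter keeps only nodes strictly above all five stage medians", {
  # vertex-transitive graph: all metrics tied, strict > median fails everywhere
  ring <- cycle_graph(paste0("N", 1:5))
  expect_warning(out <- core_target_filter(ring), "no nodes")
  expect_equal(igraph::vcount(out$network), 0)
  expect_equal(out$thresholds$rule, "median")

  # K5 core with 7 pendant leaves attached round-robin: survivors (if any)
  # can only be K5 nodes -- pendants are below median on every metric
  k5_ids <- paste0("C", 1:5)
  pend <- lapply(1:7, function(i) c(k5_ids[(i - 1) %% 5 + 1], paste0("L", i)))
  g <- graph_from_pairs(c(asplit(t(utils::combn(k5_ids, 2)), 1), pend))
  out <- suppressWarnings(core_target_filter(g))
  kept <- igraph::V(out$network)$name
  expect_true(all(kept %in% k5_ids))
})

test_that("a dense module with a sparse periphery survives the five-way filter", {
  # K6 module; 12-node peripheral ring, each peripheral tied to one module
  # node (round-robin). Module nodes beat the periphery on all five metrics.
  core_ids <- paste0("C", 1:6)
  ring_ids <- paste0("P", sprintf("%02d", 1:12))
  edges <- c(
    asplit(t(utils::combn(core_ids, 2)), 1),
    lapply(1:12, function(i) c(ring_ids[i], ring_ids[i %% 12 + 1])),
    lapply(1:12, function(i) c(ring_ids[i], core_ids[(i - 1) %% 6 + 1]))
  )
  g <- graph_from_pairs(edges)
  out <- core_target_filter(g)
  kept <- igraph::V(out$network)$name
  expect_setequal(kept, core_ids)

  # survivors strictly exceed the recorded thresholds, re-checked from the table
  tab <- out$table
  th <- out$thresholds
  surv <- tab[tab$node %in% kept, ]
  expect_true(all(surv$degree > th$degree_cut))
  expect_true(all(surv$closeness > th$closeness_cut))
  expect_true(all(surv$betweenness > th$betweenness_cut))
  expect_true(all(surv$neighborhood_connectivity > th$nc_cut))
  expect_true(all(surv$lac > th$lac_cut))
})

test_that("run_screening composes the cascade; star example by hand", {
  star <- star_graph(8)
  res <- suppressWarnings(suppressMessages(run_screening(star, star)))
  expect_equal(edge_key(res$intersection), edge_key(star))
  expect_equal(igraph::V(res$hit_hubs)$name, "C")
  # a single node cannot strictly exceed its own median on any metric
  expect_equal(igraph::vcount(res$core), 0)
  expect_true(igraph::vcount(res$core) <= igraph::vcount(res$hit_hubs))
})

test_that("disjoint drug/disease networks propagate emptiness through all stages", {
  a <- graph_from_pairs(list(c("A", "B")))
  b <- graph_from_pairs(list(c("X", "Y")))
  res <- suppressMessages(run_screening(a, b))
  expect_equal(igraph::vcount(res$intersection), 0)
  expect_equal(igraph::vcount(res$hit_hubs), 0)
  expect_equal(igraph::vcount(res$core), 0)
})

test_that("cascade nesting and strict threshold exceedance hold on simulated pairs", {
  for (s in 1:15) {
    cfg <- sim_config(n_proteins = 120, attachment_edges = 2, core_size = 12,
                      core_density = 0.7, n_drug_seeds = 12, n_disease_seeds = 12,
                      seed_core_fraction = 0.7, rng_seed = s)
    sim <- simulate_interactome(cfg)
    seeds <- sample_seed_sets(sim$interactome, sim$truth, cfg)
    drug <- build_seed_network(sim$interactome, seeds$drug)
    dis <- build_seed_network(sim$interactome, seeds$disease)
    res <- suppressWarnings(suppressMessages(run_screening(drug, dis)))
    expect_true(all(igraph::V(res$core)$name %in% igraph::V(res$hit_hubs)$name))
    expect_true(all(igraph::V(res$hit_hubs)$name %in%
                      igraph::V(res$intersection)$name))
    # hit hubs and core are induced subgraphs of their parent stage
    expect_equal(edge_key(res$hit_hubs),
                 edge_key(igraph::induced_subgraph(res$intersection,
                                                   igraph::V(res$hit_hubs)$name)))
    expect_equal(edge_key(res$core),
                 edge_key(igraph::induced_subgraph(res$hit_hubs,
                                                   igraph::V(res$core)$name)))
    if (!is.null(res$hit_hubs_table) && igraph::vcount(res$core) > 0) {
      th <- res$core_thresholds
      surv <- res$hit_hubs_table[res$hit_hubs_table$node %in%
                                   igraph::V(res$core)$name, ]
      expect_true(all(surv$degree > th$degree_cut &
                        surv$closeness > th$closeness_cut &
                        surv$betweenness > th$betweenness_cut &
                        surv$neighborhood_connectivity > th$nc_cut &
                        surv$lac > th$lac_cut))
    }
  }
})

test_that("rerunning the hit-hub stage on its own output is not idempotent", {
  # star: first pass keeps the center; second pass (single node, median 0,
  # strict >) empties the network -- medians are stage-input quantities
  star <- star_graph(8)
  first <- hit_hub_filter(star)
  expect_equal(igraph::vcount(first$network), 1)
  second <- suppressWarnings(hit_hub_filter(first$network))
  expect_equal(igraph::vcount(second$network), 0)
})

test_that("with a frozen threshold, edges added to failing nodes never evict survivors", {
  for (s in 1:10) {
    case <- random_graph_case(s + 40, n_max = 9, p = 0.4)
    g <- case$graph
    deg <- igraph::degree(g)
    thr <- 2 * stats::median(deg)
    survivors <- names(deg)[deg > thr]
    failing <- names(deg)[deg <= thr]
    if (length(failing) < 2) next
    # add an edge between two failing nodes (if absent) and re-apply the cut
    pair <- sort(failing[1:2])
    if (!igraph::are_adjacent(g, pair[1], pair[2])) {
      g2 <- igraph::add_edges(g, pair)
      deg2 <- igraph::degree(g2)
      survivors2 <- names(deg2)[deg2 > thr]
      expect_true(all(survivors %in% survivors2))
    }
  }
})

test_that("top_k_by_degree ranks descending with lexicographic tie-break", {
  tab <- tibble::tibble(node = c("A", "B", "C"), degree = c(3, 5, 5))
  expect_equal(top_k_by_degree(tab, 2)$node, c("B", "C"))
  expect_equal(top_k_by_degree(tab, 10)$node, c("B", "C", "A"))
  expect_error(top_k_by_degree(tab, 0))

  cfg <- sim_config(n_proteins = 100, core_size = 10, n_drug_seeds = 10,
                    n_disease_seeds = 10, rng_seed = 7)
  tab <- compute_all(simulate_interactome(cfg)$interactome)
  top15 <- top_k_by_degree(tab, 15)
  expect_equal(nrow(top15), 15)
  expect_true(all(diff(top15$degree) <= 0))
})

test_that("the cascade recovers the planted core at the hit-hub stage", {
  # characterization: with the benchmark generator the hit-hub stage contains
  # the entire planted core, and the stage-2 survivors are almost pure core
  cfg <- sim_config(rng_seed = 11)
  study <- simulate_study(cfg)
  drug <- build_seed_network(study$interactome, study$seeds$drug)
  dis <- build_seed_network(study$interactome, study$seeds$disease)
  res <- suppressWarnings(suppressMessages(run_screening(drug, dis)))
  truth <- study$truth$core_nodes
  hh <- igraph::V(res$hit_hubs)$name
  expect_true(all(truth %in% hh))  # full recall at stage 1
  core <- igraph::V(res$core)$name
  if (length(core) > 0) {
    expect_gte(length(intersect(core, truth)) / length(core), 0.9)
  }
})

test_that("screening results serialize to a consistent report directory", {
  cfg <- sim_config(n_proteins = 120, core_size = 12, n_drug_seeds = 12,
                    n_disease_seeds = 12, rng_seed = 3)
  study <- simulate_study(cfg)
  drug <- build_seed_network(study$interactome, study$seeds$drug)
  dis <- build_seed_network(study$interactome, study$seeds$disease)
  res <- suppressWarnings(suppressMessages(run_screening(drug, dis)))
  dir <- withr::local_tempdir()
  report <- write_screening_result(res, dir)
  inter <- read_edge_list(file.path(dir, "intersection.tsv"), "tsv")
  expect_equal(igraph::vcount(inter), report$intersection_nodes)
  expect_equal(igraph::ecount(inter), report$intersection_edges)
  json <- jsonlite::read_json(file.path(dir, "screening_report.json"),
                              simplifyVector = TRUE)
  expect_equal(json$core_nodes, report$core_nodes)
  expect_setequal(json$core_targets, igraph::V(res$core)$name)
})
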