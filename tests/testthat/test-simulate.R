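test_that("invalid configurations are rejected naming the offending field", {
  expect_error(sim_config(core_size = 500, n_proteins = 500), "core_size")
  expect_error(sim_config(n_drug_seeds = 300, n_disease_seeds = 300,
                          n_proteins = 500), "n_drug_seeds")
  expect_error(sim_config(term_size_range = c(1, 10)), "term_size_range")
  expect_error(sim_config(term_size_range = c(10, 600), n_proteins = 500),
               "term_size_range")
  expect_error(sim_config(core_density = 1.5), "core_density")
  expect_error(sim_config(enrichment_strength = -0.1), "enrichment_strength")
})

test_that("preferential attachment with one edge per node yields a tree", {
  cfg <- sim_config(n_proteins = 10, attachment_edges = 1, core_size = 0,
                    n_drug_seeds = 2, n_disease_seeds = 2,
                    term_size_range = c(2, 5), rng_seed = 1)
  sim <- simulate_interactome(cfg)
  expect_equal(igraph::vcount(sim$interactome), 10)
  expect_equal(igraph::ecount(sim$interactome), 9)
  expect_true(igraph::is_connected(sim$interactome))
  expect_equal(sim$truth$core_nodes, character(0))
})

test_that("planted cores reach the requested density and ids are zero-padded", {
  cfg <- sim_config(n_proteins = 200, attachment_edges = 3, core_size = 20,
                    core_density = 0.8, n_drug_seeds = 20, n_disease_seeds = 20,
                    rng_seed = 42)
  sim <- simulate_interactome(cfg)
  expect_equal(igraph::vcount(sim$interactome), 200)
  expect_true(all(grepl("^P\\d{4}$", igraph::V(sim$interactome)$name)))
  expect_true(all(sim$truth$core_nodes %in% igraph::V(sim$interactome)$name))
  core_sub <- igraph::induced_subgraph(sim$interactome, sim$truth$core_nodes)
  expect_gte(igraph::ecount(core_sub), ceiling(0.8 * choose(20, 2)))
  # right-skewed degree distribution: hubs dominate the median
  deg <- igraph::degree(sim$interactome)
  expect_gt(max(deg), 3 * stats::median(deg))
})

test_that("core density >= target in repeated seeded runs; graphs stay simple", {
  for (s in 1:25) {
    cfg <- sim_config(n_proteins = 100, attachment_edges = 2, core_size = 10,
                      core_density = 0.7, n_drug_seeds = 10,
                      n_disease_seeds = 10, rng_seed = s)
    sim <- simulate_interactome(cfg)
    expect_true(igraph::is_simple(sim$interactome))
    core_sub <- igraph::induced_subgraph(sim$interactome, sim$truth$core_nodes)
    expect_gte(igraph::ecount(core_sub), ceiling(0.7 * choose(10, 2)))
  }
})

test_that("identical rng_seed gives bit-identical interactomes, seeds and GMT", {
  cfg <- sim_config(n_proteins = 150, core_size = 15, n_drug_seeds = 15,
                    n_disease_seeds = 15, n_terms = 30, rng_seed = 99)
  a <- simulate_study(cfg)
  b <- simulate_study(cfg)
  expect_identical(edge_key(a$interactome), edge_key(b$interactome))
  expect_identical(a$truth, b$truth)
  expect_identical(a$seeds$drug$members, b$seeds$drug$members)
  expect_identical(a$seeds$disease$members, b$seeds$disease$members)
  fa <- withr::local_tempfile(); fb <- withr::local_tempfile()
  write_gmt(a$db, fa); write_gmt(b$db, fb)
  expect_identical(readLines(fa), readLines(fb))
  # and a different seed actually changes the world
  c <- simulate_study(sim_config(n_proteins = 150, core_size = 15,
                                 n_drug_seeds = 15, n_disease_seeds = 15,
                                 n_terms = 30, rng_seed = 100))
  expect_false(identical(edge_key(a$interactome), edge_key(c$interactome)))
})

test_that("seed_core_fraction saturates at 1 and inverts at 0", {
  cfg1 <- sim_config(n_proteins = 200, core_size = 40, seed_core_fraction = 1,
                     n_drug_seeds = 20, n_disease_seeds = 20, rng_seed = 5)
  sim <- simulate_interactome(cfg1)
  seeds <- sample_seed_sets(sim$interactome, sim$truth, cfg1)
  pool <- union(sim$truth$core_nodes,
                unlist(lapply(igraph::adjacent_vertices(sim$interactome,
                                                        sim$truth$core_nodes),
                              igraph::as_ids)))
  expect_true(all(seeds$drug$members %in% pool))
  expect_true(all(seeds$disease$members %in% pool))

  cfg0 <- sim_config(n_proteins = 200, core_size = 10, seed_core_fraction = 0,
                     n_drug_seeds = 15, n_disease_seeds = 15, rng_seed = 5)
  sim0 <- simulate_interactome(cfg0)
  seeds0 <- sample_seed_sets(sim0$interactome, sim0$truth, cfg0)
  expect_true(all(!seeds0$drug$members %in% sim0$truth$core_nodes))
  expect_true(all(!seeds0$disease$members %in% sim0$truth$core_nodes))

  # reruns with the same config are identical
  again <- sample_seed_sets(sim$interactome, sim$truth, cfg1)
  expect_identical(seeds$drug$members, again$drug$members)
})

test_that("fully saturated enrichment makes planted terms core subsets", {
  cfg <- sim_config(n_proteins = 100, core_size = 20, n_drug_seeds = 10,
                    n_disease_seeds = 10, n_terms = 12, n_enriched_terms = 4,
                    enrichment_strength = 1, term_size_range = c(10, 10),
                    rng_seed = 21)
  sim <- simulate_interactome(cfg)
  ann <- simulate_annotation_db(sim$interactome, sim$truth, cfg)
  expect_equal(ann$truth$enriched_term_ids, sprintf("T%04d", 1:4))
  for (tid in ann$truth$enriched_term_ids) {
    members <- ann$db$terms[[tid]]$members
    expect_equal(length(members), 10)
    expect_true(all(members %in% sim$truth$core_nodes))
  }
  sizes <- vapply(ann$db$terms, function(t) length(t$members), numeric(1))
  expect_true(all(sizes == 10))
})

test_that("without planted terms the core overlap matches random expectation", {
  # oracle: mean overlap of a uniform K-subset with the 20-node core is
  # K * core_size / n_proteins; estimate over 100 simulated databases
  cfg0 <- sim_config(n_proteins = 100, core_size = 20, n_drug_seeds = 10,
                     n_disease_seeds = 10, n_terms = 10, n_enriched_terms = 0,
                     term_size_range = c(10, 10), rng_seed = 1)
  sim <- simulate_interactome(cfg0)
  overlaps <- unlist(lapply(1:100, function(s) {
    cfg <- sim_config(n_proteins = 100, core_size = 20, n_drug_seeds = 10,
                      n_disease_seeds = 10, n_terms = 10, n_enriched_terms = 0,
                      term_size_range = c(10, 10), rng_seed = s)
    ann <- simulate_annotation_db(sim$interactome, sim$truth, cfg)
    vapply(ann$db$terms, function(t) {
      length(intersect(t$members, sim$truth$core_nodes))
    }, numeric(1))
  }))
  expected <- 10 * 20 / 100  # K * core_size / n_proteins = 2
  se <- stats::sd(overlaps) / sqrt(length(overlaps))
  expect_lt(abs(mean(overlaps) - expected), 3 * se + 1e-9)
})

test_that("the degree tail stays heavy at scale (scale-free proxy)", {
  # scaled-down version of the 1000-node/100-run tail property: 20 seeded runs
  hits <- vapply(1:20, function(s) {
    cfg <- sim_config(n_proteins = 1000, attachment_edges = 3, core_size = 0,
                      n_drug_seeds = 10, n_disease_seeds = 10, rng_seed = s)
    deg <- igraph::degree(simulate_interactome(cfg)$interactome)
    max(deg) > 5 * stats::median(deg)
  }, logical(1))
  expect_gte(sum(hits), 19)
})

test_that("simulate_study writes the full artifact set and it re-reads", {
  dir <- withr::local_tempdir()
  cfg <- sim_config(n_proteins = 80, core_size = 8, n_drug_seeds = 8,
                    n_disease_seeds = 8, n_terms = 10,
                    term_size_range = c(5, 10), rng_seed = 2)
  study <- simulate_study(cfg, dir = dir)
  tsv <- read_edge_list(file.path(dir, "interactome.tsv"), "tsv")
  sif <- read_edge_list(file.path(dir, "interactome.sif"), "sif")
  expect_equal(edge_key(tsv), edge_key(study$interactome))
  expect_equal(edge_key(sif), edge_key(study$interactome))
  expect_equal(read_seed_list(file.path(dir, "drug_seeds.txt"))$members,
               study$seeds$drug$members)
  back <- read_gmt(file.path(dir, "annotation.gmt"))
  expect_equal(names(back$terms), names(study$db$terms))
  truth <- jsonlite::read_json(file.path(dir, "ground_truth.json"),
                               simplifyVector = TRUE)
  expect_setequal(truth$core_nodes, study$truth$core_nodes)
})
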