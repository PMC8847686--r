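# Independent brute-force oracles. Everything here works on a plain edge
# matrix / adjacency list and never calls igraph or the package's own
# metric code, so oracle and implementation stay separate routes.

# adjacency list from a 2-column character edge matrix + node vector
adj_from_edges <- function(nodes, edges) {
  adj <- stats::setNames(vector("list", length(nodes)), nodes)
  for (v in nodes) adj[[v]] <- character(0)
  if (nrow(edges) > 0) {
    for (i in seq_len(nrow(edges))) {
      a <- edges[i, 1]; b <- edges[i, 2]
      adj[[a]] <- union(adj[[a]], b)
      adj[[b]] <- union(adj[[b]], a)
    }
  }
  adj
}

# single-source BFS distances (Inf where unreachable), hand-rolled
bfs_dist <- function(adj, src) {
  d <- stats::setNames(rep(Inf, length(adj)), names(adj))
  d[src] <- 0
  frontier <- src
  while (length(frontier) > 0) {
    nxt <- character(0)
    for (v in frontier) {
      for (w in adj[[v]]) {
        if (!is.finite(d[w])) {
          d[w] <- d[v] + 1
          nxt <- c(nxt, w)
        }
      }
    }
    frontier <- nxt
  }
  d
}

# all shortest s-t paths by explicit recursive enumeration over BFS levels
enumerate_shortest_paths <- function(adj, s, t) {
  d <- bfs_dist(adj, s)
  if (!is.finite(d[t])) return(list())
  walk <- function(v) {
    if (v == s) return(list(s))
    preds <- Filter(function(u) d[u] == d[v] - 1, adj[[v]])
    out <- list()
    for (u in preds) {
      for (p in walk(u)) out <- c(out, list(c(p, v)))
    }
    out
  }
  walk(t)
}

# betweenness by literal enumeration of every shortest path
oracle_betweenness <- function(nodes, edges) {
  adj <- adj_from_edges(nodes, edges)
  b <- stats::setNames(rep(0, length(nodes)), nodes)
  pairs <- if (length(nodes) >= 2) utils::combn(nodes, 2) else matrix(character(0), 2, 0)
  for (j in seq_len(ncol(pairs))) {
    s <- pairs[1, j]; t <- pairs[2, j]
    paths <- enumerate_shortest_paths(adj, s, t)
    if (length(paths) == 0) next
    for (p in paths) {
      interior <- setdiff(p, c(s, t))
      b[interior] <- b[interior] + 1 / length(paths)
    }
  }
  b
}

# component-wise closeness: (c-1)/sum of BFS distances within the component
oracle_closeness <- function(nodes, edges) {
  adj <- adj_from_edges(nodes, edges)
  vapply(nodes, function(v) {
    d <- bfs_dist(adj, v)
    comp <- d[is.finite(d)]
    if (length(comp) < 2) return(0)
    (length(comp) - 1) / sum(comp)
  }, numeric(1))
}

oracle_degree <- function(nodes, edges) {
  adj <- adj_from_edges(nodes, edges)
  vapply(adj, length, numeric(1))[nodes]
}

# mean degree of neighbors
oracle_nc <- function(nodes, edges) {
  adj <- adj_from_edges(nodes, edges)
  deg <- vapply(adj, length, numeric(1))
  vapply(nodes, function(v) {
    if (length(adj[[v]]) == 0) 0 else mean(deg[adj[[v]]])
  }, numeric(1))
}

# mean degree of neighbors inside the neighbor-induced subgraph
oracle_lac <- function(nodes, edges) {
  adj <- adj_from_edges(nodes, edges)
  vapply(nodes, function(v) {
    nb <- adj[[v]]
    if (length(nb) == 0) return(0)
    inner <- vapply(nb, function(w) length(intersect(adj[[w]], nb)), numeric(1))
    mean(inner)
  }, numeric(1))
}

# exact hypergeometric upper tail by direct summation of binomial terms;
# every C(K,i)*C(N-K,n-i) term is an integer <= C(N,n) <= C(40,20) < 2^53,
# so for N <= 40 the sum is exact up to one final division
oracle_hyper_upper <- function(k, K, n, N) {
  if (k == 0) return(1)
  i <- k:min(K, n)
  sum(choose(K, i) * choose(N - K, n - i)) / choose(N, n)
}

# naive BH step-up: q_(i) = min_{j >= i} p_(j) m / j, capped at 1
oracle_bh <- function(p) {
  m <- length(p)
  ord <- order(p)
  q_sorted <- numeric(m)
  for (i in seq_len(m)) {
    js <- i:m
    q_sorted[i] <- min(1, min(p[ord][js] * m / js))
  }
  q <- numeric(m)
  q[ord] <- q_sorted
  q
}

# seeded Erdos-Renyi edge matrix + graph for oracle comparisons
random_graph_case <- function(seed, n_max = 10, p = 0.4) {
  withr::with_seed(seed, {
    n <- sample(2:n_max, 1)
    nodes <- sprintf("v%02d", seq_len(n))
    pairs <- t(utils::combn(nodes, 2))
    keep <- stats::runif(nrow(pairs)) < p
    edges <- pairs[keep, , drop = FALSE]
  })
  g <- igraph::graph_from_data_frame(
    as.data.frame(edges, stringsAsFactors = FALSE),
    directed = FALSE,
    vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  list(nodes = nodes, edges = edges, graph = g)
}

# canonical representation of an igraph's undirected edge set
edge_key <- function(g) {
  m <- igraph::as_edgelist(g, names = TRUE)
  if (nrow(m) == 0) return(character(0))
  sort(paste(pmin(m[, 1], m[, 2]), pmax(m[, 1], m[, 2]), sep = "|"))
}

# small named graphs used across test files
graph_from_pairs <- function(pairs, isolates = character(0)) {
  nodes <- sort(unique(c(unlist(pairs), isolates)))
  df <- if (length(pairs) > 0) {
    do.call(rbind, lapply(pairs, function(p) data.frame(from = p[1], to = p[2],
                                                        stringsAsFactors = FALSE)))
  } else {
    data.frame(from = character(0), to = character(0), stringsAsFactors = FALSE)
  }
  igraph::graph_from_data_frame(df, directed = FALSE,
                                vertices = data.frame(name = nodes,
                                                      stringsAsFactors = FALSE))
}

star_graph <- function(n_leaves, center = "C") {
  graph_from_pairs(lapply(seq_len(n_leaves), function(i) c(center, paste0("L", i))))
}

path_graph <- function(ids) {
  graph_from_pairs(lapply(seq_len(length(ids) - 1), function(i) ids[c(i, i + 1)]))
}

complete_graph <- function(ids) {
  graph_from_pairs(asplit(t(utils::combn(ids, 2)), 1))
}

cycle_graph <- function(ids) {
  n <- length(ids)
  graph_from_pairs(lapply(seq_len(n), function(i) c(ids[i], ids[i %% n + 1])))
}
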