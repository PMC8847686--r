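#' @importFrom igraph V E gorder gsize vcount ecount
NULL

# Internal: canonicalize an igraph object -- simple, undirected, vertices in
# lexicographic name order so downstream accumulation order is reproducible.
normalize_graph <- function(g, provenance = NULL) {
  stopifnot(igraph::is_igraph(g))
  if (igraph::is_directed(g)) g <- igraph::as_undirected(g, mode = "collapse")
  g <- igraph::simplify(g, remove.multiple = TRUE, remove.loops = TRUE)
  nm <- igraph::V(g)$name
  if (is.null(nm)) {
    igraph::V(g)$name <- as.character(seq_len(igraph::vcount(g)))
    nm <- igraph::V(g)$name
  }
  g <- igraph::permute(g, match(nm, sort(nm)))
  if (!is.null(provenance)) g <- igraph::set_graph_attr(g, "provenance", provenance)
  g
}

# Internal: graph provenance label ("drug", "disease", "intersection", ...)
provenance <- function(g) {
  p <- igraph::graph_attr(g, "provenance")
  if (is.null(p)) NA_character_ else p
}

# Internal: edges as a 2-column character matrix with endpoints sorted within
# each row and rows sorted lexicographically -- the canonical edge list.
edge_pairs <- function(g) {
  if (igraph::ecount(g) == 0) {
    return(matrix(character(0), ncol = 2, dimnames = list(NULL, c("from", "to"))))
  }
  m <- igraph::as_edgelist(g, names = TRUE)
  swap <- m[, 1] > m[, 2]
  m[swap, ] <- m[swap, c(2, 1)]
  m <- m[order(m[, 1], m[, 2]), , drop = FALSE]
  colnames(m) <- c("from", "to")
  m
}

#' Read an interactome or subnetwork from an edge-list file
#'
#' Supported dialects: `"tsv"` (two tab-separated identifier columns; a line
#' `#nodes` may introduce a trailing section of one isolated node id per
#' line), `"sif"` (Cytoscape simple interaction format, `A pp B [C ...]`;
#' a bare single-identifier line declares an isolated node) and `"graphml"`.
#' Duplicate edges (in either orientation) collapse to one undirected edge;
#' self-loops are dropped with a warning stating how many were removed.
#' Extra columns beyond the two endpoints of a TSV line (e.g. a weight
#' column) are ignored with a warning.
#'
#' @param path file to read.
#' @param dialect one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return an undirected simple `igraph` graph with character vertex names.
#' @export
read_edge_list <- function(path, dialect = c("tsv", "sif", "graphml")) {
  dialect <- match.arg(dialect)
  if (!file.exists(path)) stop("file does not exist: ", path)
  if (dialect == "graphml") {
    g <- igraph::read_graph(path, format = "graphml")
    return(normalize_graph(g))
  }
  lines <- readLines(path, warn = FALSE)
  lines_keep <- !grepl("^\\s*$", lines)
  if (!any(lines_keep)) stop("empty network file: ", path)
  from <- character(0); to <- character(0); isolated <- character(0)
  n_loops <- 0L
  weight_warned <- FALSE
  node_section <- FALSE
  for (i in seq_along(lines)) {
    ln <- lines[[i]]
    if (grepl("^\\s*$", ln)) next
    if (dialect == "tsv" && grepl("^#\\s*nodes\\s*$", ln, ignore.case = TRUE)) {
      node_section <- TRUE
      next
    }
    if (node_section) {
      isolated <- c(isolated, trimws(ln))
      next
    }
    if (dialect == "tsv") {
      f <- strsplit(ln, "\t", fixed = TRUE)[[1]]
      if (length(f) < 2L || any(!nzchar(f[1:2]))) {
        stop("malformed TSV edge line ", i, " in ", path, ": ", ln)
      }
      if (length(f) > 2L && !weight_warned) {
        warning("extra columns (e.g. weights) in ", path, " are ignored")
        weight_warned <- TRUE
      }
      a <- f[[1]]; bs <- f[[2]]
    } else { # sif
      f <- strsplit(trimws(ln), "[ \t]+")[[1]]
      if (length(f) == 1L) { isolated <- c(isolated, f); next }
      if (length(f) < 3L) stop("malformed SIF line ", i, " in ", path, ": ", ln)
      a <- f[[1]]; bs <- f[-(1:2)]
    }
    for (b in bs) {
      if (a == b) { n_loops <- n_loops + 1L; next }
      from <- c(from, a); to <- c(to, b)
    }
  }
  if (n_loops > 0) warning("dropped ", n_loops, " self-loop(s) while reading ", path)
  nodes <- sort(unique(c(from, to, isolated)))
  if (length(nodes) == 0) stop("no nodes parsed from ", path)
  g <- igraph::graph_from_data_frame(
    data.frame(from = from, to = to, stringsAsFactors = FALSE),
    directed = FALSE, vertices = data.frame(name = nodes, stringsAsFactors = FALSE)
  )
  normalize_graph(g)
}

#' Write a network to disk
#'
#' Output re-reads to an identical graph through [read_edge_list()]
#' (round-trip identity); nodes and edges are emitted in lexicographic
#' order so outputs are diff-stable.
#'
#' @param net an `igraph` graph.
#' @param path output file.
#' @param dialect one of `"tsv"`, `"sif"`, `"graphml"`.
#' @return `path`, invisibly.
#' @export
write_network <- function(net, path, dialect = c("tsv", "sif", "graphml")) {
  dialect <- match.arg(dialect)
  net <- normalize_graph(net, provenance = provenance(net))
  if (dialect == "graphml") {
    igraph::write_graph(net, path, format = "graphml")
    return(invisible(path))
  }
  ep <- edge_pairs(net)
  deg <- igraph::degree(net)
  isolated <- sort(names(deg)[deg == 0])
  if (dialect == "tsv") {
    out <- sprintf("%s\t%s", ep[, 1], ep[, 2])
    if (length(isolated) > 0) out <- c(out, "#nodes", isolated)
  } else { # sif
    out <- c(sprintf("%s\tpp\t%s", ep[, 1], ep[, 2]), isolated)
  }
  writeLines(out, path)
  invisible(path)
}

#' Seed target sets
#'
#' A seed set is a named collection of protein/gene identifiers, e.g. the
#' predicted targets of a compound or the known targets of a disease.
#' Identifiers are opaque case-sensitive strings without whitespace.
#'
#' @param name label for the set (e.g. `"drug"`, `"disease"`).
#' @param members character vector of identifiers.
#' @return an object of class `seed_set`.
#' @export
seed_set <- function(name, members) {
  members <- unique(as.character(members))
  if (length(members) == 0) stop("seed set '", name, "' is empty")
  if (any(!nzchar(members)) || any(grepl("\\s", members))) {
    stop("seed identifiers must be non-empty and whitespace-free")
  }
  structure(list(name = as.character(name), members = sort(members)),
            class = "seed_set")
}

#' @export
print.seed_set <- function(x, ...) {
  cat("<seed_set> ", x$name, ": ", length(x$members), " identifiers\n", sep = "")
  invisible(x)
}

#' Read a seed set from a one-identifier-per-line text file
#' @param path file to read.
#' @param name label for the set; defaults to the file name without extension.
#' @return a [seed_set()].
#' @export
read_seed_list <- function(path, name = tools::file_path_sans_ext(basename(path))) {
  ids <- trimws(readLines(path, warn = FALSE))
  seed_set(name, ids[nzchar(ids)])
}

#' Write a seed set as one identifier per line
#' @param seeds a [seed_set()].
#' @param path output file.
#' @export
write_seed_list <- function(seeds, path) {
  stopifnot(inherits(seeds, "seed_set"))
  writeLines(seeds$members, path)
  invisible(path)
}
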