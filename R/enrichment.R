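# Over-representation analysis (ORA) of a query gene set against an
# annotation term database: hypergeometric upper-tail p-values,
# Benjamini-Hochberg FDR, significance at q < alpha. Terms may carry a
# namespace (e.g. the three GO sub-ontologies); correction is applied
# within each namespace independently, mirroring per-ontology analyses.

#' Construct an annotation term database
#'
#' @param terms named list: `term_id -> list(description =, members =)`.
#'   A namespace may be encoded in the description as `"namespace|text"`;
#'   absent a `|`, the namespace is `"all"`.
#' @param background character vector of identifiers forming the testing
#'   universe; every term's members must be a subset of it.
#' @return an object of class `annotation_db`.
#' @export
annotation_db <- function(terms, background) {
  background <- sort(unique(as.character(background)))
  stopifnot(length(terms) > 0, length(background) > 0)
  if (is.null(names(terms)) || any(!nzchar(names(terms)))) {
    stop("terms must be a named list keyed by term id")
  }
  for (id in names(terms)) {
    t <- terms[[id]]
    if (length(t$members) < 1) stop("term ", id, " has no members")
    if (!all(t$members %in% background)) {
      stop("term ", id, " has members outside the background")
    }
    terms[[id]]$members <- sort(unique(as.character(t$members)))
  }
  structure(list(terms = terms[order(names(terms))], background = background),
            class = "annotation_db")
}

#' @export
print.annotation_db <- function(x, ...) {
  cat("<annotation_db> ", length(x$terms), " terms over a background of ",
      length(x$background), " identifiers\n", sep = "")
  invisible(x)
}

# Internal: namespace encoded in a term description as "namespace|text".
term_namespace <- function(description) {
  ifelse(grepl("|", description, fixed = TRUE),
         sub("\\|.*$", "", description), "all")
}

#' Read a GMT file
#'
#' One term per line: `term_id TAB description TAB member1 TAB member2 ...`.
#' @param path GMT file.
#' @param background optional explicit background; defaults to the union of
#'   all term members.
#' @return an [annotation_db()].
#' @export
read_gmt <- function(path, background = NULL) {
  lines <- readLines(path, warn = FALSE)
  lines <- lines[nzchar(trimws(lines))]
  if (length(lines) == 0) stop("empty GMT file: ", path)
  terms <- list()
  for (i in seq_along(lines)) {
    f <- strsplit(lines[[i]], "\t", fixed = TRUE)[[1]]
    if (length(f) < 3) stop("malformed GMT line ", i, " in ", path)
    terms[[f[[1]]]] <- list(description = f[[2]], members = f[-(1:2)])
  }
  if (is.null(background)) {
    background <- unique(unlist(lapply(terms, `[[`, "members")))
  }
  annotation_db(terms, background)
}

#' Write an annotation database as GMT
#' @param db an [annotation_db()].
#' @param path output file.
#' @export
write_gmt <- function(db, path) {
  stopifnot(inherits(db, "annotation_db"))
  out <- vapply(names(db$terms), function(id) {
    t <- db$terms[[id]]
    paste(c(id, t$description, t$members), collapse = "\t")
  }, character(1))
  writeLines(out, path)
  invisible(path)
}

#' Hypergeometric upper-tail probability
#'
#' \eqn{P[X \ge k]} for \eqn{X \sim} Hypergeometric(N, K, n): the chance of
#' drawing at least `k` members of a `K`-sized term in a query of size `n`
#' from a background of size `N`. Computed in log space (via the stable
#' cumulative hypergeometric) and exact for small N.
#'
#' @param k overlap count, `0 <= k <= min(K, n)`.
#' @param K term size; `K <= N`.
#' @param n query size; `n <= N`.
#' @param N background size.
#' @return the upper-tail probability in [0, 1].
#' @export
hypergeom_upper_tail <- function(k, K, n, N) {
  stopifnot(length(k) == 1, length(K) == 1, length(n) == 1, length(N) == 1)
  if (k < 0 || K < 0 || n < 0 || N < 1 || K > N || n > N || k > min(K, n)) {
    stop("invalid hypergeometric arguments: k=", k, " K=", K, " n=", n, " N=", N)
  }
  if (k == 0) return(1)
  stats::phyper(k - 1, m = K, n = N - K, k = n, lower.tail = FALSE)
}

#' Benjamini-Hochberg step-up q-values
#'
#' \eqn{q_{(i)} = \min_{j \ge i} p_{(j)} m / j}, capped at 1; output order
#' matches input order; invariant under input permutation.
#'
#' @param p_values numeric vector of p-values in [0, 1].
#' @return q-values in the same order, each `>=` its p-value.
#' @export
bh_fdr <- function(p_values) {
  if (any(!is.finite(p_values)) || any(p_values < 0) || any(p_values > 1)) {
    stop("p-values must lie in [0, 1]")
  }
  stats::p.adjust(p_values, method = "BH")
}

#' Over-representation analysis of a query set
#'
#' Tests every term with at least one query member (zero-overlap terms may
#' be included via `test_zero_overlap`); p-values from
#' [hypergeom_upper_tail()], q-values from [bh_fdr()] applied within each
#' term namespace independently; rows sorted ascending by q, then p, then
#' term id.
#'
#' @param query character vector of identifiers; members outside the
#'   background are dropped with a warning and `n` reflects the retained set.
#' @param db an [annotation_db()].
#' @param alpha significance level on the q-value (default 0.05).
#' @param test_zero_overlap include terms with zero overlap in the testing
#'   (and correction) set; default `FALSE`, matching common ORA tools.
#' @param background optional override of the database background (e.g. the
#'   interactome node set); term members outside it are trimmed.
#' @return a tibble with columns `term_id`, `description`, `namespace`,
#'   `k`, `K`, `n`, `N`, `p_value`, `q_value`, `significant`.
#' @export
enrich <- function(query, db, alpha = 0.05, test_zero_overlap = FALSE,
                   background = NULL) {
  stopifnot(inherits(db, "annotation_db"))
  bg <- if (is.null(background)) db$background else sort(unique(background))
  query <- unique(as.character(query))
  dropped <- setdiff(query, bg)
  if (length(dropped) > 0) {
    warning(length(dropped), " query identifier(s) outside the background were dropped")
  }
  query <- intersect(query, bg)
  if (length(query) == 0) stop("no query identifiers map into the background")
  N <- length(bg)
  n <- length(query)
  rows <- lapply(names(db$terms), function(id) {
    t <- db$terms[[id]]
    members <- intersect(t$members, bg)
    if (length(members) == 0) return(NULL)
    k <- length(intersect(members, query))
    if (k == 0 && !test_zero_overlap) return(NULL)
    tibble::tibble(
      term_id = id, description = t$description,
      namespace = term_namespace(t$description),
      k = k, K = length(members), n = n, N = N,
      p_value = hypergeom_upper_tail(k, length(members), n, N)
    )
  })
  rows <- do.call(rbind, rows)
  if (is.null(rows) || nrow(rows) == 0) {
    return(tibble::tibble(
      term_id = character(0), description = character(0),
      namespace = character(0), k = integer(0), K = integer(0),
      n = integer(0), N = integer(0), p_value = numeric(0),
      q_value = numeric(0), significant = logical(0)
    ))
  }
  rows$q_value <- stats::ave(rows$p_value, rows$namespace, FUN = bh_fdr)
  rows$significant <- rows$q_value < alpha
  rows[order(rows$q_value, rows$p_value, rows$term_id), ]
}

#' Write an enrichment table as TSV
#' @param result tibble from [enrich()].
#' @param path output file.
#' @export
write_enrichment <- function(result, path) {
  utils::write.table(result, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}
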