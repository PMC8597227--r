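#' Disease ontology container
#'
#' Holds the term universe, the child-to-parent edge relation (a term may have
#' several parents, as in MeSH descriptor trees), and the mapping from disease
#' names to their term identifiers. The edge relation must be acyclic so that
#' the ancestor closure `DAG(D)` of any disease is finite.
#'
#' @param terms character vector of term identifiers.
#' @param edges data.frame with columns `child`, `parent` (both in `terms`).
#' @param disease_terms named list: disease name -> character vector of terms.
#' @return object of class `disease_ontology`.
#' @export
disease_ontology <- function(terms, edges, disease_terms) {
  terms <- as.character(terms)
  stopifnot(!anyDuplicated(terms))
  edges <- data.frame(
    child = as.character(edges$child),
    parent = as.character(edges$parent),
    stringsAsFactors = FALSE
  )
  bad <- setdiff(c(edges$child, edges$parent), terms)
  if (length(bad) > 0) {
    stop("edge terms not in term set: ", paste(bad, collapse = ", "),
         call. = FALSE)
  }
  if (!is.list(disease_terms) || is.null(names(disease_terms))) {
    stop("disease_terms must be a named list", call. = FALSE)
  }
  for (d in names(disease_terms)) {
    miss <- setdiff(disease_terms[[d]], terms)
    if (length(miss) > 0) {
      stop("disease '", d, "' maps to unknown terms: ",
           paste(miss, collapse = ", "), call. = FALSE)
    }
  }
  parents <- split(edges$parent, factor(edges$child, levels = terms))
  children <- split(edges$child, factor(edges$parent, levels = terms))
  onto <- structure(
    list(terms = terms, edges = edges,
         disease_terms = lapply(disease_terms, as.character),
         parents = parents, children = children),
    class = "disease_ontology"
  )
  assert_acyclic(onto)
  onto
}

#' @export
print.disease_ontology <- function(x, ...) {
  cat("disease_ontology:", length(x$terms), "terms,",
      nrow(x$edges), "child->parent edges,",
      length(x$disease_terms), "diseases\n")
  invisible(x)
}

# Kahn's algorithm on the child->parent orientation; errors on any cycle.
assert_acyclic <- function(onto) {
  # indegree of a term = number of its children (edges arriving at it)
  indeg <- stats::setNames(
    vapply(onto$children, length, integer(1))[onto$terms], onto$terms
  )
  queue <- onto$terms[indeg == 0L]
  seen <- 0L
  while (length(queue) > 0) {
    t0 <- queue[[1]]
    queue <- queue[-1]
    seen <- seen + 1L
    for (p in onto$parents[[t0]]) {
      indeg[p] <- indeg[p] - 1L
      if (indeg[p] == 0L) queue <- c(queue, p)
    }
  }
  if (seen != length(onto$terms)) {
    stop("ontology edge relation contains a cycle", call. = FALSE)
  }
  invisible(onto)
}

#' Extract the ancestor sub-DAG of a disease
#'
#' Returns `DAG(D)`: the disease's own term(s) plus every ancestor reachable
#' through child-to-parent edges, together with the ontology edges induced on
#' that node set.
#'
#' @param ontology a [disease_ontology()].
#' @param disease disease name present in the ontology mapping.
#' @return object of class `disease_dag` with fields `disease`, `own_terms`,
#'   `nodes`, `edges`, `children` (within-DAG child lists).
#' @export
build_dag <- function(ontology, disease) {
  stopifnot(inherits(ontology, "disease_ontology"))
  own <- ontology$disease_terms[[disease]]
  if (is.null(own)) {
    stop("disease '", disease, "' has no term in the ontology",
         call. = FALSE)
  }
  nodes <- character(0)
  frontier <- own
  while (length(frontier) > 0) {
    nodes <- union(nodes, frontier)
    nxt <- unique(unlist(ontology$parents[frontier], use.names = FALSE))
    frontier <- setdiff(nxt, nodes)
  }
  keep <- ontology$edges$child %in% nodes & ontology$edges$parent %in% nodes
  edges <- ontology$edges[keep, , drop = FALSE]
  rownames(edges) <- NULL
  structure(
    list(disease = disease, own_terms = own, nodes = nodes, edges = edges,
         children = split(edges$child, factor(edges$parent, levels = nodes))),
    class = "disease_dag"
  )
}

#' @export
print.disease_dag <- function(x, ...) {
  cat("disease_dag for '", x$disease, "': ", length(x$nodes), " terms, ",
      nrow(x$edges), " edges\n", sep = "")
  invisible(x)
}

#' Count, for every term, how many disease DAGs contain it
#'
#' Used by the second semantic model, where rarer ancestors carry more
#' meaning. The count for a term is the number of diseases whose ancestor
#' closure includes that term.
#'
#' @param ontology a [disease_ontology()].
#' @return named integer vector over all terms (zeros for unused terms).
#' @export
term_dag_counts <- function(ontology) {
  counts <- stats::setNames(integer(length(ontology$terms)), ontology$terms)
  for (d in names(ontology$disease_terms)) {
    dag <- build_dag(ontology, d)
    counts[dag$nodes] <- counts[dag$nodes] + 1L
  }
  counts
}
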