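# Shared fixtures and independent oracles. Everything is built in code.

# --- tiny hand-checkable ontologies -------------------------------------

chain_ontology <- function() {
  disease_ontology(
    c("c", "p", "g"),
    data.frame(child = c("c", "p"), parent = c("p", "g")),
    list(X = "c")
  )
}

diamond_ontology <- function(extra_edge = FALSE) {
  edges <- data.frame(child = c("c", "c", "p1", "p2"),
                      parent = c("p1", "p2", "g", "g"))
  if (extra_edge) edges <- rbind(edges, data.frame(child = "c", parent = "g"))
  disease_ontology(c("c", "p1", "p2", "g"), edges, list(X = "c"))
}

shared_parent_ontology <- function() {
  disease_ontology(
    c("A", "B", "P"),
    data.frame(child = c("A", "B"), parent = c("P", "P")),
    list(A = "A", B = "B")
  )
}

# --- toy association / similarity data ----------------------------------

toy_disease_sim <- function() {
  S <- diag(1, 3)
  S[1, 3] <- S[3, 1] <- 0.4
  S[2, 3] <- S[3, 2] <- 0.8
  dimnames(S) <- list(c("d1", "d2", "d3"), c("d1", "d2", "d3"))
  S
}

toy_associations <- function() {
  A <- rbind(m1 = c(1, 1, 0), m2 = c(0, 0, 1))
  colnames(A) <- c("d1", "d2", "d3")
  A
}

# 1 miRNA, 1 disease, 1 association: the minimal coupled graph.
minimal_graph <- function() {
  MS <- matrix(1, 1, 1, dimnames = list("m1", "m1"))
  DS <- matrix(1, 1, 1, dimnames = list("d1", "d1"))
  A <- matrix(1, 1, 1, dimnames = list("m1", "d1"))
  assemble_graph(MS, DS, A)
}

random_coupled_graph <- function(n_m, n_d, seed, density = 0.3) {
  set.seed(seed)
  rand_sim <- function(n, labs) {
    S <- matrix(0, n, n)
    S[upper.tri(S)] <- ifelse(stats::runif(n * (n - 1) / 2) < density,
                              round(stats::runif(n * (n - 1) / 2), 3), 0)
    S <- S + t(S)
    diag(S) <- 1
    dimnames(S) <- list(labs, labs)
    S
  }
  m_lab <- sprintf("m%02d", seq_len(n_m))
  d_lab <- sprintf("d%02d", seq_len(n_d))
  A <- matrix(stats::rbinom(n_m * n_d, 1, density), n_m, n_d,
              dimnames = list(m_lab, d_lab))
  assemble_graph(rand_sim(n_m, m_lab), rand_sim(n_d, d_lab), A)
}

# --- independent oracles -------------------------------------------------

# AUC by exhaustive positive-negative pair comparison, ties counting 1/2.
auc_brute <- function(labels, scores) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) for (n in neg) {
    total <- total + (p > n) + 0.5 * (p == n)
  }
  total / (length(pos) * length(neg))
}

# Model-1 contribution by enumerating all upward paths: delta^len over the
# shortest path (max rule == shortest hop distance).
contribution_by_paths <- function(dag, delta) {
  parents_of <- split(dag$edges$parent, factor(dag$edges$child,
                                               levels = dag$nodes))
  best <- stats::setNames(rep(Inf, length(dag$nodes)), dag$nodes)
  walk <- function(node, len) {
    if (len < best[node]) best[node] <<- len
    for (p in parents_of[[node]]) walk(p, len + 1)
  }
  for (t0 in dag$own_terms) walk(t0, 0)
  delta^best
}

# Random DAG on <= n nodes: node i may take parents among nodes < i.
random_tree_dag <- function(n, seed) {
  set.seed(seed)
  child <- character(0)
  parent <- character(0)
  terms <- sprintf("t%02d", seq_len(n))
  for (i in seq(2, n)) {
    n_par <- sample(1:min(2, i - 1), 1)
    for (p in sample(seq_len(i - 1), n_par)) {
      child <- c(child, terms[i])
      parent <- c(parent, terms[p])
    }
  }
  # disease sits at the last (deepest) node; its ancestors are earlier nodes
  onto <- disease_ontology(terms,
                           data.frame(child = child, parent = parent),
                           list(D = terms[n]))
  build_dag(onto, "D")
}

expect_valid_similarity <- function(S, tol = 1e-8) {
  expect_true(is.matrix(S))
  expect_equal(S, t(S), tolerance = tol)
  expect_gte(min(S), -tol)
  expect_lte(max(S), 1 + tol)
}
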