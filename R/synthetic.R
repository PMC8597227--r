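# Synthetic fixtures: random multi-rooted ontology DAGs and planted-block
# association matrices, so the whole pipeline is testable offline.

#' Generate a random multi-rooted ontology DAG
#'
#' Terms are created in topological order and partitioned round-robin over
#' `n_roots` disjoint subtrees; every non-root term draws one mandatory
#' parent among the earlier terms of its subtree plus extra parents with
#' probability `p_attach` (up to `max_parents`), giving a MeSH-like
#' multi-parent DAG. Diseases are mapped to leaf-ish terms (terms without
#' children), cycling through the leaves of the subtree their group points
#' to, so same-group diseases share nearby ancestors.
#'
#' @param n_terms number of ontology terms.
#' @param n_roots number of independent subtree roots (default 1).
#' @param max_parents maximum parents per term (default 2).
#' @param p_attach probability of each extra parent (default 0.3).
#' @param seed integer seed; same seed, same ontology.
#' @param diseases character vector of disease names to map (default: one
#'   disease per leaf term, named `d001`, `d002`, ...).
#' @param disease_groups optional integer group per disease in
#'   `1..n_roots`; default cycles `1, 2, ..., n_roots`.
#' @return a [disease_ontology()].
#' @export
make_ontology <- function(n_terms, n_roots = 1, max_parents = 2,
                          p_attach = 0.3, seed = 1, diseases = NULL,
                          disease_groups = NULL) {
  stopifnot(n_terms >= 1, n_roots >= 1, n_roots <= n_terms,
            max_parents >= 1, p_attach >= 0, p_attach <= 1)
  set.seed(derive_seed(seed, "ontology"))
  terms <- sprintf("T%04d", seq_len(n_terms))
  subtree <- rep_len(seq_len(n_roots), n_terms)
  # first occurrence of each subtree id is its root
  is_root <- !duplicated(subtree)
  child <- character(0)
  parent <- character(0)
  for (i in seq_len(n_terms)) {
    if (is_root[i]) next
    pool <- which(subtree[seq_len(i - 1)] == subtree[i])
    n_par <- 1 + stats::rbinom(1, min(max_parents, length(pool)) - 1,
                               p_attach)
    pars <- if (length(pool) == 1) pool else sample(pool, n_par)
    child <- c(child, rep(terms[i], length(pars)))
    parent <- c(parent, terms[pars])
  }
  edges <- data.frame(child = child, parent = parent)
  leaves <- setdiff(terms, parent)
  if (is.null(diseases)) diseases <- sprintf("d%03d", seq_along(leaves))
  if (is.null(disease_groups)) {
    disease_groups <- rep_len(seq_len(n_roots), length(diseases))
  }
  stopifnot(length(disease_groups) == length(diseases),
            all(disease_groups %in% seq_len(n_roots)))
  mapping <- stats::setNames(vector("list", length(diseases)), diseases)
  for (g in seq_len(n_roots)) {
    dg <- which(disease_groups == g)
    lg <- leaves[subtree[match(leaves, terms)] == g]
    if (length(lg) == 0) lg <- terms[subtree == g][1]
    for (k in seq_along(dg)) {
      mapping[[dg[k]]] <- lg[((k - 1) %% length(lg)) + 1]
    }
  }
  disease_ontology(terms, edges, mapping)
}

#' Generate a planted-block association matrix
#'
#' miRNAs and diseases are assigned round-robin to `n_groups` matched
#' groups; a cell is an association with probability `p_in` when the miRNA
#' and disease groups coincide and `p_out` otherwise. The one-to-one group
#' coupling is what makes similarity (through shared interaction profiles)
#' genuinely predictive of held-out links.
#'
#' @param n_mirnas,n_diseases matrix dimensions.
#' @param n_groups number of matched groups.
#' @param p_in within-group association probability.
#' @param p_out background association probability (`p_out < p_in`).
#' @param seed integer seed.
#' @return list with the binary labeled matrix `A` and the ground-truth
#'   integer vectors `mirna_groups`, `disease_groups`.
#' @export
make_associations <- function(n_mirnas, n_diseases, n_groups = 4,
                              p_in = 0.3, p_out = 0.02, seed = 1) {
  stopifnot(n_mirnas >= 1, n_diseases >= 1, n_groups >= 1,
            p_out >= 0, p_out < p_in, p_in <= 1)
  set.seed(derive_seed(seed, "associations"))
  mg <- rep_len(seq_len(n_groups), n_mirnas)
  dg <- rep_len(seq_len(n_groups), n_diseases)
  prob <- ifelse(outer(mg, dg, `==`), p_in, p_out)
  A <- matrix(stats::rbinom(length(prob), 1, prob), n_mirnas, n_diseases)
  dimnames(A) <- list(sprintf("mir-%03d", seq_len(n_mirnas)),
                      sprintf("d%03d", seq_len(n_diseases)))
  list(A = A, mirna_groups = mg, disease_groups = dg)
}

#' Generate a coherent fixture bundle
#'
#' Couples a planted-block association matrix with a group-structured
#' ontology: disease groups map onto disjoint ontology subtrees, so the
#' semantic similarity is also informative about the planted structure.
#'
#' @inheritParams make_associations
#' @param n_terms ontology size (default `3 * n_diseases`, at least
#'   `2 * n_groups`).
#' @param seed master seed; ontology and associations use derived streams.
#' @return list with `A`, `ontology`, `mirna_groups`, `disease_groups`.
#' @export
make_fixture_bundle <- function(n_mirnas, n_diseases, n_groups = 4,
                                p_in = 0.3, p_out = 0.02, seed = 1,
                                n_terms = NULL) {
  if (is.null(n_terms)) n_terms <- max(3 * n_diseases, 2 * n_groups)
  assoc <- make_associations(n_mirnas, n_diseases, n_groups, p_in, p_out,
                             seed = derive_seed(seed, "bundle-assoc"))
  onto <- make_ontology(n_terms, n_roots = n_groups,
                        seed = derive_seed(seed, "bundle-onto"),
                        diseases = colnames(assoc$A),
                        disease_groups = assoc$disease_groups)
  list(A = assoc$A, ontology = onto,
       mirna_groups = assoc$mirna_groups,
       disease_groups = assoc$disease_groups)
}

#' Named fixture presets
#'
#' `tiny` (12 x 9, 3 groups) for smoke tests, `bench` (120 x 80, 8 groups,
#' `p_in = 0.3`, `p_out = 0.02`) for the recovery benchmark, and
#' `paper-scale` (495 x 383, 20 groups, background rate calibrated so the
#' expected association count is about 5430, the scale of the curated
#' human miRNA-disease catalogue this method targets).
#'
#' @param preset one of `"tiny"`, `"bench"`, `"paper-scale"`.
#' @param seed master seed.
#' @return a [make_fixture_bundle()] result.
#' @export
fixture_preset <- function(preset = c("tiny", "bench", "paper-scale"),
                           seed = 1) {
  preset <- match.arg(preset)
  switch(preset,
    tiny = make_fixture_bundle(12, 9, n_groups = 3, p_in = 0.35,
                               p_out = 0.02, seed = seed),
    bench = make_fixture_bundle(120, 80, n_groups = 8, p_in = 0.3,
                                p_out = 0.02, seed = seed),
    `paper-scale` = make_paper_scale_fixture(seed)
  )
}

#' Full-scale synthetic input bundle
#'
#' 495 miRNAs x 383 diseases with a 20-group planted structure. With the
#' matched-cell fraction `f = 1/20` and `p_in = 0.4`, the background rate is
#' solved from `N (f p_in + (1-f) p_out) = 5430`, so the expected
#' association count matches the real catalogue's size in expectation.
#'
#' @param seed master seed.
#' @param dir optional directory; when given, the bundle is written as
#'   `associations.tsv`, `ontology_edges.tsv`, `ontology_mapping.tsv` and
#'   `groups.tsv`.
#' @return a [make_fixture_bundle()] result (invisibly when written).
#' @export
make_paper_scale_fixture <- function(seed = 1, dir = NULL) {
  n_m <- 495
  n_d <- 383
  g <- 20
  f <- 1 / g
  p_in <- 0.4
  p_out <- (5430 / (n_m * n_d) - f * p_in) / (1 - f)
  bundle <- make_fixture_bundle(n_m, n_d, n_groups = g, p_in = p_in,
                                p_out = p_out, seed = seed,
                                n_terms = 950)
  if (!is.null(dir)) {
    write_fixture_bundle(bundle, dir)
    return(invisible(bundle))
  }
  bundle
}

#' Write a fixture bundle to a directory
#'
#' @param bundle a [make_fixture_bundle()] result.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_fixture_bundle <- function(bundle, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write_associations(bundle$A, file.path(dir, "associations.tsv"))
  write_ontology(bundle$ontology,
                 file.path(dir, "ontology_edges.tsv"),
                 file.path(dir, "ontology_mapping.tsv"))
  groups <- rbind(
    data.frame(entity = rownames(bundle$A), type = "mirna",
               group = bundle$mirna_groups),
    data.frame(entity = colnames(bundle$A), type = "disease",
               group = bundle$disease_groups)
  )
  utils::write.table(groups, file.path(dir, "groups.tsv"), sep = "\t",
                     quote = FALSE, row.names = FALSE)
  invisible(dir)
}
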