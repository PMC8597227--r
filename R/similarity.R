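#' Similarity-kernel parameters
#'
#' Bundles the four scalar knobs of the similarity stage: the Gaussian kernel
#' bandwidth control `gamma_prime`, the semantic/kernel mixing factor `alpha`,
#' the edge-pruning threshold `h`, and the semantic decay factor `delta`.
#'
#' @param gamma_prime bandwidth control (> 0); the effective bandwidth is
#'   `gamma_prime` divided by the mean squared profile norm. Default 0.5.
#' @param alpha weight of the semantic/functional part in the integrated
#'   similarity, in `[0,1]`. Default 0.5.
#' @param h similarity threshold below which intra-type edges are dropped,
#'   in `[0,1]`. Default 0.5.
#' @param delta per-hop decay of ancestor contributions in semantic model 1,
#'   in `(0,1)`. Default 0.5.
#' @param log_base logarithm base for semantic model 2 rarity scores; the
#'   model-2 similarity ratio is base-invariant, so this only affects the raw
#'   contribution scores. Default natural log.
#' @return object of class `kernel_params`.
#' @export
kernel_params <- function(gamma_prime = 0.5, alpha = 0.5, h = 0.5,
                          delta = 0.5, log_base = exp(1)) {
  stopifnot(gamma_prime > 0, alpha >= 0, alpha <= 1, h >= 0, h <= 1,
            delta > 0, delta < 1, log_base > 1)
  structure(list(gamma_prime = gamma_prime, alpha = alpha, h = h,
                 delta = delta, log_base = log_base),
            class = "kernel_params")
}

#' Model-1 semantic contribution scores
#'
#' The disease's own term contributes 1; every ancestor term contributes the
#' maximum over its within-DAG children of `delta` times the child's
#' contribution, so contributions decay with hop distance from the disease.
#' Computed by memoized recursion over the acyclic children relation.
#'
#' @param dag a [build_dag()] result.
#' @param delta decay factor in `(0,1)`.
#' @return object of class `contribution_table` with fields `disease`,
#'   `contributions` (named numeric over DAG terms), `model = "model1"`.
#' @export
semantic_contribution_m1 <- function(dag, delta = 0.5) {
  stopifnot(inherits(dag, "disease_dag"), delta > 0, delta < 1)
  memo <- new.env(parent = emptyenv())
  for (t0 in dag$own_terms) assign(t0, 1, envir = memo)
  contrib <- function(t0) {
    if (exists(t0, envir = memo, inherits = FALSE)) {
      return(get(t0, envir = memo, inherits = FALSE))
    }
    kids <- dag$children[[t0]]
    if (length(kids) == 0) {
      stop("term '", t0, "' unreachable from disease term", call. = FALSE)
    }
    v <- max(vapply(kids, function(k) delta * contrib(k), numeric(1)))
    assign(t0, v, envir = memo)
    v
  }
  scores <- vapply(dag$nodes, contrib, numeric(1))
  structure(
    list(disease = dag$disease,
         contributions = stats::setNames(scores, dag$nodes),
         model = "model1"),
    class = "contribution_table"
  )
}

#' Model-2 semantic contribution scores
#'
#' Replaces depth decay by rarity: a term appearing in few disease DAGs is
#' more informative. The contribution of term `d` is
#' `-log(count(d) / n_diseases)` where `count(d)` is the number of disease
#' DAGs containing `d`. A term present in every DAG contributes 0.
#'
#' @param ontology a [disease_ontology()].
#' @param disease disease name.
#' @param counts optional precomputed [term_dag_counts()]; recomputed when
#'   `NULL`.
#' @param log_base logarithm base (similarity is base-invariant).
#' @return a `contribution_table` with `model = "model2"`.
#' @export
semantic_contribution_m2 <- function(ontology, disease, counts = NULL,
                                     log_base = exp(1)) {
  stopifnot(inherits(ontology, "disease_ontology"))
  if (is.null(counts)) counts <- term_dag_counts(ontology)
  n_dis <- length(ontology$disease_terms)
  stopifnot(n_dis >= 1)
  dag <- build_dag(ontology, disease)
  cts <- counts[dag$nodes]
  if (any(cts < 1) || any(cts > n_dis)) {
    stop("term DAG counts outside [1, n_diseases]; inconsistent ontology",
         call. = FALSE)
  }
  scores <- -log(cts / n_dis, base = log_base)
  structure(
    list(disease = disease,
         contributions = stats::setNames(as.numeric(scores), dag$nodes),
         model = "model2"),
    class = "contribution_table"
  )
}

#' Semantic value of a disease
#'
#' Sum of all term contributions in the disease's DAG.
#'
#' @param contribs a `contribution_table`.
#' @return scalar semantic value.
#' @export
semantic_value <- function(contribs) {
  stopifnot(inherits(contribs, "contribution_table"),
            length(contribs$contributions) > 0)
  sum(contribs$contributions)
}

#' Semantic similarity between two diseases
#'
#' Shared-ancestor score normalized by the two semantic values:
#' `sum over shared terms of (c_i(t) + c_j(t)) / (DV_i + DV_j)`.
#' Zero when the DAGs are disjoint; 1 for identical model-1 tables.
#'
#' @param contribs_i,contribs_j `contribution_table`s built with the same
#'   model.
#' @return similarity in `[0,1]`.
#' @export
semantic_similarity <- function(contribs_i, contribs_j) {
  stopifnot(inherits(contribs_i, "contribution_table"),
            inherits(contribs_j, "contribution_table"))
  if (!identical(contribs_i$model, contribs_j$model)) {
    stop("contribution tables built with different models", call. = FALSE)
  }
  shared <- intersect(names(contribs_i$contributions),
                      names(contribs_j$contributions))
  dv <- semantic_value(contribs_i) + semantic_value(contribs_j)
  if (dv <= 0) {
    warning("both semantic values are zero; returning 0", call. = FALSE)
    return(0)
  }
  if (length(shared) == 0) return(0)
  sum(contribs_i$contributions[shared] + contribs_j$contributions[shared]) / dv
}

#' Pairwise disease semantic similarity matrix
#'
#' Builds one contribution table per disease under the requested model and
#' evaluates all pairwise semantic similarities. Diseases absent from the
#' ontology get zero off-diagonal similarity (unit diagonal) and are reported
#' via the `"missing"` attribute; the Gaussian kernel then acts as their
#' supplement in the integrated similarity.
#'
#' @param ontology a [disease_ontology()] or `NULL` (all-missing).
#' @param diseases ordered character vector of disease names (matrix labels).
#' @param model `"model1"` or `"model2"`.
#' @param params a [kernel_params()].
#' @return labeled symmetric similarity matrix in `[0,1]`.
#' @export
disease_semantic_matrix <- function(ontology, diseases,
                                    model = c("model1", "model2"),
                                    params = kernel_params()) {
  model <- match.arg(model)
  n <- length(diseases)
  S <- diag(1, n)
  dimnames(S) <- list(diseases, diseases)
  if (is.null(ontology)) {
    attr(S, "missing") <- diseases
    return(S)
  }
  present <- diseases[diseases %in% names(ontology$disease_terms)]
  missing <- setdiff(diseases, present)
  if (length(missing) > 0) {
    warning(length(missing), " disease(s) absent from the ontology; ",
            "their semantic similarity is 0 (kernel supplement applies)",
            call. = FALSE)
  }
  counts <- if (model == "model2") term_dag_counts(ontology) else NULL
  tabs <- lapply(present, function(d) {
    if (model == "model1") {
      semantic_contribution_m1(build_dag(ontology, d), delta = params$delta)
    } else {
      semantic_contribution_m2(ontology, d, counts = counts,
                               log_base = params$log_base)
    }
  })
  names(tabs) <- present
  dvs <- vapply(tabs, semantic_value, numeric(1))
  if (length(present) >= 2) {
    for (a in seq_len(length(present) - 1)) {
      for (b in seq(a + 1, length(present))) {
        s <- suppressWarnings(semantic_similarity(tabs[[a]], tabs[[b]]))
        S[present[a], present[b]] <- s
        S[present[b], present[a]] <- s
      }
    }
  }
  # model 2 self-similarity is 1 whenever DV > 0; keep unit diagonal even
  # when a disease's every ancestor is universal (DV = 0).
  diag(S) <- 1
  attr(S, "missing") <- missing
  check_similarity_matrix(S, "semantic similarity matrix")
  S
}

#' Gaussian interaction-profile kernel similarity
#'
#' Profiles are the rows of the supplied matrix (disease profiles are the
#' columns of the association matrix, passed transposed; miRNA profiles its
#' rows). The bandwidth is `gamma_prime` divided by the mean squared profile
#' norm, making the kernel invariant to uniform positive rescaling of all
#' profiles.
#'
#' @param profiles numeric matrix, one interaction profile per row, with
#'   rownames used as labels.
#' @param gamma_prime bandwidth control, > 0 (default 0.5).
#' @return labeled symmetric kernel matrix with unit diagonal.
#' @export
gip_similarity <- function(profiles, gamma_prime = 0.5) {
  stopifnot(is.matrix(profiles), nrow(profiles) >= 1, gamma_prime > 0)
  norms2 <- rowSums(profiles^2)
  if (all(norms2 == 0)) {
    stop("all interaction profiles are zero; kernel bandwidth undefined",
         call. = FALSE)
  }
  gamma <- gamma_prime / mean(norms2)
  d2 <- outer(norms2, norms2, "+") - 2 * tcrossprod(profiles)
  d2[d2 < 0] <- 0
  S <- exp(-gamma * d2)
  S <- (S + t(S)) / 2
  diag(S) <- 1
  dimnames(S) <- list(rownames(profiles), rownames(profiles))
  S
}

#' Similarity of a disease to a disease set
#'
#' Max-linkage: the best similarity between `d_t` and any member of `DT`.
#'
#' @param d_t disease name.
#' @param DT nonempty character vector of disease names.
#' @param S labeled disease similarity matrix.
#' @return scalar similarity.
#' @export
disease_set_similarity <- function(d_t, DT, S) {
  if (length(DT) == 0) stop("disease set DT is empty", call. = FALSE)
  miss <- setdiff(c(d_t, DT), rownames(S))
  if (length(miss) > 0) {
    stop("diseases not indexed in S: ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  max(S[d_t, DT])
}

#' miRNA functional similarity from associated disease sets
#'
#' Two miRNAs are functionally similar when their associated disease sets are
#' semantically similar: each disease of one set is matched to its best
#' counterpart in the other set (max-linkage), and the matched similarities
#' are averaged over both directions. miRNAs with no associated disease get a
#' zero off-diagonal row (diagonal 1) with a warning.
#'
#' @param A binary miRNA-by-disease association matrix with dimnames.
#' @param disease_sim labeled disease similarity matrix used for matching
#'   (typically the mean of the two semantic models).
#' @return labeled symmetric functional similarity matrix, unit diagonal.
#' @export
mirna_functional_similarity <- function(A, disease_sim) {
  stopifnot(is.matrix(A), !is.null(rownames(A)), !is.null(colnames(A)))
  check_same_labels(t(A), disease_sim, "association columns and disease_sim")
  n_m <- nrow(A)
  mirnas <- rownames(A)
  dsets <- lapply(seq_len(n_m), function(i) colnames(A)[A[i, ] == 1])
  empty <- vapply(dsets, length, integer(1)) == 0
  if (any(empty)) {
    warning(sum(empty), " miRNA(s) with no associated disease; ",
            "functional similarity row set to 0", call. = FALSE)
  }
  FS <- diag(1, n_m)
  dimnames(FS) <- list(mirnas, mirnas)
  if (n_m >= 2) {
    for (i in seq_len(n_m - 1)) {
      if (empty[i]) next
      for (j in seq(i + 1, n_m)) {
        if (empty[j]) next
        sub <- disease_sim[dsets[[i]], dsets[[j]], drop = FALSE]
        val <- (sum(apply(sub, 1, max)) + sum(apply(sub, 2, max))) /
          (length(dsets[[i]]) + length(dsets[[j]]))
        FS[i, j] <- val
        FS[j, i] <- val
      }
    }
  }
  FS
}

#' Integrate semantic/functional similarity with the Gaussian kernel
#'
#' Disease mode mixes the mean of the two semantic models with the kernel:
#' `alpha * (DSS1 + DSS2)/2 + (1 - alpha) * DGS`. miRNA mode mixes functional
#' similarity with the kernel: `alpha * FS + (1 - alpha) * MGS`. Pass one or
#' two matrices in `semantic_parts` accordingly.
#'
#' @param semantic_parts list of one (FS) or two (DSS1, DSS2) labeled
#'   similarity matrices.
#' @param gip_part labeled Gaussian kernel similarity matrix.
#' @param alpha mixing weight in `[0,1]`.
#' @return labeled integrated similarity matrix.
#' @export
integrate_similarity <- function(semantic_parts, gip_part, alpha = 0.5) {
  stopifnot(is.list(semantic_parts), length(semantic_parts) >= 1,
            alpha >= 0, alpha <= 1)
  for (p in semantic_parts) check_same_labels(p, gip_part)
  sem <- Reduce(`+`, semantic_parts) / length(semantic_parts)
  S <- alpha * sem + (1 - alpha) * gip_part
  check_similarity_matrix(S, "integrated similarity matrix")
  S
}

#' Drop low-similarity entries
#'
#' Entries `>= h` are kept unchanged, entries below are zeroed. The diagonal
#' is exempt so self-similarity never vanishes. Idempotent, never increases
#' an entry, preserves symmetry.
#'
#' @param S_prime labeled similarity matrix.
#' @param h threshold in `[0,1]`.
#' @return filtered similarity matrix.
#' @export
threshold_filter <- function(S_prime, h = 0.5) {
  stopifnot(h >= 0, h <= 1)
  d <- diag(S_prime)
  S <- S_prime
  S[S < h] <- 0
  diag(S) <- d
  S
}

#' Compute all similarity matrices for an association matrix
#'
#' Runs the full similarity stage: both disease semantic models from the
#' ontology, Gaussian interaction-profile kernels for diseases (columns of
#' `A`) and miRNAs (rows of `A`), miRNA functional similarity from the mean
#' semantic disease similarity, integration with weight `alpha`, and
#' threshold filtering at `h`.
#'
#' @param A binary miRNA-by-disease association matrix with dimnames.
#' @param ontology a [disease_ontology()] or `NULL` (kernel-only similarity).
#' @param params a [kernel_params()].
#' @param gip_fallback when `TRUE`, diseases absent from the ontology use the
#'   pure kernel similarity in their rows/columns (alpha forced to 0 there)
#'   instead of the diluted `alpha * 0 + (1-alpha) * DGS`.
#' @param functional_disease_sim which disease similarity feeds the
#'   functional-similarity matching: `"semantic"` (mean of the two models,
#'   default) or `"integrated"`.
#' @return list with components `DSS1`, `DSS2`, `DGS`, `MGS`, `FS`,
#'   `DS_prime`, `MS_prime`, `DS`, `MS` and the `params` used.
#' @export
compute_similarities <- function(A, ontology = NULL,
                                 params = kernel_params(),
                                 gip_fallback = FALSE,
                                 functional_disease_sim = c("semantic",
                                                            "integrated")) {
  stopifnot(is.matrix(A), !is.null(rownames(A)), !is.null(colnames(A)))
  functional_disease_sim <- match.arg(functional_disease_sim)
  diseases <- colnames(A)
  DSS1 <- disease_semantic_matrix(ontology, diseases, "model1", params)
  DSS2 <- disease_semantic_matrix(ontology, diseases, "model2", params)
  DGS <- gip_similarity(t(A), gamma_prime = params$gamma_prime)
  MGS <- gip_similarity(A, gamma_prime = params$gamma_prime)
  DS_prime <- integrate_similarity(list(DSS1, DSS2), DGS, params$alpha)
  if (gip_fallback) {
    miss <- union(attr(DSS1, "missing"), attr(DSS2, "missing"))
    if (length(miss) > 0) {
      DS_prime[miss, ] <- DGS[miss, ]
      DS_prime[, miss] <- DGS[, miss]
    }
  }
  dsim <- if (functional_disease_sim == "semantic") {
    (DSS1 + DSS2) / 2
  } else {
    DS_prime
  }
  FS <- mirna_functional_similarity(A, dsim)
  MS_prime <- integrate_similarity(list(FS), MGS, params$alpha)
  DS <- threshold_filter(DS_prime, params$h)
  MS <- threshold_filter(MS_prime, params$h)
  list(DSS1 = DSS1, DSS2 = DSS2, DGS = DGS, MGS = MGS, FS = FS,
       DS_prime = DS_prime, MS_prime = MS_prime, DS = DS, MS = MS,
       params = params)
}
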