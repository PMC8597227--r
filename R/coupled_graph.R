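#' Assemble the coupled heterogeneous graph
#'
#' Joins the two intra-type similarity networks (miRNA-miRNA from `MS`,
#' disease-disease from `DS`, both already threshold-filtered) with the
#' inter-type association edges of `A`. Intra-type edges carry their
#' similarity as weight; inter-type edges carry the scalar `w_dm` (1 for a
#' binary association matrix). Self-edges are excluded; self-similarity is
#' handled by the embedding stage separately.
#'
#' Node ordering convention used everywhere downstream: miRNAs first
#' (indices `1..m`), then diseases (`m+1..m+n`).
#'
#' @param MS miRNA similarity matrix (n_m x n_m, labeled).
#' @param DS disease similarity matrix (n_d x n_d, labeled).
#' @param A binary miRNA-by-disease association matrix (n_m x n_d, labeled).
#' @param w_dm weight assigned to observed association edges (default 1).
#' @return object of class `coupled_graph` with the similarity matrices, the
#'   association matrix, and edge lists `edges_mm`, `edges_dd`, `edges_md`
#'   (data.frames with integer endpoints and weights; intra-type lists store
#'   each unordered pair once, `i < j`).
#' @export
assemble_graph <- function(MS, DS, A, w_dm = 1) {
  check_similarity_matrix(MS, "MS")
  check_similarity_matrix(DS, "DS")
  stopifnot(is.matrix(A), all(A %in% c(0, 1)))
  if (nrow(A) != nrow(MS) || ncol(A) != nrow(DS)) {
    stop("dimension mismatch between MS, DS and A", call. = FALSE)
  }
  check_same_labels(MS, A, "MS and association rows")
  check_same_labels(DS, t(A), "DS and association columns")

  upper_edges <- function(S) {
    idx <- which(upper.tri(S) & S != 0, arr.ind = TRUE)
    data.frame(i = idx[, 1], j = idx[, 2], weight = S[idx])
  }
  md <- which(A == 1, arr.ind = TRUE)
  structure(
    list(
      mirna_labels = rownames(A), disease_labels = colnames(A),
      MS = MS, DS = DS, A = A, w_dm = w_dm,
      edges_mm = upper_edges(MS),
      edges_dd = upper_edges(DS),
      edges_md = data.frame(i = md[, 1], j = md[, 2], weight = w_dm)
    ),
    class = "coupled_graph"
  )
}

#' @export
print.coupled_graph <- function(x, ...) {
  cat("coupled_graph:", length(x$mirna_labels), "miRNAs,",
      length(x$disease_labels), "diseases |",
      nrow(x$edges_mm), "mm edges,", nrow(x$edges_dd), "dd edges,",
      nrow(x$edges_md), "md edges\n")
  invisible(x)
}

#' Bipartite adjacency of the association network
#'
#' Builds the symmetric `(m+n) x (m+n)` block matrix `[[0, A], [A^T, 0]]`
#' (miRNAs first, then diseases) used by the graph-convolution stage, which
#' deliberately propagates over the association network only. An optional
#' fold mask zeroes held-out test associations before building, so feature
#' propagation never sees test edges.
#'
#' @param A binary miRNA-by-disease association matrix with dimnames.
#' @param mask optional two-column matrix/data.frame of (miRNA index,
#'   disease index) cells to zero out.
#' @return symmetric binary matrix with zero diagonal and labels
#'   `c(rownames(A), colnames(A))`.
#' @export
bipartite_adjacency <- function(A, mask = NULL) {
  stopifnot(is.matrix(A), all(A %in% c(0, 1)))
  if (!is.null(mask)) {
    mask <- as.matrix(mask)[, 1:2, drop = FALSE]
    storage.mode(mask) <- "integer"
    A[mask] <- 0
  }
  m <- nrow(A)
  n <- ncol(A)
  B <- matrix(0, m + n, m + n)
  B[seq_len(m), m + seq_len(n)] <- A
  B[m + seq_len(n), seq_len(m)] <- t(A)
  labs <- c(rownames(A), colnames(A))
  dimnames(B) <- list(labs, labs)
  B
}

#' Export a coupled graph as an edge-list TSV
#'
#' Writes columns `src_label`, `dst_label`, `weight`, `edge_type` with
#' `edge_type` one of `mm`, `dd`, `md`, for inspection and plotting.
#'
#' @param graph a [assemble_graph()] result.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_edgelist <- function(graph, path) {
  stopifnot(inherits(graph, "coupled_graph"))
  rows <- rbind(
    data.frame(src_label = graph$mirna_labels[graph$edges_mm$i],
               dst_label = graph$mirna_labels[graph$edges_mm$j],
               weight = graph$edges_mm$weight, edge_type = "mm"),
    data.frame(src_label = graph$disease_labels[graph$edges_dd$i],
               dst_label = graph$disease_labels[graph$edges_dd$j],
               weight = graph$edges_dd$weight, edge_type = "dd"),
    data.frame(src_label = graph$mirna_labels[graph$edges_md$i],
               dst_label = graph$disease_labels[graph$edges_md$j],
               weight = graph$edges_md$weight, edge_type = "md")
  )
  utils::write.table(rows, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}
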