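# Readers/writers for the interchange formats: pair-list TSVs, labeled
# similarity CSVs, ontology TSVs, JSON run configs. All matching is by exact
# string label after whitespace trimming; UTF-8, LF line endings.

read_tsv_checked <- function(path, required_cols) {
  lines <- readLines(path, encoding = "UTF-8")
  if (length(lines) == 0) stop("empty file: ", path, call. = FALSE)
  lines <- lines[nzchar(lines)]
  fields <- strsplit(lines, "\t", fixed = TRUE)
  header <- trimws(fields[[1]])
  miss <- setdiff(required_cols, header)
  if (length(miss) > 0) {
    stop(path, ": missing column(s) ", paste(miss, collapse = ", "),
         call. = FALSE)
  }
  n_col <- length(header)
  bad <- which(vapply(fields[-1], length, integer(1)) != n_col)
  if (length(bad) > 0) {
    stop(path, ": malformed row at line ", bad[1] + 1,
         " (expected ", n_col, " fields)", call. = FALSE)
  }
  body <- do.call(rbind, fields[-1])
  df <- as.data.frame(body, stringsAsFactors = FALSE)
  names(df) <- header
  df[] <- lapply(df, trimws)
  df
}

#' Read an association pair list
#'
#' TSV with header columns `mirna`, `disease`; builds the label-indexed
#' binary association matrix. Duplicate pairs collapse to a single 1 with a
#' warning; malformed rows error with their line number.
#'
#' @param path TSV path.
#' @return binary matrix with miRNA rownames and disease colnames.
#' @export
read_associations <- function(path) {
  df <- read_tsv_checked(path, c("mirna", "disease"))
  key <- paste(df$mirna, df$disease, sep = "\r")
  if (anyDuplicated(key)) {
    warning(sum(duplicated(key)), " duplicate association pair(s) collapsed",
            call. = FALSE)
    df <- df[!duplicated(key), , drop = FALSE]
  }
  mirnas <- sort(unique(df$mirna))
  diseases <- sort(unique(df$disease))
  A <- matrix(0L, length(mirnas), length(diseases),
              dimnames = list(mirnas, diseases))
  A[cbind(match(df$mirna, mirnas), match(df$disease, diseases))] <- 1L
  A
}

#' Write an association matrix as a pair list
#'
#' @param A binary matrix with dimnames.
#' @param path output TSV path.
#' @return the path, invisibly.
#' @export
write_associations <- function(A, path) {
  idx <- which(A == 1, arr.ind = TRUE)
  df <- data.frame(mirna = rownames(A)[idx[, 1]],
                   disease = colnames(A)[idx[, 2]])
  df <- df[order(df$mirna, df$disease), , drop = FALSE]
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(path)
}

#' Read / write a labeled matrix as CSV
#'
#' CSV with a label header row and a label first column. Round-trips are
#' exact to formatting precision (15 significant digits).
#'
#' @param path CSV path.
#' @param expect_symmetric error when the matrix read is not symmetric.
#' @return labeled numeric matrix.
#' @export
read_matrix <- function(path, expect_symmetric = FALSE) {
  df <- utils::read.csv(path, row.names = 1, check.names = FALSE,
                        fileEncoding = "UTF-8")
  M <- as.matrix(df)
  if (nrow(M) != ncol(M)) stop(path, ": matrix is not square", call. = FALSE)
  if (!identical(rownames(M), colnames(M))) {
    stop(path, ": row labels do not match column labels", call. = FALSE)
  }
  if (expect_symmetric && max(abs(M - t(M))) > 1e-8) {
    stop(path, ": expected a symmetric matrix", call. = FALSE)
  }
  M
}

#' @rdname read_matrix
#' @param S labeled numeric matrix to write.
#' @export
write_matrix <- function(S, path) {
  df <- as.data.frame(S, check.names = FALSE)
  utils::write.csv(format(df, digits = 15, trim = TRUE, scientific = FALSE),
                   path, quote = FALSE, fileEncoding = "UTF-8")
  invisible(path)
}

#' Read a disease ontology from TSV files
#'
#' @param dag_path TSV with columns `child_term`, `parent_term`.
#' @param mapping_path TSV with columns `disease_name`, `term_id` (a disease
#'   may appear on several rows).
#' @return a [disease_ontology()].
#' @export
read_ontology <- function(dag_path, mapping_path) {
  ed <- read_tsv_checked(dag_path, c("child_term", "parent_term"))
  mp <- read_tsv_checked(mapping_path, c("disease_name", "term_id"))
  terms <- unique(c(ed$child_term, ed$parent_term, mp$term_id))
  disease_ontology(
    terms,
    data.frame(child = ed$child_term, parent = ed$parent_term),
    split(mp$term_id, mp$disease_name)
  )
}

#' Write a disease ontology to TSV files
#'
#' @param ontology a [disease_ontology()].
#' @param dag_path,mapping_path output paths.
#' @return `dag_path`, invisibly.
#' @export
write_ontology <- function(ontology, dag_path, mapping_path) {
  utils::write.table(
    data.frame(child_term = ontology$edges$child,
               parent_term = ontology$edges$parent),
    dag_path, sep = "\t", quote = FALSE, row.names = FALSE,
    fileEncoding = "UTF-8"
  )
  mp <- data.frame(
    disease_name = rep(names(ontology$disease_terms),
                       lengths(ontology$disease_terms)),
    term_id = unlist(ontology$disease_terms, use.names = FALSE)
  )
  utils::write.table(mp, mapping_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, fileEncoding = "UTF-8")
  invisible(dag_path)
}

config_schema <- function() {
  list(
    paths = c("associations", "ontology_edges", "ontology_mapping",
              "out_dir"),
    similarity = c("alpha", "h", "gamma_prime", "delta"),
    eoe = c("epochs", "learning_rate", "negative", "seed", "init",
            "init_rank"),
    predictor = c("layers", "k", "z", "mlp_hidden",
                  "interlayer_activation", "learning_rate", "epochs",
                  "patience", "eval_every", "val_fraction", "threshold",
                  "use_eoe"),
    evaluation = c("folds", "ratio", "threshold", "seed")
  )
}

#' Default run configuration
#'
#' Nested list mirroring the JSON config schema with the package defaults:
#' `alpha = 0.5`, `h = 0.5`, `gamma_prime = 0.5`, `delta = 0.5`, EOE with
#' 200 epochs at learning rate 1e-3, predictor with 2 layers, `k = 2`,
#' `z = 64`, MLP width 64, and 5-fold CV at a 1:5 positive:negative ratio.
#'
#' @return nested configuration list.
#' @export
default_config <- function() {
  list(
    paths = list(),
    similarity = list(alpha = 0.5, h = 0.5, gamma_prime = 0.5, delta = 0.5),
    eoe = list(epochs = 200, learning_rate = 1e-3, negative = "all_pairs",
               seed = 1, init = "similarity", init_rank = 32),
    predictor = list(layers = 2, k = 2, z = 64, mlp_hidden = 64,
                     interlayer_activation = "none", learning_rate = 1e-3,
                     epochs = 300, patience = 10, eval_every = 10,
                     val_fraction = 0.1, threshold = 0.5, use_eoe = TRUE),
    evaluation = list(folds = 5, ratio = 5, threshold = 0.5, seed = 1)
  )
}

#' Read and validate a JSON run configuration
#'
#' Unknown sections or keys are rejected; recognized keys override the
#' defaults of [default_config()]; every numeric field is range-checked by
#' the constructor it feeds.
#'
#' @param path JSON file path.
#' @return validated nested configuration list.
#' @export
read_config <- function(path) {
  user <- jsonlite::read_json(path, simplifyVector = TRUE)
  schema <- config_schema()
  bad_sec <- setdiff(names(user), names(schema))
  if (length(bad_sec) > 0) {
    stop("unknown config section(s): ", paste(bad_sec, collapse = ", "),
         call. = FALSE)
  }
  cfg <- default_config()
  for (sec in names(user)) {
    bad <- setdiff(names(user[[sec]]), schema[[sec]])
    if (length(bad) > 0) {
      stop("unknown key(s) in config section '", sec, "': ",
           paste(bad, collapse = ", "), call. = FALSE)
    }
    cfg[[sec]][names(user[[sec]])] <- user[[sec]]
  }
  # range validation through the typed constructors
  do.call(kernel_params, cfg$similarity[c("gamma_prime", "alpha", "h",
                                          "delta")])
  do.call(eoe_config, cfg$eoe)
  do.call(predictor_config, cfg$predictor)
  stopifnot(cfg$evaluation$folds >= 2, cfg$evaluation$ratio >= 1)
  cfg
}

#' Write a cross-validation report
#'
#' JSON report (metrics, means, config echo, seed) plus a TSV of per-fold
#' test scores, making the run reconstructible from its outputs.
#'
#' @param report a `cv_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_cv_report <- function(report, dir) {
  stopifnot(inherits(report, "cv_report"))
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  jsonlite::write_json(
    list(metrics = report$metrics, means = as.list(report$means),
         config = report$config, seed = report$seed),
    file.path(dir, "cv_report.json"),
    auto_unbox = TRUE, digits = NA, pretty = TRUE
  )
  utils::write.table(report$scores, file.path(dir, "fold_scores.tsv"),
                     sep = "\t", quote = FALSE, row.names = FALSE,
                     fileEncoding = "UTF-8")
  invisible(dir)
}

#' Save / load a trained predictor as a JSON checkpoint
#'
#' Single text archive holding every weight matrix, the config, and the node
#' labels; `load_model` restores an identical `predictor_state`.
#'
#' @param model a `predictor_state`.
#' @param path JSON path.
#' @return the path (`save_model`) or the restored model (`load_model`).
#' @export
save_model <- function(model, path) {
  stopifnot(inherits(model, "predictor_state"))
  payload <- list(
    params = lapply(model$params, function(p) {
      if (is.matrix(p)) list(dim = dim(p), data = as.numeric(p))
      else list(dim = NULL, data = as.numeric(p))
    }),
    config = unclass(model$config),
    n_mirna = model$n_mirna, n_disease = model$n_disease,
    mirna_labels = model$mirna_labels,
    disease_labels = model$disease_labels,
    embeddings = list(dim = dim(model$embeddings),
                      data = as.numeric(model$embeddings))
  )
  jsonlite::write_json(payload, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname save_model
#' @export
load_model <- function(path) {
  p <- jsonlite::read_json(path, simplifyVector = TRUE)
  rebuild <- function(x) {
    if (!is.null(x$dim) && length(x$dim) == 2) {
      matrix(x$data, x$dim[1], x$dim[2])
    } else {
      as.numeric(x$data)
    }
  }
  params <- lapply(p$params, rebuild)
  cfg <- p$config
  config <- do.call(predictor_config, cfg[setdiff(names(cfg), character(0))])
  structure(
    list(params = params, config = config,
         n_mirna = p$n_mirna, n_disease = p$n_disease,
         mirna_labels = p$mirna_labels, disease_labels = p$disease_labels,
         embeddings = rebuild(p$embeddings),
         loss_history = numeric(0), val_history = numeric(0)),
    class = "predictor_state"
  )
}

#' Export EOE embeddings and the harmony matrix
#'
#' Embeddings as TSV (label column plus coordinates), harmony matrix as an
#' unlabeled CSV.
#'
#' @param state an `eoe_state`.
#' @param graph the [assemble_graph()] the state was trained on (for
#'   labels).
#' @param dir output directory.
#' @return `dir`, invisibly.
#' @export
write_eoe_state <- function(state, graph, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  wr <- function(M, labels, path) {
    df <- data.frame(label = labels, M, check.names = FALSE)
    names(df) <- c("label", paste0("v", seq_len(ncol(M))))
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, fileEncoding = "UTF-8")
  }
  wr(state$mirna_vecs, graph$mirna_labels,
     file.path(dir, "mirna_embeddings.tsv"))
  wr(state$disease_vecs, graph$disease_labels,
     file.path(dir, "disease_embeddings.tsv"))
  utils::write.table(state$harmony, file.path(dir, "harmony.csv"),
                     sep = ",", quote = FALSE, row.names = FALSE,
                     col.names = FALSE, fileEncoding = "UTF-8")
  invisible(dir)
}
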