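#' Entity registry
#'
#' An ordered, deduplicated set of identifiers for one entity kind
#' (circRNA, disease or miRNA) with a bijective id -> 0-based index map.
#' Registry order is lexicographic so every matrix built on top of it is
#' reproducible byte-for-byte across runs.
#'
#' @param ids character vector of identifiers (duplicates collapsed).
#' @param kind one of \code{"circRNA"}, \code{"disease"}, \code{"miRNA"}.
#' @return An object of class \code{entity_registry} with elements
#'   \code{kind}, \code{ids} (sorted, unique) and \code{index} (named
#'   integer vector of 0-based positions).
#' @export
entity_registry <- function(ids, kind = c("circRNA", "disease", "miRNA")) {
  kind <- match.arg(kind)
  ids <- as.character(ids)
  if (anyNA(ids) || any(!nzchar(ids))) {
    stop("registry ids must be non-empty strings", call. = FALSE)
  }
  # locale-independent lexicographic order
  ids <- sort(unique(ids), method = "radix")
  idx <- seq_along(ids) - 1L
  names(idx) <- ids
  structure(list(kind = kind, ids = ids, index = idx),
            class = "entity_registry")
}

#' @export
length.entity_registry <- function(x) length(x$ids)

#' @export
print.entity_registry <- function(x, ...) {
  cat(sprintf("<entity_registry: %d %s ids>\n", length(x$ids), x$kind))
  invisible(x)
}

registry_lookup <- function(registry, ids) {
  pos <- registry$index[ids]
  if (anyNA(pos)) {
    bad <- ids[is.na(pos)]
    stop(sprintf("unknown %s id(s): %s", registry$kind,
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  unname(pos) + 1L  # 1-based for R indexing
}

#' Read a two-column association edge list
#'
#' Reads a TSV file of identifier pairs (lines starting with \code{#} are
#' comments). Duplicated pairs are collapsed; the order of first appearance
#' is preserved in the returned value (registries built later sort ids).
#'
#' @param path file path.
#' @param kind_a,kind_b entity kinds of the two columns (informational,
#'   recorded as attributes).
#' @return data.frame with columns \code{id_a}, \code{id_b}, one row per
#'   unique pair.
#' @export
load_edge_list <- function(path, kind_a = "circRNA", kind_b = "disease") {
  lines <- readLines(path, warn = FALSE)
  keep <- which(!grepl("^\\s*#", lines) & nzchar(trimws(lines)))
  if (length(keep) == 0) {
    stop(sprintf("empty network: no edges in '%s'", path), call. = FALSE)
  }
  parts <- strsplit(lines[keep], "\t", fixed = TRUE)
  nfield <- lengths(parts)
  if (any(nfield < 2)) {
    bad <- keep[which(nfield < 2)[1]]
    stop(sprintf("parse error in '%s' at line %d: expected 2 tab-separated fields",
                 path, bad), call. = FALSE)
  }
  id_a <- vapply(parts, `[[`, character(1), 1L)
  id_b <- vapply(parts, `[[`, character(1), 2L)
  dup <- duplicated(paste(id_a, id_b, sep = "\r"))
  out <- data.frame(id_a = id_a[!dup], id_b = id_b[!dup],
                    stringsAsFactors = FALSE)
  attr(out, "kind_a") <- kind_a
  attr(out, "kind_b") <- kind_b
  out
}

pairs_to_matrix <- function(pairs, reg_row, reg_col) {
  M <- matrix(0L, nrow = length(reg_row), ncol = length(reg_col),
              dimnames = list(reg_row$ids, reg_col$ids))
  if (nrow(pairs) > 0) {
    M[cbind(registry_lookup(reg_row, pairs$id_a),
            registry_lookup(reg_col, pairs$id_b))] <- 1L
  }
  M
}

#' Build the three indexed association matrices
#'
#' Assembles the circRNA-disease (A), circRNA-miRNA (Y) and disease-miRNA
#' (O) 0/1 adjacency matrices on shared entity registries. The miRNA axis
#' of Y and O is the union of miRNA ids seen in either interaction file, so
#' the two matrices are always column-aligned. Entities appearing in only
#' some of the inputs are retained with all-zero rows/columns.
#'
#' @param cd_pairs,cm_pairs,dm_pairs data.frames with columns
#'   \code{id_a}, \code{id_b} as returned by [load_edge_list()]:
#'   circRNA-disease, circRNA-miRNA and disease-miRNA pairs.
#' @return An object of class \code{bipartite_network}: list with 0/1
#'   matrices \code{A} (nc x nd), \code{Y} (nc x nm), \code{O} (nd x nm)
#'   and registries \code{circ}, \code{disease}, \code{mirna}.
#' @export
build_network <- function(cd_pairs, cm_pairs = NULL, dm_pairs = NULL) {
  empty <- data.frame(id_a = character(), id_b = character(),
                      stringsAsFactors = FALSE)
  if (is.null(cm_pairs)) cm_pairs <- empty
  if (is.null(dm_pairs)) dm_pairs <- empty
  circ <- entity_registry(c(cd_pairs$id_a, cm_pairs$id_a), "circRNA")
  disease <- entity_registry(c(cd_pairs$id_b, dm_pairs$id_a), "disease")
  mir_ids <- c(cm_pairs$id_b, dm_pairs$id_b)
  mirna <- if (length(mir_ids)) entity_registry(mir_ids, "miRNA") else
    structure(list(kind = "miRNA", ids = character(),
                   index = structure(integer(), names = character())),
              class = "entity_registry")
  structure(list(
    A = pairs_to_matrix(cd_pairs, circ, disease),
    Y = pairs_to_matrix(cm_pairs, circ, mirna),
    O = pairs_to_matrix(dm_pairs, disease, mirna),
    circ = circ, disease = disease, mirna = mirna
  ), class = "bipartite_network")
}

#' @export
print.bipartite_network <- function(x, ...) {
  cat(sprintf("<bipartite_network: %d circRNAs x %d diseases x %d miRNAs; %d / %d / %d edges>\n",
              nrow(x$A), ncol(x$A), ncol(x$Y),
              sum(x$A), sum(x$Y), sum(x$O)))
  invisible(x)
}

#' Read / write a labelled similarity kernel matrix
#'
#' Kernels travel as TSV matrices with the entity ids as first row and
#' first column. Matrices asymmetric beyond \code{1e-8} are symmetrized to
#' \code{(K + t(K))/2} with a warning; negative entries are an error.
#'
#' @param path file path.
#' @return numeric matrix with identical row and column names.
#' @export
read_kernel_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  K <- as.matrix(tab)
  storage.mode(K) <- "double"
  if (nrow(K) != ncol(K)) {
    stop(sprintf("kernel in '%s' is not square (%d x %d)", path,
                 nrow(K), ncol(K)), call. = FALSE)
  }
  if (any(K < 0)) {
    stop(sprintf("kernel in '%s' has negative entries", path), call. = FALSE)
  }
  asym <- max(abs(K - t(K)))
  if (asym > 1e-8) {
    warning(sprintf("kernel in '%s' asymmetric (max dev %.3g); symmetrizing",
                    path, asym), call. = FALSE)
    K <- (K + t(K)) / 2
  } else if (asym > 0) {
    K <- (K + t(K)) / 2
  }
  K
}

#' @rdname read_kernel_matrix
#' @param kernel square numeric matrix with row/column names.
#' @export
write_kernel_matrix <- function(kernel, path) {
  stopifnot(is.matrix(kernel), nrow(kernel) == ncol(kernel))
  df <- data.frame(id = rownames(kernel),
                   format(kernel, digits = 15, scientific = TRUE,
                          trim = TRUE),
                   check.names = FALSE, stringsAsFactors = FALSE)
  colnames(df) <- c("id", colnames(kernel))
  utils::write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read an expression matrix (entities x conditions)
#'
#' TSV with a header of condition labels and row ids in the first column.
#' Rows containing missing values are rejected.
#'
#' @param path file path.
#' @return numeric matrix, rownames are entity ids.
#' @export
read_expression_matrix <- function(path) {
  tab <- utils::read.table(path, sep = "\t", header = TRUE, row.names = 1,
                           check.names = FALSE, stringsAsFactors = FALSE)
  M <- as.matrix(tab)
  storage.mode(M) <- "double"
  if (anyNA(M)) {
    bad <- rownames(M)[which(rowSums(is.na(M)) > 0)]
    stop(sprintf("missing expression values for: %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  M
}

#' Read circRNA sequences from FASTA
#'
#' @param path FASTA file path.
#' @return named character vector of upper-case sequences.
#' @export
read_sequences <- function(path) {
  ss <- Biostrings::readDNAStringSet(path)
  seqs <- toupper(as.character(ss))
  names(seqs) <- sub("\\s.*$", "", names(ss))
  seqs
}

#' Disease term hierarchy (directed acyclic graph)
#'
#' Builds the DAG used for semantic similarity from a parent -> child edge
#' table. Acyclicity is enforced.
#'
#' @param edges data.frame with columns \code{parent}, \code{child} (or a
#'   TSV path with those two columns).
#' @param term_map optional named character vector mapping disease ids to
#'   term ids; defaults to the identity on DAG terms.
#' @return object of class \code{disease_dag}: list with \code{terms},
#'   \code{parents} (named list: term -> character vector of parents),
#'   \code{children}, and \code{term_map}.
#' @export
disease_dag <- function(edges, term_map = NULL) {
  if (is.character(edges) && length(edges) == 1) {
    edges <- load_edge_list(edges, "disease", "disease")
    names(edges) <- c("parent", "child")
  }
  stopifnot(all(c("parent", "child") %in% names(edges)))
  edges$parent <- as.character(edges$parent)
  edges$child <- as.character(edges$child)
  terms <- sort(unique(c(edges$parent, edges$child)), method = "radix")
  g <- igraph::graph_from_data_frame(edges[, c("parent", "child")],
                                     directed = TRUE)
  if (!igraph::is_dag(g)) {
    stop("disease term graph contains a cycle", call. = FALSE)
  }
  parents <- split(edges$parent, edges$child)
  children <- split(edges$child, edges$parent)
  if (is.null(term_map)) {
    term_map <- structure(terms, names = terms)
  } else if (!all(term_map %in% terms)) {
    stop("term_map refers to terms missing from the DAG", call. = FALSE)
  }
  structure(list(terms = terms, parents = parents, children = children,
                 term_map = term_map),
            class = "disease_dag")
}

#' @export
print.disease_dag <- function(x, ...) {
  cat(sprintf("<disease_dag: %d terms, %d mapped diseases>\n",
              length(x$terms), length(x$term_map)))
  invisible(x)
}
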