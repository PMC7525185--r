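#' circRNA regulatory similarity from shared miRNA partners
#'
#' Overlap similarity between the miRNA partner sets of two circRNAs.
#' The default is the Ochiai form |Mi n Mj| / sqrt(|Mi| |Mj|), which is 1
#' for identical non-empty sets as a similarity kernel should be; the raw
#' product denominator |Mi n Mj| / (|Mi| |Mj|) is available as
#' \code{form = "product"}. Either score is 0 when either set is empty.
#'
#' @param m_i,m_j character vectors of miRNA ids interacting with each
#'   circRNA.
#' @param form \code{"ochiai"} (default) or \code{"product"}.
#' @return similarity in \[0, 1\].
#' @export
regulatory_similarity <- function(m_i, m_j, form = c("ochiai", "product")) {
  form <- match.arg(form)
  m_i <- unique(m_i); m_j <- unique(m_j)
  if (length(m_i) == 0 || length(m_j) == 0) return(0)
  inter <- length(intersect(m_i, m_j))
  denom <- if (form == "ochiai") sqrt(length(m_i) * length(m_j)) else
    length(m_i) * length(m_j)
  inter / denom
}

#' circRNA expression similarity (clipped Pearson correlation)
#'
#' Pearson correlation of two expression profiles, clipped below at zero
#' so that anti-correlated profiles count as "not similar" (downstream
#' fusion requires nonnegative kernels). Constant profiles have no defined
#' correlation; the pair scores 0 and a warning is raised.
#'
#' @param x,y numeric vectors of equal length >= 2.
#' @return similarity in \[0, 1\].
#' @export
expression_similarity <- function(x, y) {
  stopifnot(length(x) == length(y), length(x) >= 2)
  if (stats::sd(x) == 0 || stats::sd(y) == 0) {
    warning("constant expression profile: similarity set to 0", call. = FALSE)
    return(0)
  }
  max(0, stats::cor(x, y, method = "pearson"))
}

#' Gaussian interaction profile (GIP) kernel
#'
#' K\[i,j\] = exp(-gamma * ||p_i - p_j||^2) over the rows of a 0/1
#' interaction-profile matrix, with bandwidth gamma = n / sum_i ||p_i||^2
#' (the reciprocal mean squared profile norm). Rows with all-zero profiles
#' are kept and scored by the same formula.
#'
#' @param profiles 0/1 matrix, one interaction profile per row.
#' @return symmetric kernel matrix with unit diagonal and the bandwidth in
#'   attribute \code{"gamma"}.
#' @export
gip_kernel <- function(profiles) {
  profiles <- as.matrix(profiles)
  n <- nrow(profiles)
  stopifnot(n >= 2)
  norms2 <- rowSums(profiles^2)
  total <- sum(norms2)
  if (total == 0) {
    stop("GIP bandwidth undefined: all interaction profiles are zero",
         call. = FALSE)
  }
  gamma <- n / total
  # squared distances via the Gram expansion
  G <- tcrossprod(profiles)
  D2 <- outer(norms2, norms2, `+`) - 2 * G
  D2[D2 < 0] <- 0
  K <- exp(-gamma * D2)
  diag(K) <- 1
  K <- (K + t(K)) / 2
  dimnames(K) <- list(rownames(profiles), rownames(profiles))
  attr(K, "gamma") <- gamma
  K
}

dag_ancestors <- function(dag, term) {
  seen <- character()
  frontier <- term
  while (length(frontier)) {
    seen <- c(seen, frontier)
    frontier <- unique(unlist(dag$parents[frontier], use.names = FALSE))
    frontier <- setdiff(frontier, seen)
  }
  unique(seen)
}

#' Semantic contribution and value of a disease term
#'
#' Contribution of every ancestor t of d decays with the generations
#' separating it from d: D_d(d) = 1 and, for t above d,
#' D_d(t) = delta * max over children c of t inside d's ancestor closure
#' of D_d(c). The semantic value DV(d) is the sum of contributions.
#'
#' @param dag a [disease_dag()].
#' @param term term id present in the DAG.
#' @param delta decay factor in (0, 1); default 0.5.
#' @return list with \code{contributions} (named numeric over the ancestor
#'   closure) and \code{value} (DV).
#' @export
semantic_value <- function(dag, term, delta = 0.5) {
  stopifnot(delta > 0, delta < 1)
  if (!term %in% dag$terms) {
    stop(sprintf("unknown term '%s'", term), call. = FALSE)
  }
  anc <- dag_ancestors(dag, term)
  memo <- new.env(parent = emptyenv())
  # within the ancestor closure the graph is acyclic and every downward
  # path reaches the focus term, so plain memoized recursion terminates
  contrib <- function(t) {
    if (t == term) return(1)
    got <- get0(t, envir = memo, inherits = FALSE)
    if (!is.null(got)) return(got)
    kids <- intersect(dag$children[[t]], anc)
    val <- delta * max(vapply(kids, contrib, numeric(1)))
    assign(t, val, envir = memo)
    val
  }
  D <- vapply(anc, contrib, numeric(1))
  names(D) <- anc
  list(contributions = D, value = sum(D))
}

#' DAG-based disease semantic similarity
#'
#' Shared-ancestor similarity: the summed contributions of the terms in
#' the intersection of the two ancestor closures, from both sides, divided
#' by the total semantic values DV(d_i) + DV(d_j).
#'
#' @inheritParams semantic_value
#' @param term_i,term_j term ids.
#' @return similarity in \[0, 1\].
#' @export
semantic_similarity <- function(dag, term_i, term_j, delta = 0.5) {
  sv_i <- semantic_value(dag, term_i, delta)
  sv_j <- semantic_value(dag, term_j, delta)
  shared <- intersect(names(sv_i$contributions), names(sv_j$contributions))
  if (length(shared) == 0) return(0)
  sum(sv_i$contributions[shared] + sv_j$contributions[shared]) /
    (sv_i$value + sv_j$value)
}

#' Full disease semantic similarity kernel
#'
#' @inheritParams semantic_value
#' @param disease_ids disease ids (must be mapped by the DAG's term_map).
#' @return symmetric kernel matrix with unit diagonal.
#' @export
semantic_kernel <- function(dag, disease_ids, delta = 0.5) {
  terms <- dag$term_map[disease_ids]
  if (anyNA(terms)) {
    stop(sprintf("diseases without mapped DAG term: %s",
                 paste(utils::head(disease_ids[is.na(terms)], 5),
                       collapse = ", ")), call. = FALSE)
  }
  sv <- lapply(terms, function(t) semantic_value(dag, t, delta))
  n <- length(disease_ids)
  K <- diag(1, n)
  if (n >= 2) {
    for (i in 1:(n - 1)) {
      for (j in (i + 1):n) {
        shared <- intersect(names(sv[[i]]$contributions),
                            names(sv[[j]]$contributions))
        K[i, j] <- K[j, i] <- if (length(shared) == 0) 0 else
          sum(sv[[i]]$contributions[shared] + sv[[j]]$contributions[shared]) /
            (sv[[i]]$value + sv[[j]]$value)
      }
    }
  }
  dimnames(K) <- list(disease_ids, disease_ids)
  K
}

#' Full regulatory similarity kernel over a circRNA-miRNA matrix
#'
#' @param Y 0/1 circRNA x miRNA interaction matrix.
#' @inheritParams regulatory_similarity
#' @return symmetric kernel with unit diagonal for circRNAs with at least
#'   one miRNA partner (0 on the diagonal only for isolated circRNAs).
#' @export
regulatory_kernel <- function(Y, form = c("ochiai", "product")) {
  form <- match.arg(form)
  Y <- as.matrix(Y)
  inter <- tcrossprod(Y)                 # |Mi n Mj|
  deg <- rowSums(Y)
  denom <- if (form == "ochiai") sqrt(outer(deg, deg)) else outer(deg, deg)
  K <- ifelse(denom > 0, inter / denom, 0)
  dimnames(K) <- list(rownames(Y), rownames(Y))
  (K + t(K)) / 2
}

#' Full expression similarity kernel
#'
#' Pairwise clipped Pearson correlations of expression rows. circRNAs with
#' no (or constant) expression profile get zero rows/columns; coverage is
#' reported via a message.
#'
#' @param expr numeric matrix circRNAs x conditions (rownames are ids).
#' @param circ_ids circRNA ids the kernel must span (registry order).
#' @return symmetric kernel over \code{circ_ids}.
#' @export
expression_kernel <- function(expr, circ_ids = rownames(expr)) {
  n <- length(circ_ids)
  K <- matrix(0, n, n, dimnames = list(circ_ids, circ_ids))
  have <- intersect(circ_ids, rownames(expr))
  have <- have[apply(expr[have, , drop = FALSE], 1, stats::sd) > 0]
  if (length(have) < n) {
    message(sprintf("expression profiles cover %d of %d circRNAs",
                    length(have), n))
  }
  if (length(have) >= 2) {
    C <- stats::cor(t(expr[have, , drop = FALSE]), method = "pearson")
    C[C < 0] <- 0
    K[have, have] <- C
  }
  diag(K)[circ_ids %in% have] <- 1
  (K + t(K)) / 2
}

#' Assemble the per-side kernel stacks for fusion
#'
#' circRNA side: sequence, regulatory, expression and GIP kernels (those
#' whose inputs are available); disease side: semantic and GIP kernels
#' plus any precomputed kernels, in the given order. Each side needs at
#' least two kernels for cross-diffusion to be defined.
#'
#' @param network a [build_network()] result.
#' @param expression optional expression matrix (circRNAs x conditions).
#' @param sequences optional named character vector of circRNA sequences.
#' @param dag optional [disease_dag()].
#' @param precomputed optional named list of square disease kernels
#'   (ids matching the disease registry).
#' @param align_params alignment parameters, see [alignment_params()].
#' @return list with elements \code{circ} and \code{disease}, each a named
#'   list of kernel matrices.
#' @export
assemble_kernel_stacks <- function(network, expression = NULL,
                                   sequences = NULL, dag = NULL,
                                   precomputed = list(),
                                   align_params = alignment_params()) {
  circ_ids <- network$circ$ids
  dis_ids <- network$disease$ids
  circ <- list()
  if (!is.null(sequences)) {
    circ$SC_Seq <- sequence_kernel(sequences, circ_ids, align_params)
  } else message("no sequences: skipping sequence kernel")
  circ$SC_RG <- regulatory_kernel(network$Y)
  if (!is.null(expression)) {
    circ$SC_EP <- expression_kernel(expression, circ_ids)
  } else message("no expression matrix: skipping expression kernel")
  circ$SC_GIP <- gip_kernel(network$Y)
  attr(circ$SC_GIP, "gamma") <- NULL

  disease <- list()
  if (!is.null(dag)) {
    disease$SD_Dss <- semantic_kernel(dag, dis_ids)
  } else message("no DAG: skipping semantic kernel")
  disease$SD_GIP <- gip_kernel(network$O)
  attr(disease$SD_GIP, "gamma") <- NULL
  for (nm in names(precomputed)) {
    K <- precomputed[[nm]]
    if (!identical(rownames(K), dis_ids)) {
      K <- K[dis_ids, dis_ids]
    }
    disease[[nm]] <- K
  }
  if (length(circ) < 2 || length(disease) < 2) {
    stop(sprintf(
      "need at least 2 kernels per side for fusion (have %d circRNA, %d disease)",
      length(circ), length(disease)), call. = FALSE)
  }
  list(circ = circ, disease = disease)
}
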