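#' Specification of a planted-block synthetic study
#'
#' The generator emulates the structure of curated circRNA-disease
#' resources with a planted community model: circRNAs and diseases are
#' grouped into blocks; within-block pairs associate with high
#' probability, other pairs with low background probability; same-block
#' entities share miRNA neighbourhoods, expression programmes, sequence
#' consensus and DAG parents, so every similarity kernel carries the same
#' recoverable signal.
#'
#' @param nc,nd,nm entity counts (circRNAs, diseases, miRNAs).
#' @param n_blocks planted community count.
#' @param within_block_assoc_prob,background_assoc_prob association
#'   probabilities inside / outside blocks.
#' @param mirna_within_prob,mirna_background_prob interaction
#'   probabilities for the miRNA bipartite matrices.
#' @param kernel_noise_sd Gaussian noise added to precomputed disease
#'   kernels.
#' @param n_conditions expression profile length.
#' @param seq_length,mutation_rate consensus sequence length and per-base
#'   mutation probability.
#' @param n_precomputed number of precomputed disease kernels to emit.
#' @param seed RNG seed; every output is reproducible from it.
#' @return list of class \code{synthetic_spec}.
#' @export
synthetic_spec <- function(nc = 40, nd = 15, nm = 60, n_blocks = 3,
                           within_block_assoc_prob = 0.6,
                           background_assoc_prob = 0.02,
                           mirna_within_prob = 0.5,
                           mirna_background_prob = 0.05,
                           kernel_noise_sd = 0.05,
                           n_conditions = 30,
                           seq_length = 120, mutation_rate = 0.1,
                           n_precomputed = 5, seed = 7) {
  stopifnot(background_assoc_prob >= 0,
            background_assoc_prob < within_block_assoc_prob,
            within_block_assoc_prob <= 1,
            nc >= n_blocks, nd >= n_blocks, nm >= n_blocks)
  structure(as.list(environment()), class = "synthetic_spec")
}

block_assign <- function(n, n_blocks) {
  sort(rep_len(seq_len(n_blocks), n))
}

#' Generate a complete synthetic study
#'
#' @param spec a [synthetic_spec()].
#' @return list with \code{network} (a \code{bipartite_network}),
#'   \code{expression} (matrix), \code{sequences} (named character),
#'   \code{dag} (a \code{disease_dag}), \code{precomputed} (named list of
#'   disease kernels), and the block assignments \code{circ_block},
#'   \code{disease_block}.
#' @export
generate_study <- function(spec = synthetic_spec()) {
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(spec$seed)
  pad <- function(prefix, n) sprintf("%s%0*d", prefix,
                                     nchar(as.character(n)), seq_len(n))
  circ_ids <- pad("circ", spec$nc)
  dis_ids <- pad("dis", spec$nd)
  mir_ids <- pad("mir", spec$nm)
  cb <- block_assign(spec$nc, spec$n_blocks)
  db <- block_assign(spec$nd, spec$n_blocks)
  mb <- block_assign(spec$nm, spec$n_blocks)
  names(cb) <- circ_ids; names(db) <- dis_ids; names(mb) <- mir_ids

  bern <- function(p_mat) matrix(stats::rbinom(length(p_mat), 1, p_mat),
                                 nrow(p_mat), ncol(p_mat))
  same <- function(a, b) outer(a, b, `==`)
  pA <- ifelse(same(cb, db), spec$within_block_assoc_prob,
               spec$background_assoc_prob)
  pY <- ifelse(same(cb, mb), spec$mirna_within_prob,
               spec$mirna_background_prob)
  pO <- ifelse(same(db, mb), spec$mirna_within_prob,
               spec$mirna_background_prob)
  A <- bern(pA); dimnames(A) <- list(circ_ids, dis_ids)
  Y <- bern(pY); dimnames(Y) <- list(circ_ids, mir_ids)
  O <- bern(pO); dimnames(O) <- list(dis_ids, mir_ids)
  # make sure GIP bandwidths are defined and fusion is non-degenerate
  for (i in which(rowSums(Y) == 0)) Y[i, sample.int(spec$nm, 1)] <- 1L
  for (i in which(rowSums(O) == 0)) O[i, sample.int(spec$nm, 1)] <- 1L

  edges_of <- function(M, rows, cols) {
    w <- which(M == 1, arr.ind = TRUE)
    data.frame(id_a = rows[w[, 1]], id_b = cols[w[, 2]],
               stringsAsFactors = FALSE)
  }
  network <- build_network(edges_of(A, circ_ids, dis_ids),
                           edges_of(Y, circ_ids, mir_ids),
                           edges_of(O, dis_ids, mir_ids))

  centroids <- matrix(stats::rnorm(spec$n_blocks * spec$n_conditions, sd = 2),
                      spec$n_blocks, spec$n_conditions)
  expression <- centroids[cb, , drop = FALSE] +
    matrix(stats::rnorm(spec$nc * spec$n_conditions, sd = 1),
           spec$nc, spec$n_conditions)
  dimnames(expression) <- list(circ_ids,
                               sprintf("cond%02d", seq_len(spec$n_conditions)))

  bases <- c("A", "C", "G", "T")
  consensus <- replicate(spec$n_blocks,
                         paste(sample(bases, spec$seq_length, TRUE),
                               collapse = ""))
  sequences <- vapply(seq_len(spec$nc), function(i) {
    s <- strsplit(consensus[cb[i]], "")[[1]]
    mut <- stats::runif(spec$seq_length) < spec$mutation_rate
    s[mut] <- sample(bases, sum(mut), TRUE)
    paste(s, collapse = "")
  }, character(1))
  names(sequences) <- circ_ids

  # DAG: one root, one internal parent term per block, diseases as leaves
  parents <- sprintf("block%d", seq_len(spec$n_blocks))
  dag_edges <- rbind(
    data.frame(parent = "root", child = parents, stringsAsFactors = FALSE),
    data.frame(parent = parents[db], child = dis_ids, stringsAsFactors = FALSE))
  dag <- disease_dag(dag_edges)

  precomputed <- list()
  if (spec$n_precomputed > 0) {
    base <- ifelse(same(db, db), 0.8, 0.2)
    for (k in seq_len(spec$n_precomputed)) {
      Kk <- base + matrix(stats::rnorm(spec$nd^2, sd = spec$kernel_noise_sd),
                          spec$nd, spec$nd)
      Kk <- (Kk + t(Kk)) / 2
      Kk[Kk < 0] <- 0; Kk[Kk > 1] <- 1
      diag(Kk) <- 1
      dimnames(Kk) <- list(dis_ids, dis_ids)
      precomputed[[sprintf("SD_pre%d", k)]] <- Kk
    }
  }
  list(network = network, expression = expression, sequences = sequences,
       dag = dag, precomputed = precomputed,
       circ_block = cb, disease_block = db, mirna_block = mb, spec = spec)
}

#' Generate random valid similarity kernels (fusion-stage test input)
#'
#' Symmetric matrices with entries in \[0, 1\], unit diagonal and strictly
#' positive off-diagonal mass in every row.
#'
#' @param n matrix size (>= 2).
#' @param K number of kernels (>= 2).
#' @param seed RNG seed.
#' @return list of K matrices.
#' @export
generate_random_kernels <- function(n, K, seed) {
  stopifnot(n >= 2, K >= 2)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  lapply(seq_len(K), function(k) {
    M <- matrix(stats::runif(n * n, min = 0.01, max = 1), n, n)
    M <- (M + t(M)) / 2
    diag(M) <- 1
    M
  })
}

#' Write a synthetic study to disk in the pipeline's file formats
#'
#' Emits TSV edge lists for the three association networks and the DAG, a
#' FASTA file of sequences, a TSV expression matrix, and one TSV per
#' precomputed disease kernel.
#'
#' @param study a [generate_study()] result.
#' @param dir output directory (created if missing).
#' @return invisibly, the named vector of written paths.
#' @export
write_study <- function(study, dir) {
  dir.create(dir, showWarnings = FALSE, recursive = TRUE)
  nw <- study$network
  write_edges <- function(M, path) {
    w <- which(M == 1, arr.ind = TRUE)
    df <- data.frame(rownames(M)[w[, 1]], colnames(M)[w[, 2]])
    df <- df[order(df[[1]], df[[2]], method = "radix"), ]
    utils::write.table(df, path, sep = "\t", quote = FALSE,
                       row.names = FALSE, col.names = FALSE)
    path
  }
  paths <- c(
    cd = write_edges(nw$A, file.path(dir, "circ_disease.tsv")),
    cm = write_edges(nw$Y, file.path(dir, "circ_mirna.tsv")),
    dm = write_edges(nw$O, file.path(dir, "disease_mirna.tsv")))
  dag_path <- file.path(dir, "disease_dag.tsv")
  dag_df <- do.call(rbind, lapply(names(study$dag$children), function(p) {
    data.frame(p, study$dag$children[[p]])
  }))
  utils::write.table(dag_df, dag_path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = FALSE)
  paths["dag"] <- dag_path
  fa <- file.path(dir, "sequences.fasta")
  writeLines(paste0(">", names(study$sequences), "\n", study$sequences), fa)
  paths["fasta"] <- fa
  expr_path <- file.path(dir, "expression.tsv")
  df <- data.frame(id = rownames(study$expression), study$expression,
                   check.names = FALSE)
  utils::write.table(df, expr_path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  paths["expression"] <- expr_path
  for (nm in names(study$precomputed)) {
    p <- file.path(dir, paste0(nm, ".tsv"))
    write_kernel_matrix(study$precomputed[[nm]], p)
    paths[nm] <- p
  }
  invisible(paths)
}
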