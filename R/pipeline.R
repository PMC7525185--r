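#' @keywords internal
#' @useDynLib skfcnn, .registration = TRUE
#' @importFrom Rcpp evalCpp
"_PACKAGE"

#' Prepare fused kernels and the miRNA projector for a study
#'
#' Runs the kernel-construction and fusion stages end to end: assembles
#' the per-side kernel stacks, cross-diffuses each side into one fused
#' kernel, and fits the PCA projector on the stacked miRNA profiles.
#'
#' @param study a [generate_study()] result, or any list with the same
#'   elements (\code{network}, optional \code{expression},
#'   \code{sequences}, \code{dag}, \code{precomputed}).
#' @param skf an [skf_config()]; the neighbourhood size is clamped per
#'   side to n - 1.
#' @param np PCA components for the miRNA blocks; default
#'   \code{min(50, nc + nd, nm)}.
#' @return list with \code{Sc}, \code{Sd} (fused kernels), \code{circ_fusion},
#'   \code{disease_fusion} (full \code{fused_kernel} objects),
#'   \code{projector}, \code{network}.
#' @export
prepare_study <- function(study, skf = skf_config(), np = NULL) {
  nw <- study$network
  stacks <- assemble_kernel_stacks(
    nw,
    expression = study$expression,
    sequences = study$sequences,
    dag = study$dag,
    precomputed = if (is.null(study$precomputed)) list() else study$precomputed)
  clamp <- function(cfg, n) {
    cfg$neighbor_count <- as.integer(min(cfg$neighbor_count, n - 1L))
    cfg
  }
  circ_fusion <- fuse_kernels(stacks$circ, clamp(skf, nrow(nw$A)))
  disease_fusion <- fuse_kernels(stacks$disease, clamp(skf, ncol(nw$A)))
  if (is.null(np)) np <- min(50L, nrow(nw$A) + ncol(nw$A), ncol(nw$Y))
  projector <- fit_mirna_projector(nw$Y, nw$O, np = np)
  list(Sc = circ_fusion$S, Sd = disease_fusion$S,
       circ_fusion = circ_fusion, disease_fusion = disease_fusion,
       projector = projector, network = nw)
}

#' Cross-validate a prepared study
#'
#' Convenience wrapper around [cross_validate()] taking the output of
#' [prepare_study()].
#'
#' @param prep a [prepare_study()] result.
#' @inheritParams cross_validate
#' @return a \code{cv_report}.
#' @export
cross_validate_study <- function(prep, config = cnn_config(), folds = 5,
                                 repetitions = 10, seed = 1,
                                 shuffle_labels = FALSE) {
  cross_validate(prep$network, prep$Sc, prep$Sd, prep$projector,
                 config = config, folds = folds, repetitions = repetitions,
                 seed = seed, shuffle_labels = shuffle_labels)
}

#' Score and rank all unobserved pairs of a prepared study
#'
#' Trains \code{n_models} classifiers on the full positive set plus
#' independently re-sampled negative sets, scores every unobserved
#' circRNA-disease pair with each model, and ranks the averaged scores.
#'
#' @param prep a [prepare_study()] result.
#' @param config a [cnn_config()].
#' @param n_models number of models whose scores are averaged
#'   (default 10, one per negative sample).
#' @param seed master seed.
#' @param per_disease add a within-disease rank column.
#' @return ranked candidate data.frame, see [rank_candidates()].
#' @export
predict_novel <- function(prep, config = cnn_config(), n_models = 10,
                          seed = 1, per_disease = FALSE) {
  A <- prep$network$A
  pos <- which(A == 1, arr.ind = TRUE)
  positives <- data.frame(circ = rownames(A)[pos[, 1]],
                          disease = colnames(A)[pos[, 2]],
                          label = 1L, stringsAsFactors = FALSE)
  models <- lapply(seq_len(n_models), function(k) {
    negatives <- sample_negatives(A, nrow(positives), seed = seed + 7000L * k)
    dataset <- build_dataset(rbind(positives, negatives), prep$Sc, prep$Sd,
                             prep$network, prep$projector, mask_label = TRUE)
    cfg <- config
    cfg$seed <- as.integer(seed + 7000L * k + 1L)
    train_cnn(dataset, cfg)
  })
  unk <- which(A == 0, arr.ind = TRUE)
  candidates <- data.frame(circ = rownames(A)[unk[, 1]],
                           disease = colnames(A)[unk[, 2]],
                           label = NA_integer_, stringsAsFactors = FALSE)
  cand_ds <- build_dataset(candidates, prep$Sc, prep$Sd, prep$network,
                           prep$projector, mask_label = TRUE)
  rank_candidates(models, cand_ds, per_disease = per_disease)
}
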