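#' Fit the PCA projector for miRNA interaction profiles
#'
#' The miRNA blocks of the pair feature matrix are too sparse and too wide
#' to use raw, so interaction profiles are compressed to their first
#' \code{np} principal-component scores. The PCA is fitted once on the
#' row-stack of the circRNA-miRNA matrix Y and the disease-miRNA matrix O
#' (mean-centred, not whitened); no association labels enter the fit, so
#' the projector is shared across folds.
#'
#' @param Y 0/1 circRNA x miRNA matrix.
#' @param O 0/1 disease x miRNA matrix (same miRNA axis).
#' @param np number of components to keep (default 50).
#' @return object of class \code{mirna_projector}: list with
#'   \code{rotation} (nm x np, orthonormal columns), \code{center} (nm),
#'   \code{np}, \code{sdev}.
#' @export
fit_mirna_projector <- function(Y, O, np = 50) {
  stopifnot(ncol(Y) == ncol(O))
  stacked <- rbind(Y, O)
  if (np > min(nrow(stacked), ncol(stacked))) {
    stop(sprintf("np = %d exceeds min(nc + nd, nm) = %d", np,
                 min(nrow(stacked), ncol(stacked))), call. = FALSE)
  }
  pc <- stats::prcomp(stacked, center = TRUE, scale. = FALSE)
  if (ncol(pc$rotation) < np || pc$sdev[np] < 1e-12) {
    stop(sprintf(
      "interaction profiles have rank < %d; choose a smaller np", np),
      call. = FALSE)
  }
  structure(list(rotation = pc$rotation[, seq_len(np), drop = FALSE],
                 center = pc$center, np = as.integer(np),
                 sdev = pc$sdev[seq_len(np)]),
            class = "mirna_projector")
}

#' Project an miRNA interaction profile to PCA scores
#'
#' @param projector a [fit_mirna_projector()].
#' @param profile numeric vector of length nm (or a matrix of rows).
#' @return numeric vector (or matrix) of np scores per profile.
#' @export
project_profile <- function(projector, profile) {
  p <- if (is.matrix(profile)) profile else matrix(profile, nrow = 1)
  scores <- sweep(p, 2, projector$center) %*% projector$rotation
  if (is.matrix(profile)) scores else drop(scores)
}

#' Build the two-row feature matrix for one circRNA-disease pair
#'
#' Three blocks side by side, each contributing the same two rows:
#' over circRNAs (width nc) the fused circRNA-similarity row of c_i on
#' top of disease d_j's circRNA association column; over diseases (width
#' nd) circRNA c_i's disease association row on top of the fused
#' disease-similarity row of d_j; over miRNA components (width np) the
#' PCA scores of c_i's and d_j's miRNA interaction profiles. With
#' \code{mask_label = TRUE} (the default for training features) the
#' pair's own cell A\[i,j\] is zeroed in both association rows before
#' assembly, so the input cannot leak the label it is meant to predict.
#'
#' @param circ_id,disease_id entity ids.
#' @param Sc,Sd fused circRNA / disease similarity matrices.
#' @param network a [build_network()] result (supplies A, Y, O).
#' @param projector a [fit_mirna_projector()].
#' @param mask_label zero out A\[i,j\] in the feature (default TRUE).
#' @return numeric matrix 2 x (nc + nd + np) with attribute
#'   \code{"blocks"} = c(nc, nd, np).
#' @export
build_pair_feature <- function(circ_id, disease_id, Sc, Sd, network,
                               projector, mask_label = TRUE) {
  i <- registry_lookup(network$circ, circ_id)
  j <- registry_lookup(network$disease, disease_id)
  A <- network$A
  a_col <- A[, j]            # associations of d_j with all circRNAs
  a_row <- A[i, ]            # associations of c_i with all diseases
  if (mask_label) {
    a_col[i] <- 0
    a_row[j] <- 0
  }
  block_c <- rbind(Sc[i, ], a_col)
  block_d <- rbind(a_row, Sd[j, ])
  block_m <- rbind(project_profile(projector, network$Y[i, ]),
                   project_profile(projector, network$O[j, ]))
  X <- cbind(block_c, block_d, block_m)
  dimnames(X) <- NULL
  attr(X, "blocks") <- c(nc = ncol(block_c), nd = ncol(block_d),
                         np = ncol(block_m))
  X
}

#' Build a feature dataset for a list of pairs
#'
#' @param pairs data.frame with columns \code{circ}, \code{disease} and
#'   optionally \code{label} (0/1; absent or NA means unknown).
#' @inheritParams build_pair_feature
#' @return object of class \code{pair_dataset}: list with \code{X}
#'   (array n x 2 x width), \code{pairs} (the input data.frame),
#'   \code{blocks}, \code{mask_label}.
#' @export
build_dataset <- function(pairs, Sc, Sd, network, projector,
                          mask_label = TRUE) {
  stopifnot(all(c("circ", "disease") %in% names(pairs)))
  key <- paste(pairs$circ, pairs$disease, sep = "\r")
  if (anyDuplicated(key)) {
    stop("duplicate circRNA-disease pair in dataset", call. = FALSE)
  }
  if (is.null(pairs$label)) pairs$label <- NA_integer_
  n <- nrow(pairs)
  width <- nrow(network$A) + ncol(network$A) + projector$np
  X <- array(NA_real_, dim = c(n, 2, width))
  blocks <- NULL
  for (s in seq_len(n)) {
    f <- build_pair_feature(pairs$circ[s], pairs$disease[s], Sc, Sd,
                            network, projector, mask_label)
    X[s, , ] <- f
    if (is.null(blocks)) blocks <- attr(f, "blocks")
  }
  structure(list(X = X, pairs = pairs, blocks = blocks,
                 mask_label = mask_label),
            class = "pair_dataset")
}

#' @export
print.pair_dataset <- function(x, ...) {
  cat(sprintf("<pair_dataset: %d pairs x 2 x %d (%d pos / %d neg / %d unknown)>\n",
              dim(x$X)[1], dim(x$X)[3],
              sum(x$pairs$label %in% 1), sum(x$pairs$label %in% 0),
              sum(is.na(x$pairs$label))))
  invisible(x)
}
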