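#' Cross-diffusion fusion configuration
#'
#' @param alpha diffusion weight in (0, 1); the complementary weight
#'   anchors every iterate to the mean of the initial kernels. Default 0.1.
#' @param neighbor_count neighbourhood size for the sparse diffusion
#'   operator and the mutual-neighbour mask (clamped to n-1 per matrix).
#'   Default 36.
#' @param iterations number of cross-diffusion steps. Default 10.
#' @return list of class \code{skf_config}.
#' @export
skf_config <- function(alpha = 0.1, neighbor_count = 36, iterations = 10) {
  stopifnot(alpha > 0, alpha < 1, neighbor_count >= 1, iterations >= 1)
  structure(list(alpha = alpha, neighbor_count = as.integer(neighbor_count),
                 iterations = as.integer(iterations)),
            class = "skf_config")
}

#' Column-normalize a similarity kernel
#'
#' NS\[i,j\] = S\[i,j\] / sum_k S\[k,j\]; every column of the result sums
#' to 1.
#'
#' @param S nonnegative square matrix.
#' @return column-stochastic matrix.
#' @export
normalize_kernel <- function(S) {
  cs <- colSums(S)
  if (any(cs == 0)) {
    bad <- colnames(S)[cs == 0]
    if (is.null(bad)) bad <- which(cs == 0)
    stop(sprintf("degenerate kernel: all-zero column for %s",
                 paste(utils::head(bad, 5), collapse = ", ")), call. = FALSE)
  }
  sweep(S, 2, cs, "/")
}

top_neighbors <- function(S, neighbor_count) {
  # per row: the neighbor_count highest-similarity entities plus the row
  # entity itself; ties broken by index order (lexicographic registry order)
  n <- nrow(S)
  k <- min(neighbor_count, n - 1L)
  lapply(seq_len(n), function(i) {
    ord <- order(-S[i, ], seq_len(n))     # score desc, index asc
    ord <- setdiff(ord, i)
    sort(c(i, ord[seq_len(k)]))
  })
}

#' Row-normalized top-k sparse kernel
#'
#' F\[i,j\] = S\[i,j\] / sum over i's neighbourhood for j in the
#' neighbourhood (the top-k most similar entities plus i itself), else 0;
#' rows sum to 1. This is the diffusion operator of the fusion iteration.
#'
#' @param S nonnegative square matrix.
#' @param neighbor_count neighbourhood size (self excluded from the count).
#' @return row-stochastic sparse kernel with attribute
#'   \code{"neighbors"} (list of neighbourhood index vectors).
#' @export
sparse_kernel <- function(S, neighbor_count) {
  n <- nrow(S)
  nb <- top_neighbors(S, neighbor_count)
  F_ <- matrix(0, n, n, dimnames = dimnames(S))
  for (i in seq_len(n)) {
    mass <- sum(S[i, nb[[i]]])
    if (mass == 0) {
      stop(sprintf("degenerate row %d: zero mass over its neighbourhood", i),
           call. = FALSE)
    }
    F_[i, nb[[i]]] <- S[i, nb[[i]]] / mass
  }
  attr(F_, "neighbors") <- nb
  F_
}

#' Cross-diffusion iteration over a kernel stack
#'
#' Starting from the column-normalized kernels, each kernel's status
#' matrix is repeatedly diffused through its own sparse operator applied
#' to the mean of the other kernels' current statuses, anchored to the
#' mean of the other kernels' initial statuses:
#' S_m(t+1) = alpha * F_m \%*\% mean_\{r != m\}(S_r(t)) \%*\% t(F_m) +
#' (1 - alpha) * mean_\{r != m\}(S_r(0)).
#' The per-kernel relative Frobenius change is recorded at every step.
#'
#' @param kernels list of >= 2 nonnegative square matrices (same shape).
#' @param config an [skf_config()].
#' @return list with \code{status} (final status matrices), \code{trace}
#'   (iterations x kernels matrix of relative errors) and \code{sparse}
#'   (the diffusion operators).
#' @export
skf_iterate <- function(kernels, config = skf_config()) {
  K <- length(kernels)
  stopifnot(K >= 2)
  dims <- vapply(kernels, dim, integer(2))
  if (any(dims != dims[, 1])) stop("kernels must share one shape", call. = FALSE)
  NS <- lapply(kernels, normalize_kernel)
  F_ <- lapply(kernels, sparse_kernel, neighbor_count = config$neighbor_count)
  mean_other <- function(mats, m) Reduce(`+`, mats[-m]) / (K - 1)
  anchors <- lapply(seq_len(K), function(m) (1 - config$alpha) * mean_other(NS, m))
  status <- NS
  trace <- matrix(NA_real_, nrow = config$iterations, ncol = K,
                  dimnames = list(NULL, names(kernels)))
  for (t in seq_len(config$iterations)) {
    nxt <- lapply(seq_len(K), function(m) {
      config$alpha * (F_[[m]] %*% mean_other(status, m) %*% t(F_[[m]])) +
        anchors[[m]]
    })
    for (m in seq_len(K)) {
      if (!all(is.finite(nxt[[m]]))) {
        stop(sprintf("non-finite values in kernel %d at iteration %d", m, t),
             call. = FALSE)
      }
      trace[t, m] <- norm(nxt[[m]] - status[[m]], "F") / norm(status[[m]], "F")
    }
    status <- nxt
  }
  names(status) <- names(kernels)
  list(status = status, trace = trace, sparse = F_)
}

#' Combine diffused status matrices into the fused kernel
#'
#' Averages the status matrices, masks the average with the
#' mutual-neighbour weight matrix w (1 where each entity is in the other's
#' top-k neighbourhood, 0 where neither is, 0.5 otherwise; neighbourhoods
#' derived from the averaged matrix and including self), and symmetrizes.
#'
#' @param status list of status matrices (from [skf_iterate()]).
#' @param neighbor_count neighbourhood size for the mask.
#' @return list with the fused kernel \code{S} and the weight matrix
#'   \code{w}.
#' @export
skf_fuse <- function(status, neighbor_count) {
  S <- Reduce(`+`, status) / length(status)
  nb <- top_neighbors(S, neighbor_count)
  n <- nrow(S)
  in_nb <- matrix(FALSE, n, n)                  # in_nb[i,j]: j in N_i
  for (i in seq_len(n)) in_nb[i, nb[[i]]] <- TRUE
  w <- (in_nb & t(in_nb)) * 1 + (xor(in_nb, t(in_nb))) * 0.5
  Sw <- w * S
  Sfused <- (Sw + t(Sw)) / 2
  dimnames(Sfused) <- dimnames(S)
  list(S = Sfused, w = w)
}

#' Fuse a kernel stack by cross-diffusion
#'
#' One-call wrapper: iterate then combine. Returns the fused kernel with
#' the iteration trace and weight mask attached.
#'
#' @inheritParams skf_iterate
#' @return object of class \code{fused_kernel}: list with \code{S},
#'   \code{w}, \code{trace}, \code{config}.
#' @export
fuse_kernels <- function(kernels, config = skf_config()) {
  it <- skf_iterate(kernels, config)
  fz <- skf_fuse(it$status, config$neighbor_count)
  structure(list(S = fz$S, w = fz$w, trace = it$trace, config = config),
            class = "fused_kernel")
}

#' @export
print.fused_kernel <- function(x, ...) {
  cat(sprintf("<fused_kernel: %d x %d; final relative error %.3g>\n",
              nrow(x$S), ncol(x$S), max(x$trace[nrow(x$trace), ])))
  invisible(x)
}

#' Element-wise average fusion baseline
#'
#' @param kernels list of same-shape matrices.
#' @return their element-wise mean.
#' @export
average_fusion <- function(kernels) Reduce(`+`, kernels) / length(kernels)
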