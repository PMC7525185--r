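#' Configuration of the two-layer convolutional classifier
#'
#' The classifier sees each pair as a 2 x width image: a first valid
#' convolution with \code{n_filters} kernels of size \code{kernel1}
#' (spanning both rows by default), a second valid convolution of size
#' \code{kernel2} along the length axis, global max pooling per filter
#' map, dropout, and a two-unit softmax head trained with cross-entropy.
#'
#' @param n_filters filters per convolutional layer (default 8).
#' @param kernel1 first-layer kernel (rows, length); default c(2, 32).
#' @param kernel2 second-layer kernel (rows, length); default c(1, 16).
#' @param dropout drop probability on the pooled vector during training.
#' @param learning_rate,epochs,batch_size Adam training hyperparameters.
#' @param seed RNG seed for weight initialization, shuffling and dropout.
#' @return list of class \code{cnn_config}.
#' @export
cnn_config <- function(n_filters = 8, kernel1 = c(2, 32), kernel2 = c(1, 16),
                       dropout = 0.5, learning_rate = 1e-3, epochs = 50,
                       batch_size = 32, seed = 42) {
  stopifnot(kernel1[1] %in% 1:2, kernel2[1] == 1,
            dropout >= 0, dropout < 1, n_filters >= 1)
  structure(list(n_filters = as.integer(n_filters),
                 kernel1 = as.integer(kernel1), kernel2 = as.integer(kernel2),
                 dropout = dropout, learning_rate = learning_rate,
                 epochs = as.integer(epochs),
                 batch_size = as.integer(batch_size), seed = as.integer(seed)),
            class = "cnn_config")
}

#' Layer output shapes for a given feature width
#'
#' Valid (no padding, stride 1) convolution shape algebra: the first layer
#' maps 2 x W to (2 - n_w + 1) x (W - n_l + 1) per filter; the second
#' slides along the length axis only; pooling leaves one value per filter.
#'
#' @param width feature matrix width (nc + nd + np).
#' @param config a [cnn_config()].
#' @return list with \code{conv1}, \code{conv2} (rows, cols, filters) and
#'   \code{pooled} (length of the pooled vector).
#' @export
cnn_shapes <- function(width, config = cnn_config()) {
  r1 <- 2L - config$kernel1[1] + 1L
  l1 <- width - config$kernel1[2] + 1L
  l2 <- l1 - config$kernel2[2] + 1L
  if (l2 < 1) {
    stop(sprintf("feature width %d too small for kernels %d + %d", width,
                 config$kernel1[2], config$kernel2[2]), call. = FALSE)
  }
  list(conv1 = c(rows = r1, cols = l1, filters = config$n_filters),
       conv2 = c(rows = r1, cols = l2, filters = config$n_filters),
       pooled = config$n_filters)
}

#' Build an untrained classifier
#'
#' He-initialized weights drawn with the config seed.
#'
#' @inheritParams cnn_shapes
#' @return list of class \code{cnn_model} with weight matrices
#'   \code{W1, b1, W2, b2, Wd, bd}, the config, width and shapes.
#' @export
build_cnn <- function(config = cnn_config(), width) {
  shapes <- cnn_shapes(width, config)
  f <- config$n_filters
  p1 <- config$kernel1[1] * config$kernel1[2]
  p2 <- config$kernel2[2] * f
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed)
  model <- list(
    W1 = matrix(stats::rnorm(p1 * f, sd = sqrt(2 / p1)), p1, f),
    b1 = numeric(f),
    W2 = matrix(stats::rnorm(p2 * f, sd = sqrt(2 / p2)), p2, f),
    b2 = numeric(f),
    Wd = matrix(stats::rnorm(f * 2, sd = sqrt(2 / f)), f, 2),
    bd = numeric(2),
    config = config, width = as.integer(width), shapes = shapes
  )
  class(model) <- "cnn_model"
  model
}

.Random.seed_save <- function() {
  if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
    get(".Random.seed", envir = globalenv()) else NULL
}
.Random.seed_restore <- function(old) {
  if (!is.null(old)) assign(".Random.seed", old, envir = globalenv())
}

# im2col for the first layer: X is B x 2 x W, returns (B*R1*L1) x (n_w*n_l)
# with rows ordered sample-slowest, patch-row, then column position.
im2col1 <- function(X, n_w, n_l) {
  B <- dim(X)[1]; W <- dim(X)[3]
  R1 <- 2L - n_w + 1L; L1 <- W - n_l + 1L
  P <- matrix(0, B * R1 * L1, n_w * n_l)
  for (i in seq_len(R1)) {
    rows <- as.vector(outer(seq_len(L1), (seq_len(B) - 1) * R1 * L1 + (i - 1) * L1, `+`))
    # rows above are ordered j fastest within each sample block
    for (r in seq_len(n_w)) {
      slab <- X[, i + r - 1, , drop = FALSE]   # B x 1 x W
      for (o in seq_len(n_l)) {
        P[rows, (r - 1) * n_l + o] <- as.vector(t(slab[, 1, o:(o + L1 - 1)]))
      }
    }
  }
  P
}

cnn_forward <- function(model, X, dropout_mask = NULL) {
  cfg <- model$config
  B <- dim(X)[1]
  n_w <- cfg$kernel1[1]; n_l1 <- cfg$kernel1[2]; n_l2 <- cfg$kernel2[2]
  f <- cfg$n_filters
  R1 <- 2L - n_w + 1L
  L1 <- model$width - n_l1 + 1L
  L2 <- L1 - n_l2 + 1L
  SI <- B * R1
  P1 <- im2col1(X, n_w, n_l1)
  Z1 <- sweep(P1 %*% model$W1, 2, model$b1, `+`)
  A1 <- pmax(Z1, 0)
  # second-layer im2col over the length axis, channels side by side
  bases1 <- (seq_len(SI) - 1L) * L1
  P2 <- matrix(0, SI * L2, n_l2 * f)
  idx <- vector("list", n_l2)
  for (o in seq_len(n_l2)) {
    idx[[o]] <- rep(bases1, each = L2) + rep(seq_len(L2) + o - 1L, times = SI)
    P2[, ((o - 1L) * f + 1L):(o * f)] <- A1[idx[[o]], , drop = FALSE]
  }
  Z2 <- sweep(P2 %*% model$W2, 2, model$b2, `+`)
  A2 <- pmax(Z2, 0)
  # global max pool per sample and filter (positions R1*L2 per sample)
  G <- R1 * L2
  pooled <- matrix(0, B, f)
  argmax <- matrix(0L, B, f)
  for (ch in seq_len(f)) {
    M <- matrix(A2[, ch], nrow = G)          # columns are samples
    argmax[, ch] <- max.col(t(M), ties.method = "first")
    pooled[, ch] <- M[cbind(argmax[, ch], seq_len(B))]
  }
  pooled_d <- pooled
  if (!is.null(dropout_mask)) {
    pooled_d <- pooled * dropout_mask / (1 - cfg$dropout)
  }
  logits <- sweep(pooled_d %*% model$Wd, 2, model$bd, `+`)
  mx <- apply(logits, 1, max)
  ex <- exp(logits - mx)
  probs <- ex / rowSums(ex)
  list(P1 = P1, Z1 = Z1, A1 = A1, P2 = P2, Z2 = Z2, A2 = A2,
       pooled = pooled, pooled_d = pooled_d, argmax = argmax,
       probs = probs, idx2 = idx, dims = list(B = B, R1 = R1, L1 = L1,
                                              L2 = L2, SI = SI, G = G, f = f))
}

cnn_backward <- function(model, fw, y, dropout_mask = NULL) {
  cfg <- model$config
  d <- fw$dims
  onehot <- cbind(1 - y, y)
  dimnames(onehot) <- NULL
  dlogits <- (fw$probs - onehot) / d$B
  dWd <- crossprod(fw$pooled_d, dlogits)
  dbd <- colSums(dlogits)
  dpooled <- dlogits %*% t(model$Wd)
  if (!is.null(dropout_mask)) {
    dpooled <- dpooled * dropout_mask / (1 - cfg$dropout)
  }
  dA2 <- matrix(0, d$SI * d$L2, d$f)
  for (ch in seq_len(d$f)) {
    rows <- (seq_len(d$B) - 1L) * d$G + fw$argmax[, ch]
    dA2[cbind(rows, ch)] <- dpooled[, ch]
  }
  dZ2 <- dA2 * (fw$Z2 > 0)
  dW2 <- crossprod(fw$P2, dZ2)
  db2 <- colSums(dZ2)
  dP2 <- tcrossprod(dZ2, model$W2)
  dA1 <- matrix(0, nrow(fw$A1), d$f)
  n_l2 <- cfg$kernel2[2]
  for (o in seq_len(n_l2)) {
    cols <- ((o - 1L) * d$f + 1L):(o * d$f)
    add <- dP2[, cols, drop = FALSE]
    ix <- fw$idx2[[o]]
    dA1[ix, ] <- dA1[ix, , drop = FALSE] + add
  }
  dZ1 <- dA1 * (fw$Z1 > 0)
  dW1 <- crossprod(fw$P1, dZ1)
  db1 <- colSums(dZ1)
  list(W1 = dW1, b1 = db1, W2 = dW2, b2 = db2, Wd = dWd, bd = dbd)
}

cross_entropy <- function(probs, y) {
  p <- probs[cbind(seq_along(y), y + 1L)]
  -mean(log(pmax(p, 1e-12)))
}

#' Train the classifier
#'
#' Mini-batch Adam on softmax cross-entropy; dropout is active only
#' during training, and all randomness (initial weights, shuffling,
#' dropout masks) is driven by the config seed, so two runs with the same
#' seed produce identical models.
#'
#' @param dataset a [build_dataset()] with labels 0/1 (no unknowns).
#' @param config a [cnn_config()].
#' @return object of class \code{cnn_model} with the learned weights and
#'   a per-epoch \code{loss_trace}.
#' @export
train_cnn <- function(dataset, config = cnn_config()) {
  y <- dataset$pairs$label
  if (anyNA(y)) stop("training dataset has unlabeled pairs", call. = FALSE)
  if (length(unique(y)) < 2) {
    stop("training requires both classes", call. = FALSE)
  }
  X <- dataset$X
  n <- dim(X)[1]
  model <- build_cnn(config, width = dim(X)[3])
  f <- config$n_filters
  adam <- lapply(model[c("W1", "b1", "W2", "b2", "Wd", "bd")],
                 function(w) list(m = w * 0, v = w * 0))
  beta1 <- 0.9; beta2 <- 0.999; eps <- 1e-8
  step <- 0L
  loss_trace <- numeric(config$epochs)
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(config$seed + 1L)
  for (ep in seq_len(config$epochs)) {
    ord <- sample.int(n)
    ep_loss <- 0
    nb <- 0L
    for (start in seq(1, n, by = config$batch_size)) {
      sel <- ord[start:min(start + config$batch_size - 1L, n)]
      Xb <- X[sel, , , drop = FALSE]
      yb <- y[sel]
      mask <- if (config$dropout > 0) {
        matrix(stats::rbinom(length(sel) * f, 1, 1 - config$dropout),
               length(sel), f)
      } else NULL
      fw <- cnn_forward(model, Xb, dropout_mask = mask)
      ep_loss <- ep_loss + cross_entropy(fw$probs, yb)
      nb <- nb + 1L
      grads <- cnn_backward(model, fw, yb, dropout_mask = mask)
      step <- step + 1L
      for (w in names(grads)) {
        adam[[w]]$m <- beta1 * adam[[w]]$m + (1 - beta1) * grads[[w]]
        adam[[w]]$v <- beta2 * adam[[w]]$v + (1 - beta2) * grads[[w]]^2
        mhat <- adam[[w]]$m / (1 - beta1^step)
        vhat <- adam[[w]]$v / (1 - beta2^step)
        model[[w]] <- model[[w]] -
          config$learning_rate * mhat / (sqrt(vhat) + eps)
      }
    }
    loss_trace[ep] <- ep_loss / nb
  }
  model$loss_trace <- loss_trace
  model
}

#' Score pairs with a trained classifier
#'
#' Deterministic forward pass (dropout disabled); returns the softmax
#' probability of the positive class per pair.
#'
#' @param model a trained \code{cnn_model}.
#' @param dataset a [build_dataset()] (labels may be unknown).
#' @return numeric vector of association scores in \[0, 1\].
#' @export
score_pairs <- function(model, dataset) {
  X <- dataset$X
  if (dim(X)[3] != model$width) {
    stop(sprintf("feature width %d does not match model width %d",
                 dim(X)[3], model$width), call. = FALSE)
  }
  fw <- cnn_forward(model, X, dropout_mask = NULL)
  unname(fw$probs[, 2])
}

#' @export
print.cnn_model <- function(x, ...) {
  cat(sprintf("<cnn_model: width %d, %d filters, kernels %dx%d / %dx%d%s>\n",
              x$width, x$config$n_filters,
              x$config$kernel1[1], x$config$kernel1[2],
              x$config$kernel2[1], x$config$kernel2[2],
              if (is.null(x$loss_trace)) " (untrained)" else
                sprintf(", final loss %.4f", utils::tail(x$loss_trace, 1))))
  invisible(x)
}
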