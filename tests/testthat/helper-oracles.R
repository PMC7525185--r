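# Independent brute-force oracles used across the test files. These are
# deliberately naive re-derivations (enumeration / direct formula loops),
# kept free of any code path they are used to check.

oracle_subscore <- function(x, y, match = 5, mismatch = -4) {
  if (x == "N" || y == "N") 0 else if (x == y) match else mismatch
}

# Enumerate every global alignment of a and b as a sequence of moves
# ("D" diagonal, "U" gap in b / consume a, "L" gap in a / consume b),
# score each with affine run costs (open + (len-1) * ext per gap run),
# and return the optimal score plus the set of positive-column fractions
# achieved by score-optimal alignments.
oracle_alignment <- function(a, b, match = 5, mismatch = -4,
                             gap_open = 16, gap_ext = 4) {
  av <- strsplit(a, "")[[1]]
  bv <- strsplit(b, "")[[1]]
  results <- new.env(parent = emptyenv())
  results$best <- -Inf
  results$fracs <- numeric()
  recurse <- function(i, j, score, pos, len, last) {
    if (i > length(av) && j > length(bv)) {
      if (score > results$best + 1e-9) {
        results$best <- score
        results$fracs <- pos / len
      } else if (abs(score - results$best) <= 1e-9) {
        results$fracs <- unique(c(results$fracs, pos / len))
      }
      return(invisible())
    }
    if (i <= length(av) && j <= length(bv)) {
      s <- oracle_subscore(av[i], bv[j], match, mismatch)
      recurse(i + 1, j + 1, score + s, pos + (s > 0), len + 1, "D")
    }
    if (i <= length(av)) {
      cost <- if (last == "U") gap_ext else gap_open
      recurse(i + 1, j, score - cost, pos, len + 1, "U")
    }
    if (j <= length(bv)) {
      cost <- if (last == "L") gap_ext else gap_open
      recurse(i, j + 1, score - cost, pos, len + 1, "L")
    }
  }
  recurse(1, 1, 0, 0, 0, "")
  list(score = results$best, fractions = results$fracs)
}

# Direct-formula confusion metrics (loops, no shared code with the package)
oracle_metrics <- function(tp, tn, fp, fn) {
  list(
    Pre = tp / (tp + fp),
    Sen = tp / (tp + fn),
    Acc = (tp + tn) / (tp + tn + fp + fn),
    F1 = {
      pre <- tp / (tp + fp); sen <- tp / (tp + fn)
      2 * sen * pre / (sen + pre)
    },
    MCC = (tp * tn - fp * fn) /
      sqrt((tp + fn)) / sqrt((tp + fp)) / sqrt((tn + fn)) / sqrt((tn + fp))
  )
}

# All-pairs AUC with ties counted half
oracle_auc <- function(scores, labels) {
  pos <- scores[labels == 1]
  neg <- scores[labels == 0]
  total <- 0
  for (p in pos) total <- total + sum(p > neg) + 0.5 * sum(p == neg)
  total / (length(pos) * length(neg))
}

# Cell-by-cell pair-feature assembly straight from the definition
oracle_pair_feature <- function(i, j, Sc, Sd, A, Yp, Op, mask) {
  nc <- nrow(A); nd <- ncol(A); np <- ncol(Yp)
  X <- matrix(NA_real_, 2, nc + nd + np)
  for (k in 1:nc) {
    X[1, k] <- Sc[i, k]
    X[2, k] <- if (mask && k == i) 0 else A[k, j]
  }
  for (k in 1:nd) {
    X[1, nc + k] <- if (mask && k == j) 0 else A[i, k]
    X[2, nc + k] <- Sd[j, k]
  }
  for (k in 1:np) {
    X[1, nc + nd + k] <- Yp[i, k]
    X[2, nc + nd + k] <- Op[j, k]
  }
  X
}

# 5 circRNA x 3 disease x 4 miRNA toy context for assembly checks
make_acceptance_toy <- function(seed = 404) {
  set.seed(seed)
  circ <- sprintf("c%d", 1:5); dis <- sprintf("d%d", 1:3)
  mir <- sprintf("m%d", 1:4)
  A <- matrix(rbinom(15, 1, 0.4), 5, 3, dimnames = list(circ, dis))
  Y <- matrix(rbinom(20, 1, 0.5), 5, 4, dimnames = list(circ, mir))
  O <- matrix(rbinom(12, 1, 0.5), 3, 4, dimnames = list(dis, mir))
  Y[rowSums(Y) == 0, 1] <- 1L; O[rowSums(O) == 0, 1] <- 1L
  A[1, 1] <- 1L  # ensure at least one positive
  edges <- function(M) {
    w <- which(M == 1, arr.ind = TRUE)
    data.frame(id_a = rownames(M)[w[, 1]], id_b = colnames(M)[w[, 2]])
  }
  nw <- build_network(edges(A), edges(Y), edges(O))
  Sc <- generate_random_kernels(5, 2, seed)[[1]]
  Sd <- generate_random_kernels(3, 2, seed + 1)[[1]]
  dimnames(Sc) <- list(nw$circ$ids, nw$circ$ids)
  dimnames(Sd) <- list(nw$disease$ids, nw$disease$ids)
  proj <- fit_mirna_projector(nw$Y, nw$O, np = 2)
  list(nw = nw, Sc = Sc, Sd = Sd, proj = proj)
}

# Linearly separable fixture: positives carry a localized bump in both
# rows, negatives are pure noise.
separable_dataset <- function(n = 200, width = 60, seed = 5) {
  set.seed(seed)
  X <- array(rnorm(n * 2 * width, sd = 0.3), dim = c(n, 2, width))
  y <- rep(0:1, length.out = n)
  for (s in which(y == 1)) X[s, , 20:30] <- X[s, , 20:30] + 2
  list(X = X, pairs = data.frame(circ = sprintf("c%d", seq_len(n)),
                                 disease = "d1", label = y),
       blocks = NULL, mask_label = TRUE)
}

# Small study used by several files (kept tiny so kernels are quick)
tiny_study <- function(seed = 7) {
  generate_study(synthetic_spec(nc = 20, nd = 8, nm = 30, n_blocks = 2,
                                seq_length = 40, n_precomputed = 2,
                                seed = seed))
}
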