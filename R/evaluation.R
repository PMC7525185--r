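#' Sample negative pairs from the unobserved cells of A
#'
#' Uniform sampling without replacement from the zero cells of the
#' circRNA-disease matrix; the result is disjoint from the positive set
#' and reproducible from the seed.
#'
#' @param A 0/1 circRNA x disease matrix with dimnames.
#' @param count number of negatives to draw.
#' @param seed RNG seed.
#' @return data.frame with columns \code{circ}, \code{disease},
#'   \code{label} (all 0).
#' @export
sample_negatives <- function(A, count, seed) {
  zeros <- which(A == 0)
  if (count > length(zeros)) {
    stop(sprintf("requested %d negatives but only %d unobserved pairs exist",
                 count, length(zeros)), call. = FALSE)
  }
  old <- .Random.seed_save()
  on.exit(.Random.seed_restore(old), add = TRUE)
  set.seed(seed)
  pick <- sort(sample(zeros, count))
  ij <- arrayInd(pick, dim(A))
  data.frame(circ = rownames(A)[ij[, 1]], disease = colnames(A)[ij[, 2]],
             label = 0L, stringsAsFactors = FALSE)
}

#' Rank-statistic AUC (Mann-Whitney with midranks)
#'
#' @param scores numeric prediction scores.
#' @param labels 0/1 true labels.
#' @return AUC in \[0, 1\].
#' @export
auc_score <- function(scores, labels) {
  stopifnot(length(scores) == length(labels))
  pos <- labels == 1
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores, ties.method = "average")
  (sum(r[pos]) - n1 * (n1 + 1) / 2) / (n1 * n0)
}

#' Classification metrics from scores and labels
#'
#' Precision, sensitivity, accuracy, F1, Matthews correlation coefficient
#' (from the confusion table at the given threshold) and rank-based AUC.
#' Metrics with a zero denominator are NaN with a warning.
#'
#' @param scores numeric prediction scores in \[0, 1\].
#' @param labels 0/1 true labels.
#' @param threshold decision threshold for the confusion table
#'   (default 0.5; softmax argmax).
#' @return named list with \code{Pre}, \code{Sen}, \code{Acc}, \code{F1},
#'   \code{MCC}, \code{AUC} and the counts \code{TP, TN, FP, FN}.
#' @export
compute_metrics <- function(scores, labels, threshold = 0.5) {
  if (length(scores) == 0) stop("empty input", call. = FALSE)
  pred <- as.integer(scores >= threshold)
  tp <- sum(pred == 1 & labels == 1); tn <- sum(pred == 0 & labels == 0)
  fp <- sum(pred == 1 & labels == 0); fn <- sum(pred == 0 & labels == 1)
  metrics_from_counts(tp, tn, fp, fn,
                      auc = auc_score(scores, labels))
}

#' @rdname compute_metrics
#' @param tp,tn,fp,fn confusion counts.
#' @param auc optional AUC to attach.
#' @export
metrics_from_counts <- function(tp, tn, fp, fn, auc = NA_real_) {
  safe <- function(num, den, what) {
    if (den == 0) {
      warning(sprintf("%s undefined (zero denominator)", what), call. = FALSE)
      return(NaN)
    }
    num / den
  }
  pre <- safe(tp, tp + fp, "precision")
  sen <- safe(tp, tp + fn, "sensitivity")
  acc <- (tp + tn) / (tp + tn + fp + fn)
  f1 <- if (is.nan(pre) || is.nan(sen) || (pre + sen) == 0) NaN else
    2 * sen * pre / (sen + pre)
  mcc_den <- sqrt(prod(c(tp + fn, tp + fp, tn + fn, tn + fp)))
  mcc <- if (mcc_den == 0) {
    warning("MCC undefined (zero denominator)", call. = FALSE); NaN
  } else (tp * tn - fp * fn) / mcc_den
  list(Pre = pre, Sen = sen, Acc = acc, F1 = f1, MCC = mcc, AUC = auc,
       TP = tp, TN = tn, FP = fp, FN = fn)
}

make_folds <- function(n, k) {
  # balanced random partition: every index lands in exactly one fold
  sizes <- rep(n %/% k, k) + c(rep(1, n %% k), rep(0, k - n %% k))
  split(sample.int(n), rep(seq_len(k), sizes))
}

#' Repeated stratified cross-validation of the full pipeline
#'
#' For every repetition a fresh negative set the size of the positive set
#' is drawn; positives and negatives are partitioned into \code{folds}
#' parallel folds; the classifier is trained on the remaining folds and
#' evaluated on the held-out positive + negative fold. Feature matrices
#' are built once per repetition (the per-pair label cell is masked, so a
#' pair's features do not depend on the fold split).
#'
#' @param network a [build_network()] result.
#' @param Sc,Sd fused circRNA / disease similarity matrices.
#' @param projector a [fit_mirna_projector()].
#' @param config a [cnn_config()] (its seed is re-derived per fold).
#' @param folds,repetitions cross-validation layout (defaults 5 and 10).
#' @param seed master seed; negative sampling, fold splits and training
#'   seeds all derive from it.
#' @param shuffle_labels permute training/test labels (null-calibration
#'   control).
#' @return object of class \code{cv_report}: list with \code{folds}
#'   (data.frame, one row per fold x repetition with all metrics),
#'   \code{summary} (mean and sd per metric) and \code{seed}.
#' @export
cross_validate <- function(network, Sc, Sd, projector,
                           config = cnn_config(), folds = 5,
                           repetitions = 10, seed = 1,
                           shuffle_labels = FALSE) {
  A <- network$A
  pos_idx <- which(A == 1)
  if (length(pos_idx) < folds) stop("too few positives for the fold count",
                                    call. = FALSE)
  ij <- arrayInd(pos_idx, dim(A))
  positives <- data.frame(circ = rownames(A)[ij[, 1]],
                          disease = colnames(A)[ij[, 2]],
                          label = 1L, stringsAsFactors = FALSE)
  rows <- list()
  for (rep_i in seq_len(repetitions)) {
    negatives <- sample_negatives(A, nrow(positives),
                                  seed = seed + 1000L * rep_i)
    pairs <- rbind(positives, negatives)
    dataset <- build_dataset(pairs, Sc, Sd, network, projector,
                             mask_label = TRUE)
    labels <- dataset$pairs$label
    old <- .Random.seed_save()
    set.seed(seed + 1000L * rep_i + 1L)
    pos_folds <- make_folds(nrow(positives), folds)
    neg_folds <- lapply(make_folds(nrow(negatives), folds),
                        function(ix) ix + nrow(positives))
    if (shuffle_labels) labels <- sample(labels)
    .Random.seed_restore(old)
    for (f in seq_len(folds)) {
      test_ix <- c(pos_folds[[f]], neg_folds[[f]])
      train_ix <- setdiff(seq_len(nrow(pairs)), test_ix)
      tr <- dataset
      tr$X <- dataset$X[train_ix, , , drop = FALSE]
      tr$pairs <- dataset$pairs[train_ix, ]
      tr$pairs$label <- labels[train_ix]
      te <- dataset
      te$X <- dataset$X[test_ix, , , drop = FALSE]
      te$pairs <- dataset$pairs[test_ix, ]
      cfg <- config
      cfg$seed <- as.integer(seed + 1000L * rep_i + f)
      model <- train_cnn(tr, cfg)
      scores <- score_pairs(model, te)
      m <- compute_metrics(scores, labels[test_ix])
      rows[[length(rows) + 1L]] <- data.frame(
        repetition = rep_i, fold = f,
        Pre = m$Pre, Sen = m$Sen, Acc = m$Acc, F1 = m$F1,
        MCC = m$MCC, AUC = m$AUC,
        TP = m$TP, TN = m$TN, FP = m$FP, FN = m$FN)
    }
  }
  per_fold <- do.call(rbind, rows)
  metric_cols <- c("Pre", "Sen", "Acc", "F1", "MCC", "AUC")
  summ <- data.frame(
    metric = metric_cols,
    mean = vapply(per_fold[metric_cols], function(v) mean(v[!is.nan(v)]),
                  numeric(1)),
    sd = vapply(per_fold[metric_cols], function(v) stats::sd(v[!is.nan(v)]),
                numeric(1)),
    row.names = NULL)
  structure(list(folds = per_fold, summary = summ, seed = seed),
            class = "cv_report")
}

#' @export
print.cv_report <- function(x, ...) {
  cat(sprintf("<cv_report: %d folds x %d repetitions>\n",
              max(x$folds$fold), max(x$folds$repetition)))
  print(x$summary, digits = 4)
  invisible(x)
}

#' Rank candidate (unknown) pairs by averaged model scores
#'
#' Scores every candidate pair with each trained model, averages the
#' scores, and ranks (score descending, circRNA id ascending on ties).
#'
#' @param models list of trained \code{cnn_model}s.
#' @param dataset a [build_dataset()] of candidate pairs; all labels must
#'   be unknown (NA).
#' @param per_disease also compute a within-disease rank column.
#' @return data.frame with \code{circ}, \code{disease}, \code{score},
#'   \code{rank} (and \code{disease_rank} if requested), ordered by rank.
#' @export
rank_candidates <- function(models, dataset, per_disease = FALSE) {
  stopifnot(length(models) >= 1)
  if (any(!is.na(dataset$pairs$label))) {
    stop("candidate set must contain only unlabeled pairs", call. = FALSE)
  }
  scores <- rowMeans(vapply(models, score_pairs, numeric(nrow(dataset$pairs)),
                            dataset = dataset))
  out <- data.frame(circ = dataset$pairs$circ,
                    disease = dataset$pairs$disease,
                    score = scores, stringsAsFactors = FALSE)
  ord <- order(-out$score, out$circ, method = "radix")
  out <- out[ord, ]
  out$rank <- seq_len(nrow(out))
  if (per_disease) {
    out$disease_rank <- stats::ave(seq_len(nrow(out)), out$disease,
                                   FUN = seq_along)
  }
  rownames(out) <- NULL
  out
}
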