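#' Alignment parameters for circRNA sequence similarity
#'
#' EDNAFULL-style scoring restricted to unambiguous bases: +5 for an
#' identical base, -4 for any substitution, 0 for any column involving N.
#' Gaps are affine: a run of length L costs \code{gap_open + (L-1) *
#' gap_extend}. Defaults follow the EMBOSS stretcher settings commonly
#' used for circRNA sequence kernels (open 16, extend 4).
#'
#' @param match,mismatch substitution scores.
#' @param gap_open,gap_extend affine gap penalties (positive costs);
#'   \code{gap_open >= gap_extend > 0}.
#' @return list of class \code{alignment_params}.
#' @export
alignment_params <- function(match = 5, mismatch = -4,
                             gap_open = 16, gap_extend = 4) {
  stopifnot(gap_open >= gap_extend, gap_extend > 0, match > 0)
  structure(list(match = match, mismatch = mismatch,
                 gap_open = gap_open, gap_extend = gap_extend),
            class = "alignment_params")
}

#' Global-alignment sequence similarity
#'
#' Aligns two sequences globally with affine gap penalties (three-state
#' Gotoh recurrence) and returns the fraction of alignment columns with a
#' positive substitution score -- the "similarity percentage" of EMBOSS
#' global aligners, as a fraction in \[0, 1\].
#'
#' @param seq_a,seq_b non-empty strings over A, C, G, T, N.
#' @param params an [alignment_params()].
#' @return similarity in \[0, 1\]; the optimal alignment score and length
#'   are attached as attributes \code{"score"} and \code{"length"}.
#' @export
sequence_similarity <- function(seq_a, seq_b, params = alignment_params()) {
  seq_a <- toupper(seq_a); seq_b <- toupper(seq_b)
  for (s in c(seq_a, seq_b)) {
    if (!nzchar(s)) stop("empty sequence", call. = FALSE)
    if (grepl("[^ACGTN]", s)) {
      stop("sequence contains characters outside {A,C,G,T,N}", call. = FALSE)
    }
  }
  res <- .gotoh_align(seq_a, seq_b, params$match, params$mismatch,
                      params$gap_open, params$gap_extend)
  structure(res$similarity, score = res$score, length = res$length)
}

#' Pairwise sequence similarity kernel
#'
#' @param sequences named character vector of sequences.
#' @param circ_ids ids the kernel must span (registry order); circRNAs
#'   without a sequence get zero rows/columns.
#' @param params an [alignment_params()].
#' @return symmetric kernel over \code{circ_ids}, diagonal 1 where a
#'   sequence is available.
#' @export
sequence_kernel <- function(sequences, circ_ids = names(sequences),
                            params = alignment_params()) {
  n <- length(circ_ids)
  K <- matrix(0, n, n, dimnames = list(circ_ids, circ_ids))
  have <- intersect(circ_ids, names(sequences))
  if (length(have) < n) {
    message(sprintf("sequences cover %d of %d circRNAs", length(have), n))
  }
  for (i in seq_along(have)) {
    K[have[i], have[i]] <- 1
    if (i < length(have)) {
      for (j in (i + 1):length(have)) {
        s <- as.numeric(sequence_similarity(sequences[[have[i]]],
                                            sequences[[have[j]]], params))
        K[have[i], have[j]] <- K[have[j], have[i]] <- s
      }
    }
  }
  K
}
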