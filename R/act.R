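#' Autocovariance transformation of one segment
#'
#' For amino acid type j and lag lg, the feature is the mean product of
#' mean-centred column entries lg rows apart within the segment:
#' sum((P[i,j] - mean_j)(P[i+lg,j] - mean_j)) / (M - lg).  The centring
#' mean is the segment's own lambda = 0 PsePSSM column mean, not the
#' whole-sequence mean, so each segment is self-contained.
#'
#' @param block Numeric M x 20 matrix (one segment of a normalised
#'   profile).
#' @param seg_mean Numeric vector of 20 segment column means; defaults to
#'   `colMeans(block)`.
#' @param lg_max Largest lag; requires M > lg_max.
#' @return 20 x lg_max matrix; row j holds amino acid j, column l holds
#'   lg = l.
#' @export
act_segment <- function(block, seg_mean = colMeans(block), lg_max) {
  block <- as.matrix(block)
  M <- nrow(block)
  lg_max <- as.integer(lg_max)
  if (M <= lg_max) {
    stop("insufficient segment length: M = ", M,
         " must exceed lg_max = ", lg_max)
  }
  if (length(seg_mean) != 20L) stop("seg_mean must have 20 entries")
  centred <- sweep(block, 2L, seg_mean, "-")
  out <- matrix(0, nrow = 20L, ncol = lg_max,
                dimnames = list(aa_alphabet(), paste0("lg", seq_len(lg_max))))
  for (lg in seq_len(lg_max)) {
    a <- centred[seq_len(M - lg), , drop = FALSE]
    b <- centred[seq_len(M - lg) + lg, , drop = FALSE]
    out[, lg] <- colSums(a * b) / (M - lg)
  }
  out
}

seg_act <- function(pssm, n, lg_max) {
  m <- as_norm_matrix(pssm)
  seg <- segment_bounds(nrow(m), n)
  out <- lapply(seq_len(n), function(s) {
    block <- m[seg$starts[s]:seg$ends[s], , drop = FALSE]
    flatten_segment(act_segment(block, colMeans(block), lg_max),
                    paste0("seg", n, "_act"), s)
  })
  unlist(out)
}

#' Two-segment autocovariance features (160 values)
#'
#' Autocovariance at lags 1..4 within each of two segments:
#' 2 x 20 x 4 = 160 features, ordered segment-major, then amino acid,
#' then lag.  A constant column yields exact zeros.
#'
#' @inheritParams seg_psepssm_n2
#' @return Named numeric vector of length 160.
#' @export
seg_act_n2 <- function(pssm) {
  seg_act(pssm, 2L, 4L)
}

#' Three-segment autocovariance features (120 values)
#'
#' Autocovariance at lags 1..2 within each of three segments:
#' 3 x 20 x 2 = 120 features.
#'
#' @inheritParams seg_psepssm_n2
#' @return Named numeric vector of length 120.
#' @export
seg_act_n3 <- function(pssm) {
  seg_act(pssm, 3L, 2L)
}
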