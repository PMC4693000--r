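#' Equal-length segmentation of a profile
#'
#' Splits rows 1..L into n contiguous segments.  The unit length is
#' L1 = round(L/n) with round-half-away-from-zero (so L = 5, n = 2 gives
#' L1 = 3); the first n - 1 segments have length L1 exactly and the last
#' segment takes the remaining L - (n - 1) L1 rows, which may be longer or
#' shorter than L1.
#'
#' @param L Profile length (>= 10).
#' @param n Number of segments, 2 or 3.
#' @return An object of class `segmentation` with fields `n`, `L1`,
#'   `starts`, `ends`, `lengths`.
#' @export
#' @examples
#' segment_bounds(10, 3)  # rows 1-3, 4-6, 7-10
segment_bounds <- function(L, n) {
  L <- as.integer(L)
  if (!n %in% c(2L, 3L)) stop("n must be 2 or 3")
  if (L < 10L) {
    stop("profile too short: L = ", L, " but segmentation requires L >= 10")
  }
  L1 <- as.integer(round_half_away(L / n))
  starts <- 1L + (seq_len(n) - 1L) * L1
  ends <- c(starts[-1L] - 1L, L)
  lengths <- ends - starts + 1L
  if (any(lengths < 1L)) stop("degenerate segmentation for L = ", L)
  structure(list(n = n, L1 = L1, starts = starts, ends = ends,
                 lengths = lengths),
            class = "segmentation")
}

#' Pseudo-PSSM correlation factors of one segment
#'
#' For each amino acid type j (column of the segment): the lambda = 0
#' feature is the column mean over the segment (the average substitution
#' propensity); for lambda >= 1 it is the mean squared difference between
#' entries lambda rows apart within the segment,
#' sum((P[i,j] - P[i+lambda,j])^2) / (M - lambda).  Pairs never straddle a
#' segment boundary.
#'
#' @param block Numeric M x 20 matrix (one segment of a normalised
#'   profile).
#' @param lambda_max Largest lag; requires M > lambda_max.
#' @return 20 x (lambda_max + 1) matrix; row j holds amino acid j, column
#'   l holds lambda = l - 1.
#' @export
psepssm_segment <- function(block, lambda_max) {
  block <- as.matrix(block)
  M <- nrow(block)
  lambda_max <- as.integer(lambda_max)
  if (M <= lambda_max) {
    stop("insufficient segment length: M = ", M,
         " must exceed lambda_max = ", lambda_max)
  }
  out <- matrix(0, nrow = 20L, ncol = lambda_max + 1L,
                dimnames = list(aa_alphabet(),
                                paste0("lam", 0:lambda_max)))
  out[, 1L] <- colMeans(block)
  for (lam in seq_len(lambda_max)) {
    d <- block[seq_len(M - lam), , drop = FALSE] -
      block[seq_len(M - lam) + lam, , drop = FALSE]
    out[, lam + 1L] <- colSums(d * d) / (M - lam)
  }
  out
}

# flatten a per-segment 20 x K feature matrix in (amino acid, then
# lag-ascending) order and name the entries
flatten_segment <- function(feat, prefix, segment) {
  vals <- as.vector(t(feat))
  names(vals) <- paste0(prefix, ".s", segment, ".",
                        rep(rownames(feat), each = ncol(feat)), ".",
                        rep(colnames(feat), times = nrow(feat)))
  vals
}

seg_psepssm <- function(pssm, n, lambda_max) {
  m <- as_norm_matrix(pssm)
  seg <- segment_bounds(nrow(m), n)
  out <- lapply(seq_len(n), function(s) {
    block <- m[seg$starts[s]:seg$ends[s], , drop = FALSE]
    flatten_segment(psepssm_segment(block, lambda_max),
                    paste0("seg", n, "_psep"), s)
  })
  unlist(out)
}

#' Two-segment PsePSSM features (200 values)
#'
#' The profile is cut in two; each segment contributes 20 column means
#' (lambda = 0) plus 20 x 4 squared-difference correlation factors
#' (lambda = 1..4), for 2 x 20 x 5 = 200 features.  Ordering is
#' segment-major, then amino acid in column order, then lambda ascending.
#'
#' @param pssm A [normalize_pssm()] result (a raw [pssm_profile()] is
#'   normalised on the fly).
#' @return Named numeric vector of length 200.
#' @export
seg_psepssm_n2 <- function(pssm) {
  seg_psepssm(pssm, 2L, 4L)
}

#' Three-segment PsePSSM features (180 values)
#'
#' As [seg_psepssm_n2()] but with three segments and lambda = 0..2, giving
#' 3 x 20 x 3 = 180 features.  With the minimum profile length of 10 the
#' shortest segment has 3 rows, which still exceeds the largest lag.
#'
#' @inheritParams seg_psepssm_n2
#' @return Named numeric vector of length 180.
#' @export
seg_psepssm_n3 <- function(pssm) {
  seg_psepssm(pssm, 3L, 2L)
}
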