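# Independent naive-loop oracles for every feature family, written directly
# from the defining formulas with explicit loops and global row indices.
# They deliberately share no code with the package implementation.

AA <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I",
        "L", "K", "M", "F", "P", "S", "T", "W", "Y", "V")

random_raw_profile <- function(L, id = "rand") {
  m <- matrix(sample(-10:12, L * 20, replace = TRUE), nrow = L)
  pssm_profile(m, protein_id = id)
}

random_norm_matrix <- function(L) {
  matrix(runif(L * 20), nrow = L)
}

oracle_consensus <- function(mat) {
  out <- character(nrow(mat))
  for (i in seq_len(nrow(mat))) {
    best <- 1L
    for (j in 2:20) if (mat[i, j] > mat[i, best]) best <- j
    out[i] <- AA[best]
  }
  paste(out, collapse = "")
}

oracle_csaac <- function(cs) {
  r <- strsplit(cs, "")[[1]]
  out <- numeric(20)
  for (j in 1:20) {
    for (i in seq_along(r)) if (r[i] == AA[j]) out[j] <- out[j] + 1
  }
  out / length(r)
}

oracle_cscm <- function(cs) {
  r <- strsplit(cs, "")[[1]]
  L <- length(r)
  out <- numeric(20)
  for (j in 1:20) {
    for (i in seq_len(L)) if (r[i] == AA[j]) out[j] <- out[j] + i
  }
  out / (L * (L - 1))
}

# segment unit length, recomputed independently (round half away from zero)
oracle_L1 <- function(L, n) {
  x <- L / n
  f <- floor(x)
  if (x - f >= 0.5) f + 1 else f
}

# segmented PsePSSM with global indices, transcribed from the printed
# per-segment sums; returns features in (segment, aa, lambda) order
oracle_seg_psep <- function(P, n, lambda_max) {
  P <- unname(P)
  L <- nrow(P)
  L1 <- oracle_L1(L, n)
  starts <- 1 + (seq_len(n) - 1) * L1
  ends <- c(starts[-1] - 1, L)
  out <- c()
  for (s in seq_len(n)) {
    for (j in 1:20) {
      for (lam in 0:lambda_max) {
        if (lam == 0) {
          acc <- 0
          for (i in starts[s]:ends[s]) acc <- acc + P[i, j]
          out <- c(out, acc / (ends[s] - starts[s] + 1))
        } else {
          acc <- 0
          for (i in starts[s]:(ends[s] - lam)) {
            acc <- acc + (P[i, j] - P[i + lam, j])^2
          }
          out <- c(out, acc / (ends[s] - starts[s] + 1 - lam))
        }
      }
    }
  }
  out
}

# segmented autocovariance with global indices; centring mean is the
# segment's own lambda = 0 column mean
oracle_seg_act <- function(P, n, lg_max) {
  P <- unname(P)
  L <- nrow(P)
  L1 <- oracle_L1(L, n)
  starts <- 1 + (seq_len(n) - 1) * L1
  ends <- c(starts[-1] - 1, L)
  out <- c()
  for (s in seq_len(n)) {
    for (j in 1:20) {
      mu <- mean(P[starts[s]:ends[s], j])
      for (lg in 1:lg_max) {
        acc <- 0
        for (i in starts[s]:(ends[s] - lg)) {
          acc <- acc + (P[i, j] - mu) * (P[i + lg, j] - mu)
        }
        out <- c(out, acc / (ends[s] - starts[s] + 1 - lg))
      }
    }
  }
  out
}

# full 700D vector assembled purely from the oracles above
oracle_full_vector <- function(raw_mat) {
  raw_mat <- unname(raw_mat)
  P <- 1 / (1 + exp(-raw_mat))
  cs <- oracle_consensus(raw_mat)
  cs <- unname(cs)
  c(oracle_csaac(cs), oracle_cscm(cs),
    oracle_seg_psep(P, 2, 4), oracle_seg_psep(P, 3, 2),
    oracle_seg_act(P, 2, 4), oracle_seg_act(P, 3, 2))
}

# small balanced synthetic dataset shared by classifier tests
make_separable_blobs <- function(n_per_class = 10, sd = 0.2, seed = 1) {
  centers <- rbind(c(0, 0), c(4, 0), c(0, 4), c(4, 4))
  withr::with_seed(seed, {
    x <- do.call(rbind, lapply(1:4, function(k) {
      cbind(rnorm(n_per_class, centers[k, 1], sd),
            rnorm(n_per_class, centers[k, 2], sd))
    }))
  })
  y <- factor(rep(structural_classes(), each = n_per_class),
              levels = structural_classes())
  list(x = x, y = y)
}
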