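#' Default planted class-bias matrix
#'
#' Each structural class shifts the mean of five of the 20 profile columns
#' by `strength` log-odds units, on disjoint column sets (class 1 biases
#' columns 1-5, class 2 columns 6-10, ...).  This mimics the class-specific
#' residue-substitution preferences that make real profiles separable,
#' while keeping the construction transparent.
#'
#' @param strength Mean offset in log-odds units; 0 gives a null
#'   (signal-free) design.
#' @return 4 x 20 numeric matrix, rows named by [structural_classes()].
#' @export
class_bias_matrix <- function(strength = 2) {
  bias <- matrix(0, nrow = 4L, ncol = 20L,
                 dimnames = list(structural_classes(), aa_alphabet()))
  for (k in 1:4) bias[k, ((k - 1L) * 5L + 1L):(k * 5L)] <- strength
  bias
}

#' Specification of a synthetic profile dataset
#'
#' Defines the generative conditions for synthetic PSI-BLAST-like
#' profiles: each column of a profile is an AR(1)-correlated Gaussian
#' series around the class's column offset, rounded to integers and
#' clipped to [-12, 12] to mimic PSI-BLAST log-odds output.  The AR(1)
#' structure puts genuine signal into the lag-indexed PsePSSM and
#' autocovariance features, not only the column means.
#'
#' @param n_per_class Profiles per structural class.
#' @param length_range Integer (min, max) sequence lengths; min >= 10.
#' @param class_bias 4 x 20 matrix of per-class column mean offsets
#'   (log-odds units), rows in [structural_classes()] order.
#' @param rho AR(1) coefficient in [0, 1): lag-1 correlation of the
#'   column series before rounding.
#' @param noise_sd Stationary standard deviation of the column series
#'   (log-odds units, > 0).
#' @param seed Integer seed; dataset generation is bit-reproducible.
#' @return Object of class `synthetic_spec`.
#' @export
synthetic_spec <- function(n_per_class = 30L,
                           length_range = c(50L, 180L),
                           class_bias = class_bias_matrix(2),
                           rho = 0.5, noise_sd = 2, seed = 42L) {
  length_range <- as.integer(length_range)
  if (length(length_range) != 2L || length_range[1L] < 10L ||
      length_range[2L] < length_range[1L]) {
    stop("length_range must be (min, max) with min >= 10")
  }
  if (rho < 0 || rho >= 1) stop("rho must be in [0, 1)")
  if (noise_sd <= 0) stop("noise_sd must be positive")
  class_bias <- as.matrix(class_bias)
  if (!all(dim(class_bias) == c(4L, 20L))) {
    stop("class_bias must be a 4 x 20 matrix")
  }
  rownames(class_bias) <- structural_classes()
  structure(list(n_per_class = as.integer(n_per_class),
                 length_range = length_range, class_bias = class_bias,
                 rho = rho, noise_sd = noise_sd, seed = as.integer(seed)),
            class = "synthetic_spec")
}

#' Generate one synthetic PSSM profile
#'
#' Draws L uniformly from the spec's length range, simulates each of the
#' 20 columns as a stationary AR(1) Gaussian series (coefficient `rho`,
#' stationary sd `noise_sd`) around the class's column offset, then rounds
#' to integers and clips to [-12, 12].  Uses the current RNG state unless
#' `seed` is given, so [generate_dataset()] controls reproducibility with
#' a single seed.
#'
#' @param spec A [synthetic_spec()].
#' @param class_label One of [structural_classes()].
#' @param protein_id Identifier for the profile.
#' @param seed Optional seed for a standalone reproducible draw.
#' @return A [pssm_profile()].
#' @export
generate_profile <- function(spec, class_label, protein_id = "synthetic",
                             seed = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  class_label <- match.arg(class_label, structural_classes())
  draw <- function() {
    L <- spec$length_range[1L] +
      sample.int(spec$length_range[2L] - spec$length_range[1L] + 1L, 1L) - 1L
    innov_sd <- spec$noise_sd * sqrt(1 - spec$rho^2)
    e <- matrix(0, nrow = L, ncol = 20L)
    e[1L, ] <- stats::rnorm(20L, sd = spec$noise_sd)
    if (L > 1L) {
      innov <- matrix(stats::rnorm((L - 1L) * 20L, sd = innov_sd),
                      nrow = L - 1L)
      for (t in 2:L) e[t, ] <- spec$rho * e[t - 1L, ] + innov[t - 1L, ]
    }
    raw <- sweep(e, 2L, spec$class_bias[class_label, ], "+")
    m <- pmax(pmin(round(raw), 12), -12)
    pssm_profile(m, protein_id = protein_id)
  }
  if (is.null(seed)) draw() else withr::with_seed(seed, draw())
}

#' Generate a balanced labelled synthetic dataset
#'
#' Produces `n_per_class` profiles for each of the four structural classes
#' (bit-identical across runs with the same spec) and optionally writes
#' them as PSI-BLAST-dialect `.pssm` fixture files plus a `labels.tsv`
#' manifest (columns `protein_id`, `class`).
#'
#' @param spec A [synthetic_spec()].
#' @param out_dir Optional directory to write `.pssm` files and
#'   `labels.tsv` into (created if missing).
#' @return List with `profiles` (list of [pssm_profile()]) and `labels`
#'   (data frame `protein_id`, `class`).
#' @export
#' @examples
#' d <- generate_dataset(synthetic_spec(n_per_class = 2, seed = 7))
#' table(d$labels$class)
generate_dataset <- function(spec, out_dir = NULL) {
  stopifnot(inherits(spec, "synthetic_spec"))
  classes <- structural_classes()
  slug <- c("alpha", "beta", "alphabeta", "alphaplusbeta")
  profiles <- list()
  labels <- list()
  withr::with_seed(spec$seed, {
    for (k in seq_along(classes)) {
      for (r in seq_len(spec$n_per_class)) {
        id <- sprintf("%s_%03d", slug[k], r)
        profiles[[id]] <- generate_profile(spec, classes[k],
                                           protein_id = id)
        labels[[id]] <- data.frame(protein_id = id, class = classes[k],
                                   stringsAsFactors = FALSE)
      }
    }
  })
  labels <- do.call(rbind, labels)
  rownames(labels) <- NULL
  if (!is.null(out_dir)) {
    dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
    for (p in profiles) {
      write_pssm(p, file.path(out_dir, paste0(p$protein_id, ".pssm")))
    }
    utils::write.table(labels, file.path(out_dir, "labels.tsv"),
                       sep = "\t", quote = FALSE, row.names = FALSE)
  }
  list(profiles = unname(profiles), labels = labels)
}
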