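FEATURE_GROUPS <- c("csaac", "cscm", "seg2_psep", "seg3_psep",
                    "seg2_act", "seg3_act")

GROUP_DIMS <- c(csaac = 20L, cscm = 20L, seg2_psep = 200L,
                seg3_psep = 180L, seg2_act = 160L, seg3_act = 120L)

#' Resolve feature-group names
#'
#' Expands the aliases `csp` (csaac + cscm), `segpsep` (both segmented
#' PsePSSM blocks), `segact` (both autocovariance blocks) and `full` (all
#' six blocks, 700 features) and returns the atomic group names in
#' canonical layout order: csaac, cscm, seg2_psep, seg3_psep, seg2_act,
#' seg3_act.
#'
#' @param groups Character vector of group names and/or aliases.
#' @return Character vector of atomic group names in layout order.
#' @export
#' @examples
#' feature_groups(c("csp", "seg2_psep"))  # 40 + 200 = 240 features
feature_groups <- function(groups = "full") {
  groups <- unlist(strsplit(as.character(groups), ",", fixed = TRUE))
  groups <- trimws(groups)
  if (length(groups) == 0L) stop("empty feature group selection")
  alias <- list(csp = c("csaac", "cscm"),
                segpsep = c("seg2_psep", "seg3_psep"),
                segact = c("seg2_act", "seg3_act"),
                full = FEATURE_GROUPS)
  expanded <- unlist(lapply(groups, function(g) {
    if (g %in% names(alias)) alias[[g]]
    else if (g %in% FEATURE_GROUPS) g
    else stop("unknown feature group: '", g, "'")
  }))
  out <- FEATURE_GROUPS[FEATURE_GROUPS %in% expanded]
  if (length(out) == 0L) stop("empty feature group selection")
  out
}

#' Extract the CSP-SegPseP-SegACP feature vector of one profile
#'
#' Computes the selected feature blocks of a profile and concatenates them
#' in the fixed layout order csaac (20), cscm (20), seg2_psep (200),
#' seg3_psep (180), seg2_act (160), seg3_act (120).  The full selection
#' yields the method's 700-dimensional vector; partial selections give the
#' ablation dimensionalities (20, 40, 240, 420, 680, ...).
#'
#' @param pssm A [pssm_profile()] or [normalize_pssm()] result with
#'   L >= 10.
#' @param groups Feature groups / aliases, see [feature_groups()].
#' @return Named numeric vector.
#' @export
#' @examples
#' p <- generate_profile(synthetic_spec(seed = 1), "all-alpha")
#' length(extract_features(p))            # 700
#' length(extract_features(p, "csp"))     # 40
extract_features <- function(pssm, groups = "full") {
  groups <- feature_groups(groups)
  norm <- normalize_pssm(pssm)
  blocks <- list()
  if (any(c("csaac", "cscm") %in% groups)) {
    cs <- consensus_sequence(norm)
    if ("csaac" %in% groups) blocks$csaac <- csaac(cs)
    if ("cscm" %in% groups) blocks$cscm <- cscm(cs)
  }
  if ("seg2_psep" %in% groups) blocks$seg2_psep <- seg_psepssm_n2(norm)
  if ("seg3_psep" %in% groups) blocks$seg3_psep <- seg_psepssm_n3(norm)
  if ("seg2_act" %in% groups) blocks$seg2_act <- seg_act_n2(norm)
  if ("seg3_act" %in% groups) blocks$seg3_act <- seg_act_n3(norm)
  # entries are already block-qualified; drop the list-level prefixes
  unlist(unname(blocks[groups]))
}

#' Build a labelled feature dataset from profiles
#'
#' Applies [extract_features()] to each profile and stacks the vectors
#' into an N x p matrix.
#'
#' @param profiles List of profiles.
#' @param labels Optional character/factor vector of structural class
#'   labels, one per profile.
#' @param groups Feature groups, see [feature_groups()].
#' @return List of class `labeled_dataset`: `ids`, `x` (feature matrix
#'   with named columns), `labels` (factor or NULL).
#' @export
extract_dataset <- function(profiles, labels = NULL, groups = "full") {
  if (length(profiles) == 0L) stop("no profiles supplied")
  feats <- lapply(profiles, extract_features, groups = groups)
  x <- do.call(rbind, feats)
  ids <- vapply(profiles, function(p) p$protein_id, character(1L))
  rownames(x) <- ids
  if (!is.null(labels)) {
    if (length(labels) != length(profiles)) {
      stop("labels length does not match number of profiles")
    }
    lev <- if (all(labels %in% structural_classes())) {
      structural_classes()
    } else {
      sort(unique(as.character(labels)))
    }
    labels <- factor(as.character(labels), levels = lev)
  }
  structure(list(ids = ids, x = x, labels = labels),
            class = "labeled_dataset")
}

#' Write / read a feature matrix as TSV
#'
#' One protein per row; first column `protein_id`, remaining columns the
#' block-qualified feature names.
#'
#' @param x Feature matrix with row and column names.
#' @param path Output (input) path.
#' @return `write_features` returns `path` invisibly; `read_features`
#'   returns the numeric matrix.
#' @export
write_features <- function(x, path) {
  df <- data.frame(protein_id = rownames(x), x, check.names = FALSE)
  utils::write.table(df, path, sep = "\t", quote = FALSE,
                     row.names = FALSE)
  invisible(path)
}

#' @rdname write_features
#' @export
read_features <- function(path) {
  df <- utils::read.delim(path, check.names = FALSE)
  m <- as.matrix(df[, -1L, drop = FALSE])
  rownames(m) <- df[[1L]]
  m
}

#' Principal component analysis of a feature matrix
#'
#' Covariance PCA (centred, unscaled by default): the data are projected
#' onto the top-k eigenvectors of the sample covariance matrix, ordered by
#' decreasing eigenvalue.  Features are left unscaled because all blocks
#' derive from the same (0,1) normalised profile; set `scale = TRUE` for a
#' correlation-PCA sensitivity analysis.  For reproducible output files
#' each loading is oriented so its largest-magnitude entry is positive.
#'
#' @param x Numeric N x p matrix (N >= 2).
#' @param k Number of components to keep; must satisfy
#'   1 <= k <= min(N - 1, p) (centring removes one degree of freedom).
#' @param scale Standardise columns to unit variance first.
#' @return Object of class `pssm_pca`: `mean`, `scale`, `rotation`
#'   (p x k orthonormal loadings), `explained_variance` (k eigenvalues,
#'   non-increasing), `total_variance`, `scores` (N x k), `k`.
#' @export
fit_pca <- function(x, k = 224L, scale = FALSE) {
  x <- as.matrix(x)
  n <- nrow(x)
  p <- ncol(x)
  if (n < 2L) stop("PCA requires at least 2 rows")
  k <- as.integer(k)
  kmax <- min(n - 1L, p)
  if (k < 1L || k > kmax) {
    stop("k = ", k, " out of range: must be in [1, ", kmax,
         "] for ", n, " x ", p, " data")
  }
  ctr <- colMeans(x)
  if (scale) {
    sds <- apply(x, 2L, stats::sd)
    sds[sds == 0] <- 1  # constant columns carry no signal either way
  } else {
    sds <- rep(1, p)
  }
  names(sds) <- colnames(x)
  # scaling handled manually so the stored vectors match apply_pca exactly
  xs <- sweep(sweep(x, 2L, ctr, "-"), 2L, sds, "/")
  pr <- stats::prcomp(xs, center = FALSE, scale. = FALSE)
  names(ctr) <- colnames(x)
  rot <- pr$rotation[, seq_len(k), drop = FALSE]
  scores <- pr$x[, seq_len(k), drop = FALSE]
  # deterministic sign: largest-magnitude loading entry positive
  for (j in seq_len(k)) {
    i <- which.max(abs(rot[, j]))
    if (rot[i, j] < 0) {
      rot[, j] <- -rot[, j]
      scores[, j] <- -scores[, j]
    }
  }
  colnames(rot) <- colnames(scores) <- paste0("PC", seq_len(k))
  structure(
    list(mean = ctr, scale = sds, scaled = scale, rotation = rot,
         explained_variance = pr$sdev[seq_len(k)]^2,
         total_variance = sum(pr$sdev^2),
         scores = scores, k = k),
    class = "pssm_pca"
  )
}

#' Project feature vectors onto a fitted PCA model
#'
#' Centres (and, if the model was fitted with `scale = TRUE`, scales) the
#' rows and projects them onto the stored loadings.  Used to place
#' held-out proteins into the reduced space during jackknife evaluation.
#'
#' @param model A [fit_pca()] result.
#' @param x Numeric M x p matrix (p must match the training data).
#' @return M x k score matrix.
#' @export
apply_pca <- function(model, x) {
  stopifnot(inherits(model, "pssm_pca"))
  x <- as.matrix(x)
  if (is.null(dim(x)) || ncol(x) != length(model$mean)) {
    stop("column count mismatch: model expects ", length(model$mean),
         " features, got ", ncol(x))
  }
  xc <- sweep(x, 2L, model$mean, "-")
  if (model$scaled) xc <- sweep(xc, 2L, model$scale, "/")
  xc %*% model$rotation
}

#' @export
print.pssm_pca <- function(x, ...) {
  cat("<pssm_pca> k = ", x$k, " components, ",
      sprintf("%.1f%%", 100 * sum(x$explained_variance) / x$total_variance),
      " variance retained\n", sep = "")
  invisible(x)
}

#' Serialise / restore a PCA model as JSON
#'
#' @param model A [fit_pca()] result.
#' @param path JSON path.
#' @return `write_pca_json` returns `path` invisibly; `read_pca_json`
#'   returns the restored `pssm_pca` model (without scores).
#' @export
write_pca_json <- function(model, path) {
  stopifnot(inherits(model, "pssm_pca"))
  obj <- list(mean = unname(model$mean), scale = unname(model$scale),
              scaled = model$scaled,
              rotation = unname(model$rotation),
              explained_variance = model$explained_variance,
              total_variance = model$total_variance,
              k = model$k, feature_names = names(model$mean))
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_pca_json
#' @export
read_pca_json <- function(path) {
  obj <- jsonlite::read_json(path, simplifyVector = TRUE)
  rot <- as.matrix(obj$rotation)
  colnames(rot) <- paste0("PC", seq_len(obj$k))
  mean <- as.numeric(obj$mean)
  names(mean) <- obj$feature_names
  rownames(rot) <- obj$feature_names
  structure(
    list(mean = mean, scale = as.numeric(obj$scale), scaled = obj$scaled,
         rotation = rot,
         explained_variance = as.numeric(obj$explained_variance),
         total_variance = obj$total_variance,
         scores = NULL, k = as.integer(obj$k)),
    class = "pssm_pca"
  )
}
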