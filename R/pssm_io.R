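#' Construct a PSSM profile object
#'
#' A PSSM profile is an L x 20 log-odds matrix: entry (i, j) scores the
#' residue at position i of the query being substituted by amino acid type
#' j during evolution.  Columns follow [aa_alphabet()] order.
#'
#' @param matrix Numeric L x 20 matrix of log-odds scores (L >= 1).
#' @param protein_id Identifier string for the protein.
#' @param sequence Optional query (or residue-column) sequence of length L.
#'   Non-standard residue letters (e.g. `X`) are kept verbatim.
#' @return An object of class `pssm_profile` with fields `protein_id`,
#'   `length`, `matrix` and `sequence`.
#' @export
#' @examples
#' p <- pssm_profile(matrix(0, 12, 20), "toy")
#' p$length
pssm_profile <- function(matrix, protein_id = "query", sequence = NULL) {
  matrix <- as.matrix(matrix)
  if (ncol(matrix) != 20L) {
    stop("PSSM matrix must have exactly 20 columns, found ", ncol(matrix))
  }
  if (nrow(matrix) < 1L) {
    stop("empty profile: PSSM must have at least 1 row")
  }
  if (!is.numeric(matrix) || anyNA(matrix) || any(!is.finite(matrix))) {
    stop("PSSM matrix must be finite numeric")
  }
  if (!is.null(sequence)) {
    sequence <- as.character(sequence)
    if (nchar(sequence) != nrow(matrix)) {
      stop("sequence length (", nchar(sequence),
           ") does not match profile length (", nrow(matrix), ")")
    }
  }
  storage.mode(matrix) <- "double"
  colnames(matrix) <- aa_alphabet()
  structure(
    list(protein_id = as.character(protein_id), length = nrow(matrix),
         matrix = matrix, sequence = sequence),
    class = "pssm_profile"
  )
}

#' @export
print.pssm_profile <- function(x, ...) {
  cat("<pssm_profile> ", x$protein_id, ": L = ", x$length,
      ", scores in [", min(x$matrix), ", ", max(x$matrix), "]\n", sep = "")
  invisible(x)
}

#' Parse a PSI-BLAST ASCII PSSM
#'
#' Reads the text produced by `psiblast -out_ascii_pssm` (header lines, then
#' one row per residue: position index, residue letter, 20 log-odds
#' integers, 20 weighted-percentage integers, and two trailing per-position
#' statistics; then footer lines).  The log-odds block — the first 20
#' numeric columns — becomes the profile matrix; the residue column becomes
#' the stored sequence.
#'
#' Profiles shorter than 10 residues are rejected: the segmented
#' descriptors downstream require at least 10 rows.
#'
#' @param text Either a single string containing the whole file (with
#'   newlines) or a character vector of lines.
#' @param protein_id Identifier to attach to the profile.
#' @return A [pssm_profile()].
#' @seealso [read_pssm()] for reading from a file path, [write_pssm()] for
#'   the inverse.
#' @export
parse_pssm <- function(text, protein_id = "query") {
  if (length(text) == 1L && grepl("\n", text, fixed = TRUE)) {
    lines <- strsplit(text, "\n", fixed = TRUE)[[1L]]
  } else {
    lines <- as.character(text)
  }
  is_data <- grepl("^\\s*[0-9]+\\s+[A-Za-z*]\\s", paste0(lines, " "))
  if (!any(is_data)) {
    stop("empty profile: no PSSM data rows found")
  }
  # contiguous data block: stop at the first non-data line after the table
  first <- which(is_data)[1L]
  run_end <- first
  while (run_end < length(lines) && is_data[run_end + 1L]) {
    run_end <- run_end + 1L
  }
  rows <- vector("list", run_end - first + 1L)
  seq_chars <- character(length(rows))
  for (k in seq_along(rows)) {
    ln <- first + k - 1L
    fields <- strsplit(trimws(lines[ln]), "\\s+")[[1L]]
    nnum <- length(fields) - 2L  # drop index and residue
    if (!(nnum %in% c(20L, 40L, 42L))) {
      stop("malformed PSSM row at line ", ln, ": expected 20, 40 or 42 ",
           "numeric fields after the residue, found ", nnum)
    }
    scores <- suppressWarnings(as.numeric(fields[3:22]))
    if (anyNA(scores)) {
      stop("non-numeric log-odds score at line ", ln)
    }
    seq_chars[k] <- fields[2L]
    rows[[k]] <- scores
  }
  mat <- do.call(rbind, rows)
  if (nrow(mat) < 10L) {
    stop("profile too short: L = ", nrow(mat),
         " but segmented features require L >= 10")
  }
  pssm_profile(mat, protein_id = protein_id,
               sequence = paste(seq_chars, collapse = ""))
}

#' Read a PSI-BLAST ASCII PSSM file
#'
#' @param path Path to a `.pssm` file.
#' @param protein_id Identifier; defaults to the file name without
#'   extension.
#' @return A [pssm_profile()].
#' @export
read_pssm <- function(path, protein_id = NULL) {
  if (!file.exists(path)) stop("PSSM file not found: ", path)
  if (is.null(protein_id)) {
    protein_id <- tools::file_path_sans_ext(basename(path))
  }
  parse_pssm(readLines(path, warn = FALSE), protein_id = protein_id)
}

#' Write a profile in the PSI-BLAST ASCII PSSM dialect
#'
#' Emits the same layout [parse_pssm()] consumes, so synthetic profiles can
#' be used as fixtures for the parser and for the command-line tools.  The
#' weighted-percentage block is written as zeros and the two per-position
#' statistics as 0.00 (they are ignored on read).
#'
#' @param profile A [pssm_profile()].
#' @param path Optional output path; if `NULL` the lines are returned.
#' @return Invisibly, the character vector of file lines.
#' @export
write_pssm <- function(profile, path = NULL) {
  stopifnot(inherits(profile, "pssm_profile"))
  aa <- aa_alphabet()
  res <- if (is.null(profile$sequence)) {
    aa[max.col(profile$matrix, ties.method = "first")]
  } else {
    strsplit(profile$sequence, "")[[1L]]
  }
  header <- c(
    "",
    paste("Last position-specific scoring matrix computed, weighted",
          "observed percentages rounded down, information per position,",
          "and relative weight of gapless real matches to pseudocounts"),
    paste0("            ", paste(sprintf("%3s", c(aa, aa)), collapse = " "))
  )
  body <- vapply(seq_len(profile$length), function(i) {
    paste0(sprintf("%5d %s  ", i, res[i]),
           paste(sprintf("%3d", as.integer(round(profile$matrix[i, ]))),
                 collapse = " "),
           " ",
           paste(sprintf("%3d", integer(20L)), collapse = " "),
           sprintf("  %4.2f %8.2f", 0, 0))
  }, character(1L))
  lines <- c(header, body, "", "                      K         Lambda")
  if (!is.null(path)) writeLines(lines, path)
  invisible(lines)
}

#' Sigmoid-normalise a PSSM profile
#'
#' Maps every log-odds entry x to 1 / (1 + exp(-x)), the standard logistic
#' sigmoid, so all entries lie strictly in (0, 1).  All downstream features
#' are computed on this normalised matrix (the consensus sequence is
#' unaffected because the sigmoid is strictly monotone).
#'
#' @param profile A [pssm_profile()].
#' @return An object of class `pssm_norm`: same fields, matrix in (0, 1).
#' @export
#' @examples
#' p <- pssm_profile(matrix(0, 12, 20), "toy")
#' normalize_pssm(p)$matrix[1, 1]  # 0.5
normalize_pssm <- function(profile) {
  if (inherits(profile, "pssm_norm")) return(profile)
  stopifnot(inherits(profile, "pssm_profile"))
  m <- 1 / (1 + exp(-profile$matrix))
  structure(
    list(protein_id = profile$protein_id, length = profile$length,
         matrix = m, sequence = profile$sequence),
    class = "pssm_norm"
  )
}

#' @export
print.pssm_norm <- function(x, ...) {
  cat("<pssm_norm> ", x$protein_id, ": L = ", x$length,
      ", sigmoid-normalised\n", sep = "")
  invisible(x)
}

# accept either representation where only the matrix is needed
as_norm_matrix <- function(x) {
  if (inherits(x, "pssm_norm")) return(x$matrix)
  if (inherits(x, "pssm_profile")) return(normalize_pssm(x)$matrix)
  stop("expected a pssm_profile or pssm_norm object")
}
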