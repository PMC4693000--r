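#' Consensus sequence of a PSSM profile
#'
#' Position i of the consensus sequence is the amino acid whose column
#' attains the maximum score in row i of the profile.  Ties are broken by
#' the lowest column index (first in A R N D ... order), deterministically.
#' The result is identical on the raw and the sigmoid-normalised matrix
#' because the sigmoid is strictly increasing.
#'
#' @param profile A [pssm_profile()] or [normalize_pssm()] result.
#' @return An object of class `consensus_seq` with fields `protein_id` and
#'   `residues` (a string of length L over the 20-letter alphabet).
#' @export
#' @examples
#' m <- matrix(0, 10, 20); m[, 2] <- 5   # R dominates everywhere
#' consensus_sequence(pssm_profile(m))$residues
consensus_sequence <- function(profile) {
  stopifnot(inherits(profile, c("pssm_profile", "pssm_norm")))
  idx <- max.col(profile$matrix, ties.method = "first")
  structure(
    list(protein_id = profile$protein_id,
         residues = paste(aa_alphabet()[idx], collapse = "")),
    class = "consensus_seq"
  )
}

#' @export
print.consensus_seq <- function(x, ...) {
  cat("<consensus_seq> ", x$protein_id, ": ", x$residues, "\n", sep = "")
  invisible(x)
}

cs_residue_vector <- function(cs) {
  if (inherits(cs, "consensus_seq")) cs <- cs$residues
  r <- strsplit(as.character(cs), "")[[1L]]
  if (!all(r %in% aa_alphabet())) {
    stop("consensus sequence contains letters outside the 20-letter alphabet")
  }
  r
}

#' Amino acid composition of a consensus sequence (CSAAC)
#'
#' Entry j is the count of amino acid j in the consensus sequence divided
#' by its length L; the 20 values sum to 1.
#'
#' @param cs A `consensus_seq` or a plain string over the 20-letter
#'   alphabet.
#' @return Named numeric vector of 20 composition fractions, in
#'   [aa_alphabet()] order.
#' @export
#' @examples
#' csaac("AR")  # 0.5 for A, 0.5 for R
csaac <- function(cs) {
  r <- cs_residue_vector(cs)
  counts <- table(factor(r, levels = aa_alphabet()))
  out <- as.numeric(counts) / length(r)
  names(out) <- paste0("csaac.", aa_alphabet())
  out
}

#' Composition moment of a consensus sequence (CSCM)
#'
#' Entry i is the sum of the 1-based positions at which amino acid i occurs
#' in the consensus sequence, divided by L(L - 1).  Unlike plain
#' composition, this weights each occurrence by where it sits along the
#' chain, so it carries coarse sequence-order information.  Amino acids
#' absent from the sequence score 0, and the 20 values always sum to
#' (L + 1) / (2(L - 1)).
#'
#' @inheritParams csaac
#' @return Named numeric vector of 20 nonnegative composition moments.
#' @export
#' @examples
#' cscm("AR")  # A: 1/(2*1) = 0.5, R: 2/(2*1) = 1.0
cscm <- function(cs) {
  r <- cs_residue_vector(cs)
  L <- length(r)
  if (L < 2L) {
    stop("degenerate length: composition moment requires L >= 2")
  }
  pos_sum <- vapply(split(seq_len(L), factor(r, levels = aa_alphabet())),
                    sum, numeric(1L))
  out <- as.numeric(pos_sum) / (L * (L - 1))
  names(out) <- paste0("cscm.", aa_alphabet())
  out
}

#' Extract consensus sequences from PSSM files and write FASTA
#'
#' Convenience exporter behind the `pssmclass consensus` subcommand.
#'
#' @param profiles List of [pssm_profile()] objects.
#' @param path Output FASTA path.
#' @return Invisibly, the list of `consensus_seq` objects.
#' @export
write_consensus_fasta <- function(profiles, path) {
  if (!requireNamespace("seqinr", quietly = TRUE)) {
    stop("package 'seqinr' is required for FASTA export")
  }
  cs <- lapply(profiles, consensus_sequence)
  seqinr::write.fasta(
    sequences = lapply(cs, function(x) strsplit(x$residues, "")[[1L]]),
    names = vapply(cs, function(x) x$protein_id, character(1L)),
    file.out = path
  )
  invisible(cs)
}
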