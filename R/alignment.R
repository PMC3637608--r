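# Pairwise global alignment (Gotoh affine-gap, compiled backend).
#
# Scoring convention: a gap run of length L costs gap_open + (L-1)*gap_extend.
# Ties are broken deterministically: substitution > gap-in-A > gap-in-B.

.nt_submat <- function(match = 1, mismatch = -1) {
  ab <- c("A", "C", "G", "T", "N")
  m <- matrix(mismatch, 5, 5, dimnames = list(ab, ab))
  diag(m) <- match
  m["N", ] <- 0; m[, "N"] <- 0   # ambiguity: neutral
  m
}

.aa_submat <- function() {
  e <- new.env()
  utils::data("BLOSUM62", package = "Biostrings", envir = e)
  m <- e$BLOSUM62
  ab <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K", "M",
          "F", "P", "S", "T", "W", "Y", "V", "X", "*")
  m <- m[ab, ab]
  m["X", ] <- 0; m[, "X"] <- 0
  m
}

#' Default alignment scoring parameters
#'
#' Nucleotide: match +1, mismatch -1, gap open -4, gap extend -1, ambiguity
#' (N) neutral. Amino acid: BLOSUM62 with gap open -10, extend -1, X neutral.
#'
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @return list with `submat`, `gap_open`, `gap_extend`.
#' @export
alignment_scoring <- function(alphabet = c("nucleotide", "amino_acid")) {
  alphabet <- match.arg(alphabet)
  if (alphabet == "nucleotide")
    list(submat = .nt_submat(), gap_open = -4, gap_extend = -1)
  else
    list(submat = .aa_submat(), gap_open = -10, gap_extend = -1)
}

#' Optimal global alignment of two ungapped sequences
#'
#' Needleman-Wunsch/Gotoh alignment with affine gaps under the convention
#' that a gap of length L costs `gap_open + (L-1)*gap_extend`. The optimum
#' is made unique by a fixed tie-break (substitution preferred over a gap
#' placed in `a`, preferred over a gap placed in `b`), so results are
#' deterministic.
#'
#' @param a,b character scalars (ungapped) over the same alphabet.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @param scoring list as from [alignment_scoring()]; defaults per alphabet.
#' @return object of class `pairwise_alignment`: `aligned_a`, `aligned_b`
#'   (equal-length gapped strings), `score`, and integer maps `map_a`,
#'   `map_b` giving, per alignment column, the 1-based ungapped position
#'   consumed in each input (NA at gap columns).
#' @export
global_align <- function(a, b, alphabet = c("nucleotide", "amino_acid"),
                         scoring = NULL) {
  alphabet <- match.arg(alphabet)
  if (inherits(a, "seq_collection") || inherits(b, "seq_collection"))
    stop("pass single sequences, not collections")
  a <- toupper(as.character(a)); b <- toupper(as.character(b))
  if (!nzchar(a) || !nzchar(b)) stop("empty sequence")
  if (grepl("-", a, fixed = TRUE) || grepl("-", b, fixed = TRUE))
    stop("inputs must be ungapped")
  if (is.null(scoring)) scoring <- alignment_scoring(alphabet)
  sm <- scoring$submat
  res <- .gotoh_align(a, b, sm, paste(rownames(sm), collapse = ""),
                      scoring$gap_open, scoring$gap_extend)
  ca <- strsplit(res$aligned_a, "")[[1]]
  cb <- strsplit(res$aligned_b, "")[[1]]
  map_a <- ifelse(ca == "-", NA_integer_, cumsum(ca != "-"))
  map_b <- ifelse(cb == "-", NA_integer_, cumsum(cb != "-"))
  structure(list(aligned_a = res$aligned_a, aligned_b = res$aligned_b,
                 score = res$score, map_a = map_a, map_b = map_b,
                 alphabet = alphabet),
            class = "pairwise_alignment")
}

#' @export
print.pairwise_alignment <- function(x, ...) {
  cat("<pairwise_alignment> length ", nchar(x$aligned_a),
      ", score ", x$score, ", identity ",
      round(100 * alignment_identity(x), 1), "%\n", sep = "")
  invisible(x)
}

#' Fraction of identical columns in a pairwise alignment
#'
#' @param aln a `pairwise_alignment`.
#' @param ungapped_only if TRUE (default) the denominator counts only
#'   columns where both sequences have a residue.
#' @return fraction in \[0,1\].
#' @export
alignment_identity <- function(aln, ungapped_only = TRUE) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  both <- ca != "-" & cb != "-"
  denom <- if (ungapped_only) sum(both) else length(ca)
  if (denom == 0L) return(0)
  sum(ca == cb & both) / denom
}

# Per-column match indicator of an alignment (TRUE where residues equal and
# both ungapped); used by the homology-window detector.
.match_profile <- function(aln) {
  ca <- strsplit(aln$aligned_a, "")[[1]]
  cb <- strsplit(aln$aligned_b, "")[[1]]
  ca == cb & ca != "-" & cb != "-"
}
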