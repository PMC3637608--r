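# CDS translation and three-way (paralog A, paralog B, outgroup) alignment.

#' Translate a coding sequence
#'
#' Standard genetic code. A trailing incomplete codon is trimmed (with a
#' message); a terminal stop codon is dropped; an internal stop translates
#' to `X` with a warning; codons containing the ambiguity code `N`
#' translate to `X` unless the code is unambiguous regardless.
#'
#' @param nt character scalar, ungapped nucleotide sequence.
#' @return character scalar amino-acid sequence, with attribute `codons`
#'   (the codon per residue, used for codon back-threading).
#' @export
translate_cds <- function(nt) {
  nt <- toupper(as.character(nt))
  if (nchar(nt) < 3L) stop("coding sequence shorter than one codon")
  extra <- nchar(nt) %% 3L
  if (extra) {
    message("trimming ", extra, " trailing nucleotide(s) (incomplete codon)")
    nt <- substr(nt, 1L, nchar(nt) - extra)
  }
  gc <- Biostrings::GENETIC_CODE
  codons <- substring(nt, seq(1L, nchar(nt), 3L), seq(3L, nchar(nt), 3L))
  aa <- unname(gc[codons])
  aa[is.na(aa)] <- "X"                      # ambiguity (N) or odd codon
  if (length(aa) > 1L && !is.na(aa[length(aa)]) && aa[length(aa)] == "*") {
    aa <- aa[-length(aa)]
    codons <- codons[-length(codons)]
  }
  if (any(aa == "*")) {
    warning("internal stop codon(s) translated as X")
    aa[aa == "*"] <- "X"
  }
  structure(paste(aa, collapse = ""), codons = codons)
}

# Merge two pairwise alignments sharing anchor sequence A:
# aln_ab (A vs B) and aln_ao (A vs O) -> equal-length gapped strings for
# A, B, O. Columns where only B (or only O) has a residue appear with gaps
# in the other two sequences.
.merge_on_anchor <- function(aln_ab, aln_ao) {
  a1 <- strsplit(aln_ab$aligned_a, "")[[1]]
  b1 <- strsplit(aln_ab$aligned_b, "")[[1]]
  a2 <- strsplit(aln_ao$aligned_a, "")[[1]]
  o2 <- strsplit(aln_ao$aligned_b, "")[[1]]
  i <- 1L; j <- 1L
  n1 <- length(a1); n2 <- length(a2)
  ra <- character(0); rb <- character(0); ro <- character(0)
  while (i <= n1 || j <= n2) {
    g1 <- i <= n1 && a1[i] == "-"
    g2 <- j <= n2 && a2[j] == "-"
    if (g1) {                      # B insertion relative to A
      ra <- c(ra, "-"); rb <- c(rb, b1[i]); ro <- c(ro, "-"); i <- i + 1L
    } else if (g2) {               # O insertion relative to A
      ra <- c(ra, "-"); rb <- c(rb, "-"); ro <- c(ro, o2[j]); j <- j + 1L
    } else {                       # both consume the same A residue
      ra <- c(ra, a1[i]); rb <- c(rb, b1[i]); ro <- c(ro, o2[j])
      i <- i + 1L; j <- j + 1L
    }
  }
  list(a = ra, b = rb, o = ro)
}

# Thread codons back onto a gapped amino-acid vector ("---" at gaps).
.backthread <- function(aa_gapped, codons) {
  out <- character(length(aa_gapped))
  k <- 0L
  for (i in seq_along(aa_gapped)) {
    if (aa_gapped[i] == "-") out[i] <- "---"
    else { k <- k + 1L; out[i] <- codons[[k]] }
  }
  paste(out, collapse = "")
}

#' Build an aligned triplet (paralog A, paralog B, outgroup)
#'
#' The three coding sequences are translated; paralog B and the outgroup
#' are each globally aligned to paralog A at the amino-acid level and the
#' two pairwise alignments are merged on the shared anchor. The nucleotide
#' triplet is obtained by threading each sequence's codons back through the
#' protein alignment (gap columns become `---`), so the nucleotide and
#' protein alignments are codon-consistent.
#'
#' @param cds_a,cds_b,cds_out ungapped CDS strings.
#' @param level `"nucleotide"` or `"amino_acid"`.
#' @param mask optional logical vector over alignment columns restricting
#'   the homologous region; default marks columns where both paralogs are
#'   ungapped.
#' @return object of class `triplet_alignment` with `aligned_a`,
#'   `aligned_b`, `aligned_out`, `level`, `homologous_mask`.
#' @export
build_triplet_alignment <- function(cds_a, cds_b, cds_out,
                                    level = c("nucleotide", "amino_acid"),
                                    mask = NULL) {
  level <- match.arg(level)
  aa_a <- translate_cds(cds_a)
  aa_b <- translate_cds(cds_b)
  aa_o <- translate_cds(cds_out)
  aln_ab <- global_align(aa_a, aa_b, "amino_acid")
  aln_ao <- global_align(aa_a, aa_o, "amino_acid")
  m <- .merge_on_anchor(aln_ab, aln_ao)
  if (level == "amino_acid") {
    sa <- paste(m$a, collapse = ""); sb <- paste(m$b, collapse = "")
    so <- paste(m$o, collapse = "")
  } else {
    sa <- .backthread(m$a, attr(aa_a, "codons"))
    sb <- .backthread(m$b, attr(aa_b, "codons"))
    so <- .backthread(m$o, attr(aa_o, "codons"))
  }
  ca <- strsplit(sa, "")[[1]]; cb <- strsplit(sb, "")[[1]]
  if (is.null(mask)) mask <- ca != "-" & cb != "-"
  if (length(mask) != length(ca))
    stop("mask length must equal alignment length")
  structure(list(aligned_a = sa, aligned_b = sb, aligned_out = so,
                 level = level, homologous_mask = mask),
            class = "triplet_alignment")
}

#' Construct a triplet alignment from already-aligned strings
#'
#' @param aligned_a,aligned_b,aligned_out equal-length gapped strings.
#' @param level `"nucleotide"` or `"amino_acid"`.
#' @param mask optional logical mask (default: both paralogs ungapped).
#' @return a `triplet_alignment`.
#' @export
triplet_alignment <- function(aligned_a, aligned_b, aligned_out,
                              level = c("nucleotide", "amino_acid"),
                              mask = NULL) {
  level <- match.arg(level)
  n <- nchar(aligned_a)
  if (nchar(aligned_b) != n || nchar(aligned_out) != n)
    stop("aligned sequences must have equal length")
  ca <- strsplit(toupper(aligned_a), "")[[1]]
  cb <- strsplit(toupper(aligned_b), "")[[1]]
  if (is.null(mask)) mask <- ca != "-" & cb != "-"
  if (length(mask) != n) stop("mask length must equal alignment length")
  structure(list(aligned_a = toupper(aligned_a),
                 aligned_b = toupper(aligned_b),
                 aligned_out = toupper(aligned_out),
                 level = level, homologous_mask = mask),
            class = "triplet_alignment")
}

#' @export
print.triplet_alignment <- function(x, ...) {
  cat("<triplet_alignment> ", nchar(x$aligned_a), " ", x$level,
      " columns, ", sum(x$homologous_mask), " in homologous mask\n",
      sep = "")
  invisible(x)
}
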