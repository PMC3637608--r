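#' @useDynLib paralogasym, .registration = TRUE
#' @importFrom Rcpp sourceCpp
#' @import stats
#' @importFrom utils read.delim write.table capture.output packageVersion
NULL

.NT_CHARS <- c("A", "C", "G", "T", "N", "-")
.AA_CHARS <- c("A", "R", "N", "D", "C", "Q", "E", "G", "H", "I", "L", "K",
               "M", "F", "P", "S", "T", "W", "Y", "V", "X", "*", "-")

#' Read a FASTA file into a validated sequence collection
#'
#' Thin wrapper around [Biostrings::readBStringSet()] that uppercases
#' residues, enforces the declared alphabet (nucleotide: ACGT plus the
#' ambiguity code N; amino acid: the 20 standard residues plus X and the
#' stop symbol), allows the gap character \code{-}, and rejects duplicate
#' record ids. Record order is preserved.
#'
#' @param path path to a FASTA file.
#' @param alphabet `"nucleotide"` or `"amino_acid"`.
#' @return a named character vector of residues (class `seq_collection`),
#'   with attribute `alphabet`; names are the FASTA ids (first whitespace
#'   token of each header), full headers kept in attribute `descriptions`.
#' @export
read_fasta <- function(path, alphabet = c("nucleotide", "amino_acid")) {
  alphabet <- match.arg(alphabet)
  if (!file.exists(path)) stop("file not found: ", path)
  ss <- Biostrings::readBStringSet(path)
  if (length(ss) == 0L) stop("no FASTA records in ", path)
  headers <- names(ss)
  ids <- vapply(strsplit(headers, "[ \t]+"), `[[`, "", 1L)
  if (anyDuplicated(ids))
    stop("duplicate id in ", path, ": ",
         paste(unique(ids[duplicated(ids)]), collapse = ", "))
  res <- toupper(as.character(ss))
  ok <- if (alphabet == "nucleotide") .NT_CHARS else .AA_CHARS
  for (i in seq_along(res)) {
    if (nchar(res[[i]]) == 0L) stop("empty sequence for id ", ids[[i]])
    bad <- setdiff(unique(strsplit(res[[i]], "")[[1]]), ok)
    if (length(bad))
      stop("illegal ", alphabet, " character(s) in record '", ids[[i]],
           "': ", paste(bad, collapse = ""))
  }
  structure(setNames(res, ids), descriptions = setNames(headers, ids),
            alphabet = alphabet, class = "seq_collection")
}

#' Write a sequence collection to FASTA
#'
#' @param seqs named character vector (as returned by [read_fasta()]).
#' @param path output path.
#' @param width line-wrap width.
#' @return `path`, invisibly.
#' @export
write_fasta <- function(seqs, path, width = 70L) {
  ss <- Biostrings::BStringSet(unclass(seqs))
  Biostrings::writeXStringSet(ss, path, width = width)
  invisible(path)
}

#' @export
print.seq_collection <- function(x, ...) {
  cat("<seq_collection> ", length(x), " ", attr(x, "alphabet"),
      " sequence(s); lengths ", min(nchar(x)), "-", max(nchar(x)), "\n",
      sep = "")
  invisible(x)
}

.parse_exons <- function(s, gene_id) {
  if (is.na(s) || !nzchar(s)) stop("gene ", gene_id, ": no exons")
  parts <- strsplit(strsplit(s, ",")[[1]], "-")
  ex <- t(vapply(parts, function(p) {
    if (length(p) != 2L) stop("gene ", gene_id, ": malformed exon field")
    as.integer(p)
  }, integer(2)))
  colnames(ex) <- c("start", "end")
  if (any(is.na(ex))) stop("gene ", gene_id, ": non-numeric exon bound")
  if (any(ex[, "start"] >= ex[, "end"]))
    stop("gene ", gene_id, ": exon start >= end")
  o <- order(ex[, "start"])
  ex <- ex[o, , drop = FALSE]
  if (nrow(ex) > 1L && any(ex[-1L, "start"] < ex[-nrow(ex), "end"]))
    stop("gene ", gene_id, ": overlapping exons")
  ex
}

#' Read the gene-annotation table
#'
#' Tab-separated, one row per gene, columns: `gene_id`, `chromosome`,
#' `strand` (+/-), `start`, `end` (0-based half-open gene span), `exons`
#' (comma-separated `start-end` pairs, 0-based half-open, within the span),
#' `pseudogene` (0/1), and optional `ortholog_id`, `ortholog_chromosome`.
#'
#' @param path path to the TSV file.
#' @return a data.frame keyed by `gene_id` with a list-column `exons` of
#'   two-column integer matrices.
#' @export
read_annotations <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("gene_id", "chromosome", "strand", "start", "end", "exons",
            "pseudogene")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("annotation table missing column(s): ",
                         paste(miss, collapse = ", "))
  if (anyDuplicated(df$gene_id))
    stop("duplicate gene_id: ",
         paste(unique(df$gene_id[duplicated(df$gene_id)]), collapse = ", "))
  if (!all(df$strand %in% c("+", "-")))
    stop("strand must be '+' or '-'")
  out <- data.frame(gene_id = df$gene_id, chromosome = df$chromosome,
                    strand = df$strand,
                    start = as.integer(df$start), end = as.integer(df$end),
                    pseudogene = as.integer(df$pseudogene) != 0L,
                    ortholog_id = if ("ortholog_id" %in% names(df))
                      ifelse(nzchar(df$ortholog_id), df$ortholog_id, NA_character_)
                    else NA_character_,
                    ortholog_chromosome = if ("ortholog_chromosome" %in% names(df))
                      ifelse(nzchar(df$ortholog_chromosome),
                             df$ortholog_chromosome, NA_character_)
                    else NA_character_,
                    stringsAsFactors = FALSE)
  bad <- out$gene_id[is.na(out$start) | is.na(out$end) | out$start >= out$end |
                       out$start < 0L]
  if (length(bad)) stop("invalid span for gene ", paste(bad, collapse = ", "))
  out$exons <- lapply(seq_len(nrow(df)),
                      function(i) .parse_exons(df$exons[[i]], df$gene_id[[i]]))
  names(out$exons) <- out$gene_id
  for (i in seq_len(nrow(out))) {
    ex <- out$exons[[i]]
    if (min(ex[, "start"]) < out$start[[i]] || max(ex[, "end"]) > out$end[[i]])
      stop("gene ", out$gene_id[[i]], ": exon outside gene span")
  }
  rownames(out) <- out$gene_id
  out
}

#' Write a gene-annotation table
#'
#' Inverse of [read_annotations()].
#' @param annot annotation data.frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_annotations <- function(annot, path) {
  df <- annot
  df$exons <- vapply(annot$exons, function(ex)
    paste(paste0(ex[, "start"], "-", ex[, "end"]), collapse = ","), "")
  df$pseudogene <- as.integer(df$pseudogene)
  df$ortholog_id[is.na(df$ortholog_id)] <- ""
  df$ortholog_chromosome[is.na(df$ortholog_chromosome)] <- ""
  write.table(df, path, sep = "\t", quote = FALSE, row.names = FALSE)
  invisible(path)
}

#' Read and cross-validate the pairing manifest
#'
#' The manifest is a TSV with columns `pair_id`, `paralog_a`, `paralog_b`,
#' `outgroup` and optional `outgroup_source`. Every id must resolve to a
#' loaded sequence, and the two paralogs must additionally carry
#' annotations.
#'
#' @param path path to the manifest TSV.
#' @param sequences a `seq_collection` (or plain named vector) holding all
#'   referenced sequences.
#' @param annotations annotation data.frame from [read_annotations()], or
#'   `NULL` to skip the annotation cross-check.
#' @return data.frame of validated triplets.
#' @export
read_manifest <- function(path, sequences, annotations = NULL) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- read.delim(path, stringsAsFactors = FALSE, colClasses = "character")
  need <- c("pair_id", "paralog_a", "paralog_b", "outgroup")
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("manifest missing column(s): ",
                         paste(miss, collapse = ", "))
  if (nrow(df) == 0L) {
    warning("empty manifest: ", path)
    df$outgroup_source <- character(0)
    return(df[c(need, "outgroup_source")])
  }
  if (!"outgroup_source" %in% names(df)) df$outgroup_source <- NA_character_
  if (anyDuplicated(df$pair_id)) stop("duplicate pair_id in manifest")
  if (any(df$paralog_a == df$paralog_b))
    stop("paralog_a == paralog_b for pair ",
         paste(df$pair_id[df$paralog_a == df$paralog_b], collapse = ", "))
  refd <- unique(c(df$paralog_a, df$paralog_b, df$outgroup))
  unresolved <- setdiff(refd, names(sequences))
  if (length(unresolved))
    stop("manifest references absent sequence id(s): ",
         paste(unresolved, collapse = ", "))
  if (!is.null(annotations)) {
    unannot <- setdiff(unique(c(df$paralog_a, df$paralog_b)),
                       annotations$gene_id)
    if (length(unannot))
      stop("manifest references unannotated gene(s): ",
           paste(unannot, collapse = ", "))
  }
  df[c(need, "outgroup_source")]
}
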