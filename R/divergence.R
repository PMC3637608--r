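# Synonymous divergence (K_S) between paralogs: Nei-Gojobori (1986)
# counting with Jukes-Cantor correction, over the codon alignment induced
# by back-threading the protein alignment.

.codon_table <- function() Biostrings::GENETIC_CODE

# Per-codon synonymous site count: for each position, the fraction of
# non-stop single-base alternatives that preserve the amino acid, summed
# over the three positions. Stop-codon targets are excluded from both
# numerator and denominator.
.syn_sites_codon <- local({
  cache <- NULL
  function() {
    if (!is.null(cache)) return(cache)
    gc <- .codon_table()
    nts <- c("A", "C", "G", "T")
    codons <- names(gc)
    s <- setNames(numeric(length(codons)), codons)
    for (cd in codons) {
      if (gc[[cd]] == "*") { s[[cd]] <- NA_real_; next }
      tot <- 0
      for (pos in 1:3) {
        alts <- setdiff(nts, substr(cd, pos, pos))
        nsyn <- 0; nvalid <- 0
        for (x in alts) {
          alt <- cd
          substr(alt, pos, pos) <- x
          if (gc[[alt]] == "*") next
          nvalid <- nvalid + 1
          if (gc[[alt]] == gc[[cd]]) nsyn <- nsyn + 1
        }
        if (nvalid > 0) tot <- tot + nsyn / nvalid
      }
      s[[cd]] <- tot
    }
    cache <<- s
    s
  }
})

# syn/nonsyn difference counts between two codons, averaged over all
# minimal substitution pathways; pathways traversing a stop codon are
# excluded (unless every pathway does, in which case all are used).
.codon_diffs <- function(c1, c2) {
  gc <- .codon_table()
  pos <- which(strsplit(c1, "")[[1]] != strsplit(c2, "")[[1]])
  nd <- length(pos)
  if (nd == 0L) return(c(syn = 0, nonsyn = 0))
  perms <- if (nd == 1L) list(pos)
  else if (nd == 2L) list(pos, rev(pos))
  else list(pos[c(1, 2, 3)], pos[c(1, 3, 2)], pos[c(2, 1, 3)],
            pos[c(2, 3, 1)], pos[c(3, 1, 2)], pos[c(3, 2, 1)])
  path_counts <- list(); path_ok <- logical(0)
  for (p in perms) {
    cur <- c1; syn <- 0; nonsyn <- 0; ok <- TRUE
    for (k in p) {
      nxt <- cur
      substr(nxt, k, k) <- substr(c2, k, k)
      if (gc[[nxt]] == "*" || gc[[cur]] == "*") ok <- FALSE
      if (gc[[nxt]] == gc[[cur]]) syn <- syn + 1 else nonsyn <- nonsyn + 1
      cur <- nxt
    }
    path_counts[[length(path_counts) + 1L]] <- c(syn = syn, nonsyn = nonsyn)
    path_ok <- c(path_ok, ok)
  }
  use <- if (any(path_ok)) path_counts[path_ok] else path_counts
  Reduce(`+`, use) / length(use)
}

#' Nei-Gojobori (1986) synonymous and nonsynonymous divergence
#'
#' Counts synonymous/nonsynonymous sites per codon (fraction of non-stop
#' single-base changes that are synonymous, averaged over the two
#' sequences) and observed differences with equal weighting over all
#' minimal substitution pathways (stop-traversing pathways excluded), then
#' applies the Jukes-Cantor correction `d = -3/4 log(1 - 4p/3)` to the
#' proportions. Codons containing a gap, an ambiguity code, or a stop in
#' either sequence are skipped.
#'
#' @param aligned_cds_a,aligned_cds_b equal-length gapped codon-aligned
#'   nucleotide strings (alignment length divisible by 3).
#' @return object of class `ks_estimate`: `ks`, `ka` (NA when saturated),
#'   `syn_sites`, `nonsyn_sites`, `syn_diffs`, `nonsyn_diffs`,
#'   `saturated`.
#' @export
ng86_divergence <- function(aligned_cds_a, aligned_cds_b) {
  a <- toupper(as.character(aligned_cds_a))
  b <- toupper(as.character(aligned_cds_b))
  if (nchar(a) != nchar(b)) stop("aligned sequences must have equal length")
  if (nchar(a) %% 3L != 0L) stop("alignment length must be divisible by 3")
  st <- .syn_sites_codon()
  gc <- .codon_table()
  n_cod <- nchar(a) %/% 3L
  S <- 0; Sd <- 0; Nd <- 0; used <- 0L
  for (i in seq_len(n_cod)) {
    c1 <- substr(a, 3L * i - 2L, 3L * i)
    c2 <- substr(b, 3L * i - 2L, 3L * i)
    if (grepl("[^ACGT]", c1) || grepl("[^ACGT]", c2)) next
    if (gc[[c1]] == "*" || gc[[c2]] == "*") next
    S <- S + (st[[c1]] + st[[c2]]) / 2
    d <- .codon_diffs(c1, c2)
    Sd <- Sd + d[["syn"]]; Nd <- Nd + d[["nonsyn"]]
    used <- used + 1L
  }
  if (used == 0L) stop("no comparable codons")
  Ns <- 3 * used - S
  ps <- if (S > 0) Sd / S else 0
  pn <- if (Ns > 0) Nd / Ns else 0
  jc <- function(p) if (p >= 0.75) NA_real_ else -0.75 * log(1 - 4 * p / 3)
  ks <- jc(ps); ka <- jc(pn)
  structure(list(ks = ks, ka = ka, syn_sites = S, nonsyn_sites = Ns,
                 syn_diffs = Sd, nonsyn_diffs = Nd,
                 saturated = is.na(ks) || is.na(ka), n_codons = used),
            class = "ks_estimate")
}

#' @export
print.ks_estimate <- function(x, ...) {
  cat("<ks_estimate> Ks = ", signif(x$ks, 4), ", Ka = ", signif(x$ka, 4),
      " (", x$n_codons, " codons", if (x$saturated) ", saturated" else "",
      ")\n", sep = "")
  invisible(x)
}

.COHORT_BREAKS <- c(0, 0.01, 0.03, 0.05, 0.08, 0.14)
.COHORT_LABELS <- c("[0,0.01)", "[0.01,0.03)", "[0.03,0.05)",
                    "[0.05,0.08)", "[0.08,0.14)")

#' Assign a synonymous-divergence value to its age cohort
#'
#' Five half-open bins on K_S: \[0,0.01), \[0.01,0.03), \[0.03,0.05),
#' \[0.05,0.08), \[0.08,0.14). Values at or above 0.14 return
#' `"out_of_range"` (excluded from cohort profiles, retained elsewhere).
#'
#' @param ks non-negative K_S value(s).
#' @return factor with the five cohort labels plus `"out_of_range"`.
#' @export
assign_cohort <- function(ks) {
  if (any(is.na(ks))) stop("ks must be non-missing")
  if (any(ks < 0)) stop("negative ks")
  idx <- findInterval(ks, .COHORT_BREAKS, rightmost.closed = FALSE)
  lab <- ifelse(idx >= 1 & idx <= 5, .COHORT_LABELS[pmin(idx, 5L)],
                "out_of_range")
  lab[ks >= 0.14] <- "out_of_range"
  factor(lab, levels = c(.COHORT_LABELS, "out_of_range"))
}

#' Cohort definitions
#'
#' @return data.frame of cohort labels and half-open K_S bounds.
#' @export
age_cohorts <- function() {
  data.frame(label = .COHORT_LABELS,
             lower = .COHORT_BREAKS[-6],
             upper = .COHORT_BREAKS[-1])
}
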