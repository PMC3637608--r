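# Unique-site counting, the relative-rate chi-square test, and the
# continuous per-site asymmetry statistics.

# unreadable states per level: the nucleotide ambiguity code is N, the
# amino-acid one is X (N is asparagine there); '*' marks a translated stop
.ambig_chars <- function(level)
  if (level == "nucleotide") c("N", "-") else c("X", "*", "-")

#' Count sites unique to each paralog relative to the outgroup
#'
#' Scans alignment columns inside the homologous mask where none of the
#' three sequences carries a gap or ambiguity code (N for nucleotide, X for
#' amino acid). A column counts toward `m_a` when paralog A's state differs
#' from both paralog B and the outgroup while B equals the outgroup
#' (`m_b` symmetrically). Columns where all three states are pairwise
#' distinct are tallied separately (`n_alldiff`) and, by default, excluded
#' from `m_a`/`m_b` but retained in the usable length `L`.
#'
#' @param t a `triplet_alignment`.
#' @return object of class `unique_site_counts`: `m_a`, `m_b`, `n_alldiff`,
#'   `L`, `level`.
#' @export
count_unique_sites <- function(t) {
  stopifnot(inherits(t, "triplet_alignment"))
  ca <- strsplit(t$aligned_a, "")[[1]]
  cb <- strsplit(t$aligned_b, "")[[1]]
  co <- strsplit(t$aligned_out, "")[[1]]
  amb <- .ambig_chars(t$level)
  usable <- t$homologous_mask &
    !(ca %in% amb) & !(cb %in% amb) & !(co %in% amb)
  L <- sum(usable)
  if (L == 0L) stop("no homologous sites")
  a <- ca[usable]; b <- cb[usable]; o <- co[usable]
  m_a <- sum(a != b & a != o & b == o)
  m_b <- sum(b != a & b != o & a == o)
  n_alldiff <- sum(a != b & b != o & a != o)
  structure(list(m_a = m_a, m_b = m_b, n_alldiff = n_alldiff, L = L,
                 level = t$level),
            class = "unique_site_counts")
}

#' @export
print.unique_site_counts <- function(x, ...) {
  cat("<unique_site_counts> m_a=", x$m_a, " m_b=", x$m_b, " all-diff=",
      x$n_alldiff, " L=", x$L, " (", x$level, ")\n", sep = "")
  invisible(x)
}

#' Relative-rate chi-square test on unique-site counts
#'
#' Tests the molecular-clock null of equal substitution rates on the two
#' paralog branches: under the null the `m_a + m_b` unique sites split
#' evenly, giving `chi^2 = (m_a - m_b)^2 / (m_a + m_b)` on 1 df (upper
#' tail, no continuity correction). When `m_a + m_b == 0` the statistic is
#' 0 and p = 1.
#'
#' @param counts a `unique_site_counts` object, or a list with `m_a`,`m_b`.
#' @param alpha significance level for the `significant` flag.
#' @param include_alldiff if TRUE, sites where all three states differ are
#'   added to both `m_a` and `m_b` before testing (alternative convention;
#'   default FALSE).
#' @return object of class `relrate_result`: `counts`, `chi_square`,
#'   `p_value`, `significant`.
#' @export
tajima_test <- function(counts, alpha = 0.05, include_alldiff = FALSE) {
  m_a <- counts$m_a; m_b <- counts$m_b
  if (isTRUE(include_alldiff) && !is.null(counts$n_alldiff)) {
    m_a <- m_a + counts$n_alldiff
    m_b <- m_b + counts$n_alldiff
  }
  tot <- m_a + m_b
  if (tot == 0) {
    chi <- 0; p <- 1
  } else {
    chi <- (m_a - m_b)^2 / tot
    p <- pchisq(chi, df = 1, lower.tail = FALSE)
  }
  structure(list(counts = counts, chi_square = chi, p_value = p,
                 significant = p < alpha, alpha = alpha),
            class = "relrate_result")
}

#' @export
print.relrate_result <- function(x, ...) {
  cat("<relrate_result> chi^2 = ", signif(x$chi_square, 5), ", p = ",
      signif(x$p_value, 4), if (x$significant) " *" else "", "\n", sep = "")
  invisible(x)
}

#' Minimal unique-site difference detectable at a given total
#'
#' For a fixed total number of unique sites `m_a + m_b`, the smallest
#' absolute difference `|m_a - m_b|` whose relative-rate chi-square exceeds
#' the `alpha` critical value on 1 df. Illustrates the test's limited power
#' for young duplicates (e.g. 9 at a total of 20).
#'
#' @param total total unique sites on the two branches.
#' @param alpha significance level.
#' @return smallest integer difference rejecting the equal-rates null.
#' @export
min_detectable_difference <- function(total, alpha = 0.05) {
  stopifnot(total >= 1)
  crit <- qchisq(1 - alpha, df = 1)
  for (d in 0:total) if (d^2 / total > crit) return(as.integer(d))
  NA_integer_
}

#' Per-site asymmetry between paralogs
#'
#' The absolute difference in unique-site counts scaled by the usable
#' homologous length: `|m_a - m_b| / L`. Zero indicates equal rates.
#'
#' @param counts a `unique_site_counts`.
#' @return non-negative number.
#' @export
asymmetry_per_site <- function(counts) {
  if (is.null(counts$L) || counts$L <= 0) stop("L must be positive")
  abs(counts$m_a - counts$m_b) / counts$L
}

#' Signed standardized asymmetry (ancestral minus derived)
#'
#' `(m_ancestral - m_derived) / L`; negative values mean the derived copy
#' accumulated more unique sites (i.e. evolved faster).
#'
#' @param counts a `unique_site_counts` for the pair (A, B order as built).
#' @param ancestral_is_a TRUE if paralog A is the ancestral copy; NA is an
#'   error (assignment required).
#' @return signed number.
#' @export
signed_standardized_asymmetry <- function(counts, ancestral_is_a) {
  if (is.na(ancestral_is_a)) stop("ancestral/derived assignment missing")
  if (is.null(counts$L) || counts$L <= 0) stop("L must be positive")
  d <- if (isTRUE(ancestral_is_a)) counts$m_a - counts$m_b
       else counts$m_b - counts$m_a
  d / counts$L
}
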