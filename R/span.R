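# Duplication-span detection and structural classification.
#
# The homology detector operationalises "no homology apparent": a stretch is
# called non-homologous iff no sliding window of `window_bp` columns reaches
# `min_identity` matching. Starting from a homologous seed, the examined
# region is extended outward in `step_bp` increments on each side
# independently; a side terminates when the most recently examined stretch
# contains no qualifying window. Short (< step_bp) interruptions therefore do
# not terminate the region.

#' Homology-detection configuration
#'
#' @param window_bp sliding-window width (alignment columns).
#' @param min_identity minimum fraction of identical columns for a window to
#'   count as homologous.
#' @param step_bp outward extension increment; a side of the region
#'   terminates when a full increment contains no homologous window.
#' @return list of config values.
#' @export
homology_config <- function(window_bp = 100L, min_identity = 0.6,
                            step_bp = 1000L) {
  stopifnot(window_bp >= 10L, min_identity > 0, min_identity <= 1,
            step_bp >= window_bp)
  list(window_bp = as.integer(window_bp), min_identity = min_identity,
       step_bp = as.integer(step_bp))
}

# Boolean per alignment column: covered by at least one window of
# window_bp consecutive columns with >= min_identity matches.
.homologous_columns <- function(match, window_bp, min_identity) {
  n <- length(match)
  if (n < window_bp) return(rep(FALSE, n))
  cs <- cumsum(c(0L, as.integer(match)))
  wsum <- cs[(window_bp + 1L):(n + 1L)] - cs[1L:(n - window_bp + 1L)]
  ok_start <- wsum >= min_identity * window_bp          # window start indices
  hom <- rep(FALSE, n)
  if (!any(ok_start)) return(hom)
  # mark all columns covered by any qualifying window
  d <- integer(n + 1L)
  ws <- which(ok_start)
  for (s in ws) { d[s] <- d[s] + 1L; d[min(s + window_bp, n + 1L)] <- d[min(s + window_bp, n + 1L)] - 1L }
  cumsum(d[seq_len(n)]) > 0L
}

#' Locate the homologous region shared by two genomic contexts
#'
#' Globally aligns the two contexts, identifies homologous alignment columns
#' with a sliding identity window, then walks outward from a homologous seed
#' in `step_bp` increments on each side. A side is *terminated* (its
#' duplication termination point found) when a full increment holds no
#' homologous window; if the sequence runs out first, the side is flagged
#' unterminated ("flank exhausted") rather than an error.
#'
#' @param a_context,b_context character scalars: each paralog's genomic
#'   context (ORF plus available flanks), sense strand, ungapped.
#' @param config list from [homology_config()].
#' @param seed optional length-2 integer vector: 0-based half-open bounds,
#'   in `a_context`, of a region known to be homologous (e.g. the ORF);
#'   defaults to the best-scoring homologous window.
#' @return object of class `homology_region`: 0-based half-open bounds
#'   `a_start`,`a_end`,`b_start`,`b_end`, flags `terminated_5prime`,
#'   `terminated_3prime`, and the underlying `alignment`.
#' @export
find_homology_region <- function(a_context, b_context,
                                 config = homology_config(), seed = NULL) {
  aln <- global_align(a_context, b_context, "nucleotide")
  match <- .match_profile(aln)
  n <- length(match)
  hom <- .homologous_columns(match, config$window_bp, config$min_identity)
  if (!any(hom)) stop("pair not homologous: no window of ", config$window_bp,
                      " columns reaches ", config$min_identity, " identity")
  # seed columns
  if (!is.null(seed)) {
    seed_cols <- which(!is.na(aln$map_a) & aln$map_a > seed[[1L]] &
                         aln$map_a <= seed[[2L]] & hom)
    if (length(seed_cols) == 0L) seed_cols <- which(hom)
  } else seed_cols <- which(hom)
  s <- min(seed_cols); e <- max(seed_cols)
  # contiguity-aware outward walk: extend while each next step window holds
  # a homologous column
  step <- config$step_bp
  terminated_3 <- FALSE
  repeat {
    if (e >= n) {                                          # flank exhausted
      terminated_3 <- FALSE
      message("flank exhausted on 3' side before a ", step,
              " bp homology-free stretch was seen")
      break
    }
    slice <- (e + 1L):min(e + step, n)
    h <- slice[hom[slice]]
    if (length(h)) { e <- max(h); next }
    if (length(slice) == step) { terminated_3 <- TRUE } else {
      terminated_3 <- FALSE
      message("flank exhausted on 3' side before a ", step,
              " bp homology-free stretch was seen")
    }
    break
  }
  terminated_5 <- FALSE
  repeat {
    if (s <= 1L) {
      terminated_5 <- FALSE
      message("flank exhausted on 5' side before a ", step,
              " bp homology-free stretch was seen")
      break
    }
    slice <- max(s - step, 1L):(s - 1L)
    h <- slice[hom[slice]]
    if (length(h)) { s <- min(h); next }
    if (length(slice) == step) { terminated_5 <- TRUE } else {
      terminated_5 <- FALSE
      message("flank exhausted on 5' side before a ", step,
              " bp homology-free stretch was seen")
    }
    break
  }
  cols <- s:e
  # trim to columns that are actually homologous at the edges
  cols <- cols[hom[cols]]
  a_pos <- aln$map_a[cols]; a_pos <- a_pos[!is.na(a_pos)]
  b_pos <- aln$map_b[cols]; b_pos <- b_pos[!is.na(b_pos)]
  if (!length(a_pos) || !length(b_pos))
    stop("pair not homologous: region degenerate")
  structure(list(a_start = min(a_pos) - 1L, a_end = max(a_pos),
                 b_start = min(b_pos) - 1L, b_end = max(b_pos),
                 terminated_5prime = terminated_5,
                 terminated_3prime = terminated_3,
                 alignment = aln),
            class = "homology_region")
}

#' @export
print.homology_region <- function(x, ...) {
  cat("<homology_region> A [", x$a_start, ",", x$a_end, ") B [",
      x$b_start, ",", x$b_end, ") terminated 5'/3': ",
      x$terminated_5prime, "/", x$terminated_3prime, "\n", sep = "")
  invisible(x)
}

#' Duplication span of a pair
#'
#' The span is the length (bp) of sequence homology shared by the two
#' paralogs between their duplication termination points. Each paralog is
#' treated in turn as the ancestral copy (its ungapped length over the
#' region), and the lower, conservative value of the two is reported.
#'
#' @param region a `homology_region`.
#' @return list of class `span_result`: `span_a`, `span_b`, `span`
#'   (`= min(span_a, span_b)`).
#' @export
duplication_span <- function(region) {
  stopifnot(inherits(region, "homology_region"))
  span_a <- region$a_end - region$a_start
  span_b <- region$b_end - region$b_start
  if (span_a < 1L || span_b < 1L) stop("degenerate homology region")
  structure(list(span_a = span_a, span_b = span_b,
                 span = min(span_a, span_b)),
            class = "span_result")
}

#' @export
print.span_result <- function(x, ...) {
  cat("<span_result> span ", x$span, " (A ", x$span_a, ", B ", x$span_b,
      ")\n", sep = "")
  invisible(x)
}

#' Structural classification of a duplicate pair
#'
#' An exon is *unique* to a paralog iff less than `overlap_fraction` of its
#' length lies inside that paralog's homology bounds. Pairs where neither
#' paralog has unique exons are `complete`; exactly one, `partial`; both,
#' `chimeric`. The classification is symmetric in the paralog labels.
#'
#' @param annot_a,annot_b single annotation rows (data.frame rows from
#'   [read_annotations()]).
#' @param region a `homology_region` computed from the pair's contexts.
#' @param offset_a,offset_b genomic coordinate of position 0 of the context
#'   each paralog contributed to `region` (so exon coordinates can be
#'   compared with the region bounds).
#' @param overlap_fraction uniqueness threshold (default 0.5).
#' @return list of class `structure_class`: `value` (one of `"complete"`,
#'   `"partial"`, `"chimeric"`), `unique_exons_a`, `unique_exons_b`.
#' @export
classify_structure <- function(annot_a, annot_b, region,
                               offset_a = 0L, offset_b = 0L,
                               overlap_fraction = 0.5) {
  stopifnot(inherits(region, "homology_region"))
  count_unique <- function(exons, hom_start, hom_end) {
    if (is.null(exons) || nrow(exons) == 0L) stop("empty exon list")
    ov <- pmax(0L, pmin(exons[, "end"], hom_end) -
                 pmax(exons[, "start"], hom_start))
    sum(ov < overlap_fraction * (exons[, "end"] - exons[, "start"]))
  }
  ua <- count_unique(annot_a$exons[[1L]],
                     region$a_start + offset_a, region$a_end + offset_a)
  ub <- count_unique(annot_b$exons[[1L]],
                     region$b_start + offset_b, region$b_end + offset_b)
  value <- if (ua == 0L && ub == 0L) "complete"
           else if (ua > 0L && ub > 0L) "chimeric"
           else "partial"
  structure(list(value = value, unique_exons_a = ua, unique_exons_b = ub),
            class = "structure_class")
}

#' @export
print.structure_class <- function(x, ...) {
  cat("<structure_class> ", x$value, " (unique exons A/B: ",
      x$unique_exons_a, "/", x$unique_exons_b, ")\n", sep = "")
  invisible(x)
}
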