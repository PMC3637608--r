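# Orchestration: per-pair feature extraction, ancestral/derived assignment,
# and the full inference battery rendered as a structured report.

# internal exon boundaries as offsets from the gene's first exon start
.internal_boundaries <- function(exons) {
  b <- sort(unique(c(exons[, "start"], exons[, "end"])))
  origin <- min(exons[, "start"])
  b <- b - origin
  b[b > 0 & b < max(b)]
}

.boundary_score <- function(exons, exons_out, tol = 6L) {
  ba <- .internal_boundaries(exons)
  bo <- .internal_boundaries(exons_out)
  if (!length(bo)) return(0L)
  sum(vapply(bo, function(x) any(abs(ba - x) <= tol), NA))
}

#' Assign ancestral versus derived status within a duplicate pair
#'
#' Two rules, mirroring synteny and structural conservation with the
#' outgroup ortholog. The synteny rule applies when the paralogs reside on
#' different chromosomes and exactly one shares the outgroup ortholog's
#' chromosome label: that copy is ancestral. The structure rule applies
#' when the paralogs' exon-boundary similarity scores to the outgroup
#' (shared internal boundaries within `tol` bp, as offsets from the gene
#' start) differ: the more similar copy is ancestral. If both rules apply
#' they must agree (otherwise `"conflicting"`); if neither discriminates
#' the pair is `"unassigned"`.
#'
#' @param annot_a,annot_b annotation rows for the two paralogs.
#' @param annot_out annotation row for the outgroup ortholog, or NULL.
#' @param tol exon-boundary match tolerance in bp.
#' @return list: `ancestral_id` (NA if unassigned), `method` (`"synteny"`,
#'   `"structure"`, `"both"`, `"unassigned"`, `"conflicting"`), `reason`.
#' @export
assign_ancestral <- function(annot_a, annot_b, annot_out, tol = 6L) {
  if (is.null(annot_out) || !nrow(annot_out))
    return(list(ancestral_id = NA_character_, method = "unassigned",
                reason = "no outgroup annotation"))
  syn <- NA_character_
  if (annot_a$chromosome != annot_b$chromosome) {
    ja <- annot_a$chromosome == annot_out$chromosome
    jb <- annot_b$chromosome == annot_out$chromosome
    if (xor(ja, jb)) syn <- if (ja) annot_a$gene_id else annot_b$gene_id
  }
  sa <- .boundary_score(annot_a$exons[[1L]], annot_out$exons[[1L]], tol)
  sb <- .boundary_score(annot_b$exons[[1L]], annot_out$exons[[1L]], tol)
  str <- NA_character_
  if (sa != sb) str <- if (sa > sb) annot_a$gene_id else annot_b$gene_id
  if (!is.na(syn) && !is.na(str)) {
    if (syn == str)
      return(list(ancestral_id = syn, method = "both", reason = "agree"))
    return(list(ancestral_id = NA_character_, method = "conflicting",
                reason = "synteny and structure rules disagree"))
  }
  if (!is.na(syn))
    return(list(ancestral_id = syn, method = "synteny", reason = ""))
  if (!is.na(str))
    return(list(ancestral_id = str, method = "structure", reason = ""))
  list(ancestral_id = NA_character_, method = "unassigned",
       reason = "neither rule discriminates")
}

# nearest-edge genomic distance between two annotation spans (0 if they
# touch or overlap)
.genomic_distance <- function(a, b)
  max(0L, max(a$start, b$start) - min(a$end, b$end))

#' Load a dataset directory written by [simulate_dataset()]
#'
#' @param dir directory containing `cds.fasta`, `contexts.fasta`,
#'   `annotations.tsv`, `manifest.tsv`, `context_offsets.tsv` and
#'   optionally `truth.tsv`.
#' @return list with elements matching [simulate_dataset()]'s return.
#' @export
load_dataset <- function(dir) {
  cds <- read_fasta(file.path(dir, "cds.fasta"), "nucleotide")
  contexts <- read_fasta(file.path(dir, "contexts.fasta"), "nucleotide")
  annotations <- read_annotations(file.path(dir, "annotations.tsv"))
  manifest <- read_manifest(file.path(dir, "manifest.tsv"),
                            c(unclass(cds), unclass(contexts)), annotations)
  off <- read.delim(file.path(dir, "context_offsets.tsv"),
                    stringsAsFactors = FALSE)
  offsets <- setNames(as.numeric(off$offset), off$gene_id)
  truth <- NULL
  tf <- file.path(dir, "truth.tsv")
  if (file.exists(tf)) truth <- read.delim(tf, stringsAsFactors = FALSE)
  list(cds = cds, contexts = contexts, annotations = annotations,
       manifest = manifest, truth = truth, context_offsets = offsets)
}

#' Extract per-pair features and rate statistics
#'
#' Runs the sequence stages for every manifest triplet: homology-region and
#' span detection on the genomic contexts, structural classification,
#' triplet alignment with unique-site counting and relative-rate tests at
#' the nucleotide and amino-acid level, NG86 K_S, and ancestral/derived
#' assignment.
#'
#' @param data list with `cds`, `contexts`, `annotations`, `manifest`,
#'   `context_offsets` (see [simulate_dataset()], [load_dataset()]).
#' @param config homology-detection configuration ([homology_config()]).
#' @param alpha significance level for the relative-rate tests.
#' @return data.frame (`pair_features`), one row per pair; failed pairs are
#'   flagged in the `note` column and carry NA statistics.
#' @export
build_pair_features <- function(data, config = homology_config(),
                                alpha = 0.05) {
  man <- data$manifest
  ann <- data$annotations
  rows <- vector("list", nrow(man))
  for (i in seq_len(nrow(man))) {
    pid <- man$pair_id[[i]]
    ida <- man$paralog_a[[i]]; idb <- man$paralog_b[[i]]
    ido <- man$outgroup[[i]]
    row <- list(pair_id = pid, paralog_a = ida, paralog_b = idb,
                outgroup = ido, note = "")
    res <- try({
      aa <- ann[ida, ]; ab <- ann[idb, ]
      ao <- if (ido %in% rownames(ann)) ann[ido, ] else NULL
      # --- span & structure --------------------------------------------
      region <- find_homology_region(data$contexts[[ida]],
                                     data$contexts[[idb]], config)
      sp <- duplication_span(region)
      st <- classify_structure(aa, ab, region,
                               offset_a = data$context_offsets[[ida]],
                               offset_b = data$context_offsets[[idb]])
      # --- triplet statistics ------------------------------------------
      trip_nt <- build_triplet_alignment(data$cds[[ida]], data$cds[[idb]],
                                         data$cds[[ido]], "nucleotide")
      trip_aa <- build_triplet_alignment(data$cds[[ida]], data$cds[[idb]],
                                         data$cds[[ido]], "amino_acid")
      cnt_nt <- count_unique_sites(trip_nt)
      cnt_aa <- count_unique_sites(trip_aa)
      tt_nt <- tajima_test(cnt_nt, alpha)
      tt_aa <- tajima_test(cnt_aa, alpha)
      ks <- ng86_divergence(trip_nt$aligned_a, trip_nt$aligned_b)
      anc <- assign_ancestral(aa, ab, ao)
      same_chr <- aa$chromosome == ab$chromosome
      row <- c(row[1:4], list(
        structure3 = st$value,
        structure = if (st$value == "complete") "homogeneous"
                    else "heterogeneous",
        chromosome_relation = if (same_chr) "same" else "different",
        orientation = if (same_chr) {
          if (aa$strand == ab$strand) "same" else "opposite"
        } else NA_character_,
        genomic_distance_bp = if (same_chr) .genomic_distance(aa, ab)
                              else NA_integer_,
        span_bp = sp$span, span_a = sp$span_a, span_b = sp$span_b,
        ks = ks$ks, ka = ks$ka, ks_saturated = ks$saturated,
        m_a_nt = cnt_nt$m_a, m_b_nt = cnt_nt$m_b, L_nt = cnt_nt$L,
        chi_nt = tt_nt$chi_square, p_nt = tt_nt$p_value,
        significant_nt = tt_nt$significant,
        m_a_aa = cnt_aa$m_a, m_b_aa = cnt_aa$m_b, L_aa = cnt_aa$L,
        chi_aa = tt_aa$chi_square, p_aa = tt_aa$p_value,
        significant_aa = tt_aa$significant,
        asym_nt = asymmetry_per_site(cnt_nt),
        asym_aa = asymmetry_per_site(cnt_aa),
        pseudogene_pair = isTRUE(aa$pseudogene) || isTRUE(ab$pseudogene),
        ancestral_id = anc$ancestral_id,
        ancestral_method = anc$method,
        signed_asym_nt = if (!is.na(anc$ancestral_id))
          signed_standardized_asymmetry(cnt_nt, anc$ancestral_id == ida)
        else NA_real_,
        signed_asym_aa = if (!is.na(anc$ancestral_id))
          signed_standardized_asymmetry(cnt_aa, anc$ancestral_id == ida)
        else NA_real_,
        note = ""))
      row
    }, silent = TRUE)
    if (inherits(res, "try-error")) {
      row$note <- paste("failed:", conditionMessage(attr(res, "condition")))
      rows[[i]] <- row
    } else rows[[i]] <- res
  }
  # pad failed rows to the full column set
  all_cols <- Reduce(union, lapply(rows, names))
  df <- do.call(rbind, lapply(rows, function(r) {
    miss <- setdiff(all_cols, names(r))
    for (m in miss) r[[m]] <- NA
    as.data.frame(r[all_cols], stringsAsFactors = FALSE)
  }))
  df$cohort <- NA_character_
  has_ks <- !is.na(df$ks)
  if (any(has_ks))
    df$cohort[has_ks] <- as.character(assign_cohort(pmax(0, df$ks[has_ks])))
  df
}

.block_skip <- function(reason) list(skipped = TRUE, reason = reason)

.regression_block <- function(y, X, force_all = FALSE) {
  ok <- stats::complete.cases(y, X)
  if (sum(ok) <= ncol(X) + 2L) return(.block_skip("insufficient data"))
  ea <- if (force_all) 1 else 0.15
  sa <- if (force_all) 1 else 0.10
  m <- stepwise_regression(y[ok], X[ok, , drop = FALSE],
                           entry_alpha = ea, stay_alpha = sa)
  m$n_used <- sum(ok)
  m
}

#' Run the full analysis battery
#'
#' Produces one block per analysis: the per-pair table; the cohort
#' significance profile; stepwise regressions of per-site asymmetry on
#' structure, chromosomal location, duplication span and K_S at both
#' levels; the same-chromosome sub-model (genomic distance + orientation,
#' full least squares); pseudogene comparisons (G-test over structural
#' classes and rank-sum tests on asymmetry); the span-by-structure
#' Kruskal-Wallis test; rank correlations of K_S with asymmetry; and the
#' ancestral-versus-derived signed-rank tests. Blocks with insufficient
#' data are marked skipped, never silently absent.
#'
#' @param data dataset list (see [build_pair_features()]), or NULL if
#'   `features` is supplied directly.
#' @param features optional precomputed pair-features data.frame.
#' @param config homology-detection configuration.
#' @param alpha significance level for the relative-rate tests.
#' @return object of class `analysis_report`.
#' @export
run_full_analysis <- function(data = NULL, features = NULL,
                              config = homology_config(), alpha = 0.05) {
  if (is.null(features)) {
    stopifnot(!is.null(data))
    features <- build_pair_features(data, config, alpha)
  }
  pf <- features[features$note == "" | is.na(features$note), ]
  blocks <- list()

  # cohort profile (Fig-1 analogue)
  ck <- pf[!is.na(pf$ks), ]
  blocks$cohort_profile <- if (nrow(ck))
    cohort_significance_profile(assign_cohort(pmax(0, ck$ks)),
                                ck$significant_nt, ck$significant_aa)
  else .block_skip("no pairs with a K_S estimate")

  pred <- data.frame(structure = pf$structure,
                     chromosome_relation = pf$chromosome_relation,
                     span_bp = pf$span_bp, ks = pf$ks,
                     stringsAsFactors = FALSE)
  blocks$regression_nt <- .regression_block(pf$asym_nt, pred)
  blocks$regression_aa <- .regression_block(pf$asym_aa, pred)

  # same-chromosome sub-analysis: distance + orientation, full LS fit
  sc <- pf[!is.na(pf$chromosome_relation) & pf$chromosome_relation == "same", ]
  if (nrow(sc) >= 8 && length(unique(sc$orientation)) == 2L) {
    Xs <- data.frame(genomic_distance_bp = sc$genomic_distance_bp,
                     orientation = sc$orientation, stringsAsFactors = FALSE)
    blocks$same_chromosome_nt <- .regression_block(sc$asym_nt, Xs,
                                                   force_all = TRUE)
    blocks$same_chromosome_aa <- .regression_block(sc$asym_aa, Xs,
                                                   force_all = TRUE)
  } else {
    blocks$same_chromosome_nt <- .block_skip("too few same-chromosome pairs")
    blocks$same_chromosome_aa <- .block_skip("too few same-chromosome pairs")
  }

  # pseudogene composition across the three structural classes
  tab <- table(factor(ifelse(pf$pseudogene_pair, "pseudogene", "functional"),
                      levels = c("functional", "pseudogene")),
               factor(pf$structure3,
                      levels = c("complete", "partial", "chimeric")))
  blocks$pseudogene_structure_gtest <-
    if (all(rowSums(tab) > 0) && all(colSums(tab) > 0))
      g_test_williams(tab) else .block_skip("zero marginal in table")
  ps <- pf$pseudogene_pair
  blocks$pseudogene_asym_nt <- if (sum(ps) >= 2 && sum(!ps) >= 2)
    wilcoxon_rank_sum(pf$asym_nt[ps], pf$asym_nt[!ps])
  else .block_skip("too few pseudogene pairs")
  blocks$pseudogene_asym_aa <- if (sum(ps) >= 2 && sum(!ps) >= 2)
    wilcoxon_rank_sum(pf$asym_aa[ps], pf$asym_aa[!ps])
  else .block_skip("too few pseudogene pairs")

  # span by structural class
  gs <- split(pf$span_bp, pf$structure3)
  gs <- gs[lengths(gs) > 0]
  blocks$span_by_structure <- if (length(gs) >= 2)
    kruskal_wallis(gs) else .block_skip("fewer than 2 structural classes")

  # K_S vs asymmetry rank correlation
  blocks$ks_asym_tau_nt <- if (nrow(pf) >= 3)
    kendall_tau(pf$ks, pf$asym_nt) else .block_skip("too few pairs")
  blocks$ks_asym_tau_aa <- if (nrow(pf) >= 3)
    kendall_tau(pf$ks, pf$asym_aa) else .block_skip("too few pairs")

  # ancestral vs derived (signed-rank on the assigned subset only)
  sub <- pf[!is.na(pf$ancestral_id), ]
  blocks$ancestral_derived_nt <- if (nrow(sub) >= 5)
    wilcoxon_signed_rank(sub$signed_asym_nt)
  else .block_skip("fewer than 5 assigned pairs")
  blocks$ancestral_derived_aa <- if (nrow(sub) >= 5)
    wilcoxon_signed_rank(sub$signed_asym_aa)
  else .block_skip("fewer than 5 assigned pairs")
  blocks$n_assigned <- nrow(sub)

  structure(list(features = features, blocks = blocks,
                 provenance = list(alpha = alpha, config = config,
                                   n_pairs = nrow(features),
                                   n_analysed = nrow(pf),
                                   package_version =
                                     as.character(utils::packageVersion("paralogasym")),
                                   timestamp = format(Sys.time(), "%Y-%m-%d"))),
            class = "analysis_report")
}

#' @export
print.analysis_report <- function(x, ...) {
  cat("== Paralog rate-asymmetry analysis report ==\n")
  cat("Pairs analysed:", x$provenance$n_analysed, "of",
      x$provenance$n_pairs, "\n\n")
  cat("-- Cohort significance profile --\n")
  print(x$blocks$cohort_profile)
  for (nm in c("regression_nt", "regression_aa")) {
    cat("\n-- Stepwise regression (", sub("regression_", "", nm),
        " asymmetry/site) --\n", sep = "")
    b <- x$blocks[[nm]]
    if (isTRUE(b$skipped)) cat("skipped:", b$reason, "\n") else print(b)
  }
  simple <- c(pseudogene_structure_gtest = "Pseudogene x structure G-test",
              pseudogene_asym_nt = "Pseudogene vs functional asym (nt)",
              pseudogene_asym_aa = "Pseudogene vs functional asym (aa)",
              span_by_structure = "Span by structure (Kruskal-Wallis)",
              ks_asym_tau_nt = "Ks vs asym tau (nt)",
              ks_asym_tau_aa = "Ks vs asym tau (aa)",
              ancestral_derived_nt = "Ancestral vs derived signed-rank (nt)",
              ancestral_derived_aa = "Ancestral vs derived signed-rank (aa)")
  cat("\n-- Tests --\n")
  for (nm in names(simple)) {
    b <- x$blocks[[nm]]
    cat(simple[[nm]], ": ", sep = "")
    if (isTRUE(b$skipped)) cat("skipped (", b$reason, ")\n", sep = "")
    else cat(b$statistic_name, "=", signif(b$value, 5), ", p =",
             signif(b$p_value, 4), "\n")
  }
  invisible(x)
}

#' Write an analysis report to disk
#'
#' Writes `pair_features.tsv`, a machine-readable `report.json`, and a
#' human-readable `report.txt`.
#'
#' @param report an `analysis_report`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
write_report <- function(report, dir) {
  if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
  write.table(report$features, file.path(dir, "pair_features.tsv"),
              sep = "\t", quote = FALSE, row.names = FALSE)
  strip <- function(b) {
    if (inherits(b, "stepwise_model"))
      return(list(selected_terms = b$selected_terms,
                  coefficients = b$coefficients, r_square = b$r_square,
                  r_square_adj = b$r_square_adj, rmse = b$rmse,
                  mean_response = b$mean_response, n = b$n,
                  anova = b$anova))
    if (inherits(b, "asym_test")) return(unclass(b))
    b
  }
  json <- jsonlite::toJSON(list(blocks = lapply(report$blocks, strip),
                                provenance = report$provenance),
                           auto_unbox = TRUE, digits = NA, na = "null",
                           pretty = TRUE)
  writeLines(json, file.path(dir, "report.json"))
  txt <- utils::capture.output(print(report))
  writeLines(txt, file.path(dir, "report.txt"))
  invisible(dir)
}
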