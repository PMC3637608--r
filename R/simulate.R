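# Synthetic paralog-triplet data with known ground truth.
#
# Generative model: an ancestral coding/genomic tract is duplicated; each
# copy then accumulates a Poisson number of substitutions on its own branch
# under an equal-rates (Jukes-Cantor-style) placement, with the derived
# branch's rate multiplied by an asymmetry factor. The outgroup diverges
# from the ancestral sequence on a deeper branch. Expected pairwise
# synonymous divergence is calibrated to a target K_S.

.SENSE_CODONS <- local({
  gc <- NULL
  function() {
    if (is.null(gc)) gc <<- names(Biostrings::GENETIC_CODE)[
      Biostrings::GENETIC_CODE != "*"]
    gc
  }
})

.random_cds <- function(n_codons)
  paste(sample(.SENSE_CODONS(), n_codons, replace = TRUE), collapse = "")

.random_dna <- function(n)
  paste(sample(c("A", "C", "G", "T"), n, replace = TRUE), collapse = "")

# expected per-site substitution density giving Jukes-Cantor distance d
.p_from_d <- function(d) 0.75 * (1 - exp(-4 * d / 3))

# Apply k substitutions at uniform positions (uniform choice among the
# three alternative bases). `codon_starts` lists 1-based start positions of
# codons within `seq`; a substitution that would turn such a codon into a
# stop is redrawn (substitutions elsewhere are unconstrained).
.mutate <- function(seq, k, codon_starts = integer(0)) {
  if (k == 0L) return(seq)
  x <- strsplit(seq, "")[[1]]
  n <- length(x)
  codon_of <- integer(n)
  for (cs in codon_starts) codon_of[cs:(cs + 2L)] <- cs
  gc <- Biostrings::GENETIC_CODE
  pos <- sample.int(n, k, replace = TRUE)
  nts <- c("A", "C", "G", "T")
  for (p in pos) {
    alts <- setdiff(nts, x[p])
    nb <- NA_character_
    while (length(alts)) {
      cand <- if (length(alts) == 1L) alts else sample(alts, 1L)
      if (codon_of[p] > 0L) {
        cs <- codon_of[p]
        cod <- x[cs:(cs + 2L)]
        cod[p - cs + 1L] <- cand
        if (gc[[paste(cod, collapse = "")]] == "*") {
          alts <- setdiff(alts, cand)
          next
        }
      }
      nb <- cand
      break
    }
    if (!is.na(nb)) x[p] <- nb
  }
  paste(x, collapse = "")
}

#' Simulate one paralog triplet (coding sequences only)
#'
#' An ancestral CDS is drawn uniformly over sense codons; the two paralogs
#' receive independent Poisson substitution counts with the derived
#' branch's expectation multiplied by `asymmetry_factor` (the total is
#' calibrated so the expected pairwise synonymous divergence equals
#' `ks_target`); the outgroup receives `outgroup_depth` times the total
#' pairwise expectation. Substitutions are placed uniformly with a uniform
#' choice among the three alternative bases; changes creating a stop codon
#' are redrawn. No indels, so the three sequences are returned pre-aligned.
#'
#' @param n_codons CDS length in codons (>= 30).
#' @param ks_target target pairwise synonymous divergence (0 <= ks < 0.75).
#' @param asymmetry_factor rate multiplier (>= 1) on the derived branch.
#' @param outgroup_depth outgroup branch length as a multiple of the total
#'   paralog-pair divergence (default 3).
#' @return list: `cds_ancestral`, `cds_derived`, `cds_outgroup` (the
#'   ancestral-branch copy, the accelerated copy, the outgroup) and
#'   `truth` (per-branch substitution counts and generating parameters).
#' @export
simulate_triplet <- function(n_codons, ks_target, asymmetry_factor = 1,
                             outgroup_depth = 3) {
  stopifnot(n_codons >= 30, ks_target >= 0, asymmetry_factor >= 1,
            outgroup_depth > 0)
  if (ks_target >= 0.75) stop("ks_target too large to calibrate")
  anc <- .random_cds(n_codons)
  L <- 3L * n_codons
  lambda_pair <- .p_from_d(ks_target) * L
  f <- asymmetry_factor
  k_anc <- rpois(1L, lambda_pair / (1 + f))
  k_der <- rpois(1L, lambda_pair * f / (1 + f))
  k_out <- rpois(1L, outgroup_depth * lambda_pair)
  frames <- seq(1L, L, by = 3L)
  list(cds_ancestral = .mutate(anc, k_anc, frames),
       cds_derived = .mutate(anc, k_der, frames),
       cds_outgroup = .mutate(anc, k_out, frames),
       truth = list(n_sub_ancestral = k_anc, n_sub_derived = k_der,
                    n_sub_outgroup = k_out, ks_target = ks_target,
                    asymmetry_factor = f, n_codons = n_codons))
}

#' Simulation configuration
#'
#' Defaults emulate the study conditions of the analysed dataset: 130
#' duplicate pairs with K_S spanning \[0, 0.14), an L-shaped (log-normal)
#' duplication-span distribution with median near 1.7 kb, structure-class
#' mix of roughly one half complete / one fifth partial / three tenths
#' chimeric, about a quarter of pairs with one copy relocated to a
#' different chromosome, 15% pseudogene-containing pairs, and 2 kb of
#' retrievable flanking sequence. The asymmetry model maps each pair's
#' features to the derived-branch rate multiplier
#' `max(1, 1 + b0 + b_ks*ks + b_reloc*relocated + b_span*span)`, giving the
#' downstream regression a recoverable positive K_S effect, positive
#' relocation effect and negative span effect.
#'
#' @param n_pairs number of duplicate pairs.
#' @param cds_codons length-2 range of CDS lengths (codons).
#' @param ks_range length-2 range for uniform K_S sampling.
#' @param outgroup_depth outgroup depth multiplier.
#' @param asymmetry_model coefficients `b0`, `b_ks`, `b_reloc`, `b_span`.
#' @param p_relocation probability one copy is on a different chromosome.
#' @param structure_probs probabilities of (complete, partial, chimeric).
#' @param span_meanlog,span_sdlog,span_min,span_max log-normal span law
#'   (bp), truncated.
#' @param p_pseudogene probability a pair contains a pseudogene.
#' @param flank_bp flanking sequence available on each side.
#' @return list of class `sim_config`.
#' @export
sim_config <- function(n_pairs = 130L,
                       cds_codons = c(120L, 320L),
                       ks_range = c(0, 0.14),
                       outgroup_depth = 3,
                       asymmetry_model = list(b0 = 1.0, b_ks = 15,
                                              b_reloc = 1.0,
                                              b_span = -2e-4),
                       p_relocation = 0.26,
                       structure_probs = c(complete = 0.5, partial = 0.2,
                                           chimeric = 0.3),
                       span_meanlog = log(1670), span_sdlog = 0.8,
                       span_min = 600L, span_max = 10646L,
                       p_pseudogene = 0.15,
                       flank_bp = 2000L) {
  stopifnot(n_pairs >= 1, length(cds_codons) == 2, cds_codons[1] >= 30,
            ks_range[1] >= 0, ks_range[2] <= 0.14,
            p_relocation >= 0, p_relocation <= 1,
            p_pseudogene >= 0, p_pseudogene <= 1,
            length(structure_probs) == 3,
            abs(sum(structure_probs) - 1) < 1e-8,
            span_min >= 128, span_max > span_min)
  structure(as.list(environment()), class = "sim_config")
}

.draw_span <- function(cfg) {
  repeat {
    s <- rlnorm(1L, cfg$span_meanlog, cfg$span_sdlog)
    if (s >= cfg$span_min && s <= cfg$span_max) return(as.integer(round(s)))
  }
}

.asym_factor <- function(model, ks, relocated, span)
  max(1, 1 + model$b0 + model$b_ks * ks + model$b_reloc * as.numeric(relocated) +
        model$b_span * span)

# Partition n_codons of CDS into exons of ~50 codons with short introns;
# returns list(exon_codons, intron_lens)
.gene_layout <- function(n_codons) {
  n_ex <- max(2L, min(6L, round(n_codons / 60)))
  cuts <- sort(sample(seq_len(n_codons - 1L), n_ex - 1L))
  exon_codons <- diff(c(0L, cuts, n_codons))
  intron_lens <- sample(60:200, n_ex - 1L, replace = TRUE)
  list(exon_codons = exon_codons, intron_lens = intron_lens)
}

#' Simulate a complete synthetic dataset
#'
#' Generates `n_pairs` paralog triplets with genomic context and writes (or
#' returns) the exact dialects the readers consume: a FASTA of spliced CDS,
#' a FASTA of genomic contexts (tract plus flanks), the annotation TSV, the
#' pairing manifest, and a ground-truth table. Structure classes are
#' realised by truncating the duplicated tract inside the gene (partial) or
#' additionally granting the derived copy a novel exon (chimeric);
#' relocation places the derived copy on a different chromosome; the
#' derived branch's substitution rate is multiplied by the asymmetry factor
#' computed from the pair's features via `asymmetry_model`.
#'
#' Which paralog of each pair is listed as `paralog_a` in the manifest is
#' randomised, and the truth table records the ancestral copy's id.
#'
#' @param config a `sim_config`.
#' @param dir optional output directory; when given, files
#'   `cds.fasta`, `contexts.fasta`, `annotations.tsv`, `manifest.tsv`,
#'   `truth.tsv` are written there.
#' @return invisibly, a list with `cds` and `contexts` (named vectors),
#'   `annotations` (data.frame), `manifest` (data.frame), `truth`
#'   (data.frame), `context_offsets` (named vector: genomic coordinate of
#'   context position 0).
#' @export
simulate_dataset <- function(config = sim_config(), dir = NULL) {
  cfg <- config
  chroms <- c("chrI", "chrII", "chrIII", "chrIV", "chrV", "chrX")
  cds <- character(0); contexts <- character(0)
  annot_rows <- list(); manifest_rows <- list(); truth_rows <- list()
  offsets <- numeric(0)

  for (i in seq_len(cfg$n_pairs)) {
    pair_id <- sprintf("pair%04d", i)
    structure_true <- sample(names(cfg$structure_probs), 1L,
                             prob = cfg$structure_probs)
    relocated <- runif(1L) < cfg$p_relocation
    ks <- runif(1L, cfg$ks_range[1], cfg$ks_range[2])
    span_target <- .draw_span(cfg)

    # --- ancestral gene ---------------------------------------------------
    # size the gene to the span: complete spans cover the gene with shared
    # flank left over; partial/chimeric tracts end inside the gene
    if (structure_true == "complete") {
      g_target <- round(span_target * 0.7)
    } else {
      g_target <- round(span_target * 1.4)
    }
    n_codons <- max(cfg$cds_codons[1],
                    min(cfg$cds_codons[2], g_target %/% 4L))
    lay <- .gene_layout(n_codons)
    n_ex <- length(lay$exon_codons)
    anc_cds <- .random_cds(n_codons)
    # assemble gene: exons from the CDS, random introns
    exon_nt <- substring(anc_cds,
                         cumsum(c(0L, lay$exon_codons[-n_ex])) * 3L + 1L,
                         cumsum(lay$exon_codons) * 3L)
    introns <- vapply(lay$intron_lens, .random_dna, "")
    gene <- exon_nt[1L]
    for (k in seq_len(n_ex - 1L))
      gene <- paste0(gene, introns[k], exon_nt[k + 1L])
    g_len <- nchar(gene)
    # exon coordinates within the gene (0-based half-open)
    ex_start <- integer(n_ex); ex_end <- integer(n_ex)
    posn <- 0L
    for (k in seq_len(n_ex)) {
      ex_start[k] <- posn
      posn <- posn + nchar(exon_nt[k])
      ex_end[k] <- posn
      if (k < n_ex) posn <- posn + lay$intron_lens[k]
    }

    # --- duplicated tract -------------------------------------------------
    up <- .random_dna(cfg$flank_bp)
    down <- .random_dna(cfg$flank_bp)
    locus <- paste0(up, gene, down)           # ancestral locus sequence
    gene_at <- cfg$flank_bp                   # gene start within locus
    if (structure_true == "complete") {
      extra <- span_target - g_len
      ls <- min(cfg$flank_bp, max(0L, extra %/% 2L))
      rs <- min(cfg$flank_bp, max(0L, extra - ls))
      w_start <- gene_at - ls
      w_end <- gene_at + g_len + rs
      cut_exon <- n_ex + 1L                  # none excluded
    } else {
      # cut inside the intron preceding a terminal exon so that at least
      # one exon is excluded from the tract
      cut_exon <- if (n_ex == 2L) 2L else sample(2:n_ex, 1L)  # first excluded exon
      cut_pos <- ex_start[cut_exon] - max(10L, lay$intron_lens[cut_exon - 1L] %/% 2L)
      ls <- min(cfg$flank_bp, max(0L, span_target - cut_pos))
      w_start <- gene_at - ls
      w_end <- gene_at + cut_pos
    }
    w_start <- max(0L, w_start); w_end <- min(nchar(locus), w_end)
    tract <- substr(locus, w_start + 1L, w_end)
    true_span <- nchar(tract)

    # --- evolve the two copies -------------------------------------------
    factor_i <- .asym_factor(cfg$asymmetry_model, ks, relocated, true_span)
    p_pair <- .p_from_d(ks)
    lambda_pair <- p_pair * true_span
    k_anc <- rpois(1L, lambda_pair / (1 + factor_i))
    k_der <- rpois(1L, lambda_pair * factor_i / (1 + factor_i))

    # exon boundaries are codon-aligned, so codons never span introns;
    # protect the coding frame of exons retained in the tract from stops
    if (structure_true == "complete") keep_tract <- seq_len(n_ex)
    else keep_tract <- seq_len(cut_exon - 1L)
    tract_codon_starts <- unlist(lapply(keep_tract, function(k) {
      s <- (gene_at - w_start) + ex_start[k]          # tract-local, 0-based
      seq(s + 1L, s + (ex_end[k] - ex_start[k]), by = 3L)
    }))
    anc_tract <- .mutate(tract, k_anc, tract_codon_starts)
    der_tract <- .mutate(tract, k_der, tract_codon_starts)
    # rebuild the ancestral copy's locus with its evolved tract
    anc_locus <- paste0(substr(locus, 1L, w_start), anc_tract,
                        substr(locus, w_end + 1L, nchar(locus)))

    # derived copy context: new random flanks around its tract; chimeric
    # copies gain a novel exon just downstream of the tract
    der_up <- .random_dna(cfg$flank_bp)
    der_down <- .random_dna(cfg$flank_bp)
    novel_exon <- ""
    if (structure_true == "chimeric")
      novel_exon <- .random_cds(sample(30:50, 1L))
    der_gap <- if (nzchar(novel_exon))
      paste0(.random_dna(80L), novel_exon) else ""
    der_locus <- paste0(der_up, der_tract, der_gap, der_down)

    # --- per-copy annotations --------------------------------------------
    id_anc <- paste0(pair_id, "_anc")
    id_der <- paste0(pair_id, "_der")
    id_out <- paste0(pair_id, "_out")
    chr_anc <- sample(chroms, 1L)
    chr_der <- if (relocated) sample(setdiff(chroms, chr_anc), 1L) else chr_anc
    anc_gstart <- sample(50000:2000000, 1L)
    # genomic distance on same chromosome: log-uniform gap
    gap_bp <- round(exp(runif(1L, log(2000), log(5e6))))
    der_gstart <- if (relocated) sample(50000:2000000, 1L) else
      anc_gstart + g_len + gap_bp
    strand_anc <- sample(c("+", "-"), 1L)
    strand_der <- sample(c("+", "-"), 1L)

    # ancestral copy exons in genomic coords (gene at offset gene_at in
    # context; genomic start anc_gstart corresponds to context position 0)
    anc_ex <- cbind(start = anc_gstart + gene_at + ex_start,
                    end = anc_gstart + gene_at + ex_end)
    anc_span <- c(anc_gstart + gene_at, anc_gstart + gene_at + g_len)

    # derived copy: exons that survive in the tract (fully left of the cut)
    keep <- keep_tract
    der_gene_at <- cfg$flank_bp + (gene_at - w_start)  # gene start in context
    der_ex_local <- cbind(start = der_gene_at + ex_start[keep],
                          end = der_gene_at + ex_end[keep])
    if (nzchar(novel_exon)) {
      ne_start <- cfg$flank_bp + nchar(der_tract) + 80L
      der_ex_local <- rbind(der_ex_local,
                            c(ne_start, ne_start + nchar(novel_exon)))
    }
    der_ex <- cbind(start = der_gstart + (der_ex_local[, 1L] - cfg$flank_bp),
                    end = der_gstart + (der_ex_local[, 2L] - cfg$flank_bp))
    der_span <- c(min(der_ex[, 1L]), max(der_ex[, 2L]))

    # derived CDS: retained exons (evolved states from its tract) + novel
    der_cds <- paste(substring(der_locus, der_ex_local[, 1L] + 1L,
                               der_ex_local[, 2L]), collapse = "")

    # ancestral copy CDS: its (evolved) exons from its locus
    anc_cds_evolved <- paste(substring(anc_locus,
                                       gene_at + ex_start + 1L,
                                       gene_at + ex_end), collapse = "")

    # outgroup: evolved from the ancestral CDS on a deeper branch
    k_out <- rpois(1L, cfg$outgroup_depth * .p_from_d(ks) * 3L * n_codons)
    out_cds <- .mutate(anc_cds, k_out, seq(1L, 3L * n_codons, by = 3L))
    out_chr <- chr_anc                       # synteny: outgroup marks the
                                             # ancestral genomic position
    out_gstart <- sample(50000:2000000, 1L)
    out_ex <- cbind(start = out_gstart + ex_start, end = out_gstart + ex_end)

    pseudo <- runif(1L) < cfg$p_pseudogene   # independent of asymmetry

    # randomise which copy is listed first
    a_is_anc <- runif(1L) < 0.5
    id_a <- if (a_is_anc) id_anc else id_der
    id_b <- if (a_is_anc) id_der else id_anc

    cds[[id_anc]] <- anc_cds_evolved
    cds[[id_der]] <- der_cds
    cds[[id_out]] <- out_cds
    contexts[[id_anc]] <- anc_locus
    contexts[[id_der]] <- der_locus
    # genomic coordinate of context position 0 (the ancestral context
    # starts at anc_gstart; the derived tract starts at der_gstart)
    offsets[[id_anc]] <- anc_gstart
    offsets[[id_der]] <- der_gstart - cfg$flank_bp

    annot_rows[[id_anc]] <- list(gene_id = id_anc, chromosome = chr_anc,
                                 strand = strand_anc,
                                 start = anc_span[1], end = anc_span[2],
                                 exons = anc_ex, pseudogene = FALSE,
                                 ortholog_id = id_out,
                                 ortholog_chromosome = out_chr)
    annot_rows[[id_der]] <- list(gene_id = id_der, chromosome = chr_der,
                                 strand = strand_der,
                                 start = der_span[1], end = der_span[2],
                                 exons = der_ex, pseudogene = pseudo,
                                 ortholog_id = id_out,
                                 ortholog_chromosome = out_chr)
    annot_rows[[id_out]] <- list(gene_id = id_out, chromosome = out_chr,
                                 strand = "+",
                                 start = out_gstart,
                                 end = out_gstart + g_len,
                                 exons = out_ex, pseudogene = FALSE,
                                 ortholog_id = NA_character_,
                                 ortholog_chromosome = NA_character_)

    manifest_rows[[pair_id]] <- list(pair_id = pair_id, paralog_a = id_a,
                                     paralog_b = id_b, outgroup = id_out,
                                     outgroup_source = "synthetic_outgroup")
    truth_rows[[pair_id]] <- list(pair_id = pair_id, true_ks = ks,
                                  true_asymmetry_factor = factor_i,
                                  true_span_bp = true_span,
                                  true_structure = structure_true,
                                  relocated = relocated,
                                  ancestral_id = id_anc,
                                  n_sub_ancestral = k_anc,
                                  n_sub_derived = k_der,
                                  n_sub_outgroup = k_out,
                                  pseudogene_pair = pseudo)
  }

  to_df <- function(rows) {
    do.call(rbind, lapply(rows, function(r)
      as.data.frame(r[setdiff(names(r), "exons")], stringsAsFactors = FALSE)))
  }
  annotations <- to_df(annot_rows)
  annotations$exons <- lapply(annot_rows, function(r) {
    ex <- r$exons
    storage.mode(ex) <- "integer"
    dimnames(ex) <- list(NULL, c("start", "end"))
    ex
  })
  rownames(annotations) <- annotations$gene_id
  manifest <- to_df(manifest_rows)
  truth <- to_df(truth_rows)
  rownames(manifest) <- NULL; rownames(truth) <- NULL

  out <- list(cds = structure(cds, alphabet = "nucleotide",
                              class = "seq_collection"),
              contexts = structure(contexts, alphabet = "nucleotide",
                                   class = "seq_collection"),
              annotations = annotations, manifest = manifest, truth = truth,
              context_offsets = offsets, config = cfg)

  if (!is.null(dir)) {
    if (!dir.exists(dir)) dir.create(dir, recursive = TRUE)
    write_fasta(out$cds, file.path(dir, "cds.fasta"))
    write_fasta(out$contexts, file.path(dir, "contexts.fasta"))
    write_annotations(out$annotations, file.path(dir, "annotations.tsv"))
    write.table(out$manifest, file.path(dir, "manifest.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(out$truth, file.path(dir, "truth.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
    write.table(data.frame(gene_id = names(offsets), offset = offsets),
                file.path(dir, "context_offsets.tsv"), sep = "\t",
                quote = FALSE, row.names = FALSE)
  }
  invisible(out)
}

#' Simulate a feature-level dataset of duplicate pairs
#'
#' Draws each pair's genomic features (K_S, relocation, span, structure,
#' pseudogene status) from the configured laws and realises unique-site
#' counts directly from the Poisson branch model (the same sampling
#' distribution the sequence-level generator induces), without sequence
#' realisation. Used for regression power/recovery studies at large n.
#'
#' @param config a `sim_config`.
#' @return data.frame with one row per pair: features (`ks`, `span_bp`,
#'   `chromosome_relation`, `structure`, `pseudogene_pair`), counts
#'   (`m_ancestral`, `m_derived`, `L_nt`), the response `asym_nt`, and the
#'   generating `true_asymmetry_factor`.
#' @export
simulate_pair_features <- function(config = sim_config()) {
  cfg <- config
  n <- cfg$n_pairs
  ks <- runif(n, cfg$ks_range[1], cfg$ks_range[2])
  relocated <- runif(n) < cfg$p_relocation
  span <- vapply(seq_len(n), function(i) .draw_span(cfg), 0L)
  structure3 <- sample(names(cfg$structure_probs), n, replace = TRUE,
                       prob = cfg$structure_probs)
  L <- 3L * round(runif(n, cfg$cds_codons[1], cfg$cds_codons[2]))
  f <- vapply(seq_len(n), function(i)
    .asym_factor(cfg$asymmetry_model, ks[i], relocated[i], span[i]), 0)
  lambda_pair <- .p_from_d(ks) * L
  m_anc <- rpois(n, lambda_pair / (1 + f))
  m_der <- rpois(n, lambda_pair * f / (1 + f))
  data.frame(pair_id = sprintf("pair%05d", seq_len(n)),
             ks = ks, span_bp = span,
             chromosome_relation = ifelse(relocated, "different", "same"),
             structure = ifelse(structure3 == "complete", "homogeneous",
                                "heterogeneous"),
             structure3 = structure3,
             pseudogene_pair = runif(n) < cfg$p_pseudogene,
             m_ancestral = m_anc, m_derived = m_der, L_nt = L,
             asym_nt = abs(m_anc - m_der) / L,
             signed_asym_nt = (m_anc - m_der) / L,
             true_asymmetry_factor = f,
             stringsAsFactors = FALSE)
}
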