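# Independent oracles used to cross-check the package implementations.
# These are deliberately written against the definitions, not the package
# code paths.

# Plain-R Gotoh dynamic programme (score only), same gap convention:
# a gap of length L costs open + (L-1)*extend.
oracle_align_score <- function(a, b, match = 1, mismatch = -1,
                               open = -4, extend = -1) {
  a <- strsplit(a, "")[[1]]; b <- strsplit(b, "")[[1]]
  n <- length(a); m <- length(b)
  NEG <- -1e18
  M <- matrix(NEG, n + 1, m + 1)
  X <- matrix(NEG, n + 1, m + 1)   # gap in a
  Y <- matrix(NEG, n + 1, m + 1)   # gap in b
  M[1, 1] <- 0
  for (j in 2:(m + 1)) X[1, j] <- open + (j - 2) * extend
  for (i in 2:(n + 1)) Y[i, 1] <- open + (i - 2) * extend
  for (i in 2:(n + 1)) for (j in 2:(m + 1)) {
    s <- if (a[i - 1] == b[j - 1]) match else mismatch
    M[i, j] <- max(M[i - 1, j - 1], X[i - 1, j - 1], Y[i - 1, j - 1]) + s
    X[i, j] <- max(M[i, j - 1] + open, X[i, j - 1] + extend,
                   Y[i, j - 1] + open)
    Y[i, j] <- max(M[i - 1, j] + open, X[i - 1, j] + open,
                   Y[i - 1, j] + extend)
  }
  max(M[n + 1, m + 1], X[n + 1, m + 1], Y[n + 1, m + 1])
}

random_dna_str <- function(n) paste(sample(c("A", "C", "G", "T"), n,
                                           replace = TRUE), collapse = "")

# Exhaustive rank-sum null: distribution of the sum of sample-1 ranks over
# all assignments of n1 labels among n1+n2 observations.
oracle_ranksum_exact <- function(a, b) {
  n1 <- length(a); n <- n1 + length(b)
  r <- rank(c(a, b))
  W_obs <- sum(r[seq_len(n1)])
  combs <- utils::combn(n, n1)
  W_all <- apply(combs, 2, function(idx) sum(r[idx]))
  list(W = W_obs,
       p_two_sided = min(1, 2 * min(mean(W_all <= W_obs),
                                    mean(W_all >= W_obs))))
}

# Exhaustive signed-rank null over all 2^n sign assignments (midranks kept).
oracle_signedrank_exact <- function(d) {
  d <- d[d != 0]
  n <- length(d)
  r <- rank(abs(d))
  wpos <- sum(r[d > 0])
  signs <- as.matrix(expand.grid(rep(list(c(0, 1)), n)))
  wdist <- as.vector(signs %*% r)
  list(wpos = wpos,
       p_two_sided = min(1, 2 * min(mean(wdist <= wpos),
                                    mean(wdist >= wpos))))
}

# Brute-force Kendall: concordant/discordant counts over all pairs, exact
# p by enumerating all permutations of y (n <= 6, no ties).
oracle_kendall <- function(x, y, exact_p = FALSE) {
  n <- length(x)
  S <- 0
  for (i in seq_len(n - 1)) for (j in (i + 1):n)
    S <- S + sign(x[j] - x[i]) * sign(y[j] - y[i])
  tau <- S / (n * (n - 1) / 2)
  out <- list(S = S, tau = tau)
  if (exact_p) {
    perms <- combinat_perms(seq_len(n))
    Ss <- apply(perms, 1, function(p) {
      s <- 0
      yy <- y[p]
      for (i in seq_len(n - 1)) for (j in (i + 1):n)
        s <- s + sign(x[j] - x[i]) * sign(yy[j] - yy[i])
      s
    })
    out$p_two_sided <- min(1, 2 * min(mean(Ss <= S), mean(Ss >= S)))
  }
  out
}

combinat_perms <- function(v) {
  if (length(v) == 1L) return(matrix(v, 1, 1))
  out <- NULL
  for (i in seq_along(v)) {
    rest <- combinat_perms(v[-i])
    out <- rbind(out, cbind(v[i], rest))
  }
  out
}

# Williams-corrected G computed straight from the formula.
oracle_g_williams <- function(tab) {
  rs <- rowSums(tab); cs <- colSums(tab); N <- sum(tab)
  E <- outer(rs, cs) / N
  G <- 0
  for (i in seq_len(nrow(tab))) for (j in seq_len(ncol(tab)))
    if (tab[i, j] > 0) G <- G + 2 * tab[i, j] * log(tab[i, j] / E[i, j])
  df <- (nrow(tab) - 1) * (ncol(tab) - 1)
  q <- 1 + (N * sum(1 / rs) - 1) * (N * sum(1 / cs) - 1) / (6 * N * df)
  G / q
}

# Independent stepwise mixed selection using explicit least-squares algebra
# (normal equations), no lm/anova.
oracle_stepwise <- function(y, X, entry = 0.15, stay = 0.10) {
  X <- as.matrix(X)
  n <- length(y)
  rss <- function(cols) {
    Xm <- cbind(1, X[, cols, drop = FALSE])
    beta <- solve(crossprod(Xm), crossprod(Xm, y))
    sum((y - Xm %*% beta)^2)
  }
  p_add <- function(S, t) {
    r0 <- rss(S); r1 <- rss(c(S, t))
    df2 <- n - length(S) - 2
    f <- (r0 - r1) / (r1 / df2)
    pf(f, 1, df2, lower.tail = FALSE)
  }
  included <- character(0)
  cand <- colnames(X)
  seen <- character(0)               # cycle guard, as in the implementation
  repeat {
    changed <- FALSE
    pool <- setdiff(cand, included)
    if (length(pool)) {
      pv <- vapply(pool, function(t) p_add(included, t), 0)
      if (min(pv) <= entry) {
        included <- c(included, pool[which.min(pv)])
        changed <- TRUE
      }
    }
    repeat {
      if (!length(included)) break
      pv <- vapply(included, function(t)
        p_add(setdiff(included, t), t), 0)
      if (max(pv) > stay) {
        included <- setdiff(included, included[which.max(pv)])
        changed <- TRUE
      } else break
    }
    key <- paste(sort(included), collapse = "|")
    if (!changed || key %in% seen) break
    seen <- c(seen, key)
  }
  Xm <- cbind(1, X[, included, drop = FALSE])
  beta <- solve(crossprod(Xm), crossprod(Xm, y))
  list(included = included,
       coefficients = setNames(as.vector(beta), c("(Intercept)", included)))
}

# Build a homology_region object directly (unit-test fixture).
make_region <- function(a_start, a_end, b_start, b_end) {
  structure(list(a_start = a_start, a_end = a_end, b_start = b_start,
                 b_end = b_end, terminated_5prime = TRUE,
                 terminated_3prime = TRUE, alignment = NULL),
            class = "homology_region")
}

# Build a one-row annotation data.frame with a list-column of exons.
make_annot <- function(gene_id, chromosome, strand, exons,
                       pseudogene = FALSE, ortholog_id = NA_character_,
                       ortholog_chromosome = NA_character_) {
  ex <- matrix(as.integer(exons), ncol = 2, byrow = TRUE,
               dimnames = list(NULL, c("start", "end")))
  df <- data.frame(gene_id = gene_id, chromosome = chromosome,
                   strand = strand, start = min(ex[, 1]), end = max(ex[, 2]),
                   pseudogene = pseudogene, ortholog_id = ortholog_id,
                   ortholog_chromosome = ortholog_chromosome,
                   stringsAsFactors = FALSE)
  df$exons <- list(ex)
  rownames(df) <- gene_id
  df
}
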