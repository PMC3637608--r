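# The inference battery: stepwise mixed-selection regression with a final
# least-squares fit, Kendall's tau-b, Wilcoxon two-sample and signed-rank
# tests, Kruskal-Wallis, and the Williams-corrected G-test. All authored
# here; base R equivalents serve as independent cross-checks in the tests.

.test_result <- function(statistic_name, value, p_value, n, df = NA_real_,
                         note = NULL) {
  structure(list(statistic_name = statistic_name, value = value, df = df,
                 p_value = p_value, n = n, note = note),
            class = "asym_test")
}

#' @export
print.asym_test <- function(x, ...) {
  cat("<asym_test> ", x$statistic_name, " = ", signif(x$value, 5),
      if (!is.na(x$df)) paste0(", df = ", x$df) else "",
      ", p = ", signif(x$p_value, 4), "\n", sep = "")
  invisible(x)
}

# number of untied-permutation arrangements of 1..n with k discordant pairs
.kendall_inversion_counts <- function(n) {
  w <- 1
  for (m in 2:n) {
    k_max <- m * (m - 1) / 2
    nw <- numeric(k_max + 1)
    cs <- cumsum(w)
    for (k in 0:k_max) {
      hi <- k + 1
      lo <- k - (m - 1)
      nw[k + 1] <- cs[min(hi, length(cs))] -
        if (lo >= 1) cs[lo] else 0
    }
    w <- nw
  }
  w
}

#' Kendall's rank correlation (tau-b)
#'
#' Tie-corrected tau-b. For n <= 30 with no ties in either vector the
#' p-value is exact (enumeration of the null inversion distribution);
#' otherwise a normal approximation with the standard tie-corrected
#' variance is used. Two-sided.
#'
#' @param x,y paired numeric vectors (n >= 3).
#' @return an `asym_test` with `statistic_name = "tau"`.
#' @export
kendall_tau <- function(x, y) {
  ok <- stats::complete.cases(x, y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (n < 3) stop("need at least 3 pairs")
  if (length(unique(x)) == 1L || length(unique(y)) == 1L)
    stop("constant vector")
  S <- 0; nc <- 0; nd <- 0
  for (i in seq_len(n - 1)) {
    dx <- sign(x[(i + 1):n] - x[i])
    dy <- sign(y[(i + 1):n] - y[i])
    nc <- nc + sum(dx * dy > 0)
    nd <- nd + sum(dx * dy < 0)
  }
  S <- nc - nd
  tx <- table(x); ty <- table(y)
  n0 <- n * (n - 1) / 2
  n1 <- sum(tx * (tx - 1) / 2); n2 <- sum(ty * (ty - 1) / 2)
  tau <- S / sqrt((n0 - n1) * (n0 - n2))
  no_ties <- n1 == 0 && n2 == 0
  if (no_ties && n <= 30) {
    w <- .kendall_inversion_counts(n)
    tot <- sum(w)
    # S = n0 - 2*inversions; |S| >= |s| <=> inversions extreme
    inv_obs <- (n0 - S) / 2
    p <- (sum(w[seq_len(min(inv_obs, n0 - inv_obs) + 1)]) / tot) * 2
    p <- min(1, p)
    note <- "exact"
  } else {
    v0 <- n * (n - 1) * (2 * n + 5)
    vt <- sum(tx * (tx - 1) * (2 * tx + 5))
    vu <- sum(ty * (ty - 1) * (2 * ty + 5))
    v1 <- sum(tx * (tx - 1)) * sum(ty * (ty - 1)) / (2 * n * (n - 1))
    v2 <- sum(tx * (tx - 1) * (tx - 2)) * sum(ty * (ty - 1) * (ty - 2)) /
      (9 * n * (n - 1) * (n - 2))
    v <- (v0 - vt - vu) / 18 + v1 + v2
    z <- S / sqrt(v)
    p <- 2 * pnorm(-abs(z))
    note <- "normal approximation"
  }
  .test_result("tau", tau, p, n, note = note)
}

#' Wilcoxon two-sample (rank-sum) test
#'
#' Midranks for ties; Z statistic via normal approximation with
#' tie-corrected variance; two-sided p. Continuity correction off by
#' default, matching a plain large-sample Z.
#'
#' @param a,b numeric vectors (total n >= 4).
#' @param continuity apply a 0.5 continuity correction.
#' @return an `asym_test` with `statistic_name = "Z"`; positive Z means
#'   sample `a` tends larger.
#' @export
wilcoxon_rank_sum <- function(a, b, continuity = FALSE) {
  a <- a[!is.na(a)]; b <- b[!is.na(b)]
  if (!length(a) || !length(b)) stop("both samples must be non-empty")
  n1 <- length(a); n2 <- length(b); n <- n1 + n2
  if (n < 4) stop("need total n >= 4")
  r <- rank(c(a, b))
  W <- sum(r[seq_len(n1)])
  EW <- n1 * (n + 1) / 2
  t <- table(r)
  tiecorr <- sum(t^3 - t) / (n * (n - 1))
  V <- n1 * n2 / 12 * ((n + 1) - tiecorr)
  d <- W - EW
  if (continuity) d <- sign(d) * max(0, abs(d) - 0.5)
  z <- d / sqrt(V)
  p <- 2 * pnorm(-abs(z))
  .test_result("Z", z, p, c(n_a = n1, n_b = n2))
}

#' Wilcoxon signed-rank test
#'
#' Zeros are dropped; midranks on tied absolute differences. The reported
#' statistic is `T = (W+ - W-)/2`, half the difference between the
#' positive and negative rank sums (equivalently `W+ - n(n+1)/4`):
#' negative when negative differences dominate, zero under perfect
#' balance. p-value: exact (signed-rank null distribution) when absolute
#' differences are untied and n <= 25; full sign-flip enumeration when
#' tied and n <= 12; otherwise normal approximation with tie-corrected
#' variance. Two-sided.
#'
#' @param differences numeric vector of paired differences (n >= 5 after
#'   zero removal).
#' @return an `asym_test` with `statistic_name = "T"`.
#' @export
wilcoxon_signed_rank <- function(differences) {
  d <- differences[!is.na(differences)]
  if (all(d == 0)) stop("degenerate: all differences zero")
  d <- d[d != 0]
  n <- length(d)
  if (n < 5) stop("need n >= 5 nonzero differences")
  r <- rank(abs(d))
  wpos <- sum(r[d > 0]); wneg <- sum(r[d < 0])
  Tval <- (wpos - wneg) / 2
  ties <- anyDuplicated(abs(d)) > 0L
  if (!ties && n <= 25) {
    w <- min(wpos, wneg)
    p <- min(1, 2 * psignrank(w, n))
    note <- "exact (signed-rank null)"
  } else if (ties && n <= 12) {
    # enumerate all sign assignments of the midrank vector
    total <- 2^n
    wplus <- 0
    grid <- expand.grid(rep(list(c(0, 1)), n))
    wdist <- as.matrix(grid) %*% r
    p <- min(1, 2 * min(mean(wdist <= wpos), mean(wdist >= wpos)))
    note <- "exact (sign-flip enumeration)"
  } else {
    EW <- n * (n + 1) / 4
    t <- table(r)
    V <- n * (n + 1) * (2 * n + 1) / 24 - sum(t^3 - t) / 48
    z <- (wpos - EW) / sqrt(V)
    p <- 2 * pnorm(-abs(z))
    note <- "normal approximation"
  }
  res <- .test_result("T", Tval, p, n, note = note)
  res$rank_sums <- c(positive = wpos, negative = wneg)
  res
}

#' Kruskal-Wallis test
#'
#' Tie-corrected H with a chi-square p-value on k-1 df.
#'
#' @param groups list of numeric vectors (>= 2 non-empty groups).
#' @return an `asym_test` with `statistic_name = "H"`.
#' @export
kruskal_wallis <- function(groups) {
  groups <- lapply(groups, function(g) g[!is.na(g)])
  if (length(groups) < 2) stop("need at least 2 groups")
  if (any(!lengths(groups))) stop("empty group")
  x <- unlist(groups)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  r <- rank(x)
  H <- 12 / (N * (N + 1)) *
    sum(tapply(r, g, sum)^2 / lengths(groups)) - 3 * (N + 1)
  t <- table(x)
  corr <- 1 - sum(t^3 - t) / (N^3 - N)
  if (corr > 0) H <- H / corr
  df <- length(groups) - 1
  p <- pchisq(H, df, lower.tail = FALSE)
  .test_result("H", H, p, lengths(groups), df = df)
}

#' Williams-corrected G-test of independence
#'
#' Log-likelihood-ratio G on an r x k count table with expected counts from
#' the margins, divided by the Williams correction factor
#' `q = 1 + (N*sum(1/row)-1)(N*sum(1/col)-1) / (6N(r-1)(k-1))`;
#' p-value from chi-square on (r-1)(k-1) df.
#'
#' @param table matrix of nonnegative integer counts (no all-zero row or
#'   column).
#' @return an `asym_test` with `statistic_name = "G_adj"`; the uncorrected
#'   G is attached as `$G`.
#' @export
g_test_williams <- function(table) {
  tab <- as.matrix(table)
  if (any(tab < 0)) stop("negative counts")
  rs <- rowSums(tab); cs <- colSums(tab)
  if (any(rs == 0) || any(cs == 0)) stop("zero marginal")
  N <- sum(tab)
  E <- outer(rs, cs) / N
  nz <- tab > 0
  G <- 2 * sum(tab[nz] * log(tab[nz] / E[nz]))
  r <- nrow(tab); k <- ncol(tab)
  df <- (r - 1) * (k - 1)
  q <- 1 + (N * sum(1 / rs) - 1) * (N * sum(1 / cs) - 1) / (6 * N * df)
  Gadj <- G / q
  p <- pchisq(Gadj, df, lower.tail = FALSE)
  res <- .test_result("G_adj", Gadj, p, N, df = df)
  res$G <- G
  res$q <- q
  res
}

# ---- stepwise mixed-selection regression ---------------------------------

# code two-level nominal columns as 0/1 indicators; reference level is
# "same"/"homogeneous" when present (sign-comparable coefficients),
# otherwise the first sorted level. Constant columns (numeric or
# single-level nominal) carry no information and are dropped.
.code_predictors <- function(predictors) {
  refs <- list()
  out <- list()
  dropped <- character(0)
  for (nm in names(predictors)) {
    v <- predictors[[nm]]
    if (is.numeric(v)) {
      if (length(unique(v[!is.na(v)])) < 2L) { dropped <- c(dropped, nm); next }
      out[[nm]] <- v
      next
    }
    v <- as.character(v)
    lev <- sort(unique(v[!is.na(v)]))
    if (length(lev) < 2L) { dropped <- c(dropped, nm); next }
    if (length(lev) > 2L)
      stop("nominal predictor '", nm, "' must have exactly 2 levels")
    ref <- intersect(c("same", "homogeneous", "FALSE", "0"), lev)
    ref <- if (length(ref)) ref[[1L]] else lev[[1L]]
    other <- setdiff(lev, ref)
    refs[[nm]] <- ref
    out[[paste0(nm, " (", other, ")")]] <- as.numeric(v == other)
  }
  list(X = as.data.frame(out, check.names = FALSE, optional = TRUE),
       references = refs, dropped = dropped)
}

# partial-F p-value for adding `term` to the model containing `terms`
.partial_f_p <- function(y, X, terms, term) {
  d0 <- if (length(terms)) as.matrix(X[terms]) else NULL
  f0 <- if (is.null(d0)) lm(y ~ 1) else lm(y ~ ., data = X[terms])
  f1 <- lm(y ~ ., data = X[c(terms, term)])
  a <- anova(f0, f1)
  a[["Pr(>F)"]][2L]
}

#' Stepwise mixed-selection multiple regression
#'
#' Forward selection with backward elimination on partial-F p-values:
#' at each step the candidate with the smallest partial-F p-value enters
#' if it meets `entry_alpha`; any included term whose p-value then exceeds
#' `stay_alpha` is removed (largest first). Ties on p-value admit the
#' candidate listed earlier in `predictors`. After selection terminates the
#' model is refit by ordinary least squares and reported with a summary of
#' fit, a whole-model analysis of variance, and parameter estimates.
#'
#' Two-level nominal predictors are coded 0/1 with `"same"`/
#' `"homogeneous"` as reference levels where present.
#'
#' @param y numeric response.
#' @param predictors data.frame of candidate predictors (numeric or
#'   two-level nominal), in the documented tie-break order.
#' @param entry_alpha partial-F significance to enter (default 0.15).
#' @param stay_alpha significance to stay (default 0.10).
#' @return object of class `stepwise_model`.
#' @export
stepwise_regression <- function(y, predictors, entry_alpha = 0.15,
                                stay_alpha = 0.10) {
  stopifnot(is.numeric(y), nrow(predictors) == length(y))
  ok <- stats::complete.cases(y, predictors)
  y <- y[ok]
  predictors <- predictors[ok, , drop = FALSE]
  if (length(y) <= ncol(predictors) + 1L)
    stop("need n > number of candidate predictors + 1")
  coded <- .code_predictors(predictors)
  X <- coded$X
  if (length(coded$dropped))
    message("dropping constant predictor(s): ",
            paste(coded$dropped, collapse = ", "))
  cand <- names(X)
  included <- character(0)
  path <- list()
  seen <- character(0)
  repeat {
    changed <- FALSE
    # entry
    pool <- setdiff(cand, included)
    if (length(pool)) {
      pv <- vapply(pool, function(tm) {
        d <- as.matrix(X[c(included, tm)])
        if (qr(cbind(1, d))$rank < ncol(d) + 1L) return(NA_real_)
        .partial_f_p(y, X, included, tm)
      }, 0)
      pv_ok <- pv[!is.na(pv)]
      if (length(pv_ok) && min(pv_ok) <= entry_alpha) {
        best <- names(pv_ok)[which.min(pv_ok)]  # first index wins ties
        included <- c(included, best)
        path[[length(path) + 1L]] <- list(action = "enter", term = best,
                                          p = min(pv_ok))
        changed <- TRUE
      }
    }
    # removal (iterate)
    repeat {
      if (!length(included)) break
      fit <- lm(y ~ ., data = X[included])
      ct <- summary(fit)$coefficients
      pr <- ct[-1L, 4L]
      names(pr) <- included
      if (max(pr) > stay_alpha) {
        worst <- names(pr)[which.max(pr)]
        included <- setdiff(included, worst)
        path[[length(path) + 1L]] <- list(action = "remove", term = worst,
                                          p = max(pr))
        changed <- TRUE
      } else break
    }
    key <- paste(sort(included), collapse = "|")
    if (!changed || key %in% seen) break
    seen <- c(seen, key)
  }
  # final least-squares fit
  fit <- if (length(included)) lm(y ~ ., data = X[included]) else lm(y ~ 1)
  sm <- summary(fit)
  ct <- sm$coefficients
  coef_tab <- data.frame(term = c("Intercept", included),
                         estimate = ct[, 1L], std_error = ct[, 2L],
                         t_ratio = ct[, 3L], p_value = ct[, 4L],
                         row.names = NULL)
  n <- length(y)
  fitted <- fitted(fit)
  model_ss <- sum((fitted - mean(y))^2)
  error_ss <- sum(residuals(fit)^2)
  total_ss <- sum((y - mean(y))^2)
  model_df <- length(included)
  error_df <- n - model_df - 1L
  f_ratio <- if (model_df > 0)
    (model_ss / model_df) / (error_ss / error_df) else NA_real_
  f_p <- if (model_df > 0)
    pf(f_ratio, model_df, error_df, lower.tail = FALSE) else NA_real_
  structure(list(selected_terms = included,
                 coefficients = coef_tab,
                 r_square = if (total_ss > 0) model_ss / total_ss else 0,
                 r_square_adj = if (total_ss > 0)
                   1 - (error_ss / error_df) / (total_ss / (n - 1))
                 else 0,
                 rmse = sqrt(error_ss / error_df),
                 mean_response = mean(y),
                 n = n,
                 anova = list(model_df = model_df, error_df = error_df,
                              total_df = n - 1L,
                              model_ss = model_ss, error_ss = error_ss,
                              total_ss = total_ss,
                              model_ms = if (model_df > 0)
                                model_ss / model_df else NA_real_,
                              error_ms = error_ss / error_df,
                              f_ratio = f_ratio, p_value = f_p),
                 references = coded$references,
                 path = path,
                 entry_alpha = entry_alpha, stay_alpha = stay_alpha,
                 fit = fit),
            class = "stepwise_model")
}

#' @export
print.stepwise_model <- function(x, digits = 6, ...) {
  cat("Summary of fit:\n")
  cat(sprintf("  R-square           %.4f\n", x$r_square))
  cat(sprintf("  R-square adjusted  %.4f\n", x$r_square_adj))
  cat(sprintf("  Root mean square error  %.4g\n", x$rmse))
  cat(sprintf("  Mean of response   %.4g\n", x$mean_response))
  cat(sprintf("  Observations       %d\n", x$n))
  a <- x$anova
  cat("Analysis of variance:\n")
  cat(sprintf("  Model    df %3d  SS %.6g  MS %.6g  F %.4f  p %.4g\n",
              a$model_df, a$model_ss, a$model_ms, a$f_ratio, a$p_value))
  cat(sprintf("  Error    df %3d  SS %.6g  MS %.6g\n",
              a$error_df, a$error_ss, a$error_ms))
  cat(sprintf("  C. Total df %3d  SS %.6g\n", a$total_df, a$total_ss))
  cat("Parameter estimates:\n")
  print(x$coefficients, digits = digits, row.names = FALSE)
  invisible(x)
}

#' Per-cohort fractions of pairs with significant rate asymmetry
#'
#' @param cohort factor of cohort labels (from [assign_cohort()]).
#' @param significant_nt,significant_aa logical per pair.
#' @return data.frame: cohort, n, fraction significant at the nucleotide
#'   and amino-acid level (NA where a cohort is empty).
#' @export
cohort_significance_profile <- function(cohort, significant_nt,
                                        significant_aa = NULL) {
  stopifnot(length(cohort) == length(significant_nt))
  lev <- levels(assign_cohort(0))[1:5]
  cohort <- factor(as.character(cohort), levels = lev)
  keep <- !is.na(cohort)
  cohort <- cohort[keep]
  significant_nt <- significant_nt[keep]
  n <- as.integer(table(cohort))
  frac <- function(sig) {
    s <- tapply(sig, cohort, mean)
    as.numeric(s)[match(lev, names(s))]
  }
  out <- data.frame(cohort = lev, n = n, frac_nt = frac(significant_nt))
  if (!is.null(significant_aa))
    out$frac_aa <- frac(significant_aa[keep])
  out
}
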