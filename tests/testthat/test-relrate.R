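test_that("CDS translation follows the documented conventions", {
  expect_identical(as.character(translate_cds("ATGAAATGA")), "MK")
  expect_identical(as.character(translate_cds("ATGNNNAAA")), "MXK")
  expect_warning(aa <- translate_cds("ATGTAAAAA"), "internal stop")
  expect_identical(as.character(aa), "MXK")
  expect_message(aa2 <- translate_cds("ATGAAAC"), "trimming")
  expect_identical(as.character(aa2), "MK")
  expect_error(translate_cds("AT"), "shorter")
})

test_that("unique-site counting matches a hand-enumerated 12-column fixture", {
  # col:        123456789012
  # A           AAAACGAAAAAT
  # B           AAAAACTC-NAT
  # O           AAAAACAGAAAA
  # 5,6: A-unique; 7: B-unique; 8: all different; 9: gap; 10: ambiguity;
  # 11: masked out; 12: shared change (A==B != O, counts to L only)
  mask <- rep(TRUE, 12); mask[11] <- FALSE
  trip <- triplet_alignment("AAAACGAAAAAT", "AAAAACTC-NAT", "AAAAACAGAAAA",
                            level = "nucleotide", mask = mask)
  cnt <- count_unique_sites(trip)
  expect_equal(cnt$m_a, 2L)
  expect_equal(cnt$m_b, 1L)
  expect_equal(cnt$n_alldiff, 1L)
  expect_equal(cnt$L, 9L)
})

test_that("ambiguity handling is level-aware (N is a residue, X is not)", {
  # amino-acid level: asparagine columns are usable, X columns are not
  trip <- triplet_alignment("MNKX", "MNRX", "MNKX", level = "amino_acid")
  cnt <- count_unique_sites(trip)
  expect_equal(cnt$L, 3L)       # X column excluded, N column kept
  expect_equal(cnt$m_b, 1L)     # the K/R/K column is unique to B
  # nucleotide level: N excludes the column
  trip2 <- triplet_alignment("ACNG", "ACNG", "ACNG", level = "nucleotide")
  expect_equal(count_unique_sites(trip2)$L, 3L)
})

test_that("identical triplets yield zero counts and full length", {
  s <- strrep("ACG", 100)
  cnt <- count_unique_sites(triplet_alignment(s, s, s))
  expect_equal(cnt$m_a, 0L)
  expect_equal(cnt$m_b, 0L)
  expect_equal(cnt$n_alldiff, 0L)
  expect_equal(cnt$L, 300L)
  tt <- tajima_test(cnt)
  expect_equal(tt$chi_square, 0)
  expect_equal(tt$p_value, 1)
})

test_that("relative-rate chi-square matches closed form", {
  mk <- function(m_a, m_b) list(m_a = m_a, m_b = m_b, n_alldiff = 0L,
                                L = 1000L)
  tt <- tajima_test(mk(15, 5))
  expect_equal(tt$chi_square, 100 / 20)
  expect_equal(tt$p_value, pchisq(5, 1, lower.tail = FALSE))
  expect_equal(round(tt$p_value, 4), 0.0253)
  expect_true(tt$significant)

  tt2 <- tajima_test(mk(14, 6))
  expect_equal(tt2$chi_square, 3.2)
  expect_false(tt2$significant)

  expect_equal(tajima_test(mk(7, 7))$p_value, 1)

  # the all-different convention is toggleable
  c3 <- list(m_a = 10, m_b = 4, n_alldiff = 3, L = 500)
  expect_equal(tajima_test(c3, include_alldiff = TRUE)$chi_square,
               (13 - 7)^2 / 20)
})

test_that("nine is the minimal detectable difference at twenty unique sites", {
  expect_identical(min_detectable_difference(20), 9L)
  # boundary arithmetic: 8^2/20 = 3.2 below, 9^2/20 = 4.05 above 3.841
  expect_lt(8^2 / 20, qchisq(0.95, 1))
  expect_gt(9^2 / 20, qchisq(0.95, 1))
})

test_that("asymmetry per site is |m_a - m_b| / L with its scaling law", {
  expect_equal(asymmetry_per_site(list(m_a = 3, m_b = 3, L = 300)), 0)
  expect_equal(asymmetry_per_site(list(m_a = 7, m_b = 2, L = 500)), 0.01)
  expect_equal(asymmetry_per_site(list(m_a = 7, m_b = 2, L = 1000)), 0.005)
  expect_error(asymmetry_per_site(list(m_a = 1, m_b = 0, L = 0)), "positive")
})

test_that("signed standardized asymmetry is antisymmetric in the assignment", {
  cnt <- list(m_a = 4, m_b = 9, L = 500)
  expect_equal(signed_standardized_asymmetry(cnt, TRUE), -0.01)
  expect_equal(signed_standardized_asymmetry(cnt, FALSE), 0.01)
  expect_equal(signed_standardized_asymmetry(list(m_a = 5, m_b = 5, L = 100),
                                             TRUE), 0)
  expect_error(signed_standardized_asymmetry(cnt, NA), "missing")
})

test_that("rejection frequency increases with the simulated asymmetry factor", {
  set.seed(301)
  rej <- vapply(c(1, 2, 4), function(f) {
    mean(replicate(150, {
      t <- simulate_triplet(250, 0.08, f)
      trip <- triplet_alignment(t$cds_ancestral, t$cds_derived,
                                t$cds_outgroup)
      tajima_test(count_unique_sites(trip))$significant
    }))
  }, 0)
  expect_true(all(diff(rej) > 0))
  expect_lt(rej[1], 0.12)
  expect_gt(rej[3], 0.5)
})

test_that("nucleotide and amino-acid asymmetry are positively correlated", {
  set.seed(302)
  res <- t(replicate(120, {
    t <- simulate_triplet(200, 0.1, 3)
    nt <- count_unique_sites(triplet_alignment(t$cds_ancestral,
                                               t$cds_derived,
                                               t$cds_outgroup))
    aa <- count_unique_sites(
      build_triplet_alignment(t$cds_ancestral, t$cds_derived,
                              t$cds_outgroup, "amino_acid"))
    c(asymmetry_per_site(nt), asymmetry_per_site(aa))
  }))
  expect_gt(cor(res[, 1], res[, 2], method = "spearman"), 0.3)
})
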