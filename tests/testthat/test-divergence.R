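test_that("identical coding sequences give zero divergence", {
  s <- strrep("ATGGCT", 30)
  est <- ng86_divergence(s, s)
  expect_equal(est$ks, 0)
  expect_equal(est$ka, 0)
  expect_false(est$saturated)
})

test_that("site and difference counting matches hand-worked NG86 arithmetic", {
  # AAA: 1/3 syn sites (AAG at pos 3); TTT: 1/3 (TTC); GGG: 1 (pos 3
  # fourfold); CCC: 1 (pos 3 fourfold). Per-sequence S = 8/3.
  a <- "AAATTTGGGCCC"
  b <- "AAATTCGGGCCC"   # one synonymous difference (Phe TTT -> TTC)
  est <- ng86_divergence(a, b)
  expect_equal(est$syn_sites, 8 / 3)
  expect_equal(est$syn_diffs, 1)
  expect_equal(est$nonsyn_diffs, 0)
  # p_s = 1/(8/3) = 0.375; Jukes-Cantor: -3/4 log(1 - 0.5)
  expect_equal(est$ks, -0.75 * log(1 - 4 * 0.375 / 3))
  expect_equal(est$ka, 0)

  # a nonsynonymous change: AAA (Lys) -> GAA (Glu), pos 1
  est2 <- ng86_divergence("AAATTTGGGCCC", "GAATTTGGGCCC")
  expect_equal(est2$syn_diffs, 0)
  expect_equal(est2$nonsyn_diffs, 1)
  expect_gt(est2$ka, 0)
  expect_equal(est2$ks, 0)
})

test_that("two-position codon differences average over both minimal pathways", {
  # TTT (Phe) vs TTA+pos1 change: compare CTT (Leu) vs TTA (Leu)?
  # Use a codon pair differing at positions 1 and 3: AAA (Lys) vs GAG (Glu)
  # pathways: AAA->GAA(nonsyn)->GAG(syn)  and AAA->AAG(syn)->GAG(nonsyn)
  # average: 1 syn, 1 nonsyn
  est <- ng86_divergence("AAA", "GAG")
  expect_equal(est$syn_diffs, 1)
  expect_equal(est$nonsyn_diffs, 1)
})

test_that("divergence estimation is symmetric and saturation is flagged", {
  set.seed(401)
  t <- simulate_triplet(120, 0.1, 2)
  e1 <- ng86_divergence(t$cds_ancestral, t$cds_derived)
  e2 <- ng86_divergence(t$cds_derived, t$cds_ancestral)
  expect_equal(e1$ks, e2$ks)
  expect_equal(e1$ka, e2$ka)

  # a single Phe codon pair differing synonymously has p_s = 3 >= 3/4
  est <- ng86_divergence("TTT", "TTC")
  expect_true(est$saturated)
  expect_true(is.na(est$ks))
})

test_that("ks increases with constructively added synonymous changes", {
  base <- strrep("GGTACTCCTGAA", 25)  # 100 codons
  mut <- function(k) {
    # change the 3rd position of the first k GGT codons to GGC (syn)
    x <- strsplit(base, "")[[1]]
    idx <- (which(seq_len(100) %% 4 == 1)[seq_len(k)] - 1) * 3 + 3
    x[idx] <- "C"
    paste(x, collapse = "")
  }
  ks <- vapply(c(2, 6, 12), function(k) ng86_divergence(base, mut(k))$ks, 0)
  expect_true(all(diff(ks) > 0))
})

test_that("simulated divergence is recovered on average within 10%", {
  set.seed(402)
  est <- replicate(200, {
    t <- simulate_triplet(200, 0.05, 1)
    ng86_divergence(t$cds_ancestral, t$cds_derived)$ks
  })
  expect_lt(abs(mean(est, na.rm = TRUE) - 0.05) / 0.05, 0.10)
})

test_that("age cohort assignment uses the five half-open bins", {
  expect_identical(as.character(assign_cohort(0)), "[0,0.01)")
  expect_identical(as.character(assign_cohort(0.02)), "[0.01,0.03)")
  expect_identical(as.character(assign_cohort(0.01)), "[0.01,0.03)")
  expect_identical(as.character(assign_cohort(0.0799)), "[0.05,0.08)")
  expect_identical(as.character(assign_cohort(0.14)), "out_of_range")
  expect_identical(as.character(assign_cohort(0.5)), "out_of_range")
  expect_error(assign_cohort(-0.01), "negative")
  expect_equal(nrow(age_cohorts()), 5L)
})
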