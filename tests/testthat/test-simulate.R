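test_that("triplet simulation is deterministic under a fixed seed", {
  set.seed(601)
  t1 <- simulate_triplet(100, 0.05, 2)
  set.seed(601)
  t2 <- simulate_triplet(100, 0.05, 2)
  expect_identical(t1, t2)
})

test_that("the symmetric null produces balanced unique-site counts", {
  set.seed(602)
  signed <- replicate(600, {
    t <- simulate_triplet(150, 0.08, 1)
    cnt <- count_unique_sites(triplet_alignment(t$cds_ancestral,
                                                t$cds_derived,
                                                t$cds_outgroup))
    (cnt$m_a - cnt$m_b) / cnt$L
  })
  ci <- 1.96 * sd(signed) / sqrt(length(signed))
  expect_lt(abs(mean(signed)), ci * 1.5)
})

test_that("a higher asymmetry factor yields larger per-site asymmetry", {
  set.seed(603)
  asym <- function(f) replicate(250, {
    t <- simulate_triplet(150, 0.08, f)
    asymmetry_per_site(count_unique_sites(
      triplet_alignment(t$cds_ancestral, t$cds_derived, t$cds_outgroup)))
  })
  a1 <- asym(1); a3 <- asym(3)
  expect_gt(mean(a3), mean(a1))
  expect_lt(wilcox.test(a1, a3)$p.value, 0.01)
})

test_that("dataset bookkeeping: counts, ids and file round trip", {
  set.seed(604)
  d <- simulate_dataset(sim_config(n_pairs = 5), dir = withr::local_tempdir())
  expect_equal(nrow(d$manifest), 5L)
  expect_equal(length(d$cds), 15L)
  expect_equal(nrow(d$truth), 5L)
  expect_true(all(d$truth$ancestral_id %in%
                    c(d$manifest$paralog_a, d$manifest$paralog_b)))
  expect_true(all(c(d$manifest$paralog_a, d$manifest$paralog_b,
                    d$manifest$outgroup) %in% names(d$cds)))
  # annotation invariants hold for every simulated gene
  for (i in seq_len(nrow(d$annotations))) {
    ex <- d$annotations$exons[[i]]
    expect_true(all(diff(ex[, "start"]) > 0))
    expect_true(all(ex[, "end"] > ex[, "start"]))
    expect_gte(min(ex[, "start"]), d$annotations$start[i])
    expect_lte(max(ex[, "end"]), d$annotations$end[i])
  }
})

test_that("written dataset files reload identically", {
  dir <- withr::local_tempdir()
  set.seed(605)
  d <- simulate_dataset(sim_config(n_pairs = 4), dir = dir)
  back <- load_dataset(dir)
  expect_identical(as.character(back$cds), as.character(d$cds))
  expect_identical(names(back$cds), names(d$cds))
  expect_equal(back$annotations$exons, d$annotations$exons)
  expect_equal(back$manifest$pair_id, d$manifest$pair_id)
  expect_equal(back$context_offsets[names(d$context_offsets)],
               d$context_offsets)
})

test_that("identical config and seed yield identical datasets", {
  set.seed(606)
  d1 <- simulate_dataset(sim_config(n_pairs = 3))
  set.seed(606)
  d2 <- simulate_dataset(sim_config(n_pairs = 3))
  expect_identical(as.character(d1$cds), as.character(d2$cds))
  expect_identical(as.character(d1$contexts), as.character(d2$contexts))
  expect_identical(d1$truth, d2$truth)
})

test_that("forcing a single structure class propagates to classification", {
  set.seed(607)
  d <- simulate_dataset(sim_config(n_pairs = 6,
                                   structure_probs = c(complete = 1,
                                                       partial = 0,
                                                       chimeric = 0)))
  expect_true(all(d$truth$true_structure == "complete"))
  pf <- suppressMessages(build_pair_features(d))
  expect_true(all(pf$structure3 == "complete"))
})

test_that("relocated pairs show larger mean asymmetry when so configured", {
  set.seed(608)
  pfF <- simulate_pair_features(sim_config(n_pairs = 4000))
  m_rel <- mean(pfF$asym_nt[pfF$chromosome_relation == "different"])
  m_same <- mean(pfF$asym_nt[pfF$chromosome_relation == "same"])
  expect_gt(m_rel, m_same)
})

test_that("feature-level and config invariants are enforced", {
  expect_error(sim_config(structure_probs = c(0.5, 0.2, 0.2)), "structure")
  expect_error(sim_config(ks_range = c(0, 0.5)))
  expect_error(simulate_triplet(10, 0.05), "n_codons")
  expect_error(simulate_triplet(100, 0.8), "calibrate")
})
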