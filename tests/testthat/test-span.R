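test_that("homology region covers identical contexts end to end", {
  set.seed(201)
  ctx <- random_dna_str(3000)
  expect_message(reg <- find_homology_region(ctx, ctx), "flank exhausted")
  expect_equal(reg$a_start, 0L)
  expect_equal(reg$a_end, 3000L)
  expect_false(reg$terminated_5prime)   # sequence ran out, no 1 kb desert
  expect_false(reg$terminated_3prime)
  sp <- duplication_span(reg)
  expect_equal(sp$span, 3000L)
})

test_that("a planted homologous tract is recovered within window tolerance", {
  set.seed(202)
  tract <- random_dna_str(1500)
  a <- paste0(random_dna_str(1200), tract, random_dna_str(1200))
  b <- paste0(random_dna_str(1200), tract, random_dna_str(1200))
  reg <- find_homology_region(a, b)
  w <- homology_config()$window_bp
  expect_lte(abs(reg$a_start - 1200L), w)
  expect_lte(abs(reg$a_end - 2700L), w)
  expect_lte(abs(reg$b_start - 1200L), w)
  expect_lte(abs(reg$b_end - 2700L), w)
  expect_true(reg$terminated_5prime)
  expect_true(reg$terminated_3prime)
})

test_that("a sub-kilobase interruption does not terminate the region", {
  set.seed(203)
  t1 <- random_dna_str(800); t2 <- random_dna_str(700)
  mid_a <- random_dna_str(800); mid_b <- random_dna_str(800)
  a <- paste0(random_dna_str(1200), t1, mid_a, t2, random_dna_str(1200))
  b <- paste0(random_dna_str(1200), t1, mid_b, t2, random_dna_str(1200))
  reg <- find_homology_region(a, b)
  # region must include both homologous tracts across the 800 bp gap
  w <- homology_config()$window_bp
  expect_lte(reg$a_start, 1200L + w)
  expect_gte(reg$a_end, 1200L + 800L + 800L + 700L - w)
})

test_that("no homology anywhere raises an error", {
  set.seed(204)
  expect_error(find_homology_region(random_dna_str(2000),
                                    random_dna_str(2000)),
               "not homologous")
})

test_that("span uses the lower of the two per-paralog spans", {
  set.seed(205)
  tract <- random_dna_str(2000)
  # paralog B carries a 50 bp deletion inside the tract
  b_tract <- paste0(substr(tract, 1, 1000), substr(tract, 1051, 2000))
  a <- paste0(random_dna_str(1100), tract, random_dna_str(1100))
  b <- paste0(random_dna_str(1100), b_tract, random_dna_str(1100))
  reg <- find_homology_region(a, b)
  sp <- duplication_span(reg)
  w <- homology_config()$window_bp   # each edge can overshoot by ~1 window
  expect_lte(abs(sp$span_a - 2000L), 2 * w)
  expect_lte(abs(sp$span_b - 1950L), 2 * w)
  expect_equal(sp$span, min(sp$span_a, sp$span_b))
  expect_lte(sp$span, sp$span_a)
  expect_lte(sp$span, sp$span_b)
})

test_that("detected span does not shrink when the true tract grows", {
  set.seed(206)
  spans <- vapply(c(600L, 1200L, 2400L), function(L) {
    tract <- random_dna_str(L)
    a <- paste0(random_dna_str(1100), tract, random_dna_str(1100))
    b <- paste0(random_dna_str(1100), tract, random_dna_str(1100))
    duplication_span(find_homology_region(a, b))$span
  }, 0L)
  expect_true(all(diff(spans) > 0))
})

test_that("structural classification follows the unique-exon rule and is label-symmetric", {
  reg <- make_region(1000L, 3000L, 500L, 2500L)
  # both paralogs' exons inside the homology bounds -> complete
  annA <- make_annot("A", "chrI", "+", c(1100, 1400, 1600, 2000))
  annB <- make_annot("B", "chrI", "+", c(600, 900, 1100, 1500))
  expect_identical(classify_structure(annA, annB, reg)$value, "complete")

  # A has an exon past the homology bounds, B does not -> partial
  annA2 <- make_annot("A", "chrI", "+", c(1100, 1400, 3200, 3500))
  st <- classify_structure(annA2, annB, reg)
  expect_identical(st$value, "partial")
  expect_equal(st$unique_exons_a, 1L)
  expect_equal(st$unique_exons_b, 0L)

  # each paralog has a unique exon -> chimeric
  annB2 <- make_annot("B", "chrI", "+", c(600, 900, 2800, 3100))
  st2 <- classify_structure(annA2, annB2, reg)
  expect_identical(st2$value, "chimeric")

  # swapping labels preserves the class
  reg_sw <- make_region(reg$b_start, reg$b_end, reg$a_start, reg$a_end)
  expect_identical(classify_structure(annB2, annA2, reg_sw)$value, "chimeric")
  expect_identical(classify_structure(annB, annA2, reg_sw)$value, "partial")

  # an exon straddling the boundary is unique iff under half is covered
  annC <- make_annot("A", "chrI", "+", c(2900, 3140))  # 100/240 inside
  expect_identical(classify_structure(annC, annB, reg)$value, "partial")
  annD <- make_annot("A", "chrI", "+", c(2900, 3080))  # 100/180 inside
  expect_identical(classify_structure(annD, annB, reg)$value, "complete")
})
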