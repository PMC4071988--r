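test_that("genetic-model contrasts map genotype counts to the right cells", {
  au <- load_fixture("rs861539")$studies[[1]]   # Auranen
  dom <- build_contrast(au, "dominant")
  expect_equal(unlist(dom[c("a", "b", "c", "d")]),
               c(a = 989, b = 676, c = 2529, d = 1712))

  quaye <- load_fixture("rs1799794")$studies[[2]]
  rec <- build_contrast(quaye, "recessive")
  expect_equal(unlist(rec[c("a", "b", "c", "d")]),
               c(a = 37, b = 1424, c = 89, d = 2218))

  hom <- build_contrast(au, "homozygote")
  expect_equal(hom$a + hom$b, au$cases$n11 + au$cases$n22)
  het <- build_contrast(au, "heterozygote")
  expect_equal(het$a, au$cases$n12)
  expect_error(build_contrast(au, "additive"))
})

test_that("odds ratio, CI and p reproduce printed per-study cells", {
  # Quaye and Auranen homozygote cells of the rs1799794 table
  e1 <- odds_ratio(two_by_two(37, 940, 89, 1505))
  expect_equal(round_half_up(c(e1$or, e1$ci_low, e1$ci_high), 2),
               c(0.67, 0.45, 0.99))
  e2 <- odds_ratio(two_by_two(48, 1060, 161, 2551))
  expect_equal(round_half_up(c(e2$or, e2$ci_low, e2$ci_high), 2),
               c(0.72, 0.52, 1.00))

  for (k in c(1, 7, 400)) {
    e <- odds_ratio(two_by_two(k, k, k, k))
    expect_equal(e$or, 1)
    expect_equal(e$log_or, 0)
    expect_equal(e$p_value, 1)
  }
})

test_that("continuity-correction policies behave as specified", {
  t0 <- two_by_two(0, 10, 5, 10)
  expect_error(odds_ratio(t0, cc = "none"), "continuity")
  e <- odds_ratio(t0, cc = "halves-when-zero")
  expect_true(e$corrected)
  expect_equal(e$or, (0.5 * 10.5) / (10.5 * 5.5))  # longhand arithmetic
  # no zero cell: halves-when-zero leaves counts untouched
  e2 <- odds_ratio(two_by_two(1, 2, 3, 4), cc = "halves-when-zero")
  expect_false(e2$corrected)
  expect_equal(e2$or, (1 * 4) / (2 * 3))
  e3 <- odds_ratio(two_by_two(1, 2, 3, 4), cc = "halves-always")
  expect_equal(e3$or, (1.5 * 4.5) / (2.5 * 3.5))
  # an empty margin is undefined even with correction
  expect_error(odds_ratio(two_by_two(0, 10, 0, 10)), "margin")
})

test_that("OR inversion symmetries hold across random tables", {
  set.seed(42)
  for (i in 1:25) {
    cells <- rpois(4, 30) + 1
    t <- two_by_two(cells[1], cells[2], cells[3], cells[4])
    e <- odds_ratio(t)
    swapped <- odds_ratio(two_by_two(t$c, t$d, t$a, t$b))  # case<->control
    expect_equal(swapped$or, 1 / e$or, tolerance = 1e-12)
    expect_equal(swapped$se, e$se, tolerance = 1e-12)
    transposed <- odds_ratio(two_by_two(t$b, t$a, t$d, t$c))  # exposure swap
    expect_equal(transposed$or, 1 / e$or, tolerance = 1e-12)
  }
})

test_that("Hardy-Weinberg chi-square matches closed-form expectations", {
  # exact HWE proportions: statistic 0
  h <- hwe_test(genotype_counts(25, 50, 25))
  expect_equal(h$chi_square, 0)
  expect_equal(h$p_value, 1)
  expect_true(h$in_equilibrium)

  # all homozygotes at q = 0.5: expected (25, 50, 25) per 100, so
  # chi-square = 25 + 50 + 25 = n
  h2 <- hwe_test(genotype_counts(50, 0, 50))
  expect_equal(h2$chi_square, 100)
  expect_lt(h2$p_value, 1e-20)
  expect_false(h2$in_equilibrium)

  # the packaged control arms are all in equilibrium ("Yes" columns)
  h3 <- hwe_test(genotype_counts(1505, 713, 89))
  expect_true(h3$in_equilibrium)

  expect_warning(h4 <- hwe_test(genotype_counts(10, 0, 0)), "monomorphic")
  expect_true(h4$in_equilibrium)
  expect_equal(h4$chi_square, 0)
})

test_that("HWE p-values are approximately uniform under the null", {
  set.seed(7)
  p <- replicate(2000, {
    arm <- as.integer(rmultinom(1, 1000, c(0.25, 0.5, 0.25)))
    hwe_test(genotype_counts(arm[1], arm[2], arm[3]))$p_value
  })
  # discrete counts give occasional tied p-values; the KS warning about
  # ties is immaterial at this resolution
  expect_gt(suppressWarnings(ks.test(p, "punif"))$p.value, 0.001)
})

test_that("quality rubric reproduces printed study scores", {
  beesley <- quality_features("population_or_registry", "population",
                              "blood_or_normal_tissue", TRUE, 1478)
  qs <- quality_score(beesley)
  expect_equal(qs$total, 15L)
  expect_true(qs$is_high_quality)
  expect_equal(sum(qs$per_category), qs$total)

  auranen <- quality_features("mixed", "population",
                              "blood_or_normal_tissue", TRUE, 5906)
  expect_equal(quality_score(auranen)$total, 14L)

  worst <- quality_features("other", "not_described", "tumor_or_exfoliated",
                            FALSE, 100)
  qs0 <- quality_score(worst)
  expect_equal(qs0$total, 0L)
  expect_false(qs0$is_high_quality)

  # size bands
  sz <- function(n) quality_score(quality_features(
    "other", "not_described", "tumor_or_exfoliated", FALSE, n))$total
  expect_equal(c(sz(199), sz(200), sz(499), sz(500), sz(999), sz(1000)),
               c(0L, 1L, 1L, 2L, 2L, 3L))
})
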