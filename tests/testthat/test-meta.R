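test_that("Cochran Q matches longhand weighted-sum arithmetic", {
  # theta = (0, 0.5, 1), all se = 0.2: w = 25, pooled = 0.5,
  # Q = 25 * (0.25 + 0 + 0.25) = 12.5
  eff <- lapply(c(0, 0.5, 1), make_effect, se = 0.2)
  h <- cochran_q(eff)
  expect_equal(h$q, 12.5)
  expect_equal(h$df, 2L)
  expect_equal(h$p_value, pchisq(12.5, 2, lower.tail = FALSE))
  expect_equal(h$i_squared, (12.5 - 2) / 12.5)
  # DL: denom = sum(w) - sum(w^2)/sum(w) = 75 - 1875/75 = 50
  expect_equal(h$tau_squared, (12.5 - 2) / 50)

  same <- lapply(rep(0.3, 4), make_effect, se = 0.1)
  h0 <- cochran_q(same)
  expect_equal(h0$q, 0)
  expect_equal(h0$i_squared, 0)
  expect_equal(h0$p_value, 1)
  expect_equal(h0$tau_squared, 0)

  expect_error(cochran_q(list(make_effect(0, 1))), "at least 2")
})

test_that("inverse-variance pooling matches the arithmetic oracle", {
  eff <- list(make_effect(0.2, 0.1), make_effect(0.6, 0.3))
  fixed <- pool_inverse_variance(eff)
  # w = (100, 11.111...): pooled = (20 + 6.6667) / 111.11 = 0.24
  expect_equal(fixed$estimate$log_or, 0.24, tolerance = 1e-12)
  expect_equal(fixed$estimate$se, 1 / sqrt(100 + 1 / 0.09), tolerance = 1e-12)

  # Q <= df forces tau^2 = 0, so random collapses onto fixed
  close_eff <- list(make_effect(0.20, 0.1), make_effect(0.21, 0.1))
  expect_equal(pool_inverse_variance(close_eff, random = TRUE)$estimate,
               pool_inverse_variance(close_eff, random = FALSE)$estimate)
})

test_that("Mantel-Haenszel pooling is correct on degenerate-simple input", {
  t1 <- two_by_two(20, 15, 12, 18)
  dup <- pool_mantel_haenszel(list(t1, t1))
  expect_equal(dup$estimate$or, odds_ratio(t1)$or, tolerance = 1e-12)

  null2 <- pool_mantel_haenszel(list(two_by_two(10, 10, 10, 10),
                                     two_by_two(20, 20, 20, 20)))
  expect_equal(null2$estimate$or, 1)

  expect_error(pool_mantel_haenszel(list(t1)), "at least 2")
  expect_error(pool_mantel_haenszel(list(two_by_two(5, 0, 5, 5),
                                         two_by_two(5, 5, 0, 5))),
               "cross-product")
})

test_that("MH estimate and RBG variance agree with metafor", {
  skip_if_not_installed("metafor")
  for (snp in c("rs861539", "rs1799794")) {
    ds <- load_fixture(snp)
    for (model in genetic_models()) {
      tables <- lapply(ds$studies, build_contrast, model = model)
      ours <- pool_mantel_haenszel(tables)
      ref <- metafor::rma.mh(
        ai = sapply(tables, `[[`, "a"), bi = sapply(tables, `[[`, "b"),
        ci = sapply(tables, `[[`, "c"), di = sapply(tables, `[[`, "d"),
        measure = "OR", add = 0, to = "none", correct = FALSE)
      expect_equal(ours$estimate$log_or, as.numeric(ref$beta),
                   tolerance = 1e-10)
      expect_equal(ours$estimate$se, ref$se, tolerance = 1e-10)
    }
  }
})

test_that("IV fixed, DL random and Q agree with metafor", {
  skip_if_not_installed("metafor")
  set.seed(11)
  theta <- rnorm(6, 0.2, 0.4)
  se <- runif(6, 0.1, 0.5)
  eff <- Map(make_effect, theta, se)
  ref_fe <- metafor::rma(yi = theta, sei = se, method = "FE")
  ref_dl <- metafor::rma(yi = theta, sei = se, method = "DL")
  fe <- pool_inverse_variance(eff)
  dl <- pool_inverse_variance(eff, random = TRUE)
  expect_equal(fe$estimate$log_or, as.numeric(ref_fe$beta), tolerance = 1e-10)
  expect_equal(fe$estimate$se, ref_fe$se, tolerance = 1e-10)
  expect_equal(dl$estimate$log_or, as.numeric(ref_dl$beta), tolerance = 1e-10)
  expect_equal(dl$estimate$se, ref_dl$se, tolerance = 1e-10)
  expect_equal(fe$heterogeneity$q, ref_fe$QE, tolerance = 1e-10)
  expect_equal(dl$heterogeneity$tau_squared, ref_dl$tau2, tolerance = 1e-10)
})

test_that("model selection follows the heterogeneity gate strictly", {
  het <- function(p) structure(list(q = 1, df = 1L, p_value = p,
                                    i_squared = 0, tau_squared = 0),
                               class = "heterogeneity_result")
  cfg <- meta_config(heterogeneity_alpha = 0.05)
  expect_equal(select_model(het(0.001), cfg), "dersimonian_laird_random")
  expect_equal(select_model(het(0.05), cfg), "mantel_haenszel_fixed")  # boundary
  expect_equal(select_model(het(0.5), cfg), "mantel_haenszel_fixed")
  expect_equal(select_model(het(0.5), meta_config(fixed_method = "iv")),
               "inverse_variance_fixed")
})

test_that("meta_analyze assembles per-study and pooled results coherently", {
  m <- meta_analyze(load_fixture("rs861539"))
  expect_named(m$models, genetic_models())
  hom <- m$models$homozygote$pooled
  expect_equal(round_half_up(c(hom$estimate$or, hom$estimate$ci_low,
                               hom$estimate$ci_high), 2),
               c(0.95, 0.85, 1.06))
  het <- meta_analyze(load_fixture("rs1799796"))$models$heterozygote$pooled
  expect_equal(round_half_up(c(het$estimate$or, het$estimate$ci_low,
                               het$estimate$ci_high), 2),
               c(0.91, 0.83, 0.99))
  # fixed pooled log OR stays inside the per-study hull
  for (mod in genetic_models()) {
    eff <- m$models[[mod]]$effects
    los <- vapply(eff, function(e) e$log_or, numeric(1))
    pooled <- m$models[[mod]]$pooled$estimate$log_or
    expect_gte(pooled, min(los))
    expect_lte(pooled, max(los))
  }
  # duplicated study: pooled equals per-study, Q = 0, for all models
  s <- load_fixture("rs861539")$studies[[1]]
  s2 <- s; s2$study_id <- "copy"
  twin <- meta_analyze(snp_dataset("twin", list(s, s2)))
  for (mod in genetic_models()) {
    expect_equal(twin$models[[mod]]$pooled$estimate$or,
                 twin$models[[mod]]$effects[[1]]$or, tolerance = 1e-10)
    expect_equal(twin$models[[mod]]$heterogeneity$q, 0, tolerance = 1e-10)
  }
})

test_that("study order never affects numeric results", {
  ds <- load_fixture("rs861539")
  perm <- snp_dataset(ds$snp_id, ds$studies[c(3, 1, 4, 2)])
  a <- meta_analyze(ds); b <- meta_analyze(perm)
  for (mod in genetic_models()) {
    expect_equal(a$models[[mod]]$pooled$estimate,
                 b$models[[mod]]$pooled$estimate, tolerance = 1e-12)
    expect_equal(a$models[[mod]]$heterogeneity$q,
                 b$models[[mod]]$heterogeneity$q, tolerance = 1e-12)
  }
})

test_that("leave-one-out returns k tagged results and needs k >= 3", {
  ds <- load_fixture("rs861539")
  loo <- leave_one_out(ds, "dominant")
  expect_length(loo, 4)
  expect_equal(vapply(loo, `[[`, character(1), "omitted"),
               vapply(ds$studies, `[[`, character(1), "study_id"))
  for (r in loo) expect_equal(r$k, 3)

  expect_error(leave_one_out(load_fixture("rs1799794"), "dominant"),
               "at least 3")

  # omitting a study that sits exactly at the pooled mean barely moves it
  base <- meta_analyze(ds)$models$dominant$pooled$estimate$log_or
  devs <- abs(vapply(loo, function(r) r$estimate$log_or, numeric(1)) - base)
  expect_lt(min(devs), 0.02)
})
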