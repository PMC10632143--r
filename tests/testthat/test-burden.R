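cfg <- simulation_config()

test_that("LMM recovers the generative fixed effects within its CI", {
  sb <- simulate_burden_records(cfg, n_patients = 100, clones_per_patient = 5,
                                seed = 21)
  fit <- fit_burden_lmm(sb$records, "burden_nonpsoralen", "age")
  co <- fit$coefficients[fit$coefficients$term == "age", ]
  expect_lt(abs(co$estimate - 14.6), 3 * co$se)
  expect_true(all(fit$ranef_sd >= 0))
  # adding a fixed effect never lowers the ML log-likelihood
  f1 <- fit_burden_lmm(sb$records, "burden_nonpsoralen", "age", reml = FALSE)
  f2 <- fit_burden_lmm(sb$records, "burden_nonpsoralen", c("age", "duration"),
                       reml = FALSE)
  expect_gte(f2$loglik, f1$loglik - 1e-6)
})

test_that("null duration effects are covered by the CI", {
  # generator with no duration effect on the total burden response
  cfg0 <- simulation_config(duration_effect_sbs15 = 0)
  hits <- 0
  for (s in 1:5) {
    sb <- simulate_burden_records(cfg0, n_patients = 60,
                                  clones_per_patient = 4, seed = 100 + s)
    fit <- fit_burden_lmm(sb$records, "burden_sbs15", c("age", "duration"))
    co <- fit$coefficients[fit$coefficients$term == "duration", ]
    if (co$ci_lo <= 0 && 0 <= co$ci_hi) hits <- hits + 1
  }
  expect_gte(hits, 4)
})

test_that("likelihood-ratio machinery is exact on knowns", {
  f <- list(loglik = -100, df = 4, mode = "ML")
  r <- list(loglik = -100, df = 4, mode = "ML")
  class(f) <- class(r) <- "lmm_fit"
  out <- lrt_nested(f, r)
  expect_equal(out$statistic, 0)
  expect_equal(out$p_value, 1)
  f2 <- list(loglik = -100 + 3.841459 / 2, df = 5, mode = "ML")
  class(f2) <- "lmm_fit"
  expect_equal(lrt_nested(f2, r)$p_value, 0.05, tolerance = 1e-4)
  r3 <- list(loglik = -90, df = 6, mode = "ML"); class(r3) <- "lmm_fit"
  expect_error(lrt_nested(f, r3), "not nested")
  fr <- list(loglik = -100, df = 5, mode = "REML"); class(fr) <- "lmm_fit"
  expect_error(lrt_nested(fr, r), "ML")
})

test_that("PUVA band model recovers the configured dose effect", {
  sb <- simulate_burden_records(cfg, n_patients = 120, clones_per_patient = 5,
                                seed = 31)
  pf <- puva_dose_model(sb$records)
  hi <- pf$contrasts[pf$contrasts$band == ">200", ]
  expect_lt(abs(hi$estimate - 616), 3 * hi$se)
  expect_lt(pf$lrt$p_value, 1e-4)
  # band ordering preserved in the output
  expect_equal(pf$contrasts$band, c("1-50", "51-200", ">200"))
})

test_that("clonality regression behaves on degenerate and signal cases", {
  flat <- data.frame(patient_id = 1:10, age = seq(20, 65, 5),
                     median_vaf = 0.25,
                     psoralen_positive = rep(c(TRUE, FALSE), 5))
  out <- clonality_vs_age(flat)
  expect_equal(out$slope, 0, tolerance = 1e-12)
  expect_error(clonality_vs_age(flat[1:2, ]), "at least 3")
  set.seed(41)
  d <- data.frame(age = runif(100, 20, 80),
                  psoralen_positive = runif(100) < 0.3)
  d$median_vaf <- 0.2 + 0.001 * d$age + 0.05 * d$psoralen_positive +
    rnorm(100, 0, 0.02)
  d$patient_id <- seq_len(100)
  out2 <- clonality_vs_age(d)
  expect_lt(out2$psoralen_lrt$p_value, 0.001)
  expect_gt(out2$slope, 0)
})

test_that("basal stem-cell counts follow the areal model", {
  expect_equal(estimate_basal_stem_cells(pi * 4.5^2), 1)
  expect_equal(estimate_basal_stem_cells(636), 10)
  expect_error(estimate_basal_stem_cells(0), "positive")
  # generator default areas give a median of ~30 founding cells
  co <- simulate_cohort(simulation_config(n_patients = 10, rng_seed = 51))
  cells <- estimate_basal_stem_cells(co$microbiopsies$area)
  expect_lt(abs(stats::median(cells) - 30), 6)
})

test_that("detection probability is monotone and calibrates burden correction", {
  p <- detection_probability(c(0.05, 0.1, 0.25, 0.5), mean_depth = 56)
  expect_true(all(diff(p) > 0))
  expect_gt(p[4], 0.99)
  # Monte-Carlo agreement
  set.seed(61)
  d <- rpois(20000, 56)
  a <- rbinom(20000, d, 0.1)
  expect_equal(mean(d >= 4 & a >= 3), detection_probability(0.1, 56),
               tolerance = 0.01)
  expect_equal(correct_burden(100, 0.5, 56), 100 / p[4])
})
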