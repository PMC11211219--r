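test_that("default 1.5T preset reproduces the study group sizes", {
  coh <- generate_cohort(cohort_preset(), seed = 11)
  counts <- table(coh$severity)
  expect_equal(unname(counts[severity_levels()]),
               c(86, 66, 78, 84), ignore_attr = TRUE)
  expect_s3_class(coh$severity, "ordered")
  expect_true(all(coh$ao_lv_ratio > 0))
  expect_identical(unique(coh$field_strength), "1.5T")
})

test_that("cohorts are bit-stable for a fixed seed and leave the RNG alone", {
  cfg <- cohort_preset()
  a <- generate_cohort(cfg, seed = 7)
  set.seed(123)
  before <- .Random.seed
  b <- generate_cohort(cfg, seed = 7)
  expect_identical(a, b)
  expect_identical(before, .Random.seed)
  expect_false(identical(a$ao_lv_ratio,
                         generate_cohort(cfg, seed = 8)$ao_lv_ratio))
})

test_that("zero-variance configuration is exactly degenerate", {
  g <- group_params(n = 10, ratio_mean = 0.45, ratio_sd = 0,
                    peak_velocity_mean = 4.08, peak_velocity_sd = 0)
  cfg <- cohort_config(list(severe = g), within_group_coupling = 0)
  coh <- generate_cohort(cfg, seed = 1)
  expect_identical(coh$ao_lv_ratio, rep(0.45, 10))
  expect_identical(coh$peak_velocity_ms, rep(4.08, 10))
})

test_that("group moments converge to the configured parameters", {
  big <- lapply(cohort_preset()$groups, function(g) { g$n <- 10000L; g })
  cfg <- cohort_config(big)
  coh <- generate_cohort(cfg, seed = 5)
  for (sev in severity_levels()) {
    g <- cohort_preset()$groups[[sev]]
    x <- coh$ao_lv_ratio[coh$severity == sev]
    se <- g$ratio_sd / sqrt(length(x))
    expect_lt(abs(mean(x) - g$ratio_mean), 3 * se)
    expect_lt(abs(sd(x) - g$ratio_sd), 3 * g$ratio_sd / sqrt(2 * length(x)))
  }
  means <- tapply(coh$ao_lv_ratio, coh$severity, mean)
  expect_true(all(diff(means[severity_levels()]) < 0))
})

test_that("within-group ratio-velocity coupling follows the configuration", {
  big <- lapply(cohort_preset()$groups, function(g) { g$n <- 5000L; g })
  cfg0 <- cohort_config(big, within_group_coupling = 0)
  coh0 <- generate_cohort(cfg0, seed = 3)
  for (sev in severity_levels()) {
    sub <- coh0[coh0$severity == sev, ]
    expect_lt(abs(cor(sub$ao_lv_ratio, sub$peak_velocity_ms)),
              3 / sqrt(nrow(sub)))
  }
  cfgn <- cohort_config(big, within_group_coupling = -0.5)
  cohn <- generate_cohort(cfgn, seed = 3)
  sub <- cohn[cohn$severity == "control", ]
  expect_lt(abs(cor(sub$ao_lv_ratio, sub$peak_velocity_ms) - (-0.5)), 0.06)
})

test_that("replicated control means match an independent truncated-normal draw", {
  cfg <- cohort_preset()
  reps <- vapply(1:200, function(r) {
    coh <- generate_cohort(cfg, seed = 3000 + r)
    mean(coh$ao_lv_ratio[coh$severity == "control"])
  }, numeric(1))
  # independent oracle: direct inverse-CDF sampling from the same
  # truncated normal, bypassing the copula machinery
  set.seed(99)
  plo <- pnorm(0.05, 1.01, 0.19)
  direct <- qnorm(plo + runif(200 * 86) * (1 - plo), 1.01, 0.19)
  se <- sqrt(var(reps) / length(reps) + var(direct) / length(direct))
  expect_lt(abs(mean(reps) - mean(direct)), 3 * se)
})

test_that("records respect the physiological flag invariants", {
  coh <- generate_cohort(cohort_preset(), seed = 21)
  expect_identical(coh$low_flow, coh$svi_ml_m2 <= 35)
  expect_type(coh$bicuspid, "logical")
  expect_true(all(coh$peak_gradient_mmhg > 0 & coh$mean_gradient_mmhg > 0))
  # Bernoulli relation keeps gradients coherent with velocity
  expect_gt(cor(coh$peak_gradient_mmhg, 4 * coh$peak_velocity_ms^2), 0.99)
})

test_that("invalid configurations are rejected and empty groups allowed", {
  expect_error(group_params(n = 5, ratio_mean = 1, ratio_sd = -0.1,
                            peak_velocity_mean = 1, peak_velocity_sd = 0.5),
               "standard deviations")
  g <- group_params(n = 5, ratio_mean = 1, ratio_sd = 0.1,
                    peak_velocity_mean = 1, peak_velocity_sd = 0.5)
  expect_error(cohort_config(list(control = g), within_group_coupling = 1.5),
               "within_group_coupling")
  g0 <- g; g0$n <- 0L
  coh <- generate_cohort(cohort_config(list(control = g0)), seed = 1)
  expect_identical(nrow(coh), 0L)
})

test_that("3T preset shrinks ratio separations but keeps the ordering", {
  c15 <- cohort_preset("1.5T")
  c3 <- cohort_preset("3T", separation_shrink = 0.5)
  m15 <- vapply(c15$groups, function(g) g$ratio_mean, numeric(1))
  m3 <- vapply(c3$groups, function(g) g$ratio_mean, numeric(1))
  expect_equal(diff(range(m3)), 0.5 * diff(range(m15)), tolerance = 1e-12)
  expect_true(all(diff(m3[severity_levels()]) < 0))
  expect_identical(generate_cohort(c3, seed = 1)$field_strength[1], "3T")
})

test_that("cohort CSV round-trips with types intact", {
  coh <- generate_cohort(cohort_preset(), seed = 13)
  f <- withr::local_tempfile(fileext = ".csv")
  write_cohort_csv(coh, f)
  back <- read_cohort_csv(f)
  expect_equal(back$ao_lv_ratio, coh$ao_lv_ratio, tolerance = 1e-12)
  expect_identical(as.character(back$severity), as.character(coh$severity))
  expect_identical(back$low_flow, coh$low_flow)
  expect_identical(names(back), names(coh))
})
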