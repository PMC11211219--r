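test_that("Pearson correlation matches the explicit formula and t-transform", {
  x <- 1:10
  expect_equal(pearson_correlation(x, 2 * x + 1)$r, 1.0, tolerance = 1e-12)
  expect_equal(pearson_correlation(x, -x)$r, -1.0, tolerance = 1e-12)

  set.seed(10)
  a <- rnorm(20); b <- 0.5 * a + rnorm(20)
  res <- pearson_correlation(a, b)
  expect_equal(res$r, oracle_pearson(a, b), tolerance = 1e-12)
  tstat <- res$r * sqrt((res$n - 2) / (1 - res$r^2))
  expect_equal(res$p_value, 2 * pt(-abs(tstat), res$n - 2),
               tolerance = 1e-12)
  expect_error(pearson_correlation(rep(1, 10), rnorm(10)), "x is constant")
  expect_error(pearson_correlation(rnorm(10), rep(2, 10)), "y is constant")
})

test_that("AUC equals exhaustive pairwise concordance, including ties", {
  set.seed(11)
  scores <- round(c(rnorm(15, 0.6, 0.2), rnorm(15, 0.9, 0.2)), 1)  # forces ties
  labels <- rep(c(TRUE, FALSE), each = 15)
  roc <- roc_analysis(scores, labels, ci_bootstrap_n = 0)
  expect_equal(roc$auc, oracle_auc(scores, labels), tolerance = 1e-12)
  expect_equal(oracle_auc_trapezoid(roc), roc$auc, tolerance = 1e-12)
})

test_that("AUC hits the separable and null reference points", {
  sep <- roc_analysis(c(0.3, 0.4, 0.9, 1.0), c(TRUE, TRUE, FALSE, FALSE),
                      ci_bootstrap_n = 0)
  expect_identical(sep$auc, 1.0)
  set.seed(12)
  n <- 2000
  null <- roc_analysis(runif(n), runif(n) < 0.5, ci_bootstrap_n = 0)
  expect_lt(abs(null$auc - 0.5), 3 / sqrt(n))
})

test_that("ROC agrees with an independent library implementation", {
  skip_if_not_installed("pROC")
  set.seed(13)
  scores <- c(rnorm(40, 0.6, 0.2), rnorm(40, 1.0, 0.2))
  labels <- rep(c(TRUE, FALSE), each = 40)
  ours <- roc_analysis(scores, labels, ci_bootstrap_n = 0)
  ref <- pROC::roc(response = labels, predictor = scores, direction = ">",
                   levels = c(FALSE, TRUE), quiet = TRUE)
  expect_equal(ours$auc, as.numeric(pROC::auc(ref)), tolerance = 1e-12)
})

test_that("sensitivity and specificity sweep monotonely and CI brackets AUC", {
  coh <- generate_cohort(cohort_preset(), seed = 17)
  roc <- roc_analysis(coh$ao_lv_ratio, coh$severity != "control",
                      ci_bootstrap_n = 400, seed = 5)
  o <- order(roc$thresholds)
  expect_true(all(diff(roc$sensitivity[o]) >= 0))
  expect_true(all(diff(roc$specificity[o]) <= 0))
  expect_true(roc$auc_ci[1] <= roc$auc && roc$auc <= roc$auc_ci[2])
  expect_true(roc$auc >= 0 && roc$auc <= 1)
  expect_error(roc_analysis(1:5, rep(TRUE, 5)), "both diseased")
})

test_that("Youden cut-off maximises J, preferring higher specificity on ties", {
  # interleaved classes give J = 0.5 at two thresholds (2 and 4); the
  # lower threshold has the higher specificity and must win
  scores <- c(1, 3, 2, 4)
  labels <- c(TRUE, TRUE, FALSE, FALSE)
  roc <- roc_analysis(scores, labels, ci_bootstrap_n = 0)
  j <- roc$sensitivity + roc$specificity - 1
  best_j <- max(j)
  at <- which(roc$thresholds == roc$youden_cutoff)
  expect_equal(j[at], best_j, tolerance = 1e-12)
  expect_equal(roc$specificity[at], max(roc$specificity[j == best_j]),
               tolerance = 1e-12)
  expect_identical(roc$youden_cutoff, 2)
})

test_that("operating-point metrics come from direct 2x2 counts", {
  expect_equal(sens_spec_at_cutoff(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                                   0.5),
               c(sensitivity = 0, specificity = 1))
  expect_equal(sens_spec_at_cutoff(c(1, 2, 3, 4), c(TRUE, TRUE, FALSE, FALSE),
                                   10),
               c(sensitivity = 1, specificity = 0))
  # reconstructed 2x2 table: TP=10, FN=2, TN=9, FP=3
  scores <- c(rep(0.4, 10), rep(0.6, 2), rep(0.7, 9), rep(0.3, 3))
  labels <- c(rep(TRUE, 12), rep(FALSE, 12))
  ss <- sens_spec_at_cutoff(scores, labels, 0.5)
  expect_equal(unname(ss), c(10 / 12, 9 / 12), tolerance = 1e-12)
})

test_that("ANOVA F matches the sum-of-squares oracle", {
  coh <- generate_cohort(cohort_preset(), seed = 19)
  groups <- split(coh$ao_lv_ratio, coh$severity)
  gc <- group_comparison(groups)
  expect_equal(gc$f_statistic, oracle_anova_f(groups), tolerance = 1e-10)
  expect_identical(nrow(gc$pairwise), 6L)
  expect_true(all(gc$pairwise$p_adj >= 0 & gc$pairwise$p_adj <= 1))
  # default synthetic cohort separates every severity pair decisively
  expect_true(all(gc$pairwise$p_adj < 0.001))
})

test_that("two-group Tukey collapses to the pooled-variance t-test", {
  set.seed(20)
  g <- list(a = rnorm(12, 0, 1), b = rnorm(15, 0.4, 1))
  gc <- group_comparison(g)
  tt <- t.test(g$a, g$b, var.equal = TRUE)
  expect_equal(gc$pairwise$p_adj, tt$p.value, tolerance = 1e-10)
  # q = sqrt(2)|t| equivalence through the studentized range directly
  q <- sqrt(2) * abs(tt$statistic)
  expect_equal(gc$pairwise$p_adj,
               unname(1 - ptukey(q, nmeans = 2, df = tt$parameter)),
               tolerance = 1e-10)
})

test_that("equal group means give F near 0 and adjusted p near 1", {
  g <- list(a = c(1, 2, 3, 4), b = c(2, 3, 1, 4), c = c(4, 1, 2, 3))
  gc <- group_comparison(g)
  expect_equal(gc$f_statistic, 0, tolerance = 1e-12)
  expect_true(all(gc$pairwise$p_adj > 0.999))
  expect_error(group_comparison(list(a = 1:3)), "at least 2")
  expect_error(group_comparison(list(a = 1:3, b = 2)), "at least 2 values")
})

test_that("Tukey adjustment never reports less than the pairwise t p-value", {
  set.seed(21)
  groups <- split(rnorm(60, rep(c(0, 0.3, 0.6), each = 20), 1),
                  rep(letters[1:3], each = 20))
  gc <- group_comparison(groups)
  mse <- sum(vapply(groups, function(g) sum((g - mean(g))^2), numeric(1))) /
    (60 - 3)
  for (k in seq_len(nrow(gc$pairwise))) {
    pair <- strsplit(gc$pairwise$pair[k], "-")[[1]]
    a <- groups[[pair[1]]]; b <- groups[[pair[2]]]
    tstat <- (mean(a) - mean(b)) /
      sqrt(mse * (1 / length(a) + 1 / length(b)))
    p_unadj <- 2 * pt(-abs(tstat), 60 - 3)
    expect_gte(gc$pairwise$p_adj[k] + 1e-12, p_unadj)
  }
})

test_that("stratified cell means equal a direct group-by computation", {
  cfg <- cohort_preset()
  coh <- generate_cohort(cfg, seed = 23)
  for (strat in c("morphology", "flow_state", "root_dilation")) {
    sc <- stratified_comparison(coh, strat)
    col <- switch(strat, morphology = "bicuspid", flow_state = "low_flow",
                  root_dilation = "dilated_root")
    for (sev in severity_levels()) {
      sub <- coh[coh$severity == sev, ]
      for (fl in c(FALSE, TRUE)) {
        cell <- sub$ao_lv_ratio[sub[[col]] == fl]
        expect_equal(sc$cell_n[fl + 1, sev], length(cell))
        if (length(cell)) {
          expect_equal(sc$cell_means[fl + 1, sev], mean(cell),
                       tolerance = 1e-12)
        } else {
          expect_true(is.na(sc$cell_means[fl + 1, sev]))
        }
      }
    }
  }
})

test_that("a null generator shows no stratum effect beyond the nominal rate", {
  cfg <- cohort_preset()  # bicuspid_ratio_offset is 0 in every group
  pvals <- c()
  for (r in 1:50) {
    coh <- generate_cohort(cfg, seed = 5000 + r)
    sc <- stratified_comparison(coh, "morphology")
    pvals <- c(pvals, sc$tests$p_value)
  }
  pvals <- pvals[!is.na(pvals)]
  # rejection rate should sit near alpha = 0.05 (3-sigma binomial bound)
  bound <- 0.05 + 3 * sqrt(0.05 * 0.95 / length(pvals))
  expect_lt(mean(pvals < 0.05), bound)
})

test_that("morphology-dependent means are recovered from offset generators", {
  tri <- c(control = 1.06, mild = 0.91, moderate = 0.75, severe = 0.55)
  bic <- c(control = 0.87, mild = 0.85, moderate = 0.72, severe = 0.57)
  groups <- lapply(severity_levels(), function(sev) {
    g <- cohort_preset()$groups[[sev]]
    g$n <- 2000L
    g$ratio_mean <- tri[[sev]]
    g$bicuspid_ratio_offset <- bic[[sev]] - tri[[sev]]
    g$bicuspid_fraction <- 0.3
    g
  })
  names(groups) <- severity_levels()
  coh <- generate_cohort(cohort_config(groups), seed = 29)
  sc <- stratified_comparison(coh, "morphology")
  for (sev in severity_levels()) {
    for (fl in c(FALSE, TRUE)) {
      target <- if (fl) bic[[sev]] else tri[[sev]]
      n_cell <- sc$cell_n[fl + 1, sev]
      sd_cell <- sd(coh$ao_lv_ratio[coh$severity == sev &
                                      coh$bicuspid == fl])
      expect_lt(abs(sc$cell_means[fl + 1, sev] - target),
                3 * sd_cell / sqrt(n_cell))
    }
  }
})

test_that("agreement statistics behave at the degenerate reference points", {
  r1 <- c(0.41, 0.63, 0.85, 0.99, 1.21, 0.52, 0.77)
  perfect <- agreement_stats(r1, r1)
  expect_equal(perfect$icc, 1.0, tolerance = 1e-12)
  expect_identical(perfect$bland_altman_bias, 0)
  expect_identical(c(perfect$loa_low, perfect$loa_high), c(0, 0))
  expect_equal(perfect$pearson_inter, 1.0, tolerance = 1e-12)

  shifted <- agreement_stats(r1, r1 + 0.1)
  expect_equal(shifted$pearson_inter, 1.0, tolerance = 1e-12)
  expect_lt(shifted$icc, 1.0)  # absolute agreement penalises the offset
  expect_equal(shifted$bland_altman_bias, 0.1, tolerance = 1e-12)
  expect_error(agreement_stats(r1, r1[-1]), "equal length")
  expect_error(agreement_stats(r1[1:3], r1[1:3]), "at least 5")
})

test_that("ICC mean squares agree with a two-way aov decomposition", {
  set.seed(31)
  truth <- rnorm(40, 0.8, 0.2)
  x1 <- truth + rnorm(40, 0, 0.1)
  x2 <- truth + rnorm(40, 0, 0.1)
  res <- agreement_stats(x1, x2)
  d <- data.frame(y = c(x1, x2),
                  subj = factor(rep(1:40, 2)),
                  rater = factor(rep(1:2, each = 40)))
  ms <- anova(aov(y ~ subj + rater, data = d))[["Mean Sq"]]
  icc_oracle <- (ms[1] - ms[3]) /
    (ms[1] + ms[3] + 2 * (ms[2] - ms[3]) / 40)
  expect_equal(res$icc, icc_oracle, tolerance = 1e-10)
})

test_that("ICC recovers the generating variance ratio", {
  sigma_t <- 0.2; sigma_e <- 0.1
  true_icc <- sigma_t^2 / (sigma_t^2 + sigma_e^2)
  set.seed(33)
  iccs <- vapply(1:60, function(i) {
    truth <- rnorm(150, 0.8, sigma_t)
    agreement_stats(truth + rnorm(150, 0, sigma_e),
                    truth + rnorm(150, 0, sigma_e))$icc
  }, numeric(1))
  expect_lt(abs(mean(iccs) - true_icc), 3 * sd(iccs) / sqrt(length(iccs)))
})
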