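#' Pearson correlation with t-transform p-value
#'
#' Product-moment correlation between an imaging ratio and a reference
#' parameter, with the two-sided p-value from
#' `t = r * sqrt((n - 2) / (1 - r^2))` on n - 2 degrees of freedom.
#'
#' @param x,y numeric vectors of equal length >= 3.
#' @return An object of class `correlation_result` with `r`, `p_value`, `n`.
#' @export
pearson_correlation <- function(x, y) {
  ok <- is.finite(x) & is.finite(y)
  x <- x[ok]; y <- y[ok]
  n <- length(x)
  if (length(y) != n) stop("x and y must have equal length")
  if (n < 3) stop("need at least 3 complete pairs")
  if (stats::sd(x) == 0) stop("x is constant; correlation undefined")
  if (stats::sd(y) == 0) stop("y is constant; correlation undefined")
  ct <- stats::cor.test(x, y, method = "pearson")
  structure(
    list(r = unname(ct$estimate), p_value = ct$p.value, n = n),
    class = "correlation_result"
  )
}

# Mann-Whitney AUC for "lower score = positive": P(score_pos < score_neg),
# ties counted 1/2. Rank identity keeps this O(n log n) for the bootstrap.
auc_mw <- function(scores, labels) {
  pos <- as.logical(labels)
  n1 <- sum(pos); n0 <- sum(!pos)
  if (n1 == 0 || n0 == 0) return(NA_real_)
  r <- rank(scores)
  (sum(r[!pos]) - n0 * (n0 + 1) / 2) / (n0 * n1)
}

#' ROC analysis of the Ao:LV ratio
#'
#' Empirical ROC with the orientation fixed to "lower ratio = positive
#' (diseased)": a patient is called positive when the score is strictly
#' below the threshold. The AUC is the Mann-Whitney concordance
#' probability (ties counted 1/2); its 95% CI is a seeded nonparametric
#' percentile bootstrap over patients; the Youden cut-off maximises
#' sensitivity + specificity - 1, with ties resolved towards the higher
#' specificity (lower threshold).
#'
#' @param scores Ao:LV ratios.
#' @param labels disease indicators (logical or 0/1); `TRUE` = diseased.
#' @param ci_bootstrap_n bootstrap replicates for the AUC CI (0 skips it).
#' @param seed seed for the bootstrap resampling.
#' @return An object of class `roc_result` with `thresholds`,
#'   `sensitivity`, `specificity`, `auc`, `auc_ci`, `youden_cutoff`,
#'   `orientation`.
#' @export
#' @examples
#' coh <- generate_cohort(cohort_preset(), seed = 7)
#' roc <- roc_analysis(coh$ao_lv_ratio, coh$severity != "control",
#'                     ci_bootstrap_n = 200, seed = 1)
#' round(c(roc$auc, roc$auc_ci), 3)
roc_analysis <- function(scores, labels, ci_bootstrap_n = 2000, seed = NULL) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  ok <- is.finite(scores) & !is.na(labels)
  scores <- scores[ok]; labels <- labels[ok]
  n1 <- sum(labels); n0 <- sum(!labels)
  if (n1 == 0 || n0 == 0) {
    stop("both diseased and non-diseased patients are required")
  }

  thr <- c(-Inf, sort(unique(scores)), Inf)
  pos_scores <- scores[labels]
  neg_scores <- scores[!labels]
  sens <- vapply(thr, function(t) mean(pos_scores < t), numeric(1))
  spec <- vapply(thr, function(t) mean(neg_scores >= t), numeric(1))

  auc <- auc_mw(scores, labels)

  j <- sens + spec - 1
  best <- which(j == max(j))
  if (length(best) > 1) best <- best[which.max(spec[best])]
  youden <- thr[best]

  ci <- c(NA_real_, NA_real_)
  if (ci_bootstrap_n > 0) {
    n <- length(scores)
    aucs <- with_seed(seed, {
      vapply(seq_len(ci_bootstrap_n), function(b) {
        idx <- sample.int(n, n, replace = TRUE)
        auc_mw(scores[idx], labels[idx])
      }, numeric(1))
    })
    aucs <- aucs[is.finite(aucs)]
    ci <- unname(stats::quantile(aucs, c(0.025, 0.975)))
  }

  structure(
    list(thresholds = thr, sensitivity = sens, specificity = spec,
         auc = auc, auc_ci = ci, youden_cutoff = youden,
         n_pos = n1, n_neg = n0,
         orientation = "lower ratio = positive"),
    class = "roc_result"
  )
}

#' @export
print.roc_result <- function(x, ...) {
  cat(sprintf("ROC (%s): AUC = %.3f (95%% CI %.3f-%.3f), Youden cutoff = %.3f\n",
              x$orientation, x$auc, x$auc_ci[1], x$auc_ci[2],
              x$youden_cutoff))
  invisible(x)
}

#' Sensitivity and specificity at a fixed cut-off
#'
#' Positive call iff `score < cutoff` (lower ratio = diseased).
#'
#' @param scores Ao:LV ratios.
#' @param labels disease indicators; `TRUE` = diseased.
#' @param cutoff ratio cut-off.
#' @return named numeric vector `c(sensitivity, specificity)`.
#' @export
#' @examples
#' sens_spec_at_cutoff(c(0.4, 0.7, 0.9, 1.1), c(TRUE, TRUE, FALSE, FALSE), 0.86)
sens_spec_at_cutoff <- function(scores, labels, cutoff) {
  labels <- as.logical(labels)
  if (length(scores) != length(labels)) {
    stop("scores and labels must have equal length")
  }
  if (!any(labels) || all(labels)) {
    stop("both diseased and non-diseased patients are required")
  }
  pos <- scores < cutoff
  c(sensitivity = mean(pos[labels]), specificity = mean(!pos[!labels]))
}

#' One-way ANOVA with Tukey HSD across severity groups
#'
#' Compares the Ao:LV ratio across severity classes by one-way analysis of
#' variance, with all pairwise contrasts adjusted by Tukey's honestly
#' significant difference (studentized range).
#'
#' @param groups named list of numeric vectors (>= 2 groups, each >= 2
#'   values), or a data.frame with columns `value` and `group`.
#' @return An object of class `group_comparison` with `f_statistic`,
#'   `p_value`, and a `pairwise` data.frame (`pair`, `diff`, `p_adj`).
#' @export
#' @examples
#' coh <- generate_cohort(cohort_preset(), seed = 3)
#' gc <- group_comparison(split(coh$ao_lv_ratio, coh$severity))
#' gc$pairwise
group_comparison <- function(groups) {
  if (is.data.frame(groups)) {
    groups <- split(groups$value, groups$group)
  }
  groups <- groups[vapply(groups, length, integer(1)) > 0]
  if (length(groups) < 2) stop("need at least 2 non-empty groups")
  if (any(vapply(groups, length, integer(1)) < 2)) {
    stop("each group needs at least 2 values")
  }
  if (all(vapply(groups, stats::sd, numeric(1)) == 0) &&
      length(unique(vapply(groups, mean, numeric(1)))) == 1) {
    stop("all values identical; ANOVA undefined")
  }
  df <- data.frame(
    value = unlist(groups, use.names = FALSE),
    group = factor(rep(names(groups), lengths(groups)), levels = names(groups))
  )
  fit <- stats::aov(value ~ group, data = df)
  an <- summary(fit)[[1]]
  tk <- stats::TukeyHSD(fit)$group
  structure(
    list(f_statistic = an[["F value"]][1],
         p_value = an[["Pr(>F)"]][1],
         df_between = an[["Df"]][1], df_within = an[["Df"]][2],
         pairwise = data.frame(pair = rownames(tk),
                               diff = unname(tk[, "diff"]),
                               p_adj = unname(tk[, "p adj"]),
                               row.names = NULL)),
    class = "group_comparison"
  )
}

#' Stratified subgroup comparison of the Ao:LV ratio
#'
#' Within each severity class, compares the ratio between the two levels of
#' a patient stratifier -- valve morphology (bicuspid vs trileaflet), flow
#' state (stroke volume index <= 35 ml/m^2 vs normal), or aortic root
#' dilation (> 40 mm vs not) -- by a pooled-variance two-sample t-test, and
#' reports the per-cell means in a stratum x severity layout. Cells with
#' fewer than two patients are flagged absent (`NA`), not an error.
#'
#' @param records cohort data.frame from [generate_cohort()] /
#'   [read_cohort_csv()].
#' @param stratifier one of `"morphology"`, `"flow_state"`,
#'   `"root_dilation"`.
#' @return An object of class `stratified_comparison` with `cell_means`,
#'   `cell_n` (stratum x severity matrices) and `tests` (per-severity
#'   t-statistics and p-values).
#' @export
stratified_comparison <- function(records,
                                  stratifier = c("morphology", "flow_state",
                                                 "root_dilation")) {
  stratifier <- match.arg(stratifier)
  col <- switch(stratifier, morphology = "bicuspid", flow_state = "low_flow",
                root_dilation = "dilated_root")
  if (!col %in% names(records)) {
    stop("records lack the '", col, "' column for stratifier ", stratifier)
  }
  strata <- switch(stratifier,
                   morphology = c("tricuspid", "bicuspid"),
                   flow_state = c("normal_flow", "low_flow"),
                   root_dilation = c("non_dilated", "dilated"))
  sevs <- severity_levels()
  cm <- matrix(NA_real_, 2, length(sevs), dimnames = list(strata, sevs))
  cn <- matrix(0L, 2, length(sevs), dimnames = list(strata, sevs))
  tests <- data.frame(severity = sevs, t = NA_real_, df = NA_real_,
                      p_value = NA_real_)
  for (k in seq_along(sevs)) {
    sub <- records[records$severity == sevs[k], ]
    flag <- as.logical(sub[[col]])
    a <- sub$ao_lv_ratio[!flag]  # reference stratum
    b <- sub$ao_lv_ratio[flag]
    cn[1, k] <- length(a); cn[2, k] <- length(b)
    if (length(a)) cm[1, k] <- mean(a)
    if (length(b)) cm[2, k] <- mean(b)
    if (length(a) >= 2 && length(b) >= 2) {
      tt <- stats::t.test(a, b, var.equal = TRUE)
      tests$t[k] <- unname(tt$statistic)
      tests$df[k] <- unname(tt$parameter)
      tests$p_value[k] <- tt$p.value
    }
  }
  structure(
    list(stratifier = stratifier, cell_means = cm, cell_n = cn,
         tests = tests),
    class = "stratified_comparison"
  )
}

#' Observer agreement statistics
#'
#' Inter-observer agreement between two readers' Ao:LV measurements:
#' ICC(2,1) (two-way random effects, absolute agreement, single measure)
#' from the mean-squares decomposition, Pearson correlation, and
#' Bland-Altman bias (mean of reader2 - reader1) with 95% limits of
#' agreement (bias +/- 1.96 SD of the differences). Optional repeat
#' readings by one reader give the intra-observer Pearson correlation.
#'
#' @param reader1,reader2 paired measurements from two readers (>= 5 pairs).
#' @param repeat1,repeat2 optional paired repeat measurements from one
#'   reader.
#' @return An object of class `agreement_result`.
#' @export
#' @examples
#' r1 <- c(0.4, 0.6, 0.8, 1.0, 1.2)
#' agreement_stats(r1, r1 + 0.05)
agreement_stats <- function(reader1, reader2, repeat1 = NULL,
                            repeat2 = NULL) {
  if (length(reader1) != length(reader2)) {
    stop("reader1 and reader2 must have equal length")
  }
  n <- length(reader1)
  if (n < 5) stop("need at least 5 paired measurements")
  x <- cbind(reader1, reader2)
  k <- 2L
  rowm <- rowMeans(x); colm <- colMeans(x); gm <- mean(x)
  msr <- k * sum((rowm - gm)^2) / (n - 1)
  msc <- n * sum((colm - gm)^2) / (k - 1)
  sse <- sum((x - matrix(rowm, n, k) -
                matrix(colm, n, k, byrow = TRUE) + gm)^2)
  mse <- sse / ((n - 1) * (k - 1))
  denom <- msr + (k - 1) * mse + k * (msc - mse) / n
  icc <- if (denom == 0) NA_real_ else (msr - mse) / denom

  d <- reader2 - reader1
  bias <- mean(d)
  sdd <- stats::sd(d)
  loa <- bias + c(-1.96, 1.96) * sdd

  pearson_intra <- NA_real_
  if (!is.null(repeat1) && !is.null(repeat2)) {
    if (length(repeat1) != length(repeat2)) {
      stop("repeat1 and repeat2 must have equal length")
    }
    pearson_intra <- stats::cor(repeat1, repeat2)
  }
  structure(
    list(icc = icc, icc_model = "ICC(2,1) absolute agreement",
         pearson_inter = stats::cor(reader1, reader2),
         pearson_intra = pearson_intra,
         bland_altman_bias = bias, loa_low = loa[1], loa_high = loa[2],
         n = n),
    class = "agreement_result"
  )
}

#' @export
print.agreement_result <- function(x, ...) {
  cat(sprintf("%s = %.3f; inter-reader r = %.3f; bias = %.4f (LoA %.4f to %.4f)\n",
              x$icc_model, x$icc, x$pearson_inter, x$bland_altman_bias,
              x$loa_low, x$loa_high))
  if (!is.na(x$pearson_intra)) {
    cat(sprintf("intra-reader r = %.3f\n", x$pearson_intra))
  }
  invisible(x)
}

#' Closed-form AUC for a mixture of truncated-normal groups
#'
#' Analytic benchmark for the any-AS discrimination task: for Gaussian
#' class-conditional scores, P(X_pos < X_neg) = Phi((mu_neg - mu_pos) /
#' sqrt(sd_neg^2 + sd_pos^2)). With the diseased class a mixture of
#' severity groups, the AUC is the group-size-weighted average of the
#' pairwise values against the control group. Truncation is ignored: at
#' the calibrated parameters the sub-floor mass is negligible (< 1e-6).
#'
#' @param config a [cohort_config()].
#' @return analytic AUC for AS (mild+moderate+severe) vs control.
#' @export
mixture_auc_normal <- function(config) {
  g <- config$groups
  ctrl <- g$control
  as_groups <- g[setdiff(names(g), "control")]
  w <- vapply(as_groups, function(x) x$n, numeric(1))
  auc_g <- vapply(as_groups, function(x) {
    stats::pnorm((ctrl$ratio_mean - x$ratio_mean) /
                   sqrt(ctrl$ratio_sd^2 + x$ratio_sd^2))
  }, numeric(1))
  sum(w * auc_g) / sum(w)
}
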