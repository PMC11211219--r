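#' Study run configuration
#'
#' Bundles everything [run_study()] needs: the cohort generator
#' configuration, the diagnostic cut-offs, the number of Monte-Carlo
#' replicates, the optional phantom check, the simulated dual-reader
#' protocol, and the master seed. Replicate r uses seed `seed + r`, so the
#' whole study is deterministic for a fixed seed.
#'
#' @param cohort a [cohort_config()].
#' @param cutoffs a [cutoff_scheme()].
#' @param replicates number of cohort replicates (>= 1).
#' @param n_phantoms phantoms to render and measure (0 skips the block).
#' @param phantom_template [phantom_spec()] used for the phantom block
#'   (its `true_ratio` and `seed` are overridden per phantom).
#' @param observer_subset patients re-read in the simulated dual-reader
#'   block.
#' @param observer_sigma SD of the simulated reader measurement noise on
#'   the ratio scale.
#' @param ci_bootstrap_n bootstrap replicates for the AUC CI.
#' @param seed master seed.
#' @return An object of class `run_config`.
#' @export
run_config <- function(cohort = cohort_preset(),
                       cutoffs = cutoff_scheme(),
                       replicates = 200L,
                       n_phantoms = 0L,
                       phantom_template = phantom_spec(),
                       observer_subset = 46L,
                       observer_sigma = 0.06,
                       ci_bootstrap_n = 2000L,
                       seed = 1L) {
  if (replicates < 1) stop("replicates must be >= 1")
  if (observer_sigma < 0) stop("observer_sigma must be >= 0")
  structure(
    list(cohort = cohort, cutoffs = cutoffs,
         replicates = as.integer(replicates),
         n_phantoms = as.integer(n_phantoms),
         phantom_template = phantom_template,
         observer_subset = as.integer(observer_subset),
         observer_sigma = observer_sigma,
         ci_bootstrap_n = as.integer(ci_bootstrap_n),
         seed = as.integer(seed)),
    class = "run_config"
  )
}

.config_hash <- function(config) {
  json <- jsonlite::toJSON(rapply(unclass(config), unclass, how = "replace"),
                           auto_unbox = TRUE, digits = 15, force = TRUE)
  f <- tempfile()
  on.exit(unlink(f))
  writeLines(as.character(json), f)
  unname(tools::md5sum(f))
}

.agg <- function(x) {
  list(mean = mean(x), mc_se = stats::sd(x) / sqrt(length(x)))
}

#' Run the full desk-scale study
#'
#' Orchestrates the pipeline: generates `replicates` synthetic cohorts,
#' computes for each the any-AS ROC AUC, sensitivity/specificity at both
#' cut-offs (any-AS at the upper cut-off, severe-AS at the lower), the
#' per-severity group means and the ratio--covariate correlations, and
#' aggregates each statistic as mean with Monte-Carlo standard error. On
#' the first replicate it additionally runs the full ROC with bootstrap CI,
#' the ANOVA/Tukey group comparison, the three stratified subgroup tables,
#' and a simulated dual-reader agreement block. Optionally renders and
#' measures phantoms against ground truth. Deterministic for a fixed seed;
#' stage timings are logged via `message()` and never enter the report.
#'
#' @param config a [run_config()].
#' @param quiet suppress stage log messages.
#' @return An object of class `study_report` (nested list; see
#'   [write_study_report()]).
#' @export
#' @examples
#' rep <- run_study(run_config(replicates = 5, ci_bootstrap_n = 50), quiet = TRUE)
#' rep$roc_any_as$auc
run_study <- function(config = run_config(), quiet = FALSE) {
  if (!inherits(config, "run_config")) stop("config must be a run_config")
  log_stage <- function(stage, t0) {
    if (!quiet) {
      message(sprintf("[%s] done in %.2f s", stage,
                      as.numeric(Sys.time()) - t0))
    }
  }
  cuts <- config$cutoffs
  R <- config$replicates
  sevs <- severity_levels()

  t0 <- as.numeric(Sys.time())
  per <- vector("list", R)
  first_cohort <- NULL
  for (r in seq_len(R)) {
    coh <- tryCatch(
      generate_cohort(config$cohort, seed = config$seed + r),
      error = function(e) stop_stage("simulate", conditionMessage(e))
    )
    if (r == 1L) first_cohort <- coh
    any_as <- coh$severity != "control"
    severe <- coh$severity == "severe"
    ss_any <- sens_spec_at_cutoff(coh$ao_lv_ratio, any_as, cuts$any_as_cutoff)
    ss_sev <- sens_spec_at_cutoff(coh$ao_lv_ratio, severe, cuts$severe_cutoff)
    roc <- roc_analysis(coh$ao_lv_ratio, any_as, ci_bootstrap_n = 0)
    gm <- vapply(sevs, function(s) mean(coh$ao_lv_ratio[coh$severity == s]),
                 numeric(1))
    gs <- vapply(sevs, function(s) stats::sd(coh$ao_lv_ratio[coh$severity == s]),
                 numeric(1))
    cors <- vapply(c("peak_velocity_ms", "mean_gradient_mmhg",
                     "peak_gradient_mmhg", "dimensionless_index", "ava_cm2"),
                   function(v) {
                     pearson_correlation(coh$ao_lv_ratio, coh[[v]])$r
                   }, numeric(1))
    per[[r]] <- list(auc = roc$auc, youden = roc$youden_cutoff,
                     sens_any = ss_any[["sensitivity"]],
                     spec_any = ss_any[["specificity"]],
                     sens_severe = ss_sev[["sensitivity"]],
                     spec_severe = ss_sev[["specificity"]],
                     group_means = gm, group_sds = gs, cors = cors)
  }
  log_stage("simulate+diagnose", t0)

  pull <- function(field) vapply(per, function(p) p[[field]], numeric(1))
  group_summary <- lapply(seq_along(sevs), function(k) {
    list(severity = sevs[k],
         n = config$cohort$groups[[sevs[k]]]$n,
         ratio_mean = .agg(vapply(per, function(p) p$group_means[k],
                                  numeric(1))),
         ratio_sd = .agg(vapply(per, function(p) p$group_sds[k],
                                numeric(1))))
  })
  names(group_summary) <- sevs
  cor_names <- names(per[[1]]$cors)
  correlations <- lapply(seq_along(cor_names), function(k) {
    .agg(vapply(per, function(p) p$cors[k], numeric(1)))
  })
  names(correlations) <- cor_names

  t0 <- as.numeric(Sys.time())
  any_as1 <- first_cohort$severity != "control"
  roc_full <- roc_analysis(first_cohort$ao_lv_ratio, any_as1,
                           ci_bootstrap_n = config$ci_bootstrap_n,
                           seed = config$seed + 900001L)
  anova1 <- group_comparison(split(first_cohort$ao_lv_ratio,
                                   first_cohort$severity))
  strata <- lapply(c("morphology", "flow_state", "root_dilation"),
                   function(s) {
                     sc <- stratified_comparison(first_cohort, s)
                     list(stratifier = s,
                          cell_means = sc$cell_means,
                          cell_n = sc$cell_n,
                          tests = sc$tests)
                   })
  names(strata) <- c("morphology", "flow_state", "root_dilation")
  log_stage("analyze", t0)

  t0 <- as.numeric(Sys.time())
  agreement <- with_seed(config$seed + 900002L, {
    idx <- sample.int(nrow(first_cohort),
                      min(config$observer_subset, nrow(first_cohort)))
    truth <- first_cohort$ao_lv_ratio[idx]
    r1 <- truth + stats::rnorm(length(idx), 0, config$observer_sigma)
    r2 <- truth + stats::rnorm(length(idx), 0, config$observer_sigma)
    rep1 <- truth + stats::rnorm(length(idx), 0, config$observer_sigma)
    rep2 <- truth + stats::rnorm(length(idx), 0, config$observer_sigma)
    agreement_stats(r1, r2, rep1, rep2)
  })
  log_stage("agreement", t0)

  phantom_block <- NULL
  if (config$n_phantoms > 0) {
    t0 <- as.numeric(Sys.time())
    ratios <- seq(0.3, 1.2, length.out = config$n_phantoms)
    rows <- lapply(seq_len(config$n_phantoms), function(j) {
      spec <- config$phantom_template
      spec$true_ratio <- ratios[j]
      spec$seed <- config$seed + 900100L + j
      ph <- tryCatch(render_phantom(spec),
                     error = function(e) stop_stage("render-phantom",
                                                    conditionMessage(e)))
      m <- tryCatch(measure_cine(ph$cine, ph$landmarks, cuts),
                    error = function(e) stop_stage("measure",
                                                   conditionMessage(e)))
      list(true_ratio = ratios[j], measured_ratio = m$ratio,
           abs_error = abs(m$ratio - ratios[j]),
           class = as.character(m$class))
    })
    phantom_block <- list(n = config$n_phantoms,
                          noise_sigma = config$phantom_template$noise_sigma,
                          results = rows,
                          max_abs_error = max(vapply(rows,
                                                     function(x) x$abs_error,
                                                     numeric(1))))
    log_stage("phantoms", t0)
  }

  report <- list(
    schema_version = "1.0",
    provenance = list(
      package = "aolvratio",
      version = as.character(utils::packageVersion("aolvratio")),
      seed = config$seed,
      replicates = R,
      config_hash = .config_hash(config)
    ),
    group_summary = group_summary,
    correlations = correlations,
    roc_any_as = list(
      auc = .agg(pull("auc")),
      auc_ci_first_replicate = roc_full$auc_ci,
      youden_cutoff = .agg(pull("youden")),
      sens_at_any_cutoff = .agg(pull("sens_any")),
      spec_at_any_cutoff = .agg(pull("spec_any")),
      cutoff_any = cuts$any_as_cutoff
    ),
    roc_severe_as = list(
      sens_at_severe_cutoff = .agg(pull("sens_severe")),
      spec_at_severe_cutoff = .agg(pull("spec_severe")),
      cutoff_severe = cuts$severe_cutoff
    ),
    analytic_auc_any_as = mixture_auc_normal(config$cohort),
    anova_first_replicate = list(
      f_statistic = anova1$f_statistic,
      p_value = anova1$p_value,
      pairwise = anova1$pairwise
    ),
    subgroups_first_replicate = strata,
    agreement = list(
      icc = agreement$icc, icc_model = agreement$icc_model,
      pearson_inter = agreement$pearson_inter,
      pearson_intra = agreement$pearson_intra,
      bland_altman_bias = agreement$bland_altman_bias,
      loa_low = agreement$loa_low, loa_high = agreement$loa_high,
      n = agreement$n, observer_sigma = config$observer_sigma
    ),
    phantoms = phantom_block
  )
  structure(report, class = "study_report")
}

#' @export
print.study_report <- function(x, ...) {
  cat("aolvratio study report (schema", x$schema_version, ")\n")
  cat(sprintf("  replicates: %d, seed: %d\n", x$provenance$replicates,
              x$provenance$seed))
  for (g in x$group_summary) {
    cat(sprintf("  %-8s n=%3d  Ao:LV %.3f +/- %.3f\n", g$severity, g$n,
                g$ratio_mean$mean, g$ratio_sd$mean))
  }
  cat(sprintf("  any-AS AUC %.3f (MC SE %.4f); sens/spec @%.2f: %.1f%%/%.1f%%\n",
              x$roc_any_as$auc$mean, x$roc_any_as$auc$mc_se,
              x$roc_any_as$cutoff_any,
              100 * x$roc_any_as$sens_at_any_cutoff$mean,
              100 * x$roc_any_as$spec_at_any_cutoff$mean))
  cat(sprintf("  severe-AS sens/spec @%.2f: %.1f%%/%.1f%%\n",
              x$roc_severe_as$cutoff_severe,
              100 * x$roc_severe_as$sens_at_severe_cutoff$mean,
              100 * x$roc_severe_as$spec_at_severe_cutoff$mean))
  invisible(x)
}

#' Write a study report as JSON
#'
#' @param report a `study_report` from [run_study()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_study_report <- function(report, path) {
  if (!inherits(report, "study_report")) {
    stop("report must be a study_report")
  }
  jsonlite::write_json(unclass(report), path, auto_unbox = TRUE,
                       digits = NA, pretty = TRUE, force = TRUE,
                       na = "null")
  invisible(path)
}
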