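# Provenance header written at the top of every run log.
run_log_lines <- function(command, seed, extra = character()) {
  c(sprintf("command: %s", command),
    sprintf("package: relapsefrailty %s",
            as.character(utils::packageVersion("relapsefrailty"))),
    sprintf("seed: %d", seed),
    sprintf("date: %s", format(Sys.time(), "%Y-%m-%d %H:%M:%S %Z")),
    extra)
}

write_run_log <- function(lines, out_dir, name = "run_log.txt") {
  writeLines(lines, file.path(out_dir, name))
}

#' Simulate a synthetic cohort and write it to disk
#'
#' Writes `dataset.csv` (long gap-time format), `truth.csv` (the
#' generating parameters, flat key-value) and `run_log.txt` (provenance:
#' package version, seed, configuration) into `out_dir`.
#'
#' @param out_dir output directory (created if needed).
#' @param n_subjects cohort size.
#' @param params generating [model_params()].
#' @param profile covariate [cohort_profile()].
#' @param seed integer seed; recorded in the log.
#' @param ... further arguments to [simulate_cohort()].
#' @return the simulated `gap_dataset`, invisibly.
#' @export
run_simulate <- function(out_dir, n_subjects = 159,
                         params = default_truth(),
                         profile = default_profile(), seed = 1, ...) {
  if (n_subjects < 1) {
    stop("run_simulate: n_subjects must be >= 1", call. = FALSE)
  }
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  ds <- simulate_cohort(n_subjects = n_subjects, params = params,
                        profile = profile, seed = seed, ...)
  write_gap_data(ds, file.path(out_dir, "dataset.csv"))
  truth_kv <- data.frame(
    name = c("beta0", paste0("beta.", names(params$beta)),
             "gamma", "alpha", "theta"),
    value = sprintf("%.17g", c(params$beta0, params$beta, params$gamma,
                               params$alpha, params$theta)))
  utils::write.csv(truth_kv, file.path(out_dir, "truth.csv"),
                   row.names = FALSE, quote = FALSE)
  write_run_log(run_log_lines("simulate", seed,
                              sprintf("n_subjects: %d", n_subjects)),
                out_dir)
  invisible(ds)
}

# Relabel the summary for tabular output: covariate rows plus the named
# shape / event-dependence / frailty-variance rows, intercept dropped.
summary_table2 <- function(smry) {
  labels <- c(
    age_onset = "Age of onset", gender = "Gender (male)",
    marital = "Marital status (single)", mode_onset = "Mode of onset (gradual)",
    head_injury = "History of head injury (yes)",
    family_history = "Family history (yes)",
    alpha = "Event dependence", gamma = "Weibull shape",
    theta = "Frailty variance")
  rows <- smry[match(names(labels), smry$parameter), , drop = FALSE]
  rows$variable <- unname(labels)
  rows[, c("variable", "mean", "sd", "lower", "upper", "significant")]
}

#' Fit a dataset and write posterior summaries to disk
#'
#' Validates the dataset (reporting all violations before any sampling),
#' runs [run_mcmc()], and writes `summary.csv` (nine-row table: six
#' covariate effects, event dependence, Weibull shape, frailty
#' variance), `draws.csv` (retained draws with chain and iteration
#' columns), `diagnostics.csv` (split R-hat and ESS) and `run_log.txt`.
#'
#' @param data_file CSV dataset in the long gap-time format.
#' @param out_dir output directory (created if needed).
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()].
#' @return list with elements `summary`, `draws`, `diagnostics`,
#'   invisibly.
#' @export
run_fit <- function(data_file, out_dir, priors = prior_spec(),
                    config = mcmc_config()) {
  ds <- read_gap_data(data_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  draws <- run_mcmc(ds, priors = priors, config = config)
  smry <- summarize_posterior(draws)
  diag <- mcmc_diagnostics(draws)

  utils::write.csv(summary_table2(smry), file.path(out_dir, "summary.csv"),
                   row.names = FALSE)
  draw_df <- data.frame(chain = draws$chain,
                        iteration = stats::ave(draws$chain, draws$chain,
                                               FUN = seq_along),
                        draws$draws)
  utils::write.csv(draw_df, file.path(out_dir, "draws.csv"),
                   row.names = FALSE)
  utils::write.csv(as.data.frame(diag),
                   file.path(out_dir, "diagnostics.csv"), row.names = FALSE)
  acc <- vapply(draws$accept, function(a) paste(sprintf("%s=%.2f",
                                                        names(a), a),
                                                collapse = " "),
                character(1))
  write_run_log(run_log_lines(
    "fit", config$seed,
    c(sprintf("data_file: %s", data_file),
      sprintf("chains: %d iterations: %d burnin: %d thin: %d",
              config$n_chains, config$n_iter, config$n_burnin, config$thin),
      sprintf("acceptance chain %d: %s", seq_along(acc), acc))), out_dir)
  invisible(list(summary = smry, draws = draws, diagnostics = diag))
}

#' Run a simulate-then-fit recovery study and write the report
#'
#' Single-seed mode writes `recovery.csv` (truth, posterior mean/sd, 95%
#' interval, coverage indicator and absolute error per parameter).  With
#' `seeds` of length > 1 the study is repeated and
#' `recovery_aggregate.csv` additionally reports per-parameter coverage
#' proportions and mean absolute errors across seeds.
#'
#' @param out_dir output directory.
#' @param truth generating [model_params()].
#' @param profile covariate [cohort_profile()].
#' @param n_subjects cohort size.
#' @param priors a [prior_spec()].
#' @param config an [mcmc_config()]; its seed field is replaced by each
#'   element of `seeds` in turn.
#' @param seeds integer vector of seeds (one recovery run each).
#' @param ... passed to [simulate_cohort()].
#' @return list of `recovery_report`s, invisibly.
#' @export
run_recover <- function(out_dir, truth = default_truth(),
                        profile = default_profile(), n_subjects = 159,
                        priors = prior_spec(), config = mcmc_config(),
                        seeds = config$seed, ...) {
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  reports <- lapply(seeds, function(s) {
    cfg <- config
    cfg$seed <- as.integer(s)
    rep_s <- recover_params(truth = truth, profile = profile,
                            n_subjects = n_subjects, priors = priors,
                            config = cfg, ...)
    rep_s$seed <- s
    rep_s
  })
  flat <- do.call(rbind, lapply(reports, as.data.frame))
  utils::write.csv(flat, file.path(out_dir, "recovery.csv"),
                   row.names = FALSE)
  if (length(seeds) > 1) {
    agg <- stats::aggregate(cbind(covered, abs_error) ~ parameter,
                            data = flat, FUN = mean)
    names(agg) <- c("parameter", "coverage", "mean_abs_error")
    utils::write.csv(agg, file.path(out_dir, "recovery_aggregate.csv"),
                     row.names = FALSE)
  }
  write_run_log(run_log_lines(
    "recover", seeds[1],
    c(sprintf("seeds: %s", paste(seeds, collapse = ",")),
      sprintf("n_subjects: %d", n_subjects))), out_dir)
  invisible(reports)
}

#' Describe a cohort: covariate distribution and relapse cross-tab
#'
#' Writes `covariates.csv` (per-covariate frequency or mean/sd) and
#' `relapse_table.csv` (relapse-count by family-history by gender
#' cross-tabulation with within-stratum percentages) into `out_dir`.
#'
#' @param data_file CSV dataset in the long gap-time format.
#' @param out_dir output directory.
#' @return list with elements `covariates` and `relapse_table`,
#'   invisibly.
#' @export
run_describe <- function(data_file, out_dir) {
  ds <- read_gap_data(data_file)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  per_subject <- unique(as.data.frame(ds)[, c("subject_id",
                                              COVARIATE_COLS)])
  cov_rows <- lapply(COVARIATE_COLS, function(col) {
    v <- per_subject[[col]]
    if (col == "age_onset") {
      data.frame(covariate = col, statistic = "mean (sd)",
                 value = sprintf("%.2f (%.2f)", mean(v), stats::sd(v)))
    } else {
      data.frame(covariate = col, statistic = "proportion of 1s",
                 value = sprintf("%.4f", mean(v)))
    }
  })
  covariates <- do.call(rbind, cov_rows)
  tab <- relapse_frequency_table(ds, c("family_history", "gender"))
  utils::write.csv(covariates, file.path(out_dir, "covariates.csv"),
                   row.names = FALSE)
  utils::write.csv(tab, file.path(out_dir, "relapse_table.csv"),
                   row.names = FALSE)
  invisible(list(covariates = covariates, relapse_table = tab))
}
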