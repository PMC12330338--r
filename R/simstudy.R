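#' Enumerate the factorial simulation scenarios
#'
#' The full grid: two sample sizes (750, 3500) x nine missing-data patterns
#' (A-I) x three imputation strategies — 54 bootstrap-imputation (BI)
#' scenarios — plus the 18 complete-case (CC) reference arms.
#'
#' @param n_sim Simulation replicates per scenario (study scale: 1000).
#' @param B Bootstrap resamples per replicate (study scale: 500).
#' @param tau Horizon in years.
#' @return Data frame of scenario specifications with a logical
#'   `is_reference` column marking the CC arms.
#' @export
build_scenarios <- function(n_sim = 1000, B = 500, tau = 5) {
  grid <- expand.grid(
    n = c(750L, 3500L),
    pattern = LETTERS[1:9],
    approach = c("impute_all", "impute_gt10", "impute_le2", "complete_case"),
    stringsAsFactors = FALSE
  )
  grid$is_reference <- grid$approach == "complete_case"
  grid$n_sim <- n_sim
  grid$B <- B
  grid$tau <- tau
  grid[order(grid$pattern, grid$n, grid$is_reference, grid$approach), ,
       drop = FALSE] -> grid
  rownames(grid) <- NULL
  grid
}

#' Bias of averaged individual predicted survival probabilities
#'
#' Averages predicted 5-year survival probabilities on the complementary
#' log-log scale — \eqn{\mathrm{cloglog}(p) = \log(-\log p)}, back-transform
#' \eqn{\exp(-e^{x})} — within each dataset, then takes the difference:
#' full-data average minus approach average. Probabilities are clipped to
#' machine-safe bounds before the transform.
#'
#' @param full_surv Predicted survival probabilities from the full-data model.
#' @param approach_surv Predicted survival probabilities from the
#'   missing-data approach (possibly fewer subjects, e.g. complete cases
#'   only).
#' @return A single bias value.
#' @export
individual_prediction_bias <- function(full_surv, approach_surv) {
  if (!length(full_surv) || !length(approach_surv))
    stop("empty prediction vector", call. = FALSE)
  avg <- function(p) {
    p <- pmin(pmax(p, 1e-12), 1 - 1e-12)
    exp(-exp(mean(log(-log(p)))))
  }
  avg(full_surv) - avg(approach_surv)
}

#' Run one simulation replicate
#'
#' Generates a complete cohort, computes the full-data reference performance
#' (all four estimators, via the same bootstrap machinery), imposes the
#' missing-data pattern, and runs each requested approach arm on the same
#' masked cohort (paired design, so bias isolates the missing-data handling).
#' Bias is full-data value minus approach value, estimator against matching
#' estimator.
#'
#' @param n Cohort size.
#' @param pattern Pattern letter ("A"-"I") or a named marginal-target vector.
#' @param approaches Character vector of strategies to run (see
#'   [apply_strategy()]).
#' @param B Bootstrap resamples per validation.
#' @param tau Horizon in years.
#' @param seed Optional integer seed.
#' @param config Generation configuration (defaults to the study parameters
#'   at size `n`).
#' @param joint_overrides Passed to [build_missingness_spec()].
#' @return A list: `bias` (data frame approach x metric x estimator),
#'   `pred_bias` (per-approach individual prediction bias), `failures`
#'   (per-approach logical with the failure message), `full` (the reference
#'   `validation_report`).
#' @export
run_single_sim <- function(n, pattern,
                           approaches = c("impute_all", "impute_gt10",
                                          "impute_le2", "complete_case"),
                           B = 100, tau = 5, seed = NULL,
                           config = default_generation_config(n),
                           joint_overrides = NULL) {
  if (!is.null(seed)) set.seed(seed)
  if (is.character(pattern) && length(pattern) == 1L)
    pattern <- missingness_pattern(pattern)
  cohort <- simulate_cohort(config)
  full <- boot_validate(cohort, "complete_case", B = B, tau = tau)
  surv_full <- 1 - predict_risk(full$apparent_fit, cohort, tau)
  spec <- build_missingness_spec(pattern, cohort,
                                 joint_overrides = joint_overrides)
  masked <- impose_missingness(cohort, spec)

  estimators <- c("apparent", "harrell", "e632", "e632plus")
  bias <- list(); pred <- list(); fails <- list()
  for (ap in approaches) {
    rep_ap <- tryCatch(boot_validate(masked, ap, B = B, tau = tau),
                       bivalid_fit_failure = function(e) e,
                       bivalid_undefined_metric = function(e) e)
    if (inherits(rep_ap, "condition")) {
      fails[[ap]] <- data.frame(approach = ap, failed = TRUE,
                                message = conditionMessage(rep_ap))
      next
    }
    fails[[ap]] <- data.frame(approach = ap, failed = FALSE, message = "")
    rows <- lapply(c("auc", "brier"), function(m) {
      fv <- unlist(full$estimates[full$estimates$metric == m, estimators])
      av <- unlist(rep_ap$estimates[rep_ap$estimates$metric == m, estimators])
      data.frame(approach = ap, metric = m, estimator = estimators,
                 full = unname(fv), value = unname(av),
                 bias = unname(fv - av))
    })
    bias[[ap]] <- do.call(rbind, rows)
    surv_ap <- 1 - predict_risk(rep_ap$apparent_fit, rep_ap$original$cohort, tau)
    pred[[ap]] <- data.frame(
      approach = ap,
      pred_bias = individual_prediction_bias(surv_full, surv_ap))
  }
  rbind_all <- function(x) {
    if (!length(x)) return(NULL)
    out <- do.call(rbind, x)
    rownames(out) <- NULL
    out
  }
  list(bias = rbind_all(bias), pred_bias = rbind_all(pred),
       failures = rbind_all(fails), full = full)
}

#' Run a full scenario
#'
#' `n_sim` independent replicates of [run_single_sim()] under a per-replicate
#' seed stream spawned from `seed`, aggregated into bias summaries and
#' failure rates.
#'
#' @param pattern Pattern letter or named marginal-target vector.
#' @param n Cohort size.
#' @param approaches Strategies to run in each replicate.
#' @param n_sim Number of replicates.
#' @param B Bootstrap resamples per validation.
#' @param tau Horizon in years.
#' @param seed Master seed; spawns one sub-seed per replicate so arms stay
#'   paired.
#' @param joint_overrides Passed to [build_missingness_spec()].
#' @param verbose Print per-replicate progress.
#' @return A `scenario_result`: list with `bias_summary` (mean, SD and mean
#'   absolute bias per approach/metric/estimator with effective counts),
#'   `pred_summary`, `failure_rates`, `records` (per-replicate bias rows) and
#'   the scenario parameters.
#' @export
run_scenario <- function(pattern, n,
                         approaches = c("impute_all", "impute_gt10",
                                        "impute_le2", "complete_case"),
                         n_sim = 200, B = 100, tau = 5, seed = NULL,
                         joint_overrides = NULL, verbose = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  sim_seeds <- sample.int(.Machine$integer.max - 1L, n_sim)
  pat_label <- if (is.character(pattern)) pattern else "custom"
  recs <- vector("list", n_sim)
  preds <- vector("list", n_sim)
  fails <- vector("list", n_sim)
  for (s in seq_len(n_sim)) {
    one <- run_single_sim(n, pattern, approaches, B = B, tau = tau,
                          seed = sim_seeds[s],
                          joint_overrides = joint_overrides)
    if (!is.null(one$bias)) one$bias$sim <- s
    if (!is.null(one$pred_bias)) one$pred_bias$sim <- s
    one$failures$sim <- s
    recs[[s]] <- one$bias
    preds[[s]] <- one$pred_bias
    fails[[s]] <- one$failures
    if (verbose && s %% 10 == 0)
      message(sprintf("pattern %s, n = %d: %d/%d replicates", pat_label, n,
                      s, n_sim))
  }
  records <- do.call(rbind, recs)
  pred_records <- do.call(rbind, preds)
  failures <- do.call(rbind, fails)

  bias_summary <- do.call(rbind, lapply(
    split(records, records[c("approach", "metric", "estimator")], drop = TRUE),
    function(d) data.frame(
      approach = d$approach[1], metric = d$metric[1],
      estimator = d$estimator[1],
      mean_bias = mean(d$bias), sd_bias = stats::sd(d$bias),
      mean_abs_bias = mean(abs(d$bias)), n_eff = nrow(d))
  ))
  rownames(bias_summary) <- NULL
  pred_summary <- do.call(rbind, lapply(
    split(pred_records, pred_records$approach),
    function(d) data.frame(approach = d$approach[1],
                           mean_pred_bias = mean(d$pred_bias),
                           sd_pred_bias = stats::sd(d$pred_bias),
                           n_eff = nrow(d))
  ))
  rownames(pred_summary) <- NULL
  failure_rates <- do.call(rbind, lapply(
    split(failures, failures$approach),
    function(d) data.frame(approach = d$approach[1],
                           n_failed = sum(d$failed),
                           failure_rate = mean(d$failed))
  ))
  rownames(failure_rates) <- NULL
  structure(
    list(pattern = pat_label, n = n, n_sim = n_sim, B = B, tau = tau,
         bias_summary = bias_summary, pred_summary = pred_summary,
         failure_rates = failure_rates, records = records,
         pred_records = pred_records),
    class = "scenario_result"
  )
}

#' @export
print.scenario_result <- function(x, ...) {
  cat(sprintf("Scenario: pattern %s, n = %d (%d replicates, B = %d)\n",
              x$pattern, x$n, x$n_sim, x$B))
  df <- x$bias_summary
  df[c("mean_bias", "sd_bias", "mean_abs_bias")] <-
    lapply(df[c("mean_bias", "sd_bias", "mean_abs_bias")], round, 4)
  print(df, row.names = FALSE)
  if (any(x$failure_rates$n_failed > 0)) {
    cat("Fit failures:\n")
    print(x$failure_rates, row.names = FALSE)
  }
  invisible(x)
}

#' Write scenario results to a tidy CSV
#'
#' One row per scenario x approach x metric x estimator with bias statistics
#' and the approach's failure rate.
#'
#' @param results A `scenario_result` or list of them.
#' @param path Output CSV path.
#' @return The tidy data frame, invisibly.
#' @export
write_results <- function(results, path) {
  if (inherits(results, "scenario_result")) results <- list(results)
  tidy <- do.call(rbind, lapply(results, function(r) {
    d <- r$bias_summary
    d$pattern <- r$pattern
    d$n <- r$n
    d$n_sim <- r$n_sim
    d$failure_rate <- r$failure_rates$failure_rate[
      match(d$approach, r$failure_rates$approach)]
    d[c("pattern", "n", "n_sim", "approach", "metric", "estimator",
        "mean_bias", "sd_bias", "mean_abs_bias", "n_eff", "failure_rate")]
  }))
  utils::write.csv(tidy, path, row.names = FALSE)
  invisible(tidy)
}
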