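#' Draw bootstrap resamples and their out-of-bag sets
#'
#' Each resample is `n` row indices drawn uniformly with replacement; its
#' out-of-bag set is the rows absent from the resample (about 36.8% of rows
#' at large `n`).
#'
#' @param n Number of rows in the original data.
#' @param B Number of resamples.
#' @param seed Optional integer seed.
#' @return A list with elements `index` (list of length-`n` integer vectors)
#'   and `oob` (list of integer vectors).
#' @export
draw_bootstrap <- function(n, B, seed = NULL) {
  stopifnot(B >= 1, n >= 1)
  if (!is.null(seed)) set.seed(seed)
  index <- replicate(B, sample.int(n, n, replace = TRUE), simplify = FALSE)
  oob <- lapply(index, function(ix) setdiff(seq_len(n), ix))
  list(index = index, oob = oob)
}

#' Apparent performance of the strategy-processed original data
#'
#' Imputes/filters the original incomplete data per the strategy, fits the
#' Cox outcome model, and scores it on that same processed dataset —
#' the optimistically biased baseline the corrected estimators adjust.
#'
#' @param masked Incomplete cohort `data.frame`.
#' @param strategy An imputation-scope strategy (see [apply_strategy()]).
#' @param tau Horizon in years.
#' @return Named vector `c(auc = , brier = )`.
#' @export
apparent_performance <- function(masked, strategy = "impute_all", tau = 5) {
  proc <- apply_strategy(masked, strategy)
  fit <- fit_cox(proc$cohort)
  performance_pair(fit, proc$cohort, tau)
}

#' Harrell's bootstrap-corrected performance
#'
#' Apparent performance minus the average optimism, where optimism is the
#' mean over resamples of (in-resample performance minus performance of the
#' resample's model on the original imputed data).
#'
#' @param apparent Apparent performance value.
#' @param in_sample Per-resample in-sample performance values.
#' @param on_original Per-resample performance of each resample's model on
#'   the original imputed dataset.
#' @return The corrected estimate.
#' @export
harrell_corrected <- function(apparent, in_sample, on_original) {
  if (length(in_sample) != length(on_original) || !length(in_sample))
    stop("`in_sample` and `on_original` must be equal-length, non-empty",
         call. = FALSE)
  apparent - mean(in_sample - on_original)
}

#' The 0.632 estimator
#'
#' `0.368 * apparent + 0.632 * mean_test`, where `mean_test` is the average
#' out-of-bag (test-set) performance across resamples.
#'
#' @param apparent Apparent performance value.
#' @param mean_test Mean out-of-bag performance.
#' @return The 0.632 estimate.
#' @export
est_632 <- function(apparent, mean_test) {
  0.368 * apparent + 0.632 * mean_test
}

#' The 0.632+ estimator
#'
#' Adapts the 0.632 weight by the relative overfitting rate
#' \eqn{R = (\mathrm{mean\_test} - \mathrm{apparent}) /
#' (\mathrm{no\_info} - \mathrm{apparent})}, clamped to \[0, 1\]; the weight
#' is \eqn{w = 0.632 / (1 - 0.368 R)} and the estimate
#' \eqn{(1 - w)\,\mathrm{apparent} + w\,\mathrm{mean\_test}}. The
#' no-information benchmark is 0.5 for the AUC and 0.25 for the Brier score.
#'
#' @param apparent Apparent performance value.
#' @param mean_test Mean out-of-bag performance.
#' @param no_info No-information performance value.
#' @return The 0.632+ estimate.
#' @export
est_632_plus <- function(apparent, mean_test, no_info) {
  if (no_info == apparent)
    stop("degenerate relative overfitting rate: no_info equals apparent",
         call. = FALSE)
  R <- (mean_test - apparent) / (no_info - apparent)
  R <- min(max(R, 0), 1)
  w <- 0.632 / (1 - 0.368 * R)
  (1 - w) * apparent + w * mean_test
}

#' Bootstrap-then-impute internal validation
#'
#' The core procedure: (1) impute/filter the original incomplete data once
#' (the "original imputed dataset") and measure apparent performance;
#' (2) draw `B` bootstrap resamples of the *incomplete* data, impute/filter
#' each resample independently (imputation models refit from scratch inside
#' every resample), fit the Cox model per resample, and score it on the
#' resample itself, on the original imputed dataset, and on the out-of-bag
#' rows of the original imputed dataset; (3) assemble apparent, Harrell
#' bootstrap-corrected, 0.632 and 0.632+ estimates of the time-dependent AUC
#' and Brier score at `tau`, with no-information values 0.5 and 0.25.
#' Resamples whose fit fails are counted and excluded from the averages.
#'
#' @param masked Incomplete cohort `data.frame` (may also be complete, in
#'   which case the strategy is a no-op).
#' @param strategy Imputation-scope strategy (see [apply_strategy()]).
#' @param B Number of bootstrap resamples (default 500).
#' @param tau Horizon in years (default 5).
#' @param seed Optional integer seed making the whole report reproducible.
#' @return A `validation_report`: list with `estimates` (data frame, one row
#'   per metric with the four estimators, optimism, mean test performance,
#'   overfitting rate `R` and weight `w`), `boot` (per-resample diagnostics),
#'   `n_failed`, `B`, `strategy`, `tau`, `apparent_fit` (the original-data
#'   `cox_fit`) and `original` (the processed original dataset and row map).
#' @examples
#' cfg <- default_generation_config(n = 400)
#' dat <- simulate_cohort(cfg, seed = 7)
#' masked <- impose_missingness(dat, guided_example_spec(dat), seed = 8)
#' rep <- boot_validate(masked, "impute_all", B = 20, tau = 5, seed = 9)
#' rep$estimates
#' @export
boot_validate <- function(masked, strategy = "impute_all", B = 500, tau = 5,
                          seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  proc0 <- apply_strategy(masked, strategy)
  fit0 <- fit_cox(proc0$cohort)
  app <- performance_pair(fit0, proc0$cohort, tau)
  n <- nrow(masked)
  bs <- draw_bootstrap(n, B)
  # map original row index -> row of the processed original dataset
  row_of <- match(seq_len(n), proc0$rows_kept)

  boot <- data.frame(b = seq_len(B), failed = FALSE,
                     in_auc = NA_real_, in_brier = NA_real_,
                     orig_auc = NA_real_, orig_brier = NA_real_,
                     oob_auc = NA_real_, oob_brier = NA_real_,
                     oob_size = NA_integer_)
  for (b in seq_len(B)) {
    res <- tryCatch({
      resample <- masked[bs$index[[b]], , drop = FALSE]
      procb <- apply_strategy(resample, strategy)
      fitb <- fit_cox(procb$cohort)
      ins <- performance_pair(fitb, procb$cohort, tau)
      org <- performance_pair(fitb, proc0$cohort, tau)
      oob_rows <- row_of[bs$oob[[b]]]
      oob_rows <- oob_rows[!is.na(oob_rows)]
      oob_dat <- proc0$cohort[oob_rows, , drop = FALSE]
      oob <- performance_pair(fitb, oob_dat, tau)
      list(ins = ins, org = org, oob = oob, oob_size = nrow(oob_dat))
    }, bivalid_fit_failure = function(e) NULL,
       bivalid_undefined_metric = function(e) NULL)
    if (is.null(res)) {
      boot$failed[b] <- TRUE
    } else {
      boot[b, c("in_auc", "in_brier")] <- res$ins
      boot[b, c("orig_auc", "orig_brier")] <- res$org
      boot[b, c("oob_auc", "oob_brier")] <- res$oob
      boot$oob_size[b] <- res$oob_size
    }
  }
  ok <- !boot$failed
  if (!any(ok))
    stop(cox_fit_failure("all bootstrap resample fits failed"))

  est_one <- function(metric, no_info) {
    apparent <- unname(app[metric])
    ins <- boot[[paste0("in_", metric)]][ok]
    org <- boot[[paste0("orig_", metric)]][ok]
    mt <- mean(boot[[paste0("oob_", metric)]][ok])
    R <- (mt - apparent) / (no_info - apparent)
    Rc <- min(max(R, 0), 1)
    data.frame(metric = metric,
               apparent = apparent,
               harrell = harrell_corrected(apparent, ins, org),
               e632 = est_632(apparent, mt),
               e632plus = est_632_plus(apparent, mt, no_info),
               optimism = mean(ins - org),
               mean_test = mt,
               R = Rc,
               w = 0.632 / (1 - 0.368 * Rc))
  }
  estimates <- rbind(est_one("auc", 0.5), est_one("brier", 0.25))
  structure(
    list(estimates = estimates, boot = boot, n_failed = sum(!ok),
         B = B, strategy = strategy, tau = tau,
         apparent_fit = fit0,
         original = list(cohort = proc0$cohort,
                         rows_kept = proc0$rows_kept,
                         n_dropped = proc0$n_dropped)),
    class = "validation_report"
  )
}

#' @export
print.validation_report <- function(x, ...) {
  cat(sprintf(
    "Bootstrap-then-impute internal validation (strategy = %s, B = %d, tau = %g y)\n",
    x$strategy, x$B, x$tau))
  if (x$n_failed > 0)
    cat(sprintf("  %d of %d resample fits failed and were excluded\n",
                x$n_failed, x$B))
  if (x$original$n_dropped > 0)
    cat(sprintf("  %d incomplete rows dropped from the original data\n",
                x$original$n_dropped))
  df <- x$estimates
  df[-1] <- lapply(df[-1], round, 4)
  print(df, row.names = FALSE)
  invisible(x)
}
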