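#' Fit the multivariable Cox proportional-hazards outcome model
#'
#' Partial-likelihood fit (Breslow tie handling, so the Breslow baseline
#' cumulative hazard is its exact companion; simulated times are continuous,
#' making this identical to Efron) with explicit failure detection: too few
#' complete rows, zero events, singular designs (`NA` coefficients),
#' non-convergence or monotone-likelihood warnings all raise a condition of
#' class `bivalid_fit_failure` instead of returning a silently unusable fit.
#'
#' @param cohort Complete cohort `data.frame` (covariate columns plus `time`
#'   and `event`).
#' @return A `cox_fit`: list with `coefficients`, `means` (covariate means of
#'   the fitting data), `basehaz` (Breslow baseline cumulative hazard step
#'   function data, centered at `means`), `n`, `n_events`, and the underlying
#'   `coxph` object as `model`.
#' @export
fit_cox <- function(cohort) {
  covs <- covariate_columns(cohort)
  p <- length(covs)
  if (anyNA(cohort[covs])) stop("cohort must be complete", call. = FALSE)
  if (nrow(cohort) < p + 2L)
    stop(cox_fit_failure(sprintf("only %d complete rows for %d covariates",
                                 nrow(cohort), p)))
  if (sum(cohort$event) < 1L)
    stop(cox_fit_failure("no events"))
  f <- stats::as.formula(paste("survival::Surv(time, event) ~",
                               paste(covs, collapse = " + ")))
  bad <- NULL
  fit <- withCallingHandlers(
    tryCatch(
      survival::coxph(f, data = cohort, ties = "breslow",
                      model = FALSE, x = FALSE, y = TRUE),
      error = function(e) stop(cox_fit_failure(conditionMessage(e)))
    ),
    warning = function(w) {
      msg <- conditionMessage(w)
      if (grepl("converge|infinite|singular|beta may be|out of iterations",
                msg, ignore.case = TRUE))
        bad <<- msg
      invokeRestart("muffleWarning")
    }
  )
  if (!is.null(bad)) stop(cox_fit_failure(bad))
  if (anyNA(fit$coefficients))
    stop(cox_fit_failure("singular design: NA coefficients"))
  bh <- survival::basehaz(fit, centered = TRUE)
  structure(
    list(coefficients = fit$coefficients,
         means = fit$means,
         basehaz = bh,
         n = nrow(cohort),
         n_events = sum(cohort$event),
         model = fit),
    class = "cox_fit"
  )
}

cox_fit_failure <- function(msg) {
  structure(
    class = c("bivalid_fit_failure", "error", "condition"),
    list(message = paste("Cox model fit failed:", msg), call = NULL)
  )
}

#' @export
print.cox_fit <- function(x, ...) {
  cat(sprintf("Cox proportional-hazards fit: n = %d, events = %d\n",
              x$n, x$n_events))
  print(round(exp(x$coefficients), 4))
  invisible(x)
}

#' Predict absolute event risk at a horizon
#'
#' \eqn{\mathrm{risk}_i = 1 - S_0(\tau)^{\exp(lp_i)}} with
#' \eqn{S_0(\tau) = \exp(-H_0(\tau))} the Breslow baseline survival (centered
#' at the fitting-data covariate means) and \eqn{lp_i} the mean-centered
#' linear predictor.
#'
#' @param fit A [fit_cox()] result.
#' @param newdata Cohort `data.frame` (or covariate matrix) to predict for.
#' @param tau Horizon in years; if beyond the last observed time, the last
#'   baseline-hazard step is used with a warning.
#' @return Vector of event probabilities in \[0, 1\].
#' @export
predict_risk <- function(fit, newdata, tau) {
  stopifnot(inherits(fit, "cox_fit"), tau > 0)
  X <- as.matrix(as.data.frame(newdata)[names(fit$coefficients)])
  lp <- drop(sweep(X, 2, fit$means) %*% fit$coefficients)
  bh <- fit$basehaz
  if (tau > max(bh$time))
    warning("horizon beyond last observed time; using last baseline-hazard step")
  idx <- findInterval(tau, bh$time)
  H0 <- if (idx == 0L) 0 else bh$hazard[idx]
  1 - exp(-H0 * exp(lp))
}

#' Inverse-probability-of-censoring weights at a horizon
#'
#' Reverse Kaplan-Meier estimate \eqn{G(t)} of the censoring survival
#' function. Subjects with an event at or before `tau` get weight
#' \eqn{1/G(s_i^-)}; subjects still at risk past `tau` get \eqn{1/G(\tau)};
#' subjects censored at or before `tau` get weight 0.
#'
#' @param time Observed follow-up times.
#' @param event Event indicators (1 = event, 0 = censored).
#' @param tau Horizon in years.
#' @return Vector of nonnegative weights, one per subject.
#' @export
censoring_weights <- function(time, event, tau) {
  stopifnot(tau > 0, length(time) == length(event))
  sf <- survival::survfit(survival::Surv(time, 1 - event) ~ 1)
  G <- stats::stepfun(sf$time, c(1, sf$surv))               # G(t), right-continuous
  Gminus <- stats::stepfun(sf$time, c(1, sf$surv), right = TRUE)  # G(t-)
  w <- numeric(length(time))
  case <- time <= tau & event == 1
  ctrl <- time > tau
  if (any(case)) {
    g <- Gminus(time[case])
    if (any(g <= 0)) stop("degenerate censoring weights: G(t-) = 0",
                          call. = FALSE)
    w[case] <- 1 / g
  }
  if (any(ctrl)) {
    gt <- G(tau)
    if (gt <= 0) stop("degenerate censoring weights: G(tau) = 0", call. = FALSE)
    w[ctrl] <- 1 / gt
  }
  w
}

#' Time-dependent AUC at a horizon (IPCW)
#'
#' Cumulative-case / dynamic-control AUC at `tau`: the weighted proportion of
#' (case, control) pairs in which the case's predicted risk exceeds the
#' control's, with half credit for ties. Cases (event by `tau`) carry their
#' IPCW weights; controls are subjects at risk past `tau`.
#'
#' @param risk Predicted event risks (any monotone risk score works: the
#'   estimator depends only on the ordering).
#' @param time,event Observed follow-up and event indicator.
#' @param tau Horizon in years.
#' @return AUC in \[0, 1\].
#' @export
td_auc <- function(risk, time, event, tau) {
  w <- censoring_weights(time, event, tau)
  case <- time <= tau & event == 1
  ctrl <- time > tau
  if (!any(case) || !any(ctrl))
    stop(structure(class = c("bivalid_undefined_metric", "error", "condition"),
                   list(message = "AUC undefined: no cases or no controls",
                        call = NULL)))
  rc <- risk[case]; wc <- w[case]
  rv <- risk[ctrl]; wv <- w[ctrl]
  o <- order(rv)
  rv <- rv[o]; cumw <- cumsum(wv[o])
  n_le <- findInterval(rc, rv)
  n_lt <- findInterval(rc, rv, left.open = TRUE)
  s_le <- ifelse(n_le > 0L, cumw[pmax(n_le, 1L)], 0)
  s_lt <- ifelse(n_lt > 0L, cumw[pmax(n_lt, 1L)], 0)
  num <- sum(wc * (s_lt + 0.5 * (s_le - s_lt)))
  num / (sum(wc) * sum(wv))
}

#' Time-dependent Brier score at a horizon (IPCW)
#'
#' Graf-style estimator
#' \eqn{\frac{1}{n}\sum_i w_i \left(1\{s_i > \tau\} - \hat S_i(\tau)\right)^2}
#' with reverse-Kaplan-Meier censoring weights: event-by-`tau` subjects
#' contribute \eqn{(0 - \hat S_i)^2 / G(s_i^-)}, at-risk subjects
#' \eqn{(1 - \hat S_i)^2 / G(\tau)}, censored-by-`tau` subjects nothing.
#'
#' @param surv_pred Predicted survival probabilities at `tau`, in \[0, 1\].
#' @param time,event Observed follow-up and event indicator.
#' @param tau Horizon in years.
#' @return The Brier score (0 is perfect; 0.25 is the uninformative constant
#'   50% prediction on uncensored data).
#' @export
td_brier <- function(surv_pred, time, event, tau) {
  if (any(surv_pred < 0 | surv_pred > 1))
    stop("predicted survival probabilities must lie in [0, 1]", call. = FALSE)
  w <- censoring_weights(time, event, tau)
  mean(w * (as.numeric(time > tau) - surv_pred)^2)
}

# score a fitted model on a cohort: AUC and Brier at tau
performance_pair <- function(fit, cohort, tau) {
  risk <- predict_risk(fit, cohort, tau)
  c(auc = td_auc(risk, cohort$time, cohort$event, tau),
    brier = td_brier(1 - risk, cohort$time, cohort$event, tau))
}
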