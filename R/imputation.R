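#' Fit deterministic regression imputation models
#'
#' For every covariate with at least one missing value, fits an independent
#' generalized linear model on the rows where that covariate is observed,
#' using as predictors all covariates that are fully observed in this dataset.
#' The link is logit for binary targets (observed values all in \{0, 1\}) and
#' identity for continuous targets. The survival outcome (`time`, `event`) is
#' never used: deterministic imputation requires the outcome to be excluded
#' from the imputation models.
#'
#' @param masked A cohort `data.frame` with `NA` holes in covariate columns.
#' @return An `imputation_models` object: a named list (one element per
#'   imputed covariate) of records with `link`, `coef` (intercept first),
#'   `predictors` and `n_fit`.
#' @export
fit_imputation_models <- function(masked) {
  covs <- covariate_columns(masked)
  n_miss <- vapply(masked[covs], function(v) sum(is.na(v)), integer(1))
  targets <- covs[n_miss > 0L]
  predictors <- covs[n_miss == 0L]
  if (length(targets) && !length(predictors))
    stop("no fully observed covariate available as an imputation predictor",
         call. = FALSE)
  models <- lapply(targets, function(tg) {
    obs <- !is.na(masked[[tg]])
    n_fit <- sum(obs)
    if (n_fit <= length(predictors) + 1L)
      stop(imputation_fit_error(tg, "too few observed rows to fit"))
    y <- masked[[tg]][obs]
    Xp <- as.matrix(masked[obs, predictors, drop = FALSE])
    binary <- all(y %in% c(0, 1))
    fit <- if (binary) {
      stats::glm.fit(cbind(1, Xp), y, family = stats::binomial())
    } else {
      stats::lm.fit(cbind(1, Xp), y)
    }
    cf <- fit$coefficients
    if (anyNA(cf))
      stop(imputation_fit_error(tg, "singular imputation design"))
    list(link = if (binary) "logit" else "identity",
         coef = unname(cf), predictors = predictors, n_fit = n_fit)
  })
  names(models) <- targets
  structure(models, class = "imputation_models")
}

imputation_fit_error <- function(covariate, msg) {
  structure(
    class = c("bivalid_fit_failure", "error", "condition"),
    list(message = sprintf("imputation model for %s failed: %s", covariate, msg),
         call = NULL, covariate = covariate)
  )
}

#' @export
print.imputation_models <- function(x, ...) {
  cat("Deterministic imputation models for:",
      paste(names(x), collapse = ", "), "\n")
  for (nm in names(x))
    cat(sprintf("  %s: %s link, %d predictors, n_fit = %d\n",
                nm, x[[nm]]$link, length(x[[nm]]$predictors), x[[nm]]$n_fit))
  invisible(x)
}

#' Apply deterministic imputation
#'
#' Replaces each missing entry by its model-predicted response: the linear
#' predictor for identity-link targets, the logistic-transformed linear
#' predictor (a probability, not thresholded) for logit-link targets.
#' Observed entries pass through bit-identically.
#'
#' @param masked Masked cohort `data.frame`.
#' @param models An [fit_imputation_models()] result covering every covariate
#'   to be imputed.
#' @param targets Covariate names to impute (default: all modeled ones).
#' @param rows Optional integer row subset to impute into (other rows keep
#'   their `NA`s); default all rows.
#' @param threshold_binary Dichotomize logit-link predictions at 0.5 instead
#'   of keeping the conditional-mean probability (sensitivity switch;
#'   default `FALSE`).
#' @return The cohort with imputed values filled in.
#' @export
apply_imputation <- function(masked, models, targets = names(models),
                             rows = NULL, threshold_binary = FALSE) {
  stopifnot(inherits(models, "imputation_models"))
  out <- masked
  if (is.null(rows)) rows <- seq_len(nrow(masked))
  for (tg in targets) {
    mod <- models[[tg]]
    if (is.null(mod))
      stop("no imputation model for covariate ", tg, call. = FALSE)
    fill <- intersect(which(is.na(masked[[tg]])), rows)
    if (!length(fill)) next
    Xp <- as.matrix(masked[fill, mod$predictors, drop = FALSE])
    lp <- drop(cbind(1, Xp) %*% mod$coef)
    val <- if (mod$link == "logit") stats::plogis(lp) else lp
    if (mod$link == "logit" && threshold_binary) val <- as.numeric(val > 0.5)
    out[[tg]][fill] <- val
  }
  out
}

#' Apply an imputation-scope strategy
#'
#' The three imputation strategies of the study, plus complete-case analysis:
#' \describe{
#'   \item{`impute_all`}{impute every missing value; no rows dropped.}
#'   \item{`impute_gt10`}{impute only covariates missing in more than 10% of
#'     rows of this dataset; rows still incomplete afterwards are dropped.}
#'   \item{`impute_le2`}{impute only rows missing two or fewer covariates;
#'     rows missing three or more are dropped first.}
#'   \item{`complete_case`}{drop every incomplete row; impute nothing.}
#' }
#' Thresholds are evaluated on the dataset at hand (original or bootstrap
#' resample), never on population targets.
#'
#' @param masked Masked cohort `data.frame`.
#' @param strategy One of `"impute_all"`, `"impute_gt10"`, `"impute_le2"`,
#'   `"complete_case"`.
#' @return A list: `cohort` (complete data ready for model fitting),
#'   `n_dropped`, `rows_kept` (row indices into `masked`), `models` (the
#'   fitted imputation models, or `NULL`), `strategy`.
#' @export
apply_strategy <- function(masked,
                           strategy = c("impute_all", "impute_gt10",
                                        "impute_le2", "complete_case")) {
  strategy <- match.arg(strategy)
  covs <- covariate_columns(masked)
  miss <- is.na(as.matrix(masked[covs]))
  n <- nrow(masked)
  models <- NULL
  if (strategy == "complete_case" || !any(miss)) {
    keep <- which(rowSums(miss) == 0L)
    dat <- masked[keep, , drop = FALSE]
    if (strategy != "complete_case" && any(miss)) stop("unreachable")
  } else if (strategy == "impute_all") {
    models <- fit_imputation_models(masked)
    dat <- apply_imputation(masked, models)
    keep <- seq_len(n)
  } else if (strategy == "impute_gt10") {
    frac <- colMeans(miss)
    targets <- covs[frac > 0.10]
    models <- fit_imputation_models(masked)
    models <- structure(models[intersect(names(models), targets)],
                        class = "imputation_models")
    dat <- apply_imputation(masked, models)
    keep <- which(stats::complete.cases(dat[covs]))
    dat <- dat[keep, , drop = FALSE]
  } else { # impute_le2
    keep <- which(rowSums(miss) <= 2L)
    sub <- masked[keep, , drop = FALSE]
    if (anyNA(sub[covs])) {
      models <- fit_imputation_models(sub)
      sub <- apply_imputation(sub, models)
    }
    dat <- sub
  }
  rownames(dat) <- NULL
  list(cohort = dat, n_dropped = n - length(keep), rows_kept = keep,
       models = models, strategy = strategy)
}

#' Complete-case filter
#'
#' Convenience alias for [apply_strategy()] with `"complete_case"`.
#'
#' @param masked Masked cohort `data.frame`.
#' @return The complete-case cohort `data.frame` (rows with any missing
#'   covariate removed).
#' @export
complete_cases <- function(masked) {
  apply_strategy(masked, "complete_case")$cohort
}
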