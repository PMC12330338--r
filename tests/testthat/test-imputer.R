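test_that("imputation models match an independent least-squares oracle", {
  set.seed(301)
  n <- 2000
  x2 <- rnorm(n); x3 <- rnorm(n)
  x1 <- 1.5 + 2 * x2 - 0.5 * x3 + rnorm(n, sd = 0.3)
  dat <- data.frame(x1 = x1, x2 = x2, x3 = x3,
                    time = rexp(n), event = rbinom(n, 1, 0.5))
  dat$x1[sample.int(n, 400)] <- NA  # MCAR holes
  models <- fit_imputation_models(dat)
  expect_named(models, "x1")
  expect_equal(models$x1$link, "identity")
  expect_equal(models$x1$n_fit, 1600L)
  # oracle: normal equations solved directly on the observed subset
  obs <- !is.na(dat$x1)
  Xo <- cbind(1, dat$x2[obs], dat$x3[obs])
  beta_oracle <- solve(crossprod(Xo), crossprod(Xo, dat$x1[obs]))
  expect_equal(models$x1$coef, drop(beta_oracle), tolerance = 1e-8)
  # survival outcome is never a predictor (structural assertion)
  expect_false(any(c("time", "event") %in% models$x1$predictors))
})

test_that("binary targets get a logit link with probability-valued imputations", {
  set.seed(302)
  n <- 1500
  x2 <- rnorm(n)
  x1 <- rbinom(n, 1, plogis(0.3 + 1.2 * x2))
  dat <- data.frame(x1 = x1, x2 = x2, time = rexp(n), event = 1L)
  dat$x1[sample.int(n, 300)] <- NA
  models <- fit_imputation_models(dat)
  expect_equal(models$x1$link, "logit")
  imp <- apply_imputation(dat, models)
  filled <- imp$x1[is.na(dat$x1)]
  expect_true(all(filled > 0 & filled < 1))
  # sensitivity switch: thresholding dichotomizes at 0.5
  thr <- apply_imputation(dat, models, threshold_binary = TRUE)
  expect_true(all(thr$x1[is.na(dat$x1)] %in% c(0, 1)))
})

test_that("imputed values are the model-predicted response; observed pass through", {
  dat <- data.frame(x1 = c(NA, 2, 4), x2 = c(3, 1, 0),
                    time = c(1, 2, 3), event = c(1L, 0L, 1L))
  models <- structure(
    list(x1 = list(link = "identity", coef = c(1, 2), predictors = "x2",
                   n_fit = 2L)),
    class = "imputation_models")
  imp <- apply_imputation(dat, models)
  expect_equal(imp$x1, c(7, 2, 4))  # 1 + 2 * 3 for the missing entry
  expect_identical(imp[2:3, ], dat[2:3, ])
  # fully observed input is returned unchanged
  full <- data.frame(x1 = 1:3 / 2, x2 = 3:1, time = 1:3, event = c(1L, 1L, 0L))
  expect_identical(apply_imputation(full, models), full)
  # a missing covariate without a model violates the contract
  expect_error(apply_imputation(dat, structure(list(), class = "imputation_models"),
                                targets = "x1"),
               "no imputation model")
})

test_that("strategies impute and drop rows per their scope rules", {
  masked <- guided_masked(n = 1200, seed = 303)
  covs <- grep("^x", names(masked), value = TRUE)
  frac <- colMeans(is.na(masked[covs]))
  expect_lt(frac["x1"], 0.10)  # pattern E: 5% target
  expect_gt(frac["x3"], 0.10)

  all_in <- apply_strategy(masked, "impute_all")
  expect_equal(all_in$n_dropped, 0L)
  expect_false(anyNA(all_in$cohort[covs]))
  expect_equal(nrow(all_in$cohort), nrow(masked))

  gt10 <- apply_strategy(masked, "impute_gt10")
  # x1 (under 10%) is not imputed: rows missing x1 are dropped
  expect_equal(sort(gt10$rows_kept), which(!is.na(masked$x1)))
  expect_false(anyNA(gt10$cohort[covs]))
  expect_false("x1" %in% names(gt10$models))

  le2 <- apply_strategy(masked, "impute_le2")
  n_miss_row <- rowSums(is.na(masked[covs]))
  expect_equal(sort(le2$rows_kept), which(n_miss_row <= 2))
  # pattern E has at most 3 missing per row, so only >=3-missing rows drop
  expect_equal(le2$n_dropped, sum(n_miss_row >= 3))

  cc <- apply_strategy(masked, "complete_case")
  expect_null(cc$models)
  expect_equal(nrow(cc$cohort), sum(n_miss_row == 0))
  # observed values pass through bit-exactly in every strategy
  for (proc in list(all_in, gt10, le2, cc)) {
    src <- masked[proc$rows_kept, covs]
    out <- proc$cohort[covs]
    expect_identical(out[!is.na(src)], src[!is.na(src)])
  }
})

test_that("when every incomplete row misses at most two covariates, le2 equals impute_all", {
  masked <- guided_masked(n = 500, seed = 304)
  covs <- grep("^x", names(masked), value = TRUE)
  n_miss_row <- rowSums(is.na(masked[covs]))
  drop3 <- which(n_miss_row >= 3)
  m2 <- if (length(drop3)) masked[-drop3, ] else masked
  rownames(m2) <- NULL
  a <- apply_strategy(m2, "impute_all")
  b <- apply_strategy(m2, "impute_le2")
  expect_equal(a$cohort, b$cohort)
  expect_equal(b$n_dropped, 0L)
})

test_that("complete-case filtering matches a brute-force row scan", {
  masked <- guided_masked(n = 800, seed = 305)
  covs <- grep("^x", names(masked), value = TRUE)
  cc <- complete_cases(masked)
  keep_oracle <- which(apply(!is.na(masked[covs]), 1, all))
  expect_equal(nrow(cc), length(keep_oracle))
  expect_equal(cc$time, masked$time[keep_oracle])
  # fully observed data is returned whole
  full <- simulate_cohort(default_generation_config(n = 50), seed = 306)
  expect_equal(complete_cases(full), full)
  one_hole <- full
  one_hole$x3[5] <- NA
  expect_equal(nrow(complete_cases(one_hole)), 49L)
})

test_that("insufficient observed rows raise a structured imputation failure", {
  dat <- data.frame(x1 = c(rnorm(3), rep(NA, 17)), x2 = rnorm(20),
                    x3 = rnorm(20), x4 = rnorm(20),
                    time = rexp(20), event = 1L)
  expect_error(fit_imputation_models(dat), class = "bivalid_fit_failure")
})
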