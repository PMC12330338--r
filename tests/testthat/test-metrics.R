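test_that("Cox fit recovers a known two-group exponential hazard ratio", {
  set.seed(501)
  n <- 20000
  x1 <- rbinom(n, 1, 0.5)
  dat <- data.frame(x1 = x1, time = rexp(n, rate = ifelse(x1 == 1, 2, 1)),
                    event = 1L)
  fit <- fit_cox(dat)
  expect_equal(unname(exp(fit$coefficients["x1"])), 2, tolerance = 0.05)
  expect_equal(fit$n_events, n)
})

test_that("under-determined and degenerate fits signal structured failures", {
  set.seed(502)
  small <- as.data.frame(matrix(rnorm(12 * 11), 12, 11,
                                dimnames = list(NULL, paste0("x", 1:11))))
  small$time <- rexp(12)
  small$event <- rep(c(1L, 0L, 0L, 0L), 3)
  expect_error(fit_cox(small), class = "bivalid_fit_failure")
  no_events <- data.frame(x1 = rnorm(30), time = rexp(30), event = 0L)
  expect_error(fit_cox(no_events), class = "bivalid_fit_failure")
  # perfectly collinear design
  coll <- data.frame(x1 = rnorm(100))
  coll$x2 <- 2 * coll$x1
  coll$time <- rexp(100); coll$event <- 1L
  expect_error(fit_cox(coll), class = "bivalid_fit_failure")
})

test_that("predicted risks follow the baseline-survival power formula", {
  set.seed(503)
  n <- 4000
  dat <- data.frame(x1 = rnorm(n))
  dat$time <- rexp(n, exp(0.8 * dat$x1))
  dat$event <- 1L
  fit <- fit_cox(dat)
  tau <- 0.5
  risk <- predict_risk(fit, dat, tau)
  expect_true(all(risk >= 0 & risk <= 1))
  # mean-covariate subject: risk equals baseline risk 1 - S0(tau)
  base <- predict_risk(fit, data.frame(x1 = unname(fit$means["x1"])), tau)
  H0 <- fit$basehaz$hazard[findInterval(tau, fit$basehaz$time)]
  expect_equal(base, 1 - exp(-H0))
  # ordering identical to linear-predictor ordering
  lp <- (dat$x1 - fit$means["x1"]) * fit$coefficients["x1"]
  expect_equal(cor(rank(risk), rank(lp)), 1)
  # saturating limit
  expect_equal(predict_risk(fit, data.frame(x1 = 50), tau), 1, tolerance = 1e-6)
  expect_warning(predict_risk(fit, dat[1:5, ], max(dat$time) + 1),
                 "beyond last observed time")
})

test_that("a null-covariate baseline matches the product-limit estimate", {
  set.seed(504)
  n <- 5000
  dat <- data.frame(x1 = rnorm(n), time = rexp(n), event = rbinom(n, 1, 0.8))
  fit <- fit_cox(dat)  # x1 unrelated to survival: beta ~ 0
  expect_lt(abs(fit$coefficients["x1"]), 0.05)
  tau <- 0.7
  km <- survival::survfit(survival::Surv(time, event) ~ 1, data = dat)
  S_km <- summary(km, times = tau)$surv
  base_risk <- predict_risk(fit, data.frame(x1 = unname(fit$means["x1"])), tau)
  expect_equal(1 - base_risk, S_km, tolerance = 0.005)
})

test_that("censoring weights reproduce hand-computed reverse Kaplan-Meier values", {
  # subjects: times 1, 2, 3, 4, 6; events 1, 0, 1, 1, 0; tau = 5
  # one censoring at t = 2 with 4 at risk: G drops to 3/4 there
  w <- censoring_weights(c(1, 2, 3, 4, 6), c(1, 0, 1, 1, 0), tau = 5)
  expect_equal(w, c(1, 0, 4 / 3, 4 / 3, 4 / 3))
  # no censoring: every contributing subject has weight 1
  w2 <- censoring_weights(c(1, 2, 3, 10), c(1, 1, 1, 0), tau = 5)
  expect_equal(w2, c(1, 1, 1, 1))
  # censored strictly before tau contribute nothing
  expect_equal(censoring_weights(c(1, 4), c(0, 1), tau = 5)[1], 0)
})

test_that("time-dependent AUC equals the brute-force pair count when uncensored", {
  dat <- toy_uncensored(risk = c(0.9, 0.4, 0.5, 0.1),
                        is_case = c(TRUE, TRUE, FALSE, FALSE))
  expect_equal(td_auc(dat$risk, dat$time, dat$event, tau = 5), 3 / 4)
  expect_equal(td_auc(dat$risk, dat$time, dat$event, tau = 5),
               brute_auc(c(0.9, 0.4), c(0.5, 0.1)))
  # all risks equal: no discrimination
  expect_equal(td_auc(rep(0.3, 4), dat$time, dat$event, tau = 5), 0.5)
  # perfect separation
  expect_equal(td_auc(c(0.9, 0.8, 0.2, 0.1), dat$time, dat$event, tau = 5), 1)
  # half credit for ties, verified against the brute-force oracle
  r <- c(0.5, 0.4, 0.5, 0.1)
  expect_equal(td_auc(r, dat$time, dat$event, tau = 5),
               brute_auc(c(0.5, 0.4), c(0.5, 0.1)))
  expect_error(td_auc(c(0.2, 0.3), c(1, 2), c(1, 1), tau = 5),
               class = "bivalid_undefined_metric")
})

test_that("AUC reduces to the binary oracle on larger uncensored data and is rank-invariant", {
  set.seed(505)
  n <- 60
  is_case <- rep(c(TRUE, FALSE), n / 2)
  risk <- plogis(rnorm(n) + is_case)
  dat <- toy_uncensored(risk, is_case)
  auc <- td_auc(dat$risk, dat$time, dat$event, tau = 5)
  expect_equal(auc, brute_auc(risk[is_case], risk[!is_case]))
  # invariant to strictly monotone transforms of the score
  expect_equal(td_auc(qlogis(dat$risk), dat$time, dat$event, tau = 5), auc)
  expect_equal(td_auc(dat$risk^3, dat$time, dat$event, tau = 5), auc)
})

test_that("Brier score matches the direct formula on uncensored data", {
  set.seed(506)
  n <- 40
  is_case <- rep(c(TRUE, FALSE), n / 2)
  dat <- toy_uncensored(runif(n), is_case)
  # constant prediction p: mean((1{s > tau} - (1 - p))^2), several p
  for (p in c(0.2, 0.5, 0.9)) {
    expect_equal(td_brier(rep(1 - p, n), dat$time, dat$event, tau = 5),
                 mean((as.numeric(dat$time > 5) - (1 - p))^2))
  }
  # perfect 0/1 predictions
  expect_equal(td_brier(as.numeric(!is_case), dat$time, dat$event, tau = 5), 0)
  expect_error(td_brier(rep(1.2, n), dat$time, dat$event, 5), "lie in")
})

test_that("Brier score weights censored subjects per the hand-computed sum", {
  # same 5-subject configuration as the weight test
  time <- c(1, 2, 3, 4, 6); event <- c(1, 0, 1, 1, 0)
  sp <- c(0.9, 0.5, 0.6, 0.4, 0.7)
  w <- c(1, 0, 4 / 3, 4 / 3, 4 / 3)
  hand <- mean(w * (as.numeric(time > 5) - sp)^2)
  expect_equal(td_brier(sp, time, event, tau = 5), hand)
})
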