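#' Odds ratio from a 2 x 2 cross-tabulation of missingness proportions
#'
#' Given two marginal missingness proportions and their joint proportion,
#' forms the implied 2 x 2 table of cell proportions
#' \eqn{p_{11} = p_J}, \eqn{p_{10} = p_A - p_J}, \eqn{p_{01} = p_B - p_J},
#' \eqn{p_{00} = 1 - p_A - p_B + p_J} and returns
#' \eqn{(p_{00} p_{11}) / (p_{10} p_{01})}.
#'
#' @param p_a,p_b Marginal missingness proportions of the two covariates.
#' @param p_joint Target joint missingness proportion; must not exceed either
#'   marginal.
#' @return The odds ratio (a positive scalar).
#' @export
cross_tab_or <- function(p_a, p_b, p_joint) {
  if (p_joint < 0 || p_joint > min(p_a, p_b))
    stop("joint proportion must lie in [0, min(p_a, p_b)]", call. = FALSE)
  p11 <- p_joint
  p10 <- p_a - p_joint
  p01 <- p_b - p_joint
  p00 <- 1 - p_a - p_b + p_joint
  if (min(p11, p10, p01, p00) < 0)
    stop("cross-tabulation has a negative cell", call. = FALSE)
  if (p10 == 0 || p01 == 0)
    stop("degenerate cross-tabulation: a denominator cell is zero", call. = FALSE)
  (p00 * p11) / (p10 * p01)
}

#' Solve the missingness-model intercept
#'
#' Plug-in solution of the logistic missingness model intercept:
#' \eqn{\gamma_0 = \mathrm{logit}(\pi) - \gamma_1 P(M_k = 1) - \gamma_2 \bar X_l}.
#' Approximate by construction (the expectation of a logistic is not the
#' logistic of the expectation), so realized marginals deviate slightly from
#' their targets.
#'
#' @param pi_j Target marginal missingness proportion, in (0, 1).
#' @param gamma1 Log odds ratio for the driver covariate's missingness.
#' @param p_mk Marginal missingness probability of the driver covariate
#'   (0 when that covariate never goes missing).
#' @param xbar_l Sample mean of the value-driver covariate in the cohort
#'   being masked.
#' @param gamma2 Log odds per unit of the value-driver covariate.
#' @return The intercept \eqn{\gamma_0}.
#' @export
solve_intercept <- function(pi_j, gamma1, p_mk, xbar_l, gamma2) {
  if (pi_j <= 0 || pi_j >= 1)
    stop("target marginal must lie strictly in (0, 1)", call. = FALSE)
  stats::qlogis(pi_j) - gamma1 * p_mk - gamma2 * xbar_l
}

# Table of fixed missingness-mechanism parameters: for each covariate that can
# go missing, the index k of the covariate whose *missingness* drives it, the
# index l of the covariate whose *value* drives it, and the fixed log-odds
# slope gamma2. X1 has no missingness driver.
.mar_drivers <- data.frame(
  j = c(1L, 3L, 4L, 7L, 10L, 11L),
  k = c(NA, 1L, 3L, 4L, 5L, 10L),
  l = c(2L, 5L, 6L, 8L, 9L, 2L),
  gamma2 = log(c(1.05, 0.80, 0.70, 0.90, 0.60, 1.05))
)

# Joint missingness targets keyed by the unordered pair of marginals.
.joint_targets <- data.frame(
  p1 = c(0.05, 0.05, 0.15, 0.15, 0.30, 0.30, 0.60),
  p2 = c(0.05, 0.15, 0.15, 0.30, 0.30, 0.60, 0.60),
  joint = c(0.01, 0.02, 0.05, 0.07, 0.10, 0.20, 0.40)
)

lookup_joint_target <- function(pi_a, pi_b) {
  lo <- round(min(pi_a, pi_b), 6)
  hi <- round(max(pi_a, pi_b), 6)
  hit <- which(.joint_targets$p1 == lo & .joint_targets$p2 == hi)
  if (length(hit) != 1L)
    stop(sprintf("no joint missingness target for marginal pair (%.2f, %.2f)",
                 lo, hi), call. = FALSE)
  .joint_targets$joint[hit]
}

#' Standard missing-data patterns
#'
#' The nine named marginal-missingness patterns of the simulation study:
#' X1 alone at 5/15/60% (A-C); (X1, X3, X4) at (5,5,5), (5,15,30),
#' (15,30,60)% (D-F); (X1, X3, X4, X7, X10, X11) at (5,5,5,5,5,5),
#' (5,5,15,15,30,30), (15,15,30,30,60,60)% (G-I).
#'
#' @param letter A single letter "A" through "I".
#' @return Named numeric vector of marginal targets, names `x<j>`.
#' @export
missingness_pattern <- function(letter) {
  pat <- switch(toupper(letter),
    A = c(x1 = 0.05),
    B = c(x1 = 0.15),
    C = c(x1 = 0.60),
    D = c(x1 = 0.05, x3 = 0.05, x4 = 0.05),
    E = c(x1 = 0.05, x3 = 0.15, x4 = 0.30),
    F = c(x1 = 0.15, x3 = 0.30, x4 = 0.60),
    G = c(x1 = 0.05, x3 = 0.05, x4 = 0.05, x7 = 0.05, x10 = 0.05, x11 = 0.05),
    H = c(x1 = 0.05, x3 = 0.05, x4 = 0.15, x7 = 0.15, x10 = 0.30, x11 = 0.30),
    I = c(x1 = 0.15, x3 = 0.15, x4 = 0.30, x7 = 0.30, x10 = 0.60, x11 = 0.60),
    stop("unknown pattern: ", letter, call. = FALSE)
  )
  pat
}

#' Build a calibrated missingness specification
#'
#' Derives, for every covariate in `pattern`, the logistic missingness-model
#' coefficients: \eqn{\gamma_2} is fixed by the mechanism table;
#' \eqn{\gamma_1} is the log odds ratio implied by the joint-missingness
#' target for the unordered pair of marginals (zero for X1, and zero when the
#' missingness driver never goes missing under this pattern); \eqn{\gamma_0}
#' is solved by the plug-in intercept equation using the driver covariate's
#' sample mean in `cohort`.
#'
#' @param pattern Named numeric vector of marginal targets (names `x<j>`),
#'   e.g. from [missingness_pattern()].
#' @param cohort Complete cohort `data.frame` (supplies the sample means).
#' @param joint_overrides Optional named numeric vector overriding specific
#'   joint targets; names are `"x<j>:x<k>"` with the lower index first
#'   (e.g. `c("x3:x4" = 0.075)` for the guided example).
#' @return A `missingness_spec`: a data frame with one row per masked
#'   covariate (in imposition order) and columns `j`, `target`, `k`, `l`,
#'   `gamma0`, `gamma1`, `gamma2`, `p_mk`, `joint`.
#' @export
build_missingness_spec <- function(pattern, cohort, joint_overrides = NULL) {
  idx <- as.integer(sub("^x", "", names(pattern)))
  if (anyNA(idx)) stop("pattern names must be of the form x<j>", call. = FALSE)
  if (!all(idx %in% .mar_drivers$j))
    stop("pattern includes a covariate with no missingness mechanism",
         call. = FALSE)
  if (any(pattern <= 0 | pattern >= 1))
    stop("marginal targets must lie strictly in (0, 1)", call. = FALSE)
  # fixed topological order of the missingness-driver graph
  order_j <- intersect(.mar_drivers$j, idx)
  rows <- lapply(order_j, function(j) {
    d <- .mar_drivers[.mar_drivers$j == j, ]
    pi_j <- unname(pattern[paste0("x", j)])
    k <- d$k
    driver_active <- !is.na(k) && paste0("x", k) %in% names(pattern)
    if (j != 1L && driver_active) {
      pi_k <- unname(pattern[paste0("x", k)])
      key <- paste0("x", min(j, k), ":x", max(j, k))
      joint <- if (!is.null(joint_overrides) && key %in% names(joint_overrides))
        unname(joint_overrides[key]) else lookup_joint_target(pi_j, pi_k)
      gamma1 <- log(cross_tab_or(pi_j, pi_k, joint))
      p_mk <- pi_k
    } else {
      joint <- NA_real_
      gamma1 <- 0
      p_mk <- 0
    }
    xbar_l <- mean(cohort[[paste0("x", d$l)]])
    gamma0 <- solve_intercept(pi_j, gamma1, p_mk, xbar_l, d$gamma2)
    data.frame(j = j, target = pi_j, k = k, l = d$l,
               gamma0 = gamma0, gamma1 = gamma1, gamma2 = d$gamma2,
               p_mk = p_mk, joint = joint)
  })
  spec <- do.call(rbind, rows)
  class(spec) <- c("missingness_spec", "data.frame")
  spec
}

#' @export
print.missingness_spec <- function(x, ...) {
  cat("MAR missingness specification (", nrow(x), " covariate",
      if (nrow(x) > 1) "s", ")\n", sep = "")
  print.data.frame(x, row.names = FALSE, digits = 4)
  invisible(x)
}

#' Impose missing-at-random missingness on a complete cohort
#'
#' Processes the spec's covariates in driver order; for each, the missingness
#' indicator is drawn Bernoulli with probability
#' \eqn{\mathrm{logistic}(\gamma_0 + \gamma_1 M_{ik} + \gamma_2 X_{il})},
#' where \eqn{M_{ik}} is the already-assigned missingness of the driver
#' covariate and \eqn{X_{il}} an always-observed covariate value. Missing
#' entries become `NA`; `time` and `event` are untouched, so the mechanism is
#' MAR by construction.
#'
#' @param cohort Complete cohort `data.frame`.
#' @param spec A [build_missingness_spec()] result.
#' @param seed Optional integer seed.
#' @return The cohort with `NA` holes in the spec's covariate columns.
#' @export
impose_missingness <- function(cohort, spec, seed = NULL) {
  stopifnot(inherits(spec, "missingness_spec"))
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(cohort)
  masked <- cohort
  value_drivers <- paste0("x", spec$l)
  if (any(value_drivers %in% paste0("x", spec$j)))
    stop("a value-driver covariate is itself masked; mechanism would not be MAR",
         call. = FALSE)
  M <- matrix(0, n, max(spec$j, spec$k, na.rm = TRUE))
  for (r in seq_len(nrow(spec))) {
    j <- spec$j[r]
    mk <- if (!is.na(spec$k[r]) && spec$gamma1[r] != 0) M[, spec$k[r]] else 0
    p <- stats::plogis(spec$gamma0[r] + spec$gamma1[r] * mk +
                         spec$gamma2[r] * cohort[[paste0("x", spec$l[r])]])
    m <- stats::rbinom(n, 1L, p)
    M[, j] <- m
    masked[[paste0("x", j)]][m == 1L] <- NA_real_
  }
  masked
}

#' Realized missingness proportions
#'
#' Marginal `NA` fraction per covariate column, plus joint fractions for the
#' (target, driver) pairs of a spec when supplied.
#'
#' @param masked Masked cohort `data.frame`.
#' @param spec Optional `missingness_spec` to compute joint proportions for.
#' @return A list with `marginal` (named vector) and, when `spec` is given,
#'   `joint` (data frame of pair proportions).
#' @export
missingness_proportions <- function(masked, spec = NULL) {
  covs <- covariate_columns(masked)
  marginal <- vapply(masked[covs], function(v) mean(is.na(v)), numeric(1))
  out <- list(marginal = marginal)
  if (!is.null(spec)) {
    pairs <- spec[!is.na(spec$k) & spec$gamma1 != 0, c("j", "k")]
    if (nrow(pairs)) {
      out$joint <- data.frame(
        j = pairs$j, k = pairs$k,
        proportion = mapply(function(j, k) {
          mean(is.na(masked[[paste0("x", j)]]) & is.na(masked[[paste0("x", k)]]))
        }, pairs$j, pairs$k)
      )
    }
  }
  out
}

#' Guided-example missingness specification
#'
#' Pattern (X1, X3, X4) at marginals (0.05, 0.15, 0.30) with joint targets
#' 0.02 for (X1, X3) and 0.075 for (X3, X4) — the worked-example calibration,
#' which fixes the (X3, X4) joint at 0.075 rather than the simulation grid's
#' 0.07.
#'
#' @param cohort Complete cohort supplying sample means.
#' @return A `missingness_spec`.
#' @export
guided_example_spec <- function(cohort) {
  build_missingness_spec(missingness_pattern("E"), cohort,
                         joint_overrides = c("x3:x4" = 0.075))
}
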