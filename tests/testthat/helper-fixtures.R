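# shared fixtures built in code

# small configuration with independent covariates for fast structural tests
toy_config <- function(n = 200, p = 3) {
  generation_config(
    n = n,
    mu = rep(0, p),
    sigma = diag(p),
    binary = c(TRUE, rep(FALSE, p - 1)),
    beta = rep(0, p)
  )
}

# uncensored toy survival data with known case/control split at tau = 5
toy_uncensored <- function(risk, is_case) {
  data.frame(risk = risk,
             time = ifelse(is_case, 2, 10),
             event = ifelse(is_case, 1L, 0L))
}

# brute-force binary AUC with half credit for ties (independent oracle)
brute_auc <- function(risk_case, risk_ctrl) {
  tot <- 0
  for (rc in risk_case) for (rv in risk_ctrl)
    tot <- tot + (rc > rv) + 0.5 * (rc == rv)
  tot / (length(risk_case) * length(risk_ctrl))
}

# guided-example masked cohort at reduced size, fixed seed
guided_masked <- function(n = 600, seed = 401) {
  dat <- simulate_cohort(default_generation_config(n = n), seed = seed)
  impose_missingness(dat, guided_example_spec(dat), seed = seed + 1)
}
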