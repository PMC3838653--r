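# Small in-code fixtures shared across test files.

# compact synthetic cohort for sampler tests
tiny_cohort <- function(n_workers = 5, seed = 42, outcome = "sbp",
                        ...) {
  cfg <- cohort_config(outcome = outcome, n_workers = n_workers, ...)
  simulate_cohort(cfg, seed = seed)
}

# hand-built single-worker cohort with controllable covariates
flat_cohort <- function(n = 5, y = rep(0, n), worker = rep("A", n),
                        age = rep(25, n), bmi = rep(24, n)) {
  long_cohort(data.frame(
    worker_id = worker, exam_time = stats::ave(seq_len(n), worker,
                                               FUN = seq_along) - 1,
    sbp = y, age = age, bmi = bmi, sex = "male", marital = "single",
    education = "diploma", shift = "day", job = "bluecollar"),
    outcome = "sbp")
}

# a bare sampler state around a prepared data list
make_state <- function(data, beta = rep(0, data$p), b = numeric(data$m),
                       sigma_b2 = 1, omega2 = 1, lambda = 0, nu = 10,
                       u = numeric(data$n), w = rep(1, data$n),
                       fix = list()) {
  list(beta = beta, b = b, sigma_b2 = sigma_b2, omega2 = omega2,
       lambda = lambda, nu = nu, u = u, w = w,
       step_lambda = 0.2, step_lognu = 0.2,
       lambda_accepts = 0L, lambda_tries = 0L, lambda_alpha = 0.35,
       nu_accepts = 0L, nu_tries = 0L, nu_alpha = 0.35, fix = fix)
}

sample_skewness <- function(x) {
  mean((x - mean(x))^3) / stats::sd(x)^3
}
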