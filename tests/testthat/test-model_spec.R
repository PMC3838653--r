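test_that("cohort validation enforces keys, levels and exam ordering", {
  df <- as.data.frame(tiny_cohort(4, seed = 2))
  expect_s3_class(long_cohort(df, "sbp"), "long_cohort")
  expect_error(long_cohort(df[, -3], "sbp"), "missing required columns")
  bad <- df; bad$sbp[2] <- NA
  expect_error(long_cohort(bad, "sbp"), "missing outcome")
  bad <- df; bad$sex[3] <- "other"
  expect_error(long_cohort(bad, "sbp"), "unknown level 'other'.*`sex`")
  bad <- df
  bad$exam_time[bad$worker_id == bad$worker_id[1]] <- 0  # ties
  if (sum(bad$worker_id == bad$worker_id[1]) > 1)
    expect_error(long_cohort(bad, "sbp"), "strictly increasing")
})

test_that("design matrix uses treatment coding against reference levels", {
  ref <- data.frame(worker_id = "A", exam_time = 0, sbp = 120,
                    age = 30, bmi = 24, sex = "female",
                    marital = "married", education = "diploma",
                    shift = "day", job = "whitecollar")
  X <- build_design(ref)
  expect_identical(colnames(X), design_labels())
  expect_equal(ncol(X), 10L)
  expect_equal(drop(X), c(intercept = 1, age = 30, bmi = 24, male = 0,
                          single = 0, educ_associate = 0,
                          educ_bachelor = 0, shift_weekly = 0,
                          shift_routine = 0, blue_collar = 0))
  full <- ref
  full[c("sex", "marital", "education", "shift", "job")] <-
    list("male", "single", "bachelor", "routine", "bluecollar")
  expect_equal(unname(drop(build_design(full))[c("male", "single",
    "educ_bachelor", "shift_routine", "blue_collar")]), rep(1, 5))
  # k - 1 dummies for 3-level education
  expect_length(grep("^educ_", design_labels()), 2L)
  bad <- ref; bad$education <- "phd"
  expect_error(build_design(bad), "unknown level 'phd'.*`education`.*row 1")
})

test_that("joint log-likelihood matches closed forms and is additive", {
  one <- flat_cohort(n = 1, y = 120, age = 25, bmi = 24)
  beta <- c(120 - 0.5 * 25 - 0.2 * 24 - 1 - 1 - 1, 0.5, 0.2, 1, 1,
            0, 0, 0, 0, 1)
  pars <- model_params(beta, sigma_b2 = 1,
                       resid = skewt_params(omega = 1, lambda = 0, nu = 5))
  ll <- mlm_loglikelihood(pars, c(A = 0), one)
  expect_equal(ll, dt(0, 5, log = TRUE) + dnorm(0, log = TRUE),
               tolerance = 1e-12)
  # additivity: concatenating a cohort with itself doubles the exam term
  coh <- tiny_cohort(4, seed = 3)
  pars2 <- model_params(stats::setNames(c(100, rep(0.1, 9)),
                                        design_labels()),
                        sigma_b2 = 4, resid = skewt_params(3, 1, 6))
  ids <- unique(coh$worker_id)
  b <- stats::setNames(seq_along(ids) / 10, ids)
  df2 <- as.data.frame(coh)
  df2$worker_id <- paste0(df2$worker_id, "bis")
  both <- long_cohort(rbind(as.data.frame(coh), df2), "sbp")
  b2 <- c(b, stats::setNames(b, paste0(ids, "bis")))
  ll1 <- mlm_loglikelihood(pars2, b, coh)
  ll12 <- mlm_loglikelihood(pars2, b2, both)
  expect_equal(ll12, 2 * ll1, tolerance = 1e-10)
  # invariance to worker relabeling
  df3 <- as.data.frame(coh)
  df3$worker_id <- chartr("W", "Z", df3$worker_id)
  b3 <- stats::setNames(b, chartr("W", "Z", names(b)))
  expect_equal(mlm_loglikelihood(pars2, b3, long_cohort(df3, "sbp")), ll1)
  expect_error(mlm_loglikelihood(
    model_params(1:3, 1, skewt_params(1)), b, coh), "design width")
})

test_that("normal-limit log-likelihood agrees with a Gaussian mixed model", {
  coh <- tiny_cohort(6, seed = 4)
  beta <- sbp_truth()$beta
  beta["intercept"] <- 76
  ids <- unique(coh$worker_id)
  b <- stats::setNames(rnorm(length(ids)), ids)
  pars <- model_params(beta, sigma_b2 = 9,
                       resid = skewt_params(omega = 2.3, lambda = 0,
                                            nu = 1e6))
  X <- build_design(coh)
  r <- coh$sbp - drop(X %*% beta) - b[coh$worker_id]
  normal_ll <- sum(dnorm(r, 0, 2.3, log = TRUE)) +
    sum(dnorm(b, 0, 3, log = TRUE))
  expect_equal(mlm_loglikelihood(pars, b, coh), normal_ll,
               tolerance = 1e-4)
})

test_that("prior and chain configuration enforce their invariants", {
  pr <- prior_spec()
  expect_equal(pr$beta_variance, 100)
  expect_equal(pr$precision_shape, 0.001)
  expect_equal(pr$nu_rate, 0.1)
  expect_equal(pr$on, "precision")
  expect_error(prior_spec(precision_rate = 0), "positive")
  cc <- chain_config()
  expect_equal(retained_draws(cc), 100L)
  expect_equal(retained_draws(chain_config(5000, 500, 30)),
               (5000L - 500L) %/% 30L)
  expect_error(chain_config(1000, 1000, 10), "burn_in")
  expect_error(chain_config(1000, 100, 0), "thin")
  expect_error(model_params(1:10, -1, skewt_params(1)), "sigma_b2")
  expect_error(model_params(1:10, 1, skewt_params(1, xi = 2)),
               "location")
})
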