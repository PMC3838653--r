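#' Declared category levels for cohort covariates
#'
#' The first level of each covariate is the reference category used by
#' \code{\link{build_design}}: female, married, diploma-or-lower education,
#' day-shift and white-collar workers.
#'
#' @return Named list of character vectors.
#' @export
cohort_levels <- function() {
  list(
    sex       = c("female", "male"),
    marital   = c("married", "single"),
    education = c("diploma", "associate", "bachelor"),
    shift     = c("day", "weekly", "routine"),
    job       = c("whitecollar", "bluecollar")
  )
}

required_cohort_columns <- function(outcome) {
  c("worker_id", "exam_time", outcome, "age", "bmi",
    names(cohort_levels()))
}

#' Long-format longitudinal cohort
#'
#' Validates and classes a long-format repeated-measures data set: one row
#' per health examination, keyed by \code{worker_id} and \code{exam_time}
#' (years since the worker's first exam).  Required columns are the outcome
#' (\code{sbp} or \code{dbp}, mmHg), \code{age} (years), \code{bmi}
#' (kg/m^2) and the categorical covariates \code{sex}, \code{marital},
#' \code{education}, \code{shift}, \code{job} with levels as in
#' \code{\link{cohort_levels}}.
#'
#' Invariants enforced: every worker has at least one exam, exam times are
#' strictly increasing within worker, and no retained row has a missing
#' outcome.
#'
#' @param data a data.frame in long format.
#' @param outcome which outcome column the model will use.
#' @return The data, ordered by worker and exam time, with class
#'   \code{"long_cohort"} and attribute \code{outcome}.
#' @export
long_cohort <- function(data, outcome = c("sbp", "dbp")) {
  outcome <- match.arg(outcome)
  stopifnot(is.data.frame(data))
  need <- required_cohort_columns(outcome)
  miss <- setdiff(need, names(data))
  if (length(miss))
    stop("missing required columns: ", paste(miss, collapse = ", "),
         call. = FALSE)
  if (nrow(data) == 0L) stop("cohort has no rows", call. = FALSE)
  if (anyNA(data[[outcome]]))
    stop("missing outcome values in column `", outcome, "`", call. = FALSE)
  lv <- cohort_levels()
  for (col in names(lv)) {
    vals <- as.character(data[[col]])
    bad <- which(!(vals %in% lv[[col]]))
    if (length(bad))
      stop(sprintf("unknown level '%s' in column `%s` (row %d)",
                   vals[bad[1L]], col, bad[1L]), call. = FALSE)
    data[[col]] <- vals
  }
  data <- data[order(data$worker_id, data$exam_time), , drop = FALSE]
  rownames(data) <- NULL
  dup <- stats::ave(data$exam_time, data$worker_id,
                    FUN = function(t) c(1, diff(t)))
  if (any(dup <= 0 & stats::ave(data$exam_time, data$worker_id,
                                FUN = seq_along) > 1))
    stop("exam times must be strictly increasing within worker",
         call. = FALSE)
  structure(data, class = c("long_cohort", "data.frame"),
            outcome = outcome)
}

#' @export
print.long_cohort <- function(x, ...) {
  cat(sprintf("long_cohort: %d exams, %d workers, outcome `%s`\n",
              nrow(x), length(unique(x$worker_id)), attr(x, "outcome")))
  NextMethod()
}

#' Design matrix for the random-intercept regression
#'
#' Builds the fixed-effects design matrix with treatment (dummy) coding
#' against the reference categories of \code{\link{cohort_levels}}:
#' intercept first, then age and BMI untransformed, then dummies for male
#' sex, single marital status, associate and bachelor education, weekly and
#' routine rotating shifts, and blue-collar job.
#'
#' @param cohort a \code{\link{long_cohort}} (or any data.frame carrying
#'   the covariate columns).
#' @return Numeric matrix with one row per exam and the 10 columns
#'   \code{intercept, age, bmi, male, single, educ_associate,
#'   educ_bachelor, shift_weekly, shift_routine, blue_collar}.
#' @export
build_design <- function(cohort) {
  lv <- cohort_levels()
  for (col in names(lv)) {
    vals <- as.character(cohort[[col]])
    bad <- which(!(vals %in% lv[[col]]))
    if (length(bad))
      stop(sprintf("unknown level '%s' in column `%s` (row %d)",
                   vals[bad[1L]], col, bad[1L]), call. = FALSE)
  }
  X <- cbind(
    intercept      = 1,
    age            = as.numeric(cohort$age),
    bmi            = as.numeric(cohort$bmi),
    male           = as.numeric(cohort$sex == "male"),
    single         = as.numeric(cohort$marital == "single"),
    educ_associate = as.numeric(cohort$education == "associate"),
    educ_bachelor  = as.numeric(cohort$education == "bachelor"),
    shift_weekly   = as.numeric(cohort$shift == "weekly"),
    shift_routine  = as.numeric(cohort$shift == "routine"),
    blue_collar    = as.numeric(cohort$job == "bluecollar")
  )
  X
}

#' Design column labels
#' @return Character vector of the 10 design-matrix column names.
#' @export
design_labels <- function() {
  c("intercept", "age", "bmi", "male", "single", "educ_associate",
    "educ_bachelor", "shift_weekly", "shift_routine", "blue_collar")
}

#' Model parameters of the skew-t random-intercept regression
#'
#' The model is \eqn{y_{ij} = x_{ij}'\beta + b_i + e_{ij}} with
#' \eqn{b_i \sim N(0, \sigma_b^2)} (between-subject variance) and
#' \eqn{e_{ij} \sim} skew-t\eqn{(0, \omega, \lambda, \nu)}
#' (within-subject error).
#'
#' @param beta named numeric coefficient vector (mmHg per covariate unit),
#'   in \code{\link{design_labels}} order, intercept included.
#' @param sigma_b2 between-subject variance (>= 0, mmHg^2).
#' @param resid a \code{\link{skewt_params}} object with \code{xi = 0}.
#' @return An object of class \code{"model_params"}.
#' @export
model_params <- function(beta, sigma_b2, resid) {
  stopifnot(is.numeric(beta), inherits(resid, "skewt_params"))
  if (!is.numeric(sigma_b2) || length(sigma_b2) != 1L || sigma_b2 < 0)
    stop("`sigma_b2` must be a single number >= 0", call. = FALSE)
  if (resid$xi != 0)
    stop("residual skew-t location must be fixed at 0", call. = FALSE)
  if (is.null(names(beta))) names(beta) <- design_labels()[seq_along(beta)]
  structure(list(beta = beta, sigma_b2 = sigma_b2, resid = resid),
            class = "model_params")
}

#' @export
print.model_params <- function(x, ...) {
  cat("model_params\n  beta:\n")
  print(round(x$beta, 4))
  cat(sprintf("  sigma_b2 = %g;  omega2 = %g, lambda = %g, nu = %g\n",
              x$sigma_b2, x$resid$omega^2, x$resid$lambda, x$resid$nu))
  invisible(x)
}

#' Prior specification
#'
#' Vague priors for the Bayesian fit: independent Normal(mean, variance)
#' on each regression coefficient; Gamma(shape, rate) on the between- and
#' within-subject precisions (or, optionally, on the variances);
#' Exponential(rate) on the degrees of freedom \eqn{\nu}; Normal on the
#' skewness \eqn{\lambda}.
#'
#' @param beta_mean,beta_variance normal prior on each reported
#'   coefficient (default 0, 100).
#' @param intercept_variance normal prior variance for the intercept
#'   (default 1e6, effectively flat).  The intercept is not one of the
#'   reported coefficients; a near-flat prior keeps the baseline outcome
#'   level (~120 mmHg for SBP) from being shrunk toward zero, which would
#'   otherwise leak bias into coefficients of near-constant covariates
#'   such as sex.
#' @param precision_shape,precision_rate gamma prior hyperparameters for
#'   the variance parameters (default 0.001, 0.001), applied to both the
#'   between-subject and within-subject term.
#' @param nu_rate exponential prior rate for \eqn{\nu} (default 0.1).
#' @param lambda_mean,lambda_variance normal prior on \eqn{\lambda}
#'   (default 0, 100).
#' @param on whether the gamma prior is placed on the precisions
#'   \eqn{1/\sigma^2} (BUGS idiom; the default) or literally on the
#'   variances.
#' @return An object of class \code{"prior_spec"}.
#' @export
prior_spec <- function(beta_mean = 0, beta_variance = 100,
                       intercept_variance = 1e6,
                       precision_shape = 0.001, precision_rate = 0.001,
                       nu_rate = 0.1,
                       lambda_mean = 0, lambda_variance = 100,
                       on = c("precision", "variance")) {
  on <- match.arg(on)
  for (nm in c("beta_variance", "intercept_variance", "precision_shape",
               "precision_rate", "nu_rate", "lambda_variance")) {
    v <- get(nm)
    if (!is.numeric(v) || length(v) != 1L || !is.finite(v) || v <= 0)
      stop("`", nm, "` must be a single positive number", call. = FALSE)
  }
  structure(list(beta_mean = beta_mean, beta_variance = beta_variance,
                 intercept_variance = intercept_variance,
                 precision_shape = precision_shape,
                 precision_rate = precision_rate,
                 nu_rate = nu_rate, lambda_mean = lambda_mean,
                 lambda_variance = lambda_variance, on = on),
            class = "prior_spec")
}

#' MCMC chain schedule
#'
#' Defaults follow the analysis schedule: a chain of length 11,000 with a
#' burn-in of 1,000, keeping every 100th draw, so
#' \code{floor((11000 - 1000)/100) = 100} retained draws.
#'
#' @param n_iterations total sweeps.
#' @param burn_in discarded initial sweeps (< \code{n_iterations}).
#' @param thin keep every \code{thin}-th post-burn-in sweep (>= 1).
#' @param seed integer RNG seed for the chain.
#' @param step_lambda,step_lognu initial random-walk Metropolis step sizes
#'   for \eqn{\lambda} and \eqn{\log\nu} (adapted during burn-in).
#' @param adapt adapt the Metropolis step sizes during burn-in
#'   (Robbins-Monro towards 0.35 acceptance), frozen afterwards.
#' @return An object of class \code{"chain_config"}.
#' @export
chain_config <- function(n_iterations = 11000L, burn_in = 1000L,
                         thin = 100L, seed = 1L,
                         step_lambda = 0.1, step_lognu = 0.2,
                         adapt = TRUE) {
  n_iterations <- as.integer(n_iterations)
  burn_in <- as.integer(burn_in)
  thin <- as.integer(thin)
  if (burn_in >= n_iterations)
    stop("`burn_in` must be < `n_iterations`", call. = FALSE)
  if (thin < 1L) stop("`thin` must be >= 1", call. = FALSE)
  if (step_lambda <= 0 || step_lognu <= 0)
    stop("step sizes must be > 0", call. = FALSE)
  structure(list(n_iterations = n_iterations, burn_in = burn_in,
                 thin = thin, seed = as.integer(seed),
                 step_lambda = step_lambda, step_lognu = step_lognu,
                 adapt = isTRUE(adapt)),
            class = "chain_config")
}

#' Retained draw count implied by a chain schedule
#' @param config a \code{\link{chain_config}}.
#' @return \code{floor((n_iterations - burn_in)/thin)}.
#' @export
retained_draws <- function(config) {
  stopifnot(inherits(config, "chain_config"))
  (config$n_iterations - config$burn_in) %/% config$thin
}

#' Joint log-likelihood of the random-intercept skew-t model
#'
#' Sum over exams of the skew-t log-density of
#' \eqn{y_{ij} - x_{ij}'\beta - b_i}, plus the sum over workers of the
#' normal log-density of the random intercepts \eqn{b_i}.
#'
#' @param params a \code{\link{model_params}}.
#' @param intercepts named numeric vector of per-worker random intercepts;
#'   names are worker ids (every worker in the cohort must be present).
#' @param cohort a \code{\link{long_cohort}}.
#' @return The joint log-likelihood (a single number).
#' @export
mlm_loglikelihood <- function(params, intercepts, cohort) {
  stopifnot(inherits(params, "model_params"),
            inherits(cohort, "long_cohort"))
  X <- build_design(cohort)
  if (length(params$beta) != ncol(X))
    stop("coefficient vector length (", length(params$beta),
         ") does not match design width (", ncol(X), ")", call. = FALSE)
  ids <- unique(cohort$worker_id)
  if (!all(ids %in% names(intercepts)))
    stop("`intercepts` must contain one entry per worker", call. = FALSE)
  b <- intercepts[as.character(cohort$worker_id)]
  y <- cohort[[attr(cohort, "outcome")]]
  r <- y - drop(X %*% params$beta) - b
  sum(dskewt(r, params$resid, log = TRUE)) +
    sum(stats::dnorm(intercepts[as.character(ids)], 0,
                     sqrt(params$sigma_b2), log = TRUE))
}
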