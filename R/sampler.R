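# Data-augmentation sampler for the random-intercept skew-t model.
#
# Augmentation: with delta = lambda/sqrt(1+lambda^2), each residual is
#   e_ij | u_ij, w_ij ~ N(delta * u_ij, omega^2 (1 - delta^2) / w_ij)
#   u_ij | w_ij      ~ N+(0, omega^2 / w_ij)        (half-normal, >= 0)
#   w_ij             ~ Gamma(nu/2, nu/2)
# which marginalizes to the skew-t(0, omega, lambda, nu) of dskewt().
# Conditionals used below:
#   u_ij | rest ~ N+(delta * r_ij, omega^2 (1 - delta^2) / w_ij)
#   w_ij | rest ~ Gamma(nu/2 + 1,
#                       nu/2 + ((r-du)^2/(1-d^2) + u^2) / (2 omega^2))
#   1/omega^2   ~ Gamma(a + n, b + S/2),
#                 S = sum w [ (r - d u)^2/(1-d^2) + u^2 ]
# (u carries a factor omega, so each exam contributes a full unit to the
# shape, not 1/2).  (lambda, nu) are updated jointly by random-walk
# Metropolis on (lambda, log nu) against the skew-t likelihood with the
# latents integrated out; the latents are refreshed at the start of the
# next sweep before anything re-uses them, keeping the partially collapsed
# scheme valid.

prepare_chain_data <- function(cohort) {
  stopifnot(inherits(cohort, "long_cohort"))
  X <- build_design(cohort)
  y <- as.numeric(cohort[[attr(cohort, "outcome")]])
  wf <- factor(cohort$worker_id, levels = unique(cohort$worker_id))
  list(X = X, y = y, widx = as.integer(wf), worker_ids = levels(wf),
       n = nrow(X), m = nlevels(wf), p = ncol(X), labels = colnames(X))
}

# truncated-normal N+(mean, sd^2) draws on [0, Inf); tail-safe
rtrunc_norm_pos <- function(mean, sd) {
  a <- -mean / sd
  out <- numeric(length(mean))
  far <- a > 30  # mass numerically indistinguishable from an exp tail
  if (any(!far)) {
    s0 <- stats::pnorm(a[!far], lower.tail = FALSE)
    u <- stats::runif(sum(!far))
    out[!far] <- stats::qnorm(u * s0, lower.tail = FALSE) * sd[!far] +
      mean[!far]
  }
  if (any(far))
    out[far] <- stats::rexp(sum(far), rate = a[far] / sd[far])
  pmax(out, 0)
}

update_latents <- function(state, data) {
  d <- state$lambda / sqrt(1 + state$lambda^2)
  one_m_d2 <- 1 / (1 + state$lambda^2)
  r <- data$y - drop(data$X %*% state$beta) - state$b[data$widx]
  sd_u <- sqrt(one_m_d2 * state$omega2 / state$w)
  state$u <- rtrunc_norm_pos(d * r, sd_u)
  q <- ((r - d * state$u)^2 / one_m_d2 + state$u^2) / state$omega2
  state$w <- stats::rgamma(data$n, shape = state$nu / 2 + 1,
                           rate = state$nu / 2 + q / 2)
  state
}

update_intercepts <- function(state, priors, data) {
  if (!is.null(state$fix$sigma_b2) && state$fix$sigma_b2 == 0) {
    state$b <- numeric(data$m)
    return(state)
  }
  d <- state$lambda / sqrt(1 + state$lambda^2)
  one_m_d2 <- 1 / (1 + state$lambda^2)
  tau <- state$w / (one_m_d2 * state$omega2)
  e <- data$y - drop(data$X %*% state$beta) - d * state$u
  sw <- rowsum(tau, data$widx)[, 1L]
  swe <- rowsum(tau * e, data$widx)[, 1L]
  prec <- 1 / state$sigma_b2 + sw
  state$b <- stats::rnorm(data$m, mean = swe / prec, sd = sqrt(1 / prec))
  state
}

# beta is drawn as a block with the random intercepts integrated out
# (per-worker Woodbury identity on the marginal covariance
# diag(1/tau) + sigma_b^2 11'); update_intercepts then draws b | beta.
# This removes the beta--b coupling that otherwise makes worker-level
# covariates (BMI, sex, marital status) mix very slowly.
update_beta <- function(state, priors, data) {
  d <- state$lambda / sqrt(1 + state$lambda^2)
  one_m_d2 <- 1 / (1 + state$lambda^2)
  tau <- state$w / (one_m_d2 * state$omega2)
  z <- data$y - d * state$u
  prior_prec <- ifelse(data$labels == "intercept",
                       1 / priors$intercept_variance,
                       1 / priors$beta_variance)
  A <- crossprod(data$X * tau, data$X)
  rhs <- crossprod(data$X, tau * z)
  if (state$sigma_b2 > 0) {
    Xw <- rowsum(data$X * tau, data$widx)
    zw <- rowsum(tau * z, data$widx)[, 1L]
    s <- rowsum(tau, data$widx)[, 1L]
    ci <- state$sigma_b2 / (1 + state$sigma_b2 * s)
    A <- A - crossprod(Xw * ci, Xw)
    rhs <- rhs - crossprod(Xw, ci * zw)
  }
  diag(A) <- diag(A) + prior_prec
  ch <- tryCatch(chol(A), error = function(e)
    stop("singular conditional covariance for beta (collinear design)",
         call. = FALSE))
  rhs <- rhs + priors$beta_mean * prior_prec
  mu <- backsolve(ch, backsolve(ch, rhs, transpose = TRUE))
  state$beta <- drop(mu + backsolve(ch, stats::rnorm(data$p)))
  names(state$beta) <- data$labels
  state
}

# Metropolis step on log(variance) when the gamma prior sits literally on
# the variance (non-conjugate); shape/rate are the likelihood's gamma
# sufficient statistics for the precision.
draw_variance_mh <- function(var_cur, lik_shape, lik_rate, priors,
                             step = 0.3) {
  logpost <- function(v) {
    phi <- 1 / v
    lik_shape * log(phi) - lik_rate * phi +
      (priors$precision_shape - 1) * log(v) - priors$precision_rate * v +
      log(v)  # Jacobian of the log-variance walk
  }
  prop <- var_cur * exp(stats::rnorm(1, sd = step))
  if (log(stats::runif(1)) < logpost(prop) - logpost(var_cur)) prop
  else var_cur
}

update_precisions <- function(state, priors, data) {
  d <- state$lambda / sqrt(1 + state$lambda^2)
  one_m_d2 <- 1 / (1 + state$lambda^2)
  r <- data$y - drop(data$X %*% state$beta) - state$b[data$widx]
  S <- sum(state$w * ((r - d * state$u)^2 / one_m_d2 + state$u^2))
  if (is.null(state$fix$omega2)) {
    if (priors$on == "precision") {
      phi_e <- stats::rgamma(1, shape = priors$precision_shape + data$n,
                             rate = priors$precision_rate + S / 2)
      state$omega2 <- 1 / phi_e
    } else {
      state$omega2 <- draw_variance_mh(state$omega2, data$n, S / 2, priors)
    }
  }
  if (is.null(state$fix$sigma_b2)) {
    sb <- sum(state$b^2)
    if (priors$on == "precision") {
      phi_b <- stats::rgamma(1, shape = priors$precision_shape + data$m / 2,
                             rate = priors$precision_rate + sb / 2)
      state$sigma_b2 <- 1 / phi_b
    } else {
      state$sigma_b2 <- draw_variance_mh(state$sigma_b2, data$m / 2,
                                         sb / 2, priors)
    }
  }
  state
}

# Shape updates are partially collapsed Metropolis steps, each paired
# with the exact conditional redraw of the latent it collapsed over (the
# pairing is what keeps the scheme invariant):
#   lambda | w, r  (u integrated out; only the skew-normal skewing factor
#                   prod Phi(lambda sqrt(w) r / omega) depends on lambda),
#   then u | lambda, w, r exactly (truncated normal);
#   nu | u, r      (w integrated out; the (r, u) pair given nu is a
#                   bivariate scale mixture with closed-form marginal
#                   proportional to nu^(nu/2+1) (nu + q)^-(nu/2+1)),
#   then w | nu, u, r exactly (gamma).
update_shape <- function(state, priors, data) {
  r <- data$y - drop(data$X %*% state$beta) - state$b[data$widx]
  omega <- sqrt(state$omega2)
  if (is.null(state$fix$lambda)) {
    z0 <- sqrt(state$w) * r / omega
    ltarget <- function(lam)
      sum(stats::pnorm(lam * z0, log.p = TRUE)) +
        stats::dnorm(lam, priors$lambda_mean,
                     sqrt(priors$lambda_variance), log = TRUE)
    lam_p <- state$lambda + stats::rnorm(1, sd = state$step_lambda)
    state$lambda_tries <- state$lambda_tries + 1L
    lr <- ltarget(lam_p) - ltarget(state$lambda)
    if (!is.finite(lr)) lr <- -Inf  # auto-reject degenerate proposals
    state$lambda_alpha <- min(1, exp(lr))
    if (log(stats::runif(1)) < lr) {
      state$lambda <- lam_p
      state$lambda_accepts <- state$lambda_accepts + 1L
    }
  }
  d <- state$lambda / sqrt(1 + state$lambda^2)
  one_m_d2 <- 1 / (1 + state$lambda^2)
  state$u <- rtrunc_norm_pos(d * r,
                             sqrt(one_m_d2 * state$omega2 / state$w))
  q <- ((r - d * state$u)^2 / one_m_d2 + state$u^2) / state$omega2
  if (is.null(state$fix$nu)) {
    ntarget <- function(nu)
      sum((nu / 2 + 1) * (log(nu) - log(nu + q))) +
        stats::dexp(nu, rate = priors$nu_rate, log = TRUE)
    nu_p <- exp(log(state$nu) + stats::rnorm(1, sd = state$step_lognu))
    state$nu_tries <- state$nu_tries + 1L
    if (is.finite(nu_p) && nu_p > 0) {  # else auto-reject
      # log(nu) terms are the Jacobian of the log-nu random walk
      lr <- ntarget(nu_p) + log(nu_p) -
        (ntarget(state$nu) + log(state$nu))
      if (!is.finite(lr)) lr <- -Inf
      state$nu_alpha <- min(1, exp(lr))
      if (log(stats::runif(1)) < lr) {
        state$nu <- nu_p
        state$nu_accepts <- state$nu_accepts + 1L
      }
    } else state$nu_alpha <- 0
  }
  state$w <- stats::rgamma(data$n, shape = state$nu / 2 + 1,
                           rate = state$nu / 2 + q / 2)
  state
}

init_state <- function(data, config, fix = list()) {
  fit <- stats::lm.fit(data$X, data$y)
  beta <- fit$coefficients
  beta[!is.finite(beta)] <- 0
  r <- data$y - drop(data$X %*% beta)
  # one-way ANOVA-style variance decomposition of the OLS residuals
  rb <- rowsum(r, data$widx)[, 1L] / tabulate(data$widx, data$m)
  within <- stats::var(r - rb[data$widx])
  if (!is.finite(within) || within <= 0) within <- stats::var(r)
  if (!is.finite(within) || within <= 0) within <- 1
  between <- max(stats::var(rb) - within / mean(tabulate(data$widx, data$m)),
                 0.05 * within)
  list(beta = beta, b = numeric(data$m),
       sigma_b2 = if (!is.null(fix$sigma_b2)) fix$sigma_b2 else between,
       omega2 = if (!is.null(fix$omega2)) fix$omega2 else within,
       lambda = if (!is.null(fix$lambda)) fix$lambda else 0,
       nu = if (!is.null(fix$nu)) fix$nu else 10,
       u = numeric(data$n), w = rep(1, data$n),
       step_lambda = config$step_lambda, step_lognu = config$step_lognu,
       lambda_accepts = 0L, lambda_tries = 0L, lambda_alpha = 0.35,
       nu_accepts = 0L, nu_tries = 0L, nu_alpha = 0.35,
       fix = fix)
}

#' Run the data-augmentation MCMC chain
#'
#' Fits the Bayesian random-intercept regression with skew-t within-subject
#' errors by Metropolis-within-Gibbs sampling.  Per sweep, the update order
#' is: latent augmentation variables, then the coefficient block (drawn
#' with the random intercepts integrated out), the random intercepts given
#' the coefficients, the precisions, and finally random-walk Metropolis
#' proposals for \eqn{\lambda} and \eqn{\log\nu}, each against a target
#' with one latent block integrated out and paired with the exact
#' conditional redraw of that block.  Metropolis step sizes are adapted during
#' burn-in only (targeting 0.35 acceptance) and frozen afterwards.
#'
#' @param cohort a \code{\link{long_cohort}}.
#' @param priors a \code{\link{prior_spec}}.
#' @param config a \code{\link{chain_config}}; all randomness flows from
#'   \code{config$seed}, so identical inputs give bit-identical draws.
#' @param fix_lambda,fix_nu,fix_sigma_b2,fix_omega2 optionally hold a
#'   parameter fixed at the given value (e.g. \code{fix_lambda = 0,
#'   fix_nu = 1e6} for a normal-error fit).
#' @param verbose log progress every 500 sweeps.
#' @return An object of class \code{"posterior_draws"}: a list with
#'   \code{draws} (retained draws x named parameters: the design labels
#'   plus \code{between_var}, \code{within_var}, \code{resid_var},
#'   \code{lambda}, \code{nu}), \code{b_mean} (posterior-mean random
#'   intercepts), \code{acceptance} (Metropolis rates for lambda and nu),
#'   plus the config,
#'   priors and data labels.
#' @export
run_chain <- function(cohort, priors = prior_spec(),
                      config = chain_config(),
                      fix_lambda = NULL, fix_nu = NULL,
                      fix_sigma_b2 = NULL, fix_omega2 = NULL,
                      verbose = FALSE) {
  stopifnot(inherits(priors, "prior_spec"), inherits(config, "chain_config"))
  data <- prepare_chain_data(cohort)
  fix <- list(lambda = fix_lambda, nu = fix_nu,
              sigma_b2 = fix_sigma_b2, omega2 = fix_omega2)
  fix <- fix[!vapply(fix, is.null, logical(1))]
  set.seed(config$seed)
  state <- init_state(data, config, fix)
  n_keep <- retained_draws(config)
  cols <- c(data$labels, "between_var", "within_var", "resid_var",
            "lambda", "nu")
  draws <- matrix(NA_real_, n_keep, length(cols),
                  dimnames = list(NULL, cols))
  b_sum <- numeric(data$m)
  kept <- 0L
  for (it in seq_len(config$n_iterations)) {
    state <- update_latents(state, data)
    state <- update_beta(state, priors, data)
    state <- update_intercepts(state, priors, data)
    state <- update_precisions(state, priors, data)
    if (!is.finite(state$omega2) || !is.finite(state$sigma_b2) ||
        state$omega2 <= 0 || 1 / state$omega2 > 1e12 ||
        (state$sigma_b2 > 0 && 1 / state$sigma_b2 > 1e12) ||
        anyNA(state$beta) || anyNA(state$b))
      stop("divergent precision draw at iteration ", it, call. = FALSE)
    state <- update_shape(state, priors, data)
    if (config$adapt && it <= config$burn_in) {
      g <- it^-0.6
      state$step_lambda <- state$step_lambda *
        exp(g * (state$lambda_alpha - 0.35))
      state$step_lognu <- state$step_lognu *
        exp(g * (state$nu_alpha - 0.35))
    }
    if (verbose && it %% 500L == 0L)
      message(sprintf(
        "sweep %d/%d (acceptance: lambda %.2f, nu %.2f)", it,
        config$n_iterations,
        state$lambda_accepts / max(1L, state$lambda_tries),
        state$nu_accepts / max(1L, state$nu_tries)))
    if (it > config$burn_in &&
        (it - config$burn_in) %% config$thin == 0L && kept < n_keep) {
      kept <- kept + 1L
      rv <- if (state$nu > 2) {
        p <- skewt_params(sqrt(state$omega2), state$lambda, state$nu)
        skewt_moments(p)$variance
      } else NA_real_
      draws[kept, ] <- c(state$beta, state$sigma_b2, state$omega2, rv,
                         state$lambda, state$nu)
      b_sum <- b_sum + state$b
    }
  }
  acc <- c(lambda = state$lambda_accepts / max(1L, state$lambda_tries),
           nu = state$nu_accepts / max(1L, state$nu_tries))
  structure(list(draws = draws, config = config, priors = priors,
                 labels = data$labels, seed = config$seed,
                 acceptance = acc,
                 b_mean = stats::setNames(b_sum / max(1L, kept),
                                          data$worker_ids),
                 fixed = fix),
            class = "posterior_draws")
}

#' @export
print.posterior_draws <- function(x, ...) {
  cat(sprintf(
    "posterior_draws: %d retained draws x %d parameters (seed %d)\n",
    nrow(x$draws), ncol(x$draws), x$seed))
  cat(sprintf("Metropolis acceptance: lambda %.2f, nu %.2f\n",
              x$acceptance[["lambda"]], x$acceptance[["nu"]]))
  invisible(x)
}

#' Fit the Bayesian skew-t random-intercept model
#'
#' High-level wrapper: runs \code{\link{run_chain}}, summarizes the
#' retained draws into a table of posterior mean, SD, Monte-Carlo SE,
#' equal-tailed credible interval and Bayesian p-value, computes fitted
#' residuals \eqn{y_{ij} - x_{ij}'\hat\beta - \hat b_i} at posterior means
#' and runs the Kolmogorov-Smirnov residual normality check.
#'
#' @inheritParams run_chain
#' @param ci_level credible-interval level (default 0.95).
#' @param ... passed to \code{\link{run_chain}} (e.g. \code{fix_lambda}).
#' @return An object of class \code{"skewt_lmm"} with elements
#'   \code{draws}, \code{summary}, \code{residuals}, \code{ks} and
#'   \code{outcome}.
#' @examples
#' cfg <- cohort_config(n_workers = 40)
#' coh <- simulate_cohort(cfg, seed = 1)
#' fit <- skewt_lmm(coh, config = chain_config(600, 100, 5, seed = 2))
#' fit$summary
#' @export
skewt_lmm <- function(cohort, priors = prior_spec(),
                      config = chain_config(), ci_level = 0.95, ...) {
  draws <- run_chain(cohort, priors = priors, config = config, ...)
  X <- build_design(cohort)
  y <- cohort[[attr(cohort, "outcome")]]
  beta_hat <- colMeans(draws$draws[, draws$labels, drop = FALSE])
  res <- y - drop(X %*% beta_hat) -
    draws$b_mean[as.character(cohort$worker_id)]
  ks <- ks_residual_check(unname(res))
  structure(list(draws = draws,
                 summary = posterior_summary(draws, ci_level = ci_level),
                 residuals = unname(res), ks = ks,
                 outcome = attr(cohort, "outcome")),
            class = "skewt_lmm")
}

#' @export
print.skewt_lmm <- function(x, ...) {
  cat(sprintf("Bayesian skew-t random-intercept model for `%s`\n\n",
              x$outcome))
  print(x$summary)
  cat(sprintf("\nKS residual normality check: D = %.4f, p = %.4g\n",
              x$ks$statistic, x$ks$p_value))
  invisible(x)
}
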