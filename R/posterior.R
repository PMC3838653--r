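# Posterior summaries in the conventional multilevel reporting layout:
# label, posterior mean, SD, Monte-Carlo SE, equal-tailed 95% CI, and a
# two-sided Bayesian p-value (twice the smaller posterior tail
# probability of the coefficient's sign).

#' Effective sample size of a draw sequence
#'
#' ESS for the posterior-mean estimator, \eqn{n / (1 + 2\sum_k \rho_k)},
#' with the autocorrelation sum truncated by Geyer's initial positive
#' sequence (pairs of consecutive autocorrelations are summed until a pair
#' goes non-positive).
#'
#' @param x numeric vector of retained draws.
#' @return Effective sample size (capped at \code{length(x)}).
#' @export
ess_mean <- function(x) {
  n <- length(x)
  if (n < 3L || stats::sd(x) == 0) return(n)
  rho <- stats::acf(x, lag.max = min(n - 2L, 200L), plot = FALSE,
                    demean = TRUE)$acf[-1L]
  s <- 0
  k <- 1L
  while (k + 1L <= length(rho)) {
    pair <- rho[k] + rho[k + 1L]
    if (pair <= 0) break
    s <- s + pair
    k <- k + 2L
  }
  min(n, n / (1 + 2 * s))
}

#' Two-sided Bayesian p-value of a coefficient
#'
#' \eqn{2 \min\{\Pr(\theta > 0), \Pr(\theta < 0)\}} estimated from the
#' retained draws, floored at \code{1/length(x)}; when no draw crosses
#' zero the value is reported as below that floor (attribute
#' \code{floored}), mirroring "< 0.001"-style table entries.
#'
#' @param x numeric vector of draws (>= 2).
#' @return A number in (0, 1] with logical attribute \code{floored}.
#' @export
bayes_pvalue <- function(x) {
  if (length(x) < 2L) stop("need >= 2 draws", call. = FALSE)
  p <- 2 * min(mean(x > 0), mean(x < 0))
  floored <- p == 0
  structure(min(1, max(p, 1 / length(x))), floored = floored)
}

#' Summarize retained posterior draws
#'
#' One row per parameter: posterior mean, sample SD (n-1 denominator),
#' Monte-Carlo standard error SD/\eqn{\sqrt{ESS}}, equal-tailed credible
#' interval, and the two-sided Bayesian p-value.
#'
#' @param draws a \code{posterior_draws} object from
#'   \code{\link{run_chain}}, or a numeric matrix of retained draws with
#'   named columns.
#' @param ci_level credible level (default 0.95, equal-tailed).
#' @return A data.frame of class \code{"mlm_summary"} with columns
#'   \code{label, mean, sd, se, ci_lower, ci_upper, p_value, p_label}.
#' @export
posterior_summary <- function(draws, ci_level = 0.95) {
  m <- if (inherits(draws, "posterior_draws")) draws$draws else draws
  stopifnot(is.matrix(m), !is.null(colnames(m)))
  if (nrow(m) < 2L)
    stop("need >= 2 retained draws to summarize", call. = FALSE)
  a <- (1 - ci_level) / 2
  rows <- lapply(colnames(m), function(lab) {
    x <- m[, lab]
    keep <- is.finite(x)
    x <- x[keep]
    if (length(x) < 2L)
      return(data.frame(label = lab, mean = NA_real_, sd = NA_real_,
                        se = NA_real_, ci_lower = NA_real_,
                        ci_upper = NA_real_, p_value = NA_real_,
                        p_label = NA_character_))
    q <- unname(stats::quantile(x, c(a, 1 - a), type = 7))
    pv <- bayes_pvalue(x)
    data.frame(label = lab, mean = mean(x), sd = stats::sd(x),
               se = stats::sd(x) / sqrt(ess_mean(x)),
               ci_lower = q[1L], ci_upper = q[2L],
               p_value = as.numeric(pv),
               p_label = if (isTRUE(attr(pv, "floored")))
                 sprintf("< %.3g", as.numeric(pv)) else
                   sprintf("%.3g", as.numeric(pv)))
  })
  out <- do.call(rbind, rows)
  class(out) <- c("mlm_summary", "data.frame")
  out
}

#' @export
print.mlm_summary <- function(x, digits = 3, ...) {
  df <- as.data.frame(x)
  num <- c("mean", "sd", "se", "ci_lower", "ci_upper")
  df[num] <- lapply(df[num], round, digits = digits)
  df$p_value <- NULL
  names(df) <- c("Variable", "MCMC Beta", "MCMC SD", "MCMC SE",
                 "95% CI lower", "95% CI upper", "P value")
  print(df, row.names = FALSE)
  invisible(x)
}

#' Write a posterior summary table as CSV
#' @param summary an \code{mlm_summary}.
#' @param path output file path.
#' @return The path, invisibly.
#' @export
write_summary_csv <- function(summary, path) {
  utils::write.csv(as.data.frame(summary)[
    c("label", "mean", "sd", "se", "ci_lower", "ci_upper", "p_label")],
    path, row.names = FALSE)
  invisible(path)
}

#' Write a posterior summary as an aligned plain-text table
#' @inheritParams write_summary_csv
#' @export
write_summary_text <- function(summary, path) {
  df <- as.data.frame(summary)
  lines <- c(sprintf("%-16s %10s %8s %8s %10s %10s %8s", "Variable",
                     "Beta", "SD", "SE", "CI lower", "CI upper", "P"),
             sprintf("%-16s %10.3f %8.3f %8.3f %10.3f %10.3f %8s",
                     df$label, df$mean, df$sd, df$se, df$ci_lower,
                     df$ci_upper, df$p_label))
  writeLines(lines, path)
  invisible(path)
}

#' Kolmogorov-Smirnov residual normality check
#'
#' One-sample KS test of the fitted residuals against a normal
#' distribution with mean and SD estimated from the residuals themselves.
#' With \code{lilliefors = TRUE} the Lilliefors correction (which accounts
#' for the estimated parameters) is used instead, via the \pkg{nortest}
#' package.
#'
#' @param residuals numeric vector of fitted residuals
#'   (\eqn{y_{ij} - x_{ij}'\hat\beta - \hat b_i} at posterior means);
#'   at least 5 values.
#' @param lilliefors use the Lilliefors-corrected test.
#' @return List with \code{statistic} and \code{p_value}.
#' @export
ks_residual_check <- function(residuals, lilliefors = FALSE) {
  if (!is.numeric(residuals) || length(residuals) < 5L)
    stop("need >= 5 residuals", call. = FALSE)
  if (lilliefors) {
    if (!requireNamespace("nortest", quietly = TRUE))
      stop("package `nortest` is required for lilliefors = TRUE",
           call. = FALSE)
    t <- nortest::lillie.test(residuals)
    return(list(statistic = unname(t$statistic),
                p_value = unname(t$p.value)))
  }
  t <- suppressWarnings(
    stats::ks.test(residuals, "pnorm", mean(residuals),
                   stats::sd(residuals)))
  list(statistic = unname(t$statistic), p_value = unname(t$p.value))
}
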