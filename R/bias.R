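## Small-study / publication-bias diagnostics: funnel-plot tables, the
## Begg-Mazumdar rank correlation, and Egger's regression test.

bias_test_result <- function(test, statistic, p, intercept = NA_real_,
                             se_intercept = NA_real_) {
  structure(list(test = test, statistic = statistic, intercept = intercept,
                 se_intercept = se_intercept, p = p),
            class = "bias_test_result")
}

#' @export
print.bias_test_result <- function(x, ...) {
  if (x$test == "begg") {
    cat(sprintf("Begg-Mazumdar rank correlation test: z = %.4f, p = %.4g\n",
                x$statistic, x$p))
  } else {
    cat(sprintf("Egger regression test: intercept = %.4f (SE %.4f), t = %.4f, p = %.4g\n",
                x$intercept, x$se_intercept, x$statistic, x$p))
  }
  invisible(x)
}

#' Funnel-plot table with pseudo 95% confidence limits
#'
#' Per-study (beta, se) points plus the pseudo-limit curves
#' `pooled +/- 1.96 * se` evaluated over the observed se range (from 0 to the
#' largest observed se), around the fixed-effect pooled estimate.
#'
#' @param estimates data frame with columns `beta` and `se`
#' @param n_grid number of se values at which the limits are evaluated
#' @return list with data frames `points` (`study_id, beta, se`) and `limits`
#'   (`se, lower, upper, pooled`)
#' @export
funnel_table <- function(estimates, n_grid = 50L) {
  estimates <- check_estimates(estimates, min_k = 1L)
  pooled <- fixed_effect_meta(estimates)$beta
  if (is.null(estimates$study_id)) {
    estimates$study_id <- sprintf("study_%03d", seq_len(nrow(estimates)))
  }
  se_grid <- seq(0, max(estimates$se), length.out = n_grid)
  list(
    points = estimates[, c("study_id", "beta", "se")],
    limits = data.frame(se = se_grid,
                        lower = pooled - 1.96 * se_grid,
                        upper = pooled + 1.96 * se_grid,
                        pooled = pooled)
  )
}

# Kendall concordant/discordant counts between two vectors (ties contribute
# to neither count).
kendall_counts <- function(a, b) {
  n <- length(a)
  P <- 0L; Qd <- 0L
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- sign(a[j] - a[i]) * sign(b[j] - b[i])
      if (s > 0) P <- P + 1L else if (s < 0) Qd <- Qd + 1L
    }
  }
  c(P = P, Q = Qd)
}

#' Begg-Mazumdar rank correlation test for funnel asymmetry
#'
#' Correlates the variance-standardized deviates
#' `u_i = (beta_i - beta_FE) / sqrt(se_i^2 - se_FE^2)` with the sampling
#' variances `se_i^2` via Kendall's tau, using the normal approximation
#' `z = (P - Q) / sqrt(k (k-1) (2k+5) / 18)` with a continuity correction
#' (1 subtracted from `|P - Q|`). Studies whose variance does not exceed the
#' pooled variance fall back to the uncorrected variance in the deviate, with
#' a warning.
#'
#' @param estimates data frame with columns `beta` and `se` (k >= 3)
#' @return a `bias_test_result` with `test = "begg"`
#' @references Begg CB, Mazumdar M (1994) Biometrics 50:1088-1101.
#' @export
begg_test <- function(estimates) {
  estimates <- check_estimates(estimates, min_k = 3L)
  k <- nrow(estimates)
  fe <- fixed_effect_meta(estimates)
  v <- estimates$se^2
  vstar <- v - fe$se^2
  bad <- vstar <= 0
  if (any(bad)) {
    warning(sprintf("%d study(ies) with variance <= pooled variance; using uncorrected variance for their deviates", sum(bad)))
    vstar[bad] <- v[bad]
  }
  u <- (estimates$beta - fe$beta) / sqrt(vstar)
  cnt <- kendall_counts(u, v)
  s <- as.numeric(cnt["P"] - cnt["Q"])
  denom <- sqrt(k * (k - 1) * (2 * k + 5) / 18)
  z <- if (s == 0) 0 else sign(s) * max(abs(s) - 1, 0) / denom
  bias_test_result("begg", statistic = as.numeric(z), p = z_pvalue(z))
}

#' Egger regression test for funnel asymmetry
#'
#' Ordinary least-squares regression of the standardized effect
#' `beta_i / se_i` on the precision `1 / se_i` (Egger et al. 1997). The
#' intercept estimates the small-study effect; its two-sided t-test has
#' k - 2 df.
#'
#' @param estimates data frame with columns `beta` and `se` (k >= 3, at least
#'   two distinct se values)
#' @return a `bias_test_result` with `test = "egger"` carrying the intercept
#'   and its standard error
#' @export
egger_bias_test <- function(estimates) {
  estimates <- check_estimates(estimates, min_k = 3L)
  if (length(unique(estimates$se)) < 2L) {
    stop("all standard errors are equal: precision has no variance, Egger regression is undefined")
  }
  y <- estimates$beta / estimates$se
  x <- 1 / estimates$se
  fit <- lm(y ~ x)
  sm <- summary(fit)$coefficients
  bias_test_result("egger",
                   statistic = sm[1, "t value"],
                   p = t_pvalue(sm[1, "t value"], df = nrow(estimates) - 2L),
                   intercept = sm[1, "Estimate"],
                   se_intercept = sm[1, "Std. Error"])
}
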