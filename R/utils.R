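## Internal helpers shared across modules.

#' Convert a relative risk and 95% CI to a log-scale standard error
#'
#' Uses the standard Wald back-calculation `se = (log(ci_high) - log(ci_low)) / 3.92`,
#' i.e. the average half-width of the log CI divided by 1.96. When the CI is
#' asymmetric on the log scale (ratio of half-widths > 1.1) a warning is issued;
#' the average half-width is still used.
#'
#' @param rr relative risk (or odds ratio), > 0
#' @param ci_low,ci_high 95% confidence bounds, `0 < ci_low < rr < ci_high`
#' @return standard error of `log(rr)`
#' @examples
#' se_from_ci(1.07, 1.04, 1.10)
#' @export
se_from_ci <- function(rr, ci_low, ci_high) {
  stopifnot(all(ci_low > 0), all(ci_high > ci_low))
  if (any(rr <= ci_low | rr >= ci_high)) {
    stop("point estimate must lie strictly inside its confidence interval")
  }
  up <- log(ci_high) - log(rr)
  lo <- log(rr) - log(ci_low)
  ratio <- pmax(up, lo) / pmin(up, lo)
  if (any(ratio > 1.1)) {
    warning(sprintf(
      "%d confidence interval(s) asymmetric on the log scale (half-width ratio > 1.1); using average half-width",
      sum(ratio > 1.1)
    ))
  }
  (log(ci_high) - log(ci_low)) / 3.92
}

# two-sided normal p-value
z_pvalue <- function(z) 2 * pnorm(-abs(z))

# two-sided t p-value
t_pvalue <- function(t, df) 2 * pt(-abs(t), df = df)

# check a scalar is a single finite number
is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

stop_if_not_number <- function(x, name, positive = FALSE) {
  if (!is_number(x)) stop(sprintf("'%s' must be a single finite number", name))
  if (positive && x <= 0) stop(sprintf("'%s' must be > 0", name))
  invisible(x)
}

# validate a data frame of study estimates (beta, se)
check_estimates <- function(estimates, min_k = 1L) {
  if (is.list(estimates) && !is.data.frame(estimates)) {
    estimates <- as.data.frame(estimates)
  }
  if (!is.data.frame(estimates) || !all(c("beta", "se") %in% names(estimates))) {
    stop("'estimates' must be a data frame with columns 'beta' and 'se'")
  }
  if (nrow(estimates) < min_k) {
    stop(sprintf("at least %d estimate(s) required, got %d", min_k, nrow(estimates)))
  }
  if (any(!is.finite(estimates$beta))) stop("all 'beta' values must be finite")
  if (any(!is.finite(estimates$se) | estimates$se <= 0)) stop("all 'se' values must be positive")
  estimates
}
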