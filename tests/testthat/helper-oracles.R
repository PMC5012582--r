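# Independent oracles and fixture builders used across the suite.
# These deliberately avoid the implementation paths they are checking.

# weighted least squares through the origin: beta and se
wls_origin_oracle <- function(x, y, w) {
  beta <- sum(w * x * y) / sum(w * x^2)
  list(beta = beta, se = sqrt(1 / sum(w * x^2)))
}

# weighted least squares with intercept via explicit normal equations
wls_intercept_oracle <- function(x, y, w) {
  X <- cbind(1, x)
  XtWX <- t(X) %*% (w * X)
  coefs <- solve(XtWX, t(X) %*% (w * y))
  resid <- y - X %*% coefs
  s2 <- sum(w * resid^2) / (length(y) - 2)
  covb <- s2 * solve(XtWX)
  list(intercept = coefs[1], slope = coefs[2],
       se_intercept = sqrt(covb[1, 1]), se_slope = sqrt(covb[2, 2]))
}

# dense grid search maximizing the restricted log-likelihood over tau2
reml_grid_oracle <- function(beta, se, upper = 1, n_grid = 2001L) {
  v <- se^2
  ll <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * beta) / sum(w)
    -0.5 * sum(log(v + tau2)) - 0.5 * log(sum(w)) - 0.5 * sum(w * (beta - mu)^2)
  }
  grid <- seq(0, upper, length.out = n_grid)
  best <- grid[which.max(vapply(grid, ll, numeric(1)))]
  # refine around the best grid point
  opt <- optimize(ll, interval = c(max(0, best - upper / n_grid),
                                   min(upper, best + upper / n_grid)),
                  maximum = TRUE, tol = 1e-10)
  opt$maximum
}

# all permutations of a vector (for exact Kendall permutation nulls)
permutations_of <- function(x) {
  if (length(x) == 1L) return(list(x))
  out <- list()
  for (i in seq_along(x)) {
    for (rest in permutations_of(x[-i])) out <- c(out, list(c(x[i], rest)))
  }
  out
}

kendall_s_oracle <- function(a, b) {
  s <- 0L
  n <- length(a)
  for (i in seq_len(n - 1L)) {
    for (j in (i + 1L):n) {
      s <- s + sign(a[j] - a[i]) * sign(b[j] - b[i])
    }
  }
  s
}

# five-study table reused across meta-analysis and bias tests
five_study_fixture <- function() {
  data.frame(
    study_id = paste0("s", 1:5),
    beta = c(0.05, 0.12, -0.02, 0.20, 0.09),
    se = c(0.03, 0.08, 0.05, 0.12, 0.04),
    stringsAsFactors = FALSE
  )
}

# small categorical study (cumulative incidence) with internally consistent
# crude RRs so the pseudo-count fit has a known fixed point
crude_categorical_fixture <- function() {
  n_cases <- c(40, 55, 75)
  n_total <- c(1000, 1000, 1000)
  risk <- n_cases / n_total
  rr <- risk / risk[1]
  se <- sqrt(1 / n_cases - 1 / n_total + 1 / n_cases[1] - 1 / n_total[1])
  categorical_study(
    study_id = "crude_toy", design = "cumulative_incidence",
    levels = data.frame(
      lower_cm = c(150, 160, 170), upper_cm = c(160, 170, 180),
      score_cm = NA_real_, n_cases = n_cases, n_total = n_total,
      rr = c(1, rr[2:3]),
      ci_low = c(NA, (rr * exp(-1.96 * se))[2:3]),
      ci_high = c(NA, (rr * exp(1.96 * se))[2:3]),
      is_reference = c(TRUE, FALSE, FALSE)
    )
  )
}

# categorical study whose adjusted RRs differ from the crude ones
adjusted_categorical_fixture <- function(design = "cumulative_incidence") {
  rr <- c(1, 1.25, 1.62)
  se <- c(NA, 0.12, 0.14)
  lv <- data.frame(
    lower_cm = c(150, 160, 170), upper_cm = c(160, 170, 180),
    score_cm = NA_real_,
    n_cases = c(42, 58, 71), n_total = c(1100, 980, 1040),
    rr = rr,
    ci_low = c(NA, rr[2] * exp(-1.96 * se[2]), rr[3] * exp(-1.96 * se[3])),
    ci_high = c(NA, rr[2] * exp(1.96 * se[2]), rr[3] * exp(1.96 * se[3])),
    is_reference = c(TRUE, FALSE, FALSE)
  )
  if (design == "incidence_rate") lv$person_time <- lv$n_total * 8.3
  categorical_study(study_id = "adj_toy", design = design, levels = lv)
}

# bisection over the reference pseudo-cell: an independent root-finder for
# the pseudo-count margin equation (cumulative-incidence design)
gl_bisection_oracle <- function(study, tol = 1e-6) {
  lv <- study$levels
  ref <- which(lv$is_reference)
  nonref <- which(!lv$is_reference)
  a_total <- sum(lv$n_cases)
  f <- function(a0) {
    a0 + sum(lv$rr[nonref] * lv$n_total[nonref] * a0 / lv$n_total[ref]) - a_total
  }
  lo <- 1e-9
  hi <- lv$n_total[ref] - 1e-9
  while (hi - lo > tol / 10) {
    mid <- (lo + hi) / 2
    if (f(mid) > 0) hi <- mid else lo <- mid
  }
  (lo + hi) / 2
}

# simple 3-SNP instrument with hand-set numbers
three_snp_instrument <- function() {
  exposure <- data.frame(
    snp = c("rs1", "rs2", "rs3"),
    effect_allele = c("A", "T", "A"), other_allele = c("G", "C", "C"),
    eaf = c(0.3, 0.4, 0.2), beta = c(0.10, 0.15, 0.08),
    se = c(0.01, 0.012, 0.011), pval = c(1e-20, 1e-25, 1e-12),
    info = c(0.99, 0.95, 0.98), stringsAsFactors = FALSE
  )
  outcome <- exposure
  outcome$beta <- c(0.02, 0.035, 0.01)
  outcome$se <- c(0.010, 0.015, 0.012)
  harmonize(exposure, outcome)
}
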