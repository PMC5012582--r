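## Inverse-variance-weighted pooling of per-study log-RR estimates:
## fixed-effect and REML random-effects models, Cochran's Q, I^2, and a
## Q-between test of subgroup homogeneity.

meta_result <- function(model, beta, se, k, Q = NA_real_, df = NA_integer_,
                        p_Q = NA_real_, tau2 = 0, i2 = NA_real_) {
  structure(list(
    model = model, beta = beta, se = se,
    ci_low = exp(beta - 1.96 * se), ci_high = exp(beta + 1.96 * se),
    k = k, Q = Q, df = df, p_Q = p_Q, tau2 = tau2, i2 = i2
  ), class = "meta_result")
}

#' @export
print.meta_result <- function(x, ...) {
  cat(sprintf("%s-effect meta-analysis of %d studies\n",
              if (x$model == "fixed") "Fixed" else "Random", x$k))
  cat(sprintf("  RR %.4f (95%% CI %.4f, %.4f); log-RR %.5f (SE %.5f)\n",
              exp(x$beta), x$ci_low, x$ci_high, x$beta, x$se))
  if (!is.na(x$Q)) {
    cat(sprintf("  Q = %.4f (df = %d, p = %.4g); tau2 = %.5f; I2 = %.1f%%\n",
                x$Q, x$df, x$p_Q, x$tau2, 100 * x$i2))
  }
  invisible(x)
}

#' Fixed-effect inverse-variance-weighted meta-analysis
#'
#' Pools estimates with weights `w_i = 1 / se_i^2`:
#' `beta = sum(w b) / sum(w)`, `se = 1 / sqrt(sum(w))`. With k >= 2 the
#' heterogeneity statistics Q, p and I^2 are attached.
#'
#' @param estimates data frame with columns `beta` (log-RR) and `se`
#' @return a `meta_result` with `model = "fixed"` and `tau2 = 0`
#' @examples
#' fixed_effect_meta(data.frame(beta = c(0.1, 0.1), se = c(0.05, 0.05)))
#' @export
fixed_effect_meta <- function(estimates) {
  estimates <- check_estimates(estimates, min_k = 1L)
  w <- 1 / estimates$se^2
  beta <- sum(w * estimates$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  k <- nrow(estimates)
  if (k >= 2L) {
    q <- cochran_q(estimates)
    i2 <- max(0, (q$Q - q$df) / q$Q)
    if (q$Q == 0) i2 <- 0
    meta_result("fixed", beta, se, k, q$Q, q$df, q$p, tau2 = 0, i2 = i2)
  } else {
    meta_result("fixed", beta, se, k)
  }
}

#' Cochran's Q test of homogeneity
#'
#' `Q = sum(w_i (beta_i - beta_FE)^2)` with fixed-effect weights
#' `w_i = 1/se_i^2`; under homogeneity Q is chi-square with k - 1 df.
#'
#' @param estimates data frame with columns `beta` and `se` (k >= 2)
#' @return list with `Q`, `df`, and upper-tail `p`
#' @export
cochran_q <- function(estimates) {
  estimates <- check_estimates(estimates, min_k = 2L)
  w <- 1 / estimates$se^2
  beta_fe <- sum(w * estimates$beta) / sum(w)
  Q <- sum(w * (estimates$beta - beta_fe)^2)
  df <- nrow(estimates) - 1L
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE))
}

#' Restricted maximum-likelihood estimate of between-study variance
#'
#' Maximizes the restricted log-likelihood
#' `l_R(tau2) = -1/2 sum(log(se^2 + tau2)) - 1/2 log(sum(1/(se^2 + tau2)))
#'  - 1/2 sum((beta - mu(tau2))^2 / (se^2 + tau2))`
#' over `tau2 >= 0` by Fisher scoring with step-halving; the boundary
#' solution `tau2 = 0` is returned when the score at zero is non-positive.
#'
#' @param estimates data frame with columns `beta` and `se` (k >= 2)
#' @param tol convergence tolerance on tau2
#' @param max_iter maximum scoring iterations
#' @return the REML tau2 estimate, with attributes `iterations` and
#'   `converged`
#' @export
reml_tau2 <- function(estimates, tol = 1e-8, max_iter = 100L) {
  estimates <- check_estimates(estimates, min_k = 2L)
  b <- estimates$beta
  v <- estimates$se^2

  score <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * b) / sum(w)
    r2 <- (b - mu)^2
    -0.5 * sum(w) + 0.5 * sum(w^2) / sum(w) + 0.5 * sum(w^2 * r2)
  }
  restricted_ll <- function(tau2) {
    w <- 1 / (v + tau2)
    mu <- sum(w * b) / sum(w)
    -0.5 * sum(log(v + tau2)) - 0.5 * log(sum(w)) - 0.5 * sum(w * (b - mu)^2)
  }

  if (score(0) <= 0) {
    return(structure(0, iterations = 0L, converged = TRUE))
  }
  tau2 <- max(var(b) - mean(v), 1e-6)  # moment start
  iter <- 0L
  converged <- FALSE
  while (iter < max_iter) {
    iter <- iter + 1L
    w <- 1 / (v + tau2)
    s1 <- sum(w); s2 <- sum(w^2); s3 <- sum(w^3)
    info <- 0.5 * (s2 - 2 * s3 / s1 + (s2 / s1)^2)
    step <- score(tau2) / info
    tau2_new <- tau2 + step
    ll_old <- restricted_ll(tau2)
    halvings <- 0L
    while ((tau2_new < 0 || restricted_ll(tau2_new) < ll_old) && halvings < 50L) {
      step <- step / 2
      tau2_new <- tau2 + step
      halvings <- halvings + 1L
    }
    tau2_new <- max(tau2_new, 0)
    if (abs(tau2_new - tau2) < tol) {
      tau2 <- tau2_new
      converged <- TRUE
      break
    }
    tau2 <- tau2_new
  }
  if (!converged) {
    stop(sprintf("REML did not converge in %d iterations; last tau2 = %.8g", max_iter, tau2))
  }
  structure(tau2, iterations = iter, converged = TRUE)
}

#' Random-effects meta-analysis with REML between-study variance
#'
#' Applies the inverse-variance formulas with weights
#' `w_i = 1 / (se_i^2 + tau2_REML)`. Q, p and I^2 are computed from the
#' fixed-effect weights. By default confidence limits are Wald normal;
#' `knha = TRUE` switches to Knapp-Hartung t-based limits.
#'
#' @param estimates data frame with columns `beta` and `se` (k >= 2)
#' @param knha use the Knapp-Hartung adjustment (t quantiles and scaled se)
#' @return a `meta_result` with `model = "random"`
#' @export
random_effects_meta <- function(estimates, knha = FALSE) {
  estimates <- check_estimates(estimates, min_k = 2L)
  tau2 <- as.numeric(reml_tau2(estimates))
  w <- 1 / (estimates$se^2 + tau2)
  beta <- sum(w * estimates$beta) / sum(w)
  se <- sqrt(1 / sum(w))
  k <- nrow(estimates)
  q <- cochran_q(estimates)
  i2 <- if (q$Q > 0) max(0, (q$Q - q$df) / q$Q) else 0
  res <- meta_result("random", beta, se, k, q$Q, q$df, q$p, tau2 = tau2, i2 = i2)
  if (knha) {
    s2 <- sum(w * (estimates$beta - beta)^2) / ((k - 1) * sum(w))
    res$se <- sqrt(s2)
    tq <- stats::qt(0.975, df = k - 1)
    res$ci_low <- exp(beta - tq * res$se)
    res$ci_high <- exp(beta + tq * res$se)
  }
  res
}

#' Q-between test of subgroup homogeneity
#'
#' Treats each subgroup's pooled estimate as a single observation and tests
#' whether the subgroup means are equal:
#' `Q_between = sum(w_j (beta_j - beta_bar)^2)` with `w_j = 1/se_j^2` and
#' `beta_bar` their inverse-variance mean; chi-square with J - 1 df.
#'
#' @param beta vector of subgroup (meta-analytic or MR) point estimates on the
#'   log scale
#' @param se their standard errors
#' @return list with `Q`, `df`, and `p`
#' @examples
#' subgroup_homogeneity(c(0.05, 0.10), c(0.02, 0.02))
#' @export
subgroup_homogeneity <- function(beta, se) {
  if (length(beta) != length(se)) stop("'beta' and 'se' must have equal length")
  if (length(beta) < 2L) stop("at least 2 subgroup estimates required")
  if (any(!is.finite(beta)) || any(!is.finite(se) | se <= 0)) {
    stop("subgroup estimates must be finite with positive se")
  }
  w <- 1 / se^2
  bbar <- sum(w * beta) / sum(w)
  Q <- sum(w * (beta - bbar)^2)
  df <- length(beta) - 1L
  list(Q = Q, df = df, p = pchisq(Q, df, lower.tail = FALSE))
}

#' Plot-ready forest table
#'
#' One row per study (RR, 95% CI, percentage weight within its block) plus a
#' summary row per block. With `by` given, studies are grouped by that stratum
#' column and an overall summary row is appended.
#'
#' @param estimates data frame with `study_id`, `beta`, `se`, and any stratum
#'   columns
#' @param model `"random"` or `"fixed"`: the pooling model for summary rows
#'   and the weighting used for the weight column
#' @param by optional name of a stratum column to group by
#' @return data frame with columns `block, row_type, label, rr, ci_low,
#'   ci_high, weight_pct`
#' @export
forest_table <- function(estimates, model = c("random", "fixed"), by = NULL) {
  model <- match.arg(model)
  estimates <- check_estimates(estimates, min_k = 1L)
  if (is.null(estimates$study_id)) {
    estimates$study_id <- sprintf("study_%03d", seq_len(nrow(estimates)))
  }
  pool <- function(d) {
    if (model == "random" && nrow(d) >= 2L) random_effects_meta(d) else fixed_effect_meta(d)
  }
  block_rows <- function(d, block) {
    m <- pool(d)
    w <- 1 / (d$se^2 + m$tau2)
    w <- 100 * w / sum(w)
    rbind(
      data.frame(block = block, row_type = "study", label = d$study_id,
                 rr = exp(d$beta), ci_low = exp(d$beta - 1.96 * d$se),
                 ci_high = exp(d$beta + 1.96 * d$se), weight_pct = w,
                 stringsAsFactors = FALSE),
      data.frame(block = block, row_type = "summary",
                 label = sprintf("%s-effect summary", m$model),
                 rr = exp(m$beta), ci_low = m$ci_low, ci_high = m$ci_high,
                 weight_pct = 100, stringsAsFactors = FALSE)
    )
  }
  if (is.null(by)) {
    block_rows(estimates, "all")
  } else {
    if (!by %in% names(estimates)) stop(sprintf("stratum column '%s' not found", by))
    groups <- split(estimates, estimates[[by]])
    out <- do.call(rbind, lapply(names(groups), function(g) block_rows(groups[[g]], g)))
    rbind(out, block_rows(estimates, "overall"))
  }
}
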