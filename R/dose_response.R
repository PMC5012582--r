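## Greenland-Longnecker conversion of per-quantile relative risks to a
## continuous linear trend: quantile scores, pseudo-counts matching the
## adjusted RRs and the observed margins, the implied covariance among
## level-vs-reference contrasts, and the GLS trend through the reference.

#' Construct a categorical (per-quantile) study
#'
#' @param study_id study identifier
#' @param design one of `"incidence_rate"` (person-time denominators),
#'   `"cumulative_incidence"` (risk ratios from counts), `"case_control"`
#'   (odds ratios)
#' @param levels data frame, one row per ordered exposure category, with
#'   columns `lower_cm, upper_cm` (either bound may be `NA`/`Inf` = open),
#'   optional `score_cm`, `n_cases`, `n_total` (or `person_time` for
#'   incidence-rate designs), `rr, ci_low, ci_high` (95% CI; `rr = 1` and CI
#'   absent at the reference), and logical `is_reference`
#' @param strata optional named list of stratum labels (sex, cancer site, ...)
#' @return object of class `categorical_study`
#' @export
categorical_study <- function(study_id, design = c("cumulative_incidence", "incidence_rate", "case_control"),
                              levels, strata = list()) {
  design <- match.arg(design)
  if (!is.data.frame(levels) || nrow(levels) < 2L) {
    stop("'levels' must be a data frame with at least 2 rows")
  }
  required <- c("rr", "is_reference")
  missing_cols <- setdiff(required, names(levels))
  if (length(missing_cols)) stop("missing level columns: ", paste(missing_cols, collapse = ", "))
  if (!"score_cm" %in% names(levels)) levels$score_cm <- NA_real_
  if (!"lower_cm" %in% names(levels)) levels$lower_cm <- NA_real_
  if (!"upper_cm" %in% names(levels)) levels$upper_cm <- NA_real_
  if (sum(levels$is_reference) != 1L) stop("exactly one reference level is required")
  ref <- which(levels$is_reference)
  if (abs(levels$rr[ref] - 1) > 1e-12) stop("reference level must have rr = 1")
  nonref <- which(!levels$is_reference)
  if (!all(c("ci_low", "ci_high") %in% names(levels))) {
    stop("levels must carry 'ci_low' and 'ci_high'")
  }
  bad <- nonref[!(levels$ci_low[nonref] < levels$rr[nonref] &
                    levels$rr[nonref] < levels$ci_high[nonref])]
  if (length(bad)) {
    stop("ci_low < rr < ci_high violated at level(s) ", paste(bad, collapse = ", "))
  }
  lo <- levels$lower_cm
  up <- levels$upper_cm
  lo[!is.finite(lo)] <- NA_real_
  up[!is.finite(up)] <- NA_real_
  known <- stats::na.omit(as.vector(rbind(lo, up)))
  if (length(known) > 1 && any(diff(known) < -1e-9)) {
    stop("category bounds must be non-decreasing across ordered levels")
  }
  if (design == "incidence_rate") {
    if (!all(c("n_cases", "person_time") %in% names(levels))) {
      stop("incidence_rate design requires 'n_cases' and 'person_time'")
    }
  }
  structure(list(study_id = study_id, design = design, levels = levels,
                 strata = strata),
            class = "categorical_study")
}

#' @export
print.categorical_study <- function(x, ...) {
  cat(sprintf("Categorical study '%s' (%s design, %d levels)\n",
              x$study_id, x$design, nrow(x$levels)))
  print(x$levels, digits = 4)
  invisible(x)
}

#' Assign exposure scores to quantile categories
#'
#' Supplied scores (category means or medians) are used verbatim. Closed
#' intervals without a supplied score get their midpoint. An open-ended
#' extreme interval gets its closed boundary plus/minus half the width of the
#' adjacent closed interval (Il'yasova et al. 2005): an upper-open category
#' scores `lower + w/2`, a lower-open category `upper - w/2`.
#'
#' @param study a [categorical_study()]
#' @param method `"given"` keeps supplied scores and fills only missing ones;
#'   `"midpoint"` recomputes every score from the interval bounds
#' @return the study with `score_cm` filled on every level
#' @export
assign_scores <- function(study, method = c("given", "midpoint")) {
  method <- match.arg(method)
  lv <- study$levels
  n <- nrow(lv)
  lo <- lv$lower_cm
  up <- lv$upper_cm
  lo[!is.finite(lo)] <- NA_real_
  up[!is.finite(up)] <- NA_real_
  open_low <- is.na(lo)
  open_up <- is.na(up)
  if (any(open_low & open_up)) stop("interval open at both ends has no usable bounds")

  scores <- lv$score_cm
  if (method == "midpoint") scores <- rep(NA_real_, n)

  width <- up - lo  # NA for open intervals
  for (i in seq_len(n)) {
    if (!is.na(scores[i])) next
    if (!open_low[i] && !open_up[i]) {
      scores[i] <- (lo[i] + up[i]) / 2
    } else if (open_up[i]) {
      j <- i - 1L
      if (j < 1L || is.na(width[j])) {
        stop("open-ended upper interval adjacent to another open interval: no width available")
      }
      scores[i] <- lo[i] + width[j] / 2
    } else {
      j <- i + 1L
      if (j > n || is.na(width[j])) {
        stop("open-ended lower interval adjacent to another open interval: no width available")
      }
      scores[i] <- up[i] - width[j] / 2
    }
  }
  study$levels$score_cm <- scores
  study
}

# Per-design map from the reference pseudo-count a0 to the non-reference
# pseudo cases that reproduce the adjusted RRs exactly.
gl_cells_given_ref <- function(a0, r, denom, denom0, design) {
  switch(design,
    incidence_rate = r * denom * a0 / denom0,
    cumulative_incidence = r * denom * a0 / denom0,
    case_control = {
      z <- a0 / (denom0 - a0)
      denom * r * z / (1 + r * z)
    }
  )
}

#' Fit Greenland-Longnecker pseudo-counts
#'
#' Finds per-level pseudo case counts such that (i) crude level-vs-reference
#' effect measures computed from the pseudo table equal the published adjusted
#' RRs, and (ii) the total number of cases and the per-level denominators
#' match the observed margins exactly. Solved by damped Newton iteration on
#' the reference-cell pseudo count (Greenland & Longnecker 1992).
#'
#' @param study a [categorical_study()] with counts on every level
#' @param tol convergence tolerance on the cases margin equation
#' @param max_iter maximum Newton iterations
#' @return data frame with per-level pseudo cases `A`, pseudo non-cases or
#'   person time `B`, and denominators `N`
#' @export
gl_pseudo_counts <- function(study, tol = 1e-10, max_iter = 100L) {
  lv <- study$levels
  design <- study$design
  denom <- if (design == "incidence_rate") lv$person_time else lv$n_total
  if (is.null(denom) || any(!is.finite(denom) | denom <= 0)) {
    stop("per-level denominators (n_total or person_time) required and positive")
  }
  if (is.null(lv$n_cases) || any(!is.finite(lv$n_cases) | lv$n_cases <= 0)) {
    stop("per-level case counts required and positive")
  }
  ref <- which(lv$is_reference)
  nonref <- which(!lv$is_reference)
  r <- lv$rr[nonref]
  a_total <- sum(lv$n_cases)
  denom0 <- denom[ref]

  upper_a0 <- if (design == "incidence_rate") Inf else denom0
  a0 <- min(lv$n_cases[ref], if (is.finite(upper_a0)) 0.9 * upper_a0 else Inf)

  f <- function(a0) a0 + sum(gl_cells_given_ref(a0, r, denom[nonref], denom0, design)) - a_total
  converged <- FALSE
  for (iter in seq_len(max_iter)) {
    fv <- f(a0)
    if (abs(fv) < tol) { converged <- TRUE; break }
    eps <- max(1e-6, abs(a0) * 1e-7)
    deriv <- (f(a0 + eps) - f(a0 - eps)) / (2 * eps)
    step <- fv / deriv
    a0_new <- a0 - step
    # damp steps that would leave the admissible interval
    while (a0_new <= 0 || a0_new >= upper_a0) {
      step <- step / 2
      a0_new <- a0 - step
      if (abs(step) < .Machine$double.eps * max(1, abs(a0))) break
    }
    a0 <- a0_new
  }
  if (!converged && abs(f(a0)) >= tol) {
    stop(sprintf("pseudo-count fit did not converge in %d iterations (last a0 = %.6g, margin residual = %.3g)",
                 max_iter, a0, f(a0)))
  }

  a <- numeric(nrow(lv))
  a[ref] <- a0
  a[nonref] <- gl_cells_given_ref(a0, r, denom[nonref], denom0, design)
  b <- denom - a  # person-time is left untouched for rate designs
  if (design == "incidence_rate") b <- denom
  bad <- which(a <= 0 | (design != "incidence_rate" & b <= 0))
  if (length(bad)) {
    stop("negative or zero fitted pseudo-count at level(s) ", paste(bad, collapse = ", "),
         "; the published numbers are mutually inconsistent")
  }
  data.frame(A = a, B = b, N = denom, is_reference = lv$is_reference)
}

#' Covariance of the non-reference log relative risks
#'
#' Applies the design-specific Greenland-Longnecker formulas to the fitted
#' pseudo-counts. With pseudo cases A (and pseudo non-cases B, denominators N;
#' subscript 0 the reference):
#' incidence rate `var = 1/A_i + 1/A_0`, `cov = 1/A_0`;
#' cumulative incidence `var = 1/A_i - 1/N_i + 1/A_0 - 1/N_0`,
#' `cov = 1/A_0 - 1/N_0`;
#' case-control `var = 1/A_i + 1/B_i + 1/A_0 + 1/B_0`, `cov = 1/A_0 + 1/B_0`.
#'
#' @param study a [categorical_study()]
#' @param pseudo output of [gl_pseudo_counts()]
#' @return symmetric positive-definite covariance matrix, one row/column per
#'   non-reference level
#' @export
gl_covariance <- function(study, pseudo) {
  ref <- which(pseudo$is_reference)
  nonref <- which(!pseudo$is_reference)
  A <- pseudo$A
  B <- pseudo$B
  N <- pseudo$N
  cov0 <- switch(study$design,
    incidence_rate = 1 / A[ref],
    cumulative_incidence = 1 / A[ref] - 1 / N[ref],
    case_control = 1 / A[ref] + 1 / B[ref]
  )
  var_i <- switch(study$design,
    incidence_rate = 1 / A[nonref] + 1 / A[ref],
    cumulative_incidence = 1 / A[nonref] - 1 / N[nonref] + 1 / A[ref] - 1 / N[ref],
    case_control = 1 / A[nonref] + 1 / B[nonref] + 1 / A[ref] + 1 / B[ref]
  )
  m <- matrix(cov0, length(nonref), length(nonref))
  diag(m) <- var_i
  ev <- eigen(m, symmetric = TRUE, only.values = TRUE)$values
  if (any(ev <= 0)) {
    stop("covariance matrix is not positive definite; the published numbers are mutually inconsistent")
  }
  m
}

#' Generalized-least-squares linear trend through the reference point
#'
#' Regresses the non-reference adjusted log-RRs on the score contrasts
#' `x_i = score_i - score_ref` with no intercept:
#' `beta = (x' C^-1 y) / (x' C^-1 x)`, `se = sqrt(1 / (x' C^-1 x))`.
#' When no covariance is supplied the level estimates are treated as
#' independent with variances back-calculated from their published CIs
#' (`method = "independence_fallback"`); because the contrasts share the
#' reference group this understates the standard error, so a warning is
#' issued.
#'
#' @param study a score-assigned [categorical_study()]
#' @param covariance covariance matrix from [gl_covariance()], or `NULL` for
#'   the independence fallback
#' @return object of class `trend_estimate`: log-RR per cm (`unit_cm = 1`)
#'   with its standard error
#' @export
gls_trend <- function(study, covariance = NULL) {
  lv <- study$levels
  if (any(is.na(lv$score_cm))) stop("scores not assigned; call assign_scores() first")
  ref <- which(lv$is_reference)
  nonref <- which(!lv$is_reference)
  x <- lv$score_cm[nonref] - lv$score_cm[ref]
  y <- log(lv$rr[nonref])
  if (max(abs(x - x[1])) < 1e-12 && length(x) > 1) {
    stop("all score contrasts are equal: no exposure contrast to estimate a trend from")
  }
  if (all(abs(x) < 1e-12)) stop("score contrasts are all zero")
  if (is.null(covariance)) {
    warning("no covariance supplied; falling back to independent variance-weighted least squares")
    v <- se_from_ci(lv$rr[nonref], lv$ci_low[nonref], lv$ci_high[nonref])^2
    covariance <- diag(v, nrow = length(v))
    method <- "independence_fallback"
  } else {
    method <- "gl"
  }
  ci_x <- solve(covariance, x)
  xtcx <- sum(x * ci_x)
  beta <- sum(ci_x * y) / xtcx
  se <- sqrt(1 / xtcx)
  structure(list(beta = beta, se = se, unit_cm = 1,
                 n_levels_used = length(nonref) + 1L, method = method),
            class = "trend_estimate")
}

#' @export
print.trend_estimate <- function(x, ...) {
  cat(sprintf("Linear trend (%s): log-RR %.5f (SE %.5f) per %g cm\n",
              x$method, x$beta, x$se, x$unit_cm))
  rr10 <- rescale_estimate(x, 10)
  cat(sprintf("  RR per 10 cm: %.4f (95%% CI %.4f, %.4f)\n",
              exp(rr10$beta), exp(rr10$beta - 1.96 * rr10$se),
              exp(rr10$beta + 1.96 * rr10$se)))
  invisible(x)
}

#' Rescale a trend estimate to a different exposure unit
#'
#' Multiplies the log-effect and its standard error by
#' `target_unit_cm / unit_cm`, e.g. from per-cm to per-10-cm.
#'
#' @param estimate a `trend_estimate`
#' @param target_unit_cm positive exposure increment the estimate should refer to
#' @return the rescaled `trend_estimate`
#' @export
rescale_estimate <- function(estimate, target_unit_cm) {
  if (!inherits(estimate, "trend_estimate")) stop("'estimate' must be a trend_estimate")
  if (is.null(estimate$unit_cm) || !is_number(estimate$unit_cm) || estimate$unit_cm <= 0) {
    stop("source exposure unit unknown or non-positive")
  }
  stop_if_not_number(target_unit_cm, "target_unit_cm", positive = TRUE)
  f <- target_unit_cm / estimate$unit_cm
  estimate$beta <- estimate$beta * f
  estimate$se <- estimate$se * f
  estimate$unit_cm <- target_unit_cm
  estimate
}

#' One-call Greenland-Longnecker trend for a categorical study
#'
#' Convenience wrapper: assigns scores, fits pseudo-counts and their
#' covariance, runs the GLS trend, and rescales to the requested unit. Falls
#' back to independent weighted least squares when counts are unavailable.
#'
#' @param study a [categorical_study()]
#' @param unit_cm exposure increment of the returned estimate (default 10 cm)
#' @param scores score policy passed to [assign_scores()]
#' @return a `trend_estimate`
#' @export
gl_trend <- function(study, unit_cm = 10, scores = "given") {
  study <- assign_scores(study, method = scores)
  has_counts <- !is.null(study$levels$n_cases) &&
    all(is.finite(study$levels$n_cases)) &&
    (study$design == "incidence_rate" ||
       (!is.null(study$levels$n_total) && all(is.finite(study$levels$n_total))))
  est <- if (has_counts) {
    pseudo <- gl_pseudo_counts(study)
    gls_trend(study, gl_covariance(study, pseudo))
  } else {
    gls_trend(study, covariance = NULL)
  }
  rescale_estimate(est, unit_cm)
}
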