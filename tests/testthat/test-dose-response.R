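test_that("categorical_study validates its levels", {
  lv <- data.frame(lower_cm = c(150, 160), upper_cm = c(160, 170),
                   rr = c(1, 1.2), ci_low = c(NA, 1.05), ci_high = c(NA, 1.4),
                   is_reference = c(TRUE, FALSE))
  expect_s3_class(categorical_study("ok", "cumulative_incidence", lv),
                  "categorical_study")
  bad <- lv; bad$is_reference <- c(TRUE, TRUE)
  expect_error(categorical_study("x", "cumulative_incidence", bad),
               "exactly one reference")
  bad <- lv; bad$ci_low[2] <- 1.3
  expect_error(categorical_study("x", "cumulative_incidence", bad),
               "ci_low < rr < ci_high")
  bad <- lv; bad$lower_cm <- c(170, 150); bad$upper_cm <- c(180, 160)
  expect_error(categorical_study("x", "cumulative_incidence", bad),
               "non-decreasing")
})

test_that("score assignment: midpoints, supplied values, and open-end rule", {
  lv <- data.frame(
    lower_cm = c(NA, 160, 170, 180), upper_cm = c(160, 170, 180, NA),
    score_cm = c(NA, 165, NA, NA),
    rr = c(1, 1.1, 1.2, 1.3),
    ci_low = c(NA, 1.01, 1.05, 1.1), ci_high = c(NA, 1.25, 1.4, 1.55),
    is_reference = c(TRUE, FALSE, FALSE, FALSE)
  )
  st <- categorical_study("s", "cumulative_incidence", lv)
  scored <- assign_scores(st, method = "given")
  # supplied value kept verbatim; closed interval -> midpoint;
  # open ends -> boundary -/+ half the adjacent closed width
  expect_equal(scored$levels$score_cm, c(155, 165, 175, 185))

  # midpoint method ignores the supplied score
  scored2 <- assign_scores(st, method = "midpoint")
  expect_equal(scored2$levels$score_cm, c(155, 165, 175, 185))

  both_open <- lv
  both_open$lower_cm <- c(NA, NA, 170, 180)
  both_open$upper_cm <- c(NA, 170, 180, NA)
  st2 <- categorical_study("s2", "cumulative_incidence", both_open)
  expect_error(assign_scores(st2, "midpoint"), "open")
})

test_that("pseudo-counts reproduce adjusted RRs and margins across designs", {
  for (design in c("cumulative_incidence", "incidence_rate", "case_control")) {
    st <- adjusted_categorical_fixture(design)
    pseudo <- gl_pseudo_counts(st)
    lv <- st$levels
    # margins preserved exactly
    expect_equal(sum(pseudo$A), sum(lv$n_cases), tolerance = 1e-9)
    denom <- if (design == "incidence_rate") lv$person_time else lv$n_total
    expect_equal(pseudo$N, denom)
    # crude effect measures from the pseudo table equal the adjusted RRs
    crude <- switch(design,
      cumulative_incidence = (pseudo$A / pseudo$N) / (pseudo$A[1] / pseudo$N[1]),
      incidence_rate = (pseudo$A / pseudo$B) / (pseudo$A[1] / pseudo$B[1]),
      case_control = (pseudo$A / pseudo$B) / (pseudo$A[1] / pseudo$B[1])
    )
    expect_equal(log(crude[-1]), log(lv$rr[-1]), tolerance = 1e-8)
  }
})

test_that("a study whose adjusted RRs equal its crude RRs is a fixed point", {
  st <- crude_categorical_fixture()
  pseudo <- gl_pseudo_counts(st)
  expect_equal(pseudo$A, st$levels$n_cases, tolerance = 1e-8)
  expect_equal(pseudo$B, st$levels$n_total - st$levels$n_cases, tolerance = 1e-8)
})

test_that("pseudo-count fit matches an independent bisection oracle", {
  st <- adjusted_categorical_fixture("cumulative_incidence")
  pseudo <- gl_pseudo_counts(st)
  a0_oracle <- gl_bisection_oracle(st)
  expect_equal(pseudo$A[1], a0_oracle, tolerance = 1e-6)
})

test_that("inconsistent published numbers are flagged", {
  # near-saturated counts with RR 1.6 force a fitted pseudo risk above 1
  st <- categorical_study("bad", "cumulative_incidence", data.frame(
    lower_cm = c(150, 160), upper_cm = c(160, 170), score_cm = c(155, 165),
    n_cases = c(95, 99), n_total = c(100, 100),
    rr = c(1, 1.6), ci_low = c(NA, 1.2), ci_high = c(NA, 2.1),
    is_reference = c(TRUE, FALSE)))
  expect_error(gl_pseudo_counts(st), "level")
})

test_that("covariance matches design formulas, CIs, and limiting behaviour", {
  st <- adjusted_categorical_fixture("cumulative_incidence")
  pseudo <- gl_pseudo_counts(st)
  covm <- gl_covariance(st, pseudo)
  expect_true(isSymmetric(covm))
  expect_true(all(eigen(covm, symmetric = TRUE)$values > 0))
  expect_equal(covm[1, 2], 1 / pseudo$A[1] - 1 / pseudo$N[1])
  expect_equal(covm[1, 1],
               1 / pseudo$A[2] - 1 / pseudo$N[2] + 1 / pseudo$A[1] - 1 / pseudo$N[1])

  # on well-behaved simulated data the diagonal tracks the published CIs
  sim <- simulate_cohort_study(cohort_sim_config(n_subjects = 200000, seed = 31))
  ps <- gl_pseudo_counts(sim)
  cv <- gl_covariance(sim, ps)
  lv <- sim$levels
  nonref <- which(!lv$is_reference)
  v_ci <- se_from_ci(lv$rr[nonref], lv$ci_low[nonref], lv$ci_high[nonref])^2
  expect_equal(diag(cv), v_ci, tolerance = 0.10)

  # single non-reference level: 1x1 matrix from the variance formula
  two <- categorical_study("two", "cumulative_incidence", data.frame(
    lower_cm = c(150, 160), upper_cm = c(160, 170), score_cm = c(155, 165),
    n_cases = c(30, 45), n_total = c(800, 800),
    rr = c(1, 1.5), ci_low = c(NA, 1.1), ci_high = c(NA, 2.1),
    is_reference = c(TRUE, FALSE)))
  p2 <- gl_pseudo_counts(two)
  c2 <- gl_covariance(two, p2)
  expect_equal(dim(c2), c(1L, 1L))
  expect_equal(c2[1, 1],
               1 / p2$A[2] - 1 / p2$N[2] + 1 / p2$A[1] - 1 / p2$N[1])

  # off-diagonals vanish as the reference cell grows without bound
  pseudo_big <- pseudo
  pseudo_big$A[1] <- 1e9
  pseudo_big$N[1] <- 2e9
  cv_big <- gl_covariance(st, pseudo_big)
  expect_lt(abs(cv_big[1, 2]), 1e-8)
})

test_that("GLS trend: closed form, WLS oracle, and score-shift invariance", {
  # single non-reference level: beta = y1/x1, se = sqrt(v1)/|x1|
  two <- categorical_study("two", "cumulative_incidence", data.frame(
    lower_cm = c(150, 160), upper_cm = c(160, 170), score_cm = c(155, 165),
    n_cases = c(30, 45), n_total = c(800, 800),
    rr = c(1, 1.5), ci_low = c(NA, 1.1), ci_high = c(NA, 2.1),
    is_reference = c(TRUE, FALSE)))
  v1 <- 0.04
  tr <- gls_trend(two, covariance = matrix(v1, 1, 1))
  expect_equal(tr$beta, log(1.5) / 10, tolerance = 1e-12)
  expect_equal(tr$se, sqrt(v1) / 10, tolerance = 1e-12)

  # diagonal covariance reduces to weighted LS through the origin
  st <- assign_scores(adjusted_categorical_fixture("cumulative_incidence"), "midpoint")
  lv <- st$levels
  x <- lv$score_cm[-1] - lv$score_cm[1]
  y <- log(lv$rr[-1])
  v <- c(0.013, 0.021)
  tr2 <- gls_trend(st, covariance = diag(v))
  oracle <- wls_origin_oracle(x, y, 1 / v)
  expect_equal(tr2$beta, oracle$beta, tolerance = 1e-10)
  expect_equal(tr2$se, oracle$se, tolerance = 1e-10)

  # only score contrasts matter: shifting all scores changes nothing
  shifted <- st
  shifted$levels$score_cm <- shifted$levels$score_cm + 37.5
  tr3 <- gls_trend(shifted, covariance = diag(v))
  expect_equal(tr3$beta, tr2$beta, tolerance = 1e-12)
  expect_equal(tr3$se, tr2$se, tolerance = 1e-12)
})

test_that("independence fallback understates the GL standard error", {
  # sharing the reference group induces positive covariance among the
  # level-vs-reference contrasts; ignoring it overstates precision
  for (seed in 1:5) {
    sim <- simulate_cohort_study(cohort_sim_config(n_subjects = 100000, seed = seed))
    sim <- assign_scores(sim, "given")
    gl <- gls_trend(sim, gl_covariance(sim, gl_pseudo_counts(sim)))
    indep <- suppressWarnings(gls_trend(sim, covariance = NULL))
    expect_identical(indep$method, "independence_fallback")
    expect_lte(indep$se, gl$se)
  }
})

test_that("rescaling squares a per-5-cm RR to per-10-cm and is invertible", {
  tr <- structure(list(beta = log(1.05), se = 0.0123,
                       unit_cm = 5, n_levels_used = 4L, method = "gl"),
                  class = "trend_estimate")
  tr10 <- rescale_estimate(tr, 10)
  expect_equal(exp(tr10$beta), 1.1025, tolerance = 1e-12)
  # doubling the exposure increment squares the RR and both CI bounds
  expect_equal(exp(tr10$beta - 1.96 * tr10$se),
               exp(tr$beta - 1.96 * tr$se)^2, tolerance = 1e-12)
  expect_equal(exp(tr10$beta + 1.96 * tr10$se),
               exp(tr$beta + 1.96 * tr$se)^2, tolerance = 1e-12)
  expect_equal(rescale_estimate(tr10, 5)$beta, tr$beta, tolerance = 1e-14)
  # identity when target equals source
  expect_equal(rescale_estimate(tr, 5), tr)
  # per-SD effects rescale linearly: 0.07 per 7-cm SD -> exp(0.10) per 10 cm
  tr_sd <- structure(list(beta = 0.07, se = 0.01, unit_cm = 7,
                          n_levels_used = 3L, method = "gl"),
                     class = "trend_estimate")
  expect_equal(exp(rescale_estimate(tr_sd, 10)$beta), exp(0.10), tolerance = 1e-12)
})

test_that("full GL pipeline recovers a null trend on average", {
  reps <- 60
  betas <- vapply(seq_len(reps), function(k) {
    st <- simulate_cohort_study(cohort_sim_config(
      n_subjects = 30000, beta_per_cm = 0, seed = 1000 + k))
    gl_trend(st, unit_cm = 1)$beta
  }, numeric(1))
  expect_lt(abs(mean(betas)), 3 * stats::sd(betas) / sqrt(reps))
})
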