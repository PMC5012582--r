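## Synthetic-data generators: GWAS summary statistics for two-sample MR,
## study collections for meta-analysis, and cohort quantile tables for
## dose-response trend estimation.

#' Configuration for simulating two-sample MR summary statistics
#'
#' Defaults emulate a strong polygenic height instrument (423 uncorrelated
#' variants jointly explaining 16% of height variance, exposure GWAS of
#' ~253k individuals) paired with a case-control outcome GWAS of roughly the
#' size of a large cancer consortium stratum. `exposure_sd_cm` is the
#' population SD of height; 6.5 cm is a typical sex-specific adult value.
#'
#' @param n_snps number of independent variants in the instrument
#' @param r2_target fraction of exposure variance jointly explained, in [0, 1)
#' @param n_exposure exposure-GWAS sample size
#' @param n_cases,n_controls outcome case-control GWAS sample sizes
#' @param causal_beta causal log-OR on the outcome per cm of exposure
#' @param pleiotropy_mean,pleiotropy_sd mean and SD of per-SNP direct
#'   (pleiotropic) log-OR effects on the outcome
#' @param pleiotropy_cor correlation between pleiotropic effects and true
#'   exposure effects; 0 (default) satisfies the InSIDE condition, nonzero
#'   values deliberately violate it for negative-control experiments
#' @param exposure_sd_cm population SD of the exposure in cm
#' @param maf_range interval of minor-allele frequencies, within (0, 0.5]
#' @param seed integer seed; generation is bit-reproducible given config
#' @return an object of class `mr_sim_config`
#' @export
mr_sim_config <- function(n_snps = 423L, r2_target = 0.16, n_exposure = 253288L,
                          n_cases = 14160L, n_controls = 12724L,
                          causal_beta = 0, pleiotropy_mean = 0, pleiotropy_sd = 0,
                          pleiotropy_cor = 0, exposure_sd_cm = 6.5,
                          maf_range = c(0.05, 0.5), seed = 1L) {
  stop_if_not_number(n_snps, "n_snps", positive = TRUE)
  stop_if_not_number(r2_target, "r2_target")
  if (r2_target < 0 || r2_target >= 1) stop("'r2_target' must be in [0, 1)")
  for (nm in c("n_exposure", "n_cases", "n_controls")) {
    v <- get(nm)
    stop_if_not_number(v, nm)
    if (v < 1) stop(sprintf("'%s' must be >= 1", nm))
  }
  stop_if_not_number(causal_beta, "causal_beta")
  stop_if_not_number(pleiotropy_mean, "pleiotropy_mean")
  stop_if_not_number(pleiotropy_sd, "pleiotropy_sd")
  if (pleiotropy_sd < 0) stop("'pleiotropy_sd' must be >= 0")
  stop_if_not_number(pleiotropy_cor, "pleiotropy_cor")
  if (abs(pleiotropy_cor) > 1) stop("'pleiotropy_cor' must be in [-1, 1]")
  stop_if_not_number(exposure_sd_cm, "exposure_sd_cm", positive = TRUE)
  if (length(maf_range) != 2L || any(maf_range <= 0) || any(maf_range > 0.5) ||
      maf_range[1] > maf_range[2]) {
    stop("'maf_range' must be an interval within (0, 0.5]")
  }
  structure(list(
    n_snps = as.integer(n_snps), r2_target = r2_target,
    n_exposure = n_exposure, n_cases = n_cases, n_controls = n_controls,
    causal_beta = causal_beta, pleiotropy_mean = pleiotropy_mean,
    pleiotropy_sd = pleiotropy_sd, pleiotropy_cor = pleiotropy_cor,
    exposure_sd_cm = exposure_sd_cm, maf_range = maf_range,
    seed = as.integer(seed)
  ), class = "mr_sim_config")
}

#' Simulate paired exposure/outcome GWAS summary-statistic tables
#'
#' Per SNP g: allele frequency drawn uniformly on `maf_range`; true per-allele
#' exposure effects are drawn as half-normal deviates (effect allele coded as
#' the exposure-increasing allele, the usual instrument convention) and scaled
#' so that `sum(2 p (1-p) beta^2) = r2_target * exposure_sd_cm^2` holds
#' exactly. The reported exposure beta adds normal noise with
#' `se = exposure_sd_cm * sqrt((1 - r2) / (2 p (1-p) n_exposure))`. The true
#' per-allele outcome log-OR is `causal_beta * beta_g + alpha_g` with
#' pleiotropic effects `alpha_g ~ N(pleiotropy_mean, pleiotropy_sd^2)`
#' (optionally correlated with the exposure effects via `pleiotropy_cor`);
#' the reported outcome beta adds noise with the balanced logistic
#' approximation `se = sqrt(1 / (2 p (1-p)) * (1/n_cases + 1/n_controls))`.
#'
#' Allele pairs are non-palindromic so that strict harmonization retains all
#' SNPs. True per-SNP effects are attached as attributes `beta_true` and
#' `alpha` for simulation-based validation.
#'
#' @param config an [mr_sim_config()]
#' @return list with elements `exposure` and `outcome` (data frames with
#'   columns `snp, effect_allele, other_allele, eaf, beta, se, pval, info`)
#'   and the `config`
#' @examples
#' sim <- simulate_mr_summary(mr_sim_config(n_snps = 50, seed = 7))
#' head(sim$exposure)
#' @export
simulate_mr_summary <- function(config) {
  if (!inherits(config, "mr_sim_config")) stop("'config' must be an mr_sim_config")
  set.seed(config$seed)
  n <- config$n_snps
  p <- runif(n, config$maf_range[1], config$maf_range[2])
  het <- 2 * p * (1 - p)

  # Effect magnitudes follow a half-normal truncated below at half its scale:
  # an instrument built from genome-wide-significant loci contains no
  # near-zero effects, and mass at zero would let exposure-side noise flip
  # the apparent orientation of weak SNPs.
  u <- runif(n, 2 * pnorm(0.5) - 1, 1)
  b_raw <- qnorm((1 + u) / 2)
  scale_k <- if (config$r2_target > 0) {
    sqrt(config$r2_target * config$exposure_sd_cm^2 / sum(het * b_raw^2))
  } else 0
  beta_true <- b_raw * scale_k

  se_x <- config$exposure_sd_cm *
    sqrt((1 - config$r2_target) / (het * config$n_exposure))
  x_obs <- beta_true + rnorm(n, 0, se_x)

  z_indep <- rnorm(n)
  z_beta <- if (n > 1 && stats::sd(beta_true) > 0) {
    as.numeric(scale(beta_true))
  } else rep(0, n)
  rho <- config$pleiotropy_cor
  alpha <- config$pleiotropy_mean +
    config$pleiotropy_sd * (rho * z_beta + sqrt(1 - rho^2) * z_indep)

  se_y <- sqrt((1 / het) * (1 / config$n_cases + 1 / config$n_controls))
  y_true <- config$causal_beta * beta_true + alpha
  y_obs <- y_true + rnorm(n, 0, se_y)

  pairs <- matrix(c("A", "G", "A", "C", "T", "G", "T", "C"), ncol = 2, byrow = TRUE)
  idx <- sample.int(4L, n, replace = TRUE)
  snp <- sprintf("rs%06d", seq_len(n))

  exposure <- data.frame(
    snp = snp, effect_allele = pairs[idx, 1], other_allele = pairs[idx, 2],
    eaf = p, beta = x_obs, se = se_x, pval = z_pvalue(x_obs / se_x),
    info = runif(n, 0.8, 1), stringsAsFactors = FALSE
  )
  outcome <- data.frame(
    snp = snp, effect_allele = pairs[idx, 1], other_allele = pairs[idx, 2],
    eaf = p, beta = y_obs, se = se_y, pval = z_pvalue(y_obs / se_y),
    info = runif(n, 0.8, 1), stringsAsFactors = FALSE
  )
  out <- list(exposure = exposure, outcome = outcome, config = config)
  attr(out, "beta_true") <- beta_true
  attr(out, "alpha") <- alpha
  out
}

#' Configuration for simulating a collection of study estimates
#'
#' @param n_studies number of studies drawn before any selection
#' @param true_beta true mean log-RR per 10 cm
#' @param tau2 between-study variance of the log-RR (>= 0)
#' @param se_range interval from which per-study standard errors are drawn
#' @param selection_prob probability that a study with two-sided p > 0.05 is
#'   published; 1 disables small-study selection
#' @param seed integer seed
#' @return an object of class `study_sim_config`
#' @export
study_sim_config <- function(n_studies = 20L, true_beta = log(1.10),
                             tau2 = 0.01, se_range = c(0.02, 0.15),
                             selection_prob = 1, seed = 1L) {
  stop_if_not_number(n_studies, "n_studies", positive = TRUE)
  stop_if_not_number(true_beta, "true_beta")
  stop_if_not_number(tau2, "tau2")
  if (tau2 < 0) stop("'tau2' must be >= 0")
  if (length(se_range) != 2L || any(se_range <= 0) || se_range[1] > se_range[2]) {
    stop("'se_range' must be a positive interval")
  }
  stop_if_not_number(selection_prob, "selection_prob")
  if (selection_prob <= 0 || selection_prob > 1) stop("'selection_prob' must be in (0, 1]")
  structure(list(
    n_studies = as.integer(n_studies), true_beta = true_beta, tau2 = tau2,
    se_range = se_range, selection_prob = selection_prob, seed = as.integer(seed)
  ), class = "study_sim_config")
}

#' Simulate a collection of study-level log-RR estimates
#'
#' Study-specific true effects are drawn `N(true_beta, tau2)`; observed effects
#' add sampling noise at a per-study SE drawn uniformly from `se_range`.
#' With `selection_prob < 1`, studies whose two-sided p-value exceeds 0.05
#' survive publication only with that probability, inducing the small-study
#' funnel asymmetry that Begg's and Egger's tests target.
#'
#' @param config a [study_sim_config()]
#' @return data frame with columns `study_id, beta, se` (log-RR per 10 cm)
#' @export
simulate_study_collection <- function(config) {
  if (!inherits(config, "study_sim_config")) stop("'config' must be a study_sim_config")
  set.seed(config$seed)
  k <- config$n_studies
  theta <- rnorm(k, config$true_beta, sqrt(config$tau2))
  se <- runif(k, config$se_range[1], config$se_range[2])
  beta <- theta + rnorm(k, 0, se)
  keep <- rep(TRUE, k)
  if (config$selection_prob < 1) {
    p <- z_pvalue(beta / se)
    nonsig <- p > 0.05
    keep[nonsig] <- runif(sum(nonsig)) < config$selection_prob
  }
  if (sum(keep) < 2L) {
    stop("publication selection left fewer than 2 studies; increase n_studies or selection_prob")
  }
  data.frame(
    study_id = sprintf("study_%03d", which(keep)),
    beta = beta[keep], se = se[keep], stringsAsFactors = FALSE
  )
}

#' Configuration for simulating a cohort with quantile-categorized exposure
#'
#' The risk model is log-linear in height (relative risk, not odds ratio),
#' matching the scale on which trend estimates are pooled downstream. Configs
#' whose implied risk leaves (0, 1) anywhere within +/- 4 SD of the mean are
#' rejected.
#'
#' @param n_subjects cohort size
#' @param mean_height_cm,sd_height_cm exposure distribution
#' @param baseline_risk probability of disease at the mean height, in (0, 1)
#' @param beta_per_cm true log-RR per cm of height
#' @param n_quantiles number of exposure categories (>= 2)
#' @param seed integer seed
#' @return an object of class `cohort_sim_config`
#' @export
cohort_sim_config <- function(n_subjects = 200000L, mean_height_cm = 170,
                              sd_height_cm = 6.5, baseline_risk = 0.05,
                              beta_per_cm = log(1.10) / 10, n_quantiles = 5L,
                              seed = 1L) {
  stop_if_not_number(n_subjects, "n_subjects", positive = TRUE)
  stop_if_not_number(mean_height_cm, "mean_height_cm", positive = TRUE)
  stop_if_not_number(sd_height_cm, "sd_height_cm", positive = TRUE)
  stop_if_not_number(baseline_risk, "baseline_risk")
  if (baseline_risk <= 0 || baseline_risk >= 1) stop("'baseline_risk' must be in (0, 1)")
  stop_if_not_number(beta_per_cm, "beta_per_cm")
  stop_if_not_number(n_quantiles, "n_quantiles")
  if (n_quantiles < 2) stop("'n_quantiles' must be >= 2")
  risk_hi <- baseline_risk * exp(abs(beta_per_cm) * 4 * sd_height_cm)
  if (risk_hi >= 1) {
    stop("implied risk exceeds 1 within +/- 4 SD of mean height; reduce baseline_risk or beta_per_cm")
  }
  structure(list(
    n_subjects = as.integer(n_subjects), mean_height_cm = mean_height_cm,
    sd_height_cm = sd_height_cm, baseline_risk = baseline_risk,
    beta_per_cm = beta_per_cm, n_quantiles = as.integer(n_quantiles),
    seed = as.integer(seed)
  ), class = "cohort_sim_config")
}

#' Simulate a cohort study reporting per-quantile relative risks
#'
#' Heights are drawn normally; the case indicator follows the log-linear risk
#' model `P(case | h) = baseline_risk * exp(beta_per_cm * (h - mean))`.
#' Subjects are cut into `n_quantiles` categories at empirical quantiles; the
#' emitted table carries per-category case counts, totals, the mean height as
#' the category score, and crude RRs versus the lowest (reference) category
#' with Woolf-type log-scale confidence intervals. The extreme categories are
#' open-ended, as published cohort tables usually are.
#'
#' @param config a [cohort_sim_config()]
#' @return a [categorical_study()] of design `"cumulative_incidence"`
#' @export
simulate_cohort_study <- function(config) {
  if (!inherits(config, "cohort_sim_config")) stop("'config' must be a cohort_sim_config")
  set.seed(config$seed)
  h <- rnorm(config$n_subjects, config$mean_height_cm, config$sd_height_cm)
  risk <- config$baseline_risk * exp(config$beta_per_cm * (h - config$mean_height_cm))
  risk <- pmin(risk, 1)  # guard the extreme tail beyond the 4-SD config check
  case <- rbinom(config$n_subjects, 1L, risk)

  q <- config$n_quantiles
  breaks <- quantile(h, probs = seq(0, 1, length.out = q + 1))
  breaks[1] <- -Inf
  breaks[q + 1] <- Inf
  grp <- cut(h, breaks = breaks, labels = FALSE, include.lowest = TRUE)

  n_cases <- as.numeric(tapply(case, grp, sum))
  n_total <- as.numeric(tabulate(grp, nbins = q))
  if (any(n_cases == 0)) {
    stop("zero cases in at least one category; increase n_subjects or baseline_risk")
  }
  score <- as.numeric(tapply(h, grp, mean))

  risk_cat <- n_cases / n_total
  rr <- risk_cat / risk_cat[1]
  se_log_rr <- sqrt(1 / n_cases - 1 / n_total + 1 / n_cases[1] - 1 / n_total[1])
  ci_low <- rr * exp(-1.96 * se_log_rr)
  ci_high <- rr * exp(1.96 * se_log_rr)
  rr[1] <- 1
  ci_low[1] <- NA_real_
  ci_high[1] <- NA_real_

  lower <- as.numeric(breaks[seq_len(q)])
  upper <- as.numeric(breaks[seq_len(q) + 1])

  categorical_study(
    study_id = sprintf("cohort_seed%d", config$seed),
    design = "cumulative_incidence",
    levels = data.frame(
      lower_cm = lower, upper_cm = upper, score_cm = score,
      n_cases = n_cases, n_total = n_total,
      rr = rr, ci_low = ci_low, ci_high = ci_high,
      is_reference = seq_len(q) == 1L
    )
  )
}
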