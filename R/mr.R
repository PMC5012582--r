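## Two-sample summary-statistic Mendelian randomization: allele
## harmonization, the inverse-variance-weighted estimator, MR-Egger
## pleiotropy regression, pleiotropy-exclusion sensitivity analysis,
## per-10-cm standardization, and instrument power.

COMPLEMENT <- c(A = "T", T = "A", C = "G", G = "C")

is_palindromic <- function(a1, a2) COMPLEMENT[a1] == a2

#' Drop variants with poor imputation quality
#'
#' Removes records whose `info` (imputation r-squared / info score) is
#' strictly below `threshold`; a record exactly at the threshold is kept.
#' Tables without an `info` column pass unchanged with a warning.
#'
#' @param records a summary-statistic data frame (see [read_summary_stats()])
#' @param threshold minimum acceptable imputation quality (default 0.3; some
#'   consortia use 0.7)
#' @return the filtered records, with attribute `n_dropped_info`
#' @export
filter_info <- function(records, threshold = 0.3) {
  if (!"info" %in% names(records) || all(is.na(records$info))) {
    warning("no imputation-quality column; all records pass the info filter")
    attr(records, "n_dropped_info") <- 0L
    return(records)
  }
  keep <- is.na(records$info) | records$info >= threshold
  out <- records[keep, , drop = FALSE]
  attr(out, "n_dropped_info") <- sum(!keep)
  out
}

#' Harmonize exposure and outcome summary statistics into an instrument
#'
#' Matches SNPs by identifier and aligns the outcome effect to the exposure's
#' effect allele: swapped effect/other alleles flip the outcome beta's sign
#' and complement its allele frequency; strand-flipped non-palindromic pairs
#' are complemented and re-matched. Palindromic (A/T, C/G) variants are
#' dropped under `palindromic = "drop"` (the default) or oriented by allele
#' frequency under `"freq"` when both frequencies are decisive
#' (`|eaf - 0.5| > eaf_threshold`). Variants absent from the outcome table or
#' below the imputation-quality threshold are dropped and counted.
#'
#' @param exposure,outcome summary-statistic data frames with columns
#'   `snp, effect_allele, other_allele, eaf, beta, se` (and optional `info`)
#' @param info_threshold imputation-quality cutoff applied to the outcome
#'   records (`NULL` to skip)
#' @param palindromic `"drop"` or `"freq"`
#' @param eaf_threshold minimum distance of eaf from 0.5 for frequency-based
#'   orientation of palindromic variants
#' @param exposure_unit free-text unit of the exposure betas (e.g. "cm")
#' @return object of class `harmonized_instrument`: data frame `snps` with
#'   columns `snp, x, se_x, y, sigma_y, eaf`, plus bookkeeping counts
#'   `n_input_exposure, n_dropped_missing, n_dropped_info,
#'   n_dropped_palindromic, n_dropped_irreconcilable`
#' @export
harmonize <- function(exposure, outcome, info_threshold = 0.3,
                      palindromic = c("drop", "freq"), eaf_threshold = 0.08,
                      exposure_unit = "cm") {
  palindromic <- match.arg(palindromic)
  for (tab in list(exposure, outcome)) {
    if (!all(c("snp", "effect_allele", "other_allele", "beta", "se") %in% names(tab))) {
      stop("exposure and outcome tables need columns snp, effect_allele, other_allele, beta, se")
    }
    if (anyDuplicated(tab$snp)) stop("duplicate SNP identifiers in input table")
  }
  n_input <- nrow(exposure)

  n_dropped_info <- 0L
  if (!is.null(info_threshold) && "info" %in% names(outcome)) {
    outcome <- filter_info(outcome, info_threshold)
    n_dropped_info <- attr(outcome, "n_dropped_info")
  }

  idx <- match(exposure$snp, outcome$snp)
  n_dropped_missing <- sum(is.na(idx))
  keep <- !is.na(idx)
  exp_m <- exposure[keep, , drop = FALSE]
  out_m <- outcome[idx[keep], , drop = FALSE]

  ea_x <- toupper(exp_m$effect_allele); oa_x <- toupper(exp_m$other_allele)
  ea_y <- toupper(out_m$effect_allele); oa_y <- toupper(out_m$other_allele)
  pal <- is_palindromic(ea_x, oa_x)

  y <- out_m$beta
  eaf_y <- if ("eaf" %in% names(out_m)) out_m$eaf else rep(NA_real_, nrow(out_m))
  status <- rep("irreconcilable", nrow(exp_m))

  same <- ea_y == ea_x & oa_y == oa_x
  swapped <- ea_y == oa_x & oa_y == ea_x
  flip_same <- COMPLEMENT[ea_y] == ea_x & COMPLEMENT[oa_y] == oa_x
  flip_swapped <- COMPLEMENT[ea_y] == oa_x & COMPLEMENT[oa_y] == ea_x

  status[same | (!pal & flip_same)] <- "aligned"
  status[(swapped | (!pal & flip_swapped)) & status == "irreconcilable"] <- "swapped"
  # palindromic: alleles cannot distinguish strand from swap
  status[pal] <- "palindromic"

  sw <- status == "swapped"
  y[sw] <- -y[sw]
  eaf_y[sw] <- 1 - eaf_y[sw]

  drop_pal <- rep(FALSE, nrow(exp_m))
  if (any(status == "palindromic")) {
    if (palindromic == "drop") {
      drop_pal <- status == "palindromic"
    } else {
      pidx <- which(status == "palindromic")
      eaf_x <- exp_m$eaf[pidx]
      ef <- eaf_y[pidx]
      decisive <- !is.na(eaf_x) & !is.na(ef) &
        abs(eaf_x - 0.5) > eaf_threshold & abs(ef - 0.5) > eaf_threshold
      agree <- (eaf_x > 0.5) == (ef > 0.5)
      flip <- decisive & !agree
      y[pidx[flip]] <- -y[pidx[flip]]
      eaf_y[pidx[flip]] <- 1 - eaf_y[pidx[flip]]
      drop_pal[pidx[!decisive]] <- TRUE
    }
  }
  irrec <- status == "irreconcilable"
  if (any(irrec)) {
    message(sprintf("dropping %d SNP(s) with irreconcilable allele pairs: %s",
                    sum(irrec), paste(utils::head(exp_m$snp[irrec], 5), collapse = ", ")))
  }
  keep2 <- !drop_pal & !irrec
  if (!any(keep2)) stop("no SNPs retained after harmonization")

  snps <- data.frame(
    snp = exp_m$snp[keep2],
    x = exp_m$beta[keep2],
    se_x = exp_m$se[keep2],
    y = y[keep2],
    sigma_y = out_m$se[keep2],
    eaf = if ("eaf" %in% names(exp_m)) exp_m$eaf[keep2] else NA_real_,
    stringsAsFactors = FALSE
  )
  structure(list(
    snps = snps,
    n_input_exposure = n_input,
    n_dropped_missing = as.integer(n_dropped_missing),
    n_dropped_info = as.integer(n_dropped_info),
    n_dropped_palindromic = as.integer(sum(drop_pal)),
    n_dropped_irreconcilable = as.integer(sum(irrec)),
    exposure_unit = exposure_unit
  ), class = "harmonized_instrument")
}

#' @export
print.harmonized_instrument <- function(x, ...) {
  cat(sprintf("Harmonized instrument: %d SNPs retained of %d exposure SNPs\n",
              nrow(x$snps), x$n_input_exposure))
  cat(sprintf("  dropped: %d missing from outcome, %d low imputation quality, %d palindromic, %d irreconcilable\n",
              x$n_dropped_missing, x$n_dropped_info, x$n_dropped_palindromic,
              x$n_dropped_irreconcilable))
  invisible(x)
}

#' Remove listed variants from a harmonized instrument
#'
#' Sensitivity analysis dropping SNPs with suspected pleiotropic effects on
#' other traits; downstream estimates can then be recomputed on the reduced
#' instrument.
#'
#' @param instrument a `harmonized_instrument`
#' @param snp_ids character vector of SNP identifiers to exclude
#' @return the reduced instrument
#' @export
exclude_pleiotropic <- function(instrument, snp_ids) {
  if (!inherits(instrument, "harmonized_instrument")) {
    stop("'instrument' must be a harmonized_instrument")
  }
  if (length(snp_ids) == 0L) return(instrument)
  present <- snp_ids %in% instrument$snps$snp
  if (!all(present)) {
    warning(sprintf("%d exclusion id(s) not present in the instrument", sum(!present)))
  }
  keep <- !instrument$snps$snp %in% snp_ids
  if (!any(keep)) stop("exclusion list empties the instrument")
  instrument$snps <- instrument$snps[keep, , drop = FALSE]
  instrument
}

mr_result <- function(method, beta, se, n_snps, p, exposure_unit,
                      intercept = NA_real_, se_intercept = NA_real_,
                      p_intercept = NA_real_) {
  structure(list(method = method, beta = beta, se = se, p = p,
                 n_snps = n_snps, exposure_unit = exposure_unit,
                 intercept = intercept, se_intercept = se_intercept,
                 p_intercept = p_intercept,
                 or_per_10cm = NA_real_, ci_low = NA_real_, ci_high = NA_real_,
                 unit_cm = NA_real_),
            class = "mr_result")
}

#' @export
print.mr_result <- function(x, ...) {
  cat(sprintf("MR %s estimate from %d SNPs\n", toupper(x$method), x$n_snps))
  cat(sprintf("  causal log-OR %.5f (SE %.5f) per %s of exposure, p = %.4g\n",
              x$beta, x$se, x$exposure_unit, x$p))
  if (x$method == "egger") {
    cat(sprintf("  pleiotropy intercept %.5f (SE %.5f), p = %.4g\n",
                x$intercept, x$se_intercept, x$p_intercept))
  }
  if (!is.na(x$or_per_10cm)) {
    cat(sprintf("  OR per 10 cm: %.4f (95%% CI %.4f, %.4f)\n",
                x$or_per_10cm, x$ci_low, x$ci_high))
  }
  invisible(x)
}

#' Inverse-variance-weighted causal estimate
#'
#' The two-sample summary-statistic IVW estimator (Burgess et al. 2013):
#' `beta = sum(X Y / sigma_Y^2) / sum(X^2 / sigma_Y^2)`,
#' `se = 1 / sqrt(sum(X^2 / sigma_Y^2))`, where X is the SNP-exposure beta,
#' Y the SNP-outcome beta, and sigma_Y its standard error. Equivalent to
#' weighted least squares of Y on X through the origin with weights
#' `1/sigma_Y^2`; exposure-side uncertainty does not enter the weights.
#' The p-value is a two-sided Wald test.
#'
#' @param instrument a `harmonized_instrument`
#' @return an `mr_result` with `method = "ivw"`, on the instrument's exposure
#'   scale (use [standardize_or()] for per-10-cm ORs)
#' @export
ivw_estimate <- function(instrument) {
  if (!inherits(instrument, "harmonized_instrument")) {
    stop("'instrument' must be a harmonized_instrument")
  }
  s <- instrument$snps
  if (nrow(s) < 1L) stop("empty instrument")
  w <- 1 / s$sigma_y^2
  denom <- sum(s$x^2 * w)
  beta <- sum(s$x * s$y * w) / denom
  se <- sqrt(1 / denom)
  mr_result("ivw", beta, se, nrow(s), p = z_pvalue(beta / se),
            exposure_unit = instrument$exposure_unit)
}

#' MR-Egger pleiotropy regression
#'
#' Weighted regression of the outcome betas on the exposure betas with a free
#' intercept and weights `1/sigma_Y^2`, after orienting every SNP so its
#' exposure beta is non-negative (Bowden et al. 2015). The slope is the
#' causal estimate (consistent under the InSIDE condition); the intercept
#' estimates the average directional pleiotropic effect. p-values are
#' two-sided t-tests with n - 2 df.
#'
#' @param instrument a `harmonized_instrument` with at least 3 SNPs
#' @return an `mr_result` with `method = "egger"` carrying slope and intercept
#' @export
mr_egger <- function(instrument) {
  if (!inherits(instrument, "harmonized_instrument")) {
    stop("'instrument' must be a harmonized_instrument")
  }
  s <- instrument$snps
  n <- nrow(s)
  if (n < 3L) stop("MR-Egger requires at least 3 SNPs")
  flip <- sign(s$x)
  flip[flip == 0] <- 1
  x <- s$x * flip
  y <- s$y * flip
  w <- 1 / s$sigma_y^2
  fit <- lm(y ~ x, weights = w)
  sm <- summary(fit)$coefficients
  mr_result("egger",
            beta = sm["x", "Estimate"], se = sm["x", "Std. Error"],
            n_snps = n,
            p = t_pvalue(sm["x", "Estimate"] / sm["x", "Std. Error"], df = n - 2L),
            exposure_unit = instrument$exposure_unit,
            intercept = sm["(Intercept)", "Estimate"],
            se_intercept = sm["(Intercept)", "Std. Error"],
            p_intercept = t_pvalue(sm["(Intercept)", "Estimate"] /
                                     sm["(Intercept)", "Std. Error"], df = n - 2L))
}

#' Standardize an MR estimate to an odds ratio per 10 cm
#'
#' Rescales the causal log-OR and its standard error by
#' `10 / exposure_unit_cm` (the number of cm represented by one unit of the
#' SNP-exposure betas, e.g. the height SD when the exposure GWAS reports
#' per-SD effects) and fills the per-10-cm OR and 95% CI.
#'
#' @param result an `mr_result`
#' @param exposure_unit_cm cm per unit of the exposure betas (> 0)
#' @return the `mr_result` with `beta`/`se` per 10 cm and `or_per_10cm`,
#'   `ci_low`, `ci_high` filled
#' @examples
#' # log-OR 0.07 per SD of height, SD = 7 cm:
#' r <- trendmr:::mr_result("ivw", 0.07, 0.02, 10, 0.001, "sd")
#' standardize_or(r, 7)$or_per_10cm  # exp(0.10)
#' @export
standardize_or <- function(result, exposure_unit_cm) {
  if (!inherits(result, "mr_result")) stop("'result' must be an mr_result")
  stop_if_not_number(exposure_unit_cm, "exposure_unit_cm", positive = TRUE)
  f <- 10 / exposure_unit_cm
  result$beta <- result$beta * f
  result$se <- result$se * f
  result$or_per_10cm <- exp(result$beta)
  result$ci_low <- exp(result$beta - 1.96 * result$se)
  result$ci_high <- exp(result$beta + 1.96 * result$se)
  result$unit_cm <- 10
  result$exposure_unit <- "10 cm"
  result
}

#' Power of a two-sample MR study with a binary outcome
#'
#' Burgess (2014) non-centrality approximation for a two-sided Wald test:
#' with non-centrality `b = sqrt(N r2 phi (1 - phi)) * |log(or_alt)|`,
#' `power = pnorm(b - z_(1-alpha/2)) + pnorm(-b - z_(1-alpha/2))`, where
#' `N = n_cases + n_controls` and `phi = n_cases / N` is the case fraction
#' (the second term is negligible except near the null, where it makes the
#' power equal alpha rather than alpha/2).
#' `or_alt` is the alternative-hypothesis odds ratio per standard deviation
#' of the exposure, and `r2` the variance in the exposure explained by the
#' instrument.
#'
#' @param n_cases,n_controls outcome sample sizes
#' @param r2 instrument strength, in (0, 1)
#' @param or_alt alternative odds ratio per exposure SD (> 0)
#' @param alpha two-sided significance level
#' @return power as a fraction in (0, 1)
#' @examples
#' mr_power(14160, 12724, r2 = 0.16, or_alt = 1.09)
#' @export
mr_power <- function(n_cases, n_controls, r2, or_alt, alpha = 0.05) {
  stop_if_not_number(n_cases, "n_cases", positive = TRUE)
  stop_if_not_number(n_controls, "n_controls", positive = TRUE)
  stop_if_not_number(r2, "r2")
  if (r2 <= 0 || r2 >= 1) stop("'r2' must be in (0, 1)")
  stop_if_not_number(or_alt, "or_alt", positive = TRUE)
  stop_if_not_number(alpha, "alpha")
  if (alpha <= 0 || alpha >= 1) stop("'alpha' must be in (0, 1)")
  n <- n_cases + n_controls
  phi <- n_cases / n
  b <- sqrt(n * r2 * phi * (1 - phi)) * abs(log(or_alt))
  z <- qnorm(1 - alpha / 2)
  pnorm(b - z) + pnorm(-b - z)
}
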