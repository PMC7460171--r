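# Seeded generator for study-like datasets with known generative truth.
#
# Covariates emulate the descriptive statistics of the real cohort
# (n = 555 middle-school students): six psychosocial questionnaire totals
# (BDI, BAI, BIS, CASS, AQ, STAXI_E) with the published means, SDs and
# correlation block; gender/alcohol/smoking binaries; right-skewed usage
# hours; birth year. Outcomes are drawn from the copula regression model
# itself (log-normal IAT margin, gamma SAS margin, t copula), so every
# pipeline stage can be validated against known truth.

psychosocial_defaults <- tibble::tibble(
  variable = c("BDI", "BAI", "BIS", "CASS", "AQ", "STAXI_E"),
  mean = c(7.46, 6.46, 63.55, 17.91, 63.42, 53.28),
  sd = c(7.82, 8.56, 8.34, 12.59, 20.06, 11.39)
)

psychosocial_correlation_default <- local({
  v <- psychosocial_defaults$variable
  R <- diag(6)
  dimnames(R) <- list(v, v)
  up <- rbind(
    c("BDI", "BAI", 0.65), c("BDI", "BIS", 0.31), c("BDI", "CASS", 0.52),
    c("BDI", "AQ", 0.50), c("BDI", "STAXI_E", 0.33),
    c("BAI", "BIS", 0.30), c("BAI", "CASS", 0.55), c("BAI", "AQ", 0.52),
    c("BAI", "STAXI_E", 0.30),
    c("BIS", "CASS", 0.44), c("BIS", "AQ", 0.33), c("BIS", "STAXI_E", 0.14),
    c("CASS", "AQ", 0.60), c("CASS", "STAXI_E", 0.44),
    c("AQ", "STAXI_E", 0.53)
  )
  for (i in seq_len(nrow(up))) {
    R[up[i, 1], up[i, 2]] <- R[up[i, 2], up[i, 1]] <- as.numeric(up[i, 3])
  }
  R
})

usage_hours_defaults <- tibble::tibble(
  variable = c("WDGH", "WEGH", "WDIH", "WDSH", "WESH"),
  meanlog = c(log(1), log(2), log(1.5), log(3), log(4)),
  sdlog = c(0.9, 0.9, 0.8, 0.7, 0.7)
)

# final-model coefficients used as generative truth (link scale; YEAR
# centered at its expectation, so the intercept is solved from the target
# outcome means at the covariate means)
beta1_default <- c(
  GENDER = -0.0929, BDI = -0.0044, BAI = 0.0089, BIS = 0.0052,
  CASS = 0.0029, AQ = 0.0037, WDGH = 0.0375, WEGH = 0.0264,
  WDIH = 0.0376, YEAR = -0.0332, ALC = -0.1677, SMK = 0.0969
)
beta2_default <- c(
  GENDER = 0.0484, BDI = -0.0019, BAI = 0.0079, BIS = 0.0082,
  CASS = -0.0007, AQ = 0.0049, WDSH = 0.0057, WESH = 0.0251,
  YEAR = -0.051, ALC = 0.0341, SMK = 0.0497
)

nearest_psd_correlation <- function(R, eps = 1e-8) {
  e <- eigen((R + t(R)) / 2, symmetric = TRUE)
  if (min(e$values) >= eps) {
    return(R)
  }
  vals <- pmax(e$values, eps)
  M <- e$vectors %*% diag(vals) %*% t(e$vectors)
  D <- diag(1 / sqrt(diag(M)))
  out <- D %*% M %*% D
  dimnames(out) <- dimnames(R)
  out
}

# Gaussian-copula (Nataf) correlation distortion: the normal-score
# correlation that yields the target Pearson correlation after both
# coordinates are pushed through moment-matched gamma margins. Solved per
# pair by Gauss-Hermite quadrature + uniroot.
nataf_zcorr <- function(target, shape1, rate1, shape2, rate2, n_nodes = 48) {
  gh <- pracma::gaussHermite(n_nodes)
  x <- gh$x * sqrt(2)
  w <- gh$w / sqrt(pi)
  m1 <- shape1 / rate1
  s1 <- sqrt(shape1) / rate1
  m2 <- shape2 / rate2
  s2 <- sqrt(shape2) / rate2
  # clamp: extreme nodes would push pnorm to exactly 1 and qgamma to Inf,
  # with quadrature weights far too small to matter
  pclamp <- function(z) pmin(pmax(pnorm(z), 1e-15), 1 - 1e-15)
  g1 <- qgamma(pclamp(x), shape1, rate1)
  pearson_at <- function(r) {
    Z2 <- r * matrix(x, n_nodes, n_nodes) +
      sqrt(1 - r^2) * matrix(x, n_nodes, n_nodes, byrow = TRUE)
    G2 <- qgamma(pclamp(Z2), shape2, rate2)
    ex12 <- sum(w * g1 * drop(G2 %*% w))
    (ex12 - m1 * m2) / (s1 * s2)
  }
  if (abs(target) < 1e-12) {
    return(0)
  }
  # pearson_at is monotone in r with pearson_at(0) = 0; targets beyond the
  # attainable (Frechet) range for these margins clamp to the extreme
  hi <- 0.9999
  if (target > 0) {
    if (target >= pearson_at(hi)) {
      return(hi)
    }
    uniroot(function(r) pearson_at(r) - target, lower = 0, upper = hi,
            tol = 1e-6)$root
  } else {
    if (target <= pearson_at(-hi)) {
      return(-hi)
    }
    uniroot(function(r) pearson_at(r) - target, lower = -hi, upper = 0,
            tol = 1e-6)$root
  }
}

#' Generative configuration for a synthetic study
#'
#' Collects every knob of the synthetic-data generator. Defaults emulate
#' the study conditions: `n = 555` analyzed subjects; psychosocial totals
#' with the published means, SDs and correlation block (generated from a
#' Gaussian copula with moment-matched gamma margins, normal-score
#' correlations calibrated so the *Pearson* correlations hit their
#' targets, then rounded to integers); gender split 295 male / 260 female;
#' right-skewed log-normal usage hours; birth years 1998/1999; final-model
#' regression coefficients as generative truth; log-normal IAT margin with
#' log-scale sigma 0.346; gamma SAS margin with shape solved so the SAS
#' mean 80.25 and SD 27.94 hold at the covariate means; t copula with
#' rho = 0.364 and 3 degrees of freedom.
#'
#' @param n Number of subjects generated.
#' @param psychosocial Tibble with columns `variable`, `mean`, `sd`.
#' @param psychosocial_correlation Target Pearson correlation matrix for
#'   the psychosocial block (projected to the nearest positive-definite
#'   correlation matrix if needed).
#' @param usage_hours Tibble with columns `variable`, `meanlog`, `sdlog`.
#' @param p_female,p_alc,p_smk Binary covariate rates.
#' @param birth_years Integer birth years sampled uniformly.
#' @param beta1,beta2 Named generative coefficient vectors (link scale;
#'   intercepts are solved from `mean1`/`mean2` at the covariate means).
#' @param margin1,margin2 Outcome margin families.
#' @param sigma1 Margin-1 dispersion (log-scale sigma for the default
#'   log-normal margin).
#' @param mean1,mean2,sd2 Target outcome means (and margin-2 SD) at the
#'   covariate means; `sigma2` (gamma shape) is `(mean2 / sd2)^2`.
#' @param copula,rho,df Copula family and parameters.
#' @param missing_rate Fraction of rows whose outcome pair is deleted
#'   completely at random by [simulate_study()] (0 disables; set
#'   `n = 714` and `missing_rate = 159/714` to emulate the original
#'   collection-to-analysis flow).
#' @return A `generative_config` list; pair-wise normal-score correlations
#'   are pre-computed here so repeated simulation is cheap.
#' @export
generative_config <- function(n = 555,
                              psychosocial = psychosocial_defaults,
                              psychosocial_correlation = psychosocial_correlation_default,
                              usage_hours = usage_hours_defaults,
                              p_female = 260 / 555, p_alc = 0.15, p_smk = 0.07,
                              birth_years = c(1998L, 1999L),
                              beta1 = beta1_default, beta2 = beta2_default,
                              margin1 = "lognormal", margin2 = "gamma",
                              sigma1 = 0.346,
                              mean1 = exp(3.464 + 0.346^2 / 2),
                              mean2 = 80.25, sd2 = 27.94,
                              copula = "student_t", rho = 0.364, df = 3,
                              missing_rate = 0) {
  stopifnot(n >= 1)
  for (r in c(p_female, p_alc, p_smk, missing_rate)) {
    if (r < 0 || r > 1) abort_config("rates must lie in [0, 1].")
  }
  if (missing_rate >= 1) abort_config("`missing_rate` must be below 1.")
  check_copula_params(copula, rho, if (copula == "student_t") df else NULL)
  vars <- psychosocial$variable
  R <- psychosocial_correlation
  if (!isTRUE(all.equal(R, t(R))) || any(abs(diag(R) - 1) > 1e-8)) {
    abort_config("`psychosocial_correlation` must be symmetric with unit diagonal.")
  }
  R <- nearest_psd_correlation(R)
  if (min(eigen(R, symmetric = TRUE, only.values = TRUE)$values) < -1e-10) {
    abort_config("correlation matrix is not positive semi-definite.")
  }

  shapes <- (psychosocial$mean / psychosocial$sd)^2
  rates <- psychosocial$mean / psychosocial$sd^2
  Z <- diag(nrow(R))
  dimnames(Z) <- dimnames(R)
  for (i in seq_len(nrow(R) - 1)) {
    for (j in (i + 1):nrow(R)) {
      Z[i, j] <- Z[j, i] <- nataf_zcorr(R[i, j], shapes[i], rates[i],
                                        shapes[j], rates[j])
    }
  }
  Z <- nearest_psd_correlation(Z)

  sigma2 <- (mean2 / sd2)^2 # gamma shape from the target mean/SD

  cfg <- list(
    n = as.integer(n),
    psychosocial = psychosocial, psychosocial_correlation = R,
    zscore_correlation = Z, psychosocial_shapes = shapes,
    psychosocial_rates = rates,
    usage_hours = usage_hours,
    p_female = p_female, p_alc = p_alc, p_smk = p_smk,
    birth_years = as.integer(birth_years),
    beta1 = beta1, beta2 = beta2,
    margin1 = check_reg_family(margin1), margin2 = check_reg_family(margin2),
    sigma1 = sigma1, sigma2 = sigma2,
    mean1 = mean1, mean2 = mean2, sd2 = sd2,
    copula = copula, rho = rho,
    df = if (copula == "student_t") df else NULL,
    missing_rate = missing_rate
  )
  cfg$covariate_means <- covariate_expectations(cfg)
  cfg$intercept1 <- solve_intercept(cfg$margin1, cfg$mean1, cfg$sigma1,
                                    cfg$beta1, cfg$covariate_means)
  cfg$intercept2 <- solve_intercept(cfg$margin2, cfg$mean2, cfg$sigma2,
                                    cfg$beta2, cfg$covariate_means)
  structure(cfg, class = "generative_config")
}

covariate_expectations <- function(cfg) {
  ph <- setNames(cfg$psychosocial$mean, cfg$psychosocial$variable)
  uh <- setNames(exp(cfg$usage_hours$meanlog + cfg$usage_hours$sdlog^2 / 2),
                 cfg$usage_hours$variable)
  c(
    GENDER = cfg$p_female, ph, uh,
    YEAR = 0, # enters centered at its expectation
    ALC = cfg$p_alc, SMK = cfg$p_smk
  )
}

# link-scale intercept so the conditional outcome mean at the covariate
# means equals the target marginal mean
solve_intercept <- function(family, target_mean, disp, beta, means) {
  shift <- sum(beta * means[names(beta)])
  switch(family,
    normal = target_mean - shift,
    lognormal = log(target_mean) - disp^2 / 2 - shift,
    gamma = log(target_mean) - shift
  )
}

#' @export
print.generative_config <- function(x, ...) {
  cat(sprintf(
    "<generative_config> n = %d, margins %s/%s, %s copula (rho = %.3f%s), missing rate %.3f\n",
    x$n, x$margin1, x$margin2, x$copula, x$rho,
    if (!is.null(x$df)) sprintf(", df = %g", x$df) else "", x$missing_rate
  ))
  invisible(x)
}

#' Generate the covariate table
#'
#' Psychosocial totals via the calibrated Gaussian copula with gamma
#' margins (then rounded to integers and floored at 0); independent
#' Bernoulli gender/alcohol/smoking indicators; independent log-normal
#' usage hours rounded to 0.1 h; uniform birth years.
#'
#' @param config A [generative_config()].
#' @param seed Optional integer seed.
#' @param n Override for the number of rows.
#' @return A tibble of covariates.
#' @export
generate_covariates <- function(config, seed = NULL, n = config$n) {
  with_seed(seed, {
    L <- chol(config$zscore_correlation)
    Zm <- matrix(rnorm(n * nrow(L)), n) %*% L
    P <- pnorm(Zm)
    psy <- purrr::imap_dfc(
      setNames(seq_along(config$psychosocial$variable),
               config$psychosocial$variable),
      function(j, nm) {
        pmax(round(qgamma(P[, j], config$psychosocial_shapes[j],
                          config$psychosocial_rates[j])), 0)
      }
    )
    uh <- purrr::imap_dfc(
      setNames(seq_len(nrow(config$usage_hours)), config$usage_hours$variable),
      function(j, nm) {
        round(rlnorm(n, config$usage_hours$meanlog[j],
                     config$usage_hours$sdlog[j]), 1)
      }
    )
    tibble::tibble(
      GENDER = rbinom(n, 1, config$p_female),
      psy,
      uh,
      YEAR = sample(config$birth_years, n, replace = TRUE),
      ALC = rbinom(n, 1, config$p_alc),
      SMK = rbinom(n, 1, config$p_smk)
    )
  })
}

generative_eta <- function(covariates, intercept, beta, birth_years) {
  year_center <- mean(birth_years)
  eta <- rep(intercept, nrow(covariates))
  for (v in names(beta)) {
    col <- as.numeric(covariates[[v]])
    if (v == "YEAR") col <- col - year_center
    eta <- eta + beta[[v]] * col
  }
  eta
}

#' Draw outcome pairs from the generative copula regression
#'
#' Samples `(u1, u2)` from the configured copula and inverts each margin's
#' conditional quantile function at the row's linear predictor.
#'
#' @param covariates Covariate tibble (from [generate_covariates()]).
#' @param config A [generative_config()].
#' @param seed Optional integer seed.
#' @return A tibble with columns `y1`, `y2`.
#' @export
generate_outcomes <- function(covariates, config, seed = NULL) {
  miss <- setdiff(
    setdiff(unique(c(names(config$beta1), names(config$beta2))), "YEAR"),
    names(covariates)
  )
  if (length(miss)) {
    abort_config(paste0(
      "covariate table lacks generative coefficients' columns: ",
      paste(miss, collapse = ", ")
    ))
  }
  eta1 <- generative_eta(covariates, config$intercept1, config$beta1,
                         config$birth_years)
  eta2 <- generative_eta(covariates, config$intercept2, config$beta2,
                         config$birth_years)
  with_seed(seed, {
    u <- sample_copula(config$copula, config$rho, config$df, nrow(covariates))
    tibble::tibble(
      y1 = margin_reg_quantile(config$margin1, u$u1, eta1, config$sigma1),
      y2 = margin_reg_quantile(config$margin2, u$u2, eta2, config$sigma2)
    )
  })
}

#' Simulate a complete synthetic study
#'
#' Covariates, outcomes and (optionally) completely-at-random outcome
#' missingness, bundled with the generative configuration and seed so the
#' truth is always recoverable. Regeneration with the same configuration
#' and seed is byte-identical.
#'
#' @param config A [generative_config()].
#' @param seed Integer seed.
#' @return A `synthetic_study`: list with `data` (tibble), `config`,
#'   `seed`.
#' @examples
#' study <- simulate_study(generative_config(n = 200), seed = 1)
#' head(study$data)
#' @export
simulate_study <- function(config = generative_config(), seed = NULL) {
  study <- with_seed(seed, {
    cov <- generate_covariates(config)
    out <- generate_outcomes(cov, config)
    st <- structure(
      list(data = dplyr::bind_cols(cov, out), config = config, seed = seed),
      class = "synthetic_study"
    )
    if (config$missing_rate > 0) {
      st <- inject_missingness(st, config$missing_rate)
    }
    st
  })
  study
}

#' @export
print.synthetic_study <- function(x, ...) {
  cat(sprintf(
    "<synthetic_study> %d rows (%d complete), seed %s\n",
    nrow(x$data), sum(complete.cases(x$data[, c("y1", "y2")])),
    if (is.null(x$seed)) "none" else x$seed
  ))
  invisible(x)
}

#' Delete outcome pairs completely at random
#'
#' Each row's outcome pair is deleted independently with probability
#' `rate` (both outcomes set to `NA`), mimicking a
#' missing-completely-at-random collection loss ahead of complete-case
#' analysis.
#'
#' @param study A `synthetic_study` (or plain data frame with `y1`, `y2`).
#' @param rate Deletion probability in [0, 1).
#' @param seed Optional integer seed.
#' @return Object of the same type with missing outcomes.
#' @export
inject_missingness <- function(study, rate, seed = NULL) {
  if (rate < 0 || rate >= 1) abort_config("`rate` must lie in [0, 1).")
  d <- if (inherits(study, "synthetic_study")) study$data else study
  if (rate > 0) {
    drop <- with_seed(seed, rbinom(nrow(d), 1, rate) == 1)
    d$y1[drop] <- NA_real_
    d$y2[drop] <- NA_real_
  }
  if (inherits(study, "synthetic_study")) {
    study$data <- d
    study
  } else {
    d
  }
}

#' Restrict to rows with both outcomes observed
#'
#' Complete-case filter on the outcome columns only (covariate
#' missingness, if any, is left untouched and not modelled).
#'
#' @param study A `synthetic_study` or data frame.
#' @param outcomes Outcome column names.
#' @return Same type, outcome-complete rows only. Errors if nothing
#'   remains.
#' @export
complete_cases <- function(study, outcomes = c("y1", "y2")) {
  d <- if (inherits(study, "synthetic_study")) study$data else study
  keep <- complete.cases(d[, outcomes, drop = FALSE])
  if (!any(keep)) abort_pipeline("no complete outcome pairs remain.")
  d <- d[keep, , drop = FALSE]
  if (inherits(study, "synthetic_study")) {
    study$data <- d
    study
  } else {
    d
  }
}

#' Regression specification matching the generative model
#'
#' Convenience constructor for the full final-model specification (the
#' covariate sets carried by the generative coefficient vectors), ready
#' for [fit_copula_regression()] on a simulated study.
#'
#' @param config A [generative_config()].
#' @param df_mode Passed to [copreg_spec()].
#' @return A [copreg_spec()].
#' @export
default_regression_spec <- function(config = generative_config(),
                                    df_mode = "fixed") {
  copreg_spec(
    config$margin1, config$margin2,
    names(config$beta1), names(config$beta2),
    copula = config$copula, df = config$df %||% 3, df_mode = df_mode
  )
}

#' Generative truth as a parameter vector / coefficient table
#'
#' Returns the true parameter values of a configuration in the layout of
#' [fit_copula_regression()] estimates, for coverage and recovery checks.
#'
#' @param config A [generative_config()].
#' @return A tibble with columns `margin`, `term`, `truth`.
#' @export
generative_truth <- function(config) {
  dplyr::bind_rows(
    tibble::tibble(
      margin = "y1",
      term = c("(Intercept)", names(config$beta1), "dispersion"),
      truth = c(config$intercept1, unname(config$beta1), config$sigma1)
    ),
    tibble::tibble(
      margin = "y2",
      term = c("(Intercept)", names(config$beta2), "dispersion"),
      truth = c(config$intercept2, unname(config$beta2), config$sigma2)
    ),
    tibble::tibble(margin = "copula", term = "rho", truth = config$rho)
  )
}

#' Histograms of the simulated outcome scores
#'
#' @param object A `synthetic_study`.
#' @param bins Number of histogram bins.
#' @param ... Unused.
#' @return A ggplot object showing both outcome distributions.
#' @export
autoplot.synthetic_study <- function(object, bins = 30, ...) {
  d <- tidyr::pivot_longer(object$data[, c("y1", "y2")],
                           cols = dplyr::everything(),
                           names_to = "outcome", values_to = "score")
  ggplot2::ggplot(d[!is.na(d$score), ],
                  ggplot2::aes(x = .data$score)) +
    ggplot2::geom_histogram(bins = bins, fill = "grey70", colour = "grey30") +
    ggplot2::facet_wrap(~outcome, scales = "free") +
    ggplot2::labs(x = "total score", y = "count")
}
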