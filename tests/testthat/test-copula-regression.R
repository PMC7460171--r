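test_that("the joint likelihood factorizes exactly under independence", {
  cfg <- small_config(n = 200)
  st <- simulate_study(cfg, seed = 10)
  spec <- small_spec(copula = "gaussian")
  d <- st$data
  X1 <- bicopreg:::build_design(d, spec$covariates1)
  X2 <- bicopreg:::build_design(d, spec$covariates2)
  f1 <- bicopreg:::fit_margin_regression(d$y1, X1, "lognormal")
  f2 <- bicopreg:::fit_margin_regression(d$y2, X2, "gamma")
  params <- c(f1$beta, f1$disp, f2$beta, f2$disp, 0) # rho = 0
  ll <- joint_loglik(spec, params, d)
  expect_identical(as.numeric(ll), f1$loglik + f2$loglik)
})

test_that("the joint likelihood matches a hand-computed single observation", {
  spec <- copreg_spec("normal", "normal", character(0), character(0),
                      copula = "gaussian")
  d <- tibble::tibble(y1 = 31.5, y2 = 78.2)
  params <- c(33, 12, 80, 25, 0.4) # (mu1, sd1, mu2, sd2, rho)
  ll <- as.numeric(joint_loglik(spec, params, d))
  # oracle: bivariate normal density over the product of univariate ones
  z <- c((31.5 - 33) / 12, (78.2 - 80) / 25)
  lc <- mvtnorm::dmvnorm(z, sigma = matrix(c(1, 0.4, 0.4, 1), 2), log = TRUE) -
    dnorm(z[1], log = TRUE) - dnorm(z[2], log = TRUE)
  by_hand <- dnorm(31.5, 33, 12, log = TRUE) + dnorm(78.2, 80, 25, log = TRUE) + lc
  expect_equal(ll, by_hand, tolerance = 1e-12)
})

test_that("the joint likelihood is location-equivariant for normal margins", {
  cfg <- small_config(n = 150)
  st <- simulate_study(cfg, seed = 11)
  d <- st$data
  spec <- copreg_spec("normal", "gamma", c("BAI"), c("AQ"),
                      copula = "student_t", df = 3)
  params <- c(34, 0.01, 13, 4.3, 0.005, 8, 0.36)
  ll1 <- as.numeric(joint_loglik(spec, params, d))
  d2 <- d
  d2$y1 <- d$y1 + 100
  params2 <- params
  params2[1] <- params[1] + 100
  expect_equal(as.numeric(joint_loglik(spec, params2, d2)), ll1,
               tolerance = 1e-10)
})

test_that("joint MLE recovers generative parameters and ascends", {
  cfg <- small_config(n = 1500)
  st <- simulate_study(cfg, seed = 21)
  fit <- fit_copula_regression(st$data, small_spec())
  expect_gte(fit$loglik, fit$init_loglik)
  truth <- generative_truth(cfg)
  m <- dplyr::inner_join(tidy(fit), truth, by = c("margin", "term"))
  expect_equal(nrow(m), 10)
  expect_true(all(abs(m$estimate - m$truth) <= 3.5 * m$std.error))
  expect_equal(fit$aic, -2 * fit$loglik + 2 * fit$k)
  # null dependence: estimated rho near 0, AIC within 2 of independence
  cfg0 <- generative_config(
    n = 1200, copula = "gaussian", rho = 0,
    beta1 = cfg$beta1, beta2 = cfg$beta2
  )
  st0 <- simulate_study(cfg0, seed = 22)
  fit0 <- fit_copula_regression(st0$data, small_spec(copula = "gaussian"))
  expect_lt(abs(fit0$rho), 3 / sqrt(1200))
  ind0 <- fit_independent_margins(st0$data, "lognormal", "gamma",
                                  small_spec()$covariates1,
                                  small_spec()$covariates2)
  expect_lt(abs(fit0$aic - ind0$total_aic), 2 + 1e-6)
})

test_that("estimates are invariant to covariate standardization", {
  cfg <- small_config(n = 900)
  st <- simulate_study(cfg, seed = 31)
  d <- st$data
  spec <- small_spec()
  fit_raw <- fit_copula_regression(d, spec)
  d2 <- d
  sd_bai <- sd(d$BAI)
  mu_bai <- mean(d$BAI)
  d2$BAI <- (d$BAI - mu_bai) / sd_bai
  fit_std <- fit_copula_regression(d2, spec)
  # back-transform the margin-1 BAI coefficient and intercept
  b_raw <- fit_raw$beta1
  b_std <- fit_std$beta1
  expect_equal(unname(b_std["m1_BAI"] / sd_bai), unname(b_raw["m1_BAI"]),
               tolerance = 1e-6)
  expect_equal(
    unname(b_std["m1_(Intercept)"] - b_std["m1_BAI"] * mu_bai / sd_bai),
    unname(b_raw["m1_(Intercept)"]),
    tolerance = 1e-6
  )
  expect_equal(fit_std$loglik, fit_raw$loglik, tolerance = 1e-8)
  expect_equal(fit_std$rho, fit_raw$rho, tolerance = 1e-6)
})

test_that("Wald inference matches direct normal-tail computation", {
  cfg <- small_config(n = 700)
  st <- simulate_study(cfg, seed = 41)
  fit <- fit_copula_regression(st$data, small_spec())
  wt <- wald_inference(fit)
  expect_true(all(wt$p.value >= 0 & wt$p.value <= 1))
  expect_equal(wt$p.value,
               2 * (1 - pnorm(abs(wt$estimate / wt$std.error))),
               tolerance = 1e-10)
  expect_identical(wald_inference(fit), tidy(fit))
  # the published-scale example: estimate 0.0089, SE 0.0019 -> p < 1e-4
  expect_lt(2 * (1 - pnorm(0.0089 / 0.0019)), 1e-4)
  # a zero estimate is maximally non-significant
  fake <- fit
  fake$params[2] <- 0
  expect_equal(wald_inference(fake)$p.value[2], 1)
})

test_that("the Fisher-z correlation interval behaves correctly", {
  # closed form at rho = 0: tanh(+/- 1.96 * se_z)
  ci <- bicopreg:::fisher_z_ci(0, 0.1, 0.95)
  expect_equal(unname(ci), c(-0.1937, 0.1937), tolerance = 1e-3)
  # boundedness near the boundary
  ci99 <- bicopreg:::fisher_z_ci(0.99, 0.05, 0.95)
  expect_lt(ci99[["upper"]], 1)
  expect_gt(ci99[["lower"]], -1)
  # interval from a fit contains the estimate; width shrinks with n
  widths <- vapply(c(400, 1600), function(n) {
    cfg <- small_config(n = n)
    st <- simulate_study(cfg, seed = 51)
    fit <- fit_copula_regression(st$data, small_spec())
    ci <- correlation_ci(fit)
    expect_gt(fit$rho, ci[["lower"]])
    expect_lt(fit$rho, ci[["upper"]])
    ci[["upper"]] - ci[["lower"]]
  }, numeric(1))
  expect_lt(widths[2], widths[1])
})

test_that("conditional means follow the margin link functions", {
  # closed-form expectations through a hand-built fit object
  cfg <- small_config(n = 400)
  st <- simulate_study(cfg, seed = 61)
  fit <- fit_copula_regression(st$data, small_spec())
  pred <- conditional_mean(fit, st$data[1:5, ])
  eta1 <- fit$beta1[1] + fit$beta1[2] * st$data$GENDER[1:5] +
    fit$beta1[3] * st$data$BAI[1:5] + fit$beta1[4] * st$data$WDGH[1:5]
  expect_equal(pred$.mean_y1, unname(exp(eta1 + fit$sigma1^2 / 2)),
               tolerance = 1e-10)
  eta2 <- fit$beta2[1] + fit$beta2[2] * st$data$BAI[1:5] +
    fit$beta2[3] * st$data$AQ[1:5]
  expect_equal(pred$.mean_y2, unname(exp(eta2)), tolerance = 1e-10)
  expect_identical(predict(fit, st$data[1:5, ]), pred)
  # missing covariate values abort
  bad <- st$data[1:2, ]
  bad$BAI[1] <- NA
  expect_error(conditional_mean(fit, bad), class = "bicopreg_prediction_error")
  expect_error(conditional_mean(fit, bad[, "GENDER", drop = FALSE]),
               class = "bicopreg_prediction_error")
})

test_that("intercept-only margins reproduce marginal closed forms", {
  spec <- copreg_spec("lognormal", "gamma", character(0), character(0),
                      copula = "gaussian")
  cfg <- generative_config(
    n = 3000,
    beta1 = setNames(numeric(0), character(0)),
    beta2 = setNames(numeric(0), character(0)),
    copula = "gaussian", rho = 0.4
  )
  st <- simulate_study(cfg, seed = 71)
  fit <- fit_copula_regression(st$data, spec)
  # lognormal margin: mean exp(b0 + sigma^2/2) near the configured 33.9
  expect_equal(
    conditional_mean(fit, st$data[1, ])$.mean_y1,
    exp(unname(fit$beta1[1]) + fit$sigma1^2 / 2)
  )
  expect_equal(unname(fit$beta1[1]), 3.464, tolerance = 0.02)
  expect_equal(conditional_mean(fit, st$data[1, ])$.mean_y2,
               exp(unname(fit$beta2[1])))
})

test_that("per-parameter Wald interval coverage is nominal across replicates", {
  res <- default_replicate_results(100)
  coverage <- mean(unlist(purrr::map(res, "covered")))
  expect_gte(coverage, 0.90)
  expect_lte(coverage, 0.99)
  # 3-SE recovery, aggregated over parameters and replicates
  expect_gte(mean(unlist(purrr::map(res, "within3se"))), 0.94)
})

test_that("warnings and errors surface for deficient inputs", {
  cfg <- small_config(n = 80)
  st <- simulate_study(cfg, seed = 81)
  spec <- default_regression_spec(generative_config(n = 80))
  expect_warning(fit_copula_regression(simulate_study(generative_config(n = 120), seed = 5)$data, spec),
                 class = "bicopreg_smalln_warning")
  expect_error(fit_copula_regression(st$data[, 1:3], small_spec()),
               class = "bicopreg_schema_error")
})
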