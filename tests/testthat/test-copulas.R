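test_that("copula cdf is grounded, uniform-margined and matches quadrature", {
  # independence factorizes
  expect_equal(copula_cdf("gaussian", 0, u = c(0.3, 0.7)), 0.21,
               tolerance = 1e-9)
  # uniform margins and groundedness
  for (u in c(0.05, 0.364, 0.9)) {
    expect_equal(copula_cdf("gaussian", 0.364, u = c(u, 1)), u,
                 tolerance = 1e-9)
    expect_equal(copula_cdf("student_t", 0.364, 3, u = c(1, u)), u,
                 tolerance = 1e-9)
    expect_equal(copula_cdf("gaussian", 0.5, u = c(u, 0)), 0)
  }
  # independent 2-D numerical integration of the bivariate t (mvtnorm)
  for (pt in list(c(0.5, 0.5), c(0.1, 0.8), c(0.95, 0.05))) {
    ref <- mvtnorm::pmvt(
      upper = qt(pt, df = 3), df = 3,
      corr = matrix(c(1, 0.364, 0.364, 1), 2)
    )[1]
    expect_equal(copula_cdf("student_t", 0.364, 3, u = pt), ref,
                 tolerance = 1e-4)
  }
  # independent adaptive-quadrature oracle via the conditional form
  cdf_ref <- function(rho, u1, u2) {
    s <- sqrt(1 - rho^2)
    z2 <- qnorm(u2)
    integrate(function(t) dnorm(t) * pnorm((z2 - rho * t) / s),
              -Inf, qnorm(u1), rel.tol = 1e-12)$value
  }
  for (pt in list(c(0.3, 0.7), c(0.05, 0.9), c(0.99, 0.01))) {
    expect_equal(copula_cdf("gaussian", 0.364, u = pt),
                 cdf_ref(0.364, pt[1], pt[2]), tolerance = 1e-6)
  }
})

test_that("copula density matches closed forms and the cdf mixed derivative", {
  expect_equal(copula_density("gaussian", 0, u = c(0.5, 0.5)), 1.0)
  expect_equal(copula_density("gaussian", 0.364, u = c(0.5, 0.5)),
               1 / sqrt(1 - 0.364^2), tolerance = 1e-12)
  # central-difference second mixed derivative of the cdf
  h <- 1e-3
  for (pt in list(c(0.3, 0.6), c(0.5, 0.5), c(0.7, 0.2))) {
    num <- (copula_cdf("student_t", 0.5, 3, u = pt + c(h, h)) -
              copula_cdf("student_t", 0.5, 3, u = pt + c(h, -h)) -
              copula_cdf("student_t", 0.5, 3, u = pt + c(-h, h)) +
              copula_cdf("student_t", 0.5, 3, u = pt + c(-h, -h))) / (4 * h^2)
    expect_equal(copula_density("student_t", 0.5, 3, u = pt), num,
                 tolerance = 1e-3)
  }
})

test_that("copula density integrates to 1 over the unit square", {
  # substitution u = pnorm(z) turns the corner-singular integrand into a
  # smooth one; tensor Gauss-Legendre on the z scale
  gl <- pracma::gaussLegendre(120, -8, 8)
  uu <- pnorm(gl$x)
  w <- gl$w * dnorm(gl$x)
  grid <- cbind(rep(uu, each = length(uu)), rep(uu, times = length(uu)))
  wts <- rep(w, each = length(w)) * rep(w, times = length(w))
  for (rho in c(-0.8, 0, 0.364, 0.8)) {
    expect_equal(sum(copula_density("gaussian", rho, u = grid) * wts), 1,
                 tolerance = 1e-4)
    for (nu in c(3, 10)) {
      expect_equal(sum(copula_density("student_t", rho, nu, u = grid) * wts),
                   1, tolerance = 1e-4)
    }
  }
})

test_that("Frechet-Hoeffding bounds and exchangeability hold", {
  set.seed(1)
  pts <- matrix(runif(400), ncol = 2)
  for (fam in list(list("gaussian", NULL), list("student_t", 4))) {
    C <- copula_cdf(fam[[1]], 0.6, fam[[2]], pts)
    expect_true(all(C <= pmin(pts[, 1], pts[, 2]) + 1e-9))
    expect_true(all(C >= pmax(pts[, 1] + pts[, 2] - 1, 0) - 1e-9))
    # symmetry under swapping coordinates
    expect_equal(C, copula_cdf(fam[[1]], 0.6, fam[[2]], pts[, 2:1]),
                 tolerance = 1e-9)
    expect_equal(copula_density(fam[[1]], 0.6, fam[[2]], pts),
                 copula_density(fam[[1]], 0.6, fam[[2]], pts[, 2:1]),
                 tolerance = 1e-12)
  }
})

test_that("t copula approaches the gaussian as df grows", {
  g <- seq(0.05, 0.95, by = 0.05)
  grid <- cbind(rep(g, each = length(g)), rep(g, times = length(g)))
  for (rho in c(0.364, -0.5)) {
    expect_equal(copula_density("student_t", rho, 500, grid),
                 copula_density("gaussian", rho, u = grid),
                 tolerance = 1e-2)
  }
})

test_that("the sampler reproduces the elliptical Kendall tau identity", {
  # tau = (2/pi) asin(rho) for both elliptical families
  u <- sample_copula("gaussian", 0, n = 1e5, seed = 11)
  expect_lt(abs(kendall_tau(u$u1, u$u2)), 0.01)
  u <- sample_copula("student_t", 0.364, 3, n = 1e5, seed = 12)
  expect_lt(abs(kendall_tau(u$u1, u$u2) - (2 / pi) * asin(0.364)), 0.01)
  # copula margins are uniform: KS statistic below the 1% critical value
  u <- sample_copula("gaussian", 0.9, n = 1e4, seed = 13)
  for (col in list(u$u1, u$u2)) {
    ks <- max(abs(sort(col) - (seq_along(col) - 0.5) / length(col)))
    expect_lt(ks, 1.63 / sqrt(length(col)))
  }
  # reproducibility under the seed, without touching the caller's stream
  expect_identical(sample_copula("student_t", 0.5, 5, n = 100, seed = 9),
                   sample_copula("student_t", 0.5, 5, n = 100, seed = 9))
})

test_that("kendall_tau matches the quadratic-time reference implementation", {
  set.seed(21)
  for (i in 1:4) {
    n <- sample(10:300, 1)
    x <- rnorm(n)
    y <- 0.4 * x + rnorm(n)
    expect_equal(kendall_tau(x, y), cor(x, y, method = "kendall"),
                 tolerance = 1e-12)
  }
})

test_that("pseudo-observations use rank/(n+1) with average ranks for ties", {
  po <- pseudo_observations(cbind(c(1, 2, 3), c(10, 20, 30)))
  expect_equal(po$u1, c(0.25, 0.5, 0.75))
  expect_equal(po$u2, c(0.25, 0.5, 0.75))
  # invariance to strictly monotone transforms
  set.seed(2)
  m <- cbind(rexp(50), rexp(50))
  expect_equal(pseudo_observations(m),
               pseudo_observations(cbind(log(m[, 1]), m[, 2])))
  # ties share the average rank
  pot <- pseudo_observations(cbind(c(5, 5, 7, 9), 1:4))
  expect_equal(pot$u1, c(1.5 / 5, 1.5 / 5, 3 / 5, 4 / 5))
})

test_that("pseudo-MLE recovers copula parameters from its own sampler", {
  po <- pseudo_observations(sample_copula("gaussian", 0.5, n = 5000, seed = 31))
  fit <- fit_copula_pseudo_mle(po, "gaussian")
  expect_equal(fit$rho, 0.5, tolerance = 0.03)
  expect_equal(fit$aic, -2 * fit$loglik + 2)

  po <- pseudo_observations(sample_copula("student_t", 0.364, 3, n = 5000, seed = 32))
  fitt <- fit_copula_pseudo_mle(po, "student_t",
                                df_grid = c(2.1, 3, 4, 5, 6, 8, 10, 15, 20, 30))
  expect_equal(fitt$rho, 0.364, tolerance = 0.05)
  expect_lt(abs(fitt$df - 3), 1.5)
  expect_equal(fitt$aic, -2 * fitt$loglik + 4)

  # comonotone input pushes rho to the boundary and flags it
  x <- seq_len(200) / 201
  fitb <- fit_copula_pseudo_mle(cbind(x, x), "gaussian")
  expect_true(fitb$boundary)
  expect_gt(fitb$rho, 0.99)
})

test_that("family selection is consistent and honors the AIC tie-break", {
  sel_g <- vapply(1:10, function(i) {
    po <- pseudo_observations(sample_copula("gaussian", 0.4, n = 5000,
                                            seed = 300 + i))
    select_copula_family(po, df_grid = c(2.1, 3, 5, 10, 20),
                         refine_df = FALSE)$family
  }, character(1))
  expect_gte(mean(sel_g == "gaussian"), 0.7)
  sel_t <- vapply(1:10, function(i) {
    po <- pseudo_observations(sample_copula("student_t", 0.364, 3, n = 555,
                                            seed = 400 + i))
    select_copula_family(po, df_grid = c(2.1, 3, 5, 10, 20),
                         refine_df = FALSE)$family
  }, character(1))
  expect_gte(mean(sel_t == "student_t"), 0.7)
  # independence data: selected rho within sampling error of 0
  po <- pseudo_observations(sample_copula("gaussian", 0, n = 4000, seed = 55))
  expect_lt(abs(select_copula_family(po)$rho), 3 / sqrt(4000))
})

test_that("parameter validation rejects invalid copulas", {
  expect_error(copula_cdf("gaussian", 1.2, u = c(0.5, 0.5)),
               class = "bicopreg_domain_error")
  expect_error(copula_density("student_t", 0.5, 1.5, u = c(0.5, 0.5)),
               class = "bicopreg_domain_error")
  expect_error(copula_density("gaussian", 0.5, u = c(0, 0.5)),
               class = "bicopreg_domain_error")
  expect_error(fit_copula_pseudo_mle(cbind(c(0, 0.5), c(0.2, 0.7)), "gaussian"),
               class = "bicopreg_domain_error")
})

test_that("the CvM statistic is zero for a perfectly matching model", {
  set.seed(77)
  u <- as.matrix(pseudo_observations(cbind(rnorm(80), rnorm(80))))
  cn <- bicopreg:::empirical_copula(u)
  expect_equal(bicopreg:::cvm_statistic(u, cn), 0)
})

test_that("the bootstrap GoF test rejects a grossly misspecified copula", {
  # gaussian fit to strongly tail-dependent t data
  small_p <- vapply(1:3, function(i) {
    po <- pseudo_observations(
      sample_copula("student_t", 0.8, 2.5, n = 1000, seed = 600 + i)
    )
    fit <- fit_copula_pseudo_mle(po, "gaussian")
    gof_copula_cvm(fit, po, n_boot = 99, seed = 700 + i)$p_value
  }, numeric(1))
  expect_gte(mean(small_p < 0.05), 2 / 3)
  # low n_boot warns
  po <- pseudo_observations(sample_copula("gaussian", 0.3, n = 100, seed = 1))
  fit <- fit_copula_pseudo_mle(po, "gaussian")
  expect_warning(gof_copula_cvm(fit, po, n_boot = 20, seed = 2),
                 class = "bicopreg_config_warning")
})
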