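# Single-margin regression likelihoods used both by the independence
# baselines and as building blocks of the joint copula likelihood.
#
# Link conventions (constant dispersion throughout):
#   normal    : identity link, y ~ N(X b, sigma)         (the LM baseline)
#   lognormal : linear model for the log-scale location, y ~ LN(X b, sigma)
#   gamma     : log link for the mean with free shape a, y ~ Gamma(a, a/exp(X b))

regression_margin_families <- c("normal", "lognormal", "gamma")

margin_reg_logpdf <- function(family, y, eta, disp) {
  switch(family,
    normal    = dnorm(y, mean = eta, sd = disp, log = TRUE),
    lognormal = dlnorm(y, meanlog = eta, sdlog = disp, log = TRUE),
    gamma     = dgamma(y, shape = disp, rate = disp / exp(eta), log = TRUE)
  )
}

margin_reg_cdf <- function(family, y, eta, disp) {
  switch(family,
    normal    = pnorm(y, mean = eta, sd = disp),
    lognormal = plnorm(y, meanlog = eta, sdlog = disp),
    gamma     = pgamma(y, shape = disp, rate = disp / exp(eta))
  )
}

margin_reg_quantile <- function(family, p, eta, disp) {
  switch(family,
    normal    = qnorm(p, mean = eta, sd = disp),
    lognormal = qlnorm(p, meanlog = eta, sdlog = disp),
    gamma     = qgamma(p, shape = disp, rate = disp / exp(eta))
  )
}

margin_reg_mean <- function(family, eta, disp) {
  switch(family,
    normal    = eta,
    lognormal = exp(eta + disp^2 / 2),
    gamma     = exp(eta)
  )
}

check_reg_family <- function(family) {
  if (!family %in% regression_margin_families) {
    abort_config(sprintf(
      "margin family `%s` is not supported in the regression context (use %s).",
      family, paste(regression_margin_families, collapse = ", ")
    ))
  }
  family
}

# MLE of one margin regression; returns beta, dispersion, loglik, aic.
# normal/lognormal have closed forms (OLS on the appropriate scale with the
# MLE variance); gamma is maximized by BFGS from a glm()-style start.
fit_margin_regression <- function(y, X, family) {
  check_reg_family(family)
  n <- length(y)
  p <- ncol(X)
  if (family %in% c("normal", "lognormal")) {
    z <- if (family == "normal") y else log(y)
    qr_x <- qr(X)
    beta <- qr.coef(qr_x, z)
    res <- z - drop(X %*% beta)
    disp <- sqrt(mean(res^2))
    if (disp == 0) abort_fit("degenerate margin: zero residual variance.")
    loglik <- sum(margin_reg_logpdf(family, y, drop(X %*% beta), disp))
  } else {
    lz <- log(y)
    beta0 <- qr.coef(qr(X), lz)
    eta0 <- drop(X %*% beta0)
    a0 <- max(1 / max(var(y / exp(eta0)), 1e-8), 0.1)
    nll <- function(par) {
      eta <- drop(X %*% par[seq_len(p)])
      val <- -sum(suppressWarnings(
        margin_reg_logpdf("gamma", y, eta, exp(par[p + 1]))
      ))
      if (is.nan(val)) Inf else val
    }
    opt <- optim(c(beta0, log(a0)), nll, method = "BFGS",
                 control = list(maxit = 500, reltol = 1e-12))
    if (opt$convergence != 0) {
      abort_fit("gamma margin regression did not converge.", trace = opt)
    }
    beta <- opt$par[seq_len(p)]
    disp <- unname(exp(opt$par[p + 1]))
    loglik <- -opt$value
  }
  k <- p + 1
  list(
    family = family, beta = setNames(as.numeric(beta), colnames(X)),
    disp = disp, loglik = loglik, k = k, aic = -2 * loglik + 2 * k, n = n
  )
}
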