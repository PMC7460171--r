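# Analytic score of the joint copula-regression log-likelihood.
#
# All beta, dispersion and rho coordinates are exact; the derivative of
# the gamma CDF with respect to its shape (no closed form) and of the
# copula density with respect to the t degrees of freedom are central
# finite differences confined to those single coordinates. The score
# drives both the quasi-Newton optimizer and the observed-information
# matrix (central-difference Jacobian of the score), which keeps the
# joint fit orders of magnitude cheaper than differencing the likelihood
# coordinate-wise.

# per-observation d log f / d eta and d log f / d dispersion
margin_dlogf <- function(family, y, eta, disp) {
  switch(family,
    normal = {
      r <- (y - eta) / disp
      list(deta = r / disp, ddisp = (r^2 - 1) / disp)
    },
    lognormal = {
      r <- (log(y) - eta) / disp
      list(deta = r / disp, ddisp = (r^2 - 1) / disp)
    },
    gamma = {
      a <- disp
      rel <- y * exp(-eta)
      list(
        deta = a * (rel - 1),
        ddisp = log(a) + 1 - eta - digamma(a) + log(y) - rel
      )
    }
  )
}

# per-observation d F(y | eta, disp) / d eta and / d dispersion
margin_dcdf <- function(family, y, eta, disp) {
  switch(family,
    normal = {
      phi <- dnorm((y - eta) / disp)
      r <- (y - eta) / disp
      list(deta = -phi / disp, ddisp = -phi * r / disp)
    },
    lognormal = {
      r <- (log(y) - eta) / disp
      phi <- dnorm(r)
      list(deta = -phi / disp, ddisp = -phi * r / disp)
    },
    gamma = {
      a <- disp
      s <- a * y * exp(-eta)
      # d/da of pgamma(y; a, a e^-eta): no closed form, central difference
      h <- 1e-6 * (1 + a)
      dda <- (pgamma(y, a + h, rate = (a + h) * exp(-eta)) -
                pgamma(y, a - h, rate = (a - h) * exp(-eta))) / (2 * h)
      list(deta = -dgamma(s, a, rate = 1) * s, ddisp = dda)
    }
  )
}

# per-observation d log c(u1, u2) / du1, du2, drho (+ dnu numerically)
copula_dlogdensity <- function(family, rho, df, u1, u2, want_df = FALSE) {
  r2 <- 1 - rho^2
  if (family == "gaussian") {
    z1 <- qnorm(u1)
    z2 <- qnorm(u2)
    du1 <- rho * (z2 - rho * z1) / r2 / dnorm(z1)
    du2 <- rho * (z1 - rho * z2) / r2 / dnorm(z2)
    drho <- rho / r2 +
      (z1 * z2 * (1 + rho^2) - rho * (z1^2 + z2^2)) / r2^2
    list(du1 = du1, du2 = du2, drho = drho, ddf = NULL)
  } else {
    x1 <- qt(u1, df)
    x2 <- qt(u2, df)
    q <- (x1^2 - 2 * rho * x1 * x2 + x2^2) / r2
    dx1 <- -(df + 2) * (x1 - rho * x2) / (r2 * (df + q)) +
      (df + 1) * x1 / (df + x1^2)
    dx2 <- -(df + 2) * (x2 - rho * x1) / (r2 * (df + q)) +
      (df + 1) * x2 / (df + x2^2)
    drho <- rho / r2 -
      (df + 2) * (rho * (x1^2 + x2^2) - x1 * x2 * (1 + rho^2)) /
        (r2^2 * (df + q))
    ddf <- NULL
    if (want_df) {
      h <- 1e-5 * (1 + df)
      ddf <- (copula_logdensity("student_t", rho, df + h, u1, u2) -
                copula_logdensity("student_t", rho, df - h, u1, u2)) / (2 * h)
    }
    list(du1 = dx1 / dt(x1, df), du2 = dx2 / dt(x2, df),
         drho = drho, ddf = ddf)
  }
}

# score (gradient of the joint log-likelihood) on the original scale;
# clamped PITs contribute no copula-derivative term (the clamp is flat)
joint_score <- function(spec, params, y1, y2, X1, X2, info) {
  disp1 <- params[info$i_disp1]
  disp2 <- params[info$i_disp2]
  rho <- params[info$i_rho]
  df <- if (!is.null(info$i_df)) params[info$i_df] else spec$df
  eta1 <- drop(X1 %*% params[info$i_beta1])
  eta2 <- drop(X2 %*% params[info$i_beta2])

  u1 <- margin_reg_cdf(spec$margin1, y1, eta1, disp1)
  u2 <- margin_reg_cdf(spec$margin2, y2, eta2, disp2)
  in1 <- u1 >= pit_clamp & u1 <= 1 - pit_clamp
  in2 <- u2 >= pit_clamp & u2 <= 1 - pit_clamp
  u1c <- pmin(pmax(u1, pit_clamp), 1 - pit_clamp)
  u2c <- pmin(pmax(u2, pit_clamp), 1 - pit_clamp)

  dl1 <- margin_dlogf(spec$margin1, y1, eta1, disp1)
  dl2 <- margin_dlogf(spec$margin2, y2, eta2, disp2)
  dF1 <- margin_dcdf(spec$margin1, y1, eta1, disp1)
  dF2 <- margin_dcdf(spec$margin2, y2, eta2, disp2)
  dc <- copula_dlogdensity(spec$copula, rho, df, u1c, u2c,
                           want_df = !is.null(info$i_df))

  w1 <- dc$du1 * in1 # no propagation through a clamped PIT
  w2 <- dc$du2 * in2

  g <- numeric(info$k)
  g[info$i_beta1] <- drop(crossprod(X1, dl1$deta + w1 * dF1$deta))
  g[info$i_disp1] <- sum(dl1$ddisp + w1 * dF1$ddisp)
  g[info$i_beta2] <- drop(crossprod(X2, dl2$deta + w2 * dF2$deta))
  g[info$i_disp2] <- sum(dl2$ddisp + w2 * dF2$ddisp)
  g[info$i_rho] <- sum(dc$drho)
  if (!is.null(info$i_df)) g[info$i_df] <- sum(dc$ddf)
  g
}

# observed information: symmetrized central-difference Jacobian of the
# analytic score at the optimum, on the original parameter scale
joint_observed_information <- function(spec, params, y1, y2, X1, X2, info) {
  k <- info$k
  H <- matrix(NA_real_, k, k)
  h <- 1e-5 * (1 + abs(params))
  for (j in seq_len(k)) {
    up <- params
    dn <- params
    up[j] <- up[j] + h[j]
    dn[j] <- dn[j] - h[j]
    H[, j] <- -(joint_score(spec, up, y1, y2, X1, X2, info) -
                  joint_score(spec, dn, y1, y2, X1, X2, info)) / (2 * h[j])
  }
  (H + t(H)) / 2
}
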