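#' Declare a bivariate copula regression model
#'
#' A `copreg_spec` names the marginal family and covariate list for each
#' outcome and the copula that couples them. Margin 1 is the internet-
#' addiction score (Y-IAT) analogue, margin 2 the smartphone-addiction
#' (SAS) analogue, but any pair of positive outcomes fits the scheme.
#'
#' @param margin1,margin2 Marginal families, one of `"normal"`,
#'   `"lognormal"`, `"gamma"`.
#' @param covariates1,covariates2 Character vectors of covariate column
#'   names (may be `character(0)` for an intercept-only margin; an
#'   intercept is always included).
#' @param copula `"gaussian"` or `"student_t"`.
#' @param df Degrees of freedom for the t copula (used when
#'   `df_mode = "fixed"`, the default two-stage flow: select the family and
#'   df first, then regress).
#' @param df_mode `"fixed"` or `"estimated"` (df re-estimated inside the
#'   joint likelihood).
#' @param outcome1,outcome2 Names of the outcome columns in the data.
#' @return A `copreg_spec` object.
#' @examples
#' copreg_spec("lognormal", "gamma", c("GENDER", "BAI"), c("GENDER", "BAI"))
#' @export
copreg_spec <- function(margin1, margin2, covariates1, covariates2,
                        copula = "student_t", df = 3,
                        df_mode = c("fixed", "estimated"),
                        outcome1 = "y1", outcome2 = "y2") {
  df_mode <- match.arg(df_mode)
  check_reg_family(margin1)
  check_reg_family(margin2)
  if (!copula %in% c("gaussian", "student_t")) {
    abort_config('`copula` must be "gaussian" or "student_t".')
  }
  if (copula == "student_t" && df_mode == "fixed") {
    check_copula_params(copula, 0, df)
  }
  structure(
    list(
      margin1 = margin1, margin2 = margin2,
      covariates1 = as.character(covariates1),
      covariates2 = as.character(covariates2),
      copula = copula, df = if (copula == "student_t") df else NULL,
      df_mode = df_mode, outcome1 = outcome1, outcome2 = outcome2
    ),
    class = "copreg_spec"
  )
}

#' @export
print.copreg_spec <- function(x, ...) {
  cat(sprintf(
    "<copreg_spec> %s: %s(%s) x %s(%s), %s copula%s\n",
    paste(x$outcome1, x$outcome2, sep = " + "),
    x$margin1, paste(x$covariates1, collapse = ", "),
    x$margin2, paste(x$covariates2, collapse = ", "),
    x$copula,
    if (x$copula == "student_t") {
      sprintf(" (df %s%s)", if (x$df_mode == "fixed") "fixed at " else "estimated, start ",
              format(x$df))
    } else ""
  ))
  invisible(x)
}

spec_param_info <- function(spec, X1, X2) {
  p1 <- ncol(X1)
  p2 <- ncol(X2)
  nm <- c(
    paste0("m1_", colnames(X1)), "m1_dispersion",
    paste0("m2_", colnames(X2)), "m2_dispersion",
    "rho",
    if (spec$copula == "student_t" && spec$df_mode == "estimated") "df"
  )
  list(
    p1 = p1, p2 = p2, k = length(nm), names = nm,
    i_beta1 = seq_len(p1), i_disp1 = p1 + 1,
    i_beta2 = p1 + 1 + seq_len(p2), i_disp2 = p1 + p2 + 2,
    i_rho = p1 + p2 + 3,
    i_df = if (spec$copula == "student_t" && spec$df_mode == "estimated") {
      p1 + p2 + 4
    }
  )
}

build_design <- function(data, covariates, centers = NULL) {
  X <- cbind("(Intercept)" = rep(1, nrow(data)))
  for (v in covariates) {
    if (!v %in% names(data)) {
      abort_schema(sprintf("covariate `%s` not found in `data`.", v))
    }
    col <- as.numeric(data[[v]])
    if (!is.null(centers) && v %in% names(centers)) col <- col - centers[[v]]
    X <- cbind(X, col)
  }
  colnames(X) <- c("(Intercept)", covariates)
  X
}

pit_clamp <- 1e-10

#' Joint log-likelihood of the bivariate copula regression
#'
#' Evaluates `sum(log c(F1(y1 | x), F2(y2 | x)) + log f1(y1 | x) +
#' log f2(y2 | x))`: the copula density on the probability-integral
#' transforms of each margin plus the marginal log-densities (the Sklar
#' decomposition of the joint density). PITs that underflow to 0 or 1 are
#' clamped to `[1e-10, 1 - 1e-10]`; the number of clamped values is
#' attached as attribute `n_clamped`.
#'
#' @param spec A [copreg_spec()].
#' @param params Full parameter vector on the original scale, in the order
#'   (beta1, dispersion1, beta2, dispersion2, rho, df-if-estimated).
#' @param data Data frame with the outcome and covariate columns.
#' @return The joint log-likelihood (scalar) with attribute `n_clamped`.
#' @export
joint_loglik <- function(spec, params, data) {
  X1 <- build_design(data, spec$covariates1)
  X2 <- build_design(data, spec$covariates2)
  info <- spec_param_info(spec, X1, X2)
  if (length(params) != info$k) {
    abort_domain(sprintf("`params` must have length %d.", info$k))
  }
  y1 <- data[[spec$outcome1]]
  y2 <- data[[spec$outcome2]]
  joint_loglik_impl(spec, params, y1, y2, X1, X2, info)
}

joint_loglik_impl <- function(spec, params, y1, y2, X1, X2, info) {
  disp1 <- params[info$i_disp1]
  disp2 <- params[info$i_disp2]
  rho <- params[info$i_rho]
  df <- if (!is.null(info$i_df)) params[info$i_df] else spec$df
  if (disp1 <= 0 || disp2 <= 0 || abs(rho) >= 1 ||
      (spec$copula == "student_t" && df <= 2)) {
    return(structure(-Inf, n_clamped = 0L))
  }
  if (any(!is.finite(params))) {
    return(structure(-Inf, n_clamped = 0L))
  }
  eta1 <- drop(X1 %*% params[info$i_beta1])
  eta2 <- drop(X2 %*% params[info$i_beta2])
  # line-search excursions can overflow the gamma rate: the NaNs collapse
  # to -Inf below, so their warnings are suppressed
  ll1 <- suppressWarnings(margin_reg_logpdf(spec$margin1, y1, eta1, disp1))
  ll2 <- suppressWarnings(margin_reg_logpdf(spec$margin2, y2, eta2, disp2))
  u1 <- suppressWarnings(margin_reg_cdf(spec$margin1, y1, eta1, disp1))
  u2 <- suppressWarnings(margin_reg_cdf(spec$margin2, y2, eta2, disp2))
  if (anyNA(u1) || anyNA(u2)) {
    return(structure(-Inf, n_clamped = 0L))
  }
  n_clamped <- sum(u1 < pit_clamp | u1 > 1 - pit_clamp |
                     u2 < pit_clamp | u2 > 1 - pit_clamp)
  u1 <- pmin(pmax(u1, pit_clamp), 1 - pit_clamp)
  u2 <- pmin(pmax(u2, pit_clamp), 1 - pit_clamp)
  lc <- copula_logdensity(spec$copula, rho, df, u1, u2)
  val <- sum(ll1) + sum(ll2) + sum(lc)
  if (!is.finite(val)) val <- -Inf
  structure(val, n_clamped = as.integer(n_clamped))
}

# original scale <-> unconstrained optimizer scale
transform_params <- function(spec, params, info) {
  out <- params
  out[info$i_disp1] <- log(params[info$i_disp1])
  out[info$i_disp2] <- log(params[info$i_disp2])
  out[info$i_rho] <- atanh(params[info$i_rho])
  if (!is.null(info$i_df)) out[info$i_df] <- log(params[info$i_df] - 2)
  out
}
untransform_params <- function(spec, tpar, info) {
  out <- tpar
  out[info$i_disp1] <- exp(tpar[info$i_disp1])
  out[info$i_disp2] <- exp(tpar[info$i_disp2])
  out[info$i_rho] <- tanh(tpar[info$i_rho])
  if (!is.null(info$i_df)) out[info$i_df] <- 2 + exp(tpar[info$i_df])
  out
}

#' Fit the bivariate copula regression by joint maximum likelihood
#'
#' Maximizes [joint_loglik()] over all marginal coefficients, dispersions
#' and the copula parameter(s). Optimization runs on unconstrained
#' transforms (log dispersions, `atanh(rho)`, `log(df - 2)`) and is
#' warm-started by two-stage estimation: each margin is fitted
#' independently, the copula is fitted to the parametric
#' probability-integral transforms of those margin fits, then everything is
#' refined jointly (BFGS). Standard errors are the inverse observed
#' information — a central-difference numerical Hessian of the negative
#' log-likelihood at the optimum, on the original parameter scale — with
#' Wald p-values from the normal reference and a Fisher-z interval for the
#' copula correlation.
#'
#' @param data Data frame with outcome and covariate columns (complete
#'   cases only; rows with a missing outcome are dropped with a message).
#' @param spec A [copreg_spec()].
#' @param center Covariates to center at their sample mean before fitting
#'   (numerical conditioning for large-magnitude covariates such as birth
#'   year; coefficients are unchanged, the intercept is reported on the
#'   centered scale). Defaults to `"YEAR"` when present.
#' @param init Optional full initial parameter vector (original scale);
#'   overrides the two-stage warm start.
#' @param level Confidence level for the correlation interval.
#' @param control Passed to [stats::optim()] (method BFGS).
#' @return A `copula_regression_fit`; see [tidy.copula_regression_fit()],
#'   [glance.copula_regression_fit()], [conditional_mean()],
#'   [correlation_ci()] and [autoplot.copula_regression_fit()].
#' @export
fit_copula_regression <- function(data, spec, center = intersect("YEAR", names(data)),
                                  init = NULL, level = 0.95,
                                  control = list()) {
  if (!inherits(spec, "copreg_spec")) abort_config("`spec` must be a copreg_spec.")
  need <- unique(c(spec$outcome1, spec$outcome2, spec$covariates1, spec$covariates2))
  miss <- setdiff(need, names(data))
  if (length(miss)) {
    abort_schema(paste0("missing columns: ", paste(miss, collapse = ", ")))
  }
  keep <- complete.cases(data[, need, drop = FALSE])
  if (!all(keep)) {
    message(sprintf("dropping %d incomplete rows.", sum(!keep)))
    data <- data[keep, , drop = FALSE]
  }
  n <- nrow(data)
  centers <- NULL
  center <- intersect(center, names(data))
  if (length(center)) {
    centers <- purrr::map(setNames(center, center), ~ mean(as.numeric(data[[.x]])))
  }
  X1 <- build_design(data, spec$covariates1, centers)
  X2 <- build_design(data, spec$covariates2, centers)
  info <- spec_param_info(spec, X1, X2)
  if (n < 10 * info$k) {
    warn(sprintf(
      "n = %d is below 10 parameters-worth of data (k = %d); estimates may be unstable.",
      n, info$k
    ), class = "bicopreg_smalln_warning")
  }
  y1 <- data[[spec$outcome1]]
  y2 <- data[[spec$outcome2]]
  for (y in list(y1, y2)) {
    if (!is.numeric(y) || any(!is.finite(y))) {
      abort_schema("outcomes must be finite numerics.")
    }
  }

  # two-stage (inference-functions-for-margins) warm start
  if (is.null(init)) {
    f1 <- fit_margin_regression(y1, X1, spec$margin1)
    f2 <- fit_margin_regression(y2, X2, spec$margin2)
    u1 <- margin_reg_cdf(spec$margin1, y1, drop(X1 %*% f1$beta), f1$disp)
    u2 <- margin_reg_cdf(spec$margin2, y2, drop(X2 %*% f2$beta), f2$disp)
    uu <- cbind(
      pmin(pmax(u1, pit_clamp), 1 - pit_clamp),
      pmin(pmax(u2, pit_clamp), 1 - pit_clamp)
    )
    cop0 <- fit_copula_pseudo_mle(uu, spec$copula, df = spec$df)
    init <- c(
      f1$beta, f1$disp, f2$beta, f2$disp, cop0$rho,
      if (!is.null(info$i_df)) spec$df %||% 5
    )
  }
  if (length(init) != info$k) {
    abort_config(sprintf("`init` must have length %d.", info$k))
  }

  ll0 <- joint_loglik_impl(spec, init, y1, y2, X1, X2, info)
  if (!is.finite(ll0)) abort_fit("initial parameter vector has -Inf likelihood.")

  nll_t <- function(tpar) {
    -as.numeric(joint_loglik_impl(
      spec, untransform_params(spec, tpar, info), y1, y2, X1, X2, info
    ))
  }
  # chain rule from the original-scale analytic score to the optimizer scale
  gr_t <- function(tpar) {
    p <- untransform_params(spec, tpar, info)
    g <- joint_score(spec, p, y1, y2, X1, X2, info)
    g[info$i_disp1] <- g[info$i_disp1] * p[info$i_disp1]
    g[info$i_disp2] <- g[info$i_disp2] * p[info$i_disp2]
    g[info$i_rho] <- g[info$i_rho] * (1 - p[info$i_rho]^2)
    if (!is.null(info$i_df)) {
      g[info$i_df] <- g[info$i_df] * (p[info$i_df] - 2)
    }
    -g
  }
  ctrl <- utils::modifyList(list(maxit = 400, reltol = 1e-12), control)
  opt <- optim(transform_params(spec, init, info), nll_t, gr = gr_t,
               method = "BFGS", control = ctrl)
  if (opt$convergence != 0 && opt$convergence != 1) {
    abort_fit("joint copula regression did not converge.", trace = opt)
  }
  est <- untransform_params(spec, opt$par, info)
  names(est) <- info$names
  ll_fin <- joint_loglik_impl(spec, est, y1, y2, X1, X2, info)
  loglik <- as.numeric(ll_fin)

  # observed information on the original scale
  hess <- joint_observed_information(spec, est, y1, y2, X1, X2, info)
  vc <- tryCatch(solve(hess), error = function(e) NULL)
  se_ok <- !is.null(vc) && all(is.finite(diag(vc))) && all(diag(vc) > 0)
  if (se_ok) {
    se <- sqrt(diag(vc))
  } else {
    warn("singular observed information: standard errors unavailable.",
         class = "bicopreg_inference_warning")
    se <- rep(NA_real_, info$k)
    vc <- matrix(NA_real_, info$k, info$k)
  }
  names(se) <- info$names

  rho <- est[info$i_rho]
  se_rho <- se[info$i_rho]
  rho_ci <- fisher_z_ci(rho, se_rho, level)

  structure(
    list(
      spec = spec, n = n, centers = centers,
      params = est, se = se, vcov = vc, info = info,
      beta1 = est[info$i_beta1], sigma1 = est[info$i_disp1],
      beta2 = est[info$i_beta2], sigma2 = est[info$i_disp2],
      rho = unname(rho), df = if (!is.null(info$i_df)) unname(est[info$i_df]) else spec$df,
      rho_ci = rho_ci, ci_level = level,
      loglik = loglik, aic = -2 * loglik + 2 * info$k, k = info$k,
      n_clamped = attr(ll_fin, "n_clamped"),
      init = init, init_loglik = as.numeric(ll0),
      convergence = opt$convergence, design_names = list(colnames(X1), colnames(X2))
    ),
    class = "copula_regression_fit"
  )
}

fisher_z_ci <- function(rho, se_rho, level = 0.95) {
  rho <- unname(rho)
  se_rho <- unname(se_rho)
  if (!is.finite(se_rho)) {
    return(c(lower = NA_real_, upper = NA_real_))
  }
  z <- atanh(rho)
  se_z <- se_rho / (1 - rho^2) # delta method on the z scale
  q <- qnorm(1 - (1 - level) / 2)
  c(lower = tanh(z - q * se_z), upper = tanh(z + q * se_z))
}

#' Confidence interval for the copula correlation
#'
#' Fisher z-transform Wald interval `tanh(atanh(rho) +/- z * se_z)`; the
#' endpoints always lie inside (-1, 1).
#'
#' @param fit A `copula_regression_fit`.
#' @param level Confidence level.
#' @return Named numeric vector `c(lower, upper)`.
#' @export
correlation_ci <- function(fit, level = 0.95) {
  if (!inherits(fit, "copula_regression_fit")) {
    abort_domain("`fit` must be a copula_regression_fit.")
  }
  se_rho <- fit$se[fit$info$i_rho]
  if (!is.finite(se_rho)) abort_inference("no standard error available for rho.")
  fisher_z_ci(fit$rho, se_rho, level)
}

#' Wald coefficient table
#'
#' Per-coefficient estimates, standard errors, z statistics and two-sided
#' normal-reference p-values `2 * (1 - pnorm(|estimate / se|))` for both
#' margins, the dispersions and the copula parameter(s). `tidy()` on the
#' fit returns the same table.
#'
#' @param fit A `copula_regression_fit`.
#' @return A tibble with columns `margin`, `term`, `estimate`,
#'   `std.error`, `statistic`, `p.value`.
#' @export
wald_inference <- function(fit) {
  if (!inherits(fit, "copula_regression_fit")) {
    abort_domain("`fit` must be a copula_regression_fit.")
  }
  info <- fit$info
  margin <- character(info$k)
  margin[c(info$i_beta1, info$i_disp1)] <- fit$spec$outcome1
  margin[c(info$i_beta2, info$i_disp2)] <- fit$spec$outcome2
  margin[info$i_rho] <- "copula"
  if (!is.null(info$i_df)) margin[info$i_df] <- "copula"
  term <- sub("^m[12]_", "", info$names)
  z <- unname(fit$params / fit$se)
  tibble::tibble(
    margin = margin, term = term,
    estimate = unname(fit$params), std.error = unname(fit$se),
    statistic = z, p.value = 2 * pnorm(-abs(z))
  )
}

#' @rdname wald_inference
#' @param x A `copula_regression_fit`.
#' @param ... Unused.
#' @export
tidy.copula_regression_fit <- function(x, ...) wald_inference(x)

#' One-row model summary
#'
#' @param x A `copula_regression_fit`.
#' @param ... Unused.
#' @return A tibble with log-likelihood, AIC, the copula correlation and
#'   its confidence interval, degrees of freedom and sample size.
#' @export
glance.copula_regression_fit <- function(x, ...) {
  tibble::tibble(
    logLik = x$loglik, AIC = x$aic, rho = x$rho,
    rho.lower = x$rho_ci[["lower"]], rho.upper = x$rho_ci[["upper"]],
    df = x$df %||% NA_real_, nobs = x$n, n.params = x$k,
    n.clamped = x$n_clamped
  )
}

#' Conditional mean prediction for both outcomes
#'
#' Margin-wise expectations given a covariate row: `exp(x'b + sigma^2/2)`
#' for a log-normal margin, `exp(x'b)` for a gamma margin (log link),
#' `x'b` for a normal margin. Centering applied during fitting is replayed
#' on the new data.
#'
#' @param fit A `copula_regression_fit`.
#' @param newdata Data frame of covariate rows.
#' @return A tibble with the predicted mean of each outcome per row.
#' @export
conditional_mean <- function(fit, newdata) {
  if (!inherits(fit, "copula_regression_fit")) {
    abort_domain("`fit` must be a copula_regression_fit.")
  }
  need <- unique(c(fit$spec$covariates1, fit$spec$covariates2))
  miss <- setdiff(need, names(newdata))
  if (length(miss)) {
    abort(paste0("missing covariate values: ", paste(miss, collapse = ", ")),
          class = "bicopreg_prediction_error")
  }
  if (anyNA(newdata[, need, drop = FALSE])) {
    abort("missing covariate values in `newdata`.",
          class = "bicopreg_prediction_error")
  }
  X1 <- build_design(newdata, fit$spec$covariates1, fit$centers)
  X2 <- build_design(newdata, fit$spec$covariates2, fit$centers)
  out <- tibble::tibble(
    margin_reg_mean(fit$spec$margin1, drop(X1 %*% fit$beta1), fit$sigma1),
    margin_reg_mean(fit$spec$margin2, drop(X2 %*% fit$beta2), fit$sigma2)
  )
  names(out) <- paste0(".mean_", c(fit$spec$outcome1, fit$spec$outcome2))
  out
}

#' @export
predict.copula_regression_fit <- function(object, newdata, ...) {
  conditional_mean(object, newdata)
}

#' @export
print.copula_regression_fit <- function(x, ...) {
  cat(sprintf(
    "<copula_regression_fit> %s(%s) x %s(%s), %s copula%s\n",
    x$spec$outcome1, x$spec$margin1, x$spec$outcome2, x$spec$margin2,
    x$spec$copula,
    if (!is.null(x$df)) sprintf(" (df = %.2f)", x$df) else ""
  ))
  cat(sprintf(
    "n = %d, logLik = %.3f, AIC = %.3f\nrho = %.3f (%d%% CI %.3f, %.3f)\n",
    x$n, x$loglik, x$aic, x$rho, round(100 * x$ci_level),
    x$rho_ci[["lower"]], x$rho_ci[["upper"]]
  ))
  print(as.data.frame(wald_inference(x)), digits = 4)
  invisible(x)
}

#' Forest plot of copula-regression coefficients
#'
#' Point estimates with Wald intervals (estimate +/- z * SE) per margin,
#' excluding intercepts and dispersions — the coefficient-plot view of the
#' fitted model.
#'
#' @param object A `copula_regression_fit`.
#' @param level Interval level.
#' @param ... Unused.
#' @return A ggplot object.
#' @export
autoplot.copula_regression_fit <- function(object, level = 0.95, ...) {
  q <- qnorm(1 - (1 - level) / 2)
  td <- wald_inference(object) |>
    dplyr::filter(!.data$term %in% c("(Intercept)", "dispersion", "rho", "df"))
  ggplot2::ggplot(td, ggplot2::aes(x = .data$estimate, y = .data$term)) +
    ggplot2::geom_vline(xintercept = 0, linetype = 2, colour = "grey50") +
    ggplot2::geom_errorbarh(
      ggplot2::aes(xmin = .data$estimate - q * .data$std.error,
                   xmax = .data$estimate + q * .data$std.error),
      height = 0.2
    ) +
    ggplot2::geom_point() +
    ggplot2::facet_wrap(~margin, scales = "free_x") +
    ggplot2::labs(x = "coefficient (link scale)", y = NULL)
}
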