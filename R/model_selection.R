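#' Independence baselines: per-outcome regressions summed by AIC
#'
#' Fits the two outcome regressions separately (assuming independence) and
#' totals their AICs, the comparison baseline for the copula model. Mode
#' `"lm"` covers the linear-regression baselines (normal margin by least
#' squares; log-normal margin as a linear model for the log outcome, with
#' the Jacobian term so AIC stays on the outcome scale). Mode `"glm"`
#' covers the generalized-linear baselines (log-normal or gamma margins by
#' maximum likelihood, gamma with a log link).
#'
#' @param data Data frame (complete cases used).
#' @param margin1,margin2 Marginal families per outcome.
#' @param covariates1,covariates2 Covariate names per outcome.
#' @param mode `"lm"` or `"glm"` — which baseline class the family pair
#'   must belong to.
#' @param outcome1,outcome2 Outcome column names.
#' @param center As in [fit_copula_regression()].
#' @return An `independent_fit` with the two margin fits and
#'   `total_aic = AIC1 + AIC2`.
#' @export
fit_independent_margins <- function(data, margin1, margin2,
                                    covariates1, covariates2,
                                    mode = c("glm", "lm"),
                                    outcome1 = "y1", outcome2 = "y2",
                                    center = intersect("YEAR", names(data))) {
  mode <- match.arg(mode)
  allowed <- if (mode == "lm") c("normal", "lognormal") else c("lognormal", "gamma")
  for (f in c(margin1, margin2)) {
    if (!f %in% allowed) {
      abort_config(sprintf(
        'family "%s" is not available in mode "%s" (allowed: %s).',
        f, mode, paste(allowed, collapse = ", ")
      ))
    }
  }
  need <- unique(c(outcome1, outcome2, covariates1, covariates2))
  data <- data[complete.cases(data[, need, drop = FALSE]), , drop = FALSE]
  centers <- NULL
  center <- intersect(center, names(data))
  if (length(center)) {
    centers <- purrr::map(setNames(center, center), ~ mean(as.numeric(data[[.x]])))
  }
  X1 <- build_design(data, covariates1, centers)
  X2 <- build_design(data, covariates2, centers)
  f1 <- fit_margin_regression(data[[outcome1]], X1, margin1)
  f2 <- fit_margin_regression(data[[outcome2]], X2, margin2)
  structure(
    list(
      mode = mode, fit1 = f1, fit2 = f2,
      total_aic = f1$aic + f2$aic,
      total_loglik = f1$loglik + f2$loglik,
      k = f1$k + f2$k, n = nrow(data)
    ),
    class = "independent_fit"
  )
}

#' @export
print.independent_fit <- function(x, ...) {
  cat(sprintf(
    "<independent_fit> mode %s: %s + %s, total AIC = %.3f (n = %d)\n",
    x$mode, x$fit1$family, x$fit2$family, x$total_aic, x$n
  ))
  invisible(x)
}

#' Default candidate grid for the model comparison
#'
#' The twelve model configurations of the comparison stage: four
#' linear-regression rows (normal/log-normal margin pairs), four GLM rows
#' (log-normal/gamma pairs) and four copula rows (Gaussian and Student-t
#' over the leading margin pairs).
#'
#' @param df Degrees of freedom for the t-copula candidates.
#' @return A list of candidate descriptions for [compare_models()].
#' @export
default_candidates <- function(df = 3) {
  lm_pairs <- list(
    c("normal", "normal"), c("lognormal", "lognormal"),
    c("normal", "lognormal"), c("lognormal", "normal")
  )
  glm_pairs <- list(
    c("lognormal", "lognormal"), c("gamma", "gamma"),
    c("lognormal", "gamma"), c("gamma", "lognormal")
  )
  cop <- list(
    list(m = c("lognormal", "gamma"), copula = "gaussian"),
    list(m = c("lognormal", "lognormal"), copula = "student_t"),
    list(m = c("lognormal", "gamma"), copula = "student_t"),
    list(m = c("gamma", "lognormal"), copula = "student_t")
  )
  c(
    purrr::map(lm_pairs, ~ list(type = "lm", margin1 = .x[1], margin2 = .x[2])),
    purrr::map(glm_pairs, ~ list(type = "glm", margin1 = .x[1], margin2 = .x[2])),
    purrr::map(cop, ~ list(
      type = "copula", margin1 = .x$m[1], margin2 = .x$m[2],
      copula = .x$copula, df = df
    ))
  )
}

candidate_label <- function(cand) {
  paste0(
    cand$type, ":", cand$margin1, "+", cand$margin2,
    if (identical(cand$type, "copula")) paste0("+", cand$copula) else ""
  )
}

#' Compare independence and copula models by total AIC
#'
#' Fits every candidate (independence baselines via
#' [fit_independent_margins()], copula candidates via
#' [fit_copula_regression()]) on the same data and covariate sets and
#' returns one row per candidate sorted by total AIC. Ties break toward
#' fewer parameters, then lexicographic label; candidates whose fit fails
#' are flagged (`converged = FALSE`, AIC `NA`) and sort last.
#'
#' @param data Data frame.
#' @param covariates1,covariates2 Covariate names per outcome.
#' @param candidates List of candidate descriptions (see
#'   [default_candidates()]).
#' @param outcome1,outcome2 Outcome column names.
#' @return A tibble with columns `model`, `type`, `margin1`, `margin2`,
#'   `copula`, `k`, `total_aic`, `converged`.
#' @export
compare_models <- function(data, covariates1, covariates2,
                           candidates = default_candidates(),
                           outcome1 = "y1", outcome2 = "y2") {
  if (length(candidates) < 2) abort_config("need at least 2 candidates.")
  rows <- purrr::map(candidates, function(cand) {
    label <- candidate_label(cand)
    res <- tryCatch(
      {
        if (cand$type == "copula") {
          spec <- copreg_spec(cand$margin1, cand$margin2, covariates1,
                              covariates2, copula = cand$copula,
                              df = cand$df %||% 3,
                              outcome1 = outcome1, outcome2 = outcome2)
          fit <- fit_copula_regression(data, spec)
          list(aic = fit$aic, k = fit$k, ok = TRUE)
        } else {
          fit <- fit_independent_margins(
            data, cand$margin1, cand$margin2, covariates1, covariates2,
            mode = cand$type, outcome1 = outcome1, outcome2 = outcome2
          )
          list(aic = fit$total_aic, k = fit$k, ok = TRUE)
        }
      },
      error = function(e) {
        warn(sprintf("candidate %s failed: %s", label, conditionMessage(e)),
             class = "bicopreg_candidate_warning")
        list(aic = NA_real_, k = NA_integer_, ok = FALSE)
      }
    )
    tibble::tibble(
      model = label, type = cand$type,
      margin1 = cand$margin1, margin2 = cand$margin2,
      copula = if (cand$type == "copula") cand$copula else NA_character_,
      k = res$k, total_aic = res$aic, converged = res$ok
    )
  })
  dplyr::bind_rows(rows) |>
    dplyr::arrange(!.data$converged + 0, .data$total_aic, .data$k, .data$model)
}

#' Backward elimination of covariates by joint-model AIC
#'
#' Starting from the full model, repeatedly refits the joint copula
#' regression with each single covariate removed from one margin at a time
#' and applies the removal giving the largest AIC decrease; stops when no
#' removal lowers the AIC. Intercepts are never candidates. A removal
#' whose refit fails is skipped (recorded in `skipped`).
#'
#' @param data Data frame.
#' @param spec Full-model [copreg_spec()].
#' @param scope Covariates eligible for removal; default all covariates of
#'   either margin.
#' @param max_steps Safety cap on elimination steps.
#' @param verbose Print each removal.
#' @return A list of class `elimination_result`: `spec` (final),
#'   `initial_fit`, `final_fit`, `trace` (tibble: step, margin, term,
#'   aic_before, aic_after) and `skipped`.
#' @export
backward_eliminate <- function(data, spec, scope = NULL, max_steps = 50,
                               verbose = FALSE) {
  if (!inherits(spec, "copreg_spec")) abort_config("`spec` must be a copreg_spec.")
  scope <- scope %||% unique(c(spec$covariates1, spec$covariates2))
  if (!length(scope)) abort_config("`scope` must name at least one covariate.")
  current <- spec
  fit <- fit_copula_regression(data, current)
  initial_fit <- fit
  trace <- list()
  skipped <- list()
  step <- 0L
  repeat {
    step <- step + 1L
    if (step > max_steps) break
    cands <- dplyr::bind_rows(
      tibble::tibble(margin = 1L, term = intersect(current$covariates1, scope)),
      tibble::tibble(margin = 2L, term = intersect(current$covariates2, scope))
    )
    if (!nrow(cands)) break
    best <- NULL
    for (i in seq_len(nrow(cands))) {
      cand_spec <- drop_covariate(current, cands$margin[i], cands$term[i])
      cand_fit <- tryCatch(fit_copula_regression(data, cand_spec),
                           error = function(e) e)
      if (inherits(cand_fit, "error")) {
        skipped <- c(skipped, list(list(
          step = step, margin = cands$margin[i], term = cands$term[i],
          message = conditionMessage(cand_fit)
        )))
        next
      }
      if (is.null(best) || cand_fit$aic < best$fit$aic) {
        best <- list(spec = cand_spec, fit = cand_fit,
                     margin = cands$margin[i], term = cands$term[i])
      }
    }
    if (is.null(best) || best$fit$aic >= fit$aic) break
    trace[[step]] <- tibble::tibble(
      step = step, margin = best$margin, term = best$term,
      aic_before = fit$aic, aic_after = best$fit$aic
    )
    if (verbose) {
      message(sprintf("step %d: drop %s from margin %d (AIC %.3f -> %.3f)",
                      step, best$term, best$margin, fit$aic, best$fit$aic))
    }
    current <- best$spec
    fit <- best$fit
  }
  structure(
    list(
      spec = current, initial_fit = initial_fit, final_fit = fit,
      trace = if (length(trace)) dplyr::bind_rows(trace) else
        tibble::tibble(step = integer(), margin = integer(),
                       term = character(), aic_before = double(),
                       aic_after = double()),
      skipped = skipped
    ),
    class = "elimination_result"
  )
}

drop_covariate <- function(spec, margin, term) {
  if (margin == 1L) {
    spec$covariates1 <- setdiff(spec$covariates1, term)
  } else {
    spec$covariates2 <- setdiff(spec$covariates2, term)
  }
  spec
}

#' @export
print.elimination_result <- function(x, ...) {
  cat(sprintf(
    "<elimination_result> %d removal(s); AIC %.3f -> %.3f\n",
    nrow(x$trace), x$initial_fit$aic, x$final_fit$aic
  ))
  if (nrow(x$trace)) print(as.data.frame(x$trace), digits = 6)
  invisible(x)
}
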