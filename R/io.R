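#' @importFrom generics tidy glance
#' @export
generics::tidy

#' @export
generics::glance

#' @importFrom ggplot2 autoplot
#' @export
ggplot2::autoplot

dataset_binary_columns <- c("GENDER", "ALC", "SMK")

#' Read a per-subject addiction dataset from CSV
#'
#' Strictly typed reader for the study table: numeric outcome columns
#' (positive where present, missingness preserved), numeric covariates,
#' 0/1 binaries (gender reference 0 = male). Rows with unparseable
#' numerics are rejected with a row-indexed report; a non-numeric binary
#' column (e.g. gender coded "M"/"F") raises a schema error suggesting
#' 0/1 recoding.
#'
#' @param path CSV file path (header row required).
#' @param outcomes Names of the two outcome columns.
#' @param required Columns that must be present.
#' @return A tibble.
#' @export
read_addiction_data <- function(path, outcomes = c("y1", "y2"),
                                required = outcomes) {
  if (!file.exists(path)) abort_schema(sprintf("file not found: %s", path))
  raw <- readr::read_csv(path, show_col_types = FALSE,
                         col_types = readr::cols(.default = readr::col_character()))
  miss <- setdiff(required, names(raw))
  if (length(miss)) {
    abort_schema(paste0("required column(s) absent: ",
                        paste(miss, collapse = ", ")))
  }
  out <- raw
  bad_rows <- integer()
  for (nm in names(raw)) {
    col <- raw[[nm]]
    num <- suppressWarnings(as.numeric(col))
    unparseable <- !is.na(col) & col != "" & is.na(num)
    if (any(unparseable)) {
      if (nm %in% dataset_binary_columns) {
        abort_schema(sprintf(
          "column `%s` is not numeric (values like %s); recode to 0/1 (0 = male reference for GENDER).",
          nm, paste0('"', head(unique(col[unparseable]), 3), '"', collapse = ", ")
        ))
      }
      bad_rows <- union(bad_rows, which(unparseable))
    }
    out[[nm]] <- num
  }
  if (length(bad_rows)) {
    warn(sprintf("rejected %d row(s) with unparseable numerics (rows %s).",
                 length(bad_rows),
                 paste(sort(bad_rows), collapse = ", ")),
         class = "bicopreg_parse_warning")
    out <- out[-sort(bad_rows), , drop = FALSE]
  }
  for (nm in intersect(dataset_binary_columns, names(out))) {
    v <- out[[nm]]
    if (any(!is.na(v) & !v %in% c(0, 1))) {
      abort_schema(sprintf("binary column `%s` must contain only 0/1.", nm))
    }
  }
  for (nm in intersect(outcomes, names(out))) {
    if (any(!is.na(out[[nm]]) & out[[nm]] <= 0)) {
      abort_schema(sprintf("outcome `%s` must be strictly positive.", nm))
    }
  }
  out
}

#' @rdname read_addiction_data
#' @param data Data frame to write.
#' @export
write_addiction_data <- function(data, path) {
  readr::write_csv(data, path)
  invisible(path)
}

#' Write a synthetic study as CSV plus a JSON truth sidecar
#'
#' @param study A `synthetic_study`.
#' @param path CSV output path; the sidecar is written next to it as
#'   `<path>.truth.json` (generative coefficients, copula parameters,
#'   seed).
#' @return The CSV path, invisibly.
#' @export
write_study <- function(study, path) {
  if (!inherits(study, "synthetic_study")) {
    abort_config("`study` must be a synthetic_study.")
  }
  rlang::check_installed("jsonlite")
  write_addiction_data(study$data, path)
  truth <- list(
    seed = study$seed,
    n = study$config$n,
    margin1 = study$config$margin1, margin2 = study$config$margin2,
    copula = study$config$copula, rho = study$config$rho,
    df = study$config$df,
    sigma1 = study$config$sigma1, sigma2 = study$config$sigma2,
    intercept1 = study$config$intercept1, intercept2 = study$config$intercept2,
    beta1 = as.list(study$config$beta1), beta2 = as.list(study$config$beta2),
    missing_rate = study$config$missing_rate
  )
  jsonlite::write_json(truth, paste0(path, ".truth.json"),
                       auto_unbox = TRUE, digits = NA, null = "null")
  invisible(path)
}

#' Run the full analysis workflow on one dataset
#'
#' Orchestrates the modelling stages end to end: complete-case filtering,
#' marginal-family comparison for each outcome, copula-family selection on
#' pseudo-observations (optionally with the bootstrap goodness-of-fit
#' test), the AIC model comparison across independence and copula
#' candidates, backward elimination, and the final joint fit. Each stage's
#' AIC is logged via `message()`.
#'
#' @param data Data frame (e.g. from [read_addiction_data()] or
#'   [simulate_study()]`$data`).
#' @param covariates1,covariates2 Covariate sets for the two margins.
#' @param outcomes Outcome column names.
#' @param candidates Model-comparison candidates; `NULL` skips the stage.
#' @param eliminate Run backward elimination.
#' @param gof_boot Bootstrap resamples for the copula goodness-of-fit
#'   test; `0` skips it.
#' @param df_grid Degrees-of-freedom profile grid for copula selection.
#' @param seed Seed for the stochastic stages (goodness of fit).
#' @return A `pipeline_report` list: `marginal_report1/2`,
#'   `copula_selection`, `gof`, `model_comparison`, `elimination`,
#'   `final_fit`, `seed`, `n`.
#' @export
run_pipeline <- function(data, covariates1, covariates2,
                         outcomes = c("y1", "y2"),
                         candidates = default_candidates(),
                         eliminate = TRUE, gof_boot = 0,
                         df_grid = c(2.1, 3, 4, 5, 6, 8, 10, 15, 20, 30),
                         seed = NULL) {
  stage <- function(name, expr) {
    tryCatch(expr, error = function(e) {
      abort_pipeline(sprintf("stage `%s` failed: %s", name,
                             conditionMessage(e)))
    })
  }
  data <- stage("complete_cases", complete_cases(data, outcomes))
  n <- nrow(data)
  message(sprintf("analyzing %d complete cases", n))

  marg1 <- stage("marginals_y1", fit_marginals(data, outcomes[1]))
  marg2 <- stage("marginals_y2", fit_marginals(data, outcomes[2]))
  message(sprintf("best marginal families: %s (%s), %s (%s)",
                  marg1$family[1], outcomes[1], marg2$family[1], outcomes[2]))

  pobs <- stage("pseudo_observations",
                pseudo_observations(data[, outcomes]))
  cop_sel <- stage("copula_selection",
                   select_copula_family(pobs, df_grid = df_grid))
  message(sprintf("selected copula: %s (rho = %.3f%s, AIC = %.2f)",
                  cop_sel$family, cop_sel$rho,
                  if (!is.null(cop_sel$df)) sprintf(", df = %.2f", cop_sel$df) else "",
                  cop_sel$aic))
  gof <- NULL
  if (gof_boot > 0) {
    gof <- stage("goodness_of_fit",
                 gof_copula_cvm(cop_sel, pobs, n_boot = gof_boot, seed = seed))
    message(sprintf("GoF: S_n = %.5f, p = %.3f", gof$statistic, gof$p_value))
  }

  comparison <- NULL
  if (!is.null(candidates)) {
    comparison <- stage("model_comparison",
                        compare_models(data, covariates1, covariates2,
                                       candidates = candidates,
                                       outcome1 = outcomes[1],
                                       outcome2 = outcomes[2]))
    message(sprintf("best model by total AIC: %s (%.2f)",
                    comparison$model[1], comparison$total_aic[1]))
  }

  cop_df <- if (cop_sel$family == "student_t") cop_sel$df else 3
  spec <- copreg_spec(marg1$family[1], marg2$family[1],
                      covariates1, covariates2,
                      copula = cop_sel$family, df = cop_df,
                      outcome1 = outcomes[1], outcome2 = outcomes[2])

  elim <- NULL
  final_fit <- NULL
  if (eliminate) {
    elim <- stage("backward_elimination", backward_eliminate(data, spec))
    final_fit <- elim$final_fit
    message(sprintf("elimination: %d removal(s), final AIC %.3f",
                    nrow(elim$trace), final_fit$aic))
  } else {
    final_fit <- stage("final_fit", fit_copula_regression(data, spec))
    message(sprintf("final fit AIC %.3f", final_fit$aic))
  }

  structure(
    list(
      n = n, seed = seed,
      marginal_report1 = marg1, marginal_report2 = marg2,
      copula_selection = cop_sel, gof = gof,
      model_comparison = comparison,
      elimination = elim, final_fit = final_fit
    ),
    class = "pipeline_report"
  )
}

#' @export
print.pipeline_report <- function(x, ...) {
  cat(sprintf("<pipeline_report> n = %d\n", x$n))
  cat("-- copula selection --\n")
  print(x$copula_selection)
  if (!is.null(x$model_comparison)) {
    cat("-- model comparison (total AIC) --\n")
    print(as.data.frame(x$model_comparison), digits = 6)
  }
  cat("-- final fit --\n")
  print(x$final_fit)
  invisible(x)
}
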