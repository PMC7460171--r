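#' @importFrom rlang abort warn .data
#' @importFrom stats dnorm pnorm qnorm rnorm dlnorm plnorm qlnorm rlnorm
#'   dgamma pgamma qgamma dweibull pweibull qweibull dt pt qt rchisq runif
#'   rbinom optim optimize var sd cor setNames complete.cases quantile
#' @importFrom utils head
NULL

abort_domain <- function(msg) abort(msg, class = "bicopreg_domain_error")
abort_fit <- function(msg, trace = NULL) {
  abort(msg, class = "bicopreg_fit_error", trace_info = trace)
}
abort_config <- function(msg) abort(msg, class = "bicopreg_config_error")
abort_schema <- function(msg) abort(msg, class = "bicopreg_schema_error")
abort_inference <- function(msg) abort(msg, class = "bicopreg_inference_error")
abort_pipeline <- function(msg) abort(msg, class = "bicopreg_pipeline_error")

#' Run an expression with a locally seeded RNG
#'
#' Sets the random seed for the duration of `expr` and restores the previous
#' RNG state afterwards, so seeded helpers do not disturb the caller's
#' random-number stream. With `seed = NULL` the current stream is used
#' (and advanced) as usual.
#'
#' @param seed Integer seed or `NULL`.
#' @param expr Expression to evaluate.
#' @return The value of `expr`.
#' @keywords internal
with_seed <- function(seed, expr) {
  if (is.null(seed)) {
    return(expr)
  }
  if (!exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
    set.seed(NULL)
  }
  old <- get(".Random.seed", envir = globalenv())
  on.exit(assign(".Random.seed", old, envir = globalenv()), add = TRUE)
  set.seed(seed)
  expr
}

# 2-column numeric matrix from matrix / data frame / length-2 vector
as_pair_matrix <- function(u, arg = "u") {
  if (is.data.frame(u)) u <- as.matrix(u[, seq_len(2), drop = FALSE])
  if (is.null(dim(u))) {
    if (length(u) != 2) {
      abort_domain(sprintf("`%s` must have two columns or length 2.", arg))
    }
    u <- matrix(u, nrow = 1)
  }
  if (ncol(u) != 2) {
    abort_domain(sprintf("`%s` must have exactly two columns.", arg))
  }
  storage.mode(u) <- "double"
  u
}
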