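#' Evidence-accumulator parameters
#'
#' Each output unit owns one accumulator. Per iteration, accumulator k gains
#' an independent draw from `Normal(mu_k, sigma)` with drift
#' `mu_k = alpha * (act_k - max(act_l, l != k))`; the first accumulator to
#' exceed `threshold` determines the response, and the number of iterations
#' is the reaction time. Evidence starts at 0, may go negative (no reflecting
#' bound), and a trial with no crossing by `max_iter` is a timeout, excluded
#' from analysis like an incorrect response (the analogue of the 2-s human
#' response window).
#'
#' @param alpha Evidence-accumulation rate (default 0.1).
#' @param sigma SD of the per-iteration increment (default 0.1).
#' @param threshold Response criterion (default 6).
#' @param max_iter Safety cap on iterations (default 10000).
#' @return List of class `np_accumulator_params`.
#' @export
accumulator_params <- function(alpha = 0.1, sigma = 0.1, threshold = 6,
                               max_iter = 10000) {
  if (alpha <= 0) stop("alpha must be > 0")
  if (sigma < 0) stop("sigma must be >= 0")
  if (threshold <= 0) stop("threshold must be > 0")
  if (max_iter <= threshold / alpha)
    stop("max_iter is too small to permit a crossing at any activation gap")
  structure(list(alpha = alpha, sigma = sigma, threshold = threshold,
                 max_iter = as.integer(max_iter)),
            class = "np_accumulator_params")
}

#' Drift means from output activations
#'
#' `mu_k = alpha * (act_k - max(act_l, l != k))`. At most one entry is
#' strictly positive (the unique maximum, if any); ties leave no positive
#' drift.
#'
#' @param act Output activation vector.
#' @param alpha Accumulation rate.
#' @export
drift_means <- function(act, alpha = 0.1) {
  vapply(seq_along(act),
         function(k) alpha * (act[k] - max(act[-k])),
         numeric(1))
}

#' Run the evidence accumulator on one trial
#'
#' @param act Output activation vector (length 5).
#' @param params An [accumulator_params()].
#' @return List with `winner` (index of the responding unit, `NA` on
#'   timeout), `iterations`, and `timeout` (logical).
#' @export
run_accumulator <- function(act, params = accumulator_params()) {
  mu <- drift_means(act, params$alpha)
  if (params$sigma == 0) {
    # deterministic limit in closed form: ceiling(threshold / (alpha * gap)),
    # immune to accumulated floating-point drift
    if (max(mu) <= 0)
      return(list(winner = NA_integer_, iterations = params$max_iter,
                  timeout = TRUE))
    it <- ceiling(params$threshold / max(mu) - 1e-9)
    if (it > params$max_iter)
      return(list(winner = NA_integer_, iterations = params$max_iter,
                  timeout = TRUE))
    return(list(winner = which.max(mu), iterations = as.integer(it),
                timeout = FALSE))
  }
  ev <- numeric(length(act))
  for (it in seq_len(params$max_iter)) {
    ev <- ev + rnorm(length(act), mu, params$sigma)
    if (any(ev > params$threshold)) {
      return(list(winner = which.max(ev), iterations = it, timeout = FALSE))
    }
  }
  list(winner = NA_integer_, iterations = params$max_iter, timeout = TRUE)
}
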