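# Model selection utilities shared by the trait-evolution analyses.

#' AIC for MCMC samples (AICM)
#'
#' Moment estimator computed from a posterior sample of log-likelihoods:
#' `AICM = 2 * var(trace) - 2 * mean(trace)` (deviance scale, lower is
#' better). Recorded in output metadata wherever it is used, since several
#' AICM variants circulate.
#'
#' @param loglik_trace Numeric vector of sampled log-likelihoods
#'   (length >= 100).
#' @return AICM value.
#' @export
aicm <- function(loglik_trace) {
  if (length(loglik_trace) < 100)
    stop("need at least 100 posterior log-likelihood samples")
  v <- stats::var(loglik_trace)
  if (v == 0) {
    warning("log-likelihood trace has zero variance")
    return(-2 * mean(loglik_trace))
  }
  2 * v - 2 * mean(loglik_trace)
}

#' Select a trait-evolution model by the delta-AIC-2 parsimony rule
#'
#' The best-AIC model wins unless a simpler model lies within 2 AIC units of
#' it, in which case the simpler model is chosen; simplicity follows the
#' fixed order BM, rBM1, jump-BM, jump-rBM. No model averaging.
#'
#' @param aic_values Named numeric vector of AIC (or AICM) values.
#' @param order Character vector giving models from simplest to most
#'   complex; defaults to the four-model Brownian family.
#' @return Name of the selected model.
#' @export
select_model <- function(aic_values,
                         order = c("BM", "rBM1", "jumpBM", "jumpRBM")) {
  if (length(aic_values) == 0) stop("no models supplied")
  if (length(aic_values) == 1) return(names(aic_values))
  if (!all(names(aic_values) %in% order))
    stop("models not covered by simplicity order: ",
         paste(setdiff(names(aic_values), order), collapse = ", "))
  ord <- order[order %in% names(aic_values)]
  aic <- aic_values[ord]
  best <- min(aic)
  # a model is significantly better only when it leads by more than 2 units
  ord[which(aic <= best + 2)[1]]
}
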