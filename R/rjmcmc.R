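# R-side driver for the reversible-jump MCMC over the Brownian model family.

#' Reversible-jump MCMC for Brownian trait models
#'
#' Samples the posterior of one of four models of continuous trait
#' evolution: `BM` (single rate), `rBM1` (rate shifts allowed, each shift
#' rescaling its branch and subtree), `jumpBM` (single rate plus mean jumps
#' at branch starts) and `jumpRBM` (both). The numbers of shifts and of
#' jumps carry truncated Poisson(log 2) priors, so the prior expected count
#' of each is below one; shift multipliers are log-normal(0, 1) and jump
#' sizes are normal with variance proportional to `sigma2` times the median
#' branch length. The Brownian rate has a scale-invariant 1/sigma2 prior
#' and the root state a flat prior. The sampler is seed-deterministic.
#'
#' @param tree A binary ultrametric `phylo`.
#' @param traits Named numeric tip values.
#' @param model One of `"BM"`, `"rBM1"`, `"jumpBM"`, `"jumpRBM"`.
#' @param ngen Chain length in generations (default 1.25e6, sampled every
#'   `thin`).
#' @param thin Thinning interval (default 1000).
#' @param seed Integer seed (required).
#' @param prop_width Proposal-width calibration constant; 8 is the
#'   calibrated default and all proposal scales are expressed relative to it.
#' @param burnin Fraction of the chain discarded (default 0.25).
#' @param poisson_mean Prior mean of the shift and jump counts (default
#'   `log(2)`).
#' @param jump_prior_c Proportionality constant of the jump-size prior
#'   variance `c * sigma2 * median branch length` (default 16, i.e. prior
#'   SD of four median-branch Brownian standard deviations).
#' @return An object of class `rj_posterior`: `trace` (data.frame of thinned
#'   samples), `shift_prob` / `jump_prob` (per-branch posterior
#'   probabilities, indexed by child node id), `jump_mean_size`,
#'   `acceptance_rate`, `model`, `ess_loglik`, `settings`.
#' @export
rjmcmc_bm <- function(tree, traits, model = c("BM", "rBM1", "jumpBM", "jumpRBM"),
                      ngen = 1.25e6, thin = 1000, seed, prop_width = 8,
                      burnin = 0.25, poisson_mean = log(2), jump_prior_c = 16) {
  model <- match.arg(model)
  if (missing(seed)) stop("a seed is required")
  if (ngen < 10 * thin) stop("chain generations must be >= 10 * thin")
  if (!(prop_width > 0)) stop("proposal width must be > 0")
  x <- .match_tip_values(tree, traits)
  stop_if_not_ultrametric(tree)
  tt <- tree_traversal(tree)
  n_tip <- tt$n_tip
  n_all <- n_tip + tt$n_node
  sub <- subtree_edges(tree)
  sub_edges0 <- vector("list", n_all)
  sub_tips0 <- vector("list", n_all)
  for (b in seq_len(n_all)) {
    if (b == n_tip + 1L || is.null(sub[[b]])) next
    sub_edges0[[b]] <- as.integer(sub[[b]] - 1L)
    sub_tips0[[b]] <- as.integer(sub[[b]][sub[[b]] <= n_tip] - 1L)
  }
  fit0 <- fit_bm_ml(tree, stats::setNames(x, tree$tip.label))
  sigma2_init <- if (fit0$boundary) 1e-6 else fit0$sigma2
  set.seed(seed)
  res <- .rjmcmc_run(
    n_tip, as.integer(tt$parent - 1L), as.integer(tt$child - 1L), tt$length,
    sub_edges0, sub_tips0, x,
    allow_shifts = model %in% c("rBM1", "jumpRBM"),
    allow_jumps = model %in% c("jumpBM", "jumpRBM"),
    ngen = as.integer(ngen), thin = as.integer(thin), burnin_frac = burnin,
    prop_width = prop_width, poisson_mean = poisson_mean,
    jump_c = jump_prior_c, med_bl = stats::median(tree$edge.length),
    sigma2_init = sigma2_init, alpha_init = fit0$alpha_root
  )
  trace <- as.data.frame(res$trace)
  ess <- ess_from_trace(trace$loglik)
  if (is.finite(ess) && ess < 200)
    warning(sprintf("effective sample size of the log-likelihood is %.0f (< 200); consider a longer chain", ess))
  structure(list(
    trace = trace,
    shift_prob = stats::setNames(res$shift_prob, seq_len(n_all)),
    jump_prob = stats::setNames(res$jump_prob, seq_len(n_all)),
    jump_mean_size = stats::setNames(res$jump_mean_size, seq_len(n_all)),
    acceptance_rate = res$acceptance_rate,
    model = model, ess_loglik = ess,
    settings = list(ngen = ngen, thin = thin, seed = seed,
                    prop_width = prop_width, burnin = burnin,
                    poisson_mean = poisson_mean, jump_prior_c = jump_prior_c,
                    aicm_formula = "2*var(logL) - 2*mean(logL)")
  ), class = "rj_posterior")
}

#' @method print rj_posterior
#' @export
print.rj_posterior <- function(x, ...) {
  cat(sprintf("rjMCMC posterior (%s): %d samples, acceptance %.2f, ESS(logL) %.0f\n",
              x$model, nrow(x$trace), x$acceptance_rate, x$ess_loglik))
  if (any(x$jump_prob > 0.5))
    cat("branches with jump PP > 0.5:",
        paste(names(which(x$jump_prob > 0.5)), collapse = ", "), "\n")
  invisible(x)
}

# Effective sample size via the initial positive sequence of autocorrelations.
ess_from_trace <- function(v) {
  n <- length(v)
  if (n < 10 || stats::var(v) == 0) return(NA_real_)
  ac <- stats::acf(v, lag.max = min(n - 1, 200), plot = FALSE)$acf[-1]
  s <- 0
  for (r in ac) {
    if (r <= 0) break
    s <- s + r
  }
  n / (1 + 2 * s)
}

#' Fit and compare the four Brownian models for one trait
#'
#' Runs [rjmcmc_bm()] under each requested model, scores them by AICM and
#' applies the parsimony selection rule of [select_model()]. Reported
#' "jumps" is the posterior mean number of jumps under the selected model
#' (count, not rate); `alpha` is reported both as the posterior mean and as
#' the ML estimate under single-rate BM.
#'
#' @param tree A binary ultrametric `phylo`.
#' @param traits Named numeric tip values.
#' @param models Character vector of models to compare.
#' @param ... Passed to [rjmcmc_bm()] (notably `ngen`, `thin`, `seed`).
#' @return List with `fits` (per-model posteriors), `aicm` (named vector),
#'   `selected`, and `report` (one-row data.frame with columns alpha, jumps,
#'   sigma2, LnL, AIC, model).
#' @export
compare_bm_models <- function(tree, traits,
                              models = c("BM", "rBM1", "jumpBM", "jumpRBM"),
                              ...) {
  fits <- lapply(models, function(m) rjmcmc_bm(tree, traits, model = m, ...))
  names(fits) <- models
  aic <- vapply(fits, function(f) aicm(f$trace$loglik), 0)
  sel <- select_model(aic)
  best <- fits[[sel]]
  ml <- fit_bm_ml(tree, traits)
  report <- data.frame(
    alpha_posterior = mean(best$trace$alpha),
    alpha_ml = ml$alpha_root,
    jumps = mean(best$trace$k_jumps),
    sigma2 = mean(best$trace$sigma2),
    LnL = mean(best$trace$loglik),
    AIC = unname(aic[sel]),
    model = sel
  )
  list(fits = fits, aicm = aic, selected = sel, report = report)
}
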