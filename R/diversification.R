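# Likelihood fitting of constant, time-dependent and environment-dependent
# birth-death models on reconstructed trees, plus the constant-rates (gamma)
# test, the Magallon-Sanderson estimator, and paleo-covariate builders.
#
# Time runs in Ma before present (t = 0 now, increasing into the past); the
# coefficient of exponential models multiplies t in the exponent, so a
# negative coefficient means rates rising toward the present.

#' Environment curve
#'
#' A covariate as a function of age, e.g. Andean paleoelevation (km) or
#' inter-continental connectivity (probability in `[0, 1]`).
#'
#' @param times Ages in Ma, ascending from 0.
#' @param values Covariate values at those ages.
#' @param method Interpolation: `"linear"` (default), `"spline"`, or
#'   `"constant"` (step function, value taken from the most recent knot at
#'   or below the queried age).
#' @return An object of class `env_curve`; call it like a function of age.
#' @export
env_curve <- function(times, values, method = c("linear", "spline", "constant")) {
  method <- match.arg(method)
  if (length(times) != length(values)) stop("times and values differ in length")
  if (is.unsorted(times)) stop("times must be ascending")
  fun <- switch(method,
    linear = stats::approxfun(times, values, rule = 2),
    constant = stats::approxfun(times, values, method = "constant", rule = 2,
                                f = 0),
    spline = stats::splinefun(times, values, method = "natural")
  )
  structure(list(times = times, values = values, method = method, fun = fun),
            class = "env_curve")
}

#' @method print env_curve
#' @export
print.env_curve <- function(x, ...) {
  cat(sprintf("env_curve: %d knots over [%g, %g] Ma (%s interpolation)\n",
              length(x$times), min(x$times), max(x$times), x$method))
  invisible(x)
}

env_value <- function(curve, t) curve$fun(t)

#' Parametric rate model for birth-death fitting
#'
#' Speciation and extinction are each `constant` (`rate0`), `exponential`
#' (`rate0 * exp(coef * t)`), `linear` (`rate0 + coef * t`, floored at 0
#' with a warning), or environment-dependent (`env_exponential` /
#' `env_linear`: the environment value at age t replaces t). Extinction may
#' be structurally absent (`"zero"`), which removes its parameters rather
#' than estimating them at 0.
#'
#' @param lambda_form,mu_form Functional forms; `mu_form = "zero"` for a
#'   pure-birth model.
#' @param lambda0,lambda_coef,mu0,mu_coef Parameters (intercepts per lineage
#'   per Ma; coefficients per Ma or per environment unit).
#' @param env An [env_curve()] for environment-dependent forms.
#' @return Object of class `rates_model`.
#' @export
rates_model <- function(lambda_form = c("constant", "exponential", "linear",
                                        "env_exponential", "env_linear"),
                        mu_form = c("zero", "constant", "exponential",
                                    "linear", "env_exponential", "env_linear"),
                        lambda0, lambda_coef = 0, mu0 = 0, mu_coef = 0,
                        env = NULL) {
  lambda_form <- match.arg(lambda_form)
  mu_form <- match.arg(mu_form)
  needs_env <- grepl("^env_", lambda_form) || grepl("^env_", mu_form)
  if (needs_env && is.null(env)) stop("environment-dependent form needs an env curve")
  if (mu_form == "zero" && (mu0 != 0 || mu_coef != 0))
    stop("mu_form = 'zero' implies mu0 = mu_coef = 0")
  structure(list(lambda_form = lambda_form, mu_form = mu_form,
                 lambda0 = lambda0, lambda_coef = lambda_coef,
                 mu0 = mu0, mu_coef = mu_coef, env = env),
            class = "rates_model")
}

.eval_rate <- function(form, r0, coef, t, env, warn_floor = TRUE) {
  z <- switch(form,
    zero = return(rep(0, length(t))),
    constant = rep(r0, length(t)),
    exponential = r0 * exp(coef * t),
    linear = r0 + coef * t,
    env_exponential = r0 * exp(coef * env_value(env, t)),
    env_linear = r0 + coef * env_value(env, t)
  )
  if (any(z < 0)) {
    if (warn_floor) warning("rate went negative; floored at 0")
    z <- pmax(z, 0)
  }
  z
}

#' Evaluate a rate model at given ages
#'
#' @param model A [rates_model()].
#' @param t Ages in Ma before present.
#' @param what `"lambda"` or `"mu"`.
#' @return Per-lineage per-Ma rate(s).
#' @export
rate_at <- function(model, t, what = c("lambda", "mu")) {
  what <- match.arg(what)
  if (what == "lambda")
    .eval_rate(model$lambda_form, model$lambda0, model$lambda_coef, t, model$env)
  else
    .eval_rate(model$mu_form, model$mu0, model$mu_coef, t, model$env)
}

# Cumulative integral of f sampled on a uniform grid of spacing h, by
# composite Simpson (pairs of intervals) with a 3-point Newton-Cotes closer
# on odd prefixes; O(h^4) accurate and fully vectorised.
.cumquad <- function(f, h) {
  n <- length(f)
  C <- numeric(n)
  odd <- seq(3, n, by = 2)
  pair <- h / 3 * (f[odd - 2] + 4 * f[odd - 1] + f[odd])
  C[odd] <- cumsum(pair)
  even <- seq(4, n, by = 2)
  C[even] <- C[even - 1] + h / 12 * (5 * f[even] + 8 * f[even - 1] - f[even - 2])
  # first interval has no left neighbour: forward 3-point rule
  C[2] <- h / 12 * (5 * f[1] + 8 * f[2] - f[3])
  C
}

# R(t) = int_0^t (lambda - mu) du and I(t) = int_0^t lambda(u) e^{R(u)} du
# at the requested ages: closed forms when both rates are constant, else
# high-order quadrature on a fine uniform grid (4097 points over the span),
# interpolated at the branching times by cubic splines.
.bd_integrals <- function(model, ages) {
  ages <- sort(unique(c(0, ages)))
  if (model$lambda_form == "constant" && model$mu_form %in% c("zero", "constant")) {
    lam <- model$lambda0; r <- lam - model$mu0
    R <- r * ages
    I <- if (abs(r) > 1e-12) lam * (exp(r * ages) - 1) / r else lam * ages
    return(list(ages = ages, R = R, I = I))
  }
  t1 <- max(ages)
  ngrid <- 2049L
  grid <- seq(0, t1, length.out = ngrid)
  h <- grid[2] - grid[1]
  lam <- .eval_rate(model$lambda_form, model$lambda0, model$lambda_coef,
                    grid, model$env, warn_floor = FALSE)
  mu <- .eval_rate(model$mu_form, model$mu0, model$mu_coef,
                   grid, model$env, warn_floor = FALSE)
  # rates this large can only come from runaway optimizer proposals
  if (any(!is.finite(lam)) || any(!is.finite(mu)) ||
      any(lam > 1e6) || any(mu > 1e6))
    stop("rate integration failed")
  Rg <- .cumquad(lam - mu, h)
  Ig <- .cumquad(lam * exp(Rg), h)
  if (any(!is.finite(Ig)) || any(!is.finite(Rg)))
    stop("rate integration failed")
  list(ages = ages,
       R = stats::spline(grid, Rg, xout = ages, method = "fmm")$y,
       I = pmax(stats::spline(grid, Ig, xout = ages, method = "fmm")$y, 0))
}

#' Log-likelihood of a reconstructed tree under a birth-death model
#'
#' Likelihood of the branching times given the crown age, conditioned on the
#' survival of both crown lineages (so that the reconstructed tree exists).
#' Rate integrals are evaluated by adaptive stiff integration; for constant
#' speciation with no extinction the result reduces to the pure-birth closed
#' form `(n-2) log(lambda) - lambda * S` with `S` the total branch length.
#'
#' @param tree An ultrametric `phylo`, or a [branching_times()] vector.
#' @param model A [rates_model()].
#' @return Log-likelihood.
#' @export
bd_loglik <- function(tree, model) {
  bt <- if (inherits(tree, "phylo")) branching_times(tree) else tree
  n <- attr(bt, "n_tips")
  if (is.null(n)) n <- length(bt) + 1L
  t1 <- bt[1]
  span <- seq(0, t1, length.out = 65)
  if (any(rate_at(model, span, "lambda") < 0) || any(rate_at(model, span, "mu") < 0))
    stop("rates must be non-negative over the tree's age span")
  ints <- .bd_integrals(model, bt)
  Rf <- stats::approxfun(ints$ages, ints$R)
  If <- stats::approxfun(ints$ages, ints$I)
  inner <- bt[-1]
  lam_inner <- .eval_rate(model$lambda_form, model$lambda0, model$lambda_coef,
                          inner, model$env, warn_floor = FALSE)
  if (any(lam_inner <= 0)) return(-Inf)
  sum(log(lam_inner) + Rf(inner) - 2 * log1p(If(inner))) -
    2 * log1p(If(t1))
}

#' Maximum-likelihood fit of a birth-death model
#'
#' Maximises [bd_loglik()] over the free parameters by multi-start
#' Nelder-Mead (intercepts on the log scale), seeded for reproducibility.
#' Structural zeros (`mu_form = "zero"`) are excluded from the parameter
#' count.
#'
#' @param tree An ultrametric `phylo` (>= 5 tips recommended).
#' @param lambda_form,mu_form Functional forms as in [rates_model()].
#' @param env Optional [env_curve()] for environment-dependent forms.
#' @param nstart Number of optimiser starts (default 10).
#' @param seed Integer seed for the start jitter (default 1).
#' @param label Optional row label for [model_table()].
#' @return List of class `bd_fit`: fitted `model`, `loglik`, `n_params`,
#'   `aic`, `converged`, `label`.
#' @export
fit_bd <- function(tree, lambda_form = "constant", mu_form = "zero",
                   env = NULL, nstart = 10, seed = 1, label = NULL) {
  bt <- branching_times(tree)
  n <- attr(bt, "n_tips")
  if (n < 5) warning("fewer than 5 tips: optimisation may be unstable")
  S <- attr(bt, "total_branch_length")
  lam_hat <- max((n - 2) / S, 1e-4)

  has_lcoef <- lambda_form != "constant"
  has_mu <- mu_form != "zero"
  has_mcoef <- has_mu && mu_form != "constant"
  k <- 1L + has_lcoef + has_mu + has_mcoef

  unpack <- function(p) {
    i <- 1L
    lambda0 <- exp(p[i]); i <- i + 1L
    lambda_coef <- if (has_lcoef) { v <- p[i]; i <- i + 1L; v } else 0
    mu0 <- if (has_mu) { v <- exp(p[i]); i <- i + 1L; v } else 0
    mu_coef <- if (has_mcoef) p[i] else 0
    rates_model(lambda_form, mu_form, lambda0 = lambda0,
                lambda_coef = lambda_coef, mu0 = mu0, mu_coef = mu_coef,
                env = env)
  }
  negll <- function(p) {
    if (any(!is.finite(p)) || any(abs(p) > 15)) return(1e10)
    m <- try(suppressWarnings(bd_loglik(bt, unpack(p))), silent = TRUE)
    if (inherits(m, "try-error") || !is.finite(m)) return(1e10)
    -m
  }
  base <- c(log(lam_hat), if (has_lcoef) 0, if (has_mu) log(lam_hat / 10),
            if (has_mcoef) 0)
  set.seed(seed)
  best <- NULL
  meth <- if (length(base) == 1L) "BFGS" else "Nelder-Mead"
  for (s in seq_len(nstart)) {
    p0 <- if (s == 1) base else base + stats::rnorm(length(base), 0, 0.5)
    opt <- try(stats::optim(p0, negll, method = meth,
                            control = list(maxit = 2000, reltol = 1e-12)),
               silent = TRUE)
    if (inherits(opt, "try-error")) next
    if (is.null(best) || opt$value < best$value) best <- opt
  }
  if (is.null(best) || best$value >= 1e10)
    return(structure(list(model = NULL, loglik = NA_real_, n_params = k,
                          aic = NA_real_, converged = FALSE, label = label),
                     class = "bd_fit"))
  structure(list(model = unpack(best$par), loglik = -best$value, n_params = k,
                 aic = 2 * k + 2 * best$value, converged = TRUE,
                 label = label %||% paste(lambda_form, mu_form, sep = " / ")),
            class = "bd_fit")
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Model comparison table (AIC bookkeeping)
#'
#' Assembles fitted models into a comparison table with
#' `AIC = 2 k - 2 logLik` and delta-AIC relative to the best row. Rows can
#' be full [fit_bd()] results or bare `list(loglik =, n_params =, label =)`
#' entries, which makes the same bookkeeping usable for published
#' log-likelihoods.
#'
#' @param fits List of fits; non-converged fits are dropped with a message.
#' @param digits Optional rounding applied to the numeric columns.
#' @return data.frame with columns label, lambda, mu, lambda0, lambda_coef,
#'   mu0, mu_coef, loglik, n_params, AIC, delta_AIC.
#' @export
model_table <- function(fits, digits = NULL) {
  if (inherits(fits, "bd_fit")) fits <- list(fits)
  keep <- vapply(fits, function(f) is.finite(f$loglik %||% NA_real_), TRUE)
  if (!any(keep)) stop("no converged fits")
  if (any(!keep)) message(sum(!keep), " non-converged fit(s) excluded")
  fits <- fits[keep]
  row <- function(f) {
    m <- f$model
    data.frame(
      label = f$label %||% NA_character_,
      lambda = if (!is.null(m)) m$lambda_form else NA_character_,
      mu = if (!is.null(m)) m$mu_form else NA_character_,
      lambda0 = if (!is.null(m)) m$lambda0 else NA_real_,
      lambda_coef = if (!is.null(m)) m$lambda_coef else NA_real_,
      mu0 = if (!is.null(m)) m$mu0 else NA_real_,
      mu_coef = if (!is.null(m)) m$mu_coef else NA_real_,
      loglik = f$loglik, n_params = f$n_params,
      AIC = 2 * f$n_params - 2 * f$loglik
    )
  }
  out <- do.call(rbind, lapply(fits, row))
  out$delta_AIC <- out$AIC - min(out$AIC)
  if (!is.null(digits)) {
    num <- vapply(out, is.numeric, TRUE)
    out[num] <- lapply(out[num], round, digits = digits)
  }
  out
}

#' Pybus-Harvey gamma statistic (constant-rates test)
#'
#' Standardised summary of the internode intervals of an ultrametric tree;
#' values near 0 are expected under constant-rate pure birth, negative
#' values indicate internal nodes concentrated early (deceleration toward
#' the present is positive gamma's mirror: compressing recent intervals
#' toward the root makes gamma negative).
#'
#' @param tree An ultrametric `phylo` with >= 4 tips.
#' @return The gamma statistic.
#' @export
gamma_stat <- function(tree) {
  bt <- if (inherits(tree, "phylo")) branching_times(tree) else tree
  n <- attr(bt, "n_tips") %||% (length(bt) + 1L)
  if (n < 4) stop("need at least 4 tips")
  g <- c(bt, 0)
  g <- g[-length(g)] - g[-1]          # g_k, k = 2..n lineages
  k <- 2:n
  Tt <- sum(k * g)
  cum <- cumsum(k * g)                # sum_{j=2}^{k} j g_j
  num <- mean(cum[seq_len(n - 2)]) - Tt / 2
  num / (Tt * sqrt(1 / (12 * (n - 2))))
}

#' Magallon-Sanderson net diversification estimator
#'
#' Method-of-moments inversion of the expected extant diversity of a clade
#' of age `t` under constant-rate birth-death with relative extinction
#' `epsilon = mu / lambda`, conditional on clade survival. The stem variant
#' inverts `n = (e^{rt} - eps) / (1 - eps)`; the crown variant starts from
#' two lineages and inverts `n (1 - alpha^2) = 2 e^{rt}` with `alpha` the
#' per-lineage extinction probability, which is a quadratic in `e^{rt}`.
#'
#' @param n Extant species count (>= 1 stem, >= 2 crown).
#' @param t Clade age in Ma.
#' @param epsilon Relative extinction, in `[0, 1)`.
#' @param mode `"stem"` or `"crown"`.
#' @return Net diversification rate r per Ma.
#' @export
ms_rate <- function(n, t, epsilon = 0, mode = c("stem", "crown")) {
  mode <- match.arg(mode)
  if (epsilon < 0 || epsilon >= 1) stop("epsilon must be in [0, 1)")
  if (mode == "stem") {
    if (n < 1) stop("n must be >= 1 for stem")
    return(log(n * (1 - epsilon) + epsilon) / t)
  }
  if (n < 2) stop("n must be >= 2 for crown")
  # 2 x^2 - (n (1 - eps^2) + 4 eps) x + 2 eps^2 + 2 eps n (1 - eps) = 0
  B <- n * (1 - epsilon^2) + 4 * epsilon
  C <- 2 * epsilon^2 + 2 * epsilon * n * (1 - epsilon)
  x <- (B + sqrt(B^2 - 8 * C)) / 4
  log(x) / t
}

#' Migration-rate epochs for the Panama connectivity proxy
#'
#' @param boundaries Ages in Ma, strictly decreasing, ending at 0
#'   (default the published epoch limits 50, 41.1, 23.7, 8.7, 5.2, 0).
#' @param rates Migration events per Ma for each epoch (oldest first);
#'   must be non-negative and nondecreasing toward the present.
#' @return Object of class `migration_epochs`.
#' @export
migration_epochs <- function(boundaries = c(50, 41.1, 23.7, 8.7, 5.2, 0),
                             rates) {
  if (any(diff(boundaries) >= 0)) stop("boundaries must be strictly decreasing")
  if (length(rates) != length(boundaries) - 1L)
    stop("need one rate per epoch")
  if (any(rates < 0)) stop("rates must be >= 0")
  if (any(diff(rates) < 0))
    stop("migration rates must be nondecreasing toward the present")
  structure(list(boundaries = boundaries, rates = rates),
            class = "migration_epochs")
}

#' Connectivity curve from migration-rate epochs
#'
#' Per epoch, the probability of observing at least one migration event per
#' Ma is `1 - exp(-rate)`; the probabilities are assembled into a step
#' curve over age. The `cumulative` variant returns the running maximum
#' toward the present (monotone nondecreasing), reading the epoch
#' probabilities as a cumulative connectivity proxy.
#'
#' @param epochs A [migration_epochs()] object.
#' @param cumulative Use the running-maximum variant (default `FALSE`).
#' @return An [env_curve()] (step interpolation) with values in `[0, 1]`.
#' @export
build_connectivity_curve <- function(epochs, cumulative = FALSE) {
  p <- 1 - exp(-epochs$rates)
  # knots at ascending age; epoch value applies from its recent edge upward
  knots <- rev(epochs$boundaries)[-length(epochs$boundaries)]  # 0, 5.2, ...
  vals <- rev(p)
  if (cumulative) vals <- rev(cummax(rev(vals)))
  env_curve(knots, vals, method = "constant")
}

#' Synthetic Andean paleoelevation curve
#'
#' A smooth monotone uplift history (km above sea level) with accelerated
#' pulses in the late Miocene and Pliocene, standing in for published
#' paleoelevation series in examples and tests; replace with a measured
#' curve via [env_curve()] for real analyses.
#'
#' @param t_max Oldest age covered (Ma), default 32.
#' @return An [env_curve()] with linear interpolation.
#' @export
sim_paleoelevation_curve <- function(t_max = 32) {
  ages <- seq(0, t_max, by = 0.25)
  logistic <- function(z) 1 / (1 + exp(-z))
  elev <- 0.2 + 4.3 * (0.55 * logistic((10 - ages) / 3.5) +
                         0.45 * logistic((4.5 - ages) / 1.2))
  env_curve(ages, elev)
}
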