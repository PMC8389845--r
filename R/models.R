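#' PUC model parameters
#'
#' Parameters of the Posterior-Utility-Choice model: Gaussian measurement
#' noise `sigma` (rating units, one measurement per time step on the
#' fixated item), uncertainty aversion `A` (utility = posterior mean -
#' A * posterior sd), a Gaussian value prior, a Weibull collapsing decision
#' bound B(t) = B0 * exp(-(t/lambda)^k) on the utility difference, a
#' guessing rate `g` and a non-decision time `tau` (ms, time spent looking
#' after the internal decision).
#'
#' @param sigma Measurement noise sd, > 0 (rating units).
#' @param A Uncertainty-aversion weight (may be negative; forced to 0 when
#'   `zero_A` is set).
#' @param prior A [prior_spec()].
#' @param B0 Initial bound, > 0 (rating units).
#' @param k Bound shape, > 0.
#' @param lam Bound timescale, > 0 (ms).
#' @param g Guessing rate in \[0, 1\].
#' @param tau Non-decision time, >= 0 (ms).
#' @param free_prior_sigma,free_prior_mean,zero_A Variant flags: treat the
#'   prior sd (and mean) as free parameters, or clamp A to 0.
#' @return A `puc_params` object (also class `model_params`).
#' @export
puc_params <- function(sigma, A, prior, B0, k, lam, g, tau,
                       free_prior_sigma = FALSE, free_prior_mean = FALSE,
                       zero_A = FALSE) {
  stopifnot(inherits(prior, "prior_spec"),
            sigma > 0, B0 > 0, k > 0, lam > 0,
            g >= 0, g <= 1, tau >= 0)
  if (zero_A) A <- 0
  structure(
    list(model = "puc", sigma = as.numeric(sigma), A = as.numeric(A),
         prior = prior, B0 = as.numeric(B0), k = as.numeric(k),
         lam = as.numeric(lam), g = as.numeric(g), tau = as.numeric(tau),
         free_prior_sigma = isTRUE(free_prior_sigma),
         free_prior_mean = isTRUE(free_prior_mean),
         zero_A = isTRUE(zero_A)),
    class = c("puc_params", "model_params")
  )
}

#' aDDM / acbDDM parameters
#'
#' Attentional drift-diffusion model: per-step drift d * (r_fix - theta *
#' r_unfix) toward the fixated item plus zero-mean Gaussian noise of sd
#' `sigma` per time step. The bound is fixed at B0 = 1 (the model's scale
#' is arbitrary); with `collapsing = TRUE` (acbDDM) it decays as
#' exp(-(t/lambda)^k).
#'
#' @param sigma Per-step diffusion noise sd, > 0.
#' @param d Drift scaling constant, > 0.
#' @param theta Attentional discount of the unfixated item, in \[0, 1\].
#' @param k,lam Collapsing-bound shape/timescale (used when `collapsing`).
#' @param collapsing FALSE = aDDM (fixed bound), TRUE = acbDDM.
#' @param g Guessing rate in \[0, 1\].
#' @param tau Non-decision time, >= 0 (ms).
#' @return A `ddm_params` object (also class `model_params`).
#' @export
ddm_params <- function(sigma, d, theta, k = 1, lam = 1e9, collapsing = FALSE,
                       g = 0, tau = 0) {
  stopifnot(sigma > 0, d > 0, theta >= 0, theta <= 1, k > 0, lam > 0,
            g >= 0, g <= 1, tau >= 0)
  structure(
    list(model = if (collapsing) "acbddm" else "addm",
         sigma = as.numeric(sigma), d = as.numeric(d),
         theta = as.numeric(theta), k = as.numeric(k),
         lam = as.numeric(lam), collapsing = isTRUE(collapsing),
         g = as.numeric(g), tau = as.numeric(tau)),
    class = c("ddm_params", "model_params")
  )
}

#' @export
print.model_params <- function(x, ...) {
  flds <- setdiff(names(x), c("model", "prior"))
  vals <- vapply(x[flds], function(v) paste(format(v), collapse = ","),
                 character(1))
  cat("<", x$model, " params> ", paste(flds, vals, sep = "=",
                                       collapse = " "), "\n", sep = "")
  if (!is.null(x$prior)) {
    cat("  prior: mu_p=", x$prior$mu_p, " sigma_p=", x$prior$sigma_p,
        "\n", sep = "")
  }
  invisible(x)
}

#' Serialize model parameters to JSON
#'
#' @param params A `model_params` object.
#' @param fixed Optional character vector naming parameters held fixed
#'   during fitting; recorded alongside the values.
#' @return A JSON string.
#' @export
params_to_json <- function(params, fixed = character()) {
  x <- unclass(params)
  if (!is.null(x$prior)) x$prior <- unclass(x$prior)
  x$fixed <- as.character(fixed)
  jsonlite::toJSON(x, auto_unbox = TRUE, digits = NA)
}

#' Deserialize model parameters from JSON
#'
#' @param json JSON string produced by [params_to_json()].
#' @return A `model_params` object (the `fixed` vector is attached as
#'   attribute `"fixed"`).
#' @export
params_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  p <- if (identical(x$model, "puc")) {
    puc_params(x$sigma, x$A, prior_spec(x$prior$mu_p, x$prior$sigma_p),
               x$B0, x$k, x$lam, x$g, x$tau,
               free_prior_sigma = isTRUE(x$free_prior_sigma),
               free_prior_mean = isTRUE(x$free_prior_mean),
               zero_A = isTRUE(x$zero_A))
  } else {
    ddm_params(x$sigma, x$d, x$theta, x$k, x$lam,
               collapsing = identical(x$model, "acbddm"),
               g = x$g, tau = x$tau)
  }
  attr(p, "fixed") <- as.character(x$fixed)
  p
}

#' Gaussian posterior moments after T measurements
#'
#' Conjugate-Gaussian posterior over an item's value after `T` measurements
#' with sample mean `xbar`, measurement noise `sigma`, and prior
#' N(mu_p, sigma_p^2):
#' mu_post = (mu_p/sigma_p^2 + T*xbar/sigma^2) / (1/sigma_p^2 + T/sigma^2),
#' sigma_post = (1/sigma_p^2 + T/sigma^2)^(-1/2).
#'
#' @param prior A [prior_spec()].
#' @param sigma Measurement noise sd, > 0.
#' @param T Number of measurements, integer >= 0.
#' @param xbar Sample mean of the measurements (ignored when `T` is 0).
#' @return Named numeric vector `c(mu_post =, sigma_post =)`.
#' @export
posterior_moments <- function(prior, sigma, T, xbar = 0) {
  stopifnot(inherits(prior, "prior_spec"), sigma > 0, T >= 0)
  T <- unname(T); xbar <- unname(xbar)
  if (T == 0) {
    return(c(mu_post = prior$mu_p, sigma_post = prior$sigma_p))
  }
  kap <- 1 / prior$sigma_p^2 + T / sigma^2
  mu <- (prior$mu_p / prior$sigma_p^2 + T * xbar / sigma^2) / kap
  c(mu_post = mu, sigma_post = 1 / sqrt(kap))
}

#' Initialize a two-item posterior state at the prior
#'
#' @param prior A [prior_spec()].
#' @return A `posterior_state` object with per-item measurement counts `T`,
#'   running sums `S`, and posterior moments, indexed by "left"/"right".
#' @export
posterior_state <- function(prior) {
  structure(
    list(prior = prior,
         T = c(left = 0L, right = 0L),
         S = c(left = 0, right = 0),
         mu_post = c(left = prior$mu_p, right = prior$mu_p),
         sigma_post = c(left = prior$sigma_p, right = prior$sigma_p)),
    class = "posterior_state"
  )
}

#' One-measurement posterior update for one item
#'
#' Incorporates a single measurement `x` of the fixated item. Equivalent to
#' the recursion mu_new = alpha * mu_old + beta * x with
#' alpha = kappa_T / kappa_(T+1), beta = (1/sigma^2) / kappa_(T+1),
#' kappa_T = 1/sigma_p^2 + T/sigma^2. The other item is untouched.
#'
#' @param state A [posterior_state()].
#' @param item "left" or "right".
#' @param x The measurement value.
#' @param sigma Measurement noise sd.
#' @return The updated `posterior_state`.
#' @export
posterior_update_step <- function(state, item = c("left", "right"), x,
                                  sigma) {
  item <- match.arg(item)
  stopifnot(inherits(state, "posterior_state"), sigma > 0)
  state$T[item] <- state$T[item] + 1L
  state$S[item] <- state$S[item] + x
  m <- posterior_moments(state$prior, sigma, state$T[item],
                         state$S[item] / state$T[item])
  state$mu_post[item] <- m[["mu_post"]]
  state$sigma_post[item] <- m[["sigma_post"]]
  state
}

#' Mean-variance utility of a posterior belief
#'
#' Utility = posterior mean - A * posterior sd. A positive `A` encodes
#' uncertainty aversion: gathering measurements shrinks the posterior sd
#' and so raises utility even when the mean is unchanged.
#'
#' @param mu_post,sigma_post Posterior mean and sd (`sigma_post` > 0).
#' @param A Uncertainty-aversion weight.
#' @return Numeric utility.
#' @export
utility <- function(mu_post, sigma_post, A) {
  stopifnot(all(sigma_post > 0))
  mu_post - A * sigma_post
}

#' Threshold utility: posterior probability that value exceeds a criterion
#'
#' An alternative utility aimed at the loss domain: U = Pr(v > v_crit | x)
#' = Phi((mu_post - v_crit) / sigma_post). In the flat-prior case with
#' v_crit = 0 this reduces to Phi(xbar * sqrt(T) / sigma), so an aversive
#' item (negative running mean) becomes *less* preferred with longer
#' looking.
#'
#' @param mu_post,sigma_post Posterior mean and sd (`sigma_post` > 0).
#' @param v_crit Value criterion.
#' @return Probability in (0, 1).
#' @export
utility_threshold <- function(mu_post, sigma_post, v_crit = 0) {
  stopifnot(all(sigma_post > 0))
  stats::pnorm(mu_post, mean = v_crit, sd = sigma_post)
}

#' Decision bound at time t
#'
#' Weibull collapsing bound B(t) = B0 * exp(-(t/lambda)^k); a fixed bound
#' returns B0 for all t. `k = 1` gives simple exponential decay.
#'
#' @param t Time since trial onset, ms, >= 0 (vectorized).
#' @param B0 Initial bound, > 0.
#' @param k,lam Weibull shape and timescale (ms).
#' @param collapsing Logical; FALSE returns the fixed bound B0.
#' @return Numeric bound value(s).
#' @export
bound_at <- function(t, B0, k = 1, lam = 1e9, collapsing = TRUE) {
  if (any(t < 0)) stop("bound_at: negative time")
  stopifnot(B0 > 0, k > 0, lam > 0)
  if (!collapsing) return(rep(B0, length(t)))
  B0 * exp(-(t / lam)^k)
}

#' Deterministic aDDM drift for one time step
#'
#' Drift of the decision variable (positive toward "left") while fixating
#' `side`: d * (r_left - theta * r_right) for left fixations and
#' d * (theta * r_left - r_right) for right fixations. The Gaussian
#' diffusion noise is added by the propagation/simulation layer.
#'
#' @param side "left" or "right".
#' @param r_left,r_right Item ratings.
#' @param d Drift scaling constant.
#' @param theta Attentional discount in \[0, 1\].
#' @return Numeric drift increment per step.
#' @export
addm_increment_mean <- function(side = c("left", "right"), r_left, r_right,
                                d, theta) {
  side <- match.arg(side)
  stopifnot(theta >= 0, theta <= 1)
  if (side == "left") d * (r_left - theta * r_right)
  else d * (theta * r_left - r_right)
}
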