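#' Fit the guess-time distribution for a subject
#'
#' Maximum-likelihood Weibull fit to a subject's observed total fixation
#' times, binned on the step grid with an overflow bin beyond the maximum
#' observed time. Guess trials draw their decision moment from this
#' distribution; it is fitted once per subject, before and independently of
#' model-parameter optimization, so the likelihood stays well defined
#' during fitting.
#'
#' @param total_fixation_times Numeric vector of total fixation times (ms),
#'   at least 5, all positive.
#' @param step_ms Time-bin width in ms (default 100).
#' @return A `guess_time_pmf` object: Weibull `shape`/`scale`, `step_ms`,
#'   `binned_pmf` (one entry per bin plus a final overflow bin), `n_bins`.
#' @export
fit_guess_time_pmf <- function(total_fixation_times, step_ms = 100) {
  x <- as.numeric(total_fixation_times)
  stopifnot(length(x) >= 5L, all(x > 0))
  if (length(unique(x)) == 1L) {
    warning("degenerate total fixation times: using a single-bin point mass")
    b <- max(1L, floor(x[1] / step_ms) + 1L)
    pmf <- c(rep(0, b - 1L), 1, 0)  # point mass + empty overflow
    return(structure(list(shape = NA_real_, scale = NA_real_,
                          step_ms = step_ms, binned_pmf = pmf,
                          n_bins = b),
                     class = "guess_time_pmf"))
  }
  fit <- fitdistrplus::fitdist(x, "weibull",
                               start = list(shape = 1.5, scale = mean(x)))
  shape <- unname(fit$estimate["shape"])
  scale <- unname(fit$estimate["scale"])
  n_bins <- ceiling(max(x) / step_ms)
  edges <- (0:n_bins) * step_ms
  cdf <- stats::pweibull(edges, shape, scale)
  pmf <- c(diff(cdf), 1 - cdf[n_bins + 1L])  # overflow bin beyond max(x)
  structure(list(shape = shape, scale = scale, step_ms = step_ms,
                 binned_pmf = pmf, n_bins = n_bins),
            class = "guess_time_pmf")
}

#' @export
print.guess_time_pmf <- function(x, ...) {
  cat("<guess_time_pmf> Weibull(shape =", round(x$shape, 3),
      ", scale =", round(x$scale, 1), "ms ) |", x$n_bins, "bins x",
      x$step_ms, "ms + overflow\n")
  invisible(x)
}

#' Probability mass of the guess-time distribution at a given time
#'
#' @param guess A `guess_time_pmf`.
#' @param t_ms Time in ms.
#' @return The pmf mass of the bin containing `t_ms` (overflow bin if
#'   beyond the modelled range).
#' @export
guess_pmf_at <- function(guess, t_ms) {
  b <- floor(t_ms / guess$step_ms) + 1L
  b <- pmin(pmax(b, 1L), length(guess$binned_pmf))
  guess$binned_pmf[b]
}

LOG_FLOOR <- log(1e-300)

#' Joint likelihood of one trial's choice and total fixation time
#'
#' Mixes the model component (absorption mass for the chosen side in the
#' time bin containing `T_obs - tau`) with the guessing component (50/50
#' choice, decision moment from the subject's fitted guess-time
#' distribution): p = (1 - g) * p_model + g * p_guess. The decision bin may
#' fall anywhere in the fixation series -- total fixation time is not
#' constrained to come after the last observed fixation -- and contributes
#' 0 to the model component if it falls outside the modelled bins. The log
#' probability is floored at log(1e-300).
#'
#' @param absorption An [absorption_record()] for the trial.
#' @param choice "left" or "right".
#' @param T_obs Observed total fixation time, ms, > 0.
#' @param g Guessing rate.
#' @param tau Non-decision time, ms, >= 0.
#' @param guess A [fit_guess_time_pmf()] object.
#' @return A `trial_likelihood` object: `log_p`, `p_model_component`,
#'   `p_guess_component`.
#' @export
trial_loglik <- function(absorption, choice = c("left", "right"), T_obs,
                         g, tau, guess) {
  choice <- match.arg(choice)
  if (tau < 0) stop("non-decision time tau must be >= 0")
  stopifnot(T_obs > 0, g >= 0, g <= 1)
  step <- absorption$step_ms
  # 0-based decision bin; a decision time on a bin edge belongs to the
  # completed step (the model absorbs at step ends, so simulated total
  # fixation times are exact multiples of the step)
  b <- ceiling((T_obs - tau) / step) - 1
  p_vec <- if (choice == "left") absorption$p_left else absorption$p_right
  p_model <- if (b >= 0 && b < length(p_vec)) p_vec[b + 1L] else 0
  p_guess <- 0.5 * guess_pmf_at(guess, T_obs)
  log_p <- max(log((1 - g) * p_model + g * p_guess), LOG_FLOOR)
  structure(list(log_p = log_p, p_model_component = p_model,
                 p_guess_component = p_guess),
            class = "trial_likelihood")
}

#' Log-likelihood of a parameter set on one subject's data
#'
#' Sum over trials of the joint log probability of (choice, total fixation
#' time), each trial propagated over its own empirical fixation schedule.
#' Deterministic for fixed inputs.
#'
#' @param params A [puc_params()] or [ddm_params()]; the model is taken
#'   from the object.
#' @param dataset A [subject_dataset()].
#' @param step_ms Discretization step in ms (default 100).
#' @param n_grid Optional propagation grid-size override.
#' @param guess Optional precomputed [fit_guess_time_pmf()]; fitted from
#'   the dataset's total fixation times when omitted.
#' @param schedules Optional precomputed list of [step_schedule()]s
#'   matching `dataset$trials` (avoids re-quantizing inside optimization).
#' @param verbose If `TRUE`, message the decision bin and the model/guess
#'   probability components for every trial.
#' @return Scalar log-likelihood.
#' @export
dataset_loglik <- function(params, dataset, step_ms = 100, n_grid = NULL,
                           guess = NULL, schedules = NULL,
                           verbose = FALSE) {
  stopifnot(inherits(dataset, "subject_dataset"),
            inherits(params, "model_params"))
  if (is.null(guess)) {
    guess <- fit_guess_time_pmf(
      vapply(dataset$trials, function(t) t$total_fixation_time, numeric(1)),
      step_ms = step_ms)
  }
  if (is.null(schedules)) {
    schedules <- lapply(dataset$trials,
                        function(t) quantize_fixations(t$fixations, step_ms))
  }
  ll <- 0
  for (i in seq_along(dataset$trials)) {
    tr <- dataset$trials[[i]]
    ab <- tryCatch(
      propagate_trial(schedules[[i]], params, tr$rating_left,
                      tr$rating_right, n_grid = n_grid),
      error = function(e) {
        stop("propagation failed on trial ", tr$trial_id, ": ",
             conditionMessage(e))
      })
    tl <- trial_loglik(ab, tr$choice, tr$total_fixation_time,
                       params$g, params$tau, guess)
    if (verbose) {
      message(sprintf(
        "trial %d: bin %d, p_model %.3g, p_guess %.3g, log_p %.4f",
        tr$trial_id,
        ceiling((tr$total_fixation_time - params$tau) / step_ms) - 1,
        tl$p_model_component, tl$p_guess_component, tl$log_p))
    }
    ll <- ll + tl$log_p
  }
  ll
}

#' Serialize an absorption record or guess-time pmf to JSON
#'
#' Debugging aid: dumps the per-bin probabilities (and, for a guess-time
#' pmf, the fitted Weibull parameters) as a JSON string.
#'
#' @param x An [absorption_record()] or [fit_guess_time_pmf()] object.
#' @return A JSON string.
#' @export
likelihood_to_json <- function(x) {
  stopifnot(inherits(x, c("absorption_record", "guess_time_pmf")))
  jsonlite::toJSON(unclass(x), auto_unbox = TRUE, digits = NA)
}
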