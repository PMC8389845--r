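#' Empirical fixation-duration sampler
#'
#' Continuation fixations (needed when a simulated decision has not yet
#' occurred at the end of the empirical series) are drawn independently
#' with replacement from a pool of fixation durations, with sides strictly
#' alternating; the first side of a fully synthetic series is "left" with
#' probability `first_side_prob_left`.
#'
#' @param duration_pool Numeric vector of fixation durations (ms), all
#'   positive.
#' @param first_side_prob_left Probability the first fixation is on the
#'   left item (default 0.5).
#' @return A `fixation_sampler` object.
#' @export
fixation_sampler <- function(duration_pool, first_side_prob_left = 0.5) {
  duration_pool <- as.numeric(duration_pool)
  stopifnot(length(duration_pool) >= 1L, all(duration_pool > 0),
            first_side_prob_left >= 0, first_side_prob_left <= 1)
  structure(list(duration_pool = duration_pool,
                 first_side_prob_left = first_side_prob_left),
            class = "fixation_sampler")
}

#' Sampler built from a subject's own fixation durations
#'
#' @param dataset A [subject_dataset()].
#' @inheritParams fixation_sampler
#' @return A [fixation_sampler()].
#' @export
subject_fixation_sampler <- function(dataset, first_side_prob_left = 0.5) {
  durs <- unlist(lapply(dataset$trials, function(t) t$fixations$duration))
  fixation_sampler(durs, first_side_prob_left)
}

# draw an alternating fixation series of total duration >= total_ms
draw_fixation_series <- function(sampler, total_ms, first_side = NULL) {
  if (is.null(first_side)) {
    first_side <- if (stats::runif(1) < sampler$first_side_prob_left)
      "left" else "right"
  }
  mean_dur <- mean(sampler$duration_pool)
  n_guess <- max(4L, ceiling(total_ms / mean_dur) + 4L)
  durs <- sample(sampler$duration_pool, n_guess, replace = TRUE)
  while (sum(durs) < total_ms) {
    durs <- c(durs, sample(sampler$duration_pool, n_guess, replace = TRUE))
  }
  durs <- durs[seq_len(which(cumsum(durs) >= total_ms)[1L])]
  sides <- rep(c("left", "right"), length.out = length(durs))
  if (first_side == "right") {
    sides <- rep(c("right", "left"), length.out = length(durs))
  }
  data.frame(side = sides, duration = durs)
}

# side sequence per step for the schedule, extended by sampler-drawn
# continuation fixations (quantized by cumulative rounding) up to max_ms
extend_sides <- function(schedule, sampler, max_ms) {
  sides <- schedule$sides
  have_ms <- length(sides) * schedule$step_ms
  if (!is.null(sampler) && have_ms < max_ms) {
    last <- sides[length(sides)]
    first_cont <- if (last == "left") "right" else "left"
    cont <- draw_fixation_series(sampler, max_ms - have_ms,
                                 first_side = first_cont)
    sides <- c(sides, quantize_fixations(cont, schedule$step_ms)$sides)
  }
  sides
}

# guess-time draw: continuous Weibull when available, else from the pmf
draw_guess_time <- function(guess, n = 1) {
  if (is.finite(guess$shape)) {
    stats::rweibull(n, guess$shape, guess$scale)
  } else {
    (sample.int(length(guess$binned_pmf), n, replace = TRUE,
                prob = guess$binned_pmf) - 0.5) * guess$step_ms
  }
}

# fixation side totals over [0, t_ms] of a per-step side sequence
side_totals <- function(sides, step_ms, t_ms) {
  n_full <- min(floor(t_ms / step_ms), length(sides))
  left <- sum(sides[seq_len(n_full)] == "left") * step_ms
  rem <- t_ms - n_full * step_ms
  if (rem > 0 && n_full < length(sides)) {
    if (sides[n_full + 1L] == "left") left <- left + rem
  }
  c(left = left, right = t_ms - left)
}

#' Vectorized generative simulation over a common side sequence
#'
#' Low-level engine behind [simulate_trial()] and
#' [predict_trial_ensemble()]: simulates `n_reps` independent replicates
#' of the model over one per-step fixation side sequence. Replicates that
#' reach the end of the sequence without absorption get `choice = "none"`.
#'
#' @param params A `model_params` object.
#' @param r_left,r_right Item ratings.
#' @param sides Character vector of "left"/"right", one per step.
#' @param step_ms Step size in ms.
#' @param n_reps Number of replicates.
#' @param guess A [fit_guess_time_pmf()] (required when `g > 0`).
#' @return Data frame with one row per replicate: `choice`,
#'   `decision_time`, `total_fixation_time`, `fix_left_ms`,
#'   `fix_right_ms`, `last_side`, `guessed`.
#' @export
simulate_reps <- function(params, r_left, r_right, sides, step_ms,
                          n_reps, guess = NULL) {
  S <- length(sides)
  model <- params$model
  is_guess <- if (params$g > 0) stats::runif(n_reps) < params$g
              else rep(FALSE, n_reps)
  n_model <- sum(!is_guess)

  dec_step <- rep(NA_integer_, n_reps)   # absorbing step index
  dec_side <- rep(NA_character_, n_reps)
  if (n_model > 0) {
    idx <- which(!is_guess)
    alive <- rep(TRUE, n_model)
    if (model == "puc") {
      mu_p <- params$prior$mu_p; sigma_p <- params$prior$sigma_p
      inv_sp2 <- 1 / sigma_p^2; inv_s2 <- 1 / params$sigma^2
      SL <- numeric(n_model); SR <- numeric(n_model)
      TL <- 0L; TR <- 0L
      for (t in seq_len(S)) {
        if (!any(alive)) break
        v <- if (sides[t] == "left") r_left else r_right
        x <- stats::rnorm(n_model, v, params$sigma)
        if (sides[t] == "left") { SL <- SL + ifelse(alive, x, 0); TL <- TL + 1L }
        else { SR <- SR + ifelse(alive, x, 0); TR <- TR + 1L }
        kapL <- inv_sp2 + TL * inv_s2; kapR <- inv_sp2 + TR * inv_s2
        muL <- (mu_p * inv_sp2 + SL * inv_s2) / kapL
        muR <- (mu_p * inv_sp2 + SR * inv_s2) / kapR
        dv <- (muL - muR) - params$A * (1 / sqrt(kapL) - 1 / sqrt(kapR))
        B <- bound_at(t * step_ms, params$B0, params$k, params$lam,
                      collapsing = TRUE)
        hit <- alive & abs(dv) >= B
        if (any(hit)) {
          dec_step[idx[hit]] <- t
          dec_side[idx[hit]] <- ifelse(dv[hit] >= 0, "left", "right")
          alive[hit] <- FALSE
        }
      }
    } else {
      dv <- numeric(n_model)
      dl <- addm_increment_mean("left", r_left, r_right, params$d,
                                params$theta)
      dr <- addm_increment_mean("right", r_left, r_right, params$d,
                                params$theta)
      for (t in seq_len(S)) {
        if (!any(alive)) break
        drift <- if (sides[t] == "left") dl else dr
        dv <- dv + ifelse(alive, drift + stats::rnorm(n_model, 0,
                                                      params$sigma), 0)
        B <- bound_at(t * step_ms, 1, params$k, params$lam,
                      collapsing = params$collapsing)
        hit <- alive & abs(dv) >= B
        if (any(hit)) {
          dec_step[idx[hit]] <- t
          dec_side[idx[hit]] <- ifelse(dv[hit] >= 0, "left", "right")
          alive[hit] <- FALSE
        }
      }
    }
  }

  choice <- rep("none", n_reps)
  decision_time <- rep(NA_real_, n_reps)
  total_time <- rep(NA_real_, n_reps)
  guessed <- is_guess

  done <- !is.na(dec_step)
  choice[done] <- dec_side[done]
  decision_time[done] <- dec_step[done] * step_ms
  total_time[done] <- decision_time[done] + params$tau

  if (any(is_guess)) {
    if (is.null(guess)) stop("g > 0 requires a guess-time distribution")
    ng <- sum(is_guess)
    tg <- pmax(draw_guess_time(guess, ng), 1)
    choice[is_guess] <- ifelse(stats::runif(ng) < 0.5, "left", "right")
    total_time[is_guess] <- tg
    decision_time[is_guess] <- pmax(tg - params$tau, 0)
  }

  fl <- rep(NA_real_, n_reps); fr <- rep(NA_real_, n_reps)
  last <- rep(NA_character_, n_reps)
  for (i in which(choice != "none")) {
    st <- side_totals(sides, step_ms, min(total_time[i], S * step_ms))
    fl[i] <- st[["left"]]; fr[i] <- st[["right"]]
    dstep <- max(1L, min(ceiling(decision_time[i] / step_ms), S))
    last[i] <- sides[dstep]
  }
  data.frame(choice = choice, decision_time = decision_time,
             total_fixation_time = total_time,
             fix_left_ms = fl, fix_right_ms = fr,
             last_side = last, guessed = guessed,
             stringsAsFactors = FALSE)
}

#' Simulate a single trial in generative mode
#'
#' Runs the chosen model forward over the given fixation schedule. With
#' probability `g` the trial is a guess (uniform choice, decision moment
#' from the guess-time distribution); otherwise the model steps until the
#' decision variable reaches the (possibly collapsing) bound. If the
#' schedule is exhausted before absorption and a sampler is supplied,
#' continuation fixations are drawn from it; without a sampler the outcome
#' is `choice = "none"`.
#'
#' @param params A [puc_params()] or [ddm_params()].
#' @param r_left,r_right Item ratings.
#' @param schedule A [step_schedule()].
#' @param sampler Optional [fixation_sampler()] for continuation fixations.
#' @param guess Optional [fit_guess_time_pmf()] (required when `g > 0`).
#' @param max_ms Simulation horizon in ms (default 30000).
#' @param seed Optional integer seed for reproducibility.
#' @return A one-row data frame: `choice` ("left"/"right"/"none"),
#'   `decision_time`, `total_fixation_time` (= decision time + tau),
#'   `fix_left_ms`, `fix_right_ms`, `last_side`, `guessed`.
#' @export
simulate_trial <- function(params, r_left, r_right, schedule,
                           sampler = NULL, guess = NULL, max_ms = 30000,
                           seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  sides <- extend_sides(schedule, sampler, max_ms)
  simulate_reps(params, r_left, r_right, sides, schedule$step_ms, 1L,
                guess = guess)
}

#' Ensemble of model predictions for one observed trial
#'
#' Simulates `n_reps` outcomes for a trial, each using the trial's
#' empirical fixation schedule followed by sampler-drawn continuation
#' fixations, giving model-predicted summary statistics with unrestricted
#' total fixation times.
#'
#' @param params A `model_params` object.
#' @param trial A [new_trial()].
#' @param sampler A [fixation_sampler()].
#' @param n_reps Number of replicates (default 10).
#' @param guess Optional [fit_guess_time_pmf()] (required when `g > 0`).
#' @param step_ms Discretization step (default 100).
#' @param max_ms Simulation horizon per replicate (default 30000).
#' @param seed Optional integer seed.
#' @return A data frame with `n_reps` rows (columns as [simulate_trial()]),
#'   plus the trial's ratings attached as columns `rating_left`,
#'   `rating_right`.
#' @export
predict_trial_ensemble <- function(params, trial, sampler, n_reps = 10,
                                   guess = NULL, step_ms = 100,
                                   max_ms = 30000, seed = NULL) {
  stopifnot(n_reps >= 1)
  if (!is.null(seed)) set.seed(seed)
  schedule <- quantize_fixations(trial$fixations, step_ms)
  # each replicate gets its own continuation draw
  out <- do.call(rbind, lapply(seq_len(n_reps), function(r) {
    sides <- extend_sides(schedule, sampler, max_ms)
    simulate_reps(params, trial$rating_left, trial$rating_right, sides,
                  step_ms, 1L, guess = guess)
  }))
  out$rating_left <- trial$rating_left
  out$rating_right <- trial$rating_right
  out
}
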