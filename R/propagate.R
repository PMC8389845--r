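#' Absorption record constructor (internal use by the propagators)
#'
#' Per-time-bin probability of the decision variable crossing the upper
#' (left-choice) and lower (right-choice) bound, plus the probability mass
#' surviving past the final modelled bin.
#'
#' @param step_ms Time-bin width in ms.
#' @param p_left,p_right Numeric vectors, one entry per time bin.
#' @param p_survive Scalar surviving mass.
#' @return An `absorption_record` object.
#' @export
absorption_record <- function(step_ms, p_left, p_right, p_survive) {
  stopifnot(length(p_left) == length(p_right), length(p_left) >= 1L)
  structure(list(step_ms = as.numeric(step_ms),
                 p_left = as.numeric(p_left),
                 p_right = as.numeric(p_right),
                 p_survive = as.numeric(p_survive)),
            class = "absorption_record")
}

#' @export
print.absorption_record <- function(x, ...) {
  cat("<absorption_record>", length(x$p_left), "bins x", x$step_ms, "ms |",
      "P(left) =", round(sum(x$p_left), 4),
      "P(right) =", round(sum(x$p_right), 4),
      "P(survive) =", round(x$p_survive, 4), "\n")
  invisible(x)
}

#' Total mass check for an absorption record
#'
#' @param x An [absorption_record()].
#' @return `sum(p_left) + sum(p_right) + p_survive` (should be 1).
#' @export
total_mass <- function(x) sum(x$p_left) + sum(x$p_right) + x$p_survive

side_codes <- function(sides) ifelse(sides == "left", 0L, 1L)

#' Propagate the aDDM / acbDDM decision-variable distribution
#'
#' Discrete-time propagation of the 1-D decision-variable density over a
#' trial's fixation schedule: starting from a point mass at 0, each step
#' shifts the density by the fixation-dependent drift, convolves it with
#' zero-mean Gaussian noise of sd `sigma`, and removes (into the per-bin
#' absorption record) the mass at or beyond the symmetric bound, which is
#' fixed at 1 for the aDDM and Weibull-collapsing for the acbDDM. Surviving
#' mass is carried without renormalization.
#'
#' @param schedule A [step_schedule()].
#' @param params A [ddm_params()]; `sigma` is the per-step noise sd at the
#'   schedule's step size.
#' @param r_left,r_right Item ratings.
#' @param n_grid Number of grid points (default 601) over
#'   `[-1.5, 1.5] * B0` with `B0 = 1`.
#' @return An [absorption_record()].
#' @export
propagate_addm <- function(schedule, params, r_left, r_right,
                           n_grid = 601) {
  stopifnot(inherits(schedule, "step_schedule"),
            inherits(params, "ddm_params"))
  S <- length(schedule$sides)
  bounds <- bound_at(seq_len(S) * schedule$step_ms, B0 = 1,
                     k = params$k, lam = params$lam,
                     collapsing = params$collapsing)
  res <- cpp_propagate_addm(
    side_codes(schedule$sides),
    addm_increment_mean("left", r_left, r_right, params$d, params$theta),
    addm_increment_mean("right", r_left, r_right, params$d, params$theta),
    params$sigma, bounds, as.integer(n_grid), 1.5)
  absorption_record(schedule$step_ms, res$p_left, res$p_right,
                    res$p_survive)
}

#' Propagate the PUC decision-variable distribution
#'
#' The PUC decision variable U_left - U_right is a deterministic function
#' of the two posterior means (given the fixation schedule), but it is not
#' Markov on its own, so propagation runs on the joint 2-D grid over
#' (mu_post_left, mu_post_right). Each step applies, along the fixated
#' item's axis only, the conjugate-update contraction plus measurement
#' noise; the posterior standard deviations evolve deterministically with
#' the measurement counts. Mass in the region where the utility difference
#' reaches +/- the (possibly collapsing) bound is absorbed per bin. Before
#' an item's first measurement its axis is an exact point mass at the prior
#' mean, so early propagation is 0-D/1-D and expands to 2-D on the other
#' item's first measurement.
#'
#' @param schedule A [step_schedule()]; one value measurement of the
#'   fixated item per step.
#' @param params A [puc_params()].
#' @param r_left,r_right Item ratings (used as the items' true values).
#' @param n_grid Grid points per axis (default 401, at which doubling the
#'   grid changes bin probabilities by well under 1e-3). Both axes share the
#'   range `[min(mu_p, r) - 6 sigma_p, max(mu_p, r) + 6 sigma_p]` over both
#'   ratings, keeping left/right exchange symmetry exact on the grid.
#' @return An [absorption_record()].
#' @export
propagate_puc <- function(schedule, params, r_left, r_right,
                          n_grid = 401) {
  stopifnot(inherits(schedule, "step_schedule"),
            inherits(params, "puc_params"))
  S <- length(schedule$sides)
  bounds <- bound_at(seq_len(S) * schedule$step_ms, B0 = params$B0,
                     k = params$k, lam = params$lam, collapsing = TRUE)
  mu_p <- params$prior$mu_p
  sigma_p <- params$prior$sigma_p
  g_lo <- min(mu_p, r_left, r_right) - 6 * sigma_p
  g_hi <- max(mu_p, r_left, r_right) + 6 * sigma_p
  res <- cpp_propagate_puc(
    side_codes(schedule$sides), r_left, r_right, mu_p, sigma_p,
    params$sigma, params$A, bounds, as.integer(n_grid), g_lo, g_hi)
  absorption_record(schedule$step_ms, res$p_left, res$p_right,
                    res$p_survive)
}

#' Propagate a trial under any of the three models
#'
#' @param schedule A [step_schedule()].
#' @param params A [puc_params()] or [ddm_params()].
#' @param r_left,r_right Item ratings.
#' @param n_grid Optional grid-size override (model-specific default).
#' @return An [absorption_record()].
#' @export
propagate_trial <- function(schedule, params, r_left, r_right,
                            n_grid = NULL) {
  if (inherits(params, "puc_params")) {
    propagate_puc(schedule, params, r_left, r_right,
                  n_grid = if (is.null(n_grid)) 401 else n_grid)
  } else {
    propagate_addm(schedule, params, r_left, r_right,
                   n_grid = if (is.null(n_grid)) 601 else n_grid)
  }
}
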