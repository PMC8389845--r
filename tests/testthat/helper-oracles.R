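# Independent oracles and fixture builders. The Monte-Carlo simulators
# here deliberately re-implement the model dynamics in plain R, separate
# from both the C++ propagators and the package's generative simulator.

# brute-force Gaussian-posterior moments by discretizing value on a fine
# grid and applying Bayes' rule
grid_bayes_posterior <- function(mu_p, sigma_p, sigma, xs, n = 20001L) {
  v <- seq(mu_p - 10 * sigma_p, mu_p + 10 * sigma_p, length.out = n)
  logpost <- stats::dnorm(v, mu_p, sigma_p, log = TRUE)
  for (x in xs) logpost <- logpost + stats::dnorm(x, v, sigma, log = TRUE)
  w <- exp(logpost - max(logpost))
  w <- w / sum(w)
  mu <- sum(w * v)
  c(mu = mu, sd = sqrt(sum(w * (v - mu)^2)))
}

# Monte-Carlo first-passage simulation of the aDDM / acbDDM dynamics
mc_addm <- function(sides, params, r_left, r_right, n = 1e5,
                    step_ms = 100) {
  S <- length(sides)
  dl <- params$d * (r_left - params$theta * r_right)
  dr <- params$d * (params$theta * r_left - r_right)
  dv <- numeric(n)
  alive <- rep(TRUE, n)
  bin <- rep(NA_integer_, n)
  side <- rep(NA_integer_, n)  # 1 = left, 2 = right
  for (t in seq_len(S)) {
    drift <- if (sides[t] == "left") dl else dr
    dv[alive] <- dv[alive] + drift + stats::rnorm(sum(alive), 0,
                                                  params$sigma)
    B <- pucddm::bound_at(t * step_ms, 1, params$k, params$lam,
                          params$collapsing)
    hit <- alive & abs(dv) >= B
    bin[hit] <- t
    side[hit] <- ifelse(dv[hit] >= 0, 1L, 2L)
    alive[hit] <- FALSE
  }
  list(bin = bin, side = side, n = n, n_steps = S)
}

# Monte-Carlo simulation of the PUC measurement process: sample one value
# measurement per step for the fixated item, update the conjugate
# posterior, stop when the utility difference reaches the bound
mc_puc <- function(sides, params, r_left, r_right, n = 1e5,
                   step_ms = 100) {
  S <- length(sides)
  mp <- params$prior$mu_p
  sp <- params$prior$sigma_p
  isp2 <- 1 / sp^2
  is2 <- 1 / params$sigma^2
  SL <- numeric(n); SR <- numeric(n)
  TL <- 0; TR <- 0
  alive <- rep(TRUE, n)
  bin <- rep(NA_integer_, n)
  side <- rep(NA_integer_, n)
  for (t in seq_len(S)) {
    if (sides[t] == "left") {
      SL <- SL + stats::rnorm(n, r_left, params$sigma); TL <- TL + 1
    } else {
      SR <- SR + stats::rnorm(n, r_right, params$sigma); TR <- TR + 1
    }
    kL <- isp2 + TL * is2
    kR <- isp2 + TR * is2
    muL <- (mp * isp2 + SL * is2) / kL
    muR <- (mp * isp2 + SR * is2) / kR
    dv <- (muL - muR) - params$A * (1 / sqrt(kL) - 1 / sqrt(kR))
    B <- pucddm::bound_at(t * step_ms, params$B0, params$k, params$lam,
                          TRUE)
    hit <- alive & abs(dv) >= B
    bin[hit] <- t
    side[hit] <- ifelse(dv[hit] >= 0, 1L, 2L)
    alive[hit] <- FALSE
  }
  list(bin = bin, side = side, n = n, n_steps = S)
}

# compare an absorption record with a Monte-Carlo run: total choice
# probabilities and the decision-time CDF, in units of binomial SE under
# the propagated probabilities (the hypothesis being tested; SE estimated
# from the MC proportion is badly biased for rare outcomes). CDF bins
# outside (0.01, 0.99) are skipped: their SE degenerates and the
# normal-approximation comparison is ill-posed.
mc_deviation <- function(record, mc) {
  n <- mc$n
  pl <- sum(record$p_left)
  pr <- sum(record$p_right)
  ml <- sum(mc$side == 1L, na.rm = TRUE) / n
  mr <- sum(mc$side == 2L, na.rm = TRUE) / n
  se_l <- sqrt(max(pl * (1 - pl), 1 / n) / n)
  se_r <- sqrt(max(pr * (1 - pr), 1 / n) / n)
  cdf_p <- cumsum(record$p_left + record$p_right)
  tab <- tabulate(mc$bin[!is.na(mc$bin)], nbins = mc$n_steps)
  cdf_m <- cumsum(tab) / n
  keep <- cdf_p > 0.01 & cdf_p < 0.99
  cdf_dev <- if (any(keep)) {
    max(abs(cdf_p - cdf_m)[keep] / sqrt(cdf_p * (1 - cdf_p) / n)[keep])
  } else 0
  c(dev_left = abs(pl - ml) / se_l,
    dev_right = abs(pr - mr) / se_r,
    dev_cdf = cdf_dev)
}

# small valid datasets for I/O and invariance tests
make_test_trial <- function(id, seed = id) {
  set.seed(seed)
  n_fix <- sample(1:5, 1)
  fx <- data.frame(
    side = rep(c("left", "right"), length.out = n_fix),
    duration = round(stats::runif(n_fix, 150, 800), 3))
  new_trial(id, sample(-10:10, 1), sample(-10:10, 1), fx,
            choice = sample(c("left", "right"), 1))
}

make_test_dataset <- function(subject_id = "s1", n_trials = 6, seed = 1) {
  set.seed(seed)
  subject_dataset(subject_id,
                  lapply(seq_len(n_trials), function(i)
                    make_test_trial(i, seed = seed * 100 + i)))
}

random_schedule <- function(max_steps = 25, step_ms = 100) {
  n <- sample(2:max_steps, 1)
  # runs of fixations, alternating sides
  sides <- character(0)
  side <- sample(c("left", "right"), 1)
  while (length(sides) < n) {
    run <- sample(1:6, 1)
    sides <- c(sides, rep(side, run))
    side <- if (side == "left") "right" else "left"
  }
  step_schedule(step_ms, sides[seq_len(n)])
}

random_ddm_params <- function(collapsing = NA) {
  if (is.na(collapsing)) collapsing <- stats::runif(1) < 0.5
  ddm_params(stats::runif(1, 0.15, 0.5), stats::runif(1, 0.01, 0.08),
             stats::runif(1, 0.2, 0.9),
             k = stats::runif(1, 1, 3), lam = stats::runif(1, 1500, 5000),
             collapsing = collapsing,
             g = stats::runif(1, 0, 0.1), tau = stats::runif(1, 0, 300))
}

random_puc_params <- function() {
  puc_params(stats::runif(1, 1.5, 5), stats::runif(1, 0.1, 0.8),
             prior_spec(stats::runif(1, -1, 1), stats::runif(1, 4, 7)),
             B0 = stats::runif(1, 1.5, 6), k = stats::runif(1, 1.5, 3),
             lam = stats::runif(1, 1500, 5000),
             g = stats::runif(1, 0, 0.1), tau = stats::runif(1, 0, 300))
}
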