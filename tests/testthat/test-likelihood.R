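test_that("guess-time Weibull fit recovers simulated shapes", {
  set.seed(9)
  x <- stats::rweibull(1e4, shape = 2, scale = 1500)
  g <- fit_guess_time_pmf(x)
  expect_lt(abs(g$shape - 2) / 2, 0.05)
  expect_equal(sum(g$binned_pmf), 1, tolerance = 1e-6)

  x1 <- stats::rweibull(1e4, shape = 1, scale = 1200)
  g1 <- fit_guess_time_pmf(x1)
  expect_lt(abs(g1$shape - 1), 0.05)

  expect_error(fit_guess_time_pmf(c(100, 200)), "length")
  expect_warning(gd <- fit_guess_time_pmf(rep(500, 10)), "degenerate")
  expect_equal(sum(gd$binned_pmf), 1)
  expect_equal(guess_pmf_at(gd, 510), 1)
})

test_that("trial likelihood mixes model and guess components", {
  rec <- absorption_record(100, p_left = c(0.1, 0.12, 0.2),
                           p_right = c(0.05, 0.1, 0.13), p_survive = 0.3)
  set.seed(2)
  guess <- fit_guess_time_pmf(stats::rweibull(200, 2, 1500))

  # pure guess: independent of the absorption record
  tl <- trial_loglik(rec, "left", T_obs = 250, g = 1, tau = 0, guess)
  expect_equal(tl$log_p, log(0.5 * guess_pmf_at(guess, 250)))

  # pure model: picks the absorption mass of the decision bin
  tl2 <- trial_loglik(rec, "left", T_obs = 250, g = 0, tau = 100, guess)
  expect_equal(tl2$log_p, log(0.12))
  expect_equal(tl2$p_model_component, 0.12)

  # decision bin before zero: only the guess component contributes
  tl3 <- trial_loglik(rec, "right", T_obs = 80, g = 0.3, tau = 200, guess)
  expect_equal(tl3$p_model_component, 0)
  expect_equal(exp(tl3$log_p), 0.3 * tl3$p_guess_component,
               tolerance = 1e-12)

  # mixture identity
  tl4 <- trial_loglik(rec, "right", T_obs = 250, g = 0.2, tau = 0, guess)
  expect_equal(exp(tl4$log_p),
               0.8 * tl4$p_model_component + 0.2 * tl4$p_guess_component,
               tolerance = 1e-12)

  # floored at log(1e-300)
  tl5 <- trial_loglik(rec, "left", T_obs = 5000, g = 0, tau = 0, guess)
  expect_equal(tl5$log_p, log(1e-300))
  expect_error(trial_loglik(rec, "left", 250, 0.1, tau = -1, guess),
               "tau")

  # a decision time exactly on a bin edge belongs to the completed step
  tl6 <- trial_loglik(rec, "left", T_obs = 300, g = 0, tau = 0, guess)
  expect_equal(tl6$p_model_component, 0.2)

  # debug serialization round-trips the per-bin probabilities
  js <- jsonlite::fromJSON(likelihood_to_json(rec))
  expect_equal(js$p_left, rec$p_left)
  expect_equal(jsonlite::fromJSON(likelihood_to_json(guess))$shape,
               guess$shape)
})

test_that("dataset log-likelihood sums per-trial terms order-invariantly", {
  set.seed(17)
  gen <- generate_synthetic_experiment(
    synth_config(n_subjects = 1, trials_per_subject = 12, model = "addm"),
    seed = 5)
  ds <- gen$datasets[[1]]
  p <- gen$manifest$subjects[[1]]
  ll <- dataset_loglik(p, ds, n_grid = 201)
  perm <- sample(length(ds$trials))
  ds2 <- subject_dataset(ds$subject_id, ds$trials[perm], ds$rating_scale)
  # same guess pmf: it is order-invariant too, but fit once for speed
  guess <- fit_guess_time_pmf(
    vapply(ds$trials, function(t) t$total_fixation_time, numeric(1)))
  expect_equal(dataset_loglik(p, ds2, n_grid = 201, guess = guess),
               dataset_loglik(p, ds, n_grid = 201, guess = guess),
               tolerance = 1e-12)

  # single-trial dataset equals that trial's log_p
  one <- subject_dataset("s", ds$trials[1])
  sch <- quantize_fixations(ds$trials[[1]]$fixations, 100)
  rec <- propagate_addm(sch, p, ds$trials[[1]]$rating_left,
                        ds$trials[[1]]$rating_right, n_grid = 201)
  expect_equal(dataset_loglik(p, one, n_grid = 201, guess = guess),
               trial_loglik(rec, ds$trials[[1]]$choice,
                            ds$trials[[1]]$total_fixation_time,
                            p$g, p$tau, guess)$log_p)
})

test_that("true PUC parameters beat a noise-doubled alternative in likelihood", {
  set.seed(23)
  wins <- 0L
  n_rep <- 20L
  for (r in seq_len(n_rep)) {
    gen <- generate_synthetic_experiment(
      synth_config(n_subjects = 1, trials_per_subject = 200,
                   model = "puc"),
      seed = 1000 + r)
    ds <- gen$datasets[[1]]
    truth <- gen$manifest$subjects[[1]]
    worse <- truth
    worse$sigma <- truth$sigma * 2
    guess <- fit_guess_time_pmf(
      vapply(ds$trials, function(t) t$total_fixation_time, numeric(1)))
    ll_true <- dataset_loglik(truth, ds, n_grid = 61, guess = guess)
    ll_worse <- dataset_loglik(worse, ds, n_grid = 61, guess = guess)
    if (ll_true > ll_worse) wins <- wins + 1L
  }
  expect_gte(wins, ceiling(0.95 * n_rep))
})
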