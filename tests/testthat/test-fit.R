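test_that("information criteria match the closed formulas", {
  ic <- information_criteria(-100, 5, 95)
  expect_equal(ic[["aicc"]], 210 + 60 / 89, tolerance = 1e-10)
  expect_equal(ic[["bic"]], 200 + 5 * log(95), tolerance = 1e-10)

  ic0 <- information_criteria(-50, 0, 40)
  expect_equal(ic0[["aicc"]], 100)
  expect_equal(ic0[["bic"]], 100)

  # AICc tends to AIC as n grows
  ic_big <- information_criteria(-100, 5, 1e9)
  expect_equal(ic_big[["aicc"]], 210, tolerance = 1e-6)

  expect_error(information_criteria(-10, 5, 6), "AICc undefined")

  # random-input agreement with an independently coded formula
  set.seed(4)
  for (i in 1:20) {
    ll <- stats::runif(1, -500, -10)
    k <- sample(1:8, 1)
    n <- sample((k + 2):300, 1)
    ic <- information_criteria(ll, k, n)
    expect_equal(ic[["aicc"]],
                 -2 * ll + 2 * k * n / (n - k - 1), tolerance = 1e-10)
    expect_equal(ic[["bic"]], -2 * ll + k * log(n), tolerance = 1e-10)
  }
})

make_fake_fit <- function(id, model, loglik, k = 5, n = 95) {
  ic <- information_criteria(loglik, k, n)
  structure(list(subject_id = as.character(id), model = model,
                 params_hat = NULL,
                 loglik = loglik, n_free_params = k, n_trials = n,
                 aicc = ic[["aicc"]], bic = ic[["bic"]], starts = NULL),
            class = "fit_result")
}

test_that("model comparison sums subject differences with bootstrap CIs", {
  # identical fits: zero differences, degenerate CIs
  fits <- list(m1 = lapply(1:6, make_fake_fit, model = "m1",
                           loglik = -100),
               m2 = lapply(1:6, make_fake_fit, model = "m2",
                           loglik = -100))
  cr <- compare_models(fits, c("m1", "m2"), n_boot = 500, seed = 1)
  for (m in c("negll", "aicc", "bic")) {
    expect_equal(cr[[m]]$estimate, 0)
    expect_equal(cr[[m]]$ci_lower, 0)
    expect_equal(cr[[m]]$ci_upper, 0)
  }

  # equal parameter counts: delta AICc equals delta BIC exactly
  set.seed(2)
  ll1 <- stats::runif(8, -300, -200); ll2 <- stats::runif(8, -300, -200)
  fits2 <- list(a = lapply(1:8, function(i)
                  make_fake_fit(i, "a", ll1[i], k = 7)),
                b = lapply(1:8, function(i)
                  make_fake_fit(i, "b", ll2[i], k = 7)))
  cr2 <- compare_models(fits2, c("a", "b"), n_boot = 500, seed = 1)
  expect_equal(cr2$aicc$estimate, cr2$bic$estimate)
  expect_equal(cr2$aicc$ci_lower, cr2$bic$ci_lower)
  # sign convention: first-mentioned model minus second
  expect_equal(cr2$negll$estimate, sum(-ll1) - sum(-ll2))
  expect_true(cr2$negll$ci_lower <= cr2$negll$estimate &
                cr2$negll$estimate <= cr2$negll$ci_upper)

  # subject mismatch is an error naming the stray ids
  fits3 <- list(a = fits2$a, b = fits2$b[1:7])
  expect_error(compare_models(fits3, c("a", "b"), n_boot = 10), "8")

  # point estimate invariant to subject order; bootstrap seed-stable
  fits4 <- list(a = fits2$a[sample(8)], b = fits2$b)
  cr4 <- compare_models(fits4, c("a", "b"), n_boot = 500, seed = 1)
  expect_equal(cr4$negll$estimate, cr2$negll$estimate)
  cr5 <- compare_models(fits2, c("a", "b"), n_boot = 500, seed = 1)
  expect_equal(cr5$aicc$ci_upper, cr2$aicc$ci_upper)
})

test_that("bootstrap CIs cover the true summed difference at nominal rate", {
  # per-subject differences i.i.d. N(-10, 5^2), 39 subjects: the summed
  # mean is -390; percentile CIs should cover it ~95% of the time
  set.seed(31)
  n_meta <- 200
  cover <- 0L
  for (r in seq_len(n_meta)) {
    d <- stats::rnorm(39, -10, 5)
    idx <- matrix(sample.int(39, 39 * 2000, replace = TRUE), nrow = 2000)
    sums <- rowSums(matrix(d[idx], nrow = 2000))
    ci <- stats::quantile(sums, c(0.025, 0.975), names = FALSE)
    if (ci[1] <= -390 && -390 <= ci[2]) cover <- cover + 1L
  }
  expect_gt(cover / n_meta, 0.90)
  expect_lt(cover / n_meta, 0.99)
})

test_that("subject fits are seed-deterministic and beat their starts", {
  gen <- generate_synthetic_experiment(
    synth_config(n_subjects = 1, trials_per_subject = 40, model = "addm"),
    seed = 51)
  ds <- gen$datasets[[1]]
  cfg <- fit_config(n_starts = 2, maxit = 60, reltol = 1e-4,
                    n_grid = 151, seed = 3)
  f1 <- fit_subject(ds, "addm", cfg)
  f2 <- fit_subject(ds, "addm", cfg)
  expect_equal(f1$params_hat, f2$params_hat)
  expect_equal(f1$loglik, f2$loglik)
  # never worse than the best start's initial value
  expect_gte(f1$loglik, max(f1$starts$value_init) - 1e-9)
  # information criteria consistent with the reported log-likelihood
  ic <- information_criteria(f1$loglik, f1$n_free_params, f1$n_trials)
  expect_equal(f1$aicc, ic[["aicc"]])
  expect_equal(f1$bic, ic[["bic"]])
  expect_equal(f1$n_free_params, 5L)

  # achieved optimum dominates the generating parameters (MLE property)
  truth <- gen$manifest$subjects[[1]]
  guess <- fit_guess_time_pmf(
    vapply(ds$trials, function(t) t$total_fixation_time, numeric(1)))
  ll_true <- dataset_loglik(truth, ds, n_grid = 151, guess = guess)
  expect_gte(f1$loglik, ll_true - 1e-3)
})

test_that("free-parameter counts follow the model and variant flags", {
  fp <- pucddm:::free_param_names
  expect_length(fp("puc"), 7)
  expect_length(fp("acbddm"), 7)
  expect_length(fp("addm"), 5)
  expect_length(fp("puc", zero_A = TRUE), 6)
  expect_length(fp("puc", free_prior_sigma = TRUE), 8)
  expect_length(fp("puc", free_prior_sigma = TRUE,
                   free_prior_mean = TRUE), 9)
  expect_false("A" %in% fp("puc", zero_A = TRUE))
  expect_true(all(c("k", "lam") %in% fp("acbddm")))
  expect_false(any(c("k", "lam") %in% fp("addm")))
})
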