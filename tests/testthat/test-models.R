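test_that("posterior moments match conjugate formulas and a grid-Bayes oracle", {
  pr <- prior_spec(0, 1)
  # no data returns the prior
  expect_equal(posterior_moments(pr, sigma = 1, T = 0),
               c(mu_post = 0, sigma_post = 1))
  # flat-prior limit: mu -> xbar, sigma_post -> sigma / sqrt(T)
  m <- posterior_moments(prior_spec(0, 1e6), sigma = 1, T = 4, xbar = 3)
  expect_equal(m[["mu_post"]], 3, tolerance = 1e-6)
  expect_equal(m[["sigma_post"]], 0.5, tolerance = 1e-6)
  # grid-Bayes oracle
  oracle <- grid_bayes_posterior(0, 1, 1, xs = 2)
  m2 <- posterior_moments(pr, sigma = 1, T = 1, xbar = 2)
  expect_equal(m2[["mu_post"]], oracle[["mu"]], tolerance = 1e-4)
  expect_equal(m2[["sigma_post"]], oracle[["sd"]], tolerance = 1e-4)
  # sigma_post independent of xbar, strictly decreasing in T
  sds <- vapply(0:10, function(T)
    posterior_moments(pr, 2, T, xbar = stats::runif(1, -5, 5))[["sigma_post"]],
    numeric(1))
  expect_true(all(diff(sds) < 0))
})

test_that("sequential updates equal the batch posterior (conjugacy)", {
  set.seed(5)
  for (rep in 1:10) {
    pr <- prior_spec(stats::runif(1, -2, 2), stats::runif(1, 0.5, 5))
    sigma <- stats::runif(1, 0.5, 4)
    xs <- stats::rnorm(sample(1:12, 1), 1, 2)
    st <- posterior_state(pr)
    for (x in xs) st <- posterior_update_step(st, "left", x, sigma)
    batch <- posterior_moments(pr, sigma, length(xs), mean(xs))
    expect_equal(st$mu_post[["left"]], batch[["mu_post"]],
                 tolerance = 1e-12)
    expect_equal(st$sigma_post[["left"]], batch[["sigma_post"]],
                 tolerance = 1e-12)
    # the non-updated item is untouched
    expect_equal(st$T[["right"]], 0L)
    expect_equal(st$mu_post[["right"]], pr$mu_p)
    expect_equal(st$sigma_post[["right"]], pr$sigma_p)
  }
  # equal-precision first update averages prior mean and measurement
  st <- posterior_update_step(posterior_state(prior_spec(1, 1)), "left",
                              x = 3, sigma = 1)
  expect_equal(st$mu_post[["left"]], 2)
})

test_that("utility functions behave per the mean-sd and threshold forms", {
  expect_equal(utility(2, 1, A = 0), 2)
  expect_equal(utility(2, 1, A = 2), 0)
  # for A > 0 utility strictly increases as sigma_post decreases
  u <- utility(1, c(3, 2, 1, 0.5), A = 0.7)
  expect_true(all(diff(u) > 0))

  expect_equal(utility_threshold(5, 2, v_crit = 5), 0.5)
  expect_equal(utility_threshold(1e8, 1, v_crit = 0), 1)
  # flat-prior loss domain: negative running mean, growing T lowers U
  sigma <- 2
  xbar <- -0.8
  Ts <- 1:20
  u_t <- stats::pnorm(xbar * sqrt(Ts) / sigma)
  expect_true(all(diff(u_t) < 0))
  # ranking agreement with mean-sd utility at A = 0, equal sigma_post
  expect_equal(utility(2, 1, 0) > utility(1, 1, 0),
               utility_threshold(2, 1, 0) > utility_threshold(1, 1, 0))
})

test_that("Weibull bound collapses as specified", {
  expect_equal(bound_at(0, B0 = 2, k = 3, lam = 1000), 2)
  for (k in c(0.5, 1, 2, 5)) {
    expect_equal(bound_at(1000, B0 = 2, k = k, lam = 1000), 2 * exp(-1))
  }
  # k = 1 is simple exponential decay
  t <- c(0, 200, 700, 1500)
  expect_equal(bound_at(t, 1.5, k = 1, lam = 900), 1.5 * exp(-t / 900))
  # non-increasing in t when collapsing; constant otherwise
  b <- bound_at(seq(0, 5000, 100), 1, k = 2.2, lam = 1200)
  expect_true(all(diff(b) <= 0))
  expect_equal(bound_at(t, 1, collapsing = FALSE), rep(1, 4))
  expect_error(bound_at(-1, 1), "negative")
})

test_that("aDDM drift increments follow the attentional weighting", {
  expect_equal(addm_increment_mean("left", 5, 3, d = 0.1, theta = 0.5),
               0.35)
  # theta = 1 removes the attentional asymmetry
  expect_equal(addm_increment_mean("left", 4, -2, 0.2, 1),
               addm_increment_mean("right", 4, -2, 0.2, 1))
  # equal ratings: equal magnitude, opposite sign
  expect_equal(addm_increment_mean("left", 3, 3, 0.1, 0.4),
               -addm_increment_mean("right", 3, 3, 0.1, 0.4))
})

test_that("parameter containers validate and serialize to JSON", {
  pr <- prior_spec(0, 6)
  p <- puc_params(2, 0.5, pr, 3, 2, 2000, 0.05, 150)
  q <- params_from_json(params_to_json(p, fixed = c("prior")))
  expect_equal(attr(q, "fixed"), "prior")
  attr(q, "fixed") <- NULL
  expect_equal(q, p)

  d <- ddm_params(0.3, 0.05, 0.6, k = 2, lam = 3000, collapsing = TRUE,
                  g = 0.02, tau = 100)
  expect_equal(d$model, "acbddm")
  d2 <- params_from_json(params_to_json(d))
  attr(d2, "fixed") <- NULL
  expect_equal(d2, d)

  expect_error(puc_params(-1, 0, pr, 1, 1, 1, 0, 0))
  expect_error(ddm_params(0.3, 0.05, 1.5))
  # zero_A flag forces A = 0
  expect_equal(puc_params(1, 5, pr, 1, 1, 1, 0, 0, zero_A = TRUE)$A, 0)
})
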