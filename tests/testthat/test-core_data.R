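test_that("trial and dataset invariants are enforced", {
  fx <- data.frame(side = c("left", "right"), duration = c(300, 200))
  tr <- new_trial(1, 5, -3, fx, choice = "left")
  expect_equal(tr$total_fixation_time, 500)

  expect_error(new_trial(2, 0, 0, fx[0, ], choice = "left"), "non-empty")
  expect_error(new_trial(3, 0, 0,
                         data.frame(side = "left", duration = -50),
                         choice = "left"),
               "non-positive fixation duration")
  expect_error(new_trial(4, 0, 0, fx, choice = "left",
                         total_fixation_time = 510),
               "more than 1 ms")
  # 1 ms rounding tolerance is allowed
  expect_silent(new_trial(5, 0, 0, fx, choice = "left",
                          total_fixation_time = 500.8))

  expect_error(subject_dataset("s", list()), "at least 1 trial")
  expect_error(subject_dataset("s", list(tr, tr)), "duplicate trial_id")
  big <- new_trial(9, 11, 0, fx, choice = "left")
  expect_error(subject_dataset("s", list(big)), "outside declared scale")
})

test_that("read/write round-trips datasets exactly", {
  ds1 <- make_test_dataset("subjA", n_trials = 5, seed = 3)
  ds2 <- make_test_dataset("subjB", n_trials = 7, seed = 4)
  tp <- tempfile(fileext = ".csv")
  fp <- tempfile(fileext = ".csv")
  write_subject_data(list(ds1, ds2), tp, fp)
  back <- read_subject_data(tp, fp)
  expect_length(back, 2)
  expect_equal(back[[1]], ds1)
  expect_equal(back[[2]], ds2)
  # both subject ids present in the files
  expect_true(all(c("subjA", "subjB") %in%
                    utils::read.csv(tp)$subject_id))
})

test_that("reader reports schema and integrity problems", {
  ds <- make_test_dataset()
  tp <- tempfile(fileext = ".csv")
  fp <- tempfile(fileext = ".csv")
  write_subject_data(ds, tp, fp)

  tr <- utils::read.csv(tp)
  tr$choice <- NULL
  tp2 <- tempfile(fileext = ".csv")
  utils::write.csv(tr, tp2, row.names = FALSE)
  expect_error(read_subject_data(tp2, fp), "choice")

  fx <- utils::read.csv(fp)
  fx$trial_id[1] <- 999L
  fp2 <- tempfile(fileext = ".csv")
  utils::write.csv(fx, fp2, row.names = FALSE)
  expect_error(read_subject_data(tp, fp2), "unknown subject/trial")

  fx <- utils::read.csv(fp)
  fx$duration_ms[2] <- -50
  fp3 <- tempfile(fileext = ".csv")
  utils::write.csv(fx, fp3, row.names = FALSE)
  expect_error(read_subject_data(tp, fp3), "row 2")
})

test_that("quantization uses cumulative rounding without drift", {
  q1 <- quantize_fixations(data.frame(side = c("left", "right"),
                                      duration = c(300, 200)), 100)
  expect_equal(q1$sides, c("left", "left", "left", "right", "right"))

  # boundary at round(250/100) = 3 under half-up rounding
  q2 <- quantize_fixations(data.frame(side = c("left", "right"),
                                      duration = c(250, 250)), 100)
  expect_equal(q2$sides, c("left", "left", "left", "right", "right"))

  # sub-step trials promote to a single step
  q3 <- quantize_fixations(data.frame(side = "left", duration = 40), 100)
  expect_equal(q3$sides, "left")

  expect_error(quantize_fixations(data.frame(side = character(0),
                                             duration = numeric(0)), 100),
               "empty")

  # total time conserved within one step for random series
  set.seed(11)
  for (i in 1:50) {
    n <- sample(1:12, 1)
    fx <- data.frame(side = rep(c("left", "right"), length.out = n),
                     duration = stats::runif(n, 30, 900))
    q <- quantize_fixations(fx, 100)
    expect_lte(abs(length(q$sides) * 100 - sum(fx$duration)), 100)
  }
})

test_that("empirical prior pools ratings and is order-invariant", {
  fx <- data.frame(side = "left", duration = 300)
  mk <- function(id, rl, rr) new_trial(id, rl, rr, fx, choice = "left")
  ds <- subject_dataset("s", list(mk(1, 1, 2), mk(2, 3, 4)))
  pr <- empirical_prior(ds)
  expect_equal(pr$mu_p, 2.5)
  expect_equal(pr$sigma_p, sd(1:4))  # 1.2909944...

  ds_rev <- subject_dataset("s", list(mk(2, 3, 4), mk(1, 1, 2)))
  expect_equal(empirical_prior(ds_rev)[c("mu_p", "sigma_p")],
               pr[c("mu_p", "sigma_p")])

  ds_sym <- subject_dataset("s", list(mk(1, -2, 2)))
  expect_equal(empirical_prior(ds_sym)$mu_p, 0)

  ds_const <- subject_dataset("s", list(mk(1, 0, 0), mk(2, 0, 0)))
  expect_error(empirical_prior(ds_const), "identical")

  pop <- empirical_prior(ds, estimator = "population")
  expect_equal(pop$sigma_p, sd(1:4) * sqrt(3 / 4))
})
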