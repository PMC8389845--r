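#' Fitting configuration
#'
#' Controls the multi-start bounded maximum-likelihood optimization.
#' Parameters are optimized on transformed scales (log for sigma, d, B0,
#' k, lambda and tau + 10 ms; logit over the box for theta and g; identity
#' for A), with box constraints enforced by clamping plus a smooth
#' out-of-box penalty; the local optimizer is derivative-free
#' (Nelder-Mead), since the likelihood is piecewise constant in tau.
#'
#' @param n_starts Number of Latin-hypercube start points (default 20).
#' @param maxit Maximum Nelder-Mead iterations per start (default 400).
#' @param reltol Optimizer relative tolerance (default 1e-6).
#' @param n_grid Propagation grid override used during optimization
#'   (`NULL` = model default: 601 for the DDMs, 201 per axis for PUC).
#' @param boxes Optional named list of c(lo, hi) parameter boxes
#'   overriding [default_param_boxes()].
#' @param seed RNG seed for the start points (default 1).
#' @return A `fit_config` object.
#' @export
fit_config <- function(n_starts = 20, maxit = 400, reltol = 1e-6,
                       n_grid = NULL, boxes = NULL, seed = 1) {
  stopifnot(n_starts >= 1, maxit >= 1)
  structure(list(n_starts = n_starts, maxit = maxit, reltol = reltol,
                 n_grid = n_grid, boxes = boxes, seed = seed),
            class = "fit_config")
}

#' Default parameter boxes for fitting
#'
#' Bounds on each free parameter during optimization (rating units, ms).
#'
#' @return Named list of c(lo, hi).
#' @export
default_param_boxes <- function() {
  list(sigma = c(0.01, 20), A = c(-10, 10), B0 = c(0.1, 100),
       k = c(0.2, 10), lam = c(100, 20000), g = c(1e-4, 0.5),
       tau = c(0, 1000), d = c(1e-4, 5), theta = c(1e-4, 1 - 1e-4),
       prior_mean = c(-10, 10), prior_sigma = c(0.5, 20))
}

# profile likelihood over (g, tau) given cached absorption records: the
# records do not depend on either, so this inner maximization is cheap
# (tau moves the decision bin; g mixes in the guess component)
profile_g_tau <- function(records, choices, t_obs, guess, step_ms, boxes) {
  n <- length(records)
  p_guess <- 0.5 * guess_pmf_at(guess, t_obs)
  tau_box <- boxes$tau
  tau_grid <- seq(tau_box[1], tau_box[2], by = step_ms / 4)
  g_box <- boxes$g
  best <- list(ll = -Inf, g = NA_real_, tau = NA_real_)
  p_model_at <- function(tau) {
    vapply(seq_len(n), function(i) {
      b <- ceiling((t_obs[i] - tau) / step_ms) - 1  # see trial_loglik
      pv <- if (choices[i] == "left") records[[i]]$p_left
            else records[[i]]$p_right
      if (b >= 0 && b < length(pv)) pv[b + 1L] else 0
    }, numeric(1))
  }
  for (tau in tau_grid) {
    pm <- p_model_at(tau)
    nll_g <- function(g) {
      -sum(pmax(log((1 - g) * pm + g * p_guess), LOG_FLOOR))
    }
    o <- stats::optimize(nll_g, lower = g_box[1], upper = g_box[2])
    if (-o$objective > best$ll) {
      best <- list(ll = -o$objective, g = o$minimum, tau = tau)
    }
  }
  best
}

# free-parameter names per model/variant; PUC prior fixed empirically by
# default (7 free), acbDDM 7, aDDM 5
free_param_names <- function(model, free_prior_sigma = FALSE,
                             free_prior_mean = FALSE, zero_A = FALSE) {
  if (model == "puc") {
    nm <- c("sigma", "A", "B0", "k", "lam", "g", "tau")
    if (zero_A) nm <- setdiff(nm, "A")
    if (free_prior_sigma) nm <- c(nm, "prior_sigma")
    if (free_prior_mean) nm <- c(nm, "prior_mean")
    nm
  } else if (model == "acbddm") {
    c("sigma", "d", "theta", "k", "lam", "g", "tau")
  } else {
    c("sigma", "d", "theta", "g", "tau")
  }
}

param_transform <- function(name) {
  switch(name,
         sigma = , d = , B0 = , k = , lam = , prior_sigma = "log",
         tau = "log_shift",
         theta = , g = "logit",
         "identity")
}

TAU_SHIFT <- 10  # ms offset so tau = 0 is reachable on the log scale

to_z <- function(x, name, box) {
  switch(param_transform(name),
         log = log(x),
         log_shift = log(x + TAU_SHIFT),
         logit = stats::qlogis((x - box[1]) / (box[2] - box[1])),
         x)
}

from_z <- function(z, name, box) {
  x <- switch(param_transform(name),
              log = exp(z),
              log_shift = exp(z) - TAU_SHIFT,
              logit = box[1] + (box[2] - box[1]) * stats::plogis(z),
              z)
  min(max(x, box[1]), box[2])
}

# out-of-box penalty on the natural scale (clamping alone flattens the
# objective at the box edge)
box_penalty <- function(z, name, box) {
  x <- switch(param_transform(name),
              log = exp(z),
              log_shift = exp(z) - TAU_SHIFT,
              logit = return(0),  # logit respects the box by construction
              z)
  scale <- box[2] - box[1]
  if (x < box[1]) ((box[1] - x) / scale)^2 * 100
  else if (x > box[2]) ((x - box[2]) / scale)^2 * 100
  else 0
}

build_params <- function(model, values, base_prior,
                         free_prior_sigma = FALSE, free_prior_mean = FALSE,
                         zero_A = FALSE) {
  if (model == "puc") {
    prior <- prior_spec(
      if (free_prior_mean) values[["prior_mean"]] else base_prior$mu_p,
      if (free_prior_sigma) values[["prior_sigma"]] else base_prior$sigma_p)
    puc_params(values[["sigma"]], if (zero_A) 0 else values[["A"]], prior,
               values[["B0"]], values[["k"]], values[["lam"]],
               values[["g"]], values[["tau"]],
               free_prior_sigma = free_prior_sigma,
               free_prior_mean = free_prior_mean, zero_A = zero_A)
  } else {
    ddm_params(values[["sigma"]], values[["d"]], values[["theta"]],
               k = if ("k" %in% names(values)) values[["k"]] else 1,
               lam = if ("lam" %in% names(values)) values[["lam"]] else 1e9,
               collapsing = model == "acbddm",
               g = values[["g"]], tau = values[["tau"]])
  }
}

#' Small-sample information criteria
#'
#' AICc = -2 logL + 2k + 2k(k+1)/(n-k-1); BIC = -2 logL + k log n, with
#' k free parameters and n trials (the independent units of the
#' likelihood).
#'
#' @param loglik Maximized log-likelihood.
#' @param n_free Number of free parameters k.
#' @param n_trials Number of trials n (must exceed k + 1 for AICc).
#' @return Named numeric vector `c(aicc =, bic =)`.
#' @export
information_criteria <- function(loglik, n_free, n_trials) {
  if (n_trials <= n_free + 1) {
    stop("AICc undefined: n_trials must exceed n_free + 1")
  }
  aicc <- -2 * loglik + 2 * n_free +
    2 * n_free * (n_free + 1) / (n_trials - n_free - 1)
  bic <- -2 * loglik + n_free * log(n_trials)
  c(aicc = aicc, bic = bic)
}

#' Maximum-likelihood fit of one model to one subject
#'
#' Maximizes the joint choice/total-fixation-time log-likelihood over the
#' model's free parameters (PUC: sigma, A, B0, k, lambda, g, tau with the
#' prior fixed to the subject's empirical rating moments; acbDDM: sigma, d,
#' theta, k, lambda, g, tau; aDDM: sigma, d, theta, g, tau with a fixed
#' unit bound) using Nelder-Mead from Latin-hypercube start points on the
#' transformed scale. The guessing rate and non-decision time are profiled
#' out at every outer evaluation: the propagated absorption records do not
#' depend on (g, tau), so their conditional maximum is found cheaply on a
#' fine tau grid with 1-D optimization over g. The subject's guess-time
#' Weibull is fitted once, before optimization.
#'
#' @param dataset A [subject_dataset()].
#' @param model "puc", "addm" or "acbddm".
#' @param config A [fit_config()].
#' @param step_ms Discretization step (default 100).
#' @param free_prior_sigma,free_prior_mean,zero_A PUC variant flags.
#' @return A `fit_result`: `subject_id`, `model`, `params_hat`, `loglik`,
#'   `n_free_params`, `n_trials`, `aicc`, `bic`, `starts` (per-start
#'   diagnostics data frame).
#' @export
fit_subject <- function(dataset, model = c("puc", "addm", "acbddm"),
                        config = fit_config(), step_ms = 100,
                        free_prior_sigma = FALSE, free_prior_mean = FALSE,
                        zero_A = FALSE) {
  model <- match.arg(model)
  stopifnot(inherits(dataset, "subject_dataset"))
  boxes <- utils::modifyList(default_param_boxes(),
                             if (is.null(config$boxes)) list()
                             else config$boxes)
  nm <- free_param_names(model, free_prior_sigma, free_prior_mean, zero_A)
  # (g, tau) are profiled out: the absorption records do not depend on
  # them, so the outer search runs over the propagation parameters only
  nm_shape <- setdiff(nm, c("g", "tau"))
  base_prior <- if (model == "puc") empirical_prior(dataset) else NULL

  tft <- vapply(dataset$trials, function(t) t$total_fixation_time,
                numeric(1))
  choices <- vapply(dataset$trials, function(t) t$choice, character(1))
  guess <- fit_guess_time_pmf(tft, step_ms = step_ms)
  schedules <- lapply(dataset$trials,
                      function(t) quantize_fixations(t$fixations, step_ms))

  shape_to_params <- function(z, g = 0.01, tau = 0) {
    vals <- stats::setNames(
      lapply(seq_along(nm_shape),
             function(i) from_z(z[i], nm_shape[i], boxes[[nm_shape[i]]])),
      nm_shape)
    vals$g <- g
    vals$tau <- tau
    build_params(model, vals, base_prior, free_prior_sigma,
                 free_prior_mean, zero_A)
  }

  last_gt <- NULL  # (g, tau) at the most recent evaluation
  negll <- function(z) {
    pen <- sum(vapply(seq_along(nm_shape),
                      function(i) box_penalty(z[i], nm_shape[i],
                                              boxes[[nm_shape[i]]]),
                      numeric(1)))
    p <- shape_to_params(z)
    records <- tryCatch(
      lapply(seq_along(schedules), function(i) {
        tr <- dataset$trials[[i]]
        propagate_trial(schedules[[i]], p, tr$rating_left,
                        tr$rating_right, n_grid = config$n_grid)
      }),
      error = function(e) NULL)
    if (is.null(records)) return(1e10)
    prof <- profile_g_tau(records, choices, tft, guess, step_ms, boxes)
    last_gt <<- c(prof$g, prof$tau)
    -prof$ll + pen
  }

  set.seed(config$seed)
  u <- lhs::randomLHS(config$n_starts, max(length(nm_shape), 2L))
  starts <- lapply(seq_len(config$n_starts), function(s) {
    vapply(seq_along(nm_shape), function(i) {
      b <- boxes[[nm_shape[i]]]
      # spread starts over the middle of the box, log-uniform for
      # log-scale parameters
      if (param_transform(nm_shape[i]) %in% c("log", "log_shift")) {
        zl <- to_z(b[1], nm_shape[i], b); zh <- to_z(b[2], nm_shape[i], b)
        zl + (0.1 + 0.8 * u[s, i]) * (zh - zl)
      } else {
        to_z(b[1] + (0.1 + 0.8 * u[s, i]) * (b[2] - b[1]), nm_shape[i], b)
      }
    }, numeric(1))
  })

  diag_rows <- list()
  best <- NULL
  best_gt <- NULL
  for (s in seq_along(starts)) {
    z0 <- starts[[s]]
    f0 <- negll(z0)
    opt <- stats::optim(z0, negll, method = "Nelder-Mead",
                        control = list(maxit = config$maxit,
                                       reltol = config$reltol))
    diag_rows[[s]] <- data.frame(start = s, value_init = -f0,
                                 value_final = -opt$value,
                                 convergence = opt$convergence)
    if (is.null(best) || opt$value < best$value) {
      best <- opt
      # re-evaluate at the optimum to recover its profiled (g, tau)
      negll(opt$par)
      best_gt <- last_gt
    }
  }
  if (is.null(best) || !is.finite(best$value) || best$value >= 1e10) {
    stop("all optimization starts failed; diagnostics: ",
         paste(utils::capture.output(do.call(rbind, diag_rows)),
               collapse = "\n"))
  }
  params_hat <- shape_to_params(best$par, g = best_gt[1], tau = best_gt[2])
  loglik <- -best$value
  n_trials <- length(dataset$trials)
  ic <- information_criteria(loglik, length(nm), n_trials)
  structure(list(subject_id = dataset$subject_id, model = model,
                 params_hat = params_hat, loglik = loglik,
                 n_free_params = length(nm), n_trials = n_trials,
                 aicc = ic[["aicc"]], bic = ic[["bic"]],
                 starts = do.call(rbind, diag_rows)),
            class = "fit_result")
}

#' @export
print.fit_result <- function(x, ...) {
  cat("<fit_result>", x$model, "| subject", x$subject_id,
      "| logL =", round(x$loglik, 2), "| k =", x$n_free_params,
      "| n =", x$n_trials, "| AICc =", round(x$aicc, 2),
      "| BIC =", round(x$bic, 2), "\n")
  invisible(x)
}

#' Pairwise model comparison with subject-level bootstrap CIs
#'
#' Sums per-subject differences (first model minus second; lower is better
#' for the first) in negative log-likelihood, AICc, and BIC, and computes
#' percentile 95% confidence intervals by resampling subjects with
#' replacement.
#'
#' @param fits Named list: one entry per model, each a list of
#'   `fit_result`s covering the same subjects.
#' @param pair Character vector of two model names in `fits`.
#' @param n_boot Bootstrap replicates (default 10000).
#' @param seed RNG seed for the bootstrap.
#' @return A `comparison_result`: per-metric point estimates and CIs.
#' @export
compare_models <- function(fits, pair, n_boot = 10000, seed = 1) {
  stopifnot(length(pair) == 2L, all(pair %in% names(fits)))
  f1 <- fits[[pair[1]]]; f2 <- fits[[pair[2]]]
  id1 <- vapply(f1, function(f) f$subject_id, character(1))
  id2 <- vapply(f2, function(f) f$subject_id, character(1))
  miss <- c(setdiff(id1, id2), setdiff(id2, id1))
  if (length(miss)) {
    stop("subject mismatch between models: ", paste(miss, collapse = ", "))
  }
  f2 <- f2[match(id1, id2)]
  d_negll <- vapply(seq_along(f1),
                    function(i) -f1[[i]]$loglik + f2[[i]]$loglik,
                    numeric(1))
  d_aicc <- vapply(seq_along(f1),
                   function(i) f1[[i]]$aicc - f2[[i]]$aicc, numeric(1))
  d_bic <- vapply(seq_along(f1),
                  function(i) f1[[i]]$bic - f2[[i]]$bic, numeric(1))
  n <- length(f1)
  set.seed(seed)
  idx <- matrix(sample.int(n, n * n_boot, replace = TRUE), nrow = n_boot)
  boot_sum <- function(d) {
    sums <- rowSums(matrix(d[idx], nrow = n_boot))
    stats::quantile(sums, c(0.025, 0.975), names = FALSE)
  }
  metrics <- list(negll = d_negll, aicc = d_aicc, bic = d_bic)
  out <- lapply(metrics, function(d) {
    ci <- boot_sum(d)
    list(estimate = sum(d), ci_lower = ci[1], ci_upper = ci[2])
  })
  structure(list(pair = pair, n_subjects = n, n_boot = n_boot,
                 negll = out$negll, aicc = out$aicc, bic = out$bic),
            class = "comparison_result")
}

#' @export
print.comparison_result <- function(x, ...) {
  cat("<comparison_result>", x$pair[1], "-", x$pair[2],
      "(summed over", x$n_subjects, "subjects; 95% bootstrap CI)\n")
  for (m in c("negll", "aicc", "bic")) {
    v <- x[[m]]
    cat(sprintf("  %-6s %9.1f  (%.1f, %.1f)\n",
                toupper(m), v$estimate, v$ci_lower, v$ci_upper))
  }
  invisible(x)
}

#' Parameter-recovery harness
#'
#' Fits a model to synthetic datasets generated from known parameters and
#' tabulates true vs recovered values, per-parameter Pearson correlation
#' and bias across subjects, and cross-correlations of the recovery errors
#' (flagging potential soft trade-offs between parameters).
#'
#' @param model "puc", "addm" or "acbddm".
#' @param manifest True-parameter manifest from
#'   [generate_synthetic_experiment()].
#' @param datasets The matching synthetic datasets.
#' @param config A [fit_config()].
#' @param step_ms Discretization step (default 100).
#' @return A `recovery_report`: `table` (subject x parameter rows of
#'   true/recovered), `correlations`, `bias`, `tradeoff_flags`, `fits`.
#' @export
recover_parameters <- function(model, manifest, datasets,
                               config = fit_config(), step_ms = 100) {
  ids <- vapply(datasets, function(d) d$subject_id, character(1))
  if (!all(ids %in% names(manifest$subjects))) {
    stop("manifest does not cover all datasets")
  }
  nm <- free_param_names(model)
  fits <- lapply(datasets, fit_subject, model = model, config = config,
                 step_ms = step_ms)
  get_val <- function(p, name) {
    if (name == "prior_sigma") p$prior$sigma_p
    else if (name == "prior_mean") p$prior$mu_p
    else p[[name]]
  }
  rows <- list()
  for (i in seq_along(datasets)) {
    truth <- manifest$subjects[[ids[i]]]
    est <- fits[[i]]$params_hat
    for (p in nm) {
      rows[[length(rows) + 1L]] <- data.frame(
        subject_id = ids[i], parameter = p,
        true = get_val(truth, p), recovered = get_val(est, p),
        stringsAsFactors = FALSE)
    }
  }
  tab <- do.call(rbind, rows)
  cors <- vapply(nm, function(p) {
    d <- tab[tab$parameter == p, ]
    if (stats::sd(d$true) == 0 || stats::sd(d$recovered) == 0) NA_real_
    else stats::cor(d$true, d$recovered)
  }, numeric(1))
  bias <- vapply(nm, function(p) {
    d <- tab[tab$parameter == p, ]
    mean(d$recovered - d$true)
  }, numeric(1))
  err <- sapply(nm, function(p) {
    d <- tab[tab$parameter == p, ]
    d$recovered - d$true
  })
  flags <- character(0)
  if (is.matrix(err) && nrow(err) > 3) {
    ec <- suppressWarnings(stats::cor(err))
    for (i in seq_len(ncol(ec) - 1)) {
      for (j in (i + 1):ncol(ec)) {
        if (is.finite(ec[i, j]) && abs(ec[i, j]) > 0.8) {
          flags <- c(flags, paste0(nm[i], "~", nm[j], " (r = ",
                                   round(ec[i, j], 2), ")"))
        }
      }
    }
  }
  structure(list(model = model, table = tab, correlations = cors,
                 bias = bias, tradeoff_flags = flags, fits = fits),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cat("<recovery_report>", x$model, "|",
      length(unique(x$table$subject_id)), "subjects\n")
  cat("  true-vs-recovered Pearson r:\n")
  for (p in names(x$correlations)) {
    cat(sprintf("    %-12s %6.3f  (bias %+.3g)\n", p,
                x$correlations[[p]], x$bias[[p]]))
  }
  if (length(x$tradeoff_flags)) {
    cat("  possible trade-offs:", paste(x$tradeoff_flags,
                                        collapse = "; "), "\n")
  }
  invisible(x)
}
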