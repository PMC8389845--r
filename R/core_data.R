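#' Construct a single choice trial
#'
#' A trial holds the two item ratings, the ordered fixation series, the
#' observed choice, and the observed total fixation time. Total fixation time
#' (the summed duration of all item fixations) is modelled in place of
#' reaction time, so the fixation series must already exclude saccade and
#' transition gaps.
#'
#' @param trial_id Integer trial identifier, unique within a subject.
#' @param rating_left,rating_right Item ratings (default scale -10..10).
#'   Stored as reals so synthetic data may use continuous values.
#' @param fixations Data frame with columns `side` ("left"/"right") and
#'   `duration` (ms, strictly positive), in presentation order.
#' @param choice "left" or "right".
#' @param total_fixation_time Total fixation time in ms. Must equal the sum
#'   of fixation durations within 1 ms. Defaults to that sum.
#' @return An object of class `puc_trial`.
#' @export
new_trial <- function(trial_id, rating_left, rating_right, fixations,
                      choice = c("left", "right"),
                      total_fixation_time = NULL) {
  choice <- match.arg(choice)
  fixations <- as.data.frame(fixations)
  if (nrow(fixations) == 0L) {
    stop("trial ", trial_id, ": fixation series must be non-empty")
  }
  if (!all(c("side", "duration") %in% names(fixations))) {
    stop("fixations need columns 'side' and 'duration'")
  }
  fixations$side <- as.character(fixations$side)
  bad_side <- which(!fixations$side %in% c("left", "right"))
  if (length(bad_side)) {
    stop("trial ", trial_id, ": invalid fixation side at row ", bad_side[1L])
  }
  bad_dur <- which(!is.finite(fixations$duration) | fixations$duration <= 0)
  if (length(bad_dur)) {
    stop("trial ", trial_id, ": non-positive fixation duration at row ",
         bad_dur[1L])
  }
  if (is.null(total_fixation_time)) {
    total_fixation_time <- sum(fixations$duration)
  }
  if (abs(total_fixation_time - sum(fixations$duration)) > 1) {
    stop("trial ", trial_id, ": total_fixation_time (", total_fixation_time,
         ") differs from summed fixation durations (",
         sum(fixations$duration), ") by more than 1 ms")
  }
  structure(
    list(
      trial_id = as.integer(trial_id),
      rating_left = as.numeric(rating_left),
      rating_right = as.numeric(rating_right),
      fixations = fixations[, c("side", "duration")],
      choice = choice,
      total_fixation_time = as.numeric(total_fixation_time)
    ),
    class = "puc_trial"
  )
}

#' Construct a subject dataset
#'
#' @param subject_id Subject identifier (coerced to character).
#' @param trials List of [new_trial()] objects; at least one, unique ids.
#' @param rating_scale Length-2 numeric, the declared rating bounds.
#' @return An object of class `subject_dataset`.
#' @export
subject_dataset <- function(subject_id, trials, rating_scale = c(-10, 10)) {
  if (length(trials) < 1L) stop("a subject needs at least 1 trial")
  stopifnot(all(vapply(trials, inherits, logical(1), "puc_trial")))
  ids <- vapply(trials, function(t) t$trial_id, integer(1))
  if (anyDuplicated(ids)) {
    stop("duplicate trial_id for subject ", subject_id, ": ",
         ids[duplicated(ids)][1L])
  }
  rating_scale <- as.numeric(rating_scale)
  stopifnot(length(rating_scale) == 2L, rating_scale[1] < rating_scale[2])
  r <- unlist(lapply(trials, function(t) c(t$rating_left, t$rating_right)))
  if (any(r < rating_scale[1] - 1e-9 | r > rating_scale[2] + 1e-9)) {
    stop("subject ", subject_id, ": ratings outside declared scale [",
         rating_scale[1], ", ", rating_scale[2], "]")
  }
  structure(
    list(subject_id = as.character(subject_id), trials = trials,
         rating_scale = rating_scale),
    class = "subject_dataset"
  )
}

#' @export
print.subject_dataset <- function(x, ...) {
  cat("<subject_dataset> id:", x$subject_id,
      "| trials:", length(x$trials),
      "| rating scale: [", x$rating_scale[1], ",", x$rating_scale[2], "]\n")
  invisible(x)
}

#' Read subject datasets from delimited trial and fixation files
#'
#' The trials file has columns `subject_id`, `trial_id`, `rating_left`,
#' `rating_right`, `choice`, `total_fixation_time_ms`; the fixations file
#' has `subject_id`, `trial_id`, `fixation_index` (0-based, contiguous),
#' `side`, `duration_ms`. Comma-delimited by default; tab accepted. All
#' times in milliseconds.
#'
#' @param trials_path,fixations_path Paths to the two files.
#' @param sep Field separator, `","` (default) or `"\t"`.
#' @param rating_scale Declared rating bounds, default `c(-10, 10)`.
#' @return A list of [subject_dataset()] objects, one per distinct subject,
#'   in order of first appearance.
#' @export
read_subject_data <- function(trials_path, fixations_path, sep = ",",
                              rating_scale = c(-10, 10)) {
  tr <- utils::read.table(trials_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  fx <- utils::read.table(fixations_path, header = TRUE, sep = sep,
                          stringsAsFactors = FALSE)
  need_tr <- c("subject_id", "trial_id", "rating_left", "rating_right",
               "choice", "total_fixation_time_ms")
  need_fx <- c("subject_id", "trial_id", "fixation_index", "side",
               "duration_ms")
  miss <- setdiff(need_tr, names(tr))
  if (length(miss)) stop("trials file missing column(s): ",
                         paste(miss, collapse = ", "))
  miss <- setdiff(need_fx, names(fx))
  if (length(miss)) stop("fixations file missing column(s): ",
                         paste(miss, collapse = ", "))

  bad <- which(!is.finite(fx$duration_ms) | fx$duration_ms <= 0)
  if (length(bad)) {
    stop("fixations file: non-positive duration_ms at row ", bad[1L])
  }
  tr_key <- paste(tr$subject_id, tr$trial_id, sep = "\r")
  fx_key <- paste(fx$subject_id, fx$trial_id, sep = "\r")
  unknown <- which(!fx_key %in% tr_key)
  if (length(unknown)) {
    stop("fixations file row ", unknown[1L],
         " references unknown subject/trial: ", fx$subject_id[unknown[1L]],
         "/", fx$trial_id[unknown[1L]])
  }

  fx_by_trial <- split(fx, fx_key)
  out <- list()
  for (sid in unique(tr$subject_id)) {
    rows <- tr[tr$subject_id == sid, , drop = FALSE]
    trials <- lapply(seq_len(nrow(rows)), function(i) {
      row <- rows[i, ]
      key <- paste(row$subject_id, row$trial_id, sep = "\r")
      f <- fx_by_trial[[key]]
      if (is.null(f)) {
        stop("subject ", sid, " trial ", row$trial_id, ": no fixations")
      }
      f <- f[order(f$fixation_index), , drop = FALSE]
      if (!identical(as.integer(f$fixation_index),
                     seq_len(nrow(f)) - 1L)) {
        stop("subject ", sid, " trial ", row$trial_id,
             ": fixation_index not 0-based contiguous")
      }
      new_trial(row$trial_id, row$rating_left, row$rating_right,
                data.frame(side = f$side, duration = f$duration_ms),
                choice = row$choice,
                total_fixation_time = row$total_fixation_time_ms)
    })
    out[[length(out) + 1L]] <- subject_dataset(sid, trials, rating_scale)
  }
  out
}

#' Write subject datasets to delimited trial and fixation files
#'
#' Inverse of [read_subject_data()]: reading the written files reproduces
#' the datasets (numeric values round-trip at 15 significant digits).
#'
#' @param datasets List of [subject_dataset()] objects.
#' @param trials_path,fixations_path Output paths.
#' @param sep Field separator, default `","`.
#' @export
write_subject_data <- function(datasets, trials_path, fixations_path,
                               sep = ",") {
  if (inherits(datasets, "subject_dataset")) datasets <- list(datasets)
  stopifnot(length(datasets) >= 1L)
  fmt <- function(x) formatC(x, digits = 15, format = "g")
  tr_rows <- list(); fx_rows <- list()
  for (ds in datasets) {
    for (t in ds$trials) {
      tr_rows[[length(tr_rows) + 1L]] <- data.frame(
        subject_id = ds$subject_id, trial_id = t$trial_id,
        rating_left = fmt(t$rating_left), rating_right = fmt(t$rating_right),
        choice = t$choice,
        total_fixation_time_ms = fmt(t$total_fixation_time),
        stringsAsFactors = FALSE)
      fx_rows[[length(fx_rows) + 1L]] <- data.frame(
        subject_id = ds$subject_id, trial_id = t$trial_id,
        fixation_index = seq_len(nrow(t$fixations)) - 1L,
        side = t$fixations$side,
        duration_ms = fmt(t$fixations$duration),
        stringsAsFactors = FALSE)
    }
  }
  utils::write.table(do.call(rbind, tr_rows), trials_path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  utils::write.table(do.call(rbind, fx_rows), fixations_path, sep = sep,
                     row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

round_half_up <- function(x) floor(x + 0.5)

#' Quantize a fixation series onto a fixed time grid
#'
#' Discretizes a fixation series into steps of `step_ms` (default 100 ms,
#' one value-measurement epoch per step) using cumulative rounding: the
#' boundary after fixation j is placed at `round(cumulative_duration_j /
#' step_ms)` steps, so the total step count is `round(total / step_ms)` and
#' rounding drift never accumulates across long series. Schedules that would
#' round to length 0 are promoted to a single step carrying the first
#' fixation's side.
#'
#' @param fixations Data frame with columns `side` and `duration` (ms), or a
#'   [new_trial()] object.
#' @param step_ms Step size in ms, default 100.
#' @return An object of class `step_schedule`: list with `step_ms` and
#'   `sides` (character vector, one side per step).
#' @export
quantize_fixations <- function(fixations, step_ms = 100) {
  if (inherits(fixations, "puc_trial")) fixations <- fixations$fixations
  stopifnot(step_ms > 0)
  if (nrow(fixations) == 0L) stop("empty fixation sequence")
  cum <- cumsum(fixations$duration)
  bounds <- round_half_up(cum / step_ms)       # step index after fixation j
  n_steps <- bounds[length(bounds)]
  if (n_steps < 1L) {
    return(step_schedule(step_ms, fixations$side[1L]))
  }
  sides <- character(n_steps)
  prev <- 0L
  for (j in seq_along(bounds)) {
    if (bounds[j] > prev) {
      sides[(prev + 1L):bounds[j]] <- fixations$side[j]
      prev <- bounds[j]
    }
  }
  step_schedule(step_ms, sides)
}

#' Construct a step schedule directly
#'
#' @param step_ms Step size in ms.
#' @param sides Character vector of "left"/"right", one per step.
#' @return A `step_schedule` object.
#' @export
step_schedule <- function(step_ms, sides) {
  sides <- as.character(sides)
  stopifnot(step_ms > 0, length(sides) >= 1L,
            all(sides %in% c("left", "right")))
  structure(list(step_ms = as.numeric(step_ms), sides = sides),
            class = "step_schedule")
}

#' @export
print.step_schedule <- function(x, ...) {
  cat("<step_schedule>", length(x$sides), "steps x", x$step_ms, "ms:",
      paste(ifelse(x$sides == "left", "L", "R"), collapse = ""), "\n")
  invisible(x)
}

#' Gaussian prior over item value
#'
#' @param mu_p Prior mean (rating units).
#' @param sigma_p Prior standard deviation, > 0.
#' @return A `prior_spec` object.
#' @export
prior_spec <- function(mu_p, sigma_p) {
  stopifnot(is.finite(mu_p), is.finite(sigma_p), sigma_p > 0)
  structure(list(mu_p = as.numeric(mu_p), sigma_p = as.numeric(sigma_p)),
            class = "prior_spec")
}

#' Empirical value prior from a subject's ratings
#'
#' Pools both item ratings from every trial and returns their mean and
#' standard deviation as the subject's Gaussian prior over value. The
#' estimator for `sigma_p` is configurable; the sample (n-1) estimator is
#' the default.
#'
#' @param dataset A [subject_dataset()].
#' @param estimator "sample" (n-1 denominator, default) or "population" (n).
#' @return A [prior_spec()].
#' @export
empirical_prior <- function(dataset, estimator = c("sample", "population")) {
  estimator <- match.arg(estimator)
  stopifnot(inherits(dataset, "subject_dataset"))
  r <- unlist(lapply(dataset$trials,
                     function(t) c(t$rating_left, t$rating_right)))
  if (length(unique(r)) < 2L) {
    stop("all ratings identical: empirical prior sd would be 0")
  }
  s <- stats::sd(r)
  if (estimator == "population") s <- s * sqrt((length(r) - 1) / length(r))
  prior_spec(mean(r), s)
}
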