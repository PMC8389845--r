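#' Flatten datasets or prediction ensembles into choice records
#'
#' Summary statistics aggregate over individual trials (not rating pairs).
#' A choice record has one row per trial or per simulated prediction, with
#' columns `choice`, `fix_left_ms`, `fix_right_ms`, `rating_left`,
#' `rating_right`, `last_side`, `total_ms`.
#'
#' @param x A [subject_dataset()], a list of them, or a prediction data
#'   frame from [predict_trial_ensemble()] / [simulate_trial()].
#' @return A choice-record data frame (rows with `choice == "none"` are
#'   dropped).
#' @export
choice_records <- function(x) {
  if (inherits(x, "subject_dataset")) x <- list(x)
  if (is.data.frame(x)) {
    stopifnot(all(c("choice", "fix_left_ms", "fix_right_ms",
                    "rating_left", "rating_right", "last_side",
                    "total_fixation_time") %in% names(x)))
    out <- data.frame(choice = x$choice,
                      fix_left_ms = x$fix_left_ms,
                      fix_right_ms = x$fix_right_ms,
                      rating_left = x$rating_left,
                      rating_right = x$rating_right,
                      last_side = x$last_side,
                      total_ms = x$total_fixation_time,
                      stringsAsFactors = FALSE)
    return(out[out$choice != "none", , drop = FALSE])
  }
  rows <- lapply(x, function(ds) {
    do.call(rbind, lapply(ds$trials, function(t) {
      left <- sum(t$fixations$duration[t$fixations$side == "left"])
      data.frame(choice = t$choice,
                 fix_left_ms = left,
                 fix_right_ms = sum(t$fixations$duration) - left,
                 rating_left = t$rating_left,
                 rating_right = t$rating_right,
                 last_side = t$fixations$side[nrow(t$fixations)],
                 total_ms = t$total_fixation_time,
                 stringsAsFactors = FALSE)
    }))
  })
  do.call(rbind, rows)
}

summary_curve <- function(bin_edges, values, counts, group = NA_character_) {
  structure(data.frame(bin_lo = utils::head(bin_edges, -1),
                       bin_hi = bin_edges[-1],
                       bin_center = (utils::head(bin_edges, -1) +
                                       bin_edges[-1]) / 2,
                       value = values, count = counts,
                       group = group, stringsAsFactors = FALSE),
            class = c("summary_curve", "data.frame"))
}

prop_by_bin <- function(z, success, bin_edges) {
  b <- cut(z, breaks = bin_edges, include.lowest = TRUE, right = FALSE)
  counts <- as.integer(table(b))
  hits <- tapply(success, b, sum)
  hits[is.na(hits)] <- 0
  values <- ifelse(counts > 0, as.numeric(hits) / counts, NA_real_)
  list(values = values, counts = counts)
}

#' Choice proportion vs total fixation-time advantage
#'
#' Proportion of left choices per bin of the signed fixation-time
#' advantage (left total fixation minus right, ms). Empty bins carry `NA`,
#' not zero.
#'
#' @param x Datasets or predictions (see [choice_records()]).
#' @param bin_edges Advantage bin edges in ms (default 200 ms bins over
#'   -2000..2000).
#' @return A `summary_curve` data frame.
#' @export
choice_vs_fixation_advantage <- function(x,
                                         bin_edges = seq(-2000, 2000, 200)) {
  rec <- choice_records(x)
  adv <- rec$fix_left_ms - rec$fix_right_ms
  pb <- prop_by_bin(adv, rec$choice == "left", bin_edges)
  summary_curve(bin_edges, pb$values, pb$counts)
}

#' Fixation-advantage curves conditioned on item rating
#'
#' One curve per rating group, where a trial's rating level is the mean of
#' the two items' ratings (how preferred the pair is overall). Supports
#' checking the model prediction that the fixation-modulation effect is
#' larger when both items are more highly valued: for the PUC model,
#' fixating an item whose value exceeds the prior mean pulls its posterior
#' mean up, so attention helps valuable items multiplicatively on top of
#' the additive uncertainty channel.
#'
#' @inheritParams choice_vs_fixation_advantage
#' @param rating_groups List of c(lo, hi) intervals partitioning the
#'   rating-level range (closed on the left, open on the right except the
#'   last).
#' @return List of `summary_curve`s, one per group (empty groups give
#'   all-`NA` curves).
#' @export
choice_vs_advantage_by_rating <- function(x,
                                          bin_edges = seq(-2000, 2000, 200),
                                          rating_groups = list(c(0, 5),
                                                               c(5, 10.5))) {
  rec <- choice_records(x)
  adv <- rec$fix_left_ms - rec$fix_right_ms
  lvl <- (rec$rating_left + rec$rating_right) / 2
  lapply(seq_along(rating_groups), function(gi) {
    gr <- rating_groups[[gi]]
    last <- gi == length(rating_groups)
    in_g <- lvl >= gr[1] & (if (last) lvl <= gr[2] else lvl < gr[2])
    pb <- prop_by_bin(adv[in_g], rec$choice[in_g] == "left", bin_edges)
    summary_curve(bin_edges, pb$values, pb$counts,
                  group = paste0("[", gr[1], ",", gr[2],
                                 if (last) "]" else ")"))
  })
}

#' Last-fixation effect on choice
#'
#' Proportion of left choices vs rating difference (left minus right),
#' split by the side fixated last (for predictions: the fixation
#' containing the decision time).
#'
#' @inheritParams choice_vs_fixation_advantage
#' @param rating_diff_bins Bin edges for the rating difference (default
#'   integer steps over -10.5..10.5).
#' @return Named list of two `summary_curve`s: `last_left`, `last_right`.
#' @export
last_fixation_effect <- function(x,
                                 rating_diff_bins = seq(-10.5, 10.5, 1)) {
  rec <- choice_records(x)
  rd <- rec$rating_left - rec$rating_right
  out <- lapply(c("left", "right"), function(s) {
    in_g <- rec$last_side == s
    pb <- prop_by_bin(rd[in_g], rec$choice[in_g] == "left",
                      rating_diff_bins)
    summary_curve(rating_diff_bins, pb$values, pb$counts,
                  group = paste0("last_", s))
  })
  stats::setNames(out, c("last_left", "last_right"))
}

#' Distribution of total fixation time
#'
#' Normalized histogram (density per ms) of total fixation times.
#'
#' @inheritParams choice_vs_fixation_advantage
#' @param bin_width_ms Histogram bin width (default 100 ms).
#' @return A `summary_curve` with `value` the density per bin.
#' @export
fixation_time_distribution <- function(x, bin_width_ms = 100) {
  stopifnot(bin_width_ms > 0)
  rec <- choice_records(x)
  t <- rec$total_ms
  edges <- seq(0, (floor(max(t) / bin_width_ms) + 1) * bin_width_ms,
               bin_width_ms)
  b <- cut(t, breaks = edges, include.lowest = TRUE, right = FALSE)
  counts <- as.integer(table(b))
  dens <- counts / (sum(counts) * bin_width_ms)
  summary_curve(edges, dens, counts)
}

#' Write a summary curve (or list of them) as delimited text
#'
#' Columns: bin_lo, bin_hi, value, count, group.
#'
#' @param curves A `summary_curve` or list of them.
#' @param path Output path.
#' @param sep Field separator (default tab).
#' @export
write_summary_curves <- function(curves, path, sep = "\t") {
  if (inherits(curves, "summary_curve")) curves <- list(curves)
  tab <- do.call(rbind, lapply(curves, function(cv) {
    as.data.frame(cv)[, c("bin_lo", "bin_hi", "value", "count", "group")]
  }))
  utils::write.table(tab, path, sep = sep, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}
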