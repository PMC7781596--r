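#' Behavioral performance summary
#'
#' Test-phase accuracy overall, per goal location, and split by
#' route congruence (test route equal to vs different from the sample
#' outbound route), each with a percentile-bootstrap 95% CI over trials.
#' Empty splits are reported as missing rather than zero.
#'
#' @param trials an `fg_trials` table.
#' @param n_boot bootstrap replicates.
#' @param seed RNG seed for the bootstrap.
#' @return data.frame `(split_label, n, accuracy, ci_low, ci_high)`.
#' @export
performance_summary <- function(trials, n_boot = 2000, seed = 1) {
  splits <- c(list(overall = rep(TRUE, nrow(trials))),
              lapply(1:3, function(g) trials$goal == g),
              list(congruent = trials$test_route == trials$sample_route,
                   incongruent = trials$test_route != trials$sample_route))
  names(splits)[2:4] <- paste0("goal_", 1:3)
  out <- lapply(names(splits), function(nm) {
    f <- trials$correct[splits[[nm]]]
    if (!length(f))
      return(data.frame(split_label = nm, n = 0L, accuracy = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    ci <- bootstrap_accuracy_ci(f, n_boot = n_boot, seed = seed)
    data.frame(split_label = nm, n = length(f), accuracy = mean(f),
               ci_low = ci[1], ci_high = ci[2])
  })
  do.call(rbind, out)
}

#' Vicarious trial-and-error (VTE) screen
#'
#' Head position is the midpoint of the two LEDs. Speed is displacement over
#' sliding windows of `speed_window` seconds stepped one tracking sample at a
#' time. A trial is flagged as a candidate VTE event when at least one
#' window's speed falls below `speed_thresh` within the `event_window`
#' centered on outer-ring entry (`t_choice_entry`). Trials whose event
#' window is not covered by tracking are returned as `NA` (unevaluable).
#'
#' @param tracking tracking data.frame (see [session()]).
#' @param trials an `fg_trials` table.
#' @param speed_window speed-window length, seconds (default 0.330).
#' @param speed_thresh threshold, cm/s (default 5).
#' @param event_window evaluation window centered on choice-point entry,
#'   seconds (default 0.800).
#' @return logical vector, one element per trial (`NA` = unevaluable).
#' @export
detect_vte <- function(tracking, trials, speed_window = 0.330,
                       speed_thresh = 5, event_window = 0.800) {
  tx <- (tracking$x1_cm + tracking$x2_cm) / 2
  ty <- (tracking$y1_cm + tracking$y2_cm) / 2
  tt <- tracking$t_s
  dt <- stats::median(diff(tt))
  vapply(seq_len(nrow(trials)), function(i) {
    t0 <- trials$t_choice_entry[i] - event_window / 2
    t1 <- trials$t_choice_entry[i] + event_window / 2
    if (t0 < tt[1] - dt / 2 || t1 > tt[length(tt)] + dt / 2) return(NA)
    starts <- tt[tt >= t0 - 1e-9 & tt + speed_window <= t1 + 1e-9]
    if (!length(starts)) return(NA)
    x0 <- approx(tt, tx, starts, rule = 2)$y
    y0 <- approx(tt, ty, starts, rule = 2)$y
    x1 <- approx(tt, tx, starts + speed_window, rule = 2)$y
    y1 <- approx(tt, ty, starts + speed_window, rule = 2)$y
    sp <- sqrt((x1 - x0)^2 + (y1 - y0)^2) / speed_window
    any(sp < speed_thresh)
  }, NA)
}

#' Start-search time by trial outcome
#'
#' Search time is the interval from the (configurable) search onset --
#' default the center arrival after the sample phase -- to nose-poke onset.
#' Reports mean and bootstrap 95% CI separately for correct and incorrect
#' trials; a group with no trials is reported missing.
#'
#' @param trials an `fg_trials` table.
#' @param t_search_start optional per-trial search-onset times; default
#'   `trials$t_center_arrival`.
#' @param n_boot,seed bootstrap settings.
#' @return data.frame `(outcome, n, mean_s, ci_low, ci_high)`.
#' @export
search_time_summary <- function(trials, t_search_start = NULL,
                                n_boot = 2000, seed = 1) {
  if (is.null(t_search_start)) t_search_start <- trials$t_center_arrival
  dur <- trials$t_delay_on - t_search_start
  out <- lapply(c(correct = TRUE, incorrect = FALSE), function(ok) {
    d <- dur[trials$correct == ok]
    if (!length(d))
      return(data.frame(outcome = NA_character_, n = 0L, mean_s = NA_real_,
                        ci_low = NA_real_, ci_high = NA_real_))
    set.seed(derive_seed(seed, "search_boot"))
    bm <- replicate(n_boot, mean(sample(d, replace = TRUE)))
    data.frame(outcome = NA_character_, n = length(d), mean_s = mean(d),
               ci_low = unname(quantile(bm, 0.025)),
               ci_high = unname(quantile(bm, 0.975)))
  })
  res <- do.call(rbind, out)
  res$outcome <- c("correct", "incorrect")
  res
}
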