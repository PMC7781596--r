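#' Drop trials from the beginning of a session
#'
#' Settling-in trials at the start of a session (handling-related global rate
#' drift) are removed before analysis; spikes, LFP and tracking are left
#' untouched. Trial indices are renumbered contiguously from 0.
#'
#' @param s an `fg_session`.
#' @param n_trim number of initial trials to drop (`0 <= n_trim < n_trials`).
#' @return the trimmed `fg_session`.
#' @export
trim_initial_trials <- function(s, n_trim) {
  n <- nrow(s$trials)
  if (n_trim < 0 || n_trim >= n)
    stop("n_trim must be in [0, ", n - 1, "], got ", n_trim)
  if (n_trim == 0) return(s)
  tr <- s$trials[(n_trim + 1):n, ]
  tr$index <- 0:(nrow(tr) - 1)
  tr <- trial_table(tr, attr(s$trials, "delay_duration"))
  session(tr, s$units, s$spikes, lfp = s$lfp, tracking = s$tracking, meta = s$meta)
}

#' Session-wide firing-rate stability
#'
#' The firing rate is computed in 10 s bins across the session, standardized
#' over bins (mean 0, SD 1), and an ordinary least-squares line is fitted
#' against bin index. The criterion statistic is the absolute difference of
#' the fitted line between the last and first bin; the cell passes when it
#' does not exceed 1 (the fitted drift stays within one SD of the binned
#' rate distribution). Perfectly constant binned rates (SD 0) pass with
#' statistic 0: a flat cell is maximally stable.
#'
#' @param spike_times sorted spike times, seconds.
#' @param span length-2 session span `(t0, t1)`, at least 20 s.
#' @return list with `pass` and `z_diff`.
#' @export
session_rate_stability <- function(spike_times, span) {
  if (diff(span) < 20) stop("session span must be at least 20 s")
  nb <- floor(diff(span) / 10)
  edges <- span[1] + 10 * (0:nb)
  cnt <- tabulate(findInterval(spike_times[spike_times >= span[1] &
                                           spike_times < edges[nb + 1]], edges),
                  nbins = nb)
  r <- cnt / 10
  if (sd(r) == 0) return(list(pass = TRUE, z_diff = 0))
  z <- (r - mean(r)) / sd(r)
  fit <- stats::lm.fit(cbind(1, seq_len(nb)), z)
  z_diff <- abs(fit$coefficients[2] * (nb - 1))
  list(pass = unname(z_diff <= 1), z_diff = unname(z_diff))
}

#' Delay-period rate stability
#'
#' Linear regression of raw per-delay spike counts on delay index; the
#' absolute fitted difference between the last and the first delay must not
#' exceed 1.4 spikes. Because goals are pseudorandomly interleaved, a
#' stationary goal-selective cell is not excluded by this criterion.
#'
#' @param spike_times sorted spike times, seconds.
#' @param trials an `fg_trials` table (>= 2 delay periods).
#' @return list with `pass` and `fit_diff` (spikes).
#' @export
delay_rate_stability <- function(spike_times, trials) {
  n <- nrow(trials)
  if (n < 2) stop("need at least 2 delay periods")
  cnt <- delay_counts(spike_times, trials)
  fit <- stats::lm.fit(cbind(1, seq_len(n)), cnt)
  fit_diff <- abs(fit$coefficients[2] * (n - 1))
  list(pass = unname(fit_diff <= 1.4), fit_diff = unname(fit_diff))
}

delay_counts <- function(spike_times, trials) {
  vapply(seq_len(nrow(trials)), function(i)
    sum(spike_times >= trials$t_delay_on[i] & spike_times < trials$t_delay_off[i]),
    0)
}

#' Minimum delay-period activity
#'
#' A cell must fire at least one spike in at least one-sixth of all delay
#' periods (boundary inclusive: exactly n/6 active delays passes). The
#' threshold is lenient by design so that a cell active in half the delays
#' for one goal and silent otherwise survives.
#'
#' @inheritParams delay_rate_stability
#' @return logical.
#' @export
delay_activity_minimum <- function(spike_times, trials) {
  n <- nrow(trials)
  if (n < 6) stop("need at least 6 delay periods")
  sum(delay_counts(spike_times, trials) > 0) >= n / 6
}

#' Exclude putative fast-spiking interneurons
#'
#' Removes units that combine a faster waveform (peak-to-trough below
#' `width_max`) with a higher session-wide firing rate (above `rate_min`);
#' both conditions are required. The thresholds are configuration
#' parameters, not published values.
#'
#' @param units units data.frame (see [session()]).
#' @param width_max waveform width threshold, ms.
#' @param rate_min firing-rate threshold, Hz.
#' @return the units data.frame with putative interneurons removed.
#' @export
exclude_interneurons <- function(units, width_max = 0.4, rate_min = 10) {
  stopifnot(width_max > 0, rate_min > 0)
  drop <- units$waveform_width_ms < width_max & units$mean_rate_hz > rate_min
  units[!drop, , drop = FALSE]
}

#' Full cell-selection pipeline
#'
#' Applies, in fixed order: initial-trial trimming, the session-rate and
#' delay-rate stability criteria, the delay-activity minimum, and
#' interneuron exclusion.
#'
#' @param s an `fg_session`.
#' @param n_trim initial trials to drop (session-specific, typically 3-20
#'   for real sessions; default 0 for synthetic ones).
#' @param width_max,rate_min interneuron thresholds, see
#'   [exclude_interneurons()].
#' @return list: `session` (trimmed), `selected` (unit ids surviving all
#'   filters), `report` (counts per stage: total, stable, principal, plus
#'   per-unit pass flags).
#' @export
select_cells <- function(s, n_trim = 0, width_max = 0.4, rate_min = 10) {
  s <- trim_initial_trials(s, n_trim)
  dur <- session_duration(s)
  span <- c(0, dur)
  u <- s$units
  st1 <- vapply(as.character(u$unit_id), function(id)
    session_rate_stability(s$spikes[[id]], span)$pass, TRUE)
  st2 <- vapply(as.character(u$unit_id), function(id)
    delay_rate_stability(s$spikes[[id]], s$trials)$pass, TRUE)
  st3 <- vapply(as.character(u$unit_id), function(id)
    delay_activity_minimum(s$spikes[[id]], s$trials), TRUE)
  stable <- u[st1 & st2 & st3, , drop = FALSE]
  principal <- exclude_interneurons(stable, width_max, rate_min)
  list(session = s, selected = principal$unit_id,
       report = list(n_total = nrow(u), n_stable = nrow(stable),
                     n_principal = nrow(principal),
                     pass_session_rate = st1, pass_delay_rate = st2,
                     pass_activity = st3))
}
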