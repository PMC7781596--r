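#' LFP channel quality control
#'
#' Removes reference-like and noisy channels: a channel is dropped when its
#' standard deviation is below 1/4 of the mean channel SD (flat/reference)
#' or above 4 times the mean SD (noisy).
#'
#' @param lfp LFP list (see [session()]).
#' @return the LFP list restricted to retained channels.
#' @export
lfp_channel_qc <- function(lfp) {
  if (nrow(lfp$samples) < 2) stop("need at least 2 channels")
  sds <- apply(lfp$samples, 1, sd)
  m <- mean(sds)
  keep <- !(sds < m / 4 | sds > 4 * m)
  if (!any(keep)) stop("all LFP channels removed by QC")
  list(fs = lfp$fs, samples = lfp$samples[keep, , drop = FALSE],
       channel_indices = lfp$channel_indices[keep])
}

#' Reference LFP trace for a unit
#'
#' Averages 10 LFP channels that are at least `min_dist` sites away from
#' the unit's channel, taking the 5 nearest eligible sites on each side
#' when available and shifting the split toward one side near array edges
#' (e.g. 8 above / 2 below for a unit near the bottom).
#'
#' @param lfp (QC'd) LFP list.
#' @param channel_index the unit's channel index.
#' @param n_ref number of channels to average (default 10).
#' @param min_dist minimum distance in sites (default 8).
#' @return list: `trace` (numeric vector), `channels` (indices used).
#' @export
reference_lfp_for_unit <- function(lfp, channel_index, n_ref = 10, min_dist = 8) {
  d <- lfp$channel_indices - channel_index
  below <- which(d <= -min_dist); above <- which(d >= min_dist)
  if (length(below) + length(above) < n_ref)
    stop("only ", length(below) + length(above), " channels at least ", min_dist,
         " sites away (", length(below), " below, ", length(above),
         " above); need ", n_ref)
  below <- below[order(-d[below])]  # nearest first
  above <- above[order(d[above])]
  nb <- min(length(below), ceiling(n_ref / 2))
  na_ <- min(length(above), n_ref - nb)
  nb <- n_ref - na_  # shift toward the side with room
  sel <- c(below[seq_len(nb)], above[seq_len(na_)])
  list(trace = colMeans(lfp$samples[sel, , drop = FALSE]),
       channels = lfp$channel_indices[sel])
}

# analytic signal via the frequency-domain Hilbert construction
hilbert_analytic <- function(x) {
  n <- length(x)
  X <- fft(x)
  h <- numeric(n)
  if (n %% 2 == 0) { h[1] <- 1; h[n / 2 + 1] <- 1; h[2:(n / 2)] <- 2 }
  else { h[1] <- 1; h[2:((n + 1) / 2)] <- 2 }
  fft(X * h, inverse = TRUE) / n
}

#' Instantaneous band phase over delay periods
#'
#' Band-passes the reference trace with a zero-phase FIR filter (forward-
#' backward application of a Hamming-window design, order about three
#' cycles of the band's low edge), computes the instantaneous phase as the
#' angle of the analytic signal, and masks every peak-to-peak interval in
#' which the phase fails to increase monotonically (amplitude nulls produce
#' phase slips there). The trace is filtered with `pad` seconds of context
#' around each delay; only the delay itself is retained.
#'
#' @param trace reference LFP trace (numeric vector from recording start).
#' @param fs sampling rate, Hz.
#' @param trials an `fg_trials` table supplying the delay windows.
#' @param band length-2 band edges, Hz: one of (2.5, 5), (5, 12), (15, 30)
#'   canonically; any band below Nyquist is accepted.
#' @param pad filter context around each delay, seconds (default 3).
#' @return object of class `fg_phase_series`: `band`, `fs`, and per-delay
#'   entries with `t` (absolute sample times), `phase` (radians, wrapped to
#'   (-pi, pi]), `valid` mask and `valid_duration` (s).
#' @export
band_phase <- function(trace, fs, trials, band = c(5, 12), pad = 3) {
  if (band[2] >= fs / 2) stop("band edge ", band[2], " Hz at or above Nyquist")
  ord <- min(2 * floor(1.5 * fs / band[1]), floor((length(trace) - 1) / 3) * 2 - 2)
  flt <- signal::fir1(ord, band / (fs / 2), type = "pass")
  filtered <- signal::filtfilt(signal::Ma(flt), trace)
  an <- hilbert_analytic(filtered)
  phase <- Arg(an)
  delays <- vector("list", nrow(trials))
  for (i in seq_len(nrow(trials))) {
    i0 <- max(1L, floor(trials$t_delay_on[i] * fs) + 1L)
    i1 <- min(length(phase), ceiling(trials$t_delay_off[i] * fs))
    ph <- phase[i0:i1]
    valid <- monotone_phase_mask(ph)
    delays[[i]] <- list(t = (seq(i0, i1) - 1) / fs, phase = ph, valid = valid,
                        valid_duration = sum(valid) / fs)
  }
  structure(list(band = band, fs = fs, delays = delays),
            class = "fg_phase_series")
}

# TRUE where the sample lies in a peak-to-peak interval with monotonically
# increasing phase; whole intervals containing any phase regression are
# rejected.
monotone_phase_mask <- function(ph) {
  n <- length(ph)
  if (n < 3) return(rep(FALSE, n))
  d <- diff(ph)
  wraps <- which(d < -pi)  # end of one cycle
  bounds <- c(0, wraps, n)
  valid <- logical(n)
  for (k in seq_len(length(bounds) - 1)) {
    a <- bounds[k] + 1; b <- bounds[k + 1]
    if (b <= a) next
    ok <- all(d[a:(b - 1)] > 0) || b - a == 0
    valid[a:b] <- ok
  }
  valid
}

#' Delay-period power spectrum in log-spaced bins
#'
#' Notch-filters the trace at 60 Hz, computes a periodogram for every delay
#' period, averages them, and aggregates power into `n_bins`
#' logarithmically spaced frequency bins.
#'
#' @param trace LFP trace (numeric vector from recording start).
#' @param fs sampling rate, Hz.
#' @param trials an `fg_trials` table.
#' @param n_bins number of log-spaced bins (default 31).
#' @param frange frequency range, Hz.
#' @param notch notch center, Hz (NULL to skip).
#' @return data.frame `(f_lo, f_hi, f_center, power)`.
#' @export
delay_spectrogram <- function(trace, fs, trials, n_bins = 31,
                              frange = c(2, 100), notch = 60) {
  if (!is.null(notch) && notch < fs / 2) {
    flt <- signal::fir1(min(400, 2 * floor((length(trace) - 1) / 7)),
                        c(notch - 2, notch + 2) / (fs / 2), type = "stop")
    trace <- signal::filtfilt(signal::Ma(flt), trace)
  }
  nlen <- min(floor((trials$t_delay_off - trials$t_delay_on) * fs))
  P <- NULL; freqs <- NULL
  for (i in seq_len(nrow(trials))) {
    i0 <- floor(trials$t_delay_on[i] * fs) + 1L
    seg <- trace[i0:(i0 + nlen - 1)]
    sp <- Mod(fft(seg - mean(seg)))^2 / (nlen * fs)
    half <- 2:(floor(nlen / 2))
    if (is.null(P)) { P <- sp[half]; freqs <- (half - 1) * fs / nlen }
    else P <- P + sp[half]
  }
  P <- P / nrow(trials)
  edges <- exp(seq(log(frange[1]), log(frange[2]), length.out = n_bins + 1))
  bin <- findInterval(freqs, edges, rightmost.closed = TRUE)
  keep <- bin >= 1 & bin <= n_bins
  pw <- vapply(seq_len(n_bins), function(b) {
    w <- keep & bin == b
    if (any(w)) mean(P[w]) else NA_real_
  }, 0)
  data.frame(f_lo = edges[-(n_bins + 1)], f_hi = edges[-1],
             f_center = sqrt(edges[-(n_bins + 1)] * edges[-1]), power = pw)
}

# map delay-period spikes of one unit onto valid phase samples
spike_phases_by_delay <- function(spike_times, ps) {
  lapply(ps$delays, function(d) {
    if (!length(d$t)) return(numeric(0))
    w <- spike_times[spike_times >= d$t[1] & spike_times <= d$t[length(d$t)]]
    if (!length(w)) return(numeric(0))
    idx <- pmin(length(d$t), pmax(1, round((w - d$t[1]) * ps$fs) + 1))
    d$phase[idx][d$valid[idx]]
  })
}

resultant <- function(ph) {
  if (!length(ph)) return(c(r = NA_real_, mu = NA_real_))
  z <- mean(exp(1i * ph))
  c(r = Mod(z), mu = Arg(z))
}

rayleigh_p <- function(ph) {
  n <- length(ph)
  if (n == 0) return(NA_real_)
  R <- n * resultant(ph)["r"]
  # Zar's approximation
  p <- exp(sqrt(1 + 4 * n + 4 * (n^2 - R^2)) - (1 + 2 * n))
  unname(min(1, p))
}

#' Phase-locking statistics for one unit
#'
#' Maps the unit's delay-period spikes onto valid instantaneous phases and
#' computes the resultant vector length r (and mean phase) overall and per
#' remembered-goal class, plus a Rayleigh test of overall phase locking.
#' r = 1 means all spikes at one phase; r = 0, uniform phases.
#'
#' @param spike_times the unit's spike times, seconds.
#' @param ps an `fg_phase_series` from [band_phase()].
#' @param trials an `fg_trials` table (delay goal labels).
#' @param by_goal also compute per-goal statistics (default TRUE).
#' @return list of class `fg_phase_stats`: `n_spikes`, `r`, `mean_phase`,
#'   `rayleigh_p`, and (if `by_goal`) `r_by_goal`, `mu_by_goal`,
#'   `n_by_goal`.
#' @export
phase_locking_stats <- function(spike_times, ps, trials, by_goal = TRUE) {
  phs <- spike_phases_by_delay(spike_times, ps)
  all_ph <- unlist(phs)
  res <- resultant(all_ph)
  out <- list(n_spikes = length(all_ph), r = unname(res["r"]),
              mean_phase = unname(res["mu"]), rayleigh_p = rayleigh_p(all_ph))
  if (by_goal) {
    rg <- vapply(1:3, function(g) {
      resultant(unlist(phs[trials$goal == g]))
    }, c(r = 0, mu = 0))
    out$r_by_goal <- rg["r", ]; out$mu_by_goal <- rg["mu", ]
    out$n_by_goal <- vapply(1:3, function(g)
      length(unlist(phs[trials$goal == g])), 0L)
  }
  structure(out, class = "fg_phase_stats")
}

#' Label-shuffle test for goal-dependent phase locking
#'
#' Compares the observed distribution of per-(cell, goal) resultant vector
#' lengths with the distribution obtained after shuffling the delay-period
#' goal labels (one permutation per shuffle, applied to all cells), using a
#' two-sample Kolmogorov-Smirnov test against the pooled shuffle
#' distribution.
#'
#' @param phase_lists list over cells; each element a list over delays of
#'   spike-phase vectors (see [spike_phases_by_delay()] via
#'   [phase_locking_stats()] internals, or built directly).
#' @param goals per-delay goal labels.
#' @param n_shuffle number of label shuffles.
#' @param seed RNG seed.
#' @param min_spikes per-(cell, goal) minimum spike count for an r value to
#'   enter the distributions.
#' @return list: `p`, `observed_r`, `shuffled_r`.
#' @export
goal_phase_shuffle_test <- function(phase_lists, goals, n_shuffle = 200,
                                    seed = 1, min_spikes = 5) {
  r_values <- function(lab) {
    unlist(lapply(phase_lists, function(phs) {
      vapply(1:3, function(g) {
        ph <- unlist(phs[lab == g])
        if (length(ph) < min_spikes) NA_real_ else Mod(mean(exp(1i * ph)))
      }, 0)
    }))
  }
  obs <- r_values(goals)
  obs <- obs[!is.na(obs)]
  set.seed(derive_seed(seed, "phase_shuffle"))
  sh <- unlist(lapply(seq_len(n_shuffle), function(k) r_values(sample(goals))))
  sh <- sh[!is.na(sh)]
  if (length(obs) < 2 || length(sh) < 2 || sd(obs) == 0 || sd(sh) == 0) {
    warning("degenerate resultant-length distributions; p = 1")
    return(list(p = 1, observed_r = obs, shuffled_r = sh))
  }
  p <- suppressWarnings(ks.test(obs, sh)$p.value)
  list(p = p, observed_r = obs, shuffled_r = sh)
}

#' Phase-of-firing goal decoding
#'
#' Features are, per cell and phase bin, the number of delay-period spikes
#' falling in that instantaneous-phase bin divided by the delay's total
#' valid phase duration; features are standardized over delay periods and
#' classified with leave-one-out logistic regression with class balancing.
#' Delays with zero valid duration are dropped with a warning.
#'
#' @param s an `fg_session`.
#' @param ps_list list of `fg_phase_series`, one per decoded cell (cells
#'   may share a series when a common reference is used).
#' @param cells unit ids matching `ps_list`.
#' @param n_bins number of phase bins: 2, 6 or 12 canonically.
#' @param spec classifier spec (default logistic regression).
#' @param correct_only use correct trials only.
#' @param seed RNG seed.
#' @return an `fg_decoding`.
#' @export
phase_bin_decoding <- function(s, ps_list, cells, n_bins = 6,
                               spec = classifier_specs()$lr,
                               correct_only = TRUE, seed = 1) {
  n <- nrow(s$trials)
  stopifnot(length(ps_list) == length(cells))
  # bins centered on phase 0: bin 1 covers [-pi/n_bins, pi/n_bins), so for
  # n_bins = 2 the first bin is the descending half-cycle (-90..90 degrees)
  phase_bin <- function(ph) {
    floor(((ph + pi / n_bins) %% (2 * pi)) / (2 * pi / n_bins)) + 1L
  }
  X <- matrix(0, n, length(cells) * n_bins)
  vd <- matrix(NA_real_, n, length(cells))
  for (j in seq_along(cells)) {
    ps <- ps_list[[j]]
    phs <- spike_phases_by_delay(s$spikes[[as.character(cells[j])]], ps)
    for (i in seq_len(n)) {
      vd[i, j] <- ps$delays[[i]]$valid_duration
      if (vd[i, j] <= 0) next
      cnt <- tabulate(phase_bin(phs[[i]]), nbins = n_bins)
      X[i, (j - 1) * n_bins + seq_len(n_bins)] <- cnt / vd[i, j]
    }
  }
  keep <- if (correct_only) s$trials$correct else rep(TRUE, n)
  zero <- apply(vd <= 0, 1, any)
  if (any(zero & keep))
    warning(sum(zero & keep), " delay(s) dropped: zero valid phase duration")
  keep <- keep & !zero
  loo_cv(X[keep, , drop = FALSE], s$trials$goal[keep], spec, seed = seed)
}
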