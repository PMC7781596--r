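#' Selectivity configuration for the synthetic session generator
#'
#' Describes the cell population of a simulated session: how many cells,
#' their baseline Poisson rate, which exclusive selectivity classes they are
#' drawn from, and optional rate drift, oscillatory phase locking, pairwise
#' fast synchrony, interneuron contamination, LFP and tracking synthesis.
#'
#' Fractions refer to exclusive classes and must sum to at most 1; the
#' remainder of the population is unselective. `gain` is the multiplicative
#' rate factor applied during the delay period (or at a sequence cell's
#' latency) when the trial's label matches the cell's preferred label.
#'
#' @param n_cells number of putative principal cells.
#' @param base_rate baseline rate, Hz.
#' @param frac_goal_cells,frac_start_cells,frac_ego_cells,frac_conjunctive_cells,frac_sequence_cells
#'   fractions of the population in each exclusive selectivity class.
#' @param gain multiplicative rate factor (>= 1) for the preferred class.
#' @param drift_cells list of `list(cell, start_rate, end_rate)`: cells whose
#'   baseline ramps linearly across the session (Hz at start and end).
#' @param phase_lock list of `list(cell, band, kappa, preferred_phase,
#'   goal_specific)`: delay-period spikes of `cell` follow a von Mises phase
#'   preference of concentration `kappa` relative to LFP band 1..3
#'   (2.5-5, 5-12, 15-30 Hz). With `goal_specific = TRUE` the preferred
#'   phase rotates by 2*pi/3 per remembered goal at unchanged rate.
#' @param sync_pairs list of `list(cell_a, cell_b, shared_event_rate,
#'   jitter_sd, preferred_only, goal)`: the pair receives shared excess
#'   delay-period spikes at `shared_event_rate` Hz, each member jittered
#'   independently by `N(0, jitter_sd)` around common event times;
#'   `preferred_only` restricts injection to trials of `goal`.
#' @param n_interneurons putative fast-spiking cells appended to the
#'   population (short waveform, high rate) to exercise the exclusion rule.
#' @param lfp logical; synthesize multi-channel LFP.
#' @param lfp_fs,lfp_n_channels LFP sampling rate (Hz) and channel count.
#' @param tracking logical; synthesize 30 Hz two-LED tracking.
#' @param tracking_noise_cm sensor noise SD (cm) on each LED coordinate.
#' @param ego_convention see [class_labels()].
#' @param sequence_goal_gated if TRUE, sequence cells fire their rate bump
#'   only on trials of a preferred goal.
#' @param seed master seed; independent named streams are derived for
#'   trials/spikes/lfp/tracking so stages are independently reproducible.
#' @return list of class `fg_config`.
#' @export
selectivity_config <- function(n_cells = 90, base_rate = 2,
                               frac_goal_cells = 0, frac_start_cells = 0,
                               frac_ego_cells = 0, frac_conjunctive_cells = 0,
                               frac_sequence_cells = 0, gain = 3,
                               drift_cells = list(), phase_lock = list(),
                               sync_pairs = list(), n_interneurons = 0,
                               lfp = FALSE, lfp_fs = 500, lfp_n_channels = 32,
                               tracking = TRUE, tracking_noise_cm = 0.08,
                               ego_convention = c(behind = 1, left = 2, right = 3),
                               sequence_goal_gated = FALSE, seed = 1) {
  fr <- c(frac_goal_cells, frac_start_cells, frac_ego_cells,
          frac_conjunctive_cells, frac_sequence_cells)
  if (any(fr < 0) || sum(fr) > 1 + 1e-9)
    stop("selectivity fractions must be non-negative and sum to at most 1")
  if (gain < 1) stop("gain must be >= 1")
  for (pl in phase_lock) if (pl$kappa < 0) stop("kappa must be >= 0")
  for (sp in sync_pairs) if (sp$jitter_sd < 0) stop("jitter_sd must be >= 0")
  structure(as.list(environment()), class = "fg_config")
}

band_centers <- c(3.5, 8, 22)  # Hz, one oscillator per elevated band

#' Generate a synthetic session with known ground truth
#'
#' Spike trains are inhomogeneous Poisson (thinning sampler). The per-cell
#' rate is `base_rate` (optionally drifting linearly), multiplied by `gain`
#' during the delay period of trials whose label matches the cell's
#' preferred label, by a Gaussian bump at a cell-specific latency for
#' sequence cells, and by a von Mises factor of the instantaneous band phase
#' for phase-locked cells. Sync pairs additionally receive shared
#' jittered spikes. LFP is a sum of three band-limited oscillations
#' (amplitude elevated during delays) plus 1/f-like noise, duplicated across
#' channels with small per-channel delays. Tracking follows piecewise-linear
#' paths between task locations and is stationary (noise only) during each
#' nose poke.
#'
#' @param trials an `fg_trials` table, e.g. from [generate_trial_sequence()].
#' @param config an [selectivity_config()].
#' @return list with elements `session` (an `fg_session`) and `truth`
#'   (class `fg_ground_truth`: per-cell class/preferred label, injected
#'   synchrony and phase-locking specs, conventions, and the config).
#' @export
generate_session <- function(trials, config) {
  stopifnot(inherits(config, "fg_config"))
  n <- nrow(trials)
  duration <- ceiling(max(trials$t_test_goal_arrival) + 10)
  nc <- config$n_cells

  # --- assign exclusive selectivity classes -------------------------------
  set.seed(derive_seed(config$seed, "assign"))
  counts <- round(nc * c(goal = config$frac_goal_cells,
                         start = config$frac_start_cells,
                         ego = config$frac_ego_cells,
                         conj = config$frac_conjunctive_cells,
                         seq = config$frac_sequence_cells))
  cls <- rep("none", nc)
  idx <- sample(nc)
  pos <- 1
  for (k in names(counts)) {
    if (counts[k] > 0) cls[idx[pos:(pos + counts[k] - 1)]] <- k
    pos <- pos + counts[k]
  }
  pref <- integer(nc)
  for (k in c("goal", "start", "ego")) {
    w <- which(cls == k)
    pref[w] <- rep_len(sample(3), length(w))
  }
  w <- which(cls == "conj"); pref[w] <- rep_len(sample(9), length(w))
  w <- which(cls == "seq")
  dd <- attr(trials, "delay_duration")
  latency <- rep(NA_real_, nc)
  latency[w] <- runif(length(w), 0.25, dd - 0.25)
  seq_goal <- rep(NA_integer_, nc)
  if (config$sequence_goal_gated) seq_goal[w] <- rep_len(sample(3), length(w))

  drift <- matrix(NA_real_, nc, 2)
  for (d in config$drift_cells) drift[d$cell, ] <- c(d$start_rate, d$end_rate)
  pl_cell <- rep(NA_integer_, nc); pl_band <- rep(NA_integer_, nc)
  pl_kappa <- rep(0, nc); pl_mu <- rep(0, nc); pl_goal <- rep(FALSE, nc)
  for (pl in config$phase_lock) {
    i <- pl$cell
    pl_cell[i] <- i; pl_band[i] <- pl$band; pl_kappa[i] <- pl$kappa
    pl_mu[i] <- pl$preferred_phase
    pl_goal[i] <- isTRUE(pl$goal_specific)
  }

  # per-trial, per-cell constant delay gain factor
  lab <- list(goal = class_labels(trials, "goal"),
              start = class_labels(trials, "start"),
              ego = class_labels(trials, "ego", config$ego_convention),
              conj = class_labels(trials, "start_x_goal"))
  G <- delay_gain_matrix(cls, pref, lab, config$gain, n)

  # band phase functions: phi_b(t) = 2*pi*f_b*t + phi0_b
  set.seed(derive_seed(config$seed, "lfp"))
  phi0 <- runif(3, -pi, pi)

  # --- spikes --------------------------------------------------------------
  set.seed(derive_seed(config$seed, "spikes"))
  spikes <- vector("list", nc)
  for (i in seq_len(nc)) {
    spikes[[i]] <- gen_cell_spikes(
      i, duration, trials, config, cls[i], pref[i], latency[i], seq_goal[i],
      drift[i, ], pl_band[i], pl_kappa[i], pl_mu[i], pl_goal[i], G[, i], phi0)
  }

  # shared-event synchrony injection
  truth_pairs <- list()
  for (spx in config$sync_pairs) {
    g <- if (!is.null(spx$goal)) spx$goal else 1L
    sel <- if (isTRUE(spx$preferred_only)) which(trials$goal == g) else seq_len(n)
    ev <- numeric(0)
    for (ti in sel) {
      k <- rpois(1, spx$shared_event_rate * dd)
      if (k > 0) ev <- c(ev, runif(k, trials$t_delay_on[ti], trials$t_delay_off[ti]))
    }
    for (m in c("cell_a", "cell_b")) {
      i <- spx[[m]]
      spikes[[i]] <- sort(c(spikes[[i]], pmax(0, ev + rnorm(length(ev), 0, spx$jitter_sd))))
    }
    truth_pairs[[length(truth_pairs) + 1]] <-
      data.frame(cell_a = spx$cell_a, cell_b = spx$cell_b,
                 shared_event_rate = spx$shared_event_rate,
                 jitter_sd = spx$jitter_sd,
                 preferred_only = isTRUE(spx$preferred_only), goal = g)
  }

  # interneurons: short waveform + high rate
  n_int <- config$n_interneurons
  if (n_int > 0) {
    for (j in seq_len(n_int)) {
      k <- rpois(1, 18 * duration)
      spikes[[nc + j]] <- sort(runif(k, 0, duration))
    }
  }
  n_all <- nc + n_int
  width <- c(pmax(0.45, rnorm(nc, 0.65, 0.08)),
             if (n_int) pmin(0.32, pmax(0.12, rnorm(n_int, 0.2, 0.03))))
  units <- data.frame(
    unit_id = seq_len(n_all),
    waveform_width_ms = width,
    mean_rate_hz = vapply(spikes, length, 0L) / duration,
    subarea = rep(c("PL", "IL", "ACC"), length.out = n_all),
    channel_index = sort(sample(1:384, n_all)))
  names(spikes) <- as.character(units$unit_id)

  lfp <- if (config$lfp) gen_lfp(trials, config, duration, phi0) else NULL
  tracking <- if (config$tracking) gen_tracking(trials, config, duration) else NULL

  truth <- structure(list(
    cells = data.frame(unit_id = seq_len(n_all),
                       class = c(cls, rep("interneuron", n_int)),
                       preferred = c(pref, rep(NA_integer_, n_int)),
                       latency = c(latency, rep(NA_real_, n_int)),
                       sequence_goal = c(seq_goal, rep(NA_integer_, n_int)),
                       kappa = c(pl_kappa, rep(0, n_int)),
                       band = c(pl_band, rep(NA_integer_, n_int)),
                       preferred_phase = c(pl_mu, rep(NA_real_, n_int)),
                       phase_goal_specific = c(pl_goal, rep(FALSE, n_int))),
    sync_pairs = if (length(truth_pairs)) do.call(rbind, truth_pairs) else NULL,
    drift = drift, ego_convention = config$ego_convention,
    band_phi0 = phi0, rotation = NULL, config = config),
    class = "fg_ground_truth")

  s <- session(trials, units, spikes,
               lfp = lfp, tracking = tracking,
               meta = list(duration = duration, seed = config$seed,
                           generator = "flexgoal synthetic"))
  list(session = s, truth = truth)
}

delay_gain_matrix <- function(cls, pref, lab, gain, n_trials) {
  nc <- length(cls)
  G <- matrix(1, n_trials, nc)
  for (i in seq_len(nc)) {
    m <- switch(cls[i],
                goal = lab$goal == pref[i],
                start = lab$start == pref[i],
                ego = lab$ego == pref[i],
                conj = lab$conj == pref[i],
                NULL)
    if (!is.null(m)) G[m, i] <- gain
  }
  G
}

# thinning sampler for one cell
gen_cell_spikes <- function(i, duration, trials, config, cls, pref, latency,
                            seq_goal, drift, band, kappa, mu, goal_specific,
                            gvec, phi0) {
  base0 <- if (!is.na(drift[1])) max(drift) else config$base_rate
  vmmax <- if (kappa > 0) exp(kappa) / besselI(kappa, 0) else 1
  bumpmax <- if (cls == "seq") config$gain else 1
  rmax <- base0 * max(gvec) * vmmax * bumpmax
  ncand <- rpois(1, rmax * duration)
  if (ncand == 0) return(numeric(0))
  t <- sort(runif(ncand, 0, duration))
  r <- rep(if (is.na(drift[1])) config$base_rate else NA_real_, ncand)
  if (!is.na(drift[1])) r <- drift[1] + (drift[2] - drift[1]) * t / duration
  ti <- findInterval(t, trials$t_delay_on)
  in_delay <- ti >= 1 & t < trials$t_delay_off[pmax(ti, 1)]
  w <- which(in_delay)
  if (cls == "goal") {
    # goal cells are spatially tuned at their goal: elevated rate while the
    # animal is at the preferred goal in sample and test phases as well
    si <- findInterval(t, trials$t_sample_goal_arrival)
    at_sample <- si >= 1 & t < trials$t_sample_goal_arrival[pmax(si, 1)] + 3 &
      trials$goal[pmax(si, 1)] == pref
    gi <- findInterval(t, trials$t_test_goal_arrival)
    at_test <- gi >= 1 & t < trials$t_test_goal_arrival[pmax(gi, 1)] + 3 &
      trials$test_choice[pmax(gi, 1)] == pref
    r[at_sample | at_test] <- r[at_sample | at_test] * config$gain
  }
  if (length(w)) {
    r[w] <- r[w] * gvec[ti[w]]
    if (cls == "seq") {
      tau <- t[w] - trials$t_delay_on[ti[w]]
      gated <- if (!is.na(seq_goal)) trials$goal[ti[w]] == seq_goal else TRUE
      bump <- 1 + (config$gain - 1) * exp(-(tau - latency)^2 / (2 * 0.25^2)) * gated
      r[w] <- r[w] * bump
    }
    if (kappa > 0) {
      ph <- 2 * pi * band_centers[band] * t[w] + phi0[band]
      mu_t <- mu + if (goal_specific) 2 * pi * (trials$goal[ti[w]] - 1) / 3 else 0
      r[w] <- r[w] * exp(kappa * cos(ph - mu_t)) / besselI(kappa, 0)
    }
  }
  t[runif(ncand) < r / rmax]
}

gen_lfp <- function(trials, config, duration, phi0) {
  fs <- config$lfp_fs
  nch <- config$lfp_n_channels
  nt <- floor(duration * fs)
  t <- (0:(nt - 1)) / fs
  di <- findInterval(t, trials$t_delay_on)
  in_delay <- di >= 1 & t < trials$t_delay_off[pmax(di, 1)]
  amp <- 1 + 2 * in_delay  # delay-gated band power elevation
  samples <- matrix(0, nch, nt)
  for (ch in seq_len(nch)) {
    lag <- (ch - 1) * 2e-4  # small per-channel delay, seconds
    osc <- rowSums(vapply(1:3, function(b)
      amp * sin(2 * pi * band_centers[b] * (t - lag) + phi0[b]), numeric(nt)))
    noise <- as.numeric(stats::filter(rnorm(nt, 0, 0.8), 0.95, "recursive"))
    samples[ch, ] <- osc + noise
  }
  list(fs = fs, samples = samples, channel_indices = seq_len(nch))
}

# maze geometry (cm): center at origin, start ports on an inner ring,
# goals on the outer ring, choice point (outer-ring entry) between them.
maze_xy <- function(kind, k) {
  ang <- switch(kind, start = c(90, 210, 330), goal = c(30, 150, 270),
                ring = c(30, 150, 270))
  r <- switch(kind, start = 25, goal = 60, ring = 45)
  a <- ang[k] * pi / 180
  c(r * cos(a), r * sin(a))
}

gen_tracking <- function(trials, config, duration) {
  set.seed(derive_seed(config$seed, "tracking"))
  n <- nrow(trials)
  # anchor points (time, x, y); linear interpolation between anchors
  A <- matrix(0, 0, 3)
  add <- function(A, t, p) rbind(A, c(t, p))
  A <- add(A, 0, c(0, 0))
  for (i in seq_len(n)) {
    tr <- trials[i, ]
    gs <- maze_xy("goal", tr$goal)  # sample-phase goal
    A <- add(A, tr$t_sample_goal_arrival, gs)
    A <- add(A, min(tr$t_sample_goal_arrival + 2.0, tr$t_center_arrival - 0.3), gs)
    A <- add(A, tr$t_center_arrival, c(0, 0))
    st <- maze_xy("start", tr$start)
    A <- add(A, max(tr$t_center_arrival + 0.2, tr$t_delay_on - 0.35), st)
    A <- add(A, tr$t_delay_off + 0.05, st)  # stationary nose poke
    A <- add(A, tr$t_choice_entry, maze_xy("ring", tr$test_choice))
    gt <- maze_xy("goal", tr$test_choice)
    A <- add(A, tr$t_test_goal_arrival, gt)
    A <- add(A, min(tr$t_test_goal_arrival + 2.0,
                    if (i < n) trials$t_sample_goal_arrival[i + 1] - 2.5 else duration - 1), gt)
    if (i < n) A <- add(A, trials$t_sample_goal_arrival[i + 1] - 1.5, c(0, 0))
  }
  A <- A[!duplicated(A[, 1]), , drop = FALSE]
  A <- A[order(A[, 1]), , drop = FALSE]
  ts <- seq(0, duration - 1 / 30, by = 1 / 30)
  x <- approx(A[, 1], A[, 2], xout = ts, rule = 2)$y
  y <- approx(A[, 1], A[, 3], xout = ts, rule = 2)$y
  # heading from motion; hold last heading when stationary
  dx <- c(diff(x), 0); dy <- c(diff(y), 0)
  sp <- sqrt(dx^2 + dy^2)
  hx <- ifelse(sp > 1e-6, dx / pmax(sp, 1e-12), NA)
  hy <- ifelse(sp > 1e-6, dy / pmax(sp, 1e-12), NA)
  ok <- !is.na(hx)
  if (!any(ok)) { hx[] <- 1; hy[] <- 0; ok <- !is.na(hx) }
  f <- findInterval(seq_along(hx), which(ok))
  f[f == 0] <- 1
  hx <- hx[which(ok)[f]]; hy <- hy[which(ok)[f]]
  sep <- 2  # cm, half LED separation along the head axis
  ns <- length(ts); sdn <- config$tracking_noise_cm
  data.frame(t_s = ts,
             x1_cm = x + sep * hx + rnorm(ns, 0, sdn),
             y1_cm = y + sep * hy + rnorm(ns, 0, sdn),
             x2_cm = x - sep * hx + rnorm(ns, 0, sdn),
             y2_cm = y - sep * hy + rnorm(ns, 0, sdn))
}

#' Remap spatial tuning mid-session (maze-rotation experiment)
#'
#' From trial `at_trial` (1-based row) onward, the spatial preferred labels
#' of goal/start/ego/conjunctive cells are remapped by a random non-identity
#' permutation and delay-period spikes of those trials are regenerated under
#' the new tuning; behavioral accuracy drops to a floor and recovers along
#' an exponential ramp. Trial labels themselves are unchanged.
#'
#' @param result a `list(session, truth)` from [generate_session()].
#' @param at_trial first affected trial (1-based row); earlier trials are
#'   untouched.
#' @param p_floor accuracy immediately after rotation.
#' @param tau relearning time constant, trials.
#' @param seed RNG seed for the remap, the redrawn outcomes and the
#'   regenerated spikes.
#' @return `list(session, truth)` with `truth$rotation` describing the remap.
#' @export
apply_rotation <- function(result, at_trial, p_floor = 0.35, tau = 15, seed = 1) {
  s <- result$session; truth <- result$truth
  n <- nrow(s$trials)
  if (at_trial < 1 || at_trial > n) stop("at_trial out of range 1..", n)
  set.seed(derive_seed(seed, "rotation"))
  perm <- sample(3)
  while (all(perm == 1:3)) perm <- sample(3)

  config <- truth$config
  trials <- s$trials
  rot <- at_trial:n
  # accuracy: drop then exponential recovery toward the pre-rotation level
  p_pre <- if (at_trial > 1) mean(trials$correct[1:(at_trial - 1)]) else 0.77
  p_pre <- max(p_pre, p_floor + 0.05)
  p <- p_floor + (p_pre - p_floor) * (1 - exp(-(rot - at_trial) / tau))
  correct <- runif(length(rot)) < p
  wrong <- vapply(trials$goal[rot], function(g) sample(setdiff(1:3, g), 1), 0L)
  trials$correct[rot] <- correct
  trials$test_choice[rot] <- ifelse(correct, trials$goal[rot], wrong)
  trials <- trial_table(trials, attr(s$trials, "delay_duration"))

  # remap preferred labels of spatially tuned cells
  cells <- truth$cells
  spat <- cells$class %in% c("goal", "start", "ego")
  cells$preferred[spat] <- perm[cells$preferred[spat]]
  cj <- cells$class == "conj"
  if (any(cj)) {
    st <- (cells$preferred[cj] - 1) %/% 3 + 1
    gl <- (cells$preferred[cj] - 1) %% 3 + 1
    cells$preferred[cj] <- (perm[st] - 1) * 3 + perm[gl]
  }
  truth$cells <- cells
  truth$rotation <- list(at_trial = at_trial, perm = perm,
                         p_floor = p_floor, tau = tau)

  # regenerate delay spikes of rotated trials under the new tuning
  lab <- list(goal = class_labels(trials, "goal"),
              start = class_labels(trials, "start"),
              ego = class_labels(trials, "ego", config$ego_convention),
              conj = class_labels(trials, "start_x_goal"))
  nc <- config$n_cells
  G <- delay_gain_matrix(cells$class[1:nc],
                         cells$preferred[1:nc], lab, config$gain, n)
  dur <- session_duration(s)
  for (i in which(spat[1:nc] | cj[1:nc])) {
    id <- as.character(i)
    sp <- s$spikes[[id]]
    for (ti in rot) {
      on <- trials$t_delay_on[ti]; off <- trials$t_delay_off[ti]
      sp <- sp[sp < on | sp >= off]
      k <- rpois(1, config$base_rate * G[ti, i] * (off - on))
      if (k > 0) sp <- c(sp, runif(k, on, off))
    }
    s$spikes[[id]] <- sort(sp)
  }
  s$units$mean_rate_hz <- vapply(s$spikes, length, 0L) / dur
  s <- session(trials, s$units, s$spikes, lfp = s$lfp,
               tracking = s$tracking, meta = s$meta)
  list(session = s, truth = truth)
}
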