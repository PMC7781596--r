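# shared fixtures, built once per test run and memoized
.fx <- new.env()

fx_cache <- function(key, expr) {
  if (is.null(.fx[[key]])) .fx[[key]] <- force(expr)
  .fx[[key]]
}

# a start-selective session with no goal signal (the dissociation setting)
fx_start_session <- function(seed = 5, n_blocks = 2, n_cells = 30,
                             frac_start = 0.3, gain = 3) {
  fx_cache(paste("start", seed, n_blocks, n_cells, frac_start, gain), {
    tr <- generate_trial_sequence(n_blocks = n_blocks, seed = seed)
    cfg <- selectivity_config(n_cells = n_cells, base_rate = 2,
                              frac_start_cells = frac_start, gain = gain,
                              tracking = FALSE, seed = seed)
    generate_session(tr, cfg)
  })
}

# a goal-selective session
fx_goal_session <- function(seed = 7, n_blocks = 2, n_cells = 30,
                            frac_goal = 0.3, gain = 3) {
  fx_cache(paste("goal", seed, n_blocks, n_cells, frac_goal, gain), {
    tr <- generate_trial_sequence(n_blocks = n_blocks, seed = seed)
    cfg <- selectivity_config(n_cells = n_cells, base_rate = 2,
                              frac_goal_cells = frac_goal, gain = gain,
                              tracking = FALSE, seed = seed)
    generate_session(tr, cfg)
  })
}

# hand-built minimal session: n trials with regular timing, explicit spikes
fx_manual_session <- function(spikes, n_trials = 6, delay = 3,
                              period = 20, n_units = length(spikes)) {
  t0 <- period * (seq_len(n_trials) - 1)
  tr <- data.frame(
    index = seq_len(n_trials) - 1L,
    goal = rep(1:3, length.out = n_trials),
    start = rep(c(1, 2, 3), length.out = n_trials),
    sample_route = rep(1:3, length.out = n_trials),
    test_route = rep(c(2, 3, 1), length.out = n_trials),
    correct = TRUE,
    t_sample_goal_arrival = t0 + 2, t_center_arrival = t0 + 6,
    t_delay_on = t0 + 8, t_delay_off = t0 + 8 + delay,
    t_choice_entry = t0 + 8 + delay + 1, t_test_goal_arrival = t0 + 8 + delay + 2)
  tr$test_choice <- tr$goal
  trials <- trial_table(tr, delay_duration = delay)
  if (is.null(names(spikes))) names(spikes) <- seq_along(spikes)
  units <- data.frame(unit_id = as.integer(names(spikes)),
                      waveform_width_ms = 0.6,
                      mean_rate_hz = vapply(spikes, length, 0L) /
                        (period * n_trials),
                      subarea = "PL", channel_index = seq_along(spikes) * 20L)
  session(trials, units, spikes, meta = list(duration = period * n_trials))
}
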