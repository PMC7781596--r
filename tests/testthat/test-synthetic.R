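test_that("null config gives homogeneous Poisson delay activity", {
  tr <- generate_trial_sequence(n_blocks = 4, seed = 21)
  cfg <- selectivity_config(n_cells = 20, base_rate = 2, tracking = FALSE,
                            seed = 21)
  s <- generate_session(tr, cfg)$session
  cnt <- apply(bin_aligned_counts(s, tr$t_delay_on, c(0, 3), 3), c(1, 2), sum)
  # mean rate within 3 SE of base rate
  m <- mean(cnt) / 3
  se <- sd(cnt / 3) / sqrt(length(cnt))
  expect_lt(abs(m - 2), 3 * se)
  # Fano factor of delay counts ~ 1 (pooled over 108 trials x 20 cells)
  fano <- mean(apply(cnt, 2, function(x) stats::var(x) / mean(x)))
  expect_lt(abs(fano - 1), 0.15)
})

test_that("goal cells express the configured gain on preferred trials", {
  tr <- generate_trial_sequence(n_blocks = 4, seed = 22)
  cfg <- selectivity_config(n_cells = 6, base_rate = 2, frac_goal_cells = 1,
                            gain = 3, tracking = FALSE, seed = 22)
  res <- generate_session(tr, cfg)
  s <- res$session
  pv <- population_vector(s, cbind(tr$t_delay_on, tr$t_delay_off))$values
  for (j in 1:6) {
    g <- res$truth$cells$preferred[j]
    on <- mean(pv[tr$goal == g, j]); off <- mean(pv[tr$goal != g, j])
    se_on <- sd(pv[tr$goal == g, j]) / sqrt(sum(tr$goal == g))
    se_off <- sd(pv[tr$goal != g, j]) / sqrt(sum(tr$goal != g))
    expect_lt(abs(on - 6), 3.5 * se_on)   # Poisson mean oracle: 2 Hz x gain 3
    expect_lt(abs(off - 2), 3.5 * se_off)
  }
})

test_that("tracking is stationary during every delay period", {
  res <- fx_cache("tracking_session", {
    tr <- generate_trial_sequence(n_blocks = 2, seed = 23)
    generate_session(tr, selectivity_config(n_cells = 3, seed = 23))
  })
  s <- res$session
  trk <- s$tracking
  mx <- (trk$x1_cm + trk$x2_cm) / 2; my <- (trk$y1_cm + trk$y2_cm) / 2
  for (i in seq_len(nrow(s$trials))) {
    w <- trk$t_s >= s$trials$t_delay_on[i] & trk$t_s <= s$trials$t_delay_off[i]
    # speed over 0.33 s windows, as the VTE screen measures it
    x <- mx[w]; y <- my[w]; k <- 10  # 10 samples ~ 0.33 s at 30 Hz
    sp <- sqrt((x[-(1:k)] - head(x, -k))^2 + (y[-(1:k)] - head(y, -k))^2) / (k / 30)
    expect_lt(max(sp), 1)
  }
})

test_that("sequence cells place a rate bump at their latency", {
  tr <- generate_trial_sequence(n_blocks = 4, seed = 24)
  cfg <- selectivity_config(n_cells = 4, base_rate = 2, frac_sequence_cells = 1,
                            gain = 4, tracking = FALSE, seed = 24)
  res <- generate_session(tr, cfg)
  cnt <- bin_aligned_counts(res$session, tr$t_delay_on, c(0, 3), 0.25)
  prof <- apply(cnt, c(2, 3), mean)  # cells x bins
  for (j in 1:4) {
    lat <- res$truth$cells$latency[j]
    peak_bin <- which.max(prof[j, ])
    expect_lt(abs((peak_bin - 0.5) * 0.25 - lat), 0.5)
  }
})

test_that("drift cells ramp and are caught by the stability filter", {
  tr <- generate_trial_sequence(n_blocks = 4, seed = 25)
  cfg <- selectivity_config(n_cells = 2, base_rate = 2, tracking = FALSE,
                            drift_cells = list(list(cell = 1, start_rate = 0.5,
                                                    end_rate = 8)),
                            seed = 25)
  s <- generate_session(tr, cfg)$session
  dur <- s$meta$duration
  early <- sum(s$spikes[["1"]] < dur / 4) / (dur / 4)
  late <- sum(s$spikes[["1"]] > 3 * dur / 4) / (dur / 4)
  expect_gt(late, 2 * early)
  expect_false(session_rate_stability(s$spikes[["1"]], c(0, dur))$pass)
  expect_true(session_rate_stability(s$spikes[["2"]], c(0, dur))$pass)
})

test_that("rotation remaps tuning, drops accuracy and leaves earlier trials intact", {
  tr <- generate_trial_sequence(n_blocks = 4, seed = 26, p_correct = 0.85)
  cfg <- selectivity_config(n_cells = 10, base_rate = 2, frac_goal_cells = 0.5,
                            gain = 3, tracking = FALSE, seed = 26)
  res <- generate_session(tr, cfg)
  at <- 55
  rot <- apply_rotation(res, at_trial = at, seed = 3)
  # identity on earlier trials
  expect_equal(as.data.frame(rot$session$trials)[1:(at - 1), ],
               as.data.frame(res$session$trials)[1:(at - 1), ])
  pre_spk <- lapply(res$session$spikes, function(x) x[x < tr$t_delay_on[at]])
  post_spk <- lapply(rot$session$spikes, function(x) x[x < tr$t_delay_on[at]])
  expect_equal(pre_spk, post_spk)
  # preferred labels changed for goal cells
  gc <- res$truth$cells$class == "goal"
  expect_false(all(rot$truth$cells$preferred[gc] == res$truth$cells$preferred[gc]))
  expect_error(apply_rotation(res, 1000), "out of range")
  # accuracy drop then recovery, averaged over seeds
  accs <- vapply(1:25, function(sd) {
    r <- apply_rotation(res, at_trial = at, seed = sd)
    c(pre = mean(r$session$trials$correct[1:(at - 1)]),
      early = mean(r$session$trials$correct[at:(at + 14)]),
      late = mean(r$session$trials$correct[(at + 30):nrow(tr)]))
  }, c(pre = 0, early = 0, late = 0))
  expect_gt(mean(accs["pre", ]), mean(accs["early", ]))
  expect_gt(mean(accs["late", ]), mean(accs["early", ]))
})

test_that("interneurons are generated with short waveforms and high rates", {
  tr <- generate_trial_sequence(n_blocks = 1, seed = 27)
  cfg <- selectivity_config(n_cells = 5, n_interneurons = 3, tracking = FALSE,
                            seed = 27)
  s <- generate_session(tr, cfg)$session
  expect_equal(nrow(s$units), 8)
  int_units <- s$units[6:8, ]
  expect_true(all(int_units$waveform_width_ms < 0.4))
  expect_true(all(int_units$mean_rate_hz > 10))
})

test_that("config validation rejects impossible settings", {
  expect_error(selectivity_config(frac_goal_cells = 0.7, frac_start_cells = 0.5),
               "sum to at most 1")
  expect_error(selectivity_config(gain = 0.5), "gain")
  expect_error(selectivity_config(
    sync_pairs = list(list(cell_a = 1, cell_b = 2, shared_event_rate = 1,
                           jitter_sd = -1))), "jitter_sd")
})
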