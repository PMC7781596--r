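# R reference implementation of the jitter-corrected cross-covariance,
# used as the oracle for the compiled kernel
r_jitter_xcov <- function(a, b, block, n_shuffle, max_lag) {
  B <- length(a)
  xcov <- function(x, y) {
    x <- x - mean(x); y <- y - mean(y)
    vapply(-max_lag:max_lag, function(l) {
      t0 <- max(1, 1 - l); t1 <- min(B, B - l)
      sum(x[t0:t1] * y[(t0:t1) + l]) / B
    }, 0)
  }
  raw <- xcov(a, b)
  if (n_shuffle == 0) return(raw)
  acc <- 0
  for (s in seq_len(n_shuffle)) {
    pa <- a; pb <- b
    for (b0 in seq(1, B, block)) {
      i <- b0:min(B, b0 + block - 1)
      pa[i] <- pa[sample(i)]
      pb[i] <- pb[sample(i)]
    }
    acc <- acc + xcov(pa, pb)
  }
  raw - acc / n_shuffle
}

test_that("a spike train paired with itself has a large positive zero-lag scalar", {
  tr <- generate_trial_sequence(n_blocks = 2, seed = 91)
  cfg <- selectivity_config(n_cells = 2, base_rate = 5, tracking = FALSE,
                            seed = 91)
  s <- generate_session(tr, cfg)$session
  s$spikes[["2"]] <- s$spikes[["1"]]
  s$units$mean_rate_hz[2] <- s$units$mean_rate_hz[1]
  xc <- jitter_corrected_xcov(s, 1, 2, n_shuffle = 100, seed = 1)
  expect_gt(mean(xc$zero_lag), 0)
  expect_gt(mean(xc$zero_lag) / sd(xc$zero_lag) * sqrt(length(xc$zero_lag)), 5)
})

test_that("the compiled kernel agrees with the R oracle in expectation", {
  set.seed(92)
  a <- rpois(100, 2); b <- rpois(100, 2)
  # deterministic part: raw cross-covariance at zero shuffles
  cpp0 <- flexgoal:::jitter_xcov_cpp(matrix(a, 1), matrix(b, 1), 5L, 0L, 3L)
  r0 <- r_jitter_xcov(a, b, 5, 0, 3)
  expect_equal(as.vector(cpp0), r0, tolerance = 1e-12)
  # stochastic part: both corrections converge to the same mean
  set.seed(93)
  cpp1 <- flexgoal:::jitter_xcov_cpp(matrix(a, 1), matrix(b, 1), 5L, 400L, 3L)
  set.seed(94)
  r1 <- r_jitter_xcov(a, b, 5, 400, 3)
  expect_equal(as.vector(cpp1), r1, tolerance = 0.05)
})

test_that("independent pairs give corrected covariance consistent with zero", {
  tr <- generate_trial_sequence(n_blocks = 4, seed = 95)
  cfg <- selectivity_config(n_cells = 4, base_rate = 4, tracking = FALSE,
                            seed = 95)
  s <- generate_session(tr, cfg)$session
  xc <- jitter_corrected_xcov(s, 1, 2, n_shuffle = 200, seed = 2)
  m <- mean(xc$zero_lag)
  se <- sd(xc$zero_lag) / sqrt(length(xc$zero_lag))
  expect_lt(abs(m) / se, 3)
})

test_that("shared slow rate modulation is removed by the jitter correction", {
  # two cells driven by the same 1 Hz sinusoidal rate, no fast synchrony
  set.seed(96)
  s0 <- fx_manual_session(list(`1` = numeric(0), `2` = numeric(0)),
                          n_trials = 100, period = 16)
  tr <- s0$trials
  gen <- function() {
    sort(unlist(lapply(seq_len(nrow(tr)), function(i) {
      on <- tr$t_delay_on[i]
      cand <- runif(rpois(1, 12 * 3), on, on + 3)
      keep <- runif(length(cand)) < (1 + sin(2 * pi * 1 * (cand - on))) / 2
      cand[keep]
    })))
  }
  s <- fx_manual_session(list(`1` = gen(), `2` = gen()),
                         n_trials = 100, period = 16)
  xc <- jitter_corrected_xcov(s, 1, 2, n_shuffle = 200, seed = 3)
  m <- mean(xc$zero_lag); se <- sd(xc$zero_lag) / sqrt(length(xc$zero_lag))
  expect_lt(abs(m) / se, 3)
  # whereas the uncorrected covariance is clearly positive
  raw <- jitter_corrected_xcov(s, 1, 2, n_shuffle = 0, seed = 3)
  mr <- mean(raw$zero_lag); ser <- sd(raw$zero_lag) / sqrt(length(raw$zero_lag))
  expect_gt(mr / ser, 5)
})

test_that("injected fast co-spiking survives the correction", {
  tr <- generate_trial_sequence(n_blocks = 4, seed = 97)
  cfg <- selectivity_config(
    n_cells = 2, base_rate = 2, tracking = FALSE,
    sync_pairs = list(list(cell_a = 1, cell_b = 2, shared_event_rate = 2,
                           jitter_sd = 0.002, preferred_only = FALSE)),
    seed = 97)
  s <- generate_session(tr, cfg)$session
  xc <- jitter_corrected_xcov(s, 1, 2, n_shuffle = 200, seed = 4)
  m <- mean(xc$zero_lag); se <- sd(xc$zero_lag) / sqrt(length(xc$zero_lag))
  expect_gt(m / se, 4)
})

test_that("pair sign classification follows the consistency rule", {
  expect_equal(classify_pair_sign(c(0.5, 0.5), c(0.3, 0.1)), "excitatory")
  expect_equal(classify_pair_sign(c(-0.3, -0.3), c(-0.2, 0)), "inhibitory")
  expect_equal(classify_pair_sign(c(0.4, 0.2), c(-0.2, 0)), "discard")
  expect_equal(classify_pair_sign(c(0, 0), c(0.1, 0.1)), "discard")
})

test_that("candidate pairs honor shared preference", {
  p <- data.frame(cell = 1:3, preferred_goal = c(1, 1, 2))
  expect_equal(nrow(candidate_pairs(p)), 1)
  p2 <- data.frame(cell = 1:5, preferred_goal = 1)
  expect_equal(nrow(candidate_pairs(p2)), 10)  # k(k-1)/2
  p3 <- data.frame(cell = 1:3, preferred_goal = 1:3)
  expect_equal(nrow(candidate_pairs(p3)), 0)
})

test_that("goal-modulated cell selection recovers ground truth preferences", {
  res <- fx_goal_session()
  s <- res$session
  prefs <- goal_modulated_cells(s)
  truth <- res$truth$cells
  gc <- truth$unit_id[truth$class == "goal"]
  expect_gt(mean(gc %in% prefs$cell), 0.9)
  hit <- prefs[prefs$cell %in% gc, ]
  expect_equal(hit$preferred_goal,
               truth$preferred[match(hit$cell, truth$unit_id)])
  # unselective cells selected at about the alpha rate
  other <- setdiff(truth$unit_id[truth$class == "none"], gc)
  expect_lt(mean(other %in% prefs$cell), 0.25)
})

test_that("CCSI is zero for identical trial sets and antisymmetric under swap", {
  z <- rnorm(20, 0.3)
  ps <- list(list(pref = z, nonpref = z))
  cc <- ccsi(ps, n_boot = 1000, seed = 1)
  expect_equal(cc$ccsi, 0)
  set.seed(98)
  a <- rnorm(15, 0.5, 0.2); b <- rnorm(24, 0.2, 0.2)  # both-positive signs
  p1 <- list(list(pref = a, nonpref = b))
  p2 <- list(list(pref = b, nonpref = a))
  expect_equal(ccsi(p1, n_boot = 1000, seed = 7)$ccsi,
               -ccsi(p2, n_boot = 1000, seed = 7)$ccsi)
})

test_that("time-resolved CCSI window count follows the arithmetic", {
  range <- c(-2, 5); window <- 1; step <- 0.05
  starts <- seq(range[1], range[2] - window, by = step)
  expect_length(starts, floor((diff(range) - window) / step) + 1)
})

test_that("session pair stats and time-resolved CCSI run end to end", {
  tr <- generate_trial_sequence(n_blocks = 2, seed = 99)
  cfg <- selectivity_config(
    n_cells = 8, base_rate = 3, frac_goal_cells = 1, gain = 3,
    tracking = FALSE,
    sync_pairs = list(list(cell_a = 1, cell_b = 2, shared_event_rate = 3,
                           jitter_sd = 0.002, preferred_only = TRUE, goal = 1)),
    seed = 99)
  res <- generate_session(tr, cfg)
  pstats <- session_pair_stats(res$session, n_shuffle = 50, max_pairs = 4,
                               seed = 99)
  expect_lte(pstats$counts["total"], 4)
  expect_true(all(c("prefs", "pairs", "pair_stats", "counts") %in% names(pstats)))
  if (nrow(pstats$pairs) >= 1) {
    cc <- ccsi(pstats$pair_stats, n_boot = 1000, seed = 99)
    expect_true(all(cc$n_pairs >= 1))
    trc <- time_resolved_ccsi(res$session, pstats$pairs[1, , drop = FALSE],
                              window = 1, step = 0.5, range = c(-1, 2),
                              n_shuffle = 30, seed = 99)
    expect_true(all(c("t", "sign_class", "ccsi") %in% names(trc)))
    expect_lte(length(unique(trc$t)), floor((3 - 1) / 0.5) + 1)
  }
})
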