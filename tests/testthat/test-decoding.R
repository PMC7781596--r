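test_that("build_features concatenates cell x bin counts and standardizes", {
  res <- fx_start_session()
  s <- res$session
  f <- build_features(s, binwidth = 1, cells = s$units$unit_id[1:2],
                      standardize = FALSE)
  expect_equal(ncol(f$X), 6)  # 2 cells x 3 bins
  expect_equal(f$feature_cell, rep(s$units$unit_id[1:2], 3))
  fz <- build_features(s, binwidth = 1, standardize = TRUE)
  nz <- apply(fz$X, 2, sd) > 0
  expect_true(all(abs(colMeans(fz$X[, nz])) < 1e-12))
  expect_true(all(abs(apply(fz$X[, nz, drop = FALSE], 2, sd) - 1) < 1e-12))
  # sd-0 policy: constant features become all zero
  Z <- standardize_features(cbind(a = rep(2, 10), b = rnorm(10)))
  expect_true(all(Z[, 1] == 0))
})

test_that("perfectly separable features give accuracy 1 for all four classifiers", {
  set.seed(71)
  y <- rep(1:3, each = 8)
  X <- matrix(0, 24, 3)
  X[cbind(seq_len(24), y)] <- 30
  X <- X + matrix(rnorm(72, 0, 0.05), 24)
  X <- cbind(X, matrix(rnorm(24 * 27, 0, 0.3), 24))  # distractor features
  for (spec in classifier_specs()) {
    # glmnet warns about the small balanced folds (7 per class); expected here
    r <- suppressWarnings(loo_cv(X, y, spec, seed = 1,
                                 standardize_policy = "none"))
    expect_equal(r$accuracy, 1)
  }
})

test_that("training folds are balanced by subsampling the larger classes", {
  set.seed(72)
  y <- rep(1:3, c(54, 27, 27))
  X <- matrix(rnorm(108 * 5), 108)
  r <- loo_cv(X, y, classifier_specs()$lr, seed = 3)
  # in each fold the left-out trial's class loses one member before
  # balancing; the fold minimum is 26 or 27, and all classes match it
  for (i in seq_len(108)) {
    cnt <- r$fold_train_counts[i, ]
    expect_true(all(cnt == min(cnt)))
    expect_equal(unname(min(cnt)), if (y[i] %in% 2:3) 26 else 27)
  }
})

test_that("confusion-matrix bookkeeping and mean-class accuracy are consistent", {
  res <- fx_start_session()
  s <- res$session
  keep <- s$trials$correct
  f <- build_features(s, binwidth = 0.75, standardize = FALSE)
  r <- loo_cv(f$X[keep, ], s$trials$start[keep], classifier_specs()$lr, seed = 1)
  expect_equal(unname(rowSums(r$confusion)),
               unname(as.vector(table(s$trials$start[keep]))))
  expect_equal(r$accuracy, mean(diag(r$confusion) / rowSums(r$confusion)))
  expect_gt(r$accuracy, 0.85)  # start cells present
})

test_that("naive Bayes selects 10% of features within the training fold", {
  spec <- classifier_specs()$nb
  set.seed(73)
  X <- matrix(rnorm(40 * 100), 40)
  y <- rep(1:2, 20)
  model <- train_classifier(spec, X, y)
  expect_length(model$fit$sel, 10)
  # random-forest mtry covers all features (literal n), overridable
  rf <- classifier_specs()$rf
  expect_equal(rf$mtry_frac, 1)
  expect_equal(rf$num_trees, 1000)
})

test_that("specs survive a config round-trip", {
  specs <- classifier_specs()
  json <- jsonlite::toJSON(specs, auto_unbox = TRUE)
  back <- jsonlite::fromJSON(json, simplifyVector = TRUE)
  expect_equal(back, specs, ignore_attr = TRUE)
})

test_that("standardization leakage policy: global and per-fold both supported", {
  res <- fx_start_session()
  s <- res$session
  keep <- s$trials$correct
  f <- build_features(s, binwidth = 1.5, standardize = FALSE)
  rg <- loo_cv(f$X[keep, ], s$trials$start[keep], classifier_specs()$lr,
               seed = 1, standardize_policy = "global")
  rf <- loo_cv(f$X[keep, ], s$trials$start[keep], classifier_specs()$lr,
               seed = 1, standardize_policy = "fold")
  expect_gt(rg$accuracy, 0.85)
  expect_gt(rf$accuracy, 0.85)
})

test_that("nine-class decoding separates starts but not goals within start", {
  res <- fx_cache("nine_session", {
    tr <- generate_trial_sequence(n_blocks = 4, seed = 74, p_correct = 1)
    cfg <- selectivity_config(n_cells = 40, base_rate = 2,
                              frac_start_cells = 0.4, gain = 3,
                              tracking = FALSE, seed = 74)
    generate_session(tr, cfg)
  })
  s <- res$session
  r <- nine_class_decoding(s, binwidth = 1.5)
  conf <- r$confusion
  # same-start blocks: class k has start (k-1) %/% 3 + 1
  start_of <- (0:8) %/% 3 + 1
  block_mass <- sum(conf[outer(start_of, start_of, "==")]) / sum(conf)
  expect_gt(block_mass, 0.8)        # start is decodable
  expect_lt(mean(diag(conf) / rowSums(conf)), 0.6)  # goal within start is not
  # a missing combination is refused
  s2 <- s
  drop <- class_labels(s$trials, "start_x_goal") == 5
  s2$trials <- trial_table(as.data.frame(s$trials)[!drop, , drop = FALSE] |>
                             transform(index = seq_len(sum(!drop)) - 1L), 3.0)
  expect_error(nine_class_decoding(s2, binwidth = 1.5), "missing")
})

test_that("time-resolved neural decoding finds the start code during the delay", {
  res <- fx_start_session()
  acc <- time_resolved_decoding(res$session, source = "neural",
                                alignment = "delay_on", target = "start",
                                range = c(0.2, 2.2), seed = 5)
  expect_equal(nrow(acc), length(seq(0.2, 1.4, by = 0.2)))
  expect_true(all(acc$accuracy > 0.8))
  expect_true(all(acc$ci_low <= acc$accuracy & acc$accuracy <= acc$ci_high))
})

test_that("outcome decoding is calibrated on shuffled outcomes and detects signal", {
  # null: outcomes independent of activity
  res <- fx_start_session()
  s <- res$session
  r <- outcome_decoding(s, "upcoming_error", binwidth = 3)
  n <- length(r$predictions)
  band <- qbinom(c(0.025, 0.975), n, 0.5) / n
  expect_gte(r$overall_accuracy, band[1] - 2 / n)
  expect_lte(r$overall_accuracy, band[2] + 2 / n)

  # constructed signal: an "error cell" doubles its delay rate before errors
  tr <- generate_trial_sequence(n_blocks = 4, seed = 75, p_correct = 0.6)
  spikes <- lapply(1:6, function(j) {
    sort(unlist(lapply(seq_len(nrow(tr)), function(i) {
      rate <- if (!tr$correct[i]) 9 else 2
      runif(rpois(1, rate * 3), tr$t_delay_on[i], tr$t_delay_off[i])
    })))
  })
  names(spikes) <- 1:6
  units <- data.frame(unit_id = 1:6, waveform_width_ms = 0.6,
                      mean_rate_hz = vapply(spikes, length, 0L) /
                        (max(tr$t_test_goal_arrival) + 10),
                      subarea = "PL", channel_index = (1:6) * 10)
  s2 <- session(tr, units, spikes,
                meta = list(duration = max(tr$t_test_goal_arrival) + 10))
  r2 <- outcome_decoding(s2, "upcoming_error", binwidth = 3)
  expect_gt(r2$overall_accuracy, 0.8)
  # past-error target drops the first trial
  r3 <- outcome_decoding(s2, "past_error", binwidth = 3)
  expect_equal(length(r3$predictions), nrow(tr) - 1)
})

test_that("task-phase decoding supports inbound-bridge matching", {
  res <- fx_start_session()
  s <- res$session
  set.seed(76)
  bridge <- sample(1:3, nrow(s$trials), replace = TRUE)
  r <- outcome_decoding(s, "task_phase", inbound_bridge = bridge)
  expect_equal(sort(unique(r$labels)), 1:2)
  expect_equal(length(r$predictions), 2 * sum(bridge == which.max(tabulate(bridge))))
})
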