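#' Pearson correlation matrix between two PV sets
#'
#' Entry (i, j) is the Pearson correlation of row i of `A` with row j of
#' `B` across cells. Rows with zero variance yield undefined correlations;
#' these are recorded as `NA` with a warning rather than forced to 0, so
#' that silent bins cannot masquerade as decorrelated ones.
#'
#' @param A,B `fg_pv` objects (or plain matrices) over the same cell set
#'   and order.
#' @return numeric matrix `nrow(A) x nrow(B)`.
#' @export
pv_correlation_matrix <- function(A, B) {
  a <- if (inherits(A, "fg_pv")) A$values else as.matrix(A)
  b <- if (inherits(B, "fg_pv")) B$values else as.matrix(B)
  if (ncol(a) != ncol(b)) stop("PV matrices must share the cell set")
  if (inherits(A, "fg_pv") && inherits(B, "fg_pv") &&
      !identical(A$cell_ids, B$cell_ids))
    stop("PV matrices must share the cell set and order")
  va <- apply(a, 1, sd) == 0
  vb <- apply(b, 1, sd) == 0
  va[is.na(va)] <- TRUE; vb[is.na(vb)] <- TRUE
  suppressWarnings(m <- cor(t(a), t(b)))
  if (any(va) || any(vb)) {
    m[va, ] <- NA_real_
    m[, vb] <- NA_real_
    warning(sum(va) + sum(vb), " zero-variance PV row(s): correlations recorded as NA")
  }
  m
}

#' Per-goal template population vectors
#'
#' The goal template for goal g is the mean population vector over the 3 s
#' window after sample-phase goal arrival, averaged across (by default)
#' correct trials with that goal.
#'
#' @param s an `fg_session`.
#' @param cells unit ids (default all).
#' @param correct_only use correct trials only (default TRUE).
#' @param window_dur template window duration after goal arrival, seconds.
#' @return 3 x cells matrix of template rates (Hz), rows = goals 1..3.
#' @export
goal_template_pvs <- function(s, cells = NULL, correct_only = TRUE,
                              window_dur = 3) {
  if (is.null(cells)) cells <- s$units$unit_id
  keep <- if (correct_only) s$trials$correct else rep(TRUE, nrow(s$trials))
  pv <- population_vector(
    s, cbind(s$trials$t_sample_goal_arrival,
             s$trials$t_sample_goal_arrival + window_dur),
    cells, "sample_goal_arrival")
  out <- matrix(NA_real_, 3, length(cells),
                dimnames = list(paste0("goal_", 1:3), as.character(cells)))
  for (g in 1:3) {
    w <- keep & s$trials$goal == g
    if (!any(w)) stop("no usable trials for goal ", g)
    out[g, ] <- colMeans(pv$values[w, , drop = FALSE])
  }
  out
}

#' Classify one delay period from bin-template correlations
#'
#' Workhorse shared by [correlation_decode()] and exposed for direct
#' checking: given the per-bin population vectors of one delay period and
#' the class templates, correlates every bin with every template and picks
#' the winning class either by the highest bin-averaged correlation
#' (`mode = "mean"`) or by the class winning the most bins
#' (`mode = "majority"`). All-zero (zero-variance) bins cast no vote and
#' are excluded from averages. Ties break deterministically to the lowest
#' class index and are counted.
#'
#' @param bin_pvs bins x cells matrix of rates.
#' @param templates classes x cells matrix of template rates.
#' @param mode `"mean"` or `"majority"`.
#' @return list: `pred` (class index or NA), `tie` (logical).
#' @export
correlation_vote <- function(bin_pvs, templates, mode = c("mean", "majority")) {
  mode <- match.arg(mode)
  suppressWarnings(cm <- pv_correlation_matrix(bin_pvs, templates))
  ok <- rowSums(is.na(cm)) == 0
  if (!any(ok)) return(list(pred = NA_integer_, tie = FALSE))
  cm <- cm[ok, , drop = FALSE]
  if (mode == "mean") {
    sc <- colMeans(cm)
  } else {
    winners <- apply(cm, 1, which.max)  # which.max ties -> lowest index
    sc <- tabulate(winners, nbins = ncol(cm))
  }
  best <- which(sc == max(sc))
  list(pred = best[1], tie = length(best) > 1)
}

#' Correlation-based delay-period decoder
#'
#' Decodes the remembered goal (or the current start location) of each delay
#' period by correlating time-binned delay population vectors with class
#' template PVs. Goal templates are sample-phase goal-arrival PVs
#' ([goal_template_pvs()]); start templates are full-delay PVs averaged per
#' start with the decoded trial excluded from its own template. Accuracy is
#' reported over correct trials.
#'
#' @param s an `fg_session`.
#' @param target `"goal"` or `"start"`.
#' @param binwidth delay bin width, seconds. The canonical grids are
#'   0.375/0.75/1.5/3 s for 3.0 s delays and 0.4/0.8/1.6/3.2 s for 3.2 s
#'   delays; any positive width that fits the delay is accepted.
#' @param mode `"mean"` or `"majority"`, see [correlation_vote()].
#' @param cells unit ids (default all).
#' @param correct_only restrict templates and accuracy to correct trials.
#' @param n_boot,seed bootstrap-CI settings.
#' @return object of class `fg_corr_decode`: list with `predictions`,
#'   `accuracy`, `class_accuracy`, `ci`, `n_ties`, `mode`, `binwidth`.
#' @export
correlation_decode <- function(s, target = c("goal", "start"), binwidth = 0.375,
                               mode = c("mean", "majority"), cells = NULL,
                               correct_only = TRUE, n_boot = 2000, seed = 1) {
  target <- match.arg(target); mode <- match.arg(mode)
  if (is.null(cells)) cells <- s$units$unit_id
  dd <- attr(s$trials, "delay_duration")
  if (binwidth <= 0 || binwidth > dd + 1e-9)
    stop("binwidth must be in (0, ", dd, "] s")
  n <- nrow(s$trials)
  counts <- bin_aligned_counts(s, s$trials$t_delay_on, c(0, dd), binwidth, cells)
  keep <- if (correct_only) s$trials$correct else rep(TRUE, n)

  if (target == "goal") {
    templates <- goal_template_pvs(s, cells, correct_only = correct_only)
    labels <- s$trials$goal
  } else {
    delay_pv <- population_vector(
      s, cbind(s$trials$t_delay_on, s$trials$t_delay_off), cells, "delay")$values
    labels <- s$trials$start
  }

  pred <- rep(NA_integer_, n); tie <- logical(n)
  for (i in seq_len(n)) {
    bins <- t(matrix(counts[i, , ], nrow = dim(counts)[2])) / binwidth  # bins x cells
    if (target == "start") {
      templates <- matrix(NA_real_, 3, length(cells))
      for (st in 1:3) {
        w <- keep & s$trials$start == st
        w[i] <- FALSE  # exclude the decoded trial from its own template
        if (!any(w)) stop("no template trials for start ", st)
        templates[st, ] <- colMeans(delay_pv[w, , drop = FALSE])
      }
    }
    v <- correlation_vote(bins, templates, mode)
    pred[i] <- v$pred; tie[i] <- v$tie
  }
  flags <- (pred == labels)[keep & !is.na(pred)]
  cls_acc <- vapply(1:3, function(k) {
    w <- keep & !is.na(pred) & labels == k
    if (!any(w)) NA_real_ else mean(pred[w] == k)
  }, 0)
  structure(list(predictions = pred, labels = labels,
                 accuracy = mean(flags), class_accuracy = cls_acc,
                 mean_class_accuracy = mean(cls_acc, na.rm = TRUE),
                 ci = bootstrap_accuracy_ci(flags, n_boot = n_boot, seed = seed),
                 n_ties = sum(tie), n_undecidable = sum(is.na(pred)),
                 mode = mode, binwidth = binwidth, target = target),
            class = "fg_corr_decode")
}

#' Percentile bootstrap CI for a decoding accuracy
#'
#' Draws `n_boot` resamples (with replacement) of the per-trial correctness
#' flags and returns the 2.5 and 97.5 percentiles of the resampled means.
#'
#' @param correct_flags logical vector of per-trial outcomes.
#' @param n_boot number of resamples, 1000-10000.
#' @param seed RNG seed.
#' @return numeric `c(low, high)`.
#' @export
bootstrap_accuracy_ci <- function(correct_flags, n_boot = 2000, seed = 1) {
  stopifnot(length(correct_flags) >= 1)
  if (n_boot < 1000 || n_boot > 10000) stop("n_boot must be in [1000, 10000]")
  set.seed(derive_seed(seed, "boot_ci"))
  m <- matrix(sample(correct_flags, length(correct_flags) * n_boot, replace = TRUE),
              nrow = n_boot)
  unname(quantile(rowMeans(m), c(0.025, 0.975)))
}

#' Cross-phase goal decoding
#'
#' Trains a goal classifier on one task phase's goal-arrival population
#' vectors and tests it on the other phase's (and vice versa), probing
#' whether the goal code generalizes between sample and test phases.
#'
#' @param s an `fg_session`.
#' @param cells unit ids (default all).
#' @param window_dur goal-arrival window, seconds.
#' @param spec classifier spec (default L2 logistic regression).
#' @return list with `sample_to_test` and `test_to_sample` mean class
#'   accuracies.
#' @export
goal_phase_cross_decoding <- function(s, cells = NULL, window_dur = 3,
                                      spec = classifier_specs()$lr) {
  if (is.null(cells)) cells <- s$units$unit_id
  keep <- s$trials$correct
  if (!any(keep)) stop("no correct trials")
  Xs <- population_vector(s, cbind(s$trials$t_sample_goal_arrival,
                                   s$trials$t_sample_goal_arrival + window_dur),
                          cells)$values[keep, , drop = FALSE]
  Xt <- population_vector(s, cbind(s$trials$t_test_goal_arrival,
                                   s$trials$t_test_goal_arrival + window_dur),
                          cells)$values[keep, , drop = FALSE]
  y <- s$trials$goal[keep]
  one_way <- function(Xtr, Xte) {
    z <- standardize_features(rbind(Xtr, Xte))
    ntr <- nrow(Xtr)
    fit <- train_classifier(spec, z[1:ntr, , drop = FALSE], y)
    p <- predict_classifier(fit, z[-(1:ntr), , drop = FALSE])
    mean(vapply(sort(unique(y)), function(k) mean(p[y == k] == k), 0))
  }
  list(sample_to_test = one_way(Xs, Xt), test_to_sample = one_way(Xt, Xs))
}
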