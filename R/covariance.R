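#' Goal-modulated cells and their preferred goal
#'
#' Cells significantly modulated at the sample goal location: a
#' Kruskal-Wallis test across the three goals on goal-arrival firing rates
#' (3 s after sample-phase goal arrival, correct trials) at level `alpha`.
#' The preferred goal is the one with the highest mean rate; argmax ties
#' resolve to the lowest goal index and are counted.
#'
#' @param s an `fg_session`.
#' @param cells unit ids (default all).
#' @param alpha significance level (default 0.05).
#' @param correct_only use correct trials only.
#' @return data.frame `(cell, preferred_goal, p, tie)` for selected cells.
#' @export
goal_modulated_cells <- function(s, cells = NULL, alpha = 0.05,
                                 correct_only = TRUE) {
  if (is.null(cells)) cells <- s$units$unit_id
  keep <- if (correct_only) s$trials$correct else rep(TRUE, nrow(s$trials))
  pv <- population_vector(
    s, cbind(s$trials$t_sample_goal_arrival, s$trials$t_sample_goal_arrival + 3),
    cells)$values[keep, , drop = FALSE]
  g <- s$trials$goal[keep]
  out <- lapply(seq_along(cells), function(j) {
    kw <- kruskal_wallis_h(split(pv[, j], g))
    if (kw$p > alpha) return(NULL)
    m <- vapply(1:3, function(k) mean(pv[g == k, j]), 0)
    best <- which(m == max(m))
    data.frame(cell = cells[j], preferred_goal = best[1], p = kw$p,
               tie = length(best) > 1)
  })
  res <- do.call(rbind, out)
  if (is.null(res))
    res <- data.frame(cell = integer(0), preferred_goal = integer(0),
                      p = numeric(0), tie = logical(0))
  res
}

#' Same-preference cell pairs
#'
#' All unordered pairs of cells sharing the same preferred goal location.
#'
#' @param prefs data.frame from [goal_modulated_cells()].
#' @return data.frame `(cell_a, cell_b, preferred_goal)` (0 rows when no
#'   preference is shared).
#' @export
candidate_pairs <- function(prefs) {
  out <- list()
  for (g in sort(unique(prefs$preferred_goal))) {
    cl <- sort(prefs$cell[prefs$preferred_goal == g])
    if (length(cl) < 2) next
    cmb <- utils::combn(cl, 2)
    out[[length(out) + 1]] <- data.frame(cell_a = cmb[1, ], cell_b = cmb[2, ],
                                         preferred_goal = g)
  }
  if (!length(out))
    return(data.frame(cell_a = integer(0), cell_b = integer(0),
                      preferred_goal = integer(0)))
  do.call(rbind, out)
}

#' Jitter-corrected cross-covariance of a cell pair
#'
#' Spikes of both cells are binned at `binwidth` within each trial window;
#' for each of `n_shuffle` surrogates the bins of each cell are permuted
#' independently within consecutive blocks of `jitter` seconds, and the
#' mean surrogate cross-covariance is subtracted from the raw one per
#' trial, cancelling covariance from co-modulation slower than the block.
#' The zero-lag scalar is the mean of the three lag bins around lag 0.
#'
#' @param s an `fg_session`.
#' @param cell_a,cell_b unit ids.
#' @param windows per-trial windows (n x 2 matrix of absolute seconds);
#'   default the delay periods. Must be at least 0.5 s long.
#' @param binwidth count bin, seconds (default 0.010).
#' @param jitter shuffle block length, seconds (default 0.050).
#' @param n_shuffle number of surrogates (default 1000).
#' @param max_lag maximum lag in bins for the returned trace (default 10).
#' @param seed RNG seed for the surrogate permutations.
#' @return list of class `fg_xcov`: `lags` (seconds), `xcov` (trials x
#'   lags corrected covariance), `zero_lag` (per-trial scalar).
#' @export
jitter_corrected_xcov <- function(s, cell_a, cell_b, windows = NULL,
                                  binwidth = 0.010, jitter = 0.050,
                                  n_shuffle = 1000, max_lag = 10, seed = 1) {
  if (is.null(windows))
    windows <- cbind(s$trials$t_delay_on, s$trials$t_delay_off)
  windows <- as.matrix(windows)
  if (any(windows[, 2] - windows[, 1] < 0.5))
    stop("windows must be at least 0.5 s long")
  dur <- windows[1, 2] - windows[1, 1]
  cnt <- bin_aligned_counts(s, windows[, 1], c(0, dur), binwidth,
                            cells = c(cell_a, cell_b))
  a <- matrix(cnt[, 1, ], nrow = nrow(windows))
  b <- matrix(cnt[, 2, ], nrow = nrow(windows))
  block <- max(1L, round(jitter / binwidth))
  set.seed(derive_seed(seed, "jitter"))
  xc <- jitter_xcov_cpp(a, b, block, n_shuffle, max_lag)
  zl <- rowMeans(xc[, max_lag + (0:2), drop = FALSE])
  structure(list(lags = (-max_lag:max_lag) * binwidth, xcov = xc,
                 zero_lag = zl, binwidth = binwidth, jitter = jitter,
                 n_shuffle = n_shuffle), class = "fg_xcov")
}

#' Sign-consistency classification of a pair
#'
#' A pair is excitatory when its mean corrected zero-lag covariance is
#' positive in both preferred and non-preferred trials, inhibitory when
#' negative in both, and discarded when the signs disagree (or either mean
#' is exactly zero).
#'
#' @param zero_pref,zero_nonpref per-trial zero-lag scalars in preferred
#'   and non-preferred trials.
#' @return `"excitatory"`, `"inhibitory"` or `"discard"`.
#' @export
classify_pair_sign <- function(zero_pref, zero_nonpref) {
  mp <- mean(zero_pref); mn <- mean(zero_nonpref)
  if (mp > 0 && mn > 0) return("excitatory")
  if (mp < 0 && mn < 0) return("inhibitory")
  "discard"
}

#' Cross-correlation selectivity index (CCSI)
#'
#' Per pair, the preferred and non-preferred trial sets are matched in size
#' by a seeded random subsample of the larger set, drawn once per pair. The
#' pair's contribution is the mean corrected zero-lag covariance difference
#' (preferred minus non-preferred) over the matched sets, and -- by default
#' -- the pair's sign class is classified from the same matched sets, which
#' keeps the class-conditioned index exactly unbiased under exchangeable
#' trials (classifying the sign from the unmatched sets while differencing
#' matched ones leaves a selection bias in the null). The CCSI of a sign
#' class is the mean over its pairs, with a percentile bootstrap CI over
#' pairs.
#'
#' @param pair_stats list over pairs: each element a list with `pref`
#'   (per-trial zero-lag scalars, preferred trials), `nonpref`, and
#'   optionally `sign_class`.
#' @param n_boot bootstrap replicates over pairs.
#' @param seed RNG seed for the matching subsamples and the bootstrap.
#' @param match_sign classify signs from the matched sets (default TRUE);
#'   when FALSE the supplied `sign_class` elements are used.
#' @return data.frame `(sign_class, n_pairs, ccsi, ci_low, ci_high)` with
#'   one row per non-empty sign class.
#' @export
ccsi <- function(pair_stats, n_boot = 1000, seed = 1, match_sign = TRUE) {
  # one matched subsample per pair, keyed by vector length so that
  # swapping preferred/non-preferred flips the index sign exactly
  matched <- lapply(seq_along(pair_stats), function(i) {
    p <- pair_stats[[i]]
    m <- min(length(p$pref), length(p$nonpref))
    sub <- function(x) {
      if (length(x) <= m) return(x)
      set.seed(derive_seed(seed, paste0("pair", i, "_n", length(x))))
      sample(x, m)
    }
    list(pref = sub(p$pref), nonpref = sub(p$nonpref))
  })
  cls <- if (match_sign)
    vapply(matched, function(p) classify_pair_sign(p$pref, p$nonpref), "")
  else vapply(pair_stats, function(p) p$sign_class, "")
  contrib <- vapply(matched, function(p) mean(p$pref) - mean(p$nonpref), 0)
  out <- list()
  for (sc in c("excitatory", "inhibitory")) {
    ct <- contrib[cls == sc]
    if (!length(ct)) next
    set.seed(derive_seed(seed, paste0(sc, "_boot")))
    bs <- vapply(seq_len(n_boot), function(r)
      mean(ct[sample.int(length(ct), replace = TRUE)]), 0)
    out[[sc]] <- data.frame(sign_class = sc, n_pairs = length(ct),
                            ccsi = mean(ct),
                            ci_low = unname(quantile(bs, 0.025)),
                            ci_high = unname(quantile(bs, 0.975)))
  }
  if (!length(out))
    return(data.frame(sign_class = character(0), n_pairs = integer(0),
                      ccsi = numeric(0), ci_low = numeric(0),
                      ci_high = numeric(0)))
  do.call(rbind, out)
}

#' Pair statistics for a session
#'
#' Convenience wrapper running the full covariance pipeline: select
#' goal-modulated cells, form same-preference pairs, compute per-trial
#' corrected zero-lag covariances in the delay window, classify pair signs
#' and return the structures consumed by [ccsi()].
#'
#' @param s an `fg_session`.
#' @param cells candidate unit ids (default all).
#' @param windows per-trial windows; default delay periods.
#' @param correct_only use correct trials only.
#' @param max_pairs optional cap on the number of pairs (first pairs kept)
#'   to bound compute.
#' @inheritParams jitter_corrected_xcov
#' @return list: `prefs`, `pairs`, `pair_stats` (input to [ccsi()]),
#'   `counts` (total / excitatory / inhibitory pair bookkeeping).
#' @export
session_pair_stats <- function(s, cells = NULL, windows = NULL,
                               correct_only = TRUE, binwidth = 0.010,
                               jitter = 0.050, n_shuffle = 1000,
                               max_pairs = Inf, seed = 1) {
  prefs <- goal_modulated_cells(s, cells, correct_only = correct_only)
  pairs <- candidate_pairs(prefs)
  if (nrow(pairs) > max_pairs) pairs <- pairs[seq_len(max_pairs), ]
  keep <- if (correct_only) s$trials$correct else rep(TRUE, nrow(s$trials))
  stats <- vector("list", nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    xc <- jitter_corrected_xcov(s, pairs$cell_a[i], pairs$cell_b[i],
                                windows = windows, binwidth = binwidth,
                                jitter = jitter, n_shuffle = n_shuffle,
                                max_lag = 2, seed = seed + i)
    pref <- keep & s$trials$goal == pairs$preferred_goal[i]
    nonpref <- keep & !pref
    zp <- xc$zero_lag[pref]; zn <- xc$zero_lag[nonpref]
    stats[[i]] <- list(cell_a = pairs$cell_a[i], cell_b = pairs$cell_b[i],
                       preferred_goal = pairs$preferred_goal[i],
                       sign_class = classify_pair_sign(zp, zn),
                       pref = zp, nonpref = zn)
  }
  cls <- vapply(stats, function(p) p$sign_class, "")
  list(prefs = prefs, pairs = pairs, pair_stats = stats,
       counts = c(total = nrow(pairs),
                  excitatory = sum(cls == "excitatory"),
                  inhibitory = sum(cls == "inhibitory")))
}

#' Time-resolved CCSI
#'
#' Recomputes the CCSI in sliding windows around delay onset. Pair signs
#' are classified once from the extended window (the whole `range`), as in
#' the time-resolved variant of the source analysis.
#'
#' @param s an `fg_session`.
#' @param pairs data.frame from [candidate_pairs()].
#' @param window sliding window length, seconds (default 1).
#' @param step window step, seconds (default 0.050).
#' @param range window range around delay onset, seconds (default -2..5).
#' @param correct_only use correct trials only.
#' @inheritParams jitter_corrected_xcov
#' @param n_boot,ccsi_seed bootstrap settings passed to [ccsi()].
#' @return data.frame `(t, sign_class, n_pairs, ccsi, ci_low, ci_high)`;
#'   `t` is the window center relative to delay onset.
#' @export
time_resolved_ccsi <- function(s, pairs, window = 1, step = 0.050,
                               range = c(-2, 5), correct_only = TRUE,
                               binwidth = 0.010, jitter = 0.050,
                               n_shuffle = 100, seed = 1, n_boot = 1000,
                               ccsi_seed = 1) {
  keep <- if (correct_only) s$trials$correct else rep(TRUE, nrow(s$trials))
  ev <- s$trials$t_delay_on
  # extended-window sign classification
  sign_class <- character(nrow(pairs))
  for (i in seq_len(nrow(pairs))) {
    xc <- jitter_corrected_xcov(s, pairs$cell_a[i], pairs$cell_b[i],
                                windows = cbind(ev + range[1], ev + range[2]),
                                binwidth = binwidth, jitter = jitter,
                                n_shuffle = n_shuffle, max_lag = 2,
                                seed = seed + i)
    pref <- keep & s$trials$goal == pairs$preferred_goal[i]
    sign_class[i] <- classify_pair_sign(xc$zero_lag[pref],
                                        xc$zero_lag[keep & !pref])
  }
  starts <- seq(range[1], range[2] - window, by = step)
  out <- list()
  for (t0 in starts) {
    stats <- vector("list", nrow(pairs))
    for (i in seq_len(nrow(pairs))) {
      xc <- jitter_corrected_xcov(s, pairs$cell_a[i], pairs$cell_b[i],
                                  windows = cbind(ev + t0, ev + t0 + window),
                                  binwidth = binwidth, jitter = jitter,
                                  n_shuffle = n_shuffle, max_lag = 2,
                                  seed = seed + i)
      pref <- keep & s$trials$goal == pairs$preferred_goal[i]
      stats[[i]] <- list(sign_class = sign_class[i],
                         pref = xc$zero_lag[pref],
                         nonpref = xc$zero_lag[keep & !pref])
    }
    cc <- ccsi(stats, n_boot = n_boot, seed = ccsi_seed)
    if (nrow(cc)) { cc$t <- t0 + window / 2; out[[length(out) + 1]] <- cc }
  }
  res <- do.call(rbind, out)
  res[, c("t", "sign_class", "n_pairs", "ccsi", "ci_low", "ci_high")]
}
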