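#' Kruskal-Wallis H with tie correction
#'
#' Rank-based one-way test comparing spike-count distributions across
#' classes. Returns the tie-corrected H statistic and a chi-square p-value
#' with k-1 degrees of freedom. When every observation is identical the tie
#' correction degenerates; this is defined as H = 0, p = 1.
#'
#' @param groups list of numeric vectors, one per class (>= 2 non-empty
#'   groups).
#' @return list with `H` and `p`.
#' @export
kruskal_wallis_h <- function(groups) {
  if (length(groups) < 2 || any(!lengths(groups)))
    stop("need at least 2 non-empty groups")
  x <- unlist(groups, use.names = FALSE)
  g <- rep(seq_along(groups), lengths(groups))
  N <- length(x)
  if (length(unique(x)) == 1) return(list(H = 0, p = 1))
  r <- rank(x)
  R <- vapply(split(r, g), sum, 0)
  H <- 12 / (N * (N + 1)) * sum(R^2 / lengths(groups)) - 3 * (N + 1)
  ties <- table(x)
  H <- H / (1 - sum(ties^3 - ties) / (N^3 - N))
  list(H = H, p = stats::pchisq(H, length(groups) - 1, lower.tail = FALSE))
}

# vectorized Kruskal-Wallis over the columns of a matrix (features), shared
# group labels; used by the screen and by per-fold feature scoring.
kw_h_matrix <- function(X, g) {
  g <- as.integer(factor(g))
  k <- max(g)
  N <- nrow(X)
  ng <- tabulate(g, k)
  H <- numeric(ncol(X))
  for (j in seq_len(ncol(X))) {
    x <- X[, j]
    if (length(unique(x)) == 1) { H[j] <- 0; next }
    r <- rank(x)
    R <- vapply(seq_len(k), function(kk) sum(r[g == kk]), 0)
    h <- 12 / (N * (N + 1)) * sum(R^2 / ng) - 3 * (N + 1)
    ties <- table(x)
    H[j] <- h / (1 - sum(ties^3 - ties) / (N^3 - N))
  }
  list(H = H, p = stats::pchisq(H, k - 1, lower.tail = FALSE), df = k - 1)
}

#' Benjamini-Hochberg step-up FDR mask
#'
#' Returns the significance mask of the BH step-up procedure at level
#' `alpha`: with ordered p-values p(1) <= ... <= p(m), all hypotheses up to
#' the largest k with p(k) <= k * alpha / m are rejected.
#'
#' @param pvalues numeric vector in `[0, 1]`.
#' @param alpha FDR level.
#' @return logical mask aligned with `pvalues` (empty input gives an empty
#'   mask).
#' @export
fdr_bh <- function(pvalues, alpha = 0.05) {
  m <- length(pvalues)
  if (m == 0) return(logical(0))
  if (any(pvalues < 0 | pvalues > 1, na.rm = TRUE)) stop("p-values must be in [0, 1]")
  o <- order(pvalues)
  ok <- which(pvalues[o] <= seq_len(m) * alpha / m)
  mask <- logical(m)
  if (length(ok)) mask[o[seq_len(max(ok))]] <- TRUE
  mask
}

#' Single-cell selectivity screen (H-score analysis)
#'
#' For each binwidth, delay-period spikes are binned and each (cell, bin)
#' pair is treated as one feature whose spike-count distribution is compared
#' across trial classes with the Kruskal-Wallis test; Benjamini-Hochberg
#' FDR correction is applied separately within each binwidth.
#'
#' @param s an `fg_session`.
#' @param scheme class scheme, see [class_labels()].
#' @param binwidths bin widths in seconds; the default grid doubles from
#'   0.1 s (clipped to the delay) up to the full delay duration.
#' @param cells unit ids (default all).
#' @param alpha FDR level.
#' @param correct_only use correct trials only.
#' @param ego_convention passed to [class_labels()].
#' @return data.frame of class `fg_hscore`: one row per
#'   (cell, bin, binwidth) with `H`, `p`, `significant`.
#' @export
hscore_screen <- function(s, scheme = "goal", binwidths = NULL, cells = NULL,
                          alpha = 0.05, correct_only = TRUE,
                          ego_convention = c(behind = 1, left = 2, right = 3)) {
  if (is.null(cells)) cells <- s$units$unit_id
  dd <- attr(s$trials, "delay_duration")
  if (is.null(binwidths)) {
    binwidths <- 0.1 * 2^(0:ceiling(log2(dd / 0.1)))
    binwidths <- c(binwidths[binwidths < dd], dd)
  }
  keep <- if (correct_only) s$trials$correct else rep(TRUE, nrow(s$trials))
  lab <- class_labels(s$trials, scheme, ego_convention)[keep]
  out <- vector("list", length(binwidths))
  for (bi in seq_along(binwidths)) {
    bw <- binwidths[bi]
    cnt <- bin_aligned_counts(s, s$trials$t_delay_on[keep], c(0, dd), bw, cells)
    nb <- dim(cnt)[3]
    X <- matrix(cnt, nrow = dim(cnt)[1])  # trials x (cells*bins), cell-major
    kw <- kw_h_matrix(X, lab)
    out[[bi]] <- data.frame(
      cell = rep(cells, times = nb), bin = rep(seq_len(nb), each = length(cells)),
      binwidth = bw, H = kw$H, p = kw$p, significant = fdr_bh(kw$p, alpha))
  }
  res <- do.call(rbind, out)
  class(res) <- c("fg_hscore", "data.frame")
  res
}
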