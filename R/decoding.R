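#' Build a trial-by-feature tensor from binned delay activity
#'
#' Bins each trial's window at `binwidth` and concatenates all bins of all
#' cells into one feature vector per trial (each cell x bin is a separate
#' feature, referenced to window onset). Optionally standardizes each
#' feature over all trials (mean 0, SD 1); zero-variance features are set
#' to all-0 rather than NaN.
#'
#' @param s an `fg_session`.
#' @param windows per-trial absolute windows (n x 2 matrix), or a length-2
#'   window relative to delay onset applied to every trial (default the
#'   full delay).
#' @param binwidth bin width, seconds.
#' @param cells unit ids (default all).
#' @param standardize standardize features over trials (default TRUE).
#' @return list of class `fg_features`: `X` (trials x features),
#'   `feature_cell`, `feature_bin`, `center`, `scale`.
#' @export
build_features <- function(s, windows = NULL, binwidth = 0.375, cells = NULL,
                           standardize = TRUE) {
  if (is.null(cells)) cells <- s$units$unit_id
  dd <- attr(s$trials, "delay_duration")
  if (is.null(windows)) windows <- c(0, dd)
  if (is.vector(windows) && length(windows) == 2) {
    events <- s$trials$t_delay_on
    win <- windows
  } else {
    windows <- as.matrix(windows)
    events <- windows[, 1]
    win <- c(0, windows[1, 2] - windows[1, 1])
  }
  cnt <- bin_aligned_counts(s, events, win, binwidth, cells)
  nb <- dim(cnt)[3]
  X <- matrix(as.numeric(cnt), nrow = dim(cnt)[1])
  fc <- rep(cells, times = nb); fb <- rep(seq_len(nb), each = length(cells))
  ctr <- rep(0, ncol(X)); scl <- rep(1, ncol(X))
  if (standardize) {
    z <- standardize_features(X)
    X <- z; ctr <- attr(z, "center"); scl <- attr(z, "scale")
  }
  structure(list(X = X, feature_cell = fc, feature_bin = fb,
                 center = ctr, scale = scl, binwidth = binwidth),
            class = "fg_features")
}

standardize_features <- function(X) {
  ctr <- colMeans(X)
  scl <- apply(X, 2, sd)
  z <- sweep(X, 2, ctr)
  nz <- scl > 0
  z[, nz] <- sweep(z[, nz, drop = FALSE], 2, scl[nz], "/")
  z[, !nz] <- 0  # sd-0 policy: constant features carry no signal
  attr(z, "center") <- ctr; attr(z, "scale") <- ifelse(nz, scl, 1)
  z
}

#' The four fixed classifier specifications
#'
#' Hyperparameter bundles for the four classifier families used throughout:
#' \describe{
#'   \item{lr}{multinomial logistic regression with L2 (ridge) penalty;
#'     `lambda` is the glmnet penalty (default 0.01).}
#'   \item{svm}{support vector machine, Gaussian (RBF) kernel with kernel
#'     coefficient `gamma = 0.001` and L2-regularized hinge loss
#'     (`cost = 1`).}
#'   \item{rf}{random forest of 1000 trees; the number of candidate split
#'     features is n, the total number of features (`mtry_frac = 1`,
#'     overridable -- the conventional default in the field would be
#'     sqrt(n)).}
#'   \item{nb}{Gaussian naive Bayes on the 10\% of features with the
#'     highest Kruskal-Wallis H-scores, selected within each training fold
#'     (leakage-safe).}
#' }
#'
#' @return named list of classifier specs.
#' @export
classifier_specs <- function() {
  list(lr = list(method = "lr", lambda = 0.01),
       svm = list(method = "svm", gamma = 0.001, cost = 1),
       rf = list(method = "rf", num_trees = 1000, mtry_frac = 1),
       nb = list(method = "nb", feature_frac = 0.1))
}

train_classifier <- function(spec, X, y) {
  y <- factor(y)
  if (nlevels(droplevels(y)) < 2) stop("degenerate single-class training set")
  pad <- spec$method == "lr" && ncol(X) < 2  # glmnet needs >= 2 columns
  if (pad) X <- cbind(X, 0)
  fit <- switch(spec$method,
    lr = {
      fam <- if (nlevels(y) > 2) "multinomial" else "binomial"
      # fit a short descending path ending at the target lambda; a
      # single-value path is numerically brittle in glmnet
      glmnet::glmnet(X, y, family = fam, alpha = 0,
                     lambda = spec$lambda * c(100, 10, 1),
                     standardize = FALSE)
    },
    svm = e1071::svm(X, y, kernel = "radial", gamma = spec$gamma,
                     cost = spec$cost, scale = FALSE),
    rf = ranger::ranger(x = as.data.frame(X), y = y,
                        num.trees = spec$num_trees,
                        mtry = max(1, floor(spec$mtry_frac * ncol(X))),
                        num.threads = 1),
    nb = {
      H <- kw_h_matrix(X, y)$H
      k <- max(1, round(spec$feature_frac * ncol(X)))
      sel <- order(H, decreasing = TRUE)[seq_len(k)]
      list(nb = e1071::naiveBayes(X[, sel, drop = FALSE], y), sel = sel)
    },
    stop("unknown classifier method ", spec$method))
  list(spec = spec, fit = fit, levels = levels(y), pad = pad)
}

predict_classifier <- function(model, X) {
  spec <- model$spec
  if (isTRUE(model$pad)) X <- cbind(X, 0)
  p <- switch(spec$method,
    lr = as.character(as.vector(predict(model$fit, X, type = "class",
                                        s = spec$lambda))),
    svm = as.character(predict(model$fit, X)),
    rf = as.character(predict(model$fit,
                              data = as.data.frame(X))$predictions),
    nb = as.character(predict(model$fit$nb,
                              X[, model$fit$sel, drop = FALSE],
                              eps = 1e-9, threshold = 1e-9)))
  as.integer(p)
}

#' Leave-one-out cross-validated decoding with class balancing
#'
#' Each trial is predicted by a classifier trained on all other trials.
#' Within every training fold the class counts are balanced by randomly
#' subsampling the larger classes down to the smallest count (per-fold
#' seeded RNG). Feature standardization follows the `standardize_policy`:
#' `"global"` standardizes over all trials before cross-validation (the
#' default, matching common practice in the source analyses), `"fold"`
#' recomputes mean/SD on each training fold only (strictly leakage-free).
#' The naive-Bayes feature selection is always computed within the fold.
#'
#' @param X trials x features numeric matrix (raw counts; standardization
#'   is handled here according to the policy).
#' @param labels integer class labels.
#' @param spec a classifier spec from [classifier_specs()].
#' @param seed master seed for the per-fold subsampling.
#' @param standardize_policy `"global"`, `"fold"` or `"none"` (features
#'   used as supplied).
#' @param balance balance training classes (default TRUE).
#' @param n_boot bootstrap replicates for the accuracy CI.
#' @return object of class `fg_decoding`: `predictions`, `confusion`
#'   (rows = true class), `class_accuracy`, `accuracy` (mean over classes),
#'   `ci`, `spec`.
#' @export
loo_cv <- function(X, labels, spec = classifier_specs()$lr, seed = 1,
                   standardize_policy = c("global", "fold", "none"), balance = TRUE,
                   n_boot = 2000) {
  standardize_policy <- match.arg(standardize_policy)
  X <- as.matrix(X)
  labels <- as.integer(labels)
  lev <- sort(unique(labels))
  if (length(lev) < 2) stop("need at least 2 classes")
  n <- nrow(X)
  if (standardize_policy == "global") X <- standardize_features(X)
  pred <- integer(n)
  fold_counts <- matrix(0L, n, length(lev),
                        dimnames = list(NULL, as.character(lev)))
  for (i in seq_len(n)) {
    Xtr <- X[-i, , drop = FALSE]; ytr <- labels[-i]
    Xte <- X[i, , drop = FALSE]
    if (standardize_policy == "fold") {
      z <- standardize_features(Xtr)
      Xte <- sweep(sweep(Xte, 2, attr(z, "center")), 2, attr(z, "scale"), "/")
      Xtr <- z
    }
    if (balance) {
      set.seed(derive_seed(seed, paste0("fold", i)))
      m <- min(table(ytr))
      keep <- unlist(lapply(lev, function(k) {
        w <- which(ytr == k)
        if (length(w) > m) sample(w, m) else w
      }))
      Xtr <- Xtr[keep, , drop = FALSE]; ytr <- ytr[keep]
    }
    fold_counts[i, ] <- tabulate(match(ytr, lev), length(lev))
    model <- train_classifier(spec, Xtr, ytr)
    pred[i] <- predict_classifier(model, Xte)
  }
  res <- decoding_result(pred, labels, spec, seed, n_boot)
  res$fold_train_counts <- fold_counts
  res
}

decoding_result <- function(pred, labels, spec, seed, n_boot = 2000) {
  lev <- sort(unique(labels))
  conf <- table(factor(labels, lev), factor(pred, lev))
  cls_acc <- vapply(lev, function(k) mean(pred[labels == k] == k), 0)
  flags <- pred == labels
  structure(list(predictions = pred, labels = labels,
                 confusion = unclass(conf), class_accuracy = cls_acc,
                 accuracy = mean(cls_acc),
                 overall_accuracy = mean(flags),
                 ci = bootstrap_accuracy_ci(flags, n_boot = n_boot, seed = seed),
                 spec = spec), class = "fg_decoding")
}

#' @exportS3Method base::print
print.fg_decoding <- function(x, ...) {
  cat("fg_decoding (", x$spec$method, "): mean class accuracy ",
      round(x$accuracy, 3), " [", round(x$ci[1], 3), ", ",
      round(x$ci[2], 3), "]\n", sep = "")
  invisible(x)
}

#' Nine-class (start x goal) delay decoding
#'
#' LOO-CV decoding of the conjunction of current start and remembered goal
#' (9 classes) from binned delay activity. A pure start code yields
#' confusion mass concentrated in same-start 3 x 3 blocks with near-uniform
#' rows within a block; a conjunctive code yields a dominant diagonal.
#'
#' @param s an `fg_session`.
#' @param binwidth bin width, seconds.
#' @param spec classifier spec.
#' @param cells unit ids.
#' @param correct_only use correct trials only.
#' @param seed RNG seed.
#' @return an `fg_decoding` with a 9 x 9 confusion matrix.
#' @export
nine_class_decoding <- function(s, binwidth = 0.375, spec = classifier_specs()$lr,
                                cells = NULL, correct_only = TRUE, seed = 1) {
  keep <- if (correct_only) s$trials$correct else rep(TRUE, nrow(s$trials))
  lab <- class_labels(s$trials, "start_x_goal")[keep]
  missing <- setdiff(1:9, lab)
  if (length(missing))
    stop("missing (start,goal) combination(s): ", paste(missing, collapse = ", "))
  f <- build_features(s, binwidth = binwidth, cells = cells, standardize = FALSE)
  loo_cv(f$X[keep, , drop = FALSE], lab, spec, seed = seed)
}

#' Time-resolved decoding from neural or tracking data
#'
#' Slides a decoding window along trials aligned to one of the five task
#' events and reports the LOO-CV accuracy per window. Neural features are
#' spike counts in 800 ms windows of 200 ms bins stepped by 200 ms;
#' tracking features are the two LED coordinates interpolated at 10 equal
#' offsets inside a 330 ms window, plus the head-axis angle (cos/sin),
#' stepped by 100 ms.
#'
#' @param s an `fg_session`.
#' @param source `"neural"` or `"tracking"`.
#' @param alignment one of `"sample_goal_arrival"`, `"center_arrival"`,
#'   `"delay_on"`, `"delay_off"`, `"test_goal_arrival"`.
#' @param target label scheme, see [class_labels()].
#' @param range time range around the alignment event, seconds.
#' @param spec classifier spec (default logistic regression).
#' @param cells unit ids (neural source).
#' @param correct_only use correct trials only.
#' @param seed RNG seed.
#' @return data.frame: `t` (window center relative to event), `accuracy`,
#'   `ci_low`, `ci_high`.
#' @export
time_resolved_decoding <- function(s, source = c("neural", "tracking"),
                                   alignment = "delay_on", target = "goal",
                                   range = c(-3, 3), spec = classifier_specs()$lr,
                                   cells = NULL, correct_only = TRUE, seed = 1) {
  source <- match.arg(source)
  ev_col <- switch(alignment,
                   sample_goal_arrival = "t_sample_goal_arrival",
                   center_arrival = "t_center_arrival",
                   delay_on = "t_delay_on", delay_off = "t_delay_off",
                   test_goal_arrival = "t_test_goal_arrival",
                   stop("unknown alignment ", alignment))
  events <- s$trials[[ev_col]]
  keep <- if (correct_only) s$trials$correct else rep(TRUE, nrow(s$trials))
  lab <- class_labels(s$trials, target)[keep]
  win <- if (source == "neural") 0.8 else 0.33
  step <- if (source == "neural") 0.2 else 0.1
  starts <- seq(range[1], range[2] - win, by = step)
  out <- lapply(starts, function(t0) {
    if (source == "neural") {
      cnt <- bin_aligned_counts(s, events, c(t0, t0 + win), 0.2, cells)
      X <- matrix(as.numeric(cnt), nrow = dim(cnt)[1])[keep, , drop = FALSE]
    } else {
      X <- tracking_features(s, events + t0, win)[keep, , drop = FALSE]
    }
    r <- tryCatch(loo_cv(X, lab, spec, seed = seed),
                  error = function(e) NULL)
    if (is.null(r)) return(data.frame(t = t0 + win / 2, accuracy = NA,
                                      ci_low = NA, ci_high = NA))
    data.frame(t = t0 + win / 2, accuracy = r$accuracy,
               ci_low = r$ci[1], ci_high = r$ci[2])
  })
  do.call(rbind, out)
}

tracking_features <- function(s, t0, win, n_pts = 10) {
  if (is.null(s$tracking)) stop("session has no tracking data")
  tr <- s$tracking
  offs <- seq(0, win, length.out = n_pts)
  X <- matrix(NA_real_, length(t0), n_pts * 4 + 2)
  for (i in seq_along(t0)) {
    tq <- t0[i] + offs
    x1 <- approx(tr$t_s, tr$x1_cm, tq, rule = 2)$y
    y1 <- approx(tr$t_s, tr$y1_cm, tq, rule = 2)$y
    x2 <- approx(tr$t_s, tr$x2_cm, tq, rule = 2)$y
    y2 <- approx(tr$t_s, tr$y2_cm, tq, rule = 2)$y
    ang <- atan2(mean(y1 - y2), mean(x1 - x2))  # head axis
    X[i, ] <- c(x1, y1, x2, y2, cos(ang), sin(ang))
  }
  X
}

#' Outcome and task-phase decoding
#'
#' Two-class LOO-CV decoding from delay activity of (a) whether the
#' upcoming test choice will be an error, (b) whether the previous trial's
#' test choice was an error, or (c) the task phase (post-sample vs
#' post-test center visit) from activity around the two center arrivals.
#' For the task-phase target, trials can be restricted to a matching
#' inbound bridge so that arrival direction is comparable across classes.
#'
#' @param s an `fg_session`.
#' @param target `"upcoming_error"`, `"past_error"` or `"task_phase"`.
#' @param binwidth bin width, seconds.
#' @param spec classifier spec.
#' @param cells unit ids.
#' @param inbound_bridge optional per-trial inbound-bridge labels used with
#'   `target = "task_phase"`: only trials taking the modal bridge back to
#'   center are compared.
#' @param phase_window window length after each center arrival for the
#'   task-phase target, seconds.
#' @param seed RNG seed.
#' @return an `fg_decoding`.
#' @export
outcome_decoding <- function(s, target = c("upcoming_error", "past_error",
                                           "task_phase"),
                             binwidth = 0.375, spec = classifier_specs()$lr,
                             cells = NULL, inbound_bridge = NULL,
                             phase_window = 1, seed = 1) {
  target <- match.arg(target)
  n <- nrow(s$trials)
  if (target %in% c("upcoming_error", "past_error")) {
    f <- build_features(s, binwidth = binwidth, cells = cells, standardize = FALSE)
    if (target == "upcoming_error") {
      keep <- rep(TRUE, n); lab <- as.integer(!s$trials$correct) + 1L
    } else {
      keep <- c(FALSE, rep(TRUE, n - 1))
      lab <- c(NA, as.integer(!s$trials$correct[-n]) + 1L)
    }
    X <- f$X[keep, , drop = FALSE]; lab <- lab[keep]
  } else {
    keep <- rep(TRUE, n)
    if (!is.null(inbound_bridge)) {
      modal <- as.integer(names(which.max(table(inbound_bridge))))
      keep <- inbound_bridge == modal
    }
    # post-sample center visit vs post-test center visit
    t_ret <- if (!is.null(s$meta$t_return_center))
      unlist(s$meta$t_return_center) else s$trials$t_test_goal_arrival + 3
    wA <- cbind(s$trials$t_center_arrival, s$trials$t_center_arrival + phase_window)
    wB <- cbind(t_ret, t_ret + phase_window)
    cntA <- population_vector(s, wA, cells)$values[keep, , drop = FALSE]
    cntB <- population_vector(s, wB, cells)$values[keep, , drop = FALSE]
    X <- rbind(cntA, cntB)
    lab <- rep(1:2, each = sum(keep))
  }
  if (min(table(lab)) < 2) stop("a class has fewer than 2 trials after filtering")
  loo_cv(X, lab, spec, seed = seed)
}
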