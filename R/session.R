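#' Construct a trial table
#'
#' A trial table holds one row per trial with the task labels and the event
#' timestamps that anchor every analysis window. Timestamps are seconds from
#' recording start and must increase within a trial in task order:
#' sample-goal arrival, center arrival, delay onset, delay offset (nose-poke
#' release), outer-ring entry during the test phase, test-goal arrival.
#'
#' @param trials data.frame with columns `index`, `goal`, `start`,
#'   `sample_route`, `test_route`, `correct`, `t_sample_goal_arrival`,
#'   `t_center_arrival`, `t_delay_on`, `t_delay_off`, `t_choice_entry`,
#'   `t_test_goal_arrival`, `test_choice`.
#' @param delay_duration nose-poke delay duration in seconds, 3.0 or 3.2.
#' @return the validated data.frame with class `fg_trials` and attribute
#'   `delay_duration`.
#' @export
trial_table <- function(trials, delay_duration = 3.0) {
  trials <- as.data.frame(trials)
  req <- c("index", "goal", "start", "sample_route", "test_route", "correct",
           "t_sample_goal_arrival", "t_center_arrival", "t_delay_on",
           "t_delay_off", "t_choice_entry", "t_test_goal_arrival", "test_choice")
  miss <- setdiff(req, names(trials))
  if (length(miss)) stop("trial table missing columns: ", paste(miss, collapse = ", "))
  trials <- trials[, req]
  rownames(trials) <- NULL
  trials$correct <- as.logical(trials$correct)
  attr(trials, "delay_duration") <- delay_duration
  class(trials) <- c("fg_trials", "data.frame")
  validate_trials(trials)
  trials
}

validate_trials <- function(trials) {
  dd <- attr(trials, "delay_duration")
  if (!dd %in% c(3.0, 3.2)) stop("delay_duration must be 3.0 or 3.2 s, got ", dd)
  if (nrow(trials) == 0) stop("trial table is empty")
  if (!all(diff(trials$index) == 1)) stop("trial indices not contiguous")
  if (trials$index[1] < 0) stop("trial indices must be >= 0")
  tcols <- c("t_sample_goal_arrival", "t_center_arrival", "t_delay_on",
             "t_delay_off", "t_choice_entry", "t_test_goal_arrival")
  tm <- as.matrix(trials[, tcols])
  bad <- which(apply(tm, 1, function(x) any(diff(x) <= 0)))
  if (length(bad))
    stop("trial ", trials$index[bad[1]], ": event timestamps not strictly increasing")
  dlen <- trials$t_delay_off - trials$t_delay_on
  bad <- which(abs(dlen - dd) > 1e-3)
  if (length(bad))
    stop("trial ", trials$index[bad[1]], ": delay duration ", round(dlen[bad[1]], 4),
         " s differs from session delay ", dd, " s by more than 1 ms")
  for (cl in c("goal", "start", "sample_route", "test_route", "test_choice"))
    if (!all(trials[[cl]] %in% 1:3)) stop("column ", cl, " must be in {1,2,3}")
  bad <- which(trials$correct != (trials$test_choice == trials$goal))
  if (length(bad))
    stop("trial ", trials$index[bad[1]], ": correct flag inconsistent with test_choice")
  invisible(trials)
}

#' Assemble a recording session
#'
#' Binds a trial table, unit metadata plus spike trains, and (optionally)
#' multi-channel LFP and LED tracking into one object consumed by all
#' analysis stages.
#'
#' @param trials an [trial_table()] object.
#' @param units data.frame with columns `unit_id`, `waveform_width_ms`,
#'   `mean_rate_hz`, `subarea`, `channel_index`.
#' @param spikes named list of sorted spike-time vectors (seconds), names
#'   matching `units$unit_id`.
#' @param lfp optional list with elements `fs` (Hz), `samples`
#'   (channels x time matrix) and `channel_indices`.
#' @param tracking optional data.frame `t_s, x1_cm, y1_cm, x2_cm, y2_cm`
#'   sampled at 30 Hz (two head-mounted LEDs, cm).
#' @param meta free-form provenance list; `meta$duration` (seconds) is used
#'   as the recording span when present.
#' @return object of class `fg_session`.
#' @export
session <- function(trials, units, spikes, lfp = NULL, tracking = NULL,
                    meta = list()) {
  stopifnot(inherits(trials, "fg_trials"))
  units <- as.data.frame(units)
  req <- c("unit_id", "waveform_width_ms", "mean_rate_hz", "subarea", "channel_index")
  if (!all(req %in% names(units))) stop("units table missing required columns")
  spikes <- lapply(spikes, as.numeric)
  if (is.null(names(spikes)) || !setequal(names(spikes), as.character(units$unit_id)))
    stop("spike list names must match units$unit_id")
  s <- structure(list(trials = trials, units = units,
                      spikes = spikes[as.character(units$unit_id)],
                      lfp = lfp, tracking = tracking, meta = meta),
                 class = "fg_session")
  validate_session(s)
  s
}

validate_session <- function(s) {
  validate_trials(s$trials)
  for (i in seq_len(nrow(s$units))) {
    id <- as.character(s$units$unit_id[i])
    sp <- s$spikes[[id]]
    if (is.unsorted(sp)) stop("unit ", id, ": spike times not sorted")
    if (length(sp) && sp[1] < 0) stop("unit ", id, ": negative spike time")
  }
  dur <- session_duration(s)
  tmax <- max(s$trials$t_test_goal_arrival)
  if (tmax > dur + 1e-6)
    stop("event timestamps exceed recording duration (", round(tmax, 2), " > ",
         round(dur, 2), " s)")
  if (!is.null(s$meta$duration)) {
    for (i in seq_len(nrow(s$units))) {
      id <- as.character(s$units$unit_id[i])
      r <- length(s$spikes[[id]]) / s$meta$duration
      if (abs(r - s$units$mean_rate_hz[i]) > 1e-6)
        stop("unit ", id, ": mean_rate_hz inconsistent with spike count / duration")
    }
  }
  if (!is.null(s$lfp)) {
    if (s$lfp$fs <= 60) stop("LFP sampling rate must exceed 60 Hz")
    if (nrow(s$lfp$samples) != length(s$lfp$channel_indices))
      stop("LFP channel_indices length must match sample rows")
  }
  invisible(s)
}

#' @exportS3Method base::print
print.fg_session <- function(x, ...) {
  cat("fg_session:", nrow(x$trials), "trials,", nrow(x$units), "units,",
      if (is.null(x$lfp)) "no LFP," else paste0(nrow(x$lfp$samples), "-ch LFP,"),
      if (is.null(x$tracking)) "no tracking\n" else "tracking\n")
  invisible(x)
}

session_duration <- function(s) {
  if (!is.null(s$meta$duration)) return(s$meta$duration)
  max(c(s$trials$t_test_goal_arrival + 10,
        vapply(s$spikes, function(x) if (length(x)) max(x) else 0, 0)))
}

#' Write a session to a directory of plain-text files
#'
#' Writes `trials.csv`, `spikes.csv`, `units.csv` always, plus `lfp.bin` +
#' `lfp.json` (little-endian float32, channel-major frames), `tracking.csv`
#' and `meta.json` when present.
#'
#' @param s an `fg_session`.
#' @param dir output directory (created if needed).
#' @return `dir`, invisibly.
#' @export
save_session <- function(s, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  tr <- as.data.frame(s$trials)
  tr$correct <- as.integer(tr$correct)
  write.csv(tr, file.path(dir, "trials.csv"), row.names = FALSE, quote = FALSE)
  ids <- rep(s$units$unit_id, vapply(s$spikes, length, 0L))
  tt <- unlist(s$spikes, use.names = FALSE)
  o <- order(tt)
  write.csv(data.frame(unit_id = ids[o], time_s = tt[o]),
            file.path(dir, "spikes.csv"), row.names = FALSE, quote = FALSE)
  write.csv(s$units, file.path(dir, "units.csv"), row.names = FALSE, quote = FALSE)
  if (!is.null(s$lfp)) {
    con <- file(file.path(dir, "lfp.bin"), "wb")
    # channel-major frames: all channels of sample 1, then sample 2, ...
    writeBin(as.numeric(s$lfp$samples), con, size = 4, endian = "little")
    close(con)
    jsonlite::write_json(list(fs_hz = s$lfp$fs,
                              n_channels = nrow(s$lfp$samples),
                              channel_indices = s$lfp$channel_indices),
                         file.path(dir, "lfp.json"), auto_unbox = TRUE)
  }
  if (!is.null(s$tracking))
    write.csv(s$tracking, file.path(dir, "tracking.csv"), row.names = FALSE, quote = FALSE)
  meta <- s$meta
  meta$delay_duration <- attr(s$trials, "delay_duration")
  jsonlite::write_json(meta, file.path(dir, "meta.json"), auto_unbox = TRUE, digits = NA)
  invisible(dir)
}

#' Load a session from a directory
#'
#' Counterpart of [save_session()]. `trials.csv`, `spikes.csv` and
#' `units.csv` are mandatory; LFP and tracking are optional and absent
#' fields stay `NULL` (stages that need them refuse with a clear error).
#'
#' @param dir directory containing the session files.
#' @return an `fg_session` with all invariants validated.
#' @export
load_session <- function(dir) {
  for (f in c("trials.csv", "spikes.csv", "units.csv"))
    if (!file.exists(file.path(dir, f)))
      stop("cannot load session: missing mandatory file ", f)
  meta <- list()
  if (file.exists(file.path(dir, "meta.json")))
    meta <- jsonlite::read_json(file.path(dir, "meta.json"), simplifyVector = TRUE)
  dd <- if (!is.null(meta$delay_duration)) meta$delay_duration else 3.0
  meta$delay_duration <- NULL
  tr <- read.csv(file.path(dir, "trials.csv"))
  trials <- trial_table(tr, delay_duration = dd)
  units <- read.csv(file.path(dir, "units.csv"))
  sp <- read.csv(file.path(dir, "spikes.csv"))
  spikes <- split(sp$time_s, factor(sp$unit_id, levels = units$unit_id))
  spikes <- lapply(spikes, sort)
  names(spikes) <- as.character(units$unit_id)
  lfp <- NULL
  if (file.exists(file.path(dir, "lfp.bin"))) {
    if (!file.exists(file.path(dir, "lfp.json")))
      stop("lfp.bin present but lfp.json descriptor missing")
    hdr <- jsonlite::read_json(file.path(dir, "lfp.json"), simplifyVector = TRUE)
    n <- file.size(file.path(dir, "lfp.bin")) / 4
    con <- file(file.path(dir, "lfp.bin"), "rb")
    x <- readBin(con, "numeric", n = n, size = 4, endian = "little")
    close(con)
    lfp <- list(fs = hdr$fs_hz,
                samples = matrix(x, nrow = hdr$n_channels),
                channel_indices = hdr$channel_indices)
  }
  tracking <- NULL
  if (file.exists(file.path(dir, "tracking.csv")))
    tracking <- read.csv(file.path(dir, "tracking.csv"))
  session(trials, units, spikes, lfp = lfp, tracking = tracking, meta = meta)
}

#' Event-aligned spike counts
#'
#' Bins each unit's spikes into fixed-width bins aligned to a per-trial event
#' (typically delay-period onset). Bin edges are half-open `[a, b)`: a spike
#' exactly at a bin's right edge belongs to the next bin, and a spike at the
#' window end is excluded. If `binwidth` does not tile the window, the final
#' partial bin is dropped.
#'
#' @param s an `fg_session`.
#' @param events numeric vector, one event time (s) per trial.
#' @param window length-2 numeric, window relative to the event, seconds.
#' @param binwidth bin width in seconds.
#' @param cells unit ids to include (default all).
#' @return integer array `trials x cells x bins` with dimnames.
#' @export
bin_aligned_counts <- function(s, events, window, binwidth, cells = NULL) {
  if (is.null(cells)) cells <- s$units$unit_id
  if (length(cells) == 0) stop("empty unit list")
  unknown <- setdiff(as.character(cells), names(s$spikes))
  if (length(unknown)) stop("unknown cell id(s): ", paste(unknown, collapse = ", "))
  dur <- session_duration(s)
  bad <- which(events + window[1] < -1e-9 | events + window[2] > dur + 1e-6)
  if (length(bad)) stop("trial ", bad[1], ": window outside recording")
  nb <- floor((window[2] - window[1]) / binwidth + 1e-9)
  if (nb < 1) stop("window shorter than one bin")
  edges_rel <- window[1] + binwidth * (0:nb)
  out <- array(0L, dim = c(length(events), length(cells), nb),
               dimnames = list(NULL, as.character(cells), NULL))
  for (j in seq_along(cells)) {
    sp <- s$spikes[[as.character(cells[j])]]
    if (!length(sp)) next
    for (i in seq_along(events)) {
      edges <- events[i] + edges_rel
      lo <- findInterval(edges[1], sp, left.open = TRUE) + 1L  # first spike >= left edge
      if (lo > length(sp)) next
      seg <- sp[lo:length(sp)]
      seg <- seg[seg < edges[nb + 1]]
      if (!length(seg)) next
      out[i, j, ] <- tabulate(findInterval(seg, edges), nbins = nb)
    }
  }
  out
}

#' Population-vector matrix
#'
#' One row per trial, one column per cell; entries are firing rates (Hz)
#' within a per-trial window: spike count divided by window duration.
#'
#' @param s an `fg_session`.
#' @param windows numeric matrix `n_trials x 2` of absolute window
#'   `[t0, t1)` times in seconds (or a length-2 vector recycled per trial).
#' @param cells unit ids (default all).
#' @param window_name label recorded on the result.
#' @return object of class `fg_pv`: list with `values` (trials x cells, Hz),
#'   `trial_indices`, `cell_ids`, `window_name`.
#' @export
population_vector <- function(s, windows, cells = NULL, window_name = "window") {
  if (is.null(cells)) cells <- s$units$unit_id
  unknown <- setdiff(as.character(cells), names(s$spikes))
  if (length(unknown)) stop("unknown cell id(s): ", paste(unknown, collapse = ", "))
  if (is.vector(windows) && length(windows) == 2)
    windows <- matrix(windows, nrow(s$trials), 2, byrow = TRUE)
  windows <- as.matrix(windows)
  durs <- windows[, 2] - windows[, 1]
  if (any(durs <= 0)) stop("window durations must be positive")
  vals <- matrix(0, nrow(windows), length(cells),
                 dimnames = list(NULL, as.character(cells)))
  for (j in seq_along(cells)) {
    sp <- s$spikes[[as.character(cells[j])]]
    if (!length(sp)) next
    # half-open [t0, t1): count spikes with t0 <= t < t1
    vals[, j] <- (findInterval(windows[, 2], sp, left.open = TRUE) -
                  findInterval(windows[, 1], sp, left.open = TRUE)) / durs
  }
  ti <- if (nrow(windows) == nrow(s$trials)) s$trials$index
        else seq_len(nrow(windows)) - 1L
  structure(list(values = vals, trial_indices = ti,
                 cell_ids = cells, window_name = window_name),
            class = "fg_pv")
}
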