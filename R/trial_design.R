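#' Generate a balanced pseudorandom trial sequence
#'
#' Builds the MSMGMR task's trial sequence. There are 27 distinct
#' (start, goal, test-route) combinations; each 27-trial block is a
#' permutation of all 27 under three constraints: (a) each 9-trial subblock
#' contains each start, each goal and each test bridge exactly three times;
#' (b) the same goal never occurs on more than two consecutive trials,
#' enforced across subblock and block boundaries; (c) within each subblock,
#' the three trials sharing a goal use the three sample routes once each.
#' Correctness is drawn from a Bernoulli accuracy model; errors pick a wrong
#' goal uniformly. Event timestamps follow a simple session clock with
#' configurable mean segment durations.
#'
#' @param n_blocks number of 27-trial blocks (>= 1).
#' @param delay_duration 3.0 (default) or 3.2 seconds.
#' @param seed integer seed for the trial-stream RNG.
#' @param p_correct per-trial probability of a correct test choice, or a
#'   vector of length `27 * n_blocks` for trial-varying accuracy.
#' @param timing named list overriding mean segment durations (seconds):
#'   `travel` (port-to-port travel, default 2), `goal_dwell` (reward
#'   consumption at a goal, default 3), `search` (start-port search, default
#'   2), `bridge` (delay end to outer-ring entry, default 1),
#'   `ring_to_goal` (outer ring to goal, default 1), `iti` (return +
#'   inter-trial pause, default 4).
#' @param max_retries bounded retries for the ordering constraint before the
#'   generator gives up with an error reporting the seed.
#' @return an [trial_table()] object of `27 * n_blocks` trials.
#' @export
generate_trial_sequence <- function(n_blocks = 4, delay_duration = 3.0, seed = 1,
                                    p_correct = 0.77, timing = list(),
                                    max_retries = 1000) {
  stopifnot(n_blocks >= 1)
  tm <- modifyList(list(travel = 2, goal_dwell = 3, search = 2, bridge = 1,
                        ring_to_goal = 1, iti = 4), timing)
  set.seed(derive_seed(seed, "trials"))
  n <- 27L * n_blocks
  rows <- vector("list", n_blocks)
  prev_goals <- integer(0)  # tail of goals already placed (run-rule memory)
  for (b in seq_len(n_blocks)) {
    blk <- NULL
    for (attempt in seq_len(max_retries)) {
      blk <- try_block(prev_goals)
      if (!is.null(blk)) break
    }
    if (is.null(blk))
      stop("trial sequence constraints unsatisfied after ", max_retries,
           " retries (seed ", seed, ")")
    prev_goals <- tail(c(prev_goals, blk$goal), 2)
    rows[[b]] <- blk
  }
  d <- do.call(rbind, rows)
  d$index <- 0:(n - 1)

  # accuracy model
  p <- rep_len(p_correct, n)
  d$correct <- runif(n) < p
  wrong <- vapply(d$goal, function(g) sample(setdiff(1:3, g), 1), 0L)
  d$test_choice <- ifelse(d$correct, d$goal, wrong)

  # session clock
  jit <- function(m, k = length(m)) m * rlnorm(k, 0, 0.15)
  t <- 5
  ts <- matrix(0, n, 6)
  for (i in seq_len(n)) {
    t_sga <- t + jit(tm$travel, 1)
    t_ca  <- t_sga + tm$goal_dwell + jit(tm$travel, 1)
    t_on  <- t_ca + jit(tm$search, 1)
    t_off <- t_on + delay_duration
    t_ce  <- t_off + jit(tm$bridge, 1)
    t_tga <- t_ce + jit(tm$ring_to_goal, 1)
    ts[i, ] <- c(t_sga, t_ca, t_on, t_off, t_ce, t_tga)
    t <- t_tga + tm$goal_dwell + jit(tm$iti, 1)
  }
  d$t_sample_goal_arrival <- ts[, 1]; d$t_center_arrival <- ts[, 2]
  d$t_delay_on <- ts[, 3]; d$t_delay_off <- ts[, 4]
  d$t_choice_entry <- ts[, 5]; d$t_test_goal_arrival <- ts[, 6]
  trial_table(d, delay_duration = delay_duration)
}

# one 27-trial block satisfying all constraints, or NULL on failure.
# Subblock membership comes from a randomly relabelled mod-3 Latin design:
# with random permutations ps, pg, pr of the class labels, subblock k holds
# the 9 combos with (ps[start] + pg[goal] + pr[route]) mod 3 == k. Each
# subblock then contains every (start, goal) pair once, hence every start,
# goal and bridge three times.
try_block <- function(prev_goals) {
  combos <- expand.grid(start = 1:3, goal = 1:3, test_route = 1:3)
  ps <- sample(0:2); pg <- sample(0:2); pr <- sample(0:2)
  sub <- (ps[combos$start] + pg[combos$goal] + pr[combos$test_route]) %% 3
  sub_order <- sample(0:2)
  out <- vector("list", 3)
  tail_goals <- prev_goals
  for (si in 1:3) {
    rows <- combos[sub == sub_order[si], ]
    ok <- FALSE
    for (a in 1:50) {
      ord <- sample(nrow(rows))
      g <- rows$goal[ord]
      if (max_run(c(tail_goals, g)) <= 2) { ok <- TRUE; break }
    }
    if (!ok) return(NULL)
    rows <- rows[ord, ]
    # sample routes: each route once per goal within the subblock
    rows$sample_route <- NA_integer_
    for (gg in 1:3) rows$sample_route[rows$goal == gg] <- sample(1:3)
    tail_goals <- tail(rows$goal, 2)
    out[[si]] <- rows
  }
  do.call(rbind, out)
}

max_run <- function(x) if (length(x)) max(rle(x)$lengths) else 0L

#' Per-trial class labels for a coding scheme
#'
#' @param trials an `fg_trials` table.
#' @param scheme `"start"`, `"goal"`, `"ego"` (goal in egocentric
#'   coordinates: behind / left / right of the start) or `"start_x_goal"`
#'   (9-class conjunction).
#' @param ego_convention integer offset-to-class map for the egocentric
#'   scheme: class index assigned to `(goal - start) mod 3` of 0, 1, 2.
#'   The task defines the three egocentric classes but not the geometric
#'   mapping; the default identifies offset 0 with "behind".
#' @return integer vector of class labels (1..3, or 1..9 for the conjunction).
#' @export
class_labels <- function(trials, scheme = c("start", "goal", "ego", "start_x_goal"),
                         ego_convention = c(behind = 1, left = 2, right = 3)) {
  scheme <- match.arg(scheme)
  switch(scheme,
    start = trials$start,
    goal = trials$goal,
    ego = as.integer(ego_convention[((trials$goal - trials$start) %% 3) + 1]),
    start_x_goal = (trials$start - 1L) * 3L + trials$goal)
}
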