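#' Task-location population vectors
#'
#' One PV per (correct trial, location type): the delay period (labelled by
#' start port), the 3 s after sample-phase goal arrival (labelled by goal),
#' and the bridge crossing between delay offset and outer-ring entry
#' (labelled by test route). Shares the [population_vector()] code path
#' with every other PV analysis.
#'
#' @param s an `fg_session`.
#' @param cells unit ids (default all).
#' @return list: `pv` (an `fg_pv` with stacked rows), `labels`
#'   (e.g. `"start-2"`), `location_type`, `mean_bridge_crossing_s`.
#' @export
task_location_pvs <- function(s, cells = NULL) {
  if (is.null(cells)) cells <- s$units$unit_id
  keep <- which(s$trials$correct)
  tr <- s$trials[keep, ]
  wins <- rbind(cbind(tr$t_delay_on, tr$t_delay_off),
                cbind(tr$t_sample_goal_arrival, tr$t_sample_goal_arrival + 3),
                cbind(tr$t_delay_off, tr$t_choice_entry))
  pvd <- population_vector(s, wins[seq_len(nrow(tr)), , drop = FALSE], cells, "delay")
  pvg <- population_vector(s, wins[nrow(tr) + seq_len(nrow(tr)), , drop = FALSE],
                           cells, "goal_arrival")
  pvb <- population_vector(s, wins[2 * nrow(tr) + seq_len(nrow(tr)), , drop = FALSE],
                           cells, "bridge")
  vals <- rbind(pvd$values, pvg$values, pvb$values)
  labels <- c(paste0("start-", tr$start), paste0("goal-", tr$goal),
              paste0("bridge-", tr$test_route))
  pv <- structure(list(values = vals, trial_indices = rep(tr$index, 3),
                       cell_ids = cells, window_name = "task_locations"),
                  class = "fg_pv")
  list(pv = pv, labels = labels,
       location_type = rep(c("delay", "goal", "bridge"), each = nrow(tr)),
       mean_bridge_crossing_s = mean(tr$t_choice_entry - tr$t_delay_off))
}

#' t-SNE embedding of population vectors
#'
#' Runs `n_runs` two-dimensional t-SNE embeddings (perplexity 35, learning
#' rate 100 by default) and returns the run with the lowest final
#' Kullback-Leibler divergence. PVs are standardized per cell beforehand
#' (disable with `standardize = FALSE`). When fewer than `3 * perplexity`
#' points are supplied the perplexity is reduced with a warning.
#'
#' @param pvs an `fg_pv` or numeric matrix (points x cells).
#' @param perplexity,learning_rate t-SNE hyperparameters.
#' @param n_runs number of restarts.
#' @param seed RNG seed.
#' @param standardize standardize columns first.
#' @param max_iter t-SNE iterations per run.
#' @return list: `coords` (points x 2, min-KL run), `kl` (per-run final
#'   KL), `selected` (index of the chosen run).
#' @export
tsne_embed <- function(pvs, perplexity = 35, learning_rate = 100, n_runs = 10,
                       seed = 1, standardize = TRUE, max_iter = 1000) {
  X <- if (inherits(pvs, "fg_pv")) pvs$values else as.matrix(pvs)
  if (nrow(X) < 5) stop("need at least 5 points to embed")
  if (standardize) X <- standardize_features(X)
  if (nrow(X) < 3 * perplexity + 1) {
    perplexity <- max(2, floor((nrow(X) - 1) / 3))
    warning("few points for requested perplexity; reduced to ", perplexity)
  }
  runs <- vector("list", n_runs)
  kl <- numeric(n_runs)
  for (r in seq_len(n_runs)) {
    set.seed(derive_seed(seed, paste0("tsne", r)))
    fit <- Rtsne::Rtsne(X, dims = 2, perplexity = perplexity,
                        eta = learning_rate, max_iter = max_iter,
                        check_duplicates = FALSE, pca = FALSE, verbose = FALSE)
    runs[[r]] <- fit$Y
    kl[r] <- tail(fit$itercosts, 1)
  }
  sel <- which.min(kl)
  list(coords = runs[[sel]], kl = kl, selected = sel)
}

#' Machine-readable session report
#'
#' Collates the outputs of the analysis stages into a single JSON-ready
#' list (and optionally writes it). Keys for stages that were not run are
#' present with `NULL` values so downstream consumers see a stable schema.
#'
#' @param behavior output of [performance_summary()] (optional).
#' @param selection report element of [select_cells()] (optional).
#' @param decoding named list of `fg_decoding` results (optional).
#' @param phase named list of phase-stage outputs (optional).
#' @param covariance output of [ccsi()] plus counts (optional).
#' @param embedding output of [tsne_embed()] (optional).
#' @param seeds named list of seeds used.
#' @param config an `fg_config` (hashed into the report).
#' @param file optional path; when given the report is written as JSON.
#' @return the report list, invisibly when written.
#' @export
session_report <- function(behavior = NULL, selection = NULL, decoding = NULL,
                           phase = NULL, covariance = NULL, embedding = NULL,
                           seeds = list(), config = NULL, file = NULL) {
  dec <- if (!is.null(decoding)) lapply(decoding, function(d) {
    if (inherits(d, "fg_decoding"))
      list(accuracy = d$accuracy, ci = unname(d$ci),
           confusion = unclass(d$confusion), method = d$spec$method)
    else d
  })
  rep <- list(
    schema_version = "1.0",
    behavior = behavior,
    selection = if (!is.null(selection))
      selection[c("n_total", "n_stable", "n_principal")],
    decoding = dec,
    phase = phase,
    covariance = covariance,
    embedding = if (!is.null(embedding))
      list(kl = embedding$kl, selected = embedding$selected),
    seeds = seeds,
    config_hash = if (!is.null(config))
      sum(utf8ToInt(paste(deparse(config[setdiff(names(config), "seed")]),
                          collapse = ""))))
  if (!is.null(file)) {
    jsonlite::write_json(rep, file, auto_unbox = TRUE, digits = NA,
                         pretty = TRUE, null = "null", force = TRUE)
    return(invisible(rep))
  }
  rep
}
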