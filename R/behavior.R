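#' Baseline-corrected reward
#'
#' Per valid trial, the obtained reward minus the mean reward currently
#' available at the two planets, in unmultiplied treasure units (stakes
#' multipliers never enter). Trials with a missed response contribute `NA`
#' and are excluded from the mean. A uniformly random chooser scores 0 in
#' expectation; positive values index reward above the exploration
#' baseline.
#'
#' @param dataset A `metarl_dataset` whose sequence carries the reward
#'   walks.
#' @return List with `per_trial` (numeric vector, `NA` on missed trials)
#'   and `mean`.
#' @export
baseline_corrected_reward <- function(dataset) {
  obs <- dataset$obs
  walk_mean <- rowMeans(dataset$sequence$walks)
  per_trial <- obs$reward - walk_mean
  per_trial[obs$miss1 == 1 | obs$miss2 == 1] <- NA_real_
  list(per_trial = per_trial, mean = mean(per_trial, na.rm = TRUE))
}

#' Flag revaluation trials
#'
#' A revaluation trial is the first trial on which a changed transition
#' mapping could be observed: for each reversal event, the first subsequent
#' trial (the event trial included) whose start state is the affected state
#' and whose first-stage response was made. A second-stage miss does not
#' block the flag, since the planet is revealed on arrival. Stable-block
#' trials are never flagged, and several pending reversals of the same
#' state collapse onto a single flag at the first visit.
#'
#' @param dataset A `metarl_dataset`.
#' @return Logical vector, one flag per trial.
#' @export
identify_revaluation_trials <- function(dataset) {
  tr <- dataset$sequence$trials
  ev <- dataset$sequence$reversals
  flags <- rep(FALSE, nrow(tr))
  if (!nrow(ev)) return(flags)
  valid <- dataset$obs$miss1 == 0
  ev_block <- tr$block[match(ev$trial, tr$trial)]
  for (i in seq_len(nrow(ev))) {
    # the changed mapping counts as observed only within its own
    # variable block; stable-block trials are never flagged
    cand <- which(tr$trial >= ev$trial[i] & tr$block == ev_block[i] &
                    tr$start_state == ev$state[i] & valid)
    if (length(cand)) flags[cand[1]] <- TRUE
  }
  flags
}

#' Per-participant summary for matching and regression
#'
#' @param dataset A `metarl_dataset`.
#' @param fit Optional [fit_map()] result supplying model-based weights.
#' @return One-row data frame with `participant`, `group`,
#'   `mean_bc_reward` and, when a fit is given, the four `omega_*`
#'   estimates.
#' @export
participant_summary <- function(dataset, fit = NULL) {
  out <- data.frame(participant = dataset$participant_id,
                    group = dataset$group,
                    mean_bc_reward = baseline_corrected_reward(dataset)$mean,
                    stringsAsFactors = FALSE)
  if (!is.null(fit)) {
    om <- fit$params_hat[paste0("omega_", omega_cells())]
    out <- cbind(out, as.data.frame(as.list(om)))
  }
  out
}

#' Performance matching by mutual nearest neighbours
#'
#' Assigns to each participant the member of the other group with the
#' smallest absolute difference in mean baseline-corrected reward; pairs
#' that are mutually each other's candidate partner form the
#' performance-matched sample. Distance ties break deterministically toward
#' the earlier row in the other group's table.
#'
#' @param group_a,group_b Data frames with columns `participant` and
#'   `mean_bc_reward` (extra columns are ignored), one per group.
#' @return List with `pairs` (data frame `participant_a`, `participant_b`,
#'   `diff`) and the unmatched ids per group. The pair set is invariant
#'   under swapping the two groups.
#' @export
performance_match <- function(group_a, group_b) {
  stopifnot(nrow(group_a) > 0, nrow(group_b) > 0)
  nearest <- function(x, pool) {
    vapply(x, function(v) which.min(abs(pool - v)), integer(1))
  }
  a2b <- nearest(group_a$mean_bc_reward, group_b$mean_bc_reward)
  b2a <- nearest(group_b$mean_bc_reward, group_a$mean_bc_reward)
  mutual <- which(b2a[a2b] == seq_len(nrow(group_a)))
  pairs <- data.frame(
    participant_a = group_a$participant[mutual],
    participant_b = group_b$participant[a2b[mutual]],
    diff = abs(group_a$mean_bc_reward[mutual] -
                 group_b$mean_bc_reward[a2b[mutual]]),
    stringsAsFactors = FALSE)
  list(pairs = pairs,
       unmatched_a = setdiff(group_a$participant, pairs$participant_a),
       unmatched_b = setdiff(group_b$participant, pairs$participant_b))
}

#' Reaction-time preprocessing for the revaluation analysis
#'
#' Keeps variable-block trials with a valid second-stage response and a
#' second-stage reaction time of at least 200 ms (strictly faster responses
#' are dropped), log-transforms the RT, attaches the revaluation flag and
#' the dummy codes used in the revaluation regressions (non-revaluation =
#' 0, revaluation = 1; younger = 0, older = 1).
#'
#' @param dataset A `metarl_dataset` with RTs filled.
#' @param expectations Optional per-trial second-stage reward expectations
#'   (e.g. from [expectation_covariate()]) carried into the table.
#' @return Data frame with one row per retained trial: `participant`,
#'   `group`, `trial`, `stakes`, `revaluation`, `old`, `rt2_ms`, `log_rt2`
#'   and optionally `expectation`.
#' @export
rt_preprocess <- function(dataset, expectations = NULL) {
  obs <- dataset$obs
  reval <- identify_revaluation_trials(dataset)
  keep <- obs$block_condition == "variable" & obs$miss1 == 0 &
    obs$miss2 == 0 & !is.na(obs$rt2_ms) & obs$rt2_ms >= 200
  out <- data.frame(participant = dataset$participant_id,
                    group = dataset$group,
                    trial = obs$trial[keep],
                    stakes = obs$stakes[keep],
                    revaluation = as.integer(reval[keep]),
                    old = as.integer(dataset$group == "older"),
                    rt2_ms = obs$rt2_ms[keep],
                    log_rt2 = log(obs$rt2_ms[keep]),
                    stringsAsFactors = FALSE)
  if (!is.null(expectations)) out$expectation <- expectations[keep]
  out
}

#' Trial-wise second-stage reward expectations at fitted parameters
#'
#' Replays the learner at the fitted parameters and returns, for each
#' trial, the model-free value of the visited planet immediately before the
#' reward update (`NA` on first-stage misses). Used as a response-vigor
#' covariate in the reaction-time regressions.
#'
#' @param dataset A `metarl_dataset`.
#' @param fit A [fit_map()] result (or a named parameter vector).
#' @param variant Model variant of the fit.
#' @return Numeric vector, one value per trial.
#' @export
expectation_covariate <- function(dataset, fit, variant = NULL) {
  params <- if (inherits(fit, "metarl_fit")) fit$params_hat else fit
  if (is.null(variant))
    variant <- if (inherits(fit, "metarl_fit")) fit$variant else "standard"
  replay_learner(dataset, params, variant)$q2_pre
}

#' Long-format model-based weight table for regression
#'
#' Stacks each participant's four fitted model-based weights into one row
#' per condition cell, with the effect codes used in the metacontrol
#' regressions (younger = +0.5 / older = -0.5; low = -0.5 / high = +0.5;
#' stable = +0.5 / variable = -0.5).
#'
#' @param fits List of [fit_map()] results (standard layout).
#' @return Data frame with columns `participant`, `group`, `stakes`,
#'   `transition`, `omega`, `age_c`, `stakes_c`, `transition_c`.
#' @export
omega_table <- function(fits) {
  rows <- lapply(fits, function(f) {
    om <- f$params_hat[paste0("omega_", omega_cells())]
    cells <- strsplit(omega_cells(), "_")
    data.frame(participant = f$participant_id, group = f$group,
               stakes = vapply(cells, `[`, "", 1),
               transition = vapply(cells, `[`, "", 2),
               omega = unname(om), stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out$age_c <- ifelse(out$group == "younger", 0.5, -0.5)
  out$stakes_c <- ifelse(out$stakes == "high", 0.5, -0.5)
  out$transition_c <- ifelse(out$transition == "stable", 0.5, -0.5)
  out
}
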