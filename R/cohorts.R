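# Deterministic per-stage seed derivation: every source of randomness in a
# multi-stage run flows from one global seed through named substreams.
derive_seed <- function(global_seed, stage) {
  h <- 0
  for (k in utf8ToInt(as.character(stage))) h <- (h * 131 + k) %% 1999999973
  as.integer((as.numeric(global_seed) %% 1000003 * 2017 + h) %% 2147483646 + 1)
}

make_dataset <- function(participant_id, group, sequence, obs, sim_trace = NULL) {
  ds <- list(participant_id = participant_id, group = group,
             sequence = sequence, obs = obs, sim_trace = sim_trace)
  class(ds) <- "metarl_dataset"
  ds
}

#' Simulate one agent playing the task
#'
#' Plays the hybrid learner generatively through a trial sequence: on every
#' trial the first-stage action is sampled from [choice_prob()], the
#' environment resolves the transition and reward via [task_step()], and the
#' learner state is updated exactly as [sequence_loglik()] assumes
#' (transition update with rate 1 in stable blocks, then the SARSA(lambda)
#' reward update). Optional miss rates inject aborted responses uniformly at
#' random: a first-stage miss aborts the trial before anything is shown; a
#' second-stage miss keeps the observed transition but forfeits the reward.
#'
#' @param params Parameter vector in the standard (or dual-rate) layout, see
#'   [model_params()].
#' @param sequence A [generate_trial_sequence()] object.
#' @param seed Optional RNG seed.
#' @param miss_rates Length-2 numeric `c(stage1, stage2)` miss
#'   probabilities in `[0, 1)`.
#' @param participant_id,group Labels stored with the dataset.
#' @return A `metarl_dataset`: list with `participant_id`, `group`,
#'   `sequence`, `obs` (one row per trial) and `sim_trace` (the generative
#'   log of pre-update second-stage reward expectations).
#' @export
simulate_agent <- function(params, sequence, seed = NULL,
                           miss_rates = c(0, 0),
                           participant_id = "agent", group = "synthetic") {
  if (!is.null(seed)) set.seed(seed)
  variant <- if ("eta_cf" %in% names(params)) "dual_transition_rate" else "standard"
  check_params_in_support(params, variant)
  stopifnot(all(miss_rates >= 0 & miss_rates < 1))
  cfg <- sequence$config
  trials <- sequence$trials
  n <- nrow(trials)
  state <- init_learner_state(cfg)
  structure <- sequence$initial_transitions
  rev_by_trial <- split(sequence$reversals$state, sequence$reversals$trial)

  action1 <- key1 <- planet <- rep(NA_integer_, n)
  reward <- points <- q2_trace <- rep(NA_real_, n)
  miss1 <- miss2 <- integer(n)
  eta_free <- unname(params[["eta"]])
  eta_cf_free <- if (variant == "dual_transition_rate")
    unname(params[["eta_cf"]]) else eta_free

  for (t in seq_len(n)) {
    tr <- trials[t, ]
    key <- as.character(tr$trial)
    if (!is.null(rev_by_trial[[key]]))
      for (s in rev_by_trial[[key]]) structure <- apply_reversal(structure, s)

    if (stats::runif(1) < miss_rates[1]) { miss1[t] <- 1L; next }

    cell <- cell_of(tr$stakes, tr$block_condition)
    pr <- choice_prob(state, tr$start_state, params, cell, tr$left_action)
    a <- sample(0:1, 1L, prob = pr)
    out <- task_step(structure, tr, a, sequence$walks, cfg)

    action1[t] <- 2L * tr$start_state + a
    key1[t] <- if (a == tr$left_action) 0L else 1L
    planet[t] <- out$planet

    in_variable <- tr$block_condition == "variable"
    eta <- if (in_variable) eta_free else 1
    eta_cf <- if (in_variable) eta_cf_free else 1
    state <- transition_update(state, tr$start_state, a, out$planet, eta, eta_cf)
    q2_trace[t] <- state$q2[out$planet + 1L]

    if (stats::runif(1) < miss_rates[2]) {
      miss2[t] <- 1L
    } else {
      reward[t] <- out$reward
      points[t] <- out$points
      state <- mf_update(state, tr$start_state, a, out$planet, out$reward,
                         unname(params[["alpha"]]), unname(params[["lam"]]))
    }
    state$prev_action <- action1[t]
    state$prev_key <- key1[t]
  }

  obs <- data.frame(trial = trials$trial, block = trials$block,
                    block_condition = trials$block_condition,
                    stakes = trials$stakes, start_state = trials$start_state,
                    action1 = action1, key1 = key1, planet = planet,
                    reward = reward, points = points,
                    rt1_ms = NA_real_, rt2_ms = NA_real_,
                    miss1 = miss1, miss2 = miss2,
                    stringsAsFactors = FALSE)
  make_dataset(participant_id, group, sequence, obs, sim_trace = q2_trace)
}

#' Synthetic reaction-time generator specification
#'
#' Log-normal reaction times with additive effects on the log scale. The
#' generator is synthetic plumbing for exercising the RT analysis stage: its
#' parameters are configuration, not empirical claims. Second-stage RTs get
#' a group-specific slowing on revaluation trials (the first observation of
#' a changed transition) and a response-vigor effect of the model-derived
#' second-stage reward expectation; first-stage RTs use the base terms only.
#'
#' @param base_log_mean Named numeric, log-milliseconds per group.
#' @param log_sd Positive trial-level dispersion on the log scale.
#' @param revaluation_shift Named numeric, additive log-ms slowing of
#'   stage-2 RTs on revaluation trials, per group.
#' @param vigor_slope Effect of second-stage reward expectation (treasure
#'   units) on log RT.
#' @param between_sd Between-participant sd of the baseline log RT
#'   (individual speed differences).
#' @param shift_sd Between-participant sd of the revaluation shift.
#' @return An object of class `metarl_rt_spec`.
#' @export
rt_gen_spec <- function(base_log_mean = c(younger = log(600), older = log(825)),
                        log_sd = 0.25,
                        revaluation_shift = c(younger = 0.15, older = 0.06),
                        vigor_slope = -0.01,
                        between_sd = 0.1,
                        shift_sd = 0.05) {
  stopifnot(log_sd > 0, between_sd >= 0, shift_sd >= 0)
  spec <- list(base_log_mean = base_log_mean, log_sd = log_sd,
               revaluation_shift = revaluation_shift,
               vigor_slope = vigor_slope,
               between_sd = between_sd, shift_sd = shift_sd)
  class(spec) <- "metarl_rt_spec"
  spec
}

#' Fill a dataset's reaction-time fields from the synthetic RT model
#'
#' `log rt2 = base_log_mean[group] + b_i + (revaluation_shift[group] + s_i)
#' * reval + vigor_slope * expectation + noise(0, log_sd)`, with
#' participant-level offsets `b_i ~ N(0, between_sd^2)` and
#' `s_i ~ N(0, shift_sd^2)` drawn once per dataset; `rt1` is generated from
#' the baseline terms and noise only. RTs stay `NA` on the corresponding
#' missed stages.
#'
#' @param dataset A `metarl_dataset`.
#' @param spec An [rt_gen_spec()].
#' @param expectations Optional per-trial second-stage reward expectations
#'   aligned to trials (defaults to the dataset's simulation trace, else 0).
#' @param seed Optional RNG seed.
#' @return The dataset with `rt1_ms` and `rt2_ms` filled.
#' @export
simulate_reaction_times <- function(dataset, spec, expectations = NULL,
                                    seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  n <- nrow(dataset$obs)
  grp <- dataset$group
  base <- unname(spec$base_log_mean[[grp]])
  shift <- unname(spec$revaluation_shift[[grp]])
  if (is.null(expectations)) {
    expectations <- if (!is.null(dataset$sim_trace)) dataset$sim_trace
    else rep(0, n)
  }
  stopifnot(length(expectations) == n)
  reval <- as.numeric(identify_revaluation_trials(dataset))
  ex <- ifelse(is.na(expectations), 0, expectations)
  b_i <- stats::rnorm(1, 0, spec$between_sd)
  s_i <- stats::rnorm(1, 0, spec$shift_sd)
  log_rt1 <- base + b_i + stats::rnorm(n, 0, spec$log_sd)
  log_rt2 <- base + b_i + (shift + s_i) * reval + spec$vigor_slope * ex +
    stats::rnorm(n, 0, spec$log_sd)
  dataset$obs$rt1_ms <- ifelse(dataset$obs$miss1 == 1, NA_real_, exp(log_rt1))
  dataset$obs$rt2_ms <- ifelse(dataset$obs$miss1 == 1 | dataset$obs$miss2 == 1,
                               NA_real_, exp(log_rt2))
  dataset
}

#' Convert effect-coded cell effects to per-group cell shifts
#'
#' Translates effect-coded regression coefficients (age group +0.5 younger /
#' -0.5 older; stakes -0.5 low / +0.5 high; transitions +0.5 stable / -0.5
#' variable) into additive shifts of the mean model-based weight for each of
#' the four condition cells in each group.
#'
#' @param group,stakes,transition,group_stakes,group_transition Effect-coded
#'   coefficients on the model-based weight.
#' @return List with one named length-4 shift vector per group
#'   (`younger`, `older`), cells ordered as [variant_layout()] omegas.
#' @export
omega_effects_to_shifts <- function(group = 0, stakes = 0, transition = 0,
                                    group_stakes = 0, group_transition = 0) {
  cg <- c(younger = 0.5, older = -0.5)
  cs <- c(low = -0.5, high = 0.5)
  ct <- c(stable = 0.5, variable = -0.5)
  cells <- omega_cells()
  out <- lapply(names(cg), function(g) {
    sh <- vapply(cells, function(cl) {
      p <- strsplit(cl, "_")[[1]]
      cg[[g]] * group + cs[[p[1]]] * stakes + ct[[p[2]]] * transition +
        cg[[g]] * cs[[p[1]]] * group_stakes +
        cg[[g]] * ct[[p[2]]] * group_transition
    }, numeric(1))
    stats::setNames(sh, cells)
  })
  stats::setNames(out, names(cg))
}

#' Specification of a synthetic cohort
#'
#' Defines the group-level distributions from which agent parameters are
#' drawn, planted condition effects on the model-based weight, miss rates
#' and the RT generator. Bounded parameters are drawn from Beta
#' distributions parameterized by mean and concentration, `beta` from a
#' Gamma, and the stickiness parameters from normals. Default miss rates
#' follow the published marginal rates (younger 0.2% / 1.2%, older
#' 1.6% / 2.1% at stages 1 / 2); default planted effects put the group,
#' stakes and transition effects on the model-based weight at the published
#' effect-size scale.
#'
#' @param n_per_group Agents per group.
#' @param groups Group labels.
#' @param omega_base Baseline mean model-based weight before shifts.
#' @param omega_kappa Beta concentration of individual model-based weights.
#' @param planted_omega_effects List per group of length-4 additive shifts
#'   on the mean model-based weight (see [omega_effects_to_shifts()]).
#' @param param_dists Per-group distribution hyperparameters for the
#'   remaining parameters; see the default for the expected shape.
#' @param miss_rates List per group of `c(stage1, stage2)` probabilities.
#' @param rt_model An [rt_gen_spec()].
#' @param seed RNG seed for cohort generation.
#' @return An object of class `metarl_cohort_spec`.
#' @export
cohort_spec <- function(n_per_group = 50L,
                        groups = c("younger", "older"),
                        omega_base = 0.5,
                        omega_kappa = 12,
                        planted_omega_effects =
                          omega_effects_to_shifts(group = 0.11, stakes = 0.05,
                                                  transition = 0.04,
                                                  group_stakes = 0.12,
                                                  group_transition = 0.09),
                        param_dists = NULL,
                        miss_rates = list(younger = c(0.002, 0.012),
                                          older = c(0.016, 0.021)),
                        rt_model = rt_gen_spec(),
                        seed = NULL) {
  if (is.null(param_dists)) {
    param_dists <- list(
      younger = list(alpha = c(mean = 0.55, kappa = 6),
                     lam = c(mean = 0.5, kappa = 6),
                     eta = c(mean = 0.7, kappa = 6),
                     beta = c(shape = 4, scale = 0.25),
                     pi = c(mean = 0.2, sd = 0.3),
                     rho = c(mean = 0.05, sd = 0.2)),
      older = list(alpha = c(mean = 0.45, kappa = 6),
                   lam = c(mean = 0.5, kappa = 6),
                   eta = c(mean = 0.45, kappa = 6),
                   beta = c(shape = 4, scale = 0.25),
                   pi = c(mean = 0.25, sd = 0.3),
                   rho = c(mean = 0.05, sd = 0.2)))
  }
  spec <- list(n_per_group = as.integer(n_per_group), groups = groups,
               omega_base = omega_base, omega_kappa = omega_kappa,
               planted_omega_effects = planted_omega_effects,
               param_dists = param_dists, miss_rates = miss_rates,
               rt_model = rt_model,
               seed = if (is.null(seed)) NULL else as.integer(seed))
  class(spec) <- "metarl_cohort_spec"
  for (g in groups) {
    mu <- omega_base + spec$planted_omega_effects[[g]]
    if (any(mu < 0 | mu > 1))
      stop("shifted mean model-based weight outside [0, 1] for group ", g,
           call. = FALSE)
    if (any(spec$miss_rates[[g]] < 0 | spec$miss_rates[[g]] >= 1))
      stop("miss rates must lie in [0, 1)", call. = FALSE)
  }
  spec
}

# Beta draw parameterized by mean and concentration.
rbeta_ms <- function(n, mean, kappa) {
  stats::rbeta(n, shape1 = mean * kappa, shape2 = (1 - mean) * kappa)
}

#' Draw ground-truth parameters for a cohort
#'
#' @param spec A [cohort_spec()].
#' @param seed Optional RNG seed (falls back to `spec$seed`).
#' @return Data frame with `participant`, `group` and one column per
#'   standard model parameter (four `omega_*` columns).
#' @export
draw_cohort_truth <- function(spec, seed = NULL) {
  if (is.null(seed)) seed <- spec$seed
  if (!is.null(seed)) set.seed(seed)
  rows <- list()
  for (g in spec$groups) {
    d <- spec$param_dists[[g]]
    n <- spec$n_per_group
    if (n == 0L) next
    mu_om <- pmin(pmax(spec$omega_base + spec$planted_omega_effects[[g]],
                       0.02), 0.98)
    om <- vapply(mu_om, function(m) rbeta_ms(n, m, spec$omega_kappa),
                 numeric(n))
    om <- matrix(om, nrow = n)
    colnames(om) <- paste0("omega_", omega_cells())
    rows[[g]] <- data.frame(
      participant = paste0(substr(g, 1, 1), sprintf("%03d", seq_len(n))),
      group = g,
      alpha = rbeta_ms(n, d$alpha[["mean"]], d$alpha[["kappa"]]),
      lam = rbeta_ms(n, d$lam[["mean"]], d$lam[["kappa"]]),
      eta = rbeta_ms(n, d$eta[["mean"]], d$eta[["kappa"]]),
      om,
      beta = stats::rgamma(n, shape = d$beta[["shape"]],
                           scale = d$beta[["scale"]]),
      pi = stats::rnorm(n, d$pi[["mean"]], d$pi[["sd"]]),
      rho = stats::rnorm(n, d$rho[["mean"]], d$rho[["sd"]]),
      stringsAsFactors = FALSE)
  }
  if (!length(rows))
    return(data.frame(participant = character(0), group = character(0)))
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  out
}

truth_row_params <- function(row) {
  model_params(alpha = row$alpha, lam = row$lam, eta = row$eta,
               omega = unlist(row[paste0("omega_", omega_cells())]),
               beta = row$beta, pi = row$pi, rho = row$rho)
}

#' Simulate a full synthetic cohort
#'
#' Draws ground-truth parameters per agent from the group distributions
#' (with planted condition shifts on the model-based weight), plays every
#' agent through the task, injects missed responses at the group miss
#' rates, and fills synthetic reaction times. By default all agents share
#' one trial sequence (the published design reused fixed sequences across
#' participants); set `share_sequence = FALSE` for independent sequences.
#'
#' @param spec A [cohort_spec()].
#' @param config A [task_config()].
#' @param seed RNG seed (falls back to `spec$seed`).
#' @param share_sequence Reuse a single trial sequence for every agent?
#' @param fill_rts Fill reaction times from `spec$rt_model`?
#' @return List with `datasets` (list of `metarl_dataset`) and `truth`
#'   (the ground-truth parameter table).
#' @export
simulate_cohort <- function(spec, config = task_config(), seed = NULL,
                            share_sequence = TRUE, fill_rts = TRUE) {
  if (is.null(seed)) seed <- spec$seed
  if (is.null(seed)) seed <- 1L
  truth <- draw_cohort_truth(spec, seed = derive_seed(seed, "truth"))
  shared_seq <- if (share_sequence)
    generate_trial_sequence(config, seed = derive_seed(seed, "sequence"))
  datasets <- vector("list", nrow(truth))
  for (i in seq_len(nrow(truth))) {
    row <- truth[i, ]
    sq <- if (share_sequence) shared_seq
      else generate_trial_sequence(config, seed = derive_seed(seed, paste0("seq", i)))
    ds <- simulate_agent(truth_row_params(row), sq,
                         seed = derive_seed(seed, paste0("agent", i)),
                         miss_rates = spec$miss_rates[[row$group]],
                         participant_id = row$participant, group = row$group)
    if (fill_rts)
      ds <- simulate_reaction_times(ds, spec$rt_model,
                                    seed = derive_seed(seed, paste0("rt", i)))
    datasets[[i]] <- ds
  }
  list(datasets = datasets, truth = truth)
}
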