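choice_csv_columns <- function() {
  c("participant", "group", "trial", "block", "block_condition", "stakes",
    "start_state", "action1", "key1", "planet", "reward", "points",
    "rt1_ms", "rt2_ms", "miss1", "miss2")
}

#' Write behavioral datasets as long-format CSV
#'
#' One row per trial with the documented schema (`participant`, `group`,
#' `trial`, `block`, `block_condition`, `stakes`, `start_state`, `action1`,
#' `key1`, `planet`, `reward`, `points`, `rt1_ms`, `rt2_ms`, `miss1`,
#' `miss2`). Missing values are serialized as empty fields, miss flags as
#' 0/1 integers, and floats at full precision, so a write/read round trip
#' is exact.
#'
#' @param datasets A `metarl_dataset` or list of them.
#' @param path Output CSV path.
#' @return `path`, invisibly.
#' @export
write_choice_csv <- function(datasets, path) {
  if (inherits(datasets, "metarl_dataset")) datasets <- list(datasets)
  rows <- lapply(datasets, function(ds) {
    cbind(data.frame(participant = ds$participant_id, group = ds$group,
                     stringsAsFactors = FALSE),
          ds$obs[, setdiff(choice_csv_columns(), c("participant", "group"))])
  })
  out <- do.call(rbind, rows)
  for (col in c("reward", "points", "rt1_ms", "rt2_ms")) {
    x <- out[[col]]
    out[[col]] <- ifelse(is.na(x), NA_character_, sprintf("%.17g", x))
  }
  utils::write.csv(out, path, row.names = FALSE, na = "", quote = FALSE)
  invisible(path)
}

#' Read behavioral datasets from long-format CSV
#'
#' Validates the schema (naming any offending column), trial contiguity per
#' participant, and the consistency of miss flags with the recorded fields
#' (a missed response cannot carry a reaction time, choice or reward).
#'
#' @param path CSV path written by [write_choice_csv()] (or matching its
#'   schema).
#' @param sequence Optional `metarl_trial_sequence` attached to every
#'   returned dataset (required by the sequence-dependent analyses).
#' @return List of `metarl_dataset`, one per participant, in file order.
#' @export
read_choice_csv <- function(path, sequence = NULL) {
  df <- utils::read.csv(path, stringsAsFactors = FALSE,
                        colClasses = c(participant = "character",
                                       group = "character"))
  missing_cols <- setdiff(choice_csv_columns(), names(df))
  if (length(missing_cols))
    stop("choice CSV lacks column(s): ", paste(missing_cols, collapse = ", "),
         call. = FALSE)
  if (nrow(df) == 0) return(list())
  for (col in c("trial", "block", "start_state", "action1", "key1", "planet",
                "miss1", "miss2"))
    df[[col]] <- as.integer(df[[col]])
  for (col in c("reward", "points", "rt1_ms", "rt2_ms"))
    df[[col]] <- as.numeric(df[[col]])

  bad1 <- df$miss1 == 1 &
    (!is.na(df$action1) | !is.na(df$rt1_ms) | !is.na(df$reward))
  if (any(bad1))
    stop("rows with miss1 = 1 but recorded action1/rt1_ms/reward",
         call. = FALSE)
  bad2 <- df$miss2 == 1 & (!is.na(df$rt2_ms) | !is.na(df$reward))
  if (any(bad2))
    stop("rows with miss2 = 1 but recorded rt2_ms/reward", call. = FALSE)

  ids <- unique(df$participant)
  lapply(ids, function(id) {
    sub <- df[df$participant == id, ]
    if (!identical(sub$trial, seq_len(nrow(sub)) - 1L))
      stop("non-contiguous trial indices for participant ", id, call. = FALSE)
    obs <- sub[, setdiff(choice_csv_columns(), c("participant", "group"))]
    rownames(obs) <- NULL
    make_dataset(id, sub$group[1], sequence, obs)
  })
}

#' Write a cohort ground-truth table as CSV
#' @param truth Table from [draw_cohort_truth()].
#' @param path Output path.
#' @return `path`, invisibly.
#' @export
write_truth_csv <- function(truth, path) {
  utils::write.csv(truth, path, row.names = FALSE, na = "")
  invisible(path)
}

#' Run the full synthetic pipeline
#'
#' Executes the stages simulate (cohort generation), fit (per-agent MAP
#' estimation), recover (true-vs-recovered parameter report) and analyze
#' (effect-coded hierarchical regression of model-based weights), writing
#' every artifact as CSV/JSON under `output_dir` and recording them in a
#' JSON manifest with per-stage seeds. All randomness derives from
#' `global_seed` through named substreams, so a rerun with the same
#' configuration reproduces the numeric outputs exactly. On a stage
#' failure the manifest still records the completed stages before the
#' error propagates.
#'
#' @param task A [task_config()].
#' @param cohort A [cohort_spec()].
#' @param fitting List of [fit_map()] settings: `variant`, `n_restarts`,
#'   optional `priors`, `control`.
#' @param analysis List of [fit_hierarchical_lm()] settings: `chains`,
#'   `iter`, `warmup`.
#' @param output_dir Writable output directory (created if needed).
#' @param global_seed Integer master seed.
#' @return The manifest (named list), invisibly; also written as
#'   `manifest.json`.
#' @export
run_pipeline <- function(task = task_config(), cohort = cohort_spec(),
                         fitting = list(variant = "standard", n_restarts = 20L),
                         analysis = list(chains = 2L, iter = 1000L,
                                         warmup = 500L),
                         output_dir, global_seed = 1L) {
  dir.create(output_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list(global_seed = global_seed, stages = list(), files = list())
  emit <- function() {
    jsonlite::write_json(manifest, file.path(output_dir, "manifest.json"),
                         auto_unbox = TRUE, digits = NA, pretty = TRUE)
  }
  record <- function(stage, seed, files) {
    manifest$stages[[stage]] <<- list(seed = seed, files = files)
    manifest$files <<- c(manifest$files, files)
    emit()
  }
  fail <- function(stage, e) {
    manifest$error <<- list(stage = stage, message = conditionMessage(e))
    emit()
    stop("pipeline stage '", stage, "' failed: ", conditionMessage(e),
         call. = FALSE)
  }

  # simulate
  seed_sim <- derive_seed(global_seed, "simulate")
  cohort_out <- tryCatch({
    co <- simulate_cohort(cohort, task, seed = seed_sim)
    write_choice_csv(co$datasets, file.path(output_dir, "cohort.csv"))
    write_truth_csv(co$truth, file.path(output_dir, "truth.csv"))
    utils::write.csv(sequence_to_df(co$datasets[[1]]$sequence),
                     file.path(output_dir, "sequence.csv"), row.names = FALSE)
    co
  }, error = function(e) fail("simulate", e))
  record("simulate", seed_sim, c("cohort.csv", "truth.csv", "sequence.csv"))

  # fit
  seed_fit <- derive_seed(global_seed, "fit")
  fits <- tryCatch({
    variant <- fitting$variant %||% "standard"
    priors <- fitting$priors %||% prior_spec()
    fits <- lapply(seq_along(cohort_out$datasets), function(i) {
      fit_map(cohort_out$datasets[[i]], variant = variant, priors = priors,
              n_restarts = fitting$n_restarts %||% 20L,
              seed = derive_seed(seed_fit, paste0("fit", i)),
              control = fitting$control %||% list())
    })
    tab <- do.call(rbind, lapply(fits, function(f) {
      data.frame(participant = f$participant_id, group = f$group,
                 t(f$params_hat), log_posterior = f$log_posterior,
                 log_likelihood = f$log_likelihood, aic = aic(f),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(tab, file.path(output_dir, "fits.csv"), row.names = FALSE)
    fits
  }, error = function(e) fail("fit", e))
  record("fit", seed_fit, "fits.csv")

  # recover
  tryCatch({
    lay <- variant_layout(fitting$variant %||% "standard")
    rec <- do.call(rbind, lapply(fits, function(f) f$params_hat[lay$name]))
    common <- intersect(lay$name, names(cohort_out$truth))
    rep_df <- do.call(rbind, lapply(common, function(p) {
      tv <- cohort_out$truth[[p]]
      data.frame(parameter = p, correlation = stats::cor(tv, rec[, p]),
                 bias = mean(rec[, p] - tv),
                 rmse = sqrt(mean((rec[, p] - tv)^2)),
                 stringsAsFactors = FALSE)
    }))
    utils::write.csv(rep_df, file.path(output_dir, "recovery.csv"),
                     row.names = FALSE)
    jsonlite::write_json(rep_df, file.path(output_dir, "recovery.json"),
                         digits = NA, pretty = TRUE)
  }, error = function(e) fail("recover", e))
  record("recover", NA, c("recovery.csv", "recovery.json"))

  # analyze
  seed_an <- derive_seed(global_seed, "analyze")
  tryCatch({
    tab <- omega_table(fits)
    reg <- analyze_omega_weights(tab, chains = analysis$chains %||% 2L,
                                 iter = analysis$iter %||% 1000L,
                                 warmup = analysis$warmup %||% 500L,
                                 seed = seed_an)
    utils::write.csv(reg$coefficients,
                     file.path(output_dir, "omega_regression.csv"),
                     row.names = FALSE)
    jsonlite::write_json(
      list(converged = reg$converged, coefficients = reg$coefficients),
      file.path(output_dir, "omega_regression.json"),
      digits = NA, pretty = TRUE)
  }, error = function(e) fail("analyze", e))
  record("analyze", seed_an, c("omega_regression.csv", "omega_regression.json"))

  invisible(manifest)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
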