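#' Task configuration for the two-step spaceship task
#'
#' Bundles the design constants of the sequential decision-making task: block
#' structure, reversal schedule range, reward random-walk parameters, stakes
#' multipliers and response deadlines. The defaults reproduce the published
#' design: 320 trials in four alternating stable/variable blocks of 80,
#' transition reversals every 6--14 trials in variable blocks, integer
#' rewards between 0 and 9 drifting as a reflected Gaussian walk with sd 2, and
#' stakes multipliers of 1 (low) and 5 (high).
#'
#' @param n_blocks Number of blocks.
#' @param trials_per_block Trials per block; must be divisible by 4 so that
#'   stakes can be exactly counterbalanced over the two start states.
#' @param block_order Character vector of length `n_blocks` with entries
#'   `"stable"` or `"variable"`.
#' @param reversal_interval Integer pair `(min, max)`: inclusive range of
#'   gaps, in trials, between transition reversals in variable blocks.
#' @param reward_walk_sd Standard deviation of the Gaussian walk increments
#'   (treasure units).
#' @param reward_bounds Integer pair `(lo, hi)`: reflecting boundaries of the
#'   reward walks.
#' @param stakes_multipliers Named integer vector `c(low = , high = )`
#'   converting treasure to points.
#' @param stage1_deadline,stage2_deadline Response deadlines in seconds.
#' @param seed Optional RNG seed attached to the config.
#'
#' @return An object of class `metarl_task_config` (a named list).
#' @export
task_config <- function(n_blocks = 4L,
                        trials_per_block = 80L,
                        block_order = c("stable", "variable", "stable", "variable"),
                        reversal_interval = c(6L, 14L),
                        reward_walk_sd = 2,
                        reward_bounds = c(0L, 9L),
                        stakes_multipliers = c(low = 1L, high = 5L),
                        stage1_deadline = 3,
                        stage2_deadline = 2,
                        seed = NULL) {
  cfg <- list(n_blocks = as.integer(n_blocks),
              trials_per_block = as.integer(trials_per_block),
              block_order = as.character(block_order),
              reversal_interval = as.integer(reversal_interval),
              reward_walk_sd = as.numeric(reward_walk_sd),
              reward_bounds = as.integer(reward_bounds),
              stakes_multipliers = stakes_multipliers,
              stage1_deadline = as.numeric(stage1_deadline),
              stage2_deadline = as.numeric(stage2_deadline),
              seed = if (is.null(seed)) NULL else as.integer(seed))
  class(cfg) <- "metarl_task_config"
  validate_task_config(cfg)
  cfg
}

validate_task_config <- function(cfg) {
  stopifnot(inherits(cfg, "metarl_task_config"))
  if (cfg$n_blocks < 1L) stop("n_blocks must be a positive integer", call. = FALSE)
  if (cfg$trials_per_block < 1L) stop("trials_per_block must be positive", call. = FALSE)
  if (length(cfg$block_order) != cfg$n_blocks)
    stop("block_order must have length n_blocks", call. = FALSE)
  if (!all(cfg$block_order %in% c("stable", "variable")))
    stop("block_order entries must be 'stable' or 'variable'", call. = FALSE)
  if (length(cfg$reversal_interval) != 2L ||
      cfg$reversal_interval[1] > cfg$reversal_interval[2])
    stop("reversal_interval must be (min, max) with min <= max", call. = FALSE)
  if (cfg$reward_walk_sd < 0) stop("reward_walk_sd must be non-negative", call. = FALSE)
  if (cfg$reward_bounds[1] >= cfg$reward_bounds[2])
    stop("reward_bounds must satisfy lo < hi", call. = FALSE)
  mult <- cfg$stakes_multipliers
  if (is.null(names(mult)) || !all(c("low", "high") %in% names(mult)))
    stop("stakes_multipliers must be named c(low = , high = )", call. = FALSE)
  if (any(mult < 1)) stop("stakes multipliers must be >= 1", call. = FALSE)
  invisible(cfg)
}

#' Total number of trials implied by a task configuration
#' @param config A [task_config()] object.
#' @return Integer: `n_blocks * trials_per_block`.
#' @export
n_trials <- function(config) {
  validate_task_config(config)
  config$n_blocks * config$trials_per_block
}

#' Read or write a task configuration as YAML or JSON
#'
#' The on-disk representation uses exactly the field names of
#' [task_config()]. Format is chosen from the file extension
#' (`.yaml`/`.yml` vs `.json`).
#'
#' @param path File path.
#' @return `read_task_config()` returns a `metarl_task_config`;
#'   `write_task_config()` returns `path` invisibly.
#' @export
read_task_config <- function(path) {
  raw <- if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::read_json(path, simplifyVector = TRUE)
  } else {
    yaml::read_yaml(path)
  }
  mult <- unlist(raw$stakes_multipliers)
  do.call(task_config, c(raw[setdiff(names(raw), "stakes_multipliers")],
                         list(stakes_multipliers = mult)))
}

#' @rdname read_task_config
#' @param config A `metarl_task_config`.
#' @export
write_task_config <- function(config, path) {
  validate_task_config(config)
  x <- unclass(config)
  x$stakes_multipliers <- as.list(x$stakes_multipliers)
  if (grepl("\\.json$", path, ignore.case = TRUE)) {
    jsonlite::write_json(x, path, auto_unbox = TRUE, digits = NA, null = "null")
  } else {
    yaml::write_yaml(x, path)
  }
  invisible(path)
}
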