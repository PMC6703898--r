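#' Hierarchical Bayesian linear regression via JAGS
#'
#' Gaussian-likelihood hierarchical linear model with a by-participant
#' random intercept and optional by-participant random slopes, sampled with
#' JAGS. The model is fitted in hierarchically centered form: predictors
#' that are constant within every participant (the intercept, group
#' membership, ...) enter a participant-level regression on which the
#' random intercept is centered, while within-participant predictors stay
#' at the trial level -- an equivalent parameterization that keeps the
#' Gibbs sampler well mixed. Weakly informative default priors: slope
#' coefficients `Normal(0, (10 * sd(y))^2)`, the intercept
#' `Normal(mean(y), (10 * sd(y))^2)` (centering the prior on the outcome
#' location, as standard regression defaults do), residual and
#' random-effect standard deviations `Uniform(0, 10 * sd(y))`.
#'
#' Convergence is assessed by the Gelman-Rubin statistic (all monitored
#' parameters R-hat < 1.1) and the effective sample size of every reported
#' coefficient (ESS >= 400); if either criterion fails, the number of
#' iterations is doubled once before the result is flagged.
#'
#' Categorical predictors must arrive numerically coded (effect codes
#' +/-0.5 or dummy codes 0/1) in `data`; the formula is taken at face
#' value.
#'
#' @param data Data frame with the outcome, predictors and grouping column.
#' @param formula Fixed-effects formula, e.g. `omega ~ age_c * stakes_c`.
#' @param group Name of the participant (grouping) column.
#' @param random_slopes Character vector of design-matrix column names
#'   (within-participant predictors) that also get by-participant random
#'   slopes; the random intercept is always included.
#' @param chains,iter,warmup MCMC layout: independent chains, total
#'   iterations per chain, warm-up iterations discarded.
#' @param seed RNG seed (controls the JAGS chain streams).
#' @param rhat_max,ess_min Convergence thresholds.
#' @param extend Double the iterations once if a criterion fails?
#' @return An object of class `metarl_regression`: list with
#'   `coefficients` (data frame `term`, `mean`, `ci_low`, `ci_high`,
#'   `rhat`, `ess`), `sigma` (posterior-mean residual sd), `converged`,
#'   `extended` and the MCMC layout.
#' @export
fit_hierarchical_lm <- function(data, formula, group = "participant",
                                random_slopes = NULL,
                                chains = 4L, iter = 2000L, warmup = 1000L,
                                seed = 1L, rhat_max = 1.1, ess_min = 400,
                                extend = TRUE) {
  stopifnot(warmup < iter, group %in% names(data))
  mf <- stats::model.frame(formula, data)
  y <- stats::model.response(mf)
  X <- stats::model.matrix(formula, mf)
  pid <- as.integer(factor(data[[group]]))
  J <- max(pid)

  missing_z <- setdiff(random_slopes, colnames(X))
  if (length(missing_z))
    stop("random_slopes not in design matrix: ",
         paste(missing_z, collapse = ", "), call. = FALSE)

  s_y <- stats::sd(y)
  if (!is.finite(s_y) || s_y <= 0) s_y <- max(abs(mean(y)), 1) * 1e-3
  scale <- 10 * s_y

  # split the design into participant-level and trial-level parts
  is_constant <- vapply(seq_len(ncol(X)), function(k) {
    all(abs(tapply(X[, k], pid, function(v) max(v) - min(v))) < 1e-12)
  }, logical(1))
  if (any(colnames(X)[is_constant] %in% random_slopes))
    stop("random slopes must be within-participant predictors", call. = FALSE)
  W <- X[match(seq_len(J), pid), is_constant, drop = FALSE]
  Xw <- X[, !is_constant, drop = FALSE]
  Zs <- X[, intersect(colnames(X), random_slopes), drop = FALSE]

  # pad empty blocks with a zero column so the JAGS model is unconditional;
  # the padded coefficient just samples its prior and is never reported
  pad_x <- ncol(Xw) == 0L
  if (pad_x) Xw <- matrix(0, nrow(X), 1, dimnames = list(NULL, ".pad"))
  pad_z <- ncol(Zs) == 0L
  if (pad_z) Zs <- matrix(0, nrow(X), 1, dimnames = list(NULL, ".pad"))

  model_string <- "
  model {
    for (i in 1:N) {
      mu[i] <- a[pid[i]] + inprod(Xw[i, ], bw) + inprod(Zs[i, ], s[pid[i], ])
      y[i] ~ dnorm(mu[i], tau_e)
    }
    for (j in 1:J) { a[j] ~ dnorm(inprod(W[j, ], g), tau_a) }
    for (k in 1:Pg) { g[k] ~ dnorm(g0[k], prec_b) }
    for (k in 1:Pw) { bw[k] ~ dnorm(0, prec_b) }
    for (j in 1:J) {
      for (k in 1:K) { s[j, k] ~ dnorm(0, tau_s[k]) }
    }
    for (k in 1:K) {
      sigma_s[k] ~ dunif(s_min, s_max)
      tau_s[k] <- pow(sigma_s[k], -2)
    }
    sigma_a ~ dunif(s_min, s_max)
    tau_a <- pow(sigma_a, -2)
    sigma_e ~ dunif(s_min, s_max)
    tau_e <- pow(sigma_e, -2)
  }"

  run <- function(n_iter, n_warmup) {
    g0 <- numeric(ncol(W))
    g0[colnames(W) == "(Intercept)"] <- mean(y)
    jdata <- list(y = as.numeric(y), pid = pid, N = length(y), J = J,
                  W = W, Pg = ncol(W), g0 = g0,
                  Xw = Xw, Pw = ncol(Xw), Zs = Zs, K = ncol(Zs),
                  prec_b = 1 / scale^2, s_max = scale,
                  s_min = scale * 1e-5)
    inits <- lapply(seq_len(chains), function(ch) {
      list(.RNG.name = "base::Mersenne-Twister",
           .RNG.seed = derive_seed(seed, paste0("chain", ch)))
    })
    jm <- rjags::jags.model(textConnection(model_string), data = jdata,
                            inits = inits, n.chains = chains,
                            n.adapt = max(200L, n_warmup %/% 2L),
                            quiet = TRUE)
    stats::update(jm, n.iter = n_warmup, progress.bar = "none")
    rjags::coda.samples(jm, c("g", "bw", "sigma_e", "sigma_a", "sigma_s"),
                        n.iter = n_iter - n_warmup, progress.bar = "none")
  }

  # map design-matrix terms to their monitored JAGS nodes
  term_of <- c(stats::setNames(sprintf("g[%d]", seq_len(ncol(W))),
                               colnames(W)),
               stats::setNames(sprintf("bw[%d]", seq_len(ncol(Xw))),
                               colnames(Xw)))
  term_of <- term_of[colnames(X)]

  # coda drops the "[1]" suffix on length-1 parameter vectors
  fix_names <- function(nm) {
    ifelse(nm %in% c("g", "bw", "sigma_s"), paste0(nm, "[1]"), nm)
  }

  summarize <- function(samples) {
    mat <- as.matrix(samples)
    colnames(mat) <- fix_names(colnames(mat))
    rhat <- tryCatch(
      coda::gelman.diag(samples, autoburnin = FALSE,
                        multivariate = FALSE)$psrf[, 1],
      error = function(e) stats::setNames(rep(NA_real_, ncol(mat)),
                                          colnames(mat)))
    names(rhat) <- fix_names(names(rhat))
    ess <- coda::effectiveSize(samples)
    names(ess) <- fix_names(names(ess))
    sub <- mat[, term_of, drop = FALSE]
    coefs <- data.frame(
      term = colnames(X),
      mean = colMeans(sub),
      ci_low = apply(sub, 2, stats::quantile, 0.025),
      ci_high = apply(sub, 2, stats::quantile, 0.975),
      rhat = unname(rhat[term_of]),
      ess = unname(ess[term_of]),
      stringsAsFactors = FALSE)
    rownames(coefs) <- NULL
    monitored <- names(rhat)
    if (pad_x) monitored <- setdiff(monitored, "bw[1]")
    if (pad_z) monitored <- setdiff(monitored, c("sigma_s[1]"))
    list(coefs = coefs, sigma = mean(mat[, "sigma_e"]),
         all_rhat = rhat[monitored])
  }

  ok <- function(s) {
    all(is.na(s$all_rhat) | s$all_rhat < rhat_max) &&
      all(s$coefs$ess >= ess_min)
  }

  sm <- summarize(run(iter, warmup))
  extended <- FALSE
  if (!ok(sm) && extend) {
    extended <- TRUE
    sm <- summarize(run(2L * iter, warmup))
  }

  out <- list(coefficients = sm$coefs, sigma = sm$sigma,
              converged = ok(sm), extended = extended,
              chains = chains, iter = if (extended) 2L * iter else iter,
              warmup = warmup, formula = formula)
  class(out) <- "metarl_regression"
  out
}

#' @export
print.metarl_regression <- function(x, ...) {
  cat("Hierarchical Bayesian regression (", x$chains, " chains, ",
      x$iter, " iterations, warmup ", x$warmup, ")\n", sep = "")
  cat("Converged:", x$converged,
      if (x$extended) "(iterations were doubled once)" else "", "\n\n")
  df <- x$coefficients
  df[, c("mean", "ci_low", "ci_high", "rhat")] <-
    round(df[, c("mean", "ci_low", "ci_high", "rhat")], 3)
  df$ess <- round(df$ess)
  print(df, row.names = FALSE)
  invisible(x)
}

#' Effect-coded metacontrol regression of model-based weights
#'
#' Regresses the fitted model-based weights on effect-coded age group,
#' stakes and transition-stability condition (full factorial) with a
#' by-participant random intercept -- the regression that quantifies
#' metacontrol: main effects of stakes and transition stability, and their
#' reduction in older adults as interaction terms with age group.
#'
#' @param table An [omega_table()].
#' @param ... Passed to [fit_hierarchical_lm()] (chains, iter, seed, ...).
#' @return A `metarl_regression`.
#' @export
analyze_omega_weights <- function(table, ...) {
  fit_hierarchical_lm(table, omega ~ age_c * stakes_c * transition_c,
                      group = "participant", ...)
}

#' Dummy-coded regression of revaluation-trial reaction times
#'
#' Regresses log second-stage reaction times from variable-transitions
#' blocks on dummy-coded age group (`old`) and revaluation trial
#' (`revaluation`) and their interaction, with a by-participant random
#' intercept and a random slope for the within-subject revaluation factor.
#' Optionally controls for the model-derived second-stage reward
#' expectation (response vigor).
#'
#' @param table An [rt_preprocess()] table (stacked over participants).
#' @param include_expectation Add `expectation` and its age interaction?
#' @param ... Passed to [fit_hierarchical_lm()].
#' @return A `metarl_regression`.
#' @export
analyze_revaluation_rt <- function(table, include_expectation = FALSE, ...) {
  fml <- if (include_expectation)
    log_rt2 ~ old * revaluation + old * expectation
  else log_rt2 ~ old * revaluation
  fit_hierarchical_lm(table, fml, group = "participant",
                      random_slopes = "revaluation", ...)
}
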