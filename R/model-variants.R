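#' @keywords internal
"_PACKAGE"

#' @useDynLib metarl, .registration = TRUE
#' @importFrom Rcpp sourceCpp
NULL

# Condition cells, ordered as (stakes, transition condition):
# low_stable, high_stable, low_variable, high_variable.
omega_cells <- function() {
  c("low_stable", "high_stable", "low_variable", "high_variable")
}

cell_of <- function(stakes, block_condition) {
  paste(stakes, block_condition, sep = "_")
}

#' Construct a standard hybrid-model parameter vector
#'
#' The standard model has ten free parameters: reward learning rate `alpha`,
#' eligibility-trace decay `lam`, transition learning rate `eta` (free only
#' in variable blocks; fixed at 1 in stable blocks), four condition-specific
#' model-based weights `omega` (one per stakes x transition cell), inverse
#' softmax temperature `beta`, choice stickiness `pi` and response
#' stickiness `rho`.
#'
#' @param alpha,lam,eta Learning rates in `[0, 1]`.
#' @param omega Model-based weights: either a single value recycled to all
#'   four cells or a length-4 vector ordered `low_stable, high_stable,
#'   low_variable, high_variable` (names optional).
#' @param beta Inverse softmax temperature, `>= 0`.
#' @param pi,rho Choice and response stickiness (unbounded).
#' @param eta_cf Optional counterfactual transition learning rate; by
#'   default equal to `eta` (the selected single-rate model). Supplying it
#'   yields the dual-rate parameter layout.
#' @return Named numeric vector in the layout of [variant_layout()].
#' @export
model_params <- function(alpha = 0.5, lam = 0.5, eta = 0.5, omega = 0.5,
                         beta = 2, pi = 0, rho = 0, eta_cf = NULL) {
  if (length(omega) == 1L) omega <- rep(omega, 4L)
  stopifnot(length(omega) == 4L)
  theta <- c(alpha = alpha, lam = lam, eta = eta,
             stats::setNames(as.numeric(omega), paste0("omega_", omega_cells())),
             beta = beta, pi = pi, rho = rho)
  if (!is.null(eta_cf)) theta <- c(theta, eta_cf = eta_cf)
  theta
}

#' Free-parameter layout of a model variant
#'
#' Three variants are supported. `standard`: `alpha`, `lam`, `eta`, `beta`,
#' `pi`, `rho` global plus four condition-specific `omega` (10 free
#' parameters). `exhaustive`: `alpha`, `lam`, `beta`, `pi`, `rho` and
#' `omega` each split over the four stakes x transition cells, plus `eta`
#' split over stakes within variable blocks (26 free parameters).
#' `dual_transition_rate`: the standard layout plus a separate
#' counterfactual transition learning rate `eta_cf` (11 free parameters).
#'
#' @param variant `"standard"`, `"exhaustive"` or `"dual_transition_rate"`.
#' @return Data frame with one row per free parameter: `name`, `family`
#'   (`"unit"`, `"positive"` or `"real"`; the support class used for priors
#'   and optimizer transforms).
#' @export
variant_layout <- function(variant = c("standard", "exhaustive",
                                       "dual_transition_rate")) {
  variant <- match.arg(variant)
  cells <- omega_cells()
  unit <- function(n) data.frame(name = n, family = "unit",
                                 stringsAsFactors = FALSE)
  pos <- function(n) data.frame(name = n, family = "positive",
                                stringsAsFactors = FALSE)
  real <- function(n) data.frame(name = n, family = "real",
                                 stringsAsFactors = FALSE)
  switch(variant,
    standard = rbind(unit(c("alpha", "lam", "eta", paste0("omega_", cells))),
                     pos("beta"), real(c("pi", "rho"))),
    dual_transition_rate =
      rbind(unit(c("alpha", "lam", "eta", "eta_cf", paste0("omega_", cells))),
            pos("beta"), real(c("pi", "rho"))),
    exhaustive = rbind(
      unit(c(paste0("alpha_", cells), paste0("lam_", cells),
             "eta_low", "eta_high", paste0("omega_", cells))),
      pos(paste0("beta_", cells)),
      real(c(paste0("pi_", cells), paste0("rho_", cells)))))
}

#' Number of free parameters of a model variant
#'
#' @inheritParams variant_layout
#' @return Integer: 10 (standard), 26 (exhaustive) or 11 (dual rate).
#' @export
count_free_params <- function(variant) {
  nrow(variant_layout(variant))
}

# Resolve a variant's flat parameter vector to per-trial parameter vectors.
# trials: the sequence's trial data frame. Returns a list of length-n
# numeric vectors alpha, lam, eta, eta_cf, beta, pi, rho, omega.
# eta (and eta_cf) are clamped to 1 on stable-block trials.
resolve_trial_params <- function(theta, variant, trials) {
  n <- nrow(trials)
  variable <- trials$block_condition == "variable"
  cell <- cell_of(trials$stakes, trials$block_condition)
  pick <- function(base) {
    if (base %in% names(theta)) rep(unname(theta[[base]]), n)
    else unname(theta[paste0(base, "_", cell)])
  }
  if (variant == "exhaustive") {
    eta <- rep(1, n)
    eta[variable] <- unname(theta[paste0("eta_", trials$stakes[variable])])
    eta_cf <- eta
  } else {
    eta <- ifelse(variable, unname(theta[["eta"]]), 1)
    eta_cf <- if (variant == "dual_transition_rate")
      ifelse(variable, unname(theta[["eta_cf"]]), 1) else eta
  }
  list(alpha = pick("alpha"), lam = pick("lam"),
       eta = eta, eta_cf = eta_cf,
       beta = pick("beta"), pi = pick("pi"), rho = pick("rho"),
       omega = unname(theta[paste0("omega_", cell)]))
}

check_params_in_support <- function(theta, variant) {
  lay <- variant_layout(variant)
  miss <- setdiff(lay$name, names(theta))
  if (length(miss))
    stop("missing parameters: ", paste(miss, collapse = ", "), call. = FALSE)
  v <- theta[lay$name]
  bad <- (lay$family == "unit" & (v < 0 | v > 1)) |
    (lay$family == "positive" & v < 0) | !is.finite(v)
  if (any(bad))
    stop("parameters out of bounds: ", paste(lay$name[bad], collapse = ", "),
         call. = FALSE)
  invisible(TRUE)
}
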