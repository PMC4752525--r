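#' Model parameters for the event-dependent Weibull frailty model
#'
#' The conditional hazard for subject `i`'s gap of rank `k`, given the
#' subject's frailty `nu_i`, is
#' \deqn{h(t \mid k, x_i, \nu_i) = \nu_i \, \alpha^{k-1}
#'   e^{\beta_0 + x_i'\beta} \, \gamma t^{\gamma-1},}
#' a Weibull proportional-hazards model with shape `gamma`, a
#' multiplicative event-dependence factor `alpha` per prior event, and a
#' mean-one gamma frailty with variance `theta`.  `beta` holds the six
#' covariate log-hazard ratios in the canonical order (`age_onset` per
#' raw year, then the `gender`, `marital`, `mode_onset`, `head_injury`,
#' `family_history` indicators); `beta0` is the baseline log-scale
#' intercept absorbed into the proportional-hazards term.
#'
#' @param beta numeric 6-vector of covariate coefficients (named or in
#'   canonical order).
#' @param gamma Weibull shape, > 0.
#' @param alpha event-dependence multiplier, > 0.
#' @param theta frailty variance, >= 0.
#' @param beta0 baseline intercept on the log-hazard scale.
#' @return a `frailty_params` object.
#' @export
model_params <- function(beta, gamma, alpha, theta, beta0 = 0) {
  beta <- as.numeric_named(beta, COVARIATE_COLS, "beta")
  stopifnot(is.finite(beta0), all(is.finite(beta)))
  if (!is.finite(gamma) || gamma <= 0) {
    stop("model_params: gamma must be positive", call. = FALSE)
  }
  if (!is.finite(alpha) || alpha <= 0) {
    stop("model_params: alpha must be positive", call. = FALSE)
  }
  if (!is.finite(theta) || theta < 0) {
    stop("model_params: theta must be non-negative", call. = FALSE)
  }
  structure(list(beta0 = as.numeric(beta0), beta = beta,
                 gamma = as.numeric(gamma), alpha = as.numeric(alpha),
                 theta = as.numeric(theta)),
            class = "frailty_params")
}

# Coerce a vector to a named numeric vector in canonical order.
as.numeric_named <- function(x, nm, what) {
  x <- unlist(x)
  if (length(x) != length(nm)) {
    stop(sprintf("%s must have length %d", what, length(nm)), call. = FALSE)
  }
  if (!is.null(names(x)) && all(nm %in% names(x))) {
    x <- x[nm]
  } else {
    names(x) <- nm
  }
  stats::setNames(as.numeric(x), nm)
}

#' @export
print.frailty_params <- function(x, ...) {
  cat("Event-dependent Weibull frailty model parameters\n")
  cat(sprintf("  intercept beta0 : %.4g\n", x$beta0))
  for (nm in names(x$beta)) {
    cat(sprintf("  beta[%s] : %.4g\n", nm, x$beta[[nm]]))
  }
  cat(sprintf("  gamma (Weibull shape)      : %.4g\n", x$gamma))
  cat(sprintf("  alpha (event dependence)   : %.4g\n", x$alpha))
  cat(sprintf("  theta (frailty variance)   : %.4g\n", x$theta))
  invisible(x)
}

# Linear predictor beta0 + x'beta for a covariate vector (named numeric,
# list, or one-row data frame).
linear_predictor <- function(x, params) {
  x <- as.numeric_named(x, COVARIATE_COLS, "x")
  params$beta0 + sum(x * params$beta)
}

#' Conditional hazard of the gap-time model
#'
#' Hazard of ending the rank-`k` gap at elapsed time `t`, given the
#' subject's covariates and frailty:
#' `nu * alpha^(k-1) * exp(beta0 + x'beta) * gamma * t^(gamma-1)`.
#'
#' @param t elapsed time within the gap (weeks), > 0; vectorised.
#' @param k event rank (1 = first gap), >= 1.
#' @param x covariate vector (named numeric, list, or one-row data frame
#'   with the six canonical covariates).
#' @param nu positive frailty multiplier.
#' @param params a [model_params()] object.
#' @return hazard rate per week.
#' @export
conditional_hazard <- function(t, k, x, nu, params) {
  if (any(t <= 0)) stop("conditional_hazard: t must be > 0", call. = FALSE)
  if (any(k < 1)) stop("conditional_hazard: k must be >= 1", call. = FALSE)
  if (any(nu <= 0)) stop("conditional_hazard: nu must be > 0", call. = FALSE)
  lp <- linear_predictor(x, params)
  nu * params$alpha^(k - 1) * exp(lp) * params$gamma * t^(params$gamma - 1)
}

#' Conditional cumulative hazard of the gap-time model
#'
#' `H(t) = nu * alpha^(k-1) * exp(beta0 + x'beta) * t^gamma`; the
#' derivative of `H` in `t` is [conditional_hazard()].
#'
#' @inheritParams conditional_hazard
#' @param t elapsed time within the gap (weeks), >= 0; vectorised.
#' @return dimensionless cumulative hazard, `H(0) = 0`.
#' @export
cumulative_hazard <- function(t, k, x, nu, params) {
  if (any(t < 0)) stop("cumulative_hazard: t must be >= 0", call. = FALSE)
  if (any(k < 1)) stop("cumulative_hazard: k must be >= 1", call. = FALSE)
  if (any(nu <= 0)) stop("cumulative_hazard: nu must be > 0", call. = FALSE)
  lp <- linear_predictor(x, params)
  nu * params$alpha^(k - 1) * exp(lp) * t^params$gamma
}

# Per-record frailty-free log hazard and cumulative hazard for a dataset,
# computed in log space.  Returns list(log_b, B, subject, event).
record_terms <- function(ds, params) {
  ds <- as.data.frame(ds)
  X <- as.matrix(ds[, COVARIATE_COLS, drop = FALSE])
  lp <- params$beta0 + drop(X %*% params$beta) +
    (ds$rank - 1) * log(params$alpha)
  logt <- log(ds$gap_weeks)
  list(
    log_b = lp + log(params$gamma) + (params$gamma - 1) * logt,
    B = exp(lp + params$gamma * logt),
    subject = ds$subject_id,
    event = ds$event
  )
}

#' Conditional log-likelihood given frailties
#'
#' Censored-survival log-likelihood of a gap dataset given the latent
#' per-subject frailties: each record contributes
#' `event * log h(t) - H(t)`.
#'
#' @param ds a `gap_dataset`.
#' @param params a [model_params()] object.
#' @param frailties named numeric vector of positive frailties, one per
#'   subject (names = subject ids).
#' @return the log-likelihood (a finite scalar).
#' @export
conditional_loglik <- function(ds, params, frailties) {
  if (nrow(ds) == 0) return(0)
  missing_nu <- setdiff(unique(ds$subject_id), names(frailties))
  if (length(missing_nu) > 0) {
    stop("conditional_loglik: missing frailty for subject(s): ",
         paste(missing_nu, collapse = ", "), call. = FALSE)
  }
  nu <- frailties[ds$subject_id]
  if (any(nu <= 0)) {
    stop("conditional_loglik: frailties must be positive", call. = FALSE)
  }
  tm <- record_terms(ds, params)
  sum(tm$event * (tm$log_b + log(nu))) - sum(nu * tm$B)
}

#' Marginal log-likelihood with the gamma frailty integrated out
#'
#' Under a mean-one gamma frailty with variance `theta`, the frailty
#' integrates out in closed form.  For subject `i` with `d_i` observed
#' events, frailty-free record hazards `b_ik` and cumulative hazards
#' `B_ik`,
#' \deqn{\log L_i = \sum_{\delta_{ik}=1} \log b_{ik}
#'   + \log\Gamma(1/\theta + d_i) - \log\Gamma(1/\theta)
#'   + d_i \log\theta - (1/\theta + d_i)\log(1 + \theta \sum_k B_{ik}).}
#' For `theta` below `1e-8` the degenerate-frailty limit (conditional
#' likelihood with all frailties 1) is used; the function is continuous
#' there.
#'
#' @inheritParams conditional_loglik
#' @return the log-likelihood (a finite scalar).
#' @export
marginal_loglik <- function(ds, params) {
  if (params$theta < 0) {
    stop("marginal_loglik: theta must be >= 0", call. = FALSE)
  }
  if (nrow(ds) == 0) return(0)
  theta <- params$theta
  if (theta < 1e-8) {
    nu1 <- stats::setNames(rep(1, n_subjects(ds)), unique(ds$subject_id))
    return(conditional_loglik(ds, params, nu1))
  }
  tm <- record_terms(ds, params)
  subj <- factor(tm$subject, levels = unique(tm$subject))
  d <- as.numeric(rowsum(tm$event, subj))
  Bsum <- as.numeric(rowsum(tm$B, subj))
  inv <- 1 / theta
  sum(tm$event * tm$log_b) +
    sum(lgamma(inv + d) - lgamma(inv) + d * log(theta) -
          (inv + d) * log1p(theta * Bsum))
}

#' Marginal (population-averaged) survival of a single gap
#'
#' With the gamma frailty integrated out, the survival function of a
#' rank-`k` gap is `S(t) = (1 + theta * B(t))^(-1/theta)`, where `B` is
#' the frailty-free cumulative hazard; as `theta -> 0` this tends to the
#' Weibull survival `exp(-B(t))`.
#'
#' @inheritParams conditional_hazard
#' @param t elapsed time (weeks), >= 0; vectorised.
#' @return survival probability in (0, 1].
#' @export
marginal_survival <- function(t, k, x, params) {
  if (any(t < 0)) stop("marginal_survival: t must be >= 0", call. = FALSE)
  B <- cumulative_hazard(t, k, x, nu = 1, params)
  if (params$theta < 1e-8) {
    exp(-B)
  } else {
    exp(-log1p(params$theta * B) / params$theta)
  }
}

#' Kendall's tau implied by the shared gamma frailty
#'
#' For two gap times sharing a mean-one gamma frailty with variance
#' `theta`, the population rank correlation is `theta / (theta + 2)`:
#' zero at `theta = 0` and increasing towards 1.
#'
#' @param theta frailty variance, >= 0; vectorised.
#' @return Kendall's tau in `[0, 1)`.
#' @export
kendalls_tau <- function(theta) {
  if (any(theta < 0)) stop("kendalls_tau: theta must be >= 0", call. = FALSE)
  theta / (theta + 2)
}
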