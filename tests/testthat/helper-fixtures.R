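# Shared fixtures and independent oracles, built in code at test time.

covariate_names <- c("age_onset", "gender", "marital", "mode_onset",
                     "head_injury", "family_history")

zero_covariates <- function(subject_id, age = 1) {
  data.frame(subject_id = subject_id, age_onset = age, gender = 0,
             marital = 0, mode_onset = 0, head_injury = 0,
             family_history = 0, stringsAsFactors = FALSE)
}

# Two subjects, two observed gaps each.
make_toy_dataset <- function() {
  gap_dataset(data.frame(
    subject_id = c("A", "A", "B", "B"),
    rank = c(1, 2, 1, 2),
    gap_weeks = c(12.5, 30, 55, 8),
    event = c(1, 1, 1, 1),
    age_onset = c(20, 20, 31, 31),
    gender = c(1, 1, 0, 0),
    marital = c(1, 1, 0, 0),
    mode_onset = c(0, 0, 1, 1),
    head_injury = c(0, 0, 1, 1),
    family_history = c(0, 0, 0, 0),
    stringsAsFactors = FALSE))
}

# Random small dataset with arbitrary covariates and gap patterns.
random_small_dataset <- function(n_subj = 4, max_events = 4) {
  rows <- do.call(rbind, lapply(seq_len(n_subj), function(j) {
    k <- sample(seq_len(max_events), 1)
    ev <- c(rep(1, k - 1), sample(0:1, 1))
    if (sum(ev) == 0) ev[1] <- 1
    data.frame(subject_id = sprintf("S%02d", j), rank = seq_len(k),
               gap_weeks = stats::rexp(k, 0.2) + 0.3, event = ev,
               stringsAsFactors = FALSE)
  }))
  covs <- data.frame(
    subject_id = sprintf("S%02d", seq_len(n_subj)),
    age_onset = stats::runif(n_subj, 12, 40),
    gender = stats::rbinom(n_subj, 1, 0.5),
    marital = stats::rbinom(n_subj, 1, 0.5),
    mode_onset = stats::rbinom(n_subj, 1, 0.5),
    head_injury = stats::rbinom(n_subj, 1, 0.5),
    family_history = stats::rbinom(n_subj, 1, 0.5),
    stringsAsFactors = FALSE)
  gap_dataset(merge(rows, covs))
}

random_params <- function() {
  model_params(beta = c(stats::runif(1, 0.01, 0.08),
                        stats::runif(5, -0.6, 0.6)),
               gamma = stats::runif(1, 0.6, 1.5),
               alpha = stats::runif(1, 0.7, 3),
               theta = stats::runif(1, 0.05, 1.2),
               beta0 = stats::runif(1, -4, -1))
}

# Independent quadrature oracle for the marginal log-likelihood: numeric
# integration over the frailty per subject, normalised at the peak of
# the log-integrand for stability.
quad_marginal_loglik <- function(ds, params) {
  ds <- as.data.frame(ds)
  theta <- params$theta
  total <- 0
  for (s in unique(ds$subject_id)) {
    sub <- ds[ds$subject_id == s, , drop = FALSE]
    X <- as.matrix(sub[, covariate_names, drop = FALSE])
    lp <- params$beta0 + drop(X %*% params$beta) +
      (sub$rank - 1) * log(params$alpha)
    b <- exp(lp) * params$gamma * sub$gap_weeks^(params$gamma - 1)
    B <- exp(lp) * sub$gap_weeks^params$gamma
    d <- sum(sub$event)
    SB <- sum(B)
    log_f <- function(nu) {
      d * log(nu) - nu * SB +
        stats::dgamma(nu, shape = 1 / theta, rate = 1 / theta, log = TRUE)
    }
    peak <- stats::optimize(log_f, c(1e-12, 60), maximum = TRUE)$objective
    I <- stats::integrate(function(nu) exp(log_f(nu) - peak), 0, Inf,
                          rel.tol = 1e-12, abs.tol = 0)$value
    total <- total + sum(sub$event * log(b)) + peak + log(I)
  }
  total
}

# Small synthetic cohort for sampler tests (kept light).
small_cohort <- function(n = 50, seed = 42, theta = 0.3) {
  tr <- default_truth()
  tr$theta <- theta
  simulate_cohort(n_subjects = n, params = tr, seed = seed)
}
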