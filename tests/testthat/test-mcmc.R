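test_that("frailty Gibbs draws follow the conjugate gamma conditional", {
  # 1e5 identical subjects: 3 events, cumulative hazard sum 2.5, theta 0.5
  # -> full conditional Gamma(shape 1/0.5 + 3 = 5, rate 1/0.5 + 2.5 = 4.5)
  n <- 1e5
  one <- data.frame(rank = 1:4, gap_weeks = c(0.8, 0.9, 0.5, 0.3),
                    event = c(1, 1, 1, 0))
  stopifnot(sum(one$gap_weeks) == 2.5)
  idx <- rep(seq_len(n), each = 4)
  long <- data.frame(subject_id = sprintf("S%06d", idx),
                     one[rep(1:4, n), ],
                     zero_covariates("x", age = 1)[rep(1, 4 * n), -1],
                     row.names = NULL)
  ds <- gap_dataset(long)
  p <- model_params(beta = rep(0, 6), gamma = 1, alpha = 1, theta = 0.5)
  set.seed(99)
  nu <- gibbs_update_frailties(ds, p)
  expect_length(nu, n)
  expect_gt(stats::ks.test(nu, "pgamma", shape = 5, rate = 4.5)$p.value,
            0.001)
  expect_equal(mean(nu), 5 / 4.5, tolerance = 4 * sqrt(5 / 4.5^2 / n) / (5 / 4.5))

  # theta = 0 degenerates to unit frailties
  p0 <- model_params(beta = rep(0, 6), gamma = 1, alpha = 1, theta = 0)
  expect_true(all(gibbs_update_frailties(make_toy_dataset(), p0) == 1))
})

test_that("single-step Metropolis updates behave at the extremes", {
  set.seed(3)
  ds <- random_small_dataset(5)
  p <- random_params()
  nu <- gibbs_update_frailties(ds, p)

  # vanishing proposal scale: every proposal is accepted
  acc <- replicate(50, mh_update_block(p, "beta", ds, nu,
                                       scale = 1e-12)$accept)
  expect_true(all(acc))

  # fixed seed gives a bit-identical trajectory
  run_traj <- function() {
    set.seed(17)
    st <- p
    out <- numeric(20)
    for (i in 1:20) {
      st <- mh_update_block(st, "log_gamma", ds, nu, scale = 0.3)$params
      out[i] <- st$gamma
    }
    out
  }
  expect_identical(run_traj(), run_traj())

  # positivity preserved under log-scale proposals
  st <- p
  set.seed(8)
  for (i in 1:50) {
    st <- mh_update_block(st, "log_alpha", ds, nu, scale = 1)$params
  }
  expect_gt(st$alpha, 0)
})

test_that("theta updates track the frailty dispersion", {
  set.seed(12)
  pr <- prior_spec()
  ds <- make_toy_dataset()  # unused content; theta target depends on nu only

  run_theta_chain <- function(frailties, n_steps, start = 0.2,
                              scale = 0.15) {
    p <- model_params(rep(0, 6), 1, 1, start)
    out <- numeric(n_steps)
    for (i in seq_len(n_steps)) {
      p <- update_theta(p, ds, frailties, pr, scale = scale)$params
      out[i] <- p$theta
    }
    out
  }

  # frailties all exactly 1: posterior concentrates near 0
  th1 <- run_theta_chain(stats::setNames(rep(1, 300), 1:300), 1500)
  expect_lt(stats::median(th1[-(1:300)]), 0.02)

  # frailties drawn with variance 0.206, n = 1e4: posterior centres there
  nu <- stats::rgamma(1e4, shape = 1 / 0.206, rate = 1 / 0.206)
  th2 <- run_theta_chain(stats::setNames(nu, seq_along(nu)), 2000,
                         scale = 0.05)
  expect_equal(mean(th2[-(1:500)]), 0.206, tolerance = 0.05)

  expect_error(update_theta(model_params(rep(0, 6), 1, 1, 0.2), ds,
                            c(a = -1, b = 2)), "positive")
})

test_that("runs are reproducible and invariant to record order", {
  ds <- small_cohort(n = 25, seed = 8)
  cfg <- mcmc_config(n_chains = 2, n_iter = 400, n_burnin = 150, seed = 21)
  d1 <- run_mcmc(ds, config = cfg)
  d2 <- run_mcmc(ds, config = cfg)
  expect_identical(d1$draws, d2$draws)

  perm <- as.data.frame(ds)[sample(nrow(ds)), ]
  d3 <- run_mcmc(gap_dataset(perm), config = cfg)
  expect_identical(d1$draws, d3$draws)
})

test_that("doubling the data shrinks posterior sds by about 1/sqrt(2)", {
  ds1 <- small_cohort(n = 60, seed = 31)
  ds2 <- small_cohort(n = 60, seed = 32)
  both <- as.data.frame(ds2)
  both$subject_id <- paste0(both$subject_id, "_rep")
  doubled <- gap_dataset(rbind(as.data.frame(ds1), both))

  cfg <- mcmc_config(n_chains = 2, n_iter = 3000, n_burnin = 1000,
                     seed = 77)
  sd1 <- summarize_posterior(run_mcmc(ds1, config = cfg))$sd
  sd2 <- summarize_posterior(run_mcmc(doubled, config = cfg))$sd
  beta_idx <- 2:7
  ratio <- mean(sd2[beta_idx] / sd1[beta_idx])
  expect_equal(ratio, 1 / sqrt(2), tolerance = 0.2)
})

test_that("all three update schemes agree on the posterior", {
  tr <- default_truth()
  tr$theta <- 0.3
  ds <- simulate_cohort(n_subjects = 60, params = tr, seed = 42)
  cfg <- mcmc_config(n_chains = 2, n_iter = 4000, n_burnin = 1500,
                     seed = 7)
  cfg_cond <- mcmc_config(n_chains = 2, n_iter = 9000, n_burnin = 4000,
                          seed = 7)
  fits <- list(gibbs = run_mcmc(ds, config = cfg, method = "gibbs"),
               marginal = run_mcmc(ds, config = cfg, method = "marginal"),
               conditional = run_mcmc(ds, config = cfg_cond,
                                      method = "conditional"))
  sums <- lapply(fits, summarize_posterior)
  mcses <- lapply(names(fits), function(nm) {
    sums[[nm]]$sd / sqrt(mcmc_diagnostics(fits[[nm]])$ess)
  })
  names(mcses) <- names(fits)
  for (other in c("marginal", "conditional")) {
    dmean <- abs(sums$gibbs$mean - sums[[other]]$mean)
    tol <- pmax(6 * sqrt(mcses$gibbs^2 + mcses[[other]]^2),
                0.35 * sums$gibbs$sd)
    expect_true(all(dmean <= tol),
                info = sprintf("gibbs vs %s: worst ratio %.2f", other,
                               max(dmean / tol)))
  }
})

test_that("posterior summaries are correct on known draw sets", {
  fake <- function(mat, chains = 2) {
    structure(list(draws = mat,
                   chain = rep(seq_len(chains), each = nrow(mat) / chains),
                   config = mcmc_config(n_chains = chains, n_iter = 2,
                                        n_burnin = 1),
                   method = "gibbs"),
              class = "frailty_draws")
  }
  cols <- c("beta0", covariate_names, "gamma", "alpha", "theta")

  m <- matrix(rep(c(2, rep(0.5, 6), 1.2, 1.1, 0.3), each = 200), 200)
  colnames(m) <- cols
  s <- summarize_posterior(fake(m))
  expect_equal(s$mean[1], 2)
  expect_equal(s$sd, rep(0, 10))
  expect_equal(s$lower, s$upper)

  expect_error(summarize_posterior(fake(m[1:50, ])), "at least 100")

  set.seed(10)
  m2 <- matrix(stats::rnorm(1e5 * 10), 1e5)
  colnames(m2) <- cols
  s2 <- summarize_posterior(fake(m2))
  expect_equal(s2$lower, rep(-1.96, 10), tolerance = 0.02)
  expect_equal(s2$upper, rep(1.96, 10), tolerance = 0.02)

  # interval excluding the null flags significance: the reported gender
  # interval (0.146, 0.686) excludes 0
  m3 <- m2
  m3[, "gender"] <- stats::qnorm(stats::runif(1e5), 0.418, 0.137)
  s3 <- summarize_posterior(fake(m3))
  g <- s3[s3$parameter == "gender", ]
  expect_true(g$significant)
  expect_equal(c(g$lower, g$upper), c(0.146, 0.686), tolerance = 0.01)
})

test_that("diagnostics detect mixing and independence properly", {
  fake <- function(mat, chains) {
    structure(list(draws = mat,
                   chain = rep(seq_len(chains), each = nrow(mat) / chains),
                   config = mcmc_config(n_chains = chains, n_iter = 2,
                                        n_burnin = 1),
                   method = "gibbs"),
              class = "frailty_draws")
  }
  cols <- c("beta0", covariate_names, "gamma", "alpha", "theta")
  set.seed(4)

  iid <- matrix(stats::rnorm(8000 * 10), 8000)
  colnames(iid) <- cols
  d <- mcmc_diagnostics(fake(iid, 2))
  expect_true(all(abs(d$rhat - 1) < 0.01))
  expect_true(all(abs(d$ess - 8000) / 8000 < 0.2))

  disjoint <- iid
  disjoint[4001:8000, ] <- disjoint[4001:8000, ] + 10
  d2 <- mcmc_diagnostics(fake(disjoint, 2))
  expect_true(all(d2$rhat > 1.1))
  expect_true(all(d2$flag))
})

test_that("recovery reports tabulate truth, coverage and error", {
  tr <- default_truth()
  rep <- recover_params(truth = tr, n_subjects = 40,
                        config = mcmc_config(n_chains = 2, n_iter = 800,
                                             n_burnin = 300, seed = 5))
  expect_s3_class(rep, "recovery_report")
  expect_equal(nrow(rep), 10)
  expect_equal(rep$truth[rep$parameter == "gamma"], 0.860)
  expect_type(rep$covered, "logical")
  expect_true(all(rep$abs_error >= 0))
  expect_s3_class(attr(rep, "diagnostics"), "frailty_diagnostics")
})
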