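make_decomp_obs <- function(seed, n = 40, beta1 = 4.2, beta2 = -0.12,
                            sigma = 0.3) {
  set.seed(seed)
  cc <- runif(n, 11, 35)
  tibble::tibble(experiment = "EX1", day = seq_len(n), c_content = cc,
                 cu = exp(beta1 + beta2 * cc + rnorm(n, 0, sigma)),
                 cu_censored = FALSE, cu_limit = 0.01)
}

test_that("detection-limit substitution is exact and idempotent", {
  obs <- make_decomp_obs(1)
  expect_identical(substitute_detection_limits(obs), obs)

  obs$cu_censored[3] <- TRUE
  obs$cu[3] <- 0.0001
  obs$cu_limit <- 0.001
  out <- substitute_detection_limits(obs)
  expect_equal(out$cu[3], 0.001)
  expect_true(out$cu_censored[3])
  expect_identical(substitute_detection_limits(out), out)

  obs$cu_limit <- NA_real_
  expect_error(substitute_detection_limits(obs), "no positive detection limit")
})

test_that("decomposition log-likelihood matches its closed form and oracle", {
  # single observation exactly on the line with unit variance
  expect_equal(decomp_loglik(2, 0.1, 1, 10, exp(2 + 0.1 * 10)),
               -0.5 * log(2 * pi))
  # naive per-observation summation oracle at arbitrary parameter points
  obs <- make_decomp_obs(2)
  for (i in 1:5) {
    set.seed(i)
    b1 <- rnorm(1, 4, 1); b2 <- rnorm(1, -0.1, 0.05)
    s2 <- exp(rnorm(1, -1, 0.5))
    naive <- sum(dnorm(log(obs$cu), b1 + b2 * obs$c_content, sqrt(s2),
                       log = TRUE))
    expect_equal(decomp_loglik(b1, b2, s2, obs$c_content, obs$cu), naive)
  }
  # quadratic decay away from the truth on noiseless data
  cc <- c(15, 20, 25, 30)
  y <- exp(4 - 0.1 * cc)
  lls <- vapply(c(0, 0.01, 0.05, 0.1),
                function(d) decomp_loglik(4, -0.1 - d, 1, cc, y), numeric(1))
  expect_true(all(diff(lls) < 0))
  expect_error(decomp_loglik(1, 1, 0, cc, y), "positive")
  expect_error(decomp_loglik(1, 1, 1, cc, -y), "positive")
})

test_that("the Gibbs sampler reproduces the conjugate closed-form posterior", {
  for (i in 1:4) {
    obs <- make_decomp_obs(100 + i, n = 25,
                           beta1 = rnorm(1, 4, 1),
                           beta2 = rnorm(1, 0, 0.15),
                           sigma = runif(1, 0.1, 0.5))
    fit <- fit_decomposition(obs, "cu", "EX1",
                             mcmc = fast_decomp_config(200 + i))
    post <- oracle_nig_posterior(obs$c_content, log(obs$cu))
    d <- fit$draws
    expect_lt(abs(mean(d$beta1) - post$beta_mean[1]), 3 * mcse(d$beta1))
    expect_lt(abs(mean(d$beta2) - post$beta_mean[2]), 3 * mcse(d$beta2))
    expect_lt(abs(mean(d$sigma2) - post$sigma2_mean), 3 * mcse(d$sigma2))
    expect_lt(abs(sd(d$beta2) - post$beta_sd[2]),
              3 * post$beta_sd[2] / sqrt(nrow(d)) + mcse(d$beta2))
  }
})

test_that("noiseless data concentrate the posterior on the OLS solution", {
  cc <- seq(12, 34, length.out = 20)
  obs <- tibble::tibble(experiment = "EX2", day = 1, c_content = cc,
                        pb = exp(5.65 - 0.277 * cc),
                        pb_censored = FALSE, pb_limit = 0.005)
  fit <- fit_decomposition(obs, "pb", "EX2",
                           mcmc = fast_decomp_config(7))
  expect_lt(abs(fit$summary$mean[1] - 5.65), 0.01)
  expect_lt(abs(fit$summary$mean[2] + 0.277), 5e-4)
  expect_lt(fit$summary$mean[3], 1e-2)
})

test_that("the full schedule retains a balanced 10,000 draws and converges", {
  cfg <- decomp_mcmc_config(seed = 1)
  idx <- zmetals:::retained_indices(cfg)
  counts <- lengths(idx)
  expect_equal(sum(counts), 10000L)
  expect_lte(diff(range(counts)), 1L)

  obs <- make_decomp_obs(55, n = 60)
  fit <- fit_decomposition(obs, "cu", "EX1", mcmc = cfg)
  expect_equal(nrow(fit$draws), 10000L)
  expect_lte(diff(range(table(fit$draws$chain))), 1L)
  expect_true(all(fit$summary$rhat < 1.1))
  expect_true(all(fit$draws$sigma2 > 0))
})

test_that("shifting carbon content reparameterizes the intercept only", {
  obs <- make_decomp_obs(77, n = 50)
  shift <- 10
  obs2 <- obs
  obs2$c_content <- obs$c_content + shift
  f1 <- fit_decomposition(obs, "cu", "EX1", mcmc = fast_decomp_config(8))
  f2 <- fit_decomposition(obs2, "cu", "EX1", mcmc = fast_decomp_config(8))
  b2 <- mean(f1$draws$beta2)
  tol <- 4 * (mcse(f1$draws$beta1) + shift * mcse(f1$draws$beta2))
  expect_lt(abs(mean(f2$draws$beta1) - (mean(f1$draws$beta1) - b2 * shift)),
            tol)
  expect_lt(abs(mean(f2$draws$beta2) - b2), 4 * mcse(f1$draws$beta2))
  expect_lt(abs(mean(f2$draws$sigma2) - mean(f1$draws$sigma2)),
            4 * mcse(f1$draws$sigma2))
})

test_that("degenerate inputs are refused with informative messages", {
  obs <- make_decomp_obs(9, n = 3)
  expect_error(fit_decomposition(obs, "cu", "EX1"), "at least 4")
  obs <- make_decomp_obs(10, n = 10)
  obs$cu_censored <- TRUE
  expect_error(fit_decomposition(obs, "cu", "EX1"), "below the detection")
})

test_that("slope signs are recovered across the default truth table", {
  truth <- default_decomp_truth()
  ok <- 0L
  runs <- 0L
  for (i in seq_len(nrow(truth))) {
    for (rep in 1:2) {
      cfg <- simulation_config(seed = 3000 + 17 * i + rep, n_obs = 25L)
      dec <- simulate_decomposition(cfg, metals = truth$metal[i])
      fit <- fit_decomposition(dec, truth$metal[i], truth$experiment[i],
                               mcmc = fast_decomp_config(cfg$seed))
      s <- fit$summary[fit$summary$parameter == "beta2", ]
      runs <- runs + 1L
      if (sign(truth$beta2[i]) > 0 && s$lower > 0) ok <- ok + 1L
      if (sign(truth$beta2[i]) < 0 && s$upper < 0) ok <- ok + 1L
    }
  }
  expect_gte(ok / runs, 0.9)
})
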