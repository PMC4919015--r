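test_that("delta notation converts ratios and round-trips", {
  expect_equal(delta_from_ratio(0.011, 0.011), 0)
  expect_equal(delta_from_ratio(1.001 * 0.011, 0.011), 1)
  r_std <- 0.0112372  # PDB 13C/12C
  for (d in c(-22.2, -13.4, -9.7, 0, 5)) {
    expect_equal(delta_from_ratio(ratio_from_delta(d, r_std), r_std), d)
  }
  expect_error(delta_from_ratio(0.01, 0), "positive")
})

test_that("mixing log-likelihood matches the per-observation oracle", {
  set.seed(31)
  sources <- default_source_params()
  cfg <- simulation_config(seed = 31, r_true = 0.4)
  il <- simulate_initial_leaves(cfg)
  for (tracers in list(c("c_content", "d13c"),
                       c("c_content", "d13c", "n_content", "d15n"))) {
    for (r in runif(10)) {
      expect_equal(mixing_loglik(r, sources, il, tracers),
                   oracle_mixing_loglik(r, sources, il, tracers))
    }
  }
})

test_that("mixing likelihood handles degenerate and symmetric cases", {
  # zero source variance: maximal exactly where the mixture mean hits the
  # observation, -Inf elsewhere (reported, not an error)
  sources <- tibble::tibble(
    source = c("eelgrass", "epiphytes"), tracer = "c_content",
    mean = c(40, 20), sd = 0, n = 5L)
  il <- tibble::tibble(c_content = 30)
  expect_equal(mixing_loglik(0.5, sources, il, "c_content"), 0)
  expect_identical(mixing_loglik(0.3, sources, il, "c_content"), -Inf)

  # symmetric sources with the observation at the midpoint
  sources$sd <- c(2, 2)
  rr <- seq(0.05, 0.45, by = 0.1)
  expect_equal(mixing_loglik(rr, sources, il, "c_content"),
               mixing_loglik(1 - rr, sources, il, "c_content"))
})

test_that("the weight-ratio sampler matches grid quadrature", {
  cfg <- simulation_config(seed = 41, r_true = 0.3)
  il <- simulate_initial_leaves(cfg)
  sources <- cfg$source_params
  fit <- fit_wre(il, sources, mcmc = wre_mcmc_config(seed = 42))
  grid <- oracle_grid_posterior(sources, il, c("c_content", "d13c"))
  tol_mean <- 3 * mcse(fit$draws)
  expect_lt(abs(fit$summary$mean - grid$mean), tol_mean)
  expect_lt(abs(fit$summary$sd - grid$sd), 3 * grid$sd / sqrt(
    2 * (length(fit$draws) - 1)) + tol_mean)
  # recovery: posterior mean within 3 posterior SDs of the truth
  expect_lt(abs(fit$summary$mean - 0.3), 3 * fit$summary$sd)
  # schedule contract
  expect_equal(fit$diagnostics$retained, 10000L)
  expect_true(all(fit$draws >= 0 & fit$draws <= 1))
  expect_gt(fit$diagnostics$acceptance_rate, 0.2)
  expect_lt(fit$diagnostics$acceptance_rate, 0.5)
})

test_that("swapping source labels reflects the posterior about one half", {
  cfg <- simulation_config(seed = 43, r_true = 0.25)
  il <- simulate_initial_leaves(cfg)
  sources <- cfg$source_params
  swapped <- sources
  swapped$source <- ifelse(sources$source == "eelgrass",
                           "epiphytes", "eelgrass")
  f1 <- fit_wre(il, sources, mcmc = fast_wre_config(1))
  f2 <- fit_wre(il, swapped, mcmc = fast_wre_config(2))
  tol <- 3 * (mcse(f1$draws) + mcse(f2$draws))
  expect_lt(abs(f1$summary$mean - (1 - f2$summary$mean)), tol)
  expect_lt(abs(f1$summary$sd - f2$summary$sd), tol)
})

test_that("an uninformative tracer leaves the posterior unchanged", {
  cfg <- simulation_config(seed = 44, r_true = 0.6)
  il <- simulate_initial_leaves(cfg)
  sources <- cfg$source_params
  # make d15n identical in both sources and centre the IL values on it
  sources$mean[sources$tracer == "d15n"] <- 7.5
  sources$sd[sources$tracer == "d15n"] <- 0.5
  il$d15n <- rnorm(nrow(il), 7.5, 0.5)
  f_base <- fit_wre(il, sources, tracers = c("c_content", "d13c"),
                    mcmc = fast_wre_config(3))
  f_plus <- fit_wre(il, sources, tracers = c("c_content", "d13c", "d15n"),
                    mcmc = fast_wre_config(4))
  expect_lt(abs(f_base$summary$mean - f_plus$summary$mean),
            3 * (mcse(f_base$draws) + mcse(f_plus$draws)))
})

test_that("identical sources yield the uniform prior and are flagged", {
  sources <- default_source_params()
  sources$mean <- rep(sources$mean[1:4], 2)
  sources$sd <- rep(sources$sd[1:4], 2)
  il <- tibble::tibble(c_content = c(34, 36), d13c = c(-13, -14))
  fit <- fit_wre(il, sources, mcmc = wre_mcmc_config(seed = 5))
  expect_true(fit$diagnostics$non_identifiable)
  expect_lt(abs(fit$summary$lower - 0.025), 0.02)
  expect_lt(abs(fit$summary$upper - 0.975), 0.02)
  expect_lt(abs(fit$summary$mean - 0.5), 0.02)
})

test_that("posterior summaries implement the equal-tailed convention", {
  expect_error(summarize_posterior(numeric(0)), "no posterior draws")
  s <- summarize_posterior(rep(3.2, 10))
  expect_equal(unlist(s), c(mean = 3.2, sd = 0, lower = 3.2, upper = 3.2))
  set.seed(51)
  z <- rnorm(10000)
  s <- summarize_posterior(z)
  expect_lt(abs(s$lower + 1.96), 0.08)
  expect_lt(abs(s$upper - 1.96), 0.08)
  u <- runif(10000)
  expect_lt(abs(summarize_posterior(u)$mean - 0.5), 0.02)
})

test_that("weight-ratio coverage holds across true fractions", {
  hits <- 0L
  total <- 0L
  for (r_true in c(0.2, 0.5, 0.8)) {
    for (rep in 1:8) {
      cfg <- simulation_config(seed = 600 + 37 * rep + round(1000 * r_true),
                               r_true = r_true)
      il <- simulate_initial_leaves(cfg)
      fit <- fit_wre(il, cfg$source_params,
                     mcmc = fast_wre_config(cfg$seed))
      total <- total + 1L
      if (fit$summary$lower <= r_true && r_true <= fit$summary$upper) {
        hits <- hits + 1L
      }
    }
  }
  expect_gte(hits / total, 0.8)
})
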