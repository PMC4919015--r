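test_that("source draws respect configured moments and degenerate variance", {
  params <- default_source_params()
  params$sd <- 0
  cfg <- simulation_config(seed = 1, source_params = params)
  src <- simulate_sources(cfg)
  for (s in c("eelgrass", "epiphytes")) {
    for (tr in c("c_content", "d13c", "n_content", "d15n")) {
      expect_equal(unique(src[[tr]][src$source == s]),
                   params$mean[params$source == s & params$tracer == tr])
    }
  }

  # default variability: sample means within 3 standard errors
  cfg <- simulation_config(seed = 21)
  src <- simulate_sources(cfg)
  p <- cfg$source_params
  for (i in seq_len(nrow(p))) {
    x <- src[[p$tracer[i]]][src$source == p$source[i]]
    expect_lt(abs(mean(x) - p$mean[i]), 3 * p$sd[i] / sqrt(p$n[i]) + 1e-12)
  }
})

test_that("generators are deterministic in the seed and vary across seeds", {
  cfg <- simulation_config(seed = 7)
  expect_identical(simulate_sources(cfg), simulate_sources(cfg))
  expect_identical(simulate_initial_leaves(cfg), simulate_initial_leaves(cfg))
  expect_identical(simulate_decomposition(cfg), simulate_decomposition(cfg))
  expect_identical(simulate_sediment_cores(cfg),
                   simulate_sediment_cores(cfg))
  cfg2 <- simulation_config(seed = 8)
  expect_false(identical(simulate_sources(cfg)$d13c,
                         simulate_sources(cfg2)$d13c))
})

test_that("initial leaves are the configured convex combination of sources", {
  # boundary: r = 0 reproduces the eelgrass source exactly (zero variance)
  params <- default_source_params()
  params$sd <- 0
  cfg <- simulation_config(seed = 2, r_true = 0, source_params = params)
  il <- simulate_initial_leaves(cfg)
  expect_equal(unique(il$c_content), 35)
  expect_equal(unique(il$d13c), -13.4)

  # arithmetic: r = 0.5 with C means 35 and 20 gives exactly 27.5
  cfg <- simulation_config(seed = 2, r_true = 0.5, source_params = params)
  il <- simulate_initial_leaves(cfg)
  expect_equal(unique(il$c_content), 27.5)

  # per-replicate convex-combination invariant at stochastic sources
  cfg <- simulation_config(seed = 3, r_true = 0.192)
  il <- simulate_initial_leaves(cfg)
  expect_equal(attr(il, "r_true"), 0.192)
  sd_draws <- attr(il, "source_draws")
  for (tr in c("c_content", "d13c", "n_content", "d15n")) {
    expect_equal(il[[tr]],
                 (1 - 0.192) * sd_draws$eelgrass[[tr]] +
                   0.192 * sd_draws$epiphytes[[tr]])
  }
  expect_error(simulation_config(r_true = 1.2), "0, 1")
})

test_that("decomposition series follow the log-linear generative model", {
  # degenerate: zero coefficients and zero noise give 1 microgram/g exactly
  truth <- default_decomp_truth()
  truth$beta1 <- 0
  truth$beta2 <- 0
  truth$sigma2 <- 0
  cfg <- simulation_config(seed = 4, decomp_truth = truth)
  dec <- simulate_decomposition(cfg)
  for (m in c("cu", "zn", "cd", "pb")) expect_equal(unique(dec[[m]]), 1)

  # law of large numbers at fixed C: mean log concentration near the line
  truth <- default_decomp_truth()
  row <- truth[truth$metal == "pb" & truth$experiment == "EX2", ]
  cfg <- simulation_config(seed = 5, n_obs = 10000L, c_range = c(20, 20),
                           decomp_truth = truth)
  dec <- simulate_decomposition(cfg, metals = "pb")
  ex2 <- dec[dec$experiment == "EX2", ]
  expect_lt(abs(mean(log(ex2$pb)) - (row$beta1 + row$beta2 * 20)),
            3 * sqrt(row$sigma2) / sqrt(10000))

  # monotone trend in expectation for a negative slope
  cfg <- simulation_config(seed = 6, n_obs = 2000L)
  dec <- simulate_decomposition(cfg, metals = "pb")
  ex2 <- dec[dec$experiment == "EX2", ]
  lo <- ex2$c_content < 20
  expect_gt(mean(log(ex2$pb[lo])), mean(log(ex2$pb[!lo])))

  expect_error(simulate_decomposition(cfg, metals = character(0)),
               "at least one metal")
})

test_that("below-detection values are censored by substitution", {
  lim <- c(cu = 50, zn = 0.05, cd = 0.001, pb = 0.005)
  cfg <- simulation_config(seed = 9, detection_limits = lim)
  dec <- simulate_decomposition(cfg)
  expect_true(any(dec$cu_censored))
  expect_true(all(dec$cu[dec$cu_censored] == 50))
  expect_true(all(dec$cu >= 50))
  expect_false(any(dec$pb_censored))
})

test_that("sediment cores follow the configured pool structure", {
  cfg <- simulation_config(seed = 10)
  sed <- simulate_sediment_cores(cfg)
  # default design: 3 replicates x 4 months = 12 surface samples per pool
  expect_equal(sum(sed$pool == "eelgrass" & sed$layer == "surface"), 12)
  expect_equal(sum(sed$pool == "reference" & sed$layer == "surface"), 12)

  # zero slope and zero noise collapse to the baseline exactly
  st <- default_sediment_trend()
  st$surface$slope <- 0
  st$surface$sigma <- 0
  st$surface$intercept <- log(5)
  st$bottom$log_sd <- 0
  cfg0 <- simulation_config(seed = 11, sediment_trend = st)
  sed0 <- simulate_sediment_cores(cfg0)
  expect_equal(unique(sed0$cu[sed0$layer == "surface"]), 5)
  expect_equal(unique(sed0$cu[sed0$layer == "bottom"]),
               exp(st$bottom$log_mean[st$bottom$element == "cu"]))

  # a configured positive eelgrass-pool slope is recovered by the trend fit
  tr <- d13c_trend(sed, "cu", "eelgrass")
  expect_gt(tr$slope, 0)
  expect_lt(tr$p, 0.05)
})

test_that("generated tables round-trip losslessly through the I/O layer", {
  cfg <- simulation_config(seed = 12)
  tabs <- list(sources = simulate_sources(cfg),
               initial_leaves = simulate_initial_leaves(cfg),
               decomposition = simulate_decomposition(cfg),
               sediment = simulate_sediment_cores(cfg))
  for (kind in names(tabs)) {
    path <- withr::local_tempfile(fileext = ".csv")
    write_table_csv(tabs[[kind]], path)
    back <- read_table_csv(path)
    orig <- tabs[[kind]]
    attributes(orig) <- attributes(orig)[c("names", "row.names", "class")]
    expect_equal(as.data.frame(back), as.data.frame(orig))
  }
})
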