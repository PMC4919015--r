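# Independent oracles used across the suite. These re-derive each quantity
# from first principles (naive summation, closed forms, exhaustive
# enumeration, grid quadrature) without going through the package's
# computational path.

# Naive mixing-model log-likelihood: per-observation dnorm summation.
oracle_mixing_loglik <- function(r, sources, il, tracers) {
  total <- 0
  for (t in tracers) {
    me <- sources$mean[sources$source == "eelgrass" & sources$tracer == t]
    mp <- sources$mean[sources$source == "epiphytes" & sources$tracer == t]
    se <- sources$sd[sources$source == "eelgrass" & sources$tracer == t]
    sp <- sources$sd[sources$source == "epiphytes" & sources$tracer == t]
    m <- (1 - r) * me + r * mp
    v <- (1 - r)^2 * se^2 + r^2 * sp^2
    total <- total + sum(dnorm(il[[t]], m, sqrt(v), log = TRUE))
  }
  total
}

# Deterministic posterior moments of r by quadrature on an n-point grid
# under the uniform(0, 1) prior.
oracle_grid_posterior <- function(sources, il, tracers, n_grid = 10000L) {
  grid <- seq(0, 1, length.out = n_grid)
  ll <- vapply(grid, oracle_mixing_loglik, numeric(1),
               sources = sources, il = il, tracers = tracers)
  w <- exp(ll - max(ll))
  w <- w / sum(w)
  m <- sum(w * grid)
  v <- sum(w * (grid - m)^2)
  list(mean = m, sd = sqrt(v),
       lower = grid[which.max(cumsum(w) >= 0.025)],
       upper = grid[which.max(cumsum(w) >= 0.975)])
}

# Closed-form normal-inverse-gamma posterior for the log-linear regression
# log(y) = b1 + b2 * x under beta | s2 ~ N(0, s2 * g * I), s2 ~ IG(a0, c0).
oracle_nig_posterior <- function(x, logy, g = 1e6, a0 = 1e-3, c0 = 1e-3) {
  n <- length(logy)
  X <- cbind(1, x)
  A <- crossprod(X) + diag(1 / g, 2)
  Bn <- solve(A)
  mn <- drop(Bn %*% crossprod(X, logy))
  an <- a0 + n / 2
  cn <- c0 + 0.5 * (sum(logy^2) - drop(t(mn) %*% A %*% mn))
  beta_cov <- cn / (an - 1) * Bn
  list(beta_mean = mn,
       beta_sd = sqrt(diag(beta_cov)),
       sigma2_mean = cn / (an - 1),
       sigma2_sd = sqrt(cn^2 / ((an - 1)^2 * (an - 2))),
       Bn = Bn, an = an, cn = cn)
}

# Exact draws from the NIG posterior (for predictive-oracle tests).
oracle_nig_draws <- function(x, logy, n_draws, g = 1e6, a0 = 1e-3,
                             c0 = 1e-3) {
  post <- oracle_nig_posterior(x, logy, g, a0, c0)
  s2 <- 1 / rgamma(n_draws, shape = post$an, rate = post$cn)
  L <- chol(post$Bn)
  z <- matrix(rnorm(2 * n_draws), ncol = 2)
  beta <- t(post$beta_mean + t((z %*% L) * sqrt(s2)))
  tibble::tibble(beta1 = beta[, 1], beta2 = beta[, 2], sigma2 = s2)
}

# Analytic posterior-predictive moments of log y' at fixed carbon content c
# under the NIG posterior: a scaled-t with 2*an degrees of freedom.
oracle_nig_predictive <- function(x, logy, c_fixed, g = 1e6, a0 = 1e-3,
                                  c0 = 1e-3) {
  post <- oracle_nig_posterior(x, logy, g, a0, c0)
  xv <- c(1, c_fixed)
  scale2 <- post$cn / post$an * (1 + drop(t(xv) %*% post$Bn %*% xv))
  df <- 2 * post$an
  list(mean = sum(xv * post$beta_mean),
       var = scale2 * df / (df - 2))
}

# Tie-corrected standardized rank-sum statistic for one pair, written
# directly from the textbook formulas.
oracle_pair_z <- function(a, b) {
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  w <- sum(r[(m + 1):N])
  ties <- table(c(a, b))
  v <- m * n / 12 * ((N + 1) - sum(ties^3 - ties) / (N * (N - 1)))
  if (v <= 0) return(0)
  (w - n * (N + 1) / 2) / sqrt(v)
}

# All assignments of `vals` into groups of the given sizes (distinct
# multiset permutations of the labels), as a list of index lists.
enumerate_assignments <- function(n_total, sizes) {
  recurse <- function(remaining, sizes) {
    if (length(sizes) == 0L) return(list(list()))
    out <- list()
    picks <- utils::combn(remaining, sizes[1], simplify = FALSE)
    for (p in picks) {
      rest <- setdiff(remaining, p)
      for (tail in recurse(rest, sizes[-1])) {
        out[[length(out) + 1L]] <- c(list(p), tail)
      }
    }
    out
  }
  recurse(seq_len(n_total), sizes)
}

# Exact familywise p-values for the DSCF max-statistic test by exhaustive
# enumeration of the permutation distribution.
oracle_dscf_exact <- function(groups) {
  sizes <- lengths(groups)
  vals <- unlist(groups, use.names = FALSE)
  k <- length(groups)
  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  obs <- apply(pairs, 1L, function(ij) {
    abs(oracle_pair_z(groups[[ij[1]]], groups[[ij[2]]]))
  })
  assigns <- enumerate_assignments(length(vals), sizes)
  maxima <- vapply(assigns, function(a) {
    g <- lapply(a, function(idx) vals[idx])
    max(apply(pairs, 1L, function(ij) {
      abs(oracle_pair_z(g[[ij[1]]], g[[ij[2]]]))
    }))
  }, numeric(1))
  vapply(obs, function(z) mean(maxima >= z - 1e-12), numeric(1))
}

# Monte-Carlo standard error of a posterior mean treating thinned draws as
# independent (thinning keeps autocorrelation negligible here).
mcse <- function(draws) sd(draws) / sqrt(length(draws))

# Minimal posterior-draw table tagged with a metal, for interface tests.
fit_stub <- function(metal, experiment = "EX1") {
  draws <- tibble::tibble(beta1 = 4, beta2 = -0.1, sigma2 = 0.01)
  attr(draws, "metal") <- metal
  attr(draws, "experiment") <- experiment
  draws
}

# A small, fast MCMC schedule for repetition-heavy recovery checks.
fast_wre_config <- function(seed) {
  wre_mcmc_config(seed = seed, iterations = 20000L, burn_in = 5000L,
                  thinning = 3L)
}
fast_decomp_config <- function(seed) {
  decomp_mcmc_config(seed = seed, chains = 1L, iterations = 6000L,
                     burn_in = 1000L, thinning = 5L)
}
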