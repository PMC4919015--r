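#' Substitute detection limits for censored concentrations
#'
#' Below-detection-limit assays carry no usable concentration; the analysis
#' convention is to substitute the metal's detection limit for them. Censored
#' flags are preserved, so the operation is idempotent.
#'
#' @param observations Decomposition table as produced by
#'   [simulate_decomposition()]: per metal `<m>`, `<m>_censored`,
#'   `<m>_limit` columns.
#' @param limits Optional named vector of detection limits overriding the
#'   `<m>_limit` columns.
#' @return The table with censored entries replaced by the detection limit.
#' @export
substitute_detection_limits <- function(observations, limits = NULL) {
  metals <- intersect(ZM_METALS, names(observations))
  for (m in metals) {
    flag_col <- paste0(m, "_censored")
    if (!flag_col %in% names(observations)) next
    cens <- observations[[flag_col]]
    if (!any(cens)) next
    lim_col <- paste0(m, "_limit")
    lim <- if (!is.null(limits) && m %in% names(limits)) {
      rep(limits[[m]], nrow(observations))
    } else if (lim_col %in% names(observations)) {
      observations[[lim_col]]
    } else {
      rep(NA_real_, nrow(observations))
    }
    if (any(is.na(lim[cens]) | lim[cens] <= 0)) {
      stop("censored ", m, " values have no positive detection limit")
    }
    observations[[m]][cens] <- lim[cens]
  }
  observations
}

#' Log-likelihood of the log-linear decomposition model
#'
#' The concentration `y_j` of one metal in one experiment is modelled on the
#' natural-log scale as `log_e y_j = beta1 + beta2 * C_j + eps_j` with
#' `eps_j ~ N(0, sigma2)` i.i.d., where `C_j` is the leaf carbon content in
#' % dry weight.
#'
#' @param beta1 Intercept (log_e microgram per gram).
#' @param beta2 Slope per % carbon.
#' @param sigma2 Residual variance on the log scale; must be positive.
#' @param c_content Carbon contents (% dry weight).
#' @param concentration Concentrations (microgram per gram); must be
#'   positive.
#' @return The summed normal log-density.
#' @export
decomp_loglik <- function(beta1, beta2, sigma2, c_content, concentration) {
  if (length(concentration) < 1L) stop("at least one observation is required")
  if (sigma2 <= 0) stop("`sigma2` must be positive")
  if (any(concentration <= 0)) {
    stop("concentrations must be positive (log undefined)")
  }
  sum(dnorm(log(concentration), beta1 + beta2 * c_content, sqrt(sigma2),
            log = TRUE))
}

# Default normal-inverse-gamma prior: beta | sigma2 ~ N(0, sigma2 * g * I),
# sigma2 ~ IG(a0, c0). Vague (g = 1e6) so posteriors are data-dominated;
# fully conjugate so the Gibbs sampler has an exact analytic counterpart.
decomp_default_prior <- function() {
  list(g = 1e6, a0 = 1e-3, c0 = 1e-3)
}

#' Fit the Bayesian log-linear decomposition model by Gibbs sampling
#'
#' Regresses log_e metal concentration on leaf carbon content for one metal
#' in one decomposition experiment under a conjugate normal-inverse-gamma
#' prior (`beta | sigma2 ~ N(0, sigma2 * 1e6 * I)`,
#' `sigma2 ~ IG(1e-3, 1e-3)`). The default schedule runs 3 chains of 50,000
#' post-burn-in sweeps (burn-in 5,000 each), thinned every 15 sweeps across
#' the pooled 150,000 post-burn-in stream to exactly 10,000 retained draws.
#' A split-chain potential-scale-reduction diagnostic is attached per
#' parameter; values above 1.1 raise a warning, never an abort.
#'
#' @param observations Decomposition table (see [simulate_decomposition()]).
#' @param metal One of `"cu"`, `"zn"`, `"cd"`, `"pb"`.
#' @param experiment One of `"EX1"`, `"EX2"`, `"EX3"`.
#' @param mcmc An [mcmc_config()]; defaults to [decomp_mcmc_config()].
#' @param prior List with elements `g`, `a0`, `c0` overriding the default
#'   prior constants.
#' @return An object of class `regression_posterior`: `draws` tibble
#'   (`chain`, `beta1`, `beta2`, `sigma2`), `summary` tibble (`parameter`,
#'   `mean`, `sd`, `lower`, `upper`, `rhat`), plus `metal`, `experiment`,
#'   `n_obs`.
#' @export
fit_decomposition <- function(observations, metal, experiment,
                              mcmc = decomp_mcmc_config(),
                              prior = decomp_default_prior()) {
  stopifnot(inherits(mcmc, "mcmc_config"))
  metal <- match.arg(metal, ZM_METALS)
  experiment <- match.arg(experiment, ZM_EXPERIMENTS)
  obs <- observations[observations$experiment == experiment, ]
  if (nrow(obs) < 4L) {
    stop("need at least 4 observations to fit 3 parameters (have ",
         nrow(obs), ")")
  }
  flag_col <- paste0(metal, "_censored")
  if (flag_col %in% names(obs) && all(obs[[flag_col]])) {
    stop("every ", metal, " value in ", experiment,
         " is below the detection limit; fit refused")
  }
  obs <- substitute_detection_limits(obs)
  y <- log(obs[[metal]])
  if (any(!is.finite(y))) stop("non-positive ", metal, " concentrations")
  x <- obs$c_content
  n <- length(y)

  # sufficient statistics and the (sigma2-free) conditional posterior of beta
  XtX <- matrix(c(n, sum(x), sum(x), sum(x^2)), 2L, 2L)
  Xty <- c(sum(y), sum(x * y))
  A <- XtX + diag(1 / prior$g, 2L)
  Bn <- solve(A)
  mn <- drop(Bn %*% Xty)
  R <- chol(Bn)  # t(R) %*% R == Bn
  a_post <- prior$a0 + (n + 2L) / 2
  yty <- sum(y^2)
  sxx <- XtX[2L, 2L]
  sx <- XtX[1L, 2L]

  set.seed(mcmc$seed)
  keep <- retained_indices(mcmc)
  chains <- vector("list", mcmc$chains)
  for (ch in seq_len(mcmc$chains)) {
    idx <- keep[[ch]]
    out <- matrix(NA_real_, length(idx), 3L)
    # overdispersed start for sigma2 across chains
    sigma2 <- exp(rnorm(1, 0, 1))
    kept <- 0L
    post_i <- 0L
    for (it in seq_len(mcmc$iterations)) {
      z <- rnorm(2L)
      s <- sqrt(sigma2)
      b1 <- mn[1L] + s * R[1L, 1L] * z[1L]
      b2 <- mn[2L] + s * (R[1L, 2L] * z[1L] + R[2L, 2L] * z[2L])
      # residual sum of squares from sufficient statistics
      rss <- yty - 2 * (b1 * Xty[1L] + b2 * Xty[2L]) +
        n * b1^2 + 2 * sx * b1 * b2 + sxx * b2^2
      rate <- prior$c0 + 0.5 * (rss + (b1^2 + b2^2) / prior$g)
      sigma2 <- 1 / rgamma(1, shape = a_post, rate = rate)
      if (it > mcmc$burn_in) {
        post_i <- post_i + 1L
        if (kept < length(idx) && post_i == idx[kept + 1L]) {
          kept <- kept + 1L
          out[kept, ] <- c(b1, b2, sigma2)
        }
      }
    }
    chains[[ch]] <- out
  }
  draws <- tibble::tibble(
    chain = rep(seq_len(mcmc$chains),
                vapply(chains, nrow, integer(1))),
    beta1 = unlist(lapply(chains, function(m) m[, 1])),
    beta2 = unlist(lapply(chains, function(m) m[, 2])),
    sigma2 = unlist(lapply(chains, function(m) m[, 3]))
  )
  pars <- c("beta1", "beta2", "sigma2")
  summ <- do.call(rbind, lapply(pars, function(p) {
    s <- summarize_posterior(draws[[p]])
    s$parameter <- p
    s$rhat <- split_rhat(lapply(chains, function(m) m[, match(p, pars)]))
    s[, c("parameter", "mean", "sd", "lower", "upper", "rhat")]
  }))
  if (any(summ$rhat > 1.1, na.rm = TRUE)) {
    warning("potential scale reduction above 1.1 for: ",
            paste(summ$parameter[summ$rhat > 1.1], collapse = ", "),
            " (chains may not have converged)")
  }
  structure(
    list(draws = draws, summary = tibble::as_tibble(summ),
         metal = metal, experiment = experiment, n_obs = n,
         prior = prior, config = mcmc),
    class = "regression_posterior"
  )
}

#' @export
print.regression_posterior <- function(x, ...) {
  cat(sprintf("Log-linear decomposition fit: %s %s (n = %d, %d draws)\n",
              toupper(x$metal), x$experiment, x$n_obs, nrow(x$draws)))
  print(x$summary)
  invisible(x)
}

# Split-chain potential scale reduction (each chain halved, variance ratio
# across the resulting segments).
split_rhat <- function(chain_list) {
  segs <- list()
  for (ch in chain_list) {
    h <- length(ch) %/% 2L
    if (h < 2L) return(NA_real_)
    segs <- c(segs, list(ch[seq_len(h)]), list(ch[(h + 1L):(2L * h)]))
  }
  m <- length(segs)
  n <- length(segs[[1L]])
  means <- vapply(segs, mean, numeric(1))
  vars <- vapply(segs, var, numeric(1))
  w <- mean(vars)
  b <- n * var(means)
  if (w == 0) return(1)
  sqrt(((n - 1) / n * w + b / n) / w)
}
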