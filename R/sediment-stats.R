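#' Annual summary on the log scale (geometric mean with multiplicative spread)
#'
#' Concentration data in this domain are strictly positive and right-skewed,
#' so annual summaries are computed on log_e values and back-transformed:
#' the exponentiated mean is the geometric mean and the exponentiated SD/SE
#' are multiplicative spread factors.
#'
#' @param values Positive numeric vector.
#' @param log_scale Compute on the log scale (default `TRUE`); with
#'   `FALSE`, plain arithmetic summaries are returned.
#' @return A tibble with `n`, `mean`, `sd`, `se` (back-transformed when
#'   `log_scale`) and, on the log scale, `log_mean`, `log_sd`, `log_se`.
#' @export
annual_summary <- function(values, log_scale = TRUE) {
  if (length(values) == 0L) stop("no values to summarise")
  if (!log_scale) {
    return(tibble::tibble(n = length(values), mean = mean(values),
                          sd = sd_or_zero(values),
                          se = sd_or_zero(values) / sqrt(length(values))))
  }
  if (any(values <= 0)) stop("log-scale summary requires positive values")
  lx <- log(values)
  m <- mean(lx)
  s <- sd_or_zero(lx)
  se <- s / sqrt(length(lx))
  tibble::tibble(n = length(values),
                 mean = exp(m), sd = exp(s), se = exp(se),
                 log_mean = m, log_sd = s, log_se = se)
}

sd_or_zero <- function(x) if (length(x) > 1L) sd(x) else 0

#' Kruskal-Wallis rank-sum test across groups
#'
#' Wraps the standard tie-corrected Kruskal-Wallis test. The fully tied
#' degenerate case (every observation equal) is handled explicitly with a
#' zero statistic rather than a division-by-zero failure.
#'
#' @param groups List of two or more non-empty numeric vectors.
#' @return A tibble with `chi_squared`, `df`, `p`.
#' @export
kruskal_wallis <- function(groups) {
  if (length(groups) < 2L) stop("at least two groups are required")
  if (any(vapply(groups, length, integer(1)) == 0L)) {
    stop("all groups must be non-empty")
  }
  x <- unlist(groups, use.names = FALSE)
  if (length(unique(x)) == 1L) {
    return(tibble::tibble(chi_squared = 0, df = length(groups) - 1L, p = 1))
  }
  g <- factor(rep(seq_along(groups), vapply(groups, length, integer(1))))
  kt <- kruskal.test(x, g)
  tibble::tibble(chi_squared = unname(kt$statistic),
                 df = unname(kt$parameter), p = kt$p.value)
}

# Tie-corrected standardized two-sample rank-sum statistic for one pair
# (mid-ranks; Z = (W - E W)/sqrt(Var W), Var with the tie correction of the
# Dwass-Steel-Critchlow-Fligner convention). Used for observed statistics;
# the permutation maxima come from the compiled kernel with identical math.
dscf_pair_z <- function(a, b) {
  m <- length(a); n <- length(b); N <- m + n
  r <- rank(c(a, b))
  w <- sum(r[(m + 1L):N])
  ew <- n * (N + 1) / 2
  ties <- table(c(a, b))
  tie_term <- sum(ties^3 - ties) / (N * (N - 1))
  v <- m * n / 12 * ((N + 1) - tie_term)
  if (v <= 0) return(0)
  (w - ew) / sqrt(v)
}

#' Monte-Carlo Dwass-Steel-Critchlow-Fligner multiple comparisons
#'
#' All-pairs nonparametric comparison with familywise error control. For
#' each pair of groups the tie-corrected standardized rank-sum statistic is
#' computed; the joint null is built by permuting the pooled observations
#' `n_iter` times and recording, for every permutation, the maximum absolute
#' pairwise statistic. Each pairwise p-value is the (add-one corrected)
#' proportion of permuted maxima at least as large as the observed absolute
#' statistic, so it is familywise by construction (single-step max-T). The
#' reported `w` statistic is `sqrt(2)` times the standardized statistic, the
#' scale used by the studentized-range convention.
#'
#' @param groups List of three or more numeric vectors with at least two
#'   observations each (two groups are accepted, collapsing to a permutation
#'   rank-sum test).
#' @param n_iter Number of Monte-Carlo permutations (default 10,000; fewer
#'   than 100 is refused as unstable).
#' @param seed Integer seed.
#' @return An object of class `group_comparison`: `pairs` tibble
#'   (`group1`, `group2`, `w`, `p`, `stars`), the companion
#'   [kruskal_wallis()] result, and `n_iter`.
#' @export
steel_dwass_mc <- function(groups, n_iter = 10000L, seed = 1L) {
  if (length(groups) < 2L) stop("at least two groups are required")
  if (any(vapply(groups, length, integer(1)) < 2L)) {
    stop("every group needs at least two observations")
  }
  n_iter <- as.integer(n_iter)
  if (n_iter < 100L) stop("`n_iter` below 100 gives unstable p-values; refused")
  labels <- names(groups) %||% paste0("group", seq_along(groups))
  if (is.null(names(groups)) || any(!nzchar(labels))) {
    labels <- paste0("group", seq_along(groups))
  }
  k <- length(groups)
  sizes <- vapply(groups, length, integer(1))
  pooled <- unlist(groups, use.names = FALSE)

  pairs <- which(upper.tri(matrix(0, k, k)), arr.ind = TRUE)
  obs <- apply(pairs, 1L, function(ij) {
    dscf_pair_z(groups[[ij[1L]]], groups[[ij[2L]]])
  })
  set.seed(seed)
  maxima <- dscf_perm_maxima(pooled, sizes, n_iter)
  p <- vapply(abs(obs), function(z) {
    (1 + sum(maxima >= z - 1e-12)) / (n_iter + 1)
  }, numeric(1))
  structure(
    list(pairs = tibble::tibble(group1 = labels[pairs[, 1L]],
                                group2 = labels[pairs[, 2L]],
                                w = sqrt(2) * obs, p = p,
                                stars = significance_stars(p)),
         kruskal = kruskal_wallis(groups),
         n_iter = n_iter),
    class = "group_comparison"
  )
}

#' @export
print.group_comparison <- function(x, ...) {
  cat(sprintf("DSCF multiple comparisons (%d Monte-Carlo permutations)\n",
              x$n_iter))
  print(x$pairs)
  cat(sprintf("Kruskal-Wallis chi-squared = %.3g, df = %d, p = %.3g\n",
              x$kruskal$chi_squared, x$kruskal$df, x$kruskal$p))
  invisible(x)
}

#' Significance stars
#'
#' Conventional star coding: `***` p < 0.001, `**` p < 0.01, `*` p < 0.05,
#' empty otherwise.
#'
#' @param p Numeric vector of p-values.
#' @return Character vector of stars.
#' @export
significance_stars <- function(p) {
  vapply(p, function(pi) {
    if (pi < 0.001) "***" else if (pi < 0.01) "**"
    else if (pi < 0.05) "*" else ""
  }, character(1))
}

#' Log-linear trend of an element against delta-13C in surface sediment
#'
#' Ordinary least-squares fit of log_e concentration on delta-13C within one
#' pool's surface sediment, with the normal-theory slope p-value. Because
#' the log transform is itself a modelling choice, a companion fit on the
#' untransformed response is always produced.
#'
#' @param samples Sediment table as from [simulate_sediment_cores()].
#' @param element Column name of the response element.
#' @param pool `"eelgrass"` or `"reference"`.
#' @param layer Sediment layer to use (default `"surface"`).
#' @return A tibble with one row: `element`, `pool`, `n`, `intercept`,
#'   `slope`, `p`, `stars` (log-scale fit) and `slope_raw`, `p_raw`
#'   (untransformed companion).
#' @export
d13c_trend <- function(samples, element, pool, layer = "surface") {
  pool <- match.arg(pool, c("eelgrass", "reference"))
  dat <- samples[samples$pool == pool & samples$layer == layer, ]
  if (nrow(dat) < 3L) stop("need at least 3 samples in the ", pool, " pool")
  if (!element %in% names(dat)) stop("no column '", element, "' in samples")
  if (var(dat$d13c) < .Machine$double.eps) {
    stop("delta-13C is constant; the slope is not identifiable")
  }
  y <- dat[[element]]
  if (any(y <= 0)) stop("log-linear fit requires positive concentrations")
  fit_log <- glm(log(y) ~ d13c, data = dat)
  fit_raw <- glm(y ~ d13c, data = dat)
  ct_log <- trend_coefs(fit_log)
  ct_raw <- trend_coefs(fit_raw)
  tibble::tibble(
    element = element, pool = pool, n = nrow(dat),
    intercept = ct_log["(Intercept)", "Estimate"],
    slope = ct_log["d13c", "Estimate"],
    p = ct_log["d13c", "Pr(>|t|)"],
    stars = significance_stars(ct_log["d13c", "Pr(>|t|)"]),
    slope_raw = ct_raw["d13c", "Estimate"],
    p_raw = ct_raw["d13c", "Pr(>|t|)"])
}

# Coefficient table with a defined p-value in the zero-residual degenerate
# case (perfectly flat noiseless data has no evidence against a zero slope).
trend_coefs <- function(fit) {
  s <- summary(fit)
  ct <- s$coefficients
  # a numerically perfect fit carries no sampling variability: a (near-)zero
  # slope is then no evidence of a trend, a non-zero one is exact
  if (s$dispersion < 1e-16 || !is.finite(ct["d13c", "Pr(>|t|)"])) {
    ct["d13c", "Pr(>|t|)"] <-
      if (abs(ct["d13c", "Estimate"]) < 1e-8) 1 else 0
  }
  ct
}

#' Days of experienced temperature for a leaf of known rank
#'
#' A leaf's thermal history before sampling is the plastochrone interval
#' (mean days between successive leaf initiations on a shoot) multiplied by
#' the leaf-rank factor (2.5 for the third-youngest leaf), rounded to the
#' nearest whole day.
#'
#' @param plastochrone_interval Days; must be positive.
#' @param leaf_rank_factor Unitless factor; must be positive.
#' @return Integer number of days.
#' @export
experienced_temperature_days <- function(plastochrone_interval,
                                         leaf_rank_factor) {
  if (plastochrone_interval <= 0 || leaf_rank_factor <= 0) {
    stop("both inputs must be positive")
  }
  as.integer(round(plastochrone_interval * leaf_rank_factor))
}
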