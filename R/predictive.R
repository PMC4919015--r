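#' Draw the initial-leaf carbon content distribution
#'
#' The carbon content of the initial leaf-with-epiphytes material is the
#' mass-fraction mixture `C(0) = (1 - r) * C_eelgrass + r * C_epiphytes`.
#' Each iteration resamples `r` with replacement from the epiphyte
#' weight-ratio posterior and draws the two source carbon contents from
#' independent normals, so the returned draws integrate over all three
#' uncertainties.
#'
#' @param wre A `wre_posterior` (or a numeric vector of `r` draws).
#' @param c_eel,c_epi Length-2 vectors `c(mean, sd)` of the source carbon
#'   contents in % dry weight; SDs must be non-negative.
#' @param n_iter Number of Monte-Carlo iterations (default 100,000).
#' @param seed Integer seed.
#' @return Numeric vector of `C(0)` draws (% dry weight).
#' @export
draw_initial_carbon <- function(wre, c_eel, c_epi, n_iter = 100000L,
                                seed = 1L) {
  r_draws <- if (inherits(wre, "wre_posterior")) wre$draws else as.numeric(wre)
  if (length(r_draws) == 0L) stop("no weight-ratio draws supplied")
  if (n_iter < 1L) stop("`n_iter` must be at least 1")
  if (c_eel[2] < 0 || c_epi[2] < 0) stop("source carbon SDs must be >= 0")
  set.seed(seed)
  r <- r_draws[sample.int(length(r_draws), n_iter, replace = TRUE)]
  ce <- rnorm(n_iter, c_eel[1], c_eel[2])
  cp <- rnorm(n_iter, c_epi[1], c_epi[2])
  (1 - r) * ce + r * cp
}

#' Posterior-predictive metal concentration at a target carbon content
#'
#' Integrates the log-linear decomposition model over the joint posterior of
#' `(beta1, beta2, sigma2)` and the target carbon-content distribution
#' `p(C)`: each iteration resamples one joint posterior draw (preserving
#' posterior correlation), one carbon content (a fixed value or a draw from
#' `c_draws`), and then draws
#' `log_e y' ~ N(beta1 + beta2 * C, sigma2)`.
#'
#' @param posterior A `regression_posterior` from [fit_decomposition()] (or
#'   a tibble with `beta1`, `beta2`, `sigma2` columns).
#' @param c_target Either a single fixed carbon content (% dry weight) or a
#'   numeric vector of carbon-content draws, e.g. from
#'   [draw_initial_carbon()].
#' @param n_iter Number of Monte-Carlo iterations (default 100,000).
#' @param seed Integer seed.
#' @return An object of class `predictive_target`: `draws_log`, `draws`
#'   (linear scale, microgram per gram), `summary` (one row per scale with
#'   mean, sd and equal-tailed 95 % interval), `target` kind, and the
#'   originating `metal`/`experiment` when known.
#' @export
predict_concentration <- function(posterior, c_target, n_iter = 100000L,
                                  seed = 1L) {
  if (inherits(posterior, "regression_posterior")) {
    draws <- posterior$draws
    metal <- posterior$metal
    experiment <- posterior$experiment
  } else {
    draws <- posterior
    metal <- attr(posterior, "metal")
    experiment <- attr(posterior, "experiment")
  }
  if (!all(c("beta1", "beta2", "sigma2") %in% names(draws))) {
    stop("posterior draws must have beta1, beta2 and sigma2 columns")
  }
  if (nrow(draws) == 0L) stop("no posterior draws available")
  if (n_iter < 1L) stop("`n_iter` must be at least 1")
  if (length(c_target) == 0L || any(!is.finite(c_target))) {
    stop("`c_target` must be a fixed value or a vector of finite draws")
  }
  set.seed(seed)
  idx <- sample.int(nrow(draws), n_iter, replace = TRUE)
  b1 <- draws$beta1[idx]
  b2 <- draws$beta2[idx]
  s2 <- draws$sigma2[idx]
  cc <- if (length(c_target) == 1L) {
    rep(c_target, n_iter)
  } else {
    c_target[sample.int(length(c_target), n_iter, replace = TRUE)]
  }
  logy <- rnorm(n_iter, b1 + b2 * cc, sqrt(s2))
  y <- exp(logy)
  summ <- rbind(
    cbind(scale = "log", summarize_posterior(logy)),
    cbind(scale = "linear", summarize_posterior(y)))
  structure(
    list(draws_log = logy, draws = y,
         summary = tibble::as_tibble(summ),
         target = if (length(c_target) == 1L) "fixed_c" else "distribution",
         c_target = if (length(c_target) == 1L) c_target else NULL,
         metal = metal, experiment = experiment, n_iter = n_iter),
    class = "predictive_target"
  )
}

#' @export
print.predictive_target <- function(x, ...) {
  lab <- paste(c(if (!is.null(x$metal)) toupper(x$metal), x$experiment),
               collapse = " ")
  cat(sprintf("Posterior-predictive concentration%s (%s target, %d draws)\n",
              if (nzchar(lab)) paste0(" for ", lab) else "", x$target,
              x$n_iter))
  print(x$summary)
  invisible(x)
}

#' Fold change between two predictive targets
#'
#' Headline fold change in a metal's concentration between two prediction
#' targets (typically the lowest observed carbon content versus the
#' initial-leaf content `C(0)`), as the ratio of linear-scale predictive
#' means; a draw-wise ratio distribution with its equal-tailed 95 % interval
#' is reported alongside.
#'
#' @param pred_num Numerator `predictive_target` (e.g. at the lowest C).
#' @param pred_den Denominator `predictive_target` (e.g. at `C(0)`).
#' @return A tibble with the mean-ratio fold change, the direction, and the
#'   draw-wise ratio summary.
#' @export
fold_change <- function(pred_num, pred_den) {
  stopifnot(inherits(pred_num, "predictive_target"),
            inherits(pred_den, "predictive_target"))
  if (!is.null(pred_num$metal) && !is.null(pred_den$metal) &&
      (pred_num$metal != pred_den$metal ||
         !identical(pred_num$experiment, pred_den$experiment))) {
    stop("fold change requires targets from the same metal and experiment")
  }
  ratio_means <- mean(pred_num$draws) / mean(pred_den$draws)
  n <- min(length(pred_num$draws), length(pred_den$draws))
  rw <- pred_num$draws[seq_len(n)] / pred_den$draws[seq_len(n)]
  q <- quantile(rw, c(0.025, 0.975), names = FALSE)
  tibble::tibble(
    metal = pred_num$metal %||% NA_character_,
    experiment = pred_num$experiment %||% NA_character_,
    fold_change = ratio_means,
    direction = ifelse(ratio_means >= 1, "increase", "decrease"),
    ratio_mean = mean(rw), ratio_lower = q[1], ratio_upper = q[2])
}
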