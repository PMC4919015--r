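#' Default tracer summaries for the two mixing sources
#'
#' Per-source, per-tracer means, standard deviations and sample sizes for the
#' two end members of the mixing model: eelgrass leaf tissue and the epiphyte
#' assemblage (mainly crustose coralline algae) scraped from the leaves.
#' Values are typical of a temperate Zostera marina mesocosm: eelgrass leaves
#' are carbon-rich (about 35 % dry weight) with a depleted carbon isotope
#' signature, epiphytes are carbonate-diluted (about 20 % C) and isotopically
#' heavier. Eelgrass summaries come from monthly shoot replicates (n = 5),
#' epiphyte summaries from annually pooled samples (n = 10).
#'
#' @return A tibble with columns `source`, `tracer`, `mean`, `sd`, `n`.
#' @export
default_source_params <- function() {
  tibble::tibble(
    source = rep(c("eelgrass", "epiphytes"), each = 4L),
    tracer = rep(c("c_content", "d13c", "n_content", "d15n"), 2L),
    mean = c(35.0, -13.4, 2.0, 8.0,
             20.0, -9.7, 0.5, 7.0),
    sd = c(1.5, 2.1, 0.3, 0.5,
           1.5, 0.5, 0.1, 0.5),
    n = c(rep(5L, 4L), rep(10L, 4L))
  )
}

#' Default ground-truth parameters for the decomposition simulator
#'
#' One row per metal and experiment with the log-linear model truth
#' (`beta1` intercept in log_e microgram per gram, `beta2` slope per % carbon,
#' `sigma2` residual variance on the log scale). Magnitudes are typical of
#' copper, zinc, cadmium and lead in decomposing eelgrass litter: copper and
#' lead concentrate as carbon is lost (negative slope), zinc and cadmium leach
#' (positive slope).
#'
#' @return A tibble with columns `metal`, `experiment`, `beta1`, `beta2`,
#'   `sigma2`.
#' @export
default_decomp_truth <- function() {
  tibble::tribble(
    ~metal, ~experiment, ~beta1, ~beta2, ~sigma2,
    "cu", "EX1",  4.23, -0.120, 0.08,
    "cu", "EX2",  4.12, -0.105, 0.03,
    "cu", "EX3",  3.88, -0.037, 0.07,
    "zn", "EX1",  3.59,  0.025, 0.04,
    "zn", "EX2",  2.90,  0.089, 0.01,
    "zn", "EX3",  3.03,  0.071, 0.14,
    "cd", "EX1", -6.68,  0.237, 0.38,
    "cd", "EX2", -6.81,  0.276, 0.08,
    "cd", "EX3", -6.53,  0.204, 0.34,
    "pb", "EX1",  4.73, -0.238, 0.11,
    "pb", "EX2",  5.65, -0.277, 0.11,
    "pb", "EX3",  4.04, -0.168, 0.16
  )
}

#' Default detection limits (microgram per gram dry weight)
#'
#' Procedure detection limits typical of ICP-MS trace-metal assays on
#' acid-digested plant and sediment material; concentrations below these are
#' flagged censored and substituted by the limit.
#'
#' @return Named numeric vector over `cu`, `zn`, `cd`, `pb`.
#' @export
default_detection_limits <- function() {
  c(cu = 0.01, zn = 0.05, cd = 0.001, pb = 0.005)
}

#' Default sediment-core trend configuration
#'
#' Surface-sediment log concentrations follow
#' `log_e(conc) = intercept + slope * d13c + noise` within each pool; carbon
#' and nitrogen rise with delta-13C in both pools (organic sedimentation from
#' marine producers), the four metals rise only in the eelgrass pool (shed
#' leaf material), the reference pool being flat. Bottom sediment sits at the
#' original-sediment baseline. delta-13C spans reflect the mixing of original
#' sediment (about -22 permil) with eelgrass/epiphyte material (about -10
#' permil) in the vegetated pool only.
#'
#' @return A list with elements `surface` (tibble: `pool`, `element`,
#'   `intercept`, `slope`, `sigma`), `bottom` (tibble: `element`, `log_mean`,
#'   `log_sd`), `d13c_range` (list of pool ranges), `bottom_d13c`
#'   (mean, sd), `months`, `replicates`.
#' @export
default_sediment_trend <- function() {
  elements <- c("c", "n", "cu", "zn", "cd", "pb")
  base_log <- c(c = -1.2, n = -3.0, cu = 2.7, zn = 4.38, cd = -1.9, pb = 3.22)
  eel_slope <- c(c = 0.25, n = 0.25, cu = 0.15, zn = 0.15, cd = 0.15, pb = 0.15)
  ref_slope <- c(c = 0.20, n = 0.20, cu = 0, zn = 0, cd = 0, pb = 0)
  # intercepts anchor the baseline concentration at d13c = -22 permil
  surface <- tibble::tibble(
    pool = rep(c("eelgrass", "reference"), each = length(elements)),
    element = rep(elements, 2L),
    intercept = c(base_log + 22 * eel_slope, base_log + 22 * ref_slope),
    slope = c(eel_slope, ref_slope),
    sigma = rep(c(0.30, 0.15), c(length(elements), length(elements)))
  )
  surface$sigma <- ifelse(surface$pool == "eelgrass", 0.30,
                          ifelse(surface$element %in% c("c", "n"), 0.15, 0.30))
  list(
    surface = surface,
    bottom = tibble::tibble(element = elements,
                            log_mean = unname(base_log),
                            log_sd = c(0.2, 0.2, 0.2, 0.2, 0.25, 0.2)),
    d13c_range = list(eelgrass = c(-20, -10), reference = c(-22, -17)),
    bottom_d13c = c(mean = -22.2, sd = 0.6),
    months = c("2005-07", "2005-09", "2005-12", "2006-03"),
    replicates = 3L
  )
}

#' Simulation configuration with known ground truth
#'
#' Bundles every generative parameter the synthetic-data module needs:
#' two tracer sources with per-tracer normal variability, initial-leaf
#' mixtures at a true epiphyte weight fraction `r_true`, log-linear
#' decomposition truth per metal and experiment, sediment-core trends per
#' pool, and per-metal detection limits for censoring.
#'
#' @param seed Integer master seed for all generators.
#' @param n_il Number of initial-leaf replicates.
#' @param r_true True epiphyte weight fraction in `[0, 1]`.
#' @param source_params Tibble as [default_source_params()].
#' @param decomp_truth Tibble as [default_decomp_truth()].
#' @param n_obs Observations per decomposition experiment (25 by default:
#'   five replicate bags over five sampling days).
#' @param c_range Carbon-content interval (% dry weight) the decomposition
#'   series spans.
#' @param sediment_trend List as [default_sediment_trend()].
#' @param detection_limits Named vector as [default_detection_limits()].
#' @return An object of class `simulation_config`.
#' @export
simulation_config <- function(seed = 1L,
                              n_il = 5L,
                              r_true = 0.192,
                              source_params = default_source_params(),
                              decomp_truth = default_decomp_truth(),
                              n_obs = 25L,
                              c_range = c(11, 35),
                              sediment_trend = default_sediment_trend(),
                              detection_limits = default_detection_limits()) {
  stopifnot(is.numeric(r_true), length(r_true) == 1L)
  if (r_true < 0 || r_true > 1) stop("`r_true` must lie in [0, 1]")
  if (any(source_params$sd < 0)) stop("source tracer SDs must be >= 0")
  if (any(decomp_truth$sigma2 < 0)) stop("decomposition sigma2 must be >= 0")
  if (length(c_range) != 2L || any(c_range <= 0) || any(c_range >= 100) ||
      c_range[1] > c_range[2]) {
    stop("`c_range` must be an increasing interval within (0, 100)")
  }
  if (any(detection_limits <= 0)) stop("detection limits must be > 0")
  n_il <- as.integer(n_il)
  n_obs <- as.integer(n_obs)
  if (n_il < 1L) stop("`n_il` must be a positive count")
  if (n_obs < 1L) stop("`n_obs` must be a positive count")
  structure(
    list(seed = as.integer(seed), n_il = n_il, r_true = r_true,
         source_params = source_params, decomp_truth = decomp_truth,
         n_obs = n_obs, c_range = as.numeric(c_range),
         sediment_trend = sediment_trend,
         detection_limits = detection_limits),
    class = "simulation_config"
  )
}

# Draw one table of per-replicate tracer vectors for a named source.
draw_source_table <- function(params, source, n, clip_log = TRUE) {
  rows <- params[params$source == source, ]
  if (nrow(rows) == 0L) stop("no source parameters for '", source, "'")
  out <- tibble::tibble(source = rep(source, n), replicate = seq_len(n))
  clipped <- 0L
  for (k in seq_len(nrow(rows))) {
    tr <- rows$tracer[k]
    x <- rnorm(n, rows$mean[k], rows$sd[k])
    if (tr %in% c("c_content", "n_content")) {
      bad <- x < 0 | x > 100
      if (any(bad)) {
        clipped <- clipped + sum(bad)
        x <- pmin(pmax(x, 0), 100)
      }
    }
    out[[tr]] <- x
  }
  if (clip_log && clipped > 0L) {
    message(sprintf("clipped %d %s tracer draw(s) to [0, 100] %% dry weight",
                    clipped, source))
  }
  attr(out, "n_clipped") <- clipped
  out
}

#' Simulate tracer panels for the two mixing sources
#'
#' Draws `n` replicates per source (as recorded in `source_params`) for each
#' tracer from independent normals. Elemental contents are clipped to the
#' physical range 0-100 % dry weight; clipping is reported via a message and
#' the `n_clipped` attribute, never silent.
#'
#' @param config A [simulation_config()].
#' @return A tibble of tracer vectors, one row per source replicate, with an
#'   `n_clipped` attribute.
#' @export
simulate_sources <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  ns <- unique(config$source_params[, c("source", "n")])
  if (any(ns$n <= 0)) stop("source replicate counts must be positive")
  set.seed(config$seed)
  tabs <- lapply(seq_len(nrow(ns)), function(i) {
    draw_source_table(config$source_params, ns$source[i], ns$n[i])
  })
  out <- tibble::as_tibble(do.call(rbind, tabs))
  attr(out, "n_clipped") <- sum(vapply(tabs, attr, integer(1), "n_clipped"))
  out
}

#' Simulate initial-leaf tracer mixtures at a known epiphyte weight fraction
#'
#' Each initial-leaf (IL) replicate is a leaf-with-epiphytes composite: every
#' tracer is the mass-fraction mixture
#' `(1 - r_true) * eelgrass draw + r_true * epiphyte draw`,
#' with fresh source draws per replicate. The generating `r_true` is recorded
#' in the `r_true` attribute as ground truth for recovery studies.
#'
#' @param config A [simulation_config()].
#' @return A tibble of IL tracer vectors with attribute `r_true`.
#' @export
simulate_initial_leaves <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  r <- config$r_true
  set.seed(config$seed + 1L)
  eel <- draw_source_table(config$source_params, "eelgrass", config$n_il,
                           clip_log = FALSE)
  epi <- draw_source_table(config$source_params, "epiphytes", config$n_il,
                           clip_log = FALSE)
  tracers <- setdiff(names(eel), c("source", "replicate"))
  out <- tibble::tibble(replicate = seq_len(config$n_il))
  for (tr in tracers) out[[tr]] <- (1 - r) * eel[[tr]] + r * epi[[tr]]
  attr(out, "r_true") <- r
  attr(out, "source_draws") <- list(eelgrass = eel, epiphytes = epi)
  out
}

#' Simulate decomposition-experiment observations
#'
#' For every metal-by-experiment row of the configured truth, draws `n_obs`
#' carbon contents uniformly over `c_range` (or along a supplied exponential
#' day-to-carbon decay curve) and generates concentrations from the
#' log-linear model `log_e y = beta1 + beta2 * C + N(0, sigma)`. Values below
#' a metal's detection limit are flagged censored and substituted by the
#' limit, mirroring how below-limit assays are treated in analysis.
#'
#' @param config A [simulation_config()].
#' @param metals Metals to generate (default all four).
#' @param day_curve Optional list `list(c0 = , k = )` mapping day to expected
#'   carbon content `c0 * exp(-k * day)`; when supplied, days are drawn
#'   uniformly on 0-56 and C follows the curve (truncated to `c_range`).
#' @return A tibble with columns `experiment`, `day`, `c_content`, then per
#'   metal `<m>`, `<m>_censored`, `<m>_limit`.
#' @export
simulate_decomposition <- function(config, metals = ZM_METALS,
                                   day_curve = NULL) {
  stopifnot(inherits(config, "simulation_config"))
  if (length(metals) == 0L) stop("at least one metal must be requested")
  metals <- match.arg(metals, ZM_METALS, several.ok = TRUE)
  truth <- config$decomp_truth
  experiments <- unique(truth$experiment)
  missing <- setdiff(
    paste(rep(metals, each = length(experiments)), experiments),
    paste(truth$metal, truth$experiment))
  if (length(missing)) {
    stop("decomp_truth lacks rows for: ", paste(missing, collapse = ", "))
  }
  set.seed(config$seed + 2L)
  out <- list()
  for (ex in experiments) {
    n <- config$n_obs
    if (is.null(day_curve)) {
      cc <- runif(n, config$c_range[1], config$c_range[2])
      # nominal day assignment: carbon falls as decomposition proceeds
      day <- as.numeric(rank(-cc, ties.method = "first") - 1L) *
        (56 / max(n - 1L, 1L))
    } else {
      day <- runif(n, 0, 56)
      cc <- day_curve$c0 * exp(-day_curve$k * day)
      cc <- pmin(pmax(cc, config$c_range[1]), config$c_range[2])
    }
    tab <- tibble::tibble(experiment = ex, day = day, c_content = cc)
    for (m in metals) {
      row <- truth[truth$metal == m & truth$experiment == ex, ]
      logy <- row$beta1 + row$beta2 * cc + rnorm(n, 0, sqrt(row$sigma2))
      y <- exp(logy)
      lim <- config$detection_limits[[m]]
      cens <- y < lim
      y[cens] <- lim
      tab[[m]] <- y
      tab[[paste0(m, "_censored")]] <- cens
      tab[[paste0(m, "_limit")]] <- lim
    }
    out[[ex]] <- tab
  }
  tibble::as_tibble(do.call(rbind, unname(out)))
}

#' Simulate sediment-core records for the two mesocosm pools
#'
#' Surface slices (0-1 cm) carry a delta-13C value spanning the configured
#' pool range and log element concentrations following the configured linear
#' trend with delta-13C; bottom slices (5-7 cm) are drawn around the
#' original-sediment baseline. The default design yields 3 replicate cores in
#' each of 4 sampling months per pool (12 surface and 12 bottom samples per
#' pool).
#'
#' @param config A [simulation_config()].
#' @return A tibble with columns `pool`, `layer`, `month`, `replicate`,
#'   `d13c` and one column per element.
#' @export
simulate_sediment_cores <- function(config) {
  stopifnot(inherits(config, "simulation_config"))
  st <- config$sediment_trend
  if (!all(c("eelgrass", "reference") %in% unique(st$surface$pool))) {
    stop("both pools must be configured in `sediment_trend`")
  }
  set.seed(config$seed + 3L)
  months <- st$months
  reps <- st$replicates
  elements <- unique(st$surface$element)
  rows <- list()
  for (pool in c("eelgrass", "reference")) {
    n <- length(months) * reps
    rng <- st$d13c_range[[pool]]
    d13c_surf <- runif(n, rng[1], rng[2])
    surf <- tibble::tibble(
      pool = pool, layer = "surface",
      month = rep(months, each = reps), replicate = rep(seq_len(reps),
                                                        length(months)),
      d13c = d13c_surf)
    d13c_bot <- rnorm(n, st$bottom_d13c[["mean"]], st$bottom_d13c[["sd"]])
    bot <- tibble::tibble(
      pool = pool, layer = "bottom",
      month = rep(months, each = reps), replicate = rep(seq_len(reps),
                                                        length(months)),
      d13c = d13c_bot)
    for (el in elements) {
      tr <- st$surface[st$surface$pool == pool & st$surface$element == el, ]
      surf[[el]] <- exp(tr$intercept + tr$slope * d13c_surf +
                          rnorm(n, 0, tr$sigma))
      bl <- st$bottom[st$bottom$element == el, ]
      bot[[el]] <- exp(rnorm(n, bl$log_mean, bl$log_sd))
    }
    rows[[paste0(pool, "_s")]] <- surf
    rows[[paste0(pool, "_b")]] <- bot
  }
  tibble::as_tibble(do.call(rbind, unname(rows)))
}
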