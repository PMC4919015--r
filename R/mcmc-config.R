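#' MCMC schedule configuration
#'
#' Holds the sampling schedule shared by the isotope-mixing and decomposition
#' samplers. `iterations` counts total sweeps per chain *including* burn-in;
#' retained draws are taken every `thinning`-th sweep from the pooled
#' post-burn-in stream (chain-major), so the retained count is
#' `floor(chains * (iterations - burn_in) / thinning)`.
#'
#' The default schedules are those used for the two model fits:
#' [wre_mcmc_config()] gives a single chain of 200,000 sweeps with 50,000
#' burn-in thinned every 15 (10,000 retained draws);
#' [decomp_mcmc_config()] gives 3 chains of 55,000 sweeps with 5,000 burn-in
#' each, thinned every 15 across the pooled 150,000 post-burn-in sweeps
#' (10,000 retained draws, per-chain retention balanced to within one draw).
#'
#' @param chains Number of independent chains.
#' @param iterations Total sweeps per chain, burn-in included.
#' @param burn_in Sweeps discarded at the start of each chain.
#' @param thinning Keep every `thinning`-th pooled post-burn-in sweep.
#' @param seed Integer seed; mandatory so every fit is reproducible.
#' @param proposal_sd Initial random-walk proposal standard deviation
#'   (isotope-mixing sampler only; adapted during burn-in towards a 20-50%
#'   acceptance rate and frozen afterwards).
#' @return An object of class `mcmc_config`.
#' @export
mcmc_config <- function(chains = 1L, iterations = 200000L, burn_in = 50000L,
                        thinning = 15L, seed = 1L, proposal_sd = 0.05) {
  chains <- as.integer(chains)
  iterations <- as.integer(iterations)
  burn_in <- as.integer(burn_in)
  thinning <- as.integer(thinning)
  stopifnot(chains >= 1L, thinning >= 1L, proposal_sd > 0)
  if (is.null(seed) || is.na(seed)) stop("`seed` is mandatory in mcmc_config()")
  if (burn_in >= iterations) stop("`burn_in` must be smaller than `iterations`")
  retained <- (chains * (iterations - burn_in)) %/% thinning
  if (retained < 1L) stop("schedule retains no draws: increase iterations or reduce thinning")
  structure(
    list(chains = chains, iterations = iterations, burn_in = burn_in,
         thinning = thinning, seed = as.integer(seed),
         proposal_sd = proposal_sd, retained = retained),
    class = "mcmc_config"
  )
}

#' @rdname mcmc_config
#' @export
wre_mcmc_config <- function(seed = 1L, iterations = 200000L, burn_in = 50000L,
                            thinning = 15L, proposal_sd = 0.05) {
  mcmc_config(chains = 1L, iterations = iterations, burn_in = burn_in,
              thinning = thinning, seed = seed, proposal_sd = proposal_sd)
}

#' @rdname mcmc_config
#' @export
decomp_mcmc_config <- function(seed = 1L, chains = 3L, iterations = 55000L,
                               burn_in = 5000L, thinning = 15L) {
  mcmc_config(chains = chains, iterations = iterations, burn_in = burn_in,
              thinning = thinning, seed = seed)
}

#' @export
print.mcmc_config <- function(x, ...) {
  cat(sprintf(
    "MCMC schedule: %d chain(s) x %d sweeps (burn-in %d), thin %d -> %d retained draws (seed %d)\n",
    x$chains, x$iterations, x$burn_in, x$thinning, x$retained, x$seed))
  invisible(x)
}

# Indices (per chain) of retained sweeps, thinning the pooled chain-major
# post-burn-in stream every `thinning` sweeps. Returns a list of integer
# vectors of post-burn-in sweep indices, one per chain; counts differ by at
# most one across chains.
retained_indices <- function(config) {
  per_chain <- config$iterations - config$burn_in
  total <- config$chains * per_chain
  pooled <- seq.int(config$thinning, total, by = config$thinning)
  lapply(seq_len(config$chains), function(ch) {
    local <- pooled - (ch - 1L) * per_chain
    local[local >= 1L & local <= per_chain]
  })
}
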