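#' Simulation parameters
#'
#' Bundle and validate the model constants and run controls of the
#' host-switching simulator. Defaults are the reference parameter set used
#' throughout the package: a single founding individual (`n0 = 1`) perfectly
#' adapted to a host resource with phenotype optimum `p_r0 = 5`, birth rate
#' `b = 0.5` offspring per individual per generation, carrying capacity
#' `K = 500`, per-individual emigration probability `d = 0.05`, survival-kernel
#' width `sigma_r = 0.5`, mutational standard deviation `sigma_v = 0.2`, and a
#' maximum offset `delta_r = 5` for newly offered resource optima. Runs last
#' `max_generations = 1000` generations or until extinction, and the first
#' `burn_in = 50` generations are excluded from pooled statistics.
#'
#' @param n0 Initial population size (count, >= 1).
#' @param b Birth rate, offspring per individual per generation (>= 0). May be
#'   fractional; see `offspring_law`.
#' @param K Carrying capacity: hard cap on population size, applied at
#'   reproduction (count, >= 1).
#' @param d Per-individual probability of attempting dispersal to the newly
#'   offered resource, each generation (in \[0, 1\]).
#' @param sigma_r Standard deviation of the Gaussian survival kernel, in
#'   phenotype units (> 0). All standardized distances and the Information
#'   Space are expressed in multiples of `sigma_r`.
#' @param sigma_v Standard deviation of the mutational deviate added to each
#'   offspring phenotype, in phenotype units (>= 0).
#' @param delta_r Maximum offset of a newly offered resource optimum from the
#'   current one, in phenotype units (>= 0).
#' @param p_r0 Phenotype optimum of the initial host resource.
#' @param max_generations Run length cap, in generations (>= 0).
#' @param burn_in Number of initial generations excluded from pooled
#'   statistics (>= 0).
#' @param offspring_law How the integer number of offspring is drawn from the
#'   rate `b`: `"poisson"` (default) draws `Poisson(b * N)`;
#'   `"binomial"` gives each parent `floor(b)` offspring plus a Bernoulli
#'   `b - floor(b)` extra. Both are truncated at `K - N`.
#' @param newborns_subject_to_events If `FALSE` (default), offspring produced
#'   in generation `n` join the population at `n + 1` and are exempt from that
#'   generation's dispersal and mortality; if `TRUE` they enter both pools
#'   immediately.
#' @param failed_disperser_fate What happens to a disperser that fails the
#'   colonization trial on the offered resource: `"return"` (default) puts it
#'   back on the home resource, where it undergoes the ordinary mortality
#'   check against the home optimum; `"die"` removes it outright, making
#'   every failed dispersal attempt lethal.
#'
#' @return An object of class `sim_params` (a validated named list).
#' @examples
#' p <- sim_params()
#' p$K
#' sim_params(b = 2, K = 1000)
#' @export
sim_params <- function(n0 = 1L, b = 0.5, K = 500L, d = 0.05,
                       sigma_r = 0.5, sigma_v = 0.2, delta_r = 5,
                       p_r0 = 5, max_generations = 1000L, burn_in = 50L,
                       offspring_law = c("poisson", "binomial"),
                       newborns_subject_to_events = FALSE,
                       failed_disperser_fate = c("return", "die")) {
  offspring_law <- match.arg(offspring_law)
  failed_disperser_fate <- match.arg(failed_disperser_fate)
  p <- list(
    n0 = as.integer(n0), b = as.numeric(b), K = as.integer(K),
    d = as.numeric(d), sigma_r = as.numeric(sigma_r),
    sigma_v = as.numeric(sigma_v), delta_r = as.numeric(delta_r),
    p_r0 = as.numeric(p_r0),
    max_generations = as.integer(max_generations),
    burn_in = as.integer(burn_in),
    offspring_law = offspring_law,
    newborns_subject_to_events = isTRUE(newborns_subject_to_events),
    failed_disperser_fate = failed_disperser_fate
  )
  validate_sim_params(p)
  structure(p, class = "sim_params")
}

check_scalar <- function(x, key) {
  if (length(x) != 1L || is.na(x)) {
    stop("parameter '", key, "' must be a single non-missing value",
         call. = FALSE)
  }
}

validate_sim_params <- function(p) {
  for (key in c("n0", "b", "K", "d", "sigma_r", "sigma_v", "delta_r",
                "p_r0", "max_generations", "burn_in")) {
    check_scalar(p[[key]], key)
  }
  fail <- function(key, what) {
    stop("parameter '", key, "' ", what, " (got ", p[[key]], ")",
         call. = FALSE)
  }
  if (p$n0 < 1L) fail("n0", "must be >= 1")
  if (p$b < 0) fail("b", "must be >= 0")
  if (p$K < 1L) fail("K", "must be >= 1")
  if (p$d < 0 || p$d > 1) fail("d", "must lie in [0, 1]")
  if (p$sigma_r <= 0) fail("sigma_r", "must be > 0")
  if (p$sigma_v < 0) fail("sigma_v", "must be >= 0")
  if (p$delta_r < 0) fail("delta_r", "must be >= 0")
  if (p$max_generations < 0L) fail("max_generations", "must be >= 0")
  if (p$burn_in < 0L) fail("burn_in", "must be >= 0")
  invisible(p)
}

#' @export
print.sim_params <- function(x, ...) {
  cat("Host-switching simulation parameters\n")
  cat(sprintf("  n0 = %d, b = %g, K = %d, d = %g\n", x$n0, x$b, x$K, x$d))
  cat(sprintf("  sigma_r = %g, sigma_v = %g, delta_r = %g, p_r0 = %g\n",
              x$sigma_r, x$sigma_v, x$delta_r, x$p_r0))
  cat(sprintf("  max_generations = %d, burn_in = %d\n",
              x$max_generations, x$burn_in))
  cat(sprintf("  offspring_law = %s, newborns_subject_to_events = %s\n",
              x$offspring_law, x$newborns_subject_to_events))
  cat(sprintf("  failed_disperser_fate = %s\n", x$failed_disperser_fate))
  invisible(x)
}
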