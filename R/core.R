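#' Gaussian survival probability on a host resource
#'
#' Survival of a parasite with phenotype `p_i` on a resource with optimum
#' `p_r` is `exp(-(p_i - p_r)^2 / (2 * sigma_r^2))`: a Gaussian kernel of the
#' phenotypic mismatch. A perfectly matched phenotype survives with
#' probability 1 and survival decays with the standardized distance
#' `|p_i - p_r| / sigma_r`; at three kernel widths it is `exp(-4.5)`, about
#' 1%. The same kernel governs both the colonization trial on a newly
#' offered resource and resident mortality on the current one.
#'
#' @param phenotype Numeric vector of parasite phenotypes.
#' @param optimum Resource phenotype optimum (recycled against `phenotype`).
#' @param sigma_r Kernel standard deviation, phenotype units (> 0).
#' @return Numeric vector of probabilities in (0, 1].
#' @examples
#' survival_probability(5, 5, 0.5)        # 1: perfect match
#' survival_probability(6.5, 5, 0.5)      # exp(-4.5), about 1%
#' @export
survival_probability <- function(phenotype, optimum, sigma_r) {
  if (length(sigma_r) != 1L || is.na(sigma_r) || sigma_r <= 0) {
    stop("parameter 'sigma_r' must be a single value > 0", call. = FALSE)
  }
  z <- (phenotype - optimum) / sigma_r
  exp(-z * z / 2)
}

#' Draw the number of offspring for one generation
#'
#' The population reproduces at rate `b` offspring per individual, but the
#' total population may never exceed the carrying capacity `K`: the drawn
#' count is truncated at `K - current_size`. Under the default `"poisson"`
#' law the count is `Poisson(b * current_size)`, which handles fractional and
#' greater-than-one rates uniformly and lets a single founder leave
#' offspring. The `"binomial"` law gives each parent `floor(b)` offspring
#' plus a Bernoulli extra with probability `b - floor(b)`.
#'
#' @param current_size Current population size (0 <= `current_size` <= `K`).
#' @param b Birth rate (offspring per individual per generation).
#' @param K Carrying capacity.
#' @param law `"poisson"` or `"binomial"`.
#' @return Integer count in `[0, K - current_size]`.
#' @export
draw_offspring_count <- function(current_size, b, K,
                                 law = "poisson") {
  # hot path: called once per generation, so avoid match.arg machinery
  if (!law %in% c("poisson", "binomial")) {
    stop("unknown offspring law: ", law, call. = FALSE)
  }
  if (current_size > K) {
    stop("invalid state: population size ", current_size,
         " exceeds carrying capacity ", K, call. = FALSE)
  }
  if (current_size <= 0L) return(0L)
  room <- K - current_size
  n <- switch(law,
    poisson  = stats::rpois(1L, b * current_size),
    binomial = as.integer(floor(b)) * current_size +
               stats::rbinom(1L, current_size, b - floor(b))
  )
  as.integer(min(n, room))
}

#' Generate offspring phenotypes by recombination and mutation
#'
#' Each offspring phenotype is the arithmetic mean of two parents drawn
#' uniformly at random with replacement (the first parent is returned to the
#' pool before the second draw, so self-fertilization occurs with probability
#' `1/N`), plus an independent Gaussian mutational deviate of mean zero and
#' standard deviation `sigma_v`. The averaging stands for recombination; the
#' deviate for spontaneous mutation.
#'
#' @param parent_pool Numeric vector of parent phenotypes (non-empty when
#'   `count > 0`).
#' @param count Number of offspring to generate.
#' @param sigma_v Mutational standard deviation (>= 0).
#' @return Numeric vector of `count` offspring phenotypes.
#' @export
generate_offspring <- function(parent_pool, count, sigma_v) {
  count <- as.integer(count)
  if (count == 0L) return(numeric(0L))
  n <- length(parent_pool)
  if (n == 0L) {
    stop("invalid state: cannot generate offspring from an empty parent pool",
         call. = FALSE)
  }
  i1 <- sample.int(n, count, replace = TRUE)
  i2 <- sample.int(n, count, replace = TRUE)
  mid <- (parent_pool[i1] + parent_pool[i2]) / 2
  if (sigma_v > 0) mid <- mid + stats::rnorm(count, 0, sigma_v)
  mid
}

#' Propose a new host resource optimum
#'
#' Each generation a single new resource is offered whose phenotype optimum
#' is uniform on `[current_optimum - delta_r, current_optimum + delta_r]`.
#'
#' @param current_optimum Optimum of the currently occupied resource.
#' @param delta_r Maximum offset (>= 0); `delta_r = 0` returns
#'   `current_optimum` exactly.
#' @return A single optimum value.
#' @export
propose_resource <- function(current_optimum, delta_r) {
  if (delta_r < 0) stop("parameter 'delta_r' must be >= 0", call. = FALSE)
  stats::runif(1L, current_optimum - delta_r, current_optimum + delta_r)
}

#' Select which individuals attempt dispersal
#'
#' Every individual independently attempts dispersal to the offered resource
#' with probability `d`. Returns the index partition into dispersers and
#' residents.
#'
#' @param population_size Number of individuals eligible to disperse.
#' @param d Per-individual dispersal probability (in \[0, 1\]).
#' @return A list with integer index vectors `dispersers` and `residents`.
#' @export
select_dispersers <- function(population_size, d) {
  if (d < 0 || d > 1) stop("parameter 'd' must lie in [0, 1]", call. = FALSE)
  if (population_size == 0L) {
    return(list(dispersers = integer(0L), residents = integer(0L)))
  }
  goes <- stats::runif(population_size) < d
  list(dispersers = which(goes), residents = which(!goes))
}
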