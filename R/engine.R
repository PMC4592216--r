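#' Create a population state
#'
#' A light container for the current phenotype collection, the optimum of the
#' occupied resource, the generation index, and the generation of the last
#' host switch (0 when the lineage is still on its initial host).
#'
#' @param phenotypes Numeric vector, one phenotype per living parasite.
#' @param resource_optimum Optimum of the currently occupied resource.
#' @param generation Integer generation index (0 = initial state).
#' @param last_switch_generation Generation of the most recent establishment.
#' @return An object of class `population_state`.
#' @export
population_state <- function(phenotypes, resource_optimum, generation = 0L,
                             last_switch_generation = 0L) {
  structure(
    list(phenotypes = as.numeric(phenotypes),
         resource_optimum = as.numeric(resource_optimum),
         generation = as.integer(generation),
         last_switch_generation = as.integer(last_switch_generation)),
    class = "population_state"
  )
}

record_cols <- c("generation", "population_size", "p_min", "p_max", "IS",
                 "resource_optimum", "offered_optimum", "n_dispersers",
                 "n_founders", "switch_occurred", "time_since_switch")

#' Advance the population by one generation
#'
#' Executes one cycle of the model, in order: (1) reproduction — an offspring
#' count capped at `K - N` is drawn and offspring phenotypes generated from
#' the current adults; (2) a single new resource optimum is proposed; (3)
#' each eligible individual attempts dispersal with probability `d`; (4)
#' dispersers face the colonization trial, surviving with the Gaussian kernel
#' evaluated against the offered optimum; (5) if at least one founder
#' survives, the founders alone form the next generation on the new resource
#' (the ancestral population, including that generation's offspring, is
#' dropped) and a colonization event is recorded; otherwise the population
#' stays on its resource: failed dispersers rejoin the residents (or die
#' outright, under `failed_disperser_fate = "die"`), everyone undergoes the
#' mortality check against the current optimum, and survivors plus offspring
#' form the next generation.
#'
#' By default offspring produced in a generation are exempt from that
#' generation's dispersal and mortality, joining the population afterwards;
#' `newborns_subject_to_events = TRUE` puts them in both pools immediately.
#'
#' @param state A `population_state` with at least one individual.
#' @param params A [sim_params()] object.
#' @return A list with elements `state` (the new `population_state`),
#'   `record` (named numeric vector of per-generation observables), and
#'   `event` (`NULL`, or a list describing an establishment).
#' @export
step_generation <- function(state, params) {
  phen <- state$phenotypes
  n <- length(phen)
  if (n == 0L) {
    stop("invalid state: cannot step an extinct population", call. = FALSE)
  }
  gen <- state$generation + 1L
  p_r <- state$resource_optimum

  n_off <- draw_offspring_count(n, params$b, params$K, params$offspring_law)
  offspring <- generate_offspring(phen, n_off, params$sigma_v)

  p_new <- propose_resource(p_r, params$delta_r)

  pool <- if (params$newborns_subject_to_events) c(phen, offspring) else phen
  sel <- select_dispersers(length(pool), params$d)
  dispersers <- pool[sel$dispersers]
  n_disp <- length(dispersers)

  founders <- numeric(0L)
  if (n_disp > 0L) {
    s <- survival_probability(dispersers, p_new, params$sigma_r)
    founders <- dispersers[stats::runif(n_disp) < s]
  }
  n_found <- length(founders)

  event <- NULL
  if (n_found >= 1L) {
    rng <- range(phen)
    event <- list(
      generation = gen,
      source_optimum = p_r,
      target_optimum = p_new,
      standardized_distance = abs(p_new - p_r) / params$sigma_r,
      n_founders = n_found,
      pre_switch_size = n,
      pre_switch_IS = (rng[2L] - rng[1L]) / params$sigma_r,
      time_since_last_switch = state$generation - state$last_switch_generation,
      founder_phenotypes = founders
    )
    new_phen <- founders
    new_opt <- p_new
    last_switch <- gen
  } else {
    residents <- pool[sel$residents]
    if (identical(params$failed_disperser_fate, "return")) {
      residents <- c(residents, dispersers)
    }
    if (length(residents) > 0L) {
      s <- survival_probability(residents, p_r, params$sigma_r)
      residents <- residents[stats::runif(length(residents)) < s]
    }
    new_phen <- if (params$newborns_subject_to_events) residents
                else c(residents, offspring)
    new_opt <- p_r
    last_switch <- state$last_switch_generation
  }

  sz <- length(new_phen)
  if (sz > 0L) {
    rng <- range(new_phen)
    p_min <- rng[1L]; p_max <- rng[2L]
    is_val <- (p_max - p_min) / params$sigma_r
  } else {
    p_min <- NA_real_; p_max <- NA_real_; is_val <- NA_real_
  }
  record <- c(generation = gen, population_size = sz, p_min = p_min,
              p_max = p_max, IS = is_val, resource_optimum = p_r,
              offered_optimum = p_new, n_dispersers = n_disp,
              n_founders = n_found, switch_occurred = as.numeric(n_found >= 1L),
              time_since_switch = gen - last_switch)

  list(
    state = population_state(new_phen, new_opt, gen, last_switch),
    record = record,
    event = event
  )
}

#' Run one replicate of the host-switching simulation
#'
#' Starts from `n0` individuals, all with phenotype equal to the initial
#' resource optimum `p_r0` (a best-adapted founding population), and iterates
#' [step_generation()] until the population goes extinct or
#' `max_generations` is reached. Generation 0 is the initial state; records
#' are emitted for generations `1..final_generation`. All randomness flows
#' through R's global RNG stream, seeded once from `seed`, so identical
#' `(params, seed)` pairs yield bit-identical results.
#'
#' @param params A [sim_params()] object.
#' @param seed Integer seed for the run.
#' @param initial_phenotypes Optional numeric vector overriding the default
#'   founding phenotypes (a testing hook; length sets the initial size).
#' @return An object of class `ecofit_run`: a list with `records` (one
#'   data.frame row per generation), `events` (one row per establishment,
#'   with outcome `"pending"` until [classify_outcomes()] resolves it;
#'   founder phenotypes in the list column `founder_phenotypes`),
#'   `termination` (`"extinct"` or `"reached_cap"`), `final_generation`,
#'   `params`, and `seed`.
#' @examples
#' run <- run_simulation(sim_params(max_generations = 100L), seed = 1)
#' run$termination
#' head(run$records)
#' @export
run_simulation <- function(params, seed, initial_phenotypes = NULL) {
  stopifnot(inherits(params, "sim_params"))
  set.seed(seed)
  phen <- if (is.null(initial_phenotypes)) rep(params$p_r0, params$n0)
          else as.numeric(initial_phenotypes)
  state <- population_state(phen, params$p_r0)

  n_max <- params$max_generations
  rec <- matrix(NA_real_, nrow = n_max, ncol = length(record_cols),
                dimnames = list(NULL, record_cols))
  events <- vector("list", 64L)
  n_events <- 0L

  g <- 0L
  while (g < n_max && length(state$phenotypes) > 0L) {
    out <- step_generation(state, params)
    state <- out$state
    g <- g + 1L
    rec[g, ] <- out$record
    if (!is.null(out$event)) {
      n_events <- n_events + 1L
      if (n_events > length(events)) events <- c(events, vector("list", length(events)))
      events[[n_events]] <- out$event
    }
  }

  records <- as.data.frame(rec[seq_len(g), , drop = FALSE])
  termination <- if (length(state$phenotypes) == 0L) "extinct" else "reached_cap"

  structure(
    list(records = records, events = build_events_df(events[seq_len(n_events)]),
         termination = termination, final_generation = g,
         params = params, seed = seed),
    class = "ecofit_run"
  )
}

build_events_df <- function(ev) {
  num <- function(f) vapply(ev, function(e) as.numeric(e[[f]]), numeric(1L))
  df <- data.frame(
    generation = if (length(ev)) as.integer(num("generation")) else integer(0L),
    source_optimum = num("source_optimum"),
    target_optimum = num("target_optimum"),
    standardized_distance = num("standardized_distance"),
    n_founders = if (length(ev)) as.integer(num("n_founders")) else integer(0L),
    pre_switch_size = if (length(ev)) as.integer(num("pre_switch_size")) else integer(0L),
    pre_switch_IS = num("pre_switch_IS"),
    time_since_last_switch = if (length(ev)) as.integer(num("time_since_last_switch")) else integer(0L),
    outcome = rep("pending", length(ev)),
    resolution_generation = rep(NA_integer_, length(ev)),
    stringsAsFactors = FALSE
  )
  df$founder_phenotypes <- I(lapply(ev, `[[`, "founder_phenotypes"))
  df
}

#' @export
print.ecofit_run <- function(x, ...) {
  cat(sprintf(
    "<ecofit_run> %d generation(s), %d colonization event(s), %s (seed %s)\n",
    x$final_generation, nrow(x$events), x$termination, format(x$seed)))
  invisible(x)
}

#' Resolve colonization outcomes retrospectively
#'
#' A colonization event is a *successful* host switch if the founded lineage
#' does not go extinct before the next establishment (or before the end of
#' the observation window); it is a *failed* attempt if the population dies
#' out first, regardless of how many generations that takes. Events still
#' pending at the generation cap are classified successful: the colonization
#' did not lead to extinction within the observed horizon.
#'
#' @param events The `events` data.frame of a run (ordered by generation).
#' @param result The `ecofit_run` the events came from.
#' @return `events` with `outcome` set to `"success"`/`"failure"` and
#'   `resolution_generation` filled in.
#' @export
classify_outcomes <- function(events, result) {
  n <- nrow(events)
  if (n == 0L) return(events)
  if (is.unsorted(events$generation)) {
    stop("invalid input: events must be ordered by generation", call. = FALSE)
  }
  out <- rep("success", n)
  res <- c(events$generation[-1L], result$final_generation)
  if (identical(result$termination, "extinct")) out[n] <- "failure"
  events$outcome <- out
  events$resolution_generation <- as.integer(res)
  events
}
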