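#' Information Space of a phenotype collection
#'
#' The Information Space (IS) is the standardized phenotypic amplitude of a
#' population, `(p_max - p_min) / sigma_r`: the operational measure of how
#' much of the surrounding resource space the population's accumulated
#' variation covers. A single individual has IS = 0.
#'
#' @param phenotypes Non-empty numeric vector of phenotypes.
#' @param sigma_r Survival-kernel standard deviation (> 0).
#' @return Non-negative IS value, in multiples of `sigma_r`.
#' @examples
#' information_space(c(4.5, 5, 5.5), 0.5)  # 2
#' @export
information_space <- function(phenotypes, sigma_r) {
  if (length(phenotypes) == 0L) {
    stop("invalid input: empty phenotype collection", call. = FALSE)
  }
  if (sigma_r <= 0) stop("parameter 'sigma_r' must be > 0", call. = FALSE)
  r <- range(phenotypes)
  (r[2L] - r[1L]) / sigma_r
}

#' Standardized population-to-resource metrics
#'
#' Computes, for one population on one resource: the Information Space
#' `IS = (p_max - p_min) / sigma_r`; the standardized distance between the
#' resource optimum and the midpoint of the phenotype distribution,
#' `|p_r - (p_min + (p_max - p_min)/2)| / sigma_r` (the midpoint is taken in
#' raw phenotype units and only the distance is standardized, keeping the
#' quantity dimensionally consistent); and the standardized distance between
#' the optimum and the population maximum, `|p_r - p_max| / sigma_r`. The
#' variant using the phenotype farthest from the optimum on either side,
#' `max_i |p_r - p_i| / sigma_r`, is returned alongside as
#' `max_abs_distance`.
#'
#' @param phenotypes Non-empty numeric vector.
#' @param resource_optimum The occupied resource's optimum `p_r`.
#' @param sigma_r Survival-kernel standard deviation (> 0).
#' @return A list with `IS`, `midpoint_distance`, `max_distance`, and
#'   `max_abs_distance`, all in multiples of `sigma_r`.
#' @export
population_metrics <- function(phenotypes, resource_optimum, sigma_r) {
  if (length(phenotypes) == 0L) {
    stop("invalid input: empty phenotype collection", call. = FALSE)
  }
  if (sigma_r <= 0) stop("parameter 'sigma_r' must be > 0", call. = FALSE)
  r <- range(phenotypes)
  midpoint <- r[1L] + (r[2L] - r[1L]) / 2
  list(
    IS = (r[2L] - r[1L]) / sigma_r,
    midpoint_distance = abs(resource_optimum - midpoint) / sigma_r,
    max_distance = abs(resource_optimum - r[2L]) / sigma_r,
    max_abs_distance = max(abs(resource_optimum - phenotypes)) / sigma_r
  )
}

resolve_check <- function(events) {
  if (any(events$outcome == "pending")) {
    stop("invalid input: events contain unresolved (pending) outcomes; ",
         "run classify_outcomes() first", call. = FALSE)
  }
  invisible(events)
}

event_covariates <- c("pre_switch_size", "pre_switch_IS",
                      "standardized_distance", "time_since_last_switch",
                      "n_founders")

bin_index <- function(v, width) as.integer(floor(v / width + 1e-9))

#' Colonization success probability along one covariate
#'
#' Bins resolved colonization events by a pre-switch covariate (population
#' size, Information Space, standardized source-to-target distance, or time
#' since the previous switch — all measured just before establishment) and
#' returns the per-bin attempt count, success count, and success
#' probability. Events within the burn-in window are excluded; empty bins
#' are omitted, never zero-filled.
#'
#' @param events Resolved events (pooled across runs is fine).
#' @param covariate One of `"pre_switch_size"`, `"pre_switch_IS"`,
#'   `"standardized_distance"`, `"time_since_last_switch"`, `"n_founders"`.
#' @param bin_width Positive bin width, in the covariate's units
#'   (standardized `sigma_r` multiples for IS and distances, individuals for
#'   sizes, generations for times).
#' @param burn_in Events with `generation <= burn_in` are dropped
#'   (default 50).
#' @return A data.frame with `bin_lower`, `bin_upper`, `attempts`,
#'   `successes`, `probability`.
#' @export
success_curve <- function(events, covariate, bin_width, burn_in = 50L) {
  covariate <- match.arg(covariate, event_covariates)
  if (bin_width <= 0) stop("parameter 'bin_width' must be > 0", call. = FALSE)
  resolve_check(events)
  ev <- events[events$generation > burn_in, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(bin_lower = numeric(0L), bin_upper = numeric(0L),
                      attempts = integer(0L), successes = integer(0L),
                      probability = numeric(0L)))
  }
  idx <- bin_index(ev[[covariate]], bin_width)
  succ <- ev$outcome == "success"
  attempts <- tapply(succ, idx, length)
  successes <- tapply(succ, idx, sum)
  lev <- as.numeric(names(attempts))
  ord <- order(lev)
  data.frame(
    bin_lower = lev[ord] * bin_width,
    bin_upper = (lev[ord] + 1) * bin_width,
    attempts = as.integer(attempts[ord]),
    successes = as.integer(successes[ord]),
    probability = as.numeric(successes[ord] / attempts[ord])
  )
}

#' Colonization success phase diagram over two covariates
#'
#' Two-dimensional analogue of [success_curve()]: resolved events are binned
#' jointly on two pre-switch covariates (e.g. Information Space against the
#' standardized distance to the offered resource) and the per-cell attempt
#' count, success count, and success probability are returned. Only occupied
#' cells appear.
#'
#' @param events Resolved events.
#' @param x_covariate,y_covariate Covariate names, as in [success_curve()].
#' @param x_bin_width,y_bin_width Positive bin widths.
#' @param burn_in Events with `generation <= burn_in` are dropped.
#' @return A data.frame with `x_lower`, `x_upper`, `y_lower`, `y_upper`,
#'   `attempts`, `successes`, `probability`.
#' @export
phase_diagram <- function(events, x_covariate, y_covariate,
                          x_bin_width = 0.1, y_bin_width = 0.1,
                          burn_in = 50L) {
  x_covariate <- match.arg(x_covariate, event_covariates)
  y_covariate <- match.arg(y_covariate, event_covariates)
  if (x_bin_width <= 0 || y_bin_width <= 0) {
    stop("bin widths must be > 0", call. = FALSE)
  }
  resolve_check(events)
  ev <- events[events$generation > burn_in, , drop = FALSE]
  if (nrow(ev) == 0L) {
    return(data.frame(x_lower = numeric(0L), x_upper = numeric(0L),
                      y_lower = numeric(0L), y_upper = numeric(0L),
                      attempts = integer(0L), successes = integer(0L),
                      probability = numeric(0L)))
  }
  ix <- bin_index(ev[[x_covariate]], x_bin_width)
  iy <- bin_index(ev[[y_covariate]], y_bin_width)
  key <- paste(ix, iy)
  succ <- ev$outcome == "success"
  attempts <- tapply(succ, key, length)
  successes <- tapply(succ, key, sum)
  parts <- do.call(rbind, strsplit(names(attempts), " ", fixed = TRUE))
  bx <- as.numeric(parts[, 1L]); by <- as.numeric(parts[, 2L])
  ord <- order(bx, by)
  data.frame(
    x_lower = bx[ord] * x_bin_width, x_upper = (bx[ord] + 1) * x_bin_width,
    y_lower = by[ord] * y_bin_width, y_upper = (by[ord] + 1) * y_bin_width,
    attempts = as.integer(attempts[ord]),
    successes = as.integer(successes[ord]),
    probability = as.numeric(successes[ord] / attempts[ord])
  )
}

#' First-order Spearman partial correlation
#'
#' Rank-based partial correlation of `x` and `y` controlling for `z`:
#' Spearman coefficients (average ranks for ties) are combined by the
#' first-order formula
#' `(r_xy - r_xz * r_yz) / sqrt((1 - r_xz^2) * (1 - r_yz^2))`, equivalent to
#' correlating the residuals of rank-on-rank regressions.
#'
#' @param x,y Numeric vectors of equal length (>= 3).
#' @param z Controlling variable, same length.
#' @return A single correlation in `[-1, 1]`.
#' @examples
#' set.seed(1)
#' x <- rnorm(200); z <- rnorm(200)
#' spearman_partial(x, exp(x), z)  # ~1: monotone association, independent z
#' @export
spearman_partial <- function(x, y, z) {
  n <- length(x)
  if (length(y) != n || length(z) != n) {
    stop("invalid input: x, y, z must have equal length", call. = FALSE)
  }
  if (n < 3L) stop("invalid input: need at least 3 observations", call. = FALSE)
  rx <- rank(x); ry <- rank(y); rz <- rank(z)
  if (stats::sd(rx) == 0 || stats::sd(ry) == 0 || stats::sd(rz) == 0) {
    stop("undefined correlation: a ranked variable is constant", call. = FALSE)
  }
  rxy <- stats::cor(rx, ry)
  rxz <- stats::cor(rx, rz)
  ryz <- stats::cor(ry, rz)
  den <- sqrt((1 - rxz^2) * (1 - ryz^2))
  if (den == 0) {
    stop("undefined correlation: control variable explains x or y exactly",
         call. = FALSE)
  }
  (rxy - rxz * ryz) / den
}
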