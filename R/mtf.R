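#' Randomly allocate total bed capacity over facilities
#'
#' Draws a vector of `n` integer capacities, each at least `minimum`, summing
#' exactly to `total`. The surplus `total - n * minimum` is distributed as a
#' uniformly random integer composition over the `n` facilities (stars and
#' bars), which is exchangeable: every facility has marginal mean
#' `total / n`.
#'
#' @param total Total capacity to distribute.
#' @param n Number of facilities.
#' @param minimum Smallest allowed single-facility capacity.
#' @return Integer vector of length `n`.
#' @export
allocate_capacities <- function(total, n, minimum) {
  total <- as.integer(total); n <- as.integer(n); minimum <- as.integer(minimum)
  if (total < n * minimum)
    stop("infeasible: total (", total, ") < n * minimum (", n * minimum, ")",
         call. = FALSE)
  s <- total - n * minimum
  if (n == 1L) return(total)
  if (s == 0L) return(rep(minimum, n))
  cuts <- sort(sample.int(s + n - 1L, n - 1L))
  parts <- diff(c(0L, cuts, s + n)) - 1L
  parts + minimum
}

#' Sample one day's casualty dispatch counts
#'
#' Each source generates `casualty_rate` casualties and routes each one
#' independently to a facility according to its routing-probability column,
#' i.e. one multinomial draw per source.
#'
#' @param casualty_rate Casualties per source for the day.
#' @param config An [mtf_config()].
#' @return Integer matrix `n_mtfs` x `n_sources` of dispatched counts; each
#'   column sums to `casualty_rate`.
#' @export
sample_arrivals <- function(casualty_rate, config) {
  if (casualty_rate < 0) stop("casualty_rate must be >= 0", call. = FALSE)
  n <- config$n_mtfs
  if (casualty_rate == 0)
    return(matrix(0L, n, config$n_sources))
  out <- vapply(seq_len(config$n_sources), function(j) {
    as.integer(stats::rmultinom(1L, casualty_rate, config$routing_probs[, j]))
  }, integer(n))
  matrix(out, nrow = n)
}

#' Apply per-kilometre transit attrition to dispatched casualties
#'
#' A casualty travelling `D` km survives each kilometre independently with
#' probability `1 - p_dow_transit_per_km`, so survives transit with
#' probability `(1 - p)^D`; survivor counts are binomial.
#'
#' @param dispatched Integer matrix `n_mtfs` x `n_sources` from
#'   [sample_arrivals()].
#' @param config An [mtf_config()].
#' @return List with `survivors` (integer matrix, same shape) and
#'   `transit_dow` (total deaths in transit).
#' @export
transit_attrition <- function(dispatched, config) {
  if (any(dispatched < 0)) stop("dispatched must be non-negative", call. = FALSE)
  p_surv <- (1 - config$p_dow_transit_per_km) ^ config$distances
  survivors <- matrix(
    stats::rbinom(length(dispatched), as.vector(dispatched), as.vector(p_surv)),
    nrow = nrow(dispatched)
  )
  list(survivors = survivors,
       transit_dow = sum(dispatched) - sum(survivors))
}

#' Initialize an empty MTF system state
#'
#' @param capacities Integer vector of per-facility bed capacities.
#' @return An object of class `mtf_state` with zero occupancy and zeroed
#'   cumulative patient accounting.
#' @export
new_mtf_state <- function(capacities) {
  structure(list(
    occupancy = integer(length(capacities)),
    capacity = as.integer(capacities),
    cum_dow_transit = 0L, cum_dow_facility = 0L,
    cum_rtd = 0L, cum_transferred = 0L, cum_generated = 0L
  ), class = "mtf_state")
}

mtf_conservation_gap <- function(state) {
  state$cum_generated -
    (state$cum_dow_transit + state$cum_dow_facility + state$cum_rtd +
       state$cum_transferred + sum(state$occupancy))
}

#' Advance the MTF system by one day
#'
#' Executes, in order: (1) a per-facility multinomial split of the standing
#' occupancy into died / returned-to-duty / stayed with probabilities
#' `(p_dow, p_rtd, 1 - p_dow - p_rtd)`; (2) hospital transfer-out of
#' `min(r_out, occupancy)` patients; (3) casualty generation, transit
#' attrition and arrival of the survivors; (4) conversion of any occupancy
#' above capacity into deaths (overflow, always last); (5) recording of the
#' post-overflow fullness row `occupancy / capacity`, guaranteed in
#' `[0, 1]`. Patients admitted on a given day are thus visible in that
#' day's recorded occupancy (and exposed to same-day overflow) but face
#' their first exit lottery the next day. Patient conservation is checked
#' after every step.
#'
#' @param state An `mtf_state`.
#' @param config An [mtf_config()].
#' @return List with updated `state`, the day's `fullness` row and the day's
#'   total deaths `daily_dow` (transit + in-facility + overflow).
#' @export
step_day <- function(state, config) {
  n <- config$n_mtfs
  occ <- state$occupancy

  # per-facility fate lottery for the standing population
  dow <- integer(n); rtd <- integer(n)
  for (i in seq_len(n)) {
    if (occ[i] == 0L) next
    split <- stats::rmultinom(1L, occ[i],
                              c(config$p_dow[i], config$p_rtd[i],
                                1 - config$p_dow[i] - config$p_rtd[i]))
    dow[i] <- split[1L]; rtd[i] <- split[2L]
  }
  occ <- occ - dow - rtd

  transferred <- pmin(config$r_out, occ)
  occ <- occ - transferred

  dispatched <- sample_arrivals(config$casualty_rate, config)
  att <- transit_attrition(dispatched, config)
  occ <- occ + as.integer(rowSums(att$survivors))
  state$cum_generated <- state$cum_generated + sum(dispatched)
  state$cum_dow_transit <- state$cum_dow_transit + att$transit_dow

  overflow <- pmax(0L, occ - state$capacity)
  occ <- occ - overflow

  state$occupancy <- as.integer(occ)
  state$cum_dow_facility <- state$cum_dow_facility + sum(dow) + sum(overflow)
  state$cum_rtd <- state$cum_rtd + sum(rtd)
  state$cum_transferred <- state$cum_transferred + sum(transferred)

  if (mtf_conservation_gap(state) != 0L)
    stop("internal consistency error: patient conservation violated",
         call. = FALSE)

  list(state = state,
       fullness = occ / state$capacity,
       daily_dow = att$transit_dow + sum(dow) + sum(overflow))
}

#' Run one MTF simulation
#'
#' Draws facility capacities once with [allocate_capacities()], then advances
#' [step_day()] for `config$n_days` days, recording the fullness observable
#' (occupancy / capacity per facility per day) and the death toll.
#'
#' @param config An [mtf_config()].
#' @param seed Optional integer seed for a reproducible run.
#' @return An object of class `mtf_run`: `fullness` (`n_days` x `n_mtfs`
#'   matrix), `total_dow`, `daily_dow`, `capacities`, and the final `state`
#'   with cumulative accounting.
#' @export
run_mtf <- function(config, seed = NULL) {
  if (!is.null(seed)) set.seed(seed)
  caps <- allocate_capacities(config$total_capacity, config$n_mtfs,
                              config$min_capacity)
  state <- new_mtf_state(caps)
  fullness <- matrix(NA_real_, config$n_days, config$n_mtfs)
  daily_dow <- integer(config$n_days)
  for (d in seq_len(config$n_days)) {
    res <- step_day(state, config)
    state <- res$state
    fullness[d, ] <- res$fullness
    daily_dow[d] <- res$daily_dow
  }
  structure(list(
    fullness = fullness,
    total_dow = state$cum_dow_transit + state$cum_dow_facility,
    daily_dow = daily_dow,
    capacities = caps,
    state = state,
    casualty_rate = config$casualty_rate
  ), class = "mtf_run")
}

#' Summarize deaths across replicate MTF runs
#'
#' @param results Non-empty list of `mtf_run` objects.
#' @param casualty_rate The shared casualty rate, used to normalize.
#' @return List with `mean_dow`, `sd_dow`, `normalized_mean` and
#'   `normalized_sd` (mean and SD divided by the casualty rate).
#' @export
dow_summary <- function(results, casualty_rate) {
  if (length(results) == 0L) stop("empty result list", call. = FALSE)
  if (casualty_rate <= 0)
    stop("normalized DOW undefined for casualty_rate <= 0", call. = FALSE)
  dows <- vapply(results, function(r) as.numeric(r$total_dow), numeric(1))
  m <- mean(dows)
  s <- if (length(dows) > 1L) stats::sd(dows) else 0
  list(mean_dow = m, sd_dow = s,
       normalized_mean = m / casualty_rate,
       normalized_sd = s / casualty_rate)
}
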