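#' Build the hexagonal mission-site network
#'
#' Sites are laid out on an offset ("odd-row shifted") hexagonal lattice,
#' numbered row-major from 1. Two sites are adjacent when their hexes share
#' an edge, so every site has between 2 (corner) and 6 (interior) neighbors.
#' The depot is attached to `depot_neighbors`; by default the left ends of
#' the first and last rows (sites 1 and 31 on the 6 x 6 grid), the sites
#' nearest the fuel source.
#'
#' @param rows,cols Grid dimensions.
#' @param depot_neighbors Site ids linked to the depot; default picks the
#'   left ends of the first and last rows.
#' @return An object of class `sf_network`: `neighbors` (list of integer
#'   vectors, site-to-site adjacency), `depot_links`, `rows`, `cols`.
#' @export
build_hex_grid <- function(rows, cols, depot_neighbors = NULL) {
  rows <- as.integer(rows); cols <- as.integer(cols)
  if (rows < 1L || cols < 1L) stop("rows and cols must be >= 1", call. = FALSE)
  n <- rows * cols
  if (is.null(depot_neighbors))
    depot_neighbors <- unique(c(1L, (rows - 1L) * cols + 1L))
  depot_neighbors <- as.integer(depot_neighbors)
  if (any(depot_neighbors < 1L | depot_neighbors > n))
    stop("depot_neighbors out of range 1..", n, call. = FALSE)

  # odd-r offset deltas (dcol, drow); rr, cc are 0-based
  deltas_even <- cbind(c(1L, 0L, -1L, -1L, -1L, 0L),
                       c(0L, -1L, -1L, 0L, 1L, 1L))
  deltas_odd <- cbind(c(1L, 1L, 0L, -1L, 0L, 1L),
                      c(0L, -1L, -1L, 0L, 1L, 1L))
  neighbors <- vector("list", n)
  for (s in seq_len(n)) {
    rr <- (s - 1L) %/% cols
    cc <- (s - 1L) %% cols
    d <- if (rr %% 2L == 0L) deltas_even else deltas_odd
    nc <- cc + d[, 1L]; nr <- rr + d[, 2L]
    ok <- nc >= 0L & nc < cols & nr >= 0L & nr < rows
    neighbors[[s]] <- sort(nr[ok] * cols + nc[ok] + 1L)
  }
  structure(list(neighbors = neighbors, depot_links = depot_neighbors,
                 rows = rows, cols = cols),
            class = "sf_network")
}

DEPOT <- 0L  # location id of the depot

new_sf_state <- function(config) {
  n_sites <- config$grid_rows * config$grid_cols
  assets <- if (config$n_assets > 0L) {
    lapply(seq_len(config$n_assets), function(i) list(
      location = DEPOT,
      internal = config$internal_max,
      towed = config$towed_max,
      alive = TRUE
    ))
  } else list()
  list(site_fuel = rep(config$site_capacity, n_sites),
       assets = assets, step = 0L)
}

#' Enumerate the legal actions of one asset
#'
#' At the depot with internal fuel below maximum, the only action is to
#' refuel. At the depot with full internal fuel, the asset must move to one
#' of the depot-linked sites. At a site, the action set is \{stay\} plus one
#' distinct transfer action per integer amount `1..min(towed, free site
#' capacity)` plus one move action per neighboring site (and the depot, if
#' linked). Each listed action is equiprobable when sampled, so large site
#' deficits make transfers dominate the action set.
#'
#' @param asset Asset state list (`location`, `internal`, `towed`, `alive`).
#' @param site_fuel Integer vector of current site fuel levels.
#' @param net An `sf_network`.
#' @param config An [sf_config()].
#' @return List with `n` (total action count) and components describing the
#'   action set: `stay` (logical), `refuel` (logical), `n_transfer` (max
#'   transferable amount; actions transfer 1..n_transfer), `moves` (integer
#'   vector of destinations, `0` = depot).
#' @export
legal_actions <- function(asset, site_fuel, net, config) {
  if (!asset$alive) stop("dead asset has no actions", call. = FALSE)
  if (asset$location == DEPOT) {
    if (asset$internal < config$internal_max)
      return(list(stay = FALSE, refuel = TRUE, n_transfer = 0L,
                  moves = integer(0), n = 1L))
    return(list(stay = FALSE, refuel = FALSE, n_transfer = 0L,
                moves = net$depot_links, n = length(net$depot_links)))
  }
  s <- asset$location
  n_transfer <- min(asset$towed, config$site_capacity - site_fuel[s])
  n_transfer <- max(0L, as.integer(n_transfer))
  moves <- net$neighbors[[s]]
  if (s %in% net$depot_links) moves <- c(moves, DEPOT)
  list(stay = TRUE, refuel = FALSE, n_transfer = n_transfer, moves = moves,
       n = 1L + n_transfer + length(moves))
}

# sample and apply one uniformly chosen legal action; returns updated
# (asset, site_fuel)
apply_random_action <- function(asset, site_fuel, net, config) {
  acts <- legal_actions(asset, site_fuel, net, config)
  if (acts$refuel) {
    asset$internal <- min(config$internal_max,
                          asset$internal + config$depot_refuel_rate)
    asset$towed <- config$towed_max  # reset after a depot step
    return(list(asset = asset, site_fuel = site_fuel))
  }
  u <- if (acts$n == 1L) 1L else sample.int(acts$n, 1L)
  offset <- 0L
  if (acts$stay) {
    if (u == 1L) return(list(asset = asset, site_fuel = site_fuel))
    offset <- 1L
  }
  if (u <= offset + acts$n_transfer) {
    k <- u - offset
    asset$towed <- asset$towed - k
    site_fuel[asset$location] <- site_fuel[asset$location] + k
    return(list(asset = asset, site_fuel = site_fuel))
  }
  dest <- acts$moves[u - offset - acts$n_transfer]
  asset$location <- dest
  list(asset = asset, site_fuel = site_fuel)
}

#' Advance the ship-fueling system by one step
#'
#' In order: (1) each living asset, in fixed id order, samples one legal
#' action uniformly and applies it immediately; (2) every site burns
#' `site_burn` fuel; (3) every living asset outside the depot burns
#' `asset_burn` internal fuel, and is lost if its internal fuel reaches
#' zero; (4) the caller checks termination (any site fuel <= 0).
#'
#' @param state State list from `new_sf_state` or a previous step.
#' @param net An `sf_network`.
#' @param config An [sf_config()].
#' @return The updated state (with `step` incremented).
#' @export
sf_step <- function(state, net, config) {
  for (i in seq_along(state$assets)) {
    if (!state$assets[[i]]$alive) next
    res <- apply_random_action(state$assets[[i]], state$site_fuel, net, config)
    state$assets[[i]] <- res$asset
    state$site_fuel <- res$site_fuel
  }
  state$site_fuel <- state$site_fuel - config$site_burn
  for (i in seq_along(state$assets)) {
    a <- state$assets[[i]]
    if (!a$alive || a$location == DEPOT) next
    a$internal <- a$internal - config$asset_burn
    if (a$internal <= 0L) {
      a$internal <- 0L
      a$alive <- FALSE
    }
    state$assets[[i]] <- a
  }
  state$step <- state$step + 1L
  state
}

#' Run one ship-fueling simulation
#'
#' Starts with every site at `site_capacity` and every asset at the depot
#' with full internal and towed fuel, then iterates [sf_step()] until some
#' site's fuel reaches zero (or `max_steps`, in which case the run is
#' flagged censored). The recorded observable is the post-burn site-fuel
#' vector at each completed step.
#'
#' @param config An [sf_config()].
#' @param seed Optional integer seed.
#' @param record_assets If `TRUE`, also keep a per-step log of asset
#'   locations and fuels.
#' @return An object of class `sf_run`: `site_fuel` (`mission_life` x
#'   `n_sites` integer matrix), `mission_life`, `censored`, `site_capacity`,
#'   and optionally `asset_log`.
#' @export
run_sf <- function(config, seed = NULL, record_assets = FALSE) {
  if (!is.null(seed)) set.seed(seed)
  net <- build_hex_grid(config$grid_rows, config$grid_cols,
                        config$depot_neighbors)
  state <- new_sf_state(config)
  n_sites <- length(state$site_fuel)
  fuel_log <- matrix(NA_integer_, config$max_steps, n_sites)
  asset_log <- if (record_assets) vector("list", config$max_steps) else NULL
  steps <- 0L
  while (steps < config$max_steps) {
    state <- sf_step(state, net, config)
    steps <- steps + 1L
    fuel_log[steps, ] <- state$site_fuel
    if (record_assets) {
      asset_log[[steps]] <- do.call(rbind, lapply(state$assets, function(a)
        data.frame(location = a$location, internal = a$internal,
                   towed = a$towed, alive = a$alive)))
    }
    if (any(state$site_fuel <= 0L)) break
  }
  structure(list(
    site_fuel = fuel_log[seq_len(steps), , drop = FALSE],
    mission_life = steps,
    censored = !any(state$site_fuel <= 0L),
    site_capacity = config$site_capacity,
    asset_log = if (record_assets) asset_log[seq_len(steps)] else NULL
  ), class = "sf_run")
}

#' Summarize mission life across replicate runs
#'
#' @param results Non-empty list of `sf_run` objects sharing one site
#'   capacity.
#' @return List with `mean`, `sd` and `mean_minus_capacity` (the mean excess
#'   over the minimum possible mission life, which equals the initial site
#'   fuel).
#' @export
mission_life_summary <- function(results) {
  if (length(results) == 0L) stop("empty result list", call. = FALSE)
  caps <- vapply(results, function(r) r$site_capacity, integer(1))
  if (length(unique(caps)) != 1L)
    stop("results mix different site capacities", call. = FALSE)
  lives <- vapply(results, function(r) as.numeric(r$mission_life), numeric(1))
  m <- mean(lives)
  list(mean = m,
       sd = if (length(lives) > 1L) stats::sd(lives) else 0,
       mean_minus_capacity = m - caps[1])
}
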