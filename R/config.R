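#' Construct a medical-treatment-facility network configuration
#'
#' Bundles the parameters of the casualty-flow network: five combat-zone
#' sources dispatch casualties daily to `n_mtfs` medical treatment facilities
#' (MTFs) according to per-source routing probabilities; casualties face a
#' per-kilometre Bernoulli risk of dying in transit; each facility has daily
#' death (DOW) and return-to-duty (RTD) probabilities, a hospital transfer-out
#' rate, and a share of the randomly allocated total bed capacity.
#'
#' @param distances Numeric matrix (`n_mtfs` x `n_sources`), km between each
#'   facility and each source.
#' @param routing_probs Numeric matrix (`n_mtfs` x `n_sources`); column `j`
#'   is the probability distribution over facilities for casualties from
#'   source `j`. Each column must sum to 1 within `5e-4`.
#' @param p_dow,p_rtd Numeric vectors (length `n_mtfs`): daily per-patient
#'   probabilities of death of wounds and return to duty. Must satisfy
#'   `p_dow + p_rtd <= 1` facility-wise.
#' @param r_out Integer vector (length `n_mtfs`): patients transferred out to
#'   hospital per day (up to current occupancy).
#' @param casualty_rate Casualties generated per source per day.
#' @param total_capacity Total bed capacity summed over facilities.
#' @param min_capacity Minimum bed capacity of any single facility.
#' @param p_dow_transit_per_km Per-kilometre probability of death in transit.
#' @param n_days Number of simulated days.
#' @return An object of class `mtf_config`.
#' @seealso [load_mtf_tables()] for the bundled network, [run_mtf()]
#' @export
mtf_config <- function(distances, routing_probs, p_dow, p_rtd, r_out,
                       casualty_rate = 90L, total_capacity = 800L,
                       min_capacity = 5L, p_dow_transit_per_km = 0.015,
                       n_days = 365L) {
  cfg <- structure(list(
    n_sources = ncol(distances),
    n_mtfs = nrow(distances),
    distances = unname(as.matrix(distances)) * 1.0,
    routing_probs = unname(as.matrix(routing_probs)) * 1.0,
    p_dow_transit_per_km = as.numeric(p_dow_transit_per_km),
    p_dow = as.numeric(p_dow),
    p_rtd = as.numeric(p_rtd),
    r_out = as.integer(r_out),
    total_capacity = as.integer(total_capacity),
    min_capacity = as.integer(min_capacity),
    casualty_rate = as.integer(casualty_rate),
    n_days = as.integer(n_days)
  ), class = c("mtf_config", "koop_config"))
  validate_mtf_config(cfg)
  cfg
}

validate_mtf_config <- function(cfg) {
  n <- cfg$n_mtfs
  s <- cfg$n_sources
  if (!all(dim(cfg$distances) == c(n, s)))
    stop("distances: expected a ", n, " x ", s, " matrix", call. = FALSE)
  if (!all(dim(cfg$routing_probs) == c(n, s)))
    stop("routing_probs: expected a ", n, " x ", s, " matrix", call. = FALSE)
  if (any(cfg$distances < 0))
    stop("distances: negative distance", call. = FALSE)
  if (any(cfg$routing_probs < 0) || any(cfg$routing_probs > 1))
    stop("routing_probs: entries must be probabilities in [0, 1]", call. = FALSE)
  colsums <- colSums(cfg$routing_probs)
  bad <- which(abs(colsums - 1) > 5e-4)
  if (length(bad))
    stop("routing_probs: column ", bad[1], " sums to ",
         format(colsums[bad[1]]), ", not 1 (tolerance 5e-4)", call. = FALSE)
  for (f in c("p_dow", "p_rtd")) {
    v <- cfg[[f]]
    if (length(v) != n || any(v < 0) || any(v > 1))
      stop(f, ": expected ", n, " probabilities in [0, 1]", call. = FALSE)
  }
  if (any(cfg$p_dow + cfg$p_rtd > 1))
    stop("p_dow/p_rtd: p_dow + p_rtd exceeds 1 at facility ",
         which(cfg$p_dow + cfg$p_rtd > 1)[1], call. = FALSE)
  if (length(cfg$r_out) != n || any(cfg$r_out < 0))
    stop("r_out: expected ", n, " non-negative integers", call. = FALSE)
  if (cfg$p_dow_transit_per_km < 0 || cfg$p_dow_transit_per_km > 1)
    stop("p_dow_transit_per_km: must be a probability", call. = FALSE)
  if (cfg$min_capacity < 1 || cfg$total_capacity < 1)
    stop("total_capacity/min_capacity: must be positive", call. = FALSE)
  if (cfg$min_capacity * n > cfg$total_capacity)
    stop("total_capacity: min_capacity * n_mtfs (", cfg$min_capacity * n,
         ") exceeds total_capacity (", cfg$total_capacity, ")", call. = FALSE)
  if (cfg$casualty_rate < 0)
    stop("casualty_rate: must be non-negative", call. = FALSE)
  if (cfg$n_days < 1)
    stop("n_days: must be positive", call. = FALSE)
  invisible(cfg)
}

#' Load the bundled MTF network parameter tables
#'
#' Reads the three delimited tables shipped with the package (source-facility
#' distances in km, per-source routing probabilities, and per-facility
#' DOW/RTD probabilities and hospital transfer rates) and assembles a
#' validated [mtf_config()]. The files use 1-based facility/source labels.
#'
#' @param dir Directory holding `mtf_distances.csv`, `mtf_routing.csv` and
#'   `mtf_rates.csv`; defaults to the copies installed with the package.
#' @param ... Passed on to [mtf_config()] (e.g. `casualty_rate`, `n_days`).
#' @return An `mtf_config` with the 15-facility, 5-source network.
#' @examples
#' cfg <- load_mtf_tables()
#' cfg$distances[8, 4]   # 25 km
#' @export
load_mtf_tables <- function(dir = NULL, ...) {
  if (is.null(dir))
    dir <- system.file("extdata", package = "kooplog")
  read_one <- function(name, ncol_expected) {
    path <- file.path(dir, name)
    if (!file.exists(path))
      stop("bundled table not found: ", path, call. = FALSE)
    tab <- utils::read.csv(path, check.names = FALSE)
    if (ncol(tab) != ncol_expected)
      stop("bundled table ", name, ": expected ", ncol_expected,
           " columns, found ", ncol(tab), call. = FALSE)
    if (any(tab$mtf != seq_len(nrow(tab))))
      stop("bundled table ", name, ": facility labels are not 1..",
           nrow(tab), call. = FALSE)
    tab
  }
  dist_tab <- read_one("mtf_distances.csv", 6L)
  rout_tab <- read_one("mtf_routing.csv", 6L)
  rate_tab <- read_one("mtf_rates.csv", 4L)
  mtf_config(
    distances = as.matrix(dist_tab[, -1]),
    routing_probs = as.matrix(rout_tab[, -1]),
    p_dow = rate_tab$p_dow,
    p_rtd = rate_tab$p_rtd,
    r_out = rate_tab$r_out,
    ...
  )
}

#' Construct a ship-fueling network configuration
#'
#' Parameters of the fuel-supply system: `grid_rows` x `grid_cols` mission
#' sites on a hexagonal grid, each burning one fuel unit per step from a full
#' tank of `site_capacity`, resupplied by `n_assets` mobile assets shuttling
#' towed fuel from an infinite-fuel depot linked to two sites. The run ends
#' when any site's fuel reaches zero ("mission life").
#'
#' @param site_capacity Starting and maximum fuel of every site.
#' @param grid_rows,grid_cols Hex-grid dimensions.
#' @param n_assets Number of mobile supply assets.
#' @param site_burn,asset_burn Fuel units consumed per step by a site and by
#'   an asset outside the depot.
#' @param internal_max,towed_max Asset internal / towed fuel capacities.
#' @param depot_refuel_rate Internal fuel gained per step spent at the depot.
#' @param depot_neighbors Site ids linked to the depot.
#' @param max_steps Safety cap on simulated steps (runs reaching it are
#'   flagged censored).
#' @return An object of class `sf_config`.
#' @seealso [run_sf()], [build_hex_grid()]
#' @export
sf_config <- function(site_capacity = 100L, grid_rows = 6L, grid_cols = 6L,
                      n_assets = 6L, site_burn = 1L, asset_burn = 2L,
                      internal_max = 150L, towed_max = 400L,
                      depot_refuel_rate = 2L, depot_neighbors = c(1L, 31L),
                      max_steps = 10000L) {
  cfg <- structure(list(
    grid_rows = as.integer(grid_rows),
    grid_cols = as.integer(grid_cols),
    n_assets = as.integer(n_assets),
    site_capacity = as.integer(site_capacity),
    site_burn = as.integer(site_burn),
    asset_burn = as.integer(asset_burn),
    internal_max = as.integer(internal_max),
    towed_max = as.integer(towed_max),
    depot_refuel_rate = as.integer(depot_refuel_rate),
    depot_neighbors = as.integer(depot_neighbors),
    max_steps = as.integer(max_steps)
  ), class = c("sf_config", "koop_config"))
  validate_sf_config(cfg)
  cfg
}

validate_sf_config <- function(cfg) {
  n_sites <- cfg$grid_rows * cfg$grid_cols
  for (f in c("grid_rows", "grid_cols", "site_capacity", "site_burn",
              "asset_burn", "internal_max", "towed_max",
              "depot_refuel_rate", "max_steps")) {
    if (length(cfg[[f]]) != 1L || is.na(cfg[[f]]) || cfg[[f]] < 1L)
      stop(f, ": must be a positive integer", call. = FALSE)
  }
  if (length(cfg$n_assets) != 1L || is.na(cfg$n_assets) || cfg$n_assets < 0L)
    stop("n_assets: must be a non-negative integer", call. = FALSE)
  if (length(cfg$depot_neighbors) < 1L ||
      any(cfg$depot_neighbors < 1L | cfg$depot_neighbors > n_sites))
    stop("depot_neighbors: site ids must lie in 1..", n_sites, call. = FALSE)
  invisible(cfg)
}

#' Seeded run specification for replicate sweeps
#'
#' @param seed Master integer seed; per-replicate substreams are derived from
#'   it deterministically, with the same replicate substream reused across
#'   sweep values (common random numbers).
#' @param n_replicates Replicates per sweep value (the reference study scale
#'   is 100; the package default is a desk-scale 10).
#' @param sweep_values Parameter values swept (casualty rate for the MTF
#'   system, site fuel capacity for the ship-fueling system).
#' @return An object of class `run_spec`.
#' @export
run_spec <- function(seed, n_replicates = 10L, sweep_values) {
  if (length(seed) != 1L || is.na(seed))
    stop("seed: must be a single integer", call. = FALSE)
  if (n_replicates < 1L)
    stop("n_replicates: must be >= 1", call. = FALSE)
  if (length(sweep_values) < 1L)
    stop("sweep_values: must be non-empty", call. = FALSE)
  structure(list(
    seed = as.integer(seed),
    n_replicates = as.integer(n_replicates),
    sweep_values = as.numeric(sweep_values)
  ), class = c("run_spec", "koop_config"))
}

#' Write a configuration to structured text
#'
#' Serializes an [mtf_config()], [sf_config()] or [run_spec()] as YAML with a
#' `type` tag; [read_config()] restores and re-validates it, so a round trip
#' is the identity on valid configurations.
#'
#' @param config The configuration object.
#' @param path File path to write / read.
#' @return `write_config` returns `path` invisibly; `read_config` returns the
#'   restored, validated configuration.
#' @export
write_config <- function(config, path) {
  type <- config_type(config)
  x <- unclass(config)
  # matrices -> row-major list-of-rows for portable YAML
  for (f in names(x)) if (is.matrix(x[[f]]))
    x[[f]] <- apply(x[[f]], 1, identity, simplify = FALSE)
  yaml::write_yaml(c(list(type = type), x), path)
  invisible(path)
}

config_type <- function(config) {
  if (inherits(config, "mtf_config")) return("mtf")
  if (inherits(config, "sf_config")) return("sf")
  if (inherits(config, "run_spec")) return("run_spec")
  stop("not a kooplog configuration object", call. = FALSE)
}

#' @rdname write_config
#' @export
read_config <- function(path) {
  x <- yaml::read_yaml(path)
  if (is.null(x$type))
    stop("config file ", path, ": missing 'type' field", call. = FALSE)
  need <- function(fields) {
    miss <- setdiff(fields, names(x))
    if (length(miss))
      stop("config file ", path, ": missing field '", miss[1], "'",
           call. = FALSE)
  }
  as_mat <- function(rows) do.call(rbind, lapply(rows, as.numeric))
  switch(x$type,
    mtf = {
      need(c("distances", "routing_probs", "p_dow", "p_rtd", "r_out",
             "casualty_rate", "total_capacity", "min_capacity",
             "p_dow_transit_per_km", "n_days"))
      mtf_config(distances = as_mat(x$distances),
                 routing_probs = as_mat(x$routing_probs),
                 p_dow = x$p_dow, p_rtd = x$p_rtd, r_out = x$r_out,
                 casualty_rate = x$casualty_rate,
                 total_capacity = x$total_capacity,
                 min_capacity = x$min_capacity,
                 p_dow_transit_per_km = x$p_dow_transit_per_km,
                 n_days = x$n_days)
    },
    sf = {
      need(c("grid_rows", "grid_cols", "n_assets", "site_capacity",
             "site_burn", "asset_burn", "internal_max", "towed_max",
             "depot_refuel_rate", "depot_neighbors", "max_steps"))
      sf_config(site_capacity = x$site_capacity, grid_rows = x$grid_rows,
                grid_cols = x$grid_cols, n_assets = x$n_assets,
                site_burn = x$site_burn, asset_burn = x$asset_burn,
                internal_max = x$internal_max, towed_max = x$towed_max,
                depot_refuel_rate = x$depot_refuel_rate,
                depot_neighbors = x$depot_neighbors,
                max_steps = x$max_steps)
    },
    run_spec = {
      need(c("seed", "n_replicates", "sweep_values"))
      run_spec(seed = x$seed, n_replicates = x$n_replicates,
               sweep_values = x$sweep_values)
    },
    stop("config file ", path, ": unknown type '", x$type, "'", call. = FALSE)
  )
}

#' @export
print.koop_config <- function(x, ...) {
  cat("<", class(x)[1], ">\n", sep = "")
  for (f in names(x)) {
    v <- x[[f]]
    if (is.matrix(v)) {
      cat("  ", f, ": ", nrow(v), " x ", ncol(v), " matrix\n", sep = "")
    } else if (length(v) > 8) {
      cat("  ", f, ": [", paste(utils::head(v, 4), collapse = ", "),
          ", ...] (length ", length(v), ")\n", sep = "")
    } else {
      cat("  ", f, ": ", paste(v, collapse = ", "), "\n", sep = "")
    }
  }
  invisible(x)
}
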