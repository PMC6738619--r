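#' Run the MTF casualty-rate sweep
#'
#' For each casualty rate: `n_replicates` independent simulations (fresh
#' random capacity draws), DMD of each run's fullness matrix, dominant /
#' second mode selection, pooled eigenvalue statistics, death-toll
#' summaries and a circle-count health assessment of the pooled spectrum.
#' Replicate `r` uses the same derived substream seed at every rate, giving
#' common random numbers across sweep values.
#'
#' @param rates Casualty rates to sweep (the reference scale is
#'   `seq(30, 330, by = 20)`).
#' @param spec A [run_spec()] (its `sweep_values` are ignored in favor of
#'   `rates`).
#' @param config Base [mtf_config()]; defaults to the bundled network.
#' @param rtol Rank tolerance for [dmd()].
#' @param r,h_green,h_red Health-indicator parameters.
#' @return List of `sweep_result` objects, one per rate, each with
#'   `sweep_value`, `per_replicate` (lists of `run`, `kmd`, `modes`),
#'   `spectrum` ([spectrum_summary()]), `outcome` ([dow_summary()]), `p`
#'   and `status`.
#' @export
run_mtf_sweep <- function(rates, spec, config = load_mtf_tables(),
                          rtol = NULL, r = 0.1, h_green = 0.2, h_red = 0.6) {
  if (length(rates) == 0L) stop("rates must be non-empty", call. = FALSE)
  lapply(rates, function(rate) {
    cfg <- config
    cfg$casualty_rate <- as.integer(rate)
    validate_mtf_config(cfg)
    per <- lapply(seq_len(spec$n_replicates), function(rep_i) {
      run <- run_mtf(cfg, seed = derive_seed(spec$seed, 1L, rep_i))
      kmd <- dmd(build_snapshots(run$fullness, dt = 1), rtol = rtol)
      list(run = run, kmd = kmd, modes = select_modes(kmd))
    })
    finish_sweep_value(rate, per, r, h_green, h_red,
                       outcome = dow_summary(lapply(per, `[[`, "run"), rate))
  })
}

#' Run the ship-fueling capacity sweep
#'
#' As [run_mtf_sweep()], for site fuel capacities (reference scale
#' `seq(25, 200, by = 25)`): each replicate simulates to mission end, runs
#' DMD on the site-fuel time series, and mission-life statistics replace
#' the death-toll summaries.
#'
#' @param capacities Site fuel capacities to sweep.
#' @param spec A [run_spec()].
#' @param config Base [sf_config()].
#' @param rtol,r,h_green,h_red As in [run_mtf_sweep()].
#' @return List of `sweep_result` objects (see [run_mtf_sweep()]), with
#'   `outcome` from [mission_life_summary()].
#' @export
run_sf_sweep <- function(capacities, spec, config = sf_config(),
                         rtol = NULL, r = 0.1, h_green = 0.2, h_red = 0.6) {
  if (length(capacities) == 0L)
    stop("capacities must be non-empty", call. = FALSE)
  lapply(capacities, function(cap) {
    cfg <- config
    cfg$site_capacity <- as.integer(cap)
    validate_sf_config(cfg)
    per <- lapply(seq_len(spec$n_replicates), function(rep_i) {
      run <- run_sf(cfg, seed = derive_seed(spec$seed, 2L, rep_i))
      kmd <- dmd(build_snapshots(run$site_fuel, dt = 1), rtol = rtol)
      list(run = run, kmd = kmd, modes = select_modes(kmd))
    })
    finish_sweep_value(cap, per, r, h_green, h_red,
                       outcome = mission_life_summary(lapply(per, `[[`, "run")))
  })
}

finish_sweep_value <- function(value, per, r, h_green, h_red, outcome) {
  kmds <- lapply(per, `[[`, "kmd")
  pooled <- unlist(lapply(kmds, `[[`, "gammas"))
  p <- health_indicator(pooled, r)
  structure(list(
    sweep_value = value,
    per_replicate = per,
    spectrum = spectrum_summary(kmds),
    outcome = outcome,
    p = p,
    status = classify_health(p, h_green, h_red)
  ), class = "sweep_result")
}

#' Export sweep results as delimited text plus a run manifest
#'
#' Writes, per sweep value: the pooled eigenvalue cloud with mode norms
#' (`cloud_<value>.csv`), the dominant / second mode selections per
#' replicate (`modes_<value>.csv`), and one overall `summary.csv` (one row
#' per sweep value: eigenvalue statistics, outcome statistics, health
#' indicator and status). A `manifest.json` records the seed, replicate
#' count and sweep values so the sweep can be reproduced exactly.
#'
#' @param results List of `sweep_result` objects from [run_mtf_sweep()] or
#'   [run_sf_sweep()].
#' @param out_dir Output directory (created if needed).
#' @param spec The [run_spec()] used, stored in the manifest.
#' @param experiment Label stored in the manifest (`"mtf"` or `"sf"`).
#' @return Invisibly, the vector of written file paths.
#' @export
export_report <- function(results, out_dir, spec = NULL,
                          experiment = "sweep") {
  if (length(results) == 0L) stop("no results to export", call. = FALSE)
  dir.create(out_dir, showWarnings = FALSE, recursive = TRUE)
  written <- character(0)
  summary_rows <- list()
  for (res in results) {
    v <- res$sweep_value
    cloud_path <- file.path(out_dir, sprintf("cloud_%g.csv", v))
    utils::write.csv(res$spectrum$eigenvalue_cloud, cloud_path,
                     row.names = FALSE)
    modes_tab <- do.call(rbind, lapply(seq_along(res$per_replicate),
                                       function(i) {
      ms <- res$per_replicate[[i]]$modes
      data.frame(replicate = i,
                 dominant_re = Re(ms$dominant$gamma),
                 dominant_im = Im(ms$dominant$gamma),
                 dominant_norm = ms$dominant$mode_norm,
                 second_re = Re(ms$second$gamma),
                 second_im = Im(ms$second$gamma),
                 second_norm = ms$second$mode_norm)
    }))
    modes_path <- file.path(out_dir, sprintf("modes_%g.csv", v))
    utils::write.csv(modes_tab, modes_path, row.names = FALSE)
    written <- c(written, cloud_path, modes_path)
    summary_rows[[length(summary_rows) + 1L]] <- data.frame(
      sweep_value = v,
      mean_re = res$spectrum$mean_re, sd_re = res$spectrum$sd_re,
      mean_abs_im = res$spectrum$mean_abs_im, sd_im = res$spectrum$sd_im,
      mean_second_re = mean(vapply(res$per_replicate, function(x)
        Re(x$modes$second$gamma), numeric(1))),
      mean_second_abs_im = mean(vapply(res$per_replicate, function(x)
        abs(Im(x$modes$second$gamma)), numeric(1))),
      outcome_mean = res$outcome[[1]], outcome_sd = res$outcome[[2]],
      p = res$p, status = res$status
    )
  }
  summary_path <- file.path(out_dir, "summary.csv")
  utils::write.csv(do.call(rbind, summary_rows), summary_path,
                   row.names = FALSE)
  manifest_path <- file.path(out_dir, "manifest.json")
  manifest <- list(
    experiment = experiment,
    package_version = as.character(utils::packageVersion("kooplog")),
    sweep_values = vapply(results, `[[`, numeric(1), "sweep_value")
  )
  if (!is.null(spec))
    manifest <- c(manifest, list(seed = spec$seed,
                                 n_replicates = spec$n_replicates))
  jsonlite::write_json(manifest, manifest_path, auto_unbox = TRUE,
                       digits = NA)
  invisible(c(written, summary_path, manifest_path))
}
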