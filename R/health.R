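#' Collapse conjugate eigenvalue pairs
#'
#' For a real-valued signal the DMD spectrum is closed under complex
#' conjugation; to make "largest and second-largest real part" well defined
#' this keeps, of each conjugate pair, the member with non-negative
#' imaginary part, and keeps real eigenvalues as-is.
#'
#' @param gammas Complex eigenvalue vector.
#' @param tol Imaginary parts within `tol` of zero count as real.
#' @return The reduced complex eigenvalue vector.
#' @export
dedup_conjugates <- function(gammas, tol = 1e-8) {
  gammas[dedup_indices(gammas, tol)]
}

dedup_indices <- function(gammas, tol = 1e-8) {
  which(Im(gammas) > -tol)
}

#' Select the dominant and second Koopman modes
#'
#' After collapsing conjugate pairs, ranks eigenvalues by real part
#' (descending; ties broken by larger modulus, then larger mode norm) and
#' returns the top two with their modes. The dominant mode typically
#' captures the mean of the observable; the second mode carries the leading
#' fluctuation / damping behavior and is the more sensitive bifurcation
#' indicator.
#'
#' @param result A [dmd()] result with at least two deduplicated
#'   eigenvalues.
#' @return An object of class `mode_selection`: lists `dominant` and
#'   `second`, each with `gamma`, `lambda`, `mode`, `mode_norm`.
#' @export
select_modes <- function(result) {
  idx <- dedup_indices(result$gammas)
  if (length(idx) < 2L)
    stop("insufficient spectrum: need at least 2 deduplicated eigenvalues",
         call. = FALSE)
  g <- result$gammas[idx]
  ord <- order(-Re(g), -Mod(g), -result$mode_norms[idx])
  pick <- function(j) {
    i <- idx[ord[j]]
    list(gamma = result$gammas[i], lambda = result$lambdas[i],
         mode = result$modes[, i], mode_norm = result$mode_norms[i])
  }
  structure(list(dominant = pick(1L), second = pick(2L)),
            class = "mode_selection")
}

#' Pool eigenvalue statistics over replicate spectra
#'
#' Pools all eigenvalues (without conjugate deduplication, matching
#' all-eigenvalue cloud plots) from a list of [dmd()] results and summarizes
#' the real and imaginary components.
#'
#' @param results Non-empty list of `kmd_result` objects.
#' @return An object of class `spectrum_summary`: `mean_re`, `sd_re`,
#'   `mean_abs_im`, `sd_im`, and `eigenvalue_cloud`, a data frame with
#'   columns `re`, `im`, `mode_norm`, `replicate`.
#' @export
spectrum_summary <- function(results) {
  if (length(results) == 0L) stop("empty result list", call. = FALSE)
  cloud <- do.call(rbind, lapply(seq_along(results), function(i) {
    r <- results[[i]]
    data.frame(re = Re(r$gammas), im = Im(r$gammas),
               mode_norm = r$mode_norms,
               amplitude = if (is.null(r$amplitudes)) NA_real_
                           else Mod(r$amplitudes),
               replicate = i)
  }))
  structure(list(
    mean_re = mean(cloud$re),
    sd_re = if (nrow(cloud) > 1L) stats::sd(cloud$re) else 0,
    mean_abs_im = mean(abs(cloud$im)),
    sd_im = if (nrow(cloud) > 1L) stats::sd(cloud$im) else 0,
    eigenvalue_cloud = cloud
  ), class = "spectrum_summary")
}

#' Circle-count spectral health indicator
#'
#' Fraction of eigenvalues lying inside the circle of radius `r` centered
#' at 1 in the complex plane. Eigenvalues clustering near 1 signal slowly
#' decaying or non-decaying fluctuations (weak damping); eigenvalues near
#' the origin signal a strongly damped fluctuation-dissipation regime.
#'
#' @param gammas Complex eigenvalue vector (discrete, unit-disk picture).
#' @param r Circle radius (> 0).
#' @param denominator `"spectrum"` (default) divides by the number of
#'   computed eigenvalues, guaranteeing `p` in `[0, 1]` after rank
#'   truncation; `"window"` divides by `m`, the literal window length.
#' @param m Window length, required for `denominator = "window"`.
#' @return The indicator `p`.
#' @export
health_indicator <- function(gammas, r,
                             denominator = c("spectrum", "window"), m = NULL) {
  if (length(gammas) == 0L) stop("empty spectrum", call. = FALSE)
  if (r <= 0) stop("r must be positive", call. = FALSE)
  denominator <- match.arg(denominator)
  inside <- sum(Mod(1 - gammas) < r)
  if (denominator == "window") {
    if (is.null(m)) stop("m required for denominator = \"window\"",
                         call. = FALSE)
    inside / m
  } else {
    inside / length(gammas)
  }
}

#' Classify the health indicator into green / yellow / red
#'
#' Green ("healthy") when `p < h_green`, red ("unhealthy") when
#' `p > h_red`, yellow in between. The default thresholds are arbitrary
#' placeholders to be tuned per system.
#'
#' @param p Health indicator from [health_indicator()].
#' @param h_green,h_red Thresholds with `0 < h_green < h_red <= 1`.
#' @return One of `"green"`, `"yellow"`, `"red"`.
#' @export
classify_health <- function(p, h_green = 0.2, h_red = 0.6) {
  if (!(h_green > 0 && h_green < h_red && h_red <= 1))
    stop("thresholds must satisfy 0 < h_green < h_red <= 1", call. = FALSE)
  if (p < h_green) "green" else if (p > h_red) "red" else "yellow"
}

#' Sliding-window spectral monitoring
#'
#' Runs DMD on consecutive windows of a multivariate time series and
#' classifies each window's spectrum with the circle-count indicator,
#' emulating online health monitoring of a running system.
#'
#' @param series Numeric matrix, rows = time.
#' @param window_length Snapshots per window (>= 3).
#' @param step Window start increment (>= 1).
#' @param dt Sampling interval.
#' @param r Circle radius for [health_indicator()].
#' @param h_green,h_red Classification thresholds.
#' @param rtol Rank tolerance passed to [dmd()].
#' @return A list of per-window records, each with `window` (index),
#'   `t_start`, `t_end`, `kmd` (the [dmd()] result), `p` and `status`;
#'   classed `health_monitor`.
#' @export
windowed_monitor <- function(series, window_length, step = 1L, dt = 1,
                             r = 0.1, h_green = 0.2, h_red = 0.6,
                             rtol = NULL) {
  series <- as.matrix(series)
  L <- nrow(series)
  if (window_length < 3L) stop("window_length must be >= 3", call. = FALSE)
  if (step < 1L) stop("step must be >= 1", call. = FALSE)
  if (L < window_length)
    stop("series shorter than one window", call. = FALSE)
  starts <- seq(1L, L - window_length + 1L, by = step)
  out <- lapply(seq_along(starts), function(w) {
    rows <- starts[w]:(starts[w] + window_length - 1L)
    res <- dmd(build_snapshots(series[rows, , drop = FALSE], dt), rtol = rtol)
    p <- health_indicator(res$gammas, r)
    list(window = w, t_start = rows[1], t_end = rows[length(rows)],
         kmd = res, p = p, status = classify_health(p, h_green, h_red))
  })
  structure(out, class = "health_monitor")
}
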