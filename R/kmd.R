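#' Build snapshot matrices from a multivariate time series
#'
#' Converts a time-by-variable series into the column-snapshot convention:
#' `X` holds snapshots `f_0 .. f_{m-1}` and `X_prime` the shifted snapshots
#' `f_1 .. f_m`, with `m = T - 1`.
#'
#' @param series Numeric matrix, `T` rows (time) x `n` columns (observables).
#' @param dt Sampling interval between consecutive rows.
#' @return An object of class `snapshot_pair` with `X`, `X_prime` (both
#'   `n` x `m`) and `dt`.
#' @export
build_snapshots <- function(series, dt = 1) {
  series <- as.matrix(series)
  if (nrow(series) < 3L)
    stop("series too short: need at least 3 time points", call. = FALSE)
  if (dt <= 0) stop("dt must be positive", call. = FALSE)
  f <- t(series)  # n x T, columns are snapshots
  m <- ncol(f) - 1L
  structure(list(X = f[, seq_len(m), drop = FALSE],
                 X_prime = f[, seq_len(m) + 1L, drop = FALSE],
                 dt = dt),
            class = "snapshot_pair")
}

#' Numerical rank from a singular spectrum
#'
#' @param singular_values Non-negative singular values, sorted descending.
#' @param rtol Relative threshold: the rank is the number of singular values
#'   exceeding `rtol * sigma_1`.
#' @return Integer rank `k >= 1`.
#' @export
numerical_rank <- function(singular_values, rtol) {
  if (any(singular_values < 0) || is.unsorted(rev(singular_values)))
    stop("singular values must be non-negative and non-increasing",
         call. = FALSE)
  if (singular_values[1] == 0)
    stop("degenerate input: all singular values are zero", call. = FALSE)
  sum(singular_values > rtol * singular_values[1])
}

#' Dynamic mode decomposition of a snapshot pair
#'
#' Computes the thin SVD `X = K Sigma W*`, truncates to the numerical rank
#' `k`, forms the projected one-step operator
#' `A = K_k* X' W_k Sigma_k^{-1}` (Schmid's formula), and eigendecomposes it
#' with unit-norm eigenvectors `S`. The Koopman mode approximations are
#' `V = K_k S`; the discrete eigenvalues `gamma_j` map to continuous
#' frequencies `lambda_j = log(gamma_j) / dt` via the principal branch of
#' the complex logarithm (branch cut on the negative real axis; `gamma = 0`
#' yields an undefined `lambda`, reported as `NA` and flagged).
#'
#' @param snapshots A [build_snapshots()] pair.
#' @param rtol Relative rank-truncation tolerance; default
#'   `max(n, m) * .Machine$double.eps` (standard conditioning practice).
#' @return An object of class `kmd_result`: complex `gammas` and `lambdas`
#'   (length `k`), complex `modes` (`n` x `k`), `mode_norms`, `rank`,
#'   logical `numerically_zero` (|gamma| below `1e-12`), `dt`, complex
#'   `amplitudes` (least-squares fit of the modes to the first snapshot;
#'   modes themselves are unit-norm, so `|amplitudes|` carries the mode
#'   weighting), and `residual`, the relative Frobenius misfit of the
#'   fitted one-step map (`||X' - K_k A K_k* X|| / ||X'||`), a quality
#'   diagnostic for the computed eigenpairs.
#' @export
dmd <- function(snapshots, rtol = NULL) {
  X <- snapshots$X
  Xp <- snapshots$X_prime
  dt <- snapshots$dt
  if (is.null(rtol)) rtol <- max(dim(X)) * .Machine$double.eps
  sv <- svd(X)
  k <- numerical_rank(sv$d, rtol)
  Kk <- sv$u[, seq_len(k), drop = FALSE]
  Wk <- sv$v[, seq_len(k), drop = FALSE]
  sk <- sv$d[seq_len(k)]
  A <- crossprod(Kk, Xp) %*% sweep(Wk, 2L, sk, "/")
  eg <- eigen(A)
  S <- eg$vectors  # eigen() returns unit-norm columns
  gammas <- as.complex(eg$values)
  modes <- Kk %*% S
  mode_norms <- sqrt(colSums(Mod(modes)^2))
  numerically_zero <- Mod(gammas) < 1e-12
  lambdas <- rep(NA_complex_, k)
  nz <- !numerically_zero
  lambdas[nz] <- log(gammas[nz]) / dt
  residual <- {
    fit <- Kk %*% (A %*% crossprod(Kk, X))
    norm(Xp - fit, "F") / norm(Xp, "F")
  }
  amplitudes <- tryCatch(qr.solve(modes, as.complex(X[, 1L])),
                         error = function(e) rep(NA_complex_, k))
  structure(list(gammas = gammas, lambdas = lambdas, modes = modes,
                 mode_norms = mode_norms, rank = k,
                 numerically_zero = numerically_zero,
                 dt = dt, amplitudes = amplitudes, residual = residual),
            class = "kmd_result")
}

#' Least-squares mode amplitudes for an initial snapshot
#'
#' @param result A [dmd()] result.
#' @param f0 The initial snapshot (length `n`).
#' @return Complex amplitude vector `a` minimizing `||modes %*% a - f0||`.
#' @export
fit_amplitudes <- function(result, f0) {
  qr.solve(result$modes, as.complex(f0))
}

#' Reconstruct a signal from modes, amplitudes and eigenvalues
#'
#' Evaluates `sum_j a_j gamma_j^t v_j` on a grid of times, returning the
#' real part (the imaginary residue is below numerical tolerance for real
#' input data with conjugate-symmetric spectra).
#'
#' @param result A [dmd()] result.
#' @param amplitudes Complex amplitudes, e.g. from [fit_amplitudes()].
#' @param t_grid Numeric vector of (integer-step) times.
#' @return Real matrix `length(t_grid)` x `n`; row `i` is the reconstruction
#'   at `t_grid[i]`.
#' @export
reconstruct <- function(result, amplitudes, t_grid) {
  if (length(amplitudes) != result$rank)
    stop("amplitudes length (", length(amplitudes),
         ") does not match rank (", result$rank, ")", call. = FALSE)
  out <- vapply(t_grid, function(t) {
    Re(result$modes %*% (amplitudes * result$gammas ^ t))
  }, numeric(nrow(result$modes)))
  t(matrix(out, nrow = nrow(result$modes)))
}

#' @export
print.kmd_result <- function(x, ...) {
  cat("<kmd_result> rank", x$rank, "| residual",
      format(x$residual, digits = 3), "\n")
  ord <- order(Re(x$gammas), decreasing = TRUE)
  show <- utils::head(ord, 5L)
  for (j in show) {
    cat(sprintf("  gamma = %s  |gamma| = %.4f  mode norm = %.3f\n",
                format(x$gammas[j], digits = 4), Mod(x$gammas[j]),
                x$mode_norms[j]))
  }
  if (x$rank > 5L) cat("  ...", x$rank - 5L, "more eigenvalues\n")
  invisible(x)
}
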