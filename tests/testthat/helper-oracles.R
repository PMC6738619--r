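# Independent oracles used across the suite. Each is a deliberately naive
# implementation, kept separate from the package's code paths.

# Hex adjacency via cube coordinates: two offset cells are neighbors iff
# their cube distance is 1 (odd-row-shifted offset convention).
oracle_hex_adjacent <- function(site_a, site_b, rows, cols) {
  cube <- function(s) {
    rr <- (s - 1) %/% cols
    cc <- (s - 1) %% cols
    x <- cc - (rr - (rr %% 2)) / 2
    z <- rr
    c(x = x, y = -x - z, z = z)
  }
  max(abs(cube(site_a) - cube(site_b))) == 1
}

# Per-agent single-facility day: each patient is an individual Bernoulli/
# categorical draw; arrivals land after exits, overflow last. Returns the
# post-day occupancy and death count. Distributionally matches the
# count-based simulator for one facility.
oracle_agent_day <- function(occupancy, arrivals, p_dow, p_rtd, r_out, cap) {
  fates <- if (occupancy > 0)
    sample(c("dow", "rtd", "stay"), occupancy, replace = TRUE,
           prob = c(p_dow, p_rtd, 1 - p_dow - p_rtd))
  else character(0)
  occ <- sum(fates == "stay")
  dow <- sum(fates == "dow")
  transferred <- min(r_out, occ)
  occ <- occ - transferred + arrivals
  overflow <- max(0, occ - cap)
  list(occupancy = occ - overflow, dow = dow + overflow)
}

# Data generated by a known linear map, for DMD exact-recovery checks:
# x_{k+1} = A x_k embedded in n ambient dimensions.
make_linear_system_data <- function(A, n_ambient, m) {
  d <- nrow(A)
  Q <- qr.Q(qr(matrix(rnorm(n_ambient * d), n_ambient, d)))
  x <- matrix(rnorm(d), d, 1)
  traj <- matrix(NA_real_, m + 1, d)
  traj[1, ] <- x
  for (k in seq_len(m)) traj[k + 1, ] <- A %*% traj[k, ]
  traj %*% t(Q)  # (m+1) x n_ambient, rows are time
}

# Real matrix with prescribed eigenvalues (complex ones given as a+bi with
# b > 0 expand to 2x2 rotation-scaling blocks).
matrix_with_eigenvalues <- function(eigs_real, eigs_complex = complex(0)) {
  blocks <- c(lapply(eigs_real, function(e) matrix(e, 1, 1)),
              lapply(eigs_complex, function(e) {
                a <- Re(e); b <- Im(e)
                matrix(c(a, -b, b, a), 2, 2)
              }))
  d <- sum(vapply(blocks, nrow, integer(1)))
  M <- matrix(0, d, d)
  at <- 1
  for (B in blocks) {
    idx <- at:(at + nrow(B) - 1)
    M[idx, idx] <- B
    at <- at + nrow(B)
  }
  P <- matrix(rnorm(d * d), d, d)
  while (abs(det(P)) < 1e-3) P <- matrix(rnorm(d * d), d, d)
  P %*% M %*% solve(P)
}

# Random decay-with-jumps spec in the dt << c regime where the triangular
# operator representation holds at machine precision.
random_decay_spec <- function(J = sample(0:3, 1)) {
  n <- sample(5:40, 1)
  m <- sample(40:120, 1)
  c0 <- runif(1, 50, 200)
  dt <- c0 * 10^runif(1, -8, -7)
  times <- if (J > 0) sort(sample(seq_len(m - 2), J)) else integer(0)
  vecs <- if (J > 0) lapply(seq_len(J), function(i) runif(n, 0.1, 20))
          else list()
  decay_signal_spec(n, m, c0, dt, times, vecs)
}
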