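# kooplog

Koopman mode analysis of logistics agent-based simulations.

`kooplog` is for modellers who want to read the *dynamical regime* of a
stochastic logistics system off its data rather than off its rules. It
bundles two exemplar agent-based simulators — a casualty-flow network of
medical treatment facilities (MTFs) and a ship-fueling supply network on a
hexagonal grid — together with a dynamic mode decomposition (DMD) core that
approximates the spectrum of the system's Koopman operator from simulated
(or any user-supplied) multivariate time series, and a spectral "health
indicator" that tracks the bifurcation between damped and saturated
operating regimes across parameter sweeps.

## The methods

**Koopman mode decomposition.** A multivariate signal `g_t ∈ R^n` is
decomposed as `g_t ≈ Σ_j e^{λ_j t} v_j + conj.`, where each complex
frequency `λ_j = a_j + iω_j` carries growth/decay and oscillation and each
mode `v_j ∈ C^n` is the spatial structure moving at that frequency. From
snapshots `f_0, …, f_m` the DMD algorithm forms `X = (f_0 … f_{m−1})`,
`X′ = (f_1 … f_m)`, computes the SVD `X = KΣW*`, truncates at the numerical
rank `k`, builds the projected one-step operator
`A = K_k* X′ W_k Σ_k^{−1}` (Schmid's formula), and eigendecomposes
`A S = S Γ`. The discrete eigenvalues `γ_j` live in the unit-disk picture
and map to frequencies by the principal logarithm `λ_j = log(γ_j)/Δt`;
the modes are `V = K_k S`.

**Spectral health.** For a spectrum `{γ_j}`, the indicator
`p = #{γ_j : |1 − γ_j| < r} / k` measures clustering near 1 — the
signature of slowly decaying or non-decaying fluctuations. With thresholds
`0 < h_g < h_r ≤ 1`, a system is "green" (healthy, strongly damped) when
`p < h_g` and "red" (saturated, undamped) when `p > h_r`. Both simulators
exhibit a bifurcation that this indicator tracks: the MTF network from
efficient operation to a high-mortality saturated state as the casualty
rate grows, and the fueling network from short, decay-dominated missions
to sustained resupply as site fuel capacity grows.

**Linear decay theory.** Site-fuel signals decay *linearly* with random
resupply jumps — `f_k = c·1_n − kΔt·1_n + Σ_j H(k − t_j) z_j` — not
exponentially, so it is not obvious what DMD should return. Representing
the one-step shift on the span `{1_n, z_1, …, z_J}` gives an
upper-triangular matrix with spectrum `{1 (×J), 1 − Δt/c}` plus exact
zeros: approximating a linear signal by complex exponentials forces a
repeated eigenvalue at 1, and floating-point arithmetic splits that
repeated root into the cluster near 1 seen in computation. The package
constructs the signal, the exact operator, and the comparison between the
analytic and numerically split spectra.

## Worked example

```r
library(kooplog)

# the bundled 15-facility network at 90 casualties/source/day
cfg <- load_mtf_tables(casualty_rate = 90)
run <- run_mtf(cfg, seed = 1)
run$total_dow
#> [1] 97439

res <- dmd(build_snapshots(run$fullness, dt = 1))
res
#> <kmd_result> rank 15 | residual 0.108
#>   gamma = 1+0i       |gamma| = 1.0000  mode norm = 1.000
#>   gamma = 0.6887+0i  |gamma| = 0.6887  mode norm = 1.000
#>   gamma = 0.6227+0i  |gamma| = 0.6227  mode norm = 1.000
#>   ...

p <- health_indicator(res$gammas, r = 0.1)
c(p = p, status = classify_health(p))
#> p = 0.0667 -> "green"
```

The dominant eigenvalue sits at 1 (the mean occupancy pattern); the second
eigenvalue (0.689) is the slowest genuine fluctuation — its distance from
the unit circle measures how strongly the network damps casualty shocks.
At rate 90 only 1 of 15 eigenvalues is near 1, so the system is "green".

The decay theory in one call:

```r
spec <- decay_signal_spec(n = 50, m = 101, c = 100, dt = 1,
                          jump_times = c(30, 60),
                          jump_vectors = list(runif(50, 0, 20),
                                              runif(50, 0, 20)))
analytic_operator(spec)$eigenvalues
#> [1] 0.99 1.00 1.00
cmp <- compare_dmd_to_analytic(spec)
cmp$computed
#> [1] 0.993139+0.012594i 0.993139-0.012594i 0.949781+0.000000i
cmp$splitting_radius
#> [1] 0.0402
```

The exact spectrum `{1, 1, 0.99}` splits under floating point into a
conjugate pair hugging 1 and a real eigenvalue pushed toward 0.95 — the
clustering-near-1 phenomenon, reproduced and explained.

A command-line front end with `simulate-mtf`, `simulate-sf`, `kmd`,
`analyze`, `theory-check`, `sweep-mtf` and `sweep-sf` subcommands is
installed at `inst/cli/kooplog.R`:

```sh
Rscript inst/cli/kooplog.R sweep-mtf --rates 30,170,330 --replicates 10 \
        --seed 1 --out sweep_out
```

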