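---
title: "Koopman mode analysis of logistics simulations: models, methods and numerical choices"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Koopman mode analysis of logistics simulations}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(kooplog)
```

This vignette is the package's own account of its science: the two
agent-based models, the spectral method, the analytic theory for linearly
decaying signals, and — because several design points are genuinely open —
the numerical and modelling choices we made, with their rationale and
known limitations.

## The medical-treatment-facility model

Five sources (combat zones) each generate a fixed number `casualty_rate`
of casualties per day (swept over 30–330 in the reference experiment).
Each casualty is routed independently to one of 15 medical treatment
facilities (MTFs) according to a per-source routing-probability column
(`routing_probs`, bundled; each column sums to 1 within 5e-4, the rounding
of the printed 4-decimal values). Transit is hazardous: over a distance of
`D` km (bundled `distances`, 25–49 km) each kilometre is an independent
Bernoulli trial with death probability `p_dow_transit_per_km = 0.015`, so
a casualty survives transit with probability `0.985^D` (≈ 0.685 at 25 km)
and survivor counts are binomial.

Each facility has a daily per-patient probability of dying of wounds
(`p_dow`, 0.10–0.25), of returning to duty (`p_rtd`, 0.05–0.15), and a
hospital transfer-out rate (`r_out`, 10–20 patients/day). Bed capacity is
random: a total of 800 beds is split over the 15 facilities with a minimum
of 5 each, re-drawn for every simulation. A run lasts `n_days = 365` days,
and the observable fed to the spectral analysis is the *fullness* matrix:
occupancy divided by capacity, per facility per day.

**Capacity sampler.** "Randomly determined" subject to sum and minimum
constraints leaves the distribution open. We use the uniform random
integer composition (stars and bars) of the surplus `800 − 15·5` over the
15 facilities: it is the maximum-entropy choice on the feasible set and is
exchangeable, so every facility has marginal mean 800/15 ≈ 53.3. The
marginal distribution is wide (sd ≈ 45), which matters for the saturation
behaviour discussed under limitations.

**Within-day ordering.** The daily step executes: (1) a per-facility
multinomial split of the standing occupancy into died / returned / stayed
with probabilities `(p_dow, p_rtd, 1 − p_dow − p_rtd)` — a single
multinomial per facility, since the probabilities are specified jointly
and sum below 1; (2) transfer-out of `min(r_out, occupancy)`; (3) arrival
of the day's transit survivors; (4) conversion of any occupancy above
capacity to deaths (overflow is literally the end-of-day event); (5)
recording of fullness, which is therefore always in [0, 1]. We initially
exposed arrivals to the same-day exit lottery, but that ordering is
untenable at low casualty rates: the transfer-out rates (10–20/day) exceed
post-lottery arrivals (~6/facility/day at rate 30), occupancy is flushed
to exactly zero almost every day, and the fullness matrix degenerates to
numerical rank 1 — no second mode exists and the low-rate end of the sweep
cannot be analysed at all. With arrivals joining after the day's exits,
each day's recorded occupancy reflects incoming load immediately, new
patients face their first exit lottery the next morning, and the low-rate
spectrum is full-rank with eigenvalues clustered near the origin, the
damped fluctuation-dissipation regime the method is meant to detect.

Patients within a facility are exchangeable, so the simulator evolves
*counts* with binomial/multinomial draws rather than individual agent
objects; this is distributionally identical to a per-agent loop (the test
suite checks the equivalence against a per-agent oracle at small scale)
and orders of magnitude faster. Patient conservation — generated equals
died-in-transit + died-in-facility + returned + transferred + standing —
is asserted after every simulated day.

## The ship-fueling model

36 mission sites on a 6×6 hexagonal grid each burn 1 fuel unit per step
from a full starting tank of `site_capacity` (swept over 25–200). Six
mobile assets shuttle fuel from an infinite depot: each asset has internal
fuel (max 150; consumed at 2/step outside the depot; reaching 0 strands
the asset) and towed fuel (max 400; refilled to maximum after a depot
visit). At the depot an asset below full internal fuel can only refuel
(+2/step); once full it must move to one of the depot-linked sites. At a
site, the action set is {stay} ∪ {transfer k : 1 ≤ k ≤ min(towed, free
site capacity)} ∪ {move to each neighbour}, every action equiprobable —
so a large site deficit makes transfers dominate the action set and the
expected behaviour is to keep transferring until the site is nearly full.
The run ends when any site's fuel reaches zero; the completed step count
is the *mission life*, bounded below by `site_capacity`.

Layout and tie-break choices, each documented because the source material
fixes only the qualitative picture: the lattice is an odd-row-shifted
offset hex grid, numbered row-major, so sites 1 and 31 (the left ends of
the first and last rows) carry the depot links and the right-edge sites
are farthest from resupply; assets act in fixed id order within a step and
may co-occupy a site; moving back into the depot from a linked site is
legal (the towed-refill rule presupposes return visits); assets do not
burn internal fuel while in the depot; sites keep burning after an asset
is lost, and asset loss does not end the run; termination is checked after
the site-burn phase. Adjacency is validated in the tests against an
independent cube-coordinate oracle.

## The spectral core

Snapshots are columns: a T×n time series becomes `X = (f_0 … f_{m−1})`,
`X′ = (f_1 … f_m)` with `m = T − 1`. DMD computes the thin SVD
`X = KΣW*`, truncates at the numerical rank, forms
`A = K_k* X′ W_k Σ_k^{−1}`, and eigendecomposes `A`. Choices:

* **Rank tolerance.** `k` counts singular values above
  `rtol · σ_1` with default `rtol = max(n, m) · eps` — standard
  conditioning practice; overridable. Rank 0 (an identically zero
  window) is an error, not a silent result.
* **Eigenvector scaling.** The eigenvectors of `A` are unit-norm, so the
  modes `V = K_k S` are unit-norm too (orthonormal `K_k` preserves
  norms). Mode *weights* are therefore carried separately as the
  least-squares amplitudes fitted to the first snapshot; exported
  eigenvalue clouds include `|amplitude|`.
* **Frequencies.** `λ_j = log(γ_j)/Δt` with the principal branch (cut on
  the negative real axis). `|γ| < 1e-12` is flagged "numerically zero"
  and its `λ` is undefined (`NA`): exact zeros arise structurally in the
  decay theory below.
* **Residual.** The relative Frobenius misfit
  `‖X′ − K_k A K_k* X‖ / ‖X′‖` is reported as an eigenpair-quality
  diagnostic. It is 0 exactly when `X′`'s columns lie in the image of
  the fitted map on span(X); no iterative refinement of eigenpairs is
  attempted.

For real data the spectrum is conjugate-symmetric, so "the second-largest
real part" is made well defined by keeping one member of each conjugate
pair (the one with Im ≥ 0) before ranking; ties break by larger modulus,
then larger mode norm. The dominant mode is typically the mean pattern
(eigenvalue at or near 1); the second mode carries the leading
fluctuation and is the sensitive regime indicator.

**Health indicator.** `p = #{γ_j : |1 − γ_j| < r}/k` with defaults
`r = 0.1`, `h_green = 0.2`, `h_red = 0.6` — explicitly arbitrary
placeholders, to be tuned per system. Two normalisation choices are
deliberate: the denominator defaults to the number of *computed*
eigenvalues (the window length `m` can exceed the rank after truncation,
and dividing by `m` could then never reach 1), with
`denominator = "window"` available for the literal definition; and the
indicator is applied to the discrete eigenvalues γ (the unit-disk
picture in which the clustering phenomenon is stated), not to the
continuous frequencies.

## Linearly decaying signals with jumps

The site-fuel signal class is `f_k = c·1_n − kΔt·1_n + Σ_j H(k − t_j) z_j`
with `Δt ≪ c`. The snapshot matrix is spanned by `{1_n, z_1, …, z_J}`, and
representing the one-step shift in that basis gives an upper-triangular
`(J+1)×(J+1)` matrix: diagonal `(1 − Δt/c, 1, …, 1)`, first row continuing
with the telescoping entries `−t_1Δt²/c, −(t_2 − t_1)Δt²/c, …` (the
two-jump derivation extends to general J by induction on the same
telescoping pattern; `verify_operator` checks the generalised matrix
numerically rather than assuming it). The spectrum is
`{1 (×J), 1 − Δt/c}` plus exact zeros — with `Δt = 1`, `c = 100`:
`{1, 1, 0.99, 0, …}`.

Two exactness caveats, both verified and enforced in code:

* The representation is constructed from the anchor relations at
  `k = 0, t_1, …, t_J`. The jump-*onset* transitions
  `f_{t_j−1} → f_{t_j}` add the exogenous impulse `z_j`, which no
  autonomous linear one-step map on the span can emit; `verify_operator`
  therefore excludes the J onset steps from its column-by-column check.
* Away from the anchors the first coordinate drifts by
  `(k − nearest anchor)·Δt²/c`, because the coefficient `c − kΔt` is
  affine, not linear, under the shift. The representation is exact to
  machine precision only in the limit `Δt/c → 0`; the property suite
  draws `Δt/c ∈ [1e-8, 1e-7]`, where the bound `m·Δt²/c` sits below
  `1e-10·c` for every generated spec. At `Δt = 1`, `c = 100` the drift
  is visible (≤ `m·Δt²/c ≈ 1`), which is precisely the regime where the
  *numerical* DMD spectrum splits.

The splitting itself is a conditioning story: the repeated unit eigenvalue
is defective on the data, and its floating-point splitting radius grows
when the jumps crowd the edges of the observation window (few pre- or
post-jump columns leave the corresponding basis direction weakly excited).
In the reference configuration — `n = 50`, `m = 101`, jumps in separated
mid-window positions (the bundled example uses steps 30 and 60), jump
components uniform on (0, 20) — the measured splitting radius stays below
0.08: a conjugate pair hugs 1 and a real eigenvalue is pushed toward 0.95.
Edge-crowded realisations (e.g. both jumps within the last 15 steps) can
split by 0.2–1.0, and the test suite asserts that crowding effect as a
property rather than hiding it.

## Sweeps, seeds and problem sizes

A sweep runs `n_replicates` simulations per parameter value, each with a
fresh capacity draw (MTF) or trajectory (SF), applies DMD per replicate,
selects dominant/second modes, and pools eigenvalue clouds. Replicate
substreams are derived arithmetically from (master seed, stream,
replicate index), and replicate `r` gets the *same* substream at every
sweep value — common random numbers, so cross-value comparisons are
paired. Identical run specifications reproduce byte-identical exports;
the manifest written with every export suffices to reproduce the sweep.

The reference experiments use 100 replicates per value and the full rate
grid 30–330 / capacity grid 25–200. The package defaults and the test
suite use a desk scale chosen to keep the whole suite under a minute —
10 replicates, three sweep points ({30, 170, 330} and {25, 200}), 365-day
runs for spectral tests and 25–120-day runs for accounting tests. These
sizes are the package's choice of a fast, still-discriminating default;
every reported trend was also observed at 50 replicates.

## What the tests do and do not show

The simulators double as the synthetic-data generators for the test
suite, so green tests certify: exact accounting (patient conservation,
fuel bookkeeping, capacity constraints), exact recovery of DMD on finite
linear systems (the algorithmic core), the analytic decay spectrum and
its numerically split counterpart, and the *direction* of both regime
transitions at desk scale (normalized death toll rising, mission life
lengthening, second-mode |Im| collapsing onto the real axis, low-rate
windows green vs saturated windows elevated).

They do not show fidelity to any real medical or naval logistics system —
arrival processes are constant-rate, facilities do not interact, there is
no triage or routing intelligence — and two known model-intrinsic effects
temper the idealised spectral picture:

* **Saturation freezes the observable.** At casualty rate 330 nearly
  every facility is pinned at fullness exactly 1 by the end-of-day
  overflow rule. Frozen rows are exact duplicates, rank truncation
  removes their directions, and the surviving fluctuations are one-day
  dip/refill events with small autocorrelation: the mean second-mode
  real part *retreats* after the transition (≈ 0.17 at rate 30, peaking
  ≈ 0.75 near rate 170, ≈ 0.64 at 330 with 50 replicates) instead of
  continuing toward 1, and the circle-count indicator plateaus in the
  yellow band (p ≈ 0.25) rather than reaching red at the default
  thresholds. The transition itself remains unambiguous — it is carried
  by the 30→170 rise, the monotone collapse of |Im(γ₂)|, and the
  normalized death toll — but a monotone rise of Re(γ₂) through full
  saturation is not a property of this model, and the one acceptance
  expectation asserting it is left failing rather than weakened.
* **Short windows over-split.** At site capacity 25 a mission yields ~24
  snapshots of near-pure linear decay; the repeated unit root then
  splits outward (mean Re(γ₂) ≈ 1.03). The paired trend that is true and
  tested is that the second eigenvalue *clusters toward 1* with growing
  capacity (mean |γ₂ − 1| falls from ≈ 0.16 at capacity 25 to ≈ 0.05 at
  200), not that its real part rises monotonically.
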