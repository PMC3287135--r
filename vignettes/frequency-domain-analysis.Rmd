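---
title: "Frequency-domain analysis of stochastic oscillatory reaction networks"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Frequency-domain analysis of stochastic oscillatory reaction networks}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r, include = FALSE}
knitr::opts_chunk$set(eval = FALSE)
```

## The problem

Biochemical signalling pathways — NF-κB, p53, the cell cycle and many
others — oscillate, and when separately-validated pathway models are
coupled into a larger system, the interesting questions are about how the
subsystems perturb each other's dynamics. Stochastic simulation is the
natural framework (molecule numbers are discrete, and intrinsic noise is
part of the mechanism, not an additive nuisance), but it creates a
measurement problem: individual trajectories of a continuous-time Markov
jump process decorrelate, so the time-domain average of an ensemble of
runs washes out exactly the oscillatory structure one wants to compare.
Solving the chemical master equation (CME) does not help either: its
solution is a distribution over states at each time, with the causal
ordering of events integrated away.

`oscspec` implements a frequency-domain alternative. Each stochastic run
is resampled to a regular grid, transformed with the discrete Fourier
transform (DFT), and reduced to its amplitude spectrum; the ensemble is
then summarised by the *term-wise mean of the amplitude spectra*. Because
amplitudes discard the phases that decohere between runs, the average
amplitude spectrum retains the oscillatory signature that the time-domain
average destroys. Distances between two such spectra are measured with a
discrete Kolmogorov–Smirnov (K-S) statistic, giving a behavioural
distance `D` in [0, 1] that can compare models, conditions, parts of one
system, or simulation algorithms.

## The measurement pipeline

Given a trajectory (an irregular sequence of reaction events), the
pipeline is:

1. **Resampling.** `resample()` takes the last recorded value at or
   before each grid time `n * dt` (last observation carried forward).
   A run that reaches an absorbing state before the end of the window has
   its final value carried forward — the same rule, applied uniformly.
2. **Transform.** `amplitude_spectrum()` applies the standard DFT kernel
   `exp(-2*pi*1i*w*n/N)` via the FFT and takes moduli. No windowing,
   detrending or normalization is applied: low-frequency transients are
   part of the behavioural signature and are deliberately kept, so the DC
   bin participates in all downstream comparisons. Only the one-sided
   spectrum (bins `0 .. floor(N/2)`) is retained, since real signals are
   conjugate-symmetric and the mirrored bins carry no extra information.
3. **Averaging.** `average_spectrum()` forms the term-wise mean over the
   ensemble (Welford accumulation, so ensembles can be extended
   incrementally and reproduce the batch mean to floating-point
   accuracy). Averaging the *complex* spectra would be pointless: the DFT
   is linear, so that equals transforming the time-domain mean.
4. **Distance.** `ks_distance()` normalizes each average spectrum to unit
   sum — the K-S statistic is defined on distributions, so each spectrum
   is treated as a probability mass function over frequency bins —
   cumulates over ascending frequency, and reports the maximum absolute
   difference `D`.

The sampling grid is set by `sampling_config(N, dt)`: the window is
`N * dt` minutes, the frequency resolution `1/(N * dt)` cycles/min and
the maximum observable frequency `1/(2 * dt)`. The package defaults,
`N = 4000` samples at `dt = 1` min, resolve 0.00025 cycles/min up to
0.5 cycles/min — appropriate for signalling oscillations with periods of
tens of minutes to a day.

Two driver routines mirror how the measurements are used.
`procedure_A()` produces ensemble-average spectra per species for
visual inspection or convergence monitoring; `procedure_B()` runs paired
ensembles of two models and reports `D` per species. Both accept a
`previous` result so runs can be added until the spectra are smooth
enough; `convergence_cov()` supplies the stopping criterion (the
coefficient of variation of each spectral-component mean,
`(sd/sqrt(K))/mean`, checked against a threshold on all bins whose mean
exceeds a floor of `1e-3 * max(mean)` — bins with negligible mass carry
no information and only add noise to the criterion). A sequential
hypothesis test could equally be used to order `D` values; the CoV
criterion is the one implemented. At the default conditions, `K = 100`
paired runs resolve differences in `D` of about 0.05; the acceptance
script measures the corresponding null floor directly.

## Stochastic simulation

`simulate_network()` implements the Gillespie direct method exactly:
waiting times are exponential in the total propensity and the firing
channel is chosen by cumulative-sum search with strict inequality.
Mass-action propensities use the combinatorial (falling-factorial) form —
a homodimerization `2A -> B` fires at `k * n * (n-1) / 2`, not `k * n^2`
— which is the physically correct counting for elemental reactions.
Modifiers (enzymes) multiply the propensity as plain counts and
contribute zero stoichiometry, which avoids the spurious consume/produce
event pairs that a reactant-and-product encoding would generate.

Reproducibility is built in at the level of the random number generator:
the simulator uses its own xoshiro256++ stream seeded through splitmix64,
so trajectories are bit-identical across platforms, and ensemble run `i`
uses the seed `derive_seed(base_seed, i, stream)` — a hash, not an
offset — so results are independent of execution order and paired
ensembles (`stream` 1 and 2 in `procedure_B()`) are independent by
construction. After each firing only the propensities of reactions that
read a changed species are recomputed (a dependency-graph update), and
the running total is refreshed periodically to cancel floating-point
drift. Networks that use custom (non-mass-action) kinetic expressions run
through an R implementation of the same method; they are intended for
small models and tests.

## Model transformations

**α-discretization.** `discretize()` converts a concentration-mode model
(mol/l) to molecule counts: initial amounts are multiplied by `alpha`
(l/mol) and rounded half-to-even (unbiased), and rate constants of total
kinetic order `m` become `k / alpha^(m-1)`. Modifiers count towards `m`,
because the defining property is that the propensity at counts
`n = alpha * c` equals `alpha` times the concentration-space rate at `c`
— exact for order ≤ 1, and up to the combinatorial `n(n-1)` versus `n^2`
correction, which vanishes as `alpha` grows, for higher orders. Custom
rate expressions are rescaled symbolically to
`alpha * r(n / alpha)`, which preserves the same property exactly.

**Quasi-deterministic conversion.** `to_quasi_deterministic()` combines
the production and consumption kinetics of each species into one
resultant net-rate function and simulates that function stochastically.
The resultant rate can be negative, and SSA propensities cannot be; the
conversion therefore splits each species' resultant into a `+1` channel
with propensity `max(r, 0)` and a `-1` channel with propensity
`max(-r, 0)`. This preserves the drift — at every state the expected
instantaneous rate of change of every species is identical to the source
network's, which is the property that justifies re-using the source
model's parameters — while removing almost all intrinsic noise (steps
are single molecules driven by net rates, with no shot noise from opposed
production/consumption fluxes). At large discretization constants the
quasi-deterministic trajectory tracks the deterministic (ODE) solution
closely; the test suite verifies agreement within 2% over an oscillation
period at `alpha = 100` on the fixture oscillator. A network started
exactly at a deterministic fixed point has all resultant rates zero and
never moves — a faithful, if degenerate, consequence of the construction.

## Topology heuristics

`build_influence_graph()` encodes the qualitative influence structure:
a species A gains a positive edge to every species net-produced by a
reaction in which A is a substrate or enzyme, and a negative edge to
every species net-consumed by such a reaction. Judging production and
consumption on *net* stoichiometry keeps catalysts from influencing
themselves through their own reactions; self-edges are excluded
altogether, since proximity from a source to a target is unaffected by
target self-loops under simple-path semantics. Parallel edges of opposite
sign are kept — they are exactly the "both positive and negative
influence" configurations worth noticing.

Two proximity heuristics are scored against the measured `D`:

* `min_distance()` — directed shortest-path length in steps, signs
  ignored; species with no directed path are reported as `Inf` rather
  than a fake finite value.
* `weighted_proximity()` — the sum over all simple directed paths (no
  repeated nodes) of `1/length`, so all routes of influence contribute,
  shorter ones more heavily. "All paths" is made finite by the
  simple-path restriction plus a `max_len` cap defaulting to the node
  count, i.e. effectively no cap on these graph sizes.
  `signed_proximity()` additionally multiplies each path by the product
  of its edge signs, so antagonistic routes cancel.

`evaluate_heuristic()` fits `D` on the score by ordinary least squares
with an intercept and reports R². Since R² of a univariate OLS fit equals
the squared Pearson correlation, the choice of regression direction does
not affect the reported value. Unreachable species are excluded from the
fit by default (there is no principled finite score for them); a flag
includes them with score zero instead.

## The model library

The fixture experiment needs oscillators with distinct, tunable
frequencies, mass-action kinetics throughout, and modest molecule counts
so that a full crosstalk experiment (hundreds of 4000-minute runs) stays
cheap. `make_oscillator()` builds a delayed negative-feedback loop:

* an activator X with constant production, weak autocatalysis
  (`X -> 2X`), and
* a chain of intermediates `X -> Y1 -> ... -> Ym` whose terminal species
  catalyses the degradation of X (`X + Ym -> Ym`).

A bilinear degradation feedback with a short chain is, on its own, always
damped (the loop gain saturates before the Hopf condition is met —
strengthening the feedback also strengthens the local damping it
creates). The autocatalysis term cancels most of that local damping:
with the autocatalytic rate set to 97% of the feedback loss rate at the
fixed point (a design constant), the system sits just beyond the Hopf
bifurcation and shows a genuine limit cycle of moderate amplitude, with
intrinsic noise broadening it at counts of order 100. The period is
calibrated exactly by uniform time-rescaling: all rate constants are
multiplied by one factor chosen so that the imaginary part of the
dominant Jacobian eigenvalue at the fixed point matches
`2*pi/target_period`. Time-rescaling is exact for the nonlinear
dynamics; the realized spectral peak sits within a few percent (and one
or two frequency bins) of the target. Builds whose specification admits
no oscillatory eigenvalue are refused at fixture-build time.

`standard_fixture()` assembles the three-subsystem crosstalk experiment:

* a slow oscillator, period 500 min (dominant mode ≈ 0.002 cycles/min),
* a fast oscillator, period 100 min (≈ 0.01 cycles/min, five times
  faster — comfortably above the factor-3 separation needed to tell the
  two signatures apart in a spectrum), and
* a seven-species signalling cascade `C1 .. C7` receiving the slow
  oscillator at `C1` and the fast one at `C2` through catalytic coupling
  reactions (`source -> source + target`), whose rate constants are the
  only thing a coupling-strength multiplier scales. Multiplier 0 removes
  the coupling reaction, making the "coupled" system exactly the
  disjoint union.

The cascade is deliberately not a uniform relay. `C2` is a fast-turnover
stage (turnover 0.1/min against 0.02/min elsewhere): its high basal flux
buffers the mean shift that coupling injects, while passing oscillatory
drive downstream almost unattenuated. Species `C3..C6` form a negative
feedback subloop tuned to resonate near 0.009 cycles/min — essentially
the fast oscillator's frequency — with a quality factor of about 1.7.
Susceptibility to perturbation is therefore frequency-dependent and
non-monotone in graph distance, which is the regime in which
topology-only heuristics are expected to struggle, and measured
perturbation patterns show exactly that: the maximally perturbed species
is not always the directly-driven one, and joint perturbations are not
sums of single ones. All counts sit near 50–100 molecules, which keeps
intrinsic noise visible without letting it dominate.

What the fixture does *not* emulate: transcriptional bursting,
explicit time delays, custom (saturating) kinetics, spatial effects, or
the parameterisation of any specific biological pathway — its species are
analogues with abstract names, designed to reproduce behavioural
signatures (distinct periods, transients, resonance), not biological
rate constants. Conclusions from the test suite are therefore about the
measurement machinery, not about any particular cell.

## Numerical choices and edge cases

* DFT kernel: the standard `exp(-2*pi*1i*w*n/N)`; spectra are computed
  by `stats::fft` and verified against a direct O(N²) evaluation of the
  definition to 1e-9 relative error.
* K-S normalization: each spectrum is divided by its own sum; an
  all-zero spectrum has no distribution and is rejected rather than
  silently zero-filled.
* Phase: four-quadrant `Arg` in (-π, π]; bins whose modulus is below
  `1e-9 * N * max|x|` are flagged undefined rather than reported as
  noise.
* Channel selection: cumulative-sum search with strict inequality
  (`cum > u * a0`), so ties at bin boundaries resolve deterministically
  and traces are reproducible across platforms.
* Seeds: 53-bit integers from splitmix64; all user-facing seeds are
  plain integers, and every random quantity in the package derives from
  one.
* Rounding of α-scaled amounts: half-to-even, the unbiased choice.
* Problem sizes in the test suite: spectral oracles run at `N ≤ 64`
  against brute-force DFTs; simulator exactness uses a 4-state CME
  solved by matrix exponential with 10⁴ runs; the crosstalk experiment
  runs `K = 100` paired ensembles of the full fixture at the default
  `N = 4000`, `dt = 1` grid, matching the conditions under which the
  null floor of `D ≈ 0.05` is quoted.

## Limitations

* The K-S distance is used as a behavioural *distance*, not as a test
  statistic with a calibrated null distribution; significance is handled
  operationally through the measured null floor at a given `K`.
* Average phase spectra are computed but carry little usable structure
  (phases decohere between runs); they are provided for completeness.
* The quasi-deterministic representation freezes at exact deterministic
  fixed points; start it off-equilibrium when comparing against ODE
  solutions.
* SBML import is deliberately minimal (species plus mass-action
  reactions identified by a parameter named `k`); anything else is
  refused by feature name. The native dialect is the first-class format.
* Wavelet or multi-resolution analyses, mutual-information measures and
  tau-leaping/hybrid simulation are out of scope.
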