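# oscspec

Frequency-domain analysis of stochastic oscillatory reaction networks.

Coupled signalling pathways (think NF-κB, p53 and the cell cycle)
oscillate, and the practical question when joining separately-validated
pathway models is *how much, and where, does coupling change the
behaviour?* Stochastic simulation answers it in principle, but averaging
stochastic time series destroys oscillations: run phases decorrelate, so
the ensemble mean flattens out exactly the structure of interest, while
the chemical master equation's state distributions discard causality
altogether. `oscspec` implements the frequency-domain workaround and the
machinery around it, for modellers who need a quantitative, reproducible
behavioural distance between stochastic models.

## The method

Each simulation run (Gillespie direct method, exact) is resampled to a
regular grid by last-value sampling, `x_n = x_t | max(t ≤ n·δt)`, and
transformed with the DFT,

    f_ω = Σ_{n=0}^{N-1} x_n e^{-2πiωn/N},      f̂_ω = |f_ω|,

computed by FFT. The ensemble of K runs is summarised by the term-wise
**mean of the amplitude spectra**, f̃_ω = (1/K) Σ_i f̂_{ω,i} — not the
mean of the complex spectra, which by linearity would equal transforming
the washed-out time-domain mean. Two average spectra are compared with a
discrete Kolmogorov–Smirnov distance

    D = max |F₁ - F₂| ∈ [0, 1],

where F₁ and F₂ are the cumulative distributions of the unit-normalized
spectra. `N` and `δt` fix the observation window `N·δt`, frequency
resolution `1/(N·δt)` and maximum observable frequency `1/(2·δt)`; the
defaults N = 4000, δt = 1 min give 0.00025 and 0.5 cycles/min.

On top of this sit: a plain-text reaction dialect (plus minimal SBML
import), α-discretization of concentration models to molecule counts,
quasi-deterministic conversion (per-species net-rate channels — same
drift, almost no intrinsic noise), signed influence graphs with
distance/path-proximity heuristics scored by R² against measured D, and
a library of coupled mass-action oscillators for crosstalk experiments.
See the vignette in `vignettes/frequency-domain-analysis.Rmd` for the
full account.

## Worked example

Measure the crosstalk between two oscillators (periods 500 and 100 min)
and a seven-species signalling cascade they drive:

```r
library(oscspec)

fix <- standard_fixture()                  # slow -> C1, fast -> C2
sc  <- sampling_config(N = 4000, dt = 1)   # 4000 min window
res <- procedure_B(fix$coupled, fix$uncoupled, sc, K = 100,
                   base_seed = 1, species = paste0("C", 1:7))
print(res)
#> <procedure_B_result> K=100 pairs; per-species D:
#>     C1     C2     C3     C4     C5     C6     C7
#> 0.1032 0.1149 0.0362 0.0591 0.0572 0.0581 0.0520
```

Every cascade species is perturbed well above the null floor (a
same-model comparison at K = 100 gives D ≈ 0.01, and differences of
about 0.05 are reliably resolved). The pattern is not a monotone decay
with network distance: the relay species `C2` is perturbed *more* than
the directly-driven `C1`, and the resonant subloop (`C4`–`C6`) is more
perturbed than its upstream neighbour `C3`. Scoring topology heuristics
against these measurements:

```r
g <- build_influence_graph(fix$coupled)
evaluate_heuristic(-min_distance(g, "slow_X")[paste0("C", 1:7)], res$D)
#> <heuristic_evaluation> R^2 = 0.433 over 7 species
evaluate_heuristic(weighted_proximity(g, "slow_X")[paste0("C", 1:7)], res$D)
#> <heuristic_evaluation> R^2 = 0.523 over 7 species
```

— topology alone is a weak predictor of where coupling is felt, which is
precisely what the spectral measurement is for.

A command-line wrapper over the same functions is installed at
`inst/cli/oscspec.R` with verbs `simulate`, `spectra`, `compare`,
`heuristics` and `fixture`:

```sh
Rscript inst/cli/oscspec.R fixture --out models
Rscript inst/cli/oscspec.R compare --model-a models/coupled.osc \
    --model-b models/uncoupled.osc --runs 100 --seed 1 --out results
```

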