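# lissastab

Simulation and analysis of bistable perception of rotating Lissajous
figures, for psychophysicists and computational cognitive scientists
studying how contextual cues stabilise perception under ambiguity.

A Lissajous figure — `x(t) = sin(a t)`, `y(t) = cos(b t + δ)` with the
phase offset δ increasing continuously — is seen as a 3D object rotating
in depth whose direction is ambiguous; percepts flip almost exclusively at
*self-occlusions*, the configurations where front and back of the figure
coincide (δ = 0° and 180° for a = 3, b = 6). Under a 2×2 within-subject
design (shifting frequency 0.15/0.30 rps × size 2.05°/4.10°) the package
provides:

* **Stimulus geometry** — self-occlusion phases by a depth-ambiguity
  search, occlusion event schedules (rate 2·f per second), overlap
  durations from stroke-width geometry, the parameter-relation multipliers
  of the design, and randomized 345-s run schedules.
* **Synthetic observers** — a memoryless (Markov) switcher and an observer
  that forward-samples the generative model below, both emitting realistic
  button-press logs (CW/CCW/MIXED) with response latencies.
* **Preprocessing** — event logs → per-interval percept series `θ`
  sampled at self-occlusions, phase durations, press-phase histograms.
* **Conventional analysis** — transition probability (percept changes per
  self-occlusion), run-then-subject averaging, and a closed-form 2×2
  repeated-measures ANOVA with partial eta squared.
* **Generative model of perceptual stability** — trial-by-trial
  prediction of `θ(t)` from a stability prior with mean
  `μ_stab(t) = θ(t−1)` and precision reset to `π_init` after each new
  percept, otherwise decayed by a precision-weighted prediction error
  `π(t) = π(t−1)·exp(−(π_sensory/π(t−1))·|PE(t−1)|)`; posterior
  `P(θ=1) = 1/(r+1)` with
  `r = exp(((θ0−μ)² − (θ1−μ)²)·π/(−2))`; MAP inversion of
  `ξ = log π_init` per condition under a standard-normal prior, with a
  Laplace approximation to the log-model evidence, plus the prior-free
  control model (evidence exactly `n·log(1/2)`).
* **Random-effects Bayesian model selection** — variational Dirichlet
  posterior over model frequencies, expected model probabilities and
  exceedance probabilities (Monte-Carlo, with the closed-form Beta tail
  for two models).

## Worked example

Simulate a small cohort from the stability-prior observer (π_init = 2
slow, 3 fast), run the whole pipeline, and inspect the summary:

```r
library(lissastab)
cfg <- pipeline_config(n_subjects = 6, n_runs = 4, seed = 42)
res <- run_pipeline(cfg)

round(unlist(res$summary$transition_probability), 3)
#>   fast_big fast_small   slow_big slow_small
#>      0.240      0.214      0.281      0.309

round(unlist(res$summary$pi_init_mean), 2)
#>   slow_big slow_small   fast_big fast_small
#>       2.00       1.79       2.72       3.00

print(res$summary$anova, digits = 3)
#>      effect        F df1 df2        p eta_p_sq
#> 1      freq 56.30196   1   5 0.000665 0.918437
#> 2      size  0.00139   1   5 0.971733 0.000277
#> 3 freq:size  4.52153   1   5 0.086800 0.474874

round(unlist(res$summary$exceedance_prob), 4)
#> stability_prior        no_prior
#>          0.9919          0.0081
```

The higher stability precision in the fast conditions produces fewer
transitions there (0.21–0.24 vs 0.28–0.31 per occlusion), the ANOVA on
transition probabilities shows the corresponding frequency main effect
with no size effect, the inversion recovers the generating per-condition
precisions, and model selection favours the stability-prior model over
the prior-free control. Passing `out_dir =` to `run_pipeline()` writes
`events.csv`, `trials.csv` and JSON records (`conv.json`, `fitsA.json`,
`fitsB.json`, `bms.json`, `summary.json`), byte-reproducible from the
configuration and seed.

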