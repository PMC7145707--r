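# unwindFRET

Single-molecule FRET analysis of CRISPR–Cas9 induced DNA unwinding, from
dual-channel TIRF movies (or pre-extracted intensity traces) to the
unwinding statistics used to compare Cas9 variants and guide-RNA designs.

## The problem

DNA unwinding is a checkpoint before cleavage by Cas9: the Cas9–RNA–DNA
complex interconverts between a *rewound* state (duplex reformed, high
FRET, E ≈ 0.75) and an *unwound* state (R-loop open, low FRET,
E ≈ 0.3). How readily a Cas9/gRNA combination unwinds targets carrying
PAM-distal mismatches predicts how promiscuously it will cleave them.
In the smFRET assay, surface-immobilised Cy3/Cy5-labelled DNA duplexes
are imaged on the two halves of one EMCCD frame (donor left, acceptor
right), and per molecule and frame

    E = I_A / (I_D + I_A)

with background-corrected donor and acceptor intensities. Per condition
(Cas9 variant × gRNA design × number of PAM-distal mismatches `n_PD`),
the pooled E histogram of the first five frames of every molecule is
classified into donor-only (E ≤ 0.2), low-FRET/unwound and
high-FRET/rewound populations (boundary 0.6/0.65/0.7), giving the
unwound fraction

    f_unwound = n_low / (n_low + n_high)

and, from a mismatch profile `n_PD = 0..3`:

    promiscuity  P = Σ_{n=1..3} n · f_unwound(n)
    specificity  S = f_unwound(0) / P

Truncated guides (X18, gX18, X17) cannot pair with the full 20-nt
protospacer, so P and S are undefined for them and only on-target
activity is reported.

The package is aimed at single-molecule biophysicists who want a tested,
reproducible implementation of this analysis — including a
ground-truth-labelled synthetic data generator (two-state kinetics,
photobleaching, donor-only molecules, rendered dual-channel movies) so
every stage can be validated without raw recordings, which were never
deposited for this assay.

## What's inside

| Stage | Functions |
|---|---|
| Synthetic data | `kinetic_params()`, `photophysics_params()`, `condition()`, `condition_panel()`, `simulate_states()`, `simulate_traces()`, `render_movie()` |
| Trace extraction | `split_channels()`, `detect_spots()`, `map_to_donor()`, `extract_traces()` |
| FRET analysis | `fret_efficiency()`, `pool_first_k()`, `fret_histogram()`, `classify_populations()`, **`fit_unwinding()`** (returns an `unwind_fit` with `print`/`summary`/`coef`/`confint`/`plot`/`simulate` methods) |
| Specificity | `mismatch_profile()`, `promiscuity()`, `specificity_score()`, `compare_conditions()`, `plot_activity_promiscuity()` |
| Pipeline | `pipeline_config()`, `read_config()`/`write_config()`, `run_pipeline()`, `demo_panel()`; CLI wrapper in `inst/scripts/unwindfret.R` |

## Worked example

Simulate one condition (60% unwound-state occupancy, 2500 molecules),
fit the unwound fraction, and score a mismatch profile:

```r
library(unwindFRET)

cond <- condition("SniperCas9", n_pd = 1,
                  kinetics = kinetic_params(p_unwound = 0.6))
sim <- simulate_traces(cond, n_molecules = 2500, n_frames = 8, seed = 42)
fit <- fit_unwinding(sim$traces, n_boot = 1000, seed = 1,
                     total_intensity = 500, label = "SniperCas9, n_PD = 1")
summary(fit)
#> Two-state unwinding fit: SniperCas9, n_PD = 1
#>   f_unwound = 0.5885 (bootstrap SD 0.0099), 2500 molecules, first 5 frames
#>   pooled E values: 12500 (donor-only 1376, low 6546, high 4578)
#>   thresholds: donor-only <= 0.20, low/high boundary 0.65
#>   mean E: low 0.301, high 0.752
#>   95% bootstrap CI: [0.5685, 0.6080] (1000 replicates)
```

The fit recovers the simulated occupancy (0.5885 vs 0.6, within its
bootstrap SD); the donor-only peak (the ~10% of molecules simulated with
an inactive acceptor) is counted but excluded from the denominator, and
the low/high population means sit at the state efficiencies 0.3/0.75.

```r
prof <- mismatch_profile(
  data.frame(n_pd = 0:3, f_unwound = c(0.90, 0.60, 0.40, 0.10),
             sd = c(0.006, 0.010, 0.010, 0.006)),
  label = "SniperCas9")
specificity_score(prof)
#> Specificity of 'SniperCas9' (X20):
#>   on-target activity 0.900 +- 0.006, promiscuity 1.700 +- 0.029
#>   S = 0.529 +- 0.010
```

Here promiscuity is `1·0.60 + 2·0.40 + 3·0.10 = 1.70` and
`S = 0.90 / 1.70 = 0.53`: high on-target activity, but enough residual
unwinding of mismatched targets to keep specificity middling.

A complete five-variant comparison (20 conditions, each ≥ 2000
molecules) runs in under a minute:

```r
res <- run_pipeline(demo_panel(seed = 1), out_dir = "demo_out")
res$comparison          # one row per variant, sorted by S
plot_activity_promiscuity(res$comparison)
```

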