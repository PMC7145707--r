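---
title: "Quantifying Cas9-induced DNA unwinding from single-molecule FRET data"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Quantifying Cas9-induced DNA unwinding from single-molecule FRET data}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(unwindFRET)
```

## The measurement and the model

Cas9 bound to its guide RNA interrogates double-stranded DNA by unwinding
the protospacer and forming an R-loop. Unwinding is a checkpoint before
cleavage, so the degree of unwinding of a catalytically dead Cas9 (dCas9)
is a proxy for the enzyme's cleavage specificity. In the smFRET assay this
package emulates and analyses, DNA duplexes carrying a Cy3/Cy5 pair are
immobilised on a passivated surface and imaged by TIRF microscopy; both
emission channels are projected side by side onto the two halves of one
EMCCD frame at 100 or 35 ms per frame. Per molecule and frame the FRET
proximity ratio is

$$E = \frac{I_A}{I_D + I_A},$$

with $I_D$, $I_A$ the background-corrected donor and acceptor intensities.
Intact duplex (or the re-zipped "rewound" complex) gives $E \approx
0.75$; Cas9-induced unwinding moves the dyes apart, $E \approx 0.3$. The
complex interconverts between these two states, modelled here as a
reversible two-state Markov chain

$$\text{rewound} \;\underset{k_\text{close}}{\overset{k_\text{open}}{\rightleftharpoons}}\; \text{unwound},
\qquad p_\text{unwound} = \frac{k_\text{open}}{k_\text{open} + k_\text{close}}.$$

The quantity of interest per experimental condition (Cas9 variant x gRNA
design x number of PAM-distal mismatches $n_{PD}$) is the unwound
fraction $f_\text{unwound}$, estimated from an $E$ histogram; from the
mismatch profile two derived statistics compare conditions:

* **promiscuity** $P = \sum_{n_{PD}=1}^{3} n_{PD}\, f_\text{unwound}(n_{PD})$ —
  off-target unwinding, penalised more heavily the more mismatches the
  target carries; and
* **specificity** $S = f_\text{unwound}(0) / P$.

Truncated guides (X18, gX18, X17) cannot pair with the full 20-nt
protospacer, so $P$ and $S$ are undefined for them; the comparison table
reports their on-target activity only.

## The estimator

`fit_unwinding()` implements the histogram estimator as a classed model
fit:

1. `fret_efficiency()` forms $E$ per frame, marking frames invalid when
   $I_D + I_A$ falls below a floor (default 10% of the configured total
   emission, else the 5th percentile of totals). Without the floor,
   post-bleach frames contribute wild ratios of two near-zero numbers.
2. `pool_first_k()` pools the first $k = 5$ valid frames of every
   molecule, so each molecule contributes equally and early, before
   appreciable photobleaching. A molecule with fewer valid frames
   contributes what it has. Reference histograms of this kind are built
   from more than 2000 molecules; smaller samples trigger a warning.
3. `classify_populations()` splits the pooled values at fixed thresholds
   into donor-only ($E \le 0.2$), low-FRET/unwound
   ($0.2 < E <$ boundary) and high-FRET/rewound ($E \ge$ boundary), with
   the boundary one of 0.6, 0.65 or 0.7 (default 0.65, the middle of the
   conventional set). Both cut points close on the side conservative for
   $f_\text{unwound}$: a value exactly at the boundary counts as high,
   exactly at 0.2 as donor-only.
4. The estimate is $\hat f_\text{unwound} = n_\text{low} /
   (n_\text{low} + n_\text{high})$. Donor-only observations are excluded
   from the denominator by default: a molecule without an active acceptor
   carries no unwinding information, and the acceptor-channel detection
   step exists precisely to exclude such molecules. The alternative
   convention (donor-only in the denominator) is available as
   `include_donor_only = TRUE`.
5. The SD is a nonparametric bootstrap over molecules (default 1000
   replicates, seeded). Frames within a molecule are strongly correlated
   — under slow exchange the first five frames mostly sample one state —
   so resampling frames would understate the error; the molecule is the
   exchangeable unit. At 3000 molecules the bootstrap SD agrees with the
   binomial closed form $\sqrt{f(1-f)/n}$ within a factor of 1.5.

The SD of $P$ combines the three per-condition SDs in quadrature with
weights 1, 2, 3; the SD of $S$ is first-order (delta-method) propagation
of the ratio, with a molecule-level bootstrap alternative behind
`sd_method = "bootstrap"`. Reported SDs are statistical (sampling)
uncertainties of a single synthetic data set, not replicate-to-replicate
experimental scatter.

## What the generator emulates — and what it does not

`simulate_traces()` and `render_movie()` produce ground-truth-labelled
data with the statistical structure the analysis assumes:

* **States.** Trajectories are sampled with the exact discrete-time
  propagator of the two-state chain (matrix exponential of the 2x2
  generator in closed form), so there is no time-step discretisation
  error; an event-driven Gillespie simulation is used as an independent
  oracle in the tests. Published histograms constrain only the
  equilibrium occupancy, not the rates, so the generator is parameterised
  by occupancy with a default total exchange rate of 0.5/s — slow
  relative to the 100 ms frame, making the first five frames quasi-static
  — and that default is an explicit placeholder, not a measurement.
* **Intensities.** A molecule in state $s$ emits $I_A = E_s T$ and
  $I_D = (1-E_s) T$ with total emission $T$ constant across states, plus
  per-channel additive Gaussian noise (EMCCD excess noise at these count
  levels is approximately Gaussian, and a single SD keeps the $E$
  broadening interpretable). Defaults $T = 500$ and noise 25 counts give
  a per-frame $E$ SD of about 0.04 in either state. At that width,
  leakage of the rewound population ($E = 0.75$) across the 0.65 boundary
  is about 0.6%, and the estimator recovers occupancies across
  $[0.05, 0.95]$ to better than 0.03. This choice is deliberate: with a
  per-frame $E$ SD as large as 0.08, 10.6% of rewound frames fall below a
  0.65 boundary — a structural bias of the threshold method itself that
  no sample size cures — so the generator's default noise sits where the
  threshold classifier is in its valid regime, and the boundary-robustness
  checks use still narrower peaks ("well separated": $E$ SD ~0.02,
  because the 0.7 boundary lies only 0.05 from the rewound mode).
* **Nuisance populations.** A configurable fraction of molecules
  (default 10%) is donor-only ($E \approx 0$); photobleaching is
  single-step per dye with independent geometric bleach frames, the
  acceptor turning the molecule donor-only and the donor silencing it.
* **Movies.** Each molecule is a pixel-integrated 2-D Gaussian PSF
  (default sigma 1.1 px) at an acceptor-half position drawn at least
  $3\sigma$ from the half borders and at least $6\sigma$ from any other
  molecule, with the donor-half position a pure sub-pixel translation.
  A constant camera pedestal and Gaussian read noise are added and frames
  are clipped to 16-bit. Coordinates are 1-based pixel centres, the
  R convention, throughout.

Not emulated: diffusing molecules, stage drift, spectral crosstalk and
gamma correction, Cy3/Cy5 blinking beyond single-step bleaching, and
affine (non-translational) channel registration. Passing tests therefore
demonstrate correctness of the estimator and pipeline under the stated
model, not robustness to every artefact of real recordings — in
particular, real data would require crosstalk/gamma calibration before
$E$ values near the published ones are quantitative.

## Extraction choices

Detection runs on the acceptor channel only, implementing the exclusion
of molecules with missing or inactive acceptors, and on a time-averaged
image (mean of the first 20 frames): molecules are immobilised, so
averaging raises SNR without smearing and fixes molecule identity across
frames. The pipeline is difference-of-Gaussians band-pass at the PSF
scale, a robust threshold at median + 6 MAD, 8-neighbour local maxima,
and centroid refinement in a 7x7 window. Two gates enforce the
single-emitter model: a spot whose measured major-axis width exceeds
1.4x the PSF sigma is rejected (two emitters closer than the band-pass
resolution limit blend into one broadened maximum), and both members of
any pair closer than the minimum separation are dropped. Photometry is a
circular aperture (radius 3.5 px) minus the annulus-median background
(radii 5–8 px) times the aperture area; the median is robust to the odd
neighbouring spot. The circular aperture captures 98.5–99.4% of the PSF
mass depending on the sub-pixel centre; because the loss is common to
both channels it cancels in the ratio $E$.

## Numerical and degenerate-input conventions

* Histogram bins are half-open $[lo, lo+w)$ with exactly reproducible
  edges; out-of-range values are clipped into the edge bins so counts are
  conserved. Densities sum to one over bins.
* Zero detected spots is a valid empty result; zero FRET-active
  molecules is an error naming the condition.
* With both rates zero the chain is frozen in its (occupancy-drawn)
  initial state; inconsistent occupancy/rate combinations are rejected at
  `1e-12` relative tolerance.
* All randomness flows from one top-level seed per entry point; identical
  seeds give byte-identical traces, movies, histograms and tables.
  Artifact TSVs are written with fixed 15-significant-digit formatting to
  make that guarantee hold at the file level.

## The synthetic demonstration panel

`demo_panel()` builds a five-variant panel (WT, HypaCas9, SniperCas9,
Cas9-HF1, eCas9; canonical X20 guide; $n_{PD}$ 0–3). Per-condition
unwound fractions for these enzymes are not published as tables, so the
panel's occupancies are constructed values, chosen once so that (i) each
variant's exact $S$ equals its reference specificity (0.23, 0.50, 0.53,
0.66, 0.71), and (ii) the qualitative pattern matches the assay's
narrative: HypaCas9 pays for its specificity with low on-target activity
(0.55), SniperCas9 keeps the highest on-target activity (0.90) but is
the most promiscuous engineered variant, and WT is promiscuous outright.
The default of 5000 molecules per condition follows from a power
analysis: the smallest gap in the ladder (SniperCas9 vs HypaCas9, 0.03)
has a molecule-level sampling SD of about 0.017 at 2000 molecules, so
strict ordering would fail on an appreciable fraction of runs; at 5000
molecules the gap is about 2.4 SD and the recovered ladder is stable.
Problem sizes used elsewhere in the tests (3000 molecules for recovery
sweeps, 200-molecule movies for the imaging path) were chosen on the
same principle: large enough that sampling error is small against the
tolerance being checked, small enough to run interactively.

```{r panel, eval = FALSE}
cfg <- demo_panel(seed = 1)
res <- run_pipeline(cfg, out_dir = "demo_out")
res$comparison
plot_activity_promiscuity(res$comparison)
```

## Known limitations

* The threshold classifier is the assay's stated method, kept
  deliberately; it is biased once the state peaks broaden toward the
  boundary (see above). A mixture fit or HMM would degrade more
  gracefully but would no longer be the published procedure.
* Exchange kinetics, dwell times and the intrinsic cleavage rate are out
  of scope; the two-state rates exist in the generator only to make
  trajectories, and nothing downstream estimates them.
* Channel registration is a known translation. Real dual-view optics
  need a measured affine map; feeding one is the caller's job
  (`map_to_donor()` accepts any offset, but only a translation).
* The per-condition SD is statistical only. Experimental
  replicate-to-replicate variation (surface chemistry, labelling
  efficiency, day effects) is not modelled, so real error bars would be
  wider.
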