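---
title: "Models and methods behind NanoSiMPull"
author: "NanoSiMPull authors"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind NanoSiMPull}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(NanoSiMPull)
```

# The assay and what the package computes

In a lipid Nanodisc single-molecule pulldown (SiMPull) assay, biotinylated
Nanodiscs carrying a phosphoinositide (PIP) of interest are tethered to a
passivated slide, whole-cell lysate containing an EGFP-tagged protein is
flowed in, and two-channel TIRF movies are recorded: a far-red channel in
which DiD dyes mark the disc positions, and a green channel in which EGFP
marks bound protein. Because a ~10 nm disc presents a handful of PIP
molecules on ~40 nm^2 of lipid surface, each disc carries at most one
bound protein (or protein complex) at a time, so the assay reads out at
true single-molecule resolution.

NanoSiMPull implements the complete downstream analysis:

1. **Spot counting** — PSF-based detection of diffraction-limited spots,
   per-field counts adjusted by pre-lysate background, summaries over
   fields.
2. **Binding calls** — a detection threshold (mean + 2 SD of a nonbinder
   panel) combined with a one-sample, one-tailed t-test.
3. **Stoichiometry** — photobleaching step counting (1–4 steps) per spot.
4. **Kinetics** — dwell times of transient binding events, exponential
   maximum-likelihood estimation of the dissociation rate `k_off`,
   likelihood-ratio comparison of rates, rebinding quantification.
5. **Simulation** — a forward model of the movies with complete ground
   truth, so that every stage above is testable without any raw data.

A deterministic stoichiometry calculator reproduces the composition
arithmetic of the disc and vesicle preparations (anionic lipids per
leaflet, accessible PIPs on a vesicle, leaflet area, dye mass fraction).

# The forward model

`simulateField()` generates one two-channel field. Its defaults are the
assay's own conditions, not free dials:

* **Geometry.** 160 nm/pixel (100x objective, 16 um EMCCD pixel) on a
  250 x 250 pixel field, i.e. 1,600 um^2 — the field area over which
  counts are reported. Disc density defaults to 700 per field, the
  density the discs are diluted to. Positions are uniform with a minimum
  separation (default 4 px); an impossible packing request is an error.
* **Timing.** 10 frames/s. Counting acquisitions are 20 frames; kinetics
  movies 30–40 s (300–400 frames). The disc channel is acquired first
  and briefly (`discFrames`), then the protein channel (`nFrames`).
* **Photophysics.** Each disc carries 2 DiD dyes; each bound protein
  carries 1 fluorophore (2 in dimer mode). Fluorophores bleach at
  independent exponential times. Pixel formation is pixel-integrated
  Gaussian PSF (sigma 1 px) -> Poisson shot noise -> camera gain ->
  Gaussian read noise -> constant offset. The EMCCD excess-noise factor
  is deliberately omitted; its effect is equivalent to a somewhat larger
  read noise, which is a free parameter anyway. Laser power and gain are
  not reported quantities for this assay, so `photonsPerFluor` (default
  600/frame) is chosen to put a single fluorophore at peak-pixel SNR
  ~11, comfortably in the regime where detection is reliable; results
  are reported as functions of SNR, not of hardware settings.
* **Kinetics.** Binding at each occupied disc is an alternating renewal
  process: unbound waits ~ Exp(`kOnPseudo`) (pseudo-first-order at the
  fixed lysate concentration), bound dwells ~ Exp(`kOff`); a
  `stableFraction` of binders never dissociates within the movie. Each
  bound interval is a fresh molecule with fresh fluorophores — rebinding
  ("blinking") is dissociation followed by binding of another copy, and
  the single-molecule regime (at most one binder per disc at a time) is
  enforced and asserted in the ground truth's validity method.

What the simulator does **not** emulate: diffusing background
fluorophores, evanescent-field depth, stage drift, chromatic offset
between channels, and EM excess noise. Passing tests therefore
demonstrate the correctness and calibration of the analysis chain under
a faithful idealization of the assay, not robustness to every
instrumental pathology of real data.

`simulateDwellTimes()` draws exponential dwells directly and
discretizes them to whole frames by the ceiling rule (an event shorter
than one frame is recorded as one frame), which is how a dwell read off
a movie behaves. `simulateBleachTrace()` produces descending
photobleaching staircases with Gaussian noise; its ground truth records
both the nominal fluorophore number and the number of *visible* steps —
bleach events falling in the same frame merge into one drop, and events
after the movie end never appear, so the visible count is the only
recoverable truth.

# Spot detection

Detection follows the standard matched-filter recipe for
diffraction-limited emitters: correlate the time-averaged image with the
pixel-integrated Gaussian PSF, keep local maxima whose least-squares
amplitude exceeds `snrMin` (default 5) times the robust noise (MAD) of
the filtered image, refine each maximum to subpixel precision with a
local Gaussian (parabolic) fit, merge duplicates closer than 2 sigma,
and drop spots within 3 sigma of the border (edge exclusion). On
simulated fields at 700 discs/1,600 um^2 and SNR >= 10 this reaches
recall and precision >= 0.95 with localization error well under a pixel
(the test suite checks >= 0.95; typical values are ~1.0 and ~0.07 px
RMSE).

Counting uses the average of the 20-frame acquisition; the adjusted
count of a field is (spots after lysate) − (spots before lysate),
preserved even when negative. Colocalization between channels is greedy
nearest-neighbour matching within 2 px; by default EGFP counting is
*not* restricted to DiD-colocalized spots (the counting procedure is
defined on the EGFP channel alone), but `colocalize()` provides the
restricted mode.

# Traces and binarization

`extractTrace()` does aperture photometry per frame: the sum over a
3-px-radius aperture minus the annulus (5–7 px) median scaled to the
aperture area. The geometry is a package choice (no extraction geometry
is prescribed by the assay); a 3 px aperture captures ~98% of a
sigma = 1 px PSF while keeping neighbour contamination low at 700
spots/field with 4 px minimum separation.

`binarizeTrace()` segments a trace into bound/unbound intervals by
deterministic 1-D two-means clustering with the threshold at the
midpoint of the two centres — invariant under affine rescaling of the
intensities. A trace whose centres are closer than 3 robust SDs is
declared single-level and classified against an optional on-level
prior. The two-means threshold (rather than an HMM) is deliberate: the
dissociation model is a single memoryless exponential, so a two-state
threshold is sufficient, auditable, and free of tuning. There is **no
gap closing**: a single dark frame counts as an unbinding/rebinding
cycle. This is the operational definition of blinking used throughout,
and it matters for the rebinding statistics. First and last intervals
are flagged censored.

Two events separated by less than one frame are merged by any method at
this sampling rate; the recovery tests therefore score against
frame-resolvable events (complete events with both flanking gaps longer
than one frame), of which >= 95% are recovered within +/- 1 frame at
SNR ~10.

# Photobleaching step counting

`fitSteps()` fits piecewise-constant models with 0..4 change points by
*exact* dynamic programming (globally optimal segmented least squares,
implemented in C++; with at most 4 change points the exact search is
cheap and fully deterministic — no stochastic search, no pruning).
Model order is selected by BIC on Gaussian residuals, with selection
restricted to the *admissible* class of photobleaching staircases:
every step must go down, by more than `minStepSigma` (default 2) robust
noise SDs, and the final level must sit at background within
`baselineTol` (default 3) SDs. If no step model is admissible the trace
is returned unclassified (`nSteps = 0`) with the violation as the
reason — upward steps, for instance, indicate rebinding and belong to
the kinetics branch, not the stoichiometry branch. Classification is
scored against the *visible* step count of the generator (see above);
at step-height SNR 5 accuracy is ~98% per class, and 100% on noiseless
staircases. Reading a 2-step class as "one dimer" versus "two monomers"
is a reporting interpretation, not something the classifier decides.

# Dwell-time kinetics

The dissociation model is a single, uncensored exponential decay.
`collectDwells()` pools bound-interval durations across spots and
experiments, excluding censored intervals (those touching the movie
start or end) by default; a censoring-aware likelihood (events
contribute the density, censored intervals the survival function) is
available as an explicit option for sensitivity analysis.

For continuous durations the ML estimate is the closed form
`k_off = n / sum(t)`, with Fisher standard error `k_off / sqrt(n)` and
a log-scale Wald 95% CI `k_off * exp(±1.96 / sqrt(n))` (the CI form is a
declared package choice). For frame-discretized durations the package
uses the exact discrete-sampling likelihood by default: conditional on
being observed at all, the dwell length in frames of an exponential
event is geometric with success probability `1 − exp(−k dt)`, so

```
k_hat = −log(1 − n / sum(m)) / dt ,   m_i = duration_i / dt ,
```

which reduces to `n / sum(t)` as `dt -> 0`. The naive continuous closed
form applied to ceiling-discretized dwells is biased low by about
`k dt / 2` (−2.8% at `k dt = 0.055`, i.e. within 5%, as the test suite
documents); the geometric form removes this bias, and the same
conditional geometric law holds for dwells read off a binarized movie
(frames above threshold with uniform event phase), so one estimator
serves both paths. `discretization = "none"` forces the continuous
closed form. Two practical notes: dwell sets in which every event
lasted exactly one frame leave the rate unidentifiable (an error, not a
number), and excluding right-censored dwells leaves a small upward bias
of order (mean dwell)/(movie length) that the censoring-aware option
quantifies.

`lrtCompare()` tests a shared rate against separate rates:
`LR = 2[(l_A + l_B) − l_pooled]` with each term maximized in closed
form, referred to the upper tail of chi-square with 1 df. The statistic
is non-negative by nesting and symmetric in its arguments; under a
simulated null its p-values are uniform and the 5% rejection rate is
5% within Monte-Carlo error.

A spot **displays rebinding** when its movie contains >= 2 distinct
bound intervals; the denominator is spots with at least one bound
interval. Percentages are computed per experiment and summarized as
mean ± SEM, with an unpaired two-tailed t-test between conditions.

# Binding threshold and calls

`deriveThreshold()` recomputes mean + 2 x sample SD from a dataset's own
nonbinder panel. The reference value 80 adjusted spots per 1,600 um^2
(from a 175-assay nonbinder panel whose underlying values are not
published, so it can be applied but not recomputed) corresponds to a
panel mean of 40 and SD of 20, which are the defaults of
`simulateNonbinderPanel()`. A pair is called **bound** only when its
per-assay mean exceeds the threshold *and* a one-sample upper-tailed
t-test against the threshold gives p < 0.05 (>= 3 independent assays
required); under a simulated nonbinder null this joint rule holds the
false-bound rate far below 5%.

# Numerical and design choices

* Counts round half away from zero; "nearest hundred" style reporting is
  presentation only and never feeds back into computation.
* Area per lipid is a caller-supplied parameter with documented defaults
  (0.50 nm^2 for gel-phase DMPC discs, 0.65 nm^2 for fluid-phase vesicle
  arithmetic); vesicle PIP accessibility counts the outer leaflet only,
  since lysate proteins cannot reach the lumen.
* A "percent PIP" statement can be read per leaflet or per disc;
  `discPipCount()` reports both and does not guess intent.
* Two-means initialization is the data range, iterated to a fixed point —
  deterministic, no random restarts anywhere in the analysis path.
* All stochastic code flows from a single integer seed per call
  (`rngSeed`); the same configuration and seed reproduce movies, truths
  and pipeline reports byte-for-byte. Pipeline stage timings go to the
  log, not the report, precisely to keep reports byte-identical.
* The change-point search floor (`rss >= n * (1e-8 * max|y|)^2`)
  guards the BIC's log against exactly-zero residuals on noiseless
  traces; it selects the smallest model achieving the floor.
* No correction is applied for fluorophore photobleaching during a bound
  interval — bleaching and dissociation are indistinguishable in a
  single-colour dwell, which is why validation simulations of the
  kinetics chain disable protein bleaching, and why reported `k_off`
  values from real movies are upper bounds at high excitation power.

# Problem sizes used in validation

The shipped tests and the acceptance script validate at these scales,
chosen to make Monte-Carlo error comfortably smaller than the margins
being tested: rate recovery at k = 0.3–0.6 1/s with n = 1,000 events and
500 replicates per rate; LRT calibration with 2,000 null replicates of
n = 100 each; detection on 10 fields of 700 discs; step classification
on 200 traces per class; end-to-end movie recovery on 20 seeded runs of
a 96 px field (60 discs, 400 frames) — a reduced field at the same
optical and kinetic settings, which keeps per-run dwell counts near
what one field of a real assay pools while holding the whole validation
suite to a couple of minutes on one CPU.

# Known limitations

* The detector assumes an isotropic Gaussian PSF of known width; no
  astigmatism, no per-spot width fitting.
* Kinetics assume a single exponential dwell population; mixtures (e.g.
  stable + transient subpopulations) must be separated upstream, as the
  `stableFraction` of the simulator does.
* The frame-discretized likelihood assumes dwells are whole multiples of
  the frame interval; mixed continuous/discretized pools are refused.
* Binary calls inherit the nonbinder panel's distributional assumptions;
  a threshold derived from too few assays is noisy, and the package
  deliberately refuses fewer than 2 (threshold) or 3 (call) assays.
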