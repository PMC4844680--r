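---
title: "Models and methods behind the dpstr pipeline"
output: rmarkdown::html_vignette
vignette: >
  %\VignetteIndexEntry{Models and methods behind the dpstr pipeline}
  %\VignetteEngine{knitr::rmarkdown}
  %\VignetteEncoding{UTF-8}
---

```{r setup, include = FALSE}
knitr::opts_chunk$set(collapse = TRUE, comment = "#>")
library(dpstr)
```

## The measurement problem

A dynamic protein synthesis translocation reporter (dPSTR) reads out
promoter activity in single live cells without waiting for a fluorophore
to mature. A fluorescent protein (FP) is expressed constitutively and
diffuses freely between nucleus and cytoplasm; the promoter of interest
drives a short-lived peptide carrying two nuclear localization signals
(NLS) and one half of a SynZip heterodimer. As soon as peptide is made it
captures an already-mature FP and drags it into the nucleus, so nuclear
enrichment of the FP (nuclear minus cytoplasmic mean intensity) tracks
protein synthesis on the minute timescale. The canonical application is
expression driven by the yeast HOG (high-osmolarity glycerol) MAPK
pathway: a hyper-osmotic NaCl step transiently drives Hog1 into the
nucleus, cells shrink and re-swell as they adapt, and osmostress
promoters fire transiently.

`dpstr` implements, as one connected and testable pipeline:

1. a stochastic simulator of signalling, promoter switching and reporter
   biochemistry for cohorts of virtual cells;
2. a renderer that turns cohorts into multichannel TIFF time-lapse movies
   with ground-truth masks;
3. segmentation, tracking and quality control recovering per-cell
   compartment traces from movies;
4. the trace-level quantification conventions of translocation-reporter
   analysis (basal correction, expression output and timing, signalling
   output, the transcription-site statistic, half-life estimation); and
5. the dual-reporter intrinsic/extrinsic noise decomposition, resolved in
   time.

Because every stage can be fed by the stage before it, each analysis
convention can be validated against exact ground truth.

## Signalling and cell-area model

Hog1 relocation is modelled phenomenologically, not mechanistically: the
nuclear/cytoplasmic ratio after each NaCl step is a double-exponential
pulse (rise time `rise_time`, default 0.7 min, so the response is visible
within two frames at 2-min sampling) relaxing back to `basal_ratio` with
an adaptation time constant. The relative projected cell area is the
mirror image of the pulse: an immediate dip of `shrink_fraction x
concentration increment`, recovering on the same time constant. No
glycerol feedback loop is modelled; the pulse *is* the model, because the
pipeline uses Hog1 only as an input and readout.

The adaptation time constant scales with the post-step concentration
(`adaptation_time * conc / 0.2 M`). The default `adaptation_time = 6.5`
min puts full recovery (about 2.3 time constants) at roughly 7 min for a
0.1 M step and 30 min for 0.4 M, the range osmotically stressed budding
yeast actually needs. Per-cell lognormal factors (`cell_cv`, default
0.15) scatter both amplitude and adaptation time.

The activity trace handed to the promoter model is the basal-subtracted
ratio normalized by `peak_gain * 0.2 M`, i.e. calibrated so a 0.2 M step
peaks near 1 in the average cell. This scale is a package convention; any
monotone rescaling with a matching `activity_threshold` is equivalent.

## Promoter archetypes

Two kinetic archetypes span the behaviour of osmostress promoters:

* **repressed + remodelling** (pSTL1-like): the locus is silent at rest.
  While activity exceeds `activity_threshold` the locus switches ON with
  hazard `remodeling_rate` (exponential waiting time - the stochastic
  chromatin-remodelling step). It switches OFF, and must re-remodel, once
  activity falls below threshold, which is what decorrelates expression
  between two successive stress pulses.
* **basal + active** (pGPD1-like): always competent, transcribing at
  `basal_tx_rate` plus the induced term, with no stochastic delay.

When ON, the transcription rate is `induced_tx_rate` times the activity
excess over threshold, clipped to [0, 1].

No quantitative promoter rates are available for these systems, so the
defaults are declared calibrations, not inferred biology: they were
chosen once so that the default cohort reproduces the qualitative
behaviours the archetypes are defined by - roughly 60-75% of cells
expressing at 0.2 M (`remodeling_rate = 0.12`/min against a ~10-min
activity window), transcript numbers in the range of strongly induced
stress genes (`induced_tx_rate = 25`/min, peak mRNA around 100 with a
5-min mRNA half-life), and onset of detectable expression near 10 min
post-stimulus.

## Reporter biochemistry

The reporter network per cell and locus is simulated exactly
(event-driven Gillespie algorithm, implemented in C++), with the
transcription rate piecewise constant on the frame grid:

* transcription creates a nascent transcript that dwells at the locus
  (`nascent_dwell`, 1.5 min) - this count drives the PP7
  transcription-site channel - then joins the cytoplasmic mRNA pool;
* mRNA decays first-order (`mrna_halflife`, 5 min);
* translation produces peptide at `translation_rate` per mRNA per min;
* peptide binds free FP irreversibly and instantaneously (SynZip
  heterodimers are strong and specific; no dissociation constant is
  modelled). If the FP pool is exhausted, peptide queues unbound - the
  saturation regime;
* the FP:peptide complex is imported into the nucleus at `import_rate`
  (3/min; sub-minute import) and leaks back at `leak_rate` (0.05/min);
* peptide degrades first-order everywhere (`peptide_halflife`: 2 min for
  the destabilized UbiY form, `Inf` for the stable form). Degradation of
  complexed peptide releases the FP back into the free pool, which is the
  mechanism by which the unstable reporter resets after a transient.

The constitutive FP pool (`fp_pool`, 600 copies) is held constant per
cell for the duration of a movie (no production or dilution over <= 2 h),
treating the constitutive moiety as a fixed resource whose level should
roughly match the induced peptide. The invariant `fp_free + complex_cyt +
complex_nuc = fp_pool` holds exactly at every sampled time and is
asserted in the tests.

Free FP carries a small passive nuclear enrichment at equilibrium
(`passive_nuc_bias`, default 1.03): resting cells show a slightly higher
nuclear than cytoplasmic FP concentration. This is what the osmotic
shrink amplifies at stimulus time, producing the well-known t = 0
enrichment artifact that the basal-correction rule is designed to remove.
The value is kept small so the artifact stays small relative to induced
outputs, as it is in real recordings.

Two derived readouts: the Venus channel reports only *matured*
fluorophore on the peptide-fused conventional FP (first-order maturation,
`maturation_halftime`, 18 min, integrated exactly on the frame grid and
degraded with its peptide), and the PP7 channel is proportional to the
nascent transcript count.

Extrinsic noise is injected as one lognormal factor per cell
(`extrinsic_cv`, 0.25) scaling `translation_rate` of *both* reporters of
a dual-reporter cell - shared expression capacity - while each locus
draws its own remodelling delay and its own reaction realization
(intrinsic noise). One integer seed per cohort generates all per-cell
substreams deterministically.

## Synthetic imaging

Cells are ellipses with interior nuclear ellipses, laid out without
overlap by rejection sampling. Per frame, both ellipses are scaled by
`sqrt(rel_area)` while molecule counts are untouched, so per-pixel
intensity rises when the cell shrinks and integrated fluorescence is
conserved - the shrink artifact arises geometrically, exactly as in a
microscope. Compartment intensity is `background + photon_gain *
molecules / compartment area`; Poisson shot noise, Gaussian read noise
and quantization to 16 bits follow. The nuclear-marker channel carries a
constant per-cell nuclear fluorophore plus a dim uniform whole-cell
component (`cell_body_level`) that serves as the cell-body proxy for
contour segmentation; emulating bright-field contour detection is out of
scope. Exposure-to-SNR mapping is not modelled; the synthetic SNR is set
by `photon_gain`, `background` and `read_noise_sd` and documented in the
configuration. The PP7 mode renders z-stacks (three planes by default)
with a Gaussian spot at a fixed intranuclear position per cell, amplitude
proportional to nascent transcripts, and computes per-frame
maximum-intensity projections.

## Segmentation, tracking, QC

Nuclei are segmented by thresholding the nuclear-marker channel: Otsu's
method per frame, floored at `background + 3 * read_noise_sd` so empty
frames yield nothing. Cell bodies are recovered by seeded geodesic
propagation (EBImage `propagate`) over the body-proxy foreground, whose
threshold is an Otsu computed on non-nuclear pixels (excluding the bright
nuclear mode keeps the threshold between background and the dim body
signal). The cytoplasm is the cell minus the nucleus dilated by 2 px
(disc structuring element). Tracking is greedy nearest-centroid matching
under a displacement bound; only cells tracked from the first to the last
frame are eligible for analysis. The quality-control filter keeps traces
whose nuclear area, cell area and nuclear-marker intensity each have a
coefficient of variation <= 0.15 over the movie; these limits are
config-exposed and were set once so that the default synthetic cohort
retains more than 65% of tracked cells, the retention regime typical of
such pipelines. Neither the tracking algorithm nor the QC cutoffs of the
original acquisition platforms are published; both are declared package
choices.

## Quantification conventions

* **Nuclear enrichment**: nuclear minus cytoplasmic mean, per frame.
* **Basal level**: mean of the first two frames at or after the stimulus.
  On a 2-min grid these are T = 0 and T = 2 min; the rule generalizes to
  the first two post-stimulus frames on any grid. Taking the baseline
  *after* the stimulus deliberately folds the shrink artifact into it.
* **Corrected enrichment**: centred 3-point moving average (window
  truncated at the trace ends, preserving the grid) minus basal.
* **Expression output**: maximum of the corrected trace (ties resolve to
  the earlier time wherever a time is reported).
* **Expression threshold**: the 99th-percentile order statistic of the
  expression outputs of a non-induced control population (>= 20 cells).
  The rule is a declared default - the original choice is unpublished -
  and is exposed in configuration and recorded in output metadata. A pure
  order statistic (no interpolation) is used so that the held-out
  exceedance rate has a known sampling distribution: for a rank-k
  threshold from n controls the expected rate is (n + 1 - k)/(n + 1),
  about 1.05% at n = 2000, with variance combining threshold-estimation
  and binomial sampling.
* **Timing**: time to threshold is the first frame whose corrected
  enrichment reaches the threshold; time to half-max is computed on the
  raw (non-smoothed) basal-subtracted trace.
* **Hog1 signalling output**: the nuclear/cytoplasmic ratio integrated
  (trapezoid) over the population activity window - the contiguous
  interval around the population peak where the mean ratio exceeds basal
  by more than 5% of the peak excess - after subtracting the basal ratio,
  clipped at zero. Baseline subtraction before integration is a package
  decision (the plain area under the curve is config-switchable); in
  double-step experiments windows and outputs are computed per step over
  `[step_i, step_{i+1})`.
* **Transcription-site intensity**: mean of the 20 brightest nuclear
  pixels minus the mean of all nuclear pixels, on the max projection;
  shift-invariant by construction.
* **Half-life from a chase**: after a translation arrest, ln(mean
  abundance) is fit by least squares against time; the half-life is ln 2
  over the decay rate. On the default simulated chase (500 cells, steady
  induction, arrest at 30 min) this recovers the generative 2-min
  half-life to within a few percent.

## Noise decomposition

For dual-reporter cohorts the corrected enrichment of each channel is
min-max normalized per replicate (the extremes of the whole replicate,
never pooled across replicates), and the classical dual-reporter moments
are computed with population (1/n) averages:

$$\eta^2_{int} = \frac{\langle (r-y)^2\rangle}{2\langle r\rangle\langle y\rangle},\qquad
\eta^2_{ext} = \frac{\langle r y\rangle-\langle r\rangle\langle y\rangle}{\langle r\rangle\langle y\rangle},\qquad
\eta^2_{tot} = \frac{\langle r^2+y^2\rangle/2-\langle r\rangle\langle y\rangle}{\langle r\rangle\langle y\rangle}.$$

The additivity identity holds exactly and is asserted to 1e-10;
components are cross-checked against an independent brute-force
evaluation of the raw moments. Whether the original analysis used 1/n or
1/(n-1) averages is not recoverable; the population form is adopted and
recorded in output metadata. On finite samples the extrinsic component
can be negative; it is reported unclipped, while the plotted intrinsic
fraction eta_int^2/eta_tot^2 is clipped to [0, 1]. Percentile bootstrap
over cells provides confidence bands.

The model-discrimination behaviour follows directly: with two
repressed-remodelling loci, early expression arises stochastically from
one locus or the other, so the intrinsic fraction rises early and falls
as both loci engage; two basal-active loci stay tightly correlated
throughout (per-time-point correlation above 0.8 around the expression
peak under the default extrinsic CV at the package's default molecule
numbers - at the rising edge, where counts are still low, molecular shot
noise pushes it slightly lower).

## What the generator does and does not emulate

Emulated: dose-dependent transient signalling; stochastic promoter
switching with re-repression between pulses; mRNA/peptide birth-death at
realistic copy numbers; FP-pool capture, saturation and recovery;
FP-maturation delay; the t = 0 shrink artifact; camera shot/read noise;
PP7 spot rendering across focal planes. Not emulated: cell growth and
division, lineages, photobleaching, focus drift, bright-field optics,
mechanistic osmo-adaptation, and the MAPK cascade itself. Passing tests
therefore validate the *analysis conventions* against data with the
assumed statistical structure; they do not certify performance on real
bright-field segmentation or on drifting acquisitions.

## Numerical choices and degenerate inputs

Stochastic kinetics are exact (no tau-leaping is needed at these problem
sizes); time-varying rates are handled by restarting the exponential
clock at frame boundaries, which is exact for piecewise-constant rates.
Problem sizes in the test-suite were chosen to make each check
statistically decisive at desk scale: 10^4 replicates for closed-form
comparisons (3 Monte-Carlo SEs), 500-800 cells for cohort-level
behaviours, 1000 random samples for identities. Hypo-osmotic steps are
rejected; zero cytoplasmic intensity yields a missing ratio; empty
cytoplasm after nucleus dilation flags the cell; all-missing traces
produce missing metrics, never zeros. Missing compartments propagate as
missing through every stage.

## Known limitations

The Hog1 model cannot express phenomena that depend on osmolyte dynamics
(e.g. pulse-frequency adaptation memory). Trace-level synthetic cohorts
carry no measurement noise unless `add_trace_noise()` is applied or the
imaging stage is used. The renderer's 2-D geometry makes nuclear volume
fraction and projected-area scaling approximations of 3-D reality.
Headline numbers measured on real cells (correlation coefficients between
reporter pairs, exact expressing fractions, absolute delays between
specific promoters) depend on unpublished rate constants and are treated
as qualitative behaviours, not targets.
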