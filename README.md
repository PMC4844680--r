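# dpstr

Simulation and quantification of **dynamic protein synthesis
translocation reporters** (dPSTR) in single-cell time-lapse microscopy.

A dPSTR reads out promoter activity without the fluorophore-maturation
delay that blinds conventional FP reporters to fast expression dynamics:
a constitutively expressed, already-mature fluorescent protein is pulled
into the nucleus by an inducibly expressed, short-lived NLS–SynZip
peptide. The **nuclear enrichment** of the FP — nuclear minus
cytoplasmic mean intensity — then tracks protein synthesis with
sub-minute resolution. Applied to osmostress signalling in budding
yeast, two promoter archetypes (a repressed, chromatin-remodelling
pSTL1-like promoter and a basally active pGPD1-like one) produce
strikingly different expression dynamics and noise.

`dpstr` provides, for users analysing such data and for method
validation:

* a **stochastic simulator** (exact Gillespie kinetics in C++) of
  transient Hog1-like signalling with dose-dependent adaptation and the
  osmotic-shrink artifact, stochastic promoter switching, mRNA/peptide
  birth–death, FP-pool capture and saturation, FP maturation delay, and
  PP7 nascent-transcription signals;
* a **synthetic movie renderer** producing multichannel 16-bit TIFF
  time-lapses with ground-truth masks (shot/read noise, shrink artifact,
  PP7 z-stacks with max projection);
* **segmentation, tracking and QC**: CFP-style nuclear thresholding,
  seeded cell-region growing, cytoplasm = cell minus 2-px-dilated
  nucleus, nearest-centroid tracking, CV-based trace filtering;
* **per-cell quantification**: basal correction (first two post-stimulus
  frames), 3-point smoothing, expression output, expression threshold
  from non-induced controls, time-to-threshold / time-to-half-max, Hog1
  signalling output (area under the curve), the 20-brightest-pixel
  transcription-site statistic, and exponential half-life fits to
  translation-arrest chases;
* the **Elowitz dual-reporter noise decomposition**, time-resolved:

  η²_int = ⟨(r−y)²⟩ / 2⟨r⟩⟨y⟩,  η²_ext = (⟨ry⟩−⟨r⟩⟨y⟩) / ⟨r⟩⟨y⟩,
  η²_tot = (⟨r²+y²⟩/2 − ⟨r⟩⟨y⟩) / ⟨r⟩⟨y⟩,

  with min–max normalization per replicate, bootstrap confidence bands
  and stacked-area plotting of the intrinsic fraction.

## Worked example

Simulate a 20-cell cohort under a 0.2 M NaCl step, render and analyse the
movie, and quantify expression:

```r
library(dpstr)

st <- stimulus_profile(0, 0.2, duration = 40, frame_interval = 2)
co <- simulate_cohort(cohort_config(stimulus = st), n_cells = 20, rng_seed = 7)
co
#> dPSTR cohort: 20 cells, 21 frames, dpstr_R reporter(s)

g  <- layout_cells(20, 256, rng_seed = 7)
mv <- render_movie(co, g, imaging_params(), rng_seed = 7)
fr <- segment_movie(mv)
tk <- track_cells(fr)
tr <- build_traces(fr, tk, mv$frame_times)
qc <- qc_filter(tr)          # 20 tracked, 20 QC-passed
m  <- expression_metrics(qc$traces, "dpstr_R", stimulus_time = 0)
head(m[, c("track_id", "basal", "expression_output", "time_to_half_max")], 5)
#>   track_id basal expression_output time_to_half_max
#> 1        1  0.53             23.11               12
#> 2        2  1.63             62.82               12
#> 3        3  3.45             28.51               16
#> 4        4  3.34             14.70               14
#> 5        5  6.42             20.52               12
```

`basal` is the enrichment baseline (mean of the frames at 0 and 2 min,
which absorbs the shrink artifact), `expression_output` the maximal
smoothed, basal-subtracted nuclear enrichment (a.u. — proportional to
the peak number of nuclear reporter complexes), and `time_to_half_max`
the minutes until half of that cell's own maximum, here 12–16 min after
the stress, as expected for a remodelling-gated stress promoter.

Estimating the destabilized peptide's half-life from a simulated
translation-arrest (cycloheximide) chase:

```r
ch <- simulate_chase_cohort(n_cells = 200, rng_seed = 7)
halflife_from_chase(ch$mean_abundance, ch$times, ch$arrest_time)
#> Exponential chase fit: half-life 2.02 min (rate 0.343 /min, R^2 1.000)
```

And the dual-reporter noise decomposition on its classic two-cell
worked example:

```r
noise_components(c(1, 0), c(0, 1))
#> eta_int_sq eta_ext_sq eta_tot_sq
#>          2         -1          1
```

A YAML-driven command-line front end covering the whole pipeline
(`simulate` → `render` → `segment` → `quantify` → `noise`) is installed
at `inst/cli/dpstr.R`:

```sh
Rscript inst/cli/dpstr.R all --config run.yaml --seed 17 --out results/
```

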