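# Shared fixtures built in code. Kept small so the default run stays fast;
# acceptance-scale cohorts live in test-acceptance.R.

single_step <- function(duration = 60, frame_interval = 2, conc = 0.2)
  stimulus_profile(0, conc, duration = duration,
                   frame_interval = frame_interval)

# a dual-reporter configuration with both loci driven by the same promoter
# archetype on orthogonal channels
dual_config <- function(mode, stimulus = single_step(), extrinsic_cv = 0.25,
                        ...) {
  pp <- promoter_params(mode = mode, ...)
  rp <- reporter_params()
  cohort_config(stimulus = stimulus,
                reporters = list(dpstr_R = list(promoter = pp, reporter = rp),
                                 dpstr_Y = list(promoter = pp, reporter = rp)),
                extrinsic_cv = extrinsic_cv)
}

# tidy ground-truth traces of a cohort in the trace-table contract
cohort_trace_table <- function(cohort) cohort_traces(cohort)

# brute-force Elowitz moments straight from their definitions, written
# independently of noise_components()
brute_noise <- function(r, y) {
  n <- length(r)
  mr <- sum(r) / n; my <- sum(y) / n
  int <- (sum((r - y)^2) / n) / (2 * mr * my)
  ext <- (sum(r * y) / n - mr * my) / (mr * my)
  tot <- (sum(r^2 + y^2) / (2 * n) - mr * my) / (mr * my)
  c(int, ext, tot)
}
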