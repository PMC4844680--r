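#' Parameters of the phenomenological Hog1 relocation model
#'
#' Hog1 nuclear accumulation after a hyper-osmotic step is described by a
#' double-exponential pulse: a fast rise (sub-2-frame) followed by relaxation
#' back to the basal nuclear/cytoplasmic ratio on the cell's adaptation
#' timescale. The relative cell area is the mirror image of that pulse: an
#' immediate shrink proportional to the concentration increment, recovering
#' on the same adaptation timescale. No osmolyte feedback is modelled; the
#' pulse shape itself is the model.
#'
#' @param basal_ratio resting Hog1 nuclear/cytoplasmic ratio.
#' @param peak_gain peak ratio increase per mol/L of NaCl increment.
#' @param adaptation_time minutes; relaxation time constant at the 0.2 M
#'   reference dose. The effective time constant scales with the post-step
#'   concentration (`conc / 0.2`); full recovery takes ~2.3 time
#'   constants, so 0.1-0.4 M steps recover in roughly 10-30 min at the
#'   default.
#' @param rise_time minutes; rise time constant of the pulse (fast).
#' @param shrink_fraction fractional cell-area loss per mol/L of increment.
#' @param cell_cv lognormal coefficient of variation of per-cell peak
#'   amplitude and adaptation time.
#' @return object of class `"signaling_params"`.
#' @export
signaling_params <- function(basal_ratio = 1.0, peak_gain = 3.0,
                             adaptation_time = 6.5, rise_time = 0.7,
                             shrink_fraction = 0.6, cell_cv = 0.15) {
  stopifnot(peak_gain > 0, adaptation_time > 0, rise_time > 0,
            shrink_fraction >= 0, shrink_fraction < 1, cell_cv >= 0)
  structure(list(basal_ratio = basal_ratio, peak_gain = peak_gain,
                 adaptation_time = adaptation_time, rise_time = rise_time,
                 shrink_fraction = shrink_fraction, cell_cv = cell_cv),
            class = "signaling_params")
}

# lognormal with mean 1 and coefficient of variation cv
rlnorm_cv <- function(n, cv) {
  if (cv <= 0) return(rep(1, n))
  s2 <- log(1 + cv^2)
  rlnorm(n, meanlog = -s2 / 2, sdlog = sqrt(s2))
}

#' Simulate Hog1 relocation and cell-area traces for a cohort
#'
#' Generates, for each virtual cell, the Hog1 nuclear/cytoplasmic ratio and
#' the relative projected cell area over the movie. Each step in the
#' stimulus adds one pulse; the ratio rises within two frames of the step
#' and decays back to basal with the cell's dose-dependent adaptation time,
#' while the relative area dips by `shrink_fraction * increment` and
#' recovers on the same timescale (the mirror-image behaviour of stressed
#' cells).
#'
#' @param stimulus a [stimulus_profile()].
#' @param params a [signaling_params()].
#' @param n_cells number of cells.
#' @param rng_seed integer seed fixing the per-cell parameter draws.
#' @return list with `times` (minutes), `hog1_ratio` and `rel_area`
#'   (`n_cells x n_times` matrices), and the per-cell amplitude and
#'   adaptation draws in `$cells`.
#' @export
simulate_signaling <- function(stimulus, params = signaling_params(),
                               n_cells = 1, rng_seed = 1) {
  stopifnot(inherits(stimulus, "stimulus_profile"), n_cells >= 1)
  set.seed(as.integer(rng_seed))
  times <- stimulus$times
  nt <- length(times)
  inc <- step_increments(stimulus)
  amp_f <- rlnorm_cv(n_cells, params$cell_cv)
  tau_f <- rlnorm_cv(n_cells, params$cell_cv)
  ratio <- matrix(params$basal_ratio, n_cells, nt)
  area <- matrix(1, n_cells, nt)
  for (j in seq_along(stimulus$step_times)) {
    t0 <- stimulus$step_times[j]
    conc <- stimulus$step_concentrations[j]
    dt <- pmax(times - t0, 0)
    on <- times >= t0
    for (i in seq_len(n_cells)) {
      tau <- params$adaptation_time * (conc / 0.2) * tau_f[i]
      tr <- params$rise_time
      # double-exponential pulse normalized to unit peak
      tp <- tau * tr / (tau - tr) * log(tau / tr)
      norm <- exp(-tp / tau) - exp(-tp / tr)
      pulse <- (exp(-dt / tau) - exp(-dt / tr)) / norm * on
      a_ratio <- params$peak_gain * inc[j] * amp_f[i]
      ratio[i, ] <- ratio[i, ] + a_ratio * pulse
      # shrink is immediate at the step, recovery on the adaptation timescale
      a_area <- min(params$shrink_fraction * inc[j] * amp_f[i], 0.9)
      area[i, ] <- area[i, ] * (1 - a_area * exp(-dt / tau) * on)
    }
  }
  list(times = times, hog1_ratio = ratio, rel_area = area,
       cells = data.frame(amp_factor = amp_f, tau_factor = tau_f),
       basal_ratio = params$basal_ratio,
       activity_scale = params$peak_gain * 0.2)
}

# dimensionless signalling activity: basal-subtracted ratio normalized so a
# 0.2 M step peaks near 1 in the average cell
signaling_activity <- function(sig) {
  (sig$hog1_ratio - sig$basal_ratio) / sig$activity_scale
}
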