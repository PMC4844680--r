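#' Configuration of a virtual-cell cohort
#'
#' Bundles a stimulus, the signalling model, and one or two reporters (each
#' a promoter + reporter-parameter pair bound to a fluorescence channel)
#' into one simulation configuration. Dual-reporter cells share the same
#' Hog1 activity trace and the same per-cell translation-capacity scaling
#' factor (the extrinsic-noise component, a lognormal with CV
#' `extrinsic_cv` applied to `translation_rate` of both reporters) while
#' each locus draws its own chromatin-remodelling delay (the
#' intrinsic-noise component).
#'
#' @param stimulus a [stimulus_profile()].
#' @param signaling a [signaling_params()].
#' @param reporters named list of reporter definitions; each element is a
#'   list with components `promoter` ([promoter_params()]) and `reporter`
#'   ([reporter_params()]). Names become channel names (e.g. `dpstr_R`,
#'   `dpstr_Y`).
#' @param extrinsic_cv lognormal CV of the shared per-cell translation
#'   capacity.
#' @return object of class `"cohort_config"`.
#' @export
cohort_config <- function(stimulus = stimulus_profile(0, 0.2),
                          signaling = signaling_params(),
                          reporters = list(dpstr_R = list(
                            promoter = promoter_params(),
                            reporter = reporter_params())),
                          extrinsic_cv = 0.25) {
  stopifnot(inherits(stimulus, "stimulus_profile"),
            inherits(signaling, "signaling_params"),
            length(reporters) >= 1, !is.null(names(reporters)),
            extrinsic_cv >= 0)
  for (r in reporters)
    stopifnot(inherits(r$promoter, "promoter_params"),
              inherits(r$reporter, "reporter_params"))
  structure(list(stimulus = stimulus, signaling = signaling,
                 reporters = reporters, extrinsic_cv = extrinsic_cv),
            class = "cohort_config")
}

#' Simulate a cohort of virtual cells
#'
#' Runs signalling, promoter switching and reporter kinetics for `n_cells`
#' independent cells and assembles both the mechanistic species traces and
#' the ground-truth cell traces (apparent compartment intensities including
#' the osmotic shrink artifact, before any imaging noise).
#'
#' @param config a [cohort_config()].
#' @param n_cells number of cells (> 0).
#' @param rng_seed integer cohort seed; per-cell substreams are derived
#'   deterministically from it.
#' @return object of class `"dpstr_cohort"`: list with `times`, `config`,
#'   `signaling` (output of [simulate_signaling()]), `cells` (per cell: a
#'   list of `species` traces and promoter results per channel, the
#'   extrinsic factor), and `traces`, a tidy ground-truth `data.frame` with
#'   columns `cell`, `time`, `channel`, `nuc_mean`, `cyt_mean`, `rel_area`
#'   plus a `hog1` channel (ratio encoded as nuc/cyt with cyt = 100).
#' @export
simulate_cohort <- function(config, n_cells, rng_seed = 1) {
  stopifnot(inherits(config, "cohort_config"))
  if (!is.numeric(n_cells) || n_cells <= 0) stop("n_cells must be > 0")
  n_cells <- as.integer(n_cells)
  seeds <- derive_seeds(rng_seed, 3L + 2L * n_cells * length(config$reporters))
  sig <- simulate_signaling(config$stimulus, config$signaling, n_cells,
                            rng_seed = seeds[1])
  set.seed(seeds[2])
  ext <- rlnorm_cv(n_cells, config$extrinsic_cv)
  act <- signaling_activity(sig)
  times <- sig$times
  chans <- names(config$reporters)
  cells <- vector("list", n_cells)
  rows <- vector("list", n_cells)
  sidx <- 3L
  for (i in seq_len(n_cells)) {
    cell <- list(extrinsic = ext[i],
                 hog1_ratio = sig$hog1_ratio[i, ],
                 rel_area = sig$rel_area[i, ],
                 species = list(), promoter = list(), readouts = list())
    tr <- list()
    for (ch in chans) {
      rp <- config$reporters[[ch]]
      sidx <- sidx + 1L
      prom <- simulate_promoter(act[i, ], times, rp$promoter,
                                rng_seed = seeds[sidx])
      pars <- rp$reporter
      pars$translation_rate <- pars$translation_rate * ext[i]
      sidx <- sidx + 1L
      sp <- simulate_reporter_species(prom$tx_rate, times, pars,
                                      rng_seed = seeds[sidx])
      ro <- fluorescent_readouts(sp, pars)
      cell$promoter[[ch]] <- prom
      cell$species[[ch]] <- sp
      cell$readouts[[ch]] <- ro
      shrink <- 1 / cell$rel_area  # projected-density amplification
      tr[[ch]] <- data.frame(cell = i, time = times, channel = ch,
                             nuc_mean = ro$dpstr_nuc * shrink,
                             cyt_mean = ro$dpstr_cyt * shrink,
                             rel_area = cell$rel_area)
    }
    tr$hog1 <- data.frame(cell = i, time = times, channel = "hog1",
                          nuc_mean = 100 * cell$hog1_ratio,
                          cyt_mean = 100,
                          rel_area = cell$rel_area)
    cells[[i]] <- cell
    rows[[i]] <- do.call(rbind, tr)
  }
  traces <- do.call(rbind, rows)
  rownames(traces) <- NULL
  structure(list(times = times, config = config, signaling = sig,
                 cells = cells, traces = traces, n_cells = n_cells,
                 seed = rng_seed),
            class = "dpstr_cohort")
}

#' @export
print.dpstr_cohort <- function(x, ...) {
  cat("dPSTR cohort:", x$n_cells, "cells,",
      length(x$times), "frames,",
      paste(names(x$config$reporters), collapse = "+"),
      "reporter(s)\n")
  invisible(x)
}

#' Tidy ground-truth traces in the pipeline trace-table contract
#'
#' @param cohort a `dpstr_cohort`.
#' @return data.frame with `track_id`, `time_min`, `channel`, `nuc_mean`,
#'   `cyt_mean`, `nuc_area_px`, `cell_area_px` (areas `NA`: no imaging).
#' @export
cohort_traces <- function(cohort) {
  stopifnot(inherits(cohort, "dpstr_cohort"))
  tr <- cohort$traces
  data.frame(track_id = tr$cell, time_min = tr$time, channel = tr$channel,
             nuc_mean = tr$nuc_mean, cyt_mean = tr$cyt_mean,
             nuc_area_px = NA_real_, cell_area_px = NA_real_)
}

#' Add compartment-mean measurement noise to a trace table
#'
#' Emulates the residual error of compartment-mean intensity measurements
#' (shot/read noise averaged over the compartment pixels) as independent
#' Gaussian perturbations of `nuc_mean` and `cyt_mean`.
#'
#' @param traces tidy trace table.
#' @param sd noise SD in intensity units.
#' @param rng_seed integer seed.
#' @return the perturbed trace table.
#' @export
add_trace_noise <- function(traces, sd = 3, rng_seed = 1) {
  set.seed(as.integer(rng_seed))
  traces$nuc_mean <- traces$nuc_mean + rnorm(nrow(traces), 0, sd)
  traces$cyt_mean <- traces$cyt_mean + rnorm(nrow(traces), 0, sd)
  traces
}

#' Ground-truth nuclear peptide maximum per cell and channel
#'
#' Convenience accessor used to validate the quantification pipeline:
#' maximum over time of the nuclear complex count for each cell/channel.
#'
#' @param cohort a `dpstr_cohort`.
#' @return data.frame with `cell`, `channel`, `max_complex_nuc`.
#' @export
ground_truth_expression <- function(cohort) {
  stopifnot(inherits(cohort, "dpstr_cohort"))
  out <- list()
  for (i in seq_len(cohort$n_cells)) {
    for (ch in names(cohort$cells[[i]]$species)) {
      out[[length(out) + 1L]] <- data.frame(
        cell = i, channel = ch,
        max_complex_nuc = max(cohort$cells[[i]]$species[[ch]]$complex_nuc))
    }
  }
  do.call(rbind, out)
}
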