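#' Reporter biochemistry parameters
#'
#' Kinetic constants of one dPSTR reporter: the inducible NLS-SynZip
#' peptide, its mRNA, and the constitutive fluorescent-protein (FP) pool it
#' captures. The peptide binds a free FP irreversibly and instantaneously
#' (SynZip heterodimers are treated as infinitely strong); the complex is
#' imported into the nucleus with a fast rate and leaks back slowly.
#' Degradation of the destabilized peptide acts on free and complexed
#' peptide alike and releases the FP back into the free pool, which is how
#' the reporter recovers its uniform distribution after a transient.
#'
#' @param mrna_halflife minutes.
#' @param translation_rate peptides per mRNA per minute.
#' @param peptide_halflife minutes; 2 for the destabilized (UbiY) reporter,
#'   `Inf` for the stable variant.
#' @param fp_pool constitutive FP copies per cell (held constant during the
#'   movie).
#' @param import_rate 1/min nuclear import of the complex (sub-minute
#'   timescale: default 3/min).
#' @param leak_rate 1/min nuclear leak/export of the complex.
#' @param nuclear_volume_fraction fraction of cell volume occupied by the
#'   nucleus.
#' @param maturation_halftime minutes; fluorophore maturation half-time of
#'   the conventional-FP (Venus) readout channel.
#' @param nascent_dwell minutes a nascent transcript dwells at the locus
#'   before release (sets the PP7 transcription-site signal).
#' @param passive_nuc_bias mild passive nuclear enrichment of the free FP
#'   at equilibrium (nuclear/cytoplasmic concentration ratio of unbound
#'   FP). Values slightly above 1 reproduce the small positive nuclear
#'   enrichment of resting cells that the osmotic-shrink artifact
#'   amplifies at stimulus time.
#' @return object of class `"reporter_params"`.
#' @export
reporter_params <- function(mrna_halflife = 5, translation_rate = 0.8,
                            peptide_halflife = 2, fp_pool = 600,
                            import_rate = 3, leak_rate = 0.05,
                            nuclear_volume_fraction = 0.12,
                            maturation_halftime = 18,
                            nascent_dwell = 1.5,
                            passive_nuc_bias = 1.03) {
  stopifnot(mrna_halflife > 0, translation_rate >= 0, peptide_halflife > 0,
            fp_pool > 0, import_rate > 0, leak_rate >= 0,
            nuclear_volume_fraction > 0, nuclear_volume_fraction < 1,
            maturation_halftime >= 0, nascent_dwell > 0,
            passive_nuc_bias >= 1)
  structure(list(mrna_halflife = mrna_halflife,
                 translation_rate = translation_rate,
                 peptide_halflife = peptide_halflife, fp_pool = fp_pool,
                 import_rate = import_rate, leak_rate = leak_rate,
                 nuclear_volume_fraction = nuclear_volume_fraction,
                 maturation_halftime = maturation_halftime,
                 nascent_dwell = nascent_dwell,
                 passive_nuc_bias = passive_nuc_bias),
            class = "reporter_params")
}

#' Simulate reporter species for one cell (exact stochastic simulation)
#'
#' Runs an event-driven (Gillespie) simulation of the reporter reaction
#' network driven by a transcription-rate trace that is piecewise constant
#' on the frame grid: mRNA birth-death, translation, first-order peptide
#' degradation (releasing complexed FP), irreversible FP binding, and
#' nucleocytoplasmic shuttling of the complex. The FP pool is conserved
#' exactly: `fp_free + complex_cyt + complex_nuc = fp_pool` at every frame.
#'
#' @param tx_rate transcription-rate trace, mRNA/min, one value per frame
#'   (the rate over the interval starting at that frame).
#' @param times frame times in minutes.
#' @param params a [reporter_params()].
#' @param rng_seed integer seed.
#' @return a `data.frame` of class `"species_trace"` with columns `time`,
#'   `nascent_mrna`, `mrna`, `free_peptide`, `fp_free`, `complex_cyt`,
#'   `complex_nuc`.
#' @export
simulate_reporter_species <- function(tx_rate, times, params = reporter_params(),
                                      rng_seed = 1) {
  stopifnot(inherits(params, "reporter_params"),
            length(tx_rate) == length(times), length(times) >= 2)
  if (any(!is.finite(tx_rate))) stop("non-finite transcription rate")
  set.seed(as.integer(rng_seed))
  d_p <- if (is.finite(params$peptide_halflife)) log(2) / params$peptide_halflife else 0
  out <- .ssa_reporter(as.numeric(times), as.numeric(tx_rate),
                       1 / params$nascent_dwell,
                       log(2) / params$mrna_halflife,
                       params$translation_rate, d_p,
                       as.integer(params$fp_pool),
                       params$import_rate, params$leak_rate)
  res <- data.frame(time = times, out)
  class(res) <- c("species_trace", "data.frame")
  res
}

#' Fluorescence readouts from a species trace
#'
#' Maps molecule counts to compartment fluorescence. dPSTR compartment
#' signals are concentrations: molecules per compartment divided by the
#' compartment volume fraction, with the free FP distributed evenly between
#' compartments (equal concentration) and the complex counted where it
#' resides. The Venus channel reports only matured fluorophore on the
#' peptide (first-order maturation with half-time `maturation_halftime`,
#' applied to the total peptide-fused Venus population and degraded with
#' it). The PP7 channel is proportional to the nascent transcript count at
#' the locus.
#'
#' @param species a `species_trace` from [simulate_reporter_species()].
#' @param params the matching [reporter_params()].
#' @return `data.frame` with `time`, `dpstr_nuc`, `dpstr_cyt` (a.u.
#'   concentration units), `venus_total` (matured molecules) and
#'   `pp7_nascent` (molecules).
#' @export
fluorescent_readouts <- function(species, params) {
  stopifnot(inherits(species, "species_trace"))
  nvf <- params$nuclear_volume_fraction
  b <- params$passive_nuc_bias
  # free FP at passive equilibrium: nuclear concentration b times the
  # cytoplasmic one, total free count conserved
  f_cyt <- species$fp_free / (1 - nvf + b * nvf)
  dpstr_nuc <- b * f_cyt + species$complex_nuc / nvf
  dpstr_cyt <- f_cyt + species$complex_cyt / (1 - nvf)
  # venus maturation: dM/dt = km * (tot - M) - d_p * M, on the frame grid
  tot <- species$free_peptide + species$complex_cyt + species$complex_nuc
  d_p <- if (is.finite(params$peptide_halflife)) log(2) / params$peptide_halflife else 0
  if (params$maturation_halftime <= 0) {
    mat <- tot
  } else {
    km <- log(2) / params$maturation_halftime
    mat <- numeric(length(tot))
    for (k in 2:length(tot)) {
      dt <- species$time[k] - species$time[k - 1]
      # exact step for linear ODE with source km*tot (tot held at interval start)
      a <- km + d_p
      mat[k] <- mat[k - 1] * exp(-a * dt) + km * tot[k - 1] / a * (1 - exp(-a * dt))
      mat[k] <- min(mat[k], tot[k])
    }
  }
  data.frame(time = species$time, dpstr_nuc = dpstr_nuc,
             dpstr_cyt = dpstr_cyt, venus_total = mat,
             pp7_nascent = species$nascent_mrna)
}
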