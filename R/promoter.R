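#' Promoter kinetic parameters
#'
#' Two archetypes of stress-responsive promoters are modelled. A
#' `repressed_remodeling` promoter (pSTL1-like) is silent at rest; when
#' signalling activity exceeds `activity_threshold` the locus switches ON
#' after a stochastic chromatin-remodelling delay that is exponentially
#' distributed with rate `remodeling_rate`, and it switches OFF again (and
#' must re-remodel) once activity falls back below threshold. A
#' `basal_active` promoter (pGPD1-like) transcribes at `basal_tx_rate` at
#' rest and responds to activity immediately, with no stochastic delay.
#'
#' @param mode `"repressed_remodeling"` or `"basal_active"`.
#' @param remodeling_rate 1/min; OFF->ON switching hazard while activity is
#'   above threshold (repressed_remodeling only).
#' @param basal_tx_rate mRNA/min basal transcription (basal_active only;
#'   forced to 0 for repressed_remodeling).
#' @param induced_tx_rate mRNA/min at full (unit) activity.
#' @param activity_threshold dimensionless activity above which the
#'   promoter can engage.
#' @return object of class `"promoter_params"`.
#' @export
promoter_params <- function(mode = c("repressed_remodeling", "basal_active"),
                            remodeling_rate = 0.12,
                            basal_tx_rate = 1,
                            induced_tx_rate = 25,
                            activity_threshold = 0.2) {
  mode <- match.arg(mode)
  stopifnot(remodeling_rate >= 0, basal_tx_rate >= 0,
            induced_tx_rate >= 0, activity_threshold >= 0)
  if (mode == "repressed_remodeling") basal_tx_rate <- 0
  structure(list(mode = mode, remodeling_rate = remodeling_rate,
                 basal_tx_rate = basal_tx_rate,
                 induced_tx_rate = induced_tx_rate,
                 activity_threshold = activity_threshold),
            class = "promoter_params")
}

#' Simulate promoter state and transcription rate for one cell
#'
#' Converts a signalling-activity trace into a locus ON/OFF trace and a
#' piecewise-constant transcription-rate trace on the same grid.
#'
#' For `repressed_remodeling`, the OFF->ON waiting time while activity
#' exceeds the threshold is exponential with rate `remodeling_rate`
#' (memoryless across frames); when ON, the transcription rate is
#' `induced_tx_rate * min(max(activity, 0), 1)`. The locus returns OFF when
#' activity drops below threshold, so a second stress pulse requires a fresh
#' remodelling delay. For `basal_active`, the locus is always competent and
#' the rate is `basal_tx_rate + induced_tx_rate * min(max(activity - threshold, 0), 1)`
#' with no stochastic delay.
#'
#' @param activity numeric activity trace (dimensionless, ~1 at a 0.2 M
#'   peak), aligned to the simulation grid.
#' @param times minutes, same length as `activity`.
#' @param params a [promoter_params()].
#' @param rng_seed integer seed (used only by repressed_remodeling).
#' @return list with `locus_on` (logical) and `tx_rate` (mRNA/min) traces,
#'   plus `on_time` (first switch-on time, `NA` if never).
#' @export
simulate_promoter <- function(activity, times, params, rng_seed = 1) {
  stopifnot(inherits(params, "promoter_params"),
            length(activity) == length(times))
  if (any(!is.finite(activity))) stop("activity trace must be finite")
  if (any(activity < -1e-9)) stop("negative signalling activity")
  activity <- pmax(activity, 0)
  nt <- length(times)
  if (nt < 2) stop("activity trace must span at least two frames")
  dt <- diff(times)
  drive <- pmin(pmax(activity - params$activity_threshold, 0) /
                  max(1 - params$activity_threshold, .Machine$double.eps), 1)
  if (params$mode == "basal_active") {
    tx <- params$basal_tx_rate + params$induced_tx_rate * drive
    return(list(locus_on = rep(TRUE, nt), tx_rate = tx,
                on_time = times[1]))
  }
  set.seed(as.integer(rng_seed))
  above <- activity > params$activity_threshold
  on <- logical(nt)
  state <- FALSE
  on_time <- NA_real_
  # exponential waiting time accrued only while activity is above threshold
  budget <- stats::rexp(1, 1)  # unit-rate exponential, spent as rate*dt
  for (k in seq_len(nt)) {
    if (!state && above[k]) {
      spend <- params$remodeling_rate * (if (k < nt) dt[k] else dt[length(dt)])
      if (budget <= spend) {
        state <- TRUE
        if (is.na(on_time) && params$remodeling_rate > 0)
          on_time <- times[k] + budget / params$remodeling_rate
      }
      budget <- budget - spend
    } else if (state && !above[k]) {
      state <- FALSE
      budget <- stats::rexp(1, 1)
    }
    on[k] <- state
  }
  tx <- ifelse(on, params$induced_tx_rate * drive, 0)
  list(locus_on = on, tx_rate = tx, on_time = on_time)
}
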