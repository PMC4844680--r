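#' Nuclear enrichment of a channel
#'
#' The per-frame difference between mean nuclear and mean cytoplasmic
#' fluorescence, the primary dPSTR readout. Missing compartment values
#' propagate as `NA` at that frame only.
#'
#' @param nuc_mean,cyt_mean numeric vectors over time.
#' @return numeric vector `nuc_mean - cyt_mean`.
#' @export
nuclear_enrichment <- function(nuc_mean, cyt_mean) {
  stopifnot(length(nuc_mean) == length(cyt_mean))
  nuc_mean - cyt_mean
}

#' Basal level of an enrichment trace
#'
#' Mean of the enrichment at the first two frames at or after the stimulus
#' (the "T = 0 and T = 2 min" rule of 2-min movies, generalized to any
#' frame grid). Taking the basal level *after* stimulus deliberately folds
#' the osmotic-shrink artifact into the baseline so it is subtracted out.
#'
#' @param enrichment numeric vector.
#' @param times minutes, same length.
#' @param stimulus_time minutes.
#' @return scalar basal level.
#' @export
basal_level <- function(enrichment, times, stimulus_time = 0) {
  stopifnot(length(enrichment) == length(times))
  idx <- which(times >= stimulus_time)
  if (length(idx) < 2) stop("need at least two frames at/after the stimulus")
  mean(enrichment[idx[1:2]])
}

#' Three-point moving average
#'
#' Centred window of three frames; at the trace ends the average is taken
#' over the available neighbours (window truncation), so the time grid is
#' preserved. `NA` values are skipped within the window.
#'
#' @param x numeric vector of length >= 3.
#' @return smoothed vector, same length.
#' @export
moving_average3 <- function(x) {
  n <- length(x)
  if (n < 3) stop("trace must have at least 3 frames")
  out <- numeric(n)
  for (k in seq_len(n)) {
    w <- max(1, k - 1):min(n, k + 1)
    v <- x[w]
    out[k] <- if (all(is.na(v))) NA_real_ else mean(v, na.rm = TRUE)
  }
  out
}

#' Corrected nuclear enrichment
#'
#' The single-cell trace smoothed by a three-point moving average, minus
#' its basal level.
#'
#' @param enrichment raw enrichment trace (length >= 3).
#' @param basal scalar from [basal_level()].
#' @return corrected trace.
#' @export
corrected_enrichment <- function(enrichment, basal) {
  moving_average3(enrichment) - basal
}

#' Expression output: maximal corrected nuclear enrichment
#'
#' @param corrected corrected enrichment trace.
#' @return scalar maximum (NA if the trace is all-missing).
#' @export
expression_output <- function(corrected) {
  if (all(is.na(corrected))) return(NA_real_)
  max(corrected, na.rm = TRUE)
}

#' Expression threshold from a non-induced control population
#'
#' Default rule: the 99th percentile of the expression outputs of the
#' non-induced cells, so ~1% of controls classify as expressing. The rule
#' (quantile level) is exposed; record it with the results.
#'
#' @param control_outputs expression outputs of >= 20 control cells.
#' @param probs quantile level of the rule.
#' @return scalar threshold.
#' @export
expression_threshold <- function(control_outputs, probs = 0.99) {
  control_outputs <- control_outputs[!is.na(control_outputs)]
  if (length(control_outputs) < 20)
    stop("need at least 20 control cells to set a threshold")
  # pure order statistic (no interpolation): the held-out exceedance rate
  # of x_(ceil(q*n)) has a known negative-hypergeometric null
  unname(quantile(control_outputs, probs = probs, type = 1))
}

#' First time the corrected enrichment reaches the expression threshold
#'
#' @param corrected corrected trace.
#' @param times minutes.
#' @param threshold expression threshold.
#' @return minutes, or `NA` if the trace never reaches it.
#' @export
time_to_threshold <- function(corrected, times, threshold) {
  stopifnot(is.finite(threshold))
  idx <- which(corrected >= threshold)
  if (!length(idx)) return(NA_real_)
  times[idx[1]]
}

#' First time the raw enrichment reaches half of its own maximum
#'
#' Computed on the non-smoothed, basal-subtracted trace; ties and plateaus
#' resolve to the earliest time.
#'
#' @param enrichment raw enrichment trace.
#' @param times minutes.
#' @param basal basal level subtracted before halving.
#' @return minutes, or `NA` when the basal-subtracted maximum is not
#'   positive.
#' @export
time_to_half_max <- function(enrichment, times, basal = 0) {
  x <- enrichment - basal
  if (all(is.na(x))) return(NA_real_)
  m <- max(x, na.rm = TRUE)
  if (m <= 0) return(NA_real_)
  idx <- which(x >= m / 2)
  times[idx[1]]
}

#' Hog1 signalling metrics for one cell
#'
#' The Hog1 readout is the nuclear/cytoplasmic intensity ratio. The
#' activity window is determined on the *population mean* ratio: the
#' maximal contiguous interval (containing the population peak) where the
#' mean ratio exceeds basal + `delta_frac` of the peak excess. The
#' signalling output is the trapezoidal integral of the cell's
#' basal-subtracted ratio over that window, clipped at 0.
#'
#' @param nuc_mean,cyt_mean the cell's Hog1-channel compartment means.
#' @param times minutes.
#' @param population_ratio mean ratio trace of the population (same grid).
#' @param delta_frac window threshold as a fraction of the population peak
#'   excess over basal.
#' @param window optional `(start, end)` minutes overriding the automatic
#'   window (used for per-step windows in double-step experiments).
#' @return list with `ratio` trace, `activity_window` and
#'   `signaling_output`.
#' @export
hog1_metrics <- function(nuc_mean, cyt_mean, times, population_ratio,
                         delta_frac = 0.05, window = NULL) {
  ratio <- ifelse(cyt_mean == 0, NA_real_, nuc_mean / cyt_mean)
  if (is.null(window)) {
    window <- hog1_activity_window(population_ratio, times, delta_frac)
  }
  inw <- times >= window[1] & times <= window[2]
  basal <- basal_ratio_of(population_ratio, times, window)
  x <- ratio[inw] - basal
  t_w <- times[inw]
  ok <- !is.na(x)
  out <- if (sum(ok) >= 2) max(trapz(t_w[ok], x[ok]), 0) else NA_real_
  list(ratio = ratio, activity_window = window, signaling_output = out,
       basal_ratio = basal)
}

# activity window on the population mean ratio: contiguous run around the
# peak where the excess over basal exceeds delta_frac of the peak excess
hog1_activity_window <- function(population_ratio, times,
                                 delta_frac = 0.05) {
  basal <- min(population_ratio, na.rm = TRUE)
  excess <- population_ratio - basal
  pk <- which.max(excess)
  th <- delta_frac * excess[pk]
  lo <- pk; while (lo > 1 && excess[lo - 1] > th) lo <- lo - 1
  hi <- pk; while (hi < length(excess) && excess[hi + 1] > th) hi <- hi + 1
  c(times[lo], times[hi])
}

basal_ratio_of <- function(population_ratio, times, window) {
  pre <- population_ratio[times < window[1]]
  if (length(pre)) mean(pre, na.rm = TRUE) else
    min(population_ratio, na.rm = TRUE)
}

trapz <- function(x, y) sum(diff(x) * (head(y, -1) + tail(y, -1)) / 2)

#' Transcription-site intensity from nuclear pixel values
#'
#' The mean of the 20 brightest nuclear pixels minus the mean of all
#' nuclear pixels; shift-invariant, zero for a uniform nucleus.
#'
#' @param pixels numeric vector of >= 20 nuclear pixel values.
#' @param n_brightest number of brightest pixels (default 20).
#' @return scalar intensity, a.u.
#' @export
pp7_site_intensity <- function(pixels, n_brightest = 20) {
  if (length(pixels) < n_brightest)
    stop("need at least ", n_brightest, " nuclear pixels")
  s <- sort(pixels, decreasing = TRUE)
  mean(s[seq_len(n_brightest)]) - mean(pixels)
}

#' Delay between two reporters in the same cell
#'
#' Difference in time to overcome the expression threshold,
#' `time_to_threshold(B) - time_to_threshold(A)`; positive when reporter A
#' precedes reporter B. `NA` unless both reporters classify as expressing.
#'
#' @param tt_a,tt_b threshold-crossing times (minutes) of reporters A and
#'   B.
#' @param expressing_a,expressing_b logical expression classifications.
#' @return minutes or `NA`.
#' @export
promoter_delay <- function(tt_a, tt_b, expressing_a = !is.na(tt_a),
                           expressing_b = !is.na(tt_b)) {
  if (!isTRUE(expressing_a) || !isTRUE(expressing_b) ||
      is.na(tt_a) || is.na(tt_b)) return(NA_real_)
  tt_b - tt_a
}

#' Per-cell expression metrics for one channel of a trace table
#'
#' Applies the full quantification chain (enrichment, basal level,
#' smoothing, correction, output, timings) to every track of a tidy trace
#' table.
#'
#' @param traces trace table (`track_id`, `time_min`, `channel`,
#'   `nuc_mean`, `cyt_mean`, ...).
#' @param channel channel to quantify.
#' @param stimulus_time minutes.
#' @param threshold optional expression threshold; when supplied,
#'   `time_to_threshold` and `expressing` are filled in.
#' @return data.frame, one row per track: `track_id`, `basal`,
#'   `expression_output`, `time_to_threshold`, `time_to_half_max`,
#'   `expressing`.
#' @export
expression_metrics <- function(traces, channel, stimulus_time = 0,
                               threshold = NULL) {
  need <- c("track_id", "time_min", "channel", "nuc_mean", "cyt_mean")
  miss <- setdiff(need, names(traces))
  if (length(miss)) stop("trace table lacks column(s): ",
                         paste(miss, collapse = ", "))
  tr <- traces[traces$channel == channel, ]
  ids <- unique(tr$track_id)
  out <- lapply(ids, function(id) {
    one <- tr[tr$track_id == id, ]
    one <- one[order(one$time_min), ]
    enr <- nuclear_enrichment(one$nuc_mean, one$cyt_mean)
    bas <- basal_level(enr, one$time_min, stimulus_time)
    cor <- corrected_enrichment(enr, bas)
    eo <- expression_output(cor)
    tt <- if (!is.null(threshold))
      time_to_threshold(cor, one$time_min, threshold) else NA_real_
    th <- time_to_half_max(enr, one$time_min, bas)
    data.frame(track_id = id, basal = bas, expression_output = eo,
               time_to_threshold = tt, time_to_half_max = th,
               expressing = if (!is.null(threshold)) isTRUE(eo >= threshold)
               else NA)
  })
  res <- do.call(rbind, out)
  rownames(res) <- NULL
  res
}
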