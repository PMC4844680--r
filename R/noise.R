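#' Min-max normalization of dual-reporter channels
#'
#' Each channel is scaled as `(x - min) / (max - min)` with the minimum and
#' maximum taken over all cells and all times of the replicate, so
#' normalized values span [0, 1] and affine channel transformations cancel.
#' Normalization is per replicate, never pooled across replicates.
#'
#' @param r,y numeric matrices (cells x times) of corrected nuclear
#'   enrichment for the two channels.
#' @return list of matrices `r`, `y` normalized to [0, 1].
#' @export
normalize_channels <- function(r, y) {
  stopifnot(is.matrix(r), is.matrix(y), all(dim(r) == dim(y)))
  nz <- function(x) {
    lo <- min(x, na.rm = TRUE); hi <- max(x, na.rm = TRUE)
    if (hi <= lo) stop("degenerate replicate: channel has zero range")
    (x - lo) / (hi - lo)
  }
  list(r = nz(r), y = nz(y))
}

#' Dual-reporter noise components at one time point
#'
#' The Elowitz-style intrinsic/extrinsic/total decomposition from paired
#' reporter measurements, using population (1/n) averages:
#' \deqn{\eta^2_{int} = \frac{\langle (r-y)^2 \rangle}{2\langle r\rangle\langle y\rangle},\quad
#'       \eta^2_{ext} = \frac{\langle ry\rangle - \langle r\rangle\langle y\rangle}{\langle r\rangle\langle y\rangle},\quad
#'       \eta^2_{tot} = \frac{\langle r^2+y^2\rangle/2 - \langle r\rangle\langle y\rangle}{\langle r\rangle\langle y\rangle}}
#' The identity \eqn{\eta^2_{int} + \eta^2_{ext} = \eta^2_{tot}} holds
#' exactly. \eqn{\eta^2_{ext}} can be negative on finite samples and is
#' reported unclipped.
#'
#' @param r,y numeric vectors, one value per cell (normalized nuclear
#'   accumulation in the red and yellow channels).
#' @return named numeric `c(eta_int_sq, eta_ext_sq, eta_tot_sq)`, `NA`s
#'   when either channel mean is zero.
#' @export
noise_components <- function(r, y) {
  stopifnot(length(r) == length(y))
  ok <- !is.na(r) & !is.na(y)
  r <- r[ok]; y <- y[ok]
  if (length(r) < 2) stop("need at least 2 cells")
  mr <- mean(r); my <- mean(y)
  if (mr == 0 || my == 0)
    return(c(eta_int_sq = NA_real_, eta_ext_sq = NA_real_,
             eta_tot_sq = NA_real_))
  denom <- mr * my
  c(eta_int_sq = mean((r - y)^2) / (2 * denom),
    eta_ext_sq = (mean(r * y) - denom) / denom,
    eta_tot_sq = (mean(r^2 + y^2) / 2 - denom) / denom)
}

#' Time course of the intrinsic-noise fraction with bootstrap CIs
#'
#' Applies [noise_components()] at every time point of a dual-reporter
#' cohort and reports the intrinsic fraction
#' `eta_int_sq / eta_tot_sq`, clipped to [0, 1] for plotting parity, with
#' percentile bootstrap confidence intervals over cells. Times with
#' undefined components (zero channel mean) are omitted.
#'
#' @param r,y matrices (cells x times) of normalized accumulation.
#' @param times minutes, one per column.
#' @param n_boot bootstrap resamples (0 disables CIs).
#' @param rng_seed integer seed.
#' @param conf confidence level.
#' @return data.frame of class `"noise_timecourse"`: `time`, `eta_int_sq`,
#'   `eta_ext_sq`, `eta_tot_sq`, `intrinsic_fraction`, and `ci_lo`/`ci_hi`
#'   when bootstrapped.
#' @export
intrinsic_fraction_timecourse <- function(r, y, times = seq_len(ncol(r)),
                                          n_boot = 0, rng_seed = 1,
                                          conf = 0.95) {
  stopifnot(all(dim(r) == dim(y)), length(times) == ncol(r))
  set.seed(as.integer(rng_seed))
  n <- nrow(r)
  rows <- list()
  for (k in seq_len(ncol(r))) {
    comp <- noise_components(r[, k], y[, k])
    if (any(is.na(comp))) next
    frac <- clip01(comp[["eta_int_sq"]] / comp[["eta_tot_sq"]])
    row <- data.frame(time = times[k], eta_int_sq = comp[["eta_int_sq"]],
                      eta_ext_sq = comp[["eta_ext_sq"]],
                      eta_tot_sq = comp[["eta_tot_sq"]],
                      intrinsic_fraction = frac)
    if (n_boot > 0) {
      bf <- replicate(n_boot, {
        idx <- sample.int(n, n, replace = TRUE)
        bc <- noise_components(r[idx, k], y[idx, k])
        clip01(bc[["eta_int_sq"]] / bc[["eta_tot_sq"]])
      })
      a <- (1 - conf) / 2
      qs <- quantile(bf, c(a, 1 - a), na.rm = TRUE)
      row$ci_lo <- qs[[1]]; row$ci_hi <- qs[[2]]
    }
    rows[[length(rows) + 1L]] <- row
  }
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  class(out) <- c("noise_timecourse", "data.frame")
  out
}

clip01 <- function(x) pmin(pmax(x, 0), 1)

#' Stacked-area plot of a noise time course
#'
#' Blue area: proportion of intrinsic noise; yellow area above it:
#' proportion of extrinsic noise (summing to 1 at each retained time).
#'
#' @param x a `noise_timecourse`.
#' @param ... passed to [graphics::plot()].
#' @return invisibly `x`.
#' @export
plot.noise_timecourse <- function(x, ...) {
  graphics::plot(x$time, x$intrinsic_fraction, type = "n", ylim = c(0, 1),
                 xlab = "time (min)", ylab = "noise fraction", ...)
  graphics::polygon(c(x$time, rev(x$time)),
                    c(x$intrinsic_fraction, rep(0, nrow(x))),
                    col = "#4477AA", border = NA)
  graphics::polygon(c(x$time, rev(x$time)),
                    c(rep(1, nrow(x)), rev(x$intrinsic_fraction)),
                    col = "#DDCC77", border = NA)
  graphics::lines(x$time, x$intrinsic_fraction, lwd = 2)
  invisible(x)
}

#' Corrected-enrichment matrices for a dual-reporter cohort
#'
#' Convenience bridge from a tidy trace table to the (cells x times)
#' matrices the noise decomposition consumes: computes corrected nuclear
#' enrichment per cell for both channels on the common cell set.
#'
#' @param traces tidy trace table.
#' @param channels length-2 character; red and yellow channel names.
#' @param stimulus_time minutes.
#' @return list with matrices `r`, `y`, vector `times`, and `cells`.
#' @export
dual_reporter_matrices <- function(traces, channels, stimulus_time = 0) {
  stopifnot(length(channels) == 2)
  ids <- sort(unique(traces$track_id))
  tms <- sort(unique(traces$time_min))
  mk <- function(ch) {
    m <- matrix(NA_real_, length(ids), length(tms))
    for (i in seq_along(ids)) {
      one <- traces[traces$track_id == ids[i] & traces$channel == ch, ]
      one <- one[order(one$time_min), ]
      if (nrow(one) != length(tms)) next
      enr <- nuclear_enrichment(one$nuc_mean, one$cyt_mean)
      bas <- basal_level(enr, one$time_min, stimulus_time)
      m[i, ] <- corrected_enrichment(enr, bas)
    }
    m
  }
  r <- mk(channels[1]); y <- mk(channels[2])
  keep <- apply(is.finite(r), 1, all) & apply(is.finite(y), 1, all)
  list(r = r[keep, , drop = FALSE], y = y[keep, , drop = FALSE],
       times = tms, cells = ids[keep])
}
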