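#' Define a hyper-osmotic stimulus profile
#'
#' A step profile of extracellular NaCl concentration over the course of a
#' time-lapse movie. Only hyper-osmotic (non-decreasing) step sequences are
#' supported; a typical double-step experiment raises the concentration at
#' time zero and doubles it ~43 min later.
#'
#' @param step_times numeric, minutes; times of the concentration steps,
#'   strictly increasing, within `[0, duration]`.
#' @param step_concentrations numeric, mol/L NaCl reached after each step;
#'   non-negative and non-decreasing.
#' @param duration total movie length in minutes.
#' @param frame_interval imaging interval in minutes (> 0). The simulation
#'   grid equals the frame grid.
#' @return an object of class `"stimulus_profile"` with the validated fields
#'   and the frame-time grid in `$times`.
#' @examples
#' stimulus_profile(0, 0.2, duration = 60, frame_interval = 2)
#' stimulus_profile(c(0, 43), c(0.2, 0.4), duration = 90, frame_interval = 2)
#' @export
stimulus_profile <- function(step_times, step_concentrations,
                             duration = 60, frame_interval = 2) {
  step_times <- as.numeric(step_times)
  step_concentrations <- as.numeric(step_concentrations)
  if (length(step_times) != length(step_concentrations))
    stop("step_times and step_concentrations must have equal length")
  if (length(step_times) && any(diff(step_times) <= 0))
    stop("step_times must be strictly increasing")
  if (length(step_times) && (min(step_times) < 0 || max(step_times) > duration))
    stop("step_times must lie within [0, duration]")
  if (any(step_concentrations < 0))
    stop("concentrations must be non-negative")
  if (length(step_concentrations) > 1 && any(diff(step_concentrations) < 0))
    stop("hypo-osmotic steps are not modelled: concentrations must be non-decreasing")
  if (!is.numeric(frame_interval) || frame_interval <= 0)
    stop("frame_interval must be > 0")
  structure(list(
    step_times = step_times,
    step_concentrations = step_concentrations,
    duration = duration,
    frame_interval = frame_interval,
    times = seq(0, duration, by = frame_interval)
  ), class = "stimulus_profile")
}

#' @export
print.stimulus_profile <- function(x, ...) {
  cat("Stimulus profile:", length(x$step_times), "step(s),",
      x$duration, "min at", x$frame_interval, "min/frame\n")
  if (length(x$step_times))
    cat(paste0("  t=", x$step_times, " min -> ", x$step_concentrations,
               " M NaCl", collapse = "\n"), "\n")
  invisible(x)
}

# concentration increments per step (first step measured from 0 M)
step_increments <- function(stimulus) {
  diff(c(0, stimulus$step_concentrations))
}
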