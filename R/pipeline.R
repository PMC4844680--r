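TRACE_SCHEMA_VERSION <- "1.0"
TRACE_COLUMNS <- c("track_id", "time_min", "channel", "nuc_mean",
                   "cyt_mean", "nuc_area_px", "cell_area_px", "qc_pass")

#' Write a trace table to CSV with a versioned schema header
#'
#' @param traces trace table (contract columns; extra columns preserved).
#' @param path output CSV path.
#' @return invisibly `path`.
#' @export
write_traces <- function(traces, path) {
  miss <- setdiff(setdiff(TRACE_COLUMNS, "qc_pass"), names(traces))
  if (length(miss)) stop("trace table lacks column(s): ",
                         paste(miss, collapse = ", "))
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(paste0("# dpstr_trace_schema ", TRACE_SCHEMA_VERSION), con)
  write.csv(traces, con, row.names = FALSE, na = "")
  invisible(path)
}

#' Read a trace table, validating the contract
#'
#' Write-then-read round-trips values at full precision; missing cells come
#' back as `NA`, never 0. Unknown columns are preserved. Files declaring an
#' unknown major schema version are rejected.
#'
#' @param path CSV path (with or without the schema header line).
#' @return trace data.frame.
#' @export
roundtrip_traces <- function(path) {
  first <- readLines(path, n = 1)
  skip <- 0L
  if (startsWith(first, "# dpstr_trace_schema")) {
    ver <- trimws(sub("# dpstr_trace_schema", "", first))
    major <- strsplit(ver, ".", fixed = TRUE)[[1]][1]
    if (major != strsplit(TRACE_SCHEMA_VERSION, ".", fixed = TRUE)[[1]][1])
      stop("unsupported trace schema major version: ", ver)
    skip <- 1L
  }
  hdr <- strsplit(readLines(path, n = skip + 1L)[skip + 1L], ",")[[1]]
  cc <- if ("channel" %in% gsub('"', "", hdr))
    c(channel = "character") else NA
  df <- tryCatch(
    read.csv(path, skip = skip, na.strings = "", colClasses = cc),
    error = function(e) stop("malformed trace CSV: ", conditionMessage(e)))
  need <- setdiff(TRACE_COLUMNS, c("qc_pass", "nuc_area_px", "cell_area_px"))
  miss <- setdiff(need, names(df))
  if (length(miss)) stop("trace table lacks column(s): ",
                         paste(miss, collapse = ", "))
  bad <- which(!is.finite(df$time_min))
  if (length(bad)) stop("malformed rows (non-numeric time_min): row ",
                        paste(head(bad, 5), collapse = ", "))
  df
}

#' Load a run configuration from YAML
#'
#' Keys mirror the parameter constructors: `stimulus`, `signaling`,
#' `reporters` (named list of `promoter`/`reporter` blocks),
#' `extrinsic_cv`, `n_cells`, `imaging`, `qc` (cv limits), `threshold`
#' (quantile level), `seed`.
#'
#' @param path YAML file.
#' @return list of class `"run_config"` with constructed parameter objects
#'   and the raw YAML retained in `$raw`.
#' @export
load_run_config <- function(path) {
  raw <- yaml::read_yaml(path)
  build_run_config(raw)
}

#' @rdname load_run_config
#' @param raw configuration list (as parsed from YAML).
#' @export
build_run_config <- function(raw) {
  grab <- function(f, args) do.call(f, args %||% list())
  st <- grab(stimulus_profile, raw$stimulus)
  sg <- grab(signaling_params, raw$signaling)
  reps <- raw$reporters
  if (is.null(reps))
    reps <- list(dpstr_R = list())
  reporters <- lapply(reps, function(r)
    list(promoter = grab(promoter_params, r$promoter),
         reporter = grab(reporter_params, r$reporter)))
  cfg <- list(
    cohort = cohort_config(st, sg, reporters,
                           extrinsic_cv = raw$extrinsic_cv %||% 0.25),
    imaging = grab(imaging_params, raw$imaging),
    n_cells = raw$n_cells %||% 20,
    qc = raw$qc %||% list(nuclear_area = 0.15, cell_area = 0.15,
                          nuclear_marker_intensity = 0.15),
    threshold_quantile = raw$threshold %||% 0.99,
    seed = raw$seed %||% 1,
    stimulus_time = if (length(st$step_times)) st$step_times[1] else 0,
    raw = raw)
  class(cfg) <- "run_config"
  cfg
}

`%||%` <- function(a, b) if (is.null(a)) b else a

#' Run the full synthetic pipeline
#'
#' Executes the selected stages — simulate (cohort), render (synthetic
#' movie), segment (+track+QC), quantify (expression metrics), noise
#' (dual-reporter decomposition, when two reporters are configured) — and
#' writes artifacts plus a run report to `out_dir`. All stage seeds derive
#' deterministically from the run seed, so a given (config, seed) pair
#' reproduces its artifacts byte for byte.
#'
#' @param config a `run_config` (from [load_run_config()] /
#'   [build_run_config()]).
#' @param out_dir output directory.
#' @param stages character subset of
#'   `c("simulate", "render", "segment", "quantify", "noise")`.
#' @param seed overrides `config$seed` when given.
#' @return the run report (invisibly written as `report.json`): per-stage
#'   record counts, thresholds used, file manifest with MD5 hashes.
#' @export
run_pipeline <- function(config, out_dir,
                         stages = c("simulate", "render", "segment",
                                    "quantify", "noise"),
                         seed = NULL) {
  stopifnot(inherits(config, "run_config"))
  stages <- match.arg(stages, several.ok = TRUE)
  seed <- seed %||% config$seed
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  seeds <- derive_seeds(seed, 4)
  report <- list(seed = seed, stages = stages, counts = list(),
                 thresholds = list())
  t_all <- proc.time()[3]
  log_msg <- function(...) message(sprintf("[dpstr] %s", sprintf(...)))

  cohort <- NULL; movie <- NULL; traces <- NULL
  if ("simulate" %in% stages) {
    t0 <- proc.time()[3]
    cohort <- simulate_cohort(config$cohort, config$n_cells,
                              rng_seed = seeds[1])
    write_traces(within(cohort$traces, {
      track_id <- cell; time_min <- time
      nuc_area_px <- NA_real_; cell_area_px <- NA_real_
      cell <- NULL; time <- NULL
    })[, c("track_id", "time_min", "channel", "nuc_mean", "cyt_mean",
           "nuc_area_px", "cell_area_px")],
    file.path(out_dir, "ground_truth_traces.csv"))
    report$counts$cells_simulated <- cohort$n_cells
    log_msg("simulate: %d cells in %.1fs", cohort$n_cells,
            proc.time()[3] - t0)
  }
  if ("render" %in% stages) {
    if (is.null(cohort)) stop("stage 'render' requires stage 'simulate'")
    t0 <- proc.time()[3]
    geoms <- layout_cells(cohort$n_cells, config$imaging$field_size,
                          rng_seed = seeds[2])
    movie <- render_movie(cohort, geoms, config$imaging,
                          rng_seed = seeds[3])
    write_movie(movie, file.path(out_dir, "movie"))
    log_msg("render: %d frames in %.1fs", length(movie$frame_times),
            proc.time()[3] - t0)
  }
  if ("segment" %in% stages) {
    if (is.null(movie)) stop("stage 'segment' requires stage 'render'")
    t0 <- proc.time()[3]
    frames <- segment_movie(movie)
    tracks <- track_cells(frames)
    tr <- build_traces(frames, tracks, movie$frame_times)
    qc <- qc_filter(tr, cv_limits = unlist(config$qc))
    traces <- qc$traces
    write_traces(qc$all, file.path(out_dir, "traces.csv"))
    report$counts$cells_tracked <- qc$report$n_tracks
    report$counts$cells_qc_passed <- qc$report$n_pass
    report$qc <- qc$report
    log_msg("segment: %d tracked, %d QC-passed in %.1fs",
            qc$report$n_tracks, qc$report$n_pass, proc.time()[3] - t0)
  }
  if ("quantify" %in% stages) {
    if (is.null(traces)) stop("stage 'quantify' requires traces")
    t0 <- proc.time()[3]
    chans <- names(config$cohort$reporters)
    mets <- list()
    for (ch in chans) {
      m <- expression_metrics(traces, ch,
                              stimulus_time = config$stimulus_time)
      m$channel <- ch
      mets[[ch]] <- m
    }
    metrics <- do.call(rbind, mets)
    write.csv(metrics, file.path(out_dir, "expression_metrics.csv"),
              row.names = FALSE)
    report$counts$cells_quantified <- length(unique(metrics$track_id))
    report$thresholds$threshold_quantile <- config$threshold_quantile
    log_msg("quantify: %d cells in %.1fs",
            report$counts$cells_quantified, proc.time()[3] - t0)
  }
  if ("noise" %in% stages && length(config$cohort$reporters) >= 2) {
    t0 <- proc.time()[3]
    chans <- names(config$cohort$reporters)[1:2]
    dm <- dual_reporter_matrices(traces, chans,
                                 stimulus_time = config$stimulus_time)
    nm <- normalize_channels(dm$r, dm$y)
    ntc <- intrinsic_fraction_timecourse(nm$r, nm$y, dm$times,
                                         rng_seed = seeds[4])
    write.csv(ntc, file.path(out_dir, "noise_timecourse.csv"),
              row.names = FALSE)
    log_msg("noise: %d time points in %.1fs", nrow(ntc),
            proc.time()[3] - t0)
  }
  files <- list.files(out_dir, recursive = TRUE, full.names = TRUE)
  files <- setdiff(files, file.path(out_dir, "report.json"))
  report$manifest <- data.frame(
    file = sub(paste0(out_dir, "/"), "", files, fixed = TRUE),
    md5 = unname(tools::md5sum(files)))
  report$elapsed_s <- proc.time()[3] - t_all
  jsonlite::write_json(report, file.path(out_dir, "report.json"),
                       auto_unbox = TRUE, digits = NA, force = TRUE)
  invisible(report)
}
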