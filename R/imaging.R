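#' Imaging model parameters
#'
#' Camera and optics model for the synthetic movie renderer: compartment
#' intensities are `background + photon_gain * (molecules / compartment
#' area in px)`, corrupted by Poisson shot noise and Gaussian read noise,
#' then quantized to `bit_depth` bits.
#'
#' @param field_size side of the square field in pixels (>= 64).
#' @param background camera offset, a.u.
#' @param photon_gain a.u. per molecule per pixel of compartment density.
#' @param read_noise_sd Gaussian read-noise SD, a.u.
#' @param bit_depth output bit depth.
#' @param psf_sigma in-plane Gaussian PSF sigma in px (PP7 spots).
#' @param psf_sigma_z axial PSF sigma in microns (PP7 z-stacks).
#' @param nuclear_marker_count fluorophore copies of the constitutive
#'   nuclear tag per cell.
#' @param cell_body_level dim uniform whole-cell signal added to the
#'   nuclear-marker channel (fraction of nuclear density) serving as the
#'   cell-body proxy for contour segmentation.
#' @return object of class `"imaging_params"`.
#' @export
imaging_params <- function(field_size = 256, background = 100,
                           photon_gain = 50, read_noise_sd = 2,
                           bit_depth = 16, psf_sigma = 1.3,
                           psf_sigma_z = 0.8,
                           nuclear_marker_count = 4000,
                           cell_body_level = 0.1) {
  stopifnot(field_size >= 64, background >= 0, photon_gain > 0,
            read_noise_sd >= 0, bit_depth %in% c(8, 16),
            psf_sigma > 0, psf_sigma_z > 0,
            nuclear_marker_count > 0, cell_body_level >= 0)
  structure(list(field_size = field_size, background = background,
                 photon_gain = photon_gain, read_noise_sd = read_noise_sd,
                 bit_depth = bit_depth, psf_sigma = psf_sigma,
                 psf_sigma_z = psf_sigma_z,
                 nuclear_marker_count = nuclear_marker_count,
                 cell_body_level = cell_body_level),
            class = "imaging_params")
}

#' Lay out non-overlapping cell geometries on a field
#'
#' Places `n` elliptical cells (with an interior nuclear ellipse) by
#' rejection sampling; cells never overlap and stay clear of the border by
#' a margin that accommodates the full (unshrunken) cell.
#'
#' @param n number of cells (0 allowed).
#' @param field_size field side in pixels.
#' @param rng_seed integer seed.
#' @param cell_axes mean cell ellipse semi-axes (px).
#' @param nucleus_axes mean nucleus semi-axes (px).
#' @param jitter relative SD of per-cell size variation.
#' @param max_tries rejection-sampling retry bound per cell.
#' @return list of geometries, each `list(centroid, cell_axes,
#'   nucleus_axes, orientation, nucleus_offset)`.
#' @export
layout_cells <- function(n, field_size = 256, rng_seed = 1,
                         cell_axes = c(13, 10), nucleus_axes = c(4.5, 3.8),
                         jitter = 0.08, max_tries = 2000) {
  stopifnot(n >= 0, field_size >= 64)
  if (n == 0) return(list())
  set.seed(as.integer(rng_seed))
  margin <- max(cell_axes) * (1 + 3 * jitter) + 2
  geoms <- list()
  tries <- 0
  while (length(geoms) < n) {
    tries <- tries + 1
    if (tries > max_tries * n)
      stop(sprintf("could not place %d cells on a %d px field (placed %d)",
                   n, field_size, length(geoms)))
    ctr <- runif(2, margin, field_size - margin)
    sc <- max(1 + rnorm(1, 0, jitter), 0.7)
    ca <- cell_axes * sc
    na <- nucleus_axes * sc
    r <- max(ca)
    ok <- TRUE
    for (g in geoms) {
      if (sqrt(sum((ctr - g$centroid)^2)) < r + max(g$cell_axes) + 2) {
        ok <- FALSE; break
      }
    }
    if (!ok) next
    # nucleus offset kept small so the nucleus stays strictly inside
    off <- runif(2, -1, 1) * (ca - na) * 0.25
    geoms[[length(geoms) + 1L]] <- list(
      centroid = ctr, cell_axes = ca, nucleus_axes = na,
      orientation = runif(1, 0, pi), nucleus_offset = off)
  }
  geoms
}

# rasterize an ellipse: TRUE for pixel centres inside
ellipse_mask <- function(field_size, centroid, axes, orientation = 0) {
  x <- matrix(rep(seq_len(field_size), each = field_size), field_size)
  y <- matrix(rep(seq_len(field_size), times = field_size), field_size)
  dx <- x - centroid[1]; dy <- y - centroid[2]
  co <- cos(orientation); si <- sin(orientation)
  u <- dx * co + dy * si; v <- -dx * si + dy * co
  (u / axes[1])^2 + (v / axes[2])^2 <= 1
}

# per-frame geometry under shrink: axes scaled by sqrt(rel_area)
scaled_geometry <- function(g, rel_area) {
  s <- sqrt(rel_area)
  list(centroid = g$centroid, cell_axes = g$cell_axes * s,
       nucleus_axes = g$nucleus_axes * s, orientation = g$orientation,
       nucleus_offset = g$nucleus_offset * s)
}

# noise-free expected image for one frame of one channel
expected_frame <- function(cohort, geometries, imaging, frame,
                           channel = c("nuclear_marker", "dpstr", "venus"),
                           reporter_channel = NULL) {
  channel <- match.arg(channel)
  fs <- imaging$field_size
  img <- matrix(imaging$background, fs, fs)
  for (i in seq_along(geometries)) {
    cell <- cohort$cells[[i]]
    g <- scaled_geometry(geometries[[i]], cell$rel_area[frame])
    nmask <- ellipse_mask(fs, g$centroid + g$nucleus_offset,
                          g$nucleus_axes, g$orientation)
    cmask <- ellipse_mask(fs, g$centroid, g$cell_axes, g$orientation)
    cyt <- cmask & !nmask
    a_n <- sum(nmask); a_c <- sum(cyt)
    if (a_n == 0 || a_c == 0) next
    counts <- compartment_counts(cell, channel, reporter_channel, frame,
                                 imaging, a_n, a_c)
    img[nmask] <- img[nmask] + imaging$photon_gain * counts$nuc / a_n
    img[cyt] <- img[cyt] + imaging$photon_gain * counts$cyt / a_c
    if (channel == "nuclear_marker" && imaging$cell_body_level > 0) {
      body <- imaging$cell_body_level * imaging$nuclear_marker_count / a_n
      img[cmask] <- img[cmask] + imaging$photon_gain * body
    }
  }
  img
}

# molecule counts per compartment for a channel at one frame; the free FP
# splits between nucleus and cytoplasm at its passive concentration ratio
# using the rasterized compartment areas, so the rendered baseline
# reproduces the small positive nuclear enrichment of resting cells
compartment_counts <- function(cell, channel, reporter_channel, frame,
                               imaging, a_n, a_c) {
  if (channel == "nuclear_marker")
    return(list(nuc = imaging$nuclear_marker_count, cyt = 0))
  sp <- cell$species[[reporter_channel]]
  if (is.null(sp)) stop("unknown reporter channel: ", reporter_channel)
  rp_pars <- cell$reporter_params[[reporter_channel]]
  b <- rp_pars$passive_nuc_bias
  f_nuc <- sp$fp_free[frame] * b * a_n / (a_c + b * a_n)
  if (channel == "dpstr") {
    list(nuc = f_nuc + sp$complex_nuc[frame],
         cyt = sp$fp_free[frame] - f_nuc + sp$complex_cyt[frame])
  } else {  # venus: matured fluorophore located with the peptide
    ro <- cell$readouts[[reporter_channel]]
    tot <- sp$free_peptide[frame] + sp$complex_cyt[frame] + sp$complex_nuc[frame]
    mat <- ro$venus_total[frame]
    if (tot == 0) return(list(nuc = 0, cyt = 0))
    list(nuc = mat * sp$complex_nuc[frame] / tot,
         cyt = mat * (tot - sp$complex_nuc[frame]) / tot)
  }
}

apply_camera_noise <- function(img, imaging) {
  noisy <- rpois(length(img), pmax(img, 0)) +
    rnorm(length(img), 0, imaging$read_noise_sd)
  img[] <- pmin(pmax(round(noisy), 0), 2^imaging$bit_depth - 1)
  img
}

#' Render a cohort into a multichannel synthetic movie
#'
#' Produces image stacks for the nuclear-marker channel and each dPSTR
#' reporter channel (plus a Venus channel when requested), together with
#' ground-truth nucleus and cell label masks per frame. Cell and nucleus
#' ellipses are scaled by `sqrt(rel_area)` each frame while molecule counts
#' are untouched, so apparent per-pixel intensity rises when cells shrink:
#' the t = 0 artifact of hyper-osmotic stress movies arises geometrically.
#'
#' @param cohort a `dpstr_cohort`.
#' @param geometries from [layout_cells()]; one per cell.
#' @param imaging an [imaging_params()].
#' @param rng_seed integer seed for the camera noise.
#' @param channels character; which channels to render. Default: nuclear
#'   marker plus every reporter channel in the cohort.
#' @param venus logical; also render a maturation-delayed Venus channel for
#'   the first reporter.
#' @param noise logical; apply shot/read noise (FALSE gives the expected
#'   image).
#' @return object of class `"synthetic_movie"`: list with `channels`
#'   (named list of `field x field x n_frames` arrays), `gt_nuclei`,
#'   `gt_cells` (label stacks), `frame_times`, `geometries`, `imaging`.
#' @export
render_movie <- function(cohort, geometries, imaging = imaging_params(),
                         rng_seed = 1, channels = NULL, venus = FALSE,
                         noise = TRUE) {
  stopifnot(inherits(cohort, "dpstr_cohort"), inherits(imaging, "imaging_params"))
  if (length(geometries) != cohort$n_cells)
    stop("need exactly one geometry per cell")
  # attach reporter params to cells for count bookkeeping
  for (i in seq_len(cohort$n_cells))
    cohort$cells[[i]]$reporter_params <-
      lapply(cohort$config$reporters, `[[`, "reporter")
  rep_ch <- names(cohort$config$reporters)
  if (is.null(channels)) channels <- c("nuclear_marker", rep_ch)
  set.seed(as.integer(rng_seed))
  fs <- imaging$field_size
  nt <- length(cohort$times)
  stacks <- lapply(channels, function(ch) array(0, c(fs, fs, nt)))
  names(stacks) <- channels
  if (venus) stacks$venus <- array(0, c(fs, fs, nt))
  gt_n <- array(0L, c(fs, fs, nt))
  gt_c <- array(0L, c(fs, fs, nt))
  for (k in seq_len(nt)) {
    for (i in seq_along(geometries)) {
      g <- scaled_geometry(geometries[[i]], cohort$cells[[i]]$rel_area[k])
      nm <- ellipse_mask(fs, g$centroid + g$nucleus_offset, g$nucleus_axes,
                         g$orientation)
      cm <- ellipse_mask(fs, g$centroid, g$cell_axes, g$orientation)
      gt_n[, , k][nm] <- i
      gt_c[, , k][cm] <- i
    }
    for (ch in names(stacks)) {
      img <- if (ch == "nuclear_marker") {
        expected_frame(cohort, geometries, imaging, k, "nuclear_marker")
      } else if (ch == "venus") {
        expected_frame(cohort, geometries, imaging, k, "venus",
                       reporter_channel = rep_ch[1])
      } else {
        expected_frame(cohort, geometries, imaging, k, "dpstr",
                       reporter_channel = ch)
      }
      if (noise) img <- apply_camera_noise(img, imaging)
      stacks[[ch]][, , k] <- img
    }
  }
  structure(list(channels = stacks, gt_nuclei = gt_n, gt_cells = gt_c,
                 frame_times = cohort$times, geometries = geometries,
                 imaging = imaging, seed = rng_seed),
            class = "synthetic_movie")
}

#' Render a PP7 transcription-site z-stack and its maximum projection
#'
#' For each frame, renders `n_z` focal planes of the PP7 channel: a diffuse
#' nuclear background from the free PP7-2xGFP pool plus one Gaussian spot
#' per active locus (fixed intranuclear position and z-offset per cell)
#' whose amplitude is proportional to the nascent transcript count. The
#' per-frame maximum-intensity projection across z is the image the
#' transcription-site statistic is computed on.
#'
#' @param cohort a `dpstr_cohort` simulated with nascent mRNA.
#' @param geometries one per cell.
#' @param imaging an [imaging_params()].
#' @param rng_seed integer seed.
#' @param reporter_channel which reporter's locus to image (default first).
#' @param z_positions focal-plane offsets in microns.
#' @param spot_gain a.u. amplitude per nascent transcript.
#' @param pp7_background diffuse nuclear PP7-2xGFP intensity, a.u.
#' @param noise logical; camera noise on each plane.
#' @return list with `zstack` (field x field x n_z x n_frames),
#'   `max_projection` (field x field x n_frames), `spots` (per-cell spot
#'   positions), `frame_times`.
#' @export
render_pp7_stack <- function(cohort, geometries, imaging = imaging_params(),
                             rng_seed = 1, reporter_channel = NULL,
                             z_positions = c(-2, 0, 2), spot_gain = 40,
                             pp7_background = 30, noise = TRUE) {
  stopifnot(inherits(cohort, "dpstr_cohort"))
  if (is.null(reporter_channel))
    reporter_channel <- names(cohort$config$reporters)[1]
  set.seed(as.integer(rng_seed))
  fs <- imaging$field_size
  nt <- length(cohort$times)
  nz <- length(z_positions)
  zst <- array(0, c(fs, fs, nz, nt))
  # fixed intranuclear spot position and z-offset per cell
  spots <- lapply(seq_along(geometries), function(i) {
    g <- geometries[[i]]
    list(xy = g$centroid + g$nucleus_offset +
           runif(2, -0.4, 0.4) * g$nucleus_axes,
         z = runif(1, -1, 1))
  })
  xg <- matrix(rep(seq_len(fs), each = fs), fs)
  yg <- matrix(rep(seq_len(fs), times = fs), fs)
  for (k in seq_len(nt)) {
    base <- matrix(imaging$background, fs, fs)
    for (i in seq_along(geometries)) {
      g <- scaled_geometry(geometries[[i]], cohort$cells[[i]]$rel_area[k])
      nm <- ellipse_mask(fs, g$centroid + g$nucleus_offset, g$nucleus_axes,
                         g$orientation)
      base[nm] <- base[nm] + pp7_background
    }
    for (z in seq_len(nz)) {
      img <- base
      for (i in seq_along(geometries)) {
        amp <- spot_gain *
          cohort$cells[[i]]$species[[reporter_channel]]$nascent_mrna[k]
        if (amp <= 0) next
        sp <- spots[[i]]
        az <- amp * exp(-(z_positions[z] - sp$z)^2 / (2 * imaging$psf_sigma_z^2))
        r2 <- (xg - sp$xy[1])^2 + (yg - sp$xy[2])^2
        img <- img + az * exp(-r2 / (2 * imaging$psf_sigma^2))
      }
      if (noise) img <- apply_camera_noise(img, imaging)
      zst[, , z, k] <- img
    }
  }
  mp <- apply(zst, c(1, 2, 4), max)
  list(zstack = zst, max_projection = mp, spots = spots,
       frame_times = cohort$times)
}

#' Write a synthetic movie to multipage TIFF files with a metadata sidecar
#'
#' One 16-bit multipage TIFF per channel (frame-major) plus 16-bit label
#' TIFFs for the ground-truth masks and a JSON sidecar holding frame times,
#' channel names, the render seed and a configuration hash.
#'
#' @param movie a `synthetic_movie`.
#' @param dir output directory (created if needed).
#' @return invisibly, the sidecar path.
#' @export
write_movie <- function(movie, dir) {
  stopifnot(inherits(movie, "synthetic_movie"))
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  scale <- 2^movie$imaging$bit_depth - 1
  wr <- function(arr, path) {
    pages <- lapply(seq_len(dim(arr)[3]),
                    function(k) arr[, , k] / scale)
    tiff::writeTIFF(pages, path, bits.per.sample = 16L)
  }
  for (ch in names(movie$channels))
    wr(movie$channels[[ch]], file.path(dir, paste0(ch, ".tif")))
  wr(movie$gt_nuclei, file.path(dir, "gt_nuclei.tif"))
  wr(movie$gt_cells, file.path(dir, "gt_cells.tif"))
  cfgf <- tempfile()
  saveRDS(list(movie$imaging, movie$frame_times, names(movie$channels)),
          cfgf)
  meta <- list(frame_times = movie$frame_times,
               channels = names(movie$channels),
               seed = movie$seed,
               config_hash = unname(tools::md5sum(cfgf)),
               bit_depth = movie$imaging$bit_depth,
               imaging = unclass(movie$imaging))
  unlink(cfgf)
  side <- file.path(dir, "movie.json")
  jsonlite::write_json(meta, side, auto_unbox = TRUE, digits = NA)
  invisible(side)
}

#' Read a synthetic movie written by [write_movie()]
#'
#' @param dir directory holding the channel TIFFs and `movie.json`.
#' @return a `synthetic_movie`-like list (without geometries).
#' @export
read_movie <- function(dir) {
  meta <- jsonlite::read_json(file.path(dir, "movie.json"),
                              simplifyVector = TRUE)
  scale <- 2^meta$bit_depth - 1
  rd <- function(path) {
    pages <- tiff::readTIFF(path, all = TRUE)
    arr <- array(0, c(dim(pages[[1]]), length(pages)))
    for (k in seq_along(pages)) arr[, , k] <- round(pages[[k]] * scale)
    arr
  }
  channels <- lapply(meta$channels,
                     function(ch) rd(file.path(dir, paste0(ch, ".tif"))))
  names(channels) <- meta$channels
  out <- list(channels = channels,
              gt_nuclei = rd(file.path(dir, "gt_nuclei.tif")),
              gt_cells = rd(file.path(dir, "gt_cells.tif")),
              frame_times = meta$frame_times,
              imaging = do.call(imaging_params, meta$imaging[
                intersect(names(meta$imaging), names(formals(imaging_params)))]),
              seed = meta$seed)
  class(out) <- "synthetic_movie"
  out
}
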