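#' Segment nuclei by thresholding a nuclear-marker image
#'
#' Thresholds the nuclear-marker (histone-tag) channel and labels connected
#' components, discarding objects below `min_area`. The default rule is an
#' Otsu threshold computed on the frame, floored at
#' `background + 3 * read_noise_sd` so empty frames yield no objects.
#'
#' @param nuclear_image numeric matrix, raw intensities.
#' @param threshold `"otsu"` or an absolute numeric threshold.
#' @param min_area minimum object area in pixels.
#' @param floor lower bound applied to the automatic threshold.
#' @return integer label matrix (0 = background).
#' @export
segment_nuclei <- function(nuclear_image, threshold = "otsu", min_area = 15,
                           floor = 0) {
  stopifnot(is.matrix(nuclear_image))
  if (identical(threshold, "otsu")) {
    rng <- range(nuclear_image)
    th <- if (diff(rng) <= 0) Inf else
      EBImage::otsu(EBImage::Image(nuclear_image), range = rng, levels = 256)
    th <- max(th, floor)
  } else {
    th <- as.numeric(threshold)
  }
  mask <- nuclear_image > th
  if (!any(mask)) return(matrix(0L, nrow(nuclear_image), ncol(nuclear_image)))
  lab <- EBImage::bwlabel(EBImage::Image(mask))
  lab <- as.matrix(lab)
  sizes <- tabulate(lab[lab > 0])
  keep <- which(sizes >= min_area)
  out <- matrix(0L, nrow(lab), ncol(lab))
  newid <- integer(max(lab))
  newid[keep] <- seq_along(keep)
  sel <- lab > 0
  out[sel] <- newid[lab[sel]]
  out
}

#' Grow cell regions around nuclear seeds over a cell-body image
#'
#' Seeded region growing: foreground pixels of the cell-body proxy image
#' (above `body_threshold`) are assigned to the nearest nuclear seed by
#' geodesic propagation, so touching cells are split along the geodesic
#' midline. Nuclei falling outside the foreground are dropped with a
#' warning. The default body threshold is an Otsu threshold computed on the
#' image after clipping values above the nuclear-intensity range, which
#' separates background from the dim cell-body signal.
#'
#' @param nuclei integer label matrix of nuclear seeds.
#' @param body_image numeric matrix with a (possibly dim) whole-cell signal.
#' @param body_threshold numeric threshold, or `NULL` for automatic.
#' @return integer label matrix of cell regions; labels match `nuclei`.
#' @export
grow_cell_regions <- function(nuclei, body_image, body_threshold = NULL) {
  stopifnot(is.matrix(nuclei), is.matrix(body_image),
            all(dim(nuclei) == dim(body_image)))
  if (is.null(body_threshold)) {
    # Otsu on the non-nuclear pixels only, so the bright nuclear mode does
    # not drag the threshold above the dim cell-body signal
    v <- body_image[nuclei == 0]
    body_threshold <- if (length(v) < 2 || diff(range(v)) <= 0) Inf
      else otsu_vec(v)
  }
  fg <- body_image > body_threshold | nuclei > 0
  if (!any(fg)) return(matrix(0L, nrow(nuclei), ncol(nuclei)))
  ids <- setdiff(sort(unique(as.vector(nuclei))), 0L)
  lab <- EBImage::propagate(EBImage::Image(body_image / max(body_image)),
                            seeds = EBImage::Image(nuclei),
                            mask = EBImage::Image(fg), lambda = 1e4)
  lab <- matrix(as.integer(round(as.matrix(lab))), nrow(nuclei))
  grown <- setdiff(sort(unique(as.vector(lab))), 0L)
  lost <- setdiff(ids, grown)
  if (length(lost))
    warning("nuclei outside foreground dropped: ", paste(lost, collapse = ", "))
  lab
}

# Otsu threshold of a numeric vector (256-bin between-class variance)
otsu_vec <- function(v, levels = 256) {
  rng <- range(v)
  h <- tabulate(pmin(floor((v - rng[1]) / diff(rng) * levels) + 1L, levels),
                nbins = levels)
  p <- h / sum(h)
  mids <- rng[1] + (seq_len(levels) - 0.5) / levels * diff(rng)
  w0 <- cumsum(p)
  mu0 <- cumsum(p * mids)
  mu_t <- mu0[levels]
  sigma_b <- (mu_t * w0 - mu0)^2 / (w0 * (1 - w0))
  sigma_b[!is.finite(sigma_b)] <- 0
  mids[which.max(sigma_b)]
}

#' Cytoplasm mask: cell minus dilated nucleus
#'
#' For each cell, removes its nucleus dilated by `dilation_px` (disk
#' structuring element) from the cell region. Cells whose cytoplasm is
#' empty after subtraction are flagged.
#'
#' @param cells integer cell label matrix.
#' @param nuclei integer nucleus label matrix (same labels).
#' @param dilation_px dilation radius in pixels (default 2).
#' @return list with `labels` (cytoplasm label matrix) and `empty`
#'   (integer ids of cells with empty cytoplasm).
#' @export
cytoplasm_mask <- function(cells, nuclei, dilation_px = 2) {
  stopifnot(all(dim(cells) == dim(nuclei)), dilation_px >= 0)
  if (dilation_px > 0) {
    brush <- EBImage::makeBrush(2 * dilation_px + 1, shape = "disc")
    dil <- EBImage::dilate(EBImage::Image(nuclei), brush)
    dil <- matrix(as.integer(round(as.matrix(dil))), nrow(nuclei))
  } else {
    dil <- nuclei
  }
  cyt <- cells
  cyt[dil > 0] <- 0L
  ids <- setdiff(sort(unique(as.vector(cells))), 0L)
  empty <- ids[!(ids %in% setdiff(unique(as.vector(cyt)), 0L))]
  list(labels = cyt, empty = as.integer(empty))
}

#' Measure per-object compartment statistics on one frame
#'
#' Mean intensity of every labelled nucleus and cytoplasm in each channel,
#' plus areas and centroids, and the sorted nuclear pixel values needed for
#' the transcription-site statistic. Missing compartments yield `NA`, never
#' zero.
#'
#' @param nuclei nucleus label matrix.
#' @param cytoplasm cytoplasm label matrix.
#' @param cells cell label matrix.
#' @param images named list of channel matrices.
#' @return data.frame with one row per (object, channel): `label`,
#'   `channel`, `nuc_mean`, `cyt_mean`, `nuc_area_px`, `cell_area_px`,
#'   `centroid_x`, `centroid_y`. The sorted nuclear pixels of the first
#'   channel are attached as attribute `"nuclear_pixels"` (list by label).
#' @export
measure_frame <- function(nuclei, cytoplasm, cells, images) {
  stopifnot(is.list(images), length(images) >= 1)
  ids <- sort(unique(c(as.vector(nuclei), as.vector(cells))))
  ids <- setdiff(ids, 0L)
  if (!length(ids)) return(data.frame())
  nuc_area <- tabulate(nuclei[nuclei > 0], nbins = max(ids))
  cell_area <- tabulate(cells[cells > 0], nbins = max(ids))
  # x = column, y = row (the renderer's ellipse convention)
  cx <- vapply(ids, function(i) mean(which(nuclei == i, arr.ind = TRUE)[, 2]), 0)
  cy <- vapply(ids, function(i) mean(which(nuclei == i, arr.ind = TRUE)[, 1]), 0)
  rows <- list()
  npx <- list()
  for (ch in names(images)) {
    img <- images[[ch]]
    nm <- vapply(ids, function(i) {
      v <- img[nuclei == i]
      if (length(v)) mean(v) else NA_real_
    }, 0)
    cm <- vapply(ids, function(i) {
      v <- img[cytoplasm == i]
      if (length(v)) mean(v) else NA_real_
    }, 0)
    rows[[ch]] <- data.frame(label = ids, channel = ch, nuc_mean = nm,
                             cyt_mean = cm,
                             nuc_area_px = nuc_area[ids],
                             cell_area_px = cell_area[ids],
                             centroid_x = cx, centroid_y = cy)
  }
  ch1 <- images[[1]]
  for (i in ids) npx[[as.character(i)]] <- sort(ch1[nuclei == i],
                                                decreasing = TRUE)
  out <- do.call(rbind, rows)
  rownames(out) <- NULL
  attr(out, "nuclear_pixels") <- npx
  out
}

#' Segment and measure every frame of a movie
#'
#' Applies [segment_nuclei()], [grow_cell_regions()], [cytoplasm_mask()]
#' and [measure_frame()] per frame. When ground-truth masks are supplied
#' they replace the image-based segmentation (used to isolate measurement
#' fidelity from segmentation error).
#'
#' @param movie a `synthetic_movie` (or compatible list of channel stacks).
#' @param nuclear_channel channel used for nuclear segmentation.
#' @param body_channel channel providing the cell-body proxy (defaults to
#'   the nuclear channel, whose dim whole-cell component is the proxy).
#' @param use_ground_truth logical; take masks from `gt_nuclei`/`gt_cells`.
#' @param dilation_px cytoplasm exclusion radius.
#' @param min_area minimum nuclear area.
#' @return list of per-frame lists: `nuclei`, `cells`, `cytoplasm`,
#'   `stats` (from [measure_frame()]).
#' @export
segment_movie <- function(movie, nuclear_channel = "nuclear_marker",
                          body_channel = nuclear_channel,
                          use_ground_truth = FALSE, dilation_px = 2,
                          min_area = 15) {
  nt <- dim(movie$channels[[1]])[3]
  floor_th <- movie$imaging$background + 3 * movie$imaging$read_noise_sd
  frames <- vector("list", nt)
  for (k in seq_len(nt)) {
    imgs <- lapply(movie$channels, function(a) a[, , k])
    if (use_ground_truth) {
      nuc <- matrix(as.integer(movie$gt_nuclei[, , k]),
                    nrow = dim(movie$gt_nuclei)[1])
      cel <- matrix(as.integer(movie$gt_cells[, , k]),
                    nrow = dim(movie$gt_cells)[1])
    } else {
      nuc <- segment_nuclei(imgs[[nuclear_channel]], min_area = min_area,
                            floor = floor_th)
      cel <- grow_cell_regions(nuc, imgs[[body_channel]])
    }
    cyt <- cytoplasm_mask(cel, nuc, dilation_px = dilation_px)
    frames[[k]] <- list(nuclei = nuc, cells = cel, cytoplasm = cyt$labels,
                        empty_cytoplasm = cyt$empty,
                        stats = measure_frame(nuc, cyt$labels, cel, imgs))
  }
  frames
}
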