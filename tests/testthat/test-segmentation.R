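disk_image <- function(size, centres, radius, value = 1000, bg = 0) {
  img <- matrix(bg, size, size)
  x <- matrix(rep(seq_len(size), each = size), size)
  y <- matrix(rep(seq_len(size), times = size), size)
  for (c in centres)
    img[(x - c[1])^2 + (y - c[2])^2 <= radius^2] <- value
  img
}

test_that("blank images yield zero nuclei, disks yield one label each", {
  expect_equal(max(segment_nuclei(matrix(0, 64, 64))), 0)
  img <- disk_image(64, list(c(16, 16), c(48, 48)), 6)
  lab <- segment_nuclei(img, min_area = 15)
  expect_equal(max(lab), 2)
  for (i in 1:2) {
    px <- which(lab == i, arr.ind = TRUE)
    ctr <- c(mean(px[, 2]), mean(px[, 1]))  # x = col, y = row
    expect_true(any(vapply(list(c(16, 16), c(48, 48)),
                           function(cc) all(abs(ctr - cc) <= 0.5), NA)))
  }
  # a disk below min_area is rejected
  small <- disk_image(64, list(c(32, 32)), 2)
  expect_equal(max(segment_nuclei(small, min_area = 15)), 0)
})

test_that("region growing recovers an ellipse around its nucleus", {
  fs <- 96
  cellm <- dpstr:::ellipse_mask(fs, c(48, 48), c(20, 14), 0.3)
  nucm <- dpstr:::ellipse_mask(fs, c(48, 48), c(6, 5), 0.3)
  body <- matrix(0, fs, fs); body[cellm] <- 50; body[nucm] <- 500
  nuclei <- matrix(0L, fs, fs); nuclei[nucm] <- 1L
  grown <- grow_cell_regions(nuclei, body, body_threshold = 25)
  jac <- sum(grown == 1 & cellm) / sum(grown == 1 | cellm)
  expect_gte(jac, 0.95)
  # no foreground: empty mask
  expect_equal(max(grow_cell_regions(matrix(0L, 8, 8), matrix(0, 8, 8))), 0)
})

test_that("touching cells split into disjoint regions along the seed midline", {
  fs <- 96
  c1 <- dpstr:::ellipse_mask(fs, c(36, 48), c(16, 12), 0)
  c2 <- dpstr:::ellipse_mask(fs, c(60, 48), c(16, 12), 0)
  body <- matrix(0, fs, fs); body[c1 | c2] <- 50
  n1 <- dpstr:::ellipse_mask(fs, c(34, 48), c(4, 4), 0)
  n2 <- dpstr:::ellipse_mask(fs, c(62, 48), c(4, 4), 0)
  nuclei <- matrix(0L, fs, fs); nuclei[n1] <- 1L; nuclei[n2] <- 2L
  body[n1 | n2] <- 500
  grown <- grow_cell_regions(nuclei, body, body_threshold = 25)
  expect_setequal(setdiff(unique(as.vector(grown)), 0L), c(1L, 2L))
  expect_equal(sum(grown == 1 & grown == 2), 0)
  # each region contains its seed
  expect_true(all(grown[n1] == 1L))
  expect_true(all(grown[n2] == 2L))
})

test_that("cytoplasm excludes the 2-px-dilated nucleus; annulus arithmetic exact", {
  fs <- 64
  cellm <- disk_image(fs, list(c(32, 32)), 20, value = 1) > 0
  nucm <- disk_image(fs, list(c(32, 32)), 8, value = 1) > 0
  cells <- matrix(0L, fs, fs); cells[cellm] <- 1L
  nuclei <- matrix(0L, fs, fs); nuclei[nucm] <- 1L
  cm0 <- cytoplasm_mask(cells, nuclei, dilation_px = 0)
  expect_equal(sum(cm0$labels == 1), sum(cellm) - sum(nucm))
  cm2 <- cytoplasm_mask(cells, nuclei, dilation_px = 2)
  # oracle: dilation is the union of brush-offset shifts of the nucleus
  brush <- as.matrix(EBImage::makeBrush(5, shape = "disc"))
  off <- which(brush == 1, arr.ind = TRUE) - 3  # offsets from brush centre
  dil <- matrix(FALSE, fs, fs)
  nucpx <- which(nucm, arr.ind = TRUE)
  for (o in seq_len(nrow(off))) {
    r <- nucpx[, 1] + off[o, 1]; c <- nucpx[, 2] + off[o, 2]
    dil[cbind(r, c)] <- TRUE
  }
  expect_equal(sum(cm2$labels == 1), sum(cellm) - sum(dil & cellm))
  expect_length(cm2$empty, 0)
  # nucleus = cell: flagged empty
  cme <- cytoplasm_mask(nuclei, nuclei, dilation_px = 0)
  expect_equal(cme$empty, 1L)
  # compartment exclusivity after dilation
  expect_equal(sum(cm2$labels > 0 & as.vector(dil)), 0)
})

test_that("uniform images measure the uniform value; missing stays missing", {
  fs <- 32
  nuclei <- matrix(0L, fs, fs); nuclei[10:14, 10:14] <- 1L
  cells <- matrix(0L, fs, fs); cells[8:20, 8:20] <- 1L
  cyt <- cytoplasm_mask(cells, nuclei, 0)$labels
  st <- measure_frame(nuclei, cyt, cells, list(a = matrix(7, fs, fs)))
  expect_equal(st$nuc_mean, 7)
  expect_equal(st$cyt_mean, 7)
  # label with no cytoplasm: NA, not zero
  st2 <- measure_frame(nuclei, matrix(0L, fs, fs), nuclei,
                       list(a = matrix(7, fs, fs)))
  expect_true(is.na(st2$cyt_mean))
})

test_that("pipeline traces reproduce ground truth within 2% on noise-free movies", {
  st <- single_step(duration = 20)
  co <- simulate_cohort(cohort_config(stimulus = st), n_cells = 5,
                        rng_seed = 11)
  g <- layout_cells(5, 192, rng_seed = 2)
  im <- imaging_params(field_size = 192, background = 0, read_noise_sd = 0)
  mv <- render_movie(co, g, im, rng_seed = 1, noise = FALSE)
  fr <- segment_movie(mv, use_ground_truth = TRUE)
  tk <- track_cells(fr)
  tr <- build_traces(fr, tk, mv$frame_times)
  map <- match_tracks_to_cells(fr, tk, g)
  for (r in seq_len(nrow(map))) {
    cell <- co$cells[[map$cell[r]]]
    one <- tr[tr$track_id == map$track_id[r] & tr$channel == "dpstr_R", ]
    one <- one[order(one$time_min), ]
    for (k in seq_along(co$times)) {
      sp <- cell$species$dpstr_R
      pars <- co$config$reporters$dpstr_R$reporter
      b <- pars$passive_nuc_bias
      nmask <- mv$gt_nuclei[, , k] == map$cell[r]
      cmask <- mv$gt_cells[, , k] == map$cell[r] & !nmask
      f_nuc <- sp$fp_free[k] * b * sum(nmask) / (sum(cmask) + b * sum(nmask))
      exp_nuc <- im$photon_gain * (f_nuc + sp$complex_nuc[k]) / sum(nmask)
      # cytoplasm measurement excludes the dilated-nucleus ring but the
      # ring pixels carry the same cytoplasmic concentration
      expect_equal(one$nuc_mean[k], exp_nuc, tolerance = 0.02)
    }
  }
})

test_that("stationary cells give complete identity tracks; gaps break tracks", {
  mk_frame <- function(centres) {
    s <- data.frame(label = seq_along(centres),
                    channel = "a", nuc_mean = 1, cyt_mean = 1,
                    nuc_area_px = 10, cell_area_px = 20,
                    centroid_x = vapply(centres, `[`, 0, 1),
                    centroid_y = vapply(centres, `[`, 0, 2))
    list(stats = s)
  }
  pos <- list(c(10, 10), c(40, 40))
  frames <- list(mk_frame(pos), mk_frame(pos), mk_frame(pos))
  tk <- track_cells(frames, max_displacement = 5)
  expect_true(all(tk$complete))
  expect_equal(length(unique(tk$track_id)), 2)
  # one cell vanishes mid-movie: its track is incomplete
  frames2 <- list(mk_frame(pos), mk_frame(pos[1]), mk_frame(pos))
  tk2 <- track_cells(frames2, max_displacement = 5)
  expect_equal(sum(tapply(tk2$complete, tk2$track_id, all)), 1)
  # cells jumping beyond max_displacement terminate and restart tracks
  frames3 <- list(mk_frame(pos), mk_frame(list(c(80, 80), c(95, 95))))
  tk3 <- track_cells(frames3, max_displacement = 5)
  expect_false(any(tk3$complete))
  expect_equal(length(unique(tk3$track_id)), 4)
})

test_that("tracking is exact on synthetic movies when motion is bounded", {
  st <- single_step(duration = 12)
  co <- simulate_cohort(cohort_config(stimulus = st), n_cells = 8,
                        rng_seed = 13)
  g <- layout_cells(8, 224, rng_seed = 3)
  mv <- render_movie(co, g, imaging_params(field_size = 224), rng_seed = 2)
  fr <- segment_movie(mv)
  tk <- track_cells(fr, max_displacement = 8)
  comp <- unique(tk$track_id[tk$complete])
  expect_equal(length(comp), 8)
  map <- match_tracks_to_cells(fr, tk, g)
  # every complete track maps to a distinct true cell at sub-pixel distance
  expect_equal(sort(map$cell), 1:8)
  expect_true(all(map$dist_px < 3))
})

test_that("QC passes constant traces, rejects high-CV ones, with recorded reasons", {
  t5 <- seq(0, 8, 2)
  good <- data.frame(track_id = 1L, time_min = t5, channel = "nuclear_marker",
                     nuc_mean = 100, cyt_mean = 10, nuc_area_px = 50,
                     cell_area_px = 400)
  bad <- good; bad$track_id <- 2L; bad$nuc_area_px <- c(50, 90, 30, 80, 40)
  qc <- qc_filter(rbind(good, bad))
  expect_equal(sort(unique(qc$traces$track_id)), 1L)
  expect_equal(qc$report$rejected_nuclear_area, 1)
  expect_equal(qc$report$n_pass, 1)
})

test_that("QC retains more than 65% of tracked cells on a default synthetic cohort", {
  st <- single_step(duration = 30)
  co <- simulate_cohort(cohort_config(stimulus = st), n_cells = 12,
                        rng_seed = 17)
  g <- layout_cells(12, 256, rng_seed = 5)
  mv <- render_movie(co, g, imaging_params(), rng_seed = 6)
  fr <- segment_movie(mv)
  tk <- track_cells(fr)
  tr <- build_traces(fr, tk, mv$frame_times)
  qc <- qc_filter(tr)
  expect_gt(qc$report$pass_fraction, 0.65)
})
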