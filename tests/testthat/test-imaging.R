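test_that("layout produces the requested number of disjoint in-field cells", {
  expect_length(layout_cells(0), 0)
  g1 <- layout_cells(1, 128, rng_seed = 1)
  expect_length(g1, 1)
  g <- layout_cells(50, 512, rng_seed = 3)
  expect_length(g, 50)
  masks <- lapply(g, function(gg)
    dpstr:::ellipse_mask(512, gg$centroid, gg$cell_axes, gg$orientation))
  total <- Reduce(`+`, lapply(masks, function(m) m * 1L))
  expect_lte(max(total), 1)  # pairwise disjoint pixels
  # deterministic under seed
  expect_identical(layout_cells(10, 256, rng_seed = 5),
                   layout_cells(10, 256, rng_seed = 5))
  expect_error(layout_cells(500, 128, rng_seed = 1, max_tries = 20),
               "could not place")
})

test_that("noise-free rendering matches the analytic compartment intensities", {
  st <- single_step(duration = 4)
  cfg <- cohort_config(stimulus = st)
  co <- simulate_cohort(cfg, n_cells = 1, rng_seed = 2)
  g <- layout_cells(1, 128, rng_seed = 1)
  im <- imaging_params(field_size = 128, background = 0, read_noise_sd = 0)
  mv <- render_movie(co, g, im, rng_seed = 1, noise = FALSE)
  k <- 1
  nm <- mv$gt_nuclei[, , k] == 1
  cy <- mv$gt_cells[, , k] == 1 & !nm
  sp <- co$cells[[1]]$species$dpstr_R
  pars <- cfg$reporters$dpstr_R$reporter
  b <- pars$passive_nuc_bias
  f_nuc <- sp$fp_free[k] * b * sum(nm) / (sum(cy) + b * sum(nm))
  exp_nuc <- im$photon_gain * (f_nuc + sp$complex_nuc[k]) / sum(nm)
  exp_cyt <- im$photon_gain * (sp$fp_free[k] - f_nuc + sp$complex_cyt[k]) / sum(cy)
  expect_equal(mean(mv$channels$dpstr_R[, , k][nm]), exp_nuc, tolerance = 1e-12)
  expect_equal(mean(mv$channels$dpstr_R[, , k][cy]), exp_cyt, tolerance = 1e-12)
})

test_that("integrated fluorescence is conserved under the shrink artifact", {
  st <- single_step(duration = 10)
  cfg <- cohort_config(stimulus = st,
                       signaling = signaling_params(shrink_fraction = 0.6,
                                                    cell_cv = 0),
                       reporters = list(dpstr_R = list(
                         promoter = promoter_params(induced_tx_rate = 0),
                         reporter = reporter_params())))
  co <- simulate_cohort(cfg, n_cells = 1, rng_seed = 4)
  expect_lt(min(co$cells[[1]]$rel_area), 0.92)
  g <- layout_cells(1, 128, rng_seed = 2)
  im <- imaging_params(field_size = 128, background = 0, read_noise_sd = 0)
  mv <- render_movie(co, g, im, rng_seed = 1, noise = FALSE)
  totals <- vapply(seq_along(co$times), function(k)
    sum(mv$channels$dpstr_R[, , k]), 0)
  # total photons constant although the cell area changes
  expect_lt(diff(range(totals)) / mean(totals), 0.001)
  # but the apparent nuclear-cytoplasmic difference transiently rises
  diffs <- vapply(seq_along(co$times), function(k) {
    nm <- mv$gt_nuclei[, , k] == 1
    cy <- mv$gt_cells[, , k] == 1 & !nm
    mean(mv$channels$dpstr_R[, , k][nm]) - mean(mv$channels$dpstr_R[, , k][cy])
  }, 0)
  shrunk <- which.min(co$cells[[1]]$rel_area)
  expect_gt(diffs[shrunk], diffs[length(diffs)] * 1.02)
})

test_that("same cohort renders identical expectations but different noise per seed", {
  st <- single_step(duration = 4)
  co <- simulate_cohort(cohort_config(stimulus = st), 2, rng_seed = 3)
  g <- layout_cells(2, 128, rng_seed = 1)
  im <- imaging_params(field_size = 128)
  clean1 <- render_movie(co, g, im, rng_seed = 1, noise = FALSE)
  clean2 <- render_movie(co, g, im, rng_seed = 2, noise = FALSE)
  expect_identical(clean1$channels, clean2$channels)
  n1 <- render_movie(co, g, im, rng_seed = 1)
  n2 <- render_movie(co, g, im, rng_seed = 2)
  expect_false(identical(n1$channels$dpstr_R, n2$channels$dpstr_R))
})

test_that("pp7 rendering: no transcript, no spot; amplitude is linear", {
  st <- single_step(duration = 4)
  co <- simulate_cohort(cohort_config(stimulus = st,
                                      signaling = signaling_params(shrink_fraction = 0),
                                      reporters = list(dpstr_R = list(
                                        promoter = promoter_params(induced_tx_rate = 0),
                                        reporter = reporter_params()))),
                        1, rng_seed = 2)
  g <- layout_cells(1, 96, rng_seed = 1)
  im <- imaging_params(field_size = 96)
  pp <- render_pp7_stack(co, g, im, rng_seed = 1, noise = FALSE)
  k <- 1
  # silent locus: the 20-brightest statistic on the nucleus is ~0
  nm <- dpstr:::ellipse_mask(96, g[[1]]$centroid + g[[1]]$nucleus_offset,
                             g[[1]]$nucleus_axes, g[[1]]$orientation)
  expect_lt(pp7_site_intensity(pp$max_projection[, , k][nm]), 1e-9)

  # doubling the nascent count doubles the noise-free spot peak
  co2 <- co
  co2$cells[[1]]$species$dpstr_R$nascent_mrna[] <- 1L
  p1 <- render_pp7_stack(co2, g, im, rng_seed = 1, noise = FALSE)
  co2$cells[[1]]$species$dpstr_R$nascent_mrna[] <- 2L
  p2 <- render_pp7_stack(co2, g, im, rng_seed = 1, noise = FALSE)
  base <- pp$max_projection[, , 1]
  s1 <- max(p1$max_projection[, , 1] - base)
  s2 <- max(p2$max_projection[, , 1] - base)
  expect_equal(s2 / s1, 2, tolerance = 1e-6)
})

test_that("max projection recovers the spot peak across focal planes", {
  st <- single_step(duration = 4)
  co <- simulate_cohort(cohort_config(stimulus = st), 1, rng_seed = 2)
  co$cells[[1]]$species$dpstr_R$nascent_mrna[] <- 3L
  g <- layout_cells(1, 96, rng_seed = 4)
  im <- imaging_params(field_size = 96)
  pp <- render_pp7_stack(co, g, im, rng_seed = 1, noise = FALSE,
                         z_positions = seq(-2, 2, 0.5), pp7_background = 0,
                         spot_gain = 40)
  # analytic in-focus peak: amplitude at the nearest z plane and sub-pixel
  # offset attenuation bounded by the PSF discretization
  z0 <- pp$spots[[1]]$z
  az <- 120 * exp(-min(abs(seq(-2, 2, 0.5) - z0))^2 / (2 * im$psf_sigma_z^2))
  peak <- max(pp$max_projection[, , 1]) - im$background
  expect_gt(peak, az * exp(-0.5 / (2 * im$psf_sigma^2)))  # within half-pixel offset
  expect_lte(peak, az * (1 + 1e-9))
})

test_that("movies round-trip through TIFF with sidecar metadata", {
  st <- single_step(duration = 4)
  co <- simulate_cohort(cohort_config(stimulus = st), 2, rng_seed = 3)
  g <- layout_cells(2, 96, rng_seed = 1)
  mv <- render_movie(co, g, imaging_params(field_size = 96), rng_seed = 7)
  dir <- file.path(tempdir(), "movtest")
  write_movie(mv, dir)
  rt <- read_movie(dir)
  expect_equal(rt$frame_times, mv$frame_times)
  expect_equal(rt$channels$dpstr_R, mv$channels$dpstr_R)
  expect_equal(rt$gt_nuclei, mv$gt_nuclei * 1.0)
  expect_equal(rt$seed, 7)
  unlink(dir, recursive = TRUE)
})
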