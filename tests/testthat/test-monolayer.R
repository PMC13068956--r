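# Monolayer image quantifications.

test_that("nuclei counting recovers generated density and splits touching
           nuclei", {
  ml <- gen_monolayer_images(density = 1500, field_size_um = 200, seed = 3)
  res <- count_nuclei_density(ml)
  expect_equal(res$count, ml$truth$n_cells, tolerance = 0.02)
  expect_equal(res$density_cells_mm2, ml$truth$density_cells_mm2,
               tolerance = 0.02)
  # blank image
  expect_warning(res0 <- count_nuclei_density(matrix(0, 64, 64),
                                              px_um = 0.5), "empty")
  expect_equal(res0$count, 0L)
  # two touching discs are split by the watershed
  img <- 150 * (disc_mask(64, 25, 32, 8) | disc_mask(64, 39, 32, 8))
  res2 <- count_nuclei_density(img, px_um = 0.5, gaussian_sigma = 1)
  expect_equal(res2$count, 2L)
  # density linearity: doubling the truth count doubles the density
  ml2 <- gen_monolayer_images(density = 3000, field_size_um = 200, seed = 3)
  r2 <- count_nuclei_density(ml2)
  expect_equal(r2$density_cells_mm2 / res$density_cells_mm2, 2,
               tolerance = 0.02)
})

test_that("proliferation fraction is the positive percentage", {
  expect_equal(proliferation_fraction(2, 1000), 0.2)
  expect_equal(proliferation_fraction(0, 500), 0)
  expect_error(proliferation_fraction(1, 0), "positive")
  expect_error(proliferation_fraction(10, 5), "0, n_total")
})

test_that("cell height is the vertical extent at sampled columns", {
  for (h in c(9.1, 11.6)) {
    slab <- gen_cross_section_slab(h, axial_px_um = 0.1)
    res <- measure_cell_height(slab)
    expect_equal(res$mean_um, h, tolerance = 1e-9)
    # isotropy: identical at every sampled position
    expect_equal(var(res$heights_um), 0)
  }
  # one-pixel sheet
  sheet <- matrix(FALSE, 50, 20); sheet[, 10] <- TRUE
  expect_equal(measure_cell_height(sheet, axial_px_um = 0.5)$mean_um, 0.5)
  expect_error(measure_cell_height(matrix(FALSE, 10, 10),
                                   axial_px_um = 0.5), "foreground")
})

test_that("shape factor behaves like P/sqrt(A): squares near 4, discs near
           the isoperimetric bound, scale invariant", {
  lab <- matrix(0L, 40, 40); lab[11:30, 11:30] <- 1L  # 20 px square
  q_sq <- shape_factor(lab, px_um = 1)$shape_factor
  expect_equal(q_sq, 4, tolerance = 0.02)
  lab2 <- matrix(0L, 80, 80); lab2[disc_mask(80, 40.5, 40.5, 30)] <- 1L
  q_disc <- shape_factor(lab2, px_um = 1)$shape_factor
  # the chamfered crack estimator overestimates smooth contours by a few
  # percent but never violates the isoperimetric lower bound
  expect_gte(q_disc, 2 * sqrt(pi) - 0.01)
  expect_equal(q_disc, 2 * sqrt(pi), tolerance = 0.06)
  # q is dimensionless: rescaling the same cell leaves it unchanged
  lab3 <- matrix(0L, 80, 80); lab3[21:60, 21:60] <- 1L  # 2x the square
  expect_equal(shape_factor(lab3, px_um = 1)$shape_factor, q_sq,
               tolerance = 0.01)
  expect_equal(shape_factor(lab, px_um = 0.25)$shape_factor, q_sq)
  # border-touching cells are excluded
  lab4 <- lab; lab4[1:5, 1:5] <- 2L
  expect_equal(nrow(shape_factor(lab4, px_um = 1)), 1)
})

test_that("shape factor discretisation error shrinks with resolution on
           axis-aligned cells", {
  qs <- sapply(c(10, 20, 40, 80), function(s) {
    lab <- matrix(0L, s + 20, s + 20); lab[10 + 1:s, 10 + 1:s] <- 1L
    shape_factor(lab, px_um = 1)$shape_factor
  })
  expect_true(all(diff(abs(qs - 4)) < 0))
})

test_that("stress-fibre fraction normalises flags to the cell count", {
  lab <- matrix(rep(1:100, each = 16), 40, 40)  # 100 cells
  expect_equal(stress_fibre_fraction(10, lab)$percent, 10)
  expect_equal(stress_fibre_fraction(0, lab)$percent, 0)
  expect_error(stress_fibre_fraction(200, lab), "more flagged")
  # point annotations: one on a cell, one on background
  lab0 <- lab; lab0[1:4, 1:4] <- 0L
  pts <- data.frame(x_um = c(10, 1), y_um = c(10, 1))
  res <- stress_fibre_fraction(pts, lab0, px_um = 1)
  expect_equal(res$n_flagged, 1L)
  expect_equal(res$n_background, 1L)
})

test_that("microvilli length is the moment-fit minor axis, rotation
           invariant", {
  # 3 x 1 µm band at 0.05 µm pixels: semi-axes 30 and 10 px
  img <- 200 * ellipse_mask(100, 50.5, 50.5, 30, 10)
  res <- microvilli_length(img, px_um = 0.05, gaussian_sigma = 0)
  expect_equal(res$minor_um, 1.0, tolerance = 0.05)
  rot <- 200 * ellipse_mask(100, 50.5, 50.5, 30, 10, theta = pi / 4)
  res_rot <- microvilli_length(rot, px_um = 0.05, gaussian_sigma = 0)
  expect_equal(res_rot$minor_um, res$minor_um, tolerance = 0.02)
  # a disc is its own minor axis
  circ <- 200 * disc_mask(64, 32.5, 32.5, 15)
  res_c <- microvilli_length(circ, px_um = 0.1, gaussian_sigma = 0)
  expect_equal(res_c$minor_um, res_c$major_um, tolerance = 0.02)
  expect_equal(res_c$minor_um, 3.0, tolerance = 0.05)
  expect_error(microvilli_length(matrix(0, 32, 32), px_um = 0.1), "empty")
})

test_that("junctional/cytoplasmic ratio recovers the generated contrast", {
  ml <- gen_monolayer_images(density = 1000, field_size_um = 150, seed = 4)
  res <- junctional_cytoplasmic_ratio(ml, shrink_px = 1)
  expect_equal(res$ratio, 2.0)
  # uniform image gives exactly 1
  uni <- matrix(100, nrow(ml$labels), ncol(ml$labels))
  expect_equal(junctional_cytoplasmic_ratio(uni, ml$labels,
                                            shrink_px = 1)$ratio, 1.0)
  # additive offsets pull the ratio toward 1 (documented non-invariance)
  off <- ml$channels$junction + 100
  expect_lt(junctional_cytoplasmic_ratio(off, ml$labels,
                                         shrink_px = 1)$ratio, 2.0)
})

test_that("nuclear/cytoplasmic ratio recovers the generated contrast", {
  ml <- gen_monolayer_images(density = 1000, field_size_um = 150, seed = 5)
  expect_equal(nuclear_cytoplasmic_ratio(ml)$ratio, 3.0)
  uni <- matrix(80, nrow(ml$labels), ncol(ml$labels))
  expect_equal(nuclear_cytoplasmic_ratio(uni, ml$nuclei_mask)$ratio, 1.0)
  # masking more sub-threshold background leaves the ratio unchanged
  img <- ml$channels$nuclear_factor
  r1 <- nuclear_cytoplasmic_ratio(img, ml$nuclei_mask, threshold = 10)
  r2 <- nuclear_cytoplasmic_ratio(img, ml$nuclei_mask, threshold = 40)
  expect_equal(r1$ratio, r2$ratio)
})

test_that("thresholded junctional mean uses supra-threshold pixels only", {
  img <- matrix(0, 30, 30); img[1:3, ] <- 200
  expect_equal(thresholded_junctional_mean(img, threshold = 100)$mean, 200)
  expect_equal(thresholded_junctional_mean(matrix(150, 10, 10),
                                           threshold = 100)$mean, 150)
  ml <- gen_monolayer_images(density = 1000, field_size_um = 150,
                             intensities = list(nuclei = 150, junction = 180,
                                                cytoplasm = 100,
                                                nf_nuclear = 150,
                                                nf_cytoplasmic = 50),
                             seed = 6)
  expect_equal(thresholded_junctional_mean(ml$channels$junction)$mean, 180)
  expect_error(thresholded_junctional_mean(img, threshold = 300), "empty")
})

test_that("extrusion counting matches truth, with and without stage drift", {
  mv <- gen_extrusion_movie(n_cells = 500, extrusion_fraction = 0.02,
                            n_frames = 30, seed = 8)
  res <- count_extrusions(mv)
  expect_equal(res$count, 10L)
  expect_equal(res$percent_of_cells, 2.0)
  # no events
  mv0 <- gen_extrusion_movie(extrusion_fraction = 0, n_frames = 10,
                             seed = 8)
  expect_equal(count_extrusions(mv0)$count, 0L)
  # simulated stage drift is corrected by the alignment step
  drifted <- apply_drift(mv$frames, 7, -5)
  res_d <- count_extrusions(drifted, total_cells = 500)
  expect_equal(res_d$count, 10L)
  expect_error(count_extrusions(mv$frames[, , 1, drop = FALSE]), "frames")
})
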