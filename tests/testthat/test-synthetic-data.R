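# Generator contracts: determinism, analytic values, ground-truth coupling.

test_that("Hertz curve generator matches the closed-form force law", {
  # direct evaluation of F = (4/3) E sqrt(R) delta^{3/2} as the oracle
  oracle <- (4 / 3) * 694 * sqrt(10e-6) * (2.5e-6)^1.5
  expect_equal(hertz_force(2.5, 694, 10), oracle)
  expect_equal(oracle, 1.16e-8, tolerance = 0.005)

  # with a rigid cantilever the generated curve hits the oracle exactly
  cv <- gen_hertz_curve(694, k = 1e6, z_c = 1, max_displacement = 6,
                        n_points = 601)
  i <- which.min(abs(cv$data$z_um - 3.5))  # delta = 2.5 at z = 3.5
  expect_equal(cv$data$force_N[i], oracle, tolerance = 1e-6)

  # pre-contact baseline is exactly zero
  cv <- gen_hertz_curve(694, z_c = 2)
  expect_true(all(cv$data$force_N[cv$data$z_um <= 2] == 0))

  # the compliance-corrected depth reproduces the generating relation
  d <- cv$data[cv$data$z_um > 2, ]
  delta <- (d$z_um - 2) - d$force_N / 0.025 * 1e6
  expect_equal(d$force_N, hertz_force(delta, 694, 10), tolerance = 1e-9)
})

test_that("generators are pure functions of (config, seed)", {
  expect_identical(gen_hertz_curve(694, noise_level = 0.02, seed = 7),
                   gen_hertz_curve(694, noise_level = 0.02, seed = 7))
  expect_identical(gen_brillouin_spectrum(noise_level = 0.05, seed = 7),
                   gen_brillouin_spectrum(noise_level = 0.05, seed = 7))
  expect_identical(gen_z_profile(noise_sd = 0.002, seed = 7),
                   gen_z_profile(noise_sd = 0.002, seed = 7))
  a <- gen_monolayer_images(density = 1000, field_size_um = 150, seed = 7)
  b <- gen_monolayer_images(density = 1000, field_size_um = 150, seed = 7)
  expect_identical(a$labels, b$labels)
  expect_identical(gen_extrusion_movie(n_cells = 100, n_frames = 6,
                                       field_px = 96, seed = 7)$truth,
                   gen_extrusion_movie(n_cells = 100, n_frames = 6,
                                       field_px = 96, seed = 7)$truth)
  # different seeds differ
  expect_false(identical(
    gen_hertz_curve(694, noise_level = 0.02, seed = 1)$data,
    gen_hertz_curve(694, noise_level = 0.02, seed = 2)$data))
})

test_that("Brillouin doublet has the analytic peak height and symmetry", {
  sp <- gen_brillouin_spectrum(omega_B = 6.30, Gamma = 0.5, I0 = 1,
                               freq_axis = seq(-8, 8, by = 0.01))
  d <- sp$data
  # maxima at +-6.30 GHz
  expect_equal(abs(d$freq_GHz[which.max(d$intensity)]), 6.30)
  pos <- d[d$freq_GHz > 0, ]; neg <- d[d$freq_GHz < 0, ]
  expect_equal(pos$freq_GHz[which.max(pos$intensity)], 6.30)
  expect_equal(neg$freq_GHz[which.max(neg$intensity)], -6.30)
  # peak value I0 / (pi Gamma)
  expect_equal(max(d$intensity), 1 / (pi * 0.5), tolerance = 1e-12)
  # mirror symmetry about zero
  expect_equal(d$intensity, rev(d$intensity))
  # axis not covering both peaks is rejected
  expect_error(gen_brillouin_spectrum(freq_axis = seq(0, 8, by = 0.01)),
               "cover")
})

test_that("z-profile generator builds the stated peak and plateau families", {
  p <- gen_z_profile(gel_shift = 6.25, peak_shift = 6.40,
                     medium_shift = 6.10, peak_z = 20)
  expect_equal(max(p$data$shift_GHz), 6.40, tolerance = 1e-9)
  expect_equal(p$data$z_um[which.max(p$data$shift_GHz)], 20)
  q <- gen_z_profile(with_peak = FALSE)
  expect_true(all(diff(q$data$shift_GHz) <= 1e-12))
  expect_error(gen_z_profile(width = -1), "width")
})

test_that("shift map regions carry exact truth means and conserve the total", {
  m <- gen_shift_map(core_shift = 6.37, interstitium_shift = 6.33,
                     n_cells = 8, seed = 11)
  expect_equal(mean(m$grid[m$core_mask]), 6.37)
  expect_equal(mean(m$grid[!m$core_mask]), 6.33)
  n_c <- sum(m$core_mask); n_i <- sum(!m$core_mask)
  expect_equal((n_c * 6.37 + n_i * 6.33) / (n_c + n_i), mean(m$grid))
  # degenerate tessellation: one cell, ring interstitium at the border
  m1 <- gen_shift_map(n_cells = 1, seed = 3)
  expect_true(all(!m1$core_mask[1, ]) && all(!m1$core_mask[, 1]))
  expect_true(any(m1$core_mask))
  expect_error(gen_shift_map(step = 100, map_size = 50), "step")
})

test_that("monolayer images carry exact counts and intensity truths", {
  ml <- gen_monolayer_images(density = 3000, field_size_um = sqrt(1e5),
                             seed = 2)
  expect_identical(ml$truth$n_cells, 300)
  expect_equal(ml$truth$junctional_cytoplasmic_ratio, 2.0)
  # nuclei beyond the packing limit are rejected
  expect_error(gen_monolayer_images(density = 3000, nucleus_radius_um = 8),
               "packed")
})

test_that("POS stack truth has requested classes, margins and voxel volumes", {
  st <- gen_pos_stack(n_internalised = 12, n_bound = 8,
                      field_um = c(30, 30), seed = 4)
  tp <- st$truth$particles
  expect_equal(sum(tp$class == "internalised"), 12)
  expect_equal(sum(tp$class == "bound"), 8)
  cutoff <- st$truth$cutoff_um
  expect_true(all(tp$z_um[tp$class == "internalised"] < cutoff - 0.2))
  expect_true(all(tp$z_um[tp$class == "bound"] > cutoff + 0.2))
  # volumes are voxel counts times the voxel volume
  vv <- prod(st$voxel_size_um)
  expect_true(all(abs(tp$volume_um3 / vv - round(tp$volume_um3 / vv)) < 1e-9))
  expect_equal(st$truth$cutoff_um, 9.1)
  expect_warning(gen_pos_stack(n_internalised = 0, n_bound = 0,
                               field_um = c(10, 10)), "zero particles")
})

test_that("extrusion movie truth count follows the requested fraction", {
  mv <- gen_extrusion_movie(n_cells = 500, extrusion_fraction = 0.02,
                            n_frames = 10, field_px = 96, seed = 6)
  expect_identical(mv$truth$n_events, 10)
  mv0 <- gen_extrusion_movie(extrusion_fraction = 0, n_frames = 4,
                             field_px = 64, seed = 6)
  expect_identical(mv0$truth$n_events, 0)
  expect_error(gen_extrusion_movie(extrusion_fraction = 1.5), "fraction")
})

test_that("estimator error grows monotonically with generator noise", {
  # rank correlation between noise level and median recovery error
  levels <- c(0.005, 0.01, 0.02, 0.05, 0.1)
  err_h <- sapply(levels, function(nl) {
    median(sapply(1:5, function(s) {
      cv <- gen_hertz_curve(694, noise_level = nl, seed = 100 * s)
      abs(analyze_curve(cv)$E_eff_Pa - 694)
    }))
  })
  expect_gt(cor(seq_along(levels), err_h, method = "spearman"), 0)
  err_b <- sapply(levels, function(nl) {
    median(sapply(1:5, function(s) {
      sp <- gen_brillouin_spectrum(6.30, noise_level = nl, seed = 100 * s)
      abs(fit_spectrum(sp)$omega_B_GHz - 6.30)
    }))
  })
  expect_gt(cor(seq_along(levels), err_b, method = "spearman"), 0)
})
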