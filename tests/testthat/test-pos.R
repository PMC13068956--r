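# POS internalisation: surface, 3D segmentation, classification, summaries,
# apical area.

test_that("apical surface height and cut-off recover the generated truth", {
  st <- gen_pos_stack(n_internalised = 5, n_bound = 5, field_um = c(20, 20),
                      seed = 1)
  surf <- build_apical_surface(st)
  expect_equal(surf$cutoff_um, 9.1)
  expect_equal(surf$missing_fraction, 0)
  # tilted plane from 8 to 10 µm averages to 9 (mean of a linear ramp)
  nx <- 80
  hm <- matrix(rep(seq(8, 10, length.out = nx), nx), nx, nx)
  st2 <- suppressWarnings(
    gen_pos_stack(n_internalised = 0, n_bound = 0, field_um = c(20, 20),
                  voxel_size = c(0.25, 0.25, 0.1), height_map = hm))
  surf2 <- build_apical_surface(st2)
  expect_equal(surf2$cutoff_um, 9.0, tolerance = 0.01)
  # empty channel errors
  empty <- array(0, dim = c(8, 8, 8))
  expect_error(build_apical_surface(empty, voxel_size_um = c(1, 1, 1)),
               "empty")
})

test_that("3D segmentation finds every non-touching particle with exact
           voxel volumes", {
  st <- gen_pos_stack(n_internalised = 12, n_bound = 8,
                      field_um = c(30, 30), seed = 2)
  pp <- segment_particles(st)
  expect_equal(nrow(pp), 20)
  # voxel-count volumes match truth (both sides quantised identically)
  expect_equal(sort(pp$volume_um3), sort(st$truth$particles$volume_um3),
               tolerance = 1e-9)
  # volume = n_voxels x voxel volume
  expect_equal(pp$volume_um3, pp$n_voxels * prod(st$voxel_size_um))
  # an 8-voxel particle at 0.05 µm^3 voxels has volume 0.4
  a <- array(0, dim = c(6, 6, 6)); a[2:3, 2:3, 2:3] <- 100
  p8 <- segment_particles(a, voxel_size_um = c(0.5, 0.5, 0.2),
                          threshold = 50)
  expect_equal(p8$volume_um3, 8 * 0.05)
  # sub-min_voxels speckle removed
  a[6, 6, 6] <- 100
  expect_equal(nrow(segment_particles(a, voxel_size_um = c(0.5, 0.5, 0.2),
                                      threshold = 50, min_voxels = 4)), 1)
  # 26-connectivity joins diagonal neighbours
  b <- array(0, dim = c(4, 4, 4)); b[1, 1, 1] <- 1; b[2, 2, 2] <- 1
  expect_equal(max(epimech:::label_components_3d(b > 0)), 1)
})

test_that("classification by centroid against the cut-off is exhaustive,
           tie goes to bound, monotone in the cut-off", {
  st <- gen_pos_stack(n_internalised = 12, n_bound = 8,
                      field_um = c(30, 30), seed = 3)
  pp <- segment_particles(st)
  cl <- classify_particles(pp, build_apical_surface(st))
  expect_equal(sum(cl$class == "internalised"), 12)
  expect_equal(sum(cl$class == "bound"), 8)
  # partition: every particle in exactly one class
  expect_equal(sum(cl$class %in% c("internalised", "bound")), nrow(cl))
  # tie-break: centroid exactly at the cut-off is bound
  one <- data.frame(id = 1, x_um = 1, y_um = 1, z_um = 5, volume_um3 = 1)
  expect_equal(classify_particles(one, 5)$class, "bound")
  # monotonicity in the cut-off
  cuts <- seq(0, 20, by = 0.5)
  n_int <- sapply(cuts, function(ct)
    sum(classify_particles(pp, ct)$class == "internalised"))
  expect_true(all(diff(n_int) >= 0))
  expect_equal(n_int[length(n_int)], nrow(pp))  # cut-off above all: all internalised
})

test_that("classes remain correct under 2% intensity noise", {
  mis <- sapply(1:20, function(s) {
    st <- gen_pos_stack(n_internalised = 15, n_bound = 10,
                        field_um = c(32, 32), noise_level = 0.02, seed = s)
    pp <- segment_particles(st)
    cl <- classify_particles(pp, build_apical_surface(st))
    truth <- st$truth$particles
    # match by nearest truth centroid
    wrong <- 0
    for (i in seq_len(nrow(cl))) {
      j <- which.min((truth$x_um - cl$x_um[i])^2 +
                     (truth$y_um - cl$y_um[i])^2 +
                     (truth$z_um - cl$z_um[i])^2)
      if (truth$class[j] != cl$class[i]) wrong <- wrong + 1
    }
    c(wrong, nrow(cl))
  })
  expect_lt(sum(mis[1, ]) / sum(mis[2, ]), 0.02)
})

test_that("internalisation summary reports counts, mean volumes and
           per-cell normalisation", {
  v <- rep(c(1, 2, 3), 10)
  pp <- data.frame(id = 1:35, volume_um3 = c(v, rep(2, 5)),
                   class = rep(c("internalised", "bound"), c(30, 5)))
  s <- summarize_internalisation(pp, cell_count = 30)
  expect_equal(s$n_internalised, 30)
  expect_equal(s$n_bound, 5)
  expect_equal(s$mean_volume_internalised, 2.0)
  expect_equal(s$per_cell, 1.0)
  # empty class flagged as NA
  pp2 <- pp[pp$class == "internalised", ]
  expect_true(is.na(summarize_internalisation(pp2)$mean_volume_bound))
  # conservation on a generated fixture
  st <- gen_pos_stack(n_internalised = 6, n_bound = 4, field_um = c(25, 25),
                      seed = 9)
  cl <- classify_particles(segment_particles(st), build_apical_surface(st))
  s2 <- summarize_internalisation(cl)
  expect_equal(s2$n_internalised + s2$n_bound, nrow(cl))
})

test_that("apical area equals the footprint for flat surfaces and grows
           with corrugation, matching the analytic mesh oracle", {
  st <- suppressWarnings(
    gen_pos_stack(n_internalised = 0, n_bound = 0, field_um = c(25, 25),
                  seed = 1))
  aa <- apical_actin_area(st)
  expect_equal(aa$area_um2, aa$footprint_um2)
  # corrugated surface: strictly larger area, matching the oracle on the
  # truth height map within 1%
  nx <- 100
  xs <- (seq_len(nx) - 0.5) * 0.25
  hm <- 9 + 0.8 * sin(outer(xs, xs, function(a, b) a / 2 + b / 3))
  stc <- suppressWarnings(
    gen_pos_stack(n_internalised = 0, n_bound = 0, field_um = c(25, 25),
                  voxel_size = c(0.25, 0.25, 0.05), height_map = hm))
  ac <- apical_actin_area(stc)
  expect_gt(ac$area_um2, ac$footprint_um2)
  oracle <- epimech:::height_map_area(hm, 0.25, 0.25)
  expect_equal(ac$area_um2, oracle, tolerance = 0.01)
  expect_error(apical_actin_area(st, slices = 10000), "subset")
})

test_that("volume is conserved between the label field and the particle
           table", {
  st <- gen_pos_stack(n_internalised = 8, n_bound = 6, field_um = c(25, 25),
                      seed = 12)
  pp <- segment_particles(st, min_voxels = 1)
  labs <- attr(pp, "labels")
  expect_equal(sum(pp$n_voxels), sum(labs > 0))
  expect_equal(sum(pp$volume_um3),
               sum(labs > 0) * prod(st$voxel_size_um))
})
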