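# Seeded synthetic-data generators. Every generator is a pure function of its
# arguments and `seed`, and returns the dataset together with a `truth` list
# holding the ground-truth parameters, so every analysis operation in the
# package can be tested for parameter recovery without instrument data.
#
# Noise model: additive Gaussian. For instrument-like signals (force curves,
# spectra, images) the standard deviation is `noise_level` times the signal
# amplitude; for Brillouin shift profiles and maps, whose natural scale is
# absolute GHz, the standard deviation is given directly as `noise_sd` (GHz).

#' Lorentzian Brillouin line shape
#'
#' Spectral density of a Brillouin peak,
#' \deqn{I(\omega) = \frac{I_0}{\pi}\,
#'   \frac{\Gamma \omega_B^2}{(\omega^2-\omega_B^2)^2 + \Gamma^2\omega_B^2}.}
#' Because the expression depends on \eqn{\omega^2} only, evaluating it on a
#' signed frequency axis yields the mirror-symmetric Stokes/anti-Stokes
#' doublet at \eqn{\pm\omega_B}. The peak value at \eqn{\omega = \omega_B} is
#' \eqn{I_0/(\pi\Gamma)}.
#'
#' @param omega Frequency axis (GHz), signed.
#' @param omega_B Brillouin shift magnitude (GHz).
#' @param Gamma Linewidth (GHz).
#' @param I0 Integrated amplitude (counts GHz).
#' @return Intensity at `omega`.
#' @export
brillouin_lorentzian <- function(omega, omega_B, Gamma, I0) {
  (I0 / pi) * Gamma * omega_B^2 /
    ((omega^2 - omega_B^2)^2 + Gamma^2 * omega_B^2)
}

#' Hertzian force for a spherical probe
#'
#' \eqn{F = \tfrac{4}{3} E_{\mathrm{eff}} \sqrt{R}\, \delta^{3/2}} with all
#' lengths in metres internally; `R_um` and `delta_um` are given in
#' micrometres and the force is returned in newtons.
#'
#' @param delta_um Indentation depth (µm), non-negative.
#' @param E_eff Effective Young's modulus (Pa).
#' @param R_um Probe radius (µm).
#' @return Force (N).
#' @export
hertz_force <- function(delta_um, E_eff, R_um) {
  (4 / 3) * E_eff * sqrt(R_um * 1e-6) * pmax(delta_um * 1e-6, 0)^1.5
}

#' Generate a synthetic force-indentation curve
#'
#' Emulates a displacement-controlled indentation of a soft monolayer with a
#' spherical probe. Before contact (`z < z_c`) the force is zero; past
#' contact the force follows the Hertz model with the cantilever compliance
#' taken into account, i.e. the indentation depth solves
#' \eqn{\delta = (z - z_c) - F/k} with \eqn{F = \tfrac43 E \sqrt{R}
#' \delta^{3/2}}. The implicit relation is solved by damped fixed-point
#' iteration (the map is contractive for physical parameters).
#'
#' @param E_eff True effective Young's modulus (Pa).
#' @param R_um Probe radius (µm); default 10 (20 µm diameter sphere).
#' @param k Cantilever stiffness (N/m); default 0.025.
#' @param z_c True contact point (µm).
#' @param max_displacement Piezo travel (µm); default 6.
#' @param n_points Samples along the loading ramp.
#' @param noise_level Gaussian noise s.d. as a fraction of the maximum force.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `fi_curve` with elements `data` (data.frame
#'   `z_um`, `force_N`), `R_um`, `k_N_per_m` and `truth`.
#' @export
gen_hertz_curve <- function(E_eff, R_um = 10, k = 0.025, z_c = 1,
                            max_displacement = 6, n_points = 601,
                            noise_level = 0, seed = NULL) {
  check_positive(E_eff, "E_eff"); check_positive(R_um, "R_um")
  check_positive(k, "k"); check_fraction(noise_level, "noise_level")
  if (!is.numeric(z_c) || z_c < 0 || z_c >= max_displacement)
    abort("`z_c` must satisfy 0 <= z_c < max_displacement")
  z <- seq(0, max_displacement, length.out = n_points)
  F <- numeric(n_points)
  past <- z > z_c
  if (any(past)) {
    zz <- z[past]
    Fi <- hertz_force(zz - z_c, E_eff, R_um)  # compliance-free start
    for (iter in 1:200) {
      delta <- (zz - z_c) - (Fi / k) * 1e6    # F/k in m -> µm
      Fn <- hertz_force(delta, E_eff, R_um)
      if (max(abs(Fn - Fi)) < 1e-18) { Fi <- Fn; break }
      Fi <- (Fi + Fn) / 2
    }
    F[past] <- Fi
  }
  truth <- list(E_eff_Pa = E_eff, z_c_um = z_c, R_um = R_um, k_N_per_m = k,
                noise_level = noise_level)
  if (noise_level > 0) {
    sd <- noise_level * max(F)
    F <- with_seed(seed, F + stats::rnorm(length(F), 0, sd))
  }
  structure(list(data = data.frame(z_um = z, force_N = F),
                 R_um = R_um, k_N_per_m = k, truth = truth),
            class = "fi_curve")
}

#' Generate a synthetic Stokes/anti-Stokes Brillouin doublet
#'
#' @param omega_B True Brillouin shift (GHz).
#' @param Gamma True linewidth (GHz).
#' @param I0 True integrated amplitude.
#' @param freq_axis Signed frequency axis (GHz); must cover both
#'   \eqn{+\omega_B} and \eqn{-\omega_B}.
#' @param noise_level Gaussian noise s.d. as a fraction of the peak height.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `brillouin_spectrum` with `data` (data.frame
#'   `freq_GHz`, `intensity`) and `truth`.
#' @export
gen_brillouin_spectrum <- function(omega_B = 6.30, Gamma = 0.5, I0 = 1,
                                   freq_axis = seq(-8, 8, by = 0.01),
                                   noise_level = 0, seed = NULL) {
  check_positive(omega_B, "omega_B"); check_positive(Gamma, "Gamma")
  check_positive(I0, "I0"); check_fraction(noise_level, "noise_level")
  if (min(freq_axis) > -omega_B || max(freq_axis) < omega_B)
    abort("`freq_axis` must cover both -omega_B and +omega_B")
  intensity <- brillouin_lorentzian(freq_axis, omega_B, Gamma, I0)
  if (noise_level > 0) {
    sd <- noise_level * I0 / (pi * Gamma)
    intensity <- with_seed(seed,
      intensity + stats::rnorm(length(intensity), 0, sd))
  }
  structure(list(data = data.frame(freq_GHz = freq_axis, intensity = intensity),
                 truth = list(omega_B_GHz = omega_B, Gamma_GHz = Gamma,
                              I0 = I0, noise_level = noise_level)),
            class = "brillouin_spectrum")
}

#' Generate a synthetic Brillouin z-scan profile
#'
#' Emulates an axial scan through hydrogel, monolayer and medium: a plateau
#' at `gel_shift` decays sigmoidally to `medium_shift`, and (optionally) a
#' Gaussian bump raises the profile to exactly `peak_shift` at `peak_z`,
#' mimicking the stiff basal side of the monolayer. With `with_peak = FALSE`
#' the profile is a monotone non-increasing gel-to-medium transition, the
#' family handled by the plateau branch of [analyze_z_profile()].
#'
#' @param gel_shift,peak_shift,medium_shift Shifts (GHz) of the hydrogel
#'   plateau, the monolayer peak and the medium plateau.
#' @param peak_z Peak position (µm).
#' @param width Gaussian peak s.d. (µm).
#' @param z_step,z_range Axial sampling (µm); defaults 2 and 80.
#' @param transition_z,transition_width Centre and scale (µm) of the sigmoid
#'   gel-to-medium transition.
#' @param with_peak Logical; include the monolayer peak?
#' @param noise_sd Gaussian noise s.d. in GHz (absolute).
#' @param seed Integer seed or `NULL`.
#' @return A list of class `z_profile` with `data` (data.frame `z_um`,
#'   `shift_GHz`) and `truth`.
#' @export
gen_z_profile <- function(gel_shift = 6.25, peak_shift = 6.40,
                          medium_shift = 6.10, peak_z = 20, width = 6,
                          z_step = 2, z_range = 80,
                          transition_z = peak_z + 12, transition_width = 5,
                          with_peak = TRUE, noise_sd = 0, seed = NULL) {
  check_positive(width, "width"); check_positive(z_step, "z_step")
  check_fraction(noise_sd, "noise_sd")
  if (transition_width <= 0) abort("`transition_width` must be positive")
  z <- seq(0, z_range, by = z_step)
  base <- medium_shift + (gel_shift - medium_shift) /
    (1 + exp((z - transition_z) / transition_width))
  shift <- base
  if (isTRUE(with_peak)) {
    amp <- peak_shift - base[which.min(abs(z - peak_z))]
    if (amp <= 0) abort("`peak_shift` must exceed the baseline at `peak_z`")
    shift <- base + amp * exp(-(z - peak_z)^2 / (2 * width^2))
  }
  if (noise_sd > 0)
    shift <- with_seed(seed, shift + stats::rnorm(length(shift), 0, noise_sd))
  structure(list(data = data.frame(z_um = z, shift_GHz = shift),
                 truth = list(with_peak = isTRUE(with_peak),
                              gel_shift_GHz = gel_shift,
                              peak_shift_GHz = if (isTRUE(with_peak)) peak_shift,
                              peak_z_um = if (isTRUE(with_peak)) peak_z,
                              medium_shift_GHz = medium_shift,
                              noise_sd_GHz = noise_sd)),
            class = "z_profile")
}

# Voronoi labelling of a pixel grid by nearest seed point (squared Euclidean).
voronoi_labels <- function(xs, ys, seeds_x, seeds_y) {
  nx <- length(xs); ny <- length(ys)
  lab <- matrix(0L, nx, ny)
  px <- matrix(xs, nx, ny)
  py <- matrix(ys, nx, ny, byrow = TRUE)
  best <- matrix(Inf, nx, ny)
  for (s in seq_along(seeds_x)) {
    d2 <- (px - seeds_x[s])^2 + (py - seeds_y[s])^2
    take <- d2 < best
    lab[take] <- s
    best[take] <- d2[take]
  }
  lab
}

# TRUE where a 4-neighbour carries a different label, or on the map border.
label_boundary <- function(lab) {
  nx <- nrow(lab); ny <- ncol(lab)
  b <- matrix(FALSE, nx, ny)
  b[-1, ] <- b[-1, ] | (lab[-1, ] != lab[-nx, ])
  b[-nx, ] <- b[-nx, ] | (lab[-nx, ] != lab[-1, ])
  b[, -1] <- b[, -1] | (lab[, -1] != lab[, -ny])
  b[, -ny] <- b[, -ny] | (lab[, -ny] != lab[, -1])
  b[1, ] <- TRUE; b[nx, ] <- TRUE; b[, 1] <- TRUE; b[, ny] <- TRUE
  b
}

# Binary dilation of a logical matrix by a disc of radius r pixels (r >= 0).
dilate_disc <- function(mask, r) {
  if (r <= 0) return(mask)
  sz <- 2L * as.integer(ceiling(r)) + 1L
  brush <- EBImage::makeBrush(sz, shape = "disc")
  EBImage::dilate(EBImage::Image(mask * 1), brush) > 0.5
}

#' Generate a synthetic Brillouin shift raster map
#'
#' A Voronoi tessellation over the field gives the cell layout; eroded cell
#' interiors form the "core" region at `core_shift` and the boundary band the
#' "interstitium" at `interstitium_shift`, emulating the mechanical
#' compartmentalisation seen in basal raster scans. With `n_cells = 1` the
#' whole field is one core surrounded by a ring of interstitium at the map
#' border.
#'
#' @param core_shift,interstitium_shift Region shifts (GHz).
#' @param n_cells Number of Voronoi seed points (>= 1).
#' @param map_size Field side length (µm); default 50.
#' @param step Lateral step (µm); default 1.5.
#' @param band_px Half-width of the interstitial band (pixels).
#' @param noise_sd Gaussian noise s.d. in GHz.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `shift_map` with `grid` (matrix, GHz), `step_um`,
#'   `core_mask` (logical matrix ground truth) and `truth`.
#' @export
gen_shift_map <- function(core_shift = 6.37, interstitium_shift = 6.33,
                          n_cells = 12, map_size = 50, step = 1.5,
                          band_px = 1, noise_sd = 0, seed = NULL) {
  if (n_cells < 1) abort("`n_cells` must be >= 1")
  if (step > map_size) abort("`step` must not exceed `map_size`")
  check_fraction(noise_sd, "noise_sd")
  xs <- seq(0, map_size, by = step); ys <- xs
  res <- with_seed(seed, {
    sx <- stats::runif(n_cells, 0, map_size)
    sy <- stats::runif(n_cells, 0, map_size)
    lab <- voronoi_labels(xs, ys, sx, sy)
    interstitium <- dilate_disc(label_boundary(lab), band_px - 1)
    core <- !interstitium
    grid <- matrix(interstitium_shift, length(xs), length(ys))
    grid[core] <- core_shift
    if (noise_sd > 0)
      grid <- grid + stats::rnorm(length(grid), 0, noise_sd)
    list(grid = grid, core = core, labels = lab)
  })
  structure(list(grid = res$grid, step_um = step, core_mask = res$core,
                 labels = res$labels,
                 truth = list(core_shift_GHz = core_shift,
                              interstitium_shift_GHz = interstitium_shift,
                              n_cells = n_cells, noise_sd_GHz = noise_sd)),
            class = "shift_map")
}

#' Generate synthetic epithelial monolayer images
#'
#' Builds a Voronoi-tessellated confluent field (a geometric fixture, not a
#' biophysical model) with one nucleus per cell and four intensity channels:
#' `nuclei` (nuclear stain), `junction` (junctional marker over cytoplasmic
#' background), `cytoplasm` (uniform cytoplasmic stain) and `nuclear_factor`
#' (a nucleocytoplasmic shuttling factor, e.g. MRTFA). Ground truth carries
#' the label map, nucleus centres/count, and the set intensities.
#'
#' Seeds are placed on a jittered square grid so that nuclei can never touch;
#' a nucleus radius beyond the packing limit of that grid is rejected.
#'
#' @param density Cell density (cells/mm^2).
#' @param field_size_um Field side length (µm); default `sqrt(1e5)` so that
#'   the field area is 0.1 mm^2.
#' @param px_um Pixel size (µm).
#' @param nucleus_radius_um Nucleus radius (µm).
#' @param junction_width_um Full width of the junctional band (µm).
#' @param intensities Named list: `nuclei`, `junction`, `cytoplasm`,
#'   `nf_nuclear`, `nf_cytoplasmic`.
#' @param noise_level Gaussian noise s.d. as a fraction of each channel's
#'   peak intensity.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `monolayer_images` with `channels` (named list of
#'   intensity matrices), `labels` (integer matrix), `nuclei_mask` (logical
#'   matrix), `px_um` and `truth`.
#' @export
gen_monolayer_images <- function(density = 3000,
                                 field_size_um = sqrt(1e5),
                                 px_um = 0.5,
                                 nucleus_radius_um = 3,
                                 junction_width_um = 1.5,
                                 intensities = list(nuclei = 150,
                                                    junction = 200,
                                                    cytoplasm = 100,
                                                    nf_nuclear = 150,
                                                    nf_cytoplasmic = 50),
                                 noise_level = 0, seed = NULL) {
  check_positive(density, "density"); check_positive(px_um, "px_um")
  check_fraction(noise_level, "noise_level")
  area_mm2 <- (field_size_um / 1000)^2
  n_cells <- round(density * area_mm2)
  if (n_cells < 1) abort("field too small: density * area < 1 cell")
  ng <- ceiling(sqrt(n_cells))
  spacing <- field_size_um / ng
  # jitter of at most spacing/4 keeps any two seeds >= spacing/2 apart
  if (2 * nucleus_radius_um >= spacing / 2)
    abort("nuclei of radius %.2g um cannot be packed without overlap at %.0f cells/mm^2",
          nucleus_radius_um, density)
  res <- with_seed(seed, {
    centres <- expand.grid(gx = seq_len(ng) - 0.5, gy = seq_len(ng) - 0.5)
    keep <- sample.int(nrow(centres), n_cells)
    sx <- centres$gx[keep] * spacing +
      stats::runif(n_cells, -spacing / 4, spacing / 4)
    sy <- centres$gy[keep] * spacing +
      stats::runif(n_cells, -spacing / 4, spacing / 4)
    npx <- round(field_size_um / px_um)
    xs <- (seq_len(npx) - 0.5) * px_um
    lab <- voronoi_labels(xs, xs, sx, sy)
    junction_band <- dilate_disc(label_boundary(lab),
                                 junction_width_um / (2 * px_um) - 0.5)
    px_mat <- matrix(xs, npx, npx)
    py_mat <- matrix(xs, npx, npx, byrow = TRUE)
    nuclei_mask <- matrix(FALSE, npx, npx)
    for (s in seq_len(n_cells)) {
      near <- abs(px_mat - sx[s]) <= nucleus_radius_um &
              abs(py_mat - sy[s]) <= nucleus_radius_um
      hit <- near & ((px_mat - sx[s])^2 + (py_mat - sy[s])^2 <=
                       nucleus_radius_um^2)
      nuclei_mask <- nuclei_mask | hit
    }
    chan <- list(
      nuclei = intensities$nuclei * nuclei_mask,
      junction = ifelse(junction_band, intensities$junction,
                        intensities$cytoplasm),
      cytoplasm = matrix(intensities$cytoplasm, npx, npx),
      nuclear_factor = ifelse(nuclei_mask, intensities$nf_nuclear,
                              intensities$nf_cytoplasmic)
    )
    if (noise_level > 0)
      chan <- lapply(chan, function(m)
        m + stats::rnorm(length(m), 0, noise_level * max(m)))
    list(chan = chan, lab = lab, nuclei = nuclei_mask, sx = sx, sy = sy)
  })
  structure(list(channels = res$chan, labels = res$lab,
                 nuclei_mask = res$nuclei, px_um = px_um,
                 field_size_um = field_size_um,
                 truth = list(n_cells = n_cells,
                              density_cells_mm2 = n_cells / area_mm2,
                              nucleus_x_um = res$sx, nucleus_y_um = res$sy,
                              intensities = intensities,
                              junctional_cytoplasmic_ratio =
                                intensities$junction / intensities$cytoplasm,
                              nuclear_cytoplasmic_ratio =
                                intensities$nf_nuclear / intensities$nf_cytoplasmic)),
            class = "monolayer_images")
}

#' Generate a synthetic 3D stack with apical actin surface and POS particles
#'
#' The actin channel contains an apical cortex band whose upper surface sits
#' at `monolayer_height` (optionally corrugated via `height_map`); the POS
#' channel contains non-touching ellipsoidal particles whose centroids lie
#' strictly below (internalised) or above (bound) the mean surface height,
#' with at least a one-voxel margin so the true class is unambiguous.
#'
#' @param n_internalised,n_bound Particle counts per class.
#' @param particle_volume_range Range (µm^3) for requested particle volumes.
#' @param monolayer_height Mean apical surface height (µm).
#' @param voxel_size Voxel size (µm), length-3 `(dx, dy, dz)`.
#' @param field_um Lateral field size (µm), length-2.
#' @param stack_top_um Top of the stack (µm); default leaves head room above
#'   the surface for bound particles.
#' @param height_map Optional matrix of surface heights (µm) per (x, y)
#'   column, overriding the flat surface (its mean then defines the truth
#'   cutoff).
#' @param noise_level Gaussian noise s.d. as a fraction of channel intensity.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `pos_stack` with `actin` and `pos` 3D arrays,
#'   `voxel_size_um` and `truth` (classes, centroids, voxelised volumes,
#'   surface height map).
#' @export
gen_pos_stack <- function(n_internalised = 30, n_bound = 20,
                          particle_volume_range = c(0.3, 1.2),
                          monolayer_height = 9.1,
                          voxel_size = c(0.25, 0.25, 0.2),
                          field_um = c(40, 40),
                          stack_top_um = monolayer_height + 8,
                          height_map = NULL,
                          noise_level = 0, seed = NULL) {
  if (n_internalised < 0 || n_bound < 0) abort("particle counts must be >= 0")
  if (n_internalised + n_bound == 0)
    warning("zero particles requested in both classes", call. = FALSE)
  check_fraction(noise_level, "noise_level")
  dx <- voxel_size[1]; dy <- voxel_size[2]; dz <- voxel_size[3]
  nx <- round(field_um[1] / dx); ny <- round(field_um[2] / dy)
  nz <- round(stack_top_um / dz)
  xs <- (seq_len(nx) - 0.5) * dx
  ys <- (seq_len(ny) - 0.5) * dy
  zs <- (seq_len(nz) - 0.5) * dz
  if (is.null(height_map)) {
    hmap <- matrix(monolayer_height, nx, ny)
  } else {
    stopifnot(nrow(height_map) == nx, ncol(height_map) == ny)
    hmap <- height_map
  }
  cutoff <- mean(hmap)
  actin <- array(0, dim = c(nx, ny, nz))
  band <- 1.5  # apical cortex thickness, µm
  for (j in seq_len(ny)) {
    top <- hmap[, j]
    for (i in seq_len(nx)) {
      sel <- zs <= top[i] & zs > top[i] - band
      actin[i, j, sel] <- 200
    }
  }
  res <- with_seed(seed, {
    pos <- array(0, dim = c(nx, ny, nz))
    n_tot <- n_internalised + n_bound
    cls <- rep(c("internalised", "bound"), c(n_internalised, n_bound))
    margin <- max(2 * dz, 0.6)
    placed <- matrix(numeric(0), ncol = 3)
    info <- vector("list", n_tot)
    for (p in seq_len(n_tot)) {
      vol <- stats::runif(1, particle_volume_range[1], particle_volume_range[2])
      r <- (3 * vol / (4 * pi))^(1 / 3)          # sphere-equivalent radius
      ax <- r * stats::runif(1, 0.8, 1.25)       # mild anisotropy
      az <- vol * 3 / (4 * pi * ax^2)
      for (try in 1:2000) {
        cx <- stats::runif(1, ax + dx, field_um[1] - ax - dx)
        cy <- stats::runif(1, ax + dy, field_um[2] - ax - dy)
        cz <- if (cls[p] == "internalised")
          stats::runif(1, az + dz, cutoff - margin) else
          stats::runif(1, cutoff + margin, stack_top_um - az - dz)
        ok <- nrow(placed) == 0 ||
          all(sqrt((placed[, 1] - cx)^2 + (placed[, 2] - cy)^2 +
                   (placed[, 3] - cz)^2) > 2 * max(ax, az) + 3 * max(dx, dz))
        if (ok) break
        if (try == 2000) abort("could not place particles without contact")
      }
      placed <- rbind(placed, c(cx, cy, cz))
      ix <- which(abs(xs - cx) <= ax); iy <- which(abs(ys - cy) <= ax)
      iz <- which(abs(zs - cz) <= az)
      nvox <- 0L
      for (k in iz) for (j in iy) {
        sel <- ((xs[ix] - cx)^2 + (ys[j] - cy)^2) / ax^2 +
          (zs[k] - cz)^2 / az^2 <= 1
        if (any(sel)) { pos[ix[sel], j, k] <- 180; nvox <- nvox + sum(sel) }
      }
      info[[p]] <- data.frame(id = p, x_um = cx, y_um = cy, z_um = cz,
                              volume_um3 = nvox * dx * dy * dz,
                              class = cls[p])
    }
    truth_particles <- if (n_tot > 0) do.call(rbind, info) else
      data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                 z_um = numeric(), volume_um3 = numeric(), class = character())
    if (noise_level > 0) {
      actin <- actin + stats::rnorm(length(actin), 0, noise_level * 200)
      pos <- pos + stats::rnorm(length(pos), 0, noise_level * 180)
    }
    list(actin = actin, pos = pos, particles = truth_particles)
  })
  structure(list(actin = res$actin, pos = res$pos,
                 voxel_size_um = voxel_size,
                 truth = list(particles = res$particles,
                              n_internalised = n_internalised,
                              n_bound = n_bound,
                              surface_height_um = hmap,
                              cutoff_um = cutoff)),
            class = "pos_stack")
}

#' Generate a synthetic extrusion time-lapse movie
#'
#' Frames share a fixed smooth background texture (so translation
#' registration has structure to lock onto) plus per-frame noise; extrusion
#' events appear as very bright Gaussian spots at random positions and
#' frames. Event positions keep a minimum separation so a maximum-intensity
#' projection preserves the event count.
#'
#' @param n_cells Number of cells in the field (used for the truth fraction).
#' @param extrusion_fraction Fraction of cells extruding (0..1).
#' @param n_frames Number of frames.
#' @param field_px Field side length (pixels).
#' @param spot_sigma_px Gaussian spot s.d. (pixels).
#' @param spot_intensity Peak added intensity of a spot.
#' @param background_sd Per-frame Gaussian noise s.d.
#' @param seed Integer seed or `NULL`.
#' @return A list of class `extrusion_movie` with `frames` (3D array
#'   x, y, t), `n_cells` and `truth` (event table and count).
#' @export
gen_extrusion_movie <- function(n_cells = 500, extrusion_fraction = 0.02,
                                n_frames = 60, field_px = 192,
                                spot_sigma_px = 2.5, spot_intensity = 255,
                                background_sd = 4, seed = NULL) {
  if (extrusion_fraction < 0 || extrusion_fraction > 1)
    abort("`extrusion_fraction` must be in [0, 1]")
  n_events <- round(n_cells * extrusion_fraction)
  res <- with_seed(seed, {
    # static texture: blurred white noise, gives registration features
    tex <- matrix(stats::rnorm(field_px^2), field_px, field_px)
    tex <- as.matrix(EBImage::gblur(EBImage::Image(tex), sigma = 4))
    tex <- 40 + (tex - mean(tex)) / stats::sd(tex) * 10
    ev_x <- numeric(0); ev_y <- numeric(0)
    min_sep <- 8 * spot_sigma_px
    tries <- 0L
    while (length(ev_x) < n_events) {
      if ((tries <- tries + 1L) > 10000L)
        abort("cannot place %d separated events in a %d px field",
              n_events, field_px)
      x <- stats::runif(1, 6 * spot_sigma_px, field_px - 6 * spot_sigma_px)
      y <- stats::runif(1, 6 * spot_sigma_px, field_px - 6 * spot_sigma_px)
      if (length(ev_x) == 0 ||
          all(sqrt((ev_x - x)^2 + (ev_y - y)^2) > min_sep)) {
        ev_x <- c(ev_x, x); ev_y <- c(ev_y, y)
      }
    }
    ev_t <- if (n_events > 0) sample.int(n_frames, n_events, replace = TRUE)
            else integer(0)
    frames <- array(0, dim = c(field_px, field_px, n_frames))
    ix <- matrix(seq_len(field_px), field_px, field_px)
    iy <- t(ix)
    for (t in seq_len(n_frames)) {
      f <- tex + matrix(stats::rnorm(field_px^2, 0, background_sd),
                        field_px, field_px)
      for (e in which(ev_t == t)) {
        f <- f + spot_intensity *
          exp(-((ix - ev_x[e])^2 + (iy - ev_y[e])^2) / (2 * spot_sigma_px^2))
      }
      frames[, , t] <- f
    }
    list(frames = frames,
         events = data.frame(frame = ev_t, x_px = ev_x, y_px = ev_y))
  })
  structure(list(frames = res$frames, n_cells = n_cells,
                 truth = list(n_events = n_events, events = res$events,
                              fraction = extrusion_fraction)),
            class = "extrusion_movie")
}

#' Generate a binary cross-section slab mask
#'
#' A uniform x-z slab of given thickness, the fixture used by
#' [measure_cell_height()]: all columns span the same vertical extent.
#'
#' @param thickness_um Slab thickness (µm).
#' @param axial_px_um Axial pixel size (µm).
#' @param lateral_px Number of lateral columns.
#' @param z_px Total axial extent (pixels); defaults to twice the slab.
#' @param z_offset_px Axial offset of the slab top (pixels).
#' @return A list of class `cross_section` with `mask` (logical matrix,
#'   rows = lateral, cols = axial), `axial_px_um` and `truth`.
#' @export
gen_cross_section_slab <- function(thickness_um, axial_px_um = 0.1,
                                   lateral_px = 200, z_px = NULL,
                                   z_offset_px = 5) {
  check_positive(thickness_um, "thickness_um")
  n_thick <- round(thickness_um / axial_px_um)
  if (is.null(z_px)) z_px <- 2L * n_thick + 2L * z_offset_px
  mask <- matrix(FALSE, lateral_px, z_px)
  mask[, z_offset_px + seq_len(n_thick)] <- TRUE
  structure(list(mask = mask, axial_px_um = axial_px_um,
                 truth = list(thickness_um = n_thick * axial_px_um)),
            class = "cross_section")
}

#' Generate an oscillatory indentation sweep from known moduli
#'
#' Forward model for [compute_dma_moduli()]: given storage and loss moduli
#' per frequency, synthesises force amplitude and phase lag through the
#' linearised Hertzian contact stiffness \eqn{S = 2\sqrt{R\,\delta_{op}}}, so
#' the inverse operation recovers the moduli to machine precision.
#'
#' @param E_storage,E_loss Moduli (Pa), one per frequency.
#' @param frequencies Frequencies (Hz); default `c(1, 2, 4, 10)`.
#' @param delta_amp_um Oscillation amplitude (µm).
#' @param delta_op_um Operating indentation depth (µm).
#' @param R_um Probe radius (µm).
#' @return A list of class `oscillation_sweep` with `data` (data.frame
#'   `frequency_Hz`, `delta_amp_um`, `force_amp_N`, `phase_rad`),
#'   `delta_op_um`, `R_um` and `truth`.
#' @export
gen_oscillation_sweep <- function(E_storage, E_loss,
                                  frequencies = c(1, 2, 4, 10),
                                  delta_amp_um = 0.1, delta_op_um = 2.5,
                                  R_um = 10) {
  stopifnot(length(E_storage) == length(frequencies),
            length(E_loss) == length(frequencies))
  S <- 2 * sqrt(R_um * 1e-6 * delta_op_um * 1e-6)  # contact factor (m)
  Emag <- sqrt(E_storage^2 + E_loss^2)
  F_amp <- Emag * S * delta_amp_um * 1e-6
  phase <- atan2(E_loss, E_storage)
  structure(list(data = data.frame(frequency_Hz = frequencies,
                                   delta_amp_um = delta_amp_um,
                                   force_amp_N = F_amp,
                                   phase_rad = phase),
                 delta_op_um = delta_op_um, R_um = R_um,
                 truth = list(E_storage_Pa = E_storage, E_loss_Pa = E_loss)),
            class = "oscillation_sweep")
}
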