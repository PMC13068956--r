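# Force-indentation curve analysis: contact-point detection, spherical Hertz
# fit with cantilever compliance correction, R^2 quality filtering,
# matrix-scan aggregation, and storage/loss moduli from oscillatory segments.
#
# Conventions: piezo displacement z in µm, force F in N, probe radius R in
# µm, stiffness k in N/m. The effective modulus E_eff = E/(1 - nu^2) is
# reported without assuming a Poisson ratio. The indentation depth is
# compliance-corrected, delta = (z - z_c) - F/k.

check_curve <- function(curve) {
  if (!inherits(curve, "fi_curve")) {
    # accept a bare list with the same fields
    stopifnot(is.list(curve), !is.null(curve$data),
              !is.null(curve$R_um), !is.null(curve$k_N_per_m))
  }
  d <- curve$data
  if (nrow(d) < 10L) abort("curve must have at least 10 samples")
  if (any(diff(d$z_um) <= 0))
    abort("malformed curve: loading displacement must be strictly increasing")
  invisible(curve)
}

# compliance-corrected depth (µm) for measured forces at candidate z_c
compliance_depth <- function(z_um, force_N, z_c, k) {
  (z_um - z_c) - (force_N / k) * 1e6
}

# Closed-form least-squares E_eff for fixed z_c on the selected samples:
# F = a * delta^{3/2}, a = (4/3) E sqrt(R). Returns list(E, rss, fitted).
hertz_ls <- function(z_um, force_N, z_c, R_um, k) {
  delta <- pmax(compliance_depth(z_um, force_N, z_c, k), 0)
  x <- (delta * 1e-6)^1.5 * (4 / 3) * sqrt(R_um * 1e-6)
  sxx <- sum(x^2)
  if (sxx == 0) return(list(E = NA_real_, rss = sum(force_N^2), fitted = 0 * x))
  E <- sum(x * force_N) / sxx
  fitted <- E * x
  list(E = E, rss = sum((force_N - fitted)^2), fitted = fitted)
}

#' Detect the contact point of a force-indentation curve
#'
#' Joint fit of contact point and modulus restricted to the low-load part of
#' the loading segment: only samples with force at most `load_fraction` of
#' the maximum load enter the fit (the instrument-style "range for the
#' contact point fit of 30% of the maximum load"). For each candidate
#' \eqn{z_c}, the modulus has a closed-form least-squares solution, so the
#' search is one-dimensional: a coarse grid over the admissible range
#' followed by golden-section refinement of the best bracket.
#'
#' @param curve An `fi_curve` (see [gen_hertz_curve()]) or a compatible list.
#' @param load_fraction Fraction of the maximum load delimiting the fit
#'   window; default 0.30.
#' @param n_grid Coarse grid size.
#' @param smooth_window Moving-average window (samples, odd) applied to the
#'   force for the contact-point objective only; damps the noise-induced
#'   early-contact bias near the kink. `1` disables smoothing.
#' @return Contact point `z_c` (µm).
#' @export
detect_contact_point <- function(curve, load_fraction = 0.30, n_grid = 80,
                                 smooth_window = 7) {
  check_curve(curve)
  if (load_fraction <= 0 || load_fraction > 1)
    abort("`load_fraction` must be in (0, 1]")
  d <- curve$data
  f <- if (smooth_window > 1) moving_average(d$force_N, smooth_window)
       else d$force_N
  f_max <- max(f)
  if (f_max <= 0) abort("no contact detected: force never rises above zero")
  sel <- f <= load_fraction * f_max
  z_hi <- d$z_um[max(which(sel))]
  z_lo <- min(d$z_um)
  if (z_hi <= z_lo) abort("no contact detected: empty low-load window")
  obj <- function(zc)
    hertz_ls(d$z_um[sel], f[sel], zc, curve$R_um, curve$k_N_per_m)$rss
  grid <- seq(z_lo, z_hi, length.out = n_grid)
  rss <- vapply(grid, obj, numeric(1))
  i <- which.min(rss)
  lo <- grid[max(1L, i - 1L)]; hi <- grid[min(n_grid, i + 1L)]
  stats::optimize(obj, lower = lo, upper = hi, tol = 1e-6)$minimum
}

#' Brute-force contact point by exhaustive grid search
#'
#' Reference implementation used to validate [detect_contact_point()]:
#' evaluates the restricted joint-fit residual on a dense grid and returns
#' the minimising candidate. Independent of the optimiser path.
#'
#' @inheritParams detect_contact_point
#' @param n_grid Grid density.
#' @return Contact point `z_c` (µm).
#' @export
detect_contact_point_grid <- function(curve, load_fraction = 0.30,
                                      n_grid = 2000, smooth_window = 7) {
  check_curve(curve)
  d <- curve$data
  f <- if (smooth_window > 1) moving_average(d$force_N, smooth_window)
       else d$force_N
  f_max <- max(f)
  if (f_max <= 0) abort("no contact detected: force never rises above zero")
  sel <- f <= load_fraction * f_max
  grid <- seq(min(d$z_um), d$z_um[max(which(sel))], length.out = n_grid)
  rss <- vapply(grid, function(zc)
    hertz_ls(d$z_um[sel], f[sel], zc, curve$R_um, curve$k_N_per_m)$rss,
    numeric(1))
  grid[which.min(rss)]
}

#' Fit the Hertz model to a force-indentation curve
#'
#' Least-squares fit of \eqn{F = \tfrac43 E_{\mathrm{eff}} \sqrt{R}\,
#' \delta^{3/2}} on the segment between the contact point and `max_depth`
#' of compliance-corrected indentation. \eqn{R^2} is computed against the
#' mean-force null on the fitted segment only; fits with \eqn{R^2 > 0.95}
#' are flagged `accepted`.
#'
#' @inheritParams detect_contact_point
#' @param z_c Contact point (µm), e.g. from [detect_contact_point()].
#' @param max_depth Maximum indentation depth fitted (µm); default 2.5.
#' @param r2_threshold Acceptance threshold on \eqn{R^2}; default 0.95.
#' @return A one-row data.frame of class `hertz_fit`: `z_c_um`, `E_eff_Pa`,
#'   `r_squared`, `accepted`, `fit_depth_um`, `n_points`.
#' @export
fit_hertz <- function(curve, z_c, max_depth = 2.5, r2_threshold = 0.95) {
  check_curve(curve)
  d <- curve$data
  delta <- compliance_depth(d$z_um, d$force_N, z_c, curve$k_N_per_m)
  sel <- delta > 0 & delta <= max_depth
  if (sum(sel) < 5L)
    abort("insufficient data: fewer than 5 samples within (0, max_depth]")
  fit <- hertz_ls(d$z_um[sel], d$force_N[sel], z_c, curve$R_um,
                  curve$k_N_per_m)
  f <- d$force_N[sel]
  ss_tot <- sum((f - mean(f))^2)
  r2 <- if (ss_tot > 0) 1 - fit$rss / ss_tot else NA_real_
  out <- data.frame(z_c_um = z_c, E_eff_Pa = fit$E, r_squared = r2,
                    accepted = isTRUE(r2 > r2_threshold),
                    fit_depth_um = max(delta[sel]), n_points = sum(sel))
  class(out) <- c("hertz_fit", class(out))
  out
}

#' Analyse one curve end-to-end
#'
#' Convenience wrapper: contact-point detection followed by the Hertz fit.
#'
#' @inheritParams fit_hertz
#' @inheritParams detect_contact_point
#' @return A `hertz_fit` row (see [fit_hertz()]).
#' @export
analyze_curve <- function(curve, load_fraction = 0.30, max_depth = 2.5,
                          r2_threshold = 0.95) {
  z_c <- detect_contact_point(curve, load_fraction)
  fit_hertz(curve, z_c, max_depth, r2_threshold)
}

#' Filter Hertz fits by R-squared
#'
#' Keeps fits with `r_squared` strictly above `threshold` (order preserved),
#' mirroring the rule that only fits with \eqn{R^2} better than 0.95 enter
#' further statistics.
#'
#' @param results A data.frame of Hertz fit rows (e.g. rbind of
#'   [fit_hertz()] outputs).
#' @param threshold R-squared threshold; default 0.95.
#' @return The accepted subset (possibly empty).
#' @export
filter_by_r2 <- function(results, threshold = 0.95) {
  stopifnot(is.data.frame(results), "r_squared" %in% names(results))
  results[!is.na(results$r_squared) & results$r_squared > threshold, ,
          drop = FALSE]
}

#' Storage and loss moduli from an oscillatory indentation sweep
#'
#' For small oscillations about an operating depth \eqn{\delta_{op}}, the
#' Hertzian contact linearises to stiffness \eqn{S = 2 E^* \sqrt{R\,
#' \delta_{op}}}, so the complex modulus is
#' \deqn{E^* = \frac{F_{amp}/\delta_{amp}\; e^{i\varphi}}
#'   {2\sqrt{R\,\delta_{op}}},}
#' with storage modulus \eqn{E' = \mathrm{Re}\,E^*} and loss modulus
#' \eqn{E'' = \mathrm{Im}\,E^*}.
#'
#' @param sweep An `oscillation_sweep` (see [gen_oscillation_sweep()]) or a
#'   list with `data` (`frequency_Hz`, `delta_amp_um`, `force_amp_N`,
#'   `phase_rad`), `delta_op_um` and `R_um`.
#' @return A data.frame: `frequency_Hz`, `E_storage_Pa`, `E_loss_Pa`.
#' @export
compute_dma_moduli <- function(sweep) {
  d <- sweep$data
  check_positive(sweep$delta_op_um, "delta_op_um")
  if (any(d$delta_amp_um <= 0))
    abort("oscillation amplitude must be positive")
  S <- 2 * sqrt(sweep$R_um * 1e-6 * sweep$delta_op_um * 1e-6)
  Emag <- d$force_amp_N / (d$delta_amp_um * 1e-6) / S
  data.frame(frequency_Hz = d$frequency_Hz,
             E_storage_Pa = Emag * cos(d$phase_rad),
             E_loss_Pa = Emag * sin(d$phase_rad))
}

#' Aggregate accepted fits of matrix scans into a per-monolayer modulus
#'
#' Mean of accepted indentations within each scan, then mean over scans
#' (e.g. three matrix scans of 16 indentations per monolayer).
#'
#' @param results Data.frame of Hertz fit rows with an `accepted` column.
#' @param scan Vector identifying the scan of each row (recycled if length
#'   1); defaults to a single scan.
#' @return A list with `E_eff_Pa` (per-monolayer mean), `scan_means`
#'   (named numeric), `n_accepted`, `n_total`.
#' @export
aggregate_matrix_scan <- function(results, scan = 1L) {
  stopifnot(is.data.frame(results), "E_eff_Pa" %in% names(results))
  if (length(scan) == 1L) scan <- rep(scan, nrow(results))
  stopifnot(length(scan) == nrow(results))
  acc <- !is.na(results$accepted) & results$accepted
  if (!any(acc))
    abort("empty monolayer: no accepted indentations to aggregate")
  means <- tapply(results$E_eff_Pa[acc], scan[acc], mean)
  list(E_eff_Pa = mean(means), scan_means = means,
       n_accepted = sum(acc), n_total = nrow(results))
}

#' Probing-depth fraction of the monolayer height
#'
#' Indentation depth expressed as a percentage of the (live) cell height,
#' e.g. 2.5 µm of a 27.8 µm monolayer probes the apical-most 9%.
#'
#' @param depth_um Indentation depth (µm).
#' @param height_um Cell height (µm).
#' @return Percentage, rounded to the nearest integer percent on printing
#'   left to the caller (raw value returned).
#' @export
probing_depth_fraction <- function(depth_um, height_um) {
  check_positive(depth_um, "depth_um"); check_positive(height_um, "height_um")
  100 * depth_um / height_um
}
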