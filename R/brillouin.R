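# Brillouin spectroscopy analysis: Lorentzian doublet fitting with
# Stokes/anti-Stokes averaging, z-scan line-profile peak/plateau analysis,
# 8-bit map scaling and core/interstitium region statistics.

#' Fit the Brillouin Lorentzian to one spectral window
#'
#' Nonlinear least-squares estimate of \eqn{(I_0, \Gamma, \omega_B)} in the
#' Brillouin line shape (see [brillouin_lorentzian()]) over one sign window
#' of the spectrum. The initial shift guess is the window argmax; the side
#' (Stokes vs anti-Stokes) is recorded from the window sign.
#'
#' @param spectrum A `brillouin_spectrum` or a data.frame with `freq_GHz`
#'   and `intensity`.
#' @param side `"stokes"` (\eqn{\omega > 0}) or `"antistokes"`
#'   (\eqn{\omega < 0}).
#' @param window Optional length-2 numeric restricting the fitted frequency
#'   magnitudes (GHz), e.g. `c(4, 8)`.
#' @return A one-row data.frame of class `lorentzian_fit`: `omega_B_GHz`
#'   (magnitude), `Gamma_GHz`, `I0`, `side`, `rss`, `valid`.
#' @export
fit_lorentzian <- function(spectrum, side = c("stokes", "antistokes"),
                           window = NULL) {
  side <- match.arg(side)
  d <- if (is.data.frame(spectrum)) spectrum else spectrum$data
  sel <- if (side == "stokes") d$freq_GHz > 0 else d$freq_GHz < 0
  if (!is.null(window))
    sel <- sel & abs(d$freq_GHz) >= window[1] & abs(d$freq_GHz) <= window[2]
  w <- abs(d$freq_GHz[sel]); y <- d$intensity[sel]
  if (length(w) < 7L) abort("spectral window has fewer than 7 samples")
  o <- order(w); w <- w[o]; y <- y[o]
  wB0 <- w[which.max(y)]
  G0 <- 0.3
  I00 <- max(y) * pi * G0
  fit <- tryCatch(
    minpack.lm::nlsLM(y ~ brillouin_lorentzian(w, wB, G, I0),
                      start = list(wB = wB0, G = G0, I0 = I00),
                      lower = c(1e-3, 1e-4, 1e-12),
                      control = minpack.lm::nls.lm.control(maxiter = 200)),
    error = function(e) NULL)
  if (is.null(fit)) {
    out <- data.frame(omega_B_GHz = NA_real_, Gamma_GHz = NA_real_,
                      I0 = NA_real_, side = side, rss = NA_real_,
                      valid = FALSE)
  } else {
    cf <- stats::coef(fit)
    out <- data.frame(omega_B_GHz = unname(cf["wB"]),
                      Gamma_GHz = unname(cf["G"]), I0 = unname(cf["I0"]),
                      side = side, rss = sum(stats::resid(fit)^2),
                      valid = TRUE)
  }
  class(out) <- c("lorentzian_fit", class(out))
  out
}

#' Average Stokes and anti-Stokes fits into a voxel shift
#'
#' The Brillouin shift and linewidth of one voxel are the arithmetic means
#' of the corresponding values fitted to the Stokes and anti-Stokes peaks.
#' If one side failed to fit, the valid side is used alone and the voxel is
#' flagged single-sided.
#'
#' @param stokes,antistokes `lorentzian_fit` rows.
#' @return A one-row data.frame: `omega_B_GHz`, `Gamma_GHz`, `single_sided`.
#' @export
average_sides <- function(stokes, antistokes) {
  fits <- rbind(as.data.frame(stokes), as.data.frame(antistokes))
  ok <- fits$valid
  if (!any(ok)) abort("both side fits invalid; voxel excluded")
  data.frame(omega_B_GHz = mean(abs(fits$omega_B_GHz[ok])),
             Gamma_GHz = mean(fits$Gamma_GHz[ok]),
             single_sided = sum(ok) == 1L)
}

#' Fit both sides of a spectrum and average
#'
#' @inheritParams fit_lorentzian
#' @return As [average_sides()].
#' @export
fit_spectrum <- function(spectrum, window = NULL) {
  average_sides(fit_lorentzian(spectrum, "stokes", window),
                fit_lorentzian(spectrum, "antistokes", window))
}

#' Analyse a Brillouin z-scan line profile
#'
#' Implements the peak/plateau dichotomy used on axial scans through
#' hydrogel, monolayer and medium:
#' \enumerate{
#'   \item smooth the profile with a Savitzky-Golay filter;
#'   \item detect interior local maxima, imposing a minimum width and a
#'     minimum prominence to prevent false peak identification;
#'   \item refine the winning peak with a Gaussian fit bounded by the
#'     z-positions of the local maximum of the profile derivative preceding
#'     the peak and the local minimum following it;
#'   \item if no admissible peak exists, locate the onset of the drop from
#'     the initial plateau as the first index where a moving average of the
#'     derivative falls below `-plateau_drop_threshold`, and report the mean
#'     filtered shift before that onset.
#' }
#' A profile with neither a peak nor a detectable drop is flagged
#' indeterminate (to be excluded, as in outlier checking of real scans).
#'
#' @param profile A `z_profile` or data.frame with `z_um`, `shift_GHz`.
#' @param sg_window Savitzky-Golay window length (odd); default 5.
#' @param sg_order Savitzky-Golay polynomial order; default 2.
#' @param min_peak_width Minimum peak width at half prominence (samples);
#'   default 3.
#' @param min_prominence Minimum peak prominence (GHz); default 0.02.
#' @param plateau_drop_threshold Drop-onset threshold on the smoothed
#'   derivative (GHz/µm); default 0.005.
#' @param ma_window Moving-average window for the derivative (samples).
#' @return A list of class `profile_feature`: `kind` (`"peak"`, `"plateau"`
#'   or `"indeterminate"`), `value_GHz`, `z_position_um` (peak only).
#' @export
analyze_z_profile <- function(profile, sg_window = 5, sg_order = 2,
                              min_peak_width = 3, min_prominence = 0.02,
                              plateau_drop_threshold = 0.005,
                              ma_window = 3) {
  d <- if (is.data.frame(profile)) profile else profile$data
  z <- d$z_um; s <- d$shift_GHz
  n <- length(z)
  if (n < sg_window) abort("profile shorter than the filter window")
  sm <- signal::sgolayfilt(s, p = sg_order, n = sg_window)
  dz <- mean(diff(z))
  deriv <- c(diff(sm) / diff(z), NA)
  deriv[n] <- deriv[n - 1]

  feature <- function(kind, value, z_pos = NA_real_)
    structure(list(kind = kind, value_GHz = value, z_position_um = z_pos),
              class = "profile_feature")

  # ---- peak branch -------------------------------------------------------
  cand <- which(diff(sign(diff(sm))) == -2) + 1L
  best <- NULL
  for (i in cand) {
    left_min <- min(sm[1:i]); right_min <- min(sm[i:n])
    prom <- sm[i] - max(left_min, right_min)
    if (prom < min_prominence) next
    half <- sm[i] - prom / 2
    lo <- i; while (lo > 1 && sm[lo - 1] >= half) lo <- lo - 1
    hi <- i; while (hi < n && sm[hi + 1] >= half) hi <- hi + 1
    if (hi - lo + 1 < min_peak_width) next
    if (is.null(best) || prom > best$prom)
      best <- list(i = i, prom = prom)
  }
  if (!is.null(best)) {
    i <- best$i
    # Gaussian refinement bounded by derivative extrema flanking the peak
    dleft <- deriv[seq_len(max(i - 1, 1))]
    lo <- if (length(dleft) > 1) which.max(dleft) else 1L
    dright <- deriv[i:n]
    hi <- i - 1L + which.min(dright)
    lo <- max(1L, lo); hi <- min(n, hi)
    if (hi - lo + 1 >= 5) {
      zz <- z[lo:hi]; yy <- sm[lo:hi]
      gfit <- tryCatch(
        minpack.lm::nlsLM(yy ~ c0 + a * exp(-(zz - mu)^2 / (2 * sig^2)),
                          start = list(c0 = min(yy), a = diff(range(yy)),
                                       mu = z[i], sig = max(2 * dz, 2)),
                          lower = c(-Inf, 0, min(zz), dz / 2),
                          upper = c(Inf, Inf, max(zz), diff(range(z))),
                          control = minpack.lm::nls.lm.control(maxiter = 200)),
        error = function(e) NULL)
      if (!is.null(gfit)) {
        cf <- stats::coef(gfit)
        return(feature("peak", unname(cf["c0"] + cf["a"]), unname(cf["mu"])))
      }
    }
    return(feature("peak", sm[i], z[i]))
  }

  # ---- plateau branch ----------------------------------------------------
  dma <- moving_average(deriv, ma_window)
  onset <- which(dma < -plateau_drop_threshold)[1]
  if (is.na(onset) || onset <= 1L)
    return(feature("indeterminate", NA_real_))
  feature("plateau", mean(sm[seq_len(onset - 1L)]))
}

#' Linearly scale a shift map to an 8-bit grayscale image
#'
#' Maps the finite minimum to 0 and maximum to 255 with round-half-up
#' quantisation, keeping the inverse mapping so byte values remain
#' proportional to the original Brillouin shifts. Missing voxels stay `NA`.
#'
#' @param map A `shift_map` or numeric matrix (GHz).
#' @return A list: `bytes` (integer matrix, `NA` for missing voxels),
#'   `offset_GHz`, `scale_GHz_per_level`, and `inverse(bytes)` closure.
#' @export
scale_map_to_8bit <- function(map) {
  g <- if (is.matrix(map)) map else map$grid
  fin <- is.finite(g)
  vals <- g[fin]
  if (length(unique(vals)) < 2L)
    abort("constant map has no dynamic range to scale")
  lo <- min(vals); hi <- max(vals)
  scale <- (hi - lo) / 255
  bytes <- matrix(NA_integer_, nrow(g), ncol(g))
  # half-up rounding with a relative guard against floating-point ties
  bytes[fin] <- as.integer(floor((g[fin] - lo) * 255 / (hi - lo) +
                                   0.5 + 1e-9))
  list(bytes = bytes, offset_GHz = lo, scale_GHz_per_level = scale,
       inverse = function(b) lo + b * scale)
}

#' Core/interstitium/whole statistics of a shift map
#'
#' Mean, standard deviation and voxel count of the Brillouin shift over the
#' core region (mask), its complement (interstitium) and the whole map.
#' Non-finite voxels are excluded from all three regions. An empty region is
#' reported with `n_voxels = 0` and `NA` mean/sd.
#'
#' @param map A `shift_map` or numeric matrix (GHz).
#' @param core_mask Logical matrix congruent with the map; `TRUE` = core.
#' @return A data.frame with rows `core`, `interstitium`, `whole` and
#'   columns `region`, `mean_GHz`, `sd_GHz`, `n_voxels`.
#' @export
region_stats <- function(map, core_mask) {
  g <- if (is.matrix(map)) map else map$grid
  if (!is.logical(core_mask)) core_mask <- core_mask > 0
  if (!all(dim(core_mask) == dim(g)))
    abort("`core_mask` must be congruent with the map grid")
  fin <- is.finite(g)
  one <- function(region, sel) {
    v <- g[sel & fin]
    data.frame(region = region,
               mean_GHz = if (length(v)) mean(v) else NA_real_,
               sd_GHz = if (length(v) > 1) stats::sd(v) else NA_real_,
               n_voxels = length(v))
  }
  rbind(one("core", core_mask), one("interstitium", !core_mask),
        one("whole", matrix(TRUE, nrow(g), ncol(g))))
}
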