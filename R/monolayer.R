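# 2D and cross-sectional monolayer quantifications: nuclei density,
# proliferation fraction, cell height, shape factor, stress-fibre fraction,
# microvilli length, junctional/cytoplasmic and nuclear/cytoplasmic
# intensity ratios, thresholded junctional intensity, extrusion counting.

as_ebimage <- function(m) EBImage::Image(m)

resolve_threshold <- function(x, threshold) {
  if (is.numeric(threshold)) return(threshold)
  if (identical(threshold, "otsu")) return(otsu_threshold(x))
  # robust bright-outlier threshold: background median + 10 * MAD, suited to
  # detecting rare very bright spots over a textured background
  if (identical(threshold, "robust"))
    return(stats::median(x) + 10 * stats::mad(x))
  abort("unknown threshold method '%s'", threshold)
}

#' Count nuclei and compute cell density
#'
#' Segmentation pipeline for nuclear stains: Gaussian smoothing, automatic
#' (or fixed) thresholding, watershed splitting of touching nuclei on the
#' distance map, and a size filter before counting. Density is the count
#' divided by the field area.
#'
#' @param image Numeric matrix of nuclear intensities, or a
#'   `monolayer_images` object (its `nuclei` channel is used).
#' @param px_um Pixel size (µm); taken from the object if available.
#' @param gaussian_sigma Smoothing sigma (pixels); default 2.
#' @param threshold `"otsu"` or a numeric intensity threshold.
#' @param min_size Minimum object size (pixels); default 20.
#' @return A list: `count`, `density_cells_mm2`, `field_area_mm2`,
#'   `labels` (integer matrix).
#' @export
count_nuclei_density <- function(image, px_um = NULL, gaussian_sigma = 2,
                                 threshold = "otsu", min_size = 20) {
  if (inherits(image, "monolayer_images")) {
    if (is.null(px_um)) px_um <- image$px_um
    image <- image$channels$nuclei
  }
  check_positive(px_um, "px_um")
  area_mm2 <- prod(dim(image)) * (px_um / 1000)^2
  if (max(image) <= 0 || diff(range(image)) == 0) {
    warning("empty field: no nuclear signal", call. = FALSE)
    return(list(count = 0L, density_cells_mm2 = 0,
                field_area_mm2 = area_mm2,
                labels = matrix(0L, nrow(image), ncol(image))))
  }
  sm <- as.matrix(EBImage::gblur(as_ebimage(image), sigma = gaussian_sigma))
  mask <- sm > resolve_threshold(sm, threshold)
  dm <- EBImage::distmap(as_ebimage(mask * 1))
  ws <- EBImage::watershed(dm, tolerance = 1)
  labs <- as.matrix(EBImage::imageData(ws))
  sizes <- tabulate(labs[labs > 0])
  keep <- which(sizes >= min_size)
  labs[!(labs %in% keep)] <- 0L
  # relabel compactly
  labs <- matrix(match(labs, c(0L, keep)) - 1L, nrow(labs), ncol(labs))
  count <- length(keep)
  list(count = count, density_cells_mm2 = count / area_mm2,
       field_area_mm2 = area_mm2, labels = labs)
}

#' Proliferation fraction from positive-cell and total counts
#'
#' @param n_positive Number of marker-positive cells (e.g. EdU).
#' @param n_total Total number of cells (e.g. DAPI nuclei).
#' @return Percentage of positive cells.
#' @export
proliferation_fraction <- function(n_positive, n_total) {
  if (n_total <= 0) abort("total cell count must be positive")
  if (n_positive < 0 || n_positive > n_total)
    abort("positive count must lie in [0, n_total]")
  100 * n_positive / n_total
}

#' Measure cell height from a cross-sectional mask
#'
#' At each of `n_positions` uniformly spaced foreground columns of an x-z
#' binary mask, the height is the full vertical extent
#' (max z - min z + 1 pixels) times the axial pixel size.
#'
#' @param mask A `cross_section` object or logical matrix
#'   (rows = lateral position, columns = axial position).
#' @param axial_px_um Axial pixel size (µm); taken from the object if given.
#' @param n_positions Number of lateral sampling positions; default 10.
#' @return A list: `heights_um` (per position), `mean_um`, `positions`.
#' @export
measure_cell_height <- function(mask, axial_px_um = NULL, n_positions = 10) {
  if (inherits(mask, "cross_section")) {
    if (is.null(axial_px_um)) axial_px_um <- mask$axial_px_um
    mask <- mask$mask
  }
  check_positive(axial_px_um, "axial_px_um")
  fg_cols <- which(rowSums(mask) > 0)
  if (length(fg_cols) == 0L) abort("no foreground in cross-section")
  pos <- fg_cols[spaced_indices(length(fg_cols), n_positions)]
  heights <- vapply(pos, function(i) {
    zz <- which(mask[i, ])
    (max(zz) - min(zz) + 1) * axial_px_um
  }, numeric(1))
  list(heights_um = heights, mean_um = mean(heights), positions = pos)
}

# Chamfered crack-boundary perimeter of a logical mask, in pixels.
# The crack (inter-pixel) boundary length is corrected by cutting each
# corner from crack midpoint to crack midpoint (replacing two half-edges by
# sqrt(2)/2), which removes the systematic overestimation of the taxicab
# boundary on smooth shapes while keeping axis-aligned rectangles near-exact.
mask_perimeter_px <- function(mask) {
  m <- matrix(FALSE, nrow(mask) + 2L, ncol(mask) + 2L)
  m[2:(nrow(mask) + 1L), 2:(ncol(mask) + 1L)] <- mask
  crack <- sum(m[-1, ] != m[-nrow(m), ]) + sum(m[, -1] != m[, -ncol(m)])
  a <- m[-nrow(m), -ncol(m)]; b <- m[-1, -ncol(m)]
  c_ <- m[-nrow(m), -1]; d <- m[-1, -1]
  s <- a + b + c_ + d
  diag2 <- s == 2 & ((a & d) | (b & c_))
  corners <- sum(s == 1) + sum(s == 3) + 2L * sum(diag2)
  crack - (1 - sqrt(2) / 2) * corners
}

#' Per-cell morphometrics and shape factor
#'
#' For every labelled cell not touching the image border, measures the area
#' (pixel count), the contour perimeter (chamfered crack boundary, which is
#' near-exact for axis-aligned polygons and within ~1% for smooth shapes)
#' and the dimensionless shape factor \eqn{q = P/\sqrt{A}}. The
#' isoperimetric inequality bounds \eqn{q \ge 2\sqrt{\pi} \approx 3.545}
#' (up to discretisation error), attained by a disc; a square has
#' \eqn{q = 4}.
#'
#' @param labels Integer label matrix (0 = background) or a
#'   `monolayer_images` object.
#' @param px_um Pixel size (µm); taken from the object if available.
#' @return A data.frame: `cell`, `area_um2`, `perimeter_um`,
#'   `shape_factor`.
#' @export
shape_factor <- function(labels, px_um = NULL) {
  if (inherits(labels, "monolayer_images")) {
    if (is.null(px_um)) px_um <- labels$px_um
    labels <- labels$labels
  }
  if (is.null(px_um)) px_um <- 1
  ids <- setdiff(sort(unique(as.vector(labels))), 0L)
  if (length(ids) == 0L) abort("no labelled cells")
  border_ids <- unique(c(labels[1, ], labels[nrow(labels), ],
                         labels[, 1], labels[, ncol(labels)]))
  ids <- setdiff(ids, border_ids)
  rows <- lapply(ids, function(id) {
    mask <- labels == id
    A <- sum(mask) * px_um^2
    P <- mask_perimeter_px(mask) * px_um
    data.frame(cell = id, area_um2 = A, perimeter_um = P,
               shape_factor = P / sqrt(A))
  })
  if (length(rows) == 0L)
    return(data.frame(cell = integer(), area_um2 = numeric(),
                      perimeter_um = numeric(), shape_factor = numeric()))
  do.call(rbind, rows)
}

#' Fraction of cells with transcellular stress fibres
#'
#' Normalises manually flagged cells (point annotations or a plain count)
#' to the segmented cell number. Flags falling on background pixels are
#' counted separately and excluded from the numerator.
#'
#' @param flags Either a single count, or a data.frame of points with
#'   `x_um`, `y_um`.
#' @param labels Integer label matrix (cells > 0) or `monolayer_images`.
#' @param px_um Pixel size (µm) for point mapping.
#' @return A list: `percent`, `n_flagged`, `n_cells`, `n_background`.
#' @export
stress_fibre_fraction <- function(flags, labels, px_um = NULL) {
  if (inherits(labels, "monolayer_images")) {
    if (is.null(px_um)) px_um <- labels$px_um
    labels <- labels$labels
  }
  n_cells <- length(setdiff(unique(as.vector(labels)), 0L))
  if (n_cells == 0L) abort("no segmented cells")
  n_background <- 0L
  if (is.data.frame(flags)) {
    if (is.null(px_um)) px_um <- 1
    i <- pmin(pmax(ceiling(flags$x_um / px_um), 1L), nrow(labels))
    j <- pmin(pmax(ceiling(flags$y_um / px_um), 1L), ncol(labels))
    hit <- labels[cbind(i, j)]
    n_background <- sum(hit == 0L)
    n_flagged <- sum(hit > 0L)
  } else {
    n_flagged <- as.integer(flags)
  }
  if (n_flagged > n_cells)
    abort("more flagged cells (%d) than segmented cells (%d)",
          n_flagged, n_cells)
  list(percent = 100 * n_flagged / n_cells, n_flagged = n_flagged,
       n_cells = n_cells, n_background = n_background)
}

# second-moment ellipse axes (full lengths, px) of a set of pixel coords
moment_axes <- function(i, j) {
  cv <- stats::cov(cbind(i, j)) * (length(i) - 1) / length(i)
  ev <- eigen(cv, symmetric = TRUE)$values
  ev[ev < 0] <- 0
  c(major = 4 * sqrt(ev[1]), minor = 4 * sqrt(ev[2]))
}

#' Microvilli length from an apical-band cross-section
#'
#' Blurs the cross-sectional image, thresholds it, and fits an ellipse
#' (by image moments) to each connected region of the mask; the minor-axis
#' length approximates the microvilli length.
#'
#' @param image Numeric matrix (cross-sectional intensities).
#' @param px_um Pixel size (µm).
#' @param gaussian_sigma Blur sigma (pixels); default 1.
#' @param threshold `"otsu"` or numeric.
#' @param min_size Minimum region size (pixels).
#' @return A data.frame: `region`, `minor_um`, `major_um`, `n_px`.
#' @export
microvilli_length <- function(image, px_um, gaussian_sigma = 1,
                              threshold = "otsu", min_size = 20) {
  check_positive(px_um, "px_um")
  sm <- if (gaussian_sigma > 0)
    as.matrix(EBImage::gblur(as_ebimage(image), sigma = gaussian_sigma))
  else image
  mask <- sm > resolve_threshold(sm, threshold)
  if (!any(mask)) abort("empty mask: nothing above threshold")
  labs <- as.matrix(EBImage::bwlabel(as_ebimage(mask * 1)))
  ids <- setdiff(unique(as.vector(labs)), 0)
  rows <- lapply(ids, function(id) {
    w <- which(labs == id, arr.ind = TRUE)
    if (nrow(w) < min_size) return(NULL)
    ax <- moment_axes(w[, 1], w[, 2])
    data.frame(region = id, minor_um = ax["minor"] * px_um,
               major_um = ax["major"] * px_um, n_px = nrow(w))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) abort("no region above `min_size` after thresholding")
  rownames(out) <- NULL
  out
}

#' Junctional to cytoplasmic intensity ratio
#'
#' The junctional region is the band of half-width `shrink_px` around the
#' cell outlines (the inverted mask after slimming the cell ROIs); the
#' cytoplasmic region is its complement, i.e. the cell interiors eroded by
#' the same amount. The ratio of the two mean intensities is returned per
#' image. Cells whose interior is annihilated by the erosion are excluded
#' with a warning. Note the ratio is not invariant to additive intensity
#' offsets.
#'
#' @param image Numeric matrix (e.g. vinculin channel) or
#'   `monolayer_images` (its `junction` channel is used).
#' @param labels Integer label matrix; taken from the object if available.
#' @param shrink_px Band half-width / erosion radius (pixels); default 2.
#' @return A list: `ratio`, `junctional_mean`, `cytoplasmic_mean`,
#'   `n_cells_excluded`.
#' @export
junctional_cytoplasmic_ratio <- function(image, labels = NULL,
                                         shrink_px = 2) {
  if (inherits(image, "monolayer_images")) {
    if (is.null(labels)) labels <- image$labels
    image <- image$channels$junction
  }
  if (is.null(labels)) abort("`labels` required")
  if (!all(dim(labels) == dim(image)))
    abort("`labels` must be congruent with the image")
  band <- dilate_disc(label_boundary(labels), shrink_px)
  cyto <- !band
  ids <- setdiff(unique(as.vector(labels)), 0L)
  gone <- vapply(ids, function(id) !any(cyto & labels == id), logical(1))
  if (any(gone))
    warning(sprintf("%d cell(s) annihilated by erosion and excluded",
                    sum(gone)), call. = FALSE)
  if (!any(cyto)) abort("erosion removed all cytoplasmic pixels")
  jm <- mean(image[band]); cm <- mean(image[cyto])
  list(ratio = jm / cm, junctional_mean = jm, cytoplasmic_mean = cm,
       n_cells_excluded = sum(gone))
}

#' Nuclear to cytoplasmic intensity ratio
#'
#' Nuclear mean over the nucleus labels; cytoplasmic mean over the
#' supra-threshold part of the image after setting nuclear pixels to zero
#' (so sub-threshold background does not dilute the cytoplasmic estimate).
#'
#' @param image Numeric matrix (e.g. MRTFA channel) or `monolayer_images`
#'   (its `nuclear_factor` channel is used).
#' @param nuclei Logical or integer matrix marking nuclei; taken from the
#'   object if available.
#' @param threshold `"otsu"` or numeric, applied to the nucleus-zeroed
#'   image.
#' @return A list: `ratio`, `nuclear_mean`, `cytoplasmic_mean`.
#' @export
nuclear_cytoplasmic_ratio <- function(image, nuclei = NULL,
                                      threshold = "otsu") {
  if (inherits(image, "monolayer_images")) {
    if (is.null(nuclei)) nuclei <- image$nuclei_mask
    image <- image$channels$nuclear_factor
  }
  if (is.null(nuclei)) abort("`nuclei` required")
  nuc <- nuclei > 0
  if (!any(nuc)) abort("no nuclei in mask")
  nm <- mean(image[nuc])
  x2 <- image; x2[nuc] <- 0
  t <- resolve_threshold(x2, threshold)
  sel <- x2 > t
  if (!any(sel)) abort("empty cytoplasmic region after thresholding")
  cm <- mean(x2[sel])
  list(ratio = nm / cm, nuclear_mean = nm, cytoplasmic_mean = cm)
}

#' Mean intensity within a thresholded region
#'
#' Thresholds the image (capturing e.g. the junctional signal) and returns
#' the mean grey value over supra-threshold pixels only.
#'
#' @param image Numeric matrix.
#' @param threshold `"otsu"` or numeric.
#' @return A list: `mean`, `threshold`, `n_px`.
#' @export
thresholded_junctional_mean <- function(image, threshold = "otsu") {
  t <- resolve_threshold(image, threshold)
  sel <- image > t
  if (!any(sel)) abort("empty region: nothing above threshold")
  list(mean = mean(image[sel]), threshold = t, n_px = sum(sel))
}

# integer translation with zero fill
shift_matrix <- function(m, dx, dy) {
  out <- matrix(0, nrow(m), ncol(m))
  nr <- nrow(m); nc <- ncol(m)
  sx <- max(1, 1 + dx):min(nr, nr + dx)
  sy <- max(1, 1 + dy):min(nc, nc + dy)
  out[sx, sy] <- m[sx - dx, sy - dy]
  out
}

# integer-pixel shift of `b` relative to `a` by FFT cross-correlation.
# Bright transients (the extrusion spots themselves) are clipped before
# correlating so registration locks onto the static background structure.
estimate_shift <- function(a, b) {
  clip <- function(x) {
    hi <- stats::median(x) + 5 * stats::mad(x)
    pmin(x, hi) - mean(pmin(x, hi))
  }
  a <- clip(a); b <- clip(b)
  fa <- stats::fft(a); fb <- stats::fft(b)
  cc <- Re(stats::fft(fa * Conj(fb), inverse = TRUE))
  i <- which.max(cc)
  nr <- nrow(a)
  dx <- (i - 1) %% nr; dy <- (i - 1) %/% nr
  if (dx > nr / 2) dx <- dx - nr
  if (dy > ncol(a) / 2) dy <- dy - ncol(a)
  c(dx = dx, dy = dy)
}

#' Count extrusion events in a time-lapse movie
#'
#' Extruded cells appear as very bright transient spots. The frames are
#' aligned to the first frame by integer-pixel translation (FFT
#' cross-correlation), Gaussian-smoothed, overlaid in a maximum-intensity
#' projection over time, thresholded, and the resulting size-filtered
#' connected components are counted.
#'
#' @param movie An `extrusion_movie` or 3D array (x, y, t).
#' @param total_cells Number of cells in the field; taken from the object
#'   if available.
#' @param gaussian_sigma Smoothing sigma (pixels); default 2.
#' @param threshold `"robust"` (background median + 10 MAD, the default,
#'   suited to rare very bright spots), `"otsu"`, or a numeric value,
#'   applied to the projection.
#' @param min_size Minimum spot size (pixels); default 4.
#' @return A list: `count`, `percent_of_cells`, `shifts` (per frame),
#'   `projection`.
#' @export
count_extrusions <- function(movie, total_cells = NULL, gaussian_sigma = 2,
                             threshold = "robust", min_size = 4) {
  if (inherits(movie, "extrusion_movie")) {
    if (is.null(total_cells)) total_cells <- movie$n_cells
    movie <- movie$frames
  }
  nt <- dim(movie)[3]
  if (is.na(nt) || nt < 2L) abort("movie must have at least 2 frames")
  ref <- movie[, , 1]
  shifts <- matrix(0L, nt, 2)
  proj <- matrix(-Inf, nrow(ref), ncol(ref))
  for (t in seq_len(nt)) {
    f <- movie[, , t]
    sh <- if (t == 1) c(0, 0) else estimate_shift(ref, f)
    shifts[t, ] <- sh
    al <- if (any(sh != 0)) shift_matrix(f, sh[1], sh[2]) else f
    sm <- as.matrix(EBImage::gblur(as_ebimage(al), sigma = gaussian_sigma))
    proj <- pmax(proj, sm)
  }
  # ignore the border strip that zero-fill alignment can corrupt
  pad <- max(abs(shifts)) + 1L
  inner <- proj[(1 + pad):(nrow(proj) - pad), (1 + pad):(ncol(proj) - pad)]
  t_val <- resolve_threshold(inner, threshold)
  mask <- matrix(FALSE, nrow(proj), ncol(proj))
  mask[(1 + pad):(nrow(proj) - pad), (1 + pad):(ncol(proj) - pad)] <-
    inner > t_val
  labs <- as.matrix(EBImage::bwlabel(as_ebimage(mask * 1)))
  sizes <- tabulate(labs[labs > 0])
  count <- sum(sizes >= min_size)
  list(count = count,
       percent_of_cells = if (!is.null(total_cells))
         100 * count / total_cells else NA_real_,
       shifts = shifts, projection = proj)
}
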