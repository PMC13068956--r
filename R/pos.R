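# Photoreceptor outer segment (POS) internalisation analysis: apical actin
# surface construction, 3D particle segmentation (26-connected components),
# internalised-vs-bound classification by the apical cut-off height, field
# summaries, and apical actin surface area.

#' Build the apical actin surface and cut-off height
#'
#' Per lateral column, the surface height is the physical z of the uppermost
#' supra-threshold actin voxel. Columns without signal are missing and are
#' excluded from the mean; the cut-off height is the arithmetic mean of the
#' finite heights (a single scalar cut-off, matching the mean-z convention
#' of the commercial surface object it emulates).
#'
#' @param stack A `pos_stack` or 3D numeric array (its actin channel).
#' @param voxel_size_um Voxel size (µm, length 3); taken from the object if
#'   available.
#' @param threshold `"otsu"` or numeric.
#' @param max_missing Maximum tolerated fraction of missing columns;
#'   default 0.5.
#' @return A list of class `apical_surface`: `height_um` (matrix),
#'   `cutoff_um`, `missing_fraction`.
#' @export
build_apical_surface <- function(stack, voxel_size_um = NULL,
                                 threshold = "otsu", max_missing = 0.5) {
  if (inherits(stack, "pos_stack")) {
    if (is.null(voxel_size_um)) voxel_size_um <- stack$voxel_size_um
    stack <- stack$actin
  }
  if (max(stack) <= 0 || diff(range(stack)) == 0)
    abort("empty actin channel: no surface to build")
  t <- resolve_threshold(stack, threshold)
  supra <- stack > t
  nz <- dim(stack)[3]
  dz <- voxel_size_um[3]
  zs <- (seq_len(nz) - 0.5) * dz
  height <- topmost_height(supra, zs)
  miss <- mean(is.na(height))
  if (miss > max_missing)
    abort("surface unreliable: %.0f%% of columns have no actin signal",
          100 * miss)
  structure(list(height_um = height, cutoff_um = mean(height, na.rm = TRUE),
                 missing_fraction = miss),
            class = "apical_surface")
}

# physical height of the uppermost TRUE voxel per (x, y) column; NA where
# the column has none
topmost_height <- function(supra, zs) {
  d <- dim(supra)
  idx <- matrix(0L, d[1], d[2])
  for (k in seq_len(d[3])) {
    sl <- supra[, , k]
    idx[sl] <- k
  }
  height <- matrix(NA_real_, d[1], d[2])
  height[idx > 0] <- zs[idx[idx > 0]]
  height
}

# 26-connected component labelling of a 3D logical array (BFS flood fill).
label_components_3d <- function(mask) {
  d <- dim(mask)
  nb <- as.matrix(expand.grid(dx = -1:1, dy = -1:1, dz = -1:1))
  nb <- nb[rowSums(abs(nb)) > 0, ]
  labels <- array(0L, dim = d)
  fg <- which(mask)
  if (length(fg) == 0L) return(labels)
  coord <- arrayInd(fg, d)
  lin_of <- function(i, j, k) i + (j - 1L) * d[1] + (k - 1L) * d[1] * d[2]
  current <- 0L
  for (s in seq_along(fg)) {
    if (labels[fg[s]] != 0L) next
    current <- current + 1L
    queue <- matrix(coord[s, ], ncol = 3)
    labels[fg[s]] <- current
    while (nrow(queue) > 0L) {
      nxt <- vector("list", nrow(queue))
      for (q in seq_len(nrow(queue))) {
        p <- queue[q, ]
        cand <- sweep(nb, 2, p, `+`)
        ok <- cand[, 1] >= 1 & cand[, 1] <= d[1] &
              cand[, 2] >= 1 & cand[, 2] <= d[2] &
              cand[, 3] >= 1 & cand[, 3] <= d[3]
        cand <- cand[ok, , drop = FALSE]
        lin <- lin_of(cand[, 1], cand[, 2], cand[, 3])
        new <- mask[lin] & labels[lin] == 0L
        if (any(new)) {
          labels[lin[new]] <- current
          nxt[[q]] <- cand[new, , drop = FALSE]
        }
      }
      queue <- do.call(rbind, nxt)
      if (is.null(queue)) queue <- matrix(numeric(0), ncol = 3)
    }
  }
  labels
}

#' Segment POS particles in 3D
#'
#' Thresholds the POS channel and labels 26-connected components, keeping
#' those of at least `min_voxels` voxels; per particle the physical centroid
#' and the voxel-count volume are recorded.
#'
#' @param stack A `pos_stack` or 3D numeric array (its POS channel).
#' @param voxel_size_um Voxel size (µm, length 3); taken from the object if
#'   available.
#' @param threshold `"otsu"` or numeric.
#' @param min_voxels Minimum particle size (voxels); default 4.
#' @return A data.frame: `id`, `x_um`, `y_um`, `z_um`, `volume_um3`,
#'   `n_voxels`; attribute `labels` carries the label array.
#' @export
segment_particles <- function(stack, voxel_size_um = NULL,
                              threshold = "otsu", min_voxels = 4) {
  if (inherits(stack, "pos_stack")) {
    if (is.null(voxel_size_um)) voxel_size_um <- stack$voxel_size_um
    stack <- stack$pos
  }
  empty <- data.frame(id = integer(), x_um = numeric(), y_um = numeric(),
                      z_um = numeric(), volume_um3 = numeric(),
                      n_voxels = integer())
  if (max(stack) <= 0 || diff(range(stack)) == 0) return(empty)
  t <- resolve_threshold(stack, threshold)
  mask <- stack > t
  labs <- label_components_3d(mask)
  ids <- seq_len(max(labs))
  if (length(ids) == 0L) return(empty)
  dx <- voxel_size_um[1]; dy <- voxel_size_um[2]; dz <- voxel_size_um[3]
  vv <- dx * dy * dz
  rows <- lapply(ids, function(id) {
    w <- which(labs == id)
    if (length(w) < min_voxels) return(NULL)
    co <- arrayInd(w, dim(labs))
    data.frame(id = id,
               x_um = mean((co[, 1] - 0.5) * dx),
               y_um = mean((co[, 2] - 0.5) * dy),
               z_um = mean((co[, 3] - 0.5) * dz),
               volume_um3 = length(w) * vv, n_voxels = length(w))
  })
  out <- do.call(rbind, rows)
  if (is.null(out)) return(empty)
  out$id <- seq_len(nrow(out))
  attr(out, "labels") <- labs
  out
}

#' Classify particles as internalised or bound
#'
#' A particle whose centroid z lies strictly below the cut-off height is
#' internalised; at or above the cut-off it is bound (the tie goes to bound,
#' conservative against over-counting internalisation). Classes are
#' exhaustive and exclusive.
#'
#' @param particles Data.frame from [segment_particles()].
#' @param surface An `apical_surface` or a numeric cut-off height (µm).
#' @return The particle data.frame with a `class` column added.
#' @export
classify_particles <- function(particles, surface) {
  cutoff <- if (inherits(surface, "apical_surface")) surface$cutoff_um
            else surface
  if (!is.finite(cutoff)) abort("cut-off height must be finite")
  particles$class <- ifelse(particles$z_um < cutoff, "internalised", "bound")
  attr(particles, "cutoff_um") <- cutoff
  particles
}

#' Summarise internalisation for one field of view
#'
#' Per-class counts and mean volumes, plus the internalised count normalised
#' by the cell number. Empty classes report `NA` mean volume.
#'
#' @param particles Classified particle data.frame
#'   (see [classify_particles()]).
#' @param cell_count Number of cells in the field (optional).
#' @return A list: `n_internalised`, `n_bound`, `mean_volume_internalised`,
#'   `mean_volume_bound`, `per_cell` (internalised per cell or `NA`).
#' @export
summarize_internalisation <- function(particles, cell_count = NULL) {
  int <- particles$class == "internalised"
  n_i <- sum(int); n_b <- sum(!int)
  list(n_internalised = n_i, n_bound = n_b,
       mean_volume_internalised =
         if (n_i) mean(particles$volume_um3[int]) else NA_real_,
       mean_volume_bound =
         if (n_b) mean(particles$volume_um3[!int]) else NA_real_,
       per_cell = if (!is.null(cell_count) && cell_count > 0)
         n_i / cell_count else NA_real_)
}

# triangulated area of a height map over a regular lateral grid
height_map_area <- function(height, dx, dy) {
  nx <- nrow(height); ny <- ncol(height)
  area <- 0
  tri <- function(p1, p2, p3) {
    v1 <- p2 - p1; v2 <- p3 - p1
    cx <- v1[2] * v2[3] - v1[3] * v2[2]
    cy <- v1[3] * v2[1] - v1[1] * v2[3]
    cz <- v1[1] * v2[2] - v1[2] * v2[1]
    0.5 * sqrt(cx^2 + cy^2 + cz^2)
  }
  for (i in seq_len(nx - 1)) for (j in seq_len(ny - 1)) {
    h00 <- height[i, j]; h10 <- height[i + 1, j]
    h01 <- height[i, j + 1]; h11 <- height[i + 1, j + 1]
    if (anyNA(c(h00, h10, h01, h11))) next
    p00 <- c(0, 0, h00); p10 <- c(dx, 0, h10)
    p01 <- c(0, dy, h01); p11 <- c(dx, dy, h11)
    area <- area + tri(p00, p10, p11) + tri(p00, p11, p01)
  }
  area
}

#' Apical actin surface area
#'
#' Builds the height map of the uppermost supra-threshold actin voxel per
#' column within a subset of slices (the same upper portion of the monolayer
#' for every field) and returns the area of the triangulated surface mesh.
#' A perfectly flat surface gives exactly the lateral footprint area;
#' roughness strictly increases the area.
#'
#' @param stack A `pos_stack` or 3D numeric array (actin channel).
#' @param voxel_size_um Voxel size (µm, length 3); taken from the object if
#'   available.
#' @param slices Integer vector of slice indices to use (default: all).
#' @param threshold `"otsu"` or numeric.
#' @return A list: `area_um2`, `footprint_um2`, `height_um` (matrix).
#' @export
apical_actin_area <- function(stack, voxel_size_um = NULL, slices = NULL,
                              threshold = "otsu") {
  if (inherits(stack, "pos_stack")) {
    if (is.null(voxel_size_um)) voxel_size_um <- stack$voxel_size_um
    stack <- stack$actin
  }
  nz <- dim(stack)[3]
  if (is.null(slices)) slices <- seq_len(nz)
  if (any(slices < 1 | slices > nz)) abort("slice subset outside the stack")
  sub <- stack[, , slices, drop = FALSE]
  if (max(sub) <= 0 || diff(range(sub)) == 0)
    abort("empty slice subset: no actin signal")
  t <- resolve_threshold(sub, threshold)
  supra <- sub > t
  dz <- voxel_size_um[3]
  zs <- (slices - 0.5) * dz
  height <- topmost_height(supra, zs)
  dx <- voxel_size_um[1]; dy <- voxel_size_um[2]
  list(area_um2 = height_map_area(height, dx, dy),
       footprint_um2 = (nrow(height) - 1) * dx * (ncol(height) - 1) * dy,
       height_um = height)
}
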