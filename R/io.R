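# File interfaces. Tabular data (curves, spectra, profiles, maps) travel as
# CSV with fixed column names; images, stacks and movies as TIFF (multi-page
# for z and t) with a JSON metadata sidecar; ground truth as JSON.

#' Write / read a force-indentation curve
#'
#' CSV columns `z_um`, `force_N`; probe metadata (`R_um`, `k_N_per_m`) and
#' any ground truth go to a `.json` sidecar next to the CSV.
#'
#' @param curve An `fi_curve`.
#' @param path CSV path.
#' @return `read_curve_csv` returns an `fi_curve`.
#' @export
write_curve_csv <- function(curve, path) {
  utils::write.csv(curve$data, path, row.names = FALSE)
  meta <- list(R_um = curve$R_um, k_N_per_m = curve$k_N_per_m,
               truth = curve$truth)
  jsonlite::write_json(meta, sidecar_path(path), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @rdname write_curve_csv
#' @export
read_curve_csv <- function(path) {
  d <- utils::read.csv(path)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  else list()
  structure(list(data = d, R_um = meta$R_um, k_N_per_m = meta$k_N_per_m,
                 truth = meta$truth),
            class = "fi_curve")
}

sidecar_path <- function(path) sub("\\.[^.]+$", ".json", path)

#' Write / read a Brillouin spectrum
#'
#' CSV columns `freq_GHz`, `intensity`.
#'
#' @param spectrum A `brillouin_spectrum` or its `data`.
#' @param path CSV path.
#' @export
write_spectrum_csv <- function(spectrum, path) {
  d <- if (is.data.frame(spectrum)) spectrum else spectrum$data
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_spectrum_csv
#' @export
read_spectrum_csv <- function(path) {
  structure(list(data = utils::read.csv(path), truth = NULL),
            class = "brillouin_spectrum")
}

#' Write / read a z-scan profile
#'
#' CSV columns `z_um`, `shift_GHz`.
#'
#' @param profile A `z_profile` or its `data`.
#' @param path CSV path.
#' @export
write_profile_csv <- function(profile, path) {
  d <- if (is.data.frame(profile)) profile else profile$data
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_profile_csv
#' @export
read_profile_csv <- function(path) {
  structure(list(data = utils::read.csv(path), truth = NULL),
            class = "z_profile")
}

#' Write / read a shift map as long-format CSV
#'
#' CSV columns `x_um`, `y_um`, `shift_GHz` on the regular raster grid.
#'
#' @param map A `shift_map`.
#' @param path CSV path.
#' @export
write_map_csv <- function(map, path) {
  g <- map$grid; step <- map$step_um
  d <- data.frame(x_um = rep((seq_len(nrow(g)) - 1) * step, ncol(g)),
                  y_um = rep((seq_len(ncol(g)) - 1) * step, each = nrow(g)),
                  shift_GHz = as.vector(g))
  utils::write.csv(d, path, row.names = FALSE)
  invisible(path)
}

#' @rdname write_map_csv
#' @export
read_map_csv <- function(path) {
  d <- utils::read.csv(path)
  xs <- sort(unique(d$x_um)); ys <- sort(unique(d$y_um))
  g <- matrix(NA_real_, length(xs), length(ys))
  g[cbind(match(d$x_um, xs), match(d$y_um, ys))] <- d$shift_GHz
  step <- if (length(xs) > 1) diff(xs)[1] else 1
  structure(list(grid = g, step_um = step, core_mask = NULL, truth = NULL),
            class = "shift_map")
}

#' Write / read a 3D stack (or movie) as multi-page TIFF
#'
#' One 32-bit float page per slice/frame; voxel sizes and channel names go
#' to a JSON sidecar. Intensities are stored divided by `scale` to fit the
#' [0, 1] range of float TIFF viewers and rescaled on reading.
#'
#' @param arr 3D numeric array (x, y, z-or-t).
#' @param path TIFF path.
#' @param voxel_size_um Voxel size triplet (µm) for the sidecar.
#' @param scale Intensity scale; default the array maximum.
#' @export
write_stack_tiff <- function(arr, path, voxel_size_um = c(1, 1, 1),
                             scale = max(arr)) {
  if (scale <= 0) scale <- 1
  pages <- lapply(seq_len(dim(arr)[3]), function(k) arr[, , k] / scale)
  tiff::writeTIFF(pages, path, bits.per.sample = 32L)
  jsonlite::write_json(list(voxel_size_um = voxel_size_um, scale = scale),
                       sidecar_path(path), auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_stack_tiff
#' @export
read_stack_tiff <- function(path) {
  pages <- tiff::readTIFF(path, all = TRUE)
  meta <- if (file.exists(sidecar_path(path)))
    jsonlite::read_json(sidecar_path(path), simplifyVector = TRUE)
  else list(voxel_size_um = c(1, 1, 1), scale = 1)
  arr <- array(0, dim = c(dim(pages[[1]]), length(pages)))
  for (k in seq_along(pages)) arr[, , k] <- pages[[k]] * meta$scale
  list(data = arr, voxel_size_um = meta$voxel_size_um)
}

#' Write ground truth to JSON
#'
#' @param truth Truth list from any generator.
#' @param path JSON path.
#' @export
write_truth_json <- function(truth, path) {
  jsonlite::write_json(truth, path, auto_unbox = TRUE, digits = NA,
                       dataframe = "columns")
  invisible(path)
}

#' @rdname write_truth_json
#' @export
read_truth_json <- function(path) {
  jsonlite::read_json(path, simplifyVector = TRUE)
}
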