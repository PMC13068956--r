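# Internal helpers shared across modules.

#' Evaluate code under a temporary RNG seed
#'
#' Runs `code` with the global RNG seeded by `seed` and restores the previous
#' RNG state afterwards, so generators are pure functions of (config, seed).
#'
#' @param seed Integer seed, or `NULL` to use the current RNG state.
#' @param code Expression to evaluate.
#' @return The value of `code`.
#' @keywords internal
with_seed <- function(seed, code) {
  if (is.null(seed)) return(force(code))
  stopifnot(is.numeric(seed), length(seed) == 1L, is.finite(seed))
  had_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (had_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (had_seed) assign(".Random.seed", old, envir = globalenv())
    else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE))
      rm(".Random.seed", envir = globalenv())
  })
  set.seed(as.integer(seed))
  force(code)
}

# stop() with sprintf-style formatting and no call in the condition
abort <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

check_positive <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x <= 0)
    abort("`%s` must be a single positive finite number", name)
  invisible(x)
}

check_fraction <- function(x, name) {
  if (!is.numeric(x) || length(x) != 1L || !is.finite(x) || x < 0)
    abort("`%s` must be a single non-negative number", name)
  invisible(x)
}

# centred moving average, window w (odd); endpoints use shrinking windows
moving_average <- function(x, w) {
  n <- length(x)
  half <- w %/% 2
  vapply(seq_len(n), function(i) {
    lo <- max(1L, i - half); hi <- min(n, i + half)
    mean(x[lo:hi])
  }, numeric(1))
}

# Otsu threshold on a numeric matrix/array (histogram-based, 256 bins).
# Returns a value t such that `x > t` is the foreground.
otsu_threshold <- function(x) {
  x <- x[is.finite(x)]
  if (length(x) == 0L) abort("cannot threshold an empty image")
  r <- range(x)
  if (diff(r) == 0) return(r[1])
  # EBImage::otsu expects values in [0, 1]
  sc <- (x - r[1]) / diff(r)
  t01 <- EBImage::otsu(EBImage::Image(matrix(sc, nrow = 1L)), levels = 256)
  r[1] + t01 * diff(r)
}

# Uniformly spaced integer positions 1..n (used for lateral height sampling)
spaced_indices <- function(n, k) {
  if (k >= n) return(seq_len(n))
  unique(round(seq(1, n, length.out = k)))
}
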