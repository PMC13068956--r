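# Shared fixture builders. Everything is generated in code at test time.

# filled disc mask in an n x n field
disc_mask <- function(n, cx, cy, r) {
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  (i - cx)^2 + (j - cy)^2 <= r^2
}

# filled (optionally rotated) ellipse mask, semi-axes a >= b, angle radians
ellipse_mask <- function(n, cx, cy, a, b, theta = 0) {
  i <- matrix(seq_len(n), n, n)
  j <- t(i)
  u <- (i - cx) * cos(theta) + (j - cy) * sin(theta)
  v <- -(i - cx) * sin(theta) + (j - cy) * cos(theta)
  u^2 / a^2 + v^2 / b^2 <= 1
}

# drift-corrupt a movie by progressive integer translations
apply_drift <- function(frames, dx_total, dy_total) {
  nt <- dim(frames)[3]
  dx <- round(seq(0, dx_total, length.out = nt))
  dy <- round(seq(0, dy_total, length.out = nt))
  out <- frames
  for (t in seq_len(nt))
    out[, , t] <- epimech:::shift_matrix(frames[, , t], dx[t], dy[t])
  out
}

# small synthetic 16-curve matrix scan; `corrupt` curves are replaced by
# flat noise so their Hertz fit fails the R^2 gate
make_matrix_scan <- function(E_true, n = 16, corrupt = 0, noise = 0.02,
                             seed = 1) {
  curves <- lapply(seq_len(n), function(i)
    gen_hertz_curve(E_true, noise_level = noise, seed = seed * 1000 + i))
  if (corrupt > 0) {
    for (i in seq_len(corrupt)) {
      cv <- curves[[i]]
      set.seed(seed * 2000 + i)
      cv$data$force_N <- stats::rnorm(nrow(cv$data), 0, 1e-9)
      curves[[i]] <- cv
    }
  }
  curves
}
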