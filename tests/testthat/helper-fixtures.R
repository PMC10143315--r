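# Shared fixtures: scaled-down generator configs and small deterministic
# containers, all built in code at test time.

# compact axis (dyadic length so wavelet level 3 stays feasible)
small_axis <- function(n = 256L) spectral_axis(seq(210, 231, length.out = n))

# reduced design keeps every structural feature of the default generator
small_config <- function(seed = 1L, ...) {
  generator_config(design = c(4L, 8L, 3L), axis = small_axis(), seed = seed, ...)
}

# deterministic toy spectra_set: intensities are a smooth ramp plus row index
toy_set <- function(n_samples = 6L, n_channels = 8L) {
  axis <- spectral_axis(seq(210, 231, length.out = n_channels))
  reps <- 3L
  cells <- ceiling(n_samples / reps)
  meta <- data.frame(
    sample_id = sprintf("S%02d", seq_len(n_samples)),
    brand = rep(seq_len(cells), each = reps)[seq_len(n_samples)],
    group = 1L,
    replicate = rep(seq_len(reps), cells)[seq_len(n_samples)],
    Cd = seq_len(n_samples) * 1.5,
    Cu = seq_len(n_samples) * 2.0,
    Pb = seq_len(n_samples) * 0.5
  )
  X <- outer(seq_len(n_samples), seq_len(n_channels), function(i, j) i * 10 + sqrt(j))
  spectra_set(axis, X, meta)
}

# orthogonal-column design where columns 1 and 4 carry y and have the
# largest norms, so SPA projection chains must reach both
spa_toy <- function(seed = 42L) {
  withr::with_seed(seed, {
    Q <- qr.Q(qr(matrix(stats::rnorm(64), 8L)))[, 1:6]
    X <- sweep(Q, 2L, c(5, 1, 1, 4, 1, 1), `*`)
    list(X = X, y = 3 * X[, 1] - 2 * X[, 4])
  })
}

expect_matrix_equal <- function(a, b, tol = 1e-10) {
  expect_lt(max(abs(as.matrix(a) - as.matrix(b))), tol)
}
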