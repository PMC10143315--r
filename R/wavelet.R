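# Periodized orthogonal discrete wavelet transform (Daubechies family).
# Implemented as explicit orthonormal analysis matrices per dyadic length:
# rows of H (approximation) and G (detail) are the scaling/wavelet filters
# circularly shifted by 2, so H %*% t(H) = I, G %*% t(G) = I, H %*% t(G) = 0
# and x = t(H) a + t(G) d reconstructs exactly.

# scaling (reconstruction lowpass) filters; db4 = 8 taps
WT_FILTERS <- list(
  db4 = c(0.2303778133088965, 0.7148465705529157, 0.6308807679298589,
          -0.027983769416859854, -0.18703481171909309, 0.030841381835560764,
          0.0328830116668852, -0.010597401785069032),
  haar = c(1 / sqrt(2), 1 / sqrt(2))
)

dwt_matrices <- function(n, h) {
  L <- length(h)
  g <- rev(h) * (-1)^(seq_len(L) - 1)  # quadrature mirror filter
  half <- n %/% 2L
  H <- matrix(0, half, n)
  G <- matrix(0, half, n)
  for (k in seq_len(half)) {
    idx <- ((2L * (k - 1L) + seq_len(L) - 1L) %% n) + 1L
    # accumulate: for n < L the circular indices wrap onto themselves
    for (m in seq_len(L)) {
      H[k, idx[m]] <- H[k, idx[m]] + h[m]
      G[k, idx[m]] <- G[k, idx[m]] + g[m]
    }
  }
  list(H = H, G = G)
}

wt_cache <- new.env(parent = emptyenv())

get_dwt_matrices <- function(n, wavelet) {
  key <- paste0(wavelet, ":", n)
  if (is.null(wt_cache[[key]])) {
    h <- WT_FILTERS[[wavelet]]
    if (is.null(h)) stop("unknown wavelet family: ", wavelet)
    wt_cache[[key]] <- dwt_matrices(n, h)
  }
  wt_cache[[key]]
}

# multilevel periodized DWT of one vector: list(details = list(d1..dlevel),
# approx = a_level); d1 is the finest scale
dwt_periodized <- function(x, wavelet = "db4", level = 3L) {
  n <- length(x)
  if (level < 1L) stop("level must be >= 1")
  if (n %% (2^level) != 0L)
    stop(sprintf("signal length %d is not divisible by 2^%d; level infeasible", n, level))
  details <- vector("list", level)
  a <- x
  for (l in seq_len(level)) {
    mats <- get_dwt_matrices(length(a), wavelet)
    details[[l]] <- drop(mats$G %*% a)
    a <- drop(mats$H %*% a)
  }
  list(details = details, approx = a)
}

idwt_periodized <- function(decomp, wavelet = "db4") {
  a <- decomp$approx
  for (l in rev(seq_along(decomp$details))) {
    d <- decomp$details[[l]]
    mats <- get_dwt_matrices(2L * length(a), wavelet)
    a <- drop(crossprod(mats$H, a) + crossprod(mats$G, d))
  }
  a
}

soft_threshold <- function(x, t) sign(x) * pmax(abs(x) - t, 0)
hard_threshold <- function(x, t) x * (abs(x) > t)
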