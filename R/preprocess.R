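# Spectral pretreatments: multiplicative scatter correction (MSC), standard
# normal variate (SNV), Savitzky-Golay smoothing (SG) and wavelet denoising
# (WT), plus RMSECV-based selection among them. All transforms are row-wise
# (per spectrum); only MSC carries fitted state (the reference spectrum),
# which is always learned on calibration rows only.

#' Multiplicative scatter correction
#'
#' Per spectrum, fits \eqn{x_i = a_i + b_i \cdot ref} by least squares and
#' returns \eqn{(x_i - a_i)/b_i}, removing per-sample multiplicative and
#' additive scatter relative to a reference spectrum (conventionally the
#' mean calibration spectrum).
#'
#' @param X Spectra matrix (rows = samples).
#' @param reference Reference spectrum; defaults to \code{colMeans(X)}. When
#'   correcting test spectra, pass the reference learned from calibration
#'   rows.
#' @return Corrected matrix of the same shape. Rows whose fitted slope is
#'   below 1e-12 in magnitude are returned unchanged with a warning.
#' @export
msc <- function(X, reference = colMeans(X)) {
  X <- as.matrix(X)
  if (length(reference) != ncol(X))
    stop("reference length does not match channel count")
  if (stats::sd(reference) == 0) stop("reference spectrum is constant")
  rc <- reference - mean(reference)
  denom <- sum(rc^2)
  # slope/intercept of x ~ a + b*ref for all rows at once
  b <- as.numeric(X %*% rc) / denom
  a <- rowMeans(X) - b * mean(reference)
  flat <- abs(b) < 1e-12
  if (any(flat)) {
    warning(sprintf("%d row(s) with near-zero scatter slope left uncorrected: %s",
                    sum(flat), paste(which(flat), collapse = ", ")))
    b[flat] <- 1
    a[flat] <- 0
  }
  (X - a) / b
}

#' Standard normal variate
#'
#' Per spectrum, subtracts the row mean and divides by the row standard
#' deviation (sample convention, ddof = 1), so every output row has mean 0
#' and unit sd.
#'
#' @param X Spectra matrix.
#' @return Transformed matrix.
#' @export
snv <- function(X) {
  X <- as.matrix(X)
  if (ncol(X) < 2L) stop("SNV needs at least 2 channels per spectrum")
  s <- apply(X, 1L, stats::sd)
  if (any(s == 0))
    stop("constant row(s) cannot be SNV-scaled: ", paste(which(s == 0), collapse = ", "))
  (X - rowMeans(X)) / s
}

#' Savitzky-Golay smoothing
#'
#' Local least-squares polynomial smoothing of each spectrum
#' (\code{signal::sgolayfilt}); boundary points come from the polynomial
#' fits anchored at the edges.
#'
#' @param X Spectra matrix.
#' @param window Odd window length (default 9).
#' @param polyorder Polynomial order, < window (default 3).
#' @return Smoothed matrix.
#' @export
sg_smooth <- function(X, window = 9L, polyorder = 3L) {
  X <- as.matrix(X)
  if (window %% 2L != 1L) stop("window must be odd")
  if (polyorder >= window) stop("polyorder must be < window")
  if (window > ncol(X)) stop("window exceeds channel count")
  t(apply(X, 1L, signal::sgolayfilt, p = polyorder, n = window))
}

#' Wavelet denoising
#'
#' Per spectrum: multilevel periodized orthogonal wavelet decomposition,
#' universal threshold \eqn{t = \hat\sigma \sqrt{2 \ln n}} with
#' \eqn{\hat\sigma = median(|d_1|)/0.6745} estimated from the finest detail
#' coefficients, soft (default) or hard thresholding of all detail levels,
#' reconstruction.
#'
#' @param X Spectra matrix; channel count must be divisible by
#'   \code{2^level}.
#' @param wavelet Wavelet family (\code{"db4"} default, \code{"haar"}).
#' @param level Decomposition depth (default 3).
#' @param mode \code{"soft"} or \code{"hard"}.
#' @param threshold Optional fixed threshold overriding the universal rule
#'   (0 gives perfect reconstruction).
#' @return Denoised matrix.
#' @export
wt_denoise <- function(X, wavelet = "db4", level = 3L, mode = c("soft", "hard"),
                       threshold = NULL) {
  X <- as.matrix(X)
  mode <- match.arg(mode)
  thr_fun <- if (mode == "soft") soft_threshold else hard_threshold
  n <- ncol(X)
  out <- t(apply(X, 1L, function(x) {
    dec <- dwt_periodized(x, wavelet, level)
    t <- if (is.null(threshold)) {
      sigma <- stats::median(abs(dec$details[[1L]])) / 0.6745
      sigma * sqrt(2 * log(n))
    } else threshold
    dec$details <- lapply(dec$details, thr_fun, t = t)
    idwt_periodized(dec, wavelet)
  }))
  out
}

PREPROCESS_METHODS <- c("none", "msc", "snv", "wt", "sg")
# tie-break order: simpler method wins
PREPROCESS_SIMPLICITY <- c(none = 1, snv = 2, sg = 3, wt = 4, msc = 5)

#' Fit a pretreatment on calibration spectra
#'
#' Returns a \code{preprocess_method} object holding the method name, its
#' parameters and any fitted state (the MSC reference spectrum, learned from
#' the supplied calibration rows only). Apply it to calibration or test
#' spectra with \code{apply_preprocess}.
#'
#' @param method One of \code{"none"}, \code{"msc"}, \code{"snv"},
#'   \code{"wt"}, \code{"sg"}.
#' @param X_cal Calibration spectra matrix (used only by MSC).
#' @param params Optional list of method parameters (\code{window},
#'   \code{polyorder} for SG; \code{wavelet}, \code{level}, \code{mode} for
#'   WT).
#' @return Object of class \code{preprocess_method}.
#' @export
fit_preprocess <- function(method, X_cal = NULL, params = list()) {
  method <- match.arg(method, PREPROCESS_METHODS)
  state <- NULL
  if (method == "msc") {
    if (is.null(X_cal)) stop("MSC requires calibration spectra to fit its reference")
    state <- colMeans(as.matrix(X_cal))
  }
  defaults <- switch(method,
    sg = list(window = 9L, polyorder = 3L),
    wt = list(wavelet = "db4", level = 3L, mode = "soft"),
    list())
  params <- utils::modifyList(defaults, params)
  structure(list(name = method, params = params, fitted_state = state),
            class = "preprocess_method")
}

#' Apply a fitted pretreatment
#'
#' @param pp A \code{preprocess_method} from \code{fit_preprocess}.
#' @param X Spectra matrix to transform.
#' @return Transformed matrix.
#' @export
apply_preprocess <- function(pp, X) {
  stopifnot(inherits(pp, "preprocess_method"))
  switch(pp$name,
    none = as.matrix(X),
    msc = msc(X, reference = pp$fitted_state),
    snv = snv(X),
    sg = sg_smooth(X, window = pp$params$window, polyorder = pp$params$polyorder),
    wt = wt_denoise(X, wavelet = pp$params$wavelet, level = pp$params$level,
                    mode = pp$params$mode))
}

#' Select the best pretreatment by cross-validated PLSR
#'
#' For each candidate method, runs k-fold cross-validation on the
#' calibration data: inside each fold the method is fitted on the fold's
#' training rows only (MSC reference included), both fold partitions are
#' transformed, a PLSR reference model is fitted, and the held-out rows
#' predicted. The method with the lowest RMSECV wins; ties go to the
#' simpler method (none < SNV < SG < WT < MSC).
#'
#' @param X Calibration spectra matrix.
#' @param y Calibration reference concentrations, mg/kg.
#' @param methods Candidate method names.
#' @param folds A \code{fold_spec} from \code{make_folds}, or \code{NULL} to
#'   build a 5-fold split stratified by \code{strata}.
#' @param strata Optional stratification variable (concentration group) used
#'   when \code{folds} is \code{NULL}.
#' @param n_components PLSR latent variables for the reference model
#'   (capped by fold rank).
#' @param seed Seed for fold construction when \code{folds} is \code{NULL}.
#' @return List with \code{best} (method name), \code{table}
#'   (\code{data.frame} of method, R2cv, RMSECV), and \code{fitted} (the
#'   winning \code{preprocess_method} fitted on all of \code{X}).
#' @export
select_preprocessing <- function(X, y, methods = PREPROCESS_METHODS,
                                 folds = NULL, strata = NULL,
                                 n_components = 10L, seed = 1L) {
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y length does not match row count")
  if (length(methods) < 1L) stop("supply at least one method")
  methods <- vapply(methods, match.arg, "", choices = PREPROCESS_METHODS)
  if (is.null(folds)) folds <- make_folds(length(y), k = 5L, strata = strata, seed = seed)
  res <- lapply(methods, function(m) {
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(folds$k)) {
      tr <- which(folds$assignments != f)
      te <- which(folds$assignments == f)
      pp <- fit_preprocess(m, X_cal = X[tr, , drop = FALSE])
      Xtr <- apply_preprocess(pp, X[tr, , drop = FALSE])
      Xte <- apply_preprocess(pp, X[te, , drop = FALSE])
      nc <- min(n_components, length(tr) - 1L, ncol(Xtr))
      fit <- plsr_fit(Xtr, y[tr], n_components = nc)
      oof[te] <- plsr_predict(fit, Xte)
    }
    c(R2cv = r_squared(y, oof), RMSECV = rmse(y, oof))
  })
  tab <- data.frame(method = methods,
                    R2cv = vapply(res, `[[`, 0, "R2cv"),
                    RMSECV = vapply(res, `[[`, 0, "RMSECV"),
                    row.names = NULL, stringsAsFactors = FALSE)
  ord <- order(tab$RMSECV, PREPROCESS_SIMPLICITY[tab$method])
  best <- tab$method[ord[1L]]
  list(best = best, table = tab, fitted = fit_preprocess(best, X_cal = X))
}
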