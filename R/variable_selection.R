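# Wavelength / feature selection: PCA score extraction, the successive
# projections algorithm (SPA) and competitive adaptive reweighted sampling
# (CARS). SPA and CARS return a variable_subset (sorted channel indices +
# selection score); PCA returns a fitted model and a component count.

#' Fit a principal component analysis model
#'
#' Mean-centered singular value decomposition. When a cumulative
#' explained-variance target is given, the chosen component count is the
#' smallest k whose cumulative explained ratio reaches the target (the
#' conventional 95 percent rule in this pipeline).
#'
#' @param X Data matrix (rows = samples).
#' @param variance_target Fraction in (0, 1]; mutually exclusive with
#'   \code{k}.
#' @param k Fixed component count.
#' @return Object of class \code{pca_model}: \code{mean}, \code{loadings}
#'   (orthonormal columns), \code{explained_ratio}, \code{k} (chosen count).
#' @export
pca_fit <- function(X, variance_target = NULL, k = NULL) {
  X <- as.matrix(X)
  if (nrow(X) < 2L) stop("need at least 2 rows")
  if (is.null(variance_target) == is.null(k))
    stop("supply exactly one of variance_target or k")
  pc <- stats::prcomp(X, center = TRUE, scale. = FALSE)
  ev <- pc$sdev^2
  ratio <- ev / sum(ev)
  if (!is.null(k)) {
    if (k < 1L || k > length(ratio)) stop(sprintf("k must be in [1, %d]", length(ratio)))
    chosen <- as.integer(k)
  } else {
    if (variance_target <= 0 || variance_target > 1)
      stop("variance_target must be in (0, 1]")
    chosen <- which(cumsum(ratio) >= variance_target - 1e-12)[1L]
    if (is.na(chosen)) chosen <- length(ratio)
  }
  structure(list(mean = pc$center, loadings = pc$rotation,
                 explained_ratio = ratio, k = chosen),
            class = "pca_model")
}

#' Project data onto principal components
#'
#' \code{(X - mean) \%*\% loadings[, 1:k]}.
#'
#' @param model A \code{pca_model}.
#' @param X Data with the same channel count.
#' @param k Component count; defaults to the count chosen at fit time.
#' @return Score matrix, \code{n_samples x k}.
#' @export
pca_transform <- function(model, X, k = model$k) {
  stopifnot(inherits(model, "pca_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$mean)) stop("channel count does not match model")
  if (k > ncol(model$loadings)) stop("k exceeds stored components")
  sweep(X, 2L, model$mean) %*% model$loadings[, seq_len(k), drop = FALSE]
}

new_variable_subset <- function(indices, method, score, extra = list()) {
  structure(c(list(indices = sort(as.integer(indices)), method = method,
                   score = score), extra),
            class = "variable_subset")
}

#' @export
print.variable_subset <- function(x, ...) {
  cat(sprintf("<variable_subset> %s: %d channels (score %.4g)\n",
              x$method, length(x$indices), x$score))
  invisible(x)
}

#' Serialize a variable subset to JSON
#'
#' @param subset A \code{variable_subset}.
#' @param path Optional output file.
#' @return JSON string (invisibly when written).
#' @export
subset_to_json <- function(subset, path = NULL) {
  stopifnot(inherits(subset, "variable_subset"))
  js <- jsonlite::toJSON(list(method = subset$method, indices = subset$indices,
                              score = subset$score),
                         auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}

# projection chains for every candidate start column: at each step the
# remaining columns are projected onto the orthogonal complement of the
# chosen span and the maximum-norm projection is picked
spa_chains <- function(X, k_max, starts = seq_len(ncol(X))) {
  n <- nrow(X); p <- ncol(X)
  chains <- matrix(NA_integer_, length(starts), k_max)
  for (s in seq_along(starts)) {
    R <- X
    chain <- integer(k_max)
    chain[1L] <- starts[s]
    for (step in seq_len(k_max)) {
      j <- chain[step]
      u <- R[, j]
      nu <- sqrt(sum(u^2))
      if (nu < 1e-12) break  # chain exhausted: nothing independent remains
      u <- u / nu
      R <- R - tcrossprod(u, crossprod(R, u))
      if (step == k_max) break
      norms <- colSums(R^2)
      norms[chain[seq_len(step)]] <- -Inf
      nxt <- which.max(norms)
      if (norms[nxt] < 1e-20) break
      chain[step + 1L] <- nxt
    }
    chains[s, ] <- chain
  }
  chains
}

mlr_rmsecv <- function(X, y, folds) {
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(folds$k)) {
    tr <- folds$assignments != f
    te <- !tr
    A <- cbind(1, X[tr, , drop = FALSE])
    fit <- stats::.lm.fit(A, y[tr])
    cf <- fit$coefficients
    cf[is.na(cf)] <- 0
    oof[te] <- drop(cbind(1, X[te, , drop = FALSE]) %*% cf)
  }
  rmse(y, oof)
}

#' Successive projections algorithm
#'
#' For every candidate start channel, builds a minimally collinear chain by
#' repeatedly projecting all remaining columns onto the orthogonal
#' complement of the chosen span and taking the maximum-norm projection.
#' Every (start, chain length k) candidate with k in \code{[k_min, k_max]}
#' is scored by the cross-validated RMSE of a multiple linear regression on
#' the chain's first k channels; the minimum wins, ties broken by smaller k
#' then lower start index.
#'
#' @param X Calibration spectra matrix.
#' @param y Calibration response.
#' @param k_min,k_max Chain-length range; \code{k_max} must not exceed
#'   \code{min(ncol(X), nrow(X) - 1)}.
#' @param folds A \code{fold_spec} (5-fold default when \code{NULL}).
#' @param seed Fold seed when \code{folds} is \code{NULL}.
#' @return A \code{variable_subset} (method "SPA", score = winning RMSECV)
#'   with extra fields \code{start} and \code{k}.
#' @export
spa_select <- function(X, y, k_min = 1L, k_max = 10L, folds = NULL, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  if (any(colSums(X^2) == 0)) stop("degenerate X: zero column(s) ",
                                   paste(which(colSums(X^2) == 0), collapse = ", "))
  if (k_max > min(p, nrow(X) - 1L))
    stop(sprintf("k_max must be <= min(n_channels, n_rows - 1) = %d", min(p, nrow(X) - 1L)))
  if (k_min < 1L || k_min > k_max) stop("require 1 <= k_min <= k_max")
  if (is.null(folds)) folds <- make_folds(length(y), k = 5L, seed = seed)
  chains <- spa_chains(X, k_max)
  best <- NULL
  records <- vector("list", p)
  for (s in seq_len(p)) {
    chain <- chains[s, ]
    valid_len <- sum(!is.na(chain) & chain > 0L)
    upper <- min(k_max, valid_len)
    if (upper < k_min) next
    ks <- k_min:upper
    sc <- vapply(ks, function(k) mlr_rmsecv(X[, chain[seq_len(k)], drop = FALSE], y, folds),
                 numeric(1))
    records[[s]] <- data.frame(start = s, k = ks, rmsecv = sc)
  }
  tab <- do.call(rbind, records)
  if (is.null(tab) || nrow(tab) == 0L) stop("no feasible SPA candidate")
  pick <- tab[order(tab$rmsecv, tab$k, tab$start), ][1L, ]
  chain <- chains[pick$start, seq_len(pick$k)]
  new_variable_subset(chain, "SPA", pick$rmsecv,
                      extra = list(start = pick$start, k = pick$k))
}

#' Exponential decreasing function constants for CARS
#'
#' With p channels and N runs, the retained fraction at run i is
#' \eqn{r_i = a e^{-k i}} with \eqn{a = (p/2)^{1/(N-1)}} and
#' \eqn{k = \ln(p/2)/(N-1)}, so run 1 keeps all channels and run N keeps 2.
#'
#' @param p Channel count.
#' @param n_runs Number of Monte Carlo runs N.
#' @return List with \code{a}, \code{k} and \code{ratio} (length-N vector).
#' @export
cars_edf <- function(p, n_runs) {
  if (n_runs < 2L) stop("n_runs must be >= 2")
  a <- (p / 2)^(1 / (n_runs - 1))
  k <- log(p / 2) / (n_runs - 1)
  i <- seq_len(n_runs)
  list(a = a, k = k, ratio = a * exp(-k * i))
}

#' Competitive adaptive reweighted sampling
#'
#' Monte Carlo wavelength selection: each run draws 80 percent of the
#' calibration rows, fits a PLSR on the currently retained channels, shrinks
#' the retained count by the exponential decreasing function of
#' \code{cars_edf}, resamples that many channels with probability
#' proportional to the absolute PLS regression coefficients (adaptive
#' reweighted sampling, without replacement), and records the k-fold RMSECV
#' of the retained set. The retained set of the best run is returned.
#'
#' @param X Calibration spectra matrix (p >= 3 channels).
#' @param y Calibration response.
#' @param n_runs Number of runs N (default 50).
#' @param n_pls_components PLS latent variables; chosen once on the full
#'   spectrum by cross-validation when \code{NULL}, then held fixed (capped
#'   when a retained set is smaller).
#' @param folds A \code{fold_spec} for the RMSECV (5-fold default).
#' @param mc_fraction Row fraction per Monte Carlo draw (default 0.8).
#' @param seed Integer seed; the whole procedure is deterministic given it.
#' @return A \code{variable_subset} (method "CARS", score = winning RMSECV)
#'   with extra field \code{diagnostics}: \code{data.frame(run, n_retained,
#'   rmsecv)}.
#' @export
cars_select <- function(X, y, n_runs = 50L, n_pls_components = NULL,
                        folds = NULL, mc_fraction = 0.8, seed = 1L) {
  X <- as.matrix(X)
  p <- ncol(X)
  n <- nrow(X)
  if (p < 3L) stop("CARS needs at least 3 channels")
  if (n_runs < 2L) stop("n_runs must be >= 2")
  if (is.null(folds)) folds <- make_folds(length(y), k = 5L, seed = seed)
  edf <- cars_edf(p, n_runs)
  counts <- pmin(pmax(round(edf$ratio * p), 2L), p)
  withr::with_seed(as.integer(seed), {
    if (is.null(n_pls_components))
      n_pls_components <- plsr_select_ncomp(X, y, max_components = 15L, folds = folds)$n_components
    retained <- seq_len(p)
    sets <- vector("list", n_runs)
    diag <- data.frame(run = seq_len(n_runs), n_retained = NA_integer_,
                       rmsecv = NA_real_)
    capped <- FALSE
    for (i in seq_len(n_runs)) {
      rows <- sample.int(n, max(2L, round(mc_fraction * n)))
      nc <- min(n_pls_components, length(retained), length(rows) - 1L)
      if (nc < n_pls_components) capped <- TRUE
      fit <- plsr_fit(X[rows, retained, drop = FALSE], y[rows], n_components = nc)
      w <- abs(fit$coefficients) + 1e-300  # zero-weight channels stay drawable
      keep_n <- min(counts[i], length(retained))
      retained <- sort(retained[sample.int(length(retained), keep_n, prob = w)])
      nc_cv <- min(n_pls_components, length(retained))
      cv <- cross_validate(function(Xtr, ytr)
        plsr_fit(Xtr, ytr, n_components = min(nc_cv, nrow(Xtr) - 1L)),
        X[, retained, drop = FALSE], y, folds)
      sets[[i]] <- retained
      diag$n_retained[i] <- length(retained)
      diag$rmsecv[i] <- cv$RMSECV
    }
    if (capped) message("CARS: PLS component count capped for small retained sets")
    best <- which.min(diag$rmsecv)
    new_variable_subset(sets[[best]], "CARS", diag$rmsecv[best],
                        extra = list(diagnostics = diag, best_run = best,
                                     n_pls_components = n_pls_components))
  })
}
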