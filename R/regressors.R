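# Regressors: PLS1 regression (NIPALS) and a single-hidden-layer
# back-propagation network with tanh hidden units, linear output and
# min-max [-1, 1] scaling fitted on calibration data only. The flattened
# parameter-vector view (W1, b1, W2, b2 row-major) is what the PSO/SSA
# hybrids optimize over.

#' Fit a PLS1 regression model
#'
#' NIPALS convention for a single response: component weights from
#' \eqn{X^T y}, scores \eqn{t = X w}, loading deflation of X per component;
#' the final regression coefficients reproduce the latent model exactly, so
#' prediction is \code{(x - x_mean) \%*\% coef + y_mean}.
#'
#' @param X Predictor matrix.
#' @param y Numeric response (mg/kg).
#' @param n_components Number of latent variables; must not exceed
#'   \code{min(nrow(X) - 1, ncol(X))}.
#' @return Object of class \code{plsr_model}.
#' @export
plsr_fit <- function(X, y, n_components) {
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (length(y) != nrow(X)) stop("y length does not match row count")
  if (stats::var(y) == 0) stop("y has zero variance")
  max_nc <- min(nrow(X) - 1L, ncol(X))
  if (n_components < 1L || n_components > max_nc)
    stop(sprintf("n_components must be in [1, %d]", max_nc))
  x_mean <- colMeans(X)
  y_mean <- mean(y)
  E <- sweep(X, 2L, x_mean)
  f <- y - y_mean
  p <- ncol(X)
  W <- matrix(0, p, n_components)
  P <- matrix(0, p, n_components)
  q <- numeric(n_components)
  used <- n_components
  for (a in seq_len(n_components)) {
    w <- drop(crossprod(E, f))
    nw <- sqrt(sum(w^2))
    if (nw < 1e-12) { used <- a - 1L; break }  # X residual carries no covariance with y
    w <- w / nw
    t_sc <- drop(E %*% w)
    tt <- sum(t_sc^2)
    p_a <- drop(crossprod(E, t_sc)) / tt
    q_a <- sum(t_sc * f) / tt
    E <- E - tcrossprod(t_sc, p_a)
    f <- f - q_a * t_sc
    W[, a] <- w; P[, a] <- p_a; q[a] <- q_a
  }
  if (used == 0L) stop("no usable latent variable: X carries no covariance with y")
  W <- W[, seq_len(used), drop = FALSE]
  P <- P[, seq_len(used), drop = FALSE]
  q <- q[seq_len(used)]
  coef <- drop(W %*% solve(crossprod(P, W), q))
  structure(list(n_components = used, x_mean = x_mean, y_mean = y_mean,
                 weights = W, loadings = P, q = q, coefficients = coef),
            class = "plsr_model")
}

#' Predict from a PLS1 model
#'
#' @param model A \code{plsr_model}.
#' @param X New predictor matrix (same channel count).
#' @return Numeric predictions, mg/kg.
#' @export
plsr_predict <- function(model, X) {
  stopifnot(inherits(model, "plsr_model"))
  X <- as.matrix(X)
  if (ncol(X) != length(model$x_mean)) stop("feature count does not match model")
  drop(sweep(X, 2L, model$x_mean) %*% model$coefficients) + model$y_mean
}

#' Choose the PLS component count by cross-validated RMSE
#'
#' @param X Predictor matrix.
#' @param y Response.
#' @param max_components Cap on the latent-variable count (default 20, also
#'   capped by fold rank).
#' @param folds A \code{fold_spec}; 5-fold when \code{NULL}.
#' @param seed Fold seed when \code{folds} is \code{NULL}.
#' @return List with \code{n_components} (argmin RMSECV) and \code{rmsecv}
#'   (per-count values).
#' @export
plsr_select_ncomp <- function(X, y, max_components = 20L, folds = NULL, seed = 1L) {
  X <- as.matrix(X)
  if (is.null(folds)) folds <- make_folds(length(y), k = 5L, seed = seed)
  min_train <- min(table(folds$assignments[folds$assignments > 0]))
  nc_max <- min(max_components, ncol(X), length(y) - max(table(folds$assignments)) - 1L)
  if (nc_max < 1L) stop("not enough rows for cross-validated component selection")
  preds <- matrix(NA_real_, length(y), nc_max)
  for (f in seq_len(folds$k)) {
    tr <- which(folds$assignments != f)
    te <- which(folds$assignments == f)
    nc_f <- min(nc_max, length(tr) - 1L)
    fit <- plsr_fit(X[tr, , drop = FALSE], y[tr], n_components = nc_f)
    Xte_c <- sweep(X[te, , drop = FALSE], 2L, fit$x_mean)
    # predictions for every truncated component count from one fit
    Tte <- Xte_c %*% fit$weights %*% solve(crossprod(fit$loadings, fit$weights))
    contrib <- sweep(Tte, 2L, fit$q, `*`)
    cum <- if (ncol(contrib) == 1L) contrib
           else matrix(t(apply(contrib, 1L, cumsum)), nrow = nrow(contrib))
    preds[te, seq_len(ncol(cum))] <- cum + fit$y_mean
  }
  rmsecv <- apply(preds, 2L, function(p) {
    ok <- !is.na(p)
    if (!any(ok)) return(NA_real_)  # count unreachable in every fold
    rmse(y[ok], p[ok])
  })
  valid <- which(!is.na(rmsecv))
  rmsecv <- rmsecv[valid]
  list(n_components = valid[which.min(rmsecv)], rmsecv = rmsecv)
}

scale_minmax_fit <- function(M) {
  M <- as.matrix(M)
  lo <- apply(M, 2L, min)
  hi <- apply(M, 2L, max)
  span <- hi - lo
  span[span == 0] <- 1  # constant feature maps to -1; unscales exactly
  list(lo = lo, span = span)
}

scale_minmax <- function(M, sc) sweep(sweep(as.matrix(M), 2L, sc$lo), 2L, sc$span, `/`) * 2 - 1
unscale_minmax <- function(M, sc) sweep(sweep((as.matrix(M) + 1) / 2, 2L, sc$span, `*`), 2L, sc$lo, `+`)

#' Initialize a back-propagation network
#'
#' Single hidden layer, tanh hidden activation, identity output. Weights and
#' thresholds are drawn uniformly in [-1, 1] from the seeded generator;
#' input/output min-max scalers are unfitted until training.
#'
#' @param n_in,n_hidden,n_out Layer sizes.
#' @param seed Integer seed.
#' @return Object of class \code{bpnn_model} with fields \code{W1}
#'   (\code{n_hidden x n_in}), \code{b1}, \code{W2} (\code{n_out x
#'   n_hidden}), \code{b2}, and empty scalers.
#' @export
bpnn_init <- function(n_in, n_hidden, n_out = 1L, seed = 1L) {
  stopifnot(n_in >= 1L, n_hidden >= 1L, n_out >= 1L)
  withr::with_seed(as.integer(seed), {
    structure(list(n_in = n_in, n_hidden = n_hidden, n_out = n_out,
                   W1 = matrix(stats::runif(n_hidden * n_in, -1, 1), n_hidden, n_in),
                   b1 = stats::runif(n_hidden, -1, 1),
                   W2 = matrix(stats::runif(n_out * n_hidden, -1, 1), n_out, n_hidden),
                   b2 = stats::runif(n_out, -1, 1),
                   x_scale = NULL, y_scale = NULL),
              class = "bpnn_model")
  })
}

#' Default hidden-layer size heuristic
#'
#' \code{round(sqrt(n_in + n_out)) + 4}, the conventional sizing rule for
#' small regression networks.
#'
#' @param n_in,n_out Input/output sizes.
#' @return Integer hidden-unit count.
#' @export
bpnn_hidden_size <- function(n_in, n_out = 1L) as.integer(round(sqrt(n_in + n_out)) + 4L)

#' Training configuration for the network
#'
#' @param epochs Full-batch gradient-descent epochs.
#' @param learning_rate Step size in scaled space.
#' @param goal Stop early when the scaled-space MSE falls below this.
#' @param seed Seed (used when scalers or initialization are created here).
#' @return List of class \code{train_config}.
#' @export
train_config <- function(epochs = 1000L, learning_rate = 0.01, goal = 1e-4, seed = 1L) {
  stopifnot(epochs >= 0L, learning_rate > 0)
  structure(list(epochs = as.integer(epochs), learning_rate = learning_rate,
                 goal = goal, seed = as.integer(seed)),
            class = "train_config")
}

bpnn_forward_scaled <- function(model, Xs) {
  H <- tanh(tcrossprod(Xs, model$W1) + rep(model$b1, each = nrow(Xs)))
  list(H = H, out = tcrossprod(H, model$W2) + rep(model$b2, each = nrow(Xs)))
}

#' Train a network by full-batch gradient descent
#'
#' Fits min-max scalers on (X, y) if not already fitted, then runs
#' full-batch gradient descent on the mean squared error in scaled space.
#'
#' @param model A \code{bpnn_model}.
#' @param X Calibration predictors.
#' @param y Calibration response.
#' @param cfg A \code{train_config}.
#' @return The trained model, with attribute \code{loss_history} (scaled
#'   MSE per epoch, starting with the pre-training loss).
#' @export
bpnn_train <- function(model, X, y, cfg = train_config()) {
  stopifnot(inherits(model, "bpnn_model"))
  X <- as.matrix(X)
  Y <- matrix(as.numeric(y), ncol = model$n_out)
  if (ncol(X) != model$n_in) stop("feature count does not match network input size")
  if (is.null(model$x_scale)) model$x_scale <- scale_minmax_fit(X)
  if (is.null(model$y_scale)) model$y_scale <- scale_minmax_fit(Y)
  Xs <- scale_minmax(X, model$x_scale)
  Ys <- scale_minmax(Y, model$y_scale)
  n <- nrow(Xs)
  fwd <- bpnn_forward_scaled(model, Xs)
  loss <- mean((fwd$out - Ys)^2)
  history <- numeric(cfg$epochs + 1L)
  history[1L] <- loss
  epochs_run <- 0L
  for (e in seq_len(cfg$epochs)) {
    if (loss <= cfg$goal) break
    err <- fwd$out - Ys                              # n x n_out
    dW2 <- crossprod(err, fwd$H) * (2 / n)           # n_out x n_hidden
    db2 <- colSums(err) * (2 / n)
    dH <- err %*% model$W2                           # n x n_hidden
    dZ <- dH * (1 - fwd$H^2)
    dW1 <- crossprod(dZ, Xs) * (2 / n)               # n_hidden x n_in
    db1 <- colSums(dZ) * (2 / n)
    model$W2 <- model$W2 - cfg$learning_rate * dW2
    model$b2 <- model$b2 - cfg$learning_rate * db2
    model$W1 <- model$W1 - cfg$learning_rate * dW1
    model$b1 <- model$b1 - cfg$learning_rate * db1
    fwd <- bpnn_forward_scaled(model, Xs)
    loss <- mean((fwd$out - Ys)^2)
    if (!is.finite(loss))
      stop(sprintf("training diverged at epoch %d (non-finite loss); reduce learning_rate", e))
    epochs_run <- e
    history[e + 1L] <- loss
  }
  attr(model, "loss_history") <- history[seq_len(epochs_run + 1L)]
  model
}

#' Predict from a trained network
#'
#' @param model A \code{bpnn_model} with fitted scalers.
#' @param X New predictors.
#' @return Numeric predictions, mg/kg (vector when \code{n_out == 1}).
#' @export
bpnn_predict <- function(model, X) {
  stopifnot(inherits(model, "bpnn_model"))
  if (is.null(model$x_scale)) stop("model scalers are unfitted; train first")
  X <- as.matrix(X)
  if (ncol(X) != model$n_in) stop("feature count does not match network input size")
  out <- bpnn_forward_scaled(model, scale_minmax(X, model$x_scale))$out
  drop(unscale_minmax(out, model$y_scale))
}

#' Flatten network parameters to a vector
#'
#' Fixed ordering W1 (row-major), b1, W2 (row-major), b2 — the search space
#' of the PSO/SSA hybrids.
#'
#' @param model A \code{bpnn_model}.
#' @return Numeric vector of length
#'   \code{n_hidden*n_in + n_hidden + n_out*n_hidden + n_out}.
#' @export
weights_to_vector <- function(model) {
  stopifnot(inherits(model, "bpnn_model"))
  c(as.numeric(t(model$W1)), model$b1, as.numeric(t(model$W2)), model$b2)
}

#' Rebuild a network from a flat parameter vector
#'
#' @param vec Parameter vector in the \code{weights_to_vector} ordering.
#' @param n_in,n_hidden,n_out Layer sizes.
#' @param template Optional \code{bpnn_model} whose scalers are carried over.
#' @return A \code{bpnn_model}.
#' @export
vector_to_weights <- function(vec, n_in, n_hidden, n_out = 1L, template = NULL) {
  expected <- n_hidden * n_in + n_hidden + n_out * n_hidden + n_out
  if (length(vec) != expected)
    stop(sprintf("parameter vector length %d does not match expected %d",
                 length(vec), expected))
  i <- 0L
  take <- function(k) { v <- vec[(i + 1L):(i + k)]; i <<- i + k; v }
  model <- structure(list(n_in = n_in, n_hidden = n_hidden, n_out = n_out,
                          W1 = matrix(take(n_hidden * n_in), n_hidden, n_in, byrow = TRUE),
                          b1 = take(n_hidden),
                          W2 = matrix(take(n_out * n_hidden), n_out, n_hidden, byrow = TRUE),
                          b2 = take(n_out),
                          x_scale = template$x_scale, y_scale = template$y_scale),
                     class = "bpnn_model")
  model
}

#' Serialize a model to JSON
#'
#' Works for \code{plsr_model} and \code{bpnn_model}: shapes, flattened
#' weights/coefficients and scalers.
#'
#' @param model The model object.
#' @param path Optional output file.
#' @return JSON string (invisibly when written).
#' @export
model_to_json <- function(model, path = NULL) {
  obj <- if (inherits(model, "bpnn_model")) {
    list(type = "bpnn", n_in = model$n_in, n_hidden = model$n_hidden,
         n_out = model$n_out, parameters = weights_to_vector(model),
         x_scale = model$x_scale, y_scale = model$y_scale)
  } else if (inherits(model, "plsr_model")) {
    list(type = "plsr", n_components = model$n_components,
         x_mean = model$x_mean, y_mean = model$y_mean,
         coefficients = model$coefficients)
  } else stop("unsupported model class: ", paste(class(model), collapse = "/"))
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) { writeLines(js, path); return(invisible(js)) }
  js
}
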