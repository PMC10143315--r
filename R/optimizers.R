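# Population metaheuristics used to optimize the network's initial weights
# and thresholds: particle swarm optimization (PSO) and the sparrow search
# algorithm (SSA), plus the hybrid procedure (metaheuristic initialization
# followed by back-propagation fine-tuning).

#' PSO configuration
#'
#' @param swarm_size Particles (>= 2).
#' @param iterations Velocity/position updates (0 allowed: initial
#'   evaluation only).
#' @param inertia Length-2 start/end inertia weights, decayed linearly.
#' @param c1,c2 Cognitive/social acceleration coefficients.
#' @param bounds Length-2 \code{c(low, high)} applied to every dimension, or
#'   a \code{dim x 2} matrix.
#' @param v_max_frac Velocity clip as a fraction of each bound span.
#' @param seed Integer seed.
#' @return List of class \code{pso_config}.
#' @export
pso_config <- function(swarm_size = 30L, iterations = 50L,
                       inertia = c(0.9, 0.4), c1 = 1.49445, c2 = 1.49445,
                       bounds = c(-3, 3), v_max_frac = 0.2, seed = 1L) {
  stopifnot(swarm_size >= 2L, iterations >= 0L, length(inertia) == 2L,
            c1 > 0, c2 > 0, v_max_frac > 0)
  structure(list(swarm_size = as.integer(swarm_size),
                 iterations = as.integer(iterations), inertia = inertia,
                 c1 = c1, c2 = c2, bounds = bounds, v_max_frac = v_max_frac,
                 seed = as.integer(seed)),
            class = "pso_config")
}

#' SSA configuration
#'
#' @param population Sparrows (>= 2).
#' @param iterations Update rounds.
#' @param producer_fraction Fraction of discoverers (PD).
#' @param scout_fraction Fraction of scouts (SD), aware of danger.
#' @param safety_threshold Alarm threshold ST in (0, 1].
#' @param bounds As in \code{pso_config}.
#' @param seed Integer seed.
#' @return List of class \code{ssa_config}.
#' @export
ssa_config <- function(population = 30L, iterations = 50L,
                       producer_fraction = 0.2, scout_fraction = 0.2,
                       safety_threshold = 0.8, bounds = c(-3, 3), seed = 1L) {
  stopifnot(population >= 2L, iterations >= 0L,
            producer_fraction > 0, producer_fraction < 1,
            scout_fraction > 0, scout_fraction < 1,
            safety_threshold > 0, safety_threshold <= 1)
  structure(list(population = as.integer(population),
                 iterations = as.integer(iterations),
                 producer_fraction = producer_fraction,
                 scout_fraction = scout_fraction,
                 safety_threshold = safety_threshold,
                 bounds = bounds, seed = as.integer(seed)),
            class = "ssa_config")
}

expand_bounds <- function(bounds, dim) {
  if (is.matrix(bounds)) {
    stopifnot(nrow(bounds) == dim, ncol(bounds) == 2L)
    b <- bounds
  } else {
    stopifnot(length(bounds) == 2L)
    b <- matrix(rep(as.numeric(bounds), each = dim), dim, 2L)
  }
  if (any(b[, 1] >= b[, 2])) stop("bounds must satisfy low < high")
  b
}

clip_rows <- function(M, b) {
  M <- pmax(M, matrix(b[, 1], nrow(M), ncol(M), byrow = TRUE))
  pmin(M, matrix(b[, 2], nrow(M), ncol(M), byrow = TRUE))
}

eval_fitness <- function(fitness, P) {
  f <- apply(P, 1L, fitness)
  if (any(!is.finite(f))) {
    bad <- which(!is.finite(f))[1L]
    stop("non-finite fitness at position: ",
         paste(signif(P[bad, ], 4), collapse = ", "))
  }
  f
}

new_opt_result <- function(best_position, best_fitness, history, elapsed) {
  structure(list(best_position = best_position, best_fitness = best_fitness,
                 history = history, elapsed = elapsed),
            class = "opt_result")
}

#' @export
print.opt_result <- function(x, ...) {
  cat(sprintf("<opt_result> best fitness %.6g after %d iterations (%.2f s)\n",
              x$best_fitness, length(x$history) - 1L, x$elapsed))
  invisible(x)
}

#' Minimize a function by particle swarm optimization
#'
#' Standard update: \code{v <- w v + c1 r1 (pbest - x) + c2 r2 (gbest - x)},
#' \code{x <- clip(x + v, bounds)}; velocities clipped to
#' \code{v_max_frac * span}; inertia decays linearly across iterations;
#' the best-ever position is returned. Deterministic given the seed.
#'
#' @param fitness Function mapping a numeric vector to a finite scalar.
#' @param dim Dimensionality.
#' @param cfg A \code{pso_config}.
#' @return An \code{opt_result}; \code{history} has length
#'   \code{iterations + 1} (initial evaluation included) and is
#'   non-increasing.
#' @export
pso_minimize <- function(fitness, dim, cfg = pso_config()) {
  stopifnot(dim >= 1L)
  b <- expand_bounds(cfg$bounds, dim)
  span <- b[, 2] - b[, 1]
  v_max <- cfg$v_max_frac * span
  t0 <- proc.time()[["elapsed"]]
  res <- withr::with_seed(cfg$seed, {
    ns <- cfg$swarm_size
    P <- matrix(stats::runif(ns * dim), ns, dim)
    P <- sweep(sweep(P, 2L, span, `*`), 2L, b[, 1], `+`)
    V <- matrix(stats::runif(ns * dim, -1, 1), ns, dim) *
      matrix(v_max, ns, dim, byrow = TRUE)
    f <- eval_fitness(fitness, P)
    pbest <- P; pbest_f <- f
    g <- which.min(f)
    gbest <- P[g, ]; gbest_f <- f[g]
    history <- numeric(cfg$iterations + 1L)
    history[1L] <- gbest_f
    for (it in seq_len(cfg$iterations)) {
      w <- cfg$inertia[1] + (cfg$inertia[2] - cfg$inertia[1]) *
        (it - 1) / max(cfg$iterations - 1, 1)
      r1 <- matrix(stats::runif(ns * dim), ns, dim)
      r2 <- matrix(stats::runif(ns * dim), ns, dim)
      V <- w * V + cfg$c1 * r1 * (pbest - P) +
        cfg$c2 * r2 * (matrix(gbest, ns, dim, byrow = TRUE) - P)
      V <- clip_rows(V, cbind(-v_max, v_max))
      P <- clip_rows(P + V, b)
      f <- eval_fitness(fitness, P)
      improved <- f < pbest_f
      pbest[improved, ] <- P[improved, , drop = FALSE]
      pbest_f[improved] <- f[improved]
      g <- which.min(pbest_f)
      if (pbest_f[g] < gbest_f) { gbest <- pbest[g, ]; gbest_f <- pbest_f[g] }
      history[it + 1L] <- gbest_f
    }
    list(gbest = gbest, gbest_f = gbest_f, history = history)
  })
  new_opt_result(res$gbest, res$gbest_f, res$history,
                 proc.time()[["elapsed"]] - t0)
}

#' Minimize a function by the sparrow search algorithm
#'
#' Per iteration the population is ranked by fitness and split into
#' discoverers (best \code{producer_fraction}), joiners (the rest) and a
#' random \code{scout_fraction} of danger-aware scouts. When the alarm value
#' stays below the safety threshold, discoverers contract exponentially
#' toward smaller coordinates (exploitation); otherwise they take a Gaussian
#' jump. Joiners in the worse half make a long escape jump away from the
#' worst position; the remaining joiners follow the best discoverer with a
#' random binary-weighted displacement. Scouts at the global best step away
#' by a bounded uniform factor scaled by their distance to the worst
#' individual; other scouts move toward the best. Positions are clipped to
#' the bounds and the best-ever solution is retained.
#'
#' @param fitness Function mapping a numeric vector to a finite scalar.
#' @param dim Dimensionality.
#' @param cfg An \code{ssa_config}.
#' @return An \code{opt_result} (same contract as \code{pso_minimize}).
#' @export
ssa_minimize <- function(fitness, dim, cfg = ssa_config()) {
  stopifnot(dim >= 1L)
  b <- expand_bounds(cfg$bounds, dim)
  t0 <- proc.time()[["elapsed"]]
  res <- withr::with_seed(cfg$seed, {
    np <- cfg$population
    n_prod <- max(1L, round(cfg$producer_fraction * np))
    n_scout <- max(1L, round(cfg$scout_fraction * np))
    P <- matrix(stats::runif(np * dim), np, dim)
    P <- sweep(sweep(P, 2L, b[, 2] - b[, 1], `*`), 2L, b[, 1], `+`)
    f <- eval_fitness(fitness, P)
    best_i <- which.min(f)
    gbest <- P[best_i, ]; gbest_f <- f[best_i]
    history <- numeric(cfg$iterations + 1L)
    history[1L] <- gbest_f
    for (it in seq_len(cfg$iterations)) {
      ord <- order(f)
      P <- P[ord, , drop = FALSE]
      f <- f[ord]
      x_best <- P[1L, ]; x_worst <- P[np, ]
      f_best <- f[1L];   f_worst <- f[np]
      # discoverers
      r2 <- stats::runif(1)
      for (i in seq_len(n_prod)) {
        if (r2 < cfg$safety_threshold) {
          alpha <- stats::runif(1, 1e-8, 1)
          P[i, ] <- P[i, ] * exp(-i / (alpha * cfg$iterations))
        } else {
          P[i, ] <- P[i, ] + stats::rnorm(1) * 1
        }
      }
      # joiners
      if (np > n_prod) for (i in (n_prod + 1L):np) {
        if (i > np / 2) {
          P[i, ] <- stats::rnorm(dim) * exp((x_worst - P[i, ]) / i^2)
        } else {
          A <- sample(c(-1, 1), dim, replace = TRUE)
          P[i, ] <- x_best + abs(P[i, ] - x_best) * A / dim
        }
      }
      # scouts
      scouts <- sample.int(np, n_scout)
      for (i in scouts) {
        if (f[i] > f_best) {
          P[i, ] <- x_best + stats::rnorm(1) * abs(P[i, ] - x_best)
        } else {
          K <- stats::runif(1, -1, 1)
          P[i, ] <- P[i, ] + K * abs(P[i, ] - x_worst) /
            (abs(f[i] - f_worst) + 1e-50)
        }
      }
      P <- clip_rows(P, b)
      f <- eval_fitness(fitness, P)
      i_min <- which.min(f)
      if (f[i_min] < gbest_f) { gbest <- P[i_min, ]; gbest_f <- f[i_min] }
      history[it + 1L] <- gbest_f
    }
    list(gbest = gbest, gbest_f = gbest_f, history = history)
  })
  new_opt_result(res$gbest, res$gbest_f, res$history,
                 proc.time()[["elapsed"]] - t0)
}

#' Hybrid metaheuristic + back-propagation training
#'
#' The PSO-BP / SSA-BP procedure: the flattened network parameter vector
#' (weights and thresholds) is optimized by the chosen metaheuristic with
#' fitness = calibration RMSE of the resulting network (no gradient steps
#' inside the fitness); the best vector initializes the network, which is
#' then fine-tuned by full-batch back-propagation. With 0 optimizer
#' iterations the result reduces to plain seeded BPNN training.
#'
#' @param X Calibration predictors.
#' @param y Calibration response, mg/kg.
#' @param n_hidden Hidden-layer size; default
#'   \code{bpnn_hidden_size(ncol(X))}.
#' @param method \code{"PSO"} or \code{"SSA"}.
#' @param opt_cfg A \code{pso_config} or \code{ssa_config} matching
#'   \code{method}; defaults constructed with \code{seed}.
#' @param train_cfg A \code{train_config} for the fine-tuning phase.
#' @param seed Seed used for default configs and the fallback plain
#'   initialization.
#' @return List with \code{model} (trained \code{bpnn_model}) and
#'   \code{opt} (the \code{opt_result}, or \code{NULL} when iterations = 0).
#' @export
hybrid_train <- function(X, y, n_hidden = NULL, method = c("SSA", "PSO"),
                         opt_cfg = NULL, train_cfg = train_config(), seed = 1L) {
  method <- match.arg(method)
  X <- as.matrix(X)
  y <- as.numeric(y)
  if (nrow(X) < 2L || stats::var(y) == 0) stop("degenerate calibration data")
  n_in <- ncol(X)
  if (is.null(n_hidden)) n_hidden <- bpnn_hidden_size(n_in)
  if (is.null(opt_cfg))
    opt_cfg <- if (method == "PSO") pso_config(seed = seed) else ssa_config(seed = seed)
  template <- bpnn_init(n_in, n_hidden, 1L, seed = seed)
  template$x_scale <- scale_minmax_fit(X)
  template$y_scale <- scale_minmax_fit(matrix(y, ncol = 1L))
  iterations <- opt_cfg$iterations
  if (iterations == 0L) {
    model <- bpnn_train(template, X, y, train_cfg)
    return(list(model = model, opt = NULL))
  }
  dim_theta <- n_hidden * n_in + n_hidden + n_hidden + 1L
  fitness <- function(theta) {
    m <- vector_to_weights(theta, n_in, n_hidden, 1L, template = template)
    rmse(y, bpnn_predict(m, X))
  }
  opt <- if (method == "PSO") pso_minimize(fitness, dim_theta, opt_cfg)
         else ssa_minimize(fitness, dim_theta, opt_cfg)
  init <- vector_to_weights(opt$best_position, n_in, n_hidden, 1L, template = template)
  model <- bpnn_train(init, X, y, train_cfg)
  list(model = model, opt = opt)
}
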