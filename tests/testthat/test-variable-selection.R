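test_that("PCA explained variance matches the covariance eigen-oracle", {
  withr::with_seed(8, X <- matrix(stats::rnorm(600), 20, 30))
  m <- pca_fit(X, k = 19L)
  ev <- eigen(stats::cov(X), symmetric = TRUE)$values
  ev <- ev[ev > 1e-12]
  expect_equal(m$explained_ratio[seq_along(ev)], ev / sum(ev), tolerance = 1e-8)
  # loadings orthonormal
  G <- crossprod(m$loadings)
  expect_lt(max(abs(G - diag(ncol(G)))), 1e-8)
  expect_true(all(diff(m$explained_ratio) <= 1e-12))
  expect_lte(sum(m$explained_ratio), 1 + 1e-12)
})

test_that("PCA component count follows the cumulative-variance rule", {
  # rank-1 matrix: first ratio is 1, k = 1 at any target
  r1 <- outer(1:10, seq(0.5, 2, length.out = 6))
  m1 <- pca_fit(r1, variance_target = 0.99)
  expect_equal(m1$explained_ratio[1L], 1, tolerance = 1e-12)
  expect_identical(m1$k, 1L)
  # two orthogonal equal-variance directions: k = 2 at 0.95
  c1 <- rep(c(1, -1), 8)
  c2 <- rep(c(1, 1, -1, -1), 4)
  m2 <- pca_fit(cbind(c1, c2), variance_target = 0.95)
  expect_identical(m2$k, 2L)
  expect_equal(m2$explained_ratio[1:2], c(0.5, 0.5), tolerance = 1e-12)
  expect_error(pca_fit(r1, variance_target = 0.95, k = 2), "exactly one")
  expect_error(pca_fit(r1[1, , drop = FALSE], k = 1), "at least 2 rows")
})

test_that("PCA scores satisfy the transform identities", {
  withr::with_seed(9, X <- matrix(stats::rnorm(400), 20, 20))
  m <- pca_fit(X, k = 19L)
  S <- pca_transform(m, X)
  total <- sum(apply(X, 2, stats::var))
  expect_equal(apply(S, 2, stats::var), m$explained_ratio[1:19] * total,
               tolerance = 1e-8, ignore_attr = TRUE)
  # the mean spectrum maps to the origin
  expect_lt(max(abs(pca_transform(m, rbind(colMeans(X))))), 1e-8)
  # full-component reconstruction
  Xhat <- S %*% t(m$loadings[, 1:19]) + rep(m$mean, each = 20)
  expect_matrix_equal(Xhat, X, tol = 1e-8)
  expect_error(pca_transform(m, X, k = 25L), "exceeds")
  expect_error(pca_transform(m, X[, 1:5]), "channel count")
})

test_that("SPA finds the informative orthogonal channels with near-zero error", {
  toy <- spa_toy()
  folds <- make_folds(8L, k = 4L, seed = 1L)
  vs <- spa_select(toy$X, toy$y, k_min = 1L, k_max = 3L, folds = folds)
  expect_true(all(c(1L, 4L) %in% vs$indices))
  expect_lt(vs$score, 1e-8)
  expect_s3_class(vs, "variable_subset")
  expect_identical(vs$method, "SPA")
})

test_that("SPA equals an independent exhaustive chain-search oracle", {
  # independent oracle: projection chains via qr, CV via lm()
  oracle_chain <- function(X, start, k_max) {
    chain <- start
    for (step in seq_len(k_max - 1L)) {
      Q <- qr.Q(qr(X[, chain, drop = FALSE]))
      R <- X - Q %*% crossprod(Q, X)
      norms <- colSums(R^2)
      norms[chain] <- -Inf
      if (max(norms) < 1e-20) break
      chain <- c(chain, which.max(norms))
    }
    chain
  }
  oracle_cv <- function(X, y, idx, folds) {
    oof <- rep(NA_real_, length(y))
    for (f in seq_len(folds$k)) {
      tr <- folds$assignments != f
      df_tr <- data.frame(y = y[tr], X[tr, idx, drop = FALSE])
      df_te <- data.frame(X[!tr, idx, drop = FALSE])
      names(df_te) <- names(df_tr)[-1L]
      fit <- stats::lm(y ~ ., data = df_tr)
      oof[!tr] <- stats::predict(fit, newdata = df_te)
    }
    sqrt(mean((y - oof)^2))
  }
  for (seed in c(11L, 12L, 13L)) {
    withr::with_seed(seed, {
      X <- matrix(stats::rnorm(10 * 8), 10, 8)
      y <- stats::rnorm(10)
    })
    folds <- make_folds(10L, k = 5L, seed = seed)
    vs <- spa_select(X, y, k_min = 1L, k_max = 3L, folds = folds)
    grid <- expand.grid(start = 1:8, k = 1:3)
    grid$rmsecv <- mapply(function(s, k) {
      ch <- oracle_chain(X, s, 3L)
      if (length(ch) < k) return(Inf)
      oracle_cv(X, y, ch[seq_len(k)], folds)
    }, grid$start, grid$k)
    best <- grid[order(grid$rmsecv, grid$k, grid$start), ][1L, ]
    expect_equal(vs$score, best$rmsecv, tolerance = 1e-8)
    expect_identical(sort(oracle_chain(X, best$start, 3L)[seq_len(best$k)]),
                     vs$indices)
  }
})

test_that("SPA chains pick mutually orthogonal columns in norm order", {
  withr::with_seed(14, Q <- qr.Q(qr(matrix(stats::rnorm(64), 8L)))[, 1:6])
  norms <- c(5, 4, 3, 2.5, 2, 1.5)
  X <- sweep(Q, 2L, norms, `*`)
  ch <- libsquant:::spa_chains(X, 6L)
  # from start 3: remaining channels in decreasing column-norm order
  expect_identical(ch[3, ], c(3L, 1L, 2L, 4L, 5L, 6L))
  # duplicated columns never co-selected
  Xd <- cbind(X[, 1:3], X[, 1])
  ch2 <- libsquant:::spa_chains(Xd, 4L)
  for (r in seq_len(nrow(ch2))) {
    sel <- ch2[r, ch2[r, ] > 0L]
    expect_false(all(c(1L, 4L) %in% sel))
  }
  expect_error(spa_select(cbind(X, 0), 1:8, 1L, 2L), "zero column")
})

test_that("CARS exponential decreasing function matches the stated arithmetic", {
  e <- cars_edf(1024, 50L)
  expect_equal(e$a, 512^(1 / 49), tolerance = 1e-12)
  expect_equal(e$k, log(512) / 49, tolerance = 1e-12)
  expect_equal(e$k, 0.1273, tolerance = 1e-3)
  expect_equal(round(e$ratio[1L] * 1024), 1024)   # run 1 keeps all
  expect_equal(round(e$ratio[50L] * 1024), 2)     # run N keeps 2
  expect_true(all(diff(e$ratio) < 0))
  expect_error(cars_edf(100, 1L), "n_runs")
})

test_that("CARS is seed-deterministic with non-increasing retained counts", {
  withr::with_seed(15, {
    X <- matrix(stats::rnorm(40 * 50), 40, 50)
    y <- X[, 5] - 2 * X[, 25] + stats::rnorm(40, 0, 0.2)
  })
  folds <- make_folds(40L, k = 5L, seed = 2L)
  a <- suppressMessages(cars_select(X, y, n_runs = 20L, folds = folds, seed = 3L))
  b <- suppressMessages(cars_select(X, y, n_runs = 20L, folds = folds, seed = 3L))
  expect_identical(a$indices, b$indices)
  expect_identical(a$diagnostics, b$diagnostics)
  expect_true(all(diff(a$diagnostics$n_retained) <= 0))
  expect_identical(a$method, "CARS")
  expect_error(cars_select(X[, 1:2], y, folds = folds), "at least 3 channels")
})

test_that("CARS recovers informative channels among noise", {
  overlaps <- vapply(1:10, function(s) {
    withr::with_seed(s, {
      X <- matrix(stats::rnorm(60 * 200), 60, 200)
      informative <- c(10L, 50L, 90L, 130L, 170L)
      beta <- rep(0, 200)
      beta[informative] <- c(3, -2, 4, 2.5, -3)
      y <- drop(X %*% beta) + stats::rnorm(60, 0, 0.5)
    })
    vs <- suppressMessages(cars_select(X, y, n_runs = 30L, seed = s))
    length(intersect(vs$indices, informative))
  }, numeric(1))
  expect_gte(stats::median(overlaps), 4)
})

test_that("variable subsets serialize to JSON", {
  toy <- spa_toy()
  vs <- spa_select(toy$X, toy$y, 1L, 3L, folds = make_folds(8L, k = 4L, seed = 1L))
  js <- jsonlite::fromJSON(subset_to_json(vs))
  expect_identical(js$method, "SPA")
  expect_identical(sort(js$indices), vs$indices)
})
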