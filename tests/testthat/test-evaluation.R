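test_that("R2 is the coefficient of determination", {
  expect_identical(r_squared(c(1, 2, 3), c(1, 2, 3)), 1)
  expect_identical(r_squared(c(0, 1, 2), c(2, 1, 0)), -3)
  y <- c(4, 8, 2, 6)
  expect_equal(r_squared(y, rep(mean(y), 4)), 0)
  # invariant under a common affine map
  withr::with_seed(29, {
    yt <- stats::rnorm(20); yp <- yt + stats::rnorm(20, 0, 0.3)
  })
  expect_equal(r_squared(3 * yt - 7, 3 * yp - 7), r_squared(yt, yp),
               tolerance = 1e-12)
  expect_error(r_squared(rep(1, 5), 1:5), "constant")
  expect_error(r_squared(1:3, 1:4), "length")
})

test_that("RMSE arithmetic", {
  expect_identical(rmse(c(0, 4), c(1, 3)), 1)
  expect_identical(rmse(1:5, 1:5), 0)
  expect_identical(rmse(3, 7.5), 4.5)
  expect_error(rmse(numeric(0), numeric(0)), "empty")
})

test_that("RPD definition, scale invariance, and classes", {
  expect_equal(rpd(c(0, 4), 1), stats::sd(c(0, 4)), tolerance = 1e-10)
  y <- c(1, 5, 9, 13)
  expect_equal(rpd(3 * y, 3 * 2.2), rpd(y, 2.2), tolerance = 1e-12)
  expect_warning(inf <- rpd(y, 0), "infinite")
  expect_identical(inf, Inf)
  # strictly decreasing in RMSEP
  vals <- vapply(c(0.5, 1, 2, 4), function(r) rpd(y, r), numeric(1))
  expect_true(all(diff(vals) < 0))
  expect_identical(rpd_class(3.5), "valid")
  expect_identical(rpd_class(2.2), "satisfactory")
  expect_identical(rpd_class(1.7), "good")
  expect_identical(rpd_class(1.2), "poor")
})

test_that("stratified folds are balanced and deterministic", {
  groups <- rep(1:8, each = 12)
  f <- make_folds(96L, k = 5L, strata = groups, seed = 9L)
  expect_identical(f$k, 5L)
  sizes <- table(f$assignments)
  expect_lte(max(sizes) - min(sizes), 1L)
  # every fold sees most concentration groups
  for (fold in 1:5) {
    got <- unique(groups[f$assignments == fold])
    expect_gte(length(got), 7L)
  }
  expect_identical(f, make_folds(96L, k = 5L, strata = groups, seed = 9L))
  expect_error(make_folds(3L, k = 5L), "exceeds")
  expect_error(make_folds(10L, k = 1L), ">= 2")
})

test_that("cross-validation recovers an exactly linear model and rejects noise", {
  withr::with_seed(30, X <- matrix(stats::rnorm(200), 40, 5))
  y <- drop(X %*% c(1, -2, 0.5, 0, 3))
  f <- make_folds(40L, k = 5L, seed = 10L)
  cv <- cross_validate(function(Xtr, ytr) plsr_fit(Xtr, ytr, 5L), X, y, f)
  expect_lt(cv$RMSECV, 1e-8)
  expect_equal(cv$R2_cv, 1, tolerance = 1e-10)
  # pure-noise response: no apparent skill
  r2s <- vapply(1:10, function(s) {
    withr::with_seed(100 + s, {
      Xn <- matrix(stats::rnorm(200), 40, 5)
      yn <- stats::rnorm(40)
    })
    cross_validate(function(Xtr, ytr) plsr_fit(Xtr, ytr, 3L), Xn, yn,
                   make_folds(40L, k = 5L, seed = s))$R2_cv
  }, numeric(1))
  expect_lte(stats::median(r2s), 0.1)
  # identical factories give identical metrics
  cv2 <- cross_validate(function(Xtr, ytr) {
    m <- plsr_fit(Xtr, ytr, 5L)
    function(Xn) plsr_predict(m, Xn)
  }, X, y, f)
  expect_equal(cv$RMSECV, cv2$RMSECV, tolerance = 1e-12)
  expect_error(cross_validate(function(Xtr, ytr) stop("boom"), X, y, f),
               "fold 1")
})

test_that("evaluate_model populates all seven metrics and guards leakage", {
  withr::with_seed(31, {
    X <- matrix(stats::rnorm(300), 60, 5)
    y <- drop(X %*% c(2, -1, 0, 1, 0.5)) + stats::rnorm(60, 0, 0.05)
  })
  tr <- 1:40; te <- 41:60
  f <- make_folds(40L, k = 5L, seed = 11L)
  rep_ <- evaluate_model(function(Xt, yt) plsr_fit(Xt, yt, 5L),
                         X[tr, ], y[tr], X[te, ], y[te], f,
                         element = "Cd", model_name = "PLSR",
                         train_ids = paste0("s", tr), test_ids = paste0("s", te),
                         seed = 1L)
  for (field in c("R2_c", "RMSEC", "R2_cv", "RMSECV", "R2_p", "RMSEP", "RPD"))
    expect_true(is.finite(rep_[[field]]))
  expect_identical(rep_$element, "Cd")
  expect_identical(rep_$n_variables, 5L)
  expect_gte(rep_$duration, 0)
  # RPD consistent with its definition
  expect_equal(rep_$RPD, stats::sd(y[te]) / rep_$RMSEP, tolerance = 1e-12)
  # shared ids abort
  expect_error(
    evaluate_model(function(Xt, yt) plsr_fit(Xt, yt, 2L),
                   X[tr, ], y[tr], X[te, ], y[te], f,
                   train_ids = paste0("s", 1:40), test_ids = paste0("s", 40:59)),
    "leakage guard")
  # a factory that knows the exact data-generating function scores perfectly
  y_exact <- drop(X %*% c(2, -1, 0, 1, 0.5))
  perfect <- suppressWarnings(evaluate_model(function(Xt, yt)
    function(Xn) drop(Xn %*% c(2, -1, 0, 1, 0.5)),
    X[tr, ], y_exact[tr], X[te, ], y_exact[te], f))
  expect_equal(perfect$R2_p, 1, tolerance = 1e-10)
  expect_equal(perfect$R2_c, 1, tolerance = 1e-10)
  expect_lt(perfect$RMSEP, 1e-10)
  expect_lt(perfect$RMSEC, 1e-10)
})

test_that("poisoning the test partition never changes calibration-time results", {
  withr::with_seed(32, {
    X <- matrix(stats::rnorm(300), 60, 5)
    y <- drop(X %*% c(1, 1, 0, -1, 2)) + stats::rnorm(60, 0, 0.1)
  })
  tr <- 1:40; te <- 41:60
  f <- make_folds(40L, k = 5L, seed = 12L)
  factory <- function(Xt, yt) plsr_fit(Xt, yt, 4L)
  clean <- evaluate_model(factory, X[tr, ], y[tr], X[te, ], y[te], f)
  poison <- evaluate_model(factory, X[tr, ],
                           y[tr], matrix(1e6, 20, 5), y[te], f)
  expect_identical(clean$R2_c, poison$R2_c)
  expect_identical(clean$RMSEC, poison$RMSEC)
  expect_identical(clean$R2_cv, poison$R2_cv)
  expect_identical(clean$RMSECV, poison$RMSECV)
})

test_that("relative error table distinguishes zero references and strata", {
  t1 <- relative_error_table(c(100, 0, 50), c(110, 0.5, 50))
  expect_equal(t1$error, c(0.1, 0.5, 0))
  expect_identical(t1$error_type, c("relative", "absolute", "relative"))
  expect_identical(t1$stratum, c("high", "low", "low"))
  t2 <- relative_error_table(c(10, 20), c(10, 20), threshold = 15)
  expect_identical(t2$stratum, c("low", "high"))
})

test_that("report tables aggregate reports row-wise", {
  withr::with_seed(33, {
    X <- matrix(stats::rnorm(200), 40, 5)
    y <- X[, 1] + stats::rnorm(40, 0, 0.1)
  })
  f <- make_folds(30L, k = 5L, seed = 1L)
  r1 <- evaluate_model(function(Xt, yt) plsr_fit(Xt, yt, 3L),
                       X[1:30, ], y[1:30], X[31:40, ], y[31:40], f,
                       element = "Cd", model_name = "A")
  r2 <- evaluate_model(function(Xt, yt) plsr_fit(Xt, yt, 1L),
                       X[1:30, ], y[1:30], X[31:40, ], y[31:40], f,
                       element = "Cd", model_name = "B")
  tab <- report_table(list(r1, r2))
  expect_identical(nrow(tab), 2L)
  expect_identical(tab$model, c("A", "B"))
  expect_true(all(c("R2_c", "RMSEC", "R2_cv", "RMSECV", "R2_p", "RMSEP", "RPD")
                  %in% names(tab)))
})
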