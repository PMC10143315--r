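# Model evaluation: R2 (coefficient of determination), RMSE on the
# calibration / cross-validation / prediction partitions, RPD, stratified
# k-fold construction, and the per-model performance report.

#' Coefficient of determination
#'
#' \eqn{R^2 = 1 - \sum(y - \hat y)^2 / \sum(y - \bar y)^2}. This is the
#' determination coefficient (RMSE-consistent), not the squared Pearson
#' correlation; \code{squared_pearson} is available where the alternative
#' reading is wanted.
#'
#' @param y_true Reference values (length >= 2, non-constant).
#' @param y_pred Predictions.
#' @return Dimensionless scalar (1 is perfect; can be negative).
#' @export
r_squared <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) < 2L) stop("need at least 2 values")
  ss_tot <- sum((y_true - mean(y_true))^2)
  if (ss_tot == 0) stop("y_true is constant; R2 undefined")
  1 - sum((y_true - y_pred)^2) / ss_tot
}

#' Squared Pearson correlation
#'
#' @param y_true Reference values.
#' @param y_pred Predictions.
#' @return Squared correlation coefficient.
#' @export
squared_pearson <- function(y_true, y_pred) stats::cor(y_true, y_pred)^2

#' Root mean square error
#'
#' @param y_true Reference values, mg/kg.
#' @param y_pred Predictions, mg/kg.
#' @return RMSE in mg/kg.
#' @export
rmse <- function(y_true, y_pred) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  if (length(y_true) == 0L) stop("empty input")
  sqrt(mean((y_true - y_pred)^2))
}

#' Relative percent deviation (ratio of performance to deviation)
#'
#' Sample standard deviation (ddof = 1) of the test references divided by
#' RMSEP. Conventional reading: > 1.5 good, 2.0--2.5 satisfactory, > 3.0 a
#' valid prediction model.
#'
#' @param y_true_test Test-partition reference values (length >= 2).
#' @param rmsep Root mean square error of prediction (> 0).
#' @return Dimensionless RPD (Inf with a warning when \code{rmsep} is 0).
#' @export
rpd <- function(y_true_test, rmsep) {
  if (length(y_true_test) < 2L) stop("need at least 2 test values")
  if (rmsep < 0) stop("rmsep must be >= 0")
  if (rmsep == 0) {
    warning("rmsep is 0; RPD reported as infinite")
    return(Inf)
  }
  stats::sd(y_true_test) / rmsep
}

#' Qualitative RPD class
#'
#' @param rpd_value RPD value.
#' @return One of \code{"valid"} (> 3.0), \code{"satisfactory"} (2.0--2.5),
#'   \code{"good"} (> 1.5) or \code{"poor"}.
#' @export
rpd_class <- function(rpd_value) {
  if (rpd_value > 3.0) "valid"
  else if (rpd_value >= 2.0 && rpd_value <= 2.5) "satisfactory"
  else if (rpd_value > 1.5) "good"
  else "poor"
}

#' Build stratified cross-validation folds
#'
#' Near-equal fold sizes; when a stratification variable (typically the
#' concentration group) is given, rows are dealt to folds within each
#' stratum so every fold spans the concentration range.
#'
#' @param n Number of rows.
#' @param k Fold count (>= 2).
#' @param strata Optional stratification vector of length \code{n}.
#' @param seed Integer seed for the per-call generator.
#' @return Object of class \code{fold_spec}: list with \code{k},
#'   \code{assignments} (integer row -> fold map) and \code{seed}.
#' @export
make_folds <- function(n, k = 5L, strata = NULL, seed = 1L) {
  if (k < 2L) stop("k must be >= 2")
  if (k > n) stop(sprintf("fold count %d exceeds row count %d", k, n))
  assignments <- integer(n)
  withr::with_seed(as.integer(seed), {
    groups <- if (is.null(strata)) rep(1L, n) else as.integer(factor(strata))
    offset <- sample.int(k, 1L) - 1L  # decouple stratum boundaries from fold 1
    pos <- 0L
    for (g in unique(groups)) {
      rows <- which(groups == g)
      rows <- rows[sample.int(length(rows))]
      assignments[rows] <- ((pos + seq_along(rows) - 1L + offset) %% k) + 1L
      pos <- pos + length(rows)
    }
  })
  structure(list(k = as.integer(k), assignments = assignments, seed = as.integer(seed)),
            class = "fold_spec")
}

#' Cross-validate a model factory
#'
#' The factory is refitted inside every fold on the fold's training rows
#' only, so any fitted state it creates (preprocessing references, scalers,
#' selections) never sees the held-out rows. Out-of-fold predictions are
#' concatenated and the metrics computed once on the full vector.
#'
#' @param model_factory Function \code{(X_train, y_train)} returning an
#'   object with a working \code{predict_fun}; alternatively a function
#'   returning a plain prediction function. See Details.
#' @param X Calibration predictors.
#' @param y Calibration response.
#' @param folds A \code{fold_spec}.
#' @details The factory must return either (a) a function of \code{X_new}
#'   producing predictions, or (b) a model for which a \code{predict}-style
#'   function is resolvable (\code{plsr_model}, \code{bpnn_model}).
#' @return List with \code{R2_cv}, \code{RMSECV} and \code{oof}
#'   (out-of-fold predictions).
#' @export
cross_validate <- function(model_factory, X, y, folds) {
  stopifnot(inherits(folds, "fold_spec"))
  X <- as.matrix(X)
  if (length(y) != nrow(X)) stop("y length does not match row count")
  oof <- rep(NA_real_, length(y))
  for (f in seq_len(folds$k)) {
    tr <- which(folds$assignments != f)
    te <- which(folds$assignments == f)
    if (length(te) == 0L) stop(sprintf("fold %d is empty", f))
    fitted <- tryCatch(model_factory(X[tr, , drop = FALSE], y[tr]),
                       error = function(e) stop(sprintf("model factory failed in fold %d: %s",
                                                        f, conditionMessage(e))))
    oof[te] <- predict_any(fitted, X[te, , drop = FALSE])
  }
  list(R2_cv = r_squared(y, oof), RMSECV = rmse(y, oof), oof = oof)
}

predict_any <- function(fitted, X_new) {
  if (is.function(fitted)) return(as.numeric(fitted(X_new)))
  if (inherits(fitted, "plsr_model")) return(plsr_predict(fitted, X_new))
  if (inherits(fitted, "bpnn_model")) return(bpnn_predict(fitted, X_new))
  stop("cannot predict from object of class ", paste(class(fitted), collapse = "/"))
}

#' Full performance report for one model
#'
#' Fits the factory on the calibration partition, computes R2c/RMSEC there,
#' R2cv/RMSECV by k-fold cross-validation of the same factory on the
#' calibration partition only, and R2p/RMSEP/RPD on the test partition.
#' Aborts if any sample id appears in both partitions.
#'
#' @param model_factory Function \code{(X_train, y_train) -> fitted model}.
#' @param X_train,y_train Calibration partition.
#' @param X_test,y_test Test partition.
#' @param folds A \code{fold_spec} for the calibration rows.
#' @param element Element label ("Cd", "Cu", "Pb").
#' @param model_name Model label for the report.
#' @param n_variables Number of input variables (for table parity).
#' @param train_ids,test_ids Optional sample ids used for the leakage guard.
#' @param seed Seed recorded in the report.
#' @return Object of class \code{performance_report} (a one-row-style list
#'   with all seven metrics, the duration in seconds, and labels).
#' @export
evaluate_model <- function(model_factory, X_train, y_train, X_test, y_test,
                           folds, element = NA_character_, model_name = "model",
                           n_variables = ncol(as.matrix(X_train)),
                           train_ids = NULL, test_ids = NULL, seed = NA_integer_) {
  if (!is.null(train_ids) && !is.null(test_ids) &&
      length(intersect(train_ids, test_ids)) > 0L)
    stop("leakage guard: sample ids shared between train and test partitions: ",
         paste(utils::head(intersect(train_ids, test_ids), 5L), collapse = ", "))
  t0 <- proc.time()[["elapsed"]]
  fitted <- model_factory(as.matrix(X_train), y_train)
  pred_c <- predict_any(fitted, as.matrix(X_train))
  cv <- cross_validate(model_factory, X_train, y_train, folds)
  pred_p <- predict_any(fitted, as.matrix(X_test))
  rmsep <- rmse(y_test, pred_p)
  elapsed <- proc.time()[["elapsed"]] - t0
  structure(list(element = element, model_name = model_name,
                 n_variables = n_variables,
                 R2_c = r_squared(y_train, pred_c), RMSEC = rmse(y_train, pred_c),
                 R2_cv = cv$R2_cv, RMSECV = cv$RMSECV,
                 R2_p = r_squared(y_test, pred_p), RMSEP = rmsep,
                 RPD = rpd(y_test, rmsep),
                 duration = elapsed, seed = seed,
                 predictions_test = pred_p),
            class = "performance_report")
}

#' @export
print.performance_report <- function(x, ...) {
  cat(sprintf("<performance_report> %s / %s (%d variables)\n",
              x$element, x$model_name, x$n_variables))
  cat(sprintf("  R2c %.3f  RMSEC %.3f | R2cv %.3f  RMSECV %.3f | R2p %.3f  RMSEP %.3f  RPD %.2f (%s)\n",
              x$R2_c, x$RMSEC, x$R2_cv, x$RMSECV, x$R2_p, x$RMSEP, x$RPD,
              rpd_class(x$RPD)))
  invisible(x)
}

#' Collect reports into a table
#'
#' @param reports List of \code{performance_report} objects.
#' @return \code{data.frame} shaped like the conventional results tables
#'   (one row per element x model, metric columns, full precision).
#' @export
report_table <- function(reports) {
  do.call(rbind, lapply(reports, function(r) {
    data.frame(element = r$element, model = r$model_name,
               n_variables = r$n_variables,
               R2_c = r$R2_c, RMSEC = r$RMSEC, R2_cv = r$R2_cv,
               RMSECV = r$RMSECV, R2_p = r$R2_p, RMSEP = r$RMSEP,
               RPD = r$RPD, duration_s = r$duration, seed = r$seed,
               stringsAsFactors = FALSE)
  }))
}

#' Per-sample relative prediction errors
#'
#' \eqn{|\hat y - y| / y} for positive references; for zero references the
#' absolute error is recorded and flagged. Each sample is labelled as
#' low/high concentration relative to the median reference (threshold
#' configurable).
#'
#' @param y_true Reference values.
#' @param y_pred Predictions.
#' @param threshold Stratum boundary; defaults to \code{median(y_true)}.
#' @return \code{data.frame} with columns \code{y_true}, \code{y_pred},
#'   \code{error}, \code{error_type} ("relative"/"absolute"),
#'   \code{stratum} ("low"/"high").
#' @export
relative_error_table <- function(y_true, y_pred, threshold = stats::median(y_true)) {
  if (length(y_true) != length(y_pred)) stop("length mismatch")
  zero <- y_true == 0
  err <- ifelse(zero, abs(y_pred - y_true), abs(y_pred - y_true) / y_true)
  data.frame(y_true = y_true, y_pred = y_pred, error = err,
             error_type = ifelse(zero, "absolute", "relative"),
             stratum = ifelse(y_true <= threshold, "low", "high"),
             stringsAsFactors = FALSE)
}
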