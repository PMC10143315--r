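# Config-driven orchestration: synthetic data (or a spectra CSV) ->
# replicate-aware split -> preprocessing selection -> variable selection ->
# models -> performance reports and per-sample relative-error tables.

#' Pipeline configuration
#'
#' @param input \code{"synthetic"} or a path to a spectra CSV.
#' @param generator A \code{generator_config} (used when input is
#'   synthetic).
#' @param elements Subset of Cd, Cu, Pb to model.
#' @param preprocessing \code{"auto"} (RMSECV selection among all methods)
#'   or a fixed method name.
#' @param selectors Subset of \code{"PCA"}, \code{"SPA"}, \code{"CARS"}.
#' @param models Subset of \code{"PLSR"}, \code{"BP"}, \code{"PSO-BP"},
#'   \code{"SSA-BP"}.
#' @param n_train_reps Replicates per (brand, group) in the calibration
#'   partition.
#' @param cv_k Cross-validation fold count.
#' @param seed Global seed; all stage seeds derive from it.
#' @param repeats Stochastic-model repeats; the run with the median RMSEP is
#'   flagged as the headline, all runs retained.
#' @param variance_target PCA cumulative explained-variance rule.
#' @param spa_k_max Maximum SPA chain length.
#' @param cars_runs CARS Monte Carlo runs.
#' @param opt_iterations Metaheuristic iterations for PSO-BP/SSA-BP
#'   (\code{NULL} keeps each optimizer's default).
#' @param epochs Back-propagation epochs.
#' @param error_threshold Low/high stratum boundary for the relative-error
#'   tables; \code{NULL} uses the median test reference.
#' @param output_dir Directory for CSV/JSON artifacts; \code{NULL} skips
#'   writing.
#' @return List of class \code{pipeline_config}.
#' @export
pipeline_config <- function(input = "synthetic", generator = generator_config(),
                            elements = ELEMENTS, preprocessing = "auto",
                            selectors = c("PCA", "SPA", "CARS"),
                            models = c("PLSR", "BP", "PSO-BP", "SSA-BP"),
                            n_train_reps = 2L, cv_k = 5L, seed = 1L,
                            repeats = 1L, variance_target = 0.95,
                            spa_k_max = 10L, cars_runs = 50L,
                            opt_iterations = NULL, epochs = 1000L,
                            error_threshold = NULL, output_dir = NULL) {
  elements <- match.arg(elements, ELEMENTS, several.ok = TRUE)
  selectors <- match.arg(selectors, c("PCA", "SPA", "CARS"), several.ok = TRUE)
  models <- match.arg(models, c("PLSR", "BP", "PSO-BP", "SSA-BP"), several.ok = TRUE)
  if (!identical(preprocessing, "auto"))
    preprocessing <- match.arg(preprocessing, PREPROCESS_METHODS)
  stopifnot(length(elements) >= 1L, length(selectors) >= 1L,
            length(models) >= 1L, repeats >= 1L)
  structure(list(input = input, generator = generator, elements = elements,
                 preprocessing = preprocessing, selectors = selectors,
                 models = models, n_train_reps = as.integer(n_train_reps),
                 cv_k = as.integer(cv_k), seed = as.integer(seed),
                 repeats = as.integer(repeats),
                 variance_target = variance_target,
                 spa_k_max = as.integer(spa_k_max),
                 cars_runs = as.integer(cars_runs),
                 opt_iterations = opt_iterations,
                 epochs = as.integer(epochs),
                 error_threshold = error_threshold,
                 output_dir = output_dir),
            class = "pipeline_config")
}

#' Read a pipeline configuration from YAML
#'
#' Keys mirror the arguments of \code{pipeline_config}; \code{generator}
#' may itself be a map of \code{generator_config} arguments.
#'
#' @param path YAML file.
#' @return A \code{pipeline_config}.
#' @export
pipeline_config_from_yaml <- function(path) {
  cfg <- yaml::read_yaml(path)
  if (!is.null(cfg$generator)) {
    gen_args <- cfg$generator
    if (!is.null(gen_args$sensitivity)) gen_args$sensitivity <- unlist(gen_args$sensitivity)
    if (!is.null(gen_args$background_median))
      gen_args$background_median <- unlist(gen_args$background_median)
    cfg$generator <- do.call(generator_config, gen_args)
  }
  do.call(pipeline_config, cfg)
}

derive_seed <- function(seed, ...) {
  key <- paste(c(seed, ...), collapse = "|")
  # deterministic small-integer hash of the stage path
  as.integer(sum(utf8ToInt(key) * (seq_along(utf8ToInt(key)) %% 97 + 1)) %% 2147483629L + 1L)
}

model_factory_for <- function(model_name, cfg, seed, repeat_i) {
  s <- derive_seed(seed, model_name, repeat_i)
  tc <- train_config(epochs = cfg$epochs, seed = s)
  switch(model_name,
    "PLSR" = function(Xtr, ytr) {
      nc <- plsr_select_ncomp(Xtr, ytr, max_components = 20L, seed = s)$n_components
      plsr_fit(Xtr, ytr, n_components = nc)
    },
    "BP" = function(Xtr, ytr) {
      m <- bpnn_init(ncol(Xtr), bpnn_hidden_size(ncol(Xtr)), 1L, seed = s)
      bpnn_train(m, Xtr, ytr, tc)
    },
    "PSO-BP" = function(Xtr, ytr) {
      oc <- if (is.null(cfg$opt_iterations)) pso_config(seed = s)
            else pso_config(iterations = cfg$opt_iterations, seed = s)
      hybrid_train(Xtr, ytr, method = "PSO", opt_cfg = oc, train_cfg = tc, seed = s)$model
    },
    "SSA-BP" = function(Xtr, ytr) {
      oc <- if (is.null(cfg$opt_iterations)) ssa_config(seed = s)
            else ssa_config(iterations = cfg$opt_iterations, seed = s)
      hybrid_train(Xtr, ytr, method = "SSA", opt_cfg = oc, train_cfg = tc, seed = s)$model
    },
    stop("unknown model: ", model_name))
}

log_stage <- function(verbose, fmt, ...) {
  if (verbose) message(sprintf(paste0("[libsquant] ", fmt), ...))
}

#' Run the full calibration pipeline
#'
#' Per element: replicate-aware split; preprocessing (RMSECV selection when
#' "auto", fitted on the calibration partition only); each requested
#' selector applied to the calibration data; each requested model trained on
#' each selector's variables (stochastic models repeated
#' \code{cfg$repeats} times with derived seeds, median-RMSEP run flagged as
#' headline); per-sample relative-error tables for the test partition.
#' All artifacts are written to \code{cfg$output_dir} when set, with the
#' config and seeds echoed.
#'
#' @param cfg A \code{pipeline_config}.
#' @param verbose Log one line per stage.
#' @return List of class \code{pipeline_result}: \code{data}, \code{split},
#'   per-element list with \code{preprocess} (choice + table),
#'   \code{selections}, \code{reports} (all repeats),
#'   \code{headline} (data.frame of headline reports), and
#'   \code{relative_errors}.
#' @export
run_pipeline <- function(cfg, verbose = FALSE) {
  stopifnot(inherits(cfg, "pipeline_config"))
  data <- if (identical(cfg$input, "synthetic")) {
    gen <- cfg$generator
    gen$seed <- derive_seed(cfg$seed, "generate")
    log_stage(verbose, "generate: synthetic dataset, seed %d", gen$seed)
    generate_dataset(gen)
  } else {
    log_stage(verbose, "load: %s", cfg$input)
    load_spectra(cfg$input)
  }
  split <- split_by_replicate(data, cfg$n_train_reps,
                              seed = derive_seed(cfg$seed, "split"))
  Xtr_raw <- data$intensities[split$train_idx, , drop = FALSE]
  Xte_raw <- data$intensities[split$test_idx, , drop = FALSE]
  meta_tr <- data$meta[split$train_idx, ]
  meta_te <- data$meta[split$test_idx, ]
  out <- list(config = cfg, data = data, split = split, elements = list())
  for (el in cfg$elements) {
    y_tr <- meta_tr[[el]]
    y_te <- meta_te[[el]]
    folds <- make_folds(length(y_tr), k = cfg$cv_k, strata = meta_tr$group,
                        seed = derive_seed(cfg$seed, "folds", el))
    # preprocessing (calibration rows only drive the choice and the state)
    if (identical(cfg$preprocessing, "auto")) {
      sel <- select_preprocessing(Xtr_raw, y_tr, folds = folds)
      pp <- sel$fitted
      pp_table <- sel$table
    } else {
      pp <- fit_preprocess(cfg$preprocessing, X_cal = Xtr_raw)
      pp_table <- NULL
    }
    log_stage(verbose, "%s: preprocessing = %s", el, pp$name)
    Xtr <- apply_preprocess(pp, Xtr_raw)
    Xte <- apply_preprocess(pp, Xte_raw)
    # variable selection on calibration data
    selections <- list()
    features <- list()
    for (sel_name in cfg$selectors) {
      if (sel_name == "PCA") {
        pca <- pca_fit(Xtr, variance_target = cfg$variance_target)
        selections$PCA <- pca
        features$PCA <- list(train = pca_transform(pca, Xtr),
                             test = pca_transform(pca, Xte),
                             n_variables = pca$k)
      } else if (sel_name == "SPA") {
        vs <- spa_select(Xtr, y_tr, k_min = 1L, k_max = cfg$spa_k_max, folds = folds)
        selections$SPA <- vs
        features$SPA <- list(train = Xtr[, vs$indices, drop = FALSE],
                             test = Xte[, vs$indices, drop = FALSE],
                             n_variables = length(vs$indices))
      } else if (sel_name == "CARS") {
        vs <- cars_select(Xtr, y_tr, n_runs = cfg$cars_runs, folds = folds,
                          seed = derive_seed(cfg$seed, "cars", el))
        selections$CARS <- vs
        features$CARS <- list(train = Xtr[, vs$indices, drop = FALSE],
                              test = Xte[, vs$indices, drop = FALSE],
                              n_variables = length(vs$indices))
      }
      log_stage(verbose, "%s: selector %s -> %d variables", el, sel_name,
                features[[sel_name]]$n_variables)
    }
    # models
    reports <- list()
    headline <- list()
    rel_errors <- list()
    for (sel_name in names(features)) {
      ft <- features[[sel_name]]
      for (model_name in cfg$models) {
        n_rep <- if (model_name == "PLSR") 1L else cfg$repeats
        runs <- vector("list", n_rep)
        for (r in seq_len(n_rep)) {
          factory <- model_factory_for(model_name, cfg, cfg$seed, r)
          runs[[r]] <- evaluate_model(
            factory, ft$train, y_tr, ft$test, y_te, folds,
            element = el, model_name = paste0(sel_name, "-", model_name),
            n_variables = ft$n_variables,
            train_ids = split$train_ids, test_ids = split$test_ids,
            seed = derive_seed(cfg$seed, model_name, r))
        }
        rmseps <- vapply(runs, `[[`, 0, "RMSEP")
        head_i <- which.min(abs(rmseps - stats::median(rmseps)))
        key <- paste0(sel_name, "-", model_name)
        reports[[key]] <- runs
        headline[[key]] <- runs[[head_i]]
        rel_errors[[key]] <- relative_error_table(
          y_te, runs[[head_i]]$predictions_test,
          threshold = if (is.null(cfg$error_threshold)) stats::median(y_te)
                      else cfg$error_threshold)
        log_stage(verbose, "%s: %s RMSEP %.3f (headline of %d run(s))",
                  el, key, headline[[key]]$RMSEP, n_rep)
      }
    }
    out$elements[[el]] <- list(preprocess = list(method = pp$name, table = pp_table),
                               selections = selections, reports = reports,
                               headline = report_table(headline),
                               relative_errors = rel_errors)
  }
  class(out) <- "pipeline_result"
  if (!is.null(cfg$output_dir)) write_pipeline_outputs(out, cfg$output_dir)
  out
}

#' @export
print.pipeline_result <- function(x, ...) {
  cat(sprintf("<pipeline_result> %d samples, elements: %s\n",
              nrow(x$data$intensities), paste(names(x$elements), collapse = ", ")))
  for (el in names(x$elements)) {
    cat(sprintf("-- %s (preprocessing: %s)\n", el, x$elements[[el]]$preprocess$method))
    print(x$elements[[el]]$headline[c("model", "n_variables", "R2_p", "RMSEP", "RPD")],
          row.names = FALSE, digits = 4)
  }
  invisible(x)
}

write_pipeline_outputs <- function(result, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  cfg <- result$config
  cfg_echo <- cfg
  cfg_echo$generator <- cfg$generator[c("design", "seed", "noise_sd",
                                        "scatter_sdlog", "brand_effect_sd")]
  writeLines(jsonlite::toJSON(unclass(cfg_echo), auto_unbox = TRUE, digits = NA,
                              force = TRUE, null = "null"),
             file.path(dir, "config.json"))
  writeLines(split_to_json(result$split), file.path(dir, "split.json"))
  for (el in names(result$elements)) {
    res <- result$elements[[el]]
    if (!is.null(res$preprocess$table))
      utils::write.csv(res$preprocess$table,
                       file.path(dir, sprintf("preprocessing_%s.csv", el)),
                       row.names = FALSE)
    utils::write.csv(res$headline, file.path(dir, sprintf("reports_%s.csv", el)),
                     row.names = FALSE)
    all_runs <- report_table(unlist(res$reports, recursive = FALSE))
    writeLines(jsonlite::toJSON(all_runs, dataframe = "rows", digits = NA),
               file.path(dir, sprintf("reports_%s.json", el)))
    for (key in names(res$relative_errors))
      utils::write.csv(res$relative_errors[[key]],
                       file.path(dir, sprintf("relative_errors_%s_%s.csv", el, key)),
                       row.names = FALSE)
    for (sel_name in names(res$selections)) {
      s <- res$selections[[sel_name]]
      if (inherits(s, "variable_subset"))
        subset_to_json(s, file.path(dir, sprintf("subset_%s_%s.json", el, sel_name)))
      else
        writeLines(jsonlite::toJSON(list(method = "PCA", k = s$k,
                                         explained_ratio = s$explained_ratio),
                                    auto_unbox = TRUE, digits = NA),
                   file.path(dir, sprintf("subset_%s_%s.json", el, sel_name)))
    }
  }
  invisible(dir)
}
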