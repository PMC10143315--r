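#' @keywords internal
"_PACKAGE"

ELEMENTS <- c("Cd", "Cu", "Pb")
META_COLS <- c("sample_id", "brand", "group", "replicate", "Cd", "Cu", "Pb")

#' Construct a spectral axis
#'
#' A strictly ascending wavelength grid. The default grid is 1024 equally
#' spaced channels spanning 210--231 nm, the window in which the Cd, Cu and
#' Pb emission lines used throughout this package fall.
#'
#' @param wavelengths Numeric vector of wavelengths in nm, strictly
#'   ascending. Defaults to 1024 points over \code{[210, 231]}.
#' @return An object of class \code{spectral_axis}: a numeric vector of
#'   wavelengths with attribute \code{n_channels}.
#' @export
spectral_axis <- function(wavelengths = seq(210, 231, length.out = 1024)) {
  wavelengths <- as.numeric(wavelengths)
  if (length(wavelengths) < 1L) stop("spectral axis must have at least one channel")
  if (anyNA(wavelengths)) stop("spectral axis contains missing values")
  if (length(wavelengths) > 1L && any(diff(wavelengths) <= 0)) {
    bad <- which(diff(wavelengths) <= 0)[1L]
    stop(sprintf("wavelengths must be strictly ascending (violation at channel %d: %.6f >= %.6f)",
                 bad, wavelengths[bad], wavelengths[bad + 1L]))
  }
  structure(wavelengths, n_channels = length(wavelengths), class = "spectral_axis")
}

#' Construct a spectra set
#'
#' The universal container moved through the pipeline: a sample-by-wavelength
#' intensity matrix plus per-sample metadata (brand, gradient group,
#' replicate, and reference Cd/Cu/Pb concentrations in mg/kg).
#'
#' @param axis A \code{spectral_axis}.
#' @param intensities Numeric matrix, \code{n_samples x n_channels}.
#' @param meta \code{data.frame} with columns \code{sample_id}, \code{brand},
#'   \code{group}, \code{replicate}, \code{Cd}, \code{Cu}, \code{Pb}; one row
#'   per spectrum.
#' @return An object of class \code{spectra_set} (list with elements
#'   \code{axis}, \code{intensities}, \code{meta}).
#' @export
spectra_set <- function(axis, intensities, meta) {
  if (!inherits(axis, "spectral_axis")) axis <- spectral_axis(axis)
  intensities <- as.matrix(intensities)
  storage.mode(intensities) <- "double"
  if (ncol(intensities) != length(axis))
    stop(sprintf("intensity matrix has %d columns but axis has %d channels",
                 ncol(intensities), length(axis)))
  if (!is.data.frame(meta)) stop("meta must be a data.frame")
  missing_cols <- setdiff(META_COLS, names(meta))
  if (length(missing_cols))
    stop("meta is missing columns: ", paste(missing_cols, collapse = ", "))
  meta <- meta[META_COLS]
  if (nrow(meta) != nrow(intensities))
    stop(sprintf("meta has %d rows but intensity matrix has %d", nrow(meta), nrow(intensities)))
  if (anyNA(intensities)) stop("intensity matrix contains missing values")
  if (nrow(meta) > 0L) {
    meta$sample_id <- as.character(meta$sample_id)
    if (anyDuplicated(meta$sample_id))
      stop("duplicated sample_id: ", meta$sample_id[anyDuplicated(meta$sample_id)])
    for (col in c("brand", "group", "replicate"))
      if (any(meta[[col]] != as.integer(meta[[col]])))
        stop(sprintf("meta column '%s' must be integer-valued", col))
    if (anyNA(meta[ELEMENTS]) || any(as.matrix(meta[ELEMENTS]) < 0))
      stop("reference concentrations must be present and non-negative")
  }
  rownames(intensities) <- meta$sample_id
  structure(list(axis = axis, intensities = intensities, meta = meta),
            class = "spectra_set")
}

#' @export
print.spectra_set <- function(x, ...) {
  cat(sprintf("<spectra_set> %d samples x %d channels (%.2f-%.2f nm)\n",
              nrow(x$intensities), length(x$axis),
              if (length(x$axis)) min(x$axis) else NA, if (length(x$axis)) max(x$axis) else NA))
  if (nrow(x$meta)) {
    cat(sprintf("  brands %s | groups %s | replicates %s\n",
                paste(range(x$meta$brand), collapse = "-"),
                paste(range(x$meta$group), collapse = "-"),
                paste(range(x$meta$replicate), collapse = "-")))
  }
  invisible(x)
}

#' @export
dim.spectra_set <- function(x) dim(x$intensities)

#' Subset a spectra set by row
#'
#' @param set A \code{spectra_set}.
#' @param i Row indices (integer or logical).
#' @return A \code{spectra_set} with the selected samples.
#' @export
subset_samples <- function(set, i) {
  spectra_set(set$axis, set$intensities[i, , drop = FALSE], set$meta[i, , drop = FALSE])
}

#' Plot spectra
#'
#' Overlays up to \code{max_rows} spectra against wavelength; a quick visual
#' check of peak positions and baseline.
#'
#' @param x A \code{spectra_set}.
#' @param max_rows Maximum number of spectra to overlay.
#' @param ... Passed to \code{matplot}.
#' @export
plot.spectra_set <- function(x, max_rows = 12L, ...) {
  n <- min(nrow(x$intensities), max_rows)
  graphics::matplot(as.numeric(x$axis), t(x$intensities[seq_len(n), , drop = FALSE]),
                    type = "l", lty = 1, xlab = "wavelength (nm)",
                    ylab = "intensity (a.u.)", ...)
  invisible(x)
}

fmt_wl <- function(w) formatC(w, format = "f", digits = 4)

#' Write a spectra set to CSV
#'
#' Dialect: comma-separated, UTF-8, '.' decimal; seven metadata columns
#' (\code{sample_id, brand, group, replicate, Cd, Cu, Pb}) followed by one
#' column per channel whose header is the wavelength in nm formatted to four
#' decimals. Intensities and concentrations are written at full double
#' precision so that \code{load_spectra} round-trips.
#'
#' @param set A \code{spectra_set}.
#' @param path Output file path.
#' @return \code{path}, invisibly.
#' @seealso [load_spectra()]
#' @export
save_spectra <- function(set, path) {
  stopifnot(inherits(set, "spectra_set"))
  header <- c(META_COLS, fmt_wl(as.numeric(set$axis)))
  con <- tryCatch(file(path, "w", encoding = "UTF-8"),
                  error = function(e) stop("cannot open '", path, "' for writing: ",
                                           conditionMessage(e)))
  on.exit(close(con))
  writeLines(paste(header, collapse = ","), con)
  n <- nrow(set$intensities)
  if (n > 0L) {
    num <- function(v) formatC(v, format = "g", digits = 17)
    meta_part <- cbind(set$meta$sample_id,
                       set$meta$brand, set$meta$group, set$meta$replicate,
                       num(set$meta$Cd), num(set$meta$Cu), num(set$meta$Pb))
    spec_part <- matrix(num(set$intensities), nrow = n)
    writeLines(apply(cbind(meta_part, spec_part), 1L, paste, collapse = ","), con)
  }
  invisible(path)
}

#' Read a spectra set from CSV
#'
#' Reads the dialect written by \code{save_spectra} and validates all
#' container invariants (ascending wavelengths, complete metadata, no
#' missing intensities). Parse failures name the offending row/column.
#'
#' @param path CSV file path.
#' @return A \code{spectra_set}.
#' @seealso [save_spectra()]
#' @export
load_spectra <- function(path) {
  if (!file.exists(path)) stop("file not found: ", path)
  df <- utils::read.csv(path, check.names = FALSE, colClasses = NA,
                        stringsAsFactors = FALSE, encoding = "UTF-8")
  if (!all(META_COLS %in% names(df)[seq_len(min(7L, ncol(df)))]))
    stop("malformed header: expected leading columns ",
         paste(META_COLS, collapse = ", "))
  wl_names <- names(df)[-seq_len(7L)]
  if (length(wl_names) < 1L) stop("malformed header: no wavelength columns")
  wl <- suppressWarnings(as.numeric(wl_names))
  if (anyNA(wl)) stop("malformed header: non-numeric wavelength column '",
                      wl_names[which(is.na(wl))[1L]], "'")
  if (anyDuplicated(wl)) stop("duplicated wavelength column: ", wl_names[anyDuplicated(wl)])
  if (is.unsorted(wl, strictly = TRUE)) stop("wavelength columns must be strictly ascending")
  if (nrow(df) == 0L) {
    return(spectra_set(spectral_axis(wl),
                       matrix(numeric(0), 0L, length(wl)),
                       df[META_COLS]))
  }
  for (col in c("brand", "group", "replicate", ELEMENTS, wl_names)) {
    v <- suppressWarnings(as.numeric(df[[col]]))
    if (anyNA(v) && !anyNA(df[[col]]))
      stop(sprintf("non-numeric cell in column '%s', row %d", col,
                   which(is.na(v))[1L]))
    if (anyNA(v))
      stop(sprintf("missing value in column '%s', row %d", col, which(is.na(v))[1L]))
    df[[col]] <- v
  }
  spectra_set(spectral_axis(wl), as.matrix(df[wl_names]), df[META_COLS])
}

#' Replicate-aware train/test split
#'
#' Partitions samples so that, within every (brand, group) cell,
#' exactly \code{n_train_reps} replicates go to the calibration (training)
#' partition and the remainder to the test partition. Replicates are chosen
#' uniformly at random per cell from a dedicated generator seeded per call,
#' so whole replicate pellets never straddle the partitions. For the default
#' 8 brands x 8 groups x 3 replicates design with \code{n_train_reps = 2}
#' this yields the 128/64 calibration/test division.
#'
#' @param set A \code{spectra_set}.
#' @param n_train_reps Number of replicates per (brand, group) cell assigned
#'   to the calibration partition.
#' @param seed Integer seed for the per-call random generator.
#' @return An object of class \code{split_spec}: list with integer vectors
#'   \code{train_idx}, \code{test_idx} (1-based row indices into the set),
#'   character vectors \code{train_ids}, \code{test_ids}, and \code{seed}.
#' @export
split_by_replicate <- function(set, n_train_reps = 2L, seed = 1L) {
  stopifnot(inherits(set, "spectra_set"))
  meta <- set$meta
  if (nrow(meta) == 0L) {
    return(structure(list(train_idx = integer(0), test_idx = integer(0),
                          train_ids = character(0), test_ids = character(0),
                          seed = as.integer(seed)),
                     class = "split_spec"))
  }
  cells <- split(seq_len(nrow(meta)), list(brand = meta$brand, group = meta$group),
                 drop = TRUE)
  counts <- lengths(cells)
  if (length(unique(counts)) != 1L) {
    bad <- names(counts)[counts != stats::median(counts)]
    stop("unequal replicate counts across (brand, group) cells: ",
         paste(bad, collapse = ", "))
  }
  n_reps <- counts[[1L]]
  if (n_train_reps >= n_reps || n_train_reps < 1L)
    stop(sprintf("n_train_reps must be in [1, %d)", n_reps))
  train_idx <- withr::with_seed(as.integer(seed), {
    unlist(lapply(cells, function(rows) {
      rows[sample.int(length(rows), n_train_reps)]
    }), use.names = FALSE)
  })
  train_idx <- sort(train_idx)
  test_idx <- setdiff(seq_len(nrow(meta)), train_idx)
  structure(list(train_idx = train_idx, test_idx = test_idx,
                 train_ids = meta$sample_id[train_idx],
                 test_ids = meta$sample_id[test_idx],
                 seed = as.integer(seed)),
            class = "split_spec")
}

#' @export
print.split_spec <- function(x, ...) {
  cat(sprintf("<split_spec> %d train / %d test (seed %d)\n",
              length(x$train_idx), length(x$test_idx), x$seed))
  invisible(x)
}

#' Serialize a split to JSON
#'
#' @param split A \code{split_spec}.
#' @param path Optional file path; when \code{NULL} the JSON string is
#'   returned.
#' @return JSON string (invisibly when written to file).
#' @export
split_to_json <- function(split, path = NULL) {
  stopifnot(inherits(split, "split_spec"))
  obj <- list(train = split$train_ids, test = split$test_ids, seed = split$seed)
  js <- jsonlite::toJSON(obj, auto_unbox = TRUE, digits = NA)
  if (!is.null(path)) {
    writeLines(js, path)
    return(invisible(js))
  }
  js
}
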