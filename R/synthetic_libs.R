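# Synthetic LIBS spectra with the spiked concentration-gradient study design.
# Emission line positions follow the NIST ASD lines identifiable for Cd, Cu
# and Pb in the 210-231 nm window; relative strengths and all instrument-like
# parameters are generator choices, not physical constants.

# molar masses (g/mol) consistent with the printed spike-volume arithmetic;
# exact IUPAC values available via build_gradient_plan(exact_masses = TRUE)
MOLAR_MASS_NOMINAL <- c(Cd = 112.4, Cu = 64, Pb = 207.2)
MOLAR_MASS_IUPAC   <- c(Cd = 112.414, Cu = 63.546, Pb = 207.2)

GRADIENT_LEVELS <- list(
  Cd = c(0, 5, 10, 20, 25, 50, 80, 100),
  Cu = c(0, 20, 40, 60, 80, 100, 200, 300),
  Pb = c(0, 5, 20, 40, 60, 80, 100, 200)
)

#' Default analyte emission lines
#'
#' The Cd, Cu and Pb emission lines within 210--231 nm used by the
#' generator: Cd II 214.44 and 226.50 nm, Cd I 228.80 nm, Cu II 217.94,
#' 222.89 and 224.26 nm, Pb I 217.00 nm and Pb II 220.35 nm. Relative
#' strengths are generator conventions chosen so each element has one
#' dominant line.
#'
#' @return \code{data.frame} with columns \code{element}, \code{stage},
#'   \code{center} (nm) and \code{relative_strength}.
#' @export
emission_lines <- function() {
  data.frame(
    element = c("Cd", "Cd", "Cd", "Cu", "Cu", "Cu", "Pb", "Pb"),
    stage   = c("II", "II", "I", "II", "II", "II", "I", "II"),
    center  = c(214.44, 226.50, 228.80, 217.94, 222.89, 224.26, 217.00, 220.35),
    relative_strength = c(0.8, 0.9, 1.0, 1.0, 0.7, 0.5, 1.0, 0.8),
    stringsAsFactors = FALSE
  )
}

validate_lines <- function(lines) {
  stopifnot(is.data.frame(lines),
            all(c("element", "stage", "center", "relative_strength") %in% names(lines)))
  if (any(lines$relative_strength <= 0)) stop("relative_strength must be > 0")
  if (any(lines$center < 210 | lines$center > 231))
    stop("line centers must lie within [210, 231] nm")
  lines
}

#' Spike volume for a target concentration
#'
#' Volume of nitrate stock solution needed to bring a powder aliquot to a
#' target analyte concentration:
#' \deqn{V[\mu L] = c_{target} \cdot m_{sample} / (M \cdot C_{molar})}
#' with \eqn{c_{target}} in mg/kg, \eqn{m_{sample}} in g, molar mass
#' \eqn{M} in g/mol and stock molarity in mol/L. Exact arithmetic, no
#' rounding.
#'
#' @param target_conc Target concentration, mg/kg (>= 0).
#' @param sample_mass Powder mass, g (>= 0).
#' @param molarity Stock solution molarity, mol/L (> 0).
#' @param molar_mass Analyte molar mass, g/mol (> 0).
#' @return Spike volume in microliters.
#' @examples
#' spike_volume(5, 5, 0.01, 112.4)   # 22.24 uL of 0.01 M cadmium nitrate
#' @export
spike_volume <- function(target_conc, sample_mass, molarity, molar_mass) {
  if (any(target_conc < 0) || any(sample_mass < 0))
    stop("target_conc and sample_mass must be >= 0")
  if (any(molarity <= 0) || any(molar_mass <= 0))
    stop("molarity and molar_mass must be > 0")
  # mg/kg * g = ug of analyte; ug / (g/mol) = umol; umol / (mol/L) = uL
  target_conc * sample_mass / (molar_mass * molarity)
}

#' Gradient spike plan for one element
#'
#' The concentration gradients used across the eight groups (Cd: 0, 5, 10,
#' 20, 25, 50, 80, 100 mg/kg; Cu: 0, 20, 40, 60, 80, 100, 200, 300 mg/kg;
#' Pb: 0, 5, 20, 40, 60, 80, 100, 200 mg/kg) together with the stock volumes
#' that realize them on 5 g aliquots of 0.01 mol/L nitrate solutions.
#'
#' @param element One of \code{"Cd"}, \code{"Cu"}, \code{"Pb"}.
#' @param sample_mass Powder mass per group, g.
#' @param molarity Stock molarity, mol/L.
#' @param exact_masses Use exact IUPAC molar masses instead of the nominal
#'   roundings (Cd 112.4, Cu 64, Pb 207.2) that reproduce the conventional
#'   printed volumes.
#' @return Object of class \code{spike_plan}: list with \code{element},
#'   \code{molar_mass}, \code{molarity}, \code{sample_mass}, \code{levels}
#'   (mg/kg) and \code{volumes} (uL).
#' @export
build_gradient_plan <- function(element, sample_mass = 5, molarity = 0.01,
                                exact_masses = FALSE) {
  element <- match.arg(element, ELEMENTS)
  mm <- if (exact_masses) MOLAR_MASS_IUPAC[[element]] else MOLAR_MASS_NOMINAL[[element]]
  levels <- GRADIENT_LEVELS[[element]]
  volumes <- spike_volume(levels, sample_mass, molarity, mm)
  structure(list(element = element, molar_mass = mm, molarity = molarity,
                 sample_mass = sample_mass, levels = levels, volumes = volumes),
            class = "spike_plan")
}

#' @export
print.spike_plan <- function(x, ...) {
  cat(sprintf("<spike_plan> %s (%g g powder, %g mol/L stock, M = %g g/mol)\n",
              x$element, x$sample_mass, x$molarity, x$molar_mass))
  print(data.frame(level_mg_kg = x$levels, volume_uL = round(x$volumes, 2)))
  invisible(x)
}

#' Generator configuration
#'
#' All knobs of the synthetic LIBS spectrum generator. Defaults encode the
#' emulated study: 8 brands x 8 gradient groups x 3 replicates on a
#' 1024-channel axis over 210--231 nm, analyte peaks at the known emission
#' lines whose height scales linearly with concentration, a smooth matrix
#' baseline plus fixed decoy matrix lines, per-sample multiplicative scatter
#' and additive offset (so scatter-correcting pretreatments have something
#' real to remove), additive detector noise, and a lognormal per-brand
#' background concentration emulating unspiked native content.
#'
#' @param design Integer triple (n_brands, n_groups, n_replicates).
#' @param axis A \code{spectral_axis}.
#' @param lines Emission line table as from \code{emission_lines()}.
#' @param sensitivity Named numeric: peak-height intensity units per mg/kg
#'   for each element (at relative_strength 1).
#' @param peak_sigma Gaussian line width (sigma), nm.
#' @param baseline_coef Polynomial coefficients (ascending powers) of the
#'   baseline in the reduced variable \code{(lambda - 220.5)/10.5}.
#' @param brand_effect_sd SD of the per-brand lognormal intensity factor.
#' @param scatter_sdlog SD of the per-sample lognormal multiplicative
#'   scatter factor; 0 disables.
#' @param scatter_offset_sd SD of the per-sample additive offset, intensity
#'   units; 0 disables.
#' @param noise_sd SD of the additive per-channel noise, intensity units.
#' @param matrix_lines \code{data.frame(center, strength)} of decoy peaks not
#'   tied to any analyte.
#' @param background_median Named numeric, mg/kg: medians of the lognormal
#'   per-brand background concentrations (group-1 native content).
#' @param background_sdlog SD (log scale) of the background distribution.
#' @param saturation Optional positive constant K for the saturating
#'   response \code{c / (1 + c/K)}; \code{NULL} keeps the response linear.
#' @param seed Integer seed.
#' @return Object of class \code{generator_config} (a validated list).
#' @export
generator_config <- function(design = c(8L, 8L, 3L),
                             axis = spectral_axis(),
                             lines = emission_lines(),
                             sensitivity = c(Cd = 30, Cu = 10, Pb = 15),
                             peak_sigma = 0.06,
                             baseline_coef = c(3000, -800, 500),
                             brand_effect_sd = 0.05,
                             scatter_sdlog = 0.1,
                             scatter_offset_sd = 60,
                             noise_sd = 8,
                             matrix_lines = data.frame(
                               center = c(211.5, 213.2, 216.1, 219.0, 223.5, 229.8),
                               strength = c(4500, 3000, 7000, 2500, 5000, 3500)),
                             background_median = c(Cd = 0.4, Cu = 3, Pb = 0.3),
                             background_sdlog = 0.5,
                             saturation = NULL,
                             seed = 1L) {
  design <- as.integer(design)
  stopifnot(length(design) == 3L, all(design >= 1L))
  if (!inherits(axis, "spectral_axis")) axis <- spectral_axis(axis)
  validate_lines(lines)
  stopifnot(all(ELEMENTS %in% names(sensitivity)), all(sensitivity > 0),
            peak_sigma > 0, brand_effect_sd >= 0, scatter_sdlog >= 0,
            scatter_offset_sd >= 0, noise_sd >= 0, background_sdlog >= 0,
            all(background_median >= 0))
  if (!is.null(saturation) && saturation <= 0) stop("saturation constant must be > 0")
  structure(list(design = design, axis = axis, lines = lines,
                 sensitivity = sensitivity, peak_sigma = peak_sigma,
                 baseline_coef = baseline_coef, brand_effect_sd = brand_effect_sd,
                 scatter_sdlog = scatter_sdlog, scatter_offset_sd = scatter_offset_sd,
                 noise_sd = noise_sd, matrix_lines = matrix_lines,
                 background_median = background_median,
                 background_sdlog = background_sdlog,
                 saturation = saturation, seed = as.integer(seed)),
            class = "generator_config")
}

baseline_values <- function(config) {
  u <- (as.numeric(config$axis) - 220.5) / 10.5
  drop(outer(u, seq_along(config$baseline_coef) - 1L, `^`) %*% config$baseline_coef)
}

gauss_peak <- function(wl, center, sigma) exp(-0.5 * ((wl - center) / sigma)^2)

# deterministic part of a spectrum: baseline + analyte lines + matrix lines
clean_spectrum <- function(conc, config) {
  wl <- as.numeric(config$axis)
  s <- baseline_values(config)
  g <- function(c_el) {
    if (is.null(config$saturation)) c_el else c_el / (1 + c_el / config$saturation)
  }
  for (i in seq_len(nrow(config$lines))) {
    el <- config$lines$element[i]
    c_el <- if (el %in% names(conc)) conc[[el]] else 0
    if (c_el > 0) {
      h <- config$lines$relative_strength[i] * config$sensitivity[[el]] * g(c_el)
      s <- s + h * gauss_peak(wl, config$lines$center[i], config$peak_sigma)
    }
  }
  ml <- config$matrix_lines
  if (!is.null(ml) && nrow(ml)) {
    for (i in seq_len(nrow(ml)))
      s <- s + ml$strength[i] * gauss_peak(wl, ml$center[i], config$peak_sigma)
  }
  s
}

#' Generate one synthetic LIBS spectrum
#'
#' \code{intensity(lambda) = m * [baseline + analyte peaks + matrix lines]
#' + offset + noise}, clipped at zero; the multiplicative factor \code{m},
#' the additive offset and the per-channel noise are drawn from the supplied
#' seed. Analyte peak height is linear in concentration by default or
#' saturating (\code{c/(1 + c/K)}) when the config enables it.
#'
#' @param conc Named numeric (mg/kg) for any subset of Cd, Cu, Pb.
#' @param config A \code{generator_config}.
#' @param seed Integer seed for this spectrum's random draws.
#' @param intensity_factor Extra deterministic multiplicative factor
#'   (e.g. a brand effect); default 1.
#' @return Numeric intensity vector of length \code{n_channels}.
#' @export
generate_spectrum <- function(conc, config, seed = 1L, intensity_factor = 1) {
  if (any(unlist(conc) < 0)) stop("concentrations must be >= 0")
  s <- clean_spectrum(conc, config) * intensity_factor
  withr::with_seed(as.integer(seed), {
    m <- if (config$scatter_sdlog > 0) exp(stats::rnorm(1, 0, config$scatter_sdlog)) else 1
    off <- if (config$scatter_offset_sd > 0) stats::rnorm(1, 0, config$scatter_offset_sd) else 0
    noise <- if (config$noise_sd > 0) stats::rnorm(length(s), 0, config$noise_sd) else 0
    pmax(m * s + off + noise, 0)
  })
}

#' Generate a full synthetic dataset
#'
#' One spectrum per (brand, group, replicate). Per brand, a native
#' background concentration of each element is drawn once (lognormal with
#' configurable medians) and a lognormal intensity factor emulates
#' brand-to-brand matrix differences; per group, the three element gradients
#' follow \code{build_gradient_plan}. Reference concentrations recorded in
#' the metadata are background + spiked level.
#'
#' @param config A \code{generator_config}.
#' @return A \code{spectra_set} with \code{prod(design)} rows.
#' @export
generate_dataset <- function(config = generator_config()) {
  stopifnot(inherits(config, "generator_config"))
  nb <- config$design[1]; ng <- config$design[2]; nr <- config$design[3]
  plans <- lapply(ELEMENTS, build_gradient_plan)
  names(plans) <- ELEMENTS
  levels_of <- function(el, grp) {
    lv <- plans[[el]]$levels
    lv[((grp - 1L) %% length(lv)) + 1L]
  }
  brand_draws <- withr::with_seed(config$seed, {
    list(
      background = vapply(ELEMENTS, function(el) {
        if (config$background_median[[el]] > 0)
          stats::rlnorm(nb, log(config$background_median[[el]]), config$background_sdlog)
        else rep(0, nb)
      }, numeric(nb)),
      factor = if (config$brand_effect_sd > 0)
        exp(stats::rnorm(nb, 0, config$brand_effect_sd)) else rep(1, nb)
    )
  })
  bg <- matrix(brand_draws$background, nrow = nb,
               dimnames = list(NULL, ELEMENTS))
  n <- nb * ng * nr
  X <- matrix(0, n, length(config$axis))
  meta <- data.frame(sample_id = character(n), brand = integer(n),
                     group = integer(n), replicate = integer(n),
                     Cd = numeric(n), Cu = numeric(n), Pb = numeric(n),
                     stringsAsFactors = FALSE)
  row <- 0L
  for (b in seq_len(nb)) for (g in seq_len(ng)) for (r in seq_len(nr)) {
    row <- row + 1L
    conc <- vapply(ELEMENTS, function(el) bg[b, el] + levels_of(el, g), numeric(1))
    # per-spectrum seed derived deterministically; kept < 2^31
    spec_seed <- (config$seed * 7919L + row * 104729L) %% 2147483647L
    X[row, ] <- generate_spectrum(as.list(conc), config, seed = spec_seed,
                                  intensity_factor = brand_draws$factor[b])
    meta$sample_id[row] <- sprintf("B%02d-G%02d-R%d", b, g, r)
    meta$brand[row] <- b; meta$group[row] <- g; meta$replicate[row] <- r
    meta$Cd[row] <- conc[["Cd"]]; meta$Cu[row] <- conc[["Cu"]]; meta$Pb[row] <- conc[["Pb"]]
  }
  spectra_set(config$axis, X, meta)
}

#' Average accumulated per-position spectra
#'
#' Multi-shot acquisition records several accumulated spectra at several
#' sample positions; the first position is discarded (surface contamination
#' / conditioning shots) and the remaining spectra averaged. With 7
#' positions and 3 accumulations this reproduces the 18-spectrum average.
#'
#' @param spectra List of numeric vectors, position-major order (all
#'   accumulations of position 1 first).
#' @param positions Number of positions.
#' @param accumulations Accumulated spectra per position.
#' @return The averaged intensity vector.
#' @export
average_shots <- function(spectra, positions, accumulations) {
  if (length(spectra) != positions * accumulations)
    stop(sprintf("expected %d spectra (%d positions x %d accumulations), got %d",
                 positions * accumulations, positions, accumulations, length(spectra)))
  if (positions < 2L) stop("need at least 2 positions (the first is dropped)")
  keep <- spectra[-seq_len(accumulations)]
  Reduce(`+`, keep) / length(keep)
}
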