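test_that("spike volumes reproduce the printed sample-prep arithmetic", {
  # Cd: 0.01 mol/L stock, 5 g powder, M = 112.4 g/mol
  cd <- spike_volume(c(5, 10, 20, 25, 50, 80, 100), 5, 0.01, 112.4)
  expect_equal(round(cd, 2),
               c(22.24, 44.48, 88.97, 111.21, 222.42, 355.87, 444.84))
  # Cu: M = 64 g/mol
  cu <- spike_volume(c(20, 40, 60, 80, 100, 200, 300), 5, 0.01, 64)
  expect_equal(round(cu, 2),
               c(156.25, 312.5, 468.75, 625, 781.25, 1562.5, 2343.75))
  # Pb: M = 207.2 g/mol (printed list starts at the 20 mg/kg level)
  pb <- spike_volume(c(20, 40, 60, 80, 100, 200), 5, 0.01, 207.2)
  expect_equal(round(pb, 2),
               c(48.26, 96.53, 144.79, 193.05, 241.31, 482.63))
  expect_identical(spike_volume(0, 5, 0.01, 112.4), 0)
  expect_error(spike_volume(5, 5, 0, 112.4), "> 0")
  expect_error(spike_volume(5, 5, 0.01, 0), "> 0")
  expect_error(spike_volume(-1, 5, 0.01, 112.4), ">= 0")
})

test_that("spike volume is linear and invertible back to concentration", {
  v1 <- spike_volume(7, 5, 0.01, 112.4)
  expect_equal(spike_volume(14, 5, 0.01, 112.4), 2 * v1, tolerance = 1e-12)
  expect_equal(spike_volume(7, 10, 0.01, 112.4), 2 * v1, tolerance = 1e-12)
  # invert: conc = V * M * molarity / mass
  plan <- build_gradient_plan("Pb")
  back <- plan$volumes * plan$molar_mass * plan$molarity / plan$sample_mass
  expect_equal(back, plan$levels, tolerance = 1e-9)
})

test_that("gradient plans carry the design's levels and volumes", {
  cd <- build_gradient_plan("Cd")
  expect_identical(cd$levels, c(0, 5, 10, 20, 25, 50, 80, 100))
  expect_equal(max(round(cd$volumes, 2)), 444.84)
  cu <- build_gradient_plan("Cu")
  expect_identical(cu$levels, c(0, 20, 40, 60, 80, 100, 200, 300))
  expect_equal(max(cu$volumes), 2343.75)
  pb <- build_gradient_plan("Pb")
  expect_identical(pb$levels, c(0, 5, 20, 40, 60, 80, 100, 200))
  expect_equal(round(pb$volumes[pb$levels == 20], 2), 48.26)
  # zero level -> zero volume; volumes strictly increasing with level
  for (el in c("Cd", "Cu", "Pb")) {
    p <- build_gradient_plan(el)
    expect_identical(p$volumes[1L], 0)
    expect_true(all(diff(p$volumes) > 0))
  }
  expect_error(build_gradient_plan("Hg"))
})

test_that("noiseless spectrum equals baseline plus lines, linear in conc", {
  cfg <- generator_config(scatter_sdlog = 0, scatter_offset_sd = 0, noise_sd = 0)
  wl <- as.numeric(cfg$axis)
  i_cd <- which.min(abs(wl - 228.80))
  s0 <- generate_spectrum(list(Cd = 0, Cu = 0, Pb = 0), cfg, seed = 1L)
  # baseline value at that channel from the polynomial directly (matrix
  # lines are > 0.9 nm away, > 15 sigma, so their contribution vanishes)
  u <- (wl[i_cd] - 220.5) / 10.5
  expect_equal(s0[i_cd], 3000 - 800 * u + 500 * u^2, tolerance = 1e-6)
  # doubling concentration doubles the baseline-subtracted height
  s1 <- generate_spectrum(list(Cd = 10), cfg, seed = 1L)
  s2 <- generate_spectrum(list(Cd = 20), cfg, seed = 1L)
  expect_equal(s2[i_cd] - s0[i_cd], 2 * (s1[i_cd] - s0[i_cd]), tolerance = 1e-9)
  # invariant to the other analytes at the Cd line
  s1b <- generate_spectrum(list(Cd = 10, Cu = 200, Pb = 100), cfg, seed = 1L)
  expect_equal(s1b[i_cd], s1[i_cd], tolerance = 1e-9)
  # strictly increasing in the analyte concentration
  heights <- vapply(c(0, 5, 10, 20, 50), function(cc)
    generate_spectrum(list(Cd = cc), cfg, seed = 1L)[i_cd], numeric(1))
  expect_true(all(diff(heights) > 0))
  expect_error(generate_spectrum(list(Cd = -1), cfg), ">= 0")
})

test_that("spectrum generation is seed-deterministic", {
  cfg <- small_config()
  a <- generate_spectrum(list(Cd = 10, Cu = 5, Pb = 2), cfg, seed = 99L)
  b <- generate_spectrum(list(Cd = 10, Cu = 5, Pb = 2), cfg, seed = 99L)
  expect_identical(a, b)
  c <- generate_spectrum(list(Cd = 10, Cu = 5, Pb = 2), cfg, seed = 100L)
  expect_false(identical(a, c))
})

test_that("saturating response bends the calibration curve", {
  cfg <- generator_config(scatter_sdlog = 0, scatter_offset_sd = 0,
                          noise_sd = 0, saturation = 50)
  wl <- as.numeric(cfg$axis)
  i_cd <- which.min(abs(wl - 228.80))
  s0 <- generate_spectrum(list(Cd = 0), cfg, seed = 1L)[i_cd]
  h <- vapply(c(25, 50, 100), function(cc)
    generate_spectrum(list(Cd = cc), cfg, seed = 1L)[i_cd] - s0, numeric(1))
  # c/(1 + c/K): doubling concentration less than doubles the height
  expect_lt(h[2], 2 * h[1])
  expect_lt(h[3], 2 * h[2])
  expect_true(all(diff(h) > 0))
})

test_that("generated dataset matches the emulated design", {
  d <- generate_dataset(generator_config(
    axis = spectral_axis(seq(210, 231, length.out = 16))))
  expect_identical(dim(d$intensities), c(192L, 16L))
  expect_identical(sort(unique(d$meta$brand)), 1:8)
  expect_identical(sort(unique(d$meta$group)), 1:8)
  expect_identical(sort(unique(d$meta$replicate)), 1:3)
  # concentrations follow the gradient plus a positive brand background
  for (el in c("Cd", "Cu", "Pb")) {
    lv <- build_gradient_plan(el)$levels
    bg <- d$meta[[el]] - lv[d$meta$group]
    expect_true(all(bg > 0))
    expect_true(all(bg < 30))  # small native content, mg/kg
    # background constant within brand
    expect_true(all(tapply(bg, d$meta$brand, function(v) diff(range(v))) < 1e-9))
  }
  d1 <- generate_dataset(generator_config(
    design = c(1, 1, 1), axis = spectral_axis(seq(210, 231, length.out = 16))))
  expect_identical(nrow(d1$intensities), 1L)
})

test_that("default full-size dataset is 192 x 1024", {
  d <- generate_dataset(generator_config())
  expect_identical(dim(d$intensities), c(192L, 1024L))
})

test_that("replicates are identical when all randomness is disabled", {
  cfg <- small_config(brand_effect_sd = 0, noise_sd = 0,
                      scatter_sdlog = 0, scatter_offset_sd = 0)
  d <- generate_dataset(cfg)
  within <- split(seq_len(nrow(d$intensities)),
                  interaction(d$meta$brand, d$meta$group))
  for (rows in within)
    expect_lt(max(abs(sweep(d$intensities[rows, ], 2,
                            d$intensities[rows[1], ]))), 1e-9)
})

test_that("Cd concentration and Cd-line height correlate strongly at default noise", {
  cors <- vapply(1:10, function(s) {
    d <- generate_dataset(generator_config(seed = s))
    wl <- as.numeric(d$axis)
    i <- which.min(abs(wl - 228.80))
    bg <- c(which.min(abs(wl - 228.3)), which.min(abs(wl - 229.3)))
    stats::cor(d$meta$Cd, d$intensities[, i] - rowMeans(d$intensities[, bg]))
  }, numeric(1))
  expect_gt(mean(cors), 0.95)
})

test_that("shot averaging drops the first position and averages the rest", {
  base <- seq(0, 1, length.out = 5)
  specs <- lapply(seq_len(21L), function(i) base + ceiling(i / 3))  # position i/3
  avg <- average_shots(specs, positions = 7L, accumulations = 3L)
  expect_equal(avg, base + mean(2:7), tolerance = 1e-12)  # mean of 18 kept
  same <- replicate(21L, base, simplify = FALSE)
  expect_equal(average_shots(same, 7L, 3L), base, tolerance = 1e-12)
  ab <- list(c(1, 1), c(5, 7))
  expect_equal(average_shots(ab, 2L, 1L), c(5, 7))
  expect_error(average_shots(specs[1:20], 7L, 3L), "expected 21")
})
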