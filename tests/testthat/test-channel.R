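test_that("interface coefficients follow the impedance-mismatch formulas", {
  r <- reflection_coefficient(400, 1.6e6)
  expect_equal(r, (1.6e6 - 400) / (1.6e6 + 400))
  expect_gt(r, 0.99)  # nearly total reflection at the air/wood interface
  expect_equal(reflection_coefficient(1234, 1234), 0)
  expect_equal(reflection_coefficient(1.6e6, 400), -r)

  expect_equal(transmission_coefficient(500, 500), 1)
  expect_equal(transmission_coefficient(400, 1.6e6),
               2 * 1.6e6 / (1.6e6 + 400))
  expect_error(reflection_coefficient(0, 100), "positive")
  expect_error(transmission_coefficient(100, -1), "positive")
})

test_that("t = 1 + r holds to machine precision for random impedances", {
  set.seed(11)
  z1 <- 10^runif(200, 1, 7)
  z2 <- 10^runif(200, 1, 7)
  expect_equal(transmission_coefficient(z1, z2),
               1 + reflection_coefficient(z1, z2), tolerance = 1e-14)
})

test_that("through-transmission gain responds to defects as expected", {
  sp <- reference_specimen()
  g_sound <- through_transmission_gain(sp, 0.03, 0.005)
  g_knot <- through_transmission_gain(sp, 0.018, 0.018)
  g_pit <- through_transmission_gain(sp, 0.042, 0.042)
  expect_gt(g_pit, g_sound)   # thinner board, less loss
  expect_lt(g_knot, g_sound)  # impedance mismatch + scatter
  expect_gt(g_knot, 0)
  expect_error(through_transmission_gain(sp, 0.1, 0.005), "off the board")
})

test_that("gain is monotone in impedance multiplier and thickness", {
  cfg <- channel_config()
  gains_k <- sapply(c(1.5, 2, 3, 5), function(mult) {
    sp <- specimen(0.03, 0.03, 0.01, defects = list(
      board_defect("knot", center = c(0.015, 0.015), radius = 0.005,
                   impedance_multiplier = mult, scatter_loss_db = 6)))
    through_transmission_gain(sp, 0.015, 0.015, cfg)
  })
  expect_true(all(diff(gains_k) < 0))

  gains_t <- sapply(c(0.9, 0.7, 0.5, 0.3), function(fr) {
    sp <- specimen(0.03, 0.03, 0.01, defects = list(
      board_defect("pit", center = c(0.015, 0.015), radius = 0.005,
                   thickness_fraction = fr)))
    through_transmission_gain(sp, 0.015, 0.015, cfg)
  })
  expect_true(all(diff(gains_t) > 0))
})

test_that("a transparent medium passes with unit gain", {
  med <- medium(impedance = 400, sound_speed = 1500, attenuation_coeff = 0)
  sp <- specimen(0.03, 0.03, 0.01, base_medium = med)
  air <- medium(impedance = 400, sound_speed = 343, attenuation_coeff = 0)
  cfg <- channel_config(air = air)
  expect_equal(through_transmission_gain(sp, 0.015, 0.015, cfg), 1)
})

test_that("transducer model rings at its centre frequency", {
  fs <- 1.5e6
  imp <- waveform(c(1, numeric(2999)), fs)
  td <- transducer(center_freq = 75e3, quality_factor = 10)
  out <- transducer_response(imp, td)$samples
  # dominant frequency of the ring-down
  spec <- Mod(stats::fft(out))[1:1500]
  fpk <- (which.max(spec) - 1) * fs / 3000
  expect_equal(fpk, 75e3, tolerance = 0.05)
  # decaying envelope
  env <- analytic_env <- abs(out)
  expect_lt(max(abs(out[2000:3000])), max(abs(out)) / 10)

  ring10 <- function(q) {
    o <- transducer_response(imp, transducer(75e3, q))$samples
    e <- envelope(waveform(o, fs))$samples
    max(which(e > 0.1 * max(e)))
  }
  expect_gt(ring10(20), ring10(5))

  zero <- transducer_response(waveform(numeric(100), fs), td)
  expect_equal(zero$samples, numeric(100))
  expect_error(transducer_response(waveform(1:10, 1e5), td), "fs")
})

test_that("receiver band-pass meets its centre/bandwidth design", {
  chain <- receiver_chain()
  m <- measure_bandwidth(chain, fs = 4.8e6)
  expect_equal(m$bandwidth_hz, 14e3, tolerance = 0.02)
  expect_equal(m$center_hz, 75e3, tolerance = 0.02)

  fs <- 4.8e6
  t <- (0:9999) / fs
  tone <- function(f) waveform(sin(2 * pi * f * t), fs)
  amp_out <- function(f, chain) {
    y <- receiver_filter(tone(f), chain)$samples
    max(abs(y[5000:10000]))  # past the transient
  }
  g2 <- receiver_chain(gain = 2)
  expect_equal(amp_out(75e3, g2), 2, tolerance = 0.02)
  # out-of-band tone strongly attenuated relative to the centre
  expect_lt(amp_out(200e3, chain), 0.2 * amp_out(75e3, chain))

  dc <- receiver_filter(waveform(rep(1, 5000), fs), chain)
  expect_lt(abs(mean(dc$samples[1000:5000])), 1e-3)
  expect_error(receiver_filter(waveform(1:10, 1e5), chain), "fs")
})

test_that("received-trace simulation is linear, seeded and reproducible", {
  spec <- fast_spec()
  board <- uniform_board()
  ex <- modulate_square_carrier(golay_pair(2)$a, spec)

  quiet <- channel_config(noise_sigma = 0)
  zero <- simulate_received(waveform(numeric(100), spec$fs), board,
                            0.015, 0.015, config = quiet)
  expect_equal(max(abs(zero$samples)), 0)

  r1 <- simulate_received(ex, board, 0.015, 0.015, config = quiet)
  ex2 <- waveform(2 * ex$samples, spec$fs,
                  samples_per_chip = ex$samples_per_chip)
  r2 <- simulate_received(ex2, board, 0.015, 0.015, config = quiet)
  expect_equal(r2$samples, 2 * r1$samples, tolerance = 1e-12)

  noisy <- channel_config(noise_sigma = 1e-5, rng_seed = 7L)
  n1 <- simulate_received(ex, board, 0.015, 0.015, config = noisy)
  n2 <- simulate_received(ex, board, 0.015, 0.015, config = noisy)
  expect_identical(n1$samples, n2$samples)  # bit-reproducible
  noisy$rng_seed <- 8L
  n3 <- simulate_received(ex, board, 0.015, 0.015, config = noisy)
  expect_false(identical(n1$samples, n3$samples))

  quiet2 <- channel_config(noise_sigma = 0, rng_seed = 99L)
  expect_identical(
    simulate_received(ex, board, 0.015, 0.015, config = quiet2)$samples,
    r1$samples)  # seed-independent without noise
})

test_that("simulation does not disturb the caller's RNG stream", {
  spec <- fast_spec()
  board <- uniform_board()
  ex <- modulate_square_carrier(golay_pair(1)$a, spec)
  noisy <- channel_config(noise_sigma = 1e-5, rng_seed = 3L)
  set.seed(123)
  draw1 <- runif(1)
  set.seed(123)
  invisible(simulate_received(ex, board, 0.015, 0.015, config = noisy))
  expect_identical(runif(1), draw1)
})

test_that("decoded peaks order pit > sound > knot through the channel", {
  sp <- reference_specimen()
  cfg <- fast_config()
  ex <- modulate_square_carrier(golay_pair(3)$a, cfg$modulation)
  cfg$noise_sigma <- calibrate_noise(ex, sp, 0.03, 0.005, cfg$tx, cfg$rx,
                                     cfg$chain, cfg$channel, snr_db = 20)
  pk <- function(x, y) ascan_point(sp, x, y, cfg, seed = 5L)$peak_value
  p_sound <- pk(0.03, 0.005)
  p_pit <- pk(0.042, 0.042)
  p_knot <- pk(0.018, 0.018)
  expect_gt(p_pit, p_sound)
  expect_gt(p_sound, p_knot)
})

test_that("rasterized defect mask converges to the analytic area", {
  sp <- reference_specimen()
  step <- 0.25e-3
  xs <- seq(0, sp$width, by = step)
  ys <- seq(0, sp$height, by = step)
  lab <- specimen_label_grid(sp, xs, ys)
  frac <- mean(lab != "sound")
  analytic <- (pi * 0.008^2 + pi * 0.006^2) / (0.06 * 0.06)
  expect_equal(frac, analytic, tolerance = 0.02)
  expect_equal(specimen_label(sp, 0.042, 0.042), "pit")
  expect_equal(specimen_label(sp, 0.018, 0.018), "knot")
  expect_equal(specimen_label(sp, 0.005, 0.055), "sound")
})

test_that("specimen definitions round-trip through JSON", {
  sp <- reference_specimen()
  path <- withr::local_tempfile(fileext = ".json")
  write_specimen(sp, path)
  back <- read_specimen(path)
  expect_equal(back$nominal_thickness, sp$nominal_thickness)
  expect_equal(length(back$defects), 2L)
  expect_equal(back$defects[[1]]$label, "knot")
  expect_equal(back$defects[[2]]$thickness_fraction, 0.6)
  expect_equal(through_transmission_gain(back, 0.042, 0.042),
               through_transmission_gain(sp, 0.042, 0.042))
  expect_error(specimen(0.03, 0.03, 0.01, defects = list(
    board_defect("knot", center = c(0.001, 0.001), radius = 0.005))),
    "outside")
})

test_that("ellipse and polygon defects resolve membership correctly", {
  sp <- specimen(0.04, 0.04, 0.01, defects = list(
    board_defect("pit", "ellipse", center = c(0.01, 0.01),
                 radii = c(0.006, 0.003), thickness_fraction = 0.5),
    board_defect("knot", "polygon",
                 vertices = cbind(c(0.025, 0.035, 0.030),
                                  c(0.025, 0.025, 0.035)))))
  expect_equal(specimen_label(sp, 0.01, 0.01), "pit")
  expect_equal(specimen_label(sp, 0.015, 0.01), "pit")   # inside rx
  expect_equal(specimen_label(sp, 0.01, 0.015), "sound") # outside ry
  expect_equal(specimen_label(sp, 0.030, 0.027), "knot")
  expect_equal(specimen_label(sp, 0.026, 0.034), "sound")
})

test_that("raster overrides replace parametric thickness and impedance", {
  thick <- matrix(0.01, 4, 4)
  thick[1, 1] <- 0.004  # top-left cell thinned
  sp <- specimen(0.04, 0.04, 0.01, thickness_grid = thick,
                 raster_cell = 0.01)
  g_thin <- through_transmission_gain(sp, 0.005, 0.005)
  g_full <- through_transmission_gain(sp, 0.035, 0.035)
  expect_gt(g_thin, g_full)

  imp <- matrix(1.6e6, 4, 4)
  imp[4, 4] <- 3.2e6
  sp2 <- specimen(0.04, 0.04, 0.01, impedance_grid = imp,
                  raster_cell = 0.01)
  expect_lt(through_transmission_gain(sp2, 0.035, 0.035),
            through_transmission_gain(sp2, 0.005, 0.005))

  expect_error(specimen(0.04, 0.04, 0.01, thickness_grid = thick),
               "raster_cell")

  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(thick, scan_plan(0, 0, 0.03, 0.03, 0.01), path,
                 units = "m")
  sp3 <- specimen_with_raster(specimen(0.04, 0.04, 0.01),
                              thickness_csv = path, cell = 0.01)
  expect_equal(golayscan:::point_properties(sp3, 0.005, 0.005)$thickness,
               0.004)
})

test_that("surface gain scales the through-transmission gain linearly", {
  sp <- reference_specimen()
  g1 <- through_transmission_gain(sp, 0.03, 0.005, channel_config())
  g2 <- through_transmission_gain(sp, 0.03, 0.005,
                                  channel_config(surface_gain = 1.3))
  expect_equal(g2, 1.3 * g1)
})
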