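test_that("scan grids use inclusive endpoints and row-major geometry", {
  plan <- scan_plan(0, 0, 0.05, 0.05, 0.001)
  g <- scan_grid(plan)
  expect_length(g$xs, 51L)  # 5 cm span at 1 mm: 51 points
  expect_length(g$ys, 51L)

  plan2 <- scan_plan(0.01, 0.02, 0.004, 0.006, 0.002)
  g2 <- scan_grid(plan2)
  expect_equal(g2$xs, c(0.010, 0.012, 0.014))
  expect_equal(g2$ys, c(0.020, 0.022, 0.024, 0.026))
  # point (i, j) sits at (x0 + (j-1) h, y0 + (i-1) h)
  expect_equal(g2$xs[2], plan2$x0 + 1 * plan2$interval)
  expect_equal(g2$ys[3], plan2$y0 + 2 * plan2$interval)
  expect_error(scan_plan(0, 0, 0.001, 0.05, 0.002), "interval")
})

test_that("threshold calibration reproduces the bench amplitude bands", {
  bench <- table_fixtures()[[1]]$points$peak_voltage
  thr <- calibrate_thresholds(bench)
  expect_equal(thr$knot_max, 0.4, tolerance = 0.02)
  expect_equal(thr$pit_min, 0.75, tolerance = 0.02)

  # degenerate spread falls back to +/- 20% of the mean
  flat <- calibrate_thresholds(rep(0.5, 5))
  expect_equal(flat$knot_max, 0.4)
  expect_equal(flat$pit_min, 0.6)

  # larger k widens the sound band monotonically
  ks <- c(0.5, 1, 2, 4)
  knot_bounds <- sapply(ks, function(k) calibrate_thresholds(bench, k)$knot_max)
  pit_bounds <- sapply(ks, function(k) calibrate_thresholds(bench, k)$pit_min)
  expect_true(all(diff(knot_bounds) < 0))
  expect_true(all(diff(pit_bounds) > 0))

  expect_error(calibrate_thresholds(c(0.6, 0.62)), "at least 3")
})

test_that("classification maps bench voltages to the recorded labels", {
  thr <- calibrate_thresholds(table_fixtures()[[1]]$points$peak_voltage)
  expect_equal(classify_point(0.651, thr), "sound")
  expect_equal(classify_point(0.282, thr), "knot")
  expect_equal(classify_point(0.857, thr), "pit")
  expect_equal(classify_point(c(0.64, 0.1, 0.9), thr),
               c("sound", "knot", "pit"))
  expect_error(classify_point(NA_real_, thr), "finite")
})

test_that("every point gets exactly one label", {
  thr <- calibrate_thresholds(table_fixtures()[[1]]$points$peak_voltage)
  set.seed(3)
  img <- structure(list(features = matrix(runif(100, 0, 1), 10, 10),
                        plan = NULL, method = "golay8", labels = NULL),
                   class = "cscan_image")
  img <- classify_image(img, thr)
  counts <- table(factor(img$labels, c("sound", "knot", "pit")))
  expect_equal(sum(counts), 100L)
  expect_true(all(img$labels %in% c("sound", "knot", "pit")))
})

test_that("coincidence and Dice behave at the extremes", {
  a <- matrix(c("knot", "sound", "pit", "sound"), 2, 2)
  r <- coincidence(a, a)
  expect_equal(r$coincidence, 1)
  expect_equal(unname(r$per_class), c(1, 1))
  expect_equal(r$dice, 1)

  b <- matrix(c("sound", "knot", "sound", "pit"), 2, 2)
  r0 <- coincidence(a, b)
  expect_equal(r0$coincidence, 0)
  expect_equal(r0$dice, 0)

  # Dice is symmetric; truth-normalized coincidence is not
  d1 <- matrix(c("knot", "knot", "sound", "sound"), 2, 2)
  d2 <- matrix(c("knot", "sound", "sound", "sound"), 2, 2)
  expect_equal(coincidence(d1, d2)$dice, coincidence(d2, d1)$dice)
  expect_equal(coincidence(d1, d2)$coincidence, 1)
  expect_equal(coincidence(d2, d1)$coincidence, 0.5)

  expect_error(coincidence(a, matrix("sound", 3, 3)), "dimensions")
})

test_that("rendering normalizes, upsamples and honours the colormap", {
  img <- structure(list(features = matrix(c(0.2, 0.4, 0.6, 0.8), 2, 2),
                        plan = NULL, method = "golay8", labels = NULL),
                   class = "cscan_image")
  r4 <- render_rgb(img, upsample = 4L)
  expect_equal(dim(r4), c(5L, 5L, 3L))
  r1 <- render_rgb(img, upsample = 1L)
  expect_equal(dim(r1), c(2L, 2L, 3L))
  expect_equal(r1[, , 1], (img$features - 0.2) / 0.6)

  flat <- img
  flat$features <- matrix(0.5, 2, 2)
  expect_equal(render_rgb(flat, 1L)[, , 2], matrix(0.5, 2, 2))

  # low peaks (knots) render darker than high peaks
  expect_lt(r1[1, 1, 1], r1[2, 2, 1])

  path <- withr::local_tempfile(fileext = ".png")
  render_rgb(img, 2L, file = path)
  expect_true(file.exists(path))
  expect_equal(dim(png::readPNG(path)), c(3L, 3L, 3L))
})

test_that("noiseless uniform-board scans are constant grids", {
  board <- uniform_board()
  plan <- scan_plan(0.005, 0.005, 0.02, 0.02, 0.005, serpentine = TRUE)
  cfg <- fast_config(plan = plan)
  img_s <- run_cscan(board, plan, cfg)
  expect_equal(dim(img_s$features), c(5L, 5L))
  expect_lt(diff(range(img_s$features)) / mean(img_s$features), 1e-9)

  plan_r <- scan_plan(0.005, 0.005, 0.02, 0.02, 0.005, serpentine = FALSE)
  img_r <- run_cscan(board, plan_r, cfg)
  expect_equal(img_r$features, img_s$features)
})

test_that("noisy scans are reproducible and traversal-independent", {
  board <- uniform_board()
  cfg <- fast_config(base_seed = 21L)
  cfg$noise_sigma <- 1e-5
  plan_s <- scan_plan(0.005, 0.005, 0.01, 0.01, 0.005, serpentine = TRUE)
  plan_r <- scan_plan(0.005, 0.005, 0.01, 0.01, 0.005, serpentine = FALSE)
  a <- run_cscan(board, plan_s, cfg)
  b <- run_cscan(board, plan_r, cfg)
  expect_identical(a$features, b$features)  # per-point seeding
  c2 <- run_cscan(board, plan_s, cfg)
  expect_identical(a$features, c2$features)
})

test_that("a small simulated C-scan recovers the defect map", {
  sp <- specimen(0.02, 0.02, 0.01, defects = list(
    board_defect("knot", center = c(0.005, 0.005), radius = 0.004),
    board_defect("pit", center = c(0.014, 0.014), radius = 0.003,
                 thickness_fraction = 0.6)))
  plan <- scan_plan(0, 0, 0.02, 0.02, 0.002)
  cfg <- fast_config(plan = plan, base_seed = 42L)
  ex <- modulate_square_carrier(golay_pair(3)$a, cfg$modulation)
  cfg$noise_sigma <- calibrate_noise(ex, sp, 0.01, 0.002, cfg$tx, cfg$rx,
                                     cfg$chain, cfg$channel, snr_db = 20)
  img <- run_cscan(sp, plan, cfg)
  grid <- scan_grid(plan)
  truth <- specimen_label_grid(sp, grid$xs, grid$ys)
  thr <- calibrate_thresholds(img$features[truth == "sound"])
  img <- classify_image(img, thr)
  rep <- coincidence(img$labels, truth)
  expect_gte(rep$coincidence, 0.9)
  expect_gte(rep$dice, 0.9)
})

test_that("feature grids round-trip through CSV", {
  plan <- scan_plan(0, 0, 0.004, 0.004, 0.002)
  m <- matrix(runif(9), 3, 3)
  path <- withr::local_tempfile(fileext = ".csv")
  write_grid_csv(m, plan, path)
  expect_equal(read_grid_csv(path), m, ignore_attr = TRUE)
  lab <- matrix(c("sound", "knot", "pit", "sound"), 2, 2)
  write_grid_csv(lab, plan, path, units = "label")
  expect_equal(read_grid_csv(path, character = TRUE), lab,
               ignore_attr = TRUE)
})
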