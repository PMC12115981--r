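#' Raster scan plan
#'
#' Rectangular scan with inclusive endpoints: a span of `width` at
#' `interval` yields `floor(width / interval) + 1` columns (a 5 cm span at
#' 1 mm gives 51 points). Grid point `(i, j)` (row-major, 1-based) sits at
#' `(x0 + (j-1) * interval, y0 + (i-1) * interval)`.
#'
#' @param x0,y0 Scan origin in meters.
#' @param width,height Scan spans in meters (each >= `interval`).
#' @param interval Scanning interval (grid pitch) in meters.
#' @param serpentine Traverse rows boustrophedon-style when `TRUE`.
#' @return Object of class `scan_plan`.
#' @export
scan_plan <- function(x0, y0, width, height, interval, serpentine = TRUE) {
  if (!is_number(interval) || interval <= 0) stopf("interval must be > 0")
  if (width < interval || height < interval) {
    stopf("width and height must be >= interval")
  }
  structure(list(x0 = x0, y0 = y0, width = width, height = height,
                 interval = interval, serpentine = isTRUE(serpentine)),
            class = "scan_plan")
}

#' Grid coordinates of a scan plan
#' @param plan A [scan_plan()].
#' @return List with `xs`, `ys` coordinate vectors (meters).
#' @export
scan_grid <- function(plan) {
  nx <- floor(plan$width / plan$interval + 1e-9) + 1
  ny <- floor(plan$height / plan$interval + 1e-9) + 1
  list(xs = plan$x0 + (seq_len(nx) - 1) * plan$interval,
       ys = plan$y0 + (seq_len(ny) - 1) * plan$interval)
}

## Excitations + matched filters for one excitation method. Each shot is a
## list(wave, ref); ref NULL means envelope read-out of the raw trace.
method_setup <- function(method, config) {
  spec <- config$modulation
  switch(method,
    golay8 = {
      pair <- golay_pair(config$order)
      list(shots = list(
             list(wave = modulate(pair$a, spec),
                  ref = matched_filter_reference(pair$a, spec)),
             list(wave = modulate(pair$b, spec),
                  ref = matched_filter_reference(pair$b, spec))),
           peak_mode = if (spec$carrier_freq > 0) "envelope" else "raw")
    },
    barker7 = {
      code <- barker7()
      list(shots = list(list(wave = modulate(code, spec),
                             ref = matched_filter_reference(code, spec))),
           peak_mode = "envelope")
    },
    burst8 = {
      # uncoded multi-pulse excitation: nothing to compress, the feature
      # is the received envelope peak (8 carrier cycles)
      list(shots = list(list(
             wave = modulate_square_carrier(
               1, modulation_spec(carrier_freq = spec$carrier_freq,
                                  cycles_per_chip = 8L, fs = spec$fs,
                                  amplitude = spec$amplitude)),
             ref = NULL)),
           peak_mode = "envelope")
    },
    cancelation = {
      cyc_spec <- modulation_spec(carrier_freq = spec$carrier_freq,
                                  cycles_per_chip = 1L, fs = spec$fs,
                                  amplitude = spec$amplitude)
      list(shots = list(list(
             wave = pulse_cancelation_excitation(8, cyc_spec),
             ref = NULL)),
           peak_mode = "envelope")
    },
    stopf("unknown excitation method '%s'", method)
  )
}

## Decoded peak feature at one board point for a prepared method setup.
point_feature <- function(sp, x, y, setup, config, seed) {
  shots <- setup$shots
  acc <- NULL
  for (k in seq_along(shots)) {
    cfg <- config$channel
    cfg$noise_sigma <- config$noise_sigma %||% cfg$noise_sigma
    cfg$rng_seed <- as.integer(seed + k - 1L)
    rxw <- simulate_received(shots[[k]]$wave, sp, x, y, config$tx,
                             config$rx, config$chain, cfg)
    dec <- if (is.null(shots[[k]]$ref)) rxw else correlate(rxw, shots[[k]]$ref)
    acc <- if (is.null(acc)) dec$samples else acc + dec$samples
    fs <- dec$fs; t0 <- dec$t0; spc <- dec$samples_per_chip
  }
  compression_result(waveform(acc, fs = fs, t0 = t0,
                              samples_per_chip = spc),
                     peak_mode = setup$peak_mode)
}

#' A-scan at one board point
#'
#' Simulates both Golay shots at `(x, y)` through the configured channel
#' and decodes them; the decoded peak voltage is the per-point imaging
#' feature.
#'
#' @param sp A [specimen()].
#' @param x,y Board coordinates in meters.
#' @param config An [inspection_config()].
#' @param seed Seed for the point's noise stream (default the config's
#'   base seed).
#' @return A [compression_result()].
#' @export
ascan_point <- function(sp, x, y, config = inspection_config(),
                        seed = config$base_seed) {
  setup <- method_setup("golay8", config)
  if (config$peak_mode != "auto") setup$peak_mode <- config$peak_mode
  point_feature(sp, x, y, setup, config, seed)
}

#' Run a C-scan over a virtual board
#'
#' Visits every grid point of the plan (serpentine order when requested),
#' simulates the configured excitation through the channel and records the
#' decoded peak voltage. Each point uses its own noise seed,
#' `base_seed + n_shots * (point index)`, so results are independent of
#' traversal order.
#'
#' @param sp A [specimen()].
#' @param plan A [scan_plan()] lying within the board.
#' @param config An [inspection_config()].
#' @param method One of `"golay8"`, `"barker7"`, `"burst8"`,
#'   `"cancelation"`.
#' @return Object of class `cscan_image`: `features` matrix (volts,
#'   rows = y, cols = x), the `plan`, grid coordinates, `method`, and
#'   `labels` (`NULL` until [classify_image()] is applied).
#' @export
run_cscan <- function(sp, plan, config = inspection_config(),
                      method = "golay8") {
  grid <- scan_grid(plan)
  check_on_board(sp, range(grid$xs), range(grid$ys))
  setup <- method_setup(method, config)
  if (config$peak_mode != "auto" && method == "golay8") {
    setup$peak_mode <- config$peak_mode
  }
  nx <- length(grid$xs)
  ny <- length(grid$ys)
  features <- matrix(NA_real_, ny, nx)
  n_shots <- length(setup$shots)
  rows <- seq_len(ny)
  for (i in rows) {
    cols <- if (plan$serpentine && i %% 2L == 0L) rev(seq_len(nx))
            else seq_len(nx)
    for (j in cols) {
      idx0 <- (i - 1L) * nx + (j - 1L)  # row-major, 0-based
      seed <- config$base_seed + n_shots * idx0
      res <- point_feature(sp, grid$xs[j], grid$ys[i], setup, config, seed)
      features[i, j] <- res$peak_value
    }
  }
  structure(list(features = features, plan = plan, xs = grid$xs,
                 ys = grid$ys, method = method, labels = NULL),
            class = "cscan_image")
}

#' @export
print.cscan_image <- function(x, ...) {
  cat(sprintf("<C-scan (%s): %d x %d points, peak range [%.4g, %.4g] V%s>\n",
              x$method, nrow(x$features), ncol(x$features),
              min(x$features), max(x$features),
              if (is.null(x$labels)) "" else ", classified"))
  invisible(x)
}

#' @export
plot.cscan_image <- function(x, ...) {
  graphics::image(x$xs * 100, x$ys * 100, t(x$features),
                  col = grDevices::gray.colors(256, 0, 1),
                  xlab = "x [cm]", ylab = "y [cm]", useRaster = TRUE, ...)
  invisible(x)
}

#' Calibrate knot/pit thresholds from sound-region peaks
#'
#' Places the amplitude bands from the mean and standard deviation of
#' decoded peak voltages sampled over healthy (sound) regions:
#' `knot_max = mean - k * scale_low * sd` and
#' `pit_min = mean + k * scale_high * sd`. The default scale factors put
#' the bands where a practitioner would draw them on bench data whose
#' sound-point spread is about 1% of the mean: the knot bound near 60% of
#' the sound level and the pit bound near 115%. With zero spread the bands
#' fall back to +/- 20% of the mean.
#'
#' @param sound_peaks At least 3 peak voltages from sound regions.
#' @param k Band-width multiplier (> 0); larger `k` widens the sound band.
#' @param scale_low,scale_high Asymmetric scale factors for the knot and
#'   pit bounds, in units of the sound-peak standard deviation.
#' @return Object of class `classifier_thresholds` with `knot_max` and
#'   `pit_min` (volts).
#' @export
calibrate_thresholds <- function(sound_peaks, k = 1, scale_low = 35,
                                 scale_high = 15) {
  if (length(sound_peaks) < 3L) {
    stopf("need at least 3 calibration values")
  }
  if (!is_number(k) || k <= 0) stopf("k must be positive")
  m <- mean(sound_peaks)
  s <- stats::sd(sound_peaks)
  if (s == 0) {
    knot_max <- 0.8 * m
    pit_min <- 1.2 * m
  } else {
    knot_max <- m - k * scale_low * s
    pit_min <- m + k * scale_high * s
  }
  if (!(knot_max < pit_min)) stopf("calibration produced knot_max >= pit_min")
  structure(list(knot_max = knot_max, pit_min = pit_min),
            class = "classifier_thresholds")
}

#' Classify a peak voltage
#'
#' Low peaks are knots (dense, mismatched, scattering), high peaks are pits
#' (thinner board, less loss), the band between is sound wood.
#'
#' @param peak Peak voltage(s), volts.
#' @param thr A [calibrate_thresholds()] result.
#' @return Character vector over `{"sound", "knot", "pit"}`.
#' @export
classify_point <- function(peak, thr) {
  stopifnot(inherits(thr, "classifier_thresholds"))
  if (!all(is.finite(peak))) stopf("peak values must be finite")
  ifelse(peak <= thr$knot_max, "knot",
         ifelse(peak >= thr$pit_min, "pit", "sound"))
}

#' Classify every point of a C-scan image
#'
#' @param image A [run_cscan()] result.
#' @param thr A [calibrate_thresholds()] result.
#' @return The image with its `labels` matrix filled in.
#' @export
classify_image <- function(image, thr) {
  stopifnot(inherits(image, "cscan_image"))
  lab <- classify_point(as.vector(image$features), thr)
  image$labels <- matrix(lab, nrow(image$features), ncol(image$features))
  image
}

#' Overlap between detected and true defect maps
#'
#' Truth-normalized coincidence `|detected & truth| / |truth|` (pooled over
#' both defect classes and per class) and the Dice coefficient
#' `2 |intersection| / (|detected| + |truth|)`.
#'
#' @param detected,truth Label matrices of equal dimension over
#'   `{"sound", "knot", "pit"}`.
#' @return Object of class `overlap_report`: `coincidence` (pooled),
#'   `per_class` (named vector for knot and pit), `dice`.
#' @export
coincidence <- function(detected, truth) {
  if (!all(dim(detected) == dim(truth))) {
    stopf("label grids must have equal dimensions")
  }
  frac <- function(det, tru) {
    if (sum(tru) == 0L) return(NA_real_)
    sum(det & tru) / sum(tru)
  }
  det_def <- detected != "sound"
  tru_def <- truth != "sound"
  dice <- if (sum(det_def) + sum(tru_def) == 0L) NA_real_ else {
    2 * sum(det_def & tru_def) / (sum(det_def) + sum(tru_def))
  }
  structure(list(
    coincidence = frac(det_def, tru_def),
    per_class = c(knot = frac(detected == "knot", truth == "knot"),
                  pit = frac(detected == "pit", truth == "pit")),
    dice = dice), class = "overlap_report")
}

#' @export
print.overlap_report <- function(x, ...) {
  cat(sprintf("<overlap: pooled %.1f%%, knot %.1f%%, pit %.1f%%, Dice %.3f>\n",
              100 * x$coincidence, 100 * x$per_class["knot"],
              100 * x$per_class["pit"], x$dice))
  invisible(x)
}

#' Render a C-scan as an interpolated raster image
#'
#' Min-max normalizes the feature grid (a constant grid renders mid-gray),
#' upsamples bilinearly and maps values to a colormap. Dark pixels are low
#' peaks (knot-like), light pixels high peaks (pit-like). Output dimensions
#' are `(grid - 1) * upsample + 1` per axis.
#'
#' @param image A [run_cscan()] result.
#' @param upsample Positive integer interpolation factor.
#' @param palette `"gray"` (default) or `"rgb"` (blue-green-red ramp).
#' @param file Optional PNG output path.
#' @return Numeric array `height x width x 3` in `[0, 1]`, invisibly when
#'   written to file.
#' @export
render_rgb <- function(image, upsample = 4L, palette = c("gray", "rgb"),
                       file = NULL) {
  stopifnot(inherits(image, "cscan_image"))
  palette <- match.arg(palette)
  if (!is_count(upsample) || upsample < 1) {
    stopf("upsample must be a positive integer")
  }
  f <- image$features
  rng <- range(f)
  norm <- if (rng[1] == rng[2]) {
    matrix(0.5, nrow(f), ncol(f))
  } else {
    (f - rng[1]) / (rng[2] - rng[1])
  }
  up <- bilinear_upsample(norm, as.integer(upsample))
  up <- pmin(pmax(up, 0), 1)
  if (palette == "gray") {
    arr <- array(rep(up, 3L), dim = c(dim(up), 3L))
  } else {
    ramp <- grDevices::colorRamp(c("navy", "green3", "red"))(as.vector(up))
    arr <- array(ramp / 255, dim = c(dim(up), 3L))
  }
  if (!is.null(file)) {
    png::writePNG(arr, file)
    return(invisible(arr))
  }
  arr
}

#' Compare excitation methods on the same board
#'
#' Runs the full simulate-decode-classify chain for each requested
#' excitation method with shared per-point seeds and a common absolute
#' noise level, calibrates thresholds on the true sound region of each
#' method's own feature map, and scores overlap against ground truth.
#'
#' @param sp A [specimen()].
#' @param plan A [scan_plan()].
#' @param methods Subset of `c("golay8", "barker7", "burst8",
#'   "cancelation")`.
#' @param config An [inspection_config()].
#' @param noise_sigma Absolute sensor-referred noise sigma in volts shared
#'   by all methods (instrument noise does not change with the code). If
#'   `NULL`, the config's channel noise sigma is used.
#' @return List with `truth` (label grid) and per-method entries, each
#'   holding `image` (classified), `thresholds` and `report` (an
#'   [coincidence()] overlap report).
#' @export
compare_excitations <- function(sp, plan,
                                methods = c("golay8", "barker7", "burst8",
                                            "cancelation"),
                                config = inspection_config(),
                                noise_sigma = NULL) {
  if (length(methods) == 0L) stopf("methods must be non-empty")
  methods <- match.arg(methods, c("golay8", "barker7", "burst8",
                                  "cancelation"), several.ok = TRUE)
  grid <- scan_grid(plan)
  truth <- specimen_label_grid(sp, grid$xs, grid$ys)
  if (!is.null(noise_sigma)) config$noise_sigma <- noise_sigma
  out <- list(truth = truth)
  for (m in methods) {
    img <- run_cscan(sp, plan, config, method = m)
    thr <- calibrate_thresholds(img$features[truth == "sound"],
                                k = config$classifier$k,
                                scale_low = config$classifier$scale_low,
                                scale_high = config$classifier$scale_high)
    img <- classify_image(img, thr)
    out[[m]] <- list(image = img, thresholds = thr,
                     report = coincidence(img$labels, truth))
  }
  out
}

#' Write and read feature or label grids as CSV
#'
#' Row-major CSV with a header comment line recording origin, interval and
#' units, matching the scan-grid geometry.
#'
#' @param m Matrix (features or labels).
#' @param plan The [scan_plan()] the grid was scanned on.
#' @param path Output path.
#' @param units Unit string recorded in the header.
#' @export
write_grid_csv <- function(m, plan, path, units = "V") {
  hdr <- sprintf("# x0=%g y0=%g interval=%g units=%s row-major origin=top-left",
                 plan$x0, plan$y0, plan$interval, units)
  con <- file(path, "w")
  on.exit(close(con))
  writeLines(hdr, con)
  utils::write.table(m, con, sep = ",", row.names = FALSE,
                     col.names = FALSE, quote = FALSE)
  invisible(path)
}

#' @rdname write_grid_csv
#' @param character Read the grid as character labels instead of numbers.
#' @export
read_grid_csv <- function(path, character = FALSE) {
  as.matrix(utils::read.table(path, sep = ",", comment.char = "#",
                              colClasses = if (character) "character"
                                           else "numeric"))
}
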