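#' Acoustic medium description
#'
#' Characteristic acoustic impedance, sound speed and a power-law
#' attenuation model `alpha(f) = attenuation_coeff * (f / ref_freq) ^
#' attenuation_exponent` in dB/m.
#'
#' @param impedance Characteristic impedance in Rayls (> 0).
#' @param sound_speed Longitudinal speed in m/s.
#' @param attenuation_coeff dB per meter at `ref_freq`.
#' @param attenuation_exponent Dimensionless frequency power.
#' @param ref_freq Reference frequency for the attenuation law, Hz.
#' @return Object of class `medium`.
#' @export
medium <- function(impedance, sound_speed, attenuation_coeff = 0,
                   attenuation_exponent = 1, ref_freq = 75e3) {
  if (!is_number(impedance) || impedance <= 0) {
    stopf("impedance must be positive")
  }
  if (!is_number(sound_speed) || sound_speed <= 0) {
    stopf("sound_speed must be positive")
  }
  if (!is_number(attenuation_coeff) || attenuation_coeff < 0) {
    stopf("attenuation_coeff must be >= 0")
  }
  structure(list(impedance = impedance, sound_speed = sound_speed,
                 attenuation_coeff = attenuation_coeff,
                 attenuation_exponent = attenuation_exponent,
                 ref_freq = ref_freq),
            class = "medium")
}

#' Default media for air-coupled wood inspection
#'
#' Air at 400 Rayls / 343 m/s with weak absorption; pine across the grain
#' at 1,600,000 Rayls. The wood attenuation default (600 dB/m at 75 kHz)
#' makes a 1 cm board cost about 6 dB, consistent with the amplitude
#' elevation observed over thinned (pit) regions on real pine.
#'
#' @rdname medium
#' @export
air_medium <- function() {
  medium(impedance = 400, sound_speed = 343, attenuation_coeff = 2.6,
         attenuation_exponent = 2)
}

#' @rdname medium
#' @export
wood_medium <- function() {
  medium(impedance = 1.6e6, sound_speed = 1500, attenuation_coeff = 600,
         attenuation_exponent = 1)
}

## Amplitude factor for propagation through `dist` meters of `med` at `freq`.
attenuation_factor <- function(med, dist, freq) {
  alpha <- med$attenuation_coeff *
    (freq / med$ref_freq) ^ med$attenuation_exponent
  10 ^ (-alpha * dist / 20)
}

#' Pressure reflection and transmission coefficients
#'
#' Normal-incidence plane-wave coefficients at a planar interface from a
#' medium of impedance `z1` into one of impedance `z2`:
#' \code{r = (z2 - z1) / (z2 + z1)} and \code{t = 2 z2 / (z2 + z1)}, with
#' the exact identity \code{t = 1 + r}. For the air/wood pair (400 vs
#' 1,600,000 Rayls) the reflection coefficient is about 0.9995 —
#' virtually all incident pressure is reflected,
#' which is why air-coupled inspection needs every dB the coding can buy.
#'
#' @param z1,z2 Impedances in Rayls (> 0).
#' @return Dimensionless coefficient.
#' @export
reflection_coefficient <- function(z1, z2) {
  if (any(z1 <= 0) || any(z2 <= 0)) stopf("impedances must be positive")
  (z2 - z1) / (z2 + z1)
}

#' @rdname reflection_coefficient
#' @export
transmission_coefficient <- function(z1, z2) {
  if (any(z1 <= 0) || any(z2 <= 0)) stopf("impedances must be positive")
  2 * z2 / (z2 + z1)
}

#' Parametric board defects
#'
#' A defect is a parametric region of the board: a `knot` raises the local
#' impedance (`impedance_multiplier` > 1) and adds a scattering loss in dB
#' (irregular dense knot wood distorts and scatters the beam); a `pit`
#' thins the board to `thickness_fraction` of nominal, so the ray crosses
#' less wood and arrives stronger.
#'
#' @param label `"knot"` or `"pit"`.
#' @param shape `"circle"`, `"ellipse"` or `"polygon"`.
#' @param center Defect centre `c(x, y)` in meters (circle/ellipse).
#' @param radius Circle radius in meters.
#' @param radii Ellipse semi-axes `c(rx, ry)` in meters.
#' @param vertices Two-column matrix of polygon vertices in meters.
#' @param impedance_multiplier Knot impedance factor (> 1).
#' @param scatter_loss_db Extra knot loss in dB (>= 0).
#' @param thickness_fraction Pit residual thickness fraction in (0, 1).
#' @return Object of class `board_defect`.
#' @export
board_defect <- function(label, shape = "circle", center = NULL,
                         radius = NULL, radii = NULL, vertices = NULL,
                         impedance_multiplier = 2, scatter_loss_db = 6,
                         thickness_fraction = 0.5) {
  label <- match.arg(label, c("knot", "pit"))
  shape <- match.arg(shape, c("circle", "ellipse", "polygon"))
  if (shape == "circle") {
    if (is.null(center) || is.null(radius) || radius <= 0) {
      stopf("circle defects need a center and a positive radius")
    }
  } else if (shape == "ellipse") {
    if (is.null(center) || is.null(radii) || any(radii <= 0)) {
      stopf("ellipse defects need a center and positive radii")
    }
  } else {
    if (is.null(vertices) || nrow(vertices) < 3L) {
      stopf("polygon defects need >= 3 vertices")
    }
  }
  if (label == "knot" && impedance_multiplier <= 1) {
    stopf("impedance_multiplier must be > 1 for knots")
  }
  if (label == "pit" &&
      (thickness_fraction <= 0 || thickness_fraction >= 1)) {
    stopf("thickness_fraction must be in (0, 1) for pits")
  }
  structure(list(label = label, shape = shape, center = center,
                 radius = radius, radii = radii, vertices = vertices,
                 impedance_multiplier = impedance_multiplier,
                 scatter_loss_db = scatter_loss_db,
                 thickness_fraction = thickness_fraction),
            class = "board_defect")
}

## Vectorized point-in-defect membership.
in_defect <- function(defect, x, y) {
  switch(defect$shape,
    circle = (x - defect$center[1])^2 + (y - defect$center[2])^2 <=
      defect$radius^2,
    ellipse = ((x - defect$center[1]) / defect$radii[1])^2 +
      ((y - defect$center[2]) / defect$radii[2])^2 <= 1,
    polygon = pracma::inpolygon(x, y, defect$vertices[, 1],
                                defect$vertices[, 2], boundary = TRUE)
  )
}

defect_bbox <- function(defect) {
  switch(defect$shape,
    circle = c(defect$center - defect$radius, defect$center + defect$radius),
    ellipse = c(defect$center - defect$radii, defect$center + defect$radii),
    polygon = c(apply(defect$vertices, 2, min), apply(defect$vertices, 2, max))
  )
}

#' Virtual wooden board
#'
#' A 2-D parametric board: uniform base medium and nominal thickness with a
#' list of parametric defect regions. Every scan point maps to a local
#' thickness, impedance multiplier, scatter loss and ground-truth label.
#'
#' A raster override (regular grids of local thickness in meters and local
#' impedance in Rayls, cell size `raster_cell` meters, row-major with the
#' origin at the top-left corner) replaces the parametric thickness and
#' impedance lookups wherever provided — useful for boards digitized from
#' measurements rather than described by shapes. Labels still come from the
#' parametric defect list.
#'
#' @param width,height Board size in meters.
#' @param nominal_thickness Board thickness in meters.
#' @param base_medium The wood [medium()].
#' @param defects List of [board_defect()] regions, fully inside the board.
#' @param thickness_grid,impedance_grid Optional raster override matrices.
#' @param raster_cell Raster cell size in meters (required with a grid).
#' @return Object of class `specimen`.
#' @export
specimen <- function(width, height, nominal_thickness,
                     base_medium = wood_medium(), defects = list(),
                     thickness_grid = NULL, impedance_grid = NULL,
                     raster_cell = NULL) {
  if (!is_number(width) || width <= 0 || !is_number(height) || height <= 0) {
    stopf("width and height must be positive")
  }
  if (!is_number(nominal_thickness) || nominal_thickness <= 0) {
    stopf("nominal_thickness must be positive")
  }
  for (d in defects) {
    stopifnot(inherits(d, "board_defect"))
    bb <- defect_bbox(d)
    if (bb[1] < 0 || bb[2] < 0 || bb[3] > width || bb[4] > height) {
      stopf("defect region extends outside the board")
    }
  }
  if (!is.null(thickness_grid) || !is.null(impedance_grid)) {
    if (is.null(raster_cell) || raster_cell <= 0) {
      stopf("raster overrides need a positive raster_cell size")
    }
  }
  structure(list(width = width, height = height,
                 nominal_thickness = nominal_thickness,
                 base_medium = base_medium, defects = defects,
                 thickness_grid = thickness_grid,
                 impedance_grid = impedance_grid,
                 raster_cell = raster_cell),
            class = "specimen")
}

## Nearest-cell raster lookup (row-major, origin top-left, 0-based cells).
raster_at <- function(grid, cell, x, y) {
  i <- pmin(pmax(floor(y / cell), 0), nrow(grid) - 1L) + 1L
  j <- pmin(pmax(floor(x / cell), 0), ncol(grid) - 1L) + 1L
  grid[cbind(i, j)]
}

#' @export
print.specimen <- function(x, ...) {
  cat(sprintf("<specimen %.3g x %.3g cm, %.3g mm thick, %d defect(s)>\n",
              100 * x$width, 100 * x$height, 1e3 * x$nominal_thickness,
              length(x$defects)))
  for (d in x$defects) {
    cat(sprintf("  %s (%s)\n", d$label, d$shape))
  }
  invisible(x)
}

check_on_board <- function(sp, x, y) {
  if (any(x < 0 | x > sp$width | y < 0 | y > sp$height)) {
    stopf("point (%.4g, %.4g) lies off the board", x[1], y[1])
  }
}

## Local board properties at one point. Raster overrides, when present,
## win over the parametric model for thickness and impedance.
point_properties <- function(sp, x, y) {
  check_on_board(sp, x, y)
  out <- list(label = "sound", thickness = sp$nominal_thickness,
              impedance_multiplier = 1, scatter_loss_db = 0)
  for (d in sp$defects) {
    if (in_defect(d, x, y)) {
      out$label <- d$label
      if (d$label == "knot") {
        out$impedance_multiplier <- d$impedance_multiplier
        out$scatter_loss_db <- d$scatter_loss_db
      } else {
        out$thickness <- sp$nominal_thickness * d$thickness_fraction
      }
      break
    }
  }
  if (!is.null(sp$thickness_grid)) {
    out$thickness <- raster_at(sp$thickness_grid, sp$raster_cell, x, y)
  }
  if (!is.null(sp$impedance_grid)) {
    out$impedance_multiplier <-
      raster_at(sp$impedance_grid, sp$raster_cell, x, y) /
      sp$base_medium$impedance
  }
  out
}

#' Read specimen raster overrides from CSV grids
#'
#' Reads local-thickness (meters) and/or local-impedance (Rayls) CSV grids
#' (row-major, origin top-left, `#`-prefixed header comments ignored) onto
#' an existing specimen.
#'
#' @param sp A [specimen()].
#' @param thickness_csv,impedance_csv CSV paths (either may be `NULL`).
#' @param cell Raster cell size in meters.
#' @return The specimen with overrides attached.
#' @export
specimen_with_raster <- function(sp, thickness_csv = NULL,
                                 impedance_csv = NULL, cell) {
  stopifnot(inherits(sp, "specimen"))
  if (!is.null(thickness_csv)) {
    sp$thickness_grid <- read_grid_csv(thickness_csv)
  }
  if (!is.null(impedance_csv)) {
    sp$impedance_grid <- read_grid_csv(impedance_csv)
  }
  sp$raster_cell <- cell
  sp
}

#' Ground-truth label at board coordinates
#'
#' @param sp A [specimen()].
#' @param x,y Coordinates in meters (scalars for `specimen_label`).
#' @return `"sound"`, `"knot"` or `"pit"`.
#' @export
specimen_label <- function(sp, x, y) point_properties(sp, x, y)$label

#' Ground-truth label grid
#'
#' Rasterizes defect membership at the point centres of a grid; as the grid
#' is refined, the labeled defect area fraction converges to the analytic
#' area of the parametric shapes.
#'
#' @param sp A [specimen()].
#' @param xs,ys Grid coordinate vectors in meters.
#' @return Character matrix of dimension `length(ys) x length(xs)`; row i
#'   corresponds to `ys` entry i, column j to `xs` entry j.
#' @export
specimen_label_grid <- function(sp, xs, ys) {
  check_on_board(sp, range(xs), range(ys))
  g <- expand.grid(x = xs, y = ys)
  lab <- rep("sound", nrow(g))
  for (d in sp$defects) {
    hit <- in_defect(d, g$x, g$y) & lab == "sound"
    lab[hit] <- d$label
  }
  matrix(lab, nrow = length(ys), ncol = length(xs), byrow = TRUE)
}

#' Transducer resonance model
#'
#' A piezoelectric air transducer behaves near its rated frequency like a
#' two-pole resonator: band-pass response centred at `center_freq` with
#' -3 dB bandwidth `center_freq / quality_factor` and an exponential
#' ring-down after excitation stops. The ring-down is what limits axial
#' resolution for uncoded bursts.
#'
#' @param center_freq Resonance frequency in Hz (rated 75 kHz here).
#' @param quality_factor Dimensionless Q (> 0); ring-down time scales with Q.
#' @param sensitivity Output scale (volts per unit input, arbitrary).
#' @return Object of class `transducer`.
#' @export
transducer <- function(center_freq = 75e3, quality_factor = 10,
                       sensitivity = 1) {
  if (!is_number(center_freq) || center_freq <= 0) {
    stopf("center_freq must be positive")
  }
  if (!is_number(quality_factor) || quality_factor <= 0) {
    stopf("quality_factor must be positive")
  }
  structure(list(center_freq = center_freq, quality_factor = quality_factor,
                 sensitivity = sensitivity),
            class = "transducer")
}

#' Receiver analog chain description
#'
#' DC blocking, gain, and a band-pass stage whose magnitude response peaks
#' at `bp_center` with -3 dB points separated by `bp_bandwidth_3db`
#' (defaults: 75 kHz centre, 14 kHz bandwidth).
#'
#' @param dc_block_cutoff High-pass cutoff of the DC block, Hz.
#' @param gain Linear voltage gain (> 0).
#' @param bp_center Band-pass centre frequency, Hz.
#' @param bp_bandwidth_3db -3 dB bandwidth, Hz.
#' @param filter_order Even order of the band-pass stage (2 = one biquad).
#' @return Object of class `receiver_chain`.
#' @export
receiver_chain <- function(dc_block_cutoff = 1e3, gain = 1,
                           bp_center = 75e3, bp_bandwidth_3db = 14e3,
                           filter_order = 2L) {
  if (!is_number(gain) || gain <= 0) stopf("gain must be positive")
  if (!is_number(bp_center) || !is_number(bp_bandwidth_3db) ||
      bp_bandwidth_3db <= 0 || bp_center <= bp_bandwidth_3db / 2) {
    stopf("need bp_center > bp_bandwidth_3db / 2 > 0")
  }
  if (!is_count(filter_order) || filter_order < 2 || filter_order %% 2 != 0) {
    stopf("filter_order must be a positive even integer")
  }
  structure(list(dc_block_cutoff = dc_block_cutoff, gain = gain,
                 bp_center = bp_center, bp_bandwidth_3db = bp_bandwidth_3db,
                 filter_order = as.integer(filter_order)),
            class = "receiver_chain")
}

## Butterworth band-pass whose -3 dB edges are placed symmetrically about
## `center` in the geometric-mean sense, so the response peaks at `center`
## and the edges are exactly `bw` apart.
bandpass_coefficients <- function(center, bw, fs, order = 2L) {
  lo <- (-bw + sqrt(bw^2 + 4 * center^2)) / 2
  hi <- lo + bw
  if (hi >= fs / 2) stopf("band edge %.4g Hz exceeds Nyquist", hi)
  signal::butter(order / 2L, c(lo, hi) / (fs / 2), type = "pass")
}

#' Apply the transducer resonance to a waveform
#'
#' Filters the input through the two-pole resonator of the transducer
#' model; an impulse in produces a decaying oscillation near the centre
#' frequency whose ring-down lengthens with Q.
#'
#' @param input A [waveform()] with `fs >= 10 * center_freq`.
#' @param model A [transducer()].
#' @return A [waveform()].
#' @export
transducer_response <- function(input, model) {
  stopifnot(inherits(input, "waveform"), inherits(model, "transducer"))
  if (input$fs < 10 * model$center_freq) {
    stopf("fs must be >= 10 x transducer center_freq")
  }
  bp <- bandpass_coefficients(model$center_freq,
                              model$center_freq / model$quality_factor,
                              input$fs)
  out <- model$sensitivity *
    as.numeric(signal::filter(bp, input$samples))
  waveform(out, fs = input$fs, t0 = input$t0,
           samples_per_chip = input$samples_per_chip)
}

#' Apply the receiver chain to a waveform
#'
#' DC block (first-order high-pass), gain, then the band-pass stage.
#'
#' @param input A [waveform()]; `fs` must exceed twice the top of the
#'   passband.
#' @param chain A [receiver_chain()].
#' @return A [waveform()].
#' @export
receiver_filter <- function(input, chain) {
  stopifnot(inherits(input, "waveform"), inherits(chain, "receiver_chain"))
  if (input$fs <= 2 * (chain$bp_center + chain$bp_bandwidth_3db)) {
    stopf("fs must exceed twice the passband top")
  }
  x <- input$samples
  if (chain$dc_block_cutoff > 0) {
    hp <- signal::butter(1, chain$dc_block_cutoff / (input$fs / 2),
                         type = "high")
    x <- as.numeric(signal::filter(hp, x))
  }
  x <- x * chain$gain
  bp <- bandpass_coefficients(chain$bp_center, chain$bp_bandwidth_3db,
                              input$fs, chain$filter_order)
  waveform(as.numeric(signal::filter(bp, x)), fs = input$fs, t0 = input$t0,
           samples_per_chip = input$samples_per_chip)
}

#' Measure the band-pass stage of a receiver chain
#'
#' Evaluates the designed band-pass magnitude response on a fine frequency
#' grid and reads off the peak frequency and the width between the two
#' -3 dB points (linear interpolation between grid points).
#'
#' @param chain A [receiver_chain()].
#' @param fs Sampling rate the filter is realized at, Hz.
#' @param n Number of grid points.
#' @return List with `center_hz`, `bandwidth_hz` and `peak_gain`.
#' @export
measure_bandwidth <- function(chain, fs = 4.8e6, n = 20001L) {
  bp <- bandpass_coefficients(chain$bp_center, chain$bp_bandwidth_3db,
                              fs, chain$filter_order)
  freq <- seq(chain$bp_center / 4, chain$bp_center * 2.5, length.out = n)
  mag <- abs(digital_response(bp$b, bp$a, freq, fs))
  ipk <- which.max(mag)
  half <- mag[ipk] / sqrt(2)
  cross <- function(idx) {
    # linear interpolation of the crossing between idx and idx+1
    f0 <- freq[idx]; f1 <- freq[idx + 1L]
    m0 <- mag[idx]; m1 <- mag[idx + 1L]
    f0 + (half - m0) * (f1 - f0) / (m1 - m0)
  }
  below_lo <- which(mag[seq_len(ipk - 1L)] < half)
  below_hi <- which(mag[(ipk + 1L):n] < half) + ipk
  if (length(below_lo) == 0L || length(below_hi) == 0L) {
    stopf("-3 dB points not bracketed by the frequency grid")
  }
  f_lo <- cross(max(below_lo))
  f_hi <- cross(min(below_hi) - 1L)
  list(center_hz = freq[ipk], bandwidth_hz = f_hi - f_lo,
       peak_gain = mag[ipk])
}

#' Channel-level configuration
#'
#' @param air Air [medium()].
#' @param air_path_length Transducer-to-board gap on each side, meters.
#' @param noise_sigma Additive sensor-referred Gaussian noise sigma, volts.
#' @param rng_seed Integer seed for the noise stream.
#' @param surface_gain Amplitude factor for the insonified face (> 0,
#'   default 1): a flatter face absorbs less, a rough one more; lets
#'   front/back scans of the same board differ by a fixed factor.
#' @return Object of class `channel_config`.
#' @export
channel_config <- function(air = air_medium(), air_path_length = 0.1,
                           noise_sigma = 0, rng_seed = 1L,
                           surface_gain = 1) {
  if (!is_number(air_path_length) || air_path_length < 0) {
    stopf("air_path_length must be >= 0")
  }
  if (!is_number(noise_sigma) || noise_sigma < 0) {
    stopf("noise_sigma must be >= 0")
  }
  if (!is_number(surface_gain) || surface_gain <= 0) {
    stopf("surface_gain must be positive")
  }
  structure(list(air = air, air_path_length = air_path_length,
                 noise_sigma = noise_sigma, rng_seed = as.integer(rng_seed),
                 surface_gain = surface_gain),
            class = "channel_config")
}

#' Through-transmission amplitude gain at a board point
#'
#' Composes, along the vertical ray at `(x, y)`: pressure transmission
#' air-to-wood at the entry face and wood-to-air at the exit face (using
#' the local impedance, raised inside knots), amplitude attenuation over
#' the local wood thickness (reduced inside pits, the removed wood being
#' crossed as air), attenuation over the fixed air paths, and any knot
#' scattering loss. Deterministic and strictly positive.
#'
#' @param sp A [specimen()].
#' @param x,y Board coordinates in meters.
#' @param config A [channel_config()].
#' @param freq Frequency at which to evaluate attenuation, Hz.
#' @return Dimensionless amplitude factor.
#' @export
through_transmission_gain <- function(sp, x, y, config = channel_config(),
                                      freq = 75e3) {
  props <- point_properties(sp, x, y)
  z_air <- config$air$impedance
  z_wood <- sp$base_medium$impedance * props$impedance_multiplier
  t_in <- transmission_coefficient(z_air, z_wood)
  t_out <- transmission_coefficient(z_wood, z_air)
  air_dist <- 2 * config$air_path_length +
    (sp$nominal_thickness - props$thickness)
  t_in * t_out * (config$surface_gain %||% 1) *
    attenuation_factor(sp$base_medium, props$thickness, freq) *
    attenuation_factor(config$air, air_dist, freq) *
    10 ^ (-props$scatter_loss_db / 20)
}

## Time of flight along the ray: both air gaps, the wood, and any air
## inside a pit.
flight_time <- function(sp, props, config) {
  air_dist <- 2 * config$air_path_length +
    (sp$nominal_thickness - props$thickness)
  air_dist / config$air$sound_speed +
    props$thickness / sp$base_medium$sound_speed
}

#' Simulate a received through-transmission trace
#'
#' Runs one shot through the synthetic channel at board point `(x, y)`:
#' transmit transducer resonance, propagation delay (air at the air-medium
#' speed, wood at the wood-medium speed), scaling by the local
#' through-transmission gain, receive transducer resonance, additive
#' sensor-referred Gaussian noise (seeded), then the receiver chain.
#' Bit-reproducible for a given seed; with `noise_sigma = 0` the output is
#' seed-independent.
#'
#' @param excitation Drive [waveform()].
#' @param sp A [specimen()].
#' @param x,y Board coordinates in meters.
#' @param tx,rx [transducer()] models.
#' @param chain A [receiver_chain()].
#' @param config A [channel_config()]; carries the noise sigma and seed.
#' @param stage `"output"` for the full chain, `"prefilter"` to stop where
#'   noise is injected (used for SNR calibration).
#' @return A [waveform()] starting at t = 0.
#' @export
simulate_received <- function(excitation, sp, x, y,
                              tx = transducer(), rx = transducer(),
                              chain = receiver_chain(),
                              config = channel_config(),
                              stage = c("output", "prefilter")) {
  stopifnot(inherits(excitation, "waveform"))
  stage <- match.arg(stage)
  fs <- excitation$fs
  props <- point_properties(sp, x, y)
  g <- through_transmission_gain(sp, x, y, config, freq = tx$center_freq)
  delay <- as.integer(round(flight_time(sp, props, config) * fs))
  ring_s <- 8 * (tx$quality_factor + rx$quality_factor) /
    (pi * min(tx$center_freq, rx$center_freq))
  tail <- as.integer(ceiling(ring_s * fs))
  x_pad <- c(excitation$samples, numeric(tail))
  tx_out <- transducer_response(waveform(x_pad, fs = fs), tx)$samples
  trace <- c(numeric(delay), g * tx_out)
  rx_out <- transducer_response(waveform(trace, fs = fs), rx)$samples
  if (config$noise_sigma > 0) {
    rx_out <- rx_out + with_seed(config$rng_seed,
      stats::rnorm(length(rx_out), 0, config$noise_sigma))
  }
  pre <- waveform(rx_out, fs = fs,
                  samples_per_chip = excitation$samples_per_chip)
  if (stage == "prefilter") return(pre)
  receiver_filter(pre, chain)
}

#' Noise sigma for a target sensor-referred SNR
#'
#' Runs a noiseless probe shot at a board point and returns the noise sigma
#' that puts the peak pre-filter signal amplitude `snr_db` above the noise
#' (amplitude SNR, 20 log10). Use a sound-region point to reference noise
#' to the healthy-board signal level.
#'
#' @inheritParams simulate_received
#' @param snr_db Target amplitude SNR in dB at the noise injection point.
#' @return Noise sigma in volts.
#' @export
calibrate_noise <- function(excitation, sp, x, y, tx = transducer(),
                            rx = transducer(), chain = receiver_chain(),
                            config = channel_config(), snr_db = 20) {
  cfg0 <- config
  cfg0$noise_sigma <- 0
  pre <- simulate_received(excitation, sp, x, y, tx, rx, chain, cfg0,
                           stage = "prefilter")
  max(abs(pre$samples)) / 10 ^ (snr_db / 20)
}

#' Read and write specimen definitions as JSON
#'
#' Board dimensions plus a `defects` array of parametric shapes; all
#' lengths in meters.
#'
#' @param sp A [specimen()].
#' @param path JSON file path.
#' @export
write_specimen <- function(sp, path) {
  stopifnot(inherits(sp, "specimen"))
  defects <- lapply(sp$defects, function(d) {
    out <- list(label = d$label, shape = d$shape)
    if (!is.null(d$center)) out$center <- d$center
    if (!is.null(d$radius)) out$radius <- d$radius
    if (!is.null(d$radii)) out$radii <- d$radii
    if (!is.null(d$vertices)) out$vertices <- d$vertices
    if (d$label == "knot") {
      out$impedance_multiplier <- d$impedance_multiplier
      out$scatter_loss_db <- d$scatter_loss_db
    } else {
      out$thickness_fraction <- d$thickness_fraction
    }
    out
  })
  obj <- list(width = sp$width, height = sp$height,
              nominal_thickness = sp$nominal_thickness,
              base_medium = unclass(sp$base_medium), defects = defects)
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' @rdname write_specimen
#' @export
read_specimen <- function(path) {
  obj <- jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  med <- do.call(medium, obj$base_medium)
  defects <- lapply(obj$defects, function(d) {
    board_defect(
      label = d$label, shape = d$shape,
      center = if (!is.null(d$center)) unlist(d$center),
      radius = d$radius,
      radii = if (!is.null(d$radii)) unlist(d$radii),
      vertices = if (!is.null(d$vertices))
        do.call(rbind, lapply(d$vertices, unlist)),
      impedance_multiplier = d$impedance_multiplier %||% 2,
      scatter_loss_db = d$scatter_loss_db %||% 6,
      thickness_fraction = d$thickness_fraction %||% 0.5)
  })
  specimen(obj$width, obj$height, obj$nominal_thickness, med, defects)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
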