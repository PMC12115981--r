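#' Sampled waveform container
#'
#' A uniformly sampled, real-valued signal with its sampling rate and start
#' time. Amplitudes are in volts on an arbitrary scale (the chain is linear
#' end to end).
#'
#' @param samples Finite numeric vector, length >= 1.
#' @param fs Sampling rate in Hz (> 0).
#' @param t0 Start time in seconds.
#' @param samples_per_chip Optional integer carried by modulated code
#'   waveforms; used to normalize correlation outputs to code units.
#' @return Object of class `waveform`.
#' @export
waveform <- function(samples, fs, t0 = 0, samples_per_chip = NULL) {
  if (!is_number(fs) || fs <= 0) stopf("fs must be a positive number")
  samples <- as.numeric(samples)
  if (length(samples) < 1L || !all(is.finite(samples))) {
    stopf("samples must be a non-empty finite numeric vector")
  }
  structure(list(samples = samples, fs = fs, t0 = as.numeric(t0),
                 samples_per_chip = samples_per_chip),
            class = "waveform")
}

#' @export
print.waveform <- function(x, ...) {
  cat(sprintf("<waveform: %d samples @ %g Hz, %.3g ms, peak %.4g>\n",
              length(x$samples), x$fs, 1e3 * length(x$samples) / x$fs,
              max(abs(x$samples))))
  invisible(x)
}

#' @export
plot.waveform <- function(x, ...) {
  t <- x$t0 + (seq_along(x$samples) - 1) / x$fs
  graphics::plot(t * 1e6, x$samples, type = "l", xlab = "time [us]",
                 ylab = "amplitude [V]", ...)
  invisible(x)
}

#' Time vector of a waveform
#' @param w A [waveform()].
#' @export
waveform_time <- function(w) w$t0 + (seq_along(w$samples) - 1) / w$fs

#' Modulation parameters for coded excitation
#'
#' Describes how +1/-1 chips are turned into a drive waveform. With
#' `carrier_freq = 0` the code is held as a piecewise-constant wide pulse
#' (baseband BPSK: +1 is 0 degrees, -1 is 180 degrees). With a positive
#' carrier each chip carries `cycles_per_chip` cycles of a 50%-duty square
#' wave, sign-flipped on -1 chips; this is the drive an air-coupled
#' transducer actually receives. Defaults are a 75 kHz carrier sampled at
#' 4.8 MHz (64 samples/cycle) with 8 carrier cycles per chip, so the chip
#' bandwidth (about 9 kHz) fits inside the receiver's 14 kHz passband:
#' chips shorter than the reciprocal system bandwidth cannot survive the
#' narrowband transducer/receiver chain, and the phase code would be
#' smeared away before decoding. Single-cycle chips remain available for
#' wideband chains.
#'
#' @param chip_period Chip duration T in seconds.
#' @param carrier_freq Square-carrier frequency in Hz; 0 for baseband.
#' @param cycles_per_chip Carrier cycles per chip (positive integer).
#' @param fs Sampling rate in Hz.
#' @param amplitude Drive amplitude in volts.
#' @return Object of class `modulation_spec`.
#' @export
modulation_spec <- function(carrier_freq = 75e3,
                            cycles_per_chip = 8L,
                            chip_period = if (carrier_freq > 0)
                              cycles_per_chip / carrier_freq else 1e-3,
                            fs = 4.8e6,
                            amplitude = 1) {
  if (!is_number(carrier_freq) || carrier_freq < 0) {
    stopf("carrier_freq must be >= 0")
  }
  if (!is_count(cycles_per_chip) || cycles_per_chip < 1) {
    stopf("cycles_per_chip must be a positive integer")
  }
  if (!is_number(chip_period) || chip_period <= 0) {
    stopf("chip_period must be positive")
  }
  if (!is_number(fs) || fs <= 0) stopf("fs must be positive")
  if (!is_number(amplitude)) stopf("amplitude must be a number")
  if (carrier_freq > 0) {
    if (fs < 20 * carrier_freq) stopf("fs must be >= 20 x carrier_freq")
    if (abs(chip_period * carrier_freq - cycles_per_chip) > 1e-9) {
      stopf("chip_period x carrier_freq must equal cycles_per_chip")
    }
  }
  spc <- chip_period * fs
  if (abs(spc - round(spc)) > 1e-6 || round(spc) < 1) {
    stopf("chip_period x fs must be a positive integer (samples per chip)")
  }
  structure(list(chip_period = chip_period, carrier_freq = carrier_freq,
                 cycles_per_chip = as.integer(cycles_per_chip), fs = fs,
                 amplitude = amplitude),
            class = "modulation_spec")
}

samples_per_chip <- function(spec) as.integer(round(spec$chip_period * spec$fs))

code_values <- function(code) {
  if (inherits(code, "acu_code")) code$values else check_pm1(code)
}

#' Wide-pulse (baseband BPSK) chip modulation
#'
#' Holds chip `i` of the code at `amplitude * code[i]` for one chip period:
#' a wide pulse of total duration `N * chip_period` whose sub-pulses are
#' phase-modulated 0/180 degrees by the code.
#'
#' @param code +1/-1 chip sequence or an `acu_code`.
#' @param spec A [modulation_spec()] with `carrier_freq = 0`.
#' @return A [waveform()] carrying `samples_per_chip`.
#' @export
modulate_wide_pulse <- function(code, spec) {
  stopifnot(inherits(spec, "modulation_spec"))
  if (spec$carrier_freq != 0) {
    stopf("modulate_wide_pulse requires carrier_freq = 0")
  }
  values <- code_values(code)
  spc <- samples_per_chip(spec)
  waveform(rep(values * spec$amplitude, each = spc), fs = spec$fs,
           samples_per_chip = spc)
}

#' Square-wave carrier chip modulation
#'
#' Multiplies the wide-pulse chip waveform by a unit square carrier
#' (50% duty, +1 first half-cycle) whose cycles align with chip boundaries:
#' a +1 chip is `cycles_per_chip` carrier cycles starting positive, a -1
#' chip is the same cycles inverted (180 degrees).
#'
#' @inheritParams modulate_wide_pulse
#' @param spec A [modulation_spec()] with `carrier_freq > 0`; `fs` must be
#'   an integer multiple of `2 * carrier_freq` so half-cycles sample exactly.
#' @return A [waveform()] carrying `samples_per_chip`.
#' @export
modulate_square_carrier <- function(code, spec) {
  stopifnot(inherits(spec, "modulation_spec"))
  if (spec$carrier_freq <= 0) {
    stopf("modulate_square_carrier requires carrier_freq > 0")
  }
  half <- spec$fs / (2 * spec$carrier_freq)
  if (abs(half - round(half)) > 1e-9) {
    stopf("fs must be an integer multiple of 2 x carrier_freq")
  }
  half <- as.integer(round(half))
  values <- code_values(code)
  cycle <- c(rep(1, half), rep(-1, half))
  chip <- rep(cycle, spec$cycles_per_chip)
  waveform(as.vector(outer(chip, values * spec$amplitude)), fs = spec$fs,
           samples_per_chip = length(chip))
}

modulate <- function(code, spec) {
  if (spec$carrier_freq > 0) modulate_square_carrier(code, spec)
  else modulate_wide_pulse(code, spec)
}

#' Anti-phase pulse-cancelation excitation
#'
#' A burst of `n_cycles` square-wave cycles followed, `cancel_delay_cycles`
#' cycle periods after the burst starts, by one sign-inverted cycle scaled
#' by `cancel_amplitude`. The trailing anti-phase cycle pumps energy out of
#' a ringing transducer, shortening its ring-down — the classic uncoded
#' alternative for recovering axial resolution.
#'
#' @param n_cycles Number of carrier cycles in the main burst.
#' @param spec A [modulation_spec()] with `carrier_freq > 0`.
#' @param cancel_delay_cycles Start of the canceling cycle, in cycle periods
#'   from burst start; must be >= `n_cycles` (no overlap).
#' @param cancel_amplitude Relative amplitude of the canceling cycle in
#'   `[0, 1]`; 0 gives the plain burst.
#' @return A [waveform()].
#' @export
pulse_cancelation_excitation <- function(n_cycles, spec,
                                         cancel_delay_cycles = n_cycles,
                                         cancel_amplitude = 1) {
  stopifnot(inherits(spec, "modulation_spec"))
  if (!is_count(n_cycles) || n_cycles < 1) {
    stopf("n_cycles must be a positive integer")
  }
  if (spec$carrier_freq <= 0) stopf("carrier_freq must be > 0")
  if (!is_number(cancel_amplitude) || cancel_amplitude < 0 ||
      cancel_amplitude > 1) {
    stopf("cancel_amplitude must be in [0, 1]")
  }
  if (!is_number(cancel_delay_cycles) || cancel_delay_cycles <= 0) {
    stopf("cancel_delay_cycles must be positive")
  }
  half <- spec$fs / (2 * spec$carrier_freq)
  if (abs(half - round(half)) > 1e-9) {
    stopf("fs must be an integer multiple of 2 x carrier_freq")
  }
  half <- as.integer(round(half))
  cycle <- c(rep(1, half), rep(-1, half)) * spec$amplitude
  main <- rep(cycle, n_cycles)
  if (cancel_amplitude == 0) {
    return(waveform(main, fs = spec$fs))
  }
  start <- cancel_delay_cycles * 2 * half
  if (abs(start - round(start)) > 1e-6) {
    stopf("cancel_delay_cycles must land on a sample boundary")
  }
  start <- as.integer(round(start))
  if (start < length(main)) {
    stopf("canceling cycle overlaps the main burst")
  }
  out <- numeric(start + 2L * half)
  out[seq_along(main)] <- main
  idx <- start + seq_len(2L * half)
  out[idx] <- out[idx] - cancel_amplitude * cycle
  waveform(out, fs = spec$fs)
}

#' Matched-filter reference waveform
#'
#' The time-reversed modulated waveform of a code, so that convolving a
#' received trace with it realizes correlation against the transmitted
#' code waveform (the matched filter). For the eight-bit pair at one sample
#' per chip this reproduces the classic "flip the sequence upside down"
#' construction: sequence A (1, 1, 1, -1, 1, 1, -1, 1) becomes filter A
#' (1, -1, 1, 1, -1, 1, 1, 1).
#'
#' @inheritParams modulate_wide_pulse
#' @param spec A [modulation_spec()]; baseband or square-carrier chosen by
#'   `carrier_freq` as in the modulators.
#' @return A [waveform()] carrying `samples_per_chip`.
#' @export
matched_filter_reference <- function(code, spec) {
  w <- modulate(code, spec)
  waveform(rev(w$samples), fs = w$fs, samples_per_chip = w$samples_per_chip)
}

#' Read and write waveforms as delimited text
#'
#' Two-column delimited text (`time_s`, `value`) with a JSON metadata
#' sidecar (`<path>.json`) holding the sampling rate and any
#' samples-per-chip annotation.
#'
#' @param w A [waveform()].
#' @param path Output file; the sidecar is written to `paste0(path, ".json")`.
#' @export
write_waveform <- function(w, path) {
  stopifnot(inherits(w, "waveform"))
  utils::write.table(
    data.frame(time_s = waveform_time(w), value = w$samples),
    path, sep = "\t", row.names = FALSE, quote = FALSE)
  meta <- list(fs = w$fs, t0 = w$t0)
  if (!is.null(w$samples_per_chip)) meta$samples_per_chip <- w$samples_per_chip
  jsonlite::write_json(meta, paste0(path, ".json"), auto_unbox = TRUE,
                       digits = NA)
  invisible(path)
}

#' @param fs Sampling rate override; if `NULL`, taken from the sidecar or
#'   inferred from the time column spacing.
#' @rdname write_waveform
#' @export
read_waveform <- function(path, fs = NULL) {
  d <- utils::read.table(path, header = TRUE, sep = "\t")
  meta_path <- paste0(path, ".json")
  spc <- NULL
  t0 <- d[[1]][1]
  if (is.null(fs)) {
    if (file.exists(meta_path)) {
      meta <- jsonlite::fromJSON(meta_path)
      fs <- meta$fs
      spc <- meta$samples_per_chip
      if (!is.null(meta$t0)) t0 <- meta$t0
    } else {
      fs <- 1 / stats::median(diff(d[[1]]))
    }
  }
  waveform(d[[2]], fs = fs, t0 = t0, samples_per_chip = spc)
}
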