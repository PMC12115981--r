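#' Full inspection configuration
#'
#' Bundles every tunable of the pipeline in one validated object: code
#' order, modulation, transducer models, receiver chain, channel, scan
#' plan, classifier parameters and the base noise seed. Defaults are the
#' bench conditions of the reference setup: eight-bit Golay pair, 75 kHz
#' square carrier with bandwidth-matched eight-cycle chips sampled at
#' 4.8 MHz, Q = 10 transducers, 75 kHz / 14 kHz receiver band-pass, 10 cm
#' air gaps, 1 mm scan interval.
#'
#' @param order Golay pair order (pair length `2^order`).
#' @param modulation A [modulation_spec()].
#' @param tx,rx [transducer()] models.
#' @param chain A [receiver_chain()].
#' @param channel A [channel_config()].
#' @param plan A [scan_plan()].
#' @param classifier List with `k`, `scale_low`, `scale_high` for
#'   [calibrate_thresholds()].
#' @param peak_mode `"auto"`, `"raw"` or `"envelope"` decoded-peak
#'   read-out.
#' @param noise_sigma Optional absolute noise sigma override (volts);
#'   `NULL` defers to the channel config.
#' @param base_seed Base integer seed for per-point noise streams.
#' @return Object of class `inspection_config`.
#' @export
inspection_config <- function(order = 3L,
                              modulation = modulation_spec(),
                              tx = transducer(),
                              rx = transducer(),
                              chain = receiver_chain(),
                              channel = channel_config(),
                              plan = scan_plan(0, 0, 0.05, 0.05, 0.001),
                              classifier = list(k = 1, scale_low = 35,
                                                scale_high = 15),
                              peak_mode = c("auto", "raw", "envelope"),
                              noise_sigma = NULL,
                              base_seed = 1L) {
  peak_mode <- match.arg(peak_mode)
  if (!is_count(order) || order < 0 || order > 16) {
    stopf("order must be an integer in [0, 16]")
  }
  stopifnot(inherits(modulation, "modulation_spec"),
            inherits(tx, "transducer"), inherits(rx, "transducer"),
            inherits(chain, "receiver_chain"),
            inherits(channel, "channel_config"),
            inherits(plan, "scan_plan"))
  for (f in c("k", "scale_low", "scale_high")) {
    if (!is_number(classifier[[f]]) || classifier[[f]] <= 0) {
      stopf("classifier$%s must be a positive number", f)
    }
  }
  structure(list(order = as.integer(order), modulation = modulation,
                 tx = tx, rx = rx, chain = chain, channel = channel,
                 plan = plan, classifier = classifier,
                 peak_mode = peak_mode, noise_sigma = noise_sigma,
                 base_seed = as.integer(base_seed)),
            class = "inspection_config")
}

#' Parse a unit-suffixed quantity
#'
#' Converts strings like `"75 kHz"`, `"1 mm"` or `"10 cm"` to SI numbers
#' (Hz, meters, seconds, volts); bare numerics pass through. Used by the
#' configuration loader, exported for convenience.
#'
#' @param x A number or a single unit-suffixed string.
#' @return A numeric scalar in SI units.
#' @export
parse_quantity <- function(x) {
  if (is.numeric(x)) return(x)
  if (!is.character(x) || length(x) != 1L) {
    stopf("quantity must be a number or a unit-suffixed string")
  }
  m <- regmatches(x, regexec(
    "^\\s*([-+0-9.eE]+)\\s*([A-Za-z]*)\\s*$", x))[[1]]
  if (length(m) != 3L || m[2] == "") stopf("cannot parse quantity '%s'", x)
  val <- as.numeric(m[2])
  if (is.na(val)) stopf("cannot parse quantity '%s'", x)
  unit <- m[3]
  if (unit == "") return(val)
  scale <- switch(unit,
    "m" = 1, "cm" = 1e-2, "mm" = 1e-3, "um" = 1e-6,
    "s" = 1, "ms" = 1e-3, "us" = 1e-6,
    "Hz" = 1, "kHz" = 1e3, "MHz" = 1e6,
    "V" = 1, "mV" = 1e-3, "Rayls" = 1,
    stopf("unknown unit '%s' in '%s'", unit, x))
  val * scale
}

## Apply parse_quantity to every leaf of a nested list.
parse_quantities <- function(x) {
  if (is.list(x)) return(lapply(x, parse_quantities))
  if (is.character(x) && length(x) == 1L &&
      grepl("^\\s*[-+0-9.eE]+\\s*[A-Za-z]+\\s*$", x) &&
      !grepl("^[eE]", trimws(x))) {
    return(parse_quantity(x))
  }
  x
}

check_known_keys <- function(x, allowed, where) {
  extra <- setdiff(names(x), allowed)
  if (length(extra) > 0L) {
    stopf("unknown configuration key(s) in %s: %s", where,
          paste(extra, collapse = ", "))
  }
}

#' Load and save inspection configurations
#'
#' JSON is the canonical format; YAML is accepted on load (by file
#' extension). Validation is strict: unknown keys are errors, and numeric
#' fields accept unit-suffixed strings (`"75 kHz"`, `"1 mm"`, `"10 cm"`).
#' Omitted sections take the package defaults.
#'
#' @param path Configuration file (`.json`, `.yaml` or `.yml`).
#' @return An [inspection_config()].
#' @export
load_config <- function(path) {
  if (!file.exists(path)) stopf("config file '%s' does not exist", path)
  raw <- if (grepl("\\.(yaml|yml)$", path, ignore.case = TRUE)) {
    yaml::read_yaml(path)
  } else {
    jsonlite::fromJSON(path, simplifyDataFrame = FALSE)
  }
  raw <- parse_quantities(raw)
  check_known_keys(raw, c("order", "modulation", "transducer", "tx", "rx",
                          "receiver", "channel", "plan", "classifier",
                          "peak_mode", "noise_sigma", "base_seed"),
                   "top level")
  build <- function(section, ctor, allowed) {
    if (is.null(raw[[section]])) return(NULL)
    check_known_keys(raw[[section]], allowed, section)
    do.call(ctor, raw[[section]])
  }
  args <- list()
  if (!is.null(raw$order)) args$order <- raw$order
  mod <- build("modulation", modulation_spec,
               c("carrier_freq", "cycles_per_chip", "chip_period", "fs",
                 "amplitude"))
  if (!is.null(mod)) args$modulation <- mod
  td <- build("transducer", transducer,
              c("center_freq", "quality_factor", "sensitivity"))
  if (!is.null(td)) { args$tx <- td; args$rx <- td }
  txo <- build("tx", transducer,
               c("center_freq", "quality_factor", "sensitivity"))
  if (!is.null(txo)) args$tx <- txo
  rxo <- build("rx", transducer,
               c("center_freq", "quality_factor", "sensitivity"))
  if (!is.null(rxo)) args$rx <- rxo
  ch <- build("receiver", receiver_chain,
              c("dc_block_cutoff", "gain", "bp_center", "bp_bandwidth_3db",
                "filter_order"))
  if (!is.null(ch)) args$chain <- ch
  if (!is.null(raw$channel)) {
    check_known_keys(raw$channel, c("air", "air_path_length", "noise_sigma",
                                    "rng_seed", "surface_gain"), "channel")
    ca <- raw$channel
    if (!is.null(ca$air)) ca$air <- do.call(medium, ca$air)
    args$channel <- do.call(channel_config, ca)
  }
  pl <- build("plan", scan_plan,
              c("x0", "y0", "width", "height", "interval", "serpentine"))
  if (!is.null(pl)) args$plan <- pl
  if (!is.null(raw$classifier)) {
    check_known_keys(raw$classifier, c("k", "scale_low", "scale_high"),
                     "classifier")
    args$classifier <- utils::modifyList(
      list(k = 1, scale_low = 35, scale_high = 15), raw$classifier)
  }
  if (!is.null(raw$peak_mode)) args$peak_mode <- raw$peak_mode
  if (!is.null(raw$noise_sigma)) args$noise_sigma <- raw$noise_sigma
  if (!is.null(raw$base_seed)) args$base_seed <- raw$base_seed
  do.call(inspection_config, args)
}

#' @param config An [inspection_config()].
#' @rdname load_config
#' @export
save_config <- function(config, path) {
  stopifnot(inherits(config, "inspection_config"))
  obj <- list(
    order = config$order,
    modulation = unclass(config$modulation),
    tx = unclass(config$tx), rx = unclass(config$rx),
    receiver = unclass(config$chain),
    channel = {
      ch <- unclass(config$channel)
      ch$air <- unclass(config$channel$air)
      ch
    },
    plan = unclass(config$plan),
    classifier = config$classifier,
    peak_mode = config$peak_mode,
    base_seed = config$base_seed)
  if (!is.null(config$noise_sigma)) obj$noise_sigma <- config$noise_sigma
  jsonlite::write_json(obj, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}

#' Bench peak-voltage fixtures
#'
#' The peak decoded voltages measured on real pine boards with the
#' eight-bit Golay chain: a front-face set of 8 sound points, and a
#' back-face set of 8 sound points plus one knot (0.282 V) and two pits
#' (0.845 V, 0.857 V). Useful for calibrating and exercising the
#' classifier without hardware.
#'
#' @return List of two fixtures, each a list with `name` and a
#'   data.frame `points` (`label`, `peak_voltage`).
#' @export
table_fixtures <- function() {
  front <- data.frame(
    label = rep("sound", 8),
    peak_voltage = c(0.651, 0.636, 0.641, 0.637, 0.654, 0.639, 0.651,
                     0.648))
  back <- data.frame(
    label = c(rep("sound", 8), "knot", "pit", "pit"),
    peak_voltage = c(0.648, 0.651, 0.647, 0.646, 0.643, 0.641, 0.648,
                     0.656, 0.282, 0.845, 0.857))
  list(list(name = "front_sound_points", points = front),
       list(name = "back_points_with_defects", points = back))
}

#' Reference two-defect virtual board
#'
#' The deterministic 6 cm x 6 cm pine board used throughout the package's
#' examples and validation runs: 1 cm thick with one circular knot
#' (radius 8 mm, impedance x2, 6 dB scatter loss) centred at (1.8, 1.8) cm
#' and one circular pit (radius 6 mm, residual thickness fraction 0.6)
#' centred at (4.2, 4.2) cm. `thick = TRUE` gives the harder penetration
#' case: the same defect layout on a 1.5 cm board of denser, lossier pine
#' (1000 dB/m at 75 kHz).
#'
#' @param thick Use the 1.5 cm high-attenuation variant.
#' @return A [specimen()].
#' @export
reference_specimen <- function(thick = FALSE) {
  med <- wood_medium()
  thickness <- 0.01
  if (thick) {
    med$attenuation_coeff <- 1000
    thickness <- 0.015
  }
  specimen(
    width = 0.06, height = 0.06, nominal_thickness = thickness,
    base_medium = med,
    defects = list(
      board_defect("knot", "circle", center = c(0.018, 0.018),
                   radius = 0.008, impedance_multiplier = 2,
                   scatter_loss_db = 6),
      board_defect("pit", "circle", center = c(0.042, 0.042),
                   radius = 0.006, thickness_fraction = 0.6)))
}

#' Write a JSON run manifest
#'
#' Records the configuration (with an MD5 hash), seed, package version and
#' timestamp next to a run's outputs so any figure or grid can be
#' reproduced bit-for-bit.
#'
#' @param config An [inspection_config()].
#' @param seed The seed the run used.
#' @param path Output JSON path.
#' @param extra Optional named list folded into the manifest.
#' @export
write_run_manifest <- function(config, seed, path, extra = list()) {
  tmp <- tempfile(fileext = ".json")
  on.exit(unlink(tmp))
  save_config(config, tmp)
  manifest <- c(list(
    package = "golayscan",
    version = as.character(utils::packageVersion("golayscan")),
    timestamp = format(Sys.time(), "%Y-%m-%dT%H:%M:%S%z"),
    seed = seed,
    config_md5 = unname(tools::md5sum(tmp)),
    config = jsonlite::fromJSON(tmp, simplifyDataFrame = FALSE)),
    extra)
  jsonlite::write_json(manifest, path, auto_unbox = TRUE, digits = NA)
  invisible(path)
}
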