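## Shared fixtures, all generated in code.

# Brute-force aperiodic autocorrelation: independent O(N^2)
# shift-multiply-sum oracle used to validate the library's correlation
# arithmetic.
acorr_oracle <- function(x) {
  n <- length(x)
  vapply(-(n - 1L):(n - 1L), function(lag) {
    s <- 0
    for (i in seq_len(n)) {
      j <- i + lag
      if (j >= 1L && j <= n) s <- s + x[i] * x[j]
    }
    s
  }, numeric(1))
}

# One-sample-per-chip baseband spec: decoded traces directly in code units.
unit_spec <- function() modulation_spec(carrier_freq = 0, chip_period = 1,
                                        fs = 1)

# Reduced-rate carrier spec for channel tests that need the full pipeline
# but not the default 4.8 MHz sampling (20 samples per 75 kHz cycle).
fast_spec <- function() modulation_spec(fs = 1.5e6)

fast_config <- function(...) {
  inspection_config(modulation = fast_spec(), ...)
}

# Small uniform board for channel tests.
uniform_board <- function(thickness = 0.01) {
  specimen(0.03, 0.03, thickness)
}
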