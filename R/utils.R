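#' golayscan: coded-excitation air-coupled ultrasonic inspection of wood
#'
#' Golay complementary-pair coded excitation, a synthetic air-coupled
#' through-transmission channel for virtual wooden boards, matched-filter
#' pulse compression, and A-/C-scan defect imaging with knot/pit
#' classification and overlap scoring.
#'
#' @keywords internal
"_PACKAGE"

## Internal helpers shared across modules.

stopf <- function(fmt, ...) stop(sprintf(fmt, ...), call. = FALSE)

is_count <- function(x) {
  is.numeric(x) && length(x) == 1L && is.finite(x) && x == round(x)
}

is_number <- function(x) is.numeric(x) && length(x) == 1L && is.finite(x)

check_pm1 <- function(values, what = "code") {
  if (length(values) == 0L) stopf("%s must be non-empty", what)
  if (!all(values %in% c(-1, 1))) {
    stopf("%s elements must be exactly +1 or -1", what)
  }
  as.integer(values)
}

## Run `expr` under a fixed RNG seed without disturbing the caller's RNG
## stream. Mersenne-Twister keeps results reproducible across R sessions.
with_seed <- function(seed, expr) {
  has_seed <- exists(".Random.seed", envir = globalenv(), inherits = FALSE)
  if (has_seed) old <- get(".Random.seed", envir = globalenv())
  on.exit({
    if (has_seed) {
      assign(".Random.seed", old, envir = globalenv())
    } else if (exists(".Random.seed", envir = globalenv(), inherits = FALSE)) {
      rm(".Random.seed", envir = globalenv())
    }
  })
  set.seed(as.integer(seed), kind = "Mersenne-Twister", normal.kind = "Inversion")
  expr
}

## Full linear convolution, length n + m - 1. Direct O(n m) for small
## problems (exact on integer-valued inputs), FFT with composite padding
## otherwise.
conv_full <- function(x, y) {
  n <- length(x)
  m <- length(y)
  if (n == 0L || m == 0L) stopf("conv_full: empty input")
  nout <- n + m - 1L
  if (as.double(n) * m <= 2^18) {
    out <- numeric(nout)
    for (j in seq_len(m)) {
      idx <- j:(j + n - 1L)
      out[idx] <- out[idx] + x * y[j]
    }
    return(out)
  }
  nfft <- stats::nextn(nout, c(2, 3, 5))
  X <- stats::fft(c(x, numeric(nfft - n)))
  Y <- stats::fft(c(y, numeric(nfft - m)))
  Re(stats::fft(X * Y, inverse = TRUE))[seq_len(nout)] / nfft
}

## Magnitude of the analytic signal (FFT Hilbert construction). The input
## is zero-padded to a fast composite FFT length with a real margin — the
## circular Hilbert kernel decays like 1/t, so without padding a transient
## near one end wraps onto the other; the pad is discarded.
analytic_envelope <- function(x) {
  n0 <- length(x)
  if (n0 == 1L) return(abs(x))
  n <- stats::nextn(n0 + max(256L, n0 %/% 4L), c(2, 3, 5))
  x <- c(x, numeric(n - n0))
  X <- stats::fft(x)
  h <- numeric(n)
  if (n %% 2L == 0L) {
    h[c(1L, n / 2L + 1L)] <- 1
    h[2:(n / 2L)] <- 2
  } else {
    h[1L] <- 1
    h[2:((n + 1L) / 2L)] <- 2
  }
  Mod(stats::fft(X * h, inverse = TRUE) / n)[seq_len(n0)]
}

## Bilinear upsampling of a matrix: output dims (nrow-1)*factor + 1 etc.,
## original samples preserved at the coarse grid nodes.
bilinear_upsample <- function(m, factor) {
  if (factor == 1L) return(m)
  up1 <- function(mat, f) {
    n <- nrow(mat)
    if (n == 1L) return(mat)
    pos <- seq(1, n, by = 1 / f)
    i0 <- pmin(floor(pos), n - 1L)
    w <- pos - i0
    mat[i0, , drop = FALSE] * (1 - w) + mat[i0 + 1L, , drop = FALSE] * w
  }
  t(up1(t(up1(m, factor)), factor))
}

## Frequency response of a rational digital filter at physical frequencies.
digital_response <- function(b, a, freq, fs) {
  w <- 2 * pi * freq / fs
  z <- exp(-1i * outer(w, seq_along(b) - 1))
  num <- drop(z %*% b)
  z <- exp(-1i * outer(w, seq_along(a) - 1))
  den <- drop(z %*% a)
  num / den
}
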