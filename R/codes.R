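#' Generate a Golay complementary pair
#'
#' Builds the binary Golay complementary pair of length `N = 2^order` by the
#' standard append recursion `A' = c(A, B)`, `B' = c(A, -B)` starting from
#' `A = B = 1`. The two sequences have the defining property that their
#' aperiodic autocorrelations sum to `2N` at lag zero and cancel exactly at
#' every other lag, which is what makes sidelobe-free pulse compression
#' possible.
#'
#' @param order Non-negative integer `k`; the pair has length `2^k`.
#'   The familiar eight-bit pair used for wood inspection is `order = 3`.
#' @return An object of class `golay_pair`: a list with integer vectors
#'   `a` and `b` (entries exactly +1/-1) and the `order`.
#' @examples
#' p <- golay_pair(3)
#' p$a                            # 1  1  1 -1  1  1 -1  1
#' complementary_autocorrelation(p)  # 16 at the centre lag, 0 elsewhere
#' @export
golay_pair <- function(order) {
  if (!is_count(order) || order < 0 || order > 16) {
    stopf("order must be an integer in [0, 16], got %s", format(order))
  }
  order <- as.integer(order)
  a <- 1L
  b <- 1L
  for (k in seq_len(order)) {
    a_new <- c(a, b)
    b_new <- c(a, -b)
    a <- a_new
    b <- b_new
  }
  structure(list(a = a, b = b, order = order), class = "golay_pair")
}

#' @export
print.golay_pair <- function(x, ...) {
  cat(sprintf("Golay complementary pair, order %d (N = %d)\n",
              x$order, length(x$a)))
  cat("  a:", paste(x$a, collapse = " "), "\n")
  cat("  b:", paste(x$b, collapse = " "), "\n")
  invisible(x)
}

## Aperiodic autocorrelation over lags -(N-1)...(N-1), exact integer
## arithmetic; centre (zero lag) at index N in 1-based storage.
aperiodic_autocorrelation <- function(x) {
  x <- check_pm1(x, "sequence")
  n <- length(x)
  sapply(-(n - 1L):(n - 1L), function(lag) {
    i <- seq_len(n - abs(lag))
    sum(x[i] * x[i + abs(lag)])
  })
}

#' Summed aperiodic autocorrelation of a complementary pair
#'
#' Elementwise sum of the aperiodic autocorrelations of the two sequences,
#' over lags `-(N-1)` to `N-1` (centre at index `N`). For a true
#' complementary pair this is `2N` at the centre and exactly zero elsewhere;
#' for the eight-bit pair the single main lobe has magnitude 16. Computed in
#' exact integer arithmetic.
#'
#' @param pair A [golay_pair()] (or any list with `$a`, `$b` of equal length
#'   and entries +1/-1).
#' @return Integer vector of length `2N - 1`.
#' @export
complementary_autocorrelation <- function(pair) {
  a <- check_pm1(pair$a, "a")
  b <- check_pm1(pair$b, "b")
  if (length(a) != length(b)) stopf("a and b must have equal length")
  aperiodic_autocorrelation(a) + aperiodic_autocorrelation(b)
}

#' Test whether two sequences form a complementary pair
#'
#' @param a,b Equal-length +1/-1 sequences.
#' @return `TRUE` iff the summed aperiodic autocorrelation equals
#'   `2N` at lag zero and 0 at every other lag (exact integer check).
#' @export
is_complementary <- function(a, b) {
  a <- check_pm1(a, "a")
  b <- check_pm1(b, "b")
  if (length(a) != length(b)) stopf("a and b must have equal length")
  n <- length(a)
  s <- aperiodic_autocorrelation(a) + aperiodic_autocorrelation(b)
  target <- integer(2L * n - 1L)
  target[n] <- 2L * n
  identical(as.integer(s), target)
}

#' Baseline codes: Barker-7 and uniform burst
#'
#' `barker7()` returns the length-7 Barker sequence, whose aperiodic
#' autocorrelation has peak 7 and off-peak magnitude at most 1 — good but
#' not perfect sidelobe suppression, the classic single-sequence baseline.
#' `burst(n)` returns `n` entries of +1, the uncoded multi-pulse baseline
#' whose autocorrelation is a triangle with large sidelobes.
#'
#' @return An object of class `acu_code`: list with `values` (+1/-1 integer
#'   vector) and `family` (one of `"golay_a"`, `"golay_b"`, `"barker"`,
#'   `"burst"`).
#' @export
barker7 <- function() {
  new_code(c(1L, 1L, 1L, -1L, -1L, 1L, -1L), "barker")
}

#' @param n Number of pulses (positive integer).
#' @rdname barker7
#' @export
burst <- function(n) {
  if (!is_count(n) || n < 1) stopf("n must be a positive integer")
  new_code(rep(1L, n), "burst")
}

new_code <- function(values, family) {
  family <- match.arg(family, c("golay_a", "golay_b", "barker", "burst"))
  if (family != "burst") values <- check_pm1(values, family)
  structure(list(values = as.integer(values), family = family),
            class = "acu_code")
}

#' @export
print.acu_code <- function(x, ...) {
  cat(sprintf("<%s code, %d chips> %s\n", x$family, length(x$values),
              paste(x$values, collapse = " ")))
  invisible(x)
}

#' Serialize codes to text or JSON
#'
#' One-line comma-separated form (`"1,1,-1,..."`) and a JSON object
#' `{"family":..., "values":[...]}`, round-trippable via the matching
#' readers.
#'
#' @param code An `acu_code` (or bare +1/-1 vector for `code_to_text`).
#' @export
code_to_text <- function(code) {
  values <- if (inherits(code, "acu_code")) code$values else code
  paste(as.integer(values), collapse = ",")
}

#' @param text One-line comma-separated chip values.
#' @param family Code family for the reconstructed object.
#' @rdname code_to_text
#' @export
code_from_text <- function(text, family = "burst") {
  values <- as.integer(strsplit(trimws(text), ",")[[1]])
  new_code(values, family)
}

#' @rdname code_to_text
#' @export
code_to_json <- function(code) {
  stopifnot(inherits(code, "acu_code"))
  jsonlite::toJSON(list(family = code$family, values = code$values),
                   auto_unbox = TRUE)
}

#' @param json JSON string as produced by `code_to_json`.
#' @rdname code_to_text
#' @export
code_from_json <- function(json) {
  x <- jsonlite::fromJSON(json)
  new_code(x$values, x$family)
}
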