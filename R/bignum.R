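#' Arbitrary-precision non-negative integers
#'
#' A `bigint` is a numeric vector of base-1e9 limbs (little-endian) with
#' class `"bigint"`. These are the exact-arithmetic backbone of the family
#' size calculations: Stirling numbers such as S(721, 61) run to well over a
#' thousand decimal digits and must never touch floating point until the
#' final rounded rendering.
#'
#' @param x a non-negative integral number below 2^53, or a decimal string.
#' @return a `bigint`.
#' @examples
#' bigint("1267650600228229401496703205376") == big_pow(bigint(2), 100)
#' @export
bigint <- function(x) {
  if (inherits(x, "bigint")) return(x)
  if (is.character(x)) {
    if (length(x) != 1L || !grepl("^[0-9]+$", x)) {
      stop("bigint(): string must be a single run of decimal digits")
    }
    x <- sub("^0+(?=.)", "", x, perl = TRUE)
    n <- nchar(x)
    starts <- rev(seq(n, 1L, by = -9L))
    limbs <- vapply(starts, function(s) {
      as.numeric(substr(x, max(1L, s - 8L), s))
    }, numeric(1))
    return(new_bigint(limbs))
  }
  if (!is.numeric(x) || length(x) != 1L || is.na(x) || x < 0 ||
      x != floor(x) || x >= 2^53) {
    stop("bigint(): need a single non-negative integer below 2^53")
  }
  limbs <- numeric(0)
  repeat {
    limbs <- c(limbs, x %% 1e9)
    x <- x %/% 1e9
    if (x == 0) break
  }
  new_bigint(limbs)
}

new_bigint <- function(limbs) {
  # strip high-order zero limbs; canonical zero is a single 0 limb
  while (length(limbs) > 1L && limbs[length(limbs)] == 0) {
    limbs <- limbs[-length(limbs)]
  }
  structure(limbs, class = "bigint")
}

#' @export
print.bigint <- function(x, ...) {
  cat("<bigint> ", format(x), "\n", sep = "")
  invisible(x)
}

#' @export
format.bigint <- function(x, ...) {
  limbs <- rev(unclass(x))
  paste0(limbs[1L], paste(sprintf("%09.0f", limbs[-1L]), collapse = ""))
}

#' @export
as.character.bigint <- function(x, ...) format(x)

#' @export
as.numeric.bigint <- function(x, ...) {
  limbs <- unclass(x)
  sum(limbs * 1e9^(seq_along(limbs) - 1L))
}

#' @export
`==.bigint` <- function(e1, e2) .bn_cmp(unclass(bigint(e1)), unclass(bigint(e2))) == 0L

#' Exact sum of two big integers
#' @param a,b `bigint`s (or coercible scalars).
#' @return a `bigint`.
#' @export
big_add <- function(a, b) {
  new_bigint(.bn_addmul(unclass(bigint(a)), unclass(bigint(b)), 1))
}

#' Exact product of two big integers
#' @inheritParams big_add
#' @return a `bigint`.
#' @export
big_mul <- function(a, b) {
  new_bigint(.bn_mul(unclass(bigint(a)), unclass(bigint(b))))
}

#' Fused multiply-add `m * a + b` with a small multiplier
#'
#' The workhorse of the Stirling recurrence; `m` must be an integer below
#' 2^31.
#' @inheritParams big_add
#' @param m small non-negative integer multiplier.
#' @return a `bigint`.
#' @export
big_addmul <- function(a, b, m) {
  new_bigint(.bn_addmul(unclass(bigint(a)), unclass(bigint(b)), m))
}

#' Compare two big integers
#' @inheritParams big_add
#' @return -1, 0 or 1 as `a < b`, `a == b`, `a > b`.
#' @export
big_cmp <- function(a, b) .bn_cmp(unclass(bigint(a)), unclass(bigint(b)))

#' Exact integer power with a small base
#' @param base `bigint` or small integer.
#' @param k non-negative integer exponent.
#' @return a `bigint` equal to `base^k`.
#' @export
big_pow <- function(base, k) {
  stopifnot(k >= 0, k == floor(k))
  base <- bigint(base)
  out <- bigint(1)
  if (k == 0) return(out)
  # exponentiation by squaring
  while (k > 0) {
    if (k %% 2 == 1) out <- big_mul(out, base)
    base <- big_mul(base, base)
    k <- k %/% 2
  }
  out
}

#' Exact falling factorial `n * (n-1) * ... * (n-j+1)`
#'
#' Used as `(n-1)_j = choose(n-1, j) * j!`, the number of ways to pick and
#' order `j` paternal lines; keeping it as a falling factorial avoids any
#' big-integer division.
#' @param n non-negative integer.
#' @param j non-negative integer, `j <= n` for a nonzero result.
#' @return a `bigint`.
#' @export
big_falling <- function(n, j) {
  stopifnot(n >= 0, j >= 0)
  if (j > n) return(bigint(0))
  out <- bigint(1)
  for (t in seq_len(j)) out <- big_addmul(out, 0, n - t + 1)
  out
}

#' Natural log of a big integer (double precision)
#' @param a a `bigint`, must be positive.
#' @return `log(a)` as a double.
#' @export
big_log <- function(a) {
  a <- bigint(a)
  limbs <- unclass(a)
  n <- length(limbs)
  if (n == 1L && limbs[1L] == 0) stop("big_log(): log of zero")
  top <- limbs[max(1L, n - 2L):n]
  lead <- sum(top * 1e9^(seq_along(top) - 1L))
  log(lead) + (n - length(top)) * log(1e9)
}

#' Round an exact ratio to a fixed number of decimals (half-up)
#'
#' Computes `round(num/den, digits)` with ties going up, entirely in exact
#' integer arithmetic: the quotient digit string is found by binary search
#' on `q * 2 * den <= 2 * num * 10^digits + den`.
#'
#' @param num,den numerator and denominator `bigint`s, `0 <= num <= den`,
#'   `den > 0`.
#' @param digits number of decimal places (0..15).
#' @return a double in `[0, 1]` with at most `digits` decimals.
#' @export
big_round_ratio <- function(num, den, digits = 3L) {
  stopifnot(digits >= 0, digits <= 15)
  num <- bigint(num); den <- bigint(den)
  if (big_cmp(num, den) > 0) stop("big_round_ratio(): requires num <= den")
  scale <- big_pow(bigint(10), digits)
  rhs <- big_add(big_mul(big_mul(num, scale), bigint(2)), den)  # 2*num*10^d + den
  den2 <- big_mul(den, bigint(2))
  lo <- 0; hi <- 10^digits                       # exact doubles for digits <= 15
  while (lo < hi) {
    mid <- floor((lo + hi + 1) / 2)
    if (big_cmp(big_mul(bigint(mid), den2), rhs) <= 0) lo <- mid else hi <- mid - 1
  }
  lo / 10^digits
}
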