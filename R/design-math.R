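#' Design parameters for an inter-pollination experiment
#'
#' Bundles the three integers that define the occupancy question behind
#' family-size planning: a set of `n` inbred lines is inter-pollinated, each
#' maternal line yields `k` F1 plants (one field row), and the breeder wants
#' at least `m` of the other `n - 1` lines represented as fathers in that
#' row.
#'
#' @param n number of inbred lines entering inter-pollination (>= 2).
#' @param k number of F1 offspring per maternal row (>= 0).
#' @param m minimum number of distinct paternal lines required,
#'   `0 <= m <= n - 1`.
#' @return an object of class `design_params`.
#' @examples
#' design_params(61, 420, 60)
#' @export
design_params <- function(n, k, m) {
  for (v in list(n, k, m)) {
    if (!is.numeric(v) || length(v) != 1L || is.na(v) || v != floor(v)) {
      stop("design_params(): n, k, m must be single integers")
    }
  }
  if (n < 2) stop("design_params(): n must be >= 2")
  if (k < 0) stop("design_params(): k must be >= 0")
  if (m < 0 || m > n - 1) stop("design_params(): need 0 <= m <= n - 1")
  structure(list(n = as.integer(n), k = as.integer(k), m = as.integer(m)),
            class = "design_params")
}

#' @export
print.design_params <- function(x, ...) {
  cat(sprintf("design_params: n = %d lines, k = %d offspring/row, m = %d fathers required\n",
              x$n, x$k, x$m))
  invisible(x)
}

#' Stirling numbers of the second kind, exactly
#'
#' `S(k, j)` counts the partitions of a `k`-element set into `j` non-empty
#' blocks. Computed by the triangular recurrence
#' `S(k, j) = j * S(k-1, j) + S(k-1, j-1)` in exact big-integer arithmetic;
#' no floating point is involved at any magnitude.
#'
#' @param k,j non-negative integers.
#' @return a [bigint()] equal to `S(k, j)`.
#' @examples
#' stirling2(4, 2)  # 7
#' @export
stirling2 <- function(k, j) {
  if (k < 0 || j < 0) stop("stirling2(): arguments must be non-negative")
  if (j > k) return(bigint(0))
  if (k == 0) return(bigint(1))           # S(0,0) = 1
  if (j == 0) return(bigint(0))
  cache <- stirling_cache(jmax = j)
  stirling_row(cache, k)[[j + 1L]]
}

#' Rolling cache of one row of the Stirling triangle
#'
#' Holds `S(k, 0..jmax)` for the current `k` and advances forward one row at
#' a time, so a whole probability table (ascending `k`) costs a single pass.
#' Asking for a smaller `k` restarts from row zero.
#'
#' @param jmax largest second argument that will be requested.
#' @return an environment of class `stirling_cache`.
#' @export
stirling_cache <- function(jmax) {
  stopifnot(jmax >= 0, jmax == floor(jmax))
  env <- new.env(parent = emptyenv())
  env$jmax <- as.integer(jmax)
  env$k <- 0L
  env$row <- c(list(bigint(1)), rep(list(bigint(0)), jmax))  # S(0, 0..jmax)
  class(env) <- "stirling_cache"
  env
}

#' Fetch the row `S(k, 0..jmax)` from a cache
#' @param cache a [stirling_cache()].
#' @param k row index (non-negative integer).
#' @return list of `jmax + 1` [bigint()]s.
#' @export
stirling_row <- function(cache, k) {
  stopifnot(inherits(cache, "stirling_cache"), k >= 0)
  if (k < cache$k) {          # restart: the cache only rolls forward
    fresh <- stirling_cache(cache$jmax)
    cache$k <- fresh$k
    cache$row <- fresh$row
  }
  jmax <- cache$jmax
  zero <- bigint(0)
  while (cache$k < k) {
    old <- cache$row
    new <- vector("list", jmax + 1L)
    new[[1L]] <- zero                      # S(k, 0) = 0 for k >= 1
    if (jmax >= 1L) {
      for (j in 1:jmax) {
        new[[j + 1L]] <- big_addmul(old[[j + 1L]], old[[j]], j)
      }
    }
    cache$row <- new
    cache$k <- cache$k + 1L
  }
  cache$row
}

#' Number of pollination strings with exactly j foreign fathers
#'
#' Among the `n^k` equally likely length-`k` strings over the `n` lines
#' (the pollen draws for one maternal row), counts those in which exactly
#' `j` lines other than the maternal line appear:
#' `choose(n-1, j) * j! * S(k+1, j+1)`.
#'
#' @param n,k as in [design_params()].
#' @param j number of distinct non-maternal lines, `0 <= j <= n - 1`.
#' @return a [bigint()].
#' @export
count_strings_exactly_j <- function(n, k, j) {
  if (j < 0 || j > n - 1) stop("count_strings_exactly_j(): need 0 <= j <= n - 1")
  design_params(n, k, j)                  # validates n, k

  big_mul(big_falling(n - 1, j), stirling2(k + 1L, j + 1L))
}

#' Exact probability of covering at least m paternal lines
#'
#' The central planning quantity: the probability `Q(n, k, m)` that a fixed
#' maternal line, whose `k` offspring each receive pollen from one of the
#' `n` lines uniformly at random (self included), is fathered by at least
#' `m` distinct lines other than itself:
#' \deqn{Q(n,k,m) = n^{-k} \sum_{j=m}^{n-1} \binom{n-1}{j} j!\, S(k+1, j+1)}
#' Evaluated as an exact rational; `rounded` renders it half-up at
#' `decimals` places.
#'
#' @param params a [design_params()] (or an `n`; then `k`, `m` must be given).
#' @param k,m used only when `params` is a plain number.
#' @param decimals decimal places for the rounded rendering (default 3).
#' @param cache optional [stirling_cache()] with `jmax >= n`, reused across
#'   ascending `k` values.
#' @return an object of class `design_probability` with fields `num`, `den`
#'   (exact [bigint()] numerator/denominator), `value` (double
#'   approximation), `rounded` and `decimals`.
#' @examples
#' q_probability(design_params(31, 120, 30))$rounded  # 0.540
#' @export
q_probability <- function(params, k = NULL, m = NULL, decimals = 3L,
                          cache = NULL) {
  if (!inherits(params, "design_params")) params <- design_params(params, k, m)
  n <- params$n; k <- params$k; m <- params$m
  if (is.null(cache)) {
    cache <- stirling_cache(jmax = n)
  } else if (cache$jmax < n) {
    stop("q_probability(): cache jmax too small for this n")
  }
  row <- stirling_row(cache, k + 1L)       # S(k+1, 0..jmax)
  num <- bigint(0)
  if (m <= n - 1) {
    for (j in m:(n - 1L)) {
      num <- big_add(num, big_mul(big_falling(n - 1L, j), row[[j + 2L]]))
    }
  }
  den <- big_pow(bigint(n), k)
  new_design_probability(num, den, decimals)
}

new_design_probability <- function(num, den, decimals) {
  value <- if (big_cmp(num, bigint(0)) == 0) 0 else exp(big_log(num) - big_log(den))
  structure(list(num = num, den = den, value = value,
                 rounded = big_round_ratio(num, den, decimals),
                 decimals = as.integer(decimals)),
            class = "design_probability")
}

#' @export
print.design_probability <- function(x, ...) {
  cat(sprintf("design_probability: %.*f (exact rational, ~%.6g)\n",
              x$decimals, x$rounded, x$value))
  invisible(x)
}

#' Exact equality / ordering of design probabilities
#'
#' Cross-multiplies the exact rationals, so comparisons are free of floating
#' point.
#' @param a,b `design_probability` objects.
#' @return `dp_cmp`: -1/0/1; `dp_equal`: logical.
#' @export
dp_cmp <- function(a, b) {
  big_cmp(big_mul(a$num, b$den), big_mul(b$num, a$den))
}

#' @rdname dp_cmp
#' @export
dp_equal <- function(a, b) dp_cmp(a, b) == 0L

#' Smallest family size reaching a target probability
#'
#' Returns the least `k` with `Q(n, k, m) >= p`, by exponential bracketing
#' followed by bisection; monotonicity of `Q` in `k` makes the search exact.
#' The comparison is performed on exact rationals, with `p` read as the
#' rational `round(p * 1e12) / 1e12`.
#'
#' @param n,m as in [design_params()]; `m >= 1` (for `m = 0` the answer is 0).
#' @param p target probability in (0, 1).
#' @return the minimal integer `k`.
#' @examples
#' min_offspring(2, 1, 0.5)  # 1
#' @export
min_offspring <- function(n, m, p) {
  if (!is.numeric(p) || length(p) != 1L || is.na(p) || p <= 0 || p >= 1) {
    stop("min_offspring(): p must lie strictly between 0 and 1")
  }
  design_params(n, 0, m)                  # validate n, m
  if (m == 0) return(0L)
  p_num <- bigint(round(p * 1e12)); p_den <- bigint(1e12)
  cache <- stirling_cache(jmax = n)
  meets <- function(k) {
    q <- q_probability(design_params(n, k, m), cache = cache)
    # Q >= p  <=>  num * p_den >= p_num * den
    big_cmp(big_mul(q$num, p_den), big_mul(p_num, q$den)) >= 0L
  }
  hi <- max(m, 1L)
  while (!meets(hi)) hi <- hi * 2L
  lo <- m                                  # Q(n, k, m) = 0 for k < m
  while (lo < hi) {
    mid <- (lo + hi) %/% 2L
    if (meets(mid)) hi <- mid else lo <- mid + 1L
  }
  as.integer(lo)
}

#' Grid of coverage probabilities in the published table layout
#'
#' Rows are family sizes `k`, columns the required father counts `m`;
#' entries are `Q(n, k, m)` rounded at `decimals` places. One Stirling pass
#' serves the whole ascending-`k` grid.
#'
#' @param n number of lines.
#' @param k_values integer vector of family sizes (any order).
#' @param m_values integer vector of required father counts.
#' @param decimals decimal places (default 3).
#' @return a `data.frame` with column `k` then one column `Q(n,k,m)` per `m`.
#' @export
probability_table <- function(n, k_values, m_values, decimals = 3L) {
  stopifnot(length(k_values) >= 1L, length(m_values) >= 1L)
  ord <- order(k_values)
  cache <- stirling_cache(jmax = n)
  cells <- matrix(NA_real_, nrow = length(k_values), ncol = length(m_values))
  for (i in ord) {
    for (jm in seq_along(m_values)) {
      q <- q_probability(design_params(n, k_values[i], m_values[jm]),
                         decimals = decimals, cache = cache)
      cells[i, jm] <- q$rounded
    }
  }
  out <- data.frame(k = as.integer(k_values), cells)
  names(out) <- c("k", sprintf("Q(%d,k,%d)", n, m_values))
  out
}

#' Brute-force coverage probability (verification oracle)
#'
#' Enumerates all `n^k` pollination strings and counts those in which at
#' least `m` non-maternal lines appear. This is the definition of
#' `Q(n, k, m)` itself, kept deliberately independent of the closed form so
#' the two can be cross-checked exactly.
#'
#' @inheritParams q_probability
#' @return a `design_probability` (exact rational `count / n^k`).
#' @export
brute_force_q <- function(params, k = NULL, m = NULL) {
  if (!inherits(params, "design_params")) params <- design_params(params, k, m)
  n <- params$n; k <- params$k; m <- params$m
  total <- n^k
  if (total > 1e7) stop("brute_force_q(): n^k exceeds the 1e7 guard")
  if (k == 0) {
    count <- if (m == 0) 1 else 0
    return(new_design_probability(bigint(count), bigint(1), 3L))
  }
  count <- 0
  chunk <- 1e5
  pows <- n^(0:(k - 1L))
  for (start in seq(0, total - 1, by = chunk)) {
    idx <- start:min(start + chunk - 1, total - 1)
    # digits matrix: rows = strings, cols = draws; line 0 is the mother
    digs <- outer(idx, pows, function(i, p) (i %/% p) %% n)
    distinct <- integer(length(idx))
    for (line in 1:(n - 1L)) {
      distinct <- distinct + (rowSums(digs == line) > 0L)
    }
    count <- count + sum(distinct >= m)
  }
  new_design_probability(bigint(count), bigint(total), 3L)
}

#' Number of non-reciprocal pairwise crosses among n lines
#'
#' The classical diallel workload `n(n-1)/2` that the inter-pollination
#' scheme is designed to avoid.
#' @param n number of inbred lines (>= 1).
#' @return an integer.
#' @examples
#' cross_count(100)  # 4950
#' @export
cross_count <- function(n) {
  stopifnot(is.numeric(n), length(n) == 1L, n >= 1, n == floor(n))
  as.integer(n * (n - 1) / 2)
}
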