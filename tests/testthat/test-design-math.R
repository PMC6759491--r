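test_that("bigint arithmetic is exact at scale", {
  # 2^100, frozen from an independent arbitrary-precision computation
  expect_identical(format(big_pow(bigint(2), 100)),
                   "1267650600228229401496703205376")
  expect_identical(format(big_mul(bigint("999999999999999999"), bigint(0))), "0")
  # distributivity on values straddling several limbs
  a <- bigint("123456789012345678901234567890")
  b <- bigint("98765432109876543210")
  expect_equal(big_cmp(big_mul(big_add(a, b), bigint(7)),
                       big_add(big_mul(a, bigint(7)), big_mul(b, bigint(7)))), 0L)
  expect_equal(big_cmp(a, b), 1L)
  expect_equal(big_cmp(b, a), -1L)
  expect_true(bigint("000123") == bigint(123))
  expect_error(bigint(-1), "non-negative")
  expect_error(bigint(2^53), "non-negative integer below")
})

test_that("big_round_ratio rounds half-up at the requested precision", {
  expect_equal(big_round_ratio(bigint(1), bigint(8), 2L), 0.13)   # 0.125 up
  expect_equal(big_round_ratio(bigint(1), bigint(8), 3L), 0.125)
  expect_equal(big_round_ratio(bigint(1), bigint(2000), 3L), 0.001)  # 0.0005 up
  expect_equal(big_round_ratio(bigint(0), bigint(5), 3L), 0)
  expect_equal(big_round_ratio(bigint(5), bigint(5), 3L), 1)
  expect_error(big_round_ratio(bigint(6), bigint(5), 3L), "num <= den")
})

test_that("stirling2 matches enumeration and boundary identities", {
  expect_identical(format(stirling2(3, 2)), "3")
  expect_identical(format(stirling2(4, 2)), "7")
  expect_identical(format(stirling2(7, 1)), "1")
  expect_identical(format(stirling2(5, 5)), "1")
  expect_identical(format(stirling2(0, 0)), "1")
  expect_identical(format(stirling2(4, 6)), "0")
  expect_error(stirling2(-1, 2), "non-negative")
  # S(k,1) = S(k,k) = 1 across a grid
  for (k in 1:12) {
    expect_true(stirling2(k, 1) == bigint(1))
    expect_true(stirling2(k, k) == bigint(1))
  }
})

test_that("count_strings_exactly_j partitions the n^k strings", {
  # spec micro-examples
  expect_identical(format(count_strings_exactly_j(2, 1, 0)), "1")
  expect_identical(format(count_strings_exactly_j(2, 1, 1)), "1")
  expect_identical(format(count_strings_exactly_j(2, 2, 1)), "3")
  expect_error(count_strings_exactly_j(3, 2, 3), "0 <= j <= n - 1")
  # conservation: sum_j |M_{j,k,n}| = n^k
  for (n in 2:5) {
    for (k in c(0L, 1L, 4L, 6L)) {
      total <- bigint(0)
      for (j in 0:(n - 1L)) {
        total <- big_add(total, count_strings_exactly_j(n, k, j))
      }
      expect_true(total == big_pow(bigint(n), k),
                  info = sprintf("n=%d k=%d", n, k))
    }
  }
})

test_that("surjection-count identity holds (inclusion-exclusion cross-check)", {
  # j! S(k+1, j+1) = sum_t (-1)^t C(j,t) (j+1-t)^k ; compare as
  # lhs + (negative part) == (positive part) to stay in unsigned arithmetic
  for (j in c(1L, 3L, 6L)) {
    for (k in c(2L, 9L, 17L)) {
      lhs <- big_mul(big_falling(j, j), stirling2(k + 1L, j + 1L))
      pos <- bigint(0); neg <- bigint(0)
      for (t in 0:j) {
        term <- big_mul(bigint(choose(j, t)), big_pow(bigint(j + 1L - t), k))
        if (t %% 2L == 0L) pos <- big_add(pos, term) else neg <- big_add(neg, term)
      }
      expect_true(big_add(lhs, neg) == pos, info = sprintf("j=%d k=%d", j, k))
    }
  }
})

test_that("q_probability reproduces published spot values and exact cases", {
  expect_equal(q_probability(design_params(61, 420, 60))$rounded, 0.943)
  expect_equal(q_probability(design_params(31, 270, 30))$rounded, 0.996)
  # k < m: impossible
  q0 <- q_probability(design_params(5, 3, 4))
  expect_true(q0$num == bigint(0))
  expect_equal(q0$rounded, 0)
  # n=2, k=1, m=1: exactly 1/2
  qh <- q_probability(design_params(2, 1, 1))
  expect_true(qh$num == bigint(1))
  expect_true(qh$den == bigint(2))
  # m = 0 is always satisfied
  expect_true(dp_equal(q_probability(design_params(3, 1, 0)),
                       q_probability(design_params(3, 0, 0))))
  expect_equal(q_probability(design_params(3, 1, 0))$rounded, 1)
})

test_that("q_probability equals the brute-force oracle exactly", {
  for (n in 2:4) {
    for (k in c(0L, 1L, 3L, 5L)) {
      for (m in 0:(n - 1L)) {
        p <- design_params(n, k, m)
        expect_true(dp_equal(q_probability(p), brute_force_q(p)),
                    info = sprintf("n=%d k=%d m=%d", n, k, m))
      }
    }
  }
  expect_error(brute_force_q(design_params(10, 10, 5)), "guard")
})

test_that("Q is monotone in k and in m, with the right limits", {
  cache <- stirling_cache(jmax = 6)
  for (n in c(3L, 6L)) {
    for (m in 1:(n - 1L)) {
      prev <- q_probability(design_params(n, 0, m), cache = cache)
      for (k in 1:10) {
        cur <- q_probability(design_params(n, k, m), cache = cache)
        expect_gte(dp_cmp(cur, prev), 0L)
        prev <- cur
      }
    }
    # non-increasing in m at fixed k
    for (m in 1:(n - 2L)) {
      expect_lte(dp_cmp(q_probability(design_params(n, 6, m + 1L)),
                        q_probability(design_params(n, 6, m))), 0L)
    }
  }
  # Q -> 1 for large k
  expect_equal(q_probability(design_params(3, 60, 2))$rounded, 1)
})

test_that("min_offspring brackets the target probability", {
  expect_identical(min_offspring(2, 1, 0.5), 1L)
  k <- min_offspring(31, 30, 0.5)
  expect_gt(k, 90)
  expect_lte(k, 120)
  p_num <- bigint(5e11); p_den <- bigint(1e12)   # p = 0.5
  q_at <- q_probability(design_params(31, k, 30))
  q_below <- q_probability(design_params(31, k - 1L, 30))
  expect_gte(big_cmp(big_mul(q_at$num, p_den), big_mul(p_num, q_at$den)), 0L)
  expect_lt(big_cmp(big_mul(q_below$num, p_den), big_mul(p_num, q_below$den)), 0L)
  expect_error(min_offspring(31, 30, 1), "strictly between")
  expect_identical(min_offspring(5, 0, 0.9), 0L)
})

test_that("probability_table lays out the grid and matches q_probability", {
  tab <- probability_table(3, c(1L, 4L), c(0L, 2L))
  expect_identical(names(tab), c("k", "Q(3,k,0)", "Q(3,k,2)"))
  expect_equal(tab[["Q(3,k,0)"]], c(1, 1))
  expect_equal(tab[["Q(3,k,2)"]][1L],
               q_probability(design_params(3, 1, 2))$rounded)
  expect_equal(tab[["Q(3,k,2)"]][2L],
               q_probability(design_params(3, 4, 2))$rounded)
})

test_that("cross_count gives the non-reciprocal diallel workload", {
  expect_identical(cross_count(100), 4950L)
  expect_identical(cross_count(1), 0L)
  expect_identical(cross_count(50), 1225L)
})
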