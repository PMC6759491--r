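test_that("transition_prob follows Mendelian algebra with homozygous parents", {
  f <- manual_freqs(list(L1 = c("100" = 0.75, "102" = 0.25)))
  e0 <- error_model(0, 1)
  # mother 100/100, father 102/102 -> offspring must be 100/102
  expect_equal(transition_prob(c(100L, 102L), c(100L, 100L), c(102L, 102L),
                               f, "L1", e0), 1)
  # father unknown: paternal allele integrated over frequencies
  expect_equal(transition_prob(c(100L, 102L), c(100L, 100L), NULL,
                               f, "L1", e0), 0.25)
  # the likelihood ratio for this trio is 4
  num <- transition_prob(c(100L, 102L), c(100L, 100L), c(102L, 102L), f, "L1", e0)
  den <- transition_prob(c(100L, 102L), c(100L, 100L), NULL, f, "L1", e0)
  expect_equal(num / den, 4)
  # incompatible trio is excluded at error 0 ...
  f2 <- manual_freqs(list(L1 = c("100" = 0.5, "102" = 0.25, "104" = 0.25)))
  expect_equal(transition_prob(c(100L, 102L), c(100L, 100L), c(104L, 104L),
                               f2, "L1", e0), 0)
  # ... but has positive probability once mistyping is allowed
  e <- error_model(0.002, 0.998)
  p_err <- transition_prob(c(100L, 102L), c(100L, 100L), c(104L, 104L),
                           f2, "L1", e)
  expect_gt(p_err, 0)
  expect_equal(p_err, 0.002 * 2 * 0.5 * 0.25)   # e * HWE(100/102)
})

test_that("lod_score sums per-locus log ratios and enforces the 8-of-8 rule", {
  loci <- sprintf("L%d", 1:8)
  freqs <- manual_freqs(stats::setNames(
    lapply(1:8, function(i) c("100" = 0.75, "102" = 0.25)), loci))
  mk <- function(a) stats::setNames(rep(a, 8L), loci)
  off <- list(line_id = "O", a1 = mk(100L), a2 = mk(102L))
  mo <- list(line_id = "M", a1 = mk(100L), a2 = mk(100L))
  fa <- list(line_id = "F", a1 = mk(102L), a2 = mk(102L))
  e0 <- error_model(0, 1)
  r <- lod_score(off, mo, fa, freqs, e0)
  expect_equal(r$lod, 8 * log(4))
  expect_equal(r$n_typed, 8L)
  expect_equal(r$mismatches, 0L)
  expect_true(r$evaluable)
  expect_equal(r$detail$log_ratio, rep(log(4), 8L))
  # one locus untyped: below the all-loci rule, not evaluable
  off7 <- off; off7$a1[8L] <- NA_integer_; off7$a2[8L] <- NA_integer_
  r7 <- lod_score(off7, mo, fa, freqs, e0)
  expect_false(r7$evaluable)
  expect_true(is.na(r7$lod))
  expect_true(lod_score(off7, mo, fa, freqs, e0, min_typed_loci = 7L)$evaluable)
  # hard exclusion at error 0
  freqs3 <- manual_freqs(stats::setNames(
    lapply(1:8, function(i) c("100" = 0.5, "102" = 0.25, "104" = 0.25)), loci))
  bad <- list(line_id = "B", a1 = mk(104L), a2 = mk(104L))
  rb <- lod_score(off, mo, bad, freqs3, e0)
  expect_identical(rb$lod, -Inf)
  expect_equal(rb$mismatches, 8L)
  # self-pollination candidate is flagged, not rejected
  rs <- lod_score(off, mo, mo, freqs, e0)
  expect_true(rs$self)
})

test_that("confidence thresholds are ordered, deterministic and calibrated", {
  panel <- simulate_dh_panel(20, seed = 11)
  freqs <- allele_frequencies(panel)
  t1 <- simulate_confidence_thresholds(freqs, 20, n_progeny = 2000, seed = 5)
  t2 <- simulate_confidence_thresholds(freqs, 20, n_progeny = 2000, seed = 5)
  expect_identical(t1$strict_lod, t2$strict_lod)
  expect_identical(t1$relaxed_lod, t2$relaxed_lod)
  expect_gte(t1$strict_lod, t1$relaxed_lod)
  # fully sampled, informative panel: most simulated assignments succeed
  expect_gt(t1$summary$success_rate, 0.8)
  # delta statistic is also available
  td <- simulate_confidence_thresholds(freqs, 20, n_progeny = 2000, seed = 5,
                                       statistic = "delta")
  expect_identical(td$statistic, "delta")
  expect_gte(td$strict_lod, td$relaxed_lod)
  # monomorphic-everywhere table is degenerate
  mono <- manual_freqs(list(L1 = c("100" = 1)))
  expect_error(simulate_confidence_thresholds(mono, 10, n_progeny = 200, seed = 1),
               "monomorphic")
})

test_that("true father dominates unrelated candidates in expectation", {
  panel <- simulate_dh_panel(30, seed = 21)
  freqs <- allele_frequencies(panel)
  pol <- simulate_interpollination(panel, 40, seed = 22)   # 1200 trios
  e0 <- error_model()             # small mistype rate keeps every LOD finite
  r <- dhcross:::.lod_matrix(
    pol$offspring$a1, pol$offspring$a2,
    panel$a1[match(pol$truth$mother_id, panel$lines$line_id), , drop = FALSE],
    panel$a2[match(pol$truth$mother_id, panel$lines$line_id), , drop = FALSE],
    panel$a1, panel$a2, panel$loci$locus_id, freqs, e0)
  ti <- match(pol$truth$father_id, panel$lines$line_id)
  lod_true <- r$lod[cbind(seq_len(nrow(r$lod)), ti)]
  other <- r$lod; other[cbind(seq_len(nrow(r$lod)), ti)] <- NA
  lod_other <- apply(other, 1L, max, na.rm = TRUE)   # best wrong candidate
  expect_gt(mean(lod_true), mean(lod_other))
  expect_true(all(lod_true >= lod_other))
})

test_that("assign_paternity recovers constructed trios and flags edge cases", {
  panel <- simulate_dh_panel(12, seed = 31)
  freqs <- allele_frequencies(panel)
  pol <- simulate_interpollination(panel, 20, seed = 32)
  e0 <- error_model(0, 1)
  thr <- simulate_confidence_thresholds(freqs, 12, n_progeny = 2000, seed = 33)
  asg <- assign_paternity(pol$offspring, panel, freqs, thresholds = thr, error = e0)
  assigned <- !is.na(asg$assigned_father)
  expect_true(all(label_hits(asg$assigned_father[assigned],
                             pol$truth$father_id[assigned])))
  expect_true(any(asg$confidence == "strict"))
  expect_true(all(asg$maternal_ok))
  expect_true(all(asg$mismatches[assigned] == 0L))
  # unassignable offspring: novel alleles at every locus
  off <- pol$offspring
  off$a1[1L, ] <- 999L; off$a2[1L, ] <- 999L
  asg2 <- assign_paternity(off, panel, freqs, thresholds = thr, error = e0)
  expect_false(asg2$maternal_ok[1L])           # incompatible with its mother too
  expect_true(is.na(asg2$assigned_father[1L]))
  expect_identical(asg2$confidence[1L], "unassigned")
  # unknown mother is an error
  off3 <- pol$offspring
  off3$lines$maternal_id[2L] <- "NOPE"
  expect_error(assign_paternity(off3, panel, freqs, error = e0), "no recorded mother")
})

test_that("genotypically identical candidates yield an ambiguous group", {
  panel <- simulate_dh_panel(10, seed = 41)
  # duplicate line L02 as a new candidate line DUP (same multilocus genotype)
  lines <- rbind(panel$lines,
                 data.frame(line_id = "DUP", role = "parent",
                            maternal_id = NA_character_))
  i <- match("L02", panel$lines$line_id)
  a1 <- rbind(panel$a1, panel$a1[i, ]); a2 <- rbind(panel$a2, panel$a2[i, ])
  panel2 <- marker_panel(panel$loci, lines, a1, a2)
  freqs <- allele_frequencies(panel2)
  pol <- simulate_interpollination(panel_subset(panel2, roles = "parent"),
                                   10, seed = 42)
  keep <- pol$truth$father_id %in% c("L02", "DUP")
  off <- panel_subset(pol$offspring, line_ids = pol$truth$offspring_id[keep])
  thr <- simulate_confidence_thresholds(freqs, 11, n_progeny = 2000, seed = 43)
  asg <- assign_paternity(off, panel2, freqs, thresholds = thr,
                          error = error_model(0, 1))
  assigned <- !is.na(asg$assigned_father)
  expect_true(any(assigned))
  expect_true(all(asg$ambiguous[assigned]))
  expect_true(all(asg$assigned_father[assigned] == "DUP/L02"))
  # never a confident unique father for these offspring
  expect_false(any(assigned & asg$assigned_father %in% c("L02", "DUP")))
})

test_that("detect_reciprocals performs exact set algebra", {
  r <- detect_reciprocals(data.frame(mother_id = c("A", "B", "A"),
                                     father_id = c("B", "A", "C")))
  expect_identical(r$n_combinations, 2L)
  expect_identical(r$n_reciprocal_pairs, 1L)
  expect_identical(r$reciprocal_pairs$parent_a, "A")
  expect_identical(r$reciprocal_pairs$parent_b, "B")
  # unique ordered pairs, no reversals
  r0 <- detect_reciprocals(data.frame(mother_id = c("A", "B"),
                                      father_id = c("C", "C")))
  expect_identical(r0$n_reciprocal_pairs, 0L)
  expect_identical(r0$n_combinations, 2L)
  # constructed selection set with known structure: 99 distinct pairs,
  # 24 of them selected in both orientations, 213 selections in total
  set.seed(99)
  ids <- sprintf("P%02d", 1:30)
  pairs <- t(combn(ids, 2L))[sample.int(choose(30, 2), 99L), , drop = FALSE]
  sel_m <- pairs[, 1L]; sel_f <- pairs[, 2L]
  recip_idx <- sample.int(99L, 24L)
  sel_m <- c(sel_m, pairs[recip_idx, 2L]); sel_f <- c(sel_f, pairs[recip_idx, 1L])
  extra <- sample.int(99L, 213L - length(sel_m), replace = TRUE)
  sel_m <- c(sel_m, pairs[extra, 1L]); sel_f <- c(sel_f, pairs[extra, 2L])
  rr <- detect_reciprocals(data.frame(mother_id = sel_m, father_id = sel_f))
  expect_identical(rr$n_selections, 213L)
  expect_identical(rr$n_combinations, 99L)
  expect_identical(rr$n_reciprocal_pairs, 24L)
  expect_identical(sum(rr$combinations$multiplicity), 213L)
})
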