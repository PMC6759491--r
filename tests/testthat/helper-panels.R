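# Fixtures and independent oracles shared by the test files.

# A tiny hand-written panel: 4 DH parents + 2 offspring over 2 loci.
tiny_panel <- function() {
  loci <- c("LOC1", "LOC2")
  lines <- data.frame(
    line_id = c("P1", "P2", "P3", "P4", "O1", "O2"),
    role = c(rep("parent", 4L), rep("offspring", 2L)),
    maternal_id = c(rep(NA_character_, 4L), "P1", "P2"),
    stringsAsFactors = FALSE)
  a1 <- rbind(c(100L, 200L), c(103L, 206L), c(106L, 200L), c(100L, 212L),
              c(100L, 200L), c(103L, 200L))
  a2 <- rbind(c(100L, 200L), c(103L, 206L), c(106L, 200L), c(100L, 212L),
              c(103L, 206L), c(106L, 206L))
  marker_panel(loci, lines, a1, a2)
}

# a frequency table built by hand (not via allele_frequencies)
manual_freqs <- function(tbls, n_individuals = 10L) {
  structure(tbls, class = "allele_freq_table", n_individuals = n_individuals)
}

# random panel for round-trip / property tests
random_panel <- function(n_parents, n_offspring, n_loci, seed,
                         missing_prob = 0) {
  set.seed(seed)
  loci <- sprintf("M%02d", seq_len(n_loci))
  nl <- n_parents + n_offspring
  a1 <- matrix(sample(100:130, nl * n_loci, TRUE), nl, n_loci)
  a2 <- matrix(sample(100:130, nl * n_loci, TRUE), nl, n_loci)
  if (missing_prob > 0) {
    drop <- matrix(runif(nl * n_loci) < missing_prob, nl, n_loci)
    a1[drop] <- NA_integer_; a2[drop] <- NA_integer_
  }
  lines <- data.frame(
    line_id = sprintf("X%03d", seq_len(nl)),
    role = c(rep("parent", n_parents), rep("offspring", n_offspring)),
    maternal_id = c(rep(NA_character_, n_parents),
                    sprintf("X%03d", sample.int(max(n_parents, 1L), n_offspring, TRUE))),
    stringsAsFactors = FALSE)
  marker_panel(loci, lines, pmin(a1, a2), pmax(a1, a2))
}

# Brute-force known-mother non-exclusion probability for one locus:
# enumerate mother, true father, offspring and candidate genotypes at HWE.
# Deliberately independent of the closed form used by diversity_stats().
ne_1p_enum <- function(p) {
  A <- seq_along(p)
  tot <- 0
  for (ma in A) for (mb in A) for (fa in A) for (fb in A) {
    w <- p[ma] * p[mb] * p[fa] * p[fb] / 4
    for (om in c(ma, mb)) for (of in c(fa, fb)) {
      alleles <- c(om, of)
      pat <- integer(0)
      for (i in 1:2) {
        if (alleles[3L - i] %in% c(ma, mb)) pat <- union(pat, alleles[i])
      }
      q <- sum(p[pat])
      tot <- tot + w * (1 - (1 - q)^2)
    }
  }
  tot
}

# does an assignment label (possibly an identity group "A/B") contain the
# true father?
label_hits <- function(labels, truth) {
  mapply(function(lab, tf) {
    if (is.na(lab)) return(FALSE)
    tf %in% strsplit(lab, "/", fixed = TRUE)[[1L]]
  }, labels, truth, USE.NAMES = FALSE)
}

# the two probability tables exactly as printed (k, then one column per m)
published_table_61 <- function() {
  cbind(k = seq(60, 720, 60),
        m60 = c(0.000, 0.000, 0.032, 0.304, 0.650, 0.854, 0.943, 0.979,
                0.992, 0.997, 0.999, 1.000),
        m54 = c(0.000, 0.216, 0.979, 1.000, 1.000, 1.000, 1.000, 1.000,
                1.000, 1.000, 1.000, 1.000),
        m48 = c(0.000, 0.969, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000,
                1.000, 1.000, 1.000, 1.000))
}

published_table_31 <- function() {
  cbind(k = seq(30, 360, 30),
        m30 = c(0.000, 0.004, 0.173, 0.540, 0.799, 0.921, 0.970, 0.989,
                0.996, 0.998, 0.999, 1.000),
        m27 = c(0.000, 0.340, 0.947, 0.999, 1.000, 1.000, 1.000, 1.000,
                1.000, 1.000, 1.000, 1.000),
        m24 = c(0.003, 0.925, 1.000, 1.000, 1.000, 1.000, 1.000, 1.000,
                1.000, 1.000, 1.000, 1.000))
}
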