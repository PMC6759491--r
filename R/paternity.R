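#' Genotyping error model
#'
#' Two per-locus rates govern how observed genotypes deviate from truth:
#' a locus is scored at all with probability `typed_rate`, and a scored
#' genotype is an error (replaced by a random population genotype) with
#' probability `mistype_rate`. The defaults are the rates used throughout
#' the cabbage experiment's parentage simulation.
#'
#' @param mistype_rate probability a scored locus genotype is erroneous.
#' @param typed_rate probability a locus is scored.
#' @return an object of class `error_model`.
#' @export
error_model <- function(mistype_rate = 0.002, typed_rate = 0.998) {
  stopifnot(mistype_rate >= 0, mistype_rate <= 1,
            typed_rate >= 0, typed_rate <= 1)
  structure(list(mistype_rate = mistype_rate, typed_rate = typed_rate),
            class = "error_model")
}

#' Extract one line's multilocus genotype
#' @param panel a [marker_panel()].
#' @param line_id a line id present in the panel.
#' @return list with `line_id` and integer vectors `a1`, `a2` named by locus.
#' @export
line_genotype <- function(panel, line_id) {
  i <- match(line_id, panel$lines$line_id)
  if (is.na(i)) stop("line_genotype(): unknown line_id '", line_id, "'")
  list(line_id = line_id, a1 = panel$a1[i, ], a2 = panel$a2[i, ])
}

# P(child allele == z | parent genotype {p1, p2}) by Mendelian transmission
.transmit <- function(z, p1, p2) 0.5 * (p1 == z) + 0.5 * (p2 == z)

# Hardy-Weinberg probability of the (unordered) offspring genotype
.hwe_geno <- function(fx, fy, het) ifelse(het, 2 * fx * fy, fx^2)

#' Single-locus transition probability under the error model
#'
#' With the father's genotype given, returns
#' `P(offspring genotype | mother, father)` from Mendelian segregation; with
#' `father = NULL`, the paternal allele is integrated over the population
#' allele frequencies, giving `P(offspring | mother)`. Either probability is
#' blended with the error model as the mixture
#' `(1 - e) * P_core + e * P_HWE(offspring)`, where `e` is the mistype rate:
#' an erroneous scoring looks like a random population genotype, which keeps
#' likelihood ratios finite for `e > 0` even at a Mendelian exclusion.
#'
#' @param offspring,mother,father length-2 integer allele vectors (unordered
#'   genotypes); `father = NULL` for the background hypothesis.
#' @param freqs an [allele_frequencies()] table.
#' @param locus locus id (to pick the frequency vector).
#' @param error an [error_model()].
#' @return a probability.
#' @examples
#' # mother A/A, father B/B must yield A/B:
#' # transition_prob(c(1,2), c(1,1), c(2,2), freqs, "L1", error_model(0, 1))
#' @export
transition_prob <- function(offspring, mother, father = NULL, freqs, locus,
                            error = error_model()) {
  stopifnot(length(offspring) == 2L, length(mother) == 2L)
  e <- error$mistype_rate
  ox <- offspring[1L]; oy <- offspring[2L]
  fx <- allele_freq(freqs, locus, ox); fy <- allele_freq(freqs, locus, oy)
  het <- ox != oy
  pmx <- .transmit(ox, mother[1L], mother[2L])
  pmy <- .transmit(oy, mother[1L], mother[2L])
  if (is.null(father)) {
    core <- if (het) pmx * fy + pmy * fx else pmx * fx
  } else {
    stopifnot(length(father) == 2L)
    pfx <- .transmit(ox, father[1L], father[2L])
    pfy <- .transmit(oy, father[1L], father[2L])
    core <- if (het) pmx * pfy + pmy * pfx else pmx * pfx
  }
  (1 - e) * core + e * .hwe_geno(fx, fy, het)
}

# Vectorised per-locus likelihood machinery.
#
# o1, o2, m1, m2: offspring / mother alleles, vectors of length P (NA when
# untyped). C1, C2: candidate alleles as P x C matrices (a C-vector is
# recycled across progeny). Returns log-ratio, mismatch and typed matrices
# plus the pure (error-free) maternal compatibility of each progeny.
.locus_lod <- function(o1, o2, m1, m2, C1, C2, f1, f2, e) {
  P <- length(o1)
  if (!is.matrix(C1)) { C1 <- matrix(C1, P, length(C1), byrow = TRUE)
                        C2 <- matrix(C2, P, length(C2), byrow = TRUE) }
  typed_p <- !is.na(o1) & !is.na(m1)
  typed <- typed_p & !is.na(C1)
  het <- !is.na(o1) & o1 != o2
  pmx <- 0.5 * (m1 == o1) + 0.5 * (m2 == o1)
  pmy <- 0.5 * (m1 == o2) + 0.5 * (m2 == o2)
  pfx <- 0.5 * (C1 == o1) + 0.5 * (C2 == o1)   # recycles o1 down columns
  pfy <- 0.5 * (C1 == o2) + 0.5 * (C2 == o2)
  mend <- pmx * pfx                            # homozygous-offspring form
  if (any(het)) {
    het_rows <- which(het)
    mend[het_rows, ] <- (pmx * pfy + pmy * pfx)[het_rows, , drop = FALSE]
  }
  denom_pure <- ifelse(het, pmx * f2 + pmy * f1, pmx * f1)
  hwe <- .hwe_geno(f1, f2, het)
  num <- (1 - e) * mend + e * hwe
  den <- (1 - e) * denom_pure + e * hwe
  ratio <- log(num) - log(den)            # -Inf at hard exclusion when e = 0
  ratio[is.nan(ratio)] <- -Inf            # 0/0: impossible under both hypotheses
  ratio[!typed] <- 0
  mism <- typed & mend == 0
  list(ratio = ratio, mismatch = mism, typed = typed,
       maternal_ok = !typed_p | denom_pure > 0)
}

# Full LOD matrix: offspring panel rows x candidate rows.
# cand_a1/cand_a2 are C x L matrices shared by all offspring.
.lod_matrix <- function(off_a1, off_a2, mo_a1, mo_a2, cand_a1, cand_a2,
                        loci, freqs, error) {
  P <- nrow(off_a1); C <- nrow(cand_a1); L <- length(loci)
  e <- error$mistype_rate
  lod <- matrix(0, P, C)
  mism <- matrix(0L, P, C)
  ntyped <- matrix(0L, P, C)
  maternal_bad <- integer(P)
  for (l in seq_len(L)) {
    f1 <- allele_freq(freqs, loci[l], off_a1[, l])
    f2 <- allele_freq(freqs, loci[l], off_a2[, l])
    r <- .locus_lod(off_a1[, l], off_a2[, l], mo_a1[, l], mo_a2[, l],
                    cand_a1[, l], cand_a2[, l], f1, f2, e)
    lod <- lod + r$ratio
    mism <- mism + r$mismatch
    ntyped <- ntyped + r$typed
    maternal_bad <- maternal_bad + !r$maternal_ok
  }
  list(lod = lod, mismatch = mism, n_typed = ntyped,
       maternal_ok = maternal_bad == 0L)
}

#' LOD score of one offspring / mother / candidate trio
#'
#' The LOD is the natural log of the overall likelihood ratio, summed over
#' the loci typed in all three individuals:
#' `sum ln[ P(off | mother, candidate) / P(off | mother) ]`, each factor
#' blended with the error model (see [transition_prob()]). With a zero
#' mistype rate a single Mendelian exclusion drives the LOD to `-Inf`.
#'
#' @param offspring,mother,candidate [line_genotype()] objects (or line
#'   ids with `panel` supplied).
#' @param freqs an [allele_frequencies()] table.
#' @param error an [error_model()].
#' @param min_typed_loci minimum loci typed in all three for the trio to be
#'   evaluable; default: every locus in the panel (the 8-of-8 rule).
#' @param panel optional [marker_panel()] to resolve character ids.
#' @return list with `lod`, `delta` placeholder `NA`, `n_typed`,
#'   `mismatches`, `evaluable`, `self` (candidate is the recorded mother)
#'   and a per-locus data.frame `detail`.
#' @export
lod_score <- function(offspring, mother, candidate, freqs,
                      error = error_model(), min_typed_loci = NULL,
                      panel = NULL) {
  if (is.character(offspring)) offspring <- line_genotype(panel, offspring)
  if (is.character(mother)) mother <- line_genotype(panel, mother)
  if (is.character(candidate)) candidate <- line_genotype(panel, candidate)
  loci <- names(offspring$a1)
  if (is.null(min_typed_loci)) min_typed_loci <- length(loci)
  r <- .lod_matrix(matrix(offspring$a1, 1L), matrix(offspring$a2, 1L),
                   matrix(mother$a1, 1L), matrix(mother$a2, 1L),
                   matrix(candidate$a1, 1L), matrix(candidate$a2, 1L),
                   loci, freqs, error)
  detail <- data.frame(locus_id = loci, stringsAsFactors = FALSE)
  detail$log_ratio <- vapply(seq_along(loci), function(l) {
    rr <- .locus_lod(offspring$a1[l], offspring$a2[l], mother$a1[l],
                     mother$a2[l], matrix(candidate$a1[l], 1L),
                     matrix(candidate$a2[l], 1L),
                     allele_freq(freqs, loci[l], offspring$a1[l]),
                     allele_freq(freqs, loci[l], offspring$a2[l]),
                     error$mistype_rate)
    rr$ratio[1L, 1L]
  }, numeric(1))
  evaluable <- r$n_typed[1L, 1L] >= min_typed_loci
  list(lod = if (evaluable) r$lod[1L, 1L] else NA_real_,
       n_typed = r$n_typed[1L, 1L],
       mismatches = r$mismatch[1L, 1L],
       evaluable = evaluable,
       self = identical(candidate$line_id, mother$line_id),
       maternal_ok = r$maternal_ok[1L],
       detail = detail)
}

# draw P x L HWE allele matrices from a frequency table
.draw_alleles <- function(P, freqs) {
  L <- length(freqs)
  a <- matrix(NA_integer_, P, L)
  for (l in seq_len(L)) {
    f <- freqs[[l]]
    a[, l] <- as.integer(sample(names(f), P, replace = TRUE, prob = f))
  }
  a
}

#' Simulate LOD confidence thresholds for paternity assignment
#'
#' Monte-Carlo calibration in the style of parentage-analysis software:
#' for each simulated progeny a mother and `n_candidates` candidate fathers
#' are drawn at Hardy-Weinberg proportions from `freqs`; the true father is
#' one of the candidates with probability `prop_sampled` (otherwise an
#' unsampled outsider); the offspring is generated by Mendelian segregation
#' and degraded by the error model. The best candidate's statistic (its LOD,
#' or the gap Delta to the runner-up) is recorded together with whether the
#' assignment is correct, and the thresholds returned are the smallest
#' values at which the proportion of correct assignments above threshold
#' reaches the strict (95%) and relaxed (80%) levels.
#'
#' @param freqs an [allele_frequencies()] table.
#' @param n_candidates number of candidate fathers per progeny.
#' @param n_progeny number of simulated progenies (default 10000).
#' @param prop_sampled probability the true father is among the candidates.
#' @param error an [error_model()].
#' @param strict_level,relaxed_level target assignment confidences.
#' @param seed integer seed (required: calibration must be reproducible).
#' @param statistic gate on the best candidate's `"lod"` (default; the
#'   thresholds the field reports, e.g. 5.35/5.28) or on `"delta"`.
#' @param min_typed_loci evaluability rule, default all loci.
#' @return an object of class `confidence_thresholds` with `strict_lod`,
#'   `relaxed_lod`, `statistic` and a `summary` list.
#' @export
simulate_confidence_thresholds <- function(freqs, n_candidates,
                                           n_progeny = 10000,
                                           prop_sampled = 1,
                                           error = error_model(),
                                           strict_level = 0.95,
                                           relaxed_level = 0.80,
                                           seed = 1L,
                                           statistic = c("lod", "delta"),
                                           min_typed_loci = NULL) {
  statistic <- match.arg(statistic)
  if (all(lengths(freqs) == 1L)) {
    stop("simulate_confidence_thresholds(): all loci monomorphic; thresholds undefined")
  }
  stopifnot(n_candidates >= 2, n_progeny >= 100)
  loci <- names(freqs)
  L <- length(loci)
  if (is.null(min_typed_loci)) min_typed_loci <- L
  set.seed(seed)
  P <- n_progeny; C <- n_candidates
  mo_a1 <- .draw_alleles(P, freqs); mo_a2 <- .draw_alleles(P, freqs)
  # candidate genotypes: fresh per progeny, stored per locus as P x C
  ca1 <- lapply(seq_len(L), function(l) NULL)
  ca2 <- ca1
  for (l in seq_len(L)) {
    f <- freqs[[l]]
    ca1[[l]] <- matrix(as.integer(sample(names(f), P * C, TRUE, f)), P, C)
    ca2[[l]] <- matrix(as.integer(sample(names(f), P * C, TRUE, f)), P, C)
  }
  sampled <- stats::runif(P) < prop_sampled
  true_idx <- sample.int(C, P, replace = TRUE)
  fa_a1 <- matrix(NA_integer_, P, L); fa_a2 <- fa_a1
  for (l in seq_len(L)) {
    fa_a1[, l] <- ca1[[l]][cbind(seq_len(P), true_idx)]
    fa_a2[, l] <- ca2[[l]][cbind(seq_len(P), true_idx)]
  }
  out1 <- .draw_alleles(P, freqs); out2 <- .draw_alleles(P, freqs)
  fa_a1[!sampled, ] <- out1[!sampled, ]; fa_a2[!sampled, ] <- out2[!sampled, ]
  pickm <- matrix(stats::runif(P * L) < 0.5, P, L)
  pickf <- matrix(stats::runif(P * L) < 0.5, P, L)
  off_a1 <- ifelse(pickm, mo_a1, mo_a2)
  off_a2 <- ifelse(pickf, fa_a1, fa_a2)
  swap <- off_a1 > off_a2
  tmp <- off_a1[swap]; off_a1[swap] <- off_a2[swap]; off_a2[swap] <- tmp
  # typing noise on the offspring
  untyped <- matrix(stats::runif(P * L) >= error$typed_rate, P, L)
  mistyped <- matrix(stats::runif(P * L) < error$mistype_rate, P, L) & !untyped
  if (any(mistyped)) {
    r1 <- .draw_alleles(P, freqs); r2 <- .draw_alleles(P, freqs)
    lo <- pmin(r1, r2); hi <- pmax(r1, r2)
    off_a1[mistyped] <- lo[mistyped]; off_a2[mistyped] <- hi[mistyped]
  }
  off_a1[untyped] <- NA_integer_; off_a2[untyped] <- NA_integer_
  # LOD over all candidates
  e <- error$mistype_rate
  lod <- matrix(0, P, C); mism <- matrix(0L, P, C); ntyped <- matrix(0L, P, C)
  for (l in seq_len(L)) {
    f1 <- allele_freq(freqs, loci[l], off_a1[, l])
    f2 <- allele_freq(freqs, loci[l], off_a2[, l])
    r <- .locus_lod(off_a1[, l], off_a2[, l], mo_a1[, l], mo_a2[, l],
                    ca1[[l]], ca2[[l]], f1, f2, e)
    lod <- lod + r$ratio
    mism <- mism + r$mismatch
    ntyped <- ntyped + r$typed
  }
  eligible <- mism == 0 & ntyped >= min_typed_loci
  lod_elig <- ifelse(eligible, lod, -Inf)
  best <- max.col(lod_elig, ties.method = "first")
  best_lod <- lod_elig[cbind(seq_len(P), best)]
  second <- apply(lod_elig, 1L, function(x) -sort(-x, partial = 2L)[2L])
  assigned <- is.finite(best_lod)
  stat <- if (statistic == "lod") best_lod else best_lod - pmax(second, -1e300)
  correct <- assigned & sampled & best == true_idx
  ok <- assigned
  if (!any(ok)) stop("simulate_confidence_thresholds(): no evaluable simulated assignment")
  calib <- function(level) .calibrate_threshold(stat[ok], correct[ok], level)
  relaxed <- calib(relaxed_level)
  strict <- max(calib(strict_level), relaxed)
  structure(list(strict_lod = strict, relaxed_lod = relaxed,
                 statistic = statistic,
                 summary = list(n_progeny = n_progeny,
                                n_candidates = n_candidates,
                                prop_sampled = prop_sampled,
                                typed_rate = error$typed_rate,
                                mistype_rate = error$mistype_rate,
                                seed = seed,
                                assignment_rate = mean(assigned),
                                success_rate = mean(correct))),
            class = "confidence_thresholds")
}

# smallest threshold t such that P(correct | stat > t) >= level, chosen to
# maximise the number of assignments; +Inf when no cutoff reaches the level
.calibrate_threshold <- function(stat, correct, level) {
  o <- order(stat, decreasing = TRUE)
  prec <- cumsum(correct[o]) / seq_along(o)
  feasible <- which(prec >= level)
  if (!length(feasible)) return(Inf)
  i <- max(feasible)
  stat[o][i] - 1e-9
}

#' @export
print.confidence_thresholds <- function(x, ...) {
  cat(sprintf("confidence_thresholds (%s): strict > %.3f, relaxed > %.3f\n",
              x$statistic, x$strict_lod, x$relaxed_lod))
  cat(sprintf("  simulated: %d progeny, %d candidates, sampled %.2f, typed %.3f, mistyped %.3f\n",
              x$summary$n_progeny, x$summary$n_candidates,
              x$summary$prop_sampled, x$summary$typed_rate,
              x$summary$mistype_rate))
  invisible(x)
}

#' Assign paternity to offspring with recorded mothers
#'
#' Ranks every candidate father by LOD against each offspring (mother known
#' from the maternal-parent row), then assigns the top candidate at strict
#' or relaxed confidence only if its gating statistic exceeds the simulated
#' threshold and it shows zero mismatching loci. Candidates with identical
#' multilocus genotypes can only be assigned as a group (e.g. `"28/281"`),
#' flagged ambiguous. Offspring whose recorded mother is Mendelian-
#' incompatible are reported with `maternal_ok = FALSE` and left unassigned,
#' never silently reassigned.
#'
#' @param offspring a [marker_panel()] (or subset) of offspring with
#'   `maternal_id` recorded; mothers must be present in `candidates`.
#' @param candidates a [marker_panel()] of candidate parents.
#' @param freqs an [allele_frequencies()] table.
#' @param thresholds a [simulate_confidence_thresholds()] result, or `NULL`
#'   to gate only on compatibility (both thresholds 0).
#' @param error an [error_model()].
#' @param min_typed_loci evaluability rule, default all loci.
#' @return a data.frame of class `paternity_assignments`, one row per
#'   offspring: `offspring_id`, `mother_id`, `assigned_father` (group label
#'   for ambiguous ties, `NA` when unassigned), `ambiguous`, `lod`, `delta`,
#'   `n_typed`, `mismatches`, `confidence`
#'   (`"strict"`/`"relaxed"`/`"unassigned"`), `maternal_ok`, `self`.
#' @export
assign_paternity <- function(offspring, candidates, freqs, thresholds = NULL,
                             error = error_model(), min_typed_loci = NULL) {
  off <- panel_subset(offspring, roles = "offspring")
  cand <- panel_subset(candidates, roles = "parent")
  loci <- off$loci$locus_id
  stopifnot(identical(loci, cand$loci$locus_id))
  if (is.null(min_typed_loci)) min_typed_loci <- length(loci)
  statistic <- if (is.null(thresholds)) "lod" else thresholds$statistic
  t_strict <- if (is.null(thresholds)) 0 else thresholds$strict_lod
  t_relax <- if (is.null(thresholds)) 0 else thresholds$relaxed_lod
  mo_idx <- match(off$lines$maternal_id, cand$lines$line_id)
  if (anyNA(mo_idx)) {
    bad <- off$lines$line_id[is.na(mo_idx)][1L]
    stop("assign_paternity(): offspring '", bad,
         "' has no recorded mother among the candidates")
  }
  r <- .lod_matrix(off$a1, off$a2,
                   cand$a1[mo_idx, , drop = FALSE],
                   cand$a2[mo_idx, , drop = FALSE],
                   cand$a1, cand$a2, loci, freqs, error)
  # identity groups among candidates: identical genotypes get equal LODs
  ident <- find_identical_lines(cand, roles = "parent")
  group_label <- setNames(cand$lines$line_id, cand$lines$line_id)
  group_index <- setNames(seq_len(n_lines(cand)), cand$lines$line_id)
  for (gi in seq_along(ident$groups)) {
    g <- ident$groups[[gi]]
    if (length(g) > 1L) group_label[g] <- paste(sort(g), collapse = "/")
    group_index[g] <- group_index[g[1L]]
  }
  P <- n_lines(off)
  out <- data.frame(offspring_id = off$lines$line_id,
                    mother_id = off$lines$maternal_id,
                    assigned_father = NA_character_,
                    ambiguous = FALSE,
                    lod = NA_real_, delta = NA_real_,
                    n_typed = NA_integer_, mismatches = NA_integer_,
                    confidence = "unassigned",
                    maternal_ok = r$maternal_ok,
                    self = FALSE, stringsAsFactors = FALSE)
  for (i in seq_len(P)) {
    elig <- r$mismatch[i, ] == 0L & r$n_typed[i, ] >= min_typed_loci
    if (!any(elig) || !r$maternal_ok[i]) next
    lods <- ifelse(elig, r$lod[i, ], -Inf)
    best <- which.max(lods)
    top <- lods[best]
    if (!is.finite(top)) next
    tied <- which(abs(lods - top) < 1e-9)
    tied_groups <- unique(group_index[tied])
    ambiguous <- length(tied) > 1L
    if (ambiguous && length(tied_groups) > 1L) next   # tie across distinct genotypes
    label <- group_label[cand$lines$line_id[best]]
    other <- r$lod[i, ][group_index != group_index[best]]
    delta <- if (length(other)) top - max(other) else Inf
    stat <- if (statistic == "lod") top else delta
    conf <- if (stat > t_strict) "strict" else if (stat > t_relax) "relaxed" else "unassigned"
    out$assigned_father[i] <- if (conf == "unassigned") NA_character_ else label
    out$ambiguous[i] <- ambiguous
    out$lod[i] <- top
    out$delta[i] <- delta
    out$n_typed[i] <- r$n_typed[i, best]
    out$mismatches[i] <- r$mismatch[i, best]
    out$confidence[i] <- conf
    out$self[i] <- cand$lines$line_id[best] == off$lines$maternal_id[i]
  }
  class(out) <- c("paternity_assignments", "data.frame")
  out
}

#' Reciprocal and duplicate structure of selected hybrids
#'
#' Groups parent pairs of assigned selections by unordered combination
#' `{mother, father}` and reports how many distinct combinations occur, how
#' many were selected in both orientations (true reciprocals), and the
#' multiplicity of each combination — the signatures used to argue that
#' single-plant phenotypic selection is repeatable.
#'
#' @param assignments a `paternity_assignments` data.frame (rows without an
#'   assigned father are dropped), or any data.frame with `mother_id` and
#'   `father_id` columns.
#' @return list with `n_selections`, `n_combinations`,
#'   `n_reciprocal_pairs`, `reciprocal_pairs` (data.frame of pairs seen in
#'   both orientations) and `combinations` (per-combination multiplicity).
#' @export
detect_reciprocals <- function(assignments) {
  df <- as.data.frame(assignments)
  father <- if ("father_id" %in% names(df)) df$father_id else df$assigned_father
  keep <- !is.na(father)
  mo <- as.character(df$mother_id[keep]); fa <- as.character(father[keep])
  lo <- pmin(mo, fa); hi <- pmax(mo, fa)
  key <- paste(lo, hi, sep = "\r")
  combos <- data.frame(parent_a = lo, parent_b = hi, stringsAsFactors = FALSE)
  agg <- stats::aggregate(list(multiplicity = rep(1L, length(key))),
                          by = list(key = key), FUN = sum)
  # orientation counts per unordered pair
  orient <- tapply(mo, key, function(x) length(unique(x)))
  recip_keys <- names(orient)[orient > 1L & !vapply(strsplit(names(orient), "\r"),
                                                    function(p) p[1L] == p[2L], logical(1))]
  split_key <- function(k) do.call(rbind, strsplit(k, "\r", fixed = TRUE))
  recip <- if (length(recip_keys)) {
    m <- split_key(recip_keys)
    data.frame(parent_a = m[, 1L], parent_b = m[, 2L], stringsAsFactors = FALSE)
  } else {
    data.frame(parent_a = character(0), parent_b = character(0),
               stringsAsFactors = FALSE)
  }
  mm <- split_key(agg$key)
  combinations <- data.frame(parent_a = mm[, 1L], parent_b = mm[, 2L],
                             multiplicity = agg$multiplicity,
                             stringsAsFactors = FALSE)
  list(n_selections = sum(keep),
       n_combinations = nrow(agg),
       n_reciprocal_pairs = nrow(recip),
       reciprocal_pairs = recip,
       combinations = combinations[order(-combinations$multiplicity), ])
}
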