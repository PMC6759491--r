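#' Configuration of an end-to-end breeding simulation
#'
#' Describes the world the simulator emulates: a group of fully homozygous
#' DH lines, inter-pollinated uniformly at random (every line's pollen
#' equally likely on every mother, self included unless the species'
#' self-incompatibility is switched on), offspring genotyped with a small
#' typing/mistyping error, and single-plant phenotypic selection driven by
#' additive parental effects (GCA) plus a pair-specific deviation (SCA) and
#' environmental noise.
#'
#' Defaults mirror the cabbage cage-pollination experiment: 36 lines, 8 SSR
#' loci carrying 29 alleles in total (2-5 per locus, mean 3.625), 139
#' offspring per maternal row (~5000 plants), typed rate 0.998, mistype
#' rate 0.002, and a 2.5% selected fraction.
#'
#' @param n_lines number of DH lines inter-pollinated.
#' @param n_loci number of SSR loci.
#' @param alleles_per_locus integer vector (recycled) of allele counts.
#' @param k_per_mother F1 offspring per maternal row.
#' @param m required number of distinct paternal lines per row (used by the
#'   recovery report; default `n_lines - 1`, i.e. full representation).
#' @param self_incompatible forbid self-pollination draws.
#' @param typed_rate,mistype_rate genotyping error rates, see
#'   [error_model()].
#' @param selection_fraction fraction of all F1 plants selected as elite.
#' @param gca_sd,sca_sd,env_sd standard deviations of the additive line
#'   effects, the pair deviation, and the environmental noise (phenotype
#'   units; defaults 1, 0.5, 1 give a repeatable but noisy single-plant
#'   selection).
#' @param seed integer seed for the whole run.
#' @return an object of class `simulation_config`.
#' @export
simulation_config <- function(n_lines = 36L, n_loci = 8L,
                              alleles_per_locus = c(4L, 5L, 3L, 5L, 5L, 2L, 3L, 2L),
                              k_per_mother = 139L, m = n_lines - 1L,
                              self_incompatible = FALSE,
                              typed_rate = 0.998, mistype_rate = 0.002,
                              selection_fraction = 0.025,
                              gca_sd = 1, sca_sd = 0.5, env_sd = 1,
                              seed = 1L) {
  stopifnot(n_lines >= 2, k_per_mother >= 0, n_loci >= 1,
            typed_rate >= 0, typed_rate <= 1,
            mistype_rate >= 0, mistype_rate <= 1,
            selection_fraction > 0, selection_fraction <= 1,
            m >= 0, m <= n_lines - 1)
  structure(list(n_lines = as.integer(n_lines), n_loci = as.integer(n_loci),
                 alleles_per_locus = rep_len(as.integer(alleles_per_locus), n_loci),
                 k_per_mother = as.integer(k_per_mother), m = as.integer(m),
                 self_incompatible = isTRUE(self_incompatible),
                 typed_rate = typed_rate, mistype_rate = mistype_rate,
                 selection_fraction = selection_fraction,
                 gca_sd = gca_sd, sca_sd = sca_sd, env_sd = env_sd,
                 seed = as.integer(seed)),
            class = "simulation_config")
}

# deterministic sub-stage seeds: one RNG stream per run, each stage offset
# from the config seed so stages can be reproduced in isolation
.stage_seed <- function(seed, stage) {
  (as.integer(seed) + 1000L * stage) %% .Machine$integer.max
}

#' Simulate a panel of homozygous DH lines
#'
#' Every line is homozygous at every locus (both allele copies equal), the
#' defining property of a doubled haploid. Allele labels are fragment
#' lengths: locus `l` uses lengths `140 + 10*l + 3*(0:(A_l - 1))`. By
#' default panels are redrawn until all multilocus genotypes are distinct
#' (the situation the marker panel was chosen to achieve).
#'
#' @param n_lines number of lines.
#' @param loci_spec list with `n_loci`, `alleles_per_locus` and optionally
#'   `freqs` (list of per-locus allele frequency vectors; default uniform).
#' @param seed integer seed.
#' @param require_distinct redraw until all genotypes are distinct.
#' @param max_tries bounded retries before giving up.
#' @return a [marker_panel()] of `parent` lines named `"L01"`, `"L02"`, ...
#' @export
simulate_dh_panel <- function(n_lines, loci_spec = list(), seed = 1L,
                              require_distinct = TRUE, max_tries = 1000L) {
  n_loci <- loci_spec$n_loci %||% 8L
  apl <- rep_len(loci_spec$alleles_per_locus %||% c(4L, 5L, 3L, 5L, 5L, 2L, 3L, 2L),
                 n_loci)
  stopifnot(all(apl >= 1L))
  set.seed(seed)
  locus_ids <- sprintf("SSR%02d", seq_len(n_loci))
  allele_sets <- lapply(seq_len(n_loci), function(l) 140L + 10L * l + 3L * (0:(apl[l] - 1L)))
  freqs <- loci_spec$freqs %||% lapply(apl, function(a) rep(1 / a, a))
  for (try in seq_len(max_tries)) {
    a <- vapply(seq_len(n_loci), function(l) {
      allele_sets[[l]][sample.int(apl[l], n_lines, replace = TRUE,
                                  prob = freqs[[l]])]
    }, integer(n_lines))
    if (n_lines == 1L) a <- matrix(a, nrow = 1L)
    if (!require_distinct || !anyDuplicated(apply(a, 1L, paste, collapse = "|"))) {
      lines <- data.frame(line_id = sprintf("L%02d", seq_len(n_lines)),
                          role = "parent", maternal_id = NA_character_,
                          stringsAsFactors = FALSE)
      return(marker_panel(locus_ids, lines, a, a))
    }
  }
  stop("simulate_dh_panel(): could not draw ", n_lines,
       " distinct genotypes in ", max_tries, " tries (too few alleles)")
}

#' Random inter-pollination of a DH panel
#'
#' For each mother, `k_per_mother` offspring are generated; the father of
#' each is drawn uniformly from all lines (including the mother herself
#' unless `self_incompatible`), matching the uniform-pollination assumption
#' of the design mathematics. Each offspring locus receives one random
#' maternal and one random paternal allele. True parentage is returned as
#' ground truth.
#'
#' @param panel a parent [marker_panel()].
#' @param k_per_mother offspring per maternal row.
#' @param self_incompatible exclude the mother's own pollen.
#' @param seed integer seed.
#' @return list with `offspring` (a [marker_panel()] of offspring, maternal
#'   ids recorded) and `truth` (data.frame `offspring_id`, `mother_id`,
#'   `father_id`).
#' @export
simulate_interpollination <- function(panel, k_per_mother,
                                      self_incompatible = FALSE, seed = 1L) {
  stopifnot(inherits(panel, "marker_panel"), k_per_mother >= 0)
  set.seed(seed)
  n <- n_lines(panel); L <- n_loci(panel)
  ids <- panel$lines$line_id
  k <- as.integer(k_per_mother)
  P <- n * k
  mother_idx <- rep(seq_len(n), each = k)
  father_idx <- integer(P)
  if (self_incompatible && n < 2L) stop("self-incompatible pollination needs >= 2 lines")
  if (P > 0L) {
    father_idx <- sample.int(n, P, replace = TRUE)
    if (self_incompatible) {
      redo <- which(father_idx == mother_idx)
      while (length(redo)) {
        father_idx[redo] <- sample.int(n, length(redo), replace = TRUE)
        redo <- redo[father_idx[redo] == mother_idx[redo]]
      }
    }
  }
  pickm <- matrix(stats::runif(P * L) < 0.5, P, L)
  pickf <- matrix(stats::runif(P * L) < 0.5, P, L)
  ma <- ifelse(pickm, panel$a1[mother_idx, , drop = FALSE],
               panel$a2[mother_idx, , drop = FALSE])
  fa <- ifelse(pickf, panel$a1[father_idx, , drop = FALSE],
               panel$a2[father_idx, , drop = FALSE])
  a1 <- pmin(ma, fa); a2 <- pmax(ma, fa)
  off_ids <- sprintf("%s_F1_%04d", ids[mother_idx],
                     stats::ave(seq_len(P), mother_idx, FUN = seq_along))
  lines <- data.frame(line_id = off_ids, role = "offspring",
                      maternal_id = ids[mother_idx], stringsAsFactors = FALSE)
  off <- marker_panel(panel$loci, lines, a1, a2)
  truth <- data.frame(offspring_id = off_ids, mother_id = ids[mother_idx],
                      father_id = ids[father_idx], stringsAsFactors = FALSE)
  list(offspring = off, truth = truth)
}

#' Degrade offspring genotypes with typing noise
#'
#' Each offspring-locus is independently left untyped with probability
#' `1 - typed_rate`; each remaining scored locus is replaced by a random
#' Hardy-Weinberg genotype (drawn from `freqs`) with probability
#' `mistype_rate`.
#'
#' @param offspring an offspring [marker_panel()].
#' @param typed_rate,mistype_rate rates as in [error_model()].
#' @param freqs an [allele_frequencies()] table supplying the replacement
#'   genotype distribution.
#' @param seed integer seed.
#' @return the degraded [marker_panel()].
#' @export
apply_typing_noise <- function(offspring, typed_rate, mistype_rate, freqs,
                               seed = 1L) {
  stopifnot(inherits(offspring, "marker_panel"),
            typed_rate >= 0, typed_rate <= 1,
            mistype_rate >= 0, mistype_rate <= 1)
  if (typed_rate == 1 && mistype_rate == 0) return(offspring)
  set.seed(seed)
  P <- n_lines(offspring); L <- n_loci(offspring)
  a1 <- offspring$a1; a2 <- offspring$a2
  untyped <- matrix(stats::runif(P * L) >= typed_rate, P, L)
  mistyped <- matrix(stats::runif(P * L) < mistype_rate, P, L) & !untyped
  if (any(mistyped)) {
    r1 <- .draw_alleles(P, freqs); r2 <- .draw_alleles(P, freqs)
    lo <- pmin(r1, r2); hi <- pmax(r1, r2)
    a1[mistyped] <- lo[mistyped]; a2[mistyped] <- hi[mistyped]
  }
  a1[untyped] <- NA_integer_; a2[untyped] <- NA_integer_
  marker_panel(offspring$loci, offspring$lines, a1, a2)
}

#' Phenotype the F1 field and select elite individuals
#'
#' Phenotype of an offspring of mother i and father j:
#' `g_i + g_j + s_ij + e`, with additive line effects `g ~ N(0, gca_sd^2)`,
#' a symmetric pair deviation `s_ij = s_ji ~ N(0, sca_sd^2)` and plant-level
#' noise `e ~ N(0, env_sd^2)`. The top `selection_fraction` of the whole
#' field is selected — single-plant selection, exactly as practised in the
#' scheme. The trait model is a synthetic stand-in: it is the simplest model
#' producing the qualitative signatures of interest (repeated selection of
#' the same parent pair, reciprocal selections), not an inference about any
#' real trait.
#'
#' @param truth the truth data.frame from [simulate_interpollination()].
#' @param config a [simulation_config()] (supplies effect SDs and the
#'   selection fraction).
#' @param seed integer seed.
#' @return `truth` rows of the selected plants, with a `phenotype` column,
#'   ordered best first.
#' @export
simulate_phenotypes_and_select <- function(truth, config, seed = 1L) {
  stopifnot(config$selection_fraction > 0, config$selection_fraction <= 1)
  set.seed(seed)
  ids <- sort(unique(c(truth$mother_id, truth$father_id)))
  g <- stats::setNames(stats::rnorm(length(ids), 0, config$gca_sd), ids)
  lo <- pmin(truth$mother_id, truth$father_id)
  hi <- pmax(truth$mother_id, truth$father_id)
  pair_key <- paste(lo, hi, sep = "\r")
  upairs <- unique(pair_key)
  s <- stats::setNames(stats::rnorm(length(upairs), 0, config$sca_sd), upairs)
  pheno <- g[truth$mother_id] + g[truth$father_id] + s[pair_key] +
    stats::rnorm(nrow(truth), 0, config$env_sd)
  n_sel <- max(1L, round(config$selection_fraction * nrow(truth)))
  ord <- order(pheno, decreasing = TRUE)
  sel <- truth[ord[seq_len(n_sel)], , drop = FALSE]
  sel$phenotype <- unname(pheno[ord[seq_len(n_sel)]])
  rownames(sel) <- NULL
  sel
}

#' Distinct-father counts for replicate maternal rows
#'
#' Draws `k` uniform father draws for each of `n_mothers` replicate rows
#' and counts the distinct non-maternal lines — the empirical side of the
#' `Q(n, k, m)` prediction, without genotypes.
#'
#' @param n number of lines.
#' @param k draws (offspring) per row.
#' @param n_mothers replicate rows.
#' @param self_incompatible exclude the maternal line from the draws.
#' @param seed integer seed.
#' @return integer vector of length `n_mothers`.
#' @export
simulate_father_counts <- function(n, k, n_mothers, self_incompatible = FALSE,
                                   seed = 1L) {
  set.seed(seed)
  counts <- integer(n_mothers)
  mother <- rep_len(seq_len(n), n_mothers)
  for (i in seq_len(n_mothers)) {
    draws <- sample.int(n, k, replace = TRUE)
    if (self_incompatible) {
      redo <- which(draws == mother[i])
      while (length(redo)) {
        draws[redo] <- sample.int(n, length(redo), replace = TRUE)
        redo <- redo[draws[redo] == mother[i]]
      }
    }
    counts[i] <- length(setdiff(unique(draws), mother[i]))
  }
  counts
}

#' End-to-end recovery experiment
#'
#' Runs the full scheme on synthetic data — DH panel, random
#' inter-pollination, typing noise, threshold simulation, paternity
#' assignment, phenotypic selection — and checks the simulator against the
#' closed-form design mathematics: the empirical fraction of maternal rows
#' with at least `m` distinct fathers is compared with `Q(n, k, m)` via an
#' exact binomial 99% confidence check (self-pollination must be allowed
#' for this comparison, as in the model's derivation).
#'
#' @param config a [simulation_config()].
#' @param n_father_replicates replicate maternal rows for the Q comparison
#'   (default enough to reach 2000 rows).
#' @param n_threshold_progeny progenies for threshold calibration.
#' @return an object of class `recovery_report`: see its printed summary.
#'   Fields include `father_counts`, `empirical_fraction`, `q_predicted`
#'   (exact and rounded), `binomial_ci99`, `within_ci`,
#'   `assignment` (accuracy, ambiguous and unassigned fractions),
#'   `selection` and `reciprocals`.
#' @export
recovery_experiment <- function(config,
                                n_father_replicates = max(2000L, config$n_lines),
                                n_threshold_progeny = 2000L) {
  stopifnot(inherits(config, "simulation_config"))
  n <- config$n_lines; k <- config$k_per_mother; m <- config$m
  panel <- simulate_dh_panel(n,
                             list(n_loci = config$n_loci,
                                  alleles_per_locus = config$alleles_per_locus),
                             seed = .stage_seed(config$seed, 1L))
  pol <- simulate_interpollination(panel, k,
                                   self_incompatible = config$self_incompatible,
                                   seed = .stage_seed(config$seed, 2L))
  freqs <- allele_frequencies(panel)
  err <- error_model(config$mistype_rate, config$typed_rate)
  noisy <- apply_typing_noise(pol$offspring, config$typed_rate,
                              config$mistype_rate, freqs,
                              seed = .stage_seed(config$seed, 3L))
  # empirical Q: replicate father draws (cheap, no genotypes needed)
  counts <- simulate_father_counts(n, k, n_father_replicates,
                                   self_incompatible = config$self_incompatible,
                                   seed = .stage_seed(config$seed, 4L))
  emp <- mean(counts >= m)
  qp <- q_probability(design_params(n, k, m))
  ci <- c(stats::qbinom(0.005, n_father_replicates, qp$value),
          stats::qbinom(0.995, n_father_replicates, qp$value)) / n_father_replicates
  within <- !config$self_incompatible && emp >= ci[1L] && emp <= ci[2L]
  # paternity assignment against truth
  thr <- simulate_confidence_thresholds(freqs, n_candidates = n,
                                        n_progeny = n_threshold_progeny,
                                        prop_sampled = 1, error = err,
                                        seed = .stage_seed(config$seed, 5L))
  asg <- assign_paternity(noisy, panel, freqs, thresholds = thr, error = err)
  assigned <- !is.na(asg$assigned_father)
  hit <- assigned & mapply(function(lab, truth_f) {
    truth_f %in% strsplit(lab, "/", fixed = TRUE)[[1L]]
  }, asg$assigned_father, pol$truth$father_id)
  accuracy <- if (any(assigned)) mean(hit[assigned]) else NA_real_
  sel <- simulate_phenotypes_and_select(pol$truth, config,
                                        seed = .stage_seed(config$seed, 6L))
  rec <- detect_reciprocals(data.frame(mother_id = sel$mother_id,
                                       father_id = sel$father_id))
  structure(list(config = config,
                 father_counts = counts,
                 empirical_fraction = emp,
                 q_predicted = qp,
                 binomial_ci99 = ci,
                 within_ci = within,
                 thresholds = thr,
                 assignment = list(accuracy = accuracy,
                                   assigned_fraction = mean(assigned),
                                   ambiguous_fraction = mean(asg$ambiguous),
                                   unassigned_fraction = mean(!assigned)),
                 selection = sel,
                 reciprocals = rec),
            class = "recovery_report")
}

#' @export
print.recovery_report <- function(x, ...) {
  cfg <- x$config
  cat(sprintf("recovery_report: n = %d lines, k = %d per row, m = %d (self %s)\n",
              cfg$n_lines, cfg$k_per_mother, cfg$m,
              if (cfg$self_incompatible) "excluded" else "allowed"))
  cat(sprintf("  empirical P(>= m fathers) = %.4f vs Q = %.3f  [99%% CI %.4f..%.4f, %s]\n",
              x$empirical_fraction, x$q_predicted$rounded,
              x$binomial_ci99[1L], x$binomial_ci99[2L],
              if (isTRUE(x$within_ci)) "inside" else "outside/skipped"))
  cat(sprintf("  assignment: %.1f%% assigned, accuracy %.3f, ambiguous %.3f\n",
              100 * x$assignment$assigned_fraction, x$assignment$accuracy,
              x$assignment$ambiguous_fraction))
  cat(sprintf("  selection: %d elites, %d distinct combinations, %d reciprocal pairs\n",
              nrow(x$selection), x$reciprocals$n_combinations,
              x$reciprocals$n_reciprocal_pairs))
  invisible(x)
}

`%||%` <- function(a, b) if (is.null(a)) b else a
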