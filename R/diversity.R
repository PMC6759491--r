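#' Per-locus allele frequencies from a panel
#'
#' Frequencies are plain allele-copy proportions among typed genotypes
#' (each typed line contributes two copies). The default base population is
#' the candidate-parent set — the DH line database the paternity engine
#' compares against; offspring can be included by widening `from_roles`.
#'
#' @param panel a [marker_panel()].
#' @param from_roles roles contributing copies (default `"parent"`).
#' @return an `allele_freq_table`: a named list, one element per locus, each
#'   a named numeric vector of frequencies summing to 1. The attribute
#'   `n_individuals` records the number of lines in the base population
#'   (used for the novel-allele floor frequency downstream).
#' @export
allele_frequencies <- function(panel, from_roles = "parent") {
  sub <- panel_subset(panel, roles = from_roles)
  if (n_lines(sub) == 0L) stop("allele_frequencies(): no lines in the requested roles")
  freqs <- vector("list", n_loci(sub))
  names(freqs) <- sub$loci$locus_id
  for (j in seq_len(n_loci(sub))) {
    copies <- c(sub$a1[, j], sub$a2[, j])
    copies <- copies[!is.na(copies)]
    if (length(copies) == 0L) {
      stop("allele_frequencies(): locus with zero typed genotypes: ",
           sub$loci$locus_id[j])
    }
    tab <- table(copies)
    freqs[[j]] <- as.numeric(tab) / length(copies)
    names(freqs[[j]]) <- names(tab)
  }
  structure(freqs, class = "allele_freq_table", n_individuals = n_lines(sub))
}

#' @export
print.allele_freq_table <- function(x, ...) {
  cat(sprintf("allele_freq_table: %d loci, %d alleles total (base population: %d lines)\n",
              length(x), sum(lengths(x)), attr(x, "n_individuals")))
  invisible(x)
}

#' Frequency of an allele, with a floor for novel alleles
#'
#' Alleles seen in the offspring but absent from the base population get
#' the floor `1/(2N + 1)` (N = base-population size) so likelihoods stay
#' finite while still penalising them.
#' @param freqs an `allele_freq_table`.
#' @param locus locus id.
#' @param allele integer allele label(s).
#' @return numeric frequency vector.
#' @export
allele_freq <- function(freqs, locus, allele) {
  f <- freqs[[locus]]
  out <- unname(f[as.character(allele)])
  floorf <- 1 / (2 * attr(freqs, "n_individuals") + 1)
  out[is.na(out)] <- floorf
  out
}

# power sum a_r = sum_i p_i^r of one locus' frequencies
.power_sum <- function(p, r) sum(p^r)

#' Marker informativeness statistics per locus
#'
#' For each locus: the number of alleles, observed heterozygosity `Ho`
#' (fraction of typed lines with two different alleles), Nei gene diversity
#' `He = 1 - sum p_i^2`, polymorphic information content
#' `PIC = 1 - sum p_i^2 - (sum_i<j 2 p_i^2 p_j^2)`, and `NE_1P`, the average
#' non-exclusion probability of a random candidate parent when the other
#' parent's genotype is known. `NE_1P` uses the exact closed form in power
#' sums `a_r = sum p_i^r`,
#' `NE = 2 a2 - a3 - 2 a4 + 3 a5 + 2 a2^2 - 3 a2 a3`,
#' which equals the full enumeration over mother/father/offspring/candidate
#' genotypes at Hardy-Weinberg proportions (the package tests verify this
#' against a brute-force enumerator).
#'
#' @param panel a [marker_panel()]; `Ho` is computed on `roles`.
#' @param freqs an [allele_frequencies()] table.
#' @param roles lines whose observed heterozygosity is reported.
#' @return a data.frame with one row per locus and columns `locus_id`,
#'   `n_alleles`, `Ho`, `He`, `PIC`, `NE_1P`; the attribute
#'   `combined_NE_1P` is the across-loci product.
#' @export
diversity_stats <- function(panel, freqs, roles = "parent") {
  sub <- panel_subset(panel, roles = roles)
  out <- data.frame(locus_id = sub$loci$locus_id,
                    n_alleles = NA_integer_, Ho = NA_real_, He = NA_real_,
                    PIC = NA_real_, NE_1P = NA_real_,
                    stringsAsFactors = FALSE)
  for (j in seq_len(n_loci(sub))) {
    locus <- sub$loci$locus_id[j]
    p <- unname(freqs[[locus]])
    typed <- !is.na(sub$a1[, j])
    het <- sub$a1[typed, j] != sub$a2[typed, j]
    a2 <- .power_sum(p, 2); a3 <- .power_sum(p, 3)
    a4 <- .power_sum(p, 4); a5 <- .power_sum(p, 5)
    out$n_alleles[j] <- length(p)
    out$Ho[j] <- if (any(typed)) mean(het) else NA_real_
    out$He[j] <- 1 - a2
    out$PIC[j] <- 1 - a2 - (a2^2 - a4)   # sum_{i<j} 2 p_i^2 p_j^2 = a2^2 - a4
    out$NE_1P[j] <- 2 * a2 - a3 - 2 * a4 + 3 * a5 + 2 * a2^2 - 3 * a2 * a3
  }
  attr(out, "combined_NE_1P") <- prod(out$NE_1P)
  out
}
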