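#' Multilocus SSR genotype panel
#'
#' Container for codominant marker genotypes of named lines. Alleles are
#' integer fragment lengths (base pairs); each line is either a candidate
#' `parent` (typically a fully homozygous DH line) or an `offspring` with a
#' recorded maternal line. Genotypes are unordered pairs: the two alleles at
#' a locus are stored sorted, and a locus is either fully typed (two
#' alleles) or missing (both `NA`).
#'
#' @param loci character vector of locus ids (or a data.frame with a
#'   `locus_id` column plus metadata such as the repeat motif).
#' @param lines data.frame with columns `line_id`, `role`
#'   (`"parent"`/`"offspring"`) and `maternal_id` (`NA` for parents).
#' @param a1,a2 integer matrices, one row per line and one column per locus;
#'   `NA` pairs mark untyped loci.
#' @return an object of class `marker_panel`.
#' @export
marker_panel <- function(loci, lines, a1, a2) {
  if (!is.data.frame(loci)) loci <- data.frame(locus_id = as.character(loci))
  stopifnot(is.data.frame(lines),
            all(c("line_id", "role", "maternal_id") %in% names(lines)))
  a1 <- as.matrix(a1); a2 <- as.matrix(a2)
  storage.mode(a1) <- "integer"; storage.mode(a2) <- "integer"
  if (anyDuplicated(lines$line_id)) {
    dup <- lines$line_id[duplicated(lines$line_id)][1L]
    stop("marker_panel(): duplicate line_id '", dup, "'")
  }
  if (!all(lines$role %in% c("parent", "offspring"))) {
    stop("marker_panel(): role must be 'parent' or 'offspring'")
  }
  if (nrow(a1) != nrow(lines) || ncol(a1) != nrow(loci) ||
      !identical(dim(a1), dim(a2))) {
    stop("marker_panel(): allele matrices must be lines x loci")
  }
  if (any(is.na(a1) != is.na(a2))) {
    stop("marker_panel(): a locus must be fully typed or fully missing")
  }
  swap <- which(!is.na(a1) & a1 > a2)
  if (length(swap)) {                      # store unordered pairs sorted
    tmp <- a1[swap]; a1[swap] <- a2[swap]; a2[swap] <- tmp
  }
  dimnames(a1) <- dimnames(a2) <- list(lines$line_id, loci$locus_id)
  structure(list(loci = loci, lines = lines, a1 = a1, a2 = a2),
            class = "marker_panel")
}

#' @export
print.marker_panel <- function(x, ...) {
  cat(sprintf("marker_panel: %d lines (%d parents, %d offspring) x %d loci\n",
              nrow(x$lines), sum(x$lines$role == "parent"),
              sum(x$lines$role == "offspring"), nrow(x$loci)))
  invisible(x)
}

#' Number of lines / loci in a panel
#' @param panel a [marker_panel()].
#' @return integer count.
#' @export
n_lines <- function(panel) nrow(panel$lines)

#' @rdname n_lines
#' @export
n_loci <- function(panel) nrow(panel$loci)

#' Subset a panel by line ids or roles
#' @param panel a [marker_panel()].
#' @param line_ids character vector of ids to keep, or `NULL`.
#' @param roles roles to keep, or `NULL`.
#' @return a [marker_panel()].
#' @export
panel_subset <- function(panel, line_ids = NULL, roles = NULL) {
  keep <- rep(TRUE, n_lines(panel))
  if (!is.null(line_ids)) keep <- keep & panel$lines$line_id %in% line_ids
  if (!is.null(roles)) keep <- keep & panel$lines$role %in% roles
  marker_panel(panel$loci, panel$lines[keep, , drop = FALSE],
               panel$a1[keep, , drop = FALSE], panel$a2[keep, , drop = FALSE])
}

#' Read a genotype panel from CSV
#'
#' Expected columns: `line_id`, `role`, `maternal_id`, then two columns per
#' locus named `<locus>.a1` and `<locus>.a2`. Missing alleles are encoded as
#' `missing_code` (default 0, the common parentage-software convention) or
#' left empty.
#'
#' @param source path or connection readable by [utils::read.csv()].
#' @param missing_code value standing for an untyped allele (default 0).
#' @return a [marker_panel()].
#' @export
read_genotypes <- function(source, missing_code = 0L) {
  df <- utils::read.csv(source, stringsAsFactors = FALSE,
                        check.names = FALSE)
  need <- c("line_id", "role", "maternal_id")
  if (!all(need %in% names(df))) {
    stop("read_genotypes(): missing required column(s): ",
         paste(setdiff(need, names(df)), collapse = ", "))
  }
  allele_cols <- setdiff(names(df), need)
  a1_cols <- grep("\\.a1$", allele_cols, value = TRUE)
  a2_cols <- grep("\\.a2$", allele_cols, value = TRUE)
  loci1 <- sub("\\.a1$", "", a1_cols); loci2 <- sub("\\.a2$", "", a2_cols)
  if (!setequal(loci1, loci2) || length(allele_cols) != 2L * length(loci1)) {
    stop("read_genotypes(): allele columns must come in <locus>.a1/<locus>.a2 pairs")
  }
  loci <- loci1
  get_col <- function(col) {
    v <- df[[col]]
    v[v %in% c("", NA)] <- NA
    v <- suppressWarnings(as.numeric(v))
    if (anyNA(v) && any(df[[col]] != "" & !is.na(df[[col]]) & is.na(v))) {
      bad <- which(is.na(v) & !is.na(df[[col]]) & df[[col]] != "")[1L]
      stop(sprintf("read_genotypes(): non-integer allele '%s' at row %d, column %s",
                   df[[col]][bad], bad, col))
    }
    if (any(!is.na(v) & v != floor(v))) {
      bad <- which(!is.na(v) & v != floor(v))[1L]
      stop(sprintf("read_genotypes(): non-integer allele at row %d, column %s", bad, col))
    }
    v[!is.na(v) & v == missing_code] <- NA
    as.integer(v)
  }
  a1 <- vapply(paste0(loci, ".a1"), get_col, integer(nrow(df)))
  a2 <- vapply(paste0(loci, ".a2"), get_col, integer(nrow(df)))
  if (nrow(df) == 1L) { a1 <- matrix(a1, nrow = 1L); a2 <- matrix(a2, nrow = 1L) }
  if (nrow(df) == 0L) {
    a1 <- matrix(integer(0), 0L, length(loci))
    a2 <- matrix(integer(0), 0L, length(loci))
  }
  half <- is.na(a1) != is.na(a2)
  if (any(half)) {
    bad <- which(half, arr.ind = TRUE)[1L, ]
    stop(sprintf("read_genotypes(): half-typed locus %s at row %d (one allele missing)",
                 loci[bad[2L]], bad[1L]))
  }
  lines <- data.frame(line_id = as.character(df$line_id),
                      role = as.character(df$role),
                      maternal_id = ifelse(df$maternal_id %in% c("", NA),
                                           NA_character_,
                                           as.character(df$maternal_id)),
                      stringsAsFactors = FALSE)
  marker_panel(loci, lines, a1, a2)
}

#' Write a genotype panel to CSV
#'
#' Deterministic column order (`line_id, role, maternal_id`, then locus
#' pairs in panel order); round-trips with [read_genotypes()].
#'
#' @param panel a [marker_panel()].
#' @param sink path or connection for [utils::write.csv()].
#' @param missing_code value written for untyped alleles (default 0).
#' @export
write_genotypes <- function(panel, sink, missing_code = 0L) {
  stopifnot(inherits(panel, "marker_panel"))
  a1 <- panel$a1; a2 <- panel$a2
  a1[is.na(a1)] <- missing_code; a2[is.na(a2)] <- missing_code
  out <- data.frame(line_id = panel$lines$line_id,
                    role = panel$lines$role,
                    maternal_id = ifelse(is.na(panel$lines$maternal_id), "",
                                         panel$lines$maternal_id),
                    stringsAsFactors = FALSE, check.names = FALSE)
  for (j in seq_len(n_loci(panel))) {
    out[[paste0(panel$loci$locus_id[j], ".a1")]] <- a1[, j]
    out[[paste0(panel$loci$locus_id[j], ".a2")]] <- a2[, j]
  }
  utils::write.csv(out, sink, row.names = FALSE, quote = FALSE)
  invisible(NULL)
}

#' Group lines with identical multilocus genotypes
#'
#' Lines that share every allele pair cannot be separated by the marker
#' panel, which makes paternity among them ambiguous (the situation the
#' assignment engine reports as an identity group). Fully typed lines are
#' partitioned exactly; lines with missing loci are compared on their typed
#' loci only and flagged as potentially identical to any group they match.
#'
#' @param panel a [marker_panel()].
#' @param roles which roles to examine (default `"parent"`).
#' @return list with `groups` (list of character vectors partitioning the
#'   fully typed lines; groups of size > 1 are the problem cases) and
#'   `potential` (data.frame of part-typed lines and the group keys they are
#'   compatible with).
#' @export
find_identical_lines <- function(panel, roles = "parent") {
  sub <- panel_subset(panel, roles = roles)
  full <- !apply(is.na(sub$a1), 1L, any)
  key <- apply(cbind(sub$a1, sub$a2), 1L, paste, collapse = "|")
  groups <- split(sub$lines$line_id[full], key[full])
  names(groups) <- NULL
  potential <- data.frame(line_id = character(0), matches = character(0),
                          stringsAsFactors = FALSE)
  for (i in which(!full)) {
    typed <- !is.na(sub$a1[i, ])
    hits <- character(0)
    for (g in groups) {
      ref <- match(g[1L], sub$lines$line_id)
      if (all(sub$a1[i, typed] == sub$a1[ref, typed] &
              sub$a2[i, typed] == sub$a2[ref, typed])) {
        hits <- c(hits, paste(g, collapse = "/"))
      }
    }
    if (length(hits)) {
      potential <- rbind(potential,
                         data.frame(line_id = sub$lines$line_id[i],
                                    matches = paste(hits, collapse = ","),
                                    stringsAsFactors = FALSE))
    }
  }
  list(groups = groups[order(vapply(groups, `[`, "", 1L))],
       potential = potential)
}
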