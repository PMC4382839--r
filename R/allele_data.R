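#' Locus table: the six-column allele-frequency panel
#'
#' A `locus_table` is a data frame with one row per biallelic SNP and
#' columns `name`, `chrom`, `pos`, one expected-heterozygosity column per
#' population (`het1`, `het2`, ...), and a multi-population `fst` column.
#' Rows are sorted by (chrom, pos). The classic two-population layout is
#' the six-column special case.
#'
#' @param name character vector of locus identifiers (e.g. rs numbers).
#' @param chrom character vector of chromosome labels.
#' @param pos integer vector of 1-based base-pair positions (> 0).
#' @param het numeric matrix (loci x populations) of expected
#'   heterozygosities, each in [0, 0.5].
#' @param fst numeric vector of multi-population F_ST values in [0, 1].
#' @return A data frame of class `locus_table` with attribute `n_pops`.
#' @seealso [read_freq_table()], [convert_genotypes()], [simulate_neutral()]
#' @export
locus_table <- function(name, chrom, pos, het, fst) {
  het <- as.matrix(het)
  n <- length(name)
  stopifnot(length(chrom) == n, length(pos) == n, nrow(het) == n,
            length(fst) == n, ncol(het) >= 2)
  tab <- data.frame(name = as.character(name), chrom = as.character(chrom),
                    pos = as.integer(pos), stringsAsFactors = FALSE)
  for (j in seq_len(ncol(het))) tab[[paste0("het", j)]] <- as.numeric(het[, j])
  tab$fst <- as.numeric(fst)
  tab <- tab[order(tab$chrom, tab$pos, tab$name), , drop = FALSE]
  rownames(tab) <- NULL
  attr(tab, "n_pops") <- ncol(het)
  class(tab) <- c("locus_table", "data.frame")
  validate_locus_table(tab)
}

#' @rdname locus_table
#' @param x object to test or validate.
#' @export
is_locus_table <- function(x) inherits(x, "locus_table")

#' Number of populations in a locus table
#' @param table a `locus_table`.
#' @return integer number of populations (>= 2).
#' @export
n_pops <- function(table) {
  np <- attr(table, "n_pops")
  if (is.null(np)) np <- length(het_cols(table))
  as.integer(np)
}

het_cols <- function(table) grep("^het[0-9]+$", names(table), value = TRUE)

het_matrix <- function(table) {
  as.matrix(table[, het_cols(table), drop = FALSE])
}

validate_locus_table <- function(tab) {
  hc <- het_cols(tab)
  if (length(hc) < 2L)
    stop("locus_table needs heterozygosity columns for >= 2 populations")
  if (any(tab$pos <= 0L))
    stop("positions must be positive 1-based coordinates")
  hm <- het_matrix(tab)
  bad_h <- which(hm < 0 | hm > 0.5 + 1e-9, arr.ind = TRUE)
  if (nrow(bad_h) > 0L)
    stop("heterozygosity outside [0, 0.5] at loci: ",
         paste(utils::head(tab$name[unique(bad_h[, 1])], 5L), collapse = ", "))
  bad_f <- which(tab$fst < -1e-9 | tab$fst > 1 + 1e-9)
  if (length(bad_f) > 0L)
    stop("F_ST outside [0, 1] at loci: ",
         paste(utils::head(tab$name[bad_f], 5L), collapse = ", "))
  dup <- duplicated(tab[, c("chrom", "pos")])
  if (any(dup))
    warning(sum(dup), " duplicate positions kept; windows operate on record order")
  tab
}

#' Read a whitespace-separated allele-frequency table
#'
#' Parses the plain-text panel format: locus name, chromosome, position,
#' one heterozygosity column per population, and a final F_ST column
#' (six columns when `n_pops = 2`). Any whitespace separates fields; lines
#' starting with `#` are skipped; an optional header line is detected by a
#' non-numeric third field. Rows are returned sorted by (chrom, pos).
#'
#' @param path path to the text file.
#' @param n_pops number of populations (>= 2); determines the expected
#'   column count (`3 + n_pops + 1`).
#' @return A [locus_table()].
#' @export
read_freq_table <- function(path, n_pops = 2L) {
  if (!file.exists(path)) stop("file not found: ", path)
  n_pops <- as.integer(n_pops)
  if (n_pops < 2L) stop("n_pops must be >= 2")
  lines <- readLines(path)
  keep <- !grepl("^\\s*(#|$)", lines)
  lineno <- which(keep)
  lines <- lines[keep]
  if (length(lines) == 0L)
    return(empty_locus_table(n_pops))
  fields <- strsplit(trimws(lines), "\\s+")
  # header: third field not numeric
  if (length(fields) > 0L && is.na(suppressWarnings(as.numeric(fields[[1]][3])))) {
    fields <- fields[-1L]
    lineno <- lineno[-1L]
  }
  if (length(fields) == 0L) return(empty_locus_table(n_pops))
  want <- 3L + n_pops + 1L
  nf <- lengths(fields)
  if (any(nf != want))
    stop("expected ", want, " columns but found ", nf[nf != want][1L],
         " on line ", lineno[which(nf != want)[1L]], " of ", path)
  m <- do.call(rbind, fields)
  num <- suppressWarnings(apply(m[, 3:want, drop = FALSE], 2L, as.numeric))
  num <- matrix(num, nrow = nrow(m))
  if (anyNA(num)) {
    bad <- which(apply(num, 1L, anyNA))[1L]
    stop("non-numeric value on line ", lineno[bad], " of ", path)
  }
  locus_table(name = m[, 1L], chrom = m[, 2L], pos = num[, 1L],
              het = num[, 2:(1L + n_pops), drop = FALSE],
              fst = num[, 2L + n_pops])
}

empty_locus_table <- function(np) {
  warning("no data rows; returning empty locus_table")
  locus_table_skeleton(np)
}

locus_table_skeleton <- function(np) {
  tab <- data.frame(name = character(0), chrom = character(0),
                    pos = integer(0), stringsAsFactors = FALSE)
  for (j in seq_len(np)) tab[[paste0("het", j)]] <- numeric(0)
  tab$fst <- numeric(0)
  attr(tab, "n_pops") <- as.integer(np)
  class(tab) <- c("locus_table", "data.frame")
  tab
}

#' Write a locus table back to the six-column text format
#'
#' Tab-separated, with a header line; values printed with six decimals so
#' that read and write round-trip up to formatting.
#'
#' @param table a [locus_table()].
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_freq_table <- function(table, path) {
  stopifnot(is_locus_table(table))
  hc <- het_cols(table)
  out <- table
  for (cc in c(hc, "fst")) out[[cc]] <- sprintf("%.6f", out[[cc]])
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Expected heterozygosity of a biallelic locus
#'
#' `2 p (1 - p)` for allele frequency `p`; maximal (0.5) at p = 0.5 and
#' zero at fixation.
#'
#' @param p allele frequency, in [0, 1] (vectorised).
#' @return heterozygosity in [0, 0.5].
#' @export
expected_het <- function(p) {
  if (any(p < 0 | p > 1, na.rm = TRUE)) stop("allele frequency outside [0, 1]")
  2 * p * (1 - p)
}

#' Wright/Nei F_ST from population allele frequencies
#'
#' Computes F_ST = (H_T - H_S) / H_T where H_S is the mean within-population
#' expected heterozygosity and H_T the heterozygosity at the pooled mean
#' frequency. By default populations are weighted equally; with
#' `weighted = TRUE` both the mean frequency and H_S are weighted by
#' `sizes`. The result is clamped to [0, 1] and defined as 0 when H_T = 0
#' (locus monomorphic overall).
#'
#' @param freqs numeric vector (one locus) or matrix (loci x populations)
#'   of per-population allele frequencies.
#' @param sizes per-population genotype counts; required when
#'   `weighted = TRUE`.
#' @param weighted weight populations by sample size?
#' @return F_ST value(s) in [0, 1].
#' @export
fst_wright <- function(freqs, sizes = NULL, weighted = FALSE) {
  f <- if (is.matrix(freqs)) freqs else matrix(freqs, nrow = 1L)
  if (ncol(f) < 2L) stop("need allele frequencies for >= 2 populations")
  if (any(f < 0 | f > 1)) stop("allele frequency outside [0, 1]")
  if (weighted) {
    if (is.null(sizes)) stop("sizes required when weighted = TRUE")
    if (any(sizes <= 0)) stop("population sizes must be positive")
    w <- sizes / sum(sizes)
  } else {
    w <- rep(1 / ncol(f), ncol(f))
  }
  pbar <- as.vector(f %*% w)
  ht <- 2 * pbar * (1 - pbar)
  hs <- as.vector((2 * f * (1 - f)) %*% w)
  fst <- ifelse(ht > 0, (ht - hs) / ht, 0)
  out <- pmin(pmax(fst, 0), 1)
  if (!is.matrix(freqs)) out[1L] else out
}

#' Convert genotype-count tables to heterozygosity and F_ST
#'
#' The converter role: takes per-population biallelic genotype counts
#' (n_AA, n_Aa, n_aa), drops loci where any population has fewer than
#' `min_genotypes` genotypes, estimates each population's allele frequency,
#' and returns a [locus_table()] with expected heterozygosities and Wright
#' F_ST. With `observed = TRUE` the heterozygosity columns hold the
#' observed heterozygote fraction n_Aa / n instead of 2p(1-p).
#'
#' @param counts data frame with columns `name`, `chrom`, `pos`, then
#'   three columns per population named `nAA<i>`, `nAa<i>`, `naa<i>`
#'   (as produced by [sample_genotype_counts()] / [read_genotype_counts()]).
#' @param min_genotypes drop a locus when any population has fewer total
#'   genotypes than this (default 10).
#' @param observed report observed rather than expected heterozygosity.
#' @param weighted weight the F_ST estimator by sample sizes.
#' @return A [locus_table()]; the number of dropped loci is reported via
#'   `message()`.
#' @export
convert_genotypes <- function(counts, min_genotypes = 10L, observed = FALSE,
                              weighted = FALSE) {
  stopifnot(min_genotypes >= 1L)
  np <- genotype_n_pops(counts)
  n <- nrow(counts)
  freq <- matrix(NA_real_, n, np)
  hobs <- matrix(NA_real_, n, np)
  tot <- matrix(NA_real_, n, np)
  for (j in seq_len(np)) {
    aa <- counts[[paste0("nAA", j)]]
    ab <- counts[[paste0("nAa", j)]]
    bb <- counts[[paste0("naa", j)]]
    if (any(aa < 0 | ab < 0 | bb < 0)) stop("negative genotype count")
    tot[, j] <- aa + ab + bb
    freq[, j] <- ifelse(tot[, j] > 0, (2 * aa + ab) / (2 * tot[, j]), NA_real_)
    hobs[, j] <- ifelse(tot[, j] > 0, ab / tot[, j], NA_real_)
  }
  keep <- apply(tot >= min_genotypes, 1L, all)
  n_drop <- sum(!keep)
  if (n_drop > 0L)
    message("dropped ", n_drop, " loci with < ", min_genotypes,
            " genotypes in at least one population")
  if (!any(keep)) {
    warning("all loci filtered out")
    return(locus_table_skeleton(np))
  }
  freq <- freq[keep, , drop = FALSE]
  het <- if (observed) hobs[keep, , drop = FALSE] else expected_het(freq)
  fst <- fst_wright(freq, sizes = NULL, weighted = FALSE)
  if (weighted) {
    tk <- tot[keep, , drop = FALSE]
    fst <- vapply(seq_len(nrow(freq)), function(i)
      fst_wright(freq[i, ], sizes = tk[i, ], weighted = TRUE), numeric(1))
  }
  locus_table(name = counts$name[keep], chrom = counts$chrom[keep],
              pos = counts$pos[keep], het = het, fst = fst)
}

genotype_n_pops <- function(counts) {
  np <- length(grep("^nAA[0-9]+$", names(counts)))
  if (np < 2L) stop("genotype table needs nAA/nAa/naa columns for >= 2 populations")
  for (j in seq_len(np))
    if (!all(c(paste0("nAa", j), paste0("naa", j)) %in% names(counts)))
      stop("incomplete genotype triple for population ", j)
  np
}

#' Read a genotype-count table
#'
#' Whitespace-separated text with columns `name chrom pos` followed by one
#' `nAA nAa naa` triple per population.
#'
#' @param path path to the text file.
#' @param n_pops number of populations.
#' @return data frame suitable for [convert_genotypes()].
#' @export
read_genotype_counts <- function(path, n_pops = 2L) {
  want <- 3L + 3L * n_pops
  tab <- utils::read.table(path, header = FALSE, comment.char = "#",
                           stringsAsFactors = FALSE)
  if (ncol(tab) != want)
    stop("expected ", want, " columns, found ", ncol(tab))
  names(tab) <- c("name", "chrom", "pos",
                  as.vector(t(outer(seq_len(n_pops), c("nAA", "nAa", "naa"),
                                    function(j, s) paste0(s, j)))))
  tab
}
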