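#' Genome scan for selective-sweep signatures
#'
#' The package's central routine. For every SNP in the table it evaluates
#' sliding windows of each size in `sizes` (centred on the SNP, never
#' spanning a chromosome boundary), computes the per-population mean
#' heterozygosity, mean F_ST and multi-locus F_ST variance of each window,
#' ranks each statistic against a resampled baseline built once per
#' (pool, window size) by unrestricted random sampling, and keeps per locus
#' and statistic the most extreme tail percentile across window sizes
#' together with the window size achieving it. Heterozygosity is ranked in
#' the lower tail (sweeps deplete diversity); mean F_ST and its variance in
#' the upper tail. Percentiles are reported with their -log10 transform
#' and each locus is classified into one of the four interpretation
#' outcomes (see [classify_pattern()]).
#'
#' Ties across window sizes are broken toward the smaller window (sharper
#' localisation). Loci whose smallest window does not fit (within 2 loci
#' of a chromosome end) are marked `unevaluated`; `n_sizes` records how
#' many window sizes were evaluable at each locus so scores can be
#' stratified by it.
#'
#' @param table a [locus_table()].
#' @param sizes window sizes, odd ascending (default [default_window_sizes()]).
#' @param r resamples per baseline (default 1e5).
#' @param seed RNG seed; the scan is deterministic given the seed.
#' @param pool_scope `"chromosome"` (default) or `"genome"` resampling pool.
#' @param method `"percentile"` (rank-based, default) or `"zscore"`
#'   (normal approximation).
#' @param alpha significance level on percentiles used only for outcome
#'   classification (default 0.01).
#' @param var_type variance denominator for the F_ST variance,
#'   `"sample"` (default) or `"population"`.
#' @return object of class `sweep_scan` with a `records` data frame: locus
#'   columns, `n_sizes`, and per statistic `p_*`, `size_*`, `obs_*`,
#'   `nlp_*` columns plus `outcome`.
#' @examples
#' tab <- simulate_neutral(n_loci = 400, seed = 1)
#' sc <- sweep_scan(tab, sizes = c(5, 7), r = 2000, seed = 1)
#' summary(sc)
#' @export
sweep_scan <- function(table, sizes = default_window_sizes(), r = 1e5,
                       seed = 1L, pool_scope = c("chromosome", "genome"),
                       method = c("percentile", "zscore"), alpha = 0.01,
                       var_type = c("sample", "population")) {
  stopifnot(is_locus_table(table))
  pool_scope <- match.arg(pool_scope)
  method <- match.arg(method)
  var_type <- match.arg(var_type)
  sizes <- sort(unique(vapply(sizes, check_window_size, integer(1))))
  r <- as.integer(r)
  if (r < 1L) stop("r must be >= 1")
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  np <- n_pops(table)
  stat_names <- c(paste0("het", seq_len(np)), "fst_mean", "fst_var")
  tails <- ifelse(startsWith(stat_names, "het"), "lower", "upper")
  n <- nrow(table)
  nstat <- length(stat_names)
  best_p <- matrix(NA_real_, n, nstat, dimnames = list(NULL, stat_names))
  best_size <- matrix(NA_integer_, n, nstat)
  best_obs <- matrix(NA_real_, n, nstat)
  n_sizes <- integer(n)

  chroms <- unique(table$chrom)
  hm_all <- het_matrix(table)
  set.seed(seed)

  genome_nulls <- NULL
  if (pool_scope == "genome") {
    genome_nulls <- lapply(sizes, function(k) {
      if (n < k) return(NULL)
      lapply(draw_null_set(hm_all, table$fst, k, r, var_type), sort)
    })
    names(genome_nulls) <- as.character(sizes)
  }

  any_window <- FALSE
  for (ch in chroms) {
    rows <- which(table$chrom == ch)
    L <- length(rows)
    hm <- hm_all[rows, , drop = FALSE]
    fv <- table$fst[rows]
    for (k in sizes) {
      if (L < k) next
      nulls <- if (pool_scope == "genome") {
        genome_nulls[[as.character(k)]]
      } else {
        lapply(draw_null_set(hm, fv, k, r, var_type), sort)
      }
      obs <- chrom_window_stats(hm, fv, k, var_type)
      half <- (k - 1L) %/% 2L
      centers <- rows[(half + 1L):(L - half)]
      n_sizes[centers] <- n_sizes[centers] + 1L
      any_window <- TRUE
      for (s in seq_along(stat_names)) {
        nd <- list(values = nulls[[stat_names[s]]], r = r)
        p <- if (method == "percentile") {
          tail_percentile(nd, obs[, s], tails[s])
        } else {
          zscore_probability(nd, obs[, s], tails[s])
        }
        upd <- is.na(best_p[centers, s]) | p < best_p[centers, s]
        ci <- centers[upd]
        best_p[ci, s] <- p[upd]
        best_size[ci, s] <- k
        best_obs[ci, s] <- obs[upd, s]
      }
    }
  }
  if (!any_window)
    warning("no chromosome has enough loci for the smallest window; ",
            "all loci unevaluated")

  records <- table[, c("name", "chrom", "pos"), drop = FALSE]
  class(records) <- "data.frame"
  records$n_sizes <- n_sizes
  for (s in seq_along(stat_names)) {
    sn <- stat_names[s]
    records[[paste0("p_", sn)]] <- best_p[, s]
    records[[paste0("size_", sn)]] <- best_size[, s]
    records[[paste0("obs_", sn)]] <- best_obs[, s]
    records[[paste0("nlp_", sn)]] <- ifelse(is.na(best_p[, s]), NA_real_,
                                            neglog10(pmax(best_p[, s], .Machine$double.xmin)))
  }
  records$outcome <- classify_pattern(records, alpha = alpha, n_pops = np)
  structure(list(records = records, sizes = sizes, r = r, seed = seed,
                 pool_scope = pool_scope, method = method, alpha = alpha,
                 var_type = var_type, n_pops = np, n_loci = n,
                 stat_names = stat_names, call = match.call()),
            class = "sweep_scan")
}

#' -log10 transform of a percentile
#'
#' `log10(1 / p)` — the visualization scale for percentile tracks.
#'
#' @param p percentile(s) in (0, 1].
#' @return non-negative score(s).
#' @export
neglog10 <- function(p) {
  if (any(p <= 0 | p > 1, na.rm = TRUE)) stop("percentile must be in (0, 1]")
  log10(1 / p)
}

#' Classify loci into selection-pattern outcomes
#'
#' Four interpretation outcomes of the diversity/divergence pattern at a
#' locus, decided from the best tail percentiles at level `alpha`:
#' \describe{
#'   \item{none}{no statistic extreme — does not exclude selection.}
#'   \item{old_selection}{heterozygosity extreme-low in every population
#'     while neither mean F_ST nor its variance is elevated: a sweep in
#'     the ancestral population, predating the split.}
#'   \item{new_selection_one_pop}{heterozygosity extreme-low in exactly
#'     one population with elevated F_ST variance: a sweep after the
#'     split, in one derived population.}
#'   \item{new_selection_both}{heterozygosity extreme-low in all
#'     populations with elevated F_ST variance: sweeps in both derived
#'     populations after the split.}
#' }
#' Loci with no evaluable window are marked `unevaluated`. Classification
#' uses heterozygosity and the F_ST variance; mean F_ST percentiles are
#' reported but F_ST alone is a poor estimator of selection signatures.
#'
#' @param records the `records` data frame of a [sweep_scan()] (or any
#'   data frame with its `p_*` columns).
#' @param alpha significance level on percentiles, in (0, 1).
#' @param n_pops number of populations (inferred from columns if missing).
#' @return factor of outcomes, one per record.
#' @export
classify_pattern <- function(records, alpha = 0.01, n_pops = NULL) {
  if (alpha <= 0 || alpha >= 1) stop("alpha must be in (0, 1)")
  if (is.null(n_pops))
    n_pops <- length(grep("^p_het[0-9]+$", names(records)))
  ph <- as.matrix(records[, paste0("p_het", seq_len(n_pops)), drop = FALSE])
  het_lo <- ph < alpha
  n_lo <- rowSums(het_lo)
  s2_hi <- records$p_fst_var < alpha
  fstm_hi <- records$p_fst_mean < alpha
  out <- rep("none", nrow(records))
  out[n_lo == n_pops & !s2_hi & !fstm_hi] <- "old_selection"
  out[n_lo == 1L & s2_hi] <- "new_selection_one_pop"
  out[n_lo == n_pops & s2_hi] <- "new_selection_both"
  out[is.na(records$p_fst_var)] <- "unevaluated"
  factor(out, levels = c("none", "old_selection", "new_selection_one_pop",
                         "new_selection_both", "unevaluated"))
}

#' Locate the genome-wide peak of a statistic's -log10 track
#'
#' Returns the record index with the largest -log10 best percentile for
#' the chosen statistic. Because percentiles are floored at `1/(r+1)`,
#' several loci inside a strong sweep can tie at the maximal score; ties
#' are broken by the most extreme observed statistic value at the best
#' window (lowest mean heterozygosity, highest F_ST mean/variance).
#'
#' @param scan a [sweep_scan()] object or its records data frame.
#' @param statistic statistic track, e.g. `"het1"` or `"fst_var"`.
#' @return integer row index of the peak record.
#' @export
peak_locus <- function(scan, statistic = "fst_var") {
  records <- if (inherits(scan, "sweep_scan")) scan$records else scan
  nlp <- records[[paste0("nlp_", statistic)]]
  obs <- records[[paste0("obs_", statistic)]]
  if (is.null(nlp)) stop("unknown statistic '", statistic, "'")
  if (all(is.na(nlp))) stop("no evaluated loci")
  if (startsWith(statistic, "het")) obs <- -obs
  order(-nlp, -obs, na.last = TRUE)[1L]
}

#' Write scan records to a tab-separated file
#'
#' One row per locus: locus columns, number of window sizes evaluated,
#' per-statistic best percentile / achieving window size / observed value /
#' -log10 score, and the outcome class. Percentiles are printed with
#' enough digits to round-trip at `r = 1e8`.
#'
#' @param x a `sweep_scan` object or its `records` data frame.
#' @param path output path.
#' @return `path`, invisibly.
#' @export
write_scan_table <- function(x, path) {
  records <- if (inherits(x, "sweep_scan")) x$records else x
  out <- records
  num <- vapply(out, is.numeric, logical(1)) &
    !names(out) %in% c("pos", "n_sizes") & !grepl("^size_", names(out))
  for (cc in names(out)[num])
    out[[cc]] <- ifelse(is.na(out[[cc]]), "NA", sprintf("%.10g", out[[cc]]))
  utils::write.table(out, path, sep = "\t", quote = FALSE,
                     row.names = FALSE, col.names = TRUE)
  invisible(path)
}

#' Read a scan table written by [write_scan_table()]
#' @param path path to the tab-separated scan output.
#' @return data frame of scan records.
#' @export
read_scan_table <- function(path) {
  utils::read.table(path, header = TRUE, sep = "\t",
                    stringsAsFactors = FALSE, na.strings = "NA")
}

#' @export
print.sweep_scan <- function(x, ...) {
  cat("Selective-sweep genome scan\n")
  cat("  loci:", x$n_loci, " populations:", x$n_pops,
      " chromosomes:", length(unique(x$records$chrom)), "\n")
  cat("  window sizes:", length(x$sizes), "(", min(x$sizes), "to",
      max(x$sizes), "), r =", format(x$r, big.mark = ","),
      paste0("(", x$pool_scope, " pool, ", x$method, ")"), "\n")
  ev <- sum(x$records$outcome != "unevaluated")
  cat("  evaluated loci:", ev, " alpha =", x$alpha, "\n")
  tb <- table(x$records$outcome)
  tb <- tb[tb > 0]
  cat("  outcomes:", paste(names(tb), tb, sep = "=", collapse = ", "), "\n")
  invisible(x)
}

#' @export
summary.sweep_scan <- function(object, n_top = 5L, ...) {
  rec <- object$records
  ok <- rec$outcome != "unevaluated"
  top <- rec[ok, ][order(-rec$nlp_fst_var[ok]), ][seq_len(min(n_top, sum(ok))), ]
  out <- list(scan = object, outcomes = table(rec$outcome),
              top_fst_var = top[, c("name", "chrom", "pos", "p_fst_var",
                                    "size_fst_var", "nlp_fst_var", "outcome")])
  class(out) <- "summary.sweep_scan"
  out
}

#' @export
print.summary.sweep_scan <- function(x, ...) {
  print(x$scan)
  cat("\nTop loci by -log10 F_ST-variance percentile:\n")
  print(x$top_fst_var, row.names = FALSE)
  invisible(x)
}

#' @export
as.data.frame.sweep_scan <- function(x, ...) x$records

#' Plot -log10 percentile tracks along a chromosome
#'
#' One panel per statistic: position (Mb) against the -log10 of the best
#' tail percentile, the scale on which sweep signatures stand out as
#' localized peaks.
#'
#' @param x a `sweep_scan` object.
#' @param chrom chromosome to plot (default: the first in the scan).
#' @param statistics which statistic tracks to draw (default all).
#' @param ... further arguments passed to [graphics::plot()].
#' @return `x`, invisibly.
#' @export
plot.sweep_scan <- function(x, chrom = NULL,
                            statistics = x$stat_names, ...) {
  rec <- x$records
  if (is.null(chrom)) chrom <- rec$chrom[1L]
  if (!chrom %in% rec$chrom)
    stop("chromosome '", chrom, "' not in scan; available: ",
         paste(unique(rec$chrom), collapse = ", "))
  rec <- rec[rec$chrom == chrom & rec$outcome != "unevaluated", ]
  statistics <- match.arg(statistics, x$stat_names, several.ok = TRUE)
  old <- graphics::par(mfrow = c(length(statistics), 1L),
                       mar = c(2.5, 4, 1.5, 1))
  on.exit(graphics::par(old))
  for (s in statistics) {
    y <- rec[[paste0("nlp_", s)]]
    graphics::plot(rec$pos / 1e6, y, type = "h", col = "grey40",
                   xlab = "", ylab = expression(-log[10](percentile)),
                   main = paste0(chrom, ": ", s), ...)
    graphics::abline(h = neglog10(x$alpha), lty = 2, col = "red")
  }
  invisible(x)
}
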