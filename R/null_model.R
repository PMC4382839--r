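#' Build a resampled null distribution for one window statistic
#'
#' Draws `r` random sets of `size` loci by unrestricted random sampling
#' (loci drawn independently and uniformly, with replacement) from the
#' pool — a single chromosome or the whole table — and computes the chosen
#' statistic for each set with exactly the same formula used for observed
#' windows. The sorted values form the baseline against which observed
#' window statistics are ranked.
#'
#' @param table a [locus_table()].
#' @param size number of loci per draw (a window size).
#' @param statistic one of `"het1"`, ..., `"het<P>"` (per-population mean
#'   heterozygosity), `"fst_mean"`, `"fst_var"`.
#' @param r number of resampled sets (>= 1; values below 1000 warn).
#' @param seed RNG seed.
#' @param pool_scope `"chromosome"` (draw from one chromosome, default) or
#'   `"genome"` (draw from all loci).
#' @param chrom chromosome to pool when `pool_scope = "chromosome"`.
#' @param var_type variance denominator, as in [window_summary()].
#' @return object of class `null_dist`: list with sorted `values`,
#'   `statistic`, `size`, `r`, `seed`, `pool_scope`.
#' @export
build_null <- function(table, size, statistic, r = 1e5, seed = 1L,
                       pool_scope = c("chromosome", "genome"), chrom = NULL,
                       var_type = c("sample", "population")) {
  pool_scope <- match.arg(pool_scope)
  var_type <- match.arg(var_type)
  r <- as.integer(r)
  if (r < 1L) stop("r must be >= 1")
  if (r < 1000L) warning("r < 1000 gives coarse percentiles")
  rows <- if (pool_scope == "chromosome") {
    if (is.null(chrom)) chrom <- table$chrom[1L]
    which(table$chrom == chrom)
  } else seq_len(nrow(table))
  if (length(rows) < size)
    stop("pool has ", length(rows), " loci, fewer than window size ", size)
  hm <- het_matrix(table)[rows, , drop = FALSE]
  valid_statistic(statistic, ncol(hm))
  set.seed(seed)
  vals <- draw_null_set(hm, table$fst[rows], size, r, var_type)[[statistic]]
  structure(list(statistic = statistic, size = as.integer(size),
                 values = sort(vals), r = r, seed = seed,
                 pool_scope = pool_scope),
            class = "null_dist")
}

valid_statistic <- function(statistic, np) {
  ok <- c(paste0("het", seq_len(np)), "fst_mean", "fst_var")
  if (!statistic %in% ok)
    stop("unknown statistic '", statistic, "'; available: ",
         paste(ok, collapse = ", "))
  statistic
}

# One locus-set draw serves every statistic: r sets of `size` loci are
# sampled with replacement and each statistic is computed per set.
# Returns a named list of unsorted value vectors of length r.
draw_null_set <- function(hm, fst, size, r, var_type = "sample") {
  n <- nrow(hm)
  idx <- sample.int(n, size * r, replace = TRUE)
  np <- ncol(hm)
  out <- vector("list", np + 2L)
  names(out) <- c(paste0("het", seq_len(np)), "fst_mean", "fst_var")
  for (j in seq_len(np))
    out[[j]] <- .colMeans(hm[idx, j], size, r)
  v <- fst[idx]
  m <- .colMeans(v, size, r)
  ss <- .colSums(v * v, size, r)
  denom <- if (var_type == "sample") size - 1L else size
  out[["fst_mean"]] <- m
  out[["fst_var"]] <- pmax((ss - size * m * m) / denom, 0)
  out
}

#' Tail percentile of an observed statistic in a resampled baseline
#'
#' The percentile is the inclusive rank of the observed value in the
#' resampled set divided by the number of resampled values: for the lower
#' tail the fraction of resampled values <= observed, for the upper tail
#' the fraction >= observed (ties counted inclusively). Observed values
#' more extreme than every resampled value are floored at `1 / (r + 1)` so
#' the -log10 transform stays finite; this floor is the resolution limit
#' of `r` resamples.
#'
#' @param null a `null_dist` from [build_null()], or any list with sorted
#'   `values` and `r`.
#' @param observed observed statistic value(s) (vectorised).
#' @param tail `"lower"` or `"upper"`.
#' @return numeric percentile(s) in (0, 1].
#' @export
tail_percentile <- function(null, observed, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  v <- null$values
  r <- null$r
  cnt <- if (tail == "lower") {
    findInterval(observed, v)                      # values <= observed
  } else {
    r - findInterval(observed, v, left.open = TRUE) # values >= observed
  }
  pmax(cnt / r, 1 / (r + 1))
}

#' Normal-approximation tail probability (z-score mode)
#'
#' Alternative to rank percentiles: standardises the observed value
#' against the mean and standard deviation of the resampled baseline and
#' returns the normal tail probability on the requested side, floored at
#' `1 / (r + 1)` like [tail_percentile()]. A zero-variance baseline carries
#' no signal; it returns p = 1 with attribute `degenerate = TRUE`.
#'
#' @inheritParams tail_percentile
#' @return numeric probability(ies) in (0, 1].
#' @export
zscore_probability <- function(null, observed, tail = c("lower", "upper")) {
  tail <- match.arg(tail)
  mu <- mean(null$values)
  sdv <- stats::sd(null$values)
  if (!is.finite(sdv) || sdv == 0) {
    return(structure(rep(1, length(observed)), degenerate = TRUE))
  }
  z <- (observed - mu) / sdv
  p <- stats::pnorm(z, lower.tail = (tail == "lower"))
  pmax(p, 1 / (null$r + 1))
}

#' @export
print.null_dist <- function(x, ...) {
  cat("Resampled null distribution\n")
  cat("  statistic:", x$statistic, "  window size:", x$size, "\n")
  cat("  r =", x$r, "draws (", x$pool_scope, "pool ), seed", x$seed, "\n")
  cat("  range: [", format(min(x$values), digits = 4), ",",
      format(max(x$values), digits = 4), "]\n")
  invisible(x)
}
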