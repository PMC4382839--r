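#' Default sliding-window size grid
#'
#' Window sizes are odd numbers of loci; the default grid of 5 to 65 in
#' steps of 2 gives 31 window sizes centred on every SNP.
#'
#' @param min_size,max_size smallest and largest window (odd, >= 5).
#' @param step increment between sizes (even, positive).
#' @return integer vector of window sizes.
#' @export
default_window_sizes <- function(min_size = 5L, max_size = 65L, step = 2L) {
  min_size <- as.integer(min_size); max_size <- as.integer(max_size)
  step <- as.integer(step)
  if (min_size %% 2L == 0L || max_size %% 2L == 0L)
    stop("window sizes must be odd")
  if (step <= 0L || step %% 2L == 1L)
    stop("step must be a positive even integer")
  if (min_size < 5L) stop("smallest window size is 5 loci")
  if (min_size > max_size) stop("min_size must not exceed max_size")
  seq.int(min_size, max_size, by = step)
}

#' Enumerate window centres for one window size
#'
#' Windows contain a fixed number of consecutive loci and never span
#' chromosome boundaries; a window of size k exists for every locus whose
#' (k-1)/2 flanking loci fit within its chromosome.
#'
#' @param table a [locus_table()].
#' @param size odd window size >= 5.
#' @return data frame with columns `chrom`, `center_index` (index within
#'   the chromosome's record order) and `row` (row index in `table`);
#'   zero rows when no chromosome is long enough.
#' @export
iter_windows <- function(table, size) {
  size <- check_window_size(size)
  half <- (size - 1L) %/% 2L
  out <- lapply(split(seq_len(nrow(table)), table$chrom), function(rows) {
    L <- length(rows)
    if (L < size) return(NULL)
    ci <- seq.int(half + 1L, L - half)
    data.frame(chrom = table$chrom[rows[1L]], center_index = ci,
               row = rows[ci], stringsAsFactors = FALSE)
  })
  out <- do.call(rbind, out)
  if (is.null(out))
    out <- data.frame(chrom = character(0), center_index = integer(0),
                      row = integer(0), stringsAsFactors = FALSE)
  rownames(out) <- NULL
  out
}

check_window_size <- function(size) {
  size <- as.integer(size)
  if (is.na(size) || size < 5L || size %% 2L == 0L)
    stop("window size must be an odd integer >= 5")
  size
}

#' Summarise one sliding window
#'
#' For the `size` loci centred on `center_index` of chromosome `chrom`,
#' returns the per-population mean heterozygosity, the mean F_ST, and the
#' variance of F_ST across the window's loci (the multi-locus F_ST
#' variance, S^2 F_ST).
#'
#' @param table a [locus_table()].
#' @param chrom chromosome label.
#' @param center_index index of the central locus within that chromosome.
#' @param size odd window size >= 5.
#' @param var_type `"sample"` (n-1 denominator, default) or
#'   `"population"` (n); observed and resampled statistics always share
#'   the same choice.
#' @return list with `mean_het` (numeric vector, one per population),
#'   `mean_fst` and `s2_fst`.
#' @export
window_summary <- function(table, chrom, center_index, size,
                           var_type = c("sample", "population")) {
  size <- check_window_size(size)
  var_type <- match.arg(var_type)
  rows <- which(table$chrom == chrom)
  L <- length(rows)
  half <- (size - 1L) %/% 2L
  if (center_index - half < 1L || center_index + half > L)
    stop("window of size ", size, " does not fit at index ", center_index)
  idx <- rows[(center_index - half):(center_index + half)]
  hm <- het_matrix(table)[idx, , drop = FALSE]
  f <- table$fst[idx]
  denom <- if (var_type == "sample") size - 1L else size
  m <- mean(f)
  list(mean_het = colMeans(hm), mean_fst = m,
       s2_fst = sum((f - m)^2) / denom)
}

# Rolling mean over windows of k consecutive values; returns a vector of
# length(x) - k + 1 (one value per fully contained window).
roll_mean <- function(x, k) {
  cs <- c(0, cumsum(x))
  n <- length(x)
  (cs[(k + 1L):(n + 1L)] - cs[1L:(n - k + 1L)]) / k
}

# Rolling variance via cumulative sums; safe for bounded inputs like F_ST.
roll_var <- function(x, k, var_type = "sample") {
  cs <- c(0, cumsum(x))
  cs2 <- c(0, cumsum(x * x))
  n <- length(x)
  s1 <- cs[(k + 1L):(n + 1L)] - cs[1L:(n - k + 1L)]
  s2 <- cs2[(k + 1L):(n + 1L)] - cs2[1L:(n - k + 1L)]
  denom <- if (var_type == "sample") k - 1L else k
  pmax((s2 - s1 * s1 / k) / denom, 0)
}

# All window statistics for one chromosome at one size, vectorised.
# Returns a matrix with one row per window (centres half+1 .. L-half) and
# columns het1..hetP, fst_mean, fst_var.
chrom_window_stats <- function(hm, fst, size, var_type = "sample") {
  k <- size
  nw <- nrow(hm) - k + 1L
  np <- ncol(hm)
  stats <- matrix(NA_real_, nw, np + 2L,
                  dimnames = list(NULL, c(paste0("het", seq_len(np)),
                                          "fst_mean", "fst_var")))
  for (j in seq_len(np)) stats[, j] <- roll_mean(hm[, j], k)
  stats[, np + 1L] <- roll_mean(fst, k)
  stats[, np + 2L] <- roll_var(fst, k, var_type)
  stats
}
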