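#' Simulate a neutral multi-population allele-frequency panel
#'
#' Frequency-level neutral background: each locus draws an ancestral
#' allele frequency from `ancestral` (uniform on [0.05, 0.95] by default),
#' then each population's frequency from a Beta distribution with mean p
#' and variance `F p (1 - p)` — the Balding-Nichols model, where `F` is
#' the differentiation (drift) parameter. Heterozygosities and F_ST are
#' then computed exactly as the converter would from real frequencies.
#' Loci are placed `spacing` bp apart along each chromosome.
#'
#' @param n_loci loci per chromosome (recycled across `chroms`).
#' @param n_pops number of populations (>= 2).
#' @param F differentiation parameter in (0, 1); expected F_ST of the
#'   panel grows with `F`.
#' @param chroms chromosome labels (default a single `"chr1"`).
#' @param ancestral function(n) drawing ancestral frequencies.
#' @param spacing bp between adjacent loci.
#' @param seed RNG seed; identical seeds give identical tables.
#' @return a [locus_table()].
#' @export
simulate_neutral <- function(n_loci = 1e4, n_pops = 2L, F = 0.1,
                             chroms = "chr1",
                             ancestral = function(n) stats::runif(n, 0.05, 0.95),
                             spacing = 1000L, seed = 1L) {
  if (F <= 0 || F >= 1) stop("F must be in (0, 1)")
  if (n_pops < 2L) stop("n_pops must be >= 2")
  n_loci <- rep_len(as.integer(n_loci), length(chroms))
  set.seed(seed)
  pieces <- vector("list", length(chroms))
  offset <- 0L
  for (ci in seq_along(chroms)) {
    n <- n_loci[ci]
    p <- ancestral(n)
    shape_scale <- (1 - F) / F
    freq <- matrix(stats::rbeta(n * n_pops,
                                rep(p * shape_scale, n_pops),
                                rep((1 - p) * shape_scale, n_pops)),
                   nrow = n)
    pieces[[ci]] <- list(
      name = sprintf("rs%06d", offset + seq_len(n)),
      chrom = rep(chroms[ci], n),
      pos = spacing * seq_len(n),
      het = expected_het(freq),
      fst = fst_wright(freq))
    offset <- offset + n
  }
  locus_table(name = unlist(lapply(pieces, `[[`, "name")),
              chrom = unlist(lapply(pieces, `[[`, "chrom")),
              pos = unlist(lapply(pieces, `[[`, "pos")),
              het = do.call(rbind, lapply(pieces, `[[`, "het")),
              fst = unlist(lapply(pieces, `[[`, "fst")))
}

#' Inject a selective-sweep signature into a locus table
#'
#' Plants one of the interpretable sweep patterns into an existing
#' (typically neutral) panel:
#' \describe{
#'   \item{old}{sweep in the ancestral population — heterozygosity of
#'     *all* populations is depressed; F_ST left at background.}
#'   \item{new_one_pop}{sweep in one derived population (`target_pop`) —
#'     that population's heterozygosity is depressed and the locus F_ST
#'     values are blended toward an alternation of near-fixed high and
#'     near-zero low values, the mosaic of alternatively fixed haplotypes
#'     that drives the F_ST variance up.}
#'   \item{new_both}{sweeps in all derived populations — every
#'     population's heterozygosity depressed, with the same oscillating
#'     F_ST pattern.}
#' }
#' The heterozygosity multiplier ramps linearly (triangular profile) from
#' `het_reduction` at the centre locus to 1 at the sweep edges; the F_ST
#' blend weight ramps the same way. Loci outside the affected interval
#' are returned bit-identical.
#'
#' @param table a [locus_table()].
#' @param chrom chromosome carrying the sweep.
#' @param center_index index of the sweep centre within that chromosome's
#'   record order.
#' @param half_width loci affected on each side of the centre (>= 0).
#' @param mode `"old"`, `"new_one_pop"` or `"new_both"`.
#' @param het_reduction multiplicative heterozygosity factor at the
#'   centre, in [0, 1).
#' @param target_pop swept population for `new_one_pop` (default 1).
#' @param fst_high,fst_low the alternating F_ST levels at full blend
#'   weight for the `new_*` modes.
#' @return a [locus_table()] with the sweep planted; attribute `sweep`
#'   records the specification.
#' @export
inject_sweep <- function(table, chrom, center_index, half_width,
                         mode = c("new_one_pop", "new_both", "old"),
                         het_reduction = 0.1, target_pop = 1L,
                         fst_high = 0.95, fst_low = 0.02) {
  stopifnot(is_locus_table(table), half_width >= 0L)
  mode <- match.arg(mode)
  if (het_reduction < 0 || het_reduction >= 1)
    stop("het_reduction must be in [0, 1)")
  rows <- which(table$chrom == chrom)
  if (length(rows) == 0L) stop("no loci on chromosome ", chrom)
  lo <- center_index - half_width
  hi <- center_index + half_width
  if (lo < 1L || hi > length(rows))
    stop("sweep interval exceeds chromosome bounds")
  prev <- attr(table, "sweep")
  if (!is.null(prev) && prev$chrom == chrom &&
      max(lo, prev$lo) <= min(hi, prev$hi))
    stop("overlapping sweeps; inject at disjoint intervals")
  idx <- rows[lo:hi]
  d <- abs(seq(lo, hi) - center_index)
  w <- if (half_width == 0L) 1 else 1 - d / (half_width + 1)  # 1 at centre
  factor <- 1 - w * (1 - het_reduction)   # het_reduction at centre -> ~1 at edge
  hc <- het_cols(table)
  pops <- switch(mode,
                 old = seq_along(hc),
                 new_both = seq_along(hc),
                 new_one_pop = as.integer(target_pop))
  for (j in pops) table[[hc[j]]][idx] <- table[[hc[j]]][idx] * factor
  if (mode != "old") {
    osc <- ifelse(seq_along(idx) %% 2L == 1L, fst_high, fst_low)
    table$fst[idx] <- w * osc + (1 - w) * table$fst[idx]
  }
  attr(table, "sweep") <- list(chrom = chrom, center_index = center_index,
                               half_width = half_width, lo = lo, hi = hi,
                               mode = mode, het_reduction = het_reduction,
                               target_pop = target_pop)
  table
}

#' Draw Hardy-Weinberg genotype counts from population frequencies
#'
#' Multinomial sampling of (n_AA, n_Aa, n_aa) per population and locus
#' under Hardy-Weinberg proportions; feeds [convert_genotypes()].
#'
#' @param freqs matrix (loci x populations) of allele frequencies.
#' @param n genotypes sampled per population (scalar or per-population).
#' @param name,chrom,pos locus annotation (defaults generated).
#' @param seed RNG seed.
#' @return data frame in the genotype-count layout of
#'   [convert_genotypes()].
#' @export
sample_genotype_counts <- function(freqs, n, name = NULL, chrom = "chr1",
                                   pos = NULL, seed = 1L) {
  freqs <- as.matrix(freqs)
  if (any(n < 1)) stop("n must be >= 1")
  nl <- nrow(freqs); np <- ncol(freqs)
  n <- rep_len(as.integer(n), np)
  if (is.null(name)) name <- sprintf("rs%06d", seq_len(nl))
  if (is.null(pos)) pos <- 1000L * seq_len(nl)
  set.seed(seed)
  out <- data.frame(name = name, chrom = rep_len(chrom, nl), pos = pos,
                    stringsAsFactors = FALSE)
  for (j in seq_len(np)) {
    p <- freqs[, j]
    cnt <- vapply(seq_len(nl), function(i)
      as.vector(stats::rmultinom(1L, n[j],
                                 c(p[i]^2, 2 * p[i] * (1 - p[i]),
                                   (1 - p[i])^2))),
      integer(3))
    out[[paste0("nAA", j)]] <- cnt[1L, ]
    out[[paste0("nAa", j)]] <- cnt[2L, ]
    out[[paste0("naa", j)]] <- cnt[3L, ]
  }
  out
}
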