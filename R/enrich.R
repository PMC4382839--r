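#' Read gene intervals from a BED file
#'
#' Standard BED: 0-based half-open `chrom start end [name]`; converted on
#' read to 1-based inclusive coordinates used internally. A missing name
#' column gets `gene<i>` identifiers.
#'
#' @param path path to the BED file.
#' @return data frame with columns `gene`, `chrom`, `start`, `end`
#'   (1-based inclusive).
#' @export
read_bed_genes <- function(path) {
  tab <- utils::read.table(path, header = FALSE, sep = "\t",
                           stringsAsFactors = FALSE, comment.char = "#")
  if (ncol(tab) < 3L) stop("BED needs at least chrom, start, end")
  genes <- data.frame(
    gene = if (ncol(tab) >= 4L) as.character(tab[[4L]])
           else sprintf("gene%d", seq_len(nrow(tab))),
    chrom = as.character(tab[[1L]]),
    start = as.integer(tab[[2L]]) + 1L,
    end = as.integer(tab[[3L]]),
    stringsAsFactors = FALSE)
  if (any(genes$start > genes$end)) stop("BED interval with start >= end")
  genes
}

#' Assign scan scores to gene intervals
#'
#' Each gene's score is the summary (`max` by default, capturing
#' single-peak sweeps; `mean` optional) of the -log10 best percentiles of
#' the chosen statistic over all scanned loci inside the gene's (optionally
#' flanked) interval. Genes containing no evaluated locus are flagged
#' unscored (`NA`).
#'
#' @param scan a [sweep_scan()] object or its records data frame.
#' @param genes gene intervals as from [read_bed_genes()].
#' @param statistic which statistic's -log10 track to summarise
#'   (default `"fst_var"`).
#' @param flank bp added to each side of every gene (default 0).
#' @param summary `"max"` (default) or `"mean"`.
#' @return data frame with columns `gene`, `chrom`, `n_loci`, `score`.
#' @export
score_genes <- function(scan, genes, statistic = "fst_var", flank = 0L,
                        summary = c("max", "mean")) {
  summary <- match.arg(summary)
  records <- if (inherits(scan, "sweep_scan")) scan$records else scan
  col <- paste0("nlp_", statistic)
  if (!col %in% names(records)) stop("no column ", col, " in scan records")
  if (!any(genes$chrom %in% records$chrom))
    stop("no shared chromosomes between genes and scan records")
  fun <- if (summary == "max") max else mean
  score <- rep(NA_real_, nrow(genes))
  n_loci <- integer(nrow(genes))
  for (i in seq_len(nrow(genes))) {
    hit <- records$chrom == genes$chrom[i] &
      records$pos >= genes$start[i] - flank &
      records$pos <= genes$end[i] + flank &
      !is.na(records[[col]])
    n_loci[i] <- sum(hit)
    if (n_loci[i] > 0L) score[i] <- fun(records[[col]][hit])
  }
  if (all(n_loci == 0L))
    stop("no gene overlaps any evaluated locus")
  data.frame(gene = genes$gene, chrom = genes$chrom, n_loci = n_loci,
             score = score, stringsAsFactors = FALSE)
}

#' Permutation test for enrichment of selection signals in a gene set
#'
#' Compares the mean score of a candidate gene list with the mean scores
#' of `n_random` random gene sets of the same size drawn without
#' replacement from the scored gene universe. The empirical p-value is the
#' fraction of random sets scoring at least as high as the candidates
#' (inclusive), floored at `1 / (n_random + 1)`.
#'
#' @param scores per-gene scores from [score_genes()].
#' @param candidates character vector of candidate gene ids (must be
#'   scored genes; unscored candidates are dropped with a warning).
#' @param n_random number of random sets (>= 100).
#' @param seed RNG seed.
#' @return object of class `gene_set_test`: list with `candidate_score`,
#'   `null_scores`, `p_value`, `n_candidates`, `seed`.
#' @export
gene_set_test <- function(scores, candidates, n_random = 1000L, seed = 1L) {
  if (n_random < 100L) stop("n_random must be >= 100")
  scored <- scores[!is.na(scores$score), , drop = FALSE]
  cand <- unique(candidates)
  known <- cand %in% scored$gene
  if (!all(known)) {
    warning(sum(!known), " candidate gene(s) unscored or unknown; excluded")
    cand <- cand[known]
  }
  if (length(cand) == 0L) stop("no scored candidate genes left")
  m <- length(cand)
  if (m > nrow(scored)) stop("candidate set larger than scored universe")
  cand_score <- mean(scored$score[scored$gene %in% cand])
  set.seed(seed)
  null_scores <- vapply(seq_len(n_random), function(i)
    mean(scored$score[sample.int(nrow(scored), m)]), numeric(1))
  p <- max(sum(null_scores >= cand_score) / n_random, 1 / (n_random + 1))
  structure(list(candidate_score = cand_score, null_scores = null_scores,
                 p_value = p, n_candidates = m, n_random = n_random,
                 seed = seed),
            class = "gene_set_test")
}

#' @export
print.gene_set_test <- function(x, ...) {
  cat("Gene-set enrichment permutation test\n")
  cat("  candidates:", x$n_candidates, " random sets:", x$n_random, "\n")
  cat("  candidate mean score:", format(x$candidate_score, digits = 4),
      " null mean:", format(mean(x$null_scores), digits = 4), "\n")
  cat("  empirical p =", format(x$p_value, digits = 4), "\n")
  invisible(x)
}
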