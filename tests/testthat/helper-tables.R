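# Small deterministic fixtures built in code.

# Hand-written 6-locus, 2-population table on two chromosomes.
tiny_table <- function() {
  locus_table(
    name = c("rs1", "rs2", "rs3", "rs4", "rs5", "rs6"),
    chrom = c("chr1", "chr1", "chr1", "chr1", "chr2", "chr2"),
    pos = c(100L, 200L, 300L, 400L, 50L, 150L),
    het = rbind(c(0.42, 0.38), c(0.10, 0.20), c(0.50, 0.48),
                c(0.30, 0.30), c(0.25, 0.05), c(0.40, 0.44)),
    fst = c(0.05, 0.30, 0.00, 0.12, 0.60, 0.08))
}

# Random valid table with a single chromosome, built from frequencies so
# het/fst satisfy all invariants by construction.
random_table <- function(n = 50, seed = 1, chrom = "chr1") {
  set.seed(seed)
  p1 <- runif(n, 0.02, 0.98)
  p2 <- runif(n, 0.02, 0.98)
  locus_table(name = sprintf("L%03d", seq_len(n)),
              chrom = rep(chrom, n), pos = 10L * seq_len(n),
              het = cbind(expected_het(p1), expected_het(p2)),
              fst = fst_wright(cbind(p1, p2)))
}

# Constant-statistic table: every locus identical.
constant_table <- function(n = 30, het = c(0.3, 0.2), fst = 0.25) {
  locus_table(name = sprintf("C%03d", seq_len(n)),
              chrom = rep("chr1", n), pos = 100L * seq_len(n),
              het = matrix(rep(het, each = n), n), fst = rep(fst, n))
}

write_lines_tmp <- function(lines) {
  f <- tempfile(fileext = ".txt")
  writeLines(lines, f)
  f
}
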