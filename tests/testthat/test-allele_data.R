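test_that("read_freq_table maps the six-column layout onto locus records", {
  f <- write_lines_tmp(c("# comment",
                         "rs1 chr1 1000 0.42 0.38 0.05",
                         "rs2 chr1 2000 0.10 0.20 0.30"))
  tab <- read_freq_table(f, n_pops = 2)
  expect_s3_class(tab, "locus_table")
  expect_equal(tab$name, c("rs1", "rs2"))
  expect_equal(tab$pos, c(1000L, 2000L))
  expect_equal(tab$het1, c(0.42, 0.10))
  expect_equal(tab$het2, c(0.38, 0.20))
  expect_equal(tab$fst, c(0.05, 0.30))
  expect_equal(n_pops(tab), 2L)
})

test_that("reader sorts by chromosome and position and skips a header", {
  f <- write_lines_tmp(c("name chrom pos het1 het2 fst",
                         "rsB chr2 100 0.1 0.1 0.2",
                         "rsA chr1 500 0.2 0.2 0.1",
                         "rsC chr1 100 0.3 0.3 0.0"))
  tab <- read_freq_table(f)
  expect_equal(tab$name, c("rsC", "rsA", "rsB"))
  expect_equal(tab$chrom, c("chr1", "chr1", "chr2"))
})

test_that("malformed lines are reported with their line number", {
  f <- write_lines_tmp(c("rs1 chr1 1000 0.42 0.38 0.05",
                         "rs2 chr1 2000 0.10 0.20"))
  expect_error(read_freq_table(f), "line 2")
  f2 <- write_lines_tmp("rs1 chr1 1000 0.42 oops 0.05")
  expect_error(read_freq_table(f2), "non-numeric.*line 1")
  f3 <- write_lines_tmp("rs1 chr1 1000 0.80 0.38 0.05")
  expect_error(read_freq_table(f3), "heterozygosity")
  f4 <- write_lines_tmp("rs1 chr1 1000 0.40 0.38 1.50")
  expect_error(read_freq_table(f4), "F_ST")
})

test_that("multi-population layout reads n_pops het columns plus one fst", {
  f <- write_lines_tmp("rs1 chr1 10 0.1 0.2 0.3 0.15")
  tab <- read_freq_table(f, n_pops = 3)
  expect_equal(unname(unlist(tab[1, c("het1", "het2", "het3")])),
               c(0.1, 0.2, 0.3))
  expect_equal(tab$fst, 0.15)
})

test_that("expected heterozygosity is 2p(1-p) with domain checks", {
  expect_equal(expected_het(0.5), 0.5)
  expect_equal(expected_het(c(0, 1)), c(0, 0))
  expect_equal(expected_het(0.1), 0.18)
  expect_error(expected_het(1.2), "outside")
})

test_that("Wright F_ST matches hand-computed values and boundary cases", {
  expect_equal(fst_wright(c(0.5, 0.5)), 0)
  expect_equal(fst_wright(c(1, 0)), 1)
  # p = (0.8, 0.2): H_T = 0.5, H_S = 0.32 -> (0.5 - 0.32)/0.5 = 0.36
  expect_equal(fst_wright(c(0.8, 0.2)), 0.36)
  # monomorphic overall: H_T = 0 -> defined as 0
  expect_equal(fst_wright(c(0, 0)), 0)
})

test_that("F_ST is invariant to population order; het permutes with it", {
  set.seed(42)
  for (i in 1:20) {
    p <- runif(3)
    perm <- sample(3)
    expect_equal(fst_wright(p), fst_wright(p[perm]))
    expect_equal(expected_het(p)[perm], expected_het(p[perm]))
  }
})

test_that("size weighting shifts H_S and the pooled mean consistently", {
  p <- c(0.9, 0.1)
  unw <- fst_wright(p)
  w <- fst_wright(p, sizes = c(90, 10), weighted = TRUE)
  expect_true(w >= 0 && w <= 1)
  expect_false(isTRUE(all.equal(unw, w)))
  expect_equal(fst_wright(p, sizes = c(50, 50), weighted = TRUE), unw)
})

test_that("converter drops loci below the genotype-count threshold", {
  freq <- cbind(c(0.5, 0.3, 0.7), c(0.5, 0.8, 0.7))
  cnt <- sample_genotype_counts(freq, n = 20, seed = 3)
  # plant a low-count locus: 9 genotypes in population 2
  cnt$nAA2[2] <- 4L; cnt$nAa2[2] <- 3L; cnt$naa2[2] <- 2L
  expect_message(tab <- convert_genotypes(cnt, min_genotypes = 10),
                 "dropped 1")
  expect_equal(nrow(tab), 2L)
  expect_false(cnt$name[2] %in% tab$name)
  # at the threshold it is kept
  tab10 <- suppressMessages(convert_genotypes(cnt, min_genotypes = 9))
  expect_equal(nrow(tab10), 3L)
})

test_that("converter handles monomorphic and alternatively fixed loci", {
  cnt <- data.frame(name = c("m", "f"), chrom = "chr1", pos = c(1L, 2L),
                    nAA1 = c(10L, 10L), nAa1 = 0L, naa1 = c(0L, 0L),
                    nAA2 = c(10L, 0L), nAa2 = 0L, naa2 = c(0L, 10L))
  tab <- convert_genotypes(cnt)
  m <- tab[tab$name == "m", ]
  expect_equal(c(m$het1, m$het2, m$fst), c(0, 0, 0))
  f <- tab[tab$name == "f", ]
  expect_equal(c(f$het1, f$het2, f$fst), c(0, 0, 1))
})

test_that("converter output always satisfies locus-record invariants", {
  set.seed(7)
  freq <- matrix(runif(60), ncol = 2)
  cnt <- sample_genotype_counts(freq, n = 25, seed = 8)
  tab <- suppressMessages(convert_genotypes(cnt))
  expect_true(all(tab$het1 >= 0 & tab$het1 <= 0.5))
  expect_true(all(tab$het2 >= 0 & tab$het2 <= 0.5))
  expect_true(all(tab$fst >= 0 & tab$fst <= 1))
})

test_that("write/read round-trips a random table at 6 decimal places", {
  tab <- random_table(n = 100, seed = 11)
  f <- tempfile(fileext = ".txt")
  write_freq_table(tab, f)
  back <- read_freq_table(f, n_pops = 2)
  expect_equal(back$name, tab$name)
  expect_equal(back$pos, tab$pos)
  expect_lt(max(abs(back$het1 - tab$het1)), 1e-6)
  expect_lt(max(abs(back$het2 - tab$het2)), 1e-6)
  expect_lt(max(abs(back$fst - tab$fst)), 1e-6)
})

test_that("duplicate positions are kept with a warning", {
  expect_warning(
    locus_table(name = c("a", "b"), chrom = c("chr1", "chr1"),
                pos = c(10L, 10L), het = rbind(c(0.1, 0.1), c(0.2, 0.2)),
                fst = c(0, 0)),
    "duplicate")
})
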