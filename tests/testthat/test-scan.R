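test_that("a single-size scan reproduces the directly built percentile", {
  tab <- random_table(n = 60, seed = 51)
  r <- 2000L; seed <- 7L
  sc <- sweep_scan(tab, sizes = 5, r = r, seed = seed)
  # same seed, one chromosome, one size: the scan's first (only) baseline
  # draw matches a stand-alone build_null call
  for (stat in c("het1", "fst_mean", "fst_var")) {
    nd <- build_null(tab, 5, stat, r = r, seed = seed)
    center <- 30L
    ws <- window_summary(tab, "chr1", center, 5)
    obs <- switch(stat, het1 = ws$mean_het[1], fst_mean = ws$mean_fst,
                  fst_var = ws$s2_fst)
    tail <- if (stat == "het1") "lower" else "upper"
    expect_equal(sc$records[[paste0("p_", stat)]][center],
                 tail_percentile(nd, obs, tail))
    expect_equal(sc$records[[paste0("size_", stat)]][center], 5L)
    expect_equal(sc$records[[paste0("obs_", stat)]][center], unname(obs))
  }
})

test_that("aggregation keeps the most extreme percentile across sizes", {
  tab <- random_table(n = 80, seed = 52)
  r <- 1500L; seed <- 3L
  one <- sweep_scan(tab, sizes = 5, r = r, seed = seed)
  two <- sweep_scan(tab, sizes = c(5, 7), r = r, seed = seed)
  # size 5 is drawn first in both runs, so its percentiles coincide and
  # the two-size best can only be as extreme or more
  ev <- which(!is.na(two$records$p_fst_var) & !is.na(one$records$p_fst_var))
  for (stat in c("het1", "het2", "fst_mean", "fst_var")) {
    p1 <- one$records[[paste0("p_", stat)]][ev]
    p2 <- two$records[[paste0("p_", stat)]][ev]
    expect_true(all(p2 <= p1 + 1e-15))
    # ties across sizes resolve toward the smaller window
    same <- which(p2 == p1)
    expect_true(all(two$records[[paste0("size_", stat)]][ev][same] == 5L))
  }
  # -log10 dominance over each evaluated size
  expect_true(all(two$records$nlp_fst_var[ev] >= one$records$nlp_fst_var[ev]))
})

test_that("edge loci are marked unevaluated, with size counts per locus", {
  tab <- random_table(n = 9, seed = 53)
  sc <- sweep_scan(tab, sizes = c(5, 7), r = 1200, seed = 1)
  rec <- sc$records
  expect_equal(rec$n_sizes, c(0L, 0L, 1L, 2L, 2L, 2L, 1L, 0L, 0L))
  expect_true(all(is.na(rec$p_het1[rec$n_sizes == 0])))
  expect_true(all(rec$outcome[rec$n_sizes == 0] == "unevaluated"))
  expect_true(all(rec$outcome[rec$n_sizes > 0] != "unevaluated"))
})

test_that("a table with no chromosome long enough warns and is unevaluated", {
  tab <- random_table(n = 4, seed = 54)
  expect_warning(sc <- sweep_scan(tab, sizes = 5, r = 1000, seed = 1),
                 "unevaluated")
  expect_true(all(sc$records$outcome == "unevaluated"))
})

test_that("outcome classification follows the four-pattern rules", {
  rec <- data.frame(
    p_het1     = c(0.001, 0.001, 0.5, 0.001, 0.004, NA,  0.5),
    p_het2     = c(0.002, 0.800, 0.5, 0.003, 0.500, NA,  0.5),
    p_fst_mean = c(0.600, 0.500, 0.5, 0.200, 0.005, NA,  0.005),
    p_fst_var  = c(0.600, 0.001, 0.5, 0.008, 0.600, NA,  0.5))
  out <- classify_pattern(rec, alpha = 0.01)
  expect_equal(as.character(out),
               c("old_selection",          # both het low, fst quiet
                 "new_selection_one_pop",  # one het low + s2 high
                 "none",                   # nothing extreme
                 "new_selection_both",     # both het low + s2 high
                 "none",                   # one het low, no s2 support
                 "unevaluated",
                 "none"))                  # elevated mean fst alone
  expect_error(classify_pattern(rec, alpha = 0), "alpha")
})

test_that("-log10 transform is exact on pinned values", {
  expect_equal(neglog10(1), 0)
  expect_equal(neglog10(0.01), 2)
  expect_equal(neglog10(1 / (1e5 + 1)), log10(1e5 + 1))
  expect_equal(neglog10(1 / (1e5 + 1)), 5.0000043, tolerance = 1e-7)
  expect_error(neglog10(0), "percentile")
  expect_error(neglog10(1.5), "percentile")
})

test_that("scan tables round-trip through the tab-separated output", {
  tab <- random_table(n = 30, seed = 55)
  sc <- sweep_scan(tab, sizes = 5, r = 1100, seed = 2)
  f <- tempfile(fileext = ".tsv")
  write_scan_table(sc, f)
  back <- read_scan_table(f)
  expect_equal(nrow(back), 30L)
  expect_equal(back$p_fst_var, sc$records$p_fst_var, tolerance = 1e-9)
  expect_equal(back$nlp_het1, sc$records$nlp_het1, tolerance = 1e-9)
  expect_equal(back$outcome, as.character(sc$records$outcome))
})

test_that("z-score mode runs and ranks extremes in the same direction", {
  tab <- simulate_neutral(n_loci = 500, F = 0.1, seed = 56)
  tab <- inject_sweep(tab, "chr1", 250, 20, mode = "new_one_pop",
                      het_reduction = 0.05)
  sc <- sweep_scan(tab, sizes = c(5, 9), r = 2000, seed = 4,
                   method = "zscore")
  expect_true(all(sc$records$p_het1 > 0 & sc$records$p_het1 <= 1,
                  na.rm = TRUE))
  expect_lt(abs(peak_locus(sc, "het1") - 250), 30)
})

test_that("genome-wide pooling accepts short chromosomes into one baseline", {
  tabs <- lapply(1:3, function(i) random_table(20, 60 + i, paste0("chr", i)))
  tab <- do.call(rbind, lapply(tabs, as.data.frame))
  tab <- locus_table(tab$name, tab$chrom, tab$pos,
                     cbind(tab$het1, tab$het2), tab$fst)
  sc <- sweep_scan(tab, sizes = 5, r = 1500, seed = 9,
                   pool_scope = "genome")
  expect_equal(sum(!is.na(sc$records$p_fst_var)), 3 * (20 - 4))
})

test_that("peak locus breaks percentile-floor ties by the observed value", {
  rec <- data.frame(nlp_het1 = c(2, 3, 3, 1),
                    obs_het1 = c(0.1, 0.05, 0.02, 0.3),
                    nlp_fst_var = c(1, 2, 2, 0),
                    obs_fst_var = c(0.01, 0.08, 0.02, 0.001))
  expect_equal(peak_locus(rec, "het1"), 3L)      # lowest het among ties
  expect_equal(peak_locus(rec, "fst_var"), 2L)   # highest variance among ties
})

test_that("plot method draws tracks without error", {
  tab <- random_table(n = 40, seed = 57)
  sc <- sweep_scan(tab, sizes = 5, r = 1000, seed = 5)
  f <- tempfile(fileext = ".png")
  grDevices::png(f)
  expect_no_error(plot(sc, chrom = "chr1"))
  grDevices::dev.off()
  expect_true(file.exists(f))
  expect_error(plot(sc, chrom = "chrX"), "available")
})
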