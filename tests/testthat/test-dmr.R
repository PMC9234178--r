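rec_tbl <- function(pos, n_meth, n_total, context = "CG",
                    chrom = "chr1", strand = "+") {
  data.table::data.table(chrom = chrom, pos = as.integer(pos),
                         strand = strand, n_meth = as.integer(n_meth),
                         n_total = as.integer(n_total),
                         context = context)
}

test_that("dmr_criteria reproduces the four presets", {
  expect_equal(dmr_criteria("CG"),
               list(context = "CG", min_sites = 5L,
                    min_abs_diff = 0.25, max_q = 0.05))
  expect_equal(dmr_criteria("CHH"),
               list(context = "CHH", min_sites = 15L,
                    min_abs_diff = 0.15, max_q = 0.05))
  expect_equal(dmr_criteria("ALL_C")$min_sites, 20L)
  expect_equal(dmr_criteria("CHG")$min_abs_diff, 0.25)
  expect_error(dmr_criteria("CpG"))
})

test_that("tile_windows partitions each chromosome exactly", {
  t1 <- tile_windows(c(chrA = 1000L), window = 200L)
  expect_identical(nrow(t1), 5L)
  expect_identical(t1$start, seq(1L, 801L, by = 200L))
  expect_identical(t1$end, seq(200L, 1000L, by = 200L))
  ## non-multiple length: short final tile
  t2 <- tile_windows(c(chrA = 1001L), window = 200L)
  expect_identical(nrow(t2), 6L)
  expect_identical(t2$end[6], 1001L)
  expect_identical(t2$start[6], 1001L)
  ## partition property: disjoint, covering, width-summing
  t3 <- tile_windows(c(a = 757L, b = 1200L), window = 100L)
  expect_identical(sum(t3$end - t3$start + 1L), 757L + 1200L)
  for (ch in c("a", "b")) {
    tt <- t3[chrom == ch]
    expect_identical(tt$start[-1L], tt$end[-nrow(tt)] + 1L)
  }
  expect_error(tile_windows(integer(0)), "empty")
})

test_that("window_stats pools replicates and computes shared-site levels", {
  tiles <- tile_windows(c(chr1 = 400L), window = 200L)
  ## group A: two replicates pooling to 5/10 and 15/30 at two sites
  a1 <- rec_tbl(c(50, 60), c(2, 10), c(4, 10))
  a2 <- rec_tbl(c(50, 60), c(3, 5), c(6, 20))
  ## group B: one replicate, 2/20 and 2/20
  b1 <- rec_tbl(c(50, 60), c(2, 2), c(20, 20))
  w <- window_stats(list(a1, a2), b1, tiles, context = "CG")
  expect_identical(nrow(w), 1L)
  expect_identical(w$n_sites, 2L)
  expect_equal(w$level_a, 20 / 40)
  expect_equal(w$level_b, 4 / 40)
  expect_equal(w$diff_level, 0.4)
  expect_equal(w$p_value, fisher_enum_oracle(20, 20, 4, 36))
})

test_that("only sites covered in both groups count", {
  tiles <- tile_windows(c(chr1 = 200L), window = 200L)
  a <- rec_tbl(c(10, 20), c(5, 5), c(10, 10))
  b <- rec_tbl(c(10, 20), c(0, 3), c(0, 10))  # site 10 uncovered in B
  w <- window_stats(a, b, tiles, context = "CG")
  expect_identical(w$n_sites, 1L)
  expect_identical(w$total_a, 10L)
  ## min_coverage raises the bar symmetrically
  w2 <- window_stats(a, b, tiles, context = "CG", min_coverage = 11L)
  expect_identical(nrow(w2), 0L)
})

test_that("windows with no shared site are omitted; contexts separate", {
  tiles <- tile_windows(c(chr1 = 600L), window = 200L)
  a <- rec_tbl(c(50, 250), c(5, 5), c(10, 10), context = c("CG", "CHH"))
  b <- rec_tbl(c(50, 250), c(1, 1), c(10, 10), context = c("CG", "CHH"))
  w_cg <- window_stats(a, b, tiles, context = "CG")
  expect_identical(w_cg[, .(chrom, start)],
                   data.table::data.table(chrom = "chr1", start = 1L))
  w_chh <- window_stats(a, b, tiles, context = "CHH")
  expect_identical(w_chh$start, 201L)
  ## ALL_C pools both
  w_all <- window_stats(a, b, tiles, context = "ALL_C")
  expect_identical(nrow(w_all), 2L)
  expect_identical(unique(w_all$context), "ALL_C")
})

test_that("Fisher window test matches exhaustive enumeration", {
  ## all tables with margins <= 12 exactly, a denser sweep than random
  for (total_a in c(0, 1, 5, 12)) for (total_b in c(0, 3, 12)) {
    for (ma in 0:total_a) for (mb in 0:total_b) {
      expect_equal(test_window_fisher(ma, total_a, mb, total_b),
                   if (total_a == 0 || total_b == 0 ||
                       (ma + mb) == 0 ||
                       (total_a - ma + total_b - mb) == 0) 1 else
                     fisher_enum_oracle(ma, total_a - ma,
                                        mb, total_b - mb),
                   tolerance = 1e-12,
                   label = paste(ma, total_a, mb, total_b))
    }
  }
  ## degenerate all-zero and zero-margin tables return 1
  expect_equal(test_window_fisher(0, 0, 0, 0), 1)
  expect_equal(test_window_fisher(0, 10, 0, 10), 1)
  expect_equal(test_window_fisher(10, 10, 10, 10), 1)
  ## worked example: complete separation of 20 vs 20 reads
  expect_equal(test_window_fisher(20, 20, 0, 20),
               2 / choose(40, 20), tolerance = 1e-12)
})

test_that("call_dmrs applies BH genome-wide and the preset filters", {
  w <- data.table::data.table(
    chrom = "chr1", start = seq(1L, 801L, 200L),
    end = seq(200L, 1000L, 200L), context = "CG",
    n_sites = c(5L, 4L, 8L, 6L, 5L),
    meth_a = 1L, total_a = 10L, meth_b = 1L, total_b = 10L,
    level_a = c(0.5, 0.5, 0.5, 0.30, 0.5),
    level_b = c(0.1, 0.1, 0.1, 0.12, 0.1))
  w[, diff_level := level_a - level_b]
  w[, p_value := c(1e-6, 1e-6, 0.5, 1e-6, 0.06)]
  res <- call_dmrs(w, return_windows = TRUE)
  expect_equal(res$windows$q_value, bh_stepup_oracle(w$p_value))
  ## window 2 fails min_sites, 3 fails q, 4 fails min_abs_diff,
  ## 5 fails q after BH
  expect_identical(res$dmrs$start, c(1L, 801L)[1])
  expect_identical(res$dmrs$direction, "up")
  ## mixed-context input is rejected
  w2 <- data.table::copy(w)[3, context := "CHH"]
  expect_error(call_dmrs(w2), "single context")
  ## context/criteria mismatch is rejected
  expect_error(call_dmrs(w, criteria = dmr_criteria("CHH")), "match")
})

test_that("tightening any criterion never adds DMRs (monotonicity)", {
  set.seed(21)
  n <- 60L
  w <- data.table::data.table(
    chrom = "chr1", start = seq(1L, by = 200L, length.out = n),
    end = seq(200L, by = 200L, length.out = n), context = "CG",
    n_sites = sample(1:30, n, TRUE),
    meth_a = 0L, total_a = 10L, meth_b = 0L, total_b = 10L,
    level_a = runif(n), level_b = runif(n),
    p_value = runif(n)^3)
  w[, diff_level := level_a - level_b]
  base <- call_dmrs(w, criteria = list(context = "CG", min_sites = 5L,
                                       min_abs_diff = 0.2, max_q = 0.2))
  tighter <- list(
    list(context = "CG", min_sites = 10L, min_abs_diff = 0.2, max_q = 0.2),
    list(context = "CG", min_sites = 5L, min_abs_diff = 0.4, max_q = 0.2),
    list(context = "CG", min_sites = 5L, min_abs_diff = 0.2, max_q = 0.05))
  for (cr in tighter) {
    d <- call_dmrs(w, criteria = cr)
    expect_lte(nrow(d), nrow(base))
    expect_true(all(d$start %in% base$start))
  }
})

test_that("swapping the groups flips diff_level sign and direction", {
  tiles <- tile_windows(c(chr1 = 200L), window = 200L)
  a <- rec_tbl(seq(10, 100, 10), 9, 10)
  b <- rec_tbl(seq(10, 100, 10), 1, 10)
  wab <- window_stats(a, b, tiles, context = "CG")
  wba <- window_stats(b, a, tiles, context = "CG")
  expect_equal(wab$diff_level, -wba$diff_level)
  expect_equal(wab$p_value, wba$p_value)
  dab <- call_dmrs(wab)
  dba <- call_dmrs(wba)
  expect_identical(dab$direction, "up")
  expect_identical(dba$direction, "down")
})

test_that("the replicate t-test route agrees with direct Welch t", {
  tiles <- tile_windows(c(chr1 = 200L), window = 200L)
  pos <- seq(10, 100, 10)
  mk <- function(m) rec_tbl(pos, m, 10)
  ga <- list(mk(9), mk(8), mk(7))
  gb <- list(mk(2), mk(1), mk(3))
  w <- window_stats(ga, gb, tiles, context = "CG", test = "ttest")
  la <- c(0.9, 0.8, 0.7); lb <- c(0.2, 0.1, 0.3)
  expect_equal(w$p_value, t.test(la, lb)$p.value)
  ## fewer than two replicates per group: NA p-value
  w1 <- window_stats(mk(9), list(mk(1), mk(2)), tiles,
                     context = "CG", test = "ttest")
  expect_true(is.na(w1$p_value))
})

test_that("scan_dmrs wraps tiling, stats and calling consistently", {
  set.seed(31)
  lens <- c(chr1 = 2000L)
  pos <- sort(sample(1:2000, 120))
  a <- rec_tbl(pos, rbinom(120, 20, 0.5), 20)
  b <- rec_tbl(pos, rbinom(120, 20, 0.1), 20)
  res <- scan_dmrs(a, b, lens, context = "CG")
  manual <- call_dmrs(window_stats(a, b, tile_windows(lens),
                                   context = "CG"),
                      return_windows = TRUE)
  expect_equal(res$windows, manual$windows)
  expect_equal(res$dmrs, manual$dmrs)
  expect_true(all(res$dmrs$direction == "up"))
})
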