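## Tiled genome scan for differentially methylated regions (DMRs).
##
## The genome is partitioned into consecutive 200 bp tiles; within each
## tile and sequence context, replicate read counts are pooled per
## group, the two pooled proportions are compared by Fisher's exact
## test, q-values are computed genome-wide per context by
## Benjamini-Hochberg, and context-specific filters on covered site
## count, absolute level difference and q define DMRs.

#' Context-specific DMR filter presets
#'
#' Four built-in rule sets (minimum covered context sites per window,
#' minimum absolute methylation difference, maximum q):
#' CG (5, 0.25, 0.05); CHG (5, 0.25, 0.05); CHH (15, 0.15, 0.05);
#' ALL_C (20, 0.20, 0.05).
#'
#' @param context One of `"CG"`, `"CHG"`, `"CHH"`, `"ALL_C"`.
#' @return List with `context`, `min_sites`, `min_abs_diff`, `max_q`.
#' @export
dmr_criteria <- function(context = c("CG", "CHG", "CHH", "ALL_C")) {
  context <- match.arg(context)
  presets <- list(
    CG    = list(min_sites = 5L,  min_abs_diff = 0.25, max_q = 0.05),
    CHG   = list(min_sites = 5L,  min_abs_diff = 0.25, max_q = 0.05),
    CHH   = list(min_sites = 15L, min_abs_diff = 0.15, max_q = 0.05),
    ALL_C = list(min_sites = 20L, min_abs_diff = 0.20, max_q = 0.05))
  c(list(context = context), presets[[context]])
}

#' Tile a genome into consecutive fixed-width windows
#'
#' @param genome A [Biostrings::DNAStringSet] or a named integer vector
#'   of chromosome lengths.
#' @param window Window width in bp (default 200).
#' @return `data.table` with `chrom`, `start`, `end` (1-based
#'   inclusive); the last tile of each chromosome may be shorter.
#' @export
tile_windows <- function(genome, window = 200L) {
  if (inherits(genome, "DNAStringSet")) {
    lens <- setNames(Biostrings::width(genome), names(genome))
  } else {
    lens <- genome
  }
  if (length(lens) == 0L) stop("empty genome", call. = FALSE)
  out <- lapply(names(lens), function(ch) {
    L <- as.integer(lens[[ch]])
    starts <- seq.int(1L, L, by = window)
    data.table::data.table(chrom = ch, start = starts,
                           end = pmin(starts + window - 1L, L))
  })
  data.table::rbindlist(out)
}

#' @keywords internal
#' @noRd
.pool_replicates <- function(reps) {
  if (data.table::is.data.table(reps)) reps <- list(reps)
  if (length(reps) == 0L) {
    stop("a group must contain at least one replicate", call. = FALSE)
  }
  pooled <- data.table::rbindlist(reps)[
    , .(n_meth = sum(n_meth), n_total = sum(n_total)),
    by = .(chrom, pos, strand, context)]
  pooled
}

#' Per-window pooled methylation statistics for a two-group comparison
#'
#' Replicates are pooled within each group by read-count summation.
#' `n_sites` counts cytosines of the requested context covered (at
#' least `min_coverage` pooled reads) in *both* groups; pooled counts
#' and levels are computed over those shared sites, so the two group
#' levels describe the same site set.  Windows with no shared covered
#' site are omitted.  The window p-value is a two-sided Fisher's exact
#' test on the pooled 2x2 count table, or optionally a Welch t-test on
#' per-replicate window levels.
#'
#' @param group_a,group_b Lists of replicate cytosine record tables (a
#'   single `data.table` is treated as one replicate).  Orientation:
#'   `diff_level = level_a - level_b`, so "up" later means
#'   hypermethylated in group A.
#' @param tiles Tile table from [tile_windows()].
#' @param context `"CG"`, `"CHG"`, `"CHH"` or `"ALL_C"` (all contexts
#'   combined).
#' @param min_coverage Minimum pooled reads per group for a site to
#'   count as covered (default 1).
#' @param test `"fisher"` (default) or `"ttest"`.
#' @return `data.table` of window statistics: `chrom`, `start`, `end`,
#'   `context`, `n_sites`, `meth_a`, `total_a`, `meth_b`, `total_b`,
#'   `level_a`, `level_b`, `diff_level`, `p_value`.
#' @export
window_stats <- function(group_a, group_b, tiles,
                         context = c("CG", "CHG", "CHH", "ALL_C"),
                         min_coverage = 1L,
                         test = c("fisher", "ttest")) {
  ctx <- match.arg(context)
  test <- match.arg(test)
  pa <- .pool_replicates(group_a)
  pb <- .pool_replicates(group_b)
  if (ctx != "ALL_C") {
    pa <- pa[context == ctx]
    pb <- pb[context == ctx]
  }
  shared <- merge(pa, pb, by = c("chrom", "pos", "strand", "context"),
                  suffixes = c("_a", "_b"))
  shared <- shared[n_total_a >= min_coverage &
                     n_total_b >= min_coverage]
  if (nrow(shared) == 0L) {
    return(.empty_window_stats(ctx))
  }
  ## assign sites to tiles
  tl <- data.table::copy(tiles)
  data.table::setkey(tl, chrom, start, end)
  s <- shared[, .(chrom, start = pos, end = pos, strand, pos,
                  n_meth_a, n_total_a, n_meth_b, n_total_b)]
  ov <- data.table::foverlaps(s, tl, type = "within",
                              by.x = c("chrom", "start", "end"),
                              nomatch = NULL)
  w <- ov[, .(n_sites = .N,
              meth_a = sum(n_meth_a), total_a = sum(n_total_a),
              meth_b = sum(n_meth_b), total_b = sum(n_total_b)),
          by = .(chrom, start, end)]
  w[, `:=`(context = ctx,
           level_a = meth_a / total_a,
           level_b = meth_b / total_b)]
  w[, diff_level := level_a - level_b]

  if (test == "fisher") {
    w[, p_value := mapply(test_window_fisher, meth_a, total_a,
                          meth_b, total_b)]
  } else {
    w[, p_value := .ttest_windows(group_a, group_b, w, ctx,
                                  min_coverage)]
  }
  data.table::setorder(w, chrom, start)
  data.table::setcolorder(w, c("chrom", "start", "end", "context",
                               "n_sites", "meth_a", "total_a",
                               "meth_b", "total_b", "level_a",
                               "level_b", "diff_level", "p_value"))
  w[]
}

#' @keywords internal
#' @noRd
.empty_window_stats <- function(ctx) {
  data.table::data.table(
    chrom = character(0), start = integer(0), end = integer(0),
    context = character(0), n_sites = integer(0), meth_a = integer(0),
    total_a = integer(0), meth_b = integer(0), total_b = integer(0),
    level_a = numeric(0), level_b = numeric(0),
    diff_level = numeric(0), p_value = numeric(0))
}

#' Two-sided Fisher's exact test on a pooled window count table
#'
#' Tests `[[meth_a, total_a - meth_a], [meth_b, total_b - meth_b]]`.
#' Degenerate tables (any zero margin) return `p = 1` by convention.
#'
#' @param meth_a,total_a,meth_b,total_b Pooled counts.
#' @return Two-sided p-value.
#' @export
test_window_fisher <- function(meth_a, total_a, meth_b, total_b) {
  a <- meth_a; b <- total_a - meth_a
  c_ <- meth_b; d <- total_b - meth_b
  if (total_a == 0 || total_b == 0 ||
      (a + c_) == 0 || (b + d) == 0) {
    return(1)
  }
  fisher.test(matrix(c(a, b, c_, d), nrow = 2, byrow = TRUE))$p.value
}

#' @keywords internal
#' @noRd
.ttest_windows <- function(group_a, group_b, w, ctx, min_coverage) {
  ## per-replicate weighted window levels, Welch t across replicates
  rep_levels <- function(reps) {
    if (data.table::is.data.table(reps)) reps <- list(reps)
    lapply(reps, function(r) {
      rr <- if (ctx == "ALL_C") r else r[context == ctx]
      rr <- rr[n_total > 0]
      key <- w[, .(chrom, start, end)]
      data.table::setkey(key, chrom, start, end)
      s <- rr[, .(chrom, start = pos, end = pos, n_meth, n_total)]
      ov <- data.table::foverlaps(s, key, type = "within",
                                  by.x = c("chrom", "start", "end"),
                                  nomatch = NULL)
      ov[, .(level = sum(n_meth) / sum(n_total)),
         by = .(chrom, start, end)]
    })
  }
  la <- rep_levels(group_a)
  lb <- rep_levels(group_b)
  key <- w[, .(chrom, start, end)]
  collect <- function(ls) {
    ## one column per replicate; keep the matrix shape even for a
    ## single window
    cols <- lapply(ls, function(d) {
      m <- merge(key, d, by = c("chrom", "start", "end"),
                 all.x = TRUE, sort = FALSE)
      m$level
    })
    matrix(unlist(cols), nrow = nrow(key))
  }
  ma <- collect(la); mb <- collect(lb)
  vapply(seq_len(nrow(w)), function(i) {
    xa <- ma[i, ]; xb <- mb[i, ]
    xa <- xa[!is.na(xa)]; xb <- xb[!is.na(xb)]
    if (length(xa) < 2L || length(xb) < 2L) return(NA_real_)
    if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
      return(if (mean(xa) == mean(xb)) 1 else 0)
    }
    t.test(xa, xb)$p.value
  }, numeric(1))
}

#' Apply context-specific DMR criteria with genome-wide BH correction
#'
#' q-values are Benjamini-Hochberg across all tested windows of the
#' context (one family per comparison per context, genome-wide).  A
#' window is a DMR when `n_sites >= min_sites`, `|diff_level| >=
#' min_abs_diff` and `q <= max_q`; direction is `up` when group A is
#' hypermethylated (`diff_level > 0`), `down` otherwise.
#'
#' @param windows Window table from [window_stats()] (one context).
#' @param criteria A [dmr_criteria()] preset (defaults to the preset of
#'   the windows' context).
#' @param return_windows If `TRUE`, return
#'   `list(windows = <with q_value>, dmrs = <DMR table>)`.
#' @return DMR `data.table` (window columns plus `q_value` and
#'   `direction`), or the list described above.
#' @export
call_dmrs <- function(windows, criteria = NULL, return_windows = FALSE) {
  if (nrow(windows)) {
    ctx <- unique(windows$context)
    if (length(ctx) != 1L) {
      stop("call_dmrs expects windows of a single context",
           call. = FALSE)
    }
    if (is.null(criteria)) criteria <- dmr_criteria(ctx)
    if (!identical(criteria$context, ctx)) {
      stop("criteria context (", criteria$context,
           ") does not match windows (", ctx, ")", call. = FALSE)
    }
  } else if (is.null(criteria)) {
    criteria <- dmr_criteria("CG")
  }
  w <- data.table::copy(windows)
  w[, q_value := p.adjust(p_value, method = "BH")]
  dmrs <- w[n_sites >= criteria$min_sites &
              abs(diff_level) >= criteria$min_abs_diff &
              q_value <= criteria$max_q]
  dmrs <- data.table::copy(dmrs)
  dmrs[, direction := data.table::fifelse(diff_level > 0, "up", "down")]
  if (return_windows) list(windows = w[], dmrs = dmrs[]) else dmrs[]
}

#' Full tiled DMR scan for one context
#'
#' Convenience wrapper: [tile_windows()] + [window_stats()] +
#' [call_dmrs()].
#'
#' @inheritParams window_stats
#' @param genome Genome (`DNAStringSet` or named lengths) to tile.
#' @param window Tile width in bp.
#' @param criteria Optional [dmr_criteria()] override.
#' @return `list(windows, dmrs)`.
#' @export
scan_dmrs <- function(group_a, group_b, genome, context = "CG",
                      window = 200L, min_coverage = 1L,
                      test = "fisher", criteria = NULL) {
  tiles <- tile_windows(genome, window = window)
  w <- window_stats(group_a, group_b, tiles, context = context,
                    min_coverage = min_coverage, test = test)
  call_dmrs(w, criteria = criteria, return_windows = TRUE)
}
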