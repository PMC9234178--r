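## FPKM quantification and a simple two-group DEG caller.

#' Compute FPKM from a count table
#'
#' `fpkm = count / (length_bp / 1e3) / (library_size / 1e6)` with
#' library size defaulting to the per-sample total count.
#'
#' @param counts `data.table`/`data.frame` with `gene_id`, `length_bp`
#'   and one count column per sample.
#' @param library_sizes Optional named numeric vector of per-sample
#'   library sizes; defaults to column sums.
#' @return `data.table` of the same shape with counts replaced by FPKM.
#' @export
compute_fpkm <- function(counts, library_sizes = NULL) {
  dt <- data.table::as.data.table(counts)
  if (!all(c("gene_id", "length_bp") %in% names(dt))) {
    stop("counts must have gene_id and length_bp columns",
         call. = FALSE)
  }
  if (any(dt$length_bp <= 0)) {
    stop("gene lengths must be positive", call. = FALSE)
  }
  samples <- setdiff(names(dt), c("gene_id", "length_bp"))
  if (is.null(library_sizes)) {
    library_sizes <- vapply(samples, function(s) sum(dt[[s]]),
                            numeric(1))
  }
  if (any(library_sizes == 0)) {
    stop("zero library size for: ",
         paste(samples[library_sizes == 0], collapse = ","),
         call. = FALSE)
  }
  out <- dt[, .(gene_id, length_bp)]
  for (s in samples) {
    out[[s]] <- dt[[s]] / (dt$length_bp / 1e3) /
      (library_sizes[[s]] / 1e6)
  }
  out[]
}

#' Call differentially expressed genes between two groups
#'
#' Expression is quantified as FPKM; the per-gene test is a two-sample
#' pooled-variance t-test on `log2(FPKM + 1)` across replicates (with
#' >= 2 replicates per group), or an exact binomial split test on
#' pooled counts for a 1 vs 1 design.  The pooled-variance form is
#' used because with three replicates the Welch approximation can
#' collapse to two degrees of freedom whenever one group's variance
#' shrinks, flooring attainable p-values above the BH threshold.  P-values are Benjamini-Hochberg corrected.  The DEG
#' rule is `q < 0.05` and `|log2 fold change| > 1`, where the fold
#' change is `log2((mean FPKM A + pseudocount) / (mean FPKM B +
#' pseudocount))`; `up` means higher in group A.
#'
#' @param counts Count table (`gene_id`, `length_bp`, sample columns).
#' @param group_a,group_b Character vectors of sample column names.
#' @param alpha FDR threshold (default 0.05).
#' @param lfc_min Minimum absolute log2 fold change (default 1).
#' @param pseudocount Pseudocount for the fold change (default 1).
#' @return `data.table` with `gene_id`, `mean_fpkm_a`, `mean_fpkm_b`,
#'   `log2_fc`, `p_value`, `q_value`, `is_deg`, `direction`.
#' @export
call_degs <- function(counts, group_a, group_b, alpha = 0.05,
                      lfc_min = 1, pseudocount = 1) {
  dt <- data.table::as.data.table(counts)
  missing_cols <- setdiff(c(group_a, group_b), names(dt))
  if (length(missing_cols)) {
    stop("sample columns not found: ",
         paste(missing_cols, collapse = ","), call. = FALSE)
  }
  if (length(group_a) < 1L || length(group_b) < 1L) {
    stop("each group needs at least one sample", call. = FALSE)
  }
  fpkm <- compute_fpkm(dt)
  fa <- as.matrix(fpkm[, group_a, with = FALSE])
  fb <- as.matrix(fpkm[, group_b, with = FALSE])
  mean_a <- rowMeans(fa)
  mean_b <- rowMeans(fb)
  lfc <- log2((mean_a + pseudocount) / (mean_b + pseudocount))

  if (length(group_a) >= 2L && length(group_b) >= 2L) {
    la <- log2(fa + 1); lb <- log2(fb + 1)
    p <- vapply(seq_len(nrow(la)), function(i) {
      xa <- la[i, ]; xb <- lb[i, ]
      if (stats::sd(xa) == 0 && stats::sd(xb) == 0) {
        return(if (mean(xa) == mean(xb)) 1 else 0)
      }
      t.test(xa, xb, var.equal = TRUE)$p.value
    }, numeric(1))
  } else if (length(group_a) == 1L && length(group_b) == 1L) {
    ## 1 vs 1: exact binomial split of pooled counts by library size
    ca <- dt[[group_a]]; cb <- dt[[group_b]]
    la_size <- sum(ca); lb_size <- sum(cb)
    pr <- la_size / (la_size + lb_size)
    p <- vapply(seq_along(ca), function(i) {
      tot <- ca[i] + cb[i]
      if (tot == 0) return(1)
      binom.test(ca[i], tot, p = pr)$p.value
    }, numeric(1))
  } else {
    stop("unbalanced 1 vs >=2 designs are not supported",
         call. = FALSE)
  }
  res <- data.table::data.table(
    gene_id = dt$gene_id, mean_fpkm_a = mean_a, mean_fpkm_b = mean_b,
    log2_fc = lfc, p_value = p,
    q_value = p.adjust(p, method = "BH"))
  res[, is_deg := q_value < alpha & abs(log2_fc) > lfc_min]
  res[, direction := data.table::fifelse(log2_fc > 0, "up", "down")]
  res[]
}
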