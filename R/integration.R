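## Methylation-expression integration: methylation classes, Spearman
## correlation across genes, and the DMG x DEG concordance table.

#' Assign genes to non/low/middle/high methylation classes
#'
#' Within each (region, context), genes with no covered sites or a
#' weighted level of exactly zero are `non` (the `covered` column
#' separates absence of signal from absence of data).  The remaining
#' genes are split at the empirical 1/3 and 2/3 quantiles of their
#' levels into `low`/`middle`/`high`, ties going to the lower class.
#' When the two cut-points coincide (e.g. all non-zero levels equal)
#' genes at the common value are `middle`; with fewer than three
#' non-zero genes all of them are `middle`.
#'
#' @param feature_levels Output of [assign_sites_to_elements()],
#'   typically restricted to the regions of interest.
#' @param regions Element classes to classify (default the three
#'   regions used for integration).
#' @param probs The two quantile cut-points.
#' @return `data.table` with `gene_id`, `region`, `context`, `level`,
#'   `n_reads`, `covered`, `class`.
#' @export
classify_methylation_groups <- function(feature_levels,
                                        regions = c("upstream_2k",
                                                    "gene_body",
                                                    "downstream_2k"),
                                        probs = c(1 / 3, 2 / 3)) {
  fl <- feature_levels[element %in% regions,
                       .(gene_id, region = element, context, level,
                         n_reads)]
  fl[, covered := n_reads > 0]
  fl[, class := "non"]
  classify_one <- function(lv) {
    cls <- rep("non", length(lv))
    nz <- !is.na(lv) & lv > 0
    if (sum(nz) < 3L) {
      cls[nz] <- "middle"
      return(cls)
    }
    q <- quantile(lv[nz], probs = probs, names = FALSE)
    if (q[1] == q[2]) {
      cls[nz] <- data.table::fcase(lv[nz] < q[1], "low",
                                   lv[nz] == q[1], "middle",
                                   default = "high")
    } else {
      cls[nz] <- data.table::fcase(lv[nz] <= q[1], "low",
                                   lv[nz] <= q[2], "middle",
                                   default = "high")
    }
    cls
  }
  fl[, class := classify_one(level), by = .(region, context)]
  fl[]
}

#' Spearman correlation of regional methylation with expression
#'
#' Correlates per-gene methylation levels with mean expression across
#' genes, separately per region and context.  The p-value uses the
#' exact permutation distribution for n <= 10 without ties and the
#' t-approximation otherwise.  Cells with fewer than 3 genes or a
#' constant vector report `NA` with `n` still filled in.
#'
#' @param feature_levels Output of [assign_sites_to_elements()].
#' @param expression `data.table` with `gene_id` and `mean_fpkm` (e.g.
#'   row means of a [compute_fpkm()] table).
#' @param regions Element classes to correlate.
#' @return `data.table` with `region`, `context`, `rho`, `p_value`,
#'   `n`.
#' @export
correlate_methylation_expression <- function(feature_levels, expression,
                                             regions = c("upstream_2k",
                                                         "gene_body",
                                                         "downstream_2k")) {
  fl <- feature_levels[element %in% regions & n_reads > 0,
                       .(gene_id, region = element, context, level)]
  m <- merge(fl, expression[, .(gene_id, mean_fpkm)], by = "gene_id")
  out <- m[, {
    n <- .N
    if (n < 3L || stats::sd(level) == 0 || stats::sd(mean_fpkm) == 0) {
      list(rho = NA_real_, p_value = NA_real_, n = n)
    } else {
      exact <- n <= 10L && !anyDuplicated(level) &&
        !anyDuplicated(mean_fpkm)
      ct <- suppressWarnings(
        cor.test(level, mean_fpkm, method = "spearman", exact = exact))
      list(rho = unname(ct$estimate), p_value = ct$p.value, n = n)
    }
  }, by = .(region, context)]
  data.table::setorder(out, region, context)
  out[]
}

#' Cross-tabulate DMR direction against DEG direction
#'
#' Inner-joins DMG and DEG tables (same comparison, same orientation:
#' `up` = higher in group A) on gene id.  Each record is one
#' (gene, DMR, region) with the DMR direction, DEG direction and the
#' sign of the methylation-expression relationship (`positive` when
#' the directions agree, `negative` when they oppose).  The region is
#' where the DMR hit the gene (`upstream_2k`, `gene_body`,
#' `downstream_2k`); a DMR hitting several regions yields one record
#' per region.
#'
#' @param dmgs `dmgs` table from [assign_dmrs_to_genes()].
#' @param degs Table from [call_degs()]; only rows with `is_deg` are
#'   used.
#' @return List with `records` and `counts` (per region x
#'   dmr_direction x deg_direction with `correlation_sign`).
#' @export
intersect_dmg_deg <- function(dmgs, degs) {
  if (!("direction" %in% names(dmgs)) ||
      !("direction" %in% names(degs))) {
    stop("both inputs must carry a direction column", call. = FALSE)
  }
  deg_hits <- degs[is_deg == TRUE, .(gene_id, deg_direction = direction)]
  regions <- c("upstream_2k", "gene_body", "downstream_2k")
  empty <- data.table::data.table(
    gene_id = character(0), dmr_id = character(0), region = character(0),
    dmr_direction = character(0), deg_direction = character(0),
    correlation_sign = character(0))
  if (nrow(dmgs) == 0L || nrow(deg_hits) == 0L) {
    return(list(records = empty,
                counts = empty[, .N,
                               by = .(region, dmr_direction,
                                      deg_direction, correlation_sign)]))
  }
  ## expand element_hit into the integration regions it covers
  recs <- dmgs[, {
    hit <- strsplit(element_hit, ",", fixed = TRUE)[[1]]
    list(region = intersect(regions, hit))
  }, by = .(gene_id, dmr_id, dmr_direction = direction)]
  recs <- merge(recs, deg_hits, by = "gene_id")
  recs[, correlation_sign := data.table::fifelse(
    dmr_direction == deg_direction, "positive", "negative")]
  data.table::setcolorder(recs, c("gene_id", "dmr_id", "region",
                                  "dmr_direction", "deg_direction",
                                  "correlation_sign"))
  counts <- recs[, .N, by = .(region, dmr_direction, deg_direction,
                              correlation_sign)]
  data.table::setorder(counts, region, dmr_direction, deg_direction)
  list(records = recs[], counts = counts[])
}
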