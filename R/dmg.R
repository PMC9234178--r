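## DMR-associated genes (DMGs) and gene-set enrichment.

#' Assign DMRs to genes by overlap with functional regions
#'
#' A gene's functional region is its body plus the 2 kb flanks (and
#' their sub-elements).  Overlap is >= 1 bp intersection between the
#' DMR window and any element interval; a DMR overlapping two genes
#' yields two records; `element_hit` lists every element class
#' intersected.  DMRs overlapping no gene are returned in the
#' `intergenic` ledger so that counts conserve
#' (`nrow(dmrs) == mapped DMRs + intergenic DMRs`).
#'
#' @param dmrs DMR table from [call_dmrs()].
#' @param elements Element table from [read_annotation()].
#' @return List with `dmgs` (`gene_id`, `dmr_id`, `chrom`, `start`,
#'   `end`, `context`, `direction`, `q_value`, `element_hit`) and
#'   `intergenic` (unmapped DMR rows).
#' @export
assign_dmrs_to_genes <- function(dmrs, elements) {
  d <- data.table::copy(dmrs)
  d[, dmr_id := sprintf("dmr_%05d", seq_len(.N))]
  if (nrow(d) == 0L) {
    return(list(dmgs = data.table::data.table(
      gene_id = character(0), dmr_id = character(0),
      chrom = character(0), start = integer(0), end = integer(0),
      context = character(0), direction = character(0),
      q_value = numeric(0), element_hit = character(0)),
      intergenic = d))
  }
  el <- elements[, .(gene_id, chrom, element, start, end)]
  data.table::setkey(el, chrom, start, end)
  ov <- data.table::foverlaps(
    d[, .(chrom, start, end, dmr_id)], el, type = "any",
    by.x = c("chrom", "start", "end"), nomatch = NULL)
  dmgs <- ov[, .(element_hit = paste(sort(unique(element)),
                                     collapse = ",")),
             by = .(gene_id, dmr_id)]
  dmgs <- merge(dmgs,
                d[, .(dmr_id, chrom, start, end, context, direction,
                      q_value)],
                by = "dmr_id")
  data.table::setcolorder(dmgs, c("gene_id", "dmr_id", "chrom",
                                  "start", "end", "context",
                                  "direction", "q_value",
                                  "element_hit"))
  data.table::setorder(dmgs, gene_id, start)
  intergenic <- d[!(dmr_id %in% dmgs$dmr_id)]
  list(dmgs = dmgs[], intergenic = intergenic[])
}

#' Hypergeometric gene-set enrichment
#'
#' For each term with `K` genes in a universe of `N`, a query set of
#' `n` genes with `k` hits gets the upper-tail hypergeometric
#' probability `P(X >= k)`, followed by Benjamini-Hochberg correction
#' across terms.  Term membership is an opaque term -> gene mapping
#' (e.g. from a two-column TSV); no ontology structure is assumed.
#'
#' @param gene_set Character vector of query genes (subset of the
#'   universe; genes outside it are dropped with a warning).
#' @param universe Character vector of all genes.
#' @param term_map Named list of character vectors (term -> genes) or a
#'   `data.frame` with columns `term_id`, `gene_id`.
#' @return `data.table` with `term_id`, `term_size`, `hits`,
#'   `set_size`, `universe_size`, `p_value`, `q_value`.
#' @export
enrich_terms <- function(gene_set, universe, term_map) {
  universe <- unique(universe)
  if (length(universe) == 0L) stop("empty universe", call. = FALSE)
  gene_set <- unique(gene_set)
  outside <- setdiff(gene_set, universe)
  if (length(outside)) {
    warning(length(outside), " query genes outside the universe ",
            "were dropped")
    gene_set <- intersect(gene_set, universe)
  }
  if (is.data.frame(term_map)) {
    tm <- data.table::as.data.table(term_map)
    term_map <- split(tm$gene_id, tm$term_id)
  }
  N <- length(universe)
  n <- length(gene_set)
  res <- data.table::rbindlist(lapply(names(term_map), function(t) {
    tg <- intersect(unique(term_map[[t]]), universe)
    K <- length(tg)
    k <- length(intersect(gene_set, tg))
    p <- phyper(k - 1, K, N - K, n, lower.tail = FALSE)
    data.table::data.table(term_id = t, term_size = K, hits = k,
                           set_size = n, universe_size = N,
                           p_value = p)
  }))
  res[, q_value := p.adjust(p_value, method = "BH")]
  data.table::setorder(res, p_value)
  res[]
}
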