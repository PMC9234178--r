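## Per-element methylation levels and binned metagene profiles.

#' Per-gene, per-element, per-context methylation levels
#'
#' A site contributes to every element interval it falls in (a CDS site
#' is also exon and gene_body) and to every overlapping gene; flank
#' orientation follows the gene's strand via the element table.  Levels
#' are read-count weighted within each (gene, element, context) cell;
#' the `ALL` context pools CG, CHG and CHH.  Cells with no covered site
#' are emitted with `n_reads = 0` and an undefined (`NA`) level.
#'
#' @param records Cytosine record `data.table`.
#' @param elements Element table from [read_annotation()] or
#'   [build_gene_elements()].
#' @return `data.table` with `gene_id`, `element`, `context`, `level`,
#'   `n_sites`, `n_reads`.
#' @export
assign_sites_to_elements <- function(records, elements) {
  el <- elements[, .(gene_id, chrom, element, start, end)]
  data.table::setkey(el, chrom, start, end)
  s <- records[n_total > 0,
               .(chrom, start = pos, end = pos, context, n_meth,
                 n_total)]
  ov <- data.table::foverlaps(s, el, type = "within",
                              by.x = c("chrom", "start", "end"),
                              nomatch = NULL)
  agg <- ov[, .(n_meth = sum(n_meth), n_reads = sum(n_total),
                n_sites = .N),
            by = .(gene_id, element, context)]
  agg_all <- ov[, .(n_meth = sum(n_meth), n_reads = sum(n_total),
                    n_sites = .N, context = "ALL"),
                by = .(gene_id, element)]
  agg <- data.table::rbindlist(list(agg, agg_all), use.names = TRUE)

  ## full grid so uncovered cells are reported explicitly
  grid <- data.table::CJ(gene_id = unique(elements$gene_id),
                         element = unique(elements$element),
                         context = c("CG", "CHG", "CHH", "ALL"))
  ## restrict to element classes each gene actually has
  have <- unique(elements[, .(gene_id, element)])
  grid <- grid[have, on = c("gene_id", "element")]
  out <- agg[grid, on = c("gene_id", "element", "context")]
  out[is.na(n_reads), `:=`(n_meth = 0L, n_reads = 0L, n_sites = 0L)]
  out[, level := data.table::fifelse(n_reads > 0,
                                     n_meth / n_reads, NA_real_)]
  out[, n_meth := NULL]
  data.table::setcolorder(out, c("gene_id", "element", "context",
                                 "level", "n_sites", "n_reads"))
  data.table::setorder(out, gene_id, element, context)
  out[]
}

#' Binned metagene methylation profile
#'
#' Flanks are binned in fixed steps (`flank_size / bins_upstream`, 100
#' bp at the defaults); gene bodies are mapped to the fractional
#' coordinate `(pos - start) / (end - start)` and binned, so bodies of
#' different lengths are length-normalised.  Minus-strand genes are
#' reflected so bin 1 is always the 5'-most position.  Per-bin levels
#' are read-count weighted, pooled over all genes.
#'
#' @param records Cytosine record `data.table`.
#' @param elements Element table (gene spans and strands are taken from
#'   it).
#' @param bins_upstream,bins_body,bins_downstream Bin counts
#'   (defaults 20/40/20).
#' @param flank_size Flank width in bp (default 2000).
#' @return `data.table` with `region` (`upstream`, `body`,
#'   `downstream`), `bin` (1-based, 5' to 3'), `context` (including
#'   `ALL`), `level`, `n_reads`.
#' @export
metagene_profile <- function(records, elements, bins_upstream = 20L,
                             bins_body = 40L, bins_downstream = 20L,
                             flank_size = 2000L) {
  stopifnot(bins_upstream >= 1L, bins_body >= 1L, bins_downstream >= 1L)
  genes <- gene_spans(elements)
  ext <- genes[, .(gene_id, chrom, strand, g_start = start,
                   g_end = end, start = pmax(1L, start - flank_size),
                   end = end + flank_size)]
  data.table::setkey(ext, chrom, start, end)
  s <- records[n_total > 0,
               .(chrom, start = pos, end = pos, pos, context, n_meth,
                 n_total)]
  ov <- data.table::foverlaps(s, ext, type = "within",
                              by.x = c("chrom", "start", "end"),
                              nomatch = NULL)
  if (nrow(ov) == 0L) {
    return(data.table::data.table(region = character(0),
                                  bin = integer(0),
                                  context = character(0),
                                  level = numeric(0),
                                  n_reads = integer(0)))
  }
  ## reflect minus-strand genes so the 5' flank is always "left"
  ov[, rel := data.table::fifelse(strand == "+", pos,
                                  g_start + g_end - pos)]
  ov[, region := data.table::fcase(rel < g_start, "upstream",
                                   rel > g_end, "downstream",
                                   default = "body")]
  up_step <- flank_size / bins_upstream
  dn_step <- flank_size / bins_downstream
  ov[region == "upstream",
     bin := pmax(1L, pmin(bins_upstream,
                          as.integer(ceiling((rel - (g_start -
                            flank_size) + 1L) / up_step))))]
  ov[region == "downstream",
     bin := pmax(1L, pmin(bins_downstream,
                          as.integer(ceiling((rel - g_end) /
                                             dn_step))))]
  ov[region == "body",
     bin := data.table::fifelse(
       g_end > g_start,
       pmin(bins_body, 1L + as.integer(floor((rel - g_start) /
         (g_end - g_start) * bins_body))),
       1L)]
  agg <- ov[, .(n_meth = sum(n_meth), n_reads = sum(n_total)),
            by = .(region, bin, context)]
  agg_all <- ov[, .(n_meth = sum(n_meth), n_reads = sum(n_total),
                    context = "ALL"),
                by = .(region, bin)]
  out <- data.table::rbindlist(list(agg, agg_all), use.names = TRUE)
  out[, level := n_meth / n_reads]
  out[, n_meth := NULL]
  out[, region := factor(region, levels = c("upstream", "body",
                                            "downstream"))]
  data.table::setorder(out, context, region, bin)
  data.table::setcolorder(out, c("region", "bin", "context", "level",
                                 "n_reads"))
  out[]
}
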