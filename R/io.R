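#' Read a reference genome from FASTA
#'
#' Sequences are uppercased and validated against the alphabet
#' `{A, C, G, T, N}`; any other letter (including non-`ACGTN` IUPAC
#' ambiguity codes) is rejected, since context classification is only
#' defined over unambiguous bases.
#'
#' @param path Path to a FASTA file.
#' @return A [Biostrings::DNAStringSet] in file order.
#' @export
read_genome <- function(path) {
  if (!file.exists(path)) {
    stop("genome FASTA not found: ", path, call. = FALSE)
  }
  seqs <- Biostrings::readDNAStringSet(path)
  if (length(seqs) == 0L) {
    stop("empty FASTA: ", path, call. = FALSE)
  }
  if (any(Biostrings::width(seqs) == 0L)) {
    stop("FASTA contains a zero-length sequence: ", path, call. = FALSE)
  }
  ## readDNAStringSet normalises case; restrict the alphabet here
  bad <- setdiff(Biostrings::uniqueLetters(seqs), c("A", "C", "G", "T", "N"))
  if (length(bad)) {
    stop("genome contains letters outside {A,C,G,T,N}: ",
         paste(bad, collapse = ","), call. = FALSE)
  }
  ## strip FASTA description lines down to the sequence identifier
  names(seqs) <- sub("\\s.*$", "", names(seqs))
  seqs
}

#' Read a per-cytosine methylation count table
#'
#' The table is the six-column "CX report" dialect: chromosome, 1-based
#' position of the cytosine, strand, methylated read count, unmethylated
#' read count, sequence context.  A seventh column (e.g. the
#' trinucleotide) is tolerated and ignored.  Rows with zero total
#' coverage are retained: they are needed for feature coverage
#' accounting even though their methylation level is undefined.
#'
#' @param path Path to a tab-separated file without header.
#' @return A `data.table` with columns `chrom`, `pos`, `strand`,
#'   `n_meth`, `n_total`, `context`.
#' @export
read_cx_table <- function(path) {
  if (!file.exists(path)) {
    stop("CX table not found: ", path, call. = FALSE)
  }
  dt <- data.table::fread(path, header = FALSE, sep = "\t")
  if (ncol(dt) == 7L) dt <- dt[, 1:6]
  if (ncol(dt) != 6L) {
    stop("CX table must have 6 (or 7) tab-separated columns, found ",
         ncol(dt), call. = FALSE)
  }
  data.table::setnames(dt, c("chrom", "pos", "strand", "n_meth",
                             "n_unmeth", "context"))
  dt[, chrom := as.character(chrom)]
  dt[, strand := as.character(strand)]
  dt[, context := as.character(context)]
  if (!is.numeric(dt$pos) || !is.numeric(dt$n_meth) ||
      !is.numeric(dt$n_unmeth)) {
    stop("CX table: pos and count columns must be numeric", call. = FALSE)
  }
  if (any(dt$n_meth < 0) || any(dt$n_unmeth < 0)) {
    stop("CX table contains negative read counts", call. = FALSE)
  }
  bad_strand <- setdiff(unique(dt$strand), c("+", "-"))
  if (length(bad_strand)) {
    stop("CX table: strand must be '+' or '-', found: ",
         paste(bad_strand, collapse = ","), call. = FALSE)
  }
  bad_ctx <- setdiff(unique(dt$context), c("CG", "CHG", "CHH"))
  if (length(bad_ctx)) {
    stop("CX table: context must be CG/CHG/CHH, found: ",
         paste(bad_ctx, collapse = ","), call. = FALSE)
  }
  dt[, pos := as.integer(pos)]
  dt[, n_meth := as.integer(n_meth)]
  dt[, n_total := n_meth + as.integer(n_unmeth)]
  dt[, n_unmeth := NULL]
  data.table::setcolorder(dt, c("chrom", "pos", "strand", "n_meth",
                                "n_total", "context"))
  dt[]
}

#' Write a per-cytosine methylation count table
#'
#' Inverse of [read_cx_table()]: writes the six-column CX dialect.
#'
#' @param records `data.table` with `chrom`, `pos`, `strand`, `n_meth`,
#'   `n_total`, `context`.
#' @param path Output path.
#' @export
write_cx_table <- function(records, path) {
  out <- records[, .(chrom, pos, strand, n_meth,
                     n_unmeth = n_total - n_meth, context)]
  data.table::fwrite(out, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

#' Write DMRs as a BED6 file
#'
#' BED is 0-based half-open; internal coordinates are 1-based inclusive,
#' so `start` is decremented at this boundary.  The name field is
#' `context:direction` and the score is the capped Phred-scaled q-value
#' `min(1000, round(-10 log10 q))`.
#'
#' @param dmrs DMR table from [call_dmrs()] (needs `chrom`, `start`,
#'   `end`, `context`, `direction`, `q_value`).
#' @param path Output path.
#' @export
write_dmr_bed <- function(dmrs, path) {
  if (nrow(dmrs) == 0L) {
    writeLines(character(0), path)
    return(invisible(path))
  }
  bed <- data.table::data.table(
    chrom = dmrs$chrom,
    start = dmrs$start - 1L,
    end   = dmrs$end,
    name  = paste(dmrs$context, dmrs$direction, sep = ":"),
    score = pmin(1000, round(-10 * log10(pmax(dmrs$q_value, 1e-300)))),
    strand = "."
  )
  data.table::setorder(bed, chrom, start)
  data.table::fwrite(bed, path, sep = "\t", col.names = FALSE)
  invisible(path)
}

## ---- gene annotation -------------------------------------------------

#' Read gene models from GFF3/GTF and expand them into genomic elements
#'
#' Parses gene, transcript, exon, CDS and (if present) UTR features and
#' expands every gene into the eight element classes used throughout
#' the pipeline: `gene_body`, `exon`, `intron`, `CDS`, `utr5`, `utr3`,
#' `upstream_2k`, `downstream_2k`.  Introns are derived as gaps between
#' sorted exons; when UTR rows are absent they are derived as
#' exon minus CDS, split 5'/3' by the gene's strand.  One transcript per
#' gene is assumed; if several are present the first is used.
#'
#' @param path GFF3 or GTF file (format detected by `rtracklayer`).
#' @param flank_size Width in bp of the upstream/downstream flanks
#'   (default 2000).
#' @param seqlengths Optional named integer vector of chromosome
#'   lengths used to clip flanks at chromosome ends.
#' @return A `data.table` of elements with columns `gene_id`, `chrom`,
#'   `strand`, `element`, `start`, `end` (1-based inclusive), carrying
#'   the per-gene span table as attribute `"genes"`.
#' @export
read_annotation <- function(path, flank_size = 2000L, seqlengths = NULL) {
  if (!file.exists(path)) {
    stop("annotation file not found: ", path, call. = FALSE)
  }
  gr <- rtracklayer::import(path)
  df <- data.table::data.table(
    chrom  = as.character(GenomicRanges::seqnames(gr)),
    start  = GenomicRanges::start(gr),
    end    = GenomicRanges::end(gr),
    strand = as.character(GenomicRanges::strand(gr)),
    type   = as.character(gr$type)
  )
  mc <- S4Vectors::mcols(gr)
  if ("gene_id" %in% names(mc) && !("Parent" %in% names(mc))) {
    ## GTF dialect: gene_id attached to every row
    df[, gene_id := as.character(mc$gene_id)]
  } else {
    ## GFF3 dialect: resolve Parent chains (feature -> mRNA -> gene)
    id <- if ("ID" %in% names(mc)) as.character(mc$ID) else NA_character_
    parent <- if ("Parent" %in% names(mc)) {
      vapply(as.list(mc$Parent), function(p) {
        if (length(p)) p[[1]] else NA_character_
      }, character(1))
    } else {
      rep(NA_character_, nrow(df))
    }
    df[, `:=`(id = id, parent = parent)]
    gene_ids <- df[type == "gene", id]
    tx2gene <- df[type %in% c("mRNA", "transcript") & parent %in% gene_ids,
                  setNames(parent, id)]
    df[, gene_id := data.table::fifelse(
      type == "gene", id,
      data.table::fifelse(parent %in% gene_ids, parent,
                          unname(tx2gene[parent])))]
    df[, c("id", "parent") := NULL]
  }

  genes <- df[type == "gene",
              .(gene_id, chrom, strand, start, end)]
  if (nrow(genes) == 0L) {
    ## GTF without explicit gene rows: infer spans from exons
    genes <- df[type == "exon",
                .(start = min(start), end = max(end),
                  chrom = chrom[1L], strand = strand[1L]),
                by = gene_id]
    data.table::setcolorder(genes,
                            c("gene_id", "chrom", "strand", "start", "end"))
  }
  if (anyNA(genes$gene_id)) {
    stop("annotation: gene rows without an identifier", call. = FALSE)
  }
  bad_strand <- setdiff(unique(genes$strand), c("+", "-"))
  if (length(bad_strand)) {
    stop("annotation: unknown gene strand: ",
         paste(bad_strand, collapse = ","), call. = FALSE)
  }

  type_map <- c(exon = "exon", CDS = "CDS",
                five_prime_UTR = "utr5", three_prime_UTR = "utr3",
                five_prime_utr = "utr5", three_prime_utr = "utr3")
  feats <- df[type %in% names(type_map) & gene_id %in% genes$gene_id,
              .(gene_id, type = unname(type_map[type]), start, end)]

  build_gene_elements(genes, feats, flank_size = flank_size,
                      seqlengths = seqlengths)
}

#' @keywords internal
#' @noRd
.interval_gaps <- function(starts, ends) {
  ## gaps between sorted non-overlapping intervals
  o <- order(starts)
  s <- starts[o]; e <- ends[o]
  if (length(s) < 2L) {
    return(data.table::data.table(start = integer(0), end = integer(0)))
  }
  gs <- e[-length(e)] + 1L
  ge <- s[-1L] - 1L
  keep <- gs <= ge
  data.table::data.table(start = gs[keep], end = ge[keep])
}

#' @keywords internal
#' @noRd
.interval_subtract <- function(a, b) {
  ## a, b: data.tables with start/end, both sorted non-overlapping.
  ## Returns a \ b.
  if (nrow(a) == 0L || nrow(b) == 0L) return(a[, .(start, end)])
  out_s <- integer(0); out_e <- integer(0)
  b <- b[order(start)]
  for (i in seq_len(nrow(a))) {
    s <- a$start[i]; e <- a$end[i]
    for (j in seq_len(nrow(b))) {
      bs <- b$start[j]; be <- b$end[j]
      if (be < s || bs > e) next
      if (bs > s) { out_s <- c(out_s, s); out_e <- c(out_e, bs - 1L) }
      s <- max(s, be + 1L)
      if (s > e) break
    }
    if (s <= e) { out_s <- c(out_s, s); out_e <- c(out_e, e) }
  }
  data.table::data.table(start = out_s, end = out_e)
}

#' Expand gene spans and sub-features into the eight element classes
#'
#' Shared by [read_annotation()] and the simulator so that both paths
#' produce identical element tables.
#'
#' @param genes `data.table` with `gene_id`, `chrom`, `strand`, `start`,
#'   `end`.
#' @param features `data.table` with `gene_id`, `type` in
#'   `{exon, CDS, utr5, utr3}`, `start`, `end`.
#' @param flank_size Flank width in bp.
#' @param seqlengths Optional named chromosome lengths for clipping.
#' @return Element `data.table`; see [read_annotation()].
#' @export
build_gene_elements <- function(genes, features, flank_size = 2000L,
                                seqlengths = NULL) {
  genes <- data.table::as.data.table(genes)
  features <- data.table::as.data.table(features)
  rows <- vector("list", nrow(genes))
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    if (g$start > g$end) {
      stop("gene ", g$gene_id, ": start > end", call. = FALSE)
    }
    f <- features[gene_id == g$gene_id]
    ex <- f[type == "exon"][order(start)]
    if (nrow(ex)) {
      if (any(ex$start < g$start | ex$end > g$end)) {
        stop("gene ", g$gene_id, ": exon outside gene span", call. = FALSE)
      }
      if (nrow(ex) > 1L && any(ex$start[-1L] <= ex$end[-nrow(ex)])) {
        stop("gene ", g$gene_id, ": overlapping exons", call. = FALSE)
      }
    }
    cds <- f[type == "CDS"][order(start)]
    utr5 <- f[type == "utr5"][order(start)]
    utr3 <- f[type == "utr3"][order(start)]
    if (nrow(cds) && nrow(utr5) == 0L && nrow(utr3) == 0L && nrow(ex)) {
      ## derive UTRs as exon - CDS, split by strand
      non_cds <- .interval_subtract(ex[, .(start, end)],
                                    cds[, .(start, end)])
      if (nrow(non_cds)) {
        cds_lo <- min(cds$start); cds_hi <- max(cds$end)
        left  <- non_cds[end < cds_lo]
        right <- non_cds[start > cds_hi]
        if (g$strand == "+") { utr5 <- left;  utr3 <- right }
        else                 { utr5 <- right; utr3 <- left }
      }
    }
    introns <- if (nrow(ex)) .interval_gaps(ex$start, ex$end) else
      data.table::data.table(start = integer(0), end = integer(0))

    seqlen <- if (!is.null(seqlengths) && g$chrom %in% names(seqlengths))
      as.integer(seqlengths[[g$chrom]]) else NA_integer_
    if (g$strand == "+") {
      up <- c(g$start - flank_size, g$start - 1L)
      dn <- c(g$end + 1L, g$end + flank_size)
    } else {
      up <- c(g$end + 1L, g$end + flank_size)
      dn <- c(g$start - flank_size, g$start - 1L)
    }
    clip <- function(iv) {
      s <- max(1L, as.integer(iv[1]))
      e <- if (is.na(seqlen)) as.integer(iv[2]) else
        min(seqlen, as.integer(iv[2]))
      if (s > e) NULL else c(s, e)
    }
    up <- clip(up); dn <- clip(dn)

    el <- list(
      data.table::data.table(element = "gene_body",
                             start = g$start, end = g$end),
      if (nrow(ex)) data.table::data.table(element = "exon",
                                           start = ex$start, end = ex$end),
      if (nrow(introns)) data.table::data.table(element = "intron",
                                                start = introns$start,
                                                end = introns$end),
      if (nrow(cds)) data.table::data.table(element = "CDS",
                                            start = cds$start,
                                            end = cds$end),
      if (nrow(utr5)) data.table::data.table(element = "utr5",
                                             start = utr5$start,
                                             end = utr5$end),
      if (nrow(utr3)) data.table::data.table(element = "utr3",
                                             start = utr3$start,
                                             end = utr3$end),
      if (!is.null(up)) data.table::data.table(element = "upstream_2k",
                                               start = up[1], end = up[2]),
      if (!is.null(dn)) data.table::data.table(element = "downstream_2k",
                                               start = dn[1], end = dn[2])
    )
    el <- data.table::rbindlist(el[!vapply(el, is.null, logical(1))])
    el[, `:=`(gene_id = g$gene_id, chrom = g$chrom, strand = g$strand)]
    rows[[i]] <- el
  }
  out <- data.table::rbindlist(rows)
  data.table::setcolorder(out, c("gene_id", "chrom", "strand",
                                 "element", "start", "end"))
  data.table::setattr(out, "genes", genes)
  out[]
}

#' Per-gene span table attached to an element table
#' @param elements Output of [read_annotation()] or
#'   [build_gene_elements()].
#' @return `data.table` with `gene_id`, `chrom`, `strand`, `start`, `end`.
#' @export
gene_spans <- function(elements) {
  g <- attr(elements, "genes")
  if (is.null(g)) {
    g <- elements[element == "gene_body",
                  .(gene_id, chrom, strand, start, end)]
  }
  g
}

#' Write gene models as GFF3
#'
#' Emits gene, mRNA, exon and CDS rows with ID/Parent attributes; UTRs
#' are left implicit (derived on read as exon minus CDS).
#'
#' @param genes Gene span table (`gene_id`, `chrom`, `strand`, `start`,
#'   `end`).
#' @param features Feature table (`gene_id`, `type` in `{exon, CDS}`,
#'   `start`, `end`).
#' @param path Output path.
#' @export
write_gff3 <- function(genes, features, path) {
  genes <- data.table::as.data.table(genes)
  features <- data.table::as.data.table(features)
  lines <- c("##gff-version 3")
  for (i in seq_len(nrow(genes))) {
    g <- genes[i]
    tx <- paste0(g$gene_id, ".t1")
    lines <- c(lines,
      paste(g$chrom, "dmrscan", "gene", g$start, g$end, ".", g$strand,
            ".", paste0("ID=", g$gene_id), sep = "\t"),
      paste(g$chrom, "dmrscan", "mRNA", g$start, g$end, ".", g$strand,
            ".", paste0("ID=", tx, ";Parent=", g$gene_id), sep = "\t"))
    f <- features[gene_id == g$gene_id][order(start)]
    for (j in seq_len(nrow(f))) {
      ph <- if (f$type[j] == "CDS") "0" else "."
      lines <- c(lines,
        paste(g$chrom, "dmrscan", f$type[j], f$start[j], f$end[j], ".",
              g$strand, ph, paste0("Parent=", tx), sep = "\t"))
    }
  }
  writeLines(lines, path)
  invisible(path)
}
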