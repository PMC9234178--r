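## Synthetic WGBS study generator.
##
## Emulates the structure of a two-group, three-replicate invertebrate
## WGBS + RNA-seq design: a mosaic methylome with low overall
## methylation concentrated in the CG context, ~25x per-strand
## coverage, ~1% bisulfite non-conversion, planted 200 bp differential
## windows in one group, and gene-body-methylation-coupled expression.

#' Simulation configuration
#'
#' Defaults describe the study conditions the pipeline is validated
#' under: context means CG 12.76%, CHG 0.77%, CHH 0.78%; Poisson
#' per-strand coverage with mean 25; 1% non-conversion (conversion
#' efficiency 99%); two groups of three replicates; 50 planted
#' hypermethylated CG windows of 200 bp with level shift +0.4 in the
#' case group; negative gene-body-methylation/expression coupling.
#'
#' @param seed Integer seed; fully determines every output.
#' @param genome_length Length of the main chromosome in bp.
#' @param gc_fraction Genome GC content in `[0, 1]`.
#' @param n_genes Number of non-overlapping genes to place.
#' @param mean_gene_length Mean gene length in bp.
#' @param flank_size Up/downstream flank width in bp.
#' @param base_level Named per-context mean methylation levels.
#' @param beta_concentration Concentration of the Beta site-level
#'   jitter around each context mean (larger = tighter).
#' @param mean_depth Mean per-site per-strand read depth (Poisson).
#' @param nonconversion_rate Probability an unmethylated C escapes
#'   conversion and reads as methylated.
#' @param n_replicates Replicates per group.
#' @param group_labels Two group names; planted shifts and expression
#'   shifts apply to the second (case) group.
#' @param planted_dmrs `data.frame` with columns `context`, `width`
#'   (multiple of `window_size`), `delta` (signed level shift), `count`.
#'   Use `NULL` or zero counts for a null simulation.
#' @param plant_min_sites Minimum context sites a tile must contain to
#'   host a planted window.
#' @param grid_offset Offset in bp of planted windows from the tiling
#'   grid (default 0: grid-aligned, which makes recall accounting
#'   unambiguous).
#' @param window_size Tiling grid in bp.
#' @param control_length Length of an unmethylated spike-in control
#'   contig (0 disables it).
#' @param control_name Name of the control contig.
#' @param coupling Signed strength of the gene-body-methylation effect
#'   on log expression.
#' @param dmr_expr_log2fc Absolute log2 expression shift applied in the
#'   case group to genes overlapping a planted window; its sign is
#'   `sign(coupling) * sign(delta)`.
#' @param expression_baseline Baseline expected count per gene.
#' @param expression_dispersion Negative-binomial dispersion
#'   (variance = mu + dispersion * mu^2).
#' @return A `sim_config` list.
#' @export
sim_config <- function(seed = 1L,
                       genome_length = 1e6,
                       gc_fraction = 0.35,
                       n_genes = 120L,
                       mean_gene_length = 1500L,
                       flank_size = 2000L,
                       base_level = c(CG = 0.1276, CHG = 0.0077,
                                      CHH = 0.0078),
                       beta_concentration = 20,
                       mean_depth = 25,
                       nonconversion_rate = 0.01,
                       n_replicates = 3L,
                       group_labels = c("ctrl", "case"),
                       planted_dmrs = data.frame(context = "CG",
                                                 width = 200L,
                                                 delta = 0.4,
                                                 count = 50L),
                       plant_min_sites = 5L,
                       grid_offset = 0L,
                       window_size = 200L,
                       control_length = 5000L,
                       control_name = "unmeth_spikein",
                       coupling = -0.5,
                       dmr_expr_log2fc = 3,
                       expression_baseline = 200,
                       expression_dispersion = 0.05) {
  cfg <- list(seed = as.integer(seed), genome_length = genome_length,
              gc_fraction = gc_fraction, n_genes = as.integer(n_genes),
              mean_gene_length = mean_gene_length,
              flank_size = as.integer(flank_size),
              base_level = base_level,
              beta_concentration = beta_concentration,
              mean_depth = mean_depth,
              nonconversion_rate = nonconversion_rate,
              n_replicates = as.integer(n_replicates),
              group_labels = group_labels,
              planted_dmrs = planted_dmrs,
              plant_min_sites = as.integer(plant_min_sites),
              grid_offset = as.integer(grid_offset),
              window_size = as.integer(window_size),
              control_length = as.integer(control_length),
              control_name = control_name,
              coupling = coupling,
              dmr_expr_log2fc = dmr_expr_log2fc,
              expression_baseline = expression_baseline,
              expression_dispersion = expression_dispersion)
  stopifnot(cfg$gc_fraction >= 0, cfg$gc_fraction <= 1,
            all(cfg$base_level >= 0), all(cfg$base_level <= 1),
            cfg$nonconversion_rate >= 0, cfg$nonconversion_rate < 1,
            cfg$mean_depth > 0, cfg$n_replicates >= 1,
            length(cfg$group_labels) == 2L,
            cfg$group_labels[1] != cfg$group_labels[2],
            all(c("CG", "CHG", "CHH") %in% names(cfg$base_level)))
  class(cfg) <- "sim_config"
  cfg
}

#' Simulate a genome with a non-overlapping gene annotation
#'
#' Bases are i.i.d. with `P(G) = P(C) = gc_fraction / 2`.  Genes (each
#' with at least two exons, a CDS and implied UTRs) are placed
#' uniformly with at least `2 * flank_size` spacing between gene
#' bodies so flanks never overlap a neighbouring gene body.  If
#' `control_length > 0` an additional contig (the unmethylated
#' spike-in) is appended.
#'
#' @param config A [sim_config()].
#' @return List with `genome` ([Biostrings::DNAStringSet]), `genes`,
#'   `features` (exon/CDS table) and `elements`
#'   (from [build_gene_elements()]).
#' @export
simulate_genome <- function(config) {
  if (config$genome_length < 10 * config$mean_gene_length) {
    stop("genome_length must be at least 10 * mean_gene_length",
         call. = FALSE)
  }
  set.seed(config$seed)
  gc <- config$gc_fraction
  prob <- c(A = (1 - gc) / 2, C = gc / 2, G = gc / 2, T = (1 - gc) / 2)
  L <- as.integer(config$genome_length)
  main <- paste(sample(names(prob), L, replace = TRUE, prob = prob),
                collapse = "")
  seqs <- c(chr1 = main)
  if (config$control_length > 0L) {
    ctl <- paste(sample(names(prob), config$control_length,
                        replace = TRUE, prob = prob), collapse = "")
    seqs <- c(seqs, setNames(ctl, config$control_name))
  }
  genome <- Biostrings::DNAStringSet(seqs)

  ## ---- place genes ----
  n <- config$n_genes
  lens <- pmax(600L, round(rgamma(n, shape = 4,
                                  scale = config$mean_gene_length / 4)))
  spacing <- 2L * config$flank_size
  starts <- integer(0)
  ends <- integer(0)
  for (i in seq_len(n)) {
    placed <- FALSE
    for (try in 1:500) {
      st <- sample.int(L - lens[i] - config$flank_size,
                       1L) + config$flank_size
      en <- st + lens[i] - 1L
      if (!length(starts) ||
          all(en + spacing < starts | st - spacing > ends)) {
        starts <- c(starts, st); ends <- c(ends, en)
        placed <- TRUE
        break
      }
    }
    if (!placed) {
      stop("could not place ", n, " non-overlapping genes; ",
           "increase genome_length or reduce n_genes", call. = FALSE)
    }
  }
  o <- order(starts)
  genes <- data.table::data.table(
    gene_id = sprintf("g%04d", seq_len(n)),
    chrom = "chr1",
    strand = sample(c("+", "-"), n, replace = TRUE),
    start = starts[o], end = ends[o])

  feats <- data.table::rbindlist(lapply(seq_len(n), function(i) {
    .gene_structure(genes$gene_id[i], genes$strand[i],
                    genes$start[i], genes$end[i])
  }))

  elements <- build_gene_elements(
    genes, feats, flank_size = config$flank_size,
    seqlengths = setNames(Biostrings::width(genome), names(genome)))
  list(genome = genome, genes = genes, features = feats,
       elements = elements)
}

#' @keywords internal
#' @noRd
.gene_structure <- function(gene_id, strand, start, end) {
  len <- end - start + 1L
  n_ex <- sample(2:5, 1L)
  while (len < 60L * (2L * n_ex - 1L) && n_ex > 2L) n_ex <- n_ex - 1L
  n_seg <- 2L * n_ex - 1L
  w <- rgamma(n_seg, shape = 1)
  seg <- 60L + floor(w / sum(w) * (len - 60L * n_seg))
  seg[n_seg] <- len - sum(seg[-n_seg])
  bounds <- cumsum(c(0L, seg))
  ex_idx <- seq(1L, n_seg, by = 2L)
  ex <- data.table::data.table(
    start = start + bounds[ex_idx],
    end = start + bounds[ex_idx + 1L] - 1L)

  ## transcript-coordinate CDS: trim UTRs off the mRNA ends
  mlen <- sum(ex$end - ex$start + 1L)
  u5 <- max(30L, round(0.10 * mlen))
  u3 <- max(30L, round(0.15 * mlen))
  if (mlen - u5 - u3 < 90L) {
    u5 <- u3 <- max(15L, floor((mlen - 90L) / 2))
  }
  cds <- .tx_to_genomic(ex, strand, u5 + 1L, mlen - u3)
  data.table::rbindlist(list(
    data.table::data.table(gene_id = gene_id, type = "exon",
                           start = ex$start, end = ex$end),
    data.table::data.table(gene_id = gene_id, type = "CDS",
                           start = cds$start, end = cds$end)))
}

#' @keywords internal
#' @noRd
.tx_to_genomic <- function(exons, strand, ts, te) {
  ## map transcript interval [ts, te] to genomic pieces through exons
  ex <- exons[order(if (strand == "+") start else -start)]
  out_s <- integer(0); out_e <- integer(0)
  cum <- 0L
  for (i in seq_len(nrow(ex))) {
    w <- ex$end[i] - ex$start[i] + 1L
    a <- cum + 1L; b <- cum + w
    oa <- max(a, ts); ob <- min(b, te)
    if (oa <= ob) {
      if (strand == "+") {
        out_s <- c(out_s, ex$start[i] + (oa - a))
        out_e <- c(out_e, ex$start[i] + (ob - a))
      } else {
        out_s <- c(out_s, ex$end[i] - (ob - a))
        out_e <- c(out_e, ex$end[i] - (oa - a))
      }
    }
    cum <- cum + w
  }
  data.table::data.table(start = out_s, end = out_e)[order(start)]
}

#' Simulate replicated bisulfite methylomes with planted DMRs
#'
#' Every cytosine gets a true level drawn from a Beta distribution
#' with its context mean (shared between groups and replicates: the
#' site's biology).  Planted windows shift the case group's true
#' level by `delta`, clipped to `[0, 1]`.  Per replicate, coverage is
#' Poisson and the observed methylated count is binomial with success
#' probability `p + (1 - p) * nonconversion_rate`, so non-conversion
#' injects false methylation signal.  Spike-in control sites are truly
#' unmethylated.
#'
#' @param genome Genome from [simulate_genome()].
#' @param config A [sim_config()].
#' @return List with `samples` (named list of cytosine record tables),
#'   `groups` (named character vector sample -> group), `truth`
#'   (planted window table: `chrom`, `start`, `end`, `context`,
#'   `delta`), and `site_levels` (per-site true levels `p_base`,
#'   `p_case`).
#' @export
simulate_methylome <- function(genome, config) {
  set.seed(config$seed + 1L)
  sites <- genome_cytosines(genome)
  N <- nrow(sites)

  ## site-level biological jitter around context means
  conc <- config$beta_concentration
  m <- config$base_level[sites$context]
  p <- numeric(N)
  pos_mask <- m > 0 & m < 1
  p[pos_mask] <- rbeta(sum(pos_mask), m[pos_mask] * conc,
                       (1 - m[pos_mask]) * conc)
  p[m >= 1] <- 1
  if (config$control_length > 0L) {
    p[sites$chrom == config$control_name] <- 0
  }
  sites[, p_base := p]

  ## plant differential windows on the tiling grid
  truth <- .plant_windows(sites, config)
  sites[, p_case := p_base]
  if (nrow(truth)) {
    for (i in seq_len(nrow(truth))) {
      hit <- sites$chrom == truth$chrom[i] &
        sites$pos >= truth$start[i] & sites$pos <= truth$end[i] &
        sites$context == truth$context[i]
      sites[hit, p_case := pmin(1, pmax(0, p_base + truth$delta[i]))]
    }
  }

  ## observe replicates
  eps <- config$nonconversion_rate
  labels <- config$group_labels
  samples <- list()
  groups <- character(0)
  for (g in 1:2) {
    p_true <- if (g == 1L) sites$p_base else sites$p_case
    p_obs <- p_true + (1 - p_true) * eps
    for (r in seq_len(config$n_replicates)) {
      nm <- paste0(labels[g], "_", r)
      depth <- rpois(N, config$mean_depth)
      meth <- rbinom(N, depth, p_obs)
      samples[[nm]] <- data.table::data.table(
        chrom = sites$chrom, pos = sites$pos, strand = sites$strand,
        n_meth = meth, n_total = depth, context = sites$context)
      groups[nm] <- labels[g]
    }
  }
  list(samples = samples, groups = groups, truth = truth,
       site_levels = sites)
}

#' @keywords internal
#' @noRd
.plant_windows <- function(sites, config) {
  empty <- data.table::data.table(chrom = character(0),
                                  start = integer(0), end = integer(0),
                                  context = character(0),
                                  delta = numeric(0))
  specs <- config$planted_dmrs
  if (is.null(specs) || nrow(specs) == 0L || all(specs$count == 0L)) {
    return(empty)
  }
  w <- config$window_size
  off <- config$grid_offset
  main <- sites[chrom != config$control_name]
  main_tiles <- main[, .(n_ctx = .N),
                     by = .(chrom, context,
                            tile = (pos - 1L - off) %/% w)]
  used <- character(0)
  out <- list()
  for (i in seq_len(nrow(specs))) {
    sp <- specs[i, ]
    if (sp$width %% w != 0L) {
      stop("planted width must be a multiple of window_size",
           call. = FALSE)
    }
    k <- sp$width %/% w
    cand <- main_tiles[context == sp$context & n_ctx >=
                         config$plant_min_sites & tile >= 0L]
    cand[, key := paste(chrom, tile)]
    cand <- cand[!(key %in% used)]
    if (k > 1L) {
      ## need k adjacent eligible tiles; restrict to runs
      cand <- cand[order(chrom, tile)]
      ok <- vapply(seq_len(nrow(cand)), function(j) {
        tiles_needed <- cand$tile[j] + seq_len(k) - 1L
        all(paste(cand$chrom[j], tiles_needed) %in% cand$key)
      }, logical(1))
      cand <- cand[ok]
    }
    if (nrow(cand) < sp$count) {
      stop("cannot place ", sp$count, " planted ", sp$context,
           " windows with >= ", config$plant_min_sites,
           " sites; enlarge the genome", call. = FALSE)
    }
    pick <- cand[sample.int(nrow(cand), sp$count)]
    used <- c(used, unlist(lapply(seq_len(nrow(pick)), function(j) {
      paste(pick$chrom[j], pick$tile[j] + seq_len(k) - 1L)
    })))
    out[[i]] <- data.table::data.table(
      chrom = pick$chrom,
      start = pick$tile * w + off + 1L,
      end = pick$tile * w + off + sp$width,
      context = sp$context,
      delta = sp$delta)
  }
  res <- data.table::rbindlist(out)
  data.table::setorder(res, chrom, start)
  res
}

#' Simulate expression counts coupled to gene-body methylation
#'
#' Expected expression is `baseline * exp(coupling * z_g)` where `z_g`
#' is the standardised true gene-body methylation, so negative coupling
#' makes highly methylated genes lowly expressed.  Genes overlapping a
#' planted window additionally receive a case-group log2 shift of
#' magnitude `dmr_expr_log2fc` with sign `sign(coupling) * sign(delta)`.
#' Counts are negative binomial.
#'
#' @param elements Element table from [simulate_genome()].
#' @param methylome Output of [simulate_methylome()].
#' @param config A [sim_config()].
#' @return `data.table` with `gene_id`, `length_bp` (mRNA length) and
#'   one count column per sample; attribute `"groups"` maps samples to
#'   groups.
#' @export
simulate_expression <- function(elements, methylome, config) {
  set.seed(config$seed + 2L)
  genes <- gene_spans(elements)
  sl <- methylome$site_levels

  ## true gene-body methylation (site mean of true levels)
  sp <- data.table::copy(genes)
  data.table::setkey(sp, chrom, start, end)
  s <- sl[, .(chrom, start = pos, end = pos, p_base)]
  ov <- data.table::foverlaps(s, sp, type = "within",
                              by.x = c("chrom", "start", "end"),
                              nomatch = NULL)
  gbm <- ov[, .(gbm = mean(p_base)), by = gene_id]
  g <- merge(genes, gbm, by = "gene_id", all.x = TRUE)
  g[is.na(gbm), gbm := 0]
  z <- as.numeric(scale(g$gbm))
  if (anyNA(z)) z <- rep(0, nrow(g))  # constant methylation
  mu <- config$expression_baseline * exp(config$coupling * z)

  ## case-group shift for genes overlapping a planted window
  shift <- rep(0, nrow(g))
  if (nrow(methylome$truth)) {
    tr <- data.table::copy(methylome$truth)
    data.table::setkey(tr, chrom, start, end)
    hit <- data.table::foverlaps(
      g[, .(chrom, start, end, gene_id)], tr,
      by.x = c("chrom", "start", "end"), nomatch = NULL)
    if (nrow(hit)) {
      dsign <- hit[, .(s = sign(delta[1L])), by = gene_id]
      idx <- match(dsign$gene_id, g$gene_id)
      shift[idx] <- sign(config$coupling) * dsign$s *
        config$dmr_expr_log2fc
    }
  }

  ## mRNA length from exons
  exons <- elements[element == "exon",
                    .(length_bp = sum(end - start + 1L)), by = gene_id]
  g <- merge(g, exons, by = "gene_id", all.x = TRUE)
  g[is.na(length_bp), length_bp := end - start + 1L]

  out <- g[, .(gene_id, length_bp)]
  groups <- character(0)
  disp <- config$expression_dispersion
  for (gi in 1:2) {
    lab <- config$group_labels[gi]
    mu_g <- if (gi == 1L) mu else mu * 2^shift
    for (r in seq_len(config$n_replicates)) {
      nm <- paste0(lab, "_", r)
      sf <- runif(1, 0.8, 1.2)
      out[[nm]] <- rnbinom(nrow(g), mu = mu_g * sf, size = 1 / disp)
      groups[nm] <- lab
    }
  }
  data.table::setattr(out, "groups", groups)
  out[]
}

#' Write a complete simulated study to disk
#'
#' Writes `genome.fa`, `genes.gff3`, one `<sample>.cx.tsv` per
#' replicate, `expression.tsv`, `truth_dmrs.tsv` and a `config.json`
#' echo, the on-disk layout [run_pipeline()] consumes.
#'
#' @param config A [sim_config()].
#' @param dir Output directory (created if needed).
#' @return Invisibly, the list of generated objects.
#' @export
write_simulation <- function(config, dir) {
  dir.create(dir, recursive = TRUE, showWarnings = FALSE)
  gen <- simulate_genome(config)
  met <- simulate_methylome(gen$genome, config)
  expr <- simulate_expression(gen$elements, met, config)

  Biostrings::writeXStringSet(gen$genome, file.path(dir, "genome.fa"))
  write_gff3(gen$genes, gen$features, file.path(dir, "genes.gff3"))
  for (nm in names(met$samples)) {
    write_cx_table(met$samples[[nm]],
                   file.path(dir, paste0(nm, ".cx.tsv")))
  }
  data.table::fwrite(expr, file.path(dir, "expression.tsv"), sep = "\t")
  data.table::fwrite(met$truth, file.path(dir, "truth_dmrs.tsv"),
                     sep = "\t")
  cfg <- unclass(config)
  cfg$planted_dmrs <- as.data.frame(cfg$planted_dmrs)
  jsonlite::write_json(cfg, file.path(dir, "config.json"),
                       auto_unbox = TRUE, digits = NA)
  invisible(list(genome = gen, methylome = met, expression = expr))
}
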