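small_cfg <- function(...) {
  sim_config(genome_length = 1.2e5, n_genes = 8L,
             control_length = 2000L,
             planted_dmrs = data.frame(context = "CG", width = 200L,
                                       delta = 0.4, count = 4L), ...)
}

test_that("sim_config validates its arguments", {
  expect_s3_class(sim_config(), "sim_config")
  expect_error(sim_config(gc_fraction = 1.2))
  expect_error(sim_config(nonconversion_rate = 1))
  expect_error(sim_config(group_labels = c("a", "a")))
  expect_error(sim_config(base_level = c(CG = 0.1, CHG = 0.01)))
})

test_that("simulated genome respects GC content and gene constraints", {
  cfg <- small_cfg(seed = 5L)
  gen <- simulate_genome(cfg)
  expect_identical(names(gen$genome), c("chr1", "unmeth_spikein"))
  expect_identical(Biostrings::width(gen$genome)[1], 120000L)
  freq <- Biostrings::alphabetFrequency(gen$genome[[1]])
  gc <- sum(freq[c("C", "G")]) / sum(freq)
  expect_lt(abs(gc - cfg$gc_fraction), 0.01)

  ## genes are sorted, non-overlapping, with 2 * flank spacing
  g <- gen$genes
  expect_identical(g$start, sort(g$start))
  if (nrow(g) > 1L) {
    expect_true(all(g$start[-1L] - g$end[-nrow(g)] > 2L * cfg$flank_size))
  }
  ## every gene has exons and a CDS inside its span
  for (id in g$gene_id) {
    f <- gen$features[gene_id == id]
    expect_true(all(c("exon", "CDS") %in% f$type))
    expect_true(all(f$start >= g[gene_id == id, start] &
                      f$end <= g[gene_id == id, end]))
  }
  ## gc extreme: an all-GC genome contains only G and C
  cfg2 <- sim_config(genome_length = 2e4, n_genes = 1L,
                     gc_fraction = 1, control_length = 0L,
                     planted_dmrs = NULL)
  freq2 <- Biostrings::alphabetFrequency(simulate_genome(cfg2)$genome[[1]])
  expect_identical(sum(freq2[c("A", "T")]), 0L)
})

test_that("the simulation is a pure function of its seed", {
  cfg <- small_cfg(seed = 9L)
  g1 <- simulate_genome(cfg); g2 <- simulate_genome(cfg)
  expect_identical(as.character(g1$genome), as.character(g2$genome))
  expect_equal(g1$genes, g2$genes)
  m1 <- simulate_methylome(g1$genome, cfg)
  m2 <- simulate_methylome(g2$genome, cfg)
  expect_equal(m1$samples, m2$samples)
  expect_equal(m1$truth, m2$truth)
  e1 <- simulate_expression(g1$elements, m1, cfg)
  e2 <- simulate_expression(g2$elements, m2, cfg)
  expect_equal(e1, e2, ignore_attr = TRUE)
  ## a different seed changes the data
  g3 <- simulate_genome(small_cfg(seed = 10L))
  expect_false(identical(as.character(g1$genome[[1]]),
                         as.character(g3$genome[[1]])))
})

test_that("planted truth windows are grid-aligned, eligible and disjoint", {
  cfg <- small_cfg(seed = 3L)
  gen <- simulate_genome(cfg)
  met <- simulate_methylome(gen$genome, cfg)
  tr <- met$truth
  expect_identical(nrow(tr), 4L)
  expect_true(all((tr$start - 1L) %% cfg$window_size == 0L))
  expect_true(all(tr$end - tr$start + 1L == 200L))
  expect_true(all(tr$chrom == "chr1"))
  ## disjoint
  o <- order(tr$start)
  expect_true(all(tr$start[o][-1L] > tr$end[o][-nrow(tr)]))
  ## each planted window holds >= plant_min_sites context sites
  sl <- met$site_levels
  for (i in seq_len(nrow(tr))) {
    n_ctx <- sl[chrom == tr$chrom[i] & pos >= tr$start[i] &
                  pos <= tr$end[i] & context == tr$context[i], .N]
    expect_gte(n_ctx, cfg$plant_min_sites)
    ## and the case level is shifted by delta (clipped)
    in_win <- sl[chrom == tr$chrom[i] & pos >= tr$start[i] &
                   pos <= tr$end[i] & context == tr$context[i]]
    expect_equal(in_win$p_case,
                 pmin(1, pmax(0, in_win$p_base + tr$delta[i])))
  }
  ## outside planted windows the two group levels coincide
  key <- rep(FALSE, nrow(sl))
  for (i in seq_len(nrow(tr))) {
    key <- key | (sl$chrom == tr$chrom[i] & sl$pos >= tr$start[i] &
                    sl$pos <= tr$end[i])
  }
  expect_equal(sl$p_case[!key], sl$p_base[!key])
})

test_that("a clean null with zero levels and conversion yields no signal", {
  cfg <- sim_config(genome_length = 3e4, n_genes = 2L,
                    base_level = c(CG = 0, CHG = 0, CHH = 0),
                    nonconversion_rate = 0, planted_dmrs = NULL,
                    control_length = 0L)
  gen <- simulate_genome(cfg)
  met <- simulate_methylome(gen$genome, cfg)
  expect_identical(nrow(met$truth), 0L)
  for (s in met$samples) expect_identical(sum(s$n_meth), 0L)
})

test_that("spike-in sites are truly unmethylated; only non-conversion reads", {
  cfg <- small_cfg(seed = 2L)
  gen <- simulate_genome(cfg)
  met <- simulate_methylome(gen$genome, cfg)
  expect_identical(
    unique(met$site_levels[chrom == "unmeth_spikein", p_base]), 0)
  pooled <- data.table::rbindlist(met$samples)[chrom == "unmeth_spikein"]
  obs_rate <- sum(pooled$n_meth) / sum(pooled$n_total)
  expect_lt(abs(obs_rate - cfg$nonconversion_rate), 0.005)
})

test_that("realised context levels track the configured means", {
  cfg <- small_cfg(seed = 8L)
  gen <- simulate_genome(cfg)
  met <- simulate_methylome(gen$genome, cfg)
  sl <- met$site_levels[chrom == "chr1"]
  for (ctx in c("CG", "CHG", "CHH")) {
    expect_lt(abs(mean(sl[context == ctx, p_base]) -
                    cfg$base_level[[ctx]]), 0.01)
  }
})

test_that("expression is negatively coupled to gene-body methylation", {
  cfg <- sim_config(seed = 4L, genome_length = 1e6, n_genes = 120L,
                    n_replicates = 1L, planted_dmrs = NULL,
                    control_length = 0L)
  gen <- simulate_genome(cfg)
  met <- simulate_methylome(gen$genome, cfg)
  expr <- simulate_expression(gen$elements, met, cfg)
  sl <- met$site_levels
  gsp <- gene_spans(gen$elements)
  gbm <- vapply(seq_len(nrow(gsp)), function(i) {
    mean(sl[chrom == gsp$chrom[i] & pos >= gsp$start[i] &
              pos <= gsp$end[i], p_base])
  }, numeric(1))
  counts <- rowMeans(as.matrix(
    expr[, setdiff(names(expr), c("gene_id", "length_bp")),
         with = FALSE]))
  rho <- cor(gbm, counts[match(gsp$gene_id, expr$gene_id)],
             method = "spearman")
  expect_lt(rho, -0.2)
  ## groups attribute labels every sample column
  expect_identical(sort(names(attr(expr, "groups"))),
                   sort(setdiff(names(expr), c("gene_id", "length_bp"))))
})

test_that("zero coupling leaves expression independent of methylation", {
  cfg <- sim_config(seed = 6L, genome_length = 2e6, n_genes = 220L,
                    n_replicates = 1L, coupling = 0,
                    planted_dmrs = NULL, control_length = 0L)
  gen <- simulate_genome(cfg)
  met <- simulate_methylome(gen$genome, cfg)
  expr <- simulate_expression(gen$elements, met, cfg)
  sl <- met$site_levels
  gsp <- gene_spans(gen$elements)
  gbm <- vapply(seq_len(nrow(gsp)), function(i) {
    mean(sl[chrom == gsp$chrom[i] & pos >= gsp$start[i] &
              pos <= gsp$end[i], p_base])
  }, numeric(1))
  counts <- rowMeans(as.matrix(
    expr[, setdiff(names(expr), c("gene_id", "length_bp")),
         with = FALSE]))
  rho <- cor(gbm, counts[match(gsp$gene_id, expr$gene_id)],
             method = "spearman")
  expect_lt(abs(rho), 0.1)
})

test_that("write_simulation lays out a complete, loadable study", {
  cfg <- small_cfg(seed = 7L)
  dir <- withr::local_tempdir()
  write_simulation(cfg, dir)
  expected <- c("genome.fa", "genes.gff3", "expression.tsv",
                "truth_dmrs.tsv", "config.json",
                paste0(rep(c("ctrl", "case"), each = 3), "_",
                       1:3, ".cx.tsv"))
  expect_true(all(file.exists(file.path(dir, expected))))
  g <- read_genome(file.path(dir, "genome.fa"))
  expect_identical(names(g), c("chr1", "unmeth_spikein"))
  r <- read_cx_table(file.path(dir, "ctrl_1.cx.tsv"))
  expect_true(all(c("CG", "CHG", "CHH") %in% r$context))
  ## CX rows are exactly the genome's context-classifiable cytosines
  expect_identical(nrow(r), nrow(genome_cytosines(g)))
})
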