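## End-to-end orchestration: load -> call -> profile -> dmr -> annotate
## -> deg -> integrate, with a deterministic run manifest.

#' Build a pipeline configuration
#'
#' @param genome Path to the reference FASTA.
#' @param annotation Path to the GFF3/GTF annotation.
#' @param samples Named character vector/list of per-sample CX table
#'   paths.
#' @param groups Named character vector mapping sample name -> group
#'   label.
#' @param comparison Comparison label of the form `"A_vs_B"`; `up`
#'   (DMRs, DEGs) means higher in A.
#' @param expression Optional path to a count table (`gene_id`,
#'   `length_bp`, one column per sample; sample names must match
#'   `groups`).
#' @param control_contig Optional name of an unmethylated spike-in
#'   contig used to estimate non-conversion (otherwise the CHH proxy
#'   is used).
#' @param term_map Optional path to a two-column TSV (`term_id`,
#'   `gene_id`) for DMG enrichment.
#' @param contexts Contexts to scan (default all four criteria sets).
#' @param window DMR window width in bp.
#' @param min_coverage Minimum pooled per-group reads for a site to
#'   count as covered in the window scan.
#' @param flank_size Flank width for gene elements.
#' @param site_alpha FDR threshold for per-site methylation calls.
#' @param test Window test, `"fisher"` or `"ttest"`.
#' @return A `pipeline_config` list.
#' @export
pipeline_config <- function(genome, annotation, samples, groups,
                            comparison, expression = NULL,
                            control_contig = NULL, term_map = NULL,
                            contexts = c("CG", "CHG", "CHH", "ALL_C"),
                            window = 200L, min_coverage = 1L,
                            flank_size = 2000L, site_alpha = 0.05,
                            test = "fisher") {
  samples <- unlist(samples)
  groups <- unlist(groups)
  if (!setequal(names(samples), names(groups))) {
    stop("samples and groups must name the same sample set",
         call. = FALSE)
  }
  parts <- strsplit(comparison, "_vs_", fixed = TRUE)[[1]]
  if (length(parts) != 2L || parts[1] == parts[2]) {
    stop("comparison must look like 'A_vs_B' with distinct groups",
         call. = FALSE)
  }
  if (!all(parts %in% groups)) {
    stop("comparison groups not present in the sample sheet: ",
         comparison, call. = FALSE)
  }
  for (p in samples) {
    if (!file.exists(p)) stop("missing CX table: ", p, call. = FALSE)
  }
  cfg <- list(genome = genome, annotation = annotation,
              samples = samples, groups = groups,
              comparison = comparison, expression = expression,
              control_contig = control_contig, term_map = term_map,
              contexts = contexts, window = as.integer(window),
              min_coverage = as.integer(min_coverage),
              flank_size = as.integer(flank_size),
              site_alpha = site_alpha, test = test)
  class(cfg) <- "pipeline_config"
  cfg
}

#' Pipeline configuration for a simulated study directory
#'
#' Reads the `config.json` echo written by [write_simulation()] and
#' points every path at the directory.  The comparison is oriented
#' case-vs-control, so `up` means hypermethylated (or up-regulated) in
#' the case group.
#'
#' @param dir Directory produced by [write_simulation()].
#' @param ... Overrides passed on to [pipeline_config()].
#' @return A `pipeline_config`.
#' @export
simulation_pipeline_config <- function(dir, ...) {
  cfg <- jsonlite::read_json(file.path(dir, "config.json"),
                             simplifyVector = TRUE)
  labels <- cfg$group_labels
  sample_names <- as.vector(outer(labels, seq_len(cfg$n_replicates),
                                  paste, sep = "_"))
  samples <- setNames(file.path(dir, paste0(sample_names, ".cx.tsv")),
                      sample_names)
  groups <- setNames(sub("_[0-9]+$", "", sample_names), sample_names)
  pipeline_config(
    genome = file.path(dir, "genome.fa"),
    annotation = file.path(dir, "genes.gff3"),
    samples = samples, groups = groups,
    comparison = paste0(labels[2], "_vs_", labels[1]),
    expression = file.path(dir, "expression.tsv"),
    control_contig = if (cfg$control_length > 0) cfg$control_name,
    flank_size = cfg$flank_size, window = cfg$window_size, ...)
}

#' Run the full methylome analysis pipeline
#'
#' Executes the stages in dependency order, writes all result tables
#' under `out_dir` with fixed names, and records a manifest with the
#' configuration hash and per-stage row counts.  Identical
#' configuration and inputs produce byte-identical outputs.
#'
#' @param config A [pipeline_config()].
#' @param out_dir Output directory (created if needed).
#' @return Invisibly, a list with every stage result and the manifest.
#' @export
run_pipeline <- function(config, out_dir) {
  dir.create(out_dir, recursive = TRUE, showWarnings = FALSE)
  manifest <- list()
  note <- function(stage, rows) {
    manifest[[length(manifest) + 1L]] <<- list(stage = stage,
                                               rows = rows)
  }
  fail <- function(stage, msg) {
    stop("pipeline stage '", stage, "' failed: ", msg, call. = FALSE)
  }

  ## ---- load ----
  genome <- tryCatch(read_genome(config$genome),
                     error = function(e) fail("load",
                                              conditionMessage(e)))
  elements <- tryCatch(
    read_annotation(config$annotation, flank_size = config$flank_size,
                    seqlengths = setNames(Biostrings::width(genome),
                                          names(genome))),
    error = function(e) fail("load", conditionMessage(e)))
  records <- lapply(names(config$samples), function(nm) {
    r <- tryCatch(read_cx_table(config$samples[[nm]]),
                  error = function(e) fail("load",
                                           conditionMessage(e)))
    unknown <- setdiff(unique(r$chrom), names(genome))
    if (length(unknown)) {
      fail("load", paste0("sample ", nm, ": chromosomes absent from ",
                          "the genome: ",
                          paste(unknown, collapse = ",")))
    }
    r
  })
  names(records) <- names(config$samples)
  note("load", sum(vapply(records, nrow, integer(1))))

  parts <- strsplit(config$comparison, "_vs_", fixed = TRUE)[[1]]
  samp_a <- names(config$groups)[config$groups == parts[1]]
  samp_b <- names(config$groups)[config$groups == parts[2]]

  ## ---- calling ----
  pooled_all <- .pool_replicates(records)
  nc <- estimate_nonconversion(pooled_all,
                               control_contig = config$control_contig)
  main <- if (!is.null(config$control_contig)) {
    ctl <- config$control_contig
    pooled_all[chrom != ctl]
  } else {
    pooled_all
  }
  summaries <- lapply(names(records), function(nm) {
    r <- records[[nm]]
    if (!is.null(config$control_contig)) {
      r <- r[chrom != config$control_contig]
    }
    s <- summarize_methylome(r, nonconversion_rate = nc$rate)
    list(sample = nm, group = unname(config$groups[[nm]]),
         level_overall = s$level_overall,
         level_by_context = as.list(s$level_by_context),
         n_sites_by_context = as.list(s$n_sites_by_context))
  })
  jsonlite::write_json(
    list(nonconversion_rate = nc$rate, bce = nc$bce,
         samples = summaries),
    file.path(out_dir, "methylome_summary.json"),
    auto_unbox = TRUE, digits = NA)
  note("calling", length(summaries))

  ## ---- profiles ----
  fl <- assign_sites_to_elements(main, elements)
  mg <- metagene_profile(main, elements,
                         flank_size = config$flank_size)
  data.table::fwrite(fl, file.path(out_dir, "feature_levels.tsv"),
                     sep = "\t")
  data.table::fwrite(mg, file.path(out_dir, "metagene.tsv"),
                     sep = "\t")
  note("profiles", nrow(fl))

  ## ---- dmr ----
  tiles <- tile_windows(genome, window = config$window)
  if (!is.null(config$control_contig)) {
    tiles <- tiles[chrom != config$control_contig]
  }
  group_a <- records[samp_a]
  group_b <- records[samp_b]
  all_dmrs <- list()
  n_windows <- 0L
  for (ctx in config$contexts) {
    w <- window_stats(group_a, group_b, tiles, context = ctx,
                      min_coverage = config$min_coverage,
                      test = config$test)
    res <- call_dmrs(w, criteria = dmr_criteria(ctx),
                     return_windows = TRUE)
    data.table::fwrite(res$windows,
                       file.path(out_dir,
                                 paste0("windows_", ctx, ".tsv")),
                       sep = "\t")
    data.table::fwrite(res$dmrs,
                       file.path(out_dir, paste0("dmrs_", ctx, ".tsv")),
                       sep = "\t")
    write_dmr_bed(res$dmrs,
                  file.path(out_dir, paste0("dmrs_", ctx, ".bed")))
    all_dmrs[[ctx]] <- res$dmrs
    n_windows <- n_windows + nrow(res$windows)
  }
  dmrs <- data.table::rbindlist(all_dmrs)
  note("dmr", nrow(dmrs))

  ## ---- dmg ----
  asg <- assign_dmrs_to_genes(dmrs, elements)
  data.table::fwrite(asg$dmgs, file.path(out_dir, "dmgs.tsv"),
                     sep = "\t")
  data.table::fwrite(asg$intergenic,
                     file.path(out_dir, "intergenic_dmrs.tsv"),
                     sep = "\t")
  enr <- NULL
  if (!is.null(config$term_map)) {
    tm <- data.table::fread(config$term_map, header = TRUE)
    universe <- gene_spans(elements)$gene_id
    enr <- enrich_terms(unique(asg$dmgs$gene_id), universe, tm)
    data.table::fwrite(enr, file.path(out_dir, "enrichment.tsv"),
                       sep = "\t")
  }
  note("dmg", nrow(asg$dmgs))

  ## ---- deg ----
  degs <- NULL; fpkm <- NULL
  if (!is.null(config$expression)) {
    counts <- data.table::fread(config$expression, header = TRUE)
    expr_a <- intersect(samp_a, names(counts))
    expr_b <- intersect(samp_b, names(counts))
    if (!length(expr_a) || !length(expr_b)) {
      fail("deg", "expression table has no samples from a comparison group")
    }
    fpkm <- compute_fpkm(counts)
    degs <- call_degs(counts, expr_a, expr_b)
    data.table::fwrite(fpkm, file.path(out_dir, "fpkm.tsv"),
                       sep = "\t")
    data.table::fwrite(degs, file.path(out_dir, "degs.tsv"),
                       sep = "\t")
    note("deg", nrow(degs))
  } else {
    note("deg", 0L)
  }

  ## ---- integration ----
  integ <- NULL
  if (!is.null(degs)) {
    classes <- classify_methylation_groups(fl)
    sample_cols <- setdiff(names(fpkm), c("gene_id", "length_bp"))
    expr_means <- data.table::data.table(
      gene_id = fpkm$gene_id,
      mean_fpkm = rowMeans(as.matrix(fpkm[, sample_cols,
                                          with = FALSE])))
    corr <- correlate_methylation_expression(fl, expr_means)
    integ <- intersect_dmg_deg(asg$dmgs, degs)
    data.table::fwrite(classes,
                       file.path(out_dir, "methylation_classes.tsv"),
                       sep = "\t")
    data.table::fwrite(corr, file.path(out_dir, "correlation.tsv"),
                       sep = "\t")
    data.table::fwrite(integ$records,
                       file.path(out_dir, "integration_records.tsv"),
                       sep = "\t")
    data.table::fwrite(integ$counts,
                       file.path(out_dir, "concordance.tsv"),
                       sep = "\t")
    note("integration", nrow(integ$records))
  } else {
    note("integration", 0L)
  }

  ## ---- manifest ----
  cfg_json <- jsonlite::toJSON(unclass(config), auto_unbox = TRUE,
                               digits = NA)
  cfg_path <- file.path(out_dir, "config_echo.json")
  writeLines(cfg_json, cfg_path)
  man <- list(package = "dmrscan",
              version = as.character(utils::packageVersion("dmrscan")),
              comparison = config$comparison,
              config_md5 = unname(tools::md5sum(cfg_path)),
              stages = manifest)
  jsonlite::write_json(man, file.path(out_dir, "manifest.json"),
                       auto_unbox = TRUE, digits = NA)

  invisible(list(summaries = summaries, nonconversion = nc,
                 feature_levels = fl, metagene = mg, dmrs = dmrs,
                 dmgs = asg$dmgs, intergenic = asg$intergenic,
                 enrichment = enr, fpkm = fpkm, degs = degs,
                 integration = integ, manifest = man))
}
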